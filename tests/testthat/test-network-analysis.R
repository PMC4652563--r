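test_that("degree centrality follows the (s-1) normalization", {
  tri <- undirected_net(c("A\tB", "B\tC", "A\tC"))
  expect_equal(centrality_report(tri)$dc, rep(1, 3))

  path <- undirected_net(c("A\tB", "B\tC"))
  rep <- centrality_report(path)
  expect_equal(rep$dc[rep$set == "B"], 1)
  expect_equal(rep$dc[rep$set != "B"], c(0.5, 0.5))

  # directed 3-clique: total DC reaches 2, in/out each 1
  clique <- directed_net(c("A\tB", "B\tA", "A\tC", "C\tA", "B\tC", "C\tB"))
  crep <- centrality_report(clique)
  expect_equal(crep$dc, rep(2, 3))
  expect_equal(crep$in_dc, rep(1, 3))
  expect_equal(crep$out_dc, rep(1, 3))

  lonely <- undirected_net(character())
  lonely$nodes <- tibble::tibble(set = "A", collection = "x")
  expect_error(centrality_report(lonely), "2 nodes")
})

test_that("degree sums tie out against edge counts", {
  set.seed(3)
  nodes <- sprintf("N%02d", 1:12)
  pairs <- t(combn(nodes, 2))
  pick <- pairs[sample(nrow(pairs), 25), ]
  und <- undirected_net(paste(pick[, 1], pick[, 2], sep = "\t"))
  expect_equal(sum(centrality_report(und)$degree), 2 * 25)
  dir <- directed_net(paste(pick[, 1], pick[, 2], sep = "\t"))
  drep <- centrality_report(dir)
  expect_equal(sum(drep$in_degree), 25)
  expect_equal(sum(drep$out_degree), 25)
})

test_that("closeness averages shortest paths over reachable nodes", {
  path <- undirected_net(c("A\tB", "B\tC"))
  rep <- centrality_report(path)
  expect_equal(rep$closeness[rep$set == "B"], 1)
  expect_equal(rep$closeness[rep$set == "A"], 2 / 3)

  chain <- directed_net(c("A\tB", "B\tC"))
  crep <- centrality_report(chain)
  expect_equal(crep$closeness[crep$set == "A"], 2 / 3)
  expect_equal(crep$closeness[crep$set == "C"], 0)
  expect_true(crep$unreachable[crep$set == "C"])

  star <- undirected_net(c("HUB\tL1", "HUB\tL2", "HUB\tL3", "HUB\tL4"))
  srep <- centrality_report(star)
  expect_equal(srep$closeness[srep$set == "HUB"], 1)
})

test_that("betweenness matches closed forms and path enumeration", {
  path <- undirected_net(c("A\tB", "B\tC"))
  rep <- centrality_report(path)
  expect_equal(rep$betweenness[rep$set == "B"], 1)

  tri <- undirected_net(c("A\tB", "B\tC", "A\tC"))
  expect_equal(centrality_report(tri)$betweenness, rep(0, 3))

  # 4-cycle: opposite corners have two tied shortest paths
  cyc <- undirected_net(c("A\tB", "B\tC", "C\tD", "D\tA"))
  expect_equal(centrality_report(cyc)$betweenness, rep(0.5, 4))

  # random small graphs against the brute-force path-enumeration oracle
  set.seed(9)
  for (rep_i in 1:5) {
    nodes <- sprintf("N%d", 1:6)
    pairs <- t(combn(nodes, 2))
    pick <- pairs[runif(nrow(pairs)) < 0.5, , drop = FALSE]
    if (nrow(pick) == 0L) next
    lines <- paste(pick[, 1], pick[, 2], sep = "\t")
    net <- undirected_net(lines)
    got <- centrality_report(net)
    ora <- betweenness_oracle(net$edges, sort(net$nodes$set), FALSE)
    expect_equal(got$betweenness, unname(ora[got$set]), tolerance = 1e-9)

    dnet <- directed_net(lines)
    dgot <- centrality_report(dnet)
    dora <- betweenness_oracle(dnet$edges, sort(dnet$nodes$set), TRUE)
    expect_equal(dgot$betweenness, unname(dora[dgot$set]), tolerance = 1e-9)
  }
})

test_that("normalized edge proportion applies (r/s) * (g/g_i)", {
  # normalization factor 1 when the collection covers the whole universe
  expect_equal(normalized_edge_proportion(100, 10, 500, 500), 10)
  expect_equal(normalized_edge_proportion(123, 7, 500, 500, digits = NULL),
               123 / 7)
  expect_error(normalized_edge_proportion(0, 10, 5, 10), "positive")
  expect_error(normalized_edge_proportion(10, 10, 50, 10), "exceed")
})

test_that("degree correlation equals the textbook Pearson formula", {
  a <- undirected_net(c("A\tB", "B\tC", "C\tD", "A\tD", "A\tC"))
  expect_equal(degree_correlation(a, a)$r, 1)

  set.seed(13)
  nodes <- sprintf("N%02d", 1:10)
  pairs <- t(combn(nodes, 2))
  mk <- function() {
    pick <- pairs[sample(nrow(pairs), 18), , drop = FALSE]
    undirected_net(paste(pick[, 1], pick[, 2], sep = "\t")) |>
      (\(n) { n$nodes <- tibble::tibble(set = nodes, collection = "x"); n })()
  }
  na <- mk(); nb <- mk()
  got <- degree_correlation(na, nb)
  da <- centrality_report(na)$dc; db <- centrality_report(nb)$dc
  r_formula <- sum((da - mean(da)) * (db - mean(db))) /
    sqrt(sum((da - mean(da))^2) * sum((db - mean(db))^2))
  expect_equal(got$r, r_formula, tolerance = 1e-12)
  expect_equal(got$r_squared, r_formula^2, tolerance = 1e-12)

  # zero variance is an explicit error, not NaN
  tri <- undirected_net(c("A\tB", "B\tC", "A\tC"))
  expect_error(degree_correlation(tri, tri), "variance")
})

test_that("network comparison reports shared-edge percentages", {
  a <- undirected_net(c("A\tB", "B\tC", "C\tD"))
  b <- undirected_net(c("A\tB", "B\tC", "A\tD"))
  b$nodes <- a$nodes
  cmp <- compare_networks(a, b)
  expect_equal(cmp$shared, 2L)
  expect_equal(cmp$pct_union, 100 * 2 / 4)
  expect_equal(cmp$pct_reference, 100 * 2 / 3)

  same <- compare_networks(a, a)
  expect_equal(same$pct_union, 100)
  expect_equal(same$pct_reference, 100)

  c_net <- undirected_net(c("X\tY"))
  disjoint <- compare_networks(a, c_net)
  expect_equal(disjoint$pct_union, 0)

  # symmetric in union percentage, asymmetric in reference percentage
  expect_equal(compare_networks(b, a)$pct_union, cmp$pct_union)
  expect_error(compare_networks(directed_net("A\tB"), a), "undirected")
})

test_that("random overlap null is seeded and honest about edge cases", {
  ref0 <- undirected_net("A\tB")
  ref0$edges <- ref0$edges[0, ]
  nodes <- sprintf("V%02d", 1:20)
  ref0$nodes <- tibble::tibble(set = nodes, collection = "x")
  null0 <- random_overlap_null(nodes, 30, ref0, reps = 50, seed = 4)
  expect_true(all(null0$overlaps == 0))

  ref <- undirected_net(c("V01\tV02", "V03\tV04", "V05\tV06"))
  ref$nodes <- tibble::tibble(set = nodes, collection = "x")
  n1 <- random_overlap_null(nodes, 40, ref, reps = 100, seed = 42)
  n2 <- random_overlap_null(nodes, 40, ref, reps = 100, seed = 42)
  expect_identical(n1$overlaps, n2$overlaps)
  n3 <- random_overlap_null(nodes, 40, ref, reps = 100, seed = 43)
  expect_false(identical(n1$overlaps, n3$overlaps))

  expect_error(random_overlap_null(nodes, 1000, ref, reps = 10, seed = 1),
               "exceeds")
  expect_error(random_overlap_null(nodes, 10, ref, reps = 0, seed = 1),
               "reps")
})

test_that("the Fisher table for observed overlap uses the C(n,2) universe", {
  nodes <- sprintf("V%02d", 1:12)
  a <- undirected_net(c("V01\tV02", "V03\tV04", "V05\tV06", "V07\tV08"))
  b <- undirected_net(c("V01\tV02", "V03\tV04", "V09\tV10"))
  a$nodes <- b$nodes <- tibble::tibble(set = nodes, collection = "x")
  res <- random_overlap_null(nodes, 4, b, observed = a, reps = 20, seed = 1)
  total <- choose(12, 2)
  expect_equal(res$fisher_p,
               fisher_exact(2, 2, 1, total - 4 - 3 + 2),
               tolerance = 1e-12)
})
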