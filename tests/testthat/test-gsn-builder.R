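test_that("co-membership parameters count directly", {
  p <- comembership_params(c("A", "B", "C"), c("B", "C", "D"), 10)
  expect_equal(unclass(p)[c("N", "n", "K", "k")],
               list(N = 10, n = 3, K = 3, k = 2))
  expect_equal(comembership_params(c("A"), c("B"), 10)$k, 0)
  p2 <- comembership_params(sprintf("G%d", 1:5), sprintf("G%d", 1:5), 20)
  expect_equal(unclass(p2)[c("N", "n", "K", "k")],
               list(N = 20, n = 5, K = 5, k = 5))
  expect_error(comembership_params(sprintf("G%d", 1:5), "G1", 3), "universe")
})

test_that("M-GSN keeps only BH-significant co-membership edges", {
  # pairwise disjoint sets never connect
  disjoint <- gsc_from_list(list(S1 = c("A", "B"), S2 = c("C", "D"),
                                 S3 = c("E", "F")))
  expect_equal(nrow(build_mgsn(disjoint)$edges), 0L)

  # two identical 10-gene sets in a 1000-gene universe: a single edge whose
  # p equals the closed-form product for drawing all 10 marked genes
  uni <- sprintf("U%04d", 1:1000)
  twin <- gsc_from_list(list(T1 = uni[1:10], T2 = uni[1:10]), universe = uni)
  net <- build_mgsn(twin)
  expect_equal(nrow(net$edges), 1L)
  p_closed <- prod((10:1) / (1000:991))
  expect_equal(net$edges$p, p_closed, tolerance = 1e-10)

  # one-set collection: a valid network with zero edges
  single <- build_mgsn(gsc_from_list(list(ONLY = c("A", "B"))))
  expect_equal(nrow(single$edges), 0L)
  expect_equal(nrow(single$nodes), 1L)
})

test_that("M-GSN edges re-verify against the raw collection", {
  set.seed(5)
  uni <- sprintf("G%03d", 1:400)
  sets <- lapply(setNames(1:12, sprintf("S%02d", 1:12)), function(i) {
    sample(uni[1:120], sample(8:25, 1))
  })
  gsc <- gsc_from_list(sets, universe = uni)
  net <- build_mgsn(gsc)
  expect_true(all(net$edges$q <= net$alpha))
  for (i in seq_len(nrow(net$edges))) {
    e <- net$edges[i, ]
    prm <- comembership_params(sets[[e$gs1]], sets[[e$gs2]], 400)
    expect_equal(e$k, prm$k)
    expect_equal(e$p, hypergeom_pvalue(prm), tolerance = 1e-12)
  }
  # symmetry of the model: the test table never depends on pair orientation
  swapped <- comembership_params(sets$S02, sets$S01, 400)
  forward <- comembership_params(sets$S01, sets$S02, 400)
  expect_equal(hypergeom_pvalue(swapped), hypergeom_pvalue(forward))
})

test_that("regulatory parameters implement unique-part counting", {
  reg <- regnet_from_pairs(c("A", "B", "C", "D", "F"),
                           c("D", "E", "D", "A", "G"))
  prm <- regulatory_params(c("A", "B", "C"), c("C", "D", "E"), reg)
  expect_equal(unclass(prm)[c("N", "n", "K", "k")],
               list(N = 5, n = 2, K = 2, k = 2))

  # identical membership is untestable
  expect_null(regulatory_params(c("A", "B"), c("A", "B"), reg))
  # empty regulation network is untestable
  empty <- regulation_network(tibble::tibble(source = character(),
                                             target = character()))
  expect_null(regulatory_params(c("A"), c("B"), empty))
})

test_that("a regulation touching neither unique part only changes N", {
  gs1 <- c("A", "B"); gs2 <- c("C", "D")
  reg1 <- regnet_from_pairs(c("A", "B"), c("C", "D"))
  reg2 <- regnet_from_pairs(c("A", "B", "X"), c("C", "D", "Y"))
  p1 <- regulatory_params(gs1, gs2, reg1)
  p2 <- regulatory_params(gs1, gs2, reg2)
  expect_equal(p1$k, p2$k)
  expect_equal(p2$N, p1$N + 1L)
  expect_equal(p1[c("n", "K")], p2[c("n", "K")])
})

test_that("R-GSN recovers planted regulation and respects symmetry", {
  # perfectly symmetric regulation between two sets: both directions or none
  gsc <- gsc_from_list(list(P = c("A", "B"), Q = c("C", "D")),
                       universe = c("A", "B", "C", "D", sprintf("Z%d", 1:50)))
  sym <- regnet_from_pairs(c("A", "B", "C", "D", "Z1", "Z2"),
                           c("C", "D", "A", "B", "Z2", "Z3"))
  net <- build_rgsn(gsc, sym)
  has_pq <- any(net$edges$gs1 == "P" & net$edges$gs2 == "Q")
  has_qp <- any(net$edges$gs1 == "Q" & net$edges$gs2 == "P")
  expect_equal(has_pq, has_qp)

  # empty regulation input: zero edges
  empty <- regulation_network(tibble::tibble(source = character(),
                                             target = character()))
  expect_equal(nrow(build_rgsn(gsc, empty)$edges), 0L)
})

test_that("directed networks collapse correctly to undirected", {
  net <- directed_net(c("A\tB", "B\tA", "A\tC"))
  net$alpha <- 0.05
  und <- to_undirected(net)
  expect_false(und$directed)
  keys <- paste(und$edges$gs1, und$edges$gs2)
  expect_setequal(keys, c("A B", "A C"))
  expect_error(to_undirected(und), "already undirected")

  # all edges reciprocal: 2m directed -> m undirected
  recip <- directed_net(c("A\tB", "B\tA", "C\tD", "D\tC"))
  expect_equal(nrow(to_undirected(recip)$edges), 2L)

  # no reciprocal pairs: count unchanged
  chain <- directed_net(c("A\tB", "B\tC"))
  expect_equal(nrow(to_undirected(chain)$edges), 2L)
})

test_that("reciprocal collapse keeps the smaller p-value", {
  gsc <- gsc_from_list(list(P = c("A", "B", "C"), Q = c("D", "E")),
                       universe = c("A", "B", "C", "D", "E",
                                    sprintf("Z%d", 1:20)))
  src <- c("A", "A", "B", "C", "D", "Z1", "Z2", "Z3")
  tgt <- c("D", "E", "D", "E", "A", "Z2", "Z3", "Z4")
  net <- build_rgsn(gsc, regnet_from_pairs(src, tgt), alpha = 0.9)
  if (sum(net$edges$gs1 %in% c("P", "Q")) == 2L) {
    und <- to_undirected(net)
    expect_equal(und$edges$p, min(net$edges$p))
  }
  expect_s3_class(to_undirected(net), "gsn")
})

test_that("exclusive network subtracts unordered edge sets", {
  base <- undirected_net(c("A\tB", "A\tC"))
  base$alpha <- 0.05
  sub <- undirected_net("A\tB")
  excl <- exclusive_network(base, sub)
  expect_equal(paste(excl$edges$gs1, excl$edges$gs2), "A C")

  # subtracting a superset empties the network
  all_of_it <- undirected_net(c("A\tB", "A\tC", "B\tC"))
  expect_equal(nrow(exclusive_network(base, all_of_it)$edges), 0L)

  # disjoint edge sets: base is preserved
  other <- undirected_net("X\tY")
  expect_equal(nrow(exclusive_network(base, other)$edges), 2L)

  dir_net <- directed_net("A\tB")
  expect_error(exclusive_network(dir_net, sub), "undirected")
})

test_that("edge sets are nested across FDR levels", {
  spec <- fixture_spec(universe_size = 400, n_sets = 15, overlap = 0.3,
                       background_rate = 0.002, seed = 21,
                       planted = tibble::tibble(gs1 = "SET001",
                                                gs2 = "SET002"))
  gsc <- generate_collection(spec)
  sim <- generate_regulations(gsc, spec)
  key <- function(net) paste(net$edges$gs1, net$edges$gs2)
  m01 <- build_mgsn(gsc, alpha = 0.01); m05 <- build_mgsn(gsc, alpha = 0.05)
  expect_true(all(key(m01) %in% key(m05)))
  r01 <- build_rgsn(gsc, sim$regnet, alpha = 0.01)
  r05 <- build_rgsn(gsc, sim$regnet, alpha = 0.05)
  expect_true(all(key(r01) %in% key(r05)))
})
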