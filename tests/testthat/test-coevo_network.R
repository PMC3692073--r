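test_that("edge retention is strictly greater than the threshold", {
  sc <- fake_scores(c(7.0, 6.5, 6.4))
  net <- build_network(sc, threshold = 6.5)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$z, 7.0)
  expect_equal(nrow(net$nodes), 3)  # isolated nodes are retained

  none <- build_network(fake_scores(c(1, 2, 3)), threshold = 6.5)
  expect_equal(nrow(none$edges), 0)
  expect_equal(nrow(none$nodes), 3)
})

test_that("cumulative MI sums incident retained z-scores", {
  # node 1 has incident z {7.0, 8.5}; the 6.0 pair is not retained
  sc <- fake_scores(c(7.0, 8.5, 6.0))  # pairs (1,2), (1,3), (2,3)
  net <- build_network(sc, threshold = 6.5)
  cmi <- cumulative_mi(net)
  expect_equal(unname(cmi["1"]), 15.5)
  expect_equal(unname(cmi["2"]), 7.0)
  expect_equal(unname(cmi["3"]), 8.5)
  expect_equal(unname(net$nodes$cmi), unname(cmi[as.character(net$nodes$position)]))

  # isolated node -> 0
  iso <- build_network(fake_scores(c(7, NA, NA, NA, NA, NA), n_pos = 4), 6.5)
  expect_equal(unname(cumulative_mi(iso)["4"]), 0)
})

test_that("handshake identity: sum of cMI = 2 * sum of retained z", {
  set.seed(33)
  zv <- runif(45, 0, 12)  # 10 positions
  net <- build_network(fake_scores(zv), threshold = 6.5)
  expect_equal(sum(cumulative_mi(net)), 2 * sum(net$edges$z),
               tolerance = 1e-12)
  # brute-force incidence sum
  for (p in net$nodes$position) {
    inc <- sum(net$edges$z[net$edges$position_i == p]) +
      sum(net$edges$z[net$edges$position_j == p])
    expect_equal(unname(cumulative_mi(net)[as.character(p)]), inc)
  }
})

test_that("proximity MI averages neighbor cMI within the radius", {
  net <- build_network(fake_scores(rep(0, 6), n_pos = 4), threshold = 6.5)
  net$nodes$cmi <- c(0, 10, 20, 30)
  map <- structure(list(
    pairs = data.frame(column = 1:4, ref_pos = 1:4, res_index = 1:4,
                       pdb_number = 1:4, pdb_label = as.character(1:4)),
    coverage = 1, chain_id = "A"), class = "seqstruct_map")
  d <- matrix(10, 4, 4); diag(d) <- 0
  d[1, 2:4] <- d[2:4, 1] <- c(3, 4, 5)  # node 1 is within 5 A of all others
  pmi <- proximity_mi(net, map, d, radius = 5)
  expect_equal(unname(pmi["1"]), 20)  # mean(10, 20, 30)
  expect_equal(unname(pmi["2"]), 0)   # only node 1 in range, cMI 0

  # no neighbor within radius -> missing
  far <- matrix(100, 4, 4); diag(far) <- 0
  expect_true(all(is.na(proximity_mi(net, map, far, radius = 5))))

  # include_self folds the node's own cMI into the average
  pmi_self <- proximity_mi(net, map, d, radius = 5, include_self = TRUE)
  expect_equal(unname(pmi_self["1"]), mean(c(0, 10, 20, 30)))

  # unmapped positions are missing
  map$pairs <- map$pairs[-2, ]
  pmi2 <- proximity_mi(net, map, d, radius = 5)
  expect_true(is.na(pmi2["2"]))
})

test_that("percentile bands split 5/25/70 with ties promoted upward", {
  set.seed(44)
  zv <- sample(seq(7, 17, length.out = 100))  # 100 distinct retained values
  net <- build_network(fake_scores(zv, n_pos = 15), threshold = 6.5)
  expect_equal(nrow(net$edges), 100)
  b <- percentile_bands(net)
  expect_equal(sum(b == "top5"), 5)
  expect_equal(sum(b == "mid70_95"), 25)
  expect_equal(sum(b == "low"), 70)
  expect_equal(net$edges$band, b)
  # nested consistency
  expect_gt(min(net$edges$z[b == "top5"]), max(net$edges$z[b == "mid70_95"]))
  expect_gt(min(net$edges$z[b == "mid70_95"]), max(net$edges$z[b == "low"]))

  # 20 distinct edges -> exactly 1 in the top band
  net20 <- build_network(fake_scores(seq(7, 8, length.out = 20), n_pos = 7),
                         threshold = 6.5)
  expect_equal(sum(percentile_bands(net20) == "top5"), 1)

  # all-equal z: everything promoted to top5; single edge is top5
  neteq <- build_network(fake_scores(rep(9, 10), n_pos = 5), 6.5)
  expect_true(all(percentile_bands(neteq) == "top5"))
  net1 <- build_network(fake_scores(7), 6.5)
  expect_equal(percentile_bands(net1), "top5")
})

test_that("filters restrict nodes and edges as documented", {
  set.seed(55)
  zv <- runif(45, 5, 15)
  net <- build_network(fake_scores(zv), threshold = 6.5)

  # top-N with N >= edge count is the identity on edges
  expect_equal(filter_network(net, top_n = 1000)$edges, net$edges)
  top3 <- filter_network(net, top_n = 3)
  expect_equal(nrow(top3$edges), 3)
  expect_equal(top3$edges$z, sort(net$edges$z, decreasing = TRUE)[1:3])
  expect_setequal(top3$nodes$position,
                  unique(c(top3$edges$position_i, top3$edges$position_j)))

  # sequence separation: fake positions are 1..10, so separation >= 9 keeps
  # at most the (1,10) pair
  far <- filter_network(net, separation = c(9, Inf))
  expect_true(all(abs(far$edges$position_j - far$edges$position_i) >= 9))

  # cMI node filter against a brute-force scan
  thr <- stats::median(net$nodes$cmi)
  f <- filter_network(net, cmi = c(thr, Inf))
  expect_setequal(f$nodes$position,
                  net$nodes$position[net$nodes$cmi >= thr])
  expect_true(all(f$edges$position_i %in% f$nodes$position &
                    f$edges$position_j %in% f$nodes$position))

  # contradictory ranges give an empty network, not an error
  empty <- filter_network(net, cmi = c(10, 5))
  expect_equal(nrow(empty$nodes), 0)
  expect_equal(nrow(empty$edges), 0)
})

test_that("neighborhoods: first neighbors and connected components", {
  # two components: a triangle (1,2,3) and an edge (4,5); 6 isolated
  z <- matrix(NA_real_, 6, 6)
  z[1, 2] <- z[1, 3] <- z[2, 3] <- 8
  z[4, 5] <- 9
  z[lower.tri(z)] <- t(z)[lower.tri(z)]
  sc <- fake_scores(numeric(0), n_pos = 6)
  sc$z <- z; sc$mi_raw <- z; sc$mi_apc <- z
  net <- build_network(sc, threshold = 6.5)

  iso <- neighborhood(net, 6, "first_neighbors")
  expect_equal(iso$nodes$position, 6)
  expect_equal(nrow(iso$edges), 0)

  fn <- neighborhood(net, 2, "first_neighbors")
  expect_setequal(fn$nodes$position, c(1, 2, 3))

  for (start in 1:3) {
    cc <- neighborhood(net, start, "connected_component")
    expect_setequal(cc$nodes$position, oracle_component(net$edges, start))
    expect_setequal(cc$nodes$position, c(1, 2, 3))
  }
  cc45 <- neighborhood(net, 5, "connected_component")
  expect_setequal(cc45$nodes$position, c(4, 5))

  expect_error(neighborhood(net, 99), "unknown node")
})

test_that("node-level filtering commutes with neighborhood extraction", {
  set.seed(66)
  net <- build_network(fake_scores(runif(45, 6, 14)), threshold = 6.5)
  # keep node 1 passing so the neighborhood seed exists on both paths
  thr <- min(net$nodes$cmi[net$nodes$position == 1],
             stats::quantile(net$nodes$cmi, 0.3))
  a <- filter_network(neighborhood(net, 1, "first_neighbors"),
                      cmi = c(thr, Inf))
  b <- neighborhood(filter_network(net, cmi = c(thr, Inf)), 1,
                    "first_neighbors")
  expect_equal(a$nodes, b$nodes)
})
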