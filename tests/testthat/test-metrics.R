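# Network measures against brute-force oracles and hand-computed cases.

test_that("global efficiency: complete, disconnected and path-graph cases", {
  comp <- matrix(1, 5, 5); diag(comp) <- 0
  expect_equal(global_efficiency(comp, "binary"), 1)
  expect_equal(global_efficiency(matrix(0, 2, 2), "binary"), 0)
  path4 <- matrix(0, 4, 4); path4[cbind(1:3, 2:4)] <- 1
  path4 <- path4 + t(path4)
  expect_equal(global_efficiency(path4, "binary"),
               mean(c(1, 1, 1, 1 / 2, 1 / 2, 1 / 3)))
  expect_error(global_efficiency(matrix(0, 1, 1), "binary"), "2 nodes")
})

test_that("local efficiency: triangle is 1, star is 0", {
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  expect_equal(local_efficiency(tri, "binary")$per_node, rep(1, 3),
               ignore_attr = TRUE)
  star <- matrix(0, 5, 5); star[1, 2:5] <- 1; star <- star + t(star)
  expect_equal(local_efficiency(star, "binary")$mean, 0)
})

test_that("efficiencies match Floyd-Warshall oracles on random graphs", {
  for (rep in 1:30) {
    n <- sample(5:12, 1)
    W <- rand_graph(n, runif(1, 0.25, 0.8), weighted = rep %% 2 == 0,
                    seed = 400 + rep)
    for (v in c("weighted", "binary")) {
      expect_equal(global_efficiency(W, v),
                   oracle_global_eff(W, v == "weighted"), tolerance = 1e-10)
      expect_equal(local_efficiency(W, v)$per_node,
                   oracle_local_eff(W, v == "weighted"), tolerance = 1e-10,
                   ignore_attr = TRUE)
    }
  }
})

test_that("weighted distances agree with igraph on an independent route", {
  W <- rand_graph(15, 0.4, TRUE, seed = 41)
  len <- matrix(0, 15, 15)
  len[W > 0] <- 1 / W[W > 0]
  ig <- igraph::graph_from_adjacency_matrix(len, mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  d_ig <- igraph::distances(ig, weights = igraph::E(ig)$weight)
  d_us <- neurogenet:::graph_distances(W, "weighted")
  expect_equal(unname(d_us), unname(d_ig), tolerance = 1e-10)
})

test_that("adding an edge never decreases binary global efficiency", {
  set.seed(42)
  W <- rand_graph(10, 0.3, FALSE, seed = 42)
  e0 <- global_efficiency(W, "binary")
  miss <- which(W == 0 & upper.tri(W))
  for (idx in sample(miss, 5)) {
    W2 <- W
    W2[idx] <- 1
    W2[cbind(col(W)[idx], row(W)[idx])] <- 1
    expect_gte(global_efficiency(W2, "binary"), e0 - 1e-12)
  }
})

test_that("participation: by-hand cases and the oracle", {
  # all edges inside own module -> 0
  cl <- matrix(0, 6, 6); cl[1:3, 1:3] <- 1; cl[4:6, 4:6] <- 1; diag(cl) <- 0
  pc <- participation_coefficient(cl, rep(1:2, each = 3), "binary")
  expect_equal(unname(pc$per_node), rep(0, 6))
  # degree-4 node split evenly across 2 modules -> 0.5
  W <- matrix(0, 5, 5)
  W[1, 2:5] <- 1; W <- W + t(W)
  labs <- c(1, 1, 1, 2, 2)   # node 1: 2 edges in module 1, 2 in module 2
  pc2 <- participation_coefficient(W, labs, "binary")
  expect_equal(unname(pc2$per_node[1]), 0.5)
  # equal strength to each of M modules -> 1 - 1/M
  M <- 4
  W3 <- matrix(0, M + 1, M + 1); W3[1, 2:(M + 1)] <- 0.7; W3 <- W3 + t(W3)
  pc3 <- participation_coefficient(W3, c(1, seq_len(M) + 1), "weighted")
  expect_equal(unname(pc3$per_node[1]), 1 - 1 / (M + 0))
  # oracle on random graphs; values bounded by 1 - 1/M_max
  for (rep in 1:10) {
    W4 <- rand_graph(11, 0.5, TRUE, seed = 430 + rep)
    labs4 <- sample(1:3, 11, replace = TRUE)
    pc4 <- participation_coefficient(W4, labs4, "weighted")
    expect_equal(unname(pc4$per_node), oracle_participation(W4, labs4, TRUE),
                 tolerance = 1e-10)
    expect_true(all(pc4$per_node >= 0 & pc4$per_node <= 1 - 1 / 3 + 1e-12))
    # invariant to uniform weight rescaling
    pc5 <- participation_coefficient(3.7 * W4, labs4, "weighted")
    expect_equal(pc4$per_node, pc5$per_node, tolerance = 1e-12)
  }
})

test_that("node 1 spread over M modules formula", {
  # hub with equal strength to each of M = 5 modules: P = 1 - 1/5
  W <- matrix(0, 6, 6); W[1, 2:6] <- 2; W <- W + t(W)
  pc <- participation_coefficient(W, c(2, 1:5), "weighted")
  expect_equal(unname(pc$per_node[1]), 1 - 1 / 5)
})

test_that("measure suite emits every cell and matches binary on unit weights", {
  set.seed(44)
  ts <- matrix(rnorm(120 * 24), 120, 24)
  r <- correlation_matrix(ts)
  st <- build_stack(r, seq(0.1, 0.3, by = 0.1))
  part <- louvain(st$weighted[[3]], seed = 1)
  m <- measure_suite(st, part, variants = c("weighted", "binary"),
                     modularity_seeds = 1:3)
  n_mod <- part$n_modules
  # per density and variant: 3 whole-brain + 2 * n_mod module rows
  expect_equal(nrow(m), 3 * 2 * (3 + 2 * n_mod))
  expect_true(all(is.finite(m$value)))
  # binary curves equal weighted curves when retained weights are exactly 1
  bin <- st$binary[[2]]
  stb <- structure(list(raw = bin, densities = c(0.1, 0.2),
                        weighted = list(st$binary[[1]], bin),
                        binary = list(st$binary[[1]], bin)),
                   class = "conn_stack")
  mw <- measure_suite(stb, part, variants = "weighted",
                      measures = c("global_efficiency", "local_efficiency"))
  mb <- measure_suite(stb, part, variants = "binary",
                      measures = c("global_efficiency", "local_efficiency"))
  expect_equal(mw$value, mb$value, tolerance = 1e-12)
})
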