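test_that("location graph builds W, W_plus and M per the definitions", {
  g <- location_graph(cbind("a", "b"), c("a", "b"))
  expect_equal(as.matrix(g$W), rbind(c(0, 1), c(1, 0)), ignore_attr = TRUE)
  expect_equal(as.matrix(g$W_plus), as.matrix(g$W), ignore_attr = TRUE)
  expect_equal(as.matrix(g$M), diag(2), ignore_attr = TRUE)

  # 3-node path a-b-c
  gp <- location_graph(rbind(c("a", "b"), c("b", "c")), c("a", "b", "c"))
  expect_equal(as.matrix(gp$W_plus),
               rbind(c(0, 1, 0), c(.5, 0, .5), c(0, 1, 0)), ignore_attr = TRUE)
  expect_equal(Matrix::diag(gp$M), c(1, .5, 1))
  expect_equal(Matrix::rowSums(gp$W_plus), rep(1, 3), ignore_attr = TRUE)
})

test_that("duplicate and reversed edges are idempotent; errors are caught", {
  e1 <- rbind(c("a", "b"), c("a", "b"), c("b", "a"))
  g1 <- location_graph(e1, c("a", "b"))
  g2 <- location_graph(cbind("a", "b"), c("a", "b"))
  expect_equal(as.matrix(g1$W), as.matrix(g2$W))
  expect_error(location_graph(cbind("a", "z"), c("a", "b")), "not in location set")
  expect_warning(location_graph(cbind("a", "b"), c("a", "b", "c")), "isolated")
})

test_that("CAR and SAR at rho = 0 reduce to sigma_s2 * M", {
  g <- lattice_graph(3, 3)
  M <- diag(1 / Matrix::rowSums(g$W))
  for (s in c(1, 2.5)) {
    expect_equal(spatial_covariance(g, "CAR", s, 0), s * M,
                 ignore_attr = TRUE, tolerance = 1e-12)
    expect_equal(spatial_covariance(g, "SAR", s, 0), s * M,
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
  expect_equal(spatial_covariance(g, "IND", 2), 2 * diag(9), ignore_attr = TRUE)
})

test_that("2-node covariances match the hand-inverted matrices", {
  g <- location_graph(cbind("a", "b"), c("a", "b"))
  expect_equal(spatial_covariance(g, "CAR", 1, 0.5),
               rbind(c(4 / 3, 2 / 3), c(2 / 3, 4 / 3)),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(spatial_covariance(g, "SAR", 1, 0.5),
               (1 / 0.5625) * rbind(c(1.25, 1), c(1, 1.25)),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("spatial covariance equals direct evaluation of the printed formulas", {
  set.seed(7)
  graphs <- list(lattice_graph(4, 4), lattice_graph(3, 5),
                 location_graph(rbind(c("a", "b"), c("b", "c"), c("c", "d"), c("d", "a")),
                                c("a", "b", "c", "d")))
  for (g in graphs) for (st in c("CAR", "SAR")) for (rho in c(-0.9, -0.5, 0, 0.5, 0.9)) {
    Sig <- spatial_covariance(g, st, 1.3, rho)
    expect_equal(Sig, oracle_spatial_cov(g, st, 1.3, rho),
                 ignore_attr = TRUE, tolerance = 1e-8)
    expect_lt(max(abs(Sig - t(Sig))), 1e-10)
    expect_gt(min(eigen(Sig, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("invalid spatial parameters are rejected", {
  g <- lattice_graph(2, 2)
  expect_error(spatial_covariance(g, "CAR", 1, 1), "rho")
  expect_error(spatial_covariance(g, "CAR", 1, -1.2), "rho")
  expect_error(spatial_precision(g, "CAR", -1, 0), "sigma_s2")
})

test_that("CAR precision is sparse on the graph edges", {
  g <- lattice_graph(5, 5)
  Q <- spatial_precision(g, "CAR", 0.7, 0.6)
  Qd <- as.matrix(Q)
  W <- as.matrix(g$W)
  off <- abs(Qd) > 1e-12 & upper.tri(Qd)
  expect_true(all(W[off] == 1))
})

test_that("isolated locations become independent unit-variance components", {
  suppressWarnings(g <- location_graph(cbind("a", "b"), c("a", "b", "c")))
  for (st in c("CAR", "SAR")) {
    Sig <- spatial_covariance(g, st, 2, 0.5)
    expect_equal(Sig["c", "c"], 2, tolerance = 1e-12)
    expect_equal(unname(Sig["c", c("a", "b")]), c(0, 0), tolerance = 1e-12)
  }
})

test_that("Gower factor matches its definition and properties", {
  # all individuals in one location -> 0
  expect_equal(gower_factor(rep(1L, 5), matrix(2, 1, 1)), 0)
  # one individual per location with Sigma = s * I -> s
  expect_equal(gower_factor(1:4, diag(1.7, 4)), 1.7)
  # 3 individuals in 2 locations (2,1 split) against brute-force evaluation
  Zs <- rbind(c(1, 0), c(1, 0), c(0, 1))
  S <- rbind(c(2, 1), c(1, 2))
  Cmat <- diag(3) - matrix(1 / 3, 3, 3)
  brute <- sum(diag(Cmat %*% Zs %*% S %*% t(Zs))) / 2
  expect_equal(gower_factor(Zs, S), brute)
  expect_equal(gower_factor(Zs, S), 2 / 3)
  # linear in sigma_s2
  expect_equal(gower_factor(Zs, 2 * S), 2 * gower_factor(Zs, S))
  expect_error(gower_factor(1L, matrix(1)), "at least 2")
  expect_error(gower_factor(rbind(c(1, 1), c(1, 0)), diag(2)), "exactly one")
})
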