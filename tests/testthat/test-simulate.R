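test_that("scenario validation enforces the liability budget", {
  expect_error(sim_scenario(vc = c(g = 0.6, s = 0.5)), "sum to < 1")
  expect_error(sim_scenario(prevalence = 0), "prevalence")
  expect_error(sim_scenario(rr = 25, prevalence = 0.2), "rr")
  sc <- sim_scenario(vc = c(g = 0.25))
  expect_equal(sc$eps, 0.75)
})

test_that("simulated cohorts have the requested bookkeeping and are reproducible", {
  sc <- sim_scenario(n_families = 100, dims = c(5, 5))
  set.seed(9)
  cg <- sim_cohort(sc)
  expect_equal(cg$cohort$N, 400)
  expect_equal(cg$cohort$N_F, 100)
  expect_equal(length(cg$graph$locations), 25)
  expect_true(all(cg$cohort$family_sizes == 4))

  st1 <- sim_study(sc, seed = 33)
  st2 <- sim_study(sc, seed = 33)
  expect_identical(st1$cohort$data, st2$cohort$data)
  expect_identical(st1$Y, st2$Y)
  expect_identical(st1$exposures, st2$exposures)
})

test_that("families-per-location distribution matches the target shape", {
  sc <- sim_scenario(n_families = 3000)
  set.seed(10)
  cg <- sim_cohort(sc)
  counts <- table(factor(cg$cohort$data$location_id[cg$cohort$data$role == "father"],
                         levels = cg$graph$locations))
  med <- median(counts[counts > 0])
  expect_gt(med, 5)
  expect_lt(med, 50)
})

test_that("mixed family sizes are supported end to end", {
  sc <- sim_scenario(n_families = 150, dims = c(4, 4),
                     family_size = c(`3` = .4, `4` = .4, `5` = .15, `6` = .05),
                     confounder_effect = 0)
  st <- sim_study(sc, seed = 5)
  expect_true(all(st$cohort$family_sizes %in% 3:6))
  st$cohort$data$status <- st$Y
  fit <- smile(status ~ age, st$cohort, graph = st$graph, se = FALSE,
               components = c("G", "P", "C"))
  expect_true(fit$convergence$converged)
})

test_that("spatial draws reproduce the target covariance", {
  g2 <- location_graph(cbind("a", "b"), c("a", "b"))
  set.seed(11)
  # rho = 0 reduces to sigma^2 * M
  d0 <- sim_spatial_effects(g2, "CAR", 1.5, 0, n = 1e4)
  expect_equal(cov(d0), 1.5 * diag(2), tolerance = 0.06, ignore_attr = TRUE)
  # rho = 0.5 matches the closed-form covariance
  d5 <- sim_spatial_effects(g2, "CAR", 1, 0.5, n = 2e4)
  expect_equal(cov(d5), rbind(c(4 / 3, 2 / 3), c(2 / 3, 4 / 3)),
               tolerance = 0.05, ignore_attr = TRUE)
  # neighbors correlate more than non-neighbors on a path graph
  gp <- location_graph(rbind(c("a", "b"), c("b", "c")), c("a", "b", "c"))
  dp <- sim_spatial_effects(gp, "CAR", 1, 0.8, n = 2e4)
  cc <- cor(dp)
  expect_gt(cc[1, 2], cc[1, 3])
})

test_that("liability thresholding yields the target prevalence and sibling structure", {
  # all variance residual: sibling phenotype correlation ~ 0
  sc0 <- sim_scenario(n_families = 4000, dims = c(5, 5), vc = c(g = 0),
                      prevalence = 0.5, confounder_effect = 0)
  set.seed(12)
  cg <- sim_cohort(sc0)
  ph <- sim_phenotype(cg$cohort, cg$graph, sc0)
  Y4 <- matrix(ph$Y, nrow = 4)
  expect_lt(abs(cor(Y4[3, ], Y4[4, ])), 3 / sqrt(4000))
  expect_lt(abs(mean(ph$Y) - 0.5), 3 * sqrt(0.25 / 16000))

  # genetic-only: parent-child observed covariance matches the
  # liability-threshold closed form
  scg <- sim_scenario(n_families = 12000, dims = c(5, 5), vc = c(g = 0.5),
                      prevalence = 0.2, confounder_effect = 0)
  cg2 <- sim_cohort(scg)
  ph2 <- sim_phenotype(cg2$cohort, cg2$graph, scg)
  Y4 <- matrix(ph2$Y, nrow = 4)
  obs_cov <- (cov(Y4[1, ], Y4[3, ]) + cov(Y4[2, ], Y4[4, ])) / 2
  expected <- oracle_observed_cov(0.25, 0.2)
  expect_equal(obs_cov, expected, tolerance = 0.25)

  # realized prevalence at K = 0.05 with ~10^5 individuals
  sck <- sim_scenario(n_families = 25000, vc = c(g = 0.3), prevalence = 0.05,
                      dims = c(10, 10), confounder_effect = 0)
  cg3 <- sim_cohort(sck)
  ph3 <- sim_phenotype(cg3$cohort, cg3$graph, sck)
  expect_gt(mean(ph3$Y), 0.045)
  expect_lt(mean(ph3$Y), 0.055)
})

test_that("exposure generation has relevant instruments and exogenous confounding", {
  sc <- sim_scenario(n_families = 500, dims = c(12, 12))
  set.seed(14)
  cg <- sim_cohort(sc)
  env <- sim_exposure_instruments(cg$graph, sc)
  enc <- encode_wind(env$instruments$wind_speed, env$instruments$wind_dir)
  # instrument relevance: encoded wind predicts the pollutant
  r2 <- summary(lm(env$exposures$pm25 ~ enc))$r.squared
  expect_gt(sqrt(r2), 0.3)
  # instrument exogeneity: first-stage prediction uncorrelated with confounder
  fs <- first_stage(env$exposures, env$instruments, "pm25")
  expect_lt(abs(cor(fs$P_tilde, env$confounder)), 0.25)
  # raw exposure is confounded by construction
  expect_gt(cor(env$exposures$pm25, env$confounder), 0.3)
})

test_that("relationship-error injection attenuates genetic recovery monotonically", {
  sc <- sim_scenario(n_families = 1500, dims = c(5, 5), vc = c(g = 0.5),
                     prevalence = 0.3, confounder_effect = 0)
  set.seed(15)
  cg <- sim_cohort(sc)
  expect_error(inject_relationship_errors(cg$cohort, 0.9), "0, 0.5")
  co0 <- inject_relationship_errors(cg$cohort, 0)
  expect_true(!any(co0$data$misattributed))

  est_g <- vapply(c(0, 0.25, 0.5), function(rate) {
    co <- inject_relationship_errors(cg$cohort, rate)
    ph <- sim_phenotype(co, cg$graph, sc)
    co$data$status <- ph$Y
    fit <- smile(status ~ 1, co, components = "G", se = FALSE)
    v <- setNames(fit$vc$variance, fit$vc$component)
    v[["g"]]
  }, numeric(1))
  expect_true(est_g[1] > est_g[2] && est_g[2] > est_g[3])
})

test_that("measurement noise wraps directions and leaves noise_sd = 0 untouched", {
  sc <- sim_scenario(n_families = 50, dims = c(4, 4))
  set.seed(16)
  cg <- sim_cohort(sc)
  env <- sim_exposure_instruments(cg$graph, sc)
  same <- add_measurement_noise(env$exposures, env$instruments, 0)
  expect_identical(same$exposures, env$exposures)
  noisy <- add_measurement_noise(env$exposures, env$instruments, 0.5)
  expect_false(identical(noisy$exposures$pm25, env$exposures$pm25))
  expect_true(all(noisy$instruments$wind_dir >= 0 & noisy$instruments$wind_dir < 360))
  expect_true(all(noisy$instruments$wind_speed >= 0))
  expect_error(add_measurement_noise(env$exposures, env$instruments, -1), ">= 0")
})
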