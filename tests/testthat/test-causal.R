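make_env <- function(seed = 20, L = 144, n_fam = 400) {
  set.seed(seed)
  sc <- sim_scenario(n_families = n_fam, dims = c(sqrt(L), sqrt(L)),
                     rr = 1.2, exposure = "pm25")
  sim_study(sc)
}

test_that("wind encoding is continuous across the 0/360 seam", {
  e1 <- encode_wind(5, 0.001)
  e2 <- encode_wind(5, 359.999)
  expect_equal(e1, e2, tolerance = 1e-3)
  expect_error(encode_wind(-1, 90), "speed")
})

test_that("first stage recovers exact linear structure and flags weak instruments", {
  set.seed(21)
  loc <- sprintf("l%02d", 1:40)
  inst <- data.frame(location_id = loc, wind_speed = runif(40, 1, 6),
                     wind_dir = runif(40, 0, 360))
  enc <- encode_wind(inst$wind_speed, inst$wind_dir)
  # exposure exactly linear in the encoding -> fitted equals observed
  expo <- data.frame(location_id = loc, pm25 = drop(enc %*% c(1, 2, .5, .3, -.2)) + 3)
  fs <- first_stage(expo, inst, "pm25")
  expect_equal(fs$P_tilde, expo$pm25, tolerance = 1e-8)
  expect_gt(fs$r_squared, 0.999)
  expect_false(fs$weak)

  # instruments unrelated to exposure -> R2 ~ 0, weak warning
  expo2 <- data.frame(location_id = loc, pm25 = rnorm(40))
  expect_warning(fs2 <- first_stage(expo2, inst, "pm25"), "weak instrument")
  expect_lt(fs2$r_squared, 0.35)
  expect_equal(fs2$P_tilde, rep(mean(expo2$pm25), 40), tolerance = 0.6)

  # constant instruments -> error
  inst3 <- data.frame(location_id = loc, wind_speed = 2, wind_dir = 90)
  expect_error(suppressWarnings(first_stage(expo, inst3, "pm25")), "singular|weak|variance")
  expect_error(first_stage(expo[1:5, ], inst, "pm25"), "at least 10")
})

test_that("the summed exposure is the sum of standardized pollutant levels", {
  st <- make_env()
  P <- smilevc:::exposure_vector(st$exposures, "sum")
  expect_equal(P, drop(scale(st$exposures$pm25)) + drop(scale(st$exposures$no2)))
})

test_that("smile2 recovers a positive effect under the alternative", {
  set.seed(22)
  sc <- sim_scenario(n_families = 500, dims = c(12, 12), rr = 1.5,
                     exposure = "pm25")
  betas <- numeric(5)
  for (r in 1:5) {
    st <- sim_study(sc)
    st$cohort$data$status <- st$Y
    est <- smile2(status ~ age + sex, st$cohort, st$exposures, st$instruments,
                  exposure = "pm25", se = FALSE)
    betas[r] <- est$beta
  }
  expect_s3_class(est, "smile2")
  expect_gt(mean(betas), 0)
  expect_gt(or_from_beta(mean(betas) * sd(st$exposures$pm25), est$prevalence), 1)
  expect_true(est$p >= 0 && est$p <= 1)
  expect_gt(est$first_stage$r_squared, 0.2)
  expect_output(print(est), "SMILE-2")
})

test_that("IND-FE on parents matches textbook two-stage least squares", {
  st <- make_env(seed = 23)
  st$cohort$data$status <- st$Y
  est <- ind_fe(status ~ age, st$cohort, st$exposures, st$instruments, "pm25")
  # oracle: hand-computed 2SLS normal equations on the parent subset
  par_rows <- st$cohort$data$role %in% c("father", "mother")
  dat <- st$cohort$data[par_rows, ]
  fs <- first_stage(st$exposures, st$instruments, "pm25")
  pt <- fs$P_tilde[match(dat$location_id, fs$location_id)]
  Xm <- cbind(1, pt, dat$age)
  bh <- solve(t(Xm) %*% Xm, t(Xm) %*% st$Y[par_rows])
  expect_equal(est$beta, bh[2], tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(est$method, "IND-FE")
})

test_that("on singleton families with variance forced to residual, SMILE-2 collapses to OLS", {
  set.seed(24)
  graph <- lattice_graph(5, 5)
  n <- 400
  ped <- data.frame(individual_id = paste0("i", 1:n),
                    family_id = paste0("f", 1:n),
                    role = "father", sex = "M",
                    birth_year = 1960, months_enrolled = 84,
                    location_id = sample(graph$locations, n, replace = TRUE),
                    stringsAsFactors = FALSE)
  ped$age <- 40 + rnorm(n)
  co <- smile_cohort(ped, locations = graph$locations)
  sc <- sim_scenario(n_families = 10, dims = c(5, 5))
  env <- sim_exposure_instruments(graph, sc)
  P <- drop(scale(env$exposures$pm25))[match(ped$location_id, graph$locations)]
  co$data$status <- rbinom(n, 1, pmin(pmax(0.3 + 0.1 * P, 0.01), 0.99))
  s2 <- suppressWarnings(smile2(status ~ age, co, env$exposures, env$instruments,
                                "pm25", components = "G", se = FALSE))
  fe <- suppressWarnings(ind_fe(status ~ age, co, env$exposures, env$instruments, "pm25"))
  expect_equal(s2$beta, fe$beta, tolerance = 1e-6)
})

test_that("odds-ratio transform behaves at the boundaries", {
  expect_equal(or_from_beta(0, 0.1), 1)
  expect_gt(or_from_beta(0.05, 0.1), 1)
  expect_lt(or_from_beta(-0.05, 0.1), 1)
  expect_gt(or_from_beta(-0.2, 0.1), 0)
})

test_that("phenome screen applies the Bonferroni threshold and prevalence floor", {
  res <- data.frame(trait = rep(paste0("t", 1:10), each = 3),
                    exposure = rep(c("pm25", "no2", "sum"), 10),
                    beta = 0.01, se = 0.005,
                    p = rep(c(1e-5, 0.2, 0.001), 10),
                    or = 1.05,
                    prevalence = c(rep(0.05, 27), rep(5e-4, 3)),
                    stringsAsFactors = FALSE)
  out <- phenome_screen(res)
  expect_equal(unique(out$threshold), 0.05 / (9 * 3))
  expect_true(all(out$excluded[out$prevalence < 0.001] == "prevalence below floor"))
  expect_false(any(out$significant[out$prevalence < 0.001]))
  expect_true(all(out$significant[out$p < 0.05 / 27 & out$prevalence >= 0.001]))
})

test_that("IV debiasing: naive regression is confounded, two-stage is not", {
  # strong confounding, null effect: naive slope biased away from zero,
  # two-stage slope near zero
  set.seed(26)
  sc <- sim_scenario(n_families = 800, dims = c(14, 14), rr = 1,
                     confounder_effect = 0.3)
  reps <- 8
  naive <- numeric(reps); iv <- numeric(reps)
  for (r in seq_len(reps)) {
    st <- sim_study(sc)
    st$cohort$data$status <- st$Y
    P <- drop(scale(st$exposures$pm25))
    pin <- P[match(st$cohort$data$location_id, st$exposures$location_id)]
    naive[r] <- coef(lm(st$Y ~ pin + st$cohort$data$age))[2]
    est <- smile2(status ~ age, st$cohort, st$exposures, st$instruments,
                  "pm25", se = FALSE)
    # beta is per raw unit of pm25; rescale to per-SD to match the naive slope
    iv[r] <- est$beta * sd(st$exposures$pm25)
  }
  # naive picks up the confounder (positive bias); IV stays within noise
  expect_gt(mean(naive), mean(iv) + 2 * sd(iv) / sqrt(reps))
  expect_lt(abs(mean(iv)), 3 * sd(iv) / sqrt(reps) + 0.01)
})
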