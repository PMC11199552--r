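#' Define a simulation scenario
#'
#' Collects the generating conditions for a synthetic cohort study:
#' nuclear families nested in locations on a spatial graph, liability
#' threshold binary outcomes, and location-level exposures driven partly by
#' wind instruments and partly by a spatially smooth confounder.
#'
#' Defaults reflect the study conditions emulated by the package: quad
#' families allocated to locations with a heavy-tailed log-normal
#' distribution (median about 15 families per location, IQR roughly 5-50),
#' liability variance split `g = 0.3`, `par = 0.1`, `child = 0.1`,
#' `s = 0.1` with CAR autocorrelation `rho = 0.6`, disease prevalence 5%,
#' and a null exposure effect (`rr = 1`). The exposure's location-level
#' variance splits 50% instrument signal, 25% confounder, 25% noise.
#'
#' @param n_families number of nuclear families.
#' @param family_size `"quad"` (two parents, two children) or a named
#'   probability vector over family sizes 3 to 6.
#' @param dims lattice dimensions `c(nrow, ncol)` for the location graph,
#'   or `NULL` to size the graph from the families-per-location
#'   distribution.
#' @param graph optionally a pre-built [location_graph] to place families on.
#' @param vc named liability-scale variance components
#'   (`g`, `par`, `child`, `s`); the residual takes the complement to 1.
#' @param rho spatial autocorrelation of the community random effect.
#' @param spatial spatial structure used to draw the community effect.
#' @param prevalence disease prevalence K in (0, 1).
#' @param rr causal effect of the exposure as a relative risk at +1 SD of
#'   exposure (1 = null).
#' @param exposure which simulated pollutant drives the liability
#'   (`"pm25"`, `"no2"` or `"sum"`).
#' @param confounder_effect liability shift per SD of the location-level
#'   confounder (creates endogeneity of the raw exposure).
#' @param instrument_strength fraction of exposure variance explained by the
#'   wind instruments.
#' @param confounding fraction of exposure variance from the confounder.
#' @param field_rho spatial autocorrelation of the simulated wind and
#'   confounder fields on the location graph.
#' @param noise_sd measurement noise level for [add_measurement_noise()]
#'   (0 = exact measurements).
#' @param relationship_error fraction of children mislabeled as biological
#'   (see [inject_relationship_errors()]).
#' @param alloc_meanlog,alloc_sdlog log-normal parameters of the
#'   families-per-location distribution.
#' @return an object of class `sim_scenario`.
#' @export
sim_scenario <- function(n_families = 2000, family_size = "quad", dims = NULL,
                         graph = NULL,
                         vc = c(g = 0.3, par = 0.1, child = 0.1, s = 0.1),
                         rho = 0.6, spatial = "CAR", prevalence = 0.05,
                         rr = 1, exposure = "pm25",
                         confounder_effect = 0.15,
                         instrument_strength = 0.5, confounding = 0.25,
                         field_rho = 0.6,
                         noise_sd = 0, relationship_error = 0,
                         alloc_meanlog = log(15), alloc_sdlog = 1.7) {
  vc_full <- c(g = 0, par = 0, child = 0, s = 0)
  vc_full[names(vc)] <- vc
  if (any(vc_full < 0)) stop("variance components must be >= 0")
  eps <- 1 - sum(vc_full)
  if (eps <= 0) stop("liability variance components must sum to < 1")
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must lie in (0, 1)")
  if (rr * prevalence >= 1) stop("rr * prevalence must be < 1")
  if (instrument_strength + confounding > 1)
    stop("instrument_strength + confounding must be <= 1")
  structure(list(n_families = n_families, family_size = family_size,
                 dims = dims, graph = graph, vc = vc_full, eps = eps,
                 rho = rho, spatial = spatial, prevalence = prevalence,
                 rr = rr, exposure = exposure,
                 confounder_effect = confounder_effect,
                 instrument_strength = instrument_strength,
                 confounding = confounding, field_rho = field_rho,
                 noise_sd = noise_sd,
                 relationship_error = relationship_error,
                 alloc_meanlog = alloc_meanlog, alloc_sdlog = alloc_sdlog),
            class = "sim_scenario")
}

#' Simulate a nuclear-family cohort on a spatial graph
#'
#' Places families on locations with a heavy-tailed (log-normal)
#' families-per-location distribution and generates pedigree records with
#' roles, sexes, birth years and enrollment covariates. Deterministic given
#' the RNG state (set a seed before calling for byte-identical cohorts).
#'
#' @param scenario a [sim_scenario].
#' @return a list with elements `cohort` (a [smile_cohort]) and `graph`
#'   (a [location_graph]).
#' @export
sim_cohort <- function(scenario) {
  n_fam <- scenario$n_families
  if (!is.null(scenario$graph)) {
    graph <- scenario$graph
    L <- length(graph$locations)
    w <- stats::rlnorm(L, 0, scenario$alloc_sdlog)
    counts <- as.vector(stats::rmultinom(1, n_fam, w))
  } else if (!is.null(scenario$dims)) {
    graph <- lattice_graph(scenario$dims[1], scenario$dims[2])
    L <- length(graph$locations)
    w <- stats::rlnorm(L, 0, scenario$alloc_sdlog)
    counts <- as.vector(stats::rmultinom(1, n_fam, w))
  } else {
    # draw per-location family counts directly from the target distribution
    counts <- integer(0)
    while (sum(counts) < n_fam) {
      draw <- pmax(1, round(stats::rlnorm(64, scenario$alloc_meanlog,
                                          scenario$alloc_sdlog)))
      counts <- c(counts, draw)
    }
    counts <- counts[cumsum(counts) - counts < n_fam]
    counts[length(counts)] <- n_fam - sum(counts[-length(counts)])
    L <- length(counts)
    side <- ceiling(sqrt(L))
    graph <- lattice_graph(side, ceiling(L / side), n_keep = L)
  }

  sizes <- family_sizes(scenario$family_size, n_fam)
  fam_loc <- rep.int(seq_len(L), counts)

  n_children <- sizes - 2L
  fam_id <- sprintf("fam%05d", seq_len(n_fam))
  enroll_year <- sample(2005:2011, n_fam, replace = TRUE)
  father_age <- pmax(30, round(stats::rnorm(n_fam, 47, 5)))
  mother_age <- pmax(28, round(stats::rnorm(n_fam, 45, 5)))
  months <- pmin(156, pmax(72, round(stats::rnorm(n_fam, 84, 20))))
  loc_ids <- graph$locations[fam_loc]
  n_child_total <- sum(n_children)
  child_ages <- pmax(10, pmin(26, round(stats::rnorm(n_child_total, 15, 3))))
  child_sexes <- sample(c("M", "F"), n_child_total, replace = TRUE)

  fam_of_child <- rep.int(seq_len(n_fam), n_children)
  child_no <- sequence(n_children)
  fam_row <- c(seq_len(n_fam), seq_len(n_fam), fam_of_child)
  member_no <- c(rep(1L, n_fam), rep(2L, n_fam), 2L + child_no)
  ped <- data.frame(
    individual_id = sprintf("%s_%d", fam_id[fam_row], member_no),
    family_id = fam_id[fam_row],
    role = rep(c("father", "mother", "child"),
               c(n_fam, n_fam, n_child_total)),
    sex = c(rep("M", n_fam), rep("F", n_fam), child_sexes),
    birth_year = enroll_year[fam_row] - c(father_age, mother_age, child_ages),
    months_enrolled = months[fam_row],
    location_id = loc_ids[fam_row],
    stringsAsFactors = FALSE
  )
  ped$enroll_year <- enroll_year[fam_row]
  ped$age <- ped$enroll_year - ped$birth_year
  list(cohort = smile_cohort(ped, locations = graph$locations), graph = graph)
}

family_sizes <- function(family_size, n_fam) {
  if (identical(family_size, "quad")) return(rep(4L, n_fam))
  if (is.numeric(family_size) && !is.null(names(family_size))) {
    sz <- as.integer(names(family_size))
    if (any(sz < 3 | sz > 6)) stop("family sizes must be 3 to 6 members")
    return(sample(sz, n_fam, replace = TRUE, prob = family_size))
  }
  stop("family_size must be \"quad\" or a named probability vector")
}

#' Draw spatial random effects
#'
#' Multivariate normal draws of the location-level random effect under the
#' requested spatial structure, via the sparse precision Cholesky.
#'
#' @param graph a [location_graph].
#' @param spatial `"IND"`, `"CAR"` or `"SAR"`.
#' @param sigma_s2 spatial variance.
#' @param rho autocorrelation.
#' @param n number of replicate draws.
#' @return an `n x L` matrix of draws.
#' @export
sim_spatial_effects <- function(graph, spatial = "CAR", sigma_s2 = 1,
                                rho = 0.6, n = 1) {
  L <- length(graph$locations)
  Q <- spatial_precision(graph, spatial, sigma_s2, rho)
  R <- chol(as.matrix(Q))
  z <- matrix(stats::rnorm(L * n), L, n)
  t(backsolve(R, z))
}

#' Liability shift equivalent to a target relative risk
#'
#' The liability-threshold effect size such that
#' `P(case | exposure + 1 SD) / P(case | baseline)` equals `rr` at
#' prevalence `K`: `beta = qnorm(1 - K) - qnorm(1 - rr * K)`.
#'
#' @param rr target relative risk (per +1 SD of exposure).
#' @param K disease prevalence.
#' @return liability shift per SD of exposure.
#' @export
rr_to_liability_shift <- function(rr, K) {
  if (rr * K >= 1) stop("rr * K must be < 1")
  stats::qnorm(1 - K) - stats::qnorm(1 - rr * K)
}

# genetic + family-environment draws for a cohort; honors the
# `misattributed` column (children with broken genetic links) if present
draw_family_effects <- function(cohort, g = 0, par = 0, child = 0) {
  N <- cohort$N
  out <- numeric(N)
  if (g > 0) {
    role <- cohort$data$role
    mis <- cohort$data$misattributed %||% rep(FALSE, N)
    fam <- as.integer(cohort$family)
    fam_rows <- split(seq_len(N), fam)
    key <- vapply(fam_rows, function(r)
      paste(paste(role[r], as.integer(mis[r]), sep = "."), collapse = ","),
      character(1))
    for (ky in unique(key)) {
      rows <- fam_rows[key == ky]
      r1 <- rows[[1]]
      G <- kinship_matrix(role[r1])
      broken <- which(mis[r1])
      if (length(broken)) {
        G[broken, ] <- 0
        G[, broken] <- 0
        diag(G) <- 1
      }
      k <- length(r1)
      Rg <- chol(G)
      nf <- length(rows)
      draws <- t(Rg) %*% matrix(stats::rnorm(k * nf), k, nf) * sqrt(g)
      out[unlist(rows)] <- as.vector(draws)
    }
  }
  if (par > 0 || child > 0) {
    Z <- family_env_design(cohort)
    if (par > 0)
      out <- out + drop(as.matrix(Z$Z_par %*% stats::rnorm(ncol(Z$Z_par), sd = sqrt(par))))
    if (child > 0)
      out <- out + drop(as.matrix(Z$Z_child %*% stats::rnorm(ncol(Z$Z_child), sd = sqrt(child))))
  }
  out
}

#' Simulate liability-threshold binary phenotypes
#'
#' Builds the latent liability as the sum of genetic, parent-shared,
#' child-shared, spatial, optional exposure and confounder contributions,
#' and residual noise, then thresholds at the `(1 - K)` standard-normal
#' quantile: individuals whose liability exceeds the threshold are cases.
#' The generating variance components sum to 1 on the liability scale, so
#' the realized prevalence is within binomial error of `K` (exposure and
#' confounder shifts are centered and small).
#'
#' @param cohort a [smile_cohort] (possibly perturbed by
#'   [inject_relationship_errors()]).
#' @param graph the [location_graph] the cohort lives on.
#' @param scenario a [sim_scenario] carrying the generating components.
#' @param exposure_liability optional per-location liability contribution of
#'   the exposure (already multiplied by its effect size).
#' @param confounder_liability optional per-location confounder
#'   contribution.
#' @return a list with the 0/1 vector `Y` and a `truth` list (spatial
#'   effects `u_s`, the liability, the threshold, per-component draws).
#' @export
sim_phenotype <- function(cohort, graph, scenario,
                          exposure_liability = NULL,
                          confounder_liability = NULL) {
  vc <- scenario$vc
  N <- cohort$N
  liab <- draw_family_effects(cohort, vc["g"], vc["par"], vc["child"])
  u_s <- NULL
  sigma_s2_raw <- 0
  if (vc["s"] > 0) {
    # the scenario's s is the Gower-standardized (per-individual average)
    # spatial variance; rescale the raw CAR/SAR parameter accordingly so the
    # liability components really sum to 1
    g1 <- gower_factor(as.integer(cohort$location),
                       spatial_covariance(graph, scenario$spatial, 1, scenario$rho))
    sigma_s2_raw <- vc[["s"]] / g1
    u_s <- drop(sim_spatial_effects(graph, scenario$spatial, sigma_s2_raw,
                                    scenario$rho, n = 1))
    liab <- liab + u_s[as.integer(cohort$location)]
  }
  loc_of <- as.integer(cohort$location)
  if (!is.null(exposure_liability)) liab <- liab + exposure_liability[loc_of]
  if (!is.null(confounder_liability)) liab <- liab + confounder_liability[loc_of]
  liab <- liab + stats::rnorm(N, sd = sqrt(scenario$eps))
  thr <- stats::qnorm(1 - scenario$prevalence)
  Y <- as.integer(liab > thr)
  list(Y = Y,
       truth = list(u_s = u_s, liability = liab, threshold = thr,
                    vc = vc, eps = scenario$eps, sigma_s2_raw = sigma_s2_raw,
                    misattributed = cohort$data$misattributed %||% rep(FALSE, N)))
}

#' Simulate location-level exposures, wind instruments and a confounder
#'
#' Wind speed and direction vary smoothly over the graph (CAR-correlated
#' fields); each pollutant is a mixture of an instrument-driven component
#' (a linear combination of the encoded wind variables), a spatially smooth
#' confounder shared between pollutants, and independent noise. The
#' confounder also enters the disease liability in [sim_study()], creating
#' endogeneity of the raw exposure, while the instruments are exogenous by
#' construction.
#'
#' @param graph a [location_graph].
#' @param scenario a [sim_scenario] (uses `instrument_strength` and
#'   `confounding`).
#' @return a list with `exposures` (`location_id`, `pm25` in ug/m3, `no2`
#'   in ppb), `instruments` (`location_id`, `wind_speed` m/s, `wind_dir`
#'   degrees), and the standardized `confounder` vector.
#' @export
sim_exposure_instruments <- function(graph, scenario) {
  L <- length(graph$locations)
  smooth <- function() {
    f <- drop(sim_spatial_effects(graph, "CAR", 1, scenario$field_rho, 1))
    as.vector(scale(f))
  }
  wind_u <- smooth(); wind_v <- smooth()
  wind_dir <- (atan2(wind_v, wind_u) * 180 / pi) %% 360
  wind_speed <- pmax(0.1, 3 + 1.5 * smooth())
  enc <- encode_wind(wind_speed, wind_dir)
  conf <- smooth()

  vi <- scenario$instrument_strength
  vcf <- scenario$confounding
  mix <- function(weights) {
    signal <- as.vector(scale(enc %*% weights))
    sqrt(vi) * signal + sqrt(vcf) * conf +
      sqrt(max(1 - vi - vcf, 0)) * stats::rnorm(L)
  }
  pm25_std <- mix(c(1, 0.5, 0.8, 0.3, 0.3))
  no2_std <- mix(c(0.4, 1, 0.6, 0.2, 0.5))
  list(
    exposures = data.frame(location_id = graph$locations,
                           pm25 = 8 + 2.5 * pm25_std,
                           no2 = 12 + 5 * no2_std,
                           stringsAsFactors = FALSE),
    instruments = data.frame(location_id = graph$locations,
                             wind_speed = wind_speed,
                             wind_dir = wind_dir,
                             stringsAsFactors = FALSE),
    confounder = conf
  )
}

#' Mislabel a fraction of children as biological
#'
#' Emulates pedigree errors (stepchildren and adopted children recorded as
#' biological children of both parents): the stated fraction of children
#' keep the `child` label but lose all true genetic sharing with their
#' family. Downstream phenotype simulation honors the flag; the analysis
#' model never sees it.
#'
#' @param cohort a [smile_cohort].
#' @param error_rate fraction of children to mislabel, in `[0, 0.5]`.
#' @return the cohort with a logical `misattributed` column in its data.
#' @export
inject_relationship_errors <- function(cohort, error_rate) {
  cohort <- as_smile_cohort(cohort)
  if (error_rate < 0 || error_rate > 0.5)
    stop("error_rate must lie in [0, 0.5]")
  is_child <- which(cohort$data$role == "child")
  mis <- rep(FALSE, cohort$N)
  if (error_rate > 0 && length(is_child)) {
    n_err <- round(error_rate * length(is_child))
    mis[sample(is_child, n_err)] <- TRUE
  }
  cohort$data$misattributed <- mis
  cohort
}

#' Add measurement noise to exposure and instrument tables
#'
#' Independent Gaussian noise scaled by `noise_sd` times each variable's
#' standard deviation is added to the pollutant levels and the wind speed
#' (truncated at zero); wind direction receives `noise_sd * 60` degrees of
#' noise, wrapped to `[0, 360)`.
#'
#' @param exposures,instruments tables as produced by
#'   [sim_exposure_instruments()].
#' @param noise_sd nonnegative noise level (0 returns the inputs unchanged).
#' @return list with the perturbed `exposures` and `instruments`.
#' @export
add_measurement_noise <- function(exposures, instruments, noise_sd) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (noise_sd == 0) return(list(exposures = exposures, instruments = instruments))
  for (cn in intersect(c("pm25", "no2"), names(exposures))) {
    x <- exposures[[cn]]
    exposures[[cn]] <- x + stats::rnorm(length(x), sd = noise_sd * stats::sd(x))
  }
  ws <- instruments$wind_speed
  instruments$wind_speed <- pmax(0, ws + stats::rnorm(length(ws), sd = noise_sd * stats::sd(ws)))
  instruments$wind_dir <- (instruments$wind_dir +
                             stats::rnorm(length(ws), sd = noise_sd * 60)) %% 360
  list(exposures = exposures, instruments = instruments)
}

#' Run one full synthetic study
#'
#' Convenience wrapper: simulates the cohort, the exposure/instrument
#' tables, optional relationship errors and measurement noise, and the
#' binary phenotype with the scenario's exposure effect (as a relative
#' risk) and confounder acting through the location of each family.
#'
#' @param scenario a [sim_scenario].
#' @param seed optional integer seed for exact reproducibility.
#' @return a list with `cohort`, `graph`, `exposures`, `instruments`,
#'   `confounder`, `Y`, `truth`, and the `scenario`.
#' @export
sim_study <- function(scenario, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cg <- sim_cohort(scenario)
  env <- sim_exposure_instruments(cg$graph, scenario)
  if (scenario$relationship_error > 0)
    cg$cohort <- inject_relationship_errors(cg$cohort, scenario$relationship_error)

  beta_liab <- rr_to_liability_shift(scenario$rr, scenario$prevalence)
  P_std <- as.vector(scale(exposure_vector(env$exposures, scenario$exposure)))
  exposure_liab <- if (beta_liab != 0) beta_liab * P_std else NULL
  conf_liab <- if (scenario$confounder_effect != 0)
    scenario$confounder_effect * env$confounder else NULL

  # the confounder is itself a community-level effect: deduct its variance
  # from the residual so the liability variance stays 1
  if (!is.null(conf_liab)) {
    eps_adj <- scenario$eps - scenario$confounder_effect^2
    if (eps_adj <= 0)
      stop("confounder_effect^2 exceeds the residual liability variance")
    scenario$eps <- eps_adj
  }

  phen <- sim_phenotype(cg$cohort, cg$graph, scenario,
                        exposure_liability = exposure_liab,
                        confounder_liability = conf_liab)
  obs <- add_measurement_noise(env$exposures, env$instruments, scenario$noise_sd)
  list(cohort = cg$cohort, graph = cg$graph,
       exposures = obs$exposures, instruments = obs$instruments,
       confounder = env$confounder,
       Y = phen$Y, truth = c(phen$truth, list(beta_liability = beta_liab)),
       scenario = scenario)
}
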