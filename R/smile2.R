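#' Encode wind instruments for the first-stage regression
#'
#' Wind direction is circular, so it is encoded without the 0/360 degree
#' discontinuity as `(sin(theta), cos(theta), speed, speed*sin(theta),
#' speed*cos(theta))`, with theta in degrees.
#'
#' @param speed wind speed (m/s, >= 0).
#' @param direction wind direction in degrees, `[0, 360)`.
#' @return a numeric matrix with five columns.
#' @export
encode_wind <- function(speed, direction) {
  if (any(!is.finite(speed)) || any(speed < 0)) stop("wind speed must be finite and >= 0")
  if (any(!is.finite(direction))) stop("wind direction must be finite")
  th <- direction * pi / 180
  cbind(sin = sin(th), cos = cos(th), speed = speed,
        speed_sin = speed * sin(th), speed_cos = speed * cos(th))
}

#' First-stage regression of exposure on wind instruments
#'
#' Least-squares regression of a location-level exposure (e.g. PM2.5) on
#' the encoded wind speed/direction instruments, returning fitted values
#' ("predicted exposure") plus relevance diagnostics: first-stage R-squared
#' and the overall F statistic. A weak-instrument warning is raised when
#' F < 10; an error when the instruments are constant.
#'
#' @param exposures data.frame keyed by `location_id` with exposure columns
#'   (e.g. `pm25`, `no2`).
#' @param instruments data.frame keyed by `location_id` with `wind_speed`
#'   and `wind_dir` columns.
#' @param exposure name of the exposure column, or `"sum"` for the sum of
#'   the standardized `pm25` and `no2` levels.
#' @return an object of class `first_stage`: `location_id`, observed `P`,
#'   fitted `P_tilde`, `r_squared`, `f_statistic`, `weak` flag.
#' @export
first_stage <- function(exposures, instruments, exposure = "pm25") {
  exposures <- as.data.frame(exposures)
  instruments <- as.data.frame(instruments)
  idx <- match(exposures$location_id, instruments$location_id)
  if (anyNA(idx)) stop("instrument table is missing location(s): ",
                       paste(exposures$location_id[is.na(idx)], collapse = ", "))
  instruments <- instruments[idx, ]
  if (nrow(exposures) < 10) stop("first-stage regression needs at least 10 locations")
  P <- exposure_vector(exposures, exposure)
  Z <- encode_wind(instruments$wind_speed, instruments$wind_dir)
  if (all(apply(Z, 2, stats::sd) < 1e-12))
    stop("weak instrument: wind instruments have zero variance")
  keep <- apply(Z, 2, stats::sd) > 1e-12
  fit <- stats::lm(P ~ Z[, keep, drop = FALSE])
  sm <- summary(fit)
  fstat <- if (is.null(sm$fstatistic)) 0 else unname(sm$fstatistic[1])
  weak <- fstat < 10
  if (weak) warning("weak instrument: first-stage F = ", signif(fstat, 3))
  structure(list(location_id = exposures$location_id,
                 exposure = exposure,
                 P = P, P_tilde = unname(stats::fitted(fit)),
                 r_squared = sm$r.squared, f_statistic = fstat,
                 weak = weak),
            class = "first_stage")
}

exposure_vector <- function(exposures, exposure) {
  if (exposure == "sum") {
    if (!all(c("pm25", "no2") %in% names(exposures)))
      stop("the summed exposure needs pm25 and no2 columns")
    drop(scale(exposures$pm25)) + drop(scale(exposures$no2))
  } else {
    if (!exposure %in% names(exposures))
      stop("exposure column not found: ", exposure)
    exposures[[exposure]]
  }
}

#' @export
print.first_stage <- function(x, ...) {
  cat("First-stage regression of", x$exposure, "on wind instruments\n")
  cat("  locations:", length(x$P), " R2:", signif(x$r_squared, 3),
      " F:", signif(x$f_statistic, 3), if (x$weak) " (weak)" else "", "\n")
  invisible(x)
}

#' Two-stage instrumental-variable mixed model for pollution causal effects
#'
#' Stage one regresses the location-level exposure on wind speed/direction
#' instruments ([first_stage]); stage two regresses the binary phenotype on
#' the predicted exposure in a mixed model with genetic and family
#' environment random effects,
#' `Y = P_tilde beta + X pi_2 + u_g + Z_par u_par + Z_child u_child + eps`.
#' The second stage deliberately carries no spatial random effect: the
#' predicted exposure is itself location-level and would be collinear with a
#' free location effect. Standard errors do not propagate first-stage
#' uncertainty (the usual generated-regressor caveat of small-stage 2SLS).
#'
#' @inheritParams smile
#' @param exposures,instruments location-level tables keyed by
#'   `location_id` (see [first_stage]).
#' @param exposure exposure column name or `"sum"`.
#' @param components random-effect components for the second stage
#'   (default genetic + parental + children; no S).
#' @return an object of class `smile2`: causal effect `beta` on the
#'   observed scale, `se`, Wald `p`, odds ratio `or` at the trait's
#'   prevalence, first-stage diagnostics, and the underlying `smile` fit.
#' @export
smile2 <- function(formula, data, exposures, instruments, exposure = "pm25",
                   components = c("G", "P", "C"), se = TRUE, ...) {
  cohort <- as_smile_cohort(data)
  fs <- first_stage(exposures, instruments, exposure)
  ptilde <- fs$P_tilde[match(as.character(cohort$data$location_id), fs$location_id)]
  if (anyNA(ptilde))
    stop("exposure table is missing cohort location(s)")
  if (stats::sd(ptilde) < 1e-12)
    stop("predicted exposure is constant across the cohort")
  cohort$data$.P_tilde <- ptilde
  f2 <- stats::update(stats::as.formula(formula), . ~ .P_tilde + .)
  fit <- smile(f2, cohort, graph = NULL,
               components = setdiff(components, "S"), spatial = "IND",
               se = se, ...)
  beta <- unname(fit$coefficients[".P_tilde"])
  beta_se <- sqrt(diag(fit$vcov_fixed))[".P_tilde"]
  z <- beta / beta_se
  p <- 2 * stats::pnorm(-abs(z))
  K <- fit$prevalence
  structure(list(method = "SMILE-2",
                 exposure = exposure,
                 beta = beta, se = unname(beta_se), p = unname(p),
                 or = or_from_beta(beta, K),
                 prevalence = K,
                 first_stage = fs,
                 fit = fit),
            class = "smile2")
}

#' Two-stage regression comparator on unrelated parents (IND-FE)
#'
#' The fixed-effects-only comparator: ordinary least squares of the
#' phenotype on the predicted exposure and covariates over the parents only
#' (two genetically unrelated individuals per family), ignoring family and
#' community random effects.
#'
#' @inheritParams smile2
#' @return a `smile2` object with `method = "IND-FE"`.
#' @export
ind_fe <- function(formula, data, exposures, instruments, exposure = "pm25", ...) {
  cohort <- as_smile_cohort(data)
  fs <- first_stage(exposures, instruments, exposure)
  keep <- cohort$data$role %in% c("father", "mother")
  dat <- cohort$data[keep, , drop = FALSE]
  dat$.P_tilde <- fs$P_tilde[match(as.character(dat$location_id), fs$location_id)]
  if (stats::sd(dat$.P_tilde) < 1e-12)
    stop("predicted exposure is constant across the cohort")
  f2 <- stats::update(stats::as.formula(formula), . ~ .P_tilde + .)
  fit <- stats::lm(f2, data = dat)
  sm <- summary(fit)$coefficients
  beta <- sm[".P_tilde", 1]
  beta_se <- sm[".P_tilde", 2]
  z <- beta / beta_se
  K <- mean(stats::model.response(stats::model.frame(f2, dat)))
  structure(list(method = "IND-FE",
                 exposure = exposure,
                 beta = unname(beta), se = unname(beta_se),
                 p = unname(2 * stats::pnorm(-abs(z))),
                 or = or_from_beta(beta, K),
                 prevalence = K,
                 first_stage = fs,
                 fit = fit),
            class = "smile2")
}

#' @export
print.smile2 <- function(x, digits = 4, ...) {
  cat(x$method, "causal effect of", x$exposure, "\n")
  cat("  beta (observed scale):", signif(x$beta, digits),
      " se:", signif(x$se, digits), "\n")
  cat("  OR:", signif(x$or, digits), " p:", format(x$p, digits = 3), "\n")
  cat("  first stage R2:", signif(x$first_stage$r_squared, 3),
      " F:", signif(x$first_stage$f_statistic, 3), "\n")
  invisible(x)
}

#' Odds ratio from an observed-scale effect at a given prevalence
#'
#' Converts a linear-probability-model effect (risk difference per unit of
#' exposure) to an odds ratio at baseline prevalence `K`:
#' `OR = ((K + beta)/(1 - K - beta)) / (K/(1 - K))`.
#'
#' @param beta observed-scale effect.
#' @param K baseline prevalence in (0, 1).
#' @return odds ratio (> 0).
#' @export
or_from_beta <- function(beta, K) {
  p1 <- pmin(pmax(K + beta, 1e-12), 1 - 1e-12)
  (p1 / (1 - p1)) / (K / (1 - K))
}

#' Phenome-wide causal screen with Bonferroni control
#'
#' Collects per-(trait, exposure) causal estimates, excludes traits below
#' the prevalence floor before testing, and flags significance at the
#' Bonferroni threshold `alpha / (n_traits x n_exposures)`.
#'
#' @param results a data.frame with columns `trait`, `exposure`, `beta`,
#'   `se`, `p`, `or`, `prevalence`, or a list of `smile2` objects with a
#'   `trait` name each.
#' @param alpha family-wise error rate (default 0.05).
#' @param n_exposures number of exposures tested per trait (default 3:
#'   PM2.5, NO2 and their standardized sum).
#' @param prevalence_min minimum observed prevalence for inclusion
#'   (default 0.1%).
#' @return the results table with `threshold`, `significant`, and
#'   `excluded` columns.
#' @export
phenome_screen <- function(results, alpha = 0.05, n_exposures = 3,
                           prevalence_min = 0.001) {
  if (is.list(results) && !is.data.frame(results)) {
    results <- do.call(rbind, lapply(names(results), function(nm) {
      r <- results[[nm]]
      data.frame(trait = nm, exposure = r$exposure, beta = r$beta, se = r$se,
                 p = r$p, or = r$or, prevalence = r$prevalence,
                 stringsAsFactors = FALSE)
    }))
  }
  excluded <- results$prevalence < prevalence_min
  n_traits <- length(unique(results$trait[!excluded]))
  threshold <- alpha / (max(n_traits, 1) * n_exposures)
  results$threshold <- threshold
  results$excluded <- ifelse(excluded, "prevalence below floor", NA_character_)
  results$significant <- !excluded & results$p < threshold
  results
}
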