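#' Correlate spatial BLUPs with community-level risk factors
#'
#' Regresses the per-location best linear unbiased predictors of the
#' spatial random effect on external community-level environmental risk
#' factors (pollution, climate, sociodemographics), one covariate at a
#' time, reporting the Pearson correlation and the regression slope.
#' Traits are screened before testing: by default a trait must have an
#' observed prevalence of at least 2% and a (Gower-standardized) spatial
#' variance fraction of at least 2%.
#'
#' @param fits a named list of `smile` fits (one per trait), or a single
#'   fit.
#' @param covariates a data.frame keyed by `location_id` with numeric
#'   covariate columns.
#' @param prevalence_min,spatial_var_min trait inclusion filters.
#' @return a data.frame with one row per (trait, covariate): Pearson `r`,
#'   regression `slope`, `n` locations used, and an `excluded` reason for
#'   filtered traits (constant covariates give `NA` correlations).
#' @export
blup_correlations <- function(fits, covariates,
                              prevalence_min = 0.02, spatial_var_min = 0.02) {
  if (inherits(fits, "smile")) fits <- list(trait = fits)
  if (!"location_id" %in% names(covariates))
    stop("covariates must contain a location_id column")
  covariates <- as.data.frame(covariates)
  cov_names <- setdiff(names(covariates), "location_id")
  out <- list()
  for (trait in names(fits)) {
    fit <- fits[[trait]]
    excluded <- NA_character_
    if (!"S" %in% fit$components) excluded <- "no spatial component"
    else if (fit$prevalence < prevalence_min) excluded <- "prevalence below floor"
    else if (fit$sigma_s2_gower / total_variance(fit) < spatial_var_min)
      excluded <- "spatial variance below floor"
    if (!is.na(excluded)) {
      out[[trait]] <- data.frame(trait = trait, covariate = cov_names,
                                 r = NA_real_, slope = NA_real_, n = 0L,
                                 excluded = excluded, stringsAsFactors = FALSE)
      next
    }
    b <- blup(fit)
    idx <- match(names(b), covariates$location_id)
    rows <- lapply(cov_names, function(cn) {
      x <- covariates[[cn]][idx]
      ok <- is.finite(x) & is.finite(b)
      if (sum(ok) < 3 || stats::sd(x[ok]) == 0) {
        data.frame(trait = trait, covariate = cn, r = NA_real_,
                   slope = NA_real_, n = sum(ok),
                   excluded = "constant or missing covariate",
                   stringsAsFactors = FALSE)
      } else {
        r <- stats::cor(b[ok], x[ok])
        slope <- r * stats::sd(b[ok]) / stats::sd(x[ok])
        data.frame(trait = trait, covariate = cn, r = r, slope = slope,
                   n = sum(ok), excluded = NA_character_,
                   stringsAsFactors = FALSE)
      }
    })
    out[[trait]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
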