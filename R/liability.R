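#' Convert observed-scale variance components to the liability scale
#'
#' Binary outcomes are modeled linearly on the observed 0/1 scale; under the
#' liability threshold model the variance components convert to the latent
#' liability scale. Two conversions are available:
#'
#' \describe{
#' \item{`"tetrachoric"` (default)}{Component-wise exact inversion of the
#'   bivariate-normal pair covariances. The fitted observed-scale components
#'   imply a covariance for each within-family pair class --
#'   father-mother (`par + s`), parent-child (`g/2 + s`), sibling-sibling
#'   (`g/2 + child + s`) -- and for pairs of unrelated individuals sharing a
#'   location (`s`). Each class covariance is inverted through the
#'   bivariate-normal upper-orthant probability to a liability correlation,
#'   and the four liability components are recomposed from the class system.
#'   This is exact for any normally distributed shared effect and avoids the
#'   first-order conversion's inflation when pair correlations are not
#'   small relative to the threshold.}
#' \item{`"multiplier"`}{The classical first-order factor `K(1-K)/z^2`,
#'   `z = dnorm(qnorm(1-K))`, applied uniformly to every variance fraction.
#'   Accurate when all pair covariances are small; retained for comparison
#'   with published estimates that use it.}
#' }
#' No ascertainment correction is applied (appropriate for population,
#' non-case-enriched samples).
#'
#' @param x a `smile` fit, or a named numeric vector of observed-scale
#'   variances (components among `g`, `par`, `child`, `s`, `eps`; `s` is
#'   taken as already Gower-standardized).
#' @param K disease prevalence in (0, 1); defaults to the fit's observed
#'   prevalence when `x` is a fit.
#' @param method `"tetrachoric"` or `"multiplier"`.
#' @return a data.frame with one row per component: the observed-scale
#'   variance fraction and its liability-scale counterpart. The residual
#'   fraction on the liability scale is the complement of the converted
#'   components.
#' @export
liability_scale <- function(x, K = NULL, method = c("tetrachoric", "multiplier")) {
  method <- match.arg(method)
  if (inherits(x, "smile")) {
    if (is.null(K)) K <- x$prevalence
    v <- stats::setNames(x$vc$variance, x$vc$component)
    if ("s" %in% names(v)) v["s"] <- x$sigma_s2_gower
  } else {
    v <- x
    if (is.null(K)) stop("prevalence K must be supplied")
  }
  if (!is.numeric(K) || length(K) != 1 || K <= 0 || K >= 1)
    stop("prevalence K must lie strictly in (0, 1)")
  tot <- sum(v)
  frac_obs <- v / tot

  full <- stats::setNames(rep(0, 4), c("g", "par", "child", "s"))
  present <- intersect(names(full), names(frac_obs))
  full[present] <- frac_obs[present]

  if (method == "multiplier") {
    mult <- liability_multiplier(K)
    liab <- full * mult
  } else {
    KK <- K * (1 - K)
    class_cov <- KK * c(fm = full[["par"]] + full[["s"]],
                        pc = 0.5 * full[["g"]] + full[["s"]],
                        ss = 0.5 * full[["g"]] + full[["child"]] + full[["s"]],
                        loc = full[["s"]])
    r <- vapply(class_cov, tetrachoric_from_cov, numeric(1), K = K)
    s_l <- r[["loc"]]
    liab <- c(g = 2 * (r[["pc"]] - s_l),
              par = r[["fm"]] - s_l,
              child = r[["ss"]] - r[["pc"]],
              s = s_l)
    liab <- pmin(pmax(liab, 0), 1)
  }

  out_comp <- names(frac_obs)
  frac_liab <- stats::setNames(rep(NA_real_, length(out_comp)), out_comp)
  frac_liab[present] <- liab[present]
  if ("eps" %in% out_comp)
    frac_liab["eps"] <- max(1 - sum(frac_liab[present]), 0)
  data.frame(component = out_comp,
             observed = unname(frac_obs),
             liability = unname(frac_liab),
             stringsAsFactors = FALSE)
}

#' Liability correlation from an observed-scale covariance
#'
#' Inverts `P11(r) - K^2 = c`, where `P11(r)` is the probability that both
#' members of a pair with liability correlation `r` exceed the threshold
#' `qnorm(1 - K)`. The upper-orthant probability is computed by univariate
#' quadrature of the conditional normal tail.
#'
#' @param c_obs observed-scale (0/1) covariance of the pair.
#' @param K prevalence.
#' @return the liability-scale correlation.
#' @export
tetrachoric_from_cov <- function(c_obs, K) {
  if (abs(c_obs) < 1e-14) return(0)
  t <- stats::qnorm(1 - K)
  lo <- -0.999; hi <- 0.999
  c_obs <- min(max(c_obs, bvn_upper(t, lo) - K^2 + 1e-12),
               bvn_upper(t, hi) - K^2 - 1e-12)
  stats::uniroot(function(r) bvn_upper(t, r) - K^2 - c_obs,
                 c(lo, hi), tol = 1e-10)$root
}

# P(X > t, Y > t) for standard bivariate normal with correlation r
bvn_upper <- function(t, r) {
  if (abs(r) < 1e-12) return(stats::pnorm(t, lower.tail = FALSE)^2)
  stats::integrate(function(x)
    stats::dnorm(x) * stats::pnorm((t - r * x) / sqrt(1 - r^2), lower.tail = FALSE),
    t, Inf, rel.tol = 1e-10)$value
}

#' Observed-to-liability scale multiplier
#'
#' `K(1-K)/z^2` with `z` the standard-normal density at the
#' `(1-K)`-quantile. At `K = 0.5` the multiplier is `pi/2`.
#'
#' @param K prevalence in (0, 1).
#' @return scalar multiplier.
#' @export
liability_multiplier <- function(K) {
  if (!is.numeric(K) || any(K <= 0) || any(K >= 1))
    stop("prevalence K must lie strictly in (0, 1)")
  z <- stats::dnorm(stats::qnorm(1 - K))
  K * (1 - K) / z^2
}

#' Liability-scale heritability of a fit
#'
#' @param fit a `smile` fit.
#' @param K prevalence (defaults to the observed prevalence).
#' @param method conversion method, see [liability_scale()].
#' @return scalar liability-scale heritability.
#' @export
heritability_liability <- function(fit, K = NULL, method = "tetrachoric") {
  tab <- liability_scale(fit, K, method = method)
  h <- tab$liability[tab$component == "g"]
  if (length(h) == 0) 0 else h
}
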