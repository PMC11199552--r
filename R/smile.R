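#' Fit a spatial mixed linear effect model to a family cohort
#'
#' Maximum-likelihood estimation of the observed-scale linear mixed model
#' for binary disease status in nuclear families,
#' \deqn{Y = X\pi + u_g + Z_s u_s + Z_{par} u_{par} + Z_{child} u_{child} + \epsilon,}
#' where `u_g` is the genetic random effect with per-family kinship
#' covariance, `u_par`/`u_child` are the parent- and child-shared family
#' environment effects, and `u_s` is a location-level random effect with an
#' independent (IND), conditional autoregressive (CAR), or simultaneous
#' autoregressive (SAR) covariance on the location adjacency graph. Binary
#' outcomes are modeled linearly on the observed 0/1 scale; estimates can be
#' converted to the liability scale with [liability_scale()].
#'
#' Variances are optimized on the log scale and the spatial autocorrelation
#' on the `atanh` scale (bounded at |rho| <= 0.99), with fixed effects
#' profiled out by generalized least squares at every evaluation. The
#' optimizer starts from three deterministic initializations (equal split,
#' residual-dominant, spatial- or genetic-dominant); the best-scoring start
#' is polished first and the others are used as fallbacks if it fails to
#' converge.
#'
#' @param formula model formula, e.g. `status ~ age + sex`; the response is
#'   the 0/1 disease indicator and the right-hand side gives the
#'   individual-level fixed-effect covariates (an intercept is added unless
#'   suppressed).
#' @param data a [smile_cohort], or a data.frame with the pedigree columns
#'   plus the model variables.
#' @param graph a [location_graph]; required when `"S"` is among the
#'   components.
#' @param components character subset of `c("G","P","C","S")`: genetic,
#'   parent-shared, child-shared, and spatial community-level variance
#'   components. The residual variance is always included.
#' @param spatial covariance structure of the spatial component: `"CAR"`,
#'   `"SAR"` or `"IND"`.
#' @param se logical; compute standard errors of the variance components
#'   from the observed information (numerical Hessian). Fixed-effect
#'   standard errors are always available.
#' @param start optional named list of starting values (variances among
#'   `g`, `par`, `child`, `s`, `eps`, plus `rho`), tried in addition to the
#'   deterministic initializations; used e.g. to warm-start nested
#'   sub-models from a full-model fit.
#' @param control a list from [smile_control()].
#'
#' @return an object of class `"smile"` with components estimates
#'   (`$vc`), fixed effects (`$coefficients`), the Gower-standardized
#'   spatial variance (`$sigma_s2_gower`), log-likelihood, BIC, spatial
#'   BLUPs (`$blup`), and convergence diagnostics. Methods: `print`,
#'   `summary`, `coef`, `vcov`, `logLik`, `fitted`, `residuals`,
#'   [blup()], `simulate`.
#' @seealso [smile_models()] for the canonical eight-submodel comparison,
#'   [smile2()] for the two-stage instrumental-variable extension.
#' @export
smile <- function(formula, data, graph = NULL,
                  components = c("G", "P", "C", "S"),
                  spatial = c("CAR", "SAR", "IND"),
                  se = TRUE, start = NULL, control = smile_control()) {
  cl <- match.call()
  spatial <- match.arg(spatial)
  components <- match.arg(components, c("G", "P", "C", "S"), several.ok = TRUE)
  cohort <- as_smile_cohort(data)
  mf <- stats::model.frame(formula, cohort$data, na.action = stats::na.fail)
  Y <- stats::model.response(mf)
  if (!is.numeric(Y)) stop("response must be numeric 0/1 disease status")
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  check_design(X)
  prev <- mean(Y)
  if (all(Y %in% c(0, 1)) && (prev <= 0 || prev >= 1))
    stop("phenotype prevalence is ", prev, "; must lie strictly in (0, 1)")
  n_par_free <- length(components) + 1L + as.integer("S" %in% components && spatial != "IND")
  if (cohort$N < 10 * (n_par_free + ncol(X)))
    warning("fewer than 10 observations per free parameter; estimates may be unstable")

  str <- smile_structure(cohort, graph, components, spatial)
  fit <- smile_optimize(str, Y, X, control, start = start)

  vc <- fit$vc
  eval_opt <- smile_eval(str, vc, Y, X, want_pieces = TRUE)

  # Gower-standardized spatial variance and location BLUPs
  sigma_s2_gower <- NA_real_
  blup_s <- NULL
  Sigma_s <- NULL
  if (str$has_S) {
    Sigma_s <- spatial_covariance(graph, spatial, vc$s, vc$rho %||% 0)
    sigma_s2_gower <- gower_factor(str$loc_index, Sigma_s)
    tvec <- drop(as.matrix(Matrix::crossprod(spatial_design(cohort), eval_opt$Vinv_r)))
    blup_s <- drop(as.matrix(Matrix::solve(eval_opt$Q, tvec)))
    names(blup_s) <- graph$locations
  }

  comp_names <- intersect(c("g", "par", "child", "s"), names(vc))
  variances <- c(unlist(vc[comp_names]), eps = vc$eps)
  rho <- if (str$has_S && spatial != "IND") vc$rho else NA_real_

  vc_se <- rep(NA_real_, length(variances))
  rho_se <- NA_real_
  boundary <- variances < control$boundary_tol
  names(boundary) <- names(variances)
  if (se) {
    ses <- smile_vc_se(str, fit, Y, X, control)
    vc_se <- ses$vc_se
    rho_se <- ses$rho_se
  }

  df <- length(fit$par) + ncol(X)
  ll <- fit$loglik
  bic <- -2 * ll + df * log(cohort$N)

  fitted_vals <- drop(X %*% eval_opt$pi_hat)
  out <- list(
    call = cl, formula = formula, components = components, spatial = spatial,
    coefficients = stats::setNames(eval_opt$pi_hat, colnames(X)),
    vcov_fixed = structure(eval_opt$vcov_fixed, dimnames = list(colnames(X), colnames(X))),
    vc = data.frame(component = names(variances), variance = unname(variances),
                    se = unname(vc_se), boundary = unname(boundary),
                    stringsAsFactors = FALSE),
    rho = rho, rho_se = rho_se,
    sigma_s2_gower = sigma_s2_gower,
    logLik = ll, df = df, BIC = bic,
    nobs = cohort$N, n_families = cohort$N_F,
    n_locations = str$L,
    prevalence = prev,
    blup = blup_s,
    fitted = fitted_vals,
    residuals = Y - fitted_vals,
    convergence = fit$convergence,
    cohort = cohort, graph = graph,
    Y = Y, X = X
  )
  class(out) <- "smile"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Control parameters for [smile()]
#'
#' @param rel_tol relative convergence tolerance on the log-likelihood.
#' @param grad_tol gradient infinity-norm below which the solution is
#'   declared converged.
#' @param max_iter maximum optimizer iterations per start.
#' @param rho_max cap on |rho| during estimation.
#' @param boundary_tol variance below which an estimate is flagged as lying
#'   on the zero boundary (one-sided standard error).
#' @param log_var_bounds bounds on log-variances during optimization.
#' @return a list of control values.
#' @export
smile_control <- function(rel_tol = 1e-9, grad_tol = 1e-5, max_iter = 500,
                          rho_max = 0.99, boundary_tol = 1e-7,
                          log_var_bounds = c(-25, 10)) {
  list(rel_tol = rel_tol, grad_tol = grad_tol, max_iter = max_iter,
       rho_max = rho_max, boundary_tol = boundary_tol,
       log_var_bounds = log_var_bounds)
}

# parameter vector <-> named variance list
smile_par_template <- function(components, spatial) {
  nm <- c(if ("G" %in% components) "g",
          if ("P" %in% components) "par",
          if ("C" %in% components) "child",
          if ("S" %in% components) "s",
          "eps")
  list(names = nm, has_rho = "S" %in% components && spatial != "IND")
}

smile_par_to_vc <- function(par, tmpl, rho_max) {
  k <- length(tmpl$names)
  vc <- as.list(exp(par[seq_len(k)]))
  names(vc) <- tmpl$names
  if (tmpl$has_rho) vc$rho <- rho_max * tanh(par[k + 1L]) else
    if ("s" %in% tmpl$names) vc$rho <- 0
  vc
}

smile_optimize <- function(str, Y, X, control, start = NULL) {
  tmpl <- smile_par_template(str$components, str$spatial)
  k <- length(tmpl$names)
  vy <- stats::var(Y)

  objective <- function(par) {
    vc <- smile_par_to_vc(par, tmpl, control$rho_max)
    ll <- tryCatch(smile_eval(str, vc, Y, X)$loglik, error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }

  starts <- smile_starts(tmpl, vy)
  if (!is.null(start)) {
    v0 <- pmax(unlist(start[tmpl$names]), 1e-8)
    v0[is.na(v0)] <- 0.05 * vy
    p0 <- log(v0)
    if (tmpl$has_rho) {
      r0 <- start$rho %||% 0.5
      if (is.na(r0)) r0 <- 0.5
      p0 <- c(p0, atanh(min(max(r0 / control$rho_max, -0.99), 0.99)))
    }
    starts <- c(list(p0), starts)
  }
  obj0 <- vapply(starts, objective, numeric(1))
  order_try <- order(obj0)

  lower <- c(rep(control$log_var_bounds[1], k), if (tmpl$has_rho) -4)
  upper <- c(rep(control$log_var_bounds[2], k), if (tmpl$has_rho) 4)

  best <- NULL
  for (i in order_try) {
    res <- tryCatch(
      stats::nlminb(starts[[i]], objective, lower = lower, upper = upper,
                    control = list(rel.tol = control$rel_tol,
                                   iter.max = control$max_iter,
                                   eval.max = 4 * control$max_iter)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$objective < best$objective - 1e-8) {
      best <- res
      best$start_used <- i
    }
    if (!is.null(best) && best$convergence == 0) break
  }
  if (is.null(best)) stop("all optimizer starts failed")

  grad <- numeric(length(best$par))
  h <- 1e-4
  f0 <- best$objective
  for (j in seq_along(grad)) {
    pp <- best$par; pm <- best$par
    pp[j] <- pp[j] + h; pm[j] <- pm[j] - h
    grad[j] <- (objective(pp) - objective(pm)) / (2 * h)
  }
  # at an active bound (variance collapsed to zero) the gradient need not vanish
  at_bound <- best$par <= lower + 1e-6 | best$par >= upper - 1e-6
  gnorm <- max(c(abs(grad[!at_bound]), 0))
  converged <- best$convergence == 0 || gnorm < control$grad_tol

  vc <- smile_par_to_vc(best$par, tmpl, control$rho_max)
  list(vc = vc, par = best$par, loglik = -best$objective, tmpl = tmpl,
       objective = objective,
       convergence = list(converged = converged, code = best$convergence,
                          grad_norm = gnorm, start_used = best$start_used,
                          message = best$message))
}

smile_starts <- function(tmpl, vy) {
  k <- length(tmpl$names)
  eq <- rep(vy / k, k)
  resid_dom <- rep(0.1 * vy / max(k - 1, 1), k)
  resid_dom[k] <- 0.9 * vy
  dom <- rep(0.5 * vy / max(k - 1, 1), k)
  dom_idx <- if ("s" %in% tmpl$names) match("s", tmpl$names) else 1L
  dom[dom_idx] <- 0.5 * vy
  lapply(list(eq, resid_dom, dom), function(v) {
    p <- log(v)
    if (tmpl$has_rho) p <- c(p, atanh(0.5))
    p
  })
}

smile_vc_se <- function(str, fit, Y, X, control) {
  par <- fit$par
  tmpl <- fit$tmpl
  k <- length(tmpl$names)
  H <- tryCatch(stats::optimHess(par, fit$objective), error = function(e) NULL)
  vc_se <- rep(NA_real_, k)
  rho_se <- NA_real_
  if (!is.null(H)) {
    Vp <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(Vp)) {
      d <- sqrt(pmax(diag(Vp), 0))
      # delta method: var on natural scale
      vc_se <- exp(par[seq_len(k)]) * d[seq_len(k)]
      if (tmpl$has_rho) {
        rho <- control$rho_max * tanh(par[k + 1L])
        rho_se <- (control$rho_max - rho^2 / control$rho_max) * d[k + 1L]
      }
    }
  }
  # one-sided at the zero boundary: SE on the natural scale is not meaningful
  vc_se[exp(par[seq_len(k)]) < control$boundary_tol] <- NA_real_
  list(vc_se = stats::setNames(vc_se, tmpl$names), rho_se = rho_se)
}

# ---------------------------------------------------------------------------
# methods

#' @export
print.smile <- function(x, digits = 4, ...) {
  cat("Spatial mixed linear effect model (observed scale)\n")
  cat("  components:", paste(x$components, collapse = "+"),
      if ("S" %in% x$components) paste0("(", x$spatial, ")"), "\n")
  cat("  N =", x$nobs, "individuals in", x$n_families, "families,",
      x$n_locations, "locations; prevalence =", signif(x$prevalence, 3), "\n\n")
  v <- x$vc
  lbl <- c(g = "genetic", par = "parent-shared", child = "child-shared",
           s = "spatial (raw)", eps = "residual")
  tab <- data.frame(component = lbl[v$component], variance = signif(v$variance, digits),
                    se = signif(v$se, digits))
  print(tab, row.names = FALSE)
  if ("S" %in% x$components) {
    cat("  spatial variance (Gower):", signif(x$sigma_s2_gower, digits), "\n")
    if (!is.na(x$rho)) cat("  rho:", signif(x$rho, digits), "\n")
  }
  cat("  h2 (observed scale):", signif(heritability(x), digits), "\n")
  cat("  logLik:", format(x$logLik, digits = 8), "  BIC:", format(x$BIC, digits = 8), "\n")
  if (!x$convergence$converged) cat("  WARNING: fit flagged as not converged\n")
  invisible(x)
}

#' Observed-scale heritability of a fit
#'
#' Genetic variance over total phenotypic variance; the spatial component
#' enters through its Gower-standardized value.
#'
#' @param fit a `smile` fit.
#' @return scalar heritability estimate on the observed scale.
#' @export
heritability <- function(fit) {
  v <- stats::setNames(fit$vc$variance, fit$vc$component)
  tot <- total_variance(fit)
  if (!"g" %in% names(v)) return(0)
  unname(v["g"] / tot)
}

total_variance <- function(fit) {
  v <- stats::setNames(fit$vc$variance, fit$vc$component)
  tot <- sum(v[setdiff(names(v), "s")])
  if ("s" %in% names(v)) tot <- tot + fit$sigma_s2_gower
  tot
}

#' @export
summary.smile <- function(object, K = NULL, ...) {
  co <- object$coefficients
  se <- sqrt(diag(object$vcov_fixed))
  z <- co / se
  fixef <- cbind(Estimate = co, `Std. Error` = se, `z value` = z,
                 `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  out <- list(fit = object, fixef = fixef,
              h2_obs = heritability(object),
              liability = if (!is.null(K)) liability_scale(object, K) else NULL)
  class(out) <- "summary.smile"
  out
}

#' @export
print.summary.smile <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("\nFixed effects:\n")
  stats::printCoefmat(x$fixef, digits = digits)
  if (!is.null(x$liability)) {
    cat("\nLiability-scale variance fractions:\n")
    print(x$liability, digits = digits)
  }
  invisible(x)
}

#' @export
coef.smile <- function(object, ...) object$coefficients

#' @export
vcov.smile <- function(object, ...) object$vcov_fixed

#' @export
logLik.smile <- function(object, ...) {
  structure(object$logLik, df = object$df, nobs = object$nobs,
            class = "logLik")
}

#' @export
fitted.smile <- function(object, ...) object$fitted

#' @export
residuals.smile <- function(object, ...) object$residuals

#' @export
nobs.smile <- function(object, ...) object$nobs

#' Best linear unbiased predictors of random effects
#'
#' @param object a fitted model.
#' @param ... passed to methods.
#' @export
blup <- function(object, ...) UseMethod("blup")

#' Location-level BLUPs from a smile fit
#'
#' The empirical best linear unbiased predictor of the spatial random effect,
#' `u_hat = Sigma_s Z_s' V^{-1} (Y - X pi_hat)`, one value per location on
#' the adjacency graph. The predictor shrinks toward zero as the spatial
#' variance vanishes.
#'
#' @param object a `smile` fit that includes the S component.
#' @param ... unused.
#' @return named numeric vector of length L (graph location order).
#' @export
blup.smile <- function(object, ...) {
  if (!"S" %in% object$components)
    stop("fit does not include a spatial (S) component")
  object$blup
}

#' Simulate responses from a fitted smile model
#'
#' Draws Gaussian responses from the fitted observed-scale linear mixed
#' model (fixed effects plus all fitted random-effect draws). Values are
#' continuous; threshold externally if binary replicates are needed.
#'
#' @param object a `smile` fit.
#' @param nsim number of replicate response vectors.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return a data.frame with `nsim` columns of length N.
#' @export
simulate.smile <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  v <- stats::setNames(object$vc$variance, object$vc$component)
  cohort <- object$cohort
  out <- matrix(0, cohort$N, nsim)
  for (i in seq_len(nsim)) {
    y <- object$fitted
    y <- y + draw_family_effects(cohort, g = v["g"] %|na|% 0,
                                 par = v["par"] %|na|% 0,
                                 child = v["child"] %|na|% 0)
    if ("s" %in% names(v) && v["s"] > 0) {
      us <- drop(sim_spatial_effects(object$graph, object$spatial,
                                     sigma_s2 = v[["s"]],
                                     rho = object$rho %|na|% 0, n = 1))
      y <- y + us[as.integer(cohort$location)]
    }
    y <- y + stats::rnorm(cohort$N, sd = sqrt(v[["eps"]]))
    out[, i] <- y
  }
  as.data.frame(out)
}

`%|na|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else unname(a)
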