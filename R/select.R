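#' The canonical eight-submodel set
#'
#' Component combinations compared by BIC in the analysis: GPC+S, GP+S,
#' GC+S, GPC, PC+S, PC, G+S, and S, where G, P, C, S denote the genetic,
#' parental, children, and spatial community-level variance components.
#'
#' @return a named list of component character vectors.
#' @export
smile_model_set <- function() {
  list(
    `GPC+S` = c("G", "P", "C", "S"),
    `GP+S`  = c("G", "P", "S"),
    `GC+S`  = c("G", "C", "S"),
    `GPC`   = c("G", "P", "C"),
    `PC+S`  = c("P", "C", "S"),
    `PC`    = c("P", "C"),
    `G+S`   = c("G", "S"),
    `S`     = "S"
  )
}

#' Fit a set of sub-models to one phenotype
#'
#' Fits each requested component combination to the same response, cohort
#' and fixed effects, so the fits are comparable by BIC. The full model is
#' fitted first and its estimates warm-start the nested sub-models.
#'
#' @inheritParams smile
#' @param models named list of component subsets; defaults to the canonical
#'   eight ([smile_model_set()]).
#' @param ... passed to [smile()].
#' @return an object of class `smile_models`: the list of fits plus a BIC
#'   table. Use [select_model()] to extract the best fit.
#' @export
smile_models <- function(formula, data, graph, models = smile_model_set(),
                         spatial = "CAR", se = FALSE, ...) {
  cohort <- as_smile_cohort(data)
  fits <- vector("list", length(models))
  names(fits) <- names(models)
  # fit the richest model first; its estimates warm-start the nested ones
  ord <- order(-vapply(models, length, integer(1)))
  warm <- NULL
  for (nm in names(models)[ord]) {
    fits[[nm]] <- smile(formula, cohort, graph = graph,
                        components = models[[nm]],
                        spatial = if ("S" %in% models[[nm]]) spatial else "IND",
                        se = se, start = warm, ...)
    if (is.null(warm)) {
      f <- fits[[nm]]
      warm <- as.list(stats::setNames(f$vc$variance, f$vc$component))
      warm$rho <- f$rho
    }
  }
  tab <- data.frame(
    model = names(fits),
    df = vapply(fits, function(f) f$df, numeric(1)),
    logLik = vapply(fits, function(f) f$logLik, numeric(1)),
    BIC = vapply(fits, function(f) f$BIC, numeric(1)),
    converged = vapply(fits, function(f) f$convergence$converged, logical(1)),
    stringsAsFactors = FALSE
  )
  structure(list(fits = fits, table = tab), class = "smile_models")
}

#' @export
print.smile_models <- function(x, ...) {
  cat("Sub-model comparison (", nrow(x$table), " fits)\n", sep = "")
  tab <- x$table[order(x$table$BIC), ]
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Select the best-fitting model by BIC
#'
#' Returns the fit with the smallest Bayesian Information Criterion,
#' `BIC = -2 logLik + p log(N)`; ties are broken toward the model with
#' fewer free parameters.
#'
#' @param fits a `smile_models` object or a list of `smile` fits on the
#'   same data.
#' @return the selected `smile` fit, with the chosen model's name in
#'   attribute `"model"`.
#' @export
select_model <- function(fits) {
  if (inherits(fits, "smile_models")) fits <- fits$fits
  if (length(fits) == 0) stop("no fits supplied")
  bic <- vapply(fits, function(f) f$BIC, numeric(1))
  df <- vapply(fits, function(f) f$df, numeric(1))
  best <- order(bic, df)[1]
  out <- fits[[best]]
  attr(out, "model") <- names(fits)[best] %||% best
  out
}
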