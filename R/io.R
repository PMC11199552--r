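# Plain UTF-8 TSV readers/writers for all tabular interchange formats.
# Missing values are empty fields; machine-readable outputs keep full
# precision.

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = "")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(what, " file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a pedigree file
#'
#' Tab-separated with header `individual_id family_id role sex birth_year
#' months_enrolled location_id`; roles must be `father`, `mother` or
#' `child`, and individual ids unique. Violations are reported with the
#' offending line numbers (header is line 1).
#'
#' @param path file path.
#' @return a validated pedigree data.frame (not yet canonically ordered;
#'   pass to [smile_cohort()]).
#' @export
read_pedigree <- function(path) {
  ped <- read_tsv_checked(path, c("individual_id", "family_id", "role", "sex",
                                  "birth_year", "months_enrolled", "location_id"),
                          "pedigree")
  bad <- which(!ped$role %in% c("father", "mother", "child"))
  if (length(bad))
    stop("pedigree file ", path, ": invalid role at line(s) ",
         paste(bad + 1L, collapse = ", "), " (",
         paste(unique(ped$role[bad]), collapse = ", "), ")")
  dup <- which(duplicated(ped$individual_id))
  if (length(dup))
    stop("pedigree file ", path, ": duplicate individual_id at line(s) ",
         paste(dup + 1L, collapse = ", "))
  ped
}

#' Write a cohort's pedigree table
#' @param cohort a [smile_cohort] or pedigree data.frame.
#' @param path output path.
#' @export
write_pedigree <- function(cohort, path) {
  df <- if (inherits(cohort, "smile_cohort")) cohort$data else cohort
  keep <- c("individual_id", "family_id", "role", "sex", "birth_year",
            "months_enrolled", "location_id",
            intersect(c("enroll_year", "age"), names(df)))
  write_tsv(df[, keep], path)
}

#' Read an undirected location adjacency edge list
#'
#' Tab-separated `location_a location_b`, one edge per line.
#'
#' @param path file path.
#' @param locations optional full location set (defaults to the endpoints
#'   present in the file).
#' @return a [location_graph].
#' @export
read_adjacency <- function(path, locations = NULL) {
  edges <- read_tsv_checked(path, c("location_a", "location_b"), "adjacency")
  if (is.null(locations))
    locations <- sort(unique(c(edges$location_a, edges$location_b)))
  location_graph(edges[, c("location_a", "location_b")], locations)
}

#' Write a graph's edge list
#' @param graph a [location_graph].
#' @param path output path.
#' @export
write_adjacency <- function(graph, path) {
  Wt <- Matrix::which(Matrix::triu(graph$W) != 0, arr.ind = TRUE)
  write_tsv(data.frame(location_a = graph$locations[Wt[, 1]],
                       location_b = graph$locations[Wt[, 2]]), path)
}

#' Read a long-format phenotype file
#'
#' Tab-separated `individual_id phenotype_id status` with status 0/1.
#'
#' @param path file path.
#' @return a data.frame.
#' @export
read_phenotypes <- function(path) {
  ph <- read_tsv_checked(path, c("individual_id", "phenotype_id", "status"),
                         "phenotype")
  bad <- which(!ph$status %in% c(0, 1))
  if (length(bad))
    stop("phenotype file ", path, ": status must be 0/1 at line(s) ",
         paste(bad + 1L, collapse = ", "))
  ph
}

#' Write phenotypes in long format
#' @param Y named 0/1 vector (names = individual ids) or a data.frame
#'   already in long format.
#' @param phenotype_id phenotype label used when `Y` is a vector.
#' @param path output path.
#' @export
write_phenotypes <- function(Y, path, phenotype_id = "trait") {
  if (is.data.frame(Y)) return(write_tsv(Y, path))
  write_tsv(data.frame(individual_id = names(Y), phenotype_id = phenotype_id,
                       status = as.integer(Y)), path)
}

#' Read a location covariate / exposure / instrument table
#'
#' Tab-separated, keyed by `location_id`; any numeric columns (e.g. `pm25`,
#' `no2`, `wind_speed`, `wind_dir`, sociodemographics) are carried along.
#'
#' @param path file path.
#' @return a data.frame.
#' @export
read_locations <- function(path) {
  read_tsv_checked(path, "location_id", "location covariate")
}

#' Write a location-keyed table
#' @param df data.frame with a `location_id` column.
#' @param path output path.
#' @export
write_locations <- function(df, path) {
  if (!"location_id" %in% names(df)) stop("table must have a location_id column")
  write_tsv(df, path)
}

#' Load a cohort, its phenotypes, and the adjacency graph from files
#'
#' @param pedigree_path,phenotype_path,adjacency_path file paths.
#' @return a list with `cohort`, `graph`, and the long `phenotypes` table;
#'   pedigree locations absent from the adjacency file are reported.
#' @export
load_cohort <- function(pedigree_path, phenotype_path, adjacency_path) {
  ped <- read_pedigree(pedigree_path)
  graph <- read_adjacency(adjacency_path)
  orphan <- setdiff(unique(ped$location_id), graph$locations)
  if (length(orphan))
    warning("pedigree location(s) absent from the adjacency graph: ",
            paste(orphan, collapse = ", "))
  cohort <- smile_cohort(ped, locations = union(graph$locations, orphan))
  phen <- read_phenotypes(phenotype_path)
  unknown <- setdiff(unique(phen$individual_id), cohort$data$individual_id)
  if (length(unknown))
    stop("phenotype file references unknown individual(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))
  list(cohort = cohort, graph = graph, phenotypes = phen)
}

phenotype_vector <- function(cohort, phenotypes, phenotype_id) {
  ph <- phenotypes[phenotypes$phenotype_id == phenotype_id, ]
  Y <- rep(0L, cohort$N)
  idx <- match(ph$individual_id, cohort$data$individual_id)
  Y[idx] <- as.integer(ph$status)
  Y
}

#' Run the full analysis pipeline from a configuration
#'
#' Reads the input files, fits the requested sub-models to every phenotype,
#' selects the best by BIC, converts components to the liability scale,
#' correlates spatial BLUPs with location covariates, and (when exposure
#' and instrument columns are available) runs the two-stage causal screen.
#' Per-trait failures are logged and skipped, never aborting the loop.
#'
#' @param config a YAML file path or an equivalent named list with entries
#'   `pedigree`, `phenotypes`, `adjacency`, optional `locations`
#'   (covariate/exposure/instrument table), `formula` (default
#'   `status ~ age + sex`), `models` (subset of the eight canonical names),
#'   `spatial` (default `"CAR"`), `seed`, `output_dir`, and optional
#'   filters `prevalence_min_causal`, `prevalence_min_blup`,
#'   `spatial_var_min`.
#' @return invisibly, a list with the per-trait results and the paths of
#'   the artifacts written to `output_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  need <- c("pedigree", "phenotypes", "adjacency", "output_dir")
  miss <- setdiff(need, names(config))
  if (length(miss)) stop("config is missing entries: ", paste(miss, collapse = ", "))
  spatial <- config$spatial %||% "CAR"
  if (!spatial %in% c("CAR", "SAR", "IND"))
    stop("unknown spatial structure in config: ", spatial)
  model_names <- config$models %||% c("GPC+S", "GPC")
  all_models <- smile_model_set()
  unknown <- setdiff(model_names, names(all_models))
  if (length(unknown)) stop("unknown model(s) in config: ", paste(unknown, collapse = ", "))
  if (!is.null(config$seed)) set.seed(config$seed)

  t0 <- Sys.time()
  loaded <- load_cohort(config$pedigree, config$phenotypes, config$adjacency)
  loc_tab <- if (!is.null(config$locations)) read_locations(config$locations) else NULL
  form <- stats::as.formula(config$formula %||% "status ~ age + sex")
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)

  traits <- unique(loaded$phenotypes$phenotype_id)
  fit_rows <- list(); best_fits <- list(); blups <- list(); failures <- list()
  for (tr in traits) {
    res <- tryCatch({
      cohort <- loaded$cohort
      cohort$data$status <- phenotype_vector(cohort, loaded$phenotypes, tr)
      fits <- smile_models(form, cohort, loaded$graph,
                           models = all_models[model_names], spatial = spatial)
      best <- select_model(fits)
      liab <- liability_scale(best)
      rows <- do.call(rbind, lapply(names(fits$fits), function(nm) {
        f <- fits$fits[[nm]]
        v <- stats::setNames(f$vc$variance, f$vc$component)
        data.frame(phenotype = tr, model = nm,
                   sigma_g2 = v["g"] %|na|% NA_real_,
                   sigma_par2 = v["par"] %|na|% NA_real_,
                   sigma_child2 = v["child"] %|na|% NA_real_,
                   sigma_s2 = v["s"] %|na|% NA_real_,
                   sigma_s2_gower = f$sigma_s2_gower,
                   sigma_eps2 = v[["eps"]], rho = f$rho,
                   h2_obs = heritability(f),
                   h2_liab = heritability_liability(f),
                   logLik = f$logLik, BIC = f$BIC,
                   converged = f$convergence$converged,
                   selected = identical(nm, attr(best, "model")),
                   stringsAsFactors = FALSE)
      }))
      list(rows = rows, best = best)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[tr]] <- conditionMessage(res)
      next
    }
    fit_rows[[tr]] <- res$rows
    best_fits[[tr]] <- res$best
    if ("S" %in% res$best$components)
      blups[[tr]] <- blup(res$best)
  }

  artifacts <- list()
  if (length(fit_rows)) {
    fit_tab <- do.call(rbind, fit_rows)
    artifacts$fits <- file.path(config$output_dir, "fits.tsv")
    write_tsv(fit_tab, artifacts$fits)
  }
  if (length(blups)) {
    blup_tab <- data.frame(location_id = loaded$graph$locations,
                           do.call(cbind, blups), check.names = FALSE)
    artifacts$blups <- file.path(config$output_dir, "blups.tsv")
    write_tsv(blup_tab, artifacts$blups)
  }

  corr_tab <- NULL
  if (!is.null(loc_tab) && length(best_fits)) {
    covar_cols <- setdiff(names(loc_tab),
                          c("location_id", "pm25", "no2", "wind_speed", "wind_dir"))
    if (length(covar_cols)) {
      corr_tab <- blup_correlations(best_fits,
                                    loc_tab[, c("location_id", covar_cols)],
                                    prevalence_min = config$prevalence_min_blup %||% 0.02,
                                    spatial_var_min = config$spatial_var_min %||% 0.02)
      artifacts$blup_correlations <- file.path(config$output_dir, "blup_correlations.tsv")
      write_tsv(corr_tab, artifacts$blup_correlations)
    }
  }

  causal_tab <- NULL
  if (!is.null(loc_tab) &&
      all(c("pm25", "no2", "wind_speed", "wind_dir") %in% names(loc_tab))) {
    exposures <- loc_tab[, c("location_id", "pm25", "no2")]
    instruments <- loc_tab[, c("location_id", "wind_speed", "wind_dir")]
    res2 <- list()
    for (tr in names(best_fits)) {
      cohort <- loaded$cohort
      cohort$data$status <- phenotype_vector(cohort, loaded$phenotypes, tr)
      for (ex in c("pm25", "no2", "sum")) {
        est <- tryCatch(
          smile2(form, cohort, exposures, instruments, exposure = ex, se = FALSE),
          error = function(e) NULL)
        if (!is.null(est)) res2[[paste(tr, ex, sep = ".")]] <-
            data.frame(trait = tr, exposure = ex, beta = est$beta, se = est$se,
                       p = est$p, or = est$or, prevalence = est$prevalence,
                       first_stage_r2 = est$first_stage$r_squared,
                       stringsAsFactors = FALSE)
      }
    }
    if (length(res2)) {
      causal_tab <- phenome_screen(do.call(rbind, res2),
                                   prevalence_min = config$prevalence_min_causal %||% 0.001)
      artifacts$causal <- file.path(config$output_dir, "causal_screen.tsv")
      write_tsv(causal_tab, artifacts$causal)
    }
  }

  log <- c(sprintf("smilevc run %s", format(t0)),
           sprintf("seed: %s", config$seed %||% "none"),
           sprintf("R: %s", R.version.string),
           sprintf("traits: %d fitted, %d failed", length(fit_rows), length(failures)),
           sprintf("elapsed_sec: %.1f", as.numeric(difftime(Sys.time(), t0, units = "secs"))),
           if (length(failures)) paste0("failure ", names(failures), ": ", unlist(failures)))
  artifacts$log <- file.path(config$output_dir, "run_log.txt")
  writeLines(log, artifacts$log)

  invisible(list(fits = fit_rows, best = best_fits, blups = blups,
                 correlations = corr_tab, causal = causal_tab,
                 failures = failures, artifacts = artifacts))
}
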