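#' Construct a nuclear-family cohort
#'
#' Validates and canonically orders a table of individuals grouped into
#' nuclear families, each family tied to a single location. Within each
#' family, members are ordered father, mother, then children by birth year;
#' families are ordered by family id. All phenotype and covariate vectors
#' handled downstream are aligned to this ordering.
#'
#' @param data a data.frame with columns `individual_id`, `family_id`,
#'   `role` (one of `"father"`, `"mother"`, `"child"`), `sex`, `birth_year`,
#'   `months_enrolled`, `location_id`. Extra columns are carried along.
#' @param locations optional character vector fixing the location universe
#'   (e.g. the nodes of an adjacency graph); defaults to the locations
#'   present in `data`.
#'
#' @return an object of class `smile_cohort`: a list with the reordered
#'   `data`, the individual count `N`, family count `N_F`, per-family sizes,
#'   and the location factor used to build spatial design matrices.
#' @export
smile_cohort <- function(data, locations = NULL) {
  required <- c("individual_id", "family_id", "role", "sex", "birth_year",
                "months_enrolled", "location_id")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols))
    stop("pedigree data is missing column(s): ", paste(missing_cols, collapse = ", "))
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (nrow(data) == 0L) stop("pedigree data has no rows")

  data$individual_id <- as.character(data$individual_id)
  data$family_id <- as.character(data$family_id)
  data$role <- as.character(data$role)
  data$location_id <- as.character(data$location_id)

  dup <- duplicated(data$individual_id)
  if (any(dup))
    stop("duplicate individual_id(s): ",
         paste(unique(data$individual_id[dup]), collapse = ", "))
  bad_role <- !data$role %in% c("father", "mother", "child")
  if (any(bad_role))
    stop("invalid role(s): ", paste(unique(data$role[bad_role]), collapse = ", "),
         " (must be father, mother or child)")

  # canonical order: families by id; father, mother, children by birth year
  role_rank <- match(data$role, c("father", "mother", "child"))
  ord <- order(data$family_id, role_rank, data$birth_year, data$individual_id)
  data <- data[ord, , drop = FALSE]
  rownames(data) <- NULL

  fam <- factor(data$family_id, levels = unique(data$family_id))
  fi <- as.integer(fam)
  nF <- nlevels(fam)
  n_father <- tabulate(fi[data$role == "father"], nbins = nF)
  if (any(n_father > 1L))
    stop("family ", levels(fam)[which(n_father > 1L)[1]], " has more than one father")
  n_mother <- tabulate(fi[data$role == "mother"], nbins = nF)
  if (any(n_mother > 1L))
    stop("family ", levels(fam)[which(n_mother > 1L)[1]], " has more than one mother")
  first_row <- match(levels(fam), as.character(fam))
  loc_mismatch <- data$location_id != data$location_id[first_row][fi]
  if (any(loc_mismatch))
    stop("family ", as.character(fam)[which(loc_mismatch)[1]],
         " spans multiple locations; each family must be tied to one location")

  if (is.null(locations)) {
    locations <- sort(unique(data$location_id))
  } else {
    locations <- as.character(locations)
    orphan <- setdiff(data$location_id, locations)
    if (length(orphan))
      warning("location id(s) in pedigree absent from the supplied location set: ",
              paste(orphan, collapse = ", "))
    locations <- union(locations, orphan)
  }
  loc <- factor(data$location_id, levels = locations)

  structure(list(
    data = data,
    N = nrow(data),
    N_F = nlevels(fam),
    family = fam,
    family_sizes = as.integer(table(fam)),
    location = loc,
    locations = locations
  ), class = "smile_cohort")
}

#' @export
print.smile_cohort <- function(x, ...) {
  cat("Nuclear-family cohort\n")
  cat("  individuals:", x$N, "\n")
  cat("  families:   ", x$N_F, "\n")
  cat("  locations:  ", length(unique(as.character(x$location))), "used of",
      length(x$locations), "\n")
  szs <- table(x$family_sizes)
  cat("  family sizes:", paste(sprintf("%s x %s", szs, names(szs)), collapse = ", "), "\n")
  invisible(x)
}

as_smile_cohort <- function(data, locations = NULL) {
  if (inherits(data, "smile_cohort")) data else smile_cohort(data, locations)
}

#' Kinship matrix of a nuclear family
#'
#' Builds the expected-relatedness matrix (twice the kinship coefficient)
#' for a nuclear family under the assumption that all children are biological
#' children of both parents: diagonal entries 1, father-mother 0, and all
#' parent-child and full-sibling pairs 0.5. The rule extends to families with
#' a single parent or more than two children.
#'
#' @param roles character vector of member roles in canonical order
#'   (father, mother, children), each `"father"`, `"mother"` or `"child"`.
#' @return a symmetric positive semidefinite matrix of dimension
#'   `length(roles)`.
#' @export
kinship_matrix <- function(roles) {
  roles <- as.character(roles)
  if (length(roles) == 0L) stop("empty family: no roles supplied")
  if (!all(roles %in% c("father", "mother", "child")))
    stop("invalid role(s): ",
         paste(unique(roles[!roles %in% c("father", "mother", "child")]), collapse = ", "))
  k <- length(roles)
  is_parent <- roles %in% c("father", "mother")
  G <- matrix(0.5, k, k)
  # the two parents are unrelated founders
  G[is_parent, is_parent] <- 0
  diag(G) <- 1
  G
}

#' Block-diagonal genetic covariance of a cohort
#'
#' Individuals in different families are genetically unrelated, so the
#' cohort-level relatedness matrix is block diagonal in the per-family
#' kinship matrices.
#'
#' @param cohort a [smile_cohort] (or a data.frame coercible to one).
#' @return a sparse symmetric `N x N` [Matrix::Matrix] in cohort order.
#' @export
genetic_covariance <- function(cohort) {
  cohort <- as_smile_cohort(cohort)
  blocks <- lapply(split(cohort$data$role, cohort$family), kinship_matrix)
  methods::as(Matrix::bdiag(blocks), "symmetricMatrix")
}

#' Within-family environment design matrices
#'
#' Builds the indicator matrices linking individuals to the parent-shared and
#' child-shared family-environment random effects. In `Z_par`, the two
#' parents of a family load on one shared column while each child has its own
#' column; in `Z_child`, all children of a family share one column while each
#' parent has its own. Every row of each matrix has exactly one 1, so both
#' random effects contribute variance to every individual, but covariance
#' only between the two parents (parental effect) or among siblings
#' (children effect).
#'
#' @param cohort a [smile_cohort] (or a data.frame coercible to one).
#' @return a list with sparse 0/1 matrices `Z_par` (`N x q_par`) and
#'   `Z_child` (`N x q_child`).
#' @export
family_env_design <- function(cohort) {
  cohort <- as_smile_cohort(cohort)
  role <- cohort$data$role
  fam <- as.integer(cohort$family)
  is_parent <- role %in% c("father", "mother")

  # Z_par: group id = (family, shared) for parents, (family, individual) for children
  par_key <- ifelse(is_parent, paste0(fam, ":par"), paste0(fam, ":i", seq_along(fam)))
  par_col <- match(par_key, unique(par_key))
  # Z_child: shared column for children, own column for each parent
  child_key <- ifelse(!is_parent, paste0(fam, ":child"), paste0(fam, ":i", seq_along(fam)))
  child_col <- match(child_key, unique(child_key))

  N <- cohort$N
  list(
    Z_par = Matrix::sparseMatrix(i = seq_len(N), j = par_col, x = 1,
                                 dims = c(N, max(par_col))),
    Z_child = Matrix::sparseMatrix(i = seq_len(N), j = child_col, x = 1,
                                   dims = c(N, max(child_col)))
  )
}

#' Spatial incidence matrix of a cohort
#'
#' Indicator matrix mapping each individual to their location on the
#' adjacency graph; column order follows `cohort$locations`.
#'
#' @param cohort a [smile_cohort].
#' @return a sparse 0/1 `N x L` matrix.
#' @export
spatial_design <- function(cohort) {
  cohort <- as_smile_cohort(cohort)
  Matrix::sparseMatrix(i = seq_len(cohort$N), j = as.integer(cohort$location),
                       x = 1, dims = c(cohort$N, length(cohort$locations)))
}
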