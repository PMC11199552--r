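#' Location adjacency graph
#'
#' Builds the neighbourhood structure used by the spatial random effect: a
#' symmetric 0/1 adjacency matrix `W` with zero diagonal (1 for pairs of
#' locations sharing a border), its row-normalized form `W_plus`, and the
#' diagonal matrix `M` of inverse neighbour counts. Duplicate and reversed
#' edges are collapsed, so the construction is idempotent in the edge list.
#'
#' Locations with no neighbours make row normalization undefined; they are
#' retained but treated as self-contained independent components by the
#' spatial covariance constructors (variance `sigma_s2`, zero covariance
#' with every other location), and flagged with a warning here.
#'
#' @param edges two-column matrix or data.frame of undirected location pairs.
#' @param locations character vector of all location ids (the matrix order).
#' @return an object of class `location_graph` with elements `locations`,
#'   `W` (sparse), `n_neighbours`, `W_plus`, `M` (diagonal sparse), and
#'   `isolated` (logical).
#' @export
location_graph <- function(edges, locations) {
  locations <- as.character(locations)
  if (anyDuplicated(locations)) stop("duplicate location ids")
  L <- length(locations)
  if (L < 1L) stop("no locations")
  if (is.null(edges) || NROW(edges) == 0L) {
    W <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(L, L))
  } else {
    edges <- as.matrix(edges)[, 1:2, drop = FALSE]
    a <- match(as.character(edges[, 1]), locations)
    b <- match(as.character(edges[, 2]), locations)
    if (anyNA(a) || anyNA(b)) {
      bad <- unique(c(edges[is.na(a), 1], edges[is.na(b), 2]))
      stop("edge endpoint(s) not in location set: ", paste(bad, collapse = ", "))
    }
    keep <- a != b
    if (any(!keep)) warning("self-loop edge(s) dropped")
    a0 <- a[keep]; b0 <- b[keep]
    W <- Matrix::sparseMatrix(i = c(a0, b0), j = c(b0, a0), x = 1,
                              dims = c(L, L), use.last.ij = TRUE)
    W@x[] <- 1  # duplicate edges collapse to a single border
  }
  W <- methods::as(Matrix::forceSymmetric(W), "generalMatrix")
  n_nbr <- Matrix::rowSums(W)
  isolated <- n_nbr == 0
  if (any(isolated))
    warning(sum(isolated), " isolated location(s) treated as independent components")
  inv_n <- ifelse(isolated, 1, 1 / n_nbr)
  W_plus <- Matrix::Diagonal(x = inv_n) %*% W
  structure(list(
    locations = locations,
    W = W,
    n_neighbours = n_nbr,
    W_plus = W_plus,
    M = Matrix::Diagonal(x = inv_n),
    isolated = isolated
  ), class = "location_graph")
}

#' @export
print.location_graph <- function(x, ...) {
  cat("Location graph:", length(x$locations), "locations,",
      sum(x$W@x > 0) / 2, "edges")
  if (any(x$isolated)) cat(",", sum(x$isolated), "isolated")
  cat("\n")
  invisible(x)
}

#' Lattice adjacency graph
#'
#' Rook-neighbourhood rectangular lattice, a convenient synthetic stand-in
#' for a county adjacency map.
#'
#' @param nrow,ncol lattice dimensions.
#' @param n_keep optionally keep only the first `n_keep` nodes (row-major),
#'   with the induced adjacency.
#' @return a [location_graph].
#' @export
lattice_graph <- function(nrow, ncol = nrow, n_keep = NULL) {
  idx <- matrix(seq_len(nrow * ncol), nrow, ncol)
  right <- cbind(as.vector(idx[, -ncol, drop = FALSE]), as.vector(idx[, -1, drop = FALSE]))
  down <- cbind(as.vector(idx[-nrow, , drop = FALSE]), as.vector(idx[-1, , drop = FALSE]))
  edges <- rbind(right, down)
  ids <- paste0("loc", seq_len(nrow * ncol))
  if (!is.null(n_keep)) {
    n_keep <- min(n_keep, length(ids))
    keep <- seq_len(n_keep)
    edges <- edges[edges[, 1] %in% keep & edges[, 2] %in% keep, , drop = FALSE]
    ids <- ids[keep]
  }
  location_graph(matrix(paste0("loc", edges), ncol = 2), ids)
}

check_spatial_spec <- function(structure, sigma_s2, rho) {
  structure <- match.arg(structure, c("IND", "CAR", "SAR"))
  if (!is.finite(sigma_s2) || sigma_s2 < 0) stop("sigma_s2 must be >= 0")
  if (structure != "IND" && (!is.finite(rho) || abs(rho) >= 1))
    stop("spatial autocorrelation rho must lie in (-1, 1)")
  structure
}

#' Precision matrix of the spatial random effect
#'
#' Sparse precision (inverse covariance) of the location-level random effect.
#' For the conditional autoregressive (CAR) structure the precision is
#' `(diag(n_i) - rho * W) / sigma_s2`, nonzero only on the diagonal and on
#' graph edges; this is algebraically the inverse of the row-normalized CAR
#' covariance (see [spatial_covariance]). For the simultaneous autoregressive
#' (SAR) structure the precision is
#' `(I - rho * S) M^{-1} (I - rho * S) / sigma_s2` with
#' `S[i,j] = W[i,j]/sqrt(n_i n_j)` the symmetrized normalized adjacency.
#' Isolated locations get a unit diagonal precision entry (variance
#' `sigma_s2`, independent of all other locations).
#'
#' @param graph a [location_graph].
#' @param structure `"IND"`, `"CAR"` or `"SAR"`.
#' @param sigma_s2 spatial variance parameter (>= 0).
#' @param rho spatial autocorrelation in (-1, 1); ignored for `"IND"`.
#' @return a sparse symmetric positive definite `L x L` matrix.
#' @export
spatial_precision <- function(graph, structure = c("CAR", "SAR", "IND"),
                              sigma_s2 = 1, rho = 0) {
  structure <- check_spatial_spec(match.arg(structure), sigma_s2, rho)
  if (sigma_s2 == 0) stop("sigma_s2 = 0 gives a singular spatial covariance")
  L <- length(graph$locations)
  if (structure == "IND")
    return(Matrix::Diagonal(L, 1 / sigma_s2))
  n_eff <- ifelse(graph$isolated, 1, graph$n_neighbours)
  if (structure == "CAR") {
    Q <- Matrix::Diagonal(x = n_eff) - rho * graph$W
  } else {
    s <- 1 / sqrt(n_eff)
    Stilde <- Matrix::Diagonal(x = s) %*% graph$W %*% Matrix::Diagonal(x = s)
    A <- Matrix::Diagonal(L) - rho * Stilde
    Q <- A %*% Matrix::Diagonal(x = n_eff) %*% A
  }
  Matrix::forceSymmetric(Q / sigma_s2)
}

#' Covariance matrix of the spatial random effect
#'
#' Dense covariance of the location-level random effect under the
#' independent (IND), conditional autoregressive (CAR), or simultaneous
#' autoregressive (SAR) structure:
#' \describe{
#'   \item{IND}{`sigma_s2 * I`}
#'   \item{CAR}{`sigma_s2 * (M^{-1/2} (I - rho M^{-1/2} W_plus M^{1/2}) M^{-1/2})^{-1}`}
#'   \item{SAR}{`sigma_s2 * ((I - rho M^{-1/2} W_plus M^{1/2}) M^{-1} (I - rho M^{1/2} W_plus' M^{-1/2}))^{-1}`}
#' }
#' At `rho = 0` both CAR and SAR reduce to `sigma_s2 * M`. This dense path
#' is intended for moderate numbers of locations (oracle checks, Gower
#' standardization, best linear unbiased prediction); the model likelihood
#' itself only ever uses the sparse precision from [spatial_precision].
#'
#' @inheritParams spatial_precision
#' @return a dense symmetric positive definite `L x L` matrix.
#' @export
spatial_covariance <- function(graph, structure = c("CAR", "SAR", "IND"),
                               sigma_s2 = 1, rho = 0) {
  structure <- match.arg(structure)
  Q <- spatial_precision(graph, structure, sigma_s2, rho)
  Qd <- as.matrix(Q)
  ch <- tryCatch(chol(Qd), error = function(e) NULL)
  if (is.null(ch)) {
    stop("spatial precision is numerically singular (reciprocal condition number ",
         format(rcond(Qd), digits = 3), ")")
  }
  Sigma <- chol2inv(ch)
  dimnames(Sigma) <- list(graph$locations, graph$locations)
  (Sigma + t(Sigma)) / 2
}

#' Gower standardization of the spatial variance
#'
#' CAR and SAR covariances have unequal diagonal elements, so a given
#' `sigma_s2` explains different amounts of phenotypic variance at different
#' locations. The Gower factor is the averaged variance of the spatial random
#' effects across individuals,
#' `tr[(I - (1/N) 11') Z_s Sigma_s Z_s'] / (N - 1)`,
#' reported as the phenotypic variance contributed by the spatially
#' correlated community-level environment.
#'
#' @param Z_s either an `N x L` indicator matrix with exactly one 1 per row,
#'   or an integer/factor vector of location assignments of length `N`.
#' @param Sigma_s the `L x L` spatial covariance matrix.
#' @return a nonnegative scalar.
#' @export
gower_factor <- function(Z_s, Sigma_s) {
  if (is.matrix(Z_s) || inherits(Z_s, "Matrix")) {
    Zd <- as.matrix(Z_s)
    if (any(rowSums(Zd == 1) != 1) || any(rowSums(Zd != 0) != 1))
      stop("each row of Z_s must have exactly one 1")
    loc <- apply(Zd, 1, which.max)
  } else {
    loc <- as.integer(as.factor(Z_s))
  }
  N <- length(loc)
  if (N < 2) stop("Gower factor requires at least 2 individuals")
  counts <- tabulate(loc, nbins = nrow(Sigma_s))
  Sigma_s <- as.matrix(Sigma_s)
  tr_term <- sum(counts * diag(Sigma_s))
  cSc <- drop(t(counts) %*% Sigma_s %*% counts)
  val <- (tr_term - cSc / N) / (N - 1)
  max(val, 0)
}
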