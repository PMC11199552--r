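# Internal likelihood machinery.
#
# The marginal covariance of the model is
#   V = sg^2 blkdiag(G_f) + sp^2 Z_par Z_par' + sc^2 Z_child Z_child'
#       + Z_s Sigma_s Z_s' + se^2 I
# The first four family-level terms form a block-diagonal matrix B with one
# small block per family; the spatial term is a low-rank update through the
# location incidence Z_s. Families sharing a role composition share the same
# block, so B is handled per unique "pattern" with dense k x k algebra, and
# V^{-1} x and log|V| follow from the Woodbury identity
#   V^{-1} = B^{-1} - B^{-1} Z_s (Q + Z_s' B^{-1} Z_s)^{-1} Z_s' B^{-1}
# with Q the sparse spatial precision. Because every family sits in a single
# location, Z_s' B^{-1} Z_s is diagonal, so the inner solve is a sparse
# Cholesky of an L x L matrix with the graph's sparsity.

smile_structure <- function(cohort, graph = NULL, components = c("G", "P", "C", "S"),
                            spatial = "CAR") {
  cohort <- as_smile_cohort(cohort)
  has_S <- "S" %in% components
  if (has_S && is.null(graph))
    stop("a location_graph is required when the S component is included")
  if (!is.null(graph)) {
    miss <- setdiff(cohort$locations, graph$locations)
    if (length(miss))
      stop("cohort location(s) absent from the adjacency graph: ",
           paste(miss, collapse = ", "))
  }
  role <- cohort$data$role
  fam <- as.integer(cohort$family)
  loc_levels <- if (!is.null(graph)) graph$locations else cohort$locations
  loc_index <- match(as.character(cohort$location), loc_levels)
  fam_rows <- split(seq_len(cohort$N), fam)
  fam_loc <- vapply(fam_rows, function(r) loc_index[r[1]], integer(1))
  fam_key <- vapply(fam_rows, function(r) paste(role[r], collapse = ","), character(1))

  patterns <- lapply(split(seq_len(cohort$N_F), fam_key), function(fs) {
    rows <- fam_rows[fs]
    k <- length(rows[[1]])
    roles_p <- role[rows[[1]]]
    is_par <- roles_p %in% c("father", "mother")
    Ppar <- diag(k); Ppar[is_par, is_par] <- 1
    Pchild <- diag(k); Pchild[!is_par, !is_par] <- 1
    idx <- matrix(unlist(rows), nrow = k)
    list(k = k, n_fam = length(fs), roles = roles_p,
         G = kinship_matrix(roles_p),
         Ppar = Ppar, Pchild = Pchild,
         idx = idx,
         contiguous = identical(as.vector(idx), seq_len(length(idx))),
         loc = fam_loc[fs])
  })

  list(cohort = cohort, graph = graph, components = components,
       spatial = spatial, has_S = has_S,
       N = cohort$N, L = length(loc_levels),
       loc_index = loc_index, patterns = patterns)
}

# family-block matrices for one pattern at given variances
pattern_block <- function(p, vc) {
  B <- vc[["eps"]] * diag(p$k)
  if (!is.null(vc[["g"]])) B <- B + vc[["g"]] * p$G
  if (!is.null(vc[["par"]])) B <- B + vc[["par"]] * p$Ppar
  if (!is.null(vc[["child"]])) B <- B + vc[["child"]] * p$Pchild
  B
}

# apply block-diagonal inverse to dense columns via per-pattern reshapes;
# contiguous-row patterns (the common case after canonical ordering) skip
# the gather/scatter
apply_blocks <- function(str, Binv, M) {
  M <- as.matrix(M)
  if (length(str$patterns) == 1L && str$patterns[[1]]$contiguous) {
    p <- str$patterns[[1]]
    dim(M) <- c(p$k, length(M) / p$k)
    res <- Binv[[1]] %*% M
    dim(res) <- c(str$N, length(res) / str$N)
    return(res)
  }
  out <- matrix(0, nrow(M), ncol(M))
  for (j in seq_along(str$patterns)) {
    p <- str$patterns[[j]]
    rows <- as.vector(p$idx)
    a <- matrix(M[rows, , drop = FALSE], nrow = p$k)
    res <- Binv[[j]] %*% a
    out[rows, ] <- matrix(res, nrow = length(rows))
  }
  out
}

sparse_chol_logdet <- function(ch) {
  # log-determinant of the matrix factored by a CHMfactor
  2 * Matrix::determinant(ch, sqrt = TRUE)$modulus[1]
}

# Full evaluation at one parameter point. vc is a named list with entries
# among g, par, child, s, eps (variances) and rho. Returns the profile
# Gaussian log-likelihood with GLS fixed effects, plus reusable pieces.
smile_eval <- function(str, vc, Y, X, want_pieces = FALSE) {
  total_b <- vc[["eps"]]
  for (nm in c("g", "par", "child")) if (!is.null(vc[[nm]])) total_b <- total_b + vc[[nm]]
  if (total_b <= 0) stop("marginal covariance is not positive definite: all family-level variances are zero")

  Binv <- vector("list", length(str$patterns))
  logdetB <- 0
  D <- numeric(str$L)
  for (j in seq_along(str$patterns)) {
    p <- str$patterns[[j]]
    B <- pattern_block(p, vc)
    ch <- tryCatch(chol(B), error = function(e) NULL)
    if (is.null(ch)) return(list(loglik = -Inf))
    Binv[[j]] <- chol2inv(ch)
    logdetB <- logdetB + 2 * p$n_fam * sum(log(diag(ch)))
    if (str$has_S) {
      s_p <- sum(Binv[[j]])
      D <- D + s_p * tabulate(p$loc, nbins = str$L)
    }
  }

  M0 <- cbind(Y, X)
  t1 <- apply_blocks(str, Binv, M0)

  if (str$has_S) {
    Q <- spatial_precision(str$graph, str$spatial, vc[["s"]], vc[["rho"]])
    S <- Q + Matrix::Diagonal(x = D)
    chS <- tryCatch(Matrix::Cholesky(methods::as(S, "symmetricMatrix"), LDL = FALSE),
                    error = function(e) NULL)
    chQ <- tryCatch(Matrix::Cholesky(methods::as(Q, "symmetricMatrix"), LDL = FALSE),
                    error = function(e) NULL)
    if (is.null(chS) || is.null(chQ)) return(list(loglik = -Inf))
    Zt <- rowsum_by(t1, str$loc_index, str$L)
    w <- as.matrix(Matrix::solve(chS, Zt, system = "A"))
    VinvM <- t1 - apply_blocks(str, Binv, w[str$loc_index, , drop = FALSE])
    logdetV <- logdetB + sparse_chol_logdet(chS) - sparse_chol_logdet(chQ)
  } else {
    Q <- NULL; chS <- NULL
    VinvM <- t1
    logdetV <- logdetB
  }

  yv <- VinvM[, 1]
  Xv <- VinvM[, -1, drop = FALSE]
  A <- crossprod(X, Xv)            # X' V^{-1} X
  b <- crossprod(X, yv)            # X' V^{-1} Y
  A <- (A + t(A)) / 2
  chA <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(chA)) return(list(loglik = -Inf))
  pi_hat <- drop(backsolve(chA, backsolve(chA, b, transpose = TRUE)))
  quad <- drop(crossprod(Y, yv)) - drop(crossprod(b, pi_hat))
  loglik <- -0.5 * (str$N * log(2 * pi) + logdetV + quad)
  if (!is.finite(loglik)) return(list(loglik = -Inf))

  out <- list(loglik = loglik, pi_hat = pi_hat, A = A)
  if (want_pieces) {
    r <- Y - drop(X %*% pi_hat)
    Vinv_r <- yv - Xv %*% pi_hat
    out$residuals <- r
    out$Vinv_r <- drop(Vinv_r)
    out$Q <- Q
    out$vcov_fixed <- chol2inv(chA)
  }
  out
}

rowsum_by <- function(M, index, L) {
  agg <- rowsum(M, index)
  out <- matrix(0, L, ncol(M))
  out[as.integer(rownames(agg)), ] <- agg
  out
}

#' Marginal covariance matrix of a fitted or specified model
#'
#' Dense `N x N` phenotypic covariance implied by a set of variance
#' components: the sum of the genetic, parent-shared, child-shared, spatial,
#' and residual terms. Intended for small cohorts (oracle checks, teaching);
#' model fitting never forms this matrix.
#'
#' @param cohort a [smile_cohort].
#' @param graph a [location_graph] (required when `s > 0`).
#' @param g,par,child,s,eps variance components (omitted components are 0;
#'   `eps` is the residual variance).
#' @param spatial spatial structure for the S term.
#' @param rho spatial autocorrelation.
#' @return a dense symmetric `N x N` matrix.
#' @export
marginal_covariance <- function(cohort, graph = NULL, g = 0, par = 0, child = 0,
                                s = 0, eps = 1, spatial = "CAR", rho = 0) {
  cohort <- as_smile_cohort(cohort)
  if (g == 0 && par == 0 && child == 0 && s == 0 && eps == 0)
    stop("marginal covariance is not positive definite: all variances are zero")
  N <- cohort$N
  V <- eps * diag(N)
  if (g > 0) V <- V + g * as.matrix(genetic_covariance(cohort))
  if (par > 0 || child > 0) {
    Z <- family_env_design(cohort)
    if (par > 0) V <- V + par * as.matrix(Matrix::tcrossprod(Z$Z_par))
    if (child > 0) V <- V + child * as.matrix(Matrix::tcrossprod(Z$Z_child))
  }
  if (s > 0) {
    if (is.null(graph)) stop("a location_graph is required when s > 0")
    Zs <- spatial_design(cohort)
    Sig <- spatial_covariance(graph, spatial, s, rho)
    V <- V + as.matrix(Zs %*% Sig %*% Matrix::t(Zs))
  }
  (V + t(V)) / 2
}

#' Gaussian log-likelihood of the spatial mixed model
#'
#' Profile log-likelihood of the observed-scale linear mixed model at a
#' given set of variance components, with fixed effects set to their
#' generalized-least-squares values. Computed through the sparse
#' family-block/Woodbury decomposition, never forming the dense covariance.
#'
#' @param cohort a [smile_cohort].
#' @param Y numeric response vector in cohort order (0/1 disease status).
#' @param X fixed-effect design matrix (full column rank, including any
#'   intercept).
#' @param graph a [location_graph] (required when `s > 0`).
#' @inheritParams marginal_covariance
#' @return the scalar log-likelihood.
#' @export
smile_loglik <- function(cohort, Y, X, graph = NULL, g = 0, par = 0, child = 0,
                         s = 0, eps = 1, spatial = "CAR", rho = 0) {
  cohort <- as_smile_cohort(cohort)
  X <- as.matrix(X)
  check_design(X)
  comps <- c(if (g > 0) "G", if (par > 0) "P", if (child > 0) "C", if (s > 0) "S")
  str <- smile_structure(cohort, graph, components = comps, spatial = spatial)
  vc <- list(eps = eps)
  if (g > 0) vc$g <- g
  if (par > 0) vc$par <- par
  if (child > 0) vc$child <- child
  if (s > 0) { vc$s <- s; vc$rho <- rho }
  smile_eval(str, vc, Y, X)$loglik
}

check_design <- function(X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("fixed-effect design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  invisible(TRUE)
}
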