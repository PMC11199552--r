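# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: covariances are assembled densely from
# first principles and likelihoods evaluated by a plain Cholesky of the full
# N x N matrix.

# dense multivariate-normal profile log-likelihood with GLS fixed effects
oracle_loglik <- function(V, Y, X) {
  ch <- chol(V)
  Vi <- chol2inv(ch)
  A <- t(X) %*% Vi %*% X
  bh <- solve(A, t(X) %*% Vi %*% Y)
  r <- Y - X %*% bh
  drop(-0.5 * (length(Y) * log(2 * pi) + 2 * sum(log(diag(ch))) + t(r) %*% Vi %*% r))
}

# dense V assembled from explicit design matrices, independent of
# marginal_covariance(): per-family kinship from pair rules, Z matrices from
# loops over individuals
oracle_dense_V <- function(ped, graph = NULL, g = 0, par = 0, child = 0,
                           s = 0, eps = 1, spatial = "CAR", rho = 0) {
  N <- nrow(ped)
  V <- diag(eps, N)
  fams <- unique(ped$family_id)
  if (g > 0) {
    for (f in fams) {
      ix <- which(ped$family_id == f)
      roles <- ped$role[ix]
      Gf <- matrix(0.5, length(ix), length(ix))
      pp <- roles %in% c("father", "mother")
      Gf[pp, pp] <- 0
      diag(Gf) <- 1
      V[ix, ix] <- V[ix, ix] + g * Gf
    }
  }
  if (par > 0 || child > 0) {
    for (f in fams) {
      ix <- which(ped$family_id == f)
      roles <- ped$role[ix]
      pp <- roles %in% c("father", "mother")
      Ppar <- diag(length(ix)); Ppar[pp, pp] <- 1
      Pch <- diag(length(ix)); Pch[!pp, !pp] <- 1
      V[ix, ix] <- V[ix, ix] + par * Ppar + child * Pch
    }
  }
  if (s > 0) {
    Sig <- oracle_spatial_cov(graph, spatial, s, rho)
    li <- match(ped$location_id, graph$locations)
    V <- V + Sig[li, li]
  }
  (V + t(V)) / 2
}

# direct evaluation of the printed CAR/SAR covariance definitions using
# dense W_plus and M, independent of spatial_precision()
oracle_spatial_cov <- function(graph, structure, sigma_s2, rho) {
  L <- length(graph$locations)
  W <- as.matrix(graph$W)
  n <- rowSums(W)
  n[n == 0] <- 1            # isolates handled as independent units
  Wp <- W / n
  M <- diag(1 / n, L)
  Mi_h <- diag(sqrt(n), L)  # M^{-1/2}
  M_h <- diag(1 / sqrt(n), L)
  if (structure == "IND") return(diag(sigma_s2, L))
  if (structure == "CAR") {
    P <- Mi_h %*% (diag(L) - rho * Mi_h %*% Wp %*% M_h) %*% Mi_h
  } else {
    P <- (diag(L) - rho * Mi_h %*% Wp %*% M_h) %*% diag(n, L) %*%
      (diag(L) - rho * M_h %*% t(Wp) %*% Mi_h)
  }
  sigma_s2 * solve(P)
}

# Monte-Carlo gene dropping: expected relatedness (2 x kinship coefficient)
# between two members of a nuclear family, estimated by dropping alleles
oracle_gene_drop_relatedness <- function(roles, n_drop = 1e5) {
  is_par <- roles %in% c("father", "mother")
  if (sum(is_par) != 2) stop("gene-dropping oracle expects two parents")
  k <- length(roles)
  # founder alleles 1,2 (father) and 3,4 (mother); each child inherits one
  # uniformly chosen allele from each parent, independently per drop
  A1 <- matrix(0L, n_drop, k)
  A2 <- matrix(0L, n_drop, k)
  A1[, roles == "father"] <- 1L; A2[, roles == "father"] <- 2L
  A1[, roles == "mother"] <- 3L; A2[, roles == "mother"] <- 4L
  for (i in which(!is_par)) {
    A1[, i] <- sample(c(1L, 2L), n_drop, replace = TRUE)
    A2[, i] <- sample(c(3L, 4L), n_drop, replace = TRUE)
  }
  out <- matrix(0, k, k)
  for (i in 1:k) for (j in 1:k) {
    eq <- (A1[, i] == A1[, j]) + (A1[, i] == A2[, j]) +
      (A2[, i] == A1[, j]) + (A2[, i] == A2[, j])
    out[i, j] <- mean(eq) / 4   # kinship coefficient
  }
  2 * out
}

# expected observed-scale covariance of a pair with liability correlation r
oracle_observed_cov <- function(r, K) {
  t <- qnorm(1 - K)
  if (abs(r) < 1e-12) return(0)
  p11 <- integrate(function(x)
    dnorm(x) * pnorm((t - r * x) / sqrt(1 - r^2), lower.tail = FALSE),
    t, Inf, rel.tol = 1e-10)$value
  p11 - K^2
}

`%|or|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else unname(a)
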