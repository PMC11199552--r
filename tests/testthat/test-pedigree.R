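test_that("quad-family kinship matrix matches the nuclear-family rules", {
  G <- kinship_matrix(quad_roles)
  expect_equal(G, matrix(c(1, 0, .5, .5,
                           0, 1, .5, .5,
                           .5, .5, 1, .5,
                           .5, .5, .5, 1), 4, 4))
  expect_equal(kinship_matrix("child"), matrix(1, 1, 1))
  expect_equal(kinship_matrix(c("father", "mother", "child")),
               matrix(c(1, 0, .5, 0, 1, .5, .5, .5, 1), 3, 3))
})

test_that("kinship agrees with the Monte-Carlo gene-dropping oracle", {
  set.seed(101)
  for (roles in list(c("father", "mother", "child"), quad_roles)) {
    est <- oracle_gene_drop_relatedness(roles, n_drop = 1e5)
    expect_lt(max(abs(est - kinship_matrix(roles))), 0.01)
  }
})

test_that("kinship matrices are PSD and reject structural errors", {
  for (roles in list(quad_roles, c("mother", "child", "child", "child"),
                     c("father", "mother", rep("child", 4)))) {
    ev <- eigen(kinship_matrix(roles), symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-10)
  }
  expect_error(kinship_matrix(character(0)), "empty family")
  expect_error(kinship_matrix(c("father", "parent")), "invalid role")
})

test_that("quad kinship eigenvalues match the dense eigensolver oracle", {
  ev <- sort(eigen(kinship_matrix(quad_roles), symmetric = TRUE)$values)
  expect_equal(ev, c(0.2192236, 0.5, 1, 2.2807764), tolerance = 1e-6)
})

test_that("cohort construction validates and canonically orders", {
  ped <- make_ped(list(quad_roles))
  shuffled <- ped[c(3, 1, 4, 2), ]
  co <- smile_cohort(shuffled)
  expect_equal(co$data$role, c("father", "mother", "child", "child"))
  expect_equal(co$N, 4)
  expect_equal(co$N_F, 1)

  bad <- ped; bad$individual_id[2] <- bad$individual_id[1]
  expect_error(smile_cohort(bad), "duplicate individual_id")
  bad2 <- ped; bad2$role[1] <- "parent"
  expect_error(smile_cohort(bad2), "invalid role")
  bad3 <- rbind(ped, transform(ped[1, ], individual_id = "x9"))
  expect_error(smile_cohort(bad3), "more than one father")
})

test_that("family environment designs have the shared-column structure", {
  co <- smile_cohort(make_ped(list(quad_roles)))
  Z <- family_env_design(co)
  expect_equal(dim(Z$Z_par), c(4L, 3L))
  expect_equal(dim(Z$Z_child), c(4L, 3L))
  # parents share a Z_par column; children share a Z_child column
  P <- as.matrix(Matrix::tcrossprod(Z$Z_par))
  C <- as.matrix(Matrix::tcrossprod(Z$Z_child))
  expect_equal(P, rbind(c(1, 1, 0, 0), c(1, 1, 0, 0), c(0, 0, 1, 0), c(0, 0, 0, 1)))
  expect_equal(C, rbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 1, 1), c(0, 0, 1, 1)))

  solo <- smile_cohort(make_ped(list("child")))
  Zs <- family_env_design(solo)
  expect_equal(as.matrix(Zs$Z_par), matrix(1, 1, 1), ignore_attr = TRUE)
  expect_equal(as.matrix(Zs$Z_child), matrix(1, 1, 1), ignore_attr = TRUE)
})

test_that("row sums of Z matrices are exactly 1 and columns partition the cohort", {
  co <- toy_cohort()
  Z <- family_env_design(co)
  for (M in Z) {
    expect_equal(Matrix::rowSums(M), rep(1, co$N), ignore_attr = TRUE)
    expect_equal(sum(M), co$N)
  }
})

test_that("sigma_par * Z_par Z_par' has off-diagonals only between parents", {
  co <- toy_cohort()
  Z <- family_env_design(co)
  M <- 0.3 * as.matrix(Matrix::tcrossprod(Z$Z_par))
  role <- co$data$role
  fam <- as.integer(co$family)
  for (i in seq_len(co$N - 1)) for (j in (i + 1):co$N) {
    expected <- if (fam[i] == fam[j] &&
                    all(c(role[i], role[j]) %in% c("father", "mother"))) 0.3 else 0
    expect_equal(M[i, j], expected)
  }
})

test_that("genetic covariance is block diagonal in family kinships", {
  ped <- make_ped(list(quad_roles, quad_roles))
  co <- smile_cohort(ped)
  Gc <- as.matrix(genetic_covariance(co))
  G <- kinship_matrix(quad_roles)
  expect_equal(Gc[1:4, 1:4], G, ignore_attr = TRUE)
  expect_equal(Gc[5:8, 5:8], G, ignore_attr = TRUE)
  expect_equal(Gc[1:4, 5:8], matrix(0, 4, 4), ignore_attr = TRUE)

  singles <- smile_cohort(make_ped(list("child", "father", "mother")))
  expect_equal(as.matrix(genetic_covariance(singles)), diag(3), ignore_attr = TRUE)
})

test_that("genetic covariance commutes with family permutation", {
  ped_ab <- make_ped(list(quad_roles, c("father", "mother", "child")))
  ped_ba <- ped_ab
  ped_ba$family_id <- ifelse(ped_ba$family_id == "f01", "f02", "f01")
  A <- as.matrix(genetic_covariance(smile_cohort(ped_ab)))
  B <- as.matrix(genetic_covariance(smile_cohort(ped_ba)))
  expect_equal(A[1:4, 1:4], B[4:7, 4:7], ignore_attr = TRUE)
  expect_equal(A[5:7, 5:7], B[1:3, 1:3], ignore_attr = TRUE)
})
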