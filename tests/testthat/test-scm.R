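test_that("solve_scm matches topological forward substitution on random SCMs", {
  for (seed in 1:200) {
    n <- 2 + (seed %% 9)
    params <- random_scm(n, seed)
    Z <- with_seed_local(seed + 5000, matrix(rnorm(3 * n), 3, n))
    S <- with_seed_local(seed + 9000, rnorm(n))
    U <- solve_scm(params, Z, S, c = 1.5)
    Uo <- forward_substitution(params, Z, S, c = 1.5)
    expect_lt(max(abs(U - Uo)), 1e-10)
  }
})

test_that("no-edge graphs are the identity map and c = 0 gives the control solution", {
  n <- 5
  params <- scm_params(matrix(0, n, n), zero_mask(n))
  z <- matrix(rnorm(n), 1)
  s <- rnorm(n)
  expect_equal(solve_scm(params, z, s, c = 1), z + rep(s, each = 1))

  params2 <- random_scm(6, seed = 3)
  Z <- matrix(rnorm(24), 4, 6)
  expect_equal(solve_scm(params2, Z, rnorm(6), c = 0), solve_scm(params2, Z))
})

test_that("a weighted chain propagates coordinate-by-coordinate", {
  # 4-node chain 1 -> 2 -> 3 -> 4 with weights 0.5, -1, 2; exogenous e_1
  mask <- matrix(0, 4, 4)
  mask[2, 1] <- mask[3, 2] <- mask[4, 3] <- 1
  A <- matrix(0, 4, 4)
  A[2, 1] <- 0.5; A[3, 2] <- -1; A[4, 3] <- 2
  params <- scm_params(A, prespecified_mask(mask))
  U <- solve_scm(params, matrix(c(1, 0, 0, 0), 1))
  expect_equal(drop(U), c(1, 0.5, -0.5, -1))
})

test_that("solve_scm is linear in the penetrance independently of Z", {
  params <- random_scm(7, seed = 21)
  S <- rnorm(7)
  M <- solve(diag(7) - params$A)
  for (seed in 1:5) {
    Z <- with_seed_local(seed, matrix(rnorm(21), 3, 7))
    d <- solve_scm(params, Z, S, c = 1.3 + 0.4) - solve_scm(params, Z, S, c = 1.3)
    expect_equal(d, matrix(rep(0.4 * drop(M %*% S), each = 3), 3, 7),
                 tolerance = 1e-12)
  }
})

test_that("population mean shift equals c * (I - A)^-1 S exactly", {
  params <- random_scm(6, seed = 8)
  Z <- with_seed_local(1, matrix(rnorm(600), 100, 6))
  S <- with_seed_local(2, rnorm(6))
  cc <- 1.7
  d <- colMeans(solve_scm(params, Z, S, cc)) - colMeans(solve_scm(params, Z))
  expect_equal(d, cc * drop(solve(diag(6) - params$A) %*% S), tolerance = 1e-12)
})

test_that("latent control covariance has closed form and Monte-Carlo support", {
  expect_equal(latent_control_covariance(scm_params(matrix(0, 3, 3), zero_mask(3))),
               diag(3))
  # U1 = a U2 + Z1, U2 = Z2: cov = [[1 + a^2, a], [a, 1]]
  a <- 0.8
  mask <- upper_triangular_mask(2)
  params <- scm_params(matrix(c(0, 0, a, 0), 2, 2), mask)
  expect_equal(latent_control_covariance(params),
               matrix(c(1 + a^2, a, a, 1), 2, 2))
  # Monte-Carlo agreement
  params3 <- random_scm(4, seed = 14)
  Z <- with_seed_local(3, matrix(rnorm(4e5), 1e5, 4))
  U <- solve_scm(params3, Z)
  emp <- crossprod(U) / nrow(U)  # mean is 0 by construction
  expect_lt(max(abs(emp - latent_control_covariance(params3))), 0.02)
})

test_that("cyclic user-supplied systems raise a singular-system error", {
  mask <- structure(list(n = 2, kind = "prespecified_dag",
                         mask = matrix(1, 2, 2) - diag(2), seed = NULL),
                    class = "graph_mask")
  params <- scm_params(matrix(c(0, 1, 1, 0), 2, 2), mask)
  expect_error(solve_scm(params, matrix(rnorm(2), 1)),
               class = "perturbscm_singular_system")
})
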