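test_that("MMD estimator matches a naive double-loop oracle and its closed properties", {
  X <- with_seed_local(1, matrix(rnorm(60 * 4), 60, 4))
  Y <- with_seed_local(2, matrix(rnorm(40 * 4, 1), 40, 4))
  h <- 1.3
  naive <- local({
    k <- function(a, b) exp(-sum((a - b)^2) / (2 * h^2))
    acc <- function(A, B) {
      s <- 0
      for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) s <- s + k(A[i, ], B[j, ])
      s / (nrow(A) * nrow(B))
    }
    acc(X, X) + acc(Y, Y) - 2 * acc(X, Y)
  })
  expect_equal(mmd(X, Y, bandwidths = h), naive, tolerance = 1e-10)
  expect_equal(mmd(X, X, bandwidths = h), 0)
  expect_equal(mmd(X, Y, bandwidths = h), mmd(Y, X, bandwidths = h))
  expect_error(mmd(X, Y[, 1:2]), class = "perturbscm_invalid_dimension")
})

test_that("separated Gaussians give a clearly positive MMD", {
  X <- with_seed_local(3, matrix(rnorm(500), 500, 1))
  Y <- with_seed_local(4, matrix(rnorm(500, 3), 500, 1))
  expect_gt(mmd(X, Y, bandwidths = 1), 0.5)
})

test_that("the diagonal-Gaussian KL matches numerical integration", {
  kl_numeric <- function(mu, sd) {
    integrand <- function(z) {
      q <- dnorm(z, mu, sd)
      ifelse(q > 0, q * (dnorm(z, mu, sd, log = TRUE) - dnorm(z, log = TRUE)), 0)
    }
    integrate(integrand, mu - 12 * sd, mu + 12 * sd, rel.tol = 1e-10)$value
  }
  kl <- perturbscm:::kl_gaussian
  expect_equal(drop(kl(matrix(1), matrix(0))), 0.5)  # mu 1, var 1
  for (seed in 1:20) {
    p <- with_seed_local(seed, c(mu = rnorm(1), sd = exp(rnorm(1, 0, 0.5))))
    expect_equal(drop(kl(matrix(p[["mu"]]), matrix(2 * log(p[["sd"]])))),
                 kl_numeric(p[["mu"]], p[["sd"]]), tolerance = 1e-6,
                 label = sprintf("seed %d", seed))
  }
})

test_that("an untrained model maps any input to the prior and zero shift", {
  model <- toy_model()
  X <- with_seed_local(5, matrix(rnorm(3 * model$m), 3))
  post <- encode_expression(model, X)
  expect_equal(post$mean, matrix(0, 3, model$config$n))
  expect_equal(post$log_variance, matrix(0, 3, model$config$n))
  expect_equal(encode_shift(model, rnorm(model$labels$k)),
               numeric(model$config$n))
  # identical cells give identical posterior rows
  X2 <- X[c(1, 1, 2), ]
  p2 <- encode_expression(model, X2)
  expect_identical(p2$mean[1, ], p2$mean[2, ])
  expect_error(encode_expression(model, X[, -1]),
               class = "perturbscm_invalid_dimension")
})

test_that("reparameterized samples have the right moments and determinism", {
  post <- structure(list(mean = matrix(0, 1e5, 1), log_variance = matrix(0, 1e5, 1)),
                    class = "gaussian_posterior")
  Z <- sample_z(post, seed = 1)
  expect_lt(abs(mean(Z)), 0.02)
  expect_lt(abs(var(drop(Z)) - 1), 0.05)
  expect_identical(sample_z(post, seed = 3), sample_z(post, seed = 3))
  # zero-noise limit
  post2 <- structure(list(mean = matrix(2, 4, 2), log_variance = matrix(-60, 4, 2)),
                     class = "gaussian_posterior")
  expect_equal(sample_z(post2, 1), matrix(2, 4, 2), tolerance = 1e-10)
})

test_that("forward pass respects the control path and the conditional ablation", {
  d <- tiny_dataset()
  lab <- fit_labels(control_cells(d), k = 4)
  cfg <- model_config(n = 4, hidden = 16, shift_hidden = 8,
                      mask_kind = "none_conditional", seed = 2)
  model <- asNamespace("perturbscm")$init_model(ncol(d$values), lab, cfg)
  X <- control_cells(d)[1:6, ]
  # with a zero mask the decoder input is exactly Z + c * S
  lbl <- label_for_gene(lab, "G001")
  fw <- model_forward(model, X, label = lbl, c = 1.5, seed = 3)
  expect_equal(fw$U, fw$Z + matrix(1.5 * fw$S, 6, 4, byrow = TRUE))
  # control forward at the same draw equals any perturbation at c = 0
  fw0 <- model_forward(model, X, seed = 3)
  fwc <- model_forward(model, X, label = lbl, c = 0, seed = 3)
  expect_equal(fw0$X_hat, fwc$X_hat)
  expect_equal(dim(fw$X_hat), dim(X))
})

test_that("a short training run is deterministic and decreases the objective", {
  d <- tiny_dataset(n_ctrl = 150, n_pert = 80)
  lab <- fit_labels(control_cells(d), k = 4)
  split <- make_split(d, "in_distribution", seed = 1)
  cfg <- model_config(n = 4, hidden = 16, shift_hidden = 8, epochs = 12,
                      batch_size = 64, val_every = 3, seed = 5)
  m1 <- fit_scm_vae(d, lab, split, cfg)
  m2 <- fit_scm_vae(d, lab, split, cfg)
  expect_equal(m1$loss_history, m2$loss_history, tolerance = 1e-12)
  h <- m1$loss_history
  expect_lt(min(h$val_loss[is.finite(h$val_loss)]), h$val_loss[1])
  expect_s3_class(tidy(m1), "tbl_df")
  expect_true(all(c("perturbation", "penetrance") %in% names(tidy(m1))))
  expect_equal(glance(m1)$n_latent, 4)
})

test_that("the loss decomposes into its reported terms", {
  d <- tiny_dataset(n_ctrl = 150, n_pert = 80)
  lab <- fit_labels(control_cells(d), k = 4)
  split <- make_split(d, "in_distribution", seed = 1)
  cfg <- model_config(n = 4, hidden = 16, shift_hidden = 8, epochs = 4,
                      batch_size = 64, seed = 5)
  m <- fit_scm_vae(d, lab, split, cfg)
  l <- model_loss(m, d, split, role = "val", seed = 2)
  expect_equal(l$total, sum(l$breakdown$value), tolerance = 1e-6)
  expect_true(all(l$breakdown$value >= 0))
})

test_that("checkpoints reload bit-exactly", {
  d <- tiny_dataset()
  lab <- fit_labels(control_cells(d), k = 4)
  cfg <- model_config(n = 4, hidden = 16, shift_hidden = 8, epochs = 2,
                      batch_size = 32, seed = 1)
  m <- fit_scm_vae(d, lab, NULL, cfg)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(m2$par, m$par)
  expect_identical(tidy(m2), tidy(m))
})
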