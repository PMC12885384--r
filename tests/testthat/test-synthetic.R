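test_that("the default benchmark satisfies its structural invariants", {
  spec <- default_benchmark(seed = 1)
  expect_true(validate_dag(spec$mask))
  expect_equal(nrow(spec$perturbations), 20)
  expect_true(all(spec$perturbations$c_star %in% c(0.5, 1, 2)))
  expect_true(all(colSums(spec$S_star != 0) <= 3))
  expect_true(all(spec$perturbations$perturbation %in% spec$gene_ids))
  # targets of each group belong to one latent module
  for (g in unique(spec$perturbations$group)) {
    targets <- spec$perturbations$perturbation[spec$perturbations$group == g]
    mods <- spec$module_of[match(targets, spec$gene_ids)]
    expect_equal(length(unique(mods)), 1)
  }
})

test_that("simulated datasets have the declared sizes and round-trip through io", {
  spec <- default_benchmark(seed = 2)
  sim <- simulate_dataset(spec)
  expect_equal(nrow(sim$data$values), 20 * 300 + 2000)
  expect_equal(ncol(sim$data$values), 200)
  expect_equal(sum(sim$data$perturbation == "non-targeting"), 2000)
  dir <- withr::local_tempdir()
  write_dataset(sim$data, file.path(dir, "sim"), format = "mtx_dir")
  back <- suppressMessages(read_dataset(file.path(dir, "sim"), format = "mtx_dir"))
  expect_equal(unname(back$values), unname(sim$data$values), tolerance = 1e-10)
  expect_identical(back$perturbation, sim$data$perturbation)
})

test_that("simulation is deterministic given the spec seed", {
  s1 <- simulate_dataset(default_benchmark(seed = 3))
  s2 <- simulate_dataset(default_benchmark(seed = 3))
  expect_identical(s1$data$values, s2$data$values)
  s3 <- simulate_dataset(default_benchmark(seed = 4))
  expect_false(identical(s1$data$values, s3$data$values))
})

test_that("latent mean effects obey the shift identity exactly", {
  spec <- default_benchmark(seed = 5)
  sim <- simulate_dataset(spec, return_latent = TRUE)
  M <- solve(diag(spec$n_true) - spec$A)
  tt <- sim$truth$shift_table
  for (i in seq_len(nrow(tt))) {
    expected <- tt$c_star[i] * drop(M %*% spec$S_star[, i])
    expect_equal(sim$truth$latent_mean_effects[i, ], expected, tolerance = 1e-12)
  }
  # perturbations sharing a shift support have parallel latent effects
  eff <- sim$truth$latent_mean_effects
  for (g in unique(tt$group)) {
    idx <- which(tt$group == g)
    for (i in idx[-1]) {
      cs <- sum(eff[idx[1], ] * eff[i, ]) /
        (sqrt(sum(eff[idx[1], ]^2)) * sqrt(sum(eff[i, ]^2)))
      expect_gt(cs, 0.8)
    }
  }
})

test_that("noise-free linear observation reproduces the analytic gene covariance", {
  spec <- default_benchmark(seed = 6)
  spec$noise_sd <- 0
  spec$n_control <- 40000
  spec$perturbations <- spec$perturbations[0, ]
  spec$S_star <- spec$S_star[, 0, drop = FALSE]
  sim <- simulate_dataset(spec)
  X <- control_cells(sim$data)
  emp <- stats::cov(X)
  Sigma_U <- latent_control_covariance(sim$truth$params)
  expected <- spec$loadings %*% Sigma_U %*% t(spec$loadings)
  expect_lt(max(abs(emp - expected)), 0.08)
})

test_that("a zero-penetrance perturbation is indistinguishable from control", {
  spec <- default_benchmark(seed = 7)
  spec$perturbations <- tibble::tibble(
    perturbation = spec$perturbations$perturbation[1],
    group = spec$perturbations$group[1], c_star = 0, n_cells = 600L)
  spec$S_star <- spec$S_star[, 1, drop = FALSE]
  spec$n_control <- 600
  sim <- simulate_dataset(spec)
  Xp <- perturbed_cells(sim$data, spec$perturbations$perturbation)
  Xc <- control_cells(sim$data)
  obs <- energy_distance(Xp, Xc)
  # permutation null band
  pool <- rbind(Xp, Xc)
  null <- vapply(1:60, function(s) {
    idx <- with_seed_local(s, sample.int(nrow(pool)))
    energy_distance(pool[idx[1:600], ], pool[idx[601:1200], ])
  }, numeric(1))
  expect_gt(mean(null >= obs), 0.01)
})
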