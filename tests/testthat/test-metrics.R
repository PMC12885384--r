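test_that("pseudo-bulk is the per-gene mean and permutation-invariant", {
  x <- matrix(c(0, 0, 2, 2), 2, 2, byrow = TRUE)
  expect_equal(pseudo_bulk(x), c(1, 1))
  expect_equal(pseudo_bulk(x[1, , drop = FALSE]), c(0, 0))
  X <- with_seed_local(1, matrix(rnorm(40), 8, 5))
  expect_equal(pseudo_bulk(X), pseudo_bulk(X[sample(8), ]))
  expect_error(pseudo_bulk(X[0, , drop = FALSE]))
})

test_that("bulk MSE and change correlation match the worked 3-gene example", {
  ctrl <- matrix(c(1, 1, 1), 1)
  truth <- matrix(c(2, 0, 1), 1)
  pred <- matrix(c(1.5, 0.5, 1), 1)
  expect_equal(mse_metric(pred, truth), 1 / 6)
  expect_equal(pearson_change(pred, truth, ctrl), 1)
  expect_equal(mse_metric(truth, truth), 0)
  expect_true(is.na(suppressMessages(pearson_change(ctrl, truth, ctrl))))
})

test_that("energy distance has its closed forms and symmetry", {
  X <- with_seed_local(2, matrix(rnorm(50 * 4), 50, 4))
  expect_equal(energy_distance(X, X), 0)
  a <- matrix(c(0, 0), 1); b <- matrix(c(3, 4), 1)
  expect_equal(energy_distance(a, b), 2 * 5)  # two point masses at distance 5
  Y <- with_seed_local(3, matrix(rnorm(30 * 4) + 1, 30, 4))
  expect_equal(energy_distance(X, Y), energy_distance(Y, X))
})

test_that("energy distance matches a naive double-loop oracle", {
  X <- with_seed_local(4, matrix(rnorm(40 * 3), 40, 3))
  Y <- with_seed_local(5, matrix(rnorm(30 * 3, 0.5), 30, 3))
  naive <- function(A, B) {
    s <- 0
    for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B)))
      s <- s + sqrt(sum((A[i, ] - B[j, ])^2))
    s / (nrow(A) * nrow(B))
  }
  expect_equal(energy_distance(X, Y),
               2 * naive(X, Y) - naive(X, X) - naive(Y, Y),
               tolerance = 1e-8)
})

test_that("direction fractions follow the dead-zone exclusion rule", {
  ctrl <- matrix(0, 1, 4)
  truth <- matrix(c(1, -1, 1, 0), 1)
  pred <- matrix(c(1, 1, 0, 1), 1)
  fr <- fraction_same_changed(pred, truth, ctrl, epsilon = 0)
  # same on gene1, opposite on gene2; genes 3 & 4 excluded but in denominator
  expect_equal(unname(fr), c(0.25, 0.25))
  expect_equal(unname(fraction_same_changed(truth, truth, ctrl)), c(0.75, 0))
  neg <- matrix(c(-1, 1, -1, 0), 1)
  expect_equal(unname(fraction_same_changed(neg, truth, ctrl)), c(0, 0.75))
})

test_that("top HVG selection matches brute-force variance ranking", {
  X <- with_seed_local(6, {
    m <- matrix(rnorm(100 * 5), 100, 5)
    m[, 3] <- m[, 3] * 5
    m
  })
  expect_equal(top_k_hvg(X, 1), 3)
  expect_equal(top_k_hvg(X, 5), order(-apply(X, 2, var), 1:5))
  expect_error(top_k_hvg(X, 6), class = "perturbscm_invalid_parameter")
})

test_that("evaluate_predictions fills all six metrics with exact values on self-predictions", {
  d <- tiny_dataset(n_ctrl = 80, n_pert = 40)
  ctrl <- control_cells(d)
  preds <- list(G001 = perturbed_cells(d, "G001"),
                G002 = perturbed_cells(d, "G002"))
  rep <- suppressMessages(evaluate_predictions(preds, control = ctrl, data = d,
                                               hvg_k = 5, seed = 1))
  for (p in names(preds)) {
    r <- rep[rep$perturbation == p & rep$gene_set == "all", ]
    v <- setNames(r$value, r$metric)
    expect_equal(unname(v["MSE"]), 0)
    expect_equal(unname(v["MMD"]), 0)
    expect_equal(unname(v["EnergyDist"]), 0)
    expect_equal(unname(v["PearsonR"]), 1)
  }
  s <- metrics_summary(rep)
  expect_true(all(c("all", "top50") %in% s$gene_set))
  # aggregate is the unweighted mean across perturbations
  mses <- rep$value[rep$metric == "MSE" & rep$gene_set == "all"]
  expect_equal(s$mean[s$gene_set == "all" & s$metric == "MSE"], mean(mses))
})

test_that("metric reports serialize to TSV plus JSON summary", {
  d <- tiny_dataset()
  preds <- list(G001 = perturbed_cells(d, "G001"))
  rep <- suppressMessages(evaluate_predictions(preds, control = control_cells(d),
                                               data = d, hvg_k = 5))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_metrics(rep, path)
  expect_true(file.exists(path))
  js <- jsonlite::read_json(paste0(path, ".summary.json"))
  expect_true("MSE" %in% names(js$all))
})
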