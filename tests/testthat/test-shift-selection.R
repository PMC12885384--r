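test_that("grid construction covers both policies", {
  g <- build_grid(policy = "fixed_range", points = 41, range = c(-1, 3))
  expect_equal(g[1], -1)
  expect_equal(g[41], 3)
  expect_equal(diff(g)[1], 0.1, tolerance = 1e-12)
  expect_false(is.unsorted(g))

  st <- tibble::tibble(perturbation = c("a", "b", "c"), penetrance = c(1, 1, 1))
  expect_equal(build_grid(st, "learned_cp_range", points = 1, margin = 0), 1)
  g2 <- build_grid(st, "learned_cp_range", points = 5, margin = 0.5)
  expect_equal(range(g2), c(0.5, 1.5))
  expect_error(build_grid(NULL, "learned_cp_range"), "nonempty")
})

test_that("selection returns the sole candidate on degenerate grids and breaks ties toward 0", {
  d <- tiny_dataset()
  model <- toy_model(d)
  Xc <- control_cells(d)
  bulk <- pseudo_bulk(Xc)
  sel1 <- select_shift(model, label = rnorm(model$labels$k), control_cells = Xc,
                       bulk_target = bulk,
                       config = shift_search_config(grid = 0.7, B = 16, seed = 1))
  expect_equal(sel1$c, 0.7)
  # untrained model has a zero shift, so every candidate ties; smallest |c| wins
  sel2 <- select_shift(model, label = rnorm(model$labels$k), control_cells = Xc,
                       bulk_target = bulk,
                       config = shift_search_config(grid = c(-1, 0, 1, 2), B = 16, seed = 1))
  expect_equal(sel2$c, 0)
  expect_equal(nrow(sel2$curve), 4)
})

test_that("prediction at c = 0 equals the control reconstruction distribution", {
  d <- tiny_dataset()
  model <- toy_model(d)
  Xc <- control_cells(d)
  p0 <- predict_unseen(model, label = rnorm(model$labels$k), control_cells = Xc,
                       c = 0, B = 20, seed = 4)
  fw <- model_forward(model, Xc[perturbscm:::seeded_sample(
    derive_seed(4, "predict_cells"), nrow(Xc), 20), ],
    seed = derive_seed(4, "predict_z"))
  expect_equal(p0, fw$X_hat)
  # determinism
  expect_identical(p0, predict_unseen(model, label = rep(0, model$labels$k),
                                      control_cells = Xc, c = 0, B = 20, seed = 4))
  expect_equal(dim(predict_unseen(model, label = rnorm(model$labels$k),
                                  control_cells = Xc, c = 1, B = 37, seed = 1)),
               c(37, model$m))
})

test_that("pseudo-bulk standard error shrinks roughly as 1/sqrt(B)", {
  d <- tiny_dataset(n_ctrl = 200)
  model <- toy_model(d)
  Xc <- control_cells(d)
  lbl <- rnorm(model$labels$k)
  se_of <- function(B) {
    bulks <- vapply(1:30, function(s)
      pseudo_bulk(predict_unseen(model, label = lbl, control_cells = Xc,
                                 c = 1, B = B, seed = s))[1], numeric(1))
    sd(bulks)
  }
  ratio <- se_of(16) / se_of(64)
  expect_gt(ratio, 1.3)  # ideal 2; allow Monte-Carlo slack
})
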