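#' Candidate grids for penetrance search
#'
#' Two policies: `fixed_range` spaces `points` candidates evenly over a user
#' range (default `[-1, 3]`, wide enough to cover sign-flipped, absent and
#' amplified effects); `learned_cp_range` spans the range of penetrance
#' scalars learned during training, extended by `margin` on both sides.
#'
#' @param shift_table A [shift_table()] tibble (required for
#'   `learned_cp_range`).
#' @param policy `"fixed_range"` or `"learned_cp_range"`.
#' @param points Number of candidates `C`.
#' @param margin Range extension for `learned_cp_range`.
#' @param range Length-2 numeric range for `fixed_range`.
#' @return Sorted numeric vector of candidates.
#' @export
build_grid <- function(shift_table = NULL,
                       policy = c("fixed_range", "learned_cp_range"),
                       points = 41, margin = 0.5, range = c(-1, 3)) {
  policy <- match.arg(policy)
  points <- assert_count(points)
  if (policy == "learned_cp_range") {
    if (is.null(shift_table) || nrow(shift_table) == 0) {
      abort("`learned_cp_range` needs a nonempty shift table.")
    }
    lo <- min(shift_table$penetrance) - margin
    hi <- max(shift_table$penetrance) + margin
  } else {
    lo <- range[1]; hi <- range[2]
  }
  if (points == 1L) return((lo + hi) / 2)
  sort(seq(lo, hi, length.out = points))
}

#' Configuration of the penetrance grid search
#'
#' @param grid Candidate penetrance values (strictly increasing).
#' @param B Cells generated per candidate (typically 32-128).
#' @param seed Seed shared by all candidates: one control-cell batch and one
#'   reparameterization draw are used across the whole grid, which removes
#'   sampling noise from the comparison between candidates.
#' @export
shift_search_config <- function(grid = build_grid(policy = "fixed_range"),
                                B = 64, seed = 1) {
  stopifnot(length(grid) >= 1, !is.unsorted(grid, strictly = TRUE), B >= 1)
  structure(list(grid = grid, B = as.integer(B), seed = seed),
            class = "shift_search_config")
}

#' Infer the penetrance of an unseen perturbation by grid search
#'
#' An unseen perturbation's label is encoded into a shift vector by the
#' trained model, but its penetrance — how strongly the guide acts — cannot
#' be known in advance. Given only a pseudo-bulk target (the mean expression
#' of cells under the perturbation, e.g. from a bulk experiment), every
#' candidate penetrance generates `B` in-silico cells from control cells, and
#' the candidate whose pseudo-bulk has minimal mean squared error against the
#' target is selected. Ties are broken toward the smallest `|c|` (the most
#' conservative intervention). Candidates with non-finite predictions are
#' excluded with a message.
#'
#' @param model A trained `scm_vae`.
#' @param perturbation Target-gene id of the unseen perturbation (or supply
#'   `label`).
#' @param label Optional explicit label vector.
#' @param control_cells Matrix of control cells to generate from.
#' @param bulk_target Length-`m` target pseudo-bulk vector.
#' @param config A [shift_search_config()].
#' @return An object of class `shift_search`: list with `c` (selected
#'   penetrance), `min_mse`, and `curve` (tibble `c`, `mse`).
#' @export
select_shift <- function(model, perturbation = NULL, label = NULL,
                         control_cells, bulk_target,
                         config = shift_search_config()) {
  stopifnot(inherits(model, "scm_vae"))
  if (length(bulk_target) != model$m) {
    abort("`bulk_target` must have one entry per gene.",
          class = "perturbscm_invalid_dimension")
  }
  Xc <- as_dense(control_cells)
  B <- min(config$B, nrow(Xc))
  ix <- seeded_sample(derive_seed(config$seed, "select_cells"), nrow(Xc), B,
                      replace = nrow(Xc) < config$B)
  X <- Xc[ix, , drop = FALSE]
  # encode once; the same Z draw is reused across all candidates
  post <- encode_expression(model, X)
  Z <- sample_z(post, derive_seed(config$seed, "select_z"))
  if (is.null(label)) label <- label_for_gene(model$labels, perturbation)
  S <- encode_shift(model, label)
  M <- scm_inverse(model)
  mses <- vapply(config$grid, function(cc) {
    U <- sweep(Z, 2, cc * S, "+") %*% t(M)
    Xh <- decode_latent(model$par, U)
    mean((colMeans(Xh) - bulk_target)^2)
  }, numeric(1))
  valid <- is.finite(mses)
  if (!all(valid)) inform(sprintf("%d candidates gave non-finite predictions and were excluded.",
                                  sum(!valid)))
  if (!any(valid)) abort("no candidate produced finite predictions.")
  mmin <- min(mses[valid])
  best <- which(valid & mses <= mmin)
  best <- best[which.min(abs(config$grid[best]))]
  structure(list(c = config$grid[[best]], min_mse = mses[[best]],
                 curve = tibble(c = config$grid, mse = mses)),
            class = "shift_search")
}

#' @exportS3Method base::print
print.shift_search <- function(x, ...) {
  cat(sprintf("<shift_search> selected c = %.3f (pseudo-bulk MSE %.5g over %d candidates)\n",
              x$c, x$min_mse, nrow(x$curve)))
  invisible(x)
}

#' @export
autoplot.shift_search <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$c, y = .data$mse)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = object$c, linetype = 2) +
    ggplot2::labs(x = "candidate penetrance c", y = "pseudo-bulk MSE") +
    ggplot2::theme_minimal()
}

#' Generate in-silico cells for an unseen perturbation
#'
#' Samples `B` control cells (with replacement if fewer are available), runs
#' the generative pass at penetrance `c`, and returns the predicted
#' single-cell profiles. With `c = 0` the output distribution is the model's
#' control reconstruction distribution.
#'
#' @param model A trained `scm_vae`.
#' @param perturbation Target-gene id (or supply `label`).
#' @param label Optional explicit label vector.
#' @param control_cells Matrix of control cells.
#' @param c Penetrance scalar (finite).
#' @param B Number of cells to generate.
#' @param seed Seed; identical seeds give identical cells.
#' @param add_noise Add the model's estimated Gaussian observation noise
#'   (per-gene residual sd, estimated on control cells after training) so
#'   generated cells carry the same measurement-noise structure as data.
#'   Disabled automatically for untrained models.
#' @return `B x m` matrix of generated expression profiles.
#' @export
predict_unseen <- function(model, perturbation = NULL, label = NULL,
                           control_cells, c, B = 64, seed = 1,
                           add_noise = TRUE) {
  assert_scalar(c)
  Xc <- as_dense(control_cells)
  ix <- seeded_sample(derive_seed(seed, "predict_cells"), nrow(Xc), B,
                      replace = nrow(Xc) < B)
  fw <- model_forward(model, Xc[ix, , drop = FALSE], perturbation = perturbation,
                      label = label, c = c,
                      seed = derive_seed(seed, "predict_z"))
  out <- fw$X_hat
  if (add_noise && !is.null(model$noise_sd)) {
    eps <- with_seed(derive_seed(seed, "predict_noise"),
                     matrix(stats::rnorm(length(out)), nrow(out), ncol(out)))
    out <- out + sweep(eps, 2, model$noise_sd, "*")
  }
  out
}
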