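#' Pseudo-bulk profile of a cell sample
#'
#' Per-gene arithmetic mean over a population of single cells, emulating a
#' bulk measurement.
#'
#' @param cells `batch x m` matrix.
#' @return Length-`m` vector.
#' @export
pseudo_bulk <- function(cells) {
  cells <- as_dense(cells)
  if (is.null(dim(cells))) cells <- matrix(cells, nrow = 1)
  if (nrow(cells) == 0) abort("empty cell sample.")
  colMeans(cells)
}

#' Pseudo-bulk error and expression-change correlation
#'
#' `mse_metric()` is the mean squared difference between the pseudo-bulk
#' vectors of prediction and truth. `pearson_change()` correlates, across
#' genes, the predicted expression change from control with the true change
#' from control; it is `NA` (with a message) when either change vector has
#' zero variance.
#'
#' @param pred,truth,control `cells x m` samples over a common gene set.
#' @return A scalar.
#' @export
mse_metric <- function(pred, truth) {
  mean((pseudo_bulk(pred) - pseudo_bulk(truth))^2)
}

#' @rdname mse_metric
#' @export
pearson_change <- function(pred, truth, control) {
  dp <- pseudo_bulk(pred) - pseudo_bulk(control)
  dt <- pseudo_bulk(truth) - pseudo_bulk(control)
  if (stats::sd(dp) == 0 || stats::sd(dt) == 0) {
    inform("zero-variance change vector; Pearson correlation undefined.")
    return(NA_real_)
  }
  stats::cor(dp, dt)
}

#' Energy distance between two cell samples
#'
#' The standard energy distance `2 E||x - y|| - E||x - x'|| - E||y - y'||`
#' with Euclidean norms, estimated by the V-statistic. Nonnegative, zero for
#' identical samples, symmetric.
#'
#' @param X,Y `cells x m` matrices over the same gene set.
#' @export
energy_distance <- function(X, Y) {
  X <- as_dense(X); Y <- as_dense(Y)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (is.null(dim(Y))) Y <- matrix(Y, nrow = 1)
  if (ncol(X) != ncol(Y)) abort("samples must share the gene dimension.",
                                class = "perturbscm_invalid_dimension")
  exy <- mean(sqrt(pairwise_sq_dists(X, Y)))
  exx <- mean(sqrt(pairwise_sq_dists(X, X)))
  eyy <- mean(sqrt(pairwise_sq_dists(Y, Y)))
  max(2 * exy - exx - eyy, 0)
}

#' Fractions of genes changed in the same / opposite direction
#'
#' For each gene, the predicted change from control and the true change from
#' control are compared by sign. Genes whose true or predicted change has
#' magnitude `<= epsilon` are excluded from both numerators but kept in the
#' denominator, so the two fractions need not sum to one.
#'
#' @param pred,truth,control Cell samples.
#' @param epsilon Dead-zone below which a change does not count as a change.
#' @return Named vector `c(frac_same =, frac_changed =)`.
#' @export
fraction_same_changed <- function(pred, truth, control, epsilon = 0) {
  dp <- pseudo_bulk(pred) - pseudo_bulk(control)
  dt <- pseudo_bulk(truth) - pseudo_bulk(control)
  m <- length(dp)
  live <- abs(dp) > epsilon & abs(dt) > epsilon
  same <- sum(live & sign(dp) == sign(dt)) / m
  changed <- sum(live & sign(dp) == -sign(dt)) / m
  c(frac_same = same, frac_changed = changed)
}

#' Top highly variable genes of a dataset
#'
#' The `k` genes with greatest expression variance across all cells of the
#' evaluation dataset; ties are broken deterministically by gene index.
#'
#' @param data An [expression_dataset] (or a plain matrix).
#' @param k Number of genes (default 50).
#' @return Integer vector of gene column indices, sorted by rank.
#' @export
top_k_hvg <- function(data, k = 50) {
  vals <- if (inherits(data, "expression_dataset")) as_dense(data$values) else as_dense(data)
  m <- ncol(vals)
  k <- assert_count(k)
  if (k > m) abort("`k` exceeds the gene count.", class = "perturbscm_invalid_parameter")
  v <- apply(vals, 2, stats::var)
  order(-v, seq_len(m))[seq_len(k)]
}

#' Six-metric evaluation of per-perturbation predictions
#'
#' For every perturbation with a prediction sample and a ground-truth sample,
#' computes pseudo-bulk MSE, Pearson correlation of expression change, MMD,
#' energy distance, and the fractions of genes changed in the same / opposite
#' direction from control — on all genes and on the top-`hvg_k`
#' highly-variable-gene subset. MMD bandwidths are anchored on each
#' perturbation's ground-truth sample (median pairwise distance times
#' `bandwidth_factors`) so competing predictions are scored with the same
#' kernel. Each sample is subsampled to at most `max_cells` (seeded) to keep
#' the quadratic estimators tractable. Aggregation across perturbations is
#' the unweighted mean and sd.
#'
#' @param predictions Named list: perturbation id -> `cells x m` predicted
#'   sample.
#' @param truths Named list: perturbation id -> ground-truth sample (defaults
#'   to the cells of `data` when `data` is given).
#' @param control Control-cell sample used for change vectors.
#' @param data Optional [expression_dataset] supplying truths and the HVG set.
#' @param hvg_k Size of the highly-variable subset (default 50).
#' @param epsilon Dead-zone for the direction metrics.
#' @param bandwidth_factors RBF bandwidth multipliers for MMD.
#' @param max_cells Per-sample cap for MMD / energy distance.
#' @param seed Seed for the subsampling.
#' @return A `metrics_report`: tibble (`perturbation`, `gene_set`, `metric`,
#'   `value`) with a `summary` attribute tibble (`gene_set`, `metric`,
#'   `mean`, `sd`).
#' @export
evaluate_predictions <- function(predictions, truths = NULL, control,
                                 data = NULL, hvg_k = 50, epsilon = 0,
                                 bandwidth_factors = c(0.5, 1, 2),
                                 max_cells = 500, seed = 1) {
  if (is.null(truths)) {
    if (is.null(data)) abort("supply either `truths` or `data`.")
    truths <- lapply(names(predictions), function(p) perturbed_cells(data, p))
    names(truths) <- names(predictions)
  }
  missing <- setdiff(names(predictions), names(truths))
  if (length(missing) > 0) {
    warn(sprintf("no ground truth for: %s; report is partial.",
                 paste(missing, collapse = ", ")))
  }
  hvg_source <- if (!is.null(data)) data else do.call(rbind, truths)
  m <- ncol(as_dense(control))
  hvg <- if (hvg_k >= m) seq_len(m) else top_k_hvg(hvg_source, hvg_k)
  gene_sets <- list(all = seq_len(m), top50 = hvg)
  control <- as_dense(control)

  rows <- list()
  for (p in intersect(names(predictions), names(truths))) {
    pred <- as_dense(predictions[[p]]); truth <- as_dense(truths[[p]])
    pred_s <- cap_cells(pred, max_cells, derive_seed(seed, paste0("p", p)))
    truth_s <- cap_cells(truth, max_cells, derive_seed(seed, paste0("t", p)))
    for (gs in names(gene_sets)) {
      ix <- gene_sets[[gs]]
      bw <- median_heuristic(truth_s[, ix, drop = FALSE],
                             truth_s[, ix, drop = FALSE], bandwidth_factors)
      fr <- fraction_same_changed(pred[, ix, drop = FALSE],
                                  truth[, ix, drop = FALSE],
                                  control[, ix, drop = FALSE], epsilon)
      rows[[length(rows) + 1L]] <- tibble(
        perturbation = p, gene_set = gs,
        metric = c("MSE", "PearsonR", "MMD", "EnergyDist", "FracSame", "FracChanged"),
        value = c(
          mse_metric(pred[, ix, drop = FALSE], truth[, ix, drop = FALSE]),
          pearson_change(pred[, ix, drop = FALSE], truth[, ix, drop = FALSE],
                         control[, ix, drop = FALSE]),
          mmd(pred_s[, ix, drop = FALSE], truth_s[, ix, drop = FALSE], bandwidths = bw),
          energy_distance(pred_s[, ix, drop = FALSE], truth_s[, ix, drop = FALSE]),
          fr[["frac_same"]], fr[["frac_changed"]]))
    }
  }
  report <- dplyr::bind_rows(rows)
  summary <- report |>
    dplyr::filter(is.finite(.data$value)) |>
    dplyr::group_by(.data$gene_set, .data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     .groups = "drop")
  structure(report, summary = summary, class = c("metrics_report", class(report)))
}

cap_cells <- function(X, max_cells, seed) {
  if (nrow(X) <= max_cells) return(X)
  X[seeded_sample(seed, nrow(X), max_cells), , drop = FALSE]
}

#' Aggregate summary of a metrics report
#'
#' @param report A `metrics_report`.
#' @return Tibble with per-metric mean and sd by gene set.
#' @export
metrics_summary <- function(report) attr(report, "summary")

#' Write a metrics report as TSV plus a JSON summary
#'
#' @param report A `metrics_report`.
#' @param path TSV path; the JSON summary goes to `<path>.summary.json`.
#' @export
write_metrics <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  s <- metrics_summary(report)
  out <- split(s[, c("metric", "mean", "sd")], s$gene_set)
  out <- lapply(out, function(d) {
    stats::setNames(lapply(seq_len(nrow(d)), function(i)
      list(mean = d$mean[i], sd = d$sd[i])), d$metric)
  })
  jsonlite::write_json(out, paste0(path, ".summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
autoplot.metrics_report <- function(object, gene_set = "all", ...) {
  d <- object[object$gene_set == gene_set & is.finite(object$value), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = NULL, y = "per-perturbation value",
                  title = sprintf("evaluation metrics (%s genes)", gene_set)) +
    ggplot2::theme_minimal()
}
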