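#' Remove perturbations with too few cells
#'
#' Perturbations measured in fewer than `min_cells` cells (strictly below the
#' threshold) are removed together with their cells; control cells are never
#' touched. The default of 200 cells targets populations large enough for
#' distribution-level evaluation.
#'
#' @param data An [expression_dataset].
#' @param min_cells Minimum cell count for a perturbation to be retained.
#' @return A filtered [expression_dataset].
#' @export
filter_min_cells <- function(data, min_cells = 200) {
  stopifnot(inherits(data, "expression_dataset"))
  min_cells <- assert_count(min_cells)
  counts <- table(data$perturbation)
  drop <- setdiff(names(counts)[counts < min_cells], data$control_token)
  if (length(drop) > 0) {
    inform(sprintf("removing %d perturbations with < %d cells", length(drop), min_cells))
  }
  keep <- !(data$perturbation %in% drop)
  out <- subset_cells(data, keep)
  if (length(perturbations(out)) == 0) warn("no perturbations left after min-cell filter.")
  out
}

#' Keep only perturbations distinguishable from controls
#'
#' For each perturbation independently, a ridge-penalized logistic regression
#' (perturbed vs control, all genes as features, class-balanced weights) is
#' scored by stratified k-fold cross-validated accuracy; perturbations whose
#' mean CV accuracy exceeds `score_threshold` are retained. This removes
#' targets whose expression response is indistinguishable from control noise
#' and would only dilute distribution-level evaluation. The larger class is
#' subsampled to `max_class_cells` per comparison for tractability.
#'
#' @param data An [expression_dataset].
#' @param score_threshold Retain a perturbation iff mean CV accuracy is
#'   strictly greater than this (default 0.6).
#' @param folds Number of stratified CV folds (default 5).
#' @param seed Seed controlling subsampling and fold assignment.
#' @param max_class_cells Per-class cell cap for the classifier.
#' @param lambda Ridge penalty passed to [glmnet::glmnet()].
#' @return A list with `data` (the filtered dataset) and `scores` (a tibble
#'   `perturbation`, `n_cells`, `cv_accuracy`, `retained`).
#' @export
filter_distinguishable <- function(data, score_threshold = 0.6, folds = 5,
                                   seed = 1, max_class_cells = 2000,
                                   lambda = 1e-2) {
  stopifnot(inherits(data, "expression_dataset"))
  folds <- assert_count(folds, min = 2L)
  ctrl <- control_cells(data)
  perts <- perturbations(data)
  rows <- lapply(seq_along(perts), function(ix) {
    p <- perts[ix]
    Xp <- perturbed_cells(data, p)
    np <- nrow(Xp)
    if (np < folds || nrow(ctrl) < folds) {
      inform(sprintf("skipping '%s': fewer cells than folds in one class", p))
      return(tibble(perturbation = p, n_cells = np,
                    cv_accuracy = NA_real_, retained = FALSE))
    }
    acc <- with_seed(derive_seed(seed, paste0("filter_", p)), {
      Xc <- ctrl
      if (nrow(Xc) > max_class_cells) Xc <- Xc[sample.int(nrow(Xc), max_class_cells), , drop = FALSE]
      if (nrow(Xp) > max_class_cells) Xp <- Xp[sample.int(nrow(Xp), max_class_cells), , drop = FALSE]
      cv_logistic_accuracy(rbind(Xc, Xp),
                           c(rep(0L, nrow(Xc)), rep(1L, nrow(Xp))),
                           folds, lambda)
    })
    tibble(perturbation = p, n_cells = np, cv_accuracy = acc,
           retained = is.finite(acc) && acc > score_threshold)
  })
  scores <- dplyr::bind_rows(rows)
  drop <- scores$perturbation[!scores$retained]
  keep <- !(data$perturbation %in% drop)
  list(data = subset_cells(data, keep), scores = scores)
}

# stratified k-fold CV accuracy of a class-balanced ridge logistic regression
cv_logistic_accuracy <- function(X, y, folds, lambda) {
  fold_of <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold_of[idx] <- rep_len(seq_len(folds), length(idx))
  }
  w <- ifelse(y == 1, 0.5 / mean(y == 1), 0.5 / mean(y == 0))
  accs <- vapply(seq_len(folds), function(f) {
    tr <- fold_of != f
    fit <- glmnet::glmnet(X[tr, , drop = FALSE], y[tr], family = "binomial",
                          alpha = 0, lambda = lambda, weights = w[tr],
                          standardize = TRUE)
    pr <- stats::predict(fit, X[!tr, , drop = FALSE], type = "response")[, 1]
    mean((pr > 0.5) == (y[!tr] == 1))
  }, numeric(1))
  mean(accs)
}
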