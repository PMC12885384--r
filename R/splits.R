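#' Construct train/validation/test splits
#'
#' Two schemes mirror the two evaluation settings:
#'
#' * `in_distribution`: every perturbation (and the control population)
#'   contributes cells to all three roles, by default 70/10/20
#'   train/val/test. Test cells come from the same perturbational
#'   distributions seen in training.
#' * `out_of_distribution`: a subset of perturbations is held out entirely —
#'   all their cells become test cells and none reach train or val. The
#'   held-out sets for `split_index` 0..`n_splits`-1 form a seeded partition
#'   of the perturbation list, so across the rotation every perturbation is
#'   tested exactly once. Remaining perturbations (and controls, which are
#'   never held out) split 85/15 into train/val.
#'
#' Rounding assigns `floor(fraction * n)` cells to test and val and the
#' remainder to train.
#'
#' @param data An [expression_dataset].
#' @param scheme `"in_distribution"` or `"out_of_distribution"`.
#' @param split_index Which rotation element to build (OOD only; 0-based).
#' @param fractions Named fractions; `c(train=, val=, test=)` for ID,
#'   `c(train=, val=)` for OOD. Must sum to 1.
#' @param n_splits Number of rotation elements (OOD).
#' @param held_out Optional explicit character vector of held-out
#'   perturbations (OOD), overriding the seeded rotation.
#' @param seed Seed for all shuffling.
#' @return An object of class `split_assignment`: a list with `scheme`,
#'   `split_index`, `held_out_perturbations` and `roles`, a tibble
#'   (`cell_id`, `perturbation`, `role`).
#' @export
make_split <- function(data,
                       scheme = c("in_distribution", "out_of_distribution"),
                       split_index = 0,
                       fractions = NULL,
                       n_splits = 5,
                       held_out = NULL,
                       seed = 1) {
  stopifnot(inherits(data, "expression_dataset"))
  scheme <- match.arg(scheme)
  perts <- perturbations(data)
  role <- rep(NA_character_, length(data$perturbation))
  if (scheme == "in_distribution") {
    fractions <- fractions %||% c(train = 0.7, val = 0.1, test = 0.2)
    stopifnot(abs(sum(fractions) - 1) < 1e-8)
    for (p in c(data$control_token, perts)) {
      idx <- which(data$perturbation == p)
      idx <- with_seed(derive_seed(seed, paste0("id_split_", p)), sample(idx))
      nte <- floor(fractions[["test"]] * length(idx))
      nva <- floor(fractions[["val"]] * length(idx))
      role[idx] <- c(rep("test", nte), rep("val", nva),
                     rep("train", length(idx) - nte - nva))
    }
    held <- character(0)
  } else {
    fractions <- fractions %||% c(train = 0.85, val = 0.15)
    stopifnot(abs(sum(fractions) - 1) < 1e-8)
    if (is.null(held_out)) {
      if (length(perts) < n_splits) {
        abort(sprintf("OOD rotation needs at least %d perturbations.", n_splits),
              class = "perturbscm_invalid_configuration")
      }
      if (split_index < 0 || split_index >= n_splits) {
        abort("`split_index` must lie in [0, n_splits).",
              class = "perturbscm_invalid_configuration")
      }
      shuffled <- with_seed(derive_seed(seed, "ood_rotation"), sample(perts))
      chunk <- rep_len(seq_len(n_splits), length(shuffled))
      held <- shuffled[chunk == split_index + 1L]
    } else {
      held <- as.character(held_out)
      if (!all(held %in% perts)) abort("`held_out` contains unknown perturbations.")
    }
    role[data$perturbation %in% held] <- "test"
    for (p in c(data$control_token, setdiff(perts, held))) {
      idx <- which(data$perturbation == p)
      idx <- with_seed(derive_seed(seed, paste0("ood_split_", p)), sample(idx))
      nva <- floor(fractions[["val"]] * length(idx))
      role[idx] <- c(rep("val", nva), rep("train", length(idx) - nva))
    }
  }
  structure(list(scheme = scheme,
                 split_index = as.integer(split_index),
                 held_out_perturbations = held,
                 roles = tibble(cell_id = data$cell_ids,
                                perturbation = data$perturbation,
                                role = role)),
            class = "split_assignment")
}

#' @exportS3Method base::print
print.split_assignment <- function(x, ...) {
  tab <- table(x$roles$role)
  cat(sprintf("<split_assignment> %s (index %d): %s; %d held-out perturbations\n",
              x$scheme, x$split_index,
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
              length(x$held_out_perturbations)))
  invisible(x)
}

# expression matrix of the cells with a given role, optionally one perturbation
split_cells <- function(data, split, role, perturbation = NULL) {
  sel <- split$roles$role == role
  if (!is.null(perturbation)) sel <- sel & split$roles$perturbation == perturbation
  as_dense(data$values[sel, , drop = FALSE])
}

#' Export a split assignment as a two-column TSV
#'
#' @param split A [make_split()] result.
#' @param path Output TSV (`cell_id`, `role`).
#' @export
write_split <- function(split, path) {
  utils::write.table(split$roles[, c("cell_id", "role")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
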