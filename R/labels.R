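#' Perturbation labels from PCA of the transposed control matrix
#'
#' The model's only knowledge of a perturbation's identity is a label derived
#' from how its target gene behaves in unperturbed cells: each measured gene
#' is treated as an observation described by its values across the `l`
#' control cells, the `genes x cells` matrix is mean-centered per cell
#' coordinate, and each gene is projected onto the top `k` principal axes.
#' Genes that co-express under natural control-cell heterogeneity — and are
#' therefore likely to induce similar perturbational effects — receive
#' similar labels, and a label exists for any measured gene whether or not it
#' was ever perturbed during training.
#'
#' Each axis is oriented so its largest-magnitude gene score is positive,
#' which makes the fit deterministic, and full-rank fits are exact isometries
#' of the centered gene profiles. When `l` exceeds `max_cells`, control cells
#' are subsampled (seeded) before the fit. (Consumers that care about
#' co-expression pattern rather than variance — the shift encoder in
#' particular — normalize each label to unit length.)
#'
#' @param control_matrix `l cells x m genes` control expression matrix (e.g.
#'   [control_cells()] of a dataset).
#' @param k Number of principal components retained per gene.
#' @param seed Seed for the subsampling step.
#' @param max_cells Cap on control cells used in the PCA.
#' @return An object of class `perturbation_labels` with fields `labels`
#'   (`m x k` matrix), `gene_ids`, `k`, `center` (the per-cell means) and
#'   `rotation`.
#' @export
fit_labels <- function(control_matrix, k = 64, seed = 1, max_cells = 10000) {
  X <- as_dense(control_matrix)
  l <- nrow(X); m <- ncol(X)
  if (l < 2 || m < 2) abort("need at least 2 control cells and 2 genes.")
  k <- assert_count(k)
  if (k > min(m, l)) {
    abort(sprintf("`k` must be <= min(m, l) = %d.", min(m, l)),
          class = "perturbscm_invalid_parameter")
  }
  gene_ids <- colnames(X) %||% sprintf("G%03d", seq_len(m))
  if (l > max_cells) {
    keep <- with_seed(seed, sample.int(l, max_cells))
    X <- X[keep, , drop = FALSE]
    l <- max_cells
  }
  G <- t(X)                                   # genes as observations
  center <- colMeans(G)
  Gc <- sweep(G, 2, center)
  if (max(abs(Gc)) == 0) {
    abort("all genes share one expression profile; labels are degenerate.",
          class = "perturbscm_degenerate_input")
  }
  sv <- svd(Gc, nu = k, nv = k)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  rotation <- sv$v
  # fixed sign convention: largest-|score| entry of each axis is positive
  for (j in seq_len(k)) {
    s <- sign(scores[which.max(abs(scores[, j])), j])
    if (s < 0) { scores[, j] <- -scores[, j]; rotation[, j] <- -rotation[, j] }
  }
  rownames(scores) <- gene_ids
  structure(list(labels = scores, gene_ids = gene_ids, k = k,
                 center = center, rotation = rotation, n_cells = l),
            class = "perturbation_labels")
}

#' @exportS3Method base::print
print.perturbation_labels <- function(x, ...) {
  cat(sprintf("<perturbation_labels> %d genes x %d components\n",
              length(x$gene_ids), x$k))
  invisible(x)
}

#' Look up the label vector of a gene
#'
#' Works identically for genes whose perturbations were seen during training
#' and for unseen targets, as long as the gene was measured in control cells.
#'
#' @param labels A [fit_labels()] result.
#' @param gene Gene identifier.
#' @return A length-`k` numeric vector.
#' @export
label_for_gene <- function(labels, gene) {
  stopifnot(inherits(labels, "perturbation_labels"))
  i <- match(gene, labels$gene_ids)
  if (is.na(i)) {
    near <- labels$gene_ids[utils::head(order(utils::adist(gene, labels$gene_ids)), 3)]
    abort(sprintf("gene '%s' not among the measured genes; nearest matches: %s",
                  gene, paste(near, collapse = ", ")),
          class = "perturbscm_missing_gene")
  }
  labels$labels[i, ]
}

#' Export / reload labels as TSV
#'
#' The table holds `gene_id` plus `k` numeric columns and reloads bit-exactly
#' (values are written with full precision).
#'
#' @param labels A `perturbation_labels` object.
#' @param path TSV path.
#' @export
write_labels <- function(labels, path) {
  tab <- data.frame(gene_id = labels$gene_ids,
                    format(labels$labels, digits = 17, scientific = TRUE, trim = TRUE),
                    check.names = FALSE)
  names(tab)[-1] <- sprintf("pc%02d", seq_len(labels$k))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$gene_id
  structure(list(labels = m, gene_ids = tab$gene_id, k = ncol(m),
                 center = NULL, rotation = NULL, n_cells = NA_integer_),
            class = "perturbation_labels")
}
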