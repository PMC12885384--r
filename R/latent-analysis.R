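#' Mean latent embeddings of perturbations
#'
#' For each perturbation, the posterior-mean latent state of a shared sample
#' of control cells is shifted and propagated through the structural layer
#' and averaged: `U^p = mean over cells of (I - A)^{-1} (mu(X) + c S)`. No
#' reparameterization noise is used, which emulates averaging over
#' infinitely many samples. The control entry (`U` with zero shift) is
#' always included under the control token.
#'
#' @param model A trained `scm_vae`.
#' @param control_cells Control-cell expression matrix.
#' @param perturbations Character vector of perturbation ids (defaults to
#'   the trained ones).
#' @param max_cells Control subsample size (seeded).
#' @param seed Subsampling seed.
#' @param control_token Label used for the control row of the output.
#' @return An object of class `latent_embeddings`: tibble (`perturbation`,
#'   `u01..`), the control row first.
#' @export
embed_perturbations <- function(model, control_cells,
                                perturbations = names(model$c_pen),
                                max_cells = 1000, seed = 1,
                                control_token = "non-targeting") {
  stopifnot(inherits(model, "scm_vae"))
  Xc <- cap_cells(as_dense(control_cells), max_cells,
                  derive_seed(seed, "embed"))
  post <- encode_expression(model, Xc)
  M <- scm_inverse(model)
  mu_mean <- colMeans(post$mean)
  u0 <- drop(M %*% mu_mean)
  rows <- lapply(perturbations, function(p) {
    sc <- shift_for(model, p)
    u0 + drop(M %*% (sc$c * sc$S))
  })
  emb <- rbind(u0, do.call(rbind, rows))
  colnames(emb) <- sprintf("u%02d", seq_len(ncol(emb)))
  out <- dplyr::bind_cols(
    tibble(perturbation = c(control_token, perturbations)),
    as_tibble(emb))
  structure(out, class = c("latent_embeddings", class(out)))
}

embedding_matrix <- function(emb) {
  m <- as.matrix(emb[, grep("^u\\d+$", names(emb)), drop = FALSE])
  rownames(m) <- emb$perturbation
  m
}

#' Latent-distance vs expression-distance concordance
#'
#' For every perturbation, pairs the Euclidean distance between its mean
#' latent state and the control mean latent state with the MMD between its
#' expression distribution and the control expression distribution, and
#' reports the Pearson correlation of the two across perturbations. A
#' strongly positive correlation shows the latent space tracks how far each
#' perturbation moves the transcriptome.
#'
#' @param embeddings An [embed_perturbations()] result.
#' @param data An [expression_dataset] holding cells for each perturbation.
#' @param bandwidth_factors MMD bandwidth multipliers.
#' @param max_cells Per-sample cap for MMD.
#' @param seed Subsampling seed.
#' @return List with `pairs` (tibble `perturbation`, `latent_l2`, `mmd`) and
#'   `correlation` (NA with a message when degenerate).
#' @export
distance_concordance <- function(embeddings, data,
                                 bandwidth_factors = c(0.5, 1, 2),
                                 max_cells = 500, seed = 1) {
  emb <- embedding_matrix(embeddings)
  ctrl_row <- which(embeddings$perturbation == data$control_token)
  if (length(ctrl_row) == 0) abort("embeddings lack a control entry.")
  perts <- setdiff(embeddings$perturbation, data$control_token)
  Xc <- cap_cells(control_cells(data), max_cells, derive_seed(seed, "conc_ctrl"))
  rows <- lapply(perts, function(p) {
    if (!p %in% data$perturbation) {
      inform(sprintf("no cells for '%s'; skipped.", p))
      return(NULL)
    }
    Xp <- cap_cells(perturbed_cells(data, p), max_cells,
                    derive_seed(seed, paste0("conc_", p)))
    tibble(perturbation = p,
           latent_l2 = sqrt(sum((emb[p, ] - emb[ctrl_row, ])^2)),
           mmd = mmd(Xp, Xc, factors = bandwidth_factors))
  })
  pairs <- dplyr::bind_rows(rows)
  correlation <- if (nrow(pairs) >= 3 && stats::sd(pairs$latent_l2) > 0 &&
                     stats::sd(pairs$mmd) > 0) {
    stats::cor(pairs$latent_l2, pairs$mmd)
  } else {
    inform("concordance correlation undefined (fewer than 3 points or zero variance).")
    NA_real_
  }
  list(pairs = pairs, correlation = correlation)
}

#' Sweep the penetrance of one perturbation
#'
#' Generates cells with [predict_unseen()] at each value of `c_values` and
#' reports the MMD between the generated distribution and a control sample.
#' Around `c = 0` the generated cells match the model's control
#' reconstruction; increasing `|c|` pushes the distribution away from
#' control.
#'
#' @param model A trained `scm_vae`.
#' @param perturbation Perturbation id.
#' @param control_cells Control-cell matrix (generation source and MMD
#'   reference).
#' @param c_values Penetrance values to sweep.
#' @param B Cells generated per value.
#' @param seed Seed (shared across the sweep).
#' @param bandwidth_factors MMD bandwidth multipliers.
#' @return Tibble (`c`, `mmd_to_control`) with the generated samples in the
#'   `samples` attribute.
#' @export
penetrance_sweep <- function(model, perturbation, control_cells,
                             c_values = seq(-1, 3, by = 0.25), B = 64,
                             seed = 1, bandwidth_factors = c(0.5, 1, 2)) {
  Xc <- as_dense(control_cells)
  ref <- cap_cells(Xc, 500, derive_seed(seed, "sweep_ref"))
  samples <- lapply(c_values, function(cc) {
    predict_unseen(model, perturbation, control_cells = Xc, c = cc, B = B,
                   seed = seed)
  })
  out <- tibble(c = c_values,
                mmd_to_control = vapply(samples, function(s)
                  mmd(s, ref, factors = bandwidth_factors), numeric(1)))
  attr(out, "samples") <- samples
  out
}

#' Export latent embeddings as TSV
#'
#' @param embeddings An [embed_perturbations()] result.
#' @param path TSV path.
#' @export
write_embeddings <- function(embeddings, path) {
  utils::write.table(as.data.frame(embeddings), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
autoplot.latent_embeddings <- function(object, ...) {
  m <- embedding_matrix(object)
  pc <- stats::prcomp(m, rank. = 2)
  d <- tibble(perturbation = object$perturbation,
              pc1 = pc$x[, 1], pc2 = pc$x[, 2])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pc1, y = .data$pc2)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$perturbation),
                       size = 2.5, vjust = -0.8) +
    ggplot2::labs(x = "PC1", y = "PC2",
                  title = "mean latent perturbation embeddings") +
    ggplot2::theme_minimal()
}
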