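# Training of the hybrid model: per-population minibatch steps with manual
# backpropagation through decoder, structural solve, reparameterization,
# encoder and shift encoder.

# forward + backward for one population batch.
# X: control cells (batch x m); Y: target cells (controls themselves, or
# paired perturbed cells); S,c: shift and penetrance (S NULL for control);
# label: the (scaled) label row that produced S, needed for the shift-encoder
# backward; weights kl_w / mmd_w already include beta / gamma.
batch_step <- function(par, mask_mat, X, Y, S, c, label_scaled,
                       kl_w, mmd_w, eps, bw_factors, pert = NULL) {
  B <- nrow(X); n <- ncol(eps)
  efw <- mlp2_forward(X, par$enc_W1, par$enc_b1, par$enc_W2, par$enc_b2)
  MU <- sweep(efw$H2 %*% par$enc_Wmu + X %*% par$enc_Wskip, 2, par$enc_bmu, "+")
  LVr <- sweep(efw$H2 %*% par$enc_Wlv, 2, par$enc_blv, "+")
  LV <- pmin(pmax(LVr, -8), 8)
  clamp <- (LVr > -8 & LVr < 8) * 1
  Z <- MU + exp(LV / 2) * eps
  rhs <- if (!is.null(S)) sweep(Z, 2, c * S, "+") else Z
  A <- par$A_free * mask_mat
  M <- solve(diag(n) - A)
  U <- rhs %*% t(M)
  dfw <- mlp2_forward(U, par$dec_W1, par$dec_b1, par$dec_W2, par$dec_b2)
  X_hat <- sweep(dfw$H2 %*% par$dec_W3 + U %*% par$dec_Wskip, 2, par$dec_b3, "+")

  recon <- mean(rowSums((X_hat - Y)^2))
  klv <- if (kl_w > 0) mean(kl_gaussian(MU, LV)) else 0
  dX_hat <- 2 * (X_hat - Y) / B
  mmdv <- 0
  if (mmd_w > 0) {
    bw <- median_heuristic(X_hat, Y, bw_factors)
    mg <- mmd_with_grad(X_hat, Y, bw)
    mmdv <- mg$value
    dX_hat <- dX_hat + mmd_w * mg$grad
  }
  total <- recon + kl_w * klv + mmd_w * mmdv

  g <- list()
  db <- mlp2_backward(dfw, tcrossprod(dX_hat, par$dec_W3),
                      par$dec_W1, par$dec_W2)
  g$dec_W3 <- crossprod(dfw$H2, dX_hat)
  g$dec_b3 <- colSums(dX_hat)
  g$dec_W1 <- db$dW1; g$dec_b1 <- db$db1
  g$dec_W2 <- db$dW2; g$dec_b2 <- db$db2
  g$dec_Wskip <- crossprod(U, dX_hat)
  dU <- db$dX + tcrossprod(dX_hat, par$dec_Wskip)
  dRhs <- dU %*% M
  g$A_free <- (t(M) %*% crossprod(dU, rhs) %*% t(M)) * mask_mat
  if (!is.null(S)) {
    cs <- colSums(dRhs)
    dS <- c * cs
    if (!is.null(pert)) {
      dc <- sum(S * cs)
      g$c_pen <- structure(dc, names = pert)
    }
    sfw <- mlp2_forward(label_scaled, par$sh_W1, par$sh_b1, par$sh_W2, par$sh_b2)
    dSrow <- matrix(dS, nrow = 1)
    g$sh_W3 <- crossprod(sfw$H2, dSrow)
    g$sh_b3 <- dS
    sb <- mlp2_backward(sfw, tcrossprod(dSrow, par$sh_W3), par$sh_W1, par$sh_W2)
    g$sh_W1 <- sb$dW1; g$sh_b1 <- sb$db1
    g$sh_W2 <- sb$dW2; g$sh_b2 <- sb$db2
  }
  dZ <- dRhs
  dMU <- dZ
  dLV <- dZ * eps * 0.5 * exp(LV / 2)
  if (kl_w > 0) {
    dMU <- dMU + kl_w * MU / B
    dLV <- dLV + kl_w * (exp(LV) - 1) / (2 * B)
  }
  dLV <- dLV * clamp
  g$enc_Wmu <- crossprod(efw$H2, dMU); g$enc_bmu <- colSums(dMU)
  g$enc_Wskip <- crossprod(X, dMU)
  g$enc_Wlv <- crossprod(efw$H2, dLV); g$enc_blv <- colSums(dLV)
  dH2 <- tcrossprod(dMU, par$enc_Wmu) + tcrossprod(dLV, par$enc_Wlv)
  eb <- mlp2_backward(efw, dH2, par$enc_W1, par$enc_W2)
  g$enc_W1 <- eb$dW1; g$enc_b1 <- eb$db1
  g$enc_W2 <- eb$dW2; g$enc_b2 <- eb$db2

  list(grads = g, total = total,
       terms = c(recon = recon, kl = klv, mmd = mmdv))
}

seeded_sample <- function(seed, n, size, replace = FALSE) {
  with_seed(seed, sample.int(n, size, replace = replace))
}

#' Train the hybrid causal autoencoder
#'
#' Joint minibatch training of the expression encoder, shift encoder, masked
#' structural adjacency, expression decoder and per-perturbation penetrance
#' scalars. Each epoch visits every training population (controls plus each
#' perturbation with training cells) once with one batch of `batch_size`
#' cells: control batches optimize reconstruction plus the KL term; perturbed
#' batches pair a seeded sample of control cells with a seeded sample of
#' perturbed cells 1:1 (mean matching through MSE) and add the MMD term
#' (distribution matching). Validation loss is tracked every `val_every`
#' epochs and the best-validation parameter snapshot is restored at the end.
#' Training aborts with a diagnostic if the loss turns non-finite.
#'
#' @param data An [expression_dataset].
#' @param labels A [fit_labels()] result covering the dataset's genes.
#' @param split A [make_split()] assignment, or `NULL` to train on all cells
#'   with no validation.
#' @param config A [model_config()].
#' @return A trained `scm_vae` object with `shift_table` (tibble:
#'   `perturbation`, `penetrance`, shift columns `s01..`), `loss_history`
#'   (tibble: `epoch`, `train_loss`, `val_loss`) and `best_val_loss`.
#' @export
fit_scm_vae <- function(data, labels, split = NULL, config = benchmark_config()) {
  stopifnot(inherits(data, "expression_dataset"))
  if (is.null(split)) {
    split <- list(roles = tibble(cell_id = data$cell_ids,
                                 perturbation = data$perturbation,
                                 role = "train"))
  }
  seed <- config$seed
  roles <- split$roles$role
  tr_ctrl <- as_dense(data$values[roles == "train" &
                                    data$perturbation == data$control_token, , drop = FALSE])
  if (nrow(tr_ctrl) == 0) abort("no control cells in the training role.")
  perts <- sort(intersect(perturbations(data),
                          unique(split$roles$perturbation[roles == "train"])))
  tr_pert <- lapply(perts, function(p)
    as_dense(data$values[roles == "train" & data$perturbation == p, , drop = FALSE]))
  names(tr_pert) <- perts

  model <- init_model(ncol(data$values), labels, config)
  model$par$c_pen <- structure(rep(1, length(perts)), names = perts)
  labels_scaled <- lapply(perts, function(p)
    scale_label(label_for_gene(labels, p)))
  names(labels_scaled) <- perts

  state <- adam_init(model$par)
  lr_override <- list(c_pen = config$lr_penetrance)
  mask_mat <- model$mask$mask
  has_val <- any(roles == "val")
  history <- vector("list", config$epochs + 1L)
  val0 <- if (has_val) model_loss(model, data, split, role = "val",
                                  seed = derive_seed(seed, "val0"))$total else NA_real_
  history[[1]] <- tibble(epoch = 0L, train_loss = NA_real_, val_loss = val0)
  best <- list(par = model$par, val = val0 %||% Inf)
  if (!is.finite(best$val)) best$val <- Inf

  pops <- c("__control__", perts)
  for (ep in seq_len(config$epochs)) {
    sched <- with_seed(derive_seed(seed, paste0("sched", ep)), sample(pops))
    step_losses <- numeric(length(sched))
    for (si in seq_along(sched)) {
      pop <- sched[si]
      sseed <- derive_seed(seed, paste0("step", ep, "_", pop))
      if (pop == "__control__") {
        B <- min(config$batch_size, nrow(tr_ctrl))
        ix <- seeded_sample(sseed, nrow(tr_ctrl), B)
        X <- tr_ctrl[ix, , drop = FALSE]
        eps <- with_seed(sseed + 1L, matrix(stats::rnorm(B * config$n), B, config$n))
        st <- batch_step(model$par, mask_mat, X, X, NULL, 0, NULL,
                         kl_w = config$beta, mmd_w = 0, eps = eps,
                         bw_factors = config$mmd_bandwidth_factors)
      } else {
        Yp <- tr_pert[[pop]]
        B <- min(config$batch_size, nrow(Yp), nrow(tr_ctrl))
        ixc <- seeded_sample(sseed, nrow(tr_ctrl), B)
        ixp <- seeded_sample(sseed + 2L, nrow(Yp), B)
        X <- tr_ctrl[ixc, , drop = FALSE]
        Y <- Yp[ixp, , drop = FALSE]
        eps <- with_seed(sseed + 1L, matrix(stats::rnorm(B * config$n), B, config$n))
        lab_in <- labels_scaled[[pop]]
        jit <- config$label_jitter %||% 0
        if (jit > 0) {
          lab_in <- with_seed(sseed + 3L, lab_in + stats::rnorm(length(lab_in), sd = jit))
          lab_in <- lab_in / max(sqrt(sum(lab_in^2)), 1e-12)
        }
        S <- drop(encode_shift_par(model$par, lab_in))
        kl_w <- if (config$kl_all_cells) config$beta else 0
        st <- batch_step(model$par, mask_mat, X, Y, S, model$par$c_pen[[pop]],
                         lab_in, kl_w = kl_w,
                         mmd_w = config$gamma, eps = eps,
                         bw_factors = config$mmd_bandwidth_factors, pert = pop)
        # expand the scalar c gradient into the full named vector
        if (!is.null(st$grads$c_pen)) {
          gc <- model$par$c_pen * 0
          gc[names(st$grads$c_pen)] <- st$grads$c_pen
          st$grads$c_pen <- gc
        }
      }
      if (!is.finite(st$total)) {
        abort(sprintf("training diverged at epoch %d (population '%s'): non-finite loss.",
                      ep, pop))
      }
      step_losses[si] <- st$total
      upd <- adam_step(model$par, st$grads, state, config$lr, lr_override)
      model$par <- upd$par
      state <- upd$state
    }
    # gauge fixing: the factorization c * S is scale-degenerate, so the
    # penetrance scalars are renormalized to geometric mean 1 (an average
    # guide has nominal strength) and the shift-encoder output layer absorbs
    # the inverse factor. The transformation leaves every product c_p * S_p
    # unchanged; it only pins the convention, like the sigma = 1 latent scale.
    if (length(model$par$c_pen) > 0) {
      gbar <- exp(mean(log(pmax(abs(model$par$c_pen), 1e-3))))
      if (is.finite(gbar) && gbar > 0) {
        model$par$c_pen <- model$par$c_pen / gbar
        model$par$sh_W3 <- model$par$sh_W3 * gbar
        model$par$sh_b3 <- model$par$sh_b3 * gbar
      }
    }
    vl <- NA_real_
    if (has_val && (ep %% config$val_every == 0 || ep == config$epochs)) {
      vl <- model_loss(model, data, split, role = "val",
                       seed = derive_seed(seed, paste0("val", ep)))$total
      if (is.finite(vl) && vl < best$val) best <- list(par = model$par, val = vl)
    }
    history[[ep + 1L]] <- tibble(epoch = ep, train_loss = mean(step_losses),
                                 val_loss = vl)
  }
  if (has_val && is.finite(best$val)) model$par <- best$par
  model$c_pen <- model$par$c_pen
  # observation-noise scale of the Gaussian likelihood: per-gene sd of the
  # reconstruction residuals on control cells, used when sampling cells
  res_ctrl <- tr_ctrl[seeded_sample(derive_seed(seed, "noise_est"),
                                    nrow(tr_ctrl), min(nrow(tr_ctrl), 1000L)), ,
                      drop = FALSE]
  fw <- model_forward(model, res_ctrl, seed = derive_seed(seed, "noise_fwd"))
  model$noise_sd <- apply(res_ctrl - fw$X_hat, 2, stats::sd)
  model$loss_history <- dplyr::bind_rows(history)
  model$best_val_loss <- if (has_val) best$val else NA_real_
  model$trained <- TRUE
  model$shift_table <- shift_table(model)
  model
}

# shift-encoder forward on already-scaled label row, parameter-list version
encode_shift_par <- function(par, label_scaled) {
  fw <- mlp2_forward(label_scaled, par$sh_W1, par$sh_b1, par$sh_W2, par$sh_b2)
  sweep(fw$H2 %*% par$sh_W3, 2, par$sh_b3, "+")
}

#' Shift table of a trained model
#'
#' One row per trained perturbation: learned penetrance and the `n` latent
#' shift coordinates (columns `s01`, `s02`, ...). The control population maps
#' to the zero shift with zero penetrance by construction and is not listed.
#'
#' @param model A trained `scm_vae`.
#' @return A tibble.
#' @export
shift_table <- function(model) {
  perts <- names(model$c_pen)
  if (length(perts) == 0) return(tibble(perturbation = character(0), penetrance = numeric(0)))
  S <- t(vapply(perts, function(p) encode_shift(model, label_for_gene(model$labels, p)),
                numeric(model$config$n)))
  colnames(S) <- sprintf("s%02d", seq_len(ncol(S)))
  dplyr::bind_cols(tibble(perturbation = perts,
                          penetrance = unname(model$c_pen[perts])),
                   as_tibble(S))
}

#' Evaluate the training objective on a role of a split
#'
#' Computes the full objective exactly as trained: per-population mean
#' squared reconstruction error (control included as one population, each
#' perturbation's predictions generated from same-role control cells paired
#' 1:1 with its cells), plus `beta` times the closed-form KL averaged over
#' control cells, plus `gamma` times the mean MMD over non-control
#' populations. The reported total equals the sum of the reported terms.
#'
#' @param model A (possibly untrained) `scm_vae`.
#' @param data,split Dataset and split assignment.
#' @param role Which role to evaluate (`"val"`, `"test"`, `"train"`).
#' @param seed Seed for reparameterization and pairing.
#' @param max_cells Per-population cell cap.
#' @return List with `total` and `breakdown` (tibble `term`, `value`).
#' @export
model_loss <- function(model, data, split, role = "val", seed = 1,
                       max_cells = 256) {
  roles <- split$roles$role
  Xc <- as_dense(data$values[roles == role &
                               data$perturbation == data$control_token, , drop = FALSE])
  if (nrow(Xc) == 0) abort(sprintf("no control cells with role '%s'", role))
  if (nrow(Xc) > max_cells) {
    Xc <- Xc[seeded_sample(derive_seed(seed, "loss_ctrl"), nrow(Xc), max_cells), , drop = FALSE]
  }
  cfg <- model$config
  fwc <- model_forward(model, Xc, seed = derive_seed(seed, "loss_fwd_ctrl"))
  recon_terms <- mean(rowSums((fwc$X_hat - Xc)^2))
  post <- fwc$posterior
  kl_term <- cfg$beta * mean(kl_gaussian(post$mean, post$log_variance))
  perts <- intersect(names(model$par$c_pen) %||% names(model$c_pen),
                     unique(split$roles$perturbation[roles == role]))
  mmds <- numeric(0)
  for (p in perts) {
    Yp <- as_dense(data$values[roles == role & data$perturbation == p, , drop = FALSE])
    if (nrow(Yp) == 0) next
    if (nrow(Yp) > max_cells) {
      Yp <- Yp[seeded_sample(derive_seed(seed, paste0("loss_", p)), nrow(Yp), max_cells), , drop = FALSE]
    }
    ixc <- seeded_sample(derive_seed(seed, paste0("loss_pair_", p)), nrow(Xc),
                         nrow(Yp), replace = nrow(Yp) > nrow(Xc))
    fw <- model_forward(model, Xc[ixc, , drop = FALSE], perturbation = p,
                        seed = derive_seed(seed, paste0("loss_fw_", p)))
    recon_terms <- c(recon_terms, mean(rowSums((fw$X_hat - Yp)^2)))
    mmds <- c(mmds, mmd(fw$X_hat, Yp, factors = cfg$mmd_bandwidth_factors))
  }
  recon <- mean(recon_terms)
  mmd_term <- if (length(mmds) > 0) cfg$gamma * mean(mmds) else 0
  total <- recon + kl_term + mmd_term
  list(total = total,
       breakdown = tibble(term = c("reconstruction", "kl", "mmd"),
                          value = c(recon, kl_term, mmd_term)))
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS archive holding all weights, the graph
#' mask, penetrance scalars, shift table, label reference and the full
#' configuration, and reloads bit-exactly.
#'
#' @param model A `scm_vae`.
#' @param path File path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "scm_vae"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "scm_vae"))
  model
}

#' @export
tidy.scm_vae <- function(x, ...) {
  if (!x$trained) abort("model is untrained; nothing to tidy.")
  x$shift_table
}

#' @export
glance.scm_vae <- function(x, ...) {
  tibble(n_genes = x$m, n_latent = x$config$n, mask_kind = x$mask$kind,
         n_perturbations = length(x$c_pen),
         epochs = x$config$epochs,
         best_val_loss = x$best_val_loss %||% NA_real_,
         trained = x$trained)
}

#' @export
autoplot.scm_vae <- function(object, ...) {
  h <- object$loss_history
  if (is.null(h)) abort("no loss history; train the model first.")
  d <- tidyr::pivot_longer(h, c("train_loss", "val_loss"),
                           names_to = "series", values_to = "loss")
  d <- d[is.finite(d$loss), , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "objective", colour = NULL) +
    ggplot2::theme_minimal()
}
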