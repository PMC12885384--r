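#' Model configuration
#'
#' Tunable hyperparameters of the hybrid model. `n` is the number of latent
#' gene modules (512 suits genome-scale screens; the packaged synthetic
#' benchmark uses 32). `beta` and `gamma` weight the KL and MMD terms of the
#' objective and are meant to be selected on validation loss. `mask_kind`
#' chooses the structural layer: a learned DAG under a strictly
#' upper-triangular mask (default), a pre-specified DAG, a seeded random DAG,
#' or no structural mixing at all (`none_conditional`, where the decoder sees
#' `Z + c * S` directly).
#'
#' @param n Latent module count.
#' @param hidden Hidden width of the expression encoder and decoder.
#' @param shift_hidden Hidden width of the shift encoder.
#' @param beta KL weight (>= 0).
#' @param gamma MMD weight (>= 0).
#' @param mask_kind One of `"learned_upper_triangular"`, `"none_conditional"`,
#'   `"random_dag"`, `"prespecified_dag"`.
#' @param mask A [graph_mask] when `mask_kind = "prespecified_dag"`.
#' @param random_mask_density Edge density for `mask_kind = "random_dag"`.
#' @param mmd_bandwidth_factors Multipliers of the median pairwise distance
#'   used as RBF bandwidths in the training MMD term.
#' @param batch_size Cells per population per gradient step.
#' @param lr Adam learning rate for all network weights.
#' @param lr_penetrance Learning rate for the per-perturbation penetrance
#'   scalars. Kept high enough that `c^p` absorbs per-guide strength while
#'   the shift encoder represents perturbation identity; the residual scale
#'   degeneracy of the `c * S` factorization is removed during training by
#'   renormalizing the penetrance scalars to geometric mean 1 (the shift
#'   encoder's output layer absorbs the inverse factor).
#' @param label_jitter Sd of seeded Gaussian jitter applied per coordinate to
#'   the (normalized) perturbation label at each training step, re-normalized
#'   afterwards. Smooths the label-to-shift map over the angular neighbourhood
#'   of each training label, which is what lets shifts transfer to unseen
#'   targets whose labels land near — but not on — a trained one. Scaled to
#'   the typical within-program label spread; 0 disables.
#' @param epochs Training epochs (one minibatch per population per epoch).
#' @param kl_all_cells If `TRUE`, the KL term averages over all cells rather
#'   than control cells only.
#' @param val_every Validation-loss cadence in epochs.
#' @param seed Seed governing initialization, shuffling and reparameterization.
#' @return A `model_config` list.
#' @export
model_config <- function(n = 512, hidden = 1024, shift_hidden = 256,
                         beta = 1e-2, gamma = 1.0,
                         mask_kind = c("learned_upper_triangular",
                                       "none_conditional", "random_dag",
                                       "prespecified_dag"),
                         mask = NULL, random_mask_density = 0.1,
                         mmd_bandwidth_factors = c(0.5, 1, 2),
                         batch_size = 128, lr = 2e-3, lr_penetrance = 5e-3,
                         label_jitter = 0.05,
                         epochs = 100, kl_all_cells = FALSE, val_every = 5,
                         seed = 1) {
  mask_kind <- match.arg(mask_kind)
  stopifnot(beta >= 0, gamma >= 0, n >= 1)
  structure(list(n = as.integer(n), hidden = as.integer(hidden),
                 shift_hidden = as.integer(shift_hidden), beta = beta,
                 gamma = gamma, mask_kind = mask_kind, mask = mask,
                 random_mask_density = random_mask_density,
                 mmd_bandwidth_factors = mmd_bandwidth_factors,
                 batch_size = as.integer(batch_size), lr = lr,
                 lr_penetrance = lr_penetrance, label_jitter = label_jitter,
                 epochs = as.integer(epochs),
                 kl_all_cells = isTRUE(kl_all_cells),
                 val_every = as.integer(val_every), seed = seed),
            class = "model_config")
}

#' Configuration sized for the packaged synthetic benchmark
#'
#' A desk-scale setting (200 genes): 32 latent modules, width-128 encoder and
#' decoder, width-64 shift encoder, 16-component labels.
#'
#' @param ... Overrides forwarded to [model_config()].
#' @export
benchmark_config <- function(...) {
  defaults <- list(n = 32, hidden = 128, shift_hidden = 64, epochs = 100)
  args <- utils::modifyList(defaults, list(...))
  do.call(model_config, args)
}

build_mask <- function(config) {
  switch(config$mask_kind,
    learned_upper_triangular = upper_triangular_mask(config$n),
    none_conditional = zero_mask(config$n),
    random_dag = make_random_dag_mask(config$n, config$random_mask_density,
                                      derive_seed(config$seed, "random_mask")),
    prespecified_dag = {
      if (is.null(config$mask)) abort("prespecified_dag needs `mask`.")
      stopifnot(config$mask$n == config$n)
      config$mask
    })
}

# initialize all parameters; output heads of the encoder and shift encoder
# start at zero so an untrained model maps any input to the prior / zero shift
init_model <- function(m, labels, config) {
  stopifnot(inherits(labels, "perturbation_labels"))
  n <- config$n; h <- config$hidden; hs <- config$shift_hidden
  k <- labels$k
  mask <- build_mask(config)
  par <- with_seed(derive_seed(config$seed, "init"), list(
    enc_W1 = glorot(m, h),  enc_b1 = numeric(h),
    enc_W2 = glorot(h, h),  enc_b2 = numeric(h),
    enc_Wmu = matrix(0, h, n), enc_bmu = numeric(n),
    enc_Wlv = matrix(0, h, n), enc_blv = numeric(n),
    sh_W1 = glorot(k, hs), sh_b1 = numeric(hs),
    sh_W2 = glorot(hs, hs), sh_b2 = numeric(hs),
    sh_W3 = matrix(0, hs, n), sh_b3 = numeric(n),
    A_free = matrix(0, n, n),
    dec_W1 = glorot(n, h), dec_b1 = numeric(h),
    dec_W2 = glorot(h, h), dec_b2 = numeric(h),
    dec_W3 = glorot(h, m), dec_b3 = numeric(m),
    # linear skip paths: the mean head and the decoder carry a direct linear
    # term alongside the MLPs, so linear structure in the data does not have
    # to squeeze through saturating activations
    enc_Wskip = matrix(0, m, n),
    dec_Wskip = glorot(n, m)))
  structure(list(par = par, mask = mask, config = config, labels = labels,
                 m = as.integer(m),
                 gene_ids = labels$gene_ids, c_pen = numeric(0),
                 shift_table = NULL, loss_history = NULL, trained = FALSE),
            class = "scm_vae")
}

#' @exportS3Method base::print
print.scm_vae <- function(x, ...) {
  cat(sprintf(
    "<scm_vae> %d genes -> %d latent modules (%s mask)%s\n",
    x$m, x$config$n, x$mask$kind,
    if (x$trained) sprintf("; trained, %d perturbations", length(x$c_pen))
    else "; untrained"))
  invisible(x)
}

masked_A <- function(model) model$par$A_free * model$mask$mask

# (I - A)^{-1}; explicit because gradients reuse it
scm_inverse <- function(model) {
  solve(diag(model$config$n) - masked_A(model))
}

#' Encode expression into the exogenous posterior
#'
#' Maps a batch of cells to the diagonal-Gaussian posterior `q(Z | X)` over
#' the exogenous module noises. The mean map is deterministic.
#'
#' @param model An `scm_vae` model.
#' @param X `batch x m` expression matrix.
#' @return A `gaussian_posterior`: list with `mean` and `log_variance`
#'   (`batch x n` each).
#' @export
encode_expression <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as_dense(X)
  if (ncol(X) != model$m) {
    abort(sprintf("X has %d genes but the model expects %d.", ncol(X), model$m),
          class = "perturbscm_invalid_dimension")
  }
  p <- model$par
  fw <- mlp2_forward(X, p$enc_W1, p$enc_b1, p$enc_W2, p$enc_b2)
  mu <- sweep(fw$H2 %*% p$enc_Wmu + X %*% p$enc_Wskip, 2, p$enc_bmu, "+")
  lv <- pmin(pmax(sweep(fw$H2 %*% p$enc_Wlv, 2, p$enc_blv, "+"), -8), 8)
  structure(list(mean = mu, log_variance = lv), class = "gaussian_posterior")
}

#' Reparameterized sample from a Gaussian posterior
#'
#' `Z = mean + exp(log_variance / 2) * eps` with standard-normal `eps`;
#' deterministic given `seed`.
#'
#' @param posterior A `gaussian_posterior`.
#' @param seed Integer seed.
#' @export
sample_z <- function(posterior, seed = 1) {
  mu <- posterior$mean; lv <- posterior$log_variance
  eps <- with_seed(seed, matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu)))
  mu + exp(lv / 2) * eps
}

#' Encode a perturbation label into a latent shift vector
#'
#' The shift vector collects the direct (on- and off-target) effects of a
#' perturbation on the latent modules; the control token bypasses the network
#' and returns the zero vector.
#'
#' @param model An `scm_vae` model.
#' @param label Length-`k` label vector, or the control token string.
#' @return Length-`n` shift vector.
#' @export
encode_shift <- function(model, label) {
  if (is.character(label)) return(numeric(model$config$n))
  if (length(label) != model$labels$k) {
    abort("label dimension does not match the fitted label space.",
          class = "perturbscm_invalid_dimension")
  }
  p <- model$par
  x <- scale_label(label)
  fw <- mlp2_forward(x, p$sh_W1, p$sh_b1, p$sh_W2, p$sh_b2)
  drop(sweep(fw$H2 %*% p$sh_W3, 2, p$sh_b3, "+"))
}

# resolve a perturbation argument to (S, c): control -> (0, 0); a trained
# perturbation uses its learned penetrance unless `c` is given
shift_for <- function(model, perturbation = NULL, label = NULL, c = NULL) {
  if (is.null(label) && (is.null(perturbation) ||
      identical(perturbation, "control") || perturbation %in% "non-targeting")) {
    return(list(S = numeric(model$config$n), c = 0))
  }
  if (is.null(label)) label <- label_for_gene(model$labels, perturbation)
  S <- encode_shift(model, label)
  if (is.null(c)) {
    cp <- model$par$c_pen %||% model$c_pen
    c <- if (!is.null(perturbation) && perturbation %in% names(cp)) {
      cp[[perturbation]]
    } else 1
  }
  list(S = S, c = c)
}

#' Full generative pass of the hybrid model
#'
#' Encodes a batch of control cells, samples the exogenous noises, applies
#' the shifted structural solve `U = (I - A)^{-1} (Z + c * S)` and decodes to
#' expression space. With the control token (or `c = 0`) this reduces to a
#' plain VAE reconstruction pass.
#'
#' @param model An `scm_vae` model.
#' @param X `batch x m` control-cell expression.
#' @param perturbation Perturbation id (a measured gene), or `NULL`/control
#'   token for the control path.
#' @param label Optional explicit label vector (overrides `perturbation`).
#' @param c Scalar penetrance; defaults to the learned value (or 1).
#' @param seed Seed for the reparameterization draw.
#' @param reparam If `FALSE`, uses the posterior mean (no noise).
#' @return List with `X_hat`, `U`, `Z`, `posterior`, `S`, `c`.
#' @export
model_forward <- function(model, X, perturbation = NULL, label = NULL,
                          c = NULL, seed = 1, reparam = TRUE) {
  post <- encode_expression(model, X)
  Z <- if (reparam) sample_z(post, seed) else post$mean
  sc <- shift_for(model, perturbation, label, c)
  M <- scm_inverse(model)
  rhs <- if (sc$c != 0) sweep(Z, 2, sc$c * sc$S, "+") else Z
  U <- rhs %*% t(M)
  X_hat <- decode_latent(model$par, U)
  list(X_hat = X_hat, U = U, Z = Z, posterior = post, S = sc$S, c = sc$c)
}

#' Maximum mean discrepancy between two expression samples
#'
#' Biased V-statistic estimator of squared MMD under a sum of RBF kernels.
#' Zero for identical samples and symmetric in its arguments. When
#' `bandwidths` is `NULL`, they are set to the median pairwise distance of
#' the pooled sample times `factors`.
#'
#' @param X,Y `cells x genes` matrices over the same gene set.
#' @param bandwidths Numeric vector of kernel bandwidths, or `NULL`.
#' @param factors Median-heuristic multipliers used when `bandwidths` is NULL.
#' @return Nonnegative scalar.
#' @export
mmd <- function(X, Y, bandwidths = NULL, factors = c(0.5, 1, 2)) {
  X <- as_dense(X); Y <- as_dense(Y)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (is.null(dim(Y))) Y <- matrix(Y, nrow = 1)
  if (ncol(X) != ncol(Y)) abort("samples must share the gene dimension.",
                                class = "perturbscm_invalid_dimension")
  if (nrow(X) == 0 || nrow(Y) == 0) abort("samples must be nonempty.")
  if (is.null(bandwidths)) bandwidths <- median_heuristic(X, Y, factors)
  dxx <- pairwise_sq_dists(X, X); dyy <- pairwise_sq_dists(Y, Y)
  dxy <- pairwise_sq_dists(X, Y)
  val <- 0
  for (h in bandwidths) {
    val <- val + mean(exp(-dxx / (2 * h^2))) + mean(exp(-dyy / (2 * h^2))) -
      2 * mean(exp(-dxy / (2 * h^2)))
  }
  max(val, 0)
}

median_heuristic <- function(X, Y, factors) {
  P <- rbind(X, Y)
  if (nrow(P) > 500) P <- P[seq(1, nrow(P), length.out = 500), , drop = FALSE]
  d <- sqrt(pairwise_sq_dists(P, P))
  med <- stats::median(d[upper.tri(d)])
  if (!is.finite(med) || med <= 0) med <- 1
  med * factors
}

# The shift encoder consumes the direction of a label, not its magnitude:
# a gene's co-expression pattern identifies which programs it belongs to,
# while the score magnitude mostly reflects its expression variance — a
# nuisance for perturbation identity. Normalization also keeps network
# inputs on a fixed scale regardless of control-cell count.
scale_label <- function(label) {
  nrm <- sqrt(sum(label^2))
  matrix(if (nrm > 0) label / nrm else label, nrow = 1)
}

# decoder: tanh MLP plus the linear skip term
decode_latent <- function(par, U) {
  fw <- mlp2_forward(U, par$dec_W1, par$dec_b1, par$dec_W2, par$dec_b2)
  sweep(fw$H2 %*% par$dec_W3 + U %*% par$dec_Wskip, 2, par$dec_b3, "+")
}

# squared-MMD value and gradient with respect to the rows of X
mmd_with_grad <- function(X, Y, bandwidths) {
  B <- nrow(X); By <- nrow(Y)
  dxx <- pairwise_sq_dists(X, X); dyy <- pairwise_sq_dists(Y, Y)
  dxy <- pairwise_sq_dists(X, Y)
  val <- 0
  Wxx <- matrix(0, B, B); Wxy <- matrix(0, B, By)
  for (h in bandwidths) {
    Kxx <- exp(-dxx / (2 * h^2)); Kyy <- exp(-dyy / (2 * h^2))
    Kxy <- exp(-dxy / (2 * h^2))
    val <- val + mean(Kxx) + mean(Kyy) - 2 * mean(Kxy)
    Wxx <- Wxx + Kxx / h^2
    Wxy <- Wxy + Kxy / h^2
  }
  grad <- (2 / (B * By)) * (rowSums(Wxy) * X - Wxy %*% Y) -
    (2 / B^2) * (rowSums(Wxx) * X - Wxx %*% X)
  list(value = val, grad = grad)
}

# closed-form KL(q || N(0, I)) per cell, summed over coordinates
kl_gaussian <- function(mu, lv) {
  0.5 * rowSums(exp(lv) + mu^2 - 1 - lv)
}
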