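# Minimal dense-network machinery: parameter lists, Adam, and the forward /
# backward passes used by the hybrid model. Everything is plain matrix code;
# batches are rows.

glorot <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(1 / nin)), nin, nout)
}

adam_init <- function(par) {
  list(m = lapply(par, function(p) p * 0),
       v = lapply(par, function(p) p * 0),
       t = 0L)
}

# one Adam update; `lr_override` maps parameter names to specific rates
adam_step <- function(par, grad, state, lr, lr_override = NULL,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  for (nm in names(grad)) {
    g <- grad[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    rate <- lr_override[[nm]] %||% lr
    par[[nm]] <- par[[nm]] - rate * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, state = state)
}

# forward through a 2-hidden-layer tanh MLP with two linear heads;
# returns intermediates needed for the backward pass
mlp2_forward <- function(X, W1, b1, W2, b2) {
  H1 <- tanh(sweep(X %*% W1, 2, b1, "+"))
  H2 <- tanh(sweep(H1 %*% W2, 2, b2, "+"))
  list(X = X, H1 = H1, H2 = H2)
}

# backward through the same MLP given dH2 (gradient at the second hidden
# activation); returns gradients and dX
mlp2_backward <- function(fw, dH2, W1, W2) {
  dp2 <- dH2 * (1 - fw$H2^2)
  dW2 <- crossprod(fw$H1, dp2)
  db2 <- colSums(dp2)
  dH1 <- tcrossprod(dp2, W2)
  dp1 <- dH1 * (1 - fw$H1^2)
  dW1 <- crossprod(fw$X, dp1)
  db1 <- colSums(dp1)
  list(dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2,
       dX = tcrossprod(dp1, W1))
}
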