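#' Parameters of the linear latent structural causal model
#'
#' The latent state of a cell is a vector `U` of `n` gene-module activities
#' obeying `U = A U + Z + c * S`, where `Z` is exogenous noise with unit
#' standard deviation per coordinate (the scale of the endogenous variables is
#' arbitrary, so `sigma_i = 1` is a normalization, not an assumption about the
#' data), `S` is a perturbation shift vector and `c` its scalar penetrance.
#' Weights exist only where the graph mask allows them.
#'
#' @param A `n x n` matrix of edge weights; `A[i, j]` is the contribution of
#'   module `j` to module `i`.
#' @param mask A [graph_mask].
#' @return An object of class `scm_params`.
#' @export
scm_params <- function(A, mask) {
  stopifnot(inherits(mask, "graph_mask"))
  A <- as_dense(A)
  if (!is.matrix(A) || any(dim(A) != mask$n)) {
    abort("`A` must be an n x n matrix matching the mask.",
          class = "perturbscm_invalid_dimension")
  }
  A <- A * mask$mask
  structure(list(A = A, mask = mask, exogenous_sd = 1), class = "scm_params")
}

is_triangular_mask <- function(mask) {
  m <- mask$mask
  all(m[lower.tri(m, diag = TRUE)] == 0) || all(m[upper.tri(m, diag = TRUE)] == 0)
}

# (I - A), erroring on singular systems for user-supplied cyclic masks;
# triangular masks always give det(I - A) = 1
i_minus_a <- function(params) {
  IA <- diag(params$mask$n) - params$A
  if (!is_triangular_mask(params$mask)) {
    d <- determinant(IA, logarithm = TRUE)
    if (!is.finite(d$modulus)) {
      abort("(I - A) is singular; the structural system has no unique solution.",
            class = "perturbscm_singular_system")
    }
  }
  IA
}

#' Solve the (shifted) linear structural causal model exactly
#'
#' Returns the endogenous module activities `U` for a batch of cells: each row
#' of `U` solves `U = A U + Z + c * S`, i.e. `U = (I - A)^{-1} (Z + c * S)`.
#' With `S = NULL` or `c = 0` this is the control solution. The system is
#' solved directly against `(I - A)` rather than by forming the inverse.
#'
#' @param params An [scm_params] object.
#' @param Z `batch x n` matrix of exogenous values (a single vector is treated
#'   as one row).
#' @param S Length-`n` shift vector, or `NULL` for no shift.
#' @param c Scalar penetrance multiplying `S`.
#' @return A `batch x n` matrix of endogenous values.
#' @export
solve_scm <- function(params, Z, S = NULL, c = 1) {
  stopifnot(inherits(params, "scm_params"))
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = 1)
  Z <- as_dense(Z)
  n <- params$mask$n
  if (ncol(Z) != n) {
    abort("`Z` must have n columns.", class = "perturbscm_invalid_dimension")
  }
  assert_scalar(c)
  rhs <- Z
  if (!is.null(S) && c != 0) {
    if (length(S) != n) {
      abort("`S` must have length n.", class = "perturbscm_invalid_dimension")
    }
    rhs <- sweep(rhs, 2, c * S, "+")
  }
  IA <- i_minus_a(params)
  t(solve(IA, t(rhs)))
}

#' Exact latent covariance of the control population
#'
#' Under the control model `U = (I - A)^{-1} Z` with `Z ~ N(0, I)`, the
#' covariance of `U` is `(I - A)^{-1} (I - A)^{-T}`. Used as an analytic
#' oracle when validating the synthetic generator.
#'
#' @inheritParams solve_scm
#' @return `n x n` covariance matrix.
#' @export
latent_control_covariance <- function(params) {
  stopifnot(inherits(params, "scm_params"))
  IA <- i_minus_a(params)
  M <- solve(IA)
  tcrossprod(M)
}
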