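#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @import Matrix
NULL

# stop unless `x` is a single finite number
assert_scalar <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  invisible(x)
}

assert_count <- function(x, name = deparse(substitute(x)), min = 1L) {
  assert_scalar(x, name)
  if (x < min || x != as.integer(x)) {
    abort(sprintf("`%s` must be an integer >= %d.", name, min),
          class = "perturbscm_invalid_dimension")
  }
  invisible(as.integer(x))
}

as_dense <- function(x) {
  if (inherits(x, "Matrix")) as.matrix(x) else x
}

#' Derive a stage-specific seed from a global seed
#'
#' One user-facing seed fans out to per-stage seeds by hashing the stage name,
#' so stages stay reproducibly isolated: changing how many random draws one
#' stage makes never perturbs another stage.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name (e.g. `"simulate"`, `"train"`).
#' @return An integer seed below 2^31.
#' @export
derive_seed <- function(seed, stage) {
  assert_scalar(seed)
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((abs(seed) * 7919 + h * 104729) %% .Machine$integer.max)
}

# run `expr` under a local RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# euclidean pairwise squared distances between rows of A and rows of B
pairwise_sq_dists <- function(A, B) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
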