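#' Graph masks for the latent structural causal model
#'
#' A graph mask is an `n x n` binary matrix whose entry `(i, j)` is 1 when the
#' weighted adjacency entry `A[i, j]` (the contribution of latent module `j`
#' to module `i`) is allowed to be nonzero. Four kinds are supported:
#'
#' * `learned_upper_triangular`: every strictly upper-triangular entry is free,
#'   under an arbitrary fixed node ordering. Any DAG is representable up to a
#'   relabeling that the expression encoder can absorb.
#' * `prespecified_dag`: a user-supplied mask (e.g. the output of an external
#'   causal-discovery run on control cells), validated to be acyclic.
#' * `random_dag`: a seeded Erdos-Renyi DAG, used as an ablation.
#' * `none_conditional`: the all-zero mask; the structural layer degenerates to
#'   the identity and the decoder sees `Z + c * S` directly (the
#'   "conditional" ablation).
#'
#' @param n Number of latent modules.
#' @param mask Binary matrix for [prespecified_mask()].
#' @param edge_density Probability that an admissible edge is present.
#' @param seed Integer seed; the random mask is deterministic given it.
#' @return An object of class `graph_mask`: a list with `n`, `kind`, `mask`.
#' @examples
#' upper_triangular_mask(4)
#' make_random_dag_mask(6, edge_density = 0.3, seed = 1)
#' @name graph_mask
NULL

new_graph_mask <- function(n, kind, mask, seed = NULL) {
  structure(list(n = n, kind = kind, mask = mask, seed = seed),
            class = "graph_mask")
}

#' @rdname graph_mask
#' @export
upper_triangular_mask <- function(n) {
  n <- assert_count(n)
  mask <- matrix(0, n, n)
  mask[upper.tri(mask)] <- 1
  new_graph_mask(n, "learned_upper_triangular", mask)
}

#' @rdname graph_mask
#' @export
zero_mask <- function(n) {
  n <- assert_count(n)
  new_graph_mask(n, "none_conditional", matrix(0, n, n))
}

#' @rdname graph_mask
#' @export
make_random_dag_mask <- function(n, edge_density, seed) {
  n <- assert_count(n)
  assert_scalar(edge_density)
  if (edge_density < 0 || edge_density > 1) {
    abort("`edge_density` must lie in [0, 1].")
  }
  mask <- with_seed(seed, {
    perm <- sample.int(n)
    m <- matrix(0, n, n)
    # admissible edges: strictly upper triangular under the permuted ordering
    ut <- upper.tri(m)
    keep <- ut & matrix(stats::runif(n * n) < edge_density, n, n)
    m[keep] <- 1
    # map back through the permutation so the DAG ordering is hidden
    m[perm, perm]
  })
  new_graph_mask(n, "random_dag", mask, seed = seed)
}

#' @rdname graph_mask
#' @export
prespecified_mask <- function(mask) {
  mask <- as_dense(mask)
  if (!is.matrix(mask) || nrow(mask) != ncol(mask)) {
    abort("`mask` must be a square matrix.", class = "perturbscm_invalid_dimension")
  }
  mask <- (mask != 0) * 1
  if (!validate_dag(mask)) {
    abort("prespecified mask must describe a directed acyclic graph.")
  }
  new_graph_mask(nrow(mask), "prespecified_dag", mask)
}

#' Test whether a binary adjacency matrix is acyclic
#'
#' Entry `(i, j) = 1` denotes the edge `j -> i`. Acyclicity is decided by
#' Kahn's topological sort; self-loops count as cycles.
#'
#' @param mask Square binary matrix (a `graph_mask` is also accepted).
#' @return `TRUE` iff the directed graph has no cycle.
#' @export
validate_dag <- function(mask) {
  if (inherits(mask, "graph_mask")) mask <- mask$mask
  mask <- as_dense(mask)
  if (!is.matrix(mask) || nrow(mask) != ncol(mask)) {
    abort("`mask` must be a square matrix.", class = "perturbscm_invalid_dimension")
  }
  n <- nrow(mask)
  adj <- mask != 0
  indeg <- rowSums(adj)          # number of parents of each node
  alive <- rep(TRUE, n)
  removed <- 0L
  repeat {
    roots <- which(alive & indeg == 0)
    if (length(roots) == 0L) break
    alive[roots] <- FALSE
    removed <- removed + length(roots)
    if (length(roots) == 1L) {
      indeg <- indeg - adj[, roots]
    } else {
      indeg <- indeg - rowSums(adj[, roots, drop = FALSE])
    }
  }
  removed == n
}

#' @exportS3Method base::print
print.graph_mask <- function(x, ...) {
  cat(sprintf("<graph_mask> kind=%s, n=%d, %d allowed edges\n",
              x$kind, x$n, sum(x$mask != 0)))
  invisible(x)
}

#' Write / read a graph mask as an edge-list TSV
#'
#' Serialization is a TSV with columns `source`, `target` (0-based module
#' indices, one row per allowed edge `source -> target`) plus a JSON sidecar
#' header `{n, kind, seed}` at `<path>.json`.
#'
#' @param mask A `graph_mask`.
#' @param path File path for the edge list.
#' @return `read_graph_mask()` returns a `graph_mask`.
#' @export
write_graph_mask <- function(mask, path) {
  stopifnot(inherits(mask, "graph_mask"))
  idx <- which(mask$mask != 0, arr.ind = TRUE)
  # edge j -> i for mask[i, j]: source = j, target = i
  edges <- data.frame(source = idx[, 2] - 1L, target = idx[, 1] - 1L)
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(n = mask$n, kind = mask$kind, seed = mask$seed),
    paste0(path, ".json"), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_graph_mask
#' @export
read_graph_mask <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  edges <- utils::read.table(path, header = TRUE, sep = "\t")
  m <- matrix(0, hdr$n, hdr$n)
  if (nrow(edges) > 0) m[cbind(edges$target + 1L, edges$source + 1L)] <- 1
  new_graph_mask(hdr$n, hdr$kind, m, seed = hdr$seed)
}
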