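#' Expression dataset with per-cell perturbation annotation
#'
#' The shared container for real and simulated Perturb-seq data: a
#' `cells x genes` matrix of normalized expression plus, for every cell, the
#' identifier of its perturbed target gene or the control token for
#' non-targeting guides. Every non-control annotation must name a measured
#' gene (single-gene perturbations targeting measured genes) and at least one
#' control cell must exist.
#'
#' @param values `cells x genes` numeric matrix (dense or `Matrix` sparse).
#' @param perturbation Character vector, one entry per cell: a gene id or the
#'   control token.
#' @param gene_ids,cell_ids Identifiers; default to dimnames or generated ids.
#' @param control_token Annotation value marking negative-control cells.
#' @return An object of class `expression_dataset`.
#' @export
expression_dataset <- function(values, perturbation,
                               gene_ids = colnames(values),
                               cell_ids = rownames(values),
                               control_token = "non-targeting") {
  if (is.null(gene_ids)) gene_ids <- sprintf("G%03d", seq_len(ncol(values)))
  if (is.null(cell_ids)) cell_ids <- sprintf("C%06d", seq_len(nrow(values)))
  perturbation <- as.character(perturbation)
  stopifnot(length(perturbation) == nrow(values),
            length(gene_ids) == ncol(values),
            length(cell_ids) == nrow(values))
  is_ctrl <- perturbation == control_token
  if (!any(is_ctrl)) abort("dataset must contain at least one control cell.")
  bad <- setdiff(unique(perturbation[!is_ctrl]), gene_ids)
  if (length(bad) > 0) {
    warn(sprintf(
      "dropping %d cells whose perturbation target is not a measured gene (%s)",
      sum(perturbation %in% bad), paste(utils::head(bad, 5), collapse = ", ")))
    keep <- !(perturbation %in% bad)
    values <- values[keep, , drop = FALSE]
    perturbation <- perturbation[keep]
    cell_ids <- cell_ids[keep]
  }
  dimnames(values) <- list(cell_ids, gene_ids)
  rng <- range(as_dense(values[seq_len(min(nrow(values), 200L)), , drop = FALSE]))
  if (is.finite(rng[2]) && rng[2] > 50) {
    warn("expression values look un-normalized (max > 50); inputs are assumed pre-normalized.")
  }
  structure(list(values = values, gene_ids = gene_ids, cell_ids = cell_ids,
                 perturbation = perturbation, control_token = control_token),
            class = "expression_dataset")
}

#' @exportS3Method base::print
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %d cells x %d genes; %d perturbations + %d control cells\n",
              nrow(x$values), ncol(x$values), length(perturbations(x)),
              sum(x$perturbation == x$control_token)))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

#' Helpers for expression datasets
#'
#' `perturbations()` lists the non-control perturbation identifiers,
#' `control_cells()` / `perturbed_cells()` extract expression matrices,
#' `subset_cells()` subsets by logical or integer index.
#'
#' @param data An [expression_dataset].
#' @param p A perturbation identifier.
#' @param idx Logical or integer cell index.
#' @name dataset-helpers
#' @export
perturbations <- function(data) {
  setdiff(unique(data$perturbation), data$control_token)
}

#' @rdname dataset-helpers
#' @export
control_cells <- function(data) {
  as_dense(data$values[data$perturbation == data$control_token, , drop = FALSE])
}

#' @rdname dataset-helpers
#' @export
perturbed_cells <- function(data, p) {
  if (!p %in% data$perturbation) {
    abort(sprintf("no cells annotated with perturbation '%s'", p))
  }
  as_dense(data$values[data$perturbation == p, , drop = FALSE])
}

#' @rdname dataset-helpers
#' @export
subset_cells <- function(data, idx) {
  expression_dataset(data$values[idx, , drop = FALSE],
                     data$perturbation[idx],
                     gene_ids = data$gene_ids,
                     cell_ids = data$cell_ids[idx],
                     control_token = data$control_token)
}

#' Cell-level metadata as a tibble
#'
#' @param data An [expression_dataset].
#' @return A tibble with `cell_id` and `perturbation`.
#' @export
cell_metadata <- function(data) {
  tibble(cell_id = data$cell_ids, perturbation = data$perturbation)
}

#' Read and write expression datasets
#'
#' Supported formats:
#' * `tsv`: one table, first column `cell_id`, second `perturbation`,
#'   remaining columns one gene each.
#' * `mtx_dir`: a directory in the CellRanger-like layout `matrix.mtx`
#'   (MatrixMarket, genes x cells), `features.tsv`, `barcodes.tsv`, and
#'   `annotation.tsv` (columns `cell_id` and the annotation column).
#' * `h5ad`: AnnData on disk; requires a `python` interpreter with the
#'   `anndata` package on the PATH (the matrix is bridged through an MTX
#'   directory in a temporary location).
#'
#' @param path File (tsv) or directory (mtx_dir) or `.h5ad` file.
#' @param format One of `"tsv"`, `"mtx_dir"`, `"h5ad"`.
#' @param annotation_column Name of the per-cell annotation column.
#' @param control_token Annotation value marking control cells.
#' @param data An [expression_dataset] (for writing).
#' @return `read_dataset()` returns an [expression_dataset].
#' @export
read_dataset <- function(path, format = c("tsv", "mtx_dir", "h5ad"),
                         annotation_column = "perturbation",
                         control_token = "non-targeting") {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("path '%s' does not exist", path))
  ds <- switch(format,
    tsv = {
      tab <- utils::read.table(path, header = TRUE, sep = "\t",
                               check.names = FALSE, stringsAsFactors = FALSE)
      if (!annotation_column %in% names(tab)) {
        abort(sprintf("annotation column '%s' not found", annotation_column),
              class = "perturbscm_missing_column")
      }
      genes <- setdiff(names(tab), c("cell_id", annotation_column))
      vals <- as.matrix(tab[, genes, drop = FALSE])
      expression_dataset(vals, tab[[annotation_column]],
                         gene_ids = genes, cell_ids = as.character(tab$cell_id),
                         control_token = control_token)
    },
    mtx_dir = read_mtx_dir(path, annotation_column, control_token),
    h5ad = read_h5ad(path, annotation_column, control_token))
  inform(sprintf("read %d cells x %d genes, %d perturbations",
                 nrow(ds$values), ncol(ds$values), length(perturbations(ds))))
  ds
}

read_mtx_dir <- function(path, annotation_column, control_token) {
  mm <- Matrix::readMM(file.path(path, "matrix.mtx"))      # genes x cells
  genes <- readLines(file.path(path, "features.tsv"))
  cells <- readLines(file.path(path, "barcodes.tsv"))
  ann <- utils::read.table(file.path(path, "annotation.tsv"), header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
  if (!annotation_column %in% names(ann)) {
    abort(sprintf("annotation column '%s' not found", annotation_column),
          class = "perturbscm_missing_column")
  }
  ann <- ann[match(cells, ann$cell_id), , drop = FALSE]
  vals <- as.matrix(Matrix::t(mm))
  expression_dataset(vals, ann[[annotation_column]], gene_ids = genes,
                     cell_ids = cells, control_token = control_token)
}

#' @rdname read_dataset
#' @export
write_dataset <- function(data, path, format = c("tsv", "mtx_dir", "h5ad"),
                          annotation_column = "perturbation") {
  format <- match.arg(format)
  switch(format,
    tsv = {
      tab <- data.frame(cell_id = data$cell_ids,
                        perturbation = data$perturbation,
                        check.names = FALSE)
      names(tab)[2] <- annotation_column
      tab <- cbind(tab, as.data.frame(as_dense(data$values), check.names = FALSE))
      utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    },
    mtx_dir = {
      dir.create(path, showWarnings = FALSE, recursive = TRUE)
      Matrix::writeMM(Matrix::Matrix(t(as_dense(data$values)), sparse = TRUE),
                      file.path(path, "matrix.mtx"))
      writeLines(data$gene_ids, file.path(path, "features.tsv"))
      writeLines(data$cell_ids, file.path(path, "barcodes.tsv"))
      ann <- data.frame(cell_id = data$cell_ids, x = data$perturbation)
      names(ann)[2] <- annotation_column
      utils::write.table(ann, file.path(path, "annotation.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    },
    h5ad = write_h5ad(data, path, annotation_column))
  invisible(path)
}

python_with_anndata <- function() {
  py <- Sys.which("python")
  if (py == "") return(NULL)
  ok <- suppressWarnings(system2(py, c("-c", shQuote("import anndata")),
                                 stdout = FALSE, stderr = FALSE)) == 0
  if (ok) py else NULL
}

read_h5ad <- function(path, annotation_column, control_token) {
  py <- python_with_anndata()
  if (is.null(py)) {
    abort("h5ad I/O needs a `python` interpreter with the anndata package on the PATH.")
  }
  tmp <- tempfile("h5ad_bridge_")
  script <- sprintf(
    "import anndata, scipy.io, scipy.sparse, os, pandas as pd\nad = anndata.read_h5ad(%s)\nos.makedirs(%s, exist_ok=True)\nX = scipy.sparse.csr_matrix(ad.X)\nscipy.io.mmwrite(os.path.join(%s, 'matrix.mtx'), X.T)\nopen(os.path.join(%s, 'features.tsv'), 'w').write('\\n'.join(map(str, ad.var_names)) + '\\n')\nopen(os.path.join(%s, 'barcodes.tsv'), 'w').write('\\n'.join(map(str, ad.obs_names)) + '\\n')\npd.DataFrame({'cell_id': ad.obs_names, %s: ad.obs[%s].astype(str)}).to_csv(os.path.join(%s, 'annotation.tsv'), sep='\\t', index=False)\n",
    deparse(path), deparse(tmp), deparse(tmp), deparse(tmp), deparse(tmp),
    deparse(annotation_column), deparse(annotation_column), deparse(tmp))
  sf <- tempfile(fileext = ".py"); writeLines(script, sf)
  status <- system2(py, sf, stdout = FALSE, stderr = "")
  if (status != 0) abort("python anndata bridge failed while reading h5ad.")
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  read_mtx_dir(tmp, annotation_column, control_token)
}

write_h5ad <- function(data, path, annotation_column) {
  py <- python_with_anndata()
  if (is.null(py)) {
    abort("h5ad I/O needs a `python` interpreter with the anndata package on the PATH.")
  }
  tmp <- tempfile("h5ad_bridge_")
  write_dataset(data, tmp, format = "mtx_dir", annotation_column = annotation_column)
  script <- sprintf(
    "import anndata, scipy.io, pandas as pd, os\nX = scipy.io.mmread(os.path.join(%s, 'matrix.mtx')).T.tocsr()\ngenes = [l.strip() for l in open(os.path.join(%s, 'features.tsv'))]\ncells = [l.strip() for l in open(os.path.join(%s, 'barcodes.tsv'))]\nann = pd.read_csv(os.path.join(%s, 'annotation.tsv'), sep='\\t', index_col=0)\nann.index = ann.index.astype(str)\nad = anndata.AnnData(X=X.toarray(), obs=ann.loc[cells], var=pd.DataFrame(index=genes))\nad.write_h5ad(%s)\n",
    deparse(tmp), deparse(tmp), deparse(tmp), deparse(tmp), deparse(path))
  sf <- tempfile(fileext = ".py"); writeLines(script, sf)
  status <- system2(py, sf, stdout = FALSE, stderr = "")
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  if (status != 0) abort("python anndata bridge failed while writing h5ad.")
  invisible(path)
}
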