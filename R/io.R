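# Readers/writers for the external text formats: MatrixMarket sparse counts
# with sibling features/barcodes TSVs (CellRanger layout), dense CSV with
# headers, two-column annotation tables, and square transition-graph .mtx.

#' Validate a feature-by-cell expression matrix
#'
#' Checks that a matrix is usable as single-cell counts or normalized
#' expression: non-negative, finite, with unique, non-empty feature and
#' barcode identifiers as `dimnames`.
#'
#' @param mat A base matrix or `Matrix` sparse matrix, features in rows and
#'   cells in columns, with `rownames` (feature ids) and `colnames`
#'   (barcodes).
#' @return The matrix, invisibly, after validation.
#' @export
validate_expression_matrix <- function(mat) {
  if (!is(mat, "Matrix") && !is.matrix(mat)) {
    stop_validation("expression matrix must be a matrix or Matrix object")
  }
  vals <- if (is(mat, "sparseMatrix")) mat@x else as.numeric(mat)
  if (anyNA(vals) || any(!is.finite(vals))) {
    stop_validation("expression matrix contains NA or non-finite entries")
  }
  if (length(vals) && min(vals) < 0) {
    stop_validation("expression matrix contains negative entries")
  }
  fid <- rownames(mat)
  bc <- colnames(mat)
  if (is.null(fid) || is.null(bc)) {
    stop_validation("expression matrix must carry feature ids (rownames) and barcodes (colnames)")
  }
  if (anyDuplicated(fid)) {
    stop_validation(paste0("duplicate feature ids: ",
                           paste(head(unique(fid[duplicated(fid)]), 3), collapse = ", ")))
  }
  if (anyDuplicated(bc)) {
    stop_validation(paste0("duplicate barcodes: ",
                           paste(head(unique(bc[duplicated(bc)]), 3), collapse = ", ")))
  }
  invisible(mat)
}

# MatrixMarket files may come back as pattern or symmetric matrices; force
# a plain numeric general CsparseMatrix either way
to_dgc <- function(m) {
  as(as(as(m, "dMatrix"), "generalMatrix"), "CsparseMatrix")
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "mtx") "mtx" else if (ext %in% c("csv", "tsv")) "csv" else {
    stop_format(paste0("cannot guess matrix format from extension '.", ext,
                       "'; pass format explicitly"))
  }
}

sibling_path <- function(mtx_path, candidates) {
  dir <- dirname(mtx_path)
  for (f in candidates) {
    p <- file.path(dir, f)
    if (file.exists(p)) return(p)
  }
  NULL
}

#' Read a feature-by-cell count matrix
#'
#' Reads either a MatrixMarket `.mtx` file with sibling `features.tsv` (or
#' `genes.tsv`) and `barcodes.tsv` files in the same directory (the
#' CellRanger convention: features in rows, cells in columns, 1-based
#' indices), or a dense CSV whose first column holds feature ids and whose
#' header row holds barcodes.
#'
#' @param path Path to the `.mtx` or `.csv` file.
#' @param format `"auto"` (guess from extension), `"mtx"`, or `"csv"`.
#' @return A validated feature-by-cell matrix: `dgCMatrix` for mtx input
#'   (sparsity preserved), base matrix for csv.
#' @export
read_expression_matrix <- function(path, format = c("auto", "mtx", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_format(paste0("file not found: ", path))
  if (format == "auto") format <- guess_format(path)
  if (format == "mtx") {
    feat_path <- sibling_path(path, c("features.tsv", "genes.tsv", "features.txt"))
    bc_path <- sibling_path(path, c("barcodes.tsv", "barcodes.txt"))
    if (is.null(feat_path) || is.null(bc_path)) {
      stop_format(paste0("mtx input needs sibling features.tsv and barcodes.tsv next to ", path))
    }
    m <- to_dgc(readMM(path))
    feats <- read.delim(feat_path, header = FALSE, stringsAsFactors = FALSE)[[1]]
    bcs <- read.delim(bc_path, header = FALSE, stringsAsFactors = FALSE)[[1]]
    if (length(feats) != nrow(m) || length(bcs) != ncol(m)) {
      stop_format(sprintf(
        "matrix is %d x %d but features.tsv has %d rows and barcodes.tsv %d",
        nrow(m), ncol(m), length(feats), length(bcs)))
    }
    dimnames(m) <- list(feats, bcs)
  } else {
    df <- read.csv(path, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
    if (ncol(df) < 2) stop_format("csv matrix needs a feature-id column plus at least one cell")
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- as.character(df[[1]])
  }
  validate_expression_matrix(m)
  m
}

#' Write a feature-by-cell matrix
#'
#' Inverse of [read_expression_matrix()]. For `format = "mtx"` writes the
#' matrix plus sibling `features.tsv`/`barcodes.tsv` next to `path`.
#'
#' @param mat Feature-by-cell matrix with dimnames.
#' @param path Output `.mtx` or `.csv` path.
#' @param format `"auto"`, `"mtx"`, or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(mat, path, format = c("auto", "mtx", "csv")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  validate_expression_matrix(mat)
  if (format == "mtx") {
    writeMM(to_dgc(mat), path)
    dir <- dirname(path)
    writeLines(rownames(mat), file.path(dir, "features.tsv"))
    writeLines(colnames(mat), file.path(dir, "barcodes.tsv"))
  } else {
    df <- data.frame(feature = rownames(mat), as.matrix(mat),
                     check.names = FALSE, stringsAsFactors = FALSE)
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Coerce and validate a cell annotation table
#'
#' @param x A data frame whose first two columns are barcode and cluster
#'   label (or named `barcode`/`cluster`).
#' @return A tibble with character columns `barcode` and `cluster`.
#' @export
as_cell_annotation <- function(x) {
  if (!is.data.frame(x)) stop_validation("annotation must be a data frame")
  if (all(c("barcode", "cluster") %in% names(x))) {
    out <- tibble(barcode = as.character(x$barcode),
                  cluster = as.character(x$cluster))
  } else if (ncol(x) >= 2) {
    out <- tibble(barcode = as.character(x[[1]]), cluster = as.character(x[[2]]))
  } else {
    stop_validation("annotation needs two columns: barcode, cluster")
  }
  if (nrow(out) == 0) stop_validation("annotation is empty")
  dup <- out$barcode[duplicated(out$barcode)]
  if (length(dup)) {
    stop_validation(paste0("duplicate barcode in annotation: ", dup[1]))
  }
  out
}

#' Read a cell annotation table
#'
#' Two-column TSV/CSV (barcode, cluster label), with or without a header
#' row. Cluster labels are opaque strings; no case or whitespace
#' normalization is applied.
#'
#' @param path Path to the annotation file; delimiter guessed from the
#'   extension (`.tsv`/`.txt` tab, otherwise comma).
#' @return A tibble with columns `barcode`, `cluster`.
#' @export
read_cell_annotation <- function(path) {
  if (!file.exists(path)) stop_format(paste0("file not found: ", path))
  sep <- if (tolower(tools::file_ext(path)) %in% c("tsv", "txt")) "\t" else ","
  df <- tryCatch(
    read.delim(path, header = FALSE, sep = sep, stringsAsFactors = FALSE),
    error = function(e) stop_format(paste0("cannot parse annotation file: ", conditionMessage(e))))
  if (nrow(df) == 0) stop_format("annotation file is empty")
  # drop an optional header row
  if (tolower(df[1, 1]) %in% c("barcode", "cell", "cell_id") ||
      tolower(df[1, 2]) %in% c("cluster", "label", "cell_type")) {
    df <- df[-1, , drop = FALSE]
    if (nrow(df) == 0) stop_format("annotation file has a header but no rows")
  }
  as_cell_annotation(df)
}

#' Write a cell annotation table as TSV
#'
#' @param annotation Data frame with `barcode` and `cluster` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cell_annotation <- function(annotation, path) {
  ann <- as_cell_annotation(annotation)
  readr::write_tsv(ann, path, col_names = TRUE)
  invisible(path)
}

#' Read a cell-cell transition graph
#'
#' Reads a square MatrixMarket matrix of non-negative edge weights, rows
#' indexing source cells and columns target cells, in the barcode order
#' given. Typically produced by an RNA-velocity tool; a transposed
#' (target-by-source) matrix is the caller's responsibility to flip.
#'
#' @param path Path to the square `.mtx` file.
#' @param barcodes Character vector of barcodes defining row/column order.
#' @return A `dgCMatrix` with `dimnames` set to `barcodes`.
#' @export
read_transition_graph <- function(path, barcodes) {
  if (!file.exists(path)) stop_format(paste0("file not found: ", path))
  m <- to_dgc(readMM(path))
  if (nrow(m) != ncol(m)) {
    stop_format(sprintf("transition graph must be square, got %d x %d", nrow(m), ncol(m)))
  }
  if (nrow(m) != length(barcodes)) {
    stop_format(sprintf("transition graph dimension %d does not match %d barcodes",
                        nrow(m), length(barcodes)))
  }
  if (length(m@x) && (anyNA(m@x) || any(!is.finite(m@x)))) {
    stop_validation("transition graph contains NA or non-finite weights")
  }
  if (length(m@x) && min(m@x) < 0) {
    stop_validation("transition graph contains negative weights")
  }
  dimnames(m) <- list(barcodes, barcodes)
  m
}

#' Write a transition graph as MatrixMarket
#'
#' @param graph Square non-negative sparse matrix.
#' @param path Output `.mtx` path.
#' @return `path`, invisibly.
#' @export
write_transition_graph <- function(graph, path) {
  writeMM(to_dgc(graph), path)
  invisible(path)
}

#' Align matrix, annotation, and transition graph to shared barcodes
#'
#' Restricts all inputs to the intersection of their barcodes, in the order
#' the cells appear in the expression matrix, and reports how many cells
#' each side lost. Upstream velocity tools routinely filter cells, so an
#' intersection (not strict equality) is taken. Idempotent.
#'
#' @param counts Feature-by-cell matrix with barcode colnames.
#' @param annotation Data frame with `barcode`, `cluster`.
#' @param graph Optional square transition matrix with barcode dimnames.
#' @return A list with elements `counts`, `annotation`, and `graph` (NULL if
#'   not supplied), all over the same cells in the same order.
#' @export
align_cells <- function(counts, annotation, graph = NULL) {
  validate_expression_matrix(counts)
  ann <- as_cell_annotation(annotation)
  keep <- colnames(counts)[colnames(counts) %in% ann$barcode]
  if (!is.null(graph)) {
    if (is.null(rownames(graph))) {
      stop_validation("transition graph must carry barcode dimnames for alignment")
    }
    keep <- keep[keep %in% rownames(graph)]
  }
  if (length(keep) == 0) stop_validation("no barcodes shared between inputs")
  dropped_mat <- ncol(counts) - length(keep)
  dropped_ann <- nrow(ann) - length(keep)
  if (dropped_mat > 0 || dropped_ann > 0) {
    inform(sprintf("align_cells: dropped %d cell(s) from matrix, %d from annotation%s",
                   dropped_mat, dropped_ann,
                   if (is.null(graph)) "" else
                     sprintf(", %d from graph", nrow(graph) - length(keep))))
  }
  ann <- ann[match(keep, ann$barcode), , drop = FALSE]
  out_graph <- if (is.null(graph)) NULL else graph[keep, keep, drop = FALSE]
  list(counts = counts[, keep, drop = FALSE], annotation = ann, graph = out_graph)
}
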