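#' Construct a validated expression matrix
#'
#' Wraps a nonnegative gene-by-sample (or, in SC4A orientation,
#' cell-by-gene) abundance table. Values may be raw counts or floored log2
#' intensities; correspondence analysis only requires that they admit a
#' nonnegative abundance interpretation. Rows and columns that sum to zero
#' carry no mass and are dropped with a warning, since the chi-square
#' standardization divides by row and column masses.
#'
#' @param values numeric matrix with unique rownames and colnames.
#' @param orientation `"genes_by_samples"` (conventional CCA) or
#'   `"cells_by_genes"` (SC4A: cells are rows, genes are columns).
#' @param drop_empty drop all-zero rows/columns instead of erroring.
#' @return an object of class `expr_mat`: a list with elements `values`
#'   (the validated matrix), `orientation`, `row_ids` and `col_ids`.
#' @examples
#' m <- matrix(c(1, 0, 4, 2, 3, 0), 3, 2,
#'             dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' x <- expression_matrix(m)
#' dim(x$values)
#' @export
expression_matrix <- function(values,
                              orientation = c("genes_by_samples",
                                              "cells_by_genes"),
                              drop_empty = TRUE) {
  orientation <- match.arg(orientation)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)))
    rownames(values) <- paste0("row", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("col", seq_len(ncol(values)))
  if (anyDuplicated(rownames(values)))
    stop("duplicate row identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate column identifiers: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (anyNA(values)) stop("expression values must not contain NA")
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    stop(sprintf("negative value %.6g at row '%s', column '%s'",
                 values[neg[1, 1], neg[1, 2]],
                 rownames(values)[neg[1, 1]],
                 colnames(values)[neg[1, 2]]))
  }
  zr <- rowSums(values) == 0
  zc <- colSums(values) == 0
  if (any(zr) || any(zc)) {
    if (!drop_empty)
      stop("matrix has all-zero rows/columns and drop_empty = FALSE")
    if (any(zr) && any(zc)) {
      # iterate: dropping rows can zero further columns and vice versa
      repeat {
        zr <- rowSums(values) == 0
        values <- values[!zr, , drop = FALSE]
        zc <- colSums(values) == 0
        values <- values[, !zc, drop = FALSE]
        if (!any(zr) && !any(zc)) break
      }
    } else {
      values <- values[!zr, !zc, drop = FALSE]
    }
    warning(sprintf("dropped %d all-zero row(s) and %d all-zero column(s)",
                    sum(zr), sum(zc)), call. = FALSE)
  }
  if (nrow(values) == 0 || ncol(values) == 0)
    stop("expression matrix is empty after dropping all-zero rows/columns")
  structure(list(values = values,
                 orientation = orientation,
                 row_ids = rownames(values),
                 col_ids = colnames(values)),
            class = "expr_mat")
}

#' @exportS3Method print expr_mat
print.expr_mat <- function(x, ...) {
  cat(sprintf("<expr_mat> %d x %d (%s), grand total %.6g\n",
              nrow(x$values), ncol(x$values), x$orientation,
              sum(x$values)))
  invisible(x)
}

#' @exportS3Method dim expr_mat
dim.expr_mat <- function(x) dim(x$values)

as_expr_values <- function(x) {
  if (inherits(x, "expr_mat")) x$values else as.matrix(x)
}

#' Read an expression matrix from disk
#'
#' TSV tables carry sample ids in the header and gene ids in the first
#' column. MatrixMarket triplet files (`.mtx`, 1-based coordinates) must be
#' accompanied by plain-text row and column name files, one identifier per
#' line.
#'
#' @param path file path (TSV/CSV table or `.mtx` file).
#' @param format `"tsv"` or `"mtx"`; guessed from the extension by default.
#' @param rows_file,cols_file sidecar name files for `mtx` input; default
#'   `<path>.rows.txt` / `<path>.cols.txt`.
#' @param sep field separator for tabular input (`"\t"`; use `","` for CSV).
#' @inheritParams expression_matrix
#' @return validated [expression_matrix()].
#' @export
read_expression <- function(path, format = c("auto", "tsv", "mtx"),
                            rows_file = NULL, cols_file = NULL, sep = "\t",
                            orientation = "genes_by_samples") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "tsv"
  if (format == "tsv") {
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             row.names = 1, check.names = FALSE,
                             quote = "", comment.char = "")
    values <- as.matrix(tab)
  } else {
    if (is.null(rows_file)) rows_file <- paste0(path, ".rows.txt")
    if (is.null(cols_file)) cols_file <- paste0(path, ".cols.txt")
    if (!file.exists(rows_file) || !file.exists(cols_file))
      stop("mtx input needs row/column name sidecars: ",
           rows_file, ", ", cols_file)
    values <- as.matrix(Matrix::readMM(path))
    rownames(values) <- readLines(rows_file)
    colnames(values) <- readLines(cols_file)
  }
  expression_matrix(values, orientation = orientation)
}

#' Write an expression matrix
#'
#' TSV output keeps full double precision (17 significant digits) so that a
#' write/read round trip reproduces the values exactly.
#'
#' @param x an [expression_matrix()] or plain matrix.
#' @param path output path.
#' @param format `"tsv"` or `"mtx"` (the latter writes name sidecars).
#' @param sep field separator for tabular output.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, format = c("tsv", "mtx"), sep = "\t") {
  format <- match.arg(format)
  values <- as_expr_values(x)
  if (format == "tsv") {
    txt <- apply(values, 1:2, function(v) sprintf("%.17g", v))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(c("gene", colnames(values)), collapse = sep), con)
    writeLines(paste(rownames(values),
                     apply(txt, 1, paste, collapse = sep), sep = sep), con)
  } else {
    Matrix::writeMM(Matrix::Matrix(values, sparse = TRUE), path)
    writeLines(rownames(values), paste0(path, ".rows.txt"))
    writeLines(colnames(values), paste0(path, ".cols.txt"))
  }
  invisible(path)
}

#' Floor log-scale intensities
#'
#' Log2 microarray intensities below the floor are treated as absence of
#' signal and set to zero, so that the table keeps a nonnegative abundance
#' interpretation; genes (or samples) left all-zero are then dropped. The
#' default floor log2(10) reflects the common practice of discarding
#' intensities below 10 on the raw scale. The floor is applied per entry;
#' an alternative reading (excluding genes whose maximum is below the
#' floor) is available via [filter_genes_sc()]-style max filtering.
#'
#' @param x [expression_matrix()] of log2 intensities.
#' @param floor nonnegative threshold, default `log2(10)`.
#' @return floored, revalidated [expression_matrix()].
#' @export
floor_log_intensities <- function(x, floor = log2(10)) {
  stopifnot(inherits(x, "expr_mat"), floor >= 0)
  v <- x$values
  v[v < floor] <- 0
  expression_matrix(v, orientation = x$orientation)
}

#' Row and column masses of an abundance table
#'
#' Computes the mass structure of correspondence analysis: row masses
#' r_i = row sum / n, column masses c_j = column sum / n, and the grand
#' total n. The diagonal weighting operators D_r and D_c are represented
#' by the vectors themselves.
#'
#' @param x [expression_matrix()] or nonnegative matrix.
#' @return list of class `cca_masses` with elements `r`, `c`, `n`.
#' @examples
#' compute_masses(expression_matrix(
#'   matrix(c(1, 3, 2, 4), 2, 2, dimnames = list(c("a", "b"), c("s", "t")))))
#' @export
compute_masses <- function(x) {
  v <- as_expr_values(x)
  n <- sum(v)
  if (n <= 0) stop("grand total of the matrix is zero")
  structure(list(r = rowSums(v) / n, c = colSums(v) / n, n = n),
            class = "cca_masses")
}

#' Gene sets
#'
#' Lightweight named carrier for a set of gene identifiers.
#'
#' @param name label for the set.
#' @param members character vector of gene ids (deduplicated, nonempty).
#' @return list of class `gene_set` with `name` and `members`.
#' @export
gene_set <- function(name, members) {
  members <- unique(as.character(members))
  if (length(members) == 0) stop("gene set '", name, "' is empty")
  structure(list(name = name, members = members), class = "gene_set")
}

#' @exportS3Method print gene_set
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d genes\n", x$name, length(x$members)))
  invisible(x)
}

#' Read a gene list (one symbol per line; blank lines and '#' comments
#' ignored)
#'
#' @param path text file path.
#' @param name set label; defaults to the file name.
#' @return a [gene_set()].
#' @export
read_gene_list <- function(path, name = basename(path)) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  gene_set(name, lines)
}
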