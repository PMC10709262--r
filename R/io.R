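# Readers/writers for the formats the pipeline touches: Matrix Market MTX
# with side-car gene/cell label files, dense CSV, GMT genesets, RNK lists.

#' Construct a validated count matrix
#'
#' @param counts numeric matrix (genes x cells) of non-negative integers,
#'   or a sparse `Matrix`.
#' @param genes,cells character identifiers; taken from dimnames when `NULL`.
#' @return a base integer-valued matrix with gene rownames and cell colnames.
#' @export
count_matrix <- function(counts, genes = NULL, cells = NULL) {
  counts <- as.matrix(counts)
  if (is.null(genes)) genes <- rownames(counts)
  if (is.null(cells)) cells <- colnames(counts)
  if (is.null(genes) || is.null(cells)) {
    stop("gene and cell identifiers are required", call. = FALSE)
  }
  genes <- as.character(genes); cells <- as.character(cells)
  if (length(genes) != nrow(counts) || length(cells) != ncol(counts)) {
    stop("identifier lengths do not match matrix dimensions", call. = FALSE)
  }
  if (anyDuplicated(genes)) stop("duplicate gene identifiers", call. = FALSE)
  if (anyDuplicated(cells)) stop("duplicate cell identifiers", call. = FALSE)
  if (any(counts < 0)) stop("negative counts are not allowed", call. = FALSE)
  dimnames(counts) <- list(genes, cells)
  counts
}

validate_expression <- function(m) {
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("gene and cell identifiers are required", call. = FALSE)
  }
  if (anyDuplicated(rownames(m))) stop("duplicate gene identifiers", call. = FALSE)
  if (anyDuplicated(colnames(m))) stop("duplicate cell identifiers", call. = FALSE)
  if (any(!is.finite(m))) stop("non-finite entries", call. = FALSE)
  m
}

mtx_sidecars <- function(path) {
  prefix <- sub("\\.mtx$", "", path)
  list(genes = paste0(prefix, ".genes.txt"), cells = paste0(prefix, ".cells.txt"))
}

#' Read a gene x cell count matrix
#'
#' Two encodings are supported and produce identical results:
#' * `mtx` — Matrix Market coordinate file (1-based indices per the
#'   standard) with side-car label files `<prefix>.genes.txt` and
#'   `<prefix>.cells.txt`, one identifier per line;
#' * `csv` — dense CSV with a header row of cell identifiers and gene
#'   identifiers in the first column.
#'
#' @param path path to the `.mtx` or `.csv` file.
#' @param format `"auto"` (from extension), `"mtx"` or `"csv"`.
#' @param genes_file,cells_file label files for MTX input; defaults follow
#'   the side-car convention above.
#' @return a count matrix (see [count_matrix()]).
#' @export
read_count_matrix <- function(path, format = c("auto", "mtx", "csv"),
                              genes_file = NULL, cells_file = NULL) {
  read_matrix_impl(path, match.arg(format), genes_file, cells_file,
                   counts = TRUE)
}

#' Read a real-valued expression matrix (log-normalized or residual)
#'
#' Same formats and side-car conventions as [read_count_matrix()], but
#' entries may be negative reals (residuals).
#'
#' @inheritParams read_count_matrix
#' @return numeric matrix with gene rownames and cell colnames.
#' @export
read_expression_matrix <- function(path, format = c("auto", "mtx", "csv"),
                                   genes_file = NULL, cells_file = NULL) {
  read_matrix_impl(path, match.arg(format), genes_file, cells_file,
                   counts = FALSE)
}

read_matrix_impl <- function(path, format, genes_file, cells_file, counts) {
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path)) "mtx" else "csv"
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "mtx") {
    side <- mtx_sidecars(path)
    if (is.null(genes_file)) genes_file <- side$genes
    if (is.null(cells_file)) cells_file <- side$cells
    for (f in c(genes_file, cells_file)) {
      if (!file.exists(f)) stop("label file not found: ", f, call. = FALSE)
    }
    m <- tryCatch(Matrix::readMM(path), error = function(e) {
      stop("parse error in ", path, ": ", conditionMessage(e), call. = FALSE)
    })
    genes <- readLines(genes_file)
    cells <- readLines(cells_file)
    if (nrow(m) != length(genes) || ncol(m) != length(cells)) {
      stop("dimension mismatch: matrix is ", nrow(m), " x ", ncol(m),
           " but labels give ", length(genes), " genes and ",
           length(cells), " cells", call. = FALSE)
    }
    out <- as.matrix(m); dimnames(out) <- list(genes, cells)
  } else {
    df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    genes <- as.character(df[[1]])
    out <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(out) <- "double"
    rownames(out) <- genes
  }
  out <- if (counts) count_matrix(out) else validate_expression(out)
  sc_log("io", "read ", nrow(out), " genes x ", ncol(out), " cells from ", path)
  out
}

#' Write a count (or real-valued expression) matrix
#'
#' @param mat matrix with gene rownames and cell colnames.
#' @param path output path; `.mtx` writes Matrix Market plus side-car label
#'   files, anything else writes dense CSV.
#' @return invisibly, the paths written.
#' @export
write_count_matrix <- function(mat, path) {
  if (grepl("\\.mtx$", path)) {
    side <- mtx_sidecars(path)
    Matrix::writeMM(Matrix::Matrix(mat, sparse = TRUE), path)
    writeLines(rownames(mat), side$genes)
    writeLines(colnames(mat), side$cells)
    invisible(c(path, side$genes, side$cells))
  } else {
    df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
    write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
  }
}

#' Read a GMT geneset file
#'
#' One set per tab-separated line: name, description, member genes.
#' Duplicate members within a line are collapsed; duplicate set names are
#' an error; an empty file yields an empty collection.
#'
#' @param path path to the GMT file.
#' @return named list of character vectors with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list(); desc <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop("GMT parse error at line ", i, ": fewer than 3 fields", call. = FALSE)
    }
    nm <- fields[[1]]
    if (nm %in% names(sets)) {
      stop("GMT parse error at line ", i, ": duplicate set name '", nm, "'",
           call. = FALSE)
    }
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) {
      stop("GMT parse error at line ", i, ": empty set '", nm, "'", call. = FALSE)
    }
    sets[[nm]] <- members
    desc[[nm]] <- fields[[2]]
  }
  attr(sets, "descriptions") <- desc
  sets
}

#' Write a GMT geneset file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional named character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(descriptions) && nm %in% names(descriptions))
      descriptions[[nm]] else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a ranked gene list (RNK)
#'
#' Two-column tab-separated file (gene, score), descending by score — the
#' interchange format preranked enrichment tools accept.
#' @param scores named numeric vector (names are genes).
#' @param path output path.
#' @export
write_rnk <- function(scores, path) {
  ord <- order(scores, decreasing = TRUE)
  writeLines(paste(names(scores)[ord], format(scores[ord], trim = TRUE),
                   sep = "\t"), path)
  invisible(path)
}
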