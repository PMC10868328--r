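#' Read a count matrix from 10x-style MTX or dense TSV/CSV
#'
#' Reads a genes-by-cells count matrix either from a 10x-style Matrix Market
#' directory (`matrix.mtx[.gz]` plus `features.tsv[.gz]` or `genes.tsv[.gz]`
#' and `barcodes.tsv[.gz]`) or from a dense delimited file with a header row
#' of cell ids and a first column of gene ids. Gzipped variants are accepted.
#' Duplicate gene ids are de-duplicated by suffixing (with a warning);
#' dimension mismatches between the matrix and the id files, non-integer
#' entries, and cells with zero total count are errors.
#'
#' @param path Directory (10x) or file (TSV/CSV) path.
#' @param format `"auto"` (directory means 10x, `.csv` means comma-separated,
#'   anything else tab-separated), `"10x"`, `"tsv"` or `"csv"`.
#' @param transpose For dense formats only: set `TRUE` if the file stores
#'   cells as rows and genes as columns.
#' @return A validated `dgCMatrix` (genes x cells).
#' @export
read_counts <- function(path, format = c("auto", "10x", "tsv", "csv"),
                        transpose = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "10x"
              else if (grepl("\\.csv(\\.gz)?$", path)) "csv" else "tsv"
  }
  if (format == "10x") read_counts_10x(path)
  else read_counts_dense(path, sep = if (format == "csv") "," else "\t",
                         transpose = transpose)
}

read_counts_10x <- function(path) {
  if (!dir.exists(path)) stop("10x input must be a directory: ", path, call. = FALSE)
  find1 <- function(names) {
    for (nm in names) {
      f <- file.path(path, nm)
      if (file.exists(f)) return(f)
    }
    stop(sprintf("none of [%s] found in %s", paste(names, collapse = ", "), path),
         call. = FALSE)
  }
  mtx_f <- find1(c("matrix.mtx", "matrix.mtx.gz"))
  feat_f <- find1(c("features.tsv", "features.tsv.gz", "genes.tsv", "genes.tsv.gz"))
  bc_f <- find1(c("barcodes.tsv", "barcodes.tsv.gz"))
  m <- Matrix::readMM(ungzip(mtx_f))
  feats <- read.delim(feat_f, header = FALSE, stringsAsFactors = FALSE)
  barcodes <- readLines(bc_f)
  if (nrow(feats) != nrow(m))
    stop(sprintf("feature file has %d rows but matrix has %d gene rows",
                 nrow(feats), nrow(m)), call. = FALSE)
  if (length(barcodes) != ncol(m))
    stop(sprintf("barcode file has %d lines but matrix has %d cell columns",
                 length(barcodes), ncol(m)), call. = FALSE)
  rownames(m) <- dedup_ids(as.character(feats[[1L]]), "gene")
  colnames(m) <- dedup_ids(barcodes, "cell")
  validate_counts(m)
}

read_counts_dense <- function(path, sep = "\t", transpose = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(ungzip(path), sep = sep, header = TRUE,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("dense count file needs an id column plus >= 1 data column",
                          call. = FALSE)
  ids <- as.character(df[[1L]])
  mat <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- dedup_ids(ids, if (transpose) "cell" else "gene")
  if (transpose) mat <- t(mat)
  validate_counts(mat)
}

# Transparent gz handling: decompress to a tempfile when needed so plain-file
# readers (readMM) work on either variant.
ungzip <- function(path) {
  if (!grepl("\\.gz$", path)) return(path)
  tmp <- tempfile(fileext = sub("\\.gz$", "", basename(path)))
  con <- gzfile(path, "rb")
  on.exit(close(con))
  out <- file(tmp, "wb")
  on.exit(close(out), add = TRUE)
  while (length(chunk <- readBin(con, "raw", 1048576L)) > 0) writeBin(chunk, out)
  tmp
}

dedup_ids <- function(ids, what) {
  if (anyDuplicated(ids)) {
    warning(sprintf("%d duplicate %s id(s) de-duplicated by suffixing",
                    sum(duplicated(ids)), what), call. = FALSE)
    ids <- make.unique(ids, sep = "-")
  }
  ids
}

#' Write size factors to a TSV with an options header
#'
#' Writes a two-column TSV (`cell_id`, `size_factor`, 12 significant digits)
#' preceded by `#` comment lines recording the package version and the
#' options used, so any output is reproducible from its inputs and header.
#'
#' @param result A `sckwarn_norm` object from [sckwarn()], or a named numeric
#'   vector of size factors.
#' @param path Output file path.
#' @param extra Optional named character vector of additional header fields
#'   (e.g. a seed).
#' @return `path`, invisibly.
#' @export
write_size_factors <- function(result, path, extra = NULL) {
  if (inherits(result, "sckwarn_norm")) {
    theta <- result$theta
    opts <- c(cutoff = format(result$options$cutoff),
              rescale = result$options$rescale)
  } else {
    theta <- result
    opts <- NULL
  }
  if (is.null(names(theta))) names(theta) <- paste0("cell", seq_along(theta))
  hdr <- c(sprintf("# sckwarn %s", as.character(utils::packageVersion("sckwarn"))),
           sprintf("# %s: %s", names(opts), opts),
           if (length(extra)) sprintf("# %s: %s", names(extra), extra),
           "cell_id\tsize_factor")
  body <- sprintf("%s\t%.12g", names(theta), theta)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read size factors written by [write_size_factors()]
#'
#' @param path File path.
#' @return Named numeric vector of size factors; header fields are attached
#'   as the `"options"` attribute.
#' @export
read_size_factors <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  df <- read.delim(text = lines[!grepl("^#", lines)], header = TRUE,
                   stringsAsFactors = FALSE)
  structure(stats::setNames(df$size_factor, df$cell_id),
            options = sub("^# ", "", hdr))
}

#' Write a count or normalized matrix
#'
#' `"mtx"` writes a 10x-style directory (`matrix.mtx`, `features.tsv`,
#' `barcodes.tsv`); `"tsv"` writes a dense table with a `gene_id` column and
#' cell-id headers, readable by [read_counts()].
#'
#' @param mat Genes-by-cells matrix (sparse or dense).
#' @param path Output directory (`mtx`) or file (`tsv`).
#' @param format `"mtx"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(mat, path, format = c("mtx", "tsv")) {
  format <- match.arg(format)
  if (format == "mtx") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    sm <- methods::as(methods::as(methods::as(mat, "dMatrix"), "generalMatrix"),
                      "CsparseMatrix")
    Matrix::writeMM(sm, file.path(path, "matrix.mtx"))
    writeLines(rownames(mat) %||% paste0("gene", seq_len(nrow(mat))),
               file.path(path, "features.tsv"))
    writeLines(colnames(mat) %||% paste0("cell", seq_len(ncol(mat))),
               file.path(path, "barcodes.tsv"))
  } else {
    dm <- as.matrix(mat)
    df <- data.frame(gene_id = rownames(mat) %||% paste0("gene", seq_len(nrow(mat))),
                     dm, check.names = FALSE, stringsAsFactors = FALSE)
    colnames(df)[-1L] <- colnames(mat) %||% paste0("cell", seq_len(ncol(mat)))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
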