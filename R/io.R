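#' Read / write MEPM matrices
#'
#' The on-disk format is two tab-separated UTF-8 files: the matrix file has
#' a `sample_id` first column and one column per CpG site (header row of
#' site ids); the companion sample sheet carries the sample metadata
#' columns. Values are written with 12 significant digits, so a
#' write-then-read round trip reproduces the matrix to that precision and
#' the metadata exactly.
#'
#' @param x A `meth_matrix`.
#' @param matrix_path Path of the TSV matrix file.
#' @param sheet_path Path of the TSV sample sheet; defaults to
#'   `<matrix_path minus extension>.samples.tsv`.
#' @param sites Optional site catalog (data frame as returned by
#'   [read_site_catalog()]) to attach on read; must cover every matrix
#'   column.
#' @return `read_mepm_matrix()` returns a `meth_matrix`;
#'   `write_mepm_matrix()` returns the matrix path invisibly.
#' @export
write_mepm_matrix <- function(x, matrix_path,
                              sheet_path = default_sheet_path(matrix_path)) {
  validate_meth_matrix(x)
  df <- data.frame(sample_id = rownames(x$values),
                   format(x$values, digits = 12, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.table(x$samples, sheet_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
  invisible(matrix_path)
}

default_sheet_path <- function(matrix_path) {
  sub("\\.tsv$", "", matrix_path) |> paste0(".samples.tsv")
}

#' @rdname write_mepm_matrix
#' @export
read_mepm_matrix <- function(matrix_path,
                             sheet_path = default_sheet_path(matrix_path),
                             sites = NULL) {
  raw <- utils::read.table(matrix_path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           encoding = "UTF-8")
  if (names(raw)[1] != "sample_id") {
    stop("matrix file must start with a 'sample_id' column", call. = FALSE)
  }
  if (anyDuplicated(raw$sample_id)) {
    stop("duplicate sample_id in matrix file: ",
         raw$sample_id[duplicated(raw$sample_id)][1], call. = FALSE)
  }
  vals <- as.matrix(raw[, -1, drop = FALSE])
  if (anyDuplicated(colnames(vals))) {
    stop("duplicate site_id column in matrix file: ",
         colnames(vals)[duplicated(colnames(vals))][1], call. = FALSE)
  }
  if (!is.numeric(vals)) stop("non-numeric matrix entries", call. = FALSE)
  if (anyNA(vals)) stop("missing values in matrix file", call. = FALSE)
  if (any(vals < 0)) {
    bad <- which(vals < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative value at row '%s', column '%s'",
                 raw$sample_id[bad[1]], colnames(vals)[bad[2]]), call. = FALSE)
  }
  rownames(vals) <- raw$sample_id
  sheet <- utils::read.table(sheet_path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, na.strings = "NA",
                             encoding = "UTF-8")
  sheet$paired_id <- as.character(sheet$paired_id)
  sheet$stage <- as.character(sheet$stage)
  if (!setequal(sheet$sample_id, rownames(vals)) ||
      nrow(sheet) != nrow(vals)) {
    stop("sample sheet and matrix file disagree on samples", call. = FALSE)
  }
  sheet <- sheet[match(rownames(vals), sheet$sample_id), , drop = FALSE]
  rownames(sheet) <- NULL
  if (!is.null(sites)) {
    miss <- setdiff(colnames(vals), sites$site_id)
    if (length(miss)) {
      stop("site catalog lacks matrix column(s): ",
           paste(utils::head(miss, 3), collapse = ", "), call. = FALSE)
    }
    sites <- sites[match(colnames(vals), sites$site_id), , drop = FALSE]
    rownames(sites) <- NULL
  }
  meth_matrix(vals, sheet, sites)
}

#' Read / write a CpG-site catalog
#'
#' Six-column BED-like TSV: `chrom`, `start`, `end` (0-based half-open),
#' `site_id`, `motif_distance_bp` (distance in bp to the nearest CGCGCGG
#' motif), `gene_label`. Order of rows is preserved.
#'
#' @param path File path.
#' @param catalog Data frame with the six columns above.
#' @return `read_site_catalog()` returns the validated catalog data frame
#'   (columns reordered as `site_id`, `chrom`, `start`, `end`,
#'   `motif_distance_bp`, `gene_label`); an empty file yields a zero-row
#'   catalog.
#' @export
read_site_catalog <- function(path) {
  cols <- c("chrom", "start", "end", "site_id", "motif_distance_bp",
            "gene_label")
  if (file.size(path) == 0) {
    cat0 <- data.frame(site_id = character(), chrom = character(),
                       start = integer(), end = integer(),
                       motif_distance_bp = integer(),
                       gene_label = character(), stringsAsFactors = FALSE)
    return(cat0)
  }
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, col.names = cols)
  validate_site_catalog(df[, c("site_id", "chrom", "start", "end",
                               "motif_distance_bp", "gene_label")])
}

validate_site_catalog <- function(df) {
  if (any(df$start >= df$end)) {
    bad <- df$site_id[df$start >= df$end][1]
    stop("site with start >= end: ", bad, call. = FALSE)
  }
  if (any(df$motif_distance_bp < 0)) {
    stop("negative motif_distance_bp", call. = FALSE)
  }
  if (anyDuplicated(df$site_id)) {
    stop("duplicate site_id: ", df$site_id[duplicated(df$site_id)][1],
         call. = FALSE)
  }
  rownames(df) <- NULL
  df
}

#' @rdname read_site_catalog
#' @export
write_site_catalog <- function(catalog, path) {
  validate_site_catalog(catalog)
  utils::write.table(catalog[, c("chrom", "start", "end", "site_id",
                                 "motif_distance_bp", "gene_label")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
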