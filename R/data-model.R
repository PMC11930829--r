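#' Construct a methylation matrix object
#'
#' A `meth_matrix` bundles a samples-by-sites grid of MEPM values
#' (methylated alleles per million mapped molecules) with a sample sheet and
#' a CpG-site catalog. MEPM values are non-negative by construction; an
#' absent methylation signal is a true zero, not a missing value.
#'
#' @param values Numeric matrix, samples in rows, CpG sites in columns.
#'   Row names are sample ids, column names site ids (supplied from
#'   `samples`/`sites` when missing).
#' @param samples Data frame with one row per sample. Required columns:
#'   `sample_id`, `specimen` (`"tissue"` or `"plasma"`), `condition`
#'   (`"PAC"`, `"HCC"`, `"CRC"`, `"GC"` or `"normal"`), `stage`
#'   (`"I"`--`"IV"` for cancer samples, `NA` otherwise), `paired_id`
#'   (adjacent-tissue partner or `NA`) and `total_molecules`.
#' @param sites Optional data frame describing the CpG sites (see
#'   [read_site_catalog()]). When `NULL` a minimal catalog holding only the
#'   site ids is created.
#'
#' @return An object of class `meth_matrix` with elements `values`,
#'   `samples` and `sites`.
#' @export
meth_matrix <- function(values, samples, sites = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.null(dimnames(values))) {
    dimnames(values) <- lapply(dimnames(values), unname)
  }
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (is.null(rownames(values))) rownames(values) <- samples$sample_id
  if (is.null(sites)) {
    if (is.null(colnames(values))) {
      stop("`sites` is NULL and `values` has no column names", call. = FALSE)
    }
    sites <- data.frame(site_id = colnames(values), stringsAsFactors = FALSE)
  }
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  if (is.null(colnames(values))) colnames(values) <- sites$site_id
  x <- structure(list(values = values, samples = samples, sites = sites),
                 class = "meth_matrix")
  validate_meth_matrix(x)
  x
}

validate_meth_matrix <- function(x) {
  stopifnot(inherits(x, "meth_matrix"))
  v <- x$values
  if (anyNA(v)) stop("methylation matrix contains missing values", call. = FALSE)
  if (any(v < 0)) {
    bad <- which(v < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative MEPM value at sample '%s', site '%s'",
                 rownames(v)[bad[1]], colnames(v)[bad[2]]), call. = FALSE)
  }
  if (nrow(v) != nrow(x$samples)) {
    stop("number of matrix rows does not match the sample sheet", call. = FALSE)
  }
  if (ncol(v) != nrow(x$sites)) {
    stop("number of matrix columns does not match the site catalog", call. = FALSE)
  }
  validate_sample_sheet(x$samples)
  if (anyDuplicated(x$sites$site_id)) {
    stop("duplicate site_id in site catalog", call. = FALSE)
  }
  if (!identical(rownames(v), x$samples$sample_id)) {
    stop("matrix row names do not match sample sheet sample_id order", call. = FALSE)
  }
  if (!identical(colnames(v), x$sites$site_id)) {
    stop("matrix column names do not match site catalog order", call. = FALSE)
  }
  invisible(x)
}

validate_sample_sheet <- function(s) {
  need <- c("sample_id", "specimen", "condition", "stage", "paired_id",
            "total_molecules")
  miss <- setdiff(need, names(s))
  if (length(miss)) {
    stop("sample sheet lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(s$sample_id)) stop("duplicate sample_id", call. = FALSE)
  if (!all(s$specimen %in% c("tissue", "plasma"))) {
    stop("specimen must be 'tissue' or 'plasma'", call. = FALSE)
  }
  if (!all(s$condition %in% c(cancer_types(), "normal"))) {
    stop("condition must be one of ", paste(cancer_types(), collapse = "/"),
         " or 'normal'", call. = FALSE)
  }
  if (any(!is.na(s$stage) & !s$stage %in% c("I", "II", "III", "IV"))) {
    stop("stage must be I/II/III/IV or NA", call. = FALSE)
  }
  if (any(s$condition == "normal" & !is.na(s$stage))) {
    stop("stage must be NA for normal samples", call. = FALSE)
  }
  pid <- s$paired_id[!is.na(s$paired_id)]
  if (length(pid) && !all(pid %in% s$sample_id)) {
    stop("paired_id refers to an unknown sample", call. = FALSE)
  }
  if (any(s$total_molecules < 0)) stop("negative total_molecules", call. = FALSE)
  invisible(s)
}

#' The cancer types handled by the typing system
#' @return Character vector `c("PAC", "HCC", "CRC", "GC")`.
#' @export
cancer_types <- function() c("PAC", "HCC", "CRC", "GC")

#' @export
print.meth_matrix <- function(x, ...) {
  cat(sprintf("meth_matrix: %d samples x %d CpG sites\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(x$samples$specimen, x$samples$condition)
  print(tab)
  invisible(x)
}

#' @export
dim.meth_matrix <- function(x) dim(x$values)

#' Subset a methylation matrix by sample id or site id
#'
#' @param x A `meth_matrix`.
#' @param sample_ids,site_ids Character vectors of ids to keep (in the given
#'   order); `NULL` keeps everything.
#' @return A `meth_matrix` restricted to the requested samples/sites.
#' @export
mm_subset <- function(x, sample_ids = NULL, site_ids = NULL) {
  validate_meth_matrix(x)
  if (is.null(sample_ids)) sample_ids <- x$samples$sample_id
  if (is.null(site_ids)) site_ids <- x$sites$site_id
  miss <- setdiff(sample_ids, x$samples$sample_id)
  if (length(miss)) stop("unknown sample id(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  miss <- setdiff(site_ids, x$sites$site_id)
  if (length(miss)) stop("unknown site id(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  samples <- x$samples[match(sample_ids, x$samples$sample_id), , drop = FALSE]
  samples$paired_id[!samples$paired_id %in% sample_ids] <- NA_character_
  rownames(samples) <- NULL
  sites <- x$sites[match(site_ids, x$sites$site_id), , drop = FALSE]
  rownames(sites) <- NULL
  meth_matrix(x$values[sample_ids, site_ids, drop = FALSE], samples, sites)
}

#' Extract the MEPM values of one sample as a named vector
#'
#' @param x A `meth_matrix`.
#' @param sample_id A sample id present in `x`.
#' @return Named numeric vector of MEPM values, names are site ids.
#' @export
sample_values <- function(x, sample_id) {
  if (!sample_id %in% rownames(x$values)) {
    stop("unknown sample id: ", sample_id, call. = FALSE)
  }
  x$values[sample_id, ]
}

#' Methylated alleles per million mapped molecules
#'
#' Normalizes a methylated-molecule count by the sample's total molecular
#' count, on the scale of methylated alleles per million (MEPM).
#'
#' @param methylated_count Non-negative count(s) of fully methylated
#'   molecules at a site.
#' @param total_molecules Positive total molecular count(s) of the sample.
#' @return `methylated_count / total_molecules * 1e6`.
#' @examples
#' compute_mepm(5, 5e5)  # 10 MEPM
#' @export
compute_mepm <- function(methylated_count, total_molecules) {
  if (any(total_molecules <= 0)) {
    stop("total_molecules must be positive", call. = FALSE)
  }
  if (any(methylated_count < 0)) {
    stop("methylated_count must be non-negative", call. = FALSE)
  }
  methylated_count / total_molecules * 1e6
}

#' Exclude samples with too few molecules
#'
#' Samples whose total molecular count falls below `min_molecules` are
#' removed; the boundary value itself is retained (the rule is a strict
#' less-than).
#'
#' @param x A `meth_matrix`.
#' @param min_molecules Minimum acceptable total molecular count
#'   (default 10000).
#' @return List with elements `matrix` (the filtered `meth_matrix`) and
#'   `excluded` (character vector of removed sample ids).
#' @export
qc_filter_samples <- function(x, min_molecules = 10000) {
  validate_meth_matrix(x)
  keep <- x$samples$total_molecules >= min_molecules
  if (!any(keep)) stop("all samples excluded by QC filter", call. = FALSE)
  list(matrix = mm_subset(x, sample_ids = x$samples$sample_id[keep]),
       excluded = x$samples$sample_id[!keep])
}

#' Randomly partition a cohort into discovery and validation sets
#'
#' Splits the samples into two groups at the requested ratio, stratified so
#' that each level of `stratify_by` is divided at the same proportion
#' (discovery size per stratum is `round(p * n)` with
#' `p = ratio[1]/sum(ratio)`). With the default 6:4 ratio, 50 cases and 52
#' controls yield a 30 + 31 discovery set and a 20 + 21 validation set.
#'
#' @param samples Sample sheet data frame (see [meth_matrix()]).
#' @param ratio Length-2 numeric, discovery:validation proportions
#'   (default `c(6, 4)`).
#' @param stratify_by Sample-sheet column to stratify on
#'   (default `"condition"`).
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return List with character vectors `discovery_ids` and `validation_ids`;
#'   together they partition the input.
#' @export
split_cohort <- function(samples, ratio = c(6, 4), stratify_by = "condition",
                         seed) {
  stopifnot(length(ratio) == 2, all(ratio > 0))
  if (!stratify_by %in% names(samples)) {
    stop("unknown stratification column: ", stratify_by, call. = FALSE)
  }
  strata <- split(samples$sample_id, samples[[stratify_by]], drop = TRUE)
  if (any(lengths(strata) < 2)) {
    stop("each stratum needs at least 2 samples", call. = FALSE)
  }
  p <- ratio[1] / sum(ratio)
  disc <- with_seed(seed, {
    unlist(lapply(strata, function(ids) {
      sample(ids, size = round(p * length(ids)))
    }), use.names = FALSE)
  })
  list(discovery_ids = samples$sample_id[samples$sample_id %in% disc],
       validation_ids = samples$sample_id[!samples$sample_id %in% disc])
}

# Run code under a temporary RNG state so callers' streams are untouched.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  code
}
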