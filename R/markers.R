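#' Marker selection criteria
#'
#' The four tumor-vs-normal criteria: (1) differential hypermethylation in
#' tumor tissue at `p < p_max`; (2) site closer than `motif_max_bp` to the
#' nearest CGCGCGG motif (strict); (3) mean tumor-tissue MEPM at least
#' `min_mepm`; (4) background positivity frequency in normal plasma
#' strictly below `max_normal_freq`. Cross-cancer selection replaces the
#' motif criterion with a fold-change filter (`fc_min`) and lowers the
#' MEPM floor to 5.
#'
#' @param p_max Tissue differential-methylation p-value ceiling
#'   (default 0.01, strict).
#' @param motif_max_bp Maximum motif distance in bp (default 60, strict).
#' @param min_mepm Minimum mean tumor-tissue MEPM (default 10; use 5 for
#'   cross-cancer panels).
#' @param max_normal_freq Maximum normal-plasma positivity frequency
#'   (default 0.05, strict).
#' @param fc_min Minimum tumor-vs-tumor fold change for cross-cancer
#'   selection (default 2, strict).
#' @param positivity_threshold MEPM value a site must strictly exceed to
#'   count as positive (default 0: any signal).
#' @return List of class `selection_criteria`.
#' @export
selection_criteria <- function(p_max = 0.01, motif_max_bp = 60,
                               min_mepm = 10, max_normal_freq = 0.05,
                               fc_min = 2, positivity_threshold = 0) {
  stopifnot(p_max > 0, motif_max_bp > 0, min_mepm > 0,
            max_normal_freq > 0, max_normal_freq <= 1, fc_min > 0,
            positivity_threshold >= 0)
  structure(list(p_max = p_max, motif_max_bp = motif_max_bp,
                 min_mepm = min_mepm, max_normal_freq = max_normal_freq,
                 fc_min = fc_min,
                 positivity_threshold = positivity_threshold),
            class = "selection_criteria")
}

#' Background positivity frequency in normal plasma
#'
#' Fraction of samples whose MEPM value strictly exceeds the positivity
#' threshold at each requested site. The matrix should be restricted to
#' normal plasma samples.
#'
#' @param x A `meth_matrix` of normal plasma samples.
#' @param site_ids Site ids to evaluate (default: all sites in `x`).
#' @param positivity_threshold MEPM positivity threshold (default 0).
#' @return Named numeric vector of frequencies in `[0, 1]`.
#' @export
background_frequency <- function(x, site_ids = x$sites$site_id,
                                 positivity_threshold = 0) {
  validate_meth_matrix(x)
  if (nrow(x$values) == 0) stop("no normal plasma samples", call. = FALSE)
  miss <- setdiff(site_ids, colnames(x$values))
  if (length(miss)) stop("unknown site id(s): ",
                         paste(utils::head(miss, 3), collapse = ", "),
                         call. = FALSE)
  colMeans(x$values[, site_ids, drop = FALSE] > positivity_threshold)
}

#' Construct a marker panel
#'
#' @param cancer Cancer type the panel detects.
#' @param marker_ids Ordered, unique site ids.
#' @param thresholds Per-marker MEPM positivity thresholds; a scalar is
#'   recycled (default 0).
#' @param count_cutoff Panel-level positive-count cutoff (strict `>`);
#'   `NA` until calibrated with [calibrate_count_cutoff()].
#' @param stats Optional data frame of per-marker selection statistics.
#' @return List of class `marker_panel`.
#' @export
marker_panel <- function(cancer, marker_ids, thresholds = 0,
                         count_cutoff = NA_integer_, stats = NULL) {
  stopifnot(cancer %in% cancer_types(), !anyDuplicated(marker_ids))
  thresholds <- rep_len(thresholds, length(marker_ids))
  names(thresholds) <- marker_ids
  if (!is.na(count_cutoff) && count_cutoff >= length(marker_ids)) {
    stop("count_cutoff must be smaller than the panel size", call. = FALSE)
  }
  structure(list(cancer = cancer, marker_ids = marker_ids,
                 thresholds = thresholds,
                 count_cutoff = as.integer(count_cutoff), stats = stats),
            class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat(sprintf("marker_panel: %s, %d markers, count cutoff %s\n",
              x$cancer, length(x$marker_ids),
              ifelse(is.na(x$count_cutoff), "unset", x$count_cutoff)))
  invisible(x)
}

#' Select tumor-specific methylation markers (four-criteria rule)
#'
#' A site enters the panel iff it satisfies all four criteria of
#' [selection_criteria()]: hypermethylated in tumor vs adjacent tissue at
#' `p < p_max` (two-tailed Mann-Whitney), closer than `motif_max_bp` to a
#' CGCGCGG motif, mean tumor-tissue MEPM of at least `min_mepm`, and
#' normal-plasma background frequency under `max_normal_freq`. The panel
#' is ordered by ascending tissue p-value.
#'
#' @param tissue_matrix `meth_matrix` with tumor (condition = cancer type)
#'   and adjacent (condition `"normal"`) tissue samples.
#' @param plasma_matrix `meth_matrix` containing normal plasma samples
#'   (any non-normal samples are ignored).
#' @param catalog Site catalog covering every site of `tissue_matrix`.
#' @param criteria A [selection_criteria()].
#' @return A [marker_panel()] with per-site statistics attached
#'   (`$stats`).
#' @export
select_cancer_markers <- function(tissue_matrix, plasma_matrix, catalog,
                                  criteria = selection_criteria()) {
  validate_meth_matrix(tissue_matrix)
  validate_meth_matrix(plasma_matrix)
  site_ids <- tissue_matrix$sites$site_id
  miss <- setdiff(site_ids, catalog$site_id)
  if (length(miss)) {
    stop("catalog lacks site(s): ",
         paste(utils::head(miss, 3), collapse = ", "), call. = FALSE)
  }
  cond <- tissue_matrix$samples$condition
  cancer <- setdiff(unique(cond), "normal")
  if (length(cancer) != 1) {
    stop("tissue matrix must contain exactly one cancer type", call. = FALSE)
  }
  tumor_ids <- tissue_matrix$samples$sample_id[cond == cancer]
  adj_ids <- tissue_matrix$samples$sample_id[cond == "normal"]
  if (!length(tumor_ids) || !length(adj_ids)) {
    stop("need both tumor and adjacent tissue samples", call. = FALSE)
  }
  vt <- tissue_matrix$values[tumor_ids, , drop = FALSE]
  va <- tissue_matrix$values[adj_ids, , drop = FALSE]
  p <- vapply(seq_along(site_ids),
              function(j) mww_test(vt[, j], va[, j]), numeric(1))
  mean_tumor <- colMeans(vt)
  mean_adj <- colMeans(va)
  normal_ids <- plasma_matrix$samples$sample_id[
    plasma_matrix$samples$condition == "normal"]
  if (!length(normal_ids)) stop("no normal plasma samples", call. = FALSE)
  normals <- mm_subset(plasma_matrix, sample_ids = normal_ids)
  bg <- background_frequency(normals, site_ids,
                             criteria$positivity_threshold)
  motif <- catalog$motif_distance_bp[match(site_ids, catalog$site_id)]
  stats <- data.frame(site_id = site_ids, p_value = p,
                      mean_tumor = mean_tumor, mean_adjacent = mean_adj,
                      motif_distance_bp = motif, background_freq = bg,
                      stringsAsFactors = FALSE, row.names = NULL)
  pass <- p < criteria$p_max & mean_tumor > mean_adj &
    motif < criteria$motif_max_bp &
    mean_tumor >= criteria$min_mepm &
    bg < criteria$max_normal_freq
  sel <- stats[pass, , drop = FALSE]
  sel <- sel[order(sel$p_value), , drop = FALSE]
  rownames(sel) <- NULL
  marker_panel(cancer, sel$site_id,
               thresholds = criteria$positivity_threshold, stats = sel)
}

#' Pairwise discriminative markers between two tumor types
#'
#' Selects sites that tell tumor type A from tumor type B: differential
#' methylation at `p < p_max` with fold change (A over B) above `fc_min`,
#' mean MEPM in the hypermethylated tumor of at least `min_mepm`
#' (default 5 for cross-cancer panels), and normal-plasma background
#' frequency below `max_normal_freq`. Returns both directions; the two
#' panels are disjoint by construction.
#'
#' @param tumor_a_matrix,tumor_b_matrix `meth_matrix` objects of tumor
#'   tissue samples for the two types (same site set, disjoint samples).
#' @param normal_plasma_matrix `meth_matrix` of normal plasma samples.
#' @param criteria A [selection_criteria()]; default lowers `min_mepm`
#'   to 5.
#' @return List with `a_specific` and `b_specific` [marker_panel()]s.
#' @export
select_pairwise_discriminative_markers <- function(tumor_a_matrix,
                                                   tumor_b_matrix,
                                                   normal_plasma_matrix,
                                                   criteria =
                                                     selection_criteria(
                                                       min_mepm = 5)) {
  validate_meth_matrix(tumor_a_matrix)
  validate_meth_matrix(tumor_b_matrix)
  if (length(intersect(tumor_a_matrix$samples$sample_id,
                       tumor_b_matrix$samples$sample_id))) {
    stop("tumor cohorts share sample ids", call. = FALSE)
  }
  site_ids <- tumor_a_matrix$sites$site_id
  if (!identical(site_ids, tumor_b_matrix$sites$site_id)) {
    stop("tumor matrices must share one site set", call. = FALSE)
  }
  ca <- setdiff(unique(tumor_a_matrix$samples$condition), "normal")
  cb <- setdiff(unique(tumor_b_matrix$samples$condition), "normal")
  stopifnot(length(ca) == 1, length(cb) == 1)
  va <- tumor_a_matrix$values[
    tumor_a_matrix$samples$condition == ca, , drop = FALSE]
  vb <- tumor_b_matrix$values[
    tumor_b_matrix$samples$condition == cb, , drop = FALSE]
  p <- vapply(seq_along(site_ids),
              function(j) mww_test(va[, j], vb[, j]), numeric(1))
  mean_a <- colMeans(va)
  mean_b <- colMeans(vb)
  fc <- fold_change(mean_a, mean_b)
  normal_ids <- normal_plasma_matrix$samples$sample_id[
    normal_plasma_matrix$samples$condition == "normal"]
  normals <- mm_subset(normal_plasma_matrix, sample_ids = normal_ids)
  bg <- background_frequency(normals, site_ids,
                             criteria$positivity_threshold)
  base <- p < criteria$p_max & bg < criteria$max_normal_freq
  a_pass <- base & fc > criteria$fc_min & mean_a >= criteria$min_mepm
  b_pass <- base & fc < 1 / criteria$fc_min & mean_b >= criteria$min_mepm
  stats <- data.frame(site_id = site_ids, p_value = p, mean_a = mean_a,
                      mean_b = mean_b, fold_change = fc,
                      background_freq = bg, stringsAsFactors = FALSE)
  mk <- function(pass, cancer) {
    sel <- stats[pass, , drop = FALSE]
    sel <- sel[order(sel$p_value), , drop = FALSE]
    rownames(sel) <- NULL
    marker_panel(cancer, sel$site_id,
                 thresholds = criteria$positivity_threshold, stats = sel)
  }
  list(a_specific = mk(a_pass, ca), b_specific = mk(b_pass, cb))
}
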