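#' Count positive markers of a panel in one sample
#'
#' A marker is positive when the sample's MEPM value strictly exceeds the
#' marker's positivity threshold.
#'
#' @param values Named numeric vector of MEPM values covering every panel
#'   marker (e.g. from [sample_values()]).
#' @param panel A [marker_panel()].
#' @return Integer count in `[0, panel size]`.
#' @export
positive_count <- function(values, panel) {
  v <- panel_marker_values(values, panel)
  sum(v > panel$thresholds)
}

panel_marker_values <- function(values, panel) {
  miss <- setdiff(panel$marker_ids, names(values))
  if (length(miss)) {
    stop("sample lacks panel marker(s): ",
         paste(utils::head(miss, 3), collapse = ", "), call. = FALSE)
  }
  values[panel$marker_ids]
}

#' Total methylation of a panel in one sample
#'
#' Sum of MEPM values over the positive panel markers; values at or below
#' the positivity threshold contribute zero.
#'
#' @inheritParams positive_count
#' @return Non-negative MEPM sum.
#' @export
total_methylation <- function(values, panel) {
  v <- panel_marker_values(values, panel)
  sum(v[v > panel$thresholds])
}

#' Evaluate a panel on one sample
#'
#' @inheritParams positive_count
#' @return List of class `panel_evaluation` with `positive_count`,
#'   `panel_size`, `fraction_positive` and `total_methylation`.
#' @export
evaluate_panel <- function(values, panel) {
  n <- positive_count(values, panel)
  structure(list(positive_count = n,
                 panel_size = length(panel$marker_ids),
                 fraction_positive = n / length(panel$marker_ids),
                 total_methylation = total_methylation(values, panel)),
            class = "panel_evaluation")
}

#' Positive-marker counts of a panel across all samples of a matrix
#'
#' @param x A `meth_matrix` covering every panel marker.
#' @param panel A [marker_panel()].
#' @return Named integer vector of counts, one per sample.
#' @export
panel_counts <- function(x, panel) {
  miss <- setdiff(panel$marker_ids, colnames(x$values))
  if (length(miss)) {
    stop("matrix lacks panel marker(s): ",
         paste(utils::head(miss, 3), collapse = ", "), call. = FALSE)
  }
  v <- x$values[, panel$marker_ids, drop = FALSE]
  thr <- matrix(panel$thresholds, nrow(v), ncol(v), byrow = TRUE)
  rowSums(v > thr)
}

#' Calibrate a panel's positive-count cutoff on normal plasma
#'
#' Downstream classification calls a sample positive when its positive
#' count strictly exceeds the cutoff. Policy `"max"` sets the cutoff to
#' the largest count observed among the calibration normals, which fixes
#' specificity at 100% on the calibration set. Policy `"quantile"`
#' returns the smallest integer c with an empirical exceedance
#' `P(count > c) <= 1 - q`.
#'
#' @param normal_matrix `meth_matrix` of calibration normal plasma
#'   samples.
#' @param panel A [marker_panel()].
#' @param policy `"max"` or `"quantile"`.
#' @param q Coverage level for the quantile policy (default 0.95).
#' @param min_normals Minimum number of calibration samples (default 10).
#' @return Integer cutoff.
#' @export
calibrate_count_cutoff <- function(normal_matrix, panel,
                                   policy = c("max", "quantile"),
                                   q = 0.95, min_normals = 10) {
  policy <- match.arg(policy)
  counts <- panel_counts(normal_matrix, panel)
  if (length(counts) < min_normals) {
    stop("need at least ", min_normals, " calibration normals",
         call. = FALSE)
  }
  if (policy == "max") {
    as.integer(max(counts))
  } else {
    for (c_try in 0:max(counts)) {
      if (mean(counts > c_try) <= 1 - q) return(as.integer(c_try))
    }
    as.integer(max(counts))
  }
}

#' @rdname calibrate_count_cutoff
#' @return `calibrate_panel()` returns the panel with `count_cutoff` set.
#' @export
calibrate_panel <- function(panel, normal_matrix,
                            policy = c("max", "quantile"),
                            q = 0.95, min_normals = 10) {
  panel$count_cutoff <- calibrate_count_cutoff(normal_matrix, panel,
                                               policy, q, min_normals)
  panel
}

#' Classify one sample by its positive-marker count
#'
#' Positive iff the count strictly exceeds the panel's calibrated cutoff.
#'
#' @inheritParams positive_count
#' @return List with `call` (`"positive"`/`"negative"`) and `evaluation`
#'   (a `panel_evaluation`).
#' @export
classify_by_count <- function(values, panel) {
  if (is.na(panel$count_cutoff)) {
    stop("panel has no calibrated count cutoff", call. = FALSE)
  }
  ev <- evaluate_panel(values, panel)
  list(call = if (ev$positive_count > panel$count_cutoff) "positive"
       else "negative",
       evaluation = ev)
}

#' Brier score
#'
#' Mean squared difference between predicted probabilities and binary
#' outcomes.
#'
#' @param predicted_probs Probabilities in `[0, 1]`.
#' @param outcomes Binary outcomes (0/1), same length.
#' @return Value in `[0, 1]`.
#' @export
brier_score <- function(predicted_probs, outcomes) {
  if (length(predicted_probs) != length(outcomes)) {
    stop("length mismatch", call. = FALSE)
  }
  if (any(predicted_probs < 0 | predicted_probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (!all(outcomes %in% c(0, 1))) {
    stop("outcomes must be 0/1", call. = FALSE)
  }
  mean((predicted_probs - outcomes)^2)
}

#' ROC area under the curve via the rank-statistic formulation
#'
#' AUC equals the Mann-Whitney U statistic of case scores versus control
#' scores divided by the number of case-control pairs; tied pairs count
#' one half.
#'
#' @param scores Numeric scores (higher = more case-like).
#' @param labels Binary labels (1 = case, 0 = control); both classes must
#'   be present.
#' @return List with `auc` and `roc` (data frame of the ROC curve points:
#'   `threshold`, `fpr`, `tpr`).
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  if (!all(labels %in% c(0, 1)) || length(unique(labels)) < 2) {
    stop("labels must contain both classes (0 and 1)", call. = FALSE)
  }
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores)
  u <- sum(r[labels == 1]) - n1 * (n1 + 1) / 2
  auc <- u / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  roc <- data.frame(
    threshold = c(Inf, thr),
    fpr = c(0, vapply(thr, function(t) mean(scores[labels == 0] >= t),
                      numeric(1))),
    tpr = c(0, vapply(thr, function(t) mean(scores[labels == 1] >= t),
                      numeric(1))))
  list(auc = auc, roc = roc)
}

#' Monte Carlo cross-validated panel sizing by Brier score
#'
#' Repeatedly splits the cohort into equal-sized, condition-stratified
#' training and test halves. For each candidate panel size s, the top-s
#' ranked markers form a panel; a univariate logistic model mapping the
#' positive-marker count to a case probability is fitted on the training
#' half and scored on the test half with the Brier score. The selected
#' size minimizes the mean Brier score over splits (ties go to the
#' smallest size).
#'
#' @param x `meth_matrix` of the plasma cohort (cases + controls).
#' @param labels Named binary vector (1 = case) covering all samples of
#'   `x`, or NULL to derive from the sample sheet
#'   (condition != `"normal"`).
#' @param candidate_ranked Character vector of candidate marker ids in
#'   priority order (e.g. ascending selection p-value).
#' @param size_grid Integer panel sizes to evaluate (all must be at most
#'   the number of candidates).
#' @param n_splits Number of Monte Carlo splits (default 1000).
#' @param positivity_threshold MEPM positivity threshold (default 0).
#' @param seed Integer seed; results are deterministic given it.
#' @return List with `size` (selected panel size), `mean_brier` (named
#'   vector over the grid) and `n_splits`.
#' @export
monte_carlo_panel_size <- function(x, labels = NULL, candidate_ranked,
                                   size_grid, n_splits = 1000,
                                   positivity_threshold = 0, seed) {
  validate_meth_matrix(x)
  if (is.null(labels)) {
    labels <- stats::setNames(
      as.integer(x$samples$condition != "normal"), x$samples$sample_id)
  }
  labels <- labels[x$samples$sample_id]
  if (any(size_grid < 1) || any(size_grid > length(candidate_ranked))) {
    stop("size_grid must lie within [1, number of candidates]",
         call. = FALSE)
  }
  size_grid <- sort(unique(as.integer(size_grid)))
  v <- x$values[, candidate_ranked[seq_len(max(size_grid))], drop = FALSE]
  pos <- v > positivity_threshold
  # cumulative positive counts: column s holds the count over the top-s markers
  cum <- if (ncol(pos) == 1) matrix(as.numeric(pos), ncol = 1)
         else t(apply(pos, 1, cumsum))
  case_idx <- which(labels == 1)
  ctrl_idx <- which(labels == 0)
  if (!length(case_idx) || !length(ctrl_idx)) {
    stop("need both cases and controls", call. = FALSE)
  }
  briers <- with_seed(seed, {
    out <- matrix(NA_real_, n_splits, length(size_grid))
    for (b in seq_len(n_splits)) {
      tr <- c(sample(case_idx, floor(length(case_idx) / 2)),
              sample(ctrl_idx, floor(length(ctrl_idx) / 2)))
      te <- setdiff(seq_along(labels), tr)
      for (k in seq_along(size_grid)) {
        s <- size_grid[k]
        fit <- suppressWarnings(
          stats::glm.fit(cbind(1, cum[tr, s]), labels[tr],
                         family = stats::binomial()))
        eta <- cbind(1, cum[te, s]) %*% fit$coefficients
        out[b, k] <- brier_score(stats::plogis(eta), labels[te])
      }
    }
    out
  })
  mean_brier <- stats::setNames(colMeans(briers), size_grid)
  list(size = size_grid[which.min(mean_brier)],
       mean_brier = mean_brier, n_splits = n_splits)
}
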