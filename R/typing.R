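#' Evaluate all cancer panels on one sample
#'
#' @param values Named numeric vector of the sample's MEPM values,
#'   covering every marker of every panel.
#' @param panels List of calibrated [marker_panel()]s (one per cancer
#'   type, each with a `count_cutoff`).
#' @return Named list (by cancer type) of lists with `evaluation` (a
#'   `panel_evaluation`) and `flag` (logical: count strictly above the
#'   panel cutoff).
#' @export
evaluate_panels <- function(values, panels) {
  if (any(vapply(panels, function(p) is.na(p$count_cutoff), logical(1)))) {
    stop("all panels must have calibrated count cutoffs", call. = FALSE)
  }
  out <- lapply(panels, function(p) {
    ev <- evaluate_panel(values, p)
    list(evaluation = ev, flag = ev$positive_count > p$count_cutoff,
         cancer = p$cancer)
  })
  names(out) <- vapply(panels, function(p) p$cancer, character(1))
  out
}

#' Tumor-origin typing decision over the four cancer panels
#'
#' A sample is non-cancerous only when every panel is negative. With
#' exactly one positive panel, that panel's cancer type is called. With
#' several positive panels, the call goes to the panel with the highest
#' fraction of positive markers (positive count over panel size, compared
#' as exact rationals by integer cross-multiplication); an exact tie
#' among the leaders yields an indeterminate call.
#'
#' @param panel_evals Output of [evaluate_panels()].
#' @return List of class `typing_result` with `call` (cancer type,
#'   `"non_cancer"` or `"indeterminate"`), `tie_break_used`, and
#'   `per_panel` (data frame of counts, panel sizes, fractions, flags).
#' @export
typing_decision <- function(panel_evals) {
  cancers <- names(panel_evals)
  counts <- vapply(panel_evals,
                   function(e) e$evaluation$positive_count, numeric(1))
  sizes <- vapply(panel_evals,
                  function(e) e$evaluation$panel_size, numeric(1))
  flags <- vapply(panel_evals, function(e) e$flag, logical(1))
  per_panel <- data.frame(cancer = cancers, positive_count = counts,
                          panel_size = sizes,
                          fraction_positive = counts / sizes,
                          flag = flags, stringsAsFactors = FALSE,
                          row.names = NULL)
  tie_break_used <- FALSE
  if (!any(flags)) {
    call <- "non_cancer"
  } else if (sum(flags) == 1) {
    call <- cancers[flags]
  } else {
    tie_break_used <- TRUE
    idx <- which(flags)
    # exact rational comparison of count/size via cross-multiplication
    best <- idx[1]
    tied <- best
    for (i in idx[-1]) {
      lhs <- counts[i] * sizes[best]
      rhs <- counts[best] * sizes[i]
      if (lhs > rhs) {
        best <- i
        tied <- i
      } else if (lhs == rhs) {
        tied <- c(tied, i)
      }
    }
    call <- if (length(tied) > 1) "indeterminate" else cancers[best]
  }
  structure(list(call = unname(call), tie_break_used = tie_break_used,
                 per_panel = per_panel),
            class = "typing_result")
}

#' @export
print.typing_result <- function(x, ...) {
  cat(sprintf("typing_result: %s%s\n", x$call,
              if (x$tie_break_used) " (tie-break applied)" else ""))
  print(x$per_panel)
  invisible(x)
}

#' Type every sample of a plasma matrix
#'
#' @param x A `meth_matrix`.
#' @param panels List of calibrated [marker_panel()]s.
#' @return Data frame with one row per sample: `sample_id`, `call`,
#'   `tie_break_used`, and per-cancer positive counts and fractions.
#' @export
type_samples <- function(x, panels) {
  validate_meth_matrix(x)
  rows <- lapply(x$samples$sample_id, function(id) {
    res <- typing_decision(evaluate_panels(sample_values(x, id), panels))
    stats_wide <- res$per_panel
    out <- data.frame(sample_id = id, call = res$call,
                      tie_break_used = res$tie_break_used,
                      stringsAsFactors = FALSE)
    for (i in seq_len(nrow(stats_wide))) {
      out[[paste0(stats_wide$cancer[i], "_count")]] <-
        stats_wide$positive_count[i]
      out[[paste0(stats_wide$cancer[i], "_fraction")]] <-
        stats_wide$fraction_positive[i]
    }
    out
  })
  do.call(rbind, rows)
}
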