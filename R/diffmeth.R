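#' Two-tailed Mann-Whitney U test
#'
#' For small samples (`n_a + n_b <= exact_max`) the p-value is computed by
#' exact enumeration of all assignments of the pooled observations to the
#' two groups, with ties handled by mid-ranks; the two-sided p-value is the
#' permutation probability of a U statistic at least as extreme (on either
#' side of its mean) as the one observed. For larger samples a
#' tie-corrected normal approximation with continuity correction is used.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @param exact_max Largest pooled size for which the exact enumeration is
#'   used (default 12).
#' @return Two-sided p-value in (0, 1].
#' @examples
#' mww_test(c(1, 2, 3), c(4, 5, 6))  # 0.1
#' @export
mww_test <- function(group_a, group_b, exact_max = 12) {
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (anyNA(group_a) || anyNA(group_b)) {
    stop("missing values not allowed", call. = FALSE)
  }
  n_a <- length(group_a)
  n_b <- length(group_b)
  pooled <- c(group_a, group_b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  if (n_a + n_b <= exact_max) {
    idx <- utils::combn(n_a + n_b, n_a)
    u_all <- colSums(matrix(r[idx], nrow = n_a)) - n_a * (n_a + 1) / 2
    dev <- abs(u_obs - n_a * n_b / 2)
    p <- mean(abs(u_all - n_a * n_b / 2) >= dev - 1e-9)
  } else {
    n <- n_a + n_b
    ties <- table(r)
    mu <- n_a * n_b / 2
    sigma2 <- n_a * n_b / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(1)
    z <- max(0, abs(u_obs - mu) - 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-z)
  }
  min(1, max(p, .Machine$double.xmin))
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up q-values for a vector of p-values, in the input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values (same length/order), each in `[0, 1]`.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Methylation fold change with pseudocount
#'
#' `(mean_a + pseudocount) / (mean_b + pseudocount)`. The pseudocount
#' (default 0.5 MEPM) keeps the ratio defined at the zero-signal sites
#' that dominate plasma data.
#'
#' @param mean_a,mean_b Non-negative group means (MEPM).
#' @param pseudocount Non-negative stabilizer added to both means.
#' @return Positive fold change.
#' @export
fold_change <- function(mean_a, mean_b, pseudocount = 0.5) {
  if (any(mean_a < 0) || any(mean_b < 0)) {
    stop("means must be non-negative", call. = FALSE)
  }
  (mean_a + pseudocount) / (mean_b + pseudocount)
}

#' Differentially methylated sites between two groups
#'
#' Runs the two-tailed Mann-Whitney test per site, corrects across all
#' tested sites with Benjamini-Hochberg, computes pseudocounted fold
#' changes, and keeps sites with `q_value < q_max` and fold change above
#' `fc_min` (hypermethylated in group A) or below `1/fc_min`
#' (hypomethylated).
#'
#' @param x A `meth_matrix`.
#' @param group_a_ids,group_b_ids Disjoint, non-empty sets of sample ids.
#' @param q_max FDR threshold (default 0.05).
#' @param fc_min Fold-change threshold (default 2).
#' @param pseudocount Passed to [fold_change()].
#' @return List with `sites` (data frame of the retained sites: `site_id`,
#'   `mean_a`, `mean_b`, `fold_change`, `p_value`, `q_value`, `direction`,
#'   ordered by ascending p), `n_hyper` and `n_hypo`.
#' @export
differential_sites <- function(x, group_a_ids, group_b_ids,
                               q_max = 0.05, fc_min = 2, pseudocount = 0.5) {
  validate_meth_matrix(x)
  if (length(intersect(group_a_ids, group_b_ids))) {
    stop("groups overlap", call. = FALSE)
  }
  if (length(group_a_ids) == 0 || length(group_b_ids) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  va <- x$values[group_a_ids, , drop = FALSE]
  vb <- x$values[group_b_ids, , drop = FALSE]
  p <- vapply(seq_len(ncol(va)),
              function(j) mww_test(va[, j], vb[, j]), numeric(1))
  q <- bh_fdr(p)
  ma <- colMeans(va)
  mb <- colMeans(vb)
  fc <- fold_change(ma, mb, pseudocount)
  res <- data.frame(site_id = colnames(va), mean_a = ma, mean_b = mb,
                    fold_change = fc, p_value = p, q_value = q,
                    direction = ifelse(ma > mb, "hyper", "hypo"),
                    stringsAsFactors = FALSE, row.names = NULL)
  keep <- res$q_value < q_max & (res$fold_change > fc_min |
                                   res$fold_change < 1 / fc_min)
  res <- res[keep, , drop = FALSE]
  res <- res[order(res$p_value), , drop = FALSE]
  rownames(res) <- NULL
  list(sites = res,
       n_hyper = sum(res$direction == "hyper"),
       n_hypo = sum(res$direction == "hypo"))
}
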