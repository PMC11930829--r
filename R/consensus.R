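#' Consensus matrix by subsampled hierarchical clustering
#'
#' Repeatedly subsamples the cohort, clusters each subsample into k groups
#' (Ward linkage, Euclidean distance on log1p-transformed MEPM values),
#' and records how often each pair of samples lands in the same cluster.
#' Entry (i, j) is the number of co-clusterings divided by the number of
#' resamples in which both samples were drawn.
#'
#' @param x A `meth_matrix` (all samples are clustered).
#' @param k Number of clusters.
#' @param features Site ids to cluster on (default: all sites; typically
#'   restricted to a marker panel).
#' @param n_resamples Number of subsampling iterations (default 500).
#' @param subsample_frac Fraction of samples drawn per iteration
#'   (default 0.8).
#' @param seed Integer seed.
#' @return Symmetric matrix in `[0, 1]` with unit diagonal, sample ids as
#'   dimnames.
#' @export
consensus_matrix <- function(x, k, features = NULL, n_resamples = 500,
                             subsample_frac = 0.8, seed) {
  validate_meth_matrix(x)
  n <- nrow(x$values)
  if (k > n) stop("k exceeds the number of samples", call. = FALSE)
  if (is.null(features)) features <- x$sites$site_id
  v <- log1p(x$values[, features, drop = FALSE])
  if (n == 1) {
    m <- matrix(1, 1, 1, dimnames = list(rownames(v), rownames(v)))
    return(m)
  }
  m_draw <- max(2L, round(subsample_frac * n))
  with_seed(seed, {
    both <- matrix(0, n, n)
    together <- matrix(0, n, n)
    for (b in seq_len(n_resamples)) {
      idx <- sample.int(n, m_draw)
      cl <- stats::cutree(
        stats::hclust(stats::dist(v[idx, , drop = FALSE]),
                      method = "ward.D2"),
        k = min(k, m_draw))
      both[idx, idx] <- both[idx, idx] + 1
      same <- outer(cl, cl, "==")
      together[idx, idx] <- together[idx, idx] + same
    }
    cons <- ifelse(both > 0, together / pmax(both, 1), 0)
    diag(cons) <- 1
    dimnames(cons) <- list(rownames(v), rownames(v))
    cons
  })
}

#' Run consensus clustering over a range of k
#'
#' Computes the consensus matrix for each k, the empirical CDF of its
#' off-diagonal entries, the area under each CDF and the relative
#' delta-area, selects the optimal k, and derives final cluster
#' assignments by hierarchical clustering of the consensus
#' dissimilarity (1 - consensus) at the optimal k.
#'
#' @inheritParams consensus_matrix
#' @param k_max Largest k to evaluate (k runs from 2 to `k_max`).
#' @param delta_threshold Relative delta-area below which increasing k is
#'   considered to add no structure. The default 0.4 is calibrated on
#'   planted cluster geometries: splitting one true cluster of a
#'   two-cluster cohort yields relative gains around 0.2--0.3 (an
#'   artifact of frozen sample geometry under resampling), while a
#'   genuine additional cluster yields gains above 0.45.
#' @return List of class `consensus_result`: `consensus` (list of
#'   matrices indexed by k), `cdf_area`, `delta_area`, `optimal_k`,
#'   `assignments` (named integer vector at the optimal k).
#' @export
consensus_cluster <- function(x, k_max = 6, features = NULL,
                              n_resamples = 500, subsample_frac = 0.8,
                              delta_threshold = 0.4, seed) {
  stopifnot(k_max >= 2)
  ks <- 2:k_max
  cons <- lapply(ks, function(k) {
    consensus_matrix(x, k, features, n_resamples, subsample_frac,
                     seed = seed + k)
  })
  names(cons) <- ks
  area <- vapply(cons, cdf_area, numeric(1))
  delta <- delta_area(area)
  k_opt <- optimal_k_from_delta(delta, delta_threshold)
  cm <- cons[[as.character(k_opt)]]
  hc <- stats::hclust(stats::as.dist(1 - cm), method = "ward.D2")
  assignments <- stats::cutree(hc, k = k_opt)
  structure(list(consensus = cons, cdf_area = area, delta_area = delta,
                 optimal_k = k_opt, assignments = assignments),
            class = "consensus_result")
}

# Area under the empirical CDF of the off-diagonal consensus entries.
cdf_area <- function(cons) {
  vals <- sort(cons[upper.tri(cons)])
  if (length(vals) == 0) return(0)
  grid <- sort(unique(c(0, vals, 1)))
  cdf <- stats::ecdf(vals)
  sum(diff(grid) * cdf(grid[-length(grid)]))
}

# Relative increase in CDF area per added cluster (Monti-style).
delta_area <- function(area) {
  ks <- as.integer(names(area))
  d <- numeric(length(area))
  d[1] <- area[1]
  if (length(area) > 1) {
    d[-1] <- diff(area) / area[-length(area)]
  }
  stats::setNames(d, ks)
}

optimal_k_from_delta <- function(delta, delta_threshold = 0.4) {
  ks <- as.integer(names(delta))
  ok <- ks[delta >= delta_threshold]
  if (length(ok) == 0) return(2L)
  max(ok)
}

#' Choose the optimal number of clusters from consensus CDFs
#'
#' The optimal k is the largest k whose relative delta-area (relative
#' gain in area under the consensus CDF over k - 1) still reaches the
#' threshold; beyond it, adding clusters no longer increases consensus
#' structure. Structureless data fall back to k = 2.
#'
#' @param result A [consensus_cluster()] result.
#' @param delta_threshold Relative delta-area threshold (default 0.4, see
#'   [consensus_cluster()]).
#' @return Integer k.
#' @export
optimal_k <- function(result, delta_threshold = 0.4) {
  stopifnot(inherits(result, "consensus_result"))
  optimal_k_from_delta(result$delta_area, delta_threshold)
}

#' Label the CIMP cluster of a two-cluster solution
#'
#' Of the two clusters, the one with the larger median per-sample total
#' methylation over the marker panel is labelled the CpG-island
#' methylator phenotype (CIMP) cluster.
#'
#' @param assignments Named integer vector of cluster labels (exactly two
#'   distinct clusters).
#' @param x `meth_matrix` covering the panel markers for all assigned
#'   samples.
#' @param panel A [marker_panel()].
#' @return List with `cimp_cluster` (the cluster id), `summary` (data
#'   frame of per-cluster size and median total methylation) and
#'   `cimp_flags` (named logical vector).
#' @export
assign_cimp <- function(assignments, x, panel) {
  if (length(unique(assignments)) != 2) {
    stop("CIMP labelling requires exactly 2 clusters", call. = FALSE)
  }
  totals <- vapply(names(assignments), function(id) {
    total_methylation(sample_values(x, id), panel)
  }, numeric(1))
  med <- tapply(totals, assignments, stats::median)
  if (length(unique(med)) == 1) {
    stop("clusters tie on median total methylation; CIMP undefined",
         call. = FALSE)
  }
  cimp <- names(med)[which.max(med)]
  summary <- data.frame(cluster = names(med),
                        n = as.vector(table(assignments)[names(med)]),
                        median_total_methylation = as.numeric(med),
                        stringsAsFactors = FALSE)
  list(cimp_cluster = cimp, summary = summary,
       cimp_flags = stats::setNames(assignments == as.integer(cimp),
                                    names(assignments)))
}
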