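test_that("positive counts use strict per-marker thresholds", {
  p0 <- marker_panel("PAC", paste0("m", 1:5))
  v <- setNames(c(0, 0, 2.5, 0.1, 0), paste0("m", 1:5))
  expect_equal(positive_count(v, p0), 2)
  expect_equal(positive_count(v * 0, p0), 0)
  p1 <- marker_panel("PAC", paste0("m", 1:5), thresholds = 1)
  v2 <- setNames(c(0.5, 2, 1, 3, 0), paste0("m", 1:5))
  expect_equal(positive_count(v2, p1), 2)  # boundary value 1 excluded
  expect_error(positive_count(v[1:3], p0), "lacks panel marker")
})

test_that("total methylation sums only positive markers", {
  p0 <- marker_panel("PAC", paste0("m", 1:3))
  expect_equal(total_methylation(setNames(c(0, 30, 120), paste0("m", 1:3)),
                                 p0), 150)
  p_empty <- marker_panel("PAC", character(0))
  expect_equal(total_methylation(setNames(numeric(0), character(0)),
                                 p_empty), 0)
  p_thr <- marker_panel("PAC", "m1", thresholds = 2)
  expect_equal(total_methylation(c(m1 = 2), p_thr), 0)  # at threshold
})

test_that("positive_count is monotone in values and thresholds", {
  set.seed(3)
  ids <- paste0("m", 1:30)
  for (i in 1:20) {
    v <- setNames(rlnorm(30) * rbinom(30, 1, 0.5), ids)
    thr <- runif(30, 0, 2)
    p <- marker_panel("PAC", ids, thresholds = thr)
    base <- positive_count(v, p)
    j <- sample(30, 1)
    v_up <- v
    v_up[j] <- v_up[j] + 1
    expect_gte(positive_count(v_up, p), base)
    thr_up <- thr
    thr_up[j] <- thr_up[j] + 1
    expect_lte(positive_count(v, marker_panel("PAC", ids,
                                              thresholds = thr_up)), base)
  }
})

test_that("count cutoff calibration follows the stated policies", {
  counts_to_mm <- function(counts, n_sites = 10) {
    n <- length(counts)
    v <- t(vapply(counts, function(k)
      c(rep(1, k), rep(0, n_sites - k)), numeric(n_sites)))
    ids <- sprintf("N%02d", seq_len(n))
    rownames(v) <- ids
    colnames(v) <- paste0("m", seq_len(n_sites))
    samples <- data.frame(sample_id = ids, specimen = "plasma",
                          condition = "normal", stage = NA_character_,
                          paired_id = NA_character_, total_molecules = 5e4,
                          stringsAsFactors = FALSE)
    meth_matrix(v, samples)
  }
  panel <- marker_panel("PAC", paste0("m", 1:10))
  mm <- counts_to_mm(c(0, 0, 1, 2, 3, 5, 0, 0, 0, 0))
  expect_equal(calibrate_count_cutoff(mm, panel), 5L)
  expect_equal(calibrate_count_cutoff(counts_to_mm(rep(0, 12)), panel), 0L)
  counts <- 0:10
  mm2 <- counts_to_mm(counts)
  got <- calibrate_count_cutoff(mm2, panel, policy = "quantile", q = 0.95)
  brute <- min(which(vapply(0:10, function(c0)
    mean(counts > c0) <= 0.05, logical(1)))) - 1L
  expect_equal(got, brute)
  expect_error(calibrate_count_cutoff(counts_to_mm(c(0, 1)), panel),
               "calibration normals")
})

test_that("count classification is strict at the cutoff", {
  panel <- marker_panel("PAC", paste0("m", 1:10), count_cutoff = 5)
  v6 <- setNames(c(rep(1, 6), rep(0, 4)), paste0("m", 1:10))
  v5 <- setNames(c(rep(1, 5), rep(0, 5)), paste0("m", 1:10))
  expect_equal(classify_by_count(v6, panel)$call, "positive")
  expect_equal(classify_by_count(v5, panel)$call, "negative")
  expect_equal(classify_by_count(v5 * 0, panel)$call, "negative")
  uncal <- marker_panel("PAC", paste0("m", 1:10))
  expect_error(classify_by_count(v6, uncal), "cutoff")
})

test_that("Brier score equals the mean squared error of probabilities", {
  expect_equal(brier_score(c(1, 0), c(1, 0)), 0)
  expect_equal(brier_score(c(0.5, 0.5), c(1, 0)), 0.25)
  expect_equal(brier_score(c(0.8, 0.4), c(1, 0)), 0.1)
  expect_error(brier_score(0.5, c(1, 0)), "length")
  expect_error(brier_score(c(1.2, 0), c(1, 0)), "\\[0, 1\\]")
  # constant predictor at prevalence scores prevalence*(1-prevalence)
  set.seed(4)
  y <- rbinom(200, 1, 0.3)
  prev <- mean(y)
  expect_equal(brier_score(rep(prev, 200), y), prev * (1 - prev))
})

test_that("rank-based AUC matches hand cases and handles ties", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 1, 0, 1))$auc, 0.75)
  expect_equal(roc_auc(rep(2, 6), c(0, 1, 0, 1, 0, 1))$auc, 0.5)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
  roc <- roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$roc
  expect_equal(roc$fpr[1], 0)
  expect_equal(roc$tpr[nrow(roc)], 1)
  expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
})

test_that("AUC equals the O(n^2) pairwise oracle on random scores", {
  set.seed(5)
  for (i in 1:100) {
    n <- sample(6:25, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- round(rnorm(n), sample(0:1, 1))  # rounding forces ties
    expect_equal(roc_auc(scores, labels)$auc, auc_oracle(scores, labels))
  }
})

test_that("Monte Carlo sizing handles degenerate and null candidate sets", {
  set.seed(6)
  n <- 40
  ids <- sprintf("P%02d", 1:n)
  labels <- rep(c(1, 0), each = n / 2)
  # one perfectly separating candidate plus noise columns
  v <- cbind(good = ifelse(labels == 1, 5, 0),
             matrix(rbinom(n * 10, 1, 0.3) * rlnorm(n * 10), n, 10))
  colnames(v) <- c("good", paste0("noise", 1:10))
  rownames(v) <- ids
  samples <- data.frame(sample_id = ids, specimen = "plasma",
                        condition = ifelse(labels == 1, "PAC", "normal"),
                        stage = ifelse(labels == 1, "II", NA),
                        paired_id = NA_character_, total_molecules = 5e4,
                        stringsAsFactors = FALSE)
  mm <- meth_matrix(v, samples)
  res <- monte_carlo_panel_size(mm, candidate_ranked = "good",
                                size_grid = 1, n_splits = 50, seed = 1)
  expect_equal(res$size, 1L)
  expect_lt(res$mean_brier[["1"]], 0.02)
  # all-noise candidates: Brier near 0.25, smallest size wins ties
  res2 <- monte_carlo_panel_size(mm,
                                 candidate_ranked = paste0("noise", 1:10),
                                 size_grid = c(2, 5, 10), n_splits = 100,
                                 seed = 2)
  expect_true(all(abs(res2$mean_brier - 0.25) < 0.08))
  # determinism
  res3 <- monte_carlo_panel_size(mm,
                                 candidate_ranked = paste0("noise", 1:10),
                                 size_grid = c(2, 5, 10), n_splits = 100,
                                 seed = 2)
  expect_identical(res2, res3)
  expect_error(monte_carlo_panel_size(mm, candidate_ranked = "good",
                                      size_grid = 2, n_splits = 10,
                                      seed = 1), "size_grid")
})
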