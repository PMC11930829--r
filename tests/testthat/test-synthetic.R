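test_that("site catalog simulation is reproducible and plants panels", {
  cfg <- default_config()
  cs <- default_catalog()
  cs2 <- simulate_site_catalog(cfg)
  expect_identical(cs, cs2)
  expect_equal(nrow(cs$catalog), cfg$n_sites)
  expect_false(anyDuplicated(cs$catalog$site_id) > 0)
  expect_length(cs$planted_markers$PAC, 120)
  expect_length(cs$planted_markers$HCC, 38)
  expect_length(cs$planted_markers$CRC, 80)
  expect_length(cs$planted_markers$GC, 153)
  # panels are disjoint; shared subsets live inside their panel
  all_pl <- unlist(cs$planted_markers)
  expect_false(anyDuplicated(all_pl) > 0)
  for (ct in cancer_types()) {
    expect_true(all(cs$shared_markers[[ct]] %in% cs$planted_markers[[ct]]))
    expect_length(cs$shared_markers[[ct]],
                  round(0.25 * length(cs$planted_markers[[ct]])))
  }
  # planted markers sit closer than 60 bp to the motif
  motif <- setNames(cs$catalog$motif_distance_bp, cs$catalog$site_id)
  expect_true(all(motif[all_pl] < 60))
})

test_that("decoy motif distances follow the configured far fraction", {
  cfg <- sim_config(seed = 5, decoy_motif_far_fraction = 0.1)
  cs <- simulate_site_catalog(cfg)
  resp <- c(unlist(cs$planted_markers), unlist(cs$leaky_markers))
  decoys <- setdiff(cs$catalog$site_id, resp)
  far <- cs$catalog$motif_distance_bp[match(decoys, cs$catalog$site_id)] >= 60
  ci <- qbinom(c(0.005, 0.995), length(decoys), 0.1)
  expect_gte(sum(far), ci[1])
  expect_lte(sum(far), ci[2])
})

test_that("tissue cohort pairs samples and elevates planted markers", {
  tis <- default_tissue()
  s <- tis$matrix$samples
  expect_equal(nrow(s), 66)
  tumors <- s[s$condition == "PAC", ]
  expect_equal(nrow(tumors), 33)
  expect_true(all(tumors$paired_id %in% s$sample_id))
  # pairing is mutual
  expect_equal(s$paired_id[match(tumors$paired_id, s$sample_id)],
               tumors$sample_id)
  # 2 of 33 tumors flagged CIMP at the default fraction
  expect_equal(sum(tis$ground_truth$sample_labels$cimp_flag), 2)
  expect_true(all(tis$matrix$values >= 0))
})

test_that("planted tissue fold changes exceed the differential threshold", {
  cfg <- sim_config(seed = 11)
  cs <- simulate_site_catalog(cfg)
  tis <- simulate_tissue_cohort(cfg, n_pairs = 30, catalog_sim = cs)
  v <- tis$matrix$values
  cond <- tis$matrix$samples$condition
  truth <- cs$planted_markers$PAC
  fc <- colMeans(v[cond == "PAC", truth]) /
    pmax(colMeans(v[cond == "normal", truth]), 0.5)
  expect_gte(mean(fc > 2), 0.95)
  expect_true(all(colMeans(v[cond == "PAC", truth]) >= 10 * 0.5))
})

test_that("plasma background positivity is binomial at the configured rate", {
  # heterogeneity knobs off: this checks the base rate calibration
  cfg <- sim_config(seed = 21, background_sample_sd = 0,
                    marker_bg_sd = 0, n_sites = 500,
                    markers_per_cancer = c(PAC = 120, HCC = 10, CRC = 10,
                                           GC = 10))
  cs <- simulate_site_catalog(cfg)
  pla <- simulate_plasma_cohort(cfg,
                                n_cases_by_stage = c(I = 0, II = 0,
                                                     III = 0, IV = 0),
                                n_controls = 400, catalog_sim = cs)
  pos <- colSums(pla$matrix$values[, cs$planted_markers$PAC] > 0)
  ci <- qbinom(c(0.005, 0.995), 400, cfg$background_pos_freq)
  within <- pos >= ci[1] & pos <= ci[2]
  expect_gte(mean(within), 0.97)
})

test_that("cases are indistinguishable from controls when signal is zero", {
  cfg <- sim_config(seed = 31,
                    tumor_signal_by_stage = c(I = 0, II = 0, III = 0,
                                              IV = 0))
  cs <- simulate_site_catalog(cfg)
  pla <- simulate_plasma_cohort(cfg, catalog_sim = cs)
  panel <- marker_panel("PAC", cs$planted_markers$PAC)
  counts <- panel_counts(pla$matrix, panel)
  is_case <- pla$matrix$samples$condition != "normal"
  ks <- suppressWarnings(ks.test(counts[is_case], counts[!is_case]))
  expect_gt(ks$p.value, 0.01)
})

test_that("stage IV signal dominates stage I in positive counts", {
  cfg <- default_config()
  cs <- default_catalog()
  panel <- marker_panel("PAC", cs$planted_markers$PAC)
  diffs <- vapply(1:20, function(i) {
    pla <- simulate_plasma_cohort(cfg,
                                  n_cases_by_stage = c(I = 8, II = 0,
                                                       III = 0, IV = 8),
                                  n_controls = 0, catalog_sim = cs,
                                  seed = 1000 + i)
    counts <- panel_counts(pla$matrix, panel)
    stage <- pla$matrix$samples$stage
    mean(counts[stage == "IV"]) - mean(counts[stage == "I"])
  }, numeric(1))
  expect_gte(mean(diffs >= 0), 0.95)
  expect_gt(mean(diffs), 0)
})

test_that("multicancer cohort carries five label groups and shared firing", {
  cfg <- default_config()
  cs <- default_catalog()
  mc <- simulate_multicancer_plasma(cfg, catalog_sim = cs)
  expect_setequal(unique(mc$matrix$samples$condition),
                  c(cancer_types(), "normal"))
  expect_equal(nrow(mc$matrix$values), 125)
  # reproducible bit-exact
  mc2 <- simulate_multicancer_plasma(cfg, catalog_sim = cs)
  expect_identical(mc$matrix$values, mc2$matrix$values)
  # HCC cases fire at the shared subset of the PAC panel well above the
  # PAC-private background
  hcc <- mc$matrix$samples$condition == "HCC"
  shared_pac <- cs$shared_markers$PAC
  private_pac <- setdiff(cs$planted_markers$PAC, shared_pac)
  pos_shared <- mean(mc$matrix$values[hcc, shared_pac] > 0)
  pos_private <- mean(mc$matrix$values[hcc, private_pac] > 0)
  expect_gt(pos_shared, 5 * pos_private)
})

test_that("zero shared fraction removes cross-cancer firing", {
  cfg <- sim_config(seed = 41, shared_marker_fraction = 0)
  cs <- simulate_site_catalog(cfg)
  mc <- simulate_multicancer_plasma(cfg,
                                    n_per_cancer = c(PAC = 10, HCC = 10,
                                                     CRC = 0, GC = 0),
                                    n_controls = 10, catalog_sim = cs)
  hcc <- mc$matrix$samples$condition == "HCC"
  ctrl <- mc$matrix$samples$condition == "normal"
  pac_sites <- cs$planted_markers$PAC
  # HCC positivity at PAC markers is at the background level
  expect_lt(abs(mean(mc$matrix$values[hcc, pac_sites] > 0) -
                  mean(mc$matrix$values[ctrl, pac_sites] > 0)), 0.02)
})
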