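test_that("background frequency counts strictly positive normals", {
  v <- rbind(c(0, 1), c(0, 0), c(0.2, 0), c(0, 0))
  ids <- sprintf("N%d", 1:4)
  rownames(v) <- ids
  colnames(v) <- c("s1", "s2")
  samples <- data.frame(sample_id = ids, specimen = "plasma",
                        condition = "normal", stage = NA_character_,
                        paired_id = NA_character_, total_molecules = 5e4,
                        stringsAsFactors = FALSE)
  mm <- meth_matrix(v, samples)
  expect_equal(unname(background_frequency(mm, "s1")), 0.25)
  expect_equal(unname(background_frequency(mm, "s1",
                                           positivity_threshold = 0.3)), 0)
  expect_equal(unname(background_frequency(mm, "s2")), 0.25)
  zero <- meth_matrix(v * 0, samples)
  expect_equal(unname(background_frequency(zero, c("s1", "s2"))), c(0, 0))
  expect_error(background_frequency(mm, "nope"), "unknown site")
})

test_that("four-criteria selection keeps planted markers, rejects violations", {
  panel <- default_selected_panel()
  truth <- default_catalog()$planted_markers$PAC
  expect_gte(mean(panel$marker_ids %in% truth), 0.95)
  expect_gte(mean(truth %in% panel$marker_ids), 0.9)
  # every selected marker satisfies each criterion on the recorded stats
  st <- panel$stats
  expect_true(all(st$p_value < 0.01))
  expect_true(all(st$motif_distance_bp < 60))
  expect_true(all(st$mean_tumor >= 10))
  expect_true(all(st$background_freq < 0.05))
  expect_true(all(diff(st$p_value) >= 0))  # ordered by ascending p
  # leaky tumor-responsive sites fail the background criterion (a rare
  # site can slip through when its empirical frequency in 31 normals
  # lands under 5% by chance)
  leaky <- default_catalog()$leaky_markers$PAC
  expect_lte(length(intersect(panel$marker_ids, leaky)),
             ceiling(0.05 * length(leaky)))
})

test_that("each selection criterion is individually necessary", {
  tis <- default_tissue()$matrix
  pla <- default_plasma()$matrix
  catalog <- default_catalog()$catalog
  full <- length(default_selected_panel()$marker_ids)
  relaxed <- list(
    selection_criteria(p_max = 1),
    selection_criteria(motif_max_bp = 1e6),
    selection_criteria(min_mepm = 1e-9),
    selection_criteria(max_normal_freq = 1)
  )
  for (cr in relaxed) {
    n <- length(select_cancer_markers(tis, pla, catalog, cr)$marker_ids)
    expect_gte(n, full)
  }
})

test_that("motif and background boundaries are strict", {
  # two candidate sites, identical strong tissue signal; one at exactly
  # 60 bp from the motif, one with 6% normal-plasma background
  n <- 12
  v <- cbind(m_ok = c(rep(30, n), rep(1, n)),
             m_motif = c(rep(30, n), rep(1, n)),
             m_bg = c(rep(30, n), rep(1, n)))
  ids <- sprintf("T%02d", 1:(2 * n))
  rownames(v) <- ids
  tsamples <- data.frame(sample_id = ids, specimen = "tissue",
                         condition = c(rep("PAC", n), rep("normal", n)),
                         stage = c(rep("II", n), rep(NA, n)),
                         paired_id = NA_character_, total_molecules = 1e5,
                         stringsAsFactors = FALSE)
  tis <- meth_matrix(v, tsamples)
  catalog <- data.frame(site_id = colnames(v), chrom = "chr1",
                        start = c(0, 100, 200), end = c(50, 150, 250),
                        motif_distance_bp = c(10L, 60L, 10L),
                        gene_label = "G", stringsAsFactors = FALSE)
  np <- 50
  pv <- cbind(m_ok = rep(0, np), m_motif = rep(0, np),
              m_bg = c(rep(5, 3), rep(0, np - 3)))  # 3/50 = 6%
  pids <- sprintf("N%02d", 1:np)
  rownames(pv) <- pids
  psamples <- data.frame(sample_id = pids, specimen = "plasma",
                         condition = "normal", stage = NA_character_,
                         paired_id = NA_character_, total_molecules = 5e4,
                         stringsAsFactors = FALSE)
  pla <- meth_matrix(pv, psamples)
  panel <- select_cancer_markers(tis, pla, catalog)
  expect_equal(panel$marker_ids, "m_ok")
})

test_that("pairwise selection recovers type-private markers", {
  cfg <- default_config()
  cs <- default_catalog()
  tis_a <- simulate_tissue_cohort(cfg, n_pairs = 25, cancer = "PAC",
                                  catalog_sim = cs, seed = 501,
                                  cross_shared = TRUE)
  tis_b <- simulate_tissue_cohort(cfg, n_pairs = 25, cancer = "HCC",
                                  catalog_sim = cs, seed = 502,
                                  cross_shared = TRUE)
  tum_a <- mm_subset(tis_a$matrix, sample_ids =
    tis_a$matrix$samples$sample_id[tis_a$matrix$samples$condition == "PAC"])
  tum_b <- mm_subset(tis_b$matrix, sample_ids =
    tis_b$matrix$samples$sample_id[tis_b$matrix$samples$condition == "HCC"])
  # avoid id collisions between the two simulated cohorts
  tum_b$samples$sample_id <- paste0("B_", tum_b$samples$sample_id)
  rownames(tum_b$values) <- tum_b$samples$sample_id
  res <- select_pairwise_discriminative_markers(
    tum_a, tum_b, default_preselection()$matrix)
  priv_a <- setdiff(cs$planted_markers$PAC, cs$shared_markers$PAC)
  priv_b <- setdiff(cs$planted_markers$HCC, cs$shared_markers$HCC)
  expect_gte(mean(priv_a %in% res$a_specific$marker_ids), 0.9)
  expect_gte(mean(priv_b %in% res$b_specific$marker_ids), 0.9)
  # markers firing in both cancers are (almost) never in either panel
  shared_all <- unlist(cs$shared_markers)
  expect_lte(length(intersect(res$a_specific$marker_ids, shared_all)),
             ceiling(0.02 * length(shared_all)))
  expect_lte(length(intersect(res$b_specific$marker_ids, shared_all)),
             ceiling(0.02 * length(shared_all)))
  # panels are disjoint
  expect_length(intersect(res$a_specific$marker_ids,
                          res$b_specific$marker_ids), 0)
})

test_that("marker panels validate their cutoff", {
  expect_error(marker_panel("PAC", c("a", "b"), count_cutoff = 2),
               "smaller than the panel size")
  p <- marker_panel("PAC", c("a", "b", "c"), thresholds = 1,
                    count_cutoff = 1)
  expect_equal(unname(p$thresholds), c(1, 1, 1))
  expect_equal(p$count_cutoff, 1L)
})
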