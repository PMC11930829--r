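#' Configuration for the synthetic MCTA-Seq-like cohort generator
#'
#' The generator emulates the statistical structure of a semi-targeted
#' cfDNA methylation assay: sparse low-level background positivity in
#' normal plasma, strong CpG-island hypermethylation of planted marker
#' sites in tumor tissue, plasma tumor signal that scales with stage, a
#' small high-methylation (CIMP) tumor subgroup, and four cancer types
#' sharing a common core of markers on top of type-private ones.
#'
#' Noise model: at every site and sample, signal occurs ("occupancy") with
#' a Bernoulli probability and, when it occurs, has a log-normal magnitude
#' (arithmetic mean fixed, log-sd `dispersion`). Tumor signal is an
#' additional independent occupancy/magnitude channel at planted markers.
#' Plasma cases carry a per-patient tumor-burden factor (log-normal,
#' log-sd `burden_dispersion`) so that positive-marker counts span a wide
#' range within a stage, as observed in real cfDNA cohorts.
#'
#' @param n_sites Number of CpG sites in the simulated catalog.
#' @param markers_per_cancer Named integer vector, planted panel size per
#'   cancer type. Defaults mirror the deployed panel sizes
#'   (PAC 120, HCC 38, CRC 80, GC 153).
#' @param shared_marker_fraction Fraction of each panel that is
#'   pan-cancer responsive (fires in tumors of every type); the rest of
#'   the panel is type-private.
#' @param background_pos_freq Per-site probability that a normal plasma
#'   sample shows any signal (kept below 0.05 so planted markers satisfy
#'   the background-frequency selection criterion).
#' @param background_magnitude_mean Mean MEPM of background signal when
#'   present.
#' @param background_sample_sd Log-sd of a per-sample background scale
#'   factor in plasma (sample quality/input variation): sample i's
#'   per-site background positivity is `background_pos_freq * g_i` with
#'   `g_i` log-normal of mean 1. This reproduces the wide positive-count
#'   range seen among real normal plasma samples.
#' @param marker_bg_sd Log-sd of the per-marker background positivity of
#'   planted markers: marker j's normal-plasma positivity is drawn
#'   log-normally with mean `background_pos_freq` (capped at 0.045, below
#'   the 5% selection bound). Real panels mix near-silent and faintly
#'   leaky markers; 0 gives a homogeneous panel.
#' @param marker_sensitivity_tradeoff Exponent coupling a marker's case
#'   sensitivity to its background level: the per-marker responsiveness is
#'   `(bg_j / background_pos_freq)^tradeoff` (capped at 2.5, normalized to
#'   mean 1 over the planted panel). Cleaner markers are harder to detect
#'   in patient plasma, leakier ones fire in more patients -- the
#'   trade-off that gives panel growth diminishing, then negative,
#'   returns.
#' @param tumor_signal_by_stage Named multipliers (I--IV) applied to the
#'   plasma tumor-signal probability; defaults `c(1, 1, 1.5, 3)` keep the
#'   stage I/II count ranges overlapping while stage IV is clearly higher.
#' @param plasma_case_signal Baseline per-marker probability of tumor
#'   signal in a stage-I case of median burden.
#' @param burden_dispersion Log-sd of the per-patient tumor-burden factor.
#' @param plasma_case_magnitude_mean Mean MEPM of plasma tumor signal when
#'   present.
#' @param tissue_hyper_effect Fold elevation of mean MEPM at planted
#'   markers in cancer tissue over adjacent tissue (must exceed 2, the
#'   differential-methylation fold-change filter).
#' @param tissue_base_occupancy Occupancy probability of any site in
#'   tissue (both adjacent tissue everywhere and cancer tissue at
#'   non-marker sites).
#' @param tissue_cancer_occupancy Occupancy probability of planted markers
#'   in cancer tissue.
#' @param dispersion Log-sd of all signal magnitudes.
#' @param decoy_motif_far_fraction Fraction of non-marker sites placed at
#'   60 bp or more from the nearest CGCGCGG motif (so they fail the motif
#'   proximity criterion); planted markers are always closer than 60 bp.
#' @param leaky_marker_fraction Per cancer, the number of additional
#'   "leaky" cancer-responsive sites is this fraction of the panel size.
#'   Leaky sites are hypermethylated in tumor tissue and carry plasma
#'   tumor signal like planted markers, but their normal-plasma
#'   background positivity is elevated (drawn per site from
#'   `leaky_bg_range`), so they fail the background-frequency selection
#'   criterion -- the site class that criterion exists to remove, and the
#'   reason oversized panels lose specificity.
#' @param leaky_bg_range Lower/upper bound of the per-site background
#'   positivity of leaky sites.
#' @param cimp_fraction Fraction of tumors in the high-methylation (CIMP)
#'   subgroup.
#' @param cimp_boost Magnitude multiplier applied to planted-marker signal
#'   in CIMP tumors.
#' @param seed Integer master seed; every simulator derives its stream
#'   from it, so a config fixes the whole synthetic study.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_sites = 3000,
                       markers_per_cancer = c(PAC = 120, HCC = 38,
                                              CRC = 80, GC = 153),
                       shared_marker_fraction = 0.25,
                       background_pos_freq = 0.01,
                       background_magnitude_mean = 5,
                       background_sample_sd = 0.5,
                       marker_bg_sd = 0.8,
                       marker_sensitivity_tradeoff = 0.5,
                       tumor_signal_by_stage = c(I = 1, II = 1,
                                                 III = 1.5, IV = 3),
                       plasma_case_signal = 0.25,
                       burden_dispersion = 0.8,
                       plasma_case_magnitude_mean = 4,
                       tissue_hyper_effect = 8,
                       tissue_base_occupancy = 0.5,
                       tissue_cancer_occupancy = 0.9,
                       dispersion = 0.8,
                       decoy_motif_far_fraction = 0.5,
                       leaky_marker_fraction = 0.5,
                       leaky_bg_range = c(0.15, 0.40),
                       cimp_fraction = 2 / 33,
                       cimp_boost = 3,
                       seed = 101L) {
  cfg <- list(n_sites = as.integer(n_sites),
              markers_per_cancer = markers_per_cancer,
              shared_marker_fraction = shared_marker_fraction,
              background_pos_freq = background_pos_freq,
              background_magnitude_mean = background_magnitude_mean,
              background_sample_sd = background_sample_sd,
              marker_bg_sd = marker_bg_sd,
              marker_sensitivity_tradeoff = marker_sensitivity_tradeoff,
              tumor_signal_by_stage = tumor_signal_by_stage,
              plasma_case_signal = plasma_case_signal,
              burden_dispersion = burden_dispersion,
              plasma_case_magnitude_mean = plasma_case_magnitude_mean,
              tissue_hyper_effect = tissue_hyper_effect,
              tissue_base_occupancy = tissue_base_occupancy,
              tissue_cancer_occupancy = tissue_cancer_occupancy,
              dispersion = dispersion,
              decoy_motif_far_fraction = decoy_motif_far_fraction,
              leaky_marker_fraction = leaky_marker_fraction,
              leaky_bg_range = leaky_bg_range,
              cimp_fraction = cimp_fraction,
              cimp_boost = cimp_boost,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_sites >= 1,
    setequal(names(cfg$markers_per_cancer), cancer_types()),
    all(cfg$markers_per_cancer >= 1),
    sum(cfg$markers_per_cancer) <= cfg$n_sites,
    cfg$shared_marker_fraction >= 0, cfg$shared_marker_fraction <= 1,
    cfg$background_pos_freq >= 0, cfg$background_pos_freq < 0.05,
    cfg$background_magnitude_mean > 0,
    cfg$background_sample_sd >= 0,
    cfg$marker_bg_sd >= 0, cfg$marker_sensitivity_tradeoff >= 0,
    setequal(names(cfg$tumor_signal_by_stage), c("I", "II", "III", "IV")),
    all(cfg$tumor_signal_by_stage >= 0),
    cfg$plasma_case_signal > 0, cfg$plasma_case_signal <= 1,
    cfg$burden_dispersion >= 0,
    cfg$plasma_case_magnitude_mean > 0,
    cfg$tissue_hyper_effect > 2,
    cfg$tissue_base_occupancy > 0, cfg$tissue_base_occupancy <= 1,
    cfg$tissue_cancer_occupancy > 0, cfg$tissue_cancer_occupancy <= 1,
    cfg$dispersion > 0,
    cfg$decoy_motif_far_fraction >= 0, cfg$decoy_motif_far_fraction <= 1,
    cfg$leaky_marker_fraction >= 0,
    length(cfg$leaky_bg_range) == 2, cfg$leaky_bg_range[1] >= 0.05,
    cfg$leaky_bg_range[2] <= 0.9,
    sum(round((1 + cfg$leaky_marker_fraction) * cfg$markers_per_cancer)) <=
      cfg$n_sites,
    cfg$cimp_fraction >= 0, cfg$cimp_fraction <= 1,
    cfg$cimp_boost > 1
  )
  invisible(cfg)
}

# Log-normal draws with a given arithmetic mean.
rlnorm_mean <- function(n, mean, sdlog) {
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a CpG-site catalog with planted marker panels
#'
#' Creates `n_sites` synthetic CpG sites and plants one disjoint marker
#' panel per cancer type; within each panel, a `shared_marker_fraction`
#' subset is pan-cancer responsive (it fires in tumors of any type, the
#' way many CpG-island hypermethylation events recur across cancers)
#' while the rest is type-private. Planted markers are
#' always placed closer than 60 bp to the nearest CGCGCGG motif; a
#' configurable fraction of the remaining decoy sites is placed at 60 bp
#' or farther so the motif-proximity criterion has teeth.
#'
#' @param config A [sim_config()].
#' @param seed Seed for this draw; defaults to `config$seed`.
#' @return List of class `site_simulation` with elements `catalog` (site
#'   catalog data frame), `planted_markers` (named list of site-id
#'   vectors, one per cancer type; panels are disjoint),
#'   `shared_markers` (per panel, the subset that is pan-cancer
#'   responsive), `leaky_markers` (the leaky cancer-responsive site ids),
#'   `leaky_bg` (their background positivities), `site_bg` and
#'   `site_sensitivity` (per responsive site).
#' @export
simulate_site_catalog <- function(config, seed = config$seed) {
  validate_sim_config(config)
  n <- config$n_sites
  mk <- config$markers_per_cancer[cancer_types()]
  with_seed(seed, {
    gene <- sprintf("SYNG%04d", seq_len(n))
    site_id <- sprintf("%s-%d_1_1", gene, seq_len(n))
    chrom <- paste0("chr", sample(1:22, n, replace = TRUE))
    start <- sample.int(2e8, n)
    width <- sample(80:400, n, replace = TRUE)
    idx <- sample.int(n)  # random placement of planted markers
    used <- 0
    planted <- lapply(mk, function(m) {
      out <- idx[used + seq_len(m)]
      used <<- used + m
      sort(out)
    })
    names(planted) <- names(mk)
    # within each panel, a fraction of markers is pan-cancer responsive
    shared <- lapply(planted, function(p)
      sort(p[seq_len(round(config$shared_marker_fraction * length(p)))]))
    leaky <- lapply(mk, function(m) {
      nl <- round(config$leaky_marker_fraction * m)
      out <- idx[used + seq_len(nl)]
      used <<- used + nl
      sort(out)
    })
    names(leaky) <- names(mk)
    leaky_all <- unlist(leaky, use.names = FALSE)
    leaky_bg <- stats::runif(length(leaky_all), config$leaky_bg_range[1],
                             config$leaky_bg_range[2])
    planted_all <- sort(unique(unlist(planted)))
    planted_bg <- pmin(0.045, pmax(5e-4, rlnorm_mean(
      length(planted_all), config$background_pos_freq, config$marker_bg_sd)))
    is_marker <- seq_len(n) %in% c(planted_all, leaky_all)
    motif <- integer(n)
    motif[is_marker] <- sample(0:59, sum(is_marker), replace = TRUE)
    far <- !is_marker &
      stats::runif(n) < config$decoy_motif_far_fraction
    motif[far] <- sample(60:500, sum(far), replace = TRUE)
    motif[!is_marker & !far] <- sample(0:59, sum(!is_marker & !far),
                                       replace = TRUE)
    catalog <- data.frame(site_id = site_id, chrom = chrom,
                          start = start, end = start + width,
                          motif_distance_bp = motif, gene_label = gene,
                          stringsAsFactors = FALSE)
    planted_ids <- lapply(planted, function(i) site_id[i])
    shared_ids <- lapply(shared, function(i) site_id[i])
    leaky_ids <- lapply(leaky, function(i) site_id[i])
    names(leaky_bg) <- site_id[leaky_all]
    names(planted_bg) <- site_id[planted_all]
    site_bg <- c(planted_bg, leaky_bg)
    # sensitivity rises with background level; planted mean normalized to 1
    raw_sens <- pmin((site_bg / config$background_pos_freq) ^
                       config$marker_sensitivity_tradeoff, 2.5)
    site_sensitivity <- raw_sens / mean(raw_sens[names(planted_bg)])
    structure(list(catalog = catalog, planted_markers = planted_ids,
                   shared_markers = shared_ids,
                   leaky_markers = leaky_ids, leaky_bg = leaky_bg,
                   site_bg = site_bg,
                   site_sensitivity = site_sensitivity),
              class = "site_simulation")
  })
}

# Sites a tumor of `cancer` produces signal at: its own planted panel and
# leaky sites, plus (in the multi-cancer setting) the pan-cancer-responsive
# (shared) subsets of the other panels.
responsive_sites <- function(catalog_sim, cancer, cross_shared = FALSE) {
  out <- c(catalog_sim$planted_markers[[cancer]],
           catalog_sim$leaky_markers[[cancer]])
  if (cross_shared) {
    other <- setdiff(names(catalog_sim$planted_markers), cancer)
    out <- c(out, unlist(catalog_sim$shared_markers[other],
                         use.names = FALSE))
  }
  out
}

# Background/tissue channel: Bernoulli occupancy times log-normal magnitude.
sim_channel <- function(n_samples, n_sites, occupancy, magnitude_mean, sdlog) {
  occ <- matrix(stats::rbinom(n_samples * n_sites, 1, occupancy),
                n_samples, n_sites)
  mag <- matrix(rlnorm_mean(n_samples * n_sites, magnitude_mean, sdlog),
                n_samples, n_sites)
  occ * mag
}

#' Simulate a paired cancer/adjacent tissue cohort
#'
#' Generates `n_pairs` tumor tissues with matched adjacent noncancerous
#' tissues. All tissue sites carry a common occupancy/magnitude background;
#' in tumors, the planted markers of `cancer` are elevated so that their
#' mean MEPM is `tissue_hyper_effect`-fold the adjacent-tissue mean (well
#' above the 10-MEPM selection floor at defaults). A `cimp_fraction` of
#' tumors get an extra `cimp_boost` magnitude multiplier at all planted
#' markers, forming the high-methylation (CIMP) subgroup.
#'
#' @param config A [sim_config()].
#' @param n_pairs Number of tumor/adjacent pairs (default 33).
#' @param cancer Cancer type whose panel is planted (default `"PAC"`).
#' @param catalog_sim Optional [simulate_site_catalog()] result to reuse.
#' @param seed Seed for the cohort draw; defaults to `config$seed + 1`.
#' @param cross_shared Also produce tumor signal at the other panels'
#'   pan-cancer-responsive subsets (default `FALSE`: a single-cancer
#'   study models only its own cancer's marker complement; the
#'   multi-cancer simulator turns this on).
#' @return List with `matrix` (a `meth_matrix`) and `ground_truth`
#'   (`planted_markers` plus a `sample_labels` data frame with the CIMP
#'   flags).
#' @export
simulate_tissue_cohort <- function(config, n_pairs = 33, cancer = "PAC",
                                   catalog_sim = NULL,
                                   seed = config$seed + 1L,
                                   cross_shared = FALSE) {
  validate_sim_config(config)
  stopifnot(n_pairs >= 1, cancer %in% cancer_types())
  if (is.null(catalog_sim)) catalog_sim <- simulate_site_catalog(config)
  catalog <- catalog_sim$catalog
  n_sites <- nrow(catalog)
  resp_ids <- responsive_sites(catalog_sim, cancer, cross_shared)
  marker_idx <- match(resp_ids, catalog$site_id)
  n_planted <- length(catalog_sim$planted_markers[[cancer]])
  adj_site_mean <- config$tissue_base_occupancy *
    config$background_magnitude_mean
  cancer_mag_mean <- adj_site_mean * config$tissue_hyper_effect /
    config$tissue_cancer_occupancy
  with_seed(seed, {
    tumor <- sim_channel(n_pairs, n_sites, config$tissue_base_occupancy,
                         config$background_magnitude_mean, config$dispersion)
    adj <- sim_channel(n_pairs, n_sites, config$tissue_base_occupancy,
                       config$background_magnitude_mean, config$dispersion)
    n_cimp <- round(config$cimp_fraction * n_pairs)
    cimp <- seq_len(n_pairs) %in% sample.int(n_pairs, n_cimp)
    boost <- ifelse(cimp, config$cimp_boost, 1)
    # CIMP = concerted hypermethylation of the planted panel: both the
    # signal magnitude and the per-marker occupancy rise (the zero rate
    # shrinks by the boost factor)
    p_occ <- ifelse(cimp,
                    1 - (1 - config$tissue_cancer_occupancy) /
                      config$cimp_boost,
                    config$tissue_cancer_occupancy)
    boost_m <- matrix(1, n_pairs, length(marker_idx))
    boost_m[, seq_len(n_planted)] <- boost
    occ_p <- matrix(config$tissue_cancer_occupancy, n_pairs,
                    length(marker_idx))
    occ_p[, seq_len(n_planted)] <- p_occ
    occ <- matrix(stats::rbinom(length(occ_p), 1, occ_p),
                  n_pairs, length(marker_idx))
    mag <- matrix(rlnorm_mean(length(occ_p), cancer_mag_mean,
                              config$dispersion),
                  n_pairs, length(marker_idx))
    sig <- occ * mag * boost_m
    tumor[, marker_idx] <- sig  # marker signal replaces the tissue baseline
    tumor_id <- sprintf("%s_T%02d", cancer, seq_len(n_pairs))
    adj_id <- sprintf("%s_N%02d", cancer, seq_len(n_pairs))
    stage <- sample(c("I", "II", "III", "IV"), n_pairs, replace = TRUE)
    samples <- data.frame(
      sample_id = c(tumor_id, adj_id),
      specimen = "tissue",
      condition = rep(c(cancer, "normal"), each = n_pairs),
      stage = c(stage, rep(NA_character_, n_pairs)),
      paired_id = c(adj_id, tumor_id),
      total_molecules = sample(2e5:2e6, 2 * n_pairs, replace = TRUE),
      stringsAsFactors = FALSE)
    values <- rbind(tumor, adj)
    rownames(values) <- samples$sample_id
    colnames(values) <- catalog$site_id
    labels <- data.frame(sample_id = samples$sample_id,
                         condition = samples$condition,
                         stage = samples$stage,
                         cimp_flag = c(cimp, rep(FALSE, n_pairs)),
                         stringsAsFactors = FALSE)
    list(matrix = meth_matrix(values, samples, catalog),
         ground_truth = list(planted_markers = catalog_sim$planted_markers,
                             sample_labels = labels))
  })
}

#' Simulate a plasma cohort of one cancer type plus normal controls
#'
#' Controls carry only sparse background signal: each site is positive
#' with probability `background_pos_freq` with log-normal magnitude. Cases
#' carry the same background plus a tumor channel at the planted markers
#' of `cancer`: each case draws a tumor-burden factor, and each marker is
#' positive with probability
#' `min(0.95, plasma_case_signal * stage multiplier * burden)`.
#'
#' @param config A [sim_config()].
#' @param n_cases_by_stage Named integer vector of case counts per stage;
#'   default `c(I = 8, II = 7, III = 8, IV = 7)` (a 30-case discovery
#'   cohort). Use an empty/zero vector for a pure normal set.
#' @param n_controls Number of normal plasma controls (default 31).
#' @param cancer Cancer type whose panel drives the case signal.
#' @param catalog_sim Optional [simulate_site_catalog()] result to reuse.
#' @param seed Seed; defaults to `config$seed + 2`.
#' @param id_prefix Prefix for sample ids (so independent cohorts drawn
#'   from the same config get distinct ids).
#' @param cross_shared See [simulate_tissue_cohort()].
#' @return List with `matrix` and `ground_truth` as in
#'   [simulate_tissue_cohort()].
#' @export
simulate_plasma_cohort <- function(config,
                                   n_cases_by_stage = c(I = 8, II = 7,
                                                        III = 8, IV = 7),
                                   n_controls = 31, cancer = "PAC",
                                   catalog_sim = NULL,
                                   seed = config$seed + 2L,
                                   id_prefix = "P",
                                   cross_shared = FALSE) {
  validate_sim_config(config)
  stopifnot(all(n_cases_by_stage >= 0), n_controls >= 0)
  if (is.null(catalog_sim)) catalog_sim <- simulate_site_catalog(config)
  catalog <- catalog_sim$catalog
  n_sites <- nrow(catalog)
  stages <- rep(names(n_cases_by_stage), n_cases_by_stage)
  n_cases <- length(stages)
  n_tot <- n_cases + n_controls
  if (n_tot == 0) stop("empty cohort requested", call. = FALSE)
  marker_idx <- match(catalog_sim$planted_markers[[cancer]], catalog$site_id)
  with_seed(seed, {
    # per-sample background scale (sample quality variation), mean 1
    g <- exp(stats::rnorm(n_tot, -config$background_sample_sd^2 / 2,
                          config$background_sample_sd))
    # per-site background rate: generic sites at background_pos_freq,
    # responsive sites (planted/leaky of any cancer) at their own level
    site_rate <- rep(config$background_pos_freq, n_sites)
    bg_known <- match(names(catalog_sim$site_bg), catalog$site_id)
    site_rate[bg_known] <- catalog_sim$site_bg
    p_bg <- pmin(0.9, outer(g, site_rate))
    occ_bg <- matrix(stats::rbinom(length(p_bg), 1, p_bg), n_tot, n_sites)
    mag_bg <- matrix(rlnorm_mean(n_tot * n_sites,
                                 config$background_magnitude_mean,
                                 config$dispersion), n_tot, n_sites)
    values <- occ_bg * mag_bg
    burden <- numeric(0)
    if (n_cases > 0) {
      burden <- exp(stats::rnorm(n_cases, 0, config$burden_dispersion))
      p_case <- pmin(0.95, config$plasma_case_signal *
                       config$tumor_signal_by_stage[stages] * burden)
      # tumor signal hits the planted panel and the cancer's leaky sites,
      # scaled by each marker's responsiveness
      sig_ids <- responsive_sites(catalog_sim, cancer, cross_shared)
      sig_idx <- match(sig_ids, catalog$site_id)
      sens <- catalog_sim$site_sensitivity[sig_ids]
      p_sig <- pmin(0.95, outer(p_case, sens))
      occ <- matrix(stats::rbinom(length(p_sig), 1, p_sig),
                    n_cases, length(sig_idx))
      mag <- matrix(rlnorm_mean(n_cases * length(sig_idx),
                                config$plasma_case_magnitude_mean,
                                config$dispersion),
                    n_cases, length(sig_idx))
      values[seq_len(n_cases), sig_idx] <-
        values[seq_len(n_cases), sig_idx] + occ * mag
    }
    ids <- c(sprintf("%s_case%03d", id_prefix, seq_len(n_cases)),
             sprintf("%s_ctrl%03d", id_prefix, seq_len(n_controls)))
    samples <- data.frame(
      sample_id = ids,
      specimen = "plasma",
      condition = c(rep(cancer, n_cases), rep("normal", n_controls)),
      stage = c(stages, rep(NA_character_, n_controls)),
      paired_id = NA_character_,
      total_molecules = sample(5e4:5e5, n_tot, replace = TRUE),
      stringsAsFactors = FALSE)
    rownames(values) <- ids
    colnames(values) <- catalog$site_id
    labels <- data.frame(sample_id = ids, condition = samples$condition,
                         stage = samples$stage, cimp_flag = FALSE,
                         stringsAsFactors = FALSE)
    list(matrix = meth_matrix(values, samples, catalog),
         ground_truth = list(planted_markers = catalog_sim$planted_markers,
                             sample_labels = labels,
                             burden = stats::setNames(
                               burden, utils::head(ids, n_cases))))
  })
}

#' Simulate a multi-cancer plasma cohort
#'
#' Draws plasma cases for each of the four cancer types plus normal
#' controls over one shared site catalog. A case of type T receives tumor
#' signal at T's own panel and leaky sites plus the pan-cancer-responsive
#' subsets of the other panels; at other types' private markers it shows
#' background only.
#'
#' @param config A [sim_config()].
#' @param n_per_cancer Named integer vector of case counts per cancer type
#'   (default 25 each). Stages cycle I--IV within each type.
#' @param n_controls Number of normal plasma controls (default 25).
#' @param catalog_sim Optional [simulate_site_catalog()] result to reuse.
#' @param seed Seed; defaults to `config$seed + 3`.
#' @return List with `matrix` and `ground_truth`.
#' @export
simulate_multicancer_plasma <- function(config,
                                        n_per_cancer = c(PAC = 25, HCC = 25,
                                                         CRC = 25, GC = 25),
                                        n_controls = 25,
                                        catalog_sim = NULL,
                                        seed = config$seed + 3L) {
  validate_sim_config(config)
  stopifnot(setequal(names(n_per_cancer), cancer_types()),
            all(n_per_cancer >= 0), n_controls >= 0)
  if (is.null(catalog_sim)) catalog_sim <- simulate_site_catalog(config)
  parts <- list()
  for (i in seq_along(cancer_types())) {
    ct <- cancer_types()[i]
    n_ct <- n_per_cancer[[ct]]
    if (n_ct == 0) next
    stage_counts <- table(factor(rep_len(c("I", "II", "III", "IV"), n_ct),
                                 levels = c("I", "II", "III", "IV")))
    parts[[ct]] <- simulate_plasma_cohort(
      config, n_cases_by_stage = c(stage_counts), n_controls = 0,
      cancer = ct, catalog_sim = catalog_sim, seed = seed + i,
      id_prefix = ct, cross_shared = TRUE)
  }
  ctrl <- simulate_plasma_cohort(
    config, n_cases_by_stage = c(I = 0, II = 0, III = 0, IV = 0),
    n_controls = n_controls, catalog_sim = catalog_sim,
    seed = seed + 5L, id_prefix = "MC")
  parts[["controls"]] <- ctrl
  values <- do.call(rbind, lapply(parts, function(p) p$matrix$values))
  samples <- do.call(rbind, lapply(parts, function(p) p$matrix$samples))
  labels <- do.call(rbind, lapply(parts, function(p)
    p$ground_truth$sample_labels))
  rownames(samples) <- rownames(labels) <- NULL
  list(matrix = meth_matrix(values, samples, catalog_sim$catalog),
       ground_truth = list(planted_markers = catalog_sim$planted_markers,
                           sample_labels = labels))
}
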