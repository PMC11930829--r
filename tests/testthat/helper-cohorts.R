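# Shared fixtures, built once per test run. The "packaged" study is the
# default sim_config() (seed 101); every piece is derived lazily and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache, inherits = FALSE)
}

default_config <- function() fixture("cfg", function() sim_config())

default_catalog <- function() {
  fixture("cat_sim", function() simulate_site_catalog(default_config()))
}

default_tissue <- function() {
  fixture("tissue", function() {
    simulate_tissue_cohort(default_config(), n_pairs = 33,
                           catalog_sim = default_catalog())
  })
}

default_plasma <- function() {
  fixture("plasma", function() {
    simulate_plasma_cohort(default_config(), catalog_sim = default_catalog())
  })
}

# independent preselection normal set (n = 96), as used for cutoffs/ranking
default_preselection <- function() {
  fixture("norm96", function() {
    cfg <- default_config()
    simulate_plasma_cohort(cfg,
                           n_cases_by_stage = c(I = 0, II = 0, III = 0,
                                                IV = 0),
                           n_controls = 96,
                           catalog_sim = default_catalog(),
                           seed = cfg$seed + 20L, id_prefix = "CAL")
  })
}

default_selected_panel <- function() {
  fixture("panel", function() {
    select_cancer_markers(default_tissue()$matrix, default_plasma()$matrix,
                          default_catalog()$catalog)
  })
}

# small hand-made matrix: 4 plasma samples (2 cases, 2 normals), 3 sites
toy_matrix <- function(values = rbind(c(10, 0, 2),
                                      c(8, 1, 0),
                                      c(0, 0, 0),
                                      c(0, 0.2, 0))) {
  ids <- c("case1", "case2", "norm1", "norm2")
  rownames(values) <- ids
  colnames(values) <- c("s1", "s2", "s3")
  samples <- data.frame(
    sample_id = ids, specimen = "plasma",
    condition = c("PAC", "PAC", "normal", "normal"),
    stage = c("I", "III", NA, NA), paired_id = NA_character_,
    total_molecules = 5e4, stringsAsFactors = FALSE)
  meth_matrix(values, samples)
}

# well-separated Gaussian blobs on the log scale, as a meth_matrix
blob_matrix <- function(centers, n_each, n_feat = 50, noise = 1, seed = 1) {
  set.seed(seed)
  v <- do.call(rbind, lapply(seq_along(centers), function(i)
    matrix(stats::rnorm(n_each * n_feat, centers[i], noise),
           n_each, n_feat)))
  v <- pmax(v, 0)
  ids <- sprintf("B%02d", seq_len(nrow(v)))
  rownames(v) <- ids
  colnames(v) <- sprintf("site%03d", seq_len(n_feat))
  samples <- data.frame(sample_id = ids, specimen = "tissue",
                        condition = "PAC", stage = "II",
                        paired_id = NA_character_, total_molecules = 1e5,
                        stringsAsFactors = FALSE)
  meth_matrix(expm1(v), samples)  # log1p inside consensus recovers v
}

# brute-force two-sided Mann-Whitney p-value: enumerate all assignments of
# the pooled values, scoring U by direct pairwise comparison
mww_permutation_oracle <- function(a, b) {
  n_a <- length(a)
  pooled <- c(a, b)
  n <- length(pooled)
  u_of <- function(x, y) {
    sum(vapply(x, function(xi) sum(xi > y) + 0.5 * sum(xi == y),
               numeric(1)))
  }
  u_obs <- u_of(a, b)
  mu <- n_a * (n - n_a) / 2
  combos <- utils::combn(n, n_a)
  u_all <- apply(combos, 2, function(idx) {
    u_of(pooled[idx], pooled[-idx])
  })
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# hand-computed Benjamini-Hochberg step-up
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

# O(n^2) pairwise AUC oracle
auc_oracle <- function(scores, labels) {
  cases <- scores[labels == 1]
  ctrls <- scores[labels == 0]
  tot <- 0
  for (x in cases) tot <- tot + sum(x > ctrls) + 0.5 * sum(x == ctrls)
  tot / (length(cases) * length(ctrls))
}
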