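# Shared fixtures, built in code at test time.

# snp_matrix from a plain matrix, auto-naming samples/markers
snp_fix <- function(d) {
  if (is.null(rownames(d))) rownames(d) <- sprintf("s%02d", seq_len(nrow(d)))
  if (is.null(colnames(d))) colnames(d) <- sprintf("m%02d", seq_len(ncol(d)))
  snp_matrix(d)
}

# Unstructured dosage matrix with named dims
rand_dosages <- function(n, p, seed = 1, maf = c(0.1, 0.9)) {
  withr::with_seed(seed, {
    freq <- stats::runif(p, maf[1], maf[2])
    d <- matrix(stats::rbinom(n * p, 2, rep(freq, each = n)), n, p)
    storage.mode(d) <- "double"
    rownames(d) <- sprintf("s%03d", seq_len(n))
    colnames(d) <- sprintf("m%04d", seq_len(p))
    d
  })
}

# Small structured panel reused across files (computed once per run)
.panel_cache <- new.env(parent = emptyenv())
small_panel <- function() {
  if (is.null(.panel_cache$panel)) {
    cfg <- sim_config(n_populations = 24, clones_per_population = 8,
                      n_markers = 1200, n_qtl = 80, h2_clone_mean = 0.85,
                      fst = 0.2, missing_rate = 0.05, rng_seed = 101L)
    .panel_cache$panel <- simulate_panel(cfg)
  }
  .panel_cache$panel
}

# Flat temperature series helper
temp_series <- function(t_min, t_max, start = as.Date("2010-03-01")) {
  n <- max(length(t_min), length(t_max))
  data.frame(date = start + seq_len(n) - 1,
             t_min_f = rep_len(t_min, n), t_max_f = rep_len(t_max, n))
}
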