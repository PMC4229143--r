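#' Configuration for the clonal-trial simulator
#'
#' Defaults emulate a diverse multi-population association panel of a
#' clonally propagated outcrossing grass: 66 source populations of 10
#' clones each, falling into 3 structure clusters at moderate
#' differentiation (Fst 0.2), genotyped at 12,000 biallelic SNPs with
#' allele frequencies bounded away from fixation (floor 0.05) and a 10%
#' missing-call rate typical of GBS, phenotyped in a randomized complete
#' block design of 2 replicates over 3 years. The trait is additive over
#' `n_qtl` markers with a target clone-mean repeatability of 0.85; genetic
#' values are scaled to unit variance, so the year/block/genotype-by-year
#' SDs are on that scale.
#'
#' @param n_populations,clones_per_population panel layout.
#' @param n_clusters,fst structure clusters and between-cluster
#'   differentiation; populations diverge from their cluster at `fst / 5`.
#' @param n_markers,maf_floor,missing_rate marker panel settings.
#' @param n_qtl,h2_clone_mean trait architecture: causal marker count and
#'   target clone-mean repeatability in (0, 1).
#' @param n_years,n_reps trial design.
#' @param mu trait grand mean (kept well above zero so BLUPs are positive
#'   for Box-Cox).
#' @param sigma_year,sigma_block,sigma_gxy SDs of the year, block-in-year
#'   and genotype-by-year effects, on the unit genetic-SD scale.
#' @param rng_seed master seed; one seed reproduces the whole panel.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_populations = 66, clones_per_population = 10,
                       n_clusters = 3, fst = 0.2,
                       n_markers = 12000, maf_floor = 0.05,
                       missing_rate = 0.1,
                       n_qtl = 200, h2_clone_mean = 0.85,
                       n_years = 3, n_reps = 2, mu = 10,
                       sigma_year = 0.5, sigma_block = 0.25,
                       sigma_gxy = 0.25, rng_seed = 1L) {
  cfg <- list(n_populations = n_populations,
              clones_per_population = clones_per_population,
              n_clusters = n_clusters, fst = fst, n_markers = n_markers,
              maf_floor = maf_floor, missing_rate = missing_rate,
              n_qtl = n_qtl, h2_clone_mean = h2_clone_mean,
              n_years = n_years, n_reps = n_reps, mu = mu,
              sigma_year = sigma_year, sigma_block = sigma_block,
              sigma_gxy = sigma_gxy, rng_seed = as.integer(rng_seed))
  if (cfg$n_qtl > cfg$n_markers) stop("n_qtl must not exceed n_markers")
  if (cfg$h2_clone_mean <= 0 || cfg$h2_clone_mean >= 1)
    stop("h2_clone_mean must lie in (0, 1)")
  if (cfg$fst <= 0 || cfg$fst >= 1) stop("fst must lie in (0, 1)")
  if (cfg$maf_floor < 0 || cfg$maf_floor >= 0.5)
    stop("maf_floor must lie in [0, 0.5)")
  if (any(c(cfg$sigma_year, cfg$sigma_block, cfg$sigma_gxy) < 0))
    stop("effect SDs must be >= 0")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  structure(cfg, class = "sim_config")
}

#' Simulate hierarchical population structure
#'
#' Balding-Nichols allele-frequency model: ancestral frequencies uniform on
#' \[`maf_floor`, 1 - `maf_floor`\]; cluster frequencies drawn
#' \eqn{Beta(p(1-F)/F, (1-p)(1-F)/F)} at `F = fst`; population frequencies
#' drawn around their cluster at the smaller within-cluster `fst / 5`.
#' Mirrors a panel whose major genetic subdivisions (ecotype/ploidy
#' clusters) dominate the leading principal components.
#'
#' @param cfg a [sim_config]; uses `cfg$rng_seed` unless `rng_seed` given.
#' @param rng_seed optional seed override.
#' @return list with `pop_freqs` (populations x markers),
#'   `cluster_of_pop` (integer labels), `ancestral` frequencies.
#' @export
simulate_structure <- function(cfg, rng_seed = cfg$rng_seed) {
  withr::with_seed(rng_seed, {
    p0 <- stats::runif(cfg$n_markers, cfg$maf_floor, 1 - cfg$maf_floor)
    bn_draw <- function(p, F) {
      a <- p * (1 - F) / F
      b <- (1 - p) * (1 - F) / F
      stats::rbeta(length(p), a, b)
    }
    cluster_freqs <- t(vapply(seq_len(cfg$n_clusters),
                              function(c) bn_draw(p0, cfg$fst),
                              numeric(cfg$n_markers)))
    cluster_of_pop <- rep_len(seq_len(cfg$n_clusters), cfg$n_populations)
    f_within <- cfg$fst / 5
    pop_freqs <- t(vapply(seq_len(cfg$n_populations), function(i) {
      bn_draw(cluster_freqs[cluster_of_pop[i], ], f_within)
    }, numeric(cfg$n_markers)))
    # keep frequencies usable for binomial draws
    pop_freqs <- pmin(pmax(pop_freqs, 1e-4), 1 - 1e-4)
    rownames(pop_freqs) <- sprintf("POP%02d", seq_len(cfg$n_populations))
    list(pop_freqs = pop_freqs, cluster_of_pop = cluster_of_pop,
         ancestral = p0)
  })
}

#' Simulate panel genotypes from population allele frequencies
#'
#' Each clone is a distinct genotype drawn binomial(2, p) per marker from
#' its population's frequencies (diploidized dosages); an optional
#' missing-at-random mask emulates GBS missingness.
#'
#' @param structure output of [simulate_structure()].
#' @param cfg a [sim_config].
#' @param rng_seed optional seed override.
#' @return a [snp_matrix]; sample ids `POPxx_Cyy`.
#' @export
simulate_genotypes <- function(structure, cfg, rng_seed = cfg$rng_seed + 1L) {
  withr::with_seed(rng_seed, {
    pf <- structure$pop_freqs
    n_per <- cfg$clones_per_population
    rows <- lapply(seq_len(nrow(pf)), function(i) {
      matrix(stats::rbinom(n_per * cfg$n_markers, 2, rep(pf[i, ], each = n_per)),
             nrow = n_per)
    })
    d <- do.call(rbind, rows)
    storage.mode(d) <- "double"
    rownames(d) <- as.vector(t(outer(rownames(pf),
                                     sprintf("C%02d", seq_len(n_per)),
                                     paste, sep = "_")))
    colnames(d) <- sprintf("M%05d", seq_len(cfg$n_markers))
    if (cfg$missing_rate > 0) {
      mask <- matrix(stats::runif(length(d)) < cfg$missing_rate, nrow = nrow(d))
      # never blank out a whole marker
      full_cols <- which(colSums(!mask) == 0)
      mask[1, full_cols] <- FALSE
      d[mask] <- NA_real_
    }
    snp_matrix(d)
  })
}

#' Population of each simulated genotype
#'
#' @param m a simulated [snp_matrix] with `POPxx_Cyy` sample ids.
#' @return named character vector genotype -> population.
#' @export
sim_population_map <- function(m) {
  stats::setNames(sub("_C\\d+$", "", m$samples), m$samples)
}

#' Simulate plot-level phenotypes with known architecture
#'
#' Draws `n_qtl` causal markers with normal effects, scales the additive
#' genetic values to unit variance, then solves for the residual variance
#' that makes the clone-mean repeatability
#' \eqn{\sigma^2_g / (\sigma^2_g + \sigma^2_{gy}/y + \sigma^2_e/(yr))}
#' equal the target. Plot values are
#' \eqn{\mu + year + block(year) + g + (g \times year) + \varepsilon},
#' emitted for every genotype x year x replicate.
#'
#' @param m genotypes as a [snp_matrix] (missing calls are mean-imputed for
#'   the genetic values only; the returned table is unaffected).
#' @param cfg a [sim_config].
#' @param trait trait name for the records.
#' @param rng_seed optional seed override.
#' @return list with `trial` (a [trial_table]) and `truth`: `qtl_ids`,
#'   `effects`, `genetic_values`, `realized_h2`, `sigma2` (the generating
#'   variance components).
#' @export
simulate_phenotypes <- function(m, cfg, trait = "trait",
                                rng_seed = cfg$rng_seed + 2L) {
  y_ <- cfg$n_years; r_ <- cfg$n_reps
  target_noise <- 1 / cfg$h2_clone_mean - 1       # sigma2_gy/y + sigma2_e/(y r), at sigma2_g = 1
  sigma2_e <- y_ * r_ * (target_noise - cfg$sigma_gxy^2 / y_)
  if (sigma2_e < 0)
    stop(sprintf(paste0("h2_clone_mean = %.3f unattainable with sigma_gxy = %.3f: ",
                        "feasible h2 <= %.3f"),
                 cfg$h2_clone_mean, cfg$sigma_gxy,
                 1 / (1 + cfg$sigma_gxy^2 / y_)))
  withr::with_seed(rng_seed, {
    dos <- m$dosages
    if (anyNA(dos)) {
      mu_col <- colMeans(dos, na.rm = TRUE)
      idx <- which(is.na(dos), arr.ind = TRUE)
      dos[idx] <- mu_col[idx[, 2]]
    }
    n <- nrow(dos)
    if (cfg$n_qtl > 0) {
      usable <- which(apply(dos, 2, stats::sd) > 0)
      if (length(usable) < cfg$n_qtl)
        stop("not enough polymorphic markers for n_qtl = ", cfg$n_qtl)
      qtl <- sort(sample(usable, cfg$n_qtl))
      beta <- stats::rnorm(cfg$n_qtl)
      g_raw <- drop(dos[, qtl, drop = FALSE] %*% beta)
      sd_g <- stats::sd(g_raw)
      beta <- beta / sd_g
      g <- (g_raw - mean(g_raw)) / sd_g
      sigma2_g <- 1
    } else {
      qtl <- integer(0); beta <- numeric(0)
      g <- rep(0, n); sigma2_g <- 0
    }
    year_eff <- stats::rnorm(y_, 0, cfg$sigma_year)
    block_eff <- matrix(stats::rnorm(y_ * r_, 0, cfg$sigma_block), y_, r_)
    gxy <- matrix(stats::rnorm(n * y_, 0, cfg$sigma_gxy), n, y_)
    rec <- expand.grid(rep = seq_len(r_), year = seq_len(y_),
                       geno = seq_len(n), KEEP.OUT.ATTRS = FALSE)
    eps <- stats::rnorm(nrow(rec), 0, sqrt(sigma2_e))
    value <- cfg$mu + year_eff[rec$year] +
      block_eff[cbind(rec$year, rec$rep)] + g[rec$geno] +
      gxy[cbind(rec$geno, rec$year)] + eps
    pop <- sub("_C\\d+$", "", m$samples)
    trial <- trial_table(data.frame(
      genotype_id = m$samples[rec$geno],
      population_id = pop[rec$geno],
      year = 2008L + rec$year,
      field_id = "F1",
      block_id = paste0("B", rec$rep),
      trait = trait,
      value = value,
      stringsAsFactors = FALSE))
    realized_h2 <- if (sigma2_g == 0) 0 else
      sigma2_g / (sigma2_g + cfg$sigma_gxy^2 / y_ + sigma2_e / (y_ * r_))
    truth <- list(qtl_ids = colnames(dos)[qtl], effects = beta,
                  genetic_values = stats::setNames(g, m$samples),
                  realized_h2 = realized_h2,
                  sigma2 = c(genotype = sigma2_g,
                             genotype_x_year = cfg$sigma_gxy^2,
                             year = cfg$sigma_year^2,
                             block_in_year = cfg$sigma_block^2,
                             residual = sigma2_e))
    list(trial = trial, truth = truth)
  })
}

#' Simulate a complete structured clonal panel
#'
#' Structure, genotypes and phenotypes from one master seed; the building
#' blocks use `rng_seed`, `rng_seed + 1`, `rng_seed + 2` so a single seed
#' reproduces the whole panel bit-for-bit.
#'
#' @param cfg a [sim_config].
#' @param trait trait name.
#' @return list with `geno` ([snp_matrix]), `trial` ([trial_table]),
#'   `truth`, `structure`, and `cfg`.
#' @export
simulate_panel <- function(cfg = sim_config(), trait = "trait") {
  str_ <- simulate_structure(cfg)
  geno <- simulate_genotypes(str_, cfg)
  ph <- simulate_phenotypes(geno, cfg, trait = trait)
  list(geno = geno, trial = ph$trial, truth = ph$truth,
       structure = str_, cfg = cfg)
}

#' Write simulation truth as JSON
#'
#' @param truth the `truth` element of [simulate_phenotypes()] output.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sim_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
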