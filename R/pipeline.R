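#' Validate a run configuration
#'
#' Reads a YAML (or JSON) run configuration, checks it against the schema,
#' fills defaults, and reports every problem at once rather than stopping
#' at the first. A configuration either names input files
#' (`genotype_file`, `phenotype_file`) or carries a `simulate` block of
#' [sim_config()] fields.
#'
#' @param path path to a YAML/JSON config file, or an equivalent named list.
#' @return a validated `run_config` list with all defaults filled; the
#'   defaults actually applied are recorded in attribute `"defaults_used"`.
#' @export
validate_config <- function(path) {
  cfg <- if (is.character(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    yaml::read_yaml(path)
  } else as.list(path)
  known <- c("genotype_file", "phenotype_file", "simulate", "traits",
             "models", "alpha", "k_folds", "k_pcs", "maf_threshold",
             "imputation", "outlier_cutoff", "boxcox", "rng_seed",
             "n_inner_folds", "out_dir")
  defaults <- list(models = c("rrblup", "lasso", "elastic_net"),
                   alpha = 0.5, k_folds = 10, k_pcs = 2,
                   maf_threshold = 0.05, imputation = "marker_mean",
                   outlier_cutoff = 4, boxcox = TRUE, rng_seed = 1L,
                   n_inner_folds = 5, out_dir = "switchgs_run")
  problems <- character(0)
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    problems <- c(problems, paste("unknown key(s):",
                                  paste(unknown, collapse = ", ")))
  used <- setdiff(names(defaults), names(cfg))
  for (k in used) cfg[[k]] <- defaults[[k]]
  has_files <- !is.null(cfg$genotype_file) || !is.null(cfg$phenotype_file)
  if (has_files) {
    for (k in c("genotype_file", "phenotype_file")) {
      if (is.null(cfg[[k]]))
        problems <- c(problems, paste(k, "is required when loading data"))
      else if (!file.exists(cfg[[k]]))
        problems <- c(problems, paste0(k, " does not exist: ", cfg[[k]]))
    }
    if (!is.null(cfg$simulate))
      problems <- c(problems, "give input files or a simulate block, not both")
  } else if (is.null(cfg$simulate)) {
    problems <- c(problems, "config needs input files or a simulate block")
  }
  if (!is.null(cfg$traits)) {
    if (anyDuplicated(cfg$traits))
      problems <- c(problems, "duplicate trait names")
  }
  if (!is.numeric(cfg$alpha) || cfg$alpha < 0 || cfg$alpha > 1)
    problems <- c(problems, "alpha must lie in [0, 1]")
  if (!all(cfg$models %in% c("rrblup", "lasso", "elastic_net")))
    problems <- c(problems, "models must be among rrblup, lasso, elastic_net")
  if (length(cfg$models) == 0)
    problems <- c(problems, "model list must be non-empty")
  if (!cfg$imputation %in% c("marker_mean", "marker_mode", "knn"))
    problems <- c(problems, "imputation must be marker_mean, marker_mode or knn")
  if (cfg$maf_threshold < 0 || cfg$maf_threshold > 0.5)
    problems <- c(problems, "maf_threshold must lie in [0, 0.5]")
  if (cfg$k_folds < 2) problems <- c(problems, "k_folds must be >= 2")
  if (cfg$k_pcs < 1) problems <- c(problems, "k_pcs must be >= 1")
  if (length(problems))
    stop("invalid configuration:\n  - ",
         paste(problems, collapse = "\n  - "))
  if (!is.null(cfg$simulate))
    cfg$simulate <- do.call(sim_config, cfg$simulate)
  attr(cfg, "defaults_used") <- defaults[used]
  class(cfg) <- "run_config"
  cfg
}

pipeline_log <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

#' Run the full genomic-selection pipeline
#'
#' Simulate or load the panel, prepare phenotypes (outlier screen, BLUPs,
#' repeatability, Box-Cox), prepare genotypes (imputation, full-set PCA,
#' MAF filtering on each trait's evaluated subset), residualize on the
#' leading PCs, run population-grouped k-fold cross-validation for every
#' trait x model, and write all artifacts to the run directory: BLUP table
#' with JSON sidecar, PC scores, fold plan, per-trait CV tables, a summary
#' table (trait x model accuracies with a mean column), a run log, and a
#' machine-readable manifest (settings, seeds, input hashes). On error a
#' `FAILED` marker naming the stage is left in the run directory.
#'
#' @param cfg a `run_config` from [validate_config()] (or a list accepted
#'   by it).
#' @param out_dir run directory; defaults to `cfg$out_dir`.
#' @return invisibly, a list with `summary` (the accuracy table), `reports`
#'   (all `cv_report`s), `pheno` (per-trait preparation results), and the
#'   run directory path.
#' @export
run_pipeline <- function(cfg, out_dir = NULL) {
  if (!inherits(cfg, "run_config")) cfg <- validate_config(cfg)
  if (is.null(out_dir)) out_dir <- cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_con <- file(file.path(out_dir, "run.log"), open = "wt")
  on.exit(close(log_con), add = TRUE)
  stage <- "setup"
  fail <- function(e) {
    writeLines(paste("stage:", stage, "-", conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    for (d in names(attr(cfg, "defaults_used")))
      pipeline_log(log_con, "default applied: %s = %s", d,
                   paste(format(attr(cfg, "defaults_used")[[d]]), collapse = ","))
    pipeline_log(log_con,
      "conventions: GDD base 32F with 32/86 clamps; clone-mean repeatability %s",
      "sigma2_g/(sigma2_g + sigma2_gy/y + sigma2_e/(y*r)); outlier |t| > cutoff; lambda by inner CV")

    stage <- "load"
    if (!is.null(cfg$simulate)) {
      pipeline_log(log_con, "simulating panel (seed %d)", cfg$simulate$rng_seed)
      panel <- simulate_panel(cfg$simulate)
      geno <- panel$geno
      trial <- panel$trial
      write_sim_truth(panel$truth, file.path(out_dir, "sim_truth.json"))
    } else {
      pipeline_log(log_con, "reading %s / %s", cfg$genotype_file,
                   cfg$phenotype_file)
      geno <- read_snp_matrix(cfg$genotype_file)
      trial <- read_trial_table(cfg$phenotype_file)
    }
    traits <- cfg$traits
    if (is.null(traits)) traits <- unique(trial$trait)
    absent <- setdiff(traits, unique(trial$trait))
    if (length(absent))
      stop("trait(s) not in phenotype table: ", paste(absent, collapse = ", "))

    stage <- "prep-geno"
    pipeline_log(log_con, "imputing (%s) and computing PCs on %d markers",
                 cfg$imputation, ncol(geno$dosages))
    geno_imp <- impute_missing(geno, method = cfg$imputation,
                               rng_seed = cfg$rng_seed)
    pcs <- pca_scores(geno_imp, k = cfg$k_pcs)
    write_pc_scores(pcs, file.path(out_dir, "pc_scores.csv"))

    stage <- "prep-pheno"
    pheno <- list()
    for (tr in traits) {
      pipeline_log(log_con, "preparing trait %s", tr)
      pheno[[tr]] <- withCallingHandlers(
        prepare_trait(trial, tr, outlier_cutoff = cfg$outlier_cutoff,
                      boxcox = cfg$boxcox),
        warning = function(w) {
          pipeline_log(log_con, "WARN [%s]: %s", tr, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      pipeline_log(log_con,
        "  %s: H = %.3f (SE %.3f), lambda = %s, %d outliers removed",
        tr, pheno[[tr]]$repeatability, pheno[[tr]]$repeatability_se,
        format(pheno[[tr]]$boxcox_lambda), pheno[[tr]]$n_outliers)
    }
    write_blup_table(pheno, out_dir)

    stage <- "cv"
    pop_map <- population_map(trial)
    reports <- list()
    for (tr in traits) {
      blups <- pheno[[tr]]$blups_transformed
      ids <- intersect(names(blups), geno$samples)
      sub <- snp_matrix(geno_imp$dosages[ids, , drop = FALSE],
                        geno_imp$markers)
      sub <- filter_maf(sub, cfg$maf_threshold)
      pipeline_log(log_con, "trait %s: %d genotypes, %d markers after MAF >= %g",
                   tr, length(ids), ncol(sub$dosages), cfg$maf_threshold)
      y_res <- residualize_on_pcs(blups[ids], pcs, k_pcs = cfg$k_pcs)
      plan <- make_group_folds(pop_map[ids], k = cfg$k_folds,
                               rng_seed = cfg$rng_seed)
      for (mod in cfg$models) {
        rep_ <- withCallingHandlers(
          cross_validate(sub, y_res, plan, model = mod, alpha = cfg$alpha,
                         n_inner_folds = cfg$n_inner_folds,
                         repeatability = pheno[[tr]]$repeatability,
                         trait = tr, rng_seed = cfg$rng_seed),
          warning = function(w) {
            pipeline_log(log_con, "WARN [%s/%s]: %s", tr, mod,
                         conditionMessage(w))
            invokeRestart("muffleWarning")
          })
        pipeline_log(log_con, "  %s / %s: mean_r = %.3f, accuracy = %.3f",
                     tr, mod, rep_$mean_r, rep_$accuracy)
        reports[[paste(tr, mod, sep = "/")]] <- rep_
      }
      utils::write.csv(
        cv_report_table(reports[paste(tr, cfg$models, sep = "/")]),
        file.path(out_dir, paste0("cv_", gsub("[^A-Za-z0-9]", "_", tr), ".csv")),
        row.names = FALSE)
      utils::write.csv(data.frame(genotype_id = names(plan$assignment),
                                  population_id = unname(plan$grouping),
                                  fold = unname(plan$assignment)),
                       file.path(out_dir, "fold_plan.csv"), row.names = FALSE)
    }

    stage <- "report"
    summary_df <- summarize_accuracies(reports, cfg$models)
    utils::write.csv(summary_df, file.path(out_dir, "summary_accuracy.csv"),
                     row.names = FALSE)
    manifest <- list(
      package_version = as.character(utils::packageVersion("switchgs")),
      r_version = R.version.string,
      settings = unclass(cfg)[setdiff(names(unclass(cfg)), "simulate")],
      simulate = if (!is.null(cfg$simulate)) unclass(cfg$simulate),
      input_hashes = if (is.null(cfg$simulate)) list(
        genotype_file = unname(tools::md5sum(cfg$genotype_file)),
        phenotype_file = unname(tools::md5sum(cfg$phenotype_file))))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    pipeline_log(log_con, "done: %s", out_dir)
    invisible(list(summary = summary_df, reports = reports, pheno = pheno,
                   out_dir = out_dir))
  }, error = fail)
}

write_blup_table <- function(pheno, out_dir) {
  ids <- sort(unique(unlist(lapply(pheno, function(p) names(p$blups)))))
  df <- data.frame(genotype_id = ids)
  for (tr in names(pheno)) {
    df[[tr]] <- pheno[[tr]]$blups[ids]
    df[[paste0(tr, "_transformed")]] <- pheno[[tr]]$blups_transformed[ids]
  }
  utils::write.csv(df, file.path(out_dir, "blups.csv"), row.names = FALSE)
  side <- lapply(pheno, function(p) list(
    repeatability = p$repeatability,
    repeatability_se = p$repeatability_se,
    boxcox_lambda = p$boxcox_lambda,
    n_outliers = p$n_outliers,
    variance_components = as.list(p$varcomp$components),
    n_years = p$varcomp$n_years, n_reps = p$varcomp$n_reps))
  jsonlite::write_json(side, file.path(out_dir, "blups_meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

summarize_accuracies <- function(reports, models) {
  tab <- cv_report_table(reports)
  traits <- unique(tab$trait)
  out <- data.frame(trait = traits)
  for (m in models)
    out[[m]] <- vapply(traits, function(tr)
      tab$accuracy[tab$trait == tr & tab$model == m][1], numeric(1))
  out$mean_accuracy <- rowMeans(out[, models, drop = FALSE])
  out[order(-out$mean_accuracy), ]
}
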