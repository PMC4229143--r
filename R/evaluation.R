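#' Remove population structure from a trait vector
#'
#' Ordinary least squares of the per-genotype values on an intercept plus
#' the first `k_pcs` principal-component score columns; the residuals are
#' the structure-corrected response used by the prediction models.
#'
#' @param values named numeric vector of per-genotype trait values
#'   (e.g. BLUPs), names = genotype ids.
#' @param pcs a `pc_scores` object covering those genotypes.
#' @param k_pcs number of leading components to regress out (default 2).
#' @return named residual vector, aligned with `values`.
#' @export
residualize_on_pcs <- function(values, pcs, k_pcs = 2) {
  stopifnot(inherits(pcs, "pc_scores"), k_pcs >= 1,
            k_pcs <= ncol(pcs$scores))
  ids <- names(values)
  if (is.null(ids)) stop("`values` must be named by genotype id")
  missing_ids <- setdiff(ids, pcs$samples)
  if (length(missing_ids))
    stop("genotype(s) absent from PC scores: ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  S <- pcs$scores[ids, seq_len(k_pcs), drop = FALSE]
  fit <- stats::lm.fit(cbind(1, S), values)
  stats::setNames(fit$residuals, ids)
}

#' Population-grouped fold assignment
#'
#' Assigns whole source populations to folds so that clones from one
#' population never straddle the training/prediction split: populations
#' are shuffled with the seed, then assigned greedily, in shuffled order,
#' to the currently smallest fold by genotype count.
#' Deterministic given the seed.
#'
#' @param grouping named character vector `genotype_id -> population_id`
#'   (see [population_map()]).
#' @param k number of folds; must not exceed the number of populations.
#' @param rng_seed seed for the shuffle.
#' @return object of class `fold_plan`: list with `k`, `assignment`
#'   (named integer vector genotype -> fold), `grouping`, `rng_seed`.
#' @export
make_group_folds <- function(grouping, k = 10, rng_seed = 1L) {
  pops <- unique(grouping)
  if (length(pops) < k)
    stop("fewer populations (", length(pops), ") than folds (", k, ")")
  sizes <- table(grouping)
  shuffled <- withr::with_seed(rng_seed, sample(pops))
  fold_of_pop <- stats::setNames(integer(length(pops)), shuffled)
  fold_sizes <- integer(k)
  for (p in shuffled) {
    f <- which.min(fold_sizes)
    fold_of_pop[p] <- f
    fold_sizes[f] <- fold_sizes[f] + sizes[[p]]
  }
  assignment <- stats::setNames(fold_of_pop[grouping], names(grouping))
  structure(list(k = k, assignment = assignment, grouping = grouping,
                 rng_seed = rng_seed),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("fold_plan: %d folds over %d genotypes in %d populations\n",
              x$k, length(x$assignment), length(unique(x$grouping))))
  print(table(fold = x$assignment))
  invisible(x)
}

assert_no_leakage <- function(plan) {
  for (f in seq_len(plan$k)) {
    train_pops <- unique(plan$grouping[plan$assignment != f])
    test_pops <- unique(plan$grouping[plan$assignment == f])
    overlap <- intersect(train_pops, test_pops)
    if (length(overlap))
      stop("population(s) in both training and prediction sets of fold ",
           f, ": ", paste(utils::head(overlap, 5), collapse = ", "))
  }
  invisible(TRUE)
}

#' Repeatability-standardized prediction accuracy
#'
#' Mean fold correlation divided by the square root of the clone-mean
#' repeatability, estimating accuracy on the genetic rather than the
#' phenotypic scale. Never clipped: values above 1 or below 0 are returned
#' as computed.
#'
#' @param mean_r mean Pearson correlation across folds.
#' @param h clone-mean repeatability in (0, 1\].
#' @return `mean_r / sqrt(h)`.
#' @export
standardized_accuracy <- function(mean_r, h) {
  if (!is.finite(h) || h <= 0 || h > 1)
    stop("repeatability must lie in (0, 1]; got ", h)
  mean_r / sqrt(h)
}

#' Population-grouped k-fold cross-validation of one model
#'
#' For each fold, fits the model on the other k - 1 folds, predicts the
#' held-out genotypes, and records the Pearson correlation between observed
#' and predicted values (on the structure-residualized scale). A fold whose
#' predictions are constant contributes r = 0 with a warning. Train/test
#' population disjointness is asserted on every run.
#'
#' @param x fully imputed, MAF-filtered [snp_matrix] (or dosage matrix with
#'   sample row names) covering all evaluated genotypes.
#' @param y named structure-residualized response, names = genotype ids.
#' @param plan a `fold_plan` over those genotypes.
#' @param model,alpha,n_inner_folds see [fit_gs_model()].
#' @param repeatability clone-mean repeatability H used for
#'   standardization; `NA` leaves `accuracy` `NA`.
#' @param trait label carried into the report.
#' @param rng_seed seed for inner-CV penalty fold draws.
#' @return object of class `cv_report`: list with `trait`, `model`,
#'   `fold_correlations`, `mean_r`, `spread` (SD across folds; divide by
#'   `sqrt(k)` for the standard-error convention), `repeatability`,
#'   `accuracy = mean_r / sqrt(H)`, `k`.
#' @export
cross_validate <- function(x, y, plan, model = c("rrblup", "lasso", "elastic_net"),
                           alpha = 0.5, n_inner_folds = 5,
                           repeatability = NA_real_, trait = "trait",
                           rng_seed = 1L) {
  model <- match.arg(model)
  stopifnot(inherits(plan, "fold_plan"))
  Z <- as_dosage_matrix(x)
  ids <- names(y)
  if (is.null(ids) || !all(ids %in% rownames(Z)))
    stop("response names must all appear among the genotype rows of `x`")
  Z <- Z[ids, , drop = FALSE]
  assignment <- plan$assignment[ids]
  if (anyNA(assignment))
    stop("fold plan does not cover genotype(s): ",
         paste(utils::head(ids[is.na(assignment)], 5), collapse = ", "))
  assert_no_leakage(plan)
  fold_r <- numeric(plan$k)
  for (f in seq_len(plan$k)) {
    test <- assignment == f
    if (sum(test) < 3)
      stop("fold ", f, " holds fewer than 3 genotypes")
    fit <- fit_gs_model(Z[!test, , drop = FALSE], y[!test], model = model,
                        alpha = alpha, n_inner_folds = n_inner_folds,
                        rng_seed = rng_seed + f)
    pred <- predict(fit, Z[test, , drop = FALSE])
    if (stats::sd(pred) == 0) {
      warning("constant predictions in fold ", f, "; recording r = 0")
      fold_r[f] <- 0
    } else {
      fold_r[f] <- stats::cor(y[test], pred)
    }
  }
  mean_r <- mean(fold_r)
  structure(list(trait = trait, model = model, fold_correlations = fold_r,
                 mean_r = mean_r, spread = stats::sd(fold_r),
                 repeatability = repeatability,
                 accuracy = if (is.na(repeatability)) NA_real_
                            else standardized_accuracy(mean_r, repeatability),
                 k = plan$k),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report: %s / %s, %d folds\n", x$trait, x$model, x$k))
  cat(sprintf("  mean_r = %.3f (spread %.3f), H = %.3f, accuracy = %.3f\n",
              x$mean_r, x$spread, x$repeatability, x$accuracy))
  invisible(x)
}

#' Flatten cross-validation reports to a table
#'
#' @param reports list of `cv_report` objects.
#' @return data.frame with one row per report: trait, model, fold_1..fold_k,
#'   mean_r, spread, repeatability, accuracy.
#' @export
cv_report_table <- function(reports) {
  if (inherits(reports, "cv_report")) reports <- list(reports)
  do.call(rbind, lapply(reports, function(r) {
    folds <- as.data.frame(as.list(stats::setNames(
      r$fold_correlations, paste0("fold_", seq_len(r$k)))))
    cbind(data.frame(trait = r$trait, model = r$model), folds,
          data.frame(mean_r = r$mean_r, spread = r$spread,
                     repeatability = r$repeatability, accuracy = r$accuracy))
  }))
}

#' Rank correlation between repeatability and raw predictive ability
#'
#' Spearman correlation, over traits, of clone-mean repeatability against
#' the unstandardized mean fold correlation (not the standardized
#' accuracy). Ties get average ranks.
#'
#' @param h_by_trait named vector of repeatabilities.
#' @param raw_r_by_trait named vector of mean fold correlations; names must
#'   cover the same traits.
#' @return Spearman's rank correlation coefficient.
#' @export
repeatability_accuracy_spearman <- function(h_by_trait, raw_r_by_trait) {
  traits <- names(h_by_trait)
  if (is.null(traits) || !all(traits %in% names(raw_r_by_trait)))
    stop("the two vectors must be named by the same traits")
  if (length(traits) < 3) stop("need at least 3 traits")
  stats::cor(h_by_trait, raw_r_by_trait[traits], method = "spearman")
}
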