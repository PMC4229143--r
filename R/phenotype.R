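#' Screen plot-level records for outliers
#'
#' Fits the screening model for one trait — random year, block nested in
#' year, field, and population effects — and computes a studentized deleted
#' residual for every record: the conditional residual internally
#' studentized against the residual standard deviation, then externalized
#' with the usual \eqn{t_i = r_i \sqrt{(\nu - 1)/(\nu - r_i^2)}} conversion
#' (\eqn{\nu} = residual degrees of freedom). Records with \eqn{|t_i|}
#' above `cutoff` are flagged and should be dropped before BLUP fitting.
#'
#' @param t a [trial_table]
#' @param trait trait name
#' @param cutoff absolute studentized-deleted-residual threshold (default 4).
#' @return data.frame of the flagged records with their `studentized`
#'   statistic; the full per-record statistics are attached as attribute
#'   `"statistics"`. Row indices into `t` are in column `row`.
#' @export
flag_outliers <- function(t, trait, cutoff = 4) {
  stopifnot(inherits(t, "trial_table"))
  d <- as.data.frame(t)
  d <- d[d$trait == trait, , drop = FALSE]
  rows <- which(t$trait == trait & !is.na(t$value))
  d <- d[!is.na(d$value), , drop = FALSE]
  if (nrow(d) < 10)
    stop("need at least 10 non-missing records of trait '", trait, "'")
  rand <- c("(1 | year)", "(1 | year:block_id)", "(1 | field_id)",
            "(1 | population_id)")
  use <- c(length(unique(d$year)) > 1,
           length(unique(paste(d$year, d$block_id))) > length(unique(d$year)),
           length(unique(d$field_id)) > 1,
           length(unique(d$population_id)) > 1)
  if (!any(use))
    stop("outlier model for '", trait, "' has no estimable random term")
  f <- stats::as.formula(paste("value ~", paste(rand[use], collapse = " + ")))
  fit <- tryCatch(
    lme4::lmer(f, data = d, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                           calc.derivs = FALSE)),
    error = function(e) stop("outlier model failed for trait '", trait,
                             "': ", conditionMessage(e)))
  e <- stats::resid(fit)
  s <- stats::sigma(fit)
  n <- nrow(d)
  k <- 1 + sum(use)                  # intercept + variance terms
  nu <- n - k
  r <- e / s
  t_stat <- ifelse(r^2 >= nu, sign(r) * Inf,
                   r * sqrt((nu - 1) / (nu - r^2)))
  stats_df <- data.frame(row = rows, genotype_id = d$genotype_id,
                         year = d$year, block_id = d$block_id,
                         value = d$value, studentized = t_stat)
  flagged <- stats_df[abs(stats_df$studentized) > cutoff, , drop = FALSE]
  attr(flagged, "statistics") <- stats_df
  flagged
}

#' Drop flagged records from a trial table
#'
#' @param t a [trial_table]
#' @param flagged output of [flag_outliers()]
#' @return the trial table without the flagged rows.
#' @export
remove_outliers <- function(t, flagged) {
  if (nrow(flagged) == 0) return(t)
  out <- t[-flagged$row, , drop = FALSE]
  class(out) <- class(t)
  out
}

blup_model_frame <- function(t, trait) {
  d <- as.data.frame(t)
  d <- d[d$trait == trait & !is.na(d$value), , drop = FALSE]
  if (nrow(d) == 0) stop("no non-missing records of trait '", trait, "'")
  d$.y <- d$value
  d$year <- factor(d$year)
  d$genotype_id <- factor(d$genotype_id)
  d$field_id <- factor(d$field_id)
  d$block_id <- factor(d$block_id)
  d
}

# Random terms estimable from the data at hand, in canonical order.
# Values are the grouping columns pasted to form the factor.
blup_terms <- function(d) {
  terms <- list(genotype = "genotype_id",
                genotype_x_year = c("genotype_id", "year"),
                year = "year",
                block_in_year = c("year", "block_id"),
                field = "field_id")
  multi_year <- nlevels(d$year) > 1
  multi_block <- length(unique(paste(d$year, d$block_id))) > nlevels(d$year)
  keep <- c(genotype = TRUE,
            genotype_x_year = multi_year,
            year = multi_year,
            block_in_year = multi_block,
            field = nlevels(d$field_id) > 1)
  terms[keep]
}

#' Fit the BLUP variance-components model for one trait
#'
#' REML fit of the clonal-trial model
#' \deqn{y = \mu + year + block(year) + field + genotype +
#'       genotype \times year + \varepsilon}
#' with every non-intercept term random. Returns the variance components
#' with their asymptotic (observed-information) covariance, and the
#' predicted genotype values (intercept + genotype BLUP) on the trait
#' scale. Terms that are not estimable from the data (single year, single
#' field, ...) are dropped and reported as zero variance. Population is
#' deliberately not a model term: population-level structure is removed
#' later by principal-component residualization, and fitting both would
#' correct it twice (an explicit population term can be added via
#' `include_population`).
#'
#' @param t a [trial_table] (outlier-screened)
#' @param trait trait name
#' @param include_population also fit a random population term?
#' @param vcov_method `"fd_hessian"` for the observed-information covariance
#'   of the variance components (needed for [repeatability_se()]), or
#'   `"none"` to skip it.
#' @return object of class `blup_fit`: list with
#'   \item{varcomp}{a `var_comp` object: `components` (named variances,
#'     zeros for dropped terms), `vcov`, `n_years`, `n_reps`}
#'   \item{blups}{named vector of predicted genotype values}
#'   \item{loglik}{restricted log-likelihood at the optimum}
#'   \item{fit}{the underlying `lmerMod`}
#' @export
fit_blup_model <- function(t, trait, include_population = FALSE,
                           vcov_method = c("fd_hessian", "none")) {
  stopifnot(inherits(t, "trial_table"))
  vcov_method <- match.arg(vcov_method)
  d <- blup_model_frame(t, trait)
  n_years <- nlevels(droplevels(d$year))
  blocks_per_year <- tapply(d$block_id, d$year, function(b) length(unique(b)))
  n_reps <- as.integer(round(stats::median(blocks_per_year)))
  if (n_years < 2 && n_reps < 2)
    stop("trait '", trait, "': need >= 2 years or >= 2 blocks to separate ",
         "genotype from residual variance")
  terms <- blup_terms(d)
  if (include_population) {
    d$population_id <- factor(d$population_id)
    if (nlevels(d$population_id) > 1) terms$population <- "population_id"
  }
  grp <- lapply(terms, function(cols)
    factor(do.call(paste, c(unname(d[cols]), sep = ":"))))
  names(grp) <- paste0(".g_", names(terms))
  dd <- cbind(d, grp)
  f <- stats::as.formula(paste(".y ~",
        paste(sprintf("(1 | %s)", names(grp)), collapse = " + ")))
  fit <- tryCatch(
    lme4::lmer(f, data = dd, REML = TRUE,
               control = lme4::lmerControl(optimizer = "bobyqa",
                                           check.conv.singular = "ignore")),
    error = function(e) stop("BLUP model failed to converge for trait '",
                             trait, "': ", conditionMessage(e)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  sig2 <- stats::setNames(vc$vcov, sub("^\\.g_", "", vc$grp))
  names(sig2)[names(sig2) == "Residual"] <- "residual"
  all_names <- c("genotype", "genotype_x_year", "year", "block_in_year",
                 "field", if (include_population) "population", "residual")
  components <- stats::setNames(numeric(length(all_names)), all_names)
  components[names(sig2)] <- pmax(sig2, 0)
  boundary <- setdiff(names(sig2)[sig2 <= 1e-8 * stats::var(d$.y)], "residual")
  if (length(boundary))
    warning("trait '", trait, "': variance component(s) at the zero boundary: ",
            paste(boundary, collapse = ", "))
  C <- NULL
  if (vcov_method == "fd_hessian") {
    est <- c(components[names(terms)], residual = components[["residual"]])
    C <- varcomp_vcov(d, terms, est)
  }
  mu <- unname(lme4::fixef(fit)[1])
  re <- lme4::ranef(fit)$.g_genotype
  blups <- stats::setNames(mu + re[[1]], rownames(re))
  varcomp <- structure(list(components = components, vcov = C,
                            n_years = n_years, n_reps = n_reps),
                       class = "var_comp")
  structure(list(varcomp = varcomp, blups = blups,
                 loglik = -lme4::REMLcrit(fit) / 2, fit = fit),
            class = "blup_fit")
}

#' @export
print.blup_fit <- function(x, ...) {
  cat("blup_fit:", length(x$blups), "genotypes\n")
  print(round(x$varcomp$components, 4))
  invisible(x)
}

#' Clone-mean repeatability
#'
#' Fraction of clone-mean phenotypic variance attributable to genotype,
#' \deqn{H = \sigma^2_g / (\sigma^2_g + \sigma^2_{gy}/y + \sigma^2_e/(y r))}
#' with \eqn{y} years and \eqn{r} replicates per year. An upper bound on
#' broad-sense heritability.
#'
#' @param v a `var_comp` object from [fit_blup_model()], or a named vector
#'   with elements `genotype`, `genotype_x_year`, `residual`.
#' @param n_years,n_reps design counts; taken from `v` when it is a
#'   `var_comp`.
#' @return repeatability H in \[0, 1\].
#' @export
clone_mean_repeatability <- function(v, n_years = NULL, n_reps = NULL) {
  s <- repeatability_parts(v, n_years, n_reps)
  denom <- s$g + s$gy / s$y + s$e / (s$y * s$r)
  if (denom <= 0)
    stop("repeatability undefined: all variance components are zero")
  s$g / denom
}

repeatability_parts <- function(v, n_years, n_reps) {
  if (inherits(v, "var_comp")) {
    list(g = v$components[["genotype"]],
         gy = v$components[["genotype_x_year"]],
         e = v$components[["residual"]],
         y = if (is.null(n_years)) v$n_years else n_years,
         r = if (is.null(n_reps)) v$n_reps else n_reps)
  } else {
    stopifnot(!is.null(n_years), !is.null(n_reps))
    list(g = v[["genotype"]],
         gy = if ("genotype_x_year" %in% names(v)) v[["genotype_x_year"]] else 0,
         e = v[["residual"]], y = n_years, r = n_reps)
  }
}

#' Delta-method standard error of clone-mean repeatability
#'
#' First-order propagation of the asymptotic covariance of
#' \eqn{(\sigma^2_g, \sigma^2_{gy}, \sigma^2_e)} through the repeatability
#' ratio: \eqn{SE = \sqrt{g^\top C g}} with the analytic gradient \eqn{g}
#' of H evaluated at the estimates.
#'
#' @param v a `var_comp` with its `vcov` matrix (fit with
#'   `vcov_method = "fd_hessian"`).
#' @return the approximate standard error of H.
#' @export
repeatability_se <- function(v) {
  stopifnot(inherits(v, "var_comp"))
  if (is.null(v$vcov))
    stop("var_comp carries no asymptotic covariance; refit with ",
         'vcov_method = "fd_hessian"')
  s <- repeatability_parts(v, NULL, NULL)
  nm <- c("genotype", "genotype_x_year", "residual")
  nm <- intersect(nm, rownames(v$vcov))
  C <- v$vcov[nm, nm, drop = FALSE]
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-6 * max(abs(ev), 1))
    stop("asymptotic covariance of variance components is not positive ",
         "semi-definite")
  D <- s$g + s$gy / s$y + s$e / (s$y * s$r)
  grad_all <- c(genotype = (D - s$g) / D^2,
                genotype_x_year = -s$g / (s$y * D^2),
                residual = -s$g / (s$y * s$r * D^2))
  g <- grad_all[nm]
  sqrt(max(0, drop(t(g) %*% C %*% g)))
}

#' Box-Cox transformation at the profile-likelihood optimum
#'
#' Finds the power \eqn{\lambda} maximizing the Box-Cox profile
#' log-likelihood of an intercept-only model over a grid (default
#' \[-2, 2\] in steps of 0.01) and returns the transformed values
#' \eqn{(y^\lambda - 1)/\lambda} (natural log at \eqn{\lambda = 0}).
#'
#' @param y strictly positive numeric vector (typically per-genotype BLUPs).
#' @param lambda_grid candidate powers.
#' @param shift if `TRUE` and any `y <= 0`, shift by `1 - min(y)` first;
#'   otherwise non-positive input is an error. The applied shift is
#'   recorded in the result.
#' @return list with `lambda`, `transformed` (named as `y`), `shift`
#'   (0 when none), and the `grid` used.
#' @export
boxcox_optimal <- function(y, lambda_grid = seq(-2, 2, by = 0.01),
                           shift = FALSE) {
  y <- stats::na.omit(y)
  if (length(y) < 3) stop("need at least 3 values")
  applied_shift <- 0
  if (any(y <= 0)) {
    if (!shift)
      stop("Box-Cox requires strictly positive values; set shift = TRUE")
    applied_shift <- 1 - min(y)
    y <- y + applied_shift
  }
  if (stats::sd(y) == 0)
    stop("constant input: Box-Cox lambda is undefined")
  prof <- MASS::boxcox(y ~ 1, lambda = lambda_grid, plotit = FALSE,
                       interp = FALSE)
  lambda <- prof$x[which.max(prof$y)]
  transformed <- if (abs(lambda) < 1e-12) log(y) else (y^lambda - 1) / lambda
  list(lambda = lambda, transformed = transformed, shift = applied_shift,
       grid = c(min = min(lambda_grid), max = max(lambda_grid),
                step = if (length(lambda_grid) > 1) diff(lambda_grid[1:2]) else NA))
}

#' Full phenotype preparation for one trait
#'
#' Outlier screen, BLUP model fit, clone-mean repeatability with
#' delta-method SE, and Box-Cox transformation of the BLUPs, in the order a
#' trial analysis applies them.
#'
#' @inheritParams fit_blup_model
#' @param outlier_cutoff studentized-deleted-residual threshold
#' @param boxcox transform the BLUPs at the profile-likelihood lambda?
#' @return list with `blups` (raw scale), `blups_transformed` (equal to
#'   `blups` when `boxcox = FALSE`), `repeatability`, `repeatability_se`,
#'   `boxcox_lambda` (NA when not transformed), `varcomp`, `n_outliers`.
#' @export
prepare_trait <- function(t, trait, outlier_cutoff = 4, boxcox = TRUE,
                          vcov_method = "fd_hessian") {
  flagged <- flag_outliers(t, trait, cutoff = outlier_cutoff)
  t2 <- remove_outliers(t, flagged)
  fit <- fit_blup_model(t2, trait, vcov_method = vcov_method)
  H <- clone_mean_repeatability(fit$varcomp)
  se <- if (!is.null(fit$varcomp$vcov)) repeatability_se(fit$varcomp) else NA_real_
  lambda <- NA_real_
  blups_tr <- fit$blups
  if (boxcox) {
    bc <- boxcox_optimal(fit$blups, shift = TRUE)
    lambda <- bc$lambda
    blups_tr <- stats::setNames(bc$transformed, names(fit$blups))
  }
  list(blups = fit$blups, blups_transformed = blups_tr,
       repeatability = H, repeatability_se = se, boxcox_lambda = lambda,
       varcomp = fit$varcomp, n_outliers = nrow(flagged))
}
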