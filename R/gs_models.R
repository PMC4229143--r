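#' @useDynLib switchgs, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

as_dosage_matrix <- function(x) {
  if (inherits(x, "snp_matrix")) {
    if (anyNA(x$dosages)) stop("dosage matrix has missing calls; impute first")
    x$dosages
  } else {
    stopifnot(is.matrix(x), is.numeric(x))
    if (is.null(colnames(x))) colnames(x) <- paste0("m", seq_len(ncol(x)))
    x
  }
}

new_gs_fit <- function(model, intercept, effects, marker_ids,
                       penalty = NA_real_, mixing = NA_real_,
                       variance_estimates = NULL) {
  structure(list(model = model, intercept = intercept,
                 effects = stats::setNames(effects, marker_ids),
                 marker_ids = marker_ids, penalty = penalty, mixing = mixing,
                 variance_estimates = variance_estimates),
            class = "gs_fit")
}

#' @export
print.gs_fit <- function(x, ...) {
  cat(sprintf("gs_fit [%s]: %d markers, %d nonzero effects\n", x$model,
              length(x$effects), sum(x$effects != 0)))
  if (!is.na(x$penalty))
    cat(sprintf("  lambda = %.4g, alpha = %.2f\n", x$penalty, x$mixing))
  if (!is.null(x$variance_estimates))
    cat(sprintf("  sigma2_u = %.4g, sigma2_e = %.4g\n",
                x$variance_estimates[["sigma2_u"]],
                x$variance_estimates[["sigma2_e"]]))
  invisible(x)
}

#' RR-BLUP: ridge regression at the REML variance ratio
#'
#' Fits \eqn{y = 1\mu + Zu + \varepsilon} with iid marker effects
#' \eqn{u \sim N(0, \sigma^2_u I)}. The restricted likelihood is profiled in
#' one dimension over \eqn{\delta = \sigma^2_e/\sigma^2_u} on the spectrum
#' of the (column-centered) marker kernel \eqn{ZZ^\top} — efficient when the
#' marker count far exceeds the sample count. Marker effects are the BLUPs
#' \eqn{u = \sigma^2_u Z^\top V^{-1}(y - 1\hat\mu)} at the optimum, i.e. the
#' ridge solution with penalty \eqn{\lambda = \delta}.
#'
#' @param x dosage matrix (n x p) or [snp_matrix], no missing entries.
#' @param y numeric response of length n.
#' @return a `gs_fit` with `variance_estimates = c(sigma2_u, sigma2_e)` and
#'   `penalty` set to the REML ridge parameter \eqn{\delta}.
#' @export
fit_rrblup <- function(x, y) {
  Z <- as_dosage_matrix(x)
  n <- nrow(Z)
  stopifnot(length(y) == n)
  if (n < 3) stop("need at least 3 training samples")
  if (stats::sd(y) == 0) stop("zero-variance response")
  centers <- colMeans(Z)
  Zc <- sweep(Z, 2, centers)
  K <- tcrossprod(Zc)
  # restricted likelihood lives on the orthocomplement of the intercept;
  # build an explicit orthonormal basis so zero eigenvalues of the kernel
  # cannot mix with the 1-direction
  Tb <- qr.Q(qr(matrix(1, n, 1)), complete = TRUE)[, -1, drop = FALSE]
  eg <- eigen(crossprod(Tb, K %*% Tb), symmetric = TRUE)
  xi <- eg$values
  if (any(xi < -1e-6 * max(abs(xi))))
    warning("marker kernel numerically rank-deficient; flooring eigenvalues")
  xi <- pmax(xi, 0)
  U <- Tb %*% eg$vectors
  eta2 <- drop(crossprod(U, y))^2
  nm1 <- n - 1
  rll <- function(log_delta) {
    delta <- exp(log_delta)
    0.5 * (nm1 * (log(nm1 / (2 * pi)) - 1 - log(sum(eta2 / (xi + delta)))) -
             sum(log(xi + delta)))
  }
  grid <- seq(-12, 12, length.out = 49)
  vals <- vapply(grid, rll, numeric(1))
  i0 <- which.max(vals)
  lo <- grid[max(1, i0 - 1)]; hi <- grid[min(length(grid), i0 + 1)]
  opt <- stats::optimize(rll, c(lo, hi), maximum = TRUE, tol = 1e-8)
  delta <- exp(opt$maximum)
  sigma2_u <- sum(eta2 / (xi + delta)) / nm1
  sigma2_e <- delta * sigma2_u
  Vinv <- chol2inv(chol(sigma2_u * K + sigma2_e * diag(n)))
  one <- rep(1, n)
  mu <- drop(crossprod(one, Vinv %*% y) / crossprod(one, Vinv %*% one))
  u <- drop(sigma2_u * crossprod(Zc, Vinv %*% (y - mu)))
  new_gs_fit("rrblup",
             intercept = mu - sum(centers * u),
             effects = u, marker_ids = colnames(Z),
             penalty = delta,
             variance_estimates = c(sigma2_u = sigma2_u, sigma2_e = sigma2_e))
}

standardize_columns <- function(Z) {
  n <- nrow(Z)
  centers <- colMeans(Z)
  Zc <- sweep(Z, 2, centers)
  scales <- sqrt(colSums(Zc^2) / n)
  active <- scales > 0
  Zs <- sweep(Zc[, active, drop = FALSE], 2, scales[active], `/`)
  list(Zs = Zs, centers = centers, scales = scales, active = active)
}

#' Elastic-net / LASSO fit by coordinate descent
#'
#' Minimizes \deqn{\frac{1}{2n}\lVert y - \mu 1 - Zb\rVert^2 +
#'   \lambda\left[\alpha \lVert b\rVert_1 +
#'   \frac{1-\alpha}{2}\lVert b\rVert_2^2\right]} by cyclic coordinate
#' descent with soft-thresholding (`alpha = 1` gives the LASSO, `alpha = 0`
#' pure ridge). Markers are standardized to unit variance internally and
#' effects are returned on the original dosage scale; zero-variance markers
#' receive a zero effect with a warning. Convergence: maximum standardized
#' coefficient change below `tol` (default 1e-7) on a full sweep.
#'
#' @inheritParams fit_rrblup
#' @param alpha mixing parameter in \[0, 1\].
#' @param lambda penalty (>= 0), on the `1/(2n)` loss scale so values are
#'   comparable across fold sizes.
#' @param tol,max_sweeps coordinate-descent controls.
#' @return a `gs_fit`.
#' @export
fit_penalized <- function(x, y, alpha = 0.5, lambda, tol = 1e-7,
                          max_sweeps = 100000) {
  Z <- as_dosage_matrix(x)
  stopifnot(length(y) == nrow(Z))
  if (alpha < 0 || alpha > 1) stop("`alpha` must lie in [0, 1]")
  if (lambda < 0) stop("`lambda` must be >= 0")
  st <- standardize_columns(Z)
  if (any(!st$active))
    warning(sum(!st$active), " zero-variance marker(s) assigned zero effect")
  ybar <- mean(y)
  res <- .enet_path_cpp(st$Zs, y - ybar, alpha, lambda, tol, max_sweeps)
  if (!res$converged[1])
    stop(sprintf("coordinate descent did not converge at lambda = %.4g, alpha = %.2f",
                 lambda, alpha))
  b_std <- drop(res$beta)
  effects <- numeric(ncol(Z))
  effects[st$active] <- b_std / st$scales[st$active]
  new_gs_fit(if (alpha == 1) "lasso" else "elastic_net",
             intercept = ybar - sum(st$centers * effects),
             effects = effects, marker_ids = colnames(Z),
             penalty = lambda, mixing = alpha)
}

enet_lambda_max <- function(Zs, yc, alpha) {
  max(abs(crossprod(Zs, yc)) / nrow(Zs)) / max(alpha, 1e-3)
}

#' Penalty selection by inner cross-validation
#'
#' Builds a 100-point log-spaced penalty path from \eqn{\lambda_{max}} (the
#' smallest penalty with an all-zero solution) down to
#' \eqn{10^{-3}\lambda_{max}} and returns the path value minimizing the
#' mean squared prediction error over `n_inner_folds` random
#' (population-agnostic) splits of the supplied training data. Intended to
#' run strictly inside cross-validation training folds so held-out
#' phenotypes never influence the penalty.
#'
#' @inheritParams fit_penalized
#' @param n_inner_folds number of inner folds (>= 2).
#' @param rng_seed seed for the fold draw.
#' @param n_lambda,lambda_min_ratio path geometry.
#' @param path_tol convergence tolerance for the inner-CV path solutions.
#'   Deliberately looser than the final-fit tolerance: the path is only
#'   scored by held-out MSE, which is insensitive to coefficient changes at
#'   this scale, and the deep (near-saturated) end of the path is severely
#'   ill-conditioned. The fit returned by [fit_gs_model()] at the selected
#'   penalty is solved at the strict [fit_penalized()] tolerance.
#' @param path_max_sweeps sweep cap per path point during selection.
#' @return the selected penalty, with attributes `path` (the lambda path)
#'   and `cv_mse` (mean inner-CV MSE along it).
#' @export
select_lambda <- function(x, y, alpha = 0.5, n_inner_folds = 5,
                          rng_seed = 1L, n_lambda = 100,
                          lambda_min_ratio = 1e-3, path_tol = 1e-3,
                          path_max_sweeps = 2000) {
  Z <- as_dosage_matrix(x)
  n <- nrow(Z)
  if (n_inner_folds < 2) stop("need at least 2 inner folds")
  st <- standardize_columns(Z)
  lam_max <- enet_lambda_max(st$Zs, y - mean(y), alpha)
  if (lam_max <= 0) stop("degenerate penalty path: lambda_max = 0")
  path <- exp(seq(log(lam_max), log(lam_max * lambda_min_ratio),
                  length.out = n_lambda))
  fold <- withr::with_seed(rng_seed,
    sample(rep_len(seq_len(n_inner_folds), n)))
  mse <- matrix(NA_real_, n_inner_folds, n_lambda)
  for (f in seq_len(n_inner_folds)) {
    tr <- fold != f
    st_f <- standardize_columns(Z[tr, , drop = FALSE])
    ybar <- mean(y[tr])
    B <- .enet_path_cpp(st_f$Zs, y[tr] - ybar, alpha, path,
                        path_tol, path_max_sweeps)$beta
    Zheld <- Z[!tr, st_f$active, drop = FALSE]
    Zheld_s <- sweep(sweep(Zheld, 2, st_f$centers[st_f$active]), 2,
                     st_f$scales[st_f$active], `/`)
    pred <- ybar + Zheld_s %*% B
    mse[f, ] <- colMeans((y[!tr] - pred)^2)
  }
  m <- colMeans(mse)
  best <- path[which.min(m)]
  attr(best, "path") <- path
  attr(best, "cv_mse") <- m
  best
}

#' Predict from a fitted genomic-selection model
#'
#' \eqn{\hat y = \mu + Z_{new} u}: intercept plus the dosage matrix times
#' the marker effects. Marker ids must match the training set in order.
#'
#' @param object a `gs_fit`
#' @param x_new dosage matrix or [snp_matrix] with the training markers.
#' @param ... unused.
#' @return numeric vector of predictions, named by sample.
#' @export
predict.gs_fit <- function(object, x_new, ...) {
  Z <- as_dosage_matrix(x_new)
  if (!identical(colnames(Z), object$marker_ids)) {
    bad <- c(setdiff(object$marker_ids, colnames(Z)),
             setdiff(colnames(Z), object$marker_ids))
    if (length(bad) == 0) bad <- "(order differs)"
    stop("marker mismatch between fit and new data: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  drop(object$intercept + Z %*% object$effects)
}

#' Fit one of the three whole-genome prediction models
#'
#' Dispatcher used by the cross-validation driver: `"rrblup"` calls
#' [fit_rrblup()]; `"lasso"` (`alpha = 1`) and `"elastic_net"` select their
#' penalty by inner CV ([select_lambda()]) and then call [fit_penalized()].
#'
#' @inheritParams fit_penalized
#' @param model one of `"rrblup"`, `"lasso"`, `"elastic_net"`.
#' @param alpha elastic-net mixing (ignored for the other models;
#'   default 0.5, equal weight on the ridge and LASSO penalties).
#' @param n_inner_folds inner folds for penalty selection.
#' @param rng_seed seed for the inner fold draw.
#' @return a `gs_fit`.
#' @export
fit_gs_model <- function(x, y, model = c("rrblup", "lasso", "elastic_net"),
                         alpha = 0.5, n_inner_folds = 5, rng_seed = 1L) {
  model <- match.arg(model)
  if (model == "rrblup") return(fit_rrblup(x, y))
  a <- if (model == "lasso") 1 else alpha
  lam <- select_lambda(x, y, alpha = a, n_inner_folds = n_inner_folds,
                       rng_seed = rng_seed)
  fit <- fit_penalized(x, y, alpha = a, lambda = as.numeric(lam))
  fit$model <- model
  fit
}

#' Serialize a fitted model
#'
#' Writes the scalar fit metadata (model, mixing, penalty, intercept,
#' variance estimates) as JSON and the per-marker effects as CSV.
#'
#' @param fit a `gs_fit`
#' @param path_json,path_csv output paths.
#' @return `path_json`, invisibly.
#' @export
write_gs_fit <- function(fit, path_json, path_csv) {
  meta <- list(model = fit$model, alpha = fit$mixing, lambda = fit$penalty,
               intercept = fit$intercept,
               variance_estimates = as.list(fit$variance_estimates))
  jsonlite::write_json(meta, path_json, auto_unbox = TRUE, digits = NA,
                       null = "null")
  utils::write.csv(data.frame(marker_id = fit$marker_ids,
                              effect = unname(fit$effects)),
                   path_csv, row.names = FALSE, quote = FALSE)
  invisible(path_json)
}
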