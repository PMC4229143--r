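# Direct evaluation of the restricted log-likelihood of the
# variance-components model
#   y = 1*mu + sum_k Z_k u_k + e,  u_k ~ N(0, s2_k I),  e ~ N(0, s2_e I)
# via the Woodbury identity on the concatenated sparse design U = [Z_1..Z_m]:
#   V = s2_e I + U D U',  W = s2_e D^{-1} + U'U
#   log|V| = (n - q) log s2_e + sum log d_i + log|W|
#   V^{-1} = (I - U W^{-1} U') / s2_e
# Used (a) as an independent objective oracle for the lme4 fits and (b) to
# build the observed-information covariance of the variance components by
# finite differences.

reml_design <- function(data, terms) {
  mats <- lapply(terms, function(tm) {
    f <- factor(do.call(paste, c(unname(data[tm]), sep = ":")))
    Matrix::sparse.model.matrix(~ 0 + f)
  })
  q_k <- vapply(mats, ncol, integer(1))
  U <- do.call(cbind, mats)
  y <- data$.y
  list(U = U, A = Matrix::crossprod(U), Uy = Matrix::crossprod(U, y),
       Ux = Matrix::colSums(U),   # U' 1
       y = y, n = length(y), q_k = q_k,
       yy = sum(y^2), sy = sum(y))
}

#' Restricted log-likelihood at given variance components
#'
#' Evaluates the REML log-likelihood (including the `(n - p)/2 * log(2*pi)`
#' constant, so values are comparable with `-lme4::REMLcrit()/2`) of the
#' intercept-plus-random-terms model at the supplied variance components.
#' Components fixed at zero simply drop their term. Intended as an
#' independent check on fitted optima and for profile/grid exploration.
#'
#' @param t a [trial_table]
#' @param trait trait name to model
#' @param sigma2 named numeric vector of variances; names from
#'   `"genotype"`, `"genotype_x_year"`, `"year"`, `"block_in_year"`,
#'   `"field"`, plus required `"residual"` (> 0).
#' @return the restricted log-likelihood (scalar).
#' @export
reml_loglik <- function(t, trait, sigma2) {
  data <- blup_model_frame(t, trait)
  terms <- blup_terms(data)
  terms <- terms[names(terms) %in% names(sigma2)]
  parts <- reml_design(data, terms)
  reml_loglik_parts(parts, sigma2[names(terms)], sigma2[["residual"]])
}

reml_loglik_parts <- function(parts, sigma2_terms, sigma2_e) {
  if (sigma2_e <= 0) return(-Inf)
  keep <- sigma2_terms > 0
  d <- rep(sigma2_terms, parts$q_k)
  cols <- rep(keep, parts$q_k)
  n <- parts$n
  if (!any(cols)) {
    # pure intercept + residual model
    rss <- parts$yy - parts$sy^2 / n
    return(-0.5 * ((n - 1) * log(sigma2_e) + log(n) - log(sigma2_e) +
                     rss / sigma2_e + (n - 1) * log(2 * pi)))
  }
  d <- d[cols]
  A <- parts$A[cols, cols, drop = FALSE]
  Uy <- parts$Uy[cols, , drop = FALSE]
  Ux <- parts$Ux[cols]
  q <- length(d)
  W <- A + Matrix::Diagonal(q, sigma2_e / d)
  ch <- tryCatch(Matrix::Cholesky(Matrix::forceSymmetric(W), LDL = FALSE),
                 error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  logdetW <- 2 * Matrix::determinant(ch, logarithm = TRUE, sqrt = TRUE)$modulus
  logdetV <- (n - q) * log(sigma2_e) + sum(log(d)) + as.numeric(logdetW)
  uy <- as.numeric(Uy)
  Winv_Uy <- as.numeric(Matrix::solve(ch, Matrix::Matrix(uy, ncol = 1), system = "A"))
  Winv_Ux <- as.numeric(Matrix::solve(ch, Matrix::Matrix(Ux, ncol = 1), system = "A"))
  yVy <- (parts$yy - sum(uy * Winv_Uy)) / sigma2_e
  xVx <- (n - sum(Ux * Winv_Ux)) / sigma2_e
  xVy <- (parts$sy - sum(Ux * Winv_Uy)) / sigma2_e
  yPy <- yVy - xVy^2 / xVx
  -0.5 * (logdetV + log(xVx) + yPy + (n - 1) * log(2 * pi))
}

# Observed-information covariance of the variance components: inverse of the
# central finite-difference Hessian of the negative restricted log-likelihood
# at the REML estimates. Components pinned at (or near) zero are held out of
# the differentiation; their covariance rows/columns are returned as zero.
varcomp_vcov <- function(data, terms, sigma2) {
  est <- sigma2[c(names(terms), "residual")]
  scale_ref <- stats::var(data$.y)
  free <- est > 1e-8 * scale_ref
  free["residual"] <- TRUE
  parts <- reml_design(data, terms)
  nm_terms <- names(terms)
  f <- function(s_free) {
    s <- est
    s[names(s_free)] <- s_free
    if (any(s < 0)) return(Inf)
    -reml_loglik_parts(parts, s[nm_terms], s[["residual"]])
  }
  s_free <- est[free]
  H <- pracma::hessian(function(v) f(stats::setNames(v, names(s_free))), s_free)
  C_free <- tryCatch(solve(H), error = function(e) MASS::ginv(H))
  C_free <- (C_free + t(C_free)) / 2
  C <- matrix(0, length(est), length(est),
              dimnames = list(names(est), names(est)))
  C[names(s_free), names(s_free)] <- C_free
  C
}
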