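#' Multivariate normal proposal from a covariance matrix
#'
#' Builds the proposal distribution for SIR from final parameter
#' estimates and their (asymptotic) covariance matrix, the usual first
#' choice when a covariance matrix is available.  A slightly indefinite
#' input (common for published covariance matrices) is repaired to the
#' nearest positive semi-definite matrix by eigenvalue clipping, with a
#' warning.  Sampling is truncated to the parameter bounds by rejection.
#'
#' @param center named numeric vector of final estimates over the
#'   estimated parameters.
#' @param cov square covariance matrix, dimension = number of estimated
#'   parameters.
#' @param spec a [parameter_spec()]; supplies truncation bounds.
#' @return object of class `c("mvn_proposal", "sir_proposal")`.
#' @export
proposal_mvn <- function(center, cov, spec) {
  est <- spec$names[spec$estimated]
  center <- align_theta(center, spec)[est]
  cov <- as.matrix(cov)
  if (nrow(cov) != length(est) || ncol(cov) != length(est))
    stop("covariance dimension (", nrow(cov), ") does not match the ",
         length(est), " estimated parameters")
  if (max(abs(cov - t(cov))) > 1e-8 * max(1, max(abs(cov))))
    stop("covariance matrix is not symmetric")
  cov <- nearest_psd(cov, warn = TRUE)
  dimnames(cov) <- list(est, est)
  structure(list(center = center, cov = cov, spec = spec),
            class = c("mvn_proposal", "sir_proposal"))
}

#' Generic (uninformed) multivariate normal proposal
#'
#' When neither a covariance matrix nor bootstrap vectors are available,
#' the proposal is a diagonal multivariate normal with relative standard
#' errors by parameter class: 30% on fixed effects, 50% on
#' inter-individual and inter-occasion variabilities, 10% on residual
#' variabilities, and no correlations.  Parameters of class
#' `"correlation"` (for which no convention exists) default to 50%.
#'
#' @inheritParams proposal_mvn
#' @param rse named numeric of relative standard errors per class;
#'   override to change the defaults.
#' @return an `"mvn_proposal"` with diagonal covariance
#'   \eqn{SD_k = rse_k |center_k|}.
#' @export
proposal_generic <- function(center, spec,
                             rse = c(fixed_effect = 0.30,
                                     iiv_variance = 0.50,
                                     iov_variance = 0.50,
                                     residual_variance = 0.10,
                                     correlation = 0.50)) {
  est <- spec$estimated
  cvec <- align_theta(center, spec)[est]
  cls <- spec$classes[est]
  if (any(cvec == 0))
    stop("generic relative SEs cannot be formed for zero-valued ",
         "parameters: ", paste(names(cvec)[cvec == 0], collapse = ", "),
         "; supply an explicit covariance instead")
  sds <- unname(rse[cls]) * abs(cvec)
  proposal_mvn(cvec, diag(sds^2, length(sds)), spec)
}

#' Inflate a proposal distribution
#'
#' Widens a proposal by multiplying all variances and covariances (on the
#' distribution's native scale — the transformed scale for Box-Cox
#' proposals) by a single factor; the center, shapes and all pairwise
#' correlations are unchanged.  Used when the initial proposal
#' underestimates the uncertainty (its dOFV distribution lies below the
#' reference chi-square).
#'
#' @param p an `"mvn_proposal"` or `"boxcox_proposal"`.
#' @param factor inflation factor, at least 1.
#' @return a proposal of the same class.
#' @export
inflate <- function(p, factor) {
  if (!is.numeric(factor) || length(factor) != 1 || factor < 1)
    stop("inflation factor must be a single number >= 1")
  UseMethod("inflate")
}

#' @export
inflate.mvn_proposal <- function(p, factor) {
  p$cov <- p$cov * factor
  p
}

#' @export
inflate.boxcox_proposal <- function(p, factor) {
  p$cov <- p$cov * factor
  p
}

#' Fit a multivariate Box-Cox distribution to parameter vectors
#'
#' The refit step of the iterative SIR procedure: the resamples of one
#' iteration become the proposal of the next by fitting a multivariate
#' Box-Cox distribution — per-parameter power transforms
#' \eqn{z_k = ((x_k + s_k)^{\lambda_k} - 1)/\lambda_k} (\eqn{\lambda_k=0}
#' meaning \eqn{\log(x_k + s_k)}) with a multivariate normal on the
#' transformed scale.  Parameter-specific shapes let the proposal be
#' symmetric for fixed effects yet right-skewed for variance parameters.
#'
#' Each \eqn{\lambda_k} maximises the marginal profile log-likelihood
#' (grid over \eqn{[-2, 2]} plus local refinement).  The shift is
#' \eqn{s_k = 0} when all values are positive, otherwise
#' \eqn{-\min + 0.1(\max-\min)}.  Correlations are linear on the
#' transformed scale; `cap_correlation` optionally shrinks transformed-
#' scale correlations exceeding the cap down to it, guarding against a
#' misspecified proposal unduly restricting the explored space.
#'
#' @param vectors matrix or data frame of parameter vectors (rows) over
#'   the estimated parameters (columns); at least 50 rows and more rows
#'   than columns.
#' @param spec a [parameter_spec()].
#' @param fixed_shapes optional fixed shapes instead of estimation:
#'   either a named numeric by parameter class (e.g.
#'   `c(fixed_effect = 1, iiv_variance = 0, residual_variance = 0)`) or
#'   by parameter name; typical use is symmetric (1) fixed effects and
#'   log-normal (0) random effects for a first proposal.
#' @param cap_correlation `NULL` (off) or a cap in (0, 1).
#' @return object of class `c("boxcox_proposal", "sir_proposal")` with
#'   fields `lambda`, `shift`, `mean`, `cov` (transformed scale) and
#'   `center` (the medianoid on the original scale, see Details).
#' @details The proposal `center` used for relPDF normalisation is the
#'   back-transformed mean of the transformed-scale normal.
#' @export
fit_boxcox <- function(vectors, spec, fixed_shapes = NULL,
                       cap_correlation = NULL) {
  X <- as.matrix(vectors)
  est <- spec$names[spec$estimated]
  if (!is.null(colnames(X)) && all(est %in% colnames(X)))
    X <- X[, est, drop = FALSE]
  if (ncol(X) != length(est))
    stop("vector set has ", ncol(X), " columns; expected ", length(est))
  colnames(X) <- est
  if (nrow(X) < 50) stop("at least 50 parameter vectors are required")
  if (nrow(X) <= ncol(X)) stop("need more vectors than parameters")
  cls <- spec$classes[spec$estimated]

  k <- ncol(X)
  lambda <- numeric(k); shift <- numeric(k); degenerate <- logical(k)
  for (j in seq_len(k)) {
    x <- X[, j]
    rng <- max(x) - min(x)
    if (rng == 0) {                      # constant marginal
      lambda[j] <- 1; shift[j] <- if (min(x) > 0) 0 else -min(x) + 1
      degenerate[j] <- TRUE
      next
    }
    shift[j] <- if (min(x) > 0) 0 else -min(x) + 0.1 * rng
    fs <- fixed_shape_for(fixed_shapes, est[j], cls[j])
    lambda[j] <- if (!is.null(fs)) fs else
      profile_lambda(x + shift[j])
  }
  Z <- boxcox_transform(X, lambda, shift)
  mu <- colMeans(Z)
  S <- stats::cov(Z)
  if (!is.null(cap_correlation)) {
    stopifnot(cap_correlation > 0, cap_correlation < 1)
    sd <- sqrt(diag(S))
    R <- stats::cov2cor(S)
    over <- abs(R) > cap_correlation & row(R) != col(R)
    if (any(over)) {
      R[over] <- sign(R[over]) * cap_correlation
      S <- nearest_psd(diag(sd) %*% R %*% diag(sd))
    }
  }
  S <- nearest_psd(S)
  dimnames(S) <- list(est, est)
  center <- boxcox_inverse(matrix(mu, 1), lambda, shift)[1, ]
  names(center) <- names(mu) <- est
  if (any(degenerate))
    warning("degenerate (constant) marginals for: ",
            paste(est[degenerate], collapse = ", "), call. = FALSE)
  structure(list(lambda = stats::setNames(lambda, est),
                 shift = stats::setNames(shift, est),
                 mean = mu, cov = S, center = center, spec = spec,
                 degenerate = degenerate),
            class = c("boxcox_proposal", "sir_proposal"))
}

fixed_shape_for <- function(fixed_shapes, name, class) {
  if (is.null(fixed_shapes)) return(NULL)
  if (name %in% names(fixed_shapes)) return(unname(fixed_shapes[name]))
  if (class %in% names(fixed_shapes)) return(unname(fixed_shapes[class]))
  # collapse variance subclasses under a generic "variance" key
  if (grepl("variance", class) && "variance" %in% names(fixed_shapes))
    return(unname(fixed_shapes["variance"]))
  NULL
}

# Profile log-likelihood of the one-parameter Box-Cox shape on x > 0:
#   ll(lambda) = -n/2 log(var_hat(z)) + (lambda - 1) sum(log x)
profile_lambda <- function(x, grid = seq(-2, 2, by = 0.25)) {
  n <- length(x)
  slx <- sum(log(x))
  ll <- function(l) {
    z <- if (abs(l) < 1e-10) log(x) else (x^l - 1) / l
    v <- stats::var(z) * (n - 1) / n
    if (!is.finite(v) || v <= 0) return(-Inf)
    -n / 2 * log(v) + (l - 1) * slx
  }
  vals <- vapply(grid, ll, numeric(1))
  i <- which.max(vals)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(ll, c(lo, hi), maximum = TRUE)
  opt$maximum
}

# Columnwise Box-Cox transform / inverse; lambda = 0 means log.
boxcox_transform <- function(X, lambda, shift) {
  Z <- X
  for (j in seq_along(lambda)) {
    xs <- X[, j] + shift[j]
    Z[, j] <- if (abs(lambda[j]) < 1e-10) log(xs)
      else (xs^lambda[j] - 1) / lambda[j]
  }
  Z
}

boxcox_inverse <- function(Z, lambda, shift) {
  X <- Z
  for (j in seq_along(lambda)) {
    X[, j] <- if (abs(lambda[j]) < 1e-10) exp(Z[, j]) - shift[j]
      else (lambda[j] * Z[, j] + 1)^(1 / lambda[j]) - shift[j]
  }
  X
}

#' Sample parameter vectors from a proposal distribution
#'
#' Draws `n` vectors, rejecting and redrawing any that violate the
#' parameter bounds (truncation by rejection: clipping would create
#' probability atoms that corrupt relPDF).  For Box-Cox proposals,
#' transformed draws that cannot be back-transformed
#' (\eqn{\lambda z + 1 \le 0}) are likewise rejected.  An overall
#' rejection rate above 50% aborts: the proposal is grossly misplaced
#' relative to the parameter bounds.
#'
#' @param p a proposal.
#' @param n number of vectors to draw (the SIR sample size M).
#' @param seed integer seed.
#' @return matrix of `n` rows with attribute `"rejections"`.
#' @export
sample_proposal <- function(p, n, seed) UseMethod("sample_proposal")

#' @export
sample_proposal.mvn_proposal <- function(p, n, seed) {
  set.seed(seed)
  draw <- function(m) MASS::mvrnorm(m, mu = p$center, Sigma = p$cov)
  keep_fun <- function(X) in_bounds_rows(X, p$spec)
  rejection_sample(draw, keep_fun, n, colnames = names(p$center))
}

#' @export
sample_proposal.boxcox_proposal <- function(p, n, seed) {
  set.seed(seed)
  lambda <- p$lambda; shift <- p$shift
  draw <- function(m) {
    Z <- MASS::mvrnorm(m, mu = p$mean, Sigma = p$cov)
    if (m == 1) Z <- matrix(Z, 1)
    ok <- rep(TRUE, m)
    for (j in seq_along(lambda))
      if (abs(lambda[j]) >= 1e-10)
        ok <- ok & (lambda[j] * Z[, j] + 1 > 0)
    X <- matrix(NA_real_, m, ncol(Z))
    X[ok, ] <- boxcox_inverse(Z[ok, , drop = FALSE], lambda, shift)
    X
  }
  keep_fun <- function(X) !is.na(X[, 1]) & in_bounds_rows(X, p$spec)
  rejection_sample(draw, keep_fun, n, colnames = names(p$center))
}

in_bounds_rows <- function(X, spec) {
  est <- spec$estimated
  lo <- spec$lower[est]; hi <- spec$upper[est]
  ok <- rep(TRUE, nrow(X))
  for (j in seq_len(ncol(X)))
    ok <- ok & X[, j] >= lo[j] & X[, j] <= hi[j]
  ok
}

rejection_sample <- function(draw, keep_fun, n, colnames = NULL,
                             max_rate = 0.5) {
  out <- NULL; tried <- 0L; kept <- 0L
  batch <- max(n, 100L)
  repeat {
    X <- draw(batch)
    if (is.null(dim(X))) X <- matrix(X, nrow = batch)
    keep <- keep_fun(X)
    tried <- tried + nrow(X); kept <- kept + sum(keep)
    out <- rbind(out, X[keep, , drop = FALSE])
    if (tried >= max(2L * n, 400L) && 1 - kept / tried > max_rate)
      stop("proposal rejection rate ", round(100 * (1 - kept / tried)),
           "% exceeds ", 100 * max_rate,
           "%: proposal grossly misplaced relative to parameter bounds")
    if (nrow(out) >= n) break
  }
  out <- out[seq_len(n), , drop = FALSE]
  colnames(out) <- colnames
  attr(out, "rejections") <- tried - kept
  out
}

#' Relative probability density of a proposal
#'
#' relPDF is the proposal density at `theta` divided by the proposal
#' density at the final estimates (the proposal center): the denominator
#' of the importance ratio.  For Box-Cox proposals the density includes
#' the Jacobian \eqn{\prod_k (x_k + s_k)^{\lambda_k - 1}} of the
#' transform.  A vector outside the proposal's support gets relPDF 0
#' (its importance ratio is set to 0 and it is excluded from
#' resampling).  relPDF uses the untruncated density ratio; bound
#' truncation cancels in the ratio.
#'
#' @param p a proposal.
#' @param theta a parameter vector, or a matrix of vectors (rows).
#' @return numeric vector of density ratios (1 at the center).
#' @export
relpdf <- function(p, theta) exp(log_relpdf(p, theta))

log_relpdf <- function(p, theta) UseMethod("log_relpdf")

#' @export
log_relpdf.mvn_proposal <- function(p, theta) {
  X <- theta_matrix(theta, names(p$center))
  Si <- solve_psd(p$cov)
  D <- sweep(X, 2, p$center)
  -0.5 * rowSums((D %*% Si) * D)
}

#' @export
log_relpdf.boxcox_proposal <- function(p, theta) {
  X <- theta_matrix(theta, names(p$center))
  lambda <- p$lambda; shift <- p$shift
  Xs <- sweep(X, 2, -shift)              # x + s
  ok <- rowSums(Xs <= 0) == 0
  out <- rep(-Inf, nrow(X))
  if (any(ok)) {
    Z <- boxcox_transform(X[ok, , drop = FALSE], lambda, shift)
    Zc <- boxcox_transform(matrix(p$center, 1), lambda, shift)
    Si <- solve_psd(p$cov)
    D <- sweep(Z, 2, p$mean)
    Dc <- Zc - p$mean
    q <- rowSums((D %*% Si) * D) - drop(Dc %*% Si %*% t(Dc))
    # log Jacobian relative to the center
    lj <- as.vector((log(Xs[ok, , drop = FALSE]) %*% (lambda - 1))) -
      drop(log(p$center + shift) %*% (lambda - 1))
    out[ok] <- -0.5 * q + lj
  }
  out
}

theta_matrix <- function(theta, nms) {
  if (is.matrix(theta)) X <- theta
  else X <- matrix(theta, nrow = 1,
                   dimnames = list(NULL, names(theta)))
  if (!is.null(colnames(X)) && all(nms %in% colnames(X)))
    X <- X[, nms, drop = FALSE]
  if (ncol(X) != length(nms))
    stop("parameter vector does not match proposal dimension")
  X
}

# Inverse of a (possibly repaired, hence singular) PSD matrix; a tiny
# ridge keeps the quadratic form defined after eigenvalue clipping.
solve_psd <- function(S) {
  out <- try(chol2inv(chol(S)), silent = TRUE)
  if (!inherits(out, "try-error")) return(out)
  ridge <- 1e-10 * mean(diag(S))
  chol2inv(chol(S + ridge * diag(nrow(S))))
}

#' @export
print.mvn_proposal <- function(x, ...) {
  cat("Multivariate normal proposal over",
      length(x$center), "parameters\n")
  cat("center:\n"); print(x$center)
  invisible(x)
}

#' @export
print.boxcox_proposal <- function(x, ...) {
  cat("Multivariate Box-Cox proposal over",
      length(x$center), "parameters\n")
  print(data.frame(parameter = names(x$center), lambda = round(x$lambda, 3),
                   shift = round(x$shift, 4), center = signif(x$center, 5)),
        row.names = FALSE)
  invisible(x)
}
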