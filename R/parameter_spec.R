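#' Describe the joint parameter space of a mixed-effects model
#'
#' A parameter specification gives, for each parameter of the joint
#' (fixed-effect, random-effect-variance, residual-variance) vector, its
#' label, its category, whether it is estimated (fixed parameters carry no
#' uncertainty) and its box bounds.  Variance parameters are lower-bounded
#' at zero; correlations at minus one to one.
#'
#' @param names character vector of unique parameter labels.
#' @param classes per-parameter category, one of `"fixed_effect"`,
#'   `"iiv_variance"`, `"iov_variance"`, `"residual_variance"`,
#'   `"correlation"`.
#' @param lower,upper optional numeric bounds; defaults are 0/Inf for
#'   variances, -1/1 for correlations and -Inf/Inf for fixed effects.
#' @param estimated logical, per parameter; defaults to all `TRUE`.
#'
#' @return an object of class `"parameter_spec"`.
#' @export
parameter_spec <- function(names, classes, lower = NULL, upper = NULL,
                           estimated = NULL) {
  if (anyDuplicated(names)) stop("parameter names must be unique")
  classes <- match.arg(classes, c("fixed_effect", "iiv_variance",
                                  "iov_variance", "residual_variance",
                                  "correlation"),
                       several.ok = TRUE)
  k <- length(names)
  if (length(classes) != k) stop("'classes' must match 'names' in length")
  is_var <- classes %in% c("iiv_variance", "iov_variance", "residual_variance")
  is_cor <- classes == "correlation"
  if (is.null(lower)) lower <- ifelse(is_var, 0, ifelse(is_cor, -1, -Inf))
  if (is.null(upper)) upper <- ifelse(is_cor, 1, Inf)
  if (length(lower) != k || length(upper) != k)
    stop("bounds must match 'names' in length")
  if (any(is_var & lower < 0))
    stop("variance parameters must have lower bound >= 0")
  if (is.null(estimated)) estimated <- rep(TRUE, k)
  structure(list(names = names, classes = classes,
                 lower = as.numeric(lower), upper = as.numeric(upper),
                 estimated = as.logical(estimated)),
            class = "parameter_spec")
}

#' @export
print.parameter_spec <- function(x, ...) {
  cat("Parameter specification (", sum(x$estimated), " estimated of ",
      length(x$names), "):\n", sep = "")
  print(data.frame(name = x$names, class = x$classes, lower = x$lower,
                   upper = x$upper, estimated = x$estimated),
        row.names = FALSE)
  invisible(x)
}

#' Number of estimated parameters
#' @param spec a [parameter_spec()].
#' @return integer count of parameters with uncertainty.
#' @export
n_estimated <- function(spec) sum(spec$estimated)

#' Check a parameter vector against its specification
#'
#' @param theta named or ordered numeric vector aligned with `spec$names`.
#' @param spec a [parameter_spec()].
#' @return `TRUE` if all values lie within the declared bounds.
#' @export
check_bounds <- function(theta, spec) {
  theta <- align_theta(theta, spec)
  all(theta >= spec$lower & theta <= spec$upper)
}

# Reorder a (possibly named) vector to the spec order; error on mismatch.
align_theta <- function(theta, spec) {
  if (!is.null(names(theta)) && all(spec$names %in% names(theta)))
    theta <- theta[spec$names]
  if (length(theta) != length(spec$names))
    stop("parameter vector length does not match specification")
  stats::setNames(as.numeric(theta), spec$names)
}
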