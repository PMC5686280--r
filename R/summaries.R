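#' Uncertainty summary metrics
#'
#' The metrics used to compare uncertainty methods, computed from any
#' set of parameter vectors (SIR resamples, covariance-matrix draws,
#' bootstrap or SSE estimates):
#'
#' * RSE (%): \eqn{100 \cdot SD / |\hat\theta|};
#' * 95% CI: empirical 2.5th / 50th / 97.5th percentiles (type-7
#'   linear-interpolation quantiles throughout);
#' * relative width: (upper − lower) / \eqn{\hat\theta};
#' * asymmetry: (upper − median) / (median − lower).
#'
#' @name summary-metrics
NULL

#' @rdname summary-metrics
#' @param vectors matrix of parameter vectors (rows), columns named by
#'   parameter.
#' @param theta_hat named final estimates.
#' @return `rse()`: named numeric vector of percent RSEs (`NA` with a
#'   warning where the estimate is zero).
#' @export
rse <- function(vectors, theta_hat) {
  vectors <- as.matrix(vectors)
  theta_hat <- theta_hat[colnames(vectors)]
  sd <- apply(vectors, 2, stats::sd)
  out <- 100 * sd / abs(theta_hat)
  zero <- !is.na(theta_hat) & theta_hat == 0
  if (any(zero)) {
    warning("RSE undefined for zero-valued estimate(s): ",
            paste(colnames(vectors)[zero], collapse = ", "), call. = FALSE)
    out[zero] <- NA_real_
  }
  out
}

#' @rdname summary-metrics
#' @return `ci95()`: matrix with one row per parameter and columns
#'   `lower`, `median`, `upper`.
#' @export
ci95 <- function(vectors) {
  vectors <- as.matrix(vectors)
  if (nrow(vectors) < 40)
    stop("at least 40 vectors are required for a 95% CI")
  out <- t(apply(vectors, 2, stats::quantile,
                 probs = c(0.025, 0.5, 0.975), type = 7, names = FALSE))
  colnames(out) <- c("lower", "median", "upper")
  out
}

#' @rdname summary-metrics
#' @param ci a row of [ci95()] output (`lower`, `median`, `upper`) or the
#'   whole matrix.
#' @return `relative_width()`: (upper − lower)/\eqn{\hat\theta}, signed
#'   by the estimate (summaries report the magnitude).
#' @export
relative_width <- function(ci, theta_hat) {
  ci <- rbind(ci)
  if (any(theta_hat == 0, na.rm = TRUE))
    warning("relative width undefined for zero-valued estimate(s)",
            call. = FALSE)
  w <- (ci[, "upper"] - ci[, "lower"]) / theta_hat
  w[theta_hat == 0] <- NA_real_
  w
}

#' @rdname summary-metrics
#' @return `asymmetry()`: (upper − median)/(median − lower); `Inf` with a
#'   warning when the lower distance is zero.
#' @export
asymmetry <- function(ci) {
  ci <- rbind(ci)
  lo_d <- ci[, "median"] - ci[, "lower"]
  up_d <- ci[, "upper"] - ci[, "median"]
  if (any(lo_d == 0))
    warning("zero lower-distance: asymmetry is infinite", call. = FALSE)
  up_d / lo_d
}

#' Cross-method comparison table
#'
#' Assembles per-method, per-parameter uncertainty metrics (RSE, 95% CI
#' relative width, asymmetry) plus the per-method median over parameters
#' (the per-model summary convention: even-length medians use the usual
#' mean-of-middle-two rule), and — when a model/dataset pair is supplied
#' so each vector's dOFV can be evaluated — the normalised chi-square
#' degrees of freedom of each method's vector set.
#'
#' @param runs list of `"method_run"` objects (and/or SIR results via
#'   [as_method_run()]), all sharing one parameter layout.
#' @param theta_hat named final estimates.
#' @param model,data optional model/dataset pair for df computation.
#' @param reference_ofv OFV at `theta_hat`; computed when omitted and a
#'   model is given.
#' @return long-format data frame with columns `method`, `parameter`,
#'   `metric`, `value`; medians appear as parameter `"(median)"` and df
#'   as metric `"normalized_df"`.
#' @export
compare_methods <- function(runs, theta_hat, model = NULL, data = NULL,
                            reference_ofv = NULL) {
  if (!is.null(model) && is.null(reference_ofv))
    reference_ofv <- evaluate_ofv(model, data, theta_hat)
  rows <- lapply(runs, function(run) {
    X <- run$vectors
    est <- colnames(X)
    th <- theta_hat[est]
    r <- rse(X, th)
    ci <- ci95(X)
    w <- abs(relative_width(ci, th))
    a <- asymmetry(ci)
    long <- rbind(
      data.frame(method = run$method, parameter = est, metric = "rse",
                 value = unname(r)),
      data.frame(method = run$method, parameter = est, metric = "width95",
                 value = unname(w)),
      data.frame(method = run$method, parameter = est, metric = "asym95",
                 value = unname(a)))
    med <- stats::aggregate(value ~ metric, long, stats::median,
                            na.rm = TRUE)
    long <- rbind(long,
                  data.frame(method = run$method, parameter = "(median)",
                             metric = med$metric, value = med$value))
    if (!is.null(model)) {
      dofv <- vapply(seq_len(nrow(X)), function(i) {
        full <- expand_center(stats::setNames(X[i, ], est), model$spec)
        v <- try(evaluate_ofv(model, data, full), silent = TRUE)
        if (inherits(v, "try-error") || !is.finite(v)) NA_real_
        else v - reference_ofv
      }, numeric(1))
      df <- estimate_df(dofv[!is.na(dofv)], k_params = length(est))
      long <- rbind(long,
                    data.frame(method = run$method, parameter = "(all)",
                               metric = "normalized_df",
                               value = df$normalized_df))
    }
    long
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Present a SIR result as a method run
#'
#' Wraps the final resamples of a [run_sir()] result so SIR can enter
#' [compare_methods()] alongside the comparator methods.
#'
#' @param res a `"sir_result"`.
#' @return a `"method_run"` tagged `"sir"`.
#' @export
as_method_run <- function(res) {
  stopifnot(inherits(res, "sir_result"))
  X <- res$final_resamples
  method_run("sir", X, rep("ok", nrow(X)),
             list(iterations = length(res$iterations),
                  status = res$status))
}
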