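#' Estimate chi-square degrees of freedom of a dOFV distribution
#'
#' If m resampled vectors reflect the true uncertainty, their dOFV
#' values are expected to follow a chi-square distribution with degrees
#' of freedom at or below the number of estimated parameters.  The df is
#' the maximum-likelihood fit of a \eqn{\chi^2_{df}} (gamma with shape
#' df/2, scale 2): the score equation
#' \eqn{\psi(df/2) = \overline{\log x} - \log 2} is solved by 1-D root
#' finding on the digamma function.  Negative values (sampling noise or
#' local minima) are clipped to 0 with a logged count; exact zeros are
#' excluded from the mean-log statistic (the gamma log-likelihood is
#' degenerate there), also counted.
#'
#' @param dofvs numeric vector of dOFV values (at least 30).
#' @param k_params optional number of estimated parameters, for the
#'   normalised df.
#' @return object of class `"df_estimate"`: list with `df`,
#'   `normalized_df` (`df/k_params` or `NA`), `n`, `n_clipped`,
#'   `n_zero`, `degenerate` flag.
#' @export
estimate_df <- function(dofvs, k_params = NULL) {
  dofvs <- dofvs[!is.na(dofvs)]
  if (length(dofvs) < 30)
    stop("at least 30 dOFV values are required to estimate df")
  n_clipped <- sum(dofvs < 0)
  x <- pmax(dofvs, 0)
  pos <- x[x > 0]
  n_zero <- length(x) - length(pos)
  if (!length(pos)) {
    return(structure(list(df = 0, normalized_df =
                            if (is.null(k_params)) NA_real_ else 0,
                          n = length(x), n_clipped = n_clipped,
                          n_zero = n_zero, degenerate = TRUE),
                     class = "df_estimate"))
  }
  target <- mean(log(pos)) - log(2)
  score <- function(k) digamma(k / 2) - target
  # digamma is monotone increasing: bracket then uniroot
  lo <- 1e-8; hi <- 2 * exp(target + 1) + 10
  while (score(hi) < 0) hi <- hi * 4
  df <- stats::uniroot(score, c(lo, hi), tol = 1e-10)$root
  degenerate <- stats::var(pos) < 1e-12
  structure(list(df = df,
                 normalized_df = if (is.null(k_params)) NA_real_
                                 else df / k_params,
                 n = length(x), n_clipped = n_clipped, n_zero = n_zero,
                 degenerate = degenerate),
            class = "df_estimate")
}

#' @export
print.df_estimate <- function(x, ...) {
  cat("Estimated chi-square df:", round(x$df, 3))
  if (!is.na(x$normalized_df))
    cat(" (normalized:", round(x$normalized_df, 3), ")")
  cat(" [n =", x$n, "]\n")
  if (x$n_clipped) cat("  ", x$n_clipped, "negative value(s) clipped to 0\n")
  if (x$degenerate) cat("  flagged: (near-)degenerate input\n")
  invisible(x)
}

#' Percentile curve of a dOFV distribution
#'
#' The quantity plotted in the dOFV diagnostic plot: the empirical dOFV
#' quantile at each percentile of the grid (type-7 linear interpolation).
#'
#' @param dofvs numeric vector of dOFV values.
#' @param percentiles percentile grid (default 1..99).
#' @param source tag: `"proposal"`, `"resamples"` or `"reference"`.
#' @return data frame of class `"dofv_curve"` with columns `percentile`,
#'   `dofv` and attribute `"source"`.
#' @export
dofv_curve <- function(dofvs, percentiles = 1:99, source = "resamples") {
  dofvs <- dofvs[!is.na(dofvs)]
  if (!length(dofvs)) stop("no dOFV values")
  q <- stats::quantile(dofvs, probs = percentiles / 100, type = 7,
                       names = FALSE)
  structure(data.frame(percentile = percentiles, dofv = q),
            source = source, class = c("dofv_curve", "data.frame"))
}

#' Chi-square reference curve
#'
#' The reference against which dOFV distributions are judged: the
#' quantiles of \eqn{\chi^2_k} with k the number of estimated parameters.
#'
#' @param k_params number of estimated parameters.
#' @inheritParams dofv_curve
#' @return a `"dofv_curve"` tagged `"reference"`.
#' @export
chisq_reference <- function(k_params, percentiles = 1:99) {
  structure(data.frame(percentile = percentiles,
                       dofv = stats::qchisq(percentiles / 100, k_params)),
            source = "reference", class = c("dofv_curve", "data.frame"))
}

#' Detect an underestimated initial proposal
#'
#' When the dOFV distribution of the first proposal lies partly or fully
#' below the reference chi-square, the initial parameter uncertainty is
#' at risk of being underestimated and the proposal should be inflated
#' before iterating (it is harder for SIR to widen than to narrow a
#' proposal).  Operationalised as: the proposal curve is below the
#' \eqn{\chi^2_k} reference at more than `fraction` of the percentiles
#' inside `band`.
#'
#' @param proposal_curve a `"dofv_curve"` built from at least 300
#'   samples.
#' @param k_params number of estimated parameters.
#' @param fraction decision fraction (default 0.5).
#' @param band percentile band inspected (default 10–90).
#' @return logical.
#' @export
check_underestimation <- function(proposal_curve, k_params,
                                  fraction = 0.5, band = c(10, 90)) {
  sel <- proposal_curve$percentile >= band[1] &
    proposal_curve$percentile <= band[2]
  ref <- stats::qchisq(proposal_curve$percentile[sel] / 100, k_params)
  mean(proposal_curve$dofv[sel] < ref) > fraction
}

#' Resampling-noise envelope around a dOFV curve
#'
#' Quantifies how much the resamples' dOFV curve would move under a
#' fresh resampling of the same weighted sample: the weighted sample is
#' resampled `B` times with distinct child seeds and the per-percentile
#' empirical coverage interval of the resulting curves is returned.
#'
#' @param ws a [weight_sample()] result.
#' @param m resample size.
#' @param B number of replicate resamplings (at least 100).
#' @param coverage envelope coverage (default 0.95).
#' @param seed integer seed.
#' @inheritParams dofv_curve
#' @param replacement passed to [resample()].
#' @return data frame of class `"noise_envelope"` with columns
#'   `percentile`, `lower`, `upper`.
#' @export
noise_envelope <- function(ws, m, B = 200, coverage = 0.95, seed = 1L,
                           percentiles = 1:99, replacement = FALSE) {
  if (B < 100) stop("at least B = 100 replicate resamplings are required")
  curves <- matrix(NA_real_, B, length(percentiles))
  for (b in seq_len(B)) {
    rs <- resample(ws, m, seed = seed + b, replacement = replacement)
    curves[b, ] <- stats::quantile(rs$dofv, probs = percentiles / 100,
                                   type = 7, names = FALSE)
  }
  a <- (1 - coverage) / 2
  structure(data.frame(
    percentile = percentiles,
    lower = apply(curves, 2, stats::quantile, probs = a, type = 7),
    upper = apply(curves, 2, stats::quantile, probs = 1 - a, type = 7)),
    coverage = coverage, class = c("noise_envelope", "data.frame"))
}

#' Convergence test between two consecutive SIR iterations
#'
#' SIR results are final when the resamples' dOFV distributions of two
#' consecutive iterations are overlaid up to sampling noise.  The visual
#' criterion is made numeric: the previous iteration's curve must lie
#' inside the current iteration's resampling-noise envelope at at least
#' `fraction` of the percentiles within `band`.  The default fraction
#' (0.70) is calibrated so that two independent resamplings of one
#' weighted sample are accepted at 90% or more of seeds: percentile
#' deviations are strongly correlated along the curve, so the
#' containment fraction has a heavy left tail even under exact overlay.
#'
#' @param curve_current the current iteration's resamples `"dofv_curve"`.
#' @param envelope the current iteration's [noise_envelope()].
#' @param curve_previous the previous iteration's resamples curve, on the
#'   same percentile grid.
#' @param fraction required containment fraction (default 0.70; see
#'   Description).
#' @param band percentile band inspected (default 5–95).
#' @return logical.
#' @export
check_convergence <- function(curve_current, envelope, curve_previous,
                              fraction = 0.70, band = c(5, 95)) {
  if (!identical(curve_current$percentile, envelope$percentile) ||
      !identical(curve_current$percentile, curve_previous$percentile))
    stop("curves and envelope must share one percentile grid")
  sel <- curve_current$percentile >= band[1] &
    curve_current$percentile <= band[2]
  inside <- curve_previous$dofv[sel] >= envelope$lower[sel] &
    curve_previous$dofv[sel] <= envelope$upper[sel]
  mean(inside) >= fraction
}

#' Temporal-trends diagnostic of the resampling sequence
#'
#' With sequential without-replacement resampling, depletion of the
#' high-importance-ratio region over the resampling sequence signals
#' that SIR could be improved by a larger M.  The sequence is split into
#' `n_bins` consecutive bins; for each bin the fraction of draws coming
#' from the top IR quintile of the sample is reported, together with a
#' Mann-Kendall-style trend test across bins (one-sided, decreasing).
#'
#' @param rs a [resample()] result (without replacement).
#' @param ws the [weight_sample()] the resample was drawn from.
#' @param n_bins number of consecutive bins (default 5).
#' @param alpha significance level for the depletion call.
#' @return list with `bin_fraction`, `tau`, `p_value`, `depletion`.
#' @export
temporal_trends <- function(rs, ws, n_bins = 5, alpha = 0.05) {
  if (rs$replacement)
    stop("temporal-trends diagnostic requires without-replacement ",
         "resampling")
  m <- length(rs$index)
  hi <- ws$log_ir >= stats::quantile(ws$log_ir[is.finite(ws$log_ir)],
                                     0.8, type = 7)
  bins <- cut(seq_len(m), breaks = n_bins, labels = FALSE)
  frac <- tapply(hi[rs$index], bins, mean)
  ct <- tryCatch(
    suppressWarnings(stats::cor.test(seq_len(n_bins), as.numeric(frac),
                                     method = "kendall",
                                     alternative = "less")),
    error = function(e) list(estimate = NA_real_, p.value = NA_real_))
  list(bin_fraction = as.numeric(frac), tau = unname(ct$estimate),
       p_value = ct$p.value,
       depletion = is.finite(ct$p.value) && ct$p.value < alpha)
}

#' Tidy diagnostics table of a SIR run
#'
#' Long-format data behind the dOFV diagnostic plot: per iteration the
#' resamples' percentile curve, the final iteration's noise envelope and
#' the chi-square reference, plus a df-per-iteration table.
#'
#' @param res a [run_sir()] result.
#' @param model,data the model/dataset pair of the run (used to rebuild
#'   the final envelope).
#' @return list of two data frames, `curves` (iteration, source,
#'   percentile, dofv, envelope_lo, envelope_hi) and `df` (iteration,
#'   df, normalized_df).
#' @export
sir_diagnostics <- function(res, model = NULL, data = NULL) {
  cfg <- res$config
  curves <- do.call(rbind, c(
    list(data.frame(iteration = 0L, source = "proposal",
                    percentile = res$initial_curve$percentile,
                    dofv = res$initial_curve$dofv,
                    envelope_lo = NA_real_, envelope_hi = NA_real_)),
    lapply(seq_along(res$iterations), function(i) {
      it <- res$iterations[[i]]
      data.frame(iteration = i, source = "resamples",
                 percentile = it$curve$percentile, dofv = it$curve$dofv,
                 envelope_lo = NA_real_, envelope_hi = NA_real_)
    })))
  last <- length(res$iterations)
  it <- res$iterations[[last]]
  env <- noise_envelope(it$sample, it$m, B = cfg$envelope_B,
                        coverage = cfg$envelope_coverage,
                        seed = child_seed(cfg$master_seed, last, 500L),
                        percentiles = cfg$percentiles,
                        replacement = cfg$resample_with_replacement)
  sel <- curves$iteration == last
  curves$envelope_lo[sel] <- env$lower
  curves$envelope_hi[sel] <- env$upper
  ref <- chisq_reference(res$k_params, cfg$percentiles)
  curves <- rbind(curves,
                  data.frame(iteration = NA_integer_, source = "reference",
                             percentile = ref$percentile, dofv = ref$dofv,
                             envelope_lo = NA_real_, envelope_hi = NA_real_))
  df_tab <- data.frame(
    iteration = c(0L, seq_along(res$iterations)),
    df = c(res$initial_df$df, res$df_history),
    normalized_df = c(res$initial_df$df, res$df_history) / res$k_params)
  list(curves = curves, df = df_tab)
}
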