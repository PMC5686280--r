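#' Importance ratio of a sampled parameter vector
#'
#' The weight attached to each sampled vector:
#' \deqn{IR = \exp(-dOFV/2) / relPDF}
#' where dOFV is the vector's OFV minus the OFV at the final estimates
#' and relPDF the proposal density relative to its value at the final
#' estimates.  Computed in log space so that large dOFV underflow to 0
#' rather than NaN.
#'
#' @param dofv numeric vector of OFV differences.
#' @param relpdf positive numeric vector of relative proposal densities.
#' @return numeric vector of importance ratios.
#' @export
importance_ratio <- function(dofv, relpdf) {
  exp(-dofv / 2 - log(relpdf))
}

#' Weight sampled parameter vectors by their importance ratio
#'
#' Evaluates the OFV of every sampled vector, forms dOFV against the
#' reference OFV (the OFV at the final estimates) and the importance
#' ratio \eqn{\exp(-dOFV/2)/relPDF}.  Vectors whose OFV evaluation fails
#' (non-finite) or whose relPDF is 0 get IR = 0 and are excluded from
#' resampling; more than 20% failures aborts.  Any vector beating the
#' reference OFV by more than `negative_tol` is reported with a warning:
#' the final estimates may sit at a local minimum and re-estimation from
#' the best sampled vector should be considered.
#'
#' @inheritParams evaluate_ofv
#' @param vectors matrix of sampled parameter vectors (rows).
#' @param proposal the proposal the vectors were drawn from.
#' @param reference_ofv OFV at the final estimates.
#' @param negative_tol tolerance below which a negative dOFV triggers the
#'   local-minimum warning (default 0.1).
#' @return object of class `"weighted_sample"`: list with `vectors`,
#'   `ofv`, `dofv`, `relpdf`, `log_relpdf`, `ir`, `log_ir`, `failures`,
#'   `reference_ofv`, and `best` (the lowest-OFV vector if any dOFV is
#'   negative beyond tolerance).
#' @export
weight_sample <- function(model, data, vectors, proposal, reference_ofv,
                          negative_tol = 0.1) {
  M <- nrow(vectors)
  ofv <- vapply(seq_len(M), function(i) {
    v <- try(evaluate_ofv(model, data, vectors[i, ]), silent = TRUE)
    if (inherits(v, "try-error") || !is.finite(v)) NA_real_ else v
  }, numeric(1))
  failures <- sum(is.na(ofv))
  if (failures > 0.2 * M)
    stop(failures, " of ", M, " OFV evaluations failed (> 20%); ",
         "check the model or narrow the proposal")
  dofv <- ofv - reference_ofv
  lrp <- log_relpdf(proposal, vectors)
  log_ir <- -dofv / 2 - lrp
  log_ir[is.na(ofv) | !is.finite(lrp)] <- -Inf
  best <- NULL
  neg <- which(!is.na(dofv) & dofv < -negative_tol)
  if (length(neg)) {
    i_best <- neg[which.min(dofv[neg])]
    best <- list(theta = vectors[i_best, ], ofv = ofv[i_best],
                 dofv = dofv[i_best])
    warning(length(neg), " sampled vector(s) with dOFV < ",
            -negative_tol, " (best: ", round(best$dofv, 2),
            "): the final estimates may be a local minimum; consider ",
            "re-estimating from the reported best vector", call. = FALSE)
  }
  structure(list(vectors = vectors, ofv = ofv, dofv = dofv,
                 relpdf = exp(lrp), log_relpdf = lrp,
                 ir = exp(log_ir), log_ir = log_ir,
                 failures = failures, reference_ofv = reference_ofv,
                 best = best),
            class = "weighted_sample")
}

#' @export
print.weighted_sample <- function(x, ...) {
  cat("Weighted SIR sample: M =", length(x$ofv),
      "| failures =", x$failures,
      "| dOFV median =", round(stats::median(x$dofv, na.rm = TRUE), 2), "\n")
  invisible(x)
}

#' Resample parameter vectors proportionally to importance ratio
#'
#' Draws `m` of the M weighted vectors with probabilities proportional to
#' their importance ratios.  The default is sequential draws without
#' replacement (weights renormalised after each draw), and the draw
#' order is retained: the temporal-trends diagnostic inspects the
#' resampling proportion over the resampling sequence, which requires an
#' ordered, depletion-style scheme.
#'
#' @param ws a [weight_sample()] result.
#' @param m number of resamples, at most M.
#' @param seed integer seed.
#' @param replacement draw with replacement instead (disables the
#'   temporal-trends diagnostic).
#' @return object of class `"sir_resample"`: list with `vectors` (m rows,
#'   in draw order), `index` (positions in the sample), `dofv`,
#'   `replacement`.
#' @export
resample <- function(ws, m, seed, replacement = FALSE) {
  M <- length(ws$ofv)
  if (m > M) stop("cannot resample m = ", m, " from M = ", M)
  # shift in log space: only relative weights matter
  w <- exp(ws$log_ir - max(ws$log_ir[is.finite(ws$log_ir)]))
  w[!is.finite(w)] <- 0
  if (sum(w) <= 0) stop("all importance ratios are zero")
  if (!replacement && sum(w > 0) < m)
    stop("only ", sum(w > 0), " vectors with positive importance ratio, ",
         "fewer than m = ", m, "; increase M or inflate the proposal")
  set.seed(seed)
  idx <- sample.int(M, m, replace = replacement, prob = w)
  structure(list(vectors = ws$vectors[idx, , drop = FALSE], index = idx,
                 dofv = ws$dofv[idx], replacement = replacement),
            class = "sir_resample")
}

#' Default SIR iteration schedule
#'
#' The first three iterations use M = 1000 samples with increasing
#' m = 200, 400, 500 resamples (high M/m for fast improvement of the
#' proposal at low cost); all further iterations use M = 2000, m = 1000
#' for precise estimation of the uncertainty.  Entry `i` of the returned
#' list applies to iteration `i`; the last entry repeats.
#'
#' @return list of `c(M, m)` pairs.
#' @export
default_schedule <- function() {
  list(c(1000, 200), c(1000, 400), c(1000, 500), c(2000, 1000))
}

schedule_at <- function(schedule, i) {
  e <- schedule[[min(i, length(schedule))]]
  if (e[1] <= e[2] || e[2] < 1) stop("schedule entries need M > m >= 1")
  e
}

#' SIR run configuration
#'
#' @param max_iterations iteration cap (default 15; convergence typically
#'   takes about 3 iterations, difficult models up to 11).
#' @param inflation_ladder inflation factors tried, in order, when the
#'   first proposal's dOFV distribution lies below the chi-square
#'   reference; after the ladder the last factor keeps doubling until the
#'   proposal lies above the reference or `max_inflation` is exceeded.
#' @param max_inflation upper limit for the inflation search.
#' @param cap_correlation optional cap on transformed-scale correlations
#'   of refitted Box-Cox proposals (`NULL` = off; suggested value 0.95).
#' @param resample_with_replacement use with-replacement resampling.
#' @param master_seed integer; per-iteration child seeds are derived as
#'   `master_seed + 1000 * iteration + step`, so any single iteration is
#'   independently reproducible.
#' @param convergence_fraction,convergence_band containment fraction and
#'   percentile band for [check_convergence()].
#' @param underest_fraction,underest_band fraction and band for
#'   [check_underestimation()].
#' @param envelope_B,envelope_coverage replicates and coverage for the
#'   resampling-noise envelope.
#' @param negative_dofv_tol local-minimum warning tolerance on dOFV.
#' @param fixed_shapes optional fixed Box-Cox shapes (see [fit_boxcox()]).
#' @param percentiles percentile grid of the dOFV curves.
#' @param df_oscillation_tol minimal df change counted as a crossing when
#'   flagging oscillation.
#' @return a list of class `"sir_config"`.
#' @export
sir_config <- function(max_iterations = 15,
                       inflation_ladder = c(1.5, 2, 3),
                       max_inflation = 100,
                       cap_correlation = NULL,
                       resample_with_replacement = FALSE,
                       master_seed = 1L,
                       convergence_fraction = 0.70,
                       convergence_band = c(5, 95),
                       underest_fraction = 0.50,
                       underest_band = c(10, 90),
                       envelope_B = 200,
                       envelope_coverage = 0.95,
                       negative_dofv_tol = 0.1,
                       fixed_shapes = NULL,
                       percentiles = 1:99,
                       df_oscillation_tol = 0.05) {
  structure(as.list(environment()), class = "sir_config")
}

child_seed <- function(master, iteration, step = 0L) {
  as.integer((as.numeric(master) + 1000 * iteration + step) %% 2147483647)
}

#' Run one SIR iteration
#'
#' sample -> weight -> resample -> diagnostics -> refit: draws M vectors
#' from `proposal`, weights them by importance ratio, resamples m without
#' replacement, estimates the chi-square degrees of freedom of both the
#' proposal samples' and the resamples' dOFV distributions, and fits the
#' multivariate Box-Cox proposal of the next iteration to the resamples.
#'
#' @inheritParams weight_sample
#' @param M,m sample and resample counts (M > m).
#' @param seed integer seed for this iteration.
#' @param config a [sir_config()].
#' @return object of class `"sir_iteration"` with the weighted sample,
#'   the resample, `df_resamples`, `df_samples`, the fitted
#'   `next_proposal` and the dOFV `curve` of the resamples.
#' @export
run_iteration <- function(model, data, proposal, M, m, reference_ofv,
                          seed, config = sir_config()) {
  X <- sample_proposal(proposal, M, seed)
  ws <- weight_sample(model, data, X, proposal, reference_ofv,
                      negative_tol = config$negative_dofv_tol)
  rs <- resample(ws, m, seed = seed + 1L,
                 replacement = config$resample_with_replacement)
  k <- n_estimated(proposal$spec)
  df_res <- estimate_df(rs$dofv, k_params = k)
  df_smp <- estimate_df(ws$dofv[!is.na(ws$dofv)], k_params = k)
  np <- fit_boxcox(rs$vectors, proposal$spec,
                   fixed_shapes = config$fixed_shapes,
                   cap_correlation = config$cap_correlation)
  structure(list(M = M, m = m, sample = ws, resample = rs,
                 df_resamples = df_res, df_samples = df_smp,
                 next_proposal = np,
                 curve = dofv_curve(rs$dofv, config$percentiles,
                                    source = "resamples")),
            class = "sir_iteration")
}

#' Run the automated iterative SIR procedure
#'
#' The full workflow: the initial proposal (covariance matrix, limited
#' bootstrap, or generic RSEs) is first checked for underestimation — if
#' its dOFV distribution lies below the reference \eqn{\chi^2_k}, the
#' proposal is inflated by stepping through the inflation ladder until it
#' lies above.  SIR iterations then run on the configured schedule, each
#' refitting a multivariate Box-Cox proposal to its resamples, until the
#' resamples' dOFV distributions of two consecutive iterations are
#' overlaid up to sampling noise (the previous curve falls inside the
#' current resampling-noise envelope), or the iteration cap is reached.
#'
#' @inheritParams weight_sample
#' @param initial_proposal an `"sir_proposal"`; its center must be the
#'   final estimates.
#' @param schedule list of `c(M, m)` pairs (default [default_schedule()]).
#' @param config a [sir_config()].
#' @param reference_ofv OFV at the final estimates; computed from the
#'   proposal center when omitted.
#' @return object of class `"sir_result"`: list with `status` (one of
#'   `"converged"`, `"max_iterations"`, `"oscillating"`), `iterations`
#'   (list of `"sir_iteration"`), `final_resamples` (matrix), `df_history`,
#'   `inflation` (factor applied to the initial proposal, 1 if none),
#'   `initial_df`, `negative_dofv` (best local-minimum candidate or NULL).
#' @export
run_sir <- function(model, data, initial_proposal,
                    schedule = default_schedule(),
                    config = sir_config(), reference_ofv = NULL) {
  spec <- initial_proposal$spec
  k <- n_estimated(spec)
  if (is.null(reference_ofv))
    reference_ofv <- evaluate_ofv(model, data,
                                  expand_center(initial_proposal$center, spec))

  # Underestimation check on the first proposal, with inflation restarts.
  M0 <- schedule_at(schedule, 1)[1]
  proposal <- initial_proposal
  inflation <- 1
  ladder <- config$inflation_ladder
  step <- 0L
  repeat {
    X0 <- sample_proposal(proposal, M0,
                          child_seed(config$master_seed, 0L, step))
    ws0 <- suppressWarnings(
      weight_sample(model, data, X0, proposal, reference_ofv,
                    negative_tol = config$negative_dofv_tol))
    d0 <- ws0$dofv[!is.na(ws0$dofv)]
    curve0 <- dofv_curve(d0, config$percentiles, source = "proposal")
    under <- check_underestimation(curve0, k,
                                   fraction = config$underest_fraction,
                                   band = config$underest_band)
    if (!under) break
    step <- step + 1L
    f <- if (step <= length(ladder)) ladder[step]
         else ladder[length(ladder)] * 2^(step - length(ladder))
    if (f > config$max_inflation)
      stop("inflation ladder exhausted at factor ", f,
           ": initial proposal far too narrow; supply a wider proposal")
    proposal <- inflate(initial_proposal, f)
    inflation <- f
  }
  initial_df <- estimate_df(ws0$dofv[!is.na(ws0$dofv)], k_params = k)

  iterations <- list()
  status <- "max_iterations"
  prev_curve <- NULL
  neg_best <- ws0$best
  for (i in seq_len(config$max_iterations)) {
    Mm <- schedule_at(schedule, i)
    it <- withCallingHandlers(
      run_iteration(model, data, proposal, Mm[1], Mm[2], reference_ofv,
                    seed = child_seed(config$master_seed, i), config = config),
      warning = function(w) {
        if (grepl("local minimum", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    if (!is.null(it$sample$best) &&
        (is.null(neg_best) || it$sample$best$dofv < neg_best$dofv))
      neg_best <- it$sample$best
    iterations[[i]] <- it
    if (!is.null(prev_curve)) {
      env <- noise_envelope(it$sample, Mm[2], B = config$envelope_B,
                            coverage = config$envelope_coverage,
                            seed = child_seed(config$master_seed, i, 500L),
                            percentiles = config$percentiles,
                            replacement = config$resample_with_replacement)
      if (check_convergence(it$curve, env, prev_curve,
                            fraction = config$convergence_fraction,
                            band = config$convergence_band)) {
        status <- "converged"
        prev_curve <- it$curve
        break
      }
    }
    prev_curve <- it$curve
    proposal <- it$next_proposal
  }
  df_history <- vapply(iterations, function(it) it$df_resamples$df,
                       numeric(1))
  if (status == "max_iterations" &&
      is_oscillating(df_history, tol = config$df_oscillation_tol))
    status <- "oscillating"
  if (!is.null(neg_best))
    warning("negative dOFV encountered (best ", round(neg_best$dofv, 2),
            "): final estimates may be a local minimum", call. = FALSE)
  structure(list(status = status, iterations = iterations,
                 final_resamples = if (length(iterations))
                   iterations[[length(iterations)]]$resample$vectors,
                 df_history = df_history, inflation = inflation,
                 initial_df = initial_df, initial_curve = curve0,
                 reference_ofv = reference_ofv,
                 negative_dofv = neg_best, k_params = k,
                 config = config),
            class = "sir_result")
}

# A df trajectory that keeps crossing its previous value with changes
# beyond tolerance (relative) in alternating directions.
is_oscillating <- function(df, tol = 0.05) {
  if (length(df) < 4) return(FALSE)
  d <- diff(df)
  big <- abs(d) > tol * df[-length(df)]
  s <- sign(d)[big]
  if (length(s) < 3) return(FALSE)
  flips <- sum(s[-1] != s[-length(s)])
  flips >= length(s) - 1
}

expand_center <- function(center, spec) {
  theta <- stats::setNames(numeric(length(spec$names)), spec$names)
  theta[names(center)] <- center
  theta
}

#' @export
print.sir_result <- function(x, ...) {
  cat("Iterative SIR result\n")
  cat("  status:", x$status, "after", length(x$iterations), "iteration(s)\n")
  if (x$inflation > 1)
    cat("  initial proposal inflated by", x$inflation, "\n")
  cat("  estimated df by iteration:",
      paste(round(x$df_history, 2), collapse = ", "), "\n")
  cat("  final df / k:", round(utils::tail(x$df_history, 1) / x$k_params, 2),
      "(k =", x$k_params, ")\n")
  if (!is.null(x$negative_dofv))
    cat("  WARNING: negative dOFV found (best",
        round(x$negative_dofv$dofv, 2), ") - possible local minimum\n")
  invisible(x)
}
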