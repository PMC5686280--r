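#' Comparator uncertainty methods
#'
#' Three established uncertainty methods produce parameter-vector sets
#' on the same footing as SIR resamples, so all four can be summarised
#' and compared with the same metrics:
#'
#' * [cov_uncertainty()] — multivariate normal draws from the asymptotic
#'   covariance matrix, truncated to the parameter bounds;
#' * [case_bootstrap()] — datasets built by resampling subjects
#'   (individual data vectors) with replacement, re-estimated each time;
#' * [sse()] — stochastic simulation and estimation (parametric
#'   bootstrap): datasets simulated from the final model on the original
#'   design, re-estimated each time.
#'
#' Bootstrap and SSE estimates are retained regardless of the
#' termination status of the estimation; only non-finite results are
#' dropped (with a logged count).  The conventional size is 1000 vectors
#' per method.
#'
#' @name comparators
NULL

method_run <- function(method, vectors, status, settings) {
  structure(list(method = method, vectors = vectors, status = status,
                 settings = settings),
            class = "method_run")
}

#' @export
print.method_run <- function(x, ...) {
  cat("Uncertainty method run:", x$method, "|",
      nrow(x$vectors), "vectors |",
      sum(x$status != "ok"), "flagged\n")
  invisible(x)
}

#' @rdname comparators
#' @param center named final estimates over the estimated parameters.
#' @param cov covariance matrix of the estimates.
#' @param spec a [parameter_spec()].
#' @param n number of vectors (default 1000).
#' @param seed integer seed.
#' @return a `"method_run"` with fields `method`, `vectors`, `status`,
#'   `settings`.
#' @export
cov_uncertainty <- function(center, cov, spec, n = 1000, seed = 1L) {
  p <- proposal_mvn(center, cov, spec)
  X <- sample_proposal(p, n, seed)
  method_run("cov", X, rep("ok", n),
             list(n = n, seed = seed,
                  rejections = attr(X, "rejections")))
}

#' @rdname comparators
#' @inheritParams evaluate_ofv
#' @param start starting vector for re-estimation (defaults to the fit
#'   on the original data).
#' @export
case_bootstrap <- function(model, data, n = 1000, seed = 1L, start = NULL) {
  ids <- unique(data$ID)
  if (length(ids) < 2) stop("case bootstrap needs at least 2 subjects")
  spec <- model$spec
  if (is.null(start))
    start <- estimate_parameters(model, data, start = spec_start(model))$theta
  set.seed(seed)
  id_draws <- replicate(n, sample(ids, length(ids), replace = TRUE),
                        simplify = FALSE)
  out <- matrix(NA_real_, n, length(spec$names),
                dimnames = list(NULL, spec$names))
  status <- character(n)
  for (b in seq_len(n)) {
    bd <- resample_subjects(data, id_draws[[b]])
    fit <- try(estimate_parameters(model, bd, start = start), silent = TRUE)
    if (inherits(fit, "try-error")) {
      status[b] <- "crashed"
    } else {
      out[b, ] <- fit$theta
      status[b] <- if (fit$converged) "ok" else "not_converged"
    }
  }
  finite <- apply(out, 1, function(r) all(is.finite(r)))
  if (any(!finite))
    message(sum(!finite), " bootstrap run(s) without finite estimates ",
            "dropped")
  method_run("boot", out[finite, , drop = FALSE], status[finite],
             list(n = n, seed = seed, id_draws = id_draws))
}

# Rebuild a dataset from a drawn multiset of subject ids, relabelling so
# repeated subjects stay distinct.
resample_subjects <- function(data, ids) {
  pieces <- lapply(seq_along(ids), function(j) {
    d <- data[data$ID == ids[j], , drop = FALSE]
    d$ID <- j
    d
  })
  do.call(rbind, pieces)
}

#' @rdname comparators
#' @param design data frame of the original design (`ID`, `TIME`, ...).
#' @param theta_hat final estimates used as simulation truth.
#' @export
sse <- function(model, design, theta_hat, n = 1000, seed = 1L) {
  spec <- model$spec
  out <- matrix(NA_real_, n, length(spec$names),
                dimnames = list(NULL, spec$names))
  status <- character(n)
  for (b in seq_len(n)) {
    sim <- simulate_dataset(model, theta_hat, design,
                            seed = child_seed(seed, b))
    fit <- try(estimate_parameters(model, sim, start = theta_hat),
               silent = TRUE)
    if (inherits(fit, "try-error")) {
      status[b] <- "crashed"
    } else {
      out[b, ] <- fit$theta
      status[b] <- if (fit$converged) "ok" else "not_converged"
    }
  }
  finite <- apply(out, 1, function(r) all(is.finite(r)))
  if (any(!finite))
    message(sum(!finite), " SSE run(s) without finite estimates dropped")
  method_run("sse", out[finite, , drop = FALSE], status[finite],
             list(n = n, seed = seed))
}

# Neutral starting values inside the bounds, for bootstrap restarts.
spec_start <- function(model) {
  spec <- model$spec
  s <- ifelse(grepl("variance", spec$classes), 0.1, 1)
  stats::setNames(pmin(pmax(s, spec$lower + 1e-6), spec$upper), spec$names)
}
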