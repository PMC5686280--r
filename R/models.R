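#' Built-in models and the OFV evaluation contract
#'
#' The SIR machinery only needs one thing from a model/dataset pair: an
#' objective function value OFV = -2 log-likelihood (up to an additive
#' constant shared across parameter vectors) evaluable at any parameter
#' vector.  Three synthetic model families with tractable likelihoods are
#' built in so the whole workflow runs without external estimation
#' software:
#'
#' * `model_linear_mixed()` — \eqn{y_{ij} = \theta_1 + \theta_2 x_{ij} +
#'   \eta_i + \epsilon_{ij}} with \eqn{\eta_i \sim N(0,\omega^2)},
#'   \eqn{\epsilon_{ij} \sim N(0,\sigma^2)}; the marginal likelihood is an
#'   exact compound-symmetric multivariate normal.
#' * `model_onecomp_pk()` — one-compartment oral absorption PK with
#'   log-normal inter-individual variability on clearance and volume and
#'   proportional residual error; the marginal likelihood is computed by
#'   the Laplace approximation (per-subject mode search over the two
#'   random effects).
#' * `model_conjugate()` — linear regression with known residual variance;
#'   the OFV is exactly quadratic, so the sampling distribution of the
#'   estimator (and hence the dOFV distribution, exactly
#'   \eqn{\chi^2_k}) is available in closed form.  This is the strongest
#'   end-to-end correctness anchor for SIR.
#'
#' The OFV convention includes the full \eqn{n\log(2\pi)} term so that
#' values match direct density computations exactly; only OFV differences
#' (dOFV) are consumed downstream, so the convention is irrelevant to SIR
#' results.
#'
#' Datasets are rectangular data frames with columns `ID`, `TIME`, `DV`
#' (plus covariates); a design is the same without `DV`.
#'
#' @param dose administered oral dose for the PK model (amount units).
#' @param sigma0 known residual standard deviation of the conjugate model.
#' @param k number of regression coefficients of the conjugate model
#'   (intercept plus `k - 1` covariate slopes, at most 3 covariates).
#' @return an object of class `"sir_model"` carrying a [parameter_spec()].
#' @name builtin-models
NULL

#' @rdname builtin-models
#' @export
model_linear_mixed <- function() {
  spec <- parameter_spec(
    names   = c("theta1", "theta2", "omega2", "sigma2"),
    classes = c("fixed_effect", "fixed_effect", "iiv_variance",
                "residual_variance"))
  structure(list(spec = spec), class = c("linear_mixed", "sir_model"))
}

#' @rdname builtin-models
#' @export
model_onecomp_pk <- function(dose = 100) {
  spec <- parameter_spec(
    names   = c("cl", "v", "ka", "omega2_cl", "omega2_v", "sigma2"),
    classes = c("fixed_effect", "fixed_effect", "fixed_effect",
                "iiv_variance", "iiv_variance", "residual_variance"),
    lower   = c(1e-6, 1e-6, 1e-6, 0, 0, 0))
  structure(list(spec = spec, dose = dose),
            class = c("onecomp_pk", "sir_model"))
}

#' @rdname builtin-models
#' @export
model_conjugate <- function(k = 3, sigma0 = 1) {
  stopifnot(k >= 1, k <= 4, sigma0 > 0)
  nm <- paste0("beta", seq_len(k) - 1L)
  spec <- parameter_spec(names = nm, classes = rep("fixed_effect", k))
  structure(list(spec = spec, sigma0 = sigma0, k = k),
            class = c("conjugate", "sir_model"))
}

#' Evaluate the objective function value of a parameter vector
#'
#' Returns OFV = -2 log-likelihood of the data at `theta`, including the
#' full \eqn{n\log(2\pi)} constant.  A non-finite likelihood (for example
#' a zero variance with nonzero residuals) yields `Inf`, which downstream
#' code treats as an evaluation failure for that vector (importance ratio
#' 0), never as a run abort.
#'
#' `model` may also be a plain function `(data, theta) -> OFV`, which is
#' the contract for plugging in external likelihood evaluators.
#'
#' @param model a `"sir_model"` or a function `(data, theta) -> numeric`.
#' @param data dataset data frame with columns `ID`, `TIME`, `DV`.
#' @param theta parameter vector aligned with the model's spec.
#' @return a single numeric OFV.
#' @export
evaluate_ofv <- function(model, data, theta) {
  if (is.function(model)) return(model(data, theta))
  UseMethod("evaluate_ofv")
}

#' @export
evaluate_ofv.sir_model <- function(model, data, theta) {
  sum(ofv_by_subject(model, data, theta))
}

# Per-subject OFV contributions; used for the total OFV and for the
# sandwich estimator's per-subject scores.
ofv_by_subject <- function(model, data, theta) UseMethod("ofv_by_subject")

ofv_by_subject.linear_mixed <- function(model, data, theta) {
  theta <- align_theta(theta, model$spec)
  t1 <- theta[["theta1"]]; t2 <- theta[["theta2"]]
  om2 <- theta[["omega2"]]; sg2 <- theta[["sigma2"]]
  if (!is.finite(om2) || !is.finite(sg2) || om2 < 0 || sg2 <= 0)
    return(rep(Inf, length(unique(data$ID))))
  r <- data$DV - t1 - t2 * data$TIME
  id <- factor(data$ID, levels = unique(data$ID))
  n_i <- as.numeric(tabulate(id))
  s1 <- as.numeric(rowsum(r, id))          # per-subject sum of residuals
  s2 <- as.numeric(rowsum(r^2, id))
  # V_i = sigma2 I + omega2 J (compound symmetry):
  #   log det = (n-1) log sigma2 + log(sigma2 + n omega2)
  #   r' V^-1 r = S2/sigma2 - omega2 S1^2 / (sigma2 (sigma2 + n omega2))
  logdet <- (n_i - 1) * log(sg2) + log(sg2 + n_i * om2)
  qf <- s2 / sg2 - om2 * s1^2 / (sg2 * (sg2 + n_i * om2))
  n_i * log(2 * pi) + logdet + qf
}

ofv_by_subject.conjugate <- function(model, data, theta) {
  theta <- align_theta(theta, model$spec)
  X <- conjugate_design_matrix(model, data)
  r <- data$DV - drop(X %*% theta)
  id <- factor(data$ID, levels = unique(data$ID))
  n_i <- as.numeric(tabulate(id))
  s2 <- as.numeric(rowsum(r^2, id))
  n_i * log(2 * pi * model$sigma0^2) + s2 / model$sigma0^2
}

conjugate_design_matrix <- function(model, data) {
  k <- model$k
  if (k == 1) return(matrix(1, nrow(data), 1))
  covs <- c("TIME", "X2", "X3")[seq_len(k - 1)]
  missing <- setdiff(covs, names(data))
  if (length(missing))
    stop("conjugate model expects covariate columns: ",
         paste(missing, collapse = ", "))
  cbind(1, as.matrix(data[covs]))
}

ofv_by_subject.onecomp_pk <- function(model, data, theta) {
  theta <- align_theta(theta, model$spec)
  om <- theta[c("omega2_cl", "omega2_v")]
  sg2 <- theta[["sigma2"]]
  if (any(!is.finite(theta)) || any(om <= 0) || sg2 <= 0)
    return(rep(Inf, length(unique(data$ID))))
  ids <- unique(data$ID)
  vapply(ids, function(i) {
    d <- data[data$ID == i, , drop = FALSE]
    laplace_ofv_subject(d$TIME, d$DV, theta, model$dose)
  }, numeric(1))
}

# Predicted concentration, one-compartment first-order absorption.
onecomp_conc <- function(t, cl, v, ka, dose) {
  ke <- cl / v
  ka <- ifelse(abs(ka - ke) < 1e-8, ke * (1 + 1e-6), ka)  # removable pole
  dose * ka / (v * (ka - ke)) * (exp(-ke * t) - exp(-ka * t))
}

# -2 log of the Laplace-approximated marginal likelihood for one subject.
# eta = (eta_cl, eta_v), individual CL = cl exp(eta_cl), V = v exp(eta_v);
# y | eta ~ N(c, sigma2 c^2) (proportional error).
laplace_ofv_subject <- function(times, y, theta, dose) {
  cl <- theta[["cl"]]; v <- theta[["v"]]; ka <- theta[["ka"]]
  om <- c(theta[["omega2_cl"]], theta[["omega2_v"]])
  sg2 <- theta[["sigma2"]]
  m2l_joint <- function(eta) {
    cc <- onecomp_conc(times, cl * exp(eta[1]), v * exp(eta[2]), ka, dose)
    if (any(!is.finite(cc)) || any(cc <= 0)) return(1e10)
    res <- sum(log(2 * pi * sg2 * cc^2) + (y - cc)^2 / (sg2 * cc^2))
    res + sum(eta^2 / om) + sum(log(2 * pi * om))
  }
  fit <- stats::nlminb(c(0, 0), function(e) m2l_joint(e) / 2)
  eta_hat <- fit$par
  H <- stats::optimHess(eta_hat, function(e) m2l_joint(e) / 2)  # Hessian of g
  det_h <- det(H)
  if (!is.finite(det_h) || det_h <= 0) return(Inf)
  # -2 log L = 2 g(eta_hat) - q log(2pi) + log|G|, G = Hessian of g
  m2l_joint(eta_hat) - 2 * log(2 * pi) + log(det_h)
}

#' Simulate a dataset from a built-in model
#'
#' @param model a built-in `"sir_model"`.
#' @param theta simulating parameter vector (within bounds).
#' @param design data frame with columns `ID`, `TIME` (plus covariates for
#'   the conjugate model); one row per planned observation.
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#' @return the design with a simulated `DV` column appended.
#' @export
simulate_dataset <- function(model, theta, design, seed) {
  UseMethod("simulate_dataset")
}

#' @export
simulate_dataset.linear_mixed <- function(model, theta, design, seed) {
  theta <- align_theta(theta, model$spec)
  check_design(design)
  set.seed(seed)
  ids <- unique(design$ID)
  eta <- stats::rnorm(length(ids), 0, sqrt(theta[["omega2"]]))
  names(eta) <- as.character(ids)
  mu <- theta[["theta1"]] + theta[["theta2"]] * design$TIME
  design$DV <- mu + eta[as.character(design$ID)] +
    stats::rnorm(nrow(design), 0, sqrt(theta[["sigma2"]]))
  design
}

#' @export
simulate_dataset.conjugate <- function(model, theta, design, seed) {
  theta <- align_theta(theta, model$spec)
  check_design(design)
  set.seed(seed)
  X <- conjugate_design_matrix(model, design)
  design$DV <- drop(X %*% theta) +
    stats::rnorm(nrow(design), 0, model$sigma0)
  design
}

#' @export
simulate_dataset.onecomp_pk <- function(model, theta, design, seed) {
  theta <- align_theta(theta, model$spec)
  check_design(design)
  set.seed(seed)
  ids <- unique(design$ID)
  eta_cl <- stats::rnorm(length(ids), 0, sqrt(theta[["omega2_cl"]]))
  eta_v <- stats::rnorm(length(ids), 0, sqrt(theta[["omega2_v"]]))
  names(eta_cl) <- names(eta_v) <- as.character(ids)
  key <- as.character(design$ID)
  cc <- onecomp_conc(design$TIME,
                     theta[["cl"]] * exp(eta_cl[key]),
                     theta[["v"]] * exp(eta_v[key]),
                     theta[["ka"]], model$dose)
  design$DV <- cc * (1 + stats::rnorm(nrow(design), 0, sqrt(theta[["sigma2"]])))
  design
}

check_design <- function(design) {
  if (!is.data.frame(design) || !all(c("ID", "TIME") %in% names(design)) ||
      nrow(design) == 0)
    stop("design must be a non-empty data frame with columns ID and TIME")
  invisible(design)
}

#' Fit a built-in model by maximum likelihood
#'
#' Minimises the OFV from `start` under the spec's box bounds and returns
#' the estimate together with an asymptotic covariance matrix computed
#' from the numerically differentiated Hessian of OFV/2 (the observed
#' information), or the sandwich estimator
#' \eqn{H^{-1} (\sum_i g_i g_i^T) H^{-1}} built from per-subject score
#' vectors when `sandwich = TRUE`.  Non-convergence is reported via a
#' flag, never an error: the best vector found is returned regardless of
#' termination status.
#'
#' @inheritParams evaluate_ofv
#' @param start starting parameter vector; for the conjugate model the
#'   solution is closed-form and `start` may be `NULL`.
#' @param sandwich use the sandwich covariance estimator.
#' @return list with `theta` (named estimates), `ofv`, `cov` (symmetric
#'   PSD matrix over estimated parameters), `converged` flag.
#' @export
estimate_parameters <- function(model, data, start = NULL, sandwich = FALSE) {
  UseMethod("estimate_parameters")
}

#' @export
estimate_parameters.conjugate <- function(model, data, start = NULL,
                                          sandwich = FALSE) {
  X <- conjugate_design_matrix(model, data)
  xtx <- crossprod(X)
  beta <- drop(solve(xtx, crossprod(X, data$DV)))
  names(beta) <- model$spec$names
  cov <- model$sigma0^2 * solve(xtx)
  dimnames(cov) <- list(model$spec$names, model$spec$names)
  list(theta = beta, ofv = evaluate_ofv(model, data, beta), cov = cov,
       converged = TRUE)
}

#' @export
estimate_parameters.sir_model <- function(model, data, start = NULL,
                                          sandwich = FALSE) {
  spec <- model$spec
  if (is.null(start)) stop("'start' is required for this model")
  start <- align_theta(start, spec)
  lower <- pmax(spec$lower, ifelse(grepl("variance", spec$classes),
                                   1e-8, -Inf))
  obj <- function(p) {
    v <- evaluate_ofv(model, data, stats::setNames(p, spec$names))
    if (!is.finite(v)) 1e10 else v
  }
  fit <- stats::nlminb(start, obj, lower = lower, upper = spec$upper,
                       control = list(iter.max = 500, eval.max = 2000,
                                      rel.tol = 1e-9))
  theta <- stats::setNames(fit$par, spec$names)
  H <- try(stats::optimHess(fit$par, obj), silent = TRUE)
  cov <- NULL
  if (!inherits(H, "try-error")) {
    info <- H / 2                       # Hessian of -log L
    cov <- try(solve(info), silent = TRUE)
    if (inherits(cov, "try-error")) cov <- NULL
    if (!is.null(cov) && sandwich) {
      g <- subject_scores(model, data, theta)   # per-subject d(OFV_i/2)/dtheta
      S <- crossprod(g)
      cov <- solve(info, t(solve(info, t(S))))
    }
    if (!is.null(cov)) {
      cov <- nearest_psd(0.5 * (cov + t(cov)))
      dimnames(cov) <- list(spec$names, spec$names)
    }
  }
  list(theta = theta, ofv = fit$objective, cov = cov,
       converged = fit$convergence == 0)
}

# Central-difference per-subject score vectors of OFV_i / 2.
subject_scores <- function(model, data, theta, h_rel = 1e-5) {
  k <- length(theta)
  f0 <- ofv_by_subject(model, data, theta)
  g <- matrix(0, length(f0), k)
  for (j in seq_len(k)) {
    h <- h_rel * max(abs(theta[j]), 1e-4)
    up <- theta; up[j] <- up[j] + h
    dn <- theta; dn[j] <- dn[j] - h
    g[, j] <- (ofv_by_subject(model, data, up) -
                 ofv_by_subject(model, data, dn)) / (2 * h) / 2
  }
  g
}

# Symmetrise and clip negative eigenvalues at zero.
nearest_psd <- function(S, warn = FALSE) {
  S <- 0.5 * (S + t(S))
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) < 0) {
    if (warn)
      warning("covariance matrix not positive semi-definite; ",
              "negative eigenvalues clipped at 0", call. = FALSE)
    S <- e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
    S <- 0.5 * (S + t(S))
  }
  S
}
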