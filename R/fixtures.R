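#' Built-in synthetic fixtures
#'
#' Self-contained model/dataset pairs with known simulating parameters,
#' regenerable bit-identically from `(name, seed)`, sized to run in
#' minutes on one CPU while staying inside the design ranges typical of
#' population PK/PD analyses (tens to a few hundred subjects):
#'
#' * `conjugate_toy` — linear regression with known residual variance
#'   (100 subjects, 1 observation each, 3 coefficients).  The estimator's
#'   sampling covariance \eqn{\sigma_0^2 (X^TX)^{-1}} is exact, the OFV is
#'   exactly quadratic and dOFV under the true uncertainty is exactly
#'   \eqn{\chi^2_3} — the strongest end-to-end anchor for SIR.
#' * `linear_mixed_small` — random-intercept linear model, 20 subjects
#'   x 4 observations.
#' * `linear_mixed_large` — the same with 200 subjects x 4 observations
#'   (asymptotics hold; cross-method anchor).
#' * `onecomp_pk_sparse` — one-compartment oral PK, 30 subjects x 3
#'   sparse samples.
#'
#' @param name fixture name.
#' @param seed integer seed (default 42).
#' @return list of class `"sir_fixture"`: `name`, `model`, `theta`
#'   (simulating vector), `design`, `data`, `seed`, and `truth` (exact
#'   estimator covariance, conjugate fixture only).
#' @export
make_fixture <- function(name = c("conjugate_toy", "linear_mixed_small",
                                  "linear_mixed_large", "onecomp_pk_sparse"),
                         seed = 42L) {
  name <- match.arg(name)
  fx <- switch(name,
    conjugate_toy = {
      model <- model_conjugate(k = 3, sigma0 = 1)
      n <- 100
      set.seed(seed)
      design <- data.frame(ID = seq_len(n),
                           TIME = stats::runif(n, 0, 10),
                           X2 = stats::rnorm(n))
      theta <- c(beta0 = 1, beta1 = 0.5, beta2 = -0.3)
      data <- simulate_dataset(model, theta, design, seed = seed + 1L)
      X <- conjugate_design_matrix(model, design)
      truth <- list(cov = model$sigma0^2 * solve(crossprod(X)))
      dimnames(truth$cov) <- list(model$spec$names, model$spec$names)
      list(model = model, theta = theta, design = design, data = data,
           truth = truth)
    },
    linear_mixed_small = linear_mixed_fixture(20, seed),
    linear_mixed_large = linear_mixed_fixture(200, seed),
    onecomp_pk_sparse = {
      model <- model_onecomp_pk(dose = 100)
      design <- data.frame(ID = rep(seq_len(30), each = 3),
                           TIME = rep(c(0.5, 3, 12), 30))
      theta <- c(cl = 5, v = 50, ka = 1,
                 omega2_cl = 0.09, omega2_v = 0.09, sigma2 = 0.04)
      data <- simulate_dataset(model, theta, design, seed = seed + 1L)
      list(model = model, theta = theta, design = design, data = data,
           truth = NULL)
    })
  structure(c(list(name = name, seed = seed), fx), class = "sir_fixture")
}

linear_mixed_fixture <- function(n_subjects, seed) {
  model <- model_linear_mixed()
  design <- data.frame(ID = rep(seq_len(n_subjects), each = 4),
                       TIME = rep(0:3, n_subjects))
  theta <- c(theta1 = 10, theta2 = 0.5, omega2 = 1, sigma2 = 0.25)
  data <- simulate_dataset(model, theta, design, seed = seed + 1L)
  list(model = model, theta = theta, design = design, data = data,
       truth = NULL)
}

#' @export
print.sir_fixture <- function(x, ...) {
  cat("Fixture '", x$name, "': ", length(unique(x$data$ID)),
      " subjects, ", nrow(x$data), " observations (seed ", x$seed, ")\n",
      sep = "")
  invisible(x)
}

#' Limited bootstrap as an initial proposal source
#'
#' When no covariance matrix is available, the initial SIR proposal is
#' built from a limited case bootstrap (conventionally 200 samples or
#' fewer) whose vectors are then fitted with [fit_boxcox()].
#'
#' @param fixture a [make_fixture()] result (or any list with `model`
#'   and `data`).
#' @param n number of bootstrap samples (default 200).
#' @param seed integer seed.
#' @return matrix of parameter vectors, one row per bootstrap sample.
#' @export
limited_bootstrap_vectors <- function(fixture, n = 200, seed = 1L) {
  run <- case_bootstrap(fixture$model, fixture$data, n = n, seed = seed)
  run$vectors
}
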