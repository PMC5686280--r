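test_that("linear mixed OFV matches a dense multivariate-normal oracle", {
  model <- model_linear_mixed()
  set.seed(101)
  for (rep in 1:5) {
    n_sub <- sample(3:6, 1)
    design <- data.frame(ID = rep(seq_len(n_sub), each = 3),
                         TIME = rep(0:2, n_sub))
    theta <- c(theta1 = rnorm(1, 10, 2), theta2 = rnorm(1, 1, 0.5),
               omega2 = runif(1, 0.2, 2), sigma2 = runif(1, 0.1, 1))
    data <- simulate_dataset(model, theta, design, seed = 500 + rep)
    probe <- theta * c(1.05, 0.9, 1.2, 0.8)
    expect_equal(evaluate_ofv(model, data, probe),
                 dense_mvn_ofv(data, probe), tolerance = 1e-8)
  }
})

test_that("OFV differences are invariant to the additive constant", {
  fx <- make_fixture("linear_mixed_small", seed = 5)
  shifted <- function(data, theta)
    evaluate_ofv(fx$model, data, theta) + 1234.5
  thetas <- list(fx$theta, fx$theta * 1.1, fx$theta * 0.9)
  d1 <- sapply(thetas, function(t) evaluate_ofv(fx$model, fx$data, t))
  d2 <- sapply(thetas, function(t) shifted(fx$data, t))
  expect_equal(diff(d1), diff(d2), tolerance = 1e-12)
})

test_that("perfect fit with unit residual variance leaves only the 2pi term", {
  model <- model_linear_mixed()
  data <- data.frame(ID = 1, TIME = 0, DV = 3)
  theta <- c(theta1 = 3, theta2 = 0, omega2 = 1e-12, sigma2 = 1)
  expect_equal(evaluate_ofv(model, data, theta), log(2 * pi),
               tolerance = 1e-6)
})

test_that("Laplace OFV of the PK model agrees with 9-node quadrature", {
  model <- model_onecomp_pk(dose = 100)
  design <- data.frame(ID = rep(1:6, each = 3),
                       TIME = rep(c(0.5, 3, 12), 6))
  theta <- c(cl = 5, v = 50, ka = 1,
             omega2_cl = 0.09, omega2_v = 0.09, sigma2 = 0.04)
  data <- simulate_dataset(model, theta, design, seed = 77)
  lap <- evaluate_ofv(model, data, theta)
  agq <- agq_ofv(data, theta, dose = 100)
  # raw OFV: absolute agreement (the additive constant makes the OFV
  # magnitude near zero here, so a relative check is uninformative)
  expect_lt(abs(lap - agq), 0.6)
  # dOFV between parameter vectors -- the quantity SIR consumes -- to 2%
  theta2 <- theta * c(1.4, 1.4, 1, 1, 1, 1)
  dofv_lap <- evaluate_ofv(model, data, theta2) - lap
  dofv_agq <- agq_ofv(data, theta2, dose = 100) - agq
  expect_lt(abs(dofv_lap - dofv_agq) / abs(dofv_agq), 0.02)
})

test_that("dataset simulation is reproducible and moment-faithful", {
  model <- model_linear_mixed()
  design <- data.frame(ID = rep(1:500, each = 2), TIME = rep(0:1, 500))
  theta <- c(theta1 = 1, theta2 = 0, omega2 = 1, sigma2 = 1)
  d1 <- simulate_dataset(model, theta, design, seed = 9)
  d2 <- simulate_dataset(model, theta, design, seed = 9)
  expect_identical(d1, d2)
  # var of subject means = omega2 + sigma2/2; pool two replicates to keep
  # the Monte-Carlo error of the sample variance well under the tolerance
  d1b <- simulate_dataset(model, theta, design, seed = 10)
  sm <- c(tapply(d1$DV, d1$ID, mean), tapply(d1b$DV, d1b$ID, mean))
  expect_lt(abs(var(sm) - 1.5) / 1.5, 0.10)
  # no-noise limit is exact
  d0 <- simulate_dataset(model, c(theta1 = 2, theta2 = 3, omega2 = 0,
                                  sigma2 = 0), design, seed = 1)
  expect_equal(d0$DV, 2 + 3 * design$TIME)
})

test_that("estimation recovers simulating parameters at large n", {
  fx <- make_fixture("linear_mixed_large", seed = 21)
  fit <- estimate_parameters(fx$model, fx$data, start = fx$theta * 1.3)
  expect_true(fit$converged)
  se <- sqrt(diag(fit$cov))
  expect_true(all(abs(fit$theta - fx$theta) < 3 * se))
  # covariance is symmetric PSD
  expect_equal(fit$cov, t(fit$cov), tolerance = 1e-10)
  expect_gte(min(eigen(fit$cov, symmetric = TRUE)$values), 0)
})

test_that("asymptotic SEs track empirical SEs over simulation replicates", {
  model <- model_linear_mixed()
  design <- data.frame(ID = rep(1:80, each = 4), TIME = rep(0:3, 80))
  theta <- c(theta1 = 10, theta2 = 0.5, omega2 = 1, sigma2 = 0.25)
  ests <- t(sapply(1:60, function(r) {
    d <- simulate_dataset(model, theta, design, seed = 3000 + r)
    estimate_parameters(model, d, start = theta)$theta
  }))
  emp_se <- apply(ests, 2, sd)
  d0 <- simulate_dataset(model, theta, design, seed = 3999)
  asy_se <- sqrt(diag(estimate_parameters(model, d0, start = theta)$cov))
  expect_true(all(abs(asy_se - emp_se) / emp_se < 0.35))
})

test_that("zero-noise data give back the exact truth", {
  model <- model_conjugate(k = 3, sigma0 = 1)
  design <- data.frame(ID = 1:50, TIME = runif(50, 0, 10),
                       X2 = rnorm(50))
  theta <- c(beta0 = 1, beta1 = 0.5, beta2 = -0.3)
  X <- cbind(1, design$TIME, design$X2)
  data <- design
  data$DV <- drop(X %*% theta)            # no residual noise added
  fit <- estimate_parameters(model, data)
  expect_equal(unname(fit$theta), unname(theta), tolerance = 1e-10)
})

test_that("sandwich covariance option returns a valid PSD matrix", {
  fx <- make_fixture("linear_mixed_small", seed = 8)
  fit <- estimate_parameters(fx$model, fx$data, start = fx$theta,
                             sandwich = TRUE)
  expect_equal(fit$cov, t(fit$cov), tolerance = 1e-8)
  expect_gte(min(eigen(fit$cov, symmetric = TRUE)$values), 0)
  # same order of magnitude as the Hessian-based covariance
  h <- estimate_parameters(fx$model, fx$data, start = fx$theta)$cov
  expect_true(all(diag(fit$cov) / diag(h) > 0.2 &
                    diag(fit$cov) / diag(h) < 5))
})

test_that("evaluation failures surface as non-finite OFV, not errors", {
  model <- model_linear_mixed()
  data <- data.frame(ID = c(1, 1), TIME = c(0, 1), DV = c(1, 2))
  bad <- c(theta1 = 0, theta2 = 0, omega2 = 1, sigma2 = 0)
  expect_false(is.finite(evaluate_ofv(model, data, bad)))
})
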