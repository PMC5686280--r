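free_spec <- function(k) {
  parameter_spec(paste0("p", seq_len(k)), rep("fixed_effect", k))
}

test_that("covariance-based proposal samples with the declared moments", {
  spec <- free_spec(3)
  center <- c(p1 = 0, p2 = 0, p3 = 0)
  p <- proposal_mvn(center, diag(3), spec)
  X <- sample_proposal(p, 10000, seed = 1)
  expect_true(all(abs(colMeans(X)) < 3 / sqrt(10000)))
  expect_true(max(abs(cov(X) - diag(3))) < 0.06)
  expect_equal(relpdf(p, center), 1)
})

test_that("slightly indefinite covariances are repaired with a warning", {
  spec <- free_spec(2)
  v <- cbind(c(1, 1), c(1, -1)) / sqrt(2)
  S <- v %*% diag(c(1, -1e-14)) %*% t(v)
  expect_warning(p <- proposal_mvn(c(p1 = 0, p2 = 0), S, spec),
                 "positive semi-definite")
  expect_gte(min(eigen(p$cov, symmetric = TRUE)$values), 0)
})

test_that("generic proposal applies class-specific relative SEs", {
  spec <- parameter_spec(c("th", "om", "sg"),
                         c("fixed_effect", "iiv_variance",
                           "residual_variance"))
  p <- proposal_generic(c(th = 2.0, om = 0.09, sg = 0.04), spec)
  expect_equal(sqrt(diag(p$cov)), c(th = 0.6, om = 0.045, sg = 0.004))
  expect_true(all(p$cov[upper.tri(p$cov)] == 0))
  expect_error(proposal_generic(c(th = 0, om = 0.09, sg = 0.04), spec),
               "zero-valued")
})

test_that("inflation scales the covariance and preserves correlations", {
  spec <- free_spec(2)
  S <- matrix(c(0.04, 0.01, 0.01, 0.01), 2)
  p <- proposal_mvn(c(p1 = 1, p2 = 1), S, spec)
  p15 <- inflate(p, 1.5)
  expect_equal(diag(p15$cov), c(p1 = 0.06, p2 = 0.015))
  expect_lt(max(abs(cov2cor(p15$cov) - cov2cor(p$cov))), 1e-12)
  expect_equal(inflate(p, 1)$cov, p$cov)
  p3 <- inflate(p, 3)
  expect_equal(sqrt(diag(p3$cov)), sqrt(3) * sqrt(diag(p$cov)))
  expect_error(inflate(p, 0.9), ">= 1")
})

test_that("Box-Cox shape recovery: log-normal gives lambda near 0, normal near 1", {
  spec <- free_spec(2)
  set.seed(42)
  X <- cbind(p1 = exp(rnorm(1000, 0, 0.5)),          # exact log-normal
             p2 = rnorm(1000, 10, 1))                # normal, all positive
  p <- fit_boxcox(X, spec)
  expect_lt(abs(p$lambda[["p1"]]), 0.2)
  expect_gt(p$lambda[["p2"]], 0.7)
  expect_lt(p$lambda[["p2"]], 1.3)
})

test_that("fixed Box-Cox shapes are honored exactly", {
  spec <- parameter_spec(c("th", "om"), c("fixed_effect", "iiv_variance"))
  set.seed(7)
  X <- cbind(th = rnorm(200, 5, 1), om = exp(rnorm(200, -2, 0.4)))
  p <- fit_boxcox(X, spec, fixed_shapes = c(fixed_effect = 1, variance = 0))
  expect_identical(unname(p$lambda), c(1, 0))
})

test_that("shift rule makes sign-indefinite marginals fittable", {
  spec <- free_spec(1)
  set.seed(3)
  X <- cbind(p1 = rnorm(300, 0, 1))                  # negative values present
  p <- fit_boxcox(X, spec)
  expect_gt(min(X[, 1]) + p$shift[["p1"]], 0)
  expect_true(is.finite(p$lambda[["p1"]]))
})

test_that("Box-Cox with lambda = 0 samples stay positive; seeds reproduce", {
  spec <- parameter_spec("om", "iiv_variance")
  set.seed(11)
  X <- cbind(om = exp(rnorm(500, -1, 0.6)))
  p <- fit_boxcox(X, spec, fixed_shapes = c(om = 0))
  s1 <- sample_proposal(p, 2000, seed = 4)
  s2 <- sample_proposal(p, 2000, seed = 4)
  expect_identical(s1, s2)
  expect_true(all(s1 > 0))
})

test_that("Box-Cox with lambda = 1 moment-matches the normal proposal", {
  spec <- free_spec(2)
  set.seed(13)
  mu <- c(4, 6); S <- matrix(c(1, 0.5, 0.5, 2), 2)
  X <- MASS::mvrnorm(2000, mu, S)
  colnames(X) <- c("p1", "p2")
  p <- fit_boxcox(X, spec, fixed_shapes = c(p1 = 1, p2 = 1))
  Y <- sample_proposal(p, 1e5, seed = 9)
  expect_true(all(abs(colMeans(Y) - colMeans(X)) < 0.03))
  expect_true(max(abs(cov(Y) - cov(X))) < 0.1)
})

test_that("relpdf closed forms and the quadrature-normalized log-normal case", {
  spec <- free_spec(1)
  p <- proposal_mvn(c(p1 = 0), matrix(1), spec)
  expect_equal(relpdf(p, c(p1 = 2)), exp(-2))
  expect_equal(relpdf(p, c(p1 = 0)), 1)

  # lambda = 0 Box-Cox reduces to log-normal: density ratio must include
  # the 1/x Jacobian.  Oracle: numerically normalized density.
  spec1 <- parameter_spec("om", "iiv_variance")
  set.seed(5)
  X <- cbind(om = exp(rnorm(2000, -1, 0.5)))
  bp <- fit_boxcox(X, spec1, fixed_shapes = c(om = 0))
  mu <- bp$mean[[1]]; sd <- sqrt(bp$cov[1, 1])
  dens <- function(x) dnorm((log(x) - mu) / sd) / (sd * x)
  Z <- integrate(dens, 0, Inf)$value
  x0 <- bp$center[[1]]
  for (x in c(0.2, 0.5, 1.2)) {
    expect_equal(relpdf(bp, c(om = x)),
                 (dens(x) / Z) / (dens(x0) / Z), tolerance = 1e-6)
  }
  expect_equal(relpdf(bp, c(om = -0.5)), 0)   # outside support
})

test_that("out-of-bounds draws are rejected, never clipped", {
  spec <- parameter_spec("om", "iiv_variance")
  p <- proposal_mvn(c(om = 0.05), matrix(0.002), spec)  # mass below 0
  X <- sample_proposal(p, 3000, seed = 2)
  expect_true(all(X >= 0))
  expect_gt(attr(X, "rejections"), 0)
  expect_equal(sum(X == 0), 0)                 # no atom at the bound
})

test_that("a grossly misplaced proposal aborts with a diagnostic", {
  spec <- parameter_spec(c("om1", "om2"), rep("iiv_variance", 2))
  # each marginal puts ~half its mass below 0: joint keep rate ~25%
  p <- proposal_mvn(c(om1 = 0.01, om2 = 0.01), diag(4, 2), spec)
  expect_error(sample_proposal(p, 1000, seed = 1), "rejection rate")
})

test_that("refitting preserves the sign of marginal skewness", {
  spec <- free_spec(1)
  set.seed(17)
  X <- cbind(p1 = exp(rnorm(10000, 0, 0.7)))   # right-skewed truth
  p <- fit_boxcox(X, spec)
  Y <- sample_proposal(p, 10000, seed = 18)
  skew <- function(v) mean((v - mean(v))^3) / sd(v)^3
  expect_gt(skew(Y[, 1]), 0)
})
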