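test_that("importance ratio reproduces its closed form", {
  expect_identical(importance_ratio(0, 1), 1)
  expect_equal(importance_ratio(2 * log(4), 1), 0.25)
  expect_equal(importance_ratio(0, 0.5), 2)
  # log-space evaluation survives huge dOFV
  expect_identical(importance_ratio(5000, 1), 0)
  expect_false(is.nan(importance_ratio(5000, 1e-300)))
})

test_that("weighting anchors at the final estimates and flags local minima", {
  fx <- make_fixture("conjugate_toy", seed = 12)
  fit <- estimate_parameters(fx$model, fx$data)
  p <- proposal_mvn(fit$theta, fit$cov, fx$model$spec)
  center <- matrix(fit$theta, 1, dimnames = list(NULL, names(fit$theta)))
  ws <- weight_sample(fx$model, fx$data, center, p, fit$ofv)
  expect_equal(ws$dofv, 0)
  expect_equal(ws$ir, 1)

  # a vector strictly better than the reference triggers the warning
  ref_shifted <- fit$ofv + 5
  expect_warning(
    ws2 <- weight_sample(fx$model, fx$data, center, p, ref_shifted),
    "local minimum")
  expect_equal(ws2$best$dofv, -5)
})

test_that("all importance ratios from a healthy proposal are finite and nonnegative", {
  fx <- make_fixture("linear_mixed_small", seed = 4)
  fit <- estimate_parameters(fx$model, fx$data, start = fx$theta)
  p <- proposal_mvn(fit$theta, fit$cov, fx$model$spec)
  X <- sample_proposal(p, 1000, seed = 6)
  ws <- weight_sample(fx$model, fx$data, X, p, fit$ofv)
  expect_true(all(is.finite(ws$ir)))
  expect_true(all(ws$ir >= 0))
  expect_equal(ws$failures, 0L)
})

test_that("resampling degenerate weight patterns behaves exactly", {
  ws <- synthetic_weighted_sample(dofv = rep(2, 10))   # all IR equal
  rs <- resample(ws, 10, seed = 3)
  expect_setequal(rs$index, 1:10)                      # a permutation
  ws1 <- synthetic_weighted_sample(dofv = c(0, 0, 0),
                                   log_relpdf = c(0, Inf, Inf))
  expect_equal(resample(ws1, 1, seed = 1)$index, 1)    # IR = (1,0,0)
  rs_a <- resample(ws, 5, seed = 42)
  rs_b <- resample(ws, 5, seed = 42)
  expect_identical(rs_a$index, rs_b$index)
  expect_error(resample(ws1, 2, seed = 1), "positive importance ratio")
})

test_that("without-replacement inclusion probabilities match enumeration", {
  ir <- c(0.5, 0.3, 0.2)
  ws <- synthetic_weighted_sample(dofv = -2 * log(ir))
  expect_equal(ws$ir, ir, tolerance = 1e-12)
  counts <- integer(3)
  n_trials <- 20000
  for (s in seq_len(n_trials)) {
    idx <- resample(ws, 2, seed = s)$index
    counts[idx] <- counts[idx] + 1L
  }
  expect_lt(max(abs(counts / n_trials - enumerate_inclusion_m2(ir))), 0.015)
})

test_that("resamples are a subset of samples with no duplicates by default", {
  set.seed(88)
  ws <- synthetic_weighted_sample(dofv = rchisq(500, 3))
  rs <- resample(ws, 200, seed = 1)
  expect_false(any(duplicated(rs$index)))
  expect_true(all(rs$vectors[, 1] %in% ws$vectors[, 1]))
})

test_that("the default schedule follows the 1000/200-400-500 then 2000/1000 pattern", {
  s <- default_schedule()
  expect_equal(s[[1]], c(1000, 200))
  expect_equal(s[[2]], c(1000, 400))
  expect_equal(s[[3]], c(1000, 500))
  expect_equal(s[[4]], c(2000, 1000))
})

test_that("one iteration wires sampling, weighting, resampling and refit together", {
  fx <- make_fixture("conjugate_toy", seed = 2)
  fit <- estimate_parameters(fx$model, fx$data)
  p <- proposal_mvn(fit$theta, fit$cov, fx$model$spec)
  it <- run_iteration(fx$model, fx$data, p, M = 1000, m = 200,
                      reference_ofv = fit$ofv, seed = 10)
  expect_equal(it$M, 1000)
  expect_equal(it$m, 200)
  expect_equal(nrow(it$resample$vectors), 200)
  expect_s3_class(it$next_proposal, "boxcox_proposal")
  # proposal = exact sampling distribution: resample df near k = 3
  expect_lt(abs(it$df_resamples$df - 3), 1.2)
})

test_that("importance-weighted means converge to the exact posterior mean", {
  fx <- make_fixture("conjugate_toy", seed = 31)
  fit <- estimate_parameters(fx$model, fx$data)
  # deliberately wide, offset proposal; self-normalized IS must correct it
  p <- proposal_mvn(fit$theta + 0.1, 4 * fit$cov, fx$model$spec)
  X <- sample_proposal(p, 10000, seed = 32)
  ws <- weight_sample(fx$model, fx$data, X, p, fit$ofv)
  w <- ws$ir / sum(ws$ir)
  for (j in 1:3) {
    est <- sum(w * X[, j])
    mc_se <- sqrt(sum(w^2 * (X[, j] - est)^2))
    expect_lt(abs(est - fit$theta[j]), 3 * mc_se + 1e-8)
  }
})

test_that("resampling never widens the dOFV distribution beyond the samples", {
  fx <- make_fixture("conjugate_toy", seed = 55)
  fit <- estimate_parameters(fx$model, fx$data)
  p <- proposal_mvn(fit$theta, fit$cov, fx$model$spec)
  it <- run_iteration(fx$model, fx$data, p, M = 2000, m = 500,
                      reference_ofv = fit$ofv, seed = 56)
  noise <- sqrt(2 * it$df_samples$df) * 4 / sqrt(500)
  expect_lte(it$df_resamples$df, it$df_samples$df + 3 * noise + 0.5)
})

test_that("the full run converges on the conjugate fixture", {
  fx <- make_fixture("conjugate_toy", seed = 7)
  fit <- estimate_parameters(fx$model, fx$data)
  p <- proposal_mvn(fit$theta, fit$cov, fx$model$spec)
  res <- run_sir(fx$model, fx$data, p,
                 config = sir_config(master_seed = 11))
  expect_equal(res$status, "converged")
  expect_lte(length(res$iterations), 5)
  expect_equal(nrow(res$final_resamples),
               res$iterations[[length(res$iterations)]]$m)
})

test_that("a deliberately shrunken proposal triggers inflation before iterating", {
  fx <- make_fixture("conjugate_toy", seed = 7)
  fit <- estimate_parameters(fx$model, fx$data)
  p_narrow <- proposal_mvn(fit$theta, 0.25 * fit$cov, fx$model$spec)
  res <- run_sir(fx$model, fx$data, p_narrow,
                 config = sir_config(master_seed = 19, max_iterations = 6))
  expect_gt(res$inflation, 1)
})

test_that("max_iterations = 0 returns initial diagnostics only", {
  fx <- make_fixture("conjugate_toy", seed = 7)
  fit <- estimate_parameters(fx$model, fx$data)
  p <- proposal_mvn(fit$theta, fit$cov, fx$model$spec)
  res <- run_sir(fx$model, fx$data, p,
                 config = sir_config(master_seed = 3, max_iterations = 0))
  expect_equal(res$status, "max_iterations")
  expect_length(res$iterations, 0)
  expect_s3_class(res$initial_df, "df_estimate")
})

test_that("doubling M at fixed m does not inflate the final df beyond noise", {
  fx <- make_fixture("conjugate_toy", seed = 23)
  fit <- estimate_parameters(fx$model, fx$data)
  p <- proposal_mvn(fit$theta, fit$cov, fx$model$spec)
  df_at_M <- function(M) {
    it <- run_iteration(fx$model, fx$data, p, M = M, m = 300,
                        reference_ofv = fit$ofv, seed = 61)
    it$df_resamples$df
  }
  d1 <- df_at_M(1000); d2 <- df_at_M(2000)
  noise <- sqrt(2 * 3) * 4 / sqrt(300)   # sd of a chi2(3) df estimate at m=300
  expect_lte(d2, d1 + 3 * noise)
})
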