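# Independent oracles used across tests; these deliberately avoid the
# package's own computational paths.

# Dense multivariate-normal OFV for the random-intercept linear model:
# per subject V = sigma2 I + omega2 J, OFV = sum_i -2 log N(y_i; mu_i, V_i)
# built with explicit determinant() and solve() calls.
dense_mvn_ofv <- function(data, theta) {
  tot <- 0
  for (i in unique(data$ID)) {
    d <- data[data$ID == i, ]
    n <- nrow(d)
    mu <- theta[["theta1"]] + theta[["theta2"]] * d$TIME
    V <- theta[["sigma2"]] * diag(n) + theta[["omega2"]] * matrix(1, n, n)
    r <- d$DV - mu
    ld <- as.numeric(determinant(V, logarithm = TRUE)$modulus)
    tot <- tot + n * log(2 * pi) + ld + drop(t(r) %*% solve(V, r))
  }
  tot
}

# Adaptive Gauss-Hermite marginal -2 log-likelihood for one subject of
# the one-compartment PK model, centred at the conditional mode and
# scaled by the mode Hessian (9 nodes per dimension).
agq_ofv_subject <- function(times, y, theta, dose, n_nodes = 9) {
  cl <- theta[["cl"]]; v <- theta[["v"]]; ka <- theta[["ka"]]
  om <- c(theta[["omega2_cl"]], theta[["omega2_v"]])
  sg2 <- theta[["sigma2"]]
  conc <- function(eta) {
    ke <- cl * exp(eta[1]) / (v * exp(eta[2]))
    ka_ <- if (abs(ka - ke) < 1e-8) ke * (1 + 1e-6) else ka
    dose * ka_ / (v * exp(eta[2]) * (ka_ - ke)) *
      (exp(-ke * times) - exp(-ka_ * times))
  }
  neg_log_joint <- function(eta) {
    cc <- conc(eta)
    if (any(cc <= 0)) return(1e10)
    0.5 * sum(log(2 * pi * sg2 * cc^2) + (y - cc)^2 / (sg2 * cc^2)) +
      0.5 * sum(eta^2 / om) + 0.5 * sum(log(2 * pi * om))
  }
  fit <- nlminb(c(0, 0), neg_log_joint)
  mode <- fit$par
  H <- optimHess(mode, neg_log_joint)
  L <- chol(solve(H))               # scaling: eta = mode + sqrt(2) L' z
  gh <- pracma::gaussHermite(n_nodes)
  tot <- 0
  for (a in seq_len(n_nodes)) for (b in seq_len(n_nodes)) {
    z <- c(gh$x[a], gh$x[b])
    eta <- mode + sqrt(2) * drop(t(L) %*% z)
    w <- gh$w[a] * gh$w[b]
    tot <- tot + w * exp(-neg_log_joint(eta) + sum(z^2))
  }
  val <- tot * 2 / sqrt(det(H))     # (sqrt(2))^2 * det(L) = 2/sqrt(det H)
  -2 * log(val)
}

agq_ofv <- function(data, theta, dose, n_nodes = 9) {
  sum(vapply(unique(data$ID), function(i) {
    d <- data[data$ID == i, ]
    agq_ofv_subject(d$TIME, d$DV, theta, dose, n_nodes)
  }, numeric(1)))
}

# Exhaustive enumeration of inclusion probabilities for sequential
# without-replacement weighted draws of size 2 out of 3.
enumerate_inclusion_m2 <- function(p) {
  p <- p / sum(p)
  incl <- numeric(3)
  for (i in 1:3) for (j in setdiff(1:3, i)) {
    pr <- p[i] * p[j] / (1 - p[i])
    incl[i] <- incl[i] + pr
    incl[j] <- incl[j] + pr
  }
  incl
}

# A weighted sample built directly (no model evaluation) for resampling
# and diagnostics tests.
synthetic_weighted_sample <- function(dofv, log_relpdf = NULL,
                                      vectors = NULL) {
  M <- length(dofv)
  if (is.null(log_relpdf)) log_relpdf <- rep(0, M)
  if (is.null(vectors))
    vectors <- matrix(seq_len(M), ncol = 1, dimnames = list(NULL, "p1"))
  log_ir <- -dofv / 2 - log_relpdf
  structure(list(vectors = vectors, ofv = dofv, dofv = dofv,
                 relpdf = exp(log_relpdf), log_relpdf = log_relpdf,
                 ir = exp(log_ir), log_ir = log_ir, failures = 0L,
                 reference_ofv = 0, best = NULL),
            class = "weighted_sample")
}
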