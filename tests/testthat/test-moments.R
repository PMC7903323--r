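test_that("theoretical Poisson means have the right anchors and limits", {
  expect_equal(theo_mean_K(0), 0)
  expect_equal(theo_mean_K(pi), 4 * pi)
  expect_equal(theo_mean_K(pi / 2), 2 * pi)
  expect_equal(theo_mean_F(0, 10), 0)
  expect_equal(theo_mean_F(0.3, 0), 0)
  expect_true(all(diff(theo_mean_F(seq(0, pi, 0.1), 10)) >= 0))
  # H carries a small-count bias: its deviation from the F-form equals the
  # exact expectation bias (mu e^-mu - a e^-a)/(mu - a), vanishing as mu grows
  set.seed(501)
  for (i in 1:50) {
    r <- runif(1, 0.05, pi); rb <- runif(1, 0.5, 10)
    mu <- 4 * pi * rb * runif(1, 1, 3)        # physical: mu >= 4 pi rho_bar
    a <- rb * 2 * pi * (1 - cos(r))
    bias <- (a * exp(-a) - mu * exp(-mu)) / (mu - a)
    got <- theo_mean_F(r, rb) - theo_mean_H(r, rb, mu)
    if (abs(bias) > 1e-12) {
      expect_equal(got, bias, tolerance = 1e-6)
    } else {
      expect_lt(abs(got), 1e-11)   # below the cancellation floor of 1 - e^-a
    }
    expect_lt(abs(theo_mean_H(r, rb, 100 * mu) - theo_mean_F(r, rb)),
              abs(theo_mean_H(r, rb, mu) - theo_mean_F(r, rb)) + 1e-15)
  }
  expect_equal(theo_mean_H(0.3, 10, 1e6), theo_mean_F(0.3, 10),
               tolerance = 1e-6)
})

test_that("simulated means match the closed forms (CSR sphere)", {
  set.seed(502)
  nsim <- 1200
  rho <- 10; mu <- 4 * pi * rho
  P <- fibonacci_grid(64)
  r <- 0.3
  Fh <- Hh <- numeric(nsim)
  for (s in seq_len(nsim)) {
    Y <- runif_sphere_oracle(rpois(1, mu))
    sp <- sphere_pppify(Y)
    Fh[s] <- Finhom(sp, rho, rho, P, r)$est
    Hh[s] <- Hinhom(sp, rho, rho, r)$est
  }
  expect_lt(abs(mean(Fh) - theo_mean_F(r, rho)), 3 * sd(Fh) / sqrt(nsim))
  expect_lt(abs(mean(Hh) - theo_mean_H(r, rho, mu)), 3 * sd(Hh) / sqrt(nsim))
})

test_that("variance formulas vanish at r = 0 and are nonnegative", {
  ctx <- moment_context(10, P = fibonacci_grid(32))
  expect_equal(var_K(0, ctx), 0)
  expect_equal(var_F(0, ctx), 0)
  expect_equal(var_H(0, ctx), 0)
  expect_equal(cov_HF(0, ctx), 0)
  set.seed(503)
  for (i in 1:8) {
    r <- runif(1, 0.1, 2.5); rho <- runif(1, 2, 15)
    cx <- moment_context(rho, P = fibonacci_grid(16))
    expect_gte(var_K(r, cx), 0)
    expect_gte(var_F(r, cx), 0)
    expect_gte(var_H(r, cx), 0)
    expect_gte(suppressWarnings(j_moments(r, cx))$var, 0)
  }
})

test_that("constant-rho reductions agree with the quadrature route", {
  r <- 0.5
  P <- fibonacci_grid(64)
  c1 <- moment_context(10, P = P)
  cg <- moment_context(function(y) rep(10, nrow(y)), P = P, n_quad = 500)
  # smooth integrands (exact cap quadrature): tight agreement
  expect_equal(var_K(r, cg), var_K(r, c1), tolerance = 1e-8)
  # indicator-based Fibonacci pair sums: documented ~1% agreement
  expect_equal(var_F(r, cg), var_F(r, c1), tolerance = 0.05)
  expect_equal(var_H(r, cg), var_H(r, c1), tolerance = 0.05)
  expect_equal(cov_HF(r, cg), cov_HF(r, c1), tolerance = 0.1)
})

test_that("variance formulas match simulation for F and H", {
  set.seed(504)
  nsim <- 2000
  rho <- 10; r <- 0.5
  P <- fibonacci_grid(64)
  ctx <- moment_context(rho, P = P)
  Fh <- Hh <- numeric(nsim)
  for (s in seq_len(nsim)) {
    Y <- runif_sphere_oracle(rpois(1, 4 * pi * rho))
    sp <- sphere_pppify(Y)
    Fh[s] <- Finhom(sp, rho, rho, P, r)$est
    Hh[s] <- Hinhom(sp, rho, rho, r)$est
  }
  # variance of a variance estimate: ~ var * sqrt(2/(n-1)) for near-normal
  expect_lt(abs(var(Fh) - var_F(r, ctx)), 4 * var(Fh) * sqrt(2 / nsim))
  expect_lt(abs(var(Hh) - var_H(r, ctx)), 4 * var(Hh) * sqrt(2 / nsim))
})

test_that("delta-method J moments track simulation where they apply", {
  # the expansion needs the empty-ball probability to be non-negligible, so
  # the check sits at r = 0.3 for rho = 10
  set.seed(506)
  nsim <- 2000
  rho <- 10; r <- 0.3
  P <- fibonacci_grid(256)
  ctx <- moment_context(rho, P = P)
  J <- Fh <- Hh <- numeric(nsim)
  for (s in seq_len(nsim)) {
    Y <- runif_sphere_oracle(rpois(1, 4 * pi * rho))
    sp <- sphere_pppify(Y)
    Fh[s] <- Finhom(sp, rho, rho, P, r)$est
    Hh[s] <- Hinhom(sp, rho, rho, r)$est
    J[s] <- if (Fh[s] < 1) (1 - Hh[s]) / (1 - Fh[s]) else NA
  }
  attr(J, "Fh") <- Fh; attr(J, "Hh") <- Hh
  jm <- suppressWarnings(j_moments(r, ctx))
  # the expansion itself: theoretical moments plugged into the second-order
  # ratio formula agree with the same formula fed the empirical moments
  Fh <- attr(J, "Fh"); Hh <- attr(J, "Hh")
  x <- 1 - Hh; y <- 1 - Fh
  d_emp <- mean(x) / mean(y) - cov(x, y) / mean(y)^2 +
    var(y) * mean(x) / mean(y)^3
  expect_lt(abs(jm$mean - d_emp), 0.05)
  # the ratio J is heavy-tailed (its denominator is a small empty-ball
  # fraction), so its empirical mean converges slowly and the second-order
  # expansion carries O(CV^3) ~ 0.05 truncation error at these settings
  expect_lt(abs(jm$mean - mean(J, na.rm = TRUE)), 0.1)
  expect_gt(jm$var, 0)
})

test_that("K~ bias and variance follow the count decomposition", {
  r <- seq(0, pi, 0.5)
  # bias: -P(N <= 1) * 2 pi (1 - cos r), with the stated magnitude bound
  mu <- 40 * pi
  expect_equal(bias_Ktilde(r, SPH, 10), -ppois(1, mu) * 2 * pi * (1 - cos(r)))
  expect_lte(max(abs(bias_Ktilde(r, SPH, 10))),
             (4 * pi / exp(1)) * exp(-mu / 2) * (mu / 2 + 1))
  # r = 0: only the (vanishing) indicator blocks
  expect_equal(var_Ktilde(0, SPH, 10), 0)
  expect_true(all(var_Ktilde(r, SPH, 10) >= 0))
  expect_true(all(var_Ktilde(r, ELL04, 10) >= 0))
  # as mu grows, Var(K~) approaches the pair-count block of Var(K-hat)
  pair_block <- function(rr, rho) 4 * pi * 2 * pi * (1 - cos(rr)) /
    (8 * pi^2 * rho^2)
  rho_big <- 4000 / (4 * pi)
  expect_equal(var_Ktilde(0.5, SPH, rho_big), pair_block(0.5, rho_big),
               tolerance = 0.05)
})

test_that("the ratio-unbiased Poisson functionals evaluate exactly", {
  expect_equal(lemma2_R(0, 0, 1), 1)
  expect_equal(lemma2_R(2, 3, 1), 0)              # N < k
  expect_equal(lemma2_R(3, 1, 1), 3 * exp(2) / (exp(1) + 1)^3)
  # ratio-unbiasedness: E[numerator]/E[denominator] = lambda^k e^(-p lambda),
  # verified by exact Poisson series at small lambda
  lam <- 2.5
  n <- 0:120
  pr <- dpois(n, lam)
  for (k in 0:2) for (p in 1:2) {
    num <- sum(pr * ifelse(n >= k, factorial(n) / factorial(pmax(n - k, 0)) *
                             exp(n - k), 0))
    den <- sum(pr * (exp(1) + p)^n)
    expect_equal(num / den, lam^k * exp(-p * lam), tolerance = 1e-10)
    # and the implemented R has that same numerator/denominator structure
    expect_equal(mean(lemma2_R(n[1:5], k, p)),
                 mean(ifelse(n[1:5] >= k,
                             factorial(n[1:5]) / factorial(pmax(n[1:5] - k, 0)) *
                               exp(n[1:5] - k) / (exp(1) + p)^n[1:5], 0)))
  }
})

test_that("the plug-in K~ variance estimator is near ratio-unbiased", {
  set.seed(505)
  expect_warning(v0 <- estimate_var_Ktilde(0, SPH, c(0, 0.5)), "empty")
  expect_equal(v0, c(0, 0))
  expect_equal(estimate_var_Ktilde(100, SPH, 0), 0)
  est <- replicate(2000, estimate_var_Ktilde(rpois(1, 40 * pi), SPH, 0.5))
  expect_equal(mean(est), var_Ktilde(0.5, SPH, 10), tolerance = 0.15)
  # nonnegative even at tiny counts (flooring)
  for (n in 0:5)
    expect_true(all(suppressWarnings(
      estimate_var_Ktilde(n, SPH, c(0, 0.3, 1))) >= 0))
})
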