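test_that("Poisson counts and placement match the intensity measure", {
  set.seed(301)
  expect_equal(npoints(rpois_shape(SPH, 0)), 0)
  # mean count over simulations: sphere mu = 40 pi, ellipsoid mu = 5 * area
  n_s <- replicate(2000, npoints(rpois_shape(SPH, 10)))
  mu <- 40 * pi
  expect_lt(abs(mean(n_s) - mu), 3 * sd(n_s) / sqrt(2000))
  n_e <- replicate(2000, npoints(rpois_shape(ELL13, 5)))
  mu_e <- 5 * surface_area(ELL13)
  expect_lt(abs(mean(n_e) - mu_e), 3 * sd(n_e) / sqrt(2000))
  # count dispersion is Poisson (variance ~ mean)
  expect_lt(abs(var(n_s) / mean(n_s) - 1), 0.15)
  # functional intensity via thinning: z-dependent rate on the sphere
  rho_fn <- function(x) 5 * (1 + x[, 3]^2)
  n_f <- replicate(500, npoints(rpois_shape(SPH, rho_fn, rho_max = 10)))
  mu_f <- 5 * 4 * pi * (1 + 1 / 3)
  expect_lt(abs(mean(n_f) - mu_f), 3 * sd(n_f) / sqrt(500))
  expect_error(rpois_shape(SPH, rho_fn), "rho_max")
})

test_that("uniform sampling on the spheroid matches the area measure", {
  set.seed(302)
  X <- runif_shape(ELL13, 20000)
  # fraction of points with |z| <= 1.5 equals the area of that belt
  G <- fibonacci_grid(40000L)
  rt <- rho_tilde_fun(ELL13, "axis")(G)
  belt <- sum(rt[abs(G[, 3]) * 3 <= 1.5]) / sum(rt)
  phat <- mean(abs(X[, 3]) <= 1.5)
  expect_lt(abs(phat - belt), 3 * sqrt(belt * (1 - belt) / 20000))
  # cube faces are hit uniformly
  Xc <- runif_shape(CUBE1, 12000)
  f <- piece_index(CUBE1, Xc)
  expect_gt(stats::chisq.test(tabulate(f, 6))$p.value, 0.001)
})

test_that("Matern I thinning retains isolated events only", {
  set.seed(303)
  # R = 0: identical to the Poisson realisation under the same seed
  p0 <- rmatern1_shape(SPH, 10, R = 0, seed = 99)
  q0 <- rpois_shape(SPH, 10, seed = 99)
  expect_equal(p0$points, q0$points)
  # retention probability on the sphere: exp(-rho * cap area)
  nsim <- 1500
  kept <- prop <- numeric(nsim)
  for (i in seq_len(nsim)) {
    p <- rmatern1_shape(SPH, 10, R = 0.3)
    kept[i] <- npoints(p)
    prop[i] <- p$metadata$n_proposed
  }
  ret <- exp(-10 * 2 * pi * (1 - cos(0.3)))
  phat <- sum(kept) / sum(prop)
  se <- sd(kept - prop * ret) / (mean(prop) * sqrt(nsim))
  expect_lt(abs(phat - ret), 3 * se)
  # R larger than the diameter: at most one survivor
  p_big <- rmatern1_shape(SPH, 2, R = 4)
  expect_lte(npoints(p_big), 1)
})

test_that("Matern II keeps the smaller mark and attains the mean formula", {
  set.seed(304)
  # R = 0 leaves the Poisson realisation unchanged
  p0 <- rmatern2_shape(SPH, 10, R = 0, seed = 7)
  q0 <- rpois_shape(SPH, 10, seed = 7)
  expect_equal(p0$points, q0$points)
  # mean surviving count matches (1 - exp(-rho A))/A * area on the sphere
  nsim <- 1500
  cnt <- numeric(nsim)
  for (i in seq_len(nsim)) cnt[i] <- npoints(rmatern2_shape(SPH, 10, R = 0.2))
  A <- 2 * pi * (1 - cos(0.2))
  m_theo <- (1 - exp(-10 * A)) / A * 4 * pi
  expect_lt(abs(mean(cnt) - m_theo), 3 * sd(cnt) / sqrt(nsim))
})

test_that("hard-core patterns have no geodesic neighbours within R", {
  set.seed(305)
  for (i in 1:5) {
    p <- rmatern1_shape(SPH, 10, R = 0.25)
    if (npoints(p) > 1) {
      D <- geodesic_pairdist(SPH, p$points); diag(D) <- Inf
      expect_gte(min(D), 0.25)
    }
    q <- rmatern2_shape(SPH, 10, R = 0.25)
    if (npoints(q) > 1) {
      D <- geodesic_pairdist(SPH, q$points); diag(D) <- Inf
      expect_gte(min(D), 0.25)
    }
  }
  # and on the ellipsoid, in its own (mesh) metric
  q <- rmatern2_shape(ELL13, 5, R = 0.4, seed = 11)
  D <- geodesic_pairdist(ELL13, q$points); diag(D) <- Inf
  expect_gte(min(D), 0.4)
  # thinning consistency: survivors are a subset of the proposals
  expect_lte(npoints(q), q$metadata$n_proposed)
})

test_that("the Matern II intensity calibration solves the mean equation", {
  # R -> 0 limit: target / area
  expect_equal(solve_matern2_intensity(SPH, 0, 100), 100 / (4 * pi))
  # sphere closed form: constant ball area A
  A <- 2 * pi * (1 - cos(0.1))
  rho_cf <- -log(1 - 100 * A / (4 * pi)) / A
  expect_equal(solve_matern2_intensity(SPH, 0.1, 100), rho_cf,
               tolerance = 1e-6)
  # infeasible target reports the attainable maximum
  expect_error(solve_matern2_intensity(SPH, 0.1, 1 + 4 * pi / A),
               "infeasible")
  # calibrated simulation hits the target mean
  set.seed(306)
  rho <- solve_matern2_intensity(SPH, 0.1, 100)
  cnt <- replicate(1500, npoints(rmatern2_shape(SPH, rho, R = 0.1)))
  expect_lt(abs(mean(cnt) - 100), 3 * sd(cnt) / sqrt(1500))
  # quadrature route on the ellipsoid brackets the sphere value for a = b = c
  rho_q <- solve_matern2_intensity(ESPH, 0.1, 100)
  expect_equal(rho_q, rho_cf, tolerance = 0.05)
})

test_that("the Riemannian Gaussian kernel is a normalised density", {
  # 1D reduction oracle on the sphere
  chi_oracle <- 2 * pi *
    stats::integrate(function(t) exp(-t^2 / (2 * 0.5^2)) * sin(t), 0,
                     pi)$value
  expect_equal(rg_normalizer(SPH, c(0, 0, 1), 0.5), chi_oracle,
               tolerance = 1e-8)
  # maximal value at the centre is 1/chi
  expect_equal(rg_kernel(SPH, c(0, 0, 1), 0.5, c(0, 0, 1)), 1 / chi_oracle)
  # kappa -> infinity: uniform density 1/area
  expect_equal(rg_normalizer(SPH, c(0, 0, 1), 1e6), 4 * pi, tolerance = 1e-6)
  # mesh quadrature on the ellipsoid integrates to one
  m <- shape_mesh(ELL13)
  dens <- rg_kernel(ELL13, c(0, 0, 3), 0.7, m$v)
  expect_equal(sum(dens * m$varea), 1, tolerance = 1e-6)
})

test_that("Thomas processes cluster around unseen parents", {
  set.seed(307)
  # alpha = 0: empty
  expect_equal(npoints(rthomas_shape(SPH, 1, 0, 0.5)), 0)
  # kappa = Inf collapses to CSR with intensity rho_parent * alpha
  cnt <- replicate(1000, npoints(rthomas_shape(SPH, 150 / (4 * pi * 20), 20,
                                               Inf)))
  expect_lt(abs(mean(cnt) - 150), 3 * sd(cnt) / sqrt(1000))
  # mean count at finite kappa equals rho_parent * area * alpha
  cnt2 <- replicate(800, npoints(rthomas_shape(SPH, 150 / (4 * pi * 20), 20,
                                               0.5)))
  expect_lt(abs(mean(cnt2) - 150), 3 * sd(cnt2) / sqrt(800))
  # offspring really concentrate: mean nearest-neighbour distance is far
  # below the CSR value for the same count
  p <- rthomas_shape(SPH, 5 / (4 * pi), 30, 0.1, seed = 3)
  D <- geodesic_pairdist(SPH, p$points); diag(D) <- Inf
  nnd <- mean(apply(D, 1, min))
  expect_lt(nnd, 0.5 * sqrt(pi / npoints(p)))
})

test_that("simulators are bit-reproducible under a fixed seed", {
  for (f in list(function(s) rpois_shape(ELL13, 5, seed = s),
                 function(s) rmatern2_shape(SPH, 10, 0.2, seed = s),
                 function(s) rthomas_shape(SPH, 1, 10, 0.5, seed = s))) {
    a <- f(42); b <- f(42); c2 <- f(43)
    expect_identical(a$points, b$points)
    expect_false(identical(a$points, c2$points))
  }
  expect_identical(derive_seed(1, 5), derive_seed(1, 5))
  expect_true(derive_seed(1, 5) != derive_seed(1, 6))
  expect_lt(derive_seed(2^20, 10^6), 2^31)
})
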