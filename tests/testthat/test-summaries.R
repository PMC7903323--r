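test_that("the Fibonacci grid is deterministic and near-uniform", {
  expect_equal(nrow(fibonacci_grid(1)), 1)
  expect_identical(fibonacci_grid(500), fibonacci_grid(500))
  G <- fibonacci_grid(1000)
  expect_equal(sqrt(rowSums(G^2)), rep(1, 1000))
  # nearest-neighbour distances have a small coefficient of variation
  D <- tcrossprod(G); D[D > 1] <- 1; D[D < -1] <- -1
  D <- acos(D); diag(D) <- Inf
  nn <- apply(D, 1, min)
  expect_lt(sd(nn) / mean(nn), 0.15)
  # even n = 4 points spread out rather than cluster
  expect_lt(sqrt(sum(colMeans(fibonacci_grid(4))^2)), 0.5)
  # radius grids are strictly increasing within [0, pi]
  r <- radius_grid()
  expect_equal(r[1], 0)
  expect_lte(max(r), pi)
  expect_false(is.unsorted(r, strictly = TRUE))
})

test_that("K estimator matches its direct formula on tiny patterns", {
  r <- c(0.5, 3, pi)
  # single event: empty double sum
  one <- sphere_pppify(matrix(c(0, 0, 1), 1))
  expect_equal(Kinhom(one, 1, r)$est, c(0, 0, 0))
  # two antipodal events, rho = 1: 0 before pi, 2/(4 pi) at pi
  two <- sphere_pppify(rbind(c(0, 0, 1), c(0, 0, -1)))
  expect_equal(Kinhom(two, 1, r)$est, c(0, 0, 1 / (2 * pi)))
  # zero-intensity events are dropped with a warning
  expect_warning(
    K0 <- Kinhom(two, function(y) c(1, 0), r), "zero intensity")
  expect_equal(K0$est, c(0, 0, 0))
})

test_that("K estimator equals the brute-force double loop exactly", {
  set.seed(401)
  r <- c(0.2, 0.7, 1.5, 2.9)
  for (i in 1:20) {
    n <- sample(2:50, 1)
    Y <- runif_sphere_oracle(n)
    rho_vals <- runif(n, 0.5, 3)
    sp <- sphere_pppify(Y)
    got <- Kinhom(sp, function(y) rho_vals, r)$est
    expect_equal(got, khat_bruteforce(Y, rho_vals, r), tolerance = 1e-12)
  }
})

test_that("F/H/J estimators honour their boundary cases", {
  r <- c(0, 0.4, 1)
  P <- fibonacci_grid(32)
  # empty pattern: F = 0 (empty products are 1), H = 0 by convention
  empty <- sphere_pppify(matrix(0, 0, 3))
  expect_equal(Finhom(empty, 1, 1, P, r)$est, c(0, 0, 0))
  expect_equal(Hinhom(empty, 1, 1, r)$est, c(0, 0, 0))
  # single event: H = 0 for all r
  one <- sphere_pppify(matrix(c(0, 0, 1), 1))
  expect_equal(Hinhom(one, 1, 1, r)$est, c(0, 0, 0))
  # homogeneous case: F is the classical empty-ball estimator
  set.seed(402)
  Y <- runif_sphere_oracle(40)
  sp <- sphere_pppify(Y)
  DP <- P %*% t(Y); DP[DP > 1] <- 1; DP[DP < -1] <- -1
  DP <- acos(DP)
  manual <- vapply(r, function(ri) 1 - mean(apply(DP, 1,
                                                  function(d) all(d > ri))),
                   numeric(1))
  expect_equal(Finhom(sp, 1, 1, P, r)$est, manual)
  # two events at distance delta, rho = rho_bar = 1: H steps from 0 to 1
  delta <- 0.3
  twod <- sphere_pppify(rbind(c(0, 0, 1),
                              c(sin(delta), 0, cos(delta))))
  expect_equal(Hinhom(twod, 1, 1, c(0.1, 0.2, 0.31))$est, c(0, 0, 1))
  # J: ratio with flagged undefined entries
  Fc <- Finhom(sp, 1, 1, P, r); Hc <- Hinhom(sp, 1, 1, r)
  J <- Jinhom(Fc, Hc)
  expect_equal(J$est[1], 1)          # F = H = 0 at r = 0
  expect_true(all(is.na(J$est) | J$est >= 0))
  big <- Jinhom(Finhom(sp, 1, 1, P, c(2.8, pi)), Hinhom(sp, 1, 1, c(2.8, pi)))
  expect_true(all(is.na(big$est)))   # all balls occupied: F = 1
  # rho_bar validation
  expect_error(Finhom(sp, 1, 2, P, r), "rho_bar")
})

test_that("unknown-rate K~ handles tiny patterns and unit-sphere identity", {
  r <- c(1, pi)
  expect_equal(Ktilde(sphere_pppify(matrix(0, 0, 3), SPH), r)$est, c(0, 0))
  expect_equal(Ktilde(sphere_pppify(matrix(c(0, 0, 1), 1), SPH), r)$est,
               c(0, 0))
  # two antipodal points on the unit sphere: K~(pi) = 4 pi
  two <- sphere_pppify(rbind(c(0, 0, 1), c(0, 0, -1)), SPH)
  expect_equal(Ktilde(two, r)$est, c(0, 4 * pi))
})

test_that("P transform and centred K behave as documented", {
  r <- radius_grid(by = 0.1)
  set.seed(403)
  sp <- sphere_pppify(runif_sphere_oracle(80), SPH)
  Kc <- Ktilde(sp, r)
  P <- Pinhom(Kc)
  expect_equal(P$est[1], 0)                       # r = 0 always 0
  expect_equal(P$est, sqrt(Kc$est) - sqrt(2 * pi * (1 - cos(r))))
  Kd <- Kcentred(Kc)
  expect_equal(Kd$est, Kc$est - 2 * pi * (1 - cos(r)))
  # exact theoretical curve maps to the zero function
  Kth <- Kc; Kth$est <- 2 * pi * (1 - cos(r))
  expect_equal(Pinhom(Kth)$est, rep(0, length(r)))
  expect_equal(Kcentred(Kth)$est, rep(0, length(r)))
})

test_that("curves are invariant under joint rotation of pattern and intensity", {
  set.seed(404)
  Y <- runif_sphere_oracle(60)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rho_fn <- function(y) 5 + 3 * y[, 3]^2          # rotation-axis symmetric
  r <- c(0.3, 0.8, 1.7)
  sp1 <- sphere_pppify(Y); sp2 <- sphere_pppify(Y %*% t(R))
  expect_equal(Kinhom(sp1, rho_fn, r)$est, Kinhom(sp2, rho_fn, r)$est)
  expect_equal(Hinhom(sp1, rho_fn, 5, r)$est, Hinhom(sp2, rho_fn, 5, r)$est)
  # F uses a rotated reference grid for exact invariance
  P <- fibonacci_grid(64)
  expect_equal(Finhom(sp1, rho_fn, 5, P, r)$est,
               Finhom(sp2, rho_fn, 5, P %*% t(R), r)$est)
})

test_that("mapped-pattern summaries are unbiased for the Poisson forms", {
  set.seed(405)
  nsim <- 400
  r <- c(0.5, 1, 2)
  acc <- matrix(0, nsim, length(r))
  model <- intensity_model(ELL13, 5, "axis")
  for (s in seq_len(nsim)) {
    sp <- map_to_sphere(rpois_shape(ELL13, 5), "axis")
    acc[s, ] <- Kinhom(sp, model$rho_star, r)$est
  }
  theo <- 2 * pi * (1 - cos(r))
  for (k in seq_along(r))
    expect_lt(abs(mean(acc[, k]) - theo[k]), 3 * sd(acc[, k]) / sqrt(nsim))
})

test_that("radial and axis mapping pipelines agree in distribution", {
  set.seed(406)
  nsim <- 250
  r <- c(0.5, 1.2)
  res <- array(0, c(nsim, 2, length(r)))
  model_r <- intensity_model(ELL13, 5, "radial")
  model_a <- intensity_model(ELL13, 5, "axis")
  for (s in seq_len(nsim)) {
    p <- rpois_shape(ELL13, 5)
    res[s, 1, ] <- Kinhom(map_to_sphere(p, "radial"), model_r$rho_star, r)$est
    res[s, 2, ] <- Kinhom(map_to_sphere(p, "axis"), model_a$rho_star, r)$est
  }
  for (k in seq_along(r)) {
    se <- sqrt(sd(res[, 1, k])^2 + sd(res[, 2, k])^2) / sqrt(nsim)
    expect_lt(abs(mean(res[, 1, k]) - mean(res[, 2, k])), 3 * se)
  }
})

test_that("shape_summary dispatches the estimator family", {
  set.seed(407)
  p <- rpois_shape(ELL13, 5)
  r <- radius_grid(by = 0.2)
  for (st in c("K", "F", "H", "J")) {
    cv <- shape_summary(p, st, rho = 5, r = r)
    expect_s3_class(cv, "fss_curve")
    expect_equal(nrow(cv), length(r))
  }
  expect_error(shape_summary(p, "K"), "rho")
  kt <- shape_summary(p, "K_tilde", r = r)
  expect_true(all(kt$est >= 0))
  expect_equal(shape_summary(p, "P", r = r)$est,
               sqrt(kt$est) - sqrt(2 * pi * (1 - cos(r))))
})
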