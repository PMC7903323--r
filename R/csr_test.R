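## Precomputed context for the test statistics: shape-level geometry shared
## by the observed pattern and all null simulations.  Null patterns are drawn
## directly on the sphere side (density proportional to rho~), which is
## exactly the mapped image of CSR on the shape.
.test_context <- function(shape, kind = NULL, r = radius_grid()) {
  if (is.null(kind))
    kind <- if (shape$name %in% c("sphere", "ellipsoid")) "axis" else "radial"
  geo <- .ktilde_geometry(shape, kind, r)
  rt <- rho_tilde_fun(shape, kind)
  p <- shape$params
  is_sph <- .is_sphere(shape) && kind == "axis"
  rtmax <- if (is_sph) {
    1
  } else if (shape$name == "ellipsoid" && kind == "axis" &&
             abs(p$a - p$b) < 1e-12) {
    p$a * p$b * max(1, p$c / p$a)
  } else {
    max(rt(fibonacci_grid(4096L))) * 1.05
  }
  list(shape = shape, kind = kind, r = r, A = .cap_area(r),
       sqrtA = sqrt(.cap_area(r)), geo = geo, rho_tilde = rt,
       rho_tilde_max = rtmax, is_sphere = is_sph,
       rt_const = if (is_sph) p$a^2 else NA_real_, lam = geo$lam)
}

## sphere-side CSR sample: N ~ Poisson(rho * lambda_D); points with density
## proportional to rho~ by rejection from the uniform sphere
.rnull_sphere <- function(ctx, rho) {
  n <- stats::rpois(1, rho * ctx$lam)
  if (n == 0) return(matrix(0, 0, 3))
  if (ctx$is_sphere) {
    u <- matrix(stats::rnorm(3 * n), ncol = 3)
    return(u / sqrt(rowSums(u^2)))
  }
  out <- matrix(0, 0, 3)
  while (nrow(out) < n) {
    m <- ceiling((n - nrow(out)) * 1.7) + 8L
    u <- matrix(stats::rnorm(3 * m), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    v <- ctx$rho_tilde(u)
    if (any(v > ctx$rho_tilde_max * (1 + 1e-9)))
      stop("rho_tilde envelope violated")
    out <- rbind(out, u[stats::runif(m) < v / ctx$rho_tilde_max, ,
                        drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

## K~ curve and both statistics for a set of unit vectors
.ktilde_curve_fast <- function(Y, ctx) {
  n <- nrow(Y)
  if (n <= 1) return(numeric(length(ctx$r)))
  iw <- if (ctx$is_sphere) rep(1 / ctx$rt_const, n) else 1 / ctx$rho_tilde(Y)
  cang <- tcrossprod(Y)
  cang[cang > 1] <- 1; cang[cang < -1] <- -1
  D <- acos(cang)
  ut <- upper.tri(D)
  s <- 2 * .cum_pair_weight(D[ut], (tcrossprod(iw))[ut], ctx$r)
  ctx$lam^2 / (4 * pi * n * (n - 1)) * s
}

.stats_fast <- function(Y, ctx) {
  K <- .ktilde_curve_fast(Y, ctx)
  T1 <- max(abs(sqrt(pmax(0, K)) - ctx$sqrtA))
  n <- nrow(Y)
  V <- if (n == 0) numeric(length(ctx$r)) else {
    rho2 <- n * (n - 1) / ctx$lam^2
    rho3 <- n * (n - 1) * (n - 2) / ctx$lam^3
    pmax(0, 4 * pi^2 * (1 - cos(ctx$r))^2 * .pp_est(n) +
           rho3 * (1 - cos(ctx$r))^2 * ctx$geo$c2 * (n + 3)^-2 * (n + 2)^-2 +
           rho2 / (8 * pi^2) * ctx$geo$c3 * (n + 2)^-2 * (n + 1)^-2)
  }
  dev <- abs(K - ctx$A)
  z <- ifelse(V > 0, dev / sqrt(V), 0)    # zero-variance radii contribute 0
  c(T1 = T1, T2 = max(z))
}

#' CSR test statistics on the evaluation grid
#'
#' `T1` is the maximum absolute deviation of the variance-stabilised centred
#' K-curve (`sqrt(K~) - sqrt(2 pi (1 - cos r))`); `T2` is the maximum of the
#' centred K-curve standardised by its plug-in estimated standard deviation
#' ([estimate_var_Ktilde]); both over the discrete radius grid. Radii with a
#' zero (or floored) variance estimate contribute 0 to `T2`, so `r = 0` never
#' dominates.
#'
#' @param pattern a [surface_ppp] (or a `sphere_ppp` already mapped).
#' @param kind mapping kind (see [map_to_sphere]).
#' @param r evaluation grid of radii.
#' @export
stat_T1 <- function(pattern, kind = NULL, r = radius_grid()) {
  .stat_one(pattern, kind, r)["T1"]
}

#' @rdname stat_T1
#' @export
stat_T2 <- function(pattern, kind = NULL, r = radius_grid()) {
  .stat_one(pattern, kind, r)["T2"]
}

.stat_one <- function(pattern, kind, r) {
  sp <- if (inherits(pattern, "sphere_ppp")) pattern
        else map_to_sphere(pattern, kind)
  ctx <- .test_context(sp$shape, sp$kind, r)
  .stats_fast(sp$points, ctx)
}

#' Monte-Carlo test of complete spatial randomness
#'
#' Computes the chosen statistic for the observed pattern and for `m` null
#' CSR patterns simulated with the intensity fitted from the observed count
#' (`rho-hat = N / lambda_D(D)`; set `null_rho` to use a known rate), and
#' returns the add-one Monte-Carlo p-value
#' `(1 + #\{null >= observed\}) / (m + 1)`, exact for exchangeable
#' statistics; ties count towards rejection-adverse ranks (conservative).
#'
#' @param pattern a [surface_ppp].
#' @param statistic `"T1"`, `"T2"`, or `"both"`.
#' @param m number of null simulations (999 in the reference study).
#' @param alpha significance level.
#' @param seed optional integer seed for exact reproducibility.
#' @param null_rho `NULL` for the fitted rate, or a positive number.
#' @param kind mapping kind.
#' @param r evaluation grid.
#' @return an object of class `mc_test` (a list of results for
#'   `statistic = "both"`).
#' @export
mc_test <- function(pattern, statistic = c("T1", "T2", "both"), m = 999L,
                    alpha = 0.05, seed = NULL, null_rho = NULL,
                    kind = NULL, r = radius_grid()) {
  statistic <- match.arg(statistic)
  if (!is.null(seed)) set.seed(seed)
  if (m < ceiling(1 / alpha) - 1)
    warning("m too small to ever reject at this alpha")
  sp <- map_to_sphere(pattern, kind)
  ctx <- .test_context(sp$shape, sp$kind, r)
  obs <- .stats_fast(sp$points, ctx)
  rho0 <- if (is.null(null_rho)) nrow(sp$points) / ctx$lam else null_rho
  nulls <- matrix(0, m, 2, dimnames = list(NULL, c("T1", "T2")))
  for (i in seq_len(m))
    nulls[i, ] <- .stats_fast(.rnull_sphere(ctx, rho0), ctx)
  mk <- function(s) {
    p <- (1 + sum(nulls[, s] >= obs[s])) / (m + 1)
    structure(list(statistic = s, observed = unname(obs[s]),
                   null_stats = nulls[, s], p_value = p, alpha = alpha,
                   reject = p <= alpha, m = m, seed = seed,
                   n_obs = nrow(sp$points), null_rho = rho0),
              class = "mc_test")
  }
  switch(statistic, T1 = mk("T1"), T2 = mk("T2"),
         both = list(T1 = mk("T1"), T2 = mk("T2")))
}

#' @export
print.mc_test <- function(x, ...) {
  cat("Monte-Carlo CSR test,", x$statistic, "\n")
  cat(sprintf("  observed = %.5g on %d events; m = %d nulls (rho0 = %.4g)\n",
              x$observed, x$n_obs, x$m, x$null_rho))
  cat(sprintf("  p = %.4g -> %s H0 at alpha = %g\n", x$p_value,
              if (x$reject) "reject" else "do not reject", x$alpha))
  invisible(x)
}

#' Pointwise simulation envelopes for a summary statistic
#'
#' Computes the observed curve plus the pointwise minimum and maximum over
#' `m` CSR simulations fitted to the observed count (the graphical envelope
#' of the reference figures).
#'
#' @param pattern a [surface_ppp].
#' @param stat one of "K", "F", "H", "J", "P", "K_tilde", "K_std" (the
#'   standardised centred K-curve underlying T2).
#' @param m number of null simulations.
#' @param seed optional seed.
#' @param rho known intensity on the shape (fitted from the count if NULL).
#' @param kind mapping kind.
#' @param r radius grid.
#' @param P reference grid for the F-function.
#' @return class `csr_envelope`: data.frame `r, obs, lo, hi, theo`.
#' @export
csr_envelope <- function(pattern, stat = c("K", "F", "H", "J", "P",
                                           "K_tilde", "K_std"),
                         m = 99L, seed = NULL, rho = NULL, kind = NULL,
                         r = radius_grid(), P = fibonacci_grid(256L)) {
  stat <- match.arg(stat)
  if (!is.null(seed)) set.seed(seed)
  sp <- map_to_sphere(pattern, kind)
  shape <- pattern$shape
  ctx <- .test_context(shape, sp$kind, r)
  if (is.null(rho)) rho <- nrow(sp$points) / ctx$lam
  model <- if (stat %in% c("K", "F", "H", "J"))
    intensity_model(shape, rho, sp$kind) else NULL
  curve_of <- function(Y) {
    spi <- structure(list(points = Y, shape = shape, kind = sp$kind),
                     class = "sphere_ppp")
    switch(stat,
      K = Kinhom(spi, model$rho_star, r)$est,
      F = Finhom(spi, model$rho_star, model$rho_star_inf, P, r)$est,
      H = Hinhom(spi, model$rho_star, model$rho_star_inf, r)$est,
      J = Jinhom(Finhom(spi, model$rho_star, model$rho_star_inf, P, r),
                 Hinhom(spi, model$rho_star, model$rho_star_inf, r))$est,
      K_tilde = .ktilde_curve_fast(Y, ctx),
      P = sqrt(pmax(0, .ktilde_curve_fast(Y, ctx))) - ctx$sqrtA,
      K_std = {
        K <- .ktilde_curve_fast(Y, ctx)
        V <- estimate_var_Ktilde(nrow(Y), shape, r, sp$kind)
        ifelse(V > 0, (K - ctx$A) / sqrt(V), 0)
      })
  }
  obs <- curve_of(sp$points)
  sims <- matrix(NA_real_, m, length(r))
  for (i in seq_len(m)) sims[i, ] <- curve_of(.rnull_sphere(ctx, rho))
  theo <- switch(stat,
    K = , K_tilde = ctx$A,
    F = , H = 1 - exp(-(if (is.null(model)) rho else model$rho_star_inf) *
                        ctx$A),
    J = rep(1, length(r)),
    P = , K_std = rep(0, length(r)))
  structure(data.frame(r = r, obs = obs,
                       lo = suppressWarnings(apply(sims, 2, min, na.rm = TRUE)),
                       hi = suppressWarnings(apply(sims, 2, max, na.rm = TRUE)),
                       theo = theo),
            class = c("csr_envelope", "data.frame"),
            stat = stat, m = m, n_obs = nrow(sp$points))
}

#' @export
plot.csr_envelope <- function(x, main = NULL, xlab = "r", ylab = NULL, ...) {
  st <- attr(x, "stat")
  ok <- is.finite(x$lo) & is.finite(x$hi)
  ylim <- range(x$obs[is.finite(x$obs)], x$lo[ok], x$hi[ok], x$theo,
                na.rm = TRUE)
  if (is.null(ylab)) ylab <- st
  if (is.null(main))
    main <- sprintf("%s with pointwise envelope (m = %d)", st, attr(x, "m"))
  graphics::plot(x$r, x$obs, type = "n", ylim = ylim, xlab = xlab,
                 ylab = ylab, main = main, ...)
  graphics::polygon(c(x$r[ok], rev(x$r[ok])), c(x$lo[ok], rev(x$hi[ok])),
                    col = "grey85", border = NA)
  graphics::lines(x$r, x$theo, lty = 2)
  graphics::lines(x$r, x$obs, lwd = 1.5)
  invisible(x)
}
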