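#' Near-uniform deterministic grid on the unit sphere
#'
#' Spherical Fibonacci lattice: `z_i = 1 - (2i+1)/n`, azimuth stepping by the
#' golden angle. Used both as the reference grid `P` of the empty-space
#' estimator and as a quasi-uniform quadrature node set.
#'
#' @param n number of points.
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacci_grid <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 1
  z <- 1 - (2 * i + 1) / n
  phi <- 2 * pi * i * (sqrt(5) - 1) / 2
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(s * cos(phi), s * sin(phi), z)
}

#' Evaluation grid of geodesic radii
#'
#' The default replicates the grid used throughout the simulation study:
#' `{0, 0.02, 0.04, ..., pi}` (geodesic radians on the unit sphere).
#' @param by grid step.
#' @param to upper end (clamped to pi).
#' @export
radius_grid <- function(by = 0.02, to = pi) {
  r <- seq(0, min(to, pi), by = by)
  stopifnot(length(r) >= 1, !is.unsorted(r, strictly = TRUE))
  r
}

.pairdist_unit_sphere <- function(Y) {
  cang <- tcrossprod(Y)
  cang[cang > 1] <- 1; cang[cang < -1] <- -1
  D <- acos(cang); diag(D) <- 0
  D
}

.crossdist_unit_sphere <- function(A, B) {
  cang <- A %*% t(B)
  cang[cang > 1] <- 1; cang[cang < -1] <- -1
  acos(cang)
}

.rho_values <- function(rho, Y) {
  v <- if (is.function(rho)) rho(Y) else rep(rho, nrow(Y))
  if (any(v < 0)) stop("intensity values must be nonnegative")
  v
}

.fss_curve <- function(kind, r, est, theo = NULL, meta = list()) {
  df <- data.frame(r = r, est = est)
  if (!is.null(theo)) df$theo <- theo
  structure(df, class = c("fss_curve", "data.frame"),
            kind = kind, meta = meta)
}

#' @export
print.fss_curve <- function(x, ...) {
  cat("functional summary statistic:", attr(x, "kind"),
      "on", nrow(x), "radii in [", format(min(x$r)), ",",
      format(max(x$r)), "]\n")
  utils::str(unclass(attributes(x)$meta))
  invisible(x)
}

## step-function evaluation of a weighted pair count on a radius grid
.cum_pair_weight <- function(d, w, r) {
  if (length(d) == 0) return(numeric(length(r)))
  o <- order(d)
  cw <- cumsum(w[o])
  idx <- findInterval(r, d[o])
  c(0, cw)[idx + 1]
}

#' Inhomogeneous K-function estimator on the sphere
#'
#' `K(r) = (1/4pi) * sum over ordered pairs of 1[d <= r] / (rho(x) rho(y))`,
#' unbiased for `2 pi (1 - cos r)` under a Poisson process with known
#' intensity. Events where `rho` vanishes are dropped with a warning
#' (the `a/0 = 0` convention).
#'
#' @param sp a `sphere_ppp` (or any object with unit-vector `$points`).
#' @param rho intensity on the sphere: constant or function of unit vectors.
#' @param r radius grid.
#' @export
Kinhom <- function(sp, rho, r = radius_grid()) {
  Y <- sp$points
  rv <- .rho_values(rho, Y)
  if (any(rv == 0)) {
    warning("events with zero intensity dropped (a/0 = 0 convention)")
    Y <- Y[rv > 0, , drop = FALSE]
    rv <- rv[rv > 0]
  }
  n <- nrow(Y)
  if (n < 2)
    return(.fss_curve("K", r, numeric(length(r)), theo = 2 * pi * (1 - cos(r)),
                      meta = list(n = n)))
  D <- .pairdist_unit_sphere(Y)
  iw <- 1 / rv
  ut <- upper.tri(D)
  est <- .cum_pair_weight(D[ut], (tcrossprod(iw))[ut], r) * 2 / (4 * pi)
  .fss_curve("K", r, est, theo = 2 * pi * (1 - cos(r)), meta = list(n = n))
}

## shared machinery of the F- and H-estimators: for each reference point,
## the running product of (1 - rho_bar/rho) over events ordered by distance
.ball_products <- function(dmat, fac, r) {
  ## dmat: nref x nev distances; fac: length-nev factors; returns nref x nr
  nref <- nrow(dmat); nr <- length(r)
  out <- matrix(1, nref, nr)
  if (ncol(dmat) == 0) return(out)
  for (i in seq_len(nref)) {
    d <- dmat[i, ]
    o <- order(d)
    cp <- cumprod(fac[o])
    idx <- findInterval(r, d[o])
    out[i, ] <- c(1, cp)[idx + 1]
  }
  out
}

#' Inhomogeneous empty-space (F) function estimator on the sphere
#'
#' `F(r) = 1 - mean over p in P of prod over events within r of p of
#' (1 - rho_bar / rho(x))`, with `rho_bar = inf rho`. Unbiased for
#' `1 - exp(-rho_bar * 2 pi (1 - cos r))` under a Poisson process.
#'
#' @inheritParams Kinhom
#' @param rho_bar infimum of the intensity (must not exceed any event's rho).
#' @param P reference grid on the sphere (default 256-point Fibonacci grid).
#' @export
Finhom <- function(sp, rho, rho_bar, P = fibonacci_grid(256L),
                   r = radius_grid()) {
  Y <- sp$points
  rv <- .rho_values(rho, Y)
  if (rho_bar <= 0 || (nrow(Y) && rho_bar > min(rv) * (1 + 1e-9)))
    stop("rho_bar must be positive and no larger than rho at every event")
  fac <- 1 - rho_bar / rv
  dmat <- .crossdist_unit_sphere(P, Y)
  prods <- .ball_products(dmat, fac, r)
  est <- 1 - colMeans(prods)
  .fss_curve("F", r, est,
             theo = 1 - exp(-rho_bar * 2 * pi * (1 - cos(r))),
             meta = list(n = nrow(Y), P = nrow(P), rho_bar = rho_bar))
}

#' Inhomogeneous nearest-event (H) function estimator on the sphere
#'
#' Like [Finhom] but referenced at the events themselves (reduced-Palm
#' version): `H(r) = 1 - (1/N) sum over events x of prod over other events
#' within r of x of (1 - rho_bar / rho(y))`. Ratio-unbiased; the empty
#' pattern yields the zero curve (flagged in the metadata).
#'
#' @inheritParams Finhom
#' @export
Hinhom <- function(sp, rho, rho_bar, r = radius_grid()) {
  Y <- sp$points
  n <- nrow(Y)
  if (n == 0)
    return(.fss_curve("H", r, numeric(length(r)),
                      theo = 1 - exp(-rho_bar * 2 * pi * (1 - cos(r))),
                      meta = list(n = 0L, empty = TRUE, rho_bar = rho_bar)))
  rv <- .rho_values(rho, Y)
  if (rho_bar <= 0 || rho_bar > min(rv) * (1 + 1e-9))
    stop("rho_bar must be positive and no larger than rho at every event")
  fac <- 1 - rho_bar / rv
  D <- .pairdist_unit_sphere(Y)
  diag(D) <- Inf                      # exclude the event itself
  prods <- .ball_products(D, fac, r)
  est <- 1 - colMeans(prods)
  .fss_curve("H", r, est,
             theo = 1 - exp(-rho_bar * 2 * pi * (1 - cos(r))),
             meta = list(n = n, rho_bar = rho_bar))
}

#' Inhomogeneous J-function estimator
#'
#' `J = (1 - H) / (1 - F)`, ratio-unbiased; identically 1 for Poisson
#' processes. Radii where `F = 1` are flagged `NA` rather than clamped.
#'
#' @param F,H curves from [Finhom] and [Hinhom] on a common grid.
#' @export
Jinhom <- function(F, H) {
  stopifnot(isTRUE(all.equal(F$r, H$r)))
  den <- 1 - F$est
  est <- ifelse(den <= 0, NA_real_, (1 - H$est) / den)
  .fss_curve("J", F$r, est, theo = rep(1, length(F$r)),
             meta = list(n_undefined = sum(is.na(est))))
}

#' Unknown-intensity K-function estimator (homogeneous process on the shape)
#'
#' For a homogeneous process on the original shape with unknown rate, the
#' intensity plug-in uses the unbiased estimators of `rho` and `rho^2` from
#' the observed count, leaving only the geometric factor `rho~`:
#' `K~(r) = lambda_D(D)^2 / (4 pi N (N - 1)) * sum over ordered pairs of
#' 1[d <= r] / (rho~(x) rho~(y))` for `N > 1`, and the zero curve otherwise.
#'
#' @param sp a `sphere_ppp` carrying its shape and mapping kind.
#' @param r radius grid.
#' @export
Ktilde <- function(sp, r = radius_grid()) {
  Y <- sp$points
  n <- nrow(Y)
  lam <- surface_area(sp$shape)
  if (n <= 1)
    return(.fss_curve("K_tilde", r, numeric(length(r)),
                      theo = 2 * pi * (1 - cos(r)),
                      meta = list(n = n, lambda_D = lam)))
  rt <- rho_tilde_fun(sp$shape, sp$kind)(Y)
  D <- .pairdist_unit_sphere(Y)
  iw <- 1 / rt
  ut <- upper.tri(D)
  s <- .cum_pair_weight(D[ut], (tcrossprod(iw))[ut], r) * 2
  est <- lam^2 / (4 * pi * n * (n - 1)) * s
  .fss_curve("K_tilde", r, est, theo = 2 * pi * (1 - cos(r)),
             meta = list(n = n, lambda_D = lam))
}

#' Variance-stabilised centred K (the analogue-L deviation)
#'
#' `P(r) = sqrt(K(r)) - sqrt(2 pi (1 - cos r))`: zero in expectation under
#' CSR, with the square root acting as an approximate variance stabiliser.
#'
#' @param K a K-type curve ([Kinhom] or [Ktilde]).
#' @export
Pinhom <- function(K) {
  stopifnot(attr(K, "kind") %in% c("K", "K_tilde"))
  if (any(K$est < -1e-12)) stop("negative K values")
  est <- sqrt(pmax(0, K$est)) - sqrt(2 * pi * (1 - cos(K$r)))
  .fss_curve("P", K$r, est, theo = rep(0, length(K$r)),
             meta = attr(K, "meta"))
}

#' Centred (untransformed) K deviation
#'
#' `K(r) - 2 pi (1 - cos r)`; exposed alongside [Pinhom] for diagnostic
#' plots.
#' @inheritParams Pinhom
#' @export
Kcentred <- function(K) {
  stopifnot(attr(K, "kind") %in% c("K", "K_tilde"))
  .fss_curve("K_centred", K$r, K$est - 2 * pi * (1 - cos(K$r)),
             theo = rep(0, length(K$r)), meta = attr(K, "meta"))
}

#' Summary curves for a pattern on a convex shape
#'
#' Maps the pattern to the sphere and computes the requested inhomogeneous
#' summary statistic with the known-intensity machinery (`rho` known on the
#' shape) or the unknown-rate plug-in (`K_tilde`, `P`).
#'
#' @param pattern a [surface_ppp].
#' @param stat one of "K", "F", "H", "J", "P", "K_tilde".
#' @param rho the (constant) intensity on the shape, required for
#'   K/F/H/J; ignored by the plug-in statistics.
#' @param kind mapping kind (see [map_to_sphere]).
#' @param r radius grid.
#' @param P reference grid for F (and J).
#' @export
shape_summary <- function(pattern, stat = c("K", "F", "H", "J", "P",
                                            "K_tilde"),
                          rho = NULL, kind = NULL, r = radius_grid(),
                          P = fibonacci_grid(256L)) {
  stat <- match.arg(stat)
  sp <- map_to_sphere(pattern, kind)
  if (stat %in% c("K_tilde", "P")) {
    K <- Ktilde(sp, r)
    return(if (stat == "P") Pinhom(K) else K)
  }
  if (is.null(rho)) stop("rho is required for the known-intensity statistics")
  model <- intensity_model(pattern$shape, rho, sp$kind)
  switch(stat,
    K = Kinhom(sp, model$rho_star, r),
    F = Finhom(sp, model$rho_star, model$rho_star_inf, P, r),
    H = Hinhom(sp, model$rho_star, model$rho_star_inf, r),
    J = Jinhom(Finhom(sp, model$rho_star, model$rho_star_inf, P, r),
               Hinhom(sp, model$rho_star, model$rho_star_inf, r)))
}
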