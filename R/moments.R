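#' Moment context for the spherical estimators
#'
#' Bundles the spherical intensity, its infimum, the total intensity measure
#' and the reference grid, as consumed by the theoretical moment formulas.
#' Constant intensities get fast rotationally-reduced (1D) code paths;
#' functional intensities are handled by spherical quadrature.
#'
#' @param rho constant intensity on the sphere, or a function of unit vectors.
#' @param P reference grid for the F-function moments.
#' @param rho_bar infimum of `rho` (computed if omitted).
#' @param n_quad Fibonacci quadrature size for functional intensities.
#' @export
moment_context <- function(rho, P = fibonacci_grid(256L), rho_bar = NULL,
                           n_quad = 2048L) {
  if (!is.function(rho)) {
    stopifnot(rho > 0)
    list(rho = rho, rho_bar = if (is.null(rho_bar)) rho else rho_bar,
         mu = 4 * pi * rho, P = P, homog = TRUE)
  } else {
    G <- fibonacci_grid(n_quad)
    v <- rho(G)
    stopifnot(all(v > 0))
    list(rho = rho, rho_bar = if (is.null(rho_bar)) min(v) else rho_bar,
         mu = mean(v) * 4 * pi, P = P, homog = FALSE,
         quad = list(G = G, v = v, w = 4 * pi / n_quad))
  }
}

.cap_area <- function(r) 2 * pi * (1 - cos(r))

#' Theoretical Poisson means of the spherical estimators
#'
#' Under a Poisson process on the sphere with intensity infimum `rho_bar` and
#' total intensity measure `mu`:
#' `E[K] = 2 pi (1 - cos r)`; `E[F] = 1 - exp(-rho_bar * 2 pi (1 - cos r))`;
#' the H-estimator carries a small-count bias whose magnitude is bounded by
#' `exp(-mu)`:
#' `E[1 - H] = mu (exp(-rho_bar A_r) - exp(-mu)) / (mu - rho_bar A_r)`.
#'
#' @param r geodesic radius in `[0, pi]` (vectorised).
#' @param rho_bar intensity infimum.
#' @param mu total intensity measure of the sphere.
#' @export
theo_mean_K <- function(r) {
  stopifnot(all(r >= 0), all(r <= pi + 1e-12))
  2 * pi * (1 - cos(r))
}

#' @rdname theo_mean_K
#' @export
theo_mean_F <- function(r, rho_bar) 1 - exp(-rho_bar * .cap_area(r))

#' @rdname theo_mean_K
#' @export
theo_mean_H <- function(r, rho_bar, mu) {
  a <- rho_bar * .cap_area(r)
  d <- mu - a
  eu <- ifelse(abs(d) < 1e-9,
               mu * exp(-mu),                     # limit a -> mu
               mu * (exp(-a) - exp(-mu)) / d)
  1 - eu
}

## ---- numerically stable helper integrals --------------------------------
## g0(a; mu) = e^{-mu} * int_0^1 e^{at} dt           = (e^{a-mu}-e^{-mu})/a
## g1(a; mu) = e^{-mu} * int_0^1 (-ln t) e^{at} dt   = e^{-mu}(Ei(a)-ln a-g)/a
## g2(a; mu) = e^{-mu} * int_0^1 t(-ln t) e^{at} dt  = (e^{a-mu}-e^{-mu})/a^2
##                                                     - g1(a; mu)/a
## In the moment formulas 0 < a <= mu, so e^{a-mu} <= 1 and everything is
## finite; for large a, Ei(a) ~ e^a/a * sum k!/a^k is used so that the
## e^{-mu} factor can be absorbed before overflow.
.euler_gamma <- 0.577215664901532860606512

.g0 <- function(a, mu) {
  ifelse(abs(a) < 1e-8, exp(-mu) * (1 + a / 2),
         (exp(a - mu) - exp(-mu)) / a)
}

.g1 <- function(a, mu) {
  out <- numeric(length(a))
  small <- a < 1e-6
  mid <- !small & a <= 50
  big <- a > 50
  if (any(small)) out[small] <- exp(-mu) * (1 + a[small] * (2 - a[small] / 9) / 4)
  if (any(mid))
    out[mid] <- exp(-mu) *
      (pracma::expint_Ei(a[mid]) - log(a[mid]) - .euler_gamma) / a[mid]
  if (any(big)) {
    ab <- a[big]
    s <- 1
    term <- 1
    for (k in 1:12) { term <- term * k / ab; s <- s + term }
    out[big] <- exp(ab - mu) * s / ab^2 -
      exp(-mu) * (log(ab) + .euler_gamma) / ab
  }
  out
}

.g2 <- function(a, mu) {
  ifelse(abs(a) < 1e-8, exp(-mu) * (0.25 + a / 9),
         (exp(a - mu) - exp(-mu)) / a^2 - .g1(a, mu) / a)
}

## area of the intersection of two geodesic caps of radius r whose centres
## are an angle theta apart (unit sphere); 1D quadrature, vectorised via a
## spline over theta
cap_intersection_area <- function(theta, r) {
  one <- function(th) {
    if (th >= 2 * r) return(0)
    if (th <= 1e-12) return(.cap_area(r))
    f <- function(al) {
      cphi <- (cos(r) - cos(th) * cos(al)) / (sin(th) * sin(al))
      2 * acos(pmin(1, pmax(-1, cphi))) * sin(al)
    }
    stats::integrate(f, 1e-10, min(r, pi - 1e-10), rel.tol = 1e-9,
                     subdivisions = 400L)$value
  }
  vapply(theta, one, numeric(1))
}

.cap_int_spline <- function(r, n = 257L) {
  th <- seq(0, pi, length.out = n)
  stats::splinefun(th, cap_intersection_area(th, r), method = "monoH.FC")
}

## quadrature nodes on a geodesic cap B(center, r): spectral in both angles
.cap_quad <- function(center, r, nt = 24L, nphi = 48L) {
  gl <- pracma::gaussLegendre(nt, 0, r)
  phi <- (seq_len(nphi) - 0.5) * 2 * pi / nphi
  b1 <- .perp(center)
  b2 <- .cross3(matrix(center, 1), matrix(b1, 1))[1, ]
  t <- rep(gl$x, times = nphi)
  ph <- rep(phi, each = nt)
  pts <- outer(cos(t), center) +
    sin(t) * (outer(cos(ph), b1) + outer(sin(ph), b2))
  list(pts = pts, w = rep(gl$w, times = nphi) * sin(t) * (2 * pi / nphi))
}

#' Theoretical Poisson variances and covariance of the spherical estimators
#'
#' Exact second moments of the K-, F- and H-estimators and the covariance of
#' `(1 - H, 1 - F)` under a Poisson process with known intensity. Constant
#' intensities use rotationally reduced 1D integrals; functional intensities
#' use spherical quadrature (caps by product Gauss rules, pair integrals by
#' Fibonacci sums) at a documented ~0.1% accuracy.
#'
#' @param r geodesic radius (scalar).
#' @param ctx a [moment_context].
#' @export
var_K <- function(r, ctx) {
  if (r == 0) return(0)
  Ar <- .cap_area(r)
  if (ctx$homog) {
    rho <- ctx$rho
    return(4 * pi * Ar / (8 * pi^2 * rho^2) + (1 - cos(r))^2 * 4 * pi / rho)
  }
  q <- ctx$quad
  int_inv <- sum(q$w / q$v)
  ## int int 1[d<=r]/(rho rho): outer Fibonacci, inner exact cap quadrature
  inner <- vapply(seq_len(nrow(q$G)), function(i) {
    cq <- .cap_quad(q$G[i, ], r)
    sum(cq$w / ctx$rho(cq$pts))
  }, numeric(1))
  dbl <- sum(q$w * inner / q$v)
  dbl / (8 * pi^2) + (1 - cos(r))^2 * int_inv
}

#' @rdname var_K
#' @export
var_F <- function(r, ctx) {
  if (r == 0) return(0)
  Ar <- .cap_area(r)
  P <- ctx$P
  DP <- .pairdist_unit_sphere(P)
  if (ctx$homog) {
    ci <- .cap_int_spline(r)
    ex <- exp(ctx$rho_bar * ci(pmin(pmax(DP, 0), pi)))
  } else {
    q <- ctx$quad
    B <- .crossdist_unit_sphere(P, q$G) <= r
    wv <- q$w * ctx$rho_bar^2 / q$v
    I <- (B * rep(wv, each = nrow(P))) %*% t(B)
    ex <- exp(I)
  }
  e2 <- exp(-2 * ctx$rho_bar * Ar)
  e2 * mean(ex) - e2
}

#' @rdname var_K
#' @export
var_H <- function(r, ctx) {
  if (r == 0) return(0)
  Ar <- .cap_area(r)
  mu <- ctx$mu; rb <- ctx$rho_bar
  eu <- mu * .g0(mu - rb * Ar, mu)     # E[1 - H]
  if (ctx$homog) {
    A2 <- 1 - Ar / (4 * pi)
    t1 <- mu * .g1(mu * A2, mu)
    ci <- .cap_int_spline(r)
    A1 <- function(th) 1 - 2 * Ar / (4 * pi) + ci(th) / (4 * pi)
    ig <- function(th) .g2(mu * A1(th), mu) * sin(th)
    t2 <- ctx$rho^2 * 4 * pi * 2 * pi *
      stats::integrate(Vectorize(ig), r, pi, rel.tol = 1e-9)$value
    return(max(0, t1 + t2 - eu^2))
  }
  q <- ctx$quad
  M <- nrow(q$G)
  ## A2 per point, exact cap quadrature on 1/rho
  capint <- vapply(seq_len(M), function(i) {
    cq <- .cap_quad(q$G[i, ], r)
    sum(cq$w / ctx$rho(cq$pts))
  }, numeric(1))
  A2 <- 1 - 2 * rb * Ar / mu + rb^2 * capint / mu
  t1 <- sum(q$w * q$v * .g1(mu * A2, mu))
  ## pair term by Fibonacci double sum
  D <- .pairdist_unit_sphere(q$G)
  B <- D <= r
  wv <- q$w / q$v
  Iint <- (B * rep(wv, each = M)) %*% t(B)   # int_{Bx\capBy} 1/rho
  A1 <- 1 - 2 * rb * Ar / mu + rb^2 * Iint / mu
  fac <- (1 - rb * B / rep(q$v, each = M)) * (1 - rb * t(B) / rep(q$v, M))
  ## note: factors use rho at the *other* point of each ordered pair
  t2 <- sum((q$w * q$v) * ((fac * .g2m(mu * A1, mu)) %*% (q$w * q$v)))
  max(0, t1 + t2 - eu^2)
}

.g2m <- function(A, mu) matrix(.g2(as.vector(A), mu), nrow(A), ncol(A))

#' @rdname var_K
#' @export
cov_HF <- function(r, ctx) {
  if (r == 0) return(0)
  Ar <- .cap_area(r)
  mu <- ctx$mu; rb <- ctx$rho_bar
  eu <- mu * .g0(mu - rb * Ar, mu)
  ef <- exp(-rb * Ar)
  if (ctx$homog) {
    ci <- .cap_int_spline(r)
    A <- function(th) 1 - 2 * Ar / (4 * pi) + ci(th) / (4 * pi)
    ig <- function(th) .g0(mu * A(th), mu) * sin(th)
    I <- ctx$rho * 2 * pi *
      stats::integrate(Vectorize(ig), r, pi, rel.tol = 1e-9)$value
    return(I - ef * eu)
  }
  q <- ctx$quad
  P <- ctx$P; np <- nrow(P); M <- nrow(q$G)
  BP <- .crossdist_unit_sphere(P, q$G) <= r        # np x M: quad pt in B(p,r)
  Bx <- .pairdist_unit_sphere(q$G) <= r            # M x M: quad pt in B(x,r)
  wv <- q$w * rb^2 / q$v
  Ixp <- (Bx * rep(wv, each = M)) %*% t(BP)        # int_{Bx cap Bp} rb^2/rho
  A <- 1 - 2 * rb * Ar / mu + Ixp / mu
  fac <- 1 - rb * t(BP) / rep(q$v, np)             # 1 - rb 1[x in Bp]/rho(x)
  G0 <- matrix(.g0(as.vector(mu * A), mu), M, np)
  tot <- colSums((q$w * q$v) * (fac * G0))
  mean(tot) - ef * eu
}

#' Delta-method moments of the J-estimator
#'
#' Second-order Taylor approximation of the mean and variance of
#' `J = (1 - H)/(1 - F)` assembled from the exact moments of numerator and
#' denominator. The moments are guaranteed to exist only for radii below
#' `r_max` (the largest radius at which some reference ball keeps the
#' intensity strictly above its infimum); beyond it (and always for constant
#' intensity) a warning is issued and the approximation returned anyway.
#'
#' @inheritParams var_K
#' @return list with `mean`, `var`, `r_max`.
#' @export
j_moments <- function(r, ctx) {
  rmax <- j_rmax(ctx)
  if (r > rmax)
    warning("r exceeds r_max; exact J moments need not exist there")
  Ar <- .cap_area(r)
  muX <- ctx$mu * .g0(ctx$mu - ctx$rho_bar * Ar, ctx$mu)  # E[1-H]
  muY <- exp(-ctx$rho_bar * Ar)                           # E[1-F]
  vX <- var_H(r, ctx); vY <- var_F(r, ctx); cXY <- cov_HF(r, ctx)
  m <- muX / muY - cXY / muY^2 + vY * muX / muY^3
  v <- (muX / muY)^2 * (vX / muX^2 - 2 * cXY / (muX * muY) + vY / muY^2)
  list(mean = m, var = max(0, v), r_max = rmax)
}

#' @rdname j_moments
#' @export
j_rmax <- function(ctx, tol = 1e-9) {
  if (ctx$homog) return(0)
  q <- ctx$quad
  at_inf <- q$v <= ctx$rho_bar * (1 + 1e-6)
  if (!any(at_inf)) return(pi)
  D <- .crossdist_unit_sphere(ctx$P, q$G[at_inf, , drop = FALSE])
  max(apply(D, 1, min))
}

## ---- moments of the unknown-rate estimator K~ ---------------------------

.poisson_window <- function(mu) {
  lo <- max(0, floor(mu - 12 * sqrt(mu) - 10))
  hi <- ceiling(mu + 12 * sqrt(mu) + 10)
  lo:hi
}

## E[(N+a)^-2 (N+b)^-2] for N ~ Poisson(mu), truncated series
.pois_shift_e <- function(mu, a, b) {
  n <- .poisson_window(mu)
  sum(stats::dpois(n, mu) / ((n + a)^2 * (n + b)^2))
}

## shape-level geometry entering Var(K~): lambda_D, I1 = int 1/rho~,
## I2(r) = int int 1[d<=r]/(rho~ rho~); cached per (shape, kind, grid)
.ktilde_geometry <- function(shape, kind, r) {
  key <- paste0("ktgeo_", kind, "_", length(r), "_",
                format(sum(r), digits = 12))
  if (!is.null(shape$cache[[key]])) return(shape$cache[[key]])
  lam <- surface_area(shape)
  p <- shape$params
  spheroid <- shape$name %in% c("sphere", "ellipsoid") &&
    abs(p$a - p$b) < 1e-12 && kind == "axis"
  if (.is_sphere(shape) && kind == "axis") {
    R2 <- p$a^2                       # rho~ is the constant radius^2
    I1 <- 4 * pi / R2
    I2 <- 4 * pi * .cap_area(r) / R2^2
  } else if (spheroid) {
    rt_th <- function(th) {
      s2 <- sin(th)^2
      p$a * p$b * sqrt(pmax(0, 1 - (1 - p$c^2 / p$a^2) * s2))
    }
    gl <- pracma::gaussLegendre(200L, 0, pi)
    I1 <- 2 * pi * sum(gl$w * sin(gl$x) / rt_th(gl$x))
    ## azimuthal reduction of the pair integral: for polar angles (t1, t2)
    ## the azimuth-difference overlap at radius r is 2*phi*(t1,t2,r)
    ng <- 100L
    g2 <- pracma::gaussLegendre(ng, 0, pi)
    t1 <- rep(g2$x, times = ng); t2 <- rep(g2$x, each = ng)
    w12 <- rep(g2$w, times = ng) * rep(g2$w, each = ng) *
      sin(t1) * sin(t2) / (rt_th(t1) * rt_th(t2))
    ct <- cos(t1) * cos(t2); st <- sin(t1) * sin(t2)
    I2 <- vapply(r, function(ri) {
      cphi <- (cos(ri) - ct) / pmax(st, 1e-300)
      phis <- acos(pmin(1, pmax(-1, cphi)))
      phis[st < 1e-300] <- ifelse(cos(ri) <= ct[st < 1e-300], pi, 0)
      2 * pi * sum(w12 * 2 * phis)
    }, numeric(1))
  } else {
    rt <- rho_tilde_fun(shape, kind)
    G <- fibonacci_grid(2000L)
    v <- rt(G)
    w <- 4 * pi / nrow(G)
    I1 <- sum(w / v)
    D <- .pairdist_unit_sphere(G)
    ut <- upper.tri(D)
    pw <- (tcrossprod(1 / v))[ut] * w^2
    I2 <- 2 * .cum_pair_weight(D[ut], pw, r)
  }
  geo <- list(lam = lam, I1 = I1, I2 = I2, r = r,
              c2 = (lam^4 * I1 - 16 * pi^2 * lam^3),
              c3 = lam^4 * I2 - 64 * pi^4 * (1 - cos(r))^2 * lam^2)
  shape$cache[[key]] <- geo
  geo
}

#' Bias and variance of the unknown-rate K-estimator
#'
#' For a homogeneous Poisson process of rate `rho` on the shape, mapped to
#' the sphere: the bias is `-P(N <= 1) * 2 pi (1 - cos r)` (the estimator is
#' zero when fewer than two events land), and the variance decomposes into a
#' small-count block plus pair- and triple-correlation blocks driven by the
#' geometry integrals `I1 = int 1/rho~` and `I2(r) = int int 1[d<=r]/(rho~
#' rho~)` and the Poisson expectations `E[(N+3)^-2 (N+2)^-2]`,
#' `E[(N+2)^-2 (N+1)^-2]` (series truncated at 12 standard deviations).
#'
#' @param r geodesic radii (vectorised).
#' @param shape the [convex_shape].
#' @param rho homogeneous intensity on the shape.
#' @param kind mapping kind.
#' @export
bias_Ktilde <- function(r, shape, rho) {
  mu <- rho * surface_area(shape)
  -stats::ppois(1, mu) * .cap_area(r)
}

#' @rdname bias_Ktilde
#' @export
var_Ktilde <- function(r, shape, rho, kind = NULL) {
  if (is.null(kind))
    kind <- if (shape$name %in% c("sphere", "ellipsoid")) "axis" else "radial"
  geo <- .ktilde_geometry(shape, kind, r)
  mu <- rho * geo$lam
  P1 <- stats::ppois(1, mu)
  E3 <- .pois_shift_e(mu, 3, 2)
  E2 <- .pois_shift_e(mu, 2, 1)
  4 * pi^2 * (1 - cos(r))^2 * (1 - P1) * P1 +
    rho^3 * (1 - cos(r))^2 * geo$c2 * E3 +
    rho^2 / (8 * pi^2) * geo$c3 * E2
}

#' Lemma-type ratio-unbiased Poisson functional
#'
#' `R(N, k, p) = N! e^(N-k) / ((N-k)! (e+p)^N)`, ratio-unbiased for
#' `lambda^k e^(-p lambda)` when `N ~ Poisson(lambda)` (the expectation of
#' the numerator is `lambda^k e^(lambda(e-1))` and of the denominator
#' `e^(lambda(e+p-1))`). Computed in log space; zero when `N < k`.
#'
#' @param N observed count (vectorised).
#' @param k falling-factorial order.
#' @param p exponential tilt.
#' @export
lemma2_R <- function(N, k, p) {
  out <- numeric(length(N))
  ok <- N >= k
  if (any(ok)) {
    n <- N[ok]
    out[ok] <- exp(lgamma(n + 1) - lgamma(n - k + 1) + (n - k) -
                     n * log(exp(1) + p))
  }
  out
}

## ratio-unbiased plug-in for (1 - P(N<=1)) P(N<=1), assembled from the
## expansion e^-l + l e^-l - e^-2l - 2 l e^-2l - l^2 e^-2l
.pp_est <- function(N) {
  lemma2_R(N, 0, 1) + lemma2_R(N, 1, 1) -
    lemma2_R(N, 0, 2) - 2 * lemma2_R(N, 1, 2) - lemma2_R(N, 2, 2)
}

#' Plug-in variance estimate for the unknown-rate K-estimator
#'
#' Substitutes, in the variance decomposition of [var_Ktilde], the unbiased
#' falling-factorial estimators `rho^k-hat = N(N-1)...(N-k+1)/lambda_D^k`,
#' the observed values of the shifted-count expectations, and the
#' ratio-unbiased estimator of `(1 - P(N<=1)) P(N<=1)` built from
#' [lemma2_R]. Negative values (possible at small `N`) are floored at zero.
#'
#' @param N observed event count (or a `sphere_ppp`/[surface_ppp]).
#' @inheritParams var_Ktilde
#' @return estimated variance per radius.
#' @export
estimate_var_Ktilde <- function(N, shape, r = radius_grid(), kind = NULL) {
  if (is.list(N) && !is.null(N$points)) {
    if (is.null(kind) && !is.null(N$kind)) kind <- N$kind
    N <- nrow(N$points)
  }
  if (is.null(kind))
    kind <- if (shape$name %in% c("sphere", "ellipsoid")) "axis" else "radial"
  geo <- .ktilde_geometry(shape, kind, r)
  if (N == 0) {
    warning("empty pattern: variance estimate is the zero curve")
    return(numeric(length(r)))
  }
  lam <- geo$lam
  rho2 <- N * (N - 1) / lam^2
  rho3 <- N * (N - 1) * (N - 2) / lam^3
  v <- 4 * pi^2 * (1 - cos(r))^2 * .pp_est(N) +
    rho3 * (1 - cos(r))^2 * geo$c2 * (N + 3)^-2 * (N + 2)^-2 +
    rho2 / (8 * pi^2) * geo$c3 * (N + 2)^-2 * (N + 1)^-2
  pmax(0, v)
}
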