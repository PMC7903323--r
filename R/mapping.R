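#' Map a surface pattern to the unit sphere
#'
#' A Poisson process on a convex surface remains Poisson after a measurable
#' bijection onto the unit sphere; the intensity transforms with the Jacobian
#' of the map. Two maps are supported: the radial projection
#' `f(x) = x/||x||` (any centred convex shape) and, for ellipsoids, the
#' axis-scaling map `f(x) = (x1/a, x2/b, x3/c)` whose Jacobian is far simpler.
#'
#' @param pattern a [surface_ppp].
#' @param kind `"axis"` (ellipsoids/spheres; the default there) or `"radial"`.
#' @return a `sphere_ppp`: unit vectors plus the originating shape and map.
#' @export
map_to_sphere <- function(pattern, kind = NULL) {
  shape <- pattern$shape
  if (is.null(kind))
    kind <- if (shape$name %in% c("sphere", "ellipsoid")) "axis" else "radial"
  kind <- match.arg(kind, c("axis", "radial"))
  X <- pattern$points
  if (kind == "axis") {
    if (!shape$name %in% c("sphere", "ellipsoid"))
      stop("axis-scaling mapping is only defined for ellipsoids")
    p <- shape$params
    Y <- cbind(X[, 1] / p$a, X[, 2] / p$b, X[, 3] / p$c)
  } else {
    nrm <- sqrt(rowSums(X^2))
    if (any(nrm == 0)) stop("point at the origin cannot be mapped")
    Y <- X / nrm
  }
  if (nrow(Y)) Y <- Y / sqrt(rowSums(Y^2))   # guard rounding
  structure(list(points = Y, shape = shape, kind = kind,
                 source = pattern$metadata),
            class = "sphere_ppp")
}

#' @export
print.sphere_ppp <- function(x, ...) {
  cat("spherical point pattern:", nrow(x$points), "events (mapped from",
      x$shape$name, "by", x$kind, "map)\n")
  invisible(x)
}

#' Invert the sphere mapping
#'
#' @param sp a `sphere_ppp`.
#' @return the [surface_ppp] on the original shape.
#' @export
inverse_map <- function(sp) {
  Y <- sp$points
  shape <- sp$shape
  X <- .inverse_map_points(shape, Y, sp$kind)
  surface_ppp(X, shape, check = FALSE, metadata = sp$source)
}

.inverse_map_points <- function(shape, Y, kind) {
  Y <- .as_mat(Y)
  if (nrow(Y) == 0) return(Y)
  p <- shape$params
  if (kind == "axis")
    return(cbind(p$a * Y[, 1], p$b * Y[, 2], p$c * Y[, 3]))
  t <- switch(shape$name,
    sphere = rep(p$a, nrow(Y)),
    ellipsoid = 1 / sqrt(Y[, 1]^2 / p$a^2 + Y[, 2]^2 / p$b^2 +
                         Y[, 3]^2 / p$c^2),
    cube = p$l / apply(abs(Y), 1, max),
    ## generic convex level set: radial root find, unique by convexity
    apply(Y, 1, function(y)
      stats::uniroot(function(s) surface_residual(shape, s * y),
                     c(1e-8, shape$diameter))$root))
  Y * t
}

## ------------------------------------------------------------------------
## Mapped intensity.  For the radial map the density on the sphere factors as
##   rho*(y) = rho(x) * l_i(u) * (du/dy) * sqrt(1 - y_{i1}^2 - y_{i2}^2)
## where u are the planar coordinates of x on its piece, du/dy is the inverse
## Jacobian determinant of the planar map f*: u -> (y_{i1}, y_{i2}) induced by
## the projection, and the last factor converts planar measure on the image
## disc back to spherical surface measure.  det Df*(u), with n^2 = |x|^2 and
## h = height(u), h1, h2 its gradient, is
##   [ (n^2-u1^2-u1*h*h1)(n^2-u2^2-u2*h*h2) - u1 u2 (u2+h*h2)(u1+h*h1) ] / n^6.

.det_fstar <- function(u, h, h1, h2) {
  n2 <- u[, 1]^2 + u[, 2]^2 + h^2
  A <- n2 - u[, 1]^2 - u[, 1] * h * h1
  Dd <- n2 - u[, 2]^2 - u[, 2] * h * h2
  B <- -u[, 1] * (u[, 2] + h * h2)
  Cc <- -u[, 2] * (u[, 1] + h * h1)
  (A * Dd - B * Cc) / n2^3
}

#' Mapped intensity on the unit sphere
#'
#' Evaluates the intensity of the mapped process at unit vectors `y` for a
#' process with intensity `rho` on `shape`. `kind = "radial"` uses the
#' piecewise level-set machinery (valid for any registered shape);
#' `kind = "axis"` uses the ellipsoid closed form
#' `rho* = rho * a * b * sqrt(1 - (1 - c^2/a^2) y1^2 - (1 - c^2/b^2) y2^2)`.
#'
#' @param shape a [convex_shape].
#' @param y unit vectors (n x 3).
#' @param rho constant intensity on the shape, or a function of surface points.
#' @param kind mapping kind, as in [map_to_sphere].
#' @export
mapped_intensity <- function(shape, y, rho = 1, kind = NULL) {
  if (is.null(kind))
    kind <- if (shape$name %in% c("sphere", "ellipsoid")) "axis" else "radial"
  kind <- match.arg(kind, c("axis", "radial"))
  y <- .as_mat(y)
  if (nrow(y) == 0) return(numeric(0))
  nrm <- sqrt(rowSums(y^2))
  if (any(abs(nrm - 1) > 1e-8)) stop("y must be unit vectors")
  if (kind == "axis") {
    p <- shape$params
    rad <- 1 - (1 - p$c^2 / p$a^2) * y[, 1]^2 - (1 - p$c^2 / p$b^2) * y[, 2]^2
    if (any(rad < -1e-12)) stop("invalid spheroid parameters for axis map")
    rt <- p$a * p$b * sqrt(pmax(0, rad))
    rv <- if (is.function(rho))
      rho(.inverse_map_points(shape, y, "axis")) else rho
    return(rv * rt)
  }
  X <- .inverse_map_points(shape, y, "radial")
  idx <- piece_index(shape, X)
  out <- numeric(nrow(y))
  for (pi_ in unique(idx)) {
    pc <- shape$pieces[[pi_]]
    sel <- idx == pi_
    ax <- pc$axes
    u <- X[sel, ax[1:2], drop = FALSE]
    h <- X[sel, ax[3]]
    g <- pc$grad(u)
    l <- sqrt(1 + g[, 1]^2 + g[, 2]^2)
    det_fs <- .det_fstar(u, h, g[, 1], g[, 2])
    yp <- y[sel, , drop = FALSE]
    rad <- pmax(1e-14, 1 - yp[, ax[1]]^2 - yp[, ax[2]]^2)
    rv <- if (is.function(rho)) rho(X[sel, , drop = FALSE]) else rho
    out[sel] <- rv * l * (1 / det_fs) * sqrt(rad)
  }
  out
}

#' Normalised mapped intensity rho~ (mapped intensity of a unit-rate process)
#'
#' For a homogeneous process with unknown rate, the estimators only need
#' `rho~ = rho*/rho`, which is a pure geometry factor. Returns a vectorised
#' function of unit vectors.
#' @inheritParams mapped_intensity
#' @export
rho_tilde_fun <- function(shape, kind = NULL) {
  force(shape)
  if (is.null(kind))
    kind <- if (shape$name %in% c("sphere", "ellipsoid")) "axis" else "radial"
  function(y) mapped_intensity(shape, y, rho = 1, kind = kind)
}

#' Infimum of the mapped intensity over the sphere
#'
#' Analytic for the built-in shapes (cube with `l >= 1`: `rho`; spheroid with
#' `c >= a = b`: `rho*a*b`; sphere radius R, radial map: `rho*R^2`); otherwise
#' a dense Fibonacci scan refined by Nelder-Mead in a local tangent chart.
#'
#' @inheritParams mapped_intensity
#' @param n_scan size of the Fibonacci scan for the numeric route.
#' @export
rho_star_inf <- function(shape, rho = 1, kind = NULL, n_scan = 4096L) {
  if (is.null(kind))
    kind <- if (shape$name %in% c("sphere", "ellipsoid")) "axis" else "radial"
  p <- shape$params
  if (!is.function(rho)) {
    if (shape$name %in% c("sphere", "ellipsoid") && kind == "axis" &&
        p$c >= p$a && abs(p$a - p$b) < 1e-12)
      return(rho * p$a * p$b)
    if (shape$name == "sphere" && kind == "radial")
      return(rho * p$a^2)
    if (shape$name == "cube" && p$l >= 1)
      return(rho)   # attained at each face centre
  }
  G <- fibonacci_grid(n_scan)
  vals <- mapped_intensity(shape, G, rho, kind)
  i0 <- which.min(vals)
  y0 <- G[i0, ]
  ## local refinement in the tangent plane at y0
  b1 <- .perp(y0); b2 <- .cross3(matrix(y0, 1), matrix(b1, 1))[1, ]
  fn <- function(t) {
    y <- y0 + t[1] * b1 + t[2] * b2
    mapped_intensity(shape, y / sqrt(sum(y^2)), rho, kind)
  }
  op <- stats::optim(c(0, 0), fn, method = "Nelder-Mead",
                     control = list(reltol = 1e-12))
  min(vals[i0], op$value)
}

.perp <- function(v) {
  w <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  w <- w - sum(w * v) * v
  w / sqrt(sum(w^2))
}

#' Intensity model bundle
#'
#' Convenience container tying together a shape, a mapping, the intensity on
#' the shape, and the derived spherical quantities used by the estimators.
#'
#' @inheritParams mapped_intensity
#' @return list with `rho_star(y)`, `rho_tilde(y)`, `rho_star_inf`, `mu`
#'   (total intensity measure), `shape`, `kind`.
#' @export
intensity_model <- function(shape, rho = 1, kind = NULL) {
  if (is.null(kind))
    kind <- if (shape$name %in% c("sphere", "ellipsoid")) "axis" else "radial"
  if (!is.function(rho)) {
    mu <- rho * surface_area(shape)
  } else {
    G <- fibonacci_grid(8192L)
    rt <- rho_tilde_fun(shape, kind)
    mu <- mean(mapped_intensity(shape, G, rho, kind)) * 4 * pi
  }
  list(shape = shape, kind = kind, rho = rho,
       rho_star = function(y) mapped_intensity(shape, y, rho, kind),
       rho_tilde = rho_tilde_fun(shape, kind),
       rho_star_inf = rho_star_inf(shape, rho, kind),
       mu = mu)
}
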