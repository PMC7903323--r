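## independent brute-force oracle for the inhomogeneous K estimator:
## plain double loop over ordered event pairs
khat_bruteforce <- function(Y, rho_vals, r) {
  n <- nrow(Y)
  out <- numeric(length(r))
  if (n < 2) return(out)
  for (k in seq_along(r)) {
    s <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      d <- acos(min(1, max(-1, sum(Y[i, ] * Y[j, ]))))
      if (d <= r[k]) s <- s + 1 / (rho_vals[i] * rho_vals[j])
    }
    out[k] <- s / (4 * pi)
  }
  out
}

## independent straightforward implementation of the two test statistics,
## using only the exported estimator functions (no shared internals)
stats_bruteforce <- function(pattern, r = radius_grid()) {
  sp <- map_to_sphere(pattern)
  K <- Ktilde(sp, r)
  T1 <- max(abs(sqrt(pmax(0, K$est)) - sqrt(2 * pi * (1 - cos(r)))))
  V <- estimate_var_Ktilde(npoints(sp), pattern$shape, r, sp$kind)
  z <- ifelse(V > 0, abs(K$est - 2 * pi * (1 - cos(r))) / sqrt(V), 0)
  c(T1 = T1, T2 = max(z))
}

## uniform points on the unit sphere (oracle sampler, independent of the
## package's rejection machinery)
runif_sphere_oracle <- function(n) {
  u <- matrix(stats::rnorm(3 * n), ncol = 3)
  u / sqrt(rowSums(u^2))
}

sphere_pppify <- function(Y, shape = SPH, kind = "axis") {
  structure(list(points = Y, shape = shape, kind = kind),
            class = "sphere_ppp")
}
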