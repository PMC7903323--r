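#' Solve for the spheroid semi-axis giving a target surface area
#'
#' For a prolate spheroid with `a = b` fixed, finds `c >= a` such that the
#' closed-form surface area equals `target_area` (default `4 pi`, the unit
#' sphere's area), by a bracketing root-finder.
#'
#' @param a equatorial semi-axis (must satisfy `4 pi a^2 <= target_area`).
#' @param target_area desired area.
#' @param tol relative tolerance of the root.
#' @export
solve_c_for_area <- function(a, target_area = 4 * pi, tol = 1e-9) {
  stopifnot(a > 0)
  if (4 * pi * a^2 > target_area * (1 + 1e-12))
    stop("no prolate solution: 4 pi a^2 exceeds the target area")
  if (abs(4 * pi * a^2 - target_area) < 1e-12 * target_area) return(a)
  f <- function(c) .spheroid_area(a, a, c) - target_area
  hi <- a * 2
  while (f(hi) < 0) hi <- hi * 2
  stats::uniroot(f, c(a, hi), tol = tol * a)$root
}

## simulation-study rows: process parameters per experiment id.
## Tables: CSR rows use expectation 40*pi (rho = 10 on area-4pi spheroids);
## hard-core rows use expectation 100 with the thinning intensity solved from
## the expected-count equation; cluster rows use expectation 150 with 20
## expected offspring per parent.
.experiment_table <- function() {
  av <- c(a = 1, b = 0.8, c = 0.6, d = 0.4)
  rows <- list()
  for (s in names(av)) {
    rows[[paste0("1", s)]] <-
      list(model = "csr", a = av[[s]], expectation = 40 * pi)
    Rv <- c(i = 0, ii = 0.05, iii = 0.1, iv = 0.2)
    for (k in names(Rv))
      rows[[paste0("2", s, k)]] <-
        list(model = "matern2", a = av[[s]], expectation = 100, R = Rv[[k]])
    kv <- c(i = Inf, ii = 5, iii = 1, iv = 0.5)
    for (k in names(kv))
      rows[[paste0("3", s, k)]] <-
        list(model = "thomas", a = av[[s]], expectation = 150,
             kappa = kv[[k]], offspring = 20)
  }
  rows
}

#' Configuration of one simulation-study experiment
#'
#' Rows are identified as in the reference study: `"1a"`..`"1d"` (CSR,
#' expectation `40 pi`), `"2ai"`..`"2div"` (Matern II, expectation 100,
#' hard-core distance 0/0.05/0.1/0.2), `"3ai"`..`"3div"` (Thomas,
#' expectation 150, 20 offspring per parent, bandwidth Inf/5/1/0.5); the
#' letter selects `a = b` in (1, 0.8, 0.6, 0.4) with `c` solved so the
#' spheroid area is `4 pi`.
#'
#' @param id experiment identifier, e.g. `"2aiv"`.
#' @param n_reps repetitions (1000 at full study scale).
#' @param m_null null simulations per repetition (999 at full scale).
#' @param alpha significance level.
#' @param seed root seed; per-repetition seeds are derived deterministically.
#' @export
experiment_config <- function(id, n_reps = 200L, m_null = 199L,
                              alpha = 0.05, seed = 1L) {
  rows <- .experiment_table()
  if (!id %in% names(rows)) stop("unknown experiment id: ", id)
  cfg <- rows[[id]]
  cfg$id <- id
  cfg$c <- solve_c_for_area(cfg$a)
  cfg$n_reps <- as.integer(n_reps)
  cfg$m_null <- as.integer(m_null)
  cfg$alpha <- alpha
  cfg$seed <- as.integer(seed)
  class(cfg) <- "experiment_config"
  cfg
}

## simulate one observed pattern for a configuration (sphere fast paths)
.sim_observed <- function(cfg, shape) {
  switch(cfg$model,
    csr = rpois_shape(shape, cfg$expectation / surface_area(shape)),
    matern2 = {
      if (cfg$R == 0) {
        rpois_shape(shape, cfg$expectation / surface_area(shape))
      } else {
        rho <- solve_matern2_intensity(shape, cfg$R, cfg$expectation)
        rmatern2_shape(shape, rho, cfg$R)
      }
    },
    thomas = rthomas_shape(shape,
                           rho_parent = cfg$expectation /
                             (surface_area(shape) * cfg$offspring),
                           alpha = cfg$offspring, kappa = cfg$kappa),
    stop("unknown model"))
}

#' Run one experiment of the simulation study
#'
#' Simulates `n_reps` observed patterns under the configured process on the
#' area-`4pi` spheroid, tests each with both statistics against `m_null`
#' CSR simulations fitted to the observed count, and reports rejection rates
#' with binomial standard errors. Repetitions use seeds derived from the
#' root seed, so runs are exactly replayable and parallelisable by row.
#'
#' @param cfg an [experiment_config] (or an id string).
#' @param r evaluation grid of radii.
#' @param null `"true"` (default) simulates the null at the design intensity
#'   `expectation / area`, keeping observed and null statistics exchangeable
#'   (the unstandardised `T1` is badly conservative otherwise, because the
#'   observed count's variability inflates the null tail); `"fitted"` uses
#'   `rho-hat = N_obs / area` per repetition.
#' @param verbose print a progress line every 50 repetitions.
#' @return class `experiment_result`.
#' @export
run_experiment <- function(cfg, r = radius_grid(), null = c("true", "fitted"),
                           verbose = FALSE) {
  null <- match.arg(null)
  if (is.character(cfg)) cfg <- experiment_config(cfg)
  shape <- if (cfg$a == 1) cs_sphere() else cs_ellipsoid(cfg$a, cfg$a, cfg$c)
  ctx <- .test_context(shape, NULL, r)
  rho_m2 <- if (cfg$model == "matern2" && cfg$R > 0)
    solve_matern2_intensity(shape, cfg$R, cfg$expectation) else NULL
  rec <- data.frame(rep = seq_len(cfg$n_reps), seed = NA_integer_,
                    n = NA_integer_, T1 = NA_real_, T2 = NA_real_,
                    p_T1 = NA_real_, p_T2 = NA_real_)
  for (i in seq_len(cfg$n_reps)) {
    sd_i <- derive_seed(cfg$seed, i)
    set.seed(sd_i)
    obs_pat <- if (!is.null(rho_m2)) rmatern2_shape(shape, rho_m2, cfg$R)
               else .sim_observed(cfg, shape)
    Y <- map_to_sphere(obs_pat, ctx$kind)$points
    obs <- .stats_fast(Y, ctx)
    rho0 <- if (null == "fitted") nrow(Y) / ctx$lam
            else cfg$expectation / ctx$lam
    ge1 <- ge2 <- 0L
    for (j in seq_len(cfg$m_null)) {
      ns <- .stats_fast(.rnull_sphere(ctx, rho0), ctx)
      ge1 <- ge1 + (ns["T1"] >= obs["T1"])
      ge2 <- ge2 + (ns["T2"] >= obs["T2"])
    }
    rec$seed[i] <- sd_i
    rec$n[i] <- nrow(Y)
    rec$T1[i] <- obs["T1"]; rec$T2[i] <- obs["T2"]
    rec$p_T1[i] <- (1 + ge1) / (cfg$m_null + 1)
    rec$p_T2[i] <- (1 + ge2) / (cfg$m_null + 1)
    if (verbose && i %% 50 == 0)
      message(sprintf("  [%s] rep %d/%d", cfg$id, i, cfg$n_reps))
  }
  rate <- c(T1 = mean(rec$p_T1 <= cfg$alpha), T2 = mean(rec$p_T2 <= cfg$alpha))
  se <- sqrt(rate * (1 - rate) / cfg$n_reps)
  structure(list(config = cfg, rejection_rate = rate, se = se,
                 records = rec),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("experiment %s: %s on spheroid a = %g, c = %.5f (area 4pi)\n",
              cfg$id, cfg$model, cfg$a, cfg$c))
  cat(sprintf("  n_reps = %d, m_null = %d, alpha = %g\n",
              cfg$n_reps, cfg$m_null, cfg$alpha))
  cat(sprintf("  reject rate: T1 = %.4f (SE %.4f), T2 = %.4f (SE %.4f)\n",
              x$rejection_rate["T1"], x$se["T1"],
              x$rejection_rate["T2"], x$se["T2"]))
  invisible(x)
}

#' Write results of several experiments as a study-style table
#'
#' @param results list of `experiment_result`s.
#' @param file CSV path.
#' @export
write_experiment_csv <- function(results, file) {
  df <- do.call(rbind, lapply(results, function(x) {
    cfg <- x$config
    data.frame(experiment = cfg$id, model = cfg$model,
               expectation = cfg$expectation, a = cfg$a, c = cfg$c,
               R = if (is.null(cfg$R)) NA else cfg$R,
               kappa = if (is.null(cfg$kappa)) NA else cfg$kappa,
               n_reps = cfg$n_reps, m_null = cfg$m_null,
               reject_T1 = x$rejection_rate["T1"], se_T1 = x$se["T1"],
               reject_T2 = x$rejection_rate["T2"], se_T2 = x$se["T2"])
  }))
  utils::write.csv(df, file, row.names = FALSE)
  invisible(df)
}

#' Generate the small example fixtures
#'
#' Writes seeded example patterns (CSR on the cube, CSR / Matern II / Thomas
#' on the 1:1:3 prolate spheroid) as `x,y,z` CSVs with JSON sidecars, as used
#' in the documentation and tests. Deterministic for a given seed.
#'
#' @param dir output directory.
#' @param seed root seed.
#' @return invisibly, the written file paths.
#' @export
make_fixtures <- function(dir, seed = 20210301L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ell <- cs_ellipsoid(1, 1, 3)
  specs <- list(
    list(name = "csr_cube", pat = function()
      rpois_shape(cs_cube(1), 50, seed = derive_seed(seed, 1))),
    list(name = "csr_ellipsoid", pat = function()
      rpois_shape(ell, 5, seed = derive_seed(seed, 2))),
    list(name = "matern2_ellipsoid", pat = function()
      rmatern2_shape(ell, 5, R = 0.3, seed = derive_seed(seed, 3))),
    list(name = "thomas_ellipsoid", pat = function()
      rthomas_shape(ell, rho_parent = 100 / (surface_area(ell) * 15),
                    alpha = 15, kappa = 0.1, seed = derive_seed(seed, 4))))
  paths <- character(0)
  for (s in specs) {
    p <- s$pat()
    f <- file.path(dir, paste0(s$name, ".csv"))
    write_pattern(p, f)
    paths <- c(paths, f)
  }
  invisible(paths)
}
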