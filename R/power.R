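# One simulation cell: draw pairs of latent ilr-scale means, snap them to
# the achievable-mean lattices of both scale representations, test
# H0: rho = 0 with the Pearson correlation t-test on each, and estimate
# the rejection proportions and their difference (delta power).

# Possible-means lattices are expensive for large (K, I); cache them for
# the lifetime of the session, keyed by (K, p, I, representation).
.lattice_cache <- new.env(parent = emptyenv())

scenario_lattices <- function(K, p, I) {
  key <- sprintf("K%d_p%.17g_I%d", K, p, I)
  hit <- .lattice_cache[[key]]
  if (!is.null(hit)) return(hit)
  sc <- likert_scale(K, p, I)
  out <- list(scale = sc,
              ilr = possible_means(sc, which = "ilr"),
              star = possible_means(sc, which = "star"))
  .lattice_cache[[key]] <- out
  out
}

#' Define a simulation scenario
#'
#' One cell of the Monte-Carlo design: a data-generating process with scale
#' matrix built from `(s11, s22, rho)`, a Likert instrument `(K, p, I)`, and
#' the Monte-Carlo sizes.
#'
#' @param s11,s22 Positive dispersion parameters of the DGP.
#' @param rho Nonzero true association in (-1, 1).
#' @param dgp One of `"laplace"`, `"cauchy"` (or `"normal"` for
#'   benchmarking against a thin-tailed reference).
#' @param K,p,I Instrument parameters, see [likert_scale()].
#' @param n_pairs Respondents (pairs of means) per run; default 200.
#' @param n_runs Simulation runs per scenario; default 1000.
#' @param alpha Two-sided level of the correlation t-test; default 0.05.
#' @param seed Integer seed for the scenario's RNG stream.
#' @return An object of class `"scenario"` (a named list).
#' @export
scenario <- function(s11, s22, rho, dgp = c("laplace", "cauchy", "normal"),
                     K = 5, p = 0.05, I = 1, n_pairs = 200, n_runs = 1000,
                     alpha = 0.05, seed = 1L) {
  dgp <- match.arg(dgp)
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) ||
      rho == 0 || abs(rho) >= 1)
    stop("'rho' must be a single nonzero number with |rho| < 1",
         call. = FALSE)
  n_pairs <- check_count(n_pairs, "n_pairs", min = 3L)
  n_runs <- check_count(n_runs, "n_runs", min = 1L)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("'alpha' must be in (0, 1)", call. = FALSE)
  sigma <- make_scale_matrix(s11, s22, rho)  # validates s11, s22, rho
  structure(list(s11 = s11, s22 = s22, rho = rho, dgp = dgp,
                 K = check_count(K, "K", 2L), p = p,
                 I = check_count(I, "I", 1L),
                 n_pairs = n_pairs, n_runs = n_runs, alpha = alpha,
                 seed = as.integer(seed), sigma = sigma),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf(
    "Scenario: %s DGP, rho = %g, s11 = %g, s22 = %g; K = %d, I = %d, p = %g\n",
    x$dgp, x$rho, x$s11, x$s22, x$K, x$I, x$p))
  cat(sprintf("  %d runs x %d pairs, alpha = %g, seed = %d\n",
              x$n_runs, x$n_pairs, x$alpha, x$seed))
  invisible(x)
}

#' Sample Pearson correlation
#'
#' Plain sample correlation of the two columns of `pairs`. Returns `NA`
#' (an undefined statistic, not an error) when either column is constant;
#' the simulation engine counts such runs as non-rejections.
#'
#' @param pairs An `n x 2` numeric matrix, `n >= 2`.
#' @return Correlation in \[-1, 1\], or `NA` if undefined.
#' @export
pearson_r <- function(pairs) {
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L || nrow(pairs) < 2L)
    stop("'pairs' must be an n x 2 matrix with n >= 2", call. = FALSE)
  x <- pairs[, 1L]; y <- pairs[, 2L]
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) return(NA_real_)
  r <- stats::cov(x, y) / (sx * sy)
  max(-1, min(1, r))
}

#' Two-sided correlation t-test decision
#'
#' Tests `H0: rho = 0` with the statistic `t = r sqrt(n - 2) / sqrt(1 -
#' r^2)` against the two-sided Student-t critical value with `n - 2` degrees
#' of freedom. `|r| = 1` always rejects; `r = NA` (undefined statistic)
#' never rejects.
#'
#' @param r Sample correlation(s) in \[-1, 1\] (vectorised).
#' @param n Number of pairs behind `r` (`n >= 3`).
#' @param alpha Two-sided test level in (0, 1).
#' @return Logical vector: `TRUE` where H0 is rejected.
#' @export
corr_t_test <- function(r, n, alpha = 0.05) {
  n <- check_count(n, "n", min = 3L)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("'alpha' must be in (0, 1)", call. = FALSE)
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE))
    stop("'r' must lie in [-1, 1]", call. = FALSE)
  r_crit <- r_critical(n, alpha)
  out <- !is.na(r) & abs(r) > r_crit
  out
}

# Rejection boundary on the correlation scale: |r| > r_crit is equivalent
# to |t| > t_crit with t = r sqrt(n - 2) / sqrt(1 - r^2).
r_critical <- function(n, alpha) {
  t_crit <- stats::qt(1 - alpha / 2, df = n - 2L)
  sqrt(t_crit^2 / (t_crit^2 + (n - 2L)))
}

#' Run one simulation scenario
#'
#' For each run, draws `n_pairs` latent mean pairs `(z1, z2)` from the
#' scenario's DGP centred at the origin, then follows both evaluation
#' paths:
#' \describe{
#'   \item{ILR}{each `z` is snapped to the nearest achievable ilr-scale
#'     mean for `(K, p, I)`;}
#'   \item{ORIG}{each `z` is back-transformed by [inv_ilr2()], snapped (in
#'     the Euclidean metric, as done in common practice) to the nearest
#'     achievable trait-scale mean, and read off on the original `1..K`
#'     scale.}
#' }
#' The correlation t-test of `H0: rho = 0` at level `alpha` is applied to
#' both snapped datasets; the rejection proportions over runs estimate
#' `Power^ilr` and `Power^orig`, and `delta = power_ilr - power_orig`.
#' Runs in which a snapped dataset is constant have an undefined test
#' statistic; they count as non-rejections and are excluded from
#' `n_runs_effective`.
#'
#' The scenario seed initialises one RNG stream consumed sequentially by
#' all runs, so results are reproducible and independent of how scenarios
#' are scheduled.
#'
#' @param sc A [scenario()].
#' @return An object of class `"power_result"`: list with `power_ilr`,
#'   `power_orig`, `delta`, `n_runs_effective`, `n_zero_var` (runs with an
#'   undefined statistic on either path) and the scenario.
#' @export
run_scenario <- function(sc) {
  stopifnot(inherits(sc, "scenario"))
  lat <- scenario_lattices(sc$K, sc$p, sc$I)
  n_tot <- sc$n_runs * sc$n_pairs

  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(sc$seed)
  z <- draw_dgp(sc$dgp, c(0, 0), sc$sigma, n_tot)

  z_ilr <- snap_to_nearest(z, lat$ilr)
  z_orig <- snap_to_nearest(inv_ilr2(z), lat$star)
  dim(z_ilr) <- dim(z_orig) <- dim(z)

  rej_ilr <- path_rejections(z_ilr, sc)
  rej_orig <- path_rejections(z_orig, sc)

  # NA means undefined statistic -> non-rejection
  power_ilr <- sum(rej_ilr, na.rm = TRUE) / sc$n_runs
  power_orig <- sum(rej_orig, na.rm = TRUE) / sc$n_runs
  undefined <- is.na(rej_ilr) | is.na(rej_orig)
  structure(list(power_ilr = power_ilr,
                 power_orig = power_orig,
                 delta = power_ilr - power_orig,
                 n_runs_effective = sum(!undefined),
                 n_zero_var = sum(undefined),
                 scenario = sc),
            class = "power_result")
}

# Per-run correlations and test decisions for one path. `x` holds the
# snapped draws with runs stacked: rows 1..n_pairs are run 1, etc.
path_rejections <- function(x, sc) {
  n <- sc$n_pairs
  a <- matrix(x[, 1L], nrow = n)
  b <- matrix(x[, 2L], nrow = n)
  sa <- colMeans(a); sb <- colMeans(b)
  va <- colMeans(a * a) - sa^2
  vb <- colMeans(b * b) - sb^2
  cab <- colMeans(a * b) - sa * sb
  den <- sqrt(va * vb)
  r <- ifelse(den > 0, cab / den, NA_real_)
  r <- pmax(-1, pmin(1, r))
  ifelse(is.na(r), NA, abs(r) > r_critical(n, sc$alpha))
}

#' @export
print.power_result <- function(x, ...) {
  sc <- x$scenario
  cat(sprintf(
    "Power of the correlation t-test (%s DGP, rho = %g, K = %d, I = %d, p = %g):\n",
    sc$dgp, sc$rho, sc$K, sc$I, sc$p))
  cat(sprintf("  ilr scale      : %.4f\n", x$power_ilr))
  cat(sprintf("  original scale : %.4f\n", x$power_orig))
  cat(sprintf("  delta power    : %+.4f   (%d/%d runs effective)\n",
              x$delta, x$n_runs_effective, sc$n_runs))
  invisible(x)
}
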