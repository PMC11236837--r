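# The full scenario grid, its execution with a resumable results store,
# and Table-style aggregation of the power difference.

#' Specify a scenario grid
#'
#' Defaults reproduce the study design: dispersions `0.25, 0.5, ..., 2`
#' taken as unordered pairs (36 combinations), associations `+-0.05` to
#' `+-0.65` in steps of 0.05 (26 values, zero excluded), `K` in
#' `{5, 6, 10}`, `I` in `{1, 4, 10, 30}`, LOQ fractions `0.02, ..., 0.2`,
#' and both heavy-tailed DGPs — 224,640 scenarios of 1000 runs with 200
#' pairs each.
#'
#' @param variances Positive dispersion values; scenarios use the unordered
#'   pairs `{(s11, s22): s11 <= s22}`.
#' @param correlations Nonzero association values in (-1, 1).
#' @param Ks,Is,ps Instrument dimensions, see [likert_scale()].
#' @param dgps Subset of `c("laplace", "cauchy")`.
#' @param n_pairs,n_runs,alpha Monte-Carlo sizes and test level per
#'   scenario.
#' @param master_seed Integer; per-scenario child seeds are drawn from a
#'   stream seeded with it, so the grid is reproducible and each scenario
#'   is self-seeded.
#' @return An object of class `"grid_spec"`.
#' @export
grid_spec <- function(variances = seq(0.25, 2, by = 0.25),
                      correlations = setdiff(round(seq(-0.65, 0.65, by = 0.05), 2), 0),
                      Ks = c(5, 6, 10),
                      Is = c(1, 4, 10, 30),
                      ps = seq(0.02, 0.2, by = 0.02),
                      dgps = c("laplace", "cauchy"),
                      n_pairs = 200, n_runs = 1000, alpha = 0.05,
                      master_seed = 20240101L) {
  if (length(variances) == 0L || any(!is.finite(variances)) ||
      any(variances <= 0))
    stop("'variances' must be positive numbers", call. = FALSE)
  if (length(correlations) == 0L || any(!is.finite(correlations)) ||
      any(correlations == 0) || any(abs(correlations) >= 1))
    stop("'correlations' must be nonzero values in (-1, 1)", call. = FALSE)
  if (length(Ks) == 0L || length(Is) == 0L || length(ps) == 0L)
    stop("'Ks', 'Is' and 'ps' must be nonempty", call. = FALSE)
  dgps <- match.arg(dgps, c("laplace", "cauchy"), several.ok = TRUE)
  structure(list(variances = sort(unique(variances)),
                 correlations = correlations,
                 Ks = as.integer(Ks), Is = as.integer(Is), ps = ps,
                 dgps = dgps,
                 n_pairs = as.integer(n_pairs),
                 n_runs = as.integer(n_runs),
                 alpha = alpha,
                 master_seed = as.integer(master_seed)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  m <- length(x$variances)
  n_var <- choose(m, 2L) + m
  cat(sprintf(
    "Scenario grid: %d variance pairs x %d correlations x %d K x %d I x %d p x %d DGP = %d scenarios\n",
    n_var, length(x$correlations), length(x$Ks), length(x$Is),
    length(x$ps), length(x$dgps),
    n_var * length(x$correlations) * length(x$Ks) * length(x$Is) *
      length(x$ps) * length(x$dgps)))
  cat(sprintf("  %d runs x %d pairs per scenario, alpha = %g, master seed = %d\n",
              x$n_runs, x$n_pairs, x$alpha, x$master_seed))
  invisible(x)
}

#' Enumerate the scenarios of a grid
#'
#' Expands the grid deterministically (variance pairs stored with
#' `s11 <= s22`) and assigns every scenario a child seed drawn from a
#' stream seeded with `master_seed`, making each scenario independently
#' reproducible regardless of execution order.
#'
#' @param spec A [grid_spec()].
#' @return A data frame of class `"scenario_grid"`, one row per scenario,
#'   with columns `s11, s22, rho, dgp, K, I, p, n_pairs, n_runs, alpha,
#'   seed`.
#' @export
build_grid <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  v <- spec$variances
  idx <- which(outer(v, v, "<="), arr.ind = TRUE)  # s11 <= s22
  pairs <- data.frame(s11 = v[idx[, 1L]], s22 = v[idx[, 2L]])
  pairs <- pairs[order(pairs$s11, pairs$s22), , drop = FALSE]
  g <- expand.grid(pair = seq_len(nrow(pairs)),
                   rho = spec$correlations,
                   K = spec$Ks, I = spec$Is, p = spec$ps,
                   dgp = spec$dgps,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- data.frame(s11 = pairs$s11[g$pair], s22 = pairs$s22[g$pair],
                    rho = g$rho, dgp = g$dgp, K = g$K, I = g$I, p = g$p,
                    n_pairs = spec$n_pairs, n_runs = spec$n_runs,
                    alpha = spec$alpha)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(spec$master_seed)
  out$seed <- sample.int(.Machine$integer.max - 1L, nrow(out),
                         replace = nrow(out) > .Machine$integer.max - 1L)
  class(out) <- c("scenario_grid", "data.frame")
  out
}

grid_row_scenario <- function(row) {
  scenario(s11 = row$s11, s22 = row$s22, rho = row$rho, dgp = row$dgp,
           K = row$K, p = row$p, I = row$I, n_pairs = row$n_pairs,
           n_runs = row$n_runs, alpha = row$alpha, seed = row$seed)
}

scenario_key <- function(df) {
  sprintf("%.10g|%.10g|%.10g|%s|%d|%d|%.10g|%d|%d|%.10g",
          df$s11, df$s22, df$rho, as.character(df$dgp),
          as.integer(df$K), as.integer(df$I), df$p,
          as.integer(df$n_pairs), as.integer(df$n_runs), df$alpha)
}

#' Execute scenarios and collect results
#'
#' Runs [run_scenario()] for each row of a scenario grid. With a `store`
#' path, results are appended to a CSV after each scenario and scenarios
#' already present in the store (matched on all design columns) are
#' skipped, so an interrupted sweep resumes where it stopped. Each
#' scenario carries its own seed, so results do not depend on execution
#' order.
#'
#' @param scenarios A `scenario_grid` data frame from [build_grid()] (or a
#'   subset of its rows).
#' @param store Optional path to a results CSV used as an append-only
#'   store.
#' @param progress Print a line every `progress` scenarios; 0 disables.
#' @return A data frame with the design columns plus `power_ilr`,
#'   `power_orig`, `delta`, `n_runs_effective`, `n_zero_var` and `elapsed`
#'   (seconds), covering the requested scenarios (including any restored
#'   from the store).
#' @export
run_grid <- function(scenarios, store = NULL, progress = 0L) {
  scenarios <- as.data.frame(scenarios)
  if (nrow(scenarios) == 0L)
    stop("'scenarios' must contain at least one scenario", call. = FALSE)
  done <- NULL
  if (!is.null(store) && file.exists(store)) {
    done <- utils::read.csv(store, stringsAsFactors = FALSE)
    keep <- scenario_key(done) %in% scenario_key(scenarios)
    done <- done[keep, , drop = FALSE]
    todo <- !(scenario_key(scenarios) %in% scenario_key(done))
    scenarios <- scenarios[todo, , drop = FALSE]
  }
  rows <- vector("list", nrow(scenarios))
  for (i in seq_len(nrow(scenarios))) {
    row <- scenarios[i, , drop = FALSE]
    t0 <- proc.time()[["elapsed"]]
    res <- run_scenario(grid_row_scenario(row))
    rec <- cbind(row,
                 data.frame(power_ilr = res$power_ilr,
                            power_orig = res$power_orig,
                            delta = res$delta,
                            n_runs_effective = res$n_runs_effective,
                            n_zero_var = res$n_zero_var,
                            elapsed = proc.time()[["elapsed"]] - t0))
    rows[[i]] <- rec
    if (!is.null(store)) {
      new_file <- !file.exists(store)
      utils::write.table(rec, store, sep = ",", row.names = FALSE,
                         col.names = new_file, append = !new_file)
    }
    if (progress > 0L && i %% progress == 0L)
      message(sprintf("scenario %d / %d", i, length(rows)))
  }
  out <- do.call(rbind, c(list(done), rows))
  rownames(out) <- NULL
  class(out) <- c("power_grid_results", "data.frame")
  out
}

#' Aggregate delta power into summary tables
#'
#' Averages `delta = power_ilr - power_orig` over scenarios, pooling
#' `+rho` with `-rho`, in the three layouts of the study's summary tables:
#' overall by `|rho|`; by `|rho|` and LOQ fraction `p`; or by `|rho|` and
#' total variance `s^2 = s11 + s22`.
#'
#' @param results A results data frame from [run_grid()].
#' @param grouping `"overall"`, `"by_p"` or `"by_total_variance"`.
#' @param dgp Optional filter: `"laplace"` or `"cauchy"`. With
#'   `grouping = "overall"` and no filter, one column per DGP is returned.
#' @return A data frame of class `"delta_power_summary"`: rows indexed by
#'   `|rho|` (column `abs_rho`), one column per group level holding the
#'   mean delta; attribute `n_scenarios` gives cell counts.
#' @export
summarize_delta_power <- function(results,
                                  grouping = c("overall", "by_p",
                                               "by_total_variance"),
                                  dgp = NULL) {
  grouping <- match.arg(grouping)
  results <- as.data.frame(results)
  needed <- c("rho", "dgp", "p", "s11", "s22", "delta")
  if (!all(needed %in% names(results)))
    stop("'results' must contain columns ",
         paste(needed, collapse = ", "), call. = FALSE)
  if (!is.null(dgp)) {
    dgp <- match.arg(dgp, c("laplace", "cauchy"))
    results <- results[results$dgp == dgp, , drop = FALSE]
  }
  if (nrow(results) == 0L)
    stop("no results left to aggregate", call. = FALSE)
  abs_rho <- round(abs(results$rho), 10)
  group <- switch(grouping,
                  overall = results$dgp,
                  by_p = results$p,
                  by_total_variance = round(results$s11 + results$s22, 10))
  cell_mean <- tapply(results$delta, list(abs_rho, group), mean)
  cell_n <- tapply(results$delta, list(abs_rho, group), length)
  out <- data.frame(abs_rho = as.numeric(rownames(cell_mean)),
                    cell_mean, check.names = FALSE)
  rownames(out) <- NULL
  attr(out, "n_scenarios") <- cell_n
  attr(out, "grouping") <- grouping
  attr(out, "dgp") <- if (is.null(dgp)) "all" else dgp
  class(out) <- c("delta_power_summary", "data.frame")
  out
}

#' @export
print.delta_power_summary <- function(x, digits = 3, ...) {
  cat(sprintf("Mean delta power (+rho and -rho pooled), grouping = %s, dgp = %s\n",
              attr(x, "grouping"), attr(x, "dgp")))
  y <- as.data.frame(x)
  y[-1L] <- lapply(y[-1L], round, digits = digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Stratified subsample of a scenario grid
#'
#' Samples a fraction of scenarios within every `(|rho|, dgp)` stratum,
#' preserving the relative weight of each association level in the
#' aggregated tables while cutting the computation to desk scale.
#'
#' @param grid A `scenario_grid` from [build_grid()].
#' @param fraction Fraction of each stratum to keep (at least one scenario
#'   per stratum).
#' @param seed Integer seed for the stratified draw.
#' @return The sampled rows of `grid`.
#' @export
subsample_grid <- function(grid, fraction = 0.05, seed = 1L) {
  grid <- as.data.frame(grid)
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("'fraction' must be in (0, 1]", call. = FALSE)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  strata <- interaction(abs(grid$rho), grid$dgp, drop = TRUE)
  take <- unlist(lapply(split(seq_len(nrow(grid)), strata), function(ix) {
    sample(ix, max(1L, round(fraction * length(ix))))
  }), use.names = FALSE)
  out <- grid[sort(take), , drop = FALSE]
  class(out) <- c("scenario_grid", "data.frame")
  out
}

#' Generate synthetic item-level Likert responses
#'
#' End-to-end demonstration data emulating the measurement model behind the
#' simulation: each respondent has a latent pair of trait values on the ilr
#' scale drawn from a bivariate DGP with association `latent_rho`; every
#' item adds independent normal noise on the ilr scale, is back-transformed
#' to the trait scale and snapped to the nearest response-category value,
#' yielding integer responses `1..K`.
#'
#' @param scale A [likert_scale()]; its `I` sets the number of items per
#'   trait.
#' @param n_respondents Number of respondents (`n >= 2`).
#' @param latent_rho Association of the latent pair in (-1, 1).
#' @param seed Integer seed.
#' @param dgp Latent DGP: `"laplace"` (default), `"cauchy"` or `"normal"`.
#' @param item_sd Standard deviation of the per-item noise on the ilr
#'   scale; 0 gives identical items within a respondent.
#' @param s11,s22 Dispersions of the latent DGP.
#' @return A list with integer matrices `trait1` and `trait2`
#'   (`n_respondents x I`, values in `1..K`) and the `scale` used.
#' @export
generate_fixture_responses <- function(scale, n_respondents, latent_rho,
                                       seed = 1L, dgp = "laplace",
                                       item_sd = 0.3, s11 = 1, s22 = 1) {
  stopifnot(inherits(scale, "likert_scale"))
  n <- check_count(n_respondents, "n_respondents", min = 2L)
  if (!is.numeric(item_sd) || length(item_sd) != 1L || item_sd < 0)
    stop("'item_sd' must be a nonnegative number", call. = FALSE)
  sigma <- make_scale_matrix(s11, s22, latent_rho)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  zeta <- draw_dgp(dgp, c(0, 0), sigma, n)
  I <- scale$I
  one_trait <- function(latent) {
    z_items <- latent + matrix(stats::rnorm(n * I, sd = item_sd), n, I)
    star <- inv_ilr2(z_items)
    snapped <- snap_to_nearest(star, scale$r_star)
    resp <- match(snapped, scale$r_star)
    matrix(resp, n, I)
  }
  list(trait1 = one_trait(zeta[, 1L]),
       trait2 = one_trait(zeta[, 2L]),
       scale = scale)
}
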