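# Bivariate heavy-tailed samplers: elliptical Laplace and Cauchy, with a
# scale matrix parameterised by two dispersions and a target association.

#' Build a 2 x 2 scale matrix from variances and a correlation
#'
#' Sets the off-diagonal to `s12 = rho * sqrt(s11 * s22)`, so that for
#' distributions with finite second moments (the elliptical Laplace used
#' here) `rho` is exactly the Pearson correlation. For the Cauchy case the
#' entries are dispersions and `rho` is an association parameter, not a
#' moment.
#'
#' @param s11,s22 Positive dispersion (variance) parameters.
#' @param rho Association parameter in (-1, 1).
#' @return An object of class `"scale_matrix"`: the 2 x 2 positive-definite
#'   matrix with attributes `s11`, `s22`, `s12`, `rho`.
#' @examples
#' make_scale_matrix(1, 1, 0.5)
#' @export
make_scale_matrix <- function(s11, s22, rho) {
  if (!is.numeric(s11) || length(s11) != 1L || !is.finite(s11) || s11 <= 0)
    stop("'s11' must be a single positive number", call. = FALSE)
  if (!is.numeric(s22) || length(s22) != 1L || !is.finite(s22) || s22 <= 0)
    stop("'s22' must be a single positive number", call. = FALSE)
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) ||
      abs(rho) >= 1)
    stop("'rho' must be a single number with |rho| < 1", call. = FALSE)
  s12 <- rho * sqrt(s11 * s22)
  m <- matrix(c(s11, s12, s12, s22), 2L, 2L)
  structure(m, s11 = s11, s22 = s22, s12 = s12, rho = rho,
            class = c("scale_matrix", "matrix"))
}

# Upper Cholesky factor R with t(R) %*% R = sigma, validating positive
# definiteness on the way.
chol_factor <- function(sigma) {
  if (inherits(sigma, "scale_matrix")) sigma <- unclass(sigma)
  sigma <- as.matrix(sigma)
  if (!isTRUE(all.equal(sigma, t(sigma))) ||
      any(diag(sigma) <= 0) || det(sigma) <= 0)
    stop("'sigma' must be a symmetric positive-definite scale matrix",
         call. = FALSE)
  chol(sigma)
}

# Correlated standard-normal core: n x d matrix Z %*% R.
gauss_core <- function(n, R) {
  matrix(stats::rnorm(n * nrow(R)), n, nrow(R)) %*% R
}

#' Sample from the bivariate elliptical Laplace distribution
#'
#' Uses the scale-mixture representation `X = center + sqrt(W) * A Z` with
#' `W ~ Exponential(1)`, `Z` standard bivariate normal and `A A' = sigma`
#' (Cholesky). Because `E(W) = 1`, the covariance of `X` equals `sigma`, so
#' the `rho` used to build the scale matrix is literally the correlation.
#' Marginals are heavier-tailed than the normal (excess kurtosis 3).
#'
#' @param center Length-2 numeric center (location) vector.
#' @param sigma A [make_scale_matrix()] result (or 2 x 2 positive-definite
#'   matrix).
#' @param n Number of pairs to draw (`n >= 2`).
#' @param seed Optional integer seed; when supplied the draw is
#'   reproducible and the caller's RNG state is restored afterwards.
#' @return An `n x 2` numeric matrix with columns `z1`, `z2` and attribute
#'   `dgp` = `"laplace"`.
#' @export
sample_laplace <- function(center = c(0, 0), sigma, n, seed = NULL) {
  draw_dgp("laplace", center, sigma, n, seed)
}

#' Sample from the bivariate Cauchy distribution
#'
#' The multivariate Cauchy is the multivariate t with one degree of
#' freedom: `X = center + A Z / sqrt(Q)` with `Q ~ chi-square(1)` and
#' `A A' = sigma`. No moments exist; marginals are Cauchy with location
#' `center[i]` and scale `sqrt(sigma[i, i])`, and `rho` in the scale matrix
#' is an association parameter only.
#'
#' @inheritParams sample_laplace
#' @return An `n x 2` numeric matrix with columns `z1`, `z2` and attribute
#'   `dgp` = `"cauchy"`.
#' @export
sample_cauchy <- function(center = c(0, 0), sigma, n, seed = NULL) {
  draw_dgp("cauchy", center, sigma, n, seed)
}

# Shared driver; `dgp` also admits "normal" for debugging/benchmarking
# against a finite-variance thin-tailed reference.
draw_dgp <- function(dgp, center, sigma, n, seed = NULL) {
  dgp <- match.arg(dgp, c("laplace", "cauchy", "normal"))
  if (!is.numeric(center) || length(center) != 2L || !all(is.finite(center)))
    stop("'center' must be a finite length-2 vector", call. = FALSE)
  n <- check_count(n, "n", min = 2L)
  R <- chol_factor(sigma)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(as.integer(seed))
  }
  x <- switch(dgp,
    laplace = sqrt(stats::rexp(n)) * gauss_core(n, R),
    cauchy  = gauss_core(n, R) / sqrt(stats::rchisq(n, df = 1)),
    normal  = gauss_core(n, R))
  x <- sweep(x, 2L, center, "+")
  colnames(x) <- c("z1", "z2")
  attr(x, "dgp") <- dgp
  x
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
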