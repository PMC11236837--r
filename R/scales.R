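# LOQ-adjusted response scales for bipolar Likert items, the discrete
# lattices of achievable item means, and nearest-mean snapping.

# Trait-scale bounds. The construction is invariant to the choice of
# bounds, so they are fixed constants rather than parameters.
TRAIT_LOWER <- 0
TRAIT_UPPER <- 100

#' Build an LOQ-adjusted bipolar response scale
#'
#' A questionnaire with `K` response categories cannot measure the extreme
#' regions of the underlying trait continuum \[0, 100\]; the limit of
#' quantification (LOQ) fraction `p` quantifies that unaddressed boundary
#' region, split symmetrically: `lLOQ = 100 p / 2`, `uLOQ = 100 (1 - p / 2)`.
#' The original responses `1, ..., K` are embedded into the trait scale as
#' `r*_s = lLOQ + sw (s - 1)` with step width `sw = (uLOQ - lLOQ) / (K - 1)`,
#' and each `r*` value is carried to the real line by the two-part ilr
#' transform ([ilr2()]).
#'
#' @param K Integer number of response categories (`K >= 2`).
#' @param p LOQ fraction in (0, 1). Small `p` describes a high-quality
#'   instrument that covers almost the whole trait continuum.
#' @param I Integer number of items in the scale (`I >= 1`); used when
#'   enumerating achievable means of `I` responses.
#' @return An object of class `"likert_scale"`: a list with elements `K`,
#'   `p`, `I`, `lLOQ`, `uLOQ`, `sw`, and the three numeric representations
#'   `r` (original `1..K`), `r_star` (trait scale) and `r_ilr` (ilr scale).
#' @examples
#' sc <- likert_scale(K = 5, p = 0.05, I = 2)
#' sc$r_star   # 2.5 26.25 50 73.75 97.5
#' sc$sw       # 23.75
#' @export
likert_scale <- function(K, p, I = 1L) {
  K <- check_count(K, "K", min = 2L)
  I <- check_count(I, "I", min = 1L)
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p <= 0 || p >= 1)
    stop("'p' must be a single number strictly between 0 and 1",
         call. = FALSE)
  lLOQ <- (TRAIT_UPPER - TRAIT_LOWER) * p / 2
  uLOQ <- (TRAIT_UPPER - TRAIT_LOWER) * (1 - p / 2)
  sw <- (uLOQ - lLOQ) / (K - 1L)
  r_star <- lLOQ + sw * (0:(K - 1L))
  structure(
    list(K = K, p = p, I = I,
         L = TRAIT_LOWER, U = TRAIT_UPPER,
         lLOQ = lLOQ, uLOQ = uLOQ, sw = sw,
         r = seq_len(K),
         r_star = r_star,
         r_ilr = ilr2(r_star)),
    class = "likert_scale")
}

check_count <- function(x, name, min) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x))
    stop(sprintf("'%s' must be a single integer", name), call. = FALSE)
  if (x < min)
    stop(sprintf("'%s' must be >= %d", name, min), call. = FALSE)
  as.integer(x)
}

#' @export
print.likert_scale <- function(x, digits = 4, ...) {
  cat(sprintf("Bipolar Likert scale: K = %d categories, I = %d item%s, p = %g\n",
              x$K, x$I, if (x$I > 1) "s" else "", x$p))
  cat(sprintf("  LOQ bounds: [%g, %g], step width sw = %g\n",
              x$lLOQ, x$uLOQ, x$sw))
  cat("  r*  :", paste(format(x$r_star, digits = digits), collapse = " "), "\n")
  cat("  ilr :", paste(format(x$r_ilr, digits = digits), collapse = " "), "\n")
  invisible(x)
}

#' Map an observed response to the trait scale
#'
#' Applies the last step of the LOQ adjustment: response `x' = s` on the
#' original `1..K` scale becomes `x* = lLOQ + sw (s - 1)`.
#'
#' @param x_prime Integer vector of responses in `1..K`.
#' @param scale A [likert_scale()].
#' @return Numeric vector of trait-scale values.
#' @examples
#' response_to_star(3, likert_scale(5, 0.05))   # 50
#' @export
response_to_star <- function(x_prime, scale) {
  stopifnot(inherits(scale, "likert_scale"))
  if (!is.numeric(x_prime) || any(!is.finite(x_prime)) ||
      any(x_prime != round(x_prime)) ||
      any(x_prime < 1 | x_prime > scale$K))
    stop(sprintf("'x_prime' must contain integer responses in 1..%d",
                 scale$K), call. = FALSE)
  scale$r_star[as.integer(x_prime)]
}

# Lattice points are exact rational combinations of the source values;
# float noise from repeated addition (<< 1e-12 of the lattice span) must
# not split one point into two. Sorted values closer than `tol` are merged,
# keeping the first of each cluster.
dedup_tol <- function(x, tol) {
  x <- sort(as.vector(x), method = "radix")
  x[c(TRUE, diff(x) > tol)]
}

# Is the value set symmetric about 0 (v == -rev(v))? Holds for every ilr
# response scale because r* is symmetric about 50.
antisymmetric_values <- function(v, tol) {
  all(abs(v + rev(v)) <= tol)
}

equally_spaced <- function(v, tol = 1e-9) {
  d <- diff(v)
  max(d) - min(d) <= tol * max(abs(v))
}

#' Enumerate the possible means of I item responses
#'
#' Averaging `I` discrete responses yields a finite set of achievable mean
#' values. For an equally spaced source scale this is the closed-form lattice
#' `min + j * (sw / I)`, `j = 0, ..., I (K - 1)`, with `I (K - 1) + 1`
#' points. For an irregular source scale (the ilr representation) the
#' distinct sums are built by iterated sumset construction: repeatedly add
#' the source values to the current set of partial sums, merging values
#' closer than `1e-12` of the lattice span at each step (accumulated float
#' noise is orders of magnitude below that, and genuinely distinct lattice
#' points essentially never fall that close). Antisymmetric value sets —
#' every ilr response scale — are iterated on their nonnegative half only.
#' This is exact for all practical scales and avoids enumerating all `K^I`
#' response tuples.
#'
#' @param source_values Strictly increasing numeric vector of scale values,
#'   or a [likert_scale()] (see `which`).
#' @param I Integer number of items averaged (`I >= 1`); defaults to the
#'   scale's own item count when `source_values` is a `likert_scale`.
#' @param which For a `likert_scale` input, which representation to
#'   enumerate: `"ilr"`, `"star"` or `"original"`.
#' @return An object of class `"possible_means"`: list with `values`
#'   (sorted, unique), `scale_label`, `I` and `K`.
#' @examples
#' sc <- likert_scale(5, 0.05, I = 2)
#' possible_means(sc, which = "ilr")    # 13 values
#' possible_means(sc, which = "star")   # 9 values
#' @export
possible_means <- function(source_values, I = NULL, which = "ilr") {
  label <- "custom"
  if (inherits(source_values, "likert_scale")) {
    which <- match.arg(which, c("ilr", "star", "original"))
    if (is.null(I)) I <- source_values$I
    label <- which
    source_values <- switch(which,
                            ilr = source_values$r_ilr,
                            star = source_values$r_star,
                            original = as.numeric(source_values$r))
  }
  v <- as.numeric(source_values)
  if (length(v) == 0L)
    stop("'source_values' must be nonempty", call. = FALSE)
  if (is.unsorted(v, strictly = TRUE))
    stop("'source_values' must be strictly increasing", call. = FALSE)
  I <- check_count(I, "I", min = 1L)

  if (length(v) == 1L) {
    vals <- v
  } else if (equally_spaced(v)) {
    step <- (v[length(v)] - v[1L]) / (length(v) - 1L)
    vals <- v[1L] + (0:(I * (length(v) - 1L))) * (step / I)
  } else {
    tol <- max(abs(v)) * I * 1e-12
    if (antisymmetric_values(v, tol)) {
      # iterate on the nonnegative half only: if S is the antisymmetric set
      # of i-item sums, the (i+1)-item sums are abs(S+ (+) v) and their
      # negatives
      sums <- v[v >= -tol]
      for (i in seq_len(I - 1L))
        sums <- dedup_tol(abs(outer(sums, v, "+")), tol)
      vals <- dedup_tol(c(-sums, sums) / I, tol / I)
    } else {
      sums <- v
      for (i in seq_len(I - 1L))
        sums <- dedup_tol(outer(sums, v, "+"), tol)
      vals <- dedup_tol(sums / I, tol / I)
    }
  }
  structure(list(values = vals, scale_label = label,
                 I = I, K = length(v)),
            class = "possible_means")
}

#' @export
print.possible_means <- function(x, max = 20L, ...) {
  cat(sprintf("Possible means of I = %d responses on the %s scale (K = %d): %d values\n",
              x$I, x$scale_label, x$K, length(x$values)))
  shown <- utils::head(x$values, max)
  cat(" ", paste(format(shown, digits = 4), collapse = " "),
      if (length(x$values) > max) "..." else "", "\n")
  invisible(x)
}

#' Snap values to the nearest possible mean
#'
#' Replaces each continuous value with the member of the possible-means
#' lattice at minimal Euclidean (absolute) distance. When a value is exactly
#' equidistant between two lattice points the smaller one is returned; the
#' rule is deterministic and, under continuous data-generating processes,
#' ties occur with probability zero.
#'
#' @param value Numeric vector of values to snap.
#' @param means A [possible_means()] object or a sorted numeric vector.
#' @return Numeric vector of lattice members, same length as `value`.
#' @examples
#' pm <- possible_means(likert_scale(5, 0.05, I = 2), which = "ilr")
#' snap_to_nearest(0.82, pm)   # 0.93
#' @export
snap_to_nearest <- function(value, means) {
  v <- if (inherits(means, "possible_means")) means$values else
    sort(as.numeric(means))
  if (length(v) == 0L)
    stop("'means' must be nonempty", call. = FALSE)
  if (!all(is.finite(value)))
    stop("'value' must be finite", call. = FALSE)
  if (length(v) == 1L) return(rep(v, length(value)))
  mids <- (v[-length(v)] + v[-1L]) / 2
  # left-open intervals put exact midpoints with the lower lattice point
  v[findInterval(value, mids, left.open = TRUE) + 1L]
}

#' Convert a trait-scale mean to the original response scale
#'
#' Inverts the LOQ embedding on mean values: a mean `m` on the `r*` lattice
#' corresponds to `1 + (m - lLOQ) / sw` on the original `1..K` scale (a
#' multiple of `1 / I`).
#'
#' @param mean_star Numeric vector of trait-scale means; each must lie on
#'   the possible-means lattice of `scale` (within relative tolerance 1e-6).
#' @param scale A [likert_scale()].
#' @return Numeric vector of original-scale means.
#' @examples
#' star_mean_to_original_mean(73.75, likert_scale(5, 0.05, I = 2))   # 4
#' @export
star_mean_to_original_mean <- function(mean_star, scale) {
  stopifnot(inherits(scale, "likert_scale"))
  if (!all(is.finite(mean_star)))
    stop("'mean_star' must be finite", call. = FALSE)
  s <- 1 + (mean_star - scale$lLOQ) / scale$sw
  on_lattice <- abs(s * scale$I - round(s * scale$I)) < 1e-6 &
    s >= 1 - 1e-9 & s <= scale$K + 1e-9
  if (!all(on_lattice))
    stop("'mean_star' contains values off the possible-means lattice of ",
         sprintf("(K = %d, p = %g, I = %d)", scale$K, scale$p, scale$I),
         call. = FALSE)
  round(s * scale$I) / scale$I
}

#' Relative distance between two responses on a scale
#'
#' The absolute distance between two scale values divided by the range of
#' the response scale, a unit-free measure that makes distances comparable
#' across the original, trait and ilr representations. Adjacent responses on
#' the original `1..5` scale, for instance, have relative distance `1/4`.
#'
#' @param a,b Scale values (numeric scalars or vectors of equal length).
#' @param scale_values Numeric vector of the scale's values (at least two
#'   distinct elements).
#' @return Numeric vector of relative distances in \[0, 1\] for on-scale
#'   inputs.
#' @examples
#' sc <- likert_scale(5, 0.05)
#' relative_distance(0, 0.73, sc$r_ilr)   # 0.14 to 2 d.p.
#' @export
relative_distance <- function(a, b, scale_values) {
  v <- as.numeric(scale_values)
  rng <- max(v) - min(v)
  if (length(v) < 2L || rng <= 0)
    stop("'scale_values' must contain at least two distinct values",
         call. = FALSE)
  abs(a - b) / rng
}
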