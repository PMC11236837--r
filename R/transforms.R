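# Log-ratio transform family on D-part compositions, with the D = 2
# specialisations used for bipolar response scales (total kappa = 100).

#' Construct a composition
#'
#' A composition is an ordered vector of `D >= 2` strictly positive parts with
#' a fixed total `kappa`. Compositions live on the simplex and are the natural
#' representation of an (agreement, disagreement) pair on a bipolar scale.
#'
#' @param parts Numeric vector of length `D >= 2`, all entries strictly
#'   positive.
#' @param kappa Expected total of the parts. Defaults to `sum(parts)`; when
#'   supplied, the parts must sum to `kappa` within relative tolerance `1e-9`.
#' @return An object of class `"composition"`: the numeric parts vector with
#'   attribute `kappa`.
#' @examples
#' composition(c(60, 40))
#' composition(c(20, 30, 50), kappa = 100)
#' @export
composition <- function(parts, kappa = sum(parts)) {
  parts <- as.numeric(parts)
  if (length(parts) < 2L)
    stop("'parts' must have at least D = 2 components", call. = FALSE)
  if (!all(is.finite(parts)))
    stop("'parts' must be finite", call. = FALSE)
  if (any(parts <= 0))
    stop("all components of 'parts' must be strictly positive", call. = FALSE)
  if (!is.finite(kappa) || kappa <= 0)
    stop("'kappa' must be a positive number", call. = FALSE)
  if (abs(sum(parts) - kappa) > 1e-9 * abs(kappa))
    stop("'parts' must sum to 'kappa' (relative tolerance 1e-9)", call. = FALSE)
  structure(parts, kappa = kappa, class = "composition")
}

as_composition <- function(x, kappa = NULL) {
  if (inherits(x, "composition")) return(x)
  if (is.null(kappa)) composition(x) else composition(x, kappa)
}

#' @export
print.composition <- function(x, ...) {
  cat("Composition of", length(x), "parts, total kappa =",
      format(attr(x, "kappa")), "\n")
  print(as.numeric(x), ...)
  invisible(x)
}

#' Additive log-ratio transform
#'
#' Maps a `D`-part composition to `D - 1` real coordinates by taking log
#' ratios against an arbitrarily chosen reference part `j`. For `D = 2` with
#' `j = 2` the alr reduces to the logit transform
#' `ln(x1 / (kappa - x1))`.
#'
#' @param x A [composition()] (or a positive numeric vector, coerced).
#' @param j Index of the reference part, `1 <= j <= D`. Default: last part.
#' @return Numeric vector of length `D - 1`.
#' @seealso [clr()], [ilr()]
#' @export
alr <- function(x, j = length(x)) {
  x <- as_composition(x)
  D <- length(x)
  j <- as.integer(j)
  if (length(j) != 1L || is.na(j) || j < 1L || j > D)
    stop("'j' must be a single index in 1..D", call. = FALSE)
  log(as.numeric(x)[-j] / as.numeric(x)[j])
}

#' Centred log-ratio transform
#'
#' Takes log ratios against the geometric mean of the parts; the resulting
#' `D` components sum to zero. For `D = 2` the first clr component equals
#' `0.5 * ln(x1 / (kappa - x1))`, i.e. half the logit, and the second is its
#' negative.
#'
#' @inheritParams alr
#' @return Numeric vector of length `D` summing to 0.
#' @export
clr <- function(x) {
  x <- as_composition(x)
  lx <- log(as.numeric(x))
  lx - mean(lx)
}

#' Isometric log-ratio transform (sequential-balance basis)
#'
#' Maps a `D`-part composition to `D - 1` coordinates
#' `z_s = sqrt(s / (s + 1)) * ln(g(x_1, ..., x_s) / x_{s+1})`,
#' `s = 1, ..., D - 1`, where `g` is the geometric mean. The ilr is an
#' isometry from the simplex (Aitchison metric) to Euclidean space, so
#' standard statistical procedures apply to the transformed coordinates.
#' For `D = 2` the single coordinate is `sqrt(0.5) * ln(x1 / (kappa - x1))`
#' (see [ilr2()]).
#'
#' @inheritParams alr
#' @return Numeric vector of length `D - 1`.
#' @seealso [inv_ilr()], [ilr2()]
#' @examples
#' ilr(composition(c(2.5, 97.5)))   # -2.59 to 2 d.p.
#' ilr(composition(c(50, 50)))      # 0
#' @export
ilr <- function(x) {
  x <- as_composition(x)
  v <- as.numeric(x)
  D <- length(v)
  s <- seq_len(D - 1L)
  # log geometric mean of the first s parts, each s
  gm <- cumsum(log(v))[s] / s
  sqrt(s / (s + 1)) * (gm - log(v[s + 1L]))
}

#' Inverse isometric log-ratio transform
#'
#' Reconstructs the unique composition with total `kappa` whose ilr
#' coordinates (sequential-balance basis, see [ilr()]) equal `z`. Internally
#' forms the auxiliary vector
#' `y_s = sum_{j=s}^{D} z_j / sqrt(j (j + 1)) - sqrt((s - 1) / s) * z_{s-1}`
#' with the conventions `z_0 = z_D = 0`, then closes
#' `x_s = kappa * exp(y_s) / sum(exp(y))`.
#'
#' @param z Numeric vector of `D - 1` finite ilr coordinates.
#' @param kappa Positive total of the reconstructed composition.
#' @return A [composition()] of `D = length(z) + 1` parts.
#' @examples
#' inv_ilr(0.73, kappa = 100)   # (73.75, 26.25) to 2 d.p.
#' @export
inv_ilr <- function(z, kappa = 100) {
  z <- as.numeric(z)
  if (length(z) < 1L || !all(is.finite(z)))
    stop("'z' must be a nonempty vector of finite ilr coordinates",
         call. = FALSE)
  if (!is.finite(kappa) || kappa <= 0)
    stop("'kappa' must be a positive number", call. = FALSE)
  D <- length(z) + 1L
  zz <- c(z, 0)                       # z_D := 0
  j <- seq_len(D)
  tail_sums <- rev(cumsum(rev(zz / sqrt(j * (j + 1)))))
  zprev <- c(0, z)                    # z_0 := 0
  s <- seq_len(D)
  y <- tail_sums - sqrt((s - 1) / s) * zprev
  ey <- exp(y - max(y))               # guard against overflow
  composition(kappa * ey / sum(ey), kappa)
}

#' Two-part ilr of a trait-scale value
#'
#' The `D = 2` specialisation of [ilr()] applied to the composition
#' `(x*, 100 - x*)`: `z = sqrt(0.5) * ln(x* / (100 - x*))`. It is strictly
#' increasing on (0, 100) and antisymmetric about 50:
#' `ilr2(100 - x) = -ilr2(x)`.
#'
#' Values within `1e-12` of the boundaries 0 and 100 are rejected rather than
#' mapped to infinite coordinates; LOQ-adjusted scales only produce interior
#' points.
#'
#' @param x_star Numeric vector of trait-scale values in (0, 100).
#' @return Numeric vector of ilr coordinates, same length as `x_star`.
#' @seealso [inv_ilr2()]
#' @examples
#' ilr2(c(2.5, 26.25, 50, 73.75, 97.5))
#' @export
ilr2 <- function(x_star) {
  x_star <- as.numeric(x_star)
  if (!all(is.finite(x_star)))
    stop("'x_star' must be finite", call. = FALSE)
  if (any(x_star < 1e-12 | x_star > 100 - 1e-12))
    stop("'x_star' must lie strictly inside (0, 100)", call. = FALSE)
  sqrt(0.5) * log(x_star / (100 - x_star))
}

#' Inverse two-part ilr
#'
#' Back-transforms an ilr coordinate to the trait scale \[0, 100\]:
#' `x* = 100 * exp(y1) / (exp(y1) + exp(y2))` with `y1 = sqrt(0.5) * z` and
#' `y2 = -y1`. Inverse of [ilr2()] on (0, 100).
#'
#' @param z1 Numeric vector of finite ilr coordinates.
#' @return Numeric vector of trait-scale values in (0, 100).
#' @examples
#' inv_ilr2(0.73)   # 73.75 to 2 d.p.
#' inv_ilr2(0.82)   # 76.13 to 2 d.p.
#' @export
inv_ilr2 <- function(z1) {
  z1 <- as.numeric(z1)
  if (!all(is.finite(z1)))
    stop("'z1' must be finite", call. = FALSE)
  # 100 * e^{y1} / (e^{y1} + e^{-y1}) = 100 * plogis(2 * y1)
  100 * stats::plogis(sqrt(2) * z1)
}
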