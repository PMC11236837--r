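---
title: "Bipolar Likert scales as compositions: the ilr approach and its effect on correlation-test power"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bipolar Likert scales as compositions: the ilr approach and its effect on correlation-test power}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ilrpower)
```

## The measurement model

A bipolar Likert item asks for a position between two opposed poles
("not at all" to "very much"). A response expresses simultaneously an
order of magnitude of agreement (OMA) and its complement, the order of
magnitude of disagreement (OMD). On a trait continuum fixed to $[0, 100]$,
a response at $x^*$ carries the pair $(x^*,\, 100 - x^*)$: two positive
parts with a fixed total $\kappa = 100$. That pair is a two-part
*composition*, and compositions live on the simplex, whose natural
geometry (Aitchison) differs from the Euclidean geometry that means,
Pearson correlations and t-tests assume.

A questionnaire cannot resolve the extremes of the continuum. The package
models this limit of quantification (LOQ) with a single fraction
$p \in (0, 1)$, split symmetrically between the two ends:

$$\mathrm{lLOQ} = 100\,p/2, \qquad \mathrm{uLOQ} = 100\,(1 - p/2).$$

A $K$-category response scale $1, \dots, K$ is embedded into the trait
continuum by

$$x^* = \mathrm{lLOQ} + sw\,(s - 1), \qquad
  sw = \frac{\mathrm{uLOQ} - \mathrm{lLOQ}}{K - 1},$$

so category 1 sits at the lower LOQ bound and category $K$ at the upper.
`likert_scale()` performs this construction:

```{r}
sc <- likert_scale(K = 5, p = 0.05, I = 2)
sc
```

## Log-ratio transforms

The two-part isometric log-ratio (ilr) transform

$$z = \sqrt{0.5}\,\ln\frac{x^*}{100 - x^*}$$

maps the interior of the trait scale to the real line isometrically with
respect to the simplex geometry; standard statistics then apply to $z$.
`ilr()`/`inv_ilr()` implement the general $D$-part transform in the
sequential-balance basis, with `ilr2()`/`inv_ilr2()` as the fast two-part
special case. The additive log-ratio (`alr()`), the logit (its $D = 2$
case) and the centred log-ratio (`clr()`) are provided for completeness;
for $D = 2$ they differ from the ilr only by constant factors
($\sqrt{2}\,z$ and $\sqrt{0.5}\,z$ for the first clr component), so the
choice among them is immaterial for correlation testing. As $p \to 0$ the
ilr image of the response scale spreads without bound; small $p$
(a high-quality instrument) therefore produces a wide, strongly
end-stretched ilr scale.

## Possible means and snapping

Averaging $I$ discrete item responses can only produce finitely many
values. For an equally spaced source scale (the original $1..K$ scale and
its trait-scale embedding $r^*$) the achievable means form the closed-form
lattice $\min + j\,(sw/I)$, $j = 0, \dots, I(K-1)$, with $I(K-1)+1$
points. The ilr scale is *not* equally spaced, and its achievable means
are strictly richer — the ilr lattice is finer-grained, densest near the
centre:

```{r}
length(possible_means(sc, which = "ilr")$values)   # 13 for K = 5, I = 2
length(possible_means(sc, which = "star")$values)  # 9
```

`snap_to_nearest()` replaces a continuous value with its closest lattice
member in absolute (Euclidean) distance. Snapping on the trait scale uses
the Euclidean metric deliberately, although the simplex geometry would
suggest otherwise: it mirrors what practitioners actually do when they
average raw Likert scores.

Numerical choices worth knowing:

* **Lattice deduplication.** Achievable-mean sets are built by iterated
  sumsets; sorted sums closer than $10^{-12}$ of the lattice span are
  merged. Accumulated float noise is below $10^{-13}$ of the span, while
  genuinely distinct lattice points essentially never fall that close, so
  the tolerance separates noise from structure. Antisymmetric value sets
  (every ilr response scale) are iterated on their nonnegative half only,
  halving time and memory; the largest lattice the full design needs
  ($K = 10$, $I = 30$) has a few million points and builds in seconds.
* **Ties.** A value exactly midway between two lattice points snaps to
  the smaller one — deterministic and order-independent; under the
  continuous generating processes used here ties have probability zero,
  so the rule cannot bias results.
* **Boundaries.** `ilr2()` refuses values within $10^{-12}$ of 0 or 100
  instead of returning $\pm\infty$; LOQ-adjusted scales only produce
  interior points, so a boundary value always indicates an input error.

## The simulated comparison

Each scenario imagines two latent traits whose respondent-level means
$(z_1, z_2)$ on the ilr scale follow a centred bivariate distribution
with scale matrix $\Sigma$, $s_{12} = \varrho\sqrt{s_{11} s_{22}}$. Two
generating processes are provided:

* **Elliptical Laplace** — $X = \sqrt{W}\,A Z$ with $W \sim \mathrm{Exp}(1)$,
  $A A^\top = \Sigma$: heavy-tailed but with finite moments, and
  $\mathrm{Cov}(X) = \Sigma$, so $\varrho$ is literally the correlation.
* **Cauchy** — multivariate t with one degree of freedom,
  $X = A Z / \sqrt{Q}$, $Q \sim \chi^2_1$: no moments exist, and
  $\varrho$ is an association parameter of the scale matrix, not a
  correlation. The simulation treats it as the target association.

A `normal` option exists for benchmarking against a thin-tailed
reference; it is not part of the study design.

For each of `n_runs` runs, `run_scenario()` draws `n_pairs` pairs and
follows both evaluation paths: the ILR path snaps $z$ to the achievable
ilr means; the ORIG path back-transforms $z$ with the inverse ilr, snaps
on the trait scale, and reads the result on the original $1..K$ scale
(an affine relabelling that leaves Pearson correlation untouched — the
package computes on original-scale means to mirror common practice). The
correlation t-test of $H_0\!: \varrho = 0$,
$t = r\sqrt{n-2}/\sqrt{1-r^2}$, is applied to both snapped datasets; the
rejection proportions estimate $\mathrm{Power}^{ilr}$ and
$\mathrm{Power}^{orig}$, and their difference $\Delta\mathrm{Power}$
measures what ignoring the compositional structure costs.

Runs in which a snapped sample is constant on either path have an
undefined correlation; they are counted as non-rejections (dropping them
would bias power upward) and reported in `n_zero_var`.

The test level defaults to $\alpha = 0.05$ two-sided — the discipline
default, exposed as a `scenario()` argument rather than hard-coded.

## The scenario grid and seeds

`grid_spec()` defaults encode the full design: dispersions
$0.25, 0.5, \dots, 2$ as unordered pairs (36 combinations — the only
reading consistent with that count), associations $\pm 0.05, \dots,
\pm 0.65$ (26 values; beyond 0.65 both paths are saturated at power 1),
$K \in \{5, 6, 10\}$, $I \in \{1, 4, 10, 30\}$, $p = 0.02, \dots, 0.2$,
both DGPs: 224,640 scenarios of 1000 runs with 200 pairs each.

Seeding is two-level: `build_grid()` draws one child seed per scenario
from a stream seeded with `master_seed`; `run_scenario()` seeds once with
its child seed and consumes a single stream across its runs. Results are
therefore reproducible scenario-by-scenario and independent of execution
order, which is what makes `run_grid()`'s append-only CSV store resumable.

`summarize_delta_power()` averages $\Delta\mathrm{Power}$ with $+\varrho$
and $-\varrho$ pooled — overall, by LOQ fraction $p$, or by total
dispersion $s^2 = s_{11} + s_{22}$ — the three layouts of the study's
summary tables. Cells are plain arithmetic means over scenarios; no
smoothing is applied (the source figures interpolate with cubic splines,
but an interpolating spline evaluated at its knots returns the raw means
anyway).

## Desk-scale reproduction

The full grid is a cluster-scale computation. The package's tests and
examples use a stratified subsample instead: `subsample_grid()` keeps 5%
of scenarios within every $(|\varrho|, \mathrm{DGP})$ stratum (432 of
8640 per stratum) and `n_runs = 300`, which bounds the Monte-Carlo
standard error of a pooled summary-table cell near 0.002 while keeping
the sweep in the minutes range on one core. Property suites (lattice
counts against brute-force tuple enumeration, transform round trips,
t-test boundary against the Student-t quantile) cover what the subsample
cannot.

## What the fixture generator does and does not emulate

`generate_fixture_responses()` produces item-level integer responses for
end-to-end demonstrations: latent trait pairs from a chosen DGP, plus
independent normal item noise (`item_sd`, default 0.3 on the ilr scale —
a moderate item reliability), back-transformed and snapped per item. It
emulates the measurement model's structure, not real questionnaire data:
no item-specific difficulties or loadings, no response styles
(acquiescence, extreme responding), no missingness, and the same noise
scale for every item. Passing tests on these fixtures show that the
pipeline recovers a known latent association through discretisation —
not that any particular real instrument behaves this way.

Note the power engine itself never uses item-level fixtures: following
the study design, it simulates respondent-level means directly and lets
the item count enter only through the possible-means lattice.

## Size of the correlation test under elliptical mixing

One subtlety of the elliptical construction deserves emphasis: both
heavy-tailed generators share a single mixing variable between the two
coordinates ($\sqrt{W}$ for the Laplace, $1/\sqrt{Q}$ for the Cauchy).
At $\varrho = 0$ the coordinates are therefore *uncorrelated but not
independent* — large draws tend to occur in both traits at once — and
the null distribution of the sample correlation is wider than the
$\mathcal{N}(0, 1/n)$ the t-test assumes (for the Laplace,
$\mathrm{Var}(r) \approx 2/n$ on continuous data). The correlation
t-test is consequently anticonservative under these processes even
before any discretisation; snapping to a bounded lattice winsorizes the
shared-scale outliers and pulls the size back toward, but not onto, the
nominal level, by different amounts on the two paths. Rejection rates
near $\varrho = 0$ should therefore be read as the operating size of the
test under the process, not as $\alpha$; the acceptance suite computes
these rates explicitly.

## Known limitations

* Only symmetric LOQ ($|\delta_l| = |\delta_u| = p/2$) is supported; $p$
  must be supplied, never estimated from data.
* Only the correlation t-test is implemented; t-tests of means and
  regression analyses on ilr data are out of scope.
* The Cauchy path inherits the conceptual looseness of "correlation"
  for a distribution without moments; results there describe the scale
  matrix's association parameter.
* Reproductions of the source study's summary tables at desk scale agree
  in sign structure and envelope but not uniformly in magnitude; the
  residual gap is documented with the acceptance materials and appears to
  stem from an underdocumented detail of the original snapping step (the
  source's own worked snapping example is inconsistent with its stated
  Euclidean metric).
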