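# ilrpower

Bipolar Likert responses ("not at all" … "very much") encode an order of
magnitude of agreement and, implicitly, its complement of disagreement:
a pair of positive parts with a fixed total — compositional data on the
simplex, where Euclidean statistics (means, Pearson correlation, t-tests)
are not at home. `ilrpower` is for psychometricians and biostatisticians
who want to (a) treat Likert scales compositionally via the isometric
log-ratio (ilr) transform and (b) quantify what that buys or costs in the
statistical power of correlation testing.

The package provides:

* **LOQ-adjusted scales.** A `K`-category scale is embedded into the
  trait continuum [0, 100] with a limit-of-quantification fraction
  `p`: `x* = lLOQ + sw (s − 1)`, `lLOQ = 100p/2`,
  `sw = (uLOQ − lLOQ)/(K − 1)`.
* **The log-ratio family.** `alr`, `clr`, general-D `ilr`/`inv_ilr`
  (sequential-balance basis) and the two-part specialisation
  `z = √0.5 · ln(x*/(100 − x*))` with its inverse.
* **Possible-means lattices.** The finite set of achievable means of `I`
  item responses on each scale representation, with Euclidean
  nearest-mean snapping.
* **A Monte-Carlo power engine.** Bivariate elliptical-Laplace and Cauchy
  generators with scale matrix `s12 = ρ√(s11 s22)`; per-scenario
  estimation of `Power^ilr`, `Power^orig` and
  `ΔPower = Power^ilr − Power^orig` for the t-test of `H0: ρ = 0`; a
  224,640-scenario default grid with stratified subsampling, a resumable
  results store, and summary tables of mean ΔPower by `|ρ|`, by `p`, and
  by total dispersion `s² = s11 + s22`.

## Worked example

```r
library(ilrpower)

sc <- likert_scale(K = 5, p = 0.05, I = 2)
sc
#> Bipolar Likert scale: K = 5 categories, I = 2 items, p = 0.05
#>   LOQ bounds: [2.5, 97.5], step width sw = 23.75
#>   r*  :  2.50 26.25 50.00 73.75 97.50
#>   ilr : -2.5905 -0.7305  0.0000  0.7305  2.5905
```

Category 3 of 5 sits at the trait midpoint 50; the ilr image of the scale
is symmetric about 0. Averaging two items yields 13 achievable means on
the ilr scale but only 9 on the trait scale — the ilr lattice is finer:

```r
possible_means(sc, which = "ilr")
#> Possible means of I = 2 responses on the ilr scale (K = 5): 13 values
#>   -2.5905 -1.6605 -1.2953 -0.9300 -0.7305 -0.3652  0.0000  0.3652
#>    0.7305  0.9300  1.2953  1.6605  2.5905
snap_to_nearest(0.82, possible_means(sc, which = "ilr"))
#> [1] 0.7304519
```

A simulated mean of 0.82 is replaced by its nearest achievable mean,
0.73. One power scenario — two traits with true correlation 0.15 under a
heavy-tailed Laplace process, 1000 runs of 200 respondent pairs:

```r
run_scenario(scenario(s11 = 1, s22 = 1, rho = 0.15, dgp = "laplace",
                      K = 5, p = 0.1, I = 4, n_pairs = 200,
                      n_runs = 1000, seed = 42))
#> Power of the correlation t-test (laplace DGP, rho = 0.15, K = 5, I = 4, p = 0.1):
#>   ilr scale      : 0.5400
#>   original scale : 0.5270
#>   delta power    : +0.0130   (1000/1000 runs effective)
```

Here the ilr path rejects `H0: ρ = 0` in 54.0% of runs versus 52.7% on
the raw scale: at this small effect size the compositional treatment
gains about 1.3 percentage points of power. Grid sweeps follow the same
pattern:

```r
spec <- grid_spec(n_runs = 300)            # full design, desk-scale runs
grid <- subsample_grid(build_grid(spec), fraction = 0.05, seed = 42)
res  <- run_grid(grid, store = "results.csv")
summarize_delta_power(res, "overall")      # mean ΔPower by |rho| and DGP
```

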