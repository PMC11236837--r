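test_that("the default grid reproduces the study's combinatorics", {
  spec <- grid_spec()
  grid <- build_grid(spec)
  expect_equal(nrow(grid), 224640)
  expect_equal(nrow(unique(grid[c("s11", "s22")])), 36)
  expect_equal(length(spec$correlations), 26)
  expect_true(all(grid$s11 <= grid$s22))
  expect_false(any(grid$rho == 0))
  expect_true(all(grid$seed > 0 & grid$seed < .Machine$integer.max))
})

test_that("grid size follows the unordered-pair formula on small grids", {
  for (m in 1:4) {
    for (nr in 1:3) {
      spec <- grid_spec(variances = seq_len(m) / 2,
                        correlations = seq_len(nr) / 10,
                        Ks = 5, Is = c(1, 4), ps = c(0.1, 0.2),
                        dgps = "laplace")
      grid <- build_grid(spec)
      expect_equal(nrow(grid), (choose(m, 2) + m) * nr * 1 * 2 * 2 * 1)
      # oracle: explicit enumeration of unordered variance pairs
      pairs <- unique(t(apply(expand.grid(seq_len(m) / 2, seq_len(m) / 2),
                              1, sort)))
      expect_equal(nrow(unique(grid[c("s11", "s22")])), nrow(pairs))
    }
  }
  expect_equal(nrow(build_grid(grid_spec(variances = 1, correlations = 0.3,
                                         Ks = 5, Is = 2, ps = 0.1,
                                         dgps = "cauchy"))), 1)
})

test_that("grid enumeration and child seeds are deterministic", {
  g1 <- build_grid(grid_spec(variances = c(0.5, 1), correlations = c(-0.2, 0.2),
                             Ks = 5, Is = 1, ps = 0.1, master_seed = 7))
  g2 <- build_grid(grid_spec(variances = c(0.5, 1), correlations = c(-0.2, 0.2),
                             Ks = 5, Is = 1, ps = 0.1, master_seed = 7))
  g3 <- build_grid(grid_spec(variances = c(0.5, 1), correlations = c(-0.2, 0.2),
                             Ks = 5, Is = 1, ps = 0.1, master_seed = 8))
  expect_identical(g1, g2)
  expect_false(identical(g1$seed, g3$seed))
})

test_that("run_grid executes, stores, and resumes without recomputation", {
  grid <- build_grid(grid_spec(variances = 1, correlations = c(-0.3, 0.3),
                               Ks = 5, Is = 1, ps = 0.1, dgps = "laplace",
                               n_pairs = 30, n_runs = 50, master_seed = 5))
  store <- tempfile(fileext = ".csv")
  res <- run_grid(grid, store = store)
  expect_equal(nrow(res), 2)
  expect_true(all(res$power_ilr * res$n_runs ==
                    round(res$power_ilr * res$n_runs)))
  mtime <- file.mtime(store)
  res2 <- run_grid(grid, store = store)   # complete store: nothing to do
  expect_equal(file.mtime(store), mtime)
  expect_equal(sort(res2$delta), sort(res$delta))
  # partial store: only the missing scenario is computed
  partial <- utils::read.csv(store)[1, , drop = FALSE]
  store2 <- tempfile(fileext = ".csv")
  utils::write.csv(partial, store2, row.names = FALSE)
  res3 <- run_grid(grid, store = store2)
  expect_equal(nrow(res3), 2)
  expect_equal(sort(res3$delta), sort(res$delta))
})

test_that("aggregation pools +-rho and is linear in the results", {
  res <- data.frame(rho = c(0.1, -0.1, 0.2, 0.1), dgp = "laplace",
                    p = c(0.1, 0.1, 0.1, 0.2), s11 = 1, s22 = c(1, 1, 1, 2),
                    delta = c(0.04, 0.06, -0.02, 0.10))
  tab <- summarize_delta_power(res, "overall")
  expect_equal(tab$abs_rho, c(0.1, 0.2))
  expect_equal(tab$laplace, c(mean(c(0.04, 0.06, 0.10)), -0.02))
  byp <- summarize_delta_power(res, "by_p")
  expect_equal(byp[byp$abs_rho == 0.1, "0.1"], 0.05)
  expect_equal(byp[byp$abs_rho == 0.1, "0.2"], 0.10)
  bys <- summarize_delta_power(res, "by_total_variance")
  expect_equal(names(bys), c("abs_rho", "2", "3"))
  # single-scenario store: the cell equals that scenario's delta
  one <- summarize_delta_power(res[3, ], "overall")
  expect_equal(one$laplace, -0.02)
  # linearity: pooled mean equals the weighted mean of disjoint parts
  parts <- rbind(res[1:2, ], res[4, ])
  m_all <- summarize_delta_power(res[c(1, 2, 4), ], "overall")$laplace
  expect_equal(m_all, mean(parts$delta))
  # permutation invariance
  perm <- summarize_delta_power(res[sample(4), ], "overall")
  expect_equal(perm, tab, ignore_attr = TRUE)
})

test_that("stratified subsampling keeps every (|rho|, dgp) stratum", {
  grid <- build_grid(grid_spec(variances = c(0.5, 1),
                               correlations = c(-0.2, -0.1, 0.1, 0.2),
                               Ks = c(5, 6), Is = c(1, 4), ps = c(0.1, 0.2)))
  sub <- subsample_grid(grid, fraction = 0.25, seed = 2)
  expect_true(all(table(abs(sub$rho), sub$dgp) > 0))
  expect_lt(nrow(sub), nrow(grid) / 2)
  expect_identical(sub, subsample_grid(grid, fraction = 0.25, seed = 2))
})

test_that("fixture responses recover the latent association", {
  sc <- likert_scale(5, 0.1, I = 4)
  fx <- generate_fixture_responses(sc, 5000, latent_rho = 0.6, seed = 12)
  expect_true(all(fx$trait1 %in% 1:5) && all(fx$trait2 %in% 1:5))
  expect_equal(dim(fx$trait1), c(5000, 4))
  # ilr-path analysis of the generated responses
  z1 <- rowMeans(responses_to_ilr(fx$trait1, sc))
  z2 <- rowMeans(responses_to_ilr(fx$trait2, sc))
  expect_equal(stats::cor(z1, z2), 0.6, tolerance = 0.05 / 0.6)
  # independent traits stay near zero
  fx0 <- generate_fixture_responses(sc, 4000, latent_rho = 1e-6, seed = 13)
  r0 <- stats::cor(rowMeans(responses_to_ilr(fx0$trait1, sc)),
                   rowMeans(responses_to_ilr(fx0$trait2, sc)))
  expect_lt(abs(r0), 0.05)
  # zero item noise makes all items within a respondent identical
  fxd <- generate_fixture_responses(sc, 50, latent_rho = 0.3, seed = 14,
                                    item_sd = 0)
  expect_true(all(apply(fxd$trait1, 1, function(r) length(unique(r))) == 1))
})
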