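test_that("scale construction reproduces the LOQ worked example", {
  sc <- likert_scale(K = 5, p = 0.05, I = 2)
  expect_equal(sc$lLOQ, 2.5)
  expect_equal(sc$uLOQ, 97.5)
  expect_equal(sc$sw, 23.75)
  expect_equal(sc$r_star, c(2.5, 26.25, 50, 73.75, 97.5))
  expect_equal(round(sc$r_ilr, 2), c(-2.59, -0.73, 0, 0.73, 2.59))
})

test_that("scale construction rejects invalid parameters by name", {
  expect_error(likert_scale(1, 0.05), "'K'")
  expect_error(likert_scale(5, 0), "'p'")
  expect_error(likert_scale(5, 1), "'p'")
  expect_error(likert_scale(5, 0.05, I = 0), "'I'")
  expect_error(likert_scale(4.5, 0.05), "'K'")
})

test_that("r_star is symmetric about 50 and r_ilr antisymmetric about 0", {
  for (K in c(2, 5, 6, 10, 11)) {
    for (p in c(0.02, 0.1, 0.2)) {
      sc <- likert_scale(K, p)
      expect_equal(sc$r_star + rev(sc$r_star), rep(100, K))
      expect_equal(sc$r_ilr, -rev(sc$r_ilr), tolerance = 1e-12)
      expect_equal(diff(sc$r_star), rep(sc$sw, K - 1))
      if (K %% 2 == 1) expect_equal(sc$r_star[(K + 1) / 2], 50)
    }
  }
})

test_that("responses map to the trait scale per the 4-step algorithm", {
  sc <- likert_scale(5, 0.05)
  expect_equal(response_to_star(3, sc), 50)
  expect_equal(response_to_star(1, sc), 2.5)
  expect_equal(response_to_star(5, likert_scale(5, 0.02)), 99)
  expect_equal(response_to_star(1:5, sc), sc$r_star)
  expect_error(response_to_star(6, sc), "1..5")
  expect_error(response_to_star(0, sc), "1..5")
  expect_error(response_to_star(2.5, sc), "1..5")
})

test_that("possible means match the published two-item lattices", {
  sc <- likert_scale(5, 0.05, I = 2)
  pm_ilr <- possible_means(sc, which = "ilr")
  pm_star <- possible_means(sc, which = "star")
  expect_length(pm_ilr$values, 13)
  expect_length(pm_star$values, 9)
  expect_equal(round(pm_ilr$values, 2),
               c(-2.59, -1.66, -1.30, -0.93, -0.73, -0.37, 0,
                 0.37, 0.73, 0.93, 1.30, 1.66, 2.59))
  expect_equal(pm_star$values,
               c(2.5, 14.375, 26.25, 38.125, 50, 61.875, 73.75, 85.625, 97.5))
  pm_orig <- possible_means(sc, which = "original")
  expect_equal(pm_orig$values, seq(1, 5, by = 0.5))
})

test_that("possible means equal brute-force tuple enumeration (K <= 6, I <= 4)", {
  for (K in c(2, 3, 5, 6)) {
    for (I in 1:4) {
      sc <- likert_scale(K, 0.06, I = I)
      for (which in c("ilr", "star")) {
        got <- possible_means(sc, which = which)$values
        want <- brute_force_means(
          switch(which, ilr = sc$r_ilr, star = sc$r_star), I)
        expect_equal(got, want, tolerance = 1e-8,
                     info = sprintf("K=%d I=%d %s", K, I, which))
      }
    }
  }
})

test_that("equally spaced scales have I(K-1)+1 possible means", {
  for (K in 2:12) {
    for (I in 1:6) {
      pm <- possible_means(seq_len(K) * 1.0, I = I)
      expect_length(pm$values, I * (K - 1) + 1)
    }
  }
})

test_that("I = 1 returns the source scale itself", {
  sc <- likert_scale(6, 0.1, I = 1)
  expect_equal(possible_means(sc, which = "ilr")$values, sort(sc$r_ilr))
  expect_equal(possible_means(sc$r_star, I = 1)$values, sc$r_star)
})

test_that("ilr lattice is at least as fine as the trait-scale lattice", {
  for (K in c(5, 6, 10)) {
    for (p in seq(0.02, 0.2, by = 0.02)) {
      for (I in c(2, 4)) {
        sc <- likert_scale(K, p, I = I)
        n_ilr <- length(possible_means(sc, which = "ilr")$values)
        n_star <- length(possible_means(sc, which = "star")$values)
        expect_gte(n_ilr, n_star)
      }
    }
  }
})

test_that("possible-means lattices inherit the scale symmetries", {
  for (K in c(5, 6)) {
    sc <- likert_scale(K, 0.08, I = 3)
    star <- possible_means(sc, which = "star")$values
    ilr <- possible_means(sc, which = "ilr")$values
    expect_equal(star + rev(star), rep(100, length(star)))
    expect_equal(ilr, -rev(ilr), tolerance = 1e-9)
  }
})

test_that("snapping returns lattice members, is idempotent, ties go down", {
  sc <- likert_scale(5, 0.05, I = 2)
  pm <- possible_means(sc, which = "ilr")
  set.seed(3)
  z <- stats::runif(200, -3, 3)
  snapped <- snap_to_nearest(z, pm)
  expect_true(all(snapped %in% pm$values))
  expect_equal(snap_to_nearest(snapped, pm), snapped)
  expect_equal(snapped, naive_snap(z, pm$values))
  # exact midpoint of 0 and 0.3655 snaps to the smaller value
  expect_equal(snap_to_nearest(mean(pm$values[7:8]), pm), pm$values[7])
  expect_error(snap_to_nearest(numeric(0), numeric(0)), "nonempty")
  expect_error(snap_to_nearest(NaN, pm), "finite")
})

test_that("snapping reproduces the worked simulated-mean associations", {
  sc <- likert_scale(5, 0.05, I = 2)
  pm_star <- possible_means(sc, which = "star")
  expect_equal(snap_to_nearest(76.13, pm_star), 73.75)
  expect_equal(star_mean_to_original_mean(73.75, sc), 4)
})

test_that("trait-scale means convert to original-scale means and back", {
  sc <- likert_scale(5, 0.05, I = 2)
  expect_equal(star_mean_to_original_mean(sc$lLOQ, sc), 1)
  expect_equal(star_mean_to_original_mean(50, sc), 3)
  star <- possible_means(sc, which = "star")$values
  orig <- star_mean_to_original_mean(star, sc)
  expect_equal(orig, seq(1, 5, by = 0.5))
  # identity when composed with the forward embedding of original means
  expect_equal(star_mean_to_original_mean(sc$lLOQ + (orig - 1) * sc$sw, sc),
               orig)
  expect_error(star_mean_to_original_mean(60, sc), "lattice")
})

test_that("relative distance normalises by the scale range", {
  sc <- likert_scale(5, 0.05)
  expect_equal(round(relative_distance(0, 0.73, sc$r_ilr), 2), 0.14)
  expect_equal(relative_distance(2, 3, 1:5), 0.25)
  expect_equal(relative_distance(1.3, 1.3, sc$r_ilr), 0)
  expect_error(relative_distance(0, 1, c(2, 2)), "distinct")
})
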