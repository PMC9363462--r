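test_that("one-hot encoding places indicator blocks deterministically", {
  d <- preset_design("Lib4")
  enc <- one_hot_encode("QQCYIDPWMLDH", d)
  on_cols <- colnames(enc$x)[enc$x[1, ] == 1]
  expect_setequal(on_cols, c("Q@-1", "C@+1", "Y@+2", "I@+3"))
  expect_identical(sum(enc$x), 4)

  two <- one_hot_encode(rep("HQSYVDPWMLDH", 2), d)
  expect_identical(two$x[1, ], two$x[2, ])

  set.seed(17)
  peps <- random_peptides(40, 12)
  xs <- one_hot_encode(peps, d)$x
  expect_true(all(rowSums(xs) == length(d$randomized_indices)))

  expect_error(one_hot_encode("*QSYVDPWMLDH", d), "alphabet")
})

test_that("a constant response fits perfectly with zero importances", {
  d <- preset_design("Lib4")
  set.seed(19)
  x <- one_hot_encode(random_peptides(200, 12), d)$x
  y <- rep(2.5, 200)
  fit <- fit_rf_cv(x, y, k = 5, num_trees = 30, seed = 3)
  expect_lt(mean(fit$mse_fold), 1e-20)
  imp <- permutation_importance(fit, n_repeats = 2, seed = 4)
  expect_true(all(abs(imp$importance) < 1e-20))
  expect_true(all(is.na(imp$sign))) # no feature varies against a constant y
})

test_that("cross-validated forests are deterministic under a seed", {
  d <- preset_design("Lib4")
  set.seed(23)
  peps <- random_peptides(300, 12)
  x <- one_hot_encode(peps, d)$x
  y <- 2 * x[, "Q@-1"] + rnorm(300, sd = 0.3)
  f1 <- fit_rf_cv(x, y, k = 5, num_trees = 40, seed = 11)
  f2 <- fit_rf_cv(x, y, k = 5, num_trees = 40, seed = 11)
  expect_identical(f1$fold, f2$fold)
  expect_identical(f1$predictions, f2$predictions)
  expect_identical(f1$mse_fold, f2$mse_fold)
  i1 <- permutation_importance(f1, n_repeats = 3, seed = 12)
  i2 <- permutation_importance(f2, n_repeats = 3, seed = 12)
  expect_identical(i1$importance, i2$importance)
})

test_that("held-out error approaches the noise floor of a planted effect", {
  d <- preset_design("Lib4")
  set.seed(29)
  n <- 5000
  x <- one_hot_encode(random_peptides(n, 12), d)$x
  y <- 5 * x[, "Q@-1"] + rnorm(n, sd = 0.1)
  fit <- fit_rf_cv(x, y, k = 10, num_trees = 100, seed = 31)
  expect_lt(mean(fit$mse_fold), 0.015) # sigma^2 = 0.01, within 50%
  expect_gt(mean(fit$mse_fold), 0.005)
  expect_error(fit_rf_cv(x[1:5, ], y[1:5], k = 10), "fold")
})

test_that("permutation importance recovers planted effects with signs", {
  d <- preset_design("Lib4")
  set.seed(37)
  n <- 1500
  x <- one_hot_encode(random_peptides(n, 12), d)$x
  y_pos <- 5 * x[, "Q@-1"] + rnorm(n, sd = 0.3)
  fit <- fit_rf_cv(x, y_pos, k = 5, num_trees = 100, seed = 41)
  imp <- permutation_importance(fit, n_repeats = 2, seed = 42)
  top <- imp[imp$rank == 1, ]
  expect_identical(top$feature, "Q@-1")
  expect_identical(top$sign, "+")
  # unrelated pure-noise columns sit near zero
  noise_imp <- imp$importance[!imp$feature %in% "Q@-1"]
  expect_lt(max(abs(noise_imp)), 0.2 * top$importance)

  y_neg <- -3 * x[, "F@+2"] + rnorm(n, sd = 0.3)
  fit2 <- fit_rf_cv(x, y_neg, k = 5, num_trees = 100, seed = 43)
  imp2 <- permutation_importance(fit2, n_repeats = 2, seed = 44)
  top2 <- imp2[imp2$rank == 1, ]
  expect_identical(top2$feature, "F@+2")
  expect_identical(top2$sign, "-")
})

test_that("hyperparameter search returns sampled candidates monotonically", {
  d <- preset_design("Lib4")
  set.seed(47)
  x <- one_hot_encode(random_peptides(400, 12), d)$x
  y <- 3 * x[, "Q@-1"] + rnorm(400, sd = 0.5)
  one <- hypertune_rf(x, y, n_iter = 1, k = 3, num_trees = 20, seed = 7)
  expect_identical(nrow(one$results), 1L)
  expect_identical(one$best$cv_mse, one$results$cv_mse[1])

  single_grid <- list(mtry = 10L, min_node_size = 5L, max_depth = 4L)
  fixed <- hypertune_rf(x, y,
    n_iter = 3, k = 3, num_trees = 20,
    grid = single_grid, seed = 7
  )
  expect_true(all(fixed$results$mtry == 10L))
  expect_true(all(fixed$results$max_depth == 4L))

  small <- hypertune_rf(x, y, n_iter = 2, k = 3, num_trees = 20, seed = 9)
  large <- hypertune_rf(x, y, n_iter = 5, k = 3, num_trees = 20, seed = 9)
  expect_identical(
    small$results[, c("mtry", "min_node_size", "max_depth")],
    large$results[1:2, c("mtry", "min_node_size", "max_depth")]
  )
  expect_lte(large$best$cv_mse, small$best$cv_mse)
})

test_that("Welch test matches its textbook formula and conventions", {
  a <- c(1, 2, 3, 4, 5, 6)
  b <- c(2, 4, 6, 8, 10, 12)
  got <- welch_t(a, b)
  # independent evaluation of the Welch statistic and df
  va <- var(a) / 6
  vb <- var(b) / 6
  t_ref <- (mean(a) - mean(b)) / sqrt(va + vb)
  df_ref <- (va + vb)^2 / (va^2 / 5 + vb^2 / 5)
  p_ref <- 2 * pt(-abs(t_ref), df_ref)
  expect_equal(got$statistic, t_ref, tolerance = 1e-12)
  expect_equal(got$df, df_ref, tolerance = 1e-12)
  expect_equal(got$p_value, p_ref, tolerance = 1e-12)

  same <- welch_t(c(1, 1, 1), c(1, 1, 1))
  expect_identical(same$statistic, 0)
  expect_identical(same$p_value, 1)

  set.seed(53)
  sep <- welch_t(rnorm(5, 0, 1e-6), 1 + rnorm(5, 0, 1e-6))
  expect_lt(sep$p_value, 1e-6)
})

test_that("hydrophobic-count groups and tests behave as planted", {
  d <- preset_design("Lib4")
  hydro <- pepselect:::HYDROPHOBIC_AA
  polar_only <- setdiff(pepselect:::AA_ALPHABET, hydro)
  set.seed(59)
  # group 0: no hydrophobic residues at randomized sites; group 2: two
  mk <- function(n, r1, r3) {
    paste0(
      sample(r1, n, TRUE), "Q", sample(r3, n, TRUE),
      sample(polar_only, n, TRUE), sample(polar_only, n, TRUE),
      "DPWMLDH"
    )
  }
  p0 <- mk(500, polar_only, polar_only)
  p2 <- mk(500, c("V", "L"), c("I", "F"))
  et <- tibble::tibble(
    peptide = c(p0, p2),
    ef = c(rnorm(500, 1, 0.1), rnorm(500, 2, 0.1))
  )
  gc <- hydrophobic_count_analysis(et, d)
  expect_identical(gc$groups$n_hydrophobic, c(0, 2))
  expect_identical(gc$groups$n, c(500L, 500L))
  expect_true(all(gc$tests$significant))
  expect_lt(gc$tests$p_value[1], 0.01)

  solo <- hydrophobic_count_analysis(et[1:400, ], d)
  expect_identical(nrow(solo$tests), 0L) # single group: nothing to test
})

test_that("polarity splits are tested per position and skip degenerate ones", {
  d <- preset_design("Lib4")
  polar <- pepselect:::POLAR_AA
  nonpolar <- setdiff(pepselect:::AA_ALPHABET, polar)
  set.seed(61)
  n <- 600
  r2 <- sample(c("S", "G"), n, TRUE) # polar S vs nonpolar G at +2
  peps <- paste0(
    sample(nonpolar, n, TRUE), "Q", sample(nonpolar, n, TRUE), r2,
    "V", "DPWMLDH"
  )
  ef <- 1 + 0.5 * (r2 == "S") + rnorm(n, sd = 0.1)
  pol <- polarity_by_position(
    tibble::tibble(peptide = peps, ef = ef), d
  )
  row2 <- pol$tests[pol$tests$rel_pos == "+2", ]
  expect_false(row2$skipped)
  expect_true(row2$significant)
  expect_gt(row2$median_polar, row2$median_nonpolar)
  # +3 carries a single residue: degenerate split, skipped with a notice
  expect_message(
    pol2 <- polarity_by_position(
      tibble::tibble(peptide = peps, ef = ef), d
    ),
    "skipped"
  )
  expect_true(pol2$tests$skipped[pol2$tests$rel_pos == "+3"])
})
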