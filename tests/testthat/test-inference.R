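# Inference: difference curves, AUC, permutation machinery.

test_that("group difference curve: symmetry, shift and hand arithmetic", {
  x <- matrix(rnorm(20 * 5), 20, 5)
  lab <- rep(c(TRUE, FALSE), each = 10)
  expect_equal(group_difference_curve(rbind(x, x),
                                      c(lab, !lab))[1:5],
               rep(0, 5), tolerance = 1e-12)
  shifted <- x
  shifted[lab, ] <- shifted[lab, ] + 0.1
  d0 <- group_difference_curve(x, lab)
  expect_equal(group_difference_curve(shifted, lab), d0 + 0.1,
               tolerance = 1e-12)
  toy <- matrix(c(1, 2, 6, 3, 5, 10), 3, 2)   # subjects x 2 densities
  expect_equal(group_difference_curve(rbind(toy, toy), rep(c(TRUE, FALSE), each = 3)),
               c(0, 0))
  hand <- matrix(c(1, 3, 2, 8), 4, 1)
  expect_equal(group_difference_curve(hand, c(TRUE, TRUE, FALSE, FALSE)),
               mean(c(1, 3)) - mean(c(2, 8)))
  expect_error(group_difference_curve(hand, c(TRUE, TRUE, TRUE, TRUE)),
               "2 subjects")
})

test_that("slope difference matches closed-form OLS on toy data", {
  neuro <- c(1, 2, 3, 4, 10, 20, 30, 40)
  y <- c(2, 4, 6, 8, 5, 4, 3, 2)           # slopes: 2 and -0.1
  lab <- rep(c(TRUE, FALSE), each = 4)
  d <- slope_difference_curve(matrix(y, 8, 1), neuro, lab)
  expect_equal(d, 2 - (-0.1), tolerance = 1e-12)
  # identical generating slope -> near-zero difference
  set.seed(51)
  x <- rnorm(60, 0, 10)
  yy <- 0.3 * x + rnorm(60, 0, 0.5)
  lab2 <- rep(c(TRUE, FALSE), 30)
  d2 <- slope_difference_curve(matrix(yy, 60, 1), x, lab2)
  expect_lt(abs(d2), 3 * 0.5 / (10 * sqrt(15)))  # ~3 SE of a slope diff
  expect_error(slope_difference_curve(matrix(yy, 60, 1), rep(1, 60), lab2),
               "variance")
})

test_that("AUC: rectangle, exact-linear and Riemann oracle; linearity", {
  dens <- seq(0.01, 0.30, by = 0.01)
  expect_equal(auc_curve(rep(2, 30), dens), 0.29 * 2, tolerance = 1e-12)
  lin <- 3 * dens + 1
  expect_equal(auc_curve(lin, dens),
               3 / 2 * (0.30^2 - 0.01^2) + 0.29, tolerance = 1e-12)
  set.seed(52)
  f <- rnorm(30)
  # fine-grid Riemann oracle on the linear interpolant
  grid <- seq(0.01, 0.30, length.out = 200001)
  fi <- approx(dens, f, xout = grid)$y
  expect_equal(auc_curve(f, dens), mean(fi[-1] + fi[-length(fi)]) / 2 * 0.29,
               tolerance = 1e-6)
  g <- rnorm(30)
  expect_equal(auc_curve(2 * f + 3 * g, dens),
               2 * auc_curve(f, dens) + 3 * auc_curve(g, dens),
               tolerance = 1e-12)
  expect_error(auc_curve(f[1:5], dens), "length")
})

test_that("permutation test: reproducibility, symmetry, extreme rank", {
  set.seed(53)
  x <- matrix(rnorm(30 * 10), 30, 10)
  lab <- rep(c(TRUE, FALSE), 15)
  dens <- seq(0.03, 0.30, by = 0.03)
  p1 <- permutation_test(x, lab, dens, n_perm = 200, seed = 9)
  p2 <- permutation_test(x, lab, dens, n_perm = 200, seed = 9)
  expect_identical(p1$null_aucs, p2$null_aucs)
  expect_identical(p1$p_two_tailed, p2$p_two_tailed)
  # two-tailedness: relabeling risk/non-risk flips the sign, not the p
  p3 <- permutation_test(x, !lab, dens, n_perm = 200, seed = 9)
  expect_equal(p3$observed_auc, -p1$observed_auc, tolerance = 1e-12)
  expect_equal(p3$p_two_tailed, p1$p_two_tailed)
  # an effect larger than any achievable under permutation -> p = 1/(n+1)
  y <- matrix(0, 20, 4)
  y[1:10, ] <- 100
  py <- permutation_test(y, rep(c(TRUE, FALSE), each = 10),
                         c(0.1, 0.2, 0.3, 0.4), n_perm = 99, seed = 2)
  expect_equal(py$p_two_tailed, 1 / 100)
  expect_error(permutation_test(x, lab, dens, n_perm = 0), "n_perm")
})

test_that("null p-values are valid (not stochastically smaller than uniform)", {
  set.seed(54)
  dens <- seq(0.05, 0.30, by = 0.05)
  pvals <- replicate(300, {
    x <- matrix(rnorm(24 * 6), 24, 6)
    lab <- sample(rep(c(TRUE, FALSE), 12))
    permutation_test(x, lab, dens, n_perm = 99, seed = sample.int(1e6, 1)
                     )$p_two_tailed
  })
  for (a in c(0.05, 0.1, 0.25)) {
    # binomial bound: empirical rate at alpha should not exceed alpha by
    # more than ~3 sd
    expect_lte(mean(pvals <= a), a + 3 * sqrt(a * (1 - a) / 300))
  }
})

test_that("infer_cohort runs both statistics per cell and honors filters", {
  set.seed(55)
  ids <- sprintf("s%02d", 1:20)
  dens <- c(0.1, 0.2, 0.3)
  meas <- expand.grid(subject_id = ids, density = dens,
                      stringsAsFactors = FALSE)
  meas$measure <- "participation_module"
  meas$module <- 2L
  meas$variant <- "weighted"
  meas$value <- rnorm(nrow(meas))
  groups <- data.frame(subject_id = ids,
                       httlpr_group = rep(c("S-carrier", "L-homozygote"), 10))
  pheno <- data.frame(subject_id = ids, neuroticism = rnorm(20, 135, 19))
  res <- infer_cohort(meas, groups, "httlpr_group", "S-carrier",
                      neuroticism = pheno, n_perm = 50, seed = 3)
  expect_equal(sort(unique(res$statistic)),
               c("mean_difference", "slope_difference"))
  expect_equal(nrow(res), 2)
  expect_true(all(res$p_two_tailed > 0 & res$p_two_tailed <= 1))
})

test_that("slope-difference rows report within-group slopes and correlations", {
  set.seed(56)
  ids <- sprintf("s%02d", 1:24)
  dens <- c(0.1, 0.2)
  meas <- expand.grid(subject_id = ids, density = dens,
                      stringsAsFactors = FALSE)
  meas$measure <- "global_efficiency"; meas$module <- NA_integer_
  meas$variant <- "weighted"
  neuro <- rnorm(24, 135, 19)
  slope_by_subj <- ifelse(seq_len(24) %% 2 == 1, 0.02, 0)
  meas$value <- 0.5 + slope_by_subj[match(meas$subject_id, ids)] *
    (neuro[match(meas$subject_id, ids)] - 135) + rnorm(nrow(meas), 0, 0.01)
  groups <- data.frame(subject_id = ids,
                       comt_group = rep(c("risk", "non-risk"), 12))
  pheno <- data.frame(subject_id = ids, neuroticism = neuro)
  res <- infer_cohort(meas, groups, "comt_group", "risk",
                      neuroticism = pheno, n_perm = 50, seed = 4,
                      statistics = "slope_difference")
  expect_true(all(is.finite(c(res$slope_risk, res$slope_nonrisk,
                              res$cor_risk, res$cor_nonrisk))))
  expect_gt(res$slope_risk, res$slope_nonrisk)
  expect_gt(res$cor_risk, res$cor_nonrisk)
})
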