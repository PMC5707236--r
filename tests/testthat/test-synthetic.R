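# Synthetic-cohort generator: distributional targets, ground-truth recovery,
# file round-trips.

test_that("genotype draws hit the configured frequencies and stay in HWE", {
  cfg <- sim_config(n_subjects = 10000)
  g <- simulate_genotypes(cfg, seed = 61)
  rep_tab <- genotype_report(g)
  # report rows: httlpr (L), rs4680 (Met), rs165599 (A)
  expect_equal(rep_tab$freq_a,
               c(1 - cfg$freq_httlpr_s, cfg$freq_rs4680_met,
                 cfg$freq_rs165599_a), tolerance = 0.03)
  # HWE holds by construction at large n for most seeds
  hwe_ok <- vapply(1:20, function(s) {
    rt <- genotype_report(simulate_genotypes(cfg, seed = s))
    all(rt$hwe_p > 0.001)
  }, logical(1))
  expect_gte(mean(hwe_ok), 0.9)
  # degenerate frequency
  g1 <- simulate_genotypes(sim_config(n_subjects = 50, freq_httlpr_s = 1),
                           seed = 62)
  expect_true(all(g1$httlpr == "S/S"))
})

test_that("phenotypes are normal with the target moments and reproducible", {
  cfg <- sim_config(n_subjects = 10000)
  ph <- simulate_phenotypes(cfg, seed = 63)
  expect_equal(mean(ph$neuroticism), 135.5, tolerance = 1.0)
  expect_equal(sd(ph$neuroticism), 18.9, tolerance = 1.0)
  expect_identical(ph, simulate_phenotypes(cfg, seed = 63))
})

test_that("neuroticism is independent of genotype group (null calibration)", {
  cfg <- sim_config(n_subjects = 120)
  hits <- vapply(1:100, function(s) {
    co_g <- simulate_genotypes(cfg, seed = s)
    co_p <- simulate_phenotypes(cfg, seed = s + 5000)
    gr <- assign_risk_groups(co_g)
    ok <- gr$httlpr_group == "S-carrier"
    t.test(co_p$neuroticism[ok], co_p$neuroticism[!ok])$p.value < 0.05
  }, logical(1))
  expect_lt(mean(hits), 0.12)
})

test_that("empirical correlations converge to the target block covariance", {
  cfg <- sim_config(n_subjects = 1, n_rois = 30, n_volumes = 10000,
                    n_modules = 6, effect_participation = 0,
                    effect_slope = 0, noise_sd = 0, global_amp = 0,
                    motion_amp = 0)
  cohort <- simulate_cohort(cfg, seed = 64)
  emp <- cor(cohort$timeseries[[1]])
  labels <- cohort$ground_truth$module_labels
  target <- matrix(cfg$between_module_r, 30, 30)
  for (m in 1:6) target[labels == m, labels == m] <- cfg$within_module_r
  diag(target) <- 1
  expect_lt(norm(emp - target, "F") / norm(target, "F"), 0.1)
})

test_that("planted effects move covariance in the planted direction", {
  cfg <- sim_config(n_subjects = 2, n_rois = 36, n_volumes = 4000,
                    effect_participation = 0.06, effect_slope = 0.3,
                    noise_sd = 0, global_amp = 0, motion_amp = 0)
  labels <- planted_labels(cfg)
  # S-carrier vs not, at fixed neuroticism
  R_ns <- neurogenet:::subject_covariance(cfg, labels, FALSE, FALSE, 0)
  R_s  <- neurogenet:::subject_covariance(cfg, labels, TRUE, FALSE, 0)
  dm <- labels %in% cfg$participation_modules
  oth <- !dm
  expect_equal(mean(R_ns[dm, oth] - R_s[dm, oth]), 0.06, tolerance = 1e-12)
  expect_equal(R_ns[!dm, !dm], R_s[!dm, !dm])
  # COMT risk: higher neuroticism lowers within-module correlation
  R_lo <- neurogenet:::subject_covariance(cfg, labels, FALSE, TRUE, -1)
  R_hi <- neurogenet:::subject_covariance(cfg, labels, FALSE, TRUE, +1)
  for (m in cfg$slope_modules) {
    sm <- labels == m
    in_hi <- R_hi[sm, sm][upper.tri(R_hi[sm, sm])]
    in_lo <- R_lo[sm, sm][upper.tri(R_lo[sm, sm])]
    expect_true(all(in_hi < in_lo))
  }
})

test_that("cohort files round-trip through the package readers", {
  cfg <- sim_config(n_subjects = 3, n_rois = 12, n_volumes = 40)
  cohort <- simulate_cohort(cfg, seed = 66)
  dir <- tempfile("cohort")
  write_cohort(cohort, dir)
  geno <- read_genotype_table(file.path(dir, "genotypes.tsv"))
  expect_equal(geno, cohort$genotypes)
  ph <- read_phenotype_tsv(file.path(dir, "phenotypes.tsv"))
  expect_equal(ph$neuroticism, cohort$phenotypes$neuroticism,
               tolerance = 1e-12)
  co <- read_coords_tsv(file.path(dir, "coords.tsv"))
  expect_equal(co$x, cohort$coords$x, tolerance = 1e-12)
  ts1 <- read_timeseries_tsv(file.path(dir, "ts_sub001.tsv"))
  expect_equal(ts1, cohort$timeseries[[1]], tolerance = 1e-10,
               ignore_attr = TRUE)
  unlink(dir, recursive = TRUE)
})

test_that("simulated coordinates exercise the 20 mm exclusion rule", {
  cfg <- sim_config(n_subjects = 1, n_rois = 60, n_volumes = 20)
  cohort <- simulate_cohort(cfg, seed = 67)
  d <- as.matrix(dist(cohort$coords[, c("x", "y", "z")]))
  expect_gt(sum(d < 20 & upper.tri(d)), 0)
})

test_that("cohort generation is deterministic given the seed", {
  cfg <- sim_config(n_subjects = 2, n_rois = 10, n_volumes = 30)
  c1 <- simulate_cohort(cfg, seed = 68)
  c2 <- simulate_cohort(cfg, seed = 68)
  expect_identical(c1$timeseries, c2$timeseries)
  expect_identical(c1$genotypes, c2$genotypes)
})

test_that("square matrix TSVs round-trip", {
  W <- rand_graph(7, 0.5, TRUE, seed = 69)
  rownames(W) <- colnames(W) <- sprintf("roi%03d", 1:7)
  path <- tempfile(fileext = ".tsv")
  write_matrix_tsv(W, path)
  W2 <- read_matrix_tsv(path)
  expect_equal(W2, W, tolerance = 1e-12)
  unlink(path)
})
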