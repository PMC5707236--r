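# Genotype processing: parsing dialects, allele frequencies, HWE, EM
# phasing, risk groups.

test_that("allele frequencies match direct count arithmetic and sum to 1", {
  fr <- allele_frequencies(31, 57, 32)
  expect_equal(fr[["freq_a"]], (2 * 31 + 57) / 240)
  expect_identical(sum(fr), 1)
  expect_equal(allele_frequencies(10, 0, 0), c(freq_a = 1, freq_b = 0))
  expect_equal(allele_frequencies(56, 51, 11)[["freq_a"]], 163 / 236)
  expect_error(allele_frequencies(0, 0, 0), "count")
})

test_that("HWE chi-square reproduces the cohort table p-values at 2 dp", {
  expect_equal(round_half_up(hwe_chisq_test(31, 57, 32)$p_value), 0.58)
  expect_equal(round_half_up(hwe_chisq_test(34, 57, 28)$p_value), 0.67)
  expect_equal(round_half_up(hwe_chisq_test(56, 51, 11)$p_value), 0.90)
  perfect <- hwe_chisq_test(25, 50, 25)
  expect_equal(perfect$statistic, 0)
  expect_equal(perfect$p_value, 1)
  expect_error(hwe_chisq_test(10, 0, 0), "monomorphic")
})

test_that("HWE statistic equals brute-force expected-count computation", {
  set.seed(42)
  for (rep in 1:25) {
    cnt <- as.vector(stats::rmultinom(1, sample(50:400, 1),
                                      prob = runif(3, 0.05, 1)))
    if (cnt[1] + cnt[2] == 0 || cnt[3] + cnt[2] == 0) next
    n <- sum(cnt)
    p <- (2 * cnt[1] + cnt[2]) / (2 * n)
    expd <- c(n * p^2, 2 * n * p * (1 - p), n * (1 - p)^2)
    expect_equal(hwe_chisq_test(cnt[1], cnt[2], cnt[3])$statistic,
                 sum((cnt - expd)^2 / expd), tolerance = 1e-12)
  }
})

test_that("genotype parsing accepts unordered, case-varied and missing", {
  df <- data.frame(subject_id = c("a", "b", "c", "d"),
                   httlpr = c("L/S", "s/s", "", "L/L"),
                   rs4680 = c("Met/Val", "val/val", "A/G", "NA"),
                   rs165599 = c("G/A", "a/a", "g/g", "A/G"))
  g <- as_genotype_table(df)
  expect_equal(g$httlpr, c("S/L", "S/S", NA, "L/L"))
  expect_equal(g$rs4680, c("Val/Met", "Val/Val", "Val/Met", NA))
  expect_equal(g$rs165599, c("A/G", "A/A", "G/G", "A/G"))
  expect_error(as_genotype_table(transform(df, httlpr = "X/Y")),
               "unrecognized")
  expect_error(as_genotype_table(rbind(df, df)), "duplicate")
})

test_that("genotype_report reproduces the published frequencies at 2 dp", {
  # cohort assembled from the printed genotype counts
  geno <- data.frame(
    subject_id = sprintf("s%03d", 1:120),
    httlpr = rep(c("L/L", "S/L", "S/S"), c(31, 57, 32)),
    rs4680 = c(rep(c("Met/Met", "Val/Met", "Val/Val"), c(34, 57, 28)), "NA"),
    rs165599 = c(rep(c("A/A", "A/G", "G/G"), c(56, 51, 11)), "NA", "NA"))
  rep_tab <- genotype_report(as_genotype_table(geno))
  expect_equal(rep_tab$freq_a_report, c(0.50, 0.53, 0.69))
  expect_equal(rep_tab$hwe_p_report, c(0.58, 0.67, 0.90))
})

test_that("risk groups follow the carrier definitions exactly and partition", {
  df <- data.frame(
    subject_id = paste0("s", 1:6),
    httlpr = c("S/L", "S/S", "L/L", NA, "L/L", "S/L"),
    rs4680 = c("Val/Val", "Val/Met", "Met/Met", "Val/Met", NA, NA),
    rs165599 = c("G/G", "A/A", "A/G", "A/G", "A/A", "A/G"))
  gr <- assign_risk_groups(as_genotype_table(df))
  expect_equal(gr$httlpr_group,
               c("S-carrier", "S-carrier", "L-homozygote", NA,
                 "L-homozygote", "S-carrier"))
  # Val/Val -> risk regardless of rs165599; A/A -> risk regardless of rs4680;
  # non-risk needs both markers in the non-risk sets; deciding-marker NA -> NA
  expect_equal(gr$comt_group,
               c("risk", "risk", "non-risk", "non-risk", "risk", NA))
  # exhaustive and exclusive over non-missing subjects
  full <- expand.grid(rs4680 = c("Met/Met", "Val/Met", "Val/Val"),
                      rs165599 = c("A/A", "A/G", "G/G"),
                      stringsAsFactors = FALSE)
  full$subject_id <- paste0("x", seq_len(nrow(full)))
  full$httlpr <- "L/L"
  gr2 <- assign_risk_groups(as_genotype_table(full))
  expect_false(anyNA(gr2$comt_group))
  expect_equal(sum(gr2$comt_group == "risk"), 5)  # Val/Val row or A/A column
})

test_that("EM phasing: unambiguous cohorts are counted directly", {
  df <- data.frame(subject_id = paste0("s", 1:10),
                   httlpr = "L/L",
                   rs4680 = "Met/Met", rs165599 = "A/A")
  ph <- em_phase_two_markers(as_genotype_table(df))
  expect_equal(unname(ph$haplotype_freqs["Met-A"]), 1)
  expect_true(all(ph$per_subject$assigned))
  expect_true(all(ph$per_subject$posterior == 1))
})

test_that("EM phasing: all-double-heterozygote cohort stays symmetric, none assigned", {
  df <- data.frame(subject_id = paste0("s", 1:20),
                   httlpr = "L/L",
                   rs4680 = "Val/Met", rs165599 = "A/G")
  ph <- em_phase_two_markers(as_genotype_table(df))
  expect_equal(max(abs(ph$haplotype_freqs - 0.25)), 0, tolerance = 1e-9)
  expect_true(all(ph$per_subject$posterior == 0.5))
  expect_false(any(ph$per_subject$assigned))
  expect_true(all(is.na(ph$per_subject$hap1)))
})

test_that("EM log-likelihood is non-decreasing and matches a brute-force maximizer", {
  df <- data.frame(
    subject_id = paste0("s", 1:100), httlpr = "L/L",
    rs4680 = rep(c("Val/Val", "Met/Met", "Val/Met"), c(40, 40, 20)),
    rs165599 = rep(c("G/G", "A/A", "A/G"), c(40, 40, 20)))
  ph <- em_phase_two_markers(as_genotype_table(df), tol = 1e-12)
  expect_true(all(diff(ph$log_likelihood) >= -1e-9))
  expect_equal(sum(ph$haplotype_freqs), 1, tolerance = 1e-9)

  # independent maximizer: coarse simplex grid + Nelder-Mead polish on a
  # softmax parameterization of the multinomial likelihood
  nll <- function(theta) {
    f <- exp(c(theta, 0)); f <- f / sum(f)
    # class probabilities under random mating
    pM <- f[1] + f[2]; hap <- f  # Met-A, Met-G, Val-A, Val-G
    prob_pair <- function(i, j) (2 - (i == j)) * hap[i] * hap[j]
    p_vvgg <- prob_pair(4, 4)
    p_mmaa <- prob_pair(1, 1)
    p_het  <- prob_pair(1, 4) + prob_pair(2, 3)
    -(40 * log(p_vvgg) + 40 * log(p_mmaa) + 20 * log(p_het))
  }
  best <- NULL
  for (s in 1:20) {
    set.seed(s)
    o <- optim(rnorm(3), nll, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
    if (is.null(best) || o$value < best$value) best <- o
  }
  f_opt <- exp(c(best$par, 0)); f_opt <- f_opt / sum(f_opt)
  expect_equal(unname(ph$haplotype_freqs), f_opt, tolerance = 1e-4)
})

test_that("EM phasing assigns by the strict 0.80 rule", {
  # skewed cohort: double hets get posterior ~ f(MetA)f(ValG)x2 dominant
  df <- data.frame(
    subject_id = paste0("s", 1:60), httlpr = "L/L",
    rs4680 = rep(c("Met/Met", "Val/Val", "Val/Met"), c(25, 25, 10)),
    rs165599 = rep(c("A/A", "G/G", "A/G"), c(25, 25, 10)))
  ph <- em_phase_two_markers(as_genotype_table(df))
  het <- ph$per_subject$posterior[51:60]
  expect_true(all(het > 0.80))
  expect_true(all(ph$per_subject$assigned))
  expect_error(em_phase_two_markers(as_genotype_table(
    data.frame(subject_id = "a", httlpr = "S/S",
               rs4680 = NA, rs165599 = "A/A"))), "genotyped")
})
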