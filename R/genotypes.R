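# Genotype processing: parsing, Hardy-Weinberg tests, two-marker EM haplotype
# phasing, and genetic risk-group assignment.
#
# Marker conventions used throughout:
#   5-HTTLPR : alleles S / L (the low-expressing Lg variant is collapsed into
#              S upstream of this package, so only S and L appear here).
#   rs4680   : alleles Met / Val (A = Met, G = Val; Val158Met of COMT).
#   rs165599 : alleles A / G.

.httlpr_levels  <- c("S/S", "S/L", "L/L")
.rs4680_levels  <- c("Met/Met", "Val/Met", "Val/Val")
.rs165599_levels <- c("A/A", "A/G", "G/G")

# Canonicalize one genotype string against a reference pair of allele names.
# Unordered ("S/L" == "L/S"), case-insensitive; "", "NA" -> NA.
canonical_genotype <- function(x, alleles) {
  x <- trimws(as.character(x))
  x[x == "" | toupper(x) == "NA"] <- NA
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x)
  if (!any(ok)) return(out)
  parts <- strsplit(x[ok], "/", fixed = TRUE)
  low <- tolower(alleles)
  out[ok] <- vapply(parts, function(p) {
    if (length(p) != 2L) return(NA_character_)
    idx <- match(tolower(trimws(p)), low)
    if (anyNA(idx)) return(NA_character_)
    idx <- sort(idx)
    paste(alleles[idx], collapse = "/")
  }, character(1))
  bad <- ok & is.na(out) & !is.na(x)
  if (any(bad))
    stop("unrecognized genotype value(s): ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  out
}

#' Read and validate a genotype table
#'
#' Expects a tab-separated file with header columns `subject_id`, `httlpr`,
#' `rs4680`, `rs165599`. Genotypes may be written in either allele order and
#' any case (`"S/L"` equals `"l/s"`); empty strings and `"NA"` are missing.
#' rs4680 accepts either amino-acid (`Met/Val`) or nucleotide (`A/G`, with
#' A = Met, G = Val) naming.
#'
#' @param path path to a TSV file.
#' @return a data.frame with canonical genotype strings and unique subject ids.
#' @export
read_genotype_table <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = "character")
  as_genotype_table(df)
}

#' Validate an in-memory genotype table
#'
#' @param df data.frame with columns `subject_id`, `httlpr`, `rs4680`,
#'   `rs165599`.
#' @return the validated, canonicalized data.frame.
#' @export
as_genotype_table <- function(df) {
  need <- c("subject_id", "httlpr", "rs4680", "rs165599")
  if (!all(need %in% names(df)))
    stop("genotype table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id in genotype table", call. = FALSE)
  df$httlpr <- canonical_genotype(df$httlpr, c("S", "L"))
  rs4680 <- df$rs4680
  # accept nucleotide dialect for rs4680 (A = Met, G = Val)
  rs4680 <- gsub("\\bA\\b", "Met", rs4680, ignore.case = FALSE)
  rs4680 <- gsub("\\bG\\b", "Val", rs4680, ignore.case = FALSE)
  # heterozygote written Val/Met by field convention
  df$rs4680 <- canonical_genotype(rs4680, c("Val", "Met"))
  df$rs165599 <- canonical_genotype(df$rs165599, c("A", "G"))
  df[, need]
}

#' Genotype counts for one biallelic marker
#'
#' @param genotypes character vector of canonical genotype strings.
#' @param levels the three genotype categories, first-allele homozygote first.
#' @return named integer vector `c(n_aa, n_ab, n_bb)`.
#' @export
biallelic_counts <- function(genotypes, levels) {
  genotypes <- genotypes[!is.na(genotypes)]
  bad <- setdiff(unique(genotypes), levels)
  if (length(bad))
    stop("genotypes outside category set: ", paste(bad, collapse = ", "),
         call. = FALSE)
  n <- as.integer(table(factor(genotypes, levels = levels)))
  names(n) <- c("n_aa", "n_ab", "n_bb")
  n
}

#' Allele frequencies from genotype counts
#'
#' For counts (n_aa, n_ab, n_bb) of a biallelic marker, the first-allele
#' frequency is (2 n_aa + n_ab) / (2 n); the second is its complement, so the
#' two always sum to exactly 1.
#'
#' @param n_aa,n_ab,n_bb nonnegative genotype counts.
#' @return named numeric vector `c(freq_a, freq_b)`.
#' @examples
#' allele_frequencies(31, 57, 32)  # L ~ 0.50, S ~ 0.50
#' @export
allele_frequencies <- function(n_aa, n_ab, n_bb) {
  n_aa <- unname(n_aa); n_ab <- unname(n_ab); n_bb <- unname(n_bb)
  counts <- c(n_aa, n_ab, n_bb)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers", call. = FALSE)
  n <- sum(counts)
  if (n < 1) stop("total genotype count must be >= 1", call. = FALSE)
  fa <- (2 * n_aa + n_ab) / (2 * n)
  c(freq_a = fa, freq_b = 1 - fa)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' Compares observed genotype counts with the counts expected under random
#' mating at the observed allele frequencies (n p^2, 2 n p q, n q^2), using a
#' 1-df chi-square statistic without continuity correction.
#'
#' @inheritParams allele_frequencies
#' @return list with `statistic`, `p_value`, `expected` (length-3 vector).
#' @examples
#' hwe_chisq_test(31, 57, 32)$p_value  # ~ 0.58
#' @export
hwe_chisq_test <- function(n_aa, n_ab, n_bb) {
  fr <- allele_frequencies(n_aa, n_ab, n_bb)
  if (fr[1] == 0 || fr[1] == 1)
    stop("monomorphic sample: HWE test undefined", call. = FALSE)
  n <- n_aa + n_ab + n_bb
  p <- fr[["freq_a"]]
  q <- 1 - p
  expected <- c(n * p^2, 2 * n * p * q, n * q^2)
  observed <- c(n_aa, n_ab, n_bb)
  stat <- sum((observed - expected)^2 / expected)
  list(statistic = stat,
       p_value = pchisq(stat, df = 1, lower.tail = FALSE),
       expected = expected)
}

#' Cohort genotype report
#'
#' Per-marker genotype counts, allele frequencies and HWE p-values for the
#' three markers of a genotype table, with report values rounded half away
#' from zero to 2 decimals alongside the raw numbers.
#'
#' @param geno a validated genotype table (see [as_genotype_table()]).
#' @return data.frame with one row per marker.
#' @export
genotype_report <- function(geno) {
  markers <- list(
    httlpr = list(col = "httlpr", levels = .httlpr_levels,
                  allele_a = "L"),  # reported as L frequency, as in HapMap
    rs4680 = list(col = "rs4680", levels = .rs4680_levels, allele_a = "Met"),
    rs165599 = list(col = "rs165599", levels = .rs165599_levels,
                    allele_a = "A"))
  rows <- lapply(names(markers), function(m) {
    sp <- markers[[m]]
    lv <- sp$levels
    # httlpr counts come back as (S/S, S/L, L/L); report L-first frequency
    cnt <- biallelic_counts(geno[[sp$col]], lv)
    if (m == "httlpr") cnt <- rev(cnt)  # L/L, S/L, S/S so freq_a is L
    names(cnt) <- c("n_aa", "n_ab", "n_bb")
    fr <- allele_frequencies(cnt[1], cnt[2], cnt[3])
    hw <- hwe_chisq_test(cnt[1], cnt[2], cnt[3])
    data.frame(marker = m, allele_a = sp$allele_a,
               n_aa = cnt[[1]], n_ab = cnt[[2]], n_bb = cnt[[3]],
               freq_a = fr[["freq_a"]],
               freq_a_report = round_half_up(fr[["freq_a"]], 2),
               hwe_chisq = hw$statistic, hwe_p = hw$p_value,
               hwe_p_report = round_half_up(hw$p_value, 2),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# ---- two-marker EM haplotype phasing ---------------------------------------

# rs4680 alleles indexed 1 = Met, 2 = Val; rs165599 alleles 1 = A, 2 = G.
# Haplotypes enumerated as (rs4680 allele, rs165599 allele):
.hap_names <- c("Met-A", "Met-G", "Val-A", "Val-G")

# genotype -> ordered allele count of allele 2 (0, 1, 2) per marker
.dose2 <- function(g, levels) match(g, levels) - 1L

#' EM phasing of two-marker COMT haplotypes
#'
#' Estimates the four rs4680-rs165599 haplotype frequencies by
#' expectation-maximization on the multinomial likelihood under random mating
#' (Hardy-Weinberg at the haplotype level). Only double heterozygotes are
#' phase-ambiguous with two markers. Each subject's compatible haplotype pairs
#' get posterior probabilities proportional to the product of the two
#' haplotype frequencies (doubled for heterozygous pairs); a pair is assigned
#' when its posterior strictly exceeds `assign_threshold`, otherwise the
#' assignment is missing.
#'
#' Initialization is the linkage-equilibrium product of allele frequencies,
#' so the estimator is deterministic. The symmetric stationary point reached
#' when every informative subject is a double heterozygote is left in place
#' (both phasings then tie at posterior 0.5 and nothing is assigned).
#'
#' @param geno validated genotype table.
#' @param max_iter maximum EM iterations.
#' @param tol convergence: max absolute frequency change per iteration.
#' @param assign_threshold posterior needed to assign a haplotype pair
#'   (strictly greater than; default 0.80).
#' @return list with `haplotype_freqs` (named, sums to 1), `per_subject`
#'   data.frame (`subject_id`, `hap1`, `hap2`, `posterior`, `assigned`),
#'   `log_likelihood` trace, `converged` flag, `n_used`.
#' @export
em_phase_two_markers <- function(geno, max_iter = 500, tol = 1e-8,
                                 assign_threshold = 0.80) {
  d1 <- .dose2(geno$rs4680, .rs4680_levels)    # count of Val
  d2 <- .dose2(geno$rs165599, .rs165599_levels) # count of G
  use <- !is.na(d1) & !is.na(d2)
  if (!any(use))
    stop("no subject has both COMT markers genotyped", call. = FALSE)
  # 9 genotype classes: (d1, d2) in {0,1,2}^2
  cls <- d1[use] * 3L + d2[use] + 1L
  ncls <- tabulate(cls, nbins = 9L)

  # haplotype composition per genotype class: list of compatible unordered
  # haplotype pairs (i, j) with multiplicity 2 - (i == j)
  pairs_for_class <- function(k) {
    d1k <- (k - 1L) %/% 3L; d2k <- (k - 1L) %% 3L
    # alleles carried at each marker: allele 2 count d
    split1 <- switch(d1k + 1L, list(c(1L, 1L)), list(c(1L, 2L)), list(c(2L, 2L)))
    split2 <- switch(d2k + 1L, list(c(1L, 1L)), list(c(1L, 2L)), list(c(2L, 2L)))
    a1 <- split1[[1]]; a2 <- split2[[1]]
    hap <- function(x, y) (x - 1L) * 2L + y  # (rs4680 allele, rs165599 allele)
    ps <- list(c(hap(a1[1], a2[1]), hap(a1[2], a2[2])))
    if (d1k == 1L && d2k == 1L)  # double het: second phasing
      ps <- c(ps, list(c(hap(a1[1], a2[2]), hap(a1[2], a2[1]))))
    lapply(ps, sort)
  }
  class_pairs <- lapply(1:9, pairs_for_class)

  # initialization at linkage equilibrium
  n_use <- sum(ncls)
  p_val <- sum(d1[use]) / (2 * n_use)
  p_g <- sum(d2[use]) / (2 * n_use)
  f <- c((1 - p_val) * (1 - p_g), (1 - p_val) * p_g,
         p_val * (1 - p_g), p_val * p_g)
  f <- pmax(f, 1e-12); f <- f / sum(f)

  pair_prob <- function(f, pr) {
    mult <- if (pr[1] == pr[2]) 1 else 2
    mult * f[pr[1]] * f[pr[2]]
  }
  loglik <- function(f) {
    lp <- vapply(1:9, function(k) {
      p <- sum(vapply(class_pairs[[k]], pair_prob, numeric(1), f = f))
      if (ncls[k] > 0 && p <= 0) return(-Inf)
      if (ncls[k] == 0) 0 else ncls[k] * log(p)
    }, numeric(1))
    sum(lp)
  }

  ll_trace <- loglik(f)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    hap_exp <- numeric(4)
    for (k in 1:9) {
      if (ncls[k] == 0) next
      prs <- class_pairs[[k]]
      w <- vapply(prs, pair_prob, numeric(1), f = f)
      tw <- sum(w)
      if (tw <= 0) next
      w <- w / tw
      for (j in seq_along(prs)) {
        hap_exp[prs[[j]][1]] <- hap_exp[prs[[j]][1]] + ncls[k] * w[j]
        hap_exp[prs[[j]][2]] <- hap_exp[prs[[j]][2]] + ncls[k] * w[j]
      }
    }
    f_new <- hap_exp / (2 * n_use)
    ll_new <- loglik(f_new)
    if (ll_new < ll_trace[length(ll_trace)] - 1e-9)
      stop("internal error: EM log-likelihood decreased", call. = FALSE)
    delta <- max(abs(f_new - f))
    f <- f_new
    ll_trace <- c(ll_trace, ll_new)
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("EM phasing did not converge within max_iter", call. = FALSE)
  names(f) <- .hap_names

  # per-subject posterior of the most probable compatible pair
  per <- data.frame(subject_id = geno$subject_id,
                    hap1 = NA_character_, hap2 = NA_character_,
                    posterior = NA_real_, assigned = FALSE,
                    stringsAsFactors = FALSE)
  idx_use <- which(use)
  for (r in seq_along(idx_use)) {
    i <- idx_use[r]
    prs <- class_pairs[[cls[r]]]
    w <- vapply(prs, pair_prob, numeric(1), f = f)
    tw <- sum(w)
    if (tw <= 0) next
    w <- w / tw
    j <- which.max(w)
    per$hap1[i] <- .hap_names[prs[[j]][1]]
    per$hap2[i] <- .hap_names[prs[[j]][2]]
    per$posterior[i] <- w[j]
    per$assigned[i] <- w[j] > assign_threshold
  }
  per$hap1[!per$assigned] <- NA_character_
  per$hap2[!per$assigned] <- NA_character_

  list(haplotype_freqs = f, per_subject = per,
       log_likelihood = ll_trace, converged = converged, n_used = n_use)
}

#' Assign genetic risk groups
#'
#' 5-HTTLPR: S-carriers (S/S or S/L) versus L-homozygotes. COMT: the risk
#' group carries rs4680 Val/Val and/or rs165599 A/A; the non-risk group
#' carries Met/Met or Val/Met at rs4680 together with G/G or A/G at rs165599.
#' A missing genotype at a marker that could still flip the decision yields a
#' missing group label.
#'
#' @param geno validated genotype table.
#' @return data.frame `subject_id`, `httlpr_group` (`"S-carrier"`,
#'   `"L-homozygote"` or NA), `comt_group` (`"risk"`, `"non-risk"` or NA).
#' @export
assign_risk_groups <- function(geno) {
  httlpr_group <- ifelse(is.na(geno$httlpr), NA_character_,
                         ifelse(geno$httlpr == "L/L", "L-homozygote",
                                "S-carrier"))
  risk4680 <- geno$rs4680 == "Val/Val"
  risk165599 <- geno$rs165599 == "A/A"
  comt <- ifelse(
    (!is.na(risk4680) & risk4680) | (!is.na(risk165599) & risk165599),
    "risk",
    ifelse(!is.na(risk4680) & !is.na(risk165599), "non-risk", NA_character_))
  data.frame(subject_id = geno$subject_id,
             httlpr_group = httlpr_group,
             comt_group = comt,
             stringsAsFactors = FALSE)
}
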