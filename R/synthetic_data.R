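# Synthetic-cohort generator: HWE genotype draws, normal neuroticism scores,
# block-covariance ROI time series with planted genotype effects, motion and
# nuisance components, and an MNI-like spatial layout. Ground truth is kept
# alongside the data so planted structure and effects are recoverable by the
# pipeline.

#' Simulation configuration
#'
#' Defaults reproduce the study conditions: 111 analyzed subjects, 259 ROIs,
#' 300 volumes at TR 2 s, six near-equal modules, allele frequencies
#' S = 0.50 (5-HTTLPR), Met = 0.53 (rs4680), A = 0.69 (rs165599),
#' neuroticism ~ Normal(135.5, 18.9). Planted effects: S-carriers have their
#' between-module coupling for the `participation_modules` reduced by
#' `effect_participation`; COMT-risk subjects have the within-module
#' correlation of the `slope_modules` reduced by
#' `effect_slope * (neuroticism - mean) / sd`.
#'
#' @param n_subjects,n_rois,n_volumes,tr_seconds,n_modules cohort geometry.
#' @param freq_httlpr_s,freq_rs4680_met,freq_rs165599_a allele frequencies.
#' @param neuro_mean,neuro_sd neuroticism distribution.
#' @param within_module_r,between_module_r block-correlation targets.
#' @param effect_participation between-module coupling reduction in
#'   S-carriers for the designated modules (correlation units).
#' @param effect_slope within-module correlation reduction per neuroticism
#'   SD in COMT-risk subjects for the designated modules.
#' @param participation_modules,slope_modules designated module indices.
#' @param noise_sd extra white observation noise SD (signal is unit SD).
#' @param global_amp,motion_amp amplitudes of the shared global and
#'   motion-coupled nuisance components added to the signal.
#' @param motion_sd,motion_spike_prob,motion_spike_mm random-walk step SD,
#'   per-volume spike probability and spike size of the motion traces.
#' @param ar1 optional AR(1) coefficient for temporal autocorrelation.
#' @param ld_d two-marker linkage-disequilibrium coefficient D for the COMT
#'   haplotypes (0 = independent markers).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 111, n_rois = 259, n_volumes = 300,
                       tr_seconds = 2, n_modules = 6,
                       freq_httlpr_s = 0.50, freq_rs4680_met = 0.53,
                       freq_rs165599_a = 0.69,
                       neuro_mean = 135.5, neuro_sd = 18.9,
                       within_module_r = 0.5, between_module_r = 0.1,
                       effect_participation = 0.05, effect_slope = 0.05,
                       participation_modules = c(3, 4),
                       slope_modules = c(5, 6),
                       noise_sd = 0.5, global_amp = 0.3, motion_amp = 0.2,
                       motion_sd = 0.02, motion_spike_prob = 0.02,
                       motion_spike_mm = 0.4, ar1 = 0, ld_d = 0) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_modules <= cfg$n_rois,
            cfg$within_module_r > cfg$between_module_r,
            cfg$within_module_r < 1, cfg$between_module_r > -1,
            all(c(freq_httlpr_s, freq_rs4680_met, freq_rs165599_a) >= 0),
            all(c(freq_httlpr_s, freq_rs4680_met, freq_rs165599_a) <= 1))
  structure(cfg, class = "sim_config")
}

.draw_genotype <- function(n, p_a, names3) {
  # HWE draw: genotype = number of copies of allele a out of 2
  dose <- rbinom(n, 2, p_a)
  names3[3 - dose]  # dose 2 -> first level (a/a), 0 -> third (b/b)
}

#' Simulate a genotype table under Hardy-Weinberg equilibrium
#'
#' Independent HWE draws per marker at the configured allele frequencies.
#' When `ld_d` is nonzero the two COMT markers are drawn from phased
#' haplotypes with linkage-disequilibrium coefficient D (truncated to the
#' feasible range), so phasing has signal to recover.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return genotype table data.frame (see [as_genotype_table()]).
#' @export
simulate_genotypes <- function(config = sim_config(), seed = 1) {
  with_seed(seed, {
    n <- config$n_subjects
    httlpr <- .draw_genotype(n, config$freq_httlpr_s, c("S/S", "S/L", "L/L"))
    if (config$ld_d == 0) {
      rs4680 <- .draw_genotype(n, config$freq_rs4680_met,
                               c("Met/Met", "Val/Met", "Val/Val"))
      rs165599 <- .draw_genotype(n, config$freq_rs165599_a,
                                 c("A/A", "A/G", "G/G"))
    } else {
      p <- config$freq_rs4680_met   # P(Met)
      q <- config$freq_rs165599_a   # P(A)
      d <- config$ld_d
      d <- max(min(d, min(p * (1 - q), (1 - p) * q)),
               -min(p * q, (1 - p) * (1 - q)))
      hf <- c(MetA = p * q + d, MetG = p * (1 - q) - d,
              ValA = (1 - p) * q - d, ValG = (1 - p) * (1 - q) + d)
      hap <- matrix(sample(4, 2 * n, replace = TRUE, prob = hf), ncol = 2)
      met_dose <- rowSums(hap <= 2)
      a_dose <- rowSums(hap == 1 | hap == 3)
      rs4680 <- c("Val/Val", "Val/Met", "Met/Met")[met_dose + 1]
      rs165599 <- c("G/G", "A/G", "A/A")[a_dose + 1]
    }
    as_genotype_table(data.frame(
      subject_id = sprintf("sub%03d", seq_len(n)),
      httlpr = httlpr, rs4680 = rs4680, rs165599 = rs165599,
      stringsAsFactors = FALSE))
  })
}

#' Simulate neuroticism scores
#'
#' Normal(neuro_mean, neuro_sd), independent of genotype (the cohort showed
#' no genotype-trait mean association).
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return data.frame `subject_id`, `neuroticism`.
#' @export
simulate_phenotypes <- function(config = sim_config(), seed = 1) {
  with_seed(seed, data.frame(
    subject_id = sprintf("sub%03d", seq_len(config$n_subjects)),
    neuroticism = rnorm(config$n_subjects, config$neuro_mean,
                        config$neuro_sd),
    stringsAsFactors = FALSE))
}

# near-equal module sizes summing to n_rois
module_sizes <- function(n_rois, n_modules) {
  base <- n_rois %/% n_modules
  sizes <- rep(base, n_modules)
  extra <- n_rois - base * n_modules
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  sizes
}

#' Planted module labels
#' @param config a [sim_config()].
#' @return integer vector, length `n_rois`.
#' @export
planted_labels <- function(config) {
  rep(seq_len(config$n_modules), module_sizes(config$n_rois,
                                              config$n_modules))
}

# target correlation matrix for one subject given group membership and
# standardized neuroticism; shrinks toward identity if not PD
subject_covariance <- function(config, labels, s_carrier, comt_risk,
                               z_neuro) {
  n <- config$n_rois
  R <- matrix(config$between_module_r, n, n)
  for (m in seq_len(config$n_modules)) {
    idx <- labels == m
    R[idx, idx] <- config$within_module_r
  }
  if (s_carrier && config$effect_participation != 0) {
    for (m in config$participation_modules) {
      idx <- labels == m
      oth <- !(labels %in% config$participation_modules)
      R[idx, oth] <- R[idx, oth] - config$effect_participation
      R[oth, idx] <- t(R[idx, oth])
    }
  }
  if (comt_risk && config$effect_slope != 0) {
    for (m in config$slope_modules) {
      idx <- labels == m
      delta <- config$effect_slope * z_neuro
      Rm <- pmin(pmax(config$within_module_r - delta, 0.02), 0.95)
      R[idx, idx] <- Rm
    }
  }
  diag(R) <- 1
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) {
    lam <- (1e-8 - min(ev)) / (1 - min(ev))
    warning("covariance not positive definite; shrinking toward identity",
            call. = FALSE)
    R <- (1 - lam) * R + lam * diag(n)
  }
  R
}

# ROI coordinates on a 6-cluster MNI-like layout; deterministic given RNG
# state. Cluster centres are spread in a +/-60 mm box; jitter makes a few
# pairs closer than 20 mm so distance exclusion is exercised.
roi_coordinates <- function(config, labels) {
  centers <- matrix(c(-45, 30, 20,   45, 30, 20,
                      -45, -40, 35,  45, -40, 35,
                      0, -65, -10,   0, 35, -15), ncol = 3, byrow = TRUE)
  if (config$n_modules > nrow(centers)) {
    extra <- matrix(runif((config$n_modules - nrow(centers)) * 3, -60, 60),
                    ncol = 3)
    centers <- rbind(centers, extra)
  }
  xyz <- centers[labels, , drop = FALSE] +
    matrix(rnorm(length(labels) * 3, 0, 14), ncol = 3)
  colnames(xyz) <- c("x", "y", "z")
  data.frame(roi_id = sprintf("roi%03d", seq_along(labels)), xyz,
             stringsAsFactors = FALSE)
}

#' Simulate a complete synthetic cohort
#'
#' Draws genotypes, phenotypes and per-subject ROI time series from a
#' module-block covariance with the configured planted effects, adds motion
#' traces, shared-global and motion-coupled nuisance components, and returns
#' everything with the ground truth attached.
#'
#' @param config a [sim_config()].
#' @param seed master seed; all stage seeds derive from it.
#' @return list of class `synthetic_cohort`: `genotypes`, `phenotypes`,
#'   `groups`, `timeseries` (named list of volumes x ROIs matrices),
#'   `motion` (named list), `nuisance` (named list), `coords`,
#'   `ground_truth` (labels, config, per-subject flags).
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1) {
  seeds <- derive_seeds(seed, 4)
  geno <- simulate_genotypes(config, seeds[1])
  pheno <- simulate_phenotypes(config, seeds[2])
  groups <- assign_risk_groups(geno)
  labels <- planted_labels(config)
  z <- (pheno$neuroticism - config$neuro_mean) / config$neuro_sd

  with_seed(seeds[3], {
    coords <- roi_coordinates(config, labels)
    n_t <- config$n_volumes
    n_r <- config$n_rois
    s_carrier <- groups$httlpr_group == "S-carrier"
    comt_risk <- groups$comt_group == "risk"
    # cache cholesky by (group pair, rounded z) only when slope effect off
    ts_list <- vector("list", config$n_subjects)
    mot_list <- vector("list", config$n_subjects)
    nuis_list <- vector("list", config$n_subjects)
    chol_cache <- list()
    for (i in seq_len(config$n_subjects)) {
      sc <- isTRUE(s_carrier[i]); cr <- isTRUE(comt_risk[i])
      key <- if (cr && config$effect_slope != 0) NA_character_
      else paste0(sc, "_", cr)
      U <- if (!is.na(key) && !is.null(chol_cache[[key]])) {
        chol_cache[[key]]
      } else {
        R <- subject_covariance(config, labels, sc, cr, z[i])
        u <- chol(R)
        if (!is.na(key)) chol_cache[[key]] <- u
        u
      }
      sig <- matrix(rnorm(n_t * n_r), n_t, n_r) %*% U
      if (config$ar1 != 0) {
        a <- config$ar1
        sig <- apply(sig, 2, function(x) {
          as.vector(stats::filter(x, a, method = "recursive")) * sqrt(1 - a^2)
        })
      }
      # motion: random walk + occasional spikes
      steps <- matrix(rnorm(n_t * 6, 0, config$motion_sd), n_t, 6)
      spikes <- matrix(rbinom(n_t * 6, 1, config$motion_spike_prob) *
                         config$motion_spike_mm *
                         sample(c(-1, 1), n_t * 6, replace = TRUE),
                       n_t, 6)
      steps[, 4:6] <- steps[, 4:6] / 50  # rotations in radians
      spikes[, 4:6] <- spikes[, 4:6] / 50
      motion <- apply(steps + spikes, 2, cumsum)
      colnames(motion) <- c("x", "y", "z", "pitch", "roll", "yaw")
      gs <- rnorm(n_t)
      wm <- rnorm(n_t); csf <- rnorm(n_t)
      nuis <- cbind(motion, global = gs, wm = wm, csf = csf)
      load <- matrix(rnorm(6 * n_r, 0, 1), 6, n_r)
      ts <- sig + config$global_amp * gs +
        config$motion_amp * (scale(motion) %*% load) +
        matrix(rnorm(n_t * n_r, 0, config$noise_sd), n_t, n_r)
      colnames(ts) <- coords$roi_id
      ts_list[[i]] <- ts
      mot_list[[i]] <- motion
      nuis_list[[i]] <- nuis
    }
    ids <- geno$subject_id
    names(ts_list) <- names(mot_list) <- names(nuis_list) <- ids
    structure(list(
      genotypes = geno, phenotypes = pheno, groups = groups,
      timeseries = ts_list, motion = mot_list, nuisance = nuis_list,
      coords = coords,
      ground_truth = list(module_labels = labels, config = config,
                          s_carrier = s_carrier, comt_risk = comt_risk,
                          z_neuro = z, seed = seed)),
      class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cfg <- x$ground_truth$config
  cat(sprintf(
    "synthetic_cohort: %d subjects, %d ROIs x %d volumes, %d modules\n",
    cfg$n_subjects, cfg$n_rois, cfg$n_volumes, cfg$n_modules))
  invisible(x)
}

#' Planted-partition random graph
#'
#' Binary undirected graph with `n_blocks` blocks of `block_size` nodes;
#' within-block edges appear with probability `p_in`, between-block edges
#' with probability `p_out`. Used to validate community detection against a
#' known ground truth.
#'
#' @param n_blocks,block_size block structure.
#' @param p_in,p_out edge probabilities.
#' @param seed integer seed.
#' @return list with `adjacency` (0/1 matrix, zero diagonal) and `labels`.
#' @export
planted_partition_graph <- function(n_blocks = 6, block_size = 10,
                                    p_in = 0.8, p_out = 0.05, seed = 1) {
  n <- n_blocks * block_size
  labels <- rep(seq_len(n_blocks), each = block_size)
  with_seed(seed, {
    P <- ifelse(outer(labels, labels, "=="), p_in, p_out)
    A <- matrix(0, n, n)
    ut <- upper.tri(A)
    A[ut] <- rbinom(sum(ut), 1, P[ut])
    A <- A + t(A)
    diag(A) <- 0
    list(adjacency = A, labels = labels)
  })
}

#' Exchangeable null measure curves
#'
#' Per-subject measure curves with a subject-level random intercept plus
#' smooth correlated noise across densities, independent of any grouping —
#' the null input used to check permutation-test calibration.
#'
#' @param n_subjects,densities cohort shape.
#' @param subject_sd,noise_sd variance components.
#' @param seed integer seed.
#' @return subjects x densities matrix.
#' @export
simulate_null_curves <- function(n_subjects, densities,
                                 subject_sd = 1, noise_sd = 0.3, seed = 1) {
  with_seed(seed, {
    nd <- length(densities)
    base <- rnorm(n_subjects, 0, subject_sd)
    eps <- matrix(rnorm(n_subjects * nd, 0, noise_sd), n_subjects, nd)
    # smooth noise across adjacent densities
    if (nd > 2) eps <- t(apply(eps, 1, function(x)
      stats::filter(x, rep(1 / 3, 3), sides = 2, circular = TRUE)))
    sweep(eps, 1, base, "+")
  })
}
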