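# End-to-end study pipeline over a (synthetic or real-format) cohort, plus
# the calibration experiments used to validate the inference machinery:
# type-I-error under an exchangeable null and power for the planted
# participation effect.

#' Run the full network pipeline on a cohort
#'
#' Chains the stages in study order: per-subject cleanup (nuisance regression
#' with derivatives, band-pass, scrubbing with the one-third exclusion rule),
#' Pearson connectivity with 20 mm distance exclusion, proportional
#' thresholding on the density grid, group-level module decomposition at the
#' stability-selected density, per-subject measure curves reusing the fixed
#' group partition, and AUC permutation tests for both polymorphism group
#' factors.
#'
#' @param cohort a `synthetic_cohort` (or compatible list with the same
#'   fields).
#' @param densities density grid.
#' @param measures measure families to compute (see [measure_suite()]).
#' @param variants `"weighted"`, `"binary"` or both.
#' @param n_perm permutations per test (study value 5000).
#' @param seed seed for the permutation streams.
#' @param fd_threshold_mm scrubbing threshold.
#' @param selection_seeds,decomposition_seeds Louvain seed sets for density
#'   selection and final decomposition.
#' @param modularity_seeds per-subject maximized-modularity seeds.
#' @param skip_prep set TRUE when `cohort$timeseries` is already clean
#'   (skips nuisance regression/filtering/scrubbing).
#' @return list with `partition`, `selected_density`, `measures` (long
#'   data.frame), `inference_httlpr`, `inference_comt` (results tables),
#'   `excluded` (subject ids dropped by scrubbing), `stacks` (invisible
#'   per-subject stacks are not kept to bound memory).
#' @export
run_pipeline <- function(cohort, densities = seq(0.01, 0.30, by = 0.01),
                         measures = c("global_efficiency",
                                      "local_efficiency",
                                      "modularity", "participation"),
                         variants = "weighted",
                         n_perm = 5000, seed = 1, fd_threshold_mm = 0.5,
                         selection_seeds = 1:10, decomposition_seeds = 1:50,
                         modularity_seeds = 1:10, skip_prep = FALSE) {
  ids <- names(cohort$timeseries)
  coords <- cohort$coords[, c("x", "y", "z")]
  tr <- cohort$ground_truth$config$tr_seconds
  if (is.null(tr)) tr <- 2

  raw <- list(); excluded <- character()
  for (id in ids) {
    if (skip_prep) {
      dat <- cohort$timeseries[[id]]
    } else {
      pr <- prep_subject(cohort$timeseries[[id]], cohort$motion[[id]],
                         cohort$nuisance[[id]], tr_seconds = tr,
                         fd_threshold_mm = fd_threshold_mm)
      if (pr$exclude) { excluded <- c(excluded, id); next }
      dat <- pr$data
    }
    raw[[id]] <- correlation_matrix(dat, coords)
  }
  if (length(raw) < 4)
    stop("fewer than 4 subjects survive preprocessing", call. = FALSE)

  group_mean <- Reduce(`+`, raw) / length(raw)
  gstack <- build_stack(group_mean, densities)
  sel <- select_optimal_density(gstack, seeds = selection_seeds)
  partition <- best_louvain(gstack$weighted[[sel$index]],
                            seeds = decomposition_seeds)
  partition$density_used <- sel$density

  # stream per subject: build the stack, measure, discard (bounds memory)
  meas <- do.call(rbind, lapply(names(raw), function(id) {
    st <- build_stack(raw[[id]], densities = densities)
    cbind(subject_id = id,
          measure_suite(st, partition, variants = variants,
                        measures = measures,
                        modularity_seeds = modularity_seeds),
          stringsAsFactors = FALSE)
  }))

  keep <- cohort$groups$subject_id %in% names(raw)
  groups <- cohort$groups[keep, ]
  pheno <- cohort$phenotypes[cohort$phenotypes$subject_id %in% names(raw), ]
  inf_httlpr <- infer_cohort(meas, groups, "httlpr_group", "S-carrier",
                             neuroticism = pheno, n_perm = n_perm,
                             seed = seed)
  inf_comt <- infer_cohort(meas, groups, "comt_group", "risk",
                           neuroticism = pheno, n_perm = n_perm,
                           seed = seed + 1)
  list(partition = partition, selected_density = sel$density,
       group_mean = group_mean, measures = meas,
       inference_httlpr = inf_httlpr, inference_comt = inf_comt,
       excluded = excluded, subject_ids = names(raw))
}

#' Type-I-error calibration of the AUC permutation test
#'
#' Repeatedly draws exchangeable null measure curves and fresh HWE group
#' labels, runs the mean-difference AUC permutation test, and reports the
#' rejection rate at `alpha`. Under the null this should match `alpha`.
#'
#' @param n_replicates number of independent null datasets.
#' @param n_subjects subjects per dataset.
#' @param densities density grid for the curves.
#' @param n_perm permutations per test.
#' @param alpha nominal level.
#' @param risk_fraction expected fraction in the risk group (S-carrier
#'   fraction 1 - (1-p_S)^2 at p_S = 0.5 is 0.75).
#' @param seed master seed.
#' @return list with `rejection_rate`, `p_values`, `n_replicates`.
#' @export
calibrate_null_rejection <- function(n_replicates = 1000, n_subjects = 111,
                                     densities = seq(0.01, 0.30, by = 0.01),
                                     n_perm = 500, alpha = 0.05,
                                     risk_fraction = 0.75, seed = 1) {
  seeds <- derive_seeds(seed, 2 * n_replicates)
  pvals <- vapply(seq_len(n_replicates), function(r) {
    x <- simulate_null_curves(n_subjects, densities, seed = seeds[r])
    lab <- with_seed(seeds[n_replicates + r], {
      l <- runif(n_subjects) < risk_fraction
      # guarantee both groups populated
      if (sum(l) < 2) l[sample(which(!l), 2)] <- TRUE
      if (sum(!l) < 2) l[sample(which(l), 2)] <- FALSE
      l
    })
    permutation_test(x, lab, densities, "mean_difference",
                     n_perm = n_perm, seed = seeds[r] + 1L)$p_two_tailed
  }, numeric(1))
  list(rejection_rate = mean(pvals <= alpha), p_values = pvals,
       n_replicates = n_replicates)
}

# Fast participation-only pipeline for one simulated cohort: group partition
# from Louvain on the group mean at `partition_density`, per-subject
# participation curves for the designated modules, then the permutation test.
participation_effect_pvalue <- function(config, densities, seed,
                                        n_perm = 500,
                                        partition_density = 0.10) {
  cohort <- simulate_cohort(config, seed)
  ids <- names(cohort$timeseries)
  raw <- lapply(ids, function(id)
    correlation_matrix(cohort$timeseries[[id]], cohort$coords[, c("x", "y", "z")]))
  group_mean <- Reduce(`+`, raw) / length(raw)
  part <- best_louvain(
    proportional_threshold(group_mean, partition_density)$weighted,
    seeds = 1:5)
  labels <- part$labels
  # map planted designated modules onto detected labels by overlap
  planted <- cohort$ground_truth$module_labels
  target <- unique(vapply(config$participation_modules, function(m) {
    tab <- table(labels[planted == m])
    as.integer(names(tab)[which.max(tab)])
  }, integer(1)))
  curves <- vapply(raw, function(r) {
    st <- build_stack(r, densities)
    vapply(seq_along(densities), function(i) {
      pc <- participation_coefficient(st$weighted[[i]], labels, "weighted")
      mean(pc$per_node[labels %in% target])
    }, numeric(1))
  }, numeric(length(densities)))
  curves <- t(curves)
  is_risk <- cohort$groups$httlpr_group == "S-carrier"
  pt <- permutation_test(curves, is_risk, densities, "mean_difference",
                         n_perm = n_perm, seed = seed + 1L)
  list(p = pt$p_two_tailed, observed_auc = pt$observed_auc)
}

#' Power of the participation group test at the planted effect size
#'
#' Simulates cohorts with the configured participation effect, runs the
#' group-difference AUC permutation test on the designated modules'
#' participation curves, and reports the fraction of seeds rejecting at
#' `alpha` together with the sign of the mean observed AUC.
#'
#' @param config a [sim_config()]; its `effect_participation` is the planted
#'   effect under test (set it to 0 for a null check).
#' @param n_seeds number of simulated cohorts.
#' @param densities density grid.
#' @param n_perm permutations per test.
#' @param alpha nominal level.
#' @param seed master seed.
#' @return list with `power`, `p_values`, `mean_observed_auc`.
#' @export
power_participation_effect <- function(config, n_seeds = 50,
                                       densities = seq(0.02, 0.30,
                                                       by = 0.02),
                                       n_perm = 500, alpha = 0.05,
                                       seed = 1) {
  seeds <- derive_seeds(seed, n_seeds)
  res <- lapply(seq_len(n_seeds), function(k)
    participation_effect_pvalue(config, densities, seeds[k],
                                n_perm = n_perm))
  pv <- vapply(res, `[[`, numeric(1), "p")
  aucs <- vapply(res, `[[`, numeric(1), "observed_auc")
  list(power = mean(pv <= alpha), p_values = pv,
       mean_observed_auc = mean(aucs))
}

#' Summarize ground-truth recovery of a pipeline run
#'
#' Maps each planted module to the detected module with the largest node
#' overlap, then reports the detected module count, the adjusted-Rand-style
#' exact-match flag (labels identical up to relabeling), and the observed
#' AUCs for the two planted effects: the participation group difference
#' (risk minus non-risk, expected negative in the designated modules) and
#' the local-efficiency slope difference (expected negative in the
#' moderated modules).
#'
#' @param result a [run_pipeline()] result.
#' @param cohort the `synthetic_cohort` the pipeline ran on.
#' @return list with `n_modules`, `exact_recovery`, `participation_auc`
#'   (named by planted module), `slope_auc` (named by planted module).
#' @export
recovery_summary <- function(result, cohort) {
  planted <- cohort$ground_truth$module_labels
  cfg <- cohort$ground_truth$config
  detected <- result$partition$labels
  map <- vapply(sort(unique(planted)), function(m) {
    tab <- table(detected[planted == m])
    as.integer(names(tab)[which.max(tab)])
  }, integer(1))
  exact <- length(unique(detected)) == length(unique(planted)) &&
    all(detected == map[planted])
  pick_auc <- function(tab, measure, stat, modules) {
    out <- vapply(modules, function(m) {
      row <- tab$measure == measure & tab$statistic == stat &
        !is.na(tab$module) & tab$module == map[m]
      if (!any(row)) return(NA_real_)
      tab$observed_auc[which(row)[1]]
    }, numeric(1))
    names(out) <- paste0("module", modules)
    out
  }
  list(n_modules = result$partition$n_modules,
       exact_recovery = exact,
       participation_auc = pick_auc(result$inference_httlpr,
                                    "participation_module",
                                    "mean_difference",
                                    cfg$participation_modules),
       slope_auc = pick_auc(result$inference_comt,
                            "local_efficiency_module",
                            "slope_difference",
                            cfg$slope_modules))
}
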