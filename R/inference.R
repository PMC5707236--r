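# Statistical engine: per-density group-difference and slope-difference
# curves, trapezoidal AUC summarization across the density grid, and
# label-permutation tests on the AUC.

#' Group mean-difference curve
#'
#' Per density: mean(measure in risk group) - mean(measure in non-risk
#' group).
#'
#' @param values subjects x densities matrix of one measure.
#' @param is_risk logical vector per subject (TRUE = risk group).
#' @return numeric vector, one difference per density.
#' @export
group_difference_curve <- function(values, is_risk) {
  values <- as.matrix(values)
  is_risk <- as.logical(is_risk)
  if (length(is_risk) != nrow(values))
    stop("group labels must match subject rows", call. = FALSE)
  if (sum(is_risk) < 2 || sum(!is_risk) < 2)
    stop("need at least 2 subjects per group", call. = FALSE)
  colMeans(values[is_risk, , drop = FALSE]) -
    colMeans(values[!is_risk, , drop = FALSE])
}

# OLS slope of y on x for every column of Y, restricted to rows `idx`.
.ols_slopes <- function(Y, x, idx) {
  xg <- x[idx]
  xc <- xg - mean(xg)
  ssx <- sum(xc^2)
  if (ssx <= 0) stop("zero neuroticism variance within a group",
                     call. = FALSE)
  as.vector(crossprod(xc, Y[idx, , drop = FALSE])) / ssx
}

#' Slope-difference curve
#'
#' Per density: the OLS slope of the measure on the neuroticism score within
#' the risk group minus the same slope within the non-risk group.
#'
#' @param values subjects x densities measure matrix.
#' @param neuroticism numeric score per subject.
#' @param is_risk logical group indicator per subject.
#' @return numeric vector of slope differences per density.
#' @export
slope_difference_curve <- function(values, neuroticism, is_risk) {
  values <- as.matrix(values)
  is_risk <- as.logical(is_risk)
  if (length(is_risk) != nrow(values) ||
      length(neuroticism) != nrow(values))
    stop("labels/scores must match subject rows", call. = FALSE)
  if (sum(is_risk) < 3 || sum(!is_risk) < 3)
    stop("need at least 3 subjects per group", call. = FALSE)
  .ols_slopes(values, neuroticism, which(is_risk)) -
    .ols_slopes(values, neuroticism, which(!is_risk))
}

#' Area under a measure curve across the density grid
#'
#' Trapezoidal integral of the curve over the (strictly increasing) density
#' grid; the threshold-independent scalar summarizing one measure.
#'
#' @param curve numeric vector of per-density values.
#' @param densities strictly increasing grid.
#' @return scalar AUC.
#' @export
auc_curve <- function(curve, densities) {
  if (length(curve) != length(densities))
    stop("curve and densities differ in length", call. = FALSE)
  if (length(densities) < 2 || is.unsorted(densities, strictly = TRUE))
    stop("densities must be strictly increasing, length >= 2", call. = FALSE)
  pracma::trapz(densities, curve)
}

# trapezoid weights so that AUC = curve %*% w (used for vectorized perms)
.trapz_weights <- function(densities) {
  n <- length(densities)
  w <- numeric(n)
  dd <- diff(densities)
  w[1] <- dd[1] / 2
  w[n] <- dd[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (dd[-1] + dd[-(n - 1)]) / 2
  w
}

#' Permutation test on the AUC of a difference statistic
#'
#' The observed statistic is the AUC (over densities) of either the group
#' mean-difference curve or the slope-difference curve. Group labels are then
#' permuted `n_perm` times (group sizes preserved), the statistic's AUC is
#' recomputed for each permutation, and the two-tailed p-value is
#' `(# |null| >= |observed| + 1) / (n_perm + 1)`.
#'
#' @param values subjects x densities measure matrix.
#' @param is_risk logical group indicator.
#' @param densities density grid matching the columns of `values`.
#' @param statistic `"mean_difference"` or `"slope_difference"`.
#' @param neuroticism required for `"slope_difference"`.
#' @param n_perm number of permutations (study default 5000).
#' @param seed integer seed for the permutation stream.
#' @return object of class `permutation_result`: list with `observed_auc`,
#'   `null_aucs`, `p_two_tailed`, `statistic`, `n_perm`, `seed`,
#'   `observed_curve`.
#' @export
permutation_test <- function(values, is_risk, densities,
                             statistic = c("mean_difference",
                                           "slope_difference"),
                             neuroticism = NULL, n_perm = 5000, seed = 1) {
  statistic <- match.arg(statistic)
  values <- as.matrix(values)
  is_risk <- as.logical(is_risk)
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  if (anyNA(is_risk)) stop("group labels contain NA", call. = FALSE)
  curve_fun <- if (statistic == "mean_difference") {
    function(lab) group_difference_curve(values, lab)
  } else {
    if (is.null(neuroticism))
      stop("neuroticism scores required for slope_difference", call. = FALSE)
    function(lab) slope_difference_curve(values, neuroticism, lab)
  }
  obs_curve <- curve_fun(is_risk)
  w <- .trapz_weights(densities)
  if (length(w) != ncol(values))
    stop("densities must match measure columns", call. = FALSE)
  obs_auc <- sum(obs_curve * w)
  null_aucs <- with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      lab <- sample(is_risk)
      sum(curve_fun(lab) * w)
    }, numeric(1))
  })
  p <- (sum(abs(null_aucs) >= abs(obs_auc)) + 1) / (n_perm + 1)
  structure(list(observed_auc = obs_auc, null_aucs = null_aucs,
                 p_two_tailed = p, statistic = statistic,
                 n_perm = n_perm, seed = seed,
                 observed_curve = obs_curve, densities = densities),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation_result (%s): AUC = %.4g, p = %.4f (%d perms)\n",
              x$statistic, x$observed_auc, x$p_two_tailed, x$n_perm))
  invisible(x)
}

#' Run the full inference table for a cohort measure set
#'
#' Applies the AUC permutation test per (measure, module, variant) cell of a
#' long-format cohort measure table, for both the group mean-difference and
#' (when `neuroticism` is given) slope-difference statistics.
#'
#' @param measures long data.frame from [cohort_measures()].
#' @param groups data.frame `subject_id`, plus the column named by
#'   `group_col`, containing the two group labels.
#' @param group_col name of the grouping column.
#' @param risk_label label treated as the risk group.
#' @param neuroticism optional data.frame `subject_id`, `neuroticism`.
#' @param statistics which statistics to run.
#' @param n_perm,seed permutation settings.
#' @param measure_filter optional data.frame (`measure`, `module`, `variant`)
#'   restricting which cells are tested.
#' @return data.frame: `measure`, `module`, `variant`, `statistic`,
#'   `observed_auc`, `p_two_tailed`, `n_perm`, `seed`; slope-difference rows
#'   additionally carry the density-averaged within-group slopes and
#'   measure-neuroticism correlations (`slope_risk`, `slope_nonrisk`,
#'   `cor_risk`, `cor_nonrisk` — descriptive companions to the tested
#'   slope-difference AUC).
#' @export
infer_cohort <- function(measures, groups, group_col, risk_label,
                         neuroticism = NULL,
                         statistics = c("mean_difference",
                                        "slope_difference"),
                         n_perm = 5000, seed = 1, measure_filter = NULL) {
  lab_map <- groups[[group_col]]
  names(lab_map) <- groups$subject_id
  cells <- unique(measures[, c("measure", "module", "variant")])
  if (!is.null(measure_filter)) {
    key <- function(df) paste(df$measure, df$module, df$variant)
    cells <- cells[key(cells) %in% key(measure_filter), , drop = FALSE]
  }
  if ("slope_difference" %in% statistics && is.null(neuroticism))
    statistics <- setdiff(statistics, "slope_difference")
  neuro_map <- NULL
  if (!is.null(neuroticism)) {
    neuro_map <- neuroticism$neuroticism
    names(neuro_map) <- neuroticism$subject_id
  }
  rows <- list()
  for (r in seq_len(nrow(cells))) {
    sel <- measures$measure == cells$measure[r] &
      measures$variant == cells$variant[r] &
      (is.na(cells$module[r]) | measures$module %in% cells$module[r])
    if (is.na(cells$module[r])) sel <- sel & is.na(measures$module)
    sub <- measures[sel, ]
    wide <- tapply(sub$value, list(sub$subject_id, sub$density), mean)
    densities <- as.numeric(colnames(wide))
    ids <- rownames(wide)
    lab <- lab_map[ids]
    keep <- !is.na(lab)
    wide <- wide[keep, , drop = FALSE]
    is_risk <- lab[keep] == risk_label
    for (st in statistics) {
      neuro <- if (st == "slope_difference") neuro_map[ids[keep]] else NULL
      pt <- permutation_test(wide, is_risk, densities, statistic = st,
                             neuroticism = neuro, n_perm = n_perm,
                             seed = seed)
      row <- data.frame(
        measure = cells$measure[r], module = cells$module[r],
        variant = cells$variant[r], statistic = st,
        observed_auc = pt$observed_auc, p_two_tailed = pt$p_two_tailed,
        n_perm = n_perm, seed = seed, stringsAsFactors = FALSE)
      if (st == "slope_difference") {
        # density-averaged within-group slopes and correlations, reported
        # alongside the tested slope difference
        auc_mean <- function(v) mean(v)
        sl_r <- .ols_slopes(wide, neuro, which(is_risk))
        sl_n <- .ols_slopes(wide, neuro, which(!is_risk))
        cr_r <- apply(wide[is_risk, , drop = FALSE], 2, cor,
                      y = neuro[is_risk])
        cr_n <- apply(wide[!is_risk, , drop = FALSE], 2, cor,
                      y = neuro[!is_risk])
        row$slope_risk <- auc_mean(sl_r)
        row$slope_nonrisk <- auc_mean(sl_n)
        row$cor_risk <- auc_mean(cr_r)
        row$cor_nonrisk <- auc_mean(cr_n)
      } else {
        row$slope_risk <- row$slope_nonrisk <- NA_real_
        row$cor_risk <- row$cor_nonrisk <- NA_real_
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  do.call(rbind, rows)
}
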