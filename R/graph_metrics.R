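# Weighted and binary network measures, Brain-Connectivity-Toolbox
# conventions: global efficiency, local efficiency, maximized modularity,
# participation coefficient, and the per-density measure suite.

# Pairwise distance matrix under the toolbox convention: weighted edges get
# length 1/w, binary edges length 1; unreachable pairs are Inf.
graph_distances <- function(graph, variant = c("weighted", "binary")) {
  variant <- match.arg(variant)
  graph <- as.matrix(graph)
  len <- if (variant == "weighted") ifelse(graph > 0, 1 / graph, Inf)
  else ifelse(graph > 0, 1, Inf)
  diag(len) <- Inf
  cpp_apsp(len)
}

#' Global efficiency
#'
#' Mean inverse shortest-path length over all ordered node pairs; pairs in
#' different components contribute 0 (1/Inf). Weighted paths use edge lengths
#' 1/w; binary paths unit lengths.
#'
#' @param graph symmetric nonnegative matrix, zero diagonal.
#' @param variant `"weighted"` or `"binary"`.
#' @return scalar efficiency >= 0.
#' @export
global_efficiency <- function(graph, variant = c("weighted", "binary")) {
  n <- nrow(graph)
  if (n < 2) stop("need at least 2 nodes", call. = FALSE)
  d <- graph_distances(graph, variant)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Local efficiency
#'
#' Binary: the global efficiency of each node's neighbour subgraph. Weighted:
#' the 2010 weighted formulation — shortest paths within the neighbour
#' subgraph on cube-rooted edge lengths `(1/w)^(1/3)`, each pair contributing
#' `w_uj^(1/3) w_uh^(1/3) / d_jh`; on unit weights this reduces exactly to
#' the binary variant. Nodes with fewer than two neighbours score 0.
#'
#' @inheritParams global_efficiency
#' @return list with `per_node` vector and `mean`.
#' @export
local_efficiency <- function(graph, variant = c("weighted", "binary")) {
  variant <- match.arg(variant)
  if (nrow(graph) < 2) stop("need at least 2 nodes", call. = FALSE)
  per <- cpp_local_efficiency(as.matrix(graph), variant == "weighted")
  names(per) <- rownames(graph)
  list(per_node = per, mean = mean(per))
}

#' Participation coefficient
#'
#' P_i = 1 - sum over modules m of (kappa_im / kappa_i)^2, where kappa is
#' node strength (weighted) or degree (binary) and kappa_im its part landing
#' in module m. Nodes with no connections score 0.
#'
#' @inheritParams global_efficiency
#' @param labels module label per node.
#' @return list with `per_node` vector and `module_mean` (named by module).
#' @export
participation_coefficient <- function(graph, labels,
                                      variant = c("weighted", "binary")) {
  variant <- match.arg(variant)
  graph <- as.matrix(graph)
  if (length(labels) != nrow(graph))
    stop("labels must cover every node", call. = FALSE)
  if (variant == "binary") graph <- (graph > 0) * 1
  labs <- as.integer(factor(labels))
  ind <- outer(labs, sort(unique(labs)), "==") * 1
  kim <- graph %*% ind
  ki <- rowSums(graph)
  p <- ifelse(ki > 0, 1 - rowSums((kim / pmax(ki, .Machine$double.eps))^2), 0)
  p <- pmin(pmax(p, 0), 1)  # clip float dust at the [0, 1] boundary
  names(p) <- rownames(graph)
  module_mean <- tapply(p, labs, mean)
  list(per_node = p, module_mean = module_mean)
}

#' Per-subject measure curves across the density grid
#'
#' For each density of a subject's connectivity stack, computes the
#' whole-brain measures (global efficiency, mean local efficiency, maximized
#' modularity via best-of-seeds Louvain with fine-tuning) and the per-module
#' measures (mean local efficiency and mean participation per module of the
#' fixed group partition), in weighted and/or binary variants.
#'
#' @param stack a `conn_stack` for one subject.
#' @param partition the fixed group `module_partition`.
#' @param variants character subset of `c("weighted", "binary")`.
#' @param measures character subset of
#'   `c("global_efficiency", "local_efficiency", "modularity", "participation")`;
#'   whole-brain and per-module rows are emitted for whichever are requested.
#' @param modularity_seeds Louvain seeds for per-subject maximized modularity.
#' @return long data.frame: `measure`, `module` (NA for whole-brain),
#'   `density`, `variant`, `value`.
#' @export
measure_suite <- function(stack, partition,
                          variants = c("weighted", "binary"),
                          measures = c("global_efficiency",
                                       "local_efficiency",
                                       "modularity", "participation"),
                          modularity_seeds = 1:10) {
  stopifnot(inherits(stack, "conn_stack"))
  labels <- if (inherits(partition, "module_partition"))
    partition$labels else as.integer(factor(partition))
  if (length(labels) != nrow(stack$raw))
    stop("partition and stack disagree on ROI count", call. = FALSE)
  mods <- sort(unique(labels))
  out <- list()
  for (v in variants) {
    mats <- if (v == "weighted") stack$weighted else stack$binary
    for (i in seq_along(stack$densities)) {
      g <- mats[[i]]
      d <- stack$densities[i]
      add <- function(measure, module, value)
        out[[length(out) + 1]] <<- data.frame(
          measure = measure, module = module, density = d, variant = v,
          value = value, stringsAsFactors = FALSE)
      if ("global_efficiency" %in% measures)
        add("global_efficiency", NA_integer_, global_efficiency(g, v))
      if ("local_efficiency" %in% measures) {
        le <- local_efficiency(g, v)
        add("local_efficiency_mean", NA_integer_, le$mean)
        for (m in mods)
          add("local_efficiency_module", m, mean(le$per_node[labels == m]))
      }
      if ("modularity" %in% measures)
        add("modularity_max", NA_integer_,
            best_louvain(g, seeds = modularity_seeds)$q_value)
      if ("participation" %in% measures) {
        pc <- participation_coefficient(g, labels, v)
        for (m in mods)
          add("participation_module", m, pc$module_mean[[as.character(m)]])
      }
    }
  }
  do.call(rbind, out)
}

#' Measure curves for a whole cohort
#'
#' Runs [measure_suite()] per subject and binds the results with a
#' `subject_id` column.
#'
#' @param stacks named list of per-subject `conn_stack` objects.
#' @param partition fixed group partition.
#' @param ... passed to [measure_suite()].
#' @return long data.frame with `subject_id` first.
#' @export
cohort_measures <- function(stacks, partition, ...) {
  ids <- names(stacks)
  if (is.null(ids)) ids <- as.character(seq_along(stacks))
  res <- lapply(seq_along(stacks), function(i) {
    m <- measure_suite(stacks[[i]], partition, ...)
    cbind(subject_id = ids[i], m, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
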