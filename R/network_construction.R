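# Connectivity construction: Pearson matrices with short-distance and
# diagonal zeroing, proportional thresholding, and the density-grid stack.

#' Pearson connectivity matrix with distance exclusion
#'
#' Correlates every pair of ROI series over the retained volumes, zeroes
#' entries whose ROI centres lie strictly closer than `min_distance_mm`
#' (shared non-biological signal between adjacent spheres), and zeroes the
#' diagonal. A constant ROI series has undefined correlations; its row and
#' column are set to 0 with a warning.
#'
#' @param ts numeric matrix, volumes x ROIs (already cleaned/scrubbed).
#' @param coords numeric matrix or data.frame, ROIs x 3, millimetre
#'   coordinates in the same ROI order as `ts` columns; NULL skips distance
#'   exclusion.
#' @param min_distance_mm exclusion radius, strict inequality (default 20).
#' @return symmetric N x N matrix, zero diagonal.
#' @export
correlation_matrix <- function(ts, coords = NULL, min_distance_mm = 20) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 3)
    stop("need at least 3 retained volumes to correlate", call. = FALSE)
  n_roi <- ncol(ts)
  sds <- apply(ts, 2, sd)
  const <- sds == 0 | !is.finite(sds)
  r <- suppressWarnings(cor(ts))
  if (any(const)) {
    warning(sum(const), " constant ROI series; correlations set to 0",
            call. = FALSE)
    r[const, ] <- 0
    r[, const] <- 0
  }
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (nrow(coords) != n_roi || ncol(coords) != 3)
      stop("coords must be ROIs x 3 and match the time-series columns",
           call. = FALSE)
    d <- as.matrix(dist(coords))
    r[d < min_distance_mm] <- 0
  }
  diag(r) <- 0
  r[!is.finite(r)] <- 0
  dimnames(r) <- list(colnames(ts), colnames(ts))
  r
}

#' Proportional threshold at one density
#'
#' Keeps the `k = round(tau * M)` strongest of the `M = N(N-1)/2` candidate
#' edges, ranking by signed correlation (largest first) with deterministic
#' lexicographic (row, column) tie-breaking, where `round` is half away from
#' zero. At the densities studied here (<= 30 %) this retains positive edges
#' only; if fewer than `k` positive edges exist, all positive edges are kept
#' and a warning is raised.
#'
#' @param r symmetric matrix with zero diagonal.
#' @param density target edge fraction in (0, 1].
#' @return list with `weighted` (thresholded values) and `binary` (0/1)
#'   matrices sharing the same nonzero pattern.
#' @export
proportional_threshold <- function(r, density) {
  stopifnot_scalar_number(density, "density")
  if (density <= 0 || density > 1)
    stop("density must be in (0, 1]", call. = FALSE)
  n <- nrow(r)
  if (!isTRUE(all.equal(r, t(r), tolerance = 1e-12)))
    stop("matrix must be symmetric", call. = FALSE)
  if (any(diag(r) != 0))
    stop("diagonal must be zero", call. = FALSE)
  m_cand <- n * (n - 1) / 2
  k <- floor(density * m_cand + 0.5)  # half away from zero (values positive)
  if (k < 1)
    stop("density rounds to zero edges for this matrix size", call. = FALSE)
  ut <- which(upper.tri(r))
  w <- r[ut]
  ij <- arrayInd(ut, dim(r))
  ord <- order(-w, ij[, 1], ij[, 2])
  pos <- sum(w > 0)
  if (k > pos) {
    warning(sprintf(
      "only %d positive edges available for target %d; keeping all positive",
      pos, k), call. = FALSE)
    k <- pos
    if (k == 0) stop("no positive edges to retain", call. = FALSE)
  }
  keep <- ut[ord[seq_len(k)]]
  wt <- matrix(0, n, n, dimnames = dimnames(r))
  wt[keep] <- r[keep]
  wt <- wt + t(wt)
  bin <- matrix(0, n, n, dimnames = dimnames(r))
  bin[keep] <- 1
  bin <- bin + t(bin)
  list(weighted = wt, binary = bin, k = k)
}

#' Build a thresholded connectivity stack over a density grid
#'
#' Applies [proportional_threshold()] at every grid density (default 1 % to
#' 30 % in 1 % steps) and verifies the nesting invariant: the edge set at a
#' lower density is a subset of the edge set at any higher density.
#'
#' @param r symmetric connectivity matrix, zero diagonal.
#' @param densities increasing vector of edge fractions.
#' @return object of class `conn_stack`: list with `raw`, `densities`,
#'   `weighted` (list of matrices), `binary` (list of matrices).
#' @export
build_stack <- function(r, densities = seq(0.01, 0.30, by = 0.01)) {
  if (length(densities) < 1 || is.unsorted(densities, strictly = TRUE))
    stop("densities must be strictly increasing", call. = FALSE)
  th <- lapply(densities, function(d) proportional_threshold(r, d))
  weighted <- lapply(th, `[[`, "weighted")
  binary <- lapply(th, `[[`, "binary")
  for (i in seq_along(densities)[-1]) {
    if (any(binary[[i - 1]] > binary[[i]]))
      stop("internal error: edge nesting violated across densities",
           call. = FALSE)
  }
  structure(list(raw = r, densities = densities,
                 weighted = weighted, binary = binary),
            class = "conn_stack")
}

#' @export
print.conn_stack <- function(x, ...) {
  cat(sprintf("conn_stack: %d ROIs, %d densities (%.0f%%-%.0f%%)\n",
              nrow(x$raw), length(x$densities),
              100 * min(x$densities), 100 * max(x$densities)))
  invisible(x)
}
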