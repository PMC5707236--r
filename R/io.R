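# Plain-text (TSV) interfaces for every table the pipeline exchanges:
# genotypes, phenotypes, per-subject time series, motion traces, nuisance
# regressors, ROI coordinates, partitions and long-format measures.

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, ...)
}

#' Read a per-subject ROI time-series table
#'
#' TSV with one header row of ROI ids and one row per volume.
#'
#' @param path TSV path.
#' @return numeric matrix, volumes x ROIs.
#' @export
read_timeseries_tsv <- function(path) {
  df <- read_tsv(path, check.names = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) stop("non-finite values in time series",
                               call. = FALSE)
  m
}

#' Read an ROI coordinate table
#'
#' TSV with columns `roi_id`, `x`, `y`, `z` (millimetres).
#'
#' @param path TSV path.
#' @return data.frame with those four columns.
#' @export
read_coords_tsv <- function(path) {
  df <- read_tsv(path)
  need <- c("roi_id", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("coordinate table must have columns roi_id, x, y, z", call. = FALSE)
  if (anyDuplicated(df$roi_id)) stop("duplicate roi_id", call. = FALSE)
  if (any(!is.finite(as.matrix(df[, c("x", "y", "z")]))))
    stop("non-finite coordinates", call. = FALSE)
  df[, need]
}

#' Read a phenotype table
#'
#' TSV with columns `subject_id`, `neuroticism`.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_phenotype_tsv <- function(path) {
  df <- read_tsv(path)
  if (!all(c("subject_id", "neuroticism") %in% names(df)))
    stop("phenotype table must have subject_id and neuroticism",
         call. = FALSE)
  if (any(!is.finite(df$neuroticism)))
    stop("non-finite neuroticism scores", call. = FALSE)
  df
}

#' Write a synthetic cohort to a directory of TSV files
#'
#' Emits `genotypes.tsv`, `phenotypes.tsv`, `coords.tsv`,
#' `ground_truth_labels.tsv` and per-subject `ts_<id>.tsv`,
#' `motion_<id>.tsv`, `nuisance_<id>.tsv`; everything round-trips through
#' the package's readers.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(cohort$genotypes, file.path(dir, "genotypes.tsv"))
  write_tsv(cohort$phenotypes, file.path(dir, "phenotypes.tsv"))
  write_tsv(cohort$coords, file.path(dir, "coords.tsv"))
  write_tsv(data.frame(roi_id = cohort$coords$roi_id,
                       module = cohort$ground_truth$module_labels),
            file.path(dir, "ground_truth_labels.tsv"))
  for (id in names(cohort$timeseries)) {
    write_tsv(as.data.frame(cohort$timeseries[[id]]),
              file.path(dir, sprintf("ts_%s.tsv", id)))
    write_tsv(as.data.frame(cohort$motion[[id]]),
              file.path(dir, sprintf("motion_%s.tsv", id)))
    write_tsv(as.data.frame(cohort$nuisance[[id]]),
              file.path(dir, sprintf("nuisance_%s.tsv", id)))
  }
  invisible(dir)
}

#' Write a module partition table
#' @param partition `module_partition`.
#' @param roi_ids ROI ids in node order.
#' @param path TSV path.
#' @export
write_partition_tsv <- function(partition, roi_ids, path) {
  write_tsv(data.frame(roi_id = roi_ids, module = partition$labels),
            path)
}

#' Write a connectivity matrix as a square TSV
#'
#' Header row of ROI ids and an roi_id first column.
#'
#' @param m square matrix with ROI dimnames (or supply `roi_ids`).
#' @param path TSV path.
#' @param roi_ids optional ids if `m` has no dimnames.
#' @export
write_matrix_tsv <- function(m, path, roi_ids = rownames(m)) {
  if (is.null(roi_ids)) roi_ids <- sprintf("roi%03d", seq_len(nrow(m)))
  df <- data.frame(roi_id = roi_ids, m, check.names = FALSE)
  colnames(df) <- c("roi_id", roi_ids)
  write_tsv(df, path)
}

#' Read a connectivity matrix written by [write_matrix_tsv()]
#' @param path TSV path.
#' @return numeric matrix with ROI dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- read_tsv(path, check.names = FALSE)
  ids <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  dimnames(m) <- list(ids, colnames(df)[-1])
  if (nrow(m) != ncol(m)) stop("matrix TSV is not square", call. = FALSE)
  m
}
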