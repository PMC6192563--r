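#' Read and write connectomes as tab-separated files
#'
#' The on-disk representation is a pair of plain-text files: a square weight
#' matrix TSV whose header row and first column carry the region labels, and a
#' five-column region metadata TSV (`label`, `x_mm`, `y_mm`, `z_mm`,
#' `volume_mm3`). Reading validates symmetry (asymmetries beyond a `1e-9`
#' relative tolerance are an error), nonnegativity and label consistency
#' between the two files.
#'
#' @param matrix_path path to the weight-matrix TSV.
#' @param metadata_path path to the region metadata TSV.
#' @return `read_connectome` returns a `connectome`.
#' @export
read_connectome <- function(matrix_path, metadata_path) {
  mat <- utils::read.table(matrix_path, header = TRUE, sep = "\t",
                           row.names = 1, check.names = FALSE)
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat)) stop("connectome matrix file is not square")
  if (!identical(rownames(mat), colnames(mat)))
    stop("row and column labels disagree in ", matrix_path)
  meta <- utils::read.table(metadata_path, header = TRUE, sep = "\t",
                            check.names = FALSE,
                            colClasses = c(label = "character"))
  need <- c("label", "x_mm", "y_mm", "z_mm", "volume_mm3")
  if (!all(need %in% names(meta)))
    stop("metadata file must have columns: ", paste(need, collapse = ", "))
  missing <- setdiff(rownames(mat), meta$label)
  if (length(missing) > 0)
    stop("metadata missing labels: ", paste(missing, collapse = ", "))
  meta <- meta[match(rownames(mat), meta$label), ]
  connectome(mat, rownames(mat),
             as.matrix(meta[, c("x_mm", "y_mm", "z_mm")]),
             meta$volume_mm3)
}

#' @rdname read_connectome
#' @param conn a `connectome` to write.
#' @return `write_connectome` returns the paths invisibly.
#' @export
write_connectome <- function(conn, matrix_path, metadata_path) {
  stopifnot(inherits(conn, "connectome"))
  mat <- data.frame(label = conn$labels, conn$A, check.names = FALSE)
  utils::write.table(format(mat, digits = 17, trim = TRUE), matrix_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(label = conn$labels,
                     x_mm = conn$centroids[, 1],
                     y_mm = conn$centroids[, 2],
                     z_mm = conn$centroids[, 3],
                     volume_mm3 = conn$volumes)
  utils::write.table(format(meta, digits = 17, trim = TRUE), metadata_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(matrix_path, metadata_path))
}

#' Read and write region sets as newline-delimited label lists
#'
#' @param path file path; one region label per line.
#' @param name set name; defaults to the file name without extension.
#' @return `read_region_set` returns a `region_set`.
#' @export
read_region_set <- function(path, name = NULL) {
  labels <- readLines(path)
  labels <- labels[nzchar(trimws(labels))]
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  region_set(name, trimws(labels))
}

#' @rdname read_region_set
#' @param set a `region_set` to write.
#' @export
write_region_set <- function(set, path) {
  writeLines(set$labels, path)
  invisible(path)
}

#' Read and write behavior tables
#'
#' Behavior tables hold per-subject, per-task, per-condition median response
#' times in ms, as a TSV with columns `subject_id`, `task`, `condition`,
#' `median_rt_ms`.
#'
#' @param path file path.
#' @return `read_behavior` returns a data.frame.
#' @export
read_behavior <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = c(subject_id = "character",
                                          task = "character",
                                          condition = "character"))
  need <- c("subject_id", "task", "condition", "median_rt_ms")
  if (!all(need %in% names(tab)))
    stop("behavior file must have columns: ", paste(need, collapse = ", "))
  tab
}

#' @rdname read_behavior
#' @param behavior behavior data.frame to write.
#' @export
write_behavior <- function(behavior, path) {
  utils::write.table(behavior, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a simulation trace as a tabular time series
#'
#' Writes a TSV with a `time_ms` column followed by one excitatory-activity
#' column per region. Intended for inspection and plotting of short runs.
#'
#' @param trace a `sim_trace` from [simulate_network()].
#' @param path file path.
#' @param stride_ms sampling stride in ms (default 1).
#' @export
write_trace <- function(trace, path, stride_ms = 1) {
  keep <- seq(1, length(trace$time_ms),
              by = max(1L, round(stride_ms / trace$step_h)))
  tab <- data.frame(time_ms = trace$time_ms[keep],
                    t(trace$E[, keep, drop = FALSE]), check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
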