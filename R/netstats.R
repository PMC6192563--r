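#' Weighted degree centrality
#'
#' `k_i = sum_j A_ij`, and its mean over regions.
#'
#' @param conn a `connectome`.
#' @return list with `per_region` (named vector) and `average`.
#' @export
weighted_degree <- function(conn) {
  k <- rowSums(conn$A)
  list(per_region = k, average = mean(k))
}

#' Spectral radius of the weight matrix
#'
#' The largest eigenvalue of the symmetric weight matrix; a global measure
#' related to the spread of synchronization in the network. Its inverse
#' bounds the coupling at which network-wide synchronization can onset.
#'
#' @param conn a `connectome`.
#' @return list with `spectral_radius` and `inverse` (error for an all-zero
#'   matrix, whose inverse is undefined).
#' @export
spectral_radius <- function(conn) {
  ev <- eigen(conn$A, symmetric = TRUE, only.values = TRUE)$values
  sr <- max(ev)
  if (sr <= 0) stop("spectral radius not positive: inverse undefined")
  list(spectral_radius = sr, inverse = 1 / sr)
}

#' Laplacian synchronizability
#'
#' The eigenratio `lambda_2(L) / lambda_max(L)` of the graph Laplacian
#' `L = D - A` (second-smallest over largest eigenvalue, counting
#' multiplicity). Values lie in `[0, 1]`; a disconnected graph scores 0.
#'
#' @param conn a `connectome`.
#' @return scalar in `[0, 1]`.
#' @export
synchronizability <- function(conn) {
  n <- nrow(conn$A)
  if (n < 2) stop("synchronizability needs at least 2 regions")
  L <- diag(rowSums(conn$A)) - conn$A
  ev <- sort(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  lmax <- ev[n]
  if (lmax <= 0) return(0)
  max(ev[2], 0) / lmax
}

#' Per-subject network feature table
#'
#' @param cohort named list of `connectome` objects.
#' @return data.frame with columns `subject_id`, `average_degree`,
#'   `spectral_radius`, `inverse_spectral_radius`, `synchronizability`.
#' @export
network_features <- function(cohort) {
  ids <- names(cohort)
  if (is.null(ids)) ids <- sprintf("S%02d", seq_along(cohort))
  rows <- lapply(seq_along(cohort), function(i) {
    conn <- cohort[[i]]
    sr <- spectral_radius(conn)
    data.frame(subject_id = ids[i],
               average_degree = weighted_degree(conn)$average,
               spectral_radius = sr$spectral_radius,
               inverse_spectral_radius = sr$inverse,
               synchronizability = synchronizability(conn))
  })
  do.call(rbind, rows)
}
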