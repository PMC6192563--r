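#' Construct a structural connectome
#'
#' A structural connectome is a weighted, undirected, zero-diagonal graph over
#' parcellated brain regions, together with region metadata (centroid
#' coordinates in mm and region volumes in mm^3). Inter-regional Euclidean
#' distances, used downstream to derive conduction delays, are computed from
#' the centroids at construction time.
#'
#' @param A n x n numeric matrix of nonnegative connection weights
#'   (dimensionless streamline density). Must be symmetric with a zero
#'   diagonal; asymmetries within `tol` (relative to the largest weight) are
#'   symmetrized by averaging, larger ones are an error.
#' @param labels character vector of n unique region labels.
#' @param centroids n x 3 numeric matrix of region centroid coordinates (mm).
#' @param volumes numeric vector of n strictly positive region volumes (mm^3).
#' @param tol relative asymmetry tolerance (default `1e-9`).
#' @return An object of class `connectome` with elements `labels`, `A`,
#'   `centroids`, `volumes` and the derived distance matrix `distances` (mm).
#' @examples
#' A <- matrix(c(0, 1, 1, 0), 2, 2)
#' xyz <- rbind(c(0, 0, 0), c(10, 0, 0))
#' conn <- connectome(A, c("L1", "R1"), xyz, c(500, 600))
#' conn$distances[1, 2]  # 10 mm
#' @export
connectome <- function(A, labels, centroids, volumes, tol = 1e-9) {
  A <- as.matrix(A)
  n <- nrow(A)
  if (ncol(A) != n) stop("connection matrix must be square")
  if (length(labels) != n) stop("need one label per region")
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("region labels must be unique")
  if (any(!is.finite(A))) stop("connection weights must be finite")
  if (any(A < 0)) stop("connection weights must be nonnegative")

  scale <- max(abs(A), 1e-300)
  asym <- max(abs(A - t(A)))
  if (asym > tol * scale) {
    stop(sprintf("connection matrix asymmetry %.3g exceeds tolerance %.3g",
                 asym / scale, tol))
  }
  A <- (A + t(A)) / 2
  if (any(diag(A) != 0)) {
    if (max(abs(diag(A))) > tol * scale) stop("diagonal must be zero")
    diag(A) <- 0
  }

  centroids <- as.matrix(centroids)
  if (nrow(centroids) != n || ncol(centroids) != 3)
    stop("centroids must be an n x 3 matrix (mm)")
  if (any(!is.finite(centroids))) stop("centroids must be finite")
  volumes <- as.numeric(volumes)
  if (length(volumes) != n) stop("need one volume per region")
  if (any(!is.finite(volumes)) || any(volumes <= 0))
    stop("volumes must be strictly positive")

  dimnames(A) <- list(labels, labels)
  rownames(centroids) <- labels
  colnames(centroids) <- c("x_mm", "y_mm", "z_mm")
  names(volumes) <- labels

  structure(
    list(labels = labels, A = A, centroids = centroids, volumes = volumes,
         distances = as.matrix(stats::dist(centroids))),
    class = "connectome"
  )
}

#' @export
print.connectome <- function(x, ...) {
  n <- length(x$labels)
  nz <- sum(x$A[upper.tri(x$A)] > 0)
  cat(sprintf("structural connectome: %d regions, %d edges (density %.3f)\n",
              n, nz, nz / (n * (n - 1) / 2)))
  cat(sprintf("  weight range [%.4g, %.4g], centroid extent %.1f mm\n",
              min(x$A), max(x$A), max(x$distances)))
  invisible(x)
}

#' Number of regions in a connectome
#' @param conn a `connectome`.
#' @return integer region count.
#' @export
n_regions <- function(conn) length(conn$labels)

#' Build connectome weights from streamline counts
#'
#' Converts a symmetric matrix of inter-regional streamline counts into
#' connection densities by normalizing each count by the sum of the volumes of
#' the two regions it connects: `A_ij = counts_ij / (vol_i + vol_j)`.
#'
#' @param counts n x n symmetric nonnegative matrix of streamline counts with
#'   zero diagonal.
#' @param volumes n strictly positive region volumes (mm^3).
#' @param labels optional region labels (defaults to `V1..Vn`).
#' @param centroids optional n x 3 centroid matrix; defaults to the origin for
#'   all regions (distances zero), suitable when only graph statistics are
#'   needed.
#' @return a `connectome`.
#' @examples
#' build_from_streamlines(matrix(c(0, 10, 10, 0), 2), volumes = c(2, 3))$A[1, 2]
#' @export
build_from_streamlines <- function(counts, volumes, labels = NULL,
                                   centroids = NULL) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  if (any(counts < 0)) stop("streamline counts must be nonnegative")
  volumes <- as.numeric(volumes)
  if (any(volumes <= 0)) stop("volumes must be strictly positive")
  A <- counts / outer(volumes, volumes, `+`)
  diag(A) <- 0
  if (is.null(labels)) labels <- paste0("V", seq_len(n))
  if (is.null(centroids)) centroids <- matrix(0, n, 3)
  connectome(A, labels, centroids, volumes)
}

#' Shuffle connectome edge weights (randomization null)
#'
#' Randomizes network organization while preserving the overall connectivity
#' distribution: the multiset of upper-triangle weight values (zeros included)
#' is randomly reassigned to region pairs. Total weight, and hence average
#' weighted degree, is conserved exactly; topology is not preserved.
#'
#' @param conn a `connectome`.
#' @param seed integer seed for the permutation.
#' @return a `connectome` with permuted weights and unchanged metadata.
#' @export
shuffle_edge_weights <- function(conn, seed) {
  stopifnot(inherits(conn, "connectome"))
  n <- n_regions(conn)
  ut <- upper.tri(conn$A)
  w <- conn$A[ut]
  perm <- with_seed(seed, sample.int(length(w)))
  A <- matrix(0, n, n)
  A[ut] <- w[perm]
  A <- A + t(A)
  connectome(A, conn$labels, conn$centroids, conn$volumes)
}

#' Cross-subject structural variability maps
#'
#' Edge-level variability is the standard deviation of each connection weight
#' across subjects normalized by its mean across subjects (sample sd,
#' denominator n-1). Edges whose weight is zero in every subject have an
#' undefined ratio and are returned as `NA`. The regional map averages each
#' region's defined incident edge values.
#'
#' @param cohort list of `connectome` objects sharing region labels.
#' @return list with `edge_map` (n x n, `NA` where undefined) and
#'   `regional_map` (length-n named vector).
#' @export
structural_variability <- function(cohort) {
  check_cohort(cohort)
  variability_maps(lapply(cohort, function(x) x$A), cohort[[1]]$labels)
}

# std/mean maps shared by structural and functional variability
variability_maps <- function(mats, labels) {
  arr <- simplify2array(mats)
  mu <- apply(arr, c(1, 2), mean)
  sd <- apply(arr, c(1, 2), stats::sd)
  edge <- sd / mu
  edge[mu == 0] <- NA_real_
  diag(edge) <- NA_real_
  dimnames(edge) <- list(labels, labels)
  regional <- apply(edge, 1, function(r) {
    if (all(is.na(r))) NA_real_ else mean(r, na.rm = TRUE)
  })
  list(edge_map = edge, regional_map = regional)
}

check_cohort <- function(cohort) {
  if (length(cohort) < 2) stop("variability needs at least 2 subjects")
  labs <- cohort[[1]]$labels
  for (x in cohort) {
    if (!inherits(x, "connectome")) stop("cohort must be a list of connectomes")
    if (!identical(x$labels, labs)) stop("cohort subjects must share labels")
  }
  invisible(TRUE)
}

#' Define a named region set
#'
#' Region sets name functional groupings of connectome regions: the
#' stimulation seed (e.g. the four left-inferior-frontal-gyrus regions) or an
#' a-priori task circuit.
#'
#' @param name set name.
#' @param labels character vector of region labels (unique, nonempty).
#' @param conn optional `connectome` to validate membership against.
#' @return object of class `region_set`.
#' @export
region_set <- function(name, labels, conn = NULL) {
  labels <- as.character(labels)
  if (length(labels) == 0) stop("region set must be nonempty")
  if (anyDuplicated(labels)) stop("region set labels must be unique")
  if (!is.null(conn)) {
    missing <- setdiff(labels, conn$labels)
    if (length(missing) > 0)
      stop("region set labels absent from connectome: ",
           paste(missing, collapse = ", "))
  }
  structure(list(name = name, labels = labels), class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("region set '%s' (%d regions)\n", x$name, length(x$labels)))
  invisible(x)
}

region_indices <- function(set, conn) {
  idx <- match(set$labels, conn$labels)
  if (anyNA(idx))
    stop("region set '", set$name, "' labels absent from connectome: ",
         paste(set$labels[is.na(idx)], collapse = ", "))
  idx
}
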