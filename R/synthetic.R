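#' Specify a synthetic cohort
#'
#' Defines the statistical structure of a synthetic cohort of structural
#' connectomes: sparse symmetric nonnegative matrices with heavy-tailed
#' (log-normal) weights, a two-hemisphere block structure, an optional
#' planted densely connected task circuit, and common region geometry
#' (centroids and volumes shared across subjects, mirroring a common
#' parcellation atlas).
#'
#' Each subject's matrix is an independent realization of the same ensemble:
#' edge placement and edge weights are redrawn per subject, then the matrix
#' is normalized to a common mean weighted degree (`mean_strength`). This
#' emulates deterministic tractography runs that reconstruct a fixed total
#' number of streamlines per subject, so individuals differ in how
#' connectivity is organized, not in how much of it they have. The sparse
#' default density keeps the dynamics sensitive to that organization.
#' `mean_strength` sets the overall coupling scale and is chosen so the
#' excitability transition of the coupled dynamics falls inside the
#' conventional coupling sweep window (0.05-0.25).
#'
#' @param n_subjects number of subjects (>= 1).
#' @param n_regions number of regions (>= 8, even).
#' @param density fraction of off-diagonal pairs carrying a nonzero weight,
#'   in (0, 1].
#' @param weight_sdlog log-scale standard deviation of the log-normal weight
#'   family.
#' @param hemisphere_block_bonus multiplicative weight factor (>= 1) for
#'   within-hemisphere edges.
#' @param circuit_labels optional character vector of region labels forming a
#'   planted task circuit (labels are `L01..` / `R01..`); `NULL` for none.
#' @param circuit_bonus multiplicative weight factor (>= 1) for edges with
#'   both endpoints in the planted circuit.
#' @param circuit_density edge density among circuit pairs (defaults to
#'   `density`; raise it to plant a densely connected subnetwork).
#' @param coordinate_extent spatial extent of the brain in mm; the two
#'   hemisphere centroid clouds are separated by half this value.
#' @param volume_range length-2 positive interval (mm^3) for region volumes.
#' @param mean_strength target mean weighted degree (mean row sum) each
#'   subject's matrix is normalized to.
#' @param seed integer cohort seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 10, n_regions = 50, density = 0.08,
                        weight_sdlog = 1, hemisphere_block_bonus = 2,
                        circuit_labels = NULL, circuit_bonus = 1,
                        circuit_density = NULL,
                        coordinate_extent = 140, volume_range = c(500, 8000),
                        mean_strength = 85, seed = 1L) {
  if (n_regions < 8) stop("n_regions must be >= 8")
  if (n_regions %% 2 != 0) stop("n_regions must be even (two hemispheres)")
  if (density <= 0 || density > 1) stop("density must be in (0, 1]")
  if (hemisphere_block_bonus < 1 || circuit_bonus < 1)
    stop("bonuses must be >= 1")
  if (is.null(circuit_density)) circuit_density <- density
  if (circuit_density <= 0 || circuit_density > 1)
    stop("circuit_density must be in (0, 1]")
  if (length(volume_range) != 2 || any(volume_range <= 0) ||
      diff(volume_range) < 0)
    stop("volume_range must be a positive increasing interval")
  if (weight_sdlog <= 0) stop("weight_sdlog must be positive")
  if (mean_strength <= 0) stop("mean_strength must be positive")
  labels <- hemisphere_labels(n_regions)
  if (!is.null(circuit_labels)) {
    circuit_labels <- as.character(circuit_labels)
    bad <- setdiff(circuit_labels, labels)
    if (length(bad) > 0)
      stop("circuit labels not in the atlas: ", paste(bad, collapse = ", "))
  }
  structure(
    list(n_subjects = as.integer(n_subjects), n_regions = as.integer(n_regions),
         density = density, weight_sdlog = weight_sdlog,
         hemisphere_block_bonus = hemisphere_block_bonus,
         circuit_labels = circuit_labels, circuit_bonus = circuit_bonus,
         circuit_density = circuit_density,
         coordinate_extent = coordinate_extent, volume_range = volume_range,
         mean_strength = mean_strength, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

hemisphere_labels <- function(n) {
  half <- n %/% 2
  c(sprintf("L%02d", seq_len(half)), sprintf("R%02d", seq_len(half)))
}

# Cohort-level geometry shared by all subjects: labels, centroids (two
# Gaussian clouds split along x), volumes, hemisphere assignment.
cohort_geometry <- function(spec) {
  n <- spec$n_regions
  half <- n %/% 2
  labels <- hemisphere_labels(n)
  with_seed(spec$seed, {
    sep <- spec$coordinate_extent / 2
    cloud_sd <- spec$coordinate_extent / 8
    hemi <- rep(c(-1, 1), each = half)
    centroids <- cbind(
      x_mm = hemi * sep / 2 + stats::rnorm(n, 0, cloud_sd),
      y_mm = stats::rnorm(n, 0, cloud_sd),
      z_mm = stats::rnorm(n, 0, cloud_sd)
    )
    volumes <- stats::runif(n, spec$volume_range[1], spec$volume_range[2])
    list(labels = labels, centroids = centroids, volumes = volumes,
         hemisphere = rep(c("L", "R"), each = half))
  })
}

#' Generate one synthetic structural connectome
#'
#' @param spec a [cohort_spec()].
#' @param subject_index 1-based subject index (<= `n_subjects`).
#' @return a `connectome`. Identical `(spec, subject_index)` give identical
#'   output.
#' @export
generate_connectome <- function(spec, subject_index) {
  stopifnot(inherits(spec, "cohort_spec"))
  subject_index <- as.integer(subject_index)
  if (subject_index < 1 || subject_index > spec$n_subjects)
    stop("subject_index must be in 1..n_subjects")
  geo <- cohort_geometry(spec)
  n <- spec$n_regions
  in_circuit <- if (is.null(spec$circuit_labels)) rep(FALSE, n)
                else geo$labels %in% spec$circuit_labels
  ut <- upper.tri(matrix(0, n, n))
  circ_pair <- outer(in_circuit, in_circuit, `&`)
  bg_cells <- which(ut & !circ_pair)
  circ_cells <- which(ut & circ_pair)

  A <- with_seed(derive_seed(spec$seed, subject_index), {
    pick <- function(cells, dens) {
      k <- max(1L, round(dens * length(cells)))
      if (length(cells) == 0) integer(0) else cells[sample.int(length(cells), k)]
    }
    on_bg <- pick(bg_cells, spec$density)
    on_circ <- if (length(circ_cells) > 0) pick(circ_cells, spec$circuit_density)
               else integer(0)
    cells <- c(on_bg, on_circ)
    A <- matrix(0, n, n)
    A[cells] <- stats::rlnorm(length(cells), meanlog = 0,
                              sdlog = spec$weight_sdlog)
    A
  })

  # multiplicative block structure: hemispheres, then the planted circuit
  same_hemi <- outer(geo$hemisphere, geo$hemisphere, `==`)
  bonus <- ifelse(same_hemi, spec$hemisphere_block_bonus, 1)
  bonus <- bonus * ifelse(circ_pair, spec$circuit_bonus, 1)
  A <- A * bonus
  A <- A + t(A)
  A <- A * (spec$mean_strength * n / sum(A))
  connectome(A, geo$labels, geo$centroids, geo$volumes)
}

#' Generate a synthetic cohort of connectomes
#'
#' @param spec a [cohort_spec()].
#' @return list of `n_subjects` connectomes named `S01..`, sharing labels,
#'   centroids and volumes; weights differ between subjects.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  cohort <- lapply(seq_len(spec$n_subjects),
                   function(i) generate_connectome(spec, i))
  names(cohort) <- sprintf("S%02d", seq_len(spec$n_subjects))
  cohort
}

#' Specify synthetic behavior generation
#'
#' Response times are generated as a linear function of a chosen
#' model-derived feature plus Gaussian noise:
#' `RT = intercept + slope * z(feature) + N(0, noise_sd)`, with the feature
#' z-scored so the slope has stable units (ms per standard deviation) across
#' feature types. With `driving_feature = "independent"` the RTs ignore the
#' features entirely (a null cohort).
#'
#' Defaults emulate a language-task response-time scale: 600 ms intercept,
#' 50 ms/SD slope, 15 ms residual noise.
#'
#' @param intercept_ms mean response time (ms).
#' @param slope response-time change (ms) per standard deviation of the
#'   driving feature.
#' @param noise_sd_ms residual noise sd (ms, >= 0).
#' @param driving_feature one of `"c5T"`, `"circuit_functional_effect"`,
#'   `"independent"`.
#' @param seed integer seed.
#' @return object of class `behavior_spec`.
#' @export
behavior_spec <- function(intercept_ms = 600, slope = 50, noise_sd_ms = 15,
                          driving_feature = c("c5T",
                                              "circuit_functional_effect",
                                              "independent"),
                          seed = 1L) {
  if (noise_sd_ms < 0) stop("noise_sd_ms must be >= 0")
  structure(
    list(intercept_ms = intercept_ms, slope = slope,
         noise_sd_ms = noise_sd_ms,
         driving_feature = match.arg(driving_feature),
         seed = as.integer(seed)),
    class = "behavior_spec"
  )
}

#' Generate synthetic response times from model features
#'
#' @param features named numeric vector of per-subject feature values (the
#'   realized values of `driving_feature`; ignored except for names/length
#'   when `driving_feature = "independent"`).
#' @param spec a [behavior_spec()].
#' @param task,condition labels stored in the output table.
#' @return data.frame with columns `subject_id`, `task`, `condition`,
#'   `median_rt_ms`.
#' @export
generate_behavior <- function(features, spec, task = "task",
                              condition = "before") {
  stopifnot(inherits(spec, "behavior_spec"))
  n <- length(features)
  if (n < 3) stop("need at least 3 subjects")
  if (any(!is.finite(features))) stop("features must be finite")
  ids <- names(features)
  if (is.null(ids)) ids <- sprintf("S%02d", seq_len(n))
  rt <- with_seed(spec$seed, {
    eps <- stats::rnorm(n, 0, spec$noise_sd_ms)
    if (spec$driving_feature == "independent") {
      spec$intercept_ms + eps
    } else {
      if (stats::sd(features) == 0)
        stop("degenerate input: features have zero variance")
      z <- (features - mean(features)) / stats::sd(features)
      spec$intercept_ms + spec$slope * z + eps
    }
  })
  data.frame(subject_id = ids, task = task, condition = condition,
             median_rt_ms = rt)
}
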