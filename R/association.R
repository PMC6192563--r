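#' Bootstrapped Pearson correlation
#'
#' Pearson r with a two-sided p-value from the standard t reference
#' distribution, and a quantile confidence interval from resampling subject
#' pairs with replacement (default 5000 resamples, 0.05/0.95 quantiles, i.e.
#' a 90% CI). Degenerate resamples (zero variance in either coordinate) are
#' redrawn.
#'
#' @param x,y paired numeric vectors (n >= 3, nonzero variance).
#' @param n_boot number of bootstrap resamples.
#' @param quantiles lower/upper CI quantiles.
#' @param seed integer seed.
#' @param feature,task,condition labels carried into the result row.
#' @return one-row data.frame of class `association_result`: `feature`,
#'   `task`, `condition`, `n`, `r`, `p`, `ci_low`, `ci_high`.
#' @export
pearson_bootstrap <- function(x, y, n_boot = 5000, quantiles = c(0.05, 0.95),
                              seed = 1L, feature = "feature", task = "task",
                              condition = "before") {
  stopifnot(length(x) == length(y), length(x) >= 3, n_boot >= 1)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("x and y must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero-variance input")
  ct <- stats::cor.test(x, y, method = "pearson")
  n <- length(x)
  boot_r <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (stats::sd(x[idx]) > 0 && stats::sd(y[idx]) > 0)
          return(stats::cor(x[idx], y[idx]))
      }
    }, numeric(1))
  })
  ci <- stats::quantile(boot_r, quantiles, names = FALSE, type = 7)
  out <- data.frame(feature = feature, task = task, condition = condition,
                    n = n, r = unname(ct$estimate), p = ct$p.value,
                    ci_low = ci[1], ci_high = ci[2])
  class(out) <- c("association_result", "data.frame")
  out
}

#' FDR correction across tasks
#'
#' Benjamini-Hochberg adjustment of a feature's p-values across the task
#' family; an association is significant when its adjusted p-value is below
#' `alpha`. When `results` holds several features and/or conditions, each
#' (feature, condition) group is corrected separately across its tasks.
#'
#' @param results an `association_result` data.frame (rows may cover several
#'   features, tasks, conditions), or a bare numeric vector of p-values.
#' @param alpha significance level (default 0.05).
#' @return the input with columns `p_adjusted` and `fdr_significant` added
#'   (for a bare vector: a list with `p_adjusted`, `significant`).
#' @export
fdr_across_tasks <- function(results, alpha = 0.05) {
  if (is.numeric(results)) {
    padj <- stats::p.adjust(results, method = "BH")
    return(list(p_adjusted = padj, significant = padj < alpha))
  }
  stopifnot(is.data.frame(results), "p" %in% names(results))
  grp <- interaction(results$feature, results$condition, drop = TRUE)
  results$p_adjusted <- NA_real_
  for (g in levels(grp)) {
    sel <- grp == g
    results$p_adjusted[sel] <- stats::p.adjust(results$p[sel], method = "BH")
  }
  results$fdr_significant <- results$p_adjusted < alpha
  results
}

#' Random-subnetwork null for circuit specificity
#'
#' Tests whether an observed circuit-level association could arise from an
#' arbitrary region subset of the same size: for each draw, a uniform random
#' subset of `circuit_size` regions is taken, the within-subset functional
#' effect is recomputed per subject from the already-computed change-in-FC
#' matrices (no re-simulation), and its Pearson correlation with behavior is
#' evaluated against the significance rule `r > r_thresh & p < p_thresh`.
#'
#' @param delta_list list (one per subject) of n x n change-in-FC matrices
#'   (or `stim_result` objects).
#' @param behavior numeric vector of per-subject response times, aligned
#'   with `delta_list`.
#' @param circuit_size subnetwork size (>= 2); the reference protocol uses
#'   the 22-region number-reading circuit size.
#' @param n_draws number of random subnetworks (reference protocol: 10000).
#' @param r_thresh,p_thresh significance rule (defaults 0.5 and 0.05).
#' @param true_circuit optional `region_set` for overlap bookkeeping.
#' @param seed integer seed.
#' @return list of class `null_summary`: `n_draws`, `fraction_significant`,
#'   and a data.frame `draws` with per-draw `r`, `p`, `significant`,
#'   `overlap` (fraction of the true circuit contained in the draw, `NA`
#'   without `true_circuit`).
#' @export
random_subnetwork_null <- function(delta_list, behavior, circuit_size,
                                   n_draws = 10000, r_thresh = 0.5,
                                   p_thresh = 0.05, true_circuit = NULL,
                                   seed = 1L) {
  if (n_draws < 1) stop("n_draws must be >= 1")
  if (circuit_size < 2) stop("circuit_size must be >= 2")
  delta_list <- lapply(delta_list, function(d)
    if (inherits(d, "stim_result")) d$delta else d)
  n_reg <- nrow(delta_list[[1]])
  if (circuit_size > n_reg) stop("circuit_size exceeds the number of regions")
  stopifnot(length(behavior) == length(delta_list))
  labs <- rownames(delta_list[[1]])
  true_idx <- if (!is.null(true_circuit)) match(true_circuit$labels, labs)

  draws <- with_seed(seed, {
    lapply(seq_len(n_draws), function(b) {
      idx <- sample.int(n_reg, circuit_size)
      eff <- vapply(delta_list, function(d) {
        sub <- d[idx, idx]
        mean(sub[upper.tri(sub)], na.rm = TRUE)
      }, numeric(1))
      if (stats::sd(eff) == 0 || anyNA(eff))
        return(c(r = NA_real_, p = NA_real_, overlap = NA_real_))
      ct <- stats::cor.test(eff, behavior)
      c(r = unname(ct$estimate), p = ct$p.value,
        overlap = if (is.null(true_idx)) NA_real_
                  else mean(true_idx %in% idx))
    })
  })
  draws <- as.data.frame(do.call(rbind, draws))
  draws$significant <- !is.na(draws$r) & draws$r > r_thresh &
    draws$p < p_thresh
  structure(
    list(n_draws = n_draws,
         rule = sprintf("r > %g and p < %g", r_thresh, p_thresh),
         fraction_significant = mean(draws$significant),
         draws = draws),
    class = "null_summary"
  )
}

#' @export
print.null_summary <- function(x, ...) {
  cat(sprintf(
    "random-subnetwork null: %d draws, %.2f%% significant under %s\n",
    x$n_draws, 100 * x$fraction_significant, x$rule))
  invisible(x)
}

#' Enumerate spatially contiguous candidate stimulation sites
#'
#' Builds a spatial adjacency graph over the circuit's regions (symmetric
#' k-nearest-neighbor on centroids) and enumerates its connected induced
#' subsets of `site_size` regions — candidate alternate stimulation sites
#' forming a continuous spatial volume.
#'
#' @param conn a `connectome`.
#' @param circuit a `region_set` to draw sites from.
#' @param site_size regions per site (default 4, matching the
#'   left-inferior-frontal-gyrus seed).
#' @param k neighbors per region in the adjacency graph (default 3).
#' @param max_sites cap on the number of sites returned; if more exist, a
#'   uniform sample of this size is taken (seeded).
#' @param seed seed used only when sampling down to `max_sites`.
#' @return list of `region_set` sites.
#' @export
enumerate_sites <- function(conn, circuit, site_size = 4, k = 3,
                            max_sites = 50, seed = 1L) {
  stopifnot(inherits(circuit, "region_set"))
  idx <- region_indices(circuit, conn)
  m <- length(idx)
  if (site_size < 1) stop("site_size must be >= 1")
  if (site_size > m) stop("site_size exceeds the circuit size")
  adj <- knn_adjacency(conn$centroids[idx, , drop = FALSE], k)
  subsets <- connected_subsets(adj, site_size)
  if (length(subsets) == 0)
    stop("no spatially contiguous group of ", site_size, " regions found")
  if (length(subsets) > max_sites)
    subsets <- with_seed(seed, sample(subsets, max_sites))
  lapply(seq_along(subsets), function(s) {
    region_set(sprintf("%s_site%02d", circuit$name, s),
               conn$labels[idx[subsets[[s]]]], conn)
  })
}

# symmetric k-nearest-neighbour adjacency (logical matrix, no self loops)
knn_adjacency <- function(centroids, k) {
  m <- nrow(centroids)
  D <- as.matrix(stats::dist(centroids))
  adj <- matrix(FALSE, m, m)
  for (i in seq_len(m)) {
    nn <- order(D[i, ])[-1][seq_len(min(k, m - 1))]
    adj[i, nn] <- TRUE
  }
  adj | t(adj)
}

# enumerate all connected induced vertex subsets of a given size.
# Standard recursive expansion: grow each subset only with neighbours of
# vertices already in it, restricted to indices above the anchor to avoid
# duplicates.
connected_subsets <- function(adj, size) {
  m <- nrow(adj)
  out <- list()
  grow <- function(members, frontier, banned) {
    if (length(members) == size) {
      out[[length(out) + 1L]] <<- sort(members)
      return(invisible())
    }
    cand <- setdiff(frontier, banned)
    while (length(cand) > 0) {
      v <- cand[1]
      cand <- cand[-1]
      banned <- c(banned, v)  # subsets not containing v handled by siblings
      new_frontier <- union(setdiff(cand, banned),
                            setdiff(which(adj[v, ]), c(members, v, banned)))
      grow(c(members, v), new_frontier, banned)
    }
  }
  for (anchor in seq_len(m)) {
    grow(anchor, setdiff(which(adj[anchor, ]), seq_len(anchor)),
         seq_len(anchor - 1L))
  }
  out
}

#' Alternate stimulation-site control
#'
#' Runs the full stimulation pipeline once per candidate site (continuous
#' spatial volumes of `site_size` regions inside the task circuit) for every
#' subject, and correlates each site's within-circuit functional effect with
#' behavior. The reference protocol identified 7 such volumes and found no
#' significant correlation for any of them, establishing specificity of the
#' true stimulation site.
#'
#' @param cohort named list of `connectome` objects.
#' @param params a [wc_params()].
#' @param c5T named per-subject transition values (aligned with `cohort`).
#' @param circuit a `region_set` task circuit (source of sites and scope of
#'   the functional effect).
#' @param behavior per-subject response times aligned with `cohort`.
#' @param site_size regions per site (default 4).
#' @param k,max_sites site enumeration controls (see [enumerate_sites()]).
#' @param seed integer seed.
#' @param n_boot bootstrap resamples per site association.
#' @param grid_step,stride_ms,window_ms,max_lag_ms pipeline settings passed
#'   through to the stimulation and FC stages.
#' @return `association_result` data.frame, one row per site (task column
#'   holds the site name).
#' @export
alternate_site_control <- function(cohort, params, c5T, circuit, behavior,
                                   site_size = 4, k = 3, max_sites = 7,
                                   seed = 1L, n_boot = 1000,
                                   grid_step = 0.001, stride_ms = 1,
                                   window_ms = 1000, max_lag_ms = 250) {
  if (length(circuit$labels) <= site_size)
    stop("circuit must be larger than site_size")
  sites <- enumerate_sites(cohort[[1]], circuit, site_size, k, max_sites,
                           seed)
  rows <- lapply(seq_along(sites), function(s) {
    eff <- vapply(seq_along(cohort), function(i) {
      exp <- run_stimulation_experiment(
        cohort[[i]], params, c5T[i], sites[[s]],
        seed = derive_seed(seed, s * 1000 + i), grid_step = grid_step)
      res <- delta_fc(exp, window_ms, max_lag_ms, stride_ms)
      functional_effect(res, circuit)
    }, numeric(1))
    pearson_bootstrap(eff, behavior, n_boot = n_boot,
                      seed = derive_seed(seed, s),
                      feature = "circuit_functional_effect",
                      task = sites[[s]]$name)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("association_result", "data.frame")
  out
}
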