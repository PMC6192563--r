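#' Run the full personalized-network analysis
#'
#' End-to-end orchestration over a cohort: per subject, a coupling sweep
#' detects the excitability transition c5T; the targeted stimulation
#' experiment is run one grid step below it and the change in functional
#' connectivity is reduced to global / within-circuit / outside-circuit
#' functional effects; graph statistics are computed from the structural
#' matrix; and every feature is correlated with behavioral response times
#' per task and condition using the bootstrapped Pearson machinery with
#' FDR correction across tasks.
#'
#' @param cohort named list of `connectome` objects (shared labels).
#' @param behavior data.frame with columns `subject_id`, `task`,
#'   `condition`, `median_rt_ms`; subject ids must match `names(cohort)`.
#' @param targets `region_set` of stimulation targets.
#' @param circuits named list of `region_set` task circuits, indexed by task
#'   name; tasks without an entry get no circuit-scoped features.
#' @param params a [wc_params()].
#' @param grid ascending c5 sweep grid.
#' @param sim_ms sweep analysis window per grid point (ms).
#' @param seed master seed; all stage seeds derive from it.
#' @param n_boot bootstrap resamples per association.
#' @param stride_ms FC sampling stride (ms).
#' @param jump_factor transition detection threshold.
#' @param include_netstats also correlate graph statistics with behavior.
#' @param report_path optional path; when given, the report (minus bulky
#'   matrices) is written there as JSON.
#' @return list of class `conndyn_report`: `subject_features` (data.frame),
#'   `associations` (FDR-annotated `association_result`), `stim_results`
#'   (per-subject `stim_result`), `curves` (per-subject sweep curves),
#'   `failures` (named list of per-subject error messages; empty when all
#'   subjects succeed).
#' @export
run_full_analysis <- function(cohort, behavior, targets, circuits = list(),
                              params = wc_params(),
                              grid = seq(0.05, 0.25, by = 0.001),
                              sim_ms = 1000, seed = 1L, n_boot = 5000,
                              stride_ms = 1, jump_factor = 5,
                              include_netstats = TRUE, report_path = NULL) {
  if (length(cohort) == 0) stop("configuration error: empty cohort")
  if (is.null(names(cohort)))
    names(cohort) <- sprintf("S%02d", seq_along(cohort))
  need <- c("subject_id", "task", "condition", "median_rt_ms")
  if (!all(need %in% names(behavior)))
    stop("configuration error: behavior must have columns ",
         paste(need, collapse = ", "))
  unknown <- setdiff(behavior$subject_id, names(cohort))
  if (length(unknown) > 0)
    stop("behavior references unknown subjects: ",
         paste(unique(unknown), collapse = ", "))
  grid_step <- if (length(grid) > 1) stats::median(diff(grid)) else 0.001

  curves <- list(); stim_results <- list(); failures <- list()
  feat_rows <- list()
  for (i in seq_along(cohort)) {
    id <- names(cohort)[i]
    res <- tryCatch({
      sw <- sweep_coupling(cohort[[i]], params, grid, sim_ms = sim_ms,
                           seed = derive_seed(seed, i))
      c5T <- detect_transition(sw, jump_factor)
      exp <- run_stimulation_experiment(cohort[[i]], params, c5T, targets,
                                        seed = derive_seed(seed, 10000 + i),
                                        grid_step = grid_step)
      sr <- delta_fc(exp, stride_ms = stride_ms)
      row <- data.frame(subject_id = id, c5T = c5T,
                        functional_effect_global =
                          functional_effect(sr, "global"))
      for (task in names(circuits)) {
        circ <- circuits[[task]]
        row[[paste0("functional_effect_circuit_", task)]] <-
          functional_effect(sr, circ)
        row[[paste0("functional_effect_outside_", task)]] <-
          functional_effect(sr, "outside", circuit = circ)
      }
      list(curve = sw, stim = sr, row = row)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[id]] <- conditionMessage(res)
    } else {
      curves[[id]] <- res$curve
      stim_results[[id]] <- res$stim
      feat_rows[[id]] <- res$row
    }
  }
  if (length(feat_rows) < 3)
    stop("fewer than 3 subjects completed the pipeline; failures: ",
         paste(names(failures), unlist(failures),
               sep = ": ", collapse = "; "))
  features <- do.call(rbind, feat_rows)
  if (include_netstats) {
    ns <- network_features(cohort[names(feat_rows)])
    features <- merge(features, ns, by = "subject_id", sort = FALSE)
  }

  associations <- associate_features(features, behavior, circuits,
                                     n_boot = n_boot, seed = seed)
  report <- structure(
    list(subject_features = features, associations = associations,
         stim_results = stim_results, curves = curves, failures = failures),
    class = "conndyn_report"
  )
  if (!is.null(report_path)) write_report(report, report_path)
  report
}

# correlate every feature column with behavior per (task, condition);
# circuit-scoped features only against their own task
associate_features <- function(features, behavior, circuits, n_boot = 5000,
                               seed = 1L) {
  cells <- unique(behavior[, c("task", "condition")])
  feature_cols <- setdiff(names(features), "subject_id")
  rows <- list()
  k <- 0
  for (ci in seq_len(nrow(cells))) {
    task <- cells$task[ci]; cond <- cells$condition[ci]
    beh <- behavior[behavior$task == task & behavior$condition == cond, ]
    y <- beh$median_rt_ms[match(features$subject_id, beh$subject_id)]
    ok <- !is.na(y)
    if (sum(ok) < 3) next
    for (f in feature_cols) {
      scoped <- grepl("^functional_effect_(circuit|outside)_", f)
      if (scoped && !grepl(paste0("_", task, "$"), f)) next
      fname <- if (scoped)
        sub(paste0("_", task, "$"), "", f) else f
      x <- features[[f]][ok]
      if (anyNA(x) || stats::sd(x) == 0) next
      k <- k + 1
      rows[[k]] <- pearson_bootstrap(
        x, y[ok], n_boot = n_boot, seed = derive_seed(seed, 20000 + k),
        feature = fname, task = task, condition = cond)
    }
  }
  if (length(rows) == 0) stop("no testable (feature, task) pairs")
  fdr_across_tasks(do.call(rbind, rows))
}

#' @export
print.conndyn_report <- function(x, ...) {
  cat(sprintf("personalized network analysis: %d subjects, %d associations\n",
              nrow(x$subject_features), nrow(x$associations)))
  if (length(x$failures) > 0)
    cat("  failed subjects:", paste(names(x$failures), collapse = ", "), "\n")
  sig <- x$associations[x$associations$fdr_significant, ]
  if (nrow(sig) > 0) {
    cat("  FDR-significant associations:\n")
    for (i in seq_len(nrow(sig)))
      cat(sprintf("    %s ~ %s (%s): r = %.2f, p = %.3g\n",
                  sig$feature[i], sig$task[i], sig$condition[i],
                  sig$r[i], sig$p[i]))
  } else cat("  no FDR-significant associations\n")
  invisible(x)
}

#' Write an analysis report as JSON
#'
#' Persists the tabular parts of a report (subject features, associations,
#' per-subject functional effects, failure manifest); bulky trace and FC
#' matrices are omitted.
#'
#' @param report a `conndyn_report`.
#' @param path output path.
#' @export
write_report <- function(report, path) {
  payload <- list(
    subject_features = report$subject_features,
    associations = report$associations,
    failures = report$failures
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
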