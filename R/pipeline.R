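pipeline_defaults <- function() list(
  sim = NULL,                               # sim_config(); NULL = default config
  window = list(width = 18, step = 2),
  mvar = list(order = 1, lambda = 0.1, mode = "coef"),
  k = 2,
  clustering = list(metric = "L2", n_init = 10, scale_matrices = FALSE),
  inference = list(t_threshold = 3, n_perm = 1000, q = 0.05),
  reliability = list(enabled = FALSE,
                     settings = list(c(18, 2), c(30, 1), c(12, 3))),
  out_dir = NULL,
  seed = 1L)

#' Pipeline configuration
#'
#' Assembles and validates the configuration of [run_pipeline()]. Unknown
#' keys are rejected so typos cannot silently fall back to defaults. The
#' configuration round-trips through JSON.
#'
#' @param ... named overrides of the defaults: `sim` (a [sim_config()]),
#'   `window` (width, step), `mvar` (order, lambda, mode), `k`, `clustering`
#'   (metric, n_init, scale_matrices), `inference` (t_threshold, n_perm, q),
#'   `reliability` (enabled, settings), `out_dir`, `seed`.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- pipeline_defaults()
  over <- list(...)
  if (length(over) > 0 && (is.null(names(over)) || any(names(over) == "")))
    stopf("all pipeline_config arguments must be named")
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0)
    stopf("unknown pipeline_config key(s): %s", paste(unknown, collapse = ", "))
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]]) && !inherits(over[[nm]], "sim_config")) {
      sub_unknown <- setdiff(names(over[[nm]]), names(cfg[[nm]]))
      if (length(sub_unknown) > 0)
        stopf("unknown key(s) in %s: %s", nm, paste(sub_unknown, collapse = ", "))
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  if (is.null(cfg$sim)) cfg$sim <- sim_config(seed = cfg$seed)
  stopifnot(inherits(cfg$sim, "sim_config"))
  structure(cfg, class = "pipeline_config")
}

config_hash <- function(config) {
  ser <- jsonlite::toJSON(lapply(unclass(config), function(x)
    if (inherits(x, "sim_config")) unclass(x)[setdiff(names(unclass(x)), "coupling")] else x),
    auto_unbox = TRUE, force = TRUE, digits = NA)
  fnv1a(as.character(ser))
}

#' Run the full dynamic-effective-connectivity pipeline
#'
#' Simulates (or ingests) a cohort, computes windowed EC per subject,
#' clusters windows into states, extracts degree and temporal metrics, and
#' runs the group statistics: edgewise Welch tests with BH-FDR and the NBS
#' permutation component test per state, Welch comparisons of the temporal
#' properties, Spearman clinical associations of the temporal properties with
#' BH-FDR, and (optionally) ICC reliability across window settings. All
#' randomness flows from the single `seed` via per-stage derived seeds, so
#' the report is fully reproducible from (config, seed).
#'
#' @param config a [pipeline_config()].
#' @param cohort optional pre-built `dynec_cohort`; when supplied the
#'   simulation stage is skipped.
#' @return a `pipeline_report` list; when `config$out_dir` is set, stage
#'   outputs and a `report.json` are written there, each stamped with the
#'   config hash and seed.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  hash <- config_hash(config)

  if (is.null(cohort)) {
    cohort <- tryCatch(simulate_cohort(config$sim, seed = derive_seed(seed, 1L)),
                       error = function(e) stopf("stage simulate: %s", conditionMessage(e)))
  }
  groups <- vapply(cohort$subjects, `[[`, character(1), "group")
  group_levels <- unique(groups)

  stacks <- tryCatch(
    cohort_windowed_ec(cohort, width = config$window$width, step = config$window$step,
                       order = config$mvar$order, lambda = config$mvar$lambda,
                       mode = config$mvar$mode),
    error = function(e) stopf("stage dynec: %s", conditionMessage(e)))
  windows_per_subject <- vapply(stacks, function(s) dim(s$matrices)[3], integer(1))

  partition <- tryCatch(
    cluster_states(stacks, k = config$k, metric = config$clustering$metric,
                   n_init = config$clustering$n_init,
                   seed = derive_seed(seed, 2L),
                   scale_matrices = config$clustering$scale_matrices),
    error = function(e) stopf("stage states: %s", conditionMessage(e)))
  occ <- occupancy_report(partition)

  metrics <- tryCatch(state_metrics_table(stacks, partition, groups = groups),
                      error = function(e) stopf("stage netmetrics: %s", conditionMessage(e)))

  # per-state group tests on per-subject state-mean EC matrices
  summaries <- lapply(stacks, subject_state_summary, partition = partition)
  group_tests <- list()
  for (s in seq_len(config$k)) {
    ecA <- lapply(summaries[groups == group_levels[1]], function(x) x$state_means[[s]])
    ecB <- lapply(summaries[groups == group_levels[2]], function(x) x$state_means[[s]])
    tt <- edgewise_ttest(ecA, ecB)
    offp <- tt$p[!is.na(tt$p)]
    bh <- fdr_bh(offp, config$inference$q)
    nbs <- nbs_component_test(ecA, ecB,
                              t_threshold = config$inference$t_threshold,
                              n_perm = config$inference$n_perm,
                              seed = derive_seed(seed, 100L + s))
    group_tests[[sprintf("state%d", s)]] <- list(
      edgewise = tt, n_fdr_surviving = sum(bh$reject),
      nbs_components = lapply(nbs$components, function(cp)
        list(nodes = cp$nodes, size = cp$size, p_perm = cp$p_perm)))
  }

  # temporal-property group comparisons (Welch)
  temporal_tests <- list()
  for (s in seq_len(config$k)) {
    ms <- metrics[metrics$state == s, ]
    for (prop in c("F", "MDT")) {
      a <- ms[[prop]][ms$group == group_levels[1]]
      b <- ms[[prop]][ms$group == group_levels[2]]
      tt <- stats::t.test(a, b)
      temporal_tests[[sprintf("%s_state%d", prop, s)]] <- list(
        mean_a = mean(a), mean_b = mean(b), t = unname(tt$statistic),
        p = tt$p.value, group_a = group_levels[1], group_b = group_levels[2])
    }
  }
  nt <- metrics[metrics$state == 1, ]
  ttnt <- stats::t.test(nt$NT[nt$group == group_levels[1]],
                        nt$NT[nt$group == group_levels[2]])
  temporal_tests[["NT"]] <- list(
    mean_a = mean(nt$NT[nt$group == group_levels[1]]),
    mean_b = mean(nt$NT[nt$group == group_levels[2]]),
    t = unname(ttnt$statistic), p = ttnt$p.value,
    group_a = group_levels[1], group_b = group_levels[2])

  # clinical associations of temporal properties (per-state F/MDT + NT)
  assoc <- NULL
  if (!is.null(cohort$clinical)) {
    wide <- stats::reshape(
      metrics[, c("subject_id", "state", "F", "MDT", "NT")],
      direction = "wide", idvar = "subject_id", timevar = "state", sep = "_state")
    names(wide) <- sub("^NT_state1$", "NT", names(wide))
    wide <- wide[, !grepl("^NT_state", names(wide)), drop = FALSE]
    assoc <- spearman_assoc(wide, cohort$clinical, q = config$inference$q)
  }

  reliability <- NULL
  if (isTRUE(config$reliability$enabled)) {
    reliability <- reliability_across_windows(
      cohort, settings = config$reliability$settings, k = config$k,
      metric = config$clustering$metric, n_init = config$clustering$n_init,
      order = config$mvar$order, lambda = config$mvar$lambda,
      mode = config$mvar$mode, seed = derive_seed(seed, 3L))
  }

  report <- list(
    config_hash = hash, seed = seed,
    n_subjects = length(cohort$subjects),
    groups = as.list(table(groups)),
    n_timepoints = cohort$config$n_timepoints,
    window = config$window,
    windows_per_subject = as.list(windows_per_subject),
    total_windows = sum(windows_per_subject),
    k = config$k,
    occupancy_percent = occ$percent,
    inertia = partition$inertia,
    group_tests = group_tests,
    temporal_tests = temporal_tests,
    associations = assoc,
    reliability = if (is.null(reliability)) NULL else reliability$table)

  out <- structure(list(report = report, cohort = cohort, stacks = stacks,
                        partition = partition, metrics = metrics,
                        reliability = reliability),
                   class = "pipeline_report")
  if (!is.null(config$out_dir)) write_pipeline_outputs(out, config)
  out
}

write_pipeline_outputs <- function(result, config) {
  dir <- config$out_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- sprintf("%s_seed%d", result$report$config_hash, config$seed)
  write_cohort(result$cohort, file.path(dir, paste0("cohort_", stamp)))
  write.table(result$metrics, file.path(dir, paste0("metrics_", stamp, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (s in seq_len(result$partition$k)) {
    cen <- result$partition$centroids[[s]]
    write.table(cen, file.path(dir, sprintf("centroid_state%d_%s.tsv", s, stamp)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  rep <- result$report
  rep$group_tests <- lapply(rep$group_tests, function(g) {
    g$edgewise <- list(t = g$edgewise$t, p = g$edgewise$p)
    g
  })
  jsonlite::write_json(rep, file.path(dir, paste0("report_", stamp, ".json")),
                       auto_unbox = TRUE, digits = NA, force = TRUE, na = "null")
  jsonlite::write_json(rep, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE, na = "null")
  invisible(dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  r <- x$report
  cat(sprintf("pipeline_report [%s, seed %d]\n", r$config_hash, r$seed))
  cat(sprintf("  %d subjects, T = %d, window %d/%d -> %d windows total\n",
              r$n_subjects, r$n_timepoints, r$window$width, r$window$step,
              r$total_windows))
  cat(sprintf("  k = %d states, occupancy %s\n", r$k,
              paste(sprintf("%.2f%%", r$occupancy_percent), collapse = " / ")))
  for (nm in names(r$group_tests)) {
    comps <- r$group_tests[[nm]]$nbs_components
    if (length(comps) > 0) {
      best <- comps[[1]]
      cat(sprintf("  %s: largest NBS component %d edges (p = %.4f), %d FDR-surviving edges\n",
                  nm, best$size, best$p_perm, r$group_tests[[nm]]$n_fdr_surviving))
    } else {
      cat(sprintf("  %s: no suprathreshold NBS component, %d FDR-surviving edges\n",
                  nm, r$group_tests[[nm]]$n_fdr_surviving))
    }
  }
  invisible(x)
}
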