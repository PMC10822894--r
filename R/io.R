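#' Read component time courses from TSV
#'
#' Expects a header row of component names and a numeric body (rows = time
#' points). Ragged rows, non-numeric cells and NaN/NA cells are rejected with
#' the offending line (and cell) named.
#'
#' @param path TSV file path.
#' @param subject_id,group metadata stored on the result.
#' @return a `subject_tc` (without ground truth).
#' @export
read_timecourses <- function(path, subject_id = basename(path), group = NA_character_) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  nf <- count.fields(path, sep = "\t", quote = "")
  if (length(nf) < 1) stopf("%s: empty file", path)
  if (length(unique(nf)) != 1)
    stopf("%s: ragged rows (first at line %d)", path, which(nf != nf[1])[1] + 0L)
  df <- read.delim(path, sep = "\t", header = TRUE, colClasses = "character",
                   check.names = FALSE)
  if (nrow(df) == 0) stopf("%s: header only, no data rows", path)
  m <- matrix(NA_real_, nrow(df), ncol(df), dimnames = list(NULL, names(df)))
  for (j in seq_len(ncol(df))) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v) | is.nan(v))
    if (length(bad) > 0)
      stopf("%s: non-numeric or NaN cell at line %d, column '%s'",
            path, bad[1] + 1L, names(df)[j])
    m[, j] <- v
  }
  structure(list(tc = m, subject_id = subject_id, group = group, truth = NULL),
            class = "subject_tc")
}

#' Write component time courses to TSV
#'
#' @param subject a `subject_tc` or time-by-component matrix.
#' @param path output file.
#' @export
write_timecourses <- function(subject, path) {
  m <- as_tc_matrix(subject)
  if (is.null(colnames(m))) colnames(m) <- component_names(ncol(m))
  write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' Reads the manifest, the per-subject time-course TSVs, and the clinical
#' table. Ground truth is not reloaded (the ingest path treats the data as
#' observed).
#'
#' @param dir directory containing `manifest.json`, `*_timecourses.tsv` and
#'   optionally `clinical.tsv`.
#' @return a `dynec_cohort` (with `truth = NULL`); `config` carries the
#'   manifest's dimensions only.
#' @export
read_cohort <- function(dir) {
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path)) stopf("no manifest.json in %s", dir)
  man <- jsonlite::read_json(man_path)
  subjects <- list()
  for (entry in man$subjects) {
    sid <- entry$subject_id
    s <- read_timecourses(file.path(dir, paste0(sid, "_timecourses.tsv")),
                          subject_id = sid, group = entry$group)
    subjects[[sid]] <- s
  }
  clin_path <- file.path(dir, "clinical.tsv")
  clinical <- if (file.exists(clin_path))
    read.delim(clin_path, stringsAsFactors = FALSE) else NULL
  structure(list(subjects = subjects, clinical = clinical, truth = NULL,
                 config = list(n_timepoints = man$n_timepoints,
                               n_components = man$n_components),
                 seed = man$seed),
            class = "dynec_cohort")
}

#' Write a simulated cohort to disk
#'
#' One TSV per subject (rows = time points, columns = components), a cohort
#' manifest JSON (subject id, group, seed), the clinical table TSV, and the
#' ground truth in a separate JSON sidecar.
#'
#' @param cohort a `dynec_cohort`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "dynec_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$subjects)
    write_timecourses(s, file.path(dir, paste0(s$subject_id, "_timecourses.tsv")))
  manifest <- list(
    subjects = lapply(cohort$subjects, function(s)
      list(subject_id = s$subject_id, group = s$group)),
    seed = cohort$seed,
    n_timepoints = cohort$config$n_timepoints,
    n_components = cohort$config$n_components)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  write.table(cohort$clinical, file.path(dir, "clinical.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- list(states = cohort$truth$states,
                occupancy_state1 = as.list(cohort$truth$occupancy_state1),
                effect_edges = cohort$truth$effect_edges,
                clinical_betas = as.list(cohort$truth$clinical_betas))
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
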