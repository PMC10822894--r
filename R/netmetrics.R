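#' Causal-flow weighted degrees of an EC matrix
#'
#' With source rows, the out-weighted degree of component i is the summed
#' influence strength over the edges leaving i, the in-weighted degree of j
#' the summed strength over edges entering j, and the in-out-weighted degree
#' their difference (positive = net receiver, negative = net sender). The
#' diagonal (self-influence) is always excluded. Strength defaults to the
#' absolute value of the EC entry, since signed coefficients of opposite sign
#' would otherwise cancel; set `use_abs = FALSE` for signed sums (in which
#' case the in-out degrees of any single matrix sum to zero exactly).
#'
#' @param ec square numeric matrix (an `ec_matrix` or state centroid).
#' @param use_abs use absolute influence strengths (default `TRUE`).
#' @return data.frame: `component`, `in_weighted`, `out_weighted`,
#'   `in_out_weighted`.
#' @export
degree_profile <- function(ec, use_abs = TRUE) {
  ec <- unclass(ec)
  if (!is.matrix(ec) || nrow(ec) != ncol(ec)) stopf("ec must be a square matrix")
  v <- if (use_abs) abs(ec) else ec
  diag(v) <- 0
  if (any(is.na(v))) stopf("ec contains NA off-diagonal entries")
  nm <- colnames(ec)
  if (is.null(nm)) nm <- component_names(ncol(ec))
  out_w <- rowSums(v)
  in_w <- colSums(v)
  data.frame(component = nm, in_weighted = in_w, out_weighted = out_w,
             in_out_weighted = in_w - out_w,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Temporal properties of a state-label sequence
#'
#' Run-length encoding of one subject's ordered window labels gives the three
#' canonical dynamic-state summaries: fractional windows F (share of windows
#' in each state), mean dwell time MDT (average run length, in windows), and
#' the number of transitions NT (label changes = runs - 1). A state never
#' visited gets F = 0 and MDT = 0 with `visited = FALSE` rather than being
#' dropped, keeping group tables rectangular.
#'
#' @param labels integer vector of state labels in `1..k`.
#' @param k number of states.
#' @return list: `F` (length k, sums to 1), `MDT` (length k, windows),
#'   `NT` (scalar), `n_runs` (runs per state), `visited` (logical).
#' @export
temporal_properties <- function(labels, k) {
  labels <- as.integer(labels)
  if (length(labels) == 0) stopf("labels must be non-empty")
  if (any(is.na(labels)) || any(labels < 1L) || any(labels > k))
    stopf("labels must lie in 1..%d", k)
  r <- rle(labels)
  Fr <- tabulate(labels, k) / length(labels)
  n_runs <- tabulate(r$values, k)
  MDT <- rep(0, k)
  for (s in seq_len(k)) if (n_runs[s] > 0) MDT[s] <- mean(r$lengths[r$values == s])
  list(F = Fr, MDT = MDT, NT = length(r$lengths) - 1L,
       n_runs = n_runs, visited = n_runs > 0)
}

#' Convert a dwell time from windows to seconds
#'
#' Windows are the canonical dwell unit; consecutive windows are `step` TRs
#' apart, so a dwell of `mdt` windows spans about `mdt * step * tr` seconds.
#'
#' @param mdt dwell time in windows.
#' @param step window step in TRs.
#' @param tr repetition time in seconds (default 2).
#' @export
mdt_to_seconds <- function(mdt, step = 2, tr = 2) mdt * step * tr

#' Per-subject, per-state summary of a windowed EC stack
#'
#' For one subject: the mean EC matrix over the windows assigned to each
#' state, the degree profile of each state mean, and the temporal profile of
#' the subject's window label sequence. States the subject never visits are
#' flagged and their mean matrix is `NULL`.
#'
#' @param stack the subject's [windowed_ec()] stack.
#' @param partition a [cluster_states()] result containing this subject.
#' @param use_abs passed to [degree_profile()].
#' @return list: `subject_id`, `state_means` (list length k), `degrees`
#'   (list length k of data.frames or `NULL`), `temporal`
#'   ([temporal_properties()] output), `labels`.
#' @export
subject_state_summary <- function(stack, partition, use_abs = TRUE) {
  stopifnot(inherits(stack, "ec_stack"), inherits(partition, "state_partition"))
  lab <- partition$labels
  mine <- lab[lab$subject_id == stack$subject_id, , drop = FALSE]
  if (nrow(mine) == 0) stopf("subject '%s' absent from partition", stack$subject_id)
  if (nrow(mine) != dim(stack$matrices)[3])
    stopf("partition has %d windows for subject '%s' but the stack has %d",
          nrow(mine), stack$subject_id, dim(stack$matrices)[3])
  mine <- mine[order(mine$window), , drop = FALSE]
  k <- partition$k
  state_means <- vector("list", k)
  degrees <- vector("list", k)
  for (s in seq_len(k)) {
    idx <- which(mine$state == s)
    if (length(idx) > 0) {
      m <- apply(stack$matrices[, , idx, drop = FALSE], c(1, 2), mean)
      state_means[[s]] <- m
      degrees[[s]] <- degree_profile(m, use_abs = use_abs)
    }
  }
  list(subject_id = stack$subject_id, state_means = state_means,
       degrees = degrees,
       temporal = temporal_properties(mine$state, k),
       labels = mine$state)
}

#' Tidy per-subject metrics table for a cohort
#'
#' One row per subject per state: fractional windows, mean dwell time, number
#' of transitions, and one column per component for each weighted-degree
#' measure of the subject's state-mean EC (NA when the state is unvisited).
#'
#' @param stacks named list of `ec_stack` (one per subject).
#' @param partition matching [cluster_states()] result.
#' @param groups optional named group vector (or a `dynec_cohort` to take
#'   subjects' groups from).
#' @param use_abs passed to [degree_profile()].
#' @return data.frame.
#' @export
state_metrics_table <- function(stacks, partition, groups = NULL, use_abs = TRUE) {
  if (inherits(groups, "dynec_cohort"))
    groups <- vapply(groups$subjects, `[[`, character(1), "group")
  rows <- list()
  for (st in stacks) {
    ss <- subject_state_summary(st, partition, use_abs = use_abs)
    n <- dim(st$matrices)[1]
    comp <- dimnames(st$matrices)[[1]]
    if (is.null(comp)) comp <- component_names(n)
    for (s in seq_len(partition$k)) {
      deg <- ss$degrees[[s]]
      degrow <- if (is.null(deg)) {
        stats::setNames(rep(NA_real_, 3 * n),
                        c(paste0("in_", comp), paste0("out_", comp), paste0("inout_", comp)))
      } else {
        stats::setNames(c(deg$in_weighted, deg$out_weighted, deg$in_out_weighted),
                        c(paste0("in_", comp), paste0("out_", comp), paste0("inout_", comp)))
      }
      rows[[length(rows) + 1]] <- c(
        list(subject_id = ss$subject_id,
             group = if (is.null(groups)) NA_character_ else unname(groups[ss$subject_id]),
             state = s, F = ss$temporal$F[s], MDT = ss$temporal$MDT[s],
             NT = ss$temporal$NT, visited = ss$temporal$visited[s]),
        as.list(degrow))
    }
  }
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}
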