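#' Default state coupling matrices for the cohort simulator
#'
#' Directed coupling matrices (source rows: entry `(i, j)` is the effect of
#' channel `i` at lag 1 on channel `j`) for the two connectivity regimes the
#' simulator switches between. The "weak" regime is sparse: modest
#' self-decay, two strong hub edges out of component 2, and a thin chain of
#' secondary edges. The "strong" regime is dense: a directed ring plus
#' negative skip connections, emulating a state with markedly more active
#' inter-regional communication than the weak one.
#'
#' @param n_components number of channels (>= 4).
#' @param regime `"weak"` or `"strong"`.
#' @return an `n_components` x `n_components` coefficient matrix with
#'   companion spectral radius < 1.
#' @export
default_coupling <- function(n_components = 12, regime = c("weak", "strong")) {
  regime <- match.arg(regime)
  n <- as.integer(n_components)
  if (n < 4) stopf("default_coupling needs n_components >= 4, got %d", n)
  A <- diag(0.25, n)
  if (regime == "weak") {
    t1 <- ceiling(2 * n / 3)
    A[2, t1] <- 0.40
    A[2, n] <- 0.40
    A[1, 2] <- 0.25
    for (i in seq(3, n, by = 2)) A[i, i %% n + 1] <- 0.18
  } else {
    for (i in seq_len(n)) {
      A[i, i %% n + 1] <- 0.35
      A[i, (i + 2) %% n + 1] <- -0.30
    }
    diag(A) <- 0.25
  }
  dimnames(A) <- list(component_names(n), component_names(n))
  A
}

component_names <- function(n) sprintf("C%02d", seq_len(n))

# Normalize a coupling argument (matrix or list of per-lag matrices) to a
# list of p matrices.
as_lag_list <- function(coupling, n, p, what) {
  if (is.matrix(coupling)) coupling <- list(coupling)
  if (!is.list(coupling) || length(coupling) != p)
    stopf("%s must be a matrix (order 1) or a list of %d lag matrices", what, p)
  for (A in coupling) {
    if (!is.matrix(A) || nrow(A) != n || ncol(A) != n)
      stopf("%s matrices must be %d x %d", what, n, n)
    if (any(!is.finite(A))) stopf("%s contains non-finite entries", what)
  }
  coupling
}

#' Companion-form spectral radius of a VAR coefficient set
#'
#' Stationarity of a VAR(p) within one regime requires the spectral radius of
#' the companion matrix built from its lag matrices to be strictly below 1.
#'
#' @param coupling a coefficient matrix (order 1) or list of per-lag matrices.
#' @return the spectral radius (largest eigenvalue modulus).
#' @export
companion_spectral_radius <- function(coupling) {
  if (is.matrix(coupling)) coupling <- list(coupling)
  n <- nrow(coupling[[1]])
  p <- length(coupling)
  comp <- matrix(0, n * p, n * p)
  for (l in seq_len(p)) comp[seq_len(n), (l - 1) * n + seq_len(n)] <- t(coupling[[l]])
  if (p > 1) comp[n + seq_len(n * (p - 1)), seq_len(n * (p - 1))] <- diag(n * (p - 1))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' Simulator configuration
#'
#' Bundles every parameter of the hidden-Markov state-switching MVAR cohort
#' generator. Defaults emulate the acquisition scale of the motivating study
#' (76 subjects: 36 patients, 40 controls; 170 retained time points at
#' TR = 2 s; 12 network components) with dwell probabilities calibrated so
#' that state dwell times and occupancies land in the range the field reports
#' for two-state dynamic-connectivity decompositions (state 1 occupied
#' roughly 60-80% of the time, dwell times of tens of time points).
#'
#' @param n_subjects_per_group named counts, e.g. `c(patient = 36, control = 40)`.
#' @param n_timepoints retained time points per subject (default 170).
#' @param n_components number of channels (default 12).
#' @param mvar_order autoregressive order of the generator (default 1).
#' @param coupling_state1,coupling_state2 coefficient matrix (or list of lag
#'   matrices) for the weak and strong regimes; source-row orientation.
#' @param stay_probs named list with one probability vector per group,
#'   element s = probability of remaining in state s at each time point.
#' @param effect_edges two-column matrix of (source, target) state-1 edges
#'   attenuated in the patient group.
#' @param effect_size amount subtracted from each effect edge's state-1
#'   coefficient for patients (0 = exchangeable groups).
#' @param clinical_betas named coefficients linking each clinical variable to
#'   the subject's realized state-1 occupancy (standardized), giving the
#'   Spearman stage a recoverable monotone signal.
#' @param noise_sd innovation standard deviation (i.i.d. diagonal Gaussian).
#' @param seed default seed used by [simulate_cohort()] when none is passed.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_subjects_per_group = c(patient = 36, control = 40),
                       n_timepoints = 170,
                       n_components = 12,
                       mvar_order = 1,
                       coupling_state1 = default_coupling(n_components, "weak"),
                       coupling_state2 = default_coupling(n_components, "strong"),
                       stay_probs = list(patient = c(0.985, 0.95),
                                         control = c(0.970, 0.95)),
                       effect_edges = cbind(2, setdiff(unique(pmin(c(ceiling(2 * n_components / 3), n_components), n_components)), 2)),
                       effect_size = 0.30,
                       clinical_betas = c(hba1c = 1.0, moca = -2.0, dbp = 4.0, education = -1.5),
                       noise_sd = 1,
                       seed = 1L) {
  n <- as.integer(n_components)
  p <- as.integer(mvar_order)
  Tn <- as.integer(n_timepoints)
  if (p < 1) stopf("mvar_order must be >= 1")
  if (Tn <= p) stopf("n_timepoints (%d) must exceed mvar_order (%d)", Tn, p)
  if (length(n_subjects_per_group) != 2 || is.null(names(n_subjects_per_group)))
    stopf("n_subjects_per_group must be a named length-2 count vector")
  if (any(n_subjects_per_group < 2)) stopf("need at least 2 subjects per group")
  if (noise_sd <= 0) stopf("noise_sd must be positive")

  coupling <- list(as_lag_list(coupling_state1, n, p, "coupling_state1"),
                   as_lag_list(coupling_state2, n, p, "coupling_state2"))
  groups <- names(n_subjects_per_group)
  if (!setequal(names(stay_probs), groups))
    stopf("stay_probs must be named by group: %s", paste(groups, collapse = ", "))
  for (g in groups) {
    sp <- stay_probs[[g]]
    if (length(sp) != 2 || any(sp <= 0) || any(sp >= 1))
      stopf("stay_probs$%s must be 2 probabilities strictly inside (0,1)", g)
  }

  effect_edges <- as.matrix(effect_edges)
  if (ncol(effect_edges) != 2) stopf("effect_edges must have two columns (source, target)")
  if (any(effect_edges[, 1] == effect_edges[, 2])) stopf("effect edges must be off-diagonal")
  if (any(effect_edges < 1 | effect_edges > n)) stopf("effect edge indices out of range")

  cfg <- structure(list(
    n_subjects_per_group = n_subjects_per_group, n_timepoints = Tn,
    n_components = n, mvar_order = p, coupling = coupling,
    stay_probs = stay_probs, effect_edges = effect_edges,
    effect_size = effect_size, clinical_betas = clinical_betas,
    noise_sd = noise_sd, seed = as.integer(seed), burn_in = 50L,
    groups = groups), class = "sim_config")

  for (s in 1:2) {
    sr <- companion_spectral_radius(cfg$coupling[[s]])
    if (sr >= 1)
      stopf("coupling_state%d is non-stationary: companion spectral radius %.3f >= 1", s, sr)
  }
  sr <- companion_spectral_radius(patient_coupling(cfg)[[1]])
  if (sr >= 1)
    stopf("patient-attenuated state-1 coupling is non-stationary (spectral radius %.3f)", sr)
  cfg
}

# State-1 coupling with the group-effect edges attenuated (patient group).
patient_coupling <- function(cfg) {
  cp <- cfg$coupling
  A1 <- cp[[1]][[1]]
  A1[cfg$effect_edges] <- A1[cfg$effect_edges] - cfg$effect_size
  cp[[1]][[1]] <- A1
  cp
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: %s subjects (%s), T = %d, %d components, VAR(%d)\n",
              sum(x$n_subjects_per_group),
              paste(sprintf("%s=%d", names(x$n_subjects_per_group), x$n_subjects_per_group), collapse = ", "),
              x$n_timepoints, x$n_components, x$mvar_order))
  invisible(x)
}

#' Simulate a hidden Markov state sequence
#'
#' A k-state chain in which the probability of staying in the current state s
#' is `stay_probs[s]` and the remaining mass is split evenly over the other
#' states. The initial state is drawn from the chain's stationary
#' distribution.
#'
#' @param n_timepoints sequence length.
#' @param k number of states (>= 1).
#' @param stay_probs length-k vector of stay probabilities in (0, 1] (1 is
#'   allowed here and makes the state absorbing).
#' @param seed optional seed; the caller's RNG state is restored afterwards.
#' @return integer vector of length `n_timepoints` with values in `1..k`.
#' @export
simulate_state_chain <- function(n_timepoints, k, stay_probs, seed = NULL) {
  if (k < 1) stopf("k must be >= 1")
  if (length(stay_probs) != k) stopf("stay_probs must have length k = %d", k)
  if (any(stay_probs <= 0) || any(stay_probs > 1))
    stopf("stay probabilities must lie in (0, 1]")
  if (k == 1) return(rep(1L, n_timepoints))
  P <- matrix(0, k, k)
  for (s in seq_len(k)) {
    P[s, ] <- (1 - stay_probs[s]) / (k - 1)
    P[s, s] <- stay_probs[s]
  }
  with_seed(seed, {
    pi0 <- chain_stationary(P)
    states <- integer(n_timepoints)
    states[1] <- sample.int(k, 1, prob = pi0)
    u <- runif(n_timepoints)
    u2 <- runif(n_timepoints)
    for (t in seq_len(n_timepoints)[-1]) {
      cur <- states[t - 1]
      if (u[t] < stay_probs[cur]) {
        states[t] <- cur
      } else {
        others <- seq_len(k)[-cur]
        states[t] <- others[ceiling(u2[t] * (k - 1))]
      }
    }
    states
  })
}

# Stationary distribution of a row-stochastic transition matrix.
chain_stationary <- function(P) {
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sum(v)
}

#' Simulate one subject's component time courses
#'
#' The hidden state sequence switches the VAR coefficient set at the
#' time-point level; observations follow
#' `x_t = sum_l t(A_l(state_t)) x_{t-l} + e_t` with i.i.d. diagonal Gaussian
#' innovations. A burn-in of 50 samples is discarded so the emitted series
#' carries no initial-condition transient.
#'
#' @param cfg a [sim_config()].
#' @param group group label (must be one of the config's groups); the patient
#'   group uses the attenuated state-1 coupling.
#' @param seed optional seed.
#' @param subject_id identifier stored in the result.
#' @return an object of class `subject_tc`: list with `tc` (time x component
#'   matrix), `subject_id`, `group`, and `truth` (hidden states over the
#'   emitted span, the coupling matrices used, the effect edges).
#' @export
simulate_subject <- function(cfg, group, seed = NULL, subject_id = "sub-001") {
  stopifnot(inherits(cfg, "sim_config"))
  if (!group %in% cfg$groups) stopf("unknown group '%s'", group)
  coupling <- if (group == cfg$groups[1]) patient_coupling(cfg) else cfg$coupling
  n <- cfg$n_components; p <- cfg$mvar_order
  burn <- cfg$burn_in
  total <- cfg$n_timepoints + burn
  # pre-transpose so the recursion is target-row
  At <- lapply(coupling, function(lags) lapply(lags, t))
  with_seed(seed, {
    st <- simulate_state_chain(total, 2L, cfg$stay_probs[[group]])
    x <- matrix(0, total, n)
    noise <- matrix(rnorm(total * n, sd = cfg$noise_sd), total, n)
    for (t in (p + 1):total) {
      acc <- noise[t, ]
      A <- At[[st[t]]]
      for (l in seq_len(p)) acc <- acc + A[[l]] %*% x[t - l, ]
      x[t, ] <- acc
    }
    keep <- (burn + 1):total
    tc <- x[keep, , drop = FALSE]
    colnames(tc) <- component_names(n)
    structure(list(tc = tc, subject_id = subject_id, group = group,
                   truth = list(states = st[keep], coupling = coupling,
                                effect_edges = cfg$effect_edges)),
              class = "subject_tc")
  })
}

#' @export
print.subject_tc <- function(x, ...) {
  cat(sprintf("subject_tc %s (%s): %d time points x %d components\n",
              x$subject_id, x$group, nrow(x$tc), ncol(x$tc)))
  invisible(x)
}

#' Simulate a cohort with ground truth and a synthetic clinical table
#'
#' Generates `n_subjects_per_group` subjects per group from [simulate_subject()]
#' (the patient group gets attenuated state-1 effect edges and its own dwell
#' probabilities) plus a clinical table whose variables are linear in the
#' subject's realized state-1 occupancy (standardized over the cohort) plus
#' Gaussian noise, with group-specific marginal means and spreads typical of
#' a diabetes-vs-control sample: HbA1c (%), MoCA (0-30), diastolic blood
#' pressure (mmHg) and education (years).
#'
#' @param cfg a [sim_config()].
#' @param seed seed for the whole cohort (defaults to `cfg$seed`); per-subject
#'   seeds are derived from it, so the cohort is reproducible end to end.
#' @return object of class `dynec_cohort`: `subjects` (list of `subject_tc`),
#'   `clinical` (data.frame), `truth` (per-subject states and occupancies,
#'   coupling per group, effect edges, clinical betas), `config`, `seed`.
#' @export
simulate_cohort <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  groups <- rep(cfg$groups, times = cfg$n_subjects_per_group)
  n_sub <- length(groups)
  ids <- sprintf("sub-%03d", seq_len(n_sub))
  subjects <- vector("list", n_sub)
  for (i in seq_len(n_sub)) {
    subjects[[i]] <- simulate_subject(cfg, groups[i],
                                      seed = derive_seed(seed, i),
                                      subject_id = ids[i])
  }
  names(subjects) <- ids
  occ1 <- vapply(subjects, function(s) mean(s$truth$states == 1L), numeric(1))
  z <- if (sd(occ1) > 0) (occ1 - mean(occ1)) / sd(occ1) else rep(0, n_sub)

  b <- cfg$clinical_betas
  pat <- groups == cfg$groups[1]
  clinical <- with_seed(derive_seed(seed, 0L), {
    hba1c <- ifelse(pat, 10.58, 4.92) + b[["hba1c"]] * z +
      rnorm(n_sub, sd = ifelse(pat, 2.8, 0.45))
    moca <- ifelse(pat, 27.44, 27.83) + b[["moca"]] * z + rnorm(n_sub, sd = 1.2)
    dbp <- ifelse(pat, 73.08, 68.35) + b[["dbp"]] * z + rnorm(n_sub, sd = 9)
    edu <- ifelse(pat, 13.31, 13.60) + b[["education"]] * z + rnorm(n_sub, sd = 2.2)
    data.frame(subject_id = ids, group = groups,
               hba1c = pmax(round(hba1c, 2), 3.5),
               moca = pmin(pmax(round(moca), 0), 30),
               dbp = round(dbp, 1),
               education = pmax(round(edu), 0),
               stringsAsFactors = FALSE)
  })

  truth <- list(
    states = lapply(subjects, function(s) s$truth$states),
    occupancy_state1 = occ1,
    coupling = list(patient = patient_coupling(cfg), control = cfg$coupling),
    effect_edges = cfg$effect_edges,
    clinical_betas = b)
  structure(list(subjects = subjects, clinical = clinical, truth = truth,
                 config = cfg, seed = seed),
            class = "dynec_cohort")
}

#' @export
print.dynec_cohort <- function(x, ...) {
  cat(sprintf("dynec_cohort: %d subjects (%s), T = %d, %d components\n",
              length(x$subjects),
              paste(sprintf("%s=%d", names(x$config$n_subjects_per_group),
                            x$config$n_subjects_per_group), collapse = ", "),
              x$config$n_timepoints, x$config$n_components))
  invisible(x)
}
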