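# Shared fixtures and independent oracles. Oracles here are deliberately
# naive (loops, double enumeration) so they stay independent of the package's
# vectorized implementations.

# standard Laplacian sampler (variance 1)
rlap <- function(n) {
  u <- runif(n) - 0.5
  -sign(u) * log(1 - 2 * abs(u)) / sqrt(2)
}

# Run-length oracle for temporal properties: explicit scan, no rle().
temporal_oracle <- function(labels, k) {
  runs_val <- integer(0)
  runs_len <- integer(0)
  cur <- labels[1]; len <- 1L
  for (t in seq_along(labels)[-1]) {
    if (labels[t] == cur) {
      len <- len + 1L
    } else {
      runs_val <- c(runs_val, cur); runs_len <- c(runs_len, len)
      cur <- labels[t]; len <- 1L
    }
  }
  runs_val <- c(runs_val, cur); runs_len <- c(runs_len, len)
  Fr <- numeric(k); MDT <- numeric(k); n_runs <- integer(k)
  for (s in seq_len(k)) {
    Fr[s] <- sum(labels == s) / length(labels)
    sel <- runs_val == s
    n_runs[s] <- sum(sel)
    MDT[s] <- if (any(sel)) mean(runs_len[sel]) else 0
  }
  list(F = Fr, MDT = MDT, NT = length(runs_val) - 1L, n_runs = n_runs)
}

# Brute-force Benjamini-Hochberg step-up: double loop, no cummin trick.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(ord == i)
    vals <- numeric(0)
    for (j in rank_i:m) vals <- c(vals, p[ord[j]] * m / j)
    adj[i] <- min(1, min(vals))
  }
  adj
}

# Spearman rho through the explicit rank formula (Pearson on midranks,
# computed from raw sums).
spearman_oracle <- function(x, y) {
  midrank_naive <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) r[i] <- (sum(v < v[i]) + 1 + sum(v <= v[i])) / 2
    r
  }
  rx <- midrank_naive(x); ry <- midrank_naive(y)
  n <- length(x)
  num <- sum(rx * ry) - n * mean(rx) * mean(ry)
  den <- sqrt((sum(rx^2) - n * mean(rx)^2) * (sum(ry^2) - n * mean(ry)^2))
  num / den
}

# ICC(2,1) from explicitly accumulated ANOVA sums of squares.
icc_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m); g <- mean(m)
  SSR <- 0; SSC <- 0; SST <- 0
  for (i in seq_len(n)) SSR <- SSR + k * (mean(m[i, ]) - g)^2
  for (j in seq_len(k)) SSC <- SSC + n * (mean(m[, j]) - g)^2
  for (i in seq_len(n)) for (j in seq_len(k)) SST <- SST + (m[i, j] - g)^2
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- (SST - SSR - SSC) / ((n - 1) * (k - 1))
  (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
}

# Assemble an ec_stack directly from a list of matrices (planted designs).
make_stack <- function(mats, subject_id = "sub-001", width = 18, step = 2) {
  n <- nrow(mats[[1]])
  arr <- array(unlist(mats), c(n, n, length(mats)))
  structure(list(matrices = arr,
                 windows = cbind(start = seq_along(mats), end = seq_along(mats) + width - 1L),
                 subject_id = subject_id,
                 settings = list(width = width, step = step, order = 1,
                                 lambda = 0.1, mode = "coef")),
            class = "ec_stack")
}

# Assemble a state_partition directly from per-subject label vectors.
make_partition <- function(labels_by_subject, k, centroids = NULL) {
  lab <- do.call(rbind, lapply(names(labels_by_subject), function(s)
    data.frame(subject_id = s, window = seq_along(labels_by_subject[[s]]),
               state = labels_by_subject[[s]], stringsAsFactors = FALSE)))
  occ <- tabulate(lab$state, k) / nrow(lab)
  structure(list(k = k, centroids = centroids, labels = lab, occupancy = occ,
                 inertia = NA_real_, metric = "L2", seed = NULL,
                 scale_matrices = FALSE),
            class = "state_partition")
}

# Small two-regime cohort configuration used across tests.
small_cfg <- function(n_per_group = c(patient = 4, control = 4), Tn = 120,
                      n_comp = 6, seed = 1, ...) {
  sim_config(n_subjects_per_group = n_per_group, n_timepoints = Tn,
             n_components = n_comp, seed = seed, ...)
}
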