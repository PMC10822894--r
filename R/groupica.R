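#' Temporal concatenation and PCA reduction
#'
#' Stacks the subjects' time-by-feature matrices over time, centers the
#' columns, and projects onto the top `n_pc` principal axes (one-level
#' reduction; at desk scale this is equivalent to the usual two-stage
#' subject-then-group reduction and keeps the back-projection operators
#' simple). The operators needed for back-reconstruction are retained.
#'
#' @param data list of time-by-feature matrices (or `subject_tc`, or a
#'   `dynec_cohort`).
#' @param n_pc number of principal components to keep (<= rank of the
#'   concatenated data).
#' @return object of class `ica_reduction`: `scores` (total-time x n_pc),
#'   `rotation` (feature x n_pc), `center`, `explained_variance` (fraction),
#'   `eigenvalues`, `subject_rows` (row index per subject), `n_pc`.
#' @export
reduce_concat <- function(data, n_pc) {
  if (inherits(data, "dynec_cohort")) data <- data$subjects
  if (inherits(data, "subject_tc") || is.matrix(data)) data <- list(data)
  mats <- lapply(data, as_tc_matrix)
  nf <- unique(vapply(mats, ncol, integer(1)))
  if (length(nf) != 1) stopf("subjects have differing feature counts")
  X <- do.call(rbind, mats)
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  sv <- svd(Xc)
  eig <- sv$d^2 / (nrow(X) - 1)
  rank <- sum(sv$d > max(sv$d) * 1e-10)
  if (n_pc > rank)
    stopf("n_pc = %d exceeds the concatenated data rank (%d)", n_pc, rank)
  ends <- cumsum(vapply(mats, nrow, integer(1)))
  starts <- c(1L, head(ends, -1) + 1L)
  structure(list(
    scores = Xc %*% sv$v[, seq_len(n_pc), drop = FALSE],
    rotation = sv$v[, seq_len(n_pc), drop = FALSE],
    center = center,
    explained_variance = sum(eig[seq_len(n_pc)]) / sum(eig),
    eigenvalues = eig,
    subject_rows = Map(function(a, b) a:b, starts, ends),
    n_pc = n_pc), class = "ica_reduction")
}

#' Infomax independent component analysis on a reduced matrix
#'
#' Natural-gradient infomax with the logistic nonlinearity on PCA-whitened
#' data: minimizes mutual information between the recovered sources, which
#' identifies super-Gaussian (e.g. low-frequency fMRI-like) components up to
#' permutation and sign. Components are ordered by explained variance and
#' their sign is fixed so each component's largest-magnitude loading is
#' positive. If the weight change never falls below `tol`, a warning is
#' issued and the partial result returned with `converged = FALSE`; if the
#' recovered sources all look Gaussian (|excess kurtosis| < 0.5) a
#' non-identifiability warning is issued.
#'
#' @param reduction an [reduce_concat()] result.
#' @param n_ic number of components (<= `n_pc`; default `n_pc`).
#' @param learning_rate initial natural-gradient step (default 0.1,
#'   annealed on divergence or oscillation).
#' @param max_iter maximum passes over the data (default 1000).
#' @param tol relative weight-change convergence tolerance (default 1e-7).
#' @param seed optional seed for the random rotation initializing the search.
#' @return object of class `ica_result`: `unmixing` (n_ic x n_pc),
#'   `mixing` (n_pc x n_ic; `unmixing %*% mixing` is the identity),
#'   `sources` (total-time x n_ic group time courses), `maps` (feature x
#'   n_ic loadings), `converged`, `n_pc`, `n_ic`, `reduction`.
#' @export
infomax_unmix <- function(reduction, n_ic = reduction$n_pc, learning_rate = 0.1,
                          max_iter = 1000, tol = 1e-7, seed = NULL) {
  stopifnot(inherits(reduction, "ica_reduction"))
  if (n_ic > reduction$n_pc) stopf("n_ic (%d) must be <= n_pc (%d)", n_ic, reduction$n_pc)
  R <- reduction$scores
  N <- nrow(R)
  # whiten within the reduced space, keeping the top n_ic directions
  cv <- crossprod(R) / (N - 1)
  ew <- eigen(cv, symmetric = TRUE)
  K <- diag(1 / sqrt(ew$values[seq_len(n_ic)]), n_ic) %*%
    t(ew$vectors[, seq_len(n_ic), drop = FALSE])
  X <- R %*% t(K)

  W <- with_seed(seed, {
    M <- matrix(rnorm(n_ic * n_ic), n_ic)
    qr.Q(qr(M))
  })
  lr <- learning_rate
  converged <- FALSE
  delta <- Inf
  dW_prev <- NULL
  for (iter in seq_len(max_iter)) {
    W_old <- W
    U <- X %*% t(W)
    Y <- 1 / (1 + exp(-U))
    grad <- diag(n_ic) + crossprod(1 - 2 * Y, U) / N
    W <- W + lr * grad %*% W
    if (any(!is.finite(W)) || max(abs(W)) > 1e8) {
      # diverged: halve the step and restart from an orthonormal rotation
      lr <- lr / 2
      W <- qr.Q(qr(matrix(rnorm(n_ic * n_ic), n_ic)))
      dW_prev <- NULL
      next
    }
    dW <- W - W_old
    # anneal when successive updates point in opposing directions
    if (!is.null(dW_prev) && sum(dW * dW_prev) < 0) lr <- lr * 0.9
    dW_prev <- dW
    delta <- sqrt(sum(dW^2)) / sqrt(sum(W_old^2))
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warnf("infomax did not converge in %d iterations (last relative change %.2e); partial result returned",
          max_iter, delta)

  unmixing <- W %*% K                       # n_ic x n_pc
  sources <- R %*% t(unmixing)              # N x n_ic
  mixing <- t(unmixing) %*% solve(unmixing %*% t(unmixing))  # n_pc x n_ic
  # order components by the variance they explain in the reduced data
  expl <- apply(sources, 2, var) * colSums(mixing^2)
  ord <- order(-expl)
  unmixing <- unmixing[ord, , drop = FALSE]
  sources <- sources[, ord, drop = FALSE]
  mixing <- mixing[, ord, drop = FALSE]
  maps <- reduction$rotation %*% mixing     # feature x n_ic
  for (j in seq_len(n_ic)) {
    peak <- which.max(abs(maps[, j]))
    if (maps[peak, j] < 0) {
      maps[, j] <- -maps[, j]; mixing[, j] <- -mixing[, j]
      unmixing[j, ] <- -unmixing[j, ]; sources[, j] <- -sources[, j]
    }
  }
  kurt <- apply(sources, 2, function(s) mean(((s - mean(s)) / sd(s))^4) - 3)
  if (all(abs(kurt) < 0.5))
    warnf("all recovered sources look Gaussian (|excess kurtosis| < 0.5): ICA is not identifiable on this data")
  structure(list(unmixing = unmixing, mixing = mixing, sources = sources,
                 maps = maps, converged = converged, kurtosis = kurt,
                 n_pc = reduction$n_pc, n_ic = n_ic, reduction = reduction),
            class = "ica_result")
}

#' Back-reconstruct per-subject component time courses
#'
#' GICA-style back-projection: each subject's centered data is pushed through
#' the stored PCA rotation and the group unmixing matrix, yielding that
#' subject's time course for every group component.
#'
#' @param ica an [infomax_unmix()] result (carries its reduction operators).
#' @param data the same subject list the reduction was fitted on (optional;
#'   defaults to slicing the stored concatenated scores by subject).
#' @return list of time x n_ic matrices, one per subject.
#' @export
back_reconstruct <- function(ica, data = NULL) {
  stopifnot(inherits(ica, "ica_result"))
  red <- ica$reduction
  if (is.null(red)) stopf("ica result lacks its reduction operators")
  if (is.null(data)) {
    lapply(red$subject_rows, function(rows)
      red$scores[rows, , drop = FALSE] %*% t(ica$unmixing))
  } else {
    if (inherits(data, "dynec_cohort")) data <- data$subjects
    if (inherits(data, "subject_tc") || is.matrix(data)) data <- list(data)
    lapply(data, function(d) {
      X <- sweep(as_tc_matrix(d), 2, red$center)
      X %*% red$rotation %*% t(ica$unmixing)
    })
  }
}

#' Select components by low-frequency dominance and mask inclusion
#'
#' Keeps components whose group time course concentrates its spectral power
#' below `freq_cutoff` (fraction above `power_threshold`) and, when a mask is
#' supplied, whose spatial-map peak (largest-magnitude loading) lies inside
#' it. This is the desk-scale reduction of the usual component-screening
#' criteria (low-frequency fluctuations should dominate; peaks should sit in
#' plausible tissue).
#'
#' @param ica an [infomax_unmix()] result.
#' @param tr sampling interval in seconds (default 2).
#' @param freq_cutoff low-frequency boundary in Hz (default 0.1).
#' @param power_threshold minimum fraction of spectral power below the cutoff
#'   (default 0.5).
#' @param mask optional logical vector over features; a component is kept
#'   only if its peak loading falls where `mask` is `TRUE`.
#' @return list: `selected` (component indices), `report` (data.frame with
#'   the per-component low-frequency power fraction, peak feature, and the
#'   rule outcomes).
#' @export
select_components <- function(ica, tr = 2, freq_cutoff = 0.1,
                              power_threshold = 0.5, mask = NULL) {
  stopifnot(inherits(ica, "ica_result"))
  S <- ica$sources
  nI <- ncol(S)
  lf <- numeric(nI)
  for (j in seq_len(nI)) {
    s <- S[, j] - mean(S[, j])
    pw <- Mod(fft(s))^2
    nf <- length(s)
    freqs <- (seq_len(nf) - 1) / (nf * tr)
    half <- freqs <= 1 / (2 * tr)
    lf[j] <- sum(pw[half & freqs <= freq_cutoff]) / sum(pw[half])
  }
  peak <- apply(abs(ica$maps), 2, which.max)
  in_mask <- if (is.null(mask)) rep(TRUE, nI) else {
    if (length(mask) != nrow(ica$maps)) stopf("mask length must equal the feature count")
    mask[peak]
  }
  keep <- lf >= power_threshold & in_mask
  list(selected = which(keep),
       report = data.frame(component = seq_len(nI), low_freq_power = lf,
                           peak_feature = peak, in_mask = in_mask,
                           low_frequency = lf >= power_threshold,
                           selected = keep))
}

#' Back-reconstruct and select in one step
#'
#' Convenience wrapper: [back_reconstruct()] then [select_components()],
#' returning each subject's time courses restricted to the selected
#' components.
#'
#' @inheritParams back_reconstruct
#' @inheritParams select_components
#' @return list: `timecourses` (per-subject time x n_selected matrices),
#'   `selected`, `report`.
#' @export
back_reconstruct_and_select <- function(ica, data = NULL, tr = 2,
                                        freq_cutoff = 0.1,
                                        power_threshold = 0.5, mask = NULL) {
  tcs <- back_reconstruct(ica, data)
  sel <- select_components(ica, tr = tr, freq_cutoff = freq_cutoff,
                           power_threshold = power_threshold, mask = mask)
  list(timecourses = lapply(tcs, function(m) m[, sel$selected, drop = FALSE]),
       selected = sel$selected, report = sel$report)
}
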