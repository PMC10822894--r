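#' Sliding-window index intervals
#'
#' Rectangular (untapered) windows of `width` time points starting every
#' `step` points. A window starting at offset t (0-based) is admissible when
#' `t + width < n_timepoints` (strict), i.e. a final window that would end
#' exactly at the last time point is discarded; with T = 170, width = 18 and
#' step = 2 this yields exactly 76 windows. The count equals
#' `floor((T - width - 1)/step) + 1` when `T > width` and 0 otherwise.
#'
#' @param n_timepoints series length T.
#' @param width window width in time points (TRs), default 18.
#' @param step step between window starts, default 2.
#' @return integer matrix with columns `start`, `end`: 1-based inclusive row
#'   ranges of each window (zero rows when no window fits).
#' @export
sliding_windows <- function(n_timepoints, width = 18, step = 2) {
  Tn <- as.integer(n_timepoints); w <- as.integer(width); s <- as.integer(step)
  if (w < 2) stopf("window width must be >= 2")
  if (s < 1) stopf("window step must be >= 1")
  if (Tn <= w) {
    out <- matrix(integer(0), 0, 2)
  } else {
    starts <- seq.int(0L, Tn - w - 1L, by = s)
    out <- cbind(start = starts + 1L, end = starts + w)
  }
  colnames(out) <- c("start", "end")
  out
}

#' Fit a (ridge-regularized) multivariate autoregressive model
#'
#' Per-target least squares of `x_t` on the stacked lags `x_{t-1..t-p}` after
#' centering each column within the window. Short dynamic-connectivity
#' windows (18 samples, 12 channels) leave VAR(1) near-saturated, so a ridge
#' penalty scaled by the mean diagonal of the Gram matrix is applied by
#' default; `lambda = 0` recovers plain least squares.
#'
#' @param x time-by-component numeric matrix.
#' @param order VAR order p (default 1).
#' @param lambda nonnegative ridge multiplier; the effective penalty is
#'   `lambda * mean(diag(Z'Z))`.
#' @return object of class `mvar_fit`: `coefs` (list of p matrices in
#'   source-row orientation: entry (i, j) of lag-l matrix is the coefficient
#'   of channel i's lag l in channel j's equation), `resid_cov`, `n_obs`,
#'   `order`, `lambda`, `degenerate` (channels held at zero).
#' @export
fit_mvar <- function(x, order = 1, lambda = 0.1) {
  x <- as.matrix(x)
  p <- as.integer(order)
  Tn <- nrow(x); n <- ncol(x)
  if (p < 1) stopf("order must be >= 1")
  if (Tn <= p) stopf("window length (%d) must exceed order (%d)", Tn, p)
  if (lambda < 0) stopf("lambda must be nonnegative")
  if (any(!is.finite(x))) stopf("time courses contain non-finite values")

  degenerate <- apply(x, 2, function(col) max(col) == min(col))
  xc <- scale(x, center = TRUE, scale = FALSE)
  if (any(degenerate)) {
    warnf("constant channel(s) %s: coefficients set to 0",
          paste(which(degenerate), collapse = ", "))
    xc[, degenerate] <- 0
  }
  Y <- xc[(p + 1):Tn, , drop = FALSE]
  Z <- do.call(cbind, lapply(seq_len(p), function(l)
    xc[(p + 1 - l):(Tn - l), , drop = FALSE]))
  G <- crossprod(Z)
  pen <- if (lambda > 0) lambda * mean(diag(G)) else 0
  B <- tryCatch(solve(G + pen * diag(n * p), crossprod(Z, Y)),
                error = function(e) MASS::ginv(G + pen * diag(n * p)) %*% crossprod(Z, Y))
  resid <- Y - Z %*% B
  coefs <- lapply(seq_len(p), function(l) {
    A <- B[(l - 1) * n + seq_len(n), , drop = FALSE]
    dimnames(A) <- list(colnames(x), colnames(x))
    A
  })
  structure(list(coefs = coefs, resid_cov = crossprod(resid) / max(1, nrow(Y) - 1),
                 n_obs = nrow(Y), order = p, lambda = lambda,
                 degenerate = which(degenerate)),
            class = "mvar_fit")
}

#' Directed influence matrix from an MVAR fit
#'
#' Converts a fitted MVAR into a square effective-connectivity matrix with
#' source rows: entry (i, j) is the influence of component i on component j.
#' `mode = "coef"` (default) reports the signed lag-coefficient path (summed
#' over lags for p > 1). `mode = "pdc"` reports the magnitude of partial
#' directed coherence averaged over an evenly spaced frequency grid on
#' [0, 0.5] (per-sample frequency units); PDC entries lie in [0, 1].
#'
#' @param fit an [fit_mvar()] result.
#' @param mode `"coef"` or `"pdc"`.
#' @param n_freq grid size for PDC averaging.
#' @return an `ec_matrix`: numeric matrix with attributes `mode` and `window`.
#' @export
influence_matrix <- function(fit, mode = c("coef", "pdc"), n_freq = 32) {
  stopifnot(inherits(fit, "mvar_fit"))
  mode <- match.arg(mode)
  n <- nrow(fit$coefs[[1]])
  if (mode == "coef") {
    M <- Reduce(`+`, fit$coefs)
  } else {
    freqs <- seq(0, 0.5, length.out = n_freq)
    acc <- matrix(0, n, n)
    for (f in freqs) {
      Abar <- diag(n) + 0i
      for (l in seq_len(fit$order))
        Abar <- Abar - t(fit$coefs[[l]]) * exp(-2i * pi * f * l)
      # PDC source s -> target t: |Abar[t, s]| normalized over column s
      mag <- Mod(Abar)
      denom <- sqrt(colSums(mag^2))
      acc <- acc + t(mag) / denom   # row s of result = column s of mag / denom[s]
    }
    M <- acc / length(freqs)
    dimnames(M) <- dimnames(fit$coefs[[1]])
  }
  structure(M, mode = mode, window = NA_integer_, class = c("ec_matrix", "matrix"))
}

as_tc_matrix <- function(subject) {
  if (inherits(subject, "subject_tc")) subject$tc else as.matrix(subject)
}

#' Windowed effective connectivity for one subject
#'
#' Segments the subject's time courses with [sliding_windows()] and fits one
#' MVAR per window, returning the ordered stack of influence matrices.
#'
#' @param subject a `subject_tc` or a time-by-component matrix.
#' @param width,step window specification in TRs (defaults 18 and 2).
#' @param order,lambda,mode MVAR settings passed to [fit_mvar()] and
#'   [influence_matrix()].
#' @return object of class `ec_stack`: `matrices` (n x n x n_windows array),
#'   `windows` (start/end index matrix), `subject_id`, and `settings`.
#' @export
windowed_ec <- function(subject, width = 18, step = 2, order = 1,
                        lambda = 0.1, mode = c("coef", "pdc")) {
  mode <- match.arg(mode)
  x <- as_tc_matrix(subject)
  if (width < order + 2) stopf("window width must be >= order + 2")
  win <- sliding_windows(nrow(x), width, step)
  if (nrow(win) == 0)
    stopf("no admissible window: T = %d, width = %d, step = %d", nrow(x), width, step)
  n <- ncol(x)
  arr <- array(NA_real_, c(n, n, nrow(win)),
               dimnames = list(colnames(x), colnames(x), NULL))
  for (wdx in seq_len(nrow(win))) {
    fit <- fit_mvar(x[win[wdx, "start"]:win[wdx, "end"], , drop = FALSE],
                    order = order, lambda = lambda)
    M <- influence_matrix(fit, mode)
    attr(M, "window") <- wdx
    arr[, , wdx] <- M
  }
  structure(list(matrices = arr, windows = win,
                 subject_id = if (inherits(subject, "subject_tc")) subject$subject_id else "subject",
                 settings = list(width = width, step = step, order = order,
                                 lambda = lambda, mode = mode)),
            class = "ec_stack")
}

#' @export
print.ec_stack <- function(x, ...) {
  cat(sprintf("ec_stack %s: %d windows of %d x %d (width %d, step %d, VAR(%d), lambda %.3g, mode %s)\n",
              x$subject_id, dim(x$matrices)[3], dim(x$matrices)[1], dim(x$matrices)[2],
              x$settings$width, x$settings$step, x$settings$order,
              x$settings$lambda, x$settings$mode))
  invisible(x)
}

#' Whole-scan (static) effective connectivity
#'
#' A single MVAR fit over the entire scan, i.e. the static counterpart of
#' [windowed_ec()].
#'
#' @inheritParams windowed_ec
#' @return an `ec_matrix` with `window = "static"`.
#' @export
static_ec <- function(subject, order = 1, lambda = 0.1, mode = c("coef", "pdc")) {
  mode <- match.arg(mode)
  x <- as_tc_matrix(subject)
  fit <- fit_mvar(x, order = order, lambda = lambda)
  M <- influence_matrix(fit, mode)
  attr(M, "window") <- "static"
  M
}

#' Windowed EC for every subject of a cohort
#'
#' @param cohort a `dynec_cohort` (or list of `subject_tc`).
#' @inheritParams windowed_ec
#' @return named list of `ec_stack`, one per subject.
#' @export
cohort_windowed_ec <- function(cohort, width = 18, step = 2, order = 1,
                               lambda = 0.1, mode = "coef") {
  subjects <- if (inherits(cohort, "dynec_cohort")) cohort$subjects else cohort
  lapply(subjects, windowed_ec, width = width, step = step, order = order,
         lambda = lambda, mode = mode)
}
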