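# Vectorized Welch two-sample t over the columns of a subjects-by-edges
# matrix. Returns t, two-sided p (Welch-Satterthwaite df), and group counts.
welch_t_cols <- function(X, idxA, idxB) {
  A <- X[idxA, , drop = FALSE]
  B <- X[idxB, , drop = FALSE]
  nA <- colSums(!is.na(A)); nB <- colSums(!is.na(B))
  mA <- colMeans(A, na.rm = TRUE); mB <- colMeans(B, na.rm = TRUE)
  vA <- apply(A, 2, var, na.rm = TRUE); vB <- apply(B, 2, var, na.rm = TRUE)
  se2 <- vA / nA + vB / nB
  t <- (mA - mB) / sqrt(se2)
  df <- se2^2 / ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
  p <- 2 * pt(abs(t), df, lower.tail = FALSE)
  # zero-variance edges with equal means: t = 0/0; report t = 0, p = 1
  degen <- is.nan(t)
  t[degen] <- 0; p[degen] <- 1
  list(t = t, p = p, df = df, nA = nA, nB = nB)
}

# Normalize a group's per-subject EC matrices (list possibly holding NULLs,
# or an n x n x S array) to a subjects-by-edges matrix over off-diagonals.
group_to_edge_matrix <- function(ecs, off = NULL) {
  if (is.array(ecs) && length(dim(ecs)) == 3) {
    n <- dim(ecs)[1]
    ecs <- lapply(seq_len(dim(ecs)[3]), function(i) ecs[, , i])
  }
  ecs <- Filter(Negate(is.null), ecs)
  if (length(ecs) == 0) return(NULL)
  n <- nrow(ecs[[1]])
  if (is.null(off)) off <- which(row(diag(n)) != col(diag(n)))
  X <- t(vapply(ecs, function(m) as.matrix(m)[off], numeric(length(off))))
  attr(X, "n") <- n
  attr(X, "off") <- off
  X
}

edge_vec_to_matrix <- function(v, n, off, dimnames = NULL) {
  M <- matrix(NA_real_, n, n, dimnames = dimnames)
  M[off] <- v
  M
}

#' Edgewise Welch two-sample tests between groups
#'
#' Welch (unequal-variance) two-sample t-test on every off-diagonal edge of
#' per-subject EC matrices (typically state means). Subjects that lack a
#' matrix for the state (e.g. never visited it) are excluded, and the
#' per-group counts are recorded.
#'
#' @param ecA,ecB per-subject EC matrices for the two groups: lists of n x n
#'   matrices (`NULL` entries dropped) or n x n x S arrays.
#' @return list: `t` and `p` (n x n matrices, diagonal `NA`), `nA`, `nB`
#'   (per-edge counts), `df`.
#' @export
edgewise_ttest <- function(ecA, ecB) {
  XA <- group_to_edge_matrix(ecA)
  XB <- group_to_edge_matrix(ecB)
  if (is.null(XA) || nrow(XA) < 2 || is.null(XB) || nrow(XB) < 2)
    stopf("insufficient data: each group needs >= 2 subjects with data in this state")
  n <- attr(XA, "n"); off <- attr(XA, "off")
  if (!identical(n, attr(XB, "n"))) stopf("groups have inconsistent matrix dimensions")
  w <- welch_t_cols(rbind(XA, XB), seq_len(nrow(XA)), nrow(XA) + seq_len(nrow(XB)))
  list(t = edge_vec_to_matrix(w$t, n, off),
       p = edge_vec_to_matrix(w$p, n, off),
       df = edge_vec_to_matrix(w$df, n, off),
       nA = edge_vec_to_matrix(w$nA, n, off),
       nB = edge_vec_to_matrix(w$nB, n, off))
}

#' Network-based-statistic permutation test for group EC differences
#'
#' Thresholds the edgewise Welch |t| map at `t_threshold`, collects the
#' weakly connected components of the surviving directed edges, and compares
#' each component's extent (edge count) against the permutation null of the
#' maximum component extent obtained by shuffling group labels. Component
#' p-values use the add-one rule `p = (1 + #{null >= observed}) / (1 + n_perm)`.
#'
#' @param ecA,ecB as in [edgewise_ttest()].
#' @param t_threshold primary |t| threshold (default 3).
#' @param n_perm number of label permutations (default 1000, minimum 100).
#' @param seed optional seed for the permutations.
#' @return list: `t`, `p` (edgewise matrices), `components` (list with
#'   `edges` two-column matrix, `nodes`, `size`, `p_perm`), `null_max`
#'   (permutation distribution), plus the settings.
#' @export
nbs_component_test <- function(ecA, ecB, t_threshold = 3, n_perm = 1000, seed = NULL) {
  if (n_perm < 100) stopf("n_perm must be >= 100")
  XA <- group_to_edge_matrix(ecA)
  XB <- group_to_edge_matrix(ecB)
  if (is.null(XA) || nrow(XA) < 2 || is.null(XB) || nrow(XB) < 2)
    stopf("insufficient data: each group needs >= 2 subjects with data in this state")
  n <- attr(XA, "n"); off <- attr(XA, "off")
  X <- rbind(XA, XB)
  idxA <- seq_len(nrow(XA)); idxB <- nrow(XA) + seq_len(nrow(XB))
  obs <- welch_t_cols(X, idxA, idxB)

  src <- row(diag(n))[off]; tgt <- col(diag(n))[off]
  comp_sizes <- function(tvals) {
    hit <- which(abs(tvals) > t_threshold)
    if (length(hit) == 0) return(list(sizes = integer(0), membership = NULL, hit = hit))
    g <- igraph::graph_from_edgelist(cbind(src[hit], tgt[hit]), directed = TRUE)
    cmp <- igraph::components(g, mode = "weak")
    memb <- cmp$membership[src[hit]]   # component id of each surviving edge
    list(sizes = as.integer(table(memb)), membership = memb, hit = hit)
  }

  oc <- comp_sizes(obs$t)
  null_max <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      perm <- sample.int(nrow(X))
      tv <- welch_t_cols(X, perm[idxA], perm[idxB])$t
      s <- comp_sizes(tv)$sizes
      if (length(s) == 0) 0L else max(s)
    }, integer(1))
  })

  components <- list()
  if (length(oc$sizes) > 0) {
    for (cid in sort(unique(oc$membership))) {
      e <- oc$hit[oc$membership == cid]
      size <- length(e)
      components[[length(components) + 1]] <- list(
        edges = cbind(source = src[e], target = tgt[e]),
        nodes = sort(unique(c(src[e], tgt[e]))),
        size = size,
        p_perm = (1 + sum(null_max >= size)) / (1 + n_perm))
    }
    components <- components[order(-vapply(components, `[[`, integer(1), "size"))]
  }
  list(t = edge_vec_to_matrix(obs$t, n, off),
       p = edge_vec_to_matrix(obs$p, n, off),
       components = components, null_max = null_max,
       t_threshold = t_threshold, n_perm = n_perm, seed = seed)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param p vector of p-values in `[0, 1]` (`NA` allowed, passed through).
#' @param q FDR level for the rejection mask (default 0.05).
#' @return list: `adjusted` (BH-adjusted p, same order as input), `reject`
#'   (logical mask `adjusted <= q`).
#' @export
fdr_bh <- function(p, q = 0.05) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stopf("p-values must lie in [0, 1]")
  m <- sum(ok)
  adjusted <- rep(NA_real_, length(p))
  if (m > 0) {
    ord <- order(p[ok])
    ranked <- p[ok][ord] * m / seq_len(m)
    adj <- rev(cummin(rev(pmin(ranked, 1))))
    tmp <- numeric(m); tmp[ord] <- adj
    adjusted[ok] <- tmp
  }
  list(adjusted = adjusted, reject = !is.na(adjusted) & adjusted <= q)
}

# Average ranks (midranks) for Spearman.
midrank <- function(x) rank(x, ties.method = "average")

#' Spearman correlations between metrics and clinical variables
#'
#' Rank correlation (average ranks for ties) for every requested
#' metric-by-clinical pair, with BH-FDR adjustment across the family of
#' non-degenerate pairs. p-values use the t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))`.
#'
#' @param metrics data.frame with a `subject_id` column and metric columns.
#' @param clinical data.frame with `subject_id` and clinical columns.
#' @param metric_cols,clinical_cols column names to correlate (defaults: all
#'   numeric columns of each table).
#' @param q FDR level.
#' @return data.frame: `metric`, `clinical`, `n`, `rho`, `p`, `p_adj`,
#'   `excluded` (constant variable or < 4 paired observations).
#' @export
spearman_assoc <- function(metrics, clinical, metric_cols = NULL,
                           clinical_cols = NULL, q = 0.05) {
  if (!"subject_id" %in% names(metrics) || !"subject_id" %in% names(clinical))
    stopf("both tables need a subject_id column")
  merged <- merge(metrics, clinical, by = "subject_id", suffixes = c("", ".clin"))
  if (is.null(metric_cols))
    metric_cols <- setdiff(names(metrics)[vapply(metrics, is.numeric, logical(1))], "subject_id")
  if (is.null(clinical_cols))
    clinical_cols <- setdiff(names(clinical)[vapply(clinical, is.numeric, logical(1))], "subject_id")
  rows <- list()
  for (mc in metric_cols) for (cc in clinical_cols) {
    ccol <- if (cc %in% names(merged)) cc else paste0(cc, ".clin")
    x <- merged[[mc]]; y <- merged[[ccol]]
    keep <- !is.na(x) & !is.na(y)
    n <- sum(keep)
    excluded <- FALSE; rho <- NA_real_; pv <- NA_real_
    if (n < 4 || length(unique(x[keep])) < 2 || length(unique(y[keep])) < 2) {
      excluded <- TRUE
    } else {
      rho <- cor(midrank(x[keep]), midrank(y[keep]))
      if (abs(rho) >= 1) {
        pv <- 0
      } else {
        tstat <- rho * sqrt((n - 2) / (1 - rho^2))
        pv <- 2 * pt(abs(tstat), n - 2, lower.tail = FALSE)
      }
    }
    rows[[length(rows) + 1]] <- data.frame(
      metric = mc, clinical = cc, n = n, rho = rho, p = pv,
      p_adj = NA_real_, excluded = excluded, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  fam <- !out$excluded
  if (any(fam)) out$p_adj[fam] <- fdr_bh(out$p[fam], q)$adjusted
  out
}

#' ICC(2,1): two-way random effects, absolute agreement, single measures
#'
#' From the two-way ANOVA mean squares of a complete subjects-by-settings
#' matrix: `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`, with
#' the F test `MSR / MSE` on `(n-1, (n-1)(k-1))` degrees of freedom.
#'
#' @param m numeric matrix, rows = subjects (>= 3), columns = settings (>= 2),
#'   no missing cells.
#' @return object of class `icc_result`: `icc`, `F`, `df1`, `df2`, `p`,
#'   and the mean squares.
#' @export
icc_2_1 <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m); k <- ncol(m)
  if (k < 2) stopf("need >= 2 settings (columns)")
  if (n < 3) stopf("need >= 3 subjects (rows)")
  if (any(is.na(m))) stopf("missing cells are not allowed")
  grand <- mean(m)
  SSR <- k * sum((rowMeans(m) - grand)^2)
  SSC <- n * sum((colMeans(m) - grand)^2)
  SST <- sum((m - grand)^2)
  SSE <- max(SST - SSR - SSC, 0)
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  denom <- MSR + (k - 1) * MSE + k * (MSC - MSE) / n
  if (denom == 0) stopf("degenerate matrix: no variance anywhere")
  icc <- (MSR - MSE) / denom
  Fv <- if (MSE == 0) Inf else MSR / MSE
  p <- pf(Fv, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  structure(list(icc = icc, F = Fv, df1 = n - 1, df2 = (n - 1) * (k - 1),
                 p = p, MSR = MSR, MSC = MSC, MSE = MSE, n = n, k = k),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(2,1) = %.3f (F(%d,%d) = %.2f, p = %.3g)\n",
              x$icc, x$df1, x$df2, x$F, x$p))
  invisible(x)
}

# Match the states of `centroids` to `ref` by total L2 distance between
# off-diagonal centroid vectors over all k! permutations (k is small).
match_states <- function(ref, centroids) {
  k <- length(ref)
  vec <- function(M) M[!is.na(M)]
  cost <- outer(seq_len(k), seq_len(k),
                Vectorize(function(i, j) sum((vec(ref[[i]]) - vec(centroids[[j]]))^2)))
  perms <- all_permutations(k)
  tot <- vapply(perms, function(pp) sum(cost[cbind(seq_len(k), pp)]), numeric(1))
  perms[[which.min(tot)]]   # element i: which cluster of `centroids` plays ref state i
}

all_permutations <- function(k) {
  if (k == 1) return(list(1L))
  sub <- all_permutations(k - 1)
  out <- list()
  for (pp in sub) for (pos in seq_len(k)) {
    out[[length(out) + 1]] <- append(pp, k, after = pos - 1)
  }
  out
}

#' Reliability of temporal properties across window settings
#'
#' Re-runs windowing, clustering and temporal-property extraction for each
#' window setting, aligns states across settings by minimal centroid
#' distance (state labels are arbitrary per clustering run), and reports the
#' ICC(2,1) agreement between the reference (first) setting and every other
#' setting, for the fractional windows of each state and for the number of
#' transitions.
#'
#' @param cohort a `dynec_cohort`.
#' @param settings list of `c(width, step)` pairs; the first is the
#'   reference. Default: the 18/2 reference against 30/1 and 12/3.
#' @param k,metric,n_init clustering options (matched across settings).
#' @param order,lambda,mode MVAR options.
#' @param seed seed reused for every setting's clustering.
#' @return list: `table` (data.frame comparison x property x state with icc
#'   and p), `icc` (named list of `icc_result`), `measurements` (the
#'   subjects-by-settings matrices).
#' @export
reliability_across_windows <- function(cohort,
                                       settings = list(c(18, 2), c(30, 1), c(12, 3)),
                                       k = 2, metric = "L2", n_init = 10,
                                       order = 1, lambda = 0.1, mode = "coef",
                                       seed = NULL) {
  stopifnot(length(settings) >= 2)
  per_setting <- vector("list", length(settings))
  ref_centroids <- NULL
  subject_ids <- names(cohort$subjects)
  for (i in seq_along(settings)) {
    w <- settings[[i]][1]; s <- settings[[i]][2]
    stacks <- cohort_windowed_ec(cohort, width = w, step = s, order = order,
                                 lambda = lambda, mode = mode)
    part <- cluster_states(stacks, k = k, metric = metric, n_init = n_init, seed = seed)
    if (i == 1) {
      ref_centroids <- part$centroids
      align <- seq_len(k)
    } else {
      align <- match_states(ref_centroids, part$centroids)
    }
    Fm <- matrix(NA_real_, length(subject_ids), k, dimnames = list(subject_ids, NULL))
    NT <- stats::setNames(numeric(length(subject_ids)), subject_ids)
    for (sid in subject_ids) {
      lab <- part$labels[part$labels$subject_id == sid, ]
      tp <- temporal_properties(lab$state[order(lab$window)], k)
      Fm[sid, ] <- tp$F[align]
      NT[sid] <- tp$NT
    }
    per_setting[[i]] <- list(F = Fm, NT = NT)
  }
  setting_name <- vapply(settings, function(ws) sprintf("w%d_s%d", ws[1], ws[2]), character(1))
  iccs <- list(); rows <- list(); meas <- list()
  for (i in 2:length(settings)) {
    cmp <- sprintf("%s_vs_%s", setting_name[1], setting_name[i])
    for (st in seq_len(k)) {
      m <- cbind(per_setting[[1]]$F[, st], per_setting[[i]]$F[, st])
      res <- icc_2_1(m)
      key <- sprintf("F_state%d_%s", st, cmp)
      iccs[[key]] <- res; meas[[key]] <- m
      rows[[length(rows) + 1]] <- data.frame(comparison = cmp, property = "F",
                                             state = st, icc = res$icc, p = res$p,
                                             stringsAsFactors = FALSE)
    }
    m <- cbind(per_setting[[1]]$NT, per_setting[[i]]$NT)
    res <- icc_2_1(m)
    key <- sprintf("NT_%s", cmp)
    iccs[[key]] <- res; meas[[key]] <- m
    rows[[length(rows) + 1]] <- data.frame(comparison = cmp, property = "NT",
                                           state = NA_integer_, icc = res$icc,
                                           p = res$p, stringsAsFactors = FALSE)
  }
  list(table = do.call(rbind, rows), icc = iccs, measurements = meas)
}
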