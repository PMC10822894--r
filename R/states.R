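# Vectorize the off-diagonal entries of every window of every stack into a
# pooled matrix (rows = windows), with bookkeeping of subject and window ids.
pool_windows <- function(stacks) {
  if (inherits(stacks, "ec_stack")) stacks <- list(stacks)
  n <- dim(stacks[[1]]$matrices)[1]
  off <- which(row(diag(n)) != col(diag(n)))
  rows <- list(); subj <- character(0); wdx <- integer(0)
  for (st in stacks) {
    if (dim(st$matrices)[1] != n) stopf("stacks have inconsistent dimensions")
    W <- dim(st$matrices)[3]
    flat <- matrix(st$matrices, n * n, W)
    rows[[length(rows) + 1]] <- t(flat[off, , drop = FALSE])
    subj <- c(subj, rep(st$subject_id, W))
    wdx <- c(wdx, seq_len(W))
  }
  list(V = do.call(rbind, rows), subject = subj, window = wdx, n = n, off = off)
}

# Lloyd-type k-medians (L1) with n_init random restarts.
kmedians <- function(V, k, n_init, iter_max = 100) {
  best <- NULL
  for (init in seq_len(n_init)) {
    cen <- V[sample.int(nrow(V), k), , drop = FALSE]
    lab <- integer(nrow(V))
    for (it in seq_len(iter_max)) {
      d <- sapply(seq_len(k), function(j) colSums(abs(t(V) - cen[j, ])))
      newlab <- max.col(-d, ties.method = "first")
      if (identical(newlab, lab)) break
      lab <- newlab
      for (j in seq_len(k)) {
        m <- V[lab == j, , drop = FALSE]
        if (nrow(m) > 0) cen[j, ] <- apply(m, 2, median)
      }
    }
    inertia <- sum(d[cbind(seq_len(nrow(V)), lab)])
    if (is.null(best) || inertia < best$inertia)
      best <- list(cluster = lab, centers = cen, inertia = inertia)
  }
  best
}

#' Cluster windowed EC matrices into recurring states
#'
#' Pools the windowed influence matrices of all subjects, vectorizes the
#' off-diagonal entries (self-influence is not an inter-regional edge), and
#' partitions them with best-of-`n_init` k-means (L2, the default) or a
#' Lloyd-type k-medians (L1). States are renumbered by descending occupancy,
#' so state 1 is always the most frequent pattern.
#'
#' @param stacks list of [windowed_ec()] stacks (or a single stack).
#' @param k number of states (default 2).
#' @param metric `"L2"` (k-means) or `"L1"` (k-medians).
#' @param n_init number of random restarts (default 10).
#' @param seed optional seed making the clustering deterministic.
#' @param scale_matrices if `TRUE`, z-score each off-diagonal feature across
#'   windows before clustering (default `FALSE`: raw coefficients).
#' @return object of class `state_partition`: `k`, `centroids` (list of n x n
#'   matrices, diagonal `NA`), `labels` (data.frame subject_id, window,
#'   state), `occupancy`, `inertia`, `metric`, `seed`.
#' @export
cluster_states <- function(stacks, k = 2, metric = c("L2", "L1"), n_init = 10,
                           seed = NULL, scale_matrices = FALSE) {
  metric <- match.arg(metric)
  pool <- pool_windows(stacks)
  if (k < 1) stopf("k must be >= 1")
  if (k > nrow(pool$V)) stopf("k = %d exceeds the %d pooled windows", k, nrow(pool$V))
  V <- pool$V
  if (scale_matrices) {
    sds <- apply(V, 2, sd)
    sds[sds == 0] <- 1
    V <- scale(V, center = TRUE, scale = sds)
  }
  res <- with_seed(seed, {
    if (k == 1) {
      list(cluster = rep(1L, nrow(V)),
           centers = matrix(colMeans(V), 1),
           inertia = sum(scale(V, scale = FALSE)^2))
    } else if (metric == "L2") {
      km <- kmeans(V, centers = k, nstart = n_init, iter.max = 100)
      list(cluster = km$cluster, centers = km$centers, inertia = km$tot.withinss)
    } else {
      kmedians(V, k, n_init)
    }
  })
  counts <- tabulate(res$cluster, nbins = k)
  ord <- order(-counts, seq_len(k))
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  labels <- relabel[res$cluster]
  centroids <- vector("list", k)
  for (s in seq_len(k)) {
    cen <- res$centers[ord[s], ]
    if (scale_matrices) cen <- cen * attr(V, "scaled:scale") + attr(V, "scaled:center")
    M <- matrix(NA_real_, pool$n, pool$n)
    M[pool$off] <- cen
    centroids[[s]] <- M
  }
  occupancy <- counts[ord] / sum(counts)
  structure(list(k = k, centroids = centroids,
                 labels = data.frame(subject_id = pool$subject,
                                     window = pool$window,
                                     state = labels,
                                     stringsAsFactors = FALSE),
                 occupancy = occupancy, inertia = res$inertia,
                 metric = metric, seed = seed,
                 scale_matrices = scale_matrices),
            class = "state_partition")
}

#' @export
print.state_partition <- function(x, ...) {
  cat(sprintf("state_partition: k = %d (%s), %d windows, occupancy %s\n",
              x$k, x$metric, nrow(x$labels),
              paste(sprintf("%.1f%%", 100 * x$occupancy), collapse = " / ")))
  invisible(x)
}

#' Occupancy percentages and per-subject window shares
#'
#' @param partition a [cluster_states()] result.
#' @return list with `percent` (per-state percentage over all windows) and
#'   `per_subject` (data.frame: subject_id, one share column per state).
#' @export
occupancy_report <- function(partition) {
  stopifnot(inherits(partition, "state_partition"))
  lab <- partition$labels
  if (nrow(lab) == 0) stopf("empty partition")
  percent <- 100 * tabulate(lab$state, partition$k) / nrow(lab)
  subjects <- unique(lab$subject_id)
  shares <- t(vapply(subjects, function(s) {
    st <- lab$state[lab$subject_id == s]
    tabulate(st, partition$k) / length(st)
  }, numeric(partition$k)))
  per_subject <- data.frame(subject_id = subjects, shares,
                            stringsAsFactors = FALSE, row.names = NULL)
  names(per_subject)[-1] <- sprintf("state%d", seq_len(partition$k))
  list(percent = percent, per_subject = per_subject)
}

#' Clustering diagnostics over a range of k
#'
#' Reports inertia and mean silhouette width per candidate k; diagnostics
#' only, nothing is auto-selected. Silhouettes are computed on a random
#' subsample of at most `max_silhouette` windows to keep the distance matrix
#' small.
#'
#' @param stacks list of `ec_stack`.
#' @param k_range candidate state counts (default 2:6).
#' @param metric,n_init,seed as in [cluster_states()].
#' @param max_silhouette subsample cap for the silhouette computation.
#' @return data.frame with columns `k`, `inertia`, `silhouette`.
#' @export
suggest_k <- function(stacks, k_range = 2:6, metric = c("L2", "L1"),
                      n_init = 5, seed = NULL, max_silhouette = 2000) {
  metric <- match.arg(metric)
  pool <- pool_windows(stacks)
  if (max(k_range) > nrow(pool$V)) stopf("k_range exceeds the pooled window count")
  sub <- with_seed(seed, sample.int(nrow(pool$V), min(max_silhouette, nrow(pool$V))))
  D <- stats::dist(pool$V[sub, , drop = FALSE],
                   method = if (metric == "L1") "manhattan" else "euclidean")
  out <- data.frame(k = k_range, inertia = NA_real_, silhouette = NA_real_)
  for (i in seq_along(k_range)) {
    part <- cluster_states(stacks, k = k_range[i], metric = metric,
                           n_init = n_init, seed = if (is.null(seed)) NULL else seed + i)
    out$inertia[i] <- part$inertia
    labs <- part$labels$state[sub]
    if (length(unique(labs)) > 1) {
      sil <- cluster::silhouette(labs, D)
      out$silhouette[i] <- mean(sil[, "sil_width"])
    }
  }
  out
}
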