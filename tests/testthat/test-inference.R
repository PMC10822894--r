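random_group <- function(n_sub, n = 5, mean_shift = NULL, sd = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n_sub), function(i) {
    M <- matrix(rnorm(n * n, sd = sd), n)
    if (!is.null(mean_shift)) M <- M + mean_shift
    M
  })
}

test_that("edgewise Welch tests behave on identical and swapped groups", {
  g <- random_group(6, seed = 61)
  res <- edgewise_ttest(g, g)
  off <- !is.na(res$t)
  expect_true(all(res$t[off] == 0))
  expect_true(all(res$p[off] == 1))
  gB <- random_group(8, seed = 62)
  r1 <- edgewise_ttest(g, gB)
  r2 <- edgewise_ttest(gB, g)
  expect_equal(r1$t[off], -r2$t[off])
  expect_equal(r1$p[off], r2$p[off])
  expect_equal(unique(r1$nA[off]), 6)
  expect_error(edgewise_ttest(g[1], gB), "insufficient")
})

test_that("a planted mean shift on one edge attains the minimum p", {
  n <- 8
  shift <- matrix(0, n, n); shift[2, 7] <- 3
  gA <- random_group(20, n = n, mean_shift = shift, seed = 63)
  gB <- random_group(20, n = n, seed = 64)
  res <- edgewise_ttest(gA, gB)
  expect_equal(which(res$p == min(res$p, na.rm = TRUE)), (7 - 1) * n + 2)
})

test_that("NBS finds planted clusters and nothing under the null", {
  g <- random_group(6, seed = 65)
  null_res <- nbs_component_test(g, g, t_threshold = 3, n_perm = 100, seed = 1)
  expect_length(null_res$components, 0)
  # planted 4-node fully interconnected cluster among 8 nodes
  n <- 8
  nodes <- 1:4
  shift <- matrix(0, n, n)
  shift[nodes, nodes] <- 1.5; diag(shift) <- 0
  gA <- random_group(15, n = n, mean_shift = shift, seed = 66)
  gB <- random_group(15, n = n, seed = 67)
  res <- nbs_component_test(gA, gB, t_threshold = 3, n_perm = 1000, seed = 2)
  expect_gte(length(res$components), 1)
  expect_equal(res$components[[1]]$nodes, nodes)
  expect_lt(res$components[[1]]$p_perm, 0.05)
  # permutation p is invariant to a consistent node relabeling
  perm <- c(3, 1, 4, 2, 8, 6, 5, 7)
  relabel <- function(g) lapply(g, function(M) M[perm, perm])
  res2 <- nbs_component_test(relabel(gA), relabel(gB),
                             t_threshold = 3, n_perm = 1000, seed = 2)
  expect_equal(res2$components[[1]]$size, res$components[[1]]$size)
  expect_equal(res2$components[[1]]$p_perm, res$components[[1]]$p_perm)
  expect_equal(sort(perm[res2$components[[1]]$nodes]), nodes)
})

test_that("BH-FDR matches the hand example and the brute-force oracle", {
  out <- fdr_bh(c(0.002, 0.01, 0.03, 0.04), q = 0.05)
  expect_equal(out$adjusted, c(0.008, 0.02, 0.04, 0.04))
  expect_true(all(out$reject))
  expect_false(any(fdr_bh(rep(1, 5))$reject))
  expect_equal(fdr_bh(0.73)$adjusted, 0.73)
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(71)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    res <- fdr_bh(p)
    expect_equal(res$adjusted, bh_oracle(p), tolerance = 1e-12)
    expect_equal(res$adjusted, stats::p.adjust(p, "BH"), tolerance = 1e-12)
    # monotone non-decreasing in raw-p order
    expect_true(all(diff(res$adjusted[order(p)]) >= -1e-12))
  }
})

test_that("Spearman correlations match the rank-formula oracle, ties included", {
  m <- data.frame(subject_id = sprintf("s%d", 1:4), met = c(1, 2, 3, 4))
  cl <- data.frame(subject_id = sprintf("s%d", 1:4), var = c(10, 20, 30, 40))
  expect_equal(spearman_assoc(m, cl)$rho, 1)
  cl$var <- rev(cl$var)
  expect_equal(spearman_assoc(m, cl)$rho, -1)
  set.seed(72)
  for (i in 1:50) {
    n <- sample(5:30, 1)
    x <- sample(1:5, n, replace = TRUE)   # heavy ties
    y <- x + rnorm(n)
    mt <- data.frame(subject_id = sprintf("s%d", 1:n), met = x)
    ct <- data.frame(subject_id = sprintf("s%d", 1:n), var = y)
    res <- spearman_assoc(mt, ct)
    expect_equal(res$rho, spearman_oracle(x, y), tolerance = 1e-12)
    expect_equal(res$rho, suppressWarnings(cor(x, y, method = "spearman")),
                 tolerance = 1e-12)
  }
  # constant variable is flagged and excluded from the family
  ct2 <- data.frame(subject_id = sprintf("s%d", 1:10), var = rep(2, 10))
  mt2 <- data.frame(subject_id = sprintf("s%d", 1:10), met = rnorm(10))
  res2 <- spearman_assoc(mt2, ct2)
  expect_true(res2$excluded)
  expect_true(is.na(res2$rho))
})

test_that("ICC(2,1) matches the ANOVA mean-squares oracle", {
  set.seed(73)
  x <- rnorm(10)
  expect_equal(icc_2_1(cbind(x, x))$icc, 1)
  m <- cbind(c(1, 2, 3), c(3, 2, 1))
  res <- icc_2_1(m)
  expect_equal(res$icc, icc_oracle(m), tolerance = 1e-12)
  expect_lt(res$icc, 0)
  for (i in 1:20) {
    mm <- matrix(rnorm(8 * 3), 8, 3) + rnorm(8)   # subject effects
    expect_equal(icc_2_1(mm)$icc, icc_oracle(mm), tolerance = 1e-10)
  }
  # absolute agreement: adding a constant offset to one setting lowers ICC
  base <- cbind(x, x + rnorm(10, sd = 0.1))
  offset <- base; offset[, 2] <- offset[, 2] + 2
  expect_lt(icc_2_1(offset)$icc, icc_2_1(base)$icc)
  expect_error(icc_2_1(cbind(x)), "settings")
  expect_error(icc_2_1(matrix(c(1, 2, 3, NA, 5, 6), 3)), "missing")
  # independent columns: agreement near zero
  set.seed(74)
  ind <- replicate(2, rnorm(40))
  expect_lt(abs(icc_2_1(ind)$icc), 0.3)
})

test_that("reliability across window settings is coherent", {
  co <- simulate_cohort(small_cfg(n_per_group = c(patient = 6, control = 6),
                                  Tn = 150, seed = 10))
  # same setting twice: identical pipeline, ICC = 1
  rel_same <- reliability_across_windows(co, settings = list(c(18, 2), c(18, 2)),
                                         seed = 11)
  f1 <- rel_same$table[rel_same$table$property == "F" & rel_same$table$state == 1, ]
  expect_equal(f1$icc, 1, tolerance = 1e-10)
  # different settings on a well-separated cohort: high agreement
  rel <- reliability_across_windows(co, settings = list(c(18, 2), c(30, 1)),
                                    seed = 11)
  f1b <- rel$table[rel$table$property == "F" & rel$table$state == 1, ]
  expect_gt(f1b$icc, 0.7)
})
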