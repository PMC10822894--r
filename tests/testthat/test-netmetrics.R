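test_that("degree profile matches manual row/column enumeration", {
  M <- matrix(c(0, 2, 1,
                0, 0, 3,
                1, 0, 0), 3, 3, byrow = TRUE)
  d <- degree_profile(M)
  expect_equal(d$out_weighted, c(3, 3, 1))
  expect_equal(d$in_weighted, c(1, 2, 4))
  expect_equal(d$in_out_weighted, c(-2, -1, 3))
  expect_equal(degree_profile(matrix(0, 4, 4))$in_out_weighted, rep(0, 4))
  expect_error(degree_profile(matrix(0, 2, 3)), "square")
})

test_that("degree identities hold on random matrices", {
  set.seed(51)
  for (i in 1:20) {
    n <- sample(3:10, 1)
    M <- matrix(rnorm(n * n), n)
    for (use_abs in c(TRUE, FALSE)) {
      d <- degree_profile(M, use_abs = use_abs)
      # brute-force sums
      v <- if (use_abs) abs(M) else M
      for (j in seq_len(n)) {
        expect_equal(d$out_weighted[j], sum(v[j, -j]))
        expect_equal(d$in_weighted[j], sum(v[-j, j]))
      }
      # signed bookkeeping: in-out degrees always sum to zero
      expect_equal(sum(d$in_out_weighted), 0, tolerance = 1e-12)
      # transpose swaps in and out exactly
      dt <- degree_profile(t(M), use_abs = use_abs)
      expect_equal(dt$in_weighted, d$out_weighted)
      expect_equal(dt$out_weighted, d$in_weighted)
    }
    S <- M + t(M)
    ds <- degree_profile(S)
    expect_equal(ds$in_weighted, ds$out_weighted)
    expect_equal(ds$in_out_weighted, rep(0, n))
  }
})

test_that("temporal properties match manual run-length enumeration", {
  tp <- temporal_properties(c(1, 1, 2, 2, 2, 1), 2)
  expect_equal(tp$F, c(0.5, 0.5))
  expect_equal(tp$MDT, c(1.5, 3.0))
  expect_equal(tp$NT, 2L)
  tp2 <- temporal_properties(c(1, 1, 1, 1), 2)
  expect_equal(tp2$F, c(1, 0))
  expect_equal(tp2$MDT, c(4, 0))
  expect_equal(tp2$visited, c(TRUE, FALSE))
  expect_equal(tp2$NT, 0L)
  tp3 <- temporal_properties(c(1, 2, 1, 2), 2)
  expect_equal(tp3$F, c(0.5, 0.5))
  expect_equal(tp3$MDT, c(1, 1))
  expect_equal(tp3$NT, 3L)
  expect_error(temporal_properties(c(1, 3), 2), "1..2")
  expect_error(temporal_properties(integer(0), 2), "non-empty")
  expect_equal(mdt_to_seconds(3, step = 2, tr = 2), 12)
})

test_that("conservation identities hold on random label sequences", {
  set.seed(52)
  for (i in 1:1000) {
    k <- sample(2:4, 1)
    n <- sample(1:60, 1)
    labels <- sample.int(k, n, replace = TRUE)
    tp <- temporal_properties(labels, k)
    oracle <- temporal_oracle(labels, k)
    expect_identical(tp$F, oracle$F)
    expect_identical(tp$MDT, oracle$MDT)
    expect_equal(tp$NT, oracle$NT)
    expect_equal(sum(tp$F), 1)
    expect_equal(sum(tp$MDT * tp$n_runs), n)
    expect_equal(sum(tp$n_runs), tp$NT + 1L)
  }
})

test_that("subject_state_summary handles missing states and cancellation", {
  n <- 4
  M <- matrix(rnorm(n * n), n)
  stack <- make_stack(list(M, -M, M, M), subject_id = "sub-001")
  part <- make_partition(list("sub-001" = c(1L, 1L, 1L, 1L)), k = 2)
  ss <- subject_state_summary(stack, part)
  expect_equal(ss$temporal$F, c(1, 0))
  expect_null(ss$state_means[[2]])
  expect_null(ss$degrees[[2]])
  expect_false(ss$temporal$visited[2])
  # M and -M in one state average toward cancellation
  part2 <- make_partition(list("sub-001" = c(1L, 1L, 2L, 2L)), k = 2)
  ss2 <- subject_state_summary(stack, part2)
  expect_equal(ss2$state_means[[1]], (M - M) / 2, ignore_attr = TRUE)
  expect_equal(ss2$state_means[[2]], M, ignore_attr = TRUE)
  expect_error(subject_state_summary(make_stack(list(M), "ghost"), part), "absent")
})

test_that("state_metrics_table is tidy and carries degrees", {
  co <- simulate_cohort(small_cfg(seed = 8))
  stacks <- cohort_windowed_ec(co)
  part <- cluster_states(stacks, k = 2, seed = 9)
  tab <- state_metrics_table(stacks, part, groups = co)
  expect_equal(nrow(tab), 2 * length(co$subjects))
  expect_true(all(c("subject_id", "group", "state", "F", "MDT", "NT") %in% names(tab)))
  expect_true(any(grepl("^inout_", names(tab))))
  byF <- tapply(tab$F, tab$subject_id, sum)
  expect_equal(as.numeric(byF), rep(1, length(co$subjects)), tolerance = 1e-12)
})
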