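test_that("window count matches brute-force enumeration on a grid", {
  for (Tn in seq(1, 60, by = 3)) for (w in c(2, 5, 10, 18, 20)) for (s in 1:5) {
    brute <- sum((seq(0, max(Tn, 1), by = s)) + w < Tn)
    expect_equal(nrow(sliding_windows(Tn, w, s)), brute,
                 info = sprintf("T=%d w=%d s=%d", Tn, w, s))
  }
})

test_that("printed window-count facts and boundary conventions hold", {
  win <- sliding_windows(170, 18, 2)
  expect_equal(nrow(win), 76)
  expect_equal(win[1, ], c(start = 1L, end = 18L))
  expect_equal(unname(win[76, "end"]), 168L)   # strict: never touches T
  one <- sliding_windows(19, 18, 2)
  expect_equal(nrow(one), 1)
  expect_equal(one[1, ], c(start = 1L, end = 18L))
  expect_equal(nrow(sliding_windows(18, 18, 2)), 0)
})

test_that("fit_mvar is consistent at long T and deterministic", {
  A <- matrix(0, 4, 4); A[1, 2] <- 0.5; diag(A) <- 0.2
  cfg <- sim_config(n_subjects_per_group = c(patient = 2, control = 2),
                    n_timepoints = 2000, n_components = 4,
                    coupling_state1 = A, coupling_state2 = A, effect_size = 0)
  x <- simulate_subject(cfg, "control", seed = 17)$tc
  f1 <- fit_mvar(x, order = 1, lambda = 0)
  f2 <- fit_mvar(x, order = 1, lambda = 0)
  expect_identical(f1, f2)
  expect_lt(max(abs(f1$coefs[[1]] - A)), 0.05)
})

test_that("ridge shrinks coefficients monotonically toward zero", {
  set.seed(18)
  x <- matrix(rnorm(40 * 5), 40, 5)
  norms <- vapply(c(0, 0.5, 5, 50, 5000), function(l)
    sqrt(sum(fit_mvar(x, lambda = l)$coefs[[1]]^2)), numeric(1))
  expect_true(all(diff(norms) < 0))
  expect_lt(norms[5], 1e-2)
})

test_that("constant channels are zeroed with a warning", {
  set.seed(19)
  x <- cbind(rnorm(50), rep(3, 50), rnorm(50))
  expect_warning(f <- fit_mvar(x), "constant channel")
  expect_equal(f$coefs[[1]][2, ], rep(0, 3))
  expect_equal(f$coefs[[1]][, 2], rep(0, 3))
  expect_equal(f$degenerate, 2L)
})

test_that("influence matrices recover a planted edge in both modes", {
  A <- matrix(0, 4, 4); A[1, 2] <- 0.5; diag(A) <- 0.2
  cfg <- sim_config(n_subjects_per_group = c(patient = 2, control = 2),
                    n_timepoints = 2000, n_components = 4,
                    coupling_state1 = A, coupling_state2 = A, effect_size = 0)
  x <- simulate_subject(cfg, "control", seed = 23)$tc
  fit <- fit_mvar(x, lambda = 0)
  off <- which(row(diag(4)) != col(diag(4)))
  for (mode in c("coef", "pdc")) {
    M <- influence_matrix(fit, mode)
    expect_equal(which.max(abs(M[off])), which(off == (4 * (2 - 1) + 1)))
    if (mode == "pdc") expect_true(all(M >= 0 & M <= 1))
  }
  expect_error(influence_matrix(fit, "nonsense"))
  # null VAR: off-diagonals near zero in coef mode
  cfg0 <- sim_config(n_subjects_per_group = c(patient = 2, control = 2),
                     n_timepoints = 2000, n_components = 4,
                     coupling_state1 = matrix(0, 4, 4),
                     coupling_state2 = matrix(0, 4, 4), effect_size = 0)
  x0 <- simulate_subject(cfg0, "control", seed = 24)$tc
  M0 <- influence_matrix(fit_mvar(x0, lambda = 0), "coef")
  expect_lt(max(abs(M0[off])), 3 / sqrt(nrow(x0)) * 3)
})

test_that("windowed_ec produces the right stack and fails loudly on short data", {
  cfg <- small_cfg(Tn = 170, n_comp = 6)
  s <- simulate_subject(cfg, "control", seed = 25)
  st <- windowed_ec(s)
  expect_s3_class(st, "ec_stack")
  expect_equal(dim(st$matrices), c(6, 6, 76))
  expect_equal(st$settings$width, 18)
  expect_error(windowed_ec(s$tc[1:18, ]), "T = 18, width = 18, step = 2")
  expect_error(windowed_ec(s, width = 2, order = 1), "order")
})

test_that("static EC approximates the mean of windowed EC for a stationary subject", {
  A <- matrix(0, 5, 5); A[1, 2] <- 0.5; diag(A) <- 0.25
  cfg <- sim_config(n_subjects_per_group = c(patient = 2, control = 2),
                    n_timepoints = 400, n_components = 5,
                    coupling_state1 = A, coupling_state2 = A, effect_size = 0,
                    stay_probs = list(patient = c(0.9, 0.9), control = c(0.9, 0.9)))
  s <- simulate_subject(cfg, "control", seed = 26)
  st <- windowed_ec(s, width = 40, step = 5, lambda = 0.05)
  mean_windowed <- apply(st$matrices, c(1, 2), mean)
  static <- static_ec(s, lambda = 0.05)
  expect_lt(max(abs(mean_windowed - unclass(static))), 0.12)
  expect_gt(static[1, 2], 0.3)   # planted edge survives as the top entry
})
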