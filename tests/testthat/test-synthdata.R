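test_that("state chain handles degenerate and absorbing cases", {
  expect_equal(simulate_state_chain(50, 1, 0.7, seed = 1), rep(1L, 50))
  s <- simulate_state_chain(200, 2, c(1, 1), seed = 2)
  expect_equal(length(unique(s)), 1L)
  expect_error(simulate_state_chain(10, 2, c(0.5, 1.2)), "probabilit")
  expect_error(simulate_state_chain(10, 2, c(0.5, 0)), "probabilit")
})

test_that("long chains reach the analytic stationary distribution", {
  # two-state chain oracle: pi_1 = (1 - q) / ((1 - p) + (1 - q))
  p <- 0.9; q <- 0.6
  pi1 <- (1 - q) / ((1 - p) + (1 - q))
  expect_equal(pi1, 0.8)
  s <- simulate_state_chain(20000, 2, c(p, q), seed = 7)
  expect_lt(abs(mean(s == 1) - pi1), 0.02)
  # three states, asymmetric stays: oracle via direct eigen solve in the test
  stays <- c(0.9, 0.8, 0.7)
  P <- matrix(0, 3, 3)
  for (i in 1:3) { P[i, ] <- (1 - stays[i]) / 2; P[i, i] <- stays[i] }
  e <- eigen(t(P)); v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  pi_oracle <- v / sum(v)
  s3 <- simulate_state_chain(30000, 3, stays, seed = 8)
  emp <- tabulate(s3, 3) / length(s3)
  expect_lt(max(abs(emp - pi_oracle)), 0.02)
})

test_that("simulator is deterministic and rejects non-stationary coupling", {
  cfg <- small_cfg()
  a <- simulate_subject(cfg, "control", seed = 42)
  b <- simulate_subject(cfg, "control", seed = 42)
  expect_identical(a, b)
  c1 <- simulate_cohort(cfg, seed = 9)
  c2 <- simulate_cohort(cfg, seed = 9)
  expect_identical(c1, c2)
  expect_error(small_cfg(coupling_state2 = diag(1.05, 6)), "coupling_state2.*non-stationary")
  expect_error(small_cfg(stay_probs = list(patient = c(1, 0.5), control = c(0.9, 0.5))),
               "stay_probs")
  expect_error(small_cfg(Tn = 1), "n_timepoints")
})

test_that("zero coupling yields independent white noise", {
  cfg <- sim_config(n_subjects_per_group = c(patient = 2, control = 2),
                    n_timepoints = 2000, n_components = 4,
                    coupling_state1 = matrix(0, 4, 4),
                    coupling_state2 = matrix(0, 4, 4),
                    effect_size = 0)
  s <- simulate_subject(cfg, "control", seed = 5)
  x <- s$tc
  lag1 <- cor(x[-nrow(x), ], x[-1, ])
  expect_lt(mean(abs(lag1)), 0.05)
})

test_that("a planted single-state edge is recovered by a least-squares oracle", {
  A <- matrix(0, 3, 3); A[1, 2] <- 0.5
  cfg <- sim_config(n_subjects_per_group = c(patient = 2, control = 2),
                    n_timepoints = 2000, n_components = 3,
                    coupling_state1 = A, coupling_state2 = A, effect_size = 0)
  s <- simulate_subject(cfg, "control", seed = 11)
  x <- scale(s$tc, center = TRUE, scale = FALSE)
  # independent LS oracle: qr solve of lagged regression, no package code
  Z <- x[-nrow(x), ]; Y <- x[-1, ]
  B <- qr.solve(Z, Y)   # B[i, j]: effect of channel i on channel j
  expect_lt(abs(B[1, 2] - 0.5), 0.05)
  other <- matrix(TRUE, 3, 3); other[1, 2] <- FALSE
  expect_lt(max(abs(B[other])), 0.05)
})

test_that("cohort has the expected clinical table and group effects", {
  cfg <- sim_config()   # defaults: 36 patients + 40 controls
  expect_equal(sum(cfg$n_subjects_per_group), 76)
  co <- simulate_cohort(small_cfg(seed = 3))
  expect_equal(nrow(co$clinical), 8)
  expect_true(all(co$clinical$moca >= 0 & co$clinical$moca <= 30))
  expect_setequal(unique(co$clinical$group), c("patient", "control"))
  # patient state-1 coupling is the control coupling minus the planted effect
  eff <- co$truth$effect_edges
  A_pat <- co$truth$coupling$patient[[1]][[1]]
  A_ctl <- co$truth$coupling$control[[1]][[1]]
  expect_equal(A_pat[eff], A_ctl[eff] - co$config$effect_size)
  off_eff <- A_ctl; off_eff[eff] <- A_pat[eff]
  expect_equal(off_eff, A_pat)
})

test_that("higher patient stay probability raises true state-1 occupancy", {
  cfg <- sim_config(n_subjects_per_group = c(patient = 10, control = 10),
                    n_timepoints = 300, n_components = 4,
                    coupling_state1 = default_coupling(4, "weak"),
                    coupling_state2 = default_coupling(4, "strong"),
                    stay_probs = list(patient = c(0.95, 0.85),
                                      control = c(0.85, 0.85)),
                    effect_edges = cbind(2, 4))
  co <- simulate_cohort(cfg, seed = 21)
  groups <- vapply(co$subjects, `[[`, character(1), "group")
  occ <- co$truth$occupancy_state1
  expect_gt(mean(occ[groups == "patient"]), mean(occ[groups == "control"]))
})
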