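test_that("near-identity pulses keep the disease-free equilibrium constant", {
  sc <- scn_ext()
  tiny <- pulse_params(T = 1, theta1 = 1e-12, xi = 1e-12)
  traj <- simulate_pest(dfe_state(sc$rates), sc$rates, tiny, t_end = 5)
  dev <- max(abs(as.matrix(traj$data[, 2:7]) -
                   matrix(unclass(dfe_state(sc$rates)),
                          nrow(traj$data), 6, byrow = TRUE)))
  expect_lt(dev, 1e-8)
})

test_that("pulse bookkeeping: counts, left-continuity, jump consistency", {
  sc <- scn_ext()
  traj <- simulate_pest(sc$initial, sc$rates, sc$pulses, t_end = 7.5)
  expect_identical(length(traj$pulse_times), 7L)           # floor(7.5 / 1)
  expect_equal(traj$pulse_times, 1:7)

  # pulse at exactly t_end is included
  traj2 <- simulate_pest(sc$initial, sc$rates, sc$pulses, t_end = 7)
  expect_identical(length(traj2$pulse_times), 7L)

  # post-jump state is exactly the jump map of the pre-jump state
  for (k in seq_len(nrow(traj$pre_jump))) {
    pre <- validate_state(as.numeric(traj$pre_jump[k, -1]))
    expect_equal(as.numeric(traj$post_jump[k, -1]),
                 as.numeric(jump_map(pre, sc$pulses)), tolerance = 1e-15)
  }

  # value stored AT nT is the pre-jump value; both rows present
  at1 <- traj$data[traj$data$t == 1, ]
  expect_identical(at1$phase, c("pre_jump", "post_jump"))
  expect_equal(at1$S[2], (1 - sc$pulses$theta1) * at1$S[1], tolerance = 1e-15)
})

test_that("zero-infection subspace is invariant under both integrators", {
  sc <- scn_perm()
  init <- state_vec(2, 0, 0, 0, 5, 0)
  a <- simulate_pest(init, sc$rates, sc$pulses, t_end = 5)
  b <- simulate_rk4(init, sc$rates, sc$pulses, h = 0.01, t_end = 5)
  for (traj in list(a, b)) {
    expect_true(all(traj$data$E == 0 & traj$data$I == 0 &
                      traj$data$A == 0 & traj$data$M == 0))
  }
})

test_that("infection-free runs converge to the scalar pulsed orbit", {
  sc <- scn_ext()
  traj <- simulate_pest(state_vec(2, 0, 0, 0, 5, 0), sc$rates, sc$pulses,
                        t_end = 60)
  d <- traj$data[traj$data$t > 59 & traj$data$phase != "post_jump", ]
  ref <- s_star(d$t, sc$rates$Pi, sc$rates$mu, sc$pulses$theta1, sc$pulses$T)
  expect_lt(max(abs(d$S - ref)), 1e-6)
  # total population relaxes to Pi/mu
  expect_lt(abs(d$N[nrow(d)] - sc$rates$Pi / sc$rates$mu), 1e-6)
})

test_that("adaptive and fixed-step integrators agree at pulse instants", {
  for (sc in list(scn_ext(), scn_perm())) {
    a <- simulate_pest(sc$initial, sc$rates, sc$pulses, t_end = 5)
    b <- simulate_rk4(sc$initial, sc$rates, sc$pulses, h = sc$pulses$T / 2000,
                      t_end = 5, record_every = 2000L)
    expect_lt(pulse_state_deviation(a, b), 1e-6)
  }
})

test_that("fixed-step oracle validates its step size and shows fourth order", {
  sc <- scn_ext()
  expect_error(simulate_rk4(sc$initial, sc$rates, sc$pulses,
                            h = 0.3, t_end = 2), "divide")
  expect_error(simulate_rk4(sc$initial, sc$rates, sc$pulses,
                            h = 0.25, t_end = 2.1), "multiple")

  # infection-free susceptible flow has the exact solution forced_decay;
  # halving h must shrink the one-period error by about 2^4
  init <- state_vec(2, 0, 0, 0, 5, 0)
  err <- sapply(c(0.2, 0.1, 0.05), function(h) {
    tr <- simulate_rk4(init, sc$rates, sc$pulses, h = h, t_end = 1)
    abs(tr$pre_jump$S[1] - forced_decay(2, sc$rates$Pi, sc$rates$mu, 1))
  })
  expect_equal(err[1] / err[2], 16, tolerance = 0.2)
  expect_equal(err[2] / err[3], 16, tolerance = 0.2)
})

test_that("period summaries are degenerate on constant trajectories", {
  sc <- scn_ext()
  tiny <- pulse_params(T = 1, theta1 = 1e-12, xi = 1e-12)
  traj <- simulate_pest(dfe_state(sc$rates), sc$rates, tiny, t_end = 6)
  ps <- period_summaries(traj, n_last = 3)
  expect_equal(ps$min, ps$max, tolerance = 1e-9)
  expect_equal(ps$min, ps$mean, tolerance = 1e-9)
  expect_identical(nrow(ps), 18L)  # 3 periods x 6 compartments
  expect_error(period_summaries(traj, n_last = 10), "horizon")
})

test_that("trajectories started inside the invariant region stay inside", {
  set.seed(53)
  sc <- scn_ext()
  for (init in draw_initial_states(5, sc$rates)) {
    expect_true(in_omega(init, sc$rates))
    traj <- simulate_pest(init, sc$rates, sc$pulses, t_end = 10,
                          rtol = 1e-8, atol = 1e-10)
    ok <- apply(as.matrix(traj$data[, 2:7]), 1, function(row) {
      in_omega(validate_state(row), sc$rates, tol = 1e-6)
    })
    expect_true(all(ok))
    expect_true(all(as.matrix(traj$data[, 2:7]) >= 0))  # clipped at -1e-10
  }
})

test_that("susceptibles keep oscillating in the extinction regime", {
  sc <- scn_ext()
  traj <- simulate_pest(sc$initial, sc$rates, sc$pulses, t_end = 40)
  ps <- period_summaries(traj, n_last = 5)
  s_amp <- ps$max[ps$compartment == "S"] - ps$min[ps$compartment == "S"]
  expect_true(all(s_amp > 0.1))   # persistent pulse-driven amplitude
})

test_that("starting outside the region warns but integrates", {
  sc <- scn_ext()
  far <- state_vec(20, 1, 1, 1, 20, 5)  # violates every ceiling
  expect_warning(traj <- simulate_pest(far, sc$rates, sc$pulses, t_end = 3),
                 "invariant region")
  expect_s3_class(traj, "pest_trajectory")
})

test_that("trajectory CSV, tidy, glance and autoplot expose the same data", {
  sc <- scn_ext()
  traj <- simulate_pest(sc$initial, sc$rates, sc$pulses, t_end = 3)
  f <- tempfile(fileext = ".csv")
  write_trajectory_csv(traj, f)
  back <- utils::read.csv(f)
  expect_identical(names(back), c("t", "S", "E", "I", "A", "N", "M", "phase"))
  expect_identical(nrow(back), nrow(traj$data))

  long <- tidy(traj)
  expect_identical(nrow(long), 6L * nrow(traj$data))
  g <- glance(traj)
  expect_identical(g$n_pulses, 3L)
  expect_equal(g$t_end, 3)
  p <- ggplot2::autoplot(traj)
  expect_s3_class(p, "ggplot")
})
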