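test_that("the I-V law is a state-scaled hyperbolic sine", {
  p <- table_params()
  expect_identical(memristor_current(0, 0.3, p), 0)
  # conductance factor is exactly 1 at x = 1
  expect_equal(memristor_current(0.2, 1, p), p$a1 * sinh(p$b * 0.2))
  # and 1/r at x = 0: the x = 0 current is the x = 1 current divided by r
  expect_equal(memristor_current(0.2, 0, p),
               memristor_current(0.2, 1, p) / p$r)
  # sign of the current follows the sign of the voltage
  for (v in c(-1.7, -0.3, 0.4, 2)) {
    expect_identical(sign(memristor_current(v, 0.5, p)), sign(v))
  }
  expect_error(memristor_current(0.2, 1.2, p), "\\[0, 1\\]")
})

test_that("conductance ratio between the rails equals r exactly", {
  for (r in c(2, 9, 40)) {
    p <- table_params(r = r)
    expect_equal(read_conductance(1, p) / read_conductance(0, p), r)
  }
})

test_that("threshold motion has a dead zone and exponential tails", {
  p <- table_params()
  # strictly inside the dead zone, and at both closed endpoints
  expect_identical(threshold_motion(c(0.3, -0.3, 0, p$Vp, -p$Vn), p),
                   rep(0, 5))
  expect_equal(threshold_motion(1.5, p), p$Ap * (exp(1.5) - exp(p$Vp)))
  expect_equal(threshold_motion(1.5, p), 0.95 * (4.481689 - 1.648721),
               tolerance = 1e-6)
  expect_equal(threshold_motion(-1.5, p), -p$An * (exp(1.5) - exp(p$Vn)))
  # continuity: just above the threshold the motion is tiny
  expect_lt(threshold_motion(p$Vp + 1e-9, p), 1e-6)
})

test_that("window functions are continuous at their boundaries and vanish at the rails", {
  p <- table_params()
  expect_equal(window_fn(p$xp, "positive", p), 1)
  expect_equal(window_fn(p$xp - 1e-12, "positive", p), 1)
  expect_equal(window_fn(1, "positive", p), 0)
  expect_equal(window_fn(1 - p$xn, "negative", p), 1)
  expect_equal(window_fn(1 - p$xn + 1e-12, "negative", p), 1)
  expect_equal(window_fn(0, "negative", p), 0)
  xs <- seq(0, 1, by = 0.01)
  expect_true(all(window_fn(xs, "positive", p) >= 0))
  expect_true(all(window_fn(xs, "negative", p) >= 0))
  expect_error(window_fn(-0.1, "positive", p), "\\[0, 1\\]")
})

test_that("state stepping respects the dead zone and the rails", {
  p <- table_params()
  s <- memristor_state(x = 0.4)
  # sub-threshold voltage leaves the state exactly unchanged
  expect_identical(step_state(s, 0.3, 5, p)$x, 0.4)
  expect_identical(step_state(s, -0.45, 100, p)$x, 0.4)
  # supra-threshold positive voltage strictly increases x (eta = +1)
  expect_gt(step_state(s, 1.5, 1, p)$x, 0.4)
  expect_lt(step_state(s, -1.5, 1, p)$x, 0.4)
})

test_that("state is confined to [0, 1] under arbitrary voltage sequences", {
  p <- table_params()
  set.seed(7)
  for (rep in 1:5) {
    s <- memristor_state(x = runif(1))
    for (V in runif(40, -3, 3)) {
      s <- step_state(s, V, runif(1, 0.1, 8), p)
      expect_gte(s$x, 0)
      expect_lte(s$x, 1)
    }
  }
})

test_that("repeated supra-threshold stepping approaches the rail monotonically", {
  p <- table_params(x0 = 0.01)
  s <- memristor_state(p = p)
  xs <- numeric(200)
  for (i in 1:200) {
    s <- step_state(s, 1.5, 5, p)
    xs[i] <- s$x
  }
  expect_true(!is.unsorted(xs))
  expect_lte(max(xs), 1)
  expect_gt(xs[200], 0.5)
  # convergence: the same trajectory at half the Euler step differs by
  # less than 1e-3 in the final state
  s2 <- memristor_state(p = p)
  for (i in 1:200) s2 <- step_state(s2, 1.5, 5, p, dt_max = 0.025)
  expect_lt(abs(s2$x - s$x), 1e-3)
})

test_that("pulse trains give monotone LTP and LTD traces and a constant zero-amplitude trace", {
  p <- table_params()
  ltp <- run_pulse_train(memristor_state(p = p), pulse_train(), p)
  expect_identical(nrow(ltp), 100L)
  expect_true(!is.unsorted(ltp$conductance_S))
  expect_gt(dplyr::last(ltp$conductance_S), ltp$conductance_S[1])

  high <- attr(ltp, "final_state")
  ltd <- run_pulse_train(high, pulse_train(amplitude = -1.5), p)
  expect_true(!is.unsorted(rev(ltd$conductance_S)))

  # RESET drive convention: negative train expressed as driving the
  # bottom electrode
  ltd2 <- run_pulse_train(high, pulse_train(amplitude = 1.5,
                                            polarity_convention = "bottom-negative"), p)
  expect_identical(ltd$conductance_S, ltd2$conductance_S)

  flat <- run_pulse_train(memristor_state(x = 0.5), pulse_train(amplitude = 0), p)
  expect_identical(unique(flat$conductance_S), read_conductance(0.5, p))
})

test_that("noisy pulse trains are reproducible under a fixed seed", {
  p <- table_params()
  ns <- noise_spec(seed = 11)
  a <- run_pulse_train(memristor_state(p = p), pulse_train(), p, noise = ns)
  b <- run_pulse_train(memristor_state(p = p), pulse_train(), p, noise = ns)
  expect_identical(a$conductance_S, b$conductance_S)
  # and differ from the noise-free trace
  c0 <- run_pulse_train(memristor_state(p = p), pulse_train(), p)
  expect_false(identical(a$conductance_S, c0$conductance_S))
})

test_that("device sampling respects the stated noise bounds and seed", {
  p <- table_params()
  ns <- noise_spec(seed = 3)
  expect_identical(unclass(sample_device(p, noise_spec(0, 0, 0, 0, seed = 1))),
                   unclass(p))
  expect_identical(unclass(sample_device(p, ns)), unclass(sample_device(p, ns)))
  for (i in 1:50) {
    q <- sample_device(p, noise_spec(seed = i))
    expect_lte(abs(q$Ap - p$Ap) / p$Ap, 0.25)
    expect_lte(abs(q$An - p$An) / p$An, 0.20)
    expect_lte(abs(q$alpha_p - p$alpha_p) / p$alpha_p, 0.40)
    expect_lte(abs(q$alpha_n - p$alpha_n) / p$alpha_n, 0.10)
  }
})

test_that("the I-V sweep is a pinched hysteresis loop", {
  p <- table_params()
  sw <- iv_sweep(p, -2, 2, rate = 200)
  # pinched at the origin
  expect_equal(sw$current_A[sw$voltage_V == 0], rep(0, 2), tolerance = 1e-20)
  expect_true(all(sw$x >= 0 & sw$x <= 1))
  # hysteresis on the positive (SET) half: the state has grown by the
  # return pass, so the down-branch current dominates at equal voltage
  up <- sw[sw$branch == "up" & sw$voltage_V > 0.6, ]
  down <- sw[sw$branch == "down" & sw$voltage_V > 0.6, ]
  shared <- intersect(round(up$voltage_V, 6), round(down$voltage_V, 6))
  iu <- up$current_A[match(shared, round(up$voltage_V, 6))]
  id <- down$current_A[match(shared, round(down$voltage_V, 6))]
  expect_true(all(id >= iu))
  expect_gt(max(id - iu), 0)

  # a sweep confined to the dead zone does not move the state
  sw0 <- iv_sweep(table_params(x0 = 0.37), -0.4, 0.4, rate = 100)
  expect_identical(unique(sw0$x), 0.37)
  expect_error(iv_sweep(p, 2, -2), "v_min")
})
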