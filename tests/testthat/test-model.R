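test_that("ramp rectifies and rejects non-finite input", {
  expect_identical(ramp(-3), 0)
  expect_identical(ramp(0), 0)
  expect_identical(ramp(5), 5)
  expect_equal(ramp(c(-1, 2, -0.5)), c(0, 2, 0))
  expect_error(ramp(NaN), "finite")
  expect_error(ramp(Inf), "finite")
})

test_that("regulatory activation evaluation is saturating and monotone", {
  expect_identical(g_eval(0, 200, 100), 0)
  expect_equal(g_eval(100, 200, 100), 100)  # Amax/2 at Tconv = K
  expect_lt(g_eval(1e9, 200, 100), 200)     # bounded by Amax
  expect_equal(g_eval(1e9, 200, 100), 200, tolerance = 1e-6)
  tc <- seq(0, 500, by = 10)
  expect_true(all(diff(g_eval(tc, 200, 100)) > 0))
  expect_error(g_eval(-1, 200, 100), "non-negative")
})

test_that("dose-response curves match their closed forms", {
  expect_identical(predict(dose_response("linear"), 37.5), 37.5)
  # Hill half-maximum at a = Kd is algebraically forced: Q/2
  expect_equal(predict(dose_response("hill", Q = 10, Kd = 30, h = 4), 30), 5)
  expect_equal(predict(dose_response("sigmoidal"), 30), 5)
  expect_identical(predict(dose_response("step_like"), 0), 0)
  # hand-evaluated Hill value
  expect_equal(predict(dose_response("sigmoidal"), 60),
               10 * 60^4 / (30^4 + 60^4))
  a <- seq(0, 100, by = 0.5)
  for (k in c("linear", "sigmoidal", "step_like")) {
    q <- predict(dose_response(k), a)
    expect_true(all(q >= 0))
    expect_true(all(diff(q) >= 0))
  }
  expect_error(predict(dose_response("linear"), -1), "non-negative")
  expect_error(dose_response("hill", Q = 10), "requires")
  expect_error(dose_response("sigmoidal", Q = 3), "preset")
})

test_that("prediction errors are one-sided and match direct substitution", {
  expect_identical(prediction_error_conv(100, 100, ec = 0.1, mc = 1), 0)
  expect_identical(prediction_error_conv(0, 57, ec = 0.1, mc = 1), 0)
  expect_equal(prediction_error_conv(200, 50, ec = 0.1, mc = 1), 15)

  p <- immune_params(Amax = 10, K = 30, mr = 1, er = 0.5)
  expect_identical(prediction_error_reg(5, 0, 3, p), 0)      # g(0) = 0
  expect_identical(prediction_error_reg(10, 1e6, 0, p), 0)   # a >= Amax
  expect_equal(prediction_error_reg(2, 30, 1, p), 0.5 * (5 - 2 - 1))
})

test_that("the right-hand side matches hand-computed derivatives", {
  p <- default_p
  q <- lin_q
  prot <- protocol_constant(150, 100)

  # all-zero state under zero antigen: every term vanishes
  d0 <- immune_rhs(1, rep(0, 5), p, protocol_zero(10), q, q)
  expect_identical(d0[[1]], rep(0, 5))

  # all-zero state under antigen: only naive differentiation survives
  d1 <- immune_rhs(1, rep(0, 5), p, prot, q, q)
  expect_equal(d1[[1]], c(p$kc * p$Tnaive * 150, p$kr * p$Tnaive * 150, 0, 0, 0))

  # full generic state, derivative recomputed term by term in the test
  st <- c(40, 15, 3, 0.5, 20)
  a <- 150
  d <- immune_rhs(5, st, p, prot, q, q)
  Ec <- p$ec * max(a - p$mc * st[1], 0)
  Er <- p$er * max(p$Amax * st[1] / (st[1] + p$K) - a - p$mr * st[2], 0)
  expect_equal(d[[1]][1],
               -p$dc * st[1] + p$Dc * st[1] / (1 + p$sr * st[2]) +
                 p$kc * p$Tnaive * a + p$wc * st[3] * a - Ec * st[1])
  expect_equal(d[[1]][2],
               -p$dr * st[2] + p$Dr * st[2] / (1 + p$sc * st[1]) +
                 p$kr * p$Tnaive * a + p$wr * st[4] * a - Er * st[2])
  expect_equal(d[[1]][3], Ec * st[1])
  expect_equal(d[[1]][4], Er * st[2])
  expect_equal(d[[1]][5], -(p$r0 + p$rs * st[2]) * st[5] + p$ra * st[1])
  expect_equal(d$Ec, Ec)
  expect_equal(d$Er, Er)

  # response fixed point with Treg = 0: dR = 0 at R = ra Tconv / r0
  st2 <- c(10, 0, 0, 0, p$ra * 10 / p$r0)
  d2 <- immune_rhs(5, st2, p, prot, q, q)
  expect_equal(d2[[1]][5], 0)

  # states below -neg_tol abort
  expect_error(immune_rhs(1, c(-1, 0, 0, 0, 0), p, prot, q, q), "negative")
})

test_that("delayed errors use the lagged populations and antigen", {
  p <- immune_params(tau_delay = 10)
  q <- lin_q
  prot <- protocol_constant(100, 50)
  lag <- list(a = 80, Tconv = 30, Treg = 2)
  st <- c(90, 10, 1, 0, 5)
  d <- immune_rhs(20, st, p, prot, q, q, lagged = lag)
  Ec_l <- p$ec * max(80 - p$mc * 30, 0)
  Er_l <- p$er * max(p$Amax * 30 / (30 + p$K) - 80 - p$mr * 2, 0)
  # memory formation from the lagged source populations
  expect_equal(d[[1]][3], Ec_l * 30)
  expect_equal(d[[1]][4], Er_l * 2)
  # removal acts on the current populations with the lagged error
  expect_equal(d[[1]][1],
               -p$dc * 90 + p$Dc * 90 / (1 + p$sr * 10) +
                 p$kc * p$Tnaive * 100 + p$wc * 1 * 100 - Ec_l * 90)
})
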