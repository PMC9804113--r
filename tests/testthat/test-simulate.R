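test_that("the naive system without antigen stays at the zero equilibrium", {
  sim <- simulate_immune(default_p, protocol_zero(1000), n_out = 50)
  expect_true(all(unlist(sim$trajectory[-1]) == 0))
  ss <- detect_steady_state(sim)
  expect_true(ss$converged)
  expect_equal(unname(ss$state[1:5]), rep(0, 5))
})

test_that("steady high exposure drives the conventional error to zero and
           accumulates only conventional memory", {
  run <- quick_steady(200)
  expect_true(run$converged)
  st <- run$state
  tr <- run$sim$trajectory
  expect_lt(st[["Ec"]], 1e-8)
  expect_equal(st[["Er"]], 0)
  expect_equal(st[["Mreg"]], 0, tolerance = 1e-10)
  expect_gt(st[["Mconv"]], 1)
  expect_true(all(diff(tr$Mconv) >= -1e-8))
  # response fixed point: R* = ra Tconv* / (r0 + rs Treg*), exactly
  expect_equal(st[["R"]],
               default_p$ra * st[["Tconv"]] /
                 (default_p$r0 + default_p$rs * st[["Treg"]]),
               tolerance = 1e-6)
})

test_that("fixed points approached from below converge to Tconv* = a/mc", {
  # brute-force long-horizon oracle against the closed-form intersection
  for (a in c(30, 80)) {
    run <- quick_steady(a, max_horizon = 1.3e5)
    expect_true(run$converged)
    tr <- run$sim$trajectory
    expect_true(all(tr$Tconv <= a / default_p$mc * (1 + 1e-3)))  # from below
    expect_equal(run$state[["Tconv"]], a / default_p$mc, tolerance = 1e-4)
    expect_lt(run$state[["Ec"]], 1e-8)
    expect_lt(run$state[["Er"]], 1e-8)
  }
})

test_that("steady-state detection separates plateaus from drifting memory", {
  # constant trajectory: converged, summary equals the constant
  sim <- simulate_immune(default_p, protocol_zero(1000),
                         init = c(0, 0, 3, 1, 0), n_out = 100)
  # memory is neutrally stable: with no antigen it just persists
  ss <- detect_steady_state(sim)
  expect_true(ss$converged)
  expect_equal(ss$state[["Mconv"]], 3, tolerance = 1e-6)

  # linearly growing memory: not converged even though (Tconv, Treg, R)
  # plateau; fabricate the drift directly
  fake <- sim
  fake$trajectory$Mconv <- seq(0, 10, length.out = nrow(sim$trajectory))
  expect_false(detect_steady_state(fake)$converged)

  expect_error(detect_steady_state(sim, window = 1e4), "half the simulated")
})

test_that("plateau summaries are stable under solver tolerance refinement", {
  s1 <- simulate_to_steady(default_p, protocol_constant(150, 4000),
                           atol = 1e-8, rtol = 1e-8)
  s2 <- simulate_to_steady(default_p, protocol_constant(150, 4000),
                           atol = 5e-9, rtol = 5e-9)
  expect_true(s1$converged && s2$converged)
  expect_equal(s1$state[1:5], s2$state[1:5], tolerance = 1e-6)
})

test_that("the delay branch reduces to the plain ODE as the delay vanishes", {
  prot <- protocol_constant(100, 300)
  base <- simulate_immune(default_p, prot, n_out = 150)
  f_base <- unlist(base$trajectory[nrow(base$trajectory), 2:6])
  err <- vapply(c(1, 0.25), function(tau) {
    pd <- immune_params(tau_delay = tau)
    simd <- simulate_immune(pd, prot, n_out = 150)
    f <- unlist(simd$trajectory[nrow(simd$trajectory), 2:6])
    max(abs(f - f_base) / pmax(abs(f_base), 1))
  }, numeric(1))
  expect_lt(err[2], err[1])          # refinement towards the ODE solution
  expect_lt(err[2], 5e-3)
  # tau_delay = 0 dispatches to the plain path bit-for-bit
  p0 <- immune_params(tau_delay = 0)
  sim0 <- simulate_immune(p0, prot, n_out = 150)
  expect_identical(sim0$trajectory, base$trajectory)
})

test_that("explicit linear activation reproduces the baseline equations
           bit-for-bit", {
  prot <- protocol_saturating(150, 50, 400)
  s1 <- simulate_immune(default_p, prot, n_out = 100)
  s2 <- simulate_immune(default_p, prot, qc = dose_response("linear"),
                        qr = dose_response("linear"), n_out = 100)
  expect_identical(s1$trajectory, s2$trajectory)
})

test_that("simulation inputs are validated", {
  expect_error(simulate_immune(default_p, protocol_zero(10), t_end = 20),
               "protocol span")
  expect_error(simulate_immune(default_p, protocol_zero(10),
                               init = c(-1, 0, 0, 0, 0)))
  expect_error(simulate_immune(unclass(default_p), protocol_zero(10)))
})

test_that("trajectories export as tidy CSV with a JSON manifest", {
  sim <- simulate_immune(default_p, protocol_constant(50, 200), n_out = 40)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_sim(sim, csv = csv, json = js)
  back <- utils::read.csv(csv)
  expect_identical(names(back),
                   c("t", "Tconv", "Treg", "Mconv", "Mreg", "R", "Ec", "Er", "a"))
  expect_equal(nrow(back), nrow(sim$trajectory))
  meta <- jsonlite::read_json(js)
  expect_equal(meta$params$K, default_p$K)
  expect_equal(meta$solver$atol, 1e-8)
})
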