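test_that("concentration sweeps separate suppressed and strong regimes", {
  sw <- run_concentration_sweep(default_p, a_grid = c(0, 40, 80, 150, 300))
  expect_s3_class(sw, "immune_sweep")
  expect_equal(nrow(sw), 5)
  expect_true(all(sw$converged))
  expect_true(all(sw$R >= 0))
  # no antigen: all-zero steady state
  expect_equal(unlist(sw[1, 2:8]), c(Tconv = 0, Treg = 0, Mconv = 0,
                                     Mreg = 0, R = 0, Ec = 0, Er = 0))
  # below threshold: regulatory memory and suppressed response
  expect_true(all(sw$Mreg[2:3] > 1))
  expect_true(all(sw$R[2:3] < 1))
  # above threshold: no regulatory memory, strong response
  expect_true(all(sw$Mreg[4:5] < 1e-8))
  expect_true(all(sw$R[4:5] > 50))
})

test_that("find_threshold localises midpoint crossings and rejects flat data", {
  tab <- data.frame(x = seq(1, 20), y = as.numeric(seq(1, 20) >= 10))
  attr(tab, "evaluator") <- function(x) c(y = as.numeric(x >= 10))
  thr <- find_threshold(tab, response = "y", factor = 2)
  expect_equal(thr$threshold, 10, tolerance = 1e-2)

  flat <- data.frame(x = 1:10, y = rep(3, 10))
  expect_error(find_threshold(flat, response = "y"), "no threshold")

  # decreasing transitions are localised too
  tabd <- data.frame(x = 1:20, y = 100 * as.numeric(1:20 < 7) + 1)
  attr(tabd, "evaluator") <- function(x) c(y = 100 * as.numeric(x < 7) + 1)
  expect_equal(find_threshold(tabd, response = "y")$threshold, 7,
               tolerance = 1e-2)
})

test_that("sweep thresholds lie between the bracketing grid points", {
  grid <- c(20, 60, 90, 110, 200, 400)
  sw <- run_concentration_sweep(default_p, a_grid = grid)
  thr <- find_threshold(sw)
  i <- findInterval(thr$threshold, grid)
  expect_true(i >= 1 && i < length(grid))
  expect_gt(sw$R[i + 1], thr$midpoint)
  expect_lt(sw$R[i], thr$midpoint)
  expect_true(thr$bracket[1] <= thr$threshold && thr$threshold <= thr$bracket[2])
})

test_that("rapid saturating inputs reduce to the constant-input limit", {
  const <- quick_steady(200)
  rapid <- simulate_to_steady(default_p, protocol_saturating(200, 0.5, 4000))
  expect_equal(rapid$state[1:5], const$state[1:5], tolerance = 1e-2)
  # slow input at the same plateau concentration is suppressed
  slow <- simulate_to_steady(default_p, protocol_saturating(200, 2000, 40000),
                             horizon = 40000)
  expect_lt(slow$state[["R"]], 0.05 * const$state[["R"]])
  expect_gt(slow$state[["Mreg"]], 1)
})

test_that("a 1 x N phase diagram reduces to the matching 1-D sweep", {
  grid <- c(50, 150)
  pd <- run_phase_diagram(default_p, grid, default_p$K, axes = "a_K")
  sw <- run_concentration_sweep(default_p, a_grid = grid)
  expect_equal(pd$R, sw$R, tolerance = 1e-9)
  expect_equal(pd$Mreg, sw$Mreg, tolerance = 1e-9)
  expect_identical(attr(pd, "axes"), "a_K")
})

test_that("discrimination exists only when regulatory overestimation holds", {
  # low K: Amax/K > mc, threshold present; high K: Amax/K < mc, absent
  grid <- c(20, 60, 90, 110, 200, 400)
  pd <- run_phase_diagram(default_p, grid, c(100, 300), axes = "a_K")
  low <- pd[pd$K == 100, ]
  high <- pd[pd$K == 300, ]
  expect_gt(max(low$R) / min(low$R), 100)      # suppressed vs strong plateaus
  expect_lt(max(high$R) / min(high$R), 20)     # no suppressed branch
  expect_true(all(high$Mreg < 1e-8))
})

test_that("therapy ratios reproduce the dose-effect shape", {
  th <- run_therapy_protocol(default_p)
  expect_lt(th$ratio, 0.05)
  expect_named(th$phase_max, c("induction", "therapy", "challenge"))

  # degenerate zero-length therapy phase: two identical contiguous
  # challenges, ratio exactly one
  sch0 <- therapy_schedule(durations = c(1500, 0, 1500))
  th0 <- run_therapy_protocol(default_p, sch0)
  expect_equal(th0$ratio, 1, tolerance = 1e-6)

  # no induction response: undefined ratio
  schz <- therapy_schedule(a_high = 0, a_therapy = 50)
  expect_error(run_therapy_protocol(default_p, schz), "undefined")

  # dose sweep: effective only at low dose, monotone up to the transition
  sw <- run_therapy_dose_sweep(default_p, dose_grid = c(20, 60, 100, 120))
  expect_true(all(diff(sw$ratio) > 0))
  expect_true(all(sw$ratio[1:2] < 0.1))
  expect_gt(sw$ratio[4], 0.9)

  # slow therapy ramps are effective even at a high therapy dose
  thr <- run_therapy_protocol(default_p,
                              therapy_schedule(a_therapy = 150,
                                               tau_therapy = 2000))
  expect_lt(thr$ratio, 0.5)
  th_fast <- run_therapy_protocol(default_p,
                                  therapy_schedule(a_therapy = 150))
  expect_gt(th_fast$ratio, thr$ratio)
})

test_that("activation curve variants keep therapy effective but reshape
           conventional memory accumulation", {
  grid <- c(20, 50, 120, 400)
  cmp <- run_dose_response_comparison(default_p, a_grid = grid)
  expect_named(cmp, c("linear", "sigmoidal", "step_like"))
  for (k in names(cmp)) expect_lt(cmp[[k]]$therapy_ratio, 1)
  # linear: converged conventional memory roughly flat in concentration
  mc_lin <- cmp$linear$sweep$Mconv
  expect_lt(max(mc_lin) / min(mc_lin), 2)
  # saturating curves: memory grows with concentration once activation is
  # saturated (reactivation no longer scales with the dose, so the memory
  # pool itself must), unlike the flat linear case
  for (k in c("sigmoidal", "step_like")) {
    mc <- cmp[[k]]$sweep$Mconv
    n <- length(mc)
    expect_gt(mc[n] / mc[n - 1], 2)
  }
  # the sigmoidal curve additionally peaks below its half-activation point
  # before the dip (the step-like analogue sits below the feasible
  # convergence range)
  mc_sig <- cmp$sigmoidal$sweep$Mconv
  expect_gt(mc_sig[1], min(mc_sig) * 1.5)
  # early-therapy response spike is a saturating-activation phenomenon
  expect_false(cmp$linear$early_spike)
  expect_true(cmp$step_like$early_spike)
})

test_that("the persistence experiment reduces to the therapy ratio when the
           boost is removed and the probe repeats the challenge", {
  sch <- persistence_schedule(durations = c(1500, 4000, 1500, 0, 1500),
                              a_probe = 200)
  res <- run_persistence_experiment(default_p, "linear", schedule = sch)
  expect_equal(res$persistence_ratio, res$therapy_ratio, tolerance = 0.1)
  expect_lt(res$therapy_ratio, 1)
})

test_that("sensitivity analysis keys discrimination to the K-mc relation", {
  res <- run_sensitivity_analysis(default_p,
                                  parameters = c("K", "mc", "ra"),
                                  factors = c(0.5, 2),
                                  a_grid = lseq(10, 400, 7))
  base <- res[res$parameter == "(baseline)", ]
  expect_true(base$discrimination)
  # violating the overestimation condition Amax/K > mc kills discrimination
  expect_false(res[res$parameter == "K" & res$multiplier == 2, "discrimination"])
  expect_false(res[res$parameter == "mc" & res$multiplier == 2, "discrimination"])
  # tightening it (or rescaling the response readout) does not
  expect_true(res[res$parameter == "K" & res$multiplier == 0.5, "discrimination"])
  expect_true(all(res[res$parameter == "ra", "discrimination"]))
})
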