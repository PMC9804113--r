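#' Log-spaced grid helper
#'
#' @param from,to Positive range limits.
#' @param length.out Number of points.
#' @return Logarithmically spaced grid.
#' @export
lseq <- function(from, to, length.out = 25) {
  stopifnot(from > 0, to > from)
  exp(seq(log(from), log(to), length.out = length.out))
}

as_dose_response <- function(x) {
  if (is_dose_response(x)) x else dose_response(x)
}

sweep_row <- function(input, run) {
  st <- run$state
  data.frame(input, Tconv = st[["Tconv"]], Treg = st[["Treg"]],
             Mconv = st[["Mconv"]], Mreg = st[["Mreg"]], R = st[["R"]],
             Ec = st[["Ec"]], Er = st[["Er"]], converged = run$converged,
             horizon = run$horizon)
}

new_sweep <- function(rows, input_name, evaluator, type) {
  names(rows)[1] <- input_name
  structure(rows, class = c("immune_sweep", "data.frame"),
            evaluator = evaluator, type = type)
}

#' Steady-state sweep over constant antigen concentrations
#'
#' Simulates steady exposure to each antigen concentration in `a_grid` until
#' a steady state is detected (or `max_horizon` is exceeded, flagging the
#' row) and tabulates the converged state.  Low concentrations end
#' regulatory-memory dominated with a suppressed response intensity; high
#' concentrations end conventional-memory dominated with a strong response;
#' [find_threshold()] locates the transition.
#'
#' @param params An [immune_params()] object.
#' @param a_grid Sorted non-negative antigen concentrations.  The default is
#'   25 log-spaced points spanning one decade around the default parameters'
#'   analytic threshold.
#' @param qc,qr [dose_response()] curves (or kind names).
#' @param rel_tol,horizon,max_horizon Steady-state detection settings, see
#'   [simulate_to_steady()].
#' @param ... Passed to [simulate_to_steady()].
#' @return An `immune_sweep` data frame with one row per grid point and
#'   columns `a`, `Tconv`, `Treg`, `Mconv`, `Mreg`, `R`, `Ec`, `Er`,
#'   `converged`, `horizon`.  The sweep carries an evaluator so that
#'   [find_threshold()] can refine between grid points.
#' @examples
#' \donttest{
#' sw <- run_concentration_sweep(immune_params(), a_grid = c(20, 80, 150, 300))
#' sw$R
#' }
#' @export
run_concentration_sweep <- function(params, a_grid = lseq(10, 400, 25),
                                    qc = dose_response("linear"), qr = qc,
                                    rel_tol = 1e-6, horizon = 4000,
                                    max_horizon = 2.6e5, ...) {
  stopifnot(all(a_grid >= 0), !is.unsorted(a_grid))
  qc <- as_dose_response(qc); qr <- as_dose_response(qr)
  eval_one <- function(a) {
    prot <- if (a > 0) protocol_constant(a, horizon) else protocol_zero(horizon)
    simulate_to_steady(params, prot, qc, qr, rel_tol = rel_tol,
                       horizon = horizon, max_horizon = max_horizon, ...)
  }
  rows <- do.call(rbind, lapply(a_grid, function(a) sweep_row(a, eval_one(a))))
  new_sweep(rows, "a", function(x) eval_one(x)$state, "concentration")
}

#' Steady-state sweep over antigen input rapidness
#'
#' Administers the saturating-exponential input
#' `a(t) = a0 * (1 - exp(-t / tau))` for each time constant in `tau_grid`
#' and tabulates the converged state.  At high `a0`, slow inputs (large
#' `tau`) are classified harmless: the long transit through low
#' concentrations accumulates regulatory memory that suppresses the final
#' response even though the plateau concentration is the same.
#'
#' @inheritParams run_concentration_sweep
#' @param a0 Plateau concentration (the rapid-limit input).
#' @param tau_grid Sorted positive time constants.
#' @return An `immune_sweep` with first column `tau`.
#' @export
run_rapidness_sweep <- function(params, a0 = 200,
                                tau_grid = lseq(5, 5000, 25),
                                qc = dose_response("linear"), qr = qc,
                                rel_tol = 1e-6, horizon = 4000,
                                max_horizon = 5.2e5, ...) {
  stopifnot(a0 >= 0, all(tau_grid > 0), !is.unsorted(tau_grid))
  qc <- as_dose_response(qc); qr <- as_dose_response(qr)
  eval_one <- function(tau) {
    h <- max(horizon, 10 * tau)
    prot <- protocol_saturating(a0, tau, h)
    simulate_to_steady(params, prot, qc, qr, rel_tol = rel_tol, horizon = h,
                       max_horizon = max(max_horizon, 20 * tau), ...)
  }
  rows <- do.call(rbind, lapply(tau_grid, function(x) sweep_row(x, eval_one(x))))
  new_sweep(rows, "tau", function(x) eval_one(x)$state, "rapidness")
}

#' Locate the discrimination threshold in a sweep
#'
#' Takes a monotone-transition sweep (suppressed plateau on one side, strong
#' plateau on the other), computes the midpoint of the two plateau levels
#' (the response at the first and last grid point) and returns the swept
#' input at which the response crosses that midpoint.  When the sweep
#' carries an evaluator (all sweeps produced by this package do), the
#' crossing is refined by bisection between the bracketing grid points;
#' otherwise it is linearly interpolated.
#'
#' @param sweep An `immune_sweep` (or any data frame whose first column is
#'   the sorted swept input).
#' @param response Name of the response column (default `"R"`).
#' @param factor Required plateau separation: `max / min` of the two plateau
#'   levels must be at least this, else a "no threshold" error is raised.
#' @param xtol_rel Relative bracket width at which bisection stops.
#' @param refine Set to `FALSE` to skip bisection (grid interpolation only).
#' @return An object of class `immune_threshold`: a list with `threshold`,
#'   `midpoint`, `plateaus`, `bracket` and `response`.
#' @examples
#' tab <- data.frame(x = 1:20, y = as.numeric(1:20 >= 10))
#' attr(tab, "evaluator") <- function(x) c(y = as.numeric(x >= 10))
#' find_threshold(tab, response = "y")$threshold  # 10
#' @export
find_threshold <- function(sweep, response = "R", factor = 5,
                           xtol_rel = 1e-3, refine = TRUE) {
  x <- sweep[[1L]]
  y <- sweep[[response]]
  if (is.null(y)) stop("no column '", response, "' in sweep")
  stopifnot(length(x) >= 3, !is.unsorted(x))
  lo <- y[1L]; hi <- y[length(y)]
  lo_pl <- min(lo, hi); hi_pl <- max(lo, hi)
  if (hi_pl <= 0 || (lo_pl > 0 && hi_pl / lo_pl < factor))
    stop("no threshold: plateau separation ", signif(hi_pl / lo_pl, 3),
         " is below the required factor ", factor)
  mid <- (lo + hi) / 2
  increasing <- hi > lo
  above <- if (increasing) y > mid else y < mid
  i <- which(diff(above) != 0)
  if (length(i) == 0) stop("no threshold: response never crosses the midpoint")
  i <- i[1L]
  x1 <- x[i]; x2 <- x[i + 1L]
  evaluator <- attr(sweep, "evaluator")
  if (refine && !is.null(evaluator)) {
    while ((x2 - x1) > xtol_rel * max(abs(x1), abs(x2))) {
      xm <- (x1 + x2) / 2
      ym <- evaluator(xm)[[response]]
      crossed <- if (increasing) ym > mid else ym < mid
      if (crossed) x2 <- xm else x1 <- xm
    }
    thr <- (x1 + x2) / 2
  } else {
    thr <- stats::approx(y[c(i, i + 1L)], x[c(i, i + 1L)], xout = mid)$y
  }
  structure(list(threshold = thr, midpoint = mid,
                 plateaus = c(low_input = lo, high_input = hi),
                 bracket = c(x1, x2), response = response),
            class = "immune_threshold")
}

#' @export
print.immune_threshold <- function(x, ...) {
  cat(sprintf("Discrimination threshold in '%s': %.6g\n", x$response,
              x$threshold))
  cat(sprintf("  plateau levels %.4g / %.4g, midpoint %.4g, bracket [%.5g, %.5g]\n",
              x$plateaus[1], x$plateaus[2], x$midpoint,
              x$bracket[1], x$bracket[2]))
  invisible(x)
}

#' Two-parameter phase diagrams of the steady-state response
#'
#' Full-factorial steady-state maps over one of three axis pairs:
#' * `"a0_tau"` — plateau concentration x input time constant
#'   (saturating-exponential inputs);
#' * `"a_K"` — constant antigen concentration x regulatory evaluation
#'   half-saturation `K` (discrimination exists only while `Amax/K > mc`);
#' * `"therapy"` — therapy dose x therapy ramp time constant, reporting the
#'   therapy-effect ratio of [run_therapy_protocol()] instead of a steady
#'   state.
#'
#' Rows are emitted in deterministic order (`grid_x` varying fastest);
#' non-convergent cells are flagged, never fatal.
#'
#' @inheritParams run_concentration_sweep
#' @param grid_x,grid_y Axis grids (see `axes` for their meaning).
#' @param axes Which experiment the axes parameterise.
#' @return A data frame with the two grid columns followed by the per-cell
#'   outputs, of class `immune_phase_diagram`.
#' @export
run_phase_diagram <- function(params, grid_x, grid_y,
                              axes = c("a0_tau", "a_K", "therapy"),
                              qc = dose_response("linear"), qr = qc,
                              rel_tol = 1e-6, horizon = 4000,
                              max_horizon = 2.6e5, ...) {
  axes <- match.arg(axes)
  qc <- as_dose_response(qc); qr <- as_dose_response(qr)
  grid <- expand.grid(x = grid_x, y = grid_y, KEEP.OUT.ATTRS = FALSE)
  cell <- switch(axes,
    a0_tau = function(a0, tau) {
      h <- max(horizon, 10 * tau)
      run <- simulate_to_steady(params, protocol_saturating(a0, tau, h), qc, qr,
                                rel_tol = rel_tol, horizon = h,
                                max_horizon = max(max_horizon, 20 * tau), ...)
      sweep_row(a0, run)
    },
    a_K = function(a, K) {
      p2 <- params; p2$K <- K
      prot <- if (a > 0) protocol_constant(a, horizon) else protocol_zero(horizon)
      run <- simulate_to_steady(p2, prot, qc, qr, rel_tol = rel_tol,
                                horizon = horizon, max_horizon = max_horizon, ...)
      sweep_row(a, run)
    },
    therapy = function(dose, tau_ther) {
      th <- run_therapy_protocol(params,
                                 therapy_schedule(a_therapy = dose,
                                                  tau_therapy = tau_ther),
                                 qc, qr, ...)
      data.frame(input = dose, ratio = th$ratio,
                 max_R_induction = th$phase_max[1],
                 max_R_challenge = th$phase_max[3])
    })
  rows <- do.call(rbind, Map(cell, grid$x, grid$y))
  names(rows)[1] <- switch(axes, a0_tau = "a0", a_K = "a", therapy = "a_therapy")
  rows <- cbind(rows[1], switch(axes, a0_tau = data.frame(tau = grid$y),
                                a_K = data.frame(K = grid$y),
                                therapy = data.frame(tau_therapy = grid$y)),
                rows[-1])
  structure(rows, class = c("immune_phase_diagram", "data.frame"), axes = axes)
}

#' Simulate an allergen immunotherapy protocol
#'
#' Runs a multi-phase schedule (see [therapy_schedule()]) and evaluates the
#' therapeutic effect as the ratio of the maximum response intensity during
#' the post-therapy challenge to that during the initial induction:
#' a ratio below one means the therapy suppressed the response to the very
#' input that previously caused it.  Per-phase maxima are taken over the
#' phase window including its washout tail (up to the next phase start).
#'
#' @inheritParams run_concentration_sweep
#' @param schedule An [antigen_protocol()] carrying a `phases` attribute with
#'   at least three phases (as produced by [therapy_schedule()] or
#'   [persistence_schedule()]).
#' @param n_out Output grid resolution for the underlying simulation.
#' @return An object of class `immune_therapy`: list with `sim`, `ratio`
#'   (challenge / induction), `phase_max` (named per-phase maxima of `R`) and
#'   `onset_ratio` (max `R` over the window 5-15% into the therapy phase --
#'   i.e. after the fast phase-transition transient has relaxed -- relative
#'   to the induction maximum; a large value flags an early-therapy response
#'   spike, the regime where memory reactivation cannot distinguish the
#'   therapy dose from the allergen dose).
#' @export
run_therapy_protocol <- function(params, schedule = therapy_schedule(),
                                 qc = dose_response("linear"), qr = qc,
                                 n_out = 2000, ...) {
  phases <- attr(schedule, "phases")
  if (is.null(phases) || nrow(phases) < 3)
    stop("schedule must carry a 'phases' attribute with at least 3 phases; ",
         "build it with therapy_schedule() or persistence_schedule()")
  qc <- as_dose_response(qc); qr <- as_dose_response(qr)
  sim <- simulate_immune(params, schedule, qc, qr, n_out = n_out, ...)
  tr <- sim$trajectory
  phase_max <- vapply(seq_len(nrow(phases)), function(i) {
    w <- tr$t >= phases$start[i] & tr$t <= phases$window_end[i]
    if (!any(w)) return(NA_real_)
    max(tr$R[w])
  }, numeric(1))
  names(phase_max) <- phases$label
  if (!is.finite(phase_max[1]) || phase_max[1] <= 0)
    stop("undefined therapy ratio: no response during the induction phase")
  L2 <- phases$window_end[2] - phases$start[2]
  onset <- tr$t >= phases$start[2] + 0.05 * L2 &
    tr$t <= phases$start[2] + 0.15 * L2
  onset_ratio <- if (any(onset)) max(tr$R[onset]) / phase_max[1] else NA_real_
  structure(list(sim = sim, ratio = unname(phase_max[3] / phase_max[1]),
                 phase_max = phase_max, onset_ratio = onset_ratio,
                 phases = phases),
            class = "immune_therapy")
}

#' @export
print.immune_therapy <- function(x, ...) {
  cat(sprintf("Immunotherapy ratio (challenge/induction max R): %.4g  [%s]\n",
              x$ratio, if (x$ratio < 1) "therapy effective" else "no effect"))
  cat("  per-phase max R:\n")
  print(round(x$phase_max, 5))
  invisible(x)
}

#' Therapy effect as a function of therapy dose
#'
#' Convenience 1-D scan of [run_therapy_protocol()] over the dose
#' administered in the therapy phase (the dose-effect curve of allergen
#' immunotherapy: effective, ratio << 1, only below the discrimination
#' threshold).
#'
#' @inheritParams run_therapy_protocol
#' @param dose_grid Sorted therapy doses.
#' @param a_high,tau_therapy,durations,gaps Passed to [therapy_schedule()].
#' @return An `immune_sweep` with columns `a_therapy`, `ratio`, `onset_ratio`.
#' @export
run_therapy_dose_sweep <- function(params, dose_grid = lseq(10, 200, 25),
                                   qc = dose_response("linear"), qr = qc,
                                   a_high = 200, tau_therapy = 0,
                                   durations = c(1500, 4000, 1500),
                                   gaps = c(0, 0), ...) {
  stopifnot(!is.unsorted(dose_grid))
  eval_one <- function(dose) {
    th <- run_therapy_protocol(params,
                               therapy_schedule(a_high, dose, tau_therapy,
                                                durations, gaps),
                               qc, qr, ...)
    c(ratio = th$ratio, onset_ratio = th$onset_ratio)
  }
  rows <- do.call(rbind, lapply(dose_grid, eval_one))
  out <- data.frame(a_therapy = dose_grid, rows)
  structure(out, class = c("immune_sweep", "data.frame"),
            evaluator = eval_one, type = "therapy_dose")
}

#' Compare the three dose-response variants of T cell activation
#'
#' Runs, for each activation curve kind, a steady-state concentration sweep
#' and a default immunotherapy protocol.  With saturating (Hill) activation
#' the converged conventional memory is no longer flat in antigen
#' concentration (it peaks at low concentration and then grows), and the
#' step-like curve produces a response spike at the start of therapy because
#' memory reactivation no longer distinguishes concentrations above its
#' threshold; therapy nevertheless succeeds for all kinds.
#'
#' With either saturating curve, memory reactivation at the (low) therapy
#' dose is nearly as strong as at the allergen dose, so the conventional
#' population -- and with it the response -- stays elevated at therapy
#' initiation until regulatory memory builds up; with linear activation the
#' reactivation drive drops proportionally to the dose and the response
#' falls immediately.  The onset flag separates these regimes.
#'
#' @inheritParams run_concentration_sweep
#' @param kinds Activation curve kinds to compare (both lineages use the
#'   same curve).
#' @param schedule Therapy schedule used for the per-kind immunotherapy run.
#' @param spike_factor Onset ratio above which the early-therapy response
#'   spike flag is raised.
#' @return A named list (one element per kind) of lists with `sweep`,
#'   `therapy_ratio`, `onset_ratio` and `early_spike`.
#' @export
run_dose_response_comparison <- function(params,
                                         kinds = c("linear", "sigmoidal",
                                                   "step_like"),
                                         a_grid = lseq(20, 400, 15),
                                         schedule = therapy_schedule(),
                                         spike_factor = 0.05, ...) {
  out <- lapply(kinds, function(k) {
    q <- dose_response(k)
    sweep <- run_concentration_sweep(params, a_grid, qc = q, qr = q, ...)
    th <- run_therapy_protocol(params, schedule, qc = q, qr = q)
    list(kind = k, sweep = sweep, therapy_ratio = th$ratio,
         onset_ratio = th$onset_ratio,
         early_spike = is.finite(th$onset_ratio) &&
           th$onset_ratio > spike_factor)
  })
  names(out) <- kinds
  out
}

#' Persistence of the immunotherapy effect under re-exposure
#'
#' Runs the five-phase schedule of [persistence_schedule()] (induction,
#' therapy, challenge, higher-concentration boost, final probe) and returns
#' the probe-phase maximum response normalised by the pre-therapy induction
#' maximum.  A ratio below one means the therapeutic suppression persisted
#' through the additional higher exposure.
#'
#' @inheritParams run_therapy_protocol
#' @param qc_kind,qr_kind Activation curve kinds (or [dose_response()]
#'   objects) for the two lineages; `qr_kind` defaults to `qc_kind`.
#' @param schedule A five-phase schedule from [persistence_schedule()].
#' @return A list with `persistence_ratio` (probe / induction),
#'   `therapy_ratio` (challenge / induction), `phase_max` and `sim`.
#' @export
run_persistence_experiment <- function(params, qc_kind = "linear",
                                       qr_kind = qc_kind,
                                       schedule = persistence_schedule(),
                                       ...) {
  qc <- as_dose_response(qc_kind); qr <- as_dose_response(qr_kind)
  phases <- attr(schedule, "phases")
  if (is.null(phases) || nrow(phases) < 5)
    stop("schedule must have 5 phases; build it with persistence_schedule()")
  th <- run_therapy_protocol(params, schedule, qc, qr, ...)
  list(persistence_ratio = unname(th$phase_max["probe"] / th$phase_max[1]),
       therapy_ratio = th$ratio, phase_max = th$phase_max, sim = th$sim)
}

#' One-at-a-time parameter sensitivity of antigen discrimination
#'
#' Rescales each selected model parameter by each multiplier in turn and
#' tests whether concentration-dependent discrimination survives, i.e.
#' whether [find_threshold()] still finds a suppressed-to-strong transition
#' in a coarse steady-state concentration sweep.  The criterion is threshold
#' *existence* (a repository convention).  The defining condition is the
#' relative overestimation `Amax / K > mc`; rescalings that break it (e.g.
#' increasing `K` or `mc` past `Amax/K = mc`) lose discrimination, while the
#' remaining rates move the threshold without destroying it.
#'
#' @inheritParams run_concentration_sweep
#' @param parameters Character vector of parameter names to perturb
#'   (default: every rate and gain except the memory death rates and delay).
#' @param factors Positive multipliers (a baseline row with multiplier 1 is
#'   always included).
#' @param factor Plateau-separation factor passed to [find_threshold()].
#' @return A data frame with columns `parameter`, `multiplier`, `threshold`
#'   (`NA` when discrimination is lost), `discrimination` (flag) and
#'   `n_converged`.
#' @export
run_sensitivity_analysis <- function(params, parameters = NULL,
                                     factors = c(0.5, 2),
                                     a_grid = lseq(10, 400, 9),
                                     factor = 5, ...) {
  stopifnot(all(factors > 0))
  if (is.null(parameters))
    parameters <- setdiff(immune_param_names(), c("dmc", "dmr", "tau_delay"))
  stopifnot(all(parameters %in% immune_param_names()))
  one <- function(name, mult) {
    p2 <- unclass(params)
    if (!is.null(name)) p2[[name]] <- p2[[name]] * mult
    p2 <- tryCatch(validate_immune_params(p2), error = function(e) NULL)
    if (is.null(p2))  # perturbation left the admissible parameter region
      return(data.frame(parameter = if (is.null(name)) "(baseline)" else name,
                        multiplier = mult, threshold = NA_real_,
                        discrimination = FALSE, n_converged = 0L))
    sweep <- run_concentration_sweep(p2, a_grid, ...)
    thr <- tryCatch(find_threshold(sweep, factor = factor, refine = FALSE),
                    error = function(e) NULL)
    data.frame(parameter = if (is.null(name)) "(baseline)" else name,
               multiplier = mult,
               threshold = if (is.null(thr)) NA_real_ else thr$threshold,
               discrimination = !is.null(thr),
               n_converged = sum(sweep$converged))
  }
  rows <- list(one(NULL, 1))
  for (nm in parameters)
    for (f in factors)
      rows <- c(rows, list(one(nm, f)))
  do.call(rbind, rows)
}

#' Plot a one-dimensional sweep
#'
#' @param x An `immune_sweep`.
#' @param response Column to draw.
#' @param log Axis log specification (default log-log where possible).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.immune_sweep <- function(x, response = "R", log = "xy", ...) {
  graphics::plot(x[[1L]], x[[response]], type = "b", pch = 16,
                 xlab = names(x)[1L], ylab = response, log = log, ...)
  invisible(x)
}

#' Plot a phase diagram as a heat map
#'
#' @param x An `immune_phase_diagram`.
#' @param response Column to map (defaults to `R` or `ratio`).
#' @param log_response Colour by `log10` of the response.
#' @param ... Passed to [graphics::image()].
#' @export
plot.immune_phase_diagram <- function(x, response = NULL,
                                      log_response = TRUE, ...) {
  if (is.null(response))
    response <- if ("R" %in% names(x)) "R" else "ratio"
  xs <- sort(unique(x[[1L]])); ys <- sort(unique(x[[2L]]))
  z <- matrix(NA_real_, length(xs), length(ys))
  z[cbind(match(x[[1L]], xs), match(x[[2L]], ys))] <- x[[response]]
  if (log_response) z <- log10(pmax(z, 1e-12))
  graphics::image(xs, ys, z, xlab = names(x)[1L], ylab = names(x)[2L],
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}
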