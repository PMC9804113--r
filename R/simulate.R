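#' Simulate the predictive immune memory model
#'
#' Integrates the five-dimensional T cell population model under a piecewise
#' antigen input.  Without a memory-formation delay (`params$tau_delay == 0`)
#' the system is an ODE, integrated segment-by-segment with `deSolve`'s
#' `lsoda` so that the (continuous but non-smooth) protocol kinks coincide
#' with integrator restarts.  With `tau_delay > 0` the system is a
#' constant-delay DDE, integrated with [deSolve::dede()] over the whole span;
#' the pre-exposure history is the initial state with zero antigen.
#'
#' @param params An [immune_params()] object.
#' @param protocol An [antigen_protocol()].
#' @param qc,qr [dose_response()] curves for the conventional and regulatory
#'   lineages; `qr` defaults to `qc`.
#' @param t_end End of the simulated window (defaults to the protocol end);
#'   must lie within the protocol span.
#' @param init Initial state, a numeric vector
#'   `c(Tconv, Treg, Mconv, Mreg, R)`.  The default is the all-zero,
#'   antigen-inexperienced state (the naive T cell pool is a parameter, not
#'   a state variable).
#' @param n_out Approximate number of output grid points (protocol segment
#'   boundaries are always included).
#' @param atol,rtol Absolute/relative integration tolerances.
#' @param neg_tol States below `-neg_tol` abort the run; values in
#'   `(-neg_tol, 0)` are rounded up to zero.
#' @return An object of class `immune_sim`: a list with elements
#'   `trajectory` (data frame with columns `t`, `Tconv`, `Treg`, `Mconv`,
#'   `Mreg`, `R`, `Ec`, `Er`, `a`), `params`, `protocol`, `qc`, `qr` and
#'   `solver` (tolerances and step statistics).
#' @examples
#' sim <- simulate_immune(immune_params(), protocol_constant(200, 2000))
#' summary(sim)
#' @seealso [detect_steady_state()], [simulate_to_steady()]
#' @export
simulate_immune <- function(params, protocol, qc = dose_response("linear"),
                            qr = qc, t_end = NULL, init = NULL, n_out = 500,
                            atol = 1e-8, rtol = 1e-8, neg_tol = 1e-6) {
  stopifnot(is_immune_params(params), inherits(protocol, "antigen_protocol"),
            is_dose_response(qc), is_dose_response(qr))
  t0 <- min(protocol$t_start)
  if (is.null(t_end)) t_end <- max(protocol$t_end)
  if (t_end > max(protocol$t_end) + 1e-9 || t_end <= t0)
    stop("t_end must lie within the protocol span")
  if (is.null(init)) init <- c(0, 0, 0, 0, 0)
  stopifnot(is.numeric(init), length(init) == 5, all(init >= 0))
  names(init) <- c("Tconv", "Treg", "Mconv", "Mreg", "R")

  boundaries <- sort(unique(c(t0, t_end,
                              protocol$t_start[protocol$t_start < t_end],
                              protocol$t_end[protocol$t_end < t_end])))
  times <- sort(unique(c(seq(t0, t_end, length.out = max(2, n_out)),
                         boundaries)))

  if (params$tau_delay > 0) {
    out <- integrate_delay(params, protocol, qc, qr, times, init,
                           atol, rtol, neg_tol)
  } else {
    out <- integrate_plain(params, protocol, qc, qr, times, init,
                           boundaries, atol, rtol, neg_tol)
  }

  traj <- as.data.frame(out$traj)
  names(traj) <- c("t", "Tconv", "Treg", "Mconv", "Mreg", "R")
  if (any(unlist(traj[-1]) < -neg_tol))
    stop("trajectory negative beyond tolerance")
  traj[-1] <- lapply(traj[-1], pmax, 0)

  # recompute instantaneous inputs and errors on the output grid
  traj$a <- antigen_at(protocol, traj$t)
  if (params$tau_delay > 0) {
    tl <- traj$t - params$tau_delay
    al <- antigen_at(protocol, tl, before_zero = TRUE)
    Tcl <- hist_interp(traj$t, traj$Tconv, tl, init[["Tconv"]])
    Trl <- hist_interp(traj$t, traj$Treg, tl, init[["Treg"]])
    traj$Ec <- params$ec * pmax(al - params$mc * Tcl, 0)
    traj$Er <- params$er *
      pmax(g_eval(Tcl, params$Amax, params$K) - al - params$mr * Trl, 0)
  } else {
    traj$Ec <- prediction_error_conv(traj$a, traj$Tconv, params$ec, params$mc)
    traj$Er <- prediction_error_reg(traj$a, traj$Tconv, traj$Treg, params)
  }
  traj <- traj[, c("t", "Tconv", "Treg", "Mconv", "Mreg", "R", "Ec", "Er", "a")]

  structure(list(trajectory = traj, params = params, protocol = protocol,
                 qc = qc, qr = qr,
                 solver = c(list(atol = atol, rtol = rtol, n_out = n_out,
                                 delay = params$tau_delay > 0), out$stats)),
            class = "immune_sim")
}

integrate_plain <- function(params, protocol, qc, qr, times, init,
                            boundaries, atol, rtol, neg_tol) {
  traj <- NULL
  state <- init
  nsteps <- 0L
  for (i in seq_len(length(boundaries) - 1L)) {
    # restrict the RHS to the protocol row covering this chunk, so that the
    # integrator's internal trial steps beyond the chunk end never see the
    # next segment's antigen level (the clamped evaluation stays smooth)
    mid <- (boundaries[i] + boundaries[i + 1L]) / 2
    row <- which(protocol$t_start <= mid & protocol$t_end >= mid)[1L]
    seg_prot <- new_protocol(as.data.frame(protocol)[row, , drop = FALSE])
    rhs <- function(t, y, parms)
      immune_rhs(t, y, params, seg_prot, qc, qr, neg_tol = neg_tol)
    seg_times <- times[times >= boundaries[i] & times <= boundaries[i + 1L]]
    seg_times <- sort(unique(c(boundaries[i], seg_times, boundaries[i + 1L])))
    out <- deSolve::ode(y = state, times = seg_times, func = rhs,
                        parms = NULL, method = "lsoda",
                        atol = atol, rtol = rtol)
    diag <- attr(out, "istate")
    if (!is.null(diag)) nsteps <- nsteps + diag[3L]
    chunk <- out[, 1:6, drop = FALSE]
    state <- chunk[nrow(chunk), -1L]
    names(state) <- names(init)
    if (!is.null(traj)) chunk <- chunk[-1L, , drop = FALSE]
    traj <- rbind(traj, chunk)
  }
  list(traj = traj, stats = list(n_steps = as.integer(nsteps)))
}

integrate_delay <- function(params, protocol, qc, qr, times, init,
                            atol, rtol, neg_tol) {
  tau <- params$tau_delay
  t0 <- times[1L]
  rhs <- function(t, y, parms) {
    if (t - tau > t0) {
      yl <- deSolve::lagvalue(t - tau, c(1L, 2L))
    } else {
      yl <- init[1:2]
    }
    lag <- list(a = antigen_at(protocol, t - tau, before_zero = TRUE,
                               clamp = TRUE),
                Tconv = yl[1L], Treg = yl[2L])
    immune_rhs(t, y, params, protocol, qc, qr, lagged = lag,
               neg_tol = neg_tol)
  }
  # multi-segment protocols have C0 kinks mid-integration (the delay branch
  # cannot restart at boundaries without losing its lag history), so cap the
  # step size at half the shortest segment; single-segment runs are smooth
  hmax <- if (nrow(protocol) > 1L)
    max(min(protocol$t_end - protocol$t_start) / 2, 1e-3) else NULL
  out <- deSolve::dede(y = init, times = times, func = rhs, parms = NULL,
                       atol = atol, rtol = rtol,
                       control = list(mxhist = 1e5), hmax = hmax)
  diag <- attr(out, "istate")
  list(traj = out[, 1:6, drop = FALSE],
       stats = list(n_steps = if (is.null(diag)) NA_integer_
                    else as.integer(diag[3L])))
}

# linear interpolation of a trajectory column at lagged times, with constant
# pre-history
hist_interp <- function(t, y, t_query, y0) {
  out <- rep(y0, length(t_query))
  inside <- t_query >= t[1L]
  if (any(inside))
    out[inside] <- stats::approx(t, y, xout = t_query[inside], rule = 2)$y
  out
}

#' Detect a steady state in a simulated trajectory
#'
#' A run is declared converged when, over the trailing `window` of the
#' simulated span, the relative variation of *every* state component
#' (including both memory compartments -- memory is neutrally stable, so a
#' run that plateaus in `(Tconv, Treg, R)` while memory still accumulates is
#' reported as non-converged) stays below `rel_tol`.  The steady-state
#' summary is the trailing-window mean.
#'
#' @param sim An [simulate_immune()] result.
#' @param rel_tol Maximum allowed relative variation over the window.
#' @param window Length of the trailing window (default: 5% of the span).
#'   Must not exceed half the simulated span.
#' @return A list with `converged` (logical), `state` (named mean state over
#'   the window, including `Ec`, `Er`), `rel_change` (worst relative
#'   variation) and `window`.
#' @export
detect_steady_state <- function(sim, rel_tol = 1e-6, window = NULL) {
  stopifnot(inherits(sim, "immune_sim"))
  traj <- sim$trajectory
  span <- diff(range(traj$t))
  if (is.null(window)) window <- 0.05 * span
  if (window <= 0 || window > span / 2)
    stop("window must be positive and at most half the simulated span")
  tail_rows <- traj$t >= max(traj$t) - window
  if (sum(tail_rows) < 2L)
    stop("trailing window contains fewer than two output points")
  cols <- c("Tconv", "Treg", "Mconv", "Mreg", "R")
  tailblock <- traj[tail_rows, , drop = FALSE]
  m <- vapply(tailblock[cols], mean, numeric(1))
  spread <- vapply(tailblock[cols], function(v) max(v) - min(v), numeric(1))
  denom <- pmax(abs(m), sim$solver$atol * 10, 1e-12)
  rel <- spread / denom
  state <- c(m, Ec = mean(tailblock$Ec), Er = mean(tailblock$Er))
  list(converged = all(rel < rel_tol), state = state,
       rel_change = max(rel), window = window)
}

#' Run to a steady state under an open-ended protocol
#'
#' Repeatedly extends the final protocol segment and re-integrates until
#' [detect_steady_state()] reports convergence or `max_horizon` is reached.
#' Intended for constant or saturating inputs whose final segment can be
#' prolonged without changing the input law.
#'
#' @inheritParams simulate_immune
#' @param horizon Initial integration horizon.
#' @param max_horizon Give up (returning `converged = FALSE`) beyond this.
#' @param rel_tol,window Passed to [detect_steady_state()]; `window = NULL`
#'   uses 5% of the current horizon.
#' @return A list with `converged`, `state`, `horizon` and the final `sim`.
#' @export
simulate_to_steady <- function(params, protocol, qc = dose_response("linear"),
                               qr = qc, init = NULL, horizon = 4000,
                               max_horizon = 2.6e5, rel_tol = 1e-6,
                               window = NULL, n_out = 400, atol = 1e-8,
                               rtol = 1e-8) {
  stopifnot(horizon > 0)
  prot <- protocol
  span <- protocol_duration(prot)
  if (span < horizon) prot <- extend_protocol(prot, horizon - span)
  repeat {
    sim <- simulate_immune(params, prot, qc, qr, init = init, n_out = n_out,
                           atol = atol, rtol = rtol)
    ss <- detect_steady_state(sim, rel_tol = rel_tol, window = window)
    if (ss$converged || protocol_duration(prot) >= max_horizon) {
      return(list(converged = ss$converged, state = ss$state,
                  horizon = protocol_duration(prot), sim = sim))
    }
    prot <- extend_protocol(prot, protocol_duration(prot))  # double it
  }
}

#' @export
print.immune_sim <- function(x, ...) {
  tr <- x$trajectory
  cat(sprintf("Predictive immune memory simulation: t in [%g, %g], %d points%s\n",
              min(tr$t), max(tr$t), nrow(tr),
              if (isTRUE(x$solver$delay))
                sprintf(" (memory delay %g)", x$params$tau_delay) else ""))
  fin <- tr[nrow(tr), ]
  cat(sprintf("  final state: Tconv=%.4g Treg=%.4g Mconv=%.4g Mreg=%.4g R=%.4g\n",
              fin$Tconv, fin$Treg, fin$Mconv, fin$Mreg, fin$R))
  invisible(x)
}

#' @export
summary.immune_sim <- function(object, rel_tol = 1e-6, ...) {
  ss <- detect_steady_state(object, rel_tol = rel_tol)
  out <- list(steady = ss, final = object$trajectory[nrow(object$trajectory), ],
              solver = object$solver)
  class(out) <- "summary.immune_sim"
  out
}

#' @export
print.summary.immune_sim <- function(x, ...) {
  cat("Steady state", if (x$steady$converged) "reached" else "NOT reached",
      sprintf("(worst trailing relative change %.3g)\n", x$steady$rel_change))
  print(round(x$steady$state, 6))
  invisible(x)
}

#' @export
as.data.frame.immune_sim <- function(x, ...) x$trajectory

#' Plot a simulated trajectory
#'
#' Draws the antigen input, the T cell populations, the memory compartments
#' with their driving prediction errors, and the response intensity in four
#' stacked panels.
#'
#' @param x An `immune_sim`.
#' @param log_R Plot the response intensity on a log axis.
#' @param ... Unused.
#' @export
plot.immune_sim <- function(x, log_R = FALSE, ...) {
  tr <- x$trajectory
  op <- graphics::par(mfrow = c(4, 1), mar = c(2.5, 4, 1, 1), mgp = c(2, 0.7, 0))
  on.exit(graphics::par(op))
  graphics::plot(tr$t, tr$a, type = "l", xlab = "", ylab = "antigen a(t)")
  graphics::matplot(tr$t, cbind(tr$Tconv, tr$Treg), type = "l", lty = 1,
                    col = c("darkorange", "forestgreen"), xlab = "",
                    ylab = "T cells")
  graphics::legend("topright", c("Tconv", "Treg"), lty = 1, bty = "n",
                   col = c("darkorange", "forestgreen"))
  graphics::matplot(tr$t, cbind(tr$Mconv, tr$Mreg), type = "l", lty = 1,
                    col = c("darkorange", "forestgreen"), xlab = "",
                    ylab = "memory")
  graphics::plot(tr$t, tr$R, type = "l", xlab = "time", ylab = "response R",
                 log = if (log_R) "y" else "")
  invisible(x)
}

#' Export a simulation as tidy CSV plus JSON metadata
#'
#' @param sim An `immune_sim`.
#' @param csv,json Output paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_sim <- function(sim, csv = NULL, json = NULL) {
  stopifnot(inherits(sim, "immune_sim"))
  if (!is.null(csv))
    utils::write.csv(sim$trajectory, csv, row.names = FALSE)
  if (!is.null(json)) {
    meta <- list(params = unclass(sim$params),
                 protocol = as.data.frame(sim$protocol),
                 qc = unclass(sim$qc), qr = unclass(sim$qr),
                 solver = sim$solver)
    jsonlite::write_json(meta, json, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  }
  invisible(c(csv = csv, json = json))
}
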