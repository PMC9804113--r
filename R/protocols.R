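#' Piecewise antigen input protocols
#'
#' An antigen protocol is an ordered, contiguous list of time segments, each
#' of which is one of three shapes:
#' * `zero` — no antigen,
#' * `constant` — `a(t) = a0` (the rapid-input limit of the saturating form),
#' * `saturating` — `a(t) = a0 * (1 - exp(-(t - t_start)/tau))`, the
#'   saturating-exponential input whose time constant `tau` encodes the
#'   rapidness of antigen exposure.
#'
#' Protocols are built from the single-segment constructors and concatenated
#' with `c()`, which shifts each subsequent protocol to start where the
#' previous one ends.  `antigen_at()` evaluates `a(t)`; evaluation outside
#' the protocol span is an error.
#'
#' @param a0 Plateau antigen concentration, `>= 0`.
#' @param duration Segment length, `> 0`.
#' @param tau Time constant of the saturating input, `> 0`.
#' @return An object of class `antigen_protocol` (a data frame of segments
#'   with columns `t_start`, `t_end`, `shape`, `a0`, `tau`).
#' @examples
#' p <- c(protocol_constant(200, 1500), protocol_zero(300),
#'        protocol_saturating(50, 100, 2000))
#' antigen_at(p, c(0, 1500, 1700, 1800 + 100))
#' protocol_duration(p)
#' @export
protocol_constant <- function(a0, duration) {
  new_protocol(data.frame(t_start = 0, t_end = duration, shape = "constant",
                          a0 = a0, tau = NA_real_))
}

#' @rdname protocol_constant
#' @export
protocol_zero <- function(duration) {
  new_protocol(data.frame(t_start = 0, t_end = duration, shape = "zero",
                          a0 = 0, tau = NA_real_))
}

#' @rdname protocol_constant
#' @export
protocol_saturating <- function(a0, tau, duration) {
  new_protocol(data.frame(t_start = 0, t_end = duration, shape = "saturating",
                          a0 = a0, tau = tau))
}

#' Build a protocol directly from a segment table
#'
#' @param segments A data frame (or list coercible to one) with columns
#'   `t_start`, `t_end`, `shape` (`"zero"`, `"constant"` or `"saturating"`),
#'   `a0` and `tau` (`NA` except for saturating segments).
#' @return An `antigen_protocol`.
#' @export
antigen_protocol <- function(segments) {
  segments <- as.data.frame(segments)
  required <- c("t_start", "t_end", "shape", "a0")
  if (!all(required %in% names(segments)))
    stop("segments need columns: ", paste(required, collapse = ", "))
  if (is.null(segments$tau)) segments$tau <- NA_real_
  new_protocol(segments[, c("t_start", "t_end", "shape", "a0", "tau")])
}

new_protocol <- function(segments) {
  segments$shape <- as.character(segments$shape)
  bad <- !segments$shape %in% c("zero", "constant", "saturating")
  if (any(bad)) stop("unknown segment shape: ", segments$shape[bad][1])
  if (nrow(segments) == 0 || sum(segments$t_end - segments$t_start) <= 0)
    stop("protocol must have positive total duration")
  if (any(segments$t_end < segments$t_start))
    stop("segment end before start")
  # drop zero-length segments (degenerate phases are allowed in schedules)
  segments <- segments[segments$t_end > segments$t_start, , drop = FALSE]
  o <- order(segments$t_start)
  segments <- segments[o, , drop = FALSE]
  if (nrow(segments) > 1) {
    gaps <- segments$t_start[-1] - segments$t_end[-nrow(segments)]
    if (any(abs(gaps) > 1e-9))
      stop("segments must be contiguous and non-overlapping")
  }
  if (any(!is.finite(segments$a0)) || any(segments$a0 < 0))
    stop("a0 must be finite and non-negative")
  sat <- segments$shape == "saturating"
  if (any(sat & (!is.finite(segments$tau) | segments$tau <= 0)))
    stop("saturating segments need a positive time constant tau")
  rownames(segments) <- NULL
  structure(segments, class = c("antigen_protocol", "data.frame"))
}

#' @rdname protocol_constant
#' @param x An `antigen_protocol`.
#' @export
protocol_duration <- function(x) {
  stopifnot(inherits(x, "antigen_protocol"))
  max(x$t_end) - min(x$t_start)
}

#' @export
c.antigen_protocol <- function(...) {
  parts <- list(...)
  stopifnot(all(vapply(parts, inherits, logical(1), "antigen_protocol")))
  offset <- min(parts[[1]]$t_start)
  out <- NULL
  for (p in parts) {
    seg <- as.data.frame(p)
    shift <- offset - min(seg$t_start)
    seg$t_start <- seg$t_start + shift
    seg$t_end <- seg$t_end + shift
    offset <- max(seg$t_end)
    out <- rbind(out, seg)
  }
  new_protocol(out)
}

#' Evaluate an antigen protocol
#'
#' @param protocol An [antigen_protocol()].
#' @param t Time(s) within the protocol span.
#' @param before_zero If `TRUE`, times before the protocol start evaluate to
#'   zero antigen (the pre-exposure history used by the delay extension)
#'   instead of raising an error.
#' @param clamp If `TRUE`, times are clamped to the protocol span instead of
#'   raising an error (used by the integrator, whose adaptive steps may probe
#'   marginally beyond the final output time).
#' @return Antigen concentration `a(t)`, vectorised over `t`.
#' @export
antigen_at <- function(protocol, t, before_zero = FALSE, clamp = FALSE) {
  stopifnot(inherits(protocol, "antigen_protocol"))
  t0 <- min(protocol$t_start); t1 <- max(protocol$t_end)
  if (clamp) {  # lower end: keep pre-history zero when before_zero is set
    t <- pmin(t, t1)
    if (!before_zero) t <- pmax(t, t0)
  }
  tol <- 1e-9 * max(1, abs(t1))
  if (any(t > t1 + tol) || (!before_zero && any(t < t0 - tol)))
    stop("time outside protocol span [", t0, ", ", t1, "]")
  idx <- findInterval(pmin(t, t1 - tol), protocol$t_start)
  a <- numeric(length(t))
  inside <- idx >= 1L
  if (any(inside)) {
    i <- idx[inside]
    sh <- protocol$shape[i]
    a0 <- protocol$a0[i]
    ts <- protocol$t_start[i]
    tau <- protocol$tau[i]
    v <- numeric(length(i))
    con <- sh == "constant"
    v[con] <- a0[con]
    sat <- sh == "saturating"
    v[sat] <- a0[sat] * (1 - exp(-(t[inside][sat] - ts[sat]) / tau[sat]))
    a[inside] <- v
  }
  a
}

# extend the final segment in place (used to push a run further in time when
# a steady state has not yet been reached); saturating segments keep their
# original onset so the input law is unchanged
extend_protocol <- function(protocol, extra) {
  stopifnot(inherits(protocol, "antigen_protocol"), extra > 0)
  protocol$t_end[nrow(protocol)] <- protocol$t_end[nrow(protocol)] + extra
  protocol
}

#' @export
print.antigen_protocol <- function(x, ...) {
  cat(sprintf("Antigen protocol: %d segment(s), span [%g, %g]\n",
              nrow(x), min(x$t_start), max(x$t_end)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Three-phase allergen immunotherapy schedule
#'
#' Builds the antigen input of an in-silico immunotherapy experiment:
#' 1. *induction* — a rapid (constant) high-concentration input that induces
#'    the allergic, conventional-memory-dominated state;
#' 2. *therapy* — a lower dose, optionally ramped in slowly with time
#'    constant `tau_therapy`;
#' 3. *challenge* — the high input again, probing the therapeutic effect.
#'
#' Optional zero-antigen washout gaps can be inserted between phases; the
#' default is contiguous phases (see the vignette: a washout period itself
#' constitutes an "excess response" to the now-absent antigen and trains the
#' regulatory arm, which confounds the dose-effect readout).
#'
#' The returned protocol carries a `phases` attribute (one row per phase,
#' with the window used by [run_therapy_protocol()] for per-phase maxima:
#' each window extends to the start of the next phase, i.e. it includes the
#' washout tail).
#'
#' @param a_high Concentration of the induction and challenge inputs.
#' @param a_therapy Dose administered during therapy.
#' @param tau_therapy Time constant of the therapy ramp; `0` means a constant
#'   (rapid) therapy input.
#' @param durations Lengths of the three phases.  A zero length degenerates
#'   the phase away (e.g. `durations[2] = 0` gives two identical challenges).
#' @param gaps Washout lengths after phases 1 and 2.
#' @return An `antigen_protocol` with a `phases` attribute.
#' @examples
#' sch <- therapy_schedule()
#' attr(sch, "phases")
#' @export
therapy_schedule <- function(a_high = 200, a_therapy = 50, tau_therapy = 0,
                             durations = c(1500, 4000, 1500),
                             gaps = c(0, 0)) {
  stopifnot(length(durations) == 3, length(gaps) == 2,
            all(durations >= 0), all(gaps >= 0), all(durations[c(1, 3)] > 0),
            a_high >= 0, a_therapy >= 0, tau_therapy >= 0)
  phase_segment <- function(a, tau, d) {
    if (d == 0) return(NULL)
    if (a > 0 && tau > 0) protocol_saturating(a, tau, d)
    else if (a > 0) protocol_constant(a, d)
    else protocol_zero(d)
  }
  segs <- list(phase_segment(a_high, 0, durations[1]),
               if (gaps[1] > 0) protocol_zero(gaps[1]),
               phase_segment(a_therapy, tau_therapy, durations[2]),
               if (gaps[2] > 0) protocol_zero(gaps[2]),
               phase_segment(a_high, 0, durations[3]))
  segs <- Filter(Negate(is.null), segs)
  prot <- do.call(c, segs)
  starts <- cumsum(c(0, durations[1], gaps[1], durations[2], gaps[2]))
  phase_start <- starts[c(1, 3, 5)]
  phase_next <- c(phase_start[-1], sum(durations) + sum(gaps))
  attr(prot, "phases") <- data.frame(
    phase = 1:3,
    label = c("induction", "therapy", "challenge"),
    start = phase_start, end = phase_start + durations,
    window_end = phase_next)
  prot
}

#' Five-phase persistence-of-therapy schedule
#'
#' Extends [therapy_schedule()] with two further rapid exposures: a *boost*
#' at a concentration above the original allergen input, followed by a final
#' *probe* at a lower concentration that quantifies whether the therapeutic
#' suppression persisted.
#'
#' @inheritParams therapy_schedule
#' @param a_boost Concentration of the post-therapy higher exposure.
#' @param a_probe Concentration of the final probe.
#' @param durations Lengths of the five phases (induction, therapy,
#'   challenge, boost, probe).
#' @param gaps Washout lengths after phases 1-4.
#' @return An `antigen_protocol` with a five-row `phases` attribute.
#' @export
persistence_schedule <- function(a_high = 200, a_therapy = 50,
                                 tau_therapy = 0,
                                 a_boost = 400, a_probe = a_high,
                                 durations = c(1500, 4000, 1500, 1500, 1500),
                                 gaps = c(0, 0, 0, 0)) {
  stopifnot(length(durations) == 5, length(gaps) == 4,
            all(durations >= 0), all(gaps >= 0))
  base <- therapy_schedule(a_high, a_therapy, tau_therapy,
                           durations[1:3], gaps[1:2])
  extra <- list(if (gaps[3] > 0) protocol_zero(gaps[3]),
                if (durations[4] > 0) protocol_constant(a_boost, durations[4]),
                if (gaps[4] > 0) protocol_zero(gaps[4]),
                if (durations[5] > 0) protocol_constant(a_probe, durations[5]))
  extra <- Filter(Negate(is.null), extra)
  prot <- do.call(c, c(list(base), extra))
  starts <- cumsum(c(0, durations[1], gaps[1], durations[2], gaps[2],
                     durations[3], gaps[3], durations[4], gaps[4]))
  phase_start <- starts[c(1, 3, 5, 7, 9)]
  phase_next <- c(phase_start[-1], sum(durations) + sum(gaps))
  attr(prot, "phases") <- data.frame(
    phase = 1:5,
    label = c("induction", "therapy", "challenge", "boost", "probe"),
    start = phase_start, end = phase_start + durations,
    window_end = phase_next)
  prot
}
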