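#' Ramp (rectification) function
#'
#' `ramp(x)` is `0` for `x < 0` and `x` otherwise.  The model's prediction
#' errors are ramp-rectified: memory forms only when the observation exceeds
#' the prediction, never in the opposite direction.
#'
#' @param x Numeric vector, finite.
#' @return `pmax(x, 0)`.
#' @examples
#' ramp(c(-3, 0, 5))
#' @export
ramp <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("ramp() requires finite numeric input")
  pmax(x, 0)
}

#' Regulatory evaluation of conventional T cell activation
#'
#' The regulatory lineage evaluates the activation level of the conventional
#' lineage through the saturating curve
#' `g(Tconv) = Amax * Tconv / (Tconv + K)`, bounded in `[0, Amax)` and
#' non-decreasing in `Tconv`.  Its excess over the antigen concentration,
#' `g(Tconv) - a`, is the "observation" of the regulatory prediction error.
#'
#' @param Tconv Conventional T cell density, non-negative.
#' @param Amax Saturation level, `> 0`.
#' @param K Half-saturation cell density, `> 0`.
#' @return `Amax * Tconv / (Tconv + K)`, vectorised over `Tconv`.
#' @examples
#' g_eval(0, 200, 100)    # 0
#' g_eval(100, 200, 100)  # Amax / 2 at Tconv = K
#' @export
g_eval <- function(Tconv, Amax, K) {
  if (any(Tconv < 0)) stop("Tconv must be non-negative")
  stopifnot(Amax > 0, K > 0)
  Amax * Tconv / (Tconv + K)
}

#' Prediction errors of the two T cell lineages
#'
#' `prediction_error_conv()` is the rectified error of the antigen prediction,
#' `Ec = ec * ramp(a - mc * Tconv)`: positive exactly when the antigen
#' concentration exceeds what the conventional population "covers".
#'
#' `prediction_error_reg()` is the rectified error of the excess-response
#' prediction, `Er = er * ramp(g(Tconv) - a - mr * Treg)` with `g` as in
#' [g_eval()]: positive exactly when the evaluated response overhang exceeds
#' the regulatory population's prediction.  It is identically zero whenever
#' `g(Tconv) <= a`.
#'
#' @param a Antigen concentration, non-negative.
#' @param Tconv,Treg Cell densities, non-negative.
#' @param ec,mc Gain and prediction scaling of the conventional error.
#' @param params An [immune_params()] object (supplies `er`, `mr`, `Amax`,
#'   `K` for the regulatory error).
#' @return Non-negative memory-formation rate (1/time).
#' @examples
#' prediction_error_conv(200, 50, ec = 0.1, mc = 1)  # 0.1 * 150
#' p <- immune_params(Amax = 10, K = 30, mr = 1, er = 0.5)
#' prediction_error_reg(2, 30, 1, p)                 # 0.5 * (5 - 2 - 1)
#' @export
prediction_error_conv <- function(a, Tconv, ec, mc) {
  if (any(a < 0) || any(Tconv < 0))
    stop("a and Tconv must be non-negative")
  ec * ramp(a - mc * Tconv)
}

#' @rdname prediction_error_conv
#' @export
prediction_error_reg <- function(a, Tconv, Treg, params) {
  stopifnot(is_immune_params(params))
  if (any(a < 0) || any(Tconv < 0) || any(Treg < 0))
    stop("a, Tconv and Treg must be non-negative")
  params$er * ramp(g_eval(Tconv, params$Amax, params$K) - a - params$mr * Treg)
}

#' Right-hand side of the predictive immune memory model
#'
#' Time derivatives of the five-dimensional state
#' `(Tconv, Treg, Mconv, Mreg, R)`:
#' \deqn{\dot T_{conv} = -d_c T_{conv} + \frac{D_c T_{conv}}{1 + s_r T_{reg}}
#'   + k_c T_{naive}\, q_c(a) + w_c M_{conv}\, q_c(a) - E_c T_{conv}}
#' \deqn{\dot T_{reg} = -d_r T_{reg} + \frac{D_r T_{reg}}{1 + s_c T_{conv}}
#'   + k_r T_{naive}\, q_r(a) + w_r M_{reg}\, q_r(a) - E_r T_{reg}}
#' \deqn{\dot M_{conv} = -d_{mc} M_{conv} + E_c \tilde T_{conv}, \qquad
#'   \dot M_{reg} = -d_{mr} M_{reg} + E_r \tilde T_{reg}}
#' \deqn{\dot R = -(r_0 + r_s T_{reg}) R + r_a T_{conv}}
#' with prediction errors `Ec`, `Er` as in [prediction_error_conv()] and
#' [prediction_error_reg()].  Without a delay, the errors and the
#' memory-source populations \eqn{\tilde T} are evaluated at time `t`; with a
#' memory-formation delay (`tau_delay > 0`) they are evaluated at
#' `t - tau_delay` (supplied through `lagged`), while the removal terms
#' `-Ec Tconv`, `-Er Treg` act on the current populations.
#'
#' The dose-response `q(a)` enters only the naive-differentiation and
#' memory-reactivation terms; the prediction errors always see the raw
#' antigen concentration.
#'
#' State components within `neg_tol` below zero (integration round-off) are
#' clipped to zero before evaluation; components below `-neg_tol` are an
#' error.
#'
#' @param t Time.
#' @param state Numeric state vector `c(Tconv, Treg, Mconv, Mreg, R)`.
#' @param params An [immune_params()] object.
#' @param protocol An [antigen_protocol()] giving `a(t)`.
#' @param qc,qr [dose_response()] objects for the two lineages.
#' @param lagged Either `NULL` (no delay) or a list with elements `a`,
#'   `Tconv`, `Treg` evaluated at `t - tau_delay`.
#' @param neg_tol Clipping tolerance for slightly negative states.
#' @return A list whose first element is the derivative vector, with the
#'   instantaneous `Ec`, `Er` and `a` as named extras (deSolve convention).
#' @examples
#' p <- immune_params()
#' prot <- protocol_constant(200, 100)
#' q <- dose_response("linear")
#' immune_rhs(0, c(0, 0, 0, 0, 0), p, prot, q, q)
#' @export
immune_rhs <- function(t, state, params, protocol, qc, qr, lagged = NULL,
                       neg_tol = 1e-6) {
  if (any(state < -neg_tol))
    stop("state became negative beyond tolerance at t = ", signif(t, 6),
         " (min = ", signif(min(state), 4), ")")
  state <- pmax(state, 0)
  Tc <- state[[1L]]; Tr <- state[[2L]]
  Mc <- state[[3L]]; Mr <- state[[4L]]; R <- state[[5L]]
  a <- antigen_at(protocol, t, clamp = TRUE)

  if (is.null(lagged)) {
    Ec <- params$ec * max(a - params$mc * Tc, 0)
    Er <- params$er * max(params$Amax * Tc / (Tc + params$K) - a -
                            params$mr * Tr, 0)
    Tc_src <- Tc
    Tr_src <- Tr
  } else {
    al <- lagged$a; Tcl <- max(lagged$Tconv, 0); Trl <- max(lagged$Treg, 0)
    Ec <- params$ec * max(al - params$mc * Tcl, 0)
    Er <- params$er * max(params$Amax * Tcl / (Tcl + params$K) - al -
                            params$mr * Trl, 0)
    Tc_src <- Tcl
    Tr_src <- Trl
  }

  qca <- q_eval(qc, a)
  qra <- q_eval(qr, a)
  dTc <- -params$dc * Tc + params$Dc * Tc / (1 + params$sr * Tr) +
    params$kc * params$Tnaive * qca + params$wc * Mc * qca - Ec * Tc
  dTr <- -params$dr * Tr + params$Dr * Tr / (1 + params$sc * Tc) +
    params$kr * params$Tnaive * qra + params$wr * Mr * qra - Er * Tr
  dMc <- -params$dmc * Mc + Ec * Tc_src
  dMr <- -params$dmr * Mr + Er * Tr_src
  dR <- -(params$r0 + params$rs * Tr) * R + params$ra * Tc

  list(c(dTc, dTr, dMc, dMr, dR), Ec = Ec, Er = Er, a = a)
}
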