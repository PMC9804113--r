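#' Dose-response of T cell activation
#'
#' Builds the activation curve `q(a)` mapping antigen concentration to the
#' drive behind naive differentiation and memory reactivation.  Two
#' functional forms are supported: `linear`, `q(a) = a`, and `hill`,
#' `q(a) = Q a^h / (Kd^h + a^h)`.  Two named Hill presets cover the model's
#' canonical variants: `"sigmoidal"` is Hill with `(h, Q, Kd) = (4, 10, 30)`
#' and `"step_like"` is Hill with `(h, Q, Kd) = (8, 10, 10)`.
#'
#' @param kind One of `"linear"`, `"sigmoidal"`, `"step_like"` or `"hill"`.
#'   For `"hill"` all three shape parameters must be given; for the named
#'   presets they must not be.
#' @param Q Amplitude (maximal activation drive), `> 0`.
#' @param Kd Half-maximal antigen concentration, `> 0`.
#' @param h Hill coefficient, `>= 1`.
#' @return An object of class `dose_response`.
#' @examples
#' q <- dose_response("sigmoidal")
#' predict(q, c(0, 30, 300))  # half-maximum Q/2 at a = Kd
#' predict(dose_response("linear"), 37.5)
#' @export
dose_response <- function(kind = c("linear", "sigmoidal", "step_like", "hill"),
                          Q = NULL, Kd = NULL, h = NULL) {
  kind <- match.arg(kind)
  if (kind %in% c("sigmoidal", "step_like")) {
    if (!is.null(Q) || !is.null(Kd) || !is.null(h))
      stop("preset '", kind, "' fixes Q, Kd and h; do not supply them")
    preset <- switch(kind,
                     sigmoidal = c(Q = 10, Kd = 30, h = 4),
                     step_like = c(Q = 10, Kd = 10, h = 8))
    out <- list(kind = "hill", preset = kind,
                Q = preset[["Q"]], Kd = preset[["Kd"]], h = preset[["h"]])
  } else if (kind == "hill") {
    if (is.null(Q) || is.null(Kd) || is.null(h))
      stop("kind 'hill' requires Q, Kd and h")
    stopifnot(is.numeric(Q), Q > 0, is.numeric(Kd), Kd > 0,
              is.numeric(h), h >= 1)
    out <- list(kind = "hill", preset = NULL, Q = Q, Kd = Kd, h = h)
  } else {
    if (!is.null(Q) || !is.null(Kd) || !is.null(h))
      stop("kind 'linear' takes no shape parameters")
    out <- list(kind = "linear", preset = "linear", Q = NULL, Kd = NULL, h = NULL)
  }
  structure(out, class = "dose_response")
}

#' @rdname dose_response
#' @param x For `is_dose_response()`, an object to test.
#' @export
is_dose_response <- function(x) inherits(x, "dose_response")

#' Evaluate a dose-response curve
#'
#' @param object A [dose_response()] object.
#' @param a Antigen concentration(s), non-negative.
#' @param ... Unused.
#' @return Activation drive `q(a)`, same length as `a`; non-negative and
#'   non-decreasing in `a`.
#' @export
predict.dose_response <- function(object, a, ...) {
  if (!is.numeric(a) || any(!is.finite(a)))
    stop("antigen concentration must be finite numeric")
  if (any(a < 0))
    stop("antigen concentration must be non-negative")
  if (object$kind == "linear") return(a)
  ah <- a^object$h
  object$Q * ah / (object$Kd^object$h + ah)
}

# scalar fast path used inside the RHS (no input validation)
q_eval <- function(q, a) {
  if (q$kind == "linear") return(a)
  ah <- a^q$h
  q$Q * ah / (q$Kd^q$h + ah)
}

#' @export
print.dose_response <- function(x, ...) {
  if (x$kind == "linear") {
    cat("Dose-response: linear, q(a) = a\n")
  } else {
    cat(sprintf("Dose-response: %s Hill, q(a) = %g a^%g / (%g^%g + a^%g)\n",
                if (is.null(x$preset)) "custom" else x$preset,
                x$Q, x$h, x$Kd, x$h, x$h))
  }
  invisible(x)
}
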