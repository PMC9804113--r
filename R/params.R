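#' Model parameters for the predictive immune memory model
#'
#' Constructs and validates the full set of rate constants and
#' predictive-coding gains of the T cell population model.  The state
#' variables are the conventional (`Tconv`) and regulatory (`Treg`) T cell
#' densities, their memory compartments (`Mconv`, `Mreg`) and the response
#' intensity `R`; see [immune_rhs()] for the equations in which each
#' parameter appears.
#'
#' The defaults are a repository-calibrated parameter set (no reference
#' numeric parameter table accompanies this model family).  They were
#' chosen analytically so that the prediction-error feedback loops are close
#' to critically damped over the working antigen range and so that the
#' antigen-discrimination threshold sits at
#' `a = Amax - mc * K = 100`; see the package vignette for the calibration
#' rationale.
#'
#' @param dc,dr Death (apoptosis) rates of conventional / regulatory T cells
#'   (1/time).
#' @param Dc,Dr Self-proliferation rates (1/time).  Stability of the
#'   populations requires `Dc < dc` and `Dr < dr`; violations are rejected.
#' @param sc,sr Mutual-suppression coefficients (1/cell density): `sc` is the
#'   suppression of regulatory proliferation by conventional cells, `sr` the
#'   converse.
#' @param kc,kr Differentiation rates of naive T cells into each lineage
#'   (1/(antigen x time)).
#' @param wc,wr Memory-reactivation rates (1/(antigen x time)).
#' @param Tnaive Constant naive T cell pool (cell density).
#' @param ec,er Prediction-error gains (1/time per unit error).
#' @param mc Prediction scaling of antigen by conventional T cells
#'   (antigen per cell density): the lineage's prediction of the antigen
#'   concentration is `mc * Tconv`.
#' @param mr Prediction scaling of the excess response by regulatory T cells.
#' @param Amax,K Saturating evaluation of conventional T cell activation used
#'   by the regulatory prediction: `g(Tconv) = Amax * Tconv / (Tconv + K)`.
#'   Discrimination by antigen concentration requires the regulatory arm to
#'   overestimate activation at low antigen, i.e. `Amax / K > mc`.
#' @param dmc,dmr Memory death rates (1/time).  The model's working regime is
#'   `dmc = dmr = 0` (memory is long-lived on the simulated time scale);
#'   nonzero values are accepted with a warning.
#' @param r0 Baseline decay rate of the response intensity (1/time).
#' @param ra,rs Activation of the response by conventional T cells and
#'   suppression by regulatory T cells.
#' @param tau_delay Constant delay of memory formation (time); `0` disables
#'   the delay extension.
#'
#' @return An object of class `immune_params`: a validated named list of all
#'   parameters.
#'
#' @examples
#' p <- immune_params()
#' p$Amax - p$mc * p$K  # analytic discrimination threshold of the defaults
#' p2 <- immune_params(K = 300)  # high K: no discrimination regime
#' @seealso [read_immune_params()], [immune_rhs()], [simulate_immune()]
#' @export
immune_params <- function(dc = 1, dr = 1,
                          Dc = 0.5, Dr = 0.5,
                          sc = 0.01, sr = 0.01,
                          kc = 1e-4, kr = 1e-4,
                          wc = 0.05, wr = 0.05,
                          Tnaive = 100,
                          ec = 1e-4, er = 3.5e-4,
                          mc = 1, mr = 0.1,
                          Amax = 200, K = 100,
                          dmc = 0, dmr = 0,
                          r0 = 0.1, ra = 1, rs = 1,
                          tau_delay = 0) {
  p <- list(dc = dc, dr = dr, Dc = Dc, Dr = Dr, sc = sc, sr = sr,
            kc = kc, kr = kr, wc = wc, wr = wr, Tnaive = Tnaive,
            ec = ec, er = er, mc = mc, mr = mr, Amax = Amax, K = K,
            dmc = dmc, dmr = dmr, r0 = r0, ra = ra, rs = rs,
            tau_delay = tau_delay)
  validate_immune_params(p)
}

#' @rdname immune_params
#' @param x For `is_immune_params()`, an object to test.
#' @export
is_immune_params <- function(x) inherits(x, "immune_params")

validate_immune_params <- function(p) {
  fields <- immune_param_names()
  missing <- setdiff(fields, names(p))
  if (length(missing))
    stop("missing model parameter(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(names(p), fields)
  if (length(extra))
    stop("unknown model parameter(s): ", paste(extra, collapse = ", "))
  p <- p[fields]
  bad <- !vapply(p, function(v) is.numeric(v) && length(v) == 1L && is.finite(v),
                 logical(1))
  if (any(bad))
    stop("parameter(s) not finite numeric scalars: ",
         paste(fields[bad], collapse = ", "))
  neg <- vapply(p, function(v) v < 0, logical(1))
  if (any(neg))
    stop("parameter(s) must be non-negative: ", paste(fields[neg], collapse = ", "))
  for (f in c("mc", "mr", "K", "Tnaive", "Amax"))
    if (p[[f]] <= 0) stop("'", f, "' must be strictly positive")
  if (p$Dc >= p$dc || p$Dr >= p$dr)
    stop("self-proliferation must be weaker than death (Dc < dc, Dr < dr), ",
         "otherwise the populations grow without bound")
  if (p$dmc > 0 || p$dmr > 0)
    warning("nonzero memory death rates (dmc, dmr): outside the model's ",
            "long-lived memory regime; memory monotonicity no longer holds",
            call. = FALSE)
  structure(p, class = "immune_params")
}

immune_param_names <- function() {
  c("dc", "dr", "Dc", "Dr", "sc", "sr", "kc", "kr", "wc", "wr", "Tnaive",
    "ec", "er", "mc", "mr", "Amax", "K", "dmc", "dmr", "r0", "ra", "rs",
    "tau_delay")
}

#' @export
print.immune_params <- function(x, ...) {
  cat("Predictive immune memory model parameters\n")
  v <- unlist(x)
  cat(paste0("  ", format(names(v), width = 10), format(v, digits = 6)),
      sep = "\n")
  cat(sprintf("  analytic discrimination threshold Amax - mc*K = %g\n",
              x$Amax - x$mc * x$K))
  invisible(x)
}

#' @export
coef.immune_params <- function(object, ...) unlist(object)

#' Read or write a model parameter file
#'
#' Parameter files are flat structured text (YAML, `symbol: value` per line)
#' using the same symbol names as the arguments of [immune_params()].  Keys
#' omitted from the file keep their repository-calibrated defaults; unknown
#' keys are an error.
#'
#' @param path File path.
#' @return `read_immune_params()` returns a validated [immune_params()]
#'   object; `write_immune_params()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' write_immune_params(immune_params(K = 50), f)
#' read_immune_params(f)$K
#' @export
read_immune_params <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.list(vals) || is.null(names(vals)) || any(names(vals) == ""))
    stop("parameter file must be a flat mapping of 'symbol: value' entries")
  unknown <- setdiff(names(vals), immune_param_names())
  if (length(unknown))
    stop("unknown parameter key(s) in '", path, "': ",
         paste(unknown, collapse = ", "))
  do.call(immune_params, vals)
}

#' @rdname read_immune_params
#' @param params An [immune_params()] object.
#' @export
write_immune_params <- function(params, path) {
  stopifnot(is_immune_params(params))
  yaml::write_yaml(lapply(unclass(params), as.numeric), path)
  invisible(path)
}
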