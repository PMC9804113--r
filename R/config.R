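#' Run configuration files
#'
#' A run configuration is a flat YAML document selecting an experiment and
#' overriding its defaults.  Recognised top-level keys (unknown keys are
#' rejected):
#'
#' * `experiment` — one of `r paste0('"', paste(predimm_experiments(), collapse = '", "'), '"')`.
#' * `params` — either a path to a parameter file (see
#'   [read_immune_params()]) or an inline mapping of parameter overrides.
#' * `qc`, `qr` — dose-response kinds (`"linear"`, `"sigmoidal"`,
#'   `"step_like"`).
#' * `protocol` — for `simulate`: either a fixture name (see
#'   [generate_fixture()]) or a list of segment records
#'   `{start, end, shape, a0, tau}`.
#' * `solver` — `atol`, `rtol`, `n_out`, `rel_tol`.
#' * `sweep` — `a_min`, `a_max`, `tau_min`, `tau_max`, `points`, `a0`.
#' * `therapy` — `a_high`, `a_therapy`, `tau_therapy`, `durations`, `gaps`.
#' * `persistence` — `a_boost`, `a_probe`.
#' * `phase_diagram` — `axes`, `x_min`, `x_max`, `x_points`, `y_min`,
#'   `y_max`, `y_points`.
#' * `sensitivity` — `factors`, `parameters`, `points`.
#' * `out_dir` — output directory.
#'
#' `load_config()` validates every section against the model's invariants
#' (e.g. `mc: 0` is rejected) and fills in all defaults, so that
#' `save_config(load_config(x))` round-trips to the normalised form.
#'
#' @param path YAML file path.
#' @return `load_config()`: a validated `run_config` list with all defaults
#'   applied; `save_config()`: `path`, invisibly.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config must be a YAML mapping")
  normalize_config(raw)
}

#' @rdname load_config
#' @param config A `run_config` (or plain list of overrides).
#' @export
save_config <- function(config, path) {
  config <- normalize_config(config)
  plain <- unclass(config)
  plain$params <- lapply(unclass(plain$params), as.numeric)
  plain$protocol <- if (is.character(plain$protocol)) plain$protocol else {
    segs <- as.data.frame(plain$protocol)
    lapply(seq_len(nrow(segs)), function(i) {
      s <- list(start = segs$t_start[i], end = segs$t_end[i],
                shape = segs$shape[i], a0 = segs$a0[i])
      if (is.finite(segs$tau[i])) s$tau <- segs$tau[i]
      s
    })
  }
  yaml::write_yaml(plain, path)
  invisible(path)
}

predimm_experiments <- function() {
  c("simulate", "sweep_concentration", "sweep_rapidness", "phase_diagram",
    "therapy", "persistence", "sensitivity", "fixtures")
}

config_defaults <- function() {
  list(experiment = "simulate",
       params = immune_params(),
       qc = "linear", qr = NULL,  # NULL: follow qc
       protocol = "high_step",
       solver = list(atol = 1e-8, rtol = 1e-8, n_out = 500, rel_tol = 1e-6),
       sweep = list(a_min = 10, a_max = 400, tau_min = 5, tau_max = 5000,
                    points = 25, a0 = 200),
       therapy = list(a_high = 200, a_therapy = 50, tau_therapy = 0,
                      durations = c(1500, 4000, 1500), gaps = c(0, 0)),
       persistence = list(a_boost = 400, a_probe = 200),
       phase_diagram = list(axes = "a0_tau", x_min = 20, x_max = 400,
                            x_points = 10, y_min = 5, y_max = 5000,
                            y_points = 10),
       sensitivity = list(factors = c(0.5, 2), parameters = NULL, points = 9),
       out_dir = "predimm_out")
}

normalize_config <- function(raw) {
  if (inherits(raw, "run_config")) raw <- unclass(raw)
  defaults <- config_defaults()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- defaults
  for (nm in names(raw)) cfg[[nm]] <- raw[[nm]]

  if (!cfg$experiment %in% predimm_experiments())
    stop("unknown experiment '", cfg$experiment, "'; choose one of: ",
         paste(predimm_experiments(), collapse = ", "))

  # parameters: path, inline overrides, or ready-made object
  p <- cfg$params
  if (is.character(p)) {
    cfg$params <- read_immune_params(p)
  } else if (is_immune_params(p)) {
    cfg$params <- validate_immune_params(unclass(p))
  } else if (is.list(p)) {
    unknown <- setdiff(names(p), immune_param_names())
    if (length(unknown))
      stop("unknown model parameter(s) in config: ",
           paste(unknown, collapse = ", "))
    cfg$params <- do.call(immune_params, p)
  } else stop("'params' must be a file path or a mapping")

  for (q in c("qc", "qr")) {
    v <- cfg[[q]]
    if (!is.null(v) && !(is.character(v) &&
                         v %in% c("linear", "sigmoidal", "step_like")))
      stop("'", q, "' must be one of linear, sigmoidal, step_like")
  }

  if (inherits(cfg$protocol, "antigen_protocol")) {
    # already validated
  } else if (!is.character(cfg$protocol)) {
    segs <- do.call(rbind, lapply(cfg$protocol, function(s)
      data.frame(t_start = s$start, t_end = s$end, shape = s$shape,
                 a0 = if (is.null(s$a0)) 0 else s$a0,
                 tau = if (is.null(s$tau)) NA_real_ else s$tau)))
    cfg$protocol <- antigen_protocol(segs)
  } else if (!cfg$protocol %in% fixture_names()) {
    stop("'protocol' must be a fixture name (",
         paste(fixture_names(), collapse = ", "), ") or a segment list")
  }

  # section-wise merge with defaults, rejecting unknown sub-keys
  for (section in c("solver", "sweep", "therapy", "persistence",
                    "phase_diagram", "sensitivity")) {
    given <- raw[[section]]
    if (is.null(given)) next
    if (!is.list(given)) stop("'", section, "' must be a mapping")
    unknown <- setdiff(names(given), names(defaults[[section]]))
    if (length(unknown))
      stop("unknown key(s) in '", section, "': ",
           paste(unknown, collapse = ", "))
    merged <- defaults[[section]]
    for (nm in names(given)) merged[[nm]] <- given[[nm]]
    cfg[[section]] <- merged
  }
  with(cfg$solver, stopifnot(atol > 0, rtol > 0, n_out >= 2, rel_tol > 0))
  structure(cfg, class = "run_config")
}

fixture_names <- function() {
  c("naive_baseline", "high_step", "slow_ramp", "therapy_default",
    "persistence_default")
}

#' Deterministic, self-contained experiment fixtures
#'
#' Returns ready-to-run model inputs mirroring the package's canonical
#' experiments, for tests and demos:
#' * `naive_baseline` — zero antigen; the trajectory stays at the all-zero
#'   steady state.
#' * `high_step` — steady exposure at the rapid high concentration
#'   (`a0 = 200`), the harmful-classified input.
#' * `slow_ramp` — saturating input to the same plateau with a time constant
#'   above the calibrated rapidness threshold, the harmless-classified
#'   input.
#' * `therapy_default` — three-phase allergen immunotherapy schedule.
#' * `persistence_default` — the five-phase persistence protocol.
#'
#' @param name Fixture name.
#' @return A list with `params`, `protocol`, `qc`, `qr`.
#' @examples
#' fx <- generate_fixture("high_step")
#' antigen_at(fx$protocol, 10)
#' @export
generate_fixture <- function(name) {
  if (!is.character(name) || length(name) != 1 || !name %in% fixture_names())
    stop("unknown fixture; available: ", paste(fixture_names(), collapse = ", "))
  params <- immune_params()
  protocol <- switch(name,
    naive_baseline = protocol_zero(2000),
    high_step = protocol_constant(200, 4000),
    slow_ramp = protocol_saturating(200, 1000, 20000),
    therapy_default = therapy_schedule(),
    persistence_default = persistence_schedule())
  list(params = params, protocol = protocol,
       qc = dose_response("linear"), qr = dose_response("linear"))
}
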