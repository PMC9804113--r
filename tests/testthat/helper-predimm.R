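# shared fixtures for the test suite (built in code, never stored)

default_p <- immune_params()
lin_q <- dose_response("linear")

# a short, cheap steady-state run under constant antigen
quick_steady <- function(a, params = default_p, qc = lin_q, qr = qc, ...) {
  prot <- if (a > 0) protocol_constant(a, 4000) else protocol_zero(4000)
  simulate_to_steady(params, prot, qc, qr, ...)
}

# random but admissible parameter sets: defaults jittered by moderate
# multipliers, keeping the proliferation < death and overestimation
# constraints intact
random_params <- function() {
  jitter1 <- function(x) x * stats::runif(1, 0.7, 1.4)
  immune_params(
    dc = 1, dr = 1,                  # keep D < d by jittering D only
    Dc = stats::runif(1, 0.2, 0.8), Dr = stats::runif(1, 0.2, 0.8),
    sc = jitter1(0.01), sr = jitter1(0.01),
    kc = jitter1(1e-4), kr = jitter1(1e-4),
    wc = jitter1(0.05), wr = jitter1(0.05),
    Tnaive = jitter1(100),
    ec = jitter1(1e-4), er = jitter1(3.5e-4),
    mc = 1, mr = jitter1(0.1),
    Amax = 200, K = stats::runif(1, 50, 150),
    r0 = jitter1(0.1), ra = jitter1(1), rs = jitter1(1))
}

random_protocol <- function() {
  segs <- sample(1:3, 1)
  parts <- lapply(seq_len(segs), function(i) {
    shape <- sample(c("constant", "saturating", "zero"), 1)
    d <- stats::runif(1, 50, 300)
    switch(shape,
           constant = protocol_constant(stats::runif(1, 0, 300), d),
           saturating = protocol_saturating(stats::runif(1, 0, 300),
                                            stats::runif(1, 10, 500), d),
           zero = protocol_zero(d))
  })
  do.call(c, parts)
}
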