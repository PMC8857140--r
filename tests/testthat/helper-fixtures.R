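# Shared fixtures: parameter sets and cheap simulation caches.  Expensive
# runs used by several tests are computed once per session.

p_default <- biofilm_params()

# memoized runs
.cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# uniform single-node state (well-mixed ODE limit)
state_0d <- function(p = p_default, init = list()) {
  make_state1d(0.004, p, init = init, dx = 0.001)
}

# synthetic cosine trace with known minima (amplitude comfortably above the
# detector's debounce threshold)
cosine_trace <- function(period = 4, t_end = 12, dt = 0.01, width_mm = 0.3,
                         amp = 10) {
  t <- seq(0, t_end, by = dt)
  structure(data.frame(time_h = t, width_mm = width_mm,
                       mean_V_mV = amp * cos(2 * pi * t / period),
                       mean_K_mM = -amp * cos(2 * pi * t / period)),
            class = c("oscillation_trace", "data.frame"))
}
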