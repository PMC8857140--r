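# Oscillation analysis: onset detection, onset-size experiment,
# period-versus-size curves, oscillation magnitude, and finite-difference
# parameter sensitivity of the potassium oscillation magnitude.

#' Detect oscillation onsets in a trace
#'
#' An onset is the moment the spatial-mean voltage stops decreasing and
#' begins to increase: a local minimum of `mean_V_mV`.  To be robust to
#' solver-scale jitter, a candidate minimum counts only if the mean voltage
#' decreases by at least `eps_V` over the preceding `guard_h` hours and
#' increases by at least `eps_V` over the following `guard_h` hours.
#' Events occurring before the biofilm's doubled width reaches
#' `min_doubled_width_um` are flagged unsustained and excluded from
#' onset-size statistics.
#'
#' @param trace an `oscillation_trace` (or data.frame with `time_h`,
#'   `mean_V_mV` and `width_mm` or `area_mm2` columns).
#' @param min_doubled_width_um sustained-event size threshold (µm).
#' @param eps_V debounce amplitude (mV).
#' @param guard_h debounce window half-width (hours).
#' @return data.frame of class `onset_events` with columns `time_h`,
#'   `width_um`, `doubled_width_um`, `mean_V_mV`, `sustained`.
#' @export
detect_onsets <- function(trace, min_doubled_width_um = 300, eps_V = 0.5,
                          guard_h = 0.5) {
  if (nrow(trace) < 3) stop("trace too short for onset detection", call. = FALSE)
  t <- trace$time_h
  if (any(diff(t) <= 0)) stop("trace time must be strictly increasing", call. = FALSE)
  v <- trace$mean_V_mV
  n <- length(v)
  # strict-minimum scan with plateau tolerance: first index of any run of
  # equal values that is lower than both flanking values
  cand <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    j <- i
    while (j < n && v[j + 1L] == v[i]) j <- j + 1L
    if (j <= n - 1L && v[i - 1L] > v[i] && v[j + 1L] > v[i])
      cand <- c(cand, i)
    i <- j + 1L
  }
  keep <- vapply(cand, function(i) {
    pre <- v[t >= t[i] - guard_h & t < t[i]]
    post <- v[t > t[i] & t <= t[i] + guard_h]
    length(pre) > 0 && length(post) > 0 &&
      (max(pre) - v[i] >= eps_V) && (max(post) - v[i] >= eps_V)
  }, logical(1))
  cand <- cand[keep]
  width_mm <- if ("width_mm" %in% names(trace)) trace$width_mm
              else sqrt(trace$area_mm2 / pi)  # effective radius for 2D traces
  ev <- data.frame(time_h = t[cand],
                   width_um = width_mm[cand] * 1000,
                   doubled_width_um = width_mm[cand] * 2000,
                   mean_V_mV = v[cand])
  ev$sustained <- ev$doubled_width_um >= min_doubled_width_um
  class(ev) <- c("onset_events", "data.frame")
  ev
}

#' Oscillation magnitude of a series
#'
#' Difference between the highest and lowest values of a series over a
#' window — the proxy used for the strength of the potassium oscillations.
#'
#' @param x numeric series (typically spatial-mean extracellular potassium).
#' @param window optional `c(t_min, t_max)` restricting by `time`; requires
#'   `time`.
#' @param time optional time vector matching `x`.
#' @return max minus min (same units as `x`).
#' @export
oscillation_magnitude <- function(x, window = NULL, time = NULL) {
  if (!is.null(window)) {
    if (is.null(time)) stop("'window' requires 'time'", call. = FALSE)
    x <- x[time >= window[1] & time <= window[2]]
  }
  if (!length(x)) stop("empty window for oscillation magnitude", call. = FALSE)
  max(x) - min(x)
}

#' Period of oscillation by biofilm size
#'
#' Periods between consecutive sustained onsets, each attributed to the
#' biofilm size at the later onset (the 1D width, in µm, matching how the
#' period-size relationship is reported).
#'
#' @param events an `onset_events` data.frame (see [detect_onsets()]).
#' @return data.frame with columns `size_um`, `doubled_size_um`, `period_h`
#'   (zero rows, with a warning, when fewer than two sustained events exist).
#' @export
period_by_size <- function(events) {
  ev <- events[events$sustained, , drop = FALSE]
  if (nrow(ev) < 2) {
    warning("fewer than two sustained onsets; no periods computed")
    return(data.frame(size_um = numeric(0), doubled_size_um = numeric(0),
                      period_h = numeric(0)))
  }
  data.frame(size_um = ev$width_um[-1],
             doubled_size_um = ev$doubled_width_um[-1],
             period_h = diff(ev$time_h))
}

#' Onset-size experiment
#'
#' Replicated 1D simulations from jittered initial widths: base width
#' 70 µm plus a uniform random offset on ±25 µm, inlet glutamate `G0`.
#' Each replicate runs until its first sustained onset (the first
#' mean-voltage minimum at doubled width of at least 300 µm) or until
#' `t_end_h`; replicates with no sustained onset by then are reported as
#' censored, and the mean onset size is taken over uncensored replicates.
#'
#' @param p parameter set.
#' @param n_reps number of replicates.
#' @param base_width_um,jitter_um initial width and uniform jitter (µm).
#' @param G0 inlet glutamate (mM); overrides `p$G0`.
#' @param seed integer seed driving the width jitter (the model itself is
#'   deterministic).
#' @param t_end_h per-replicate time budget (hours).
#' @param dx,dt_max grid and step controls passed to [run_1d()].
#' @return list of class `onset_experiment` with `replicates` (data.frame:
#'   `rep`, `init_width_um`, `onset_time_h`, `onset_doubled_width_um`,
#'   `censored`), `mean_doubled_width_um`, `n_censored`, `seed`.
#' @export
onset_experiment <- function(p = biofilm_params(), n_reps = 53,
                             base_width_um = 70, jitter_um = 25, G0 = NULL,
                             seed = 1, t_end_h = 60, dx = 0.002,
                             dt_max = 0.01) {
  stopifnot(n_reps >= 1)
  if (!is.null(G0)) p$G0 <- G0
  set.seed(seed)
  widths_um <- base_width_um + runif(n_reps, -jitter_um, jitter_um)
  res <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    stopper <- function(tr) {
      ev <- detect_onsets(tr)
      any(ev$sustained & ev$time_h <= tr$time_h[nrow(tr)] - 0.6)
    }
    check <- local({
      count <- 0L
      function(tr) {
        count <<- count + 1L
        if (count %% 20L != 0L) return(FALSE)   # check every 20 output steps
        nrow(tr) > 30 && stopper(tr)
      }
    })
    tr <- run_1d(widths_um[r] / 1000, p, t_end_h = t_end_h, dx = dx,
                 dt_max = dt_max, stop_when = check)
    ev <- detect_onsets(tr)
    sus <- ev[ev$sustained, , drop = FALSE]
    if (nrow(sus)) {
      res[[r]] <- data.frame(rep = r, init_width_um = widths_um[r],
                             onset_time_h = sus$time_h[1],
                             onset_doubled_width_um = sus$doubled_width_um[1],
                             censored = FALSE)
    } else {
      res[[r]] <- data.frame(rep = r, init_width_um = widths_um[r],
                             onset_time_h = NA_real_,
                             onset_doubled_width_um = NA_real_,
                             censored = TRUE)
    }
  }
  reps <- do.call(rbind, res)
  structure(list(replicates = reps,
                 mean_doubled_width_um = mean(reps$onset_doubled_width_um[!reps$censored]),
                 n_censored = sum(reps$censored),
                 seed = seed),
            class = "onset_experiment")
}

#' @export
print.onset_experiment <- function(x, ...) {
  cat("onset-size experiment:", nrow(x$replicates), "replicates,",
      x$n_censored, "censored\n")
  cat(sprintf("mean doubled width at first sustained onset: %.1f um\n",
              x$mean_doubled_width_um))
  invisible(x)
}

#' Finite-difference parameter sensitivity of the oscillation magnitude
#'
#' The oscillation magnitude `O` is the max-minus-min of the spatial-mean
#' extracellular potassium over a 20-hour run started at width 300 µm.  The
#' sensitivity to a parameter `p` is the forward finite difference
#' `(O(p + h) - O(p)) / h` with `h = 0.001` in the parameter's own
#' (published-table) units, reported together with the percent change of
#' `O` for a 10% parameter change: `dO/dp * 0.1 * |p| / O * 100`.
#'
#' Runs use a fixed sub-step count for the reaction integrator so that the
#' discrete map from parameter to solution is smooth; an adaptive step
#' sequence would inject step-selection noise comparable to `h` into the
#' difference.
#'
#' @param p parameter set (internal units) used as baseline.
#' @param parameter_name one of [sensitivity_parameters()].
#' @param h finite-difference step, in the parameter's paper units.
#' @param start_width_um initial biofilm width (µm).
#' @param horizon_h run length (hours).
#' @param baseline_O optional memoized baseline magnitude (mM), as returned
#'   in a previous result's `baseline_O`; computed when `NULL`.
#' @param dx,dt_max,n_fixed numerical controls of the underlying runs.
#' @return list of class `sensitivity_result`: `parameter`, `baseline_O`,
#'   `dO_dp`, `percent_per_10pct` (NA with a warning when `O` is 0).
#' @export
sensitivity <- function(p = biofilm_params(), parameter_name, h = 0.001,
                        start_width_um = 300, horizon_h = 20,
                        baseline_O = NULL, dx = 0.002, dt_max = 0.01,
                        n_fixed = 5L) {
  if (!parameter_name %in% sensitivity_parameters())
    stop("'", parameter_name, "' is not a sensitivity-reported parameter",
         call. = FALSE)
  magn <- function(pp) {
    tr <- run_1d(start_width_um / 1000, pp, t_end_h = horizon_h, dx = dx,
                 dt_max = dt_max, ctrl = list(n_fixed = n_fixed))
    oscillation_magnitude(tr$mean_K_mM)
  }
  if (is.null(baseline_O)) baseline_O <- magn(p)
  p_paper <- denormalize_units(p)
  val <- p_paper[[parameter_name]]
  p_paper[[parameter_name]] <- val + h
  p_pert <- normalize_units(p_paper)
  O2 <- magn(p_pert)
  dO_dp <- (O2 - baseline_O) / h
  percent <- if (baseline_O > 0) dO_dp * 0.1 * abs(val) / baseline_O * 100
             else { warning("baseline magnitude is zero; percent undefined"); NA_real_ }
  structure(list(parameter = parameter_name, baseline_O = baseline_O,
                 dO_dp = dO_dp, percent_per_10pct = percent),
            class = "sensitivity_result")
}

#' Sensitivity table over all reported parameters
#'
#' Runs [sensitivity()] for every reported parameter with a single shared
#' baseline run.
#'
#' @inheritParams sensitivity
#' @param parameters parameter names (default: all 30 reported ones).
#' @return data.frame with columns `parameter`, `dO_dp`,
#'   `percent_per_10pct`; attribute `baseline_O`.
#' @export
sensitivity_table <- function(p = biofilm_params(),
                              parameters = sensitivity_parameters(),
                              h = 0.001, start_width_um = 300,
                              horizon_h = 20, dx = 0.002, dt_max = 0.01,
                              n_fixed = 5L) {
  base <- sensitivity(p, parameters[1], h, start_width_um, horizon_h,
                      baseline_O = NULL, dx = dx, dt_max = dt_max,
                      n_fixed = n_fixed)
  out <- list(data.frame(parameter = parameters[1], dO_dp = base$dO_dp,
                         percent_per_10pct = base$percent_per_10pct))
  for (nm in parameters[-1]) {
    s <- sensitivity(p, nm, h, start_width_um, horizon_h,
                     baseline_O = base$baseline_O, dx = dx, dt_max = dt_max,
                     n_fixed = n_fixed)
    out[[nm]] <- data.frame(parameter = nm, dO_dp = s$dO_dp,
                            percent_per_10pct = s$percent_per_10pct)
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  attr(tab, "baseline_O") <- base$baseline_O
  tab
}
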