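test_that("onset detection recovers the minima of a synthetic oscillation", {
  tr <- cosine_trace(period = 4, t_end = 12, dt = 0.01)
  ev <- detect_onsets(tr, eps_V = 0.5)
  expect_equal(nrow(ev), 3)
  expect_equal(ev$time_h, c(2, 6, 10), tolerance = 0.011)
  expect_true(all(ev$sustained))          # width 0.3 mm -> doubled 600 um
  expect_equal(ev$doubled_width_um, rep(600, 3))
})

test_that("onset detection agrees with a brute-force local-minimum scan", {
  set.seed(42)
  for (rep in 1:5) {
    t <- seq(0, 30, by = 0.05)
    v <- -156 + 30 * sin(2 * pi * t / runif(1, 3, 9)) + cumsum(rnorm(length(t), 0, 0.02))
    tr <- structure(data.frame(time_h = t, width_mm = 0.3, mean_V_mV = v),
                    class = c("oscillation_trace", "data.frame"))
    ev <- detect_onsets(tr, eps_V = 0.5)
    # oracle: O(N) scan with the identical debounce definition
    brute <- c()
    for (i in 2:(length(v) - 1)) {
      if (v[i - 1] > v[i] && v[i + 1] > v[i]) {
        pre <- v[t >= t[i] - 0.5 & t < t[i]]
        post <- v[t > t[i] & t <= t[i] + 0.5]
        if (length(pre) && length(post) &&
            max(pre) - v[i] >= 0.5 && max(post) - v[i] >= 0.5)
          brute <- c(brute, t[i])
      }
    }
    expect_equal(ev$time_h, brute)
  }
})

test_that("monotone traces yield no onsets and short traces error", {
  t <- seq(0, 5, by = 0.05)
  tr <- structure(data.frame(time_h = t, width_mm = 0.2, mean_V_mV = -156 - t),
                  class = c("oscillation_trace", "data.frame"))
  expect_equal(nrow(detect_onsets(tr)), 0)
  expect_error(detect_onsets(tr[1:2, ]), "short")
})

test_that("events below the doubled-width threshold are unsustained", {
  tr <- cosine_trace(period = 4, t_end = 6, dt = 0.01, width_mm = 0.1)
  ev <- detect_onsets(tr)                 # doubled width 200 um < 300 um
  expect_true(nrow(ev) >= 1)
  expect_false(any(ev$sustained))
})

test_that("oscillation magnitude is max minus min over the window", {
  expect_equal(oscillation_magnitude(c(3, 3, 3)), 0)
  expect_equal(oscillation_magnitude(c(1, 3, 2, 0.5)), 2.5)
  x <- c(0, 10, 2, 8)
  expect_equal(oscillation_magnitude(x, window = c(2, 4), time = 1:4), 8)
  expect_error(oscillation_magnitude(x, window = c(9, 10), time = 1:4), "empty")
})

test_that("periods attach to the size at the later onset", {
  ev <- structure(data.frame(time_h = c(2, 6, 10),
                             width_um = c(100, 150, 210),
                             doubled_width_um = c(200, 300, 420),
                             mean_V_mV = -200, sustained = TRUE),
                  class = c("onset_events", "data.frame"))
  pb <- period_by_size(ev)
  expect_equal(pb$period_h, c(4, 4))
  expect_equal(pb$size_um, c(150, 210))
  ev1 <- ev[1, ]
  expect_warning(pb1 <- period_by_size(ev1), "fewer")
  expect_equal(nrow(pb1), 0)
})

test_that("the onset experiment is reproducible and respects its seed", {
  # degenerate jitter: all replicates identical
  ex0 <- onset_experiment(p_default, n_reps = 2, jitter_um = 0, seed = 7,
                          t_end_h = 1)
  expect_equal(ex0$replicates$init_width_um[1], ex0$replicates$init_width_um[2])
  # same seed twice: bit-identical
  ex1 <- onset_experiment(p_default, n_reps = 2, seed = 3, t_end_h = 1)
  ex2 <- onset_experiment(p_default, n_reps = 2, seed = 3, t_end_h = 1)
  expect_identical(ex1$replicates, ex2$replicates)
  # short horizon: no oscillation -> censored, not dropped
  expect_equal(ex1$n_censored, 2)
  expect_equal(nrow(ex1$replicates), 2)
  ex3 <- onset_experiment(p_default, n_reps = 2, seed = 4, t_end_h = 1)
  expect_false(identical(ex1$replicates$init_width_um,
                         ex3$replicates$init_width_um))
})

test_that("sensitivity uses one baseline and excludes reporter constants", {
  expect_error(sensitivity(p_default, "alpha_T"), "not a sensitivity")
  s1 <- cached("sens_quick",
               sensitivity(p_default, "G_u", start_width_um = 150,
                           horizon_h = 2))
  s2 <- sensitivity(p_default, "G_u", start_width_um = 150, horizon_h = 2,
                    baseline_O = s1$baseline_O)
  expect_identical(s1$percent_per_10pct, s2$percent_per_10pct)
  # percent formula: dO/dp * 0.1 |p| / O * 100 in the parameter's own units
  expect_equal(s1$percent_per_10pct,
               s1$dO_dp * 0.1 * 18 / s1$baseline_O * 100)
})
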