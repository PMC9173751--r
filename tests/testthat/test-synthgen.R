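test_that("cohort generation is deterministic and class-faithful", {
  cfg <- cohort_config(n_per_class = c(AbRA = 3, DH = 2, C = 4), seed = 5)
  c1 <- make_cohort(cfg)
  c2 <- make_cohort(cfg)
  expect_identical(c1, c2)
  c3 <- make_cohort(cohort_config(n_per_class = c(AbRA = 3, DH = 2, C = 4),
                                  seed = 6))
  expect_false(identical(c1, c3))
  # C-fibers slower than 1 m/s, Adelta in [1, 10], Abeta above 10
  expect_true(all(c1$cv[c1$class_label == "C"] < 1))
  expect_true(all(c1$cv[c1$class_label == "DH"] >= 1 &
                    c1$cv[c1$class_label == "DH"] <= 10))
  expect_true(all(c1$cv[c1$class_label == "AbRA"] > 10))
  only_c <- make_cohort(cohort_config(n_per_class = c(C = 10), seed = 2))
  expect_true(all(only_c$cv < 1))
  expect_warning(make_cohort(cohort_config(n_per_class = c(C = 0), seed = 1)),
                 "empty cohort")
})

test_that("knockout counterparts shift b by exactly the multiplier", {
  cfg <- cohort_config(n_per_class = c(AbRA = 6), ko_paired = TRUE,
                       ko_b_multiplier = 3, seed = 8)
  coh <- make_cohort(cfg)
  ctrl <- coh[coh$genotype == "control", ]
  ko <- coh[coh$genotype == "piezo2_ko", ]
  expect_equal(nrow(ko), nrow(ctrl))
  expect_equal(ko$b, ctrl$b * 3)
  expect_equal(ko$a, ctrl$a)
  expect_equal(ko$c, ctrl$c)
})

test_that("rendered waveforms expose exactly the template features", {
  for (grp in c("A", "C")) {
    wf <- default_waveform(grp)
    for (rate in c(20000, 40000)) {
      w <- render_waveform(wf, rate)
      step_uv <- 1  # amplitude tolerance: one quantization step of the grid
      expect_equal(max(w), wf$pos_amp, tolerance = step_uv / wf$pos_amp)
      expect_equal(min(w), -wf$neg_amp, tolerance = 2 * step_uv / wf$neg_amp)
      # exactly one substantive positive and one negative extremum
      v <- as.numeric(w)
      mid <- v[-c(1, length(v))]
      is_max <- mid >= v[-c(length(v) - 1, length(v))] &
        mid > v[-c(1, 2)]
      is_min <- mid <= v[-c(length(v) - 1, length(v))] &
        mid < v[-c(1, 2)]
      expect_equal(sum(is_max & mid > 0.05 * wf$pos_amp), 1)
      expect_equal(sum(is_min & mid < -0.05 * wf$neg_amp), 1)
      f <- extract_features(as.numeric(w), rate)
      ms_per_sample <- 1000 / rate
      expect_equal(f$pos_rise_time, wf$rise_ms, tolerance = ms_per_sample / wf$rise_ms)
      expect_equal(f$spike_width, wf$width_ms, tolerance = ms_per_sample / wf$width_ms)
      expect_equal(f$neg_decay_time, wf$decay_ms, tolerance = ms_per_sample / wf$decay_ms)
    }
  }
})

test_that("waveform rendering is linear in amplitude and resolves rates", {
  wf <- default_waveform("A")
  w1 <- render_waveform(wf, 40000)
  wf2 <- wf; wf2$pos_amp <- wf$pos_amp * 2; wf2$neg_amp <- wf$neg_amp * 2
  w2 <- render_waveform(wf2, 40000)
  expect_equal(as.numeric(w2), 2 * as.numeric(w1))
  f1 <- extract_features(as.numeric(w1), 40000)
  f2 <- extract_features(as.numeric(w2), 40000)
  expect_equal(f1$pos_rise_time, f2$pos_rise_time)
  expect_equal(f1$spike_width, f2$spike_width)
  # 20 vs 40 kHz feature agreement within one (coarser) sample period
  f20 <- extract_features(as.numeric(render_waveform(wf, 20000)), 20000)
  f40 <- extract_features(as.numeric(render_waveform(wf, 40000)), 40000)
  for (feat in c("pos_rise_time", "spike_width", "neg_decay_time"))
    expect_lt(abs(f20[[feat]] - f40[[feat]]), 1000 / 20000)
  expect_error(render_waveform(wf, 2000), "too low")
})

test_that("sweep simulation follows the ground-truth response law", {
  fb <- fiber_truth("f1", "AbRA", cv = 15, a = 1, b = 1e4, c = 3,
                    jitter_sd = 0.02)
  inst <- fus_instrument()
  # two decades above b with a steep slope: y(E) ~ 1, spike on every sweep
  ev_hi <- fus_events(0.01, "fus", "t", "f1", intensity = 743, duration = 2,
                      validate = FALSE)
  set.seed(3)
  spikes_hi <- sum(vapply(1:25, function(i)
    !is.na(attr(simulate_sweep(fb, ev_hi, inst), "truth_spike_time")),
    logical(1)))
  expect_equal(spikes_hi, 25)
  # non-responsive fiber never spikes
  fb_off <- fb; fb_off$responsive <- FALSE
  spikes_off <- sum(vapply(1:25, function(i)
    !is.na(attr(simulate_sweep(fb_off, ev_hi, inst), "truth_spike_time")),
    logical(1)))
  expect_equal(spikes_off, 0)
  # at E = b with a = 1, spike fraction ~ Binomial(n, 0.5)
  dur_at_b <- 1e4 * 1e-9 / (155 * pi * inst$focal_radius_cm^2) * 1000
  ev_b <- fus_events(0.01, "fus", "t", "f1", intensity = 155,
                     duration = dur_at_b, validate = FALSE)
  e_nJ <- 1e9 * sonication_energy(155, dur_at_b, inst$focal_radius_cm)
  expect_equal(e_nJ, 1e4, tolerance = 1e-9)
  set.seed(4)
  n <- 1000
  frac <- mean(vapply(seq_len(n), function(i)
    !is.na(attr(simulate_sweep(fb, ev_b, inst), "truth_spike_time")),
    logical(1)))
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n))
})

test_that("electrical spike latency equals conduction delay plus jitter", {
  fb <- fiber_truth("f1", "AbRA", cv = 20, conduction_distance = 20,
                    jitter_sd = 0.05)
  ev <- fus_events(0.01, "electrical", "t", "f1", magnitude = 1,
                   validate = FALSE)
  set.seed(6)
  n <- 200
  lat <- vapply(seq_len(n), function(i) {
    tr <- simulate_sweep(fb, ev, fus_instrument())
    (attr(tr, "truth_spike_time") - ev$onset) * 1000
  }, numeric(1))
  expect_lt(abs(mean(lat) - 20 / 20), 3 * fb$jitter_sd / sqrt(n))
})

test_that("session simulation produces the protocol's event counts deterministically", {
  cfg <- cohort_config(n_per_class = c(AbRA = 1), seed = 12)
  coh <- make_cohort(cfg)
  proto <- parameter_grid(155, c(0.1, 0.25, 0.5, 1, 1.5, 2), n_repeats = 5)
  ses <- simulate_session(coh, proto, cfg, n_electrical = 0)
  expect_equal(sum(ses$events$modality == "fus"), 30)  # 6 durations x 5
  ses2 <- simulate_session(coh, proto, cfg, n_electrical = 0)
  expect_identical(as.data.frame(ses2$events), as.data.frame(ses$events))
  # consecutive same-fiber events separated by the ISI
  expect_true(all(abs(diff(ses$events$onset) - ses$instrument$isi_s) < 1e-9))
})

test_that("nerve-trunk thresholds exceed receptive-field thresholds in truth", {
  cfg <- cohort_config(n_per_class = c(AbRA = 5), seed = 13,
                       nt_b_multiplier_control = 4)
  coh <- make_cohort(cfg)
  energies <- 10^seq(4, 6.3, length.out = 20)
  for (i in seq_len(nrow(coh))) {
    thr_rf <- threshold_scan(energies, rep(1, 20),
                             truth_spike_prob(coh[i, ], energies, "RF") > 0.5)
    thr_nt <- threshold_scan(energies, rep(1, 20),
                             truth_spike_prob(coh[i, ], energies, "NT") > 0.5)
    expect_gt(thr_nt, thr_rf)
  }
})
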