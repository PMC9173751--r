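test_that("detection finds an injected spike and nothing in short traces", {
  set.seed(31)
  rate <- 20000
  smp <- rnorm(rate, 0, 5)  # 1 s of 5 uV noise
  true_peak <- 0.5
  smp <- fusafferent:::add_waveform_at(smp, rate, 0, true_peak,
                                       default_waveform("A"))
  tr <- fus_trace(smp, rate, 0, id = "t")
  cand <- detect_candidates(tr, k = 5, fiber_group = "A")
  expect_equal(nrow(cand$windows), 1)
  expect_lt(abs(cand$peak_times - true_peak), 1.5 / rate)
  # trace shorter than a window
  short <- fus_trace(rnorm(10, 0, 5), rate, 0, id = "s")
  expect_equal(nrow(detect_candidates(short, fiber_group = "A")$windows), 0)
})

test_that("false-positive rate on pure noise is near the Gaussian-tail bound", {
  # at k = 5 robust SDs, supra-threshold local maxima are rare: a few per
  # megasample at most
  set.seed(32)
  fp <- vapply(1:3, function(i) {
    tr <- fus_trace(rnorm(200000, 0, 5), 20000, 0, id = "n")  # 10 s
    nrow(detect_candidates(tr, k = 5, fiber_group = "A")$windows)
  }, numeric(1))
  expect_lt(mean(fp), 1)
})

test_that("feature extraction is scale-invariant in time and flags reversals", {
  rate <- 40000
  w <- as.numeric(render_waveform(default_waveform("A"), rate))
  f <- extract_features(w, rate)
  f2 <- extract_features(2 * w, rate)
  expect_equal(f2$pos_peak_amp, 2 * f$pos_peak_amp)
  expect_equal(f2$neg_peak_amp, 2 * f$neg_peak_amp)
  expect_equal(f2$pos_rise_time, f$pos_rise_time)
  expect_equal(f2$spike_width, f$spike_width)
  expect_equal(f2$neg_decay_time, f$neg_decay_time)
  # monophasic snippet: negative fields missing and flagged
  mono <- extract_features(pmax(w, 0), rate)
  expect_true(mono$monophasic)
  expect_true(is.na(mono$neg_peak_amp))
  # time reversal turns the fast rise into a slow one (roles swap)
  frev <- extract_features(rev(w), rate)
  expect_gt(frev$pos_rise_time, f$pos_rise_time)
})

test_that("templates average correctly and obey the CLT error bound", {
  rate <- 20000
  w <- waveform_template(default_waveform("A"), rate, "A")
  sn_id <- structure(list(windows = rbind(w, w, w), peak_times = 1:3,
                          trace_id = rep("t", 3), rate = rate,
                          noise_scale = 1, window_ms = 2),
                     class = "fus_snippets")
  expect_equal(as.numeric(build_template(sn_id)), as.numeric(w))
  # mirrored pair cancels to a degenerate template
  sn_mirror <- sn_id
  sn_mirror$windows <- rbind(w, -w)
  expect_warning(tm <- build_template(sn_mirror), "degenerate")
  # 100 noisy copies: RMS error below 1.5 x sd/sqrt(n)
  set.seed(33)
  noisy <- t(replicate(100, w + rnorm(length(w), 0, 5)))
  sn_noisy <- sn_id
  sn_noisy$windows <- noisy
  tmpl <- build_template(sn_noisy)
  rmse <- sqrt(mean((as.numeric(tmpl) - w)^2))
  expect_lt(rmse, 1.5 * 5 / sqrt(100))
  expect_error(build_template(fusafferent:::subset_snippets(sn_id,
                                                            integer(0))),
               "no snippets")
})

test_that("correlation filter accepts identity, rejects inversion and distractors", {
  rate <- 20000
  w <- waveform_template(default_waveform("A"), rate, "A")
  dwf <- default_waveform("A")
  dwf$rise_ms <- dwf$rise_ms * 1.3
  dwf$width_ms <- dwf$width_ms * 1.3
  dwf$decay_ms <- dwf$decay_ms * 1.3
  d <- waveform_template(dwf, rate, "A")
  sn <- structure(list(windows = rbind(w, -w, d),
                       peak_times = 1:3, trace_id = rep("t", 3),
                       rate = rate, noise_scale = 1, window_ms = 2),
                  class = "fus_snippets")
  u <- correlation_filter(sn, w, "A")
  expect_equal(u$accepted_idx, 1L)
  expect_equal(u$accepted_scores, 1.0)
  expect_true(all(u$rejected_scores < 0.97))
  expect_lt(min(u$rejected_scores), 0)  # the sign-flipped snippet
  # without the alignment search the inverted snippet is exactly -1
  expect_equal(correlation_filter(fusafferent:::subset_snippets(sn, 2), w,
                                  "A", max_shift = 0L)$rejected_scores,
               -1.0)
  # the 30%-width distractor sits clearly below the A floor
  expect_lt(max(u$rejected_scores), 0.95)
  # idempotence: filtering the accepted set again changes nothing
  u2 <- correlation_filter(u$accepted, w, "A")
  expect_equal(n_snippets <- nrow(u2$accepted$windows),
               nrow(u$accepted$windows))
  expect_equal(u2$accepted_scores, u$accepted_scores)
  # degenerate template refused
  expect_error(correlation_filter(sn, rep(1, length(w)), "A"), "degenerate")
})

test_that("Pearson correlation matches the definition to 1e-12", {
  set.seed(34)
  for (i in 1:20) {
    x <- rnorm(50); y <- rnorm(50)
    expect_equal(stats::cor(x, y), cor_bruteforce(x, y), tolerance = 1e-12)
  }
})

test_that("a non-responsive fiber yields all-zero assignments", {
  cfg <- cohort_config(n_per_class = c(AbRA = 1), seed = 35)
  coh <- make_cohort(cfg)
  coh$responsive <- FALSE
  proto <- parameter_grid(c(155, 340), 0.75, n_repeats = 5)
  ses <- simulate_session(coh, proto, cfg, n_electrical = 0)
  u <- sort_unit(ses$traces, ses$events, "A")
  expect_true(all(is.na(u$assignments$spike_time)))
})

test_that("two interleaved units are sorted into disjoint accepted sets", {
  set.seed(36)
  rate <- 20000
  wfA <- default_waveform("A")  # large fast unit (Abeta-like)
  wfD <- default_waveform("A") # smaller, slower unit (Adelta-like)
  wfD$pos_amp <- 65; wfD$neg_amp <- 30
  wfD$rise_ms <- 0.16; wfD$width_ms <- 0.24; wfD$decay_ms <- 0.32
  isi <- 0.2; n_ev <- 40; pre <- 0.01
  smp <- rnorm(n_ev * isi * rate, 0, 8)
  onsets <- (seq_len(n_ev) - 1) * isi + pre
  tA <- onsets + 0.0015
  tD <- onsets + 0.004
  for (t in tA) smp <- fusafferent:::add_waveform_at(smp, rate, 0, t, wfA)
  for (t in tD) smp <- fusafferent:::add_waveform_at(smp, rate, 0, t, wfD)
  tr <- fus_trace(smp, rate, 0, id = "t1")
  ev <- fus_events(onsets, "fus", "t1", "f1", intensity = 155,
                   duration = 0.75, validate = FALSE)
  uA <- sort_unit(list(t1 = tr), ev, "A",
                  template = waveform_template(wfA, rate, "A"))
  uD <- sort_unit(list(t1 = tr), ev, "A",
                  template = waveform_template(wfD, rate, "A"))
  expect_length(intersect(round(uA$accepted$peak_times, 5),
                          round(uD$accepted$peak_times, 5)), 0)
  near <- function(x, ref) vapply(x, function(t) min(abs(t - ref)) < 3e-4,
                                  logical(1))
  expect_true(all(near(uA$accepted$peak_times, tA)))
  expect_true(all(near(uD$accepted$peak_times, tD)))
  expect_gte(length(uA$accepted_scores), 0.9 * n_ev)
  expect_gte(length(uD$accepted_scores), 5)
})

test_that("overlapping response windows are a protocol violation", {
  set.seed(37)
  tr <- fus_trace(rnorm(20000, 0, 5), 20000, 0, id = "t")
  ev <- fus_events(c(0.1, 0.12), "fus", "t", "f", intensity = 155,
                   duration = 0.75, validate = FALSE)
  expect_error(sort_unit(list(t = tr), ev, "A"), "overlapping")
})
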