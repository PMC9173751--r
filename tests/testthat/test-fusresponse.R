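test_that("sonication energy follows E = I * pi * r^2 * t", {
  expect_equal(sonication_energy(155, 0.75, 0.0165), 9.943e-5,
               tolerance = 1e-4)
  # bilinearity: doubling intensity and duration quadruples energy
  expect_equal(sonication_energy(2 * 155, 2 * 0.75, 0.0165),
               4 * sonication_energy(155, 0.75, 0.0165))
  # the radius chosen so that pi r^2 = 1.751e-6 cm^2 maps (743 W/cm^2, 1 ms)
  # to 1301 nJ
  r_eff <- sqrt(1.751e-6 / pi)
  expect_equal(1e9 * sonication_energy(743, 1.0, r_eff), 1301,
               tolerance = 1e-3)
  expect_error(sonication_energy(-1, 1, 0.0165), "positive")
  # strict monotonicity in each argument
  expect_true(all(diff(sonication_energy(c(10, 50, 100), 1, 0.0165)) > 0))
  expect_true(all(diff(sonication_energy(100, c(0.1, 0.5, 2), 0.0165)) > 0))
  expect_true(all(diff(sonication_energy(100, 1, c(0.01, 0.0165))) > 0))
})

test_that("response tables hold exact fractions and conserve counts", {
  asg <- data.frame(
    onset = seq(0, 5.5, by = 0.5), modality = "fus", trace_id = "t",
    fiber_id = "f",
    intensity = rep(c(155, 340), each = 6), duration = 0.75, site = "RF",
    trial_index = rep(1:6, 2),
    spike_time = c(0.001, NA, 1.001, NA, 2.001, NA,    # 3/6
                   rep(3.001, 5) + 0:4 * 0.5, NA),     # 5/6
    latency_ms = 1)
  tab <- response_table(asg)
  expect_equal(nrow(tab), 2)
  expect_equal(sum(tab$n_stimuli), nrow(asg))
  expect_equal(tab$probability[tab$intensity == 155], 0.5)
  expect_equal(tab$probability[tab$intensity == 340], 5 / 6)
  expect_true(all(diff(tab$energy_nJ) > 0))
  expect_error(response_table(asg[, setdiff(names(asg), "spike_time")]),
               "spike_time")
})

test_that("the logistic law fit recovers exact parameters and identities", {
  d <- c(20, 50, 100, 186, 400, 800, 1600, 3200)
  y <- dose_response_prob(d, 1.0, 186, 0.79)
  ft <- fit_dose_response(d, y)
  expect_equal(ft$a, 1.0, tolerance = 1e-6)
  expect_equal(ft$b, 186, tolerance = 1e-6)
  expect_equal(ft$c, 0.79, tolerance = 1e-6)
  expect_equal(ft$r2, 1.0, tolerance = 1e-9)
  # y at the EC50 is half the plateau, for any a
  for (a in c(0.6, 0.8, 1.0))
    expect_equal(dose_response_prob(186, a, 186, 0.79), a / 2)
  # direct evaluation one decade above the EC50
  expect_equal(dose_response_prob(1860, 1, 186, 0.79),
               1 / (1 + 10^(-0.79)), tolerance = 1e-12)
  expect_equal(dose_response_prob(1860, 1, 186, 0.79), 0.8604,
               tolerance = 1e-4)
})

test_that("fits are invariant to the dose unit up to rescaling of b", {
  set.seed(51)
  d <- 10^seq(1, 3.5, length.out = 8)
  y <- pmin(1, pmax(0, dose_response_prob(d, 0.9, 150, 0.8) +
                      rnorm(8, 0, 0.03)))
  f_nJ <- fit_dose_response(d, y)
  f_J <- fit_dose_response(d * 1e-9, y)
  expect_equal(f_J$b * 1e9, f_nJ$b, tolerance = 1e-4)
  expect_equal(f_J$a, f_nJ$a, tolerance = 1e-6)
  expect_equal(f_J$c, f_nJ$c, tolerance = 1e-4)
})

test_that("degenerate fit inputs are refused or flagged", {
  expect_error(fit_dose_response(c(10, 20, 30), c(0, 0.5, 1)), "4 distinct")
  expect_error(fit_dose_response(c(-1, 10, 20, 30), rep(0.5, 4)), "positive")
  ft0 <- fit_dose_response(c(10, 20, 40, 80), rep(0, 4))
  expect_true(ft0$insensitive)
  expect_true(is.na(ft0$a))
})

test_that("e50_prob solves y = 0.5 in closed form", {
  # equals the EC50 exactly iff the plateau is 1
  expect_equal(e50_prob(list(a = 1, b = 186, c = 0.79)), 186)
  expect_equal(e50_prob(list(a = 0.97, b = 100, c = 1)), 100 / 0.94,
               tolerance = 1e-12)
  expect_equal(e50_prob(list(a = 0.97, b = 100, c = 1)), 106.38,
               tolerance = 1e-4)
  # rightward of the EC50 whenever 0.5 < a < 1
  for (a in c(0.51, 0.75, 0.99))
    expect_gt(e50_prob(list(a = a, b = 50, c = 1.2)), 50)
  expect_true(is.na(e50_prob(list(a = 0.5, b = 50, c = 1))))
  # and y evaluated back at e50_prob is 0.5
  for (a in c(0.6, 0.85, 1)) {
    e <- e50_prob(list(a = a, b = 220, c = 0.7))
    expect_equal(dose_response_prob(e, a, 220, 0.7), 0.5, tolerance = 1e-12)
  }
})

test_that("FUS thresholds follow the strict >50% first-crossing rule", {
  tab <- data.frame(energy_nJ = c(50, 100, 200, 400), n_stimuli = 4,
                    probability = c(0, 0.25, 0.75, 1.0))
  expect_equal(fus_threshold(tab), 200)
  tab$probability <- rep(0.5, 4)
  expect_true(is.na(fus_threshold(tab)))
  tab$probability <- rep(1, 4)
  expect_equal(fus_threshold(tab), 50)
  expect_warning(out <- fus_threshold(tab[c(3, 1, 2, 4), ]), "sorting")
  expect_equal(out, 50)
})

test_that("threshold estimation equals a brute-force scan on random tables", {
  set.seed(52)
  for (i in 1:300) {
    ne <- sample(3:10, 1)
    e <- sort(10^runif(ne, 1, 4))
    n_stim <- sample(4:10, ne, replace = TRUE)
    n_spk <- vapply(n_stim, function(n) sample(0:n, 1), integer(1))
    tab <- data.frame(energy_nJ = e, n_stimuli = n_stim,
                      probability = n_spk / n_stim)
    expect_identical(fus_threshold(tab), threshold_scan(e, n_stim, n_spk))
  }
})

test_that("raising probabilities never raises the threshold", {
  set.seed(53)
  for (i in 1:50) {
    e <- sort(10^runif(6, 1, 4))
    p <- runif(6)
    tab <- data.frame(energy_nJ = e, n_stimuli = 5, probability = p)
    tab2 <- tab
    tab2$probability <- pmin(1, p + runif(6, 0, 0.5))
    t1 <- fus_threshold(tab)
    t2 <- fus_threshold(tab2)
    if (!is.na(t1)) expect_true(!is.na(t2) && t2 <= t1)
  }
})

test_that("latency pairs and their log-log regression behave analytically", {
  expect_equal(latency_ms(0, 0.0024), 2.4)
  pairs <- data.frame(fiber_id = letters[1:6],
                      fus_latency_ms = c(1, 2, 4, 8, 16, 32),
                      electrical_latency_ms = c(1, 2, 4, 8, 16, 32))
  r <- suppressWarnings(latency_regression(pairs))  # exact fit
  expect_equal(r$slope, 1, tolerance = 1e-12)
  expect_equal(r$intercept, 0, tolerance = 1e-12)
  expect_equal(r$r2, 1)
  pairs$fus_latency_ms <- 2 * pairs$electrical_latency_ms
  r2 <- suppressWarnings(latency_regression(pairs))
  expect_equal(r2$slope, 1, tolerance = 1e-12)
  expect_equal(r2$intercept, log10(2), tolerance = 1e-12)
  # delta is fus minus electrical per fiber
  asg <- data.frame(fiber_id = "f1",
                    modality = c("fus", "fus", "electrical"),
                    spike_time = c(0.0033, 0.0035, 0.0024),
                    latency_ms = c(3.3, 3.5, 2.4))
  dl <- delta_latency(asg)
  expect_equal(dl$delta_ms, 3.4 - 2.4)
})

test_that("cumulative response counts insensitive fibers in the denominator", {
  thr <- c(1, 2, 3, 4, NA)
  cr <- suppressWarnings(cumulative_response(thr, grid = 2.5))
  expect_equal(cr$fraction, 2 / 5)
  expect_equal(cr$n_responsive, 4)
  expect_error(cumulative_response(c(1, 2)), "at least 5")
  all_na <- suppressWarnings(cumulative_response(rep(NA_real_, 6),
                                                 grid = c(1, 2, 4, 8)))
  expect_true(is.null(all_na$fit) || is.na(all_na$e50_respond))
  # a clean population: E50-Respond near the median threshold
  set.seed(54)
  thr2 <- exp(rnorm(60, log(100), 0.3))
  cr2 <- cumulative_response(thr2, grid = 10^seq(1, 3, length.out = 50))
  expect_equal(log10(cr2$e50_respond), log10(median(thr2)), tolerance = 0.05)
})

test_that("non-monotonic tuning detection uses the peak-vs-last margin", {
  tab <- data.frame(energy_nJ = c(10, 20, 40), probability = c(0.2, 1.0, 0.3))
  r <- detect_nonmonotonic(tab)
  expect_true(r$nonmonotonic)
  expect_equal(r$peak_energy, 20)
  expect_false(detect_nonmonotonic(
    data.frame(energy_nJ = c(10, 20, 40),
               probability = c(0.1, 0.5, 1.0)))$nonmonotonic)
  expect_false(detect_nonmonotonic(
    data.frame(energy_nJ = c(10, 20, 40),
               probability = c(1, 1, 1)))$nonmonotonic)
  # a declining profile whose peak is the first point is not band-pass
  expect_false(detect_nonmonotonic(
    data.frame(energy_nJ = c(10, 20, 40),
               probability = c(1, 0.4, 0.2)))$nonmonotonic)
})

test_that("beam FWHM matches analytic profiles", {
  x <- seq(-1, 1, by = 0.005)
  gauss <- exp(-x^2 / (2 * 0.14^2))
  expect_equal(beam_fwhm(x, gauss), 2 * sqrt(2 * log(2)) * 0.14,
               tolerance = 1e-3)
  # rectangular profile of width w has FWHM w
  rect <- as.numeric(abs(x) <= 0.25)
  expect_equal(beam_fwhm(x, rect), 0.5, tolerance = 0.02)
  # triangle of base 2 mm crosses half maximum at +/- 0.5 mm
  tri <- pmax(0, 1 - abs(x))
  expect_equal(beam_fwhm(x, tri), 1, tolerance = 1e-6)
  expect_error(beam_fwhm(x[x <= 0.05], exp(-x[x <= 0.05]^2 / 0.01)),
               "half maximum")
})

test_that("surface aggregation drops singleton sets, averages, interpolates", {
  tabs <- list(
    f1 = data.frame(intensity = c(45, 155, 340, 45, 340),
                    duration = c(0.75, 0.75, 0.75, 0.25, 0.25),
                    probability = c(0.5, 0.6, 1, 0, 0.8)),
    f2 = data.frame(intensity = c(45, 155, 340, 45, 155),
                    duration = c(0.75, 0.75, 0.75, 0.25, 0.25),
                    probability = c(1.0, 0.8, 0.8, 0.2, 0.4)))
  sg <- aggregate_surface(tabs)
  # the singleton sets (340, 0.25) and (155, 0.25) are excluded
  expect_equal(nrow(sg$sampled), 4)
  expect_equal(
    sg$sampled$probability[sg$sampled$intensity == 45 &
                             sg$sampled$duration == 0.75], 0.75)
  expect_equal(
    sg$sampled$probability[sg$sampled$intensity == 45 &
                             sg$sampled$duration == 0.25], 0.1)
  expect_true(sg$interpolated)
  expect_true(all(sg$probability >= 0 & sg$probability <= 1, na.rm = TRUE))
})

test_that("scattered linear interpolation is exact on a single triangle", {
  # one triangle with vertex values 0, 1, 0: the midpoint of the 0-1 edge
  # must interpolate to exactly 0.5, and nodes reproduce themselves
  x <- c(0, 1, 0); y <- c(0, 0, 1); z <- c(0, 1, 0)
  g <- fusafferent:::interp_linear_scattered(x, y, z, c(0, 0.5, 1),
                                             c(0, 0.5, 1))
  expect_equal(g[1, 1], 0)     # node (0,0)
  expect_equal(g[2, 1], 0.5)   # midpoint of the (0,0)-(1,0) edge
  expect_equal(g[3, 1], 1)     # node (1,0)
  expect_equal(g[1, 3], 0)     # node (0,1)
  expect_equal(g[2, 2], 0.5)   # midpoint of the (1,0)-(0,1) hypotenuse
  expect_true(is.na(g[3, 3]))  # (1,1) lies outside the hull
})

test_that("interpolated surfaces conserve nodes and never exceed the max", {
  set.seed(55)
  for (rep in 1:5) {
    n <- 12
    dur <- runif(n, 0.1, 2)
    int <- runif(n, 45, 743)
    p <- runif(n)
    zhat <- fusafferent:::interp_linear_scattered(dur, int, p, dur, int)
    # node i reproduces p[i] at grid position (i, i)
    expect_equal(diag(zhat), p, tolerance = 1e-9)
    grid <- fusafferent:::interp_linear_scattered(
      dur, int, p, seq(0.1, 2, length.out = 21),
      seq(45, 743, length.out = 21))
    expect_lte(max(grid, na.rm = TRUE), max(p) + 1e-9)
    expect_gte(min(grid, na.rm = TRUE), min(p) - 1e-9)
  }
})
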