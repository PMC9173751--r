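# Conduction-velocity bands used for simulation draws, matching the
# classification rules: Abeta > 10 m/s, Adelta (DH/AM) in [1, 10], C < 1.
CLASS_CV_RANGES <- list(
  AbRA = c(10.5, 25), AbSA = c(10.5, 25),
  DH = c(1, 10), AM = c(1, 10), C = c(0.25, 0.95)
)

# sqrt(2 ln 10): 10%-to-peak time of a Gaussian flank, in units of sigma.
K10 <- sqrt(2 * log(10))
# sqrt(2 ln 2): half-width at half maximum of a Gaussian flank.
KHALF <- sqrt(2 * log(2))
# Lobe separation in units of the shared inter-lobe sigma; exp(-5.7^2/2) ~ 9e-8
# so the lobes do not measurably contaminate each other's feature points.
LOBE_SEP <- 5.7

#' Default biphasic waveform template for a fiber group
#'
#' Templates are parameterized directly by the five waveform features used in
#' sorting: positive and negative peak amplitude (uV), positive-peak rise time
#' (10% to peak, ms), spike width (positive-lobe FWHM, ms) and negative-peak
#' decay time (peak to 10%, ms). A-fiber spikes are fast and large; C-fiber
#' spikes slower and smaller.
#'
#' @param group `"A"` or `"C"`.
#' @return Named list of the five template parameters.
#' @export
default_waveform <- function(group = c("A", "C")) {
  group <- match.arg(group)
  if (group == "A")
    list(pos_amp = 80, neg_amp = 40, rise_ms = 0.10, width_ms = 0.15,
         decay_ms = 0.20)
  else
    list(pos_amp = 60, neg_amp = 30, rise_ms = 0.25, width_ms = 0.40,
         decay_ms = 0.50)
}

#' Is an afferent class in the A-fiber group?
#' @param class_label Afferent class label(s).
#' @return Logical; C-fibers are FALSE, everything else TRUE.
#' @export
is_a_fiber <- function(class_label) class_label != "C"

waveform_sigmas <- function(wf) {
  sr <- wf$rise_ms / K10
  sf <- wf$width_ms / (2 * KHALF) * 2 - sr   # FWHM = KHALF * (sr + sf)
  if (sf <= 0)
    stop("spike width ", wf$width_ms, " ms too narrow for rise time ",
         wf$rise_ms, " ms (width must exceed ",
         signif(KHALF * wf$rise_ms / K10, 3), " ms)")
  sn <- wf$decay_ms / K10
  list(sr = sr, sf = sf, sn = sn, sep = LOBE_SEP * sf)
}

continuous_waveform <- function(wf) {
  s <- waveform_sigmas(wf)
  lobe <- function(t, sl, srr) ifelse(t < 0, exp(-t^2 / (2 * sl^2)),
                                      exp(-t^2 / (2 * srr^2)))
  function(t_ms) wf$pos_amp * lobe(t_ms, s$sr, s$sf) -
    wf$neg_amp * lobe(t_ms - s$sep, s$sf, s$sn)
}

#' Render a biphasic spike waveform at a sampling rate
#'
#' The continuous template is the difference of two asymmetric Gaussian lobes
#' whose flank time constants are set directly by the five feature
#' parameters, so feature extraction is exactly invertible in the noise-free
#' case. The grid is aligned so the positive peak falls on a sample.
#'
#' @param waveform Template parameters (see [default_waveform()]).
#' @param rate Sampling rate, Hz.
#' @return Numeric vector of samples (uV) with attributes `peak_index`
#'   (1-based index of the positive peak) and `rate`.
#' @export
render_waveform <- function(waveform, rate) {
  if (rate <= 0) stop("rate must be positive")
  s <- waveform_sigmas(waveform)
  pre_ms <- 3.2 * s$sr
  post_ms <- s$sep + 3.2 * s$sn
  n_span <- (pre_ms + post_ms) * rate / 1000
  if (n_span < 8)
    stop("sampling rate ", rate, " Hz too low to resolve the waveform (",
         round(n_span, 1), " samples across it; need >= 8)")
  pre <- ceiling(pre_ms * rate / 1000)
  post <- ceiling(post_ms * rate / 1000)
  t_ms <- (seq(-pre, post) / rate) * 1000
  w <- continuous_waveform(waveform)(t_ms)
  structure(w, peak_index = pre + 1L, rate = rate)
}

#' Ground truth for one simulated fiber
#'
#' @param fiber_id Identifier.
#' @param class_label Afferent class.
#' @param cv Conduction velocity, m/s.
#' @param conduction_distance mm between stimulation site and electrode.
#' @param waveform Five-parameter biphasic template ([default_waveform()]).
#' @param a,b,c Ground-truth stimulus-response law over sonication energy:
#'   maximal probability `a` in (0, 1], half-max-of-plateau energy `b` (nJ),
#'   slope `c` > 0.
#' @param nt_b_multiplier Nerve-trunk stimulation is modeled as the same law
#'   with `b` multiplied by this factor (thresholds at the trunk exceed those
#'   at the receptive field).
#' @param mech_threshold_true True mechanical threshold, mN.
#' @param transduction_delay Extra FUS-vs-electrical spike latency, ms
#'   (mechanotransduction time; ~1 ms scale).
#' @param jitter_sd Latency jitter SD, ms.
#' @param responsive Logical; non-responsive fibers never spike to FUS.
#' @param genotype `"control"` or `"piezo2_ko"`.
#' @param fail_onset_nJ Optional: energy above which an additional
#'   spike-failure ramp engages (non-monotonic tuning); NA disables it.
#' @param fail_width_nJ Width of the failure ramp, nJ.
#' @return A one-row data.frame (waveform flattened into wf_* columns).
#' @export
fiber_truth <- function(fiber_id, class_label, cv, conduction_distance = 20,
                        waveform = default_waveform(
                          if (is_a_fiber(class_label)) "A" else "C"),
                        a = 0.95, b = 6e4, c = 0.8,
                        nt_b_multiplier = 4,
                        mech_threshold_true = 1.0,
                        transduction_delay = 0.9,
                        jitter_sd = if (is_a_fiber(class_label)) 0.05 else 0.2,
                        responsive = TRUE, genotype = "control",
                        fail_onset_nJ = NA_real_, fail_width_nJ = 500) {
  stopifnot(a > 0, a <= 1, b > 0, c > 0, cv > 0, conduction_distance > 0,
            transduction_delay >= 0, jitter_sd >= 0)
  rng <- CLASS_CV_RANGES[[class_label]]
  if (!is.null(rng) && (cv < rng[1] - 1e-9 || cv > rng[2] + 1e-9))
    warning("cv ", cv, " m/s outside the ", class_label, " band [",
            rng[1], ", ", rng[2], "]")
  data.frame(
    fiber_id = as.character(fiber_id), class_label = class_label,
    cv = cv, conduction_distance = conduction_distance,
    wf_pos_amp = waveform$pos_amp, wf_neg_amp = waveform$neg_amp,
    wf_rise_ms = waveform$rise_ms, wf_width_ms = waveform$width_ms,
    wf_decay_ms = waveform$decay_ms,
    a = a, b = b, c = c, nt_b_multiplier = nt_b_multiplier,
    mech_threshold_true = mech_threshold_true,
    transduction_delay = transduction_delay, jitter_sd = jitter_sd,
    responsive = responsive, genotype = genotype,
    fail_onset_nJ = fail_onset_nJ, fail_width_nJ = fail_width_nJ,
    stringsAsFactors = FALSE
  )
}

truth_waveform <- function(truth_row) {
  list(pos_amp = truth_row$wf_pos_amp, neg_amp = truth_row$wf_neg_amp,
       rise_ms = truth_row$wf_rise_ms, width_ms = truth_row$wf_width_ms,
       decay_ms = truth_row$wf_decay_ms)
}

#' Cohort generator configuration
#'
#' @param n_per_class Named integer vector, fibers per afferent class, e.g.
#'   `c(AbRA = 5, C = 5)`.
#' @param ko_paired If TRUE, each control fiber gets a knockout counterpart
#'   sharing its base parameters, with `b` multiplied by `ko_b_multiplier`,
#'   mechanical threshold multiplied by `ko_mech_multiplier`, responsiveness
#'   dropped with probability `ko_nonresponsive_p`, and a smaller
#'   trunk-vs-field ratio.
#' @param ko_b_multiplier Rightward shift (x) of the knockout energy law.
#' @param ko_mech_multiplier Rightward shift (x) of knockout mechanical
#'   thresholds.
#' @param ko_nonresponsive_p Probability a knockout fiber never responds to
#'   FUS.
#' @param nt_b_multiplier_control,nt_b_multiplier_ko Nerve-trunk `b`
#'   multipliers per genotype.
#' @param noise_sd Recording noise SD, uV. Default 8 uV gives SNR ~ 10 on the
#'   80 uV A-fiber positive peak.
#' @param distractor_rate Poisson rate (Hz) of distractor spikes from an
#'   unsorted neighboring unit (waveform widths perturbed by
#'   `distractor_width_factor`).
#' @param distractor_width_factor Multiplier on the distractor's three lobe
#'   time constants.
#' @param transduction_delay Extra FUS latency, ms, for every fiber.
#' @param seed Integer seed; all cohort randomness flows through it.
#' @return Named list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_class = c(AbRA = 5, C = 5),
                          ko_paired = FALSE,
                          ko_b_multiplier = 3,
                          ko_mech_multiplier = 14,
                          ko_nonresponsive_p = 0.2,
                          nt_b_multiplier_control = 4,
                          nt_b_multiplier_ko = 1.8,
                          noise_sd = 8,
                          distractor_rate = 0,
                          distractor_width_factor = 1.3,
                          transduction_delay = 0.9,
                          seed = 1L) {
  stopifnot(all(n_per_class >= 0), ko_b_multiplier >= 1,
            ko_nonresponsive_p >= 0, ko_nonresponsive_p <= 1,
            noise_sd >= 0, distractor_rate >= 0)
  bad <- setdiff(names(n_per_class), names(CLASS_CV_RANGES))
  if (length(bad)) stop("unknown afferent class: ", paste(bad, collapse = ", "))
  structure(as.list(environment()), class = "cohort_config")
}

# Class-typical dose-response plateaus and half-max energies (nJ, on the
# energy axis the default 0.0165 cm focal radius delivers: the protocol grid
# spans ~1e3 to 1.3e6 nJ, and class EC50s sit in its lower middle). The
# plateau ordering (low-threshold mechanoreceptors > nociceptors) and the
# DH-most-sensitive / AM-least-sensitive ordering follow the recorded
# population; spreads are log-normal around the class center.
CLASS_DOSE_DEFAULTS <- list(
  AbRA = list(a = 0.95, b = 6.0e4), AbSA = list(a = 0.93, b = 6.5e4),
  DH = list(a = 0.97, b = 2.0e4), AM = list(a = 0.77, b = 1.1e5),
  C = list(a = 0.80, b = 8.0e4)
)
CLASS_MECH_DEFAULTS <- c(AbRA = 0.6, AbSA = 0.8, DH = 0.2, AM = 4.0, C = 2.0)

#' Generate a ground-truth cohort
#'
#' Draws per-fiber conduction velocities within each class's band, waveform
#' templates, stimulus-response laws and mechanical thresholds. Deterministic
#' given `config$seed`. With `ko_paired = TRUE` every control fiber is
#' mirrored by a knockout counterpart whose `b` is exactly
#' `ko_b_multiplier` times larger.
#'
#' @param config A [cohort_config()].
#' @return data.frame of fiber truths (one row per fiber).
#' @export
make_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (sum(config$n_per_class) == 0) {
    warning("zero fibers requested in every class; returning empty cohort")
    return(fiber_truth("x", "C", 0.5)[0, , drop = FALSE])
  }
  set.seed(config$seed)
  rows <- list()
  for (cls in names(config$n_per_class)) {
    n <- config$n_per_class[[cls]]
    if (n == 0) next
    rng <- CLASS_CV_RANGES[[cls]]
    dd <- CLASS_DOSE_DEFAULTS[[cls]]
    grp <- if (is_a_fiber(cls)) "A" else "C"
    for (i in seq_len(n)) {
      wf <- default_waveform(grp)
      # amplitude variation keeps templates distinct across fibers
      amp_scale <- stats::runif(1, 0.8, 1.25)
      wf$pos_amp <- wf$pos_amp * amp_scale
      wf$neg_amp <- wf$neg_amp * amp_scale
      base <- fiber_truth(
        fiber_id = sprintf("%s_%02d", cls, i), class_label = cls,
        cv = stats::runif(1, rng[1], rng[2]),
        conduction_distance = stats::runif(1, 15, 25),
        waveform = wf,
        a = min(1, dd$a * stats::runif(1, 0.95, 1.05)),
        b = dd$b * exp(stats::rnorm(1, 0, 0.2)),
        c = stats::runif(1, 0.6, 1.2),
        nt_b_multiplier = config$nt_b_multiplier_control,
        mech_threshold_true =
          CLASS_MECH_DEFAULTS[[cls]] * exp(stats::rnorm(1, 0, 0.25)),
        transduction_delay = config$transduction_delay
      )
      rows[[length(rows) + 1L]] <- base
      if (config$ko_paired) {
        ko <- base
        ko$fiber_id <- paste0(base$fiber_id, "_ko")
        ko$genotype <- "piezo2_ko"
        ko$b <- base$b * config$ko_b_multiplier
        ko$mech_threshold_true <-
          base$mech_threshold_true * config$ko_mech_multiplier
        ko$nt_b_multiplier <- config$nt_b_multiplier_ko
        ko$responsive <- stats::runif(1) >= config$ko_nonresponsive_p
        rows[[length(rows) + 1L]] <- ko
      }
    }
  }
  cohort <- do.call(rbind, rows)
  rownames(cohort) <- NULL
  cohort
}

#' Spike probability of a fiber for one FUS presentation
#'
#' Evaluates the fiber's ground-truth law at the presentation's sonication
#' energy (nJ), applying the nerve-trunk shift and the optional high-energy
#' failure ramp.
#'
#' @param truth_row One row of a cohort.
#' @param energy_nJ Sonication energy, nJ.
#' @param site `"RF"` or `"NT"`.
#' @return Probability in \[0, 1\].
#' @export
truth_spike_prob <- function(truth_row, energy_nJ, site = "RF") {
  if (!truth_row$responsive) return(rep(0, length(energy_nJ)))
  b <- if (site == "NT") truth_row$b * truth_row$nt_b_multiplier else truth_row$b
  p <- dose_response_prob(energy_nJ, truth_row$a, b, truth_row$c)
  if (is.finite(truth_row$fail_onset_nJ)) {
    ramp <- pmin(1, pmax(0, (energy_nJ - truth_row$fail_onset_nJ) /
                              truth_row$fail_width_nJ))
    p <- p * (1 - ramp)
  }
  p
}

#' Simulate one stimulus sweep
#'
#' Renders a short voltage trace around a single FUS or electrical
#' presentation. An evoked spike (at most one; responses are one-to-one)
#' occurs with the fiber's ground-truth probability, at latency
#' `conduction_distance / cv` plus, for FUS, the transduction delay, plus
#' Gaussian jitter. Zero-mean Gaussian noise of SD `noise_sd` is added
#' throughout; optional distractor spikes from a width-perturbed template are
#' injected at Poisson times.
#'
#' @param truth_row One cohort row.
#' @param event One-row event table ([fus_events()]).
#' @param instrument [fus_instrument()].
#' @param noise_sd Noise SD, uV.
#' @param rate Sampling rate, Hz.
#' @param pre_s Seconds of baseline before the stimulus onset.
#' @param sweep_s Total sweep duration, s.
#' @param distractor_rate,distractor_width_factor See [cohort_config()].
#' @param seed Optional seed (omit when driven by an outer seeded loop).
#' @return A [fus_trace()] carrying attribute `truth_spike_time` (s, NA when
#'   no spike was evoked).
#' @export
simulate_sweep <- function(truth_row, event, instrument = fus_instrument(),
                           noise_sd = 8, rate = 20000,
                           pre_s = 0.01, sweep_s = NULL,
                           distractor_rate = 0, distractor_width_factor = 1.3,
                           seed = NULL) {
  if (!event$modality %in% c("fus", "electrical"))
    stop("simulate_sweep handles fus and electrical events only")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sweep_s)) {
    rw <- response_window_s(if (is_a_fiber(truth_row$class_label)) "A" else "C")
    sweep_s <- pre_s + rw + 0.02
  }
  n <- round(sweep_s * rate)
  samples <- stats::rnorm(n, 0, noise_sd)
  t0 <- event$onset - pre_s
  cond_ms <- truth_row$conduction_distance / truth_row$cv
  spike_time <- NA_real_
  p <- if (event$modality == "electrical") {
    1
  } else {
    e_nJ <- 1e9 * sonication_energy(event$intensity, event$duration,
                                    instrument$focal_radius_cm)
    truth_spike_prob(truth_row, e_nJ, site = event$site)
  }
  if (stats::runif(1) < p) {
    lat_ms <- cond_ms +
      (if (event$modality == "fus") truth_row$transduction_delay else 0) +
      stats::rnorm(1, 0, truth_row$jitter_sd)
    spike_time <- event$onset + lat_ms / 1000
    samples <- add_waveform_at(samples, rate, t0, spike_time,
                               truth_waveform(truth_row))
  }
  if (distractor_rate > 0) {
    ndis <- stats::rpois(1, distractor_rate * sweep_s)
    if (ndis > 0) {
      dwf <- truth_waveform(truth_row)
      dwf$rise_ms <- dwf$rise_ms * distractor_width_factor
      dwf$width_ms <- dwf$width_ms * distractor_width_factor
      dwf$decay_ms <- dwf$decay_ms * distractor_width_factor
      dwf$pos_amp <- dwf$pos_amp * 0.9
      dwf$neg_amp <- dwf$neg_amp * 0.9
      for (td in stats::runif(ndis, t0, t0 + sweep_s))
        samples <- add_waveform_at(samples, rate, t0, td, dwf)
    }
  }
  tr <- fus_trace(samples, rate, t0, strict_rate = FALSE)
  attr(tr, "truth_spike_time") <- spike_time
  tr
}

add_waveform_at <- function(samples, rate, t0, peak_time, waveform) {
  w <- render_waveform(waveform, rate)
  pk <- attr(w, "peak_index")
  i0 <- round((peak_time - t0) * rate) + 1L - (pk - 1L)
  idx <- seq_along(w) + i0 - 1L
  keep <- idx >= 1L & idx <= length(samples)
  samples[idx[keep]] <- samples[idx[keep]] + w[keep]
  samples
}

response_window_s <- function(group) if (group == "A") 0.05 else 0.2

#' Simulate a full recording session
#'
#' For every fiber in the cohort and every row of the FUS protocol, generates
#' `n_repeats` presentations at the interstimulus interval, each rendered as
#' its own sweep trace, plus `n_electrical` electrical presentations for
#' latency comparison. Event onsets advance on a per-fiber clock at the ISI.
#' The ground-truth cohort and true spike times ride along in the session for
#' recovery tests.
#'
#' @param cohort From [make_cohort()].
#' @param protocol FUS parameter table from [parameter_grid()].
#' @param config The [cohort_config()] (noise, distractors, seed).
#' @param instrument [fus_instrument()].
#' @param rate Sampling rate, Hz.
#' @param n_electrical Electrical presentations per fiber.
#' @param sites Stimulation sites to run the protocol at (`"RF"`, `"NT"`).
#' @return A `fus_session`; `session$truth` holds the cohort and
#'   `session$provenance$true_spikes` the per-event truth assignment.
#' @export
simulate_session <- function(cohort, protocol, config,
                             instrument = fus_instrument(),
                             rate = 20000, n_electrical = 5, sites = "RF") {
  stopifnot(nrow(protocol) >= 1, nrow(cohort) >= 1)
  set.seed(config$seed + 1L)
  traces <- list()
  ev_rows <- list()
  true_spk <- list()
  for (fi in seq_len(nrow(cohort))) {
    fb <- cohort[fi, ]
    clock <- 0
    k <- 0L
    emit <- function(modality, intensity, duration, site, trial) {
      k <<- k + 1L
      tid <- sprintf("%s_s%04d", fb$fiber_id, k)
      ev <- data.frame(onset = clock, modality = modality, trace_id = tid,
                       fiber_id = fb$fiber_id, intensity = intensity,
                       duration = duration, magnitude = NA_real_,
                       carrier = instrument$carrier_mhz, site = site,
                       trial_index = trial, stringsAsFactors = FALSE)
      tr <- simulate_sweep(fb, ev, instrument, noise_sd = config$noise_sd,
                           rate = rate,
                           distractor_rate = config$distractor_rate,
                           distractor_width_factor =
                             config$distractor_width_factor)
      tr$id <- tid
      traces[[tid]] <<- tr
      ev_rows[[length(ev_rows) + 1L]] <<- ev
      true_spk[[length(true_spk) + 1L]] <<- data.frame(
        trace_id = tid, fiber_id = fb$fiber_id,
        spike_time = attr(tr, "truth_spike_time"), stringsAsFactors = FALSE)
      clock <<- clock + instrument$isi_s
    }
    for (site in sites)
      for (pi in seq_len(nrow(protocol)))
        for (rep_i in seq_len(protocol$n_repeats[pi]))
          emit("fus", protocol$intensity[pi], protocol$duration[pi],
               site, rep_i)
    for (rep_i in seq_len(n_electrical))
      emit("electrical", NA_real_, NA_real_, "RF", rep_i)
  }
  ev <- do.call(rbind, ev_rows)
  events <- fus_events(ev$onset, ev$modality, ev$trace_id, ev$fiber_id,
                       intensity = ev$intensity, duration = ev$duration,
                       magnitude = ev$magnitude, carrier = ev$carrier,
                       site = ev$site, trial_index = ev$trial_index,
                       validate = FALSE)
  fibers <- fus_fibers(cohort$fiber_id, class_label = cohort$class_label,
                       cv = cohort$cv,
                       conduction_distance = cohort$conduction_distance,
                       genotype = cohort$genotype)
  fus_session(traces, events, fibers, instrument = instrument,
              provenance = list(generator = "fusafferent-synthgen",
                                version = "1", seed = config$seed,
                                true_spikes = do.call(rbind, true_spk)),
              truth = cohort)
}

#' Simulate count-level FUS threshold measurements for a cohort
#'
#' The fast path for population-threshold studies: instead of rendering
#' voltage traces, draws the per-presentation Bernoulli outcomes directly
#' from each fiber's ground-truth law at a grid of sonication energies —
#' exactly the response tables the sorter would produce from clean
#' recordings.
#'
#' @param cohort From [make_cohort()].
#' @param energies_nJ Ascending grid of sonication energies (nJ).
#' @param n_repeats Presentations per energy (>= 4 for threshold use).
#' @param site `"RF"` or `"NT"`.
#' @param seed Integer seed.
#' @return data.frame: fiber_id, genotype, energy_nJ, n_stimuli, n_spikes,
#'   probability.
#' @export
simulate_threshold_study <- function(cohort, energies_nJ, n_repeats = 5L,
                                     site = "RF", seed = 1L) {
  stopifnot(n_repeats >= 1, all(diff(energies_nJ) > 0))
  set.seed(seed)
  out <- list()
  for (fi in seq_len(nrow(cohort))) {
    fb <- cohort[fi, ]
    p <- truth_spike_prob(fb, energies_nJ, site = site)
    n_spk <- stats::rbinom(length(energies_nJ), n_repeats, p)
    out[[fi]] <- data.frame(
      fiber_id = fb$fiber_id, genotype = fb$genotype,
      energy_nJ = energies_nJ, n_stimuli = n_repeats, n_spikes = n_spk,
      probability = n_spk / n_repeats, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
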