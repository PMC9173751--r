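# Correlation acceptance floors for template matching: spikes kept for
# analysis must correlate with the unit template strictly above these values.
CORRELATION_FLOORS <- c(A = 0.97, C = 0.85)

# Snippet window lengths (ms) per fiber group; windows are centered on the
# positive peak. A-fiber spikes are ~1 ms, C-fiber spikes ~2.5 ms.
SNIPPET_WINDOW_MS <- c(A = 2, C = 4)

#' Detect spike candidates in a trace
#'
#' Positive peaks exceeding `k` times a robust noise scale (1.4826 x median
#' absolute deviation, the Gaussian-consistent MAD estimate) are extracted as
#' fixed-length snippets centered on the peak. Peaks closer than the
#' refractory interval are merged (the larger survives); windows that would
#' be clipped at the trace edges are discarded.
#'
#' @param trace A [fus_trace()].
#' @param k Threshold multiplier on the noise scale.
#' @param window_ms Snippet window length, ms (default by `fiber_group`).
#' @param refractory_ms Minimum peak separation, ms.
#' @param fiber_group `"A"` or `"C"`, sets the default window.
#' @return List of class `fus_snippets`: `windows` (matrix, one row per
#'   snippet), `peak_times` (s, absolute), `trace_id`, `rate`,
#'   `noise_scale` (uV).
#' @export
detect_candidates <- function(trace, k = 5, window_ms = NULL,
                              refractory_ms = 1, fiber_group = "A") {
  if (is.null(window_ms)) window_ms <- SNIPPET_WINDOW_MS[[fiber_group]]
  rate <- trace$rate
  half <- ceiling(window_ms / 2 * rate / 1000)
  wlen <- 2L * half + 1L
  x <- trace$samples
  empty <- structure(list(windows = matrix(numeric(0), 0, wlen),
                          peak_times = numeric(0), trace_id = trace$id,
                          rate = rate, noise_scale = NA_real_,
                          window_ms = window_ms),
                     class = "fus_snippets")
  if (length(x) < wlen) return(empty)
  sigma <- stats::mad(x, center = stats::median(x))
  if (sigma == 0) {
    warning("flat trace (zero noise scale); returning every supra-zero peak")
    thr <- .Machine$double.eps
  } else thr <- k * sigma
  # local maxima strictly above both neighbors and the threshold
  n <- length(x)
  is_pk <- which(x[2:(n - 1)] > thr &
                 x[2:(n - 1)] >= x[1:(n - 2)] &
                 x[2:(n - 1)] > x[3:n]) + 1L
  if (!length(is_pk)) return(empty)
  # refractory enforcement: greedy by descending amplitude
  refr <- refractory_ms / 1000 * rate
  ord <- is_pk[order(x[is_pk], decreasing = TRUE)]
  keep <- logical(0)
  kept <- integer(0)
  for (p in ord)
    if (!length(kept) || all(abs(kept - p) >= refr)) kept <- c(kept, p)
  kept <- sort(kept)
  kept <- kept[kept - half >= 1L & kept + half <= n]
  if (!length(kept)) return(empty)
  win <- t(vapply(kept, function(p) x[(p - half):(p + half)], numeric(wlen)))
  structure(list(windows = win,
                 peak_times = trace$t0 + (kept - 1L) / rate,
                 trace_id = rep(trace$id, length(kept)),
                 rate = rate, noise_scale = sigma, window_ms = window_ms),
            class = "fus_snippets")
}

n_snippets <- function(s) nrow(s$windows)

bind_snippets <- function(lst) {
  lst <- Filter(function(s) n_snippets(s) > 0, lst)
  if (!length(lst))
    stop("no snippets to bind")
  structure(list(windows = do.call(rbind, lapply(lst, `[[`, "windows")),
                 peak_times = unlist(lapply(lst, `[[`, "peak_times")),
                 trace_id = unlist(lapply(lst, `[[`, "trace_id")),
                 rate = lst[[1]]$rate, noise_scale = lst[[1]]$noise_scale,
                 window_ms = lst[[1]]$window_ms),
            class = "fus_snippets")
}

# linearly interpolated time (in samples, fractional) at which the segment
# y[i]..y[i+1] crosses `level`, scanning from `from` toward `to`
cross_time <- function(y, level, from, to) {
  step <- if (to >= from) 1L else -1L
  idx <- seq(from, to, by = step)
  for (j in seq_len(max(0L, length(idx) - 1L))) {
    i1 <- idx[j]; i2 <- idx[j + 1L]
    if ((y[i1] - level) * (y[i2] - level) <= 0 && y[i1] != y[i2])
      return(i1 + (y[i1] - level) / (y[i1] - y[i2]) * (i2 - i1))
  }
  NA_real_
}

#' Extract the five sorting features from a snippet window
#'
#' Features: positive peak amplitude, negative peak amplitude (signed),
#' positive peak rise time (10% of peak to peak), spike width (positive-lobe
#' full width at half maximum) and negative peak decay time (negative peak
#' back to 10% of it). Threshold crossings are located by linear
#' interpolation between samples, so timing features have sub-sample
#' resolution.
#'
#' @param window Numeric vector, one snippet (uV), positive peak inside.
#' @param rate Sampling rate, Hz.
#' @return Named list: `pos_peak_amp`, `neg_peak_amp`, `pos_rise_time`,
#'   `spike_width`, `neg_decay_time` (ms), and `monophasic` flag. For
#'   monophasic snippets the negative-lobe fields are NA.
#' @export
extract_features <- function(window, rate) {
  ms <- 1000 / rate
  ip <- which.max(window)
  pos <- window[ip]
  if (pos <= 0) stop("snippet has no positive extremum")
  # negative extremum after the positive peak (biphasic order: + then -)
  post <- window[ip:length(window)]
  inn <- which.min(post) + ip - 1L
  neg <- window[inn]
  monophasic <- neg >= -0.1 * pos  # no substantive negative lobe
  rise10 <- cross_time(window, 0.1 * pos, ip, 1L)
  half_l <- cross_time(window, 0.5 * pos, ip, 1L)
  half_r <- cross_time(window, 0.5 * pos, ip, length(window))
  out <- list(
    pos_peak_amp = pos,
    neg_peak_amp = if (monophasic) NA_real_ else neg,
    pos_rise_time = (ip - rise10) * ms,
    spike_width = (half_r - half_l) * ms,
    neg_decay_time = NA_real_,
    monophasic = monophasic
  )
  if (!monophasic) {
    dec10 <- cross_time(window, 0.1 * neg, inn, length(window))
    out$neg_decay_time <- (dec10 - inn) * ms
  }
  out
}

#' Feature table for a snippet set
#' @param snippets A `fus_snippets`.
#' @return data.frame, one row per snippet.
#' @export
snippet_features <- function(snippets) {
  if (n_snippets(snippets) == 0)
    return(data.frame(pos_peak_amp = numeric(0), neg_peak_amp = numeric(0),
                      pos_rise_time = numeric(0), spike_width = numeric(0),
                      neg_decay_time = numeric(0), monophasic = logical(0)))
  rows <- apply(snippets$windows, 1L, extract_features, rate = snippets$rate,
                simplify = FALSE)
  do.call(rbind, lapply(rows, as.data.frame))
}

#' Average snippets into a template
#'
#' Snippets are peak-aligned by construction (windows centered on the
#' positive peak), so the template is the pointwise mean.
#'
#' @param snippets A `fus_snippets` with >= 1 snippet (>= 2 for a meaningful
#'   average).
#' @return Numeric template with attribute `correlations` (each snippet vs
#'   the template) and `degenerate` flag (zero-variance template).
#' @export
build_template <- function(snippets) {
  if (n_snippets(snippets) == 0) stop("cannot build a template from no snippets")
  tmpl <- colMeans(snippets$windows)
  degen <- stats::var(tmpl) < .Machine$double.eps
  if (degen) warning("degenerate (zero-variance) template")
  cors <- if (degen) rep(NA_real_, n_snippets(snippets))
          else apply(snippets$windows, 1L, function(w)
            if (stats::var(w) < .Machine$double.eps) NA_real_
            else stats::cor(w, tmpl))
  structure(tmpl, correlations = cors, degenerate = degen)
}

# 5-sample moving average; endpoints passed through unchanged. At 20 kHz
# this is a ~4 kHz box smoother, wide enough to suppress broadband noise but
# narrow against the spike's spectral content.
smooth_win <- function(x, k = 5L) {
  v <- as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
  v[is.na(v)] <- x[is.na(v)]
  v
}

# Contiguous index span over which |template| rises above both 2% of its
# peak and the template's own noise floor (estimated from the outer eighths
# of the window): the spike's active extent. The noise-floor term keeps
# residual ripples in an averaged template from dragging flat noise-only
# stretches into the correlation span.
active_extent <- function(template, frac = 0.02) {
  n <- length(template)
  margin <- c(seq_len(max(1L, n %/% 8L)), seq(n - max(1L, n %/% 8L) + 1L, n))
  floor_noise <- 4 * stats::mad(template[margin], center = 0)
  thr <- max(frac * max(abs(template)), floor_noise)
  act <- which(abs(template) > thr)
  if (!length(act)) act <- which.max(abs(template))
  seq(min(act), max(act))
}

#' Correlation acceptance filter
#'
#' Keeps snippets whose Pearson correlation with the template is strictly
#' above the class floor: 0.97 for A-fibers, 0.85 for C-fibers. The
#' correlation is computed over the template's active extent (the contiguous
#' span where the template exceeds 2% of its peak) after light smoothing
#' (5-sample moving average) of both waveforms: the flat, noise-only margins
#' of the snippet window would otherwise dilute the correlation of genuine
#' spikes without aiding discrimination. Because the true peak generally
#' falls between samples, each snippet is aligned to the template at the
#' integer shift (within +/- `max_shift` samples) that maximizes the
#' correlation before the floor is applied. Raw snippets are untouched for
#' feature extraction. Zero-variance snippets are rejected with a reason
#' code.
#'
#' @param snippets A `fus_snippets`.
#' @param template Template waveform (same length as the windows).
#' @param fiber_group `"A"` or `"C"`.
#' @param max_shift Alignment search half-width, samples.
#' @param extent Optional index span for the correlation (defaults to the
#'   template's own active extent). When a template is re-estimated from a
#'   filtered snippet set, the extent estimated before filtering should be
#'   reused: selection slightly imprints accepted noise onto the new
#'   template and would otherwise widen its apparent extent.
#' @return List of class `sorted_unit`: `template`, `accepted` (snippets),
#'   `accepted_scores`, `rejected_scores`, `reject_reason`,
#'   `correlation_floor`, `fiber_group`, `accepted_idx`.
#' @export
correlation_filter <- function(snippets, template, fiber_group = c("A", "C"),
                               max_shift = 2L, extent = NULL) {
  fiber_group <- match.arg(fiber_group)
  if (stats::var(template) < .Machine$double.eps)
    stop("template is degenerate (zero variance)")
  floor_r <- CORRELATION_FLOORS[[fiber_group]]
  tmpl_s <- smooth_win(template)
  act <- if (is.null(extent)) active_extent(tmpl_s) else extent
  wl <- length(template)
  shifts <- seq(-max_shift, max_shift)
  shifts <- shifts[sapply(shifts, function(s)
    min(act) + s >= 1L && max(act) + s <= wl)]
  n <- n_snippets(snippets)
  score <- rep(NA_real_, n)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    ws <- smooth_win(snippets$windows[i, ])
    if (stats::var(ws[act]) < .Machine$double.eps) {
      reason[i] <- "zero_variance"
    } else {
      score[i] <- max(vapply(shifts, function(s)
        stats::cor(ws[act + s], tmpl_s[act]), numeric(1)))
      if (score[i] <= floor_r) reason[i] <- "below_floor"
    }
  }
  acc <- which(is.na(reason))
  structure(list(
    template = as.numeric(template),
    accepted = subset_snippets(snippets, acc),
    accepted_scores = score[acc],
    accepted_idx = acc,
    rejected_scores = score[setdiff(seq_len(n), acc)],
    reject_reason = reason[setdiff(seq_len(n), acc)],
    correlation_floor = floor_r,
    fiber_group = fiber_group
  ), class = "sorted_unit")
}

subset_snippets <- function(s, idx) {
  structure(list(windows = s$windows[idx, , drop = FALSE],
                 peak_times = s$peak_times[idx],
                 trace_id = s$trace_id[idx],
                 rate = s$rate, noise_scale = s$noise_scale,
                 window_ms = s$window_ms),
            class = "fus_snippets")
}

#' Embed a rendered waveform in a snippet-length window
#'
#' Builds a template vector of the standard snippet window length for a
#' fiber group with the waveform's positive peak at the center — the layout
#' [detect_candidates()] snippets use, so the result can serve as an
#' explicit template for [sort_unit()] or [correlation_filter()].
#'
#' @param waveform Five-parameter template (see [default_waveform()]).
#' @param rate Sampling rate, Hz.
#' @param fiber_group `"A"` or `"C"` (sets the window length).
#' @return Numeric vector of the snippet window length.
#' @export
waveform_template <- function(waveform, rate, fiber_group = "A") {
  w <- render_waveform(waveform, rate)
  pk <- attr(w, "peak_index")
  half <- ceiling(SNIPPET_WINDOW_MS[[fiber_group]] / 2 * rate / 1000)
  wl <- 2L * half + 1L
  out <- numeric(wl)
  idx <- seq_along(w) + (half + 1L - pk)
  keep <- idx >= 1L & idx <= wl
  out[idx[keep]] <- w[keep]
  out
}

#' Sort one unit and assign spikes to stimuli
#'
#' The template-matching loop: detect candidates on every trace, build an
#' initial template as the mean of all candidates, apply the correlation
#' floor once, rebuild the template from the accepted set, re-filter, then
#' assign each stimulus at most one accepted spike whose peak falls inside
#' the response window after the onset (the earliest, if several). Accepted
#' spikes assigned to no stimulus are reported as spontaneous.
#'
#' @param traces Named list of [fus_trace()] (or a `fus_session`, whose
#'   traces are used).
#' @param events Event table; rows define the stimuli to assign.
#' @param fiber_group `"A"` or `"C"`.
#' @param k Detection threshold multiplier.
#' @param response_window_s Assignment window after each onset (default
#'   50 ms for A, 200 ms for C).
#' @param template Optional starting template (e.g. exemplar spikes chosen
#'   by the experimenter, or a second unit's waveform when two units share
#'   the electrode). When NULL the initial template is the mean of all
#'   candidates — adequate for a single dominant unit, but a recording with
#'   two interleaved units needs one explicit template per unit.
#' @return A `sorted_unit` with extra fields `assignments` (data.frame: one
#'   row per event, `spike_time` NA when no spike) and `spontaneous`
#'   (unassigned accepted spike times).
#' @export
sort_unit <- function(traces, events, fiber_group = c("A", "C"), k = 5,
                      response_window_s = NULL, template = NULL) {
  fiber_group <- match.arg(fiber_group)
  if (inherits(traces, "fus_session")) traces <- traces$traces
  if (is.null(response_window_s))
    response_window_s <- response_window_s(fiber_group)
  if (is.unsorted(events$onset))
    stop("events must be sorted by onset")
  gaps <- diff(events$onset)
  if (any(gaps < response_window_s & gaps > 0 &
          events$trace_id[-1] == events$trace_id[-nrow(events)]))
    stop("overlapping response windows: interstimulus interval shorter than ",
         response_window_s, " s")
  cand <- lapply(traces, detect_candidates, k = k, fiber_group = fiber_group)
  total <- sum(vapply(cand, n_snippets, integer(1)))
  if (total == 0) {
    unit <- structure(list(template = NULL, accepted = NULL,
                           accepted_scores = numeric(0),
                           correlation_floor = CORRELATION_FLOORS[[fiber_group]],
                           fiber_group = fiber_group),
                      class = "sorted_unit")
  } else {
    all_sn <- bind_snippets(cand)
    tmpl0 <- if (is.null(template)) build_template(all_sn) else template
    act0 <- active_extent(smooth_win(as.numeric(tmpl0)))
    pass1 <- correlation_filter(all_sn, tmpl0, fiber_group, extent = act0)
    unit <- if (n_snippets(pass1$accepted) == 0) {
      pass1
    } else {
      tmpl1 <- build_template(pass1$accepted)
      correlation_filter(all_sn, tmpl1, fiber_group, extent = act0)
    }
  }
  spk <- if (!is.null(unit$accepted)) sort(unit$accepted$peak_times)
         else numeric(0)
  assigned <- rep(NA_real_, nrow(events))
  used <- logical(length(spk))
  for (i in seq_len(nrow(events))) {
    lo <- events$onset[i]
    hi <- lo + response_window_s
    j <- which(!used & spk >= lo & spk <= hi)
    if (length(j)) {
      assigned[i] <- spk[j[1]]
      used[j[1]] <- TRUE
    }
  }
  unit$assignments <- data.frame(events[, c("onset", "modality", "trace_id",
                                            "fiber_id", "intensity",
                                            "duration", "site",
                                            "trial_index")],
                                 spike_time = assigned,
                                 latency_ms = (assigned - events$onset) * 1000,
                                 stringsAsFactors = FALSE)
  unit$spontaneous <- spk[!used]
  unit$response_window_s <- response_window_s
  unit
}

#' @export
print.sorted_unit <- function(x, ...) {
  nacc <- if (is.null(x$accepted)) 0L else n_snippets(x$accepted)
  cat(sprintf("<sorted_unit (%s): %d accepted spikes, floor r > %.2f%s>\n",
              x$fiber_group, nacc, x$correlation_floor,
              if (!is.null(x$assignments))
                sprintf(", %d/%d stimuli with a spike",
                        sum(!is.na(x$assignments$spike_time)),
                        nrow(x$assignments)) else ""))
  invisible(x)
}
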