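#' Conduction velocity from distance and latency
#'
#' The quotient of the distance between the stimulation site and the
#' recording electrode and the latency of the action-potential peak from the
#' stimulus artifact. mm / ms gives m/s directly.
#'
#' @param distance_mm Electrode-to-stimulus distance, mm.
#' @param latency_ms Peak latency, ms.
#' @return Conduction velocity, m/s.
#' @export
conduction_velocity <- function(distance_mm, latency_ms) {
  if (any(distance_mm <= 0) || any(latency_ms <= 0))
    stop("distance and latency must be positive")
  distance_mm / latency_ms
}

#' Adaptation label from the response to a sustained mechanical step
#'
#' Rapidly adapting (RA) units fire only during the dynamic phases of a
#' sustained indentation (stimulus onset and offset); slowly adapting (SA)
#' units also fire during the static hold. A spike train is labeled RA when
#' every spike falls within `dynamic_window_s` after the step onset or after
#' the step offset, SA otherwise.
#'
#' @param spike_times Spike times (s) during the trial.
#' @param step_onset,step_offset Step boundaries (s); the standard protocol
#'   holds for 5 s.
#' @param dynamic_window_s Width of the dynamic (on/off) windows, s.
#' @return `"RA"`, `"SA"`, or `"unknown"` when there are no spikes.
#' @export
adaptation_label <- function(spike_times, step_onset, step_offset,
                             dynamic_window_s = 0.2) {
  stopifnot(step_offset > step_onset)
  if (!length(spike_times)) return("unknown")
  dynamic <- (spike_times >= step_onset &
                spike_times <= step_onset + dynamic_window_s) |
             (spike_times >= step_offset &
                spike_times <= step_offset + dynamic_window_s)
  if (all(dynamic)) "RA" else "SA"
}

#' Classify an afferent fiber from its physiological profile
#'
#' Five-class scheme over conduction velocity, hair responsiveness, and
#' adaptation:
#' \itemize{
#'   \item C: cv < 1 m/s (any flags).
#'   \item Adelta band, 1 <= cv <= 10: DH if the fiber responds to zigzag
#'     hair movement, otherwise AM (mechanonociceptor; SA response to a
#'     sustained step expected — if adaptation is unknown the AM label
#'     carries a low-confidence flag, and an RA response in this band leaves
#'     the fiber unclassified).
#'   \item Abeta band, cv > 10: AbRA if rapidly adapting and not
#'     hair-responsive; AbSA if slowly adapting and responsive to touch-dome
#'     indentation and/or hair movement; otherwise unclassified.
#' }
#' The Adelta/Abeta boundary at exactly 10 m/s is assigned to the Adelta
#' band (the band is the closed interval \[1, 10\]).
#'
#' @param cv Conduction velocity, m/s (> 0).
#' @param responds_to_zigzag_hair Logical or NA.
#' @param responds_to_touch_dome_or_hair Logical or NA.
#' @param adaptation `"RA"`, `"SA"`, or `"unknown"`.
#' @return List: `class` (AbRA, AbSA, DH, AM, C, unclassified) and
#'   `low_confidence` flag.
#' @export
classify_afferent <- function(cv, responds_to_zigzag_hair = NA,
                              responds_to_touch_dome_or_hair = NA,
                              adaptation = c("unknown", "RA", "SA")) {
  adaptation <- match.arg(adaptation)
  if (!is.numeric(cv) || length(cv) != 1L || !is.finite(cv) || cv <= 0)
    stop("cv must be a single positive number")
  low_conf <- FALSE
  cls <-
    if (cv < 1) {
      "C"
    } else if (cv <= 10) {
      if (isTRUE(responds_to_zigzag_hair)) "DH"
      else if (adaptation == "SA" || adaptation == "unknown") {
        low_conf <- adaptation == "unknown"
        "AM"
      } else "unclassified"
    } else {
      if (adaptation == "RA" && !isTRUE(responds_to_zigzag_hair) &&
          !isTRUE(responds_to_touch_dome_or_hair)) "AbRA"
      else if (adaptation == "SA" &&
               isTRUE(responds_to_touch_dome_or_hair)) "AbSA"
      else "unclassified"
    }
  list(class = cls, low_confidence = low_conf)
}

#' Classify every fiber in a profile table
#'
#' @param profiles data.frame with columns `cv`, `responds_to_zigzag_hair`,
#'   `responds_to_touch_dome_or_hair`, `adaptation` (and optionally
#'   `fiber_id`).
#' @return The input with `class` and `low_confidence` columns appended.
#' @export
classify_afferents <- function(profiles) {
  res <- lapply(seq_len(nrow(profiles)), function(i)
    classify_afferent(profiles$cv[i],
                      profiles$responds_to_zigzag_hair[i],
                      profiles$responds_to_touch_dome_or_hair[i],
                      as.character(profiles$adaptation[i])))
  profiles$class <- vapply(res, `[[`, character(1), "class")
  profiles$low_confidence <- vapply(res, `[[`, logical(1), "low_confidence")
  profiles
}

#' Mechanical threshold from an ascending von Frey series
#'
#' The threshold is the first (weakest) monofilament that evoked action
#' potentials in strictly more than 50% of its presentations. 2/4
#' presentations is not a threshold; 3/4 is.
#'
#' @param responses data.frame with columns `force_mN` (ascending),
#'   `n_stimuli` (>= 4 recommended), `n_with_spike`.
#' @return Threshold force in mN, or `NA` (above range) when no filament
#'   crosses 50%.
#' @export
von_frey_threshold <- function(responses) {
  stopifnot(all(c("force_mN", "n_stimuli", "n_with_spike") %in%
                  names(responses)))
  if (is.unsorted(responses$force_mN, strictly = FALSE))
    stop("von Frey series must be sorted ascending by force")
  if (any(responses$n_with_spike > responses$n_stimuli) ||
      any(responses$n_stimuli < 1))
    stop("invalid response counts")
  if (any(responses$n_stimuli < 4))
    warning("fewer than 4 presentations for some filaments")
  frac <- responses$n_with_spike / responses$n_stimuli
  hit <- which(frac > 0.5)
  if (!length(hit)) return(NA_real_)
  responses$force_mN[hit[1]]
}
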