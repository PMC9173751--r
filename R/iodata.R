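#' Construct a voltage trace
#'
#' A trace is a uniformly sampled extracellular voltage record in microvolts
#' with its sampling rate and absolute start time. Teased-fiber rigs in this
#' preparation digitize at 20 or 40 kHz; other rates are accepted but flagged
#' with a warning unless `strict_rate = FALSE`.
#'
#' @param samples Numeric vector of voltages (uV). Must be finite, length >= 1.
#' @param rate Sampling rate in Hz.
#' @param t0 Recording start time in seconds (absolute session time).
#' @param id Optional trace identifier (string).
#' @param strict_rate Warn when `rate` is not one of 20000 or 40000 Hz.
#' @return An object of class `fus_trace`.
#' @export
fus_trace <- function(samples, rate, t0 = 0, id = NULL, strict_rate = TRUE) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("trace must contain at least one sample")
  if (!all(is.finite(samples))) stop("trace samples must be finite")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("sampling rate must be a single positive number")
  if (strict_rate && !rate %in% c(20000, 40000))
    warning("sampling rate ", rate, " Hz is outside the usual {20, 40} kHz")
  if (!is.numeric(t0) || length(t0) != 1L || !is.finite(t0))
    stop("t0 must be a single finite number")
  structure(
    list(samples = samples, rate = as.numeric(rate), t0 = as.numeric(t0),
         id = if (is.null(id)) NA_character_ else as.character(id)),
    class = "fus_trace"
  )
}

#' @export
print.fus_trace <- function(x, ...) {
  cat(sprintf("<fus_trace %s: %d samples @ %g kHz, t0 = %.6g s, range [%.3g, %.3g] uV>\n",
              x$id, length(x$samples), x$rate / 1000, x$t0,
              min(x$samples), max(x$samples)))
  invisible(x)
}

#' Sample times of a trace
#' @param trace A `fus_trace`.
#' @return Numeric vector of absolute times (s), one per sample.
#' @export
trace_times <- function(trace) {
  trace$t0 + (seq_along(trace$samples) - 1L) / trace$rate
}

STIM_MODALITIES <- c("fus", "electrical", "mechanical", "von_frey")
STIM_SITES <- c("RF", "NT")

#' Build a stimulus event table
#'
#' One row per stimulus presentation. FUS events carry intensity (W/cm^2),
#' duration (ms) and carrier frequency (MHz, fixed 3.57 in the protocol);
#' electrical events a magnitude in mA; mechanical / von Frey events a force
#' in mN. `site` distinguishes receptive-field (RF) from nerve-trunk (NT)
#' stimulation. The table is returned sorted by onset, ties broken by
#' trial_index.
#'
#' @param onset Onset times (s), non-negative.
#' @param modality One of `"fus"`, `"electrical"`, `"mechanical"`, `"von_frey"`.
#' @param trace_id Trace each event is recorded on.
#' @param intensity FUS intensity, W/cm^2 (NA for other modalities).
#' @param duration Stimulus duration, ms (FUS / mechanical).
#' @param magnitude Electrical (mA) or mechanical (mN) magnitude.
#' @param carrier FUS carrier, MHz.
#' @param site `"RF"` or `"NT"`.
#' @param trial_index Ordinal presentation index within a parameter set.
#' @param fiber_id Fiber the event targets.
#' @param validate Check the protocol envelope (warn outside 11-743 W/cm^2,
#'   0.1-2.0 ms).
#' @return A `data.frame` with one row per event, class `fus_events`.
#' @export
fus_events <- function(onset, modality, trace_id, fiber_id,
                       intensity = NA_real_, duration = NA_real_,
                       magnitude = NA_real_, carrier = 3.57,
                       site = "RF", trial_index = seq_along(onset),
                       validate = TRUE) {
  n <- length(onset)
  ev <- data.frame(
    onset = as.numeric(onset),
    modality = as.character(modality),
    trace_id = as.character(trace_id),
    fiber_id = as.character(fiber_id),
    intensity = rep_len(as.numeric(intensity), n),
    duration = rep_len(as.numeric(duration), n),
    magnitude = rep_len(as.numeric(magnitude), n),
    carrier = rep_len(as.numeric(carrier), n),
    site = rep_len(as.character(site), n),
    trial_index = rep_len(as.integer(trial_index), n),
    stringsAsFactors = FALSE
  )
  validate_events(ev, warn_protocol = validate)
  ev <- ev[order(ev$onset, ev$trial_index), , drop = FALSE]
  rownames(ev) <- NULL
  class(ev) <- c("fus_events", "data.frame")
  ev
}

#' Validate a stimulus event table
#' @param events Event data.frame (see [fus_events()]).
#' @param warn_protocol Warn when FUS parameters fall outside the protocol
#'   envelope (intensity 11-743 W/cm^2, duration 0.1-2.0 ms).
#' @return Invisibly, the validated table.
#' @export
validate_events <- function(events, warn_protocol = TRUE) {
  req <- c("onset", "modality", "trace_id", "fiber_id", "intensity",
           "duration", "magnitude", "carrier", "site", "trial_index")
  missing <- setdiff(req, names(events))
  if (length(missing))
    stop("event table is missing required field(s): ",
         paste(missing, collapse = ", "))
  if (any(!is.finite(events$onset)) || any(events$onset < 0))
    stop("event onsets must be finite and non-negative")
  bad <- setdiff(unique(events$modality), STIM_MODALITIES)
  if (length(bad))
    stop("unknown stimulus modality: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(events$site), STIM_SITES)
  if (length(bad))
    stop("unknown stimulation site: ", paste(bad, collapse = ", "))
  isfus <- events$modality == "fus"
  if (any(isfus)) {
    if (any(!is.finite(events$intensity[isfus])) ||
        any(!is.finite(events$duration[isfus])))
      stop("fus events require finite intensity and duration")
    if (warn_protocol) {
      out_i <- events$intensity[isfus] < 11 | events$intensity[isfus] > 743
      out_d <- events$duration[isfus] < 0.1 | events$duration[isfus] > 2.0
      if (any(out_i))
        warning(sum(out_i), " fus event(s) outside the 11-743 W/cm^2 ",
                "protocol intensity range")
      if (any(out_d))
        warning(sum(out_d), " fus event(s) outside the 0.1-2.0 ms ",
                "protocol duration range")
    }
  }
  invisible(events)
}

#' FUS parameter set
#'
#' One combination of intensity and duration with its repeat count. Under the
#' stimulation protocol each set is presented 4 to 10 times; probability and
#' threshold estimation require at least 4 repeats.
#'
#' @param intensity W/cm^2.
#' @param duration ms.
#' @param n_repeats Presentations of this set.
#' @return A one-row `data.frame`; combine with `rbind`.
#' @export
parameter_set <- function(intensity, duration, n_repeats = 5L) {
  stopifnot(intensity > 0, duration > 0, n_repeats >= 1)
  if (n_repeats < 4)
    warning("n_repeats < 4: too few presentations for threshold/probability use")
  data.frame(intensity = as.numeric(intensity),
             duration = as.numeric(duration),
             n_repeats = as.integer(n_repeats))
}

#' Cross a grid of FUS parameters into a protocol table
#'
#' @param intensities W/cm^2 values.
#' @param durations ms values.
#' @param n_repeats Repeats per set (scalar or per-set).
#' @return `data.frame` with columns intensity, duration, n_repeats.
#' @export
parameter_grid <- function(intensities, durations, n_repeats = 5L) {
  g <- expand.grid(intensity = as.numeric(intensities),
                   duration = as.numeric(durations),
                   KEEP.OUT.ATTRS = FALSE)
  g$n_repeats <- as.integer(rep_len(n_repeats, nrow(g)))
  if (any(g$n_repeats < 4))
    warning("some parameter sets have n_repeats < 4")
  g[order(g$duration, g$intensity), , drop = FALSE]
}

AFFERENT_CLASSES <- c("AbRA", "AbSA", "DH", "AM", "C", "unclassified")
GENOTYPES <- c("control", "piezo2_ko")

#' Build a fiber metadata table
#'
#' @param fiber_id Identifiers.
#' @param class_label Afferent class, one of AbRA, AbSA, DH, AM, C,
#'   unclassified.
#' @param cv Conduction velocity, m/s (NA if unmeasured).
#' @param conduction_distance Stimulus-to-electrode distance, mm.
#' @param genotype `"control"` or `"piezo2_ko"`.
#' @param mech_threshold von Frey threshold, mN (optional).
#' @param fus_threshold_rf,fus_threshold_nt Sonication-energy thresholds (J)
#'   at the receptive field / nerve trunk (optional).
#' @return `data.frame`, class `fus_fibers`.
#' @export
fus_fibers <- function(fiber_id, class_label = "unclassified", cv = NA_real_,
                       conduction_distance = NA_real_, genotype = "control",
                       mech_threshold = NA_real_,
                       fus_threshold_rf = NA_real_,
                       fus_threshold_nt = NA_real_) {
  n <- length(fiber_id)
  fb <- data.frame(
    fiber_id = as.character(fiber_id),
    class_label = rep_len(as.character(class_label), n),
    cv = rep_len(as.numeric(cv), n),
    conduction_distance = rep_len(as.numeric(conduction_distance), n),
    genotype = rep_len(as.character(genotype), n),
    mech_threshold = rep_len(as.numeric(mech_threshold), n),
    fus_threshold_rf = rep_len(as.numeric(fus_threshold_rf), n),
    fus_threshold_nt = rep_len(as.numeric(fus_threshold_nt), n),
    stringsAsFactors = FALSE
  )
  validate_fibers(fb)
  class(fb) <- c("fus_fibers", "data.frame")
  fb
}

validate_fibers <- function(fibers) {
  req <- c("fiber_id", "class_label", "cv", "conduction_distance", "genotype",
           "mech_threshold", "fus_threshold_rf", "fus_threshold_nt")
  missing <- setdiff(req, names(fibers))
  if (length(missing))
    stop("fiber table is missing required field(s): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(fibers$fiber_id))
    stop("duplicate fiber_id in fiber table")
  bad <- setdiff(unique(fibers$class_label), AFFERENT_CLASSES)
  if (length(bad)) stop("unknown class_label: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(fibers$genotype), GENOTYPES)
  if (length(bad)) stop("unknown genotype: ", paste(bad, collapse = ", "))
  cvp <- fibers$cv[!is.na(fibers$cv)]
  if (any(cvp <= 0)) stop("conduction velocities must be positive")
  for (f in c("mech_threshold", "fus_threshold_rf", "fus_threshold_nt")) {
    v <- fibers[[f]][!is.na(fibers[[f]])]
    if (any(v <= 0)) stop(f, " values must be positive")
  }
  invisible(fibers)
}

#' Instrument metadata
#'
#' @param focal_radius_cm Ultrasound focal radius r (cm) entering the
#'   sonication-energy transform E = I * pi * r^2 * t. Default 0.0165 cm is
#'   half the 0.33 mm free-field focal diameter (FWHM); the radius is an
#'   explicit knob because reported energies are sensitive to the effective
#'   focal area.
#' @param carrier_mhz Ultrasound carrier frequency, MHz.
#' @param isi_s Interstimulus interval, s.
#' @return Named list.
#' @export
fus_instrument <- function(focal_radius_cm = 0.0165, carrier_mhz = 3.57,
                           isi_s = 5) {
  stopifnot(focal_radius_cm > 0, carrier_mhz > 0, isi_s > 0)
  list(focal_radius_cm = as.numeric(focal_radius_cm),
       carrier_mhz = as.numeric(carrier_mhz),
       isi_s = as.numeric(isi_s))
}

#' Assemble a recording session
#'
#' A session bundles the voltage traces, the stimulus event log, the fiber
#' metadata, exactly one instrument record, and provenance (seed / generator
#' version when synthetic). Every event must reference an existing trace and
#' fall inside that trace's time span.
#'
#' @param traces Named list of [fus_trace()] objects (names = trace ids).
#' @param events Event table from [fus_events()] (may have zero rows).
#' @param fibers Fiber table from [fus_fibers()] (may have zero rows).
#' @param instrument [fus_instrument()] record.
#' @param provenance Named list (seed, generator, version ...), may be empty.
#' @param truth Optional ground-truth cohort (synthetic sessions only), kept
#'   for downstream recovery tests.
#' @return Object of class `fus_session`.
#' @export
fus_session <- function(traces, events, fibers,
                        instrument = fus_instrument(),
                        provenance = list(), truth = NULL) {
  s <- structure(list(traces = traces, events = events, fibers = fibers,
                      instrument = instrument, provenance = provenance,
                      truth = truth),
                 class = "fus_session")
  validate_session(s)
  s
}

#' Validate a session against its schema
#'
#' Checks trace integrity, event and fiber table schemas, event-to-trace
#' references (each event onset must lie within its trace's span), and the
#' presence of a single instrument record. Violations raise errors naming the
#' offending field; nothing is silently coerced.
#'
#' @param session A `fus_session`.
#' @return Invisibly, the session.
#' @export
validate_session <- function(session) {
  if (!inherits(session, "fus_session")) stop("not a fus_session")
  tr <- session$traces
  if (!is.list(tr)) stop("traces must be a named list of fus_trace")
  if (length(tr)) {
    if (is.null(names(tr)) || any(names(tr) == ""))
      stop("traces list must be named by trace id")
    for (id in names(tr)) {
      t <- tr[[id]]
      if (!inherits(t, "fus_trace")) stop("trace '", id, "' is not a fus_trace")
      if (t$rate <= 0) stop("trace '", id, "' has non-positive rate")
      if (!all(is.finite(t$samples)))
        stop("trace '", id, "' contains non-finite samples")
    }
  }
  validate_events(session$events, warn_protocol = FALSE)
  validate_fibers(session$fibers)
  if (nrow(session$events)) {
    missing <- setdiff(unique(session$events$trace_id), names(tr))
    if (length(missing))
      stop("event references absent trace_id: ", paste(missing, collapse = ", "))
    for (i in seq_len(nrow(session$events))) {
      t <- tr[[session$events$trace_id[i]]]
      t_end <- t$t0 + (length(t$samples) - 1L) / t$rate
      on <- session$events$onset[i]
      if (on < t$t0 - 1e-9 || on > t_end + 1e-9)
        stop("event ", i, " onset ", on, " s falls outside trace '",
             session$events$trace_id[i], "' span [", t$t0, ", ", t_end, "]")
    }
  }
  inst <- session$instrument
  if (!is.list(inst) || is.null(inst$focal_radius_cm) ||
      is.null(inst$carrier_mhz) || is.null(inst$isi_s))
    stop("session requires exactly one instrument record with ",
         "focal_radius_cm, carrier_mhz, isi_s")
  invisible(session)
}

#' @export
print.fus_session <- function(x, ...) {
  cat(sprintf("<fus_session: %d trace(s), %d event(s), %d fiber(s)%s>\n",
              length(x$traces), nrow(x$events), nrow(x$fibers),
              if (!is.null(x$truth)) ", with ground truth" else ""))
  invisible(x)
}

# Deterministic JSON writer used throughout the container: full precision,
# stable key order, trailing newline so files are diff-able.
write_json_file <- function(x, path) {
  txt <- jsonlite::toJSON(x, dataframe = "columns", auto_unbox = TRUE,
                          digits = NA, null = "null", na = "null",
                          pretty = TRUE)
  writeLines(txt, path, useBytes = TRUE)
  invisible(path)
}

read_json_file <- function(path) {
  jsonlite::fromJSON(readLines(path, warn = FALSE), simplifyVector = TRUE)
}

df_from_json <- function(lst, template) {
  # columns arrive as a named list of equal-length vectors; restore types and
  # NA encoding (JSON null -> NA)
  if (length(lst) == 0 || length(lst[[1]]) == 0) return(template[0, , drop = FALSE])
  out <- template[rep(1L, length(lst[[1]])), , drop = FALSE]
  for (nm in names(template)) {
    v <- lst[[nm]]
    if (is.null(v)) stop("container missing required field '", nm, "'")
    v[vapply(v, is.null, logical(1))] <- NA
    out[[nm]] <- if (is.numeric(template[[nm]])) as.numeric(unlist(v))
                 else if (is.integer(template[[nm]])) as.integer(unlist(v))
                 else as.character(unlist(v))
  }
  out$trial_index <- if ("trial_index" %in% names(out)) as.integer(out$trial_index) else NULL
  rownames(out) <- NULL
  out
}

#' Write a session container to disk
#'
#' The container is a directory: each trace is stored as raw little-endian
#' float64 samples (`traces/<id>.f64`) with a JSON header
#' (`traces/<id>.json`: rate, t0, n), and the event / fiber / instrument /
#' provenance tables as diff-able JSON sidecars. Writing the same session
#' twice produces byte-identical metadata files.
#'
#' @param session A valid `fus_session`.
#' @param path Target directory (created; must not be an existing non-empty
#'   non-container directory).
#' @return The container path, invisibly.
#' @seealso [read_session()]
#' @export
write_session <- function(session, path) {
  validate_session(session)
  dir.create(file.path(path, "traces"), recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create container directory: ", path)
  for (id in names(session$traces)) {
    t <- session$traces[[id]]
    con <- file(file.path(path, "traces", paste0(id, ".f64")), "wb")
    writeBin(t$samples, con, size = 8, endian = "little")
    close(con)
    write_json_file(list(id = id, rate = t$rate, t0 = t$t0,
                         n = length(t$samples), units = "uV"),
                    file.path(path, "traces", paste0(id, ".json")))
  }
  ev <- as.data.frame(session$events)
  write_json_file(as.list(ev), file.path(path, "events.json"))
  write_json_file(as.list(as.data.frame(session$fibers)),
                  file.path(path, "fibers.json"))
  write_json_file(session$instrument, file.path(path, "instrument.json"))
  write_json_file(session$provenance, file.path(path, "provenance.json"))
  if (!is.null(session$truth))
    write_json_file(as.list(as.data.frame(session$truth)),
                    file.path(path, "truth_fibers.json"))
  invisible(path)
}

#' Read a session container from disk
#'
#' Inverse of [write_session()]: metadata round-trips bit-exactly and trace
#' samples exactly (float64 storage).
#'
#' @param path Container directory written by [write_session()].
#' @return A validated `fus_session`.
#' @export
read_session <- function(path) {
  if (!dir.exists(path)) stop("no session container at ", path)
  for (f in c("events.json", "fibers.json", "instrument.json"))
    if (!file.exists(file.path(path, f)))
      stop("container missing required file '", f, "'")
  hdrs <- list.files(file.path(path, "traces"), pattern = "\\.json$",
                     full.names = TRUE)
  traces <- list()
  for (h in hdrs) {
    meta <- read_json_file(h)
    for (nm in c("id", "rate", "n", "t0"))
      if (is.null(meta[[nm]]))
        stop("trace header ", basename(h), " missing required field '", nm, "'")
    if (meta$rate <= 0) stop("trace '", meta$id, "' has non-positive rate")
    binf <- sub("\\.json$", ".f64", h)
    con <- file(binf, "rb")
    smp <- readBin(con, "double", n = meta$n, size = 8, endian = "little")
    close(con)
    if (length(smp) != meta$n)
      stop("trace '", meta$id, "' truncated: expected ", meta$n,
           " samples, read ", length(smp))
    traces[[meta$id]] <- fus_trace(smp, meta$rate, meta$t0, id = meta$id,
                                   strict_rate = FALSE)
  }
  ev_tmpl <- fus_events(numeric(0), character(0), character(0), character(0))
  ev <- df_from_json(read_json_file(file.path(path, "events.json")), ev_tmpl)
  ev <- ev[order(ev$onset, ev$trial_index), , drop = FALSE]
  rownames(ev) <- NULL
  class(ev) <- c("fus_events", "data.frame")
  fb_tmpl <- fus_fibers(character(0))
  fb <- df_from_json(read_json_file(file.path(path, "fibers.json")), fb_tmpl)
  class(fb) <- c("fus_fibers", "data.frame")
  inst <- read_json_file(file.path(path, "instrument.json"))
  prov <- read_json_file(file.path(path, "provenance.json"))
  truth <- NULL
  if (file.exists(file.path(path, "truth_fibers.json"))) {
    tl <- read_json_file(file.path(path, "truth_fibers.json"))
    truth <- as.data.frame(lapply(tl, unlist_na), stringsAsFactors = FALSE)
  }
  fus_session(traces, ev, fb, instrument = inst, provenance = prov,
              truth = truth)
}

unlist_na <- function(v) {
  if (is.list(v)) v[vapply(v, is.null, logical(1))] <- NA
  unlist(v)
}

#' Export session tables to CSV
#'
#' @param session A `fus_session`.
#' @param dir Output directory.
#' @return Character vector of files written.
#' @export
export_session_csv <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(events = file.path(dir, "events.csv"),
             fibers = file.path(dir, "fibers.csv"))
  utils::write.csv(as.data.frame(session$events), files["events"],
                   row.names = FALSE)
  utils::write.csv(as.data.frame(session$fibers), files["fibers"],
                   row.names = FALSE)
  if (!is.null(session$truth)) {
    files <- c(files, truth = file.path(dir, "truth_fibers.csv"))
    utils::write.csv(session$truth, files["truth"], row.names = FALSE)
  }
  files
}
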