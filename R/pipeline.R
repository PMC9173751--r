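#' Pipeline run configuration
#'
#' A run is a pure function of its configuration and seed: cohort
#' generation, recording simulation, sorting, classification, dose-response
#' analysis and group statistics all draw their randomness from `seed`.
#'
#' @param seed Integer master seed.
#' @param cohort A [cohort_config()] (its own seed is overridden by `seed`).
#' @param protocol FUS parameter table from [parameter_grid()].
#' @param instrument [fus_instrument()].
#' @param sites Stimulation sites to run the FUS protocol at.
#' @param n_electrical Electrical presentations per fiber.
#' @param rate Sampling rate, Hz.
#' @param detection_k Spike-detection threshold multiplier.
#' @param nonmonotonic_margin Margin for band-pass tuning detection.
#' @param out_dir Output directory for stage files.
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       cohort = cohort_config(),
                       protocol = parameter_grid(
                         intensities = c(45, 100, 155, 210, 340, 550, 743),
                         durations = 0.75, n_repeats = 5L),
                       instrument = fus_instrument(),
                       sites = "RF", n_electrical = 5L, rate = 20000,
                       detection_k = 5, nonmonotonic_margin = 0.25,
                       out_dir = tempfile("fus_run_")) {
  cohort$seed <- as.integer(seed)
  structure(as.list(environment()), class = "run_config")
}

write_stage_json <- function(x, path) {
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, na = "null", null = "null"),
             path, useBytes = TRUE)
  path
}

#' Physiological profile table implied by a ground-truth cohort
#'
#' Maps each true class to the hair-response and adaptation flags the
#' classification rules key on, so classification can be checked against the
#' generator's labels.
#'
#' @param cohort From [make_cohort()].
#' @return data.frame usable by [classify_afferents()].
#' @export
truth_profiles <- function(cohort) {
  flag <- function(cls) switch(cls,
    AbRA = list(z = FALSE, t = FALSE, ad = "RA"),
    AbSA = list(z = FALSE, t = TRUE, ad = "SA"),
    DH = list(z = TRUE, t = TRUE, ad = "RA"),
    AM = list(z = FALSE, t = FALSE, ad = "SA"),
    C = list(z = FALSE, t = FALSE, ad = "unknown"))
  fl <- lapply(cohort$class_label, flag)
  data.frame(fiber_id = cohort$fiber_id, cv = cohort$cv,
             responds_to_zigzag_hair = vapply(fl, `[[`, logical(1), "z"),
             responds_to_touch_dome_or_hair = vapply(fl, `[[`, logical(1), "t"),
             adaptation = vapply(fl, `[[`, character(1), "ad"),
             true_class = cohort$class_label, stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' Stages: simulate (cohort + recordings) -> sort (template matching per
#' fiber) -> classify -> analyze (response tables, dose-response fits,
#' thresholds, latencies, cumulative profiles) -> compare (group statistics
#' when both genotypes are present). Every stage writes plain CSV/JSON files
#' under `config$out_dir`; the returned manifest lists them with MD5
#' checksums, so identical seeds give identical manifests.
#'
#' @param config A [run_config()].
#' @return The run manifest (list), invisibly also written to
#'   `manifest.json`. On a stage failure the manifest records the stage and
#'   error, and earlier outputs are preserved.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed, stages = list(), files = character(0))
  note <- function(stage, files) {
    manifest$stages[[stage]] <<- list(status = "ok", files = basename(files))
    manifest$files <<- c(manifest$files, files)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      manifest$stages[[stage]] <<- list(status = "error",
                                        message = conditionMessage(e))
      manifest$failed_stage <<- stage
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # simulate
  cohort <- NULL; session <- NULL
  run_stage("simulate", {
    cohort <- make_cohort(config$cohort)
    session <- simulate_session(cohort, config$protocol, config$cohort,
                                instrument = config$instrument,
                                rate = config$rate,
                                n_electrical = config$n_electrical,
                                sites = config$sites)
    write_session(session, file.path(out, "session"))
    f <- export_session_csv(session, out)
    note("simulate", unname(f))
  })

  # sort
  assignments <- NULL; units <- list()
  run_stage("sort", {
    asg <- list()
    for (fid in cohort$fiber_id) {
      grp <- if (is_a_fiber(cohort$class_label[cohort$fiber_id == fid]))
        "A" else "C"
      ev <- session$events[session$events$fiber_id == fid, , drop = FALSE]
      tr <- session$traces[unique(ev$trace_id)]
      u <- sort_unit(tr, ev, fiber_group = grp, k = config$detection_k)
      units[[fid]] <- u
      asg[[fid]] <- u$assignments
    }
    assignments <- do.call(rbind, asg)
    rownames(assignments) <- NULL
    f <- file.path(out, "assignments.csv")
    utils::write.csv(assignments, f, row.names = FALSE)
    note("sort", f)
  })

  # classify
  classified <- NULL
  run_stage("classify", {
    classified <- classify_afferents(truth_profiles(cohort))
    f <- file.path(out, "classified.csv")
    utils::write.csv(classified, f, row.names = FALSE)
    note("classify", f)
  })

  # analyze
  fits <- list(); thresholds <- NULL; latency <- NULL
  run_stage("analyze", {
    r_cm <- config$instrument$focal_radius_cm
    tabs <- lapply(split(assignments, assignments$fiber_id),
                   function(a) response_table(a, focal_radius_cm = r_cm))
    tab_all <- do.call(rbind, lapply(names(tabs), function(id)
      cbind(fiber_id = id, tabs[[id]], stringsAsFactors = FALSE)))
    utils::write.csv(tab_all, file.path(out, "response_tables.csv"),
                     row.names = FALSE)
    # per-fiber thresholds (RF) and fits
    thr_rows <- list()
    for (id in names(tabs)) {
      t_rf <- tabs[[id]][tabs[[id]]$site == "RF", , drop = FALSE]
      t_nt <- tabs[[id]][tabs[[id]]$site == "NT", , drop = FALSE]
      thr_rows[[id]] <- data.frame(
        fiber_id = id,
        threshold_rf_nJ = if (nrow(t_rf)) fus_threshold(t_rf) else NA_real_,
        threshold_nt_nJ = if (nrow(t_nt)) fus_threshold(t_nt) else NA_real_,
        stringsAsFactors = FALSE)
      if (nrow(t_rf) && length(unique(t_rf$energy_nJ)) >= 4 &&
          any(t_rf$probability > 0)) {
        ft <- fit_dose_response(t_rf$energy_nJ, t_rf$probability)
        fits[[id]] <- list(level = "fiber", id = id, max_ap = ft$a,
                           ec50_nJ = ft$b, slope = ft$c, r2 = ft$r2,
                           e50_prob_nJ = ft$e50_prob)
      }
    }
    thresholds <- do.call(rbind, thr_rows)
    thresholds$nt_rf_ratio <- thresholds$threshold_nt_nJ /
      thresholds$threshold_rf_nJ
    utils::write.csv(thresholds, file.path(out, "thresholds.csv"),
                     row.names = FALSE)
    # per-class pooled fits (control arm only): mean probability at each
    # sampled energy
    for (cls in unique(cohort$class_label)) {
      ids <- cohort$fiber_id[cohort$class_label == cls &
                               cohort$genotype == "control"]
      sub <- tab_all[tab_all$fiber_id %in% ids & tab_all$site == "RF", ]
      if (!nrow(sub)) next
      pooled <- do.call(rbind, lapply(split(sub, sub$energy_nJ), function(g)
        data.frame(energy_nJ = g$energy_nJ[1],
                   probability = mean(g$probability))))
      if (nrow(pooled) >= 4 && any(pooled$probability > 0)) {
        ft <- fit_dose_response(pooled$energy_nJ, pooled$probability)
        fits[[paste0("class_", cls)]] <-
          list(level = "class", id = cls, max_ap = ft$a, ec50_nJ = ft$b,
               slope = ft$c, r2 = ft$r2, e50_prob_nJ = ft$e50_prob)
      }
    }
    write_stage_json(fits, file.path(out, "fits.json"))
    # latencies
    latency <- delta_latency(assignments)
    utils::write.csv(latency, file.path(out, "latency_pairs.csv"),
                     row.names = FALSE)
    reg <- tryCatch(latency_regression(latency), error = function(e) NULL)
    lat_sum <- list(median_delta_ms =
                      stats::median(latency$delta_ms, na.rm = TRUE),
                    regression = reg)
    write_stage_json(lat_sum, file.path(out, "latency_summary.json"))
    note("analyze", file.path(out, c("response_tables.csv", "thresholds.csv",
                                     "fits.json", "latency_pairs.csv",
                                     "latency_summary.json")))
  })

  # compare (both genotypes only)
  run_stage("compare", {
    stats_out <- list()
    arms <- split(thresholds$fiber_id,
                  cohort$genotype[match(thresholds$fiber_id,
                                        cohort$fiber_id)])
    if (all(c("control", "piezo2_ko") %in% names(arms))) {
      thr_of <- function(ids) thresholds$threshold_rf_nJ[
        match(ids, thresholds$fiber_id)]
      e_rng <- range(sonication_energy(config$protocol$intensity,
                                       config$protocol$duration,
                                       config$instrument$focal_radius_cm)) * 1e9
      dense_grid <- 10^seq(log10(e_rng[1]), log10(e_rng[2]),
                           length.out = 60)
      for (arm in c("control", "piezo2_ko")) {
        thr <- thr_of(arms[[arm]])
        cr <- tryCatch(cumulative_response(thr, grid = dense_grid),
                       error = function(e) NULL)
        stats_out[[paste0("e50_respond_", arm)]] <-
          if (is.null(cr)) NA else cr$e50_respond
        stats_out[[paste0("n_responsive_", arm)]] <- sum(is.finite(thr))
        stats_out[[paste0("n_total_", arm)]] <- length(thr)
      }
      tab <- rbind(
        c(stats_out$n_responsive_control,
          stats_out$n_total_control - stats_out$n_responsive_control),
        c(stats_out$n_responsive_piezo2_ko,
          stats_out$n_total_piezo2_ko - stats_out$n_responsive_piezo2_ko))
      stats_out$fisher_responsive <- fisher_exact_2x2(tab)
      ratios <- split(thresholds$nt_rf_ratio[is.finite(thresholds$nt_rf_ratio)],
                      cohort$genotype[match(
                        thresholds$fiber_id[is.finite(thresholds$nt_rf_ratio)],
                        cohort$fiber_id)])
      if (length(ratios) == 2 && all(lengths(ratios) >= 2))
        stats_out$t_log2_nt_rf_ratio <-
          t_test_groups(ratios$control, ratios$piezo2_ko,
                        log_transform = "log2")
      f <- write_stage_json(stats_out, file.path(out, "stats.json"))
      note("compare", f)
    } else {
      manifest$stages[["compare"]] <<-
        list(status = "skipped", reason = "single genotype")
    }
  })

  # manifest with checksums over every stage file
  files <- sort(unique(manifest$files))
  sums <- tools::md5sum(files[file.exists(files)])
  manifest$checksums <- stats::setNames(unname(sums), basename(names(sums)))
  manifest$files <- basename(files)
  write_stage_json(manifest, file.path(out, "manifest.json"))
  invisible(manifest)
}

#' Human-readable summary of a pipeline run
#'
#' Tabulates the per-class dose-response fits (Max_AP, EC50, E50-probability),
#' the latency summary, and — when a knockout arm is present — the
#' control-vs-knockout cumulative-response and trunk/field comparisons.
#' Regeneration from the same run directory is idempotent.
#'
#' @param out_dir A completed run's output directory.
#' @return Character vector of report lines, invisibly; printed when
#'   `print = TRUE`.
#' @param print Print the report to the console.
#' @export
make_report <- function(out_dir, print = TRUE) {
  lines <- c("FUS afferent analysis report",
             paste0("run directory: ", out_dir), "")
  fits_f <- file.path(out_dir, "fits.json")
  if (file.exists(fits_f)) {
    fits <- jsonlite::fromJSON(fits_f, simplifyVector = FALSE)
    cls <- Filter(function(f) identical(f$level, "class"), fits)
    if (length(cls)) {
      lines <- c(lines, "Per-class dose-response fits (energies in nJ):",
                 sprintf("  %-6s %8s %10s %8s %8s %12s",
                         "class", "Max_AP", "EC50", "slope", "R2",
                         "E50%Prob"))
      for (f in cls)
        lines <- c(lines, sprintf(
          "  %-6s %8.3f %10.4g %8.3f %8.3f %12s", f$id, f$max_ap, f$ec50_nJ,
          f$slope, f$r2,
          if (is.null(f$e50_prob_nJ) || is.na(f$e50_prob_nJ)) "undefined"
          else sprintf("%.4g", f$e50_prob_nJ)))
    }
  } else lines <- c(lines, "[fits unavailable]")
  lat_f <- file.path(out_dir, "latency_summary.json")
  if (file.exists(lat_f)) {
    lat <- jsonlite::fromJSON(lat_f)
    lines <- c(lines, "", sprintf(
      "Median FUS-electrical latency difference: %.2f ms",
      lat$median_delta_ms))
    if (!is.null(lat$regression))
      lines <- c(lines, sprintf(
        "  log-log latency regression: slope %.3f, intercept %.3f, R2 %.3f",
        lat$regression$slope, lat$regression$intercept, lat$regression$r2))
  } else lines <- c(lines, "", "[latency summary unavailable]")
  stats_f <- file.path(out_dir, "stats.json")
  if (file.exists(stats_f)) {
    st <- jsonlite::fromJSON(stats_f)
    fmt_e50 <- function(v) if (is.null(v) || is.na(v)) "undefined"
               else sprintf("%.4g nJ", v)
    lines <- c(lines, "", "Control vs knockout:",
               sprintf("  E50%%Respond control: %s   knockout: %s",
                       fmt_e50(st$e50_respond_control),
                       fmt_e50(st$e50_respond_piezo2_ko)),
               sprintf("  responsive fibers: %d/%d vs %d/%d (Fisher p = %.3g)",
                       st$n_responsive_control, st$n_total_control,
                       st$n_responsive_piezo2_ko, st$n_total_piezo2_ko,
                       st$fisher_responsive$p))
    if (!is.null(st$t_log2_nt_rf_ratio))
      lines <- c(lines, sprintf(
        "  NT/RF threshold ratio (log2): t = %.3f, p = %.3g",
        st$t_log2_nt_rf_ratio$t, st$t_log2_nt_rf_ratio$p))
  }
  if (print) cat(lines, sep = "\n")
  invisible(lines)
}
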