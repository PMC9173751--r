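#' Sonication energy of a FUS presentation
#'
#' E = I * pi * r^2 * t: intensity (W/cm^2) times the focal cross-sectional
#' area (cm^2) times the stimulus duration (s). The focal radius is an
#' explicit instrument parameter (default 0.0165 cm, half the 0.33 mm
#' free-field focal FWHM) because reported energies scale with the assumed
#' focal area.
#'
#' @param intensity W/cm^2.
#' @param duration_ms Stimulus duration, ms.
#' @param focal_radius_cm Focal radius, cm.
#' @return Energy in joules (multiply by 1e9 for the nJ reporting unit).
#' @export
sonication_energy <- function(intensity, duration_ms,
                              focal_radius_cm = 0.0165) {
  if (any(intensity <= 0) || any(duration_ms <= 0) || any(focal_radius_cm <= 0))
    stop("intensity, duration and focal radius must be positive")
  intensity * pi * focal_radius_cm^2 * (duration_ms / 1000)
}

#' The logistic stimulus-response law
#'
#' y = a / (1 + 10^((log10(b) - x) * c)) with x = log10(dose): `a` is the
#' plateau probability (Max_AP), `b` the dose at half the plateau (EC50, in
#' the dose's units), `c` the slope.
#'
#' @param dose Dose (same units as `b`; energies are reported in nJ).
#' @param a,b,c Law parameters: 0 < a <= 1, b > 0, c > 0.
#' @return Probability values.
#' @export
dose_response_prob <- function(dose, a, b, c) {
  stopifnot(a > 0, a <= 1 + 1e-12, b > 0, c > 0)
  a / (1 + 10^((log10(b) - log10(dose)) * c))
}

#' Per-fiber response probability table
#'
#' One row per distinct FUS parameter set (intensity, duration, site):
#' stimulus and evoked-spike counts, their exact fraction, and the
#' sonication energy of the set.
#'
#' @param assignments Per-event assignment table from [sort_unit()] (columns
#'   `modality`, `intensity`, `duration`, `site`, `spike_time`).
#' @param focal_radius_cm Focal radius for the energy transform.
#' @return data.frame: intensity, duration, site, n_stimuli, n_spikes,
#'   probability, energy_J, energy_nJ; ordered by energy.
#' @export
response_table <- function(assignments, focal_radius_cm = 0.0165) {
  if (!"spike_time" %in% names(assignments))
    stop("assignments lack a spike_time record")
  fus <- assignments[assignments$modality == "fus", , drop = FALSE]
  if (!nrow(fus)) stop("no fus events in the assignment table")
  key <- interaction(fus$intensity, fus$duration, fus$site, drop = TRUE)
  rows <- lapply(split(fus, key), function(g) {
    data.frame(intensity = g$intensity[1], duration = g$duration[1],
               site = g$site[1], n_stimuli = nrow(g),
               n_spikes = sum(!is.na(g$spike_time)),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$probability <- tab$n_spikes / tab$n_stimuli
  tab$energy_J <- sonication_energy(tab$intensity, tab$duration,
                                    focal_radius_cm)
  tab$energy_nJ <- tab$energy_J * 1e9
  tab <- tab[order(tab$energy_nJ, tab$intensity), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

# ---- scattered linear interpolation (Bowyer-Watson Delaunay) ----------------

circumcircle_contains <- function(tri_pts, p) {
  # TRUE when p lies inside the circumcircle of the triangle (counterclockwise)
  ax <- tri_pts[1, 1] - p[1]; ay <- tri_pts[1, 2] - p[2]
  bx <- tri_pts[2, 1] - p[1]; by <- tri_pts[2, 2] - p[2]
  cx <- tri_pts[3, 1] - p[1]; cy <- tri_pts[3, 2] - p[2]
  det <- (ax^2 + ay^2) * (bx * cy - cx * by) -
         (bx^2 + by^2) * (ax * cy - cx * ay) +
         (cx^2 + cy^2) * (ax * by - bx * ay)
  det > 1e-12
}

orient_ccw <- function(pts, tri) {
  a <- pts[tri[1], ]; b <- pts[tri[2], ]; c <- pts[tri[3], ]
  cross <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  if (cross < 0) tri[c(1, 3, 2)] else tri
}

delaunay_triangulate <- function(pts) {
  # Bowyer-Watson incremental triangulation; pts is an n x 2 matrix of
  # distinct points (assumed pre-normalized to comparable scales).
  n <- nrow(pts)
  if (n < 3) return(matrix(integer(0), 0, 3))
  m <- max(abs(pts)) + 1
  super <- matrix(c(-4 * m, -4 * m, 4 * m, -4 * m, 0, 4 * m),
                  ncol = 2, byrow = TRUE)
  allp <- rbind(super, pts)
  tris <- list(orient_ccw(allp, c(1L, 2L, 3L)))
  for (ip in 4:(n + 3)) {
    p <- allp[ip, ]
    bad <- vapply(tris, function(tr)
      circumcircle_contains(allp[tr, , drop = FALSE], p), logical(1))
    if (!any(bad)) next
    # boundary of the cavity: edges of bad triangles not shared by two of them
    edges <- do.call(rbind, lapply(tris[bad], function(tr)
      rbind(tr[c(1, 2)], tr[c(2, 3)], tr[c(3, 1)])))
    tris <- tris[!bad]
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    keep <- !(key %in% key[duplicated(key)])
    for (e in which(keep))
      tris <- c(tris, list(orient_ccw(allp, c(edges[e, ], ip))))
  }
  tris <- Filter(function(tr) all(tr > 3L), tris)
  if (!length(tris)) return(matrix(integer(0), 0, 3))
  t(vapply(tris, function(tr) tr - 3L, integer(3)))
}

barycentric <- function(p1, p2, p3, qx, qy) {
  det <- (p2[2] - p3[2]) * (p1[1] - p3[1]) + (p3[1] - p2[1]) * (p1[2] - p3[2])
  l1 <- ((p2[2] - p3[2]) * (qx - p3[1]) + (p3[1] - p2[1]) * (qy - p3[2])) / det
  l2 <- ((p3[2] - p1[2]) * (qx - p3[1]) + (p1[1] - p3[1]) * (qy - p3[2])) / det
  cbind(l1, l2, 1 - l1 - l2)
}

interp_linear_scattered <- function(x, y, z, xo, yo) {
  # piecewise-linear interpolation on the Delaunay triangulation; NA outside
  # the convex hull. Coordinates are normalized to [0, 1] before
  # triangulating so duration (ms) and intensity (W/cm^2) scales are
  # comparable.
  sx <- function(v, r) if (diff(r) == 0) rep(0.5, length(v))
                       else (v - r[1]) / diff(r)
  rx <- range(x); ry <- range(y)
  pts <- cbind(sx(x, rx), sx(y, ry))
  tris <- delaunay_triangulate(pts)
  grid <- expand.grid(xo = sx(xo, rx), yo = sx(yo, ry))
  out <- rep(NA_real_, nrow(grid))
  if (nrow(tris) == 0) return(matrix(out, nrow = length(xo)))
  eps <- 1e-9
  for (ti in seq_len(nrow(tris))) {
    tr <- tris[ti, ]
    lam <- barycentric(pts[tr[1], ], pts[tr[2], ], pts[tr[3], ],
                       grid$xo, grid$yo)
    inside <- is.na(out) & lam[, 1] >= -eps & lam[, 2] >= -eps &
      lam[, 3] >= -eps
    if (any(inside))
      out[inside] <- lam[inside, , drop = FALSE] %*% z[tr]
  }
  matrix(out, nrow = length(xo))
}

#' Aggregate per-fiber probabilities into a parameter-space surface
#'
#' Parameter sets are pooled across fibers: only sets delivered to at least
#' two fibers are retained, and their probabilities averaged. The sampled
#' points are then linearly interpolated on the Delaunay triangulation of
#' (duration, intensity) onto a regular grid; no extrapolation occurs
#' outside the convex hull (NA there), and interpolated probabilities are
#' clamped to \[0, 1\].
#'
#' @param tables Either a list of per-fiber [response_table()]s or a single
#'   data.frame carrying a `fiber_id` column.
#' @param grid_n Grid resolution per axis.
#' @param min_fibers Minimum fibers per retained parameter set.
#' @return List of class `surface_grid`: `sampled` (duration, intensity,
#'   probability, n_fibers), `duration`, `intensity` (grid axes),
#'   `probability` (matrix duration x intensity), `interpolated` flag.
#' @export
aggregate_surface <- function(tables, grid_n = 101, min_fibers = 2) {
  if (is.data.frame(tables)) {
    stopifnot("fiber_id" %in% names(tables))
    df <- tables
  } else {
    stopifnot(length(tables) >= 1)
    df <- do.call(rbind, lapply(seq_along(tables), function(i) {
      t <- tables[[i]]
      t$fiber_id <- if (!is.null(names(tables))) names(tables)[i]
                    else as.character(i)
      t
    }))
  }
  if (length(unique(df$fiber_id)) < 2)
    stop("surface aggregation requires at least two fibers")
  key <- interaction(df$duration, df$intensity, drop = TRUE)
  agg <- do.call(rbind, lapply(split(df, key), function(g)
    data.frame(duration = g$duration[1], intensity = g$intensity[1],
               probability = mean(g$probability),
               n_fibers = length(unique(g$fiber_id)))))
  agg <- agg[agg$n_fibers >= min_fibers, , drop = FALSE]
  agg <- agg[order(agg$duration, agg$intensity), , drop = FALSE]
  rownames(agg) <- NULL
  res <- list(sampled = agg, interpolated = FALSE)
  pts <- unique(agg[, c("duration", "intensity")])
  collinear <- nrow(pts) < 3 ||
    all(pts$duration == pts$duration[1]) ||
    all(pts$intensity == pts$intensity[1]) ||
    qr(cbind(1, as.matrix(pts)))$rank < 3
  if (collinear) {
    warning("fewer than 3 non-collinear retained parameter sets; ",
            "returning sampled points without interpolation")
  } else {
    dur_axis <- seq(min(agg$duration), max(agg$duration), length.out = grid_n)
    int_axis <- seq(min(agg$intensity), max(agg$intensity),
                    length.out = grid_n)
    z <- interp_linear_scattered(agg$duration, agg$intensity,
                                 agg$probability, dur_axis, int_axis)
    z[!is.na(z)] <- pmin(1, pmax(0, z[!is.na(z)]))
    res$duration <- dur_axis
    res$intensity <- int_axis
    res$probability <- z
    res$interpolated <- TRUE
  }
  class(res) <- "surface_grid"
  res
}

# ---- dose-response fitting --------------------------------------------------

#' Fit the logistic stimulus-response law
#'
#' Bounded nonlinear least squares of y = a / (1 + 10^((log10(b) - x) * c))
#' on x = log10(dose), with 0 < a <= 1, b > 0, c > 0. Initialization:
#' a0 = max observed probability, b0 = dose at the first crossing of a0/2
#' (linear interpolation), c0 = 1; three additional perturbed starts guard
#' against local minima and the best (lowest SSE) solution is kept.
#'
#' @param doses Positive doses (use nJ for sonication energies).
#' @param probabilities Observed probabilities in \[0, 1\].
#' @param weights Optional per-point weights (e.g. n_stimuli); unweighted by
#'   default.
#' @return List of class `dose_response_fit`: `a` (Max_AP), `b` (EC50, dose
#'   units), `c` (slope), `r2`, `e50_prob` (dose at absolute probability
#'   0.5; NA with a flag when a <= 0.5), `insensitive`, `fitted`,
#'   `residuals`, `converged`.
#' @export
fit_dose_response <- function(doses, probabilities, weights = NULL) {
  stopifnot(length(doses) == length(probabilities))
  if (any(doses <= 0)) stop("doses must be positive")
  if (any(probabilities < 0 | probabilities > 1))
    stop("probabilities must lie in [0, 1]")
  if (length(unique(doses)) < 4)
    stop("need at least 4 distinct doses to fit three parameters")
  if (all(probabilities == 0)) {
    out <- list(a = NA_real_, b = NA_real_, c = NA_real_, r2 = NA_real_,
                e50_prob = NA_real_, insensitive = TRUE, converged = FALSE)
    class(out) <- "dose_response_fit"
    return(out)
  }
  if (is.null(weights)) weights <- rep(1, length(doses))
  x <- log10(doses)
  y <- probabilities
  sw <- sqrt(weights)
  resid_fun <- function(par) {
    yhat <- par[1] / (1 + 10^((par[2] - x) * par[3]))
    sw * (y - yhat)
  }
  a0 <- min(1, max(y))
  b0 <- {
    ord <- order(x)
    cross <- which(y[ord] >= a0 / 2)
    if (length(cross)) {
      i <- cross[1]
      if (i == 1) 10^x[ord][1]
      else {
        x1 <- x[ord][i - 1]; x2 <- x[ord][i]
        y1 <- y[ord][i - 1]; y2 <- y[ord][i]
        10^(x1 + (a0 / 2 - y1) / (y2 - y1) * (x2 - x1))
      }
    } else stats::median(doses)
  }
  starts <- list(c(a0, log10(b0), 1),
                 c(a0, log10(b0 * 3), 0.5),
                 c(a0, log10(max(b0 / 3, 1e-6)), 2),
                 c(max(0.5, a0 * 0.8), log10(b0), 1))
  lower <- c(1e-6, log10(min(doses)) - 6, 1e-6)
  upper <- c(1, log10(max(doses)) + 6, 100)
  best <- NULL
  for (st in starts) {
    st <- pmin(pmax(st, lower), upper)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = lower, upper = upper,
                         fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           ftol = 1e-10, ptol = 1e-10, maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop("dose-response fit failed to converge from any start; ",
         "doses span [", min(doses), ", ", max(doses), "], max probability ",
         max(y))
  par <- best$par
  a <- par[1]; b <- 10^par[2]; c <- par[3]
  yhat <- a / (1 + 10^((par[2] - x) * c))
  ss_res <- sum(weights * (y - yhat)^2)
  ybar <- sum(weights * y) / sum(weights)
  ss_tot <- sum(weights * (y - ybar)^2)
  out <- list(a = a, b = b, c = c,
              r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
              insensitive = FALSE, fitted = yhat, residuals = y - yhat,
              converged = best$info %in% 1:4)
  out$e50_prob <- if (a > 0.5) e50_prob(out) else NA_real_
  class(out) <- "dose_response_fit"
  out
}

#' @export
print.dose_response_fit <- function(x, ...) {
  if (isTRUE(x$insensitive)) {
    cat("<dose_response_fit: insensitive (all probabilities zero); no fit>\n")
  } else {
    cat(sprintf(paste0("<dose_response_fit: Max_AP = %.3f, EC50 = %.4g, ",
                       "slope = %.3f, R2 = %.3f, E50%%Prob = %s>\n"),
                x$a, x$b, x$c, x$r2,
                if (is.na(x$e50_prob)) "undefined (Max_AP <= 0.5)"
                else sprintf("%.4g", x$e50_prob)))
  }
  invisible(x)
}

#' Dose at absolute probability 0.5 (half-maximal relative to 1.0)
#'
#' Solves y = 0.5 of the fitted law in closed form:
#' dose = 10^(log10(b) - log10(2a - 1) / c). Defined only when the plateau
#' exceeds 0.5; equals the EC50 exactly when a = 1, and exceeds it whenever
#' 0.5 < a < 1.
#'
#' @param fit A `dose_response_fit`, or any list with elements `a`, `b`, `c`.
#' @return The dose (same units as `b`), or NA when a <= 0.5 (the fiber's
#'   fitted probability never reaches 50%).
#' @export
e50_prob <- function(fit) {
  a <- fit$a; b <- fit$b; c <- fit$c
  if (is.na(a) || a <= 0.5) return(NA_real_)
  if (a == 1) return(b)  # log10(2a - 1) = 0: the exact algebraic case
  10^(log10(b) - log10(2 * a - 1) / c)
}

#' FUS activation threshold from a response table
#'
#' The first (lowest) sonication energy that evoked action potentials in
#' strictly more than 50% of its presentations. Ties in energy keep
#' presentation order. Returns NA (insensitive) when no energy qualifies.
#'
#' @param table [response_table()] rows (needs `energy_nJ` or `energy`,
#'   `probability`, `n_stimuli`).
#' @return Threshold energy (nJ when `energy_nJ` is present), or NA.
#' @export
fus_threshold <- function(table) {
  ecol <- if ("energy_nJ" %in% names(table)) "energy_nJ" else "energy"
  stopifnot(ecol %in% names(table), "probability" %in% names(table))
  if ("n_stimuli" %in% names(table) && any(table$n_stimuli < 4))
    warning("fewer than 4 presentations for some energies")
  e <- table[[ecol]]
  if (is.unsorted(e, strictly = FALSE)) {
    warning("response table not ordered by energy; sorting internally")
    ord <- order(e)
    table <- table[ord, , drop = FALSE]
    e <- e[ord]
  }
  hit <- which(table$probability > 0.5)
  if (!length(hit)) return(NA_real_)
  e[hit[1]]
}

# ---- latency ----------------------------------------------------------------

#' Spike latency from stimulus onset
#' @param onset Event onset(s), s.
#' @param spike_time Assigned spike peak time(s), s (NA when no spike).
#' @return Latency in ms (NA propagates).
#' @export
latency_ms <- function(onset, spike_time) (spike_time - onset) * 1000

#' Per-fiber FUS-vs-electrical latency pairs
#'
#' Summarizes each fiber's assigned spike latencies per modality (median
#' across presentations) and their difference; the population median of
#' `delta_ms` is the headline FUS-vs-electrical transduction-delay
#' statistic.
#'
#' @param assignments Assignment table(s) from [sort_unit()] — one
#'   data.frame or a list (one per fiber).
#' @return data.frame: fiber_id, fus_latency_ms, electrical_latency_ms,
#'   delta_ms (rows with either latency missing are NA-propagated).
#' @export
delta_latency <- function(assignments) {
  if (!is.data.frame(assignments)) assignments <- do.call(rbind, assignments)
  rows <- lapply(split(assignments, assignments$fiber_id), function(g) {
    fl <- g$latency_ms[g$modality == "fus" & !is.na(g$spike_time)]
    el <- g$latency_ms[g$modality == "electrical" & !is.na(g$spike_time)]
    data.frame(fiber_id = g$fiber_id[1],
               fus_latency_ms = if (length(fl)) stats::median(fl) else NA_real_,
               electrical_latency_ms =
                 if (length(el)) stats::median(el) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$delta_ms <- out$fus_latency_ms - out$electrical_latency_ms
  rownames(out) <- NULL
  out
}

#' Log-log regression of FUS on electrical latencies
#'
#' Ordinary least squares of log10(FUS latency) on log10(electrical
#' latency). A purely additive transduction delay yields a slope below 1
#' with a positive intercept on this scale.
#'
#' @param pairs Output of [delta_latency()] (or any data.frame with
#'   `fus_latency_ms` and `electrical_latency_ms`).
#' @return List: slope, intercept, r2, n.
#' @export
latency_regression <- function(pairs) {
  ok <- is.finite(pairs$fus_latency_ms) & is.finite(pairs$electrical_latency_ms)
  bad <- ok & (pairs$fus_latency_ms <= 0 | pairs$electrical_latency_ms <= 0)
  if (any(bad)) {
    warning(sum(bad), " pair(s) with non-positive latency excluded")
    ok <- ok & !bad
  }
  if (sum(ok) < 3) stop("need at least 3 positive latency pairs")
  lx <- log10(pairs$electrical_latency_ms[ok])
  ly <- log10(pairs$fus_latency_ms[ok])
  fit <- stats::lm(ly ~ lx)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = summary(fit)$r.squared, n = sum(ok))
}

# ---- population / cumulative analysis ---------------------------------------

#' Cumulative response profile and E50-Respond
#'
#' For a population of per-fiber activation thresholds (NA = insensitive
#' fiber, still counted in the denominator), computes the cumulative
#' responding fraction over a stimulus grid and fits it with the same
#' logistic law; `e50_respond` is the stimulus magnitude at which the fitted
#' fraction reaches 0.5.
#'
#' @param thresholds Per-fiber thresholds (NA for fibers that never
#'   responded).
#' @param grid Stimulus magnitudes to evaluate the cumulative fraction at;
#'   defaults to the sorted unique finite thresholds.
#' @param min_fibers Minimum population size.
#' @return List of class `cumulative_response`: `grid`, `fraction`,
#'   `n_total`, `n_responsive`, `fit` (NULL if all insensitive),
#'   `e50_respond`.
#' @export
cumulative_response <- function(thresholds, grid = NULL, min_fibers = 5) {
  n_total <- length(thresholds)
  if (n_total < min_fibers)
    stop("cumulative response requires at least ", min_fibers, " fibers")
  thr <- thresholds[is.finite(thresholds)]
  if (is.null(grid)) grid <- sort(unique(thr))
  frac <- vapply(grid, function(x) sum(thr <= x) / n_total, numeric(1))
  out <- list(grid = grid, fraction = frac, n_total = n_total,
              n_responsive = length(thr), fit = NULL,
              e50_respond = NA_real_)
  if (length(thr) == 0) {
    warning("all fibers insensitive; no cumulative fit")
  } else if (length(unique(grid)) >= 4) {
    out$fit <- fit_dose_response(grid, frac)
    out$e50_respond <- e50_prob(out$fit)
  } else {
    warning("fewer than 4 distinct grid points; cumulative fraction ",
            "returned without a fit")
  }
  class(out) <- "cumulative_response"
  out
}

#' @export
print.cumulative_response <- function(x, ...) {
  cat(sprintf(paste0("<cumulative_response: %d/%d fibers responsive, ",
                     "E50%%Respond = %s>\n"),
              x$n_responsive, x$n_total,
              if (is.na(x$e50_respond)) "undefined"
              else sprintf("%.4g", x$e50_respond)))
  invisible(x)
}

#' Detect non-monotonic (band-pass) energy tuning
#'
#' Some fibers' spike probability first rises and then falls as sonication
#' energy increases. The rule: tuning is non-monotonic when the maximum
#' probability exceeds the probability at the highest energy by more than
#' `margin`, and the maximum is not at the lowest energy.
#'
#' @param table Response table ordered by energy (`energy_nJ` or `energy`,
#'   `probability`).
#' @param margin Required drop from peak to the highest-energy probability.
#' @return List: `nonmonotonic` (logical), `peak_energy`, `peak_probability`,
#'   `drop`.
#' @export
detect_nonmonotonic <- function(table, margin = 0.25) {
  ecol <- if ("energy_nJ" %in% names(table)) "energy_nJ" else "energy"
  stopifnot(nrow(table) >= 3)
  tab <- table[order(table[[ecol]]), , drop = FALSE]
  p <- tab$probability
  imax <- which.max(p)
  drop <- p[imax] - p[length(p)]
  list(nonmonotonic = (drop > margin) && imax > 1,
       peak_energy = tab[[ecol]][imax], peak_probability = p[imax],
       drop = drop)
}

#' Full width at half maximum of a 1-D beam profile
#'
#' Linear-interpolated width between the two half-maximum crossings of a
#' single-peaked profile (e.g. a hydrophone raster line through the focus).
#'
#' @param position Positions (mm), ascending.
#' @param amplitude Profile amplitudes (>= 0), single-peaked.
#' @return FWHM in the position units.
#' @export
beam_fwhm <- function(position, amplitude) {
  stopifnot(length(position) == length(amplitude), length(position) >= 3)
  if (is.unsorted(position, strictly = TRUE))
    stop("positions must be strictly ascending")
  ipk <- which.max(amplitude)
  half <- amplitude[ipk] / 2
  left <- cross_time(amplitude, half, ipk, 1L)
  right <- cross_time(amplitude, half, ipk, length(amplitude))
  if (is.na(left) || is.na(right))
    stop("profile does not fall to half maximum on both sides of the peak")
  interp_pos <- function(fidx) {
    i <- floor(fidx); frac <- fidx - i
    if (i >= length(position)) position[length(position)]
    else position[i] + frac * (position[i + 1] - position[i])
  }
  interp_pos(right) - interp_pos(left)
}
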