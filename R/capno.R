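# Per-breath volumetric capnogram construction and every derived shape
# factor and dead-space index.

#' Per-breath capnogram index record
#'
#' Container for the full set of per-breath results. Optional arterial
#' quantities (`vde_frac`, `pa_a_co2`, `shunt_frac`) are `NA` when no
#' arterial PaCO2 is available.
#'
#' @param s2v,s3v Phase-2 and phase-3 slopes, mmHg/ml.
#' @param sn2v,sn3v Slopes normalized by end-tidal CO2, 1/ml.
#' @param etco2 End-tidal CO2, mmHg.
#' @param vdf,vdf_frac Fowler (anatomical) dead space, ml, and its fraction
#'   of tidal volume.
#' @param vdb_frac,vde_frac Bohr and Enghoff dead-space fractions.
#' @param paco2_alv Mean alveolar CO2 (phase-3 midpoint value), mmHg.
#' @param pe_co2 Mixed-expired CO2, mmHg.
#' @param vt Expired tidal volume, ml.
#' @param vco2 Expired CO2 volume per breath, ml.
#' @param pa_a_co2 Arterial--alveolar CO2 gradient, mmHg.
#' @param shunt_frac `vde_frac - vdb_frac`.
#' @param v_inflect Phase-2 inflection volume, ml.
#' @param phase3_bounds Numeric length-2: phase-3 start and end volumes, ml.
#' @param breath_id Provenance index of the breath within its recording.
#' @param flags Character vector of QC flags raised during analysis.
#' @return An object of class `"capno_indices"`.
#' @export
new_capno_indices <- function(s2v, s3v, sn2v, sn3v, etco2, vdf, vdf_frac,
                              vdb_frac, vde_frac = NA_real_, paco2_alv,
                              pe_co2, vt, vco2, pa_a_co2 = NA_real_,
                              shunt_frac = NA_real_, v_inflect,
                              phase3_bounds, breath_id = NA_integer_,
                              flags = character(0)) {
  structure(list(s2v = s2v, s3v = s3v, sn2v = sn2v, sn3v = sn3v,
                 etco2 = etco2, vdf = vdf, vdf_frac = vdf_frac,
                 vdb_frac = vdb_frac, vde_frac = vde_frac,
                 paco2_alv = paco2_alv, pe_co2 = pe_co2, vt = vt,
                 vco2 = vco2, pa_a_co2 = pa_a_co2, shunt_frac = shunt_frac,
                 v_inflect = v_inflect, phase3_bounds = phase3_bounds,
                 breath_id = breath_id, flags = flags),
            class = "capno_indices")
}

# scalar index columns in output tables
capno_index_cols <- c("s2v", "s3v", "sn2v", "sn3v", "etco2", "vdf",
                      "vdf_frac", "vdb_frac", "vde_frac", "paco2_alv",
                      "pe_co2", "vt", "vco2", "pa_a_co2", "shunt_frac",
                      "v_inflect")

#' @export
as.data.frame.capno_indices <- function(x, ...) {
  d <- as.data.frame(x[capno_index_cols])
  d$phase3_start <- x$phase3_bounds[1]
  d$phase3_end <- x$phase3_bounds[2]
  d$breath_id <- x$breath_id
  d$flags <- paste(x$flags, collapse = "; ")
  d
}

#' @export
print.capno_indices <- function(x, ...) {
  cat("Per-breath capnogram indices\n")
  cat(sprintf("  S2V %.2f  S3V %.3f mmHg/ml   Sn2V %.4f  Sn3V %.4f 1/ml\n",
              x$s2v, x$s3v, x$sn2v, x$sn3v))
  cat(sprintf("  ETCO2 %.2f  PACO2 %.2f  PECO2 %.2f mmHg\n",
              x$etco2, x$paco2_alv, x$pe_co2))
  cat(sprintf("  VDF %.3f ml (%.3f of VT)  VDB/VT %.3f  VDE/VT %s\n",
              x$vdf, x$vdf_frac, x$vdb_frac,
              ifelse(is.na(x$vde_frac), "NA", sprintf("%.3f", x$vde_frac))))
  cat(sprintf("  VT %.3f ml  VCO2 %.4f ml\n", x$vt, x$vco2))
  invisible(x)
}

#' Build the volumetric capnogram of one breath
#'
#' Maps the expiratory CO2 samples onto cumulative expired volume (obtained
#' by integrating tracheal airflow) and interpolates onto a uniform volume
#' grid. Where measurement noise makes the volume locally non-monotone,
#' samples at duplicated volumes are merged by averaging before
#' interpolation.
#'
#' @param series A delay-corrected [gas_time_series()].
#' @param breath One breath from [segment_breaths()].
#' @param volume Raw cumulative volume from [integrate_flow()]; computed if
#'   missing.
#' @param n_grid Minimum number of uniform grid points (at least 200; the
#'   number of expiratory samples is used when larger).
#' @return An object of class `"vol_capnogram"`: list with `v` (ml, uniform
#'   from 0 to `vt`), `pco2` (mmHg), `vt` (ml), `breath_id`.
#' @export
build_capnogram <- function(series, breath, volume = NULL, n_grid = 200L) {
  validate_gas_time_series(series)
  if (is.null(volume)) volume <- integrate_flow(series)$raw
  idx <- breath$i_exp_start:(breath$i_exp_end - 1L)
  # trailing samples whose flow magnitude sits inside the segmentation
  # hysteresis band can already carry inspiratory gas (the phase boundary is
  # ambiguous there under flow noise); trim them so washed-in fresh gas
  # never lands at the top of the volume axis
  thr <- 0.05 * max(abs(series$flow))
  good <- abs(series$flow[idx]) >= thr
  last_good <- max(which(good), 1L)
  idx <- idx[seq_len(last_good)]
  if (length(idx) < 10L) {
    stop("build_capnogram: expiration shorter than 10 samples (breath at ",
         breath$i_exp_start, ")")
  }
  v_exp <- volume[breath$i_exp_start] - volume[idx]
  p <- series$pco2[idx]
  # the expired gas volume runs to the expiration/inspiration boundary, not
  # to the last untrimmed sample
  vt <- volume[breath$i_exp_start] - volume[breath$i_exp_end]
  vt <- max(vt, max(v_exp))
  if (!(vt > 0)) stop("build_capnogram: nonpositive expired volume")
  ng <- max(as.integer(n_grid), length(idx))
  grid <- seq(0, vt, length.out = ng)
  # sort by volume and merge duplicated volumes by averaging, then
  # interpolate with a shape-preserving monotone Hermite spline: it renders
  # a sharp sigmoid far better than linear interpolation where high flow
  # leaves few samples across the transition, yet cannot overshoot on noise
  ord <- order(v_exp)
  vs <- v_exp[ord]; ps <- p[ord]
  if (any(duplicated(vs))) {
    ps <- as.numeric(tapply(ps, match(vs, vs), mean))
    vs <- unique(vs)
  }
  fn <- stats::splinefun(vs, ps, method = "monoH.FC")
  pg <- fn(pmin(pmax(grid, vs[1]), vs[length(vs)]))
  structure(list(v = grid, pco2 = pg, vt = vt,
                 breath_id = if (!is.null(breath$id)) breath$id else NA_integer_),
            class = "vol_capnogram")
}

# odd Savitzky-Golay window length for a volume window in ml
sg_window <- function(cap, smooth_window) {
  dv <- cap$v[2] - cap$v[1]
  w <- round(smooth_window / dv)
  w <- max(5L, as.integer(w))
  if (w %% 2L == 0L) w <- w + 1L
  min(w, length(cap$v) - (1L - length(cap$v) %% 2L))
}

#' Locate the phase-2 inflection and its slope
#'
#' Estimates dP/dV by local quadratic (Savitzky--Golay) smoothing over a
#' volume window and takes the inflection as the largest interior local
#' maximum of the smoothed derivative within the first 75% of expired
#' volume; the phase-2 slope S2V is that maximum. Restricting to interior
#' local peaks rejects spurious boundary spikes (start-of-expiration sensor
#' transients under slow early flow); the 75% cap leaves room for
#' small-animal recordings where the apparatus dead space pushes the
#' transition deep into the breath. Ties break to the smallest volume.
#'
#' @param cap A [build_capnogram()] result.
#' @param smooth_window Smoothing window in ml; default `vt / 20`.
#' @param search_frac Fraction of expired volume searched for the
#'   inflection (default 0.75).
#' @return List with `v_inflect` (ml) and `s2v` (mmHg/ml).
#' @export
find_phase2_inflection <- function(cap, smooth_window = cap$vt / 20,
                                   search_frac = 0.75) {
  if (diff(range(cap$pco2)) < 10) {
    stop("find_phase2_inflection: no sigmoid transition (CO2 rise < 10 mmHg)")
  }
  w <- sg_window(cap, smooth_window)
  dv <- cap$v[2] - cap$v[1]
  dp <- signal::sgolayfilt(cap$pco2, p = 2, n = w, m = 1, ts = dv)
  m <- sum(cap$v <= search_frac * cap$vt)
  if (m < 3L) stop("find_phase2_inflection: search region too short")
  if (diff(range(dp[1:m])) < 0.05 * max(abs(dp[1:m]))) {
    stop("find_phase2_inflection: no sigmoid transition (derivative is flat)")
  }
  i <- 2:(m - 1L)
  is_peak <- dp[i] > dp[i - 1L] & dp[i] >= dp[i + 1L]
  peaks <- i[is_peak]
  if (length(peaks) == 0L) {
    stop("find_phase2_inflection: no sigmoid transition (monotone derivative)")
  }
  best <- peaks[which.max(dp[peaks])]
  # two-stage slope: the wide window locates the inflection robustly but
  # attenuates a sharp transition; re-estimate the slope at the located
  # index with half the window (evaluating at a fixed index adds no
  # extremum-selection bias)
  w2 <- sg_window(cap, smooth_window / 2)
  dp2 <- signal::sgolayfilt(cap$pco2, p = 2, n = w2, m = 1, ts = dv)
  list(v_inflect = cap$v[best], s2v = max(dp2[best], dp[best]))
}

#' Phase-3 bounds by decay of the transition slope
#'
#' Phase 3 is taken to start where the phase-2 transition has died out:
#' the smallest volume past the inflection where the smoothed slope dP/dV
#' has descended to within 4% of its plateau-to-peak excess and stays there
#' for 5% of the tidal volume; it ends at end-expiration. On a logistic
#' transition this point coincides with the volume where the curvature
#' `|d2P/dV2|` has decayed below 10% of its peak, but a first-derivative
#' detector amplifies measurement noise far less than a second-derivative
#' one, so the slope form is used on data (the clean-profile oracle applies
#' the curvature form directly). The onset is clamped below 80% of the
#' tidal volume; if the criterion is never met, a fallback extrapolates
#' the transition width from the 25%-of-rise point and the result is
#' flagged low-confidence.
#'
#' @param cap A [build_capnogram()] result.
#' @param v_inflect Inflection volume from [find_phase2_inflection()].
#' @param smooth_window Slope smoothing window in ml; default `vt / 20`.
#'   The onset detector smooths over `detect_factor * smooth_window`.
#' @param detect_factor Multiplier on `smooth_window` for the onset
#'   detector (default 3).
#' @param decay_frac Residual fraction of the plateau-to-peak slope excess
#'   defining phase-3 onset (default 0.04, the first-derivative counterpart
#'   of a 10%-of-peak curvature decay on a logistic).
#' @return List with `v3_start`, `v3_end` (ml) and `flags` (character).
#' @export
phase3_bounds <- function(cap, v_inflect, smooth_window = cap$vt / 20,
                          detect_factor = 3, decay_frac = 0.04) {
  w <- sg_window(cap, detect_factor * smooth_window)
  dv <- cap$v[2] - cap$v[1]
  dp <- signal::sgolayfilt(cap$pco2, p = 2, n = w, m = 1, ts = dv)
  flags <- character(0)
  # provisional plateau slope from the final third of expiration
  sel3 <- cap$v >= 2 * cap$vt / 3
  vx <- cap$v[sel3]; py <- cap$pco2[sel3]
  s3_init <- sum((vx - mean(vx)) * (py - mean(py))) / sum((vx - mean(vx))^2)
  after <- which(cap$v > v_inflect)
  v3_start <- NA_real_
  if (length(after) > 2L) {
    peak <- max(dp[seq_len(after[1])])   # transition peak of the smoothed slope
    excess <- peak - s3_init
    if (excess > 0) {
      below <- dp[after] - s3_init <= decay_frac * excess
      k <- max(1L, ceiling(0.05 * cap$vt / dv))
      nb <- length(below)
      if (nb >= k) {
        run <- cumsum(below)
        sums <- run[k:nb] - c(0, run[seq_len(nb - k)])
        j <- which(sums == k)
        if (length(j) > 0L) v3_start <- cap$v[after][j[1]]
      }
    }
  }
  if (is.na(v3_start)) {
    # fallback: mirror the 25%-of-rise point through the inflection
    w1 <- sg_window(cap, smooth_window)
    dp <- signal::sgolayfilt(cap$pco2, p = 2, n = w1, m = 1, ts = dv)
    s2v <- max(dp[cap$v <= 0.6 * cap$vt])
    before <- which(cap$v < v_inflect & dp >= 0.25 * s2v)
    v25 <- if (length(before) > 0L) cap$v[before[1]] else v_inflect / 2
    v3_start <- v_inflect + 2 * (v_inflect - v25)
    flags <- c(flags, "phase3_onset_low_confidence")
  }
  if (v3_start >= 0.8 * cap$vt) {
    v3_start <- 0.8 * cap$vt - dv
    flags <- c(flags, "phase3_onset_clamped")
  }
  list(v3_start = v3_start, v3_end = cap$vt, flags = flags)
}

#' Phase-3 slope by middle-third regression
#'
#' Ordinary least squares of PCO2 on volume over the middle third (by
#' volume) of the phase-3 interval.
#'
#' @param cap A [build_capnogram()] result.
#' @param bounds Output of [phase3_bounds()].
#' @return The fitted slope S3V in mmHg/ml.
#' @export
phase3_slope <- function(cap, bounds) {
  len <- bounds$v3_end - bounds$v3_start
  lo <- bounds$v3_start + len / 3
  hi <- bounds$v3_start + 2 * len / 3
  sel <- cap$v >= lo & cap$v <= hi
  if (sum(sel) < 10L) {
    stop("phase3_slope: fewer than 10 grid points in the middle third of ",
         "phase 3 [", signif(lo, 4), ", ", signif(hi, 4), "] ml")
  }
  vx <- cap$v[sel]
  py <- cap$pco2[sel]
  sum((vx - mean(vx)) * (py - mean(py))) / sum((vx - mean(vx))^2)
}

#' End-tidal CO2
#'
#' Mean PCO2 over the final 5% of expired volume, robust to endpoint noise.
#'
#' @param cap A [build_capnogram()] result.
#' @return ETCO2 in mmHg.
#' @export
end_tidal <- function(cap) {
  mean(cap$pco2[cap$v >= 0.95 * cap$vt])
}

#' Normalize a capnogram slope by end-tidal CO2
#'
#' @param s Slope in mmHg/ml.
#' @param etco2 End-tidal CO2 in mmHg (> 0).
#' @return Normalized slope in 1/ml.
#' @export
normalize_slope <- function(s, etco2) {
  if (!(etco2 > 0)) stop("normalize_slope: etco2 must be > 0, got ", etco2)
  s / etco2
}

#' Fowler (anatomical) dead space
#'
#' The volume exhaled up to the phase-2 inflection, corrected for the
#' instrumental dead space; the fraction uses the equally corrected tidal
#' volume in the denominator. A negative corrected volume is clamped to
#' zero and flagged.
#'
#' @param v_inflect Inflection volume, ml.
#' @param instr_dead_space Instrumental dead space, ml.
#' @param vt Expired tidal volume, ml; must exceed `instr_dead_space`.
#' @return List with `vdf` (ml), `vdf_frac`, and `flags`.
#' @export
fowler_dead_space <- function(v_inflect, instr_dead_space, vt) {
  if (vt <= instr_dead_space) {
    stop("fowler_dead_space: vt (", vt, " ml) must exceed the instrumental ",
         "dead space (", instr_dead_space, " ml)")
  }
  raw <- v_inflect - instr_dead_space
  flags <- character(0)
  if (raw < 0) flags <- "fowler_clamped_to_zero"
  vdf <- max(raw, 0)
  list(vdf = vdf, vdf_frac = vdf / (vt - instr_dead_space), flags = flags)
}

#' Mixed-expired CO2 pressure
#'
#' The volume-weighted mean expired CO2: the trapezoid integral of the
#' volumetric capnogram divided by the expired volume.
#'
#' @param cap A [build_capnogram()] result.
#' @return Mixed-expired PCO2 in mmHg.
#' @export
mixed_expired <- function(cap) {
  n <- length(cap$v)
  sum((cap$pco2[-1] + cap$pco2[-n]) / 2 * diff(cap$v)) / cap$vt
}

#' Mean alveolar CO2 pressure
#'
#' PCO2 interpolated at the volume midpoint of phase 3.
#'
#' @param cap A [build_capnogram()] result.
#' @param bounds Output of [phase3_bounds()].
#' @return Mean alveolar PCO2 (PACO2) in mmHg.
#' @export
mean_alveolar <- function(cap, bounds) {
  vm <- (bounds$v3_start + bounds$v3_end) / 2
  stats::approx(cap$v, cap$pco2, xout = vm, rule = 2)$y
}

#' Bohr dead-space fraction
#'
#' `VDB/VT = (PACO2 - PECO2) / PACO2`, the physiological dead space from
#' mean alveolar and mixed-expired CO2.
#'
#' @param paco2_alv Mean alveolar PCO2, mmHg (> 0).
#' @param pe_co2 Mixed-expired PCO2, mmHg.
#' @return The Bohr fraction.
#' @export
bohr_fraction <- function(paco2_alv, pe_co2) {
  if (!(paco2_alv > 0)) {
    stop("bohr_fraction: paco2_alv must be > 0, got ", paco2_alv)
  }
  (paco2_alv - pe_co2) / paco2_alv
}

#' Enghoff dead-space fraction
#'
#' `VDE/VT = (PaCO2 - PECO2) / PaCO2`, Bohr's formula with arterial CO2 in
#' place of alveolar CO2; additionally captures intrapulmonary shunt.
#'
#' @param pa_co2 Arterial PCO2, mmHg (> 0).
#' @param pe_co2 Mixed-expired PCO2, mmHg.
#' @return The Enghoff fraction.
#' @export
enghoff_fraction <- function(pa_co2, pe_co2) {
  if (!(pa_co2 > 0)) stop("enghoff_fraction: pa_co2 must be > 0, got ", pa_co2)
  (pa_co2 - pe_co2) / pa_co2
}

#' Shunt indices
#'
#' The Enghoff-minus-Bohr dead-space difference (a virtual volume of
#' perfused but unventilated lung) and the arterial--alveolar CO2 gradient.
#'
#' @param vde_frac Enghoff fraction.
#' @param vdb_frac Bohr fraction.
#' @param pa_co2 Arterial PCO2, mmHg.
#' @param paco2_alv Mean alveolar PCO2, mmHg.
#' @return List with `shunt_frac` and `pa_a_co2` (mmHg).
#' @export
shunt_indices <- function(vde_frac, vdb_frac, pa_co2, paco2_alv) {
  list(shunt_frac = vde_frac - vdb_frac, pa_a_co2 = pa_co2 - paco2_alv)
}

#' Expired CO2 volume per breath
#'
#' Integrates the fractional CO2 concentration over expired volume, with
#' the partial pressure referred to dry gas at body temperature (47 mmHg
#' water-vapor pressure at 37 degrees C).
#'
#' @param cap A [build_capnogram()] result.
#' @param barometric Barometric pressure, mmHg (> 47).
#' @return CO2 volume in ml.
#' @export
vco2_per_breath <- function(cap, barometric = 760) {
  if (!(barometric > 47)) {
    stop("vco2_per_breath: barometric pressure must exceed 47 mmHg")
  }
  n <- length(cap$v)
  sum((cap$pco2[-1] + cap$pco2[-n]) / 2 * diff(cap$v)) / (barometric - 47)
}

#' Analyze one breath end-to-end
#'
#' Runs the full per-breath chain: capnogram construction, phase-2
#' inflection and slope, phase-3 bounds and slope, end-tidal and normalized
#' slopes, Fowler/Bohr dead spaces, mixed-expired and mean alveolar
#' pressures, CO2 volume, and -- when an arterial PaCO2 is present in the
#' metadata -- the Enghoff fraction and shunt indices.
#'
#' @param series A delay-corrected [gas_time_series()].
#' @param breath One breath from [segment_breaths()].
#' @param meta A [recording_meta()]; defaults to the series' own metadata.
#' @param volume Raw cumulative volume from [integrate_flow()]; computed if
#'   missing.
#' @param breath_id Provenance index stored in the result.
#' @param smooth_window Derivative smoothing window in ml (default
#'   `vt / 20`).
#' @return A [new_capno_indices()] record.
#' @export
analyze_breath <- function(series, breath, meta = series$meta,
                           volume = NULL, breath_id = NA_integer_,
                           smooth_window = NULL) {
  cap <- build_capnogram(series, breath, volume)
  if (is.null(smooth_window)) smooth_window <- cap$vt / 20
  infl <- find_phase2_inflection(cap, smooth_window)
  b3 <- phase3_bounds(cap, infl$v_inflect, smooth_window)
  s3v <- phase3_slope(cap, b3)
  etco2 <- end_tidal(cap)
  fow <- fowler_dead_space(infl$v_inflect, meta$instr_dead_space, cap$vt)
  pe <- mixed_expired(cap)
  pa_alv <- mean_alveolar(cap, b3)
  vdb <- bohr_fraction(pa_alv, pe)
  vco2 <- vco2_per_breath(cap, meta$barometric)
  vde <- NA_real_; shunt <- NA_real_; pa_a <- NA_real_
  if (!is.na(meta$pa_co2)) {
    vde <- enghoff_fraction(meta$pa_co2, pe)
    sh <- shunt_indices(vde, vdb, meta$pa_co2, pa_alv)
    shunt <- sh$shunt_frac
    pa_a <- sh$pa_a_co2
  }
  new_capno_indices(
    s2v = infl$s2v, s3v = s3v,
    sn2v = normalize_slope(infl$s2v, etco2),
    sn3v = normalize_slope(s3v, etco2),
    etco2 = etco2, vdf = fow$vdf, vdf_frac = fow$vdf_frac,
    vdb_frac = vdb, vde_frac = vde, paco2_alv = pa_alv, pe_co2 = pe,
    vt = cap$vt, vco2 = vco2, pa_a_co2 = pa_a, shunt_frac = shunt,
    v_inflect = infl$v_inflect, phase3_bounds = c(b3$v3_start, b3$v3_end),
    breath_id = breath_id, flags = c(b3$flags, fow$flags))
}

#' Analyze a whole recording
#'
#' Segments the recording (unless breaths are supplied), analyzes every
#' accepted breath, and aggregates the per-breath indices into a recording
#' summary. Breaths whose analysis fails are skipped with a flag rather
#' than aborting the recording.
#'
#' @param series A delay-corrected [gas_time_series()].
#' @param breaths Optional list from [segment_breaths()].
#' @param aggregate `"mean"` (default) or `"median"` across accepted
#'   breaths.
#' @param smooth_window Derivative smoothing window in ml, or `NULL` for
#'   the per-breath default.
#' @return List with `per_breath` (data frame, one row per analyzed
#'   breath), `summary` (named numeric vector of aggregated indices),
#'   `n_accepted`, `n_rejected`, and `flags`.
#' @export
analyze_recording <- function(series, breaths = NULL,
                              aggregate = c("mean", "median"),
                              smooth_window = NULL) {
  aggregate <- match.arg(aggregate)
  if (is.null(breaths)) breaths <- segment_breaths(series)
  volume <- integrate_flow(series)$raw
  rows <- list()
  flags <- character(0)
  n_acc <- 0L
  for (k in seq_along(breaths)) {
    b <- breaths[[k]]
    if (!b$accepted) next
    res <- tryCatch(
      analyze_breath(series, b, volume = volume, breath_id = k,
                     smooth_window = smooth_window),
      error = function(e) {
        flags <<- c(flags, paste0("breath ", k, ": ", conditionMessage(e)))
        NULL
      })
    if (is.null(res)) next
    n_acc <- n_acc + 1L
    rows[[length(rows) + 1L]] <- as.data.frame(res)
  }
  if (length(rows) == 0L) {
    stop("analyze_recording: no breath could be analyzed",
         if (length(flags) > 0L) paste0(" (first failure: ", flags[1], ")"))
  }
  per_breath <- do.call(rbind, rows)
  agg_fun <- if (aggregate == "mean") {
    function(x) mean(x, na.rm = TRUE)
  } else {
    function(x) stats::median(x, na.rm = TRUE)
  }
  summary <- vapply(capno_index_cols,
                    function(cn) agg_fun(per_breath[[cn]]), numeric(1))
  list(per_breath = per_breath, summary = summary,
       n_accepted = n_acc,
       n_rejected = sum(!vapply(breaths, `[[`, logical(1), "accepted")),
       flags = flags)
}
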