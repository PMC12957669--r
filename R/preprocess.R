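# Alignment of the capnogram to the flow signal, flow integration, and
# breath segmentation.

#' Estimate the capnometer transport delay from a step-change recording
#'
#' Reproduces the bench calibration: a step change in sampled CO2 is applied
#' at a flow onset, and the delay is the time between the first sample where
#' `|flow|` crosses `onset_frac` of its peak and the first sample where the
#' CO2 signal crosses `onset_frac` of its steady plateau.
#'
#' @param series A [gas_time_series()] holding the calibration epoch.
#' @param onset_frac Threshold fraction of peak flow / CO2 plateau used to
#'   define both onsets. Default 0.1.
#' @return Estimated transport delay in seconds (non-negative scalar).
#' @export
estimate_transport_delay <- function(series, onset_frac = 0.1) {
  validate_gas_time_series(series)
  rng <- diff(range(series$pco2))
  if (rng < 5) {
    stop("estimate_transport_delay: no CO2 plateau detected (range ",
         signif(rng, 3), " mmHg < 5 mmHg)")
  }
  plateau <- stats::quantile(series$pco2, 0.95, names = FALSE)
  peak_flow <- max(abs(series$flow))
  i_flow <- which(abs(series$flow) >= onset_frac * peak_flow)[1]
  i_pco2 <- which(series$pco2 >= onset_frac * plateau)[1]
  if (is.na(i_flow) || is.na(i_pco2)) {
    stop("estimate_transport_delay: onset threshold never crossed")
  }
  max(series$t[i_pco2] - series$t[i_flow], 0)
}

#' Shift the capnogram earlier to undo the sidestream transport delay
#'
#' The CO2 channel is advanced by `round(delay * sample_rate)` samples (a
#' constant integer-sample offset, no interpolation); the trailing samples
#' of all channels are dropped so lengths stay equal, and
#' `meta$transport_delay` records the applied value.
#'
#' @param series A [gas_time_series()].
#' @param delay Transport delay in seconds; must satisfy
#'   `0 <= delay < duration/2`.
#' @return The corrected [gas_time_series()]. `delay = 0` returns the input
#'   unchanged.
#' @export
apply_delay_correction <- function(series, delay) {
  validate_gas_time_series(series)
  if (delay < 0) stop("apply_delay_correction: delay must be >= 0")
  dur <- length(series$t) / series$sample_rate
  if (delay >= dur / 2) {
    stop("apply_delay_correction: delay (", delay,
         " s) must be below half the record duration (", dur / 2, " s)")
  }
  n_shift <- as.integer(round(delay * series$sample_rate))
  if (n_shift == 0L) return(series)
  n <- length(series$t)
  keep <- seq_len(n - n_shift)
  out <- series
  out$pco2 <- series$pco2[keep + n_shift]
  out$t <- series$t[keep]
  out$flow <- series$flow[keep]
  out$meta$transport_delay <- delay
  validate_gas_time_series(out)
  out
}

#' Integrate airflow to volume
#'
#' Cumulative trapezoid integration of the flow channel. When breaths are
#' supplied, a second, drift-controlled volume is returned in which the
#' integral is re-zeroed at each inspiration onset, bounding slow
#' pneumotachograph drift to a single cycle.
#'
#' @param series A [gas_time_series()].
#' @param breaths Optional list of breaths from [segment_breaths()].
#' @return A list with `raw` (cumulative volume, ml) and `rezeroed` (equal
#'   to `raw` when `breaths` is `NULL`).
#' @export
integrate_flow <- function(series, breaths = NULL) {
  validate_gas_time_series(series)
  raw <- cumtrapz(series$t, series$flow)
  rezeroed <- raw
  if (!is.null(breaths) && length(breaths) > 0L) {
    for (b in breaths) {
      idx <- b$i_insp_start:(b$i_exp_end - 1L)
      rezeroed[idx] <- raw[idx] - raw[b$i_insp_start]
    }
  }
  list(raw = raw, rezeroed = rezeroed)
}

# cumulative trapezoid with leading zero
cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum((y[-1] + y[-n]) / 2 * diff(x)))
}

#' Segment a recording into breaths
#'
#' Breath boundaries are placed at flow zero-crossings, accepted only when
#' the flow exceeds 5% of its global peak within the ensuing phase
#' (hysteresis against noise-induced micro-breaths). The leading segment
#' before the first detected inspiration and the trailing cycle that is not
#' closed by a following inspiration onset are discarded as partial. Breaths
#' failing quality thresholds are retained and flagged, never dropped.
#'
#' @param series A delay-corrected [gas_time_series()].
#' @param volume Optional raw cumulative volume from [integrate_flow()];
#'   computed if missing.
#' @param min_vt Minimum acceptable expired volume in ml; default 50% of the
#'   median expired volume over detected breaths.
#' @param min_etco2 Minimum acceptable end-tidal CO2 in mmHg (default 10).
#' @return A list of breaths, each a list with sample indices
#'   `i_insp_start`, `i_exp_start`, `i_exp_end` (expiration is the
#'   half-open index range `[i_exp_start, i_exp_end)`), volumes `vt_insp`
#'   and `vt_exp` (ml), the raw end-tidal estimate `etco2_raw` (mmHg),
#'   `accepted` (logical) and `reject_reason` (character).
#' @export
segment_breaths <- function(series, volume = NULL, min_vt = NULL,
                            min_etco2 = 10) {
  validate_gas_time_series(series)
  if (is.null(volume)) volume <- integrate_flow(series)$raw
  fl <- series$flow
  n <- length(fl)
  thr <- 0.05 * max(abs(fl))
  if (thr <= 0) stop("segment_breaths: flow signal is identically zero")

  # state machine over threshold crossings; each crossing is traced back to
  # the zero-crossing that started the phase
  insp_on <- integer(0)
  exp_on <- integer(0)
  state <- 0L  # 0 unknown, 1 inspiration, -1 expiration
  for (i in seq_len(n)) {
    if (state != 1L && fl[i] > thr) {
      j <- i
      while (j > 1L && fl[j - 1L] > 0) j <- j - 1L
      insp_on <- c(insp_on, j)
      state <- 1L
    } else if (state != -1L && fl[i] < -thr) {
      j <- i
      while (j > 1L && fl[j - 1L] < 0) j <- j - 1L
      exp_on <- c(exp_on, j)
      state <- -1L
    }
  }
  if (length(insp_on) < 2L || length(exp_on) < 1L) {
    stop("segment_breaths: fewer than 2 complete cycles detected")
  }

  breaths <- list()
  for (k in seq_len(length(insp_on) - 1L)) {
    i0 <- insp_on[k]
    i2 <- insp_on[k + 1L]
    ex <- exp_on[exp_on > i0 & exp_on < i2]
    if (length(ex) != 1L) next  # malformed cycle
    i1 <- ex[1]
    vt_insp <- volume[i1] - volume[i0]
    vt_exp <- volume[i1] - volume[i2]
    exp_idx <- i1:(i2 - 1L)
    n_tail <- max(1L, ceiling(0.05 * length(exp_idx)))
    etco2_raw <- mean(series$pco2[exp_idx[(length(exp_idx) - n_tail + 1L):
                                            length(exp_idx)]])
    breaths[[length(breaths) + 1L]] <- list(
      i_insp_start = i0, i_exp_start = i1, i_exp_end = i2,
      vt_insp = vt_insp, vt_exp = vt_exp, etco2_raw = etco2_raw,
      accepted = TRUE, reject_reason = "")
  }
  if (length(breaths) < 2L) {
    stop("segment_breaths: fewer than 2 complete cycles detected")
  }
  exp_len <- vapply(breaths, function(b) b$i_exp_end - b$i_exp_start,
                    numeric(1))
  if (stats::median(exp_len) < 10) {
    stop("segment_breaths: no plausible breaths (median expiratory phase ",
         "shorter than 10 samples; flow signal looks like noise)")
  }

  vts <- vapply(breaths, function(b) b$vt_exp, numeric(1))
  if (is.null(min_vt)) min_vt <- 0.5 * stats::median(vts)
  for (k in seq_along(breaths)) {
    b <- breaths[[k]]
    reasons <- character(0)
    if (!(b$vt_exp > 0)) reasons <- c(reasons, "nonpositive expired volume")
    if (b$vt_exp < min_vt) reasons <- c(reasons, "low tidal volume")
    if (b$etco2_raw < min_etco2) reasons <- c(reasons, "low end-tidal CO2")
    if (b$vt_exp > 0 && abs(b$vt_insp - b$vt_exp) / b$vt_exp > 0.25) {
      reasons <- c(reasons, "inspired/expired volume mismatch")
    }
    if (length(reasons) > 0L) {
      breaths[[k]]$accepted <- FALSE
      breaths[[k]]$reject_reason <- paste(reasons, collapse = "; ")
    }
  }
  breaths
}
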