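#' Parameters of the analytic expirogram profile
#'
#' Defines the underlying single-breath relation between cumulative expired
#' volume and CO2 partial pressure: a logistic phase-1/phase-2 transition
#' centred at the airway dead-space volume, multiplied into a sloped alveolar
#' plateau (phase 3).
#'
#' @param vd_aw Airway (anatomical) dead-space volume in ml. Must be > 0.
#' @param trans_width Width parameter of the logistic phase-2 transition in
#'   ml. The transition is essentially complete over `4 * trans_width`.
#' @param p3_mid CO2 partial pressure at the analytic midpoint of phase 3, in
#'   mmHg. Must be > 0.
#' @param s3_true True phase-3 slope of the underlying profile, mmHg/ml.
#' @param vt Tidal (total expired) volume in ml.
#' @param paco2_offset Arterial-minus-alveolar CO2 offset in mmHg used to
#'   derive the simulated arterial sample; models intrapulmonary shunt.
#'
#' @details Defaults describe a healthy ~300 g rat ventilated at 10 ml/kg:
#' `vt = 3` ml, airway dead space 0.6 ml, plateau around 40 mmHg, and a
#' sharp phase-2 transition (width 0.1 ml, i.e. the airway-alveolar
#' interface occupies roughly 13% of the breath). Note that a sidestream
#' sensor chain (see [sensor_model()]) smears the measured transition well
#' beyond this intrinsic width.
#'
#' @return An object of class `"expirogram_params"`.
#' @export
expirogram_params <- function(vd_aw = 0.6, trans_width = 0.1, p3_mid = 40,
                              s3_true = 2, vt = 3, paco2_offset = 3) {
  p <- list(vd_aw = vd_aw, trans_width = trans_width, p3_mid = p3_mid,
            s3_true = s3_true, vt = vt, paco2_offset = paco2_offset)
  class(p) <- "expirogram_params"
  validate_expirogram_params(p)
  p
}

validate_expirogram_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in c("vd_aw", "trans_width", "p3_mid", "s3_true", "vt",
              "paco2_offset")) {
    if (!num1(p[[f]])) stop("expirogram_params: '", f,
                            "' must be a finite numeric scalar")
  }
  if (p$vd_aw <= 0) stop("expirogram_params: vd_aw must be > 0 (got ",
                         p$vd_aw, ")")
  if (p$trans_width < 0) stop("expirogram_params: trans_width must be >= 0")
  if (p$p3_mid <= 0) stop("expirogram_params: p3_mid must be > 0 (got ",
                          p$p3_mid, ")")
  if (p$vt <= 0) stop("expirogram_params: vt must be > 0")
  if (p$vd_aw + 4 * p$trans_width >= p$vt) {
    stop("expirogram_params: the phase-2 transition must complete within ",
         "the breath: vd_aw + 4*trans_width = ",
         p$vd_aw + 4 * p$trans_width, " >= vt = ", p$vt)
  }
  # profile must be non-negative on [0, vt]; the only way it can dip below
  # zero is a steep negative plateau line
  vgrid <- seq(0, p$vt, length.out = 512L)
  if (any(expirogram_value(p, vgrid) < 0)) {
    stop("expirogram_params: profile PCO2 must be >= 0 everywhere on [0, vt]")
  }
  invisible(p)
}

#' @export
print.expirogram_params <- function(x, ...) {
  cat("Expirogram profile parameters\n")
  cat(sprintf("  vd_aw: %.3g ml  trans_width: %.3g ml  vt: %.3g ml\n",
              x$vd_aw, x$trans_width, x$vt))
  cat(sprintf("  p3_mid: %.3g mmHg  s3_true: %.3g mmHg/ml  paco2_offset: %.3g mmHg\n",
              x$p3_mid, x$s3_true, x$paco2_offset))
  invisible(x)
}

#' Ventilator flow-pattern parameters
#'
#' Describes the one-cycle flow waveform for a ventilation mode. Inspiration
#' is a half-sine in both modes. Expiration is a passive decelerating
#' exponential under positive-pressure ventilation (PPV) and a
#' ventilator-controlled half-sine under negative-pressure ventilation (NPV).
#'
#' @param mode `"PPV"` or `"NPV"`.
#' @param resp_rate Respiratory rate in breaths per minute; must lie in
#'   (20, 200). Default 65, mid-range of normocapnic rodent ventilation.
#' @param insp_frac Inspiratory fraction of the cycle, in (0, 1).
#' @param decel_tau Expiratory decay time constant for PPV, seconds.
#' @param exp_ramp Rise time of the PPV expiratory flow in seconds: the
#'   decelerating flow ramps up linearly over this interval instead of
#'   jumping, keeping the waveform continuous (and hence integrable without
#'   bias at finite sampling rates).
#'
#' @return An object of class `"flow_pattern"`.
#' @export
flow_pattern <- function(mode = c("PPV", "NPV"), resp_rate = 65,
                         insp_frac = 0.5, decel_tau = 0.2, exp_ramp = 0.02) {
  mode <- match.arg(mode)
  fp <- list(mode = mode, resp_rate = resp_rate, insp_frac = insp_frac,
             decel_tau = decel_tau, exp_ramp = exp_ramp)
  class(fp) <- "flow_pattern"
  validate_flow_pattern(fp)
  fp
}

validate_flow_pattern <- function(fp) {
  if (!fp$mode %in% c("PPV", "NPV")) stop("flow_pattern: mode must be PPV or NPV")
  if (!(fp$insp_frac > 0 && fp$insp_frac < 1)) {
    stop("flow_pattern: insp_frac must lie strictly in (0, 1), got ",
         fp$insp_frac)
  }
  if (!(fp$resp_rate > 20 && fp$resp_rate < 200)) {
    stop("flow_pattern: resp_rate must lie in (20, 200) breaths/min, got ",
         fp$resp_rate)
  }
  if (fp$decel_tau <= 0) stop("flow_pattern: decel_tau must be > 0")
  if (fp$exp_ramp < 0) stop("flow_pattern: exp_ramp must be >= 0")
  invisible(fp)
}

#' Sidestream sensor model
#'
#' Acquisition-chain parameters: the transport delay of gas drawn through the
#' sampling line, first-order sensor smoothing, additive noise, and the
#' digitization rate.
#'
#' @param transport_delay Transport delay in seconds (>= 0).
#' @param smoothing_tau First-order sensor time constant in seconds (>= 0;
#'   0 disables smoothing).
#' @param pco2_noise_sd Additive CO2 noise SD in mmHg.
#' @param flow_noise_sd Additive flow noise SD as a fraction of peak flow.
#' @param sample_rate Acquisition rate in Hz.
#'
#' @return An object of class `"sensor_model"`.
#' @export
sensor_model <- function(transport_delay = 0.58, smoothing_tau = 0.05,
                         pco2_noise_sd = 0.5, flow_noise_sd = 0.02,
                         sample_rate = 256) {
  s <- list(transport_delay = transport_delay, smoothing_tau = smoothing_tau,
            pco2_noise_sd = pco2_noise_sd, flow_noise_sd = flow_noise_sd,
            sample_rate = sample_rate)
  class(s) <- "sensor_model"
  validate_sensor_model(s)
  s
}

#' An idealized sensor: no delay, no smoothing, no noise
#'
#' Convenience constructor for ground-truth studies where the acquisition
#' chain should be transparent.
#'
#' @param sample_rate Acquisition rate in Hz.
#' @return A `"sensor_model"` with all distortions set to zero.
#' @export
ideal_sensor <- function(sample_rate = 256) {
  sensor_model(transport_delay = 0, smoothing_tau = 0, pco2_noise_sd = 0,
               flow_noise_sd = 0, sample_rate = sample_rate)
}

validate_sensor_model <- function(s) {
  if (s$transport_delay < 0) stop("sensor_model: transport_delay must be >= 0")
  if (s$smoothing_tau < 0) stop("sensor_model: smoothing_tau must be >= 0")
  if (s$pco2_noise_sd < 0 || s$flow_noise_sd < 0) {
    stop("sensor_model: noise SDs must be >= 0")
  }
  if (s$sample_rate <= 0) stop("sensor_model: sample_rate must be > 0")
  invisible(s)
}

#' Recording metadata
#'
#' Per-recording scalars carried beside the signal: ventilation mode,
#' end-expiratory pressure, animal mass, instrumental dead space, capnometer
#' transport delay, optional arterial blood-gas values, and barometric
#' pressure.
#'
#' @param mode `"PPV"` or `"NPV"`.
#' @param eep End-expiratory pressure in cmH2O (signed; negative for NPV
#'   chamber pressure). Must lie in \[-15, 15\].
#' @param weight Animal mass in g.
#' @param instr_dead_space Instrumental dead space in ml (1.14 ml is typical
#'   for a rodent PPV circuit, 0.70 ml for the NPV configuration).
#' @param transport_delay Capnometer transport delay in s.
#' @param pa_co2 Arterial CO2 partial pressure in mmHg, or `NA` if no blood
#'   gas is available.
#' @param pa_o2 Arterial O2 partial pressure in mmHg, or `NA`.
#' @param barometric Barometric pressure in mmHg.
#'
#' @return An object of class `"recording_meta"`.
#' @export
recording_meta <- function(mode = c("PPV", "NPV"), eep = 0, weight = 300,
                           instr_dead_space = 0, transport_delay = 0,
                           pa_co2 = NA_real_, pa_o2 = NA_real_,
                           barometric = 760) {
  mode <- match.arg(mode)
  m <- list(mode = mode, eep = eep, weight = weight,
            instr_dead_space = instr_dead_space,
            transport_delay = transport_delay,
            pa_co2 = as.numeric(pa_co2), pa_o2 = as.numeric(pa_o2),
            barometric = barometric)
  class(m) <- "recording_meta"
  validate_recording_meta(m)
  m
}

validate_recording_meta <- function(m) {
  if (!m$mode %in% c("PPV", "NPV")) {
    stop("recording_meta: mode must be 'PPV' or 'NPV', got '", m$mode, "'")
  }
  if (!is.finite(m$eep) || m$eep < -15 || m$eep > 15) {
    stop("recording_meta: eep must lie in [-15, 15] cmH2O, got ", m$eep)
  }
  if (m$instr_dead_space < 0) {
    stop("recording_meta: instr_dead_space must be >= 0")
  }
  if (m$transport_delay < 0) {
    stop("recording_meta: transport_delay must be >= 0")
  }
  if (!is.finite(m$barometric) || m$barometric <= 0) {
    stop("recording_meta: barometric must be > 0 mmHg")
  }
  invisible(m)
}

#' Synchronized flow + CO2 time series
#'
#' The raw material of every analysis stage: uniformly sampled airflow
#' (ml/s, positive = inspiration at the tracheal opening) and CO2 partial
#' pressure (mmHg) with acquisition metadata.
#'
#' @param t Sample times in seconds, strictly increasing with constant step
#'   `1/sample_rate`.
#' @param flow Airflow in ml/s; positive during inspiration.
#' @param pco2 CO2 partial pressure in mmHg; small negative noise excursions
#'   down to -5 mmHg are tolerated.
#' @param sample_rate Sampling rate in Hz.
#' @param meta A [recording_meta()] object.
#'
#' @return An object of class `"gas_time_series"`.
#' @export
gas_time_series <- function(t, flow, pco2, sample_rate,
                            meta = recording_meta()) {
  x <- list(t = as.numeric(t), flow = as.numeric(flow),
            pco2 = as.numeric(pco2), sample_rate = sample_rate, meta = meta)
  class(x) <- "gas_time_series"
  validate_gas_time_series(x)
  x
}

validate_gas_time_series <- function(x) {
  n <- length(x$t)
  if (n < 2L) stop("gas_time_series: need at least 2 samples, got ", n)
  if (length(x$flow) != n || length(x$pco2) != n) {
    stop("gas_time_series: t, flow and pco2 must have equal length (",
         n, ", ", length(x$flow), ", ", length(x$pco2), ")")
  }
  if (!all(is.finite(x$flow))) stop("gas_time_series: flow must be finite")
  if (!all(is.finite(x$pco2))) stop("gas_time_series: pco2 must be finite")
  if (any(x$pco2 < -5)) {
    stop("gas_time_series: pco2 below -5 mmHg at sample ",
         which(x$pco2 < -5)[1])
  }
  dt <- diff(x$t)
  step <- 1 / x$sample_rate
  bad <- which(abs(dt - step) > 1e-9)
  if (length(bad) > 0L) {
    stop("gas_time_series: non-uniform sampling at line ", bad[1] + 1L,
         " (step ", signif(dt[bad[1]], 6), " s, expected ",
         signif(step, 6), " s)")
  }
  validate_recording_meta(x$meta)
  invisible(x)
}

#' @export
print.gas_time_series <- function(x, ...) {
  cat(sprintf("Gas time series: %d samples at %g Hz (%.2f s), mode %s, EEP %g cmH2O\n",
              length(x$t), x$sample_rate, length(x$t) / x$sample_rate,
              x$meta$mode, x$meta$eep))
  invisible(x)
}
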