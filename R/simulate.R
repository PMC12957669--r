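# Synthetic flow/CO2 recordings with known ground truth.

#' Synthesize a flow + CO2 recording with known ground truth
#'
#' Tiles the one-cycle flow template over `n_breaths` cycles, evaluates the
#' analytic expirogram at the (closed-form) cumulative expired volume during
#' each expiration, lets the CO2 signal wash toward 0 mmHg during
#' inspiration, then applies the sidestream acquisition chain: an exact
#' nearest-sample transport-delay shift, a first-order low-pass, and
#' additive Gaussian noise on both channels. Identical seeds give
#' bit-identical output.
#'
#' @param params An [expirogram_params()] object.
#' @param flow A [flow_pattern()] object.
#' @param sensor A [sensor_model()] object.
#' @param n_breaths Number of ventilation cycles to synthesize (>= 1).
#' @param seed Integer seed governing all noise draws.
#' @param eep,weight,instr_dead_space Metadata labels copied into the
#'   recording's [recording_meta()]; the instrumental dead space is not
#'   physically simulated, it only enters downstream analysis as a volume
#'   correction.
#' @return A list with elements `series` (a [gas_time_series()]) and
#'   `truth` (a `sim_truth` record: the generator parameters, the seed, the
#'   simulated arterial PaCO2, and `oracle`, the [oracle_indices()] of the
#'   clean profile).
#' @examples
#' rec <- synthesize_recording(expirogram_params(), flow_pattern("PPV"),
#'                             ideal_sensor(), n_breaths = 3, seed = 1)
#' rec$series
#' @export
synthesize_recording <- function(params, flow, sensor, n_breaths, seed = 1L,
                                 eep = 0, weight = 300,
                                 instr_dead_space = 0) {
  validate_expirogram_params(params)
  validate_flow_pattern(flow)
  validate_sensor_model(sensor)
  if (!(is.numeric(n_breaths) && length(n_breaths) == 1L && n_breaths >= 1)) {
    stop("synthesize_recording: n_breaths must be >= 1")
  }
  n_breaths <- as.integer(n_breaths)

  fs <- sensor$sample_rate
  dt <- 1 / fs
  tpl <- make_flow_pattern(flow, params$vt)
  period <- attr(tpl, "period")
  t_insp <- attr(tpl, "t_insp")
  t_exp <- attr(tpl, "t_exp")

  n <- floor(n_breaths * period * fs) + 1L
  t <- (seq_len(n) - 1L) * dt
  flow_clean <- tpl(t)

  peak_flow <- max(abs(flow_clean))
  if (params$trans_width > 0 &&
      params$trans_width * fs / peak_flow < 5) {
    warning("synthesize_recording: fewer than 5 samples across trans_width ",
            "at peak flow (", signif(params$trans_width * fs / peak_flow, 3),
            "); the phase-2 transition is under-resolved at ", fs, " Hz")
  }

  # closed-form cumulative expired volume within each cycle
  tc <- t %% period
  cyc <- floor(t / period + 1e-12)
  te <- tc - t_insp                       # time into expiration
  is_exp <- te >= 0
  v_exp <- numeric(n)
  if (flow$mode == "PPV") {
    tau <- flow$decel_tau
    q0 <- params$vt / ppv_exp_integral(t_exp, tau, flow$exp_ramp)
    v_exp[is_exp] <- q0 * ppv_exp_integral(te[is_exp], tau, flow$exp_ramp)
  } else {
    v_exp[is_exp] <- params$vt * (1 - cos(pi * te[is_exp] / t_exp)) / 2
  }
  v_exp <- pmin(v_exp, params$vt)

  profile <- make_expirogram_profile(params)
  pco2_clean <- numeric(n)
  pco2_clean[is_exp] <- profile(v_exp[is_exp])

  # inspiration: first-order washin toward 0 mmHg from the end-expiratory
  # value of the previous cycle; the very first inspiration starts at 0
  p_end <- profile(params$vt)
  ins <- !is_exp & cyc >= 1L
  if (sensor$smoothing_tau > 0) {
    pco2_clean[ins] <- p_end * exp(-tc[ins] / sensor$smoothing_tau)
  }

  # --- acquisition chain ---------------------------------------------------
  n_shift <- as.integer(round(sensor$transport_delay * fs))
  pco2_meas <- delay_shift(pco2_clean, n_shift, pad = pco2_clean[1])
  if (sensor$smoothing_tau > 0) {
    a <- 1 - exp(-dt / sensor$smoothing_tau)
    pco2_meas <- as.numeric(stats::filter(a * pco2_meas, 1 - a,
                                          method = "recursive",
                                          init = pco2_meas[1]))
  }
  flow_meas <- flow_clean
  set.seed(as.integer(seed))
  if (sensor$flow_noise_sd > 0) {
    flow_meas <- flow_meas + stats::rnorm(n, 0, sensor$flow_noise_sd * peak_flow)
  }
  if (sensor$pco2_noise_sd > 0) {
    pco2_meas <- pco2_meas + stats::rnorm(n, 0, sensor$pco2_noise_sd)
  }

  oracle <- oracle_indices(params)
  pa_co2 <- oracle$paco2_alv + params$paco2_offset
  meta <- recording_meta(mode = flow$mode, eep = eep, weight = weight,
                         instr_dead_space = instr_dead_space,
                         transport_delay = sensor$transport_delay,
                         pa_co2 = pa_co2)
  series <- gas_time_series(t, flow_meas, pco2_meas, fs, meta)

  truth <- structure(
    list(params = params, flow = flow, sensor = sensor, seed = as.integer(seed),
         n_breaths = n_breaths, pa_co2 = pa_co2, oracle = oracle),
    class = "sim_truth")
  list(series = series, truth = truth)
}

# delay a signal by n samples (positive n = later in time), front-padded
delay_shift <- function(x, n, pad = x[1]) {
  if (n == 0L) return(x)
  if (n >= length(x)) stop("delay_shift: shift exceeds signal length")
  c(rep(pad, n), x[seq_len(length(x) - n)])
}

#' Synthesize a step-change CO2 calibration recording
#'
#' Emulates the bench procedure used to measure the capnometer transport
#' delay: flow starts from zero as a half-sine while the sampled gas steps
#' from 0 to a plateau at the flow onset; the sensor chain (delay, smoothing,
#' noise) is then applied. The measured delay between flow onset and the CO2
#' rise estimates `sensor$transport_delay`.
#'
#' @param sensor A [sensor_model()] object.
#' @param plateau Step plateau in mmHg (a 5% CO2 cylinder at 760 mmHg is
#'   about 38 mmHg).
#' @param lead,dur Seconds of zero-signal lead-in and of the step epoch.
#' @param seed Integer seed for the noise draws.
#' @return A [gas_time_series()] holding the calibration epoch.
#' @export
synthesize_step_calibration <- function(sensor, plateau = 38, lead = 1,
                                        dur = 2, seed = 1L) {
  validate_sensor_model(sensor)
  fs <- sensor$sample_rate
  dt <- 1 / fs
  n_lead <- round(lead * fs)
  n_on <- round(dur * fs)
  n <- n_lead + n_on
  t <- (seq_len(n) - 1L) * dt
  # rectangular flow pulse: the bench step needs a sharp flow onset so the
  # threshold crossing marks the true onset sample
  flow <- c(rep(0, n_lead), rep(20, n_on))
  pco2_clean <- c(rep(0, n_lead), rep(plateau, n_on))

  n_shift <- as.integer(round(sensor$transport_delay * fs))
  pco2 <- delay_shift(pco2_clean, n_shift, pad = 0)
  if (sensor$smoothing_tau > 0) {
    a <- 1 - exp(-dt / sensor$smoothing_tau)
    pco2 <- as.numeric(stats::filter(a * pco2, 1 - a, method = "recursive",
                                     init = pco2[1]))
  }
  set.seed(as.integer(seed))
  if (sensor$flow_noise_sd > 0) {
    flow <- flow + stats::rnorm(n, 0, sensor$flow_noise_sd * 20)
  }
  if (sensor$pco2_noise_sd > 0) {
    pco2 <- pco2 + stats::rnorm(n, 0, sensor$pco2_noise_sd)
  }
  gas_time_series(t, flow, pco2, fs,
                  recording_meta(transport_delay = sensor$transport_delay))
}
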