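# Analytic single-breath expirogram and one-cycle flow templates.

#' Analytic phase-3 midpoint of an expirogram profile
#'
#' The profile anchors its plateau pressure `p3_mid` at the midpoint of the
#' analytic phase-3 interval `[vd_aw + 4*trans_width, vt]`, i.e. from where
#' the logistic transition has reached ~98% to end-expiration.
#'
#' @param params An [expirogram_params()] object.
#' @return Volume in ml.
#' @export
phase3_mid_volume <- function(params) {
  (params$vd_aw + 4 * params$trans_width + params$vt) / 2
}

# internal: vectorized evaluation of the profile, no validation
expirogram_value <- function(params, v) {
  v_mid3 <- (params$vd_aw + 4 * params$trans_width + params$vt) / 2
  line <- params$p3_mid + params$s3_true * (v - v_mid3)
  if (params$trans_width <= 0) {
    sig <- as.numeric(v > params$vd_aw) + 0.5 * (v == params$vd_aw)
  } else {
    sig <- stats::plogis((v - params$vd_aw) / params$trans_width)
  }
  line * sig
}

#' Build the analytic expired-volume to PCO2 profile
#'
#' Returns the single-breath relation PCO2(V) used as ground truth by the
#' simulator: a line through the alveolar plateau (slope `s3_true`, value
#' `p3_mid` at the analytic phase-3 midpoint) multiplied by a logistic
#' transition centred at the airway dead-space volume `vd_aw` with width
#' `trans_width`. As `trans_width -> 0` the profile tends to a square wave
#' stepping at `vd_aw`.
#'
#' @param params An [expirogram_params()] object.
#' @return A function of expired volume (ml) returning PCO2 (mmHg),
#'   vectorized, evaluable on `[0, vt]`.
#' @examples
#' pr <- make_expirogram_profile(expirogram_params())
#' pr(c(0, 0.6, 3))
#' @export
make_expirogram_profile <- function(params) {
  validate_expirogram_params(params)
  force(params)
  function(v) expirogram_value(params, v)
}

#' Build a one-cycle flow template
#'
#' Inspiration is a half-sine whose integral is the tidal volume in both
#' modes. Expiration under PPV is a passive decelerating exponential with
#' time constant `decel_tau`, truncated at the end of the expiratory window
#' and rescaled so its integral equals the tidal volume; under NPV the
#' ventilator controls exhalation, modelled as a half-sine mirror of
#' inspiration. Flow is positive during inspiration, negative during
#' expiration.
#'
#' @param flow A [flow_pattern()] object.
#' @param vt Tidal volume in ml (> 0).
#' @return A function of time within one cycle (s) returning flow (ml/s),
#'   with attributes `period`, `t_insp`, `t_exp` (seconds). Times are taken
#'   modulo the cycle period, so the template tiles naturally.
#' @export
make_flow_pattern <- function(flow, vt) {
  validate_flow_pattern(flow)
  if (!(is.numeric(vt) && length(vt) == 1L && is.finite(vt) && vt > 0)) {
    stop("make_flow_pattern: vt must be a positive scalar")
  }
  period <- 60 / flow$resp_rate
  t_insp <- flow$insp_frac * period
  t_exp <- period - t_insp
  a_insp <- pi * vt / (2 * t_insp)            # half-sine amplitude

  if (flow$mode == "PPV") {
    tau <- flow$decel_tau
    if (tau > t_exp / 2) {
      warning("make_flow_pattern: decel_tau (", tau,
              " s) exceeds half the expiratory window (", signif(t_exp, 4),
              " s); >10% of the exponential is truncated before rescaling")
    }
    # rescale so the ramped, truncated decay integrates to vt
    q0 <- vt / ppv_exp_integral(t_exp, tau, flow$exp_ramp)
    r <- flow$exp_ramp
    exp_flow <- function(te) -q0 * pmin(if (r > 0) te / r else 1, 1) *
      exp(-te / tau)
  } else {
    a_exp <- pi * vt / (2 * t_exp)
    exp_flow <- function(te) -a_exp * sin(pi * te / t_exp)
  }

  f <- function(t) {
    tc <- t %% period
    out <- numeric(length(tc))
    ins <- tc < t_insp
    out[ins] <- a_insp * sin(pi * tc[ins] / t_insp)
    out[!ins] <- exp_flow(tc[!ins] - t_insp)
    out
  }
  attr(f, "period") <- period
  attr(f, "t_insp") <- t_insp
  attr(f, "t_exp") <- t_exp
  f
}

# closed-form integral of the unit-amplitude ramped decelerating expiration
# min(t/r, 1) * exp(-t/tau) from 0 to te (vectorized in te)
ppv_exp_integral <- function(te, tau, r) {
  if (r <= 0) return(tau * (1 - exp(-te / tau)))
  ramp <- pmin(te, r)
  i_ramp <- (tau / r) * (tau - exp(-ramp / tau) * (tau + ramp))
  i_tail <- ifelse(te > r, tau * (exp(-r / tau) - exp(-te / tau)), 0)
  i_ramp + i_tail
}
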