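# Brute-force numeric oracle for every per-breath index, evaluated on the
# clean analytic profile at fine volume resolution. This file intentionally
# re-derives everything with plain finite differences and sums so it can act
# as an independent cross-check of the analysis path; it must not call any
# of the capnogram-analysis functions.

#' Ground-truth indices from the clean analytic profile
#'
#' Evaluates the analytic expirogram on a uniform fine volume grid and
#' computes every per-breath index by direct numerics: the phase-2 inflection
#' as the argmax of a centred finite-difference first derivative, phase-3
#' onset by curvature decay, the middle-third phase-3 regression, end-tidal
#' and mixed-expired pressures, Bohr and Enghoff fractions (the simulated
#' arterial PaCO2 is the mean alveolar pressure plus `paco2_offset`), CO2
#' volume per breath, and shunt indices.
#'
#' @param params An [expirogram_params()] object.
#' @param resolution Volume grid step in ml. Must be at most
#'   `trans_width / 10` so the transition is resolved; defaults to the finer
#'   of `trans_width / 50` and `vt / 2000` (and `vt / 2500` in the
#'   square-wave limit `trans_width = 0`).
#' @param barometric Barometric pressure in mmHg used for the CO2 volume.
#' @return A `capno_indices` record (see [analyze_breath()] for the fields).
#' @export
oracle_indices <- function(params, resolution = NULL, barometric = 760) {
  validate_expirogram_params(params)
  if (is.null(resolution)) {
    resolution <- if (params$trans_width > 0) {
      min(params$trans_width / 50, params$vt / 2000)
    } else {
      params$vt / 2500
    }
  }
  if (params$trans_width > 0 && resolution > params$trans_width / 10) {
    stop("oracle_indices: resolution (", resolution,
         " ml) must be <= trans_width/10 = ", params$trans_width / 10, " ml")
  }
  n <- ceiling(params$vt / resolution) + 1L
  v <- seq(0, params$vt, length.out = n)
  if (any(diff(v) <= 0)) stop("oracle_indices: non-monotone volume grid")
  h <- v[2] - v[1]

  # closed-form profile, written out in full so the oracle stands alone
  v_mid3 <- (params$vd_aw + 4 * params$trans_width + params$vt) / 2
  line <- params$p3_mid + params$s3_true * (v - v_mid3)
  if (params$trans_width <= 0) {
    sig <- as.numeric(v > params$vd_aw) + 0.5 * (v == params$vd_aw)
  } else {
    sig <- 1 / (1 + exp(-(v - params$vd_aw) / params$trans_width))
  }
  p <- line * sig

  # centred finite differences
  i_mid <- 2:(n - 1L)
  dp <- (p[i_mid + 1L] - p[i_mid - 1L]) / (2 * h)
  i_max <- which.max(dp)
  s2v <- dp[i_max]
  v_inflect <- v[i_mid][i_max]

  # phase-3 onset: curvature decayed to <10% of its post-inflection peak and
  # staying below for 5% of VT
  d2 <- (p[i_mid + 1L] - 2 * p[i_mid] + p[i_mid - 1L]) / (h * h)
  after <- which(v[i_mid] > v_inflect)
  v3_start <- 0.8 * params$vt
  if (length(after) > 2L) {
    peak <- max(abs(d2[after]))
    if (peak > 0) {
      below <- abs(d2[after]) < 0.1 * peak
      k <- max(1L, ceiling(0.05 * params$vt / h))
      run <- cumsum(below)
      # first index j such that below[j..j+k-1] are all TRUE
      ok <- which(vapply(seq_len(length(below) - k + 1L), function(j) {
        s <- if (j == 1L) run[k] else run[j + k - 1L] - run[j - 1L]
        s == k
      }, logical(1)))
      if (length(ok) > 0L) {
        v3_start <- min(v[i_mid][after][ok[1]], 0.8 * params$vt)
      }
    }
  }
  v3_end <- params$vt

  # middle third of phase 3 by volume, ordinary least squares
  len3 <- v3_end - v3_start
  lo <- v3_start + len3 / 3
  hi <- v3_start + 2 * len3 / 3
  sel <- v >= lo & v <= hi
  vx <- v[sel]; py <- p[sel]
  s3v <- sum((vx - mean(vx)) * (py - mean(py))) / sum((vx - mean(vx))^2)

  # end-tidal: mean over the final 5% of expired volume
  tail_sel <- v >= 0.95 * params$vt
  etco2 <- mean(p[tail_sel])

  # mean alveolar pressure: value at the phase-3 volume midpoint
  vm <- (v3_start + v3_end) / 2
  j <- max(1L, min(n - 1L, findInterval(vm, v)))
  w <- (vm - v[j]) / h
  paco2_alv <- (1 - w) * p[j] + w * p[j + 1L]

  # mixed expired pressure and CO2 volume by trapezoid sums
  trap <- sum((p[-1] + p[-n]) / 2) * h
  pe_co2 <- trap / params$vt
  vco2 <- trap / (barometric - 47)

  pa_co2 <- paco2_alv + params$paco2_offset
  vdb_frac <- (paco2_alv - pe_co2) / paco2_alv
  vde_frac <- (pa_co2 - pe_co2) / pa_co2

  new_capno_indices(
    s2v = s2v, s3v = s3v, sn2v = s2v / etco2, sn3v = s3v / etco2,
    etco2 = etco2, vdf = v_inflect, vdf_frac = v_inflect / params$vt,
    vdb_frac = vdb_frac, vde_frac = vde_frac, paco2_alv = paco2_alv,
    pe_co2 = pe_co2, vt = params$vt, vco2 = vco2,
    pa_a_co2 = pa_co2 - paco2_alv, shunt_frac = vde_frac - vdb_frac,
    v_inflect = v_inflect, phase3_bounds = c(v3_start, v3_end),
    breath_id = NA_integer_, flags = character(0)
  )
}
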