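# The synthetic generator: analytic profile, flow templates, acquisition
# chain, and the independent clean-profile oracle.

test_that("analytic profile has the expected limiting and pointwise values", {
  # square-wave limit: zero-width transition is a step at vd_aw
  sq <- make_expirogram_profile(
    expirogram_params(vd_aw = 0.5, trans_width = 0, p3_mid = 40,
                      s3_true = 0, vt = 2.5, paco2_offset = 0))
  expect_equal(sq(0.4), 0)
  expect_equal(sq(0.6), 40)

  # sigmoid midpoint: the profile at vd_aw is half the local plateau-line value
  p <- expirogram_params(vd_aw = 0.5, trans_width = 0.05, p3_mid = 38,
                         s3_true = 2, vt = 2.5)
  pr <- make_expirogram_profile(p)
  line_at <- p$p3_mid + p$s3_true * (p$vd_aw - phase3_mid_volume(p))
  expect_equal(pr(p$vd_aw), line_at / 2, tolerance = 1e-12)

  # end-expiratory profile value sits above the oracle's end-tidal estimate
  # by exactly half the plateau drop over the final 5% of expired volume
  # (ETCO2 is a mean over that window)
  o <- oracle_indices(p)
  expect_lt(abs(pr(p$vt) - o$etco2 - p$s3_true * 0.05 * p$vt / 2), 0.01)
})

test_that("invalid profile parameters are rejected with the violated bound", {
  expect_error(expirogram_params(vd_aw = -1), "vd_aw")
  expect_error(expirogram_params(p3_mid = 0), "p3_mid")
  expect_error(expirogram_params(vd_aw = 2, trans_width = 0.5, vt = 3),
               "transition")
  # a steep plateau slope pulls the early profile below zero
  expect_error(expirogram_params(s3_true = 30), ">= 0")
})

test_that("flow templates conserve volume and have the stated shapes", {
  vt <- 2.5
  tt <- seq(0, 60 / 65, length.out = 20001)
  trapz <- function(x, y) sum((y[-1] + y[-length(y)]) / 2 * diff(x))

  for (mode in c("PPV", "NPV")) {
    f <- make_flow_pattern(flow_pattern(mode), vt)
    q <- f(tt)
    insp <- trapz(tt, pmax(q, 0))
    exp_v <- -trapz(tt, pmin(q, 0))
    expect_lt(abs(insp - vt) / vt, 1e-3)
    expect_lt(abs(exp_v - vt) / vt, 1e-3)
  }

  # NPV expiration is symmetric about the expiratory midpoint
  f <- make_flow_pattern(flow_pattern("NPV"), vt)
  t_insp <- attr(f, "t_insp"); t_exp <- attr(f, "t_exp")
  te <- seq(0.01, t_exp / 2 - 0.01, length.out = 50)
  expect_equal(f(t_insp + te), f(t_insp + t_exp - te), tolerance = 1e-9)

  # PPV decay: flow ratio over a decel_tau * 2 separation in the pure-decay
  # region is exp(-2)
  fp <- flow_pattern("PPV", decel_tau = 0.15)
  f <- make_flow_pattern(fp, vt)
  t0 <- attr(f, "t_insp") + fp$exp_ramp + 0.01
  expect_equal(f(t0 + 0.3) / f(t0), exp(-2), tolerance = 1e-9)

  # over-long decel_tau truncates >10% of the decay and warns
  expect_warning(make_flow_pattern(flow_pattern("PPV", decel_tau = 0.4), vt),
                 "truncated")
})

test_that("synthesis is seed-deterministic", {
  p <- expirogram_params()
  a <- quiet_synth(p, flow_pattern("PPV"), sensor_model(), 3, seed = 7)
  b <- quiet_synth(p, flow_pattern("PPV"), sensor_model(), 3, seed = 7)
  d <- quiet_synth(p, flow_pattern("PPV"), sensor_model(), 3, seed = 8)
  expect_identical(a$series$pco2, b$series$pco2)
  expect_identical(a$series$flow, b$series$flow)
  expect_false(identical(a$series$pco2, d$series$pco2))
})

test_that("an ideal sensor chain leaves expiratory samples on the profile", {
  p <- expirogram_params()
  rec <- std_recording("NPV", ideal_sensor(), n_breaths = 3)
  ser <- rec$series
  pr <- make_expirogram_profile(p)
  br <- segment_breaths(ser)
  b <- br[[2]]
  vol <- integrate_flow(ser)$raw
  idx <- b$i_exp_start:(b$i_exp_end - 1L)
  v_exp <- vol[b$i_exp_start] - vol[idx]
  # trapezoid-integrated volume deviates from the analytic volume by well
  # under a sample of the profile
  expect_lt(max(abs(ser$pco2[idx] - pr(pmin(v_exp, p$vt)))), 0.75)
})

test_that("transport delay shifts the CO2 trace by the nearest sample count", {
  p <- expirogram_params()
  clean <- std_recording("PPV", ideal_sensor(), n_breaths = 4)$series
  delayed <- std_recording("PPV",
    sensor_model(transport_delay = 0.58, smoothing_tau = 0,
                 pco2_noise_sd = 0, flow_noise_sd = 0),
    n_breaths = 4)$series
  lags <- 140:160
  sse <- vapply(lags, function(k) {
    n <- length(clean$pco2) - k
    sum((delayed$pco2[(k + 1):(k + n)] - clean$pco2[1:n])^2)
  }, numeric(1))
  expect_equal(lags[which.min(sse)], 148)  # round(0.58 * 256)
})

test_that("coarse sampling across the transition is flagged", {
  p <- expirogram_params(trans_width = 0.02)
  expect_warning(
    synthesize_recording(p, flow_pattern("PPV"), ideal_sensor(), 2, seed = 1),
    "under-resolved")
})

test_that("oracle reproduces closed-form square-wave dead-space values", {
  p <- expirogram_params(vd_aw = 0.5, trans_width = 0, p3_mid = 40,
                         s3_true = 0, vt = 2.5, paco2_offset = 0)
  o <- oracle_indices(p, resolution = 0.001)
  expect_equal(o$pe_co2, 32, tolerance = 1e-3)
  expect_equal(o$vdb_frac, 0.2, tolerance = 1e-3 / 0.2)
  expect_equal(o$vdb_frac, p$vd_aw / p$vt, tolerance = 1e-3 / 0.2)
  # with no arterial-alveolar offset Enghoff equals Bohr
  expect_equal(o$vde_frac, o$vdb_frac, tolerance = 1e-12)
})

test_that("oracle recovers an exactly linear phase-3 slope", {
  p <- expirogram_params(vd_aw = 0.5, trans_width = 0.02, p3_mid = 40,
                         s3_true = 2, vt = 2.5)
  o <- oracle_indices(p)
  expect_equal(o$s3v, 2, tolerance = 0.01)
  # clean logistic: phase-3 onset falls just past the transition
  expect_gt(o$phase3_bounds[1], p$vd_aw)
  expect_lt(o$phase3_bounds[1], p$vd_aw + 0.3)
})

test_that("oracle responds to the shunt offset and only to it", {
  offs <- c(0, 2, 5, 8, 12)
  res <- lapply(offs, function(o0)
    oracle_indices(expirogram_params(paco2_offset = o0)))
  vde <- vapply(res, `[[`, numeric(1), "vde_frac")
  vdb <- vapply(res, `[[`, numeric(1), "vdb_frac")
  paa <- vapply(res, `[[`, numeric(1), "pa_a_co2")
  expect_true(all(diff(vde) > 0))
  expect_true(all(diff(paa) > 0))
  expect_equal(paa, offs, tolerance = 1e-9)
  expect_lt(max(vdb) - min(vdb), 1e-12)
})

test_that("oracle self-consistency: Bohr fraction tends to vd_aw/vt", {
  p <- expirogram_params(vd_aw = 0.5, trans_width = 0, p3_mid = 40,
                         s3_true = 0, vt = 2.5, paco2_offset = 0)
  o <- oracle_indices(p, resolution = 0.001)  # 1 ul
  expect_lt(abs(o$vdb_frac - 0.5 / 2.5), 1e-3)
})
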