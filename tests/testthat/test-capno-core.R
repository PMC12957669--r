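# Volumetric capnogram construction and every derived index.

test_that("a constant CO2 expiration yields a flat capnogram", {
  rec <- std_recording("NPV", n_breaths = 3)
  ser <- rec$series
  ser$pco2 <- rep(40, length(ser$pco2))
  br <- segment_breaths(ser, min_etco2 = 0)
  cap <- build_capnogram(ser, br[[2]])
  expect_true(all(abs(cap$pco2 - 40) < 1e-9))
  expect_equal(mixed_expired(cap), 40, tolerance = 1e-9)
  expect_equal(end_tidal(cap), 40, tolerance = 1e-9)
})

test_that("noiseless capnograms reproduce the analytic profile", {
  p <- expirogram_params()
  pr <- make_expirogram_profile(p)
  for (mode in c("PPV", "NPV")) {
    rec <- std_recording(mode, n_breaths = 4)
    br <- segment_breaths(rec$series)
    cap <- build_capnogram(rec$series, br[[2]])
    # away from the sparse-sampled sharp transition the reconstruction is
    # interpolation-exact; across it the error stays below half a mmHg
    err <- abs(cap$pco2 - pr(pmin(cap$v, p$vt)))
    expect_lt(max(err), 0.5)
    expect_lt(stats::median(err), 0.05)
  }
})

test_that("identical profiles under PPV and NPV give matching capnograms", {
  p <- expirogram_params()
  caps <- lapply(c("PPV", "NPV"), function(m) {
    rec <- std_recording(m, n_breaths = 4)
    br <- segment_breaths(rec$series)
    build_capnogram(rec$series, br[[2]])
  })
  g <- seq(0.02, 2.97, length.out = 300)
  pa <- stats::approx(caps[[1]]$v, caps[[1]]$pco2, g)$y
  pb <- stats::approx(caps[[2]]$v, caps[[2]]$pco2, g)$y
  expect_lt(max(abs(pa - pb)), 0.75)
  expect_lt(stats::median(abs(pa - pb)), 0.05)
})

test_that("inflection detection matches logistic closed forms", {
  # max slope of A * L(V) is A / (4 w) at V = vd_aw
  p <- expirogram_params(vd_aw = 0.5, trans_width = 0.05, p3_mid = 40,
                         s3_true = 0, vt = 2.5, paco2_offset = 0)
  cap <- profile_capnogram(p, n = 2000L)
  infl <- find_phase2_inflection(cap)
  expect_equal(infl$s2v, 40 / (4 * 0.05), tolerance = 0.05)
  expect_equal(infl$v_inflect, 0.5, tolerance = 0.02 / 0.5)

  # doubling the plateau doubles the slope
  p2 <- expirogram_params(vd_aw = 0.5, trans_width = 0.05, p3_mid = 80,
                          s3_true = 0, vt = 2.5, paco2_offset = 0)
  infl2 <- find_phase2_inflection(profile_capnogram(p2, n = 2000L))
  expect_equal(infl2$s2v / infl$s2v, 2, tolerance = 1e-6)

  # a transition-free ramp has no interior derivative peak
  ramp <- structure(list(v = seq(0, 2.5, length.out = 400),
                         pco2 = seq(0, 40, length.out = 400),
                         vt = 2.5, breath_id = NA_integer_),
                    class = "vol_capnogram")
  expect_error(find_phase2_inflection(ramp), "no sigmoid transition")
})

test_that("phase-3 bounds sit just past the transition on clean profiles", {
  p <- expirogram_params(vd_aw = 0.5, trans_width = 0.05, p3_mid = 40,
                         s3_true = 2, vt = 2.5)
  cap <- profile_capnogram(p, n = 2000L)
  infl <- find_phase2_inflection(cap)
  b <- phase3_bounds(cap, infl$v_inflect)
  expect_gt(b$v3_start, p$vd_aw)
  expect_lt(b$v3_start, p$vd_aw + 0.45)
  expect_equal(b$v3_end, p$vt)
})

test_that("phase-3 regression is exact on lines", {
  v <- seq(0, 2.5, length.out = 500)
  line <- structure(list(v = v, pco2 = 30 + 2 * v, vt = 2.5,
                         breath_id = NA_integer_), class = "vol_capnogram")
  b <- list(v3_start = 0.8, v3_end = 2.5)
  expect_equal(phase3_slope(line, b), 2, tolerance = 1e-12)

  flat <- structure(list(v = v, pco2 = rep(40, 500), vt = 2.5,
                         breath_id = NA_integer_), class = "vol_capnogram")
  expect_equal(phase3_slope(flat, b), 0, tolerance = 1e-12)
  expect_error(phase3_slope(line, list(v3_start = 2.49, v3_end = 2.5)),
               "fewer than 10")
})

test_that("end-tidal is the mean over the final 5% of expired volume", {
  # linear phase 3 ending at 42 with slope 2 on a 2.5 ml breath:
  # mean over the last 0.125 ml is 42 - 2 * 0.125 / 2
  v <- seq(0, 2.5, length.out = 2501)
  cap <- structure(list(v = v, pco2 = 42 - 2 * (2.5 - v), vt = 2.5,
                        breath_id = NA_integer_), class = "vol_capnogram")
  expect_equal(end_tidal(cap), 41.875, tolerance = 1e-3)
})

test_that("scalar index formulas follow their definitions", {
  expect_equal(normalize_slope(200, 40), 5)
  expect_equal(normalize_slope(0, 40), 0)
  expect_equal(normalize_slope(5.8, 29), 0.2)
  expect_error(normalize_slope(5, 0), "> 0")

  f <- fowler_dead_space(1.64, 1.14, 3.64)
  expect_equal(f$vdf, 0.5)
  expect_equal(f$vdf_frac, 0.2)
  expect_equal(fowler_dead_space(1.64, 0, 3.64)$vdf, 1.64)
  clamped <- fowler_dead_space(0.9, 1.14, 3.64)
  expect_equal(clamped$vdf, 0)
  expect_true("fowler_clamped_to_zero" %in% clamped$flags)
  expect_error(fowler_dead_space(1, 3, 2.5), "exceed")

  expect_equal(bohr_fraction(40, 32), 0.2)
  expect_equal(bohr_fraction(40, 40), 0)
  expect_equal(bohr_fraction(40, 20), 0.5)
  expect_error(bohr_fraction(0, 20), "> 0")

  expect_equal(enghoff_fraction(50, 20), 0.6)
  expect_equal(enghoff_fraction(40, 32), 0.2)
  expect_error(enghoff_fraction(-1, 20), "> 0")

  s <- shunt_indices(0.6, 0.2, 50, 40)
  expect_equal(s$shunt_frac, 0.4)
  expect_equal(s$pa_a_co2, 10)
  s0 <- shunt_indices(0.2, 0.2, 40, 40)
  expect_equal(unlist(s0), c(shunt_frac = 0, pa_a_co2 = 0))
})

test_that("CO2 volume per breath uses BTPS dry-gas convention", {
  v <- seq(0, 2.5, length.out = 500)
  cap <- structure(list(v = v, pco2 = rep(40, 500), vt = 2.5,
                        breath_id = NA_integer_), class = "vol_capnogram")
  expect_equal(vco2_per_breath(cap, 760), 40 / 713 * 2.5, tolerance = 1e-6)
  cap$pco2 <- rep(0, 500)
  expect_equal(vco2_per_breath(cap, 760), 0)
  expect_error(vco2_per_breath(cap, 40), "47")
})

test_that("square-wave mixed-expired pressure matches the step geometry", {
  p <- expirogram_params(vd_aw = 0.5, trans_width = 0, p3_mid = 40,
                         s3_true = 0, vt = 2.5, paco2_offset = 0)
  cap <- profile_capnogram(p, n = 2501L)
  expect_equal(mixed_expired(cap), 32, tolerance = 0.05)
})

test_that("analyze_breath honors arterial optionality and identities", {
  rec <- std_recording("PPV", n_breaths = 4)
  ser <- rec$series
  br <- segment_breaths(ser)

  res <- analyze_breath(ser, br[[2]])
  expect_false(is.na(res$vde_frac))           # simulated PaCO2 present
  expect_equal(res$sn2v * res$etco2, res$s2v, tolerance = 1e-12)
  expect_equal(res$sn3v * res$etco2, res$s3v, tolerance = 1e-12)
  expect_equal(res$shunt_frac, res$vde_frac - res$vdb_frac, tolerance = 1e-12)

  meta_nogas <- ser$meta
  meta_nogas$pa_co2 <- NA_real_
  res2 <- analyze_breath(ser, br[[2]], meta = meta_nogas)
  expect_true(is.na(res2$vde_frac))
  expect_true(is.na(res2$pa_a_co2))
  expect_false(is.na(res2$vdb_frac))

  # Enghoff collapses onto Bohr when PaCO2 equals alveolar PCO2
  meta_eq <- ser$meta
  meta_eq$pa_co2 <- res$paco2_alv
  res3 <- analyze_breath(ser, br[[2]], meta = meta_eq)
  expect_equal(res3$vde_frac, res3$vdb_frac, tolerance = 1e-12)
})

test_that("perturbing arterial PaCO2 changes only the Enghoff-side outputs", {
  rec <- std_recording("NPV", n_breaths = 4)
  ser <- rec$series
  br <- segment_breaths(ser)
  base <- analyze_breath(ser, br[[2]])
  meta2 <- ser$meta
  meta2$pa_co2 <- meta2$pa_co2 + 5
  pert <- analyze_breath(ser, br[[2]], meta = meta2)
  changed <- c("vde_frac", "shunt_frac", "pa_a_co2")
  for (f in changed) expect_false(isTRUE(all.equal(base[[f]], pert[[f]])))
  same <- setdiff(capnovol:::capno_index_cols, changed)
  for (f in same) expect_equal(base[[f]], pert[[f]], tolerance = 1e-12)
})

test_that("indices are equivariant under CO2 rescaling", {
  rec <- std_recording("PPV", n_breaths = 4, seed = 6)
  ser <- rec$series
  br <- segment_breaths(ser)
  base <- analyze_breath(ser, br[[2]])
  cc <- 1.7
  scaled <- ser
  scaled$pco2 <- cc * ser$pco2
  scaled$meta$pa_co2 <- cc * ser$meta$pa_co2
  up <- analyze_breath(scaled, br[[2]])
  for (f in c("s2v", "s3v", "etco2", "pe_co2", "paco2_alv", "vco2")) {
    expect_equal(up[[f]], cc * base[[f]], tolerance = 1e-6)
  }
  for (f in c("sn2v", "sn3v", "vdb_frac", "v_inflect", "vt")) {
    expect_equal(up[[f]], base[[f]], tolerance = 1e-6)
  }
})

test_that("recording-level analysis aggregates accepted breaths", {
  rec <- std_recording("NPV", n_breaths = 8, seed = 2)
  res <- analyze_recording(rec$series)
  expect_equal(nrow(res$per_breath), res$n_accepted)
  expect_gte(res$n_accepted, 6)
  expect_equal(unname(res$summary["vdb_frac"]),
               mean(res$per_breath$vdb_frac), tolerance = 1e-12)
  med <- analyze_recording(rec$series, aggregate = "median")
  expect_equal(unname(med$summary["s3v"]),
               stats::median(med$per_breath$s3v), tolerance = 1e-12)
})
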