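# Land recalibration and the transmural calcium-sensitivity scan.

test_that("calibration returns the starting point when targets are already met", {
  start <- ss_snap("torord", "endo", 1000, TRUE)
  mech <- make_mech_params("torord") # calibrated set meets the targets
  cal <- calibrate_land("torord", mech = mech, start = start,
                        settle_beats = 6)
  expect_equal(cal$cost, 0)
  expect_equal(unname(cal$par), c(mech$n_tm, mech$k_tm))
  expect_true(cal$converged)
  expect_equal(nrow(cal$log), 1) # no search needed
})

test_that("inverse-crime recovery: known parameters are recovered within 5%", {
  start <- ss_snap("torord", "endo", 1000, TRUE)
  ep <- make_params("torord", "endo")
  truth <- make_mech_params("torord", calibrated = FALSE)
  truth$n_tm <- 3.0; truth$k_tm <- 0.025
  tr <- pace(start, ep, truth, pacing_protocol(1000, 12, record_last = 1))
  ta <- ta_biomarkers(tr, 1)
  got <- c(amplitude = ta$amplitude, tp = ta$tp, rt50 = ta$rt50,
           rt95 = ta$rt95)
  targets <- data.frame(biomarker = names(got),
                        lower = unname(got) * 0.998,
                        upper = unname(got) * 1.002,
                        weight = 1)
  cal <- calibrate_land("torord", targets = targets, start = start,
                        settle_beats = 12, grid_n = 4, maxit = 60)
  expect_lt(abs(cal$par[["n_tm"]] - 3.0) / 3.0, 0.05)
  expect_lt(abs(cal$par[["k_tm"]] - 0.025) / 0.025, 0.05)
})

test_that("calibration does not alter electrophysiology", {
  start <- ss_snap("torord", "endo", 1000, TRUE)
  ep <- make_params("torord", "endo")
  pre <- pace(start, ep, make_mech_params("torord", calibrated = FALSE),
              pacing_protocol(1000, 30, record_last = 1))
  post <- pace(start, ep, make_mech_params("torord"),
               pacing_protocol(1000, 30, record_last = 1))
  expect_lt(abs(ap_biomarkers(pre, 1)$apd90 - ap_biomarkers(post, 1)$apd90),
            0.5)
  expect_lt(abs(ap_biomarkers(pre, 1)$apd50 - ap_biomarkers(post, 1)$apd50),
            0.5)
})

test_that("the interval cost is zero iff every biomarker is inside its interval", {
  tg <- tension_targets()
  inside <- (tg$lower + tg$upper) / 2
  for (i in seq_len(nrow(tg))) {
    expect_equal(emcell:::.interval_cost(inside[i], tg$lower[i], tg$upper[i]),
                 0)
    expect_gt(emcell:::.interval_cost(tg$upper[i] + 1, tg$lower[i],
                                      tg$upper[i]), 0)
    expect_gt(emcell:::.interval_cost(tg$lower[i] - 1, tg$lower[i],
                                      tg$upper[i]), 0)
  }
})

test_that("peak tension falls monotonically with the Ca50 factor and matches endo at reduced sensitivity", {
  sc <- ca50_scan("torord", "epi", factors = c(0.5, 1, 1.5, 1.75, 2),
                  settle_beats = 30)
  tab <- sc$table
  expect_true(all(diff(tab$ta_peak) < 0))
  # factor 1 reproduces the baseline epicardial twitch
  base <- ta_biomarkers(quick_trace("torord", "epi", n_beats = 30), 1)
  expect_equal(tab$ta_peak[tab$factor == 1], base$amplitude,
               tolerance = 0.02)
  # desensitised epi approaches the endocardial peak inside the scan range
  expect_false(is.na(sc$match_range[1]))
})
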