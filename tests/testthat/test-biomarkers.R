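# Biomarker extractors against closed-form synthetic waveforms, and
# detector behaviour on constructed and simulated traces.

test_that("triangle AP biomarkers are exact", {
  # rest -85 mV, instant rise to +35 at t = 5 ms, linear fall to rest at 305
  spec <- waveform_spec("triangle_ap", amplitude = 120, baseline = -85,
                        onset = 5, rise = 0, fall = 300, cl = 1000, dt = 0.5)
  tr <- generate_waveform(spec)
  ap <- ap_biomarkers(tr, 1)
  expect_equal(ap$apd90, 270, tolerance = 1e-9)
  expect_equal(ap$apd50, 150, tolerance = 1e-9)
  expect_equal(ap$tp, 0)
  expect_equal(ap$peak, 35)
  expect_equal(ap$resting, -85)
  expect_false(detect_eads(tr, 1)$detected) # monotone repolarisation
})

test_that("raised-cosine transient decay times match the closed form", {
  spec <- waveform_spec("raised_cosine_transient", amplitude = 1,
                        baseline = 0.1, onset = 10, rise = 40, fall = 250,
                        cl = 1000, dt = 0.5)
  tr <- generate_waveform(spec)
  gt <- attr(tr, "ground_truth")
  ct <- cat_biomarkers(tr, 1)
  expect_equal(ct$tp, gt$tp, tolerance = 0.01)
  expect_equal(ct$rt50, gt$rt50, tolerance = 0.2)
  expect_equal(ct$rt90, gt$rt90, tolerance = 0.2)
  ta <- ta_biomarkers(tr, 1)
  expect_equal(ta$rt95, gt$rt95, tolerance = 0.2)
  expect_lte(ct$rt50, ct$rt90)
  expect_lte(ta$rt50, ta$rt95)
})

test_that("an injected hump during repolarisation is detected as an EAD", {
  spec <- waveform_spec("triangle_ap", amplitude = 120, baseline = -85,
                        onset = 5, rise = 0, fall = 300,
                        anomaly = list(type = "ead_hump", time = 245,
                                       amplitude = 20, width = 40),
                        cl = 1000, dt = 0.5)
  tr <- generate_waveform(spec)
  e <- detect_eads(tr, 1)
  expect_true(e$detected)
  # detection time inside the hump (anomaly time counts from beat start)
  expect_true(any(e$times >= 245 & e$times <= 285))
  # the same beat still yields defined APD thresholds (pre-stimulus rest)
  expect_equal(ap_biomarkers(tr, 1)$resting, -85)
})

test_that("an injected tension bump during relaxation is an aftercontraction", {
  spec <- waveform_spec("raised_cosine_transient", amplitude = 20,
                        baseline = 0.5, onset = 10, rise = 150, fall = 300,
                        anomaly = list(type = "aftercontraction_bump",
                                       time = 320, amplitude = 4,
                                       width = 80),
                        cl = 1000, dt = 0.5)
  tr <- generate_waveform(spec)
  expect_true(detect_aftercontractions(tr, 1)$detected)
  clean <- generate_waveform(waveform_spec("raised_cosine_transient",
                                           amplitude = 20, baseline = 0.5,
                                           onset = 10, rise = 150,
                                           fall = 300, cl = 1000, dt = 0.5))
  expect_false(detect_aftercontractions(clean, 1)$detected)
})

test_that("a dropped beat is flagged as a contractility escape", {
  spec <- waveform_spec("raised_cosine_transient", amplitude = 20,
                        baseline = 0.5, onset = 10, rise = 150, fall = 300,
                        anomaly = list(type = "dropped_beat", beat = 2),
                        cl = 800, n_beats = 3, dt = 0.5)
  tr <- generate_waveform(spec)
  expect_identical(detect_escapes(tr), 2L)
  clean <- generate_waveform(waveform_spec("raised_cosine_transient",
                                           amplitude = 20, baseline = 0.5,
                                           onset = 10, rise = 150,
                                           fall = 300, cl = 800, n_beats = 3,
                                           dt = 0.5))
  expect_length(detect_escapes(clean), 0)
})

test_that("detectors never fire on drug-free steady-state traces", {
  cases <- list(
    quick_trace("torord", "endo", 1000, TRUE, n_beats = 3, record_last = 3),
    quick_trace("torord", "epi", 1000, TRUE, n_beats = 3, record_last = 3),
    quick_trace("torord", "mid", 1000, TRUE, n_beats = 3, record_last = 3),
    quick_trace("torord", "endo", 4000, TRUE, n_beats = 2, record_last = 2),
    quick_trace("ord", "endo", 1000, TRUE, n_beats = 3, record_last = 3)
  )
  # faster / slower pacing re-converged from the 1 Hz snapshot
  ep <- make_params("torord", "endo"); mech <- make_mech_params("torord")
  st <- ss_snap("torord", "endo", 1000, TRUE)
  for (cl in c(500, 2000)) {
    ss <- suppressWarnings(run_to_steady_state(st, ep, mech, cl = cl, max_beats = 400))
    cases[[length(cases) + 1]] <-
      pace(ss$state, ep, mech, pacing_protocol(cl, 3, record_last = 3))
  }
  for (tr in cases) {
    nb <- length(attr(tr, "stim_times"))
    for (b in seq_len(nb)) {
      expect_false(detect_eads(tr, b)$detected)
      expect_false(detect_aftercontractions(tr, b)$detected)
    }
    expect_length(detect_escapes(tr), 0)
  }
})

test_that("the electro-mechanical window is zero for equal durations and NA when unresolved", {
  rep0 <- list(ap = list(apd90 = 300), cat = list(duration90 = 300))
  expect_equal(emw(rep0), 0)
  expect_true(is.na(emw(list(ap = list(apd90 = NA_real_),
                             cat = list(duration90 = 300)))))
})
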