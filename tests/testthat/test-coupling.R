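# Coupled-system properties: calcium bookkeeping, effect of the dynamic
# troponin buffer, pacing protocol mechanics, determinism and solver
# robustness.

test_that("total calcium is conserved over a beat (bookkeeping audit)", {
  st <- ss_snap("torord", "endo", 1000, TRUE)
  ep <- make_params("torord", "endo")
  mech <- make_mech_params("torord")
  tr <- pace(st, ep, mech, pacing_protocol(1000, 1, record_last = 1,
                                           dt_out = 1),
             solver = solver_options(rtol = 1e-8, atol = 1e-10),
             keep = "full")
  # free + buffered + organelle calcium minus the integrated sarcolemmal
  # influx must stay constant
  audit <- .ca_total(tr, ep) - tr$qca
  expect_lt(max(audit) - min(audit), 1e-8)
})

test_that("electro-mechanical coupling leaves the AP unchanged but reshapes the CaT", {
  em <- quick_trace("torord", coupled = TRUE, n_beats = 2)
  epo <- quick_trace("torord", coupled = FALSE, n_beats = 2)
  # AP indistinguishable: < 1 mV RMS on the common grid
  n <- min(nrow(em), nrow(epo))
  rms <- sqrt(mean((em$v[1:n] - epo$v[1:n])^2))
  expect_lt(rms, 1)
  cat_em <- cat_biomarkers(em, 1)
  cat_ep <- cat_biomarkers(epo, 1)
  # larger amplitude and faster decay under the dynamic troponin buffer
  expect_gt(cat_em$amplitude, cat_ep$amplitude)
  expect_lt(cat_em$rt90, cat_ep$rt90)
  # and rt90 moves towards the experimental median (315.6 ms)
  expect_lt(abs(cat_em$rt90 - 315.6), abs(cat_ep$rt90 - 315.6))
})

test_that("mechanical systole ends closer to electrical systole under coupling", {
  # the window CaTD90 - APD90 (mechanical minus electrical systole) shrinks
  # when the calcium transient decays faster under the dynamic buffer
  em <- biomarkers(quick_trace("torord", coupled = TRUE, n_beats = 2), 1)
  epo <- biomarkers(quick_trace("torord", coupled = FALSE, n_beats = 2), 1)
  expect_lt(-em$emw, -epo$emw)
})

test_that("a zero-amplitude stimulus elicits no action potential", {
  st <- ss_snap("torord", "endo", 1000, TRUE)
  ep <- make_params("torord", "endo")
  mech <- make_mech_params("torord")
  tr <- pace(st, ep, mech,
             pacing_protocol(1000, 1, stim_amplitude = 0,
                             stim_duration = 1))
  expect_lt(max(tr$v), -60)
  expect_false(ap_biomarkers(tr, 1)$upstroke)
})

test_that("the published stimulus elicits an AP on every beat", {
  tr <- quick_trace("torord", n_beats = 5, record_last = 5)
  for (b in 1:5) expect_true(ap_biomarkers(tr, b)$upstroke)
})

test_that("biomarkers converge in the output sampling interval", {
  a <- ap_biomarkers(quick_trace("torord", n_beats = 1, dt_out = 0.5), 1)
  b <- ap_biomarkers(quick_trace("torord", n_beats = 1, dt_out = 0.25), 1)
  expect_lt(abs(a$apd90 - b$apd90), 0.5)
  expect_lt(abs(a$apd50 - b$apd50), 0.5)
})

test_that("identical configurations give bit-identical traces", {
  a <- quick_trace("torord", n_beats = 2)
  b <- quick_trace("torord", n_beats = 2)
  expect_identical(a$v, b$v)
  expect_identical(a$cai, b$cai)
  expect_identical(a$ta, b$ta)
})

test_that("tightening solver tolerances tenfold barely moves the biomarkers", {
  st <- ss_snap("torord", "endo", 1000, TRUE)
  ep <- make_params("torord", "endo")
  mech <- make_mech_params("torord")
  a <- pace(st, ep, mech, pacing_protocol(1000, 2, record_last = 1))
  b <- pace(st, ep, mech, pacing_protocol(1000, 2, record_last = 1),
            solver = solver_options(rtol = 1e-7, atol = 1e-9))
  expect_lt(abs(ap_biomarkers(a, 1)$apd90 - ap_biomarkers(b, 1)$apd90), 0.5)
  ta_a <- ta_biomarkers(a, 1)$peak; ta_b <- ta_biomarkers(b, 1)$peak
  expect_lt(abs(ta_a - ta_b) / ta_a, 0.005)
})

test_that("pace -> save -> load -> pace equals pacing through", {
  st <- ss_snap("torord", "endo", 1000, TRUE)
  ep <- make_params("torord", "endo")
  mech <- make_mech_params("torord")
  through <- pace(st, ep, mech, pacing_protocol(1000, 4, record_last = 1))
  half <- pace(st, ep, mech, pacing_protocol(1000, 2, record_last = 1))
  f <- tempfile(fileext = ".json")
  save_state(final_state(half), f)
  resumed <- pace(load_state(f), ep, mech,
                  pacing_protocol(1000, 2, record_last = 1))
  # resuming from a snapshot restarts the solver; the serialised state and
  # the adaptive step sequence agree only to the solver tolerance, so the
  # comparison is at solver-restart accuracy, not bitwise
  expect_equal(unname(as.numeric(final_state(resumed))),
               unname(as.numeric(final_state(through))), tolerance = 1e-5)
})

test_that("run_to_steady_state recognises an already-converged snapshot", {
  st <- ss_snap("torord", "endo", 1000, TRUE)
  ep <- make_params("torord", "endo")
  mech <- make_mech_params("torord")
  res <- run_to_steady_state(st, ep, mech, cl = 1000, max_beats = 100)
  expect_true(res$converged)
  expect_lte(res$n_beats, 30) # within the first check windows
  # post-hoc drift check: APD90 stays put over 50 further beats
  tr1 <- pace(res$state, ep, mech, pacing_protocol(1000, 1, record_last = 1))
  tr2 <- pace(res$state, ep, mech, pacing_protocol(1000, 50, record_last = 1))
  expect_lt(abs(ap_biomarkers(tr1, 1)$apd90 - ap_biomarkers(tr2, 1)$apd90),
            0.2)
})

test_that("steady tension grows with pacing frequency (positive staircase)", {
  ep <- make_params("torord", "endo")
  mech <- make_mech_params("torord")
  st <- ss_snap("torord", "endo", 1000, TRUE)
  # re-converge at 0.5 Hz and 2 Hz from the 1 Hz snapshot
  lo <- suppressWarnings(run_to_steady_state(st, ep, mech, cl = 2000, max_beats = 300))
  hi <- suppressWarnings(run_to_steady_state(st, ep, mech, cl = 500, max_beats = 400))
  ta_lo <- ta_biomarkers(pace(lo$state, ep, mech,
                              pacing_protocol(2000, 1)), 1)$amplitude
  ta_hi <- ta_biomarkers(pace(hi$state, ep, mech,
                              pacing_protocol(500, 1)), 1)$amplitude
  expect_gt(ta_hi, ta_lo)
})
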