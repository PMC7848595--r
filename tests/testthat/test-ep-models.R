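# Electrophysiology model construction and right-hand-side invariants.

test_that("celltype parameter sets derive from endo by published scalings", {
  for (variant in c("torord", "ord")) {
    endo <- make_params(variant, "endo")
    epi <- make_params(variant, "epi")
    mid <- make_params(variant, "mid")
    expect_equal(epi$conductances[["IKr"]], 1.3 * endo$conductances[["IKr"]])
    expect_equal(epi$conductances[["INaL"]], 0.6 * endo$conductances[["INaL"]])
    expect_equal(mid$conductances[["IK1"]], 1.3 * endo$conductances[["IK1"]])
    expect_equal(mid$conductances[["INaK"]], 0.7 * endo$conductances[["INaK"]])
    # untouched currents identical
    expect_equal(epi$conductances[["INa"]], endo$conductances[["INa"]])
    expect_equal(mid$conductances[["IKs"]], endo$conductances[["IKs"]])
  }
  expect_error(make_params("torord", "apex"))
  expect_error(make_params("torord", "endo", channel_scale = c(IFoo = 0.5)),
               "unknown current")
  expect_error(make_params("torord", "endo", channel_scale = c(IKr = 1.2)),
               "\\[0, 1\\]")
  # all scales 1 is the drug-free identity
  p1 <- make_params("torord", "endo")
  p2 <- make_params("torord", "endo",
                    channel_scale = setNames(rep(1, 3), c("IKr", "ICaL", "INa")))
  expect_identical(p1$conductances * p1$channel_scale,
                   p2$conductances * p2$channel_scale)
})

test_that("dV/dt equals the negative sum of the individually computed currents", {
  set.seed(11)
  for (variant in c("torord", "ord")) {
    ep <- make_params(variant, "endo")
    for (k in 1:500) {
      y <- rand_ep_state(variant)
      istim <- sample(c(0, -53), 1)
      r <- ep_rhs(0, y, ep, i_stim = istim)
      isum <- sum(r$currents[1:18]) + istim
      expect_lt(abs(r$dy[["v"]] + isum) / max(abs(isum), 1e-8), 1e-12)
    }
  }
})

test_that("conductance scaling is linear: half IKr scale halves IKr exactly", {
  for (variant in c("torord", "ord")) {
    y <- initial_state(variant, "endo", coupled = FALSE)
    y[["v"]] <- -20 # open some IKr
    r1 <- ep_rhs(0, y, make_params(variant, "endo"))
    r2 <- ep_rhs(0, y, make_params(variant, "endo",
                                   channel_scale = c(IKr = 0.5)))
    expect_equal(r2$currents[["IKr"]], 0.5 * r1$currents[["IKr"]],
                 tolerance = 1e-14)
    # all other currents unchanged
    others <- setdiff(names(r1$currents), c("IKr"))
    expect_equal(r1$currents[others], r2$currents[others], tolerance = 1e-14)
  }
})

test_that("the quiescent model is at rest and stays there for 100 s", {
  for (variant in c("torord", "ord")) {
    y0 <- initial_state(variant, "endo", coupled = FALSE)
    ep <- make_params(variant, "endo")
    r <- ep_rhs(0, y0, ep)
    expect_lt(abs(r$dy[["v"]]), 0.01) # mV/ms at rest
    p <- emcell:::.pack_parms(ep, NULL, istim = 0, coupled = FALSE)
    sol <- deSolve::lsoda(unname(as.numeric(y0)), c(0, 1e5),
                          func = "emcell_derivs", parms = p,
                          dllname = "emcell", initfunc = "emcell_initmod",
                          nout = 24L, outnames = emcell:::.out_names,
                          rtol = 1e-8, atol = 1e-10, maxsteps = 1e6)
    y1 <- sol[nrow(sol), 1 + seq_along(y0)]
    expect_lt(abs(y1[1] - y0[["v"]]), 1)  # < 1 mV drift
    drift <- abs(y1 - as.numeric(y0))
    # 1% relative with a 1e-4 absolute floor: sub-1e-4 movements of gates
    # whose resting values are themselves ~1e-4 are numerically meaningless
    expect_true(all(drift <= pmax(0.01 * abs(as.numeric(y0)), 1e-4)))
  }
})

test_that("gating bounds and concentration positivity hold on paced beats", {
  conc_names <- c("nai", "nass", "ki", "kss", "cai", "cass", "cansr", "cajsr")
  for (variant in c("torord", "ord")) {
    tr <- quick_trace(variant, n_beats = 3, record_last = 3, keep = "full")
    gates <- emcell:::.gate_names(variant)
    for (g in gates) {
      expect_gte(min(tr[[g]]), -1e-8)
      expect_lte(max(tr[[g]]), 1 + 1e-8)
    }
    for (cn in conc_names) expect_gt(min(tr[[cn]]), 0)
  }
})

test_that("initial states and snapshots round-trip bit-exactly through JSON", {
  y <- initial_state("torord", "mid", coupled = TRUE)
  f <- tempfile(fileext = ".json")
  save_state(y, f, metadata = list(note = "roundtrip"))
  z <- load_state(f)
  expect_identical(unname(as.numeric(z)), unname(as.numeric(y)))
  expect_identical(names(z), names(y))
  expect_identical(attr(z, "celltype"), "mid")
  # wrong-variant load is refused
  obj <- jsonlite::read_json(f, simplifyVector = TRUE)
  obj$variant <- "ord"
  jsonlite::write_json(obj, f, digits = NA, auto_unbox = TRUE)
  expect_error(load_state(f), "does not match")
})
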