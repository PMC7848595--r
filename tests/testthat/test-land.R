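# Land contraction model: dual-transcription oracle, analytic fixed points,
# decay behaviour, tension algebra, steady-state force-calcium curve.

test_that("compiled RHS matches an independent transcription to 1e-12", {
  set.seed(21)
  mech <- make_mech_params("torord", calibrated = FALSE)
  mechs <- list(mech,
                make_mech_params("torord", lambda_ = 1.1),
                make_mech_params("torord", lambda_ = 0.85,
                                 dlambda_dt = 0.001))
  for (mp in mechs) {
    for (k in 1:200) {
      m <- rand_mech_state()
      cai <- 10^runif(1, -4.5, -2.5) # mM
      a <- land_rhs(0, m, cai, mp)
      b <- land_rhs_reference(m, cai * 1000, mp)
      expect_lt(max(abs(a$dm - b$dm)), 1e-12)
      expect_lt(abs(a$ta - b$ta), 1e-12)
    }
  }
})

test_that("troponin occupancy has its fixed point at one half when cai = ca50", {
  mech <- make_mech_params("torord", calibrated = FALSE)
  m <- rand_mech_state()
  m[["catrpn"]] <- 0.5
  r <- land_rhs(0, m, mech$ca50 / 1000, mech) # ca50 is in uM, cai in mM
  expect_lt(abs(r$dm[["catrpn"]]), 1e-14)
  # and the fixed point is attracting: above it the derivative is negative
  m[["catrpn"]] <- 0.6
  expect_lt(land_rhs(0, m, mech$ca50 / 1000, mech)$dm[["catrpn"]], 0)
})

test_that("without calcium, activation and tension decay to zero", {
  mech <- make_mech_params("torord")
  m0 <- c(xs = 0.1, xw = 0.1, catrpn = 0.5, blocked = 0.5,
          zeta_s = 0, zeta_w = 0)
  f <- function(t, y, parms) list(land_rhs(t, y, 0, mech)$dm)
  sol <- deSolve::lsoda(m0, seq(0, 5000, by = 50), f,
                        rtol = 1e-10, atol = 1e-12)
  xs <- sol[, "xs"]; xw <- sol[, "xw"]; ca <- sol[, "catrpn"]
  expect_lt(xs[length(xs)], 1e-6)
  expect_lt(xw[length(xw)], 1e-6)
  expect_lt(ca[length(ca)], 1e-4)
  # attached mass decays monotonically once the initial redistribution
  # (unattached -> weak) has passed
  expect_true(all(diff((xs + xw)[-(1:20)]) <= 1e-12))
  yend <- sol[nrow(sol), 2:7]
  names(yend) <- names(m0)
  expect_lt(active_tension(yend, mech), 1e-4)
})

test_that("active tension is zero for empty crossbridges and linear in t_ref", {
  mech <- make_mech_params("torord")
  z <- c(xs = 0, xw = 0, catrpn = 0.3, blocked = 0.6, zeta_s = 0.2,
         zeta_w = -0.1)
  expect_identical(active_tension(z, mech), 0)
  m <- rand_mech_state()
  mech2 <- mech; mech2$t_ref <- 2 * mech$t_ref
  expect_equal(active_tension(m, mech2), 2 * active_tension(m, mech),
               tolerance = 1e-14)
})

test_that("steady-state force-calcium curve: two independent methods agree", {
  mech <- make_mech_params("torord")
  grid <- 10^seq(-4.3, -2.7, length.out = 9)
  alg <- steady_state_force_ca(mech, grid, method = "algebraic")
  ode <- steady_state_force_ca(mech, grid, method = "ode", t_end = 60000)
  expect_true(all(ode$converged))
  rel <- abs(ode$curve$tension - alg$curve$tension) /
    pmax(alg$curve$tension, 1e-3 * max(alg$curve$tension))
  expect_lt(max(rel), 1e-3) # 0.1%
  # monotone non-decreasing sigmoid
  expect_true(all(diff(alg$curve$tension) >= -1e-10))
})

test_that("reduced calcium sensitivity shifts the curve right and lowers twitch drive", {
  mech <- make_mech_params("torord")
  mech2 <- make_mech_params("torord", ca50 = mech$ca50 * 1.75)
  grid <- 10^seq(-4.3, -2.7, length.out = 9)
  a <- steady_state_force_ca(mech, grid)
  b <- steady_state_force_ca(mech2, grid)
  expect_gt(b$ec50, a$ec50)
  # at a sub-saturating calcium the desensitised model makes less force
  mid <- 5
  expect_lt(b$curve$tension[mid], a$curve$tension[mid])
})

test_that("steady developed tension increases with extension ratio on [0.8, 1]", {
  cai <- 5e-4 # mM, near twitch peak
  ta <- vapply(c(0.8, 0.85, 0.9, 0.95, 1.0), function(l) {
    emcell:::.land_steady_tension(make_mech_params("torord", lambda_ = l), cai)
  }, numeric(1))
  expect_true(all(diff(ta) > 0))
})
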