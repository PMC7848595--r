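# Shared fixtures and independent oracles for the test suite.

ss_snap <- function(variant = "torord", celltype = "endo", cl = 1000,
                    coupled = TRUE) {
  steady_state_snapshot(variant, celltype, cl = cl, coupled = coupled,
                        compute_if_missing = FALSE)
}

quick_trace <- function(variant = "torord", celltype = "endo", cl = 1000,
                        coupled = TRUE, n_beats = 2, record_last = 1,
                        keep = "trace", dt_out = 0.5) {
  ep <- make_params(variant, celltype)
  mech <- if (coupled) make_mech_params(variant) else NULL
  pace(ss_snap(variant, celltype, cl, coupled), ep, mech,
       pacing_protocol(cl = cl, n_beats = n_beats,
                       record_last = record_last, dt_out = dt_out),
       keep = keep)
}

# total calcium content of a full-state trace, expressed as mM of
# myoplasmic volume (free + instantaneous buffers + dynamic troponin +
# volume-weighted organelle calcium)
.ca_total <- function(tr, ep) {
  L <- 0.01; rad <- 0.0011
  vcell <- 1000 * 3.14 * rad^2 * L
  vmyo <- 0.68 * vcell; vnsr <- 0.0552 * vcell
  vjsr <- 0.0048 * vcell; vss <- 0.02 * vcell
  cmdn <- ep$cmdnmax * tr$cai / (0.00238 + tr$cai)
  bsr <- 0.047 * tr$cass / (0.00087 + tr$cass)
  bsl <- 1.124 * tr$cass / (0.0087 + tr$cass)
  csqn <- 10 * tr$cajsr / (0.8 + tr$cajsr)
  (vmyo * (tr$cai + cmdn + ep$trpnmax * tr$catrpn) +
     vss * (tr$cass + bsr + bsl) + vnsr * tr$cansr +
     vjsr * (tr$cajsr + csqn)) / vmyo
}

# independent second transcription of the Land 2017 right-hand side,
# written directly from the published equations (kept free of the C code)
land_rhs_reference <- function(m, cai_uM, mech) {
  XS <- max(0, m[["xs"]]); XW <- max(0, m[["xw"]])
  CaTRPN <- max(0, m[["catrpn"]]); B <- m[["blocked"]]
  ZS <- m[["zeta_s"]]; ZW <- m[["zeta_w"]]
  lam <- min(mech$lambda_, 1.2)
  h <- max(0, 1 + mech$beta_0 * (lam + min(lam, 0.87) - 1.87))
  kwu <- mech$k_uw * (1 / mech$wfrac - 1) - mech$k_ws
  ksu <- mech$k_ws * (1 / mech$dr - 1) * mech$wfrac
  cdw <- mech$phi * mech$k_uw * (1 - mech$dr) * (1 - mech$wfrac) /
    ((1 - mech$dr) * mech$wfrac)
  cds <- mech$phi * mech$k_ws * (1 - mech$dr) * mech$wfrac / mech$dr
  Ag <- (0.25 * mech$tot_a) / ((1 - mech$dr) * mech$wfrac + mech$dr) *
    (mech$dr / 0.25)
  XU <- (1 - B) - XW - XS
  g_s <- mech$gamma_s * max(ifelse(ZS > 0, ZS, 0), ifelse(ZS < -1, -ZS - 1, 0))
  g_w <- mech$gamma_wu * abs(ZW)
  dXS <- mech$k_ws * XW - ksu * XS - g_s * XS
  dXW <- mech$k_uw * XU - kwu * XW - mech$k_ws * XW - g_w * XW
  ca50l <- mech$ca50 + mech$beta_1 * (lam - 1)
  dCa <- mech$k_trpn * ((max(cai_uM, 0) / ca50l)^mech$n_trpn * (1 - CaTRPN) -
                          CaTRPN)
  XSSS <- mech$dr * 0.5
  XWSS <- (1 - mech$dr) * mech$wfrac * 0.5
  kb <- mech$k_tm * mech$perm50^mech$n_tm * 0.5 / (0.5 - XSSS - XWSS)
  ct <- max(CaTRPN, 1e-12)
  dB <- kb * min(100, ct^(-mech$n_tm / 2)) * XU -
    mech$k_tm * ct^(mech$n_tm / 2) * B
  dZS <- Ag * mech$dlambda_dt - cds * ZS
  dZW <- Ag * mech$dlambda_dt - cdw * ZW
  ta <- h * (mech$t_ref / mech$dr) * ((ZS + 1) * XS + ZW * XW)
  list(dm = c(xs = dXS, xw = dXW, catrpn = dCa, blocked = dB,
              zeta_s = dZS, zeta_w = dZW), ta = ta)
}

rand_mech_state <- function() {
  xs <- runif(1, 0, 0.25); xw <- runif(1, 0, 0.25)
  blocked <- runif(1, 0, 1 - xs - xw)
  c(xs = xs, xw = xw, catrpn = runif(1, 0.01, 0.95), blocked = blocked,
    zeta_s = runif(1, -1.5, 1), zeta_w = runif(1, -1, 1))
}

rand_ep_state <- function(variant, coupled = FALSE) {
  y <- initial_state(variant, "endo", coupled = coupled)
  y[["v"]] <- runif(1, -90, 40)
  for (nm in c("nai", "nass")) y[[nm]] <- runif(1, 4, 14)
  for (nm in c("ki", "kss")) y[[nm]] <- runif(1, 120, 150)
  for (nm in c("cai", "cass")) y[[nm]] <- 10^runif(1, -4.5, -3)
  for (nm in c("cansr", "cajsr")) y[[nm]] <- runif(1, 0.5, 2.5)
  gates <- setdiff(emcell:::.gate_names(variant),
                   c("ikr_c0", "ikr_c1", "ikr_c2", "ikr_o", "ikr_i"))
  for (nm in gates) y[[nm]] <- runif(1)
  if (variant == "torord") {
    w <- runif(5); w <- w / sum(w)
    y[c("ikr_c0", "ikr_c1", "ikr_c2", "ikr_o", "ikr_i")] <- w
  }
  y[["camk_trap"]] <- runif(1, 0, 0.1)
  for (nm in c("jrel_np", "jrel_p")) y[[nm]] <- runif(1, 0, 0.5)
  if (coupled) y[emcell:::.state_names_mech] <- rand_mech_state()
  y
}

expect_within <- function(value, lower, upper, label = "value") {
  expect_true(is.finite(value) && value >= lower && value <= upper,
              label = sprintf("%s = %g not in [%g, %g]", label, value,
                              lower, upper))
}
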