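# Right-hand-side access and pacing protocols.

#' Evaluate the model right-hand side at one state
#'
#' Direct access to the compiled right-hand side, mainly for verification:
#' the returned list carries the state derivatives and every individually
#' computed transmembrane current and flux, so that the identity
#' dV/dt = -(sum of currents + i_stim) can be audited externally.
#'
#' `coupled_rhs()` evaluates the fully coupled system (electrophysiology +
#' Land contraction with dynamic troponin feedback); `ep_rhs()` evaluates the
#' electrophysiology-only model with its published steady-state troponin
#' buffer, or, when `j_trpn_buffer` is supplied, with that external
#' calcium-troponin flux (mM/ms) substituted into the calcium balance.
#'
#' @param t time (ms); the models are autonomous, kept for solver signature.
#' @param state named state vector (see [initial_state()]).
#' @param ep `ep_params`.
#' @param mech `mech_params` (coupled form).
#' @param i_stim stimulus current density, uA/uF (negative = depolarising).
#' @param j_trpn_buffer optional external troponin-calcium flux (mM/ms)
#'   replacing the internal steady-state troponin buffering of d[Ca]i/dt.
#' @return list with `dy` (named derivatives) and `currents` (named,
#'   uA/uF for currents, mM/ms for fluxes, kPa for `Ta`).
#' @export
coupled_rhs <- function(t, state, ep, mech, i_stim = 0) {
  .check_state(state, ep, coupled = TRUE)
  p <- .pack_parms(ep, mech, istim = i_stim, coupled = TRUE)
  r <- .Call(C_emcell_rhs, as.numeric(t), as.numeric(state), p)
  .rhs_result(r, ep$variant, coupled = TRUE)
}

#' @rdname coupled_rhs
#' @export
ep_rhs <- function(t, state, ep, i_stim = 0, j_trpn_buffer = NULL) {
  .check_state(state, ep, coupled = FALSE)
  p <- .pack_parms(ep, NULL, istim = i_stim, coupled = FALSE)
  r <- .Call(C_emcell_rhs, as.numeric(t), as.numeric(state), p)
  res <- .rhs_result(r, ep$variant, coupled = FALSE)
  if (!is.null(j_trpn_buffer)) {
    # replace the internal instantaneous troponin buffer by the external flux
    cai <- state[["cai"]]
    kmcmdn <- 0.00238; kmtrpn <- 0.0005
    b_legacy <- 1 / (1 + ep$cmdnmax * kmcmdn / (kmcmdn + cai)^2 +
                       ep$trpnmax * kmtrpn / (kmtrpn + cai)^2)
    b_cmdn <- 1 / (1 + ep$cmdnmax * kmcmdn / (kmcmdn + cai)^2)
    raw <- res$dy[["cai"]] / b_legacy       # unbuffered net flux
    res$dy[["cai"]] <- b_cmdn * (raw - j_trpn_buffer)
    res$currents[["Jtrpn"]] <- j_trpn_buffer
  }
  if (any(!is.finite(res$dy))) {
    bad <- names(res$dy)[!is.finite(res$dy)]
    stop("non-finite derivative for state(s): ", paste(bad, collapse = ", "))
  }
  res
}

.rhs_result <- function(r, variant, coupled) {
  dy <- r$dy
  names(dy) <- .state_names(variant, coupled)
  cur <- r$out
  names(cur) <- .out_names
  list(dy = dy, currents = cur)
}

#' Land model right-hand side and active tension
#'
#' `land_rhs()` returns the time derivatives of the six contraction states
#' for a given free calcium; `active_tension()` evaluates the algebraic
#' tension output (kPa) for a mechanics state. Tension is computed here in R,
#' independently of the compiled coupled model, so the two transcriptions can
#' be cross-checked.
#'
#' @param t time (ms), unused (autonomous).
#' @param m named mechanics state (`xs`, `xw`, `catrpn`, `blocked`,
#'   `zeta_s`, `zeta_w`).
#' @param cai free calcium, mM.
#' @param mech `mech_params`.
#' @return `land_rhs`: list with `dm` (derivatives, 1/ms) and `ta` (kPa).
#' @export
land_rhs <- function(t, m, cai, mech) {
  stopifnot(inherits(mech, "mech_params"), cai >= 0)
  ep <- make_params("torord", "endo") # carrier for packing only
  p <- .pack_parms(ep, mech, coupled = TRUE)
  r <- .Call(C_land_rhs, as.numeric(m[.state_names_mech]),
             as.numeric(cai) * 1000, p)
  dm <- r$dm
  names(dm) <- .state_names_mech
  if (any(!is.finite(dm))) stop("non-finite mechanics derivative")
  list(dm = dm, ta = r$ta)
}

#' @rdname land_rhs
#' @export
active_tension <- function(m, mech) {
  stopifnot(inherits(mech, "mech_params"))
  lam <- min(mech$lambda_, 1.2)
  h <- max(0, 1 + mech$beta_0 * (lam + min(lam, 0.87) - 1.87))
  h * (mech$t_ref / mech$dr) *
    ((m[["zeta_s"]] + 1) * m[["xs"]] + m[["zeta_w"]] * m[["xw"]])
}

#' Pacing protocol description
#'
#' @param cl cycle length, ms.
#' @param n_beats number of paced beats.
#' @param stim_amplitude stimulus current density, uA/uF (negative).
#'   Defaults to the variant-specific published stimulus when used through
#'   [pace()]: -53 uA/uF for 1 ms (ToR-ORd), -80 uA/uF for 0.5 ms (ORd).
#' @param stim_duration stimulus duration, ms.
#' @param record_last number of final beats stored in the returned trace.
#' @param dt_out output sampling interval, ms.
#' @export
pacing_protocol <- function(cl = 1000, n_beats = 1, stim_amplitude = NULL,
                            stim_duration = NULL, record_last = n_beats,
                            dt_out = 0.5) {
  stopifnot(cl > 0, n_beats >= 1, dt_out > 0, record_last >= 1)
  structure(list(cl = cl, n_beats = as.integer(n_beats),
                 stim_amplitude = stim_amplitude,
                 stim_duration = stim_duration,
                 record_last = min(as.integer(record_last), as.integer(n_beats)),
                 dt_out = dt_out),
            class = "pacing_protocol")
}

.default_stim <- function(variant) {
  # published stimulus currents of the source models
  if (variant == "torord") c(amplitude = -53, duration = 1.0)
  else c(amplitude = -80, duration = 0.5)
}

#' Solver settings
#'
#' Stiff implicit integration (lsoda) with the package defaults
#' rtol 1e-6 / atol 1e-8.
#' @param rtol,atol relative/absolute tolerances.
#' @param maxsteps maximal internal steps per output interval.
#' @export
solver_options <- function(rtol = 1e-6, atol = 1e-8, maxsteps = 100000L) {
  list(rtol = rtol, atol = atol, maxsteps = as.integer(maxsteps))
}

# integrate one constant-stimulus segment; returns deSolve matrix
.integrate_segment <- function(y, t0, t1, parms, dt_out, solver) {
  times <- seq(t0, t1, by = dt_out)
  if (times[length(times)] < t1) times <- c(times, t1)
  out <- deSolve::lsoda(y = unname(as.numeric(y)), times = times,
                        func = "emcell_derivs", parms = parms,
                        dllname = "emcell", initfunc = "emcell_initmod",
                        nout = length(.out_names), outnames = .out_names,
                        rtol = solver$rtol, atol = solver$atol,
                        maxsteps = solver$maxsteps)
  if (attr(out, "istate")[1] < 0)
    stop("solver failure (istate ", attr(out, "istate")[1], ")")
  out
}

#' Pace the model
#'
#' Applies the stimulus as a square current pulse at the start of every
#' cycle, re-initialising the solver at the pulse edges so no stimulus is
#' skipped, and returns the uniformly resampled trace of the final
#' `record_last` beats plus the final state.
#'
#' @param state starting `coupled_state` (see [initial_state()],
#'   [steady_state_snapshot()]).
#' @param ep `ep_params`.
#' @param mech `mech_params` or `NULL` for the electrophysiology-only model.
#' @param protocol a [pacing_protocol()].
#' @param solver [solver_options()].
#' @param keep `"trace"` (V, CaT, Ta) or `"full"` (all states and currents).
#' @return a `beat_trace`: data frame with columns `t` (ms), `v` (mV),
#'   `cai` (mM), `ta` (kPa), attributes `stim_times`, `cl`, `final_state`,
#'   `meta`.
#' @export
pace <- function(state, ep, mech = NULL, protocol = pacing_protocol(),
                 solver = solver_options(), keep = c("trace", "full")) {
  keep <- match.arg(keep)
  coupled <- !is.null(mech)
  .check_state(state, ep, coupled)
  stim <- .default_stim(ep$variant)
  amp <- protocol$stim_amplitude %||% stim[["amplitude"]]
  dur <- protocol$stim_duration %||% stim[["duration"]]
  stopifnot(protocol$cl > dur, dur > 0)

  p_on <- .pack_parms(ep, mech, istim = amp, coupled = coupled)
  p_off <- .pack_parms(ep, mech, istim = 0, coupled = coupled)

  y <- as.numeric(state)
  nb <- protocol$n_beats
  first_rec <- nb - protocol$record_last + 1L
  rows <- vector("list", 2L * protocol$record_last)
  ri <- 0L
  stim_times <- numeric(0)
  for (b in seq_len(nb)) {
    t0 <- (b - 1) * protocol$cl
    rec <- b >= first_rec
    seg1 <- .integrate_segment(y, t0, t0 + dur, p_on, protocol$dt_out, solver)
    y <- seg1[nrow(seg1), 1 + seq_along(y)]
    seg2 <- .integrate_segment(y, t0 + dur, t0 + protocol$cl, p_off,
                               protocol$dt_out, solver)
    y <- seg2[nrow(seg2), 1 + seq_along(y)]
    if (any(!is.finite(y)))
      stop(sprintf("solver failure at beat %d: non-finite state", b))
    if (rec) {
      rows[[ri <- ri + 1L]] <- seg1[-nrow(seg1), , drop = FALSE]
      rows[[ri <- ri + 1L]] <- seg2
      stim_times <- c(stim_times, t0)
    }
  }
  m <- do.call(rbind, rows[seq_len(ri)])
  # drop duplicated segment-boundary rows
  m <- m[!duplicated(m[, 1]), , drop = FALSE]
  snames <- .state_names(ep$variant, coupled)
  colnames(m) <- c("t", snames, .out_names)
  df <- data.frame(t = m[, "t"], v = m[, "v"], cai = m[, "cai"],
                   ta = if (coupled) m[, "Ta"] else 0)
  if (keep == "full") df <- cbind(df, as.data.frame(m[, -(1:2), drop = FALSE]))
  final <- .as_state(y, ep$variant, ep$celltype, coupled)
  structure(df,
            class = c("beat_trace", "data.frame"),
            stim_times = stim_times, cl = protocol$cl,
            dt_out = protocol$dt_out,
            final_state = final,
            meta = list(variant = ep$variant, celltype = ep$celltype,
                        coupled = coupled, cl = protocol$cl,
                        stim_amplitude = amp, stim_duration = dur,
                        drug = ep$drug,
                        solver = solver[c("rtol", "atol")]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Final state of a paced trace
#' @param trace a `beat_trace` from [pace()].
#' @export
final_state <- function(trace) attr(trace, "final_state")

#' Pace to steady state
#'
#' Paces at cycle length `cl` until the beat-to-beat relative changes of
#' APD90, calcium-transient peak and (for coupled models) peak tension over a
#' 10-beat window all fall below `tol`, or `max_beats` is reached.
#'
#' @inheritParams pace
#' @param cl cycle length, ms.
#' @param tol relative convergence tolerance (default 0.05%).
#' @param max_beats beat budget (default 1500).
#' @param block beats per convergence check window.
#' @return list with `state` (final `coupled_state`), `converged` (logical),
#'   `n_beats`, and `history` (per-block metrics).
#' @export
run_to_steady_state <- function(state, ep, mech = NULL, cl = 1000,
                                tol = 5e-4, max_beats = 1500, block = 10,
                                solver = solver_options()) {
  coupled <- !is.null(mech)
  prev <- NULL
  n <- 0L
  hist <- list()
  converged <- FALSE
  while (n < max_beats) {
    tr <- pace(state, ep, mech,
               pacing_protocol(cl = cl, n_beats = block, record_last = 1),
               solver = solver)
    state <- final_state(tr)
    n <- n + block
    bm <- tryCatch(.ss_metrics(tr), error = function(e) NULL)
    hist[[length(hist) + 1L]] <- c(beat = n, bm)
    if (!is.null(bm) && !is.null(prev) && all(is.finite(bm)) &&
        all(is.finite(prev))) {
      rel <- abs(bm - prev) / pmax(abs(prev), 1e-12)
      if (all(rel < tol)) { converged <- TRUE; break }
    }
    prev <- bm
  }
  if (!converged)
    warning(sprintf("steady-state criterion not met within %d beats", max_beats))
  list(state = state, converged = converged, n_beats = n,
       history = do.call(rbind, hist))
}

.ss_metrics <- function(tr) {
  ap <- ap_biomarkers(tr, 1)
  cat <- cat_biomarkers(tr, 1)
  out <- c(apd90 = ap$apd90, cat_peak = cat$peak)
  if (attr(tr, "meta")$coupled) {
    ta <- ta_biomarkers(tr, 1)
    out <- c(out, ta_peak = ta$peak)
  }
  out
}
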