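# Recalibration of the Land model against human twitch-tension biomarkers,
# and the transmural calcium-sensitivity scan.

#' Default active-tension calibration targets
#'
#' Target intervals for the 1 Hz twitch, pooled from human isometric twitch
#' studies at 1-1.2 Hz (mean +/- 2 SEM per study, union across studies):
#' amplitude (kPa = mN/mm^2), time to peak, and relaxation times at 50% and
#' 95% decay (ms).
#'
#' @param widen multiplicative widening of each interval about its centre.
#' @return data frame with columns `biomarker`, `lower`, `upper`, `weight`.
#' @export
tension_targets <- function(widen = 1) {
  t <- data.frame(
    biomarker = c("amplitude", "tp", "rt50", "rt95"),
    lower = c(10.1, 137, 101, 248),
    upper = c(25.6, 179, 133, 539),
    weight = c(1, 1, 1, 1)
  )
  if (widen != 1) {
    mid <- (t$lower + t$upper) / 2
    half <- (t$upper - t$lower) / 2 * widen
    t$lower <- mid - half
    t$upper <- mid + half
  }
  t
}

.interval_cost <- function(value, lower, upper) {
  w <- upper - lower
  if (!is.finite(value)) return(10)             # unresolved biomarker
  if (value < lower) (lower - value) / w
  else if (value > upper) (value - upper) / w
  else 0
}

#' Calibrate the Land model inside the coupled system
#'
#' Adjusts the two contraction parameters identified for recalibration -
#' the Hill coefficient of cooperative (tropomyosin) activation `n_tm` and
#' the tropomyosin rate constant `k_tm` - so that the twitch tension of the
#' fully coupled paced model matches human target intervals. The cost is the
#' weighted sum over biomarkers of the distance to the target interval
#' normalised by the interval width (zero iff every biomarker is inside its
#' interval). A bounded derivative-free search is used: a coarse
#' log-spaced grid followed by Nelder-Mead refinement.
#'
#' Calibration touches mechanics only; electrophysiology parameters are
#' never altered.
#'
#' @inheritParams drug_trial
#' @param targets data frame as from [tension_targets()].
#' @param bounds named list with elements `n_tm` and `k_tm`, each
#'   `c(lower, upper)`.
#' @param mech starting mechanics parameters (default: published Land set).
#' @param settle_beats beats paced per cost evaluation before the measured
#'   beat (the start state is re-used across evaluations).
#' @param grid_n points per parameter in the coarse grid stage.
#' @param maxit Nelder-Mead iteration budget.
#' @return object of class `land_calibration`: calibrated `mech_params`,
#'   achieved biomarkers, cost, and the convergence log.
#' @export
calibrate_land <- function(variant = "torord", celltype = "endo",
                           targets = tension_targets(),
                           bounds = list(n_tm = c(1.2, 8),
                                         k_tm = c(0.004, 0.12)),
                           mech = NULL, cl = 1000, settle_beats = 25,
                           start = NULL, grid_n = 4, maxit = 60,
                           solver = solver_options()) {
  variant <- .check_variant(variant)
  if (is.null(mech)) mech <- make_mech_params(variant, calibrated = FALSE)
  if (is.null(start))
    start <- steady_state_snapshot(variant, celltype, cl = cl, coupled = TRUE)
  ep <- make_params(variant, celltype)
  log_rows <- list()

  eval_point <- function(n_tm, k_tm) {
    m <- mech
    m$n_tm <- n_tm; m$k_tm <- k_tm
    tr <- pace(start, ep, m,
               pacing_protocol(cl = cl, n_beats = settle_beats,
                               record_last = 1),
               solver = solver)
    ta <- ta_biomarkers(tr, 1)
    got <- c(amplitude = ta$amplitude, tp = ta$tp, rt50 = ta$rt50,
             rt95 = ta$rt95)
    cost <- sum(targets$weight * mapply(.interval_cost, got[targets$biomarker],
                                        targets$lower, targets$upper))
    log_rows[[length(log_rows) + 1L]] <<-
      c(n_tm = n_tm, k_tm = k_tm, cost = cost, got)
    list(cost = cost, got = got)
  }

  # starting point first: if targets are already met, keep it
  s0 <- eval_point(mech$n_tm, mech$k_tm)
  best <- list(par = c(mech$n_tm, mech$k_tm), cost = s0$cost, got = s0$got)
  if (best$cost > 0) {
    gs <- expand.grid(
      n_tm = exp(seq(log(bounds$n_tm[1]), log(bounds$n_tm[2]),
                     length.out = grid_n)),
      k_tm = exp(seq(log(bounds$k_tm[1]), log(bounds$k_tm[2]),
                     length.out = grid_n)))
    for (i in seq_len(nrow(gs))) {
      r <- eval_point(gs$n_tm[i], gs$k_tm[i])
      if (r$cost < best$cost)
        best <- list(par = c(gs$n_tm[i], gs$k_tm[i]), cost = r$cost,
                     got = r$got)
      if (best$cost == 0) break
    }
    if (best$cost > 0) {
      obj <- function(lp) {
        p <- exp(lp)
        if (p[1] < bounds$n_tm[1] || p[1] > bounds$n_tm[2] ||
            p[2] < bounds$k_tm[1] || p[2] > bounds$k_tm[2]) return(1e3)
        eval_point(p[1], p[2])$cost
      }
      op <- stats::optim(log(best$par), obj, method = "Nelder-Mead",
                         control = list(maxit = maxit, reltol = 1e-4))
      if (op$value < best$cost) {
        p <- exp(op$par)
        r <- eval_point(p[1], p[2])
        best <- list(par = p, cost = r$cost, got = r$got)
      }
    }
  }
  out_mech <- mech
  out_mech$n_tm <- best$par[1]; out_mech$k_tm <- best$par[2]
  structure(list(mech = out_mech,
                 par = c(n_tm = best$par[1], k_tm = best$par[2]),
                 cost = best$cost, achieved = best$got, targets = targets,
                 converged = best$cost == 0,
                 log = do.call(rbind, log_rows),
                 variant = variant, celltype = celltype, cl = cl),
            class = "land_calibration")
}

#' @export
print.land_calibration <- function(x, ...) {
  cat(sprintf("<land_calibration> %s+Land %s, CL %g ms\n", toupper(x$variant),
              x$celltype, x$cl))
  cat(sprintf("  n_tm = %.4g, k_tm = %.4g /ms; cost = %.4g (%s)\n",
              x$par[["n_tm"]], x$par[["k_tm"]], x$cost,
              if (x$converged) "all targets met" else "best effort"))
  tg <- x$targets
  for (i in seq_len(nrow(tg)))
    cat(sprintf("  %-9s %.1f  (target [%.1f, %.1f])\n", tg$biomarker[i],
                x$achieved[[tg$biomarker[i]]], tg$lower[i], tg$upper[i]))
  invisible(x)
}

#' @export
coef.land_calibration <- function(object, ...) object$par

#' @export
summary.land_calibration <- function(object, ...) {
  cat(sprintf("Calibration evaluations: %d\n", nrow(object$log)))
  print(object)
  invisible(object)
}

#' Myofilament calcium-sensitivity scan
#'
#' Scales the contraction model's half-activation calcium (Ca50) of one cell
#' type by each factor (factor > 1 means reduced sensitivity), re-converges
#' the twitch, and records peak active tension and calcium-transient
#' amplitude. Also reports the factor sub-range where the scanned cell
#' type's peak tension falls within +/- `match_tol` of the endocardial peak
#' tension, as an estimate of the additional transmural heterogeneity in
#' calcium sensitivity needed to match experimental tension data.
#'
#' @inheritParams drug_trial
#' @param factors positive multiplicative factors applied to Ca50.
#' @param reference_celltype cell type whose peak tension is matched.
#' @param settle_beats beats paced per factor before measuring.
#' @param match_tol relative matching tolerance (default 0.05).
#' @return object of class `ca50_scan`: per-factor table and the matching
#'   factor sub-range (possibly empty).
#' @export
ca50_scan <- function(variant = "torord", celltype = "epi",
                      factors = seq(0.25, 2, by = 0.25), cl = 1000,
                      reference_celltype = "endo", settle_beats = 40,
                      match_tol = 0.05, solver = solver_options()) {
  variant <- .check_variant(variant)
  stopifnot(all(factors > 0))
  mech <- make_mech_params(variant)
  ep <- make_params(variant, celltype)
  start <- steady_state_snapshot(variant, celltype, cl = cl, coupled = TRUE)

  ref_start <- steady_state_snapshot(variant, reference_celltype, cl = cl,
                                     coupled = TRUE)
  ref_tr <- pace(ref_start, make_params(variant, reference_celltype), mech,
                 pacing_protocol(cl = cl, n_beats = 3, record_last = 1),
                 solver = solver)
  ref_peak <- ta_biomarkers(ref_tr, 1)$amplitude

  rows <- lapply(factors, function(f) {
    m <- mech
    m$ca50 <- mech$ca50 * f
    tr <- pace(start, ep, m,
               pacing_protocol(cl = cl, n_beats = settle_beats,
                               record_last = 1),
               solver = solver)
    ta <- ta_biomarkers(tr, 1)
    ct <- cat_biomarkers(tr, 1)
    c(factor = f, ta_peak = ta$amplitude, ta_tp = ta$tp,
      cat_amplitude = ct$amplitude)
  })
  tab <- as.data.frame(do.call(rbind, rows))
  rel <- tab$ta_peak / ref_peak
  match <- abs(rel - 1) <= match_tol
  rng <- if (any(match)) range(tab$factor[match]) else c(NA_real_, NA_real_)
  structure(list(table = tab, reference_peak = ref_peak,
                 match_range = rng, match_tol = match_tol,
                 variant = variant, celltype = celltype,
                 reference_celltype = reference_celltype),
            class = "ca50_scan")
}

#' @export
print.ca50_scan <- function(x, ...) {
  cat(sprintf("<ca50_scan> %s+Land %s vs %s\n", toupper(x$variant),
              x$celltype, x$reference_celltype))
  print(x$table, row.names = FALSE)
  cat(sprintf("  reference peak (endo): %.2f kPa\n", x$reference_peak))
  if (is.na(x$match_range[1]))
    cat("  no factor matches the reference peak within tolerance\n")
  else
    cat(sprintf("  matching Ca50 factor range (+/-%g%%): [%.3g, %.3g]\n",
                100 * x$match_tol, x$match_range[1], x$match_range[2]))
  invisible(x)
}
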