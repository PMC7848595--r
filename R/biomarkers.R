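# Biomarkers of the action potential, calcium transient and active tension,
# plus detectors for repolarisation and contraction abnormalities.
#
# Conventions (held fixed across all compared conditions):
#  - time-to-peak (tp) is measured from stimulus onset;
#  - resting / diastolic reference is the value immediately before the
#    stimulus (not a global minimum), so abnormal beats still have defined
#    thresholds;
#  - APDx is the time from stimulus onset to the interpolated downward
#    crossing of peak - x% * (peak - resting);
#  - rtX is the time from the signal peak to the interpolated decay of
#    X% of (peak - diastolic);
#  - the calcium-transient duration used for the electro-mechanical window
#    is CaTD90 = tp + rt90.

.beat_window <- function(trace, beat) {
  st <- attr(trace, "stim_times")
  cl <- attr(trace, "cl")
  if (beat < 1 || beat > length(st))
    stop("beat index out of range (trace holds ", length(st), " beats)")
  t0 <- st[beat]
  idx <- trace$t >= t0 & trace$t < t0 + cl
  # pre-stimulus reference: last sample strictly before the stimulus when
  # the trace holds one, else the first sample of the window (which, for
  # simulated traces, is the state at the instant the pulse switches on)
  pre <- which(trace$t < t0)
  list(t = trace$t[idx], t0 = t0, idx = idx,
       pre_idx = if (length(pre)) pre[length(pre)] else which(idx)[1],
       next_stim = if (beat < length(st)) st[beat + 1] else t0 + cl)
}

# interpolated first downward crossing of `level` after index `from`
.cross_down <- function(t, x, level, from = 1) {
  n <- length(x)
  if (from >= n) return(NA_real_)
  for (i in seq(from, n - 1)) {
    if (x[i] >= level && x[i + 1] < level) {
      f <- (x[i] - level) / (x[i] - x[i + 1])
      return(t[i] + f * (t[i + 1] - t[i]))
    }
  }
  NA_real_
}

#' Action potential biomarkers of one beat
#'
#' @param trace a `beat_trace`.
#' @param beat beat index within the trace (1 = first recorded beat).
#' @return list with `tp`, `apd50`, `apd90` (ms), `peak`, `resting` (mV),
#'   `dvdt_max` (mV/ms), and logicals `upstroke` (stimulus captured) and
#'   `repol_failure` (no 90% repolarisation before the next stimulus).
#' @export
ap_biomarkers <- function(trace, beat = 1) {
  w <- .beat_window(trace, beat)
  t <- w$t; v <- trace$v[w$idx]
  resting <- trace$v[w$pre_idx]
  # slope including the pre-stimulus sample, so an upstroke at the window
  # boundary is still seen
  tt <- c(trace$t[w$pre_idx], t); vv <- c(resting, v)
  keep <- diff(tt) > 0
  dvdt <- (diff(vv) / diff(tt))[keep]
  dvdt_max <- max(dvdt)
  if (!length(dvdt) || dvdt_max < 10)
    return(list(tp = NA_real_, apd50 = NA_real_, apd90 = NA_real_,
                peak = max(v), resting = resting, dvdt_max = dvdt_max,
                upstroke = FALSE, repol_failure = FALSE))
  ipk <- which.max(v)
  peak <- v[ipk]
  tp <- t[ipk] - w$t0
  apd <- function(x) {
    lev <- peak - x / 100 * (peak - resting)
    tc <- .cross_down(t, v, lev, from = ipk)
    if (is.na(tc)) NA_real_ else tc - w$t0
  }
  apd50 <- apd(50); apd90 <- apd(90)
  list(tp = tp, apd50 = apd50, apd90 = apd90, peak = peak, resting = resting,
       dvdt_max = dvdt_max, upstroke = TRUE, repol_failure = is.na(apd90))
}

.transient_biomarkers <- function(trace, beat, col, decays) {
  w <- .beat_window(trace, beat)
  t <- w$t; x <- trace[[col]][w$idx]
  diastolic <- trace[[col]][w$pre_idx]
  ipk <- which.max(x)
  peak <- x[ipk]
  tp <- t[ipk] - w$t0
  amp <- peak - diastolic
  rt <- lapply(decays, function(d) {
    lev <- peak - d / 100 * amp
    tc <- .cross_down(t, x, lev, from = ipk)
    if (is.na(tc)) NA_real_ else tc - t[ipk]
  })
  names(rt) <- paste0("rt", decays)
  c(list(tp = tp, peak = peak, diastolic = diastolic, amplitude = amp), rt)
}

#' Calcium transient biomarkers of one beat
#' @inheritParams ap_biomarkers
#' @return list with `tp`, `rt50`, `rt90` (ms), `peak`, `diastolic`,
#'   `amplitude` (mM) and `duration90` (= tp + rt90, ms).
#' @export
cat_biomarkers <- function(trace, beat = 1) {
  b <- .transient_biomarkers(trace, beat, "cai", c(50, 90))
  b$duration90 <- b$tp + b$rt90
  b
}

#' Active tension biomarkers of one beat
#' @inheritParams ap_biomarkers
#' @param noise_floor developed tension (kPa) below which the beat is
#'   annotated as a contractility escape.
#' @return list with `tp`, `rt50`, `rt95` (ms), `peak`, `diastolic`,
#'   `amplitude` (kPa) and logical `escape`.
#' @export
ta_biomarkers <- function(trace, beat = 1, noise_floor = 1e-3) {
  b <- .transient_biomarkers(trace, beat, "ta", c(50, 95))
  b$escape <- b$amplitude < noise_floor
  b
}

#' Detect early afterdepolarisations on one beat
#'
#' An EAD is flagged when the membrane potential slope turns positive
#' (exceeds `slope_tol` for at least `min_duration` ms) during the
#' repolarisation phase: after the action potential has repolarised by
#' `repol_frac` of its amplitude from the peak (which excludes the
#' spike-notch-dome plateau morphology of the healthy AP), before the next
#' stimulus, with V above resting + 10 mV.
#'
#' @inheritParams ap_biomarkers
#' @param slope_tol positive-slope threshold, mV/ms.
#' @param min_duration minimal persistence of the positive slope, ms.
#' @param repol_frac fraction of repolarisation from peak at which the
#'   search window opens (default 0.3).
#' @return list `(detected, times)`; `times` are the onsets (ms) of the
#'   positive-slope episodes.
#' @export
detect_eads <- function(trace, beat = 1, slope_tol = 0.01,
                        min_duration = 2, repol_frac = 0.3) {
  w <- .beat_window(trace, beat)
  t <- w$t; v <- trace$v[w$idx]
  resting <- trace$v[w$pre_idx]
  ipk <- which.max(v)
  level <- max(v) - repol_frac * (max(v) - resting)
  below <- which(seq_along(v) > ipk & v < level)
  if (!length(below)) return(list(detected = FALSE, times = numeric(0)))
  .positive_slope_episodes(t, v, from = below[1], floor = resting + 10,
                           slope_tol = slope_tol, min_duration = min_duration)
}

#' Detect aftercontractions on one beat
#'
#' Analogue of [detect_eads()] on the active tension signal: a secondary
#' rise of tension during the relaxation phase, after the tension peak and
#' before the next stimulus. The default slope tolerance is 0.1% of the beat
#' peak tension per ms.
#'
#' @inheritParams detect_eads
#' @param slope_tol positive-slope threshold, kPa/ms; default
#'   `0.001 * peak tension`.
#' @export
detect_aftercontractions <- function(trace, beat = 1, slope_tol = NULL,
                                     min_duration = 2) {
  w <- .beat_window(trace, beat)
  t <- w$t; ta <- trace$ta[w$idx]
  ipk <- which.max(ta)
  if (is.null(slope_tol)) slope_tol <- 0.001 * max(ta)
  .positive_slope_episodes(t, ta, from = ipk, floor = -Inf,
                           slope_tol = slope_tol, min_duration = min_duration)
}

.positive_slope_episodes <- function(t, x, from, floor, slope_tol,
                                     min_duration) {
  n <- length(x)
  if (from >= n - 1) return(list(detected = FALSE, times = numeric(0)))
  sl <- diff(x) / diff(t)
  ok <- logical(n - 1)
  rng <- seq(from, n - 1)
  ok[rng] <- sl[rng] > slope_tol & x[rng] > floor
  # episodes of consecutive TRUE lasting >= min_duration
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  times <- numeric(0)
  for (k in seq_along(r$values)) {
    if (r$values[k] && (t[ends[k] + 1] - t[starts[k]]) >= min_duration)
      times <- c(times, t[starts[k]])
  }
  list(detected = length(times) > 0, times = times)
}

#' Detect contractility escapes
#'
#' Flags every beat whose developed tension (peak minus pre-stimulus
#' diastolic) falls below `threshold` times the drug-free steady-state
#' developed tension.
#'
#' @param trace multi-beat `beat_trace`.
#' @param ref_developed reference developed tension (kPa); defaults to the
#'   largest developed tension across the beats of `trace`.
#' @param threshold fraction of the reference below which a beat counts as
#'   an escape (default 0.10).
#' @return integer vector of escape beat indices (possibly empty).
#' @export
detect_escapes <- function(trace, ref_developed = NULL, threshold = 0.10) {
  nb <- length(attr(trace, "stim_times"))
  dev <- vapply(seq_len(nb), function(b) {
    w <- .beat_window(trace, b)
    max(trace$ta[w$idx]) - trace$ta[w$pre_idx]
  }, numeric(1))
  if (is.null(ref_developed)) ref_developed <- max(dev)
  which(dev < threshold * ref_developed)
}

#' Electro-mechanical window
#'
#' EMw = APD90 - CaTD90, where CaTD90 is the calcium transient duration at
#' 90% decay (time-to-peak + rt90, both from stimulus onset conventions
#' documented in this file). Drug-induced EMw shortening marks torsadogenic
#' risk.
#'
#' @param report a `biomarker_report` from [biomarkers()].
#' @return EMw in ms, or `NA` if APD90 or the calcium decay is unresolved.
#' @export
emw <- function(report) {
  if (is.na(report$ap$apd90) || is.na(report$cat$duration90)) return(NA_real_)
  report$ap$apd90 - report$cat$duration90
}

#' Full biomarker report for one beat
#'
#' Combines AP, calcium and tension biomarkers, the electro-mechanical
#' window and the abnormality detectors into one report.
#'
#' @inheritParams ap_biomarkers
#' @param escape_ref reference developed tension for escape detection
#'   (passed to [detect_escapes()]).
#' @return object of class `biomarker_report`.
#' @export
biomarkers <- function(trace, beat = 1, escape_ref = NULL) {
  ap <- ap_biomarkers(trace, beat)
  cat <- cat_biomarkers(trace, beat)
  ta <- ta_biomarkers(trace, beat)
  ead <- detect_eads(trace, beat)
  ac <- detect_aftercontractions(trace, beat)
  esc <- detect_escapes(trace, ref_developed = escape_ref)
  rep <- list(ap = ap, cat = cat, ta = ta,
              flags = list(ead = ead$detected, ead_times = ead$times,
                           aftercontraction = ac$detected,
                           aftercontraction_times = ac$times,
                           escape_beats = esc),
              beat = beat)
  rep$emw <- emw(rep)
  class(rep) <- "biomarker_report"
  rep
}

#' @export
print.biomarker_report <- function(x, ...) {
  cat("<biomarker_report>\n")
  cat(sprintf("  AP : tp %.1f ms, APD50 %.1f ms, APD90 %.1f ms, peak %.1f mV, rest %.1f mV\n",
              x$ap$tp, x$ap$apd50, x$ap$apd90, x$ap$peak, x$ap$resting))
  cat(sprintf("  CaT: tp %.1f ms, rt50 %.1f ms, rt90 %.1f ms, peak %.3g mM, dia %.3g mM\n",
              x$cat$tp, x$cat$rt50, x$cat$rt90, x$cat$peak, x$cat$diastolic))
  cat(sprintf("  Ta : tp %.1f ms, rt50 %.1f ms, rt95 %.1f ms, peak %.2f kPa, dia %.2f kPa\n",
              x$ta$tp, x$ta$rt50, x$ta$rt95, x$ta$peak, x$ta$diastolic))
  cat(sprintf("  EMw: %.1f ms\n", x$emw))
  fl <- x$flags
  cat(sprintf("  flags: EAD=%s, aftercontraction=%s, escapes=%s\n",
              fl$ead, fl$aftercontraction,
              if (length(fl$escape_beats)) paste(fl$escape_beats, collapse = ",")
              else "none"))
  invisible(x)
}
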