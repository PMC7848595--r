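# Closed-form synthetic waveforms with exact ground-truth biomarkers, used
# to validate the biomarker extractors and abnormality detectors.

#' Synthetic waveform specification
#'
#' Deterministic closed-form traces: `triangle_ap` (instant rise, linear
#' fall, in mV) or `raised_cosine_transient` (raised-cosine rise and decay,
#' for calcium- or tension-like signals). An optional anomaly injects an
#' `ead_hump` (smooth bump during the falling phase), an
#' `aftercontraction_bump`, or a `dropped_beat`.
#'
#' @param kind `"triangle_ap"` or `"raised_cosine_transient"`.
#' @param amplitude peak minus baseline.
#' @param baseline resting value.
#' @param onset ms from each stimulus to waveform onset (upstroke).
#' @param rise rise time, ms (0 for the triangle's instant rise).
#' @param fall fall time, ms (baseline reached `onset + rise + fall` after
#'   the stimulus).
#' @param anomaly optional list `(type, time, amplitude, width)`; `time` is
#'   measured from the beat start (the stimulus of a `triangle_ap` falls
#'   `onset` ms after the beat start); for `dropped_beat`, `beat` gives the
#'   index to suppress.
#' @param cl cycle length, ms.
#' @param n_beats number of beats.
#' @param dt sampling interval, ms.
#' @export
waveform_spec <- function(kind = c("triangle_ap", "raised_cosine_transient"),
                          amplitude = 120, baseline = -85, onset = 5,
                          rise = 0, fall = 300, anomaly = NULL, cl = 1000,
                          n_beats = 1, dt = 0.5) {
  kind <- match.arg(kind)
  stopifnot(dt > 0, cl > 0, n_beats >= 1, fall > 0, amplitude > 0)
  if (!is.null(anomaly)) {
    stopifnot(anomaly$type %in% c("ead_hump", "aftercontraction_bump",
                                  "dropped_beat"))
    if (anomaly$type != "dropped_beat") {
      lo <- onset + rise
      hi <- onset + rise + fall
      if (anomaly$time < lo || anomaly$time + anomaly$width > hi)
        stop("anomaly must lie inside the falling (repolarisation/relaxation) phase")
    }
  }
  structure(list(kind = kind, amplitude = amplitude, baseline = baseline,
                 onset = onset, rise = rise, fall = fall, anomaly = anomaly,
                 cl = cl, n_beats = as.integer(n_beats), dt = dt),
            class = "waveform_spec")
}

#' Generate a synthetic beat trace from a specification
#'
#' @param spec a [waveform_spec()].
#' @return `beat_trace` whose `v`, `cai` and `ta` columns all carry the
#'   synthetic waveform (in its native units), with attribute
#'   `ground_truth`: exact biomarkers computed from the closed form
#'   (`tp`, `apd50`, `apd90` for the triangle; `tp`, `rt50`, `rt90`, `rt95`
#'   for the raised cosine).
#' @export
generate_waveform <- function(spec) {
  stopifnot(inherits(spec, "waveform_spec"))
  tmax <- spec$cl * spec$n_beats
  t <- seq(0, tmax - spec$dt, by = spec$dt)
  x <- rep(spec$baseline, length(t))
  an <- spec$anomaly
  for (b in seq_len(spec$n_beats)) {
    if (!is.null(an) && an$type == "dropped_beat" && b == an$beat) next
    t0 <- (b - 1) * spec$cl
    tl <- t - t0
    up <- tl >= spec$onset & tl < spec$onset + spec$rise
    if (spec$rise > 0) {
      if (spec$kind == "triangle_ap")
        x[up] <- spec$baseline + spec$amplitude * (tl[up] - spec$onset) / spec$rise
      else
        x[up] <- spec$baseline + spec$amplitude *
          0.5 * (1 - cos(pi * (tl[up] - spec$onset) / spec$rise))
    }
    dn <- tl >= spec$onset + spec$rise & tl < spec$onset + spec$rise + spec$fall
    ph <- (tl[dn] - spec$onset - spec$rise) / spec$fall
    if (spec$kind == "triangle_ap")
      x[dn] <- spec$baseline + spec$amplitude * (1 - ph)
    else
      x[dn] <- spec$baseline + spec$amplitude * 0.5 * (1 + cos(pi * ph))
    if (!is.null(an) && an$type != "dropped_beat") {
      ab <- tl >= an$time & tl < an$time + an$width
      x[ab] <- x[ab] + an$amplitude *
        0.5 * (1 - cos(2 * pi * (tl[ab] - an$time) / an$width))
    }
  }
  gt <- .waveform_ground_truth(spec)
  df <- data.frame(t = t, v = x, cai = x, ta = x)
  structure(df, class = c("beat_trace", "data.frame"),
            stim_times = (seq_len(spec$n_beats) - 1) * spec$cl +
              if (spec$kind == "triangle_ap") spec$onset else 0,
            cl = spec$cl, dt_out = spec$dt, ground_truth = gt,
            meta = list(variant = "synthetic", celltype = NA,
                        coupled = TRUE, cl = spec$cl))
}

.waveform_ground_truth <- function(spec) {
  if (spec$kind == "triangle_ap") {
    # stimulus taken at the (instant) upstroke; linear fall from peak
    list(tp = spec$rise,
         apd50 = spec$rise + 0.5 * spec$fall,
         apd90 = spec$rise + 0.9 * spec$fall,
         peak = spec$baseline + spec$amplitude, resting = spec$baseline)
  } else {
    # raised cosine decay: x(t) = base + A/2 (1 + cos(pi s)), s in [0,1]
    rt <- function(f) spec$fall * acos(1 - 2 * f) / pi
    list(tp = spec$onset + spec$rise,
         rt50 = rt(0.5), rt90 = rt(0.9), rt95 = rt(0.95),
         peak = spec$baseline + spec$amplitude, diastolic = spec$baseline)
  }
}
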