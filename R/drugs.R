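# Pore-block drug model, in-silico drug trials, dose-response construction
# with Hill fitting, and derived endpoints.

#' Pore-block fraction
#'
#' Fraction of a channel blocked at free drug concentration `conc`:
#' `conc^hill / (conc^hill + ic50^hill)`. The conductance scale applied to
#' the model is `1 - block_fraction()`.
#'
#' @param conc free drug concentration, uM (>= 0).
#' @param ic50 half-inhibitory concentration, uM (> 0).
#' @param hill Hill coefficient (> 0).
#' @return blocked fraction in `[0, 1]` (0 at `conc = 0`, 0.5 at
#'   `conc = ic50` for any `hill`).
#' @export
block_fraction <- function(conc, ic50, hill) {
  stopifnot(all(conc >= 0), all(ic50 > 0), all(hill > 0))
  ch <- conc^hill
  ch / (ch + ic50^hill)
}

#' Drug potency profile
#'
#' @param name compound name.
#' @param channels data frame with columns `current` (e.g. `"IKr"`), `ic50`
#'   (uM) and `hill`.
#' @param eftpc optional maximal effective free therapeutic concentration
#'   (uM), stored as metadata.
#' @return object of class `drug_profile`.
#' @export
drug_profile <- function(name, channels, eftpc = NA_real_) {
  channels <- as.data.frame(channels)
  stopifnot(all(c("current", "ic50", "hill") %in% names(channels)))
  bad <- setdiff(channels$current, .currents)
  if (length(bad)) stop("unknown current id(s): ", paste(bad, collapse = ", "))
  stopifnot(all(channels$ic50 > 0), all(channels$hill > 0))
  structure(list(name = name, channels = channels, eftpc = eftpc),
            class = "drug_profile")
}

#' @export
print.drug_profile <- function(x, ...) {
  cat(sprintf("<drug_profile> %s\n", x$name))
  for (i in seq_len(nrow(x$channels)))
    cat(sprintf("  %-6s IC50 %.4g uM, Hill %.3g\n", x$channels$current[i],
                x$channels$ic50[i], x$channels$hill[i]))
  if (!is.na(x$eftpc)) cat(sprintf("  EFTPC %.4g uM\n", x$eftpc))
  invisible(x)
}

#' Read a compound potency table
#'
#' CSV format: `compound,current,ic50_uM,hill[,eftpc_uM]`. The table shipped
#' with the package (`extdata/compounds_synthetic.csv`) is a synthetic
#' reconstruction of a multichannel screening dataset: see its header
#' comments for which entries are anchored to published values.
#'
#' @param path CSV path; default: the shipped table.
#' @return named list of [drug_profile()] objects.
#' @export
read_drug_table <- function(path = system.file("extdata",
                                               "compounds_synthetic.csv",
                                               package = "emcell")) {
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("compound", "current", "ic50_uM", "hill") %in% names(d)))
  out <- lapply(split(d, d$compound), function(dd) {
    eftpc <- if ("eftpc_uM" %in% names(dd)) dd$eftpc_uM[1] else NA_real_
    drug_profile(dd$compound[1],
                 data.frame(current = dd$current, ic50 = dd$ic50_uM,
                            hill = dd$hill),
                 eftpc = eftpc)
  })
  out
}

#' Apply a drug to an electrophysiology parameter set
#'
#' Multiplies the channel scale of every current listed in the profile by
#' `1 - block_fraction(conc, ic50, hill)`. Applying a drug to a parameter
#' set that already carries one is refused (pore blocks do not compose).
#'
#' @param ep `ep_params`.
#' @param drug `drug_profile`.
#' @param conc concentration, uM.
#' @return modified `ep_params` with the drug recorded in `$drug`.
#' @export
apply_drug <- function(ep, drug, conc) {
  stopifnot(inherits(ep, "ep_params"), inherits(drug, "drug_profile"),
            conc >= 0)
  if (!is.null(ep$drug))
    stop("a drug (", ep$drug$name, ") is already applied to this parameter set")
  ch <- drug$channels
  for (i in seq_len(nrow(ch))) {
    cur <- ch$current[i]
    ep$channel_scale[[cur]] <- ep$channel_scale[[cur]] *
      (1 - block_fraction(conc, ch$ic50[i], ch$hill[i]))
  }
  ep$drug <- list(name = drug$name, conc = conc)
  ep
}

#' Run one in-silico drug trial
#'
#' Implements the trial protocol: drug-free steady state at the pacing rate
#' (from a cached snapshot where available), then the drug is applied and
#' the simulation continues for `n_drug_beats` without re-converging. The
#' final `record_last` beats are inspected for repolarisation abnormalities,
#' aftercontractions and contractility escapes; biomarker deltas are
#' control-subtracted at identical cycle length.
#'
#' @inheritParams make_params
#' @param drug `drug_profile` (an empty channel list acts as placebo).
#' @param conc concentration, uM.
#' @param cl cycle length, ms.
#' @param n_drug_beats beats simulated after drug application (default 200).
#' @param record_last final beats stored and inspected (default 10).
#' @param coupled electro-mechanically coupled (TRUE) or EP-only (FALSE).
#' @param mech mechanics parameters (default: calibrated set for `variant`).
#' @param start drug-free steady-state `coupled_state`; default
#'   [steady_state_snapshot()].
#' @param solver [solver_options()].
#' @return object of class `drug_trial`: `trace` (final drug beats),
#'   `report` and `control_report` (`biomarker_report`s), `delta` (named
#'   differences: `apd50`, `apd90`, `cat_peak`, `ta_peak`, `emw`),
#'   `outcome` (`"normal"`, `"ead"`, `"repolarisation_failure"`), plus
#'   metadata.
#' @export
drug_trial <- function(variant = "torord", celltype = "endo", drug, conc,
                       cl = 1000, n_drug_beats = 200, record_last = 10,
                       coupled = TRUE, mech = NULL, start = NULL,
                       solver = solver_options()) {
  variant <- .check_variant(variant)
  celltype <- .check_celltype(celltype)
  if (coupled && is.null(mech)) mech <- make_mech_params(variant)
  if (!coupled) mech <- NULL
  if (is.null(start))
    start <- steady_state_snapshot(variant, celltype, cl = cl,
                                   coupled = coupled)
  ep0 <- make_params(variant, celltype)

  # control: continue drug-free from the steady state
  ctrl <- pace(start, ep0, mech,
               pacing_protocol(cl = cl, n_beats = record_last,
                               record_last = record_last),
               solver = solver)
  ctrl_last <- length(attr(ctrl, "stim_times"))
  ctrl_rep <- biomarkers(ctrl, ctrl_last)
  ctrl_dev <- ctrl_rep$ta$amplitude

  epd <- if (nrow(drug$channels)) apply_drug(ep0, drug, conc) else ep0
  tr <- pace(start, epd, mech,
             pacing_protocol(cl = cl, n_beats = n_drug_beats,
                             record_last = record_last),
             solver = solver)
  nb <- length(attr(tr, "stim_times"))
  rep <- biomarkers(tr, nb, escape_ref = ctrl_dev)

  # inspect all recorded final beats for abnormalities
  ead_any <- any(vapply(seq_len(nb), function(b)
    detect_eads(tr, b)$detected, logical(1)))
  ac_any <- any(vapply(seq_len(nb), function(b)
    detect_aftercontractions(tr, b)$detected, logical(1)))
  escapes <- detect_escapes(tr, ref_developed = ctrl_dev)

  outcome <- if (rep$ap$upstroke && rep$ap$repol_failure)
    "repolarisation_failure" else if (ead_any) "ead" else "normal"

  delta <- c(apd50 = rep$ap$apd50 - ctrl_rep$ap$apd50,
             apd90 = rep$ap$apd90 - ctrl_rep$ap$apd90,
             cat_peak = rep$cat$peak - ctrl_rep$cat$peak,
             ta_peak = rep$ta$peak - ctrl_rep$ta$peak,
             emw = rep$emw - ctrl_rep$emw)

  structure(list(trace = tr, report = rep, control_report = ctrl_rep,
                 delta = delta, outcome = outcome,
                 flags = list(ead = ead_any, aftercontraction = ac_any,
                              escape_beats = escapes),
                 drug = drug$name, conc = conc, cl = cl,
                 variant = variant, celltype = celltype, coupled = coupled),
            class = "drug_trial")
}

#' @export
print.drug_trial <- function(x, ...) {
  cat(sprintf("<drug_trial> %s %.4g uM on %s/%s%s, CL %g ms\n", x$drug,
              x$conc, toupper(x$variant), x$celltype,
              if (x$coupled) "+Land" else " (EP-only)", x$cl))
  cat(sprintf("  outcome: %s\n", x$outcome))
  d <- x$delta
  cat(sprintf("  dAPD90 %+.1f ms, dCaT peak %+.3g mM, dTa peak %+.2f kPa, dEMw %+.1f ms\n",
              d[["apd90"]], d[["cat_peak"]], d[["ta_peak"]], d[["emw"]]))
  cat(sprintf("  EAD=%s, aftercontraction=%s, escapes=%d\n",
              x$flags$ead, x$flags$aftercontraction,
              length(x$flags$escape_beats)))
  invisible(x)
}

#' Tension dose-response curve with Hill fit
#'
#' Runs [drug_trial()] at each concentration, computes the percentage
#' reduction of peak developed tension relative to control, and fits a Hill
#' curve with the maximal effect fixed at 100% (a pore block of the driving
#' calcium current suppresses tension completely in the limit), i.e. the
#' two-parameter model `reduction = 100 c^h / (c^h + IC50^h)` by least
#' squares on log-concentration.
#'
#' @inheritParams drug_trial
#' @param concs ascending concentrations, uM (>= 4 spanning the transition).
#' @param ... passed to [drug_trial()].
#' @return object of class `dose_response`: `data` (per-concentration
#'   reductions), `ic50`, `hill`, `fit` (diagnostics incl. residuals and a
#'   monotonicity flag).
#' @export
dose_response_tension <- function(variant = "torord", drug, concs,
                                  cl = 1000, celltype = "endo", ...) {
  stopifnot(length(concs) >= 4, !is.unsorted(concs))
  trials <- lapply(concs, function(cc)
    drug_trial(variant, celltype, drug, cc, cl = cl, ...))
  ctrl_dev <- trials[[1]]$control_report$ta$amplitude
  dev <- vapply(trials, function(x) x$report$ta$amplitude, numeric(1))
  dapd90 <- vapply(trials, function(x) x$delta[["apd90"]], numeric(1))
  outcome <- vapply(trials, function(x) x$outcome, character(1))
  red <- pmin(100, pmax(0, 100 * (1 - dev / ctrl_dev)))
  fit <- fit_hill(concs, red)
  structure(list(
    data = data.frame(conc = concs, reduction = red, developed = dev,
                      dapd90 = dapd90, outcome = outcome),
    control_developed = ctrl_dev,
    ic50 = fit$ic50, hill = fit$hill, fit = fit,
    drug = drug$name, variant = variant, cl = cl), class = "dose_response")
}

#' Fit a fixed-maximum Hill curve to percent-reduction data
#'
#' Least-squares fit of `y = 100 c^h / (c^h + ic50^h)` over
#' (log10 IC50, log h).
#'
#' @param conc concentrations (uM); `y` percent reductions in `[0, 100]`.
#' @param y observed reductions.
#' @return list with `ic50`, `hill`, `residuals`, `rss`, `converged`,
#'   `monotone` (whether the data rise monotonically with concentration).
#' @export
fit_hill <- function(conc, y) {
  stopifnot(length(conc) == length(y), all(conc > 0))
  obj <- function(par) {
    ic50 <- 10^par[1]; h <- exp(par[2])
    sum((y - 100 * block_fraction(conc, ic50, h))^2)
  }
  # coarse initialisation: concentration nearest 50% reduction
  i0 <- which.min(abs(y - 50))
  start <- c(log10(conc[i0]), 0)
  op <- stats::optim(start, obj, method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-12))
  ic50 <- 10^op$par[1]; h <- exp(op$par[2])
  res <- y - 100 * block_fraction(conc, ic50, h)
  list(ic50 = ic50, hill = h, residuals = res, rss = op$value,
       converged = op$convergence == 0, monotone = !is.unsorted(y))
}

#' @export
print.dose_response <- function(x, ...) {
  cat(sprintf("<dose_response> %s on %s+Land, CL %g ms\n", x$drug,
              toupper(x$variant), x$cl))
  print(x$data, row.names = FALSE)
  cat(sprintf("  Hill fit: IC50 = %.4g uM, h = %.3g (rss %.3g%s)\n",
              x$ic50, x$hill, x$fit$rss,
              if (!x$fit$monotone) ", non-monotone data" else ""))
  invisible(x)
}

#' @export
coef.dose_response <- function(object, ...) {
  c(ic50 = object$ic50, hill = object$hill)
}

#' Lowest concentration triggering early afterdepolarisations
#'
#' Scans an ascending concentration grid with [drug_trial()] and returns the
#' lowest concentration whose final beats flag EADs (`NA` if none does).
#'
#' @inheritParams drug_trial
#' @param conc_grid ascending concentrations, uM.
#' @param ... passed to [drug_trial()].
#' @return concentration (uM) or `NA_real_`.
#' @export
ead_onset_concentration <- function(variant = "torord", drug, conc_grid,
                                    cl = 1000, celltype = "endo", ...) {
  stopifnot(!is.unsorted(conc_grid))
  for (cc in conc_grid) {
    tr <- drug_trial(variant, celltype, drug, cc, cl = cl, ...)
    if (tr$flags$ead || tr$outcome == "repolarisation_failure") return(cc)
  }
  NA_real_
}
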