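# Model parameterisation: variants, cell types, conductance tables, the
# Land contraction parameter set, and the packed parameter vector shared
# with the compiled right-hand sides.

# order must match the current list used for channel_scale and drug block
.currents <- c("INa", "INaL", "Ito", "ICaL", "IKr", "IKs", "IK1", "INaCa",
               "INaK", "IKb", "INab", "ICab", "IpCa", "IClCa", "IClb")

# endocardial (base) maximal conductances / permeabilities.
# ToR-ORd: as published (Tomek et al. 2019).
# ORd: O'Hara et al. 2011 scaled by the Dutta et al. 2017 recalibration
# (IKr x1.119, IKs x1.648, IK1 x1.414, ICaL x1.018, INaL x2.274).
.cond_base <- list(
  torord = c(INa = 11.7802, INaL = 0.0279, Ito = 0.16, ICaL = 8.3757e-5,
             IKr = 0.0321, IKs = 0.0011, IK1 = 0.6992, INaCa = 0.0034,
             INaK = 15.4509, IKb = 0.0189, INab = 1.9239e-9, ICab = 5.9194e-8,
             IpCa = 5e-4, IClCa = 0.2843, IClb = 1.98e-3),
  ord    = c(INa = 75, INaL = 0.0075 * 2.274, Ito = 0.02, ICaL = 1e-4 * 1.018,
             IKr = 0.046 * 1.119, IKs = 0.0034 * 1.648, IK1 = 0.1908 * 1.414,
             INaCa = 0.0008, INaK = 30, IKb = 0.003, INab = 3.75e-10,
             ICab = 2.5e-8, IpCa = 5e-4, IClCa = 0, IClb = 0)
)

# published transmural scalings relative to endo (multiplicative only)
.cond_celltype <- list(
  torord = list(
    endo = c(),
    epi  = c(INaL = 0.6, Ito = 2.0, ICaL = 1.2, IKr = 1.3, IKs = 1.4,
             IK1 = 1.2, INaCa = 1.1, INaK = 0.9, IKb = 0.6),
    mid  = c(Ito = 2.0, ICaL = 2.0, IKr = 0.8, IK1 = 1.3, INaCa = 1.4,
             INaK = 0.7)
  ),
  ord = list(
    endo = c(),
    epi  = c(INaL = 0.6, Ito = 4.0, ICaL = 1.2, IKr = 1.3, IKs = 1.4,
             IK1 = 1.2, INaCa = 1.1, INaK = 0.9, IKb = 0.6),
    mid  = c(Ito = 4.0, ICaL = 2.5, IKr = 0.8, IK1 = 1.3, INaCa = 1.4,
             INaK = 0.7)
  )
)

.extracellular <- list(
  torord = c(nao = 140, cao = 1.8, ko = 5, clo = 150, cli = 24),
  ord    = c(nao = 140, cao = 1.8, ko = 5.4, clo = 150, cli = 24)
)

.variant_code <- c(torord = 1, ord = 2)
.celltype_code <- c(endo = 0, epi = 1, mid = 2)

.check_variant <- function(variant) {
  variant <- match.arg(tolower(variant), c("torord", "ord"))
  variant
}
.check_celltype <- function(celltype) {
  match.arg(tolower(celltype), c("endo", "epi", "mid"))
}

#' Electrophysiology model parameters
#'
#' Build the parameter set for one variant and transmural cell type. The
#' endocardial set is the published base; epicardial and mid-myocardial sets
#' apply the source models' published multiplicative scalings only.
#' `channel_scale` holds the per-current multiplicative factors in `[0, 1]`
#' used for pore-block drug action (1 = no block).
#'
#' @param variant `"torord"` (ToR-ORd) or `"ord"` (ORd, Dutta-modified
#'   conductances).
#' @param celltype `"endo"`, `"epi"` or `"mid"`.
#' @param channel_scale optional named numeric vector of per-current scale
#'   factors in `[0, 1]`; names must be current identifiers such as `"IKr"`.
#' @return an object of class `ep_params`: variant, celltype, resolved
#'   conductances (base x celltype scaling), channel scales and
#'   extracellular concentrations (mM).
#' @examples
#' p <- make_params("torord", "endo")
#' p$conductances[["IKr"]]
#' @export
make_params <- function(variant = "torord", celltype = "endo",
                        channel_scale = NULL) {
  variant <- .check_variant(variant)
  celltype <- .check_celltype(celltype)
  g <- .cond_base[[variant]]
  sc <- .cond_celltype[[variant]][[celltype]]
  if (length(sc)) g[names(sc)] <- g[names(sc)] * sc
  cs <- stats::setNames(rep(1, length(.currents)), .currents)
  if (!is.null(channel_scale)) {
    bad <- setdiff(names(channel_scale), .currents)
    if (length(bad))
      stop("unknown current id(s): ", paste(bad, collapse = ", "))
    if (any(channel_scale < 0 | channel_scale > 1))
      stop("channel_scale entries must lie in [0, 1]")
    cs[names(channel_scale)] <- channel_scale
  }
  structure(list(
    variant = variant,
    celltype = celltype,
    conductances = g,
    channel_scale = cs,
    extracellular = .extracellular[[variant]],
    jrel_scale = if (variant == "torord") 1.5378 else 1.0,
    jup_scale = 1.0,
    up_scale = if (celltype == "epi") 1.3 else 1.0,
    cmdnmax = if (celltype == "epi") 0.05 * 1.3 else 0.05,
    trpnmax = 0.07,
    drug = NULL
  ), class = "ep_params")
}

# celltype release scaling (mid x1.7) is folded into the release flux scale
.jrel_celltype <- function(celltype) if (celltype == "mid") 1.7 else 1.0

#' Land contraction model parameters
#'
#' Parameter set for the Land 2017 human active-tension model. Rates are per
#' millisecond, calcium in micromolar, tension in kPa (1 kPa = 1 mN/mm^2).
#' `n_tm` (Hill coefficient of cooperative tropomyosin activation) and
#' `k_tm` (tropomyosin rate constant, the unblocking rate) are the two
#' parameters recalibrated so that the coupled models driven by the
#' physiological calcium transients of ToR-ORd/ORd reproduce human twitch
#' tension data; `calibrated = TRUE` (default) loads the values obtained by
#' running [calibrate_land()] for the requested variant (stored with the
#' package, provenance in `inst/extdata/calibration/`). With
#' `calibrated = FALSE` the published Land defaults are returned.
#'
#' @param variant electrophysiology variant the calibration belongs to.
#' @param calibrated use the package's calibrated `n_tm`, `k_tm`.
#' @param ... named overrides for any parameter (e.g. `ca50 = 1.2`).
#' @return object of class `mech_params`.
#' @export
make_mech_params <- function(variant = "torord", calibrated = TRUE, ...) {
  variant <- .check_variant(variant)
  p <- list(
    ca50 = 0.805,      # uM, half-activation calcium at lambda = 1
    n_trpn = 2,        # troponin Hill coefficient
    k_trpn = 0.1,      # 1/ms, troponin unbinding rate
    n_tm = 5,          # tropomyosin cooperativity exponent (calibration target)
    k_tm = 0.021,      # 1/ms, tropomyosin unblocking rate (calibration target)
    t_ref = 120,       # kPa, reference tension
    k_uw = 0.182,      # 1/ms
    k_ws = 0.012,      # 1/ms
    perm50 = 0.35,
    dr = 0.25,
    wfrac = 0.5,
    tot_a = 25,
    gamma_s = 0.0085,
    gamma_wu = 0.615,
    phi = 2.23,
    beta_0 = 2.3,      # length dependence of reference tension
    beta_1 = -2.4,     # length dependence of ca50 (uM per unit lambda)
    lambda_ = 1,       # extension ratio (isometric at rest length)
    dlambda_dt = 0
  )
  if (calibrated) {
    cal <- .calibrated_land[[variant]]
    p[names(cal)] <- cal
  }
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad)) stop("unknown mech parameter(s): ", paste(bad, collapse = ", "))
  p[names(dots)] <- dots
  if (p$lambda_ < 0.8 || p$lambda_ > 1.2)
    stop("lambda_ outside the validated range [0.8, 1.2]")
  stopifnot(p$n_trpn >= 1, p$n_tm >= 1, p$k_trpn > 0, p$k_tm > 0, p$t_ref > 0)
  structure(p, class = "mech_params")
}

# n_tm / k_tm recovered by running calibrate_land() on each coupled model
# (see the calibration vignette section; reports shipped under
# inst/extdata/calibration/). Updated only by re-running the calibration.
.calibrated_land <- list(
  torord = c(n_tm = 2.25848647, k_tm = 0.0386195754),
  ord    = c(n_tm = 2.25848647, k_tm = 0.0386195754)
)

# pack everything into the flat vector the C code reads (see src/emcell.h)
.pack_parms <- function(ep, mech = NULL, istim = 0, coupled = !is.null(mech)) {
  stopifnot(inherits(ep, "ep_params"))
  if (coupled && is.null(mech)) mech <- make_mech_params(ep$variant)
  if (is.null(mech)) mech <- make_mech_params(ep$variant) # values unused when uncoupled
  stopifnot(inherits(mech, "mech_params"))
  g <- ep$conductances * ep$channel_scale[names(ep$conductances)]
  ex <- ep$extracellular
  c(.variant_code[[ep$variant]], .celltype_code[[ep$celltype]],
    as.numeric(coupled), istim, mech$lambda_, mech$dlambda_dt,
    unname(g[.currents]),
    ep$jrel_scale * .jrel_celltype(ep$celltype), ep$jup_scale, ep$up_scale,
    ep$cmdnmax, ep$trpnmax,
    unname(ex[c("nao", "cao", "ko", "clo", "cli")]),
    mech$ca50, mech$n_trpn, mech$k_trpn, mech$n_tm, mech$k_tm, mech$t_ref,
    mech$k_uw, mech$k_ws, mech$perm50, mech$dr, mech$wfrac, mech$tot_a,
    mech$gamma_s, mech$gamma_wu, mech$phi, mech$beta_0, mech$beta_1)
}

.out_names <- c("INa", "INaL", "Ito", "ICaL", "ICaNa", "ICaK", "IKr", "IKs",
                "IK1", "INaCa_i", "INaCa_ss", "INaK", "IKb", "INab", "ICab",
                "IpCa", "IClCa", "IClb", "Istim", "Jrel", "Jup", "Jdiff",
                "Ta", "Jtrpn")

#' @export
print.ep_params <- function(x, ...) {
  cat(sprintf("<ep_params> %s / %s\n", toupper(x$variant), x$celltype))
  blocked <- x$channel_scale[x$channel_scale < 1]
  if (length(blocked)) {
    cat("  channel scales (drug block):\n")
    for (nm in names(blocked))
      cat(sprintf("    %-6s x %.4f\n", nm, blocked[[nm]]))
  } else cat("  no channel block applied\n")
  invisible(x)
}

#' @export
print.mech_params <- function(x, ...) {
  cat("<mech_params> Land 2017 active contraction\n")
  cat(sprintf("  ca50 = %.4g uM, n_trpn = %.3g, k_trpn = %.3g /ms\n",
              x$ca50, x$n_trpn, x$k_trpn))
  cat(sprintf("  n_tm = %.4g, k_tm = %.4g /ms, t_ref = %.4g kPa\n",
              x$n_tm, x$k_tm, x$t_ref))
  cat(sprintf("  lambda = %.3g (dlambda/dt = %.3g /ms)\n",
              x$lambda_, x$dlambda_dt))
  invisible(x)
}
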