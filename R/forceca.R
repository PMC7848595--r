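# Steady-state calcium-force relationship of the contraction model.

#' Steady-state force-calcium curve
#'
#' Steady active tension of the Land model at constant free calcium, for a
#' grid of calcium values, with a fitted EC50 and Hill slope of the
#' resulting sigmoid. Two methods are available: `"algebraic"` solves the
#' steady-state equations in closed form (at constant calcium and fixed
#' length the distortion variables vanish and the crossbridge fractions
#' follow from linear balance); `"ode"` integrates the six-state model to
#' equilibrium. The two agree to solver accuracy and serve as mutual
#' checks.
#'
#' @param mech `mech_params`.
#' @param cai_grid positive ascending free calcium grid, mM.
#' @param method `"algebraic"` or `"ode"`.
#' @param t_end integration horizon for `method = "ode"`, ms.
#' @return object of class `force_ca_curve`: data frame (`cai`, `tension`),
#'   fitted `ec50` (mM) and `hill`, and per-point convergence flags.
#' @export
steady_state_force_ca <- function(mech, cai_grid,
                                  method = c("algebraic", "ode"),
                                  t_end = 20000) {
  method <- match.arg(method)
  stopifnot(inherits(mech, "mech_params"), all(cai_grid > 0),
            !is.unsorted(cai_grid))
  ok <- rep(TRUE, length(cai_grid))
  if (method == "algebraic") {
    ta <- vapply(cai_grid, function(ca) .land_steady_tension(mech, ca),
                 numeric(1))
  } else {
    ta <- numeric(length(cai_grid))
    m0 <- c(xs = 0, xw = 0, catrpn = 0.01, blocked = 0.99,
            zeta_s = 0, zeta_w = 0)
    for (i in seq_along(cai_grid)) {
      f <- function(t, y, parms) list(land_rhs(t, y, cai_grid[i], mech)$dm)
      sol <- deSolve::lsoda(m0, c(0, t_end), f, rtol = 1e-10, atol = 1e-12)
      y <- sol[nrow(sol), 1 + seq_along(m0)]
      d <- land_rhs(0, y, cai_grid[i], mech)$dm
      ok[i] <- max(abs(d)) < 1e-9
      names(y) <- names(m0)
      ta[i] <- active_tension(y, mech)
      m0 <- y  # warm start the next grid point
    }
  }
  fit <- .fit_sigmoid(cai_grid, ta)
  structure(list(curve = data.frame(cai = cai_grid, tension = ta),
                 ec50 = fit$ec50, hill = fit$hill, converged = ok,
                 method = method),
            class = "force_ca_curve")
}

# closed-form steady state at constant calcium, lambda fixed, dlambda = 0
.land_steady_tension <- function(mech, cai) {
  lam <- min(mech$lambda_, 1.2)
  ca50l <- mech$ca50 + mech$beta_1 * (lam - 1)
  x <- (1000 * cai / ca50l)^mech$n_trpn
  catrpn <- x / (1 + x)
  k_ws <- mech$k_ws; k_uw <- mech$k_uw
  k_wu <- k_uw * (1 / mech$wfrac - 1) - k_ws
  k_su <- k_ws * (1 / mech$dr - 1) * mech$wfrac
  # zeta = 0 at steady state => no distortion-mediated detachment
  rw <- k_uw / (k_wu + k_ws)         # XW / XU
  rs <- k_ws * rw / k_su             # XS / XU
  XSSS <- mech$dr * 0.5
  XWSS <- (1 - mech$dr) * mech$wfrac * 0.5
  ktm_block <- mech$k_tm * mech$perm50^mech$n_tm * 0.5 / (0.5 - XSSS - XWSS)
  b <- (ktm_block / mech$k_tm) * min(100, catrpn^(-mech$n_tm / 2)) /
    catrpn^(mech$n_tm / 2)           # TmBlocked / XU
  XU <- 1 / (1 + rw + rs + b)
  XS <- rs * XU
  h <- max(0, 1 + mech$beta_0 * (lam + min(lam, 0.87) - 1.87))
  h * (mech$t_ref / mech$dr) * XS
}

.fit_sigmoid <- function(cai, ta) {
  tmax <- max(ta)
  if (tmax <= 0) return(list(ec50 = NA_real_, hill = NA_real_))
  y <- 100 * ta / tmax
  f <- fit_hill(cai, y)
  list(ec50 = f$ic50, hill = f$hill)
}

#' @export
print.force_ca_curve <- function(x, ...) {
  cat(sprintf("<force_ca_curve> (%s) %d points\n", x$method,
              nrow(x$curve)))
  cat(sprintf("  EC50 = %.4g mM, Hill slope = %.3g, max tension = %.2f kPa\n",
              x$ec50, x$hill, max(x$curve$tension)))
  if (!all(x$converged)) cat("  warning: unconverged grid points present\n")
  invisible(x)
}
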