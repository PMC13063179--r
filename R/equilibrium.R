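# Forward model: competitive binding equilibrium and Cq mapping.
#
# One well contains target T (concentration t_tot), detection probe P
# (p_tot) and zero or more competitor compounds I_j (i_tot, kd_compound).
# At equilibrium, mass action gives bound_tp = free_t * free_p / kd_probe
# and bound_ti_j = free_t * free_i_j / kd_j.  Substituting the probe and
# compound mass balances leaves a single monotone equation in free_t,
#
#   free_t * (1 + p_tot/(kd_probe + free_t)
#               + sum_j i_j/(kd_j + free_t)) = t_tot,
#
# which has a unique root in [0, t_tot].

#' Define a competitive binding system
#'
#' Describes one well: total target, probe and compound concentrations and
#' the two dissociation constants.  `i_tot`/`kd_compound` may be vectors to
#' describe several simultaneous competitors (e.g. a compound pool plus a
#' saturating reference ligand in a counter-screen).  Inactive compounds are
#' encoded with `kd_compound = Inf`.
#'
#' @param t_tot Total target concentration, nM.
#' @param p_tot Total probe concentration, nM.
#' @param i_tot Total compound concentration(s), nM.
#' @param kd_probe Probe-target dissociation constant, nM (> 0).
#' @param kd_compound Compound-target dissociation constant(s), nM
#'   (> 0; `Inf` = inactive).
#' @return An object of class `binding_system`.
#' @examples
#' sys <- binding_system(t_tot = 0.01, p_tot = 0.2, i_tot = 9000,
#'                       kd_probe = 1.32, kd_compound = 5000)
#' solve_competitive_equilibrium(sys)
#' @export
binding_system <- function(t_tot, p_tot, i_tot = 0, kd_probe,
                           kd_compound = Inf) {
  assert_scalar_number(t_tot, "t_tot", lower = 0)
  assert_scalar_number(p_tot, "p_tot", lower = 0)
  assert_scalar_number(kd_probe, "kd_probe", lower = 0, strict = TRUE)
  if (!is.numeric(i_tot) || length(i_tot) < 1L || anyNA(i_tot) ||
      any(!is.finite(i_tot)) || any(i_tot < 0))
    stop_diana("i_tot must be finite and >= 0")
  if (!is.numeric(kd_compound) || anyNA(kd_compound) || any(kd_compound <= 0))
    stop_diana("kd_compound must be > 0 (Inf for inactive compounds)")
  if (length(kd_compound) == 1L) kd_compound <- rep(kd_compound, length(i_tot))
  if (length(kd_compound) != length(i_tot))
    stop_diana("i_tot and kd_compound lengths differ")
  structure(list(t_tot = t_tot, p_tot = p_tot, i_tot = i_tot,
                 kd_probe = kd_probe, kd_compound = kd_compound),
            class = "binding_system")
}

#' Solve the competitive binding equilibrium
#'
#' Bracketed scalar root finding for free target on `[0, t_tot]` (the mass
#' balance is strictly increasing in free target, so the root is unique),
#' followed by Newton polishing.
#'
#' @param sys A [binding_system()].
#' @param tol Relative tolerance on the mass balances.
#' @return An object of class `equilibrium_state` with components `free_t`,
#'   `free_p`, `free_i`, `bound_tp`, `bound_ti` (nM; `free_i`/`bound_ti`
#'   have one element per competitor).
#' @export
solve_competitive_equilibrium <- function(sys, tol = 1e-10) {
  if (!inherits(sys, "binding_system")) sys <- do.call(binding_system, sys)
  assert_scalar_number(tol, "tol", lower = 0, strict = TRUE)
  t_tot <- sys$t_tot; p_tot <- sys$p_tot
  i_tot <- sys$i_tot; kdp <- sys$kd_probe; kdc <- sys$kd_compound

  state <- function(t) {
    free_p <- p_tot / (1 + t / kdp)
    free_i <- i_tot / (1 + t / kdc)   # kd = Inf -> free_i = i_tot
    structure(list(free_t = t, free_p = free_p, free_i = free_i,
                   bound_tp = (t / kdp) * free_p,
                   bound_ti = (t / kdc) * free_i,
                   sys = sys, tol = tol),
              class = "equilibrium_state")
  }
  if (t_tot == 0) return(state(0))

  # mass balance residual and its derivative in free_t
  f <- function(t) {
    t * (1 + (p_tot / kdp) / (1 + t / kdp) +
           sum((i_tot / kdc) / (1 + t / kdc))) - t_tot
  }
  fp <- function(t) {
    1 + (p_tot / kdp) / (1 + t / kdp)^2 +
      sum((i_tot / kdc) / (1 + t / kdc)^2)
  }
  root <- uniroot(f, lower = 0, upper = t_tot,
                  tol = max(tol * t_tot, 1e-300))$root
  for (k in 1:3) {                    # Newton polish to machine precision
    step <- f(root) / fp(root)
    root <- min(max(root - step, 0), t_tot)
  }
  st <- state(root)
  resid <- abs(st$free_t + st$bound_tp + sum(st$bound_ti) - t_tot)
  if (resid > 10 * tol * t_tot + 1e-300)
    stop_diana("equilibrium solver did not reach requested tolerance",
               class = "dianascreen_solver_error")
  st
}

#' Equilibrium concentration of bound probe
#'
#' Convenience wrapper returning only the target-probe complex
#' concentration.  Strictly decreasing in `i_tot` (finite `kd_compound`)
#' and strictly increasing in `t_tot`.
#'
#' @inheritParams solve_competitive_equilibrium
#' @return Bound probe concentration, nM.
#' @export
bound_probe <- function(sys, tol = 1e-10) {
  solve_competitive_equilibrium(sys, tol)$bound_tp
}

#' qPCR calibration
#'
#' Maps a bound-probe quantity to a quantification cycle through a
#' reference point and a per-cycle amplification efficiency:
#' `Cq = cq_ref - log(bound / bound_ref) / log(1 + efficiency)`.
#' With `efficiency = 1` (perfect doubling) a twofold decrease in bound
#' probe adds exactly one cycle.
#'
#' @param cq_ref Reference cycle number at `bound_ref`, cycles.
#' @param bound_ref Reference bound-probe quantity, nM (> 0).
#' @param efficiency Per-cycle amplification gain in (0, 1].
#' @return An object of class `qpcr_calibration`.
#' @export
qpcr_calibration <- function(cq_ref, bound_ref, efficiency = 1) {
  assert_scalar_number(cq_ref, "cq_ref")
  assert_scalar_number(bound_ref, "bound_ref", lower = 0, strict = TRUE)
  assert_scalar_number(efficiency, "efficiency", lower = 0, strict = TRUE)
  if (efficiency > 1) stop_diana("efficiency must be in (0, 1]")
  structure(list(cq_ref = cq_ref, bound_ref = bound_ref,
                 efficiency = efficiency), class = "qpcr_calibration")
}

#' Convert bound-probe quantity to Cq
#'
#' Non-positive bound quantities cannot amplify; they are reported as the
#' censored marker `NA` ("no amplification"), never as a non-finite cycle
#' number.
#'
#' @param bound Bound probe, nM (vectorised).
#' @param cal A [qpcr_calibration()].
#' @return Cq values, cycles (`NA` where `bound <= 0`).
#' @export
cq_from_bound <- function(bound, cal) {
  stopifnot(inherits(cal, "qpcr_calibration"))
  out <- rep(NA_real_, length(bound))
  ok <- !is.na(bound) & bound > 0
  out[ok] <- cal$cq_ref - log(bound[ok] / cal$bound_ref) / log1p(cal$efficiency)
  out
}

#' Convert Cq back to bound-probe quantity
#'
#' Inverse of [cq_from_bound()]; used when fitting binding isotherms to
#' measured Cq values.
#'
#' @param cq Cq values, cycles (vectorised).
#' @inheritParams cq_from_bound
#' @return Bound probe, nM.
#' @export
bound_from_cq <- function(cq, cal) {
  stopifnot(inherits(cal, "qpcr_calibration"))
  cal$bound_ref * (1 + cal$efficiency)^(cal$cq_ref - cq)
}

#' Forward delta-Cq of a compound-containing well
#'
#' Cq difference between the well described by `sys` and the same well
#' without compound (`i_tot = 0`).  Independent of the calibration reference
#' point; only the efficiency enters.  Non-negative for any finite
#' `kd_compound` and tends to 0 as `i_tot` tends to 0.
#'
#' @inheritParams solve_competitive_equilibrium
#' @param cal Optional [qpcr_calibration()]; only `efficiency` is used
#'   (default 1, perfect doubling).
#' @return delta-Cq, cycles.
#' @export
delta_cq_forward <- function(sys, cal = NULL, tol = 1e-10) {
  if (!inherits(sys, "binding_system")) sys <- do.call(binding_system, sys)
  eff <- if (is.null(cal)) 1 else cal$efficiency
  sys0 <- binding_system(sys$t_tot, sys$p_tot, 0, sys$kd_probe, Inf)
  b1 <- bound_probe(sys, tol)
  b0 <- bound_probe(sys0, tol)
  if (b0 <= 0 || b1 <= 0) return(NA_real_)  # no probe signal to compare
  (log(b0) - log(b1)) / log1p(eff)
}
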