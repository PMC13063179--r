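# Kd inference: invert measured delta-Cq to compound dissociation constants.
#
# Single-well inversion (valid when target depletion is negligible,
# t_tot << kd_probe):
#
#   Kd = (2^-dCq / (1 - 2^-dCq)) * I_tot / (1 + P_tot / Kd_probe)
#
# equivalently Kd = I_tot / ((2^dCq - 1) * (1 + P_tot/Kd_probe)).

kd_from_dcq <- function(delta_cq, i_tot, p_tot, kd_probe) {
  (2^(-delta_cq) / (1 - 2^(-delta_cq))) * i_tot / (1 + p_tot / kd_probe)
}

#' Single-well compound Kd from delta-Cq
#'
#' Inverts one well's delta-Cq to a dissociation constant.  Small shifts
#' are indistinguishable from noise: `delta_cq <= low_censor` yields the
#' censor flag `"low"` ("no measurable inhibition") together with the Kd
#' lower bound implied by the censor threshold.  Shifts at or beyond the
#' assay window (`delta_cq >= high_censor`) keep their point estimate but
#' carry the `"high"` ("inhibition saturated") flag.  No input produces
#' `NaN` or a division error.
#'
#' @param delta_cq Measured Cq shift relative to noninhibited wells, cycles
#'   (`NA` = censored measurement).
#' @param i_tot Total compound concentration in the well, nM (> 0).
#' @param p_tot Total probe concentration, nM (default 0.2, i.e. 200 pM).
#' @param kd_probe Probe dissociation constant, nM (default 1.32).
#' @param low_censor delta-Cq at or below which no inhibition is reported
#'   (default 0; typically 3x the negative-control SD).
#' @param high_censor delta-Cq at or above which the estimate is flagged
#'   saturated (default `Inf`; typically assay window minus 3x the
#'   inhibited-control SD).
#' @return An object of class `kd_well`: list with `kd` (nM or `NA`),
#'   `censor` (`"none"`, `"low"`, `"high"` or `"missing"`), `kd_bound`
#'   (lower bound, nM, for `"low"` censoring), `delta_cq`, `i_tot`.
#' @examples
#' kd_single_well(1, i_tot = 10000)   # 8684 nM
#' @export
kd_single_well <- function(delta_cq, i_tot, p_tot = 0.2, kd_probe = 1.32,
                           low_censor = 0, high_censor = Inf) {
  assert_scalar_number(i_tot, "i_tot", lower = 0, strict = TRUE)
  assert_scalar_number(p_tot, "p_tot", lower = 0)
  assert_scalar_number(kd_probe, "kd_probe", lower = 0, strict = TRUE)
  assert_scalar_number(low_censor, "low_censor", allow_inf = FALSE)
  assert_scalar_number(high_censor, "high_censor", allow_inf = TRUE)
  out <- list(kd = NA_real_, censor = "none", kd_bound = NA_real_,
              delta_cq = delta_cq, i_tot = i_tot)
  class(out) <- "kd_well"
  if (length(delta_cq) != 1L || (!is.na(delta_cq) && !is.finite(delta_cq)))
    stop_diana("delta_cq must be a single finite number or NA")
  if (is.na(delta_cq)) {
    out$censor <- "missing"
    return(out)
  }
  if (delta_cq <= max(low_censor, 0)) {
    out$censor <- "low"
    out$kd_bound <- if (low_censor > 0)
      kd_from_dcq(low_censor, i_tot, p_tot, kd_probe) else Inf
    return(out)
  }
  out$kd <- kd_from_dcq(delta_cq, i_tot, p_tot, kd_probe)
  if (delta_cq >= high_censor) out$censor <- "high"
  out
}

#' @export
print.kd_well <- function(x, ...) {
  cat("Single-well Kd: ",
      if (is.na(x$kd)) paste0("censored (", x$censor, ")")
      else sprintf("%.4g nM%s", x$kd,
                   if (x$censor == "high") " [saturated]" else ""),
      "  (delta-Cq = ", format(x$delta_cq), ", I_tot = ",
      format(x$i_tot), " nM)\n", sep = "")
  invisible(x)
}

#' Average Kd over a dilution series
#'
#' Applies [kd_single_well()] to each well of a dilution series (delta-Cq is
#' computed against the plate's noninhibited control mean) and averages the
#' non-censored per-well estimates.  The default averaging domain is
#' arithmetic (mean +/- sample SD of the Kd values); a geometric mode is
#' available.
#'
#' @param wells Data frame with columns `i_tot_nM` and `cq` (optionally
#'   `well`); one row per well.
#' @param neg_mean_cq Mean Cq of the same plate's noninhibited
#'   (negative-control) wells, cycles.
#' @param p_tot,kd_probe Probe parameters, nM.
#' @param neg_sd Optional negative-control SD; sets the low-censor threshold
#'   to `3 * neg_sd`.
#' @param high_censor Saturation threshold forwarded to [kd_single_well()].
#' @param method `"arithmetic"` (default) or `"geometric"` averaging.
#' @param t_tot Optional effective target concentration; a warning is
#'   emitted when `t_tot > 0.05 * kd_probe`, outside the validity regime of
#'   the single-well equation (negligible target depletion).
#' @return An object of class `kd_estimate`: `per_well` table (with
#'   `delta_cq`, `kd`, `censor`), `mean_kd`, `sd_kd`, `n_used`,
#'   `n_censored_low`, `n_censored_high`, `n_missing`, and a
#'   `by_concentration` breakdown.
#' @export
kd_average <- function(wells, neg_mean_cq, p_tot = 0.2, kd_probe = 1.32,
                       neg_sd = NULL, high_censor = Inf,
                       method = c("arithmetic", "geometric"), t_tot = NULL) {
  method <- match.arg(method)
  if (!is.data.frame(wells) || nrow(wells) < 1L)
    stop_diana("wells must be a data frame with >= 1 row")
  if (!"i_tot_nM" %in% names(wells) && "i_tot" %in% names(wells))
    wells$i_tot_nM <- wells$i_tot
  if (!all(c("i_tot_nM", "cq") %in% names(wells)))
    stop_diana("wells needs columns i_tot_nM and cq")
  assert_scalar_number(neg_mean_cq, "neg_mean_cq")
  if (!is.null(t_tot) && t_tot > 0.05 * kd_probe)
    warning("t_tot is not small relative to kd_probe (", t_tot, " vs ",
            kd_probe, " nM); the single-well equation assumes negligible ",
            "target depletion", call. = FALSE)
  low_censor <- if (is.null(neg_sd)) 0 else 3 * neg_sd

  per <- wells
  per$delta_cq <- per$cq - neg_mean_cq
  res <- lapply(seq_len(nrow(per)), function(i) {
    kd_single_well(per$delta_cq[i], per$i_tot_nM[i], p_tot, kd_probe,
                   low_censor = low_censor, high_censor = high_censor)
  })
  per$kd <- vapply(res, function(r) r$kd, numeric(1))
  per$censor <- vapply(res, function(r) r$censor, character(1))

  used <- per$censor %in% c("none", "high")
  kds <- per$kd[used]
  est <- list(per_well = per,
              n_used = sum(used),
              n_censored_low = sum(per$censor == "low"),
              n_censored_high = sum(per$censor == "high"),
              n_missing = sum(per$censor == "missing"),
              method = method,
              low_censor = low_censor, high_censor = high_censor,
              all_censored = !any(used))
  if (est$all_censored) {
    est$mean_kd <- NA_real_; est$sd_kd <- NA_real_
  } else if (method == "arithmetic") {
    est$mean_kd <- mean(kds)
    est$sd_kd <- if (length(kds) > 1) sd(kds) else NA_real_
  } else {
    est$mean_kd <- exp(mean(log(kds)))
    est$sd_kd <- if (length(kds) > 1) exp(sd(log(kds))) else NA_real_
  }
  if (any(used)) {
    est$by_concentration <- aggregate(kd ~ i_tot_nM, data = per[used, ],
                                      FUN = mean)
    names(est$by_concentration)[2] <- "mean_kd"
  } else {
    est$by_concentration <- data.frame(i_tot_nM = numeric(0),
                                       mean_kd = numeric(0))
  }
  class(est) <- "kd_estimate"
  est
}

#' @export
print.kd_estimate <- function(x, digits = 3, ...) {
  if (x$all_censored) {
    cat("Kd estimate: all", nrow(x$per_well), "wells censored\n")
  } else {
    cat(sprintf("Kd = %.*g +/- %.*g nM (%s mean, n = %d used", digits,
                x$mean_kd, digits, x$sd_kd, x$method, x$n_used))
    cat(sprintf("; censored low/high/missing = %d/%d/%d)\n",
                x$n_censored_low, x$n_censored_high, x$n_missing))
  }
  invisible(x)
}

# two-species (target + probe, no compound) bound complex, closed form;
# stable formulation of the quadratic root
bound_two_species <- function(t_tot, p_tot, kd) {
  s <- t_tot + p_tot + kd
  2 * t_tot * p_tot / (s + sqrt(s^2 - 4 * t_tot * p_tot))
}

#' Calibrate the probe Kd from a titration
#'
#' Fits the one-site binding isotherm to a probe titration against a fixed
#' amount of target: bound(p_tot) follows the exact two-species closed form
#' (so probe depletion is handled), and measured Cq values are converted to
#' bound quantities through the qPCR calibration.  The single free
#' parameter, the probe Kd, is fitted by least squares on a log scale.
#'
#' @param titration Data frame with columns `probe_tot_nM` (total probe,
#'   nM) and `cq` (cycles); at least 4 points spanning at least 10-fold in
#'   probe concentration.
#' @param t_tot Target concentration, nM.
#' @param cal A [qpcr_calibration()].
#' @param p_tot Working probe concentration to record alongside the fit, nM.
#' @param interval Search interval for Kd, nM.
#' @return An object of class `probe_calibration`: `kd_probe`, `p_tot`,
#'   `fit_residual` (sum of squared residuals, nM^2) and `wide_confidence`
#'   (flag for flat/saturating titrations).
#' @export
probe_kd_fit <- function(titration, t_tot, cal, p_tot = 0.2,
                         interval = c(1e-5, 1e7)) {
  if (!is.data.frame(titration))
    stop_diana("titration must be a data frame")
  if (!"probe_tot_nM" %in% names(titration) &&
      "probe_tot" %in% names(titration))
    titration$probe_tot_nM <- titration$probe_tot
  if (!all(c("probe_tot_nM", "cq") %in% names(titration)))
    stop_diana("titration needs columns probe_tot_nM and cq")
  ok <- is.finite(titration$probe_tot_nM) & is.finite(titration$cq)
  titration <- titration[ok, ]
  if (nrow(titration) < 4L)
    stop_diana("need >= 4 usable titration points")
  span <- max(titration$probe_tot_nM) / min(titration$probe_tot_nM)
  if (!is.finite(span) || span < 10)
    stop_diana("titration must span at least 10-fold in probe concentration")
  assert_scalar_number(t_tot, "t_tot", lower = 0, strict = TRUE)

  bound <- bound_from_cq(titration$cq, cal)
  if (sd(bound) == 0 || diff(range(bound)) / max(bound) < 1e-6)
    stop_diana("degenerate titration: bound signal is flat",
               class = "dianascreen_fit_error")
  ss <- function(log_kd) {
    pred <- bound_two_species(t_tot, titration$probe_tot_nM, 10^log_kd)
    sum((bound - pred)^2)
  }
  opt <- optimise(ss, log10(interval), tol = 1e-7)
  if (min(abs(opt$minimum - log10(interval))) < 1e-3)
    stop_diana("probe Kd fit did not converge (estimate at search bound; ",
               "log10 Kd = ", signif(opt$minimum, 4), ")",
               class = "dianascreen_fit_error")
  kd_hat <- 10^opt$minimum
  # flat objective around the optimum -> poorly determined Kd
  curv <- (ss(opt$minimum + 0.3) + ss(opt$minimum - 0.3) - 2 * opt$objective)
  wide <- curv < 1e-8 * max(opt$objective, sum(bound^2) * 1e-12)
  structure(list(kd_probe = kd_hat, p_tot = p_tot,
                 fit_residual = opt$objective, wide_confidence = wide,
                 n_points = nrow(titration)),
            class = "probe_calibration")
}

#' @export
print.probe_calibration <- function(x, ...) {
  cat(sprintf("Probe Kd = %.4g nM (n = %d points, SS = %.3g%s)\n",
              x$kd_probe, x$n_points, x$fit_residual,
              if (x$wide_confidence) ", wide confidence" else ""))
  invisible(x)
}

#' Detection limit of a single-concentration screen
#'
#' Largest compound Kd still called a hit at a given delta-Cq threshold and
#' screening concentration (closed-form inversion of the single-well
#' equation at `delta_cq = threshold`).
#'
#' @param threshold Hit-calling delta-Cq threshold, cycles (> 0).
#' @param i_tot Screening concentration, nM.
#' @inheritParams kd_single_well
#' @return Kd detection boundary, nM.
#' @examples
#' kd_detection_limit(0.80, 9000)   # ~10,546 nM at the pooled-screen settings
#' @export
kd_detection_limit <- function(threshold, i_tot, p_tot = 0.2,
                               kd_probe = 1.32) {
  assert_scalar_number(threshold, "threshold", lower = 0, strict = TRUE)
  kd_from_dcq(threshold, i_tot, p_tot, kd_probe)
}
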