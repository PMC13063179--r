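# Synthetic DIANA screens: compound libraries with planted binders and
# assay interferers, plate layouts, and noisy Cq readouts from the forward
# equilibrium model.

#' Screen design parameters
#'
#' Collects the layout, chemistry and noise parameters of a synthetic
#' screen.  Defaults follow the published PD-L1 campaign where a value is
#' printed: 384-well plates, pools of 11 compounds at 9 uM each,
#' deconvolution retests at 10 uM, counter-screen with 83 nM reference
#' ligand (Kd 0.26 nM), probe at 200 pM with Kd 1.32 nM.  Where no value is
#' printed, defaults are documented choices: effective target concentration
#' 0.01 nM (well below the probe Kd, so the single-well equation regime
#' holds), Cq noise SD 0.15 cycles (between the reported 0.14 and 0.18),
#' positive-control series of six 3-fold dilutions from 100 nM in
#' duplicate, maximally inhibited controls as 2,500 nM reference ligand
#' (reproducing the ~13-cycle assay window), and a noninhibited reference
#' Cq of 9.89.
#'
#' @param n_compounds Library size.
#' @param pool_size Compounds per test well (1 = individual format).
#' @param plate_format 96 or 384.
#' @param screen_conc Per-compound screening concentration, nM.
#' @param retest_conc Deconvolution retest concentration, nM.
#' @param counter_ligand_conc Reference-ligand concentration in the
#'   counter-screen, nM.
#' @param counter_ligand_kd Reference-ligand Kd, nM.
#' @param inhibited_conc Reference-ligand concentration in maximally
#'   inhibited control wells, nM.
#' @param pos_conc Positive-control dilution series, nM.
#' @param pos_replicates Replicates per positive-control concentration.
#' @param n_neg,n_inhib Negative / maximally inhibited control wells per
#'   plate.
#' @param noise_sd Gaussian Cq noise SD, cycles.
#' @param seed Global seed for all stochastic draws of a run.
#' @param t_tot Effective target concentration, nM.
#' @param p_tot Probe concentration, nM.
#' @param kd_probe Probe Kd, nM.
#' @param efficiency qPCR per-cycle efficiency in (0, 1].
#' @param cq_ref Reference (noninhibited) Cq, cycles.
#' @param max_plates Optional cap on plate count; exceeding it is a sizing
#'   error.
#' @return An object of class `screen_design`.
#' @export
screen_design <- function(n_compounds, pool_size = 11, plate_format = 384,
                          screen_conc = 9000, retest_conc = 10000,
                          counter_ligand_conc = 83, counter_ligand_kd = 0.26,
                          inhibited_conc = 2500,
                          pos_conc = 100 / 3^(0:5),
                          pos_replicates = if (plate_format == 384) 2 else 1,
                          n_neg = if (plate_format == 384) 12 else 6,
                          n_inhib = if (plate_format == 384) 8 else 4,
                          noise_sd = 0.15, seed = 1,
                          t_tot = 0.01, p_tot = 0.2, kd_probe = 1.32,
                          efficiency = 1, cq_ref = 9.89, max_plates = NULL) {
  assert_scalar_number(n_compounds, "n_compounds", lower = 0, strict = TRUE)
  assert_scalar_number(pool_size, "pool_size", lower = 0, strict = TRUE)
  if (!plate_format %in% c(96, 384))
    stop_diana("plate_format must be 96 or 384")
  for (nm in c("screen_conc", "retest_conc", "counter_ligand_conc",
               "counter_ligand_kd", "inhibited_conc", "t_tot", "p_tot",
               "kd_probe"))
    assert_scalar_number(get(nm), nm, lower = 0, strict = TRUE)
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  if (any(pos_conc <= 0)) stop_diana("pos_conc must be > 0")
  d <- list(n_compounds = n_compounds, pool_size = pool_size,
            plate_format = plate_format, screen_conc = screen_conc,
            retest_conc = retest_conc,
            counter_ligand_conc = counter_ligand_conc,
            counter_ligand_kd = counter_ligand_kd,
            inhibited_conc = inhibited_conc, pos_conc = pos_conc,
            pos_replicates = pos_replicates, n_neg = n_neg,
            n_inhib = n_inhib, noise_sd = noise_sd, seed = seed,
            t_tot = t_tot, p_tot = p_tot, kd_probe = kd_probe,
            efficiency = efficiency, cq_ref = cq_ref,
            max_plates = max_plates)
  n_ctrl <- n_neg + n_inhib + length(pos_conc) * pos_replicates
  if (n_ctrl >= plate_format)
    stop_diana("control wells (", n_ctrl, ") do not fit the plate format")
  class(d) <- "screen_design"
  d
}

#' Default qPCR calibration for a design
#'
#' Anchors the calibration so that a compound-free well reads the design's
#' reference Cq: `bound_ref` is the bound probe at equilibrium with no
#' competitor.
#'
#' @param design A [screen_design()].
#' @return A [qpcr_calibration()].
#' @export
default_calibration <- function(design) {
  b0 <- bound_probe(binding_system(design$t_tot, design$p_tot, 0,
                                   design$kd_probe, Inf))
  qpcr_calibration(design$cq_ref, b0, design$efficiency)
}

#' Generate a synthetic compound library
#'
#' Compounds are `inactive` (Kd = Inf), `binder` (finite Kd, drawn
#' log-uniformly from `kd_range` unless `binder_kds` is given) or
#' `interferer` (additive Cq shift acting independently of binding, present
#' in screen and counter-screen alike).  Library order is plating order; by
#' default active compounds are placed at evenly spaced positions
#' (`spread_actives = TRUE`) so that sequential pooling puts at most one
#' active per pool -- the operative assumption of the pooled format and of
#' its strongest-competitor approximation.  Reproducible for a fixed seed.
#'
#' @param n Library size (>= 1).
#' @param frac_binder,frac_interferer Class fractions (sum <= 1; the
#'   remainder is inactive).  Ignored for binders when `binder_kds` is
#'   given.
#' @param binder_kds Optional explicit binder Kd values, nM.
#' @param kd_range Log-uniform sampling range for binder Kd, nM.
#' @param interferer_shift Additive Cq shift(s) for interferers, cycles
#'   (recycled).
#' @param seed Optional seed (`NULL` = use the current RNG state).
#' @param spread_actives Place actives in distinct pools (default) or fully
#'   at random.
#' @return Data frame `compound_id`, `class`, `kd`, `shift` in plating
#'   order.
#' @export
generate_library <- function(n, frac_binder = 0, frac_interferer = 0,
                             binder_kds = NULL, kd_range = c(0.1, 5000),
                             interferer_shift = 1.5, seed = NULL,
                             spread_actives = TRUE) {
  assert_scalar_number(n, "n", lower = 1)
  if (frac_binder < 0 || frac_interferer < 0 ||
      frac_binder + frac_interferer > 1)
    stop_diana("class fractions must be >= 0 and sum to <= 1")
  if (!is.null(seed)) set.seed(seed)
  n_b <- if (!is.null(binder_kds)) length(binder_kds) else
    round(frac_binder * n)
  n_i <- round(frac_interferer * n)
  if (n_b + n_i > n) stop_diana("more active compounds than library slots")
  if (is.null(binder_kds) && n_b > 0)
    binder_kds <- 10^runif(n_b, log10(kd_range[1]), log10(kd_range[2]))
  if (any(binder_kds <= 0)) stop_diana("binder Kd values must be > 0")
  shifts <- rep_len(interferer_shift, max(n_i, 1))[seq_len(n_i)]
  if (n_i > 0 && any(shifts == 0))
    stop_diana("interferer shifts must be non-zero")

  lib <- data.frame(compound_id = sprintf("C%05d", seq_len(n)),
                    class = "inactive", kd = Inf, shift = 0,
                    stringsAsFactors = FALSE)
  n_active <- n_b + n_i
  if (n_active > 0) {
    pos <- if (spread_actives) {
      p <- round(seq(1, n, length.out = n_active + 2))[seq_len(n_active) + 1]
      if (anyDuplicated(p)) p <- sample(n, n_active)  # tiny libraries
      p
    } else sample(n, n_active)
    pos <- pos[sample.int(n_active)]   # which active lands where
    b_pos <- pos[seq_len(n_b)]
    i_pos <- pos[n_b + seq_len(n_i)]
    lib$class[b_pos] <- "binder"; lib$kd[b_pos] <- binder_kds
    lib$class[i_pos] <- "interferer"; lib$shift[i_pos] <- shifts
  }
  lib
}

#' Pool assignment for a library
#'
#' Sequential pools of `pool_size` compounds in plating order; the last
#' pool may be short.  For `pool_size = 1` the pool id equals the compound
#' id.
#'
#' @param library A [generate_library()] table.
#' @param pool_size Compounds per pool.
#' @return Data frame `pool_id`, `compound_id`.
#' @export
pool_map <- function(library, pool_size) {
  n <- nrow(library)
  if (pool_size == 1)
    return(data.frame(pool_id = library$compound_id,
                      compound_id = library$compound_id,
                      stringsAsFactors = FALSE))
  idx <- ceiling(seq_len(n) / pool_size)
  data.frame(pool_id = sprintf("P%04d", idx),
             compound_id = library$compound_id, stringsAsFactors = FALSE)
}

#' Lay out a library on screening plates
#'
#' Pools are filled sequentially into test wells; each plate additionally
#' carries negative controls (no compound), maximally inhibited controls
#' (saturating reference ligand) and a positive-control dilution series of
#' the reference ligand.  `i_tot_nM` is the per-compound concentration for
#' test wells and the ligand concentration for control wells.
#'
#' @param library A [generate_library()] table.
#' @param design A [screen_design()].
#' @return Well-record data frame without Cq (`cq = NA`).
#' @export
layout_plates <- function(library, design) {
  stopifnot(inherits(design, "screen_design"))
  pm <- pool_map(library, design$pool_size)
  pools <- unique(pm$pool_id)
  content <- vapply(split(pm$compound_id, factor(pm$pool_id, levels = pools)),
                    paste, character(1), collapse = ";")
  labels <- well_labels(design$plate_format)
  n_ctrl <- design$n_neg + design$n_inhib +
    length(design$pos_conc) * design$pos_replicates
  cap <- length(labels) - n_ctrl
  n_plates <- ceiling(length(pools) / cap)
  if (!is.null(design$max_plates) && n_plates > design$max_plates)
    stop_diana("library needs ", n_plates, " plates but max_plates = ",
               design$max_plates)

  plates <- lapply(seq_len(n_plates), function(p) {
    sel <- ((p - 1) * cap + 1):min(p * cap, length(pools))
    n_test <- length(sel)
    ctrl_roles <- c(rep("negative_control", design$n_neg),
                    rep("inhibited_control", design$n_inhib),
                    rep("positive_control",
                        length(design$pos_conc) * design$pos_replicates))
    ctrl_conc <- c(rep(0, design$n_neg),
                   rep(design$inhibited_conc, design$n_inhib),
                   rep(design$pos_conc, each = design$pos_replicates))
    n_rows <- n_test + length(ctrl_roles)
    data.frame(
      plate_id = sprintf("S%02d", p),
      well = labels[seq_len(n_rows)],
      role = c(rep("test", n_test), ctrl_roles),
      content = c(unname(content[sel]),
                  ifelse(ctrl_roles == "negative_control", NA_character_,
                         "WL12")),
      pool_id = c(if (design$pool_size == 1) rep(NA_character_, n_test)
                  else pools[sel], rep(NA_character_, length(ctrl_roles))),
      i_tot_nM = c(rep(design$screen_conc, n_test), ctrl_conc),
      cq = NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, plates)
  rownames(out) <- NULL
  validate_wells(out)
  out
}

#' Simulate Cq readouts for laid-out wells
#'
#' Each well's bound probe is computed from the competitive equilibrium:
#' test wells compete with their compounds (by default a pool is
#' approximated by its strongest binder; `exact_pool = TRUE` solves the
#' full multi-competitor equilibrium), control wells with the reference
#' ligand at the well's concentration.  In counter-screen mode the
#' saturating reference ligand is added to every well.  Interferer shifts
#' are added to Cq regardless of binding and of mode, then Gaussian noise
#' of SD `design$noise_sd`.
#'
#' @param wells Output of [layout_plates()] (or any validated well table).
#' @param library The [generate_library()] table resolving compound ids.
#' @param design A [screen_design()].
#' @param cal Optional [qpcr_calibration()]; defaults to
#'   [default_calibration()].
#' @param counter Simulate the counter-screen instead of the primary
#'   screen.
#' @param exact_pool Solve the exact multi-competitor equilibrium for
#'   pools.
#' @param seed Optional seed (`NULL` = use the current RNG state).
#' @return The well table with simulated `cq`.
#' @export
simulate_cq <- function(wells, library, design, cal = NULL, counter = FALSE,
                        exact_pool = FALSE, seed = NULL) {
  stopifnot(inherits(design, "screen_design"))
  validate_wells(wells)
  if (is.null(cal)) cal <- default_calibration(design)
  if (!is.null(seed)) set.seed(seed)
  kd_of <- setNames(library$kd, library$compound_id)
  shift_of <- setNames(library$shift, library$compound_id)

  memo <- new.env(parent = emptyenv())
  base_cq <- function(kds, concs) {
    keep <- is.finite(kds)
    kds <- kds[keep]; concs <- concs[keep]
    key <- paste0("k:", paste(signif(kds, 12), signif(concs, 12),
                              collapse = "|"))
    if (!is.null(memo[[key]])) return(memo[[key]])
    sys <- binding_system(design$t_tot, design$p_tot,
                          i_tot = if (length(concs)) concs else 0,
                          kd_probe = design$kd_probe,
                          kd_compound = if (length(kds)) kds else Inf)
    cq <- cq_from_bound(bound_probe(sys), cal)
    memo[[key]] <- cq
    cq
  }

  n <- nrow(wells)
  cq <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    role <- wells$role[i]
    if (role == "empty") next
    kds <- numeric(0); concs <- numeric(0); shift <- 0
    if (role == "test") {
      ids <- split_content(wells$content[i])
      unknown <- setdiff(ids, names(kd_of))
      if (length(unknown))
        stop_diana("well ", wells$well[i], ": unknown compound id(s) ",
                   paste(unknown, collapse = ", "))
      k <- unname(kd_of[ids])
      shift <- sum(shift_of[ids])
      if (!exact_pool && any(is.finite(k))) {
        k <- min(k)                     # strongest-competitor approximation
        concs <- wells$i_tot_nM[i]; kds <- k
      } else if (exact_pool) {
        kds <- k; concs <- rep(wells$i_tot_nM[i], length(k))
      }
    } else if (role %in% c("inhibited_control", "positive_control")) {
      kds <- design$counter_ligand_kd; concs <- wells$i_tot_nM[i]
    }
    if (counter) {
      kds <- c(kds, design$counter_ligand_kd)
      concs <- c(concs, design$counter_ligand_conc)
    }
    cq[i] <- base_cq(kds, concs) + shift
  }
  live <- !is.na(cq)
  noise <- rnorm(n, 0, design$noise_sd)
  wells$cq <- cq + ifelse(live, noise, 0)
  wells
}

#' Simulate a positive-control dilution series
#'
#' Builds a small plate fragment with negative-control wells and a
#' dilution series of a competitor of known Kd, simulates Cq readouts and
#' returns the pieces needed by [kd_average()].  Used for parameter
#' recovery studies of the single-well Kd estimator.
#'
#' @param kd True competitor Kd, nM.
#' @param design A [screen_design()] (supplies binding parameters, noise
#'   and the dilution series defaults).
#' @param concs Dilution series, nM (default `design$pos_conc`).
#' @param replicates Wells per concentration.
#' @param n_neg Negative-control wells defining the delta-Cq baseline.
#' @param seed Optional seed.
#' @return List with `series` (data frame `i_tot_nM`, `cq`),
#'   `neg_mean_cq`, `neg_sd` (empirical, from the simulated negative
#'   controls).
#' @export
simulate_kd_series <- function(kd, design, concs = design$pos_conc,
                               replicates = 2, n_neg = 24, seed = NULL) {
  assert_scalar_number(kd, "kd", lower = 0, strict = TRUE)
  if (!is.null(seed)) set.seed(seed)
  cal <- default_calibration(design)
  b0 <- cq_from_bound(bound_probe(binding_system(
    design$t_tot, design$p_tot, 0, design$kd_probe, Inf)), cal)
  neg <- b0 + rnorm(n_neg, 0, design$noise_sd)
  conc_vec <- rep(concs, each = replicates)
  cq <- vapply(conc_vec, function(ci) {
    cq_from_bound(bound_probe(binding_system(
      design$t_tot, design$p_tot, ci, design$kd_probe, kd)), cal)
  }, numeric(1)) + rnorm(length(conc_vec), 0, design$noise_sd)
  list(series = data.frame(i_tot_nM = conc_vec, cq = cq),
       neg_mean_cq = mean(neg), neg_sd = sd(neg))
}
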