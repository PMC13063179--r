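# Plate-level screening pipeline: QC, delta-Cq, hit calling, counter-screen
# interference filtering, deconvolution planning, confirmation, summaries.
#
# Wells travel through the pipeline as a plain data frame with columns
# plate_id, well, role, content, pool_id, i_tot_nM, cq.  `content` holds
# ";"-separated compound ids for test wells or the control ligand name for
# control wells; `cq = NA` is the censored "no amplification" marker.

#' Validate a well-record table
#'
#' Checks the column set, role values, well labels (96- or 384-well
#' formats) and the role-specific content invariants: negative controls
#' carry no compound, positive controls carry the reference ligand at a
#' positive concentration, and test wells carry at least one compound id.
#'
#' @param wells Well-record data frame.
#' @param require_cq If `TRUE`, a `cq` column must be present.
#' @return The validated data frame, invisibly.
#' @export
validate_wells <- function(wells, require_cq = FALSE) {
  need <- c("plate_id", "well", "role", "content", "pool_id", "i_tot_nM")
  if (require_cq) need <- c(need, "cq")
  miss <- setdiff(need, names(wells))
  if (length(miss))
    stop_diana("well table is missing column(s): ", paste(miss, collapse = ", "))
  bad_role <- setdiff(unique(wells$role), WELL_ROLES)
  if (length(bad_role))
    stop_diana("unknown well role(s): ", paste(bad_role, collapse = ", "))
  ok384 <- valid_well_label(wells$well, 384)
  if (any(!ok384))
    stop_diana("invalid well label(s): ",
               paste(unique(wells$well[!ok384]), collapse = ", "))
  has_content <- !is.na(wells$content) & nzchar(wells$content)
  if (any(wells$role == "negative_control" & has_content))
    stop_diana("negative_control wells must not carry a compound")
  pos <- wells$role == "positive_control"
  if (any(pos & (!has_content | !(wells$i_tot_nM > 0))))
    stop_diana("positive_control wells need a reference ligand and a ",
               "positive concentration")
  if (any(wells$role == "test" & !has_content))
    stop_diana("test wells must carry >= 1 compound id")
  invisible(wells)
}

#' Per-well delta-Cq relative to the plate's noninhibited controls
#'
#' For each plate, delta-Cq(w) = Cq(w) - mean Cq of that plate's
#' negative-control wells, so negative-control delta-Cq values average to 0
#' by construction.  Censored Cq (`NA`) propagates to censored delta-Cq.
#'
#' @param wells Well-record data frame including `cq`.
#' @return The input table with a `delta_cq` column and, as attributes,
#'   the per-plate negative-control means.
#' @export
delta_cq_table <- function(wells) {
  validate_wells(wells, require_cq = TRUE)
  out <- wells
  out$delta_cq <- NA_real_
  neg_means <- c()
  for (pl in unique(wells$plate_id)) {
    sel <- wells$plate_id == pl
    negcq <- wells$cq[sel & wells$role == "negative_control"]
    negcq <- negcq[is.finite(negcq)]
    if (length(negcq) < 2L)
      stop_diana("plate ", pl, ": need >= 2 negative-control wells with ",
                 "numeric Cq to define delta-Cq")
    out$delta_cq[sel] <- wells$cq[sel] - mean(negcq)
    neg_means[pl] <- mean(negcq)
  }
  attr(out, "neg_mean_cq") <- neg_means
  out
}

#' Z'-factor from control statistics
#'
#' `Z' = 1 - 3 * (sd_pos + sd_neg) / |mean_pos - mean_neg|`.  Equals 1 only
#' when both SDs are 0; > 0.5 is conventionally excellent for HTS.
#'
#' @param neg_mean,neg_sd Noninhibited control mean and SD, cycles.
#' @param pos_mean,pos_sd Maximally inhibited control mean and SD, cycles.
#' @return Z'-factor (unitless).
#' @export
z_prime_factor <- function(neg_mean, neg_sd, pos_mean, pos_sd) {
  if (pos_mean == neg_mean) stop_diana("control means coincide; Z' undefined")
  1 - 3 * (pos_sd + neg_sd) / abs(pos_mean - neg_mean)
}

#' Plate QC metrics
#'
#' Control-well statistics (sample SD, n-1 denominator), the assay window
#' (mean inhibited minus mean noninhibited Cq) and the Z'-factor.  Control
#' wells are pooled across all plates present in the table (interplate QC).
#'
#' @param wells Well-record data frame including `cq`.
#' @return An object of class `qc_report` with fields `neg_mean`, `neg_sd`,
#'   `pos_mean`, `pos_sd`, `assay_window`, `z_prime`, `n_neg`, `n_pos`.
#'   Values are unrounded; the print method rounds to 2 decimals.
#' @export
qc_metrics <- function(wells) {
  validate_wells(wells, require_cq = TRUE)
  neg <- wells$cq[wells$role == "negative_control"]
  pos <- wells$cq[wells$role == "inhibited_control"]
  neg <- neg[is.finite(neg)]; pos <- pos[is.finite(pos)]
  if (length(neg) < 2L || length(pos) < 2L)
    stop_diana("QC needs >= 2 negative and >= 2 inhibited control wells ",
               "with numeric Cq")
  rep <- list(neg_mean = mean(neg), neg_sd = sd(neg),
              pos_mean = mean(pos), pos_sd = sd(pos),
              n_neg = length(neg), n_pos = length(pos))
  rep$assay_window <- rep$pos_mean - rep$neg_mean
  rep$z_prime <- z_prime_factor(rep$neg_mean, rep$neg_sd,
                                rep$pos_mean, rep$pos_sd)
  class(rep) <- "qc_report"
  rep
}

#' @export
print.qc_report <- function(x, digits = 2, ...) {
  cat(sprintf("Noninhibited controls: %.2f +/- %.2f Cq (n = %d)\n",
              x$neg_mean, x$neg_sd, x$n_neg))
  cat(sprintf("Inhibited controls:    %.2f +/- %.2f Cq (n = %d)\n",
              x$pos_mean, x$pos_sd, x$n_pos))
  cat(sprintf("Assay window: %.2f cycles   Z'-factor: %.2f\n",
              x$assay_window, x$z_prime))
  invisible(x)
}

#' @export
as.data.frame.qc_report <- function(x, ...) {
  data.frame(neg_mean = x$neg_mean, neg_sd = x$neg_sd, pos_mean = x$pos_mean,
             pos_sd = x$pos_sd, assay_window = x$assay_window,
             z_prime = x$z_prime, n_neg = x$n_neg, n_pos = x$n_pos)
}

#' delta-Cq threshold from the negative-control SD
#'
#' Returns `k * neg_sd`.  The pooled PD-L1 screen used an absolute cutoff of
#' 0.80 cycles (more than 8x its noninhibited SD); the individual-format
#' screen used 3x.
#'
#' @param neg_sd Negative-control SD, cycles (> 0).
#' @param k Multiplier (> 0).
#' @return Threshold, cycles.
#' @export
threshold_from_sd <- function(neg_sd, k) {
  assert_scalar_number(neg_sd, "neg_sd", lower = 0, strict = TRUE)
  assert_scalar_number(k, "k", lower = 0, strict = TRUE)
  k * neg_sd
}

as_dcq_frame <- function(dcq) {
  if (is.data.frame(dcq)) {
    if (!"delta_cq" %in% names(dcq))
      stop_diana("delta-Cq table needs a delta_cq column")
    return(dcq)
  }
  if (is.numeric(dcq) && (!is.null(names(dcq)) || length(dcq) == 0L)) {
    n <- length(dcq)
    return(data.frame(plate_id = rep(NA_character_, n),
                      well = names(dcq) %||% character(0),
                      role = rep("test", n),
                      content = rep(NA_character_, n),
                      pool_id = rep(NA_character_, n),
                      i_tot_nM = rep(NA_real_, n),
                      delta_cq = unname(dcq), stringsAsFactors = FALSE))
  }
  stop_diana("dcq must be a delta-Cq data frame or a named numeric vector")
}

#' Call initial hits from delta-Cq values
#'
#' Test wells with `delta_cq >= threshold` (inclusive) are labelled
#' `initial_hit`; the rest `inactive`.  Deterministic and independent of
#' well order.  Censored delta-Cq is treated as inactive with a warning.
#'
#' @param dcq Output of [delta_cq_table()] (test wells are selected by
#'   role), or a named numeric vector well -> delta-Cq.
#' @param threshold Hit threshold, cycles (> 0).
#' @return A `hit_calls` data frame: `subject`, `plate_id`, `pool_id`,
#'   `content`, `delta_cq`, `counter_delta_cq`, `status`.
#' @export
call_hits <- function(dcq, threshold) {
  assert_scalar_number(threshold, "threshold", lower = 0, strict = TRUE)
  d <- as_dcq_frame(dcq)
  if ("role" %in% names(d)) d <- d[d$role == "test", , drop = FALSE]
  subject <- if ("well" %in% names(d)) d$well else rownames(d)
  n <- nrow(d)
  col_or_na <- function(nm)
    if (nm %in% names(d)) d[[nm]] else rep(NA_character_, n)
  calls <- data.frame(subject = subject,
                      plate_id = col_or_na("plate_id"),
                      pool_id = col_or_na("pool_id"),
                      content = col_or_na("content"),
                      delta_cq = d$delta_cq,
                      counter_delta_cq = rep(NA_real_, n),
                      status = rep("inactive", n),
                      stringsAsFactors = FALSE)
  if (anyNA(calls$delta_cq))
    warning(sum(is.na(calls$delta_cq)),
            " well(s) with censored delta-Cq treated as inactive",
            call. = FALSE)
  calls$status[!is.na(calls$delta_cq) & calls$delta_cq >= threshold] <-
    "initial_hit"
  class(calls) <- c("hit_calls", class(calls))
  calls
}

#' Counter-screen interference filter
#'
#' In the counter-screen every well additionally contains a saturating
#' concentration of the reference ligand, so genuine competitors cannot
#' displace further probe; compounds that still shift Cq act through a
#' non-binding mechanism (e.g. chelation, PCR inhibition).  Counter
#' delta-Cq values must be computed against the counter plate's own
#' saturated compound-free baseline.  Initial hits with counter delta-Cq at
#' or above `significance` are reclassified `interferer`; other calls are
#' unchanged.  Hits missing from the counter data are retained with a
#' warning and flagged `counter_unresolved`.
#'
#' @param hits A `hit_calls` table from [call_hits()].
#' @param counter_dcq Counter-screen delta-Cq: a [delta_cq_table()] output
#'   or a named numeric vector well -> delta-Cq.
#' @param significance Interference threshold, cycles (> 0); typically a
#'   multiple of the counter-plate baseline SD.
#' @return The `hit_calls` table with `counter_delta_cq`, updated `status`
#'   and a `counter_unresolved` flag column.
#' @export
counter_screen_filter <- function(hits, counter_dcq, significance) {
  assert_scalar_number(significance, "significance", lower = 0, strict = TRUE)
  d <- as_dcq_frame(counter_dcq)
  key <- function(plate, well) paste(ifelse(is.na(plate), "", plate), well)
  lut <- setNames(d$delta_cq, key(d$plate_id, d$well))
  hits$counter_delta_cq <- unname(lut[key(hits$plate_id, hits$subject)])
  hits$counter_unresolved <- FALSE
  is_hit <- hits$status == "initial_hit"
  unresolved <- is_hit & is.na(hits$counter_delta_cq)
  if (any(unresolved)) {
    warning(sum(unresolved), " hit well(s) missing from the counter-screen ",
            "data; retained with counter_unresolved = TRUE (",
            paste(hits$subject[unresolved], collapse = ", "), ")",
            call. = FALSE)
    hits$counter_unresolved[unresolved] <- TRUE
  }
  flag <- is_hit & !is.na(hits$counter_delta_cq) &
    hits$counter_delta_cq >= significance
  hits$status[flag] <- "interferer"
  hits
}

as_pool_map <- function(pool_map) {
  if (is.data.frame(pool_map)) {
    if (!all(c("pool_id", "compound_id") %in% names(pool_map)))
      stop_diana("pool_map needs columns pool_id and compound_id")
    return(split(pool_map$compound_id, pool_map$pool_id))
  }
  if (is.list(pool_map)) return(pool_map)
  stop_diana("pool_map must be a data frame or a named list")
}

#' Deconvolution plan for surviving hit pools
#'
#' Lists each compound of each surviving hit pool exactly once, at the
#' retest concentration (default 10 uM), for individual retesting.
#'
#' @param hits A `hit_calls` table after counter-screen filtering; rows
#'   with status `initial_hit` are deconvoluted.
#' @param pool_map Mapping pool_id -> compound ids: either a data frame
#'   with columns `pool_id`, `compound_id` or a named list.
#' @param retest_conc Retest concentration, nM (default 10,000 = 10 uM).
#' @return Data frame `compound_id`, `pool_id`, `i_tot_nM`.
#' @export
deconvolution_plan <- function(hits, pool_map, retest_conc = 10000) {
  assert_scalar_number(retest_conc, "retest_conc", lower = 0, strict = TRUE)
  pm <- as_pool_map(pool_map)
  pools <- unique(hits$pool_id[hits$status == "initial_hit"])
  pools <- pools[!is.na(pools)]
  if (!length(pools))
    return(data.frame(compound_id = character(0), pool_id = character(0),
                      i_tot_nM = numeric(0), stringsAsFactors = FALSE))
  unknown <- setdiff(pools, names(pm))
  if (length(unknown))
    stop_diana("unknown pool_id in pool_map: ", paste(unknown, collapse = ", "))
  plan <- do.call(rbind, lapply(pools, function(p)
    data.frame(compound_id = pm[[p]], pool_id = p, stringsAsFactors = FALSE)))
  plan <- plan[!duplicated(plan$compound_id), , drop = FALSE]
  plan$i_tot_nM <- retest_conc
  rownames(plan) <- NULL
  plan
}

#' Confirm hits from individual retests
#'
#' Applies the (inclusive) hit threshold to per-compound delta-Cq values
#' from the deconvolution experiment.  A pool may yield zero, one or
#' several confirmed compounds.
#'
#' @param individual_dcq Per-compound delta-Cq: data frame with columns
#'   `compound_id` and `delta_cq`, or a named numeric vector.
#' @param threshold Confirmation threshold, cycles (> 0).
#' @param pool_map Optional pool mapping; if given, a `pool_id` column and
#'   a per-pool status attribute (`confirmed_hit` if any member confirms,
#'   else `not_confirmed`) are added.
#' @return A `hit_calls`-style data frame: `subject` (compound id),
#'   `delta_cq`, `status` (`confirmed_hit` / `not_confirmed`).
#' @export
confirm_hits <- function(individual_dcq, threshold, pool_map = NULL) {
  assert_scalar_number(threshold, "threshold", lower = 0, strict = TRUE)
  if (is.numeric(individual_dcq) && !is.null(names(individual_dcq)))
    individual_dcq <- data.frame(compound_id = names(individual_dcq),
                                 delta_cq = unname(individual_dcq),
                                 stringsAsFactors = FALSE)
  if (!all(c("compound_id", "delta_cq") %in% names(individual_dcq)))
    stop_diana("individual_dcq needs columns compound_id and delta_cq")
  calls <- data.frame(subject = individual_dcq$compound_id,
                      delta_cq = individual_dcq$delta_cq,
                      status = ifelse(!is.na(individual_dcq$delta_cq) &
                                        individual_dcq$delta_cq >= threshold,
                                      "confirmed_hit", "not_confirmed"),
                      stringsAsFactors = FALSE)
  if (!is.null(pool_map)) {
    pm <- as_pool_map(pool_map)
    comp2pool <- setNames(rep(names(pm), lengths(pm)), unlist(pm))
    calls$pool_id <- unname(comp2pool[calls$subject])
    pools <- vapply(split(calls$status, calls$pool_id),
                    function(s) if (any(s == "confirmed_hit"))
                      "confirmed_hit" else "not_confirmed", character(1))
    attr(calls, "pool_status") <- pools
  }
  class(calls) <- c("hit_calls", class(calls))
  calls
}

#' Screen summary statistics
#'
#' Counts per pipeline status and rates as percentages of the library size
#' (2 significant figures): the initial hit rate (pre-deconvolution), the
#' post-counter-screen survivor rate, and the confirmed rate when
#' compound-level calls are supplied.
#'
#' @param well_calls A `hit_calls` table after counter-screen filtering
#'   (survivors keep status `initial_hit`; removed wells are `interferer`).
#' @param library_size Number of compounds screened (> 0).
#' @param compound_calls Optional compound-level calls from [confirm_hits()].
#' @return An object of class `screen_summary`.
#' @export
screen_summary <- function(well_calls, library_size, compound_calls = NULL) {
  assert_scalar_number(library_size, "library_size", lower = 0, strict = TRUE)
  rate <- function(n) signif(100 * n / library_size, 2)
  n_surv <- sum(well_calls$status == "initial_hit")
  n_intf <- sum(well_calls$status == "interferer")
  out <- list(library_size = library_size,
              n_wells = nrow(well_calls),
              n_initial_hits = n_surv + n_intf,
              n_interferers = n_intf,
              n_survivors = n_surv,
              rate_initial = rate(n_surv + n_intf),
              rate_survivors = rate(n_surv))
  if (!is.null(compound_calls)) {
    out$n_confirmed <- sum(compound_calls$status == "confirmed_hit")
    out$rate_confirmed <- rate(out$n_confirmed)
  } else {
    out$n_confirmed <- NA_integer_
    out$rate_confirmed <- NA_real_
  }
  class(out) <- "screen_summary"
  out
}

#' @export
print.screen_summary <- function(x, ...) {
  cat(sprintf("Screened compounds: %d (test wells: %d)\n",
              x$library_size, x$n_wells))
  cat(sprintf("Initial hits: %d (%.2g%%)\n", x$n_initial_hits, x$rate_initial))
  cat(sprintf("Assay interferers removed: %d\n", x$n_interferers))
  cat(sprintf("Post-counter-screen survivors: %d (%.2g%%)\n",
              x$n_survivors, x$rate_survivors))
  if (!is.na(x$n_confirmed))
    cat(sprintf("Confirmed after deconvolution: %d (%.2g%%)\n",
                x$n_confirmed, x$rate_confirmed))
  invisible(x)
}

#' @export
as.data.frame.screen_summary <- function(x, ...) {
  data.frame(library_size = x$library_size, n_wells = x$n_wells,
             n_initial_hits = x$n_initial_hits,
             n_interferers = x$n_interferers, n_survivors = x$n_survivors,
             n_confirmed = x$n_confirmed, rate_initial = x$rate_initial,
             rate_survivors = x$rate_survivors,
             rate_confirmed = x$rate_confirmed)
}
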