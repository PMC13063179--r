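# Pipeline orchestration: configuration, the end-to-end synthetic run, and
# the file-based run over plate-map / Cq tables.

#' Pipeline configuration
#'
#' Every field defaults to the published value where one is printed: probe
#' 200 pM with Kd 1.32 nM, pooled hit threshold delta-Cq >= 0.80, retest at
#' 10 uM, counter-screen at 83 nM reference ligand.  The counter-screen
#' significance defaults to `counter_k` times the counter-plate baseline
#' SD (`counter_k = 4`; see the methods vignette for the multiplicity
#' rationale).  `threshold_k`, when set, derives the hit threshold as
#' `threshold_k * neg_sd` instead of the absolute `threshold`.
#'
#' @param ... Named overrides of the defaults.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(p_tot = 0.2, kd_probe = 1.32, t_tot = 0.01, efficiency = 1,
              cq_ref = 9.89, threshold = 0.80, threshold_k = NULL,
              counter_k = 4, counter_significance = NULL,
              retest_conc = 10000, counter_ligand_conc = 83,
              counter_ligand_kd = 0.26, rounding = 2, seed = 1)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop_diana("unknown configuration field(s): ",
               paste(unknown, collapse = ", "))
  cfg <- modifyList(cfg, dots, keep.null = TRUE)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write a pipeline configuration
#'
#' Configurations are stored as a single human-readable JSON object; fields
#' are validated against the schema of [pipeline_config()].
#'
#' @param path File path.
#' @return [read_config()] returns a `pipeline_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_diana("config file not found: ", path)
  do.call(pipeline_config, jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname read_config
#' @param config A `pipeline_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       pretty = TRUE, null = "null", digits = NA)
  invisible(path)
}

counter_baseline_sd <- function(counter_wells) {
  base <- counter_wells$cq[counter_wells$role == "negative_control"]
  base <- base[is.finite(base)]
  if (length(base) < 2L)
    stop_diana("counter-screen needs >= 2 compound-free baseline wells")
  sd(base)
}

#' Run a complete synthetic screen
#'
#' Executes the full pipeline on simulated data, in screening order:
#' primary screen, QC, delta-Cq, threshold hit calling, counter-screen
#' interference filtering, deconvolution planning, individual retest
#' simulation and confirmation (pooled format only), summary, and a
#' positive-control Kd estimate.  All randomness flows from `design$seed`;
#' identical design + library give identical results.
#'
#' @param design A [screen_design()].
#' @param library A [generate_library()] table.
#' @param config A [pipeline_config()] (thresholds and counter-screen
#'   policy; binding parameters come from `design`).
#' @param exact_pool Use the exact multi-competitor pool model.
#' @return An object of class `diana_screen_run`: the simulated tables, QC
#'   report, hit calls at each stage, deconvolution plan and calls,
#'   summary, positive-control Kd estimate, and a run log.
#' @export
run_synthetic_screen <- function(design, library, config = pipeline_config(),
                                 exact_pool = FALSE) {
  stopifnot(inherits(design, "screen_design"),
            inherits(config, "pipeline_config"))
  set.seed(design$seed)
  log <- character(0)
  say <- function(...) log <<- c(log, paste0(...))
  say("seed = ", design$seed)

  cal <- default_calibration(design)
  wells <- layout_plates(library, design)
  screen <- simulate_cq(wells, library, design, cal, counter = FALSE,
                        exact_pool = exact_pool)
  counter <- simulate_cq(wells, library, design, cal, counter = TRUE,
                         exact_pool = exact_pool)
  qc <- qc_metrics(screen)
  say(sprintf("QC: window = %.2f cycles, Z' = %.2f (n_neg = %d, n_pos = %d)",
              qc$assay_window, qc$z_prime, qc$n_neg, qc$n_pos))

  dcq <- delta_cq_table(screen)
  threshold <- if (!is.null(config$threshold_k))
    threshold_from_sd(qc$neg_sd, config$threshold_k) else config$threshold
  say("hit threshold: delta-Cq >= ", signif(threshold, 4))
  hits0 <- call_hits(dcq, threshold)

  counter_dcq <- delta_cq_table(counter)
  sig <- config$counter_significance %||%
    (config$counter_k * counter_baseline_sd(counter))
  say("counter-screen significance: delta-Cq >= ", signif(sig, 4))
  hits <- counter_screen_filter(hits0, counter_dcq, sig)
  say("initial hits: ", sum(hits0$status == "initial_hit"),
      "; interferers removed: ", sum(hits$status == "interferer"))
  removed <- hits$subject[hits$status == "interferer"]
  if (length(removed)) say("excluded wells: ", paste(removed, collapse = ", "))

  pm <- pool_map(library, design$pool_size)
  compound_calls <- NULL
  deconv_wells <- NULL
  plan <- data.frame(compound_id = character(0), pool_id = character(0),
                     i_tot_nM = numeric(0))
  if (design$pool_size > 1) {
    plan <- deconvolution_plan(hits, pm, config$retest_conc)
    say("deconvolution plan: ", nrow(plan), " compounds at ",
        config$retest_conc, " nM")
    if (nrow(plan) > 0) {
      lib_d <- library[match(plan$compound_id, library$compound_id), ]
      design_d <- design
      design_d$pool_size <- 1
      design_d$screen_conc <- config$retest_conc
      design_d$n_compounds <- nrow(lib_d)
      wells_d <- layout_plates(lib_d, design_d)
      wells_d$plate_id <- sub("^S", "D", wells_d$plate_id)
      deconv_wells <- simulate_cq(wells_d, lib_d, design_d, cal)
      dcq_d <- delta_cq_table(deconv_wells)
      test_d <- dcq_d[dcq_d$role == "test", ]
      compound_calls <- confirm_hits(
        data.frame(compound_id = test_d$content, delta_cq = test_d$delta_cq),
        threshold, pool_map = pm[pm$compound_id %in% plan$compound_id, ])
      say("confirmed compounds: ",
          sum(compound_calls$status == "confirmed_hit"))
    }
  } else say("individual format: pooling/deconvolution stages skipped")

  summary <- screen_summary(hits, nrow(library), compound_calls)

  pos <- screen[screen$role == "positive_control", ]
  kd_pos <- kd_average(data.frame(i_tot_nM = pos$i_tot_nM, cq = pos$cq),
                       neg_mean_cq = qc$neg_mean, p_tot = design$p_tot,
                       kd_probe = design$kd_probe, neg_sd = qc$neg_sd,
                       high_censor = qc$assay_window - 3 * qc$pos_sd,
                       t_tot = design$t_tot)
  say(sprintf("positive-control Kd: %.3g +/- %.3g nM (n = %d)",
              kd_pos$mean_kd, kd_pos$sd_kd, kd_pos$n_used))

  structure(list(design = design, config = config, library = library,
                 calibration = cal, screen_wells = screen,
                 counter_wells = counter, qc = qc, dcq = dcq,
                 threshold = threshold, hits_initial = hits0, hits = hits,
                 counter_significance = sig, pool_map = pm, plan = plan,
                 deconvolution_wells = deconv_wells,
                 compound_calls = compound_calls, summary = summary,
                 kd_positive_control = kd_pos, log = log),
            class = "diana_screen_run")
}

#' @export
print.diana_screen_run <- function(x, ...) {
  cat("DIANA synthetic screen run (seed ", x$design$seed, ")\n", sep = "")
  print(x$qc)
  print(x$summary)
  print(x$kd_positive_control)
  invisible(x)
}

#' Run the pipeline on plate tables in a directory
#'
#' File-based counterpart of [run_synthetic_screen()].  Reads
#' `plate_map.csv` and `cq_results.csv` from `dir`, then runs every stage
#' whose inputs are present: QC and hit calling always;
#' counter-screen filtering if `counter_cq.csv` exists (counter delta-Cq is
#' computed against the counter table's own negative-control baseline);
#' deconvolution planning if the map defines pools; confirmation if
#' `deconvolution_map.csv` and `deconvolution_cq.csv` exist.  Outputs
#' (`qc_report.csv`, `hits.csv`, `deconvolution_plan.csv`, `summary.csv`,
#' `kd_report.csv` when positive controls are present, `run_log.txt`) are
#' written back to `dir` with stable column order.
#'
#' @param config A [pipeline_config()].
#' @param dir Directory holding the input tables.
#' @return The result bundle, invisibly (list of the stage outputs).
#' @export
run_pipeline <- function(config, dir) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- character(0)
  say <- function(...) log <<- c(log, paste0(...))
  pth <- function(f) file.path(dir, f)
  wells <- read_plate_tables(pth("plate_map.csv"), pth("cq_results.csv"))
  say("read ", nrow(wells), " wells from ", dir)

  qc <- qc_metrics(wells)
  dcq <- delta_cq_table(wells)
  threshold <- if (!is.null(config$threshold_k))
    threshold_from_sd(qc$neg_sd, config$threshold_k) else config$threshold
  say("hit threshold: delta-Cq >= ", signif(threshold, 4))
  hits <- call_hits(dcq, threshold)

  if (file.exists(pth("counter_cq.csv"))) {
    counter <- read_plate_tables(pth("plate_map.csv"), pth("counter_cq.csv"))
    sig <- config$counter_significance %||%
      (config$counter_k * counter_baseline_sd(counter))
    say("counter-screen significance: delta-Cq >= ", signif(sig, 4))
    hits <- counter_screen_filter(hits, delta_cq_table(counter), sig)
    say("interferers removed: ", sum(hits$status == "interferer"))
  } else say("no counter_cq.csv: counter-screen stage skipped")

  test <- wells[wells$role == "test", ]
  compounds <- unique(unlist(lapply(test$content, split_content)))
  pooled <- any(!is.na(test$pool_id))
  plan <- data.frame(compound_id = character(0), pool_id = character(0),
                     i_tot_nM = numeric(0))
  if (pooled) {
    pm <- do.call(rbind, lapply(seq_len(nrow(test)), function(i)
      data.frame(pool_id = test$pool_id[i],
                 compound_id = split_content(test$content[i]),
                 stringsAsFactors = FALSE)))
    pm <- pm[!is.na(pm$pool_id) & !duplicated(pm), ]
    plan <- deconvolution_plan(hits, pm, config$retest_conc)
    say("deconvolution plan: ", nrow(plan), " compounds")
  }

  compound_calls <- NULL
  if (file.exists(pth("deconvolution_map.csv")) &&
      file.exists(pth("deconvolution_cq.csv"))) {
    dwells <- read_plate_tables(pth("deconvolution_map.csv"),
                                pth("deconvolution_cq.csv"))
    ddcq <- delta_cq_table(dwells)
    dtest <- ddcq[ddcq$role == "test", ]
    compound_calls <- confirm_hits(
      data.frame(compound_id = dtest$content, delta_cq = dtest$delta_cq),
      threshold)
    say("confirmed compounds: ",
        sum(compound_calls$status == "confirmed_hit"))
  }

  summary <- screen_summary(hits, length(compounds), compound_calls)

  kd_pos <- NULL
  pos <- wells[wells$role == "positive_control", ]
  if (nrow(pos) >= 1) {
    kd_pos <- kd_average(data.frame(i_tot_nM = pos$i_tot_nM, cq = pos$cq),
                         neg_mean_cq = qc$neg_mean, p_tot = config$p_tot,
                         kd_probe = config$kd_probe, neg_sd = qc$neg_sd,
                         high_censor = qc$assay_window - 3 * qc$pos_sd,
                         t_tot = config$t_tot)
    say(sprintf("positive-control Kd: %.3g +/- %.3g nM", kd_pos$mean_kd,
                kd_pos$sd_kd))
  }

  res <- list(qc = qc, dcq = dcq, threshold = threshold, hits = hits,
              plan = plan, compound_calls = compound_calls,
              summary = summary, kd_positive_control = kd_pos, log = log)
  write_report_tables(res, dir, rounding = config$rounding)
  invisible(res)
}
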