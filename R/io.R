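# Delimited-text I/O.  Canonical interchange is comma-separated UTF-8 with
# a header row:
#   plate_map.csv:  plate_id, well, role, content, pool_id, i_tot_nM
#   cq_results.csv: plate_id, well, cq        (empty cq = no amplification)

read_csv_checked <- function(path, required) {
  if (!file.exists(path)) stop_diana("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = "character", check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop_diana(basename(path), ": missing column(s) ",
               paste(miss, collapse = ", "),
               " (documented schema: ", paste(required, collapse = ", "), ")")
  df
}

parse_num_col <- function(df, col, path, lower = NULL, allow_na = FALSE) {
  raw <- df[[col]]
  out <- suppressWarnings(as.numeric(raw))
  blank <- is.na(raw) | !nzchar(trimws(raw))
  bad <- !blank & is.na(out)
  if (any(bad))
    stop_diana(basename(path), " line ", which(bad)[1] + 1L,
               ": column ", col, " is not numeric ('", raw[bad][1], "')")
  if (!allow_na && any(blank))
    stop_diana(basename(path), " line ", which(blank)[1] + 1L,
               ": column ", col, " is empty")
  if (!is.null(lower) && any(!is.na(out) & out < lower))
    stop_diana(basename(path), " line ",
               which(!is.na(out) & out < lower)[1] + 1L,
               ": column ", col, " must be >= ", lower)
  out
}

#' Read and join plate-map and Cq tables
#'
#' Reads the documented plate-map and Cq-result schemas and joins them on
#' `(plate_id, well)`.  Duplicate keys, orphan Cq rows (no map entry),
#' unmeasured non-empty map wells, malformed numbers and invalid roles,
#' well labels or unit columns are rejected with named parse errors
#' carrying line numbers.  An empty `cq` field is the censored "no
#' amplification" marker and becomes `NA`.
#'
#' @param map_path Path to `plate_map.csv` (`plate_id, well, role, content,
#'   pool_id, i_tot_nM`).
#' @param cq_path Path to `cq_results.csv` (`plate_id, well, cq`).
#' @return Joined, validated well-record data frame.
#' @export
read_plate_tables <- function(map_path, cq_path) {
  map <- read_csv_checked(map_path, c("plate_id", "well", "role", "content",
                                      "pool_id", "i_tot_nM"))
  cqt <- read_csv_checked(cq_path, c("plate_id", "well", "cq"))
  map$i_tot_nM <- parse_num_col(map, "i_tot_nM", map_path, lower = 0)
  cqt$cq <- parse_num_col(cqt, "cq", cq_path, allow_na = TRUE)
  map$content[!nzchar(trimws(map$content))] <- NA_character_
  map$pool_id[!nzchar(trimws(map$pool_id))] <- NA_character_

  key_map <- paste(map$plate_id, map$well)
  key_cq <- paste(cqt$plate_id, cqt$well)
  if (anyDuplicated(key_map))
    stop_diana(basename(map_path), " line ",
               which(duplicated(key_map))[1] + 1L,
               ": duplicate (plate_id, well) key '",
               key_map[duplicated(key_map)][1], "'")
  if (anyDuplicated(key_cq))
    stop_diana(basename(cq_path), " line ",
               which(duplicated(key_cq))[1] + 1L,
               ": duplicate (plate_id, well) key '",
               key_cq[duplicated(key_cq)][1], "'")
  orphan <- !key_cq %in% key_map
  if (any(orphan))
    stop_diana(basename(cq_path), " line ", which(orphan)[1] + 1L,
               ": orphan Cq row for well '", key_cq[orphan][1],
               "' with no plate-map entry")
  unmeasured <- !key_map %in% key_cq & map$role != "empty"
  if (any(unmeasured))
    stop_diana(basename(map_path), " line ", which(unmeasured)[1] + 1L,
               ": well '", key_map[unmeasured][1],
               "' has no Cq result")

  map$cq <- cqt$cq[match(key_map, key_cq)]
  validate_wells(map, require_cq = TRUE)
  map
}

write_csv_stable <- function(df, path) {
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write a synthetic screen run as plate tables
#'
#' Writes the interchange files a file-based analysis can consume:
#' `plate_map.csv`, `cq_results.csv`, `counter_cq.csv`,
#' `ground_truth.csv` (compound_id, class, kd, shift), and, when the run
#' includes a deconvolution stage, `deconvolution_map.csv` /
#' `deconvolution_cq.csv`.
#'
#' @param run A `diana_screen_run` from [run_synthetic_screen()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_screen_tables <- function(run, dir) {
  stopifnot(inherits(run, "diana_screen_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  map_cols <- c("plate_id", "well", "role", "content", "pool_id", "i_tot_nM")
  write_csv_stable(run$screen_wells[map_cols], file.path(dir, "plate_map.csv"))
  write_csv_stable(run$screen_wells[c("plate_id", "well", "cq")],
                   file.path(dir, "cq_results.csv"))
  write_csv_stable(run$counter_wells[c("plate_id", "well", "cq")],
                   file.path(dir, "counter_cq.csv"))
  write_csv_stable(run$library, file.path(dir, "ground_truth.csv"))
  if (!is.null(run$deconvolution_wells)) {
    write_csv_stable(run$deconvolution_wells[map_cols],
                     file.path(dir, "deconvolution_map.csv"))
    write_csv_stable(run$deconvolution_wells[c("plate_id", "well", "cq")],
                     file.path(dir, "deconvolution_cq.csv"))
  }
  invisible(dir)
}

#' Write analysis reports
#'
#' Writes `qc_report.csv`, `hits.csv`, `deconvolution_plan.csv`,
#' `summary.csv`, `kd_report.csv` (when a positive-control Kd estimate is
#' present), `confirmed.csv` (when compound calls are present) and
#' `run_log.txt`.  Cq-derived statistics are rounded at report time only
#' (default 2 decimals).
#'
#' @param res Stage-output list with elements `qc`, `hits`, `plan`,
#'   `summary` and optionally `compound_calls`, `kd_positive_control`,
#'   `log` (a `diana_screen_run` works too).
#' @param dir Output directory (created if missing).
#' @param rounding Decimal places for reported Cq statistics.
#' @return `dir`, invisibly.
#' @export
write_report_tables <- function(res, dir, rounding = 2) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  qc <- as.data.frame(res$qc)
  num <- vapply(qc, is.numeric, logical(1))
  qc[num] <- lapply(qc[num], round, rounding)
  write_csv_stable(qc, file.path(dir, "qc_report.csv"))

  hits <- as.data.frame(res$hits)
  hits$delta_cq <- round(hits$delta_cq, rounding)
  if ("counter_delta_cq" %in% names(hits))
    hits$counter_delta_cq <- round(hits$counter_delta_cq, rounding)
  write_csv_stable(hits, file.path(dir, "hits.csv"))

  write_csv_stable(res$plan, file.path(dir, "deconvolution_plan.csv"))
  write_csv_stable(as.data.frame(res$summary), file.path(dir, "summary.csv"))
  if (!is.null(res$compound_calls)) {
    cc <- as.data.frame(res$compound_calls)
    cc$delta_cq <- round(cc$delta_cq, rounding)
    write_csv_stable(cc, file.path(dir, "confirmed.csv"))
  }
  kd <- res$kd_positive_control
  if (!is.null(kd)) {
    write_csv_stable(data.frame(mean_kd_nM = kd$mean_kd, sd_kd_nM = kd$sd_kd,
                                n_used = kd$n_used,
                                n_censored_low = kd$n_censored_low,
                                n_censored_high = kd$n_censored_high),
                     file.path(dir, "kd_report.csv"))
    per <- kd$per_well
    per$delta_cq <- round(per$delta_cq, rounding)
    write_csv_stable(per, file.path(dir, "kd_per_well.csv"))
  }
  if (!is.null(res$log))
    writeLines(res$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}
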