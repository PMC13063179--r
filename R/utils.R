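# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_diana <- function(..., class = "dianascreen_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

assert_scalar_number <- function(x, name, lower = -Inf, allow_inf = FALSE,
                                 strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_diana(name, " must be a single non-missing number")
  if (!allow_inf && !is.finite(x))
    stop_diana(name, " must be finite")
  if (strict && x <= lower)
    stop_diana(name, " must be > ", lower)
  if (!strict && x < lower)
    stop_diana(name, " must be >= ", lower)
  invisible(x)
}

#' Well labels for a plate format
#'
#' Row-major well labels ("A1", "A2", ...) for a 384-well (rows A-P,
#' columns 1-24) or 96-well (rows A-H, columns 1-12) plate.
#'
#' @param plate_format 96 or 384.
#' @return Character vector of well labels in row-major order.
#' @export
well_labels <- function(plate_format = 384) {
  if (plate_format == 384) {
    rows <- LETTERS[1:16]; cols <- 1:24
  } else if (plate_format == 96) {
    rows <- LETTERS[1:8]; cols <- 1:12
  } else stop_diana("plate_format must be 96 or 384")
  as.vector(t(outer(rows, cols, paste0)))
}

valid_well_label <- function(well, plate_format = 384) {
  well %in% well_labels(plate_format)
}

# roles a well can take in a screen
WELL_ROLES <- c("negative_control", "inhibited_control", "positive_control",
                "test", "empty")

# hit-call pipeline statuses, in pipeline order
HIT_STATUSES <- c("inactive", "initial_hit", "interferer", "confirmed_hit",
                  "not_confirmed")

split_content <- function(content) {
  if (is.na(content) || !nzchar(content)) return(character(0))
  strsplit(content, ";", fixed = TRUE)[[1]]
}

round2 <- function(x, digits = 2) round(x, digits)
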