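#' @importFrom rlang .data
NULL

# Canonical column order of the long plate table (internal names).
PLATE_COLS <- c("well_id", "animal_id", "group", "side", "fragment_index",
                "fragment_length_mm", "is_negative_control", "qc_status",
                "measurement_index", "phase", "time_min", "ocr", "ecar")

# Column header of the long CSV dialect (fixed order).
PLATE_CSV_COLS <- c("well_id", "animal_id", "group", "side", "fragment_index",
                    "fragment_length_mm", "is_negative_control",
                    "measurement_index", "phase", "time_min",
                    "ocr_pmol_min", "ecar_mpH_min")

#' Construct a plate-run table
#'
#' A plate run is a long tibble with one row per (well, reading), carrying the
#' well metadata, the reading index/phase/time, and the OCR (pmol O2/min) and
#' ECAR (mpH/min) values, together with the [injection_schedule()] and a
#' provenance log stored as attributes. All pipeline stages take a plate run
#' first and return one, so they chain with the pipe.
#'
#' @param data A data frame with columns `well_id`, `animal_id`, `group`,
#'   `side`, `fragment_index`, `fragment_length_mm`, `is_negative_control`,
#'   `measurement_index`, `phase`, `time_min`, `ocr`, `ecar` (`qc_status` is
#'   added as "pending" when absent). Missing readings are `NA`, never dropped
#'   rows: every well must have exactly `n_readings(schedule)` rows.
#' @param schedule The [injection_schedule()] shared by all wells.
#' @param provenance Character vector of free-text log lines.
#'
#' @return A tibble of class `nerveflux_plate`.
#' @export
plate_run <- function(data, schedule, provenance = character()) {
  stopifnot(inherits(schedule, "injection_schedule"))
  data <- tibble::as_tibble(data)
  if (!"qc_status" %in% names(data)) data$qc_status <- "pending"
  missing_cols <- setdiff(PLATE_COLS, names(data))
  if (length(missing_cols) > 0) {
    stop("plate data is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data <- dplyr::arrange(data[PLATE_COLS], .data$well_id, .data$measurement_index)
  validate_plate_data(data, schedule)
  structure(data,
            class = c("nerveflux_plate", class(tibble::tibble())),
            schedule = schedule,
            provenance = provenance)
}

validate_plate_data <- function(data, schedule) {
  total <- n_readings(schedule)
  if (nrow(data) == 0) return(invisible(data)) # empty run: header-only I/O
  if (anyDuplicated(data[c("well_id", "measurement_index")]) > 0) {
    dup <- data[duplicated(data[c("well_id", "measurement_index")]), ]
    stop("duplicate (well_id, measurement_index) rows, e.g. well ",
         dup$well_id[1], " index ", dup$measurement_index[1], call. = FALSE)
  }
  counts <- table(data$well_id)
  bad <- names(counts)[counts != total]
  if (length(bad) > 0) {
    stop(sprintf(
      "schedule mismatch: expected %d readings per well but got other counts for well(s): %s",
      total, paste(bad, collapse = ", ")), call. = FALSE)
  }
  idx <- sort(unique(data$measurement_index))
  if (!identical(as.integer(idx), seq_len(total))) {
    stop("measurement_index must cover 1..", total, " for every well.",
         call. = FALSE)
  }
  # Per-well metadata must be constant across readings.
  meta_cols <- c("animal_id", "group", "side", "fragment_index",
                 "fragment_length_mm", "is_negative_control", "qc_status")
  n_meta <- dplyr::n_distinct(data[c("well_id", meta_cols)])
  if (n_meta != length(counts)) {
    stop("well metadata must be constant within each well.", call. = FALSE)
  }
  invisible(data)
}

#' Schedule and provenance accessors
#'
#' @param plate A [plate_run()].
#' @return `plate_schedule()` returns the [injection_schedule()];
#'   `plate_provenance()` the character log.
#' @export
plate_schedule <- function(plate) {
  sched <- attr(plate, "schedule")
  if (is.null(sched)) stop("not a plate run: no schedule attached.", call. = FALSE)
  sched
}

#' @rdname plate_schedule
#' @export
plate_provenance <- function(plate) attr(plate, "provenance") %||% character()

# Rebuild a plate from transformed data, keeping schedule and extending the log.
restore_plate <- function(data, plate, note = NULL) {
  prov <- plate_provenance(plate)
  if (!is.null(note)) prov <- c(prov, note)
  plate_run(data, plate_schedule(plate), provenance = prov)
}

#' Per-well metadata of a plate run
#'
#' @param plate A [plate_run()].
#' @return A tibble with one row per well (metadata columns only).
#' @export
well_meta <- function(plate) {
  dplyr::distinct(
    tibble::as_tibble(plate)[c("well_id", "animal_id", "group", "side",
                               "fragment_index", "fragment_length_mm",
                               "is_negative_control", "qc_status")])
}

# Wells that downstream stages consume: QC pass, exempt (negative controls),
# or still pending (QC not yet applied).
included_status <- c("pending", "pass", "exempt")

#' @export
print.nerveflux_plate <- function(x, ...) {
  sched <- plate_schedule(x)
  meta <- well_meta(x)
  cat(sprintf(
    "<plate run> %d wells x %d readings (%s); %d animals, %d group(s), %d negative control(s)\n",
    nrow(meta), n_readings(sched), format(sched),
    dplyr::n_distinct(meta$animal_id), dplyr::n_distinct(meta$group),
    sum(meta$is_negative_control)))
  qc <- table(meta$qc_status)
  cat("  qc:", paste(sprintf("%s=%d", names(qc), qc), collapse = " "), "\n")
  NextMethod()
}

#' Read a plate run from the long CSV dialect
#'
#' The file must carry exactly the documented header
#' `well_id,animal_id,group,side,fragment_index,fragment_length_mm,is_negative_control,measurement_index,phase,time_min,ocr_pmol_min,ecar_mpH_min`
#' with booleans as `true`/`false` and missing readings as empty fields.
#' Rows are reordered by measurement index per well; duplicate
#' (well, index) rows and per-well reading counts that disagree with the
#' schedule are rejected. An explicit `time_min` column is validated against
#' the nominal `(index - 1) * interval_min` grid within 0.5 min; larger
#' deviations raise a warning, not an error.
#'
#' @param path Path to a CSV file.
#' @param schedule The [injection_schedule()] the file is expected to follow.
#' @return A [plate_run()].
#' @export
read_plate_long <- function(path, schedule = injection_schedule()) {
  stopifnot(inherits(schedule, "injection_schedule"))
  header <- names(utils::read.csv(path, nrows = 1, check.names = FALSE))
  missing_cols <- setdiff(PLATE_CSV_COLS, header)
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  raw <- suppressWarnings(readr::read_csv(
    path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      well_id = readr::col_character(),
      animal_id = readr::col_character(),
      group = readr::col_character(),
      side = readr::col_character(),
      fragment_index = readr::col_integer(),
      fragment_length_mm = readr::col_double(),
      is_negative_control = readr::col_logical(),
      measurement_index = readr::col_integer(),
      phase = readr::col_character(),
      time_min = readr::col_double(),
      ocr_pmol_min = readr::col_double(),
      ecar_mpH_min = readr::col_double()
    )))
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    p <- probs[1, ]
    stop(sprintf("parse error at file line %d (column %d): expected %s, got \"%s\"",
                 p$row, p$col, p$expected, p$actual), call. = FALSE)
  }
  data <- dplyr::rename(raw, ocr = "ocr_pmol_min", ecar = "ecar_mpH_min")
  # Validate stated time stamps against the nominal grid.
  nominal <- (data$measurement_index - 1) * schedule$interval_min
  off <- abs(data$time_min - nominal)
  if (any(off > 0.5, na.rm = TRUE)) {
    warning(sprintf(
      "%d time_min value(s) deviate from the nominal %g-min grid by > 0.5 min",
      sum(off > 0.5, na.rm = TRUE), schedule$interval_min), call. = FALSE)
  }
  plate_run(data, schedule,
            provenance = sprintf("read_plate_long(\"%s\")", path))
}

#' Write a plate run in the long CSV dialect
#'
#' Emits the fixed column order documented in [read_plate_long()], booleans as
#' `true`/`false`, missing readings as empty fields, and floating-point values
#' with 9 significant digits (so write -> read -> write is byte-identical).
#'
#' @param plate A [plate_run()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_plate_long <- function(plate, path) {
  data <- tibble::as_tibble(plate)
  out <- data.frame(
    well_id = data$well_id,
    animal_id = data$animal_id,
    group = data$group,
    side = ifelse(is.na(data$side), "NA", data$side),
    fragment_index = data$fragment_index,
    fragment_length_mm = fmt_num(data$fragment_length_mm),
    is_negative_control = ifelse(data$is_negative_control, "true", "false"),
    measurement_index = data$measurement_index,
    phase = data$phase,
    time_min = fmt_num(data$time_min),
    ocr_pmol_min = fmt_num(data$ocr),
    ecar_mpH_min = fmt_num(data$ecar),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  names(out) <- PLATE_CSV_COLS
  lines <- c(paste(PLATE_CSV_COLS, collapse = ","),
             if (nrow(out) > 0) do.call(paste, c(unname(as.list(out)), sep = ",")))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

# 9-significant-digit decimal rendering; NA -> empty field.
fmt_num <- function(x) ifelse(is.na(x), "", sprintf("%.9g", x))

`%||%` <- function(x, y) if (is.null(x)) y else x
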