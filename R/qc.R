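#' Quantitative rules for inhibitor-response QC
#'
#' Traces lacking an appropriate inhibitor response are excluded from
#' analysis. These rules quantify that screen on the raw (pre-adjustment)
#' OCR trace of each standard well:
#' the oligomycin check requires `min(post-Omy OCR) / last basal OCR` at or
#' below `omy_max_ratio`; the FCCP check requires
#' `max(post-FCCP OCR) / min(post-Omy OCR)` at or above `fccp_min_ratio`; the
#' Rot/AA check requires `min(post-Rot/AA OCR) / max(post-FCCP OCR)` at or
#' below `rotaa_max_ratio`; and the last basal OCR must be at least
#' `min_basal_ocr` pmol O2/min. Rot/AA-pretreated negative-control wells are
#' exempt from all checks.
#'
#' @param omy_max_ratio,fccp_min_ratio,rotaa_max_ratio Positive ratio
#'   thresholds (defaults 0.9, 1.2, 0.9).
#' @param min_basal_ocr Absolute floor on the last basal OCR (pmol O2/min).
#' @return A list of class `qc_rules`.
#' @export
qc_rules <- function(omy_max_ratio = 0.9, fccp_min_ratio = 1.2,
                     rotaa_max_ratio = 0.9, min_basal_ocr = 5) {
  vals <- c(omy_max_ratio, fccp_min_ratio, rotaa_max_ratio, min_basal_ocr)
  if (!all(is.finite(vals)) || any(vals[1:3] <= 0)) {
    stop("QC thresholds must be finite and ratio thresholds positive.",
         call. = FALSE)
  }
  structure(list(omy_max_ratio = omy_max_ratio,
                 fccp_min_ratio = fccp_min_ratio,
                 rotaa_max_ratio = rotaa_max_ratio,
                 min_basal_ocr = min_basal_ocr),
            class = "qc_rules")
}

#' Classify every well's inhibitor response
#'
#' Evaluates the [qc_rules()] checks on each well's raw OCR trace. Negative
#' control wells are returned as `status = "exempt"` with `passed = TRUE`
#' and no checks evaluated. Wells with missing readings in a required window
#' are returned as `status = "excluded"` (neither pass nor fail) with the
#' reason recorded.
#'
#' @param plate A [plate_run()] (raw, before baseline adjustment).
#' @param rules A [qc_rules()].
#' @return A tibble with one row per well: `well_id`, `animal_id`, `group`,
#'   `status` (`pass`/`fail`/`exempt`/`excluded`), `passed`, `failed_checks`
#'   (comma-separated rule names, empty when passed), `omy_ratio`,
#'   `fccp_ratio`, `rotaa_ratio`, `last_basal_ocr`.
#' @export
qc_classify <- function(plate, rules = qc_rules()) {
  stopifnot(inherits(rules, "qc_rules"))
  sched <- plate_schedule(plate)
  win <- phase_windows(sched)
  if (!all(c("Omy", "FCCP", "RotAA") %in% win$phase)) {
    stop("inhibitor-response QC needs the Omy, FCCP and RotAA phases.",
         call. = FALSE)
  }
  data <- tibble::as_tibble(plate)
  vals <- dplyr::summarise(
    dplyr::group_by(data, .data$well_id, .data$animal_id, .data$group,
                    .data$is_negative_control),
    last_basal_ocr = .data$ocr[.data$measurement_index == sched$n_basal],
    min_omy = suppressWarnings(min(.data$ocr[.data$phase == "Omy"])),
    max_fccp = suppressWarnings(max(.data$ocr[.data$phase == "FCCP"])),
    min_rotaa = suppressWarnings(min(.data$ocr[.data$phase == "RotAA"])),
    n_missing = sum(is.na(.data$ocr[.data$phase != "basal"])),
    .groups = "drop")

  res <- dplyr::mutate(
    vals,
    omy_ratio = .data$min_omy / .data$last_basal_ocr,
    fccp_ratio = .data$max_fccp / .data$min_omy,
    rotaa_ratio = .data$min_rotaa / .data$max_fccp)

  complete <- !is.na(res$last_basal_ocr) & !is.na(res$min_omy) &
    !is.na(res$max_fccp) & !is.na(res$min_rotaa) & res$n_missing == 0 &
    is.finite(res$omy_ratio) & is.finite(res$fccp_ratio) &
    is.finite(res$rotaa_ratio)
  fail_mat <- cbind(
    omy_response = complete & res$omy_ratio > rules$omy_max_ratio,
    fccp_response = complete & res$fccp_ratio < rules$fccp_min_ratio,
    rotaa_response = complete & res$rotaa_ratio > rules$rotaa_max_ratio,
    basal_floor = complete & res$last_basal_ocr < rules$min_basal_ocr)
  failed_checks <- apply(fail_mat, 1, function(f)
    paste(colnames(fail_mat)[f], collapse = ","))
  any_fail <- rowSums(fail_mat) > 0

  status <- ifelse(!complete, "excluded", ifelse(any_fail, "fail", "pass"))
  passed <- ifelse(!complete, NA, !any_fail)
  failed_checks[!complete] <- "incomplete_window"
  neg <- res$is_negative_control
  status[neg] <- "exempt"
  passed[neg] <- TRUE
  failed_checks[neg] <- ""

  dplyr::bind_cols(
    res[c("well_id", "animal_id", "group")],
    tibble::tibble(status = status, passed = passed,
                   failed_checks = failed_checks),
    res[c("omy_ratio", "fccp_ratio", "rotaa_ratio", "last_basal_ocr")])
}

#' Apply QC decisions to a plate run
#'
#' Runs [qc_classify()] and writes the per-well outcome into the plate's
#' `qc_status` column. Failing and excluded wells are retained but flagged;
#' downstream stages consume only `pass` and `exempt` wells.
#'
#' @param plate A [plate_run()].
#' @param rules A [qc_rules()].
#' @return The plate with updated `qc_status` and a provenance entry logging
#'   counts per group.
#' @export
apply_qc <- function(plate, rules = qc_rules()) {
  res <- qc_classify(plate, rules)
  data <- tibble::as_tibble(plate)
  data$qc_status <- res$status[match(data$well_id, res$well_id)]
  tally <- dplyr::count(res, .data$group, .data$status)
  note <- sprintf(
    "apply_qc(omy<=%g, fccp>=%g, rotaa<=%g, basal>=%g): %s",
    rules$omy_max_ratio, rules$fccp_min_ratio, rules$rotaa_max_ratio,
    rules$min_basal_ocr,
    paste(sprintf("%s/%s=%d", tally$group, tally$status, tally$n),
          collapse = " "))
  restore_plate(data, plate, note)
}
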