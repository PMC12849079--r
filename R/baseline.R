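#' Baseline-adjust a plate run per experimental group
#'
#' Aligns traces within each experimental group before metric extraction.
#' Three modes:
#' \describe{
#'   \item{`group_offset` (default)}{For each adjustment stratum, compute the
#'     mean last-basal reading over included wells, then shift each well's
#'     entire trace additively so its last-basal reading equals that mean.
#'     The per-group pointwise mean trace and every within-well difference
#'     (hence every mitostress metric) are unchanged; units stay
#'     pmol O2/min. OCR and ECAR are adjusted independently with their own
#'     stratum means.}
#'   \item{`percent`}{Each well's readings divided by its own last-basal
#'     reading times 100; units become percent of baseline.}
#'   \item{`none`}{Identity.}
#' }
#' Rot/AA-pretreated negative-control wells form their own adjustment stratum
#' (pooled across groups): their floor-level basal readings would otherwise
#' drag the offset computed for standard wells. QC-failing wells do not
#' contribute to stratum means but are shifted alongside their stratum.
#'
#' @param plate A [plate_run()], normally after [apply_qc()].
#' @param mode One of `"group_offset"`, `"percent"`, `"none"`.
#' @return The adjusted plate, with the mode logged in provenance.
#' @export
baseline_adjust <- function(plate, mode = c("group_offset", "percent", "none")) {
  mode <- match.arg(mode)
  if (mode == "none") {
    return(restore_plate(tibble::as_tibble(plate), plate,
                         "baseline_adjust(mode=none)"))
  }
  sched <- plate_schedule(plate)
  data <- tibble::as_tibble(plate)
  last_basal <- dplyr::filter(data, .data$measurement_index == sched$n_basal)
  last_basal <- last_basal[c("well_id", "ocr", "ecar")]
  names(last_basal) <- c("well_id", "lb_ocr", "lb_ecar")

  if (mode == "percent") {
    if (any(is.na(last_basal$lb_ocr)) ||
        any(last_basal$lb_ocr <= 0, na.rm = TRUE)) {
      stop("percent adjustment needs a positive last-basal OCR in every well.",
           call. = FALSE)
    }
    data <- dplyr::left_join(data, last_basal, by = "well_id")
    data$ocr <- 100 * data$ocr / data$lb_ocr
    data$ecar <- 100 * data$ecar / data$lb_ecar
    data$lb_ocr <- data$lb_ecar <- NULL
    return(restore_plate(data, plate, "baseline_adjust(mode=percent)"))
  }

  # group_offset
  meta <- well_meta(plate)
  meta$stratum <- ifelse(meta$is_negative_control, ".rotaa_control", meta$group)
  included <- meta$qc_status %in% included_status
  strata <- dplyr::left_join(last_basal, meta[c("well_id", "stratum")],
                             by = "well_id")
  means <- dplyr::summarise(
    dplyr::group_by(strata[included[match(strata$well_id, meta$well_id)], ],
                    .data$stratum),
    m_ocr = mean(.data$lb_ocr, na.rm = TRUE),
    m_ecar = mean(.data$lb_ecar, na.rm = TRUE),
    n = dplyr::n(), .groups = "drop")
  empty <- setdiff(unique(meta$stratum), means$stratum)
  if (length(empty) > 0 || any(!is.finite(means$m_ocr))) {
    bad <- union(empty, means$stratum[!is.finite(means$m_ocr)])
    stop("no included wells with a last-basal reading in group(s): ",
         paste(sub("^\\.rotaa_control$", "negative controls", bad),
               collapse = ", "), call. = FALSE)
  }
  shifts <- dplyr::left_join(strata, means, by = "stratum")
  shifts$off_ocr <- shifts$m_ocr - shifts$lb_ocr
  shifts$off_ecar <- shifts$m_ecar - shifts$lb_ecar
  data <- dplyr::left_join(data, shifts[c("well_id", "off_ocr", "off_ecar")],
                           by = "well_id")
  data$ocr <- data$ocr + data$off_ocr
  data$ecar <- data$ecar + data$off_ecar
  data$off_ocr <- data$off_ecar <- NULL
  restore_plate(data, plate, "baseline_adjust(mode=group_offset)")
}
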