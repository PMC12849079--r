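#' Compute the classical mitostress parameters per well
#'
#' Extracts, for every included standard well, the window values
#' `last_basal` (the reading at index `n_basal`, i.e. the last OCR before the
#' oligomycin injection), `min_omy` (minimum over the Omy window), `max_fccp`
#' (maximum over the FCCP window), `min_rotaa` (minimum over the Rot/AA
#' window) and `max_last6_omy` (maximum over the final six readings of the
#' Omy window, kept for the uncoupling index), and derives:
#' \itemize{
#'   \item non-mitochondrial respiration `nmr = min_rotaa`
#'   \item basal respiration `basal = last_basal - nmr`
#'   \item ATP-linked respiration `atp = last_basal - min_omy`
#'   \item proton leak `leak = min_omy - nmr`
#'   \item maximal respiration `maximal = max_fccp - nmr`
#'   \item spare capacity `spare_pct = 100 * maximal / basal`
#'   \item coupling efficiency `coupling_pct = 100 * atp / basal`
#' }
#' All extrema are searched over the full post-injection window; no reading
#' is skipped or interpolated. Units follow the trace (pmol O2/min, or % of
#' baseline after percent adjustment). The identity `atp + leak = basal`
#' holds exactly. When `basal <= 0` the two percentage metrics are returned
#' missing with a note; a missing reading in a window makes the metrics that
#' need it missing, never imputed. `basal_ecar` (the last-basal ECAR) is
#' carried along for the energy map.
#'
#' @param plate A [plate_run()] after QC (and normally baseline adjustment
#'   and normalization). Negative-control and QC-failing wells are omitted.
#' @return A tibble with one row per included standard well: identifiers,
#'   the seven metrics, `basal_ecar`, the five audit window values, and
#'   `note` (empty unless a metric is undefined).
#' @export
compute_mitostress <- function(plate) {
  sched <- plate_schedule(plate)
  win <- phase_windows(sched)
  if (!all(c("Omy", "FCCP", "RotAA") %in% win$phase)) {
    stop("mitostress metrics need the Omy, FCCP and RotAA phases.",
         call. = FALSE)
  }
  if (sched$n_post < 6) {
    stop("the uncoupling window statistic needs >= 6 post-Omy readings.",
         call. = FALSE)
  }
  data <- dplyr::filter(tibble::as_tibble(plate),
                        !.data$is_negative_control,
                        .data$qc_status %in% included_status)
  if (nrow(data) == 0) {
    stop("no included standard wells to compute metrics for.", call. = FALSE)
  }
  omy_end <- win$end[win$phase == "Omy"]
  vals <- dplyr::summarise(
    dplyr::group_by(data, .data$well_id, .data$animal_id, .data$group,
                    .data$side),
    last_basal = .data$ocr[.data$measurement_index == sched$n_basal],
    min_omy = min_or_na(.data$ocr[.data$phase == "Omy"]),
    max_fccp = max_or_na(.data$ocr[.data$phase == "FCCP"]),
    min_rotaa = min_or_na(.data$ocr[.data$phase == "RotAA"]),
    max_last6_omy = max_or_na(
      .data$ocr[.data$measurement_index > omy_end - 6L &
                  .data$measurement_index <= omy_end]),
    basal_ecar = .data$ecar[.data$measurement_index == sched$n_basal],
    .groups = "drop")

  out <- dplyr::mutate(
    vals,
    nmr = .data$min_rotaa,
    basal = .data$last_basal - .data$nmr,
    atp = .data$last_basal - .data$min_omy,
    leak = .data$min_omy - .data$nmr,
    maximal = .data$max_fccp - .data$nmr,
    spare_pct = ifelse(!is.na(.data$basal) & .data$basal > 0,
                       100 * .data$maximal / .data$basal, NA_real_),
    coupling_pct = ifelse(!is.na(.data$basal) & .data$basal > 0,
                          100 * .data$atp / .data$basal, NA_real_),
    note = dplyr::case_when(
      is.na(.data$basal) ~ "missing reading in a required window",
      .data$basal <= 0 ~ "nonpositive basal: spare/coupling undefined",
      TRUE ~ ""))
  out[c("well_id", "animal_id", "group", "side",
        "nmr", "basal", "atp", "leak", "maximal", "spare_pct", "coupling_pct",
        "basal_ecar", "last_basal", "min_omy", "max_fccp", "min_rotaa",
        "max_last6_omy", "note")]
}

# min/max that return NA (not +/-Inf with a warning) when any value is NA
# or the window is empty: missing readings propagate, never imputed.
min_or_na <- function(x) if (length(x) == 0 || anyNA(x)) NA_real_ else min(x)
max_or_na <- function(x) if (length(x) == 0 || anyNA(x)) NA_real_ else max(x)

#' Energy-map coordinates per well
#'
#' The energy map plots basal OCR against basal ECAR. Consistent with the
#' basal-respiration definition, both coordinates are the last pre-injection
#' readings (reading `n_basal`) of the adjusted, normalized trace. Group
#' aggregation happens downstream ([aggregate_by_animal()]); because the
#' coordinates are linear in the trace, the group mean of per-well points
#' equals the point of the group mean trace.
#'
#' @param plate A [plate_run()].
#' @return A tibble: `well_id`, `animal_id`, `group`, `basal_ocr`,
#'   `basal_ecar` (missing values propagate with no interpolation).
#' @export
energy_map_point <- function(plate) {
  sched <- plate_schedule(plate)
  data <- dplyr::filter(tibble::as_tibble(plate),
                        !.data$is_negative_control,
                        .data$qc_status %in% included_status,
                        .data$measurement_index == sched$n_basal)
  tibble::tibble(well_id = data$well_id, animal_id = data$animal_id,
                 group = data$group, basal_ocr = data$ocr,
                 basal_ecar = data$ecar)
}
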