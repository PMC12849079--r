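#' Build a positive or negative reference line
#'
#' A reference line is the pointwise average, across a set of member wells
#' sharing one schedule, of their baseline-adjusted (and normalized) OCR
#' traces, with the per-reading SD and member count. The positive reference
#' is built from the QC-passing standard wells of a designated control group
#' (representing maximal activity); the negative reference from the
#' Rot/AA-pretreated negative-control wells of all animals (representing
#' complete inhibition).
#'
#' Alongside the mean trace, the across-member distributions needed by the
#' toxicity metrics are stored: window extrema of the mean trace
#' (`min_omy`, `max_fccp`, and `min_fccp` — the minimum over the FCCP window,
#' used as the negative line's inhibition floor), and the across-well mean
#' and SD of the members' last-basal readings and per-well FCCP-window
#' maxima (the z-score reference statistics).
#'
#' @param plate A [plate_run()] after QC, baseline adjustment and
#'   normalization.
#' @param kind `"positive"` or `"negative"`.
#' @param group For `kind = "positive"`: the reference group label.
#' @return An object of class `reference_line`; see [tidy.reference_line()]
#'   and [glance.reference_line()].
#' @export
build_reference_line <- function(plate, kind = c("positive", "negative"),
                                 group = NULL) {
  kind <- match.arg(kind)
  sched <- plate_schedule(plate)
  meta <- well_meta(plate)
  if (kind == "positive") {
    if (is.null(group)) {
      stop("a positive reference needs the reference `group` label.",
           call. = FALSE)
    }
    sel <- meta$group == group & !meta$is_negative_control &
      meta$qc_status %in% included_status
  } else {
    sel <- meta$is_negative_control & meta$qc_status %in% included_status
  }
  members <- meta$well_id[sel]
  if (length(members) == 0) {
    stop(sprintf("no included wells match the %s reference selector%s.",
                 kind,
                 if (kind == "positive") sprintf(" (group \"%s\")", group) else ""),
         call. = FALSE)
  }
  data <- dplyr::filter(tibble::as_tibble(plate), .data$well_id %in% members)
  trace <- dplyr::summarise(
    dplyr::group_by(data, .data$measurement_index, .data$phase),
    mean_ocr = mean(.data$ocr), sd_ocr = stats::sd(.data$ocr),
    n = dplyr::n(), .groups = "drop")
  trace <- dplyr::arrange(trace, .data$measurement_index)
  if (anyNA(trace$mean_ocr)) {
    stop("reference members contain missing readings.", call. = FALSE)
  }

  win <- phase_windows(sched)
  in_win <- function(p) {
    trace$measurement_index >= win$start[win$phase == p] &
      trace$measurement_index <= win$end[win$phase == p]
  }
  per_well <- dplyr::summarise(
    dplyr::group_by(data, .data$well_id),
    last_basal = .data$ocr[.data$measurement_index == sched$n_basal],
    max_fccp = max(.data$ocr[.data$phase == "FCCP"]),
    .groups = "drop")
  summary <- list(
    last_basal_mean = mean(per_well$last_basal),
    last_basal_sd = stats::sd(per_well$last_basal),
    min_omy = min(trace$mean_ocr[in_win("Omy")]),
    max_fccp = max(trace$mean_ocr[in_win("FCCP")]),
    min_fccp = min(trace$mean_ocr[in_win("FCCP")]),
    max_fccp_member_mean = mean(per_well$max_fccp),
    max_fccp_member_sd = stats::sd(per_well$max_fccp))

  structure(list(kind = kind,
                 group = if (kind == "positive") group else NA_character_,
                 trace = trace[c("measurement_index", "phase", "mean_ocr",
                                 "sd_ocr")],
                 n_wells = length(members), wells = members,
                 summary = summary, schedule = sched),
            class = "reference_line")
}

#' @export
print.reference_line <- function(x, ...) {
  cat(sprintf("<%s reference line> %d well(s)%s, %d readings\n", x$kind,
              x$n_wells,
              if (!is.na(x$group)) sprintf(" from group \"%s\"", x$group) else "",
              nrow(x$trace)))
  s <- x$summary
  cat(sprintf("  last-basal %.3g +/- %.3g; min Omy %.3g; FCCP window [%.3g, %.3g]\n",
              s$last_basal_mean, s$last_basal_sd, s$min_omy, s$min_fccp,
              s$max_fccp))
  invisible(x)
}

#' Tidy and summarize a reference line
#'
#' `tidy()` returns the per-reading mean/SD trace; `glance()` a one-row
#' tibble of the stored summary statistics.
#'
#' @param x A `reference_line`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy reference_line
#' @export
tidy.reference_line <- function(x, ...) {
  dplyr::mutate(x$trace, kind = x$kind, n_wells = x$n_wells)
}

#' @rdname tidy.reference_line
#' @method glance reference_line
#' @export
glance.reference_line <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(kind = x$kind, n_wells = x$n_wells),
                   tibble::as_tibble(x$summary))
}

# Per-well test statistics needed by the toxicity metrics.
tox_test_stats <- function(plate) {
  sched <- plate_schedule(plate)
  win <- phase_windows(sched)
  omy_end <- win$end[win$phase == "Omy"]
  data <- dplyr::filter(tibble::as_tibble(plate),
                        !.data$is_negative_control,
                        .data$qc_status %in% included_status)
  if (nrow(data) == 0) stop("no included standard wells.", call. = FALSE)
  dplyr::summarise(
    dplyr::group_by(data, .data$well_id, .data$animal_id, .data$group),
    last_basal = .data$ocr[.data$measurement_index == sched$n_basal],
    max_fccp = max_or_na(.data$ocr[.data$phase == "FCCP"]),
    max_last6_omy = max_or_na(
      .data$ocr[.data$measurement_index > omy_end - 6L &
                  .data$measurement_index <= omy_end]),
    .groups = "drop")
}

check_ref <- function(ref, kind) {
  if (!inherits(ref, "reference_line") || ref$kind != kind) {
    stop(sprintf("expected a %s reference_line.", kind), call. = FALSE)
  }
}

#' Mitochondrial toxicity index for the FCCP response
#'
#' Scores each test well's uncoupled (FCCP-window) maximum against the
#' reference lines:
#' `MTI_F = (test max FCCP - positive max FCCP) /`
#' `(positive max FCCP - negative min FCCP)`,
#' where both reference extrema are taken on the mean reference traces.
#' 0 means the test matches the positive reference's maximal FCCP response
#' (0% inhibition); -1 means it sits at the negative (Rot/AA) floor
#' (100% inhibition). Strictly increasing in the test maximum.
#'
#' @param plate A [plate_run()] after QC, adjustment and normalization.
#' @param pos,neg The positive and negative [build_reference_line()]s.
#' @return A tibble: `well_id`, `animal_id`, `group`, `mti_f`.
#' @export
compute_mti_f <- function(plate, pos, neg) {
  check_ref(pos, "positive"); check_ref(neg, "negative")
  denom <- pos$summary$max_fccp - neg$summary$min_fccp
  if (!is.finite(denom) || denom <= 0) {
    stop("degenerate references: positive FCCP maximum must exceed the ",
         "negative FCCP-window minimum.", call. = FALSE)
  }
  stats <- tox_test_stats(plate)
  tibble::tibble(
    well_id = stats$well_id, animal_id = stats$animal_id,
    group = stats$group,
    mti_f = (stats$max_fccp - pos$summary$max_fccp) / denom)
}

#' Mitochondrial toxicity index for uncoupling
#'
#' Scores each test well's late post-oligomycin plateau (maximum of the last
#' six Omy-window readings) on the positive reference's coupling span:
#' `MTI_U = (test last-6 Omy max - positive min Omy) /`
#' `(positive max FCCP - positive min Omy)`.
#' 0 means fully coupled at the positive reference's Omy floor; 1 means
#' fully uncoupled at the positive reference's FCCP maximum. Strictly
#' increasing in the test statistic.
#'
#' @inheritParams compute_mti_f
#' @return A tibble: `well_id`, `animal_id`, `group`, `mti_u`.
#' @export
compute_mti_u <- function(plate, pos) {
  check_ref(pos, "positive")
  denom <- pos$summary$max_fccp - pos$summary$min_omy
  if (!is.finite(denom) || denom <= 0) {
    stop("degenerate positive reference: FCCP maximum must exceed the Omy ",
         "minimum.", call. = FALSE)
  }
  stats <- tox_test_stats(plate)
  tibble::tibble(
    well_id = stats$well_id, animal_id = stats$animal_id,
    group = stats$group,
    mti_u = (stats$max_last6_omy - pos$summary$min_omy) / denom)
}

#' z-scores for inhibition of basal and maximal OCR
#'
#' Standardizes each test well against the across-member distribution of the
#' positive reference wells:
#' `z_basal = (test last-basal - mean of members' last-basal) / SD of
#' members' last-basal`, and `z_fccp` analogously with each member's
#' FCCP-window maximum. The averaged reference trace itself has no
#' across-sample dispersion at a reading, so the reference mean and SD are
#' computed across the positive member wells; by construction the members'
#' own z-scores average to zero.
#'
#' @inheritParams compute_mti_f
#' @return A tibble: `well_id`, `animal_id`, `group`, `z_basal`, `z_fccp`.
#' @export
compute_zscores <- function(plate, pos) {
  check_ref(pos, "positive")
  s <- pos$summary
  if (pos$n_wells < 2 || !is.finite(s$last_basal_sd) ||
      s$last_basal_sd <= 0 || s$max_fccp_member_sd <= 0) {
    stop("z-scores need >= 2 positive reference wells with nonzero spread.",
         call. = FALSE)
  }
  stats <- tox_test_stats(plate)
  tibble::tibble(
    well_id = stats$well_id, animal_id = stats$animal_id,
    group = stats$group,
    z_basal = (stats$last_basal - s$last_basal_mean) / s$last_basal_sd,
    z_fccp = (stats$max_fccp - s$max_fccp_member_mean) / s$max_fccp_member_sd)
}

#' All four reference-based toxicity metrics per well
#'
#' Convenience wrapper joining [compute_mti_f()], [compute_mti_u()] and
#' [compute_zscores()].
#'
#' @inheritParams compute_mti_f
#' @return A tibble: `well_id`, `animal_id`, `group`, `mti_f`, `mti_u`,
#'   `z_basal`, `z_fccp`.
#' @export
compute_mitotox <- function(plate, pos, neg) {
  ids <- c("well_id", "animal_id", "group")
  out <- compute_mti_f(plate, pos, neg)
  out <- dplyr::left_join(out, compute_mti_u(plate, pos), by = ids)
  dplyr::left_join(out, compute_zscores(plate, pos), by = ids)
}
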