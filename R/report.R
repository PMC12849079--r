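#' Run the full respirometry analysis pipeline
#'
#' Chains the pipeline stages in their canonical order: inhibitor-response
#' QC on raw traces, group baseline adjustment, per-animal normalization,
#' reference-line construction, mitostress and toxicity metric extraction,
#' animal-level pooling, and two-group statistics. Optionally joins a
#' phenotype table (blood glucose, body weight) and runs the two-factor
#' (group x week) comparisons with Sidak-adjusted simple effects.
#'
#' @param plate A raw [plate_run()].
#' @param factors Per-animal [normalization_factors()] (required unless
#'   `norm_mode = "none"`).
#' @param rules [qc_rules()] for the inhibitor-response screen.
#' @param baseline_mode Passed to [baseline_adjust()].
#' @param norm_mode Passed to [normalize_run()].
#' @param positive_group Group label whose standard wells define the
#'   positive reference line (the lean control strain in the study design).
#' @param phenotypes Optional phenotype tibble
#'   (`animal_id, group, week, blood_glucose_mM, body_weight_g`). Every
#'   animal on the plate must appear in it.
#' @return A list of class `nerveflux_result` with elements `plate`
#'   (processed), `qc`, `metrics`, `tox`, `pos`, `neg` (reference lines),
#'   `animal_summaries`, `comparisons`, `energy_map`, `phenotypes`,
#'   `phenotype_comparisons`, `provenance`.
#' @export
run_pipeline <- function(plate, factors = NULL, rules = qc_rules(),
                         baseline_mode = "group_offset",
                         norm_mode = if (is.null(factors)) "none" else "relative_mef",
                         positive_group, phenotypes = NULL) {
  if (!is.null(phenotypes)) {
    missing_animals <- setdiff(unique(plate$animal_id),
                               unique(phenotypes$animal_id))
    if (length(missing_animals) > 0) {
      stop("animal(s) on the plate absent from the phenotype table: ",
           paste(missing_animals, collapse = ", "), call. = FALSE)
    }
  }
  qc_tab <- qc_classify(plate, rules)
  processed <- plate |>
    apply_qc(rules) |>
    baseline_adjust(mode = baseline_mode) |>
    normalize_run(factors, mode = norm_mode)
  pos <- build_reference_line(processed, "positive", group = positive_group)
  neg_ok <- any(well_meta(processed)$is_negative_control)
  neg <- if (neg_ok) build_reference_line(processed, "negative") else NULL
  metrics <- compute_mitostress(processed)
  tox <- NULL
  if (neg_ok) {
    tox <- dplyr::left_join(compute_mti_f(processed, pos, neg),
                            compute_mti_u(processed, pos),
                            by = c("well_id", "animal_id", "group"))
    # Group-offset alignment with no per-animal normalization leaves every
    # positive member's last-basal identical; z-scores are then undefined.
    z <- tryCatch(compute_zscores(processed, pos), error = function(e) {
      warning("z-scores unavailable: ", conditionMessage(e), call. = FALSE)
      NULL
    })
    if (!is.null(z)) {
      tox <- dplyr::left_join(tox, z, by = c("well_id", "animal_id", "group"))
    } else {
      tox$z_basal <- NA_real_
      tox$z_fccp <- NA_real_
    }
  }
  summaries <- aggregate_by_animal(metrics, tox)
  n_groups <- dplyr::n_distinct(summaries$group)
  comparisons <- if (n_groups == 2) compare_groups(summaries) else NULL
  energy_map <- dplyr::summarise(
    dplyr::group_by(summaries, .data$group),
    n_animals = dplyr::n(),
    basal_ocr_mean = mean(.data$last_basal), basal_ocr_sd = stats::sd(.data$last_basal),
    basal_ecar_mean = mean(.data$basal_ecar), basal_ecar_sd = stats::sd(.data$basal_ecar),
    .groups = "drop")
  pheno_cmp <- NULL
  if (!is.null(phenotypes) && n_groups == 2) {
    pheno_cmp <- list(
      blood_glucose = compare_two_factor(phenotypes, "blood_glucose_mM"),
      body_weight = compare_two_factor(phenotypes, "body_weight_g"))
  }
  structure(list(
    plate = processed, qc = qc_tab, metrics = metrics, tox = tox,
    pos = pos, neg = neg, animal_summaries = summaries,
    comparisons = comparisons, energy_map = energy_map,
    phenotypes = phenotypes, phenotype_comparisons = pheno_cmp,
    provenance = list(
      qc_rules = unclass(rules), baseline_mode = baseline_mode,
      norm_mode = norm_mode, positive_group = positive_group,
      n_wells = nrow(qc_tab), log = plate_provenance(processed))),
    class = "nerveflux_result")
}

#' @export
print.nerveflux_result <- function(x, ...) {
  cat("<nerveflux pipeline result>\n")
  cat(sprintf("  %d wells -> %d animals in %d group(s); positive ref \"%s\" (%d wells)%s\n",
              x$provenance$n_wells, nrow(x$animal_summaries),
              dplyr::n_distinct(x$animal_summaries$group),
              x$provenance$positive_group, x$pos$n_wells,
              if (is.null(x$neg)) "" else sprintf(", negative ref (%d wells)",
                                                  x$neg$n_wells)))
  if (!is.null(x$comparisons)) {
    cat("  group comparisons:\n")
    cmp <- x$comparisons
    for (i in seq_len(nrow(cmp))) {
      cat(sprintf("    %-13s %6.2f +/- %-5.2f vs %6.2f +/- %-5.2f  p=%.4g %s\n",
                  cmp$metric[i], cmp$mean1[i], cmp$sd1[i], cmp$mean2[i],
                  cmp$sd2[i], cmp$p_value[i], cmp$signif[i]))
    }
  }
  invisible(x)
}

#' Summarize a pipeline result
#'
#' @param x A `nerveflux_result`.
#' @param ... Unused.
#' @return One row per group: animal and well counts, mean basal and maximal
#'   respiration, and mean toxicity indices where available.
#' @method glance nerveflux_result
#' @export
glance.nerveflux_result <- function(x, ...) {
  s <- x$animal_summaries
  dplyr::summarise(
    dplyr::group_by(s, .data$group),
    n_animals = dplyr::n(), n_wells = sum(.data$n_wells),
    basal = mean(.data$basal), maximal = mean(.data$maximal),
    spare_pct = mean(.data$spare_pct),
    mti_f = if ("mti_f" %in% names(s)) mean(.data$mti_f) else NA_real_,
    z_basal = if ("z_basal" %in% names(s)) mean(.data$z_basal) else NA_real_,
    .groups = "drop")
}

#' Write the report bundle of a pipeline result
#'
#' Emits plain-text tables for every pipeline product: the QC report,
#' per-well metrics and toxicity tables, reference lines, animal-level
#' summaries, group comparisons, energy-map data, group mean trace data with
#' injection markers, and a provenance JSON echoing all settings. Re-running
#' on an identical result produces byte-identical files.
#'
#' @param result A `nerveflux_result` from [run_pipeline()].
#' @param outdir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
build_report <- function(result, outdir) {
  stopifnot(inherits(result, "nerveflux_result"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(outdir, mode = 2) != 0) {
    stop("output directory is not writable: ", outdir, call. = FALSE)
  }
  paths <- character()
  emit <- function(x, name) {
    p <- file.path(outdir, name)
    readr::write_csv(x, p, progress = FALSE)
    paths[[name]] <<- p
  }
  qc_out <- result$qc
  qc_out <- qc_out[c("well_id", "animal_id", "group", "passed",
                     "failed_checks", "omy_ratio", "fccp_ratio",
                     "rotaa_ratio", "last_basal_ocr")]
  emit(qc_out, "qc_report.csv")
  emit(result$metrics, "well_metrics.csv")
  if (!is.null(result$tox)) emit(result$tox, "well_toxicity.csv")
  refs <- dplyr::bind_rows(tidy(result$pos),
                           if (!is.null(result$neg)) tidy(result$neg))
  emit(refs[c("kind", "measurement_index", "phase", "mean_ocr", "sd_ocr",
              "n_wells")], "reference_lines.csv")
  emit(result$animal_summaries, "animal_summaries.csv")
  if (!is.null(result$comparisons)) {
    emit(result$comparisons, "group_comparisons.csv")
  }
  emit(result$energy_map, "energy_map.csv")
  emit(group_trace_data(result$plate), "trace_data.csv")
  if (!is.null(result$phenotype_comparisons)) {
    emit(dplyr::bind_rows(result$phenotype_comparisons, .id = "response"),
         "phenotype_comparisons.csv")
  }
  prov_path <- file.path(outdir, "provenance.json")
  jsonlite::write_json(result$provenance, prov_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths[["provenance.json"]] <- prov_path
  invisible(paths)
}

#' Group mean trace data with injection markers
#'
#' Per group and reading, the mean and SD of OCR and ECAR over included
#' standard wells, plus an `injection` column naming the compound injected
#' immediately before the first reading of each post-injection phase — the
#' data behind the classical mitostress trace figure.
#'
#' @param plate A [plate_run()].
#' @return A tibble: `group`, `measurement_index`, `phase`, `time_min`,
#'   `injection`, `ocr_mean`, `ocr_sd`, `ecar_mean`, `ecar_sd`, `n_wells`.
#' @export
group_trace_data <- function(plate) {
  win <- phase_windows(plate_schedule(plate))
  data <- dplyr::filter(tibble::as_tibble(plate),
                        !.data$is_negative_control,
                        .data$qc_status %in% included_status)
  out <- dplyr::summarise(
    dplyr::group_by(data, .data$group, .data$measurement_index, .data$phase,
                    .data$time_min),
    ocr_mean = mean(.data$ocr), ocr_sd = stats::sd(.data$ocr),
    ecar_mean = mean(.data$ecar), ecar_sd = stats::sd(.data$ecar),
    n_wells = dplyr::n(), .groups = "drop")
  first_post <- win$start[win$phase != "basal"]
  out$injection <- ifelse(
    out$measurement_index %in% first_post,
    win$phase[match(out$measurement_index, win$start)], NA_character_)
  dplyr::arrange(out[c("group", "measurement_index", "phase", "time_min",
                       "injection", "ocr_mean", "ocr_sd", "ecar_mean",
                       "ecar_sd", "n_wells")],
                 .data$group, .data$measurement_index)
}
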