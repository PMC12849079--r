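#' Mitochondrial enrichment factor from a protein-abundance table
#'
#' For each proteomics sample, the mitochondrial enrichment factor (MEF) is
#' the summed abundance of annotated mitochondrial proteins divided by the
#' summed abundance of all proteins; the per-animal MEF is the mean over that
#' animal's replicate samples. The MEF is dimensionless in `[0, 1]` and
#' invariant under a global rescaling of a sample's abundances.
#'
#' @param abundance A data frame with columns `sample_id`, `animal_id`,
#'   `protein_id`, `abundance` (non-negative; `(sample_id, protein_id)`
#'   unique).
#' @param annotation Character vector of protein IDs annotated mitochondrial
#'   (non-empty). IDs absent from the table contribute nothing; an annotation
#'   completely disjoint from the table yields MEF 0 with a warning.
#' @return A tibble with one row per animal: `animal_id`, `mef`, `n_samples`.
#'   The per-sample values are attached as `attr(, "samples")`, a tibble
#'   `(sample_id, animal_id, mef)`.
#' @examples
#' tab <- tibble::tibble(sample_id = "s1", animal_id = "a1",
#'                       protein_id = c("m1", "p1", "p2"),
#'                       abundance = c(150, 600, 250))
#' compute_mef(tab, "m1") # MEF 0.15
#' @export
compute_mef <- function(abundance, annotation) {
  abundance <- tibble::as_tibble(abundance)
  need <- c("sample_id", "animal_id", "protein_id", "abundance")
  missing_cols <- setdiff(need, names(abundance))
  if (length(missing_cols) > 0) {
    stop("abundance table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (length(annotation) == 0) {
    stop("the mitochondrial annotation must be non-empty.", call. = FALSE)
  }
  if (any(abundance$abundance < 0, na.rm = TRUE)) {
    stop("abundances must be non-negative.", call. = FALSE)
  }
  if (anyDuplicated(abundance[c("sample_id", "protein_id")]) > 0) {
    stop("(sample_id, protein_id) pairs must be unique.", call. = FALSE)
  }
  if (!any(abundance$protein_id %in% annotation)) {
    warning("annotation shares no protein IDs with the table: MEF is 0.",
            call. = FALSE)
  }
  per_sample <- dplyr::summarise(
    dplyr::group_by(abundance, .data$sample_id, .data$animal_id),
    total = sum(.data$abundance),
    mito = sum(.data$abundance[.data$protein_id %in% annotation]),
    .groups = "drop")
  if (any(per_sample$total <= 0 | is.na(per_sample$total))) {
    bad <- per_sample$sample_id[per_sample$total <= 0 | is.na(per_sample$total)]
    stop("zero or missing total abundance in sample(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  per_sample$mef <- per_sample$mito / per_sample$total
  per_animal <- dplyr::summarise(
    dplyr::group_by(per_sample, .data$animal_id),
    mef = mean(.data$mef), n_samples = dplyr::n(), .groups = "drop")
  attr(per_animal, "samples") <-
    per_sample[c("sample_id", "animal_id", "mef")]
  per_animal
}

#' Assemble per-animal normalization factors
#'
#' Collects the per-animal divisors available to [normalize_run()]: the MEF
#' and, optionally, total protein (ug/uL) and citrate-synthase activity
#' (units/mg protein) from companion assays.
#'
#' @param mef A data frame `(animal_id, mef)`, e.g. from [compute_mef()].
#' @param total_protein,cs_activity Optional data frames
#'   `(animal_id, total_protein)` / `(animal_id, cs_activity)`.
#' @return A tibble with one row per animal and whichever factor columns were
#'   supplied.
#' @export
normalization_factors <- function(mef, total_protein = NULL,
                                  cs_activity = NULL) {
  out <- tibble::as_tibble(mef)[c("animal_id", "mef")]
  if (any(out$mef < 0 | out$mef > 1, na.rm = TRUE)) {
    stop("MEF values must lie in [0, 1].", call. = FALSE)
  }
  if (!is.null(total_protein)) {
    out <- dplyr::left_join(
      out, tibble::as_tibble(total_protein)[c("animal_id", "total_protein")],
      by = "animal_id")
  }
  if (!is.null(cs_activity)) {
    out <- dplyr::left_join(
      out, tibble::as_tibble(cs_activity)[c("animal_id", "cs_activity")],
      by = "animal_id")
  }
  out
}

#' Normalize a plate run by per-animal factors
#'
#' Divides each well's OCR and ECAR readings by its animal's normalization
#' factor. Modes:
#' \describe{
#'   \item{`relative_mef` (default)}{Divide by
#'     `MEF_animal / geometric mean of MEF over animals with included wells`.
#'     Expresses every animal relative to the cohort's mitochondrial content
#'     while preserving the cohort scale and the pmol O2/min unit; the cohort
#'     geometric-mean last-basal OCR is unchanged.}
#'   \item{`absolute_mef`}{Divide by `MEF_animal`; rates are then per unit
#'     mitochondrial-protein fraction.}
#'   \item{`total_protein`, `cs_activity`}{Divide by the respective factor.}
#'   \item{`none`}{Identity.}
#' }
#' Every normalization is a per-well positive scalar, so dimensionless
#' metrics (spare capacity, coupling efficiency, and all reference-based
#' toxicity metrics) are invariant under it. Applied after baseline
#' adjustment and before reference-line construction.
#'
#' @param plate A [plate_run()].
#' @param factors A data frame from [normalization_factors()] (or any table
#'   with `animal_id` and the needed factor column).
#' @param mode One of `"relative_mef"`, `"absolute_mef"`, `"total_protein"`,
#'   `"cs_activity"`, `"none"`.
#' @return The normalized plate, mode logged in provenance.
#' @export
normalize_run <- function(plate, factors = NULL,
                          mode = c("relative_mef", "absolute_mef",
                                   "total_protein", "cs_activity", "none")) {
  mode <- match.arg(mode)
  if (mode == "none") {
    return(restore_plate(tibble::as_tibble(plate), plate,
                         "normalize_run(mode=none)"))
  }
  fac_col <- switch(mode,
                    relative_mef = "mef", absolute_mef = "mef",
                    total_protein = "total_protein", cs_activity = "cs_activity")
  factors <- tibble::as_tibble(factors)
  if (!all(c("animal_id", fac_col) %in% names(factors))) {
    stop(sprintf("`factors` must provide columns animal_id and %s for mode %s.",
                 fac_col, mode), call. = FALSE)
  }
  meta <- well_meta(plate)
  included_animals <- unique(meta$animal_id[meta$qc_status %in% included_status])
  fac <- factors[match(included_animals, factors$animal_id), fac_col, drop = TRUE]
  if (anyNA(fac)) {
    stop("missing ", fac_col, " for animal(s): ",
         paste(included_animals[is.na(fac)], collapse = ", "), call. = FALSE)
  }
  if (any(fac <= 0)) {
    stop("nonpositive ", fac_col, " for animal(s): ",
         paste(included_animals[fac <= 0], collapse = ", "), call. = FALSE)
  }
  divisor <- stats::setNames(fac, included_animals)
  if (mode == "relative_mef") {
    gmean <- exp(mean(log(fac)))
    divisor <- divisor / gmean
  }
  data <- tibble::as_tibble(plate)
  d <- unname(divisor[data$animal_id])
  # Wells of animals with no included well keep their readings (they are
  # excluded downstream anyway).
  d[is.na(d)] <- 1
  data$ocr <- data$ocr / d
  data$ecar <- data$ecar / d
  restore_plate(data, plate, sprintf("normalize_run(mode=%s)", mode))
}
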