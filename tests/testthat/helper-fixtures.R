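# Fixture builders shared across the suite. Everything is generated in code;
# no data files.

default_sched <- injection_schedule()

# A step trace that sits exactly at its phase plateaus (plateaus "attained"
# instantly): basal readings at B, Omy window at O, FCCP window at F, RotAA
# window at R.
step_trace <- function(B, O, F, R, sched = default_sched) {
  rep(c(B, O, F, R), times = c(sched$n_basal, sched$n_post, sched$n_post,
                               sched$n_post))
}

# Assemble a plate from a named list of OCR vectors (one per well). `meta`
# may override per-well metadata columns (recycled as needed).
make_plate <- function(ocr, ecar = NULL, sched = default_sched,
                       group = "ctrl", animal_id = NULL,
                       is_negative_control = FALSE, side = "left",
                       qc_status = "pending") {
  n <- length(ocr)
  total <- n_readings(sched)
  ids <- names(ocr) %||% sprintf("W%03d", seq_len(n))
  if (is.null(animal_id)) animal_id <- sprintf("A%02d", seq_len(n))
  if (is.null(ecar)) ecar <- lapply(ocr, function(x) rep(20, total))
  rows <- lapply(seq_len(n), function(i) {
    tibble::tibble(
      well_id = ids[i],
      animal_id = rep(animal_id, length.out = n)[i],
      group = rep(group, length.out = n)[i],
      side = rep(side, length.out = n)[i],
      fragment_index = 1L,
      fragment_length_mm = 1.5,
      is_negative_control = rep(is_negative_control, length.out = n)[i],
      qc_status = rep(qc_status, length.out = n)[i],
      measurement_index = seq_len(total),
      phase = phase_of_readings_helper(sched),
      time_min = (seq_len(total) - 1) * sched$interval_min,
      ocr = ocr[[i]],
      ecar = ecar[[i]])
  })
  plate_run(dplyr::bind_rows(rows), sched)
}

phase_of_readings_helper <- function(sched) {
  w <- phase_windows(sched)
  rep(w$phase, times = w$end - w$start + 1L)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Small cohort config used in several tests: 2 groups x 4 animals x 10 wells.
small_config <- function(...) {
  sim_config(n_animals_per_group = 4L, ...)
}

# Noise-free, plateau-attaining kinetics (tau = 3 drives residual
# non-attainment below 1e-10 relative over an 8-reading window).
noisefree_config <- function(...) {
  k <- well_kinetics(B = 50.1, O = 35.5, F = 93, R = 18.7, tau = 3)
  sim_config(groups = list(BKS = k, dbdb = apply_deficit(k, 0.85)),
             n_animals_per_group = 4L, noise_cv = 0, ...)
}

row_min <- function(m) apply(m, 1, min)
row_max <- function(m) apply(m, 1, max)

# Plate comparison helper: the provenance log legitimately differs between a
# constructed plate and one read back from disk.
plate_data <- function(p) {
  x <- tibble::as_tibble(p)
  attr(x, "schedule") <- NULL
  attr(x, "provenance") <- NULL
  class(x) <- class(tibble::tibble())
  x
}

# A compact plate holding positive-reference wells, negative-control wells,
# and test wells with controllable window values. Positive members use Omy
# plateau `pos_o` and FCCP plateau `pos_f`; negative controls sit flat at
# `neg_level`.
ref_plate <- function(pos_lb = c(30, 30), pos_o = 14, pos_f = 60,
                      neg_level = 5, tests = list()) {
  n_pos <- length(pos_lb)
  pos_f <- rep(pos_f, length.out = n_pos)
  ocr <- c(
    stats::setNames(
      lapply(seq_len(n_pos),
             function(i) step_trace(pos_lb[i], pos_o, pos_f[i], 10)),
      sprintf("pos%d", seq_len(n_pos))),
    list(neg1 = rep(neg_level, 29), neg2 = rep(neg_level, 29)),
    tests)
  n <- length(ocr)
  make_plate(ocr,
             group = c(rep("ctrl", n_pos), rep("ctrl", 2),
                       rep("test", length(tests))),
             animal_id = sprintf("A%02d", seq_len(n)),
             is_negative_control = c(rep(FALSE, n_pos), TRUE, TRUE,
                                     rep(FALSE, length(tests))),
             qc_status = "pass")
}

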