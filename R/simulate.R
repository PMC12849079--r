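#' Plateau kinetics of a simulated well
#'
#' The simulator models each well as a piecewise exponential approach between
#' phase plateaus: basal plateau `B`, post-oligomycin floor `O`, post-FCCP
#' peak `F`, and post-Rot/AA floor `R` (all pmol O2/min), with approach rate
#' `tau` per reading and a basal ECAR plateau (mpH/min). A responder well has
#' `O < B`, `F > O` and `R <= O`.
#'
#' @param B,O,F,R Phase plateaus in pmol O2/min (`R >= 0`).
#' @param tau Exponential approach rate per reading (> 0). At the default 1.0
#'   the trace reaches ~63% of each plateau step by the first post-injection
#'   reading and > 99.9% by the last, so window extrema fall late in the
#'   window as in typical instrument traces.
#' @param ecar_basal Basal ECAR plateau (mpH/min).
#' @return A list of class `well_kinetics`.
#' @examples
#' k <- well_kinetics(B = 30, O = 14, F = 70, R = 10)
#' analytic_metrics(as.data.frame(unclass(k)))
#' @export
well_kinetics <- function(B, O, F, R, tau = 1.0, ecar_basal = 31.5) {
  vals <- c(B = B, O = O, F = F, R = R, tau = tau, ecar_basal = ecar_basal)
  if (!all(is.finite(vals))) stop("kinetics must be finite numbers.", call. = FALSE)
  if (R < 0) stop("`R` must be >= 0.", call. = FALSE)
  if (tau <= 0) stop("`tau` must be > 0.", call. = FALSE)
  structure(as.list(vals), class = "well_kinetics")
}

#' Apply a multiplicative mitochondrial deficit to well kinetics
#'
#' Scales the mitochondrial components of respiration — the plateaus measured
#' above the non-mitochondrial floor `R` — by a common factor, leaving `R`
#' itself unchanged: `B' = R + f (B - R)` and likewise for `O` and `F`; the
#' basal ECAR plateau is scaled by the same factor. This reproduces the
#' empirical signature of a diabetic genotype: basal, ATP-linked, leak and
#' maximal respiration all scale by `f` while spare capacity and coupling
#' efficiency are exactly unchanged.
#'
#' @param k A [well_kinetics()].
#' @param factor Positive scale on the above-floor plateaus (< 1 = deficit).
#' @return A [well_kinetics()].
#' @export
apply_deficit <- function(k, factor) {
  stopifnot(inherits(k, "well_kinetics"), is.numeric(factor), factor > 0)
  well_kinetics(B = k$R + factor * (k$B - k$R),
                O = k$R + factor * (k$O - k$R),
                F = k$R + factor * (k$F - k$R),
                R = k$R, tau = k$tau,
                ecar_basal = factor * k$ecar_basal)
}

#' Default nerve-fragment kinetics
#'
#' Plateaus implied by classical 1.5 mm sciatic-nerve fragment metrics
#' (basal 31.4, ATP-linked 14.6, maximal 74.3, non-mitochondrial
#' 18.7 pmol O2/min): `B = 50.1`, `O = 35.5`, `F = 93.0`, `R = 18.7`.
#'
#' @return A [well_kinetics()].
#' @export
default_kinetics <- function() {
  well_kinetics(B = 50.1, O = 35.5, F = 93.0, R = 18.7, tau = 1.0,
                ecar_basal = 31.5)
}

#' Simulation configuration
#'
#' Defines a two-group (or multi-group) nerve-fragment respirometry study:
#' per-group mean kinetics, cohort size, fragments per nerve side, one
#' Rot/AA-pretreated negative-control well per animal, between-animal
#' variation, per-reading multiplicative noise, and the shape of the matched
#' proteomics tables used for mitochondrial-enrichment-factor (MEF)
#' normalization. Defaults emulate the study design: 12 animals per group,
#' ten 1.5 mm fragments per animal (five per sciatic nerve side, one of which
#' is the Rot/AA-pretreated negative control), a 15% mitochondrial deficit in
#' the disease group, 10% between-animal CV and 5% per-reading noise.
#'
#' @param schedule An [injection_schedule()] with exactly the three classical
#'   injections (Omy, FCCP, Rot/AA).
#' @param groups Named list of per-group mean [well_kinetics()].
#' @param n_animals_per_group Animals per group (>= 1).
#' @param fragments_per_side,sides Fragments per nerve side and number of
#'   sides; their product is the number of wells per animal.
#' @param negative_controls_per_animal How many of each animal's wells are
#'   Rot/AA-pretreated negative controls (taken from the last fragment
#'   positions; must be < wells per animal).
#' @param nonresponder_prob Probability that a standard well ignores all
#'   injections (stays flat at its basal plateau); used to exercise QC.
#' @param noise_cv Multiplicative Gaussian coefficient of variation applied
#'   independently to every reading.
#' @param animal_cv Between-animal lognormal CV of the common scale factor
#'   applied to all plateaus (dimensionless metrics stay constant per group).
#' @param mef_mean,mef_sd Mean and SD of the per-animal mitochondrial
#'   abundance fraction; the animal's flux scale is proportional to its MEF,
#'   which MEF normalization then removes.
#' @param n_proteins,mito_fraction_of_proteins Size of the synthetic
#'   protein-abundance table and the fraction of protein IDs annotated
#'   mitochondrial.
#' @param phenotypes Named list (one entry per group) of blood-glucose and
#'   body-weight means/SDs at weeks 6 and 15; see Details in the vignette.
#' @param seed Integer RNG seed (`NULL` = use the current RNG state).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(schedule = injection_schedule(),
                       groups = list(BKS = default_kinetics(),
                                     dbdb = apply_deficit(default_kinetics(), 0.85)),
                       n_animals_per_group = 12L,
                       fragments_per_side = 5L,
                       sides = 2L,
                       negative_controls_per_animal = 1L,
                       nonresponder_prob = 0,
                       noise_cv = 0.05,
                       animal_cv = 0.10,
                       mef_mean = 0.10,
                       mef_sd = 0.02,
                       n_proteins = 200L,
                       mito_fraction_of_proteins = 0.2,
                       phenotypes = default_phenotypes(names(groups)),
                       seed = NULL) {
  stopifnot(inherits(schedule, "injection_schedule"))
  if (length(schedule$injections) != 3L) {
    stop("the simulator models the three-injection mitostress design ",
         "(Omy, FCCP, Rot/AA).", call. = FALSE)
  }
  if (length(groups) < 1L || is.null(names(groups)) ||
      !all(vapply(groups, inherits, logical(1), "well_kinetics"))) {
    stop("`groups` must be a named list of well_kinetics().", call. = FALSE)
  }
  counts <- c(n_animals_per_group = n_animals_per_group,
              fragments_per_side = fragments_per_side, sides = sides)
  if (any(counts < 1)) stop("counts must be >= 1.", call. = FALSE)
  wells_per_animal <- fragments_per_side * sides
  if (negative_controls_per_animal < 0 ||
      negative_controls_per_animal >= wells_per_animal) {
    stop("`negative_controls_per_animal` must be in [0, wells per animal).",
         call. = FALSE)
  }
  if (nonresponder_prob < 0 || nonresponder_prob > 1) {
    stop("`nonresponder_prob` must be in [0, 1].", call. = FALSE)
  }
  if (noise_cv < 0 || animal_cv < 0 || mef_sd < 0) {
    stop("noise_cv, animal_cv and mef_sd must be >= 0.", call. = FALSE)
  }
  if (mef_mean <= 0 || mef_mean >= 1) {
    stop("`mef_mean` must be a fraction in (0, 1).", call. = FALSE)
  }
  n_mito <- round(mito_fraction_of_proteins * n_proteins)
  if (n_mito < 1 || n_mito > n_proteins - 1) {
    stop("`mito_fraction_of_proteins` must leave at least one mitochondrial ",
         "and one non-mitochondrial protein.", call. = FALSE)
  }
  structure(
    list(schedule = schedule, groups = groups,
         n_animals_per_group = as.integer(n_animals_per_group),
         fragments_per_side = as.integer(fragments_per_side),
         sides = as.integer(sides),
         negative_controls_per_animal = as.integer(negative_controls_per_animal),
         nonresponder_prob = nonresponder_prob,
         noise_cv = noise_cv, animal_cv = animal_cv,
         mef_mean = mef_mean, mef_sd = mef_sd,
         n_proteins = as.integer(n_proteins),
         mito_fraction_of_proteins = mito_fraction_of_proteins,
         phenotypes = phenotypes,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "sim_config")
}

# Phenotype generator defaults. Glucose (mM) and body weight (g) at weeks 6
# and 15; first listed group is the lean control, all later groups diabetic.
default_phenotypes <- function(group_names) {
  lean <- list(glucose_mean = c(`6` = 7.5, `15` = 7.5),
               glucose_sd = c(`6` = 0.8, `15` = 1.1),
               weight_mean = c(`6` = 21.1, `15` = 26.0),
               weight_sd = c(`6` = 1.0, `15` = 1.2))
  diab <- list(glucose_mean = c(`6` = 20.1, `15` = 30.5),
               glucose_sd = c(`6` = 6.6, `15` = 4.7),
               weight_mean = c(`6` = 36.8, `15` = 48.0),
               weight_sd = c(`6` = 1.4, `15` = 3.0))
  out <- c(list(lean), rep(list(diab), max(0L, length(group_names) - 1L)))
  stats::setNames(out, group_names)
}

# Animal IDs, fixed naming shared by all generators.
sim_animals <- function(config) {
  grp <- rep(names(config$groups), each = config$n_animals_per_group)
  tibble::tibble(
    group = grp,
    animal_id = sprintf("%s_%02d", grp,
                        rep(seq_len(config$n_animals_per_group),
                            times = length(config$groups))))
}

#' Simulate a plate run with known ground truth
#'
#' Generates every well's noise-free trace as a piecewise exponential approach
#' to the phase plateaus — within a phase with target plateau `P` and entry
#' level `L0`, the level at the t-th reading of the phase is
#' `P + (L0 - P) * exp(-tau * t)` — then applies independent multiplicative
#' Gaussian noise `level * (1 + eps)`, `eps ~ N(0, noise_cv)`, to every
#' reading. Negative-control wells (Rot/AA pretreated) sit at their Rot/AA
#' floor `R` for all phases including basal; non-responder wells stay at `B`
#' throughout. Each animal's plateaus are scaled by a common factor
#' `exp(N(0, animal_cv)) * MEF_animal / mef_mean`, coupling the flux scale to
#' the animal's mitochondrial content so that MEF normalization is meaningful.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer overriding `config$seed`.
#' @return A list with elements `plate` (a [plate_run()]) and `truth`, where
#'   `truth` is a list of tibbles: `wells` (realized per-well kinetics and
#'   responder flags), `metrics` (analytic mitostress values for responder
#'   standard wells, from [analytic_metrics()]), and `mef` (per-animal
#'   mitochondrial fraction used).
#' @export
simulate_plate <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  sched <- config$schedule
  animals <- sim_animals(config)

  # Per-animal draws: biological scale, MEF, combined flux scale.
  n_a <- nrow(animals)
  animals$bio_scale <- exp(stats::rnorm(n_a, 0, config$animal_cv))
  animals$mef <- pmin(pmax(stats::rnorm(n_a, config$mef_mean, config$mef_sd),
                           0.01), 0.95)
  animals$scale <- animals$bio_scale * animals$mef / config$mef_mean

  # Well layout: fragments_per_side per side; the last fragment positions are
  # the Rot/AA-pretreated negative controls.
  wpa <- config$fragments_per_side * config$sides
  layout <- tidyr::expand_grid(
    animals,
    side = c("left", "right", paste0("side", seq_len(max(0, config$sides - 2L)) + 2L))[seq_len(config$sides)],
    fragment_index = seq_len(config$fragments_per_side))
  layout <- dplyr::arrange(layout, .data$group, .data$animal_id,
                           .data$side, .data$fragment_index)
  layout <- dplyr::mutate(
    dplyr::group_by(layout, .data$animal_id),
    well_rank = dplyr::row_number(),
    is_negative_control = .data$well_rank > wpa - config$negative_controls_per_animal)
  layout <- dplyr::ungroup(layout)
  layout$well_id <- sprintf("P%02d-%s%02d",
                            (seq_len(nrow(layout)) - 1L) %/% 96L + 1L,
                            LETTERS[((seq_len(nrow(layout)) - 1L) %% 96L) %/% 12L + 1L],
                            (seq_len(nrow(layout)) - 1L) %% 12L + 1L)

  # Realized per-well kinetics: group means scaled per animal.
  km <- do.call(rbind, lapply(config$groups, function(k) {
    unlist(k[c("B", "O", "F", "R", "tau", "ecar_basal")])
  }))
  gidx <- match(layout$group, names(config$groups))
  kcol <- function(nm) unname(km[gidx, nm])
  wells <- dplyr::mutate(
    layout,
    B = kcol("B") * .data$scale, O = kcol("O") * .data$scale,
    F = kcol("F") * .data$scale, R = kcol("R") * .data$scale,
    tau = kcol("tau"), ecar_basal = kcol("ecar_basal") * .data$scale)
  wells$responder <- !wells$is_negative_control &
    (stats::runif(nrow(wells)) >= config$nonresponder_prob)
  wells$responder[wells$is_negative_control] <- NA

  # Noise-free levels, phase by phase.
  n_wells <- nrow(wells)
  total <- n_readings(sched)
  win <- phase_windows(sched)
  ocr_plateaus <- cbind(wells$B, wells$O, wells$F, wells$R)
  ecar_mult <- c(1, 1.3, 1.2, 0.8) # basal, Omy, FCCP, RotAA multipliers
  ecar_plateaus <- outer(wells$ecar_basal, ecar_mult)
  # Negative controls: OCR pinned at R, ECAR at basal plateau, all phases.
  neg <- wells$is_negative_control
  ocr_plateaus[neg, ] <- wells$R[neg]
  ecar_plateaus[neg, ] <- wells$ecar_basal[neg]
  # Non-responders: flat at B / basal ECAR.
  flat <- !neg & !wells$responder
  ocr_plateaus[flat, ] <- wells$B[flat]
  ecar_plateaus[flat, ] <- wells$ecar_basal[flat]

  ocr_level <- matrix(NA_real_, n_wells, total)
  ecar_level <- matrix(NA_real_, n_wells, total)
  L0_ocr <- ocr_plateaus[, 1]
  L0_ecar <- ecar_plateaus[, 1]
  for (p in seq_len(nrow(win))) {
    idx <- win$start[p]:win$end[p]
    t_in <- seq_along(idx)
    decay <- exp(-outer(wells$tau, t_in)) # n_wells x phase length
    ocr_level[, idx] <- ocr_plateaus[, p] + (L0_ocr - ocr_plateaus[, p]) * decay
    ecar_level[, idx] <- ecar_plateaus[, p] + (L0_ecar - ecar_plateaus[, p]) * decay
    L0_ocr <- ocr_level[, win$end[p]]
    L0_ecar <- ecar_level[, win$end[p]]
  }
  ocr_obs <- ocr_level *
    (1 + matrix(stats::rnorm(n_wells * total, 0, config$noise_cv), n_wells, total))
  ecar_obs <- ecar_level *
    (1 + matrix(stats::rnorm(n_wells * total, 0, config$noise_cv), n_wells, total))

  data <- tibble::tibble(
    well_id = rep(wells$well_id, each = total),
    animal_id = rep(wells$animal_id, each = total),
    group = rep(wells$group, each = total),
    side = rep(wells$side, each = total),
    fragment_index = rep(wells$fragment_index, each = total),
    fragment_length_mm = 1.5,
    is_negative_control = rep(wells$is_negative_control, each = total),
    measurement_index = rep(seq_len(total), times = n_wells),
    phase = rep(phase_of_readings(sched), times = n_wells),
    time_min = rep(times_of_readings(sched), times = n_wells),
    ocr = as.vector(t(ocr_obs)),
    ecar = as.vector(t(ecar_obs)))

  plate <- plate_run(data, sched, provenance = sprintf(
    "simulate_plate(groups=%s, n_animals=%d, noise_cv=%g, seed=%s)",
    paste(names(config$groups), collapse = "/"), config$n_animals_per_group,
    config$noise_cv, if (is.null(seed)) "NULL" else seed))

  truth_wells <- wells[c("well_id", "animal_id", "group", "side",
                         "fragment_index", "is_negative_control", "responder",
                         "B", "O", "F", "R", "tau", "ecar_basal", "mef",
                         "scale")]
  responders <- truth_wells[!truth_wells$is_negative_control &
                              truth_wells$responder %in% TRUE, ]
  truth <- list(
    wells = truth_wells,
    metrics = dplyr::bind_cols(
      responders[c("well_id", "animal_id", "group")],
      analytic_metrics(responders[c("B", "O", "F", "R")])),
    mef = animals[c("animal_id", "group", "mef")])
  list(plate = plate, truth = truth)
}

#' Analytic mitostress metrics of plateau kinetics
#'
#' Closed-form values of the seven mitostress parameters implied by plateau
#' kinetics, assuming plateaus are attained within their windows:
#' NMR = `R`; basal = `B - R`; ATP-linked = `B - O`; leak = `O - R`;
#' maximal = `F - R`; spare capacity (%) = `100 (F - R) / (B - R)`;
#' coupling efficiency (%) = `100 (B - O) / (B - R)`. Serves as the
#' independent oracle for [compute_mitostress()] on noise-free simulations.
#'
#' @param kinetics A data frame with numeric columns `B`, `O`, `F`, `R` (one
#'   row per well); extra columns are ignored.
#' @return A tibble with columns `nmr`, `basal`, `atp`, `leak`, `maximal`,
#'   `spare_pct`, `coupling_pct`.
#' @export
analytic_metrics <- function(kinetics) {
  kinetics <- tibble::as_tibble(kinetics)
  stopifnot(all(c("B", "O", "F", "R") %in% names(kinetics)))
  if (any(kinetics$B == kinetics$R)) {
    stop("basal plateau equals the Rot/AA floor (B = R): spare capacity and ",
         "coupling efficiency are undefined.", call. = FALSE)
  }
  with(kinetics, tibble::tibble(
    nmr = R,
    basal = B - R,
    atp = B - O,
    leak = O - R,
    maximal = F - R,
    spare_pct = 100 * (F - R) / (B - R),
    coupling_pct = 100 * (B - O) / (B - R)))
}

#' Simulate a matched label-free proteomics table
#'
#' For each animal, generates three replicate samples of lognormal protein
#' abundances over `n_proteins` protein IDs, the first
#' `mito_fraction_of_proteins * n_proteins` of which are annotated
#' mitochondrial. Within each sample the mitochondrial abundances are rescaled
#' so that their realized share of total abundance equals the animal's drawn
#' MEF exactly, making [compute_mef()] recovery exact by construction.
#'
#' @param config A [sim_config()].
#' @param mef Optional tibble `(animal_id, mef)` fixing per-animal fractions
#'   (e.g. `truth$mef` from [simulate_plate()] so flux and proteomics agree);
#'   when `NULL`, fractions are drawn from `N(mef_mean, mef_sd)`.
#' @param seed Optional integer overriding `config$seed`.
#' @return A list with `abundance` (tibble: `sample_id`, `animal_id`,
#'   `protein_id`, `abundance`), `annotation` (character vector of
#'   mitochondrial protein IDs) and `mef` (per-animal tibble used).
#' @export
simulate_proteomics <- function(config, mef = NULL, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  animals <- sim_animals(config)
  if (is.null(mef)) {
    animals$mef <- pmin(pmax(stats::rnorm(nrow(animals), config$mef_mean,
                                          config$mef_sd), 0.01), 0.95)
  } else {
    stopifnot(all(c("animal_id", "mef") %in% names(mef)))
    animals <- dplyr::inner_join(animals, mef[c("animal_id", "mef")],
                                 by = "animal_id")
  }
  n_mito <- as.integer(round(config$mito_fraction_of_proteins * config$n_proteins))
  proteins <- c(sprintf("MITO%04d", seq_len(n_mito)),
                sprintf("CYT%04d", seq_len(config$n_proteins - n_mito)))
  is_mito <- seq_len(config$n_proteins) <= n_mito

  tabs <- lapply(seq_len(nrow(animals)), function(i) {
    reps <- lapply(1:3, function(r) {
      ab <- stats::rlnorm(config$n_proteins, meanlog = log(100), sdlog = 0.6)
      # Rescale the mitochondrial block so its realized share is exactly mef.
      f <- animals$mef[i]
      s <- f * sum(ab[!is_mito]) / ((1 - f) * sum(ab[is_mito]))
      ab[is_mito] <- ab[is_mito] * s
      tibble::tibble(
        sample_id = sprintf("%s_r%d", animals$animal_id[i], r),
        animal_id = animals$animal_id[i],
        protein_id = proteins,
        abundance = ab)
    })
    dplyr::bind_rows(reps)
  })
  list(abundance = dplyr::bind_rows(tabs),
       annotation = proteins[is_mito],
       mef = animals[c("animal_id", "group", "mef")])
}

#' Simulate the phenotype table
#'
#' Per animal and week (6 and 15), draws random-fed blood glucose (mM,
#' censored at the 33.3 mM glucometer ceiling) and body weight (g) from the
#' group's configured means and SDs.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer overriding `config$seed`.
#' @return A tibble: `animal_id`, `group`, `week`, `blood_glucose_mM`,
#'   `body_weight_g`.
#' @export
simulate_phenotypes <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  animals <- sim_animals(config)
  rows <- tidyr::expand_grid(animals, week = c(6L, 15L))
  ph <- config$phenotypes
  wk <- as.character(rows$week)
  gm <- mapply(function(g, w) ph[[g]]$glucose_mean[[w]], rows$group, wk)
  gs <- mapply(function(g, w) ph[[g]]$glucose_sd[[w]], rows$group, wk)
  wm <- mapply(function(g, w) ph[[g]]$weight_mean[[w]], rows$group, wk)
  ws <- mapply(function(g, w) ph[[g]]$weight_sd[[w]], rows$group, wk)
  rows$blood_glucose_mM <- pmin(pmax(stats::rnorm(nrow(rows), gm, gs), 0), 33.3)
  rows$body_weight_g <- pmax(stats::rnorm(nrow(rows), wm, ws), 1)
  rows[c("animal_id", "group", "week", "blood_glucose_mM", "body_weight_g")]
}

#' Simulate a complete study bundle
#'
#' Runs [simulate_plate()], [simulate_proteomics()] (with the plate's MEF
#' draws, so flux scale and proteomics agree per animal) and
#' [simulate_phenotypes()] under a single seed.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer overriding `config$seed`.
#' @return A list: `plate`, `truth`, `proteomics` (abundance + annotation),
#'   `phenotypes`, `config`.
#' @export
simulate_study <- function(config, seed = config$seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  sim <- simulate_plate(config, seed = NULL)
  prot <- simulate_proteomics(config, mef = sim$truth$mef, seed = NULL)
  pheno <- simulate_phenotypes(config, seed = NULL)
  list(plate = sim$plate, truth = sim$truth, proteomics = prot,
       phenotypes = pheno, config = config)
}

#' Write a simulated study to plain-text files
#'
#' Emits the plate long CSV, phenotype CSV, proteomics TSV
#' (`sample_id, animal_id, protein_id, abundance`), the annotation list (one
#' mitochondrial protein ID per line) and a ground-truth JSON.
#'
#' @param study Result of [simulate_study()].
#' @param outdir Output directory (created if needed).
#' @return Named character vector of the five file paths, invisibly.
#' @export
write_study_bundle <- function(study, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(plate = file.path(outdir, "plate_long.csv"),
             phenotypes = file.path(outdir, "phenotypes.csv"),
             proteomics = file.path(outdir, "proteomics.tsv"),
             annotation = file.path(outdir, "mito_annotation.txt"),
             truth = file.path(outdir, "ground_truth.json"))
  write_plate_long(study$plate, paths[["plate"]])
  readr::write_csv(study$phenotypes, paths[["phenotypes"]], progress = FALSE)
  readr::write_tsv(study$proteomics$abundance, paths[["proteomics"]],
                   progress = FALSE)
  writeLines(study$proteomics$annotation, paths[["annotation"]])
  jsonlite::write_json(
    list(wells = study$truth$wells, metrics = study$truth$metrics,
         mef = study$truth$mef),
    paths[["truth"]], digits = NA, auto_unbox = TRUE)
  invisible(paths)
}
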