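test_that("noise-free fast-settling kinetics hit their plateaus exactly", {
  k <- well_kinetics(B = 30, O = 14, F = 70, R = 10, tau = 50)
  cfg <- sim_config(groups = list(g = k), n_animals_per_group = 1,
                    noise_cv = 0, animal_cv = 0, mef_sd = 0,
                    negative_controls_per_animal = 0)
  sim <- simulate_plate(cfg, seed = 1)
  tr <- sim$plate[sim$plate$well_id == sim$plate$well_id[1], ]
  expect_equal(min(tr$ocr[tr$phase == "Omy"]), 14, tolerance = 1e-12)
  expect_equal(max(tr$ocr[tr$phase == "FCCP"]), 70, tolerance = 1e-12)
  expect_equal(min(tr$ocr[tr$phase == "RotAA"]), 10, tolerance = 1e-12)
  expect_equal(tr$ocr[5], 30, tolerance = 1e-12)
})

test_that("the exponential approach follows P + (L0 - P) exp(-tau t)", {
  k <- well_kinetics(B = 30, O = 14, F = 70, R = 10, tau = 0.7)
  cfg <- sim_config(groups = list(g = k), n_animals_per_group = 1,
                    noise_cv = 0, animal_cv = 0, mef_sd = 0,
                    negative_controls_per_animal = 0)
  sim <- simulate_plate(cfg, seed = 1)
  tr <- sim$plate[sim$plate$well_id == sim$plate$well_id[1], ]
  # First Omy-phase reading approaches O from B
  expect_equal(tr$ocr[6], 14 + (30 - 14) * exp(-0.7), tolerance = 1e-12)
  expect_equal(tr$ocr[7], 14 + (30 - 14) * exp(-1.4), tolerance = 1e-12)
  # FCCP phase starts from the Omy end level
  L0 <- tr$ocr[13]
  expect_equal(tr$ocr[14], 70 + (L0 - 70) * exp(-0.7), tolerance = 1e-12)
})

test_that("negative controls sit at the Rot/AA floor and are counted", {
  cfg <- small_config(noise_cv = 0, animal_cv = 0, mef_sd = 0, seed = 3)
  sim <- simulate_plate(cfg)
  meta <- well_meta(sim$plate)
  expect_equal(sum(meta$is_negative_control), 8L) # 1 per animal, 2x4 animals
  neg_ids <- meta$well_id[meta$is_negative_control]
  neg <- sim$plate[sim$plate$well_id %in% neg_ids, ]
  truth <- sim$truth$wells
  for (w in neg_ids) {
    expect_equal(neg$ocr[neg$well_id == w],
                 rep(truth$R[truth$well_id == w], 29), tolerance = 1e-12)
  }
})

test_that("non-responders stay flat at their basal plateau", {
  cfg <- small_config(noise_cv = 0, animal_cv = 0, mef_sd = 0,
                      nonresponder_prob = 1, seed = 2)
  sim <- simulate_plate(cfg)
  truth <- sim$truth$wells
  std <- truth[!truth$is_negative_control, ]
  expect_true(all(!std$responder))
  tr <- sim$plate[sim$plate$well_id == std$well_id[1], ]
  expect_equal(tr$ocr, rep(std$B[1], 29), tolerance = 1e-12)
})

test_that("simulation is seed-deterministic", {
  cfg <- small_config(seed = 42)
  s1 <- simulate_plate(cfg)
  s2 <- simulate_plate(cfg)
  expect_identical(s1$plate$ocr, s2$plate$ocr)
  expect_identical(s1$truth$wells, s2$truth$wells)
  s3 <- simulate_plate(cfg, seed = 43)
  expect_false(identical(s1$plate$ocr, s3$plate$ocr))
})

test_that("analytic metrics follow the plateau arithmetic and identities", {
  m <- analytic_metrics(data.frame(B = 30, O = 14, F = 70, R = 10))
  expect_equal(m$nmr, 10)
  expect_equal(m$basal, 20)
  expect_equal(m$atp, 16)
  expect_equal(m$leak, 4)
  expect_equal(m$maximal, 60)
  expect_equal(m$spare_pct, 300)
  expect_equal(m$coupling_pct, 80)

  # sub-100% spare capacity is legitimate
  m2 <- analytic_metrics(data.frame(B = 30, O = 14, F = 25, R = 10))
  expect_equal(m2$maximal, 15)
  expect_equal(m2$spare_pct, 75)

  # identity over randomized kinetics
  set.seed(5)
  k <- data.frame(R = runif(200, 0, 20))
  k$O <- k$R + runif(200, 0.1, 30)
  k$B <- k$O + runif(200, 0.1, 40)
  k$F <- k$O + runif(200, 0.1, 80)
  m3 <- analytic_metrics(k)
  expect_equal(m3$atp + m3$leak, m3$basal, tolerance = 1e-12)

  expect_error(analytic_metrics(data.frame(B = 10, O = 5, F = 20, R = 10)),
               "undefined")
})

test_that("genotype deficit scales above-floor plateaus, preserving ratios", {
  k <- default_kinetics()
  kd <- apply_deficit(k, 0.85)
  expect_equal(kd$R, k$R)
  expect_equal(kd$B - kd$R, 0.85 * (k$B - k$R))
  m <- analytic_metrics(data.frame(B = k$B, O = k$O, F = k$F, R = k$R))
  md <- analytic_metrics(data.frame(B = kd$B, O = kd$O, F = kd$F, R = kd$R))
  expect_equal(md$basal / m$basal, 0.85)
  expect_equal(md$maximal / m$maximal, 0.85)
  expect_equal(md$spare_pct, m$spare_pct)
  expect_equal(md$coupling_pct, m$coupling_pct)
})

test_that("proteomics tables are triplicate and recover the MEF draw exactly", {
  cfg <- sim_config(n_animals_per_group = 2, seed = 9)
  prot <- simulate_proteomics(cfg)
  expect_equal(dplyr::n_distinct(prot$abundance$sample_id), 12L) # 4 animals x 3
  mef <- compute_mef(prot$abundance, prot$annotation)
  j <- dplyr::inner_join(mef, prot$mef, by = "animal_id",
                         suffix = c("", ".draw"))
  expect_equal(j$mef, j$mef.draw, tolerance = 1e-12)
  samples <- attr(mef, "samples")
  expect_equal(nrow(samples), 12L)
  # every replicate individually matches the draw (exact by construction)
  j2 <- dplyr::inner_join(samples, prot$mef, by = "animal_id",
                          suffix = c("", ".draw"))
  expect_equal(j2$mef, j2$mef.draw, tolerance = 1e-12)

  prot2 <- simulate_proteomics(cfg)
  expect_identical(prot$abundance$abundance, prot2$abundance$abundance)
})

test_that("study bundles are written as readable plain-text files", {
  cfg <- sim_config(n_animals_per_group = 2, fragments_per_side = 2, seed = 4)
  st <- simulate_study(cfg)
  dir <- withr::local_tempdir()
  paths <- write_study_bundle(st, dir)
  expect_true(all(file.exists(paths)))
  back <- read_plate_long(paths[["plate"]])
  expect_equal(back$ocr, st$plate$ocr, tolerance = 1e-8)
  expect_equal(length(readLines(paths[["annotation"]])), 40L) # 0.2 * 200
})
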