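mini_table <- function() {
  tibble::tibble(
    sample_id = rep(c("s1", "s2"), each = 3),
    animal_id = rep(c("a1", "a2"), each = 3),
    protein_id = rep(c("m1", "p1", "p2"), 2),
    abundance = c(150, 600, 250, # a1: 150/1000
                  300, 500, 200)) # a2: 300/1000
}

test_that("MEF is the annotated share of total abundance", {
  mef <- compute_mef(mini_table(), "m1")
  expect_equal(mef$mef[mef$animal_id == "a1"], 0.15)
  expect_equal(mef$mef[mef$animal_id == "a2"], 0.30)
  expect_equal(mef$n_samples, c(1L, 1L))
  # full annotation -> boundary value 1
  mef_all <- compute_mef(mini_table(), c("m1", "p1", "p2"))
  expect_equal(mef_all$mef, c(1, 1))
  # disjoint annotation -> 0 with a warning
  expect_warning(mef0 <- compute_mef(mini_table(), "nothere"), "no protein")
  expect_equal(mef0$mef, c(0, 0))
})

test_that("MEF is invariant under global rescaling of a sample", {
  tab <- mini_table()
  tab2 <- tab
  tab2$abundance[tab2$sample_id == "s1"] <-
    tab2$abundance[tab2$sample_id == "s1"] * 1e6
  expect_equal(compute_mef(tab2, "m1")$mef, compute_mef(tab, "m1")$mef,
               tolerance = 1e-12)
})

test_that("degenerate abundance tables are rejected", {
  tab <- mini_table()
  tab$abundance[tab$sample_id == "s2"] <- 0
  expect_error(compute_mef(tab, "m1"), "s2")
  tab2 <- mini_table()[c(1, 1, 2), ]
  expect_error(compute_mef(tab2, "m1"), "unique")
  expect_error(compute_mef(mini_table(), character()), "non-empty")
})

test_that("replicate averaging recovers per-animal constructed values", {
  cfg <- sim_config(n_animals_per_group = 3, seed = 15)
  prot <- simulate_proteomics(cfg)
  mef <- compute_mef(prot$abundance, prot$annotation)
  j <- dplyr::inner_join(mef, prot$mef, by = "animal_id",
                         suffix = c("", ".draw"))
  expect_equal(j$mef, j$mef.draw, tolerance = 1e-12)
  expect_true(all(j$n_samples == 3L))
})

test_that("relative MEF normalization preserves cohort scale", {
  cfg <- small_config(seed = 16)
  st <- simulate_study(cfg)
  plate <- apply_qc(st$plate) |> baseline_adjust()
  factors <- normalization_factors(
    compute_mef(st$proteomics$abundance, st$proteomics$annotation))
  norm <- normalize_run(plate, factors, "relative_mef")
  # identical MEF for all animals -> identity
  flat <- factors; flat$mef <- 0.2
  expect_equal(normalize_run(plate, flat, "relative_mef")$ocr, plate$ocr,
               tolerance = 1e-12)
  # cohort geometric-mean last-basal OCR unchanged
  gmean_lb <- function(p) {
    lb <- p[p$measurement_index == 5 & !p$is_negative_control, ]
    per_animal <- tapply(lb$ocr, lb$animal_id, mean)
    exp(mean(log(per_animal)))
  }
  expect_equal(gmean_lb(norm), gmean_lb(plate), tolerance = 1e-9)
  # dimensionless metrics untouched by any normalization mode
  m0 <- compute_mitostress(plate)
  for (mode in c("relative_mef", "absolute_mef")) {
    m1 <- compute_mitostress(normalize_run(plate, factors, mode))
    expect_equal(m1$spare_pct, m0$spare_pct, tolerance = 1e-9)
    expect_equal(m1$coupling_pct, m0$coupling_pct, tolerance = 1e-9)
  }
})

test_that("an animal at double the cohort reference is halved", {
  plate <- make_plate(list(a = step_trace(30, 14, 70, 10),
                           b = step_trace(30, 14, 70, 10)),
                      animal_id = c("A1", "A2"))
  # geometric mean of (0.1, 0.4) is 0.2; A2 sits at twice that
  factors <- tibble::tibble(animal_id = c("A1", "A2"), mef = c(0.1, 0.4))
  norm <- normalize_run(plate, factors, "relative_mef")
  expect_equal(norm$ocr[norm$well_id == "b"],
               plate$ocr[plate$well_id == "b"] / 2, tolerance = 1e-12)
  expect_equal(norm$ocr[norm$well_id == "a"],
               plate$ocr[plate$well_id == "a"] * 2, tolerance = 1e-12)
})

test_that("mode none is the identity and failures are named", {
  plate <- make_plate(list(a = step_trace(30, 14, 70, 10)),
                      animal_id = "A1")
  expect_equal(normalize_run(plate, NULL, "none")$ocr, plate$ocr)
  expect_error(normalize_run(plate, tibble::tibble(animal_id = "zz", mef = 0.1),
                             "relative_mef"), "A1")
  expect_error(normalize_run(plate, tibble::tibble(animal_id = "A1", mef = 0),
                             "absolute_mef"), "nonpositive")
  expect_error(
    normalize_run(plate, tibble::tibble(animal_id = "A1", mef = 0.2),
                  "total_protein"), "total_protein")
})

test_that("alternative factors divide through directly", {
  plate <- make_plate(list(a = step_trace(30, 14, 70, 10)), animal_id = "A1")
  factors <- tibble::tibble(animal_id = "A1", mef = 0.2,
                            total_protein = 2, cs_activity = 4)
  expect_equal(normalize_run(plate, factors, "total_protein")$ocr,
               plate$ocr / 2)
  expect_equal(normalize_run(plate, factors, "cs_activity")$ocr,
               plate$ocr / 4)
  expect_equal(normalize_run(plate, factors, "absolute_mef")$ocr,
               plate$ocr / 0.2)
})
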