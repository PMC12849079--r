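test_that("animal pooling averages included wells and respects balance", {
  metrics <- tibble::tibble(
    well_id = c("w1", "w2", "w3", "w4"),
    animal_id = c("A1", "A1", "A1", "A1"),
    group = "g", side = c("left", "left", "right", "right"),
    basal = c(18, 22, 16, 24))
  pooled <- aggregate_by_animal(metrics)
  expect_equal(pooled$basal, 20)
  expect_equal(pooled$n_wells, 4L)
  by_side <- aggregate_by_animal(metrics, by_side = TRUE)
  expect_equal(sort(by_side$basal), c(20, 20))
  # balanced sides: pooled mean equals mean of side means
  expect_equal(pooled$basal, mean(by_side$basal))
  # permutation invariance to well order
  pooled_rev <- aggregate_by_animal(metrics[4:1, ])
  expect_equal(pooled_rev$basal, pooled$basal)
})

test_that("toxicity columns join by well before pooling", {
  metrics <- tibble::tibble(well_id = c("w1", "w2"), animal_id = "A1",
                            group = "g", basal = c(10, 20))
  tox <- tibble::tibble(well_id = c("w2", "w1"), animal_id = "A1",
                        group = "g", mti_f = c(-0.4, -0.2))
  pooled <- aggregate_by_animal(metrics, tox)
  expect_equal(pooled$mti_f, -0.3)
})

test_that("the two-group Student t matches the closed form", {
  summaries <- tibble::tibble(
    animal_id = sprintf("A%d", 1:6),
    group = rep(c("g1", "g2"), each = 3),
    basal = c(1, 2, 3, 4, 5, 6))
  cmp <- compare_groups(summaries, metrics = "basal")
  # pooled-variance t on {1,2,3} vs {4,5,6}: t = -3/sqrt(1*(2/3)) = -3.674
  expect_equal(cmp$statistic, -3 / sqrt(2 / 3), tolerance = 1e-9)
  expect_equal(round(cmp$statistic, 3), -3.674)
  expect_equal(cmp$df, 4)
  expect_equal(cmp$p_value, 0.0214, tolerance = 1e-2)
  expect_equal(cmp$signif, "*")
  expect_equal(cmp$mean1, 2)
  expect_equal(cmp$sd1, 1)

  # identical groups: t = 0, p = 1
  null_sum <- summaries
  null_sum$basal <- rep(c(1, 2, 3), 2)
  cmp0 <- compare_groups(null_sum, metrics = "basal")
  expect_equal(cmp0$statistic, 0)
  expect_equal(cmp0$p_value, 1)
  expect_equal(cmp0$signif, "ns")
})

test_that("group-size and group-count preconditions are enforced", {
  bad <- tibble::tibble(animal_id = c("A1", "A2", "A3"),
                        group = c("g1", "g1", "g2"), basal = 1:3)
  expect_error(compare_groups(bad), "g2")
  three <- tibble::tibble(animal_id = sprintf("A%d", 1:6),
                          group = rep(c("a", "b", "c"), 2), basal = 1:6)
  expect_error(compare_groups(three), "two groups")
})

test_that("significance tiers agree with p-values on every row", {
  set.seed(23)
  summaries <- tibble::tibble(
    animal_id = sprintf("A%d", 1:12),
    group = rep(c("g1", "g2"), each = 6),
    m1 = rnorm(12), m2 = rnorm(12) + rep(c(0, 3), each = 6),
    m3 = rnorm(12) + rep(c(0, 9), each = 6))
  cmp <- compare_groups(summaries)
  tier_of <- function(p) {
    if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
  }
  expect_equal(cmp$signif, vapply(cmp$p_value, tier_of, character(1)))
})

test_that("two-factor ANOVA reports four Sidak-adjusted simple effects", {
  set.seed(24)
  pheno <- tidyr::expand_grid(animal_id = sprintf("A%02d", 1:12),
                              week = c(6, 15))
  pheno$group <- rep(c("ctrl", "dis"), each = 12)
  mu <- ifelse(pheno$group == "dis", ifelse(pheno$week == 15, 30.5, 20.1), 7.5)
  pheno$blood_glucose_mM <- rnorm(24, mu, 1)
  cmp <- compare_two_factor(pheno, "blood_glucose_mM")
  expect_equal(nrow(cmp), 4L)
  expect_setequal(cmp$stratum, c("6", "15", "ctrl", "dis"))
  # Sidak adjustment: each adjusted p is 1 - (1 - p_raw)^4, so never smaller
  cmp_raw <- compare_two_factor(pheno, "blood_glucose_mM")
  expect_true(all(cmp$p_value >= 0 & cmp$p_value <= 1))
  # a 13 mM genotype gap at week 6 against sd 1 must be significant
  expect_equal(cmp$signif[cmp$stratum == "6"], "***")
  # no week change in controls
  expect_equal(cmp$signif[cmp$stratum == "ctrl"], "ns")
  expect_s3_class(attr(cmp, "anova")[[1]], "anova")
})

test_that("Sidak family adjustment matches the closed form", {
  set.seed(25)
  d <- tidyr::expand_grid(g = c("a", "b"), w = c("x", "y"), rep = 1:5)
  d$y <- rnorm(nrow(d)) + (d$g == "b") * 0.8
  cmp <- compare_two_factor(d, "y", factor1 = "g", factor2 = "w")
  # recompute one simple effect without adjustment via emmeans
  fit <- stats::aov(y ~ g * w, data = d)
  emm <- emmeans::emmeans(fit, ~ g * w)
  raw <- as.data.frame(emmeans::contrast(emm, "pairwise", simple = "each",
                                         combine = TRUE, adjust = "none"))
  expect_equal(cmp$p_value, 1 - (1 - raw$p.value)^4, tolerance = 1e-9)
})

test_that("hyperglycemia classification is strict and censoring-aware", {
  g <- classify_hyperglycemia(c(20.1, 7.5, 16.7, 33.3, 16.71))
  expect_equal(as.logical(g), c(TRUE, FALSE, FALSE, TRUE, TRUE))
  expect_equal(attr(g, "censored"), c(FALSE, FALSE, FALSE, TRUE, FALSE))
  expect_error(classify_hyperglycemia(-1), ">= 0")
})

test_that("a genotype deficit is detected with high power at study size", {
  hits <- 0
  n_seeds <- 40
  for (s in seq_len(n_seeds)) {
    cfg <- sim_config(n_animals_per_group = 12, seed = 3000 + s)
    sim <- simulate_plate(cfg)
    # MEF normalization is integral here: the simulated flux scale tracks
    # each animal's mitochondrial content, which normalization removes
    factors <- normalization_factors(sim$truth$mef)
    plate <- apply_qc(sim$plate) |> baseline_adjust() |>
      normalize_run(factors, "relative_mef")
    pooled <- aggregate_by_animal(compute_mitostress(plate))
    cmp <- compare_groups(pooled, metrics = "basal")
    hits <- hits + (cmp$p_value < 0.05)
  }
  expect_gte(hits / n_seeds, 0.8)
})
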