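test_that("reference lines average member traces pointwise", {
  plate <- ref_plate(pos_lb = c(28, 32))
  pos <- build_reference_line(plate, "positive", group = "ctrl")
  expect_equal(pos$n_wells, 2L)
  # members are step traces with basal 28/32 -> mean basal 30 at readings 1:5
  expect_equal(pos$trace$mean_ocr[1:5], rep(30, 5))
  expect_equal(pos$trace$sd_ocr[1:5], rep(sd(c(28, 32)), 5))
  # identical members -> sd 0 and mean equal to the trace
  plate2 <- ref_plate(pos_lb = c(30, 30))
  pos2 <- build_reference_line(plate2, "positive", group = "ctrl")
  expect_equal(pos2$trace$sd_ocr, rep(0, 29))
  expect_equal(pos2$trace$mean_ocr, step_trace(30, 14, 60, 10))
  # single-member reference is the member itself
  neg <- build_reference_line(plate, "negative")
  expect_equal(neg$trace$mean_ocr, rep(5, 29))
  expect_equal(glance(neg)$min_fccp, 5)
})

test_that("empty selections and degenerate references error", {
  plate <- ref_plate()
  expect_error(build_reference_line(plate, "positive", group = "nope"),
               "no included wells")
  expect_error(build_reference_line(plate, "positive"), "label")
})

test_that("MTI_F matches its anchor points and worked example", {
  plate <- ref_plate(tests = list(t0 = step_trace(30, 14, 60, 10),
                                  tneg = step_trace(30, 14, 5, 4),
                                  tmid = step_trace(30, 14, 38.5, 10)))
  pos <- build_reference_line(plate, "positive", group = "ctrl")
  neg <- build_reference_line(plate, "negative")
  mti <- compute_mti_f(plate, pos, neg)
  get <- function(w) mti$mti_f[mti$well_id == w]
  expect_equal(get("t0"), 0, tolerance = 1e-12) # at positive maximum
  expect_equal(get("tneg"), -1, tolerance = 1e-12) # at negative floor
  expect_equal(get("tmid"), (38.5 - 60) / 55, tolerance = 1e-12) # -0.3909...
  expect_equal(get("tmid"), -0.390909090909, tolerance = 1e-9)
})

test_that("MTI_U matches its anchor points and worked example", {
  plate <- ref_plate(tests = list(t0 = step_trace(30, 14, 70, 10),
                                  t1 = step_trace(30, 60, 70, 10),
                                  tmid = step_trace(30, 25.2, 70, 10)))
  pos <- build_reference_line(plate, "positive", group = "ctrl")
  mti <- compute_mti_u(plate, pos)
  get <- function(w) mti$mti_u[mti$well_id == w]
  expect_equal(get("t0"), 0, tolerance = 1e-12) # at positive Omy floor
  expect_equal(get("t1"), 1, tolerance = 1e-12) # at positive FCCP maximum
  expect_equal(get("tmid"), 11.2 / 46, tolerance = 1e-12) # 0.2435
})

test_that("z-scores standardize against across-member statistics", {
  lb <- c(11.2 - 1.1 / sqrt(2), 11.2 + 1.1 / sqrt(2)) # mean 11.2, sd 1.1
  plate <- ref_plate(pos_lb = lb, pos_f = c(59, 61), # spread in FCCP maxima
                     tests = list(tmean = step_trace(11.2, 5, 60, 2),
                                  tlow = step_trace(9.0, 5, 60, 2)))
  pos <- build_reference_line(plate, "positive", group = "ctrl")
  expect_equal(pos$summary$last_basal_mean, 11.2, tolerance = 1e-12)
  expect_equal(pos$summary$last_basal_sd, 1.1, tolerance = 1e-12)
  z <- compute_zscores(plate, pos)
  expect_equal(z$z_basal[z$well_id == "tmean"], 0, tolerance = 1e-12)
  expect_equal(z$z_basal[z$well_id == "tlow"], -2, tolerance = 1e-12)
  # one member-SD above the mean scores exactly 1
  plate2 <- ref_plate(pos_lb = lb, pos_f = c(59, 61),
                      tests = list(tup = step_trace(11.2 + 1.1, 5, 60, 2)))
  pos2 <- build_reference_line(plate2, "positive", group = "ctrl")
  z2 <- compute_zscores(plate2, pos2)
  expect_equal(z2$z_basal[z2$well_id == "tup"], 1, tolerance = 1e-12)
  # members' own z-scores average to zero by construction
  expect_equal(mean(z$z_basal[z$well_id %in% pos$wells]), 0,
               tolerance = 1e-12)
  expect_equal(mean(z$z_fccp[z$well_id %in% pos$wells]), 0,
               tolerance = 1e-12)
})

test_that("degenerate denominators raise errors", {
  plate <- ref_plate(pos_lb = c(30, 30), pos_f = 4, neg_level = 5,
                     tests = list(t = step_trace(30, 14, 70, 10)))
  pos <- build_reference_line(plate, "positive", group = "ctrl")
  neg <- build_reference_line(plate, "negative")
  expect_error(compute_mti_f(plate, pos, neg), "degenerate")
  # identical members -> zero member SD -> z-scores refuse
  plate2 <- ref_plate(tests = list(t = step_trace(30, 14, 70, 10)))
  pos2 <- build_reference_line(plate2, "positive", group = "ctrl")
  expect_error(compute_zscores(plate2, pos2), "spread")
})

test_that("toxicity metrics rise monotonically with their test statistic", {
  steps <- seq(20, 80, by = 10)
  tests <- stats::setNames(
    lapply(steps, function(f) step_trace(30, 14, f, 10)),
    sprintf("tf%02d", steps))
  plate <- ref_plate(tests = tests)
  pos <- build_reference_line(plate, "positive", group = "ctrl")
  neg <- build_reference_line(plate, "negative")
  mti <- compute_mti_f(plate, pos, neg)
  ord <- mti$mti_f[match(sprintf("tf%02d", steps), mti$well_id)]
  expect_true(all(diff(ord) > 0))

  tests_u <- stats::setNames(
    lapply(steps / 2, function(o) step_trace(90, o, 95, 10)),
    sprintf("tu%02d", steps))
  plate_u <- ref_plate(tests = tests_u)
  pos_u <- build_reference_line(plate_u, "positive", group = "ctrl")
  mti_u <- compute_mti_u(plate_u, pos_u)
  ord_u <- mti_u$mti_u[match(sprintf("tu%02d", steps), mti_u$well_id)]
  expect_true(all(diff(ord_u) > 0))
})

test_that("all four metrics are invariant under common positive rescaling", {
  plate <- ref_plate(pos_lb = c(28, 32), pos_f = c(55, 65),
                     tests = list(t = step_trace(26, 13, 50, 9)))
  compute_all <- function(p) {
    pos <- build_reference_line(p, "positive", group = "ctrl")
    neg <- build_reference_line(p, "negative")
    out <- compute_mitotox(p, pos, neg)
    out[out$well_id == "t", c("mti_f", "mti_u", "z_basal", "z_fccp")]
  }
  base <- compute_all(plate)
  for (c_scale in c(0.1, 2.5, 40)) {
    data <- tibble::as_tibble(plate)
    data$ocr <- data$ocr * c_scale
    scaled <- plate_run(data, plate_schedule(plate))
    expect_equal(compute_all(scaled), base, tolerance = 1e-9)
  }
})
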