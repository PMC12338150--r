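test_that("standard curve fitting recovers exact and affine-shifted lines", {
  pts <- data.frame(conc_ug_ml = c(0.01, 0.05, 0.1, 0.5, 1.0),
                    intensity = c(10, 50, 100, 500, 1000))
  cv <- fit_standard_curve(pts)
  expect_equal(cv$slope, 1000, tolerance = 1e-9)
  expect_equal(cv$intercept, 0, tolerance = 1e-9)
  expect_equal(cv$r_squared, 1, tolerance = 1e-12)
  shifted <- transform(pts, intensity = intensity + 5)
  cv2 <- fit_standard_curve(shifted)
  expect_equal(cv2$slope, 1000, tolerance = 1e-9)
  expect_equal(cv2$intercept, 5, tolerance = 1e-9)
  expect_error(fit_standard_curve(pts[1:2, ]), "3")
  expect_error(fit_standard_curve(
    data.frame(conc_ug_ml = c(1, 1, 1), intensity = c(1, 2, 3))), "distinct")
})

test_that("noisy calibration recovers the generating slope within 2%", {
  set.seed(17)
  errs <- replicate(100, {
    slope <- runif(1, 500, 5000)
    grid <- c(0.01, 0.05, 0.1, 0.5, 1.0)
    pts <- data.frame(conc_ug_ml = grid,
                      intensity = slope * grid * (1 + rnorm(5, 0, 0.01)))
    abs(fit_standard_curve(pts)$slope - slope) / slope
  })
  expect_lte(median(errs), 0.02)
})

test_that("unit conversion reproduces the reported concentration bounds", {
  expect_equal(ug_per_ml_to_uM(1, 515.7), 1.94, tolerance = 1e-2)
  expect_equal(ug_per_ml_to_uM(1, 376.57), 2.656, tolerance = 1e-3)
  expect_equal(ug_per_ml_to_uM(0, 400), 0)
  expect_error(ug_per_ml_to_uM(1, 0), "positive")
})

test_that("curve inversion applies censoring flags and unit conversion", {
  cv <- fit_standard_curve(data.frame(conc_ug_ml = c(0.01, 0.05, 0.1, 0.5, 1),
                                      intensity = c(10, 50, 100, 500, 1000)))
  # 0.5 ug/ml of DCA (392.57 g/mol) = 1.274 uM, quantified
  r <- invert_curve(500, cv, 392.57)
  expect_equal(r$conc_uM, 1.274, tolerance = 1e-3)
  expect_equal(r$flag, "quantified")
  # 0.01 ug/ml = 0.0255 uM: below the 0.05 uM detection limit
  r2 <- invert_curve(10, cv, 392.57)
  expect_equal(r2$conc_uM, 0)
  expect_equal(r2$flag, "below-LOD")
  # intensity at the intercept inverts to zero
  r3 <- invert_curve(cv$intercept, cv, 392.57)
  expect_equal(r3$conc_uM, 0)
  expect_equal(r3$flag, "below-LOD")
  # between LOD and the reporting threshold
  r4 <- invert_curve(30, cv, 392.57)  # 0.03 ug/ml -> 0.0764 uM
  expect_equal(r4$flag, "below-report")
  # negative inversions clamp to zero
  expect_equal(invert_curve(-50, cv, 392.57)$conc_uM, 0)
  # inversion composed with the forward line is the identity on the range
  conc <- seq(0.05, 1, length.out = 20)
  inten <- cv$slope * conc + cv$intercept
  back <- invert_curve(inten, cv, 392.57)$conc_uM
  expect_equal(back, ug_per_ml_to_uM(conc, 392.57), tolerance = 1e-9)
})

test_that("percent transformed is a plain ratio", {
  expect_equal(percent_transformed(93.9, 100), 93.9)
  expect_equal(percent_transformed(0, 100), 0)
  expect_equal(percent_transformed(50, 100), 50)
  expect_error(percent_transformed(1, 0), "positive")
})

test_that("activity calling respects threshold, graph edges and controls", {
  rec <- function(strain, cond, t, sp, conc)
    data.frame(strain_id = strain, condition = cond, time_h = t,
               species_id = sp, conc_uM = conc, flag = "quantified")
  records <- rbind(
    rec("A", "CA", 48, "7-oxoDCA", 46.1),     # 7a-HSD
    rec("A", "CA", 24, "7-oxoDCA", 20.0),
    rec("A", "CA", 48, "3-oxoCA", 0.09),      # below threshold: no call
    rec("B", "CA", 48, "DCA", 5.0),           # 7a-dehydroxylation
    rec("C", "CDCA", 48, "7-oxoDCA", 4.0),    # product off-substrate: no call
    rec("D", "NONE", 48, "DCA", 3.0)          # background, never called
  )
  res <- call_activities(records)
  calls <- res$calls
  expect_equal(calls$activity[calls$strain_id == "A"], "7a-HSD")
  expect_equal(calls$max_conc_uM[calls$strain_id == "A"], 46.1)
  expect_equal(calls$time_of_max_h[calls$strain_id == "A"], 48)
  expect_equal(calls$activity[calls$strain_id == "B"], "7a-dehydroxylation")
  expect_false("C" %in% calls$strain_id)
  expect_false("D" %in% calls$strain_id)
  expect_equal(res$background$strain_id, "D")
  # every call is on a graph edge and above threshold
  g <- transformation_graph()
  expect_true(all(paste(calls$substrate, calls$product) %in%
                    paste(g$substrate, g$product)))
  expect_true(all(calls$max_conc_uM >= 0.1))
})

test_that("MIX condition never scores added bile acids as products", {
  records <- data.frame(
    strain_id = "A", condition = "MIX", time_h = 48,
    species_id = c("DCA", "7-oxoDCA"), conc_uM = c(50, 10),
    flag = "quantified")
  calls <- call_activities(records)$calls
  expect_false("7a-dehydroxylation" %in% calls$activity)  # DCA was added
  expect_true("7a-HSD" %in% calls$activity)               # oxo product scores
})

test_that("mass-balance violations are flagged, not dropped", {
  records <- data.frame(strain_id = "A", condition = "CA", time_h = 48,
                        species_id = "7-oxoDCA", conc_uM = 120,
                        flag = "quantified")
  calls <- call_activities(records, substrate_added_uM = 100)$calls
  expect_equal(nrow(calls), 1)
  expect_true(calls$mass_balance_flag)
})

test_that("Z-score normalization is exact per row and flags degenerates", {
  expect_equal(as.numeric(zscore_matrix(matrix(c(10, 20, 30), 1))),
               c(-1, 0, 1))
  set.seed(3)
  m <- matrix(rnorm(60, 100, 20), nrow = 6)
  z <- zscore_matrix(m)
  expect_equal(rowMeans(z), rep(0, 6), tolerance = 1e-9)
  expect_equal(apply(z, 1, sd), rep(1, 6), tolerance = 1e-9)
  m2 <- rbind(m[1, ], c(5, 5, 5, 5, 5, 5, 5, 5, 5, 5))
  z2 <- zscore_matrix(m2)
  expect_equal(z2[2, ], rep(0, 10))
  expect_equal(attr(z2, "zero_variance"), c(FALSE, TRUE))
})

test_that("zero-noise synthetic panels invert to the planted concentrations", {
  led <- tiny_panel(seed = 12, intensity_noise_cv = 0, cal_noise_cv = 0,
                    jitter_ppm_sd = 0, rt_jitter_sd_min = 0)
  pt <- emit_peak_tables(led)
  cal <- emit_calibration(led)
  m <- stage_match(pt$features, pt$spectra, build_mz_library(),
                   led$standards)
  q <- stage_quantify(m, cal$calibration, cal$standards)
  planted <- led$concentrations
  got <- merge(q$records, planted,
               by.x = c("strain_id", "condition", "time_h", "species_id"),
               by.y = c("strain_id", "condition", "time_h", "species_id"))
  expect_gt(nrow(got), 0)
  expect_equal(got$conc_uM.x, got$conc_uM.y, tolerance = 1e-6)
})

test_that("5% intensity noise keeps median relative error within 5%", {
  set.seed(23)
  rel_err <- c()
  for (s in 1:20) {
    led <- tiny_panel(seed = 1000 + s, intensity_noise_cv = 0.05,
                      cal_noise_cv = 0)
    pt <- emit_peak_tables(led)
    cal <- emit_calibration(led)
    m <- stage_match(pt$features, NULL, build_mz_library(), led$standards)
    q <- stage_quantify(m, cal$calibration, cal$standards)
    got <- merge(q$records, led$concentrations,
                 by = c("strain_id", "condition", "time_h", "species_id"))
    keep <- got$conc_uM.y >= 0.1
    rel_err <- c(rel_err, abs(got$conc_uM.x[keep] - got$conc_uM.y[keep]) /
                   got$conc_uM.y[keep])
  }
  expect_lte(median(rel_err), 0.05)
})
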