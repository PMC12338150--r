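test_that("ppm error formula and the strict 2 ppm gate", {
  expect_equal(ppm_error(448.30685, 448.30685), 0)
  expect_equal(ppm_error(448.30752, 448.30685), 1.49, tolerance = 1e-2)
  p <- ppm_error(448.30775, 448.30685)
  expect_gt(p, 2)  # +2.01 ppm: fails the strict < 2 gate
  feat <- data.frame(sample_id = "s", rt_min = 10, mz = 448.30775,
                     intensity = 1)
  lib <- data.frame(species_id = "Gly-DCA", mz_M_minus_H = 448.30685)
  expect_equal(nrow(match_ms1(feat, lib, tol_ppm = 2)), 0)
  expect_error(ppm_error(1, 0), "positive")
})

test_that("match_ms1 agrees with the brute-force pair scan", {
  lib <- build_mz_library()
  set.seed(31)
  # features at jittered library masses plus random off-mass features
  mz <- c(lib$mz_M_minus_H[sample.int(nrow(lib), 40)] *
            (1 + runif(40, -1.5, 1.5) * 1e-6),
          runif(30, 290, 1000))
  feats <- data.frame(sample_id = "s", rt_min = runif(70, 1, 30), mz = mz,
                      intensity = 1)
  got <- match_ms1(feats, lib, tol_ppm = 2)
  want <- oracle_match_pairs(feats, lib, 2)
  expect_equal(nrow(got), nrow(want))
  expect_setequal(paste(got$feature_id, got$species_id),
                  paste(want$feature, want$species_id))
  expect_true(all(abs(got$ppm) < 2))
})

test_that("single-feature match and tolerance monotonicity", {
  lib <- build_mz_library()
  feat <- data.frame(sample_id = "s", rt_min = 5, mz = 448.30685,
                     intensity = 10)
  hit <- match_ms1(feat, lib, tol_ppm = 2)
  # the four exactly isobaric glycine conjugates (C24H40O4 cores), all
  # reported and flagged, nothing else within 2 ppm
  expect_setequal(hit$species_id,
                  c("Gly-DCA", "Gly-CDCA", "Gly-UDCA", "Gly-HDCA"))
  expect_true(all(hit$n_isobaric == 4))
  expect_equal(nrow(match_ms1(data.frame(sample_id = "s", rt_min = 5,
                                         mz = 290.0, intensity = 1),
                              lib, 2)), 0)
  set.seed(5)
  feats <- data.frame(sample_id = "s", rt_min = runif(50, 1, 30),
                      mz = runif(50, 350, 650), intensity = 1)
  m1 <- match_ms1(feats, lib, tol_ppm = 1)
  m2 <- match_ms1(feats, lib, tol_ppm = 2)
  expect_true(all(paste(m1$feature_id, m1$species_id) %in%
                    paste(m2$feature_id, m2$species_id)))
  expect_warning(match_ms1(feats, lib[0, ], 2), "empty")
})

test_that("standard-RT gating applies only to species with standards", {
  lib <- data.frame(species_id = c("DCA", "CDCA", "Phe-CDCA"),
                    mz_M_minus_H = c(391.28538, 391.28538, 538.35380),
                    rt_min = c(19.5, 18.3, NA))
  feats <- data.frame(sample_id = "s", rt_min = c(19.4, 12.0),
                      mz = c(391.28538, 538.35380), intensity = 1)
  m <- match_ms1(feats, lib, tol_ppm = 2, rt_window_min = 0.5)
  # the isobaric DCA/CDCA pair resolves by RT; the conjugate matches anywhere
  expect_equal(m$species_id[m$mz_obs < 400], "DCA")
  expect_equal(m$species_id[m$mz_obs > 500], "Phe-CDCA")
})

test_that("confirm_ms2 counts triad fragments in the right window", {
  lib <- build_mz_library()
  feat <- data.frame(sample_id = "s", rt_min = 12, mz = 448.30685,
                     intensity = 10)
  match <- match_ms1(feat, lib, 2)
  match <- match[match$species_id == "Gly-DCA", ]
  # glyco-DCA (448.31) falls in the 446-centered window (426-466) only
  spec_good <- data.frame(sample_id = "s", rt_min = 12.05,
                          precursor_center = 446, isolation_width = 40,
                          mz = c(74.02475, 391.28538, 200.1),
                          intensity = c(1e4, 2e4, 500))
  up <- confirm_ms2(match, spec_good, lib)
  expect_equal(up$evidence, "MS1_plus_MS2")
  expect_setequal(strsplit(up$fragments_found, ",")[[1]],
                  c("aa_anion", "aa_loss"))
  # the same peaks in the wrong window are never searched
  spec_wrong <- transform(spec_good, precursor_center = 370)
  expect_equal(confirm_ms2(match, spec_wrong, lib)$evidence, "MS1_only")
  # unrelated peaks leave evidence untouched
  spec_junk <- transform(spec_good, mz = c(100.1, 200.2, 300.3))
  expect_equal(confirm_ms2(match, spec_junk, lib)$evidence, "MS1_only")
  # an RT-distant spectrum is not associated
  spec_far <- transform(spec_good, rt_min = 20)
  expect_equal(confirm_ms2(match, spec_far, lib)$evidence, "MS1_only")
  # 3-of-3 rule demands the full triad
  expect_equal(confirm_ms2(match, spec_good, lib, min_fragments = 3)$evidence,
               "MS1_only")
  spec_all <- data.frame(sample_id = "s", rt_min = 12.02,
                         precursor_center = 446, isolation_width = 40,
                         mz = c(74.02475, 391.28538, 373.27481),
                         intensity = 1e4)
  expect_equal(confirm_ms2(match, spec_all, lib, min_fragments = 3)$evidence,
               "MS1_plus_MS2")
})

test_that("shrinking the fragment tolerance never upgrades evidence", {
  lib <- build_mz_library()
  feat <- data.frame(sample_id = "s", rt_min = 12, mz = 448.30685,
                     intensity = 10)
  match <- match_ms1(feat, lib, 2)
  match <- match[match$species_id == "Gly-DCA", ]
  set.seed(9)
  for (i in 1:10) {
    off <- runif(2, -20, 20)  # fragment peaks off by up to 20 ppm
    spec <- data.frame(sample_id = "s", rt_min = 12,
                       precursor_center = 446, isolation_width = 40,
                       mz = c(74.02475 * (1 + off[1] * 1e-6),
                              391.28538 * (1 + off[2] * 1e-6)),
                       intensity = 1)
    wide <- confirm_ms2(match, spec, lib, frag_tol_ppm = 10)
    narrow <- confirm_ms2(match, spec, lib, frag_tol_ppm = 2)
    if (narrow$evidence == "MS1_plus_MS2")
      expect_equal(wide$evidence, "MS1_plus_MS2")
  }
})

test_that("double-peak detection pairs adjacent separated features", {
  mk <- function(rts) data.frame(
    sample_id = "s", feature_id = seq_along(rts), species_id = "Ala-CDCA",
    rt_min = rts, mz_obs = 1, mz_theo = 1, intensity = 1, ppm = 0,
    evidence = "MS1_only", fragments_found = "", isobaric_group = "Ala",
    n_isobaric = 1L)
  p <- detect_double_peaks(mk(c(12.1, 13.0)), min_sep_min = 0.3)
  expect_equal(nrow(p), 1)
  expect_equal(p$delta_rt, 0.9, tolerance = 1e-9)
  expect_equal(nrow(detect_double_peaks(mk(10.0), 0.3)), 0)
  # sub-threshold neighbours are suppressed; only the separated couple pairs
  p3 <- detect_double_peaks(mk(c(10.0, 10.1, 12.0)), 0.3)
  expect_equal(nrow(p3), 1)
  expect_equal(c(p3$rt_1, p3$rt_2), c(10.1, 12.0))
  # different species never pair
  two <- rbind(mk(12), transform(mk(14), species_id = "Val-CA"))
  expect_equal(nrow(detect_double_peaks(two, 0.3)), 0)
})

test_that("peak table reader enforces the dialect", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,ms_level,rt_min,mz,intensity,precursor_center,isolation_width",
               "s1,1,10.5,448.30685,1000,,",
               "s1,1,11.0,391.28538,500,,",
               "s1,2,10.5,74.02475,100,446,40"), f)
  pt <- read_peak_table(f)
  expect_equal(nrow(pt$features), 2)
  expect_equal(nrow(pt$spectra), 1)
  expect_equal(pt$spectra$precursor_center, 446)
  # malformed rows are dropped with a warning naming lines
  writeLines(c("sample_id,ms_level,rt_min,mz,intensity,precursor_center,isolation_width",
               "s1,1,10.5,448.3,1000,,",
               "s1,1,10.5,448.3,-5,,",
               "s1,1,99.0,448.3,10,,"), f)
  expect_warning(pt2 <- read_peak_table(f), "malformed")
  expect_equal(nrow(pt2$features), 1)
  # missing column is named
  writeLines("sample_id,ms_level,rt_min,mz", f)
  expect_error(read_peak_table(f), "intensity")
  # empty file with header warns and returns empty
  writeLines("sample_id,ms_level,rt_min,mz,intensity,precursor_center,isolation_width",
             f)
  expect_warning(pt3 <- read_peak_table(f), "empty")
  expect_equal(nrow(pt3$features), 0)
  expect_error(read_peak_table("no/such/file.csv"), "not found")
})

test_that("peak tables round-trip through write_peak_table", {
  led <- tiny_panel()
  pt <- emit_peak_tables(led)
  f <- withr::local_tempfile(fileext = ".csv")
  s1 <- pt$features$sample_id[1]
  feats <- pt$features[pt$features$sample_id == s1, ]
  specs <- pt$spectra[pt$spectra$sample_id == s1, ]
  write_peak_table(feats, specs, f)
  back <- read_peak_table(f)
  expect_equal(nrow(back$features), nrow(feats))
  expect_equal(sort(back$features$mz), sort(feats$mz), tolerance = 1e-9)
  expect_equal(nrow(back$spectra), nrow(specs))
})
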