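test_that("calibration recovers the imaging model parameters", {
  # noise-free generator output: recovered gain within 1% of truth
  mf <- two_inlet_manifest(stock = 50)
  im <- imaging_model(gain = c(ch488 = 10), dark_offset = 100, noise_sd = 0,
                      illumination = "vignette", illumination_strength = 0.2)
  cal_frames <- render_calibration_sets(im, mf, n_frames = 3L,
                                        frame_dim = c(256L, 256L), seed = 9)
  cal <- fit_calibration(cal_frames, mf)
  expect_equal(unname(cal$dark["ch488"]), 100)  # exact on noise-free frames
  expect_lt(abs(cal$gain["ch488"] - 10) / 10, 0.01)
})

test_that("doubling the stock halves the fitted gain on the same images", {
  ex <- small_experiment()
  cal1 <- small_calibration()
  mf2 <- ex$manifest
  mf2$inlets$peg$species["PEG"] <- 100  # same frames, doubled stock
  cal2 <- fit_calibration(ex$calibration, mf2)
  expect_equal(unname(cal2$gain["ch488"] / cal1$gain["ch488"]), 0.5,
               tolerance = 1e-6)
})

test_that("a missing calibration set is a calibration error", {
  ex <- small_experiment()
  broken <- ex$calibration
  broken$dark <- NULL
  expect_error(fit_calibration(broken, ex$manifest),
               class = "dropsol_calibration_error")
})

test_that("composition inference recovers the generator truth", {
  ex <- small_experiment()
  rec <- small_records()
  comp <- infer_composition(rec, small_calibration())
  mt <- match_to_truth(rec, ex$truth)
  idx <- match(comp$droplet_id, mt$matches$droplet_id)
  tru <- ex$truth[mt$matches$truth_id[idx], ]
  # median absolute error below 3% of each species' stock
  expect_lt(median(abs(comp$PEG - tru$PEG), na.rm = TRUE), 0.03 * 50)
  expect_lt(median(abs(comp$protein - tru$protein), na.rm = TRUE), 0.03 * 10)
  # fractions conserve volume exactly after renormalisation
  fsum <- rowSums(comp[paste0("fraction_", names(ex$manifest$inlets))])
  expect_true(all(abs(fsum - 1) < 1e-9))
})

test_that("the noise-free round trip has negligible bias", {
  mf <- two_inlet_manifest(stock = 50)
  im <- imaging_model(gain = c(ch488 = 10), noise_sd = 0,
                      illumination = "vignette", illumination_strength = 0.2)
  pts <- sample_compositions(mf, 60L, ramps = list(peg = c(0.1, 0.5)),
                             seed = 21)
  rf <- render_frames(pts, rep(0L, 60L), im, mf, frame_dim = c(512L, 512L),
                      radius_range = c(10, 14), droplets_per_frame = 60L,
                      seed = 21)
  cal <- fit_calibration(render_calibration_sets(im, mf, n_frames = 2L,
                                                 frame_dim = c(512L, 512L),
                                                 seed = 22), mf)
  rec <- detect_frames(rf$frames)
  comp <- infer_composition(rec, cal)
  mt <- match_to_truth(rec, rf$truth)
  tru <- rf$truth[mt$matches$truth_id[match(comp$droplet_id,
                                            mt$matches$droplet_id)], ]
  expect_lt(abs(mean(comp$PEG - tru$PEG)), 0.01 * 50)
})

test_that("inference is invariant to rescaling gain and intensities together", {
  rec <- small_records()
  cal <- small_calibration()
  comp <- infer_composition(rec, cal)
  rec2 <- rec
  for (ch in names(cal$gain)) {
    for (st in c("mean_", "median_", "sd_"))
      rec2[[paste0(st, ch)]] <-
        (rec2[[paste0(st, ch)]] - ifelse(st == "sd_", 0, cal$dark[ch])) * 3 +
        ifelse(st == "sd_", 0, cal$dark[ch])
  }
  cal2 <- cal
  cal2$gain <- cal$gain * 3
  comp2 <- infer_composition(rec2, cal2)
  expect_equal(comp2$PEG, comp$PEG, tolerance = 1e-9)
  expect_equal(comp2$protein, comp$protein, tolerance = 1e-9)
})

test_that("negative and overshooting fractions are clipped and flagged", {
  ex <- small_experiment()
  cal <- small_calibration()
  rec <- small_records()[1:2, ]
  # force one droplet's PEG channel below dark (negative corrected signal)
  rec$median_ch488[1L] <- cal$dark["ch488"] - 10
  # and one beyond any physical fraction (sum > 1 + tol)
  rec$median_ch488[2L] <- cal$dark["ch488"] +
    2 * cal$gain["ch488"] * 50
  comp <- infer_composition(rec, cal)
  expect_true(comp$clipped[1L])
  expect_equal(comp$PEG[1L], 0)
  expect_true(comp$inconsistent[2L])
})
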