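test_that("sampled compositions conserve volume and dilute linearly", {
  mf <- two_inlet_manifest(stock = 50)
  pts <- sample_compositions(mf, 5L, ramps = list(peg = c(0.2, 0.2)),
                             seed = 1)
  expect_equal(pts$PEG, rep(10, 5))  # fraction 0.2 of a 50 w/v% stock

  mf3 <- droplet_manifest(
    inlets = list(
      buffer = list(channel = NA, species = numeric(0)),
      protein = list(channel = "ch647", species = c(protein = 10)),
      peg = list(channel = "ch488", species = c(PEG = 50))),
    channels = c(ch488 = 488, ch647 = 647))
  pts3 <- sample_compositions(mf3, 200L,
                              ramps = list(protein = c(0.3, 0.3),
                                           peg = c(0, 0.2)), seed = 2)
  sums <- rowSums(pts3[paste0("fraction_",
                              c("buffer", "protein", "peg"))])
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(pts3[paste0("fraction_",
                              c("buffer", "protein", "peg"))] >= 0))
})

test_that("a dense ramp covers its analytic envelope", {
  mf <- two_inlet_manifest(stock = 50)
  pts <- sample_compositions(mf, 1000L, ramps = list(peg = c(0, 0.6)),
                             seed = 3)
  # stratified ramp over fractions 0..0.6 of a 50 w/v% stock spans 0..30
  expect_lt(min(pts$PEG), 0.01 * 30)
  expect_gt(max(pts$PEG), 0.99 * 30)
})

test_that("a manifest with fewer than two inlets is rejected", {
  expect_error(droplet_manifest(inlets = list(buffer = list(channel = NA)),
                                channels = c(ch488 = 488)),
               class = "dropsol_config_error")
})

test_that("labels follow the logistic boundary model", {
  truth <- phase_truth(c0 = 5.7, noise_width = 0.5)
  at_boundary <- data.frame(PEG = rep(5.7, 4000), protein = 1)
  lab <- assign_labels(at_boundary, truth, seed = 7)
  # logistic midpoint: long-run aggregate fraction 0.5 +/- binomial error
  expect_lt(abs(mean(lab) - 0.5), 3 * sqrt(0.25 / 4000))

  sharp <- phase_truth(c0 = 5.7, noise_width = 1e-9)
  above <- data.frame(PEG = rep(6.2, 200), protein = 1)
  expect_true(all(assign_labels(above, sharp, seed = 8) == 1L))
  below <- data.frame(PEG = rep(5.2, 200), protein = 1)
  expect_true(all(assign_labels(below, sharp, seed = 9) == 0L))
})

test_that("binned empirical aggregate fraction matches the model probability", {
  truth <- phase_truth(c0 = 5.7, noise_width = 0.5)
  mf <- two_inlet_manifest(stock = 50)
  pts <- sample_compositions(mf, 4000L, ramps = list(peg = c(0, 0.3)),
                             seed = 11)
  lab <- assign_labels(pts, truth, seed = 12)
  p <- true_aggregation_probability(truth, pts)
  bins <- cut(p, seq(0, 1, 0.1), include.lowest = TRUE)
  for (b in levels(bins)) {
    idx <- bins == b
    if (sum(idx) < 50) next
    phat <- mean(lab[idx]); pbar <- mean(p[idx])
    expect_lt(abs(phat - pbar),
              4 * sqrt(pbar * (1 - pbar) / sum(idx)) + 1e-3)
  }
})

test_that("rendering follows the affine forward model", {
  mf <- two_inlet_manifest(stock = 2)
  im <- imaging_model(gain = c(ch488 = 10), dark_offset = 5, noise_sd = 0,
                      illumination = "flat")
  pts <- sample_compositions(mf, 1L, ramps = list(peg = c(1, 1)), seed = 1)
  rf <- render_frames(pts, labels = 0L, im, mf, frame_dim = c(64L, 64L),
                      radius_range = c(8, 8), droplets_per_frame = 1L,
                      seed = 1)
  fr <- rf$frames[[1L]][, , "ch488"]
  interior <- dropsol:::disk_pixels(rf$truth$center_row + 1,
                                    rf$truth$center_col + 1, 6, c(64L, 64L))
  # gain 10 x conc 2, illumination 1, dark 5, zero noise -> exactly 25
  expect_equal(unique(fr[cbind(interior$r, interior$c)]), 25)
  expect_equal(fr[1L, 1L], 5)  # background is the dark offset

  dark_pts <- sample_compositions(mf, 1L, ramps = list(peg = c(0, 0)),
                                  seed = 1)
  rf0 <- render_frames(dark_pts, labels = 0L, im, mf,
                       frame_dim = c(64L, 64L), radius_range = c(8, 8),
                       droplets_per_frame = 1L, seed = 1)
  expect_true(all(rf0$frames[[1L]] == 5))  # zero concentration everywhere
})

test_that("aggregated droplets are more inhomogeneous than mixed ones", {
  mf <- droplet_manifest(
    inlets = list(
      buffer = list(channel = NA, species = numeric(0)),
      protein = list(channel = "ch647", species = c(protein = 10))),
    channels = c(ch647 = 647))
  im <- imaging_model(gain = c(ch647 = 50), noise_sd = 2,
                      illumination = "flat")
  pts <- sample_compositions(mf, 40L, ramps = list(protein = c(0.1, 0.1)),
                             seed = 5)
  labs <- rep(c(0L, 1L), 20L)
  rf <- render_frames(pts, labs, im, mf, frame_dim = c(256L, 256L),
                      radius_range = c(10, 12), droplets_per_frame = 40L,
                      seed = 5)
  rec <- detect_frames(rf$frames)
  mt <- match_to_truth(rec, rf$truth)
  tl <- rf$truth$true_label[mt$matches$truth_id][
    match(rec$droplet_id, mt$matches$droplet_id)]
  cv <- rec$sd_ch647 / rec$mean_ch647
  expect_gt(min(cv[tl == 1], na.rm = TRUE), max(cv[tl == 0], na.rm = TRUE))
})

test_that("calibration sets encode dark, illumination and endpoints", {
  mf <- two_inlet_manifest(stock = 50)
  im0 <- imaging_model(gain = c(ch488 = 10), dark_offset = 100,
                       noise_sd = 0, illumination = "vignette",
                       illumination_strength = 0.2)
  cal <- render_calibration_sets(im0, mf, n_frames = 2L,
                                 frame_dim = c(128L, 128L), seed = 2)
  expect_true(all(cal$dark[[1L]] == 100))  # noise-free set C is pure dark
  # set B, dark-subtracted and max-normalised, recovers the stored field
  field <- illumination_matrix(im0, c(128L, 128L))
  flat <- cal$flat[[1L]][, , "ch488"] - 100
  expect_equal(flat / max(flat), field / max(field), tolerance = 1e-9)
  # set A endpoint droplets: intensity = gain x stock (+ dark) under the field
  ep <- cal$endpoint$peg[[1L]][, , "ch488"]
  expect_equal(max(ep), max(field) * 10 * 50 + 100, tolerance = 0.01)
})

test_that("identical seed and configuration reproduce the experiment", {
  a <- scenario_single_protein(n_droplets = 80L, seed = 123,
                               frame_dim = c(256L, 256L),
                               droplets_per_frame = 40L,
                               calibration_frames = 2L)
  b <- scenario_single_protein(n_droplets = 80L, seed = 123,
                               frame_dim = c(256L, 256L),
                               droplets_per_frame = 40L,
                               calibration_frames = 2L)
  spec_a <- attr(a$truth, "spec_centers"); spec_b <- attr(b$truth, "spec_centers")
  attr(a$truth, "spec_centers") <- NULL; attr(b$truth, "spec_centers") <- NULL
  expect_identical(a$truth, b$truth)
  expect_identical(a$frames, b$frames)
  expect_identical(spec_a, spec_b)
})

test_that("every rendered droplet appears in the truth table exactly once", {
  ex <- small_experiment()
  expect_equal(nrow(ex$truth), 600L)
  expect_equal(anyDuplicated(ex$truth$droplet_id), 0L)
  expect_equal(sort(unique(ex$truth$frame)), seq_along(ex$frames))
})
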