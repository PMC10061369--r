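test_that("inhomogeneity score behaves on constructed interiors", {
  expect_equal(as.numeric(inhomogeneity_score(rep(7, 200))), 0)
  # one pixel at 10x the mean among 100: spot fraction is 1/100
  px <- c(rep(100, 99), 1000)
  s <- inhomogeneity_score(px)
  expect_equal(attr(s, "spot_fraction"), 0.01)
  expect_equal(attr(s, "cv"), sd(px) / mean(px))
  expect_equal(as.numeric(s), max(sd(px) / mean(px), 10 * 0.01))
})

test_that("the score is scale-free and deterministic", {
  set.seed(31)
  px <- rnorm(300, 50, 5)
  px[1:6] <- 200
  s1 <- inhomogeneity_score(px)
  expect_equal(as.numeric(inhomogeneity_score(3.7 * px)), as.numeric(s1),
               tolerance = 1e-12)
  expect_identical(inhomogeneity_score(px), s1)
})

test_that("generator aggregates score above the mixed 99th percentile", {
  ex <- small_experiment()
  rec <- small_records()
  sc <- score_droplets(rec, small_calibration())
  tl <- truth_label_for_records(rec, ex)
  mixed_q99 <- quantile(sc$score[tl == 0], 0.99, na.rm = TRUE)
  expect_gt(min(sc$score[tl == 1], na.rm = TRUE), mixed_q99)
})

test_that("threshold selection separates two score populations", {
  set.seed(5)
  scores <- c(abs(rnorm(300, 0.05, 0.01)), abs(rnorm(200, 0.8, 0.2)))
  thr <- choose_threshold(scores)
  expect_equal(attr(thr, "method"), "otsu")
  expect_gt(thr, 0.05)
  expect_lt(thr, 0.8)
})

test_that("degenerate score sets fall back or error", {
  expect_equal(as.numeric(choose_threshold(rep(0.1, 100), fallback = 0.5)),
               0.5)
  expect_equal(attr(choose_threshold(rep(0.1, 100), fallback = 0.5),
                    "method"), "fallback")
  set.seed(6)
  expect_equal(attr(choose_threshold(abs(rnorm(200, 0.2, 0.03)),
                                     fallback = 0.4), "method"), "fallback")
  expect_error(choose_threshold(c(0.1, 0.2), fallback = NULL),
               class = "dropsol_threshold_error")
})

test_that("calls use a strict threshold and exclude low-signal droplets", {
  scored <- data.frame(droplet_id = 1:4,
                       score = c(0.5, 0.50001, 0.1, 2),
                       low_signal = c(FALSE, FALSE, TRUE, FALSE))
  calls <- call_droplets(scored, threshold = 0.5)
  expect_equal(calls$label, c("mixed", "aggregated", "aggregated"))
  expect_equal(attr(calls, "excluded"), c(low_signal = 1L))
  empty <- call_droplets(scored[0, ], 0.5)
  expect_equal(nrow(empty), 0L)
})

test_that("aggregate calls match the generator truth", {
  ex <- small_experiment()
  rec <- small_records()
  sc <- score_droplets(rec, small_calibration())
  thr <- choose_threshold(sc$score[!sc$low_signal], fallback = 0.5)
  calls <- call_droplets(sc, thr)
  tl <- truth_label_for_records(rec, ex)[match(calls$droplet_id,
                                               rec$droplet_id)]
  acc <- mean((calls$label == "aggregated") == (tl == 1), na.rm = TRUE)
  expect_gte(acc, 0.95)
  # prevalence consistent with the generator's label prevalence
  prev_hat <- mean(calls$label == "aggregated")
  prev_true <- mean(ex$truth$true_label)
  expect_lt(abs(prev_hat - prev_true),
            4 * sqrt(prev_true * (1 - prev_true) / nrow(calls)))
})

test_that("classification accuracy does not degrade with stronger specs", {
  accs <- vapply(c(1.5, 4), function(contrast) {
    ex <- scenario_single_protein(
      n_droplets = 250L, seed = 77, frame_dim = c(512L, 512L),
      calibration_frames = 2L,
      imaging = default_imaging(spec_contrast = contrast))
    rec <- filter_edge_and_merged(detect_frames(ex$frames), ex$frame_dim)
    cal <- fit_calibration(ex$calibration, ex$manifest)
    sc <- score_droplets(rec, cal)
    calls <- call_droplets(sc, choose_threshold(sc$score[!sc$low_signal],
                                                fallback = 0.5))
    tl <- truth_label_for_records(rec, ex)[match(calls$droplet_id,
                                                 rec$droplet_id)]
    mean((calls$label == "aggregated") == (tl == 1), na.rm = TRUE)
  }, numeric(1))
  expect_gte(accs[2L], accs[1L])
})
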