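# composition-level single-axis screen: PEG ramp against a latent boundary
peg_screen <- function(n, c0 = 5.7, noise_width = 0.5, seed = 1,
                       peg_frac = c(0, 0.3)) {
  mf <- two_inlet_manifest(stock = 50)
  pts <- sample_compositions(mf, n, ramps = list(peg = peg_frac),
                             seed = seed)
  truth <- phase_truth(c0 = c0, noise_width = noise_width)
  labels <- assign_labels(pts, truth, seed = seed + 1)
  list(points = pts[, "PEG", drop = FALSE], labels = labels)
}

test_that("a separable problem is fitted with training accuracy 1", {
  x <- data.frame(PEG = c(seq(0, 4, length.out = 60),
                          seq(8, 12, length.out = 60)))
  y <- rep(c(0L, 1L), each = 60L)
  m <- fit_phase_model(x, y, kernel = "linear")
  pred <- aggregation_probability(m, x) > 0.5
  expect_equal(mean(pred == (y == 1L)), 1)
})

test_that("single-class input errors and names the missing class", {
  x <- data.frame(PEG = runif(100, 5, 10))
  expect_error(fit_phase_model(x, rep(1L, 100)), "mixed",
               class = "dropsol_fit_error")
  expect_error(fit_phase_model(x, rep(0L, 100)), "aggregated",
               class = "dropsol_fit_error")
})

test_that("the fitted linear boundary normal aligns with the truth", {
  sim <- scenario_combo(slope_x = 0.02, slope_y = 0.02, render = FALSE,
                        n_droplets = 2000L, seed = 3)
  m <- fit_phase_model(sim$points[, c("additive_x", "additive_y")],
                       sim$labels, kernel = "linear")
  w <- linear_weights(m)
  # truth boundary x + y = const: normal along (1, 1)
  ang <- acos(abs(sum(w * c(1, 1))) / (sqrt(sum(w^2)) * sqrt(2))) * 180 / pi
  expect_lt(ang, 5)
})

test_that("poly2 beats linear on a curved (two-regime) truth", {
  mf <- two_inlet_manifest(stock = 50)
  truth <- phase_truth(c0 = 4, additive_slopes = c(NaCl = 0.03),
                       noise_width = 0.3,
                       breakpoints = list(NaCl = list(at = 300,
                                                      slope2 = 0)))
  set.seed(41)
  pts <- sample_compositions(mf, 3000L, ramps = list(peg = c(0, 0.4)),
                             seed = 41)
  pts$NaCl <- runif(3000L, 0, 700)
  labels <- assign_labels(pts, truth, seed = 42)
  cmp <- compare_kernels(pts[, c("PEG", "NaCl")], labels, seed = 43)
  expect_gt(cmp$loglik["poly2"], cmp$loglik["linear"])
  expect_equal(cmp$kernel, "poly2")
})

test_that("the probability surface is calibrated around the boundary", {
  sim <- peg_screen(3000L, seed = 51)
  m <- fit_phase_model(sim$points, sim$labels)
  sol <- relative_solubility(m, B = 60L, seed = 52)
  # p at the reported crossing is 0.5 by construction of the read-out
  p_at <- aggregation_probability(m, data.frame(PEG = sol$value))
  expect_lt(abs(as.numeric(p_at) - 0.5), 0.01)
  # deep mixed region and far-above-boundary region
  expect_lt(as.numeric(aggregation_probability(m, data.frame(PEG = 0.5))),
            0.1)
  expect_gt(as.numeric(aggregation_probability(m, data.frame(PEG = 14))),
            0.9)
  # extrapolation beyond the training range is flagged
  p_out <- aggregation_probability(m, data.frame(PEG = 40))
  expect_true(attr(p_out, "extrapolated"))
})

test_that("relative solubility recovers the latent boundary", {
  sim <- peg_screen(4000L, c0 = 5.7, seed = 61)
  m <- fit_phase_model(sim$points, sim$labels)
  sol <- relative_solubility(m, B = 60L, seed = 62)
  expect_lt(abs(sol$value - 5.7), 0.6)
  expect_gte(sol$sd, 0)
  expect_true(sol$band[1L] <= sol$value && sol$value <= sol$band[2L])
})

test_that("bootstrap uncertainty is stable across bootstrap seeds", {
  sim <- peg_screen(1500L, seed = 71)
  m <- fit_phase_model(sim$points, sim$labels)
  a <- relative_solubility(m, B = 80L, seed = 1)
  b <- relative_solubility(m, B = 80L, seed = 2)
  expect_identical(a$value, b$value)  # value is bootstrap-independent
  expect_lt(abs(a$sd - b$sd) / a$sd, 0.2)
})

test_that("an unbracketed boundary errors or censors as requested", {
  sim <- peg_screen(800L, c0 = 25, seed = 81, peg_frac = c(0, 0.2))
  # boundary far above the sampled range: almost everything stays mixed
  expect_error(fit_phase_model(sim$points, sim$labels),
               class = "dropsol_fit_error")
  sim2 <- peg_screen(800L, c0 = 10.5, seed = 82, peg_frac = c(0, 0.2))
  m2 <- fit_phase_model(sim2$points, sim2$labels, min_per_class = 10L)
  expect_error(relative_solubility(m2, B = 10L, seed = 1),
               class = "dropsol_unbracketed_error")
  cens <- relative_solubility(m2, B = 10L, seed = 1,
                              on_unbracketed = "censor")
  expect_equal(cens$censored, "above")
  expect_true(is.na(cens$value))
})

test_that("solubility curves are monotone and cross 0.5 once", {
  sim <- peg_screen(2000L, seed = 91)
  m <- fit_phase_model(sim$points, sim$labels)
  grid <- seq(0, 15, by = 0.1)
  cur <- solubility_curve(m, grid)
  expect_true(attr(cur, "monotone"))  # linear kernel: raw curve monotone
  expect_true(all(cur$p >= 0 & cur$p <= 1))
  crossings <- sum(diff(cur$p_smooth >= 0.5) == 1)
  expect_equal(crossings, 1L)
  expect_lt(cur$p[1L], 0.5)
  expect_gt(cur$p[nrow(cur)], 0.5)
})

test_that("the true boundary falls inside mean +/- 2 sd in most replicates", {
  hits <- 0L; runs <- 20L
  for (r in seq_len(runs)) {
    sim <- peg_screen(1200L, c0 = 5.7, seed = 100 + r)
    m <- fit_phase_model(sim$points, sim$labels)
    sol <- relative_solubility(m, B = 30L, seed = 200 + r)
    if (abs(sol$value - 5.7) <= 2 * sol$sd) hits <- hits + 1L
  }
  expect_gte(hits, 0.9 * runs)
})
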