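test_that("noiseless linear input reproduces the generating slope exactly", {
  conc <- c(0, 100, 200, 300, 400, 500)
  screen <- data.frame(conc = conc, solubility = 7.3 + 0.02 * conc,
                       sd = rep(0.1, 6))
  res <- additive_slope(screen, "NaCl")
  expect_equal(res$slope, 0.02, tolerance = 1e-12)
  expect_equal(res$intercept, 7.3, tolerance = 1e-10)
  expect_true(res$ci95[1L] <= res$slope && res$slope <= res$ci95[2L])
})

test_that("flat screens give slope zero and no breakpoint", {
  screen <- data.frame(conc = seq(0, 500, 100),
                       solubility = rep(7.3, 6), sd = rep(0.1, 6))
  res <- additive_slope(screen, two_regime = TRUE)
  expect_equal(res$slope, 0, tolerance = 1e-12)
  expect_null(res$breakpoint)
})

test_that("too few levels is an insufficient-data error", {
  screen <- data.frame(conc = c(0, 100), solubility = c(7, 9),
                       sd = c(0.1, 0.1))
  expect_error(additive_slope(screen),
               class = "dropsol_insufficient_data_error")
  screen4 <- data.frame(conc = seq(0, 300, 100),
                        solubility = 7 + 0.01 * seq(0, 300, 100),
                        sd = rep(0.1, 4))
  expect_error(additive_slope(screen4, two_regime = TRUE),
               class = "dropsol_insufficient_data_error")
})

test_that("the two-regime fit locates the salting-in breakpoint", {
  # boundary kinks at 350 mM: slope 0.020 then 0.0023 %/mM
  conc <- seq(0, 700, by = 100)
  sol <- 7.3 + 0.020 * pmin(conc, 350) + 0.0023 * pmax(conc - 350, 0)
  set.seed(8)
  screen <- data.frame(conc = conc, solubility = sol + rnorm(8, 0, 0.05),
                       sd = rep(0.08, 8))
  res <- additive_slope(screen, "NaCl", two_regime = TRUE)
  expect_false(is.null(res$breakpoint))
  expect_lte(abs(res$breakpoint - 350), 100)  # within one level spacing
  expect_equal(res$slope, 0.020, tolerance = 0.25)
  expect_lt(res$second_slope, 0.5 * res$slope)
})

test_that("equal per-mM effects give a combo slope of -1", {
  sim <- scenario_combo(slope_x = 0.02, slope_y = 0.02, render = FALSE,
                        n_droplets = 3000L, seed = 5)
  m <- fit_phase_model(sim$points[, c("additive_x", "additive_y")],
                       sim$labels, kernel = "linear")
  cs <- combo_slope(m)
  expect_lt(abs(cs$slope + 1), 0.1)
  expect_equal(cs$interpretation, "equal")
})

test_that("a 3.4:1 effectiveness ratio is recovered from the boundary", {
  sim <- scenario_combo(slope_x = 0.068, slope_y = 0.02, x_max = 150,
                        y_max = 500, render = FALSE, n_droplets = 3000L,
                        seed = 6)
  m <- fit_phase_model(sim$points[, c("additive_x", "additive_y")],
                       sim$labels, kernel = "linear")
  cs <- combo_slope(m)
  expect_lt(abs(cs$slope - (-3.4)) / 3.4, 0.15)
  expect_equal(cs$interpretation, "x_more_effective")
})

test_that("combo slopes are antisymmetric under axis swap", {
  sim <- scenario_combo(slope_x = 0.05, slope_y = 0.02, x_max = 200,
                        y_max = 500, render = FALSE, n_droplets = 3000L,
                        seed = 7)
  pts <- sim$points[, c("additive_x", "additive_y")]
  m_xy <- fit_phase_model(pts, sim$labels, kernel = "linear")
  m_yx <- fit_phase_model(pts[, c("additive_y", "additive_x")], sim$labels,
                          kernel = "linear")
  s_xy <- combo_slope(m_xy)$slope
  s_yx <- combo_slope(m_yx)$slope
  expect_equal(s_xy, 1 / s_yx, tolerance = 1e-6)
  expect_equal(combo_slope(m_xy)$interpretation, "x_more_effective")
  expect_equal(combo_slope(m_yx)$interpretation, "y_more_effective")
})

test_that("an ineffective additive takes the axis-parallel branch", {
  sim <- scenario_combo(slope_x = 0.03, slope_y = 0, x_max = 350,
                        y_max = 500, render = FALSE, n_droplets = 4000L,
                        seed = 8)
  m <- fit_phase_model(sim$points[, c("additive_x", "additive_y")],
                       sim$labels, kernel = "linear")
  cs <- combo_slope(m, axis_tol = 0.05)
  expect_true(is.infinite(cs$slope) || abs(cs$slope) > 20)
  expect_equal(cs$interpretation, "x_more_effective")
})

test_that("area-under-curve comparison ranks excipients", {
  conc <- seq(0, 3, by = 0.5)
  curves <- list(
    polysorbate80 = data.frame(conc = conc, solubility = 7.3 + 1.4 * conc),
    polysorbate20 = data.frame(conc = conc, solubility = 7.3 + 0.56 * conc))
  tab <- auc_compare(curves)
  expect_equal(tab$additive[1L], "polysorbate80")
  # linear curves: AUC ratio equals the slope ratio 1.4 / 0.56 = 2.5
  expect_equal(tab$auc[1L] / tab$auc[2L], 2.5, tolerance = 1e-9)

  same <- list(a = curves[[1L]], b = curves[[1L]])
  tab2 <- auc_compare(same)
  expect_true(all(tab2$tied))
  expect_equal(tab2$additive, c("a", "b"))  # alphabetical tie-break

  zero <- list(a = curves[[1L]],
               none = data.frame(conc = conc, solubility = rep(7.3, 7)))
  expect_equal(auc_compare(zero)$auc[2L], 0)
})

test_that("additive AUCs are additive for linear effects", {
  conc <- seq(0, 100, 20)
  a <- data.frame(conc = conc, solubility = 5 + 0.03 * conc)
  b <- data.frame(conc = conc, solubility = 5 + 0.01 * conc)
  ab <- data.frame(conc = conc, solubility = 5 + 0.04 * conc)
  tab <- auc_compare(list(a = a, b = b, ab = ab))
  auc <- setNames(tab$auc, tab$additive)
  expect_equal(unname(auc["ab"]), unname(auc["a"] + auc["b"]),
               tolerance = 1e-9)
})

test_that("non-overlapping concentration ranges are a range error", {
  expect_error(auc_compare(list(
    a = data.frame(conc = 0:3, solubility = 1:4),
    b = data.frame(conc = 10:13, solubility = 1:4))),
    class = "dropsol_range_error")
})

test_that("condition ranking computes pairwise z-scores", {
  mk <- function(v, s, cens = NA_character_)
    structure(list(value = v, sd = s, censored = cens, n_droplets = 1000L,
                   precipitant = "PEG"), class = "solubility_result")
  rk <- rank_conditions(list(pH4 = mk(9.7, 0.3), pH5 = mk(6.7, 0.4)))
  expect_equal(rk$table$condition, c("pH4", "pH5"))
  expect_equal(unname(rk$z["pH4", "pH5"]), 6, tolerance = 1e-9)
  expect_true(rk$table$significant_vs_next[1L])

  tie <- rank_conditions(list(a = mk(5, 0.2), b = mk(5, 0.2)))
  expect_equal(unname(tie$z["a", "b"]), 0)
  expect_false(tie$table$significant_vs_next[1L])

  cens <- rank_conditions(list(pH5 = mk(6.7, 0.4),
                               pH9 = mk(NA_real_, NA_real_, "above"),
                               pH4 = mk(9.7, 0.3)))
  expect_equal(cens$table$condition[1L], "pH9")  # censored above ranks first
  expect_equal(cens$table$censored[1L], "above")
})
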