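#' Per-additive solubility slope, optionally with two regimes
#'
#' Fits relative solubility (w/v \% precipitant) against additive
#' concentration (mM) by weighted least squares with weights
#' \code{1/sd^2}. The slope states how much precipitant the relative
#' solubility gains per mM of additive. With \code{two_regime = TRUE} a
#' continuous two-segment line is also fitted, its breakpoint chosen by
#' grid search over the interior concentration levels and accepted only
#' when the residual sum of squares improves enough to pay a one-parameter
#' penalty — the salting-in/salting-out behaviour of NaCl, where the slope
#' collapses beyond a transition concentration.
#'
#' @param screen data frame with columns \code{conc} (mM),
#'   \code{solubility} (w/v \%), and optionally \code{sd} (w/v \%; if
#'   absent or any nonpositive, the fit is unweighted).
#' @param additive additive name carried through to the result.
#' @param two_regime try the two-segment fit (needs >= 5 levels).
#' @return object of class \code{slope_result}: \code{slope},
#'   \code{intercept}, \code{ci95}, and (if a breakpoint was accepted)
#'   \code{breakpoint} and \code{second_slope}.
#' @export
additive_slope <- function(screen, additive = "additive",
                           two_regime = FALSE) {
  need <- if (two_regime) 5L else 3L
  if (length(unique(screen$conc)) < need)
    stop_dropsol(sprintf("need >= %d concentration levels, have %d", need,
                         length(unique(screen$conc))),
                 "dropsol_insufficient_data_error")
  w <- if (!is.null(screen$sd) && all(is.finite(screen$sd)) &&
           all(screen$sd > 0)) 1 / screen$sd^2 else rep(1, nrow(screen))
  f1 <- lm(solubility ~ conc, data = screen, weights = w)
  n <- nrow(screen)
  rss1 <- sum(w * resid(f1)^2)
  score1 <- n * log(max(rss1, 1e-12) / n) + 2 * 2
  out <- list(additive = additive,
              slope = unname(coef(f1)["conc"]),
              intercept = unname(coef(f1)["(Intercept)"]),
              ci95 = unname(suppressWarnings(confint(f1))["conc", ]),
              breakpoint = NULL, second_slope = NULL, fit = f1)
  if (two_regime) {
    levels <- sort(unique(screen$conc))
    cand <- levels[-c(1L, length(levels))]
    best <- NULL
    for (b in cand) {
      d <- screen; d$hinge <- pmax(d$conc - b, 0)
      f2 <- lm(solubility ~ conc + hinge, data = d, weights = w)
      rss2 <- sum(w * resid(f2)^2)
      if (is.null(best) || rss2 < best$rss) best <- list(fit = f2, rss = rss2,
                                                         b = b)
    }
    score2 <- n * log(max(best$rss, 1e-12) / n) + 2 * 3
    if (score2 < score1) {
      cf <- coef(best$fit)
      out$slope <- unname(cf["conc"])
      out$intercept <- unname(cf["(Intercept)"])
      out$ci95 <- unname(suppressWarnings(confint(best$fit))["conc", ])
      out$breakpoint <- best$b
      out$second_slope <- unname(cf["conc"] + cf["hinge"])
      out$fit <- best$fit
    }
  }
  structure(out, class = "slope_result")
}

#' @export
print.slope_result <- function(x, ...) {
  cat(sprintf("%s: %.4g %%/mM (95%% CI %.4g to %.4g)\n", x$additive, x$slope,
              x$ci95[1L], x$ci95[2L]))
  if (!is.null(x$breakpoint))
    cat(sprintf("  second regime beyond %g mM: %.4g %%/mM\n", x$breakpoint,
                x$second_slope))
  invisible(x)
}

#' Boundary slope of a two-excipient phase diagram
#'
#' For a linear-kernel phase model fitted on the plane of two additives (at
#' fixed protein and precipitant), the boundary slope dy/dx is
#' \code{-(w_x / w_y)} from the boundary-normal weights in raw mM units.
#' A slope of -1 means the two compounds are equally capable of improving
#' solubility per mM; below -1 the x-axis compound is more efficient, above
#' -1 the y-axis compound is. A boundary parallel to an axis (one additive
#' without effect) is reported symbolically as an infinite slope.
#'
#' @param model linear-kernel [fit_phase_model()] with exactly two free
#'   features.
#' @param additive_x,additive_y feature names; default to the model's first
#'   and second feature.
#' @param tol half-width of the "equally effective" band around -1.
#' @param axis_tol relative weight below which the boundary is declared
#'   axis-parallel.
#' @return object of class \code{combo_slope}: \code{slope},
#'   \code{interpretation} (\code{equal}, \code{x_more_effective},
#'   \code{y_more_effective}), \code{dominant} (NA, or the only effective
#'   axis).
#' @export
combo_slope <- function(model, additive_x = NULL, additive_y = NULL,
                        tol = 0.1, axis_tol = 1e-3) {
  w <- linear_weights(model)
  additive_x <- additive_x %||% model$features[1L]
  additive_y <- additive_y %||% model$features[2L]
  if (!all(c(additive_x, additive_y) %in% names(w)))
    stop_dropsol("additive_x/additive_y must be model features",
                 "dropsol_query_error")
  wx <- w[[additive_x]]; wy <- w[[additive_y]]
  wmax <- max(abs(wx), abs(wy))
  if (abs(wy) < axis_tol * wmax) {
    return(structure(list(additive_x = additive_x, additive_y = additive_y,
                          slope = -Inf, interpretation = "x_more_effective",
                          dominant = additive_x), class = "combo_slope"))
  }
  if (abs(wx) < axis_tol * wmax) {
    return(structure(list(additive_x = additive_x, additive_y = additive_y,
                          slope = 0, interpretation = "y_more_effective",
                          dominant = additive_y), class = "combo_slope"))
  }
  slope <- -(wx / wy)
  interp <- if (abs(slope + 1) <= tol) "equal"
  else if (slope < -1 - tol) "x_more_effective"
  else "y_more_effective"
  structure(list(additive_x = additive_x, additive_y = additive_y,
                 slope = unname(slope), interpretation = interp,
                 dominant = NA_character_),
            class = "combo_slope")
}

#' @export
print.combo_slope <- function(x, ...) {
  cat(sprintf("combo slope %s/%s: %.3g (%s)\n", x$additive_y, x$additive_x,
              x$slope, x$interpretation))
  invisible(x)
}

#' Compare excipients by area under their solubility curves
#'
#' Quantitative excipient comparison by the area between each
#' solubility-vs-concentration curve and its zero-additive baseline, over
#' the concentration range the curves share (trapezoidal rule). Ranks
#' descend by area; ties are flagged and broken alphabetically.
#'
#' @param curves named list of data frames with columns \code{conc} (mM)
#'   and \code{solubility} (w/v \%), one per additive.
#' @param tie_tol absolute area difference treated as a tie.
#' @return data frame: \code{additive}, \code{auc}, \code{rank},
#'   \code{tied}.
#' @export
auc_compare <- function(curves, tie_tol = 1e-8) {
  if (length(curves) < 2L)
    stop_dropsol("need >= 2 additives to compare", "dropsol_config_error")
  lo <- max(vapply(curves, function(d) min(d$conc), numeric(1)))
  hi <- min(vapply(curves, function(d) max(d$conc), numeric(1)))
  if (lo >= hi)
    stop_dropsol("additive concentration ranges do not overlap",
                 "dropsol_range_error")
  auc <- vapply(names(curves), function(nm) {
    d <- curves[[nm]]
    grid <- sort(unique(c(lo, hi, d$conc[d$conc >= lo & d$conc <= hi])))
    v <- approx(d$conc, d$solubility, xout = grid)$y
    trapz(grid, v - v[1L])
  }, numeric(1))
  ord <- order(-auc, names(curves))
  out <- data.frame(additive = names(curves)[ord], auc = unname(auc[ord]),
                    rank = seq_along(auc))
  out$tied <- vapply(seq_len(nrow(out)), function(i)
    any(abs(out$auc[i] - out$auc[-i]) <= tie_tol), logical(1))
  out
}

#' Rank screening conditions by relative solubility
#'
#' Orders conditions (pH values, protein variants, ...) by relative
#' solubility and computes pairwise z-scores
#' \code{z = (v1 - v2) / sqrt(sd1^2 + sd2^2)}; a difference with
#' \code{|z| >= 2} is flagged significant. Censored conditions — screens
#' whose boundary was not bracketed by the sampled precipitant range — are
#' placed above all measured values when censored \code{"above"} (their
#' solubility exceeds everything measured) and below when \code{"below"},
#' and carry no z-scores.
#'
#' @param results named list of [relative_solubility()] results.
#' @param z_significant significance threshold on |z|.
#' @return list with \code{table} (condition, value, sd, censored, rank,
#'   significant_vs_next) and \code{z} (pairwise matrix over measured
#'   conditions).
#' @export
rank_conditions <- function(results, z_significant = 2) {
  if (length(results) < 2L)
    stop_dropsol("need >= 2 conditions", "dropsol_config_error")
  df <- data.frame(
    condition = names(results),
    value = vapply(results, function(r) r$value, numeric(1)),
    sd = vapply(results, function(r) r$sd, numeric(1)),
    censored = vapply(results, function(r) as.character(r$censored),
                      character(1)))
  key <- ifelse(!is.na(df$censored) & df$censored == "above", Inf,
                ifelse(!is.na(df$censored) & df$censored == "below", -Inf,
                       df$value))
  df <- df[order(-key), ]
  df$rank <- seq_len(nrow(df))
  meas <- df[is.na(df$censored), ]
  z <- matrix(NA_real_, nrow(meas), nrow(meas),
              dimnames = list(meas$condition, meas$condition))
  for (i in seq_len(nrow(meas))) for (j in seq_len(nrow(meas)))
    if (i != j)
      z[i, j] <- (meas$value[i] - meas$value[j]) /
        sqrt(meas$sd[i]^2 + meas$sd[j]^2)
  df$significant_vs_next <- c(vapply(seq_len(nrow(df) - 1L), function(i) {
    a <- df$condition[i]; b <- df$condition[i + 1L]
    if (a %in% rownames(z) && b %in% rownames(z))
      abs(z[a, b]) >= z_significant else NA
  }, logical(1)), NA)
  rownames(df) <- NULL
  list(table = df, z = z)
}
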