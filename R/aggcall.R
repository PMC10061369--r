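#' Intra-droplet inhomogeneity score
#'
#' Aggregates are detected from inhomogeneous intensity inside a droplet:
#' protein precipitates show up as bright specs in the protein channel while
#' a mixed solution is uniform. The score combines two scale-free statistics
#' over the dark-corrected interior pixels: the coefficient of variation
#' \code{CV = sd/mean} and the bright-spot fraction (share of pixels above
#' \code{mean + k * sd}), weighted by \code{w}:
#' \code{score = max(CV, w * spot_fraction)}. Both components are invariant
#' to multiplying all pixels by a positive constant, so the score does not
#' depend on absolute brightness.
#'
#' @param pixels numeric vector of dark-corrected interior pixel intensities
#'   (protein channel).
#' @param k spot threshold in sd units (default 3).
#' @param w spot-fraction weight (default 10).
#' @return nonnegative score (0 for a perfectly uniform interior), with
#'   attributes \code{"cv"} and \code{"spot_fraction"} exposing the two
#'   components.
#' @export
inhomogeneity_score <- function(pixels, k = 3, w = 10) {
  m <- mean(pixels)
  if (!is.finite(m) || m <= 0)
    return(structure(0, cv = 0, spot_fraction = 0))
  s <- sd(pixels)
  if (!is.finite(s) || s == 0)
    return(structure(0, cv = 0, spot_fraction = 0))
  cv <- s / m
  spot <- mean(pixels > m + k * s)
  structure(max(cv, w * spot), cv = cv, spot_fraction = spot)
}

#' Score every droplet record in the protein channel
#'
#' @param records droplet records carrying a \code{pixels} list-column.
#' @param calib calibration model (supplies the protein-channel dark level);
#'   may be \code{NULL} for already-corrected pixels.
#' @param k,w score parameters, see [inhomogeneity_score()].
#' @param min_signal mean corrected intensity below which a droplet is
#'   flagged \code{low_signal} (no protein, no dye) and scored 0.
#' @return data frame: \code{droplet_id}, \code{score}, \code{low_signal}.
#' @export
score_droplets <- function(records, calib = NULL, k = 3, w = 10,
                           min_signal = 5) {
  manifest <- if (!is.null(calib)) calib$manifest else NULL
  ch <- if (!is.null(manifest)) protein_channel(manifest) else
    colnames(records$pixels[[1L]])[ncol(records$pixels[[1L]])]
  dark <- if (!is.null(calib)) calib$dark[ch] else 0
  score <- numeric(nrow(records))
  low <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    px <- records$pixels[[i]][, ch] - dark
    if (mean(px) <= min_signal) {
      low[i] <- TRUE
    } else {
      score[i] <- inhomogeneity_score(px, k = k, w = w)
    }
  }
  data.frame(droplet_id = records$droplet_id, score = score,
             low_signal = low)
}

# 1-D Otsu: threshold maximising between-class variance of a score vector
otsu_threshold_1d <- function(z, levels = 256L) {
  br <- seq(min(z), max(z), length.out = levels + 1L)
  h <- tabulate(findInterval(z, br, rightmost.closed = TRUE), nbins = levels)
  p <- h / sum(h)
  mids <- (head(br, -1L) + tail(br, -1L)) / 2
  w0 <- cumsum(p); w1 <- 1 - w0
  mu0 <- cumsum(p * mids) / pmax(w0, 1e-12)
  mu_t <- sum(p * mids)
  mu1 <- (mu_t - cumsum(p * mids)) / pmax(w1, 1e-12)
  bc <- w0 * w1 * (mu0 - mu1)^2
  bc[w0 < 1e-12 | w1 < 1e-12] <- -Inf
  mids[which.max(bc)]
}

# dip-style bimodality check + valley refinement: locate the kernel-density
# minimum between the two cluster medians; NA when there is no clear valley
# (density at the minimum not well below the density at both medians).
density_valley <- function(z, split, valley_ratio = 0.7) {
  if (sd(z) == 0) return(NA_real_)
  lo <- z[z <= split]; hi <- z[z > split]
  if (length(lo) < 3L || length(hi) < 3L) return(NA_real_)
  m0 <- median(lo); m1 <- median(hi)
  d <- stats::density(z, n = 512L)
  inside <- d$x > m0 & d$x < m1
  if (!any(inside)) return(NA_real_)
  fmin_i <- which(inside)[which.min(d$y[inside])]
  f_med <- approx(d$x, d$y, xout = c(m0, m1))$y
  if (!is.finite(d$y[fmin_i]) ||
      d$y[fmin_i] >= valley_ratio * min(f_med)) return(NA_real_)
  d$x[fmin_i]
}

#' Choose the mixed/aggregated score threshold for an experiment
#'
#' Otsu's between-class-variance maximiser on \code{log(1 + score)}
#' proposes the split; the threshold is then placed at the kernel-density
#' minimum between the two cluster medians (the Otsu split alone sits
#' inside the broad aggregated cluster and miscalls its lower tail). When
#' the histogram shows no density valley there, the configured fallback is
#' used instead. One threshold per experiment, not per frame, to avoid
#' small-n instability.
#'
#' @param scores inhomogeneity scores of all non-flagged droplets.
#' @param fallback threshold to use when the histogram is unimodal, or when
#'   fewer than \code{min_scores} scores are available.
#' @param min_scores minimum sample size for automatic thresholding.
#' @return threshold on the score scale; attribute \code{"method"} is
#'   \code{"otsu"} or \code{"fallback"}.
#' @export
choose_threshold <- function(scores, fallback = NULL, min_scores = 50L) {
  if (length(scores) < min_scores) {
    if (is.null(fallback))
      stop_dropsol(sprintf(
        "only %d scores (min %d) and no fallback threshold configured",
        length(scores), min_scores), "dropsol_threshold_error")
    return(structure(fallback, method = "fallback"))
  }
  z <- log1p(scores)
  split <- if (diff(range(z)) < 1e-12) NA_real_ else otsu_threshold_1d(z)
  valley <- if (is.na(split)) NA_real_ else density_valley(z, split)
  if (is.na(valley)) {
    if (is.null(fallback))
      stop_dropsol("unimodal score histogram and no fallback threshold",
                   "dropsol_threshold_error")
    return(structure(fallback, method = "fallback"))
  }
  structure(expm1(valley), method = "otsu")
}

#' Call droplets mixed or aggregated
#'
#' A droplet is called \code{aggregated} iff its score strictly exceeds the
#' threshold; a tie is called \code{mixed} (conservative toward solubility).
#' Low-signal droplets are excluded, with the count recorded in attribute
#' \code{"excluded"}.
#'
#' @param scored output of [score_droplets()].
#' @param threshold score threshold (e.g. from [choose_threshold()]).
#' @return data frame: \code{droplet_id}, \code{score}, \code{label}
#'   (\code{"mixed"}/\code{"aggregated"}), \code{threshold_used}.
#' @export
call_droplets <- function(scored, threshold) {
  keep <- !scored$low_signal
  s <- scored$score[keep]
  out <- data.frame(droplet_id = scored$droplet_id[keep],
                    score = s,
                    label = if (length(s))
                      ifelse(s > threshold, "aggregated", "mixed")
                    else character(0),
                    threshold_used = rep(as.numeric(threshold), length(s)))
  attr(out, "excluded") <- c(low_signal = sum(!keep))
  out
}
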