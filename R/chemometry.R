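#' Fit the three-part intensity calibration
#'
#' Converts the three calibration image sets into a per-channel correction
#' model: the dark level is the per-channel median of the empty frames
#' (set C); the flat field is the smoothed, dark-subtracted mean of the
#' homogeneous-dye frames (set B), max-normalised to 1; the endpoint gain of
#' each barcoded channel is the dark- and flatfield-corrected mean interior
#' intensity of droplets containing only that inlet's solution (set A),
#' divided by the tracer stock concentration — a linear, zero-intercept
#' intensity model, the standard dilute-dye assumption.
#'
#' @param calibration list with elements \code{endpoint} (named list:
#'   inlet -> list of frames), \code{flat} and \code{dark} (lists of
#'   frames), as produced by [render_calibration_sets()] or read from disk.
#' @param manifest the [droplet_manifest()] of the screen.
#' @param detect detection parameters for the endpoint droplets.
#' @param flat_sigma_frac Gaussian smoothing sigma for the flat field, as a
#'   fraction of the short frame side (suppresses droplet residue in set B).
#' @return object of class \code{calibration_model}: per-channel \code{dark},
#'   per-pixel \code{flatfield} array in (0, 1], per-channel \code{gain}
#'   (intensity per concentration unit) and the inlet/stock wiring.
#' @export
fit_calibration <- function(calibration, manifest,
                            detect = detect_params(),
                            flat_sigma_frac = 0.05) {
  for (set in c("endpoint", "flat", "dark"))
    if (is.null(calibration[[set]]) || !length(calibration[[set]]))
      stop_dropsol(sprintf("calibration set '%s' is missing", set),
                   "dropsol_calibration_error")
  chans <- names(manifest$channels)
  dark <- vapply(seq_along(chans), function(k)
    median(unlist(lapply(calibration$dark, function(a) a[, , k]))),
    numeric(1))
  names(dark) <- chans

  dims <- dim(calibration$flat[[1L]])[1:2]
  sigma <- flat_sigma_frac * min(dims)
  flat <- array(1, c(dims, length(chans)), dimnames = list(NULL, NULL, chans))
  for (k in seq_along(chans)) {
    m <- Reduce(`+`, lapply(calibration$flat, function(a) a[, , k])) /
      length(calibration$flat) - dark[k]
    m <- as.matrix(EBImage::gblur(EBImage::Image(m), sigma = sigma))
    m <- pmax(m, 1e-6)
    flat[, , k] <- m / max(m)
  }

  gain <- setNames(rep(NA_real_, length(chans)), chans)
  inlet_of_channel <- setNames(rep(NA_character_, length(chans)), chans)
  for (nm in barcoded_inlets(manifest)) {
    ch <- inlet_channel(manifest, nm)
    frames <- calibration$endpoint[[nm]]
    if (is.null(frames))
      stop_dropsol(sprintf("no endpoint frames for inlet '%s'", nm),
                   "dropsol_calibration_error")
    recs <- detect_frames(frames, detect)
    recs <- filter_edge_and_merged(recs, dims, detect$min_circularity)
    if (!nrow(recs))
      stop_dropsol(sprintf("no endpoint droplets detected for inlet '%s'", nm),
                   "dropsol_calibration_error")
    ff <- flat[cbind(round(recs$center_row) + 1L,
                     round(recs$center_col) + 1L,
                     match(ch, chans))]
    corr <- (recs[[paste0("median_", ch)]] - dark[ch]) / ff
    endpoint_intensity <- mean(corr)
    if (!is.finite(endpoint_intensity) || endpoint_intensity <= 0)
      stop_dropsol(sprintf("degenerate endpoint intensity for inlet '%s'", nm),
                   "dropsol_calibration_error")
    gain[ch] <- endpoint_intensity / tracer_stock(manifest, nm)
    inlet_of_channel[ch] <- nm
  }
  structure(list(dark = dark, flatfield = flat, gain = gain,
                 inlet_of_channel = inlet_of_channel,
                 manifest = manifest, frame_dim = dims),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("calibration_model\n  dark:",
      paste(sprintf("%s=%.2f", names(x$dark), x$dark), collapse = ", "),
      "\n  gain:",
      paste(sprintf("%s=%.3f", names(x$gain), x$gain), collapse = ", "), "\n")
  invisible(x)
}

# dark- and flatfield-corrected per-droplet channel intensities (n x nchan);
# composition inference uses the interior median, which is robust to the
# bright specs that raise the protein-channel mean of aggregated droplets
corrected_intensities <- function(records, calib, stat = "median") {
  chans <- names(calib$dark)
  out <- matrix(NA_real_, nrow(records), length(chans),
                dimnames = list(NULL, chans))
  ir <- pmin(pmax(round(records$center_row) + 1L, 1L), calib$frame_dim[1L])
  ic <- pmin(pmax(round(records$center_col) + 1L, 1L), calib$frame_dim[2L])
  for (k in seq_along(chans)) {
    ff <- calib$flatfield[cbind(ir, ic, k)]
    col <- paste0(stat, "_", chans[k])
    if (!col %in% names(records)) col <- paste0("mean_", chans[k])
    out[, k] <- (records[[col]] - calib$dark[k]) / ff
  }
  out
}

#' Infer droplet compositions from calibrated intensities
#'
#' For each barcoded inlet, the corrected channel intensity (the interior
#' median, robust to the bright specs of aggregated droplets) divided by the
#' endpoint gain gives the tracer concentration, and division by the tracer
#' stock gives the inlet's volume fraction. The unbarcoded buffer inlet takes
#' \code{1 - sum(fractions)}. Negative fractions are clipped to zero (flag
#' \code{clipped}); droplets whose barcoded fractions exceed 1 beyond the
#' tolerance are flagged \code{inconsistent} and meant to be excluded
#' downstream; small excesses are renormalised so fractions sum to exactly 1.
#' Species concentrations are fractions times stocks, summed over inlets.
#'
#' @param records droplet records from [detect_frames()].
#' @param calib a [fit_calibration()] model.
#' @param tol fraction-sum tolerance (default 0.05).
#' @return data frame keyed by \code{droplet_id}: \code{fraction_<inlet>}
#'   columns, one column per species, logical \code{clipped} and
#'   \code{inconsistent} flags.
#' @export
infer_composition <- function(records, calib, tol = 0.05) {
  manifest <- calib$manifest
  corr <- corrected_intensities(records, calib)
  inl <- names(manifest$inlets)
  frac <- matrix(0, nrow(records), length(inl),
                 dimnames = list(NULL, inl))
  for (nm in barcoded_inlets(manifest)) {
    ch <- inlet_channel(manifest, nm)
    frac[, nm] <- corr[, ch] / (calib$gain[ch] * tracer_stock(manifest, nm))
  }
  clipped <- rowSums(frac < 0) > 0
  frac[frac < 0] <- 0
  s <- rowSums(frac)
  inconsistent <- s > 1 + tol
  over <- s > 1 & !inconsistent
  frac[over, ] <- frac[over, , drop = FALSE] / s[over]
  clipped <- clipped | over
  buf <- buffer_inlet(manifest)
  frac[, buf] <- pmax(1 - rowSums(frac[, setdiff(inl, buf), drop = FALSE]), 0)
  conc <- frac %*% stock_matrix(manifest)
  out <- data.frame(droplet_id = records$droplet_id, frac, conc,
                    clipped = clipped, inconsistent = inconsistent,
                    check.names = FALSE)
  names(out)[1L + seq_along(inl)] <- paste0("fraction_", inl)
  out
}
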