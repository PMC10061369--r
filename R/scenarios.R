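#' Standard imaging model for a three-channel screen
#'
#' Defaults chosen to emulate a typical EMCCD acquisition of 100 pL
#' droplets: dark level 100 counts, read noise 3 counts, a gentle radial
#' vignette, and channel gains that put the brightest droplets a few
#' hundred counts above dark.
#'
#' @param gain named per-channel gains; defaults cover the usual wiring
#'   (488 nm precipitant barcode, 546 nm additive barcode, 647 nm labelled
#'   protein).
#' @param ... passed to [imaging_model()].
#' @return an [imaging_model()].
#' @export
default_imaging <- function(gain = c(ch488 = 10, ch546 = 2, ch647 = 50),
                            ...) {
  imaging_model(gain = gain, ...)
}

#' Single-protein PEG titration scenario (lysozyme-style screen)
#'
#' Three inlets — buffer, labelled protein (stock 10 mg/mL, held at a
#' constant 0.1 flow fraction so every droplet carries 1 mg/mL protein),
#' and 50 w/v\% PEG 6000 with a 488 nm barcode, ramped over flow fractions
#' 0 to 0.3 so droplets span 0 to 15 w/v\% PEG. Ground truth: boundary at
#' \code{c0} w/v\% PEG with logistic width \code{noise_width}; the
#' reference values (5.7 and 0.5) reproduce a 1 mg/mL lysozyme pH 7 screen.
#'
#' @param n_droplets droplets to simulate.
#' @param c0 true boundary (w/v \% PEG) at the working protein
#'   concentration.
#' @param noise_width logistic transition width (w/v \% PEG).
#' @param peg_fraction_max upper PEG flow fraction.
#' @param seed integer seed.
#' @param imaging an [imaging_model()].
#' @param ... passed to [simulate_experiment()] (frame size, radii, ...).
#' @return a [simulate_experiment()] result.
#' @export
scenario_single_protein <- function(n_droplets = 4000L, c0 = 5.7,
                                    noise_width = 0.5,
                                    peg_fraction_max = 0.3, seed = 0,
                                    imaging = default_imaging(), ...) {
  manifest <- droplet_manifest(
    inlets = list(
      buffer = list(channel = NA, species = numeric(0)),
      protein = list(channel = "ch647", species = c(protein = 10)),
      peg = list(channel = "ch488", species = c(PEG = 50))),
    channels = c(ch488 = 488, ch546 = 546, ch647 = 647))
  truth <- phase_truth(c0 = c0, protein_coeff = 0, noise_width = noise_width)
  simulate_experiment(manifest, truth, imaging, n_droplets,
                      ramps = list(protein = c(0.1, 0.1),
                                   peg = c(0, peg_fraction_max)),
                      seed = seed, ...)
}

#' Two-excipient combination scenario on a fixed protein/PEG background
#'
#' Both additives are ramped over their mM ranges while protein (1 mg/mL)
#' and PEG are held fixed — PEG is premixed into every inlet solution so
#' its concentration is independent of the flow programme. The ground
#' truth boundary is \code{c0 + slope_x * X + slope_y * Y}; with
#' \code{peg_fixed} above \code{c0}, droplets aggregate at low additive
#' and mix at high additive, and the boundary is the line
#' \code{slope_x * X + slope_y * Y = peg_fixed - c0}. By default \code{c0}
#' is placed so that the boundary passes through the centre of the sampled
#' additive rectangle — how one would design the screen, with the boundary
#' bracketed on both sides.
#'
#' @param slope_x,slope_y true per-mM boundary shifts (w/v \% per mM).
#' @param x_max,y_max sampled additive ranges (mM).
#' @param peg_fixed constant PEG concentration (w/v \%).
#' @param c0 boundary at zero additives (w/v \%); default centres the
#'   boundary in the sampled rectangle.
#' @param n_droplets droplets to simulate.
#' @param noise_width logistic transition width (w/v \% PEG).
#' @param render render frames and calibration sets (full image pipeline);
#'   if FALSE, return compositions and labels only.
#' @param seed integer seed.
#' @param imaging an [imaging_model()].
#' @param ... passed to [simulate_experiment()].
#' @return a [simulate_experiment()] result, or (if \code{render = FALSE})
#'   a list with \code{points}, \code{labels}, \code{manifest},
#'   \code{truth_model}.
#' @export
scenario_combo <- function(slope_x = 0.02, slope_y = 0.02, x_max = 500,
                           y_max = 500, peg_fixed = 14, c0 = NULL,
                           n_droplets = 3000L, noise_width = 0.5,
                           render = TRUE, seed = 0,
                           imaging = default_imaging(), ...) {
  c0 <- c0 %||% (peg_fixed - slope_x * x_max / 2 - slope_y * y_max / 2)
  frac_max <- 0.35
  manifest <- droplet_manifest(
    inlets = list(
      buffer = list(channel = NA, species = c(PEG = peg_fixed)),
      additive_x = list(channel = "ch488",
                        species = c(additive_x = x_max / frac_max,
                                    PEG = peg_fixed)),
      additive_y = list(channel = "ch546",
                        species = c(additive_y = y_max / frac_max,
                                    PEG = peg_fixed)),
      protein = list(channel = "ch647",
                     species = c(protein = 10, PEG = peg_fixed))),
    channels = c(ch488 = 488, ch546 = 546, ch647 = 647))
  truth <- phase_truth(c0 = c0, protein_coeff = 0,
                       additive_slopes = c(additive_x = slope_x,
                                           additive_y = slope_y),
                       noise_width = noise_width)
  ramps <- list(additive_x = c(0, frac_max), additive_y = c(0, frac_max),
                protein = c(0.1, 0.1))
  if (!render) {
    pts <- sample_compositions(manifest, n_droplets, ramps, seed = seed)
    lab <- assign_labels(pts, truth, seed = derive_seed(seed, 1L))
    return(list(points = pts, labels = lab, manifest = manifest,
                truth_model = truth))
  }
  simulate_experiment(manifest, truth, imaging, n_droplets, ramps,
                      seed = seed, ...)
}

#' Composition-level additive screen: per-level PEG titrations
#'
#' Emulates a Fig-2-style excipient screen without rendering images: at
#' each additive concentration level, a PEG titration is sampled and
#' labelled under a ground truth whose boundary moves with the additive
#' (\code{c0 + slope * additive}, optionally two-regime). The PEG ramp is
#' wide enough to bracket the boundary at every level.
#'
#' @param additive additive name.
#' @param slope true slope (w/v \% PEG per mM).
#' @param levels additive concentrations (mM); default six levels spanning
#'   a total boundary shift of \code{max_effect} w/v \%.
#' @param n_per_level droplets per level.
#' @param c0 zero-additive boundary (w/v \% PEG); 7.3 reproduces BSA at
#'   pH 5.
#' @param noise_width logistic width (w/v \%).
#' @param max_effect total boundary shift covered by the default levels.
#' @param breakpoint,slope2 optional two-regime truth.
#' @param seed integer seed.
#' @return list of per-level lists (\code{conc}, \code{points},
#'   \code{labels}), with the truth model attached as an attribute.
#' @export
simulate_additive_screen <- function(additive, slope, levels = NULL,
                                     n_per_level = 800L, c0 = 7.3,
                                     noise_width = 0.5, max_effect = 5,
                                     breakpoint = NULL, slope2 = NULL,
                                     seed = 0) {
  levels <- levels %||% seq(0, max_effect / slope, length.out = 6L)
  bps <- if (!is.null(breakpoint))
    setNames(list(list(at = breakpoint, slope2 = slope2)), additive)
  else list()
  truth <- phase_truth(c0 = c0, protein_coeff = 0,
                       additive_slopes = setNames(slope, additive),
                       noise_width = noise_width, breakpoints = bps)
  manifest <- droplet_manifest(
    inlets = list(
      buffer = list(channel = NA, species = numeric(0)),
      protein = list(channel = "ch647", species = c(protein = 10)),
      peg = list(channel = "ch488", species = c(PEG = 50))),
    channels = c(ch488 = 488, ch546 = 546, ch647 = 647))
  peg_hi <- max(boundary_position(truth,
                                  setNames(data.frame(levels), additive))) + 4
  out <- lapply(seq_along(levels), function(i) {
    pts <- sample_compositions(manifest, n_per_level,
                               ramps = list(protein = c(0.1, 0.1),
                                            peg = c(0, min(peg_hi / 50,
                                                           0.9))),
                               seed = derive_seed(seed, 10L + i))
    pts[[additive]] <- levels[i]
    lab <- assign_labels(pts, truth, seed = derive_seed(seed, 100L + i))
    list(conc = levels[i], points = pts, labels = lab)
  })
  attr(out, "truth_model") <- truth
  out
}

#' Measure an additive screen: per-level relative solubilities
#'
#' Fits a phase model per level (PEG the only free feature) and reads the
#' relative solubility with bootstrap uncertainty, producing the
#' (concentration, solubility, sd) series that [additive_slope()] fits.
#'
#' @param screen output of [simulate_additive_screen()] (or any list of
#'   \code{conc}/\code{points}/\code{labels} levels).
#' @param B bootstrap resamples per level.
#' @param kernel SVM kernel.
#' @param seed integer seed.
#' @param features feature columns for the phase model.
#' @return data frame \code{conc}, \code{solubility}, \code{sd}.
#' @export
measure_additive_screen <- function(screen, B = 50L, kernel = "linear",
                                    seed = 1L, features = "PEG") {
  rows <- lapply(seq_along(screen), function(i) {
    lev <- screen[[i]]
    m <- fit_phase_model(lev$points[, features, drop = FALSE], lev$labels,
                         kernel = kernel)
    r <- relative_solubility(m, B = B, seed = derive_seed(seed, i))
    data.frame(conc = lev$conc, solubility = r$value, sd = r$sd)
  })
  do.call(rbind, rows)
}
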