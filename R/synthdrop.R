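#' Latent phase-boundary model used to label synthetic droplets
#'
#' The ground truth behind a simulated screen. The phase boundary is linear in
#' composition: \code{boundary = c0 + protein_coeff * protein +
#' sum(additive_slopes * additive)}, in precipitant units (w/v \% PEG). A
#' positive additive slope means the additive raises the boundary, i.e.
#' improves solubility, matching the convention of "\%PEG gained per mM".
#' An optional per-additive breakpoint switches to a second slope beyond a
#' stated concentration (salting-in vs salting-out of NaCl).
#'
#' A droplet at precipitant concentration \eqn{x} aggregates with probability
#' \eqn{logistic((x - boundary)/noise_width)}: the transition has finite
#' width, as the measured probability gradient does, and \code{noise_width}
#' sets its scale.
#'
#' @param c0 boundary precipitant concentration at zero additives and zero
#'   protein (w/v \%).
#' @param protein_coeff boundary shift per mg/mL protein (w/v \% per mg/mL).
#' @param additive_slopes named numeric, boundary shift per mM of each
#'   additive (w/v \% per mM).
#' @param noise_width logistic transition width (w/v \% precipitant), > 0.
#' @param breakpoints optional named list; each element
#'   \code{list(at = mM, slope2 = w/v\% per mM)} gives that additive a second
#'   regime beyond \code{at}.
#' @return object of class \code{phase_truth}.
#' @export
phase_truth <- function(c0, protein_coeff = 0, additive_slopes = numeric(0),
                        noise_width = 0.5, breakpoints = list()) {
  stopifnot(is.numeric(c0), length(c0) == 1L)
  if (!is.numeric(noise_width) || noise_width <= 0)
    stop_dropsol("noise_width must be > 0", "dropsol_config_error")
  if (length(breakpoints) &&
      !all(names(breakpoints) %in% names(additive_slopes)))
    stop_dropsol("breakpoints must refer to additives with slopes",
                 "dropsol_config_error")
  structure(list(c0 = c0, protein_coeff = protein_coeff,
                 additive_slopes = additive_slopes,
                 noise_width = noise_width, breakpoints = breakpoints),
            class = "phase_truth")
}

#' Boundary precipitant concentration for given compositions
#'
#' @param truth a [phase_truth()].
#' @param points data frame of compositions with a protein column (if
#'   \code{protein_coeff != 0}) and one column per additive with a slope.
#' @param protein name of the protein column.
#' @return numeric vector, boundary location in precipitant units.
#' @export
boundary_position <- function(truth, points, protein = "protein") {
  b <- rep(truth$c0, nrow(points))
  if (truth$protein_coeff != 0) {
    if (!protein %in% names(points))
      stop_dropsol("protein column required by protein_coeff",
                   "dropsol_config_error")
    b <- b + truth$protein_coeff * points[[protein]]
  }
  for (a in names(truth$additive_slopes)) {
    conc <- if (a %in% names(points)) points[[a]] else 0
    s1 <- truth$additive_slopes[[a]]
    bp <- truth$breakpoints[[a]]
    if (is.null(bp)) {
      b <- b + s1 * conc
    } else {
      b <- b + s1 * pmin(conc, bp$at) + bp$slope2 * pmax(conc - bp$at, 0)
    }
  }
  b
}

#' True aggregation probability of compositions under a phase_truth
#' @inheritParams boundary_position
#' @param precipitant name of the precipitant column in \code{points}.
#' @return numeric vector of probabilities in (0, 1).
#' @export
true_aggregation_probability <- function(truth, points, precipitant = "PEG",
                                         protein = "protein") {
  if (!precipitant %in% names(points))
    stop_dropsol(sprintf("no '%s' column in points", precipitant),
                 "dropsol_config_error")
  plogis((points[[precipitant]] - boundary_position(truth, points, protein)) /
           truth$noise_width)
}

#' Draw droplet compositions from inlet flow-rate ramps
#'
#' Emulates composition programming: relative flow rates of the aqueous
#' inlets vary while the total is constant, so each droplet's composition is
#' a convex combination of the inlet stocks. Each barcoded inlet's volume
#' fraction follows a stratified ramp over \code{[lo, hi]} (an evenly spaced
#' grid, independently permuted per inlet), which covers the composition axis
#' densely and hits both endpoints; the unbarcoded buffer inlet takes the
#' remainder.
#'
#' @param manifest a [droplet_manifest()].
#' @param n_droplets number of droplets to draw (>= 1).
#' @param ramps named list, one \code{c(lo, hi)} fraction range per barcoded
#'   inlet (use \code{lo == hi} to hold an inlet constant). Fraction upper
#'   bounds must sum to at most 1.
#' @param seed integer seed.
#' @return data frame with one row per droplet: \code{fraction_<inlet>}
#'   columns (summing to 1) and one column per species (concentration =
#'   fraction times stock, summed over inlets).
#' @export
sample_compositions <- function(manifest, n_droplets, ramps, seed = 0) {
  stopifnot(inherits(manifest, "droplet_manifest"), n_droplets >= 1)
  bc <- barcoded_inlets(manifest)
  if (length(manifest$inlets) < 2L)
    stop_dropsol("manifest must define >= 2 inlets", "dropsol_config_error")
  if (!all(names(ramps) %in% names(manifest$inlets)))
    stop_dropsol("ramp names must be manifest inlets", "dropsol_config_error")
  ramped <- names(ramps)
  hi_sum <- sum(vapply(ramps, function(r) r[2L], numeric(1)))
  if (hi_sum > 1 + 1e-9)
    stop_dropsol("ramp upper bounds exceed total flow", "dropsol_config_error")
  set.seed(seed)
  frac <- matrix(0, n_droplets, length(manifest$inlets),
                 dimnames = list(NULL, names(manifest$inlets)))
  grid <- (seq_len(n_droplets) - 0.5) / n_droplets
  for (nm in ramped) {
    r <- ramps[[nm]]
    frac[, nm] <- if (r[1L] == r[2L]) r[1L] else
      r[1L] + (r[2L] - r[1L]) * sample(grid)
  }
  buf <- buffer_inlet(manifest)
  if (is.na(buf))
    stop_dropsol("manifest needs an unbarcoded remainder inlet",
                 "dropsol_config_error")
  frac[, buf] <- 1 - rowSums(frac[, setdiff(colnames(frac), buf), drop = FALSE])
  if (any(frac < -1e-9))
    stop_dropsol("ramps leave a negative buffer fraction",
                 "dropsol_config_error")
  conc <- frac %*% stock_matrix(manifest)
  out <- data.frame(frac, conc, check.names = FALSE)
  names(out)[seq_along(manifest$inlets)] <-
    paste0("fraction_", colnames(frac))
  out
}

#' Bernoulli aggregate/mixed labels for sampled compositions
#'
#' @param points composition data frame from [sample_compositions()].
#' @param truth a [phase_truth()].
#' @param seed integer seed.
#' @param precipitant,protein column names.
#' @return integer vector, 1 = aggregated, 0 = mixed.
#' @export
assign_labels <- function(points, truth, seed = 0, precipitant = "PEG",
                          protein = "protein") {
  sp <- intersect(names(points), c(precipitant, protein,
                                   names(truth$additive_slopes)))
  if (any(vapply(sp, function(s) any(points[[s]] < 0), logical(1))))
    stop_dropsol("compositions must be nonnegative", "dropsol_config_error")
  p <- true_aggregation_probability(truth, points, precipitant, protein)
  set.seed(seed)
  rbinom(nrow(points), 1L, p)
}

#' Imaging forward model for synthetic droplet micrographs
#'
#' Interior intensity of a droplet in channel k is
#' \code{illumination * gain_k * conc_k + dark + noise}, where \code{conc_k}
#' is the concentration of the tracer species reported by channel k.
#' Aggregate-containing droplets additionally carry small bright specs in the
#' protein channel only (only the protein is covalently labelled), rendered
#' as blobs at \code{spec_contrast} times the local signal.
#'
#' @param gain named numeric, intensity units per concentration unit, one per
#'   channel; all > 0.
#' @param dark_offset camera dark level (intensity units).
#' @param noise_sd Gaussian read-noise standard deviation (intensity units).
#' @param illumination \code{"vignette"} (smooth radial falloff) or
#'   \code{"flat"}.
#' @param illumination_strength peak-to-corner relative falloff in (0, 1).
#' @param spec_contrast brightness multiplier of aggregate specs (> 1).
#' @param spec_count_range integer range of specs per aggregated droplet.
#' @param spec_radius_range spec blob radius range (px).
#' @return object of class \code{imaging_model}.
#' @export
imaging_model <- function(gain, dark_offset = 100, noise_sd = 3,
                          illumination = c("vignette", "flat"),
                          illumination_strength = 0.2,
                          spec_contrast = 3, spec_count_range = c(2L, 6L),
                          spec_radius_range = c(1, 2)) {
  illumination <- match.arg(illumination)
  if (any(gain <= 0)) stop_dropsol("gain must be > 0", "dropsol_config_error")
  if (spec_contrast <= 1)
    stop_dropsol("spec_contrast must be > 1", "dropsol_config_error")
  if (illumination_strength < 0 || illumination_strength >= 1)
    stop_dropsol("illumination_strength must be in [0, 1)",
                 "dropsol_config_error")
  structure(list(gain = gain, dark_offset = dark_offset, noise_sd = noise_sd,
                 illumination = illumination,
                 illumination_strength = illumination_strength,
                 spec_contrast = spec_contrast,
                 spec_count_range = as.integer(spec_count_range),
                 spec_radius_range = spec_radius_range),
            class = "imaging_model")
}

#' Multiplicative illumination field of an imaging model
#' @param imaging an [imaging_model()].
#' @param dim frame dimensions \code{c(nrow, ncol)}.
#' @return matrix with values in (0, 1], maximum 1 at the frame centre for
#'   the vignette model.
#' @export
illumination_matrix <- function(imaging, dim) {
  if (imaging$illumination == "flat")
    return(matrix(1, dim[1L], dim[2L]))
  cr <- (dim[1L] + 1) / 2; cc <- (dim[2L] + 1) / 2
  r2 <- outer(((seq_len(dim[1L]) - cr) / (dim[1L] / 2))^2,
              ((seq_len(dim[2L]) - cc) / (dim[2L] / 2))^2, "+")
  pmax(1 - imaging$illumination_strength * r2 / 2, 1e-3)
}

# per-channel tracer concentration implied by inlet fractions (n x nchan)
channel_concentrations <- function(manifest, fractions) {
  chans <- names(manifest$channels)
  out <- matrix(0, nrow(fractions), length(chans),
                dimnames = list(NULL, chans))
  for (nm in barcoded_inlets(manifest)) {
    ch <- inlet_channel(manifest, nm)
    out[, ch] <- fractions[, nm] * tracer_stock(manifest, nm)
  }
  out
}

# place n non-overlapping disks inside a frame; error if they cannot fit
place_droplets <- function(n, frame_dim, radius_range, margin = 2,
                           max_tries = 400L) {
  rows <- numeric(n); cols <- numeric(n); rad <- numeric(n)
  for (i in seq_len(n)) {
    r <- runif(1, radius_range[1L], radius_range[2L])
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      cr <- runif(1, r + margin + 1, frame_dim[1L] - r - margin)
      cc <- runif(1, r + margin + 1, frame_dim[2L] - r - margin)
      if (i == 1L ||
          all(sqrt((rows[seq_len(i - 1L)] - cr)^2 +
                   (cols[seq_len(i - 1L)] - cc)^2) >
              rad[seq_len(i - 1L)] + r + margin)) {
        ok <- TRUE; break
      }
    }
    if (!ok)
      stop_dropsol("frame too small for requested droplets",
                   "dropsol_layout_error")
    rows[i] <- cr; cols[i] <- cc; rad[i] <- r
  }
  data.frame(center_row = rows, center_col = cols, radius_px = rad)
}

disk_pixels <- function(center_row, center_col, radius, frame_dim) {
  rs <- max(1L, floor(center_row - radius)):min(frame_dim[1L],
                                                ceiling(center_row + radius))
  cs <- max(1L, floor(center_col - radius)):min(frame_dim[2L],
                                                ceiling(center_col + radius))
  g <- expand.grid(r = rs, c = cs)
  g[(g$r - center_row)^2 + (g$c - center_col)^2 <= radius^2, , drop = FALSE]
}

#' Render droplet compositions into multi-channel fluorescence frames
#'
#' @param points compositions from [sample_compositions()].
#' @param labels 0/1 labels from [assign_labels()].
#' @param imaging an [imaging_model()].
#' @param manifest a [droplet_manifest()].
#' @param frame_dim frame size in px, default 512 x 512.
#' @param radius_range droplet radius range in px.
#' @param droplets_per_frame target droplets per frame (around 100 droplets
#'   per image in a typical screen).
#' @param seed integer seed.
#' @return list with \code{frames} (list of row x col x channel arrays) and
#'   \code{truth} (data frame: droplet_id, frame, 0-based centre, radius,
#'   inlet fractions, species concentrations, true_label, n_specs; spec blob
#'   centres as a list attribute \code{"spec_centers"}).
#' @export
render_frames <- function(points, labels, imaging, manifest,
                          frame_dim = c(512L, 512L),
                          radius_range = c(10, 14),
                          droplets_per_frame = 100L, seed = 0) {
  n <- nrow(points)
  stopifnot(length(labels) == n)
  chans <- names(manifest$channels)
  fr_cols <- paste0("fraction_", names(manifest$inlets))
  conc_ch <- channel_concentrations(
    manifest, as.matrix(setNames(points[fr_cols],
                                 names(manifest$inlets))))
  prot_ch <- tryCatch(protein_channel(manifest), error = function(e) NA)
  if (is.na(prot_ch) && any(labels == 1L))
    stop_dropsol("aggregated droplets need a protein channel to render specs",
                 "dropsol_config_error")
  illum <- illumination_matrix(imaging, frame_dim)
  set.seed(seed)
  n_frames <- ceiling(n / droplets_per_frame)
  frames <- vector("list", n_frames)
  truth <- vector("list", n_frames)
  spec_centers <- vector("list", n)
  idx0 <- 0L
  for (f in seq_len(n_frames)) {
    nf <- min(droplets_per_frame, n - idx0)
    ids <- idx0 + seq_len(nf)
    geo <- place_droplets(nf, frame_dim, radius_range)
    npix <- prod(frame_dim) * length(chans)
    sig <- array(if (imaging$noise_sd > 0)
      rnorm(npix, imaging$dark_offset, imaging$noise_sd)
      else imaging$dark_offset,
      c(frame_dim, length(chans)), dimnames = list(NULL, NULL, chans))
    for (i in seq_len(nf)) {
      px <- disk_pixels(geo$center_row[i], geo$center_col[i],
                        geo$radius_px[i], frame_dim)
      ij <- cbind(px$r, px$c)
      for (k in seq_along(chans)) {
        idx <- cbind(ij, k)
        sig[idx] <- sig[idx] + illum[ij] * imaging$gain[chans[k]] *
          conc_ch[ids[i], k]
      }
      if (labels[ids[i]] == 1L) {
        ns <- sample(imaging$spec_count_range[1L]:imaging$spec_count_range[2L],
                     1L)
        ctr <- matrix(0, ns, 2L)
        kp <- which(chans == prot_ch)
        for (s in seq_len(ns)) {
          ang <- runif(1, 0, 2 * pi)
          dd <- runif(1, 0, 0.7 * geo$radius_px[i])
          sr <- geo$center_row[i] + dd * cos(ang)
          sc <- geo$center_col[i] + dd * sin(ang)
          ctr[s, ] <- c(sr, sc)
          srad <- runif(1, imaging$spec_radius_range[1L],
                        imaging$spec_radius_range[2L])
          sp <- disk_pixels(sr, sc, srad, frame_dim)
          keep <- (sp$r - geo$center_row[i])^2 + (sp$c - geo$center_col[i])^2 <=
            geo$radius_px[i]^2
          sp <- sp[keep, , drop = FALSE]
          if (nrow(sp)) {
            sij <- cbind(sp$r, sp$c)
            # spec pixels sit at spec_contrast x the local signal (dark and
            # read noise are additive camera terms, not fluorescence)
            sig[cbind(sij, kp)] <- sig[cbind(sij, kp)] +
              (imaging$spec_contrast - 1) * illum[sij] *
              imaging$gain[chans[kp]] * conc_ch[ids[i], kp]
          }
        }
        spec_centers[[ids[i]]] <- ctr - 1  # 0-based like the truth table
      }
    }
    frames[[f]] <- sig
    truth[[f]] <- data.frame(
      droplet_id = ids, frame = f,
      center_row = geo$center_row - 1, center_col = geo$center_col - 1,
      radius_px = geo$radius_px,
      points[ids, , drop = FALSE],
      true_label = labels[ids],
      n_specs = vapply(spec_centers[ids],
                       function(m) if (is.null(m)) 0L else nrow(m),
                       integer(1)),
      row.names = NULL, check.names = FALSE)
    idx0 <- idx0 + nf
  }
  truth <- do.call(rbind, truth)
  attr(truth, "spec_centers") <- spec_centers
  list(frames = frames, truth = truth)
}

#' Render the three calibration image sets
#'
#' Produces the three correction targets measured alongside every screen:
#' set A, droplets each containing only one inlet solution (endpoint
#' intensities); set B, a homogeneous full-frame solution of all dyes
#' (laser illumination differences); set C, frames without sample (camera
#' dark background). Ten frames per condition by default.
#'
#' @inheritParams render_frames
#' @param n_frames frames per condition (default 10).
#' @param droplets_per_frame droplets per endpoint frame; by default scaled
#'   to roughly a quarter of the frame area, capped at 40.
#' @return list with elements \code{endpoint} (named list: inlet -> list of
#'   frames), \code{flat} and \code{dark} (lists of frames).
#' @export
render_calibration_sets <- function(imaging, manifest, n_frames = 10L,
                                    frame_dim = c(512L, 512L),
                                    radius_range = c(10, 14),
                                    droplets_per_frame = NULL, seed = 0) {
  stopifnot(n_frames >= 1L)
  droplets_per_frame <- droplets_per_frame %||%
    max(1L, min(40L, floor(0.25 * prod(frame_dim) /
                             (pi * max(radius_range)^2))))
  chans <- names(manifest$channels)
  illum <- illumination_matrix(imaging, frame_dim)
  set.seed(seed)
  blank <- function() {
    array(if (imaging$noise_sd > 0)
      rnorm(prod(frame_dim) * length(chans), imaging$dark_offset,
            imaging$noise_sd) else imaging$dark_offset,
      c(frame_dim, length(chans)), dimnames = list(NULL, NULL, chans))
  }
  endpoint <- list()
  for (nm in barcoded_inlets(manifest)) {
    ch <- inlet_channel(manifest, nm)
    kp <- which(chans == ch)
    conc <- tracer_stock(manifest, nm)
    endpoint[[nm]] <- lapply(seq_len(n_frames), function(f) {
      a <- blank()
      geo <- place_droplets(droplets_per_frame, frame_dim, radius_range)
      for (i in seq_len(nrow(geo))) {
        px <- disk_pixels(geo$center_row[i], geo$center_col[i],
                          geo$radius_px[i], frame_dim)
        ij <- cbind(px$r, px$c)
        a[cbind(ij, kp)] <- a[cbind(ij, kp)] +
          illum[ij] * imaging$gain[ch] * conc
      }
      a
    })
  }
  ref <- channel_concentrations(
    manifest, {
      m <- matrix(0, 1, length(manifest$inlets),
                  dimnames = list(NULL, names(manifest$inlets)))
      for (nm in barcoded_inlets(manifest)) m[, nm] <- 1
      m
    })
  flat <- lapply(seq_len(n_frames), function(f) {
    a <- blank()
    for (k in seq_along(chans))
      a[, , k] <- a[, , k] + illum * imaging$gain[chans[k]] * ref[1L, k]
    a
  })
  dark <- lapply(seq_len(n_frames), function(f) blank())
  list(endpoint = endpoint, flat = flat, dark = dark)
}

#' Simulate a complete synthetic droplet experiment
#'
#' Chains composition sampling, Bernoulli labelling under a latent phase
#' boundary, frame rendering and calibration-set rendering, all driven by
#' one seed, and returns everything the downstream pipeline (and its tests)
#' need, including the ground truth table.
#'
#' @inheritParams render_frames
#' @param truth a [phase_truth()].
#' @param n_droplets droplets to simulate.
#' @param ramps flow-fraction ramps, see [sample_compositions()].
#' @param calibration_frames frames per calibration condition.
#' @return object of class \code{synthetic_experiment}: list with
#'   \code{frames}, \code{truth}, \code{calibration}, \code{manifest},
#'   \code{imaging}, \code{truth_model}, \code{frame_dim}, \code{seed}.
#' @export
simulate_experiment <- function(manifest, truth, imaging, n_droplets, ramps,
                                frame_dim = c(512L, 512L),
                                radius_range = c(10, 14),
                                droplets_per_frame = 100L,
                                calibration_frames = 10L, seed = 0) {
  pts <- sample_compositions(manifest, n_droplets, ramps, seed = seed)
  lab <- assign_labels(pts, truth, seed = derive_seed(seed, 1L),
                       precipitant = manifest$precipitant,
                       protein = manifest$protein)
  rf <- render_frames(pts, lab, imaging, manifest, frame_dim = frame_dim,
                      radius_range = radius_range,
                      droplets_per_frame = droplets_per_frame,
                      seed = derive_seed(seed, 2L))
  cal <- render_calibration_sets(imaging, manifest,
                                 n_frames = calibration_frames,
                                 frame_dim = frame_dim,
                                 radius_range = radius_range,
                                 seed = derive_seed(seed, 3L))
  structure(list(frames = rf$frames, truth = rf$truth, calibration = cal,
                 manifest = manifest, imaging = imaging, truth_model = truth,
                 frame_dim = frame_dim, seed = seed),
            class = "synthetic_experiment")
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat("synthetic_experiment:", nrow(x$truth), "droplets in",
      length(x$frames), "frames;",
      sum(x$truth$true_label), "aggregated (seed", paste0(x$seed, ")\n"))
  invisible(x)
}

# 16-bit scale used when frames round-trip through TIFF files
.tiff_scale <- 65535

#' Write a synthetic experiment to disk as TIFF stacks plus truth table
#'
#' One multi-page 16-bit TIFF per frame (pages in manifest channel order),
#' calibration sets under \code{calibration/}, a CSV truth table and a JSON
#' manifest echo carrying the seed.
#'
#' @param experiment a [simulate_experiment()] result.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_synthetic_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "synthetic_experiment"))
  write_stack <- function(a, path) {
    pages <- lapply(seq_len(dim(a)[3L]), function(k)
      pmin(pmax(a[, , k] / .tiff_scale, 0), 1))
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  }
  dir.create(file.path(dir, "frames"), recursive = TRUE, showWarnings = FALSE)
  for (f in seq_along(experiment$frames))
    write_stack(experiment$frames[[f]],
                file.path(dir, "frames", sprintf("frame_%03d.tif", f)))
  for (set in c("flat", "dark")) {
    d <- file.path(dir, "calibration", set)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    for (f in seq_along(experiment$calibration[[set]]))
      write_stack(experiment$calibration[[set]][[f]],
                  file.path(d, sprintf("%s_%03d.tif", set, f)))
  }
  for (nm in names(experiment$calibration$endpoint)) {
    d <- file.path(dir, "calibration", paste0("endpoint_", nm))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    for (f in seq_along(experiment$calibration$endpoint[[nm]]))
      write_stack(experiment$calibration$endpoint[[nm]][[f]],
                  file.path(d, sprintf("endpoint_%03d.tif", f)))
  }
  tr <- experiment$truth
  attr(tr, "spec_centers") <- NULL
  write.csv(tr, file.path(dir, "truth.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(seed = experiment$seed,
         channels = as.list(experiment$manifest$channels),
         protein = experiment$manifest$protein,
         precipitant = experiment$manifest$precipitant,
         inlets = lapply(experiment$manifest$inlets, function(i)
           list(channel = i$channel %||% NA, species = as.list(i$species)))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read an experiment directory written by [write_synthetic_experiment()]
#'
#' @param dir experiment directory.
#' @param channels channel names, in page order; defaults to the names in
#'   \code{manifest.json}.
#' @return list with \code{frames}, \code{calibration}, \code{manifest} (a
#'   rebuilt [droplet_manifest()]) and \code{truth} (if present).
#' @export
read_experiment <- function(dir, channels = NULL) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"))
  channels <- channels %||% names(mf$channels)
  read_stack <- function(path) {
    pages <- tiff::readTIFF(path, all = TRUE)
    a <- array(0, c(dim(pages[[1L]]), length(pages)),
               dimnames = list(NULL, NULL, channels))
    for (k in seq_along(pages)) a[, , k] <- pages[[k]] * .tiff_scale
    a
  }
  read_dir <- function(d) lapply(sort(list.files(d, "\\.tif$",
                                                 full.names = TRUE)),
                                 read_stack)
  manifest <- droplet_manifest(
    inlets = lapply(mf$inlets, function(i)
      list(channel = if (is.null(i$channel) || is.na(i$channel)) NA else
        i$channel, species = unlist(i$species))),
    channels = unlist(mf$channels),
    protein = mf$protein, precipitant = mf$precipitant)
  cal_dir <- file.path(dir, "calibration")
  endpoint <- list()
  for (d in list.files(cal_dir, "^endpoint_", full.names = TRUE))
    endpoint[[sub("^endpoint_", "", basename(d))]] <- read_dir(d)
  truth_path <- file.path(dir, "truth.csv")
  list(frames = read_dir(file.path(dir, "frames")),
       calibration = list(endpoint = endpoint,
                          flat = read_dir(file.path(cal_dir, "flat")),
                          dark = read_dir(file.path(cal_dir, "dark"))),
       manifest = manifest,
       truth = if (file.exists(truth_path)) read.csv(truth_path,
                                                     check.names = FALSE))
}
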