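#' Detection parameters for droplet segmentation
#'
#' @param r_min,r_max admissible droplet radius range (px).
#' @param min_circularity minimum circularity \code{4*pi*area/perimeter^2}
#'   (perimeter measured along the object contour); fused droplet pairs fall
#'   well below 1.
#' @param detect_channel channel name to threshold, or \code{"auto"}: each
#'   channel carrying real signal is Otsu-thresholded separately and the
#'   masks are unioned, so a droplet bright in any dye channel is found
#'   (every droplet carries at least one dye: barcode or labelled protein).
#' @param interior_margin interior statistics use pixels within
#'   \code{interior_margin * radius} of the centre, excluding the oil rim.
#' @param min_pixels minimum interior pixel count for a usable droplet.
#' @param saturation_level intensity treated as sensor saturation.
#' @return list of class \code{detect_params}.
#' @export
detect_params <- function(r_min = 6, r_max = 20, min_circularity = 0.8,
                          detect_channel = "auto", interior_margin = 0.9,
                          min_pixels = 20L, saturation_level = .tiff_scale) {
  structure(list(r_min = r_min, r_max = r_max,
                 min_circularity = min_circularity,
                 detect_channel = detect_channel,
                 interior_margin = interior_margin,
                 min_pixels = as.integer(min_pixels),
                 saturation_level = saturation_level),
            class = "detect_params")
}

# contour arc length per labelled object (closed polygon through border px)
contour_perimeters <- function(lab) {
  oc <- EBImage::ocontour(lab)
  vapply(oc, function(m) {
    if (nrow(m) < 3L) return(nrow(m))
    d <- sqrt(rowSums((m - m[c(2:nrow(m), 1L), ])^2))
    sum(d)
  }, numeric(1))
}

#' Detect droplets in one multi-channel frame
#'
#' Thresholds the detection image with Otsu's method (relative to the frame's
#' own histogram, hence invariant to constant offsets), labels connected
#' components, and keeps components that are circular and of plausible
#' radius. Per-channel interior statistics (mean, sd) are computed over
#' pixels within \code{interior_margin * radius} of the fitted centre.
#'
#' @param frame numeric array, row x col x channel, channel dimnames set.
#' @param params a [detect_params()].
#' @param frame_id identifier stored on the records.
#' @return data frame of droplet records: 0-based centre (\code{center_row},
#'   \code{center_col}), \code{radius_px}, \code{circularity},
#'   \code{n_pixels}, \code{mean_<channel>}, \code{median_<channel>} and
#'   \code{sd_<channel>} columns,
#'   plus a \code{pixels} list-column of interior pixel matrices
#'   (n_pixels x n_channels). Attribute \code{"saturated"} flags a frame
#'   dominated by saturated pixels. An empty or flat frame yields zero rows.
#' @export
detect_droplets <- function(frame, params = detect_params(), frame_id = 1L) {
  stopifnot(length(dim(frame)) == 3L)
  chans <- dimnames(frame)[[3L]]
  if (is.null(chans)) chans <- paste0("ch", seq_len(dim(frame)[3L]))
  use <- if (identical(params$detect_channel, "auto")) seq_along(chans)
  else match(params$detect_channel, chans)
  empty <- droplet_records_empty(chans)
  saturated <- mean(frame >= params$saturation_level * 0.999) > 0.5
  # union of per-channel Otsu masks; a channel carrying no signal splits its
  # own noise (threshold at the background median, ~half the pixels above),
  # so channels are ignored unless the threshold clears the background and
  # the mask stays a minority of the frame
  mask <- matrix(FALSE, dim(frame)[1L], dim(frame)[2L])
  any_signal <- FALSE
  for (k in use) {
    det <- frame[, , k]
    rng <- range(det)
    if (diff(rng) < 1e-9) next
    thr <- EBImage::otsu(EBImage::Image(det), range = rng, levels = 256L)
    mk <- det > thr
    if (mean(mk) > 0.4 || thr <= median(det) + 2 * mad(det)) next
    any_signal <- TRUE
    mask <- mask | mk
  }
  if (!any_signal) {
    attr(empty, "saturated") <- saturated
    return(empty)
  }
  lab <- EBImage::bwlabel(EBImage::fillHull(mask))
  if (max(lab) == 0L) {
    attr(empty, "saturated") <- saturated
    return(empty)
  }
  shp <- EBImage::computeFeatures.shape(lab)
  mom <- EBImage::computeFeatures.moment(lab)
  per <- contour_perimeters(lab)
  area <- shp[, "s.area"]
  radius <- sqrt(area / pi)
  circ <- pmin(1, 4 * pi * area / pmax(per, 1)^2)
  keep <- which(radius >= params$r_min & radius <= params$r_max &
                  circ >= params$min_circularity)
  if (!length(keep)) {
    attr(empty, "saturated") <- saturated
    return(empty)
  }
  # EBImage moment cx is along the first matrix index (image x), 1-based
  ctr_r <- mom[keep, "m.cx"]; ctr_c <- mom[keep, "m.cy"]
  rad <- radius[keep]
  n <- length(keep)
  px_list <- vector("list", n)
  mu <- matrix(NA_real_, n, length(chans),
               dimnames = list(NULL, paste0("mean_", chans)))
  med <- matrix(NA_real_, n, length(chans),
                dimnames = list(NULL, paste0("median_", chans)))
  sig <- matrix(NA_real_, n, length(chans),
                dimnames = list(NULL, paste0("sd_", chans)))
  npx <- integer(n)
  dims <- dim(frame)[1:2]
  nr <- dims[1L]
  plane <- as.integer(prod(dims))
  pix_by_comp <- split(which(lab > 0L), lab[lab > 0L])
  fast_median <- function(x) {
    nn <- length(x); h <- (nn + 1L) %/% 2L
    if (nn %% 2L == 1L) sort(x, partial = h)[h]
    else { s <- sort(x, partial = c(h, h + 1L)); (s[h] + s[h + 1L]) / 2 }
  }
  for (i in seq_len(n)) {
    idx <- pix_by_comp[[as.character(keep[i])]]
    pr <- (idx - 1L) %% nr + 1L
    pc <- (idx - 1L) %/% nr + 1L
    inside <- (pr - ctr_r[i])^2 + (pc - ctr_c[i])^2 <=
      (params$interior_margin * rad[i])^2
    lin <- idx[inside]
    npx[i] <- length(lin)
    if (!npx[i]) next
    vals <- matrix(NA_real_, npx[i], length(chans),
                   dimnames = list(NULL, chans))
    for (k in seq_along(chans)) {
      v <- frame[lin + (k - 1L) * plane]
      vals[, k] <- v
      mu[i, k] <- mean(v)
      med[i, k] <- fast_median(v)
      sig[i, k] <- sqrt(max(sum((v - mu[i, k])^2) / (npx[i] - 1L), 0))
    }
    px_list[[i]] <- vals
  }
  ok <- npx >= params$min_pixels
  rec <- data.frame(droplet_id = NA_integer_, frame_id = frame_id,
                    center_row = ctr_r - 1, center_col = ctr_c - 1,
                    radius_px = rad, circularity = circ[keep],
                    n_pixels = npx, mu, med, sig, check.names = FALSE)
  rec$pixels <- px_list
  rec <- rec[ok, , drop = FALSE]
  rec$droplet_id <- seq_len(nrow(rec))
  attr(rec, "saturated") <- saturated
  rec
}

droplet_records_empty <- function(chans) {
  rec <- data.frame(droplet_id = integer(0), frame_id = integer(0),
                    center_row = numeric(0), center_col = numeric(0),
                    radius_px = numeric(0), circularity = numeric(0),
                    n_pixels = integer(0))
  for (ch in chans) rec[[paste0("mean_", ch)]] <- numeric(0)
  for (ch in chans) rec[[paste0("median_", ch)]] <- numeric(0)
  for (ch in chans) rec[[paste0("sd_", ch)]] <- numeric(0)
  rec$pixels <- list()
  rec
}

#' Detect droplets across a list of frames
#' @param frames list of multi-channel arrays.
#' @inheritParams detect_droplets
#' @return combined record data frame with global \code{droplet_id}.
#' @export
detect_frames <- function(frames, params = detect_params()) {
  recs <- lapply(seq_along(frames), function(f)
    detect_droplets(frames[[f]], params, frame_id = f))
  out <- do.call(rbind, recs)
  if (nrow(out)) out$droplet_id <- seq_len(nrow(out))
  attr(out, "saturated") <- any(vapply(recs, attr, logical(1), "saturated"))
  out
}

#' Drop border-touching and non-circular (merged) droplet records
#'
#' @param records output of [detect_droplets()]/[detect_frames()].
#' @param frame_dim frame size \code{c(nrow, ncol)}.
#' @param min_circularity circularity floor (same statistic as detection).
#' @return surviving subset of \code{records}; attribute \code{"removed"}
#'   counts removals per reason (\code{border}, \code{circularity}).
#' @export
filter_edge_and_merged <- function(records, frame_dim,
                                   min_circularity = 0.8) {
  if (!nrow(records)) {
    attr(records, "removed") <- c(border = 0L, circularity = 0L)
    return(records)
  }
  border <- records$center_row - records$radius_px < 0 |
    records$center_col - records$radius_px < 0 |
    records$center_row + records$radius_px > frame_dim[1L] - 1 |
    records$center_col + records$radius_px > frame_dim[2L] - 1
  round_enough <- records$circularity >= min_circularity
  keep <- !border & round_enough
  out <- records[keep, , drop = FALSE]
  attr(out, "removed") <- c(border = sum(border),
                            circularity = sum(!round_enough & !border))
  attr(out, "saturated") <- attr(records, "saturated")
  out
}

#' Match detected droplets to a ground-truth table
#'
#' Greedy nearest-centre matching within a tolerance, per frame; used to
#' score detection recall/precision against a generator truth table.
#'
#' @param records detected records (0-based centres).
#' @param truth generator truth table.
#' @param tol_px maximum centre distance for a match.
#' @return list with \code{matches} (data frame droplet_id, truth droplet_id
#'   \code{truth_id}), \code{recall} and \code{precision}.
#' @export
match_to_truth <- function(records, truth, tol_px = 2) {
  matches <- NULL
  for (f in unique(truth$frame)) {
    tr <- truth[truth$frame == f, ]
    re <- records[records$frame_id == f, ]
    if (!nrow(re)) next
    d <- outer(re$center_row, tr$center_row, "-")^2 +
      outer(re$center_col, tr$center_col, "-")^2
    d <- sqrt(d)
    used_t <- rep(FALSE, nrow(tr))
    for (i in order(apply(d, 1L, min))) {
      j <- which.min(ifelse(used_t, Inf, d[i, ]))
      if (length(j) && d[i, j] <= tol_px) {
        used_t[j] <- TRUE
        matches <- rbind(matches,
                         data.frame(droplet_id = re$droplet_id[i],
                                    truth_id = tr$droplet_id[j]))
      }
    }
  }
  n_match <- if (is.null(matches)) 0L else nrow(matches)
  list(matches = matches,
       recall = n_match / nrow(truth),
       precision = if (nrow(records)) n_match / nrow(records) else NA_real_)
}
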