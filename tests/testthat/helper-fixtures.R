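# shared fixtures, built once per test run and cached

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# mid-sized single-protein screen with images, shared across test files
small_experiment <- function() {
  cached("small_exp",
         scenario_single_protein(n_droplets = 600L, seed = 42,
                                 calibration_frames = 5L))
}

small_records <- function() {
  cached("small_rec", {
    ex <- small_experiment()
    filter_edge_and_merged(detect_frames(ex$frames), ex$frame_dim)
  })
}

small_calibration <- function() {
  cached("small_cal", fit_calibration(small_experiment()$calibration,
                                      small_experiment()$manifest))
}

# truth label aligned with each detected record (NA if unmatched)
truth_label_for_records <- function(records, experiment) {
  mt <- match_to_truth(records, experiment$truth)
  experiment$truth$true_label[mt$matches$truth_id][
    match(records$droplet_id, mt$matches$droplet_id)]
}

# two-inlet manifest used for arithmetic-level tests
two_inlet_manifest <- function(stock = 50) {
  droplet_manifest(
    inlets = list(
      buffer = list(channel = NA, species = numeric(0)),
      peg = list(channel = "ch488", species = c(PEG = stock))),
    channels = c(ch488 = 488))
}

# draw a single-disk frame directly (for focused detection tests)
one_disk_frame <- function(radius, center = c(64, 64), dim = c(128L, 128L),
                           value = 200, dark = 100, noise_sd = 0,
                           seed = 1) {
  set.seed(seed)
  a <- array(if (noise_sd > 0) rnorm(prod(dim) * 1, dark, noise_sd) else dark,
             c(dim, 1L), dimnames = list(NULL, NULL, "ch488"))
  px <- dropsol:::disk_pixels(center[1], center[2], radius, dim)
  a[cbind(px$r, px$c, 1L)] <- value
  a
}
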