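#' Default run configuration
#'
#' A run configuration is a plain named list (serialisable to YAML/JSON)
#' describing one end-to-end analysis: where the images come from (an
#' experiment directory, or \code{images = "synthetic"} plus generator
#' parameters), detection and aggregation-calling parameters, the phase
#' model, and the solubility read-out.
#'
#' @param output_dir where run outputs are written.
#' @param seed run seed (all randomness derives from it).
#' @param ... overrides merged over the defaults (named sublists are merged
#'   shallowly).
#' @return named list.
#' @export
default_config <- function(output_dir = tempfile("dropsol_run_"), seed = 0,
                           ...) {
  cfg <- list(
    seed = seed,
    output_dir = output_dir,
    images = "synthetic",
    synthetic = list(scenario = "single_protein", n_droplets = 2000L,
                     c0 = 5.7, noise_width = 0.5),
    detection = list(r_min = 6, r_max = 20, min_circularity = 0.8),
    aggregation = list(k = 3, w = 10, min_signal = 5, threshold = NULL,
                       fallback = 0.5),
    model = list(kernel = "linear", cost = 1),
    solubility = list(protein_conc = 1, B = 200L))
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    else cfg[[nm]] <- over[[nm]]
  }
  cfg
}

#' Validate a run configuration
#'
#' Schema and sanity checks, reported exhaustively rather than first-fail:
#' seed present, positive stocks, bootstrap size, kernel name, channel
#' wiring (no channel serving two inlets), and path existence for
#' image-directory runs.
#'
#' @param config a configuration list, or a path to a YAML/JSON file.
#' @return character vector of violations; empty when the config is valid.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- read_config(config)
  v <- character(0)
  say <- function(msg) v <<- c(v, msg)
  if (is.null(config$seed)) say("seed: missing (default 0 expected)")
  if (is.null(config$images)) say("images: missing")
  else if (!identical(config$images, "synthetic") &&
           !dir.exists(config$images))
    say(sprintf("images: directory '%s' does not exist", config$images))
  b <- config$solubility$B
  if (!is.null(b) && b < 50) say("solubility.B: must be >= 50")
  k <- config$model$kernel
  if (!is.null(k) && !k %in% c("linear", "poly2"))
    say(sprintf("model.kernel: '%s' is not linear/poly2", k))
  d <- config$detection
  if (!is.null(d$r_min) && !is.null(d$r_max) && d$r_min >= d$r_max)
    say("detection: r_min must be < r_max")
  mf <- config$manifest
  if (!is.null(mf)) {
    chan <- unlist(lapply(mf$inlets, function(i) i$channel))
    chan <- chan[!is.na(chan)]
    if (anyDuplicated(chan))
      say(sprintf("manifest: channel %s mapped to two inlets",
                  paste(unique(chan[duplicated(chan)]), collapse = ", ")))
    for (nm in names(mf$inlets)) {
      sp <- unlist(mf$inlets[[nm]]$species)
      if (any(sp <= 0))
        say(sprintf("manifest: nonpositive stock in inlet '%s'", nm))
    }
  }
  v
}

#' Read a YAML or JSON run configuration file
#' @param path file path (extension decides the parser).
#' @return configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    stop_dropsol(sprintf("config file '%s' not found", path),
                 "dropsol_config_error")
  if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}

#' Run the end-to-end droplet solubility pipeline
#'
#' Simulates (or loads) an experiment, detects and filters droplets,
#' calibrates intensities, infers compositions, scores and calls
#' aggregates, fits the phase model and reads the relative solubility.
#' Writes \code{droplets.csv} (one record + composition + call per row),
#' \code{phase_model.json}, \code{solubility.json}, \code{run.log} with
#' per-stage droplet accounting, and \code{phase_diagram.png}. Identical
#' config and seed give identical CSV/JSON outputs.
#'
#' @param config a configuration list from [default_config()], or a path
#'   to a YAML/JSON config file.
#' @return list of class \code{dropsol_run}: \code{droplets} (data frame),
#'   \code{model}, \code{solubility}, \code{counts}, \code{paths}.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- read_config(config)
  viol <- validate_config(config)
  if (length(viol))
    stop_dropsol(paste0("invalid config:\n  ", paste(viol, collapse = "\n  ")),
                 "dropsol_config_error")
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  logf <- function(fmt, ...) log_lines <<- c(log_lines, sprintf(fmt, ...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(c(log_lines, sprintf("FAILED at stage '%s': %s", name,
                                      conditionMessage(e))),
                 file.path(config$output_dir, "run.log"))
      stop_dropsol(sprintf("stage '%s' failed: %s", name,
                           conditionMessage(e)),
                   "dropsol_stage_error")
    })
  }
  seed <- config$seed %||% 0

  exper <- stage("acquire", {
    if (identical(config$images, "synthetic")) {
      sc <- config$synthetic
      args <- sc[setdiff(names(sc), c("scenario", "seed"))]
      if (identical(sc$scenario, "combo"))
        do.call(scenario_combo, c(args, list(seed = seed)))
      else
        do.call(scenario_single_protein, c(args, list(seed = seed)))
    } else read_experiment(config$images)
  })
  manifest <- exper$manifest
  frame_dim <- dim(exper$frames[[1L]])[1:2]
  logf("frames: %d", length(exper$frames))

  det <- do.call(detect_params, config$detection %||% list())
  records <- stage("detect", detect_frames(exper$frames, det))
  n_detected <- nrow(records)
  logf("detected: %d", n_detected)
  records <- stage("filter",
                   filter_edge_and_merged(records, frame_dim,
                                          det$min_circularity))
  rem <- attr(records, "removed")
  logf("removed border: %d", rem[["border"]])
  logf("removed circularity: %d", rem[["circularity"]])

  calib <- stage("chemometry", {
    if (is.null(exper$calibration) || !length(exper$calibration$dark %||%
                                              list()))
      stop_dropsol("no calibration frames", "dropsol_calibration_error")
    fit_calibration(exper$calibration, manifest, det)
  })
  comp <- stage("chemometry", infer_composition(records, calib))

  agg <- config$aggregation %||% list()
  scored <- stage("aggcall",
                  score_droplets(records, calib, k = agg$k %||% 3,
                                 w = agg$w %||% 10,
                                 min_signal = agg$min_signal %||% 5))
  usable <- !scored$low_signal & !comp$inconsistent
  thr <- stage("aggcall", {
    if (!is.null(agg$threshold)) structure(agg$threshold, method = "config")
    else choose_threshold(scored$score[usable],
                          fallback = agg$fallback %||% 0.5)
  })
  calls <- stage("aggcall", call_droplets(scored[usable, ], thr))
  logf("removed low_signal: %d", sum(scored$low_signal))
  logf("removed inconsistent: %d", sum(comp$inconsistent & !scored$low_signal))
  logf("kept: %d", nrow(calls))
  logf("threshold: %.4f (%s)", as.numeric(thr), attr(thr, "method"))

  droplets <- records[usable, setdiff(names(records), "pixels")]
  droplets <- merge(droplets, comp[usable, ], by = "droplet_id")
  droplets <- merge(droplets,
                    calls[, c("droplet_id", "score", "label")],
                    by = "droplet_id")
  droplets <- droplets[order(droplets$droplet_id), ]

  feats <- stage("phasemap", {
    sp <- intersect(species_names(manifest), names(droplets))
    droplets[, sp, drop = FALSE]
  })
  mcfg <- config$model %||% list()
  model <- stage("phasemap",
                 fit_phase_model(feats, droplets$label,
                                 kernel = mcfg$kernel %||% "linear",
                                 cost = mcfg$cost %||% 1,
                                 precipitant = manifest$precipitant))
  scfg <- config$solubility %||% list()
  sol <- stage("phasemap",
               relative_solubility(model,
                                   protein_conc = scfg$protein_conc %||% NULL,
                                   B = scfg$B %||% 200L,
                                   seed = derive_seed(seed, 999L),
                                   on_unbracketed = "censor"))

  paths <- list(droplets = file.path(config$output_dir, "droplets.csv"),
                model = file.path(config$output_dir, "phase_model.json"),
                solubility = file.path(config$output_dir, "solubility.json"),
                log = file.path(config$output_dir, "run.log"),
                diagram = file.path(config$output_dir, "phase_diagram.png"))
  write.csv(droplets, paths$droplets, row.names = FALSE)
  w <- if (model$kernel == "linear") {
    lw <- linear_weights(model)
    list(weights = as.list(lw), intercept = attr(lw, "intercept"))
  } else NULL
  jsonlite::write_json(
    list(kernel = model$kernel, cost = model$cost,
         features = model$features,
         center = as.list(model$center), scale = as.list(model$scale),
         platt = model$platt, linear_boundary = w,
         counts = as.list(model$counts)),
    paths$model, auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(relative_solubility = sol$value, sd = sol$sd,
         band = sol$band, protein_conc = sol$protein_conc,
         n_droplets = sol$n_droplets, B = sol$B,
         censored = sol$censored, precipitant = sol$precipitant),
    paths$solubility, auto_unbox = TRUE, digits = NA, na = "null")
  writeLines(log_lines, paths$log)
  stage("report", plot_phase_diagram(model, droplets, paths$diagram))

  structure(list(droplets = droplets, model = model, solubility = sol,
                 counts = list(detected = n_detected, kept = nrow(calls),
                               removed = c(rem,
                                           low_signal = sum(scored$low_signal),
                                           inconsistent = sum(comp$inconsistent &
                                                                !scored$low_signal))),
                 threshold = thr, calibration = calib,
                 paths = paths, config = config),
            class = "dropsol_run")
}

#' @export
print.dropsol_run <- function(x, ...) {
  cat("dropsol_run:", nrow(x$droplets), "droplets analysed\n")
  print(x$solubility)
  invisible(x)
}

#' Phase-diagram figure: calls plus probability gradient
#'
#' Blue/red droplet calls over the aggregation-probability surface, with
#' the boundary band (0.45 < p < 0.55) left white, in the style of a
#' droplet phase diagram. Falls back to a probability-vs-precipitant curve
#' when only one feature is free.
#'
#' @param model a [fit_phase_model()].
#' @param droplets droplet table with feature columns and \code{label}.
#' @param path output PNG path.
#' @return \code{path}, invisibly.
#' @export
plot_phase_diagram <- function(model, droplets, path) {
  grDevices::png(path, width = 900, height = 700, res = 120)
  on.exit(grDevices::dev.off())
  f <- model$features
  if (length(f) >= 2L) {
    xf <- model$precipitant
    if (!xf %in% f) xf <- f[1L]
    yf <- setdiff(f, xf)[1L]
    gx <- seq(model$ranges[1L, xf], model$ranges[2L, xf], length.out = 120L)
    gy <- seq(model$ranges[1L, yf], model$ranges[2L, yf], length.out = 120L)
    grid <- expand.grid(x = gx, y = gy)
    q <- setNames(data.frame(grid$x, grid$y), c(xf, yf))
    for (other in setdiff(f, c(xf, yf)))
      q[[other]] <- mean(model$training$points[[other]])
    grid$p <- as.numeric(aggregation_probability(model, q))
    grid$p[abs(grid$p - 0.5) < 0.05] <- NA  # white boundary band
    pts <- data.frame(x = droplets[[xf]], y = droplets[[yf]],
                      label = droplets$label)
    gp <- ggplot2::ggplot() +
      ggplot2::geom_raster(data = grid,
                           ggplot2::aes(x = x, y = y, fill = p)) +
      ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "#f7f7f7",
                                    high = "#b2182b", midpoint = 0.5,
                                    limits = c(0, 1), na.value = "white") +
      ggplot2::geom_point(data = pts,
                          ggplot2::aes(x = x, y = y, colour = label),
                          size = 0.4, alpha = 0.5) +
      ggplot2::scale_colour_manual(values = c(mixed = "#053061",
                                              aggregated = "#67001f")) +
      ggplot2::labs(x = xf, y = yf, fill = "p(aggregate)") +
      ggplot2::theme_minimal()
    print(gp)
  } else {
    gx <- seq(model$ranges[1L, f], model$ranges[2L, f], length.out = 200L)
    cur <- solubility_curve(model, gx)
    gp <- ggplot2::ggplot(cur, ggplot2::aes(x = precipitant, y = p)) +
      ggplot2::geom_line(colour = "#b2182b") +
      ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
      ggplot2::labs(x = f, y = "p(aggregate)") +
      ggplot2::theme_minimal()
    print(gp)
  }
  invisible(path)
}
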