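#' Describe the inlet/channel wiring of a droplet screen
#'
#' An experiment manifest records how the aqueous inlets of the droplet maker
#' map to fluorescence channels and stock concentrations. Each droplet is a
#' mixture of the inlet solutions; the volume fraction drawn from a barcoded
#' inlet is read out from its dye channel, and species concentrations follow
#' by linear dilution of the stocks.
#'
#' Each inlet is a list with elements \code{channel} (a channel name, or
#' \code{NA} for the unbarcoded buffer inlet) and \code{species}, a named
#' numeric vector of stock concentrations. The first species of a barcoded
#' inlet is its tracer: the species whose concentration the dye channel
#' reports (for the protein inlet the protein itself is covalently labelled,
#' for other inlets a free barcode dye is co-dissolved at fixed proportion).
#' A species may appear in several inlets (e.g. a precipitant premixed into
#' every solution so its final concentration is constant).
#'
#' @param inlets named list of inlets (see Details). At least two inlets are
#'   required and exactly one may be unbarcoded.
#' @param channels named numeric vector of imaging wavelengths (nm), e.g.
#'   \code{c(ch488 = 488, ch546 = 546, ch647 = 647)}.
#' @param protein name of the protein species (used to locate the protein
#'   channel for aggregate detection).
#' @param precipitant name of the precipitant species (the solubility axis,
#'   PEG 6000 w/v\% by default; ammonium sulfate screens simply relabel it).
#' @return object of class \code{droplet_manifest}.
#' @export
droplet_manifest <- function(inlets, channels, protein = "protein",
                             precipitant = "PEG") {
  if (!is.list(inlets) || length(inlets) < 2L)
    stop_dropsol("a manifest needs at least 2 aqueous inlets",
                 "dropsol_config_error")
  if (is.null(names(inlets)) || any(names(inlets) == ""))
    stop_dropsol("all inlets must be named", "dropsol_config_error")
  chan <- vapply(inlets, function(i) as.character(i$channel %||% NA_character_),
                 character(1))
  used <- chan[!is.na(chan)]
  if (anyDuplicated(used))
    stop_dropsol(sprintf("channel mapped to two inlets: %s",
                         paste(unique(used[duplicated(used)]), collapse = ", ")),
                 "dropsol_config_error")
  if (!all(used %in% names(channels)))
    stop_dropsol("inlet references a channel absent from `channels`",
                 "dropsol_config_error")
  for (nm in names(inlets)) {
    sp <- inlets[[nm]]$species %||% numeric(0)
    if (!is.na(chan[nm]) && length(sp) == 0L)
      stop_dropsol(sprintf("barcoded inlet '%s' has no species", nm),
                   "dropsol_config_error")
    if (any(sp < 0))
      stop_dropsol(sprintf("negative stock concentration in inlet '%s'", nm),
                   "dropsol_config_error")
  }
  structure(list(inlets = inlets, channels = channels,
                 protein = protein, precipitant = precipitant),
            class = "droplet_manifest")
}

#' @export
print.droplet_manifest <- function(x, ...) {
  cat("droplet_manifest:", length(x$inlets), "inlets,",
      length(x$channels), "channels\n")
  for (nm in names(x$inlets)) {
    i <- x$inlets[[nm]]
    ch <- i$channel %||% NA
    cat(sprintf("  %-10s %-6s %s\n", nm, ifelse(is.na(ch), "-", ch),
                paste(sprintf("%s=%g", names(i$species), i$species),
                      collapse = ", ")))
  }
  invisible(x)
}

# names of inlets carrying a barcode dye
barcoded_inlets <- function(manifest) {
  names(Filter(function(i) !is.na(i$channel %||% NA), manifest$inlets))
}

# the single unbarcoded (remainder) inlet, or NA
buffer_inlet <- function(manifest) {
  b <- setdiff(names(manifest$inlets), barcoded_inlets(manifest))
  if (length(b) == 0L) NA_character_ else b[1L]
}

inlet_channel <- function(manifest, inlet) manifest$inlets[[inlet]]$channel

# tracer species of a barcoded inlet (first species: the one its dye reports)
tracer_species <- function(manifest, inlet) {
  names(manifest$inlets[[inlet]]$species)[1L]
}

tracer_stock <- function(manifest, inlet) {
  unname(manifest$inlets[[inlet]]$species[1L])
}

species_names <- function(manifest) {
  unique(unlist(lapply(manifest$inlets, function(i) names(i$species))))
}

# inlet x species matrix of stock concentrations
stock_matrix <- function(manifest) {
  sp <- species_names(manifest)
  m <- matrix(0, length(manifest$inlets), length(sp),
              dimnames = list(names(manifest$inlets), sp))
  for (nm in names(manifest$inlets)) {
    s <- manifest$inlets[[nm]]$species
    m[nm, names(s)] <- s
  }
  m
}

# channel (name) through which the labelled protein is imaged
protein_channel <- function(manifest) {
  for (nm in barcoded_inlets(manifest)) {
    if (manifest$protein %in% names(manifest$inlets[[nm]]$species))
      return(inlet_channel(manifest, nm))
  }
  stop_dropsol("no barcoded inlet carries the protein species",
               "dropsol_config_error")
}
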