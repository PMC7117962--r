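# End-to-end orchestration (simulate -> reference -> spectra -> phase) and
# recording serialization (binary voltages + JSON sidecar).

grid_to_spec <- function(grid) {
  sp <- list(n_rows = grid$n_rows, n_cols = grid$n_cols, pitch = grid$pitch,
             good_mask = as.vector(grid$good_mask), kind = grid$kind,
             ids = grid$ids)
  if (grid$kind == "bipolar-virtual") {
    sp$minuend <- grid$minuend
    sp$subtrahend <- grid$subtrahend
    sp$scheme <- grid$scheme
    sp$pos <- as.vector(grid$pos)
  }
  sp
}

grid_from_spec <- function(sp) {
  base <- build_grid(sp$n_rows, sp$n_cols, sp$pitch,
                     matrix(sp$good_mask, sp$n_rows, sp$n_cols))
  if (sp$kind == "real") return(base)
  if (sp$kind == "csd") return(csd_grid(base))
  if (sp$kind == "bipolar-virtual") {
    g <- base
    g$ids <- seq_along(sp$minuend)
    g$row <- NULL; g$col <- NULL
    g$pos <- matrix(sp$pos, ncol = 2, dimnames = list(NULL, c("x", "y")))
    g$kind <- "bipolar-virtual"
    g$minuend <- sp$minuend
    g$subtrahend <- sp$subtrahend
    g$scheme <- sp$scheme
    return(g)
  }
  stop("unknown grid kind '", sp$kind, "' in sidecar")
}

#' Write a recording as binary voltages plus a JSON sidecar
#'
#' Voltages are stored as little-endian float64 in `<path>.bin` in array
#' order (electrode fastest, then trial, then time); `<path>.json` holds the
#' shape, order, sampling rate, scheme, lineage and grid specification.
#' The round-trip through [read_recording()] is bit-exact.
#'
#' @param rec an `epoched_recording`.
#' @param path basename (without extension) for the two files.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "epoched_recording"))
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(rec$samples), con, size = 8, endian = "little")
  meta <- list(shape = dim(rec$samples),
               order = "electrode,trial,time (electrode fastest)",
               dtype = "float64-le",
               sampling_rate = rec$sampling_rate,
               scheme = rec$scheme, lineage = rec$lineage,
               grid = grid_to_spec(rec$grid))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' @param path basename used at write time.
#' @return an `epoched_recording`.
#' @export
read_recording <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    stop("missing sidecar metadata file: ", sidecar)
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  shape <- as.integer(meta$shape)
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  v <- readBin(con, "double", n = prod(shape), size = 8, endian = "little")
  if (length(v) != prod(shape)) {
    stop("binary payload size does not match sidecar shape")
  }
  grid <- grid_from_spec(meta$grid)
  epoched_recording(array(v, shape), meta$sampling_rate, grid,
                    scheme = meta$scheme, lineage = meta$lineage)
}

#' Run the full analysis pipeline on a synthetic or supplied recording
#'
#' For each requested reference scheme: re-references the input recording,
#' computes tapered coefficients, the (optionally roll-off corrected and
#' noise-masked) power spectrum, a sliding-window slope profile of the mean
#' PSD across electrodes, and pairwise phase statistics by distance bin.
#' Results are returned in-process and, when `out_dir` is given, written as
#' schema-stable CSV tables plus a JSON manifest.
#'
#' @param config list with elements: `synthetic` (a `synthetic_config`) or
#'   `recording` (an `epoched_recording`); `schemes` (subset of
#'   `c("single-wire", "average", "bipolar", "csd")`); `window` (seconds,
#'   default whole epoch); `time_bandwidth`, `k` (taper spec); `mask_freqs`
#'   (default `c(100, 120, 240, 360)`); `rolloff` (logical, default FALSE
#'   for synthetic data); `slope_centers`, `slope_half_width`;
#'   `distance_bins`; `max_pair_distance` (default 4 mm);
#'   `pair_frequencies` (Hz subset for phase stats, default every 10 Hz up
#'   to 400); `bipolar_max_distance` (default one pitch, i.e. nearest
#'   neighbours); `seed`; `out_dir`.
#' @return list with per-scheme entries: `psd` (`power_spectrum`), `slopes`
#'   (data.frame, mean PSD across electrodes), `pair_stats` (aggregated
#'   data.frame); plus `manifest`.
#' @export
run_pipeline <- function(config) {
  t0 <- Sys.time()
  schemes <- config$schemes %||% c("single-wire", "average", "bipolar", "csd")
  if (!is.null(config$recording)) {
    rec <- config$recording
  } else if (!is.null(config$synthetic)) {
    rec <- generate_recording(config$synthetic, seed = config$seed)
  } else {
    stop("pipeline config needs either 'recording' or 'synthetic'")
  }
  window <- config$window %||% NULL
  tb <- config$time_bandwidth %||% 1
  k <- config$k %||% 1
  mask_freqs <- config$mask_freqs %||% c(100, 120, 240, 360)
  bins <- config$distance_bins %||% default_distance_bins()
  maxd <- config$max_pair_distance %||% 4
  centers <- config$slope_centers %||% seq(20, 400, by = 10)
  hw <- config$slope_half_width %||% 15
  pair_freqs <- config$pair_frequencies %||% seq(10, 400, by = 10)
  out <- list()
  log <- list()
  for (scheme in schemes) {
    ts <- Sys.time()
    rr <- switch(scheme,
      "single-wire" = single_wire(rec),
      "average" = average_reference(rec),
      "bipolar" = bipolar_reference(
        rec, bipolar_virtual_grid(rec$grid,
                                  max_distance = config$bipolar_max_distance
                                  %||% rec$grid$pitch)),
      "csd" = csd_reference(rec),
      stop("unknown scheme '", scheme, "'"))
    co <- spectral_coefficients(rr, window = window, time_bandwidth = tb, k = k)
    psd <- power_spectrum(co)
    if (isTRUE(config$rolloff)) psd <- rolloff_correction(psd)
    if (length(mask_freqs)) psd <- mask_frequencies(psd, mask_freqs)
    mean_psd <- psd
    mean_psd$power <- matrix(colMeans(psd$power), 1)
    slopes <- slope_profile(mean_psd, 1, f_centers = centers, half_width = hw)
    pairs <- unique_pairs(rr$grid, max_distance = maxd, bins = bins)
    if (rr$grid$kind %in% c("bipolar-virtual", "csd")) {
      pairs <- flag_shared_components(pairs, rr$grid)
    }
    prof <- pair_profiles(co, pairs, frequencies = pair_freqs)
    out[[scheme]] <- list(psd = psd, slopes = slopes,
                          pair_stats = prof$by_bin)
    log[[scheme]] <- list(stage = scheme,
                          seconds = as.numeric(Sys.time() - ts, units = "secs"),
                          n_electrodes = length(rr$grid$ids),
                          n_pairs = nrow(pairs))
  }
  manifest <- list(schemes = schemes, seed = config$seed,
                   window = window, mask_freqs = mask_freqs,
                   slope_half_width = hw, distance_bins = bins,
                   r_version = as.character(getRversion()),
                   total_seconds = as.numeric(Sys.time() - t0, units = "secs"),
                   stages = log)
  out$manifest <- manifest
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (scheme in schemes) {
      psd <- out[[scheme]]$psd
      psd_df <- data.frame(
        electrode = rep(psd$grid$ids, times = length(psd$frequencies)),
        frequency = rep(psd$frequencies, each = nrow(psd$power)),
        power = as.vector(psd$power), scheme = scheme)
      utils::write.csv(psd_df,
                       file.path(config$out_dir, paste0("psd_", scheme, ".csv")),
                       row.names = FALSE)
      sl <- out[[scheme]]$slopes; sl$scheme <- scheme
      utils::write.csv(sl,
                       file.path(config$out_dir, paste0("slopes_", scheme, ".csv")),
                       row.names = FALSE)
      ps <- out[[scheme]]$pair_stats; ps$scheme <- scheme
      utils::write.csv(ps,
                       file.path(config$out_dir, paste0("pairstats_", scheme, ".csv")),
                       row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
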