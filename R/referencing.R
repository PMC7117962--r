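# Re-referencing transforms.  All schemes act sample-wise in the time domain
# and are linear, so they commute with Fourier analysis; tests exploit this.

#' Construct an epoched multi-electrode recording
#'
#' @param samples numeric array of voltages (uV) indexed
#'   (electrode, trial, time).
#' @param sampling_rate in Hz.
#' @param grid the `electrode_grid` the electrode axis refers to; electrode i
#'   of `samples` is `grid$ids[i]`.
#' @param scheme reference-scheme provenance tag.
#' @param lineage free-text description of transforms applied so far.
#' @return object of class `epoched_recording`.
#' @export
epoched_recording <- function(samples, sampling_rate, grid,
                              scheme = "single-wire", lineage = "raw") {
  stopifnot(is.array(samples), length(dim(samples)) == 3)
  if (dim(samples)[1] != length(grid$ids)) {
    stop("electrode axis (", dim(samples)[1], ") does not match grid (",
         length(grid$ids), " electrodes)")
  }
  if (!all(is.finite(samples))) stop("samples contain non-finite values")
  scheme <- match.arg(scheme, c("single-wire", "average", "bipolar", "csd"))
  if (scheme == "csd" && grid$kind != "csd") {
    stop("scheme 'csd' requires a grid of kind 'csd'")
  }
  if (scheme == "bipolar" && grid$kind != "bipolar-virtual") {
    stop("scheme 'bipolar' requires a grid of kind 'bipolar-virtual'")
  }
  r <- list(samples = samples, sampling_rate = sampling_rate, grid = grid,
            scheme = scheme, lineage = lineage)
  class(r) <- "epoched_recording"
  r
}

#' @export
print.epoched_recording <- function(x, ...) {
  d <- dim(x$samples)
  cat(sprintf("<epoched_recording> %d electrodes x %d trials x %d samples @ %g Hz, scheme=%s\n",
              d[1], d[2], d[3], x$sampling_rate, x$scheme))
  invisible(x)
}

n_trials <- function(rec) dim(rec$samples)[2]
n_samples <- function(rec) dim(rec$samples)[3]

#' Identity pass-through tagging the single-wire scheme
#'
#' The raw recording is already referenced against the headstage wire; this
#' just normalises provenance.  Any neural activity picked up by the wire
#' itself appears as an identical component on every electrode (modelled by
#' the generator's `reference_pickup`).
#'
#' @param rec an `epoched_recording`.
#' @return the recording, scheme tagged `"single-wire"`.
#' @export
single_wire <- function(rec) {
  stopifnot(inherits(rec, "epoched_recording"))
  rec$scheme <- "single-wire"
  rec
}

#' Average reference
#'
#' Subtracts, per time sample and trial, the mean over `subset` from every
#' electrode.  Electrodes outside the subset are still re-referenced against
#' it.  Idempotent over the same subset: the subset mean of the output is
#' exactly zero.
#'
#' @param rec a single-wire `epoched_recording`.
#' @param subset electrode ids entering the reference average (default: all
#'   electrodes in the recording).
#' @return an `epoched_recording` with scheme `"average"`, same grid.
#' @export
average_reference <- function(rec, subset = NULL) {
  stopifnot(inherits(rec, "epoched_recording"))
  if (rec$scheme != "single-wire") {
    stop("average_reference() expects a single-wire recording, got '",
         rec$scheme, "'")
  }
  if (is.null(subset)) subset <- rec$grid$ids
  if (length(subset) < 1) stop("reference subset is empty")
  idx <- match(subset, rec$grid$ids)
  if (anyNA(idx)) stop("subset contains ids not in the recording")
  nE <- dim(rec$samples)[1]
  m <- colMeans(rec$samples[idx, , , drop = FALSE])   # trial x time
  out <- rec$samples - rep(m, each = nE)
  epoched_recording(out, rec$sampling_rate, rec$grid, scheme = "average",
                    lineage = paste0(rec$lineage, " | average(",
                                     length(subset), " electrodes)"))
}

#' Bipolar reference onto a virtual grid
#'
#' Each virtual electrode's trace is minuend trace minus subtrahend trace,
#' notionally recorded at the midpoint of the contributing pair.
#'
#' @param rec a single-wire `epoched_recording`.
#' @param virtual an `electrode_grid` of kind `"bipolar-virtual"` (see
#'   [bipolar_virtual_grid()]); all its real electrodes must exist in `rec`.
#' @return an `epoched_recording` on the virtual grid, scheme `"bipolar"`.
#' @export
bipolar_reference <- function(rec, virtual) {
  stopifnot(inherits(rec, "epoched_recording"),
            inherits(virtual, "electrode_grid"))
  if (rec$scheme != "single-wire") {
    stop("bipolar_reference() expects a single-wire recording")
  }
  if (virtual$kind != "bipolar-virtual") stop("grid is not bipolar-virtual")
  im <- match(virtual$minuend, rec$grid$ids)
  is <- match(virtual$subtrahend, rec$grid$ids)
  if (anyNA(im) || anyNA(is)) {
    stop("virtual grid references real electrodes missing from the recording")
  }
  out <- rec$samples[im, , , drop = FALSE] - rec$samples[is, , , drop = FALSE]
  epoched_recording(out, rec$sampling_rate, virtual, scheme = "bipolar",
                    lineage = paste0(rec$lineage, " | bipolar(",
                                     virtual$scheme, ")"))
}

#' Current source density reference
#'
#' For each electrode with four good lattice neighbours at one pitch,
#' subtracts the neighbour mean: CSD(x, y) = V(x, y) - (V(x-1, y) +
#' V(x+1, y) + V(x, y-1) + V(x, y+1)) / 4.  Computed on raw voltages (uV);
#' no 1/pitch^2 Laplacian scaling is applied.
#'
#' @param rec a single-wire `epoched_recording`.
#' @return an `epoched_recording` restricted to eligible electrodes, scheme
#'   `"csd"`.
#' @export
csd_reference <- function(rec) {
  stopifnot(inherits(rec, "epoched_recording"))
  if (rec$scheme != "single-wire") {
    stop("csd_reference() expects a single-wire recording")
  }
  cg <- csd_grid(rec$grid)
  keep <- match(cg$ids, rec$grid$ids)
  out <- rec$samples[keep, , , drop = FALSE]
  for (i in seq_along(cg$ids)) {
    nb <- match(cg$neighbors[[i]], rec$grid$ids)
    out[i, , ] <- out[i, , ] - colMeans(rec$samples[nb, , , drop = FALSE])
  }
  epoched_recording(out, rec$sampling_rate, cg, scheme = "csd",
                    lineage = paste0(rec$lineage, " | csd"))
}
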