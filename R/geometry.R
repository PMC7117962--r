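# Electrode-grid geometry: lattice positions, pair tables, CSD neighborhoods,
# virtual bipolar electrodes, shared-component bookkeeping.

#' Build a regular 2D electrode grid
#'
#' Electrodes sit on a regular lattice with spacing `pitch` (mm).  Sites are
#' numbered row-major starting at 1; the site at row r, column c has position
#' (x, y) = ((c-1) * pitch, (r-1) * pitch), so the lattice origin is the first
#' site.  Only sites marked good in `good_mask` become electrodes.
#'
#' @param n_rows,n_cols lattice dimensions (>= 1).
#' @param pitch inter-electrode spacing in mm (default 0.4, a Utah-style
#'   microelectrode array).
#' @param good_mask logical matrix `n_rows x n_cols`; `TRUE` marks a usable
#'   electrode.  Default: all good.
#' @return An object of class `electrode_grid` with fields `ids` (integer
#'   site indices of good electrodes), `row`, `col`, `pos` (n x 2 matrix of
#'   x/y positions in mm), `center` (centroid of good electrodes), `pitch`,
#'   `good_mask` and `kind = "real"`.
#' @export
build_grid <- function(n_rows, n_cols, pitch = 0.4, good_mask = NULL) {
  stopifnot(n_rows >= 1, n_cols >= 1, pitch > 0)
  if (is.null(good_mask)) {
    good_mask <- matrix(TRUE, n_rows, n_cols)
  }
  good_mask <- as.matrix(good_mask)
  if (!identical(dim(good_mask), c(as.integer(n_rows), as.integer(n_cols)))) {
    stop("good_mask must be a ", n_rows, " x ", n_cols, " logical matrix")
  }
  if (!any(good_mask)) {
    stop("no usable electrodes: good_mask is all FALSE")
  }
  idx <- which(t(good_mask))            # row-major site numbering
  row <- (idx - 1L) %/% n_cols + 1L
  col <- (idx - 1L) %% n_cols + 1L
  pos <- cbind(x = (col - 1L) * pitch, y = (row - 1L) * pitch)
  g <- list(
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    pitch = pitch, good_mask = good_mask,
    ids = idx, row = row, col = col, pos = pos,
    center = colMeans(pos), kind = "real"
  )
  class(g) <- "electrode_grid"
  g
}

#' @export
print.electrode_grid <- function(x, ...) {
  cat(sprintf("<electrode_grid> %dx%d lattice, pitch %g mm, %d electrodes (%s)\n",
              x$n_rows, x$n_cols, x$pitch, length(x$ids), x$kind))
  invisible(x)
}

n_electrodes <- function(grid) length(grid$ids)

#' Default distance-bin edges (mm)
#'
#' Reporting bins for pairwise statistics: nearest neighbours, short,
#' intermediate and long range.  Left-open, right-closed intervals.
#' @export
default_distance_bins <- function() c(0, 0.4, 1.2, 2.4, 4.0)

#' Assign distance-bin labels
#'
#' @param distance numeric vector of pair distances (mm).
#' @param bins increasing vector of bin edges; distances fall in
#'   left-open/right-closed intervals.  Distances outside all bins get `NA`.
#' @param tol absolute tolerance (mm) absorbing floating-point error in
#'   lattice arithmetic (e.g. `sqrt(0.4^2)` exceeding 0.4 by one ulp), so
#'   exact lattice distances bin unambiguously.
#' @return character vector of labels like `"(0.4,1.2]"`.
#' @export
assign_distance_bins <- function(distance, bins = default_distance_bins(),
                                 tol = 1e-6) {
  labels <- paste0("(", bins[-length(bins)], ",", bins[-1], "]")
  idx <- findInterval(distance, bins + tol, left.open = TRUE)
  out <- rep(NA_character_, length(distance))
  ok <- idx >= 1L & idx <= length(labels)
  out[ok] <- labels[idx[ok]]
  out
}

#' Unique electrode pairs within a distance cutoff
#'
#' Enumerates unordered pairs of grid electrodes, discarding pairs farther
#' apart than `max_distance`.  Virtual (bipolar) grids are supported; the
#' shared-component flag is initialised to `FALSE` and filled by
#' [flag_shared_components()].
#'
#' @param grid an `electrode_grid`.
#' @param max_distance cutoff in mm (default 4).
#' @param bins distance-bin edges passed to [assign_distance_bins()].
#' @return A `data.frame` of class `pair_table` with columns `id_a`, `id_b`,
#'   `distance_mm`, `bin`, `shared_component`, `shared_kind`.
#' @export
unique_pairs <- function(grid, max_distance = 4,
                         bins = default_distance_bins()) {
  stopifnot(inherits(grid, "electrode_grid"))
  if (max_distance <= 0) stop("max_distance must be positive")
  n <- n_electrodes(grid)
  if (n < 2) stop("need at least 2 electrodes to form pairs")
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  d <- sqrt((grid$pos[ij[, 1], 1] - grid$pos[ij[, 2], 1])^2 +
            (grid$pos[ij[, 1], 2] - grid$pos[ij[, 2], 2])^2)
  keep <- d <= max_distance + 1e-6
  pt <- data.frame(
    id_a = grid$ids[ij[keep, 1]],
    id_b = grid$ids[ij[keep, 2]],
    distance_mm = d[keep],
    bin = assign_distance_bins(d[keep], bins),
    shared_component = FALSE,
    shared_kind = "none",
    stringsAsFactors = FALSE
  )
  class(pt) <- c("pair_table", "data.frame")
  attr(pt, "grid_kind") <- grid$kind
  pt
}

# Lattice neighbours at exactly one pitch (up/down/left/right), as site ids.
# Returns NA for neighbours falling off the lattice.
lattice_neighbors <- function(grid, id) {
  r <- (id - 1L) %/% grid$n_cols + 1L
  c <- (id - 1L) %% grid$n_cols + 1L
  nb <- rbind(c(r - 1L, c), c(r + 1L, c), c(r, c - 1L), c(r, c + 1L))
  ok <- nb[, 1] >= 1L & nb[, 1] <= grid$n_rows &
        nb[, 2] >= 1L & nb[, 2] <= grid$n_cols
  out <- rep(NA_integer_, 4L)
  out[ok] <- (nb[ok, 1] - 1L) * grid$n_cols + nb[ok, 2]
  out
}

#' Electrodes eligible for CSD referencing
#'
#' An electrode is eligible when all four lattice neighbours at one pitch
#' (up, down, left, right) exist and are good; electrodes on the lattice
#' boundary are therefore never eligible.
#'
#' @param grid a real `electrode_grid`.
#' @return integer vector of eligible electrode ids (possibly empty).
#' @export
csd_eligible <- function(grid) {
  stopifnot(inherits(grid, "electrode_grid"))
  if (grid$kind != "real") stop("csd_eligible() needs a real electrode grid")
  good <- grid$ids
  ok <- vapply(good, function(id) {
    nb <- lattice_neighbors(grid, id)
    !anyNA(nb) && all(nb %in% good)
  }, logical(1))
  good[ok]
}

#' Restrict a grid to its CSD-eligible electrodes
#'
#' @param grid a real `electrode_grid`.
#' @return an `electrode_grid` of kind `"csd"`; each electrode carries its
#'   four-neighbour set in the `neighbors` field.
#' @export
csd_grid <- function(grid) {
  elig <- csd_eligible(grid)
  if (length(elig) == 0) stop("no CSD-eligible electrodes in grid")
  keep <- match(elig, grid$ids)
  g <- grid
  g$ids <- grid$ids[keep]
  g$row <- grid$row[keep]
  g$col <- grid$col[keep]
  g$pos <- grid$pos[keep, , drop = FALSE]
  g$kind <- "csd"
  g$neighbors <- lapply(elig, function(id) lattice_neighbors(grid, id))
  names(g$neighbors) <- as.character(elig)
  g
}

#' Virtual bipolar electrode grid
#'
#' One virtual electrode per retained real-electrode pair, located at the
#' pair midpoint.  The bipolar signal is minuend - subtrahend.  Under the
#' `center-out` scheme the minuend is the electrode nearer the grid centre
#' (avoiding directional bias); ties are broken toward the lower electrode
#' id.  Under `fixed-direction` the minuend is the electrode with the lower
#' (row, col) index.  With `restricted = TRUE` a greedy maximal matching over
#' pairs sorted by (distance, id) ensures each real electrode is used at most
#' once.
#'
#' @param grid a real `electrode_grid`.
#' @param scheme `"center-out"` (default) or `"fixed-direction"`.
#' @param max_distance discard real pairs farther apart than this (mm).
#' @param restricted logical; use each real electrode at most once.
#' @return an `electrode_grid` of kind `"bipolar-virtual"`; `ids` are new
#'   virtual ids 1..n, and `minuend` / `subtrahend` give the ordered real
#'   electrode ids of each virtual electrode.
#' @export
bipolar_virtual_grid <- function(grid, scheme = c("center-out", "fixed-direction"),
                                 max_distance = 4, restricted = FALSE) {
  stopifnot(inherits(grid, "electrode_grid"))
  if (grid$kind != "real") stop("bipolar referencing needs a real grid")
  scheme <- match.arg(scheme)
  pairs <- unique_pairs(grid, max_distance = max_distance)
  if (restricted) {
    ord <- order(pairs$distance_mm, pairs$id_a, pairs$id_b)
    used <- integer(0)
    keep <- logical(nrow(pairs))
    for (i in ord) {
      if (!(pairs$id_a[i] %in% used) && !(pairs$id_b[i] %in% used)) {
        keep[i] <- TRUE
        used <- c(used, pairs$id_a[i], pairs$id_b[i])
      }
    }
    pairs <- pairs[keep, , drop = FALSE]
  }
  ia <- match(pairs$id_a, grid$ids)
  ib <- match(pairs$id_b, grid$ids)
  if (scheme == "center-out") {
    da <- sqrt(rowSums((grid$pos[ia, , drop = FALSE] -
                        matrix(grid$center, nrow(pairs), 2, byrow = TRUE))^2))
    db <- sqrt(rowSums((grid$pos[ib, , drop = FALSE] -
                        matrix(grid$center, nrow(pairs), 2, byrow = TRUE))^2))
    # minuend = nearer to centre; tie -> lower id (id_a < id_b by construction)
    a_first <- da < db | (abs(da - db) < 1e-9)
  } else {
    # minuend = lower (row, col); ids are row-major so id order encodes it
    a_first <- rep(TRUE, nrow(pairs))
  }
  minu <- ifelse(a_first, pairs$id_a, pairs$id_b)
  subt <- ifelse(a_first, pairs$id_b, pairs$id_a)
  im <- match(minu, grid$ids)
  is <- match(subt, grid$ids)
  pos <- (grid$pos[im, , drop = FALSE] + grid$pos[is, , drop = FALSE]) / 2
  colnames(pos) <- c("x", "y")
  g <- list(
    n_rows = grid$n_rows, n_cols = grid$n_cols, pitch = grid$pitch,
    good_mask = grid$good_mask,
    ids = seq_len(nrow(pairs)), row = NULL, col = NULL,
    pos = pos, center = grid$center, kind = "bipolar-virtual",
    minuend = minu, subtrahend = subt, scheme = scheme
  )
  class(g) <- "electrode_grid"
  g
}

#' Flag referenced-signal pairs that share a real-electrode term
#'
#' Two bipolar virtual electrodes share a component when their real-electrode
#' sets intersect.  Two CSD electrodes share a component when the terms of
#' their CSD expansions (the electrode itself plus its four neighbours, the
#' latter weighted -1/4) overlap: adjacent electrodes (1 pitch, each appears
#' in the other's neighbour average, phase difference pi), diagonal
#' (sqrt(2) pitch, two shared neighbours, phase 0) and two-pitch pairs (one
#' shared neighbour, phase 0).  Such pairs show spuriously high coherence
#' and deterministic phase offsets and must never be pooled silently with
#' artifact-free pairs.
#'
#' @param pairs a `pair_table` built over `grid`'s electrodes.
#' @param grid the `electrode_grid` the pairs refer to; its `kind` must be
#'   `"bipolar-virtual"` or `"csd"`.
#' @return the pair table with `shared_component` and `shared_kind` filled.
#' @export
flag_shared_components <- function(pairs, grid) {
  stopifnot(inherits(pairs, "pair_table"), inherits(grid, "electrode_grid"))
  tol <- 1e-6
  if (grid$kind == "bipolar-virtual") {
    sets <- cbind(grid$minuend, grid$subtrahend)
    ia <- match(pairs$id_a, grid$ids)
    ib <- match(pairs$id_b, grid$ids)
    shared <- (sets[ia, 1] == sets[ib, 1]) | (sets[ia, 1] == sets[ib, 2]) |
              (sets[ia, 2] == sets[ib, 1]) | (sets[ia, 2] == sets[ib, 2])
    pairs$shared_component <- shared
    pairs$shared_kind <- ifelse(shared, "bipolar-shared-electrode", "none")
  } else if (grid$kind == "csd") {
    terms <- lapply(seq_along(grid$ids), function(i)
      c(grid$ids[i], grid$neighbors[[i]]))
    ia <- match(pairs$id_a, grid$ids)
    ib <- match(pairs$id_b, grid$ids)
    overlap <- vapply(seq_len(nrow(pairs)), function(k)
      length(intersect(terms[[ia[k]]], terms[[ib[k]]])) > 0, logical(1))
    p <- grid$pitch
    kind <- rep("none", nrow(pairs))
    adj  <- abs(pairs$distance_mm - p) < tol
    diag <- abs(pairs$distance_mm - sqrt(2) * p) < tol
    two  <- abs(pairs$distance_mm - 2 * p) < tol
    kind[overlap & adj]  <- "csd-adjacent"
    kind[overlap & diag] <- "csd-diagonal"
    kind[overlap & two]  <- "csd-two-pitch"
    pairs$shared_component <- overlap & (adj | diag | two)
    pairs$shared_kind <- kind
  } else {
    stop("flag_shared_components() needs a bipolar-virtual or csd grid, got kind '",
         grid$kind, "'")
  }
  pairs
}
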