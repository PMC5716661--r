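#' Three-dimensional occupancy grid over a trajectory
#'
#' Histograms atom centres on a regular grid and reports, per bin, the
#' fraction of frames in which at least one selected atom centre falls in
#' the bin (binary per-frame convention; density-weighted variants exist in
#' other tools, the binary choice is recorded in the result).
#'
#' @param system A [pore_system()].
#' @param selection Integer vector of atom indices to count.
#' @param spacing Grid spacing (Angstrom), > 0; default 0.5.
#' @param frames Frame indices to use (default all).
#' @param edges Optional list of precomputed bin edges (`x`, `y`, `z`) in
#'   axis-frame coordinates; computed from the selection's bounding box
#'   (padded by one spacing) when `NULL`.
#' @return An object of class `occupancy_grid`: list with `occupancy` (3-D
#'   array in \[0, 1\]), `edges`, `spacing`, `selection`, `n_frames` and
#'   `convention = "binary-per-frame"`.
#' @export
occupancy_grid <- function(system, selection, spacing = 0.5, frames = NULL,
                           edges = NULL) {
  stopifnot(inherits(system, "pore_system"))
  if (!length(selection)) stop("empty selection")
  if (spacing <= 0) stop("'spacing' must be positive")
  if (is.null(frames)) frames <- seq_len(n_frames(system))
  if (!length(frames)) stop("need at least one frame")

  coords <- lapply(frames, function(f)
    axis_coordinates(system$frames[[f]][selection, , drop = FALSE], system))
  if (is.null(edges)) {
    all_xyz <- do.call(rbind, coords)
    edges <- lapply(1:3, function(k) {
      rng <- range(all_xyz[, k])
      lo <- floor((rng[1L] - spacing) / spacing) * spacing
      n <- ceiling((rng[2L] + spacing - lo) / spacing)
      lo + (0:n) * spacing
    })
    names(edges) <- c("x", "y", "z")
  }
  nb <- vapply(edges, function(e) length(e) - 1L, 1L)
  counts <- array(0L, dim = nb)
  for (xyz in coords) {
    ix <- findInterval(xyz[, 1L], edges$x, rightmost.closed = TRUE)
    iy <- findInterval(xyz[, 2L], edges$y, rightmost.closed = TRUE)
    iz <- findInterval(xyz[, 3L], edges$z, rightmost.closed = TRUE)
    ok <- ix >= 1L & ix <= nb[1L] & iy >= 1L & iy <= nb[2L] &
      iz >= 1L & iz <= nb[3L]
    lin <- unique(((iz[ok] - 1L) * nb[2L] + (iy[ok] - 1L)) * nb[1L] + ix[ok])
    counts[lin] <- counts[lin] + 1L
  }
  structure(list(occupancy = counts / length(frames), edges = edges,
                 spacing = spacing, selection = selection,
                 n_frames = length(frames),
                 convention = "binary-per-frame"),
            class = "occupancy_grid")
}

#' @export
print.occupancy_grid <- function(x, ...) {
  cat(sprintf("<occupancy_grid> %s bins @ %.2f A, %d frame(s), %d occupied bin(s)\n",
              paste(dim(x$occupancy), collapse = " x "), x$spacing,
              x$n_frames, sum(x$occupancy > 0)))
  invisible(x)
}

#' XY-integrated water linear density along the pore
#'
#' For each frame and axial slab, counts water oxygens whose perpendicular
#' distance from the axis is within the pore radius at the slab centre (the
#' pore radius profile bounds the XY integration domain) and divides by the
#' slab width, giving a linear number density in Angstrom^-1.
#'
#' @param system A [pore_system()].
#' @param pore_profile A [pore_radius_profile()], or a list of one profile
#'   per analysed frame for per-frame boundaries.
#' @param z_edges Strictly increasing slab edges (Angstrom) within the
#'   profile support.
#' @param frames Frame indices (default all).
#' @return An object of class `linear_density`: list with `z_mid` (slab
#'   centres), `z_edges`, `density` (frames x slabs matrix, Angstrom^-1),
#'   `counts` (integer water counts per frame and slab) and `frames`.
#' @export
water_linear_density <- function(system, pore_profile, z_edges,
                                 frames = NULL) {
  stopifnot(inherits(system, "pore_system"))
  if (is.unsorted(z_edges, strictly = TRUE))
    stop("'z_edges' must be strictly increasing")
  if (is.null(frames)) frames <- seq_len(n_frames(system))
  per_frame <- !inherits(pore_profile, "pore_radius_profile")
  if (per_frame && length(pore_profile) != length(frames))
    stop("per-frame profiles must match the number of analysed frames")

  wat <- water_indices(system)
  z_mid <- (z_edges[-1L] + z_edges[-length(z_edges)]) / 2
  dz <- diff(z_edges)
  n_slab <- length(z_mid)
  counts <- matrix(0L, nrow = length(frames), ncol = n_slab)
  for (k in seq_along(frames)) {
    prof <- if (per_frame) pore_profile[[k]] else pore_profile
    r_bound <- stats::approx(prof$z, prof$radius, xout = z_mid, rule = 2)$y
    if (length(wat)) {
      xyz <- axis_coordinates(system$frames[[frames[k]]][wat, , drop = FALSE],
                              system)
      slab <- findInterval(xyz[, 3L], z_edges, rightmost.closed = TRUE)
      ok <- slab >= 1L & slab <= n_slab
      r_perp <- sqrt(xyz[ok, 1L]^2 + xyz[ok, 2L]^2)
      inside <- r_perp <= r_bound[slab[ok]]
      if (any(inside))
        counts[k, ] <- tabulate(slab[ok][inside], nbins = n_slab)
    }
  }
  structure(list(z_mid = z_mid, z_edges = z_edges,
                 density = sweep(counts, 2L, dz, `/`),
                 counts = counts, frames = frames),
            class = "linear_density")
}

#' @export
print.linear_density <- function(x, ...) {
  cat(sprintf("<linear_density> %d frame(s) x %d slab(s), mean density %.4g A^-1\n",
              nrow(x$density), ncol(x$density), mean(x$density)))
  invisible(x)
}

#' Pore continuity classification
#'
#' A frame is "continuous" when every axial slab within `z_range` has
#' strictly positive water linear density — the signature of an
#' uninterrupted water column (hydrated, conductive pore).
#'
#' @param density A [water_linear_density()] result.
#' @param z_range Length-2 numeric range (Angstrom) of slab centres to test.
#' @return List with `continuous` (logical per frame) and `fraction`
#'   (fraction of continuous frames).
#' @export
pore_continuity <- function(density, z_range) {
  stopifnot(inherits(density, "linear_density"))
  sel <- density$z_mid >= z_range[1L] & density$z_mid <= z_range[2L]
  if (!any(sel)) stop("'z_range' contains no slabs")
  cont <- apply(density$density[, sel, drop = FALSE] > 0, 1L, all)
  list(continuous = cont, fraction = mean(cont))
}
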