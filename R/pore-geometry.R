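#' Pore radius profile along the axis
#'
#' Simplified on-axis pore radius: for each grid position z the radius is
#' the distance from the axis point (0, 0, z) to the nearest atom surface,
#' `min_i(|r_i - (0,0,z)| - vdw_i)`, floored at zero. Unlike Monte-Carlo
#' centre-optimising profile tools, the probe centre is kept on the fixed
#' axis, which is adequate for straight pores.
#'
#' Water molecules are excluded from the radius calculation by default since
#' the profile is used as the boundary for water integration.
#'
#' @param system A [pore_system()].
#' @param z_grid Strictly increasing axial positions (Angstrom, axis frame).
#' @param frame Frame index (default 1).
#' @param exclude_water Drop HOH atoms before the scan (default `TRUE`).
#' @return An object of class `pore_radius_profile`: data frame with columns
#'   `z` and `radius` (Angstrom).
#' @export
pore_radius_profile <- function(system, z_grid, frame = 1L,
                                exclude_water = TRUE) {
  stopifnot(inherits(system, "pore_system"))
  if (is.unsorted(z_grid, strictly = TRUE))
    stop("'z_grid' must be strictly increasing")
  idx <- if (exclude_water) nonwater_indices(system) else
    seq_len(nrow(system$atoms))
  if (!length(idx)) stop("empty frame: no atoms to scan")
  xyz <- axis_coordinates(system$frames[[frame]][idx, , drop = FALSE], system)
  rad <- system$vdw_radii[idx]
  r_perp2 <- xyz[, 1L]^2 + xyz[, 2L]^2
  radius <- vapply(z_grid, function(z) {
    max(0, min(sqrt(r_perp2 + (xyz[, 3L] - z)^2) - rad))
  }, numeric(1L))
  structure(data.frame(z = z_grid, radius = radius),
            class = c("pore_radius_profile", "data.frame"))
}

#' Orientation of planar side-chain groups relative to the pore axis
#'
#' Fits a least-squares plane to each atom group and reports the angle, in
#' degrees within \[0, 90\], between the plane normal and the pore axis. A
#' group lying flat in the membrane plane (a "horizontal ring" around the
#' pore) has angle ~0; a group standing parallel to the axis ("vertical"
#' configuration) has angle ~90.
#'
#' @param system A [pore_system()].
#' @param group_atom_sets List of integer atom-index vectors, one per group,
#'   each with >= 3 non-collinear atoms.
#' @param frame Frame index (default 1).
#' @return Numeric vector of angles (degrees), one per group.
#' @export
ring_orientation <- function(system, group_atom_sets, frame = 1L) {
  stopifnot(inherits(system, "pore_system"))
  xyz_all <- axis_coordinates(system$frames[[frame]], system)
  vapply(group_atom_sets, function(idx) {
    if (length(idx) < 3L) stop("each group needs at least 3 atoms")
    pts <- xyz_all[idx, , drop = FALSE]
    ctr <- sweep(pts, 2L, colMeans(pts))
    sv <- svd(ctr)
    if (sv$d[2L] < 1e-8 * max(sv$d[1L], 1e-12))
      stop("collinear group: plane undefined")
    normal <- sv$v[, 3L]
    cosang <- abs(normal[3L]) / sqrt(sum(normal^2))  # axis frame: axis = +z
    acos(pmin(pmax(cosang, 0), 1)) * 180 / pi
  }, numeric(1L))
}

#' Atom groups of the four side-chain rings of a fixture
#'
#' Convenience accessor returning the TYC group atom indices (chains A-D) of
#' a [make_pore_fixture()] system, in chain order.
#'
#' @param system A [pore_system()] containing TYC residues.
#' @return List of four integer vectors.
#' @export
fixture_ring_groups <- function(system) {
  lapply(c("A", "B", "C", "D"), function(ch)
    residue_indices(system, "TYC", chain = ch))
}
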