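#' Structure ensemble with a designated pore axis
#'
#' Container for a (possibly multi-frame) molecular system analysed along a
#' pore axis: atom coordinates per frame, labels, van der Waals radii and
#' the axis definition. The axis origin sits at the centre of the
#' transmembrane part of the pore domain; z values are measured along the
#' axis direction from that origin.
#'
#' @param frames List of N x 3 coordinate matrices (Angstrom), identical N
#'   across frames.
#' @param atoms Data frame with one row per atom: columns `resname`,
#'   `resid`, `atom`, `chain`.
#' @param vdw_radii Numeric vector of per-atom radii (Angstrom), > 0.
#' @param axis_origin Length-3 point (Angstrom).
#' @param axis_direction Length-3 vector (normalised internally).
#' @param state Optional label, e.g. `"open"` or `"closed"`.
#' @return An object of class `pore_system`.
#' @export
pore_system <- function(frames, atoms, vdw_radii,
                        axis_origin = c(0, 0, 0),
                        axis_direction = c(0, 0, 1),
                        state = NA_character_) {
  if (!is.list(frames) || !length(frames)) stop("'frames' must be a non-empty list")
  frames <- lapply(frames, function(f) {
    f <- as.matrix(f)
    if (ncol(f) != 3L) stop("each frame must be an N x 3 matrix")
    f
  })
  n_atoms <- nrow(frames[[1L]])
  if (!all(vapply(frames, nrow, 1L) == n_atoms))
    stop("all frames must have the same atom count")
  if (nrow(atoms) != n_atoms || length(vdw_radii) != n_atoms)
    stop("'atoms' and 'vdw_radii' must match the atom count")
  if (any(vdw_radii <= 0)) stop("vdW radii must be positive")
  nrm <- sqrt(sum(axis_direction^2))
  if (nrm == 0) stop("axis direction must be non-zero")
  structure(list(frames = frames, atoms = as.data.frame(atoms),
                 vdw_radii = as.numeric(vdw_radii),
                 axis_origin = as.numeric(axis_origin),
                 axis_direction = as.numeric(axis_direction) / nrm,
                 state = state),
            class = "pore_system")
}

#' @export
print.pore_system <- function(x, ...) {
  cat(sprintf("<pore_system> %d atom(s) x %d frame(s)%s; axis (%.2f, %.2f, %.2f)\n",
              nrow(x$atoms), length(x$frames),
              if (is.na(x$state)) "" else paste0(", state '", x$state, "'"),
              x$axis_direction[1], x$axis_direction[2], x$axis_direction[3]))
  invisible(x)
}

#' Number of frames in a pore system
#' @param system A [pore_system()].
#' @return Integer frame count.
#' @export
n_frames <- function(system) length(system$frames)

#' Transform coordinates into the pore-axis frame
#'
#' Returns coordinates relative to the axis origin in an orthonormal basis
#' whose third column is the axis direction, so column 3 is the position z
#' along the pore and columns 1-2 span the membrane plane.
#'
#' @param coords N x 3 matrix (Angstrom).
#' @param system A [pore_system()] supplying origin and direction.
#' @return N x 3 matrix with columns x, y (perpendicular) and z (along axis).
#' @export
axis_coordinates <- function(coords, system) {
  e3 <- system$axis_direction
  ref <- if (abs(e3[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * e3) * e3
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(e3[2L] * e1[3L] - e3[3L] * e1[2L],
          e3[3L] * e1[1L] - e3[1L] * e1[3L],
          e3[1L] * e1[2L] - e3[2L] * e1[1L])
  sweep(as.matrix(coords), 2L, system$axis_origin) %*% cbind(e1, e2, e3)
}

## Atom indices helpers
water_indices <- function(system) which(system$atoms$resname == "HOH")
nonwater_indices <- function(system) which(system$atoms$resname != "HOH")

#' Atom indices of one residue
#' @param system A [pore_system()].
#' @param resname Residue name (e.g. "TYC").
#' @param chain Optional chain ID to restrict to one copy.
#' @return Integer vector of atom indices; error if none match.
#' @export
residue_indices <- function(system, resname, chain = NULL) {
  sel <- system$atoms$resname == resname
  if (!is.null(chain)) sel <- sel & system$atoms$chain == chain
  idx <- which(sel)
  if (!length(idx)) stop(sprintf("residue '%s' not found", resname))
  idx
}
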