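#' Build a toy pore structure in the open or closed state
#'
#' Constructs a synthetic channel for exercising the trajectory
#' post-processing: a cylindrical wall of pseudo-atoms around a z-oriented
#' pore axis, four planar three-atom "side-chain" groups (residue TYC,
#' chains A-D) centred at z = 2.5 Angstrom, and water oxygens (residue HOH)
#' placed in the accessible lumen. In the open state the groups lie flat —
#' a ring parallel to the membrane plane — and the lumen stays continuously
#' water-accessible; in the closed state the groups stand perpendicular to
#' the membrane plane and a dense constriction plug above them (z around
#' 5-6.5) blocks the channel.
#'
#' Waters combine a deterministic axial spine (one molecule per 1 Angstrom
#' z-slab wherever the axis is accessible, guaranteeing continuity of the
#' open lumen) with uniform rejection-sampled bulk water at the requested
#' number density; the plug excludes both from the constriction. Non-water
#' atoms receive a small per-frame Gaussian jitter (SD 0.05 Angstrom) and
#' waters are re-sampled each frame.
#'
#' @param state_label `"open"` or `"closed"`.
#' @param water_number_density Target number density of water oxygens in
#'   accessible space (Angstrom^-3); default 0.0334 (bulk water).
#' @param n_frames Number of frames, >= 1.
#' @param seed Optional integer seed.
#' @return A [pore_system()] whose waters differ per frame; the wall spans
#'   z in \[-12, 12\] with accessible inner radius 4 Angstrom.
#' @export
make_pore_fixture <- function(state_label = c("open", "closed"),
                              water_number_density = 0.0334,
                              n_frames = 1L, seed = NULL) {
  state_label <- match.arg(state_label)
  if (n_frames < 1L) stop("'n_frames' must be >= 1")
  if (!is.null(seed)) set.seed(seed)

  z_lo <- -12; z_hi <- 12
  r_wall <- 5.5; r_wall_atom <- 1.5   # accessible inner radius 4.0
  r_group_atom <- 1.2
  r_water <- 1.4

  ## cylindrical wall: rings of 20 atoms every 1 A in z
  ring_z <- seq(z_lo, z_hi, by = 1)
  ring_phi <- seq(0, 2 * pi, length.out = 21L)[-21L]
  wall <- do.call(rbind, lapply(ring_z, function(z)
    cbind(r_wall * cos(ring_phi), r_wall * sin(ring_phi), z)))
  wall_atoms <- data.frame(resname = "WAL", resid = 1L, atom = "C",
                           chain = "W")[rep(1L, nrow(wall)), ]

  ## four planar side-chain groups at z = 2.5, group centres at radius 3.2
  group_centre_r <- 3.2
  group_z <- 2.5
  tri <- rbind(c(0.8, 0, 0), c(-0.4, 0.7, 0), c(-0.4, -0.7, 0))  # in-plane
  groups <- list(); group_chain <- character(0)
  chains <- c("A", "B", "C", "D")
  for (g in seq_len(4L)) {
    phi <- (g - 1L) * pi / 2
    centre <- c(group_centre_r * cos(phi), group_centre_r * sin(phi), group_z)
    if (state_label == "open") {
      ## flat: triangle stays in the z = const plane (normal along the axis)
      local <- tri
    } else {
      ## vertical: rotate the triangle into the plane spanned by the radial
      ## direction and the axis (plane contains the axis direction)
      radial <- c(cos(phi), sin(phi), 0)
      local <- t(vapply(seq_len(3L), function(i)
        tri[i, 1L] * radial + c(0, 0, tri[i, 2L]), numeric(3L)))
    }
    groups[[g]] <- sweep(local, 2L, centre, `+`)
    group_chain <- c(group_chain, rep(chains[g], 3L))
  }
  group_coords <- do.call(rbind, groups)
  group_atoms <- data.frame(resname = "TYC",
                            resid = rep(seq_len(4L), each = 3L),
                            atom = rep(c("C1", "C2", "C3"), times = 4L),
                            chain = group_chain)

  ## constriction plug (closed state only): dense disk, z in [5, 6.5]
  plug <- NULL
  if (state_label == "closed") {
    g <- seq(-4.8, 4.8, by = 1.2)
    xy <- expand.grid(x = g, y = g)
    xy <- xy[xy$x^2 + xy$y^2 <= 4.8^2, ]
    plug <- rbind(cbind(xy$x, xy$y, 5.0), cbind(xy$x, xy$y, 6.2))
  }

  solid <- rbind(wall, group_coords, plug)
  solid_atoms <- rbind(
    wall_atoms,
    group_atoms,
    if (!is.null(plug)) data.frame(resname = "PLG", resid = 1L, atom = "C",
                                   chain = "P")[rep(1L, nrow(plug)), ])
  solid_radii <- c(rep(r_wall_atom, nrow(wall)),
                   rep(r_group_atom, nrow(group_coords)),
                   if (!is.null(plug)) rep(1.5, nrow(plug)))

  lumen_r <- r_wall - r_wall_atom  # 4.0
  place_waters <- function(solid_xyz) {
    accessible <- function(p) {
      d2 <- (solid_xyz[, 1L] - p[1L])^2 + (solid_xyz[, 2L] - p[2L])^2 +
        (solid_xyz[, 3L] - p[3L])^2
      all(d2 > (solid_radii)^2)
    }
    ## axial spine: one water per 1 A slab where the axis is clear
    spine <- NULL
    for (z in seq(z_lo + 0.5, z_hi - 0.5, by = 1)) {
      p <- c(0, 0, z)
      if (accessible(p)) spine <- rbind(spine, p)
    }
    ## bulk: uniform proposals in the lumen cylinder, rejected against atoms
    vol <- pi * lumen_r^2 * (z_hi - z_lo)
    n_prop <- stats::rpois(1L, water_number_density * vol)
    if (n_prop > 0L) {
      rr <- lumen_r * sqrt(stats::runif(n_prop))
      th <- stats::runif(n_prop, 0, 2 * pi)
      zz <- stats::runif(n_prop, z_lo, z_hi)
      prop <- cbind(rr * cos(th), rr * sin(th), zz)
      keep <- vapply(seq_len(n_prop), function(i) accessible(prop[i, ]),
                     logical(1L))
      bulk <- prop[keep, , drop = FALSE]
    } else bulk <- NULL
    rbind(spine, bulk)
  }

  ## the atom table is shared across frames, so every frame must carry the
  ## same water count: trim each frame's water set to the smallest count
  ## (the spine waters come first and are never trimmed)
  frames_raw <- vector("list", n_frames)
  solid_frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    jitter <- matrix(stats::rnorm(length(solid), 0, 0.05), ncol = 3L)
    solid_f <- solid + jitter
    frames_raw[[f]] <- place_waters(solid_f)
    solid_frames[[f]] <- solid_f
  }
  n_wat <- min(vapply(frames_raw, nrow, 1L))
  frames <- lapply(seq_len(n_frames), function(f)
    rbind(solid_frames[[f]], frames_raw[[f]][seq_len(n_wat), , drop = FALSE]))

  atoms <- rbind(solid_atoms,
                 data.frame(resname = "HOH", resid = seq_len(n_wat),
                            atom = "O", chain = "S"))
  radii <- c(solid_radii, rep(r_water, n_wat))
  rownames(atoms) <- NULL
  pore_system(frames, atoms, radii, axis_origin = c(0, 0, 0),
              axis_direction = c(0, 0, 1), state = state_label)
}
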