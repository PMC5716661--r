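## Independent brute-force oracles and small fixture builders shared by the
## unit tests. These deliberately avoid the package's own code paths.

## Double-loop autocovariance with the biased (1/N) estimator, normalized
## so that C(0) = 1.
brute_autocov <- function(x, n_lag) {
  n <- length(x)
  xc <- x - mean(x)
  cc <- vapply(0:n_lag, function(k) {
    s <- 0
    for (t in seq_len(n - k)) s <- s + xc[t] * xc[t + k]
    s / n
  }, numeric(1))
  cc / cc[1]
}

## Direct convolution of x with kernel k (odd length), truncated-kernel
## renormalisation at the edges.
brute_gauss_conv <- function(x, k) {
  n <- length(x)
  r <- (length(k) - 1L) / 2L
  vapply(seq_len(n), function(i) {
    j <- (-r):r
    idx <- i + j
    ok <- idx >= 1L & idx <= n
    sum(k[ok] * x[idx[ok]]) / sum(k[ok])
  }, numeric(1))
}

## Per-frame 3-D binning oracle for occupancy grids (binary per frame).
brute_occupancy <- function(coord_list, edges) {
  nb <- vapply(edges, function(e) length(e) - 1L, 1L)
  acc <- array(0, dim = nb)
  for (xyz in coord_list) {
    hit <- array(FALSE, dim = nb)
    for (i in seq_len(nrow(xyz))) {
      ix <- findInterval(xyz[i, 1], edges$x, rightmost.closed = TRUE)
      iy <- findInterval(xyz[i, 2], edges$y, rightmost.closed = TRUE)
      iz <- findInterval(xyz[i, 3], edges$z, rightmost.closed = TRUE)
      if (ix >= 1 && ix <= nb[1] && iy >= 1 && iy <= nb[2] &&
          iz >= 1 && iz <= nb[3]) hit[ix, iy, iz] <- TRUE
    }
    acc <- acc + hit
  }
  acc / length(coord_list)
}

## Dense ball of pseudo-atoms (lattice points within `radius` of `centre`),
## used to build solid SASA fixtures under the point-occupancy convention.
atom_ball <- function(centre = c(0, 0, 0), radius = 1.5, pitch = 0.4) {
  g <- seq(-radius, radius, by = pitch)
  pts <- as.matrix(expand.grid(x = g, y = g, z = g))
  pts <- pts[rowSums(pts^2) <= radius^2, , drop = FALSE]
  sweep(pts, 2, centre, `+`)
}

## Dense rectangular slab of pseudo-atoms.
atom_slab <- function(xlim, ylim, zlim, pitch = 0.4) {
  as.matrix(expand.grid(x = seq(xlim[1], xlim[2], by = pitch),
                        y = seq(ylim[1], ylim[2], by = pitch),
                        z = seq(zlim[1], zlim[2], by = pitch)))
}

## Assemble a pore_system from coordinate blocks with constant radii.
make_system <- function(blocks, resnames, radii_each, n_frames = 1L,
                        axis_direction = c(0, 0, 1),
                        axis_origin = c(0, 0, 0)) {
  coords <- do.call(rbind, blocks)
  atoms <- data.frame(
    resname = rep(resnames, vapply(blocks, nrow, 1L)),
    resid = rep(seq_along(blocks), vapply(blocks, nrow, 1L)),
    atom = "C",
    chain = rep(LETTERS[seq_along(blocks)], vapply(blocks, nrow, 1L)))
  radii <- rep(radii_each, vapply(blocks, nrow, 1L))
  pore_system(rep(list(coords), n_frames), atoms, radii,
              axis_origin = axis_origin, axis_direction = axis_direction)
}
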