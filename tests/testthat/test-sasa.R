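## SASA fixtures are built under the point-occupancy convention: "solid"
## material must have atom centres at least as dense as the grid spacing.

test_that("an isolated residue has normalized SASA 1", {
  ball <- atom_ball(radius = 1.2, pitch = 0.4)
  sys <- make_system(list(ball), "TYC", 1.2)
  s <- grid_sasa(sys, seq_len(nrow(ball)), window = 1, spacing = 0.5)
  expect_equal(s$sasa_norm, 1)
  expect_gt(s$max_surface, 0)
})

test_that("a residue enclosed in a solid shell has normalized SASA 0", {
  ball <- atom_ball(radius = 1.0, pitch = 0.4)
  shell <- atom_slab(c(-4, 4), c(-4, 4), c(-4, 4), pitch = 0.45)
  ## keep shell atoms out of the residue itself but leave no empty gap
  shell <- shell[sqrt(rowSums(shell^2)) > 1.2, , drop = FALSE]
  sys <- make_system(list(ball, shell), c("TYC", "BLK"), c(1.2, 1.2))
  s <- grid_sasa(sys, seq_len(nrow(ball)), window = 1, spacing = 0.5)
  expect_equal(s$sasa_norm, 0)
})

test_that("a half-buried residue has normalized SASA near 0.5", {
  ## large ball half-embedded in a dense flat wall filling z < 0 (wall and
  ## ball lattices overlap: solid material must be gap-free under the
  ## point-occupancy convention); the analytic exposed fraction of a sphere
  ## cut by a plane through its centre is 1/2, and the 1.5 A surface shell
  ## blurs the equator by ~shell/(2*radius)
  ball <- atom_ball(radius = 9, pitch = 0.45)
  wall <- atom_slab(c(-11.5, 11.5), c(-11.5, 11.5), c(-11.5, -0.05),
                    pitch = 0.45)
  sys <- make_system(list(ball, wall), c("TYC", "WLL"), c(1.2, 1.2))
  s <- grid_sasa(sys, seq_len(nrow(ball)), window = 1, spacing = 0.5)
  expect_equal(s$sasa_norm, 0.5, tolerance = 0.1 / 0.5)
})

test_that("normalized SASA is invariant under rigid motion of the system", {
  ## pitch 0.25 keeps the rotated lattice dense enough that every 0.5 A bin
  ## inside the solid still contains an atom centre
  ball <- atom_ball(radius = 3, pitch = 0.25)
  wall <- atom_slab(c(-5.5, 5.5), c(-5.5, 5.5), c(-5.5, -0.05), pitch = 0.25)
  coords <- rbind(ball, wall)
  ## rotate 30 degrees about y and translate; rotate the axis identically
  th <- pi / 6
  rot <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
  shift <- c(3.1, -2.4, 7.9)
  coords_rot <- sweep(coords %*% t(rot), 2, shift, `+`)
  mk <- function(xyz, axis_dir, origin) {
    atoms <- data.frame(
      resname = rep(c("TYC", "WLL"), c(nrow(ball), nrow(wall))),
      resid = 1, atom = "C",
      chain = rep(c("A", "B"), c(nrow(ball), nrow(wall))))
    pore_system(list(xyz), atoms, rep(1.2, nrow(xyz)),
                axis_origin = origin, axis_direction = axis_dir)
  }
  s0 <- grid_sasa(mk(coords, c(0, 0, 1), c(0, 0, 0)),
                  seq_len(nrow(ball)), window = 1, spacing = 0.5)
  s1 <- grid_sasa(mk(coords_rot, as.vector(rot %*% c(0, 0, 1)), shift),
                  seq_len(nrow(ball)), window = 1, spacing = 0.5)
  expect_equal(s1$sasa_norm, s0$sasa_norm, tolerance = 0.05 / s0$sasa_norm)
})

test_that("halving the grid spacing changes SASA by less than 0.05", {
  ## atom pitch must stay at or below the finest spacing tested
  ball <- atom_ball(radius = 3, pitch = 0.225)
  wall <- atom_slab(c(-5.5, 5.5), c(-5.5, 5.5), c(-5.5, -0.05), pitch = 0.225)
  sys <- make_system(list(ball, wall), c("TYC", "WLL"), c(1.2, 1.2))
  s_coarse <- grid_sasa(sys, seq_len(nrow(ball)), window = 1, spacing = 0.5)
  s_fine <- grid_sasa(sys, seq_len(nrow(ball)), window = 1, spacing = 0.25)
  expect_lt(abs(s_fine$sasa_norm - s_coarse$sasa_norm), 0.05)
})

test_that("windows partition the trajectory and inputs are validated", {
  po <- make_pore_fixture("open", n_frames = 4, seed = 12)
  res <- residue_indices(po, "TYC", chain = "A")
  s <- grid_sasa(po, res, window = 2, spacing = 0.5)
  expect_equal(nrow(s), 2L)
  expect_equal(s$frame_start, c(1L, 3L))
  expect_true(all(s$sasa_norm >= 0 & s$sasa_norm <= 1))
  expect_error(grid_sasa(po, res, window = 10), "window")
  expect_error(grid_sasa(po, res, window = 2, spacing = 2, shell = 1.5),
               "spacing")
  expect_error(grid_sasa(po, integer(0)), "empty")
  expect_error(residue_indices(po, "XYZ"), "not found")
})
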