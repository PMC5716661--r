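test_that("pore radius is distance-to-surface from the axis point", {
  ## single atom of radius 1.5 at perpendicular distance 5 from the axis
  sys <- make_system(list(matrix(c(5, 0, 2), nrow = 1)), "WAL", 1.5)
  prof <- pore_radius_profile(sys, z_grid = c(0, 2))
  expect_equal(prof$radius[prof$z == 2], 3.5, tolerance = 1e-12)
  expect_equal(prof$radius[prof$z == 0], sqrt(25 + 4) - 1.5, tolerance = 1e-12)
  ## atom centred on the axis floors the radius at zero
  sys0 <- make_system(list(matrix(c(0, 0, 1), nrow = 1)), "WAL", 1.5)
  expect_equal(pore_radius_profile(sys0, c(1))$radius, 0)
  expect_error(pore_radius_profile(sys, c(2, 1)), "increasing")
})

test_that("fixture cylinder has ~4 A accessible radius along its body", {
  po <- make_pore_fixture("open", n_frames = 1, seed = 2)
  prof <- pore_radius_profile(po, seq(-10.5, -4.5, by = 1))
  expect_true(all(abs(prof$radius - 4) < 0.25))
})

test_that("on-axis radius agrees with a dense brute-force scan", {
  po <- make_pore_fixture("closed", n_frames = 1, seed = 3)
  zg <- seq(-8, 8, by = 0.5)
  prof <- pore_radius_profile(po, zg)
  idx <- which(po$atoms$resname != "HOH")
  xyz <- po$frames[[1]][idx, , drop = FALSE]
  rad <- po$vdw_radii[idx]
  brute <- vapply(zg, function(z) {
    d <- sqrt(xyz[, 1]^2 + xyz[, 2]^2 + (xyz[, 3] - z)^2) - rad
    max(0, min(d))
  }, numeric(1))
  expect_equal(prof$radius, brute, tolerance = 1e-9)
})

test_that("occupancy grid matches the brute-force per-frame binning oracle", {
  set.seed(44)
  ## random-walk cloud over 6 frames
  n_at <- 30
  frames <- list(matrix(rnorm(n_at * 3, sd = 2), ncol = 3))
  for (f in 2:6)
    frames[[f]] <- frames[[f - 1]] + matrix(rnorm(n_at * 3, sd = 0.5),
                                            ncol = 3)
  atoms <- data.frame(resname = "ATM", resid = 1, atom = "C", chain = "A")
  sys <- pore_system(frames, atoms[rep(1, n_at), ], rep(1, n_at))
  og <- occupancy_grid(sys, seq_len(n_at), spacing = 1)
  brute <- brute_occupancy(frames, og$edges)
  expect_equal(og$occupancy, brute, tolerance = 1e-12)
  expect_true(all(og$occupancy >= 0 & og$occupancy <= 1))
})

test_that("occupancy is the fraction of frames with an atom in the bin", {
  ## one atom present in the bin in 5 of 10 frames
  frames <- lapply(1:10, function(f)
    matrix(c(if (f <= 5) 0.2 else 10, 0.2, 0.2), nrow = 1))
  atoms <- data.frame(resname = "ATM", resid = 1, atom = "C", chain = "A")
  sys <- pore_system(frames, atoms, 1)
  og <- occupancy_grid(sys, 1L, spacing = 1)
  expect_equal(sort(unique(as.vector(og$occupancy))), c(0, 0.5),
               tolerance = 1e-12)
  expect_equal(max(og$occupancy), 0.5)
  ## single frame, single atom: exactly one occupied bin at occupancy 1
  og1 <- occupancy_grid(pore_system(frames[1], atoms, 1), 1L, spacing = 1)
  expect_equal(sum(og1$occupancy == 1), 1)
  expect_equal(sum(og1$occupancy > 0), 1)
  expect_error(occupancy_grid(sys, integer(0)), "empty selection")
})

test_that("linear density of uniform waters in a cylinder is rho*pi*r^2", {
  ## place waters uniformly at known density inside a virtual r = 4 cylinder
  set.seed(45)
  rho <- 0.05
  r_cyl <- 4; z_lo <- -10; z_hi <- 10
  n <- rpois(1, rho * pi * r_cyl^2 * (z_hi - z_lo))
  rr <- r_cyl * sqrt(runif(n)); th <- runif(n, 0, 2 * pi)
  wat <- cbind(rr * cos(th), rr * sin(th), runif(n, z_lo, z_hi))
  atoms <- data.frame(resname = "HOH", resid = seq_len(n), atom = "O",
                      chain = "S")
  sys <- pore_system(list(wat), atoms, rep(1.4, n))
  prof <- structure(data.frame(z = c(-10, 10), radius = c(4, 4)),
                    class = c("pore_radius_profile", "data.frame"))
  ze <- seq(-10, 10, by = 2)
  ld <- water_linear_density(sys, prof, ze)
  expected <- rho * pi * r_cyl^2
  lambda_slab <- expected * 2           # Poisson mean count per 2 A slab
  expect_true(all(abs(ld$density[1, ] - expected) <
                    3 * sqrt(lambda_slab) / 2))
  ## z-integral equals the in-boundary water count
  expect_equal(sum(ld$density[1, ] * diff(ze)), n)
})

test_that("no waters means zero density everywhere", {
  sys <- make_system(list(matrix(c(5, 0, 0), 1)), "WAL", 1.5)
  prof <- pore_radius_profile(sys, c(-2, 0, 2))
  ld <- water_linear_density(sys, prof, seq(-2, 2, 1))
  expect_true(all(ld$density == 0))
  expect_equal(pore_continuity(ld, c(-2, 2))$fraction, 0)
})

test_that("open fixture is continuously hydrated, closed is interrupted", {
  po <- make_pore_fixture("open", n_frames = 4, seed = 6)
  pc <- make_pore_fixture("closed", n_frames = 4, seed = 6)
  ze <- seq(-11, 11, by = 1)
  ld_o <- water_linear_density(po, pore_radius_profile(po, ze), ze)
  ld_c <- water_linear_density(pc, pore_radius_profile(pc, ze), ze)
  cont_o <- pore_continuity(ld_o, c(-10, 10))
  cont_c <- pore_continuity(ld_c, c(-10, 10))
  expect_equal(cont_o$fraction, 1)
  expect_equal(cont_c$fraction, 0)
  ## the closed constriction shows at least one empty slab per frame
  expect_true(all(apply(ld_c$density == 0, 1, any)))
})

test_that("per-frame radius profiles are accepted for the boundary", {
  po <- make_pore_fixture("open", n_frames = 3, seed = 8)
  ze <- seq(-10, 10, by = 2)
  profs <- lapply(1:3, function(f) pore_radius_profile(po, ze, frame = f))
  ld <- water_linear_density(po, profs, ze)
  expect_equal(nrow(ld$density), 3)
  expect_error(water_linear_density(po, profs[1:2], ze), "per-frame")
})

test_that("ring orientation reports 0 for flat and 90 for axial planes", {
  flat <- matrix(c(1, 0, 2, -0.5, 0.8, 2, -0.5, -0.8, 2), ncol = 3,
                 byrow = TRUE)               # z = const plane
  axial <- matrix(c(3, 0, 0, 3, 0, 1.5, 3, 0.9, 0.7), ncol = 3,
                  byrow = TRUE)              # plane containing the axis
  sys <- make_system(list(flat, axial), c("FLT", "AXL"), c(1, 1))
  ang <- ring_orientation(sys, list(1:3, 4:6))
  expect_equal(ang[1], 0, tolerance = 1e-8)
  expect_equal(ang[2], 90, tolerance = 1e-8)
  ## collinear group is rejected
  line <- matrix(c(0, 0, 0, 1, 1, 1, 2, 2, 2), ncol = 3, byrow = TRUE)
  sysl <- make_system(list(line), "LIN", 1)
  expect_error(ring_orientation(sysl, list(1:3)), "collinear")
})

test_that("fixture side-chain rings are flat when open, upright when closed", {
  po <- make_pore_fixture("open", n_frames = 1, seed = 10)
  pc <- make_pore_fixture("closed", n_frames = 1, seed = 10)
  ang_o <- ring_orientation(po, fixture_ring_groups(po))
  ang_c <- ring_orientation(pc, fixture_ring_groups(pc))
  expect_true(all(ang_o < 20))
  expect_gte(sum(ang_c > 70), 3)
  ## groups sit at z ~ 2.5 on the axis
  z_groups <- axis_coordinates(
    po$frames[[1]][unlist(fixture_ring_groups(po)), ], po)[, 3]
  expect_equal(mean(z_groups), 2.5, tolerance = 0.1)
  expect_error(make_pore_fixture("ajar"), "arg")
})
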