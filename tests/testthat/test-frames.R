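test_that("default frame geometry is 32 rows x 64 columns", {
  st <- simulate_photon_frames(1, n_frames = 2, seed = 1)
  expect_equal(dim(st), c(32L, 64L, 2L))
})

test_that("spot pixel means add Poisson rates", {
  spot <- cbind(row = c(10, 10, 11, 11), col = c(20, 21, 20, 21))
  st <- simulate_photon_frames(2, 5, spot, shape = c(32, 64),
                               n_frames = 10000, seed = 3)
  spot_counts <- vapply(seq_len(dim(st)[3]),
                        function(f) mean(st[, , f][spot]), numeric(1))
  expect_equal(mean(spot_counts), 7, tolerance = 0.03 / 7)
  ## background pixels unaffected
  expect_equal(mean(st[1:5, 1:5, ]), 2, tolerance = 0.05 / 2)
})

test_that("per-pixel variance over mean is ~1 for Poisson stacks", {
  st <- simulate_photon_frames(4, n_frames = 2000, shape = c(8, 8), seed = 5)
  px <- matrix(st, nrow = 64L)
  fano <- apply(px, 1L, stats::var) / rowMeans(px)
  expect_equal(mean(fano), 1, tolerance = 0.05)
})

test_that("without a spot, spot and background pixels are indistinguishable", {
  st <- simulate_photon_frames(3, 0, cbind(5, 5), shape = c(16, 16),
                               n_frames = 500, seed = 8)
  spot_counts <- st[5, 5, ]
  bg_counts <- st[10, 10, ]
  p <- suppressWarnings(stats::wilcox.test(spot_counts, bg_counts))$p.value
  expect_gt(p, 0.01)
})

test_that("ROI definition finds isolated pixels and disjoint blocks", {
  img <- array(0, dim = c(16, 16, 1))
  img[4, 4, 1] <- 10
  rois <- define_rois(img, threshold = 5)
  expect_length(rois, 1L)
  expect_equal(unname(rois[[1]]), cbind(4L, 4L), ignore_attr = TRUE)

  img[10:11, 12:13, 1] <- 10
  rois <- define_rois(img, threshold = 5)
  expect_length(rois, 2L)
  sizes <- sort(vapply(rois, nrow, 1L))
  expect_equal(sizes, c(1L, 4L))
  ## nothing above threshold -> empty list, not an error
  expect_length(define_rois(array(1, dim = c(4, 4, 2)), threshold = 5), 0L)
})

test_that("ROIs recover the generator's spot pixels", {
  spot <- cbind(row = c(7, 7, 8), col = c(3, 4, 3))
  st <- simulate_photon_frames(1, 25, spot, shape = c(16, 16),
                               n_frames = 400, seed = 2)
  rois <- define_rois(st, threshold_quantile = 0.99)
  expect_length(rois, 1L)
  got <- rois[[1]][order(rois[[1]][, 2], rois[[1]][, 1]), , drop = FALSE]
  want <- spot[order(spot[, 2], spot[, 1]), , drop = FALSE]
  expect_equal(unname(got), unname(want))
})

test_that("photon-count histograms and modes behave like Poisson samples", {
  spot <- cbind(row = 4:5, col = 4)
  st <- simulate_photon_frames(4, 0, NULL, shape = c(8, 8),
                               n_frames = 4000, seed = 6)
  s <- photon_count_analysis(st, list(spot))
  ## Poisson(4): modal count is 3 or 4 (equal pmf)
  expect_true(s$background_mode %in% c(3L, 4L))
  expect_true(all(s$spot_modes %in% c(3L, 4L)))
  ## histogram masses account for every pixel x frame
  expect_equal(sum(s$histogram$frequency), 8 * 8 * 4000)
  expect_error(photon_count_analysis(array(0, c(2, 2, 0)), list(spot)))
})

test_that("spot modes exceed background modes when the spot is brighter", {
  spot <- cbind(row = c(3, 3, 4), col = c(3, 4, 3))
  st <- simulate_photon_frames(2, 6, spot, shape = c(12, 12),
                               n_frames = 2000, seed = 9)
  s <- photon_count_analysis(st, list(spot))
  expect_true(all(s$spot_modes > s$background_mode))
})

test_that("mode comparison is an exact two-sided Mann-Whitney test", {
  expect_error(compare_modes(c(1, 2), c(3, 4, 5)), "3 replicates")
  same <- compare_modes(c(4, 5, 6, 7), c(4, 5, 6, 7))
  expect_gt(same$p_value, 0.85)
  far <- compare_modes(c(1, 2, 3, 4), c(10, 11, 12, 13))
  expect_equal(unname(far$statistic), 0)
  expect_equal(far$p_value, 2 / choose(8, 4), tolerance = 1e-10)
})

test_that("mode comparison keeps its nominal type-I error", {
  set.seed(31)
  rejections <- mean(replicate(400, {
    compare_modes(sample(1:20, 4), sample(1:20, 4))$p_value < 0.05
  }))
  ## exact test at n = 4 is discrete: attainable level is near 0.057
  expect_gt(rejections, 0.01)
  expect_lt(rejections, 0.12)
})

test_that("ensemble averaging uses the population SD convention", {
  t1 <- fluor_trace(rep(2, 50), dt = 0.002)
  t2 <- fluor_trace(rep(-2, 50), dt = 0.002)
  ens <- ensemble_average(list(t1, t2))
  expect_equal(ens$mean$values, rep(0, 50))
  expect_equal(ens$sd, rep(2, 50))
  ens1 <- ensemble_average(list(t1, t1))
  expect_equal(ens1$mean$values, t1$values)
  expect_equal(ens1$sd, rep(0, 50))
  expect_error(ensemble_average(list(t1, fluor_trace(1:10, 0.002))),
               "mismatched")
})

test_that("agonist onset raises both the ensemble mean and its SD", {
  m_off <- emitter_model(k_open_max = 6, k_close = 6, brightness = 8,
                         ec50 = 0.33)
  traces <- lapply(1:12, function(s) {
    pre <- simulate_emitter_trace(m_off, 0, 4, 0.002, seed = s)
    post <- simulate_emitter_trace(m_off, 3, 4, 0.002, seed = s + 100)
    fluor_trace(c(pre$values, post$values), dt = 0.002)
  })
  ens <- ensemble_average(traces)
  pre_idx <- 1:2000; post_idx <- 2001:4000
  expect_gt(mean(ens$mean$values[post_idx]), mean(ens$mean$values[pre_idx]))
  expect_gt(mean(ens$sd[post_idx]), mean(ens$sd[pre_idx]))
})
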