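#' Simulate photon-count frames from a SPAD-style imager
#'
#' Independent Poisson counts per pixel per frame. Background pixels have
#' rate `lambda_bg`; the pixels listed in `spot_pixels` (an emitter spot)
#' have rate `lambda_bg + lambda_spot`. The default geometry matches a
#' 64 x 32 photon-counting array (32 rows x 64 columns).
#'
#' @param lambda_bg Background photon rate per frame, >= 0.
#' @param lambda_spot Additional spot photon rate per frame, >= 0.
#' @param spot_pixels Two-column integer matrix of (row, col) pixel indices,
#'   or `NULL` for no spot.
#' @param shape Integer vector `c(rows, cols)`; default `c(32, 64)`.
#' @param n_frames Number of frames, >= 1.
#' @param seed Optional integer seed.
#' @return Integer array of dimension `c(rows, cols, n_frames)` with
#'   attribute `spot_pixels`.
#' @export
simulate_photon_frames <- function(lambda_bg, lambda_spot = 0,
                                   spot_pixels = NULL, shape = c(32L, 64L),
                                   n_frames = 100L, seed = NULL) {
  if (lambda_bg < 0 || lambda_spot < 0) stop("rates must be non-negative")
  if (n_frames < 1L) stop("'n_frames' must be >= 1")
  shape <- as.integer(shape)
  if (!is.null(seed)) set.seed(seed)
  lam <- matrix(lambda_bg, nrow = shape[1L], ncol = shape[2L])
  if (!is.null(spot_pixels)) {
    spot_pixels <- as.matrix(spot_pixels)
    if (any(spot_pixels[, 1L] < 1L) || any(spot_pixels[, 1L] > shape[1L]) ||
        any(spot_pixels[, 2L] < 1L) || any(spot_pixels[, 2L] > shape[2L]))
      stop("'spot_pixels' outside the frame shape")
    lam[spot_pixels] <- lambda_bg + lambda_spot
  }
  counts <- stats::rpois(prod(shape) * n_frames, rep(as.vector(lam), n_frames))
  stack <- array(as.integer(counts), dim = c(shape, n_frames))
  attr(stack, "spot_pixels") <- spot_pixels
  stack
}

#' Define regions of interest on an averaged image
#'
#' Averages all frames, thresholds the averaged image at a quantile, and
#' groups supra-threshold pixels into 4-connected components, one ROI per
#' component.
#'
#' @param frame_stack 3-D array (rows, cols, frames) of pixel values.
#' @param threshold_quantile Quantile of the averaged image used as
#'   threshold (default 0.995); pixels strictly above it are kept.
#' @param threshold Absolute threshold overriding the quantile if given.
#' @return A list of ROIs, each a two-column matrix of (row, col) indices
#'   ordered by column-major position; an empty list if nothing crosses the
#'   threshold.
#' @export
define_rois <- function(frame_stack, threshold_quantile = 0.995,
                        threshold = NULL) {
  d <- dim(frame_stack)
  if (is.null(d) || length(d) != 3L || d[3L] < 1L)
    stop("'frame_stack' must be a (rows, cols, frames) array with >= 1 frame")
  avg <- rowMeans(frame_stack, dims = 2L)
  if (is.null(threshold))
    threshold <- stats::quantile(avg, threshold_quantile, names = FALSE)
  mask <- avg > threshold
  if (!any(mask)) return(list())
  label_components(mask)
}

## 4-connected component labeling by breadth-first flood fill.
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  comp <- list()
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    id <- length(comp) + 1L
    queue <- start
    lab[start] <- id
    members <- integer(0)
    while (length(queue)) {
      cur <- queue[[1L]]; queue <- queue[-1L]
      members <- c(members, cur)
      r <- (cur - 1L) %% nr + 1L
      cc <- (cur - 1L) %/% nr + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        r2 <- r + d[1L]; c2 <- cc + d[2L]
        if (r2 < 1L || r2 > nr || c2 < 1L || c2 > nc) next
        lin <- (c2 - 1L) * nr + r2
        if (mask[lin] && lab[lin] == 0L) {
          lab[lin] <- id
          queue <- c(queue, lin)
        }
      }
    }
    members <- sort(members)
    comp[[id]] <- cbind(row = (members - 1L) %% nr + 1L,
                        col = (members - 1L) %/% nr + 1L)
  }
  comp
}

#' Modal value of a count sample
#'
#' The smallest count achieving the maximal frequency (deterministic
#' tie-break).
#'
#' @param counts Integer vector of photon counts.
#' @return The modal count (integer).
#' @export
count_mode <- function(counts) {
  if (!length(counts)) stop("empty count sample")
  tab <- table(counts)
  as.integer(names(tab)[which.max(tab)])  # which.max takes the first maximum
}

#' Photon-count statistics for spot and background pixels
#'
#' Pools photon counts over frames for the spot pixels (the ROIs) and the
#' remaining background pixels, builds per-class histograms, and reports the
#' modal count per ROI (each ROI is treated as one replicate).
#'
#' @param frame_stack 3-D integer array (rows, cols, frames), >= 1 frame.
#' @param rois List of (row, col) index matrices as returned by
#'   [define_rois()].
#' @return An object of class `photon_count_summary`: list with `histogram`
#'   (data frame: class, count, frequency), `spot_modes` (one mode per ROI),
#'   `background_mode`, and `n_replicates`.
#' @export
photon_count_analysis <- function(frame_stack, rois) {
  d <- dim(frame_stack)
  if (is.null(d) || length(d) != 3L || d[3L] < 1L || prod(d) == 0)
    stop("empty or malformed frame stack")
  if (!length(rois)) stop("no ROIs supplied")
  nr <- d[1L]; nc <- d[2L]; nf <- d[3L]
  roi_lin <- lapply(rois, function(m) {
    m <- as.matrix(m)
    if (any(m[, 1L] > nr) || any(m[, 2L] > nc) || any(m < 1L))
      stop("ROI indices outside the stack shape")
    (m[, 2L] - 1L) * nr + m[, 1L]
  })
  spot_lin <- unique(unlist(roi_lin))
  frame_offsets <- (seq_len(nf) - 1L) * (nr * nc)
  all_spot <- as.vector(outer(spot_lin, frame_offsets, `+`))
  spot_counts <- frame_stack[all_spot]
  bg_lin <- setdiff(seq_len(nr * nc), spot_lin)
  bg_counts <- frame_stack[as.vector(outer(bg_lin, frame_offsets, `+`))]

  hist_df <- function(x, cls) {
    tab <- table(x)
    data.frame(class = cls, count = as.integer(names(tab)),
               frequency = as.integer(tab), row.names = NULL)
  }
  histogram <- rbind(hist_df(bg_counts, "background"),
                     hist_df(spot_counts, "spot"))
  spot_modes <- vapply(roi_lin, function(lin) {
    count_mode(frame_stack[as.vector(outer(lin, frame_offsets, `+`))])
  }, 1L)
  structure(list(histogram = histogram,
                 spot_modes = spot_modes,
                 background_mode = count_mode(bg_counts),
                 n_replicates = length(rois)),
            class = "photon_count_summary")
}

#' @export
print.photon_count_summary <- function(x, ...) {
  cat(sprintf("<photon_count_summary> %d ROI(s); spot mode(s) %s; background mode %d\n",
              x$n_replicates, paste(x$spot_modes, collapse = ", "),
              x$background_mode))
  invisible(x)
}

#' Compare replicate-level photon-count modes between two conditions
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test on the modal photon counts
#' of replicate measurements, e.g. with/without agonist.
#'
#' @param modes_a,modes_b Numeric vectors of replicate-level modes, >= 3
#'   replicates each.
#' @return List with `statistic` (the U statistic), `p_value`, and `method`.
#' @export
compare_modes <- function(modes_a, modes_b) {
  if (length(modes_a) < 3L || length(modes_b) < 3L)
    stop("need at least 3 replicates per group")
  ht <- suppressWarnings(stats::wilcox.test(modes_a, modes_b,
                                            alternative = "two.sided"))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = ht$method)
}
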