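#' Maximum intensity projection of a z-stack
#'
#' @param stack 3D numeric array `(y, x, z)` or a single-slice matrix.
#' @return Matrix: per-pixel maximum over z.
#' @export
max_projection <- function(stack) {
  if (is.matrix(stack)) return(stack)
  if (length(dim(stack)) != 3 || dim(stack)[3] < 1)
    stop("empty stack", call. = FALSE)
  apply(stack, c(1, 2), max)
}

#' Display-range rescale and Gaussian denoising
#'
#' Linear clip-rescale of `display_range` onto \[0, 1\] (the window/level
#' brightness-contrast adjustment, here parameterized by its min/max
#' endpoints) followed by a Gaussian blur of standard deviation `sigma`
#' pixels.
#'
#' @param image Numeric matrix.
#' @param display_range `(lo, hi)` intensities mapped to 0 and 1.
#' @param sigma Gaussian blur standard deviation in px (0 disables).
#' @return Matrix of values in \[0, 1\].
#' @export
preprocess <- function(image, display_range = c(35, 70), sigma = 3) {
  lo <- display_range[1]; hi <- display_range[2]
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi)
    stop("display_range must satisfy lo < hi", call. = FALSE)
  img <- pmin(pmax((image - lo) / (hi - lo), 0), 1)
  dim(img) <- dim(image)
  if (sigma > 0) {
    # replicate-pad so edges do not wrap and small images stay valid
    p <- 2 * ceiling(3 * sigma) + 2
    padded <- pad_replicate(img, p)
    blurred <- as.matrix(EBImage::gblur(padded, sigma = sigma))
    img <- blurred[p + seq_len(nrow(img)), p + seq_len(ncol(img))]
    img <- pmin(pmax(img, 0), 1)
    dim(img) <- dim(image)
  }
  img
}

pad_replicate <- function(m, p) {
  ri <- c(rep(1, p), seq_len(nrow(m)), rep(nrow(m), p))
  ci <- c(rep(1, p), seq_len(ncol(m)), rep(ncol(m), p))
  m[ri, ci, drop = FALSE]
}

#' Triangle threshold binarization
#'
#' Histogram-shape thresholding: on a 256-bin histogram over the image's
#' min-max range, a chord is drawn from the histogram peak to the far
#' end of the longer tail; the threshold is the bin maximizing the
#' perpendicular distance between histogram and chord. Pixels at or
#' above the threshold intensity are foreground. Because the histogram
#' is built over the image's own range, the resulting mask is invariant
#' to affine intensity rescaling.
#'
#' @param image Numeric matrix with at least two distinct values.
#' @return A logical matrix (the binary mask).
#' @export
triangle_threshold <- function(image) {
  rng <- range(image, finite = TRUE)
  if (rng[1] == rng[2])
    stop("triangle threshold undefined for a constant image", call. = FALSE)
  nbins <- 256L
  bins <- pmin(floor((image - rng[1]) / (rng[2] - rng[1]) * nbins), nbins - 1L)
  h <- tabulate(bins + 1L, nbins)
  thr_bin <- triangle_bin(h)
  # pixels in bins at or above the valley bin are foreground
  mask <- (bins + 1L) >= thr_bin
  dim(mask) <- dim(image)
  mask
}

# triangle construction on a histogram; returns the 0-based threshold bin
triangle_bin <- function(h) {
  nbins <- length(h)
  peak <- which.max(h)
  nz <- which(h > 0)
  lo <- min(nz); hi <- max(nz)
  # longer tail: from the peak to the farther extreme of the occupied range
  if ((hi - peak) >= (peak - lo)) {
    tail_end <- min(hi + 1L, nbins)       # first (near-)empty bin past the tail
    span <- seq(peak, tail_end)
  } else {
    tail_end <- max(lo - 1L, 1L)
    span <- seq(tail_end, peak)
  }
  x1 <- peak; y1 <- h[peak]; x2 <- tail_end; y2 <- h[tail_end]
  # perpendicular distance (up to a positive factor) from (x, h[x]) to chord
  d <- abs((y2 - y1) * span - (x2 - x1) * h[span] + x2 * y1 - y2 * x1)
  span[which.max(d)]
}

disk_kernel <- function(radius) {
  r <- ceiling(radius)
  xy <- expand.grid(x = -r:r, y = -r:r)
  k <- matrix(as.numeric(xy$x^2 + xy$y^2 <= radius^2), nrow = 2 * r + 1)
  k
}

# majority (median) vote of a binary mask over a disk neighbourhood
disk_majority <- function(mask, radius) {
  k <- disk_kernel(radius)
  cnt <- EBImage::filter2(matrix(as.numeric(mask), nrow = nrow(mask)),
                          k, boundary = "replicate")
  cnt > sum(k) / 2 + 1e-7
}

#' Clean a binary mask: erode, then remove bright and dark outliers
#'
#' One binary erosion with the full 3x3 (8-connected) structuring
#' element, then two disk-median outlier passes: foreground pixels whose
#' disk-median (radius `bright_radius`) is background are removed
#' (isolated bright specks), then background pixels whose disk-median
#' (radius `dark_radius`) is foreground are filled (isolated dark
#' holes). On binary images the disk median is exactly a majority vote
#' over the disk, which is how it is computed.
#'
#' @param mask Logical matrix.
#' @param erode_iterations Number of erosions, default 1.
#' @param bright_radius Disk radius (px) for the bright-outlier pass.
#' @param dark_radius Disk radius (px) for the dark-outlier pass.
#' @return Logical matrix.
#' @export
clean_mask <- function(mask, erode_iterations = 1, bright_radius = 5,
                       dark_radius = 10) {
  m <- matrix(as.numeric(mask), nrow = nrow(mask))
  if (erode_iterations > 0) {
    brush <- EBImage::makeBrush(3, shape = "box")
    for (i in seq_len(erode_iterations)) m <- EBImage::erode(m, brush)
    m <- as.matrix(m)
  }
  m <- m > 0.5
  if (bright_radius > 0) m <- m & disk_majority(m, bright_radius)
  if (dark_radius > 0) m <- m | disk_majority(m, dark_radius)
  dim(m) <- dim(mask)
  m
}

#' Vessel-network morphometry from a binary mask
#'
#' Computes, over a region of interest: the vasculature area (foreground
#' pixel count times pixel area) and area percentage; the total network
#' length as the calibrated length of the topological skeleton
#' (one-pixel-wide centerlines from Zhang-Suen thinning); and the mean
#' vessel diameter as total area / total length. Skeleton length is, by
#' default, the sum of inter-pixel steps along the skeleton (1 px for
#' orthogonal, sqrt(2) px for diagonal neighbours); `length_mode =
#' "pixel_count"` instead counts skeleton pixels, for strict
#' comparability with pixel-counting implementations.
#'
#' @param mask Logical matrix.
#' @param pixel_size_um Pixel size (um/px).
#' @param roi_area_um2 Reference area for the percentage; defaults to
#'   the mask extent.
#' @param length_mode `"steps"` (default) or `"pixel_count"`.
#' @return A list of class `network_metrics`: `area_percent`,
#'   `total_area_um2`, `total_length_um`, `mean_diameter_um` (`NA` for
#'   an empty mask).
#' @export
network_metrics <- function(mask, pixel_size_um = 1, roi_area_um2 = NULL,
                            length_mode = c("steps", "pixel_count")) {
  length_mode <- match.arg(length_mode)
  if (is.null(roi_area_um2))
    roi_area_um2 <- length(mask) * pixel_size_um^2
  n_fg <- sum(mask)
  total_area <- n_fg * pixel_size_um^2
  if (n_fg == 0) {
    return(structure(list(area_percent = 0, total_area_um2 = 0,
                          total_length_um = 0, mean_diameter_um = NA_real_),
                     class = "network_metrics"))
  }
  skel <- skeletonize(mask)
  len_px <- if (length_mode == "pixel_count") sum(skel)
            else skeleton_length_px(skel)
  total_length <- len_px * pixel_size_um
  structure(list(area_percent = total_area / roi_area_um2 * 100,
                 total_area_um2 = total_area,
                 total_length_um = total_length,
                 mean_diameter_um = if (total_length > 0)
                   total_area / total_length else NA_real_),
            class = "network_metrics")
}

#' @export
print.network_metrics <- function(x, ...) {
  cat(sprintf(paste0("network metrics: area %.1f%% (%.0f um^2), ",
                     "length %.0f um, mean diameter %.1f um\n"),
              x$area_percent, x$total_area_um2, x$total_length_um,
              x$mean_diameter_um))
  invisible(x)
}

# diagonal-aware skeleton length: each adjacent skeleton-pixel pair is one
# step, orthogonal steps count 1 px, diagonal sqrt(2) px; diagonal steps
# shortcutting an orthogonal corner are not double-counted
skeleton_length_px <- function(skel) {
  s <- skel
  nr <- nrow(s); nc <- ncol(s)
  right <- s[, -nc, drop = FALSE] & s[, -1, drop = FALSE]
  down  <- s[-nr, , drop = FALSE] & s[-1, , drop = FALSE]
  # diagonal pairs, skipped when the two pixels already share an
  # orthogonal common neighbour on the skeleton (staircase corner)
  a <- s[-nr, -nc, drop = FALSE]; b <- s[-1, -1, drop = FALSE]
  corner1 <- s[-nr, -1, drop = FALSE] | s[-1, -nc, drop = FALSE]
  diag1 <- a & b & !corner1
  a2 <- s[-nr, -1, drop = FALSE]; b2 <- s[-1, -nc, drop = FALSE]
  corner2 <- s[-nr, -nc, drop = FALSE] | s[-1, -1, drop = FALSE]
  diag2 <- a2 & b2 & !corner2
  sum(right) + sum(down) + sqrt(2) * (sum(diag1) + sum(diag2))
}

#' Pixelwise conjunction of two masks
#'
#' The AND overlap of two binary masks (e.g. the pericyte and vessel
#' channels of the same ROI).
#'
#' @param a,b Logical matrices of identical shape.
#' @return Logical matrix.
#' @export
overlap_mask <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("masks must have identical shapes", call. = FALSE)
  a & b
}

#' Pericyte area and vasculature coverage
#'
#' The pericyte area percentage is the alpha-SMA-positive area over the
#' ROI area; the coverage is the AND overlap of the pericyte and vessel
#' masks over the vessel area -- the fraction of the vasculature wrapped
#' by pericytes.
#'
#' @param sma_mask Logical matrix, pericyte (alpha-SMA) channel.
#' @param vessel_mask Logical matrix, vessel (GFP) channel; same shape.
#' @param pixel_size_um Pixel size (um/px).
#' @param roi_area_um2 Reference area; defaults to the mask extent.
#' @return A list: `pericyte_area_percent`, `coverage_percent` (`NA`
#'   with a warning when the vessel mask is empty).
#' @export
pericyte_metrics <- function(sma_mask, vessel_mask, pixel_size_um = 1,
                             roi_area_um2 = NULL) {
  if (!identical(dim(sma_mask), dim(vessel_mask)))
    stop("masks must have identical shapes", call. = FALSE)
  if (is.null(roi_area_um2))
    roi_area_um2 <- length(sma_mask) * pixel_size_um^2
  pericyte_area <- sum(sma_mask) * pixel_size_um^2
  n_vessel <- sum(vessel_mask)
  coverage <- if (n_vessel == 0) {
    warning("empty vessel mask: coverage undefined")
    NA_real_
  } else sum(overlap_mask(sma_mask, vessel_mask)) / n_vessel * 100
  list(pericyte_area_percent = pericyte_area / roi_area_um2 * 100,
       coverage_percent = coverage)
}

#' Full vessel-channel quantification pipeline
#'
#' Projection, display-range rescale, Gaussian blur, triangle threshold,
#' mask cleaning, morphometry -- the complete deterministic chain from a
#' raw z-stack (or projection) to network metrics.
#'
#' @param stack 3D array or matrix (raw intensities).
#' @param pixel_size_um Pixel size (um/px).
#' @param display_range,sigma Passed to [preprocess()].
#' @param erode_iterations,bright_radius,dark_radius Passed to
#'   [clean_mask()].
#' @param roi_area_um2,length_mode Passed to [network_metrics()].
#' @return A list: `metrics` (a `network_metrics`) and `mask` (the
#'   cleaned binary mask).
#' @export
quantify_vessel_stack <- function(stack, pixel_size_um = 1,
                                  display_range = c(35, 70), sigma = 3,
                                  erode_iterations = 1, bright_radius = 5,
                                  dark_radius = 10, roi_area_um2 = NULL,
                                  length_mode = "steps") {
  img <- preprocess(max_projection(stack), display_range, sigma)
  mask <- clean_mask(triangle_threshold(img), erode_iterations,
                     bright_radius, dark_radius)
  list(metrics = network_metrics(mask, pixel_size_um, roi_area_um2,
                                 length_mode),
       mask = mask)
}
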