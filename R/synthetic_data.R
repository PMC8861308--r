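#' Synthetic vessel-network image with known morphometry
#'
#' Renders a network of straight tube segments ("capsules": rectangles
#' with half-disk caps) of known width onto a canvas, applies a
#' Gaussian point-spread blur and additive Gaussian intensity noise
#' (clipped to the dynamic range). Ground-truth metrics are computed
#' from the exact noise-free rendered mask (so overlapping segments are
#' counted once): area = union of the capsules, length = sum of
#' centerline lengths, diameter = area / length.
#'
#' @param segments Data frame or matrix with columns `x0, y0, x1, y1,
#'   width` in pixels (one tube per row); zero rows give a blank image.
#' @param canvas_px Canvas side length (px) or `c(ny, nx)`.
#' @param pixel_size_um Pixel size (um/px).
#' @param background_level,foreground_level Intensities of matrix and
#'   vessel.
#' @param noise_sd Gaussian noise standard deviation (intensity units).
#' @param psf_sigma Point-spread blur sigma (px), 0 disables.
#' @param seed Integer seed; the generator is deterministic given it.
#' @return A list: `image` (matrix), `truth_mask` (logical matrix),
#'   `truth` (a `network_metrics` ground truth in um).
#' @export
synth_tube_network <- function(segments, canvas_px = 300,
                               pixel_size_um = 1,
                               background_level = 20,
                               foreground_level = 120,
                               noise_sd = 5, psf_sigma = 1, seed = 1) {
  if (length(canvas_px) == 1) canvas_px <- c(canvas_px, canvas_px)
  ny <- canvas_px[1]; nx <- canvas_px[2]
  segments <- as.data.frame(segments)
  if (nrow(segments) > 0 && any(segments$width <= 0))
    stop("tube widths must be > 0", call. = FALSE)
  xs <- matrix(rep(seq_len(nx), each = ny), ny, nx)
  ys <- matrix(rep(seq_len(ny), nx), ny, nx)
  mask <- matrix(FALSE, ny, nx)
  total_len_px <- 0
  for (i in seq_len(nrow(segments))) {
    s <- segments[i, ]
    # distance from every pixel center to the segment
    vx <- s$x1 - s$x0; vy <- s$y1 - s$y0
    len2 <- vx^2 + vy^2
    tt <- if (len2 == 0) 0 else
      pmin(pmax(((xs - s$x0) * vx + (ys - s$y0) * vy) / len2, 0), 1)
    dx <- xs - (s$x0 + tt * vx); dy <- ys - (s$y0 + tt * vy)
    mask <- mask | (dx^2 + dy^2 <= (s$width / 2)^2)
    total_len_px <- total_len_px + sqrt(len2)
  }
  img <- matrix(background_level, ny, nx)
  img[mask] <- foreground_level
  if (psf_sigma > 0) img <- as.matrix(EBImage::gblur(img, sigma = psf_sigma))
  if (noise_sd > 0) {
    set.seed(seed)
    img <- img + stats::rnorm(length(img), 0, noise_sd)
  }
  img <- pmin(pmax(img, 0), max(foreground_level, background_level) * 2)
  dim(img) <- c(ny, nx)
  area_um2 <- sum(mask) * pixel_size_um^2
  len_um <- total_len_px * pixel_size_um
  truth <- structure(list(
    area_percent = area_um2 / (ny * nx * pixel_size_um^2) * 100,
    total_area_um2 = area_um2,
    total_length_um = len_um,
    mean_diameter_um = if (len_um > 0) area_um2 / len_um else NA_real_),
    class = "network_metrics")
  list(image = img, truth_mask = mask, truth = truth)
}

#' Synthetic flow-front time-lapse with drainage-model ground truth
#'
#' Generates a fluorescent-front time-lapse whose front motion follows
#' the gravity-driven drainage model: the front position is the
#' cumulative drained volume over the hydrogel cross-section,
#' x(t) = Q(0) tau (1 - exp(-t/tau)) / A_gel. The front edge is
#' rendered with sub-pixel anti-aliasing (the boundary pixel carries
#' the partial-coverage intensity) and a small deterministic linear slant
#' across rows (`bow_px`), mirroring the tilted fronts seen in real
#' chips; both give the row-averaged tracker sub-pixel resolution, the
#' slant acting as a uniform dither that cancels pixel quantization.
#'
#' @param q0_ul_min Initial flow rate (ul/min), > 0.
#' @param vol A [volume_condition()].
#' @param geom A [chip_geometry()].
#' @param acq An [acquisition_params()] (pixel size and frame interval).
#' @param n_frames Number of frames.
#' @param canvas_px `c(ny, nx)` canvas size; `NULL` (default) sizes the
#'   canvas to hold the whole front trajectory.
#' @param x0_px Front position in the first frame (px).
#' @param bow_px Total front slant across rows (px); integer values
#'   dither best.
#' @param noise_sd Gaussian intensity noise sd (image on a 0..1 scale).
#' @param seed Integer seed.
#' @return A list: `stack` (array `(y, x, frame)`), `truth` (data frame
#'   `t_s`, `front_px` (row mean), `v_mm_s`, `q_ul_min`).
#' @export
synth_flow_stack <- function(q0_ul_min, vol = volume_condition(),
                             geom = chip_geometry(),
                             acq = acquisition_params(),
                             n_frames = 20, canvas_px = NULL,
                             x0_px = 5, bow_px = 2, noise_sd = 0.02,
                             seed = 1) {
  if (q0_ul_min <= 0) stop("q0 must be > 0", call. = FALSE)
  tau_min <- drainage_tau_min(q0_ul_min, vol, geom)
  a_gel_mm2 <- gel_cross_section_mm2(geom)
  t_s <- (seq_len(n_frames) - 1) * acq$frame_interval_s
  t_min <- t_s / 60
  q_t <- q0_ul_min * exp(-t_min / tau_min)                  # ul/min
  v_mm_s <- q_t / a_gel_mm2 / 60                            # mm/s
  # cumulative volume -> front displacement in mm -> px
  disp_mm <- q0_ul_min * tau_min * (1 - exp(-t_min / tau_min)) / a_gel_mm2
  front_px <- x0_px + disp_mm * 1000 / acq$pixel_size_um
  if (is.null(canvas_px))
    canvas_px <- c(128, ceiling(max(front_px) + bow_px + 3))
  ny <- canvas_px[1]; nx <- canvas_px[2]
  if (max(front_px) > nx) {
    warning("front exceeds canvas; stack truncated")
    keep <- front_px <= nx
    t_s <- t_s[keep]; q_t <- q_t[keep]; v_mm_s <- v_mm_s[keep]
    front_px <- front_px[keep]; n_frames <- sum(keep)
  }
  rows <- seq_len(ny)
  # linear front slant spanning exactly bow_px pixels, uniformly across
  # rows: row-averaging then cancels the pixel-quantization of the front
  bow <- bow_px * (rows - 0.5) / ny
  cols <- seq_len(nx)
  stack <- array(0, dim = c(ny, nx, n_frames))
  set.seed(seed)
  for (i in seq_len(n_frames)) {
    fr_rows <- front_px[i] + bow                # per-row front position
    # coverage of column c (spanning (c-1, c]) by the filled region
    cov <- pmin(pmax(outer(fr_rows, cols - 1, "-"), 0), 1)
    if (noise_sd > 0) cov <- cov + stats::rnorm(length(cov), 0, noise_sd)
    stack[, , i] <- pmin(pmax(cov, 0), 1)
  }
  list(stack = stack,
       truth = data.frame(t_s = t_s, front_px = front_px + mean(bow),
                          v_mm_s = v_mm_s, q_ul_min = q_t))
}

#' Pair of binary masks with an exact overlap fraction
#'
#' Constructs masks A (e.g. pericyte) and B (e.g. vessel) such that
#' |A AND B| / |B| equals `overlap_fraction` exactly, by pixel count. B
#' is a filled rectangle; A covers the first `round(f |B|)` pixels of B
#' plus a disjoint block outside it.
#'
#' @param canvas_px Side length (px) or `c(ny, nx)`.
#' @param overlap_fraction Desired |A AND B| / |B| in \[0, 1\].
#' @param b_px Number of pixels in B (default: a quarter of the canvas).
#' @param a_extra_px Pixels of A outside B (default 200, truncated to
#'   the available space).
#' @param seed Unused; accepted for generator-interface symmetry.
#' @return A list: `a`, `b` (logical matrices), `overlap_px`.
#' @export
synth_overlap_pair <- function(canvas_px = 100, overlap_fraction = 0.5,
                               b_px = NULL, a_extra_px = 200, seed = 1) {
  if (overlap_fraction < 0 || overlap_fraction > 1)
    stop("overlap fraction must be in [0, 1]", call. = FALSE)
  if (length(canvas_px) == 1) canvas_px <- c(canvas_px, canvas_px)
  ny <- canvas_px[1]; nx <- canvas_px[2]
  if (is.null(b_px)) b_px <- floor(ny * nx / 4)
  if (b_px < 1 || b_px > floor(ny * nx / 2))
    stop("infeasible B area for this canvas", call. = FALSE)
  k <- round(overlap_fraction * b_px)
  b <- matrix(FALSE, ny, nx)
  b[seq_len(b_px)] <- TRUE            # column-major fill: left block
  a <- matrix(FALSE, ny, nx)
  a[seq_len(k)] <- TRUE               # first k pixels of B
  outside <- which(!b)
  extra <- min(a_extra_px, length(outside))
  a[outside[seq_len(extra)]] <- TRUE
  list(a = a, b = b, overlap_px = k)
}

#' Synthetic qPCR Ct table with programmed fold changes
#'
#' Generates a long-format Ct table for two co-culture groups with a
#' chosen number of donor cell lines per group and technical
#' replicates. Target-gene Ct values in the treatment group are shifted
#' by -log2(fold) relative to the baseline group; reference genes have
#' zero programmed effect. Replicate noise is additive Gaussian on the
#' Ct scale.
#'
#' @param fold_changes Named numeric vector: programmed fold change per
#'   target gene (treatment vs baseline).
#' @param reference_genes Character vector of reference-gene names.
#' @param groups `c(treatment, baseline)` group labels.
#' @param donors_per_group Donor cell lines per group (default 3).
#' @param replicates Technical replicates (default 3).
#' @param base_ct Baseline Ct level for targets (cycles).
#' @param ref_ct Ct level of reference genes (cycles).
#' @param noise_sd Replicate Ct noise sd (cycles).
#' @param donor_sd Between-donor Ct shift sd (cycles), applied to all
#'   genes of a donor equally (cancels in delta Ct on average).
#' @param seed Integer seed.
#' @return Data frame with columns `sample`, `donor`, `group`, `gene`,
#'   `replicate`, `ct`.
#' @export
synth_ct_table <- function(fold_changes,
                           reference_genes = c("RNA18S", "GAPDH"),
                           groups = c("EC-BMSC", "EC-ASC"),
                           donors_per_group = 3, replicates = 3,
                           base_ct = 26, ref_ct = 18, noise_sd = 0.3,
                           donor_sd = 0, seed = 1) {
  if (any(fold_changes <= 0)) stop("fold changes must be > 0", call. = FALSE)
  set.seed(seed)
  genes <- c(names(fold_changes), reference_genes)
  rows <- list()
  for (gi in seq_along(groups)) {
    grp <- groups[gi]
    treat <- gi == 1
    for (d in seq_len(donors_per_group)) {
      donor <- sprintf("%s-donor%d", grp, d)
      d_shift <- if (donor_sd > 0) stats::rnorm(1, 0, donor_sd) else 0
      for (g in genes) {
        is_ref <- g %in% reference_genes
        mu <- (if (is_ref) ref_ct else base_ct) + d_shift -
          (if (!is_ref && treat) log2(fold_changes[[g]]) else 0)
        ct <- mu + (if (noise_sd > 0)
          stats::rnorm(replicates, 0, noise_sd) else rep(0, replicates))
        rows[[length(rows) + 1]] <- data.frame(
          sample = donor, donor = donor, group = grp, gene = g,
          replicate = seq_len(replicates), ct = ct)
      }
    }
  }
  do.call(rbind, rows)
}
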