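#' Acquisition parameters for flow-front time-lapses
#'
#' @param pixel_size_um Pixel size (um/px), default 0.615.
#' @param frame_interval_s Time between frames (s), default 5.
#' @param flow_axis Image axis along which the front advances: `"x"`
#'   (columns) or `"y"` (rows).
#' @param flow_direction `"increasing"` if the front moves toward larger
#'   pixel indices, `"decreasing"` otherwise.
#' @return An object of class `acquisition_params`.
#' @export
acquisition_params <- function(pixel_size_um = 0.615, frame_interval_s = 5,
                               flow_axis = c("x", "y"),
                               flow_direction = c("increasing", "decreasing")) {
  if (pixel_size_um <= 0 || frame_interval_s <= 0)
    stop("pixel size and frame interval must be > 0", call. = FALSE)
  structure(list(pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s,
                 flow_axis = match.arg(flow_axis),
                 flow_direction = match.arg(flow_direction)),
            class = "acquisition_params")
}

#' Binarize a fluorescence time-lapse stack
#'
#' Intensities are min-max normalized over the whole stack (not per
#' frame, so bleaching drift cannot reverse the apparent front) and
#' thresholded at `threshold`; a pixel is foreground iff its normalized
#' intensity is >= threshold.
#'
#' @param stack 3D numeric array `(y, x, frame)`, or a matrix for a
#'   single frame.
#' @param threshold Fraction of the stack dynamic range, default 0.5.
#' @return Logical array of the same shape.
#' @export
binarize_frames <- function(stack, threshold = 0.5) {
  if (is.matrix(stack)) dim(stack) <- c(dim(stack), 1L)
  if (length(stack) == 0) stop("empty stack", call. = FALSE)
  rng <- range(stack, finite = TRUE)
  norm <- if (rng[2] > rng[1]) (stack - rng[1]) / (rng[2] - rng[1])
          else array(as.numeric(stack >= threshold), dim = dim(stack))
  mask <- norm >= threshold
  dim(mask) <- dim(stack)
  mask
}

# orient a frame so the front advances along increasing column index
orient_frame <- function(frame, acq) {
  if (acq$flow_axis == "y") frame <- t(frame)
  if (acq$flow_direction == "decreasing") frame <- frame[, rev(seq_len(ncol(frame))), drop = FALSE]
  frame
}

#' Track the mean flow-front position over a binarized stack
#'
#' For each line of pixels perpendicular to the flow axis, the front is
#' the farthest foreground pixel still contiguous with the inlet edge
#' (the run of foreground starting at the first pixel of the line);
#' detached bright specks ahead of the front are ignored. The per-frame
#' front is the mean over lines carrying signal. Frames in which fewer
#' than `min_line_fraction` of the lines carry signal are flagged
#' invalid (`NA` front) -- typically start-up frames before dye entry.
#'
#' Front positions are reported as run lengths from the inlet edge, so a
#' plug filling the first k columns of every line has front k.
#'
#' @param masks Logical array `(y, x, frame)` from [binarize_frames()].
#' @param acq An [acquisition_params()].
#' @param min_line_fraction Minimum fraction of lines with signal for a
#'   frame to be considered valid, default 0.1.
#' @return Data frame with `frame_index`, `t_s`, `mean_front_px`,
#'   `valid_rows`.
#' @export
track_front <- function(masks, acq = acquisition_params(),
                        min_line_fraction = 0.1) {
  if (is.matrix(masks)) dim(masks) <- c(dim(masks), 1L)
  if (length(masks) == 0) stop("empty mask stack", call. = FALSE)
  nf <- dim(masks)[3]
  res <- vapply(seq_len(nf), function(i) {
    fr <- orient_frame(masks[, , i], acq)
    # front per row: length of the initial TRUE run
    first_false <- max.col(!fr, ties.method = "first")
    run <- ifelse(fr[cbind(seq_len(nrow(fr)), 1)] == FALSE, 0,
                  ifelse(!fr[cbind(seq_len(nrow(fr)), first_false)],
                         first_false - 1L, ncol(fr)))
    valid <- run > 0
    c(front = if (sum(valid) >= min_line_fraction * nrow(fr))
        mean(run[valid]) else NA_real_,
      nvalid = sum(valid))
  }, numeric(2))
  data.frame(frame_index = seq_len(nf),
             t_s = (seq_len(nf) - 1) * acq$frame_interval_s,
             mean_front_px = res["front", ],
             valid_rows = as.integer(res["nvalid", ]))
}

#' Front velocity series from tracked front positions
#'
#' v_i = (front_{i+1} - front_i) * pixel_size / frame_interval, in mm/s,
#' assigned to the interval between frames i and i+1. An optional
#' moving-average window smooths the velocity series; none is applied by
#' default, so the quantization oscillation seen at low flow is
#' reported, not suppressed.
#'
#' @param traces Data frame from [track_front()].
#' @param acq An [acquisition_params()].
#' @param smooth_window Odd integer moving-average width; 1 disables.
#' @return Data frame with `frame_index` (leading frame), `t_s`,
#'   `v_mm_s`.
#' @export
front_velocity <- function(traces, acq = acquisition_params(),
                           smooth_window = 1) {
  if (nrow(traces) < 2)
    stop("velocity needs at least two tracked frames", call. = FALSE)
  d_px <- diff(traces$mean_front_px)
  v <- d_px * acq$pixel_size_um / acq$frame_interval_s / 1000  # mm/s
  if (smooth_window > 1) {
    k <- rep(1 / smooth_window, smooth_window)
    v <- stats::filter(v, k, sides = 2)
    v <- as.numeric(v)
  }
  data.frame(frame_index = traces$frame_index[-nrow(traces)],
             t_s = traces$t_s[-nrow(traces)],
             v_mm_s = v)
}

#' Convert a velocity series to a flow-rate series
#'
#' Q = v * A_gel with A_gel the hydrogel cross-section (2.7 mm^2 for the
#' default 10.8 mm x 250 um geometry); reported in ul/min.
#'
#' @param velocities Data frame from [front_velocity()] (or a numeric
#'   vector of velocities in mm/s).
#' @param geom A [chip_geometry()].
#' @return Same data frame with a `q_ul_min` column (or a numeric
#'   vector).
#' @export
flow_rate_series <- function(velocities, geom = chip_geometry()) {
  a_mm2 <- gel_cross_section_mm2(geom)
  if (is.numeric(velocities)) return(velocities * a_mm2 * 60)
  velocities$q_ul_min <- velocities$v_mm_s * a_mm2 * 60
  velocities
}

#' One-call front-tracking analysis of a time-lapse stack
#'
#' Binarize, track, differentiate, convert: the full flow-front
#' velocimetry chain on a raw intensity stack.
#'
#' @inheritParams binarize_frames
#' @inheritParams track_front
#' @param geom A [chip_geometry()].
#' @param smooth_window Passed to [front_velocity()].
#' @return Data frame with per-interval `t_s`, `mean_front_px`,
#'   `v_mm_s`, `q_ul_min`.
#' @export
analyze_flow_stack <- function(stack, acq = acquisition_params(),
                               geom = chip_geometry(), threshold = 0.5,
                               smooth_window = 1) {
  traces <- track_front(binarize_frames(stack, threshold), acq)
  vel <- front_velocity(traces, acq, smooth_window = smooth_window)
  out <- flow_rate_series(vel, geom)
  out$mean_front_px <- traces$mean_front_px[-nrow(traces)]
  out
}
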