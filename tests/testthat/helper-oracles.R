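# Independent oracles, deliberately written from first principles and
# kept free of the package's own code paths.

# Benjamini-Hochberg step-up by explicit sort-and-scan.
oracle_bh_reject <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- 0
  for (i in seq_len(m)) if (ps[i] <= i * alpha / m) k <- i
  reject <- rep(FALSE, m)
  if (k > 0) reject[ord[seq_len(k)]] <- TRUE
  reject
}

# Two-stage step-up trace: BH at q/(1+q), null-count estimate, second BH.
oracle_two_stage <- function(p, q = 0.05) {
  m <- length(p)
  q1 <- q / (1 + q)
  stage1 <- oracle_bh_reject(p, q1)
  r1 <- sum(stage1)
  if (r1 == 0) return(rep(FALSE, m))
  if (r1 == m) return(rep(TRUE, m))
  oracle_bh_reject(p, q1 * m / (m - r1))
}

# Pooled-variance two-sample t, closed form.
oracle_pooled_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = tstat, p = 2 * pt(-abs(tstat), nx + ny - 2))
}

# Triangle threshold by brute force over every candidate bin: build the
# 256-bin histogram, take the chord from the peak to the far end of the
# longer occupied tail, and scan all bins between for the maximum
# perpendicular distance, computed from the explicit point-line formula.
oracle_triangle_mask <- function(image) {
  rng <- range(image)
  bins <- pmin(floor((image - rng[1]) / (rng[2] - rng[1]) * 256), 255) + 1
  h <- tabulate(bins, 256)
  peak <- which.max(h)
  occ <- range(which(h > 0))
  right <- (occ[2] - peak) >= (peak - occ[1])
  end <- if (right) min(occ[2] + 1, 256) else max(occ[1] - 1, 1)
  p1 <- c(peak, h[peak]); p2 <- c(end, h[end])
  seg <- if (right) peak:end else end:peak
  best <- seg[1]; bestd <- -1
  for (b in seg) {
    d <- abs((p2[2] - p1[2]) * b - (p2[1] - p1[1]) * h[b] +
             p2[1] * p1[2] - p2[2] * p1[1]) /
         sqrt((p2[2] - p1[2])^2 + (p2[1] - p1[1])^2)
    if (d > bestd) { bestd <- d; best <- b }
  }
  mask <- bins >= best
  dim(mask) <- dim(image)
  mask
}

# Default phantom-quantification settings used across morphometry tests:
# full display range of the default phantom levels, no denoising blur
# (phantom noise is controlled by construction).
phantom_quant <- function(image, ...) {
  quantify_vessel_stack(image, display_range = c(0, 140), sigma = 0, ...)
}
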