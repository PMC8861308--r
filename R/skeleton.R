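#' Topological skeleton of a binary mask (Zhang-Suen thinning)
#'
#' Iteratively peels boundary pixels that do not break connectivity or
#' shorten line ends, until the mask is a one-pixel-wide 8-connected
#' centerline. This is the classical two-subiteration Zhang-Suen
#' algorithm; the result approximates the medial axis and its calibrated
#' length is the network length used in [network_metrics()].
#'
#' @param mask Logical matrix.
#' @return Logical matrix of the same shape containing the skeleton.
#' @export
skeletonize <- function(mask) {
  m <- matrix(FALSE, nrow(mask) + 2, ncol(mask) + 2)
  m[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      del <- zs_deletable(m, sub)
      if (any(del)) {
        m[del] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m[2:(nrow(mask) - 1 + 2), 2:(ncol(mask) - 1 + 2), drop = FALSE]
}

# one Zhang-Suen subiteration: logical matrix of pixels to delete
zs_deletable <- function(m, sub) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- 2:(nr - 1); ci <- 2:(nc - 1)
  p1 <- m[ri, ci, drop = FALSE]
  # 8-neighbourhood, clockwise from north
  p2 <- m[ri - 1, ci, drop = FALSE]; p3 <- m[ri - 1, ci + 1, drop = FALSE]
  p4 <- m[ri, ci + 1, drop = FALSE]; p5 <- m[ri + 1, ci + 1, drop = FALSE]
  p6 <- m[ri + 1, ci, drop = FALSE]; p7 <- m[ri + 1, ci - 1, drop = FALSE]
  p8 <- m[ri, ci - 1, drop = FALSE]; p9 <- m[ri - 1, ci - 1, drop = FALSE]
  b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
  a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
       (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
  cond <- if (sub == 1) !(p2 & p4 & p6) & !(p4 & p6 & p8)
          else !(p2 & p4 & p8) & !(p2 & p6 & p8)
  del_core <- p1 & b >= 2 & b <= 6 & a == 1 & cond
  del <- matrix(FALSE, nr, nc)
  del[ri, ci] <- del_core
  del
}
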