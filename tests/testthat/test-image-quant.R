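test_that("maximum projection takes the per-pixel max over slices", {
  m <- matrix(runif(20), 4, 5)
  expect_equal(max_projection(m), m)
  st <- array(0, dim = c(4, 5, 3))
  st[2, 3, ] <- c(10, 50, 30)
  st[1, 1, 1] <- 7; st[4, 5, 2] <- 9       # disjoint bright spots
  pr <- max_projection(st)
  expect_equal(pr[2, 3], 50)
  expect_equal(pr[1, 1], 7); expect_equal(pr[4, 5], 9)
  expect_error(max_projection(array(0, dim = c(2, 2, 0))), "empty")
})

test_that("preprocess clips, rescales and blurs", {
  expect_equal(preprocess(matrix(70, 8, 8), c(35, 70), sigma = 0),
               matrix(1, 8, 8))
  expect_equal(preprocess(matrix(52.5, 8, 8), c(35, 70), sigma = 0),
               matrix(0.5, 8, 8))
  # blur of a constant is the constant
  expect_equal(preprocess(matrix(70, 16, 16), c(35, 70), sigma = 3),
               matrix(1, 16, 16), tolerance = 1e-6)
  # impulse response: peak of a sigma-3 Gaussian kernel is m / (2 pi 9)
  img <- matrix(0, 41, 41); img[21, 21] <- 1
  out <- preprocess(img, c(0, 1), sigma = 3)
  expect_equal(out[21, 21], 1 / (2 * pi * 9), tolerance = 0.01)
  expect_error(preprocess(matrix(1, 2, 2), c(5, 5)), "lo < hi")
})

test_that("triangle threshold matches the brute-force construction", {
  set.seed(7)
  for (i in 1:5) {
    img <- matrix(c(rnorm(9000, 30, 6), rnorm(1000 * i, 200, 12)),
                  nrow = 100)
    expect_identical(triangle_threshold(img), oracle_triangle_mask(img))
  }
})

test_that("triangle threshold separates a bimodal histogram sensibly", {
  set.seed(8)
  img <- matrix(c(rnorm(9000, 30, 6), rnorm(1000, 200, 12)), 100, 100)
  mk <- triangle_threshold(img)
  expect_true(all(mk[img > 150]))            # foreground mode captured
  expect_false(any(mk[img < 20]))            # background core excluded
  # invariance under affine intensity rescale
  expect_identical(triangle_threshold(3 * img + 17), mk)
  # two-value image, 90 percent background
  two <- matrix(0, 100, 100); two[1:10, ] <- 255
  mk2 <- triangle_threshold(two)
  expect_true(all(mk2[1:10, ]) && !any(mk2[11:100, ]))
  expect_error(triangle_threshold(matrix(5, 4, 4)), "constant")
})

test_that("mask cleaning removes specks, fills holes, erodes edges", {
  m <- matrix(FALSE, 120, 120)
  m[11:110, 11:110] <- TRUE
  m[60, 60] <- FALSE                          # interior hole
  m[3, 3] <- TRUE                             # isolated speck
  out <- clean_mask(m)
  expect_false(out[3, 3])
  expect_true(out[60, 60])
  # erosion alone shrinks a square side by 2
  sq <- matrix(FALSE, 30, 30); sq[10:20, 10:20] <- TRUE
  er <- clean_mask(sq, bright_radius = 0, dark_radius = 0)
  expect_equal(sum(er), (11 - 2)^2)
  expect_true(all(which(er, arr.ind = TRUE) >= 11) &&
              all(which(er, arr.ind = TRUE) <= 19))
})

test_that("network metrics: area exact, skeleton length, diameter ratio", {
  # full and empty masks
  full <- matrix(TRUE, 50, 50)
  expect_equal(network_metrics(full, 1)$area_percent, 100)
  empty <- network_metrics(matrix(FALSE, 50, 50), 1)
  expect_equal(empty$area_percent, 0)
  expect_true(is.na(empty$mean_diameter_um))
  # 400 x 40 bar: area is exact; thinning shortens blunt ends by about
  # half the width each, so the length lands between the medial-axis
  # trunk (L - w) and L
  bar <- matrix(FALSE, 60, 420); bar[11:50, 11:410] <- TRUE
  nm <- network_metrics(bar, 1)
  expect_equal(nm$total_area_um2, 400 * 40)
  expect_gte(nm$total_length_um, 355)
  expect_lte(nm$total_length_um, 405)
  expect_equal(nm$mean_diameter_um, nm$total_area_um2 / nm$total_length_um)
  # pixel-count mode counts skeleton pixels
  nm2 <- network_metrics(bar, 1, length_mode = "pixel_count")
  expect_gte(nm2$total_length_um, nm$total_length_um)
})

test_that("skeleton of a thin line is the line itself", {
  m <- matrix(FALSE, 20, 100); m[10, 5:95] <- TRUE
  sk <- skeletonize(m)
  expect_true(all(sk[10, 6:94]))
  expect_equal(sum(sk), sum(sk[10, ]))
})

test_that("tube phantoms recover diameter and length within 10 percent", {
  for (w in c(20, 50, 80)) {
    segs <- data.frame(x0 = 60, y0 = 100, x1 = 540, y1 = 100, width = w)
    g <- synth_tube_network(segs, canvas_px = c(200, 600), noise_sd = 5,
                            psf_sigma = 1, seed = 3)
    res <- phantom_quant(g$image)
    expect_lt(abs(res$metrics$total_length_um - g$truth$total_length_um) /
                g$truth$total_length_um, 0.1)
    expect_lt(abs(res$metrics$mean_diameter_um - g$truth$mean_diameter_um) /
                g$truth$mean_diameter_um, 0.1)
  }
})

test_that("area percentage equals the exact foreground pixel fraction", {
  set.seed(9)
  m <- matrix(runif(10000) < 0.37, 100, 100)
  expect_equal(network_metrics(m, 1)$area_percent, mean(m) * 100)
})

test_that("overlap mask is the pixelwise conjunction", {
  a <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  b <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2)
  expect_equal(overlap_mask(a, a), a)
  expect_equal(sum(overlap_mask(a, b)), 1)
  expect_false(any(overlap_mask(a, !a)))
  sub <- a & b
  expect_equal(overlap_mask(sub, a), sub)     # subset absorbed
  expect_error(overlap_mask(a, matrix(TRUE, 3, 3)), "identical shapes")
})

test_that("pericyte coverage: identity, disjoint, half, empty vessel", {
  v <- matrix(FALSE, 40, 40); v[11:30, 11:30] <- TRUE
  expect_equal(pericyte_metrics(v, v)$coverage_percent, 100)
  d <- matrix(FALSE, 40, 40); d[1:5, 1:5] <- TRUE
  expect_equal(pericyte_metrics(d, v)$coverage_percent, 0)
  half <- matrix(FALSE, 40, 40); half[11:30, 11:20] <- TRUE
  pm <- pericyte_metrics(half, v)
  expect_equal(pm$coverage_percent, 50)
  expect_equal(pm$pericyte_area_percent, sum(half) / 1600 * 100)
  expect_warning(pm0 <- pericyte_metrics(v, matrix(FALSE, 40, 40)), "empty")
  expect_true(is.na(pm0$coverage_percent))
})

test_that("coverage is monotone under dilation of the pericyte mask", {
  set.seed(10)
  v <- matrix(runif(2500) < 0.4, 50, 50)
  s <- matrix(runif(2500) < 0.2, 50, 50)
  cov1 <- pericyte_metrics(s, v)$coverage_percent
  s_dil <- as.matrix(EBImage::dilate(matrix(as.numeric(s), 50, 50),
                                     EBImage::makeBrush(3, "box"))) > 0.5
  dim(s_dil) <- dim(s)
  cov2 <- pericyte_metrics(s_dil, v)$coverage_percent
  expect_gte(cov2, cov1)
  expect_gte(cov1, 0); expect_lte(cov2, 100)
})

test_that("the quantification pipeline is deterministic", {
  segs <- data.frame(x0 = 30, y0 = 40, x1 = 170, y1 = 40, width = 24)
  g <- synth_tube_network(segs, canvas_px = 200, seed = 5)
  r1 <- phantom_quant(g$image)
  r2 <- phantom_quant(g$image)
  expect_identical(r1$mask, r2$mask)
  expect_identical(r1$metrics, r2$metrics)
})
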