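test_that("delta Ct averages replicates and reference genes", {
  expect_equal(delta_ct(25, 20), 5)
  expect_equal(delta_ct(25, list(20, 22)), 4)
  expect_equal(delta_ct(c(20, 21, 19), c(20, 21, 19)), 0)
  expect_equal(delta_ct(c(24, 26), list(c(19, 21), c(21, 23))), 4)
  expect_error(delta_ct(25, list()), "reference")
})

test_that("fold change is 2^-ddCt against the baseline mean", {
  expect_equal(fold_change(5, c(5, 5))$fold_change, 1)
  expect_equal(fold_change(4, 5)$fold_change, 2)
  r <- fold_change(3, c(5, 6, 7))
  expect_equal(r$delta_delta_ct, -3)
  expect_equal(r$fold_change, 8)
  expect_error(fold_change(3, numeric(0)), "baseline")
})

test_that("mean delta-Ct matrix reproduces hand-computed values", {
  tab <- data.frame(
    donor = rep(c("d1", "d2"), each = 6),
    group = rep(c("EC-BMSC", "EC-ASC"), each = 6),
    gene = rep(c("A", "B", "REF"), times = 4),
    replicate = rep(1:2, each = 3, times = 2),
    ct = c(24, 28, 20, 26, 28, 20,      # d1 r1, r2
           25, 30, 21, 27, 30, 21))     # d2 r1, r2
  sch <- normalization_scheme("REF", baseline_group = "EC-ASC")
  m <- mean_dct_matrix(tab, sch)
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(m["d1", "A"], mean(c(24, 26)) - 20)
  expect_equal(m["d2", "B"], mean(c(30, 30)) - 21)
  # duplicated replicate rows do not change the means
  expect_equal(mean_dct_matrix(rbind(tab, tab), sch), m)
  # a missing gene is an explicit error
  expect_error(mean_dct_matrix(tab[tab$gene != "A" | tab$donor != "d2", ],
                               sch), "missing")
})

test_that("single donor and gene give a 1x1 matrix with its delta Ct", {
  tab <- data.frame(donor = "d1", group = "EC-ASC",
                    gene = rep(c("A", "REF"), each = 3),
                    replicate = rep(1:3, 2), ct = c(25, 25, 25, 20, 20, 20))
  m <- mean_dct_matrix(tab, normalization_scheme("REF"))
  expect_equal(unname(m[1, 1]), 5)
})

test_that("hierarchical clustering merges nearest rows first", {
  m <- rbind(a = c(0, 0), b = c(0, 0), c = c(3, 4))
  hc <- hierarchical_cluster(m)
  expect_equal(hc$hclust$height[1], 0)            # identical rows first
  m2 <- rbind(x = 0, y = 1, z = 10)
  hc2 <- hierarchical_cluster(m2)
  expect_equal(sort(hc2$hclust$merge[1, ]), c(-2, -1))   # {0,1} merge
  # translation invariance of merge heights
  hc3 <- hierarchical_cluster(m2 + 100)
  expect_equal(hc2$hclust$height, hc3$hclust$height)
  expect_error(hierarchical_cluster(rbind(c(1, NA), c(0, 0))), "missing")
})

test_that("groups with separated delta Ct form their own clusters", {
  ct <- synth_ct_table(c(G1 = 6, G2 = 4, G3 = 5), noise_sd = 0.2, seed = 21)
  m <- mean_dct_matrix(ct, normalization_scheme(c("RNA18S", "GAPDH")))
  hc <- hierarchical_cluster(m)
  grp <- ifelse(grepl("BMSC", rownames(m)), "B", "A")
  k2 <- cutree(hc$hclust, k = 2)
  expect_equal(length(unique(tapply(grp, k2, function(g)
    paste(sort(unique(g)), collapse = "")))), 2)
})

test_that("pooled t matches the closed form to 1e-12", {
  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(3 + i %% 3); y <- rnorm(4, mean = 0.5)
    got <- unpaired_t(x, y)
    want <- oracle_pooled_t(x, y)
    expect_equal(got$t, want$t, tolerance = 1e-12)
    expect_equal(got$p_value, want$p, tolerance = 1e-12)
    expect_equal(got$df, length(x) + length(y) - 2)
  }
})

test_that("degenerate t inputs resolve by the means", {
  expect_equal(unpaired_t(c(1, 2, 3), c(1, 2, 3))$t, 0)
  expect_equal(unpaired_t(c(5, 5), c(5, 5))$p_value, 1)
  expect_equal(unpaired_t(c(0, 0, 0), c(1, 1, 1))$p_value, 0)
  eps <- 1e-9
  p <- unpaired_t(c(0, eps, -eps), c(1, 1 + eps, 1 - eps))$p_value
  expect_lt(p, 0.001)
})

test_that("two-stage FDR reproduces the hand-traced examples", {
  expect_false(any(two_stage_fdr(rep(1, 6))$reject))
  expect_true(two_stage_fdr(0.01, q = 0.05)$reject)      # 0.01 <= 0.05/1.05
  r <- two_stage_fdr(c(0.001, 0.002, 0.8, 0.9), q = 0.05)
  expect_equal(r$reject, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$m0, 2L)
  expect_error(two_stage_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  # adjusted values reproduce the decisions at the target level
  set.seed(12)
  for (i in 1:20) {
    p <- runif(12)^(1 + i %% 3)
    out <- two_stage_fdr(p, q = 0.05)
    expect_equal(out$reject, out$adjusted <= 0.05)
  }
})

test_that("two-stage FDR brackets plain BH at its two levels", {
  set.seed(13)
  q <- 0.05
  for (i in 1:50) {
    m <- sample(4:30, 1)
    p <- runif(m)^sample(1:3, 1)
    out <- two_stage_fdr(p, q)
    lo <- oracle_bh_reject(p, q / (1 + q))
    expect_true(all(out$reject[lo]))              # superset of strict BH
    hi <- oracle_bh_reject(p, q * m / max(out$m0, 1) / (1 + q))
    expect_true(all(hi[out$reject]))              # subset of inflated BH
  }
})

test_that("programmed fold changes are recovered from synthetic tables", {
  sch <- normalization_scheme(c("RNA18S", "GAPDH"))
  # zero noise: exact recovery, reference genes at fold 1
  ct0 <- synth_ct_table(c(A = 8, B = 1, C = 0.5), noise_sd = 0, seed = 14)
  fc0 <- fold_change_table(ct0, sch, drop_references = FALSE)
  agg <- aggregate(fold_change ~ gene + group, fc0, mean)
  g <- function(gene, grp) agg$fold_change[agg$gene == gene & agg$group == grp]
  expect_equal(g("A", "EC-BMSC"), 8, tolerance = 1e-12)
  expect_equal(g("B", "EC-BMSC"), 1, tolerance = 1e-12)
  expect_equal(g("C", "EC-BMSC"), 0.5, tolerance = 1e-12)
  expect_equal(g("RNA18S", "EC-BMSC"), 1, tolerance = 1e-12)
  expect_equal(g("A", "EC-ASC"), 1, tolerance = 1e-12)
  # sigma = 0.3 noise: recovery within 2^(+/- 2 sigma / sqrt(n))
  ct1 <- synth_ct_table(c(A = 8, B = 1, C = 0.5), noise_sd = 0.3, seed = 15)
  fc1 <- fold_change_table(ct1, sch)
  agg1 <- aggregate(delta_delta_ct ~ gene, fc1[fc1$group == "EC-BMSC", ], mean)
  tol <- 2 * 0.3 / sqrt(3)
  for (gene in c("A", "B", "C")) {
    programmed <- c(A = 8, B = 1, C = 0.5)[[gene]]
    got <- 2^(-agg1$delta_delta_ct[agg1$gene == gene])
    expect_lt(abs(log2(got) - log2(programmed)), tol)
  }
})

test_that("group comparison flags programmed effects and spares nulls", {
  ct <- synth_ct_table(c(UP = 6, FLAT = 1, DOWN = 0.4, FLAT2 = 1),
                       noise_sd = 0.2, seed = 16)
  fc <- fold_change_table(ct, normalization_scheme(c("RNA18S", "GAPDH")))
  res <- compare_groups(fc)
  expect_true(all(res$significant[res$gene %in% c("UP", "DOWN")]))
  expect_false(any(res$significant[res$gene %in% c("FLAT", "FLAT2")]))
  expect_equal(res$stars[res$gene == "FLAT"], "ns")
})
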