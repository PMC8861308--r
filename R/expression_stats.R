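#' Normalization scheme for relative qPCR quantification
#'
#' @param reference_genes Character vector of reference-gene symbols
#'   (e.g. `c("RNA18S", "GAPDH")` for most panels, `"PECAM1"` for
#'   endothelial genes normalized to endothelial content).
#' @param baseline_group Group whose average expression defines fold
#'   change 1.
#' @return An object of class `normalization_scheme`.
#' @export
normalization_scheme <- function(reference_genes,
                                 baseline_group = "EC-ASC") {
  if (length(reference_genes) < 1)
    stop("at least one reference gene is required", call. = FALSE)
  structure(list(reference_genes = as.character(reference_genes),
                 baseline_group = baseline_group),
            class = "normalization_scheme")
}

#' Reference-normalized Ct difference
#'
#' Delta Ct = replicate-mean Ct of the target minus the mean over
#' reference genes of their replicate-mean Ct. With several reference
#' genes, the arithmetic mean of their Ct values is used, which
#' corresponds to normalizing expression by their geometric mean.
#'
#' @param ct_target Numeric: technical-replicate Ct values of the
#'   target gene in one sample.
#' @param ct_references List of numeric vectors, one per reference
#'   gene, or a single numeric vector for one reference.
#' @return Delta Ct in cycles.
#' @export
delta_ct <- function(ct_target, ct_references) {
  if (is.numeric(ct_references)) ct_references <- list(ct_references)
  if (length(ct_references) == 0)
    stop("reference Ct values are required", call. = FALSE)
  mean(ct_target) - mean(vapply(ct_references, mean, numeric(1)))
}

#' Fold change by the 2^-ddCt method
#'
#' ddCt = dCt of the sample minus the mean dCt of the baseline samples;
#' fold change = 2^-ddCt.
#'
#' @param delta_ct_sample Delta Ct of the sample (cycles).
#' @param baseline_delta_cts Numeric vector of baseline-group delta Ct
#'   values.
#' @return A list: `delta_delta_ct`, `fold_change`.
#' @export
fold_change <- function(delta_ct_sample, baseline_delta_cts) {
  if (length(baseline_delta_cts) == 0)
    stop("baseline delta Ct values are required", call. = FALSE)
  ddct <- delta_ct_sample - mean(baseline_delta_cts)
  list(delta_delta_ct = ddct, fold_change = 2^(-ddct))
}

# per donor x gene replicate-mean delta Ct from a long Ct table
# ct_table: data.frame(sample, donor, group, gene, replicate, ct)
donor_delta_ct <- function(ct_table, scheme) {
  stopifnot(all(c("donor", "group", "gene", "ct") %in% names(ct_table)))
  miss <- setdiff(scheme$reference_genes, unique(ct_table$gene))
  if (length(miss))
    stop("reference gene(s) missing from table: ",
         paste(miss, collapse = ", "), call. = FALSE)
  mean_ct <- stats::aggregate(ct ~ donor + group + gene, ct_table, mean)
  ref <- mean_ct[mean_ct$gene %in% scheme$reference_genes, ]
  ref_mean <- stats::aggregate(ct ~ donor + group, ref, mean)
  names(ref_mean)[names(ref_mean) == "ct"] <- "ref_ct"
  out <- merge(mean_ct, ref_mean, by = c("donor", "group"))
  out$delta_ct <- out$ct - out$ref_ct
  out[order(out$gene, out$group, out$donor),
      c("donor", "group", "gene", "delta_ct")]
}

#' Donor-level fold changes for every gene in a Ct table
#'
#' Computes per-donor replicate-mean delta Ct values (target minus the
#' mean of the reference genes), then delta delta Ct and fold change
#' relative to the average delta Ct of the baseline group.
#'
#' @param ct_table Data frame with columns `donor`, `group`, `gene`,
#'   `replicate`, `ct` (long format, one row per technical replicate).
#' @param scheme A [normalization_scheme()].
#' @param drop_references Drop reference genes from the result
#'   (default TRUE).
#' @return Data frame with `donor`, `group`, `gene`, `delta_ct`,
#'   `delta_delta_ct`, `fold_change`.
#' @export
fold_change_table <- function(ct_table, scheme, drop_references = TRUE) {
  dct <- donor_delta_ct(ct_table, scheme)
  base <- dct[dct$group == scheme$baseline_group, ]
  if (nrow(base) == 0)
    stop("baseline group '", scheme$baseline_group, "' not found",
         call. = FALSE)
  base_mean <- stats::aggregate(delta_ct ~ gene, base, mean)
  names(base_mean)[2] <- "baseline_delta_ct"
  out <- merge(dct, base_mean, by = "gene")
  out$delta_delta_ct <- out$delta_ct - out$baseline_delta_ct
  out$fold_change <- 2^(-out$delta_delta_ct)
  out$baseline_delta_ct <- NULL
  if (drop_references)
    out <- out[!(out$gene %in% scheme$reference_genes), ]
  out[order(out$gene, out$group, out$donor), ]
}

#' Donor x gene matrix of mean delta Ct values
#'
#' The heatmap input: one row per donor cell line, one column per gene,
#' entries the replicate-averaged delta Ct.
#'
#' @inheritParams fold_change_table
#' @return Numeric matrix with donors as rows and genes as columns.
#' @export
mean_dct_matrix <- function(ct_table, scheme, drop_references = TRUE) {
  dct <- donor_delta_ct(ct_table, scheme)
  if (drop_references)
    dct <- dct[!(dct$gene %in% scheme$reference_genes), ]
  donors <- sort(unique(dct$donor)); genes <- sort(unique(dct$gene))
  m <- matrix(NA_real_, length(donors), length(genes),
              dimnames = list(donors, genes))
  m[cbind(match(dct$donor, donors), match(dct$gene, genes))] <- dct$delta_ct
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)
    stop("missing delta Ct for donor/gene: ",
         paste(rownames(m)[bad[, 1]], colnames(m)[bad[, 2]],
               sep = "/", collapse = ", "), call. = FALSE)
  }
  m
}

#' Hierarchical clustering of a delta-Ct matrix
#'
#' Agglomerative clustering on Euclidean row distances (complete
#' linkage by default, matching the default of the R heatmap stack used
#' for such figures).
#'
#' @param mat Numeric matrix (rows are clustered).
#' @param linkage Agglomeration method for [stats::hclust()].
#' @return A list: `hclust` (the merge tree) and `order` (leaf labels
#'   in dendrogram order).
#' @export
hierarchical_cluster <- function(mat, linkage = "complete") {
  if (nrow(mat) < 2) stop("clustering needs at least 2 rows", call. = FALSE)
  if (anyNA(mat)) stop("matrix contains missing values", call. = FALSE)
  hc <- stats::hclust(stats::dist(mat, method = "euclidean"),
                      method = linkage)
  list(hclust = hc, order = rownames(mat)[hc$order])
}

#' Unpaired two-sample t-test
#'
#' Classical pooled-variance (Student) two-sided t-test with
#' nx + ny - 2 degrees of freedom; `welch = TRUE` switches to the
#' Welch-Satterthwaite form. Degenerate zero-variance inputs are
#' resolved by the means: equal means give p = 1, unequal means p = 0.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @param welch Use the Welch test instead of pooled variance.
#' @return A list: `t`, `df`, `p_value`.
#' @export
unpaired_t <- function(x, y, welch = FALSE) {
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs at least 2 values", call. = FALSE)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, df = length(x) + length(y) - 2,
                                        p_value = 1))
    return(list(t = sign(mean(x) - mean(y)) * Inf,
                df = length(x) + length(y) - 2, p_value = 0))
  }
  ht <- stats::t.test(x, y, var.equal = !welch)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Two-stage step-up false discovery rate control
#'
#' The adaptive two-stage linear step-up procedure of Benjamini,
#' Krieger and Yekutieli: a first Benjamini-Hochberg pass at level
#' q' = q/(1+q) estimates the number of true null hypotheses
#' m0 = m - r1 from its rejection count r1; if r1 = 0 nothing is
#' rejected, if r1 = m everything is, otherwise a second BH pass runs at
#' the inflated level q' * m / m0. Reported adjusted values ("q values")
#' are the BH-adjusted p values scaled by m0/m from the second stage,
#' capped at 1, so `adjusted <= q` reproduces the stage-2 decisions in
#' the non-degenerate case.
#'
#' @param pvalues Numeric vector of p values in \[0, 1\].
#' @param q Target false discovery rate, default 0.05.
#' @return A list: `reject` (logical, per input), `adjusted` (numeric),
#'   `m0` (estimated true nulls), `r1` (stage-1 rejection count).
#' @export
two_stage_fdr <- function(pvalues, q = 0.05) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p values must lie in [0, 1]", call. = FALSE)
  m <- length(pvalues)
  q1 <- q / (1 + q)
  bh <- stats::p.adjust(pvalues, method = "BH")
  r1 <- sum(bh <= q1)
  m0 <- m - r1
  reject <- if (r1 == 0) rep(FALSE, m)
            else if (r1 == m) rep(TRUE, m)
            else bh <= q1 * m / m0                 # stage-2 BH at q1 * m/m0
  # q-values on the scale of q: adjusted <= q reproduces the decisions in
  # every branch (m0 = m when nothing was rejected at stage 1; the
  # reject-all branch uses the floor m0 = 1)
  adjusted <- pmin(bh * (1 + q) * max(m0, 1) / m, 1)
  list(reject = reject, adjusted = adjusted, m0 = as.integer(m0),
       r1 = as.integer(r1))
}

#' Per-gene group comparison with FDR correction
#'
#' Unpaired t-tests on donor-level delta delta Ct values between the
#' two groups for every gene, with two-stage step-up FDR correction
#' across genes and the conventional significance stars.
#'
#' @param fc_table Output of [fold_change_table()].
#' @param group_a,group_b Group labels to compare.
#' @param q Target FDR.
#' @param welch Passed to [unpaired_t()].
#' @return Data frame with one row per gene: mean fold change per
#'   group, `t`, `p_value`, `adjusted_p`, `significant`, `stars`.
#' @export
compare_groups <- function(fc_table, group_a = "EC-BMSC",
                           group_b = "EC-ASC", q = 0.05, welch = FALSE) {
  genes <- sort(unique(fc_table$gene))
  rows <- lapply(genes, function(g) {
    sub <- fc_table[fc_table$gene == g, ]
    xa <- sub$delta_delta_ct[sub$group == group_a]
    xb <- sub$delta_delta_ct[sub$group == group_b]
    tt <- unpaired_t(xa, xb, welch = welch)
    data.frame(gene = g,
               mean_fold_a = mean(2^(-xa)),
               mean_fold_b = mean(2^(-xb)),
               t = tt$t, p_value = tt$p_value)
  })
  out <- do.call(rbind, rows)
  fdr <- two_stage_fdr(out$p_value, q = q)
  out$adjusted_p <- fdr$adjusted
  out$significant <- fdr$reject
  out$stars <- significance_stars(out$adjusted_p)
  out$stars[!out$significant] <- "ns"
  out
}

significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
         ifelse(p < 0.05, "*", "ns")))
}
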