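#' Median-of-ratios size factors
#'
#' Per-sample scaling constants computed by the median-of-ratios method:
#' for each gene with strictly positive counts in every sample, the ratio of
#' the sample's count to the gene's geometric mean across samples is formed,
#' and the size factor of a sample is the median of those ratios.
#'
#' @param counts integer matrix, genes x samples.
#' @return named numeric vector of positive size factors, one per sample.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop_input("need at least two samples")
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) stop_input("no gene has positive counts in every sample")
  logc <- log(counts[pos, , drop = FALSE])
  loggeo <- rowMeans(logc)
  sf <- apply(logc, 2, function(lc) stats::median(exp(lc - loggeo)))
  if (any(sf <= 0)) stop_input("degenerate size factor <= 0")
  sf
}

#' Per-condition normalized expression means
#'
#' @param counts genes x samples count matrix.
#' @param factors size factors from [size_factors()].
#' @param groups two-level sample grouping; the first level is the reference
#'   (control) condition.
#' @return data.frame with columns `gene`, `mean_ctrl`, `mean_trt`.
#' @export
condition_means <- function(counts, factors, groups) {
  counts <- as.matrix(counts)
  gr <- split_groups(groups, ncol(counts))
  y <- sweep(counts, 2, factors, "/")
  data.frame(
    gene = rownames(counts),
    mean_ctrl = rowMeans(y[, gr$ref_idx, drop = FALSE]),
    mean_trt = rowMeans(y[, gr$alt_idx, drop = FALSE]),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Log2 fold change of treated over control means
#'
#' Returns `log2(mean_trt / mean_ctrl)`; positive values indicate
#' upregulation under treatment. Undefined when either mean is not strictly
#' positive, in which case `NA` is returned (such genes are excluded from
#' testing rather than pseudocounted).
#'
#' @param mean_ctrl,mean_trt normalized condition means (vectorized).
#' @return numeric vector of log2 fold changes, `NA` where undefined.
#' @export
log2_fold_change <- function(mean_ctrl, mean_trt) {
  out <- rep(NA_real_, length(mean_ctrl))
  ok <- !is.na(mean_ctrl) & !is.na(mean_trt) & mean_ctrl > 0 & mean_trt > 0
  out[ok] <- log2(mean_trt[ok] / mean_ctrl[ok])
  out
}

# Rolling-mean trend of gene-wise dispersions along the mean-expression
# ordering; windows shrink symmetrically at the edges.
dispersion_trend <- function(alpha_hat, mu, window = 101L) {
  n <- length(alpha_hat)
  window <- min(window, n)
  if (window %% 2L == 0L) window <- window - 1L
  o <- order(mu)
  a <- alpha_hat[o]
  half <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, a))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  tr <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  out <- numeric(n)
  out[o] <- tr
  out
}

#' Negative-binomial Wald test for a two-group comparison
#'
#' Gene-wise test of differential expression on normalized counts. The NB
#' dispersion alpha (variance = mu + alpha * mu^2) is estimated per gene by
#' the method of moments within each group, `max(0, (s^2 - m) / m^2)`, and
#' averaged across the two groups. With `dispersion_mode = "shrink"` (the
#' default) the gene-wise estimate is shrunk half-way toward a mean-dependent
#' trend, a rolling mean of the gene-wise estimates along the expression
#' ordering, which stabilises the small-replicate estimates. The Wald
#' statistic is the log2 fold change over its delta-method standard error,
#' `SE^2 = (1/ln 2)^2 * sum_cond (1/n_cond) * (1/mu_cond + alpha)`, referred
#' to the standard normal (two-sided).
#'
#' Genes with a non-positive mean in either condition are flagged and
#' reported with `NA` statistics.
#'
#' @param counts genes x samples count matrix (all-zero genes removed).
#' @param factors size factors from [size_factors()].
#' @param groups two-level grouping, >= 2 replicates per group.
#' @param dispersion_mode `"shrink"` (trend-shrunk) or `"gene"` (raw
#'   gene-wise method-of-moments).
#' @param shrink_weight weight of the trend in the shrunk estimate.
#' @param trend_window window (genes) of the rolling-mean trend.
#' @return data.frame with columns `gene`, `log2fc`, `se`, `dispersion`,
#'   `stat`, `pvalue`.
#' @export
nb_wald_test <- function(counts, factors, groups,
                         dispersion_mode = c("shrink", "gene"),
                         shrink_weight = 0.5, trend_window = 101L) {
  dispersion_mode <- match.arg(dispersion_mode)
  counts <- as.matrix(counts)
  gr <- split_groups(groups, ncol(counts))
  n1 <- length(gr$ref_idx)
  n2 <- length(gr$alt_idx)
  if (n1 < 2L || n2 < 2L) stop_input("each group needs >= 2 replicates")

  y <- sweep(counts, 2, factors, "/")
  y1 <- y[, gr$ref_idx, drop = FALSE]
  y2 <- y[, gr$alt_idx, drop = FALSE]
  m1 <- rowMeans(y1)
  m2 <- rowMeans(y2)
  v1 <- rowSums((y1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((y2 - m2)^2) / (n2 - 1)

  ok <- m1 > 0 & m2 > 0
  a1 <- ifelse(m1 > 0, pmax(0, (v1 - m1) / m1^2), NA_real_)
  a2 <- ifelse(m2 > 0, pmax(0, (v2 - m2) / m2^2), NA_real_)
  alpha_hat <- (a1 + a2) / 2

  if (dispersion_mode == "shrink" && sum(ok) > 2L) {
    mu0 <- (m1 + m2) / 2
    tr <- rep(NA_real_, length(alpha_hat))
    tr[ok] <- dispersion_trend(alpha_hat[ok], mu0[ok], trend_window)
    alpha_hat[ok] <- (1 - shrink_weight) * alpha_hat[ok] + shrink_weight * tr[ok]
  }

  lfc <- log2_fold_change(m1, m2)
  se2 <- (1 / log(2))^2 * ((1 / n1) * (1 / m1 + alpha_hat) +
                           (1 / n2) * (1 / m2 + alpha_hat))
  se <- ifelse(ok, sqrt(se2), NA_real_)
  z <- lfc / se
  p <- 2 * stats::pnorm(-abs(z))
  # identical groups give lfc exactly 0 hence p exactly 1
  data.frame(gene = rownames(counts), log2fc = lfc, se = se,
             dispersion = alpha_hat, stat = z, pvalue = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: the q-value of the i-th smallest p is
#' `min over j >= i of m * p_(j) / j`, capped at 1, reported in the original
#' order. Delegates to [stats::p.adjust()] with `method = "BH"`.
#'
#' @param pvalues numeric vector of p-values in \[0,1\] (`NA` passed through).
#' @return q-values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  pv <- pvalues[!is.na(pvalues)]
  if (length(pv) && (any(pv < 0) || any(pv > 1))) {
    stop_input("p-values must lie in [0,1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Call differentially expressed genes from a two-group count matrix
#'
#' The full differential-expression stage: drops all-zero genes, computes
#' median-of-ratios size factors, per-condition normalized means, log2 fold
#' changes, NB Wald p-values, and BH q-values, and flags genes with
#' `qvalue <= alpha` as DEGs. Genes with an undefined fold change (a zero
#' condition mean) are retained in the table with `NA` statistics but never
#' called.
#'
#' @param counts genes x samples count matrix.
#' @param groups two-level grouping (first level = control).
#' @param alpha DEG significance threshold on the q-value (inclusive).
#' @param ... passed to [nb_wald_test()].
#' @return object of class `deg_results`: list with `table` (one row per
#'   kept gene, sorted by q-value: `gene`, `mean_ctrl`, `mean_trt`, `log2fc`,
#'   `pvalue`, `qvalue`, `is_deg`, `direction`), `n_deg`, `n_up`, `n_down`,
#'   `size_factors`, and counts of dropped/untested genes.
#' @export
call_degs <- function(counts, groups, alpha = 0.05, ...) {
  counts <- as.matrix(counts)
  nonzero <- rowSums(counts) > 0
  n_dropped <- sum(!nonzero)
  counts <- counts[nonzero, , drop = FALSE]
  if (nrow(counts) == 0L) stop_input("no nonzero genes in the count matrix")

  sf <- size_factors(counts)
  cm <- condition_means(counts, sf, groups)
  wt <- nb_wald_test(counts, sf, groups, ...)
  q <- bh_adjust(wt$pvalue)

  tab <- data.frame(
    gene = cm$gene,
    mean_ctrl = cm$mean_ctrl,
    mean_trt = cm$mean_trt,
    log2fc = wt$log2fc,
    pvalue = wt$pvalue,
    qvalue = q,
    stringsAsFactors = FALSE
  )
  tab$is_deg <- !is.na(tab$qvalue) & tab$qvalue <= alpha
  tab$direction <- ifelse(is.na(tab$log2fc), NA_character_,
                          ifelse(tab$log2fc > 0, "up", "down"))
  tab <- tab[order(tab$qvalue, tab$gene), , drop = FALSE]
  rownames(tab) <- NULL

  structure(list(
    table = tab,
    n_deg = sum(tab$is_deg),
    n_up = sum(tab$is_deg & tab$direction == "up"),
    n_down = sum(tab$is_deg & tab$direction == "down"),
    size_factors = sf,
    n_dropped_allzero = n_dropped,
    n_untested = sum(is.na(tab$pvalue)),
    alpha = alpha
  ), class = "deg_results")
}

#' @export
print.deg_results <- function(x, ...) {
  cat(sprintf("DEG call: %d genes tested, %d untested (zero condition mean), %d all-zero dropped\n",
              nrow(x$table) - x$n_untested, x$n_untested, x$n_dropped_allzero))
  cat(sprintf("%d DEGs at q <= %g (%d up, %d down)\n",
              x$n_deg, x$alpha, x$n_up, x$n_down))
  invisible(x)
}

#' @rdname write_synthetic
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' @rdname write_synthetic
#' @export
read_sample_sheet <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname write_synthetic
#' @export
write_deg_table <- function(res, path) {
  utils::write.table(res$table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
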