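# Two-group differential statistics and the significance filter
# (padj <= 0.05 and |log2FC| >= 0.5 by default) applied to gene counts and
# peak-level signals.

#' Library-size normalisation of a count matrix
#'
#' `median_of_ratios`: per-sample factor is the median across genes of the
#' count over the gene's geometric mean (the DESeq-style size factor),
#' computed over genes with nonzero counts in every sample.
#' `per_million`: factor is the column sum divided by 1e6.
#' The normalised matrix divides each column by its factor.
#'
#' @param expr genes x samples count matrix.
#' @param mode `"median_of_ratios"` (default) or `"per_million"`.
#' @return List `normalized` (matrix) and `factors` (named positive
#'   scale factors).
#' @export
normalize_library <- function(expr, mode = c("median_of_ratios",
                                             "per_million")) {
  mode <- match.arg(mode)
  if (any(colSums(expr) == 0)) stop("all-zero sample")
  if (mode == "per_million") {
    f <- colSums(expr) / 1e6
  } else {
    pos <- rowSums(expr > 0) == ncol(expr)
    if (!any(pos))
      stop("median_of_ratios needs >= 1 gene with nonzero counts in all ",
           "samples")
    sub <- expr[pos, , drop = FALSE]
    geo <- exp(rowMeans(log(sub)))
    f <- apply(sub / geo, 2, median)
  }
  if (any(f <= 0)) stop("non-positive normalization factor")
  list(normalized = sweep(expr, 2, f, "/"), factors = f)
}

#' Spike-in derived scale factors
#'
#' Per-sample factor is the geometric mean of all spike counts divided by
#' the sample's spike count, so a sample with more spike reads (more
#' material sequenced) is scaled down. Factors are invariant to a common
#' rescaling of all spike counts and have geometric mean 1.
#'
#' @param spike_counts named positive numeric vector (sample -> count).
#' @return Named numeric factors.
#' @export
spike_in_factors <- function(spike_counts) {
  if (any(spike_counts <= 0)) stop("spike counts must be > 0")
  exp(mean(log(spike_counts))) / spike_counts
}

#' Two-group differential test on a normalised matrix
#'
#' `welch_log` runs a Welch t-test on `log2(x + 1)` per feature and needs
#' at least two replicates per group; `exact_permutation` uses the absolute
#' difference of group means of `log2(x + 1)` as statistic and enumerates
#' all distinct label assignments (the observed one included), which is
#' exact for the small designs this package targets. Log2 fold changes are
#' `log2((mean2 + 1) / (mean1 + 1))` on the normalised scale.
#'
#' @param mat normalised genes/peaks x samples matrix.
#' @param design named condition vector over columns (exactly 2 levels).
#' @param test `"welch_log"` or `"exact_permutation"`.
#' @return data.frame (feature_id, log2fc, pvalue).
#' @export
two_group_test <- function(mat, design, test = c("welch_log",
                                                 "exact_permutation")) {
  test <- match.arg(test)
  design <- design[colnames(mat)]
  lev <- unique(design)
  if (length(lev) != 2) stop("exactly two conditions required")
  g1 <- which(design == lev[1]); g2 <- which(design == lev[2])
  if (test == "welch_log" && (length(g1) < 2 || length(g2) < 2))
    stop("welch_log needs >= 2 replicates per group; ",
         "use test = 'exact_permutation'")
  lg <- log2(mat + 1)
  m1 <- rowMeans(mat[, g1, drop = FALSE])
  m2 <- rowMeans(mat[, g2, drop = FALSE])
  log2fc <- log2((m2 + 1) / (m1 + 1))
  if (test == "welch_log") {
    pvalue <- vapply(seq_len(nrow(mat)), function(i) {
      x <- lg[i, g1]; y <- lg[i, g2]
      if (stats::sd(x) == 0 && stats::sd(y) == 0)
        return(if (mean(x) == mean(y)) 1 else 0)
      stats::t.test(y, x)$p.value
    }, 0)
  } else {
    n <- ncol(mat)
    combs <- utils::combn(n, length(g1))
    pvalue <- vapply(seq_len(nrow(mat)), function(i) {
      v <- lg[i, ]
      obs <- abs(mean(v[g2]) - mean(v[g1]))
      stat <- apply(combs, 2, function(idx)
        abs(mean(v[-idx]) - mean(v[idx])))
      mean(stat >= obs - 1e-12)
    }, 0)
  }
  data.frame(feature_id = rownames(mat) %||% as.character(seq_len(nrow(mat))),
             log2fc = log2fc, pvalue = pvalue, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; monotone in p-value rank and capped at 1.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1 | is.na(pvalues)))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Apply the significance filter and count up/down features
#'
#' A feature is significant when `padj <= padj_max` and
#' `|log2fc| >= lfc_min` (both boundaries inclusive).
#'
#' @param results data.frame with `log2fc` and `pvalue` columns (a
#'   [two_group_test()] output); `padj` is added if absent.
#' @param padj_max adjusted p-value ceiling (default 0.05).
#' @param lfc_min absolute log2 fold change floor (default 0.5).
#' @return List `results` (with `padj` and `significant` columns) and
#'   `counts` (named vector n_up, n_down).
#' @export
apply_significance <- function(results, padj_max = 0.05, lfc_min = 0.5) {
  if (is.null(results$padj)) results$padj <- bh_adjust(results$pvalue)
  results$significant <- results$padj <= padj_max &
    abs(results$log2fc) >= lfc_min
  counts <- c(n_up = sum(results$significant & results$log2fc > 0),
              n_down = sum(results$significant & results$log2fc < 0))
  list(results = results, counts = counts)
}

#' Per-peak differential signal between conditions
#'
#' Sums signal-track coverage over each peak interval per sample, scales
#' by the supplied (e.g. spike-in) factors, then applies
#' [two_group_test()] and [apply_significance()].
#'
#' @param peaks a [peak_set()] (the peak universe to test).
#' @param tracks named list of [signal_track()]s, one per sample.
#' @param design named condition vector over the track names.
#' @param factors optional named scale factors (default all 1).
#' @param ... passed to [apply_significance()].
#' @return As [apply_significance()].
#' @export
peak_differential <- function(peaks, tracks, design, factors = NULL, ...) {
  if (is.null(factors)) factors <- setNames(rep(1, length(tracks)),
                                            names(tracks))
  mat <- vapply(names(tracks), function(s) {
    tr <- tracks[[s]]
    vapply(seq_len(nrow(peaks)), function(i) {
      v <- tr$values[[peaks$chrom[i]]]
      b0 <- bin_of(peaks$start[i], tr$bin_size)
      b1 <- min(bin_of(peaks$end[i] - 1, tr$bin_size), length(v))
      sum(v[b0:b1]) * tr$bin_size
    }, 0) * factors[[s]]
  }, numeric(nrow(peaks)))
  rownames(mat) <- sprintf("%s:%d-%d", peaks$chrom, peaks$start, peaks$end)
  res <- two_group_test(mat, design, test = "welch_log")
  apply_significance(res, ...)
}
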