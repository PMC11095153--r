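# Activity-by-contact (ABC) promoter-enhancer scoring and the ABC-P^2
# extension (ABC multiplied by the squared promoter activity score).

# Summed per-bp signal of a track over a 0-based half-open interval.
.track_sum <- function(track, chrom, start, end) {
  v <- track$values[[chrom]]
  if (is.null(v)) return(0)
  bs <- track$bin_size
  b0 <- bin_of(start, bs); b1 <- min(bin_of(end - 1, bs), length(v))
  if (b0 > length(v)) return(0)
  w <- vapply(b0:b1, function(b) min(end, b * bs) - max(start, (b - 1) * bs), 0)
  sum(v[b0:b1] * w)
}

#' Candidate enhancers of a gene
#'
#' Enhancers on the gene's chromosome whose midpoint lies within the
#' +/- `window` bp area around the TSS (half-open on the right).
#'
#' @param gene one-row slice of a [gene_annotation()].
#' @param enhancers an enhancer [peak_set()].
#' @param window half-width in bp (default 1 Mb).
#' @return The qualifying rows of `enhancers`.
#' @export
candidate_enhancers <- function(gene, enhancers, window = 1e6) {
  mid <- floor((enhancers$start + enhancers$end) / 2)
  keep <- enhancers$chrom == gene$chrom &
    mid >= gene$tss - window & mid < gene$tss + window
  out <- enhancers[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enhancer activity (A) score
#'
#' Activity-mark signal over the enhancer interval, scaled by the sample's
#' calibration factor. `mode = "sum"` (default) integrates per-bp signal
#' over the interval; `"mean"` averages it.
#'
#' @param enhancer one-row enhancer slice (chrom, start, end).
#' @param k27ac_track activity-mark [signal_track()].
#' @param factor calibration scale factor (e.g. spike-in derived).
#' @param mode `"sum"` or `"mean"`.
#' @return Numeric A score.
#' @export
activity_A <- function(enhancer, k27ac_track, factor = 1,
                       mode = c("sum", "mean")) {
  mode <- match.arg(mode)
  s <- .track_sum(k27ac_track, enhancer$chrom, enhancer$start, enhancer$end)
  if (mode == "mean") s <- s / (enhancer$end - enhancer$start)
  s * factor
}

#' Promoter-enhancer contact (C) score
#'
#' Raw contact count between the TSS bin and the enhancer-midpoint bin at
#' the map's resolution, divided by the chromosome's total cis contacts
#' per million — so C is invariant to sequencing depth.
#'
#' @param gene one-row gene slice; @param enhancer one-row enhancer slice
#'   (same chromosome).
#' @param contacts a [contact_map()] (conventionally at 5 kb resolution).
#' @return Numeric C score.
#' @export
contact_C <- function(gene, enhancer, contacts) {
  if (gene$chrom != enhancer$chrom)
    stop("TSS and enhancer on different chromosomes")
  m <- contacts$cis[[gene$chrom]]
  if (is.null(m)) stop("no cis matrix for ", gene$chrom)
  bs <- contacts$bin_size
  bi <- bin_of(gene$tss, bs)
  bj <- bin_of(floor((enhancer$start + enhancer$end) / 2), bs)
  if (bi > nrow(m) || bj > nrow(m)) return(0)
  # unique-pair cis total of a symmetric matrix, without masking overhead
  chrom_total <- (sum(m) + sum(diag(m))) / 2
  if (chrom_total == 0) return(0)
  m[bi, bj] / (chrom_total / 1e6)
}

#' Promoter activity (P) score
#'
#' Calibrated mean per-bp promoter-mark signal over the TSS +/-
#' `halfwidth` window (clipped at chromosome ends), scaled by the sample
#' factor. `mode = "sum"` integrates instead of averaging.
#'
#' @param gene one-row gene slice.
#' @param k4_track promoter-mark [signal_track()].
#' @param factor calibration factor; @param halfwidth bp (default 2500).
#' @param genome optional [genome_model()] for end clipping.
#' @param mode `"mean"` (default) or `"sum"`.
#' @return Numeric P score.
#' @export
promoter_p <- function(gene, k4_track, factor = 1, halfwidth = 2500L,
                       genome = NULL, mode = c("mean", "sum")) {
  mode <- match.arg(mode)
  v <- k4_track$values[[gene$chrom]]
  chrom_len <- length(v) * k4_track$bin_size
  if (!is.null(genome)) chrom_len <- genome$chrom_lengths[[gene$chrom]]
  s <- max(0, gene$tss - halfwidth)
  e <- min(chrom_len, gene$tss + halfwidth)
  tot <- .track_sum(k4_track, gene$chrom, s, e)
  if (mode == "mean") tot <- tot / (e - s)
  tot * factor
}

#' ABC record for one gene
#'
#' Resolves candidate enhancers, computes per-enhancer A and C scores and
#' their products, the summed ABC score, the promoter P score and
#' `abc_p2 = abc * p^2`.
#'
#' @param gene one-row gene slice.
#' @param enhancers enhancer [peak_set()].
#' @param k27ac_track,k4_track activity and promoter mark
#'   [signal_track()]s.
#' @param contacts a [contact_map()] at the scoring resolution.
#' @param factor calibration factor applied to both A and P.
#' @param window candidate window half-width (default 1 Mb).
#' @param a_mode,p_mode aggregation for A (default sum) and P (default
#'   mean).
#' @param genome optional [genome_model()].
#' @return List of class `abc_record`: gene_id, enhancers (data.frame with
#'   A, C, product), abc, p_score, abc_p2.
#' @export
abc_record <- function(gene, enhancers, k27ac_track, k4_track, contacts,
                       factor = 1, window = 1e6, a_mode = "sum",
                       p_mode = "mean", genome = NULL) {
  cand <- candidate_enhancers(gene, enhancers, window)
  if (nrow(cand)) {
    A <- vapply(seq_len(nrow(cand)), function(i)
      activity_A(cand[i, ], k27ac_track, factor, a_mode), 0)
    C <- vapply(seq_len(nrow(cand)), function(i)
      contact_C(gene, cand[i, ], contacts), 0)
  } else {
    A <- C <- numeric()
  }
  enh <- cbind(as.data.frame(cand), A = A, C = C, product = A * C)
  p <- promoter_p(gene, k4_track, factor, genome = genome, mode = p_mode)
  abc <- sum(A * C)
  structure(list(gene_id = gene$gene_id, enhancers = enh, abc = abc,
                 p_score = p, abc_p2 = abc * p^2),
            class = "abc_record")
}

#' @export
print.abc_record <- function(x, ...) {
  cat("<abc_record> ", x$gene_id, ": ", nrow(x$enhancers),
      " enhancer(s), ABC ", signif(x$abc, 4), ", P ", signif(x$p_score, 4),
      ", ABC-P2 ", signif(x$abc_p2, 4), "\n", sep = "")
  invisible(x)
}

#' ABC and ABC-P^2 scores for a gene table
#'
#' @param genes a [gene_annotation()].
#' @inheritParams abc_record
#' @return data.frame (gene_id, abc, p_score, abc_p2, n_enhancers), plus
#'   the per-gene records as attribute `"records"`.
#' @export
abc_table <- function(genes, enhancers, k27ac_track, k4_track, contacts,
                      factor = 1, window = 1e6, a_mode = "sum",
                      p_mode = "mean", genome = NULL) {
  recs <- lapply(seq_len(nrow(genes)), function(i)
    abc_record(genes[i, ], enhancers, k27ac_track, k4_track, contacts,
               factor, window, a_mode, p_mode, genome))
  out <- data.frame(
    gene_id = genes$gene_id,
    abc = vapply(recs, `[[`, 0, "abc"),
    p_score = vapply(recs, `[[`, 0, "p_score"),
    abc_p2 = vapply(recs, `[[`, 0, "abc_p2"),
    n_enhancers = vapply(recs, function(r) nrow(r$enhancers), 0L),
    stringsAsFactors = FALSE)
  attr(out, "records") <- recs
  out
}

#' Correlate ABC-type score changes with expression changes
#'
#' For genes shared between the two per-condition score tables, the score
#' change (`difference`, or `log2_ratio` with pseudocount 1) is Pearson
#' correlated against the expression log2 fold change.
#'
#' @param tbl1,tbl2 [abc_table()] outputs per condition.
#' @param expr_lfc named per-gene expression log2 fold changes.
#' @param score column to compare (`"abc_p2"` default, or `"abc"`).
#' @param mode `"difference"` or `"log2_ratio"`.
#' @return List (r, pvalue, n).
#' @export
abc_expression_correlation <- function(tbl1, tbl2, expr_lfc,
                                       score = c("abc_p2", "abc"),
                                       mode = c("difference",
                                                "log2_ratio")) {
  score <- match.arg(score); mode <- match.arg(mode)
  genes <- Reduce(intersect, list(tbl1$gene_id, tbl2$gene_id,
                                  names(expr_lfc)))
  if (length(genes) < 3) stop("need >= 3 shared genes")
  s1 <- setNames(tbl1[[score]], tbl1$gene_id)[genes]
  s2 <- setNames(tbl2[[score]], tbl2$gene_id)[genes]
  d <- if (mode == "difference") s2 - s1 else log2((s2 + 1) / (s1 + 1))
  y <- expr_lfc[genes]
  if (stats::sd(d) == 0 || stats::sd(y) == 0)
    stop("degenerate input: score or expression changes are constant")
  ct <- cor.test(d, y, method = "pearson")
  list(r = unname(ct$estimate), pvalue = ct$p.value, n = length(genes))
}
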