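# Peak dynamics, region annotation, promoter state typing (incl. bivalent
# promoters), enhancer definition and modification-expression correlation.

#' @importFrom IRanges IRanges findOverlaps
#' @importFrom S4Vectors queryHits subjectHits
NULL

# Which intervals in `a` overlap any interval in `b` by >= min_overlap bp?
# Both are data.frames with chrom/start/end in 0-based half-open coords.
.overlaps_any <- function(a, b, min_overlap = 1L) {
  hit <- logical(nrow(a))
  if (!nrow(a) || !nrow(b)) return(hit)
  for (ch in unique(a$chrom)) {
    ia <- which(a$chrom == ch)
    ib <- which(b$chrom == ch)
    if (!length(ib)) next
    qa <- IRanges(start = a$start[ia] + 1L, end = a$end[ia])
    qb <- IRanges(start = b$start[ib] + 1L, end = b$end[ib])
    ov <- findOverlaps(qa, qb, minoverlap = min_overlap)
    hit[ia[unique(queryHits(ov))]] <- TRUE
  }
  hit
}

# Promoter windows [tss - hw, tss + hw) clipped at zero (and at chromosome
# ends when a genome is supplied).
.promoter_windows <- function(genes, halfwidth, genome = NULL) {
  s <- pmax(0, genes$tss - halfwidth)
  e <- genes$tss + halfwidth
  if (!is.null(genome))
    e <- pmin(e, genome$chrom_lengths[genes$chrom])
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom, start = s,
             end = e, stringsAsFactors = FALSE)
}

#' Classify peak dynamics between two conditions
#'
#' A condition-1 peak overlapping at least `min_overlap_bp` of any
#' condition-2 peak is conserved, otherwise lost; condition-2 peaks with
#' no condition-1 overlap are gained. The three categories partition the
#' union of the inputs and swapping the conditions swaps lost and gained.
#'
#' @param peaks1,peaks2 [peak_set()]s for conditions 1 and 2.
#' @param min_overlap_bp minimum overlap (default 1).
#' @return List of class `peak_dynamics`: `conserved`, `lost`, `gained`
#'   peak sets and a `counts` vector.
#' @export
classify_peak_dynamics <- function(peaks1, peaks2, min_overlap_bp = 1L) {
  ov1 <- .overlaps_any(peaks1, peaks2, min_overlap_bp)
  ov2 <- .overlaps_any(peaks2, peaks1, min_overlap_bp)
  out <- list(conserved = peaks1[ov1, , drop = FALSE],
              lost = peaks1[!ov1, , drop = FALSE],
              gained = peaks2[!ov2, , drop = FALSE])
  out$counts <- c(conserved = sum(ov1), lost = sum(!ov1), gained = sum(!ov2))
  class(out) <- "peak_dynamics"
  out
}

#' @export
print.peak_dynamics <- function(x, ...) {
  cat("<peak_dynamics> conserved ", x$counts[["conserved"]], ", lost ",
      x$counts[["lost"]], ", gained ", x$counts[["gained"]], "\n", sep = "")
  invisible(x)
}

#' Annotate peaks by genomic region
#'
#' Each peak is assigned one category by its midpoint with the precedence
#' promoter > exon > intron > distal: promoter if the midpoint falls in a
#' TSS +/- `promoter_halfwidth` window, exon if inside an exon, intron if
#' inside a gene body without being exonic, otherwise distal.
#'
#' @param peaks a [peak_set()].
#' @param genes a [gene_annotation()].
#' @param gene_bodies optional data.frame (chrom, start, end) of gene
#'   extents; @param exons optional data.frame (chrom, start, end).
#' @param promoter_halfwidth half-width of the promoter window in bp.
#' @return List `category` (per-peak factor) and `counts`.
#' @export
annotate_regions <- function(peaks, genes, gene_bodies = NULL, exons = NULL,
                             promoter_halfwidth = 2500L) {
  mid <- floor((peaks$start + peaks$end) / 2)
  pts <- data.frame(chrom = peaks$chrom, start = mid, end = mid + 1)
  prom <- .promoter_windows(genes, promoter_halfwidth)
  in_prom <- .overlaps_any(pts, prom)
  in_exon <- if (!is.null(exons)) .overlaps_any(pts, exons) else
    logical(nrow(peaks))
  in_body <- if (!is.null(gene_bodies)) .overlaps_any(pts, gene_bodies) else
    logical(nrow(peaks))
  category <- ifelse(in_prom, "promoter",
              ifelse(in_exon, "exon",
              ifelse(in_body, "intron", "distal")))
  category <- factor(category, levels = c("promoter", "exon", "intron",
                                          "distal"))
  list(category = category, counts = table(category))
}

#' Promoter state typing from two promoter marks
#'
#' A promoter window (TSS +/- `promoter_halfwidth`) is typed by the 2x2
#' overlap truth table of the active (K4-type) and repressive (K27-type)
#' peak sets: both marks present means bivalent.
#'
#' @param k4,k27 [peak_set()]s of the active and repressive promoter mark.
#' @param genes a [gene_annotation()].
#' @param promoter_halfwidth bp (default 2500).
#' @return data.frame (gene_id, state) with state in
#'   none/K4_only/K27_only/bivalent.
#' @export
promoter_state <- function(k4, k27, genes, promoter_halfwidth = 2500L) {
  prom <- .promoter_windows(genes, promoter_halfwidth)
  has_k4 <- .overlaps_any(prom, k4)
  has_k27 <- .overlaps_any(prom, k27)
  state <- ifelse(has_k4 & has_k27, "bivalent",
           ifelse(has_k4, "K4_only",
           ifelse(has_k27, "K27_only", "none")))
  data.frame(gene_id = genes$gene_id, state = state, stringsAsFactors = FALSE)
}

#' Cross-tabulate expression direction against promoter-mark loss at
#' bivalent promoters
#'
#' Restricted to genes bivalent in condition 1 and significantly changed
#' in expression; columns record whether the promoter lost its repressive
#' mark (`lost_K27`), lost its active mark (`lost_K4`) or kept both
#' (`stable`) in condition 2. A promoter losing both marks counts under
#' `lost_K27`.
#'
#' @param states1,states2 [promoter_state()] outputs per condition.
#' @param diff a [apply_significance()] `results` data.frame (feature_id,
#'   log2fc, significant).
#' @return Integer matrix rows (up, down) x columns (lost_K27, lost_K4,
#'   stable).
#' @export
bivalent_transition_table <- function(states1, states2, diff) {
  tab <- matrix(0L, 2, 3, dimnames = list(c("up", "down"),
                                          c("lost_K27", "lost_K4", "stable")))
  sig <- diff[diff$significant, , drop = FALSE]
  if (!nrow(sig)) return(tab)
  biv <- states1$gene_id[states1$state == "bivalent"]
  genes <- intersect(biv, sig$feature_id)
  if (!length(genes)) return(tab)
  s2 <- setNames(states2$state, states2$gene_id)[genes]
  lfc <- setNames(sig$log2fc, sig$feature_id)[genes]
  has_k4 <- s2 %in% c("K4_only", "bivalent")
  has_k27 <- s2 %in% c("K27_only", "bivalent")
  col <- ifelse(!has_k27, "lost_K27", ifelse(!has_k4, "lost_K4", "stable"))
  row <- ifelse(lfc > 0, "up", "down")
  for (k in seq_along(genes)) tab[row[k], col[k]] <- tab[row[k], col[k]] + 1L
  tab
}

#' Mean promoter signal per gene
#'
#' Length-weighted mean of per-bp signal over the TSS +/- `halfwidth`
#' window, clipped at chromosome ends.
#'
#' @param track a [signal_track()].
#' @param genes a [gene_annotation()].
#' @param halfwidth bp (default 2500).
#' @param genome optional [genome_model()] for end clipping.
#' @return Named numeric vector (gene_id -> mean signal).
#' @export
promoter_signal <- function(track, genes, halfwidth = 2500L, genome = NULL) {
  bs <- track$bin_size
  out <- vapply(seq_len(nrow(genes)), function(i) {
    v <- track$values[[genes$chrom[i]]]
    if (is.null(v)) return(NA_real_)
    chrom_len <- length(v) * bs
    if (!is.null(genome)) chrom_len <- genome$chrom_lengths[[genes$chrom[i]]]
    s <- max(0, genes$tss[i] - halfwidth)
    e <- min(chrom_len, genes$tss[i] + halfwidth)
    b0 <- bin_of(s, bs); b1 <- min(bin_of(e - 1, bs), length(v))
    w <- vapply(b0:b1, function(b)
      min(e, b * bs) - max(s, (b - 1) * bs), 0)
    sum(v[b0:b1] * w) / sum(w)
  }, 0)
  setNames(out, genes$gene_id)
}

#' Pearson correlation between promoter-mark and expression fold changes
#'
#' @param signal_lfc,expr_lfc named numeric vectors of per-gene log2 fold
#'   changes; intersected by name.
#' @param restrict optional gene ids (e.g. significantly changed genes) to
#'   restrict the comparison to.
#' @return List (r, pvalue, n).
#' @export
modification_expression_correlation <- function(signal_lfc, expr_lfc,
                                                restrict = NULL) {
  genes <- intersect(names(signal_lfc), names(expr_lfc))
  if (!is.null(restrict)) genes <- intersect(genes, restrict)
  x <- signal_lfc[genes]; y <- expr_lfc[genes]
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need >= 3 genes after intersection")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), pvalue = ct$p.value, n = length(x))
}

#' Define active enhancers as non-promoter activity-mark peaks
#'
#' Peaks of the enhancer mark (H3K27ac-type) overlapping any promoter
#' window by >= 1 bp are removed; the remainder, with their signal, form
#' the active enhancer set.
#'
#' @param k27ac a [peak_set()] of the activity mark.
#' @param genes a [gene_annotation()].
#' @param promoter_halfwidth bp (default 2500).
#' @return A [peak_set()] of enhancers.
#' @export
define_enhancers <- function(k27ac, genes, promoter_halfwidth = 2500L) {
  prom <- .promoter_windows(genes, promoter_halfwidth)
  keep <- !.overlaps_any(k27ac, prom)
  out <- k27ac[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enhancer dynamics between two conditions
#'
#' Overlap-based, with the same rule as [classify_peak_dynamics()]:
#' shared (condition-1 enhancer overlapping condition 2), silenced
#' (condition-1 only) and activated (condition-2 only).
#'
#' @param enh1,enh2 enhancer [peak_set()]s.
#' @return Named counts (shared, silenced, activated) with the
#'   underlying peak sets as attribute `"sets"`.
#' @export
enhancer_dynamics <- function(enh1, enh2) {
  dyn <- classify_peak_dynamics(enh1, enh2)
  counts <- c(shared = unname(dyn$counts["conserved"]),
              silenced = unname(dyn$counts["lost"]),
              activated = unname(dyn$counts["gained"]))
  attr(counts, "sets") <- list(shared = dyn$conserved, silenced = dyn$lost,
                               activated = dyn$gained)
  counts
}

#' Mean signal profile around aligned regions
#'
#' For point regions (or interval midpoints) the per-offset mean track
#' value across regions is returned for offsets -`flank_bins` ..
#' +`flank_bins` (in track bins); offsets falling outside a chromosome are
#' ignored for that region.
#'
#' @param track a [signal_track()].
#' @param regions data.frame with `chrom` and either `pos` or
#'   `start`/`end` (midpoint used).
#' @param flank_bins profile half-width in bins.
#' @return Numeric vector of length `2 * flank_bins + 1` named by offset.
#' @export
signal_at_regions <- function(track, regions, flank_bins = 10L) {
  pos <- if (!is.null(regions$pos)) regions$pos else
    floor((regions$start + regions$end) / 2)
  offs <- -flank_bins:flank_bins
  acc <- numeric(length(offs)); nn <- numeric(length(offs))
  for (i in seq_len(nrow(regions))) {
    v <- track$values[[regions$chrom[i]]]
    if (is.null(v)) next
    b <- bin_of(pos[i], track$bin_size)
    idx <- b + offs
    ok <- idx >= 1 & idx <= length(v)
    acc[ok] <- acc[ok] + v[idx[ok]]
    nn[ok] <- nn[ok] + 1
  }
  setNames(ifelse(nn > 0, acc / nn, NA_real_), offs)
}
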