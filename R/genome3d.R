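# Contact-map analytics: distance decay P(s) curves, O/E matrices,
# compartment eigenvectors with a seven-way change classifier, saddle
# plots, chromosome-level interaction fold changes, top trans region
# pairs, and insulation/boundary analysis.

#' Expected contact count per diagonal offset
#'
#' @param m symmetric cis matrix.
#' @return Numeric vector of length `nrow(m)`: mean entry at offsets
#'   0 .. n-1.
#' @export
expected_by_distance <- function(m) {
  n <- nrow(m)
  vapply(0:(n - 1), function(d) {
    i <- seq_len(n - d)
    mean(m[cbind(i, i + d)], na.rm = TRUE)
  }, 0)
}

#' Observed/expected matrix
#'
#' Each entry is divided by the expected value at its diagonal offset;
#' offsets with expected 0 are masked (NA). NA observations propagate.
#'
#' @param m symmetric cis matrix.
#' @param expected optional precomputed [expected_by_distance()] vector.
#' @return O/E matrix of the same dimension.
#' @export
oe_matrix <- function(m, expected = expected_by_distance(m)) {
  n <- nrow(m)
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  e <- expected[d + 1L]
  e[e == 0] <- NA_real_
  m / matrix(e, n, n)
}

#' Compartment eigenvector (PC1) of one chromosome
#'
#' The O/E matrix is smoothed row-wise with a centered running-mean
#' window spanning `window_bp` (rounded up to an odd number of bins so
#' the window is symmetric and introduces no phase shift), the Pearson
#' correlation matrix of the
#' smoothed columns is formed over unmasked bins, and its leading
#' eigenvector is the compartment score. The sign is anchored so that the
#' track correlates positively with GC content (compartment A is GC-rich);
#' positive values are called A, negative B. Bins whose O/E row is
#' entirely missing or has zero variance are masked.
#'
#' @param oe an [oe_matrix()].
#' @param gc per-bin GC fractions for the chromosome.
#' @param bin_size bin width in bp (default 25 kb).
#' @param window_bp smoothing window in bp (default 100 kb).
#' @param min_ev_share minimum share of total correlation-matrix variance
#'   the leading eigenvector must explain; below it the chromosome is
#'   declared to carry no compartment signal.
#' @return Object of class `compartment_track`: `pc1` (full-length vector,
#'   NA at masked bins), `mask` (logical, TRUE = masked), `ev_share`.
#' @export
compartment_pc1 <- function(oe, gc, bin_size = 25000L, window_bp = 1e5,
                            min_ev_share = 0.1) {
  n <- nrow(oe)
  if (length(gc) != n) stop("gc length does not match bin count")
  w <- max(1L, round(window_bp / bin_size))
  if (w %% 2L == 0L) w <- w + 1L
  sm <- t(apply(oe, 1, function(r) {
    out <- stats::filter(r, rep(1 / w, w), sides = 2)
    out[is.na(out)] <- r[is.na(out)]
    as.numeric(out)
  }))
  mask <- apply(sm, 1, function(r) all(is.na(r)) ||
                  stats::sd(r, na.rm = TRUE) == 0)
  mask[is.na(mask)] <- TRUE
  keep <- which(!mask)
  if (length(keep) < 50) stop("fewer than 50 unmasked bins")
  cm <- suppressWarnings(cor(sm[keep, keep], use = "pairwise.complete.obs"))
  if (any(!is.finite(cm))) cm[!is.finite(cm)] <- 0
  eg <- eigen(cm, symmetric = TRUE)
  share <- eg$values[1] / sum(abs(eg$values))
  if (!is.finite(share) || share < min_ev_share)
    stop("no compartment signal")
  v <- eg$vectors[, 1]
  if (cor(v, gc[keep]) < 0) v <- -v
  pc1 <- rep(NA_real_, n)
  pc1[keep] <- v
  structure(list(pc1 = pc1, mask = mask, ev_share = share),
            class = "compartment_track")
}

#' @export
print.compartment_track <- function(x, ...) {
  cat("<compartment_track> ", length(x$pc1), " bins (", sum(x$mask),
      " masked), leading eigenvalue share ", signif(x$ev_share, 3),
      "\n", sep = "")
  invisible(x)
}

#' Seven-way compartment change classification
#'
#' Bins are classified by the first matching rule, in this order
#' (`c1`/`c2` are the condition PC1 values, `t` the strength threshold):
#' A_to_strongerA (c2-c1 > t and c1 > t), B_to_A (c2 > 0 and c1 < 0),
#' B_to_weakerB (c2-c1 > t and c2 < -t), B_to_strongerB (c2-c1 < -t and
#' c1 < -t), A_to_B (c2 < 0 and c1 > 0), A_to_weakerA (c2-c1 < -t and
#' c1 > t), else stable. The rule order resolves bins matching several
#' definitions.
#'
#' @param pc1_c1,pc1_c2 PC1 vectors sharing binning and mask (NA = masked).
#' @param t threshold (default 0.2).
#' @return List of class `compartment_change`: `category` (factor, NA at
#'   masked bins) and `fractions` (per-category fraction of unmasked bins,
#'   summing to 1).
#' @export
classify_compartment_change <- function(pc1_c1, pc1_c2, t = 0.2) {
  if (length(pc1_c1) != length(pc1_c2)) stop("mismatched track lengths")
  lev <- c("A_to_strongerA", "B_to_A", "B_to_weakerB", "B_to_strongerB",
           "A_to_B", "A_to_weakerA", "stable")
  cat_of <- function(c1, c2) {
    if (is.na(c1) || is.na(c2)) return(NA_character_)
    d <- c2 - c1
    if (d > t && c1 > t) "A_to_strongerA"
    else if (c2 > 0 && c1 < 0) "B_to_A"
    else if (d > t && c2 < -t) "B_to_weakerB"
    else if (d < -t && c1 < -t) "B_to_strongerB"
    else if (c2 < 0 && c1 > 0) "A_to_B"
    else if (d < -t && c1 > t) "A_to_weakerA"
    else "stable"
  }
  category <- factor(mapply(cat_of, pc1_c1, pc1_c2), levels = lev)
  ok <- !is.na(category)
  fr <- if (any(ok)) table(category[ok]) / sum(ok) else table(category[ok])
  structure(list(category = category, fractions = fr),
            class = "compartment_change")
}

#' @export
print.compartment_change <- function(x, ...) {
  cat("<compartment_change> fractions over unmasked bins:\n")
  print(round(x$fractions, 4))
  invisible(x)
}

#' Saddle aggregation of O/E contacts by compartment score
#'
#' Bins are ranked by PC1 genome-wide, the extreme `trim` fraction of the
#' eigenvector is removed at each tail, the remaining ranks are split into
#' `n_bins` equal groups (group 1 = strongest B, group `n_bins` =
#' strongest A), and each saddle cell is the mean cis O/E over the group
#' pair. Corner summaries average the extreme `corner` x `corner` blocks.
#'
#' @param oe_list O/E matrix or named list of per-chromosome O/E matrices.
#' @param pc1_list PC1 vector or matching list.
#' @param n_bins saddle resolution (default 50).
#' @param trim tail fraction removed (default 0.025 per tail).
#' @param corner corner block size (default 5).
#' @return Object of class `saddle_matrix`: `matrix` (n_bins x n_bins),
#'   `corners` (AA, BB, AB means), `strength` (AA*BB/AB^2).
#' @export
saddle <- function(oe_list, pc1_list, n_bins = 50L, trim = 0.025,
                   corner = 5L) {
  if (is.matrix(oe_list)) oe_list <- list(chr = oe_list)
  if (!is.list(pc1_list)) pc1_list <- list(chr = pc1_list)
  pc1 <- unlist(pc1_list, use.names = FALSE)
  offs <- c(0, cumsum(vapply(pc1_list, length, 0L)))[seq_along(pc1_list)]
  names(offs) <- names(pc1_list)
  ok <- which(!is.na(pc1))
  lo <- stats::quantile(pc1[ok], trim)
  hi <- stats::quantile(pc1[ok], 1 - trim)
  use <- ok[pc1[ok] >= lo & pc1[ok] <= hi]
  if (length(use) < n_bins)
    stop("fewer usable bins than saddle bins; reduce n_bins")
  rk <- rank(pc1[use], ties.method = "first")
  grp <- ceiling(rk * n_bins / length(use))
  group_of <- rep(NA_integer_, length(pc1))
  group_of[use] <- grp
  acc <- matrix(0, n_bins, n_bins)
  cnt <- matrix(0, n_bins, n_bins)
  for (ch in names(oe_list)) {
    g <- group_of[offs[[ch]] + seq_len(length(pc1_list[[ch]]))]
    keep <- which(!is.na(g))
    if (length(keep) < 2) next
    sub <- oe_list[[ch]][keep, keep, drop = FALSE]
    gk <- g[keep]
    for (a in sort(unique(gk))) {
      ia <- which(gk == a)
      for (b in sort(unique(gk))) {
        ib <- which(gk == b)
        v <- sub[ia, ib, drop = FALSE]
        fin <- is.finite(v)
        acc[a, b] <- acc[a, b] + sum(v[fin])
        cnt[a, b] <- cnt[a, b] + sum(fin)
      }
    }
  }
  sm <- ifelse(cnt > 0, acc / cnt, NA_real_)
  ix_b <- seq_len(corner); ix_a <- n_bins - corner + seq_len(corner)
  corners <- c(AA = mean(sm[ix_a, ix_a], na.rm = TRUE),
               BB = mean(sm[ix_b, ix_b], na.rm = TRUE),
               AB = mean(c(sm[ix_a, ix_b], sm[ix_b, ix_a]), na.rm = TRUE))
  structure(list(matrix = sm, corners = corners,
                 strength = corners[["AA"]] * corners[["BB"]] /
                   corners[["AB"]]^2),
            class = "saddle_matrix")
}

#' @export
print.saddle_matrix <- function(x, ...) {
  cat("<saddle_matrix> ", nrow(x$matrix), "x", ncol(x$matrix),
      "; corners AA ", signif(x$corners[["AA"]], 4), ", BB ",
      signif(x$corners[["BB"]], 4), ", AB ", signif(x$corners[["AB"]], 4),
      "; strength ", signif(x$strength, 4), "\n", sep = "")
  invisible(x)
}

#' Contact frequency versus genomic distance P(s)
#'
#' For each log-spaced distance bin the frequency is the summed cis count
#' at those offsets divided by the number of bin pairs at those offsets
#' and by the map's total cis count, making curves comparable across
#' sequencing depths.
#'
#' @param contacts a [contact_map()].
#' @param n_log_bins number of log-spaced distance bins (default 30).
#' @return data.frame of class `ps_curve`: s_lo, s_hi, s_mid (geometric
#'   midpoint, bp), freq.
#' @export
ps_curve <- function(contacts, n_log_bins = 30L) {
  bs <- contacts$bin_size
  max_off <- max(vapply(contacts$cis, nrow, 0L)) - 1L
  if (max_off < 1) stop("cis matrices too small")
  edges <- unique(round(exp(seq(log(bs), log((max_off + 1) * bs),
                                length.out = n_log_bins + 1L))))
  total_cis <- 0
  n_bins_edges <- length(edges) - 1L
  cnt <- numeric(n_bins_edges)
  npair <- numeric(n_bins_edges)
  for (m in contacts$cis) {
    n <- nrow(m)
    total_cis <- total_cis + sum(m[upper.tri(m, diag = TRUE)])
    for (d in seq_len(n - 1L)) {
      s <- d * bs
      b <- findInterval(s, edges, rightmost.closed = TRUE)
      if (b < 1 || b > n_bins_edges) next
      i <- seq_len(n - d)
      cnt[b] <- cnt[b] + sum(m[cbind(i, i + d)])
      npair[b] <- npair[b] + (n - d)
    }
  }
  freq <- ifelse(npair > 0, cnt / npair / total_cis, NA_real_)
  out <- data.frame(s_lo = edges[-length(edges)], s_hi = edges[-1],
                    s_mid = sqrt(edges[-length(edges)] * edges[-1]),
                    freq = freq)
  class(out) <- c("ps_curve", "data.frame")
  out
}

#' Log-log slope of a P(s) curve
#'
#' @param curve a [ps_curve()]; @param s_range optional c(min, max) bp
#'   window to fit within.
#' @return Slope of the regression of log10(freq) on log10(s).
#' @export
ps_slope <- function(curve, s_range = NULL) {
  use <- is.finite(curve$freq) & curve$freq > 0
  if (!is.null(s_range))
    use <- use & curve$s_mid >= s_range[1] & curve$s_mid <= s_range[2]
  unname(stats::coef(stats::lm(log10(curve$freq[use]) ~
                          log10(curve$s_mid[use])))[2])
}

#' Log2 ratio of two P(s) curves and their crossing points
#'
#' Ratios are defined where both curves are positive. Crossing points are
#' distances where the log2 ratio changes sign, linearly interpolated in
#' log10(s) between adjacent bin midpoints.
#'
#' @param curve1,curve2 [ps_curve()]s sharing bin edges.
#' @return List: `table` (s_mid, log2fc) and `crossings` (bp).
#' @export
ps_log2fc <- function(curve1, curve2) {
  if (!isTRUE(all.equal(curve1$s_lo, curve2$s_lo)))
    stop("curves must share bin edges")
  both <- is.finite(curve1$freq) & is.finite(curve2$freq) &
    curve1$freq > 0 & curve2$freq > 0
  if (!any(both)) stop("curves have disjoint supports")
  lfc <- rep(NA_real_, nrow(curve1))
  lfc[both] <- log2(curve2$freq[both] / curve1$freq[both])
  idx <- which(both)
  crossings <- numeric()
  if (length(idx) > 1) {
    for (k in seq_len(length(idx) - 1L)) {
      i <- idx[k]; j <- idx[k + 1L]
      y1 <- lfc[i]; y2 <- lfc[j]
      if (y1 == 0) next
      if (sign(y1) != sign(y2) && y2 != 0) {
        x1 <- log10(curve1$s_mid[i]); x2 <- log10(curve1$s_mid[j])
        crossings <- c(crossings, 10^(x1 - y1 * (x2 - x1) / (y2 - y1)))
      }
    }
  }
  list(table = data.frame(s_mid = curve1$s_mid, log2fc = lfc),
       crossings = crossings)
}

#' Chromosome-level interaction fold changes
#'
#' Each chromosome's cis count (and each chromosome pair's trans count) is
#' divided by its map's total contacts; the log2 ratio of these fractions
#' between conditions is returned. Classes with zero counts in either map
#' are masked (NA).
#'
#' @param map1,map2 [contact_map()]s on the same genome and binning.
#' @return List `cis` (named per-chromosome log2FC vector) and `trans`
#'   (data.frame chromA, chromB, log2fc).
#' @export
interaction_fold_changes <- function(map1, map2) {
  if (!identical(names(map1$cis), names(map2$cis)))
    stop("maps must share chromosomes")
  f <- function(map) {
    cis <- vapply(map$cis, function(m) sum(m[upper.tri(m, diag = TRUE)]), 0)
    tr <- vapply(map$trans, sum, 0)
    list(cis = cis / map$total_contacts, trans = tr / map$total_contacts)
  }
  a <- f(map1); b <- f(map2)
  cis_fc <- ifelse(a$cis > 0 & b$cis > 0, log2(b$cis / a$cis), NA_real_)
  keys <- union(names(a$trans), names(b$trans))
  tr <- NULL
  if (length(keys)) {
    chs <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
    v1 <- a$trans[keys]; v2 <- b$trans[keys]
    v1[is.na(v1)] <- 0; v2[is.na(v2)] <- 0
    tr <- data.frame(chromA = chs[, 1], chromB = chs[, 2],
                     log2fc = ifelse(v1 > 0 & v2 > 0, log2(v2 / v1),
                                     NA_real_),
                     stringsAsFactors = FALSE)
  }
  list(cis = cis_fc, trans = tr)
}

#' Top changed trans-contact region pairs between two chromosomes
#'
#' The trans matrix pair is aggregated into coarse bins, per-coarse-pair
#' contact fractions are compared as log2 fold changes (pseudocount 1 on
#' counts), the top `fraction` of pairs by signed change (descending for
#' `"increased"`, ascending for `"decreased"`; ties broken by coordinate
#' order) are selected, and adjacent selected pairs (8-neighbourhood) are
#' merged into region pairs.
#'
#' @param map1,map2 [contact_map()]s; @param chromA,chromB chromosome pair
#'   (genome order).
#' @param fraction selected fraction of coarse pairs (default 0.005).
#' @param direction `"increased"` or `"decreased"`.
#' @param coarse_bp coarse bin width (default 2 Mb).
#' @return data.frame of merged region pairs (chromA, startA, endA,
#'   chromB, startB, endB, n_pairs, peak_log2fc), ordered by extremity.
#' @export
top_trans_regions <- function(map1, map2, chromA, chromB, fraction = 0.005,
                              direction = c("increased", "decreased"),
                              coarse_bp = 2e6) {
  direction <- match.arg(direction)
  key <- paste(chromA, chromB, sep = "|")
  t1 <- map1$trans[[key]]; t2 <- map2$trans[[key]]
  if (is.null(t1) || is.null(t2)) stop("no trans matrix for ", key)
  fac <- max(1L, round(coarse_bp / map1$bin_size))
  coarsen <- function(m) {
    ra <- (seq_len(nrow(m)) - 1L) %/% fac
    cb <- (seq_len(ncol(m)) - 1L) %/% fac
    out <- rowsum(m, ra)
    t(rowsum(t(out), cb))
  }
  c1 <- coarsen(t1); c2 <- coarsen(t2)
  f1 <- (c1 + 1) / map1$total_contacts
  f2 <- (c2 + 1) / map2$total_contacts
  fc <- log2(f2 / f1)
  n_sel <- max(1L, ceiling(fraction * length(fc)))
  ord <- order(if (direction == "increased") -fc else fc,
               row(fc), col(fc))
  sel <- ord[seq_len(n_sel)]
  sel_rc <- cbind(row = (sel - 1L) %% nrow(fc) + 1L,
                  col = (sel - 1L) %/% nrow(fc) + 1L)
  # merge 8-neighbour adjacent selections into components
  comp <- rep(0L, n_sel)
  nc <- 0L
  for (i in seq_len(n_sel)) {
    if (comp[i] == 0L) { nc <- nc + 1L; comp[i] <- nc }
    for (j in seq_len(n_sel)) {
      if (comp[j] != 0 && comp[j] == comp[i]) next
      if (abs(sel_rc[i, 1] - sel_rc[j, 1]) <= 1 &&
          abs(sel_rc[i, 2] - sel_rc[j, 2]) <= 1) {
        if (comp[j] == 0L) comp[j] <- comp[i]
        else comp[comp == comp[j]] <- comp[i]
      }
    }
  }
  res <- lapply(unique(comp), function(k) {
    rows <- sel_rc[comp == k, 1]; cols <- sel_rc[comp == k, 2]
    vals <- fc[cbind(rows, cols)]
    peak <- if (direction == "increased") max(vals) else min(vals)
    data.frame(chromA = chromA,
               startA = (min(rows) - 1) * coarse_bp,
               endA = max(rows) * coarse_bp,
               chromB = chromB,
               startB = (min(cols) - 1) * coarse_bp,
               endB = max(cols) * coarse_bp,
               n_pairs = sum(comp == k), peak_log2fc = peak,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out[order(if (direction == "increased") -out$peak_log2fc else
    out$peak_log2fc), , drop = FALSE]
}

#' Insulation score track of one chromosome
#'
#' For each bin with a complete diamond (the `window_bins` upstream x
#' `window_bins` downstream sub-matrix excluding the bin itself) the score
#' is log2 of the diamond mean over the chromosome-wide mean of all valid
#' diamond means. Bins too close to the ends carry NA.
#'
#' @param m symmetric cis matrix.
#' @param window_bins diamond half-width in bins (default 10).
#' @return Object of class `insulation_track`: `score` (per-bin vector)
#'   and `window_bins`.
#' @export
insulation <- function(m, window_bins = 10L) {
  n <- nrow(m)
  w <- window_bins
  if (2L * w + 1L > n) stop("window does not fit chromosome")
  dm <- rep(NA_real_, n)
  for (i in (w + 1L):(n - w))
    dm[i] <- mean(m[(i - w):(i - 1L), (i + 1L):(i + w)])
  ref <- mean(dm, na.rm = TRUE)
  score <- log2(dm / ref)
  structure(list(score = score, window_bins = w),
            class = "insulation_track")
}

#' Boundaries and domains from an insulation track
#'
#' Boundaries are local insulation minima with score below `-prominence`;
#' minima closer than `min_sep` bins are collapsed keeping the lowest.
#' Domains are the inter-boundary intervals (chromosome ends included).
#'
#' @param track an [insulation_track()].
#' @param prominence minimum depth below 0 (default 0.2).
#' @param min_sep minimum separation in bins (default 5).
#' @param bin_size bp per bin, for domain sizes (default 1).
#' @return List: `boundaries` (bin indices), `domains` (data.frame
#'   start_bin, end_bin, size_bp).
#' @export
boundaries_and_domains <- function(track, prominence = 0.2, min_sep = 5L,
                                   bin_size = 1L) {
  s <- track$score
  n <- length(s)
  cand <- integer()
  for (i in 2:(n - 1)) {
    if (is.na(s[i])) next
    left <- s[i - 1]; right <- s[i + 1]
    if ((is.na(left) || s[i] <= left) && (is.na(right) || s[i] <= right) &&
        s[i] < -prominence)
      cand <- c(cand, i)
  }
  if (length(cand) > 1) {
    cand <- cand[order(s[cand])]
    kept <- integer()
    for (b in cand)
      if (!length(kept) || all(abs(kept - b) >= min_sep))
        kept <- c(kept, b)
    cand <- sort(kept)
  }
  cuts <- c(0L, cand, n)
  domains <- data.frame(start_bin = head(cuts, -1) + 1L,
                        end_bin = tail(cuts, -1))
  domains$size_bp <- (domains$end_bin - domains$start_bin + 1L) * bin_size
  list(boundaries = cand, domains = domains)
}

#' Compare insulation at merged boundaries between two conditions
#'
#' The boundary union (boundaries within 1 bin of each other merged) is
#' scored in both tracks; the summary reports the mean difference and the
#' counts of boundaries strengthening (delta < 0) or weakening
#' (delta > 0) in condition 2.
#'
#' @param track1,track2 [insulation_track()]s of the same chromosome.
#' @param boundaries1,boundaries2 bin indices (see
#'   [boundaries_and_domains()]).
#' @return List: `table` (boundary, score1, score2, delta) and `summary`
#'   (mean_delta, n_stronger, n_weaker).
#' @export
compare_boundary_insulation <- function(track1, track2, boundaries1,
                                        boundaries2) {
  merged <- sort(unique(c(boundaries1, boundaries2)))
  if (!length(merged)) stop("empty boundary union")
  keep <- c(TRUE, diff(merged) > 1L)
  merged <- merged[keep]
  s1 <- track1$score[merged]; s2 <- track2$score[merged]
  delta <- s2 - s1
  list(table = data.frame(boundary = merged, score1 = s1, score2 = s2,
                          delta = delta),
       summary = c(mean_delta = mean(delta, na.rm = TRUE),
                   n_stronger = sum(delta < 0, na.rm = TRUE),
                   n_weaker = sum(delta > 0, na.rm = TRUE)))
}

#' Distribution of per-bin mark changes by compartment-change category
#'
#' @param changes a [classify_compartment_change()] result.
#' @param mark_lfc per-bin log2 mark fold changes aligned with the
#'   classified bins (NA where the mark has no coverage).
#' @return data.frame per category: n, median, q25, q75, n_excluded
#'   (bins lacking mark coverage).
#' @export
signal_change_by_category <- function(changes, mark_lfc) {
  if (length(mark_lfc) != length(changes$category))
    stop("mark_lfc length must match classified bins")
  do.call(rbind, lapply(levels(changes$category), function(lv) {
    idx <- which(changes$category == lv)
    v <- mark_lfc[idx]
    excl <- sum(is.na(v))
    v <- v[!is.na(v)]
    data.frame(category = lv, n = length(v),
               median = if (length(v)) median(v) else NA_real_,
               q25 = if (length(v)) unname(stats::quantile(v, 0.25))
                 else NA_real_,
               q75 = if (length(v)) unname(stats::quantile(v, 0.75))
                 else NA_real_,
               n_excluded = excl, stringsAsFactors = FALSE)
  }))
}
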