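# Metabolic pathway activity from expression: per-condition relative
# expression ratios aggregated to weighted pathway scores.

#' Per-gene relative expression across conditions
#'
#' For each gene the mean (library-size normalised) expression is computed
#' per condition; the relative expression in a condition is that mean
#' divided by the average of the per-condition means, so a gene expressed
#' identically everywhere has ratio 1 in every condition. Genes with zero
#' expression in all conditions are excluded and reported.
#'
#' @param expr genes x samples numeric matrix (normalised counts; see
#'   [normalize_library()]).
#' @param design named character vector mapping sample (column) names to
#'   conditions; at least two conditions with >= 1 sample each.
#' @return List of class `relative_expression`: `ratios` (genes x
#'   conditions matrix) and `excluded` (all-zero gene ids).
#' @export
relative_expression <- function(expr, design) {
  if (is.null(colnames(expr))) stop("expr must have sample column names")
  design <- design[colnames(expr)]
  if (anyNA(design)) stop("design missing for some samples")
  conds <- unique(design)
  if (length(conds) < 2) stop("need >= 2 conditions")
  for (cc in conds) if (!sum(design == cc)) stop("condition with zero samples")
  cond_means <- vapply(conds, function(cc)
    rowMeans(expr[, design == cc, drop = FALSE]), numeric(nrow(expr)))
  if (is.null(dim(cond_means)))
    cond_means <- matrix(cond_means, nrow = nrow(expr),
                         dimnames = list(rownames(expr), conds))
  grand <- rowMeans(cond_means)
  zero <- grand == 0
  ratios <- cond_means[!zero, , drop = FALSE] / grand[!zero]
  structure(list(ratios = ratios, conditions = conds,
                 excluded = rownames(expr)[zero]),
            class = "relative_expression")
}

#' Pathway activity scores as weighted means of relative expression
#'
#' The activity of a pathway in a condition is the weighted average of the
#' relative expression ratios of its measured genes. The default weight of
#' a gene is the reciprocal of the number of pathways containing it, so
#' promiscuous genes contribute less to each pathway; `uniform` weighting
#' is also available.
#'
#' @param rel a [relative_expression()] result.
#' @param db a `pathway_db` (see [read_gmt()]).
#' @param weighting `"reciprocal_membership"` (default) or `"uniform"`.
#' @return List of class `activity_table`: `scores` (pathway x condition
#'   matrix), `difference` (last condition minus first, for 2-condition
#'   designs), `n_genes_used`, `dropped` (pathways with no measured gene).
#' @export
pathway_activity <- function(rel, db,
                             weighting = c("reciprocal_membership",
                                           "uniform")) {
  weighting <- match.arg(weighting)
  memb <- pathway_membership(db)
  measured <- rownames(rel$ratios)
  scores <- matrix(NA_real_, length(db), ncol(rel$ratios),
                   dimnames = list(names(db), colnames(rel$ratios)))
  n_used <- setNames(integer(length(db)), names(db))
  for (p in names(db)) {
    genes <- intersect(db[[p]], measured)
    n_used[p] <- length(genes)
    if (!length(genes)) next
    w <- if (weighting == "uniform") rep(1, length(genes)) else
      1 / memb[genes]
    r <- rel$ratios[genes, , drop = FALSE]
    scores[p, ] <- colSums(r * w) / sum(w)
  }
  dropped <- names(db)[n_used == 0]
  scores <- scores[n_used > 0, , drop = FALSE]
  diff <- if (ncol(scores) == 2) scores[, 2] - scores[, 1] else NULL
  structure(list(scores = scores, difference = diff,
                 n_genes_used = n_used[n_used > 0], dropped = dropped,
                 weighting = weighting),
            class = "activity_table")
}

#' @export
print.activity_table <- function(x, ...) {
  cat("<activity_table> ", nrow(x$scores), " pathway(s) x ",
      ncol(x$scores), " condition(s), weighting '", x$weighting, "'",
      if (length(x$dropped)) paste0(", ", length(x$dropped), " dropped"),
      "\n", sep = "")
  invisible(x)
}

#' Retain pathways whose between-condition activity difference exceeds a
#' threshold
#'
#' Retention requires a strict inequality `|difference| > threshold`; a
#' pathway sitting exactly on the threshold is dropped.
#'
#' @param tbl an [pathway_activity()] result for exactly two conditions.
#' @param threshold minimum absolute activity difference (default 0.1).
#' @return The filtered `activity_table`.
#' @export
filter_divergent_pathways <- function(tbl, threshold = 0.1) {
  if (is.null(tbl$difference))
    stop("divergence filter requires exactly 2 conditions")
  keep <- abs(tbl$difference) > threshold
  structure(list(scores = tbl$scores[keep, , drop = FALSE],
                 difference = tbl$difference[keep],
                 n_genes_used = tbl$n_genes_used[keep],
                 dropped = tbl$dropped, weighting = tbl$weighting),
            class = "activity_table")
}
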