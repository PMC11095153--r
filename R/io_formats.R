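#' @importFrom data.table fread fwrite data.table setorder :=
#' @importFrom stats cor cor.test median rnorm rpois rnbinom runif setNames
#' @importFrom utils head tail
NULL

# ---------------------------------------------------------------------------
# Containers
#
# All interval arithmetic in this package is 0-based half-open (BED
# convention); the bin holding position p is floor(p / bin_size) + 1 in
# R's 1-based indexing.
# ---------------------------------------------------------------------------

#' Genome model: chromosome sizes, bin grid and optional GC track
#'
#' @param chrom_names character vector of ordered chromosome identifiers.
#' @param chrom_lengths integer vector of chromosome lengths in bp.
#' @param bin_size bin width in bp.
#' @param gc optional named list (per chromosome) of per-bin GC fractions in
#'   `[0, 1]`; lengths must match the bin count of each chromosome.
#' @return An object of class `genome_model` with fields `chrom_names`,
#'   `chrom_lengths`, `bin_size`, `n_bins` (per-chromosome bin counts) and
#'   `gc`.
#' @export
genome_model <- function(chrom_names, chrom_lengths, bin_size, gc = NULL) {
  if (length(chrom_names) != length(chrom_lengths))
    stop("chrom_names and chrom_lengths must have equal length")
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be > 0")
  if (bin_size <= 0) stop("bin_size must be > 0")
  if (any(bin_size > chrom_lengths))
    stop("bin_size exceeds a chromosome length")
  n_bins <- as.integer(ceiling(chrom_lengths / bin_size))
  names(n_bins) <- chrom_names
  if (!is.null(gc)) {
    if (!all(chrom_names %in% names(gc)))
      stop("gc must be a named list covering every chromosome")
    for (ch in chrom_names) {
      if (length(gc[[ch]]) != n_bins[[ch]])
        stop("gc vector length for ", ch, " does not match bin count")
      if (any(gc[[ch]] < 0 | gc[[ch]] > 1))
        stop("gc fractions must lie in [0, 1]")
    }
  }
  structure(
    list(chrom_names = as.character(chrom_names),
         chrom_lengths = setNames(as.numeric(chrom_lengths), chrom_names),
         bin_size = as.integer(bin_size),
         n_bins = n_bins,
         gc = gc),
    class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat("<genome_model> ", length(x$chrom_names), " chromosome(s), bin_size ",
      x$bin_size, " bp, ", sum(x$n_bins), " bins",
      if (!is.null(x$gc)) ", GC track attached", "\n", sep = "")
  invisible(x)
}

#' Construct a peak set
#'
#' @param chrom,start,end,signal parallel vectors; coordinates 0-based
#'   half-open, signal non-negative (defaults to 1).
#' @return A `data.frame` of class `peak_set`, sorted by (chrom, start).
#' @export
peak_set <- function(chrom = character(), start = integer(),
                     end = integer(), signal = NULL) {
  if (is.null(signal)) signal <- rep(1, length(chrom))
  if (length(start) && any(start < 0)) stop("negative coordinates")
  if (length(start) && any(start >= end)) stop("start must be < end")
  if (length(signal) && any(signal < 0)) stop("signal must be non-negative")
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), signal = as.numeric(signal),
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("peak_set", "data.frame")
  df
}

#' Construct a signal track (fixed-bin mean signal per chromosome)
#'
#' @param values named list of per-chromosome numeric vectors (mean signal
#'   per bin); all finite and non-negative.
#' @param bin_size bin width in bp.
#' @param sample sample label.
#' @export
signal_track <- function(values, bin_size, sample = "sample") {
  for (v in values) {
    if (any(!is.finite(v)) || any(v < 0))
      stop("signal values must be finite and >= 0")
  }
  structure(list(values = values, bin_size = as.integer(bin_size),
                 sample = sample),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat("<signal_track> sample ", x$sample, ", bin_size ", x$bin_size,
      " bp, ", length(x$values), " chromosome(s)\n", sep = "")
  invisible(x)
}

#' Construct a binned contact map
#'
#' @param cis named list of symmetric per-chromosome count matrices.
#' @param trans named list (names `"chrA|chrB"`, A before B in genome order)
#'   of rectangular count matrices; may be empty.
#' @param bin_size bin width in bp.
#' @return Object of class `contact_map` with `total_contacts` equal to the
#'   upper-triangle (incl. diagonal) cis sum plus the trans sum.
#' @export
contact_map <- function(cis, trans = list(), bin_size) {
  for (ch in names(cis)) {
    m <- cis[[ch]]
    if (!isSymmetric(unname(m))) stop("cis matrix for ", ch, " not symmetric")
    if (any(m < 0)) stop("negative counts in cis matrix ", ch)
  }
  for (p in names(trans)) if (any(trans[[p]] < 0))
    stop("negative counts in trans matrix ", p)
  structure(list(cis = cis, trans = trans, bin_size = as.integer(bin_size),
                 total_contacts = .total_contacts(cis, trans)),
            class = "contact_map")
}

.total_contacts <- function(cis, trans) {
  tot <- 0
  for (m in cis) tot <- tot + sum(m[upper.tri(m, diag = TRUE)])
  for (m in trans) tot <- tot + sum(m)
  tot
}

#' @export
print.contact_map <- function(x, ...) {
  cat("<contact_map> bin_size ", x$bin_size, " bp, ", length(x$cis),
      " cis matrix(es), ", length(x$trans), " trans matrix(es), ",
      format(x$total_contacts, big.mark = ","), " contacts\n", sep = "")
  invisible(x)
}

#' Construct a gene annotation table
#'
#' @param gene_id unique identifiers; `chrom`; `strand` in `{+,-}`;
#'   `tss` 0-based TSS position (for minus-strand genes the interval
#'   end minus one).
#' @export
gene_annotation <- function(gene_id, chrom, strand, tss) {
  if (anyDuplicated(gene_id)) stop("gene_id must be unique")
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(tss < 0)) stop("tss must be >= 0")
  df <- data.frame(gene_id = as.character(gene_id),
                   chrom = as.character(chrom),
                   strand = as.character(strand), tss = as.numeric(tss),
                   stringsAsFactors = FALSE)
  class(df) <- c("gene_annotation", "data.frame")
  df
}

# ---------------------------------------------------------------------------
# BED
# ---------------------------------------------------------------------------

#' Read a BED file (3-5 columns) into a peak set
#'
#' Coordinates are kept 0-based half-open. A missing score column defaults
#' to signal 1; the optional 4th column (name) is ignored for scoring.
#'
#' @param path file path.
#' @return A [peak_set()].
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(peak_set())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(parts)
  bad <- which(n < 3)
  if (length(bad)) stop("malformed BED line ", bad[1], ": fewer than 3 fields")
  chrom <- vapply(parts, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) {
    bad <- which(is.na(start) | is.na(end))[1]
    stop("malformed BED line ", bad, ": non-numeric coordinates")
  }
  if (any(start >= end)) {
    bad <- which(start >= end)[1]
    stop("malformed BED line ", bad, ": start >= end")
  }
  signal <- rep(1, length(lines))
  has5 <- n >= 5
  if (any(has5)) {
    sig <- suppressWarnings(as.numeric(
      vapply(parts[has5], `[[`, "", 5L)))
    if (anyNA(sig)) stop("malformed BED score column")
    signal[has5] <- sig
  }
  peak_set(chrom, start, end, signal)
}

#' Write a peak set as 5-column BED
#'
#' @param x a [peak_set()]; @param path output path.
#' @export
write_bed <- function(x, path) {
  lines <- sprintf("%s\t%s\t%s\tpeak_%d\t%s",
                   x$chrom, format(x$start, scientific = FALSE, trim = TRUE),
                   format(x$end, scientific = FALSE, trim = TRUE),
                   seq_len(nrow(x)),
                   format(x$signal, scientific = FALSE, trim = TRUE))
  writeLines(lines, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# bedGraph <-> signal track
# ---------------------------------------------------------------------------

#' Read a bedGraph file into a fixed-bin signal track
#'
#' Intervals not aligned to the bin grid contribute length-weighted means:
#' each bin's value is the coverage-weighted average of the interval values
#' overlapping it (uncovered bp count as 0).
#'
#' @param path bedGraph path (chrom, start, end, value; 0-based half-open).
#' @param genome a [genome_model()] defining the bin grid.
#' @param bin_size bin width in bp (defaults to the genome's).
#' @param sample sample label.
#' @export
read_bedgraph <- function(path, genome, bin_size = genome$bin_size,
                          sample = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- fread(path, header = FALSE, sep = "\t",
              col.names = c("chrom", "start", "end", "value"))
  values <- lapply(genome$chrom_names, function(ch) {
    nb <- as.integer(ceiling(genome$chrom_lengths[[ch]] / bin_size))
    acc <- numeric(nb)
    sub <- dt[dt$chrom == ch, ]
    if (nrow(sub)) {
      for (k in seq_len(nrow(sub))) {
        s <- sub$start[k]; e <- sub$end[k]; v <- sub$value[k]
        b0 <- floor(s / bin_size); b1 <- floor((e - 1) / bin_size)
        for (b in b0:b1) {
          lo <- max(s, b * bin_size)
          hi <- min(e, (b + 1) * bin_size)
          acc[b + 1] <- acc[b + 1] + v * (hi - lo)
        }
      }
    }
    widths <- rep(bin_size, nb)
    last <- genome$chrom_lengths[[ch]] - (nb - 1) * bin_size
    widths[nb] <- last
    acc / widths
  })
  names(values) <- genome$chrom_names
  signal_track(values, bin_size, sample)
}

#' Write a signal track as bedGraph (one line per bin)
#'
#' @param x a [signal_track()]; @param genome matching [genome_model()];
#' @param path output path.
#' @export
write_bedgraph <- function(x, genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(x$values)) {
    v <- x$values[[ch]]
    starts <- (seq_along(v) - 1) * x$bin_size
    ends <- pmin(starts + x$bin_size, genome$chrom_lengths[[ch]])
    writeLines(sprintf("%s\t%s\t%s\t%s", ch,
                       format(starts, scientific = FALSE, trim = TRUE),
                       format(ends, scientific = FALSE, trim = TRUE),
                       format(v, scientific = FALSE, trim = TRUE)), con)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Contact triples
# ---------------------------------------------------------------------------

#' Read bin-pair contact triples into a contact map
#'
#' The exchange format is 5-column text: chromA, startA, chromB, startB,
#' count (0-based bin start coordinates). Cis counts are added to both
#' (i, j) and (j, i) unless i = j; each trans pair is stored once under the
#' unordered chromosome pair (genome order).
#'
#' @param path triple-text path.
#' @param genome a [genome_model()].
#' @param bin_size bin width in bp of the triples.
#' @export
read_contacts <- function(path, genome, bin_size = genome$bin_size) {
  if (!file.exists(path)) stop("file not found: ", path)
  nb <- setNames(as.integer(ceiling(genome$chrom_lengths / bin_size)),
                 genome$chrom_names)
  cis <- lapply(genome$chrom_names, function(ch)
    matrix(0, nb[[ch]], nb[[ch]]))
  names(cis) <- genome$chrom_names
  trans <- list()
  info <- file.info(path)
  if (!is.na(info$size) && info$size > 0) {
    dt <- fread(path, header = FALSE, sep = "\t",
                col.names = c("chromA", "startA", "chromB", "startB", "count"))
    if (any(dt$count < 0)) stop("negative contact count")
    unknown <- setdiff(unique(c(dt$chromA, dt$chromB)), genome$chrom_names)
    if (length(unknown)) stop("unknown chromosome: ", unknown[1])
    ia <- floor(dt$startA / bin_size) + 1L
    ib <- floor(dt$startB / bin_size) + 1L
    if (any(ia > nb[dt$chromA]) || any(ib > nb[dt$chromB]))
      stop("bin outside genome")
    ord <- match(dt$chromA, genome$chrom_names) <=
      match(dt$chromB, genome$chrom_names)
    # orient trans pairs by genome order so each unordered pair is one key
    swap <- !ord & dt$chromA != dt$chromB
    if (any(swap)) {
      tmp <- dt$chromA[swap]; dt$chromA[swap] <- dt$chromB[swap]
      dt$chromB[swap] <- tmp
      tmp <- ia[swap]; ia[swap] <- ib[swap]; ib[swap] <- tmp
    }
    dt$i <- ia; dt$j <- ib
    is_cis <- dt$chromA == dt$chromB
    if (any(is_cis)) {
      sub <- dt[is_cis, ]
      agg <- sub[, list(count = sum(count)), by = c("chromA", "i", "j")]
      for (ch in unique(agg$chromA)) {
        a <- agg[agg$chromA == ch, ]
        m <- cis[[ch]]
        ij <- cbind(a$i, a$j)
        m[ij] <- m[ij] + a$count
        off <- a$i != a$j
        ji <- cbind(a$j[off], a$i[off])
        m[ji] <- m[ji] + a$count[off]
        cis[[ch]] <- m
      }
    }
    if (any(!is_cis)) {
      sub <- dt[!is_cis, ]
      agg <- sub[, list(count = sum(count)),
                 by = c("chromA", "chromB", "i", "j")]
      agg$key <- paste(agg$chromA, agg$chromB, sep = "|")
      for (key in unique(agg$key)) {
        a <- agg[agg$key == key, ]
        ca <- a$chromA[1]; cb <- a$chromB[1]
        if (is.null(trans[[key]]))
          trans[[key]] <- matrix(0, nb[[ca]], nb[[cb]])
        ij <- cbind(a$i, a$j)
        trans[[key]][ij] <- trans[[key]][ij] + a$count
      }
    }
  }
  contact_map(cis, trans, bin_size)
}

#' Write a contact map as bin-pair triples
#'
#' Cis entries are written once (upper triangle including diagonal);
#' zero entries are omitted.
#'
#' @param x a [contact_map()]; @param path output path.
#' @export
write_contacts <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  bs <- x$bin_size
  for (ch in names(x$cis)) {
    m <- x$cis[[ch]]
    idx <- which(upper.tri(m, diag = TRUE) & m > 0, arr.ind = TRUE)
    if (nrow(idx))
      writeLines(sprintf("%s\t%d\t%s\t%d\t%s", ch, (idx[, 1] - 1L) * bs,
                         ch, (idx[, 2] - 1L) * bs,
                         format(m[idx], scientific = FALSE, trim = TRUE)), con)
  }
  for (key in names(x$trans)) {
    chs <- strsplit(key, "|", fixed = TRUE)[[1]]
    m <- x$trans[[key]]
    idx <- which(m > 0, arr.ind = TRUE)
    if (nrow(idx))
      writeLines(sprintf("%s\t%d\t%s\t%d\t%s", chs[1], (idx[, 1] - 1L) * bs,
                         chs[2], (idx[, 2] - 1L) * bs,
                         format(m[idx], scientific = FALSE, trim = TRUE)), con)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# GMT / expression / annotation
# ---------------------------------------------------------------------------

#' Read pathway gene sets from a GMT file
#'
#' @param path GMT path (name, description, genes...; tab separated).
#' @return A named list of class `pathway_db`: pathway name -> character
#'   vector of gene ids. Per-gene membership counts are available through
#'   [pathway_membership()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad)) stop("malformed GMT line ", bad[1], ": needs name, ",
                        "description and at least one gene")
  nm <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(nm)) stop("duplicate pathway name: ",
                              nm[duplicated(nm)][1])
  db <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(db) <- nm
  class(db) <- c("pathway_db", "list")
  db
}

#' Write pathway gene sets as GMT
#' @param db a `pathway_db`; @param path output path.
#' @export
write_gmt <- function(db, path) {
  writeLines(vapply(names(db), function(nm)
    paste(c(nm, "na", db[[nm]]), collapse = "\t"), ""), path)
  invisible(path)
}

#' Number of pathways containing each gene
#' @param db a `pathway_db`.
#' @return Named integer vector over all genes occurring in `db`.
#' @export
pathway_membership <- function(db) {
  tab <- table(unlist(db, use.names = FALSE))
  setNames(as.integer(tab), names(tab))
}

#' Read an expression count matrix
#'
#' TSV with a header row of sample ids and gene ids in the first column.
#' @param path file path.
#' @return Numeric matrix, genes x samples.
#' @export
read_expression <- function(path) {
  dt <- fread(path, header = TRUE, sep = "\t")
  m <- as.matrix(dt[, -1, with = FALSE])
  rownames(m) <- dt[[1]]
  storage.mode(m) <- "numeric"
  m
}

#' Write an expression count matrix as TSV
#' @param m genes x samples matrix; @param path output path.
#' @export
write_expression <- function(m, path) {
  dt <- data.table(gene_id = rownames(m))
  for (cn in colnames(m)) dt[[cn]] <- m[, cn]
  fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read a gene annotation TSV (gene_id, chrom, strand, tss)
#' @param path file path.
#' @export
read_gene_annotation <- function(path) {
  dt <- fread(path, header = TRUE, sep = "\t")
  gene_annotation(dt$gene_id, dt$chrom, dt$strand, dt$tss)
}

#' Write a gene annotation table as TSV
#' @param genes a [gene_annotation()]; @param path output path.
#' @export
write_gene_annotation <- function(genes, path) {
  fwrite(as.data.frame(unclass(genes)), path, sep = "\t")
  invisible(path)
}

# Shared helper: bin index (1-based) of a bp position.
bin_of <- function(pos, bin_size) as.integer(floor(pos / bin_size)) + 1L
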