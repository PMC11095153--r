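# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately avoid the package's own code paths.

# Weighted-mean pathway scores by explicit loops.
oracle_pathway_scores <- function(ratios, db, weighting = "reciprocal") {
  memb <- integer(0)
  for (p in names(db)) for (g in db[[p]])
    memb[g] <- (if (g %in% names(memb)) memb[g] else 0L) + 1L
  out <- matrix(NA_real_, length(db), ncol(ratios),
                dimnames = list(names(db), colnames(ratios)))
  for (p in names(db)) {
    genes <- db[[p]][db[[p]] %in% rownames(ratios)]
    if (!length(genes)) next
    for (cc in seq_len(ncol(ratios))) {
      num <- 0; den <- 0
      for (g in genes) {
        w <- if (weighting == "uniform") 1 else 1 / memb[[g]]
        num <- num + w * ratios[g, cc]
        den <- den + w
      }
      out[p, cc] <- num / den
    }
  }
  out
}

# Step-up BH by its textbook definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- numeric(m)
  run_min <- Inf
  for (i in m:1) {
    run_min <- min(run_min, sorted[i] * m / i)
    adj[i] <- min(run_min, 1)
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Seven-way compartment rule, evaluated per bin as a plain rule list.
oracle_compartment_class <- function(c1, c2, t = 0.2) {
  vapply(seq_along(c1), function(k) {
    a <- c1[k]; b <- c2[k]
    if (is.na(a) || is.na(b)) return(NA_character_)
    if (b - a > t && a > t) return("A_to_strongerA")
    if (b > 0 && a < 0) return("B_to_A")
    if (b - a > t && b < -t) return("B_to_weakerB")
    if (b - a < -t && a < -t) return("B_to_strongerB")
    if (b < 0 && a > 0) return("A_to_B")
    if (b - a < -t && a > t) return("A_to_weakerA")
    "stable"
  }, "")
}

# Per-diagonal means and diamond means by nested loops.
oracle_expected_by_distance <- function(m) {
  n <- nrow(m)
  out <- numeric(n)
  for (d in 0:(n - 1)) {
    acc <- 0; cnt <- 0
    for (i in 1:(n - d)) {
      acc <- acc + m[i, i + d]
      cnt <- cnt + 1
    }
    out[d + 1] <- acc / cnt
  }
  out
}

oracle_diamond_means <- function(m, w) {
  n <- nrow(m)
  out <- rep(NA_real_, n)
  for (i in (w + 1):(n - w)) {
    acc <- 0; cnt <- 0
    for (a in (i - w):(i - 1)) for (b in (i + 1):(i + w)) {
      acc <- acc + m[a, b]; cnt <- cnt + 1
    }
    out[i] <- acc / cnt
  }
  out
}

# Exact permutation p-value for |difference of group means| by full
# enumeration over all label splits.
oracle_permutation_p <- function(v, idx1) {
  n <- length(v)
  splits <- utils::combn(n, length(idx1))
  obs <- abs(mean(v[-idx1]) - mean(v[idx1]))
  hits <- 0
  for (k in seq_len(ncol(splits))) {
    g1 <- splits[, k]
    if (abs(mean(v[-g1]) - mean(v[g1])) >= obs - 1e-12) hits <- hits + 1
  }
  hits / ncol(splits)
}

# Small deterministic gene table on two chromosomes.
toy_genes <- function(n_per = 120L, chrom_len = 2e6) {
  gene_annotation(
    gene_id = sprintf("g%03d", seq_len(2L * n_per)),
    chrom = rep(c("chr1", "chr2"), each = n_per),
    strand = rep_len(c("+", "-"), 2L * n_per),
    tss = rep(round(seq(2e4, chrom_len - 2e4, length.out = n_per)), 2L))
}

# A planted dominant-enhancer ABC scenario: each gene has three candidate
# enhancers; the planted one has both stronger activity and more contacts.
abc_scenario <- function(n_genes = 50L, seed = 1L) {
  set.seed(seed)
  bin <- 5000L
  spacing <- 2e5
  chrom_len <- (n_genes + 2L) * spacing
  nb <- as.integer(ceiling(chrom_len / bin))
  genes <- gene_annotation(sprintf("g%02d", seq_len(n_genes)), "chr1", "+",
                           seq_len(n_genes) * spacing)
  offs <- c(-6e4, 3e4, 8e4)
  enh <- do.call(rbind, lapply(seq_len(n_genes), function(i)
    data.frame(chrom = "chr1", start = genes$tss[i] + offs - 500,
               end = genes$tss[i] + offs + 500)))
  dominant <- sample(3L, n_genes, replace = TRUE)
  track_vals <- numeric(as.integer(ceiling(chrom_len / 500)))
  m <- matrix(0, nb, nb)
  for (i in seq_len(n_genes)) {
    tb <- as.integer(genes$tss[i] %/% bin) + 1L
    for (e in 1:3) {
      row <- (i - 1L) * 3L + e
      height <- if (e == dominant[i]) 5 else 1
      b0 <- as.integer(enh$start[row] %/% 500) + 1L
      b1 <- as.integer((enh$end[row] - 1) %/% 500) + 1L
      track_vals[b0:b1] <- track_vals[b0:b1] + height
      eb <- as.integer(floor((enh$start[row] + enh$end[row]) / 2) %/% bin) + 1L
      lam <- if (e == dominant[i]) 50 else 10
      cnt <- rpois(1, lam)
      m[tb, eb] <- m[tb, eb] + cnt
      m[eb, tb] <- m[eb, tb] + cnt
    }
  }
  diag(m) <- 100
  ps <- peak_set(enh$chrom, enh$start, enh$end)
  k27ac <- signal_track(list(chr1 = track_vals), 500L, "k27ac")
  k4 <- signal_track(list(chr1 = rep(1, length(track_vals))), 500L, "k4")
  cm <- contact_map(list(chr1 = m), list(), bin)
  list(genes = genes, enhancers = ps, k27ac = k27ac, k4 = k4,
       contacts = cm, dominant = dominant,
       enhancer_of = function(i, e) enh[(i - 1L) * 3L + e, ])
}
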