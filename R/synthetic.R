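# Seeded synthetic multi-omics generator with planted ground truth.
#
# Each generator is fully deterministic given its seed argument; make_demo()
# derives one sub-seed per data modality from a master seed so that adding
# a modality never perturbs the others.

#' Generate a synthetic genome model
#'
#' GC content is drawn as a smoothed random walk rescaled into
#' `[0.3, 0.6]`; when compartment labels are supplied the A bins receive a
#' GC offset so that GC correlates positively with compartment A, as it
#' does in real genomes.
#'
#' @param n_chrom number of chromosomes (>= 1).
#' @param chrom_length_bp length of every chromosome in bp.
#' @param bin_size bin width in bp.
#' @param seed integer seed.
#' @param compartment_labels optional named list per chromosome of "A"/"B"
#'   labels (one per bin) to correlate GC with.
#' @return A [genome_model()] with a GC track.
#' @export
make_genome <- function(n_chrom, chrom_length_bp, bin_size, seed = 1L,
                        compartment_labels = NULL) {
  if (n_chrom < 1) stop("n_chrom must be >= 1")
  if (bin_size > chrom_length_bp) stop("bin_size exceeds chromosome length")
  set.seed(seed)
  chroms <- paste0("chr", seq_len(n_chrom))
  nb <- as.integer(ceiling(chrom_length_bp / bin_size))
  gc <- lapply(chroms, function(ch) {
    walk <- cumsum(rnorm(nb))
    k <- min(11L, nb)
    sm <- stats::filter(walk, rep(1 / k, k), sides = 2)
    sm[is.na(sm)] <- walk[is.na(sm)]
    rng <- range(sm)
    base <- if (diff(rng) > 0)
      0.35 + 0.15 * (sm - rng[1]) / diff(rng) else rep(0.45, nb)
    as.numeric(base)
  })
  names(gc) <- chroms
  if (!is.null(compartment_labels)) {
    for (ch in chroms) {
      lab <- compartment_labels[[ch]]
      gc[[ch]] <- pmin(0.6, pmax(0.3, gc[[ch]] + ifelse(lab == "A", 0.06, -0.06)))
    }
  }
  genome_model(chroms, rep(chrom_length_bp, n_chrom), bin_size, gc)
}

#' Alternating-block compartment labels
#'
#' @param genome a [genome_model()].
#' @param block_bins bins per compartment block.
#' @return Named list per chromosome of "A"/"B" labels, starting with "A".
#' @export
checkerboard_labels <- function(genome, block_bins = 10L) {
  labs <- lapply(genome$chrom_names, function(ch) {
    nb <- genome$n_bins[[ch]]
    blk <- (seq_len(nb) - 1L) %/% block_bins
    ifelse(blk %% 2L == 0L, "A", "B")
  })
  names(labs) <- genome$chrom_names
  labs
}

#' Flip a fraction of compartment blocks between conditions
#'
#' Whole blocks are relabelled A<->B; the genome itself is untouched, so
#' the flip set is the only signal separating the two conditions.
#'
#' @param labels named list of per-bin labels (see [checkerboard_labels()]).
#' @param block_bins block size used to build `labels`.
#' @param flip_fraction fraction of blocks to flip.
#' @param seed integer seed.
#' @return List with `labels` (flipped copy) and `flipped` (named list of
#'   flipped bin indices per chromosome).
#' @export
flip_labels <- function(labels, block_bins = 10L, flip_fraction = 0.1,
                        seed = 1L) {
  set.seed(seed)
  out <- labels
  flipped <- list()
  for (ch in names(labels)) {
    nb <- length(labels[[ch]])
    n_blocks <- ceiling(nb / block_bins)
    k <- round(flip_fraction * n_blocks)
    flipped[[ch]] <- integer()
    if (k > 0) {
      blocks <- sample(n_blocks, k)
      for (b in blocks) {
        idx <- ((b - 1L) * block_bins + 1L):min(b * block_bins, nb)
        out[[ch]][idx] <- ifelse(labels[[ch]][idx] == "A", "B", "A")
        flipped[[ch]] <- c(flipped[[ch]], idx)
      }
      flipped[[ch]] <- sort(flipped[[ch]])
    }
  }
  list(labels = out, flipped = flipped)
}

#' Simulate a two-condition RNA-seq count matrix
#'
#' Counts are negative binomial with a shared per-gene baseline mean drawn
#' from a log-normal abundance distribution scaled to the target depth;
#' planted differential genes have condition-2 means multiplied by
#' `2^lfc` (sign alternating up/down so both directions are represented,
#' as in a typical resistance-formation contrast).
#'
#' @param n_genes total genes; @param n_de planted differential genes.
#' @param lfc magnitude of the planted log2 fold change (non-zero).
#' @param dispersion NB dispersion (1/size); must be > 0. Default 0.02,
#'   the scale typical of isogenic cell-line replicates.
#' @param depth target per-sample total count.
#' @param n_rep replicates per condition (default 3).
#' @param seed integer seed.
#' @return List with `counts` (genes x samples matrix, columns
#'   `c1_r*`/`c2_r*`), `design` (named condition vector) and `truth`
#'   (data.frame gene_id, planted signed lfc for DE genes).
#' @export
simulate_expression <- function(n_genes = 2000L, n_de = 200L, lfc = 2,
                                dispersion = 0.02, depth = 2.5e6,
                                n_rep = 3L, seed = 1L) {
  if (n_de > n_genes) stop("n_de must be <= n_genes")
  if (n_de > 0 && lfc == 0) stop("lfc must be non-zero for DE genes")
  if (dispersion <= 0) stop("dispersion must be > 0")
  set.seed(seed)
  gene_id <- sprintf("gene_%04d", seq_len(n_genes))
  abund <- exp(rnorm(n_genes, 0, 1))
  mu1 <- depth * abund / sum(abund)
  sign_vec <- numeric(n_genes)
  if (n_de > 0)
    sign_vec[seq_len(n_de)] <- rep_len(c(1, -1), n_de)
  mu2 <- mu1 * 2^(lfc * sign_vec)
  size <- 1 / dispersion
  samples <- c(paste0("c1_r", seq_len(n_rep)), paste0("c2_r", seq_len(n_rep)))
  counts <- matrix(0L, n_genes, 2L * n_rep,
                   dimnames = list(gene_id, samples))
  for (r in seq_len(n_rep))
    counts[, r] <- rnbinom(n_genes, mu = mu1, size = size)
  for (r in seq_len(n_rep))
    counts[, n_rep + r] <- rnbinom(n_genes, mu = mu2, size = size)
  design <- setNames(rep(c("c1", "c2"), each = n_rep), samples)
  truth <- data.frame(gene_id = gene_id[seq_len(n_de)],
                      lfc = (lfc * sign_vec)[seq_len(n_de)],
                      stringsAsFactors = FALSE)
  list(counts = counts, design = design, truth = truth, seed = seed)
}

#' Plant per-gene promoter states for two conditions
#'
#' @param genes a [gene_annotation()].
#' @param probs state probabilities for condition 1 over
#'   (none, K4_only, K27_only, bivalent); defaults reflect the typical
#'   predominance of unmarked and K4-marked promoters.
#' @param transition_fraction fraction of genes whose state changes in
#'   condition 2 (a marked state drops one mark).
#' @param seed integer seed.
#' @return data.frame (gene_id, state_c1, state_c2).
#' @export
plant_promoter_states <- function(genes,
                                  probs = c(none = 0.45, K4_only = 0.35,
                                            K27_only = 0.1, bivalent = 0.1),
                                  transition_fraction = 0.15, seed = 1L) {
  set.seed(seed)
  states <- c("none", "K4_only", "K27_only", "bivalent")
  s1 <- sample(states, nrow(genes), replace = TRUE, prob = probs)
  s2 <- s1
  n_tr <- round(transition_fraction * nrow(genes))
  if (n_tr > 0) {
    cand <- which(s1 != "none")
    cand <- cand[seq_len(min(n_tr, length(cand)))]
    s2[cand] <- vapply(s1[cand], function(s) switch(s,
      K4_only = "none", K27_only = "none",
      bivalent = sample(c("K4_only", "K27_only"), 1), "none"), "")
  }
  data.frame(gene_id = genes$gene_id, state_c1 = s1, state_c2 = s2,
             stringsAsFactors = FALSE)
}

# Peaks from a noisy track: maximal runs of >= min_bins bins above
# threshold (the width floor rejects isolated noise bins).
call_peaks_from_track <- function(values, bin_size, threshold,
                                  min_bins = 2L) {
  above <- values > threshold
  if (!any(above)) return(list(start = numeric(), end = numeric(),
                               signal = numeric()))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= min_bins)
  if (!length(keep)) return(list(start = numeric(), end = numeric(),
                                 signal = numeric()))
  list(start = (starts[keep] - 1) * bin_size,
       end = ends[keep] * bin_size,
       signal = vapply(keep, function(k)
         mean(values[starts[k]:ends[k]]), 0))
}

#' Simulate histone-mark peak sets and signal tracks
#'
#' Three marks are produced per condition: a promoter-active mark ("K4"),
#' a repressive mark ("K27") and an enhancer/activity mark ("K27ac").
#' Promoter peaks follow the planted per-gene states; the activity mark
#' gains peaks at planted enhancer positions (with conserved / lost /
#' gained dynamics) and at K4-marked promoters. Signal tracks are the
#' binned peak coverage plus truncated Gaussian noise of standard
#' deviation `peak_height / snr`; the emitted peak sets are re-called from
#' the noisy track at half peak height, so recovery degrades as `snr`
#' falls.
#'
#' @param genome a [genome_model()].
#' @param genes a [gene_annotation()].
#' @param states planted promoter states (see [plant_promoter_states()]);
#'   generated automatically when `NULL`.
#' @param n_enhancers planted enhancer count per condition pair.
#' @param enhancer_dynamics integer vector `c(lost, gained)` among the
#'   planted enhancers.
#' @param snr peak height over noise standard deviation; `Inf` for a
#'   noise-free dataset.
#' @param peak_width planted peak width in bp.
#' @param peak_height planted peak height (arbitrary calibrated units).
#' @param track_bin signal-track bin width in bp.
#' @param seed integer seed.
#' @return List `data` (nested: `data[[mark]][[condition]]` is a list with
#'   `peaks` and `track`) and `truth` (states, planted enhancers with
#'   dynamics labels, planted promoter peak intervals).
#' @export
simulate_marks <- function(genome, genes, states = NULL, n_enhancers = 60L,
                           enhancer_dynamics = c(lost = 10L, gained = 5L),
                           snr = Inf, peak_width = 1500L, peak_height = 10,
                           track_bin = 250L, seed = 1L) {
  if (is.null(states)) states <- plant_promoter_states(genes, seed = seed)
  set.seed(seed + 1L)
  hw <- 2500L
  # planted promoter peak interval per gene, centred on the TSS
  prom_start <- pmax(0, genes$tss - peak_width %/% 2)
  prom_end <- pmin(genes$tss + peak_width %/% 2,
                   genome$chrom_lengths[genes$chrom])
  if (any(prom_start >= prom_end)) stop("degenerate promoter peak interval")
  # planted enhancers: drawn outside all promoter windows
  # clearance includes one track bin so bin-rounded called peaks never
  # touch a promoter window
  enh <- .draw_enhancers(genome, genes, n_enhancers, peak_width,
                         hw + track_bin)
  n_lost <- enhancer_dynamics[[1]]; n_gained <- enhancer_dynamics[[2]]
  if (n_lost + n_gained > n_enhancers)
    stop("more dynamic enhancers than planted enhancers")
  lab <- rep("conserved", n_enhancers)
  lab[seq_len(n_lost)] <- "lost"
  lab[n_lost + seq_len(n_gained)] <- "gained"
  marks <- c("K4", "K27", "K27ac")
  data <- lapply(marks, function(m) list())
  names(data) <- marks
  for (cond in c("c1", "c2")) {
    st <- if (cond == "c1") states$state_c1 else states$state_c2
    k4_idx <- which(st %in% c("K4_only", "bivalent"))
    k27_idx <- which(st %in% c("K27_only", "bivalent"))
    plan <- list(
      K4 = data.frame(chrom = genes$chrom[k4_idx],
                      start = prom_start[k4_idx], end = prom_end[k4_idx]),
      K27 = data.frame(chrom = genes$chrom[k27_idx],
                       start = prom_start[k27_idx], end = prom_end[k27_idx]))
    keep <- if (cond == "c1") lab != "gained" else lab != "lost"
    plan$K27ac <- rbind(
      enh[keep, c("chrom", "start", "end")],
      data.frame(chrom = genes$chrom[k4_idx],
                 start = prom_start[k4_idx], end = prom_end[k4_idx]))
    for (m in marks) {
      pl <- plan[[m]]
      .check_no_overlap(pl, m)
      tr_vals <- lapply(genome$chrom_names, function(ch) {
        nb <- as.integer(ceiling(genome$chrom_lengths[[ch]] / track_bin))
        v <- numeric(nb)
        sub <- pl[pl$chrom == ch, , drop = FALSE]
        for (k in seq_len(nrow(sub))) {
          b0 <- bin_of(sub$start[k], track_bin)
          b1 <- bin_of(sub$end[k] - 1, track_bin)
          v[b0:b1] <- v[b0:b1] + peak_height
        }
        if (is.finite(snr)) v <- pmax(0, v + rnorm(nb, 0, peak_height / snr))
        v
      })
      names(tr_vals) <- genome$chrom_names
      called <- lapply(genome$chrom_names, function(ch)
        call_peaks_from_track(tr_vals[[ch]], track_bin, peak_height / 2))
      ps <- peak_set(
        chrom = rep(genome$chrom_names, vapply(called, function(x)
          length(x$start), 0L)),
        start = unlist(lapply(called, `[[`, "start")),
        end = unlist(lapply(called, `[[`, "end")),
        signal = unlist(lapply(called, `[[`, "signal")))
      data[[m]][[cond]] <- list(
        peaks = ps,
        track = signal_track(tr_vals, track_bin,
                             sample = paste(m, cond, sep = "_")))
    }
  }
  enh$dynamics <- lab
  list(data = data,
       truth = list(states = states, enhancers = enh,
                    promoter_peaks = data.frame(
                      gene_id = genes$gene_id, chrom = genes$chrom,
                      start = prom_start, end = prom_end,
                      stringsAsFactors = FALSE),
                    seed = seed))
}

.draw_enhancers <- function(genome, genes, n, width, prom_hw) {
  placed <- list()
  tries <- 0L
  while (length(placed) < n && tries < 50L * n) {
    tries <- tries + 1L
    ch <- sample(genome$chrom_names, 1)
    len <- genome$chrom_lengths[[ch]]
    s <- floor(runif(1, 0, len - width))
    e <- s + width
    g <- genes[genes$chrom == ch, , drop = FALSE]
    # keep clear of promoter windows and previously placed enhancers
    if (nrow(g) && any(s < g$tss + prom_hw & e > g$tss - prom_hw)) next
    clash <- FALSE
    for (p in placed)
      if (p$chrom == ch && s < p$end + width && e > p$start - width) {
        clash <- TRUE; break
      }
    if (clash) next
    placed[[length(placed) + 1L]] <- list(chrom = ch, start = s, end = e)
  }
  if (length(placed) < n) stop("could not place ", n, " enhancers")
  data.frame(chrom = vapply(placed, `[[`, "", "chrom"),
             start = vapply(placed, `[[`, 0, "start"),
             end = vapply(placed, `[[`, 0, "end"),
             stringsAsFactors = FALSE)
}

.check_no_overlap <- function(df, mark) {
  if (nrow(df) < 2) return(invisible())
  df <- df[order(df$chrom, df$start), ]
  same <- df$chrom[-1] == df$chrom[-nrow(df)]
  if (any(same & df$start[-1] < df$end[-nrow(df)]))
    stop("overlapping planted peaks for mark ", mark)
  invisible()
}

#' Simulate a pair of condition-specific contact maps
#'
#' Cis expected counts follow a power-law distance decay
#' `s^decay_exponent` with a multiplicative same-compartment boost
#' `(1 + delta)`; counts are Poisson sampled. Trans maps are uniform with
#' planted enriched region pairs. Both conditions share the decay law and
#' differ only through their compartment labels (and the trans plant).
#'
#' @param genome a [genome_model()].
#' @param labels1,labels2 per-condition compartment labels (named lists of
#'   per-bin "A"/"B").
#' @param decay_exponent power-law exponent (< 0).
#' @param delta same-compartment contact boost (> 0; 0 allowed to produce
#'   a compartment-free control map).
#' @param total_reads expected total contacts per condition.
#' @param trans_fraction fraction of reads placed in trans.
#' @param trans_spec optional data.frame (chromA, binA_lo, binA_hi, chromB,
#'   binB_lo, binB_hi, fold) of planted trans enrichments applying to
#'   condition 2 only.
#' @param seed integer seed.
#' @return List `maps` (condition -> [contact_map()]) and `truth`.
#' @export
simulate_contacts <- function(genome, labels1, labels2 = labels1,
                              decay_exponent = -1, delta = 1,
                              total_reads = 5e6, trans_fraction = 0.2,
                              trans_spec = NULL, seed = 1L) {
  if (decay_exponent >= 0) stop("decay_exponent must be < 0")
  if (delta < 0) stop("delta must be >= 0")
  set.seed(seed)
  chroms <- genome$chrom_names
  n_pairs_diag <- sum(vapply(genome$n_bins, function(n) n * (n + 1) / 2, 0))
  mean_per_dist <- total_reads * (1 - trans_fraction) / n_pairs_diag
  if (mean_per_dist < 10)
    warning("total_reads low: fewer than 10 expected contacts per bin pair")
  build <- function(labels, plant_trans) {
    cis <- list()
    lam_sum <- 0
    lam_list <- list()
    for (ch in chroms) {
      nb <- genome$n_bins[[ch]]
      d <- abs(outer(seq_len(nb), seq_len(nb), "-"))
      s <- pmax(d, 0.5)
      lam <- s^decay_exponent
      lab <- labels[[ch]]
      same <- outer(lab, lab, "==")
      lam <- lam * (1 + delta * same)
      lam_list[[ch]] <- lam
      lam_sum <- lam_sum + sum(lam[upper.tri(lam, diag = TRUE)])
    }
    scale <- total_reads * (1 - trans_fraction) / lam_sum
    for (ch in chroms) {
      nb <- genome$n_bins[[ch]]
      lam <- lam_list[[ch]] * scale
      up <- upper.tri(lam, diag = TRUE)
      cnt <- matrix(0, nb, nb)
      cnt[up] <- rpois(sum(up), lam[up])
      cnt <- cnt + t(cnt) - diag(diag(cnt))
      cis[[ch]] <- cnt
    }
    trans <- list()
    if (length(chroms) > 1 && trans_fraction > 0) {
      pairs <- utils::combn(chroms, 2)
      lam_t <- list()
      tot_t <- 0
      for (k in seq_len(ncol(pairs))) {
        ca <- pairs[1, k]; cb <- pairs[2, k]
        lam <- matrix(1, genome$n_bins[[ca]], genome$n_bins[[cb]])
        if (plant_trans && !is.null(trans_spec)) {
          sub <- trans_spec[trans_spec$chromA == ca & trans_spec$chromB == cb, ,
                            drop = FALSE]
          for (r in seq_len(nrow(sub)))
            lam[sub$binA_lo[r]:sub$binA_hi[r],
                sub$binB_lo[r]:sub$binB_hi[r]] <- sub$fold[r]
        }
        lam_t[[paste(ca, cb, sep = "|")]] <- lam
        tot_t <- tot_t + sum(lam)
      }
      scale_t <- total_reads * trans_fraction / tot_t
      for (key in names(lam_t)) {
        lam <- lam_t[[key]] * scale_t
        trans[[key]] <- matrix(rpois(length(lam), lam), nrow(lam))
      }
    }
    contact_map(cis, trans, genome$bin_size)
  }
  maps <- list(c1 = build(labels1, plant_trans = FALSE),
               c2 = build(labels2, plant_trans = TRUE))
  list(maps = maps,
       truth = list(labels = list(c1 = labels1, c2 = labels2),
                    decay_exponent = decay_exponent, delta = delta,
                    trans_spec = trans_spec, seed = seed))
}
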