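test_that("peak dynamics partition the inputs and swap under exchange", {
  p1 <- peak_set(rep("chr1", 5), c(0, 100, 200, 300, 400) * 10,
                 c(0, 100, 200, 300, 400) * 10 + 50)
  expect_equal(unname(classify_peak_dynamics(p1, p1)$counts), c(5, 0, 0))
  p2 <- peak_set(rep("chr1", 3), c(5000, 6000, 7000),
                 c(5050, 6050, 7050))
  expect_equal(unname(classify_peak_dynamics(p1, p2)$counts), c(0, 5, 3))

  # 5 vs 5 with exactly 3 overlapping pairs
  a <- peak_set(rep("chr1", 5), c(0, 200, 400, 600, 800),
                c(100, 300, 500, 700, 900))
  b <- peak_set(rep("chr1", 5), c(50, 250, 450, 5000, 6000),
                c(150, 350, 550, 5100, 6100))
  dyn <- classify_peak_dynamics(a, b)
  expect_equal(unname(dyn$counts), c(3, 2, 2))
  # swap symmetry and partition property on random fixtures
  set.seed(21)
  for (k in 1:10) {
    x <- sort(sample(0:500, 12)) * 100
    y <- sort(sample(0:500, 10)) * 100
    pa <- peak_set(rep("chr1", 12), x, x + sample(50:150, 12, TRUE))
    pb <- peak_set(rep("chr1", 10), y, y + sample(50:150, 10, TRUE))
    ab <- classify_peak_dynamics(pa, pb)
    ba <- classify_peak_dynamics(pb, pa)
    expect_equal(ab$counts[["conserved"]] + ab$counts[["lost"]], nrow(pa))
    expect_equal(ab$counts[["lost"]], ba$counts[["gained"]])
    expect_equal(ab$counts[["gained"]], ba$counts[["lost"]])
  }
})

test_that("region annotation follows midpoint precedence", {
  genes <- gene_annotation(c("g1", "g2"), "chr1", "+", c(10000, 50000))
  bodies <- data.frame(chrom = "chr1", start = c(10000, 50000),
                       end = c(30000, 70000))
  exons <- data.frame(chrom = "chr1", start = c(13000, 53000),
                      end = c(15000, 56000))
  mids <- c(8000, 11000, 48000,      # promoter windows
            14000, 54000,            # exons
            20000,                   # intron
            40000, 80000)            # distal on chr1
  peaks <- peak_set(c(rep("chr1", 8), "chr2", "chr2"),
                    c(mids - 100, 4900, 89900),
                    c(mids + 100, 5100, 90100))
  ann <- annotate_regions(peaks, genes, bodies, exons)
  expect_equal(unname(c(ann$counts)), c(3, 2, 1, 4))
  # gene-free chromosome peaks are distal
  expect_true(all(ann$category[peaks$chrom == "chr2"] == "distal"))
})

test_that("promoter states follow the two-mark truth table", {
  genes <- gene_annotation(paste0("g", 1:4), "chr1", "+",
                           c(10000, 30000, 50000, 70000))
  k4 <- peak_set(rep("chr1", 2), c(9000, 29000), c(11000, 31000))
  k27 <- peak_set(rep("chr1", 2), c(9500, 49000), c(10500, 51000))
  st <- promoter_state(k4, k27, genes)
  expect_equal(st$state, c("bivalent", "K4_only", "K27_only", "none"))
})

test_that("bivalent transition counts recover a planted 56-gene table", {
  n_biv <- 56L
  ids <- sprintf("b%02d", seq_len(n_biv))
  st1 <- data.frame(gene_id = c(ids, "x1", "x2"),
                    state = c(rep("bivalent", n_biv), "K4_only", "bivalent"))
  # 13 up: 4 lose the repressive mark; 43 down: 2 lose the active mark
  s2 <- rep("bivalent", n_biv)
  s2[1:4] <- "K4_only"
  s2[14:15] <- "K27_only"
  st2 <- data.frame(gene_id = c(ids, "x1", "x2"),
                    state = c(s2, "K4_only", "K4_only"))
  diff <- data.frame(
    feature_id = c(ids, "x1", "x2"),
    log2fc = c(rep(1, 13), rep(-1, 43), 2, 0.1),
    significant = c(rep(TRUE, n_biv), TRUE, FALSE))
  tab <- bivalent_transition_table(st1, st2, diff)
  expect_equal(tab["up", "lost_K27"], 4L)
  expect_equal(tab["up", "stable"], 9L)
  expect_equal(tab["down", "lost_K4"], 2L)
  expect_equal(tab["down", "stable"], 41L)
  expect_equal(sum(tab), n_biv)  # x1 (not bivalent) and x2 (not significant)
                                 # are excluded
  empty <- bivalent_transition_table(st1, st2,
                                     transform(diff, significant = FALSE))
  expect_equal(sum(empty), 0L)
})

test_that("promoter signal is a length-weighted per-bp mean with clipping", {
  genome <- genome_model("chr1", 10000, 2500)
  tr_const <- signal_track(list(chr1 = rep(3, 4)), 2500, "c")
  genes <- gene_annotation(c("mid", "edge"), "chr1", "+", c(5000, 1000))
  expect_equal(unname(promoter_signal(tr_const, genes, 2500, genome)),
               c(3, 3))
  tr_half <- signal_track(list(chr1 = c(0, 4, 0, 0)), 2500, "h")
  g <- gene_annotation("g", "chr1", "+", 2500)
  expect_equal(unname(promoter_signal(tr_half, g, 2500, genome)), 2)
  # clipped window at the chromosome start: [0, 3500) over values (0, 4)
  g2 <- gene_annotation("g", "chr1", "+", 1000)
  expect_equal(unname(promoter_signal(tr_half, g2, 2500, genome)),
               4 * 1000 / 3500)
})

test_that("modification-expression correlation matches hand covariance", {
  x <- setNames(c(1, 2, 3), paste0("g", 1:3))
  expect_equal(modification_expression_correlation(x, 2 * x)$r, 1)
  expect_equal(modification_expression_correlation(x, -x)$r, -1)
  y <- setNames(c(1, 3, 2), names(x))
  out <- modification_expression_correlation(x, y)
  expect_equal(out$r, 0.5, tolerance = 1e-12)
  expect_equal(out$n, 3L)
  expect_error(modification_expression_correlation(x[1:2], y[1:2]),
               ">= 3")
})

test_that("enhancer definition removes every promoter-overlapping peak", {
  genes <- gene_annotation(c("g1", "g2"), "chr1", "+", c(10000, 50000))
  inside <- peak_set(rep("chr1", 4), c(8000, 9000, 48000, 51000),
                     c(8500, 9500, 48500, 51500))
  expect_equal(nrow(define_enhancers(inside, genes)), 0L)
  free <- peak_set(rep("chr2", 3), c(100, 200, 300) * 100,
                   c(105, 205, 305) * 100)
  expect_equal(nrow(define_enhancers(free, genes)), 3L)
  mixed <- peak_set(rep("chr1", 10), seq(0, 90000, 10000),
                    seq(0, 90000, 10000) + 3000)
  enh <- define_enhancers(mixed, genes)
  # peaks starting at 10 kb and 50 kb overlap promoter windows; so do the
  # ones ending at 13 kb and 53 kb... count checked by construction
  prom <- data.frame(chrom = "chr1", start = c(7500, 47500),
                     end = c(12500, 52500))
  n_in <- sum(vapply(seq_len(nrow(mixed)), function(i)
    any(mixed$chrom[i] == prom$chrom & mixed$start[i] < prom$end &
          mixed$end[i] > prom$start), TRUE))
  expect_equal(nrow(enh), nrow(mixed) - n_in)
  # no residual promoter overlap, by direct interval check
  for (i in seq_len(nrow(enh)))
    expect_false(any(enh$start[i] < prom$end & enh$end[i] > prom$start &
                       enh$chrom[i] == prom$chrom))
})

test_that("signal profiles align and average across regions", {
  tr <- signal_track(list(chr1 = rep(2, 40)), 100, "c")
  regions <- data.frame(chrom = "chr1", pos = c(1000, 3000))
  prof <- signal_at_regions(tr, regions, 5)
  expect_equal(unname(prof), rep(2, 11))
  v <- rep(0, 40); v[11] <- 7
  tr2 <- signal_track(list(chr1 = v), 100, "d")
  prof2 <- signal_at_regions(tr2, data.frame(chrom = "chr1", pos = 1050), 3)
  expect_equal(unname(prof2), c(0, 0, 0, 7, 0, 0, 0))
  v3 <- rep(0, 40); v3[11] <- 2; v3[31] <- 4
  tr3 <- signal_track(list(chr1 = v3), 100, "e")
  prof3 <- signal_at_regions(tr3, data.frame(chrom = "chr1",
                                             pos = c(1050, 3050)), 2)
  expect_equal(unname(prof3[3]), 3)
})
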