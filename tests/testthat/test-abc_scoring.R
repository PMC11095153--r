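test_that("candidate enhancers are selected by midpoint within 1 Mb", {
  gene <- gene_annotation("g", "chr1", "+", 2e6)[1, ]
  mids <- c(2e6 + 5e5, 2e6 - 5e5, 2e6 + 1.5e6, 2e6 - 1.2e6, 2e6 + 9.9e5,
            1e4, 2e6, 3.5e6)
  enh <- peak_set(rep("chr1", 8), mids - 500, mids + 500)
  out <- candidate_enhancers(gene, enh, 1e6)
  expect_equal(nrow(out), 4L)
  expect_true(all(abs((out$start + out$end) / 2 - 2e6) < 1e6))
  far <- peak_set("chr2", 2e6 - 500, 2e6 + 500)
  expect_equal(nrow(candidate_enhancers(gene, far, 1e6)), 0L)
})

test_that("A scores integrate calibrated signal over the enhancer", {
  tr <- signal_track(list(chr1 = rep(2, 10)), 500, "k27ac")
  e <- data.frame(chrom = "chr1", start = 1000, end = 1500)
  expect_equal(activity_A(e, tr, factor = 1), 1000)      # 2 * 500 bp
  expect_equal(activity_A(e, tr, factor = 1, mode = "mean"), 2)
  tr2 <- signal_track(list(chr1 = rep(4, 10)), 500, "k27ac")
  expect_equal(activity_A(e, tr2, factor = 0.5), activity_A(e, tr, 1))
  tr0 <- signal_track(list(chr1 = rep(0, 10)), 500, "z")
  expect_equal(activity_A(e, tr0), 0)
})

test_that("C scores are contacts-per-million of the chromosome cis total", {
  n <- 20L
  m <- matrix(0, n, n)
  m[1, 3] <- m[3, 1] <- 10
  m[n, n] <- 1e6 - 10
  cm <- contact_map(list(chr1 = m), list(), 5000)
  gene <- gene_annotation("g", "chr1", "+", 2500)[1, ]   # bin 1
  enh <- data.frame(chrom = "chr1", start = 12000, end = 13000) # mid bin 3
  expect_equal(contact_C(gene, enh, cm), 10)
  # depth invariance
  cm2 <- contact_map(list(chr1 = m * 2), list(), 5000)
  expect_equal(contact_C(gene, enh, cm2), 10)
  # no contacts
  enh0 <- data.frame(chrom = "chr1", start = 26000, end = 27000)
  expect_equal(contact_C(gene, enh0, cm), 0)
  expect_error(contact_C(gene, data.frame(chrom = "chr2", start = 0,
                                          end = 1000), cm),
               "different chromosomes")
})

test_that("the worked two-enhancer example gives abc 1.2 and abc_p2 4.8", {
  # Enhancer 1: 500 bp at constant 0.004 -> A = 2; contact 1 with cis
  # total 1e7 -> C = 0.1. Enhancer 2: 500 bp at 0.01 -> A = 5; contact 2
  # -> C = 0.2. Promoter mark constant 2 -> P = 2.
  n <- 20L
  m <- matrix(0, n, n)
  m[1, 3] <- m[3, 1] <- 1
  m[1, 5] <- m[5, 1] <- 2
  m[n, n] <- 1e7 - 3
  cm <- contact_map(list(chr1 = m), list(), 5000)
  vals <- rep(0, 200)                      # 500-bp track bins over 100 kb
  vals[25] <- 0.004                        # enhancer 1 in [12000, 12500)
  vals[45] <- 0.01                         # enhancer 2 in [22000, 22500)
  k27ac <- signal_track(list(chr1 = vals), 500, "k27ac")
  k4 <- signal_track(list(chr1 = rep(2, 200)), 500, "k4")
  genes <- gene_annotation("g", "chr1", "+", 2500)
  enh <- peak_set(c("chr1", "chr1"), c(12000, 22000), c(12500, 22500))
  rec <- abc_record(genes[1, ], enh, k27ac, k4, cm)
  expect_equal(rec$enhancers$A, c(2, 5))
  expect_equal(rec$enhancers$C, c(0.1, 0.2))
  expect_equal(rec$abc, 1.2)
  expect_equal(rec$p_score, 2)
  expect_equal(rec$abc_p2, 4.8)
  # enhancer order invariance and additivity over disjoint subsets
  rec_r <- abc_record(genes[1, ], enh[2:1, ], k27ac, k4, cm)
  expect_equal(rec_r$abc, rec$abc)
  expect_equal(rec_r$abc_p2, rec$abc_p2)
  r1 <- abc_record(genes[1, ], enh[1, ], k27ac, k4, cm)
  r2 <- abc_record(genes[1, ], enh[2, ], k27ac, k4, cm)
  expect_equal(r1$abc + r2$abc, rec$abc)
  # global contact scaling leaves every score unchanged
  cm3 <- contact_map(list(chr1 = m * 7), list(), 5000)
  rec3 <- abc_record(genes[1, ], enh, k27ac, k4, cm3)
  expect_equal(rec3$abc, rec$abc)
  expect_equal(rec3$abc_p2, rec$abc_p2)
  # no candidate enhancers
  none <- abc_record(genes[1, ], peak_set(), k27ac, k4, cm)
  expect_equal(none$abc, 0)
  expect_equal(none$abc_p2, 0)
})

test_that("promoter P score is a calibrated windowed mean", {
  k4 <- signal_track(list(chr1 = rep(4, 40)), 500, "k4")
  genome <- genome_model("chr1", 20000, 500)
  gplus <- gene_annotation("g", "chr1", "+", 10000)[1, ]
  gminus <- gene_annotation("g", "chr1", "-", 10000)[1, ]
  expect_equal(promoter_p(gplus, k4, factor = 0.5, genome = genome), 2)
  expect_equal(promoter_p(gminus, k4, factor = 0.5, genome = genome), 2)
  k0 <- signal_track(list(chr1 = rep(0, 40)), 500, "z")
  expect_equal(promoter_p(gplus, k0, genome = genome), 0)
  # p = 0 forces abc_p2 = 0 regardless of abc
  expect_equal(1.2 * 0^2, 0)
})

test_that("the planted dominant enhancer carries the top A*C product", {
  sc <- abc_scenario(n_genes = 60, seed = 31)
  tbl <- abc_table(sc$genes, sc$enhancers, sc$k27ac, sc$k4, sc$contacts,
                   window = 1e5)
  recs <- attr(tbl, "records")
  hit <- vapply(seq_along(recs), function(i) {
    r <- recs[[i]]
    planted <- sc$enhancer_of(i, sc$dominant[i])
    top <- which.max(r$enhancers$product)
    r$enhancers$start[top] == planted$start
  }, TRUE)
  expect_gte(mean(hit), 0.95)
})

test_that("score-expression correlation flags degenerate input", {
  t1 <- data.frame(gene_id = paste0("g", 1:5), abc = 1:5,
                   p_score = 1, abc_p2 = (1:5) * 1.0)
  lfc <- setNames(rnorm(5), t1$gene_id)
  expect_error(abc_expression_correlation(t1, t1, lfc), "degenerate")
  t2 <- t1; t2$abc_p2 <- t1$abc_p2 + c(1, 3, 2, 5, 4)
  out <- abc_expression_correlation(t1, t2,
                                    setNames(-c(1, 3, 2, 5, 4), t1$gene_id))
  expect_equal(out$r, -1, tolerance = 1e-12)
  expect_equal(out$n, 5L)
})
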