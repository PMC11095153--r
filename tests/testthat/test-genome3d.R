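test_that("expected-by-distance and O/E match loop oracles", {
  const <- matrix(5, 6, 6)
  expect_equal(expected_by_distance(const), rep(5, 6))
  expect_true(all(oe_matrix(const) == 1))
  diag_only <- diag(3, 6)
  e <- expected_by_distance(diag_only)
  expect_equal(e[1], 3)
  expect_equal(e[-1], rep(0, 5))
  # offsets with expected 0 are masked
  expect_true(all(is.na(oe_matrix(diag_only)[upper.tri(diag_only)])))

  set.seed(9)
  r <- matrix(rpois(400, 8), 20, 20)
  r <- r + t(r)
  expect_equal(expected_by_distance(r), oracle_expected_by_distance(r),
               tolerance = 1e-12)

  # doubling one entry on a diagonal of length n gives O/E 2n/(n+1)
  m4 <- matrix(2, 4, 4)
  m4[1, 2] <- m4[2, 1] <- 4
  oe4 <- oe_matrix(m4)
  expect_equal(oe4[1, 2], 2 * 3 / (3 + 1), tolerance = 1e-12)
})

test_that("compartment PC1 recovers planted labels and anchors to GC", {
  gm0 <- genome_model("chr1", 5e6, 25000)
  labs <- checkerboard_labels(gm0, 10)
  genome <- make_genome(1, 5e6, 25000, seed = 11,
                        compartment_labels = labs)
  sim <- simulate_contacts(genome, labs, decay_exponent = -1, delta = 1,
                           total_reads = 2e6, trans_fraction = 0, seed = 2)
  oe <- oe_matrix(sim$maps$c1$cis$chr1)
  ct <- compartment_pc1(oe, genome$gc$chr1)
  lab_num <- ifelse(labs$chr1 == "A", 1, -1)
  expect_gte(mean(sign(ct$pc1[!ct$mask]) == lab_num[!ct$mask]), 0.95)
  # orientation is GC-anchored, so recomputation is sign-stable
  ct2 <- compartment_pc1(oe, genome$gc$chr1)
  expect_equal(ct$pc1, ct2$pc1)
  expect_gte(cor(ct$pc1[!ct$mask], genome$gc$chr1[!ct$mask]), 0)
  # compartment-free map is rejected
  s0 <- simulate_contacts(genome, labs, delta = 0, total_reads = 2e6,
                          trans_fraction = 0, seed = 3)
  expect_error(compartment_pc1(oe_matrix(s0$maps$c1$cis$chr1),
                               genome$gc$chr1),
               "no compartment signal")
})

test_that("the seven-way classifier applies the printed thresholds in order", {
  cls <- function(a, b)
    as.character(classify_compartment_change(a, b)$category)
  expect_equal(cls(0.3, 0.6), "A_to_strongerA")
  expect_equal(cls(-0.3, 0.1), "B_to_A")
  expect_equal(cls(-0.5, -0.25), "B_to_weakerB")
  expect_equal(cls(-0.3, -0.6), "B_to_strongerB")
  expect_equal(cls(0.1, -0.1), "A_to_B")
  expect_equal(cls(0.6, 0.3), "A_to_weakerA")
  expect_equal(cls(0.1, 0.15), "stable")
  # overlap case: A_to_B wins over A_to_weakerA by rule order
  expect_equal(cls(0.3, -0.3), "A_to_B")
  expect_true(is.na(cls(NA, 0.3)))
  expect_error(classify_compartment_change(1:3 / 10, 1:2 / 10),
               "mismatched")
  # exact agreement with an independent rule evaluator
  set.seed(14)
  a <- runif(10000, -1, 1); b <- runif(10000, -1, 1)
  out <- classify_compartment_change(a, b)
  expect_identical(as.character(out$category),
                   oracle_compartment_class(a, b))
  expect_equal(sum(out$fractions), 1)
})

test_that("saddle aggregation is rank-based with enriched same-label corners", {
  # homogeneous O/E: every cell 1
  oe1 <- matrix(1, 120, 120)
  pc <- seq(-1, 1, length.out = 120)
  sd1 <- saddle(oe1, pc, n_bins = 10, trim = 0.025, corner = 2)
  expect_true(all(abs(sd1$matrix - 1) < 1e-12))
  expect_equal(sd1$strength, 1)
  # permuting bin order leaves the saddle unchanged
  set.seed(6)
  oe2 <- matrix(runif(120^2, 0.5, 1.5), 120)
  oe2 <- (oe2 + t(oe2)) / 2
  sd_a <- saddle(oe2, pc, n_bins = 10, corner = 2)
  perm <- sample(120)
  sd_b <- saddle(oe2[perm, perm], pc[perm], n_bins = 10, corner = 2)
  expect_equal(sd_a$matrix, sd_b$matrix, tolerance = 1e-12)
  # planted two-block map: same-label corners exceed the cross corner
  lab <- rep(c(1, -1), each = 60)
  oe3 <- 1 + 0.4 * outer(lab, lab)
  sd3 <- saddle(oe3, lab + rnorm(120, 0, 0.01), n_bins = 10, corner = 2)
  expect_gt(sd3$corners[["AA"]], sd3$corners[["AB"]])
  expect_gt(sd3$corners[["BB"]], sd3$corners[["AB"]])
  expect_error(saddle(oe1, pc, n_bins = 500), "reduce n_bins")
})

test_that("P(s) curves are depth-invariant with log-spaced distance bins", {
  set.seed(4)
  n <- 80
  m <- matrix(rpois(n * n, 20), n, n)
  m <- m + t(m)
  cm1 <- contact_map(list(chr1 = m), list(), 25000)
  cm2 <- contact_map(list(chr1 = m * 3), list(), 25000)
  c1 <- ps_curve(cm1, 15)
  c2 <- ps_curve(cm2, 15)
  expect_equal(c1$freq, c2$freq, tolerance = 1e-12)
  fc <- ps_log2fc(c1, c2)
  expect_true(all(abs(fc$table$log2fc) < 1e-12, na.rm = TRUE))
  expect_length(fc$crossings, 0)
  # single populated distance
  m1 <- matrix(0, 10, 10)
  for (i in 1:9) m1[i, i + 1] <- m1[i + 1, i] <- 4
  diag(m1) <- 2
  cs <- ps_curve(contact_map(list(chr1 = m1), list(), 25000), 8)
  expect_equal(sum(cs$freq > 0, na.rm = TRUE), 1L)
})

test_that("P(s) ratio crossings are interpolated within the planted interval", {
  s <- 10^seq(4, 7.2, length.out = 20)
  edges <- round(s)
  mk_curve <- function(freq) {
    out <- data.frame(s_lo = edges[-20], s_hi = edges[-1],
                      s_mid = sqrt(edges[-20] * edges[-1]), freq = freq[-20])
    class(out) <- c("ps_curve", "data.frame")
    out
  }
  base <- 1 / s
  c1 <- mk_curve(base)
  # one sign change: curve2 above below 1 Mb, beneath above 2 Mb
  ratio <- ifelse(s < 1e6, 1.3, 0.7)
  c2 <- mk_curve(base * ratio)
  fc <- ps_log2fc(c1, c2)
  expect_length(fc$crossings, 1L)
  expect_gt(fc$crossings, 1e6 / 1.5)
  expect_lt(fc$crossings, 2e6 * 1.5)
})

test_that("interaction fold changes are renormalised per map", {
  set.seed(15)
  mk <- function(f1 = 1) {
    m1 <- matrix(rpois(100, 10), 10, 10); m1 <- m1 + t(m1)
    m2 <- matrix(rpois(100, 10), 10, 10); m2 <- m2 + t(m2)
    tr <- matrix(rpois(100, 5), 10, 10)
    contact_map(list(chr1 = m1 * f1, chr2 = m2),
                list("chr1|chr2" = tr), 25000)
  }
  a <- mk()
  expect_equal(unname(interaction_fold_changes(a, a)$cis), c(0, 0))
  # global scaling changes nothing
  b <- contact_map(lapply(a$cis, `*`, 3),
                   lapply(a$trans, `*`, 3), 25000)
  fc <- interaction_fold_changes(a, b)
  expect_equal(unname(fc$cis), c(0, 0), tolerance = 1e-12)
  expect_equal(fc$trans$log2fc, 0, tolerance = 1e-12)
  # doubling chr1 cis raises chr1 and depresses everything else
  d <- contact_map(list(chr1 = a$cis$chr1 * 2, chr2 = a$cis$chr2),
                   a$trans, 25000)
  fc2 <- interaction_fold_changes(a, d)
  expect_gt(fc2$cis[["chr1"]], 0)
  expect_lt(fc2$cis[["chr2"]], 0)
  expect_lt(fc2$trans$log2fc, 0)
})

test_that("top trans regions recover a planted enriched block", {
  gm0 <- genome_model(c("chr1", "chr2"), c(2e6, 2e6), 25000)
  labs <- checkerboard_labels(gm0, 8)
  genome <- make_genome(2, 2e6, 25000, seed = 3,
                        compartment_labels = labs)
  spec <- data.frame(chromA = "chr1", binA_lo = 10, binA_hi = 20,
                     chromB = "chr2", binB_lo = 30, binB_hi = 40, fold = 8)
  sim <- simulate_contacts(genome, labs, total_reads = 8e5,
                           trans_fraction = 0.3, trans_spec = spec,
                           seed = 4)
  top <- top_trans_regions(sim$maps$c1, sim$maps$c2, "chr1", "chr2",
                           fraction = 0.02, coarse_bp = 2e5)
  planted_a <- c((spec$binA_lo - 1) * 25000, spec$binA_hi * 25000)
  planted_b <- c((spec$binB_lo - 1) * 25000, spec$binB_hi * 25000)
  expect_true(top$startA[1] < planted_a[2] && top$endA[1] > planted_a[1])
  expect_true(top$startB[1] < planted_b[2] && top$endB[1] > planted_b[1])
  # fraction 1 selects every coarse pair
  all_pairs <- top_trans_regions(sim$maps$c1, sim$maps$c2, "chr1", "chr2",
                                 fraction = 1, coarse_bp = 2e5)
  expect_equal(sum(all_pairs$n_pairs), 100)
})

test_that("insulation diamonds match the nested-loop oracle", {
  u <- matrix(7, 40, 40)
  iu <- insulation(u, 5)
  expect_true(all(iu$score[6:35] == 0))
  set.seed(12)
  r <- matrix(runif(900, 1, 5), 30, 30)
  r <- (r + t(r)) / 2
  ir <- insulation(r, 4)
  dm <- oracle_diamond_means(r, 4)
  expect_equal(ir$score, log2(dm / mean(dm, na.rm = TRUE)),
               tolerance = 1e-10)
  # two-block matrix: the global minimum sits at the junction
  blk <- matrix(1, 100, 100)
  blk[1:50, 1:50] <- 10
  blk[51:100, 51:100] <- 10
  ib <- insulation(blk, 10)
  expect_true(which.min(ib$score) %in% c(50, 51))
  expect_error(insulation(matrix(1, 5, 5), 10), "window")
})

test_that("boundary calling yields planted domain structure", {
  flat <- structure(list(score = rep(0, 80), window_bins = 5),
                    class = "insulation_track")
  bd <- boundaries_and_domains(flat, bin_size = 25000)
  expect_length(bd$boundaries, 0)
  expect_equal(nrow(bd$domains), 1L)
  # three blocks of 40 bins: two junction boundaries, three domains
  blk3 <- matrix(1, 120, 120)
  for (k in 0:2) blk3[k * 40 + 1:40, k * 40 + 1:40] <- 10
  i3 <- insulation(blk3, 8)
  b3 <- boundaries_and_domains(i3, prominence = 0.5, min_sep = 5,
                               bin_size = 25000)
  expect_length(b3$boundaries, 2)
  expect_true(all(abs(b3$boundaries - c(40, 80)) <= 1))
  expect_equal(nrow(b3$domains), 3L)
  expect_equal(sum(b3$domains$size_bp), 120 * 25000)
  # merging the last two blocks removes one boundary
  blk2 <- matrix(1, 120, 120)
  blk2[1:40, 1:40] <- 10
  blk2[41:120, 41:120] <- 10
  b2 <- boundaries_and_domains(insulation(blk2, 8), prominence = 0.5,
                               min_sep = 5)
  expect_length(b2$boundaries, 1)
})

test_that("boundary insulation comparison summarises paired differences", {
  t1 <- structure(list(score = rep(-0.5, 60), window_bins = 5),
                  class = "insulation_track")
  cmp0 <- compare_boundary_insulation(t1, t1, c(10, 30), c(10, 50))
  expect_true(all(cmp0$table$delta == 0))
  s2 <- rep(-0.5, 60)
  s2[c(10, 30, 50)] <- -0.5 + c(0.2, -0.1, 0.3)
  t2 <- structure(list(score = s2, window_bins = 5),
                  class = "insulation_track")
  cmp <- compare_boundary_insulation(t1, t2, c(10, 30), c(30, 50))
  expect_equal(cmp$table$delta, c(0.2, -0.1, 0.3))
  expect_equal(unname(cmp$summary["mean_delta"]), 0.4 / 3,
               tolerance = 1e-12)
  expect_error(compare_boundary_insulation(t1, t2, integer(), integer()),
               "empty")
})

test_that("mark-change distributions are summarised per change category", {
  cats <- classify_compartment_change(c(-0.5, -0.5, 0.1, 0.1, 0.5, NA),
                                      c(0.4, 0.3, 0.12, 0.1, 0.5, 0.2))
  lfc <- c(1, 1, 0, 0, NA, 0)
  out <- signal_change_by_category(cats, lfc)
  expect_equal(out$median[out$category == "B_to_A"], 1)
  expect_equal(out$median[out$category == "stable"], 0)
  expect_equal(out$n[out$category == "A_to_B"], 0)
  expect_equal(out$n_excluded[out$category == "stable"], 1)
  zeros <- signal_change_by_category(cats, rep(0, 6))
  expect_true(all(zeros$median[zeros$n > 0] == 0))
})
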