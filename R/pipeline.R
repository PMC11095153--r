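# End-to-end pipeline: orchestrates expression, chromatin-landscape, ABC
# and 3D-genome stages from a single declarative config, and generates a
# self-contained synthetic demo dataset.

#' Aggregate a signal track to a coarser bin grid
#'
#' @param track a [signal_track()]; @param genome a [genome_model()];
#' @param bin_size target bin width (a multiple of the track's).
#' @return A [signal_track()] at the coarser resolution (per-bin means).
#' @export
aggregate_track <- function(track, genome, bin_size) {
  fac <- bin_size / track$bin_size
  if (fac != round(fac)) stop("bin_size must be a multiple of the track's")
  values <- lapply(genome$chrom_names, function(ch) {
    v <- track$values[[ch]]
    nb <- as.integer(ceiling(genome$chrom_lengths[[ch]] / bin_size))
    grp <- (seq_along(v) - 1L) %/% as.integer(fac)
    out <- as.numeric(tapply(v, grp, mean))
    length(out) <- nb
    out[is.na(out)] <- 0
    out
  })
  names(values) <- genome$chrom_names
  signal_track(values, bin_size, track$sample)
}

#' Per-bin log2 signal fold change between two tracks
#'
#' Tracks are aggregated to `bin_size` and compared as
#' `log2((v2 + pseudocount) / (v1 + pseudocount))`.
#'
#' @param track1,track2 [signal_track()]s; @param genome [genome_model()];
#' @param bin_size comparison resolution; @param pseudocount default 1.
#' @return Named list per chromosome of per-bin log2 fold changes.
#' @export
track_log2fc <- function(track1, track2, genome, bin_size = 25000L,
                         pseudocount = 1) {
  a <- aggregate_track(track1, genome, bin_size)
  b <- aggregate_track(track2, genome, bin_size)
  out <- lapply(genome$chrom_names, function(ch)
    log2((b$values[[ch]] + pseudocount) / (a$values[[ch]] + pseudocount)))
  names(out) <- genome$chrom_names
  out
}

#' Default pipeline parameters
#'
#' The thresholds used throughout the pipeline: significance
#' (padj <= 0.05, |log2FC| >= 0.5), pathway divergence (> 0.1),
#' compartment change threshold (0.2), saddle (50 bins, 2.5% trim),
#' promoter half-width (2.5 kb), ABC candidate window (1 Mb) and
#' insulation window (10 bins).
#'
#' @return Named list of defaults.
#' @export
default_params <- function() {
  list(padj = 0.05, lfc = 0.5, pathway_diff = 0.1, classifier_t = 0.2,
       saddle_bins = 50L, saddle_trim = 0.025, promoter_halfwidth = 2500L,
       abc_window = 1e6, insulation_window = 10L, ps_log_bins = 25L)
}

.read_genome <- function(cfg) {
  gtab <- data.table::fread(cfg$genome$chroms_tsv, header = TRUE)
  gm <- genome_model(gtab$chrom, gtab$length, cfg$genome$bin_size)
  if (!is.null(cfg$genome$gc_bedgraph)) {
    gc_tr <- read_bedgraph(cfg$genome$gc_bedgraph, gm)
    gm$gc <- gc_tr$values
  }
  gm
}

#' Run the full pipeline from a config
#'
#' The config (a named list, or a YAML file path) names the input files
#' per modality and the analysis parameters; stages run in dependency
#' order (expression -> landscape -> ABC -> 3D genome), each writing TSV /
#' BED / bedGraph tables under the output directory. A missing modality
#' skips the stages that need it; a stage failure marks downstream
#' dependents skipped.
#'
#' @param config named list or YAML path. Fields: `genome` (chroms_tsv,
#'   bin_size, gc_bedgraph), `expression` (counts, design, gmt), `genes`,
#'   `marks` (per mark per condition: peaks, track), `contacts` (c1, c2
#'   at compartment resolution; c1_hires, c2_hires for ABC), `params`
#'   (see [default_params()]), `out`.
#' @return Report list: `stages` (status data.frame), `manifest` (file,
#'   md5), `params` echo. Written to `out/report.json` as well.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  params <- utils::modifyList(default_params(), config$params %||% list())
  out_dir <- config$out
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- list()
  note <- function(stage, status, detail = "") {
    stages[[length(stages) + 1L]] <<- data.frame(
      stage = stage, status = status, detail = detail,
      stringsAsFactors = FALSE)
  }
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    data.table::fwrite(as.data.frame(df), path, sep = "\t")
    path
  }
  env <- new.env()

  # --- expression stage ---------------------------------------------------
  if (!is.null(config$expression)) {
    st <- try({
      counts <- read_expression(config$expression$counts)
      des_tab <- data.table::fread(config$expression$design, header = TRUE)
      design <- setNames(des_tab$condition, des_tab$sample)
      norm <- normalize_library(counts)
      res <- two_group_test(norm$normalized, design, "welch_log")
      sig <- apply_significance(res, params$padj, params$lfc)
      emit(sig$results, "expression_differential.tsv")
      env$expr_lfc <- setNames(sig$results$log2fc, sig$results$feature_id)
      env$expr_sig <- sig$results$feature_id[sig$results$significant]
      env$diff <- sig$results
      if (!is.null(config$expression$gmt)) {
        db <- read_gmt(config$expression$gmt)
        rel <- relative_expression(norm$normalized, design)
        act <- pathway_activity(rel, db)
        div <- filter_divergent_pathways(act, params$pathway_diff)
        emit(data.frame(pathway = rownames(act$scores), act$scores,
                        difference = act$difference,
                        n_genes = act$n_genes_used),
             "pathway_activity.tsv")
        emit(data.frame(pathway = rownames(div$scores), div$scores,
                        difference = div$difference),
             "pathway_divergent.tsv")
      }
      sprintf("%d up, %d down of %d genes", sig$counts[["n_up"]],
              sig$counts[["n_down"]], nrow(res))
    }, silent = TRUE)
    if (inherits(st, "try-error")) note("expression", "failed",
                                        conditionMessage(attr(st, "condition")))
    else note("expression", "ok", st)
  } else note("expression", "skipped", "no expression input")

  genome <- if (!is.null(config$genome)) .read_genome(config) else NULL
  genes <- if (!is.null(config$genes)) read_gene_annotation(config$genes)
    else NULL

  # --- chromatin landscape stage ------------------------------------------
  if (!is.null(config$marks) && !is.null(genes)) {
    st <- try({
      hw <- params$promoter_halfwidth
      env$marks <- lapply(config$marks, function(mk) lapply(mk, function(cc)
        list(peaks = read_bed(cc$peaks),
             track = read_bedgraph(cc$track, genome,
                                   bin_size = cc$track_bin %||%
                                     genome$bin_size))))
      dyn_rows <- lapply(names(env$marks), function(m) {
        dyn <- classify_peak_dynamics(env$marks[[m]]$c1$peaks,
                                      env$marks[[m]]$c2$peaks)
        data.frame(mark = m, t(dyn$counts))
      })
      emit(do.call(rbind, dyn_rows), "peak_dynamics.tsv")
      if (all(c("K4", "K27") %in% names(env$marks))) {
        st1 <- promoter_state(env$marks$K4$c1$peaks, env$marks$K27$c1$peaks,
                              genes, hw)
        st2 <- promoter_state(env$marks$K4$c2$peaks, env$marks$K27$c2$peaks,
                              genes, hw)
        emit(data.frame(gene_id = st1$gene_id, state_c1 = st1$state,
                        state_c2 = st2$state), "promoter_states.tsv")
        env$states <- list(c1 = st1, c2 = st2)
        if (!is.null(env$diff)) {
          tab <- bivalent_transition_table(st1, st2, env$diff)
          emit(data.frame(direction = rownames(tab), tab),
               "bivalent_transitions.tsv")
        }
        if (!is.null(env$expr_lfc)) {
          cors <- lapply(c("K4", "K27"), function(m) {
            p1 <- promoter_signal(env$marks[[m]]$c1$track, genes, hw, genome)
            p2 <- promoter_signal(env$marks[[m]]$c2$track, genes, hw, genome)
            lfc <- log2((p2 + 1) / (p1 + 1))
            ct <- modification_expression_correlation(lfc, env$expr_lfc,
                                                      env$expr_sig)
            data.frame(mark = m, r = ct$r, pvalue = ct$pvalue, n = ct$n)
          })
          emit(do.call(rbind, cors), "modification_expression_cor.tsv")
        }
      }
      if ("K27ac" %in% names(env$marks)) {
        env$enh <- lapply(env$marks$K27ac, function(cc)
          define_enhancers(cc$peaks, genes, hw))
        ed <- enhancer_dynamics(env$enh$c1, env$enh$c2)
        emit(data.frame(t(unclass(ed))), "enhancer_dynamics.tsv")
        write_bed(env$enh$c1, file.path(out_dir, "enhancers_c1.bed"))
        write_bed(env$enh$c2, file.path(out_dir, "enhancers_c2.bed"))
      }
      sprintf("%d marks processed", length(env$marks))
    }, silent = TRUE)
    if (inherits(st, "try-error")) note("landscape", "failed",
                                        conditionMessage(attr(st, "condition")))
    else note("landscape", "ok", st)
  } else note("landscape", "skipped", "no marks/genes input")

  # --- ABC stage ----------------------------------------------------------
  have_hires <- !is.null(config$contacts$c1_hires) &&
    !is.null(config$contacts$c2_hires)
  if (have_hires && !is.null(env$enh) && !is.null(genes)) {
    st <- try({
      bs_hi <- config$contacts$hires_bin %||% 5000L
      cm1 <- read_contacts(config$contacts$c1_hires, genome, bs_hi)
      cm2 <- read_contacts(config$contacts$c2_hires, genome, bs_hi)
      t1 <- abc_table(genes, env$enh$c1, env$marks$K27ac$c1$track,
                      env$marks$K4$c1$track, cm1, window = params$abc_window,
                      genome = genome)
      t2 <- abc_table(genes, env$enh$c2, env$marks$K27ac$c2$track,
                      env$marks$K4$c2$track, cm2, window = params$abc_window,
                      genome = genome)
      emit(t1, "abc_c1.tsv"); emit(t2, "abc_c2.tsv")
      if (!is.null(env$expr_lfc)) {
        rows <- lapply(c("abc", "abc_p2"), function(sc) {
          ct <- try(abc_expression_correlation(t1, t2, env$expr_lfc,
                                               score = sc), silent = TRUE)
          if (inherits(ct, "try-error"))
            data.frame(score = sc, r = NA, pvalue = NA, n = NA)
          else data.frame(score = sc, r = ct$r, pvalue = ct$pvalue,
                          n = ct$n)
        })
        emit(do.call(rbind, rows), "abc_expression_cor.tsv")
      }
      sprintf("%d genes scored", nrow(t1))
    }, silent = TRUE)
    if (inherits(st, "try-error")) note("abc", "failed",
                                        conditionMessage(attr(st, "condition")))
    else note("abc", "ok", st)
  } else note("abc", "skipped", "missing contacts or enhancers")

  # --- 3D genome stage ----------------------------------------------------
  if (!is.null(config$contacts$c1) && !is.null(config$contacts$c2) &&
      !is.null(genome)) {
    st <- try({
      map1 <- read_contacts(config$contacts$c1, genome)
      map2 <- read_contacts(config$contacts$c2, genome)
      ps1 <- ps_curve(map1, params$ps_log_bins)
      ps2 <- ps_curve(map2, params$ps_log_bins)
      fc <- ps_log2fc(ps1, ps2)
      emit(cbind(ps1[, c("s_mid", "freq")],
                 freq_c2 = ps2$freq, log2fc = fc$table$log2fc),
           "ps_curves.tsv")
      emit(data.frame(crossing_bp = fc$crossings), "ps_crossings.tsv")
      ifc <- interaction_fold_changes(map1, map2)
      emit(data.frame(chrom = names(ifc$cis), log2fc = ifc$cis),
           "cis_fold_changes.tsv")
      if (!is.null(ifc$trans)) emit(ifc$trans, "trans_fold_changes.tsv")
      oe1 <- lapply(map1$cis, oe_matrix)
      oe2 <- lapply(map2$cis, oe_matrix)
      pc1 <- lapply(genome$chrom_names, function(ch)
        compartment_pc1(oe1[[ch]], genome$gc[[ch]], genome$bin_size))
      pc2 <- lapply(genome$chrom_names, function(ch)
        compartment_pc1(oe2[[ch]], genome$gc[[ch]], genome$bin_size))
      names(pc1) <- names(pc2) <- genome$chrom_names
      for (cond in c("c1", "c2")) {
        tr <- if (cond == "c1") pc1 else pc2
        vals <- lapply(tr, function(x) ifelse(is.na(x$pc1), 0, x$pc1))
        write_bedgraph(signal_track(lapply(vals, abs), genome$bin_size,
                                    paste0("pc1_abs_", cond)) , genome,
                       file.path(out_dir, paste0("pc1_abs_", cond,
                                                 ".bedgraph")))
        emit(data.frame(
          chrom = rep(genome$chrom_names, genome$n_bins),
          bin = unlist(lapply(genome$n_bins, seq_len)),
          pc1 = unlist(lapply(tr, `[[`, "pc1"))),
          paste0("pc1_", cond, ".tsv"))
      }
      v1 <- unlist(lapply(pc1, `[[`, "pc1"))
      v2 <- unlist(lapply(pc2, `[[`, "pc1"))
      chg <- classify_compartment_change(v1, v2, params$classifier_t)
      emit(data.frame(chrom = rep(genome$chrom_names, genome$n_bins),
                      bin = unlist(lapply(genome$n_bins, seq_len)),
                      category = as.character(chg$category)),
           "compartment_changes.tsv")
      emit(data.frame(category = names(chg$fractions),
                      fraction = as.numeric(chg$fractions)),
           "compartment_fractions.tsv")
      sdl1 <- saddle(oe1, lapply(pc1, `[[`, "pc1"), params$saddle_bins,
                     params$saddle_trim)
      sdl2 <- saddle(oe2, lapply(pc2, `[[`, "pc1"), params$saddle_bins,
                     params$saddle_trim)
      emit(data.frame(condition = c("c1", "c2"),
                      rbind(sdl1$corners, sdl2$corners),
                      strength = c(sdl1$strength, sdl2$strength)),
           "saddle_corners.tsv")
      ins_rows <- list(); bnd_rows <- list()
      for (ch in genome$chrom_names) {
        w <- min(params$insulation_window,
                 (genome$n_bins[[ch]] - 1L) %/% 2L)
        i1 <- insulation(map1$cis[[ch]], w)
        i2 <- insulation(map2$cis[[ch]], w)
        b1 <- boundaries_and_domains(i1, bin_size = genome$bin_size)
        b2 <- boundaries_and_domains(i2, bin_size = genome$bin_size)
        ins_rows[[ch]] <- data.frame(chrom = ch,
                                     bin = seq_along(i1$score),
                                     score_c1 = i1$score,
                                     score_c2 = i2$score)
        cmp <- try(compare_boundary_insulation(i1, i2, b1$boundaries,
                                               b2$boundaries),
                   silent = TRUE)
        if (!inherits(cmp, "try-error"))
          bnd_rows[[ch]] <- data.frame(chrom = ch, cmp$table)
      }
      emit(do.call(rbind, ins_rows), "insulation.tsv")
      if (length(bnd_rows))
        emit(do.call(rbind, bnd_rows), "boundary_insulation.tsv")
      if (!is.null(env$marks) && "K27ac" %in% names(env$marks)) {
        lfc_bins <- track_log2fc(env$marks$K27ac$c1$track,
                                 env$marks$K27ac$c2$track, genome,
                                 genome$bin_size)
        emit(signal_change_by_category(chg, unlist(lfc_bins)),
             "k27ac_change_by_compartment.tsv")
      }
      if (length(genome$chrom_names) >= 2) {
        top <- top_trans_regions(map1, map2, genome$chrom_names[1],
                                 genome$chrom_names[2],
                                 coarse_bp = config$contacts$coarse_bp %||%
                                   2e6)
        emit(top, "top_trans_regions.tsv")
      }
      "3D analytics complete"
    }, silent = TRUE)
    if (inherits(st, "try-error")) note("genome3d", "failed",
                                        conditionMessage(attr(st, "condition")))
    else note("genome3d", "ok", st)
  } else note("genome3d", "skipped", "no contacts input")

  stages <- do.call(rbind, stages)
  files <- sort(setdiff(list.files(out_dir, full.names = TRUE),
                        file.path(out_dir, "report.json")))
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  report <- list(stages = stages, manifest = manifest, params = params)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report
}

#' Generate a self-contained synthetic demo dataset and config
#'
#' Writes expression counts with planted differential genes, pathway gene
#' sets, gene annotations, three histone marks (peaks + tracks) with
#' planted promoter states and enhancer dynamics, compartment-resolution
#' and high-resolution contact maps with planted checkerboard compartments
#' that partially flip between conditions, a GC track, the planted truth
#' as JSON, and a ready-to-run pipeline config.
#'
#' @param out_dir output directory (created if needed).
#' @param seed master integer seed; one sub-seed per modality is derived
#'   from it.
#' @return The config list (invisibly written to `config.yaml`).
#' @export
make_demo <- function(out_dir, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  seeds <- list(genome = seed * 13L + 1L, expr = seed * 13L + 2L,
                marks = seed * 13L + 3L, contacts = seed * 13L + 4L,
                hires = seed * 13L + 5L)
  n_chrom <- 2L; chrom_len <- 2e6; bin25 <- 25000L; bin5 <- 5000L
  # compartments: alternating 8-bin blocks at 25 kb, 15% of blocks flip
  gm0 <- genome_model(paste0("chr", 1:n_chrom), rep(chrom_len, n_chrom),
                      bin25)
  labs1 <- checkerboard_labels(gm0, block_bins = 8L)
  fl <- flip_labels(labs1, block_bins = 8L, flip_fraction = 0.15,
                    seed = seeds$contacts)
  genome <- make_genome(n_chrom, chrom_len, bin25, seed = seeds$genome,
                        compartment_labels = labs1)
  data.table::fwrite(data.frame(chrom = genome$chrom_names,
                                length = unname(genome$chrom_lengths)),
                     p("genome.tsv"), sep = "\t")
  write_bedgraph(signal_track(genome$gc, bin25, "gc"), genome,
                 p("gc.bedgraph"))
  # genes: evenly spaced TSS, alternating strand
  set.seed(seeds$genome + 1L)
  n_per <- 120L
  genes <- gene_annotation(
    gene_id = sprintf("gene_%04d", seq_len(n_chrom * n_per)),
    chrom = rep(genome$chrom_names, each = n_per),
    strand = rep_len(c("+", "-"), n_chrom * n_per),
    tss = rep(round(seq(2e4, chrom_len - 2e4, length.out = n_per)),
              n_chrom))
  write_gene_annotation(genes, p("genes.tsv"))
  # expression: planted DE genes are real gene ids
  sim_e <- simulate_expression(n_genes = nrow(genes), n_de = 40L, lfc = 2,
                               seed = seeds$expr)
  rownames(sim_e$counts) <- genes$gene_id
  sim_e$truth$gene_id <- genes$gene_id[seq_len(nrow(sim_e$truth))]
  write_expression(sim_e$counts, p("counts.tsv"))
  data.table::fwrite(data.frame(sample = names(sim_e$design),
                                condition = unname(sim_e$design)),
                     p("design.tsv"), sep = "\t")
  # pathways: random gene sets
  set.seed(seeds$expr + 1L)
  db <- lapply(seq_len(20L), function(k)
    sample(genes$gene_id, sample(8:25, 1)))
  names(db) <- sprintf("pathway_%02d", seq_along(db))
  class(db) <- c("pathway_db", "list")
  write_gmt(db, p("pathways.gmt"))
  # marks
  sim_m <- simulate_marks(genome, genes, snr = 20, seed = seeds$marks)
  mark_cfg <- list()
  for (m in names(sim_m$data)) {
    for (cond in c("c1", "c2")) {
      bed <- p(sprintf("%s_%s.bed", m, cond))
      bg <- p(sprintf("%s_%s.bedgraph", m, cond))
      write_bed(sim_m$data[[m]][[cond]]$peaks, bed)
      write_bedgraph(sim_m$data[[m]][[cond]]$track, genome, bg)
      mark_cfg[[m]][[cond]] <- list(peaks = bed, track = bg,
                                    track_bin = sim_m$data[[m]][[cond]]$track$bin_size)
    }
  }
  # contacts at compartment resolution (with planted trans enrichment)
  trans_spec <- data.frame(chromA = "chr1", binA_lo = 10L, binA_hi = 20L,
                           chromB = "chr2", binB_lo = 30L, binB_hi = 40L,
                           fold = 6)
  sim_c <- simulate_contacts(genome, labs1, fl$labels, decay_exponent = -1,
                             delta = 1, total_reads = 6e5,
                             trans_fraction = 0.15, trans_spec = trans_spec,
                             seed = seeds$contacts)
  write_contacts(sim_c$maps$c1, p("contacts_c1_25kb.txt"))
  write_contacts(sim_c$maps$c2, p("contacts_c2_25kb.txt"))
  # high-resolution cis maps for ABC scoring
  gm5 <- genome_model(genome$chrom_names, rep(chrom_len, n_chrom), bin5)
  expand <- function(labs) lapply(labs, function(v)
    rep(v, each = bin25 / bin5)[seq_len(chrom_len / bin5)])
  sim_h <- simulate_contacts(gm5, expand(labs1), expand(fl$labels),
                             decay_exponent = -1, delta = 1,
                             total_reads = 1.2e6, trans_fraction = 0,
                             seed = seeds$hires)
  write_contacts(sim_h$maps$c1, p("contacts_c1_5kb.txt"))
  write_contacts(sim_h$maps$c2, p("contacts_c2_5kb.txt"))
  truth <- list(seed = seed,
                de_genes = sim_e$truth,
                promoter_states = sim_m$truth$states,
                enhancers = sim_m$truth$enhancers,
                compartments = list(labels_c1 = labs1,
                                    labels_c2 = fl$labels,
                                    flipped = fl$flipped),
                decay_exponent = -1, trans_spec = trans_spec)
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  config <- list(
    genome = list(chroms_tsv = p("genome.tsv"), bin_size = bin25,
                  gc_bedgraph = p("gc.bedgraph")),
    expression = list(counts = p("counts.tsv"), design = p("design.tsv"),
                      gmt = p("pathways.gmt")),
    genes = p("genes.tsv"),
    marks = mark_cfg,
    contacts = list(c1 = p("contacts_c1_25kb.txt"),
                    c2 = p("contacts_c2_25kb.txt"),
                    c1_hires = p("contacts_c1_5kb.txt"),
                    c2_hires = p("contacts_c2_5kb.txt"),
                    hires_bin = bin5, coarse_bp = 2e5),
    params = default_params(),
    out = p("out"))
  yaml::write_yaml(config, p("config.yaml"))
  invisible(config)
}
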