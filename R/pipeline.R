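#' Full run configuration
#'
#' All stage parameters with their study defaults: a 16-row x 24-column x
#' `n_plates` 3D pool design, ~98 kb HindIII inserts, 1.36 kb/CB
#' physical-map calibration, 3.4 cM/Mb, 2 x 250 bp paired reads from
#' 475 bp fragments at 130x per BAC, 24x corrected long reads, long-read
#' mining thresholds 0.2/0.9, validation thresholds 0.95/0.95, co-assembly
#' merge at 99% identity / 20 bp, association alpha 0.05. The genome size
#' defaults to a 0.5 Mb desk-scale region.
#'
#' @param genome A [sim_config()] for the synthetic region.
#' @param clone_coverage Clone-library coverage fold of the region.
#' @param insert_window Size-selection window (bp).
#' @param partial_prob Partial-digest per-site cut probability.
#' @param fp_site,fp_tolerance_bp Fingerprinting motif and band tolerance.
#' @param min_shared_bands FPC join threshold.
#' @param kb_per_cb Physical-map calibration (kb per consensus band).
#' @param short_coverage,long_coverage Read coverages (x).
#' @param read_len,frag_mean,frag_sd Short-read geometry (bp).
#' @param short_err,long_err Substitution error rates.
#' @param fn_rate,fp_rate Pool-screen flip rates.
#' @param map_len_frac,map_sim Long-read mining thresholds.
#' @param val_len_frac,val_sim Validation mapping thresholds.
#' @param merge_identity,merge_min_overlap Co-assembly thresholds.
#' @param bes_len_mean Mean BAC-end read length (bp).
#' @param bes_fail_rate Per-end sequencing failure rate.
#' @param n_families,n_offspring Association cross structure.
#' @param alpha Association significance level.
#' @param stages Character vector of stages to run, a subset of
#'   `c("genome", "library", "pools", "reads", "assemble", "hybrid",
#'   "downstream")` in that order.
#' @return A list of class `run_config`.
#' @export
run_config <- function(genome = sim_config(genome_len = 5e5),
                       clone_coverage = 6, insert_window = c(80000, 120000),
                       partial_prob = 0.03, fp_site = "GACGT",
                       fp_tolerance_bp = 3, min_shared_bands = 10,
                       kb_per_cb = 1.36,
                       short_coverage = 130, long_coverage = 24,
                       read_len = 250, frag_mean = 475, frag_sd = 60,
                       short_err = 0.002, long_err = 0.01,
                       fn_rate = 0, fp_rate = 0,
                       map_len_frac = 0.2, map_sim = 0.9,
                       val_len_frac = 0.95, val_sim = 0.95,
                       merge_identity = 0.99, merge_min_overlap = 20,
                       bes_len_mean = 854, bes_fail_rate = 0.028,
                       n_families = 5, n_offspring = 570, alpha = 0.05,
                       stages = c("genome", "library", "pools", "reads",
                                  "assemble", "hybrid", "downstream")) {
  structure(as.list(environment()), class = "run_config")
}

stage_order <- c("genome", "library", "pools", "reads", "assemble",
                 "hybrid", "downstream")

need_stage <- function(run_dir, stage, needed_by) {
  f <- file.path(run_dir, stage, "stage.rds.tsv")
  if (!file.exists(file.path(run_dir, stage))) {
    stop("dependency error: stage '", needed_by, "' requires stage '",
         stage, "' outputs under ", run_dir)
  }
  invisible(TRUE)
}

write_tsv <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the seven-step workflow end to end
#'
#' Orchestrates the full simulation-backed pipeline: (1) synthetic genome
#' with markers, genes and SNPs; (2) clone library, fingerprinting, FPC
#' contigs and MTP selection; (3) 3D pool construction, marker screening
#' and deconvolution; (4) paired-end short reads per MTP pool, BAC-end
#' sequences, and long reads; (5) per-pool trimming, normalization and
#' greedy assembly; (6) hybrid scaffolding, read-back validation with
#' zero-coverage splitting, and marker/BES anchoring; (7) microsynteny
#' detection and SNP-trait association. Stage outputs are written as
#' FASTA/FASTQ/TSV under `out_dir/<stage>/`, with a JSON manifest (stage
#' parameters, derived seeds, file md5 hashes). Any stage can be re-run
#' from its predecessors' files; a stage whose prerequisite directory is
#' missing raises a dependency error naming the stage.
#'
#' @param config A [run_config()].
#' @param out_dir Run directory (created).
#' @param seed Global integer seed; per-stage seeds derive from it via
#'   [stage_seed()].
#' @return Invisibly, a list with the in-memory stage objects and the
#'   manifest path.
#' @export
run_pipeline <- function(config = run_config(), out_dir, seed = 1) {
  stopifnot(inherits(config, "run_config"))
  stages <- intersect(stage_order, config$stages)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  state <- list()
  manifest <- list(seed = seed, stages = list())
  t_start <- Sys.time()
  log_path <- file.path(out_dir, "run.log")
  logln <- function(...) cat(sprintf(...), "\n", sep = "",
                             file = log_path, append = TRUE)
  cat("", file = log_path)

  add_stage <- function(stage, params, files) {
    manifest$stages[[stage]] <<- list(
      params = params,
      seed = stage_seed(seed, if (stage %in% names(c(
        genome = 1, library = 1, pools = 1, reads = 1, assemble = 1,
        hybrid = 1, downstream = 1))) switch(stage,
        genome = "genome", library = "library", pools = "pools",
        reads = "reads", assemble = "assembly", hybrid = "long_reads",
        downstream = "cross") else stage),
      files = as.list(tools::md5sum(files)))
    logln("[%s] done (%.1f s): %d files", stage,
          as.numeric(difftime(Sys.time(), t_start, units = "secs")),
          length(files))
  }

  # --- (1) genome ---------------------------------------------------------
  if ("genome" %in% stages) {
    gdir <- file.path(out_dir, "genome")
    gt <- generate_genome(config$genome, stage_seed(seed, "genome"))
    files <- write_genome_truth(gt, gdir)
    state$genome <- gt
    add_stage("genome", config$genome[c("genome_len", "at_frac", "repeat_frac",
                                        "n_markers", "n_genes", "n_snps")],
              files)
  }

  # --- (2) library / physical map ----------------------------------------
  if ("library" %in% stages) {
    if (is.null(state$genome)) need_stage(out_dir, "genome", "library")
    gt <- state$genome
    ldir <- file.path(out_dir, "library")
    dir.create(ldir, showWarnings = FALSE)
    n_clones <- round(config$clone_coverage * gt$length_bp /
                        (mean(config$insert_window)))
    clones <- digest_and_clone(gt, partial_prob = config$partial_prob,
                               size_window = config$insert_window,
                               n_clones = n_clones,
                               seed = stage_seed(seed, "library"))
    fps <- fingerprint_library(clones, gt, site = config$fp_site,
                               tolerance_bp = config$fp_tolerance_bp)
    contigs <- build_fpc_contigs(fps, clones,
                                 min_shared_bands = config$min_shared_bands)
    mtps <- lapply(contigs, select_mtp, clones = clones,
                   kb_per_cb = config$kb_per_cb)
    ctab <- do.call(rbind, lapply(contigs, function(ct) data.frame(
      contig_id = ct$contig_id, n_clones = length(ct$clone_ids),
      cb_units = ct$cb_units, span_start = ct$true_span[1],
      span_end = ct$true_span[2], is_singleton = ct$is_singleton)))
    mtab <- do.call(rbind, lapply(mtps, function(tp) data.frame(
      contig_id = tp$contig_id, n_mtp = length(tp$clone_ids),
      clone_ids = paste(tp$clone_ids, collapse = ","),
      expected_size_kb = round(tp$expected_size_kb, 1))))
    fptab <- do.call(rbind, lapply(fps, function(f) data.frame(
      clone_id = f$clone_id, band = f$bands)))
    files <- file.path(ldir, c("clones.tsv", "fingerprints.tsv",
                               "fpc_contigs.tsv", "tiling_paths.tsv"))
    write_tsv(as.data.frame(clones), files[1]); write_tsv(fptab, files[2])
    write_tsv(ctab, files[3]); write_tsv(mtab, files[4])
    state$clones <- clones; state$contigs <- contigs; state$mtps <- mtps
    add_stage("library", list(n_clones = n_clones,
                              clone_coverage = config$clone_coverage), files)
  }

  # --- (3) 3D pools + screening ------------------------------------------
  if ("pools" %in% stages) {
    if (is.null(state$clones)) need_stage(out_dir, "library", "pools")
    gt <- state$genome; clones <- state$clones
    pdir <- file.path(out_dir, "pools")
    dir.create(pdir, showWarnings = FALSE)
    design <- pool_design(n_plates = max(clones$plate), n_rows = 16,
                          n_cols = 24)
    pools <- build_pools(clones, design)
    sseed <- stage_seed(seed, "screen")
    screens <- list(); dec_rows <- list()
    for (i in seq_len(nrow(gt$markers))) {
      m <- gt$markers[i, ]
      sr <- screen_marker(m, pools, fn_rate = config$fn_rate,
                          fp_rate = config$fp_rate, seed = sseed + i)
      hits <- screen_and_resolve(sr, pools, m)
      screens[[i]] <- data.frame(
        marker_id = m$marker_id,
        n_positive_pools = length(sr$positive_plates) +
          length(sr$positive_rows) + length(sr$positive_cols),
        positive_clones = paste(hits, collapse = ","),
        n_positive_clones = length(hits))
    }
    stab <- do.call(rbind, screens)
    files <- file.path(pdir, c("pool_membership.tsv", "screen_results.tsv"))
    write_tsv(pools$membership, files[1]); write_tsv(stab, files[2])
    state$pools <- pools; state$screen <- stab
    add_stage("pools", list(n_plates = design$n_plates, n_rows = 16,
                            n_cols = 24, fn_rate = config$fn_rate,
                            fp_rate = config$fp_rate), files)
  }

  # --- (4) read simulation (per MTP pool) + BES + long reads -------------
  if ("reads" %in% stages) {
    if (is.null(state$mtps)) need_stage(out_dir, "library", "reads")
    if (is.null(state$screen)) need_stage(out_dir, "pools", "reads")
    gt <- state$genome; clones <- state$clones
    rdir <- file.path(out_dir, "reads")
    dir.create(rdir, showWarnings = FALSE)
    # sequenced pools = MTPs of contigs hit by at least one marker
    hit_clones <- unique(unlist(strsplit(
      state$screen$positive_clones[state$screen$n_positive_clones > 0], ",")))
    hit_ctgs <- vapply(state$contigs, function(ct)
      any(ct$clone_ids %in% hit_clones), logical(1))
    sel <- which(hit_ctgs)
    rseed <- stage_seed(seed, "reads")
    files <- character(0)
    pool_reads <- list()
    for (k in sel) {
      tp <- state$mtps[[k]]
      ins <- clone_inserts(clones[match(tp$clone_ids, clones$clone_id), ], gt)
      rs <- simulate_short_reads(ins, coverage_x = config$short_coverage,
                                 read_len = config$read_len,
                                 frag_mean = config$frag_mean,
                                 frag_sd = config$frag_sd,
                                 err_rate = config$short_err,
                                 seed = rseed + k)
      f <- file.path(rdir, paste0(tp$contig_id, "_short.fastq"))
      write_fastq(rs, f)
      files <- c(files, f)
      pool_reads[[tp$contig_id]] <- rs
    }
    # BAC-end sequences for every selected MTP clone
    set.seed(stage_seed(seed, "bes"))
    sel_clones <- clones[clones$clone_id %in% unlist(
      lapply(state$mtps[sel], `[[`, "clone_ids")), ]
    bes <- list()
    for (i in seq_len(nrow(sel_clones))) {
      cl <- sel_clones[i, ]
      for (end in c("T7", "SP6")) {
        if (runif(1) < config$bes_fail_rate) next
        blen <- min(round(rnorm(1, config$bes_len_mean, 80)), cl$insert_len_bp)
        s <- if (end == "T7") {
          substr(gt$seq, cl$start + 1, cl$start + blen)
        } else {
          as.character(revcomp_chr(substr(gt$seq, cl$end - blen + 1, cl$end)))
        }
        bes[[length(bes) + 1]] <- data.frame(
          id = paste0(cl$clone_id, "_", end), clone_id = cl$clone_id,
          end = end, seq = s)
      }
    }
    bes <- do.call(rbind, bes)
    lr <- simulate_long_reads(gt$seq, coverage_x = config$long_coverage,
                              err_rate = config$long_err,
                              seed = stage_seed(seed, "long_reads"))
    f_bes <- file.path(rdir, "bes.tsv")
    f_lr <- file.path(rdir, "long_reads.fastq")
    write_tsv(bes, f_bes)
    write_fastq(lr, f_lr)
    files <- c(files, f_bes, f_lr)
    state$pool_reads <- pool_reads; state$bes <- bes; state$long_reads <- lr
    state$sequenced_pools <- sel
    add_stage("reads", list(short_coverage = config$short_coverage,
                            long_coverage = config$long_coverage,
                            n_pools = length(sel)), files)
  }

  # --- (5) per-pool assembly ---------------------------------------------
  if ("assemble" %in% stages) {
    if (is.null(state$pool_reads)) need_stage(out_dir, "reads", "assemble")
    adir <- file.path(out_dir, "assemble")
    dir.create(adir, showWarnings = FALSE)
    files <- character(0)
    assemblies <- list()
    trimmed <- list()
    for (pool in names(state$pool_reads)) {
      rs <- trim_reads(state$pool_reads[[pool]])
      rs <- kmer_normalize(rs)
      a <- greedy_assemble(rs)
      a$contig_id <- paste0(pool, "_", a$contig_id)
      f <- file.path(adir, paste0(pool, "_contigs.fasta"))
      Biostrings::writeXStringSet(
        Biostrings::DNAStringSet(setNames(a$sequence, a$contig_id)), f)
      files <- c(files, f)
      assemblies[[pool]] <- a
      trimmed[[pool]] <- rs
    }
    state$assemblies <- assemblies
    state$trimmed_reads <- trimmed
    add_stage("assemble", list(min_overlap = 40, min_identity = 0.97), files)
  }

  # --- (6) hybrid scaffolding + validation + anchoring -------------------
  if ("hybrid" %in% stages) {
    if (is.null(state$assemblies)) need_stage(out_dir, "assemble", "hybrid")
    gt <- state$genome
    hdir <- file.path(out_dir, "hybrid")
    dir.create(hdir, showWarnings = FALSE)
    files <- character(0)
    hybrids <- list()
    report_rows <- list()
    queries <- rbind(
      data.frame(id = gt$markers$marker_id, seq = gt$markers$amplicon,
                 type = "marker"),
      data.frame(id = state$bes$id, seq = state$bes$seq, type = "BES"))
    anchor_rows <- list()
    for (pool in names(state$assemblies)) {
      a <- state$assemblies[[pool]]
      hy <- hybrid_scaffold(a, state$long_reads,
                            map_len_frac = config$map_len_frac,
                            map_sim = config$map_sim,
                            merge_identity = config$merge_identity,
                            merge_min_overlap = config$merge_min_overlap)
      val <- validate_and_split(hy, list(state$trimmed_reads[[pool]],
                                         state$long_reads),
                                map_len_frac = config$val_len_frac,
                                map_sim = config$val_sim)
      val$contig_id <- paste0(pool, "_", val$contig_id)
      f <- file.path(hdir, paste0(pool, "_scaffolds.fasta"))
      Biostrings::writeXStringSet(
        Biostrings::DNAStringSet(setNames(val$sequence, val$contig_id)), f)
      files <- c(files, f)
      hybrids[[pool]] <- val
      st_m <- pool_assembly_stats(a); st_h <- pool_assembly_stats(val)
      report_rows[[pool]] <- data.frame(
        pool = pool, n_scaffolds_miseq = st_m[["n"]], kb_miseq = st_m[["kb"]],
        n_scaffolds_hybrid = st_h[["n"]], kb_hybrid = st_h[["kb"]])
      anchor_rows[[pool]] <- cbind(pool = pool,
                                   anchor_sequences(val, queries))
    }
    report <- assembly_report(do.call(rbind, report_rows))
    anchors <- do.call(rbind, anchor_rows)
    f_rep <- file.path(hdir, "assembly_report.tsv")
    f_anc <- file.path(hdir, "anchors.tsv")
    write_tsv(report, f_rep); write_tsv(anchors, f_anc)
    files <- c(files, f_rep, f_anc)
    state$hybrids <- hybrids; state$report <- report; state$anchors <- anchors
    add_stage("hybrid", list(map_len_frac = config$map_len_frac,
                             map_sim = config$map_sim,
                             val = c(config$val_len_frac, config$val_sim)),
              files)
  }

  # --- (7) synteny + association -----------------------------------------
  if ("downstream" %in% stages) {
    if (is.null(state$hybrids)) need_stage(out_dir, "hybrid", "downstream")
    gt <- state$genome
    ddir <- file.path(out_dir, "downstream")
    dir.create(ddir, showWarnings = FALSE)
    hom <- simulate_homology_table(
      n_contigs = max(4, length(state$sequenced_pools)),
      seed = stage_seed(seed, "synteny"))
    blocks <- detect_microsynteny(hom, unique(hom$species)[1], min_genes = 3)
    bsum <- block_span_summary(blocks)
    cross <- simulate_cross(n_families = config$n_families,
                            n_offspring = config$n_offspring,
                            snps = gt$snps,
                            seed = stage_seed(seed, "cross"))
    assoc <- association_report(cross$genotypes, cross$traits,
                                alpha = config$alpha)
    files <- file.path(ddir, c("homology_table.tsv", "synteny_blocks.tsv",
                               "synteny_summary.tsv", "genotypes.tsv",
                               "traits.tsv", "association_report.tsv"))
    write_tsv(hom, files[1]); write_tsv(as.data.frame(blocks), files[2])
    write_tsv(bsum, files[3]); write_tsv(cross$genotypes, files[4])
    write_tsv(cross$traits, files[5]); write_tsv(assoc$table, files[6])
    state$synteny <- list(table = hom, blocks = blocks, summary = bsum)
    state$association <- assoc
    add_stage("downstream", list(alpha = config$alpha,
                                 n_tests = assoc$n_tests), files)
  }

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  logln("pipeline complete (%.1f s)",
        as.numeric(difftime(Sys.time(), t_start, units = "secs")))
  invisible(c(state, list(manifest = manifest_path)))
}

#' Summary arithmetic over stage outputs
#'
#' Recomputes the headline run metrics from raw counts, each with the
#' report's formatting rules (coverage folds, kb and percentages to 1
#' decimal; final assembly span in Mb to 2 decimals). Every metric is a
#' pure function of its inputs; `NULL` inputs drop the corresponding
#' metrics from the output.
#'
#' @param n_reads,mean_read_len_bp Short-read totals across pools.
#' @param n_bacs Number of sequenced BAC clones.
#' @param insert_len_kb Mean insert length (kb).
#' @param bes_pass Number of BAC ends passing QC (out of `2 * n_bacs`).
#' @param bes_both_ends Number of clones with both ends passing.
#' @param n_positive_clones,n_markers Screen outcome totals.
#' @param cb_units Total physical-map size of the tiling paths (CB units).
#' @param kb_per_cb Calibration, kb per CB.
#' @param lg_mb Stated size of the whole linkage group (Mb).
#' @param genome_mb Haploid genome size (Mb).
#' @param n_genes_annotated,n_genes_total Annotation outcome.
#' @param scaffold_table Per-pool table as in [assembly_report()] (without
#'   a Total row).
#' @return Named list of metrics.
#' @export
#' @examples
#' summary_metrics(n_reads = 3.8e6, mean_read_len_bp = 241.9, n_bacs = 72,
#'                 insert_len_kb = 98)$per_bac_coverage_x # 130.3
summary_metrics <- function(n_reads = NULL, mean_read_len_bp = NULL,
                            n_bacs = NULL, insert_len_kb = 98,
                            bes_pass = NULL, bes_both_ends = NULL,
                            n_positive_clones = NULL, n_markers = NULL,
                            cb_units = NULL, kb_per_cb = 1.36,
                            lg_mb = NULL, genome_mb = 700,
                            n_genes_annotated = NULL, n_genes_total = NULL,
                            scaffold_table = NULL) {
  out <- list()
  if (!is.null(n_bacs) && n_bacs == 0) {
    return(list(per_bac_coverage_x = 0, bes_success_pct = 0,
                mate_pair_success_pct = 0))
  }
  if (!is.null(n_reads) && !is.null(mean_read_len_bp) && !is.null(n_bacs)) {
    out$per_bac_coverage_x <- round(
      n_reads * mean_read_len_bp / (n_bacs * insert_len_kb * 1000), 1)
  }
  if (!is.null(bes_pass) && !is.null(n_bacs)) {
    out$bes_success_pct <- round(100 * bes_pass / (2 * n_bacs), 1)
  }
  if (!is.null(bes_both_ends) && !is.null(n_bacs)) {
    out$mate_pair_success_pct <- round(100 * bes_both_ends / n_bacs, 1)
  }
  if (!is.null(n_positive_clones) && !is.null(n_markers)) {
    out$mean_positives_per_marker <- round(n_positive_clones / n_markers, 1)
  }
  if (!is.null(cb_units)) {
    span_kb <- cb_to_kb(cb_units, kb_per_cb)
    out$tiling_span_kb <- round(span_kb, 1)
    out$tiling_span_mb <- round(span_kb / 1000, 1)
    # report convention: percentages are taken on the 1-decimal Mb span
    if (!is.null(lg_mb)) {
      out$pct_of_lg <- round(100 * out$tiling_span_mb / lg_mb, 1)
    }
    out$pct_of_genome <- round(100 * out$tiling_span_mb / genome_mb, 1)
  }
  if (!is.null(n_genes_annotated) && !is.null(n_genes_total)) {
    out$annotation_rate_pct <- round(100 * n_genes_annotated / n_genes_total, 1)
  }
  if (!is.null(scaffold_table)) {
    out$total_scaffolds_miseq <- sum(scaffold_table$n_scaffolds_miseq)
    out$total_scaffolds_hybrid <- sum(scaffold_table$n_scaffolds_hybrid)
    out$total_mb_miseq <- round(sum(scaffold_table$kb_miseq) / 1000, 2)
    out$total_mb_hybrid <- round(sum(scaffold_table$kb_hybrid) / 1000, 2)
  }
  out
}

#' Load the bundled per-marker accounting table
#'
#' The printed per-marker/per-pool accounting of the emulated study
#' (marker, genetic position, positive clone count, FPC contig, MTP size,
#' expected kb, and scaffold counts/sizes for the short-read-only and
#' hybrid assemblies), shipped as plain TSV. Column totals are meant to be
#' recomputed, not read.
#'
#' @return A data frame with one row per marker/pool.
#' @export
lg2_marker_table <- function() {
  read.delim(system.file("extdata", "lg2_marker_table.tsv",
                         package = "bacpool"), stringsAsFactors = FALSE)
}
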