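#' Simulation configuration for the synthetic target region
#'
#' Bundles the generative parameters for the ground-truthed genome segment
#' that every downstream stage consumes. Defaults describe the sequenced
#' target the package emulates: an AT-rich (59.4%) euchromatic region with
#' ~5.6% interspersed repeats, ~20 SSR marker loci on one linkage group at
#' a recombination rate of 3.4 cM/Mb, protein-coding genes at ~26 per Mb,
#' and a handful of bi-allelic trait-affecting SNPs inside candidate genes.
#'
#' @param genome_len Genome length in bp.
#' @param at_frac Target AT fraction of the sequence.
#' @param repeat_frac Target fraction of the genome covered by interspersed
#'   repeats; must be in `[0, 1)`.
#' @param n_repeat_families Number of repeat families; copies of a family
#'   diverge from the family consensus by 1--5% substitutions.
#' @param repeat_len_range Length range (bp) of a repeat family consensus.
#' @param n_markers Number of SSR marker loci.
#' @param amplicon_len Length (bp) of each marker's unique PCR template.
#' @param n_genes Number of genes; scaled with genome length if `NULL`
#'   (26 per Mb).
#' @param gene_len_range Gene length range (bp).
#' @param n_snp_genes Number of candidate genes carrying trait SNPs.
#' @param n_snps Total number of bi-allelic SNPs across candidate genes.
#' @param rate_cm_per_mb Linkage-map recombination rate (cM per Mb).
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(genome_len = 2e5)
#' cfg$at_frac
sim_config <- function(genome_len = 1e6, at_frac = 0.594, repeat_frac = 0.056,
                       n_repeat_families = 5, repeat_len_range = c(300, 1500),
                       n_markers = 20, amplicon_len = 300,
                       n_genes = NULL, gene_len_range = c(2000, 8000),
                       n_snp_genes = 3, n_snps = 13,
                       rate_cm_per_mb = 3.4) {
  if (genome_len < 1) stop("genome_len must be positive")
  if (repeat_frac < 0 || repeat_frac >= 1) stop("repeat_frac must be in [0, 1)")
  if (at_frac <= 0 || at_frac >= 1) stop("at_frac must be in (0, 1)")
  if (is.null(n_genes)) n_genes <- round(26 * genome_len / 1e6)
  structure(list(
    genome_len = as.integer(genome_len), at_frac = at_frac,
    repeat_frac = repeat_frac, n_repeat_families = n_repeat_families,
    repeat_len_range = repeat_len_range, n_markers = n_markers,
    amplicon_len = amplicon_len, n_genes = n_genes,
    gene_len_range = gene_len_range, n_snp_genes = n_snp_genes,
    n_snps = n_snps, rate_cm_per_mb = rate_cm_per_mb
  ), class = "sim_config")
}

#' Generate a ground-truthed genome segment
#'
#' Builds a random nucleotide sequence honoring the configured AT fraction,
#' plants interspersed repeat copies (per-copy 1--5% divergence from a
#' family consensus) to the configured repeat fraction, places
#' non-overlapping genes, selects SSR marker loci whose amplicon templates
#' are unique in the genome (rejection sampling), and places bi-allelic
#' SNPs with additive trait effects inside candidate genes. All coordinates
#' are 0-based half-open. Identical `config` + `seed` reproduce the genome
#' byte-for-byte.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A list of class `genome_truth` with elements `seq` (character),
#'   `length_bp`, `repeats`, `markers`, `genes`, `snps` (data frames),
#'   `rate_cm_per_mb` and `seed`.
#' @export
#' @examples
#' gt <- generate_genome(sim_config(genome_len = 5e4, n_markers = 3), seed = 1)
#' nchar(gt$seq)
generate_genome <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  L <- config$genome_len

  # feasibility of the packing before any sampling
  rep_target <- round(config$repeat_frac * L)
  gene_total <- config$n_genes * mean(config$gene_len_range)
  if (rep_target + gene_total > 0.9 * L) {
    stop("configuration error: repeats + genes exceed genome capacity")
  }

  base <- rand_dna(L, config$at_frac)

  # --- repeats: family consensi, then diverged copies at random positions
  repeats <- data.frame(start = integer(0), end = integer(0),
                        family_id = character(0))
  occupied <- logical(L) # repeat-occupied bases (genes placed later avoid them)
  if (config$repeat_frac > 0 && config$n_repeat_families > 0) {
    fam_len <- sample(seq(config$repeat_len_range[1], config$repeat_len_range[2]),
                      config$n_repeat_families, replace = TRUE)
    fam_seq <- vapply(fam_len, rand_dna, character(1), at_frac = config$at_frac)
    placed <- 0
    guard <- 0
    segs <- list()
    while (placed < rep_target && guard < 50 * config$n_repeat_families) {
      guard <- guard + 1
      f <- sample.int(config$n_repeat_families, 1)
      cs <- fam_seq[f]
      clen <- nchar(cs)
      s <- sample.int(L - clen, 1) - 1L # 0-based
      if (any(occupied[(s + 1):(s + clen)])) next
      div <- runif(1, 0.01, 0.05)
      copy <- .cpp_inject_substitutions(cs, div)
      if (runif(1) < 0.5) copy <- revcomp_chr(copy)
      substr(base, s + 1, s + clen) <- as.character(copy)
      occupied[(s + 1):(s + clen)] <- TRUE
      segs[[length(segs) + 1]] <- data.frame(
        start = s, end = s + clen, family_id = sprintf("fam%02d", f))
      placed <- placed + clen
    }
    if (length(segs)) repeats <- do.call(rbind, segs)
    repeats <- repeats[order(repeats$start), , drop = FALSE]
    rownames(repeats) <- NULL
  }

  # --- genes: non-overlapping, avoid repeat-occupied bases
  genes <- data.frame(gene_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0))
  if (config$n_genes > 0) {
    gene_occ <- occupied
    rows <- list()
    guard <- 0
    while (length(rows) < config$n_genes && guard < 200 * config$n_genes) {
      guard <- guard + 1
      glen <- sample(seq(config$gene_len_range[1], config$gene_len_range[2]), 1)
      if (glen >= L) next
      s <- sample.int(L - glen, 1) - 1L
      if (any(gene_occ[(s + 1):(s + glen)])) next
      gene_occ[(s + 1):(s + glen)] <- TRUE
      rows[[length(rows) + 1]] <- data.frame(
        gene_id = "", start = s, end = s + glen,
        strand = sample(c("+", "-"), 1))
    }
    if (length(rows) < config$n_genes) {
      stop("configuration error: could not place ", config$n_genes,
           " non-overlapping genes")
    }
    genes <- do.call(rbind, rows)
    genes <- genes[order(genes$start), , drop = FALSE]
    genes$gene_id <- sprintf("gene%03d", seq_len(nrow(genes)))
    rownames(genes) <- NULL
  }

  # --- SSR markers with genome-unique amplicons (rejection sampling)
  markers <- data.frame(marker_id = character(0), position_bp = integer(0),
                        position_cm = numeric(0), amplicon = character(0))
  if (config$n_markers > 0) {
    alen <- config$amplicon_len
    # spread target positions evenly, then search nearby for a unique template
    anchors <- round(seq(0.02, 0.98, length.out = config$n_markers) * (L - alen))
    gseq <- Biostrings::DNAString(base)
    pos <- integer(0)
    for (a in anchors) {
      found <- FALSE
      for (try in 0:60) {
        cand <- a + sample(seq(-2000, 2000), 1)
        cand <- max(0L, min(L - alen, as.integer(cand)))
        amp <- substr(base, cand + 1, cand + alen)
        nfwd <- Biostrings::countPattern(amp, gseq)
        nrev <- Biostrings::countPattern(as.character(revcomp_chr(amp)), gseq)
        if (nfwd == 1L && nrev == 0L) { pos <- c(pos, cand); found <- TRUE; break }
      }
      if (!found) stop("configuration error: no unique amplicon near ", a)
    }
    pos <- sort(pos)
    markers <- data.frame(
      marker_id = sprintf("ssr%03d", seq_along(pos)),
      position_bp = pos, position_cm = NA_real_,
      amplicon = substr(rep(base, length(pos)), pos + 1, pos + alen))
    markers <- assign_genetic_positions(markers, config$rate_cm_per_mb)
  }

  # --- SNPs with additive trait effects inside candidate genes
  snps <- data.frame(snp_id = character(0), gene_id = character(0),
                     position_bp = integer(0), ref_allele = character(0),
                     alt_allele = character(0), effect_bw = numeric(0),
                     effect_tl = numeric(0), effect_sl = numeric(0),
                     alt_freq = numeric(0))
  if (config$n_snps > 0 && nrow(genes) >= config$n_snp_genes) {
    cand_genes <- genes[sample.int(nrow(genes), config$n_snp_genes), , drop = FALSE]
    per_gene <- diff(round(seq(0, config$n_snps, length.out = config$n_snp_genes + 1)))
    rows <- list()
    sid <- 0
    for (gi in seq_len(nrow(cand_genes))) {
      g <- cand_genes[gi, ]
      npos <- per_gene[gi]
      if (npos == 0) next
      p <- sort(sample(seq(g$start, g$end - 1L), npos))
      for (pp in p) {
        sid <- sid + 1
        ref <- substr(base, pp + 1, pp + 1)
        alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
        # roughly half the SNPs carry a real additive effect
        has_eff <- runif(1) < 0.5
        eff <- if (has_eff) runif(1, 0.3, 1.0) else 0
        rows[[sid]] <- data.frame(
          snp_id = sprintf("snp%02d", sid), gene_id = g$gene_id,
          position_bp = pp, ref_allele = ref, alt_allele = alt,
          effect_bw = eff * 60, effect_tl = eff * 1.2, effect_sl = eff * 1.0,
          alt_freq = runif(1, 0.15, 0.5))
      }
    }
    snps <- do.call(rbind, rows)
    rownames(snps) <- NULL
  }

  structure(list(
    seq = base, length_bp = L, repeats = repeats, markers = markers,
    genes = genes, snps = snps, rate_cm_per_mb = config$rate_cm_per_mb,
    seed = seed, config = config
  ), class = "genome_truth")
}

#' @export
print.genome_truth <- function(x, ...) {
  at <- mean(strsplit(x$seq, "")[[1]] %in% c("A", "T"))
  cat(sprintf(
    "genome_truth: %s bp (AT %.1f%%), %d repeats, %d markers, %d genes, %d SNPs\n",
    format(x$length_bp, big.mark = ","), 100 * at, nrow(x$repeats),
    nrow(x$markers), nrow(x$genes), nrow(x$snps)))
  invisible(x)
}

#' Assign genetic-map positions to markers
#'
#' Converts physical positions to genetic positions with a constant
#' recombination rate: `position_cm = position_bp / 1e6 * rate_cm_per_mb`.
#' The mapping is linear, hence strictly order-preserving.
#'
#' @param markers Data frame with a `position_bp` column.
#' @param rate_cm_per_mb Recombination rate in cM per Mb (> 0).
#' @return `markers` with `position_cm` filled in.
#' @export
#' @examples
#' assign_genetic_positions(data.frame(position_bp = c(0, 5e5, 1e6)), 3.4)
assign_genetic_positions <- function(markers, rate_cm_per_mb = 3.4) {
  if (rate_cm_per_mb <= 0) stop("rate_cm_per_mb must be > 0")
  markers$position_cm <- markers$position_bp / 1e6 * rate_cm_per_mb
  markers
}

#' Write a genome truth set to disk
#'
#' Emits the genome FASTA plus TSV tables for markers, genes, repeats and
#' SNPs, and a BED file of feature intervals. TSV coordinates are 0-based
#' half-open (`start`, `end`); marker tables add `position_1based` for
#' 1-based consumers.
#'
#' @param gt A `genome_truth` object.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_genome_truth <- function(gt, dir) {
  stopifnot(inherits(gt, "genome_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dna <- Biostrings::DNAStringSet(setNames(gt$seq, "synthetic_region"))
  files <- file.path(dir, c("genome.fasta", "markers.tsv", "genes.tsv",
                            "repeats.tsv", "snps.tsv", "features.bed"))
  Biostrings::writeXStringSet(dna, files[1])
  mk <- gt$markers
  mk$position_1based <- mk$position_bp + 1L
  tsv <- function(d, f) write.table(d, f, sep = "\t", quote = FALSE,
                                    row.names = FALSE)
  tsv(mk, files[2]); tsv(gt$genes, files[3]); tsv(gt$repeats, files[4])
  tsv(gt$snps, files[5])
  bed <- rbind(
    if (nrow(gt$genes)) data.frame(chrom = "synthetic_region",
                                   start = gt$genes$start, end = gt$genes$end,
                                   name = gt$genes$gene_id),
    if (nrow(gt$repeats)) data.frame(chrom = "synthetic_region",
                                     start = gt$repeats$start,
                                     end = gt$repeats$end,
                                     name = gt$repeats$family_id))
  if (is.null(bed)) bed <- data.frame(chrom = character(0), start = integer(0),
                                      end = integer(0), name = character(0))
  write.table(bed, files[6], sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(files)
}
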