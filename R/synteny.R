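#' Count homology hits per target chromosome
#'
#' Partitions one species' best hits by chromosome and calls homologous
#' chromosomes: the argmax chromosome plus every chromosome reaching at
#' least `secondary_frac` of the maximum (the operational form of "a
#' significant number of hits", capturing species where the query region
#' is split over two chromosomes).
#'
#' @param table Homology table: data frame with at least `species` and
#'   `chromosome` columns (one best hit per query gene per species).
#' @param species Species to tabulate.
#' @param secondary_frac Fraction of the maximum needed to call a
#'   secondary homolog (default 0.25).
#' @return Data frame `chromosome`, `n_hits`, `homolog` (logical), sorted
#'   by decreasing count; zero rows for a species absent from the table.
#' @export
#' @examples
#' tab <- data.frame(species = "fishA", chromosome = c("1","1","1","2"))
#' count_hits_per_chromosome(tab, "fishA")
count_hits_per_chromosome <- function(table, species, secondary_frac = 0.25) {
  t <- table[table$species == species, , drop = FALSE]
  if (!nrow(t)) {
    return(data.frame(chromosome = character(0), n_hits = integer(0),
                      homolog = logical(0)))
  }
  cnt <- sort(table(t$chromosome), decreasing = TRUE)
  out <- data.frame(chromosome = names(cnt), n_hits = as.integer(cnt))
  out$homolog <- out$n_hits >= secondary_frac * max(out$n_hits)
  rownames(out) <- NULL
  out
}

#' Detect conserved microsynteny blocks
#'
#' A block is a maximal set of genes that are adjacent in the query gene
#' order within one FPC contig (consecutive query ranks may skip at most
#' `max_query_gap` intervening genes) and co-locate on one target
#' chromosome (each added gene's target rank must lie within
#' `max_target_gap_genes` ranks, and `max_target_gap_bp` bases, of the
#' block's current target extent). Order within the block is free: a
#' block survives any internal permutation of the target positions.
#' Blocks need at least `min_genes` members; per target chromosome, blocks
#' are disjoint in query genes.
#'
#' @param table Homology table with columns `query_gene_id`,
#'   `query_contig_id`, `query_rank`, `species`, `chromosome`,
#'   `position_bp`, `target_rank`.
#' @param species Species to analyze.
#' @param min_genes Minimum genes per reported block.
#' @param max_query_gap Maximum skipped query ranks inside a block.
#' @param max_target_gap_genes Maximum target-rank gap to the block.
#' @param max_target_gap_bp Maximum target bp gap to the block (default
#'   1 Mb, the microsynteny scale).
#' @return Data frame of class `synteny_blocks`: `block_id`, `species`,
#'   `chromosome`, `query_contig_id`, `n_genes`, `gene_ids`
#'   (comma-separated), `query_rank_min`, `query_rank_max`,
#'   `target_start_bp`, `target_end_bp`.
#' @export
detect_microsynteny <- function(table, species, min_genes = 2,
                                max_query_gap = 1, max_target_gap_genes = 5,
                                max_target_gap_bp = 1e6) {
  t <- table[table$species == species, , drop = FALSE]
  blocks <- list()
  for (ctg in unique(t$query_contig_id)) {
    for (chr in unique(t$chromosome[t$query_contig_id == ctg])) {
      g <- t[t$query_contig_id == ctg & t$chromosome == chr, , drop = FALSE]
      g <- g[order(g$query_rank), , drop = FALSE]
      cur <- integer(0)
      flush <- function(cur) {
        if (length(cur) >= min_genes) {
          gg <- g[cur, , drop = FALSE]
          blocks[[length(blocks) + 1]] <<- data.frame(
            species = species, chromosome = chr, query_contig_id = ctg,
            n_genes = nrow(gg),
            gene_ids = paste(gg$query_gene_id, collapse = ","),
            query_rank_min = min(gg$query_rank),
            query_rank_max = max(gg$query_rank),
            target_start_bp = min(gg$position_bp),
            target_end_bp = max(gg$position_bp))
        }
      }
      for (i in seq_len(nrow(g))) {
        if (!length(cur)) { cur <- i; next }
        qgap <- g$query_rank[i] - g$query_rank[cur[length(cur)]] - 1L
        tr <- g$target_rank[cur]
        tp <- g$position_bp[cur]
        rank_gap <- if (g$target_rank[i] >= min(tr) &&
                        g$target_rank[i] <= max(tr)) 0L else
          min(abs(g$target_rank[i] - min(tr)), abs(g$target_rank[i] - max(tr)))
        bp_gap <- if (g$position_bp[i] >= min(tp) &&
                      g$position_bp[i] <= max(tp)) 0 else
          min(abs(g$position_bp[i] - min(tp)), abs(g$position_bp[i] - max(tp)))
        if (qgap <= max_query_gap && rank_gap <= max_target_gap_genes &&
            bp_gap <= max_target_gap_bp) {
          cur <- c(cur, i)
        } else {
          flush(cur)
          cur <- i
        }
      }
      flush(cur)
    }
  }
  if (!length(blocks)) {
    out <- data.frame(block_id = character(0), species = character(0),
                      chromosome = character(0), query_contig_id = character(0),
                      n_genes = integer(0), gene_ids = character(0),
                      query_rank_min = integer(0), query_rank_max = integer(0),
                      target_start_bp = numeric(0), target_end_bp = numeric(0))
    class(out) <- c("synteny_blocks", "data.frame")
    return(out)
  }
  out <- do.call(rbind, blocks)
  out <- out[order(out$chromosome, out$query_rank_min), , drop = FALSE]
  out <- cbind(block_id = sprintf("blk%03d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  class(out) <- c("synteny_blocks", "data.frame")
  out
}

#' Summarize synteny blocks per species
#'
#' @param blocks A `synteny_blocks` data frame (possibly several species
#'   row-bound together).
#' @return Data frame `species`, `n_blocks`, `n_genes` (each gene counted
#'   once), `total_target_mb` (summed block extents, Mb to 1 decimal).
#' @export
block_span_summary <- function(blocks) {
  if (!nrow(blocks)) {
    return(data.frame(species = character(0), n_blocks = integer(0),
                      n_genes = integer(0), total_target_mb = numeric(0)))
  }
  sp <- unique(blocks$species)
  out <- do.call(rbind, lapply(sp, function(s) {
    b <- blocks[blocks$species == s, , drop = FALSE]
    genes <- unique(unlist(strsplit(b$gene_ids, ",")))
    data.frame(species = s, n_blocks = nrow(b), n_genes = length(genes),
               total_target_mb = round(
                 sum(b$target_end_bp - b$target_start_bp) / 1e6, 1))
  }))
  rownames(out) <- NULL
  out
}

#' Simulate a homology table with planted microsynteny blocks
#'
#' Generates the input the synteny detector consumes: query genes grouped
#' into FPC contigs with dense query ranks; a fraction of the contigs
#' carry a planted block (consecutive query genes whose best hits
#' co-locate, with freely permuted local order, in a compact window of one
#' target chromosome); the remaining genes hit uniformly random
#' chromosomes and positions (noise). The planted truth is attached as
#' attribute `planted`.
#'
#' @param n_contigs Number of query FPC contigs.
#' @param genes_per_contig Genes per contig.
#' @param n_blocks Number of planted blocks (one per chosen contig).
#' @param block_genes Genes per planted block.
#' @param n_chromosomes Number of target chromosomes.
#' @param chrom_len_bp Target chromosome length.
#' @param noise_frac Fraction of *block* genes whose hit is replaced by a
#'   uniform random (noise) hit.
#' @param species Species label.
#' @param seed Integer seed.
#' @return Homology table data frame (see [detect_microsynteny()]) with
#'   attribute `planted` (data frame of block truth).
#' @export
simulate_homology_table <- function(n_contigs = 10, genes_per_contig = 8,
                                    n_blocks = 4, block_genes = 5,
                                    n_chromosomes = 24, chrom_len_bp = 40e6,
                                    noise_frac = 0.05, species = "modelfish",
                                    seed = 1) {
  stopifnot(block_genes <= genes_per_contig, n_blocks <= n_contigs)
  set.seed(seed)
  rows <- list()
  planted <- list()
  block_ctgs <- sort(sample.int(n_contigs, n_blocks))
  rank0 <- 0L
  for (ci in seq_len(n_contigs)) {
    ctg <- sprintf("qctg%02d", ci)
    ranks <- rank0 + seq_len(genes_per_contig)
    rank0 <- rank0 + genes_per_contig
    ids <- sprintf("g%04d", ranks)
    chr <- sample.int(n_chromosomes, genes_per_contig, replace = TRUE)
    pos <- floor(runif(genes_per_contig, 0, chrom_len_bp))
    if (ci %in% block_ctgs) {
      first <- sample.int(genes_per_contig - block_genes + 1, 1)
      sel <- first:(first + block_genes - 1)
      bchr <- sample.int(n_chromosomes, 1)
      anchor <- runif(1, 0, chrom_len_bp - 600000)
      bpos <- anchor + sample(seq(0, 500000, by = 1000), block_genes)
      chr[sel] <- bchr
      pos[sel] <- sample(bpos) # local order freely permuted
      # noise: corrupt some block-gene hits
      noisy <- runif(block_genes) < noise_frac
      if (any(noisy)) {
        chr[sel[noisy]] <- sample.int(n_chromosomes, sum(noisy), replace = TRUE)
        pos[sel[noisy]] <- floor(runif(sum(noisy), 0, chrom_len_bp))
      }
      planted[[length(planted) + 1]] <- data.frame(
        query_contig_id = ctg, chromosome = as.character(bchr),
        gene_ids = paste(ids[sel], collapse = ","),
        n_genes = block_genes, corrupted = sum(noisy))
    }
    rows[[ci]] <- data.frame(
      query_gene_id = ids, query_contig_id = ctg, query_rank = ranks,
      species = species, chromosome = as.character(chr), position_bp = pos)
  }
  tab <- do.call(rbind, rows)
  # dense 1..N target ranks per chromosome by position
  tab$target_rank <- NA_integer_
  for (chr in unique(tab$chromosome)) {
    i <- which(tab$chromosome == chr)
    tab$target_rank[i] <- rank(tab$position_bp[i], ties.method = "first")
  }
  rownames(tab) <- NULL
  attr(tab, "planted") <- if (length(planted)) do.call(rbind, planted) else
    data.frame()
  tab
}
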