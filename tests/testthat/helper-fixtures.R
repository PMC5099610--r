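# Shared fixtures, built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# 200 kb genome with default composition, a handful of markers/genes/SNPs
fixture_genome <- function() {
  memo("genome", generate_genome(
    sim_config(genome_len = 2e5, n_markers = 6, n_genes = 6, n_snps = 6),
    seed = 42))
}

# ~5x clone library over the fixture genome (small inserts for speed)
fixture_clones <- function() {
  memo("clones", digest_and_clone(
    fixture_genome(), partial_prob = 0.06, size_window = c(40000, 70000),
    n_clones = 18, seed = 7))
}

fixture_fingerprints <- function() {
  memo("fps", fingerprint_library(fixture_clones(), fixture_genome()))
}

fixture_fpc <- function() {
  memo("fpc", build_fpc_contigs(fixture_fingerprints(), fixture_clones()))
}

# a fabricated genome_truth wrapper around an arbitrary sequence
toy_genome <- function(seq) {
  structure(list(seq = seq, length_bp = nchar(seq),
                 repeats = data.frame(), markers = data.frame(),
                 genes = data.frame(), snps = data.frame(),
                 rate_cm_per_mb = 3.4, seed = 0), class = "genome_truth")
}

random_seq <- function(n, seed = NULL, at = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2)),
        collapse = "")
}

revcomp <- function(x) as.character(bacpool:::revcomp_chr(x))

# brute-force minimum interval cover size (subsets enumerated by size)
brute_min_cover <- function(starts, ends) {
  n <- length(starts)
  lo <- min(starts); hi <- max(ends)
  covers <- function(idx) {
    o <- order(starts[idx])
    reach <- lo
    for (i in idx[o]) {
      if (starts[i] > reach) return(FALSE)
      reach <- max(reach, ends[i])
    }
    reach >= hi
  }
  for (k in 1:n) {
    for (idx in utils::combn(n, k, simplify = FALSE)) {
      if (covers(idx)) return(k)
    }
  }
  n
}

# shared end-to-end hybrid run for the acceptance criteria (computed once)
fixture_e2e <- function() {
  memo("e2e", {
    cfg <- sim_config(genome_len = 4e5, n_markers = 4, n_genes = 10,
                      n_snps = 4)
    gt <- generate_genome(cfg, seed = 11)
    clones <- data.frame(clone_id = c("bA", "bB", "bC"),
                         start = c(10000L, 95000L, 190000L),
                         end = c(112000L, 205000L, 290000L))
    region <- substr(gt$seq, min(clones$start) + 1, max(clones$end))
    ins <- clone_inserts(clones, gt)
    rs <- simulate_short_reads(ins, coverage_x = 130, seed = 3)
    rs <- kmer_normalize(trim_reads(rs))
    contigs <- greedy_assemble(rs)
    lr <- simulate_long_reads(region, coverage_x = 24, seed = 5)
    scaf <- hybrid_scaffold(contigs, lr)
    val <- validate_and_split(scaf, list(rs, lr))
    st <- seq(1, nchar(region) - 499, 500)
    tiles <- setNames(substring(region, st, st + 499),
                      paste0("tile", seq_along(st)))
    hits <- map_sequences(val, tiles, min_len_frac = 0.9, min_sim = 0.95,
                          best_only = TRUE)
    list(region = region, reads = rs, long_reads = lr, contigs = contigs,
         scaffolds = scaf, validated = val, tiles = tiles, tile_hits = hits)
  })
}
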