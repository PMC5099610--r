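#' Simulate a size-selected partial-digest BAC library
#'
#' Emulates construction of a HindIII clone library: restriction sites are
#' located in the genome, each virtual input molecule receives an
#' independent partial digest (every site cut with probability
#' `partial_prob`), and fragments falling inside the size-selection window
#' become clones. Clones are assigned sequential plate/row/column addresses.
#'
#' @param genome A `genome_truth` object.
#' @param site Restriction motif (default HindIII, `"AAGCTT"`).
#' @param partial_prob Per-site cut probability of the partial digest.
#' @param size_window Numeric length-2 vector, the size-selection window in
#'   bp (min, max).
#' @param n_clones Number of clones to sample.
#' @param seed Integer seed.
#' @param n_rows,n_cols Plate geometry used for sequential addressing.
#' @return A data frame of class `bac_clones` with columns `clone_id`,
#'   `plate`, `row`, `col`, `start`, `end`, `insert_len_bp` (0-based
#'   half-open genome coordinates on retained cut sites).
#' @export
#' @examples
#' gt <- generate_genome(sim_config(genome_len = 3e5, n_markers = 2,
#'                                  n_snps = 0), seed = 1)
#' cl <- digest_and_clone(gt, n_clones = 10, seed = 2,
#'                        size_window = c(3e4, 9e4), partial_prob = 0.1)
#' nrow(cl)
digest_and_clone <- function(genome, site = "AAGCTT", partial_prob = 0.03,
                             size_window = c(80000, 120000), n_clones,
                             seed, n_rows = 16, n_cols = 24) {
  stopifnot(inherits(genome, "genome_truth"))
  if (partial_prob <= 0 || partial_prob > 1) stop("partial_prob must be in (0, 1]")
  if (size_window[1] >= size_window[2]) stop("size_window min must be < max")
  set.seed(seed)
  gseq <- Biostrings::DNAString(genome$seq)
  sites <- Biostrings::start(Biostrings::matchPattern(site, gseq)) - 1L # 0-based
  cuts_all <- sort(unique(c(0L, sites, genome$length_bp)))
  n_sites <- length(cuts_all)
  if (n_sites < 3) stop("sampling-exhausted error: too few restriction sites")

  picks <- matrix(0L, nrow = 0, ncol = 2)
  attempts <- 0L
  max_attempts <- max(2000L, 50L * n_clones)
  while (nrow(picks) < n_clones && attempts < max_attempts) {
    attempts <- attempts + 1L
    # one molecule: genome ends always break; internal sites cut at partial_prob
    keep <- c(TRUE, runif(n_sites - 2) < partial_prob, TRUE)
    cuts <- cuts_all[keep]
    if (length(cuts) < 2) next
    len <- diff(cuts)
    ok <- which(len >= size_window[1] & len <= size_window[2])
    if (!length(ok)) next
    take <- ok[sample.int(length(ok), min(length(ok), n_clones - nrow(picks)))]
    picks <- rbind(picks, cbind(cuts[take], cuts[take + 1L]))
  }
  if (nrow(picks) < n_clones) {
    stop("sampling-exhausted error: only ", nrow(picks), " of ", n_clones,
         " clones obtainable in the size window after ", attempts, " molecules")
  }
  idx <- seq_len(n_clones) - 1L
  per_plate <- n_rows * n_cols
  out <- data.frame(
    clone_id = sprintf("b%05d", idx + 1L),
    plate = idx %/% per_plate + 1L,
    row = (idx %% per_plate) %/% n_cols + 1L,
    col = idx %% n_cols + 1L,
    start = as.integer(picks[, 1]),
    end = as.integer(picks[, 2])
  )
  out$insert_len_bp <- out$end - out$start
  class(out) <- c("bac_clones", "data.frame")
  out
}

#' Genomic coverage fold of a clone library
#'
#' `n_clones * mean_insert_kb / (genome_mb * 1000)`, reported to 1 decimal,
#' i.e. the number of haploid genome equivalents the library represents.
#'
#' @param n_clones Number of clones.
#' @param mean_insert_kb Mean insert size in kb.
#' @param genome_mb Haploid genome size in Mb (> 0).
#' @return Coverage fold, rounded to 1 decimal.
#' @export
#' @examples
#' coverage_fold(49152, 98, 700) # 6.9 genome equivalents
coverage_fold <- function(n_clones, mean_insert_kb, genome_mb) {
  if (genome_mb <= 0) stop("domain error: genome size must be positive")
  if (n_clones < 0 || mean_insert_kb < 0) stop("inputs must be non-negative")
  round(n_clones * mean_insert_kb / (genome_mb * 1000), 1)
}

#' Fingerprint a clone by complete digest band sizes
#'
#' The in-silico analogue of HICF fingerprinting, abstracted to a multiset
#' of restriction fragment sizes: the insert is completely digested at
#' `site` and fragment sizes are binned at `tolerance_bp` (bin index =
#' `floor(size / tolerance_bp)`), so near-equal fragments from overlapping
#' clones fall in the same band.
#'
#' @param clone One row of a `bac_clones` data frame (or any list with
#'   `clone_id`, `start`, `end`).
#' @param genome A `genome_truth` object.
#' @param site Fingerprinting motif. The default 5-mer `"GACGT"` cuts about
#'   every 1.36 kb at the default AT-rich composition, so distinct band
#'   counts track spans at the physical map's 1.36 kb/CB calibration.
#' @param tolerance_bp Band size tolerance in bp.
#' @return A list of class `fingerprint` with `clone_id` and sorted integer
#'   `bands` (bin indices; multiset, duplicates retained).
#' @export
fingerprint_clone <- function(clone, genome, site = "GACGT", tolerance_bp = 3) {
  stopifnot(inherits(genome, "genome_truth"))
  if (clone$start < 0 || clone$end > genome$length_bp) {
    stop("clone lies outside the genome")
  }
  insert <- substr(genome$seq, clone$start + 1, clone$end)
  cuts <- Biostrings::start(
    Biostrings::matchPattern(site, Biostrings::DNAString(insert))) - 1L
  frag <- diff(c(0L, cuts, nchar(insert)))
  frag <- frag[frag > 0]
  structure(list(clone_id = clone$clone_id,
                 bands = sort(as.integer(frag %/% tolerance_bp)),
                 tolerance_bp = tolerance_bp),
            class = "fingerprint")
}

#' Fingerprint every clone of a library
#'
#' @param clones A `bac_clones` data frame.
#' @param genome A `genome_truth` object.
#' @inheritParams fingerprint_clone
#' @return A list of `fingerprint` objects, one per clone, in clone order.
#' @export
fingerprint_library <- function(clones, genome, site = "GACGT",
                                tolerance_bp = 3) {
  lapply(seq_len(nrow(clones)), function(i) {
    fingerprint_clone(clones[i, ], genome, site = site,
                      tolerance_bp = tolerance_bp)
  })
}

shared_band_count <- function(a, b) {
  # multiset intersection size of two sorted integer vectors
  ta <- table(a); tb <- table(b)
  common <- intersect(names(ta), names(tb))
  if (!length(common)) return(0L)
  sum(pmin(ta[common], tb[common]))
}

#' Build FPC-style contigs from fingerprints
#'
#' Single-linkage clustering of clones on shared-band count: two clones
#' join when their fingerprints share at least `min_shared_bands` bands
#' (multiset intersection). Clones sharing fewer bands with every other
#' clone remain singletons (contigs of one). Within a contig clones are
#' ordered by their truth coordinates (simulation mode). `cb_units` is the
#' number of distinct consensus bands over the contig's clones.
#'
#' @param fingerprints List of `fingerprint` objects.
#' @param clones The `bac_clones` data frame the fingerprints came from
#'   (supplies truth coordinates for ordering and spans).
#' @param min_shared_bands Minimum shared bands to join two clones.
#' @return A list of class `fpc_contig_set`; each element has `contig_id`,
#'   `clone_ids` (ordered), `cb_units`, `true_span` (0-based half-open) and
#'   `is_singleton`.
#' @export
build_fpc_contigs <- function(fingerprints, clones, min_shared_bands = 10) {
  n <- length(fingerprints)
  if (n < 1) stop("at least one fingerprint required")
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (shared_band_count(fingerprints[[i]]$bands,
                            fingerprints[[j]]$bands) >= min_shared_bands) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  ids <- vapply(fingerprints, function(f) f$clone_id, character(1))
  stopifnot(all(ids %in% clones$clone_id))
  cl <- clones[match(ids, clones$clone_id), ]
  groups <- split(seq_len(n), roots)
  # deterministic contig order: by leftmost member clone
  ord <- order(vapply(groups, function(g) min(cl$start[g]), numeric(1)))
  groups <- groups[ord]
  out <- lapply(seq_along(groups), function(ci) {
    g <- groups[[ci]]
    g <- g[order(cl$start[g], cl$end[g])]
    bands <- sort(unique(unlist(lapply(fingerprints[g], `[[`, "bands"))))
    list(contig_id = sprintf("fpc%03d", ci),
         clone_ids = ids[g],
         cb_units = length(bands),
         true_span = c(min(cl$start[g]), max(cl$end[g])),
         is_singleton = length(g) == 1L)
  })
  structure(out, class = "fpc_contig_set")
}

#' @export
print.fpc_contig_set <- function(x, ...) {
  ns <- vapply(x, function(ct) length(ct$clone_ids), integer(1))
  cat(sprintf("fpc_contig_set: %d contigs (%d singletons), %d clones\n",
              length(x), sum(ns == 1), sum(ns)))
  invisible(x)
}

#' Select a minimum tiling path over a contig
#'
#' Greedy left-to-right interval cover: starting from the leftmost clone,
#' repeatedly pick among the clones overlapping the covered territory the
#' one reaching furthest right (tie: leftmost start, maximizing overlap
#' redundancy). The selection covers the union of all member clone
#' intervals; on instances small enough to enumerate, the greedy size
#' equals the brute-force minimum cover.
#'
#' @param contig One element of an `fpc_contig_set`.
#' @param clones The `bac_clones` data frame with member intervals.
#' @param kb_per_cb Physical-map calibration used for `expected_size_kb`.
#' @return A list of class `tiling_path` with `contig_id`, `clone_ids`
#'   (the MTP, left to right) and `expected_size_kb`.
#' @export
select_mtp <- function(contig, clones, kb_per_cb = 1.36) {
  members <- clones[match(contig$clone_ids, clones$clone_id), ]
  if (!nrow(members)) stop("contig has no clones")
  iv <- members[order(members$start, members$end), ]
  # gap check: union of member intervals must be one interval
  gaps <- list()
  cover_end <- iv$end[1]
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv$start[i] > cover_end) {
      gaps[[length(gaps) + 1]] <- c(cover_end, iv$start[i])
    }
    cover_end <- max(cover_end, iv$end[i])
  }
  if (length(gaps)) {
    stop("cover-gap error: uncovered gaps at ",
         paste(vapply(gaps, function(g) paste0("[", g[1], ",", g[2], ")"),
                      character(1)), collapse = ", "))
  }
  lo <- min(iv$start); hi <- max(iv$end)
  sel <- integer(0)
  reach <- lo
  while (reach < hi) {
    cand <- which(iv$start <= reach & iv$end > reach)
    if (!length(cand)) stop("cover-gap error: no clone covers position ", reach)
    best <- cand[order(-iv$end[cand], iv$start[cand])][1]
    sel <- c(sel, best)
    reach <- iv$end[best]
  }
  sel <- unique(sel)
  structure(list(contig_id = contig$contig_id,
                 clone_ids = iv$clone_id[sel],
                 expected_size_kb = cb_to_kb(contig$cb_units, kb_per_cb)),
            class = "tiling_path")
}

#' Convert consensus band units to kb
#'
#' Linear physical-map calibration: `cb_units * kb_per_cb`. Reports round
#' the result to 1 decimal; the function returns the exact product so that
#' it stays additive.
#'
#' @param cb_units Consensus band units (>= 0).
#' @param kb_per_cb kb per CB unit (default 1.36, the physical-map value).
#' @return Size in kb.
#' @export
#' @examples
#' round(cb_to_kb(5177), 1) # 7040.7 kb
cb_to_kb <- function(cb_units, kb_per_cb = 1.36) {
  if (any(cb_units < 0)) stop("cb_units must be >= 0")
  cb_units * kb_per_cb
}

#' Convert genetic distance to physical distance
#'
#' `cm / rate_cm_per_mb`, the linkage-map size of an interval in Mb.
#'
#' @param cm Genetic distance in cM.
#' @param rate_cm_per_mb Recombination rate in cM/Mb (> 0).
#' @return Distance in Mb.
#' @export
#' @examples
#' cm_to_mb(97, 3.4) # about 28.5 Mb
cm_to_mb <- function(cm, rate_cm_per_mb = 3.4) {
  if (rate_cm_per_mb <= 0) stop("domain error: rate must be > 0")
  cm / rate_cm_per_mb
}

#' Extract clone insert sequences
#'
#' @param clones A `bac_clones` data frame (or subset).
#' @param genome A `genome_truth` object.
#' @return A named character vector of insert sequences.
#' @export
clone_inserts <- function(clones, genome) {
  setNames(substring(genome$seq, clones$start + 1, clones$end),
           clones$clone_id)
}
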