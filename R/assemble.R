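as_seq_vector <- function(x) {
  if (inherits(x, "read_set")) return(setNames(x$reads$seq, x$reads$id))
  if (inherits(x, "assembly")) return(setNames(x$sequence, x$contig_id))
  if (is.data.frame(x)) {
    nm <- x[[intersect(c("contig_id", "scaffold_id", "id"), names(x))[1]]]
    return(setNames(x$sequence, nm))
  }
  if (is.null(names(x))) names(x) <- sprintf("seq%04d", seq_along(x))
  x
}

#' Assemble reads with a greedy overlap-layout-consensus assembler
#'
#' Desk-scale greedy OLC: a contig is seeded from the first unused read and
#' extended base by base at both ends. At each step, candidate reads
#' overlapping the contig end are located by seed k-mers and verified
#' gaplessly against the running consensus; among reads that extend the
#' contig, the longest verified overlap wins (tie: lexicographically
#' smaller read id), reads fully contained are absorbed into the per-base
#' vote matrix, and the consensus is the per-column majority. Extension
#' stops at branch points where a second well-supported extension base
#' disagrees with the winner -- exact interspersed repeats longer than the
#' read span therefore break contigs instead of creating chimeras. The
#' procedure is deterministic for a fixed input order.
#'
#' @param reads A `read_set` or named character vector of read sequences.
#' @param min_overlap Minimum verified overlap (bp).
#' @param min_identity Minimum overlap identity in `[0, 1]`.
#' @return A data frame of class `assembly` with `contig_id`, `sequence`,
#'   `length`, `n_reads`, ordered by decreasing length.
#' @export
#' @examples
#' tpl <- strrep("ACGTTGCA", 60)
#' reads <- substring(tpl, seq(1, 361, 40), seq(120, 480, 40))
#' a <- greedy_assemble(setNames(reads, sprintf("r%02d", 1:10)),
#'                      min_overlap = 30)
#' nrow(a)
greedy_assemble <- function(reads, min_overlap = 40, min_identity = 0.97) {
  seqs <- as_seq_vector(reads)
  if (!length(seqs)) stop("reads must be non-empty")
  res <- .cpp_greedy_assemble(unname(seqs), names(seqs),
                              as.integer(min_overlap), min_identity)
  out <- data.frame(contig_id = character(length(res$sequence)),
                    sequence = res$sequence, length = nchar(res$sequence),
                    n_reads = res$n_reads)
  out <- out[order(-out$length, out$sequence), , drop = FALSE]
  out$contig_id <- sprintf("ctg%04d", seq_len(nrow(out)))
  rownames(out) <- NULL
  class(out) <- c("assembly", "data.frame")
  out
}

#' Map query sequences onto references (gapless seed-and-extend)
#'
#' k-mer-seeded diagonal voting followed by ungapped verification over the
#' full query/reference intersection. Suited to the package's
#' substitution-only simulated data; hits must align at least
#' `min_len_frac` of the query at `min_sim` identity or better.
#'
#' @param refs Named character vector (or `assembly`) of references.
#' @param queries Named character vector (or `read_set`) of queries.
#' @param min_len_frac Minimum aligned fraction of the query length.
#' @param min_sim Minimum identity of the aligned region.
#' @param best_only If `TRUE` one best hit per query, else the best hit
#'   per (query, reference).
#' @return Data frame with `query`, `ref` (names), `strand`, `qstart`,
#'   `qend` (on the reported strand), `rstart`, `rend` (0-based half-open),
#'   `matches`, `aligned`, `identity`.
#' @export
map_sequences <- function(refs, queries, min_len_frac = 0.5, min_sim = 0.9,
                          best_only = FALSE) {
  r <- as_seq_vector(refs)
  q <- as_seq_vector(queries)
  hits <- .cpp_map_seqs(unname(r), unname(q), min_len_frac, min_sim, best_only)
  hits$query <- names(q)[hits$query]
  hits$ref <- names(r)[hits$ref]
  hits
}

# hits of one long read, with coordinates lifted to the original read strand
orient_hits <- function(h, qlen) {
  h$ostart <- ifelse(h$strand == 1, h$qstart, qlen - h$qend)
  h$oend <- ifelse(h$strand == 1, h$qend, qlen - h$qstart)
  h
}

#' Scaffold contigs with long reads
#'
#' Long reads are mapped against the contigs (default thresholds: length
#' fraction 0.2, similarity 0.9); a read aligning to two or more contigs
#' creates scaffold edges carrying the relative orientation and a gap
#' estimate from the read coordinates. Connected components with a
#' consistent orientation assignment are linearized; inter-contig gaps are
#' filled with the column-majority consensus of the supporting reads'
#' bases where covered (ties give `N`), else with an `N` run sized by the
#' gap estimate. Edges join the layout in decreasing support order; an
#' edge whose implied orientation or position contradicts the layout built
#' from better-supported edges is dropped and logged in the `conflicts`
#' attribute. Finally, remaining sequences whose ends dovetail at high
#' identity are co-assembled (default: match 99%, minimum overlap 20 bp).
#' The scaffold count never exceeds the contig count.
#'
#' @param contigs An `assembly` or named character vector.
#' @param long_reads A `read_set` (platform `"long"`) or named character
#'   vector.
#' @param map_len_frac,map_sim Mapping thresholds for mining long reads.
#' @param merge_identity,merge_min_overlap End-merge (co-assembly)
#'   thresholds for contigs not linked by long reads.
#' @return A data frame of class `assembly` (columns `contig_id` renamed
#'   `scaffold_id`) with attributes `edges` (the scaffold graph edge list)
#'   and `conflicts` (contig ids in orientation-conflicted components).
#' @export
hybrid_scaffold <- function(contigs, long_reads, map_len_frac = 0.2,
                            map_sim = 0.9, merge_identity = 0.99,
                            merge_min_overlap = 20) {
  ctg <- as_seq_vector(contigs)
  lr <- as_seq_vector(long_reads)
  clen <- nchar(ctg)
  n <- length(ctg)
  hits <- if (length(lr)) {
    map_sequences(ctg, lr, min_len_frac = map_len_frac, min_sim = map_sim,
                  best_only = FALSE)
  } else {
    data.frame()
  }

  edges <- list() # key -> list(a, b, oa, ob, gaps, gapseqs, support)
  if (nrow(hits)) {
    hits_by_read <- split(hits, hits$query)
    for (rid in names(hits_by_read)) {
      h <- hits_by_read[[rid]]
      if (nrow(h) < 2) next
      qlen <- nchar(lr[[rid]])
      h <- orient_hits(h, qlen)
      h <- h[order(h$ostart, -h$oend), , drop = FALSE]
      # a hit nested inside another hit of the same read is a repeat-copy
      # artifact (the read's repeat segment matching a diverged copy on a
      # different contig), not junction evidence
      nested <- vapply(seq_len(nrow(h)), function(i) {
        any(h$ostart <= h$ostart[i] & h$oend >= h$oend[i] &
              h$aligned > h$aligned[i])
      }, logical(1))
      h <- h[!nested, , drop = FALSE]
      if (nrow(h) < 2) next
      for (i in seq_len(nrow(h) - 1)) {
        A <- h[i, ]; B <- h[i + 1, ]
        if (A$ref == B$ref) next
        # junction evidence must be anchored by a substantial alignment on
        # both sides (filters reads lying inside diverged repeat copies)
        if (A$aligned < 300 || B$aligned < 300) next
        la <- clen[[A$ref]]; lb <- clen[[B$ref]]
        a_after <- if (A$strand == 1) la - A$rend else A$rstart
        b_before <- if (B$strand == 1) B$rstart else lb - B$rend
        gap <- (B$ostart - A$oend) - a_after - b_before
        gap <- max(gap, -min(la, lb))
        gseq <- if (B$ostart > A$oend) {
          substr(lr[[rid]], A$oend + 1, B$ostart)
        } else ""
        a <- A$ref; b <- B$ref; oa <- A$strand; ob <- B$strand
        flipped <- a > b
        if (flipped) {
          tmp <- a; a <- b; b <- tmp
          tmp <- oa; oa <- -ob; ob <- -tmp
          if (nzchar(gseq)) gseq <- as.character(revcomp_chr(gseq))
        }
        key <- paste(a, b, oa, ob, sep = "|")
        e <- edges[[key]] %||% list(a = a, b = b, oa = oa, ob = ob,
                                    gaps = numeric(0), gapseqs = character(0),
                                    reads = character(0))
        e$gaps <- c(e$gaps, gap)
        if (nzchar(gseq)) e$gapseqs <- c(e$gapseqs, gseq)
        e$reads <- c(e$reads, rid)
        edges[[key]] <- e
      }
    }
  }

  # Kruskal-style layout: edges join the layout in decreasing support
  # order; an edge implying an orientation flip or a position shift
  # inconsistent with the current layout of its component is dropped and
  # logged (repeat-mediated spurious links lose to true junction links).
  nm <- names(ctg)
  orient <- setNames(rep(1L, n), nm)
  pos <- setNames(rep(0, n), nm)
  comp <- setNames(seq_len(n), nm)
  placed <- setNames(rep(FALSE, n), nm)
  conflicts <- character(0)
  pos_tol <- 1000
  if (length(edges)) {
    ord <- order(-vapply(edges, function(e) length(e$reads), integer(1)))
    for (e in edges[ord]) {
      gap <- mean(e$gaps)
      a <- e$a; b <- e$b
      # target orientation/position of b implied by a's current frame
      implied_b <- function() {
        if (orient[[a]] == e$oa) {
          list(o = e$ob, p = pos[[a]] + clen[[a]] + gap)
        } else {
          list(o = -e$ob, p = pos[[a]] - gap - clen[[b]])
        }
      }
      if (comp[[a]] == comp[[b]] && placed[[a]] && placed[[b]]) {
        ib <- implied_b()
        if (orient[[b]] != ib$o || abs(pos[[b]] - ib$p) > pos_tol) {
          conflicts <- c(conflicts, sprintf(
            "%s-%s (support %d): inconsistent with layout", a, b,
            length(e$reads)))
        }
        next
      }
      placed[[a]] <- TRUE; placed[[b]] <- TRUE
      ib <- implied_b()
      members_b <- nm[comp == comp[[b]]]
      if (orient[[b]] != ib$o) {
        # mirror component b (reverse direction), then shift b onto target
        newpos <- -(pos[members_b] + unlist(clen[members_b]))
        orient[members_b] <- -orient[members_b]
        pos[members_b] <- newpos + (ib$p - newpos[[b]])
      } else {
        pos[members_b] <- pos[members_b] + (ib$p - pos[[b]])
      }
      comp[comp == comp[[b]]] <- comp[[a]]
    }
  }
  ncomp_ids <- unique(comp)

  scaffolds <- character(0)
  for (ci in ncomp_ids) {
    members <- nm[comp == ci]
    if (length(members) == 1) {
      scaffolds <- c(scaffolds, ctg[members]) # unlinked
      next
    }
    members <- members[order(pos[members])]
    seq_out <- ""
    prev_end <- NA_real_
    prev <- NULL
    for (m in members) {
      mseq <- if (orient[[m]] == 1) ctg[[m]] else as.character(revcomp_chr(ctg[[m]]))
      if (is.null(prev)) {
        seq_out <- mseq
      } else {
        gap_adj <- round(pos[[m]] - prev_end)
        if (gap_adj < 0) {
          if (-gap_adj >= clen[[m]]) next # contained in the layout
          mseq <- substr(mseq, -gap_adj + 1, clen[[m]])
          seq_out <- paste0(seq_out, mseq)
        } else {
          fill <- NULL
          for (e in edges) {
            if (e$a == prev && e$b == m && orient[[prev]] == e$oa &&
                length(e$gapseqs)) {
              fill <- as.character(.cpp_column_majority(e$gapseqs))
            } else if (e$a == m && e$b == prev && orient[[m]] == -e$ob &&
                       length(e$gapseqs)) {
              fill <- as.character(revcomp_chr(
                .cpp_column_majority(e$gapseqs)))
            }
            if (!is.null(fill)) break
          }
          if (is.null(fill)) fill <- strrep("N", gap_adj)
          seq_out <- paste0(seq_out, fill, mseq)
        }
      }
      prev <- m
      prev_end <- pos[[m]] + clen[[m]]
    }
    scaffolds <- c(scaffolds, setNames(seq_out, members[1]))
  }

  # co-assembly of remaining dovetailing ends (Sequencher-style)
  merged <- end_merge(scaffolds, min_overlap = merge_min_overlap,
                      min_identity = merge_identity)

  out <- data.frame(scaffold_id = character(length(merged)),
                    sequence = unname(merged), length = nchar(merged),
                    n_reads = NA_integer_)
  out <- out[order(-out$length, out$sequence), , drop = FALSE]
  out$scaffold_id <- sprintf("scf%04d", seq_len(nrow(out)))
  rownames(out) <- NULL
  class(out) <- c("assembly", "data.frame")
  names(out)[names(out) == "scaffold_id"] <- "contig_id"
  edge_df <- if (length(edges)) {
    do.call(rbind, lapply(edges, function(e) data.frame(
      contig_a = e$a, contig_b = e$b, orient_a = e$oa, orient_b = e$ob,
      gap_estimate_bp = mean(e$gaps), support_count = length(e$reads))))
  } else {
    data.frame(contig_a = character(0), contig_b = character(0),
               orient_a = integer(0), orient_b = integer(0),
               gap_estimate_bp = numeric(0), support_count = integer(0))
  }
  rownames(edge_df) <- NULL
  attr(out, "edges") <- edge_df
  attr(out, "conflicts") <- conflicts
  out
}

# iterative best-dovetail merging; exact seed of min_overlap bases at the
# joining ends, full overlap verified at min_identity
end_merge <- function(seqs, min_overlap = 20, min_identity = 0.99) {
  repeat {
    n <- length(seqs)
    if (n < 2) return(seqs)
    best <- NULL
    for (i in seq_len(n)) {
      li <- nchar(seqs[[i]])
      if (li < min_overlap) next
      seed <- substr(seqs[[i]], li - min_overlap + 1, li)
      for (j in seq_len(n)) {
        if (i == j) next
        for (o in c(1L, -1L)) {
          sj <- if (o == 1) seqs[[j]] else as.character(revcomp_chr(seqs[[j]]))
          lj <- nchar(sj)
          if (lj < min_overlap) next
          m <- Biostrings::matchPattern(seed, Biostrings::DNAString(sj))
          for (e in Biostrings::end(m)) {
            v <- e # overlap length
            if (v < min_overlap || v > min(li, lj) || v == lj) next
            a <- substr(seqs[[i]], li - v + 1, li)
            b <- substr(sj, 1, v)
            mm <- sum(utf8ToInt(a) != utf8ToInt(b))
            if (mm > (1 - min_identity) * v) next
            if (is.null(best) || v > best$v) best <- list(i = i, j = j, o = o,
                                                          v = v, lj = lj)
          }
        }
      }
    }
    if (is.null(best)) return(seqs)
    sj <- if (best$o == 1) seqs[[best$j]] else
      as.character(revcomp_chr(seqs[[best$j]]))
    newseq <- paste0(seqs[[best$i]], substr(sj, best$v + 1, best$lj))
    nmres <- names(seqs)[best$i]
    seqs <- seqs[-c(best$i, best$j)]
    seqs <- c(seqs, setNames(newseq, nmres))
  }
}

#' Validate scaffolds by read-back mapping and split at zero coverage
#'
#' All relevant reads are mapped back to the scaffolds under strict
#' thresholds (default length fraction 0.95, similarity 0.95); per-base
#' coverage is computed from the accepted mappings only. Maximal internal
#' zero-coverage runs split a scaffold, and terminal zero-coverage runs
#' are trimmed, so every returned piece has minimum coverage >= 1. The
#' operation is idempotent.
#'
#' @param scaffolds An `assembly` or named character vector.
#' @param all_reads A `read_set`, list of `read_set`s, or character vector
#'   of every read relevant to the scaffolds (short + long).
#' @param map_len_frac,map_sim Validation mapping thresholds.
#' @return An `assembly` data frame with a `coverage` list column of
#'   per-base integer vectors; piece ids append `.1`, `.2`, ... to the
#'   parent scaffold id when a split occurred.
#' @export
validate_and_split <- function(scaffolds, all_reads, map_len_frac = 0.95,
                               map_sim = 0.95) {
  sc <- as_seq_vector(scaffolds)
  if (is.list(all_reads) && !inherits(all_reads, "read_set")) {
    reads <- unlist(lapply(all_reads, as_seq_vector))
  } else {
    reads <- as_seq_vector(all_reads)
  }
  hits <- map_sequences(sc, reads, min_len_frac = map_len_frac,
                        min_sim = map_sim, best_only = TRUE)
  ids <- character(0); seqs <- character(0); covs <- list()
  for (s in names(sc)) {
    L <- nchar(sc[[s]])
    cov <- integer(L)
    h <- hits[hits$ref == s, , drop = FALSE]
    if (nrow(h)) {
      delta <- integer(L + 1L)
      for (i in seq_len(nrow(h))) {
        delta[h$rstart[i] + 1L] <- delta[h$rstart[i] + 1L] + 1L
        delta[h$rend[i] + 1L] <- delta[h$rend[i] + 1L] - 1L
      }
      cov <- cumsum(delta[seq_len(L)])
    }
    covered <- cov > 0
    if (!any(covered)) next
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    for (k in seq_along(runs)) {
      i <- runs[k]
      piece <- substr(sc[[s]], starts[i], ends[i])
      pid <- if (length(runs) == 1 && starts[i] == 1 && ends[i] == L) s
             else paste0(s, ".", k)
      ids <- c(ids, pid)
      seqs <- c(seqs, piece)
      covs <- c(covs, list(cov[starts[i]:ends[i]]))
    }
  }
  out <- data.frame(contig_id = ids, sequence = seqs, length = nchar(seqs))
  out$coverage <- covs
  ord <- order(-out$length, out$sequence)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("assembly", "data.frame")
  out
}

#' Anchor marker and BAC-end sequences on scaffolds
#'
#' Reports each query as a full hit (the whole query aligns), partial hit
#' (at least `min_frac` of it aligns) or absent, with the strand and
#' scaffold coordinates. A BES pair whose two ends land on one scaffold in
#' convergent orientation implies the clone's span and orientation; see
#' [bes_pair_spans()].
#'
#' @param scaffolds An `assembly` or named character vector.
#' @param queries Data frame with `id`, `seq`, `type` (e.g. `"marker"`,
#'   `"BES"`).
#' @param min_identity Minimum alignment identity.
#' @param min_frac Minimum aligned query fraction for a partial hit.
#' @return Data frame: `query_id`, `type`, `scaffold_id`, `status`
#'   (`full`/`partial`/`absent`), `strand`, `rstart`, `rend`, `identity`.
#' @export
anchor_sequences <- function(scaffolds, queries, min_identity = 0.95,
                             min_frac = 0.5) {
  if (!nrow(queries)) stop("queries must be non-empty")
  sc <- as_seq_vector(scaffolds)
  q <- setNames(queries$seq, queries$id)
  hits <- map_sequences(sc, q, min_len_frac = min_frac, min_sim = min_identity,
                        best_only = FALSE)
  rows <- lapply(seq_len(nrow(queries)), function(i) {
    id <- queries$id[i]
    qlen <- nchar(queries$seq[i])
    h <- hits[hits$query == id, , drop = FALSE]
    if (!nrow(h)) {
      return(data.frame(query_id = id, type = queries$type[i],
                        scaffold_id = NA_character_, status = "absent",
                        strand = NA_integer_, rstart = NA_integer_,
                        rend = NA_integer_, identity = NA_real_))
    }
    h <- h[order(-h$matches), , drop = FALSE]
    data.frame(query_id = id, type = queries$type[i], scaffold_id = h$ref,
               status = ifelse(h$aligned >= 0.98 * qlen, "full", "partial"),
               strand = h$strand, rstart = h$rstart, rend = h$rend,
               identity = h$identity)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Infer clone spans from anchored BES pairs
#'
#' For each clone whose two end sequences anchor on the same scaffold in
#' convergent orientation (`+` end before `-` end), the implied clone
#' interval and span are reported.
#'
#' @param anchors Output of [anchor_sequences()] for BES queries whose ids
#'   follow `<clone_id>_T7` / `<clone_id>_SP6`.
#' @return Data frame: `clone_id`, `scaffold_id`, `start`, `end`,
#'   `span_bp`, `convergent`.
#' @export
bes_pair_spans <- function(anchors) {
  b <- anchors[anchors$type == "BES" & anchors$status != "absent", , drop = FALSE]
  b$clone_id <- sub("_(T7|SP6)$", "", b$query_id)
  rows <- list()
  for (cid in unique(b$clone_id)) {
    h <- b[b$clone_id == cid, , drop = FALSE]
    scf <- intersect(h$scaffold_id[grepl("_T7$", h$query_id)],
                     h$scaffold_id[grepl("_SP6$", h$query_id)])
    if (!length(scf)) next
    s <- scf[1]
    t7 <- h[grepl("_T7$", h$query_id) & h$scaffold_id == s, ][1, ]
    sp6 <- h[grepl("_SP6$", h$query_id) & h$scaffold_id == s, ][1, ]
    lo <- min(t7$rstart, sp6$rstart)
    hi <- max(t7$rend, sp6$rend)
    left <- if (t7$rstart <= sp6$rstart) t7 else sp6
    right <- if (t7$rstart <= sp6$rstart) sp6 else t7
    rows[[length(rows) + 1]] <- data.frame(
      clone_id = cid, scaffold_id = s, start = lo, end = hi,
      span_bp = hi - lo,
      convergent = left$strand == 1 && right$strand == -1)
  }
  if (!length(rows)) {
    return(data.frame(clone_id = character(0), scaffold_id = character(0),
                      start = integer(0), end = integer(0),
                      span_bp = integer(0), convergent = logical(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Count substitutions between two alignable sequences
#'
#' Optimal global alignment with affine gap penalties
#' (via `Biostrings::pairwiseAlignment`); the return value is the
#' substitution (mismatch) count, with insertion and deletion counts
#' attached as attributes `insertions` and `deletions`.
#'
#' @param seq_a,seq_b Non-empty nucleotide strings.
#' @return Integer substitution count with attributes `insertions`,
#'   `deletions`.
#' @export
#' @examples
#' count_mismatches("ACGTACGT", "ACCTACGT") # 1
count_mismatches <- function(seq_a, seq_b) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("domain error: empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(seq_a), Biostrings::DNAString(seq_b),
    type = "global", gapOpening = 10, gapExtension = 0.5)
  ins <- Biostrings::nindel(aln)
  n <- Biostrings::nmismatch(aln)
  structure(as.integer(n),
            insertions = unname(Biostrings::insertion(ins)[1, "WidthSum"]),
            deletions = unname(Biostrings::deletion(ins)[1, "WidthSum"]))
}

#' Tabulate per-pool assembly statistics
#'
#' Builds the per-pool accounting table (scaffold counts and assembly kb
#' for the short-read-only and hybrid assemblies) plus a `Total` row with
#' column sums. kb values are reported to 1 decimal. When both columns are
#' present for a pool, the hybrid scaffold count not exceeding the
#' short-read count is asserted.
#'
#' @param per_pool Data frame with columns `pool`, `n_scaffolds_miseq`,
#'   `kb_miseq`, `n_scaffolds_hybrid`, `kb_hybrid` (any count/kb column
#'   may be `NA`). Alternatively build it with [pool_assembly_stats()].
#' @param check_reduction Assert hybrid count <= short-read count per pool.
#' @return The table with a `Total` row appended.
#' @export
assembly_report <- function(per_pool, check_reduction = TRUE) {
  req <- c("pool", "n_scaffolds_miseq", "kb_miseq", "n_scaffolds_hybrid",
           "kb_hybrid")
  if (!all(req %in% names(per_pool))) {
    stop("per_pool must have columns: ", paste(req, collapse = ", "))
  }
  if (check_reduction) {
    both <- !is.na(per_pool$n_scaffolds_miseq) &
      !is.na(per_pool$n_scaffolds_hybrid)
    if (any(per_pool$n_scaffolds_hybrid[both] >
            per_pool$n_scaffolds_miseq[both])) {
      stop("hybrid scaffold count exceeds short-read-only count for a pool")
    }
  }
  tot <- data.frame(
    pool = "Total",
    n_scaffolds_miseq = sum(per_pool$n_scaffolds_miseq),
    kb_miseq = round(sum(per_pool$kb_miseq), 1),
    n_scaffolds_hybrid = sum(per_pool$n_scaffolds_hybrid),
    kb_hybrid = round(sum(per_pool$kb_hybrid), 1))
  per_pool$kb_miseq <- round(per_pool$kb_miseq, 1)
  per_pool$kb_hybrid <- round(per_pool$kb_hybrid, 1)
  out <- rbind(per_pool[, req], tot)
  rownames(out) <- NULL
  out
}

#' Summarize one assembly for the report table
#'
#' @param assembly An `assembly` data frame (or `NULL`).
#' @return Named vector `n` (sequences) and `kb` (total kb, 1 decimal).
#' @export
pool_assembly_stats <- function(assembly) {
  if (is.null(assembly) || !nrow(assembly)) return(c(n = 0, kb = 0))
  c(n = nrow(assembly), kb = round(sum(nchar(assembly$sequence)) / 1000, 1))
}
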