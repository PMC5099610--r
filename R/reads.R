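#' Simulate paired-end short reads from insert templates
#'
#' Inward-facing read pairs (MiSeq-style 2 x 250 bp) from fragments drawn
#' along each template: fragment starts are uniform, fragment lengths
#' normal around `frag_mean`, and half the fragments come from each
#' strand. Substitution errors are injected uniformly at `err_rate`;
#' qualities follow a declining MiSeq-like profile and are independent of
#' the planted errors. Expected per-base coverage is within a few percent
#' of `coverage_x`. Templates shorter than a fragment are skipped with a
#' warning.
#'
#' @param insert_seqs Named character vector of template sequences.
#' @param coverage_x Target per-base coverage.
#' @param read_len Read length (bp).
#' @param frag_mean,frag_sd Fragment-size distribution (bp);
#'   `frag_mean >= read_len` required.
#' @param err_rate Per-base substitution error rate.
#' @param seed Integer seed.
#' @return A list of class `read_set`: data frame `reads` (`id`, `seq`,
#'   `qual`, `mate`, `pair_id`), and `platform = "short"`.
#' @export
#' @examples
#' rs <- simulate_short_reads(c(t1 = strrep("ACGT", 500)), coverage_x = 10,
#'                            read_len = 100, frag_mean = 300, frag_sd = 30,
#'                            err_rate = 0, seed = 1)
#' nrow(rs$reads)
simulate_short_reads <- function(insert_seqs, coverage_x, read_len = 250,
                                 frag_mean = 475, frag_sd = 60,
                                 err_rate = 0.002, seed = 1) {
  if (coverage_x <= 0) stop("coverage must be positive")
  if (frag_mean < read_len) stop("frag_mean must be >= read_len")
  set.seed(seed)
  all1 <- list(); all2 <- list(); pair_ids <- list()
  nm <- names(insert_seqs) %||% sprintf("tpl%02d", seq_along(insert_seqs))
  for (t in seq_along(insert_seqs)) {
    tpl <- insert_seqs[[t]]
    L <- nchar(tpl)
    if (L < frag_mean + 3 * frag_sd) {
      warning("template ", nm[t], " shorter than fragment size; skipped")
      next
    }
    n_frag <- round(coverage_x * L / (2 * read_len))
    flen <- pmin(L, pmax(read_len, round(rnorm(n_frag, frag_mean, frag_sd))))
    fstart <- floor(runif(n_frag, 0, L - flen + 1)) # 0-based
    frags <- substring(tpl, fstart + 1, fstart + flen)
    flip <- runif(n_frag) < 0.5
    frags[flip] <- revcomp_chr(frags[flip])
    r1 <- substring(frags, 1, pmin(read_len, flen))
    r2 <- revcomp_chr(substring(frags, pmax(1, flen - read_len + 1), flen))
    all1[[length(all1) + 1]] <- r1
    all2[[length(all2) + 1]] <- r2
    pair_ids[[length(pair_ids) + 1]] <- sprintf("%s_f%06d", nm[t], seq_len(n_frag))
  }
  r1 <- unlist(all1); r2 <- unlist(all2); pid <- unlist(pair_ids)
  if (is.null(r1)) stop("no template long enough for the fragment size")
  r1 <- as.character(.cpp_inject_substitutions(r1, err_rate))
  r2 <- as.character(.cpp_inject_substitutions(r2, err_rate))
  qual_for <- function(seqs) {
    vapply(nchar(seqs), function(n) {
      q <- round(38 - 8 * (seq_len(n) - 1) / max(1, n - 1) + rnorm(n, 0, 2))
      intToUtf8(pmin(40, pmax(2, q)) + 33)
    }, character(1))
  }
  reads <- data.frame(
    id = c(paste0(pid, "/1"), paste0(pid, "/2")),
    seq = c(r1, r2),
    qual = c(qual_for(r1), qual_for(r2)),
    mate = rep(c(1L, 2L), each = length(pid)),
    pair_id = c(pid, pid))
  reads <- reads[order(reads$pair_id, reads$mate), ]
  rownames(reads) <- NULL
  structure(list(reads = reads, platform = "short"), class = "read_set")
}

#' Simulate corrected long reads
#'
#' Long reads in the style of self-corrected SMRT data: lengths are
#' log-normal within `len_range` (0.5--31.4 kb by default), strand is
#' random, and the residual error is substitution-only at `err_rate`
#' (1% default), reflecting reads already error-corrected upstream.
#'
#' @param template Template sequence (character scalar).
#' @param coverage_x Target per-base coverage.
#' @param len_range Min/max read length (bp).
#' @param meanlog,sdlog Log-normal length parameters (defaults give ~6 kb
#'   median).
#' @param err_rate Residual per-base substitution rate.
#' @param seed Integer seed.
#' @return A `read_set` with `platform = "long"`.
#' @export
simulate_long_reads <- function(template, coverage_x, len_range = c(500, 31400),
                                meanlog = log(6000), sdlog = 0.7,
                                err_rate = 0.01, seed = 1) {
  if (coverage_x <= 0) stop("coverage must be positive")
  set.seed(seed)
  L <- nchar(template)
  lens <- integer(0)
  while (sum(lens) < coverage_x * L) {
    l <- round(stats::rlnorm(64, meanlog, sdlog))
    l <- pmin(pmax(l, len_range[1]), min(len_range[2], L))
    lens <- c(lens, l)
    if (sum(lens) >= coverage_x * L) {
      excess <- which(cumsum(lens) >= coverage_x * L)[1]
      lens <- lens[seq_len(excess)]
      break
    }
  }
  starts <- floor(runif(length(lens), 0, L - lens + 1))
  seqs <- substring(template, starts + 1, starts + lens)
  flip <- runif(length(seqs)) < 0.5
  seqs[flip] <- revcomp_chr(seqs[flip])
  seqs <- as.character(.cpp_inject_substitutions(seqs, err_rate))
  reads <- data.frame(
    id = sprintf("lr%05d", seq_along(seqs)),
    seq = seqs,
    qual = vapply(nchar(seqs), function(n) strrep("I", n), character(1)),
    mate = 0L, pair_id = sprintf("lr%05d", seq_along(seqs)))
  structure(list(reads = reads, platform = "long"), class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set (%s): %d reads, mean length %.1f bp\n", x$platform,
              nrow(x$reads), mean(nchar(x$reads$seq))))
  invisible(x)
}

#' Quality-trim reads
#'
#' Trimmomatic-style trimming: drop leading bases below `leading_q` and
#' trailing bases below `trailing_q`, cut at the first `window`-base
#' sliding window with mean quality below `window_q`, then drop reads
#' shorter than `min_len`. If one mate of a pair is dropped the survivor
#' is kept as an unpaired read (its `mate` set to 0), maximizing usable
#' coverage.
#'
#' @param read_set A `read_set`.
#' @param leading_q,trailing_q,window,window_q,min_len Trimming thresholds
#'   (defaults LEADING:3 TRAILING:6 SLIDINGWINDOW:4:15 MINLEN:150).
#' @return The trimmed `read_set`.
#' @export
trim_reads <- function(read_set, leading_q = 3, trailing_q = 6, window = 4,
                       window_q = 15, min_len = 150) {
  r <- read_set$reads
  tr <- .cpp_trim_reads(r$seq, r$qual, as.integer(leading_q),
                        as.integer(trailing_q), as.integer(window),
                        as.integer(window_q), as.integer(min_len))
  keep <- tr$keep
  out <- r[keep, , drop = FALSE]
  out$seq <- tr$seq[keep]
  out$qual <- tr$qual[keep]
  # orphan handling: mate dropped -> survivor unpaired
  if (any(!keep)) {
    paired <- out$mate > 0
    both <- table(out$pair_id[paired])
    orphan <- paired & both[out$pair_id] < 2
    orphan[is.na(orphan)] <- FALSE
    out$mate[orphan] <- 0L
  }
  rownames(out) <- NULL
  structure(list(reads = out, platform = read_set$platform),
            class = "read_set")
}

#' Normalize read coverage by k-mer abundance
#'
#' Streaming in-silico normalization: a read is kept when the median
#' abundance of its canonical `k`-mers among previously kept reads is
#' below `target_cov`. On templates sampled uniformly the retained set's
#' per-base coverage settles near `target_cov`; low-coverage sets pass
#' through unchanged.
#'
#' @param read_set A `read_set`.
#' @param k k-mer size (default 25; must be below the read length).
#' @param target_cov Target coverage (default 100).
#' @return The normalized `read_set`.
#' @export
kmer_normalize <- function(read_set, k = 25, target_cov = 100) {
  r <- read_set$reads
  if (k >= min(nchar(r$seq))) stop("k must be below the minimum read length")
  keep <- .cpp_kmer_normalize_keep(r$seq, as.integer(k), as.integer(target_cov))
  out <- r[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(list(reads = out, platform = read_set$platform),
            class = "read_set")
}

#' Write a read set as FASTQ
#'
#' @param read_set A `read_set`.
#' @param path Output FASTQ path.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(read_set, path) {
  r <- read_set$reads
  # plain 4-line records; handles arbitrarily long (e.g. 31 kb) reads
  rec <- rbind(paste0("@", r$id), r$seq, "+", r$qual)
  writeLines(as.vector(rec), path)
  invisible(path)
}

#' Read a FASTQ file into a read set
#'
#' @param path FASTQ path.
#' @param platform `"short"` or `"long"`.
#' @return A `read_set`. Mate numbers are recovered from `/1`, `/2` id
#'   suffixes when present.
#' @export
read_fastq <- function(path, platform = "short") {
  x <- readLines(path)
  if (length(x) %% 4 != 0) stop("malformed FASTQ: ", path)
  ids <- sub("^@", "", x[seq(1, length(x), 4)])
  ids <- sub("\\s.*$", "", ids)
  mate <- ifelse(grepl("/1$", ids), 1L, ifelse(grepl("/2$", ids), 2L, 0L))
  reads <- data.frame(
    id = ids, seq = x[seq(2, length(x), 4)], qual = x[seq(4, length(x), 4)],
    mate = mate, pair_id = sub("/[12]$", "", ids))
  rownames(reads) <- NULL
  structure(list(reads = reads, platform = platform), class = "read_set")
}
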