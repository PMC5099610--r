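test_that("greedy assembly reconstructs a tiled template exactly", {
  tpl <- random_seq(600, seed = 10)
  starts <- seq(1, 481, by = 60) # 120 bp reads, 50% overlap
  reads <- setNames(substring(tpl, starts, starts + 119),
                    sprintf("r%02d", seq_along(starts)))
  a <- greedy_assemble(reads, min_overlap = 40)
  expect_equal(nrow(a), 1)
  expect_true(a$sequence[1] == tpl || a$sequence[1] == revcomp(tpl))
  # single read assembles to itself
  one <- greedy_assemble(c(solo = substr(tpl, 1, 100)))
  expect_identical(one$sequence, substr(tpl, 1, 100))
  expect_error(greedy_assemble(character(0)), "non-empty")
})

test_that("an exact interspersed repeat longer than the reads breaks contigs", {
  set.seed(11)
  rep_unit <- random_seq(300)
  uA <- random_seq(900); uB <- random_seq(900); uC <- random_seq(900)
  tpl <- paste0(uA, rep_unit, uB, rep_unit, uC)
  starts <- seq(1, nchar(tpl) - 249, by = 10)
  reads <- setNames(substring(tpl, starts, starts + 249),
                    sprintf("r%04d", seq_along(starts)))
  a <- greedy_assemble(reads, min_overlap = 40)
  expect_gt(nrow(a), 1)
})

test_that("assembly is reverse-complement invariant", {
  tpl <- random_seq(3000, seed = 12)
  rs <- simulate_short_reads(c(t = tpl), coverage_x = 25, read_len = 120,
                             frag_mean = 350, err_rate = 0, seed = 4)
  fwd <- greedy_assemble(rs)
  rc_set <- rs
  rc_set$reads$seq <- vapply(rs$reads$seq, revcomp, character(1))
  rev <- greedy_assemble(rc_set)
  canon <- function(s) pmin(s, vapply(s, revcomp, character(1)))
  expect_setequal(canon(fwd$sequence), canon(rev$sequence))
})

test_that("a spanning long read scaffolds two contigs in order", {
  tpl <- random_seq(6000, seed = 13)
  contigs <- c(c1 = substr(tpl, 1, 3000), c2 = substr(tpl, 3501, 6000))
  lr <- c(lr1 = substr(tpl, 2000, 5500))
  sc <- hybrid_scaffold(contigs, lr)
  expect_equal(nrow(sc), 1)
  # reconstructed scaffold matches the truth across the gap
  m <- count_mismatches(sc$sequence[1], tpl)
  expect_lte(as.integer(m), 2)
  # a long read covering <20% of its length on a contig is ignored
  short_hit <- c(lr2 = paste0(substr(tpl, 2900, 3500),
                              random_seq(4000, seed = 14)))
  sc2 <- hybrid_scaffold(contigs, short_hit)
  expect_equal(nrow(sc2), 2)
})

test_that("orientation is recovered for reverse-complemented contigs", {
  tpl <- random_seq(6000, seed = 15)
  contigs <- c(c1 = substr(tpl, 1, 3000),
               c2 = revcomp(substr(tpl, 3201, 6000)))
  lr <- c(lr1 = substr(tpl, 2200, 5600))
  sc <- hybrid_scaffold(contigs, lr)
  expect_equal(nrow(sc), 1)
  s <- sc$sequence[1]
  ok <- min(as.integer(count_mismatches(s, tpl)),
            as.integer(count_mismatches(s, revcomp(tpl))))
  expect_lte(ok, 2)
})

test_that("46 truth fragments chain back into few large scaffolds", {
  gt <- fixture_genome()
  region <- gt$seq # 200 kb
  set.seed(16)
  n <- nchar(region)
  cuts <- sort(c(0, sample(seq(2000, n - 2000, by = 1000), 45), n))
  frags <- substring(region, head(cuts, -1) + 1, tail(cuts, -1))
  names(frags) <- sprintf("frag%02d", seq_along(frags))
  lr <- simulate_long_reads(region, coverage_x = 24, seed = 16)
  sc <- hybrid_scaffold(frags, lr)
  expect_lte(nrow(sc), 5)
  expect_gte(max(sc$length), 0.9 * nchar(region))
})

test_that("zero-coverage splitting cuts chimeras at the junction", {
  a <- random_seq(800, seed = 17)
  b <- random_seq(800, seed = 18)
  foreign <- random_seq(100, seed = 19)
  chimera <- c(chi = paste0(a, foreign, b))
  starts <- seq(1, 701, by = 20) # tiles reach base 800 exactly
  reads <- c(setNames(substring(a, starts, starts + 99),
                      sprintf("ra%02d", seq_along(starts))),
             setNames(substring(b, starts, starts + 99),
                      sprintf("rb%02d", seq_along(starts))))
  val <- validate_and_split(chimera, reads)
  expect_equal(nrow(val), 2)
  expect_true(all(abs(val$length - 800) <= 50))
  expect_true(all(vapply(val$coverage, min, numeric(1)) >= 1))
  # idempotence: a second pass changes nothing
  val2 <- validate_and_split(setNames(val$sequence, val$contig_id), reads)
  expect_identical(val2$sequence, val$sequence)
  # uniform coverage passes through unchanged
  solo <- validate_and_split(c(s = a), reads[seq_along(starts)])
  expect_equal(nrow(solo), 1)
  expect_identical(solo$sequence, a)
})

test_that("markers and BES anchor with the right status and strand", {
  gt <- fixture_genome()
  scaffold <- c(scf = substr(gt$seq, 20001, 120000))
  m <- gt$markers[gt$markers$position_bp > 21000 &
                    gt$markers$position_bp < 115000, ][1, ]
  bes_fwd <- substr(gt$seq, 30001, 30800)
  bes_rev <- revcomp(substr(gt$seq, 99201, 100000))
  queries <- data.frame(
    id = c(m$marker_id, "bX_T7", "bX_SP6", "nowhere"),
    seq = c(m$amplicon, bes_fwd, bes_rev, random_seq(500, seed = 20)),
    type = c("marker", "BES", "BES", "marker"))
  anc <- anchor_sequences(scaffold, queries)
  expect_identical(anc$status[anc$query_id == m$marker_id], "full")
  expect_equal(anc$strand[anc$query_id == m$marker_id], 1)
  expect_identical(anc$status[anc$query_id == "bX_SP6"], "full")
  expect_equal(anc$strand[anc$query_id == "bX_SP6"], -1)
  expect_identical(anc$status[anc$query_id == "nowhere"], "absent")
  # convergent BES pair implies the clone span
  spans <- bes_pair_spans(anc)
  expect_equal(nrow(spans), 1)
  expect_true(spans$convergent)
  expect_equal(spans$span_bp, 70000, tolerance = 0.01)
})

test_that("substitution counting matches planted differences", {
  s <- random_seq(9000, seed = 21)
  expect_equal(as.integer(count_mismatches(s, s)), 0L)
  expect_equal(as.integer(count_mismatches("ACGTACGT", "ACCTACGT")), 1L)
  planted <- s
  pos <- c(500, 1500, 3000, 4500, 6000, 7500, 8900)
  for (p in pos) {
    old <- substr(planted, p, p)
    new <- setdiff(c("A", "C", "G", "T"), old)[1]
    substr(planted, p, p) <- new
  }
  m <- count_mismatches(s, planted)
  expect_equal(as.integer(m), 7L)
  expect_equal(attr(m, "insertions") + attr(m, "deletions"), 0)
  # symmetry
  expect_equal(as.integer(count_mismatches(planted, s)), 7L)
  expect_error(count_mismatches("", "ACGT"), "domain error")
})

test_that("assembly report totals columns and checks the hybrid reduction", {
  pp <- data.frame(pool = c("p1", "p2"),
                   n_scaffolds_miseq = c(10L, 5L), kb_miseq = c(100.0, 50.5),
                   n_scaffolds_hybrid = c(3L, 5L), kb_hybrid = c(120.4, 55.1))
  rep <- assembly_report(pp)
  tot <- rep[rep$pool == "Total", ]
  expect_equal(tot$n_scaffolds_miseq, 15)
  expect_equal(tot$n_scaffolds_hybrid, 8)
  expect_equal(tot$kb_hybrid, 175.5)
  bad <- pp; bad$n_scaffolds_hybrid[1] <- 11L
  expect_error(assembly_report(bad), "exceeds")
  empty <- pool_assembly_stats(NULL)
  expect_equal(unname(empty), c(0, 0))
})
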