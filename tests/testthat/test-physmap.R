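test_that("partial digest clones land on cut sites within the size window", {
  gt <- fixture_genome()
  cl <- fixture_clones()
  expect_equal(nrow(cl), 18)
  expect_true(all(cl$insert_len_bp >= 40000 & cl$insert_len_bp <= 70000))
  expect_true(all(cl$end - cl$start == cl$insert_len_bp))
  # boundaries fall on HindIII sites or the genome ends
  on_site <- function(p) p == 0 || p == gt$length_bp ||
    substr(gt$seq, p + 1, p + 6) == "AAGCTT"
  expect_true(all(vapply(cl$start, on_site, logical(1))))
  expect_true(all(vapply(cl$end, on_site, logical(1))))
  expect_false(anyDuplicated(paste(cl$plate, cl$row, cl$col)) > 0)
})

test_that("requested clone number reproduces the coverage fold", {
  gt <- fixture_genome()
  cl <- fixture_clones()
  # direct base-coverage oracle
  cov <- numeric(gt$length_bp)
  for (i in seq_len(nrow(cl))) {
    cov[(cl$start[i] + 1):cl$end[i]] <- cov[(cl$start[i] + 1):cl$end[i]] + 1
  }
  fold_direct <- mean(cov)
  fold_formula <- nrow(cl) * mean(cl$insert_len_bp) / gt$length_bp
  expect_equal(fold_direct, fold_formula, tolerance = 1e-9)
  requested <- coverage_fold(nrow(cl), mean(cl$insert_len_bp) / 1000,
                             gt$length_bp / 1e6)
  expect_equal(fold_direct, requested, tolerance = 0.1)
})

test_that("an unreachable size window exhausts sampling", {
  gt <- fixture_genome()
  expect_error(
    digest_and_clone(gt, partial_prob = 1, size_window = c(150000, 160000),
                     n_clones = 5, seed = 1),
    "sampling-exhausted")
})

test_that("coverage_fold reproduces the library genome equivalents", {
  expect_equal(coverage_fold(49152, 98, 700), 6.9)
  expect_equal(coverage_fold(35265, 98, 700), 4.9)
  expect_equal(coverage_fold(0, 98, 700), 0.0)
  expect_error(coverage_fold(10, 98, 0), "domain error")
})

test_that("fingerprints are complete-digest band multisets", {
  # toy: 50 kb insert with planted cut sites at 10 kb and 30 kb
  set.seed(5)
  base <- random_seq(50000)
  base <- gsub("GACGT", "GACTT", base, fixed = TRUE) # clear native sites
  substr(base, 10001, 10005) <- "GACGT"
  substr(base, 30001, 30005) <- "GACGT"
  gt <- toy_genome(base)
  cl <- list(clone_id = "c1", start = 0L, end = 50000L)
  fp <- fingerprint_clone(cl, gt, tolerance_bp = 1)
  expect_equal(sort(fp$bands), sort(c(10000L, 20000L, 20000L)))
  # identical clones give identical fingerprints
  fp2 <- fingerprint_clone(list(clone_id = "c2", start = 0L, end = 50000L), gt,
                           tolerance_bp = 1)
  expect_identical(fp$bands, fp2$bands)
})

test_that("overlapping clones share the bands of their overlap", {
  gt <- fixture_genome()
  a <- list(clone_id = "a", start = 10000L, end = 70000L)
  b <- list(clone_id = "b", start = 40000L, end = 100000L)
  fa <- fingerprint_clone(a, gt)
  fb <- fingerprint_clone(b, gt)
  # oracle: fragments lying strictly inside the overlap interval, computed
  # directly from the cut-site positions (boundary fragments are
  # clone-specific and excluded)
  cuts <- Biostrings::start(Biostrings::matchPattern(
    "GACGT", Biostrings::DNAString(gt$seq))) - 1L
  inside <- cuts[cuts >= 40000 & cuts < 70000]
  interior <- as.integer(diff(inside) %/% 3L)
  tab_int <- table(interior)
  tab_a <- table(fa$bands); tab_b <- table(fb$bands)
  common <- intersect(names(tab_a), names(tab_b))
  shared <- sum(pmin(tab_a[common], tab_b[common]))
  expect_gte(shared, sum(tab_int[names(tab_int) %in% common]))
  expect_true(all(names(tab_int) %in% common))
})

test_that("FPC contig building clusters overlapping clones", {
  gt <- fixture_genome()
  cl <- fixture_clones()
  fpc <- fixture_fpc()
  # partition: every clone in exactly one contig
  all_ids <- unlist(lapply(fpc, `[[`, "clone_ids"))
  expect_setequal(all_ids, cl$clone_id)
  expect_equal(length(all_ids), nrow(cl))
  # at ~5x coverage most clones co-assemble
  in_contigs <- sum(vapply(fpc, function(ct)
    if (!ct$is_singleton) length(ct$clone_ids) else 0L, integer(1)))
  expect_gte(in_contigs / nrow(cl), 0.9)
  # CB-unit span calibration within 25% of the truth span
  for (ct in fpc) {
    if (ct$is_singleton) next
    span_kb <- (ct$true_span[2] - ct$true_span[1]) / 1000
    expect_lt(abs(cb_to_kb(ct$cb_units) - span_kb) / span_kb, 0.25)
  }
})

test_that("trivial fingerprint clusterings behave as expected", {
  gt <- fixture_genome()
  two <- data.frame(clone_id = c("x", "y"), start = c(1000L, 21000L),
                    end = c(60000L, 80000L))
  fps <- fingerprint_library(two, gt)
  ct <- build_fpc_contigs(fps, two, min_shared_bands = 10)
  expect_length(ct, 1)
  expect_setequal(ct[[1]]$clone_ids, c("x", "y"))
  disj <- data.frame(clone_id = c("x", "y"), start = c(1000L, 120000L),
                     end = c(60000L, 180000L))
  fps2 <- fingerprint_library(disj, gt)
  ct2 <- build_fpc_contigs(fps2, disj, min_shared_bands = 10)
  expect_length(ct2, 2)
  expect_true(all(vapply(ct2, `[[`, logical(1), "is_singleton")))
})

test_that("greedy MTP selection covers the contig and is minimal", {
  cl <- data.frame(clone_id = c("a", "b", "c"), start = c(0L, 50L, 90L),
                   end = c(100L, 150L, 200L))
  ct <- list(contig_id = "t1", clone_ids = cl$clone_id, cb_units = 10,
             true_span = c(0L, 200L), is_singleton = FALSE)
  tp <- select_mtp(ct, cl)
  expect_identical(tp$clone_ids, c("a", "c"))
  expect_equal(length(tp$clone_ids), brute_min_cover(cl$start, cl$end))
  # single-clone contig selects that clone
  one <- data.frame(clone_id = "solo", start = 0L, end = 10L)
  tp1 <- select_mtp(list(contig_id = "s", clone_ids = "solo", cb_units = 1,
                         true_span = c(0L, 10L), is_singleton = TRUE), one)
  expect_identical(tp1$clone_ids, "solo")
  # disconnected clone set raises a cover-gap error listing the gap
  gap <- data.frame(clone_id = c("a", "b"), start = c(0L, 200L),
                    end = c(100L, 300L))
  expect_error(select_mtp(list(contig_id = "g", clone_ids = c("a", "b"),
                               cb_units = 1, true_span = c(0L, 300L),
                               is_singleton = FALSE), gap),
               "cover-gap error.*\\[100,200\\)")
})

test_that("MTP sizes over the fixture library look like real tiling paths", {
  cl <- fixture_clones()
  fpc <- fixture_fpc()
  sizes <- vapply(fpc, function(ct)
    length(select_mtp(ct, cl)$clone_ids), integer(1))
  expect_true(all(sizes >= 1 & sizes <= 7))
  # selected union equals the full clone union per contig (no new gaps)
  for (ct in fpc) {
    tp <- select_mtp(ct, cl)
    sel <- cl[match(tp$clone_ids, cl$clone_id), ]
    all_iv <- cl[match(ct$clone_ids, cl$clone_id), ]
    cover <- function(d) {
      d <- d[order(d$start), ]
      reach <- d$start[1]
      for (i in seq_len(nrow(d))) {
        expect_lte(d$start[i], reach)
        reach <- max(reach, d$end[i])
      }
      c(d$start[1], reach)
    }
    expect_equal(cover(sel), c(min(all_iv$start), max(all_iv$end)))
  }
})

test_that("physical map unit conversions are linear and match the map", {
  expect_equal(round(cb_to_kb(5177, 1.36), 1), 7040.7)
  expect_equal(cb_to_kb(0, 1.36), 0)
  expect_equal(cb_to_kb(100, 1.36), 136.0)
  expect_equal(cb_to_kb(3 + 4), cb_to_kb(3) + cb_to_kb(4))
  expect_equal(cm_to_mb(97, 3.4), 28.529, tolerance = 1e-4)
  expect_equal(cm_to_mb(0, 3.4), 0)
  expect_equal(cm_to_mb(3.4, 3.4), 1.0)
  expect_equal(cm_to_mb(2 + 5), cm_to_mb(2) + cm_to_mb(5))
  expect_error(cm_to_mb(10, 0), "domain error")
})
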