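make_addressed_clones <- function(n_plates, n_rows, n_cols,
                                  insert = c(0L, 1000L)) {
  grid <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows),
                      plate = seq_len(n_plates))
  data.frame(clone_id = sprintf("c%04d", seq_len(nrow(grid))),
             plate = grid$plate, row = grid$row, col = grid$col,
             start = insert[1], end = insert[2])
}

test_that("the 3D design addresses clones with three pools each", {
  d <- pool_design(100, 16, 24)
  expect_equal(d$n_plates * d$n_rows * d$n_cols, 38400)
  expect_equal(d$n_plates + d$n_rows + d$n_cols, 140)
  cl <- make_addressed_clones(2, 3, 4)
  ps <- build_pools(cl, pool_design(2, 3, 4))
  # every clone appears in exactly its plate, row and column pool
  expect_equal(ncol(ps$membership) - 1L, 3L)
  expect_equal(nrow(ps$membership), 24)
  counts <- table(c(ps$membership$plate_pool, ps$membership$row_pool,
                    ps$membership$col_pool))
  expect_equal(sum(counts), 3 * nrow(cl))
  # degenerate 1x1x1 design
  one <- build_pools(make_addressed_clones(1, 1, 1), pool_design(1, 1, 1))
  expect_equal(nrow(one$membership), 1)
  # address collisions are rejected
  dup <- rbind(cl, cl[1, ])
  expect_error(build_pools(dup, pool_design(2, 3, 4)), "duplicate-address")
})

fixture_screen_setup <- function() {
  gt <- fixture_genome()
  cl <- fixture_clones()
  list(gt = gt, pools = build_pools(cl, pool_design(max(cl$plate), 16, 24)))
}

test_that("noise-free screens light up exactly the true pools", {
  s <- fixture_screen_setup()
  m <- s$gt$markers[1, ]
  cl <- s$pools$clones
  truth <- cl$start <= m$position_bp &
    cl$end >= m$position_bp + nchar(m$amplicon)
  sr <- screen_marker(m, s$pools, fn_rate = 0, fp_rate = 0, seed = 1)
  expect_setequal(sr$positive_plates, unique(cl$plate[truth]))
  expect_setequal(sr$positive_rows, unique(cl$row[truth]))
  expect_setequal(sr$positive_cols, unique(cl$col[truth]))
  # marker absent from every clone: all dimensions empty
  fake <- data.frame(marker_id = "none", position_bp = 0L,
                     amplicon = strrep("A", 5000))
  fake$position_bp <- s$gt$length_bp - 5000L
  sr0 <- screen_marker(fake, s$pools, seed = 1)
  if (!any(cl$start <= fake$position_bp & cl$end >= fake$position_bp + 5000)) {
    expect_length(sr0$positive_plates, 0)
    expect_length(sr0$positive_rows, 0)
    expect_length(sr0$positive_cols, 0)
  }
})

test_that("false-negative flips occur at the configured binomial rate", {
  cl <- make_addressed_clones(4, 4, 4)
  # marker contained in every clone: all 12 pools truly positive
  ps <- build_pools(cl, pool_design(4, 4, 4))
  m <- data.frame(marker_id = "m", position_bp = 100L,
                  amplicon = strrep("A", 50))
  miss <- 0; total <- 0
  for (i in 1:400) {
    sr <- screen_marker(m, ps, fn_rate = 0.05, fp_rate = 0, seed = i)
    pos <- length(sr$positive_plates) + length(sr$positive_rows) +
      length(sr$positive_cols)
    miss <- miss + (12 - pos)
    total <- total + 12
  }
  expect_equal(miss / total, 0.05, tolerance = 0.02 / 0.05)
})

test_that("deconvolution resolves the unique and ambiguous cases", {
  cl <- make_addressed_clones(4, 4, 4)
  ps <- build_pools(cl, pool_design(4, 4, 4))
  res <- structure(list(marker_id = "m", positive_plates = 2L,
                        positive_rows = 3L, positive_cols = 4L,
                        fn_rate = 0, fp_rate = 0, design = ps$design),
                   class = "screen_result")
  dec <- deconvolve(res, ps)
  expect_equal(nrow(dec$confirmed), 1)
  expect_equal(unlist(dec$confirmed[1, c("plate", "row", "col")],
                      use.names = FALSE), c(2L, 3L, 4L))
  expect_equal(nrow(dec$confirmations_needed), 0)
  # 2x2x2 ambiguity: 8 candidates, all to confirmation
  res2 <- structure(list(marker_id = "m", positive_plates = c(1L, 2L),
                         positive_rows = c(1L, 2L), positive_cols = c(1L, 2L),
                         fn_rate = 0, fp_rate = 0, design = ps$design),
                    class = "screen_result")
  dec2 <- deconvolve(res2, ps)
  expect_equal(nrow(dec2$candidates), 8)
  expect_equal(nrow(dec2$confirmations_needed), 8)
  expect_equal(nrow(dec2$confirmed), 0)
  # inconsistent screen: positives in one dimension only
  res3 <- structure(list(marker_id = "m", positive_plates = integer(0),
                         positive_rows = 2L, positive_cols = integer(0),
                         fn_rate = 0, fp_rate = 0, design = ps$design),
                    class = "screen_result")
  expect_warning(dec3 <- deconvolve(res3, ps), "inconsistent-screen")
  expect_equal(nrow(dec3$confirmed), 0)
  expect_equal(nrow(dec3$candidates), 0)
})

test_that("two true clones sharing plate and row deconvolve to both columns", {
  gt <- fixture_genome()
  m <- gt$markers[2, ]
  alen <- nchar(m$amplicon)
  cl <- data.frame(
    clone_id = c("t1", "t2", "far"),
    plate = c(1L, 1L, 2L), row = c(1L, 1L, 2L), col = c(1L, 2L, 3L),
    start = c(m$position_bp - 100L, m$position_bp - 200L, 0L),
    end = c(m$position_bp + alen + 100L, m$position_bp + alen + 200L, 500L))
  ps <- build_pools(cl, pool_design(2, 2, 3))
  sr <- screen_marker(m, ps, seed = 1)
  dec <- deconvolve(sr, ps)
  expect_setequal(dec$candidates$clone_id, c("t1", "t2"))
  hits <- screen_and_resolve(sr, ps, m)
  expect_setequal(hits, c("t1", "t2"))
})

test_that("confirmation plans resolve ambiguity within the candidate count", {
  one <- data.frame(clone_id = "c", plate = 1L, row = 1L, col = 1L)
  expect_equal(nrow(confirmation_plan(one)), 1)
  grid <- expand.grid(plate = 1:2, row = 1:2, col = 1:2)
  grid$clone_id <- sprintf("c%d", 1:8)
  plan <- confirmation_plan(grid)
  expect_equal(nrow(plan), 8)
  # enumerate all C(8,2) 2-positive truths: expected tests to find both
  # positives along the plan is below exhaustive testing of all 8
  need <- vapply(utils::combn(8, 2, simplify = FALSE), function(tr) {
    max(match(grid$clone_id[tr], plan$clone_id))
  }, numeric(1))
  expect_lt(mean(need), 8)
})

test_that("screening a ~5x library finds about coverage-many clones per marker", {
  gt <- fixture_genome()
  means <- vapply(c(7, 8, 9), function(sd) {
    cl <- digest_and_clone(gt, partial_prob = 0.06,
                           size_window = c(40000, 70000), n_clones = 18,
                           seed = sd)
    ps <- build_pools(cl, pool_design(max(cl$plate), 16, 24))
    hits <- vapply(seq_len(nrow(gt$markers)), function(i) {
      m <- gt$markers[i, ]
      sr <- screen_marker(m, ps, seed = i)
      length(screen_and_resolve(sr, ps, m))
    }, numeric(1))
    mean(hits)
  }, numeric(1))
  fold <- coverage_fold(18, 55, 0.2) # ~4.9x
  expect_true(all(means >= 2 & means <= 7))
  expect_equal(mean(means), fold, tolerance = 0.35)
})

test_that("raising the false-negative rate cannot inflate recovered sets", {
  s <- fixture_screen_setup()
  m <- s$gt$markers[3, ]
  n_found <- function(fn) {
    mean(vapply(1:100, function(i) {
      sr <- screen_marker(m, s$pools, fn_rate = fn, seed = 1000 + i)
      length(suppressWarnings(screen_and_resolve(sr, s$pools, m)))
    }, numeric(1)))
  }
  expect_gte(n_found(0), n_found(0.15))
  expect_gte(n_found(0.15), n_found(0.5))
})
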