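#' Define a three-dimensional BAC pool design
#'
#' A 3D pool set collapses a plate x row x column clone library into
#' `n_plates + n_rows + n_cols` superpools, so a PCR-positive clone is
#' located by the intersection of its positive plate, row and column
#' pools. The default geometry (100 plates, 16 rows, 24 columns) addresses
#' 38,400 clones with 140 PCR reactions per marker.
#'
#' @param n_plates,n_rows,n_cols Pool counts along each axis (>= 1).
#' @return A list of class `pool_design`.
#' @export
#' @examples
#' d <- pool_design()
#' d$n_plates * d$n_rows * d$n_cols # 38400 addressable clones
pool_design <- function(n_plates = 100, n_rows = 16, n_cols = 24) {
  if (n_plates < 1 || n_rows < 1 || n_cols < 1) stop("all dimensions must be >= 1")
  structure(list(n_plates = as.integer(n_plates), n_rows = as.integer(n_rows),
                 n_cols = as.integer(n_cols)), class = "pool_design")
}

#' Build the 3D pool set for a clone library
#'
#' Each clone joins exactly three pools: its plate pool, row pool and
#' column pool. Addresses must be unique and fit the design.
#'
#' @param clones A `bac_clones` data frame with `plate`, `row`, `col`.
#' @param design A [pool_design()].
#' @return A list of class `pool_set` with the design, the clone address
#'   table, and `membership` (clone -> its three pool labels).
#' @export
build_pools <- function(clones, design) {
  stopifnot(inherits(design, "pool_design"))
  addr <- paste(clones$plate, clones$row, clones$col, sep = "/")
  if (anyDuplicated(addr)) {
    stop("duplicate-address error: ", addr[duplicated(addr)][1])
  }
  if (any(clones$plate < 1 | clones$plate > design$n_plates |
          clones$row < 1 | clones$row > design$n_rows |
          clones$col < 1 | clones$col > design$n_cols)) {
    stop("clone address outside the pool design")
  }
  membership <- data.frame(
    clone_id = clones$clone_id,
    plate_pool = sprintf("P%03d", clones$plate),
    row_pool = sprintf("R%02d", clones$row),
    col_pool = sprintf("C%02d", clones$col))
  structure(list(design = design, clones = clones, membership = membership),
            class = "pool_set")
}

#' @export
print.pool_set <- function(x, ...) {
  d <- x$design
  cat(sprintf(
    "pool_set: %d clones in %d pools (%d plate + %d row + %d col), %s addresses\n",
    nrow(x$clones), d$n_plates + d$n_rows + d$n_cols, d$n_plates, d$n_rows,
    d$n_cols, format(d$n_plates * d$n_rows * d$n_cols, big.mark = ",")))
  invisible(x)
}

#' Screen a marker against the 3D pools
#'
#' A pool is truly positive iff at least one member clone's insert interval
#' fully contains the marker's amplicon template. Observed calls apply
#' independent per-pool false-negative and false-positive flips under the
#' seed, modeling a binary PCR call.
#'
#' @param marker One row of a genome-truth `markers` table (needs
#'   `marker_id`, `position_bp`, `amplicon`).
#' @param pools A `pool_set`.
#' @param fn_rate,fp_rate Per-pool flip rates in `[0, 1)`.
#' @param seed Integer seed.
#' @return A list of class `screen_result` with `marker_id`,
#'   `positive_plates`, `positive_rows`, `positive_cols` (integer index
#'   sets) and the rates used.
#' @export
screen_marker <- function(marker, pools, fn_rate = 0, fp_rate = 0, seed = 1) {
  stopifnot(inherits(pools, "pool_set"))
  if (fn_rate < 0 || fn_rate >= 1 || fp_rate < 0 || fp_rate >= 1) {
    stop("rates must be in [0, 1)")
  }
  set.seed(seed)
  cl <- pools$clones
  amp_start <- marker$position_bp
  amp_end <- amp_start + nchar(marker$amplicon)
  hit <- cl$start <= amp_start & cl$end >= amp_end
  call_dim <- function(truth_idx, n) {
    true_pos <- logical(n)
    true_pos[truth_idx] <- TRUE
    obs <- true_pos
    flips_fn <- runif(n) < fn_rate
    flips_fp <- runif(n) < fp_rate
    obs[true_pos & flips_fn] <- FALSE
    obs[!true_pos & flips_fp] <- TRUE
    which(obs)
  }
  d <- pools$design
  structure(list(
    marker_id = marker$marker_id,
    positive_plates = call_dim(unique(cl$plate[hit]), d$n_plates),
    positive_rows = call_dim(unique(cl$row[hit]), d$n_rows),
    positive_cols = call_dim(unique(cl$col[hit]), d$n_cols),
    fn_rate = fn_rate, fp_rate = fp_rate, design = d
  ), class = "screen_result")
}

#' Deconvolve a 3D screen back to clone addresses
#'
#' Candidates are the Cartesian product of the positive plate, row and
#' column index sets, intersected with the occupied addresses of the
#' library. When each dimension has exactly one positive pool the unique
#' candidate is confirmed directly; otherwise all candidates require a
#' confirmation PCR round. An inconsistent screen (some dimensions empty
#' while others are not, or a product with no occupied address) emits a
#' structured warning and an empty result, mirroring markers that fail to
#' amplify.
#'
#' @param result A `screen_result`.
#' @param pools The `pool_set` that was screened.
#' @return A list of class `deconvolution_result` with `marker_id`,
#'   `confirmed` and `candidates` (data frames of addresses with clone
#'   ids) and `confirmations_needed` (the candidate addresses to re-test,
#'   ordered by [confirmation_plan()]).
#' @export
deconvolve <- function(result, pools) {
  stopifnot(inherits(result, "screen_result"), inherits(pools, "pool_set"))
  cl <- pools$clones
  empty <- data.frame(clone_id = character(0), plate = integer(0),
                      row = integer(0), col = integer(0))
  np <- length(result$positive_plates)
  nr <- length(result$positive_rows)
  nc <- length(result$positive_cols)
  dims_present <- c(np, nr, nc) > 0
  out <- function(confirmed, candidates) {
    plan <- if (nrow(candidates)) confirmation_plan(candidates) else candidates
    structure(list(marker_id = result$marker_id, confirmed = confirmed,
                   candidates = candidates, confirmations_needed = plan),
              class = "deconvolution_result")
  }
  if (!all(dims_present)) {
    if (any(dims_present)) {
      warning("inconsistent-screen warning: marker ", result$marker_id,
              " positive in ", sum(dims_present), "/3 dimensions only")
    }
    return(out(empty, empty))
  }
  # deterministic iteration order: plate, then row, then column
  grid <- expand.grid(col = sort(result$positive_cols),
                      row = sort(result$positive_rows),
                      plate = sort(result$positive_plates))
  grid <- grid[order(grid$plate, grid$row, grid$col), c("plate", "row", "col")]
  key <- paste(grid$plate, grid$row, grid$col, sep = "/")
  ckey <- paste(cl$plate, cl$row, cl$col, sep = "/")
  occ <- match(key, ckey)
  cand <- data.frame(clone_id = cl$clone_id[occ[!is.na(occ)]],
                     grid[!is.na(occ), , drop = FALSE])
  rownames(cand) <- NULL
  if (!nrow(cand)) {
    warning("inconsistent-screen warning: marker ", result$marker_id,
            " has no occupied address in the positive product")
    return(out(empty, empty))
  }
  if (np == 1 && nr == 1 && nc == 1) {
    return(out(cand, empty))
  }
  out(empty, cand)
}

#' Order candidate addresses for confirmation PCR
#'
#' Heuristic priority for the follow-up round: candidates sharing the most
#' plate/row/column indices with other candidates are tested first, since
#' their truth value constrains the most remaining address combinations.
#' Ties resolve in plate, row, column order, so plans are reproducible.
#' This planning step is an artifact addition; the screening study it
#' emulates does not state a prioritization.
#'
#' @param candidates Data frame with `plate`, `row`, `col` (and optionally
#'   `clone_id`).
#' @return The same data frame, reordered; at most one test per candidate.
#' @export
confirmation_plan <- function(candidates) {
  if (!nrow(candidates)) return(candidates)
  score <- vapply(seq_len(nrow(candidates)), function(i) {
    sum(candidates$plate == candidates$plate[i]) +
      sum(candidates$row == candidates$row[i]) +
      sum(candidates$col == candidates$col[i]) - 3L
  }, integer(1))
  ord <- order(-score, candidates$plate, candidates$row, candidates$col)
  res <- candidates[ord, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Resolve a screen to true positive clones via confirmation
#'
#' Convenience wrapper: runs [deconvolve()], then (error-free) confirmation
#' PCR on `confirmations_needed` against the truth -- a candidate is
#' positive iff its clone really contains the marker amplicon.
#'
#' @inheritParams deconvolve
#' @param marker The marker row screened (for the truth lookup).
#' @return Character vector of confirmed positive clone ids.
#' @export
screen_and_resolve <- function(result, pools, marker) {
  dec <- deconvolve(result, pools)
  cl <- pools$clones
  amp_start <- marker$position_bp
  amp_end <- amp_start + nchar(marker$amplicon)
  truly <- function(ids) {
    i <- match(ids, cl$clone_id)
    ids[cl$start[i] <= amp_start & cl$end[i] >= amp_end]
  }
  c(dec$confirmed$clone_id, truly(dec$confirmations_needed$clone_id))
}
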