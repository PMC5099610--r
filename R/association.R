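#' Simulate a multi-family cross with genotypes and growth traits
#'
#' Emulates a mass-cross batch: a parent pool (3 sires x 5 dams by
#' default) receives alleles at each SNP by its population alt-allele
#' frequency; each family is a sire x dam pair contributing a configurable
#' (possibly very uneven) share of the offspring; offspring genotypes are
#' Mendelian draws from the parents. Traits are
#' `mu + family effect + sum(additive effect x alt-allele count) + noise`,
#' for body weight (BW, g), total length (TL, cm) and standard length
#' (SL, cm).
#'
#' @param n_families Number of full-sib families.
#' @param n_offspring Total offspring across families.
#' @param snps Data frame with `snp_id`, `alt_freq`, `effect_bw`,
#'   `effect_tl`, `effect_sl` (e.g. a genome truth's `snps` table). Effects
#'   are per alt allele in trait units.
#' @param family_weights Offspring share per family; defaults emulate two
#'   dominant families (62.1% and 27.3%) plus a small remainder split.
#' @param family_sd Between-family standard deviation, expressed per trait
#'   as a fraction of `trait_sd`.
#' @param residual_sd Residual standard deviation as a fraction of
#'   `trait_sd` (the two fractions need not sum to 1).
#' @param trait_mean,trait_sd Named vectors (BW, TL, SL) of trait means and
#'   scale units; defaults are plausible grow-out values.
#' @param monomorphic Optional character vector of `snp_id`s forced
#'   monomorphic (all parents homozygous reference), emulating a locus
#'   that segregates in one batch but not another.
#' @param seed Integer seed.
#' @return List with `genotypes` (individual_id, family_id, snp_id,
#'   allele1, allele2) and `traits` (individual_id, family_id, BW, TL, SL,
#'   age_mph).
#' @export
simulate_cross <- function(n_families = 5, n_offspring = 570, snps,
                           family_weights = c(0.621, 0.273, 0.05, 0.03, 0.026),
                           family_sd = 0.3, residual_sd = 1,
                           trait_mean = c(BW = 500, TL = 33, SL = 27),
                           trait_sd = c(BW = 80, TL = 3.5, SL = 3),
                           monomorphic = character(0), seed = 1) {
  stopifnot(n_families >= 1, n_offspring >= 1, nrow(snps) >= 1)
  if (length(family_weights) != n_families) {
    family_weights <- rep(1 / n_families, n_families)
  }
  set.seed(seed)
  family_weights <- family_weights / sum(family_weights)
  fam_n <- diff(round(cumsum(c(0, family_weights)) * n_offspring))
  fam_n[n_families] <- n_offspring - sum(fam_n[-n_families])

  n_sires <- min(3, n_families)
  n_dams <- n_families
  draw_parent <- function(freq) {
    matrix(runif(2) < freq, ncol = 2) # TRUE = alt allele
  }
  sires <- lapply(seq_len(n_sires), function(i) {
    t(vapply(seq_len(nrow(snps)), function(s) {
      if (snps$snp_id[s] %in% monomorphic) c(FALSE, FALSE)
      else runif(2) < snps$alt_freq[s]
    }, logical(2)))
  })
  dams <- lapply(seq_len(n_dams), function(i) {
    t(vapply(seq_len(nrow(snps)), function(s) {
      if (snps$snp_id[s] %in% monomorphic) c(FALSE, FALSE)
      else runif(2) < snps$alt_freq[s]
    }, logical(2)))
  })
  pairs <- data.frame(sire = rep(seq_len(n_sires), length.out = n_families),
                      dam = seq_len(n_dams))

  geno_rows <- vector("list", n_families)
  trait_rows <- vector("list", n_families)
  traits <- c("BW", "TL", "SL")
  eff <- as.matrix(snps[, c("effect_bw", "effect_tl", "effect_sl")])
  colnames(eff) <- traits
  S <- nrow(snps)
  ind0 <- 0
  for (f in seq_len(n_families)) {
    nf <- fam_n[f]
    if (nf < 1) next
    fam_eff <- rnorm(3, 0, family_sd * trait_sd[traits])
    s_g <- sires[[pairs$sire[f]]]
    d_g <- dams[[pairs$dam[f]]]
    # one random allele from each parent per offspring per SNP
    a1 <- matrix(s_g[cbind(rep(seq_len(S), nf),
                           sample(1:2, S * nf, TRUE))], nrow = S)
    a2 <- matrix(d_g[cbind(rep(seq_len(S), nf),
                           sample(1:2, S * nf, TRUE))], nrow = S)
    iid <- sprintf("ind%04d", ind0 + seq_len(nf))
    fid <- sprintf("fam%d", f)
    geno_rows[[f]] <- data.frame(
      individual_id = rep(iid, each = S), family_id = fid,
      snp_id = rep(snps$snp_id, nf),
      allele1 = ifelse(as.vector(a1), snps$alt_allele, snps$ref_allele),
      allele2 = ifelse(as.vector(a2), snps$alt_allele, snps$ref_allele))
    alt_count <- a1 + a2 # S x nf
    tv <- matrix(trait_mean[traits], nf, 3, byrow = TRUE) +
      matrix(fam_eff, nf, 3, byrow = TRUE) +
      t(alt_count) %*% eff +
      matrix(rnorm(3 * nf), nf, 3) %*% diag(residual_sd * trait_sd[traits])
    trait_rows[[f]] <- data.frame(
      individual_id = iid, family_id = fid,
      BW = tv[, 1], TL = tv[, 2], SL = tv[, 3], age_mph = 7)
    ind0 <- ind0 + nf
  }
  genotypes <- do.call(rbind, geno_rows)
  traits_df <- do.call(rbind, trait_rows)
  rownames(genotypes) <- rownames(traits_df) <- NULL
  list(genotypes = genotypes, traits = traits_df)
}

genotype_string <- function(allele1, allele2) {
  paste0(pmin(allele1, allele2), pmax(allele1, allele2))
}

#' Genotype and allele frequencies at a SNP
#'
#' @param genotypes Genotype table (`individual_id`, `snp_id`, `allele1`,
#'   `allele2`).
#' @param snp_id SNP to tabulate.
#' @return List with data frames `genotype` (`genotype`, `count`, `freq`)
#'   and `allele` (`allele`, `count`, `freq`); each `freq` column sums
#'   to 1.
#' @export
#' @examples
#' g <- data.frame(individual_id = 1:4, snp_id = "s",
#'                 allele1 = c("C","C","C","T"), allele2 = c("C","T","T","T"))
#' genotype_and_allele_freqs(g, "s")
genotype_and_allele_freqs <- function(genotypes, snp_id) {
  g <- genotypes[genotypes$snp_id == snp_id, , drop = FALSE]
  if (!nrow(g)) stop("missing-locus error: no genotypes for ", snp_id)
  gt <- table(genotype_string(g$allele1, g$allele2))
  al <- table(c(g$allele1, g$allele2))
  list(
    genotype = data.frame(genotype = names(gt), count = as.integer(gt),
                          freq = as.numeric(gt) / sum(gt)),
    allele = data.frame(allele = names(al), count = as.integer(al),
                        freq = as.numeric(al) / sum(al)))
}

# Compact letter display from a pairwise p-value matrix (sweep-and-split):
# start from one set holding every group; for each significantly different
# pair, split any set containing both into two sets omitting one member
# each; drop sets contained in others. Groups then share a letter iff no
# significant difference separates them.
cld_letters <- function(pmat, alpha) {
  groups <- rownames(pmat)
  sets <- list(groups)
  for (i in seq_along(groups)) {
    for (j in seq_along(groups)) {
      if (j <= i) next
      if (is.na(pmat[i, j]) || pmat[i, j] > alpha) next
      a <- groups[i]; b <- groups[j]
      new_sets <- list()
      for (s in sets) {
        if (a %in% s && b %in% s) {
          new_sets <- c(new_sets, list(setdiff(s, a)), list(setdiff(s, b)))
        } else {
          new_sets <- c(new_sets, list(s))
        }
      }
      keep <- rep(TRUE, length(new_sets))
      for (x in seq_along(new_sets)) {
        for (y in seq_along(new_sets)) {
          if (x == y || !keep[y]) next
          sx <- new_sets[[x]]; sy <- new_sets[[y]]
          redundant <- length(sx) == 0 ||
            (all(sx %in% sy) && (length(sy) > length(sx) || y < x))
          if (redundant) { keep[x] <- FALSE; break }
        }
      }
      sets <- new_sets[keep]
    }
  }
  # stable letter order: sets sorted by their first group's position
  ord <- order(vapply(sets, function(s) min(match(s, groups)), numeric(1)))
  sets <- sets[ord]
  out <- setNames(rep("", length(groups)), groups)
  for (k in seq_along(sets)) {
    for (g in sets[[k]]) out[g] <- paste0(out[g], letters[k])
  }
  out
}

#' Associate a SNP genotype with a growth trait
#'
#' Two genotype classes: two-sample t-test (pooled variance by default,
#' the classical Prism-era choice; Welch behind `var_equal = FALSE`).
#' Three classes: one-way ANOVA; if the F test is significant at `alpha`,
#' Tukey HSD pairwise comparisons summarized as a compact letter display
#' (genotypes sharing a letter do not differ at `alpha`). Classes with
#' fewer than 2 individuals are dropped; fewer than two remaining classes
#' is a monomorphic error.
#'
#' @param genotypes,traits Tables as returned by [simulate_cross()] (or
#'   read via [read_genotypes()] / [read_traits()]).
#' @param snp_id SNP to test.
#' @param trait One of `"BW"`, `"TL"`, `"SL"` (or any numeric column of
#'   `traits`).
#' @param alpha Significance level.
#' @param var_equal Pooled-variance t-test if `TRUE`.
#' @return A list of class `association_result`: `snp_id`, `trait`, `test`
#'   (`"t"` or `"anova"`), `statistic`, `p_value`, `groups` (per-genotype
#'   n, mean, sd, letter), `significant`.
#' @export
associate <- function(genotypes, traits, snp_id, trait, alpha = 0.05,
                      var_equal = TRUE) {
  g <- genotypes[genotypes$snp_id == snp_id, , drop = FALSE]
  if (!nrow(g)) stop("missing-locus error: no genotypes for ", snp_id)
  gt <- setNames(genotype_string(g$allele1, g$allele2), g$individual_id)
  y <- traits[[trait]][match(names(gt), traits$individual_id)]
  ok <- !is.na(y)
  gt <- gt[ok]; y <- y[ok]
  counts <- table(gt)
  keep <- names(counts)[counts >= 2]
  if (length(keep) < 2) {
    stop("monomorphic error: fewer than two genotype classes with n >= 2 at ",
         snp_id)
  }
  sel <- gt %in% keep
  gt <- factor(gt[sel]); y <- y[sel]
  if (all(vapply(split(y, gt), function(v) stats::var(v) == 0, logical(1)))) {
    stop("degenerate-variance error: zero within-group variance at ", snp_id)
  }
  grp <- data.frame(
    genotype = levels(gt),
    n = as.integer(table(gt)),
    mean = as.numeric(tapply(y, gt, mean)),
    sd = as.numeric(tapply(y, gt, sd)))
  if (nlevels(gt) == 2) {
    tt <- t.test(y ~ gt, var.equal = var_equal)
    stat <- unname(tt$statistic)
    p <- tt$p.value
    grp$letter <- if (p < alpha) c("a", "b") else c("a", "a")
    test <- "t"
  } else {
    fit <- aov(y ~ gt)
    av <- anova(fit)
    stat <- av[["F value"]][1]
    p <- av[["Pr(>F)"]][1]
    if (!is.na(p) && p < alpha) {
      tk <- TukeyHSD(fit)$gt
      pmat <- matrix(NA_real_, nlevels(gt), nlevels(gt),
                     dimnames = list(levels(gt), levels(gt)))
      for (r in rownames(tk)) {
        ab <- strsplit(r, "-", fixed = TRUE)[[1]]
        pmat[ab[1], ab[2]] <- pmat[ab[2], ab[1]] <- tk[r, "p adj"]
      }
      diag(pmat) <- 1
      grp$letter <- unname(cld_letters(pmat, alpha)[grp$genotype])
    } else {
      grp$letter <- "a"
    }
    test <- "anova"
  }
  structure(list(snp_id = snp_id, trait = trait, test = test,
                 statistic = stat, p_value = p, groups = grp,
                 alpha = alpha, significant = p < alpha),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("%s ~ %s: %s = %.3f, p = %.4g%s\n", x$trait, x$snp_id,
              if (x$test == "t") "t" else "F", x$statistic, x$p_value,
              if (x$significant) " *" else ""))
  print(x$groups, row.names = FALSE)
  invisible(x)
}

#' Replicate an association within each family
#'
#' Runs [associate()] inside every family with at least `min_family_n`
#' genotyped individuals and flags concordance: whether the ordering of
#' genotype means (by alt-allele count where resolvable, else
#' lexicographic genotype) matches the pooled analysis. Families below
#' the size threshold are skipped with a log entry in the `skipped`
#' attribute.
#'
#' @inheritParams associate
#' @param min_family_n Minimum genotyped individuals per family.
#' @return List of per-family results: `family_id`, `result`
#'   (`association_result` or error message), `concordant` (logical).
#' @export
per_family_replication <- function(genotypes, traits, snp_id, trait,
                                   min_family_n = 30, alpha = 0.05) {
  pooled <- associate(genotypes, traits, snp_id, trait, alpha = alpha)
  pooled_order <- pooled$groups$genotype[order(pooled$groups$mean)]
  fams <- unique(genotypes$family_id)
  skipped <- character(0)
  out <- list()
  for (f in fams) {
    gi <- genotypes[genotypes$family_id == f, , drop = FALSE]
    n <- length(unique(gi$individual_id[gi$snp_id == snp_id]))
    if (n < min_family_n) {
      skipped <- c(skipped, sprintf("%s: n = %d < %d", f, n, min_family_n))
      next
    }
    res <- tryCatch(
      associate(gi, traits[traits$family_id == f, , drop = FALSE],
                snp_id, trait, alpha = alpha),
      error = function(e) conditionMessage(e))
    conc <- NA
    if (inherits(res, "association_result")) {
      shared <- intersect(pooled_order, res$groups$genotype)
      if (length(shared) >= 2) {
        fam_order <- res$groups$genotype[order(res$groups$mean)]
        conc <- identical(shared[order(match(shared, pooled_order))],
                          shared[order(match(shared, fam_order))])
      }
    }
    out[[f]] <- list(family_id = f, result = res, concordant = conc)
  }
  attr(out, "skipped") <- skipped
  attr(out, "pooled") <- pooled
  out
}

#' Efficiency-corrected relative expression ratio
#'
#' Relative expression from amplification efficiencies and crossing-point
#' differences only: `E_target^dCt_target / E_ref^dCt_ref`, with
#' `dCt = Ct(calibrator) - Ct(sample)` (a positive dCt means the sample
#' crosses earlier than the calibrator, i.e. higher expression).
#'
#' @param E_target,E_ref Amplification efficiencies in `(1, 2]` (2 =
#'   perfect doubling).
#' @param dCt_target,dCt_ref Crossing-point differences
#'   (calibrator - sample) for target and reference gene.
#' @return The expression ratio.
#' @export
#' @examples
#' pfaffl_ratio(2, 3, 2, 0) # 8
pfaffl_ratio <- function(E_target, dCt_target, E_ref, dCt_ref) {
  if (any(c(E_target, E_ref) <= 1) || any(c(E_target, E_ref) > 2)) {
    stop("domain error: efficiencies must be in (1, 2]")
  }
  E_target^dCt_target / E_ref^dCt_ref
}

#' Contrast expression ratios between two groups
#'
#' Two-sample t-test on log-ratios between (e.g.) fast- and slow-growing
#' individuals; the direction is the sign of the mean log-ratio
#' difference (`+1` = first group higher).
#'
#' @param ratios_fast,ratios_slow Positive expression ratios, >= 2
#'   replicates each.
#' @param alpha Significance level.
#' @return List `direction` (-1/0/+1), `p_value`, `significant`.
#' @export
expression_contrast <- function(ratios_fast, ratios_slow, alpha = 0.05) {
  if (length(ratios_fast) < 2 || length(ratios_slow) < 2) {
    stop("precondition error: need >= 2 replicates per group")
  }
  lf <- log(ratios_fast); ls <- log(ratios_slow)
  if (stats::var(lf) == 0 && stats::var(ls) == 0) {
    if (mean(lf) == mean(ls)) {
      return(list(direction = 0, p_value = 1, significant = FALSE))
    }
    stop("degenerate-variance error: identical replicates in both groups")
  }
  tt <- t.test(lf, ls, var.equal = TRUE)
  list(direction = sign(mean(lf) - mean(ls)), p_value = tt$p.value,
       significant = tt$p.value < alpha)
}

#' Read genotype / trait tables from disk
#'
#' `read_genotypes()` expects columns `individual_id`, `family_id`,
#' `snp_id`, `allele1`, `allele2`; `read_traits()` expects
#' `individual_id`, `family_id`, `BW`, `TL`, `SL` (and optionally
#' `age_mph`). Both accept TSV or CSV by extension.
#'
#' @param path File path.
#' @return The table as a data frame.
#' @export
read_genotypes <- function(path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  read.delim(path, sep = sep, stringsAsFactors = FALSE)
}

#' @rdname read_genotypes
#' @export
read_traits <- read_genotypes

#' Table-2-style association report for a set of SNPs
#'
#' For each SNP x trait: genotype counts and frequencies, allele
#' frequencies, per-genotype mean +- sd with Tukey letters, and the
#' overall p-value. No multiple-testing correction is applied (the number
#' of uncorrected tests is reported so users can apply their own).
#'
#' @param genotypes,traits Tables as in [associate()].
#' @param snp_ids SNPs to test (default: all in `genotypes`).
#' @param trait_names Trait columns to test.
#' @param alpha Significance level.
#' @return List with `table` (long-format report data frame) and
#'   `n_tests` (uncorrected test count).
#' @export
association_report <- function(genotypes, traits, snp_ids = NULL,
                               trait_names = c("BW", "TL", "SL"),
                               alpha = 0.05) {
  snp_ids <- snp_ids %||% unique(genotypes$snp_id)
  rows <- list()
  n_tests <- 0
  for (s in snp_ids) {
    fr <- genotype_and_allele_freqs(genotypes, s)
    for (tr in trait_names) {
      res <- tryCatch(associate(genotypes, traits, s, tr, alpha = alpha),
                      error = function(e) NULL)
      if (is.null(res)) next
      n_tests <- n_tests + 1
      gfr <- fr$genotype$freq[match(res$groups$genotype, fr$genotype$genotype)]
      rows[[length(rows) + 1]] <- data.frame(
        snp_id = s, trait = tr, genotype = res$groups$genotype,
        n = res$groups$n, genotype_freq = round(gfr, 3),
        mean = round(res$groups$mean, 2), sd = round(res$groups$sd, 2),
        letter = res$groups$letter, p_value = res$p_value,
        significant = res$significant)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else data.frame()
  rownames(tab) <- NULL
  list(table = tab, n_tests = n_tests)
}
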