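one_snp <- function(alt_freq = 0.3, eff = 0) {
  data.frame(snp_id = "s1", gene_id = "g", position_bp = 100L,
             ref_allele = "C", alt_allele = "T",
             effect_bw = eff * 80, effect_tl = eff * 3.5, effect_sl = eff * 3,
             alt_freq = alt_freq)
}

test_that("simulated crosses segregate Mendelian genotypes", {
  cross <- simulate_cross(n_families = 5, n_offspring = 200,
                          snps = one_snp(0.4), seed = 2)
  expect_equal(nrow(cross$genotypes), 200)
  expect_equal(nrow(cross$traits), 200)
  expect_true(all(cross$genotypes$allele1 %in% c("C", "T")))
  fam_sizes <- table(cross$traits$family_id)
  expect_equal(unname(sort(fam_sizes, decreasing = TRUE)[1]) / 200, 0.621,
               tolerance = 0.02)
  # forced-monomorphic locus yields one genotype class and associate errors
  mono <- simulate_cross(n_families = 2, n_offspring = 50,
                         snps = one_snp(), monomorphic = "s1", seed = 3)
  expect_true(all(mono$genotypes$allele1 == "C" & mono$genotypes$allele2 == "C"))
  expect_error(associate(mono$genotypes, mono$traits, "s1", "BW"),
               "monomorphic error")
})

test_that("genotype and allele frequencies are counted and normalized", {
  g <- data.frame(individual_id = sprintf("i%03d", 1:100),
                  family_id = "f", snp_id = "s1",
                  allele1 = rep(c("C", "C"), each = 50),
                  allele2 = rep(c("C", "T"), each = 50))
  fr <- genotype_and_allele_freqs(g, "s1")
  expect_equal(fr$genotype$freq[fr$genotype$genotype == "CC"], 0.5)
  expect_equal(fr$genotype$freq[fr$genotype$genotype == "CT"], 0.5)
  expect_equal(fr$allele$freq[fr$allele$allele == "C"], 0.75)
  expect_equal(fr$allele$freq[fr$allele$allele == "T"], 0.25)
  one <- genotype_and_allele_freqs(
    data.frame(individual_id = "i1", family_id = "f", snp_id = "s1",
               allele1 = "A", allele2 = "A"), "s1")
  expect_equal(one$genotype$freq, 1)
  expect_equal(one$allele$freq, 1)
  expect_error(genotype_and_allele_freqs(g, "zzz"), "missing-locus")
  # normalization property over random tables
  set.seed(9)
  for (i in 1:10) {
    n <- sample(5:50, 1)
    gi <- data.frame(individual_id = sprintf("i%03d", 1:n), family_id = "f",
                     snp_id = "s1",
                     allele1 = sample(c("A", "G"), n, TRUE),
                     allele2 = sample(c("A", "G"), n, TRUE))
    fri <- genotype_and_allele_freqs(gi, "s1")
    expect_equal(sum(fri$genotype$freq), 1)
    expect_equal(sum(fri$allele$freq), 1)
  }
})

geno_table <- function(gts) {
  data.frame(individual_id = sprintf("i%03d", seq_along(gts)),
             family_id = "f", snp_id = "s1",
             allele1 = substr(gts, 1, 1), allele2 = substr(gts, 2, 2))
}

trait_table <- function(y) {
  data.frame(individual_id = sprintf("i%03d", seq_along(y)), family_id = "f",
             BW = y, TL = y, SL = y, age_mph = 9)
}

test_that("two-genotype association is the pooled t-test", {
  # identical group means and variances: t = 0, p = 1
  g <- geno_table(rep(c("CC", "CT"), each = 4))
  y <- rep(c(1, 2, 3, 4), 2)
  res <- associate(g, trait_table(y), "s1", "BW")
  expect_equal(res$test, "t")
  expect_equal(unname(res$statistic), 0)
  expect_equal(res$p_value, 1)
  # hand-computed pooled t on known values
  y1 <- c(5.1, 4.8, 5.5, 5.0, 4.9, 5.3, 5.2, 4.7, 5.4, 5.0)
  y2 <- c(5.9, 6.1, 5.7, 6.3, 5.8, 6.0, 6.2, 5.6, 6.4, 5.95)
  g2 <- geno_table(rep(c("CC", "TT"), each = 10))
  res2 <- associate(g2, trait_table(c(y1, y2)), "s1", "BW")
  sp2 <- ((10 - 1) * var(y1) + (10 - 1) * var(y2)) / (10 + 10 - 2)
  t_hand <- (mean(y1) - mean(y2)) / sqrt(sp2 * (1 / 10 + 1 / 10))
  p_hand <- 2 * pt(-abs(t_hand), df = 18)
  expect_equal(unname(res2$statistic), t_hand, tolerance = 1e-6)
  expect_equal(res2$p_value, p_hand, tolerance = 1e-6)
  expect_true(res2$significant)
  expect_identical(sort(res2$groups$letter), c("a", "b"))
})

test_that("ANOVA F equals squared t when only two classes remain", {
  set.seed(10)
  y <- c(rnorm(12, 10, 1), rnorm(12, 11, 1), rnorm(1, 50, 1))
  g <- geno_table(c(rep("AA", 12), rep("AT", 12), "TT"))
  # the single TT fish is dropped (class n < 2) -> pooled t-test
  res <- associate(g, trait_table(y), "s1", "BW")
  expect_equal(res$test, "t")
  f <- anova(aov(y[1:24] ~ factor(rep(c("AA", "AT"), each = 12))))$`F value`[1]
  expect_equal(unname(res$statistic)^2, f, tolerance = 1e-9)
})

test_that("Tukey letters agree with the pairwise comparisons", {
  set.seed(11)
  for (i in 1:25) {
    mu <- sample(0:3, 3, replace = TRUE)
    y <- c(rnorm(15, mu[1]), rnorm(15, mu[2]), rnorm(15, mu[3]))
    g <- geno_table(rep(c("AA", "AT", "TT"), each = 15))
    res <- associate(g, trait_table(y), "s1", "BW")
    if (res$test != "anova" || !res$significant) next
    gt <- factor(rep(c("AA", "AT", "TT"), each = 15))
    tk <- TukeyHSD(aov(y ~ gt))$gt
    letters_of <- setNames(res$groups$letter, res$groups$genotype)
    for (r in rownames(tk)) {
      ab <- strsplit(r, "-")[[1]]
      share <- any(strsplit(letters_of[ab[1]], "")[[1]] %in%
                     strsplit(letters_of[ab[2]], "")[[1]])
      expect_identical(share, tk[r, "p adj"] > 0.05)
    }
  }
})

test_that("degenerate inputs raise the documented errors", {
  g <- geno_table(rep(c("CC", "CT"), each = 3))
  y <- rep(c(1, 2), each = 3)
  expect_error(associate(g, trait_table(y), "s1", "BW"),
               "degenerate-variance")
  expect_error(associate(geno_table("CC"), trait_table(1), "s1", "BW"),
               "monomorphic")
  expect_error(associate(g, trait_table(y), "nope", "BW"), "missing-locus")
})

two_family_tables <- function(n1, n2, slope1, slope2) {
  # genotype classes balanced within each family; trait = slope x alt count
  # plus a fixed within-class jitter so variances are non-degenerate
  mk <- function(fid, n, slope, prefix) {
    alt <- rep(0:2, length.out = n)
    jit <- rep(c(-0.2, 0.1, 0.3, -0.1), length.out = n) # period 4 vs 3

    ids <- sprintf("%s%04d", prefix, seq_len(n))
    list(g = data.frame(individual_id = ids, family_id = fid, snp_id = "s1",
                        allele1 = ifelse(alt >= 1, "T", "C"),
                        allele2 = ifelse(alt == 2, "T", "C")),
         t = data.frame(individual_id = ids, family_id = fid,
                        BW = 100 + slope * alt + jit, TL = 1, SL = 1,
                        age_mph = 7))
  }
  a <- mk("fam1", n1, slope1, "a")
  b <- mk("fam2", n2, slope2, "b")
  list(genotypes = rbind(a$g, b$g), traits = rbind(a$t, b$t))
}

test_that("family replication flags concordance with the pooled analysis", {
  # shared effect: both families order genotype means the same way
  shared <- two_family_tables(120, 90, slope1 = 5, slope2 = 5)
  rep1 <- per_family_replication(shared$genotypes, shared$traits, "s1", "BW",
                                 min_family_n = 30)
  conc <- vapply(rep1, `[[`, logical(1), "concordant")
  expect_length(conc, 2)
  expect_true(all(conc))
  # a family below the size threshold is skipped with a log entry
  small <- two_family_tables(120, 10, 5, 5)
  rep2 <- per_family_replication(small$genotypes, small$traits, "s1", "BW",
                                 min_family_n = 30)
  expect_match(attr(rep2, "skipped"), "fam2")
  expect_length(rep2, 1)
  # an effect confined to the dominant family: the other family's ordering
  # opposes the pooled one
  confined <- two_family_tables(240, 60, slope1 = 5, slope2 = -5)
  rep3 <- per_family_replication(confined$genotypes, confined$traits,
                                 "s1", "BW", min_family_n = 30)
  conc3 <- vapply(rep3, `[[`, logical(1), "concordant")
  expect_true(conc3[["fam1"]])
  expect_false(conc3[["fam2"]])
})

test_that("the Pfaffl ratio follows its closed form", {
  expect_equal(pfaffl_ratio(2.0, 1.0, 2.0, 1.0), 1.0)
  expect_equal(pfaffl_ratio(2.0, 3.0, 2.0, 0.0), 8.0)
  expect_equal(pfaffl_ratio(1.9, 0, 1.8, 0), 1.0)
  expect_error(pfaffl_ratio(1.0, 2, 2, 1), "domain error")
  expect_error(pfaffl_ratio(2.6, 2, 2, 1), "domain error")
})

test_that("expression contrasts detect planted down-regulation", {
  expect_error(expression_contrast(1.5, 2.0), "precondition")
  same <- expression_contrast(c(1, 1, 1), c(1, 1, 1))
  expect_equal(same$p_value, 1)
  expect_false(same$significant)
  # planted 2-fold down-regulation in "fast", n = 6/6, CV 10%
  set.seed(12)
  hitrate <- mean(vapply(1:60, function(i) {
    fast <- exp(rnorm(6, log(0.5), 0.1))
    slow <- exp(rnorm(6, log(1.0), 0.1))
    ec <- expression_contrast(fast, slow)
    ec$significant && ec$direction == -1
  }, logical(1)))
  expect_gt(hitrate, 0.9)
})
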