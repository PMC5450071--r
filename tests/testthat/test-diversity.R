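mk_geno <- function(...) {
  cols <- list(...)
  g <- do.call(cbind, cols)
  rownames(g) <- sprintf("a%02d", seq_len(nrow(g)))
  colnames(g) <- sprintf("m%02d", seq_len(ncol(g)))
  genotype_matrix(g)
}

test_that("allele frequencies: hand count, symmetry, degenerate cases", {
  g <- mk_geno(c(2L, 2L, 1L, 0L))
  expect_equal(unname(allele_frequencies(g)), 5 / 8)
  expect_equal(unname(allele_frequencies(g)) + (1 - 5 / 8), 1)
  g2 <- mk_geno(c(NA, NA, NA, NA))
  expect_true(is.na(allele_frequencies(g2)))
  expect_error(allele_frequencies(g, rep(FALSE, 4)), "empty group")
})

test_that("heterozygosity closed forms and negative F admissibility", {
  g <- mk_geno(c(2L, 0L, 2L, 0L))          # p = 0.5
  h <- heterozygosity(g)
  expect_equal(unname(h$He), 0.5)
  expect_equal(unname(h$uHe), 0.5 * 8 / 7)
  g2 <- mk_geno(rep(1L, 6))                # all heterozygotes
  h2 <- heterozygosity(g2)
  expect_equal(unname(h2$Ho), 1)
  expect_lt(unname(h2$F), 0)
})

test_that("fixation indices: closed arithmetic and degenerate pools", {
  # p1 = 0.2, p2 = 0.8 exactly, using dosage compositions of 10 accessions
  g1 <- c(rep(0L, 6), rep(1L, 4))          # p = 4/20 = 0.2
  g2 <- c(rep(2L, 6), rep(1L, 4))          # p = 16/20 = 0.8
  g <- mk_geno(c(g1, g2))
  masks <- list(A = c(rep(TRUE, 10), rep(FALSE, 10)),
                B = c(rep(FALSE, 10), rep(TRUE, 10)))
  fx <- fixation_indices(g, masks)
  expect_equal(unname(fx$fst[1]), (0.5 - 0.32) / 0.5, tolerance = 1e-12)
  # identical subpopulation frequencies -> FST 0
  gi <- mk_geno(rep(c(0L, 1L, 2L, 1L), 4))
  mi <- list(c(rep(TRUE, 8), rep(FALSE, 8)), c(rep(FALSE, 8), rep(TRUE, 8)))
  expect_equal(unname(fixation_indices(gi, mi)$fst[1]), 0, tolerance = 1e-12)
  # fixed alternative alleles -> FST 1
  gf <- mk_geno(c(rep(0L, 5), rep(2L, 5)))
  mf <- list(c(rep(TRUE, 5), rep(FALSE, 5)), c(rep(FALSE, 5), rep(TRUE, 5)))
  expect_equal(unname(fixation_indices(gf, mf)$fst[1]), 1)
  # all loci monomorphic -> error
  gm <- mk_geno(rep(2L, 10))
  expect_error(fixation_indices(gm, mf), "polymorphic")
})

test_that("Nei decomposition identity holds per locus to 1e-12", {
  g <- rand_geno(24, 60, miss = 0.1, seed = 3)
  masks <- list(c(rep(TRUE, 12), rep(FALSE, 12)),
                c(rep(FALSE, 12), rep(TRUE, 12)))
  fx <- fixation_indices(g, masks)
  ok <- !is.na(fx$fst) & !is.na(fx$fis)
  expect_true(any(ok))
  expect_lt(max(abs((1 - fx$fit[ok]) -
                      (1 - fx$fis[ok]) * (1 - fx$fst[ok]))), 1e-12)
})

test_that("He is invariant to allele relabeling; FST to group order", {
  g <- rand_geno(16, 30, miss = 0.05, seed = 9)
  flipped <- genotype_matrix(2L - unclass(g))
  expect_equal(heterozygosity(g)$He, heterozygosity(flipped)$He)
  masks <- list(a = rep(c(TRUE, FALSE), 8), b = rep(c(FALSE, TRUE), 8))
  expect_equal(fixation_indices(g, masks)$summary,
               fixation_indices(g, rev(masks))$summary)
})

test_that("private alleles: trivial cases and brute-force agreement", {
  # locus fixed ref in A, segregating in B -> the alt allele is private to B
  g <- mk_geno(c(0L, 0L, 0L, 1L, 2L, 0L))
  masks <- list(A = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                B = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(unname(private_alleles(g, masks)), c(0L, 1L))
  # identical groups -> none private
  gd <- mk_geno(rep(c(0L, 1L, 2L), 2))
  md <- list(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
             c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(unname(private_alleles(gd, md)), c(0L, 0L))
  for (seed in 1:4) {
    gr <- rand_geno(12, 15, miss = 0.2, seed = seed)
    mr <- list(rep(c(TRUE, FALSE), 6), rep(c(FALSE, TRUE), 6))
    expect_equal(unname(private_alleles(gr, mr)), bf_private(gr, mr))
  }
})

test_that("identity and exclusion probabilities", {
  g <- mk_geno(c(2L, 0L, 2L, 0L))          # single locus p = 0.5
  ie <- identity_exclusion(g)
  expect_equal(ie$PI, 0.0625 + 0.0625 + 0.25)
  gm <- mk_geno(rep(2L, 4), rep(0L, 4))    # monomorphic panel
  iem <- identity_exclusion(gm)
  expect_equal(iem$PI, 1); expect_equal(iem$PE, 0)
  # multilocus PI = product of per-locus genotype-match enumerations
  gr <- rand_geno(30, 3, miss = 0, seed = 5)
  p <- bf_allele_freq(gr)
  expect_equal(identity_exclusion(gr)$PI, prod(sapply(p, bf_pi)),
               tolerance = 1e-12)
  # PI non-increasing as loci are added
  pis <- sapply(1:3, function(k)
    identity_exclusion(gr[, 1:k, drop = FALSE])$PI)
  expect_true(all(diff(pis) <= 0))
  # one-parent exclusion vs Monte-Carlo oracle
  pe <- identity_exclusion(mk_geno(c(rep(2L, 3), rep(1L, 4), rep(0L, 3))))
  p_obs <- 0.5
  expect_lt(abs(pe$per_locus$PE[1] - bf_pe_mc(p_obs)), 0.01)
})

test_that("all statistics match brute force on random matrices (property)", {
  for (seed in 1:5) {
    g <- rand_geno(10, 12, miss = 0.15, seed = seed + 20)
    expect_equal(unname(allele_frequencies(g)), bf_allele_freq(g))
    h <- heterozygosity(g)
    bf <- bf_het(g)
    expect_equal(unname(h$Ho), bf$Ho)
    expect_equal(unname(h$He), bf$He)
    masks <- list(rep(c(TRUE, FALSE), 5), rep(c(FALSE, TRUE), 5))
    fx <- fixation_indices(g, masks)
    bfx <- bf_fstats(g, masks)
    expect_equal(unname(fx$fst), bfx$fst)
    expect_equal(unname(fx$fis), bfx$fis)
    expect_equal(unname(fx$fit), bfx$fit)
  }
})

test_that("group_summary assembles tables and excludes admixed", {
  col <- simulate_collection(sim_config(n_markers = 400, n_pool1 = 20,
                                        n_pool2 = 25, n_admixed = 4,
                                        seed = 14))
  gs <- group_summary(col$geno, col$samples, "gene_pool")
  expect_setequal(gs$groups$group, c("Andean", "Mesoamerican"))
  expect_equal(sum(gs$groups$S), 45)
  expect_true(all(gs$groups$P_pct >= 0 & gs$groups$P_pct <= 100))
  expect_true(all(gs$groups$Ho >= 0 & gs$groups$He <= 1))
  # duplicated group -> between-group FST ~ 0
  sdup <- col$samples
  sdup$gene_pool <- rep(c("g1", "g2"), length.out = nrow(sdup))
  half <- simulate_collection(sim_config(n_markers = 300, n_pool1 = 30,
                                         n_pool2 = 0, n_admixed = 0,
                                         seed = 15))
  s2 <- half$samples
  s2$gene_pool <- rep(c("g1", "g2"), length.out = nrow(s2))
  gs2 <- group_summary(half$geno, s2, "gene_pool")
  expect_lt(abs(gs2$fstats$multilocus$estimate[1]), 0.03)
  # stratum-within-pool grouping yields four groups
  gs3 <- group_summary(col$geno, col$samples, "stratum_within_pool")
  expect_equal(nrow(gs3$groups), 4L)
})
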