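test_that("two-locus haplotype frequencies: direct counts under het masking", {
  # all accessions homozygous AABB or aabb
  g <- genotype_matrix(matrix(c(2L, 2L, 0L, 0L, 0L, 2L, 2L, 0L, 0L, 0L),
                              5, 2, dimnames = list(letters[1:5],
                                                    c("A", "B"))))
  hf <- twolocus_haplotype_freqs(g, 1, 2)
  expect_equal(unname(hf$freqs), c(2 / 5, 0, 0, 3 / 5))
  expect_equal(sum(hf$freqs), 1)
  # heterozygotes dropped; insufficient data -> uninformative
  gh <- genotype_matrix(matrix(1L, 6, 2,
                               dimnames = list(letters[1:6], c("A", "B"))))
  expect_false(twolocus_haplotype_freqs(gh, 1, 2)$informative)
})

test_that("EM haplotype frequencies match a likelihood grid search", {
  set.seed(21)
  # mixture fixture with double heterozygotes present
  n <- 60
  hap_pool <- matrix(c(1, 1, 0, 0, 1, 0, 0, 1), 4, 2, byrow = TRUE)
  pick <- sample(1:4, 2 * n, replace = TRUE, prob = c(.4, .3, .2, .1))
  h1 <- hap_pool[pick[1:n], ]; h2 <- hap_pool[pick[(n + 1):(2 * n)], ]
  g <- h1 + h2
  rownames(g) <- sprintf("a%02d", 1:n); colnames(g) <- c("A", "B")
  geno <- genotype_matrix(g)
  em <- twolocus_haplotype_freqs(geno, 1, 2, het_as_missing = FALSE)
  # grid-search oracle over f_AB with marginals fixed at the EM solution;
  # haplotype order AB, Ab, aB, ab
  haps <- rbind(c(1, 1), c(1, 0), c(0, 1), c(0, 0))
  pA <- em$freqs[1] + em$freqs[2]; pB <- em$freqs[1] + em$freqs[3]
  cells <- table(factor(g[, 1], 0:2), factor(g[, 2], 0:2))
  loglik <- function(fAB) {
    f <- c(fAB, pA - fAB, pB - fAB, 1 - pA - pB + fAB)
    if (any(f < 0)) return(-Inf)
    ll <- 0
    for (x in 0:2) for (y in 0:2) {
      if (cells[x + 1, y + 1] == 0) next
      pr <- 0
      # genotype prob = sum over ordered haplotype pairs
      for (i in 1:4) for (j in 1:4) {
        hx <- haps[i, 1] + haps[j, 1]
        hy <- haps[i, 2] + haps[j, 2]
        if (hx == x && hy == y) pr <- pr + f[i] * f[j]
      }
      ll <- ll + cells[x + 1, y + 1] * log(pr)
    }
    ll
  }
  grid <- seq(max(0, pA + pB - 1) + 1e-6, min(pA, pB) - 1e-6,
              length.out = 4001)
  best <- grid[which.max(vapply(grid, loglik, 1))]
  expect_lt(abs(em$freqs[1] - best), 2e-3)
})

test_that("D-prime confidence intervals: degenerate and simulated cases", {
  # complete association at large n: strong LD with ci_low near 1
  x <- c(rep(2L, 60), rep(0L, 60))
  g <- genotype_matrix(matrix(c(x, x), 120, 2,
                              dimnames = list(sprintf("a%03d", 1:120),
                                              c("A", "B"))))
  ci <- dprime_ci(twolocus_haplotype_freqs(g, 1, 2))
  expect_equal(ci$d_prime, 1)
  expect_gt(ci$ci_low, 0.95)
  expect_equal(ci$category, "strong_LD")
  # independent balanced loci, n = 100: strong recombination most of the time
  set.seed(22)
  hits <- replicate(40, {
    a <- sample(rep(c(0L, 2L), 50)); b <- sample(rep(c(0L, 2L), 50))
    gg <- genotype_matrix(matrix(c(a, b), 100, 2,
                                 dimnames = list(sprintf("a%03d", 1:100),
                                                 c("A", "B"))))
    dprime_ci(twolocus_haplotype_freqs(gg, 1, 2))$category
  })
  expect_gte(mean(hits == "strong_recomb"), 0.9)
  # CI grid refinement: step 1e-3 vs 1e-4 agree within one coarse step
  set.seed(23)
  a <- sample(c(rep(0L, 40), rep(2L, 40)))
  b <- ifelse(runif(80) < 0.8, a, sample(c(0L, 2L), 80, replace = TRUE))
  gg <- genotype_matrix(matrix(c(a, b), 80, 2,
                               dimnames = list(sprintf("a%03d", 1:80),
                                               c("A", "B"))))
  hf <- twolocus_haplotype_freqs(gg, 1, 2)
  c1 <- dprime_ci(hf, grid_step = 0.001)
  c2 <- dprime_ci(hf, grid_step = 0.0001)
  expect_lt(abs(c1$ci_low - c2$ci_low), 0.001 + 1e-9)
  expect_lt(abs(c1$ci_high - c2$ci_high), 0.001 + 1e-9)
  # monomorphic locus is uninformative
  gm <- genotype_matrix(matrix(c(rep(2L, 10), rep(c(0L, 2L), 5)), 10, 2,
                               dimnames = list(letters[1:10], c("A", "B"))))
  expect_equal(dprime_ci(twolocus_haplotype_freqs(gm, 1, 2))$category,
               "uninformative")
})

test_that("gabriel_blocks recovers constructed truth and degenerates", {
  set.seed(24)
  n <- 100
  h1 <- rbinom(n, 1, 0.5); h2 <- rbinom(n, 1, 0.5)
  g <- cbind(2L * h1, 2L * h1, 2L * h1, 2L * h2, 2L * h2, 2L * h2)
  rownames(g) <- sprintf("a%03d", 1:n); colnames(g) <- sprintf("m%d", 1:6)
  mk <- marker_info(colnames(g), chrom = "c1",
                    pos = c(1e4, 2e4, 3e4, 3.0e5, 3.1e5, 3.2e5))
  geno <- genotype_matrix(g)
  ci <- dprime_records(geno, mk, max_dist = 5e5)
  bl <- gabriel_blocks(ci, mk)
  expect_equal(nrow(bl), 2L)
  expect_setequal(bl$n_markers, c(3L, 3L))
  expect_equal(sort(bl$start_bp), c(1e4, 3e5))
  # members are contiguous in marker order and blocks do not overlap
  expect_true(all(vapply(bl$members, function(m)
    all(diff(match(m, mk$marker_id)) == 1), TRUE)))
  expect_true(bl$end_bp[1] < bl$start_bp[2])
  # all pairs recombination -> no blocks
  set.seed(25)
  gr <- matrix(2L * rbinom(n * 6, 1, 0.5), n, 6,
               dimnames = list(sprintf("a%03d", 1:n), sprintf("m%d", 1:6)))
  cir <- dprime_records(genotype_matrix(gr), mk, max_dist = 5e5)
  expect_equal(nrow(gabriel_blocks(cir, mk)), 0L)
  # raising informFrac never increases accepted spans
  n95 <- nrow(gabriel_blocks(ci, mk, informFrac = 0.95))
  n100 <- nrow(gabriel_blocks(ci, mk, informFrac = 1))
  expect_lte(n100 + 0L, n95 + 1L)
  expect_lte(nrow(gabriel_blocks(ci, mk, informFrac = 1)), n95)
})

test_that("block_summary reproduces coverage arithmetic", {
  blocks <- data.frame(chrom = c("c1", "c1", "c2"),
                       start_bp = c(0, 5e5, 1e5), end_bp = c(2e5, 9e5, 4e5),
                       span_bp = c(2e5, 4e5, 3e5),
                       n_markers = c(4L, 6L, 5L))
  gm <- data.frame(chrom = c("c1", "c2"), length_bp = c(1e6, 1e6))
  bs <- block_summary(blocks, gm)
  expect_equal(bs$totals$coverage_pct, 100 * 9e5 / 2e6)
  expect_equal(bs$totals$mean_snps_per_block, 5)
  expect_equal(bs$per_chrom$n_blocks, c(2L, 1L))
})
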