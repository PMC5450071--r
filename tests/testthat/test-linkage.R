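test_that("GRM closed arithmetic, twins, and loop oracle", {
  # one locus p = 0.5, genotypes (2, 0): off-diagonal (1)(-1)/0.5 = -2
  g <- genotype_matrix(matrix(c(2L, 0L), 2, 1,
                              dimnames = list(c("a", "b"), "m1")))
  A <- genetic_relationship_matrix(g)
  expect_equal(A[1, 2], -2)
  # duplicated accession rows give identical standardized scores
  gr <- rand_geno(6, 30, miss = 0, seed = 3)
  gm <- rbind(unclass(gr), unclass(gr)[1, ])
  rownames(gm)[7] <- "twin"
  gd <- genotype_matrix(gm)
  Ad <- genetic_relationship_matrix(gd)
  expect_equal(Ad[1, 7], Ad[7, 1])
  expect_equal(unname(Ad[1, 7]),
               unname(1 + (Ad[1, 7] - 1)))  # symmetric sanity
  expect_equal(unname(Ad[2, 7]), unname(Ad[2, 1]))
  # loop oracle on random fixtures with missing data
  for (seed in 1:3) {
    gx <- rand_geno(8, 20, miss = 0.1, seed = seed + 60)
    expect_equal(unname(unclass(genetic_relationship_matrix(gx))),
                 bf_grm(gx), tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("pairwise r2: trivial values and contingency oracle", {
  set.seed(4)
  x <- sample(0:2, 40, replace = TRUE)
  g <- matrix(c(x, x, 2L - x), 40, 3,
              dimnames = list(sprintf("a%02d", 1:40), c("m1", "m2", "m3")))
  mk <- marker_info(colnames(g), chrom = "c1", pos = c(100, 200, 300))
  ld <- pairwise_r2(genotype_matrix(g), mk, maf_min = 0)
  expect_equal(ld$r2[ld$id_a == "m1" & ld$id_b == "m2"], 1)
  expect_equal(ld$r2[ld$id_a == "m1" & ld$id_b == "m3"], 1)  # anticorrelated
  # orthogonal balanced vectors -> r2 = 0
  g2 <- matrix(c(rep(c(0L, 0L, 2L, 2L), 10), rep(c(0L, 2L, 0L, 2L), 10)),
               40, 2, dimnames = list(sprintf("a%02d", 1:40), c("x", "y")))
  mk2 <- marker_info(c("x", "y"), chrom = "c1", pos = c(1, 2))
  expect_equal(pairwise_r2(genotype_matrix(g2), mk2, maf_min = 0)$r2, 0)
  # contingency-table oracle with missing data
  gg <- rand_geno(30, 6, miss = 0.15, seed = 9)
  mkg <- marker_info(colnames(gg), chrom = "c1", pos = 1:6 * 1000)
  ldg <- pairwise_r2(gg, mkg, maf_min = 0)
  for (r in seq_len(nrow(ldg))) {
    xo <- unclass(gg)[, ldg$id_a[r]]; yo <- unclass(gg)[, ldg$id_b[r]]
    expect_equal(ldg$r2[r], bf_r2_contingency(xo, yo), tolerance = 1e-12)
  }
  # max_dist and same-chromosome restrictions hold
  expect_true(all(ldg$dist_bp > 0))
  mk_far <- marker_info(colnames(gg), chrom = "c1", pos = c(1, 2, 3, 4, 5,
                                                            1e7))
  ld_far <- pairwise_r2(gg, mk_far, max_dist = 1e6, maf_min = 0)
  expect_false("m006" %in% c(ld_far$id_a, ld_far$id_b))
})

test_that("r2_sv reduces to r2 under identity kinship and is idempotent", {
  gg <- rand_geno(25, 8, miss = 0.1, seed = 10)
  mk <- marker_info(colnames(gg), chrom = "c1", pos = 1:8 * 500)
  ld <- pairwise_r2(gg, mk, maf_min = 0)
  ld0 <- corrected_r2_sv(gg, ld)
  # exact only for complete data (mean imputation touches missing cells);
  # compare on the imputed matrix
  gi <- unclass(gg)
  cm <- colMeans(gi, na.rm = TRUE)
  idx <- which(is.na(gi), arr.ind = TRUE)
  gi[idx] <- cm[idx[, 2]]
  r2_imp <- sapply(seq_len(nrow(ld)), function(k)
    cor(gi[, ld$id_a[k]], gi[, ld$id_b[k]])^2)
  expect_equal(ld0$r2_sv, r2_imp, tolerance = 1e-12)
  expect_true(all(ld0$r2_sv <= 1 + 1e-12))
  # complete data: strict identity with r2
  gc <- rand_geno(25, 8, miss = 0, seed = 11)
  ldc <- pairwise_r2(gc, mk, maf_min = 0)
  expect_equal(corrected_r2_sv(gc, ldc)$r2_sv, ldc$r2, tolerance = 1e-12)
  # idempotence: whitening/projection residuals unchanged on second pass
  K <- genetic_relationship_matrix(gc)
  S <- matrix(rnorm(25), ncol = 1)
  l1 <- corrected_r2_sv(gc, ldc, S, K / mean(diag(K)))
  l2 <- corrected_r2_sv(gc, l1, S, K / mean(diag(K)))
  expect_equal(l1$r2_sv, l2$r2_sv, tolerance = 1e-8)
})

test_that("structure-driven LD collapses under correction", {
  cfg <- sim_config(n_pool1 = 50, n_pool2 = 50, n_admixed = 0,
                    target_fst_pools = 0.75, n_markers = 300, n_chrom = 2,
                    n_founders = Inf, missing_rate = 0, seed = 4)
  col <- simulate_collection(cfg)
  ld <- pairwise_r2(col$geno, col$markers, max_dist = 47e6, maf_min = 0.05)
  grm <- genetic_relationship_matrix(col$geno)
  S <- matrix(as.numeric(col$truth$pool_lab == "pool1"), ncol = 1)
  lds <- corrected_r2_sv(col$geno, ld, S, grm / mean(diag(grm)))
  expect_gt(stats::median(lds$r2), stats::median(lds$r2_sv) * 5)
  expect_lt(stats::median(lds$r2_sv), 0.05)
})

test_that("Hill-Weir model limits and parameter recovery", {
  n <- 100
  # d -> infinity: asymptote 1/n
  expect_equal(hill_weir_expectation(1e14, 1e-4, n), 1 / n,
               tolerance = 1e-3)
  # C = 0 closed form
  expect_equal(hill_weir_expectation(0, 1e-5, n),
               (10 / 22) * (1 + 36 / (22 * n)), tolerance = 1e-12)
  # recovery from noisy model-generated records
  set.seed(12)
  d <- runif(2000, 100, 5e5)
  y <- hill_weir_expectation(d, 2e-5, n) + rnorm(2000, 0, 0.02)
  fit <- fit_hill_weir(data.frame(dist_bp = d, r2 = y), n = n)
  expect_lt(abs(fit$rho - 2e-5) / 2e-5, 0.10)
  # fitted curve is monotone decreasing
  dd <- seq(1, 1e6, length.out = 200)
  expect_true(all(diff(fit$fitted(dd)) < 0))
  # half-decay point halves the d -> 0 value
  expect_equal(fit$fitted(fit$half_decay_bp), fit$fitted(1e-9) / 2,
               tolerance = 1e-6)
  # binned mode agrees approximately
  fitb <- fit_hill_weir(data.frame(dist_bp = d, r2 = y), n = n,
                        binned = TRUE)
  expect_lt(abs(fitb$rho - fit$rho) / fit$rho, 0.2)
})

test_that("LD pruning: trivial cases, exhaustive oracle, monotonicity", {
  set.seed(13)
  x <- sample(0:2, 30, replace = TRUE)
  g <- matrix(c(x, x), 30, 2, dimnames = list(sprintf("a%02d", 1:30),
                                              c("m1", "m2")))
  mk <- marker_info(c("m1", "m2"), chrom = "c1", pos = c(100, 200))
  kept <- ld_prune(genotype_matrix(g), mk, r2_threshold = 0.5)
  expect_length(kept, 1L)
  # all r2 below threshold: everything retained
  gi <- rand_geno(40, 5, miss = 0, seed = 14)
  mki <- marker_info(colnames(gi), chrom = "c1", pos = 1:5 * 100)
  cc <- cor(unclass(gi))^2
  thr_hi <- max(cc[upper.tri(cc)]) + 0.01
  expect_length(ld_prune(gi, mki, r2_threshold = thr_hi), 5L)
  # exhaustive oracle agreement on small fixtures
  for (seed in c(15, 16, 17)) {
    gg <- rand_geno(25, 12, miss = 0.05, seed = seed)
    mkg <- marker_info(colnames(gg), chrom = "c1", pos = 1:12 * 50)
    expect_setequal(ld_prune(gg, mkg, 0.4, window_markers = 50L),
                    bf_prune(gg, mkg, 0.4))
  }
  # determinism and threshold monotonicity (superset at higher threshold)
  gg <- rand_geno(25, 15, miss = 0.05, seed = 18)
  mkg <- marker_info(colnames(gg), chrom = "c1", pos = 1:15 * 50)
  k1 <- ld_prune(gg, mkg, 0.3); k2 <- ld_prune(gg, mkg, 0.3)
  expect_identical(k1, k2)
  expect_true(all(k1 %in% ld_prune(gg, mkg, 0.8)))
})

test_that("panel selection respects its rules and audits cleanly", {
  cfg <- sim_config(n_pool1 = 40, n_pool2 = 40, n_admixed = 0,
                    target_fst_pools = 0.15, n_markers = 600, n_chrom = 4,
                    missing_rate = 0.02, seed = 72)
  col <- simulate_collection(cfg)
  pn <- select_panel(col$geno, col$markers, col$samples, size_target = 100)
  expect_lte(length(pn$panel), 100L)
  # every member polymorphic in both pools
  for (pool in unique(col$samples$gene_pool)) {
    p <- allele_frequencies(col$geno[, pn$panel, drop = FALSE],
                            col$samples$gene_pool == pool)
    expect_true(all(p > 0 & p < 1, na.rm = TRUE))
  }
  # exhaustive pairwise r2 audit below the pruning threshold within
  # chromosomes
  sub <- col$geno[, pn$panel, drop = FALSE]
  mk <- col$markers[match(pn$panel, col$markers$marker_id), ]
  aud <- pairwise_r2(sub, mk, max_dist = 47e6, maf_min = 0)
  expect_true(all(aud$r2 < 0.5))
  # infeasible target: maximal panel with warning
  expect_warning(pn_all <- select_panel(col$geno, col$markers, col$samples,
                                        size_target = 1e5), "survive")
  expect_equal(length(pn_all$panel), pn_all$n_survivors)
})
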