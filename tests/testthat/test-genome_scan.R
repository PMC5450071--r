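test_that("window tiling: counts, half-open assignment, terminal window", {
  gm <- data.frame(chrom = "c1", length_bp = 250000)
  mk <- marker_info(c("a", "b", "c"), chrom = "c1",
                    pos = c(99999, 100000, 249000))
  win <- make_windows(gm, mk, 100000L)
  expect_equal(nrow(win), 3L)
  expect_equal(win$end - win$start, c(1e5, 1e5, 5e4))
  expect_equal(win$idx[[1]], 1L)          # pos 99999 -> first window
  expect_equal(win$idx[[2]], 2L)          # pos 100000 -> second window
  expect_equal(win$idx[[3]], 3L)
  # marker past chromosome end goes to terminal window with warning
  mk2 <- marker_info("z", chrom = "c1", pos = 260000)
  expect_warning(w2 <- make_windows(gm, mk2, 100000L), "beyond")
  expect_equal(w2$idx[[3]], 1L)
  # window count equals the brute-force ceiling sum over a genome map
  gm3 <- data.frame(chrom = c("c1", "c2", "c3"),
                    length_bp = c(52183500, 49033700, 31973200))
  w3 <- make_windows(gm3, mk, 100000L)
  expect_equal(nrow(w3), sum(ceiling(gm3$length_bp / 1e5)))
  # every placed marker lands in exactly one window
  col <- simulate_collection(sim_config(n_markers = 500, n_chrom = 3,
                                        seed = 21))
  gmc <- data.frame(chrom = unique(col$markers$chrom), length_bp = 47e6)
  wc <- make_windows(gmc, col$markers)
  expect_equal(sort(unlist(wc$idx)), seq_len(500))
})

test_that("window theta/pi closed forms and normalizations", {
  mask <- rep(TRUE, 2)                     # n = 4 chromosomes
  g <- genotype_matrix(matrix(c(1L, 0L, 2L, 0L, 1L, 1L), 2,
                              dimnames = list(c("a", "b"),
                                              c("m1", "m2", "m3"))))
  res <- window_theta_pi(g, mask, 1:3, window_length = 1e5)
  a3 <- 1 + 1 / 2 + 1 / 3
  expect_equal(res$S, 3L)
  expect_equal(res$theta_w, (3 / a3) / 1e5)
  resn <- window_theta_pi(g, mask, 1:3, normalization = "none")
  expect_equal(resn$theta_w, 3 / a3)
  resm <- window_theta_pi(g, mask, 1:3, normalization = "marker_count")
  expect_equal(resm$theta_w, (3 / a3) / 3)
  # empty window
  e <- window_theta_pi(g, mask, integer(0))
  expect_equal(e$S, 0L); expect_equal(e$theta_w, 0)
  # pi equals direct uHe summation
  gr <- rand_geno(10, 20, miss = 0, seed = 2)
  r <- window_theta_pi(gr, rep(TRUE, 10), 1:20, normalization = "none")
  p <- bf_allele_freq(gr)
  poly <- p > 0 & p < 1
  expect_equal(r$pi, sum((2 * p * (1 - p) * 20 / 19)[poly]))
})

test_that("Tajima's D matches a textbook implementation on haplotypes", {
  set.seed(4)
  n_acc <- 5                               # n = 10 chromosomes
  hap <- matrix(rbinom(10 * 12, 1, 0.4), 10, 12)
  geno <- hap[seq(1, 9, 2), ] + hap[seq(2, 10, 2), ]
  rownames(geno) <- letters[1:5]; colnames(geno) <- sprintf("m%02d", 1:12)
  d_pkg <- window_tajima_d(genotype_matrix(geno), rep(TRUE, 5), 1:12)
  expect_equal(d_pkg, bf_tajima_d(hap), tolerance = 1e-12)
  # S = 0 - undefined, never 0
  gmono <- genotype_matrix(matrix(2L, 5, 3,
                                  dimnames = list(letters[1:5],
                                                  c("x", "y", "z"))))
  expect_true(is.na(window_tajima_d(gmono, rep(TRUE, 5), 1:3)))
})

test_that("window FST: closed arithmetic, fixed difference, null", {
  # p_a = 0.2, p_b = 0.8 single marker, large n -> Hudson 1 - 0.32/0.68
  ga <- c(rep(0L, 60), rep(2L, 20), rep(1L, 0), rep(0L, 0))
  ga <- c(rep(0L, 64), rep(1L, 32), rep(2L, 4))   # p = 40/200 = 0.2
  gb <- c(rep(2L, 64), rep(1L, 32), rep(0L, 4))   # p = 0.8
  g <- genotype_matrix(matrix(c(ga, gb), ncol = 1,
                              dimnames = list(sprintf("i%03d", 1:200), "m")))
  ma <- c(rep(TRUE, 100), rep(FALSE, 100))
  hudson <- window_fst(g, ma, !ma, 1L)
  hw <- (2 * .2 * .8 * 200 / 199 + 2 * .8 * .2 * 200 / 199) / 2
  expect_equal(hudson, 1 - hw / 0.68, tolerance = 1e-12)
  # fixed difference -> 1
  gf <- genotype_matrix(matrix(c(rep(0L, 10), rep(2L, 10)), ncol = 1,
                               dimnames = list(sprintf("i%03d", 1:20), "m")))
  mf <- c(rep(TRUE, 10), rep(FALSE, 10))
  expect_equal(window_fst(gf, mf, !mf, 1L), 1)
  # identical pools -> near 0
  set.seed(8)
  gn <- rand_geno(100, 40, miss = 0, seed = 8)
  mn <- rep(c(TRUE, FALSE), 50)
  expect_lt(abs(window_fst(gn, mn, !mn, 1:40)), 0.02)
  # no polymorphic markers -> NA
  gmono <- genotype_matrix(matrix(2L, 10, 2,
                                  dimnames = list(sprintf("i%02d", 1:10),
                                                  c("a", "b"))))
  expect_true(is.na(window_fst(gmono, rep(c(TRUE, FALSE), 5),
                               rep(c(FALSE, TRUE), 5), 1:2)))
})

test_that("theta and pi are invariant to marker order within a window", {
  g <- rand_geno(12, 15, miss = 0.1, seed = 31)
  r1 <- window_theta_pi(g, rep(TRUE, 12), 1:15)
  r2 <- window_theta_pi(g, rep(TRUE, 12), sample(1:15))
  expect_equal(r1[c("S", "theta_w", "pi")], r2[c("S", "theta_w", "pi")])
})

test_that("windows containing selection-boosted loci show elevated FST", {
  cfg <- sim_config(n_markers = 1200, n_pool1 = 40, n_pool2 = 40,
                    n_admixed = 0, target_fst_pools = 0.05,
                    outlier_fraction = 0.04, outlier_fst_boost = 0.6,
                    n_chrom = 4, n_founders = Inf, seed = 33)
  col <- simulate_collection(cfg)
  gm <- data.frame(chrom = unique(col$markers$chrom),
                   length_bp = cfg$chrom_length_bp)
  win <- make_windows(gm, col$markers, 1e6)
  tr <- col$truth
  has_boost <- vapply(win$idx, function(i) any(tr$outlier[i]), TRUE)
  fst <- vapply(seq_len(nrow(win)), function(w) {
    idx <- match(col$markers$marker_id[win$idx[[w]]], colnames(col$geno))
    window_fst(col$geno, tr$pool_lab == "pool1", tr$pool_lab == "pool2", idx)
  }, 1)
  ok <- !is.na(fst)
  pv <- suppressWarnings(wilcox.test(fst[ok & has_boost], fst[ok & !has_boost],
                                     alternative = "greater")$p.value)
  expect_lt(pv, 1e-3)
})

test_that("scan_genome returns a tidy per-window table", {
  cfg <- sim_config(n_markers = 300, n_pool1 = 20, n_pool2 = 20,
                    n_admixed = 0, n_chrom = 2, seed = 41)
  col <- simulate_collection(cfg)
  gm <- data.frame(chrom = unique(col$markers$chrom),
                   length_bp = cfg$chrom_length_bp)
  tr <- col$truth
  sc <- scan_genome(col$geno, col$markers, gm, tr$pool_lab == "pool1",
                    tr$pool_lab == "pool2", window_length = 5e6)
  expect_equal(nrow(sc), 2 * ceiling(cfg$chrom_length_bp / 5e6))
  expect_true(all(c("S_a", "theta_w_a", "tajima_d_a", "fst") %in% names(sc)))
  expect_true(all(sc$fst <= 1, na.rm = TRUE))
})
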