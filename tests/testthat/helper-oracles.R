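# Independent brute-force oracles: plain loops over loci/genotypes, kept
# deliberately naive and separate from the package implementations.

rand_geno <- function(n, m, miss = 0.1, seed = 1) {
  set.seed(seed)
  g <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
  g[runif(n * m) < miss] <- NA
  rownames(g) <- sprintf("A%03d", seq_len(n))
  colnames(g) <- sprintf("m%03d", seq_len(m))
  genotype_matrix(g)
}

bf_allele_freq <- function(g, mask = rep(TRUE, nrow(g))) {
  sapply(seq_len(ncol(g)), function(j) {
    x <- unclass(g)[mask, j]
    x <- x[!is.na(x)]
    if (length(x) == 0) return(NA_real_)
    sum(x) / (2 * length(x))
  })
}

bf_het <- function(g, mask = rep(TRUE, nrow(g))) {
  Ho <- He <- numeric(ncol(g))
  for (j in seq_len(ncol(g))) {
    x <- unclass(g)[mask, j]; x <- x[!is.na(x)]
    p <- sum(x) / (2 * length(x))
    He[j] <- 1 - p^2 - (1 - p)^2
    Ho[j] <- mean(x == 1)
  }
  list(Ho = Ho, He = He)
}

bf_fstats <- function(g, masks) {
  L <- ncol(g)
  fst <- fis <- fit <- rep(NA_real_, L)
  for (j in seq_len(L)) {
    ps <- hos <- numeric(length(masks))
    for (k in seq_along(masks)) {
      x <- unclass(g)[masks[[k]], j]; x <- x[!is.na(x)]
      ps[k] <- sum(x) / (2 * length(x))
      hos[k] <- mean(x == 1)
    }
    Hs <- mean(2 * ps * (1 - ps))
    pb <- mean(ps)
    Ht <- 2 * pb * (1 - pb)
    if (is.na(Ht) || Ht == 0) next
    fst[j] <- (Ht - Hs) / Ht
    fis[j] <- (Hs - mean(hos)) / Hs
    fit[j] <- (Ht - mean(hos)) / Ht
  }
  list(fst = fst, fis = fis, fit = fit)
}

bf_private <- function(g, masks) {
  out <- integer(length(masks))
  for (k in seq_along(masks)) {
    for (j in seq_len(ncol(g))) {
      for (allele in c("alt", "ref")) {
        here <- bf_allele_freq(g[, j, drop = FALSE], masks[[k]])
        there <- sapply(seq_along(masks)[-k], function(o)
          bf_allele_freq(g[, j, drop = FALSE], masks[[o]]))
        f_here <- if (allele == "alt") here else 1 - here
        f_there <- if (allele == "alt") there else 1 - there
        if (!is.na(f_here) && f_here > 0 &&
            all(is.na(f_there) | f_there == 0))
          out[k] <- out[k] + 1L
      }
    }
  }
  out
}

# probability two random HWE genotypes match, per locus, by enumeration
bf_pi <- function(p) {
  gf <- c(p^2, 2 * p * (1 - p), (1 - p)^2)
  sum(gf^2)
}

# one-parent exclusion by Monte Carlo under HWE
bf_pe_mc <- function(p, n = 2e5, seed = 42) {
  set.seed(seed)
  mom <- rbinom(n, 1, p) + rbinom(n, 1, p)
  pat_allele <- rbinom(n, 1, p)
  mat_allele <- ifelse(mom == 2, 1, ifelse(mom == 0, 0, rbinom(n, 1, 0.5)))
  off <- mat_allele + pat_allele
  male <- rbinom(n, 1, p) + rbinom(n, 1, p)
  # male excluded iff no (maternal allele from mom, paternal allele from
  # male) combination yields the offspring genotype
  excl <- logical(n)
  for (i in seq_len(n)) {
    m_all <- switch(mom[i] + 1L, 0L, 0:1, 1L)
    f_all <- switch(male[i] + 1L, 0L, 0:1, 1L)
    ok <- FALSE
    for (a in m_all) for (b in f_all) if (a + b == off[i]) ok <- TRUE
    excl[i] <- !ok
  }
  mean(excl)
}

bf_grm <- function(g) {
  p <- bf_allele_freq(g)
  use <- which(!is.na(p) & p > 0 & p < 1)
  n <- nrow(g)
  A <- matrix(NA_real_, n, n)
  for (j in seq_len(n)) for (k in seq_len(n)) {
    vals <- c()
    for (i in use) {
      xj <- unclass(g)[j, i]; xk <- unclass(g)[k, i]
      pi <- p[i]; d <- 2 * pi * (1 - pi)
      if (j == k) {
        if (!is.na(xj))
          vals <- c(vals, (xj^2 - (1 + 2 * pi) * xj + 2 * pi^2) / d)
      } else if (!is.na(xj) && !is.na(xk)) {
        vals <- c(vals, (xj - 2 * pi) * (xk - 2 * pi) / d)
      }
    }
    A[j, k] <- if (j == k) 1 + mean(vals) else mean(vals)
  }
  A
}

# r2 from the 3x3 genotype contingency table
bf_r2_contingency <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  tab <- table(factor(x, 0:2), factor(y, 0:2))
  n <- sum(tab)
  vx <- 0:2; vy <- 0:2
  mx <- sum(vx * rowSums(tab)) / n; my <- sum(vy * colSums(tab)) / n
  sxy <- sum(outer(vx - mx, vy - my) * tab) / n
  sx <- sum((vx - mx)^2 * rowSums(tab)) / n
  sy <- sum((vy - my)^2 * colSums(tab)) / n
  (sxy^2) / (sx * sy)
}

# textbook Tajima's D from a haplotype 0/1 matrix (rows = chromosomes)
bf_tajima_d <- function(hap) {
  n <- nrow(hap)
  freqs <- colMeans(hap)
  seg <- freqs > 0 & freqs < 1
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  # mean pairwise differences by explicit double loop
  k <- 0; npairs <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    k <- k + sum(hap[i, ] != hap[j, ])
    npairs <- npairs + 1
  }
  pi_sum <- k / npairs
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (pi_sum - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

bf_simple_matching <- function(g) {
  n <- nrow(g)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    xi <- unclass(g)[i, ]; xj <- unclass(g)[j, ]
    keep <- !is.na(xi) & !is.na(xj)
    d[i, j] <- if (any(keep)) mean(xi[keep] != xj[keep]) else NA
  }
  d
}

# exhaustive greedy pruning over all pairs (independent of the windowed code)
bf_prune <- function(g, markers, thr) {
  ids <- markers$marker_id
  qc <- marker_qc(g)
  alive <- rep(TRUE, length(ids))
  cc <- suppressWarnings(stats::cor(unclass(g),
                                    use = "pairwise.complete.obs"))^2
  same_chr <- outer(markers$chrom, markers$chrom, "==")
  cc[!same_chr] <- NA
  diag(cc) <- NA
  repeat {
    cc_live <- cc
    cc_live[!alive, ] <- NA; cc_live[, !alive] <- NA
    mx <- suppressWarnings(max(cc_live, na.rm = TRUE))
    if (!is.finite(mx) || mx < thr) break
    hit <- which(cc_live == mx, arr.ind = TRUE)[1, ]
    i1 <- hit[1]; i2 <- hit[2]
    key <- function(i) c(qc$call_rate[i], qc$maf[i], -markers$pos[i])
    v1 <- key(i1); v2 <- key(i2)
    loser <- i2
    for (k in 1:3) {
      if (v1[k] < v2[k]) { loser <- i1; break }
      if (v1[k] > v2[k]) { loser <- i2; break }
    }
    alive[loser] <- FALSE
  }
  ids[alive]
}
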