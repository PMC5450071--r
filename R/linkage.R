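#' Genetic relationship matrix (standardized-dosage, inbreeding-adjusted)
#'
#' Off-diagonals are A_jk = mean_i (x_ij - 2 p_i)(x_ik - 2 p_i) /
#' (2 p_i (1 - p_i)); diagonals use the inbreeding-adjusted form
#' 1 + mean_i (x_ij^2 - (1 + 2 p_i) x_ij + 2 p_i^2) / (2 p_i (1 - p_i)).
#' Missing calls are handled by averaging each pair's products over the
#' markers where both accessions are typed. Monomorphic markers are
#' excluded (count reported via attribute `n_monomorphic`).
#'
#' @param geno genotype_matrix.
#' @return accession x accession matrix of class `kinship_matrix`.
#' @export
genetic_relationship_matrix <- function(geno) {
  p <- allele_freq_vec(geno)
  use <- !is.na(p) & p > 0 & p < 1
  n_mono <- sum(!use)
  g <- geno[, use, drop = FALSE]
  p <- p[use]
  denom <- 2 * p * (1 - p)
  X <- sweep(unclass(g), 2, 2 * p)              # x - 2p, NAs retained
  Z <- sweep(X, 2, sqrt(denom), "/")
  Zf <- Z; Zf[is.na(Zf)] <- 0
  obs <- (!is.na(Z)) * 1
  num <- tcrossprod(Zf)
  cnt <- tcrossprod(obs)
  A <- num / pmax(cnt, 1)
  # Yang diagonal
  x <- unclass(g)
  dterm <- sweep(x^2 - sweep(x, 2, 1 + 2 * p, `*`), 2, 2 * p^2, `+`) /
    matrix(rep(denom, each = nrow(g)), nrow(g))
  dterm[is.na(x)] <- NA
  diag(A) <- 1 + rowMeans(dterm, na.rm = TRUE)
  attr(A, "n_monomorphic") <- n_mono
  class(A) <- c("kinship_matrix", class(A))
  A
}

#' Pairwise dosage r-squared within chromosomes
#'
#' r2 is the squared Pearson correlation of dosage vectors over jointly
#' typed accessions (composite LD; phase-free, appropriate for highly
#' selfing material). Pairs are restricted to the same chromosome within
#' `max_dist` bp; markers below `maf_min` or with fewer than `min_joint`
#' jointly typed accessions are skipped (skip count in attribute
#' `n_skipped`).
#'
#' @param geno genotype_matrix. @param markers marker data.frame.
#' @param max_dist maximum pair distance in bp (default 3 Mb).
#' @param maf_min minimum MAF (default 0.05).
#' @param min_joint minimum jointly typed accessions (default 5).
#' @return data.frame(id_a, id_b, chrom, dist_bp, r2).
#' @export
pairwise_r2 <- function(geno, markers, max_dist = 3e6, maf_min = 0.05,
                        min_joint = 5L) {
  stopifnot(identical(colnames(geno), markers$marker_id))
  qc_maf <- marker_qc(geno)$maf
  keep <- !is.na(qc_maf) & qc_maf >= maf_min & !is.na(markers$chrom) &
    !is.na(markers$pos)
  g <- geno[, keep, drop = FALSE]
  mk <- markers[keep, , drop = FALSE]
  out <- list(); n_skipped <- 0L
  for (ch in unique(mk$chrom)) {
    sel <- which(mk$chrom == ch)
    sel <- sel[order(mk$pos[sel])]
    if (length(sel) < 2L) next
    sub <- unclass(g[, sel, drop = FALSE])
    pos <- mk$pos[sel]
    cc <- suppressWarnings(stats::cor(sub, use = "pairwise.complete.obs"))
    obs <- (!is.na(sub)) * 1
    joint <- crossprod(obs)
    pr <- which(upper.tri(cc), arr.ind = TRUE)
    d <- pos[pr[, 2]] - pos[pr[, 1]]
    ok_d <- d > 0 & d <= max_dist
    pr <- pr[ok_d, , drop = FALSE]; d <- d[ok_d]
    jt <- joint[pr]
    bad <- jt < min_joint | is.na(cc[pr])
    n_skipped <- n_skipped + sum(bad)
    pr <- pr[!bad, , drop = FALSE]; d <- d[!bad]
    if (nrow(pr) == 0L) next
    out[[ch]] <- data.frame(id_a = mk$marker_id[sel][pr[, 1]],
                            id_b = mk$marker_id[sel][pr[, 2]],
                            chrom = ch, dist_bp = d, r2 = cc[pr]^2,
                            stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(id_a = character(), id_b = character(), chrom = character(),
               dist_bp = numeric(), r2 = numeric())
  rownames(res) <- NULL
  attr(res, "n_skipped") <- n_skipped
  res
}

#' Structure- and kinship-corrected LD (r2_SV)
#'
#' Both dosage vectors are whitened by the inverse square root of the
#' kinship matrix (eigenvalues floored at `eig_floor`), the whitened
#' intercept and structure covariates are projected out, and r2_SV is the
#' squared correlation of the residuals. With identity kinship and no
#' structure columns this reduces exactly to the ordinary r2. Missing
#' dosages are mean-imputed per marker before correction.
#'
#' @param geno genotype_matrix.
#' @param pairs data.frame with `id_a`, `id_b` (e.g. from [pairwise_r2()]).
#' @param structure_covariates matrix of K-1 admixture columns (or NULL).
#' @param kinship accession x accession PSD matrix (or NULL for identity).
#' @param eig_floor eigenvalue floor applied before the inverse square root.
#' @return `pairs` with an `r2_sv` column appended.
#' @export
corrected_r2_sv <- function(geno, pairs, structure_covariates = NULL,
                            kinship = NULL, eig_floor = 1e-6) {
  n <- nrow(geno)
  X <- unclass(geno)
  cm <- colMeans(X, na.rm = TRUE)
  nas <- which(is.na(X), arr.ind = TRUE)
  if (nrow(nas)) X[nas] <- cm[nas[, 2]]
  if (is.null(kinship)) {
    W <- diag(n)
  } else {
    stopifnot(nrow(kinship) == n)
    K <- (unclass(kinship) + t(unclass(kinship))) / 2
    e <- eigen(K, symmetric = TRUE)
    vals <- pmax(e$values, eig_floor)
    # a Yang-diagonal GRM is mildly indefinite by construction; the floor
    # absorbs that. Error only on a grossly indefinite matrix.
    if (min(e$values) < -0.5 * max(abs(e$values)))
      stop("kinship matrix strongly non-PSD; eigenvalue range [",
           format(min(e$values)), ", ", format(max(e$values)), "]")
    W <- e$vectors %*% (t(e$vectors) / sqrt(vals))
  }
  Q <- cbind(rep(1, n), structure_covariates)
  Qw <- W %*% Q
  qrq <- qr(Qw)
  Xw <- W %*% X
  R <- Xw - qr.fitted(qrq, Xw)          # residuals after projecting out Qw
  colnames(R) <- colnames(geno)
  ia <- match(pairs$id_a, colnames(R))
  ib <- match(pairs$id_b, colnames(R))
  r <- vapply(seq_along(ia), function(k)
    suppressWarnings(stats::cor(R[, ia[k]], R[, ib[k]])), 1)
  pairs$r2_sv <- pmin(r^2, 1)
  pairs
}

#' Expected r-squared under the Hill-Weir drift model
#'
#' E[r2](C) = (10+C)/((2+C)(11+C)) * [1 + ((3+C)(12+12C+C^2)) /
#' (n(2+C)(11+C))] with C = rho * d.
#'
#' @param d distance in bp. @param rho recombination-scale parameter.
#' @param n sample size used in the finite-sample term.
#' @export
hill_weir_expectation <- function(d, rho, n) {
  C <- rho * d
  base <- (10 + C) / ((2 + C) * (11 + C))
  corr <- 1 + ((3 + C) * (12 + 12 * C + C^2)) / (n * (2 + C) * (11 + C))
  base * corr
}

#' Fit the Hill-Weir LD decay model
#'
#' Nonlinear least squares over rho (log-scale multi-start grid followed by
#' 1-D optimization). `half_decay_bp` solves E[r2](d) = E[r2](0+)/2 by
#' bracketed root finding; NA when the asymptote 1/n lies above half the
#' d -> 0 value.
#'
#' @param records data.frame with `dist_bp` and `r2` (or `r2_sv`).
#' @param n sample size for the finite-sample term.
#' @param use_r2_sv fit the `r2_sv` column instead of `r2`.
#' @param binned average records into `n_bins` distance bins before
#'   fitting (default FALSE = raw pairs).
#' @param n_bins number of bins when `binned`.
#' @return list(rho, n, half_decay_bp, rss, fitted) of class `decay_fit`;
#'   `fitted` is an evaluator function of distance.
#' @export
fit_hill_weir <- function(records, n, use_r2_sv = FALSE, binned = FALSE,
                          n_bins = 100L) {
  y <- if (use_r2_sv) records$r2_sv else records$r2
  d <- records$dist_bp
  ok <- !is.na(y) & !is.na(d) & d > 0
  y <- y[ok]; d <- d[ok]
  if (length(y) < 50L) stop("need >= 50 LD records to fit decay")
  if (binned) {
    br <- unique(stats::quantile(d, seq(0, 1, length.out = n_bins + 1L)))
    f <- cut(d, br, include.lowest = TRUE)
    d <- tapply(d, f, mean); y <- tapply(y, f, mean)
    keep <- !is.na(d); d <- d[keep]; y <- y[keep]
  }
  sse <- function(log_rho)
    sum((y - hill_weir_expectation(d, exp(log_rho), n))^2)
  grid <- log(10^seq(-9, -1, by = 0.5))
  s0 <- vapply(grid, sse, 1)
  best <- grid[which.min(s0)]
  opt <- stats::optimize(sse, lower = best - 2, upper = best + 2)
  rho <- exp(opt$minimum)
  r0 <- hill_weir_expectation(1e-9, rho, n)
  target <- r0 / 2
  hd <- NA_real_
  if (hill_weir_expectation(1e12, rho, n) < target) {
    hd <- stats::uniroot(function(dd) hill_weir_expectation(dd, rho, n) - target,
                         lower = 1e-9, upper = 1e12, tol = 1e-3)$root
  }
  structure(list(rho = rho, n = n, half_decay_bp = hd, rss = opt$objective,
                 fitted = function(dd) hill_weir_expectation(dd, rho, n)),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("Hill-Weir decay fit: rho = %.3g, n = %d, half-decay = %s bp\n",
              x$rho, x$n, ifelse(is.na(x$half_decay_bp), "NA",
                                 format(round(x$half_decay_bp)))))
  invisible(x)
}

#' LD pruning by sliding marker window
#'
#' Within each window of `window_markers` consecutive markers (advanced by
#' `step`), for every pair with r2 >= `r2_threshold` the member with the
#' lower call rate is dropped (ties: lower MAF, then later position).
#' Deterministic. A window spanning all markers performs exhaustive
#' pruning.
#'
#' @param geno genotype_matrix. @param markers marker data.frame (sorted
#'   within chromosomes by position).
#' @param r2_threshold drop threshold (pairs with r2 >= this conflict).
#' @param window_markers,step window size and advance in markers.
#' @return character vector of retained marker ids.
#' @export
ld_prune <- function(geno, markers, r2_threshold = 0.5, window_markers = 50L,
                     step = 5L) {
  stopifnot(identical(colnames(geno), markers$marker_id))
  qc <- marker_qc(geno)
  dropped <- character(0)
  for (ch in unique(markers$chrom[!is.na(markers$chrom)])) {
    sel <- which(markers$chrom == ch)
    sel <- sel[order(markers$pos[sel])]
    m <- length(sel)
    if (m < 2L) next
    alive <- rep(TRUE, m)
    starts <- unique(c(seq(1L, max(m - 1L, 1L), by = step)))
    for (s in starts) {
      w <- s:min(s + window_markers - 1L, m)
      w <- w[alive[w]]
      if (length(w) < 2L) next
      sub <- unclass(geno[, sel[w], drop = FALSE])
      cc <- suppressWarnings(stats::cor(sub, use = "pairwise.complete.obs"))^2
      repeat {
        cc_chk <- cc; diag(cc_chk) <- NA
        live <- which(alive[w])
        if (length(live) < 2L) break
        mx <- suppressWarnings(max(cc_chk[live, live], na.rm = TRUE))
        if (!is.finite(mx) || mx < r2_threshold) break
        hit <- which(cc_chk == mx, arr.ind = TRUE)[1, ]
        i1 <- w[hit[1]]; i2 <- w[hit[2]]
        v1 <- c(qc$call_rate[sel[i1]], qc$maf[sel[i1]], -markers$pos[sel[i1]])
        v2 <- c(qc$call_rate[sel[i2]], qc$maf[sel[i2]], -markers$pos[sel[i2]])
        drop_first <- FALSE
        for (k in 1:3) {
          if (v1[k] < v2[k]) { drop_first <- TRUE; break }
          if (v1[k] > v2[k]) { drop_first <- FALSE; break }
        }
        loser <- if (drop_first) i1 else i2
        alive[loser] <- FALSE
        dropped <- c(dropped, markers$marker_id[sel[loser]])
        li <- which(w == loser)
        cc[li, ] <- NA; cc[, li] <- NA
      }
    }
  }
  setdiff(markers$marker_id, dropped)
}

#' Select a reduced SNP panel
#'
#' Filters to call rate >= `min_call_rate`, overall MAF > `min_maf`, and
#' polymorphism within every gene pool; LD-prunes at `r2_threshold`; then
#' fills the panel per chromosome by greedy max-min spacing until
#' `size_target` (allocated proportionally to surviving markers per
#' chromosome). Returns the maximal feasible panel with a warning when the
#' target exceeds the survivors.
#'
#' @param geno genotype_matrix. @param markers marker data.frame.
#' @param samples sample data.frame with `gene_pool` labels.
#' @param size_target panel size.
#' @param min_call_rate,min_maf,r2_threshold filter thresholds.
#' @return list(panel = marker ids, per_chrom = counts, mean_He, n_survivors).
#' @export
select_panel <- function(geno, markers, samples, size_target = 560,
                         min_call_rate = 0.75, min_maf = 0.05,
                         r2_threshold = 0.5) {
  stopifnot(identical(rownames(geno), samples$accession_id))
  pools <- setdiff(unique(samples$gene_pool), c("admixed", "unknown", NA))
  qc <- marker_qc(geno)
  keep <- qc$call_rate >= min_call_rate & !is.na(qc$maf) & qc$maf > min_maf &
    !is.na(markers$chrom)
  for (pl in pools) {
    p <- allele_freq_vec(geno, samples$gene_pool == pl)
    keep <- keep & !is.na(p) & p > 0 & p < 1
  }
  g1 <- geno[, keep, drop = FALSE]
  m1 <- markers[keep, , drop = FALSE]
  retained <- ld_prune(g1, m1, r2_threshold = r2_threshold)
  g2 <- g1[, retained, drop = FALSE]
  m2 <- m1[match(retained, m1$marker_id), , drop = FALSE]
  n_surv <- length(retained)
  if (n_surv <= size_target) {
    if (n_surv < size_target)
      warning("only ", n_surv, " markers survive filters; target was ",
              size_target)
    panel <- retained
  } else {
    chroms <- unique(m2$chrom)
    avail <- table(factor(m2$chrom, levels = chroms))
    alloc <- round(size_target * as.numeric(avail) / n_surv)
    alloc <- pmin(alloc, as.numeric(avail))
    while (sum(alloc) < size_target) {
      room <- as.numeric(avail) - alloc
      j <- which.max(room)
      if (room[j] <= 0) break
      alloc[j] <- alloc[j] + 1L
    }
    panel <- character(0)
    for (k in seq_along(chroms)) {
      sel <- which(m2$chrom == chroms[k])
      sel <- sel[order(m2$pos[sel])]
      panel <- c(panel, m2$marker_id[sel[maxmin_spacing(m2$pos[sel], alloc[k])]])
    }
  }
  he <- heterozygosity(geno[, panel, drop = FALSE])
  list(panel = panel,
       per_chrom = table(m2$chrom[match(panel, m2$marker_id)]),
       mean_He = he$summary$mean[he$summary$stat == "He"],
       n_survivors = n_surv)
}

# greedy max-min spacing: pick k indices from sorted positions maximizing
# the minimum gap (endpoints first, then farthest-from-chosen)
maxmin_spacing <- function(pos, k) {
  m <- length(pos)
  if (k >= m) return(seq_len(m))
  if (k <= 0L) return(integer(0))
  chosen <- c(1L, m)
  if (k == 1L) return(1L)
  while (length(chosen) < k) {
    dmin <- vapply(seq_len(m), function(i)
      min(abs(pos[i] - pos[chosen])), 1)
    dmin[chosen] <- -1
    chosen <- c(chosen, which.max(dmin))
  }
  sort(chosen[seq_len(k)])
}
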