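#' Tile chromosomes into non-overlapping windows
#'
#' Windows are half-open [start, start + length): a marker whose position
#' equals a window's end coordinate belongs to the next window (so position
#' 100,000 falls in the second 100-kb window). Starts/ends are reported
#' BED-style (0-based start, exclusive end). The terminal window of each
#' chromosome may be shorter.
#'
#' @param genome_map data.frame(chrom, length_bp).
#' @param markers marker data.frame; placed markers are assigned to windows.
#' @param length window length in bp (default 100 kb).
#' @return data.frame(chrom, start, end, n_markers) with a list column
#'   `idx` of marker indices (into `markers`) per window. Markers beyond the
#'   chromosome length are assigned to the terminal window with a warning.
#' @export
make_windows <- function(genome_map, markers, length = 100000L) {
  rows <- list()
  for (i in seq_len(nrow(genome_map))) {
    ch <- genome_map$chrom[i]; L <- genome_map$length_bp[i]
    n_win <- ceiling(L / length)
    start <- seq(0L, by = length, length.out = n_win)
    end <- pmin(start + length, L)             # exclusive end
    midx <- which(markers$chrom == ch & !is.na(markers$pos))
    over <- midx[markers$pos[midx] > L]
    if (length(over) > 0)
      warning(length(over), " marker(s) beyond length of ", ch,
              "; assigned to terminal window")
    wof <- pmin(markers$pos[midx] %/% length + 1L, n_win)
    idx <- split(midx, factor(wof, levels = seq_len(n_win)))
    rows[[i]] <- data.frame(chrom = ch, start = start, end = end,
                            n_markers = lengths(idx), stringsAsFactors = FALSE)
    rows[[i]]$idx <- unname(idx)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# per-locus derived statistics for a group within a marker subset
group_counts <- function(geno, mask, idx) {
  g <- geno[as_mask(mask, nrow(geno)), idx, drop = FALSE]
  n_typed <- colSums(!is.na(g))
  p <- colSums(g, na.rm = TRUE) / (2 * n_typed)
  p[n_typed == 0L] <- NA_real_
  list(p = p, n_chrom = 2L * n_typed)
}

#' Watterson's theta, pi and within diversity for one window
#'
#' S counts markers polymorphic within the group. theta_w = S / a_n with
#' a_n = sum_{i<n} 1/i and n the number of sampled chromosomes (2 x group
#' size). pi sums the unbiased per-site heterozygosity 2pq * n/(n-1);
#' nd_within sums the uncorrected 2pq. The `normalization` divides by the
#' window length in bp, the number of genotyped markers, or nothing —
#' SNP-only panels observe no invariant sites, so per-site magnitudes
#' depend on this choice and both are exposed.
#'
#' @param geno genotype_matrix. @param mask group selector.
#' @param idx marker indices of the window.
#' @param window_length bp length used for `"window_length"` normalization.
#' @param normalization one of `"window_length"`, `"marker_count"`, `"none"`.
#' @return list(S, theta_w, pi, nd_within, n).
#' @export
window_theta_pi <- function(geno, mask, idx, window_length = 100000,
                            normalization = c("window_length", "marker_count",
                                              "none")) {
  normalization <- match.arg(normalization)
  n <- 2L * sum(as_mask(mask, nrow(geno)))
  if (length(idx) == 0L)
    return(list(S = 0L, theta_w = 0, pi = 0, nd_within = 0, n = n))
  gc <- group_counts(geno, mask, idx)
  poly <- !is.na(gc$p) & gc$p > 0 & gc$p < 1
  S <- sum(poly)
  a_n <- sum(1 / seq_len(max(n - 1L, 1L)))
  nl <- gc$n_chrom
  uhe <- ifelse(poly, 2 * gc$p * (1 - gc$p) * nl / pmax(nl - 1L, 1L), 0)
  he <- ifelse(poly, 2 * gc$p * (1 - gc$p), 0)
  denom <- switch(normalization,
                  window_length = window_length,
                  marker_count = max(sum(!is.na(gc$p)), 1L),
                  none = 1)
  list(S = S, theta_w = (S / a_n) / denom, pi = sum(uhe) / denom,
       nd_within = sum(he) / denom, n = n)
}

# Tajima (1989) normalizing constants for sample size n
tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D for one window
#'
#' D = (pi_sum - S/a1) / sqrt(e1 S + e2 S (S-1)) with the 1989 constants for
#' n sampled chromosomes. pi_sum is the un-normalized sum over polymorphic
#' markers of the average pairwise difference x(n_l - x)/C(n_l, 2) (x the
#' alternate-allele count among the n_l typed chromosomes at the locus).
#' Undefined (NA) when S = 0 or n < 4.
#'
#' @param geno genotype_matrix. @param mask group selector.
#' @param idx marker indices of the window.
#' @return scalar D (NA when undefined).
#' @export
window_tajima_d <- function(geno, mask, idx) {
  n <- 2L * sum(as_mask(mask, nrow(geno)))
  if (n < 4L || length(idx) == 0L) return(NA_real_)
  gc <- group_counts(geno, mask, idx)
  poly <- !is.na(gc$p) & gc$p > 0 & gc$p < 1
  S <- sum(poly)
  if (S == 0L) return(NA_real_)
  nl <- gc$n_chrom[poly]
  x <- gc$p[poly] * nl
  pi_sum <- sum(x * (nl - x) / (nl * (nl - 1) / 2))
  k <- tajima_constants(n)
  (pi_sum - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

#' Window FST between two groups
#'
#' Default Hudson estimator as a ratio of sums over the window's markers:
#' FST = 1 - sum(Hw) / sum(Hb), Hw = mean within-group unbiased
#' heterozygosity, Hb = p_a(1-p_b) + p_b(1-p_a). `estimator = "nei"` uses
#' the per-locus Nei (Ht-Hs)/Ht averaged over markers.
#'
#' @param geno genotype_matrix. @param mask_a,mask_b group selectors.
#' @param idx marker indices. @param estimator `"hudson"` or `"nei"`.
#' @return scalar FST (NA when no polymorphic marker).
#' @export
window_fst <- function(geno, mask_a, mask_b, idx,
                       estimator = c("hudson", "nei")) {
  estimator <- match.arg(estimator)
  if (length(idx) == 0L) return(NA_real_)
  ca <- group_counts(geno, mask_a, idx)
  cb <- group_counts(geno, mask_b, idx)
  ok <- !is.na(ca$p) & !is.na(cb$p) & ca$n_chrom > 1 & cb$n_chrom > 1
  pa <- ca$p[ok]; pb <- cb$p[ok]
  poly <- (pa > 0 & pa < 1) | (pb > 0 & pb < 1) | (pa != pb)
  if (!any(poly)) return(NA_real_)
  pa <- pa[poly]; pb <- pb[poly]
  na <- ca$n_chrom[ok][poly]; nb <- cb$n_chrom[ok][poly]
  if (estimator == "hudson") {
    hw <- (2 * pa * (1 - pa) * na / (na - 1) + 2 * pb * (1 - pb) * nb / (nb - 1)) / 2
    hb <- pa * (1 - pb) + pb * (1 - pa)
    if (sum(hb) <= 0) return(NA_real_)
    1 - sum(hw) / sum(hb)
  } else {
    hs <- (2 * pa * (1 - pa) + 2 * pb * (1 - pb)) / 2
    pbar <- (pa + pb) / 2
    ht <- 2 * pbar * (1 - pbar)
    sel <- ht > 0
    mean((ht[sel] - hs[sel]) / ht[sel])
  }
}

#' Windowed genome scan
#'
#' Computes S, Watterson's theta, pi, within diversity and Tajima's D per
#' group, and FST between two named groups, for every non-overlapping
#' window.
#'
#' @param geno genotype_matrix. @param markers marker data.frame.
#' @param genome_map data.frame(chrom, length_bp).
#' @param mask_a,mask_b the two groups compared by FST (also used for the
#'   per-group statistics, reported with suffixes `_a` and `_b`).
#' @param window_length bp (default 100 kb).
#' @param normalization passed to [window_theta_pi()].
#' @param estimator passed to [window_fst()].
#' @return data.frame, one row per window.
#' @export
scan_genome <- function(geno, markers, genome_map, mask_a, mask_b,
                        window_length = 100000L,
                        normalization = "window_length",
                        estimator = "hudson") {
  win <- make_windows(genome_map, markers, window_length)
  col_idx <- function(idx) match(markers$marker_id[idx], colnames(geno))
  res <- lapply(seq_len(nrow(win)), function(w) {
    idx <- col_idx(win$idx[[w]])
    idx <- idx[!is.na(idx)]
    ta <- window_theta_pi(geno, mask_a, idx, window_length, normalization)
    tb <- window_theta_pi(geno, mask_b, idx, window_length, normalization)
    data.frame(S_a = ta$S, theta_w_a = ta$theta_w, pi_a = ta$pi,
               nd_within_a = ta$nd_within,
               tajima_d_a = window_tajima_d(geno, mask_a, idx),
               S_b = tb$S, theta_w_b = tb$theta_w, pi_b = tb$pi,
               nd_within_b = tb$nd_within,
               tajima_d_b = window_tajima_d(geno, mask_b, idx),
               fst = window_fst(geno, mask_a, mask_b, idx, estimator))
  })
  cbind(win[, c("chrom", "start", "end", "n_markers")], do.call(rbind, res))
}
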