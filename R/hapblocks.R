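#' Two-locus haplotype frequencies
#'
#' With `het_as_missing = TRUE` (the selfing-germplasm convention)
#' heterozygous calls are masked, the remaining genotypes are homozygous,
#' and haplotype counts are read directly: each retained accession
#' contributes two identical gametes. With `het_as_missing = FALSE` an EM
#' over the double-heterozygote phase ambiguity is run.
#'
#' @param geno genotype_matrix. @param i,j marker columns (index or name).
#' @param het_as_missing mask heterozygotes (default TRUE).
#' @param min_joint minimum informative accessions (default 5).
#' @param tol,max_iter EM controls.
#' @return list(freqs = c(AB, Ab, aB, ab) with A/B = alternate alleles,
#'   n_gametes, informative) or `informative = FALSE` when data are
#'   insufficient.
#' @export
twolocus_haplotype_freqs <- function(geno, i, j, het_as_missing = TRUE,
                                     min_joint = 5L, tol = 1e-10,
                                     max_iter = 500L) {
  x <- unclass(geno)[, i]; y <- unclass(geno)[, j]
  if (het_as_missing) {
    keep <- !is.na(x) & !is.na(y) & x != 1L & y != 1L
    if (sum(keep) < min_joint)
      return(list(freqs = rep(NA_real_, 4), n_gametes = 0L,
                  informative = FALSE))
    xa <- x[keep] / 2L; yb <- y[keep] / 2L     # 0/1 allele per accession
    n <- 2L * sum(keep)
    cnt <- c(AB = sum(xa == 1 & yb == 1), Ab = sum(xa == 1 & yb == 0),
             aB = sum(xa == 0 & yb == 1), ab = sum(xa == 0 & yb == 0)) * 2L
    return(list(freqs = cnt / n, n_gametes = n, informative = TRUE))
  }
  keep <- !is.na(x) & !is.na(y)
  if (sum(keep) < min_joint)
    return(list(freqs = rep(NA_real_, 4), n_gametes = 0L,
                informative = FALSE))
  x <- x[keep]; y <- y[keep]
  n <- 2L * length(x)
  # genotype cell counts n[x, y], x/y in 0..2
  cells <- table(factor(x, 0:2), factor(y, 0:2))
  f <- rep(0.25, 4)                     # AB, Ab, aB, ab
  for (it in seq_len(max_iter)) {
    # expected AB gametes: double hets split by f_AB f_ab / (f_AB f_ab + f_Ab f_aB)
    dh <- cells["1", "1"]
    denom <- f[1] * f[4] + f[2] * f[3]
    w <- if (denom > 0) f[1] * f[4] / denom else 0.5
    nAB <- 2 * cells["2", "2"] + cells["2", "1"] + cells["1", "2"] + dh * w
    nAb <- 2 * cells["2", "0"] + cells["2", "1"] + cells["1", "0"] + dh * (1 - w)
    naB <- 2 * cells["0", "2"] + cells["0", "1"] + cells["1", "2"] + dh * (1 - w)
    nab <- 2 * cells["0", "0"] + cells["0", "1"] + cells["1", "0"] + dh * w
    f_new <- c(nAB, nAb, naB, nab) / n
    if (max(abs(f_new - f)) < tol) { f <- f_new; break }
    f <- f_new
  }
  list(freqs = stats::setNames(f, c("AB", "Ab", "aB", "ab")), n_gametes = n,
       informative = TRUE)
}

#' D-prime with a likelihood-grid confidence interval (Gabriel categories)
#'
#' D = p_AB - p_A p_B; D' = D / D_max with the sign-dependent D_max. The CI
#' comes from evaluating the multinomial likelihood of the observed gamete
#' counts on a |D'| grid (allele frequencies fixed at their MLEs),
#' normalizing, and taking the cumulative 5th/95th points. Categories:
#' `strong_LD` when ci_low >= 0.70 and ci_high >= 0.98; `strong_recomb`
#' when ci_high < 0.90; otherwise `other`.
#'
#' @param hf result of [twolocus_haplotype_freqs()].
#' @param grid_step grid resolution on |D'| (default 0.001).
#' @return list(d_prime, ci_low, ci_high, category, informative).
#' @export
dprime_ci <- function(hf, grid_step = 0.001) {
  if (!isTRUE(hf$informative))
    return(list(d_prime = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                category = "uninformative", informative = FALSE))
  f <- hf$freqs
  pA <- f[1] + f[2]; pB <- f[1] + f[3]
  if (pA %in% c(0, 1) || pB %in% c(0, 1))
    return(list(d_prime = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                category = "uninformative", informative = FALSE))
  D <- f[1] - pA * pB
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB) else
    min(pA * pB, (1 - pA) * (1 - pB))
  dp <- if (dmax > 0) abs(D) / dmax else 0
  counts <- round(f * hf$n_gametes)
  sgn <- if (D >= 0) 1 else -1
  grid <- seq(0, 1, by = grid_step)
  ll <- vapply(grid, function(g) {
    Dg <- sgn * g * dmax
    pr <- c(pA * pB + Dg, pA * (1 - pB) - Dg,
            (1 - pA) * pB - Dg, (1 - pA) * (1 - pB) + Dg)
    if (any(pr < -1e-12)) return(-Inf)
    pr <- pmax(pr, 1e-12)
    sum(counts * log(pr))
  }, 1)
  w <- exp(ll - max(ll))
  w <- w / sum(w)
  cw <- cumsum(w)
  ci_low <- grid[which(cw >= 0.05)[1]]
  ci_high <- grid[which(cw >= 0.95)[1]]
  category <- if (ci_low >= 0.70 && ci_high >= 0.98) "strong_LD"
  else if (ci_high < 0.90) "strong_recomb" else "other"
  list(d_prime = unname(dp), ci_low = ci_low, ci_high = ci_high,
       category = category, informative = TRUE)
}

#' All-pairs D-prime CI records within chromosomes
#'
#' @param geno genotype_matrix. @param markers marker data.frame.
#' @param max_dist only pairs within this distance (bp).
#' @param het_as_missing passed to [twolocus_haplotype_freqs()].
#' @param maf_min,min_call_rate marker filters applied first.
#' @return data.frame(id_a, id_b, chrom, pos_a, pos_b, dist_bp, d_prime,
#'   ci_low, ci_high, category).
#' @export
dprime_records <- function(geno, markers, max_dist = 500000L,
                           het_as_missing = TRUE, maf_min = 0.05,
                           min_call_rate = 0.75) {
  fl <- filter_markers(geno, markers, min_call_rate = min_call_rate,
                       min_maf = maf_min)
  g <- fl$geno; mk <- fl$markers
  rows <- list(); k <- 0L
  for (ch in unique(mk$chrom[!is.na(mk$chrom)])) {
    sel <- which(mk$chrom == ch)
    sel <- sel[order(mk$pos[sel])]
    m <- length(sel)
    if (m < 2L) next
    for (a in seq_len(m - 1L)) for (b in (a + 1L):m) {
      d <- mk$pos[sel[b]] - mk$pos[sel[a]]
      if (d > max_dist) break
      hf <- twolocus_haplotype_freqs(g, sel[a], sel[b], het_as_missing)
      ci <- dprime_ci(hf)
      k <- k + 1L
      rows[[k]] <- data.frame(id_a = mk$marker_id[sel[a]],
                              id_b = mk$marker_id[sel[b]], chrom = ch,
                              pos_a = mk$pos[sel[a]], pos_b = mk$pos[sel[b]],
                              dist_bp = d, d_prime = ci$d_prime,
                              ci_low = ci$ci_low, ci_high = ci$ci_high,
                              category = ci$category,
                              stringsAsFactors = FALSE)
    }
  }
  out <- if (k) do.call(rbind, rows) else
    data.frame(id_a = character(), id_b = character(), chrom = character(),
               pos_a = integer(), pos_b = integer(), dist_bp = integer(),
               d_prime = numeric(), ci_low = numeric(), ci_high = numeric(),
               category = character())
  rownames(out) <- NULL
  out
}

#' Gabriel confidence-interval haplotype blocks
#'
#' Candidate spans are marker intervals whose outermost pair is
#' `strong_LD`; a span is accepted when strong_LD / (strong_LD +
#' strong_recomb) >= `informFrac` among its informative pairs. Spans are
#' taken greedily by size (bp), ties to the leftmost start, without
#' overlap. Two-marker blocks require the single pair to be strong_LD and
#' closer than `maxDist`.
#'
#' @param ci_records output of [dprime_records()].
#' @param markers marker data.frame.
#' @param informFrac strong-LD fraction threshold (default 0.95).
#' @param maxDist maximum pair distance considered (bp).
#' @return data.frame(chrom, start_bp, end_bp, span_bp, n_markers,
#'   first_marker, last_marker) with list column `members`.
#' @export
gabriel_blocks <- function(ci_records, markers, informFrac = 0.95,
                           maxDist = 500000L) {
  out <- list()
  for (ch in unique(ci_records$chrom)) {
    rec <- ci_records[ci_records$chrom == ch, , drop = FALSE]
    ids <- unique(c(rec$id_a, rec$id_b))
    pos <- markers$pos[match(ids, markers$marker_id)]
    ord <- order(pos)
    ids <- ids[ord]; pos <- pos[ord]
    m <- length(ids)
    if (m < 2L) next
    key <- paste(rec$id_a, rec$id_b)
    cat_of <- function(a, b) {
      k1 <- match(paste(ids[a], ids[b]), key)
      if (is.na(k1)) k1 <- match(paste(ids[b], ids[a]), key)
      if (is.na(k1)) NA_character_ else rec$category[k1]
    }
    cand <- list(); ck <- 0L
    for (a in seq_len(m - 1L)) for (b in (a + 1L):m) {
      if (pos[b] - pos[a] > maxDist) break
      if (identical(cat_of(a, b), "strong_LD")) {
        inner <- expand.grid(x = a:b, y = a:b)
        inner <- inner[inner$x < inner$y, ]
        cats <- mapply(cat_of, inner$x, inner$y)
        n_ld <- sum(cats == "strong_LD", na.rm = TRUE)
        n_rec <- sum(cats == "strong_recomb", na.rm = TRUE)
        if (n_ld + n_rec == 0L) next
        if (n_ld / (n_ld + n_rec) >= informFrac) {
          ck <- ck + 1L
          cand[[ck]] <- c(a = a, b = b, span = pos[b] - pos[a])
        }
      }
    }
    if (ck == 0L) next
    cand <- do.call(rbind, cand)
    cand <- cand[order(-cand[, "span"], cand[, "a"]), , drop = FALSE]
    used <- rep(FALSE, m)
    for (r in seq_len(nrow(cand))) {
      a <- cand[r, "a"]; b <- cand[r, "b"]
      if (any(used[a:b])) next
      used[a:b] <- TRUE
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start_bp = pos[a], end_bp = pos[b],
        span_bp = pos[b] - pos[a], n_markers = b - a + 1L,
        first_marker = ids[a], last_marker = ids[b],
        members = I(list(ids[a:b])), stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start_bp = integer(), end_bp = integer(),
               span_bp = integer(), n_markers = integer(),
               first_marker = character(), last_marker = character(),
               members = I(list()))
  rownames(res) <- NULL
  res[order(res$chrom, res$start_bp), , drop = FALSE]
}

#' Per-chromosome block summary (counts, SNPs/block, span, genome coverage)
#'
#' @param blocks output of [gabriel_blocks()].
#' @param genome_map data.frame(chrom, length_bp).
#' @return list(per_chrom, totals) where totals include `coverage_pct` =
#'   100 * total block span / genome length and `mean_snps_per_block`.
#' @export
block_summary <- function(blocks, genome_map) {
  per <- lapply(genome_map$chrom, function(ch) {
    b <- blocks[blocks$chrom == ch, , drop = FALSE]
    data.frame(chrom = ch, n_blocks = nrow(b),
               mean_snps_per_block = if (nrow(b)) mean(b$n_markers) else NA,
               total_span_bp = sum(b$span_bp),
               coverage_pct = 100 * sum(b$span_bp) /
                 genome_map$length_bp[genome_map$chrom == ch])
  })
  per <- do.call(rbind, per)
  totals <- data.frame(
    n_blocks = nrow(blocks),
    mean_snps_per_block = if (nrow(blocks)) mean(blocks$n_markers) else NA,
    total_span_bp = sum(blocks$span_bp),
    coverage_pct = 100 * sum(blocks$span_bp) / sum(genome_map$length_bp))
  list(per_chrom = per, totals = totals)
}
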