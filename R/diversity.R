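#' Per-marker allele frequencies within a group
#'
#' @param geno genotype_matrix.
#' @param mask logical/integer accession selector (default: all).
#' @return vector of alternate-allele frequencies p = (2 n2 + n1)/(2 n_typed);
#'   NA where the group has no typed call.
#' @export
allele_frequencies <- function(geno, mask = NULL) {
  if (!is.null(mask) && sum(as_mask(mask, nrow(geno))) == 0L)
    stop("empty group")
  allele_freq_vec(geno, mask)
}

as_mask <- function(mask, n) {
  if (is.logical(mask)) { stopifnot(length(mask) == n); mask }
  else { m <- rep(FALSE, n); m[mask] <- TRUE; m }
}

#' Observed/expected heterozygosity and inbreeding per marker
#'
#' He = 2pq, uHe = He * 2n/(2n-1) (n = typed accessions at the marker),
#' Ho = fraction heterozygous among typed, F = 1 - Ho/He (undefined where
#' He = 0). Means are taken over defined loci with SE = sd/sqrt(L).
#'
#' @param geno genotype_matrix. @param mask accession selector.
#' @return list with per-locus vectors (`Ho`, `He`, `uHe`, `F`) and a
#'   `summary` data.frame of means and standard errors.
#' @export
heterozygosity <- function(geno, mask = NULL) {
  g <- if (is.null(mask)) geno else geno[as_mask(mask, nrow(geno)), , drop = FALSE]
  n_typed <- colSums(!is.na(g))
  p <- allele_freq_vec(g)
  He <- 2 * p * (1 - p)
  uHe <- ifelse(n_typed > 0, He * 2 * n_typed / pmax(2 * n_typed - 1, 1), NA_real_)
  Ho <- colSums(g == 1L, na.rm = TRUE) / n_typed
  Ho[n_typed == 0L] <- NA_real_
  Fl <- ifelse(!is.na(He) & He > 0, 1 - Ho / He, NA_real_)
  msd <- function(x) {
    x <- x[!is.na(x)]
    c(mean = mean(x), se = stats::sd(x) / sqrt(length(x)))
  }
  list(Ho = Ho, He = He, uHe = uHe, F = Fl,
       summary = data.frame(stat = c("Ho", "He", "uHe", "F"),
                            rbind(msd(Ho), msd(He), msd(uHe), msd(Fl)),
                            row.names = NULL))
}

#' Hierarchical F-statistics (Nei decomposition, unweighted subpopulations)
#'
#' Per locus: Hs = unweighted mean of subpopulation He; Ht = He of the
#' unweighted mean allele frequency; Ho_bar = unweighted mean of
#' subpopulation Ho. FST = (Ht-Hs)/Ht, FIS = (Hs-Ho_bar)/Hs,
#' FIT = (Ht-Ho_bar)/Ht. Loci with Ht = 0 are skipped. Satisfies
#' (1-FIT) = (1-FIS)(1-FST) per locus.
#'
#' @param geno genotype_matrix.
#' @param subpop_masks named list of accession selectors (>= 2 groups of
#'   >= 2 accessions).
#' @return list with per-locus vectors, means +/- SE, and a pairwise Nei
#'   FST matrix between the subpopulations.
#' @export
fixation_indices <- function(geno, subpop_masks) {
  stopifnot(length(subpop_masks) >= 2)
  masks <- lapply(subpop_masks, as_mask, n = nrow(geno))
  if (any(vapply(masks, sum, 1L) < 2L)) stop("each subpopulation needs >= 2 accessions")
  P <- vapply(masks, function(m) allele_freq_vec(geno, m), numeric(ncol(geno)))
  P <- matrix(P, nrow = ncol(geno), dimnames = list(NULL, names(masks)))
  Hosub <- vapply(masks, function(m) {
    g <- geno[m, , drop = FALSE]
    t <- colSums(!is.na(g))
    h <- colSums(g == 1L, na.rm = TRUE) / t
    h[t == 0L] <- NA_real_
    h
  }, numeric(ncol(geno)))
  Hosub <- matrix(Hosub, nrow = ncol(geno))
  Hs <- rowMeans(2 * P * (1 - P))
  pbar <- rowMeans(P)
  Ht <- 2 * pbar * (1 - pbar)
  Hob <- rowMeans(Hosub)
  ok <- !is.na(Ht) & Ht > 0 & !is.na(Hs) & !is.na(Hob)
  if (!any(ok)) stop("no locus polymorphic overall")
  fst <- (Ht - Hs) / Ht
  fis <- ifelse(Hs > 0, (Hs - Hob) / Hs, NA_real_)
  fit <- (Ht - Hob) / Ht
  fst[!ok] <- fis[!ok] <- fit[!ok] <- NA_real_
  msd <- function(x) {
    x <- x[!is.na(x)]
    c(mean = mean(x), se = stats::sd(x) / sqrt(length(x)))
  }
  k <- length(masks)
  pw <- matrix(NA_real_, k, k, dimnames = list(names(masks), names(masks)))
  diag(pw) <- 0
  for (a in seq_len(k - 1)) for (b in (a + 1):k) {
    hs <- (2 * P[, a] * (1 - P[, a]) + 2 * P[, b] * (1 - P[, b])) / 2
    pb <- (P[, a] + P[, b]) / 2
    ht <- 2 * pb * (1 - pb)
    sel <- !is.na(ht) & ht > 0
    pw[a, b] <- pw[b, a] <- mean((ht[sel] - hs[sel]) / ht[sel])
  }
  # multilocus (Nei 1973) estimates: heterozygosities averaged over loci
  # first, then combined — robust to near-fixed loci
  Hs_m <- mean(Hs, na.rm = TRUE); Ht_m <- mean(Ht, na.rm = TRUE)
  Hob_m <- mean(Hob, na.rm = TRUE)
  multilocus <- data.frame(stat = c("FST", "FIS", "FIT"),
                           estimate = c((Ht_m - Hs_m) / Ht_m,
                                        (Hs_m - Hob_m) / Hs_m,
                                        (Ht_m - Hob_m) / Ht_m))
  list(fst = fst, fis = fis, fit = fit, Hs = Hs, Ht = Ht, Ho_bar = Hob,
       summary = data.frame(stat = c("FST", "FIS", "FIT"),
                            rbind(msd(fst), msd(fis), msd(fit)),
                            row.names = NULL),
       multilocus = multilocus,
       pairwise_fst = pw)
}

#' Count private alleles per group
#'
#' An allele is private to group g when its frequency is > 0 in g and 0 in
#' every other group (evaluated on typed calls). Counts alleles, not loci:
#' at a biallelic locus both alleles are examined.
#'
#' @param geno genotype_matrix. @param group_masks named list of selectors.
#' @return named integer vector of private-allele counts.
#' @export
private_alleles <- function(geno, group_masks) {
  stopifnot(length(group_masks) >= 2)
  P <- vapply(group_masks, function(m) allele_freq_vec(geno, as_mask(m, nrow(geno))),
              numeric(ncol(geno)))
  P <- matrix(P, nrow = ncol(geno), dimnames = list(NULL, names(group_masks)))
  out <- integer(ncol(P)); names(out) <- colnames(P)
  for (g in seq_len(ncol(P))) {
    others <- P[, -g, drop = FALSE]
    alt_priv <- !is.na(P[, g]) & P[, g] > 0 &
      apply(others, 1, function(x) all(is.na(x) | x == 0))
    ref_priv <- !is.na(P[, g]) & P[, g] < 1 &
      apply(others, 1, function(x) all(is.na(x) | x == 1))
    out[g] <- sum(alt_priv, na.rm = TRUE) + sum(ref_priv, na.rm = TRUE)
  }
  out
}

# one-parent exclusion probability for a biallelic locus at freq p, by
# exhaustive enumeration of HWE mother/offspring configurations
pe_one_parent <- function(p) {
  q <- 1 - p
  gf <- c(p^2, 2 * p * q, q^2)          # genotype freqs for dosages 2,1,0
  alleles <- list(c(2, 2), c(2, 0), c(0, 0))  # allele pairs (2 = alt copy coded)
  # transmitted allele prob from genotype: P(transmit alt)
  tr <- c(1, 0.5, 0)
  pe <- 0
  for (gm in 1:3) for (gk in 1:3) {
    # P(mother gm, offspring gk) = gf[gm] * sum_over paternal allele
    # maternal contribution:
    pm_alt <- tr[gm]
    # offspring dosage = maternal allele + paternal allele
    # paternal allele drawn from population: P(alt) = p
    p_off <- switch(gk,
      pm_alt * p,                                   # offspring 2: alt+alt
      pm_alt * q + (1 - pm_alt) * p,                # offspring 1
      (1 - pm_alt) * q)                             # offspring 0
    pr <- gf[gm] * p_off
    if (pr == 0) next
    # which paternal alleles are compatible given (gm, gk)?
    # paternal allele must satisfy: exists maternal allele a_m from gm with
    # a_m + a_p == gk's dosage decomposition
    m_all <- unique(alleles[[gm]] / 2)              # maternal allele values 0/1
    k_dos <- c(2, 1, 0)[gk]
    compat_pat <- unique(unlist(lapply(m_all, function(a) {
      ap <- k_dos - a
      ap[ap %in% c(0, 1)]
    })))
    # random male excluded iff none of his two alleles is compatible
    if (length(compat_pat) == 2L) p_excl <- 0
    else if (length(compat_pat) == 0L) p_excl <- 1
    else {
      f_incompat <- if (compat_pat == 1) q else p    # freq of the bad allele
      p_excl <- f_incompat^2                         # male homozygous bad
    }
    pe <- pe + pr * p_excl
  }
  pe
}

#' Multilocus probability of identity and combined exclusion probability
#'
#' PI per locus = sum p_i^4 + sum_{i<j} (2 p_i p_j)^2 under HWE; multilocus
#' PI is the product (accumulated in log space). PE per locus is the
#' one-parent exclusion probability from exhaustive enumeration of HWE
#' mother/offspring configurations; combined PE = 1 - prod(1 - PE_l).
#' Monomorphic loci contribute PI = 1, PE = 0.
#'
#' @param geno genotype_matrix. @param mask accession selector.
#' @return list(PI, PE, per_locus).
#' @export
identity_exclusion <- function(geno, mask = NULL) {
  p <- allele_freq_vec(geno, if (is.null(mask)) NULL else as_mask(mask, nrow(geno)))
  p <- p[!is.na(p)]
  q <- 1 - p
  pi_l <- p^4 + q^4 + (2 * p * q)^2
  pe_l <- vapply(p, pe_one_parent, 1)
  pe_l[p %in% c(0, 1)] <- 0
  PI <- exp(sum(log(pi_l)))
  PE <- 1 - exp(sum(log1p(-pe_l)))
  list(PI = PI, PE = PE,
       per_locus = data.frame(p = p, PI = pi_l, PE = pe_l))
}

#' Group-wise diversity summary and between-group F-statistics
#'
#' Reproduces the classic germplasm-report layout: per group the sample
#' size, percent polymorphic loci, private-allele count, mean Ho/He/F with
#' SEs, PI and PE; plus hierarchical F-statistics between the groups.
#' Accessions labelled `admixed` or `unknown` in the grouping column are
#' excluded.
#'
#' @param geno genotype_matrix. @param samples sample data.frame.
#' @param grouping `"gene_pool"`, `"stratum_within_pool"` (groups are
#'   pool:stratum combinations), or the name of a column of `samples`.
#' @return list(groups = per-group data.frame, fstats = [fixation_indices()]
#'   output, masks = the group masks used).
#' @export
group_summary <- function(geno, samples, grouping = "gene_pool") {
  stopifnot(identical(rownames(geno), samples$accession_id))
  lab <- if (grouping == "stratum_within_pool") {
    ifelse(samples$gene_pool %in% c("admixed", "unknown") |
             samples$stratum %in% "unknown", "admixed",
           paste(samples$gene_pool, samples$stratum, sep = ":"))
  } else samples[[grouping]]
  keep <- !(lab %in% c("admixed", "unknown")) & !is.na(lab)
  groups <- unique(lab[keep])
  masks <- lapply(groups, function(g) lab == g & keep)
  names(masks) <- groups
  nap <- if (length(groups) >= 2) private_alleles(geno, masks) else
    stats::setNames(rep(NA_integer_, length(groups)), groups)
  rows <- lapply(groups, function(g) {
    m <- masks[[g]]
    het <- heterozygosity(geno, m)
    p <- allele_freq_vec(geno, m)
    poly <- mean(!is.na(p) & p > 0 & p < 1) * 100
    ie <- identity_exclusion(geno, m)
    s <- het$summary
    data.frame(group = g, S = sum(m), P_pct = poly, NAP = nap[[g]],
               Ho = s$mean[s$stat == "Ho"], Ho_se = s$se[s$stat == "Ho"],
               He = s$mean[s$stat == "He"], He_se = s$se[s$stat == "He"],
               F = s$mean[s$stat == "F"], F_se = s$se[s$stat == "F"],
               PI = ie$PI, PE = ie$PE, stringsAsFactors = FALSE)
  })
  fst <- if (length(groups) >= 2 && all(vapply(masks, sum, 1L) >= 2))
    fixation_indices(geno, masks) else NULL
  list(groups = do.call(rbind, rows), fstats = fst, masks = masks)
}
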