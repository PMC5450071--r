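#' Simulation configuration for a two-gene-pool selfing germplasm collection
#'
#' Defaults emulate a bean-like core collection: two deeply diverged gene
#' pools (target Nei FST 0.75) of 64 and 111 accessions plus 6 admixed
#' individuals, two strata per pool (landrace vs cultivar/line, FST ~ 0.02),
#' strong selfing (F = 0.6, giving observed heterozygosity near 0.04 when
#' within-pool gene diversity is ~0.1), ~8% missing calls, a small fraction
#' of loci with boosted between-pool divergence, and block LD generated by
#' recombining founder haplotypes (slower decay in pool 1).
#'
#' @param n_pool1,n_pool2,n_admixed accession counts per pool and admixed.
#' @param strata_split fraction of each pool labelled "landrace".
#' @param n_chrom,chrom_length_bp,n_markers genome layout (markers are split
#'   evenly over chromosomes at uniform random positions).
#' @param target_fst_pools,target_fst_strata Nei FST targets between pools
#'   and between strata within a pool.
#' @param selfing_F per-accession probability that the two gametes are
#'   identical by descent (the selfing coin).
#' @param outlier_fraction,outlier_fst_boost fraction of loci under
#'   divergent selection and the additive FST boost they receive.
#' @param n_founders founder haplotypes per pool for the LD model; `Inf`
#'   draws loci independently (no LD).
#' @param recomb_rate_per_bp per-pool per-generation crossover rate per bp
#'   (length 2; pool 1 lower = slower decay).
#' @param generations recombination generations applied to founders.
#' @param missing_rate fraction of calls masked at random.
#' @param freq_model `"uniform"` draws ancestral frequencies uniform on
#'   [0.05, 0.95]; `"neutral_sfs"` draws derived-allele counts from the
#'   neutral 1/x spectrum (used for neutrality checks of Tajima's D).
#' @param seed integer RNG seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_pool1 = 64, n_pool2 = 111, n_admixed = 6,
                       strata_split = 0.5, n_chrom = 11,
                       chrom_length_bp = 47e6, n_markers = 5000,
                       target_fst_pools = 0.75, target_fst_strata = 0.02,
                       selfing_F = 0.6, outlier_fraction = 0.01,
                       outlier_fst_boost = 0.2, n_founders = 60,
                       recomb_rate_per_bp = c(5e-9, 2e-8), generations = 30,
                       missing_rate = 0.08,
                       freq_model = c("uniform", "neutral_sfs"), seed = 1L) {
  cfg <- list(n_pool1 = n_pool1, n_pool2 = n_pool2, n_admixed = n_admixed,
              strata_split = strata_split, n_chrom = n_chrom,
              chrom_length_bp = chrom_length_bp, n_markers = n_markers,
              target_fst_pools = target_fst_pools,
              target_fst_strata = target_fst_strata, selfing_F = selfing_F,
              outlier_fraction = outlier_fraction,
              outlier_fst_boost = outlier_fst_boost, n_founders = n_founders,
              recomb_rate_per_bp = rep_len(recomb_rate_per_bp, 2),
              generations = generations, missing_rate = missing_rate,
              freq_model = match.arg(freq_model), seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_pool1 >= 0, n_pool2 >= 0, n_admixed >= 0,
              strata_split >= 0, strata_split <= 1,
              target_fst_pools >= 0, target_fst_pools < 1,
              target_fst_strata >= 0, target_fst_strata < 1,
              selfing_F >= 0, selfing_F <= 1,
              outlier_fraction >= 0, outlier_fraction <= 1,
              missing_rate >= 0, missing_rate <= 1, n_markers >= 1)
  })
  class(cfg) <- "sim_config"
  cfg
}

#' Balding-Nichols divergence: the beta parameter giving a target Nei FST
#'
#' With two descendant populations drawn from Beta(p(1-F)/F, (1-p)(1-F)/F),
#' E[Hs] = 2pq(1-F) and E[Ht] = 2pq(1-F/2), so the expected two-population
#' Nei FST is (F/2)/(1-F/2). Inverting gives F = 2t/(1+t) for target t.
#' @param target_fst desired Nei FST between two derived populations.
#' @return the Balding-Nichols F to use in [simulate_pool_freqs()].
#' @export
bn_param_for_fst <- function(target_fst) 2 * target_fst / (1 + target_fst)

#' Draw descendant-population allele frequencies (Balding-Nichols)
#'
#' @param p_anc ancestral frequencies (vector, in (0,1)).
#' @param fst the Balding-Nichols divergence parameter F (the beta-scale
#'   parameter, not the realized Nei FST; see [bn_param_for_fst()]).
#' @return vector of derived frequencies; `fst = 0` returns `p_anc` exactly.
#' @export
simulate_pool_freqs <- function(p_anc, fst) {
  stopifnot(all(p_anc > 0 & p_anc < 1), fst >= 0, fst < 1)
  if (fst == 0) return(p_anc)
  lambda <- (1 - fst) / fst
  stats::rbeta(length(p_anc), p_anc * lambda, (1 - p_anc) * lambda)
}

#' Generate recombined haplotype pools for one chromosome
#'
#' Founder haplotypes are drawn per-marker from the supplied frequencies;
#' each emitted haplotype is a founder mosaic with crossover breakpoints
#' accumulated over `generations` meioses at `rate` per bp (a Poisson
#' number of breakpoints, each segment copied from an independently chosen
#' founder). Adjacent-marker LD therefore decays with distance while
#' marker-wise allele frequencies stay pinned to the founder sample —
#' no extra genetic drift is introduced beyond the founder draw.
#'
#' @param freqs per-marker allele frequencies on this chromosome.
#' @param pos sorted marker positions (bp).
#' @param n_hap number of haplotypes to return.
#' @param n_founders founder haplotypes; `Inf` = independent loci (no LD).
#' @param rate per-bp crossover rate per generation.
#' @param generations meioses contributing breakpoints.
#' @param len chromosome length (bp).
#' @return 0/1 matrix `n_hap` x length(freqs).
#' @export
simulate_haplotypes_ld <- function(freqs, pos, n_hap, n_founders = 60,
                                   rate = 1e-8, generations = 30,
                                   len = max(pos)) {
  m <- length(freqs)
  if (m == 0L) return(matrix(integer(0), n_hap, 0L))
  stopifnot(length(pos) == m, !is.unsorted(pos))
  if (!is.finite(n_founders)) {
    return(matrix(stats::rbinom(n_hap * m, 1L, rep(freqs, each = n_hap)),
                  n_hap, m))
  }
  Fd <- matrix(stats::rbinom(n_founders * m, 1L, rep(freqs, each = n_founders)),
               n_founders, m)
  out <- matrix(0L, n_hap, m)
  n_x <- stats::rpois(n_hap, generations * rate * len)
  for (i in seq_len(n_hap)) {
    if (n_x[i] == 0L) {
      out[i, ] <- Fd[sample.int(n_founders, 1L), ]
    } else {
      brk <- sort(stats::runif(n_x[i], 0, len))
      seg <- findInterval(pos, brk) + 1L
      src <- sample.int(n_founders, n_x[i] + 1L, replace = TRUE)
      out[i, ] <- Fd[cbind(src[seg], seq_len(m))]
    }
  }
  out
}

#' Simulate a structured, selfing germplasm collection
#'
#' Composes the Balding-Nichols two-tier divergence model (pools, then
#' strata within pools, with divergent-selection loci receiving a boosted
#' pool-level FST), founder-haplotype LD, per-accession selfing (with
#' probability `selfing_F` the two gametes are identical by descent),
#' admixed accessions drawing gametes from both pools according to a true
#' q in [0.3, 0.7], random missingness, and clustered geo-coordinates.
#'
#' @param config a [sim_config()].
#' @return list(geno, markers, samples, truth) where `truth` holds the
#'   ancestral/pool/stratum frequencies, outlier flags, true q, and the
#'   per-accession pool/stratum labels used for generation.
#' @export
simulate_collection <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  m <- config$n_markers
  per_chr <- diff(round(seq(0, m, length.out = config$n_chrom + 1L)))
  chrom <- rep(sprintf("Chr%02d", seq_len(config$n_chrom)), per_chr)
  pos <- unlist(lapply(per_chr, function(k)
    sort(sample.int(config$chrom_length_bp, k))))
  marker_ids <- sprintf("snp%05d", seq_len(m))
  markers <- marker_info(marker_ids, chrom = chrom, pos = pos)

  n1 <- config$n_pool1; n2 <- config$n_pool2; na <- config$n_admixed
  n_tot <- n1 + n2 + na

  # ancestral frequencies
  if (config$freq_model == "uniform") {
    p_anc <- stats::runif(m, 0.05, 0.95)
  } else {
    n_chrms <- 2L * n_tot
    x <- sample(seq_len(n_chrms - 1L), m, replace = TRUE,
                prob = 1 / seq_len(n_chrms - 1L))
    p_anc <- x / n_chrms
  }

  # outlier loci under divergent selection
  n_out <- round(config$outlier_fraction * m)
  outlier <- rep(FALSE, m)
  if (n_out > 0) outlier[sample.int(m, n_out)] <- TRUE

  # neutral loci: Balding-Nichols divergence around the ancestral frequency
  Fb <- bn_param_for_fst(config$target_fst_pools)
  pool_f <- cbind(p1 = bn_draw(p_anc, Fb), p2 = bn_draw(p_anc, Fb))
  # outlier loci: antithetic fixation so the per-locus Nei FST is pinned at
  # base + boost (p = 0.5 +/- d gives FST = 4 d^2); direction random
  if (n_out > 0) {
    t_out <- pmin(config$target_fst_pools + config$outlier_fst_boost, 0.98)
    d <- sqrt(t_out) / 2
    z <- sample(c(-1, 1), n_out, replace = TRUE)
    pool_f[outlier, 1] <- 0.5 + z * d
    pool_f[outlier, 2] <- 0.5 - z * d
  }
  Fs <- bn_param_for_fst(config$target_fst_strata)
  strat_f <- list(
    p1 = cbind(landrace = bn_draw(pool_f[, 1], Fs),
               cultivar_line = bn_draw(pool_f[, 1], Fs)),
    p2 = cbind(landrace = bn_draw(pool_f[, 2], Fs),
               cultivar_line = bn_draw(pool_f[, 2], Fs)))

  # accession labels
  pool_lab <- c(rep("pool1", n1), rep("pool2", n2), rep("admixed", na))
  stratum <- c(lab_strata(n1, config$strata_split),
               lab_strata(n2, config$strata_split),
               rep("unknown", na))
  acc_ids <- sprintf("ACC%04d", seq_len(n_tot))

  # true admixture proportions (q = share of pool1 ancestry)
  q_true <- ifelse(pool_lab == "pool1", 1, 0)
  if (na > 0) {
    qa <- stats::rbeta(na * 10, 5, 5)
    qa <- qa[qa >= 0.3 & qa <= 0.7][seq_len(na)]
    q_true[pool_lab == "admixed"] <- qa
  }

  # haplotype pools per stratum (carry the LD structure)
  geno <- matrix(0L, n_tot, m, dimnames = list(acc_ids, marker_ids))
  chroms <- split(seq_len(m), chrom)
  hap_bank <- list()
  for (pool in 1:2) {
    for (st in c("landrace", "cultivar_line")) {
      key <- paste0("p", pool, ".", st)
      hap_bank[[key]] <- lapply(chroms, function(idx) {
        simulate_haplotypes_ld(
          strat_f[[paste0("p", pool)]][idx, st], pos[idx],
          n_hap = 2L * (n_tot + 4L), n_founders = config$n_founders,
          rate = config$recomb_rate_per_bp[pool],
          generations = config$generations, len = config$chrom_length_bp)
      })
    }
  }
  draw_gamete <- function(pool, st) {
    key <- paste0("p", pool, ".", if (st %in% c("landrace", "cultivar_line"))
      st else sample(c("landrace", "cultivar_line"), 1L))
    bank <- hap_bank[[key]]
    unlist(lapply(bank, function(H) H[sample.int(nrow(H), 1L), ]),
           use.names = FALSE)
  }
  # admixed gametes are chromosome-level mosaics: each chromosome comes
  # from pool 1 with probability q (advanced-generation admixture)
  draw_gamete_admixed <- function(q) {
    st <- sample(c("landrace", "cultivar_line"), 1L)
    unlist(lapply(names(chroms), function(ch) {
      pool <- if (stats::runif(1) < q) 1L else 2L
      bank <- hap_bank[[paste0("p", pool, ".", st)]][[ch]]
      bank[sample.int(nrow(bank), 1L), ]
    }), use.names = FALSE)
  }
  for (i in seq_len(n_tot)) {
    if (pool_lab[i] == "admixed") {
      g1 <- draw_gamete_admixed(q_true[i])
      g2 <- if (stats::runif(1) < config$selfing_F) g1
            else draw_gamete_admixed(q_true[i])
    } else {
      pool <- if (pool_lab[i] == "pool1") 1L else 2L
      g1 <- draw_gamete(pool, stratum[i])
      g2 <- if (stats::runif(1) < config$selfing_F) g1
            else draw_gamete(pool, stratum[i])
    }
    geno[i, ] <- g1 + g2
  }

  # missingness
  if (config$missing_rate > 0) {
    mask <- stats::runif(length(geno)) < config$missing_rate
    geno[mask] <- NA_integer_
  }

  samples <- data.frame(accession_id = acc_ids,
                        gene_pool = c(pool1 = "Andean", pool2 = "Mesoamerican",
                                      admixed = "admixed")[pool_lab],
                        stratum = stratum, country = "BR",
                        lat = NA_real_, lon = NA_real_,
                        stringsAsFactors = FALSE)
  samples <- assign_geography(samples, config)

  truth <- list(p_anc = p_anc, pool_freqs = pool_f, strat_freqs = strat_f,
                outlier = outlier, q_true = q_true, pool_lab = pool_lab,
                stratum = stratum)
  list(geno = genotype_matrix(geno), markers = markers, samples = samples,
       truth = truth)
}

bn_draw <- function(p, Fb) {
  Fb <- rep_len(Fb, length(p))
  out <- p
  nz <- Fb > 0
  if (any(nz)) {
    lam <- (1 - Fb[nz]) / Fb[nz]
    out[nz] <- stats::rbeta(sum(nz), p[nz] * lam, (1 - p[nz]) * lam)
  }
  # keep frequencies usable downstream (avoid exactly 0/1 wiping loci)
  pmin(pmax(out, 1e-4), 1 - 1e-4)
}

lab_strata <- function(n, frac) {
  k <- round(n * frac)
  c(rep("landrace", k), rep("cultivar_line", n - k))
}

#' Assign clustered geographic coordinates to accessions
#'
#' Each gene-pool/stratum combination receives a cluster center drawn
#' uniformly in the bounding box; accession coordinates are the center plus
#' Gaussian noise of `spread_deg` degrees. `clustering = 0` draws all
#' coordinates uniformly (ancestry uncorrelated with space).
#'
#' @param samples sample data.frame (gene_pool, stratum columns used).
#' @param config sim_config (only consulted for reproducibility notes).
#' @param bbox c(lat_min, lat_max, lon_min, lon_max); default Brazil-like.
#' @param clustering 1 = fully clustered by group, 0 = uniform.
#' @param spread_deg Gaussian spread around cluster centers (degrees).
#' @return samples with lat/lon filled.
#' @export
assign_geography <- function(samples, config = NULL,
                             bbox = c(-33, 5, -74, -35),
                             clustering = 1, spread_deg = 3) {
  n <- nrow(samples)
  lat_u <- stats::runif(n, bbox[1], bbox[2])
  lon_u <- stats::runif(n, bbox[3], bbox[4])
  grp <- paste(samples$gene_pool, samples$stratum)
  centers_lat <- stats::runif(length(unique(grp)), bbox[1], bbox[2])
  centers_lon <- stats::runif(length(unique(grp)), bbox[3], bbox[4])
  names(centers_lat) <- names(centers_lon) <- unique(grp)
  lat_c <- pmin(pmax(centers_lat[grp] + stats::rnorm(n, 0, spread_deg),
                     bbox[1]), bbox[2])
  lon_c <- pmin(pmax(centers_lon[grp] + stats::rnorm(n, 0, spread_deg),
                     bbox[3]), bbox[4])
  use_c <- stats::runif(n) < clustering
  samples$lat <- ifelse(use_c, lat_c, lat_u)
  samples$lon <- ifelse(use_c, lon_c, lon_u)
  samples
}

#' Simulate a neutral panmictic SNP panel from the 1/x site-frequency spectrum
#'
#' Derived-allele counts are drawn proportional to 1/x over 1..2N-1 and
#' placed on uniformly chosen chromosomes of the 2N sampled gametes, so
#' Tajima's D has expectation near zero by construction. Used for
#' neutrality calibration of the window scan.
#'
#' @param n_acc accessions (2N chromosomes). @param n_markers loci.
#' @param n_chrom,chrom_length_bp genome layout. @param seed RNG seed.
#' @return list(geno, markers, genome_map).
#' @export
simulate_neutral_panel <- function(n_acc = 50, n_markers = 2000, n_chrom = 5,
                                   chrom_length_bp = 4e6, seed = 1L) {
  set.seed(seed)
  n_chrms <- 2L * n_acc
  per_chr <- diff(round(seq(0, n_markers, length.out = n_chrom + 1L)))
  chrom <- rep(sprintf("Chr%02d", seq_len(n_chrom)), per_chr)
  pos <- unlist(lapply(per_chr, function(k) sort(sample.int(chrom_length_bp, k))))
  x <- sample(seq_len(n_chrms - 1L), n_markers, replace = TRUE,
              prob = 1 / seq_len(n_chrms - 1L))
  hap <- matrix(0L, n_chrms, n_markers)
  for (l in seq_len(n_markers)) hap[sample.int(n_chrms, x[l]), l] <- 1L
  geno <- hap[seq(1, n_chrms, by = 2), ] + hap[seq(2, n_chrms, by = 2), ]
  rownames(geno) <- sprintf("ACC%04d", seq_len(n_acc))
  colnames(geno) <- sprintf("snp%05d", seq_len(n_markers))
  list(geno = genotype_matrix(geno),
       markers = marker_info(colnames(geno), chrom = chrom, pos = pos),
       genome_map = data.frame(chrom = sprintf("Chr%02d", seq_len(n_chrom)),
                               length_bp = chrom_length_bp))
}
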