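#' Hierarchical island configuration for the FDIST-style null envelope
#'
#' Two groups with two demes each, following the classic hierarchical
#' outlier-scan design. Divergence levels are the *target* Nei FST among
#' groups (`fst_ct`) and among demes within groups (`fst_sc`); they are
#' translated to Balding-Nichols beta parameters internally.
#'
#' @param fst_ct,fst_sc target between-group and within-group FST (> 0 for
#'   `fst_ct`).
#' @param sample_sizes accessions sampled per deme (length
#'   `n_groups * demes_per_group`).
#' @param n_sims simulated loci (default 20000).
#' @param n_groups,demes_per_group hierarchy shape.
#' @export
hier_island_config <- function(fst_ct, fst_sc = 0.02,
                               sample_sizes = c(32, 32, 55, 56),
                               n_sims = 20000L, n_groups = 2L,
                               demes_per_group = 2L) {
  if (fst_ct <= 0) stop("calibration FST must be > 0")
  stopifnot(fst_sc >= 0, n_sims >= 1,
            length(sample_sizes) == n_groups * demes_per_group)
  structure(list(fst_ct = fst_ct, fst_sc = fst_sc,
                 sample_sizes = sample_sizes, n_sims = as.integer(n_sims),
                 n_groups = n_groups, demes_per_group = demes_per_group),
            class = "hier_island_config")
}

# per-locus between-group Nei FST and total heterozygosity from deme
# sample frequencies (columns = demes), given each deme's group
fst_het_from_demes <- function(P, group_of_deme) {
  groups <- unique(group_of_deme)
  G <- vapply(groups, function(g)
    rowMeans(P[, group_of_deme == g, drop = FALSE]), numeric(nrow(P)))
  hs <- rowMeans(2 * G * (1 - G))
  pbar <- rowMeans(G)
  ht <- 2 * pbar * (1 - pbar)
  fst <- ifelse(ht > 0, (ht - hs) / ht, NA_real_)
  data.frame(het = ht, fst = fst)
}

#' Simulate the FDIST null cloud under the hierarchical island model
#'
#' Per simulated locus: ancestral frequency uniform on (0.02, 0.98); group
#' frequencies by Balding-Nichols divergence at the between-group tier;
#' deme frequencies by a second tier within each group; binomial allele
#' counts at the configured sample sizes. Records the sample total
#' heterozygosity and the between-group Nei FST per locus.
#'
#' @param config a [hier_island_config()].
#' @return data.frame(het, fst), one row per simulated locus.
#' @export
fdist_null_simulation <- function(config) {
  stopifnot(inherits(config, "hier_island_config"))
  m <- config$n_sims
  p_anc <- stats::runif(m, 0.02, 0.98)
  F_ct <- bn_param_for_fst(config$fst_ct)
  F_sc <- bn_param_for_fst(config$fst_sc)
  n_demes <- config$n_groups * config$demes_per_group
  group_of_deme <- rep(seq_len(config$n_groups), each = config$demes_per_group)
  gfreq <- vapply(seq_len(config$n_groups),
                  function(g) bn_draw(p_anc, rep(F_ct, m)), numeric(m))
  P <- matrix(NA_real_, m, n_demes)
  for (d in seq_len(n_demes)) {
    pf <- if (F_sc > 0) bn_draw(gfreq[, group_of_deme[d]], rep(F_sc, m))
          else gfreq[, group_of_deme[d]]
    n_chr <- 2L * config$sample_sizes[d]
    P[, d] <- stats::rbinom(m, n_chr, pf) / n_chr
  }
  fst_het_from_demes(P, group_of_deme)
}

#' Observed per-locus heterozygosity/FST in the hierarchical layout
#'
#' @param geno genotype_matrix.
#' @param deme_masks list of accession selectors, one per deme.
#' @param group_of_deme group index per deme.
#' @return data.frame(locus, het, fst).
#' @export
fdist_observed_stats <- function(geno, deme_masks, group_of_deme) {
  P <- vapply(deme_masks, function(m) allele_freq_vec(geno, as_mask(m, nrow(geno))),
              numeric(ncol(geno)))
  out <- fst_het_from_demes(P, group_of_deme)
  cbind(locus = colnames(geno), out, stringsAsFactors = FALSE)
}

#' Method-of-moments calibration of the hierarchical island model
#'
#' Estimates the between-group FST (from the pooled group masks) and the
#' mean within-group between-deme FST from the observed data.
#'
#' @param geno genotype_matrix. @param deme_masks deme selectors.
#' @param group_of_deme group index per deme.
#' @return list(fst_ct, fst_sc).
#' @export
calibrate_hier_island <- function(geno, deme_masks, group_of_deme) {
  masks <- lapply(deme_masks, as_mask, n = nrow(geno))
  groups <- unique(group_of_deme)
  gmask <- lapply(groups, function(g)
    Reduce(`|`, masks[group_of_deme == g]))
  fct <- fixation_indices(geno, gmask)$summary
  fst_ct <- fct$mean[fct$stat == "FST"]
  fsc <- vapply(groups, function(g) {
    dm <- masks[group_of_deme == g]
    if (length(dm) < 2) return(NA_real_)
    s <- fixation_indices(geno, dm)$summary
    s$mean[s$stat == "FST"]
  }, 1)
  list(fst_ct = fst_ct, fst_sc = max(mean(fsc, na.rm = TRUE), 1e-4))
}

#' Classify observed loci against the simulated null envelope
#'
#' Simulated loci are binned by heterozygosity into equal-count bins
#' (at least `min_per_bin` simulations per bin). Per observed locus the
#' upper-tail empirical p is the fraction of same-bin simulated FST values
#' >= the observed one (and symmetrically below). The outlier decision uses
#' randomized tail probabilities — uniform ties split by a uniform draw —
#' because the simulated FST distribution has discrete atoms (loci fixed in
#' every deme give FST exactly 1) that would otherwise make the central
#' 1 - alpha envelope under-reject. A locus is an outlier when either
#' randomized tail probability falls below alpha/2. Monomorphic loci
#' (het = 0) are excluded. Observed heterozygosity outside the simulated
#' range falls in the nearest bin and is flagged `edge_bin`.
#'
#' @param obs data.frame(locus, het, fst) from [fdist_observed_stats()].
#' @param cloud data.frame(het, fst) from [fdist_null_simulation()].
#' @param alpha two-sided envelope level (default 0.05).
#' @param min_per_bin minimum simulations per heterozygosity bin.
#' @return data.frame per locus: het, fst, p_upper, p_lower, outlier,
#'   direction, edge_bin.
#' @export
fdist_classify <- function(obs, cloud, alpha = 0.05, min_per_bin = 200L) {
  stopifnot(nrow(cloud) > 0)
  cloud <- cloud[!is.na(cloud$fst), , drop = FALSE]
  n_bins <- max(1L, min(floor(nrow(cloud) / min_per_bin), 50L))
  br <- stats::quantile(cloud$het, probs = seq(0, 1, length.out = n_bins + 1L))
  br[1] <- -Inf; br[length(br)] <- Inf
  bin_of <- function(h) pmin(pmax(findInterval(h, br, left.open = TRUE,
                                               rightmost.closed = TRUE), 1L),
                             n_bins)
  sim_bin <- bin_of(cloud$het)
  lo <- tapply(cloud$fst, sim_bin, stats::quantile, probs = alpha / 2)
  hi <- tapply(cloud$fst, sim_bin, stats::quantile, probs = 1 - alpha / 2)
  sim_by_bin <- split(cloud$fst, sim_bin)
  usable <- !is.na(obs$het) & !is.na(obs$fst) & obs$het > 0
  b <- bin_of(obs$het)
  p_up <- p_lo <- pr_up <- pr_lo <- rep(NA_real_, nrow(obs))
  u <- stats::runif(nrow(obs))
  for (i in which(usable)) {
    s <- sim_by_bin[[as.character(b[i])]]
    gt <- mean(s > obs$fst[i]); lt <- mean(s < obs$fst[i])
    eq <- 1 - gt - lt
    p_up[i] <- gt + eq
    p_lo[i] <- lt + eq
    # randomized tail probabilities: exactly uniform under the null even
    # at the atoms of the discrete FST distribution (e.g. FST = 1 loci)
    pr_up[i] <- gt + u[i] * eq
    pr_lo[i] <- lt + (1 - u[i]) * eq
  }
  edge <- usable & (obs$het < min(cloud$het) | obs$het > max(cloud$het))
  outlier <- usable & (pr_up < alpha / 2 | pr_lo < alpha / 2)
  direction <- ifelse(!usable, NA_character_,
                      ifelse(outlier & pr_up < alpha / 2, "high",
                             ifelse(outlier, "low", "none")))
  data.frame(locus = obs$locus, het = obs$het, fst = obs$fst,
             p_upper = p_up, p_lower = p_lo,
             env_lo = unname(lo[as.character(b)]),
             env_hi = unname(hi[as.character(b)]),
             outlier = unname(outlier),
             direction = direction, edge_bin = unname(edge),
             stringsAsFactors = FALSE)
}

# beta-binomial log likelihood terms for the logistic-FST model:
# a successes of n trials, deme frequency integrated out of
# Beta(theta*p, theta*(1-p)) with theta = (1-F)/F, logit(F) = alpha + beta.
bb_loglik <- function(a, n, p, eta) {
  th <- exp(-eta)                       # (1-F)/F for logit(F) = eta
  lbeta(a + th * p, n - a + th * (1 - p)) - lbeta(th * p, th * (1 - p))
}

#' Bayesian FST outlier scan (spike-and-slab logistic decomposition)
#'
#' Per locus i and subpopulation j, logit(FST_ij) = alpha_i * delta_i +
#' beta_j; deme allele frequencies follow the Balding-Nichols beta around an
#' ancestral frequency p_i and are integrated out analytically
#' (beta-binomial marginal). delta_i is a spike-and-slab inclusion
#' indicator with prior inclusion probability `prior_inclusion`
#' (default 1/11, i.e. prior odds 10 for neutrality). Pilot runs tune the
#' random-walk proposal scales; the decision statistic is the posterior
#' inclusion probability converted to q-values, flagged at `q_threshold`.
#'
#' @param geno genotype_matrix. @param subpop_masks list of >= 2 selectors.
#' @param n_pilot,pilot_iter pilot runs and their length (proposal tuning).
#' @param burn_in,n_iter,thin main-chain controls.
#' @param prior_inclusion prior P(locus under selection).
#' @param q_threshold decision threshold on q-values (default 0.05).
#' @param seed RNG seed.
#' @return data.frame(locus, pip, q_value, alpha_mean, outlier) plus
#'   attributes `beta` (posterior mean per subpopulation) and
#'   `acceptance` rates.
#' @export
bayes_fst_mcmc <- function(geno, subpop_masks, n_pilot = 10L,
                           pilot_iter = 200L, burn_in = 2000L,
                           n_iter = 3000L, thin = 5L,
                           prior_inclusion = 1 / 11, q_threshold = 0.05,
                           seed = 1L) {
  stopifnot(length(subpop_masks) >= 2)
  set.seed(seed)
  masks <- lapply(subpop_masks, as_mask, n = nrow(geno))
  J <- length(masks)
  A <- vapply(masks, function(m) {
    g <- geno[m, , drop = FALSE]
    colSums(g, na.rm = TRUE)
  }, numeric(ncol(geno)))
  N <- vapply(masks, function(m) {
    g <- geno[m, , drop = FALSE]
    2 * colSums(!is.na(g))
  }, numeric(ncol(geno)))
  keep <- rowSums(N) > 0 & rowSums(A) > 0 & rowSums(A) < rowSums(N)
  A <- A[keep, , drop = FALSE]; N <- N[keep, , drop = FALSE]
  L <- nrow(A)
  locus_ids <- colnames(geno)[keep]

  # state
  p <- pmin(pmax(rowSums(A) / rowSums(N), 0.01), 0.99)
  lp <- stats::qlogis(p)
  beta <- rep(-1, J)
  alpha <- rep(0, L)
  delta <- rep(FALSE, L)
  sd_p <- 0.4; sd_a <- 1.0; sd_b <- 0.1
  slab_sd <- 2.0

  ll_locus <- function(lp, alpha, delta, beta) {
    p <- stats::plogis(lp)
    eta <- outer(alpha * delta, beta, `+`)
    rowSums(bb_loglik(A, N, p, eta))
  }
  ll <- ll_locus(lp, alpha, delta, beta)

  acc <- c(p = 0, alpha = 0, beta = 0); try_n <- c(p = 0, alpha = 0, beta = 0)
  one_sweep <- function() {
    # p update (vectorized over loci)
    lp_new <- lp + stats::rnorm(L, 0, sd_p)
    ll_new <- ll_locus(lp_new, alpha, delta, beta)
    accept <- log(stats::runif(L)) < ll_new - ll
    lp[accept] <<- lp_new[accept]; ll[accept] <<- ll_new[accept]
    acc["p"] <<- acc["p"] + mean(accept); try_n["p"] <<- try_n["p"] + 1
    # alpha RW for included loci
    on <- which(delta)
    if (length(on) > 0) {
      a_new <- alpha
      a_new[on] <- alpha[on] + stats::rnorm(length(on), 0, sd_a)
      ll_new <- ll_locus(lp, a_new, delta, beta)
      pr <- stats::dnorm(a_new, 0, slab_sd, log = TRUE) -
        stats::dnorm(alpha, 0, slab_sd, log = TRUE)
      accept <- rep(FALSE, L)
      accept[on] <- log(stats::runif(length(on))) <
        (ll_new[on] - ll[on] + pr[on])
      alpha[accept] <<- a_new[accept]; ll[accept] <<- ll_new[accept]
      acc["alpha"] <<- acc["alpha"] + mean(accept[on])
      try_n["alpha"] <<- try_n["alpha"] + 1
    }
    # delta toggle with prior-draw proposal for alpha
    a_prop <- ifelse(delta, 0, stats::rnorm(L, 0, slab_sd))
    d_prop <- !delta
    ll_new <- ll_locus(lp, a_prop, d_prop, beta)
    prior_odds <- ifelse(d_prop,
                         log(prior_inclusion) - log(1 - prior_inclusion),
                         log(1 - prior_inclusion) - log(prior_inclusion))
    accept <- log(stats::runif(L)) < ll_new - ll + prior_odds
    delta[accept] <<- d_prop[accept]; alpha[accept] <<- a_prop[accept]
    ll[accept] <<- ll_new[accept]
    # beta updates (one at a time, likelihood over all loci)
    for (j in seq_len(J)) {
      b_new <- beta; b_new[j] <- beta[j] + stats::rnorm(1, 0, sd_b)
      ll_new <- ll_locus(lp, alpha, delta, b_new)
      lr <- sum(ll_new) - sum(ll) +
        stats::dnorm(b_new[j], -1, 1.8, log = TRUE) -
        stats::dnorm(beta[j], -1, 1.8, log = TRUE)
      if (log(stats::runif(1)) < lr) {
        beta <<- b_new; ll <<- ll_new
        acc["beta"] <<- acc["beta"] + 1 / J
      }
    }
    try_n["beta"] <<- try_n["beta"] + 1
  }

  # pilot tuning
  for (k in seq_len(n_pilot)) {
    acc[] <- 0; try_n[] <- 0
    for (it in seq_len(pilot_iter)) one_sweep()
    rate <- ifelse(try_n > 0, acc / try_n, NA)
    tune <- function(s, r) if (is.na(r)) s else s * exp(1.2 * (r - 0.3))
    sd_p <- tune(sd_p, rate["p"]); sd_a <- tune(sd_a, rate["alpha"])
    sd_b <- tune(sd_b, rate["beta"])
  }
  acc[] <- 0; try_n[] <- 0
  for (it in seq_len(burn_in)) one_sweep()
  n_keep <- floor(n_iter / thin)
  pip <- numeric(L); a_sum <- numeric(L); b_sum <- numeric(J)
  for (it in seq_len(n_iter)) {
    one_sweep()
    if (it %% thin == 0L) {
      pip <- pip + delta; a_sum <- a_sum + alpha * delta; b_sum <- b_sum + beta
    }
  }
  pip <- pip / n_keep
  rate <- acc / pmax(try_n, 1)
  if (any(rate[c("p", "beta")] < 0.05 | rate[c("p", "beta")] > 0.85))
    warning("MCMC acceptance rates far from target; inspect convergence")

  # q-values from posterior inclusion probabilities
  ord <- order(pip, decreasing = TRUE)
  qv <- cummean_local(1 - pip[ord])
  qv <- rev(cummin(rev(qv)))            # enforce monotonicity
  q_value <- numeric(L); q_value[ord] <- qv
  res <- data.frame(locus = locus_ids, pip = pip, q_value = q_value,
                    alpha_mean = a_sum / n_keep,
                    outlier = q_value < q_threshold,
                    stringsAsFactors = FALSE)
  attr(res, "beta") <- b_sum / n_keep
  attr(res, "acceptance") <- rate
  res
}

cummean_local <- function(x) cumsum(x) / seq_along(x)

#' Intersect outlier reports
#'
#' Joint calls are loci flagged in every supplied report (set intersection
#' over the same locus universe), mirroring the convention of keeping only
#' outliers identified across all runs/methods.
#'
#' @param ... two or more reports with columns `locus` and `outlier`.
#' @return data.frame(locus, n_methods, joint) restricted to the shared
#'   universe; errors if the locus universes are disjoint.
#' @export
intersect_outliers <- function(...) {
  reports <- list(...)
  stopifnot(length(reports) >= 2)
  universe <- Reduce(intersect, lapply(reports, function(r) r$locus))
  if (length(universe) == 0L) stop("reports share no locus ids")
  flags <- vapply(reports, function(r)
    r$outlier[match(universe, r$locus)], logical(length(universe)))
  if (is.null(dim(flags))) flags <- matrix(flags, nrow = length(universe))
  data.frame(locus = universe, n_methods = rowSums(flags),
             joint = rowSums(flags) == length(reports),
             stringsAsFactors = FALSE)
}
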