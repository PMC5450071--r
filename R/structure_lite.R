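#' Lightweight EM admixture estimation
#'
#' Maximizes sum_il [x_il log(sum_k q_ik f_kl) + (2 - x_il) log(sum_k
#' q_ik (1 - f_kl))] over ancestry proportions Q (rows sum to 1) and
#' cluster allele frequencies F, by the standard allele-copy EM. Missing
#' calls are skipped. Not a Bayesian MCMC replica: a deterministic stand-in
#' supplying structure covariates and q-threshold group labels.
#'
#' @param geno genotype_matrix. @param K clusters (>= 1).
#' @param n_restarts random restarts; the best likelihood wins.
#' @param max_iter,tol EM controls.
#' @param seed RNG seed.
#' @return list(Q, F, loglik, K, trace) of class `admixture_result`; `trace`
#'   is the log-likelihood path of the winning run (non-decreasing).
#' @export
admixture_em <- function(geno, K = 2L, n_restarts = 3L, max_iter = 300L,
                         tol = 1e-6, seed = 1L) {
  if (K > nrow(geno)) stop("K exceeds the number of accessions")
  set.seed(seed)
  X <- unclass(geno)
  obs <- !is.na(X)
  Xf <- X; Xf[!obs] <- 0L
  n <- nrow(X); L <- ncol(X)
  p_hat <- allele_freq_vec(geno)
  p_hat[is.na(p_hat)] <- 0.5
  if (K == 1L) {
    f <- matrix(pmin(pmax(p_hat, 1e-6), 1 - 1e-6), 1L, L)
    Q <- matrix(1, n, 1L, dimnames = list(rownames(X), "K1"))
    ll <- sum((Xf * log(f[rep(1, n), ]) +
                 (2 - Xf) * log(1 - f[rep(1, n), ]))[obs])
    return(structure(list(Q = Q, F = f, loglik = ll, K = 1L, trace = ll),
                     class = "admixture_result"))
  }
  run_once <- function() {
    Fm <- matrix(pmin(pmax(p_hat + stats::rnorm(K * L, 0, 0.08), 0.01), 0.99),
                 K, L, byrow = TRUE)
    Q <- matrix(stats::rgamma(n * K, 1), n, K)
    Q <- Q / rowSums(Q)
    ll_old <- -Inf; trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      PA <- Q %*% Fm                    # P(alt copy) per ind x locus
      PR <- Q %*% (1 - Fm)
      PA <- pmax(PA, 1e-300); PR <- pmax(PR, 1e-300)
      ll <- sum((Xf * log(PA) + (2 - Xf) * log(PR))[obs])
      trace <- c(trace, ll)
      # responsibilities accumulated per cluster
      EA <- matrix(0, n, K); ER <- matrix(0, n, K)
      FA <- matrix(0, K, L); FR <- matrix(0, K, L)
      WA <- (Xf * obs) / PA             # weight per alt copy
      WR <- ((2 - Xf) * obs) / PR
      for (k in seq_len(K)) {
        ak <- WA * matrix(Fm[k, ], n, L, byrow = TRUE) * Q[, k]
        rk <- WR * matrix(1 - Fm[k, ], n, L, byrow = TRUE) * Q[, k]
        EA[, k] <- rowSums(ak); ER[, k] <- rowSums(rk)
        FA[k, ] <- colSums(ak); FR[k, ] <- colSums(rk)
      }
      Q <- (EA + ER) / pmax(rowSums(EA + ER), 1e-300)
      Fm <- pmin(pmax(FA / pmax(FA + FR, 1e-300), 1e-6), 1 - 1e-6)
      if (it > 1 && ll - ll_old < tol * abs(ll)) break
      ll_old <- ll
    }
    list(Q = Q, F = Fm, loglik = ll, trace = trace)
  }
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- run_once()
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  dimnames(best$Q) <- list(rownames(X), paste0("K", seq_len(K)))
  structure(list(Q = best$Q, F = best$F, loglik = best$loglik, K = K,
                 trace = best$trace), class = "admixture_result")
}

#' Assign group labels from admixture proportions
#'
#' @param Q accession x K matrix (or `admixture_result`).
#' @param threshold assignment threshold on max q (default 0.7).
#' @return character vector: `"K<j>"` for assigned accessions, `"admixed"`
#'   when max q < threshold.
#' @export
assign_groups <- function(Q, threshold = 0.7) {
  if (inherits(Q, "admixture_result")) Q <- Q$Q
  k <- max.col(Q)
  lab <- colnames(Q)[k]
  if (is.null(lab)) lab <- paste0("K", k)
  ifelse(Q[cbind(seq_len(nrow(Q)), k)] >= threshold, lab, "admixed")
}

#' Simple-matching dissimilarity between accessions
#'
#' d(i, j) = mismatching loci / jointly typed loci over genotype states
#' \{0, 1, 2\}. Pairs with no jointly typed locus get NA.
#'
#' @param geno genotype_matrix.
#' @return symmetric `dist`-compatible matrix.
#' @export
simple_matching_distance <- function(geno) {
  stopifnot(nrow(geno) >= 2)
  X <- unclass(geno)
  match_cnt <- matrix(0, nrow(X), nrow(X))
  for (s in 0:2) {
    I <- (X == s & !is.na(X)) * 1
    match_cnt <- match_cnt + tcrossprod(I)
  }
  typed <- tcrossprod((!is.na(X)) * 1)
  d <- 1 - match_cnt / typed
  d[typed == 0] <- NA_real_
  diag(d) <- 0
  dimnames(d) <- list(rownames(X), rownames(X))
  d
}

#' Neighbor-joining dendrogram with locus-bootstrap support
#'
#' NJ (Saitou-Nei, via ape) on a simple-matching distance; bootstrap
#' resamples loci with replacement, recomputes the distance and tree, and
#' reports the proportion of replicates supporting each internal
#' bipartition. Negative branch lengths are clamped to zero.
#'
#' @param geno genotype_matrix. @param bootstrap_n replicates (0 = none).
#' @param dist_fun distance function (default
#'   [simple_matching_distance()]).
#' @param seed RNG seed for the bootstrap.
#' @return list(tree = `phylo`, support = per-internal-node proportions or
#'   NULL, n_clamped).
#' @export
nj_tree <- function(geno, bootstrap_n = 100L,
                    dist_fun = simple_matching_distance, seed = 1L) {
  d <- dist_fun(geno)
  tree <- ape::nj(stats::as.dist(d))
  n_clamped <- sum(tree$edge.length < 0)
  tree$edge.length[tree$edge.length < 0] <- 0
  support <- NULL
  if (bootstrap_n > 0) {
    set.seed(seed)
    boots <- lapply(seq_len(bootstrap_n), function(b) {
      idx <- sample.int(ncol(geno), ncol(geno), replace = TRUE)
      g <- unclass(geno)[, idx, drop = FALSE]
      colnames(g) <- sprintf("b%06d", seq_along(idx))
      ape::nj(stats::as.dist(dist_fun(genotype_matrix(g))))
    })
    support <- ape::prop.clades(tree, boots, rooted = FALSE) / bootstrap_n
  }
  list(tree = tree, support = support, n_clamped = n_clamped)
}

#' Haversine great-circle distance (km)
#' @param lat1,lon1,lat2,lon2 decimal degrees (vectors recycle).
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  r <- 6371
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r * asin(pmin(sqrt(a), 1))
}

#' Spatial grid of expected heterozygosity
#'
#' Lays a regular grid (step `grid_step_km`) over the bounding box of the
#' georeferenced accessions; for each node the accessions within
#' `radius_km` (haversine) contribute their pooled allele frequencies to a
#' mean He. A single-accession neighborhood reports that accession's
#' own-frequency He (heterozygous loci contribute 0.5). Nodes with no
#' accession in range are omitted.
#'
#' @param geno genotype_matrix. @param samples sample data.frame with
#'   lat/lon (rows aligned with `geno`).
#' @param radius_km neighborhood radius (default 150).
#' @param grid_step_km grid spacing (default 50).
#' @return data.frame(lat, lon, He, n_accessions).
#' @export
spatial_he <- function(geno, samples, radius_km = 150, grid_step_km = 50) {
  stopifnot(radius_km > 0, identical(rownames(geno), samples$accession_id))
  has <- !is.na(samples$lat) & !is.na(samples$lon)
  if (!any(has)) stop("no accession has coordinates")
  n_dropped <- sum(!has)
  if (n_dropped > 0)
    message(n_dropped, " accession(s) without coordinates excluded")
  lat <- samples$lat[has]; lon <- samples$lon[has]
  g <- geno[has, , drop = FALSE]
  step_lat <- grid_step_km / 111.32
  mid_lat <- mean(range(lat))
  step_lon <- grid_step_km / (111.32 * max(cos(mid_lat * pi / 180), 0.05))
  glat <- seq(min(lat), max(lat) + step_lat / 2, by = step_lat)
  glon <- seq(min(lon), max(lon) + step_lon / 2, by = step_lon)
  nodes <- expand.grid(lat = glat, lon = glon)
  rows <- lapply(seq_len(nrow(nodes)), function(k) {
    d <- haversine_km(nodes$lat[k], nodes$lon[k], lat, lon)
    inside <- which(d <= radius_km)
    if (length(inside) == 0L) return(NULL)
    he <- if (length(inside) == 1L) {
      x <- unclass(g)[inside, ]
      p <- x[!is.na(x)] / 2
      mean(2 * p * (1 - p))
    } else {
      p <- allele_freq_vec(g, inside)
      mean(2 * p * (1 - p), na.rm = TRUE)
    }
    data.frame(lat = nodes$lat[k], lon = nodes$lon[k], He = he,
               n_accessions = length(inside))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(lat = numeric(), lon = numeric(), He = numeric(),
               n_accessions = integer())
  rownames(out) <- NULL
  out
}
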