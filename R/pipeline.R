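#' Pipeline configuration
#'
#' Bundles input paths (or a simulation config), grouping choices, and the
#' module thresholds into one validated list that round-trips through JSON.
#'
#' @param geno_path,samples_path,genome_map_path input files; leave NULL and
#'   set `sim` to run on a simulated collection.
#' @param dialect genotype file dialect (`"wide"` or `"vcf"`).
#' @param sim optional [sim_config()] used when no genotype path is given.
#' @param min_call_rate,min_maf,window_bp,r2_prune,q_threshold,alpha,radius_km
#'   module thresholds (defaults: 0.75, 0.05, 1e5, 0.5, 0.7, 0.05, 150).
#' @param panel_size SNP panel target size.
#' @param K admixture clusters. @param n_boot NJ bootstrap replicates.
#' @param run_bayes run the Bayesian outlier scan (slowest stage).
#' @param seed master seed. @param out_dir output directory.
#' @export
pipeline_config <- function(geno_path = NULL, samples_path = NULL,
                            genome_map_path = NULL, dialect = "wide",
                            sim = NULL, min_call_rate = 0.75,
                            min_maf = 0.05, window_bp = 100000L,
                            r2_prune = 0.5, q_threshold = 0.7, alpha = 0.05,
                            radius_km = 150, panel_size = 560, K = 2L,
                            n_boot = 100L, run_bayes = FALSE, seed = 1L,
                            out_dir = tempfile("germdiv_run_")) {
  cfg <- as.list(environment())
  stopifnot(min_call_rate >= 0, min_call_rate <= 1, min_maf >= 0,
            min_maf <= 0.5, window_bp > 0, r2_prune > 0, r2_prune <= 1,
            q_threshold > 0.5, q_threshold <= 1, alpha > 0, alpha < 1,
            radius_km > 0)
  class(cfg) <- "pipeline_config"
  cfg
}

stage_file <- function(out_dir, name) file.path(out_dir, paste0(name, ".csv"))

write_provenance <- function(out_dir, stage, seed, inputs = list()) {
  hashes <- lapply(inputs, function(p)
    if (is.character(p) && file.exists(p))
      as.integer(file.info(p)$size) else NA)
  jsonlite::write_json(
    list(stage = stage, seed = seed,
         package_version = as.character(utils::packageVersion("germdiv")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
         input_sizes = hashes),
    file.path(out_dir, paste0(stage, ".provenance.json")),
    auto_unbox = TRUE)
}

#' Run the full characterization pipeline
#'
#' QC -> structure (EM admixture, q-threshold labels) -> diversity tables
#' -> window scan -> FDIST outliers (optionally the Bayesian scan) -> LD +
#' decay fit -> haplotype blocks -> panel selection -> NJ tree -> spatial
#' He. Each stage writes a CSV artifact plus a JSON provenance stanza into
#' `config$out_dir`. Optional stages (spatial without coordinates, tree,
#' bayes) log and skip rather than abort.
#'
#' @param config a [pipeline_config()].
#' @return invisible list of stage results; artifact paths in
#'   `$artifacts`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  log_msg <- function(...) message("[germdiv] ", ...)

  # --- inputs
  if (!is.null(config$geno_path)) {
    if (!file.exists(config$geno_path))
      stop("mandatory input missing at stage 'input': ", config$geno_path)
    inp <- read_genotype_table(config$geno_path, config$dialect)
    geno <- inp$geno; markers <- inp$markers
    samples <- if (!is.null(config$samples_path))
      read_sample_info(config$samples_path) else
        data.frame(accession_id = rownames(geno), gene_pool = NA,
                   stratum = NA, country = NA, lat = NA_real_,
                   lon = NA_real_, stringsAsFactors = FALSE)
    samples <- samples[match(rownames(geno), samples$accession_id), ]
    genome_map <- if (!is.null(config$genome_map_path))
      read_genome_map(config$genome_map_path) else
        stats::aggregate(pos ~ chrom, data = markers[!is.na(markers$pos), ],
                         FUN = max) |>
        (\(d) data.frame(chrom = d$chrom, length_bp = d$pos))()
  } else {
    sim <- if (is.null(config$sim)) sim_config(seed = config$seed) else config$sim
    log_msg("no genotype input; simulating collection (seed ", sim$seed, ")")
    col <- simulate_collection(sim)
    geno <- col$geno; markers <- col$markers; samples <- col$samples
    genome_map <- data.frame(chrom = unique(markers$chrom),
                             length_bp = sim$chrom_length_bp)
  }
  res <- list()

  # --- QC / filtering
  qc <- marker_qc(geno)
  utils::write.csv(qc, stage_file(config$out_dir, "qc"), row.names = FALSE)
  write_provenance(config$out_dir, "qc", config$seed,
                   list(geno = config$geno_path))
  fl <- filter_markers(geno, markers, min_call_rate = config$min_call_rate)
  geno_f <- fl$geno; markers_f <- fl$markers
  log_msg("QC: ", ncol(geno_f), "/", ncol(geno), " markers pass call-rate >= ",
          config$min_call_rate)
  res$qc <- qc

  # --- structure: LE-pruned set -> EM admixture -> labels
  pruned <- ld_prune(geno_f, markers_f, r2_threshold = config$r2_prune)
  adm <- admixture_em(geno_f[, pruned, drop = FALSE], K = config$K,
                      seed = config$seed)
  labels <- assign_groups(adm, threshold = config$q_threshold)
  qdf <- data.frame(accession_id = rownames(adm$Q), adm$Q, label = labels)
  utils::write.csv(qdf, stage_file(config$out_dir, "structure"),
                   row.names = FALSE)
  write_provenance(config$out_dir, "structure", config$seed)
  res$admixture <- adm
  # map EM clusters onto gene-pool labels when metadata are absent
  if (all(is.na(samples$gene_pool))) samples$gene_pool <- labels
  res$labels <- labels

  # --- diversity tables
  div <- group_summary(geno_f, samples, grouping = "gene_pool")
  utils::write.csv(div$groups, stage_file(config$out_dir, "diversity"),
                   row.names = FALSE)
  write_provenance(config$out_dir, "diversity", config$seed)
  res$diversity <- div

  pools <- setdiff(unique(samples$gene_pool), c("admixed", "unknown", NA))
  mask_a <- samples$gene_pool == pools[1]
  mask_b <- samples$gene_pool == pools[min(2, length(pools))]

  # --- window scan
  scan <- scan_genome(geno_f, markers_f, genome_map, mask_a, mask_b,
                      window_length = config$window_bp)
  utils::write.csv(scan[, setdiff(names(scan), "idx")],
                   stage_file(config$out_dir, "scan"), row.names = FALSE)
  write_provenance(config$out_dir, "scan", config$seed)
  res$scan <- scan

  # --- outliers (FDIST envelope; Bayesian optional)
  strat_ok <- !samples$stratum %in% c(NA, "unknown")
  demes <- list(mask_a & samples$stratum == "landrace" & strat_ok,
                mask_a & samples$stratum == "cultivar_line" & strat_ok,
                mask_b & samples$stratum == "landrace" & strat_ok,
                mask_b & samples$stratum == "cultivar_line" & strat_ok)
  if (all(vapply(demes, sum, 1L) >= 2)) {
    cal <- calibrate_hier_island(geno_f, demes, c(1, 1, 2, 2))
    hic <- hier_island_config(cal$fst_ct, cal$fst_sc,
                              sample_sizes = vapply(demes, sum, 1L))
    cloud <- fdist_null_simulation(hic)
    obs <- fdist_observed_stats(geno_f, demes, c(1, 1, 2, 2))
    fd <- fdist_classify(obs, cloud, alpha = config$alpha)
    utils::write.csv(fd, stage_file(config$out_dir, "outliers_fdist"),
                     row.names = FALSE)
    write_provenance(config$out_dir, "outliers_fdist", config$seed)
    res$fdist <- fd
    if (isTRUE(config$run_bayes)) {
      bay <- bayes_fst_mcmc(geno_f, list(mask_a, mask_b),
                            seed = config$seed)
      utils::write.csv(bay, stage_file(config$out_dir, "outliers_bayes"),
                       row.names = FALSE)
      write_provenance(config$out_dir, "outliers_bayes", config$seed)
      res$bayes <- bay
      res$joint_outliers <- intersect_outliers(
        fd[, c("locus", "outlier")],
        bay[, c("locus", "outlier")])
    }
  } else log_msg("outlier stage skipped: deme groups too small")

  # --- LD and decay
  ld <- pairwise_r2(geno_f, markers_f, maf_min = config$min_maf)
  if (nrow(ld) >= 50) {
    S <- adm$Q[, -config$K, drop = FALSE]
    grm <- genetic_relationship_matrix(geno_f)
    ld <- corrected_r2_sv(geno_f, ld, structure_covariates = S,
                          kinship = grm / max(mean(diag(grm)), 1e-8))
    fit <- fit_hill_weir(ld, n = nrow(geno_f), use_r2_sv = TRUE)
    res$decay_fit <- fit
    log_msg("LD half-decay (r2_sv): ",
            ifelse(is.na(fit$half_decay_bp), "NA",
                   paste0(round(fit$half_decay_bp / 1000, 1), " kb")))
  } else log_msg("decay fit skipped: <50 LD records")
  utils::write.csv(ld, stage_file(config$out_dir, "ld"), row.names = FALSE)
  write_provenance(config$out_dir, "ld", config$seed)
  res$ld <- ld

  # --- haplotype blocks
  ci <- dprime_records(geno_f, markers_f, min_call_rate = config$min_call_rate,
                       maf_min = config$min_maf)
  blocks <- gabriel_blocks(ci, markers_f)
  bs <- block_summary(blocks, genome_map)
  utils::write.csv(blocks[, setdiff(names(blocks), "members")],
                   stage_file(config$out_dir, "blocks"), row.names = FALSE)
  utils::write.csv(bs$per_chrom, stage_file(config$out_dir, "blocks_summary"),
                   row.names = FALSE)
  write_provenance(config$out_dir, "blocks", config$seed)
  res$blocks <- blocks; res$block_summary <- bs

  # --- panel
  pn <- select_panel(geno_f, markers_f, samples, size_target = config$panel_size,
                     min_call_rate = config$min_call_rate,
                     min_maf = config$min_maf, r2_threshold = config$r2_prune)
  utils::write.csv(data.frame(marker_id = pn$panel),
                   stage_file(config$out_dir, "panel"), row.names = FALSE)
  write_provenance(config$out_dir, "panel", config$seed)
  res$panel <- pn

  # --- tree
  tr <- nj_tree(geno_f[, pruned, drop = FALSE], bootstrap_n = config$n_boot,
                seed = config$seed)
  ape::write.tree(tr$tree, file.path(config$out_dir, "tree.nwk"))
  write_provenance(config$out_dir, "tree", config$seed)
  res$tree <- tr

  # --- spatial He
  if (any(!is.na(samples$lat) & !is.na(samples$lon))) {
    sp <- spatial_he(geno_f, samples, radius_km = config$radius_km)
    utils::write.csv(sp, stage_file(config$out_dir, "spatial_he"),
                     row.names = FALSE)
    write_provenance(config$out_dir, "spatial_he", config$seed)
    res$spatial <- sp
  } else log_msg("spatial stage skipped: no coordinates")

  res$artifacts <- list.files(config$out_dir, full.names = TRUE)
  invisible(res)
}

#' Command-line entry point
#'
#' Minimal subcommand dispatcher: `simulate` (emit wide table + metadata +
#' truth JSON) and `run-all` (full pipeline). Arguments: `--seed`,
#' `--out`, `--markers`, `--bayes`.
#'
#' @param args character vector (default `commandArgs(trailingOnly=TRUE)`).
#' @export
germdiv_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L)
    stop("usage: germdiv <simulate|run-all> [--seed N] [--out DIR] ",
         "[--markers N] [--bayes]")
  cmd <- args[1]
  get_opt <- function(flag, default) {
    i <- which(args == flag)
    if (length(i) && i < length(args)) args[i + 1L] else default
  }
  seed <- as.integer(get_opt("--seed", "1"))
  out <- get_opt("--out", "germdiv_out")
  n_markers <- as.integer(get_opt("--markers", "2000"))
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  if (cmd == "simulate") {
    col <- simulate_collection(sim_config(n_markers = n_markers, seed = seed))
    write_wide_table(col$geno, col$markers, file.path(out, "genotypes.csv"))
    utils::write.csv(col$samples, file.path(out, "samples.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(outlier = col$truth$outlier,
                              q_true = col$truth$q_true,
                              pool = col$truth$pool_lab),
                         file.path(out, "truth.json"))
    message("simulated collection written to ", out)
  } else if (cmd == "run-all") {
    cfg <- pipeline_config(sim = sim_config(n_markers = n_markers,
                                            seed = seed),
                           run_bayes = "--bayes" %in% args,
                           seed = seed, out_dir = out)
    run_pipeline(cfg)
    message("pipeline artifacts in ", out)
  } else stop("unknown subcommand: ", cmd)
  invisible(NULL)
}
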