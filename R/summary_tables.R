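#' Transition/transversion ratio from class counts
#' @param n_ts,n_tv transition and transversion counts.
#' @return Ts/Tv ratio.
#' @export
ts_tv_ratio <- function(n_ts, n_tv) {
  stopifnot(n_tv > 0)
  n_ts / n_tv
}

#' Per-chromosome SNP density summary
#'
#' Adds SNPs-per-Mbp density to a chromosome table and reports the mean
#' SNP count per chromosome.
#'
#' @param chrom_table data.frame(chrom, n_snps, size_kbp).
#' @return list(table = input with `snps_per_mbp`, mean_snps_per_chrom).
#' @export
chrom_density_summary <- function(chrom_table) {
  stopifnot(all(c("chrom", "n_snps", "size_kbp") %in% names(chrom_table)))
  chrom_table$snps_per_mbp <- chrom_table$n_snps / (chrom_table$size_kbp / 1000)
  list(table = chrom_table,
       mean_snps_per_chrom = mean(chrom_table$n_snps))
}

#' Genome block coverage and mean SNPs per block from block totals
#'
#' @param n_blocks,snps_in_blocks,total_span_kb,genome_kb totals of a block
#'   scan.
#' @return list(coverage_pct, mean_snps_per_block).
#' @export
block_coverage_summary <- function(n_blocks, snps_in_blocks, total_span_kb,
                                   genome_kb) {
  stopifnot(n_blocks > 0, genome_kb > 0)
  list(coverage_pct = 100 * total_span_kb / genome_kb,
       mean_snps_per_block = snps_in_blocks / n_blocks)
}

#' Load the bundled DArTseq bean panel summary tables
#'
#' Plain-text copies of the published per-chromosome SNP counts, haplotype
#' block totals, and variant class counts for a common-bean DArTseq panel,
#' shipped so the summary-layer arithmetic can be exercised without
#' external data.
#'
#' @param which `"chromosomes"`, `"blocks"`, or `"variant_classes"`.
#' @return data.frame.
#' @export
load_reference_summary <- function(which = c("chromosomes", "blocks",
                                             "variant_classes")) {
  which <- match.arg(which)
  f <- system.file("extdata", paste0("dartseq_bean_", which, ".csv"),
                   package = "germdiv", mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE)
}
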