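#' Genotype matrix container
#'
#' A `genotype_matrix` is an integer matrix of alternate-allele dosages
#' (0, 1, 2, or `NA` for missing) with accessions in rows and markers in
#' columns. Row and column names carry the accession and marker identifiers
#' and must be unique. All statistics in the package consume this container.
#'
#' @param calls numeric/integer matrix, accessions x markers, values in
#'   \{0, 1, 2, NA\}. Must have unique rownames and colnames.
#' @return an integer matrix of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  bad <- !is.na(calls) & !(calls %in% 0:2)
  if (any(bad)) stop("genotype calls must be 0, 1, 2 or NA")
  if (is.null(rownames(calls)) || is.null(colnames(calls)))
    stop("genotype_matrix requires accession rownames and marker colnames")
  if (anyDuplicated(rownames(calls))) stop("duplicate accession ids")
  if (anyDuplicated(colnames(calls))) stop("duplicate marker ids")
  class(calls) <- c("genotype_matrix", class(calls))
  calls
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d accessions x %d markers, %.1f%% missing\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

#' Marker metadata table constructor
#'
#' @param marker_id,chrom,pos,ref,alt vectors of identifiers, chromosome
#'   labels (`NA` = unplaced), 1-based positions, and allele characters.
#' @return data.frame with one row per marker.
#' @export
marker_info <- function(marker_id, chrom = NA, pos = NA_integer_,
                        ref = "A", alt = "G") {
  df <- data.frame(marker_id = as.character(marker_id),
                   chrom = as.character(chrom),
                   pos = as.integer(pos),
                   ref = as.character(ref), alt = as.character(alt),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$marker_id)) stop("duplicate marker ids")
  if (any(!is.na(df$pos) & df$pos < 1L)) stop("positions are 1-based (>= 1)")
  df
}

default_missing_codes <- c("-", "NA", "", "9", ".", "./.")

#' Read a genotype table (wide DArT-style CSV/TSV or VCF)
#'
#' Wide dialect: one row per marker with columns `marker_id`, `chrom`,
#' `pos` followed by one column per accession holding dosage calls; any
#' symbol in `missing_codes` maps to missing. VCF dialect: VCF 4.2 with GT
#' fields; non-biallelic records are skipped (count attached as attribute
#' `n_skipped`).
#'
#' @param path file path.
#' @param dialect `"wide"` or `"vcf"`.
#' @param missing_codes symbols treated as missing in wide tables.
#' @param sep field separator for wide tables (default auto: `,` or tab).
#' @return list with `geno` (genotype_matrix) and `markers` (marker data.frame).
#' @export
read_genotype_table <- function(path, dialect = c("wide", "vcf"),
                                missing_codes = default_missing_codes,
                                sep = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "vcf") return(read_vcf(path))
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE)
  need <- c("marker_id", "chrom", "pos")
  if (!all(need %in% names(tab)))
    stop("wide table must have columns marker_id, chrom, pos")
  acc <- setdiff(names(tab), need)
  if (length(acc) == 0L) stop("no accession columns found")
  calls <- as.matrix(tab[, acc, drop = FALSE])
  calls[calls %in% missing_codes] <- NA
  suppressWarnings(num <- matrix(as.integer(calls), nrow = nrow(calls)))
  if (any(!is.na(calls) & is.na(num)) || any(!is.na(num) & !(num %in% 0:2)))
    stop("unparseable genotype symbols present (not 0/1/2 or a missing code)")
  geno <- t(num)                        # accessions x markers
  rownames(geno) <- acc
  colnames(geno) <- tab$marker_id
  markers <- marker_info(tab$marker_id,
                         chrom = ifelse(tab$chrom %in% missing_codes, NA, tab$chrom),
                         pos = suppressWarnings(as.integer(tab$pos)))
  list(geno = genotype_matrix(geno), markers = markers)
}

#' Write a genotype matrix as a wide dosage table
#' @param geno genotype_matrix. @param markers marker data.frame.
#' @param path output path. @param sep separator.
#' @export
write_wide_table <- function(geno, markers, path, sep = ",") {
  stopifnot(identical(colnames(geno), markers$marker_id))
  out <- data.frame(marker_id = markers$marker_id,
                    chrom = ifelse(is.na(markers$chrom), "-", markers$chrom),
                    pos = ifelse(is.na(markers$pos), "-", markers$pos),
                    t(unclass(geno)), check.names = FALSE,
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(out))[-(1:3)]) out[[j]][is.na(out[[j]])] <- "-"
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a VCF file into a genotype matrix
#'
#' Minimal GT-only VCF 4.2 reader for biallelic SNPs; multi-allelic records
#' are skipped and their count reported via attribute `n_skipped` on the
#' returned list. Dosage counts ALT alleles; `./.` (or any call containing
#' `.`) is missing. Phased separators are accepted.
#'
#' @param path VCF path (plain text).
#' @return list(geno, markers) with attribute `n_skipped`.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (length(hdr) != 1L) stop("no #CHROM header line in VCF")
  cols <- strsplit(sub("^#", "", lines[hdr]), "\t")[[1]]
  samples <- cols[-(1:9)]
  if (length(samples) == 0L) stop("VCF has no sample columns")
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]
  n_skipped <- 0L
  recs <- vector("list", length(body))
  for (k in seq_along(body)) {
    f <- strsplit(body[k], "\t", fixed = TRUE)[[1]]
    if (grepl(",", f[5], fixed = TRUE) || nchar(f[4]) != 1L || nchar(f[5]) != 1L) {
      n_skipped <- n_skipped + 1L
      next
    }
    gt <- sub(":.*$", "", f[-(1:9)])
    gt <- gsub("|", "/", gt, fixed = TRUE)
    dos <- rep(NA_integer_, length(gt))
    dos[gt == "0/0"] <- 0L
    dos[gt %in% c("0/1", "1/0")] <- 1L
    dos[gt == "1/1"] <- 2L
    recs[[k]] <- list(id = if (f[3] == ".") paste0(f[1], "_", f[2]) else f[3],
                      chrom = f[1], pos = as.integer(f[2]),
                      ref = f[4], alt = f[5], dos = dos)
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (length(recs) == 0L) stop("no biallelic records in VCF")
  if (n_skipped > 0L)
    message(n_skipped, " non-biallelic VCF record(s) skipped")
  geno <- vapply(recs, `[[`, integer(length(samples)), "dos")
  if (is.null(dim(geno))) geno <- matrix(geno, nrow = length(samples))
  rownames(geno) <- samples
  colnames(geno) <- vapply(recs, `[[`, "", "id")
  markers <- marker_info(colnames(geno),
                         chrom = vapply(recs, `[[`, "", "chrom"),
                         pos = vapply(recs, function(r) r$pos, 1L),
                         ref = vapply(recs, `[[`, "", "ref"),
                         alt = vapply(recs, `[[`, "", "alt"))
  out <- list(geno = genotype_matrix(geno), markers = markers)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write a genotype matrix as VCF 4.2
#'
#' Dosage 0/1/2 becomes GT `0/0`, `0/1`, `1/1`; missing becomes `./.`.
#'
#' @param geno genotype_matrix. @param markers marker data.frame with
#'   chrom/pos/ref/alt. @param path output path.
#' @param drop_unplaced drop markers without chromosome/position instead of
#'   erroring.
#' @export
write_vcf <- function(geno, markers, path, drop_unplaced = FALSE) {
  stopifnot(identical(colnames(geno), markers$marker_id))
  unplaced <- is.na(markers$chrom) | is.na(markers$pos)
  if (any(unplaced)) {
    if (!drop_unplaced) stop(sum(unplaced), " unplaced marker(s); set drop_unplaced=TRUE")
    geno <- geno[, !unplaced, drop = FALSE]
    markers <- markers[!unplaced, , drop = FALSE]
  }
  ord <- order(markers$chrom, markers$pos)
  markers <- markers[ord, , drop = FALSE]
  geno <- geno[, ord, drop = FALSE]
  gt <- c("0/0", "0/1", "1/1")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=germdiv",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(geno)), collapse = "\t")), con)
  for (j in seq_len(ncol(geno))) {
    calls <- ifelse(is.na(geno[, j]), "./.", gt[geno[, j] + 1L])
    writeLines(paste(c(markers$chrom[j], markers$pos[j], markers$marker_id[j],
                       markers$ref[j], markers$alt[j], ".", "PASS", ".", "GT",
                       calls), collapse = "\t"), con)
  }
  invisible(path)
}

#' Per-marker quality control statistics
#'
#' @param geno genotype_matrix.
#' @param pic_convention `"dart"` for 1 - p^2 - q^2 (biallelic maximum 0.5,
#'   the convention of DArT reports) or `"botstein"` for
#'   1 - p^2 - q^2 - 2 p^2 q^2.
#' @return data.frame(marker_id, n_typed, call_rate, maf, pic, het_rate);
#'   all-missing markers get NA maf/pic/het_rate and are flagged in
#'   `undefined`.
#' @export
marker_qc <- function(geno, pic_convention = c("dart", "botstein")) {
  pic_convention <- match.arg(pic_convention)
  n <- nrow(geno)
  typed <- colSums(!is.na(geno))
  p <- allele_freq_vec(geno)
  maf <- pmin(p, 1 - p)
  pq2 <- 2 * p * (1 - p)
  pic <- if (pic_convention == "dart") pq2 else pq2 - (pq2 / 2)^2 * 2
  het <- colSums(geno == 1L, na.rm = TRUE) / typed
  het[typed == 0L] <- NA_real_
  data.frame(marker_id = colnames(geno), n_typed = typed,
             call_rate = typed / n, maf = maf, pic = pic, het_rate = het,
             undefined = typed == 0L, row.names = NULL,
             stringsAsFactors = FALSE)
}

# alternate-allele frequency per marker; NA where no calls
allele_freq_vec <- function(geno, mask = NULL) {
  g <- if (is.null(mask)) geno else geno[mask, , drop = FALSE]
  typed <- colSums(!is.na(g))
  p <- colSums(g, na.rm = TRUE) / (2 * typed)
  p[typed == 0L] <- NA_real_
  p
}

#' Filter markers by call rate, MAF and placement
#'
#' @param geno genotype_matrix. @param markers marker data.frame.
#' @param min_call_rate,min_maf thresholds in [0,1]; a marker is kept when
#'   call_rate >= min_call_rate and maf >= min_maf.
#' @param placed_only drop markers without chromosome/position.
#' @return list(geno, markers, removed) where `removed` counts markers
#'   removed per rule (a marker can count under several rules).
#' @export
filter_markers <- function(geno, markers, min_call_rate = 0, min_maf = 0,
                           placed_only = FALSE) {
  stopifnot(min_call_rate >= 0, min_call_rate <= 1, min_maf >= 0, min_maf <= 1)
  qc <- marker_qc(geno)
  fail_cr <- qc$call_rate < min_call_rate
  fail_maf <- is.na(qc$maf) | qc$maf < min_maf
  if (min_maf == 0) fail_maf <- is.na(qc$maf)  # only drop all-missing
  fail_pl <- if (placed_only) is.na(markers$chrom) | is.na(markers$pos)
             else rep(FALSE, ncol(geno))
  keep <- !(fail_cr | fail_maf | fail_pl)
  if (!any(keep)) warning("all markers removed by filters")
  list(geno = geno[, keep, drop = FALSE],
       markers = markers[keep, , drop = FALSE],
       removed = c(call_rate = sum(fail_cr), maf = sum(fail_maf),
                   unplaced = sum(fail_pl), total = sum(!keep)))
}

#' Read sample metadata CSV
#'
#' Expected columns: accession_id, gene_pool, stratum, country, lat, lon.
#' Missing optional columns are filled with NA.
#' @param path CSV path.
#' @export
read_sample_info <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"accession_id" %in% names(df)) stop("accession_id column required")
  for (col in c("gene_pool", "stratum", "country"))
    if (!col %in% names(df)) df[[col]] <- NA_character_
  for (col in c("lat", "lon")) if (!col %in% names(df)) df[[col]] <- NA_real_
  ok <- is.na(df$lat) | (df$lat >= -90 & df$lat <= 90)
  ok2 <- is.na(df$lon) | (df$lon >= -180 & df$lon <= 180)
  if (!all(ok & ok2)) stop("coordinates out of range")
  df
}

#' Read a genome map CSV (chrom, length_bp)
#' @param path CSV path.
#' @export
read_genome_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("chrom", "length_bp") %in% names(df)))
    stop("genome map needs columns chrom, length_bp")
  if (any(df$length_bp <= 0)) stop("chromosome lengths must be > 0")
  if (anyDuplicated(df$chrom)) stop("duplicate chromosome labels")
  df
}
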