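# Positions are 1-based in all text formats (VCF convention); BED export is
# 0-based half-open. Conversions are centralized here.

#' Load a genotype panel from VCF, dosage TSV or HapMap-like text
#'
#' VCF genotypes are read via \pkg{vcfR}; biallelic sites only (multiallelic
#' records are dropped with a logged count). Homozygous reference maps to
#' dosage 0, homozygous alternate to 2 (haploid calls 0/1 likewise);
#' heterozygous calls are set missing with a logged count, since panels are
#' inbred. The dosage TSV format is lines x SNPs with a header of SNP ids
#' and line ids in the first column, plus a SNP map TSV (snp_id, chrom, pos,
#' major, minor). HapMap-like text has the usual leading columns
#' (rs#, alleles, chrom, pos, ...) followed by per-line base-pair calls.
#'
#' @param path genotype file path.
#' @param format one of \code{"vcf"}, \code{"tsv"}, \code{"hapmap"}.
#' @param snp_map_path SNP map TSV (required for \code{format = "tsv"}).
#' @param line_info optional data.frame (line_id, landrace, market_class);
#'   unknown labels default to \code{"unspecified"}.
#' @return a \code{\link{genotype_panel}}.
#' @export
load_genotypes <- function(path, format = c("vcf", "tsv", "hapmap"),
                           snp_map_path = NULL, line_info = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("genotype file not found: ", path)
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    multi <- grepl(",", fix$ALT)
    if (any(multi)) {
      message(sprintf("dropped %d multiallelic site(s)", sum(multi)))
      v <- v[!multi, ]
      fix <- fix[!multi, , drop = FALSE]
    }
    gt <- vcfR::extract.gt(v, element = "GT")
    dose <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    gt_clean <- gsub("\\|", "/", gt)
    dose[gt_clean %in% c("0/0", "0")] <- 0
    dose[gt_clean %in% c("1/1", "1")] <- 2
    het <- gt_clean %in% c("0/1", "1/0")
    if (any(het)) {
      message(sprintf("set %d heterozygous call(s) missing (inbred coding)", sum(het)))
    }
    map <- data.frame(snp_id = ifelse(is.na(fix$ID) | fix$ID == ".",
                                      paste0(fix$CHROM, "_", fix$POS), fix$ID),
                      chrom = fix$CHROM, pos = as.numeric(fix$POS),
                      major = fix$REF, minor = fix$ALT, stringsAsFactors = FALSE)
    geno <- t(dose)
  } else if (format == "tsv") {
    if (is.null(snp_map_path)) stop("snp_map_path is required for dosage TSV input")
    geno <- as.matrix(read.table(path, header = TRUE, sep = "\t",
                                 row.names = 1, check.names = FALSE))
    map <- read.table(snp_map_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  } else { # hapmap
    hm <- read.table(path, header = TRUE, sep = "\t", comment.char = "",
                     check.names = FALSE, stringsAsFactors = FALSE)
    meta_cols <- seq_len(11) # rs, alleles, chrom, pos, strand, ... per HapMap
    alleles <- strsplit(hm[[2]], "/")
    multi <- lengths(alleles) != 2
    if (any(multi)) {
      message(sprintf("dropped %d non-biallelic site(s)", sum(multi)))
      hm <- hm[!multi, , drop = FALSE]
      alleles <- alleles[!multi]
    }
    calls <- as.matrix(hm[, -meta_cols, drop = FALSE])
    minor <- vapply(alleles, `[`, "", 2)
    major <- vapply(alleles, `[`, "", 1)
    dose <- matrix(NA_real_, nrow(calls), ncol(calls), dimnames = dimnames(calls))
    for (i in seq_len(nrow(calls))) {
      dose[i, calls[i, ] == paste0(major[i], major[i])] <- 0
      dose[i, calls[i, ] == paste0(minor[i], minor[i])] <- 2
    }
    map <- data.frame(snp_id = hm[[1]], chrom = hm[[3]], pos = as.numeric(hm[[4]]),
                      major = major, minor = minor, stringsAsFactors = FALSE)
    geno <- t(dose)
  }
  ord <- order(map$chrom, map$pos)
  map <- map[ord, , drop = FALSE]
  geno <- geno[, ord, drop = FALSE]
  if (is.null(line_info)) {
    line_info <- data.frame(line_id = rownames(geno), landrace = "unspecified",
                            market_class = "unspecified", stringsAsFactors = FALSE)
  }
  genotype_panel(geno, map, line_info)
}

#' Write a genotype panel as VCF
#'
#' Minimal VCFv4.2 with homozygous diploid GT calls (0/0 for major, 1/1 for
#' minor, ./. for missing); REF = major allele, ALT = minor.
#'
#' @param panel a \code{\link{genotype_panel}}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_genotypes_vcf <- function(panel, path) {
  map <- panel$snp_map
  g <- panel$genotypes
  gt <- matrix("./.", ncol(g), nrow(g))
  gt[t(g) == 0] <- "0/0"
  gt[t(g) == 2] <- "1/1"
  header <- c("##fileformat=VCFv4.2",
              "##source=melscan",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(g)), collapse = "\t"))
  body <- paste(map$chrom, map$pos, map$snp_id, map$major, map$minor, ".",
                "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a genotype panel as dosage TSV + SNP map TSV
#'
#' @param panel a \code{\link{genotype_panel}}.
#' @param geno_path dosage matrix output path (lines x SNPs).
#' @param map_path SNP map output path.
#' @return invisibly, \code{geno_path}.
#' @export
write_genotypes_tsv <- function(panel, geno_path, map_path) {
  write.table(panel$genotypes, geno_path, sep = "\t", quote = FALSE,
              col.names = NA)
  write.table(panel$snp_map, map_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(geno_path)
}

#' Write a samples x features table as TSV with a provenance sidecar
#'
#' @param x matrix or data.frame.
#' @param path output TSV path; any \code{"provenance"} attribute is written
#'   to \code{<path>.provenance.json}.
#' @return invisibly, the path.
#' @export
write_table_tsv <- function(x, path) {
  write.table(as.matrix(x), path, sep = "\t", quote = FALSE, col.names = NA)
  prov <- attr(x, "provenance")
  if (!is.null(prov)) {
    jsonlite::write_json(prov, paste0(path, ".provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a samples x features TSV written by \code{\link{write_table_tsv}}
#'
#' @param path TSV path.
#' @return numeric matrix with row and column names.
#' @export
read_table_tsv <- function(path) {
  as.matrix(read.table(path, header = TRUE, sep = "\t", row.names = 1,
                       check.names = FALSE))
}

#' Export MEL regions as BED (plus a JSON sidecar with provenance)
#'
#' BED intervals are 0-based half-open; internal MEL coordinates are 1-based
#' inclusive bp positions, so start is shifted by one.
#'
#' @param mel MEL table from \code{\link{call_mel}}.
#' @param path BED output path; member SNPs and contributing (donor, trait)
#'   pairs go to \code{<path>.json}.
#' @return invisibly, the path.
#' @export
write_mel_bed <- function(mel, path) {
  bed <- data.frame(chrom = mel$chrom, start = mel$start - 1, end = mel$end,
                    name = mel$mel_id, score = mel$n_traits)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  side <- lapply(seq_len(nrow(mel)), function(i) {
    list(mel_id = mel$mel_id[i], chrom = mel$chrom[i], start = mel$start[i],
         end = mel$end[i], n_traits = mel$n_traits[i],
         n_donors = mel$n_donors[i],
         member_snps = mel$member_snps[[i]], pairs = mel$pairs[[i]])
  })
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
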