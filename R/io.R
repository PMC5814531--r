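#' Write GBS read counts as VCF v4.2
#'
#' Emits one record per SNP with `GT:AD:DP` FORMAT fields. Genotypes are
#' the presence/absence calls of [call_dosages()] (`./.` at depth 0); `AD`
#' carries the reference and alternate read counts. Internal 0-based
#' thinking stops at the door: positions are written 1-based as VCF
#' requires.
#'
#' @param reads a `ReadCountMatrix`.
#' @param file output path (plain text).
#' @return `file`, invisibly.
#' @export
write_gbs_vcf <- function(reads, file) {
  stopifnot(inherits(reads, "ReadCountMatrix"))
  depth <- reads$ref + reads$alt
  gt <- matrix("./.", nrow(depth), ncol(depth))
  gt[depth > 0] <- "0/1"
  gt[reads$alt == 0 & depth > 0] <- "0/0"
  gt[reads$ref == 0 & depth > 0] <- "1/1"
  cells <- matrix(paste0(gt, ":", reads$ref, ",", reads$alt, ":", depth),
                  nrow(depth), ncol(depth))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=polycrossGS",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths for the ref and alt alleles">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", reads$ids), collapse = "\t"))
  body <- paste(reads$snps$scaffold, reads$snps$pos, reads$snps$snp,
                reads$snps$ref, reads$snps$alt, ".", "PASS", ".", "GT:AD:DP",
                apply(cells, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), file)
  invisible(file)
}

#' Read GBS read counts from a VCF with AD fields
#'
#' Parses per-sample allele depths (`AD`) from a biallelic VCF into a
#' [read_count_matrix()]. Records without an `AD` entry for a sample are
#' treated as depth 0 (missing).
#'
#' @param file path to a VCF (plain or gzipped).
#' @return a `ReadCountMatrix`.
#' @export
read_gbs_vcf <- function(file) {
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  ad <- vcfR::extract.gt(v, element = "AD")
  parse_allele <- function(i_allele) {
    out <- vapply(strsplit(as.vector(ad), ",", fixed = TRUE), function(x) {
      if (length(x) < i_allele || is.na(x[i_allele])) 0L else as.integer(x[i_allele])
    }, integer(1))
    matrix(out, nrow(ad), ncol(ad))
  }
  ref <- t(parse_allele(1L))
  alt <- t(parse_allele(2L))
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  snps <- data.frame(snp = ifelse(is.na(fix$ID) | fix$ID == ".",
                                  paste0(fix$CHROM, "_", fix$POS), fix$ID),
                     scaffold = fix$CHROM, pos = as.integer(fix$POS),
                     ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  read_count_matrix(ref, alt, ids = colnames(ad), snps = snps)
}

#' Write/read read counts as TSV
#'
#' One row per SNP; paired `<id>.ref` / `<id>.alt` columns per individual.
#'
#' @param reads a `ReadCountMatrix`.
#' @param file path.
#' @return `file` (write) or a `ReadCountMatrix` (read).
#' @export
write_read_counts <- function(reads, file) {
  stopifnot(inherits(reads, "ReadCountMatrix"))
  tab <- data.frame(reads$snps,
                    t(reads$ref), t(reads$alt), check.names = FALSE)
  names(tab)[-seq_len(ncol(reads$snps))] <-
    c(paste0(reads$ids, ".ref"), paste0(reads$ids, ".alt"))
  utils::write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_read_counts
#' @export
read_read_counts <- function(file) {
  tab <- utils::read.delim(file, check.names = FALSE)
  snp_cols <- c("snp", "scaffold", "pos", "ref", "alt")
  ids <- sub("\\.ref$", "", grep("\\.ref$", names(tab), value = TRUE))
  ref <- t(as.matrix(tab[, paste0(ids, ".ref")]))
  alt <- t(as.matrix(tab[, paste0(ids, ".alt")]))
  read_count_matrix(ref, alt, ids = ids,
                    snps = tab[, snp_cols])
}

#' Write/read long-format phenotype records
#'
#' Tab-separated with the canonical header (family, population, site,
#' treatment, rep, row, col, year, harvest, value).
#'
#' @param records phenotype data.frame as from [simulate_trial()].
#' @param file path.
#' @export
write_phenotypes <- function(records, file) {
  utils::write.table(records, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(file) {
  utils::read.delim(file, stringsAsFactors = FALSE)
}

#' Write a relationship matrix as TSV
#'
#' Square matrix with a leading id column and id header row.
#' @param grm a `GRM` (see [standard_grm()]) or plain matrix.
#' @param file path.
#' @export
write_grm <- function(grm, file) {
  S <- if (inherits(grm, "GRM")) grm$S else grm
  tab <- data.frame(id = rownames(S), S, check.names = FALSE)
  utils::write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
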