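#' Read and write tab-separated analysis tables
#'
#' Thin wrappers over readr with the column layouts used throughout the
#' package: summary statistics (`variant_id`, `effect_allele`, `eaf`, `beta`,
#' `se`, `p`, `n`, `stratum`, plus optional positional columns), weight
#' models (`gene_id`, `tissue`, `variant_id`, `effect_allele`, `weight`) and
#' gene-region definitions (BED-like, 0-based half-open start converted to
#' the 1-based inclusive convention used internally).
#'
#' @param path File path.
#' @param x Table to write.
#' @return `read_*` return tibbles; `write_*` return `x` invisibly.
#' @name omics_io
NULL

#' @rdname omics_io
#' @export
read_summary_stats <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname omics_io
#' @export
write_summary_stats <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(x)
}

#' @rdname omics_io
#' @export
read_weight_models <- function(path) {
  w <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("gene_id", "tissue", "variant_id", "effect_allele", "weight")
  miss <- setdiff(need, names(w))
  if (length(miss)) abort(paste("weight table lacks:", paste(miss, collapse = ", ")))
  w
}

#' @rdname omics_io
#' @export
write_weight_models <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(x)
}

#' @rdname omics_io
#' @export
read_regions_bed <- function(path) {
  bed <- readr::read_tsv(path, col_names = c("chromosome", "start", "end",
                                             "gene_id"),
                         show_col_types = FALSE, comment = "#")
  cis_region(bed$gene_id, bed$chromosome,
             gene_start = bed$start + 1L, gene_stop = bed$end)
}

#' Write genotypes as TSV or minimal dosage VCF
#'
#' `write_genotypes_tsv` stores the dosage matrix with variant ids as column
#' names plus a companion `<path>.variants.tsv` metadata table.
#' `write_genotypes_vcf` writes a minimal VCFv4.2 file with dosages in a
#' per-sample `DS` FORMAT field (readable by standard VCF tooling).
#'
#' @param geno A [genotype_matrix()].
#' @param path Output path.
#' @param chromosome Chromosome label used in the VCF.
#' @return `geno`, invisibly.
#' @export
write_genotypes_tsv <- function(geno, path) {
  readr::write_tsv(tibble::as_tibble(geno$dosages), path)
  readr::write_tsv(geno$variants, paste0(path, ".variants.tsv"))
  invisible(geno)
}

#' @rdname write_genotypes_tsv
#' @export
write_genotypes_vcf <- function(geno, path, chromosome = "1") {
  n <- nrow(geno$dosages)
  samples <- sprintf("S%05d", seq_len(n))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Estimated allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")), con)
  v <- geno$variants
  for (j in seq_len(nrow(v))) {
    row <- c(chromosome, v$position[j], v$variant_id[j], v$other_allele[j],
             v$effect_allele[j], ".", "PASS",
             sprintf("AF=%.6f", v$maf[j]), "DS",
             sprintf("%.3f", geno$dosages[, j]))
    writeLines(paste(row, collapse = "\t"), con)
  }
  invisible(geno)
}
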