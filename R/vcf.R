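#' Read biallelic SNP genotypes from a VCF
#'
#' Loads GT fields from a multi-sample VCF (plain or gzip) into a
#' [genotype_matrix()]. Only biallelic SNP records are kept; multi-allelic
#' records are skipped with a warning. Genotype separators `/` and `|` are
#' treated identically (genotypes are unphased); `./.` and half-calls such
#' as `0/.` are coded as missing. Stack identity is taken from the `ID`
#' column when it has the form `locus:site` (as written by [write_vcf()]),
#' otherwise `CHROM` is the locus id and `POS - 1` the within-locus site
#' index.
#'
#' @param path path to a VCF file.
#' @param popmap a `population_map`; all VCF samples must be present in it.
#' @return a `genotype_matrix`.
#' @export
read_vcf <- function(path, popmap) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("VCF contains no records: ", path)
  gt_raw <- v@gt
  samples <- colnames(gt_raw)[-1]
  popmap_check_samples(popmap, samples)

  is_snp <- nchar(fix$REF) == 1 & nchar(fix$ALT) >= 1 & !grepl(",", fix$ALT) &
    nchar(fix$ALT) == 1
  if (any(!is_snp)) {
    warning(sum(!is_snp), " non-biallelic-SNP record(s) skipped")
  }
  fix <- fix[is_snp, , drop = FALSE]
  if (nrow(fix) == 0) stop("no biallelic SNP records in VCF")

  gt <- vcfR::extract.gt(v, element = "GT")[is_snp, , drop = FALSE]
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, samples))
  gt <- gsub("|", "/", gt, fixed = TRUE)
  code <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  code[gt == "0/0"] <- 0L
  code[gt %in% c("0/1", "1/0")] <- 1L
  code[gt == "1/1"] <- 2L
  calls <- t(code)
  rownames(calls) <- samples

  id <- fix$ID
  from_id <- !is.na(id) & grepl("^[^:]+:[0-9]+$", id)
  locus_id <- ifelse(from_id, sub(":.*$", "", id), fix$CHROM)
  site_index <- ifelse(from_id, as.integer(sub("^.*:", "", id)),
                       as.integer(fix$POS) - 1L)
  loci <- data.frame(locus_id = locus_id, site_index = as.integer(site_index),
                     ref = fix$REF, alt = fix$ALT, chrom = fix$CHROM,
                     pos = as.integer(fix$POS), stringsAsFactors = FALSE)
  genotype_matrix(calls, loci)
}

#' Write a genotype matrix as a minimal VCF 4.2
#'
#' Emits a GT-only VCF (unphased `/` separators) with `CHROM` set to the
#' locus id, `POS` to the 1-based position, and `ID` to `locus:site_index`
#' so that [read_vcf()] recovers the stack structure exactly. Missing
#' genotypes are written as `./.`.
#'
#' @param gm a `genotype_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=karstdemog",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(gm$calls)), collapse = "\t")), con)
  if (ncol(gm$calls) == 0) return(invisible(path))
  gt_str <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(ncol(gm$calls)), function(j) {
    g <- gm$calls[, j]
    gt <- ifelse(is.na(g), "./.", gt_str[g + 1L])
    l <- gm$loci[j, ]
    paste(c(l$chrom, l$pos, paste0(l$locus_id, ":", l$site_index),
            l$ref, l$alt, ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}
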