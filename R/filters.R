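#' SNP/locus filter configuration
#'
#' Mirrors the Stacks `populations` filters commonly used on
#' reduced-representation SNP tables: a presence filter (genotyped in at
#' least a fraction `r` of samples in each of at least `p` populations),
#' a pooled minor-allele-frequency floor, an observed-heterozygosity
#' ceiling, and optional thinning to the first SNP per stack.
#'
#' @param p minimum number of populations a locus must be well genotyped in.
#' @param r per-population fraction of genotyped samples required.
#' @param min_maf minimum pooled minor-allele frequency (0 disables).
#' @param max_obs_het maximum pooled observed heterozygosity (1 disables).
#' @param single_snp_per_locus keep only the first SNP of each stack.
#' @return list of class `filter_config`.
#' @export
filter_config <- function(p = 1L, r = 0, min_maf = 0, max_obs_het = 1,
                          single_snp_per_locus = FALSE) {
  stopifnot(p >= 1, r >= 0, r <= 1, min_maf >= 0, min_maf <= 0.5,
            max_obs_het >= 0, max_obs_het <= 1)
  structure(list(p = as.integer(p), r = r, min_maf = min_maf,
                 max_obs_het = max_obs_het,
                 single_snp_per_locus = isTRUE(single_snp_per_locus)),
            class = "filter_config")
}

filter_report_step <- function(step, n_in, keep) {
  data.frame(step = step, n_in = n_in, n_removed = n_in - sum(keep),
             n_retained = sum(keep), stringsAsFactors = FALSE)
}

#' Presence filter (-p / -r)
#'
#' A SNP is retained iff it is genotyped (non-missing) in at least a
#' fraction `r` of the samples of each of at least `p` populations
#' (ties at exactly `r` are retained).
#'
#' @param gm a `genotype_matrix`.
#' @param popmap a `population_map` covering all samples.
#' @param p minimum number of qualifying populations.
#' @param r required genotyped fraction per population.
#' @return list with elements `gm` (filtered matrix) and `report`.
#' @export
filter_presence <- function(gm, popmap, p, r) {
  popmap_check_samples(popmap, rownames(gm$calls))
  groups <- sample_groups(popmap, "population")
  groups <- lapply(groups, intersect, rownames(gm$calls))
  groups <- groups[lengths(groups) > 0]
  if (p > length(groups)) {
    stop("p = ", p, " exceeds the number of populations (", length(groups), ")")
  }
  ok_pops <- vapply(groups, function(s) {
    colMeans(!is.na(gm$calls[s, , drop = FALSE])) >= r
  }, logical(ncol(gm$calls)))
  if (is.null(dim(ok_pops))) ok_pops <- matrix(ok_pops, nrow = 1)
  keep <- rowSums(ok_pops) >= p
  list(gm = subset_snps(gm, keep),
       report = filter_report_step(sprintf("presence(p=%d,r=%g)", p, r),
                                   ncol(gm$calls), keep))
}

#' Minor-allele-frequency filter (--min-maf)
#'
#' MAF is computed on the pooled sample from non-missing calls; a SNP is
#' retained iff MAF >= `min_maf`.
#'
#' @inheritParams filter_presence
#' @param min_maf threshold in `[0, 0.5]`.
#' @return list with elements `gm` and `report`.
#' @export
filter_maf <- function(gm, min_maf) {
  alt <- colSums(gm$calls, na.rm = TRUE)
  genes <- 2 * colSums(!is.na(gm$calls))
  freq <- ifelse(genes > 0, alt / genes, 0)
  maf <- pmin(freq, 1 - freq)
  keep <- maf >= min_maf
  list(gm = subset_snps(gm, keep),
       report = filter_report_step(sprintf("maf(min=%g)", min_maf),
                                   ncol(gm$calls), keep))
}

#' Observed-heterozygosity filter (--max-obs-het)
#'
#' A SNP is retained iff the fraction of heterozygous genotypes among
#' non-missing genotypes (pooled across samples) is <= `max_obs_het`.
#'
#' @inheritParams filter_presence
#' @param max_obs_het threshold in `[0, 1]`.
#' @return list with elements `gm` and `report`.
#' @export
filter_obs_het <- function(gm, max_obs_het) {
  het <- colSums(gm$calls == 1L, na.rm = TRUE)
  nn <- colSums(!is.na(gm$calls))
  ho <- ifelse(nn > 0, het / nn, 0)
  keep <- ho <= max_obs_het
  list(gm = subset_snps(gm, keep),
       report = filter_report_step(sprintf("obs_het(max=%g)", max_obs_het),
                                   ncol(gm$calls), keep))
}

#' First SNP per locus (--write-single-snp)
#'
#' For each stack keeps only the SNP with the smallest within-stack site
#' index; the result does not depend on column order.
#'
#' @inheritParams filter_presence
#' @return list with elements `gm` and `report`.
#' @export
first_snp_per_locus <- function(gm) {
  o <- order(gm$loci$locus_id, gm$loci$site_index)
  first <- o[!duplicated(gm$loci$locus_id[o])]
  keep <- seq_len(ncol(gm$calls)) %in% first
  list(gm = subset_snps(gm, keep),
       report = filter_report_step("single_snp", ncol(gm$calls), keep))
}

#' Apply the full filter chain
#'
#' Order is fixed as presence -> single-SNP -> MAF -> observed
#' heterozygosity, and the report records each step's input/removed/
#' retained counts.
#'
#' @inheritParams filter_presence
#' @param config a [filter_config()].
#' @return list with `gm` (surviving SNPs) and `report` (data.frame, one
#'   row per applied step).
#' @export
filter_snps <- function(gm, popmap, config) {
  stopifnot(inherits(config, "filter_config"))
  report <- list()
  st <- filter_presence(gm, popmap, config$p, config$r)
  report <- c(report, list(st$report))
  if (config$single_snp_per_locus) {
    st <- first_snp_per_locus(st$gm)
    report <- c(report, list(st$report))
  }
  if (config$min_maf > 0) {
    st2 <- filter_maf(st$gm, config$min_maf)
    report <- c(report, list(st2$report))
    st <- st2
  }
  if (config$max_obs_het < 1) {
    st2 <- filter_obs_het(st$gm, config$max_obs_het)
    report <- c(report, list(st2$report))
    st <- st2
  }
  list(gm = st$gm, report = do.call(rbind, report))
}
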