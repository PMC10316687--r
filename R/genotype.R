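#' Genotype matrix container
#'
#' A `genotype_matrix` stores diploid biallelic SNP calls as an integer
#' matrix of alternate-allele counts (samples in rows, SNPs in columns);
#' `NA` marks a missing genotype. Column metadata (`loci`) carries, per SNP,
#' the stack (locus) identifier, the 0-based position of the SNP within the
#' stack, and REF/ALT alleles, so that "first SNP per locus" selection and
#' VCF round-trips are well defined.
#'
#' @param calls integer matrix, samples x SNPs, values in \{0,1,2,NA\}.
#' @param loci data.frame with columns `locus_id`, `site_index`, `ref`,
#'   `alt` (one row per SNP column). `chrom`/`pos` columns are optional;
#'   when absent they default to `locus_id` / `site_index + 1`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, loci) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(rownames(calls))) stop("calls must have sample ids as rownames")
  stopifnot(is.data.frame(loci))
  need <- c("locus_id", "site_index", "ref", "alt")
  miss <- setdiff(need, names(loci))
  if (length(miss)) stop("loci lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(loci) != ncol(calls)) {
    stop("loci has ", nrow(loci), " rows but calls has ", ncol(calls), " columns")
  }
  bad <- calls[!is.na(calls)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    stop("non-missing calls must be in {0,1,2}")
  }
  key <- paste(loci$locus_id, loci$site_index)
  if (anyDuplicated(key)) stop("(locus_id, site_index) pairs must be unique")
  if (is.null(loci$chrom)) loci$chrom <- as.character(loci$locus_id)
  if (is.null(loci$pos)) loci$pos <- as.integer(loci$site_index) + 1L
  rownames(loci) <- NULL
  colnames(calls) <- key
  structure(list(calls = calls, loci = loci, ploidy = 2L),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  nmiss <- sum(is.na(x$calls))
  cat("genotype_matrix: ", nrow(x$calls), " samples x ", ncol(x$calls),
      " SNPs (", length(unique(x$loci$locus_id)), " loci), ",
      format(100 * nmiss / max(1, length(x$calls)), digits = 3),
      "% missing\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Number of samples / SNPs / loci
#' @param gm a `genotype_matrix`.
#' @return integer count.
#' @export
n_samples <- function(gm) nrow(gm$calls)

#' @rdname n_samples
#' @export
n_snps <- function(gm) ncol(gm$calls)

#' @rdname n_samples
#' @export
n_loci <- function(gm) length(unique(gm$loci$locus_id))

#' Subset a genotype matrix by SNP columns
#' @param gm a `genotype_matrix`.
#' @param keep logical or integer index over SNP columns.
#' @return a `genotype_matrix` with the selected columns.
#' @export
subset_snps <- function(gm, keep) {
  genotype_matrix(gm$calls[, keep, drop = FALSE], gm$loci[keep, , drop = FALSE])
}

#' Sample-to-population-to-cluster map
#'
#' Reads a whitespace/tab-delimited text file with columns
#' `sample population cluster [lat lon]` (no header). Every sample belongs
#' to exactly one population and every population to exactly one cluster.
#' Cluster labels are conventionally `I` and `II`; more than two clusters
#' are accepted for diversity statistics but rejected by the demographic
#' fitting functions, which model exactly two demes.
#'
#' @param path path to the popmap file (plain or gzip).
#' @return data.frame of class `population_map` with columns `sample`,
#'   `population`, `cluster` and optionally `lat`, `lon`.
#' @export
read_popmap <- function(path) {
  df <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("popmap needs at least 3 columns: sample population cluster")
  names(df)[1:3] <- c("sample", "population", "cluster")
  if (ncol(df) >= 5) {
    names(df)[4:5] <- c("lat", "lon")
    df$lat <- as.numeric(df$lat)
    df$lon <- as.numeric(df$lon)
  }
  population_map(df)
}

#' @rdname read_popmap
#' @param df data.frame with columns `sample`, `population`, `cluster`
#'   and optional `lat`, `lon`.
#' @export
population_map <- function(df) {
  stopifnot(is.data.frame(df))
  if (anyDuplicated(df$sample)) {
    stop("duplicated sample id in popmap: ",
         paste(unique(df$sample[duplicated(df$sample)]), collapse = ", "))
  }
  pc <- unique(df[, c("population", "cluster")])
  if (anyDuplicated(pc$population)) {
    stop("population assigned to more than one cluster")
  }
  df$sample <- as.character(df$sample)
  df$population <- as.character(df$population)
  df$cluster <- as.character(df$cluster)
  rownames(df) <- NULL
  class(df) <- c("population_map", "data.frame")
  df
}

#' Write a popmap to file
#' @param popmap a `population_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_popmap <- function(popmap, path) {
  write.table(popmap, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

popmap_check_samples <- function(popmap, samples) {
  missing <- setdiff(samples, popmap$sample)
  if (length(missing)) {
    stop("samples absent from popmap: ", paste(missing, collapse = ", "))
  }
}

#' Split sample ids by population or cluster
#' @param popmap a `population_map`.
#' @param level `"population"` or `"cluster"`.
#' @return named list of character vectors of sample ids.
#' @export
sample_groups <- function(popmap, level = c("population", "cluster")) {
  level <- match.arg(level)
  split(popmap$sample, popmap[[level]])
}

#' Cluster sample lists in fixed (I, II) order
#' @param popmap a `population_map`.
#' @return list of two character vectors, clusters sorted so that `I`
#'   precedes `II` when those labels are used.
#' @export
cluster_samples <- function(popmap) {
  gr <- sample_groups(popmap, "cluster")
  if (all(c("I", "II") %in% names(gr))) gr <- gr[c("I", "II")] else gr <- gr[order(names(gr))]
  gr
}

#' Pairwise great-circle distances between populations
#'
#' Haversine distances in km computed from the popmap's decimal-degree
#' coordinates (one coordinate per population; the first sample's row is
#' used).
#'
#' @param popmap a `population_map` with `lat`/`lon` columns.
#' @return symmetric matrix of distances in km with populations as dimnames.
#' @export
geo_distance <- function(popmap) {
  if (is.null(popmap$lat) || is.null(popmap$lon)) {
    stop("popmap has no lat/lon columns")
  }
  first <- !duplicated(popmap$population)
  pts <- popmap[first, c("lon", "lat")]
  d <- geosphere::distm(as.matrix(pts), fun = geosphere::distHaversine) / 1000
  dimnames(d) <- list(popmap$population[first], popmap$population[first])
  d
}
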