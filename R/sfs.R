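#' Folded 2D minor-allele SFS container
#'
#' Counts of SNPs indexed by minor-allele copy number in cluster I
#' (rows, `0..2*n1`) and cluster II (columns, `0..2*n2`). Cell `(0,0)`
#' holds the monomorphic-site count `total_sites - n_variant` when
#' `total_sites` is supplied, so that likelihoods may include invariant
#' sites. Exact-half folds contribute 1/2 to each of the two complementary
#' cells, so cell values may be half-integers while totals are conserved.
#'
#' @param counts numeric matrix of dimension `(2*n1+1) x (2*n2+1)`.
#' @param n1,n2 diploid sample sizes of clusters I and II.
#' @param total_sites optional total (monomorphic + variant) site count.
#' @param seed optional imputation seed recorded for provenance.
#' @return object of class `folded_2dsfs`.
#' @export
folded_2dsfs <- function(counts, n1, n2, total_sites = NULL, seed = NULL) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == 2 * n1 + 1, ncol(counts) == 2 * n2 + 1,
            all(counts >= 0))
  dimnames(counts) <- list(0:(2 * n1), 0:(2 * n2))
  n_variant <- sum(counts) - counts[1, 1]
  if (!is.null(total_sites)) {
    if (total_sites < n_variant) stop("total_sites < number of variant sites")
    counts[1, 1] <- total_sites - n_variant
  }
  structure(list(counts = counts, n1 = as.integer(n1), n2 = as.integer(n2),
                 total_sites = total_sites, n_variant = n_variant,
                 seed = seed),
            class = "folded_2dsfs")
}

#' @export
print.folded_2dsfs <- function(x, ...) {
  cat("folded 2D minor-allele SFS: clusters of ", x$n1, " + ", x$n2,
      " diploids, ", format(x$n_variant), " variant sites",
      if (!is.null(x$total_sites)) paste0(" of ", x$total_sites, " total"),
      "\n", sep = "")
  invisible(x)
}

# Fold an unfolded (alternate/derived copy-number) matrix by the global
# minor allele: cells with i + j > (2n1 + 2n2)/2 are reflected onto their
# complement; mass at exactly half is split evenly between the cell and
# its complement.
fold_2d <- function(mat) {
  n1g <- nrow(mat) - 1L
  n2g <- ncol(mat) - 1L
  half <- (n1g + n2g) / 2
  tot <- (row(mat) - 1L) + (col(mat) - 1L)
  mrev <- mat[(n1g + 1L):1L, (n2g + 1L):1L, drop = FALSE]
  out <- (mat + mrev) * ((tot < half) + 0.5 * (tot == half))
  dimnames(out) <- dimnames(mat)
  out
}

# Fold a 1D spectrum by minor allele with the same half-split rule.
fold_1d <- function(v) {
  n <- length(v) - 1L
  out <- numeric(n + 1L)
  for (i in 0:n) {
    x <- v[i + 1L]
    if (x == 0) next
    if (i < n - i) {
      out[i + 1L] <- out[i + 1L] + x
    } else if (i > n - i) {
      out[n - i + 1L] <- out[n - i + 1L] + x
    } else {
      out[i + 1L] <- out[i + 1L] + x
    }
  }
  names(out) <- 0:n
  out[1:(floor(n / 2) + 1L)]
}

#' Bootstrap imputation of missing genotypes within clusters
#'
#' For each SNP and each cluster, every missing gene copy is drawn
#' independently with replacement from the cluster's observed gene copies
#' at that SNP (i.e. a missing diploid genotype becomes Binomial(2, p)
#' with p the observed within-cluster alternate-allele frequency).
#' Non-missing calls are never altered; the seed fully determines the
#' output.
#'
#' @param gm a `genotype_matrix`.
#' @param popmap a `population_map`.
#' @param seed RNG seed (required).
#' @return a complete `genotype_matrix` (no missing calls).
#' @export
impute_missing <- function(gm, popmap, seed) {
  if (missing(seed)) stop("seed is required for reproducible imputation")
  popmap_check_samples(popmap, rownames(gm$calls))
  set.seed(seed)
  calls <- gm$calls
  for (cl in cluster_samples(popmap)) {
    cl <- intersect(cl, rownames(calls))
    if (!length(cl)) next
    m <- calls[cl, , drop = FALSE]
    nn <- colSums(!is.na(m))
    if (any(nn == 0 & colSums(is.na(m)) > 0)) {
      bad <- which(nn == 0 & colSums(is.na(m)) > 0)
      stop("SNP(s) with a cluster entirely missing: ",
           paste(colnames(m)[bad], collapse = ", "))
    }
    p <- ifelse(nn > 0, colSums(m, na.rm = TRUE) / (2 * nn), 0)
    for (j in which(colSums(is.na(m)) > 0)) {
      miss <- which(is.na(m[, j]))
      m[miss, j] <- rbinom(length(miss), 2L, p[j])
    }
    calls[cl, ] <- m
  }
  genotype_matrix(calls, gm$loci)
}

#' Build the folded 2D minor-allele SFS from complete genotypes
#'
#' Requires a complete matrix (run [impute_missing()] first) and exactly
#' two clusters in the popmap. Per SNP the alternate-allele copy numbers
#' `(i, j)` in clusters I and II are folded by the global minor allele.
#'
#' @param gm a complete `genotype_matrix`.
#' @param popmap a `population_map` with exactly two clusters.
#' @param total_sites optional total site count for the monomorphic cell.
#' @param seed imputation seed to record, if any.
#' @return a `folded_2dsfs`.
#' @export
build_folded_2dsfs <- function(gm, popmap, total_sites = NULL, seed = NULL) {
  if (anyNA(gm$calls)) stop("matrix has missing calls; impute first")
  cls <- cluster_samples(popmap)
  if (length(cls) != 2) stop("SFS construction requires exactly 2 clusters")
  s1 <- intersect(cls[[1]], rownames(gm$calls))
  s2 <- intersect(cls[[2]], rownames(gm$calls))
  n1 <- length(s1); n2 <- length(s2)
  i <- colSums(gm$calls[s1, , drop = FALSE])
  j <- colSums(gm$calls[s2, , drop = FALSE])
  counts <- matrix(0, 2 * n1 + 1, 2 * n2 + 1)
  half <- n1 + n2  # (2n1 + 2n2)/2
  for (s in seq_along(i)) {
    tot <- i[s] + j[s]
    if (tot < half) {
      counts[i[s] + 1, j[s] + 1] <- counts[i[s] + 1, j[s] + 1] + 1
    } else if (tot > half) {
      counts[2 * n1 - i[s] + 1, 2 * n2 - j[s] + 1] <-
        counts[2 * n1 - i[s] + 1, 2 * n2 - j[s] + 1] + 1
    } else {
      counts[i[s] + 1, j[s] + 1] <- counts[i[s] + 1, j[s] + 1] + 0.5
      counts[2 * n1 - i[s] + 1, 2 * n2 - j[s] + 1] <-
        counts[2 * n1 - i[s] + 1, 2 * n2 - j[s] + 1] + 0.5
    }
  }
  folded_2dsfs(counts, n1, n2, total_sites = total_sites, seed = seed)
}

#' Marginal folded 1D spectra of a folded 2D SFS
#'
#' Row/column sums over polymorphic cells, each re-folded by that
#' cluster's own minor allele; both margins sum to the variant-site count.
#'
#' @param sfs a `folded_2dsfs`.
#' @return list with numeric vectors `cluster1` and `cluster2`.
#' @export
sfs_marginals <- function(sfs) {
  m <- sfs$counts
  m[1, 1] <- 0
  list(cluster1 = fold_1d(rowSums(m)), cluster2 = fold_1d(colSums(m)))
}

#' Write / read a folded 2D SFS as text
#'
#' `format = "tsv"` writes a commented-metadata TSV (the package's native
#' format, read back by [read_sfs()]); `format = "fsc"` writes a
#' fastsimcoal-style joint minor-allele observation file (header line,
#' labelled rows `d1_i`, columns `d2_j`).
#'
#' @param sfs a `folded_2dsfs`.
#' @param path output path.
#' @param format `"tsv"` or `"fsc"`.
#' @return `path`, invisibly.
#' @export
write_sfs <- function(sfs, path, format = c("tsv", "fsc")) {
  format <- match.arg(format)
  if (format == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
      paste0("# n1=", sfs$n1, " n2=", sfs$n2),
      paste0("# total_sites=", if (is.null(sfs$total_sites)) "NA" else sfs$total_sites),
      paste0("# seed=", if (is.null(sfs$seed)) "NA" else sfs$seed)), con)
    write.table(sfs$counts, con, sep = "\t", quote = FALSE, col.names = NA)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("1 observations", con)
    writeLines(paste(c("", paste0("d2_", 0:(2 * sfs$n2))), collapse = "\t"), con)
    for (i in 0:(2 * sfs$n1)) {
      writeLines(paste(c(paste0("d1_", i), sfs$counts[i + 1, ]), collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' @rdname write_sfs
#' @export
read_sfs <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    m <- regmatches(meta, regexpr(paste0(key, "=[^ ]+"), meta))
    v <- sub(paste0(key, "="), "", unlist(m))[1]
    if (is.na(v) || v == "NA") NULL else as.numeric(v)
  }
  n1 <- get("n1"); n2 <- get("n2")
  if (is.null(n1)) stop("not a karstdemog SFS TSV (missing '# n1=' header)")
  counts <- as.matrix(read.table(text = lines[!grepl("^#", lines)],
                                 header = TRUE, row.names = 1, sep = "\t",
                                 check.names = FALSE))
  sfs <- folded_2dsfs(counts, n1, n2, seed = get("seed"))
  ts <- get("total_sites")
  if (!is.null(ts)) sfs <- folded_2dsfs(sfs$counts, n1, n2, total_sites = ts,
                                        seed = sfs$seed)
  sfs
}
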