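group_calls <- function(gm, samples) {
  missing <- setdiff(samples, rownames(gm$calls))
  if (length(missing)) stop("samples not in matrix: ", paste(missing, collapse = ", "))
  gm$calls[samples, , drop = FALSE]
}

#' Observed heterozygosity
#'
#' Per SNP, the fraction of heterozygous genotypes among non-missing
#' genotypes in the group; SNPs with no data in the group are excluded.
#'
#' @param gm a `genotype_matrix`.
#' @param samples character vector of sample ids defining the group.
#' @return list with `per_locus` (named numeric), `mean`, `se`
#'   (sd over SNPs / sqrt(number of SNPs)).
#' @export
observed_heterozygosity <- function(gm, samples) {
  m <- group_calls(gm, samples)
  nn <- colSums(!is.na(m))
  ho <- ifelse(nn > 0, colSums(m == 1L, na.rm = TRUE) / nn, NA_real_)
  ho <- ho[nn > 0]
  list(per_locus = ho, mean = mean(ho), se = sd(ho) / sqrt(length(ho)))
}

#' Expected heterozygosity
#'
#' Per SNP, `1 - p^2 - q^2` with the alternate-allele frequency `p`
#' estimated from non-missing gene copies in the group.
#'
#' @inheritParams observed_heterozygosity
#' @return list with `per_locus`, `mean`, `se`, and `freq` (alt-allele
#'   frequencies).
#' @export
expected_heterozygosity <- function(gm, samples) {
  m <- group_calls(gm, samples)
  nn <- colSums(!is.na(m))
  p <- ifelse(nn > 0, colSums(m, na.rm = TRUE) / (2 * nn), NA_real_)
  he <- 2 * p * (1 - p)
  he <- he[nn > 0]
  list(per_locus = he, mean = mean(he), se = sd(he) / sqrt(length(he)),
       freq = p)
}

#' Inbreeding coefficient F_IS
#'
#' Per SNP with expected heterozygosity > 0,
#' `F = (H_E - H_O) / H_E`; the reported value is the mean over such SNPs.
#'
#' @inheritParams observed_heterozygosity
#' @return list with `per_locus` and `mean`; `mean` is `NA` (with a
#'   warning) when every SNP is monomorphic in the group.
#' @export
inbreeding_coefficient <- function(gm, samples) {
  m <- group_calls(gm, samples)
  nn <- colSums(!is.na(m))
  p <- ifelse(nn > 0, colSums(m, na.rm = TRUE) / (2 * nn), NA_real_)
  he <- 2 * p * (1 - p)
  ho <- ifelse(nn > 0, colSums(m == 1L, na.rm = TRUE) / nn, NA_real_)
  ok <- !is.na(he) & he > 0
  if (!any(ok)) {
    warning("all SNPs monomorphic in group; F_IS undefined")
    return(list(per_locus = numeric(0), mean = NA_real_))
  }
  f <- (he[ok] - ho[ok]) / he[ok]
  list(per_locus = f, mean = mean(f))
}

#' Private alleles per population or cluster
#'
#' An allele is private to a group iff it is observed in that group and in
#' no other group at the chosen level.
#'
#' @param gm a `genotype_matrix`.
#' @param popmap a `population_map`.
#' @param level `"population"` or `"cluster"`.
#' @return named integer vector of private-allele counts per group.
#' @export
private_alleles <- function(gm, popmap, level = c("population", "cluster")) {
  level <- match.arg(level)
  groups <- sample_groups(popmap, level)
  groups <- lapply(groups, intersect, rownames(gm$calls))
  groups <- groups[lengths(groups) > 0]
  if (length(groups) < 2) stop("need at least 2 groups for private alleles")
  # presence[g, snp, allele]: allele 1 = ref, 2 = alt
  has_ref <- vapply(groups, function(s) {
    m <- gm$calls[s, , drop = FALSE]
    colSums(m < 2L, na.rm = TRUE) > 0
  }, logical(ncol(gm$calls)))
  has_alt <- vapply(groups, function(s) {
    m <- gm$calls[s, , drop = FALSE]
    colSums(m > 0L, na.rm = TRUE) > 0
  }, logical(ncol(gm$calls)))
  if (is.null(dim(has_ref))) {
    has_ref <- matrix(has_ref, nrow = 1)
    has_alt <- matrix(has_alt, nrow = 1)
  }
  priv_ref <- has_ref & rowSums(has_ref) == 1
  priv_alt <- has_alt & rowSums(has_alt) == 1
  setNames(colSums(priv_ref) + colSums(priv_alt), names(groups))
}

#' Rarefied allelic richness
#'
#' Per SNP, the expected number of distinct alleles in a random draw of
#' `g` gene copies without replacement (hypergeometric rarefaction):
#' `A_R = sum_a (1 - choose(2n - n_a, g) / choose(2n, g))` where `n_a`
#' copies of allele `a` are observed among the `2n` non-missing gene
#' copies. SNPs with fewer than `g` gene copies are excluded.
#'
#' @inheritParams observed_heterozygosity
#' @param g rarefaction size in gene copies (>= 2).
#' @return list with `per_locus`, `mean`, and `g`.
#' @export
allelic_richness <- function(gm, samples, g) {
  if (g < 2) stop("rarefaction size g must be >= 2")
  m <- group_calls(gm, samples)
  alt <- colSums(m, na.rm = TRUE)
  genes <- 2 * colSums(!is.na(m))
  ok <- genes >= g
  ar <- vapply(which(ok), function(j) {
    counts <- c(genes[j] - alt[j], alt[j])
    counts <- counts[counts > 0]
    sum(1 - exp(lchoose(genes[j] - counts, g) - lchoose(genes[j], g)))
  }, numeric(1))
  list(per_locus = ar, mean = mean(ar), g = g)
}

#' Nucleotide diversity over variant sites
#'
#' Per SNP, `pi = n/(n-1) * (1 - sum p_i^2)` with `n` the number of
#' non-missing gene copies in the group (the average number of pairwise
#' differences at the site); the reported value is the mean over SNPs with
#' `n >= 2`.
#'
#' @inheritParams observed_heterozygosity
#' @return list with `per_locus` and `mean`.
#' @export
nucleotide_diversity <- function(gm, samples) {
  m <- group_calls(gm, samples)
  n <- 2 * colSums(!is.na(m))
  p <- ifelse(n > 0, colSums(m, na.rm = TRUE) / n, NA_real_)
  ok <- n >= 2
  pi_site <- (n[ok] / (n[ok] - 1)) * (1 - p[ok]^2 - (1 - p[ok])^2)
  list(per_locus = pi_site, mean = mean(pi_site))
}

# Weir-Cockerham variance components (a, b, c) for one biallelic SNP.
# n_i: diploid sample sizes, p_i: alt frequencies, h_i: het fractions.
wc_components <- function(n_i, p_i, h_i) {
  keep <- n_i > 0
  n_i <- n_i[keep]; p_i <- p_i[keep]; h_i <- h_i[keep]
  r <- length(n_i)
  if (r < 2) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  nbar <- mean(n_i)
  if (nbar <= 1) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

#' Weir-Cockerham F_ST
#'
#' Variance-components estimator of differentiation among populations:
#' per-SNP theta = a/(a+b+c) and the multilocus value as a ratio of sums
#' over SNPs, plus a pairwise-population multilocus F_ST matrix.
#'
#' @param gm a `genotype_matrix`.
#' @param popmap a `population_map` with >= 2 populations.
#' @param level group samples by `"population"` (default) or `"cluster"`.
#' @return list with `theta_locus`, `theta` (multilocus),
#'   and `pairwise` (matrix).
#' @export
wc_fst <- function(gm, popmap, level = "population") {
  groups <- sample_groups(popmap, level)
  groups <- lapply(groups, intersect, rownames(gm$calls))
  groups <- groups[lengths(groups) > 0]
  if (length(groups) < 2) stop("need >= 2 groups for F_ST")
  comp <- wc_fst_components(gm, groups)
  pair <- matrix(NA_real_, length(groups), length(groups),
                 dimnames = list(names(groups), names(groups)))
  diag(pair) <- 0
  for (i in seq_along(groups)[-1]) {
    for (j in seq_len(i - 1)) {
      cij <- wc_fst_components(gm, groups[c(i, j)])
      pair[i, j] <- pair[j, i] <- cij$theta
    }
  }
  list(theta_locus = comp$theta_locus, theta = comp$theta, pairwise = pair)
}

wc_fst_components <- function(gm, groups) {
  stats <- lapply(groups, function(s) {
    m <- gm$calls[s, , drop = FALSE]
    nn <- colSums(!is.na(m))
    list(n = nn,
         p = ifelse(nn > 0, colSums(m, na.rm = TRUE) / (2 * nn), NA_real_),
         h = ifelse(nn > 0, colSums(m == 1L, na.rm = TRUE) / nn, NA_real_))
  })
  nsnp <- ncol(gm$calls)
  abc <- t(vapply(seq_len(nsnp), function(j) {
    wc_components(vapply(stats, function(s) s$n[j], numeric(1)),
                  vapply(stats, function(s) s$p[j], numeric(1)),
                  vapply(stats, function(s) s$h[j], numeric(1)))
  }, numeric(3)))
  denom <- rowSums(abc)
  theta_locus <- ifelse(!is.na(denom) & denom != 0, abc[, 1] / denom, NA_real_)
  ok <- !is.na(denom)
  list(theta_locus = theta_locus,
       theta = sum(abc[ok, 1]) / sum(denom[ok]))
}

#' Nei (1972) standard genetic distance between populations
#'
#' `D = -ln(J_XY / sqrt(J_X * J_Y))` with identity sums accumulated over
#' all SNPs and both alleles from non-missing allele frequencies.
#'
#' @inheritParams wc_fst
#' @return symmetric distance matrix among populations.
#' @export
nei_distance <- function(gm, popmap, level = "population") {
  groups <- sample_groups(popmap, level)
  groups <- lapply(groups, intersect, rownames(gm$calls))
  groups <- groups[lengths(groups) > 0]
  freqs <- lapply(groups, function(s) {
    m <- gm$calls[s, , drop = FALSE]
    nn <- colSums(!is.na(m))
    ifelse(nn > 0, colSums(m, na.rm = TRUE) / (2 * nn), NA_real_)
  })
  k <- length(groups)
  d <- matrix(0, k, k, dimnames = list(names(groups), names(groups)))
  for (i in seq_len(k)[-1]) {
    for (j in seq_len(i - 1)) {
      x <- freqs[[i]]; y <- freqs[[j]]
      ok <- !is.na(x) & !is.na(y)
      jxy <- sum(x[ok] * y[ok] + (1 - x[ok]) * (1 - y[ok]))
      jx <- sum(x[ok]^2 + (1 - x[ok])^2)
      jy <- sum(y[ok]^2 + (1 - y[ok])^2)
      d[i, j] <- d[j, i] <- -log(jxy / sqrt(jx * jy))
    }
  }
  d
}

#' Mantel permutation test for matrix correlation
#'
#' Statistic: squared Pearson correlation of the lower-triangle entries of
#' the two matrices. Significance: rows and columns of the second matrix
#' are permuted jointly `n_perm` times and
#' `p = (1 + #{permuted R^2 >= observed}) / (n_perm + 1)`.
#'
#' @param m1,m2 symmetric matrices of identical dimension >= 3.
#' @param n_perm number of random permutations.
#' @param seed RNG seed (required, stored in the result).
#' @return list of class `mantel_result` with `r2`, `r`, `p`, `n_perm`,
#'   `seed`.
#' @export
mantel_test <- function(m1, m2, n_perm = 999, seed) {
  stopifnot(all(dim(m1) == dim(m2)), nrow(m1) >= 3)
  if (missing(seed)) stop("seed is required for a reproducible Mantel test")
  v1 <- m1[lower.tri(m1)]
  if (sd(v1) == 0 || sd(m2[lower.tri(m2)]) == 0) {
    stop("constant distance matrix: Mantel correlation undefined")
  }
  obs_r <- cor(v1, m2[lower.tri(m2)])
  obs <- obs_r^2
  set.seed(seed)
  n <- nrow(m1)
  ge <- 0L
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n)
    mp <- m2[idx, idx]
    if (cor(v1, mp[lower.tri(mp)])^2 >= obs) ge <- ge + 1L
  }
  structure(list(r2 = obs, r = obs_r, p = (1 + ge) / (n_perm + 1),
                 n_perm = n_perm, seed = seed),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: R^2 = %.3f (r = %.3f), p = %.3g (%d permutations, seed %s)\n",
              x$r2, x$r, x$p, x$n_perm, format(x$seed)))
  invisible(x)
}

#' Per-population and pooled-cluster diversity table
#'
#' Summarizes, for every population and for each pooled cluster: sample
#' size N, mean observed alleles per SNP (N_A), private alleles (P_A,
#' counted at the matching level), rarefied allelic richness (A_R),
#' observed and expected heterozygosity with their standard errors,
#' nucleotide diversity over variant sites, and F_IS.
#'
#' @param gm a `genotype_matrix`.
#' @param popmap a `population_map`.
#' @param g rarefaction size in gene copies; default is the smallest
#'   per-population minimum gene count over SNPs (at least 2).
#' @return data.frame, one row per population then per cluster.
#' @export
diversity_table <- function(gm, popmap, g = NULL) {
  make_rows <- function(groups, level) {
    pa <- if (length(groups) >= 2) {
      private_alleles(gm, popmap, level)
    } else {
      setNames(rep(NA_integer_, length(groups)), names(groups))
    }
    do.call(rbind, lapply(names(groups), function(gname) {
      s <- groups[[gname]]
      m <- gm$calls[s, , drop = FALSE]
      nn <- colSums(!is.na(m))
      n_alleles <- ifelse(nn == 0, NA_real_,
                          (colSums(m > 0, na.rm = TRUE) > 0) +
                          (colSums(m < 2, na.rm = TRUE) > 0))
      ho <- observed_heterozygosity(gm, s)
      he <- expected_heterozygosity(gm, s)
      fis <- suppressWarnings(inbreeding_coefficient(gm, s))
      pi <- nucleotide_diversity(gm, s)
      gg <- if (is.null(g)) max(2, min(2 * nn[nn > 0])) else g
      ar <- allelic_richness(gm, s, gg)
      data.frame(group = gname, level = level, N = length(s),
                 N_A = mean(n_alleles, na.rm = TRUE),
                 P_A = unname(pa[gname]), A_R = ar$mean,
                 H_O = ho$mean, H_O_se = ho$se,
                 H_E = he$mean, H_E_se = he$se,
                 pi = pi$mean, F_IS = fis$mean,
                 stringsAsFactors = FALSE)
    }))
  }
  pops <- lapply(sample_groups(popmap, "population"), intersect, rownames(gm$calls))
  cls <- lapply(sample_groups(popmap, "cluster"), intersect, rownames(gm$calls))
  out <- rbind(make_rows(pops[lengths(pops) > 0], "population"),
               make_rows(cls[lengths(cls) > 0], "cluster"))
  rownames(out) <- NULL
  out
}
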