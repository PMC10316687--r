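test_that("observed and expected heterozygosity match hand counts", {
  calls <- rbind(c(1L, 0L, 2L, NA),
                 c(1L, 0L, 1L, 1L),
                 c(1L, 2L, 0L, 1L),
                 c(1L, 0L, NA, 1L),
                 c(1L, 2L, 2L, 0L))
  gm <- tiny_gm(calls)
  s <- rownames(gm$calls)
  ho <- observed_heterozygosity(gm, s)
  expect_equal(unname(ho$per_locus), c(1, 0, 1 / 4, 3 / 4))
  expect_equal(ho$mean, mean(c(1, 0, 0.25, 0.75)))
  expect_equal(ho$se, sd(c(1, 0, 0.25, 0.75)) / 2)
  he <- expected_heterozygosity(gm, s)
  p <- c(5 / 10, 4 / 10, 5 / 8, 3 / 8)
  expect_equal(unname(he$per_locus), 2 * p * (1 - p))
  # p = 0.5 gives H_E = 0.5; monomorphic gives 0
  expect_equal(unname(he$per_locus[1]), 0.5)
  mono <- tiny_gm(matrix(0L, 4, 1))
  expect_equal(expected_heterozygosity(mono, rownames(mono$calls))$mean, 0)
})

test_that("F_IS is the mean of (He - Ho)/He over polymorphic loci", {
  # single locus with He = 0.5, Ho = 1 -> F = -1
  gm <- tiny_gm(matrix(1L, 6, 1))
  expect_equal(inbreeding_coefficient(gm, rownames(gm$calls))$mean, -1)
  # Ho == He at every locus -> 0 (construct p = 0.5, half hets)
  calls <- cbind(c(0L, 1L, 1L, 2L), c(2L, 1L, 1L, 0L))
  gm2 <- tiny_gm(calls)
  expect_equal(inbreeding_coefficient(gm2, rownames(gm2$calls))$mean, 0)
  # all-monomorphic group is flagged undefined
  mono <- tiny_gm(matrix(2L, 4, 2))
  expect_warning(res <- inbreeding_coefficient(mono, rownames(mono$calls)),
                 "undefined")
  expect_true(is.na(res$mean))
})

test_that("private alleles match an exhaustive allele scan", {
  pm <- population_map(data.frame(
    sample = sprintf("s%02d", 1:9),
    population = rep(c("A", "B", "C"), each = 3),
    cluster = rep(c("I", "I", "II"), each = 3)))
  calls <- matrix(0L, 9, 3, dimnames = list(pm$sample, NULL))
  calls[1, 1] <- 1L               # alt private to A
  calls[c(1, 4), 2] <- 1L         # alt shared by A and B
  calls[7:9, 3] <- 2L             # ref absent only in C -> alt shared w/ no one?
  gm <- tiny_gm(calls)
  pa <- private_alleles(gm, pm, "population")
  # brute force over groups x alleles
  brute <- sapply(sample_groups(pm, "population"), function(s) {
    other <- setdiff(pm$sample, s)
    n <- 0
    for (j in 1:3) {
      for (al in c("ref", "alt")) {
        ing <- if (al == "ref") any(gm$calls[s, j] < 2, na.rm = TRUE)
               else any(gm$calls[s, j] > 0, na.rm = TRUE)
        outg <- if (al == "ref") any(gm$calls[other, j] < 2, na.rm = TRUE)
                else any(gm$calls[other, j] > 0, na.rm = TRUE)
        if (ing && !outg) n <- n + 1
      }
    }
    n
  })
  expect_equal(pa, brute)
  expect_equal(unname(pa["A"]), 1L + 0L)   # SNP1 alt; SNP2 alt is shared
})

test_that("rarefied allelic richness equals the hypergeometric closed form", {
  # monomorphic locus: A_R = 1 for any g
  mono <- tiny_gm(matrix(0L, 10, 1))
  expect_equal(allelic_richness(mono, rownames(mono$calls), g = 4)$mean, 1)
  # singleton with g = 2n is always sampled: contribution 1
  calls <- matrix(0L, 5, 1); calls[1, 1] <- 1L
  gm <- tiny_gm(calls)
  expect_equal(allelic_richness(gm, rownames(gm$calls), g = 10)$mean, 2)
  # 2n = 20, counts {18, 2}, g = 10: direct combinatorial value
  calls <- matrix(0L, 10, 1); calls[1, 1] <- 2L
  gm <- tiny_gm(calls)
  expected <- (1 - choose(2, 10) / choose(20, 10)) +
    (1 - choose(18, 10) / choose(20, 10))
  expect_equal(allelic_richness(gm, rownames(gm$calls), g = 10)$mean, expected)
  expect_error(allelic_richness(gm, rownames(gm$calls), g = 1), ">= 2")
})

test_that("allelic richness is monotone non-decreasing in g", {
  set.seed(3)
  gm <- random_gm(12, 30, miss = 0)
  s <- rownames(gm$calls)
  ar <- vapply(seq(2, 24, by = 2), function(g) {
    allelic_richness(gm, s, g)$mean
  }, numeric(1))
  expect_true(all(diff(ar) >= -1e-12))
})

test_that("nucleotide diversity equals the all-pairs difference average", {
  calls <- rbind(c(0L, 1L), c(1L, 1L), c(2L, NA))
  gm <- tiny_gm(calls)
  pi <- nucleotide_diversity(gm, rownames(gm$calls))
  # brute force: expand gene copies, average pairwise differences
  brute_site <- function(g) {
    g <- g[!is.na(g)]
    genes <- unlist(lapply(g, function(x) c(rep(1, x), rep(0, 2 - x))))
    n <- length(genes)
    sum(outer(genes, genes, "!=")) / (n * (n - 1))
  }
  expect_equal(unname(pi$per_locus),
               c(brute_site(calls[, 1]), brute_site(calls[, 2])))
  # n = 2 genes, one of each allele -> 1; fixed site -> 0
  het1 <- tiny_gm(matrix(1L, 1, 1))
  expect_equal(nucleotide_diversity(het1, "s01")$mean, 1)
  fixed <- tiny_gm(matrix(2L, 3, 1))
  expect_equal(nucleotide_diversity(fixed, rownames(fixed$calls))$mean, 0)
})

test_that("H_E respects the 1 - 1/(2n) sample bound at every locus", {
  set.seed(5)
  for (rep in 1:5) {
    gm <- random_gm(8, 25)
    s <- rownames(gm$calls)
    he <- expected_heterozygosity(gm, s)
    m <- gm$calls[s, , drop = FALSE]
    n_genes <- 2 * colSums(!is.na(m))
    ok <- n_genes > 0
    expect_true(all(he$per_locus <= 1 - 1 / n_genes[ok] + 1e-12))
  }
})

# Weir-Cockerham theta coded independently (straight from the published
# variance-component algebra, scalar form) as the oracle
wc_oracle_locus <- function(counts_by_pop) {
  # counts_by_pop: list of genotype vectors (0/1/2, no NA)
  r <- length(counts_by_pop)
  n_i <- vapply(counts_by_pop, length, numeric(1))
  p_i <- vapply(counts_by_pop, function(g) sum(g) / (2 * length(g)), numeric(1))
  h_i <- vapply(counts_by_pop, function(g) mean(g == 1), numeric(1))
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  ssq <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- nbar / nc * (ssq - 1 / (nbar - 1) *
                      (pbar * (1 - pbar) - (r - 1) / r * ssq - hbar / 4))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * ssq -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, d = a + b + cc)
}

test_that("Weir-Cockerham theta matches the variance-component oracle", {
  g1 <- c(0L, 0L, 1L, 2L, 0L)
  g2 <- c(2L, 1L, 2L, 2L)
  g3 <- c(0L, 1L, 1L, 0L, 0L, 1L)
  gm <- tiny_gm(matrix(c(g1, g2, g3), ncol = 1))
  pm <- population_map(data.frame(
    sample = rownames(gm$calls),
    population = rep(c("A", "B", "C"), c(5, 4, 6)),
    cluster = rep(c("I", "I", "II"), c(5, 4, 6))))
  res <- wc_fst(gm, pm)
  o <- wc_oracle_locus(list(g1, g2, g3))
  expect_equal(unname(res$theta), unname(o["a"] / o["d"]))
  # multilocus = ratio of sums, bounded by per-locus extremes
  set.seed(9)
  gm2 <- random_gm(15, 20, miss = 0)
  pm2 <- population_map(data.frame(
    sample = rownames(gm2$calls),
    population = rep(c("A", "B", "C"), each = 5),
    cluster = rep(c("I", "I", "II"), each = 5)))
  res2 <- wc_fst(gm2, pm2)
  tl <- res2$theta_locus[!is.na(res2$theta_locus)]
  expect_gte(res2$theta, min(tl) - 1e-12)
  expect_lte(res2$theta, max(tl) + 1e-12)
})

test_that("fixed alternative alleles give theta near 1, identical pops near 0", {
  n <- 40
  fixed <- tiny_gm(matrix(rep(c(0L, 2L), each = n), ncol = 1))
  pm <- two_cluster_map(n, n)
  rownames(fixed$calls) <- pm$sample
  expect_gt(wc_fst(fixed, pm)$theta, 0.95)
  same <- tiny_gm(matrix(rep(c(0L, 1L, 1L, 2L), n / 2), ncol = 1))
  rownames(same$calls) <- pm$sample
  expect_lt(abs(wc_fst(same, pm)$theta), 0.05)
})

test_that("Nei (1972) distance follows the identity-sum formula", {
  pm <- two_cluster_map(4, 4)
  calls <- matrix(c(rep(0:1, 2), rep(1:2, 2),
                    rep(2L, 4), rep(0L, 4)), ncol = 2,
                  dimnames = list(pm$sample, NULL))
  gm <- tiny_gm(calls)
  d <- nei_distance(gm, pm, level = "cluster")
  px <- c(sum(calls[1:4, 1]) / 8, sum(calls[1:4, 2]) / 8)
  py <- c(sum(calls[5:8, 1]) / 8, sum(calls[5:8, 2]) / 8)
  jxy <- sum(px * py + (1 - px) * (1 - py))
  jx <- sum(px^2 + (1 - px)^2)
  jy <- sum(py^2 + (1 - py)^2)
  expect_equal(unname(d["I", "II"]), -log(jxy / sqrt(jx * jy)))
  expect_equal(unname(diag(d)), c(0, 0))
})

test_that("Mantel statistic is exact on identical matrices and enumerable at 4x4", {
  m <- as.matrix(dist(cbind(c(0, 1, 3, 6), 0)))
  res <- mantel_test(m, m, n_perm = 99, seed = 1)
  expect_equal(res$r2, 1)
  # exact enumeration over all 24 joint row/column permutations
  set.seed(2)
  g <- as.matrix(dist(runif(4)))
  res2 <- mantel_test(g, m, n_perm = 999, seed = 7)
  perms <- rbind(1:4)
  perms <- do.call(rbind, combinat_perms(4))
  obs <- cor(g[lower.tri(g)], m[lower.tri(m)])^2
  exact <- vapply(seq_len(nrow(perms)), function(i) {
    mp <- m[perms[i, ], perms[i, ]]
    cor(g[lower.tri(g)], mp[lower.tri(mp)])^2 >= obs
  }, logical(1))
  p_exact <- mean(exact)
  # permutation p within binomial error of the exact enumeration value
  se <- sqrt(p_exact * (1 - p_exact) / 1000)
  expect_lt(abs(res2$p - p_exact), 4 * se + 2 / 1000)
})

test_that("Mantel agrees with an independent implementation (vegan)", {
  skip_if_not_installed("vegan")
  set.seed(4)
  a <- as.matrix(dist(runif(8)))
  b <- as.matrix(dist(runif(8)))
  ours <- mantel_test(a, b, n_perm = 999, seed = 11)
  ref <- vegan::mantel(a, b, permutations = 999)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-10)
})

test_that("diversity table has coherent shapes and bounds", {
  set.seed(6)
  gm <- random_gm(16, 40)
  pm <- population_map(data.frame(
    sample = rownames(gm$calls),
    population = rep(c("A", "B", "C", "D"), each = 4),
    cluster = rep(c("I", "I", "II", "II"), each = 4)))
  tab <- diversity_table(gm, pm)
  expect_equal(nrow(tab), 6)   # 4 populations + 2 clusters
  expect_true(all(tab$H_O >= 0 & tab$H_O <= 1))
  expect_true(all(tab$H_E >= 0 & tab$H_E <= 1))
  expect_true(all(tab$N_A >= 1 & tab$N_A <= 2))
  expect_true(all(tab$P_A >= 0))
  expect_equal(tab$N[tab$level == "cluster"], c(8L, 8L))
})
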