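# Shared in-code fixtures for the test suite; everything is generated
# deterministically at test time.

tiny_gm <- function(calls, locus_id = NULL, site_index = NULL) {
  calls <- as.matrix(calls)
  if (is.null(rownames(calls))) {
    rownames(calls) <- sprintf("s%02d", seq_len(nrow(calls)))
  }
  ns <- ncol(calls)
  if (is.null(locus_id)) locus_id <- sprintf("L%03d", seq_len(ns))
  if (is.null(site_index)) site_index <- rep(0L, ns)
  genotype_matrix(calls, data.frame(locus_id = locus_id,
                                    site_index = as.integer(site_index),
                                    ref = rep("A", ns), alt = rep("C", ns),
                                    stringsAsFactors = FALSE))
}

two_cluster_map <- function(n1, n2, pops1 = 1, pops2 = 1) {
  s1 <- sprintf("c1_%03d", seq_len(n1))
  s2 <- sprintf("c2_%03d", seq_len(n2))
  population_map(data.frame(
    sample = c(s1, s2),
    population = c(paste0("A", rep_len(seq_len(pops1), n1)),
                   paste0("B", rep_len(seq_len(pops2), n2))),
    cluster = rep(c("I", "II"), c(n1, n2)),
    stringsAsFactors = FALSE))
}

combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  do.call(c, lapply(seq_len(n), function(i) {
    lapply(combinat_perms(n - 1), function(p) {
      c(i, (seq_len(n)[-i])[p])
    })
  }))
}

# random genotype matrix with missingness, for property-style loops
random_gm <- function(n_samples, n_snps, miss = 0.1) {
  calls <- matrix(sample(0:2, n_samples * n_snps, replace = TRUE),
                  nrow = n_samples)
  calls[runif(length(calls)) < miss] <- NA_integer_
  rownames(calls) <- sprintf("c%1d_%03d",
                             rep(1:2, c(ceiling(n_samples / 2),
                                        floor(n_samples / 2))),
                             c(seq_len(ceiling(n_samples / 2)),
                               seq_len(floor(n_samples / 2))))
  tiny_gm(calls)
}
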