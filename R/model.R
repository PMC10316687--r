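#' Two-population divergence model
#'
#' Parameterizes a two-deme history with three epochs of constant diploid
#' effective size and an optional migration window:
#' \itemize{
#'   \item epoch `[0, T1)` (present to T1): sizes `N_CLI_0`, `N_CLII_0`
#'   \item epoch `[T1, T2)`: sizes `N_CLI_1`, `N_CLII_1`
#'   \item before `T2`: the demes merge into one ancestral deme `N_ANC`
#' }
#' The four model ids select the migration window: model 1 no migration,
#' model 2 (isolation with migration) continuous migration from the
#' present back to `T2`, model 3 (ancient migration) `T1` to `T2`,
#' model 4 (secondary contact) present to `T1`.
#'
#' `Nm_I_II` is the forward-in-time number of migrant gene copies per
#' generation into cluster I from cluster II (and vice versa for
#' `Nm_II_I`); backward in time a lineage in deme i jumps to deme j at
#' rate `Nm_ij / (2 N_i(t))` (recipient-deme conversion).
#'
#' @param model_id integer 1-4.
#' @param N_CLI_0,N_CLII_0 diploid sizes, present to `T1`.
#' @param N_CLI_1,N_CLII_1 diploid sizes, `T1` to `T2`.
#' @param N_ANC ancestral diploid size before `T2`.
#' @param T1,T2 event times in generations, `0 < T1 < T2`.
#' @param Nm_I_II,Nm_II_I migrants per generation (ignored for model 1).
#' @return object of class `demographic_model`.
#' @export
demographic_model <- function(model_id, N_CLI_0, N_CLII_0, N_CLI_1, N_CLII_1,
                              N_ANC, T1, T2, Nm_I_II = 0, Nm_II_I = 0) {
  model_id <- as.integer(model_id)
  stopifnot(model_id %in% 1:4,
            N_CLI_0 > 0, N_CLII_0 > 0, N_CLI_1 > 0, N_CLII_1 > 0, N_ANC > 0,
            T1 > 0, T2 > T1, Nm_I_II >= 0, Nm_II_I >= 0)
  if (model_id == 1) Nm_I_II <- Nm_II_I <- 0
  structure(list(model_id = model_id,
                 N_CLI_0 = N_CLI_0, N_CLII_0 = N_CLII_0,
                 N_CLI_1 = N_CLI_1, N_CLII_1 = N_CLII_1, N_ANC = N_ANC,
                 T1 = T1, T2 = T2, Nm_I_II = Nm_I_II, Nm_II_I = Nm_II_I),
            class = "demographic_model")
}

# migration-window code for the C++ engine
model_window <- function(model_id) c(0L, 1L, 2L, 3L)[model_id]

model_par <- function(model) {
  c(model$N_CLI_0, model$N_CLII_0, model$N_CLI_1, model$N_CLII_1,
    model$N_ANC, model$T1, model$T2, model$Nm_I_II, model$Nm_II_I)
}

model_names <- c("no migration", "isolation with migration",
                 "ancient migration", "secondary contact")

#' @export
print.demographic_model <- function(x, ...) {
  cat("two-population divergence model ", x$model_id, " (",
      model_names[x$model_id], ")\n", sep = "")
  cat(sprintf("  sizes (diploid): CLI %g -> %g, CLII %g -> %g, ancestral %g\n",
              x$N_CLI_0, x$N_CLI_1, x$N_CLII_0, x$N_CLII_1, x$N_ANC))
  cat(sprintf("  events: T1 = %g, T2 = %g generations\n", x$T1, x$T2))
  if (x$model_id != 1) {
    cat(sprintf("  migration: Nm I<-II = %g, Nm II<-I = %g\n",
                x$Nm_I_II, x$Nm_II_I))
  }
  invisible(x)
}

#' Locus geometry and mutation rate
#'
#' @param n_loci number of independent loci (stacks).
#' @param length locus length in bp.
#' @param mu mutation rate per site per generation.
#' @return list of class `locus_spec`.
#' @export
locus_spec <- function(n_loci = 1753, length = 138, mu = 5.39e-8) {
  stopifnot(n_loci >= 1, length >= 1, mu > 0)
  structure(list(n_loci = as.integer(n_loci), length = length, mu = mu),
            class = "locus_spec")
}

#' Simulate one genealogy under a divergence model
#'
#' Event-driven structured coalescent: within-deme pairwise coalescence at
#' rate `choose(k,2)/(2N)`, per-lineage backward migration inside the
#' model's migration window, and a forced deme merger at `T2`. Returns an
#' ultrametric genealogy as parent pointers plus node times.
#'
#' @param model a `demographic_model`.
#' @param n1,n2 diploid sample sizes of clusters I and II.
#' @param seed RNG seed.
#' @return list with `parent` (1-based, root is `NA`), `time` (node times
#'   in generations; tips first, cluster I then II), `n_desc_1`/`n_desc_2`
#'   (gene copies descending from each node per cluster), `n_tips`
#'   (gene copies), `n_migrations`, `tmrca`, `total_length`.
#' @export
simulate_genealogy <- function(model, n1, n2, seed) {
  if (!missing(seed)) set.seed(seed)
  g <- cpp_sim_tree(model_par(model), model_window(model$model_id),
                    2L * n1, 2L * n2)
  parent <- g$parent + 1L
  parent[parent == 0L] <- NA_integer_
  list(parent = parent, time = g$time, n_desc_1 = g$n_desc_1,
       n_desc_2 = g$n_desc_2, n_tips = g$n_tips,
       n_migrations = g$n_migrations, tmrca = max(g$time),
       total_length = g$total_length)
}

#' Drop infinite-sites mutations on a genealogy
#'
#' Places `Poisson(total branch length * mu * length)` mutations uniformly
#' on the branches; each mutation defines a derived-allele membership over
#' the gene copies (infinite sites within the locus).
#'
#' @param genealogy output of [simulate_genealogy()].
#' @param length locus length in bp.
#' @param mu mutation rate per site per generation.
#' @param seed RNG seed.
#' @return 0/1 integer matrix (mutations x gene copies) of derived-allele
#'   carriers; zero rows when no mutation falls on the tree.
#' @export
drop_mutations <- function(genealogy, length, mu, seed) {
  if (!missing(seed)) set.seed(seed)
  parent <- genealogy$parent
  tm <- genealogy$time
  ntips <- genealogy$n_tips
  nn <- length(parent)
  bl <- ifelse(is.na(parent), 0, tm[parent] - tm)
  L <- sum(bl)
  nmut <- rpois(1, L * mu * length)
  memb <- matrix(0L, nrow = nmut, ncol = ntips)
  if (nmut == 0) return(memb)
  children <- split(seq_len(nn), factor(parent, levels = seq_len(nn)))
  branch <- sample.int(nn, nmut, replace = TRUE, prob = bl)
  for (s in seq_len(nmut)) {
    stack <- branch[s]
    while (length(stack)) {
      v <- stack[1]
      stack <- stack[-1]
      if (v <= ntips) memb[s, v] <- 1L else stack <- c(stack, children[[v]])
    }
  }
  memb
}

#' Monte-Carlo folded 2D SFS under a divergence model
#'
#' Two estimates are produced from `seed`-determined simulations:
#' \describe{
#'   \item{expected}{the normalized expected spectrum over polymorphic
#'     folded cells, computed from mean branch lengths classified by
#'     descendant counts over `n_reps` genealogies (no mutation noise);}
#'   \item{realized}{a folded count spectrum from `spec$n_loci` simulated
#'     loci with Poisson infinite-sites mutations.}
#' }
#'
#' @param model a `demographic_model`.
#' @param n1,n2 diploid sample sizes.
#' @param spec a [locus_spec()] (used for the realized spectrum).
#' @param n_reps number of genealogies for the expected spectrum.
#' @param seed RNG seed.
#' @param realized also simulate a realized count spectrum (default TRUE).
#' @return list with `expected` (probability matrix over folded cells),
#'   `lengths` (folded mean branch lengths), `total_length`, and
#'   `realized` (a `folded_2dsfs`, or NULL).
#' @export
simulate_sfs <- function(model, n1, n2, spec = locus_spec(), n_reps = 10000,
                         seed = 1, realized = TRUE) {
  set.seed(seed)
  par <- model_par(model)
  win <- model_window(model$model_id)
  bs <- cpp_branch_sfs(par, win, 2L * n1, 2L * n2, n_reps)
  lengths <- fold_2d(bs$lengths)
  expected <- lengths / sum(lengths)
  real <- NULL
  if (realized) {
    sim <- cpp_sim_loci(par, win, 2L * n1, 2L * n2, spec$n_loci,
                        spec$length, spec$mu)
    counts <- matrix(0, 2 * n1 + 1, 2 * n2 + 1)
    if (nrow(sim$membership) > 0) {
      i <- rowSums(sim$membership[, seq_len(2 * n1), drop = FALSE])
      j <- rowSums(sim$membership[, 2 * n1 + seq_len(2 * n2), drop = FALSE])
      for (s in seq_along(i)) {
        counts[i[s] + 1, j[s] + 1] <- counts[i[s] + 1, j[s] + 1] + 1
      }
    }
    real <- folded_2dsfs(fold_2d(counts), n1, n2,
                         total_sites = spec$n_loci * spec$length)
  }
  list(expected = expected, lengths = lengths,
       total_length = bs$total_length, realized = real)
}

#' Simulate a study-shaped genotype matrix under a divergence model
#'
#' Simulates `spec$n_loci` independent loci, pairs consecutive gene copies
#' into diploids, and assigns samples to the popmap's clusters (cluster I
#' receives the first `n1` diploids). Optional i.i.d. per-call missingness.
#'
#' @param model a `demographic_model`.
#' @param popmap a `population_map` with exactly two clusters; its samples
#'   define the output's sample ids and sizes.
#' @param spec a [locus_spec()].
#' @param missingness per-genotype missing probability; either a scalar or
#'   a per-sample vector (ordered as cluster I then cluster II samples).
#' @param seed RNG seed.
#' @return list with `gm` (a `genotype_matrix`) and `truth` (generating
#'   model, seed, per-SNP alternate-allele counts per cluster).
#' @export
simulate_genotypes <- function(model, popmap, spec = locus_spec(),
                               missingness = 0, seed = 1) {
  stopifnot(all(missingness >= 0), all(missingness <= 1))
  cls <- cluster_samples(popmap)
  if (length(cls) != 2) stop("demographic simulation requires exactly 2 clusters")
  n1 <- length(cls[[1]]); n2 <- length(cls[[2]])
  set.seed(seed)
  sim <- cpp_sim_loci(model_par(model), model_window(model$model_id),
                      2L * n1, 2L * n2, spec$n_loci, spec$length, spec$mu)
  memb <- sim$membership
  nsnp <- nrow(memb)
  samples <- c(cls[[1]], cls[[2]])
  if (nsnp == 0) {
    calls <- matrix(integer(0), nrow = n1 + n2, ncol = 0,
                    dimnames = list(samples, NULL))
    loci <- data.frame(locus_id = character(0), site_index = integer(0),
                       ref = character(0), alt = character(0))
    return(list(gm = genotype_matrix(calls, loci),
                truth = list(model = model, spec = spec, seed = seed,
                             alt_counts = NULL)))
  }
  # pair gene copies 2k-1, 2k into diploid k (copies are exchangeable)
  ndip <- n1 + n2
  calls <- matrix(0L, nrow = ndip, ncol = nsnp, dimnames = list(samples, NULL))
  for (k in seq_len(ndip)) {
    calls[k, ] <- memb[, 2 * k - 1] + memb[, 2 * k]
  }
  # within-locus site indices: distinct positions per stack
  site_index <- integer(nsnp)
  for (l in unique(sim$locus)) {
    idx <- which(sim$locus == l)
    if (length(idx) > spec$length) {
      stop("locus with more SNPs than sites; increase locus length")
    }
    site_index[idx] <- sort(sample.int(spec$length, length(idx))) - 1L
  }
  loci <- data.frame(locus_id = sprintf("L%05d", sim$locus),
                     site_index = site_index,
                     ref = "A", alt = "C", stringsAsFactors = FALSE)
  alt1 <- rowSums(memb[, seq_len(2 * n1), drop = FALSE])
  alt2 <- rowSums(memb[, 2 * n1 + seq_len(2 * n2), drop = FALSE])
  if (any(missingness > 0)) {
    rate <- rep_len(missingness, nrow(calls))
    drop <- matrix(rbinom(length(calls), 1L, rep(rate, times = ncol(calls))) == 1L,
                   nrow = nrow(calls))
    calls[drop] <- NA_integer_
  }
  list(gm = genotype_matrix(calls, loci),
       truth = list(model = model, spec = spec, seed = seed,
                    missingness = missingness,
                    alt_counts = data.frame(cluster1 = alt1, cluster2 = alt2)))
}
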