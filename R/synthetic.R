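#' Study-shaped dataset geometry
#'
#' Default geometry mirroring the two-cluster limestone-shrub system the
#' package's model family targets: 14 populations in two clusters of 106
#' and 81 diploid individuals, ~1753 stacks of 138 bp, and per-genotype
#' missingness. Population coordinates are laid out on a 1D southeast
#' transect (decimal degrees) so that isolation-by-distance tests have
#' geographic signal by construction.
#'
#' @param pop_sizes named integer vector of diploids per population.
#' @param clusters named character vector mapping population to cluster.
#' @param n_loci,locus_length,total_sites locus geometry.
#' @param missingness i.i.d. per-genotype missing probability.
#' @param mu mutation rate per site per generation.
#' @return list of class `study_shape`.
#' @export
study_shape <- function(
    pop_sizes = c(KY_H1 = 6, KY_B2 = 16, KY_B4 = 17, KY_B5 = 9, KY_B6 = 14,
                  KY_C2 = 22, KY_C5 = 15, CJ_S6 = 7,
                  CD_M1 = 7, CD_M3 = 8, CD_M4 = 23, CD_M5 = 10, CD_M6 = 7,
                  CD_M7 = 26),
    clusters = c(KY_H1 = "I", KY_B2 = "I", KY_B4 = "I", KY_B5 = "I",
                 KY_B6 = "I", KY_C2 = "I", KY_C5 = "I", CJ_S6 = "I",
                 CD_M1 = "II", CD_M3 = "II", CD_M4 = "II", CD_M5 = "II",
                 CD_M6 = "II", CD_M7 = "II"),
    n_loci = 1753, locus_length = 138, total_sites = 242107,
    missingness = 0.1, mu = 5.39e-8) {
  stopifnot(all(pop_sizes > 0), all(names(pop_sizes) %in% names(clusters)))
  pops <- names(pop_sizes)
  # 1D transect: cluster I populations to the northwest, cluster II to the
  # southeast, spacing a few km so within/between-cluster distances differ
  ord <- order(clusters[pops] != "I")
  pos <- seq_along(pops)
  coords <- data.frame(population = pops[ord],
                       lat = 37.20 - 0.03 * pos,
                       lon = 128.30 + 0.04 * pos,
                       stringsAsFactors = FALSE)
  structure(list(pop_sizes = pop_sizes, clusters = clusters[pops],
                 coords = coords, n_loci = as.integer(n_loci),
                 locus_length = locus_length,
                 total_sites = as.integer(total_sites),
                 missingness = missingness, mu = mu),
            class = "study_shape")
}

shape_popmap <- function(shape) {
  rows <- do.call(rbind, lapply(names(shape$pop_sizes), function(pop) {
    n <- shape$pop_sizes[[pop]]
    data.frame(sample = sprintf("%s_%02d", pop, seq_len(n)),
               population = pop, cluster = shape$clusters[[pop]],
               stringsAsFactors = FALSE)
  }))
  rows <- merge(rows, shape$coords, by = "population", sort = FALSE)
  rows <- rows[, c("sample", "population", "cluster", "lat", "lon")]
  # cluster I samples first, stable within population
  rows <- rows[order(rows$cluster, match(rows$population, names(shape$pop_sizes))), ]
  population_map(rows)
}

#' Generate a study-shaped synthetic dataset with known truth
#'
#' Simulates genotypes under a divergence model with the study geometry,
#' assigns diploids to populations (population labels within a cluster
#' are a partition of the simulated cluster sample; within-cluster
#' substructure is not simulated), applies i.i.d. missingness, and
#' optionally writes VCF + popmap + truth JSON to `dir`.
#'
#' @param shape a [study_shape()].
#' @param model a `demographic_model`; default the reference best model.
#' @param seed RNG seed; output is fully determined by it.
#' @param dir optional output directory.
#' @return list with `gm`, `popmap`, `truth`, and (when `dir` is given)
#'   `paths`.
#' @export
make_dataset <- function(shape = study_shape(), model = reference_model(),
                         seed = 1, dir = NULL) {
  popmap <- shape_popmap(shape)
  spec <- locus_spec(shape$n_loci, shape$locus_length, shape$mu)
  sim <- simulate_genotypes(model, popmap, spec = spec,
                            missingness = shape$missingness, seed = seed)
  truth <- c(sim$truth, list(shape_total_sites = shape$total_sites))
  out <- list(gm = sim$gm, popmap = popmap, truth = truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(vcf = file.path(dir, "synthetic.vcf"),
                  popmap = file.path(dir, "popmap.tsv"),
                  truth = file.path(dir, "truth.json"))
    write_vcf(sim$gm, paths$vcf)
    write_popmap(popmap, paths$popmap)
    tj <- list(model_id = model$model_id,
               parameters = unclass(model)[-1],
               seed = seed, n_loci = spec$n_loci,
               locus_length = spec$length, mu = spec$mu,
               missingness = shape$missingness,
               n_snps = ncol(sim$gm$calls),
               alt_counts = sim$truth$alt_counts)
    jsonlite::write_json(tj, paths$truth, auto_unbox = TRUE, digits = NA)
    out$paths <- paths
  }
  out
}

#' Curated small fixtures with known truth
#'
#' Deterministic datasets exercising each pipeline stage:
#' \describe{
#'   \item{toy3pop}{hand-built 3-population matrix with staged missingness
#'     for filter tests;}
#'   \item{island}{near-equilibrium two-deme model (long divergence,
#'     symmetric Nm = 1) where F_ST is expected near `1/(1 + 4Nm)`;}
#'   \item{panmictic}{single effective population split into two labelled
#'     groups, for null F_ST checks;}
#'   \item{recovery}{reference-MLE model-2 dataset at reduced geometry
#'     (300 loci) for fitting tests.}
#' }
#'
#' @param seed RNG seed.
#' @return named list of fixtures; simulated ones carry `gm`, `popmap`,
#'   `truth`.
#' @export
make_fixture_suite <- function(seed = 1) {
  # (a) 3-population toy with staged missingness
  samples <- sprintf("s%02d", 1:12)
  calls <- matrix(rep(c(0L, 1L, 2L, 1L), 12), nrow = 12, byrow = TRUE,
                  dimnames = list(samples, NULL))
  calls[1:4, 1] <- NA_integer_       # SNP 1 fully missing in pop A
  calls[5, 2] <- NA_integer_        # SNP 2 partially missing in pop B
  calls[, 4] <- c(rep(0L, 11), 1L)   # SNP 4 low MAF (1/24)
  loci <- data.frame(locus_id = c("La", "La", "Lb", "Lc"),
                     site_index = c(5L, 40L, 0L, 7L),
                     ref = "A", alt = "C", stringsAsFactors = FALSE)
  toy_popmap <- population_map(data.frame(
    sample = samples,
    population = rep(c("A", "B", "C"), each = 4),
    cluster = rep(c("I", "I", "II"), each = 4),
    stringsAsFactors = FALSE))
  toy <- list(gm = genotype_matrix(calls, loci), popmap = toy_popmap)

  two_pop_map <- function(n1, n2, prefix = "P") {
    population_map(data.frame(
      sample = c(sprintf("c1_%03d", seq_len(n1)), sprintf("c2_%03d", seq_len(n2))),
      population = rep(c(paste0(prefix, "1"), paste0(prefix, "2")), c(n1, n2)),
      cluster = rep(c("I", "II"), c(n1, n2)),
      stringsAsFactors = FALSE))
  }

  # (b) near-equilibrium island pair: N = 1000, Nm = 1 both ways, old split
  island_model <- demographic_model(2, 1000, 1000, 1000, 1000, 1000,
                                    T1 = 10000, T2 = 80000,
                                    Nm_I_II = 1, Nm_II_I = 1)
  island <- simulate_genotypes(island_model, two_pop_map(20, 20),
                               spec = locus_spec(500, 138, 1e-6),
                               seed = seed + 100)
  island$popmap <- two_pop_map(20, 20)
  island$model <- island_model

  # (c) panmictic null: tiny T1/T2, one ancestral size dominates history
  pan_model <- demographic_model(1, 5000, 5000, 5000, 5000, 5000,
                                 T1 = 1, T2 = 2)
  pan <- simulate_genotypes(pan_model, two_pop_map(20, 20),
                            spec = locus_spec(400, 138, 1e-6),
                            seed = seed + 200)
  pan$popmap <- two_pop_map(20, 20)
  pan$model <- pan_model

  # (d) reduced-geometry dataset at the reference best-model MLEs
  rec_shape <- study_shape(n_loci = 300, total_sites = 300 * 138,
                           missingness = 0)
  rec <- make_dataset(rec_shape, reference_model(), seed = seed + 300)
  rec$shape <- rec_shape

  list(toy3pop = toy, island = island, panmictic = pan, recovery = rec)
}
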