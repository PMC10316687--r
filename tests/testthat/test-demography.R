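toy_sfs <- function() {
  # 2 + 1 diploids -> 5 x 3 folded grid
  counts <- matrix(0, 5, 3)
  counts[2, 1] <- 10   # (1,0)
  counts[1, 2] <- 6    # (0,1)
  counts[2, 2] <- 4    # (1,1)
  folded_2dsfs(counts, 2, 1, total_sites = 1000)
}

test_that("the likelihood arithmetic matches a hand computation", {
  obs <- toy_sfs()
  El <- matrix(0, 5, 3)
  El[2, 1] <- 800; El[1, 2] <- 500; El[2, 2] <- 200; El[3, 1] <- 100
  total <- sum(El)
  mu <- 1e-5
  ll <- karstdemog:::ll_from_lengths(obs, El, total, mu,
                                     with_monomorphic = TRUE, n_sims = 1000)
  hand <- 10 * log10(mu * 800) + 6 * log10(mu * 500) + 4 * log10(mu * 200) +
    980 * log10(1 - mu * total)
  expect_equal(ll, hand)
  # normalized polymorphic mode
  ll2 <- karstdemog:::ll_from_lengths(obs, El, total, mu,
                                      with_monomorphic = FALSE, n_sims = 1000)
  hand2 <- 10 * log10(800 / total) + 6 * log10(500 / total) + 4 * log10(200 / total)
  expect_equal(ll2, hand2)
})

test_that("a single populated cell with certain probability has zero loglik", {
  counts <- matrix(0, 3, 3)
  counts[2, 1] <- 7
  obs <- folded_2dsfs(counts, 1, 1)
  El <- matrix(0, 3, 3); El[2, 1] <- 123
  expect_equal(karstdemog:::ll_from_lengths(obs, El, 123, 1e-6, FALSE, 100), 0)
})

test_that("observed cells with zero simulated mass are floored, not -Inf", {
  obs <- toy_sfs()
  El <- matrix(0, 5, 3)
  El[2, 1] <- 100   # only one cell simulated
  ll <- karstdemog:::ll_from_lengths(obs, El, 100, 1e-5, FALSE, n_sims = 100)
  expect_true(is.finite(ll))
  # unvisited observed cells are floored at p_poly / (n_branches * n_sims);
  # this 2+1-diploid grid has 2*(4+2)-2 = 10 branches per genealogy
  hand <- 10 * log10(1) + (6 + 4) * log10(1 / (10 * 100))
  expect_equal(ll, hand)
})

test_that("composite likelihood never exceeds the multinomial bound", {
  fx <- make_fixture_suite(seed = 2)
  rec <- fx$recovery
  sfs <- build_folded_2dsfs(rec$gm, rec$popmap, total_sites = 300 * 138)
  spec <- locus_spec(300, 138, 5.39e-8)
  bound <- loglik_bound(sfs)
  for (s in 1:3) {
    ll <- composite_loglik(sfs, reference_model(), spec, n_sims = 1000, seed = s)
    expect_lt(ll, bound)
  }
  # deterministic given (parameters, seed)
  expect_equal(composite_loglik(sfs, reference_model(), spec, 500, seed = 9),
               composite_loglik(sfs, reference_model(), spec, 500, seed = 9))
})

test_that("AIC arithmetic and model ranking behave as defined", {
  expect_equal(aic_from_ll(9, -21240), 2 * 9 - 2 * log(10) * (-21240))
  # equal likelihoods: the 7-parameter model wins by exactly 4 AIC units
  tab <- select_model(data.frame(model = c(1, 2), NP = c(7, 9),
                                 LL = c(-100, -100)))
  expect_equal(tab$model[1], 1)
  expect_equal(tab$delta_AIC[2], 4)
  expect_true(tab$best[1] && !tab$best[2])
})

test_that("derived quantities convert sizes and times as reported", {
  p <- c(N_CLI_0 = 5008, N_CLII_0 = 1766, N_CLI_1 = 9429, N_CLII_1 = 7598,
         N_ANC = 4480, T1 = 130, T2 = 24500, Nm_I_II = 1.777, Nm_II_I = 2.141)
  d <- derive_quantities(p, gen_time = 20)
  get <- function(q) d$estimate[d$quantity == q]
  expect_equal(round(get("N_CLI_0/N_CLI_1"), 3), 0.531)
  expect_equal(round(get("N_CLII_0/N_CLII_1"), 3), 0.232)
  expect_equal(round(get("N_CLI_1/N_ANC"), 3), 2.105)
  expect_equal(round(get("N_CLII_1/N_ANC"), 3), 1.696)
  expect_equal(get("T2_ka"), 490)
  expect_equal(get("T1_ka"), 2.6)
})

test_that("fitting machinery optimizes a small spectrum end to end", {
  # small, fast configuration: 8 + 6 diploids, modest locus count
  pm <- two_cluster_map(8, 6)
  truth <- demographic_model(2, 3000, 1500, 6000, 6000, 4000,
                             T1 = 500, T2 = 20000,
                             Nm_I_II = 1.5, Nm_II_I = 1.5)
  sim <- simulate_genotypes(truth, pm, locus_spec(400, 138, 1e-6), seed = 3)
  sfs <- build_folded_2dsfs(sim$gm, pm, total_sites = 400 * 138)
  spec <- locus_spec(400, 138, 1e-6)
  cfg <- fit_config(n_starts = 2, n_cycles = 5, n_sims = 400,
                    n_sims_final = 2000, seed = 4)
  fit <- fit_demography(sfs, 2, spec = spec, config = cfg)
  expect_s3_class(fit, "dm_fit")
  expect_equal(fit$np, 9L)
  expect_equal(fit$aic, aic_from_ll(9, fit$ll))
  expect_true(is.finite(fit$ll))
  expect_lt(fit$ll, loglik_bound(sfs))
  # LL from a start at the truth should not be beaten by much
  start <- matrix(c(3000, 1500, 6000, 6000, 4000, 500, 19500, 1.5, 1.5),
                  nrow = 1)
  fit_t <- fit_demography(sfs, 2, spec = spec,
                          config = fit_config(n_starts = 1, n_cycles = 2,
                                              n_sims = 400, n_sims_final = 2000,
                                              seed = 4),
                          starts = start)
  # very small search budget: allow generous slack against the truth start
  expect_gt(fit$ll, fit_t$ll - 200)

  # methods on the fitted object
  expect_named(coef(fit), c("N_CLI_0", "N_CLII_0", "N_CLI_1", "N_CLII_1",
                            "N_ANC", "T1", "T2", "Nm_I_II", "Nm_II_I"))
  expect_equal(AIC(fit), fit$aic, tolerance = 1e-10)
  p <- predict(fit, n_sims = 500, seed = 1)
  expect_equal(sum(p), 1, tolerance = 1e-8)
  r <- residuals(fit, n_sims = 500, seed = 1)
  expect_equal(dim(r), dim(sfs$counts))
  sims <- simulate(fit, nsim = 2, seed = 5)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "folded_2dsfs")
  expect_output(print(fit), "isolation with migration")
})

test_that("bootstrap ensembles give percentile intervals by definition", {
  pm <- two_cluster_map(6, 5)
  truth <- demographic_model(2, 2000, 2000, 2000, 2000, 2000,
                             T1 = 500, T2 = 10000, Nm_I_II = 1, Nm_II_I = 1)
  sim <- simulate_genotypes(truth, pm, locus_spec(150, 138, 1e-6), seed = 6)
  sfs <- build_folded_2dsfs(sim$gm, pm, total_sites = 150 * 138)
  spec <- locus_spec(150, 138, 1e-6)
  cfg <- fit_config(n_starts = 1, n_cycles = 2, n_sims = 300,
                    n_sims_final = 600, seed = 7)
  start <- matrix(c(2000, 2000, 2000, 2000, 2000, 500, 9500, 1, 1), nrow = 1)
  fit <- fit_demography(sfs, 2, spec = spec, config = cfg, starts = start)
  boot <- parametric_bootstrap(fit, n_reps = 4, config = cfg, seed = 8)
  expect_equal(nrow(boot$ensemble), 4)
  for (k in colnames(boot$ensemble)) {
    q <- quantile(boot$ensemble[, k], c(0.025, 0.975), names = FALSE)
    expect_equal(unname(boot$ci[k, ]), q)
  }
  d <- derive_quantities(boot)
  expect_true(all(c("lo", "hi", "significant") %in% names(d)))
  expect_equal(d$estimate[d$quantity == "T2_ka"],
               unname(fit$par["T2"]) * 20 / 1000)
})

test_that("degenerate single-replicate bootstrap collapses to a point", {
  pm <- two_cluster_map(4, 4)
  truth <- demographic_model(1, 2000, 2000, 2000, 2000, 2000, 500, 10000)
  sim <- simulate_genotypes(truth, pm, locus_spec(80, 138, 1e-6), seed = 9)
  sfs <- build_folded_2dsfs(sim$gm, pm, total_sites = 80 * 138)
  spec <- locus_spec(80, 138, 1e-6)
  cfg <- fit_config(n_starts = 1, n_cycles = 1, n_sims = 200,
                    n_sims_final = 200, seed = 10)
  start <- matrix(c(2000, 2000, 2000, 2000, 2000, 500, 9500), nrow = 1)
  fit <- fit_demography(sfs, 1, spec = spec, config = cfg, starts = start)
  expect_equal(fit$np, 7L)
  boot <- parametric_bootstrap(fit, n_reps = 1, config = cfg, seed = 11)
  expect_equal(unname(boot$ci[, "lo"]), unname(boot$ci[, "hi"]))
  expect_output(print(boot), "collapse")
})

test_that("reference fit summaries load with expected structure", {
  tab <- reference_fits("models")
  expect_equal(tab$model, 1:4)
  expect_equal(tab$NP, c(7, 9, 9, 9))
  ci <- reference_fits("ci")
  expect_true(all(ci$lo <= ci$mle & ci$mle <= ci$hi))
  m <- reference_model()
  expect_s3_class(m, "demographic_model")
  expect_equal(m$T2, 490 * 1000 / 20)
})
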