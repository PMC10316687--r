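#' Composite log10-likelihood of an observed folded 2D SFS
#'
#' Expected folded cell masses are obtained from `n_sims` simulated
#' genealogies as mean branch lengths classified by descendant counts
#' (deterministic given `seed`). With the monomorphic cell included
#' (default whenever the observed spectrum carries one), absolute cell
#' probabilities are `mu * E[length in cell]` per site and the monomorphic
#' probability is `1 - mu * E[total length]`, so the likelihood is
#' informative about the absolute time/size scale. Without it, cell
#' probabilities are normalized over polymorphic cells only. The
#' composite log-likelihood is `sum(m_cell * log10 p_cell)`; observed
#' cells with zero (or near-zero) simulated mass are floored at
#' `p_poly / (n_branches * n_sims)`, where `p_poly` is the total
#' polymorphic probability and `n_branches` the branch count of one
#' genealogy — the expected mass of a cell visited by a single typical
#' branch in one of the `n_sims` genealogies. The penalty shrinks with
#' the simulation count without diverging, keeping likelihoods evaluated
#' at different simulation sizes comparable.
#'
#' @param obs a `folded_2dsfs`.
#' @param model a `demographic_model`.
#' @param spec a [locus_spec()] (supplies `mu`).
#' @param n_sims number of simulated genealogies.
#' @param seed RNG seed; identical seeds give identical values (common
#'   random numbers).
#' @param with_monomorphic include the invariant-site term.
#' @param p_floor optional explicit probability floor.
#' @return composite log-likelihood in log10 units (scalar).
#' @export
composite_loglik <- function(obs, model, spec = locus_spec(), n_sims = 2000,
                             seed = 1,
                             with_monomorphic = obs$counts[1, 1] > 0,
                             p_floor = NULL) {
  stopifnot(inherits(obs, "folded_2dsfs"), inherits(model, "demographic_model"))
  set.seed(seed)
  bs <- cpp_branch_sfs(model_par(model), model_window(model$model_id),
                       2L * obs$n1, 2L * obs$n2, n_sims)
  ll_from_lengths(obs, fold_2d(bs$lengths), bs$total_length, spec$mu,
                  with_monomorphic, n_sims, p_floor)
}

ll_from_lengths <- function(obs, El, total_len, mu, with_monomorphic,
                            n_sims, p_floor = NULL) {
  m <- obs$counts
  mono <- m[1, 1]
  m[1, 1] <- 0
  if (with_monomorphic) {
    p <- mu * El
    p_mono <- 1 - mu * total_len
    if (p_mono <= 0) return(-Inf)
    p_poly <- mu * total_len
  } else {
    p <- El / total_len
    p_poly <- 1
  }
  if (is.null(p_floor)) {
    # "one typical branch in one genealogy" scale: a cell left unvisited
    # by n_sims genealogies of 2(n1g + n2g) - 2 branches has expected mass
    # below about total/(n_branches * n_sims)
    n_branches <- 2 * (2 * obs$n1 + 2 * obs$n2) - 2
    p_floor <- p_poly / (n_branches * n_sims)
  }
  sel <- m > 0
  ll <- sum(m[sel] * log10(pmax(p[sel], p_floor)))
  if (with_monomorphic && mono > 0) ll <- ll + mono * log10(p_mono)
  ll
}

#' Multinomial saturation bound of the composite log-likelihood
#'
#' `sum(m * log10(m / M))` over occupied cells — the maximum any model can
#' reach on the observed spectrum.
#'
#' @param obs a `folded_2dsfs`.
#' @param with_monomorphic include the monomorphic cell.
#' @return log10 bound (scalar).
#' @export
loglik_bound <- function(obs, with_monomorphic = obs$counts[1, 1] > 0) {
  m <- obs$counts
  if (!with_monomorphic) m[1, 1] <- 0
  m <- m[m > 0]
  sum(m * log10(m / sum(m)))
}

#' Fitting configuration
#'
#' Controls the maximum composite-likelihood search: number of random
#' log-uniform starting points, number of cyclic conditional-maximization
#' (ECM) cycles, coalescent simulations per likelihood evaluation, and
#' search ranges. Within a cycle all evaluations share one RNG seed
#' (common random numbers), so each univariate line search moves on a
#' deterministic surface.
#'
#' @param n_starts random starting values.
#' @param n_cycles ECM optimization cycles per start.
#' @param n_sims coalescent simulations per likelihood evaluation in the
#'   first third of the cycles; the count doubles in the middle third and
#'   quadruples in the final third (simulated annealing of the Monte-Carlo
#'   precision, so late cycles resolve likelihood differences that early
#'   exploration does not need to).
#' @param n_sims_final simulations for the final comparison of candidate
#'   optima (default `10 * n_sims`); the composite likelihood has
#'   appreciable Monte-Carlo spread at desk-scale `n_sims`, so the winner
#'   among starts is decided under a common, much larger simulation
#'   (default `25 * n_sims`).
#' @param seed base RNG seed.
#' @param grid_points grid size of each conditional (per-parameter) line
#'   search over the parameter's full range, on the log10 scale.
#' @param refine_steps bisection refinements around the grid winner.
#' @param size_range,time_range,mig_range log-uniform search ranges for
#'   diploid sizes, event times (generations; `T2 = T1 + dT` keeps
#'   `T1 < T2`), and migrant counts.
#' @return list of class `fit_config`.
#' @export
fit_config <- function(n_starts = 5, n_cycles = 10, n_sims = 2000,
                       n_sims_final = NULL, seed = 1, grid_points = 7,
                       refine_steps = 3,
                       size_range = c(1e2, 1e6), time_range = c(1e2, 1e7),
                       mig_range = c(1e-2, 1e2)) {
  stopifnot(n_starts >= 1, n_cycles >= 1, n_sims >= 1, grid_points >= 3,
            all(size_range > 0), all(time_range > 0), all(mig_range > 0))
  if (is.null(n_sims_final)) n_sims_final <- 25L * n_sims
  structure(list(n_starts = as.integer(n_starts),
                 n_cycles = as.integer(n_cycles),
                 n_sims = as.integer(n_sims),
                 n_sims_final = as.integer(n_sims_final),
                 seed = as.integer(seed),
                 grid_points = as.integer(grid_points),
                 refine_steps = as.integer(refine_steps),
                 size_range = size_range, time_range = time_range,
                 mig_range = mig_range),
            class = "fit_config")
}

# parameter block layout on the log10 scale; T2 is reparameterized as
# T1 + dT so the T1 < T2 invariant holds throughout the search
fit_par_names <- function(model_id) {
  nm <- c("N_CLI_0", "N_CLII_0", "N_CLI_1", "N_CLII_1", "N_ANC", "T1", "dT")
  if (model_id != 1) nm <- c(nm, "Nm_I_II", "Nm_II_I")
  nm
}

theta_ranges <- function(model_id, config) {
  lo <- c(rep(log10(config$size_range[1]), 5), rep(log10(config$time_range[1]), 2))
  hi <- c(rep(log10(config$size_range[2]), 5), rep(log10(config$time_range[2]), 2))
  if (model_id != 1) {
    lo <- c(lo, rep(log10(config$mig_range[1]), 2))
    hi <- c(hi, rep(log10(config$mig_range[2]), 2))
  }
  list(lo = lo, hi = hi)
}

theta_to_model <- function(theta, model_id) {
  v <- unname(10^theta)
  demographic_model(model_id, N_CLI_0 = v[1], N_CLII_0 = v[2],
                    N_CLI_1 = v[3], N_CLII_1 = v[4], N_ANC = v[5],
                    T1 = v[6], T2 = v[6] + v[7],
                    Nm_I_II = if (model_id == 1) 0 else v[8],
                    Nm_II_I = if (model_id == 1) 0 else v[9])
}

model_to_theta <- function(model) {
  th <- log10(c(model$N_CLI_0, model$N_CLII_0, model$N_CLI_1, model$N_CLII_1,
                model$N_ANC, model$T1, model$T2 - model$T1))
  if (model$model_id != 1) th <- c(th, log10(pmax(model$Nm_I_II, 1e-10)),
                                   log10(pmax(model$Nm_II_I, 1e-10)))
  setNames(th, fit_par_names(model$model_id))
}

#' Fit a divergence model to an observed folded 2D SFS
#'
#' Maximum composite-likelihood estimation: from each starting point
#' (drawn log-uniformly from the configured ranges, unless `starts` is
#' given), parameters are optimized by cyclic univariate line search on
#' the log10 scale — one pass over all parameters is one ECM cycle — with
#' common random numbers within a cycle. The best start under a common
#' final evaluation is returned.
#'
#' @param obs a `folded_2dsfs`.
#' @param model_id integer 1-4 (see [demographic_model()]).
#' @param spec a [locus_spec()]; `mu` scales the invariant-site term and
#'   `n_loci`/`length` define the geometry used by [simulate.dm_fit()] and
#'   [parametric_bootstrap()].
#' @param config a [fit_config()].
#' @param with_monomorphic include the invariant-site likelihood term.
#' @param starts optional matrix of starting values on the natural scale
#'   (rows = starts, columns = [fit_par_names()] with `dT = T2 - T1`).
#' @param verbose print per-cycle progress.
#' @return object of class `dm_fit` with the MLE `demographic_model`,
#'   `par` (named MLE vector including `T2`), `ll` (log10), `np`, `aic`,
#'   and the per-cycle likelihood `trace`.
#' @export
fit_demography <- function(obs, model_id, spec = locus_spec(),
                           config = fit_config(),
                           with_monomorphic = obs$counts[1, 1] > 0,
                           starts = NULL, verbose = FALSE) {
  stopifnot(inherits(obs, "folded_2dsfs"), model_id %in% 1:4)
  model_id <- as.integer(model_id)
  rng <- theta_ranges(model_id, config)
  npar <- length(rng$lo)
  n1g <- 2L * obs$n1; n2g <- 2L * obs$n2
  win <- model_window(model_id)

  ll_theta <- function(theta, seed, n_sims) {
    mod <- theta_to_model(theta, model_id)
    set.seed(seed)
    bs <- cpp_branch_sfs(model_par(mod), win, n1g, n2g, n_sims)
    ll_from_lengths(obs, fold_2d(bs$lengths), bs$total_length, spec$mu,
                    with_monomorphic, n_sims)
  }

  if (is.null(starts)) {
    set.seed(config$seed)
    starts_theta <- t(vapply(seq_len(config$n_starts), function(s) {
      rng$lo + stats::runif(npar) * (rng$hi - rng$lo)
    }, numeric(npar)))
  } else {
    starts_theta <- log10(as.matrix(starts))
  }
  n_starts <- nrow(starts_theta)

  trace <- matrix(NA_real_, nrow = config$n_cycles, ncol = n_starts)
  candidates <- list()
  for (s in seq_len(n_starts)) {
    theta <- pmin(pmax(starts_theta[s, ], rng$lo), rng$hi)
    for (cyc in seq_len(config$n_cycles)) {
      cseed <- config$seed + 7919L * s + 104729L * cyc
      n_sims_cyc <- config$n_sims *
        2L^min(2L, (3L * (cyc - 1L)) %/% config$n_cycles)
      f <- ll_theta(theta, cseed, n_sims_cyc)
      for (k in seq_len(npar)) {
        # conditional maximization over the parameter's full range: a
        # coarse grid (so plateaus and distant basins are both seen),
        # then bisection refinement around the grid winner
        grid <- seq(rng$lo[k], rng$hi[k], length.out = config$grid_points)
        for (g in grid) {
          cand <- theta
          cand[k] <- g
          f2 <- ll_theta(cand, cseed, n_sims_cyc)
          if (is.finite(f2) && f2 > f) {
            theta <- cand
            f <- f2
          }
        }
        delta <- (rng$hi[k] - rng$lo[k]) / (config$grid_points - 1) / 2
        for (it in seq_len(config$refine_steps)) {
          for (dir in c(1, -1)) {
            cand <- theta
            cand[k] <- min(max(cand[k] + dir * delta, rng$lo[k]), rng$hi[k])
            if (cand[k] == theta[k]) next
            f2 <- ll_theta(cand, cseed, n_sims_cyc)
            if (is.finite(f2) && f2 > f) {
              theta <- cand
              f <- f2
              break
            }
          }
          delta <- delta / 2
        }
      }
      trace[cyc, s] <- f
      # late-cycle iterates are all candidate optima: per-cycle reseeding
      # makes the endpoint wander on Monte-Carlo noise
      if (cyc > config$n_cycles - 3) candidates <- c(candidates, list(theta))
      if (verbose) {
        message(sprintf("start %d cycle %d: LL10 = %.3f", s, cyc, f))
      }
    }
  }
  candidates <- unique(candidates)
  # two-stage final selection under common random numbers: screen every
  # candidate at n_sims_final, then separate the leaders at 4x precision
  # (cross-region likelihood differences are of the same order as the
  # Monte-Carlo spread of a single desk-scale evaluation)
  screen_ll <- vapply(candidates, function(th) {
    ll_theta(th, config$seed, config$n_sims_final)
  }, numeric(1))
  if (all(!is.finite(screen_ll))) {
    stop("non-finite likelihood at every start; widen the search ranges")
  }
  top <- order(screen_ll, decreasing = TRUE)[seq_len(min(3, length(candidates)))]
  final_ll <- vapply(top, function(i) {
    ll_theta(candidates[[i]], config$seed + 1L, 4L * config$n_sims_final)
  }, numeric(1))
  best <- top[which.max(final_ll)]
  theta <- candidates[[best]]
  final_ll <- max(final_ll)
  mod <- theta_to_model(theta, model_id)
  np <- if (model_id == 1) 7L else 9L
  ll <- final_ll
  par <- c(N_CLI_0 = mod$N_CLI_0, N_CLII_0 = mod$N_CLII_0,
           N_CLI_1 = mod$N_CLI_1, N_CLII_1 = mod$N_CLII_1,
           N_ANC = mod$N_ANC, T1 = mod$T1, T2 = mod$T2)
  if (model_id != 1) par <- c(par, Nm_I_II = mod$Nm_I_II, Nm_II_I = mod$Nm_II_I)
  structure(list(model_id = model_id, model = mod, par = par, ll = ll,
                 np = np, aic = aic_from_ll(np, ll), trace = trace,
                 best_candidate = best, config = config, spec = spec,
                 with_monomorphic = with_monomorphic,
                 obs = obs),
            class = "dm_fit")
}

#' AIC from a log10 composite likelihood
#'
#' `AIC = 2 * NP - 2 * ln(10) * LL` for a log-likelihood reported on the
#' log10 scale.
#'
#' @param np number of free parameters.
#' @param ll10 maximized log10 likelihood.
#' @return numeric AIC.
#' @export
aic_from_ll <- function(np, ll10) 2 * np - 2 * log(10) * ll10

#' Rank fitted models by AIC
#'
#' @param fits a list of `dm_fit` objects, or a data.frame with columns
#'   `model`, `NP` and `LL` (log10).
#' @return data.frame sorted by ascending AIC with `delta_AIC` and a
#'   logical `best` flag.
#' @export
select_model <- function(fits) {
  if (is.data.frame(fits)) {
    tab <- data.frame(model = fits$model, NP = fits$NP, LL = fits$LL)
  } else {
    stopifnot(length(fits) >= 2)
    tab <- data.frame(model = vapply(fits, function(f) f$model_id, numeric(1)),
                      NP = vapply(fits, function(f) f$np, numeric(1)),
                      LL = vapply(fits, function(f) f$ll, numeric(1)))
  }
  tab$AIC <- aic_from_ll(tab$NP, tab$LL)
  tab <- tab[order(tab$AIC), ]
  tab$delta_AIC <- tab$AIC - tab$AIC[1]
  tab$best <- seq_len(nrow(tab)) == 1
  rownames(tab) <- NULL
  tab
}

#' @export
print.dm_fit <- function(x, ...) {
  cat("divergence-model fit (model ", x$model_id, ": ",
      model_names[x$model_id], ")\n", sep = "")
  cat(sprintf("  LL (log10) = %.2f, NP = %d, AIC = %.1f\n", x$ll, x$np, x$aic))
  print(round(x$par, 3))
  invisible(x)
}

#' @export
summary.dm_fit <- function(object, gen_time = 20, ...) {
  out <- list(fit = object,
              derived = derive_quantities(object, gen_time = gen_time),
              bound = loglik_bound(object$obs, object$with_monomorphic))
  class(out) <- "summary.dm_fit"
  out
}

#' @export
print.summary.dm_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  saturation bound (log10) = %.2f\n", x$bound))
  cat("derived quantities:\n")
  print(x$derived, digits = 4)
  invisible(x)
}

#' @export
coef.dm_fit <- function(object, ...) object$par

#' @export
logLik.dm_fit <- function(object, ...) {
  structure(object$ll * log(10), df = object$np,
            nobs = sum(object$obs$counts), class = "logLik")
}

#' Expected folded SFS probabilities at the fitted parameters
#'
#' @param object a `dm_fit`.
#' @param n_sims simulated genealogies.
#' @param seed RNG seed.
#' @param ... unused.
#' @return matrix of cell probabilities on the folded grid; the `(0,0)`
#'   entry is the monomorphic probability when the fit included it.
#' @export
predict.dm_fit <- function(object, n_sims = 10000, seed = 1, ...) {
  set.seed(seed)
  bs <- cpp_branch_sfs(model_par(object$model),
                       model_window(object$model_id),
                       2L * object$obs$n1, 2L * object$obs$n2, n_sims)
  El <- fold_2d(bs$lengths)
  if (object$with_monomorphic) {
    p <- object$spec$mu * El
    p[1, 1] <- 1 - object$spec$mu * bs$total_length
  } else {
    p <- El / bs$total_length
  }
  p
}

#' Pearson residuals of the fitted spectrum
#'
#' `(m - M p) / sqrt(M p (1 - p))` over occupied cells, with `M` the total
#' observed count in the cells entering the likelihood.
#'
#' @param object a `dm_fit`.
#' @param n_sims,seed passed to [predict.dm_fit()].
#' @param ... unused.
#' @return matrix of residuals (NA where the expected probability is 0).
#' @export
residuals.dm_fit <- function(object, n_sims = 10000, seed = 1, ...) {
  p <- predict(object, n_sims = n_sims, seed = seed)
  m <- object$obs$counts
  if (!object$with_monomorphic) m[1, 1] <- 0
  M <- sum(m)
  r <- (m - M * p) / sqrt(M * p * (1 - p))
  r[p <= 0 | p >= 1] <- NA_real_
  r
}

#' Simulate datasets at the fitted parameters
#'
#' Parametric simulation with the fit's locus geometry; used by the
#' parametric bootstrap.
#'
#' @param object a `dm_fit`.
#' @param nsim number of datasets.
#' @param seed RNG seed.
#' @param ... unused.
#' @return list of `folded_2dsfs` objects.
#' @export
simulate.dm_fit <- function(object, nsim = 1, seed = 1, ...) {
  spec <- object$spec
  lapply(seq_len(nsim), function(r) {
    sim <- simulate_sfs(object$model, object$obs$n1, object$obs$n2,
                        spec = spec, n_reps = 1, seed = seed + r - 1,
                        realized = TRUE)
    sim$realized
  })
}

#' Observed vs fitted marginal spectra
#'
#' Plots the folded marginal spectra of the observed SFS against the
#' fitted expectation, per cluster, on a log count scale.
#'
#' @param x a `dm_fit`.
#' @param n_sims,seed passed to [predict.dm_fit()].
#' @param ... further arguments to [graphics::matplot()].
#' @export
plot.dm_fit <- function(x, n_sims = 10000, seed = 1, ...) {
  p <- predict(x, n_sims = n_sims, seed = seed)
  m <- x$obs$counts
  mono <- m[1, 1]
  m[1, 1] <- 0
  M <- sum(m) + if (x$with_monomorphic) mono else 0
  e <- p * M
  e[1, 1] <- 0
  obs_m <- sfs_marginals(x$obs)
  exp1 <- fold_1d(rowSums(e))
  exp2 <- fold_1d(colSums(e))
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  for (side in 1:2) {
    o <- if (side == 1) obs_m$cluster1 else obs_m$cluster2
    ee <- if (side == 1) exp1 else exp2
    graphics::matplot(seq_along(o) - 1, cbind(o, ee), type = "b",
                      pch = c(1, 2), lty = c(1, 2), log = "y",
                      xlab = "minor-allele copies",
                      ylab = "SNP count",
                      main = paste0("cluster ", c("I", "II")[side]), ...)
    graphics::legend("topright", legend = c("observed", "fitted"),
                     pch = c(1, 2), lty = c(1, 2), bty = "n")
  }
  invisible(x)
}
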