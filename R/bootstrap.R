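#' Parametric-bootstrap confidence intervals for a fitted model
#'
#' Simulates `n_reps` datasets at the maximum-likelihood estimates with
#' the fit's locus geometry, refits each replicate starting from the MLE
#' (with a reduced number of ECM cycles), and derives 95% percentile
#' intervals from the ensemble of re-estimated parameter vectors.
#'
#' @param fit a `dm_fit`.
#' @param n_reps bootstrap replicates.
#' @param config optional [fit_config()] for the refits; defaults to the
#'   fit's configuration with one start (the MLE) and 15 ECM cycles.
#' @param seed base seed; replicate r uses `seed + r`.
#' @return object of class `dm_boot` with the `ensemble` matrix
#'   (replicates x parameters), percentile `ci`, and per-replicate seeds.
#' @export
parametric_bootstrap <- function(fit, n_reps = 100, config = NULL, seed = 1) {
  stopifnot(inherits(fit, "dm_fit"), n_reps >= 1)
  if (is.null(config)) {
    config <- fit$config
    config$n_starts <- 1L
    config$n_cycles <- 15L
  }
  spec <- fit$spec
  start <- matrix(10^model_to_theta(fit$model), nrow = 1)
  colnames(start) <- fit_par_names(fit$model_id)
  seeds <- seed + seq_len(n_reps)
  reps <- vector("list", n_reps)
  failed <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    sim <- simulate_sfs(fit$model, fit$obs$n1, fit$obs$n2, spec = spec,
                        n_reps = 1, seed = seeds[r], realized = TRUE)
    obs_r <- sim$realized
    cfg_r <- config
    cfg_r$seed <- as.integer(seeds[r] %% .Machine$integer.max)
    res <- tryCatch(
      fit_demography(obs_r, fit$model_id, spec = spec, config = cfg_r,
                     with_monomorphic = fit$with_monomorphic, starts = start),
      error = function(e) NULL)
    if (is.null(res)) {
      failed[r] <- TRUE
    } else {
      reps[[r]] <- res$par
    }
  }
  if (any(failed)) {
    warning(sum(failed), " bootstrap replicate(s) failed to converge and were excluded")
  }
  ens <- do.call(rbind, reps[!failed])
  ci <- t(apply(ens, 2, quantile, probs = c(0.025, 0.975), names = FALSE))
  colnames(ci) <- c("lo", "hi")
  structure(list(ensemble = ens, ci = ci, mle = fit$par,
                 seeds = seeds[!failed], n_failed = sum(failed), fit = fit),
            class = "dm_boot")
}

#' @export
print.dm_boot <- function(x, ...) {
  cat("parametric bootstrap:", nrow(x$ensemble), "replicates")
  if (x$n_failed > 0) cat(" (", x$n_failed, " failed)", sep = "")
  cat("\n")
  tab <- cbind(MLE = x$mle, x$ci)
  print(round(tab, 3))
  if (nrow(x$ensemble) == 1) {
    cat("note: single replicate; intervals collapse to a point\n")
  }
  invisible(x)
}

#' @export
confint.dm_boot <- function(object, parm, level = 0.95, ...) {
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  ci <- t(apply(object$ensemble, 2, quantile, probs = probs, names = FALSE))
  colnames(ci) <- paste0(100 * probs, "%")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Derived demographic quantities
#'
#' Size-change ratios (`N_X_0/N_X_1`, `N_X_1/N_ANC`), event times in
#' thousands of years (ka) via the generation time, and migrant counts.
#' For a bootstrap ensemble the quantities are computed per replicate and
#' summarized as 95% percentile intervals, with significance flags set
#' when a ratio's (or Nm's) interval excludes 1.0.
#'
#' @param x a `dm_boot`, a `dm_fit`, or a named parameter vector with
#'   entries `N_CLI_0`, `N_CLII_0`, `N_CLI_1`, `N_CLII_1`, `N_ANC`, `T1`,
#'   `T2` (generations) and optionally `Nm_I_II`, `Nm_II_I`.
#' @param gen_time years per generation used for the ka conversion.
#' @return data.frame with columns `quantity`, `estimate`, and (for
#'   ensembles) `lo`, `hi`, `significant`.
#' @export
derive_quantities <- function(x, gen_time = 20) {
  derive_one <- function(p) {
    out <- c(`N_CLI_0/N_CLI_1` = unname(p["N_CLI_0"] / p["N_CLI_1"]),
             `N_CLII_0/N_CLII_1` = unname(p["N_CLII_0"] / p["N_CLII_1"]),
             `N_CLI_1/N_ANC` = unname(p["N_CLI_1"] / p["N_ANC"]),
             `N_CLII_1/N_ANC` = unname(p["N_CLII_1"] / p["N_ANC"]),
             T1_ka = unname(p["T1"] * gen_time / 1000),
             T2_ka = unname(p["T2"] * gen_time / 1000))
    if ("Nm_I_II" %in% names(p)) {
      out <- c(out, Nm_I_II = unname(p["Nm_I_II"]),
               Nm_II_I = unname(p["Nm_II_I"]))
    }
    out
  }
  if (inherits(x, "dm_boot")) {
    est <- derive_one(x$mle)
    reps <- t(apply(x$ensemble, 1, derive_one))
    ci <- t(apply(reps, 2, quantile, probs = c(0.025, 0.975), names = FALSE))
    flag_names <- c("N_CLI_0/N_CLI_1", "N_CLII_0/N_CLII_1",
                    "N_CLI_1/N_ANC", "N_CLII_1/N_ANC", "Nm_I_II", "Nm_II_I")
    sig <- ifelse(names(est) %in% flag_names,
                  ci[, 1] > 1 | ci[, 2] < 1, NA)
    data.frame(quantity = names(est), estimate = unname(est),
               lo = ci[, 1], hi = ci[, 2], significant = sig,
               row.names = NULL, stringsAsFactors = FALSE)
  } else {
    p <- if (inherits(x, "dm_fit")) x$par else x
    est <- derive_one(p)
    data.frame(quantity = names(est), estimate = unname(est),
               row.names = NULL, stringsAsFactors = FALSE)
  }
}

#' Reference divergence-model fit summaries
#'
#' Fit summaries (NP, log10 LL, reported AIC, and parameter MLEs) for the
#' four divergence models from the original MIG-seq analysis of the
#' two-cluster Korean limestone-shrub dataset that this package's model
#' family mirrors, plus the best model's reported 95% confidence
#' intervals. Shipped as plain TSV under `inst/extdata/`; used as inputs
#' for arithmetic cross-checks and as realistic generating parameters for
#' synthetic data.
#'
#' @param which `"models"` for the four-model summary table or `"ci"` for
#'   the best-model MLE/interval table.
#' @return data.frame.
#' @export
reference_fits <- function(which = c("models", "ci")) {
  which <- match.arg(which)
  f <- system.file("extdata",
                   if (which == "models") "model_fits_reference.tsv"
                   else "best_model_ci_reference.tsv",
                   package = "karstdemog", mustWork = TRUE)
  read.table(f, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Reference best-fit divergence model
#'
#' The model-2 (isolation-with-migration) reference MLEs as a
#' [demographic_model()], with times converted from ka to generations
#' using the given generation time.
#'
#' @param gen_time years per generation.
#' @return a `demographic_model`.
#' @export
reference_model <- function(gen_time = 20) {
  tab <- reference_fits("ci")
  p <- function(k) tab$mle[tab$parameter == k]
  demographic_model(2,
                    N_CLI_0 = p("N_CLI_0"), N_CLII_0 = p("N_CLII_0"),
                    N_CLI_1 = p("N_CLI_1"), N_CLII_1 = p("N_CLII_1"),
                    N_ANC = p("N_ANC"),
                    T1 = p("T1_ka") * 1000 / gen_time,
                    T2 = p("T2_ka") * 1000 / gen_time,
                    Nm_I_II = p("Nm_I_II"), Nm_II_I = p("Nm_II_I"))
}
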