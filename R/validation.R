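#' Run the simulation-based parameter-recovery validation study
#'
#' For each dataset: sample a random generating prior, simulate a full
#' session of transformation batches produced by an observer carrying that
#' prior, refit the prior by the multi-restart robust-cost procedure, and
#' summarise how well the fitted priors recover the generating priors'
#' correlation coefficients and covariance-orientation angles
#' ([validation_metrics()]). Fit failures are tolerated up to 2% of
#' datasets and logged in the report.
#'
#' @param vcfg A [validation_config()].
#' @param cfg A [generator_config()].
#' @param model Observer model used both to generate and to fit.
#' @param spec A [robust_cost_spec()].
#' @param noise A [noise_model()].
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @param verbose Print one line per dataset.
#' @return A list with class `vm_validation_report`: `metrics`,
#'   `generating`, `fitted`, a per-dataset `table` (cost, converged,
#'   per-pair statistics), `n_failed`, plus the configurations.
#' @export
run_validation_study <- function(vcfg = validation_config(),
                                 cfg = generator_config(),
                                 model = "standard",
                                 spec = robust_cost_spec(),
                                 noise = noise_model(),
                                 seed = NULL, verbose = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  generating <- list()
  fitted <- list()
  rows <- list()
  n_failed <- 0L
  for (i in seq_len(vcfg$n_datasets)) {
    gp <- sample_random_prior(vcfg$prior_init_sd)
    ses <- simulate_session(gp, cfg, vcfg, model = model)
    fit <- tryCatch(
      fit_prior(model, ses, spec, n_restarts = vcfg$n_fit_restarts,
                prior_init_sd = vcfg$prior_init_sd, noise = noise),
      error = function(e) NULL)
    if (is.null(fit)) {
      n_failed <- n_failed + 1L
      if (n_failed > max(1L, ceiling(0.02 * vcfg$n_datasets))) {
        stop("more than 2% of dataset fits failed (", n_failed, " of ",
             i, ")")
      }
      next
    }
    generating[[length(generating) + 1L]] <- gp
    fitted[[length(fitted) + 1L]] <- fit$covariance
    rows[[length(rows) + 1L]] <- data.frame(dataset = i, cost = fit$cost,
                                            converged = fit$converged,
                                            n_batches = length(fit$errors))
    if (verbose) {
      message("dataset ", i, "/", vcfg$n_datasets, ": cost ",
              signif(fit$cost, 5))
    }
  }
  metrics <- validation_metrics(generating, fitted)
  structure(list(metrics = metrics, generating = generating,
                 fitted = fitted, table = do.call(rbind, rows),
                 n_failed = n_failed, vcfg = vcfg, cfg = cfg,
                 model = model, spec = spec),
            class = "vm_validation_report")
}

#' @export
print.vm_validation_report <- function(x, ...) {
  m <- x$metrics
  cat("<vm_validation_report> ", length(x$fitted), " datasets (",
      x$n_failed, " failed fits)\n",
      "  median |r_fit - r_gen|        : ", signif(m$median_abs_dr, 3), "\n",
      "  wrong-sign fraction           : ",
      signif(100 * m$wrong_sign_frac, 3), "%\n",
      "  median axial |theta_fit-gen|  : ", signif(m$median_abs_dtheta, 3),
      " deg\n", sep = "")
  invisible(x)
}

#' Random-prior baseline for the recovery metrics
#'
#' Samples independent pairs of random priors and computes the same
#' summary statistics as the recovery study: the median absolute
#' difference in pairwise correlation coefficients and the fraction of
#' sign disagreements, aggregated over the six element pairs. This is the
#' chance floor against which parameter recovery is judged.
#'
#' @param n_pairs Number of independent prior pairs.
#' @param prior_init_sd SD of the Gaussian entries of the prior factors.
#' @param seed Optional integer seed.
#' @return A list: `median_abs_dr`, `wrong_sign_frac`,
#'   `median_abs_dtheta`, `n_pairs`.
#' @export
random_prior_baseline <- function(n_pairs = 10000L, prior_init_sd = 1,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pn_rows <- 6L
  dr <- matrix(NA_real_, n_pairs, pn_rows)
  ws <- matrix(NA, n_pairs, pn_rows)
  dth <- matrix(NA_real_, n_pairs, pn_rows)
  for (i in seq_len(n_pairs)) {
    s1 <- cov_to_pair_stats(sample_random_prior(prior_init_sd))
    s2 <- cov_to_pair_stats(sample_random_prior(prior_init_sd))
    dr[i, ] <- abs(s1$r - s2$r)
    ws[i, ] <- sign(s1$r) != sign(s2$r) & abs(s1$r) > 1e-12 &
      abs(s2$r) > 1e-12
    dth[i, ] <- axial_diff(s1$theta, s2$theta)
  }
  list(median_abs_dr = median(dr), wrong_sign_frac = mean(ws),
       median_abs_dtheta = median(dth), n_pairs = n_pairs)
}
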