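pair_names <- function() {
  el <- c("a", "b", "c", "d")
  idx <- which(upper.tri(diag(4)), arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  data.frame(j = el[idx[, "row"]], k = el[idx[, "col"]],
             row = idx[, "row"], col = idx[, "col"])
}

#' Pairwise correlation and ellipse-orientation statistics of a prior
#'
#' For each of the six pairs of transformation-matrix elements, computes
#' the correlation coefficient `r = S_jk / sqrt(S_jj S_kk)` and the
#' orientation angle of the long axis of the pair's marginal covariance
#' ellipse, `theta = 0.5 * atan2(2 S_jk, S_jj - S_kk)` in degrees, reported
#' on the axial half-open range (-90, 90]. An exactly isotropic marginal
#' has no defined long axis; the angle is then reported as 0 with
#' `degenerate = TRUE` so that downstream bootstraps stay reproducible.
#'
#' @param cov A 4x4 SPD covariance matrix over `(a, b, c, d)`.
#' @return A data frame with one row per pair: `pair`, `j`, `k`, `r`,
#'   `theta` (degrees), `degenerate`.
#' @export
cov_to_pair_stats <- function(cov) {
  stopifnot(is.matrix(cov), all(dim(cov) == 4L))
  if (max(abs(cov - t(cov))) > 1e-8 || any(eigen(cov, symmetric = TRUE,
                                                 only.values = TRUE)$values <= 0)) {
    stop("cov must be symmetric positive-definite")
  }
  pn <- pair_names()
  res <- lapply(seq_len(nrow(pn)), function(i) {
    jj <- cov[pn$row[i], pn$row[i]]
    kk <- cov[pn$col[i], pn$col[i]]
    jk <- cov[pn$row[i], pn$col[i]]
    degen <- abs(2 * jk) < 1e-12 && abs(jj - kk) < 1e-12
    theta <- if (degen) 0 else 0.5 * atan2(2 * jk, jj - kk) * 180 / pi
    data.frame(pair = paste0(pn$j[i], pn$k[i]), j = pn$j[i], k = pn$k[i],
               r = jk / sqrt(jj * kk), theta = theta, degenerate = degen)
  })
  do.call(rbind, res)
}

#' Axial mean of orientation angles
#'
#' Orientation angles of ellipse axes are axial (defined modulo 180
#' degrees), so the mean is computed by doubling the angles, taking the
#' circular mean of the doubled angles, and halving, with the result mapped
#' to (-90, 90].
#'
#' @param angles Numeric vector of angles in degrees.
#' @return The axial mean in degrees.
#' @export
axial_mean <- function(angles) {
  stopifnot(length(angles) >= 1)
  ph <- 2 * angles * pi / 180
  s <- mean(sin(ph)); cc <- mean(cos(ph))
  if (sqrt(s^2 + cc^2) < 1e-9) {
    stop("axial mean undefined: angles are perfectly dispersed")
  }
  m <- atan2(s, cc) / 2 * 180 / pi
  if (m <= -90) m + 180 else m
}

#' Axial distance between two orientation angles
#'
#' @param theta1,theta2 Angles in degrees.
#' @return The absolute axial difference, in `[0, 90]` degrees.
#' @export
axial_diff <- function(theta1, theta2) {
  d <- abs(theta1 - theta2) %% 180
  pmin(d, 180 - d)
}

#' Bootstrap confidence limits on a covariance-orientation angle
#'
#' Resamples the transformed batches of a session with replacement and
#' refits the prior on each resample; the refits are warm-started at the
#' full-data best fit and augmented with random restarts. The orientation
#' angle of the requested element pair is collected across resamples and
#' summarised by its axial mean and the central 95% interval on the
#' doubled-angle circle.
#'
#' @inheritParams fit_prior
#' @param pair Element pair as a two-character string, e.g. `"bc"`.
#' @param n_resamples Number of bootstrap resamples (at least 100).
#' @param n_restarts_boot Random restarts added to the warm start in each
#'   resample fit.
#' @param full_fit Optional precomputed full-data `vm_prior_fit` (fitted
#'   here when `NULL`).
#' @param level Confidence level.
#' @return A list with class `vm_bootstrap_ci`: `pair`, `mean_angle`, `lo`,
#'   `hi`, `n_resamples`, `angles`, `best_angle`.
#' @export
bootstrap_angle_ci <- function(model, session, pair = "bc",
                               n_resamples = 1000L, spec = robust_cost_spec(),
                               n_restarts = 20L, n_restarts_boot = 2L,
                               prior_init_sd = 1, noise = noise_model(),
                               full_fit = NULL, level = 0.95,
                               control = list(maxit = 200L, factr = 1e7)) {
  if (n_resamples < 100) stop("n_resamples must be at least 100")
  if (is.null(full_fit)) {
    full_fit <- fit_prior(model, session, spec, n_restarts, prior_init_sd,
                          noise = noise, control = control)
  }
  keep <- which(vapply(session$batches, function(b) {
    b$type == "transformed" && nrow(b$trials) >= 2
  }, logical(1)))
  pick_theta <- function(fit) {
    st <- cov_to_pair_stats(fit$covariance[1:4, 1:4])
    st$theta[st$pair == pair]
  }
  if (length(pick_theta(full_fit)) != 1) {
    stop("unknown element pair '", pair, "'")
  }
  angles <- numeric(n_resamples)
  failures <- 0L
  for (i in seq_len(n_resamples)) {
    idx <- sample(keep, length(keep), replace = TRUE)
    sub <- session
    sub$batches <- session$batches[idx]
    fit <- tryCatch(
      fit_prior(model, sub, spec, n_restarts_boot, prior_init_sd,
                noise = noise, warm_start = full_fit$par, control = control),
      error = function(e) NULL)
    if (is.null(fit)) {
      failures <- failures + 1L
      angles[i] <- NA_real_
    } else {
      angles[i] <- pick_theta(fit)
    }
  }
  if (failures > 0.05 * n_resamples) {
    stop("bootstrap fit failures exceeded 5% of resamples (", failures,
         "/", n_resamples, ")")
  }
  angles <- angles[!is.na(angles)]
  m2 <- atan2(mean(sin(2 * angles * pi / 180)),
              mean(cos(2 * angles * pi / 180))) * 180 / pi
  dev <- ((2 * angles - m2 + 180) %% 360) - 180
  qs <- quantile(dev, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
  half <- function(x) {
    y <- (((m2 + x) / 2 + 90) %% 180) - 90
    if (y <= -90) y + 180 else y
  }
  structure(list(pair = pair, mean_angle = half(0), lo = half(qs[1]),
                 hi = half(qs[2]), n_resamples = length(angles),
                 angles = angles, best_angle = pick_theta(full_fit)),
            class = "vm_bootstrap_ci")
}

#' @export
print.vm_bootstrap_ci <- function(x, ...) {
  cat("<vm_bootstrap_ci> pair ", x$pair, ": mean ",
      signif(x$mean_angle, 4), " deg, 95% CI [", signif(x$lo, 4), ", ",
      signif(x$hi, 4), "] from ", x$n_resamples, " resamples\n", sep = "")
  invisible(x)
}

#' Does a bootstrap CI contain an angle (axially)?
#'
#' @param ci A `vm_bootstrap_ci`.
#' @param theta Angle in degrees.
#' @return Logical.
#' @export
ci_contains_angle <- function(ci, theta) {
  m2 <- 2 * ci$mean_angle
  wrap <- function(x) ((x + 180) %% 360) - 180
  dt <- wrap(2 * theta - m2)
  dlo <- wrap(2 * ci$lo - m2)
  dhi <- wrap(2 * ci$hi - m2)
  dt >= dlo & dt <= dhi
}

#' Tests of across-subject correlation coefficients
#'
#' Runs the two group-level tests applied to each element pair's
#' correlation coefficients across subjects: a one-sample t-test of the
#' mean against zero (with a guard for zero-variance samples, where the
#' t statistic is infinite and the p-value is 0 unless the common value is
#' itself 0), and an exact one-sample Kolmogorov-Smirnov test against the
#' uniform distribution on (-1, 1) to probe the consistency of the
#' correlation across subjects.
#'
#' @param values Numeric vector of correlation coefficients (n >= 3).
#' @return A list: `t_p`, `ks_p`, `mean_r`, `n`.
#' @export
test_correlations <- function(values) {
  if (length(values) < 3) stop("need at least 3 values")
  if (sd(values) < 1e-12) {
    t_p <- if (abs(mean(values)) < 1e-12) 1 else 0
  } else {
    n <- length(values)
    tt <- mean(values) / (sd(values) / sqrt(n))
    t_p <- 2 * pt(-abs(tt), df = n - 1)
  }
  ks <- suppressWarnings(ks.test(values, "punif", -1, 1))
  list(t_p = t_p, ks_p = unname(ks$p.value), mean_r = mean(values),
       n = length(values))
}

#' Parameter-recovery summary metrics
#'
#' For matched lists of generating and fitted 4x4 prior covariances,
#' computes per dataset and per element pair the absolute difference in
#' correlation coefficient, a sign-disagreement indicator (a coefficient
#' equal to zero to machine precision counts as agreeing), and the axial
#' absolute difference in covariance-orientation angle, all aggregated
#' across the six pairings.
#'
#' @param generating,fitted Lists of 4x4 SPD covariance matrices of equal
#'   length.
#' @return A list: `median_abs_dr`, `wrong_sign_frac`, `median_abs_dtheta`
#'   (degrees), and the underlying per-combination data frame `details`.
#' @export
validation_metrics <- function(generating, fitted) {
  if (length(generating) != length(fitted) || length(generating) < 1) {
    stop("generating and fitted must be non-empty lists of equal length")
  }
  rows <- lapply(seq_along(generating), function(i) {
    g <- cov_to_pair_stats(generating[[i]])
    f <- cov_to_pair_stats(fitted[[i]])
    data.frame(dataset = i, pair = g$pair,
               abs_dr = abs(f$r - g$r),
               wrong_sign = sign(f$r) != sign(g$r) &
                 abs(f$r) > 1e-12 & abs(g$r) > 1e-12,
               abs_dtheta = axial_diff(f$theta, g$theta))
  })
  d <- do.call(rbind, rows)
  list(median_abs_dr = median(d$abs_dr),
       wrong_sign_frac = mean(d$wrong_sign),
       median_abs_dtheta = median(d$abs_dtheta),
       details = d)
}
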