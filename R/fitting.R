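#' Robust cost specification
#'
#' The fitting cost for a session is the sum over transformed batches of
#' `min(e_i, c)` where `e_i` is the Euclidean distance between the
#' predicted and observed second-trial hand positions. The saturation
#' constant `c` (default 10 cm) keeps the cost maximally sensitive to
#' errors in the 4-10 cm range typical of model predictions while limiting
#' the influence of outliers. Model comparison and the origin sweep report
#' mean errors capped at `comparison_cap` (default 20 cm) instead.
#'
#' @param c Saturation constant of the fitting cost (cm).
#' @param comparison_cap Cap applied to errors before averaging when
#'   comparing models or origins (cm).
#' @return A list with class `vm_cost_spec`.
#' @export
robust_cost_spec <- function(c = 10, comparison_cap = 20) {
  stopifnot(c > 0, comparison_cap > 0)
  structure(list(c = c, comparison_cap = comparison_cap),
            class = "vm_cost_spec")
}

#' Robust prediction cost
#'
#' @param predictions,observations Matrices with one row per trial and two
#'   columns (x, y), of equal dimensions.
#' @param spec A [robust_cost_spec()].
#' @return The scalar cost `sum(min(error_i, c))`.
#' @export
robust_cost <- function(predictions, observations,
                        spec = robust_cost_spec()) {
  predictions <- rbind(predictions)
  observations <- rbind(observations)
  if (nrow(predictions) != nrow(observations) || nrow(predictions) < 1) {
    stop("predictions and observations must have the same, non-zero length")
  }
  e <- sqrt(rowSums((predictions - observations)^2))
  sum(pmin(e, spec$c))
}

model_code <- function(model) {
  match(match.arg(model, observer_models), observer_models)
}

n_free_par <- function(model) {
  switch(model, standard = 10L, shift = 3L, rotscale = 3L, affine = 13L,
         none = 0L)
}

# positions of the diagonal elements of U in the column-major
# upper-triangle parameter layout
diag_par_idx <- function(model) {
  tri_diag <- function(k) cumsum(seq_len(k))
  switch(model,
         standard = tri_diag(4L),
         shift = tri_diag(2L),
         rotscale = tri_diag(2L),
         affine = c(tri_diag(4L), 10L + tri_diag(2L)),
         none = integer(0))
}

# R mirror of the C++ parameterization: Lambda = U'U + eps I (block
# diagonal 4+2 for the affine model)
par_to_precision <- function(par, model, eps = 1e-6) {
  fill_u <- function(p, k) {
    U <- matrix(0, k, k)
    U[upper.tri(U, diag = TRUE)] <- p
    U
  }
  if (model == "affine") {
    L <- matrix(0, 6, 6)
    U4 <- fill_u(par[1:10], 4L)
    U2 <- fill_u(par[11:13], 2L)
    L[1:4, 1:4] <- crossprod(U4)
    L[5:6, 5:6] <- crossprod(U2)
  } else {
    k <- belief_dim(model)
    L <- crossprod(fill_u(par, k))
  }
  L + eps * diag(nrow(L))
}

precision_to_par <- function(Lambda, model) {
  if (model == "affine") {
    c(chol(Lambda[1:4, 1:4])[upper.tri(diag(4), diag = TRUE)],
      chol(Lambda[5:6, 5:6])[upper.tri(diag(2), diag = TRUE)])
  } else {
    chol(Lambda)[upper.tri(Lambda, diag = TRUE)]
  }
}

# Extract the per-batch trial-2 fitting data (first-trial evidence, second
# trial target and hand) for transformed batches with >= 2 trials, in the
# frame centred on `origin`.
trial2_data <- function(session, origin = c(0, 0)) {
  keep <- vapply(session$batches, function(b) {
    b$type == "transformed" && nrow(b$trials) >= 2
  }, logical(1))
  rows <- lapply(session$batches[keep], function(b) {
    tr <- b$trials
    c(tr$hand_x[1], tr$hand_y[1], tr$cursor_x[1], tr$cursor_y[1],
      tr$target_x[2], tr$target_y[2], tr$hand_x[2], tr$hand_y[2])
  })
  m <- do.call(rbind, rows)
  if (is.null(m)) m <- matrix(numeric(0), 0, 8)
  if (nrow(m) > 0 && any(origin != 0)) m <- sweep(m, 2, rep(origin, 4))
  attr(m, "batch_index") <- which(keep)
  m
}

trial2_errors_prec <- function(Lambda, model, data, noise) {
  .vm_trial2_errors_prec(Lambda, model_code(model), data, noise$cursor_var,
                         noise$angular_var, noise$radial_var)
}

random_start_par <- function(model, prior_init_sd, eps = 1e-6) {
  rand_u <- function(k) {
    B <- matrix(rnorm(k * k, 0, prior_init_sd), k, k)
    chol(crossprod(B) + eps * diag(k))[upper.tri(diag(k), diag = TRUE)]
  }
  if (model == "affine") c(rand_u(4L), rand_u(2L)) else
    rand_u(belief_dim(model))
}

#' Fit an observer's prior covariance to a session
#'
#' Minimizes the saturating robust cost of the model's second-trial
#' predictions (each prediction uses only the first trial's evidence of its
#' batch) with respect to the free elements of the upper-triangular factor
#' `U` of the precision matrix, `Lambda = U'U + 1e-6 I`, whose diagonal is
#' bound below at 1e-6 so that the fitted covariance is always symmetric
#' positive-definite. The optimisation is bound-constrained quasi-Newton
#' (L-BFGS-B) started from `n_restarts` random precision matrices
#' `B'B + 1e-6 I` with `B` iid Gaussian; the lowest-cost restart wins, ties
#' broken by the lowest restart index. The affine model's precision is
#' block-diagonal (4x4 linear block, 2x2 shift block; 13 free parameters).
#'
#' @param model Observer model, see [init_belief()] (`"none"` has no free
#'   parameters and returns its fixed cost).
#' @param session A `vm_session`; every transformed batch with at least two
#'   trials contributes one prediction.
#' @param spec A [robust_cost_spec()].
#' @param n_restarts Number of random restarts.
#' @param prior_init_sd SD of the Gaussian entries of the restart matrices.
#' @param origin Origin of the transformations (cm).
#' @param noise A [noise_model()].
#' @param warm_start Optional parameter vector (as returned in `$par`) run
#'   as an additional first restart.
#' @param control Passed to [stats::optim()] (`maxit`, `factr`).
#' @return A list with class `vm_prior_fit`: `model`, `covariance`,
#'   `precision`, `cost`, `par`, `errors` (uncapped per-batch trial-2
#'   errors at the optimum), `n_restarts`, `best_restart`, `converged`,
#'   `origin`.
#' @export
fit_prior <- function(model, session, spec = robust_cost_spec(),
                      n_restarts = 100L, prior_init_sd = 1,
                      origin = c(0, 0), noise = noise_model(),
                      warm_start = NULL,
                      control = list(maxit = 200L, factr = 1e7)) {
  model <- match.arg(model, observer_models)
  data <- trial2_data(session, origin)
  if (nrow(data) < 1) stop("no transformed batches with >= 2 trials")
  code <- model_code(model)
  nv <- noise$cursor_var
  av <- noise$angular_var
  rv <- noise$radial_var
  if (model == "none") {
    e <- trial2_errors_prec(matrix(0, 0, 0), model, data, noise)
    return(structure(list(model = model, covariance = NULL,
                          precision = NULL, cost = sum(pmin(e, spec$c)),
                          par = numeric(0), errors = e, n_restarts = 0L,
                          best_restart = NA_integer_, converged = TRUE,
                          origin = origin),
                     class = "vm_prior_fit"))
  }
  obj <- function(par) {
    .vm_trial2_cost_par(par, code, data, nv, av, rv, spec$c, 1e-6)
  }
  grad <- function(par) {
    .vm_trial2_cost_grad_par(par, code, data, nv, av, rv, spec$c, 1e-6)
  }
  npar <- n_free_par(model)
  lower <- rep(-Inf, npar)
  lower[diag_par_idx(model)] <- 1e-6
  starts <- lapply(seq_len(n_restarts), function(i)
    random_start_par(model, prior_init_sd))
  if (!is.null(warm_start)) starts <- c(list(warm_start), starts)
  best <- NULL
  n_fail <- 0L
  for (i in seq_along(starts)) {
    res <- tryCatch(
      optim(starts[[i]], obj, gr = grad, method = "L-BFGS-B", lower = lower,
            control = control),
      error = function(e) NULL)
    if (is.null(res)) { n_fail <- n_fail + 1L; next }
    if (is.null(best) || res$value < best$value) {
      best <- res
      best$restart <- i
    }
  }
  if (is.null(best)) {
    stop("optimization failed on all ", length(starts), " restarts (",
         n_fail, " errors)")
  }
  Lambda <- par_to_precision(best$par, model)
  covariance <- solve(Lambda)
  covariance <- (covariance + t(covariance)) / 2
  structure(list(model = model, covariance = covariance,
                 precision = Lambda, cost = best$value, par = best$par,
                 errors = trial2_errors_prec(Lambda, model, data, noise),
                 n_restarts = length(starts),
                 best_restart = best$restart,
                 converged = best$convergence == 0, origin = origin),
            class = "vm_prior_fit")
}

#' @export
print.vm_prior_fit <- function(x, ...) {
  cat("<vm_prior_fit> model '", x$model, "', cost ", signif(x$cost, 5),
      " over ", length(x$errors), " batches (best of ", x$n_restarts,
      " restarts)\n", sep = "")
  if (!is.null(x$covariance)) {
    cat("fitted covariance:\n")
    print(signif(x$covariance, 3))
  }
  invisible(x)
}

#' Cross-validated second-trial prediction errors
#'
#' Transformed batches are assigned to `k` non-overlapping, evenly-spaced
#' groups by their session order: group `g` holds batches whose index is
#' congruent to `g` modulo `k` (with 111 batches and `k = 10`, group 1 is
#' batches 1, 11, 21, ..., 101, 111). Each group's second-trial errors are
#' computed under a prior fit to the other `k - 1` groups, and capped at
#' `comparison_cap`.
#'
#' @inheritParams fit_prior
#' @param k Number of folds (at least 2).
#' @return A data frame with columns `batch` (index among transformed
#'   batches), `group`, and `error` (capped, cm).
#' @export
crossval_trial2 <- function(model, session, spec = robust_cost_spec(),
                            k = 10L, n_restarts = 20L, prior_init_sd = 1,
                            origin = c(0, 0), noise = noise_model(),
                            control = list(maxit = 200L, factr = 1e7)) {
  if (k < 2) stop("k must be at least 2 (k = 1 has no held-out data)")
  data <- trial2_data(session, origin)
  n <- nrow(data)
  if (n < k) stop("fewer transformed batches (", n, ") than folds (", k, ")")
  group <- ((seq_len(n) - 1L) %% k) + 1L
  err <- numeric(n)
  for (g in seq_len(k)) {
    hold <- group == g
    if (model == "none") {
      e <- trial2_errors_prec(matrix(0, 0, 0), model,
                              data[hold, , drop = FALSE], noise)
    } else {
      sub <- session
      sub$batches <- session$batches[attr(data, "batch_index")[!hold]]
      fit <- fit_prior(model, sub, spec, n_restarts, prior_init_sd, origin,
                       noise, control = control)
      e <- trial2_errors_prec(fit$precision, model,
                              data[hold, , drop = FALSE], noise)
    }
    err[hold] <- pmin(e, spec$comparison_cap)
  }
  data.frame(batch = seq_len(n), group = group, error = err)
}

#' Compare observer models by prediction error across trials
#'
#' Second-trial errors use 10-fold cross-validation (complex models must
#' not benefit from over-fitting); predictions for trials 3 and later come
#' from observers carrying priors fit to all second-trial data and
#' integrating the evidence of every previous trial of the batch. Only
#' batches lasting at least `trial` trials contribute to that trial's mean,
#' and all errors are capped at `comparison_cap` before averaging.
#'
#' @inheritParams crossval_trial2
#' @param models Character vector of model identities to compare.
#' @param max_trial Last trial index to evaluate (default 7).
#' @return A data frame with columns `model`, `trial`, `mean_error` (cm),
#'   `n_batches`.
#' @export
compare_models <- function(session, spec = robust_cost_spec(),
                           models = observer_models, k = 10L,
                           n_restarts = 20L, prior_init_sd = 1,
                           max_trial = 7L, noise = noise_model(),
                           control = list(maxit = 200L, factr = 1e7)) {
  keep <- vapply(session$batches, function(b) {
    b$type == "transformed" && nrow(b$trials) >= 2
  }, logical(1))
  batches <- session$batches[keep]
  out <- list()
  for (model in models) {
    cv <- crossval_trial2(model, session, spec, k, n_restarts,
                          prior_init_sd, noise = noise, control = control)
    out[[length(out) + 1L]] <- data.frame(model = model, trial = 2L,
                                          mean_error = mean(cv$error),
                                          n_batches = nrow(cv))
    prior_cov <- NULL
    if (model != "none") {
      fit <- fit_prior(model, session, spec, n_restarts, prior_init_sd,
                       noise = noise, control = control)
      prior_cov <- fit$covariance
    }
    per_batch <- lapply(batches, function(b) {
      nb <- nrow(b$trials)
      preds <- run_batch(model, prior_cov, b, noise)
      e <- sqrt(rowSums((preds - cbind(b$trials$hand_x,
                                       b$trials$hand_y)[-1, , drop = FALSE])^2))
      ec <- rep(NA_real_, max_trial - 1L)
      take <- seq_len(min(nb, max_trial) - 1L)
      ec[take] <- pmin(e[take], spec$comparison_cap)
      ec
    })
    em <- do.call(rbind, per_batch)
    for (t in seq(3L, max_trial)) {
      col <- em[, t - 1L]
      out[[length(out) + 1L]] <- data.frame(model = model, trial = t,
                                            mean_error = mean(col,
                                                              na.rm = TRUE),
                                            n_batches = sum(!is.na(col)))
    }
  }
  do.call(rbind, out)
}

#' Sweep the origin of the linear transformations
#'
#' Refits the standard model with the transformation origin set to each
#' candidate point and reports the mean capped second-trial error at the
#' optimum, mapping how strongly the data prefer the start circle (or any
#' other location, such as the eyes) as the centre of the visuomotor
#' coordinate frame.
#'
#' @inheritParams fit_prior
#' @param grid Two-column matrix or data frame of candidate origins (cm).
#' @return A data frame with columns `origin_x`, `origin_y`, `mean_error`
#'   (capped at `comparison_cap`), `cost`.
#' @export
origin_sweep <- function(session, spec = robust_cost_spec(), grid,
                         n_restarts = 20L, prior_init_sd = 1,
                         noise = noise_model(),
                         control = list(maxit = 200L, factr = 1e7)) {
  grid <- as.matrix(grid)
  if (nrow(grid) < 1 || ncol(grid) != 2) {
    stop("grid must have at least one row and exactly two columns")
  }
  res <- apply(grid, 1, function(o) {
    fit <- fit_prior("standard", session, spec, n_restarts, prior_init_sd,
                     origin = o, noise = noise, control = control)
    c(mean(pmin(fit$errors, spec$comparison_cap)), fit$cost)
  })
  data.frame(origin_x = grid[, 1], origin_y = grid[, 2],
             mean_error = res[1, ], cost = res[2, ])
}
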