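#' Configuration of the synthetic reaching experiment
#'
#' Bundles the constants of the simulated workspace and of the two
#' transformation distributions. Distances are centimetres relative to the
#' start-circle centre (x rightward, y forward). Defaults reproduce the
#' published experiment where its values are stated (11 cm target-rectangle
#' offset, 30 cm reach limit, central 80% screen rule, batch termination
#' rules) and are calibrated against the published per-element moments of
#' the correlated transformation distribution where they are not (uniform
#' range of `a`/`d`, SD of the shared `b = c` element, screen geometry; see
#' the methods vignette).
#'
#' @param uniform_lo,uniform_hi Range of the uniform distribution for the
#'   diagonal elements `a`, `d` in the correlated distribution.
#' @param sigma_bc SD of the zero-mean Gaussian for the shared off-diagonal
#'   element (`b = c`) in the correlated distribution.
#' @param sigma_ac_uncorr SD of the Gaussian draws of `a` (mean 1) and `c`
#'   (mean 0) in the uncorrelated distribution.
#' @param target_rect_w,target_rect_h Width/height of the target rectangle (cm).
#' @param target_rect_center_y Forward offset of the target-rectangle centre
#'   from the start circle (cm).
#' @param screen_w,screen_h Workspace screen dimensions (cm).
#' @param screen_center_y Forward offset of the screen centre (cm).
#' @param central_fraction Cursor positions implied by hands in the target
#'   rectangle must stay within this central fraction of the screen in each
#'   dimension.
#' @param max_reach Maximum hand distance from the start circle needed to
#'   hit any possible target (cm).
#' @param min_batch_trials Minimum trials before a hit can end a transformed
#'   batch.
#' @param spont_term_prob Probability of spontaneous batch termination after
#'   each trial from `spont_term_start_trial` onwards.
#' @param spont_term_start_trial First trial at which spontaneous
#'   termination can occur.
#' @param max_batch_trials Hard cap on batch length (simulation safeguard,
#'   not part of the task rules).
#' @param target_radius_veridical,target_radius_transformed Target radii (cm).
#' @param min_target_angle_sep Minimum angular separation (degrees) between
#'   the directions of successive targets.
#' @return A list with class `vm_generator_config`.
#' @export
generator_config <- function(uniform_lo = 0.1,
                             uniform_hi = 1.9,
                             sigma_bc = 0.6,
                             sigma_ac_uncorr = 0.55,
                             target_rect_w = 20,
                             target_rect_h = 10,
                             target_rect_center_y = 11,
                             screen_w = 140,
                             screen_h = 55,
                             screen_center_y = 4,
                             central_fraction = 0.8,
                             max_reach = 30,
                             min_batch_trials = 3,
                             spont_term_prob = 0.2,
                             spont_term_start_trial = 8,
                             max_batch_trials = 30,
                             target_radius_veridical = 2,
                             target_radius_transformed = 3,
                             min_target_angle_sep = 10) {
  stopifnot(uniform_lo < uniform_hi,
            central_fraction > 0, central_fraction <= 1,
            spont_term_prob >= 0, spont_term_prob <= 1,
            max_reach > 0, min_batch_trials >= 1,
            max_batch_trials >= min_batch_trials)
  structure(as.list(environment()), class = "vm_generator_config")
}

# corners of the target rectangle; linear maps attain their extremes on
# vertices, so checking corners is exact for the rejection rules
target_rect_corners <- function(cfg) {
  w2 <- cfg$target_rect_w / 2
  ylo <- cfg$target_rect_center_y - cfg$target_rect_h / 2
  yhi <- cfg$target_rect_center_y + cfg$target_rect_h / 2
  rbind(c(-w2, ylo), c(-w2, yhi), c(w2, ylo), c(w2, yhi))
}

#' Reachability rejection rule for a proposed transformation
#'
#' A transformation is rejected if (i) the cursor position implied by any
#' hand position within the target rectangle falls outside the central
#' `central_fraction` of the screen in either dimension, or (ii) hitting any
#' possible target would require a hand position further than `max_reach`
#' from the start circle. Both rules are evaluated on the rectangle corners,
#' which is exact for linear maps. Singular transformations are rejected
#' (rule ii cannot be satisfied).
#'
#' @param T 2x2 transformation matrix.
#' @param cfg A [generator_config()].
#' @return `TRUE` if the transformation must be rejected.
#' @export
reject_transform <- function(T, cfg = generator_config()) {
  corners <- target_rect_corners(cfg)
  hx <- cfg$screen_w / 2 * cfg$central_fraction
  hy <- cfg$screen_h / 2 * cfg$central_fraction
  cur <- corners %*% t(T)
  if (any(abs(cur[, 1]) > hx | abs(cur[, 2] - cfg$screen_center_y) > hy)) {
    return(TRUE)
  }
  dt <- T[1, 1] * T[2, 2] - T[1, 2] * T[2, 1]
  if (abs(dt) <= 1e-10) return(TRUE)
  req <- corners %*% t(invert_transform(T))
  any(rowSums(req^2) > cfg$max_reach^2)
}

give_up <- function(what) {
  stop("gave up after 10000 consecutive rejections while sampling ", what,
       "; the workspace configuration is likely inconsistent")
}

#' Sample a transformation from the correlated distribution
#'
#' Diagonal elements `a`, `d` are drawn independently from
#' `Uniform(uniform_lo, uniform_hi)`; the off-diagonal elements are set
#' equal, `b = c ~ Normal(0, sigma_bc^2)`, so that the distribution carries
#' a perfect positive correlation between the off-diagonal elements. Draws
#' are rejected and resampled until [reject_transform()] passes.
#'
#' Draws consume the current R random-number stream; call `set.seed()`
#' beforehand for reproducibility.
#'
#' @param cfg A [generator_config()].
#' @return A 2x2 transformation matrix.
#' @export
sample_correlated_transform <- function(cfg = generator_config()) {
  for (i in seq_len(10000L)) {
    a <- runif(1, cfg$uniform_lo, cfg$uniform_hi)
    d <- runif(1, cfg$uniform_lo, cfg$uniform_hi)
    b <- rnorm(1, 0, cfg$sigma_bc)
    T <- transform_matrix(a, b, b, d)
    if (!reject_transform(T, cfg)) return(T)
  }
  give_up("a correlated transformation")
}

#' Sample a transformation from the uncorrelated distribution
#'
#' Used to minimise pairwise correlations between matrix elements while
#' keeping the transformation exactly consistent with the evidence already
#' shown on the first trial of a batch: one element per row is drawn freely
#' (`a ~ Normal(1, sigma_ac_uncorr^2)`, `c ~ Normal(0, sigma_ac_uncorr^2)`)
#' and the remaining element of each row is solved from
#' `T %*% evidence_h == evidence_v`:
#' `b = (v_x - a h_x) / h_y`, `d = (v_y - c h_x) / h_y`.
#' The same rejection rules as for the correlated distribution apply.
#'
#' @param evidence_h,evidence_v Hand and cursor positions of the first trial
#'   (cm); `abs(evidence_h[2])` must exceed 0.5 cm.
#' @param cfg A [generator_config()].
#' @return A 2x2 transformation matrix mapping `evidence_h` to `evidence_v`.
#' @export
sample_uncorrelated_transform <- function(evidence_h, evidence_v,
                                          cfg = generator_config()) {
  if (abs(evidence_h[2]) <= 0.5) {
    stop("evidence hand position must be at least 0.5 cm forward/backward ",
         "of the start circle to determine the solved elements")
  }
  for (i in seq_len(10000L)) {
    a <- rnorm(1, 1, cfg$sigma_ac_uncorr)
    cc <- rnorm(1, 0, cfg$sigma_ac_uncorr)
    b <- (evidence_v[1] - a * evidence_h[1]) / evidence_h[2]
    d <- (evidence_v[2] - cc * evidence_h[1]) / evidence_h[2]
    T <- transform_matrix(a, b, cc, d)
    if (!reject_transform(T, cfg)) return(T)
  }
  give_up("an uncorrelated transformation")
}

#' Sample a target position
#'
#' Uniform over the target rectangle, resampled until the angular direction
#' from the start circle differs from the previous target's direction by at
#' least `min_target_angle_sep` degrees (skipped when `prev_target` is
#' `NULL`).
#'
#' @param prev_target Previous target position, or `NULL`.
#' @param cfg A [generator_config()].
#' @return Length-2 target position (cm).
#' @export
sample_target <- function(prev_target = NULL, cfg = generator_config()) {
  w2 <- cfg$target_rect_w / 2
  ylo <- cfg$target_rect_center_y - cfg$target_rect_h / 2
  yhi <- cfg$target_rect_center_y + cfg$target_rect_h / 2
  prev_ang <- if (!is.null(prev_target)) {
    atan2(prev_target[2], prev_target[1]) * 180 / pi
  }
  for (i in seq_len(10000L)) {
    tgt <- c(runif(1, -w2, w2), runif(1, ylo, yhi))
    if (is.null(prev_target)) return(tgt)
    ang <- atan2(tgt[2], tgt[1]) * 180 / pi
    dif <- abs(((ang - prev_ang + 180) %% 360) - 180)
    if (dif >= cfg$min_target_angle_sep) return(tgt)
  }
  give_up("a target position")
}

#' Sample a random prior covariance over transformation parameters
#'
#' Draws a covariance as `solve(crossprod(B) + 1e-6 * diag(k))` where `B` is
#' a `k` x `k` matrix of iid `Normal(0, prior_init_sd^2)` entries. The same
#' construction provides both the generating priors of the validation study
#' and the random restarts of the fitting procedure (there applied to the
#' precision matrix directly). The result is always symmetric
#' positive-definite, and its correlation structure does not depend on
#' `prior_init_sd`.
#'
#' @param prior_init_sd SD of the Gaussian entries of `B`.
#' @param k Dimension (4 for the standard linear model).
#' @return A `k` x `k` SPD covariance matrix.
#' @export
sample_random_prior <- function(prior_init_sd = 1, k = 4L) {
  stopifnot(prior_init_sd > 0)
  B <- matrix(rnorm(k * k, 0, prior_init_sd), k, k)
  # the regularizer scales with the factor variance so that the correlation
  # structure of the draw is exactly independent of prior_init_sd
  prec <- crossprod(B) + 1e-6 * prior_init_sd^2 * diag(k)
  cov <- solve(prec)
  (cov + t(cov)) / 2
}

#' Configuration of the parameter-recovery validation study
#'
#' Defaults are the full published scale (825 simulated datasets of 150
#' transformation batches, best-of-100 fits, 1 cm isotropic cursor noise);
#' reduced scales for quick runs are passed explicitly.
#'
#' @param n_datasets Number of simulated datasets.
#' @param n_transforms_per_dataset Transformation batches per dataset.
#' @param cursor_noise_sd SD (cm) of the isotropic Gaussian noise added to
#'   cursor positions.
#' @param n_fit_restarts Random restarts per fit.
#' @param prior_init_sd SD used both for generating priors and fit restarts.
#' @return A list with class `vm_validation_config`.
#' @export
validation_config <- function(n_datasets = 825L,
                              n_transforms_per_dataset = 150L,
                              cursor_noise_sd = 1,
                              n_fit_restarts = 100L,
                              prior_init_sd = 1) {
  stopifnot(n_datasets >= 1, n_transforms_per_dataset >= 1,
            n_fit_restarts >= 1, cursor_noise_sd >= 0, prior_init_sd > 0)
  structure(as.list(environment()), class = "vm_validation_config")
}

#' Simulate a session of transformed reaching batches
#'
#' Generates the observable structure of one experimental session as
#' produced by a model observer that carries a known generating prior. For
#' each batch a transformation is drawn from the correlated distribution
#' (with the uncorrelated swap-on-trial-2 behaviour available as
#' `mode = "uncorrelated"`); the first-trial hand is placed at the target
#' centre (washout assumption); the observer sees the exact displayed
#' cursor (the transformed hand) and produces each later trial's hand as
#' its MAP prediction after updating on every previous trial; the
#' *recorded* cursor positions carry added isotropic Gaussian noise
#' emulating subject variability, so a fitter never sees exactly the
#' evidence that generated the responses.
#' A batch ends when the cursor lands within the target radius with at least
#' `min_batch_trials` trials completed, by spontaneous termination with
#' probability `spont_term_prob` from trial `spont_term_start_trial`
#' onwards, or at the `max_batch_trials` safeguard.
#'
#' @param generating_prior SPD covariance of the observer's prior (4x4 for
#'   the standard model).
#' @param cfg A [generator_config()].
#' @param vcfg A [validation_config()] (supplies the cursor noise SD).
#' @param model Observer model identity, see [init_belief()].
#' @param mode `"correlated"` or `"uncorrelated"` transformation
#'   distribution.
#' @param noise Observer noise model, see [noise_model()].
#' @param subject,session Identifiers recorded in the trial table.
#' @return A `vm_session` object: a list with elements `batches` (each a
#'   `vm_batch` with `type`, `transform`, `hit`, and a `trials` data frame),
#'   `config`, `model`, `mode`, `generating_prior`, `subject`, `session`.
#' @export
simulate_session <- function(generating_prior,
                             cfg = generator_config(),
                             vcfg = validation_config(),
                             model = "standard",
                             mode = c("correlated", "uncorrelated"),
                             noise = noise_model(),
                             subject = 1L, session = 1L) {
  mode <- match.arg(mode)
  sdn <- vcfg$cursor_noise_sd
  batches <- vector("list", vcfg$n_transforms_per_dataset)
  prev_target <- NULL
  for (bi in seq_along(batches)) {
    T <- sample_correlated_transform(cfg)
    target <- sample_target(prev_target, cfg)
    hand <- target  # washout: first reach is at the target centre
    # the simulated subject sees the exact displayed cursor; the noise that
    # emulates subject variability is added to the *recorded* cursor, so
    # that the evidence available to a fitter differs from the evidence
    # that generated the responses (otherwise recovery would be a
    # zero-residual identity check)
    cursor_seen <- drop(T %*% hand)
    if (mode == "uncorrelated") {
      # evidence near the workspace margins can admit no consistent
      # transform under the rejection rules; redraw such evidence, as the
      # experiment only ever presented evidence with eligible swaps
      Tu <- NULL
      for (att in seq_len(100L)) {
        Tu <- tryCatch(sample_uncorrelated_transform(hand, cursor_seen, cfg),
                       error = function(e) NULL)
        if (!is.null(Tu)) break
        T <- sample_correlated_transform(cfg)
        cursor_seen <- drop(T %*% hand)
      }
      if (is.null(Tu)) give_up("feasible first-trial evidence")
      T <- Tu
    }
    belief <- init_belief(model, generating_prior)
    rows <- list(c(1, target, hand, cursor_seen + rnorm(2, 0, sdn)))
    belief <- update_belief(belief, hand, cursor_seen, noise)
    prev_target <- target
    trial <- 1L
    repeat {
      trial <- trial + 1L
      target <- sample_target(prev_target, cfg)
      hand <- predict_hand(belief, target)
      cursor_seen <- drop(T %*% hand)
      rows[[trial]] <- c(trial, target, hand, cursor_seen + rnorm(2, 0, sdn))
      belief <- update_belief(belief, hand, cursor_seen, noise)
      prev_target <- target
      hit <- sqrt(sum((cursor_seen - target)^2)) <=
        cfg$target_radius_transformed
      if (hit && trial >= cfg$min_batch_trials) break
      if (trial >= cfg$max_batch_trials) { hit <- FALSE; break }
      if (trial >= cfg$spont_term_start_trial &&
          runif(1) < cfg$spont_term_prob) { hit <- FALSE; break }
    }
    tr <- do.call(rbind, rows)
    trials <- data.frame(trial = as.integer(tr[, 1]),
                         target_x = tr[, 2], target_y = tr[, 3],
                         hand_x = tr[, 4], hand_y = tr[, 5],
                         cursor_x = tr[, 6], cursor_y = tr[, 7])
    batches[[bi]] <- structure(list(type = "transformed", transform = T,
                                    hit = hit, trials = trials),
                               class = "vm_batch")
  }
  structure(list(batches = batches, config = cfg, model = model, mode = mode,
                 cursor_noise_sd = sdn, generating_prior = generating_prior,
                 subject = subject, session = session),
            class = "vm_session")
}

#' @export
print.vm_session <- function(x, ...) {
  n <- length(x$batches)
  nt <- sum(vapply(x$batches, function(b) nrow(b$trials), integer(1)))
  hits <- mean(vapply(x$batches, function(b) isTRUE(b$hit), logical(1)))
  cat("<vm_session> ", n, " transformed batches, ", nt, " trials, ",
      round(100 * hits), "% ended in a hit (", x$mode,
      " distribution, ", x$model, " observer)\n", sep = "")
  invisible(x)
}

#' @export
print.vm_batch <- function(x, ...) {
  cat("<vm_batch> ", x$type, ", ", nrow(x$trials), " trials, transform [",
      paste(signif(vec_transform(x$transform), 3), collapse = ", "),
      "]\n", sep = "")
  invisible(x)
}
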