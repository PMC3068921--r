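#' Observer noise model
#'
#' The observer treats its hand position as noiseless, with all noise on the
#' transformed (visual) hand position. Cursor noise is isotropic Gaussian
#' with variance `cursor_var`; only the ratio of the prior covariance to the
#' noise variance is identified, so `cursor_var` is fixed at 1 cm^2 by
#' convention. The rotation-and-scaling model observes in polar coordinates
#' with radial variance `radial_var` and angular variance `angular_var`; the
#' defaults (1 cm^2, 0.01 rad^2) make that noise isotropic at an
#' eccentricity of 10 cm, in the middle of the target rectangle.
#'
#' @param cursor_var Isotropic cursor noise variance (cm^2).
#' @param radial_var Radial noise variance (cm^2), rotation-scaling model.
#' @param angular_var Angular noise variance (rad^2), rotation-scaling model.
#' @return A list with class `vm_noise_model`.
#' @export
noise_model <- function(cursor_var = 1, radial_var = 1, angular_var = 0.01) {
  stopifnot(cursor_var > 0, radial_var > 0, angular_var > 0)
  structure(list(cursor_var = cursor_var, radial_var = radial_var,
                 angular_var = angular_var), class = "vm_noise_model")
}

observer_models <- c("standard", "shift", "rotscale", "affine", "none")

belief_dim <- function(model) {
  switch(model, standard = 4L, shift = 2L, rotscale = 2L, affine = 6L,
         none = 0L)
}

belief_mean0 <- function(model) {
  switch(model,
         standard = c(1, 0, 0, 1),   # identity transform (a, b, c, d)
         shift = c(0, 0),            # zero shift (s_x, s_y)
         rotscale = c(0, 1),         # zero rotation, unit gain
         affine = c(1, 0, 0, 1, 0, 0),
         none = numeric(0))
}

#' Initialize an observer's belief over transformation parameters
#'
#' The belief is a multivariate Gaussian with the model's canonical mean —
#' the identity transformation (standard, affine), zero shift (shift), or
#' zero rotation and unit gain (rotation-scaling) — and precision equal to
#' the inverse of `prior_cov` (a 1e-6 jitter is added to the precision to
#' keep later solves well-conditioned).
#'
#' @param model One of `"standard"`, `"shift"`, `"rotscale"`, `"affine"`,
#'   `"none"`. Parameter order: standard `(a, b, c, d)`; shift
#'   `(s_x, s_y)`; rotscale `(dtheta [rad], gain)`; affine
#'   `(a, b, c, d, s_x, s_y)`.
#' @param prior_cov SPD prior covariance of dimension 4, 2, 2, or 6
#'   matching the model (ignored for `"none"`).
#' @return A list with class `vm_belief` (`model`, `mean`, `precision`).
#' @export
init_belief <- function(model, prior_cov = NULL) {
  model <- match.arg(model, observer_models)
  k <- belief_dim(model)
  if (k == 0L) {
    return(structure(list(model = model, mean = numeric(0),
                          precision = matrix(0, 0, 0)), class = "vm_belief"))
  }
  if (is.null(prior_cov) || !is.matrix(prior_cov) ||
      any(dim(prior_cov) != k)) {
    stop("prior_cov must be a ", k, "x", k, " SPD matrix for the '",
         model, "' model")
  }
  prec <- solve(prior_cov)
  # proportional jitter keeps the joint (noise, prior) scale invariance exact
  prec <- prec + 1e-6 * mean(diag(prec)) * diag(k)
  structure(list(model = model, mean = belief_mean0(model),
                 precision = (prec + t(prec)) / 2), class = "vm_belief")
}

wrap_angle <- function(x) {
  # wrap to (-pi, pi]
  y <- (x + pi) %% (2 * pi) - pi
  ifelse(y == -pi, pi, y)
}

#' Update an observer's belief with one trial's evidence
#'
#' Conjugate Gaussian update of the belief given the hand position and the
#' displayed cursor position. For the standard model the cursor is a linear
#' observation of the vectorized transformation through the design matrix
#' `A(h)`: the precision gains `A'A / cursor_var` and the mean solves the
#' usual Gaussian linear-model normal equations. The shift model observes
#' `v - h` directly; the affine model uses the 2x6 design with an appended
#' identity block; the rotation-scaling model observes the angular offset
#' and the radial gain in polar coordinates, with cross-covariance between
#' the two parameters carried in the joint 2x2 precision. The hand is
#' treated as noiseless.
#'
#' @param belief A `vm_belief` from [init_belief()].
#' @param hand,cursor Length-2 positions (cm). The rotation-scaling model
#'   requires `sqrt(sum(hand^2)) > 0.5`.
#' @param noise A [noise_model()].
#' @return The updated `vm_belief`.
#' @export
update_belief <- function(belief, hand, cursor, noise = noise_model()) {
  model <- belief$model
  if (model == "none") return(belief)
  s2 <- noise$cursor_var
  if (model %in% c("standard", "affine")) {
    A <- design_matrix(hand)
    if (model == "affine") A <- cbind(A, diag(2))
    prec_new <- belief$precision + crossprod(A) / s2
    rhs <- belief$precision %*% belief$mean + crossprod(A, cursor) / s2
  } else if (model == "shift") {
    prec_new <- belief$precision + diag(2) / s2
    rhs <- belief$precision %*% belief$mean + (cursor - hand) / s2
  } else { # rotscale
    r_h <- sqrt(sum(hand^2))
    if (r_h <= 0.5) {
      stop("rotation-scaling update requires the hand to be > 0.5 cm from ",
           "the origin")
    }
    th_h <- atan2(hand[2], hand[1])
    th_v <- atan2(cursor[2], cursor[1])
    r_v <- sqrt(sum(cursor^2))
    y <- c(wrap_angle(th_v - th_h), r_v)
    C <- rbind(c(1, 0), c(0, r_h))
    Rinv <- diag(c(1 / noise$angular_var, 1 / noise$radial_var))
    prec_new <- belief$precision + t(C) %*% Rinv %*% C
    rhs <- belief$precision %*% belief$mean + t(C) %*% Rinv %*% y
  }
  belief$mean <- drop(solve(prec_new, rhs))
  belief$precision <- (prec_new + t(prec_new)) / 2
  belief
}

#' Predict the next hand position from the current belief
#'
#' The observer takes the MAP estimate of the transformation (the mean of
#' its Gaussian belief) and applies its inverse to the target, so that the
#' predicted cursor lands on the target if the MAP estimate is correct.
#' The no-adaptation model always aims at the target centre.
#'
#' @param belief A `vm_belief`.
#' @param target Length-2 target position (cm).
#' @return Length-2 predicted hand position (cm).
#' @export
predict_hand <- function(belief, target) {
  switch(belief$model,
         none = target,
         standard = drop(invert_transform(unvec_transform(belief$mean)) %*%
                           target),
         shift = target - belief$mean,
         affine = {
           T <- unvec_transform(belief$mean[1:4])
           drop(invert_transform(T) %*% (target - belief$mean[5:6]))
         },
         rotscale = {
           g <- belief$mean[2]
           if (g <= 0.05) stop("MAP gain ", format(g), " below 0.05; ",
                               "prediction undefined")
           r <- sqrt(sum(target^2)) / g
           th <- atan2(target[2], target[1]) - belief$mean[1]
           c(r * cos(th), r * sin(th))
         })
}

#' Run an observer over one batch
#'
#' Resets the belief to the prior (the observer starts every transformation
#' batch with the same prior), then alternates prediction and update:
#' the prediction for trial `t` uses the evidence of trials `1 .. t-1`.
#'
#' @param model Model identity, see [init_belief()].
#' @param prior_cov SPD prior covariance matching the model.
#' @param batch A `vm_batch` (or any list with a `trials` data frame holding
#'   `target_x/y`, `hand_x/y`, `cursor_x/y`) with at least 2 trials.
#' @param noise A [noise_model()].
#' @return A matrix with one row per trial from the 2nd on, columns
#'   `pred_x`, `pred_y`.
#' @export
run_batch <- function(model, prior_cov, batch, noise = noise_model()) {
  tr <- batch$trials
  n <- nrow(tr)
  stopifnot(n >= 2)
  belief <- init_belief(model, prior_cov)
  preds <- matrix(NA_real_, n - 1, 2,
                  dimnames = list(NULL, c("pred_x", "pred_y")))
  for (t in seq_len(n)) {
    if (t >= 2) {
      preds[t - 1, ] <- predict_hand(belief, c(tr$target_x[t], tr$target_y[t]))
    }
    belief <- update_belief(belief, c(tr$hand_x[t], tr$hand_y[t]),
                            c(tr$cursor_x[t], tr$cursor_y[t]), noise)
  }
  preds
}

#' @export
print.vm_belief <- function(x, ...) {
  cat("<vm_belief> model '", x$model, "', mean [",
      paste(signif(x$mean, 4), collapse = ", "), "]\n", sep = "")
  invisible(x)
}
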