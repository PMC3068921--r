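#' Model-free adaptation vectors for one transformed batch
#'
#' Computes the perturbation vector (first-trial hand to displayed cursor,
#' `v1 - h1`), the second-trial target-hand vector (`h2 - x2*`), the
#' compensation vector (`T^{-1} x* - x*`, the hand offset that would place
#' the cursor on the second-trial target under the batch's true
#' transformation), the adaptation ratio (length of the target-hand vector
#' over length of the perturbation vector; zero-length perturbations give
#' `NA`), and the absolute angular difference between the directions of the
#' first and second targets.
#'
#' @param batch A transformed `vm_batch` with at least two trials.
#' @return A one-row data frame.
#' @export
compute_batch_vectors <- function(batch) {
  tr <- batch$trials
  if (batch$type != "transformed" || nrow(tr) < 2) {
    stop("batch must be transformed with at least 2 trials")
  }
  pert <- c(tr$cursor_x[1] - tr$hand_x[1], tr$cursor_y[1] - tr$hand_y[1])
  th <- c(tr$hand_x[2] - tr$target_x[2], tr$hand_y[2] - tr$target_y[2])
  x2 <- c(tr$target_x[2], tr$target_y[2])
  comp <- drop(invert_transform(batch$transform) %*% x2) - x2
  lp <- sqrt(sum(pert^2))
  ang <- function(v) atan2(v[2], v[1]) * 180 / pi
  dang <- abs(((ang(c(tr$target_x[2], tr$target_y[2])) -
                  ang(c(tr$target_x[1], tr$target_y[1])) + 180) %% 360) - 180)
  data.frame(pert_x = pert[1], pert_y = pert[2],
             target_hand_x = th[1], target_hand_y = th[2],
             comp_x = comp[1], comp_y = comp[2],
             adaptation_ratio = if (lp > 0) sqrt(sum(th^2)) / lp else NA_real_,
             target_angle_diff = dang)
}

#' Adaptation records for every eligible batch of a session
#'
#' @param session A `vm_session`.
#' @return A data frame with one row per transformed batch with at least
#'   two trials, as in [compute_batch_vectors()], plus a `batch` column.
#' @export
batch_vectors <- function(session) {
  keep <- which(vapply(session$batches, function(b) {
    b$type == "transformed" && nrow(b$trials) >= 2
  }, logical(1)))
  rows <- lapply(seq_along(keep), function(i) {
    cbind(batch = i, compute_batch_vectors(session$batches[[keep[i]]]))
  })
  do.call(rbind, rows)
}

#' Regression of adaptation on target-direction change
#'
#' Ordinary least squares of the adaptation ratio on the absolute angular
#' difference between successive target directions. A slope near zero
#' indicates that adaptation generalizes globally across the workspace
#' rather than decaying with target separation. Records with undefined
#' ratios are dropped, and records whose ratio exceeds `outlier_threshold`
#' (default 5) are removed as outliers, with the removed fraction reported.
#'
#' @param records Data frame from [batch_vectors()] (columns
#'   `adaptation_ratio` and `target_angle_diff`).
#' @param outlier_threshold Ratio above which a record is discarded.
#' @return A list: `slope` (per degree), `slope_p`, `intercept`,
#'   `outlier_frac`, `n_used`, `n_dropped_undefined`.
#' @export
generalization_regression <- function(records, outlier_threshold = 5) {
  ok <- !is.na(records$adaptation_ratio)
  n_undef <- sum(!ok)
  rec <- records[ok, ]
  out <- rec$adaptation_ratio > outlier_threshold
  rec <- rec[!out, ]
  if (nrow(rec) < 10) stop("fewer than 10 records after outlier removal")
  fit <- lm(adaptation_ratio ~ target_angle_diff, data = rec)
  sm <- suppressWarnings(summary(fit))$coefficients
  slope_p <- if (nrow(sm) < 2 || is.na(sm[2, 4])) NA_real_ else sm[2, 4]
  list(slope = unname(coef(fit)[2]), slope_p = unname(slope_p),
       intercept = unname(coef(fit)[1]),
       outlier_frac = mean(out), n_used = nrow(rec),
       n_dropped_undefined = n_undef)
}
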