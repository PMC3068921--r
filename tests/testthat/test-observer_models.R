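test_that("belief initialization uses the canonical means and inverted covariance", {
  b <- init_belief("standard", diag(4))
  expect_equal(b$mean, c(1, 0, 0, 1))
  expect_equal(b$precision, diag(4), tolerance = 1e-5)
  expect_equal(init_belief("shift", diag(2))$mean, c(0, 0))
  expect_equal(init_belief("rotscale", diag(2))$mean, c(0, 1))
  expect_equal(init_belief("affine", diag(6))$mean, c(1, 0, 0, 1, 0, 0))
  expect_error(init_belief("standard", diag(2)), "4x4")
})

test_that("conjugate updates match closed forms and a dogmatic prior is immovable", {
  # evidence consistent with identity leaves the identity mean fixed and
  # adds the design outer product to the precision
  b <- init_belief("standard", diag(4))
  b1 <- update_belief(b, c(0, 10), c(0, 10), noise_model(cursor_var = 1))
  expect_equal(b1$mean, c(1, 0, 0, 1), tolerance = 1e-9)
  expect_equal(b1$precision - b$precision, diag(c(0, 100, 0, 100)),
               tolerance = 1e-9)

  # dogmatic prior: posterior mean pinned at identity
  bd <- init_belief("standard", 1e-8 * diag(4))
  bd1 <- update_belief(bd, c(3, 9), c(5, 7))
  expect_equal(bd1$mean, c(1, 0, 0, 1), tolerance = 1e-4)

  # shift model scalar conjugate formula: tau^2/(tau^2 + sigma^2) * s_obs
  bs <- update_belief(init_belief("shift", diag(2)), c(0, 10), c(2, 10))
  expect_equal(bs$mean, c(1, 0), tolerance = 1e-5)
})

test_that("the standard model's posterior matches a brute-force grid oracle", {
  set.seed(21)
  prior_cov <- 0.25 * diag(4)
  evidence <- list(list(h = c(2, 9), v = c(3.5, 8)),
                   list(h = c(-4, 10), v = c(-3, 11)))
  b <- init_belief("standard", prior_cov)
  for (e in evidence) b <- update_belief(b, e$h, e$v)
  oracle <- grid_posterior_mean(c(1, 0, 0, 1), prior_cov, evidence, 1)
  # agreement within the grid resolution (0.15 per axis)
  expect_lt(max(abs(b$mean - oracle)), 0.15 / 2)
})

test_that("predictions invert the MAP transformation", {
  b <- init_belief("standard", diag(4)); b$mean <- c(2, 0, 0, 2)
  expect_equal(predict_hand(b, c(0, 10)), c(0, 5))
  expect_equal(predict_hand(init_belief("none"), c(3, 9)), c(3, 9))
  br <- init_belief("rotscale", diag(2)); br$mean <- c(pi / 2, 1)
  expect_equal(predict_hand(br, c(0, 10)), c(10, 0), tolerance = 1e-12)
  # cross-check against the rotation matrix inverse
  expect_equal(predict_hand(br, c(0, 10)),
               drop(invert_transform(rotation_scaling_matrix(pi / 2)) %*%
                      c(0, 10)), tolerance = 1e-12)
  ba <- init_belief("affine", diag(6)); ba$mean <- c(2, 0, 0, 2, 1, -1)
  expect_equal(predict_hand(ba, c(1, 9)), c(0, 5))
  br$mean <- c(0, 1e-4)
  expect_error(predict_hand(br, c(0, 10)), "gain")
})

test_that("predictions are invariant to joint scaling of noise and prior covariance", {
  set.seed(22)
  k <- 7
  tgt <- c(4, 12)
  ev <- list(h = c(1, 10), v = c(3, 8))
  for (model in c("standard", "shift", "affine")) {
    S <- random_spd(vmprior:::belief_dim(model))
    b1 <- update_belief(init_belief(model, S), ev$h, ev$v,
                        noise_model(cursor_var = 1))
    b2 <- update_belief(init_belief(model, k * S), ev$h, ev$v,
                        noise_model(cursor_var = k))
    expect_equal(predict_hand(b1, tgt), predict_hand(b2, tgt),
                 tolerance = 1e-9)
  }
  S <- random_spd(2)
  b1 <- update_belief(init_belief("rotscale", S), ev$h, ev$v,
                      noise_model(radial_var = 1, angular_var = 0.01))
  b2 <- update_belief(init_belief("rotscale", k * S), ev$h, ev$v,
                      noise_model(radial_var = k, angular_var = 0.01 * k))
  expect_equal(predict_hand(b1, tgt), predict_hand(b2, tgt),
               tolerance = 1e-9)
})

test_that("updating twice with the same evidence equals one update at halved noise", {
  set.seed(23)
  ev <- list(h = c(-2, 11), v = c(1, 9))
  for (model in c("standard", "shift")) {
    S <- random_spd(vmprior:::belief_dim(model))
    btwice <- update_belief(update_belief(init_belief(model, S),
                                          ev$h, ev$v, noise_model(1)),
                            ev$h, ev$v, noise_model(1))
    bhalf <- update_belief(init_belief(model, S), ev$h, ev$v,
                           noise_model(cursor_var = 0.5))
    expect_equal(btwice$mean, bhalf$mean, tolerance = 1e-9)
    expect_equal(btwice$precision, bhalf$precision, tolerance = 1e-9)
  }
})

test_that("the rotation-scaling noise is near-isotropic at 10 cm eccentricity", {
  nm <- noise_model()
  tangential_sd <- 10 * sqrt(nm$angular_var)
  radial_sd <- sqrt(nm$radial_var)
  expect_lt(abs(tangential_sd / radial_sd - 1), 0.01)
})

test_that("batch runs accumulate evidence with strictly growing precision", {
  set.seed(24)
  s <- quick_session(3L)
  b <- s$batches[[which(vapply(s$batches, function(b) nrow(b$trials) >= 3,
                               logical(1)))[1]]]
  S <- structured_prior()
  bel0 <- init_belief("standard", S)
  bel1 <- update_belief(bel0, c(b$trials$hand_x[1], b$trials$hand_y[1]),
                        c(b$trials$cursor_x[1], b$trials$cursor_y[1]))
  bel2 <- update_belief(bel1, c(b$trials$hand_x[2], b$trials$hand_y[2]),
                        c(b$trials$cursor_x[2], b$trials$cursor_y[2]))
  expect_gte(min(eigen(bel1$precision - bel0$precision,
                       symmetric = TRUE, only.values = TRUE)$values), -1e-9)
  expect_gte(min(eigen(bel2$precision - bel1$precision,
                       symmetric = TRUE, only.values = TRUE)$values), -1e-9)

  # run_batch's trial-3 prediction uses both earlier trials
  preds <- run_batch("standard", S, b)
  expect_equal(preds[2, ],
               unname(predict_hand(bel2, c(b$trials$target_x[3],
                                           b$trials$target_y[3]))),
               ignore_attr = TRUE)

  # perfect knowledge: belief pinned at the true transform hits the target
  T <- b$transform
  belT <- belief_with_precision("standard", 1e12 * diag(4))
  belT$mean <- vec_transform(T)
  tgt <- c(b$trials$target_x[2], b$trials$target_y[2])
  expect_equal(drop(T %*% predict_hand(belT, tgt)), tgt, tolerance = 1e-9)
})

test_that("compiled trial-2 errors agree with the reference observer path", {
  set.seed(25)
  s <- quick_session(20L)
  d <- vmprior:::trial2_data(s)
  nm <- noise_model()
  for (model in c("standard", "shift", "rotscale", "affine", "none")) {
    k <- vmprior:::belief_dim(model)
    Lam <- if (k > 0) solve(random_spd(k)) else matrix(0, 0, 0)
    ecpp <- vmprior:::trial2_errors_prec(Lam, model, d, nm)
    eref <- vapply(seq_len(nrow(d)), function(i) {
      bel <- belief_with_precision(model, Lam)
      bel <- update_belief(bel, d[i, 1:2], d[i, 3:4], nm)
      sqrt(sum((predict_hand(bel, d[i, 5:6]) - d[i, 7:8])^2))
    }, numeric(1))
    expect_equal(ecpp, eref, tolerance = 1e-8, ignore_attr = TRUE)
  }
})
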