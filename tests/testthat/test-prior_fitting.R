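test_that("the robust cost saturates per-batch errors at c", {
  pred <- rbind(c(0, 0), c(0, 0), c(0, 0))
  obs <- rbind(c(2, 0), c(0, 4), c(15, 0))
  expect_equal(robust_cost(pred, obs, robust_cost_spec(c = 10)), 16)
  expect_equal(robust_cost(obs, obs), 0)
  expect_error(robust_cost(pred, obs[1:2, ]), "same")

  # non-decreasing in any single error, constant above c
  set.seed(31)
  spec <- robust_cost_spec(c = 10)
  for (i in 1:50) {
    e <- runif(5, 0, 15)
    pred <- matrix(0, 5, 2); obs <- cbind(e, 0)
    base <- robust_cost(pred, obs, spec)
    j <- sample(5, 1)
    obs2 <- obs; obs2[j, 1] <- obs2[j, 1] + runif(1, 0, 5)
    expect_gte(robust_cost(pred, obs2, spec) + 1e-12, base)
    obs3 <- obs; obs3[j, 1] <- 12 + runif(1, 0, 10)
    obs4 <- obs; obs4[j, 1] <- 25
    expect_equal(robust_cost(pred, obs3, spec), robust_cost(pred, obs4, spec))
  }
})

test_that("fitted priors beat random priors and recover coupling structure", {
  set.seed(32)
  gen <- structured_prior(-0.85)
  s <- quick_session(40L, prior = gen, noise_sd = 1)
  fit <- fit_prior("standard", s, n_restarts = 8L)
  expect_true(all(eigen(fit$covariance, symmetric = TRUE,
                        only.values = TRUE)$values > 0))

  d <- vmprior:::trial2_data(s)
  spec <- robust_cost_spec()
  rand_costs <- replicate(100, {
    e <- vmprior:::trial2_errors_prec(solve(sample_random_prior()),
                                      "standard", d, noise_model())
    sum(pmin(e, spec$c))
  })
  expect_lt(fit$cost, min(rand_costs))

  # the strong generating b-c coupling is recovered in sign and magnitude
  r_fit <- pair_stat(fit$covariance, "bc")
  r_gen <- pair_stat(gen, "bc")
  expect_lt(abs(r_fit - r_gen), 0.3)

  # best-of-n cost is non-increasing in n on a fixed restart stream
  set.seed(33)
  f2 <- fit_prior("standard", s, n_restarts = 2L)
  set.seed(33)
  f6 <- fit_prior("standard", s, n_restarts = 6L)
  expect_lte(f6$cost, f2$cost)
})

test_that("scaling the noise variance rescales the prior without changing predictions", {
  set.seed(34)
  s <- quick_session(25L)
  d <- vmprior:::trial2_data(s)
  Lam <- solve(random_spd(4))
  e1 <- vmprior:::trial2_errors_prec(Lam, "standard", d,
                                     noise_model(cursor_var = 1))
  # doubled noise variance with halved precision (doubled covariance)
  e2 <- vmprior:::trial2_errors_prec(Lam / 2, "standard", d,
                                     noise_model(cursor_var = 2))
  expect_equal(e1, e2, tolerance = 1e-9)

  fit <- fit_prior("standard", s, n_restarts = 3L)
  e_fit <- vmprior:::trial2_errors_prec(fit$precision / 2, "standard", d,
                                        noise_model(cursor_var = 2))
  expect_equal(sum(pmin(e_fit, 10)), fit$cost, tolerance = 1e-6)
})

test_that("cross-validation groups follow the evenly-spaced modulo pattern", {
  set.seed(35)
  s <- quick_session(111L, prior = sample_random_prior())
  cv <- crossval_trial2("none", s, k = 10L)
  expect_equal(cv$batch[cv$group == 1][1:3], c(1L, 11L, 21L))
  expect_true(111L %in% cv$batch[cv$group == 1])
  expect_equal(cv$batch[cv$group == 2][1:3], c(2L, 12L, 22L))
  # groups partition the batches
  expect_setequal(cv$batch, seq_len(111L))
  expect_equal(anyDuplicated(cv$batch), 0L)
  expect_error(crossval_trial2("none", s, k = 1L), "at least 2")
  s5 <- s; s5$batches <- s$batches[1:5]
  expect_error(crossval_trial2("none", s5, k = 10L), "fewer")
})

test_that("all models are perfect on veridical noiseless data", {
  cfg_id <- generator_config(uniform_lo = 1 - 1e-9, uniform_hi = 1,
                             sigma_bc = 1e-12)
  set.seed(36)
  s <- simulate_session(0.05 * diag(4), cfg_id, quick_vcfg(12L, noise_sd = 0))
  tab <- compare_models(s, models = c("standard", "shift", "rotscale",
                                      "affine", "none"),
                        k = 4L, n_restarts = 2L, max_trial = 3L)
  expect_lt(max(tab$mean_error), 1e-6)
})

test_that("the no-adaptation model's error on shift data equals the shift magnitude", {
  # hand-built batches from a fully-compensating shift observer: on trial 2
  # the hand lands at target - s, so aiming at the target misses by |s|
  set.seed(37)
  shifts <- cbind(runif(20, -4, 4), runif(20, -4, 4))
  batches <- lapply(seq_len(20), function(i) {
    s <- shifts[i, ]
    t1 <- c(runif(1, -10, 10), runif(1, 6, 16))
    t2 <- c(runif(1, -10, 10), runif(1, 6, 16))
    structure(list(type = "transformed", transform = diag(2), hit = TRUE,
                   trials = data.frame(
                     trial = 1:2,
                     target_x = c(t1[1], t2[1]), target_y = c(t1[2], t2[2]),
                     hand_x = c(t1[1], t2[1] - s[1]),
                     hand_y = c(t1[2], t2[2] - s[2]),
                     cursor_x = c(t1[1] + s[1], t2[1]),
                     cursor_y = c(t1[2] + s[2], t2[2]))),
              class = "vm_batch")
  })
  s <- structure(list(batches = batches, config = generator_config(),
                      model = "shift", mode = "correlated",
                      cursor_noise_sd = 0, generating_prior = NULL,
                      subject = 1L, session = 1L), class = "vm_session")
  d <- vmprior:::trial2_data(s)
  e <- vmprior:::trial2_errors_prec(matrix(0, 0, 0), "none", d, noise_model())
  expect_equal(e, sqrt(rowSums(shifts^2)), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("model comparison ranks the generating standard observer best", {
  set.seed(38)
  s <- quick_session(80L, prior = structured_prior(-0.8,
                                                   v = c(0.2, 0.35, 0.35, 0.15)))
  tab <- compare_models(s, models = c("standard", "shift", "rotscale",
                                      "affine", "none"),
                        k = 5L, n_restarts = 3L, max_trial = 3L)
  t3 <- tab[tab$trial == 3L, ]
  expect_equal(t3$model[which.min(t3$mean_error)], "standard")
})

test_that("the origin sweep minimizes at the generating origin", {
  set.seed(39)
  s <- quick_session(50L)
  grid <- rbind(c(0, 0), c(0, -15), c(0, -30), c(12, 0), c(-12, 8))
  sw <- origin_sweep(s, grid = grid, n_restarts = 3L)
  expect_equal(nrow(sw), 5L)
  expect_equal(unname(unlist(sw[which.min(sw$mean_error), 1:2])), c(0, 0))

  # data generated about a shifted origin prefers that origin
  s2 <- translate_session(s, c(0, -30))
  sw2 <- origin_sweep(s2, grid = rbind(c(0, -30), c(0, 0)), n_restarts = 3L)
  expect_lt(sw2$mean_error[1], sw2$mean_error[2])

  sw1 <- origin_sweep(s, grid = rbind(c(0, 0)), n_restarts = 2L)
  expect_equal(nrow(sw1), 1L)
})
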