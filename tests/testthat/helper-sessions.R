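# shared fixtures: structured priors and small simulated sessions

# 4x4 prior covariance with a controlled b-c correlation (the structure the
# fitted priors are probed for)
structured_prior <- function(r_bc = -0.9, v = c(0.15, 0.3, 0.3, 0.1)) {
  S <- diag(v)
  S[2, 3] <- S[3, 2] <- r_bc * sqrt(v[2] * v[3])
  S
}

quick_vcfg <- function(n_batches = 30L, noise_sd = 1, restarts = 5L) {
  validation_config(n_datasets = 1L, n_transforms_per_dataset = n_batches,
                    cursor_noise_sd = noise_sd, n_fit_restarts = restarts)
}

quick_session <- function(n_batches = 30L, prior = structured_prior(),
                          noise_sd = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  simulate_session(prior, vcfg = quick_vcfg(n_batches, noise_sd), ...)
}

# translate every coordinate of a session by o (the transformations then act
# about o in the new frame)
translate_session <- function(session, o) {
  session$batches <- lapply(session$batches, function(b) {
    tr <- b$trials
    tr$target_x <- tr$target_x + o[1]; tr$target_y <- tr$target_y + o[2]
    tr$hand_x <- tr$hand_x + o[1]; tr$hand_y <- tr$hand_y + o[2]
    tr$cursor_x <- tr$cursor_x + o[1]; tr$cursor_y <- tr$cursor_y + o[2]
    b$trials <- tr
    b
  })
  session
}

# brute-force discretized posterior mean over vec(T) on a regular 4-D grid;
# independent oracle for the standard model's conjugate update
grid_posterior_mean <- function(prior_mean, prior_cov, evidence, sigma2,
                                npts = 21L, half_width = 3) {
  sds <- sqrt(diag(prior_cov))
  axes <- lapply(1:4, function(j) {
    seq(prior_mean[j] - half_width * sds[j],
        prior_mean[j] + half_width * sds[j], length.out = npts)
  })
  g <- as.matrix(expand.grid(axes))
  Lam <- solve(prior_cov)
  d <- sweep(g, 2, prior_mean)
  lp <- -0.5 * rowSums((d %*% Lam) * d)
  for (e in evidence) {
    A <- design_matrix(e$h)
    r <- sweep(g %*% t(A), 2, e$v)
    lp <- lp - rowSums(r^2) / (2 * sigma2)
  }
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  colSums(g * w)
}

# observer belief with an explicit precision (bypasses the covariance
# inversion of init_belief, for exact comparisons against the compiled path)
belief_with_precision <- function(model, precision) {
  structure(list(model = model, mean = vmprior:::belief_mean0(model),
                 precision = precision), class = "vm_belief")
}

random_spd <- function(k, sd = 1) {
  B <- matrix(rnorm(k * k, 0, sd), k, k)
  solve(crossprod(B) + 1e-6 * diag(k))
}

# look up one pair's statistic by name rather than by row position
pair_stat <- function(cov, pair, what = "r") {
  st <- cov_to_pair_stats(cov)
  st[[what]][st$pair == pair]
}
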