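# shared fixtures and independent oracles for the test suite

# a minimal valid episode data frame (standard schema labels)
make_episodes <- function(items, locations, months = 1L,
                          species = "testbird", feeder = FALSE,
                          altitude = "lowland") {
  n <- max(length(items), length(locations), length(months))
  data.frame(species = species, year = 2001L,
             month = rep_len(months, n),
             item = rep_len(items, n),
             location = rep_len(locations, n),
             altitude_band = rep_len(altitude, n),
             feeder_flag = rep_len(feeder, n),
             site_note = "", exclude_flag = FALSE,
             stringsAsFactors = FALSE)
}

write_episode_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE)
  path
}

# closed-form Pearson chi-square for a 2x2 table: n(ad - bc)^2 over the
# product of the four margins (independent oracle for the contingency tests)
chisq_2x2_closed_form <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c + d
  n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
}

# exhaustive enumeration of latent item-label configurations for a one-month
# instance with K identified items, fixed item probabilities `pi`, Dirichlet
# prior alpha on each location row, identified location counts y_kl, and
# unidentified episodes at locations `locs` (one entry per episode).
# Returns the marginal posterior probability matrix P[i, k] of episode i
# being item k, with theta integrated out analytically.
enumerate_assignment_posterior <- function(pi, y_kl, locs, alpha = 1) {
  n <- length(locs)
  k_n <- length(pi)
  l_n <- ncol(y_kl)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k_n)), n)))
  logw <- apply(grid, 1L, function(z) {
    t_kl <- y_kl
    for (i in seq_len(n)) t_kl[z[i], locs[i]] <- t_kl[z[i], locs[i]] + 1
    lw <- sum(log(pi)[z])
    for (k in seq_len(k_n))
      lw <- lw + sum(lgamma(alpha + t_kl[k, ])) -
        lgamma(sum(alpha + t_kl[k, ]))
    lw
  })
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  p <- matrix(0, n, k_n)
  for (k in seq_len(k_n))
    for (i in seq_len(n))
      p[i, k] <- sum(w[grid[, i] == k])
  p
}

# collapsed Gibbs sampler over the same instance using the package's update
# steps (latent assignment + conjugate theta), lambda held fixed at pi
gibbs_assignment_marginals <- function(pi, y_kl, locs, alpha = 1,
                                       n_iter = 4000, burn = 500, seed = 1) {
  set.seed(seed)
  k_n <- length(pi)
  l_n <- ncol(y_kl)
  u <- matrix(0L, 1L, l_n)
  for (l in locs) u[1L, l] <- u[1L, l] + 1L
  pi_mat <- matrix(pi, 1L, k_n)
  theta <- sample_theta(y_kl, alpha)
  acc <- matrix(0, k_n, l_n)
  kept <- 0L
  for (it in seq_len(n_iter)) {
    v <- sample_latent_items(pi_mat, theta, u)
    theta <- sample_theta(y_kl + v[1L, , ], alpha)
    if (it > burn) {
      acc <- acc + v[1L, , ]
      kept <- kept + 1L
    }
  }
  # per-location marginal probability of each item
  sweep(acc / kept, 2L, pmax(u[1L, ], 1L), "/")
}

fast_control <- function(chains = 2L, iterations = 800L, burn_in = 300L,
                         thin = 2L, ...) {
  mop_control(chains = chains, iterations = iterations, burn_in = burn_in,
              thin = thin, ...)
}
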