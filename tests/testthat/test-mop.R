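test_that("model inputs split identified and unidentified counts", {
  ep <- rbind(make_episodes("seed", "ground", months = 1L),
              make_episodes("unidentified", "ground", months = 3L),
              make_episodes("unidentified", "tree", months = 3L))
  inp <- build_mop_inputs(tally_episodes(ep))
  expect_equal(dim(inp$y), c(12L, 10L, 10L))
  expect_equal(sum(inp$y), 1)
  expect_equal(inp$u["Mar", "ground"], 1L)
  expect_equal(sum(inp$u), 2)
  expect_equal(unname(inp$n_month[3]), 2L)
  expect_false("unidentified" %in% inp$items)

  expect_error(build_mop_inputs(tally_episodes(ep[0, ], species = "x")),
               "all zero")

  # no unidentified episodes -> u identically zero
  inp2 <- build_mop_inputs(tally_episodes(make_episodes("seed", "tree")))
  expect_equal(sum(inp2$u), 0L)
})

test_that("latent assignment follows the item-location Bayes probabilities", {
  pi <- matrix(c(0.6, 0.4), 1)
  theta <- rbind(c(0.9, 0.1), c(0.2, 0.8))
  # location 1: P(item 1) = 0.6*0.9 / (0.6*0.9 + 0.4*0.2) = 0.54/0.62
  u <- matrix(c(5000L, 0L), 1)
  set.seed(1)
  v <- sample_latent_items(pi, theta, u)
  p_hat <- v[1, 1, 1] / 5000
  p_true <- 0.54 / 0.62
  expect_lt(abs(p_hat - p_true), 3 * sqrt(p_true * (1 - p_true) / 5000))
  # conservation within the cell
  expect_equal(apply(v, c(1, 3), sum), u, ignore_attr = TRUE)

  # pi concentrated on one item -> all assignments that item
  v1 <- sample_latent_items(matrix(c(1, 0), 1), theta,
                            matrix(c(20L, 30L), 1))
  expect_equal(sum(v1[1, 1, ]), 50)

  # identical theta rows -> assignment follows pi alone
  set.seed(2)
  v2 <- sample_latent_items(matrix(c(0.7, 0.3), 1),
                            rbind(c(0.5, 0.5), c(0.5, 0.5)),
                            matrix(c(10000L, 0L), 1))
  expect_lt(abs(v2[1, 1, 1] / 10000 - 0.7), 3 * sqrt(0.7 * 0.3 / 10000))

  # degenerate weights are an error, not a silent NaN
  expect_error(sample_latent_items(matrix(c(1, 1), 1),
                                   rbind(c(0, 1), c(0, 1)),
                                   matrix(c(3L, 0L), 1)),
               "degenerate")
})

test_that("theta update is the conjugate Dirichlet posterior", {
  set.seed(3)
  draws <- replicate(20000, sample_theta(matrix(c(3, 1), 1), alpha = 1)[1, 1])
  # posterior mean (alpha + 3) / (2 alpha + 4) = 4/6
  expect_lt(abs(mean(draws) - 2 / 3), 0.01)

  # zero counts: prior, uniform mean
  set.seed(4)
  d0 <- replicate(20000, sample_theta(matrix(0, 1, 4), alpha = 1)[1, 1])
  expect_lt(abs(mean(d0) - 0.25), 0.01)

  # rows always normalized
  th <- sample_theta(matrix(rpois(12, 5), 3, 4), alpha = 0.5)
  expect_equal(rowSums(th), rep(1, 3))

  # counts concentrated on one location dominate the prior as they grow
  thc <- replicate(2000, sample_theta(matrix(c(500, 0), 1), alpha = 1)[1, 1])
  expect_gt(mean(thc), 0.99)
})

test_that("log-frequency update respects the data and the smoothness prior", {
  # single loaded month, weak smoothing: posterior mean near the count
  n <- matrix(0, 12, 1)
  n[6, 1] <- 50
  x <- log(n + 0.5)
  tau <- 0.01
  set.seed(5)
  lam6 <- numeric(3000)
  for (i in 1:3000) {
    up <- sample_lambda(x, tau, n, mu0 = log(5), s0 = 10,
                        a_tau = 0.01, b_tau = 1, proposal_sd = 0.3)
    x <- up$log_lambda
    tau <- min(up$tau, 0.05)   # keep smoothing weak for this check
    lam6[i] <- exp(x[6, 1])
  }
  expect_lt(abs(mean(lam6[-(1:500)]) - 50) / 50, 0.1)
})

test_that("stronger smoothness priors give flatter seasonal curves", {
  truth <- synthetic_truth(seed = 9)
  gen <- generate_episodes(truth)
  ct <- tally_episodes(gen$episodes, schema = truth$schema)
  month_var <- sapply(c(2, 200, 20000), function(a_tau) {
    fit <- fit_mop(ct, fast_control(chains = 1L, a_tau = a_tau, b_tau = 0.5),
                   seed = 5)
    mean(apply(log(fit$lambda_mean), 2, var))
  })
  expect_true(all(diff(month_var) < 0))
})

test_that("fits are reproducible and conserve episode totals in every draw", {
  truth <- synthetic_truth(n_items = 3L, n_locations = 2L, n_per_month = 20L,
                           seed = 12)
  gen <- generate_episodes(truth)
  ct <- tally_episodes(gen$episodes, schema = truth$schema)
  fit1 <- fit_mop(ct, fast_control(), seed = 99)
  fit2 <- fit_mop(ct, fast_control(), seed = 99)
  expect_identical(fit1$draws, fit2$draws)
  fit3 <- fit_mop(ct, fast_control(), seed = 100)
  expect_false(identical(fit1$draws$log_lambda, fit3$draws$log_lambda))

  # conservation: complete counts in every kept draw sum to N_m
  n_m <- totals_by_month(ct)
  for (ch in 1:2) {
    sums <- apply(fit1$draws$n[, ch, , ], c(1, 2), sum)
    expect_true(all(abs(sweep(sums, 2, n_m)) < 1e-9))
  }
  expect_equal(rowSums(fit1$complete_counts), n_m, ignore_attr = TRUE)

  # diagnostics cover every log-frequency cell and each precision
  expect_equal(nrow(fit1$diagnostics), 12 * 3 + 3)
  expect_true(all(is.finite(fit1$diagnostics$rhat)))
})

test_that("with no unidentified episodes the posterior counts are the data", {
  truth <- synthetic_truth(n_items = 3L, n_locations = 2L, n_per_month = 15L,
                           miss_prob = c(0, 0), seed = 21)
  gen <- generate_episodes(truth)
  ct <- tally_episodes(gen$episodes, schema = truth$schema)
  fit <- fit_mop(ct, fast_control(chains = 1L), seed = 7)
  y_mk <- apply(build_mop_inputs(ct)$y, c(1, 2), sum)
  expect_equal(fit$complete_counts, y_mk, ignore_attr = TRUE)
  expect_identical(as.matrix(compute_mop(fit)),
                   as.matrix(rop_identified_only(ct)))
})

test_that("MOPs are rounded-count proportions, half away from zero", {
  fake <- structure(list(
    complete_counts = matrix(c(3.6, 1.4, rep(c(2.5, 1.5), 11)), 12, 2,
                             byrow = TRUE,
                             dimnames = list(month.abb, c("A", "B"))),
    species = "fake"), class = "mop_fit")
  mop <- compute_mop(fake)
  expect_equal(unname(mop$values[1, ]), c(0.8, 0.2))
  # 2.5 -> 3 and 1.5 -> 2 under half-away-from-zero (banker's would give 2/2)
  expect_equal(unname(mop$values[2, ]), c(3 / 5, 2 / 5))
  fake0 <- fake
  fake0$complete_counts[3, ] <- c(0.2, 0.2)
  expect_false(compute_mop(fake0)$defined[3])
})

test_that("split-Rhat separates mixed from unmixed chains", {
  set.seed(31)
  mixed <- list(rnorm(500), rnorm(500))
  expect_lt(split_rhat(mixed), 1.05)
  apart <- list(rnorm(500), rnorm(500, mean = 6))
  expect_gt(split_rhat(apart), 2)
  # independent hand computation on a tiny fixed case
  ch <- list(c(1, 2, 3, 4), c(2, 3, 4, 5))
  halves <- list(c(1, 2), c(3, 4), c(2, 3), c(4, 5))
  w <- mean(sapply(halves, var))
  b <- 2 * var(sapply(halves, mean))
  expect_equal(split_rhat(ch), sqrt((w / 2 + b / 2) / w))
})
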