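#' MCMC and prior settings for the diet imputation model
#'
#' Collects the tunable parameters of [fit_mop()]: the Dirichlet
#' concentration for the location-given-item rows, the Gaussian level prior
#' on log expected frequencies, the Gamma prior on the seasonal random-walk
#' precision, and the sampler settings.
#'
#' @param chains number of independent MCMC chains.
#' @param iterations iterations per chain (including burn-in).
#' @param burn_in iterations discarded per chain; must be < `iterations`.
#' @param thin keep every `thin`-th post-burn-in iteration.
#' @param proposal_sd standard deviation of the Gaussian random-walk proposal
#'   for log expected frequencies.
#' @param alpha Dirichlet concentration of the prior on each
#'   location-given-item probability row (flat when 1).
#' @param mu0 prior mean of the log-frequency level; `NULL` (default) sets it
#'   from the data as `log(mean monthly identified count per item + 0.5)`.
#' @param s0 prior standard deviation of the log-frequency level.
#' @param a_tau,b_tau shape and rate of the Gamma prior on each item's
#'   seasonal random-walk precision.
#' @return A list of class `"mop_control"`.
#' @export
mop_control <- function(chains = 3L, iterations = 20000L, burn_in = 10000L,
                        thin = 10L, proposal_sd = 0.3, alpha = 1,
                        mu0 = NULL, s0 = 2, a_tau = 2, b_tau = 0.5) {
  stopifnot(chains >= 1L, iterations > burn_in, burn_in >= 0L, thin >= 1L,
            proposal_sd > 0, alpha > 0, s0 > 0, a_tau > 0, b_tau > 0)
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 proposal_sd = proposal_sd, alpha = alpha, mu0 = mu0, s0 = s0,
                 a_tau = a_tau, b_tau = b_tau),
            class = "mop_control")
}

#' Split a counts tensor into model inputs
#'
#' Separates the identified-item counts `y[m, k, l]` (over the identified
#' item categories) from the unidentified-item counts `u[m, l]`, and records
#' the monthly totals `N_m`. Episodes whose *location* is "unidentified" stay
#' in their location column: the unidentified location is an observed
#' reporting category, only the dietary item has a missingness mechanism.
#'
#' @param counts a `"counts_tensor"`.
#' @return A list with elements `y` (12 x K x L integer array), `u` (12 x L
#'   integer matrix), `n_month` (length-12 totals), `items` (identified item
#'   labels), `locations`, and `species`.
#' @export
build_mop_inputs <- function(counts) {
  stopifnot(inherits(counts, "counts_tensor"))
  if (sum(counts) == 0L) stop("counts tensor is all zero; nothing to fit")
  items <- dimnames(counts)$item
  keep <- items != "unidentified"
  arr <- unclass(counts)
  y <- arr[, keep, , drop = FALSE]
  u <- arr[, !keep, , drop = TRUE]
  if (is.null(dim(u))) u <- matrix(u, nrow = 12L)
  dimnames(u) <- list(month = month_labels(),
                      location = dimnames(counts)$location)
  list(y = y, u = u, n_month = totals_by_month(counts),
       items = items[keep], locations = dimnames(counts)$location,
       species = attr(counts, "species"))
}

#' Sample latent item labels for unidentified episodes
#'
#' Each unidentified episode observed in month `m` at location `l` is
#' assigned identified item `k` with probability proportional to
#' `lambda[m, k] * theta[k, l]` — the month's expected foraging frequency of
#' the item times the shared probability of seeing that item foraged at that
#' location. This is the Bayes posterior over items given the location, under
#' the assumption that identified and unidentified episodes share the same
#' item-to-location law.
#'
#' @param lambda numeric matrix `12 x K` of expected monthly foraging
#'   frequencies (any positive scale; only within-month ratios matter).
#' @param theta numeric matrix `K x L`; row `k` is the probability
#'   distribution of locations for item `k`.
#' @param u integer matrix `12 x L` of unidentified-episode counts.
#' @return Integer array `12 x K x L` of latent item counts `v`, satisfying
#'   `apply(v, c(1, 3), sum) == u`.
#' @export
sample_latent_items <- function(lambda, theta, u) {
  n_k <- ncol(lambda)
  n_l <- ncol(theta)
  stopifnot(nrow(theta) == n_k, nrow(u) == nrow(lambda), ncol(u) == n_l)
  v <- array(0L, dim = c(nrow(lambda), n_k, n_l))
  cells <- which(u > 0L, arr.ind = TRUE)
  for (i in seq_len(nrow(cells))) {
    m <- cells[i, 1L]; l <- cells[i, 2L]
    w <- lambda[m, ] * theta[, l]
    s <- sum(w)
    if (!is.finite(s) || s <= 0)
      stop("degenerate assignment weights in month ", m, ", location ", l,
           ": all lambda * theta are zero")
    v[m, , l] <- as.integer(stats::rmultinom(1L, u[m, l], w))
  }
  v
}

#' Sample the location-given-item probabilities
#'
#' Conjugate update: with a Dirichlet(`alpha`) prior on each row, the full
#' conditional of row `k` given the complete (identified + latent) location
#' counts of item `k` is Dirichlet(`alpha + counts`).
#'
#' @param loc_counts numeric matrix `K x L` of complete location counts per
#'   item.
#' @param alpha Dirichlet prior concentration (scalar).
#' @return A `K x L` matrix with rows summing to 1.
#' @export
sample_theta <- function(loc_counts, alpha = 1) {
  g <- matrix(stats::rgamma(length(loc_counts),
                            shape = as.vector(loc_counts) + alpha, rate = 1),
              nrow = nrow(loc_counts))
  g / rowSums(g)
}

#' Update log expected frequencies and seasonal precisions
#'
#' One Metropolis-within-Gibbs sweep. Complete monthly item counts are
#' modelled as `n[m, k] ~ Poisson(lambda[m, k])` (the Poisson representation
#' of a multinomial conditioned on monthly totals). The prior on
#' `log lambda[., k]` is a circular first-order Gaussian random walk with
#' precision `tau[k]` (December adjacent to January) plus a Normal(`mu0`,
#' `s0^2`) prior on the 12-month mean level. Log frequencies are updated
#' month by month (all items of a month jointly vectorised, items being
#' conditionally independent) with Gaussian proposals; each `tau[k]` is then
#' drawn from its conjugate Gamma full conditional
#' `Gamma(a_tau + 11/2, b_tau + S_k/2)` where `S_k` sums the 12 circular
#' squared increments (the circular random-walk structure has rank 11).
#'
#' @param log_lambda numeric matrix `12 x K`, current state.
#' @param tau numeric vector of length K, current precisions.
#' @param n numeric matrix `12 x K` of complete monthly item counts.
#' @param mu0,s0,a_tau,b_tau prior settings (see [mop_control()]).
#' @param proposal_sd Gaussian proposal standard deviation.
#' @return A list with updated `log_lambda`, `tau`, and the sweep's
#'   `accepted` proposal count (out of `12 * K`).
#' @export
sample_lambda <- function(log_lambda, tau, n, mu0, s0, a_tau, b_tau,
                          proposal_sd) {
  n_m <- nrow(log_lambda)
  n_k <- ncol(log_lambda)
  x <- log_lambda
  xbar <- colMeans(x)
  accepted <- 0L
  for (m in seq_len(n_m)) {
    prev <- if (m == 1L) n_m else m - 1L
    nxt <- if (m == n_m) 1L else m + 1L
    cur <- x[m, ]
    prop <- cur + stats::rnorm(n_k, 0, proposal_sd)
    # Poisson likelihood term
    d_lik <- n[m, ] * (prop - cur) - (exp(prop) - exp(cur))
    # circular RW increments touching month m
    d_rw <- -tau / 2 * ((prop - x[prev, ])^2 + (x[nxt, ] - prop)^2 -
                        (cur - x[prev, ])^2 - (x[nxt, ] - cur)^2)
    # mean-level prior; xbar moves by (prop - cur) / n_m
    xbar_prop <- xbar + (prop - cur) / n_m
    d_lev <- -((xbar_prop - mu0)^2 - (xbar - mu0)^2) / (2 * s0^2)
    log_acc <- d_lik + d_rw + d_lev
    if (anyNA(log_acc))
      stop("non-finite acceptance ratio in log-frequency update; ",
           "check proposal_sd and data scale")
    take <- log(stats::runif(n_k)) < log_acc
    if (any(take)) {
      x[m, take] <- prop[take]
      xbar[take] <- xbar_prop[take]
      accepted <- accepted + sum(take)
    }
  }
  inc <- x - x[c(n_m, seq_len(n_m - 1L)), , drop = FALSE]
  s_k <- colSums(inc^2)
  tau_new <- stats::rgamma(n_k, shape = a_tau + (n_m - 1) / 2,
                           rate = b_tau + s_k / 2)
  list(log_lambda = x, tau = tau_new, accepted = accepted)
}

#' Fit the hierarchical Bayesian diet imputation model
#'
#' Estimates monthly expected foraging frequencies of each identified dietary
#' item while imputing the items of unidentified feeding episodes. The model
#' assumes (1) identified and unidentified episodes share a single
#' location-given-item probability law per species, so the foraging location
#' of an unidentified episode is informative about its item, and (2) expected
#' foraging frequencies are seasonally autocorrelated on the 12-month cycle,
#' which stabilises months with few observations. Inference is by
#' Metropolis-within-Gibbs: latent item assignments, the location-given-item
#' rows (conjugate Dirichlet), log frequencies (random-walk Metropolis) and
#' the per-item seasonal precisions (conjugate Gamma) are updated in turn.
#'
#' @param counts a `"counts_tensor"` for one species from [tally_episodes()].
#' @param control a [mop_control()] list of prior and sampler settings.
#' @param seed master integer seed; chain seeds are derived from it, and the
#'   fit is exactly reproducible given the same seed and control.
#' @return An object of class `"mop_fit"` with components:
#'   \describe{
#'     \item{complete_counts}{12 x K posterior-mean complete (identified +
#'       imputed) monthly item counts; each month sums to the month's episode
#'       total.}
#'     \item{lambda_mean, theta_mean, tau_mean}{posterior means.}
#'     \item{draws}{thinned post-burn-in draws: `log_lambda`
#'       (`draw x chain x 12 x K`), `theta`, `tau`, `n` (complete counts).}
#'     \item{diagnostics}{data frame of split-Rhat and effective sample size
#'       per monitored scalar.}
#'     \item{accept_rate}{Metropolis acceptance rate of the log-frequency
#'       updates.}
#'   }
#' @seealso [compute_mop()] to turn the fit into a composition table.
#' @examples
#' truth <- synthetic_truth(n_items = 3, n_locations = 2,
#'                          n_per_month = 15, seed = 1)
#' ep <- generate_episodes(truth)
#' ct <- tally_episodes(ep$episodes, schema = truth$schema)
#' fit <- fit_mop(ct, mop_control(chains = 2, iterations = 400,
#'                                burn_in = 200, thin = 2), seed = 1)
#' fit
#' compute_mop(fit)
#' @export
fit_mop <- function(counts, control = mop_control(), seed = 1L) {
  stopifnot(inherits(control, "mop_control"))
  inp <- build_mop_inputs(counts)
  y_mk <- apply(inp$y, c(1L, 2L), sum)            # identified counts by month/item
  y_kl <- apply(inp$y, c(2L, 3L), sum)            # identified counts by item/location
  n_k <- length(inp$items)
  n_l <- length(inp$locations)
  has_missing <- sum(inp$u) > 0L
  mu0 <- if (is.null(control$mu0)) log(mean(y_mk) + 0.5) else control$mu0

  n_keep <- (control$iterations - control$burn_in) %/% control$thin
  draws <- list(
    log_lambda = array(NA_real_, c(n_keep, control$chains, 12L, n_k)),
    theta = array(NA_real_, c(n_keep, control$chains, n_k, n_l)),
    tau = array(NA_real_, c(n_keep, control$chains, n_k)),
    n = array(NA_real_, c(n_keep, control$chains, 12L, n_k)))
  accepted <- 0L

  chain_seeds <- (as.integer(seed) * 1000L + seq_len(control$chains)) %% 2147483629L
  for (ch in seq_len(control$chains)) {
    set.seed(chain_seeds[ch])
    # initial state: identified counts plus the month's unidentified episodes
    # spread uniformly over items
    n0 <- y_mk + rowSums(inp$u) / n_k
    log_lambda <- log(n0 + 0.5)
    theta <- sample_theta(y_kl, control$alpha)
    tau <- rep(control$a_tau / control$b_tau, n_k)
    kept <- 0L
    for (it in seq_len(control$iterations)) {
      if (has_missing) {
        v <- sample_latent_items(exp(log_lambda), theta, inp$u)
        n_complete <- y_mk + apply(v, c(1L, 2L), sum)
        loc_counts <- y_kl + apply(v, c(2L, 3L), sum)
      } else {
        n_complete <- y_mk
        loc_counts <- y_kl
      }
      theta <- sample_theta(loc_counts, control$alpha)
      up <- sample_lambda(log_lambda, tau, n_complete, mu0, control$s0,
                          control$a_tau, control$b_tau, control$proposal_sd)
      log_lambda <- up$log_lambda
      tau <- up$tau
      if (it > control$burn_in) accepted <- accepted + up$accepted
      if (it > control$burn_in &&
          (it - control$burn_in) %% control$thin == 0L) {
        kept <- kept + 1L
        draws$log_lambda[kept, ch, , ] <- log_lambda
        draws$theta[kept, ch, , ] <- theta
        draws$tau[kept, ch, ] <- tau
        draws$n[kept, ch, , ] <- n_complete
      }
    }
  }

  complete_counts <- apply(draws$n, c(3L, 4L), mean)
  dimnames(complete_counts) <- list(month = month_labels(), item = inp$items)
  lambda_mean <- apply(exp(draws$log_lambda), c(3L, 4L), mean)
  dimnames(lambda_mean) <- dimnames(complete_counts)
  theta_mean <- apply(draws$theta, c(3L, 4L), mean)
  dimnames(theta_mean) <- list(item = inp$items, location = inp$locations)
  tau_mean <- apply(draws$tau, 2:3, mean)
  tau_mean <- colMeans(tau_mean)
  names(tau_mean) <- inp$items

  structure(
    list(complete_counts = complete_counts, lambda_mean = lambda_mean,
         theta_mean = theta_mean, tau_mean = tau_mean, draws = draws,
         diagnostics = mop_diagnostics(draws, inp$items),
         accept_rate = accepted /
           ((control$iterations - control$burn_in) * control$chains * 12 * n_k),
         inputs = inp, control = control, seed = as.integer(seed),
         species = inp$species),
    class = "mop_fit")
}

# split-Rhat (each chain halved) and effective sample size per scalar,
# for every log-frequency cell and each seasonal precision
mop_diagnostics <- function(draws, items) {
  n_keep <- dim(draws$log_lambda)[1]
  if (n_keep < 4L) {
    return(data.frame(parameter = character(), rhat = numeric(),
                      ess = numeric(), stringsAsFactors = FALSE))
  }
  scalar_chains <- scalar_chains_or_matrix
  rows <- list()
  for (k in seq_along(items)) {
    for (m in 1:12) {
      ch <- scalar_chains(draws$log_lambda[, , m, k, drop = TRUE])
      rows[[length(rows) + 1L]] <-
        data.frame(parameter = sprintf("log_lambda[%s,%s]",
                                       month_labels()[m], items[k]),
                   rhat = split_rhat(ch), ess = ess_scalar(ch),
                   stringsAsFactors = FALSE)
    }
    ch <- scalar_chains(draws$tau[, , k, drop = TRUE])
    rows[[length(rows) + 1L]] <-
      data.frame(parameter = sprintf("tau[%s]", items[k]),
                 rhat = split_rhat(ch), ess = ess_scalar(ch),
                 stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

scalar_chains_or_matrix <- function(a) {
  if (is.null(dim(a))) list(a) else lapply(seq_len(ncol(a)), function(j) a[, j])
}

#' Split-Rhat convergence diagnostic for a scalar
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half, so within-chain drift also inflates the statistic.
#'
#' @param chains a list of numeric vectors (one per chain) or a matrix with
#'   one column per chain.
#' @return The split-Rhat value (1 at perfect mixing).
#' @export
split_rhat <- function(chains) {
  if (!is.list(chains)) chains <- scalar_chains_or_matrix(chains)
  halves <- unlist(lapply(chains, function(v) {
    h <- length(v) %/% 2L
    list(v[seq_len(h)], v[h + seq_len(h)])
  }), recursive = FALSE)
  m <- length(halves)
  n <- length(halves[[1]])
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  w <- mean(vars)
  b <- n * stats::var(means)
  if (w == 0) return(1)
  sqrt(((n - 1) / n * w + b / n) / w)
}

ess_scalar <- function(chains) {
  v <- unlist(chains)
  if (stats::var(v) == 0) return(length(v))
  sum(vapply(chains,
             function(x) unname(coda::effectiveSize(coda::mcmc(x))), 0))
}

#' Model-aided observation proportions (MOPs)
#'
#' Converts a fitted imputation model into a monthly composition table over
#' the identified items: the posterior-mean complete (identified + imputed)
#' count of each item is rounded half-away-from-zero to an integer, and the
#' rounded counts are normalised within each month. Months whose rounded
#' counts sum to zero are flagged undefined.
#'
#' @param fit a `"mop_fit"` from [fit_mop()].
#' @return A `"composition_table"` with `kind = "MOP"`.
#' @export
compute_mop <- function(fit) {
  stopifnot(inherits(fit, "mop_fit"))
  rounded <- round_half_up(fit$complete_counts)
  n_m <- rowSums(rounded)
  composition_table(rounded / ifelse(n_m > 0, n_m, NA_real_), n_m,
                    kind = "MOP", species = fit$species)
}

# half-away-from-zero rounding (counts are nonnegative); base round() is
# round-half-even, which would map 0.5 and 1.5 both downwards/evenwards
round_half_up <- function(x) floor(x + 0.5)

#' @export
print.mop_fit <- function(x, ...) {
  cat("Bayesian diet imputation model fit for species:", x$species, "\n")
  cat("  ", length(x$inputs$items), " identified items x ",
      length(x$inputs$locations), " locations; ",
      sum(x$inputs$y), " identified and ", sum(x$inputs$u),
      " unidentified episodes\n", sep = "")
  cat(sprintf("  %d chain(s), %d iterations (%d burn-in, thin %d); MH acceptance %.2f\n",
              x$control$chains, x$control$iterations, x$control$burn_in,
              x$control$thin, x$accept_rate))
  if (nrow(x$diagnostics) > 0L)
    cat(sprintf("  max split-Rhat %.3f, min ESS %.0f\n",
                max(x$diagnostics$rhat), min(x$diagnostics$ess)))
  invisible(x)
}

#' @export
summary.mop_fit <- function(object, ...) {
  out <- list(species = object$species,
              complete_counts = object$complete_counts,
              theta_mean = object$theta_mean,
              tau_mean = object$tau_mean,
              diagnostics = object$diagnostics,
              accept_rate = object$accept_rate,
              mop = compute_mop(object))
  class(out) <- "summary.mop_fit"
  out
}

#' @export
print.summary.mop_fit <- function(x, digits = 3, ...) {
  cat("Posterior-mean complete monthly counts (identified + imputed):\n")
  print(round(x$complete_counts, 1))
  cat("\nPosterior-mean location-given-item probabilities:\n")
  print(round(x$theta_mean, digits))
  cat("\n")
  print(x$mop, digits = digits)
  if (nrow(x$diagnostics) > 0L) {
    worst <- x$diagnostics[which.max(x$diagnostics$rhat), ]
    cat(sprintf("\nWorst split-Rhat: %.3f (%s); min ESS %.0f\n",
                worst$rhat, worst$parameter, min(x$diagnostics$ess)))
  }
  invisible(x)
}

#' @export
coef.mop_fit <- function(object, ...) object$lambda_mean

#' @export
plot.mop_fit <- function(x, type = c("mop", "lambda"), ...) {
  type <- match.arg(type)
  if (type == "mop") {
    tab <- compute_mop(x)
    vals <- t(tab$values)
    vals[is.na(vals)] <- 0
    graphics::barplot(vals, col = grDevices::hcl.colors(nrow(vals), "Spectral"),
                      legend.text = rownames(vals),
                      args.legend = list(x = "topright", cex = 0.6),
                      ylab = "proportion", main = paste("MOP,", x$species), ...)
  } else {
    graphics::matplot(1:12, x$lambda_mean, type = "b", pch = 1,
                      xlab = "month", ylab = "expected foraging frequency",
                      main = paste("Posterior mean frequencies,", x$species),
                      ...)
  }
  invisible(x)
}
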