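#' Split rank-normalized R-hat convergence diagnostic
#'
#' Computes the potential-scale-reduction statistic on split chains after
#' rank-normalization, reporting the maximum of the bulk statistic and the
#' folded (tail-sensitive) statistic. Values near 1 indicate that the
#' chains sample the same distribution; the conventional convergence
#' threshold used throughout this package is 1.01.
#'
#' @param draws A matrix (iterations x chains) for one parameter, or a
#'   \code{coda::mcmc.list}, in which case a named vector with one value
#'   per parameter is returned.
#' @return R-hat value(s), >= 1 up to floating error; exactly-constant
#'   draws return 1.
#' @export
compute_rhat <- function(draws) {
  if (inherits(draws, "mcmc.list")) {
    params <- coda::varnames(draws)
    mats <- lapply(draws, as.matrix)
    out <- vapply(params, function(p) {
      compute_rhat(sapply(mats, function(m) m[, p]))
    }, numeric(1))
    return(out)
  }
  m <- as.matrix(draws)
  if (ncol(m) < 2L) stop("at least 2 chains are required")
  if (nrow(m) < 10L) stop("at least 10 draws per chain are required")
  max(.rhat_basic(.rank_normalize(.split_chains(m))),
      .rhat_basic(.rank_normalize(.split_chains(abs(m - stats::median(m))))))
}

.split_chains <- function(m) {
  n <- nrow(m)
  h <- floor(n / 2)
  cbind(m[seq_len(h), , drop = FALSE],
        m[(n - h + 1):n, , drop = FALSE])
}

.rank_normalize <- function(m) {
  s <- length(m)
  r <- rank(m, ties.method = "average")
  matrix(stats::qnorm((r - 3 / 8) / (s + 1 / 4)), nrow = nrow(m))
}

.rhat_basic <- function(m) {
  n <- nrow(m)
  cm <- colMeans(m)
  w <- mean(apply(m, 2, stats::var))
  b <- n * stats::var(cm)
  if (!is.finite(w) || w == 0) return(1)
  # clamp at 1: sampling noise can push the ratio slightly below
  max(1, sqrt(((n - 1) / n * w + b / n) / w))
}

# JAGS model for the hierarchical hyperbolic discounting fit. Participant
# log(k) values share a normal population distribution; lapse and acuity
# are exchangeable across participants with weakly-informative priors.
.jags_hyperbolic <- function(has_data) {
  lik <- if (has_data) "
  for (i in 1:N) {
    svd[i] <- llA[i] / (1 + k[pid[i]] * llD[i]) -
              ssA[i] / (1 + k[pid[i]] * ssD[i])
    pr[i] <- eps[pid[i]] + (1 - 2 * eps[pid[i]]) * phi(svd[i] / alpha[pid[i]])
    y[i] ~ dbern(pr[i])
  }" else ""
  paste0("model {
  mu ~ dnorm(prior_mu, 1 / (prior_sd^2))
  sigma ~ dnorm(0, 1 / (sigma_sd^2)) T(0,)
  tau <- 1 / (sigma^2)
  for (p in 1:P) {
    logk[p] ~ dnorm(mu, tau)
    eps[p] ~ dbeta(eps_a, eps_b)
    alpha[p] ~ dnorm(0, 1 / (alpha_sd^2)) T(0,)
    k[p] <- exp(logk[p])
  }", lik, "\n}")
}

.jags_ebert_prelec <- function() {
  "model {
  mu_a ~ dnorm(0.01, 1 / (0.05^2)) T(0,)
  sig_a ~ dnorm(0, 1 / (0.05^2)) T(0,)
  mu_b ~ dnorm(1, 1 / (0.5^2)) T(0,)
  sig_b ~ dnorm(0, 1 / (0.5^2)) T(0,)
  for (p in 1:P) {
    a[p] ~ dnorm(mu_a, 1 / (sig_a^2)) T(0,)
    b[p] ~ dnorm(mu_b, 1 / (sig_b^2)) T(0.05,)
    eps[p] ~ dbeta(eps_a, eps_b)
    alpha[p] ~ dnorm(0, 1 / (alpha_sd^2)) T(0,)
  }
  for (i in 1:N) {
    svd[i] <- llA[i] * exp(-pow(a[pid[i]] * llD[i], b[pid[i]])) -
              ssA[i] * exp(-pow(a[pid[i]] * ssD[i], b[pid[i]]))
    pr[i] <- eps[pid[i]] + (1 - 2 * eps[pid[i]]) * phi(svd[i] / alpha[pid[i]])
    y[i] ~ dbern(pr[i])
  }
}"
}

# Coarse per-participant profile likelihood over a log(k) grid; used only
# to initialize the chains in a sensible region.
.crude_logk <- function(d) {
  grid <- seq(-9, 1, by = 0.1)
  y <- as.integer(d$choice == "LL")
  ll <- vapply(grid, function(g) {
    k <- exp(g)
    svd <- d$ll_amount / (1 + k * d$ll_delay_days) -
      d$ss_amount / (1 + k * d$ss_delay_days)
    pr <- 0.02 + 0.96 * stats::pnorm(svd / 4)
    sum(stats::dbinom(y, 1, pr, log = TRUE))
  }, numeric(1))
  grid[which.max(ll)]
}

.crude_ep <- function(d) {
  a_grid <- exp(seq(log(5e-4), log(0.2), length.out = 16))
  b_grid <- seq(0.4, 1.8, by = 0.2)
  y <- as.integer(d$choice == "LL")
  best <- c(0.01, 1); best_ll <- -Inf
  for (a in a_grid) for (b in b_grid) {
    svd <- d$ll_amount * exp(-(a * d$ll_delay_days)^b) -
      d$ss_amount * exp(-(a * d$ss_delay_days)^b)
    pr <- 0.02 + 0.96 * stats::pnorm(svd / 4)
    ll <- sum(stats::dbinom(y, 1, pr, log = TRUE))
    if (ll > best_ll) { best_ll <- ll; best <- c(a, b) }
  }
  best
}

.check_dd_data <- function(data, min_trials) {
  need <- c("participant_id", "choice", "ss_amount", "ss_delay_days",
            "ll_amount", "ll_delay_days")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("data missing columns: ",
                         paste(miss, collapse = ", "))
  if (is.null(data$is_catch)) data$is_catch <- FALSE
  task <- data[!data$is_catch, , drop = FALSE]
  if (nrow(task)) {
    cnt <- table(task$participant_id)
    if (any(cnt < min_trials))
      stop("participants with fewer than ", min_trials,
           " scoreable task trials: ",
           paste(names(cnt)[cnt < min_trials], collapse = ", "))
  }
  task
}

.run_dd_mcmc <- function(model_string, data_list, inits, monitor,
                         chains, samples, burn, seed, adapt) {
  jm <- rjags::jags.model(textConnection(model_string), data = data_list,
                          inits = inits, n.chains = chains,
                          n.adapt = adapt, quiet = TRUE)
  if (burn > 0) stats::update(jm, burn)
  rjags::coda.samples(jm, monitor, n.iter = samples - burn)
}

.chain_inits <- function(chains, seed, base) {
  lapply(seq_len(chains), function(ch) {
    set.seed((as.numeric(seed) * 131 + ch) %% 2147483647)
    ini <- base(ch)
    ini$.RNG.name <- "base::Mersenne-Twister"
    ini$.RNG.seed <- (as.numeric(seed) * 1009 + ch * 9973) %% 2147483647
    ini
  })
}

#' Hierarchical Bayesian fit of the hyperbolic discounting model
#'
#' Fits one symptom group's choice data with a hierarchical model:
#' participant log(k) ~ Normal(mu, sigma), mu ~ Normal(prior_mu, prior_sd)
#' (default N(-5.3, 2.5)), sigma ~ half-Normal(0, 2.5), lapse epsilon ~
#' Beta(1.1, 10.9) and acuity alpha ~ half-Normal(0, 50 USD). Sampling via
#' JAGS; convergence is assessed with split rank-normalized R-hat on every
#' monitored parameter. Groups should be fit separately, since pooling
#' dissimilar populations into one hierarchy can distort group contrasts.
#'
#' Defaults reproduce the full-scale protocol (4 chains x 25,000 samples,
#' 1,000 burn-in, i.e. 96,000 retained draws); pass smaller \code{samples}
#' for desk-scale work.
#'
#' @param data Trial table from \code{\link{prepare_dd_data}} (catch rows
#'   are ignored by the likelihood). May have zero rows, in which case the
#'   population-level priors are sampled unchanged (prior recovery).
#' @param prior_mu,prior_sd Normal prior on the group mean log(k).
#' @param chains,samples,burn MCMC settings; \code{samples} counts total
#'   draws per chain including burn-in.
#' @param seed Integer seed for chain RNGs and initialization jitter.
#' @param min_trials Minimum scoreable task trials per participant.
#' @param keep_draws Keep the thinned \code{mcmc.list} in the result.
#' @return A \code{dd_fit} object: per-participant posterior summaries
#'   (\code{$participants}), group-level summaries (\code{$group}), R-hat
#'   per parameter (\code{$rhat}), a \code{converged} flag (all R-hat
#'   <= 1.01), and sampler metadata.
#' @export
fit_hyperbolic_group <- function(data, prior_mu = -5.3, prior_sd = 2.5,
                                 chains = 4L, samples = 25000L,
                                 burn = 1000L, seed = 1L,
                                 min_trials = 20L, keep_draws = FALSE) {
  stopifnot(chains >= 2L, samples > burn)
  task <- .check_dd_data(data, min_trials)
  hyper <- list(prior_mu = prior_mu, prior_sd = prior_sd, sigma_sd = 2.5,
                eps_a = 1.1, eps_b = 10.9, alpha_sd = 50)

  if (nrow(task) == 0L) {
    sm <- .run_dd_mcmc(.jags_hyperbolic(FALSE), c(hyper, list(P = 1L)),
                       .chain_inits(chains, seed, function(ch)
                         list(mu = prior_mu, sigma = 1)),
                       c("mu", "sigma"), chains, samples, burn, seed,
                       adapt = 200L)
    draws <- as.matrix(sm)
    rhat <- compute_rhat(sm)
    out <- structure(list(
      model = "hyperbolic",
      participants = data.frame(),
      group = data.frame(parameter = c("mu", "sigma"),
                         mean = colMeans(draws)[c("mu", "sigma")],
                         sd = apply(draws, 2, stats::sd)[c("mu", "sigma")],
                         row.names = NULL),
      rhat = rhat, converged = all(rhat <= 1.01),
      n_chains = chains, n_samples = samples, n_burn = burn,
      prior = hyper, seed = seed,
      draws = if (keep_draws) sm else NULL), class = "dd_fit")
    return(out)
  }

  ids <- sort(unique(task$participant_id))
  pid <- match(task$participant_id, ids)
  y <- as.integer(task$choice == "LL")
  boundary <- vapply(split(y, pid), function(v)
    all(v == 0L) || all(v == 1L), logical(1))
  crude <- vapply(split(task, pid), .crude_logk, numeric(1))

  data_list <- c(hyper, list(
    P = length(ids), N = nrow(task), pid = pid, y = y,
    ssA = task$ss_amount, ssD = task$ss_delay_days,
    llA = task$ll_amount, llD = task$ll_delay_days))
  inits <- .chain_inits(chains, seed, function(ch) list(
    logk = pmin(pmax(crude + stats::rnorm(length(ids), 0, 0.2), -9), 1),
    eps = rep(0.05, length(ids)),
    alpha = rep(4, length(ids)) + stats::runif(length(ids), 0, 2),
    mu = mean(crude), sigma = max(stats::sd(crude), 0.5)))

  sm <- .run_dd_mcmc(.jags_hyperbolic(TRUE), data_list, inits,
                     c("logk", "eps", "alpha", "mu", "sigma"),
                     chains, samples, burn, seed,
                     adapt = min(1000L, max(200L, burn)))
  .summarize_dd_fit(sm, ids, boundary, "hyperbolic", chains, samples,
                    burn, hyper, seed, keep_draws)
}

.summarize_dd_fit <- function(sm, ids, boundary, model, chains, samples,
                              burn, prior, seed, keep_draws) {
  draws <- as.matrix(sm)
  pm <- colMeans(draws)
  psd <- apply(draws, 2, stats::sd)
  rhat <- compute_rhat(sm)
  P <- length(ids)
  idxname <- function(par) paste0(par, "[", seq_len(P), "]")
  participants <- data.frame(participant_id = ids, stringsAsFactors = FALSE)
  if (model == "hyperbolic") {
    participants$logk_mean <- pm[idxname("logk")]
    participants$logk_sd <- psd[idxname("logk")]
  } else {
    participants$a_mean <- pm[idxname("a")]
    participants$a_sd <- psd[idxname("a")]
    participants$b_mean <- pm[idxname("b")]
    participants$b_sd <- psd[idxname("b")]
  }
  participants$eps_mean <- pm[idxname("eps")]
  participants$alpha_mean <- pm[idxname("alpha")]
  per_rhat <- sapply(c(if (model == "hyperbolic") "logk" else c("a", "b"),
                       "eps", "alpha"),
                     function(par) rhat[idxname(par)])
  participants$rhat_max <- apply(as.matrix(per_rhat), 1, max)
  participants$boundary_flag <- boundary
  rownames(participants) <- NULL
  grp_pars <- setdiff(names(rhat), unlist(lapply(
    c("logk", "a", "b", "eps", "alpha"), idxname)))
  group <- data.frame(parameter = grp_pars, mean = pm[grp_pars],
                      sd = psd[grp_pars], row.names = NULL)
  structure(list(model = model, participants = participants, group = group,
                 rhat = rhat, converged = all(rhat <= 1.01),
                 n_chains = chains, n_samples = samples, n_burn = burn,
                 prior = prior, seed = seed,
                 draws = if (keep_draws) sm else NULL),
            class = "dd_fit")
}

#' Hierarchical fit of the constant-sensitivity (Ebert-Prelec) model
#'
#' As \code{\link{fit_hyperbolic_group}} but estimating per-participant
#' impatience a and time sensitivity b, each with truncated-normal
#' population distributions (a >= 0; b > 0, so b = 1 marks exponential
#' discounting).
#'
#' @inheritParams fit_hyperbolic_group
#' @return A \code{dd_fit} with \code{a_mean}, \code{b_mean} columns.
#' @export
fit_ebert_prelec_group <- function(data, chains = 4L, samples = 25000L,
                                   burn = 1000L, seed = 1L,
                                   min_trials = 20L, keep_draws = FALSE) {
  stopifnot(chains >= 2L, samples > burn)
  task <- .check_dd_data(data, min_trials)
  if (nrow(task) == 0L) stop("Ebert-Prelec fit requires choice data")
  hyper <- list(eps_a = 1.1, eps_b = 10.9, alpha_sd = 50)
  ids <- sort(unique(task$participant_id))
  pid <- match(task$participant_id, ids)
  y <- as.integer(task$choice == "LL")
  boundary <- vapply(split(y, pid), function(v)
    all(v == 0L) || all(v == 1L), logical(1))
  crude <- t(vapply(split(task, pid), .crude_ep, numeric(2)))

  data_list <- c(hyper, list(
    P = length(ids), N = nrow(task), pid = pid, y = y,
    ssA = task$ss_amount, ssD = task$ss_delay_days,
    llA = task$ll_amount, llD = task$ll_delay_days))
  inits <- .chain_inits(chains, seed, function(ch) list(
    a = pmax(crude[, 1] * exp(stats::rnorm(length(ids), 0, 0.1)), 1e-5),
    b = pmin(pmax(crude[, 2] + stats::rnorm(length(ids), 0, 0.05), 0.1), 2.5),
    eps = rep(0.05, length(ids)),
    alpha = rep(4, length(ids)) + stats::runif(length(ids), 0, 2),
    mu_a = max(mean(crude[, 1]), 1e-4), sig_a = max(stats::sd(crude[, 1]), 0.005),
    mu_b = mean(crude[, 2]), sig_b = max(stats::sd(crude[, 2]), 0.1)))

  sm <- .run_dd_mcmc(.jags_ebert_prelec(), data_list, inits,
                     c("a", "b", "eps", "alpha",
                       "mu_a", "sig_a", "mu_b", "sig_b"),
                     chains, samples, burn, seed,
                     adapt = min(1000L, max(200L, burn)))
  .summarize_dd_fit(sm, ids, boundary, "ebert_prelec", chains, samples,
                    burn, hyper, seed, keep_draws)
}

#' Posterior-predictive choice classification accuracy
#'
#' Scores each observed task choice against the modal prediction of the
#' fitted model at the participant's posterior-mean parameters (LL
#' predicted when p(LL) > 0.5). This is the "fraction of choices the
#' model classifies correctly" summary of model adequacy.
#'
#' @param fit A \code{dd_fit}.
#' @param data Trial table covering the fitted participants (catch rows
#'   are excluded).
#' @return Fraction of choices matching the modal prediction.
#' @export
classify_choices <- function(fit, data) {
  stopifnot(inherits(fit, "dd_fit"))
  if (is.null(data$is_catch)) data$is_catch <- FALSE
  task <- data[!data$is_catch, , drop = FALSE]
  missing_ids <- setdiff(unique(task$participant_id),
                         fit$participants$participant_id)
  if (length(missing_ids))
    stop("participants missing from fit: ",
         paste(missing_ids, collapse = ", "))
  idx <- match(task$participant_id, fit$participants$participant_id)
  pp <- fit$participants
  p <- numeric(nrow(task))
  for (i in seq_len(nrow(pp))) {
    rows <- which(idx == i)
    if (!length(rows)) next
    params <- if (fit$model == "hyperbolic") {
      hyperbolic_params(pp$logk_mean[i], pp$eps_mean[i], pp$alpha_mean[i])
    } else {
      ebert_prelec_params(pp$a_mean[i], pp$b_mean[i],
                          pp$eps_mean[i], pp$alpha_mean[i])
    }
    p[rows] <- p_choose_ll(task[rows, , drop = FALSE], params)
  }
  pred <- ifelse(p > 0.5, "LL", "SS")
  mean(pred == task$choice)
}

#' @export
print.dd_fit <- function(x, ...) {
  cat("<dd_fit> model:", x$model, "\n")
  cat("  participants:", nrow(x$participants),
      " chains:", x$n_chains,
      " samples:", x$n_samples, "(burn", paste0(x$n_burn, ")"), "\n")
  cat("  max R-hat:", format(max(x$rhat), digits = 4),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  if (nrow(x$participants) && x$model == "hyperbolic")
    cat("  log(k) posterior means: ",
        format(mean(x$participants$logk_mean), digits = 4), " (mean), ",
        format(stats::sd(x$participants$logk_mean), digits = 4),
        " (sd)\n", sep = "")
  if (any(x$participants$boundary_flag))
    cat("  boundary responders:",
        sum(x$participants$boundary_flag), "\n")
  invisible(x)
}
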