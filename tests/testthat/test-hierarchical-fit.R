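# Desk-scale sampler settings throughout: enough draws for stable
# posterior means on simulated agents while keeping the suite fast.

test_that("hierarchical hyperbolic fit recovers known discount rates", {
  true_logk <- seq(-6.2, -2.6, length.out = 10)
  dd <- make_agent_data(true_logk, epsilon = 0.02, alpha = 3,
                        seed_base = 3000L)
  fit <- fit_hyperbolic_group(dd, chains = 4, samples = 2500,
                              burn = 500, seed = 21)
  est <- fit$participants$logk_mean[
    match(seq_along(true_logk), fit$participants$participant_id)]
  expect_gt(cor(est, true_logk), 0.9)
  expect_lt(mean(abs(est - true_logk)), 0.5)
  # interval coverage across agents near nominal (posterior-normal approx)
  sdv <- fit$participants$logk_sd[
    match(seq_along(true_logk), fit$participants$participant_id)]
  covered <- abs(est - true_logk) < 1.96 * sdv
  expect_gte(mean(covered), 0.8)
  expect_false(any(fit$participants$boundary_flag))
  expect_s3_class(fit, "dd_fit")
  expect_output(print(fit), "dd_fit")
})

test_that("posterior means shrink toward the group relative to per-agent MLEs", {
  # noisy agents and few trials so shrinkage is visible
  cs <- build_choice_set(seed = 4, n_trials = 48)
  true_logk <- rnorm(12, -4.5, 0.4)
  set.seed(31)
  dd <- do.call(rbind, lapply(seq_along(true_logk), function(i)
    prepare_dd_data(simulate_choices(
      cs, hyperbolic_params(true_logk[i], 0.1, 8),
      seed = 400 + i, participant_id = i), cs)))
  fit <- fit_hyperbolic_group(dd, chains = 3, samples = 1500,
                              burn = 400, seed = 32)
  # independent per-agent ML estimates (epsilon/alpha fixed at truth)
  mle <- vapply(split(dd, dd$participant_id), function(d) {
    optimize(function(g) {
      p <- p_choose_ll(d, hyperbolic_params(g, 0.1, 8))
      -sum(log(ifelse(d$choice == "LL", p, 1 - p)))
    }, c(-9, 1))$minimum
  }, numeric(1))
  post <- fit$participants$logk_mean
  expect_lt(var(post), var(mle))
})

test_that("degenerate responders are flagged at the boundary, not dropped", {
  cs <- build_choice_set(seed = 2)
  true_logk <- c(-12, -4.5, -4, -3.5)  # first agent always prefers LL
  dd <- make_agent_data(true_logk, epsilon = 0, alpha = 1e-6,
                        cs = cs, seed_base = 500L)
  fit <- fit_hyperbolic_group(dd, chains = 2, samples = 800, burn = 200,
                              seed = 33)
  pp <- fit$participants
  expect_true(pp$boundary_flag[pp$participant_id == 1])
  expect_false(any(pp$boundary_flag[pp$participant_id != 1]))
})

test_that("with no choice data the group posterior reproduces the prior", {
  fit <- fit_hyperbolic_group(empty_dd_frame(), chains = 4,
                              samples = 4000, burn = 500, seed = 34)
  mu <- fit$group[fit$group$parameter == "mu", ]
  expect_equal(mu$mean, -5.3, tolerance = 0.15)
  expect_equal(mu$sd, 2.5, tolerance = 0.15)
  expect_true(fit$converged)
})

test_that("fit contracts: trial minimum, sample bookkeeping, missing participants", {
  cs <- build_choice_set(seed = 6, n_trials = 30)
  short <- prepare_dd_data(simulate_choices(
    cs[1:10, ], hyperbolic_params(-4), seed = 1), cs)
  expect_error(fit_hyperbolic_group(short, samples = 500, burn = 100),
               "fewer than 20")
  fx <- recovery_fixture()
  expect_equal(fx$fit$n_chains, 4)
  expect_equal(fx$fit$n_samples, 6000)
  other <- fx$data
  other$participant_id <- other$participant_id + 1000
  expect_error(classify_choices(fx$fit, other), "missing from fit")
})

test_that("classification accuracy hits its analytic limits and ignores screen side", {
  cs <- build_choice_set(seed = 7)
  # deterministic agents classified perfectly by their own parameters
  det <- make_agent_data(c(-5, -4, -3), epsilon = 0, alpha = 1e-6,
                        cs = cs, seed_base = 600L)
  fake_fit <- structure(list(
    model = "hyperbolic",
    participants = data.frame(participant_id = 1:3,
                              logk_mean = c(-5, -4, -3),
                              eps_mean = 0, alpha_mean = 1e-6)),
    class = "dd_fit")
  expect_equal(classify_choices(fake_fit, det), 1.0)
  # pure-noise agents are classified at chance
  noise <- make_agent_data(rep(-4, 3), epsilon = 0.4999, alpha = 1e9,
                           cs = cs, seed_base = 700L)
  acc <- classify_choices(fake_fit, noise)
  expect_gt(acc, 0.4); expect_lt(acc, 0.6)
  # left/right counterbalancing plays no role
  flipped <- det
  flipped$ll_side <- ifelse(flipped$ll_side == "left", "right", "left")
  expect_equal(classify_choices(fake_fit, flipped), 1.0)
})

test_that("constant-sensitivity fit recovers impatience ordering and b near 1", {
  a_true <- exp(seq(log(0.002), log(0.06), length.out = 12))
  dd <- make_ep_agent_data(a_true, b = rep(1, 12), seed_base = 800L)
  fit <- fit_ebert_prelec_group(dd, chains = 4, samples = 2500,
                                burn = 500, seed = 41)
  est_a <- fit$participants$a_mean[
    match(seq_along(a_true), fit$participants$participant_id)]
  expect_gt(cor(est_a, a_true, method = "spearman"), 0.8)
  expect_equal(mean(fit$participants$b_mean), 1, tolerance = 0.25)
  # a = 0 agent: never discounts, always prefers LL, flagged boundary
  dd0 <- make_ep_agent_data(c(0, 0.02), b = c(1, 1), epsilon = 0,
                            alpha = 1e-6, seed_base = 900L)
  fit0 <- fit_ebert_prelec_group(dd0, chains = 2, samples = 700,
                                 burn = 200, seed = 42)
  pp <- fit0$participants
  expect_true(pp$boundary_flag[pp$participant_id == 1])
  expect_lt(pp$a_mean[pp$participant_id == 1],
            pp$a_mean[pp$participant_id == 2])
})

test_that("credible intervals are approximately calibrated over replicates", {
  # data drawn from (a moderate slice of) the model's own prior: CI
  # coverage of true log(k) should be near nominal
  cs <- build_choice_set(seed = 8, n_trials = 60)
  set.seed(55)
  n_rep <- 30
  covered <- total <- 0L
  for (rep in seq_len(n_rep)) {
    mu <- rnorm(1, -4.8, 0.8)
    sigma <- abs(rnorm(1, 0, 0.8)) + 0.2
    true_logk <- rnorm(5, mu, sigma)
    dd <- do.call(rbind, lapply(1:5, function(i)
      prepare_dd_data(simulate_choices(
        cs, hyperbolic_params(true_logk[i], 0.03, 4),
        seed = rep * 100 + i, participant_id = i), cs)))
    fit <- fit_hyperbolic_group(dd, chains = 2, samples = 700,
                                burn = 200, seed = rep)
    est <- fit$participants$logk_mean
    sdv <- fit$participants$logk_sd
    covered <- covered + sum(abs(est - true_logk) < 1.96 * sdv)
    total <- total + 5L
  }
  expect_gte(covered / total, 0.85)
})
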