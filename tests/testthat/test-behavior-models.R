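test_that("hyperbolic subjective value matches direct evaluation", {
  expect_equal(sv_hyperbolic(100, 0, -2), 100)
  expect_equal(sv_hyperbolic(30, 10, log(0.1)), 15)
  expect_equal(sv_hyperbolic(50, 180, -30), 50, tolerance = 1e-6)
  t <- seq(0, 180, by = 10)
  expect_true(all(diff(sv_hyperbolic(40, t, -4)) < 0))
  expect_error(sv_hyperbolic(40, -1, -4), "non-negative")
  expect_error(sv_hyperbolic(-5, 1, -4), "positive")
})

test_that("constant-sensitivity subjective value matches direct evaluation", {
  expect_equal(sv_ebert_prelec(77, 0, 0.02, 0.8), 77)
  expect_equal(sv_ebert_prelec(100, 365, 0, 1), 100)
  expect_equal(sv_ebert_prelec(100, 100, 0.01, 1), 100 * exp(-1))
  expect_error(sv_ebert_prelec(100, 10, 0.01, 0), "> 0")
  expect_error(sv_ebert_prelec(100, 10, -0.01, 1), ">= 0")
  # regression guard: EP at b = 1 (exponential) differs from hyperbolic
  # at matched rate except at t = 0
  k <- 0.02
  t <- c(7, 30, 90, 180)
  expect_true(all(abs(sv_ebert_prelec(60, t, k, 1) -
                        sv_hyperbolic(60, t, log(k))) > 0.1))
})

test_that("choice rule respects lapse bounds, symmetry and the normal CDF", {
  tie <- data.frame(ss_amount = 50, ss_delay_days = 0,
                    ll_amount = 50, ll_delay_days = 0)
  expect_equal(p_choose_ll(tie, hyperbolic_params(-4, 0.2, 3)), 0.5)
  huge <- data.frame(ss_amount = 15, ss_delay_days = 0,
                     ll_amount = 170, ll_delay_days = 7)
  expect_equal(p_choose_ll(huge, hyperbolic_params(-30, 0.1, 1e-4)), 0.9)
  # Phi(1): SV difference 10 at alpha 10, no lapses
  tr <- data.frame(ss_amount = 40, ss_delay_days = 0,
                   ll_amount = 50, ll_delay_days = 0)
  expect_equal(p_choose_ll(tr, hyperbolic_params(-4, 0, 10)),
               pnorm(1), tolerance = 1e-12)
  # p(trial) + p(value-swapped trial) = 1
  set.seed(42)
  for (i in 1:20) {
    a <- sample(15:85, 1); b <- a + sample(5:80, 1)
    d1 <- sample(0:30, 1); d2 <- d1 + sample(7:60, 1)
    tr <- data.frame(ss_amount = a, ss_delay_days = d1,
                     ll_amount = b, ll_delay_days = d2)
    sw <- data.frame(ss_amount = b, ss_delay_days = d2,
                     ll_amount = a, ll_delay_days = d1)
    p <- hyperbolic_params(runif(1, -7, -2), runif(1, 0, 0.3),
                           runif(1, 0.5, 10))
    expect_equal(p_choose_ll(tr, p) + p_choose_ll(sw, p), 1,
                 tolerance = 1e-12)
  }
  expect_error(hyperbolic_params(-4, 0.5, 1), "0.5")
  expect_error(hyperbolic_params(-4, 0.1, 0), "> 0")
})

test_that("simulated choices follow the model and its limits", {
  cs <- build_choice_set(seed = 2)
  # deterministic limit: tiny acuity, no lapses
  det <- simulate_choices(cs, hyperbolic_params(-4.5, 0, 1e-9), seed = 7)
  k <- exp(-4.5)
  svd <- cs$ll_amount / (1 + k * cs$ll_delay_days) -
    cs$ss_amount / (1 + k * cs$ss_delay_days)
  expect_identical(det$choice, ifelse(svd > 0, "LL", "SS"))
  # pure noise: choice rate near 0.5 (lapse bound makes p constant 0.5)
  eps_hi <- hyperbolic_params(-4.5, 0.4999, 1e9)
  noisy <- simulate_choices(cs, eps_hi, seed = 8)
  expect_gt(mean(noisy$choice == "LL"), 0.35)
  expect_lt(mean(noisy$choice == "LL"), 0.65)
  # determinism
  expect_identical(simulate_choices(cs, eps_hi, seed = 9),
                   simulate_choices(cs, eps_hi, seed = 9))
})

test_that("simulated LL frequency converges to the model probability", {
  # one trial replicated 10,000 times: law of large numbers
  tr <- build_choice_set(seed = 3)[10, ]
  params <- hyperbolic_params(-4.8, 0.05, 4)
  p <- p_choose_ll(tr, params)
  big <- tr[rep(1, 10000), ]
  big$trial_id <- seq_len(10000)
  sim <- simulate_choices(big, params, seed = 4)
  expect_equal(mean(sim$choice == "LL"), p, tolerance = 0.02)
  # catch trials answered correctly with probability 1 - epsilon
  ct <- make_catch_trials(10)
  ct_big <- ct[rep(1:10, 400), ]
  ct_big$trial_id <- seq_len(nrow(ct_big))
  simc <- simulate_choices(ct_big, hyperbolic_params(-4, 0.2, 4), seed = 5)
  expect_equal(mean(simc$choice == "LL"), 0.8, tolerance = 0.02)
})
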