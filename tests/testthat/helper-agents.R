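# Simulated-agent fixtures shared across tests. Everything is generated
# in code at test time; the recovery cohort is memoized because two
# different properties (parameter recovery and choice classification)
# are checked on the same fitted model.

make_agent_data <- function(true_logk, epsilon = 0.03, alpha = 4,
                            cs = build_choice_set(seed = 1),
                            seed_base = 1000L) {
  resp <- do.call(rbind, lapply(seq_along(true_logk), function(i)
    simulate_choices(cs, hyperbolic_params(true_logk[i], epsilon, alpha),
                     seed = seed_base + i, participant_id = i)))
  prepare_dd_data(resp, cs)
}

make_ep_agent_data <- function(a, b, epsilon = 0.03, alpha = 4,
                               cs = build_choice_set(seed = 1),
                               seed_base = 2000L) {
  resp <- do.call(rbind, lapply(seq_along(a), function(i)
    simulate_choices(cs, ebert_prelec_params(a[i], b[i], epsilon, alpha),
                     seed = seed_base + i, participant_id = i)))
  prepare_dd_data(resp, cs)
}

.fixture_env <- new.env(parent = emptyenv())

# 20 agents, 144-trial set, lapse 0.03, acuity 4 USD, true log(k) drawn
# from N(-4, 1); hierarchical fit at desk-scale sampler settings.
recovery_fixture <- function() {
  if (!is.null(.fixture_env$recovery)) return(.fixture_env$recovery)
  set.seed(101)
  true_logk <- rnorm(20, -4, 1)
  dd <- make_agent_data(true_logk)
  fit <- fit_hyperbolic_group(dd, chains = 4, samples = 6000,
                              burn = 1000, seed = 11)
  .fixture_env$recovery <- list(true_logk = true_logk, data = dd,
                                fit = fit)
  .fixture_env$recovery
}

empty_dd_frame <- function() {
  data.frame(participant_id = integer(0), choice = character(0),
             ss_amount = numeric(0), ss_delay_days = numeric(0),
             ll_amount = numeric(0), ll_delay_days = numeric(0),
             is_catch = logical(0))
}
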