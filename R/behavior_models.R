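#' Hyperbolic subjective value
#'
#' SV = A / (1 + k t), the single-parameter hyperbolic discount function,
#' with the discount rate parameterized on the log scale (k = exp(log_k),
#' in 1/days). At t = 0 the subjective value equals the amount.
#'
#' @param amount Reward amount in USD (> 0).
#' @param delay Delay in days (>= 0).
#' @param log_k Log discount rate.
#' @return Subjective value in USD.
#' @export
sv_hyperbolic <- function(amount, delay, log_k) {
  if (any(amount <= 0)) stop("amount must be positive")
  if (any(delay < 0)) stop("delay must be non-negative")
  amount / (1 + exp(log_k) * delay)
}

#' Constant-sensitivity (Ebert-Prelec) subjective value
#'
#' SV = A exp(-(a t)^b), separating impatience (a, per day) from time
#' sensitivity (b, dimensionless). b = 1 recovers exponential discounting;
#' a = 0 means no discounting at any delay.
#'
#' @param amount Reward amount in USD (> 0).
#' @param delay Delay in days (>= 0).
#' @param a Impatience, >= 0 (units 1/days).
#' @param b Time sensitivity, > 0.
#' @return Subjective value in USD.
#' @export
sv_ebert_prelec <- function(amount, delay, a, b) {
  if (any(amount <= 0)) stop("amount must be positive")
  if (any(delay < 0)) stop("delay must be non-negative")
  if (any(a < 0)) stop("impatience a must be >= 0")
  if (any(b <= 0)) stop("time sensitivity b must be > 0")
  amount * exp(-(a * delay)^b)
}

#' Behavioral parameter sets
#'
#' Constructors for the two decision models. Both share the psychometric
#' choice rule parameters: a lapse rate \code{epsilon} in [0, 0.5) (the
#' probability of responding at random) and a comparison acuity
#' \code{alpha} > 0 in USD (the scale of value-difference noise).
#'
#' @param log_k Log discount rate (hyperbolic model).
#' @param epsilon Lapse probability, in [0, 0.5).
#' @param alpha Comparison-acuity scale in USD, > 0.
#' @return An object of class \code{dd_params}.
#' @export
hyperbolic_params <- function(log_k, epsilon = 0.01, alpha = 2) {
  stopifnot(is.finite(log_k))
  check_choice_noise(epsilon, alpha)
  structure(list(model = "hyperbolic", log_k = log_k,
                 epsilon = epsilon, alpha = alpha),
            class = "dd_params")
}

#' @rdname hyperbolic_params
#' @param a Impatience, >= 0 (1/days).
#' @param b Time sensitivity, > 0.
#' @export
ebert_prelec_params <- function(a, b, epsilon = 0.01, alpha = 2) {
  if (a < 0) stop("impatience a must be >= 0")
  if (b <= 0) stop("time sensitivity b must be > 0")
  check_choice_noise(epsilon, alpha)
  structure(list(model = "ebert_prelec", a = a, b = b,
                 epsilon = epsilon, alpha = alpha),
            class = "dd_params")
}

check_choice_noise <- function(epsilon, alpha) {
  if (epsilon < 0 || epsilon >= 0.5)
    stop("epsilon must lie in [0, 0.5)")
  if (alpha <= 0) stop("alpha must be > 0")
  invisible(TRUE)
}

#' @export
print.dd_params <- function(x, ...) {
  cat("<dd_params> model:", x$model, "\n")
  if (x$model == "hyperbolic") {
    cat("  log(k) =", format(x$log_k), "\n")
  } else {
    cat("  a =", format(x$a), " b =", format(x$b), "\n")
  }
  cat("  epsilon =", format(x$epsilon), " alpha =", format(x$alpha), "USD\n")
  invisible(x)
}

subjective_values <- function(trials, params) {
  if (params$model == "hyperbolic") {
    list(ll = sv_hyperbolic(trials$ll_amount, trials$ll_delay_days,
                            params$log_k),
         ss = sv_hyperbolic(trials$ss_amount, trials$ss_delay_days,
                            params$log_k))
  } else {
    list(ll = sv_ebert_prelec(trials$ll_amount, trials$ll_delay_days,
                              params$a, params$b),
         ss = sv_ebert_prelec(trials$ss_amount, trials$ss_delay_days,
                              params$a, params$b))
  }
}

#' Probability of choosing the larger-later option
#'
#' The psychometric choice rule
#' p(LL) = epsilon + (1 - 2 epsilon) Phi((SV_LL - SV_SS) / alpha),
#' where Phi is the standard-normal CDF. The probability is bounded in
#' [epsilon, 1 - epsilon] and equals 0.5 when the subjective values tie.
#'
#' @param trials Data.frame of trials in choice-set column layout.
#' @param params A \code{dd_params} object.
#' @return Vector of LL-choice probabilities, one per trial.
#' @export
p_choose_ll <- function(trials, params) {
  stopifnot(inherits(params, "dd_params"))
  sv <- subjective_values(trials, params)
  params$epsilon +
    (1 - 2 * params$epsilon) * stats::pnorm((sv$ll - sv$ss) / params$alpha)
}

#' Simulate one participant's choices over a choice set
#'
#' Draws one Bernoulli response per trial at the model's LL-choice
#' probability. Catch-trial responses are generated as correct (the
#' dominant option) with probability 1 - epsilon, reflecting lapses only.
#'
#' @param cs A \code{choice_set} or data.frame in its column layout
#'   (optionally with catch rows from \code{\link{make_catch_trials}}).
#' @param params A \code{dd_params} object.
#' @param seed Integer seed; draws are reproducible.
#' @param participant_id Identifier stamped on the output rows.
#' @return Data.frame with columns \code{participant_id}, \code{trial_id},
#'   \code{is_catch}, \code{choice} (\code{"SS"} or \code{"LL"}).
#' @export
simulate_choices <- function(cs, params, seed, participant_id = 1L) {
  stopifnot(inherits(params, "dd_params"))
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  p <- numeric(nrow(cs))
  task <- !cs$is_catch
  if (any(task)) p[task] <- p_choose_ll(cs[task, , drop = FALSE], params)
  # catch trials: dominant option (LL columns) chosen unless a lapse occurs
  if (any(!task)) p[!task] <- 1 - params$epsilon
  y <- stats::rbinom(nrow(cs), 1L, p)
  data.frame(participant_id = participant_id,
             trial_id = cs$trial_id,
             is_catch = cs$is_catch,
             choice = ifelse(y == 1L, "LL", "SS"),
             stringsAsFactors = FALSE)
}

#' Join responses to their trial attributes
#'
#' Merges a long response table onto the choice set (and, separately, the
#' catch-trial table) to produce the analysis-ready trial table consumed
#' by the fitting functions. Catch rows keep their flag so the fitting
#' code never treats them as task trials.
#'
#' @param responses Data.frame with \code{participant_id},
#'   \code{trial_id}, \code{is_catch}, \code{choice}.
#' @param cs The \code{choice_set} the responses were collected on.
#' @param catch Optional catch-trial table from
#'   \code{\link{make_catch_trials}}.
#' @return Merged data.frame of responses with trial attributes.
#' @export
prepare_dd_data <- function(responses, cs, catch = NULL) {
  stopifnot(all(c("participant_id", "trial_id", "choice") %in%
                  names(responses)))
  if (!all(responses$choice %in% c("SS", "LL")))
    stop("choice must be 'SS' or 'LL'")
  if (is.null(responses$is_catch)) responses$is_catch <- FALSE
  task <- merge(responses[!responses$is_catch, , drop = FALSE],
                as.data.frame(cs)[!cs$is_catch, ],
                by = c("trial_id", "is_catch"), sort = FALSE)
  out <- task
  if (!is.null(catch) && any(responses$is_catch)) {
    cr <- merge(responses[responses$is_catch, , drop = FALSE],
                catch, by = c("trial_id", "is_catch"), sort = FALSE)
    out <- rbind(task[, setdiff(names(task), "correct_choice")],
                 cr[, setdiff(names(cr), "correct_choice")])
    out$correct_choice <- c(rep(NA_character_, nrow(task)),
                            cr$correct_choice)
  }
  out[order(out$participant_id, out$is_catch, out$trial_id), ]
}
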