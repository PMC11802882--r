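#' Construct an intertemporal choice set
#'
#' Builds a smaller-sooner (SS) versus larger-later (LL) binary choice set
#' of the kind used in hypothetical-money delay discounting experiments.
#' Each trial pairs an SS reward (amount in whole USD, delay in days) with
#' an LL reward whose amount exceeds the SS amount by a relative premium
#' and whose delay strictly exceeds the SS delay. The default grids cross
#' SS delays of today, 2 weeks and 1 month with LL delays from 1 week to
#' 6 months and premiums spanning 2--100%, yielding the 144-trial layout.
#'
#' @param seed Integer seed; the trial list is deterministic given the seed.
#' @param n_trials Number of task trials. The default (144) uses every
#'   premium-by-delay-pair cell exactly once; other sizes sample cells.
#' @param premium_grid Relative premiums (ll/ss - 1), each in [0.02, 1].
#' @param delay_grid Two-column matrix or data.frame of delay pairs in days
#'   (columns \code{ss_delay_days}, \code{ll_delay_days}).
#' @param ss_range Integer range of SS amounts in USD (whole dollars).
#'
#' @return A \code{choice_set}: a data.frame with columns \code{trial_id},
#'   \code{ss_amount}, \code{ss_delay_days}, \code{ll_amount},
#'   \code{ll_delay_days}, \code{is_catch}, \code{ll_side} and attributes
#'   \code{n_task}, \code{n_catch}.
#' @export
build_choice_set <- function(seed = 1L,
                             n_trials = 144L,
                             premium_grid = default_premium_grid(),
                             delay_grid = default_delay_grid(),
                             ss_range = c(15L, 85L)) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  if (n_trials < 1L) stop("n_trials must be >= 1")
  if (any(premium_grid < 0.02))
    stop("premium_grid below the 2% floor: ",
         paste(premium_grid[premium_grid < 0.02], collapse = ", "))
  if (any(premium_grid > 1))
    stop("premium_grid above the 100% ceiling: ",
         paste(premium_grid[premium_grid > 1], collapse = ", "))
  delay_grid <- as.data.frame(delay_grid)
  names(delay_grid) <- c("ss_delay_days", "ll_delay_days")
  if (any(delay_grid$ll_delay_days <= delay_grid$ss_delay_days))
    stop("delay_grid contains pairs with ll_delay <= ss_delay")
  if (!all(delay_grid$ss_delay_days %in% c(0, 14, 30)))
    stop("ss delays must be within {0, 14, 30} days")
  if (any(delay_grid$ll_delay_days < 7 | delay_grid$ll_delay_days > 180))
    stop("ll delays must lie in [7, 180] days")
  if (ss_range[1] < 15 || ss_range[2] > 85)
    stop("ss amounts must lie in [15, 85] USD")

  cells <- expand.grid(premium = premium_grid,
                       pair = seq_len(nrow(delay_grid)))
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)

  idx <- if (n_trials == nrow(cells)) {
    seq_len(nrow(cells))
  } else {
    sample.int(nrow(cells), n_trials, replace = n_trials > nrow(cells))
  }
  cells <- cells[idx, , drop = FALSE]

  ss <- sample(seq.int(ss_range[1], ss_range[2]), n_trials, replace = TRUE)
  ll <- round(ss * (1 + cells$premium))
  # rounding can undershoot the 2% premium floor for large ss; enforce it
  ll <- pmax(ll, ceiling(ss * 1.02))
  ll <- pmin(ll, 170L)

  side <- rep(c("left", "right"), length.out = n_trials)
  side <- side[sample.int(n_trials)]

  cs <- data.frame(
    trial_id = seq_len(n_trials),
    ss_amount = as.integer(ss),
    ss_delay_days = delay_grid$ss_delay_days[cells$pair],
    ll_amount = as.integer(ll),
    ll_delay_days = delay_grid$ll_delay_days[cells$pair],
    is_catch = FALSE,
    ll_side = side,
    stringsAsFactors = FALSE
  )
  cs <- structure(cs, n_task = n_trials, n_catch = 0L,
                  class = c("choice_set", "data.frame"))
  validate_choice_set(cs)
  cs
}

#' Default premium and delay grids for the 144-trial layout
#'
#' Nine premiums spanning 2--100% crossed with the sixteen admissible
#' SS/LL delay pairs give 144 cells. The delay pairs are reconstructed
#' from the stated ranges (SS in {0, 14, 30} days; LL in {7, 14, 30, 60,
#' 90, 120, 180} days with LL > SS), an approximation to the original
#' trial table, which is not public.
#'
#' @return \code{default_premium_grid}: numeric vector of premiums.
#' @export
default_premium_grid <- function() {
  c(0.02, 0.05, 0.10, 0.20, 0.30, 0.45, 0.60, 0.80, 1.00)
}

#' @rdname default_premium_grid
#' @return \code{default_delay_grid}: data.frame of delay pairs (days).
#' @export
default_delay_grid <- function() {
  ss <- c(0, 14, 30)
  ll <- c(7, 14, 30, 60, 90, 120, 180)
  g <- expand.grid(ss_delay_days = ss, ll_delay_days = ll)
  g <- g[g$ll_delay_days > g$ss_delay_days, , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Validate a choice set against its design invariants
#'
#' @param cs A \code{choice_set} data.frame.
#' @return \code{cs}, invisibly; errors name the violated bound.
#' @export
validate_choice_set <- function(cs) {
  need <- c("trial_id", "ss_amount", "ss_delay_days", "ll_amount",
            "ll_delay_days", "is_catch", "ll_side")
  miss <- setdiff(need, names(cs))
  if (length(miss)) stop("choice set missing columns: ",
                         paste(miss, collapse = ", "))
  task <- cs[!cs$is_catch, , drop = FALSE]
  if (nrow(task)) {
    if (any(task$ll_amount <= task$ss_amount))
      stop("task trials must have ll_amount > ss_amount")
    if (any(task$ll_delay_days <= task$ss_delay_days))
      stop("task trials must have ll_delay > ss_delay")
    if (any(task$ss_amount < 15 | task$ss_amount > 85))
      stop("ss_amount outside [15, 85]")
    if (any(task$ll_amount < 16 | task$ll_amount > 170))
      stop("ll_amount outside [16, 170]")
    r <- task$ll_amount / task$ss_amount - 1
    if (any(r < 0.02 - 1e-12 | r > 1 + 1e-12))
      stop("relative premium outside [0.02, 1.00]")
    if (!all(task$ss_delay_days %in% c(0, 14, 30)))
      stop("ss_delay outside {0, 14, 30}")
    if (any(task$ll_delay_days < 7 | task$ll_delay_days > 180))
      stop("ll_delay outside [7, 180]")
  }
  catch <- cs[cs$is_catch, , drop = FALSE]
  if (nrow(catch)) {
    dom <- catch$ll_amount > catch$ss_amount &
      catch$ll_delay_days <= catch$ss_delay_days
    if (!all(dom)) stop("catch trials must be strictly dominated")
  }
  invisible(cs)
}

#' Generate catch trials with a strictly dominant option
#'
#' Catch trials pair a larger reward at an equal-or-shorter delay against a
#' smaller, later reward, so one option dominates on both attributes. The
#' dominant option is stored in the LL columns; \code{correct_choice} is
#' therefore always \code{"LL"}. Used to screen for task compliance.
#'
#' @param n Number of catch trials (the deployed task used 2 for one
#'   recruitment arm and 10 for the other).
#' @return A data.frame in choice-set column layout plus
#'   \code{correct_choice}.
#' @export
make_catch_trials <- function(n) {
  if (n < 1) stop("n must be >= 1")
  ss <- 15L + ((seq_len(n) - 1L) * 7L) %% 61L
  ll <- pmin(ss + 10L + 5L * (seq_len(n) %% 4L), 170L)
  data.frame(
    trial_id = seq_len(n),
    ss_amount = ss,
    ss_delay_days = rep(c(30, 14), length.out = n),
    ll_amount = ll,
    ll_delay_days = rep(c(0, 7), length.out = n),
    is_catch = TRUE,
    ll_side = rep(c("left", "right"), length.out = n),
    correct_choice = "LL",
    stringsAsFactors = FALSE
  )
}

#' Noise-free LL-preference fraction of a choice set
#'
#' For a given log discount rate, computes the fraction of task trials
#' whose hyperbolic subjective value favors the larger-later option. A
#' well-balanced set yields a fraction near 0.5 at the design's reference
#' log(k), so that choices are maximally informative.
#'
#' @param cs A \code{choice_set}.
#' @param log_k Log discount rate (log of 1/days).
#' @return Fraction of task trials with SV(LL) > SV(SS).
#' @export
balance_diagnostic <- function(cs, log_k) {
  task <- cs[!cs$is_catch, , drop = FALSE]
  if (!nrow(task)) stop("choice set has no task trials")
  sv_ll <- sv_hyperbolic(task$ll_amount, task$ll_delay_days, log_k)
  sv_ss <- sv_hyperbolic(task$ss_amount, task$ss_delay_days, log_k)
  mean(sv_ll > sv_ss)
}

#' @export
print.choice_set <- function(x, ...) {
  cat("<choice_set> ", attr(x, "n_task"), " task trials, ",
      attr(x, "n_catch"), " catch trials\n", sep = "")
  cat("  ss: $", min(x$ss_amount), "-", max(x$ss_amount),
      ", delays {", paste(sort(unique(x$ss_delay_days)), collapse = ", "),
      "} d\n", sep = "")
  cat("  ll: $", min(x$ll_amount), "-", max(x$ll_amount),
      ", delays ", min(x$ll_delay_days), "-", max(x$ll_delay_days),
      " d\n", sep = "")
  invisible(x)
}

# Save/restore .Random.seed so seeded helpers don't disturb the caller's RNG.
.Random.seed_guard <- function(seed) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
}
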