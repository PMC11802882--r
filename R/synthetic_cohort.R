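#' Specify a synthetic study cohort
#'
#' Defines the generative conditions for a full synthetic study: latent
#' symptom severity (S), future orientation (F) and dispositional
#' negativity (D) with calibrated inter-trait structure; item-level
#' questionnaire responses; per-participant discounting parameters; and
#' choice/temporal-task data. Effect-map defaults are the study-scale
#' effects the generator is calibrated to reproduce: a group difference
#' in log(k) of d = 0.314 (high-symptom group lower), a group difference
#' in future orientation of d = 0.451 (high group higher),
#' r(F, log k) = -0.26, r(S, D) = 0.314 and r(F, D) = -0.290.
#'
#' @param n Number of participants (default 152, of which about 37.5%
#'   fall in the high-symptom group, as 57/152).
#' @param high_fraction Target high-symptom fraction in (0, 1).
#' @param effects Named list: d_logk_group, d_F_group, r_F_logk, r_S_D,
#'   r_F_D.
#' @param logk_mu,logk_sd Marginal location/scale of true log(k).
#' @param epsilon_beta Beta(a, b) distribution of the lapse rate
#'   (default mean 0.03).
#' @param alpha_meanlog,alpha_sdlog Log-normal acuity distribution
#'   (default median 4 USD).
#' @param n_catch Catch trials per participant.
#' @param seed Master seed.
#' @return A \code{cohort_spec} list.
#' @export
cohort_spec <- function(n = 152L,
                        high_fraction = 57 / 152,
                        effects = list(d_logk_group = 0.314,
                                       d_F_group = 0.451,
                                       r_F_logk = -0.26,
                                       r_S_D = 0.314,
                                       r_F_D = -0.290),
                        logk_mu = -4.1, logk_sd = 1.5,
                        epsilon_beta = c(3, 97),
                        alpha_meanlog = log(4), alpha_sdlog = 0.2,
                        n_catch = 10L,
                        seed = 1L) {
  if (high_fraction <= 0 || high_fraction >= 1)
    stop("high_fraction must lie in (0, 1)")
  need <- c("d_logk_group", "d_F_group", "r_F_logk", "r_S_D", "r_F_D")
  miss <- setdiff(need, names(effects))
  if (length(miss)) stop("effects missing: ", paste(miss, collapse = ", "))
  structure(list(n = as.integer(n), high_fraction = high_fraction,
                 effects = effects, logk_mu = logk_mu, logk_sd = logk_sd,
                 epsilon_beta = epsilon_beta,
                 alpha_meanlog = alpha_meanlog, alpha_sdlog = alpha_sdlog,
                 n_catch = as.integer(n_catch), seed = as.integer(seed)),
            class = "cohort_spec")
}

# Moments of a standard normal truncated at c: used to translate the
# requested group-contrast effect sizes into latent-trait coefficients.
.trunc_moments <- function(p_hi) {
  c0 <- stats::qnorm(1 - p_hi)
  ph <- stats::dnorm(c0)
  mu_hi <- ph / p_hi
  mu_lo <- -ph / (1 - p_hi)
  v_hi <- 1 + c0 * ph / p_hi - mu_hi^2
  v_lo <- 1 - c0 * ph / (1 - p_hi) - mu_lo^2
  list(cut = c0, delta = mu_hi - mu_lo,
       v_pool = p_hi * v_hi + (1 - p_hi) * v_lo)
}

# Solve the latent structural coefficients implied by the effect map:
# F = lam*S + e_F, eta_logk = bS*S + bF*F + e_k, D = cS*S + cF*F + e_D,
# all unit-variance, with the group defined by thresholding S.
.solve_structure <- function(effects, p_hi) {
  tm <- .trunc_moments(p_hi)
  d_of <- function(u) u * tm$delta / sqrt(u^2 * tm$v_pool + (1 - u^2))
  solve_u <- function(target) {
    if (target < 0) stop("group effect sizes must be non-negative")
    if (target < 1e-12) return(0)
    stats::uniroot(function(u) d_of(u) - target, c(0, 1 - 1e-6),
                   tol = 1e-10)$root
  }
  lam <- solve_u(effects$d_F_group)
  u <- -solve_u(effects$d_logk_group)  # high-symptom group has lower log(k)
  bF <- (effects$r_F_logk - lam * u) / (1 - lam^2)
  bS <- u - bF * lam
  var_ek <- 1 - u^2 - bF^2 * (1 - lam^2)
  cS <- (effects$r_S_D - lam * effects$r_F_D) / (1 - lam^2)
  cF <- effects$r_F_D - cS * lam
  var_eD <- 1 - (cS^2 + cF^2 + 2 * cS * cF * lam)
  if (var_ek <= 0 || var_eD <= 0)
    stop("infeasible effect map: implied latent correlation matrix ",
         "is not positive-definite")
  list(lam = lam, bS = bS, bF = bF, var_ek = var_ek,
       cS = cS, cF = cF, var_eD = var_eD, cut = tm$cut)
}

# Graded item responses: one latent draw per item with common thresholds
# plus per-item offsets; returns an n x n_items integer matrix of
# category indices starting at `base`.
.graded_items <- function(z, thresholds, offsets, disc, base = 1L) {
  n <- length(z)
  J <- length(offsets)
  lat <- outer(z, offsets, "-") + matrix(stats::rnorm(n * J, 0, 1 / disc),
                                         n, J)
  ans <- matrix(base, n, J)
  for (t in thresholds) ans <- ans + (lat > t)
  ans
}

# EAT-26 calibration: find the common threshold offset tau such that the
# expected total equals the cutoff (19.5, between 19 and 20) for a
# participant sitting exactly at the latent group boundary.
.eat_tau <- function(cut, item_offsets, disc, steps = c(0, 0.55, 1.1)) {
  expected_total <- function(tau) {
    sum(vapply(item_offsets, function(d0)
      sum(stats::pnorm(disc * (cut - tau - steps - d0))), numeric(1)))
  }
  stats::uniroot(function(tau) expected_total(tau) - 19.5,
                 c(-3, 3), tol = 1e-8)$root
}

#' Generate a full synthetic study
#'
#' Draws latent traits with the calibrated structure, generates
#' item-level questionnaire responses (so that symptom-group assignment
#' flows through the actual EAT-26 scoring path), per-participant
#' discounting parameters and choice data from the psychometric choice
#' model, temporal-task tables with no planted group effects (matching
#' the null results for those tasks), and demographics. Ground truth is
#' returned separately and is never consumed by analysis stages.
#'
#' @param spec A \code{\link{cohort_spec}}.
#' @param choice_set Optional \code{choice_set}; default is the
#'   144-trial layout built from \code{spec$seed}.
#' @return List with \code{items} (long item table), \code{choices}
#'   (long response table incl. catch trials), \code{volle},
#'   \code{zauberman}, \code{demographics}, \code{truth},
#'   \code{choice_set}, \code{catch}.
#' @export
generate_cohort <- function(spec = cohort_spec(), choice_set = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  coefs <- .solve_structure(spec$effects, spec$high_fraction)
  n <- spec$n
  old <- .Random.seed_guard(spec$seed)
  on.exit(old(), add = TRUE)

  S <- stats::rnorm(n)
  F_ <- coefs$lam * S + sqrt(1 - coefs$lam^2) * stats::rnorm(n)
  D <- coefs$cS * S + coefs$cF * F_ + sqrt(coefs$var_eD) * stats::rnorm(n)
  eta <- coefs$bS * S + coefs$bF * F_ + sqrt(coefs$var_ek) * stats::rnorm(n)
  logk <- spec$logk_mu + spec$logk_sd * eta
  eps <- stats::rbeta(n, spec$epsilon_beta[1], spec$epsilon_beta[2])
  alpha <- stats::rlnorm(n, spec$alpha_meanlog, spec$alpha_sdlog)
  ids <- seq_len(n)

  items <- .generate_items(S, F_, D, coefs)

  if (is.null(choice_set))
    choice_set <- build_choice_set(seed = spec$seed)
  catch <- if (spec$n_catch > 0) make_catch_trials(spec$n_catch) else NULL
  choices <- .generate_choices(ids, logk, eps, alpha, choice_set, catch)

  volle <- .generate_volle(ids)
  zaub <- .generate_zauberman(ids)

  age <- pmin(pmax(round(27.3 + 9.7 * (0.22 * S +
                                         sqrt(1 - 0.22^2) * stats::rnorm(n))),
                   18), 60)
  demographics <- data.frame(
    participant_id = ids,
    age = age,
    gender = sample(c("female", "male"), n, TRUE, prob = c(0.72, 0.28)),
    income = sample(1:7, n, TRUE),
    stringsAsFactors = FALSE)

  truth <- data.frame(participant_id = ids, S = S, F = F_, D = D,
                      logk = logk, epsilon = eps, alpha = alpha)
  list(items = items, choices = choices, volle = volle, zauberman = zaub,
       demographics = demographics, truth = truth,
       choice_set = choice_set, catch = catch,
       structure_coefs = coefs)
}

.generate_items <- function(S, F_, D, coefs) {
  n <- length(S)
  ids <- seq_len(n)
  long <- function(instrument, item_numbers, mat) {
    data.frame(participant_id = rep(ids, times = length(item_numbers)),
               instrument = instrument,
               item = rep(item_numbers, each = n),
               response = c(mat),
               stringsAsFactors = FALSE)
  }

  # EAT-26: item difficulty spread and discrimination chosen so the
  # group totals resemble a screened community sample while keeping
  # assignment through the scoring path close to the latent boundary
  disc_eat <- 2
  off_eat <- seq(-1.5, 1.5, length.out = 26)
  tau <- .eat_tau(coefs$cut, off_eat, disc_eat, steps = c(0, 1.5, 3))
  codes <- .graded_items(S, tau + c(0, 1.5, 3), off_eat, disc_eat,
                         base = 0L)
  lab_fwd <- matrix("", n, 25)
  zero_labels <- c("Never", "Rarely", "Sometimes")
  for (j in 1:25) {
    cj <- codes[, j]
    lab_fwd[, j] <- ifelse(cj == 0,
                           zero_labels[sample.int(3, n, TRUE)],
                           c("Often", "Usually", "Always")[pmax(cj, 1)])
  }
  lab26 <- c("Often", "Sometimes", "Rarely", "Never")[codes[, 26] + 1L]
  eat_long <- rbind(long("eat26", 1:25, lab_fwd),
                    long("eat26", 26L, matrix(lab26, ncol = 1)))

  # CFC: 12 items, keyed score 1..5 generated from F, reversed items
  # stored as raw = 6 - score so the scorer undoes the reversal
  key_cfc <- default_scoring_keys()$cfc
  s_cfc <- .graded_items(F_, c(-1.5, -0.5, 0.5, 1.5),
                         seq(-0.3, 0.3, length.out = 12), disc = 1.2)
  raw_cfc <- s_cfc
  raw_cfc[, key_cfc$reversed] <- 6L - s_cfc[, key_cfc$reversed]
  cfc_long <- long("cfc", 1:12, raw_cfc)

  # ZTPI future subscale items from F
  key_z <- default_scoring_keys()$ztpi_future
  s_z <- .graded_items(F_, c(-1.5, -0.5, 0.5, 1.5),
                       seq(-0.3, 0.3, length.out = length(key_z$items)),
                       disc = 1.2)
  raw_z <- s_z
  rev_pos <- match(key_z$reversed, key_z$items)
  raw_z[, rev_pos] <- 6L - s_z[, rev_pos]
  ztpi_long <- long("ztpi", key_z$items, raw_z)

  # PFE: 10 thoughts; future probability increases with F
  p_future <- stats::plogis(-0.4 + 0.5 * F_)
  n_future <- stats::rbinom(n, 10L, p_future)
  pfe_mat <- t(vapply(seq_len(n), function(i) {
    lab <- c(rep("future", n_future[i]),
             sample(c("past", "present"), 10L - n_future[i], TRUE))
    sample(lab)
  }, character(10)))
  pfe_long <- long("pfe", 1:10, pfe_mat)

  # Dispositional-negativity battery from D
  bdi <- .graded_items(D, c(0.8, 1.8, 2.6),
                       seq(-0.4, 0.4, length.out = 21), disc = 1,
                       base = 0L)
  key_st <- default_scoring_keys()$stai_t
  s_st <- .graded_items(D, c(-1, 0, 1), seq(-0.3, 0.3, length.out = 20),
                        disc = 1.2)
  raw_st <- s_st
  raw_st[, key_st$reversed] <- 5L - s_st[, key_st$reversed]
  atq <- .graded_items(D, c(-2, -1.2, -0.4, 0.4, 1.2, 2),
                       seq(-0.3, 0.3, length.out = 26), disc = 1)

  rbind(eat_long, cfc_long, ztpi_long, pfe_long,
        long("bdi", 1:21, bdi),
        long("stai_t", 1:20, raw_st),
        long("atq_na", 1:26, atq))
}

.generate_choices <- function(ids, logk, eps, alpha, cs, catch) {
  n <- length(ids)
  task <- as.data.frame(cs)[!cs$is_catch, ]
  k <- exp(logk)
  # trials x participants matrix of LL-choice probabilities
  svd <- outer(seq_len(nrow(task)), seq_len(n), function(t, p) {
    task$ll_amount[t] / (1 + k[p] * task$ll_delay_days[t]) -
      task$ss_amount[t] / (1 + k[p] * task$ss_delay_days[t])
  })
  pr <- rep(eps, each = nrow(task)) +
    (1 - 2 * rep(eps, each = nrow(task))) *
    stats::pnorm(svd / rep(alpha, each = nrow(task)))
  y <- stats::rbinom(length(pr), 1L, pr)
  out <- data.frame(
    participant_id = rep(ids, each = nrow(task)),
    trial_id = rep(task$trial_id, times = n),
    is_catch = FALSE,
    choice = ifelse(y == 1L, "LL", "SS"),
    stringsAsFactors = FALSE)
  if (!is.null(catch)) {
    yc <- stats::rbinom(n * nrow(catch), 1L,
                        1 - rep(eps, each = nrow(catch)))
    out <- rbind(out, data.frame(
      participant_id = rep(ids, each = nrow(catch)),
      trial_id = rep(catch$trial_id, times = n),
      is_catch = TRUE,
      choice = ifelse(yc == 1L, "LL", "SS"),
      stringsAsFactors = FALSE))
  }
  out
}

.generate_volle <- function(ids) {
  n <- length(ids)
  targets <- list("1Hz" = c(20, 30, 40, 50), "0.5Hz" = c(15, 20, 25, 30))
  bias1 <- stats::rnorm(n, -6.9, 11)
  bias2 <- stats::rnorm(n, -11.7, 14)
  rows <- lapply(seq_len(n), function(i) {
    data.frame(participant_id = ids[i],
               condition = rep(names(targets), each = 4),
               target_s = unlist(targets, use.names = FALSE),
               estimate_s = pmax(unlist(targets, use.names = FALSE) +
                                   rep(c(bias1[i], bias2[i]), each = 4) +
                                   stats::rnorm(8, 0, 3), 1),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.generate_zauberman <- function(ids) {
  n <- length(ids)
  horizons <- default_zauberman_horizons()
  gamma <- pmin(pmax(stats::rnorm(n, 0.75, 0.15), 0.3), 1.1)
  rows <- lapply(seq_len(n), function(i) {
    slider <- 0.08 * (horizons / 7)^gamma[i] *
      exp(stats::rnorm(length(horizons), 0, 0.2))
    data.frame(participant_id = ids[i],
               horizon_days = horizons,
               slider = pmin(pmax(slider, 0.01), 1),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cleaning rules for a raw study bundle
#'
#' @param catch_accuracy_min Minimum fraction of catch trials answered
#'   with the dominant option.
#' @param require_instruments Instruments every participant must have
#'   completed (item counts per the default keys).
#' @return A \code{cleaning_rules} list.
#' @export
cleaning_rules <- function(catch_accuracy_min = 0.5,
                           require_instruments = c("eat26", "cfc", "ztpi",
                                                   "pfe", "bdi", "stai_t",
                                                   "atq_na")) {
  structure(list(catch_accuracy_min = catch_accuracy_min,
                 require_instruments = require_instruments),
            class = "cleaning_rules")
}

#' Apply pre-analysis cleaning to a raw study bundle
#'
#' Excludes participants failing the catch-trial accuracy threshold and
#' participants with incomplete required instruments; every exclusion is
#' logged with a reason code. Remaining tables are filtered listwise.
#'
#' @param raw List with at least \code{choices} and \code{items} (as from
#'   \code{\link{generate_cohort}}).
#' @param rules A \code{\link{cleaning_rules}}.
#' @return List with the filtered \code{tables} and an \code{exclusions}
#'   data.frame (participant_id, reason).
#' @export
clean_dataset <- function(raw, rules = cleaning_rules()) {
  expected_items <- c(eat26 = 26L, cfc = 12L,
                      ztpi = length(default_scoring_keys()$ztpi_future$items),
                      pfe = 1L, bdi = 21L, stai_t = 20L, atq_na = 26L)
  ids <- sort(unique(c(raw$choices$participant_id,
                       raw$items$participant_id)))
  excl <- list()

  ids_chr <- as.character(ids)

  ch <- raw$choices[raw$choices$is_catch, , drop = FALSE]
  if (nrow(ch)) {
    acc <- tapply(ch$choice == "LL", as.character(ch$participant_id), mean)
    bad <- names(acc)[acc < rules$catch_accuracy_min]
    if (length(bad))
      excl$catch <- data.frame(participant_id = bad, reason = "catch",
                               stringsAsFactors = FALSE)
  }

  cnt <- table(as.character(raw$items$participant_id), raw$items$instrument)
  for (instr in rules$require_instruments) {
    need <- expected_items[[instr]]
    have <- if (instr %in% colnames(cnt)) cnt[, instr] else
      stats::setNames(rep(0L, nrow(cnt)), rownames(cnt))
    bad <- rownames(cnt)[have < need]
    bad <- union(bad, setdiff(ids_chr, rownames(cnt)))
    if (length(bad))
      excl[[paste0("inc_", instr)]] <-
        data.frame(participant_id = bad, reason = "incomplete",
                   stringsAsFactors = FALSE)
  }
  exclusions <- if (length(excl)) unique(do.call(rbind, excl)) else
    data.frame(participant_id = character(0), reason = character(0),
               stringsAsFactors = FALSE)
  rownames(exclusions) <- NULL
  keep <- setdiff(ids_chr, exclusions$participant_id)
  filt <- function(tb) {
    if (is.null(tb)) return(NULL)
    if (!"participant_id" %in% names(tb)) return(tb)
    tb[as.character(tb$participant_id) %in% keep, , drop = FALSE]
  }
  tables <- raw
  for (nm in c("items", "choices", "volle", "zauberman", "demographics",
               "truth"))
    tables[[nm]] <- filt(raw[[nm]])
  list(tables = tables, exclusions = exclusions, kept = keep)
}
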