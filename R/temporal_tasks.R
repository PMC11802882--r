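#' Volle time-estimation accuracy
#'
#' Scores the silent-counting duration-estimation task: per frequency
#' condition (counting paced at 1 Hz or 0.5 Hz), the mean signed error
#' estimate - target in seconds. Negative values indicate
#' under-estimation of the interval. Each condition is a complete
#' four-trial block (targets 20/30/40/50 s at 1 Hz; 15/20/25/30 s at
#' 0.5 Hz); a condition wholly absent is returned as NA and flagged.
#'
#' @param trials Data.frame with columns \code{condition} (\code{"1Hz"}
#'   or \code{"0.5Hz"}), \code{target_s}, \code{estimate_s}.
#' @return Data.frame with one row per condition: \code{condition},
#'   \code{mean_error_s}, \code{n_trials}, \code{missing}.
#' @export
volle_accuracy <- function(trials) {
  targets <- list("1Hz" = c(20, 30, 40, 50), "0.5Hz" = c(15, 20, 25, 30))
  if (!all(trials$condition %in% names(targets)))
    stop("condition must be '1Hz' or '0.5Hz'")
  rows <- lapply(names(targets), function(cond) {
    sub <- trials[trials$condition == cond, , drop = FALSE]
    if (!nrow(sub))
      return(data.frame(condition = cond, mean_error_s = NA_real_,
                        n_trials = 0L, missing = TRUE))
    if (!setequal(sub$target_s, targets[[cond]]) ||
        nrow(sub) != length(targets[[cond]]))
      stop("incomplete ", cond, " block: need one trial at each target ",
           paste(targets[[cond]], collapse = ", "), " s")
    data.frame(condition = cond,
               mean_error_s = mean(sub$estimate_s - sub$target_s),
               n_trials = nrow(sub), missing = FALSE)
  })
  do.call(rbind, rows)
}

#' Zauberman future-time growth ratios
#'
#' For each horizon beyond the 1-week anchor, the ratio of subjective to
#' objective growth: subjective growth is the relative slider change from
#' the anchor, (s_t - s_a)/s_a; objective growth is the relative
#' calendar-time change, (t - t_a)/t_a. A ratio of 1 indicates accurate
#' prospective scaling of future durations; below 1, compressed future
#' time.
#'
#' @param responses Data.frame with \code{horizon_days} and \code{slider}
#'   (in [0, 1]); the shortest horizon is the anchor (nominally 7 days)
#'   and must have slider > 0.
#' @return List with \code{ratios} (data.frame \code{horizon_days},
#'   \code{growth_ratio}) and \code{mean_ratio}.
#' @export
zauberman_growth_ratio <- function(responses) {
  if (nrow(responses) < 2L) stop("need the anchor plus >= 1 horizon")
  responses <- responses[order(responses$horizon_days), , drop = FALSE]
  anchor <- responses[1L, ]
  if (anchor$slider <= 0)
    stop("anchor slider must be > 0 (subjective growth is undefined)")
  rest <- responses[-1L, , drop = FALSE]
  objective <- (rest$horizon_days - anchor$horizon_days) / anchor$horizon_days
  subjective <- (rest$slider - anchor$slider) / anchor$slider
  ratio <- subjective / objective
  list(ratios = data.frame(horizon_days = rest$horizon_days,
                           growth_ratio = ratio),
       mean_ratio = mean(ratio))
}

#' Default Zauberman horizon grid
#'
#' Week = 7 days, month = 30, year = 365: 1 week (anchor), 1 month,
#' 3 months, 6 months, 1 year, 3 years, 5 years, 10 years.
#'
#' @return Numeric vector of horizons in days.
#' @export
default_zauberman_horizons <- function() {
  c(7, 30, 90, 180, 365, 3 * 365, 5 * 365, 10 * 365)
}
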