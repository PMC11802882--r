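#' Default instrument scoring keys
#'
#' Reverse-keying maps and item counts for the shipped instruments. The
#' ZTPI future-orientation subscale and STAI trait reversals follow the
#' published instruments; the ATQ negative-affect key is shipped as an
#' editable default (item memberships of licensed short forms vary by
#' distribution) and should be replaced with the administered form's key
#' when scoring real data.
#'
#' @return A named list of per-instrument key lists.
#' @export
default_scoring_keys <- function() {
  list(
    eat26 = list(n_items = 26L,
                 labels = c("Never", "Rarely", "Sometimes", "Often",
                            "Usually", "Always"),
                 bn_items = c(4L, 9L, 25L)),
    cfc = list(n_items = 12L, levels = 1:5,
               reversed = c(3L, 4L, 5L, 9L, 10L, 11L, 12L)),
    ztpi_future = list(items = c(6L, 9L, 10L, 13L, 18L, 21L, 24L, 30L,
                                 40L, 43L, 45L, 51L, 56L),
                       reversed = c(9L, 24L, 56L), levels = 1:5),
    bdi = list(n_items = 21L, levels = 0:3),
    stai_t = list(n_items = 20L, levels = 1:4,
                  reversed = c(1L, 3L, 6L, 7L, 10L, 13L, 14L, 16L, 19L)),
    atq_na = list(n_items = 26L, levels = 1:7, reversed = integer(0))
  )
}

.eat26_codes_fwd <- c(Never = 0, Rarely = 0, Sometimes = 0,
                      Often = 1, Usually = 2, Always = 3)
.eat26_codes_rev <- c(Never = 3, Rarely = 2, Sometimes = 1,
                      Often = 0, Usually = 0, Always = 0)

.as_eat26_labels <- function(responses) {
  labs <- names(.eat26_codes_fwd)
  if (is.numeric(responses)) {
    if (any(!responses %in% 1:6))
      stop("numeric EAT-26 responses must be levels 1..6")
    labs[responses]
  } else {
    responses <- as.character(responses)
    if (any(!responses %in% labs))
      stop("unknown EAT-26 response label(s): ",
           paste(setdiff(responses, labs), collapse = ", "))
    responses
  }
}

#' Score the Eating Attitudes Test (EAT-26)
#'
#' Items 1-25: Never/Rarely/Sometimes code 0, Often 1, Usually 2, Always
#' 3. Item 26 is reverse-anchored: Always/Usually/Often code 0, Sometimes
#' 1, Rarely 2, Never 3. The total ranges 0-78. With
#' \code{exclude_bn_items}, the binge-eating/purging items (4, 9, 25) are
#' omitted before summing, giving a bulimia-insensitive variant (max 69).
#'
#' @param responses Length-26 vector of response labels (Never..Always)
#'   or numeric levels 1..6, ordered by item number.
#' @param exclude_bn_items Drop items 4, 9 and 25 before summing.
#' @return Integer total score.
#' @export
score_eat26 <- function(responses, exclude_bn_items = FALSE) {
  if (length(responses) != 26L) {
    present <- seq_along(responses)
    stop("EAT-26 requires items 1..26; missing item(s): ",
         paste(setdiff(1:26, present), collapse = ", "))
  }
  labels <- .as_eat26_labels(responses)
  codes <- c(.eat26_codes_fwd[labels[1:25]], .eat26_codes_rev[labels[26]])
  if (exclude_bn_items)
    codes <- codes[-default_scoring_keys()$eat26$bn_items]
  as.integer(sum(codes))
}

#' Assign symptom group from an EAT-26 total
#'
#' The clinical screening cutoff is 20; scores at or above it are labeled
#' high-symptom by default (the referral guidance treats 20 as already
#' elevated; set \code{ties} to \code{"low"} for a strict "above 20"
#' rule).
#'
#' @param eat26_total Numeric total(s).
#' @param cutoff Cutoff score (default 20).
#' @param ties Group for a score exactly at the cutoff.
#' @return Factor with levels \code{low}, \code{high}.
#' @export
assign_symptom_group <- function(eat26_total, cutoff = 20,
                                 ties = c("high", "low")) {
  ties <- match.arg(ties)
  if (any(eat26_total < 0, na.rm = TRUE)) stop("scores must be non-negative")
  hi <- if (ties == "high") eat26_total >= cutoff else eat26_total > cutoff
  factor(ifelse(hi, "high", "low"), levels = c("low", "high"))
}

#' Score the Consideration of Future Consequences scale (CFC)
#'
#' Twelve items on a 1-5 characteristic-ness scale; items 3-5 and 9-12
#' are reverse-scored (6 - raw). The total ranges 12-60, higher meaning
#' more future-weighted everyday decision making.
#'
#' @param responses Length-12 vector of raw levels 1..5, by item number.
#' @return Integer total in [12, 60].
#' @export
score_cfc <- function(responses) {
  key <- default_scoring_keys()$cfc
  if (length(responses) != key$n_items)
    stop("CFC requires 12 items")
  if (any(!responses %in% key$levels))
    stop("CFC responses must be raw levels 1..5")
  scored <- responses
  scored[key$reversed] <- 6 - responses[key$reversed]
  as.integer(sum(scored))
}

#' Score the ZTPI future-orientation subscale
#'
#' Mean of the keyed future-subscale items (reverse-keyed items scored
#' 6 - raw) on the 1-5 characteristic-ness scale.
#'
#' @param responses Named numeric vector of raw levels; names are ZTPI
#'   item numbers (a full 56-item response vector also works with
#'   default sequential names).
#' @param key List with \code{items} and \code{reversed} (item numbers).
#' @return Mean subscale score in [1, 5].
#' @export
score_ztpi_future <- function(responses, key = default_scoring_keys()$ztpi_future) {
  if (is.null(names(responses)))
    names(responses) <- as.character(seq_along(responses))
  items <- as.character(key$items)
  miss <- setdiff(items, names(responses))
  if (length(miss))
    stop("ZTPI future subscale incomplete; missing item(s): ",
         paste(miss, collapse = ", "))
  raw <- responses[items]
  if (any(!raw %in% 1:5)) stop("ZTPI responses must be raw levels 1..5")
  rev_idx <- items %in% as.character(key$reversed)
  raw[rev_idx] <- 6 - raw[rev_idx]
  mean(raw)
}

#' Preoccupation with Future Events ratio
#'
#' Fraction of listed recent thoughts labeled as pertaining to the
#' future (versus past or present); nominally 10 thoughts per person.
#'
#' @param thoughts Character vector of labels in
#'   \{past, present, future\}.
#' @return Ratio in [0, 1].
#' @export
score_pfe <- function(thoughts) {
  if (length(thoughts) == 0L) stop("at least one labeled thought required")
  thoughts <- tolower(as.character(thoughts))
  if (any(!thoughts %in% c("past", "present", "future")))
    stop("thought labels must be past/present/future")
  mean(thoughts == "future")
}

#' Score the dispositional-negativity instruments
#'
#' BDI: 21 items coded 0-3, summed (0-63). STAI-T: 20 items on 1-4 with
#' the published reverse key (5 - raw), summed (20-80). ATQ negative
#' affect: mean of keyed items on 1-7 (reversals per key).
#'
#' @param bdi,stai_t,atq_na Raw response vectors ordered by item number.
#' @param keys Key list as from \code{\link{default_scoring_keys}}.
#' @return List with \code{bdi_total}, \code{stai_t_total},
#'   \code{atq_na_mean}.
#' @export
score_dn_instruments <- function(bdi, stai_t, atq_na,
                                 keys = default_scoring_keys()) {
  list(bdi_total = score_bdi(bdi, keys$bdi),
       stai_t_total = score_stai_t(stai_t, keys$stai_t),
       atq_na_mean = score_atq_na(atq_na, keys$atq_na))
}

#' @rdname score_dn_instruments
#' @param key Single-instrument key.
#' @export
score_bdi <- function(bdi, key = default_scoring_keys()$bdi) {
  if (length(bdi) != key$n_items)
    stop("BDI requires ", key$n_items, " items")
  if (any(!bdi %in% key$levels)) stop("BDI responses must be coded 0..3")
  as.integer(sum(bdi))
}

#' @rdname score_dn_instruments
#' @export
score_stai_t <- function(stai_t, key = default_scoring_keys()$stai_t) {
  if (length(stai_t) != key$n_items)
    stop("STAI-T requires ", key$n_items, " items")
  if (any(!stai_t %in% key$levels))
    stop("STAI-T responses must be raw levels 1..4")
  scored <- stai_t
  scored[key$reversed] <- 5 - stai_t[key$reversed]
  as.integer(sum(scored))
}

#' @rdname score_dn_instruments
#' @export
score_atq_na <- function(atq_na, key = default_scoring_keys()$atq_na) {
  if (length(atq_na) != key$n_items)
    stop("ATQ-NA requires ", key$n_items, " items")
  if (any(!atq_na %in% key$levels))
    stop("ATQ-NA responses must be raw levels 1..7")
  scored <- atq_na
  if (length(key$reversed))
    scored[key$reversed] <- (max(key$levels) + 1) - atq_na[key$reversed]
  mean(scored)
}

#' Score a long item-response table into a per-participant score table
#'
#' Consumes a long table (\code{participant_id}, \code{instrument},
#' \code{item}, \code{response}) covering any subset of the instruments
#' eat26, cfc, ztpi, bdi, stai_t, atq_na and pfe (pfe responses are the
#' past/present/future labels). Participants missing an instrument get
#' NA for its score.
#'
#' @param items Long item-response data.frame.
#' @param keys Scoring keys.
#' @param cutoff,ties Passed to \code{\link{assign_symptom_group}}.
#' @return Data.frame with one row per participant: eat26_total,
#'   eat26_noBN_total, symptom_group, symptom_group_noBN, cfc_total,
#'   ztpi_future_mean, pfe_ratio, bdi_total, stai_t_total, atq_na_mean.
#' @export
score_battery <- function(items, keys = default_scoring_keys(),
                          cutoff = 20, ties = "high") {
  need <- c("participant_id", "instrument", "item", "response")
  miss <- setdiff(need, names(items))
  if (length(miss)) stop("item table missing columns: ",
                         paste(miss, collapse = ", "))
  dup <- duplicated(items[, c("participant_id", "instrument", "item")])
  if (any(dup)) stop("duplicate (participant, instrument, item) rows")
  ids <- sort(unique(items$participant_id))

  one <- function(pid_items, instrument, scorer, n_req) {
    sub <- pid_items[pid_items$instrument == instrument, , drop = FALSE]
    if (!nrow(sub)) return(NA_real_)
    sub <- sub[order(as.integer(sub$item)), , drop = FALSE]
    scorer(sub)
  }
  rows <- lapply(ids, function(id) {
    pi <- items[items$participant_id == id, , drop = FALSE]
    eat <- one(pi, "eat26", function(s) {
      r <- s$response
      names(r) <- NULL
      score_eat26(if (is.character(r)) r else as.numeric(r))
    })
    eat_nobn <- one(pi, "eat26", function(s) {
      r <- s$response
      names(r) <- NULL
      score_eat26(if (is.character(r)) r else as.numeric(r),
                  exclude_bn_items = TRUE)
    })
    ztpi <- one(pi, "ztpi", function(s) {
      r <- as.numeric(s$response)
      names(r) <- as.character(s$item)
      score_ztpi_future(r, keys$ztpi_future)
    })
    data.frame(
      participant_id = id,
      eat26_total = eat,
      eat26_noBN_total = eat_nobn,
      cfc_total = one(pi, "cfc", function(s) score_cfc(as.numeric(s$response))),
      ztpi_future_mean = ztpi,
      pfe_ratio = one(pi, "pfe", function(s) score_pfe(s$response)),
      bdi_total = one(pi, "bdi", function(s)
        score_bdi(as.numeric(s$response), keys$bdi)),
      stai_t_total = one(pi, "stai_t", function(s)
        score_stai_t(as.numeric(s$response), keys$stai_t)),
      atq_na_mean = one(pi, "atq_na", function(s)
        score_atq_na(as.numeric(s$response), keys$atq_na)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$symptom_group <- assign_symptom_group(out$eat26_total, cutoff, ties)
  out$symptom_group_noBN <- assign_symptom_group(out$eat26_noBN_total,
                                                 cutoff, ties)
  out
}
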