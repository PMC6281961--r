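# Scoring of the task-motivation questionnaire: a 10-item task-motivation
# inventory (PMI, 5-point Likert items), a 10-item mood scale (PANAVA:
# positive activation, negative activation, valence; 7-point bipolar
# items), and 4 social-desirability (SDS) items used to residual-correct
# the motivation score.

#' Default item key for the motivation questionnaire
#'
#' One row per item: instrument (`PMI`, `PANAVA`, `SDS`), item id, scale
#' points, and polarity.  PMI holds 10 five-point items; the original
#' instrument mixes positively and negatively worded items (e.g. "I wish I
#' did not have to perform this task"), and this default key marks items
#' 1, 4 and 7 as negative -- the key is configuration, not a published
#' constant, and should be replaced with the user's own wording-derived
#' key.  PANAVA holds 4 positive-activation, 2 valence (both positively
#' related to motivation) and 4 negative-activation items on 7 points.
#' SDS holds 4 binary items (0/1, keyed positively).
#'
#' @return Tibble with columns `instrument`, `item_id`, `scale_points`,
#'   `polarity`.
#' @export
default_item_key <- function() {
  tibble::tibble(
    instrument = c(rep("PMI", 10), rep("PANAVA", 10), rep("SDS", 4)),
    item_id = c(sprintf("pmi_%02d", 1:10),
                paste0("pa_", 1:4), paste0("va_", 1:2), paste0("na_", 1:4),
                c("sds_07", "sds_08", "sds_17", "sds_22")),
    scale_points = c(rep(5L, 10), rep(7L, 10), rep(2L, 4)),
    polarity = c(ifelse(1:10 %in% c(1, 4, 7), "negative", "positive"),
                 rep("positive", 6), rep("negative", 4),
                 rep("positive", 4))
  )
}

key_for <- function(key, instrument) {
  k <- key[key$instrument == instrument, , drop = FALSE]
  if (!nrow(k)) stop("item key holds no ", instrument, " items")
  k
}

# match a response table/vector against one instrument's key; returns
# responses ordered as in the key
align_responses <- function(responses, k, range_lo, range_hi) {
  if (is.data.frame(responses)) {
    stopifnot(all(c("item_id", "response") %in% names(responses)))
    r <- stats::setNames(responses$response, responses$item_id)
  } else {
    r <- responses
    if (is.null(names(r))) names(r) <- k$item_id[seq_along(r)]
  }
  if (!setequal(names(r), k$item_id) || length(r) != nrow(k)) {
    stop("responses must cover exactly the ", nrow(k), " ",
         k$instrument[1], " items")
  }
  r <- as.numeric(r[k$item_id])
  if (anyNA(r) || any(r < range_lo | r > range_hi) || any(r != round(r))) {
    stop(k$instrument[1], " responses must be integers in [",
         range_lo, ", ", range_hi, "]")
  }
  r
}

#' PMI composite and percent score
#'
#' Responses on 1..5 are polarity-coded (negative items are reversed:
#' value becomes `6 - value`) and summed; the composite spans 10 to 50
#' and is mapped linearly onto 0-100%.
#'
#' @param responses 10 responses: a named vector or a tibble with
#'   `item_id` and `response`.
#' @param key Item key (see [default_item_key()]).
#' @return `pmi_composite()`: the polarity-coded sum;
#'   `score_pmi()`: the percent score.
#' @export
pmi_composite <- function(responses, key = default_item_key()) {
  k <- key_for(key, "PMI")
  r <- align_responses(responses, k, 1, 5)
  scored <- ifelse(k$polarity == "negative", 6 - r, r)
  sum(scored)
}

#' @rdname pmi_composite
#' @export
score_pmi <- function(responses, key = default_item_key()) {
  (pmi_composite(responses, key) - 10) / (50 - 10) * 100
}

#' PANAVA composite and percent score
#'
#' Positive-activation and valence items add their response value;
#' negative-activation items subtract theirs (they only contribute
#' negative points).  With 6 positive and 4 negative 7-point items the
#' composite spans -22 to 38 and is mapped linearly onto 0-100%.
#'
#' @inheritParams pmi_composite
#' @return `panava_composite()`: the signed sum; `score_panava()`: the
#'   percent score.
#' @export
panava_composite <- function(responses, key = default_item_key()) {
  k <- key_for(key, "PANAVA")
  r <- align_responses(responses, k, 1, 7)
  sum(ifelse(k$polarity == "negative", -r, r))
}

#' @rdname panava_composite
#' @export
score_panava <- function(responses, key = default_item_key()) {
  (panava_composite(responses, key) - (-22)) / (38 - (-22)) * 100
}

#' Social-desirability points
#'
#' Binary keyed scoring of the 4 SDS items: each response matching the
#' keyed direction scores one point (negative-polarity items count
#' `1 - response`).
#'
#' @inheritParams pmi_composite
#' @return Integer points, 0..4.
#' @export
score_sds <- function(responses, key = default_item_key()) {
  k <- key_for(key, "SDS")
  r <- align_responses(responses, k, 0, 1)
  sum(ifelse(k$polarity == "negative", 1 - r, r))
}

#' Score a long item-response table into motivation scores
#'
#' For every participant x experimental part, computes the PMI and PANAVA
#' percent scores, their mean (the uncorrected motivation score) and the
#' SDS points.
#'
#' @param items Long tibble with columns `participant`, `part`
#'   (`"motivation"` / `"demotivation"`), `instrument`, `item_id`,
#'   `response`.
#' @param key Item key (see [default_item_key()]).
#' @return Tibble with one row per participant x part: `pmi_pct`,
#'   `panava_pct`, `uncorrected`, `sds`.
#' @export
score_motivation <- function(items, key = default_item_key()) {
  stopifnot(all(c("participant", "part", "instrument", "item_id", "response")
                %in% names(items)))
  groups <- split(items, interaction(items$participant, items$part, drop = TRUE))
  rows <- lapply(groups, function(g) {
    tibble::tibble(
      participant = g$participant[1],
      part = g$part[1],
      pmi_pct = score_pmi(g[g$instrument == "PMI", c("item_id", "response")], key),
      panava_pct = score_panava(g[g$instrument == "PANAVA",
                                  c("item_id", "response")], key),
      sds = score_sds(g[g$instrument == "SDS", c("item_id", "response")], key)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$uncorrected <- (out$pmi_pct + out$panava_pct) / 2
  dplyr::arrange(out[, c("participant", "part", "pmi_pct", "panava_pct",
                         "uncorrected", "sds")],
                 .data$participant, .data$part)
}

#' Social-desirability residual correction of motivation scores
#'
#' Regresses the uncorrected motivation scores on the SDS points across
#' all observations (both experimental parts pooled) and returns the
#' residuals as the corrected scores.  If the SDS points are constant the
#' regression is undefined and the mean-centered scores are returned
#' instead (documented fallback).
#'
#' @param scores Either the output of [score_motivation()] (a `corrected`
#'   column is added) or a numeric vector of uncorrected scores, in which
#'   case `sds` must be given.
#' @param sds Numeric vector of SDS points (only for vector input).
#' @return Same shape as the input: a tibble with a `corrected` column,
#'   or a numeric residual vector.
#' @export
correct_motivation <- function(scores, sds = NULL) {
  if (is.data.frame(scores)) {
    stopifnot(all(c("uncorrected", "sds") %in% names(scores)))
    scores$corrected <- correct_motivation(scores$uncorrected, scores$sds)
    return(scores)
  }
  stopifnot(length(scores) == length(sds))
  if (length(scores) < 3) stop("need >= 3 observations for the residual correction")
  if (stats::sd(sds) == 0) {
    return(scores - mean(scores))
  }
  unname(stats::residuals(stats::lm(scores ~ sds)))
}

#' Motivation-manipulation inclusion criterion
#'
#' A participant enters the final sample iff their corrected motivation
#' score in the motivation part is strictly higher than in the
#' demotivation part.
#'
#' @param scores Output of [correct_motivation()] (data-frame form), with
#'   both parts present for every participant.
#' @param use Which score column the criterion reads
#'   (default `"corrected"`; the raw-score variant uses `"uncorrected"`).
#' @return Vector of included participant ids.
#' @export
apply_inclusion <- function(scores, use = "corrected") {
  stopifnot(use %in% names(scores))
  wide <- tidyr::pivot_wider(scores[, c("participant", "part", use)],
                             names_from = "part", values_from = dplyr::all_of(use))
  if (!all(c("motivation", "demotivation") %in% names(wide)) ||
      anyNA(wide$motivation) || anyNA(wide$demotivation)) {
    stop("every participant needs scores for both parts")
  }
  wide$participant[wide$motivation > wide$demotivation]
}
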