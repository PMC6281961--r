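# Trial schedules for the two discrimination experiments.
#
# A schedule is a tibble with one row per trial.  All balancing rules
# (repetitions per stimulus-pair x positioning combination, standard side,
# first-touched side, condition alternation across sessions) are exact;
# trial order within a block is randomized reproducibly from the seed.

SCHEDULE_COLUMNS <- c("participant", "session", "block", "trial",
                      "presentation_order", "category", "comparison_id",
                      "standard_side", "first_touch_side",
                      "motivation_part", "points_at_stake")

#' Latin-square orderings for counterbalancing
#'
#' Returns `n` orderings of `n` items (a cyclic Latin square): across the
#' `n` orderings each item occupies every ordinal position exactly once.
#'
#' @param n Number of items (>= 1).
#' @return An `n x n` integer matrix; row `i` is the ordering assigned to
#'   the `i`-th participant (1-based item indices).
#' @export
latin_square_orders <- function(n) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n)) {
    stop("n must be a positive integer")
  }
  n <- as.integer(n)
  outer(seq_len(n) - 1L, seq_len(n) - 1L, function(i, j) (i + j) %% n) + 1L
}

# Deterministic per-(participant, session, block) RNG stream: schedules and
# simulations split one user seed into sub-seeds so that no block's
# randomization is coupled to another's.
derive_seed <- function(seed, ...) {
  ids <- c(...)
  s <- (as.numeric(seed) %% 2147483647) + 1
  for (k in seq_along(ids)) {
    s <- (s * 48271 + as.numeric(ids[k]) * 7919 + 104729) %% 2147483647
  }
  as.integer(s)
}

# one block's trials: cross pairs x standard side, repeat, balance first
# touch within each combination, then shuffle rows
block_trials <- function(categories, comparisons, reps, rng_seed) {
  grid <- expand.grid(category = categories, comparison = comparisons,
                      standard_side = c("left", "right"),
                      stringsAsFactors = FALSE)
  rows <- grid[rep(seq_len(nrow(grid)), each = reps), , drop = FALSE]
  # first-touched side balanced within each (pair x positioning) combination;
  # odd repetition counts leave one unpaired trial per combination
  rows$first_touch_side <- rep_len(c("left", "right"), reps)[
    rep(seq_len(reps), times = nrow(grid))]
  set.seed(rng_seed)
  rows <- rows[sample.int(nrow(rows)), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

#' Build one participant's schedule for the predictability experiment
#'
#' Four sessions of four blocks each.  Sessions alternate between the
#' blocked condition (all trials of a block drawn from one softness
#' category, so the upcoming category is predictable) and the random
#' condition (all categories intermixed), starting with `start_order`.
#' In a blocked block each (comparison x standard-side) combination of the
#' block's category is repeated `blocked_reps` times (default 24, i.e.,
#' 96 trials); in a random block each of the 16 (pair x side) combinations
#' is repeated `random_reps` times (default 6, also 96 trials).  The
#' category order of the blocked blocks is `category_order` and is
#' identical in both blocked sessions.  Defaults give 1,536 trials.
#'
#' @param participant Participant identifier (integer).
#' @param start_order `"blocked"` or `"random"`: condition of session 1.
#' @param category_order Permutation of [softness_categories()] used for
#'   the four blocks of each blocked session.
#' @param seed Integer seed; trial order within each block is shuffled
#'   from a seed derived from `(seed, participant, session, block)`.
#' @param blocked_reps,random_reps Repetitions per combination in blocked
#'   and random blocks.  The printed design uses 24 and 6; smaller values
#'   give structurally identical scaled-down schedules.
#' @return A tibble with one row per trial (columns `participant`,
#'   `session`, `block`, `trial`, `presentation_order`, `category`,
#'   `comparison_id`, `standard_side`, `first_touch_side`,
#'   `motivation_part`, `points_at_stake`).
#' @export
build_exp1_schedule <- function(participant = 1L,
                                start_order = c("blocked", "random"),
                                category_order = softness_categories(1),
                                seed = 1L,
                                blocked_reps = 24L, random_reps = 6L) {
  start_order <- match.arg(start_order)
  if (!setequal(category_order, softness_categories(1)) ||
      length(category_order) != 4) {
    stop("category_order must be a permutation of the four softness categories")
  }
  orders <- if (start_order == "blocked") {
    c("blocked", "random", "blocked", "random")
  } else {
    c("random", "blocked", "random", "blocked")
  }
  sessions <- lapply(1:4, function(sess) {
    blocks <- lapply(1:4, function(blk) {
      bseed <- derive_seed(seed, participant, sess, blk)
      if (orders[sess] == "blocked") {
        b <- block_trials(category_order[blk], c("c1", "c2"), blocked_reps, bseed)
      } else {
        b <- block_trials(softness_categories(1), c("c1", "c2"), random_reps, bseed)
      }
      b$session <- sess
      b$block <- blk
      b$presentation_order <- orders[sess]
      b
    })
    dplyr::bind_rows(blocks)
  })
  finish_schedule(dplyr::bind_rows(sessions), participant,
                  motivation_part = "none", label = "exp1", seed = seed)
}

#' Build one participant's schedule for the motivation experiment
#'
#' A single session of four blocks of 112 trials (448 in total with the
#' default `reps = 14`): in every block the eight stimulus-pair
#' combinations (2 categories x 2 comparisons x standard left/right) are
#' each repeated `reps` times.  Two consecutive blocks form the motivation
#' part and the other two the demotivation part, ordered by `start_part`.
#' In motivation-part trials, half the trials of each block offer 50
#' points for a correct response and half 100 points; demotivation-part
#' trials display 0 points.
#'
#' @param participant Participant identifier.
#' @param start_part `"motivation"` or `"demotivation"`: which part comes
#'   first.
#' @param presentation_order `"random"` (categories intermixed within each
#'   block) or `"blocked"` (trials of a block grouped by category).  This
#'   between-participant factor is recorded but not analyzed.
#' @param seed Integer seed (per-block shuffling, point assignment).
#' @param reps Repetitions of each of the 8 combinations per block
#'   (printed design: 14).
#' @return A schedule tibble (see [build_exp1_schedule()]).
#' @export
build_exp2_schedule <- function(participant = 1L,
                                start_part = c("motivation", "demotivation"),
                                presentation_order = c("random", "blocked"),
                                seed = 1L, reps = 14L) {
  start_part <- match.arg(start_part)
  presentation_order <- match.arg(presentation_order)
  parts <- rep(c(start_part,
                 setdiff(c("motivation", "demotivation"), start_part)),
               each = 2)
  blocks <- lapply(1:4, function(blk) {
    bseed <- derive_seed(seed, participant, 1L, blk)
    b <- block_trials(softness_categories(2), c("c1", "c2"), reps, bseed)
    if (presentation_order == "blocked") {
      # stable regrouping by category keeps counts and within-category order
      b <- b[order(match(b$category, softness_categories(2))), , drop = FALSE]
    }
    b$session <- 1L
    b$block <- blk
    b$presentation_order <- presentation_order
    b$motivation_part <- parts[blk]
    # half the motivation-part trials play for 50 points, half for 100
    set.seed(derive_seed(seed, participant, 2L, blk))
    if (parts[blk] == "motivation") {
      pts <- sample(rep(c(50L, 100L), length.out = nrow(b)))
    } else {
      pts <- rep(0L, nrow(b))
    }
    b$points_at_stake <- pts
    b
  })
  finish_schedule(dplyr::bind_rows(blocks), participant,
                  motivation_part = NULL, label = "exp2", seed = seed)
}

finish_schedule <- function(trials, participant, motivation_part, label, seed) {
  if (!is.null(motivation_part)) {
    trials$motivation_part <- motivation_part
    trials$points_at_stake <- 0L
  }
  trials$participant <- as.integer(participant)
  trials$comparison_id <- paste(trials$category, trials$comparison, sep = "_")
  trials$category <- category_factor(trials$category,
                                     experiment = if (label == "exp1") 1 else 2)
  trials <- dplyr::group_by(trials, .data$session, .data$block)
  trials <- dplyr::mutate(trials, trial = dplyr::row_number())
  trials <- dplyr::ungroup(trials)
  out <- tibble::as_tibble(trials[, SCHEDULE_COLUMNS])
  attr(out, "design_label") <- label
  attr(out, "seed") <- seed
  out
}

#' Counterbalanced multi-participant designs
#'
#' `build_exp1_design()` assigns start conditions by alternation
#' (odd-numbered participants start blocked) and category orders by a
#' Latin square over participants.  `build_exp2_design()` alternates which
#' motivation part comes first and which presentation order a participant
#' receives; an uneven split (such as the 9/7 split of a 16-participant
#' sample) arises naturally for odd participant counts and can be forced
#' via `n_motivation_first`.
#'
#' @param n_participants Number of participants.
#' @param seed Integer seed forwarded to the per-participant builders.
#' @param ... Passed on to [build_exp1_schedule()] /
#'   [build_exp2_schedule()] (e.g. `blocked_reps`, `reps`).
#' @param n_motivation_first For experiment 2: how many participants start
#'   with the motivation part (default: alternation, i.e.
#'   `ceiling(n/2)`).
#' @return A single schedule tibble covering all participants.
#' @export
build_exp1_design <- function(n_participants = 16L, seed = 1L, ...) {
  ls4 <- latin_square_orders(4)
  cats <- softness_categories(1)
  out <- lapply(seq_len(n_participants), function(p) {
    build_exp1_schedule(
      participant = p,
      start_order = if (p %% 2 == 1) "blocked" else "random",
      category_order = cats[ls4[((p - 1L) %% 4L) + 1L, ]],
      seed = seed, ...)
  })
  combine_schedules(out, "exp1", seed)
}

#' @rdname build_exp1_design
#' @export
build_exp2_design <- function(n_participants = 16L, seed = 1L,
                              n_motivation_first = ceiling(n_participants / 2),
                              ...) {
  out <- lapply(seq_len(n_participants), function(p) {
    build_exp2_schedule(
      participant = p,
      start_part = if (p <= n_motivation_first) "motivation" else "demotivation",
      presentation_order = if (p %% 2 == 1) "blocked" else "random",
      seed = seed, ...)
  })
  combine_schedules(out, "exp2", seed)
}

combine_schedules <- function(schedules, label, seed) {
  out <- dplyr::bind_rows(schedules)
  attr(out, "design_label") <- label
  attr(out, "seed") <- seed
  out
}

#' Convert accumulated points into euros and feedback trials
#'
#' Every full 1,000 accumulated points earn one euro.  Feedback about each
#' extra euro is displayed one to three trials after the trial on which
#' the 1,000-point boundary was crossed (offset drawn from the seeded
#' RNG); feedback scheduled past the last trial is delivered at session
#' end and keeps its nominal index.
#'
#' @param points Numeric vector of points earned per trial (0 for
#'   incorrect or demotivation-part trials).
#' @param seed Optional integer seed for the feedback offsets.
#' @return A list with `euros` (total euros gained), `crossing_trials`
#'   (trial indices at which a boundary was crossed) and
#'   `feedback_trials` (scheduled feedback indices).
#' @export
accrue_reward <- function(points, seed = NULL) {
  stopifnot(is.numeric(points), all(points >= 0))
  cum <- cumsum(points)
  euros_after <- floor(cum / 1000)
  gained <- diff(c(0, euros_after))
  crossings <- which(gained > 0)
  if (!is.null(seed)) set.seed(seed)
  offsets <- if (length(crossings)) sample(1:3, length(crossings), replace = TRUE) else integer(0)
  list(euros = if (length(euros_after)) euros_after[length(euros_after)] else 0,
       crossing_trials = crossings,
       feedback_trials = crossings + offsets)
}
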