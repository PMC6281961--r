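# Repeated-measures analysis battery: condition means, difference-score
# matrices, linear contrast tests, paired t tests, coefficient-of-variation
# convergence, the rationalized arcsine transform, and Cousineau-Morey
# within-participant standard errors.

#' Default linear contrast weights over softness categories
#'
#' Equally spaced, centered integer weights for `n` categories ordered
#' soft to hard: `(-3, -1, 1, 3)` for four categories, `(-1, 1)` for two.
#' A positive contrast therefore means "values increase toward harder
#' categories".
#'
#' @param n Number of categories.
#' @return Numeric weight vector summing to zero.
#' @export
contrast_weights <- function(n) {
  stopifnot(n >= 2)
  2 * seq_len(n) - (n + 1)
}

new_test_result <- function(statistic, df, p, tail, effect, method, n) {
  structure(list(statistic = unname(statistic), df = unname(df),
                 p = unname(p), tail = tail,
                 effect_estimate = unname(effect), method = method, n = n),
            class = "haptic_test")
}

#' @export
print.haptic_test <- function(x, ...) {
  cat(x$method, "\n",
      sprintf("t(%d) = %.3f, p = %.4g (%s), effect = %.4g, n = %d",
              x$df, x$statistic, x$p, x$tail, x$effect_estimate, x$n), "\n",
      sep = "")
  invisible(x)
}

tail_p <- function(t, df, tail) {
  switch(tail,
         one_sided_positive = stats::pt(t, df, lower.tail = FALSE),
         two_sided = 2 * stats::pt(abs(t), df, lower.tail = FALSE),
         stop("unknown tail: ", tail))
}

#' Participant-by-condition means of a trial feature
#'
#' Averages a per-trial feature within every participant x condition cell.
#' For `feature = "peak"` the first- and last-indentation peak forces are
#' stacked into a `moment` column (`"first"` / `"last"`), mirroring the
#' two extremes of sensory-signal availability within a trial.
#'
#' @param features Per-trial feature table (from [extract_features()] or
#'   [simulate_dataset()]), containing `participant`, the grouping
#'   columns, and the feature columns.
#' @param feature One of `"peak"` (stacks `first_peak` / `last_peak`),
#'   `"middle_peak"`, `"n_indentations"`, `"effort"`, `"correct"`.
#' @param by Character vector of condition columns (e.g.
#'   `c("category", "presentation_order")`).
#' @return Tibble with columns `participant`, the `by` columns, `moment`
#'   (for `"peak"`), and `value`.  Errors if any participant x cell
#'   combination is empty.
#' @export
condition_means <- function(features, feature = "peak",
                            by = c("category", "presentation_order")) {
  stopifnot(all(c("participant", by) %in% names(features)))
  if (feature == "peak") {
    stopifnot(all(c("first_peak", "last_peak") %in% names(features)))
    long <- tidyr::pivot_longer(
      features[, c("participant", by, "first_peak", "last_peak")],
      cols = c("first_peak", "last_peak"),
      names_to = "moment", values_to = ".value")
    long$moment <- sub("_peak$", "", long$moment)
    keys <- c("participant", by, "moment")
  } else {
    stopifnot(feature %in% names(features))
    long <- features[, c("participant", by)]
    long$.value <- as.numeric(features[[feature]])
    keys <- c("participant", by)
  }
  out <- dplyr::summarise(dplyr::group_by(long, dplyr::across(dplyr::all_of(keys))),
                          value = mean(.data$.value), .groups = "drop")
  full <- tidyr::complete(out, !!!rlang::syms(keys))
  if (nrow(full) != nrow(out) || anyNA(full$value)) {
    bad <- full[is.na(full$value), keys, drop = FALSE]
    stop("empty condition cell(s), first: participant ", bad$participant[1],
         " / ", paste(unlist(bad[1, -1]), collapse = " x "))
  }
  dplyr::arrange(out, dplyr::across(dplyr::all_of(keys)))
}

#' Difference-score matrices for contrast analysis
#'
#' Collapses a [condition_means()] table into a participants x categories
#' matrix of peak-force difference scores:
#' \describe{
#'   \item{`predictive`}{blocked minus random condition, averaged over the
#'     exploration moments in `moments` (default both first and last).}
#'   \item{`sensory`}{last minus first indentation, averaged over all
#'     remaining grouping columns (presentation orders or motivation
#'     parts).}
#'   \item{`sensory_by_motivation`}{the sensory difference under
#'     motivation minus the sensory difference under demotivation (the
#'     moderation score); `moderator` selects the column and
#'     `moderator_levels` its (high, low) levels, so the same mode also
#'     serves e.g. an experimental-half moderator.}
#' }
#'
#' @param cond_means Output of [condition_means()] for `feature = "peak"`.
#' @param mode `"predictive"`, `"sensory"` or `"sensory_by_motivation"`.
#' @param moments Which exploration moments enter the predictive score.
#' @param moderator,moderator_levels Moderator column and its
#'   (high, low) level pair for `sensory_by_motivation`.
#' @return Numeric matrix (participants x categories, soft to hard) with
#'   class `"diff_scores"` and attribute `mode`.
#' @export
difference_scores <- function(cond_means,
                              mode = c("predictive", "sensory",
                                       "sensory_by_motivation"),
                              moments = c("first", "last"),
                              moderator = "motivation_part",
                              moderator_levels = c("motivation", "demotivation")) {
  mode <- match.arg(mode)
  cm <- cond_means
  stopifnot(all(c("participant", "category", "moment", "value") %in% names(cm)))
  if (mode == "predictive") {
    if (!"presentation_order" %in% names(cm)) {
      stop("predictive scores need a presentation_order column")
    }
    cm <- cm[cm$moment %in% moments, ]
    cell <- dplyr::summarise(
      dplyr::group_by(cm, .data$participant, .data$category,
                      .data$presentation_order),
      value = mean(.data$value), .groups = "drop")
    wide <- tidyr::pivot_wider(cell, names_from = "presentation_order",
                               values_from = "value")
    if (!all(c("blocked", "random") %in% names(wide))) {
      stop("predictive scores need both blocked and random conditions")
    }
    wide$score <- wide$blocked - wide$random
  } else if (mode == "sensory") {
    cell <- dplyr::summarise(
      dplyr::group_by(cm, .data$participant, .data$category, .data$moment),
      value = mean(.data$value), .groups = "drop")
    wide <- tidyr::pivot_wider(cell, names_from = "moment", values_from = "value")
    stopifnot(all(c("first", "last") %in% names(wide)))
    wide$score <- wide$last - wide$first
  } else {
    if (!moderator %in% names(cm)) {
      stop("sensory_by_motivation scores need a '", moderator, "' column")
    }
    cell <- dplyr::summarise(
      dplyr::group_by(cm, .data$participant, .data$category,
                      .data[[moderator]], .data$moment),
      value = mean(.data$value), .groups = "drop")
    wide <- tidyr::pivot_wider(cell, names_from = "moment", values_from = "value")
    wide$sens <- wide$last - wide$first
    wide <- tidyr::pivot_wider(wide[, c("participant", "category", moderator, "sens")],
                               names_from = dplyr::all_of(moderator),
                               values_from = "sens")
    if (!all(moderator_levels %in% names(wide))) {
      stop("moderator levels ", paste(moderator_levels, collapse = ", "),
           " not all present")
    }
    wide$score <- wide[[moderator_levels[1]]] - wide[[moderator_levels[2]]]
  }
  scores_matrix(wide, mode)
}

scores_matrix <- function(wide, mode) {
  cats <- levels(category_factor(wide$category))
  cats <- cats[cats %in% unique(as.character(wide$category))]
  m <- tidyr::pivot_wider(wide[, c("participant", "category", "score")],
                          names_from = "category", values_from = "score")
  participants <- m$participant
  m <- as.matrix(m[, cats, drop = FALSE])
  rownames(m) <- participants
  if (anyNA(m)) stop("missing cells in difference-score matrix")
  structure(m, mode = mode, class = c("diff_scores", class(m)))
}

#' One-sample linear contrast test across softness categories
#'
#' For every participant (row) computes the contrast score
#' `L_i = sum_k w_k * m_ik` and tests the mean of `L` against zero with a
#' one-sample t test.  With the default weights a significantly positive
#' contrast indicates values that increase linearly toward harder
#' categories.  With two categories and weights `(-1, 1)` the test is
#' algebraically identical to a paired t test of the two columns.
#'
#' @param m Participants x categories matrix (e.g. a
#'   [difference_scores()] result); columns ordered soft to hard.
#' @param weights Contrast weights summing to zero; default
#'   [contrast_weights()] for `ncol(m)`.
#' @param tail `"one_sided_positive"` (directed hypothesis of an increase
#'   toward harder categories) or `"two_sided"`.
#' @return A `"haptic_test"` result: `statistic`, `df = n - 1`, `p`,
#'   `tail`, `effect_estimate` (mean contrast score).
#' @export
linear_contrast_test <- function(m, weights = NULL,
                                 tail = c("one_sided_positive", "two_sided")) {
  tail <- match.arg(tail)
  m <- unclass(m)
  stopifnot(is.matrix(m), nrow(m) >= 2, ncol(m) >= 2)
  if (is.null(weights)) weights <- contrast_weights(ncol(m))
  stopifnot(length(weights) == ncol(m))
  if (abs(sum(weights)) > 1e-12) stop("contrast weights must sum to zero")
  L <- as.vector(m %*% weights)
  n <- length(L)
  s <- stats::sd(L)
  if (!is.finite(s) || s == 0) stop("degenerate test: contrast scores have zero variance")
  t <- mean(L) / (s / sqrt(n))
  new_test_result(t, n - 1L, tail_p(t, n - 1L, tail), tail, mean(L),
                  "linear contrast (one-sample t on per-participant contrast scores)",
                  n)
}

#' Paired t test with explicit tail handling
#'
#' @param a,b Equal-length per-participant value vectors; the test is on
#'   `a - b`.
#' @param tail `"two_sided"` or `"one_sided_positive"` (`a > b`).
#' @return A `"haptic_test"` result; `effect_estimate` is `mean(a - b)`.
#' @export
paired_t_test <- function(a, b, tail = c("two_sided", "one_sided_positive")) {
  tail <- match.arg(tail)
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  if (stats::sd(d) < 1e-10 * max(1, abs(mean(d)))) {
    stop("degenerate test: paired differences have zero variance")
  }
  ht <- stats::t.test(a, b, paired = TRUE,
                      alternative = if (tail == "two_sided") "two.sided" else "greater")
  new_test_result(ht$statistic, as.integer(ht$parameter), ht$p.value, tail,
                  mean(d), "paired t test", length(a))
}

#' Pearson correlation with t-based p value
#'
#' @param x,y Numeric vectors of length >= 3, non-constant.
#' @return List with `r`, `p` (two-sided), `df`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate correlation: constant input")
  }
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p = ht$p.value,
       df = unname(ht$parameter), n = length(x))
}

#' Convergence of peak forces: coefficient-of-variation test
#'
#' For every participant, computes the coefficient of variation
#' (SD / mean) of first-indentation peak forces and of last-indentation
#' peak forces across that participant's trials, then tests for a
#' decrease from first to last (one-sided paired t on
#' `CoV_first - CoV_last`).  A significant decrease indicates that
#' movement parameters converge to steady values as sensory information
#' accumulates.
#'
#' @param features Per-trial feature table with `participant`,
#'   `first_peak`, `last_peak`.
#' @return A `"haptic_test"` result; `effect_estimate` is the mean CoV
#'   decrease.
#' @export
cov_convergence_test <- function(features) {
  stopifnot(all(c("participant", "first_peak", "last_peak") %in% names(features)))
  per <- dplyr::summarise(
    dplyr::group_by(features, .data$participant),
    n = dplyr::n(),
    mean_first = mean(.data$first_peak), mean_last = mean(.data$last_peak),
    cov_first = stats::sd(.data$first_peak) / mean(.data$first_peak),
    cov_last = stats::sd(.data$last_peak) / mean(.data$last_peak),
    .groups = "drop")
  if (any(per$n < 2)) stop("need >= 2 trials per participant")
  if (any(per$mean_first == 0 | per$mean_last == 0)) {
    stop("degenerate: zero mean peak force")
  }
  paired_t_test(per$cov_first, per$cov_last, tail = "one_sided_positive")
}

#' Rationalized arcsine transform of a correct count
#'
#' Studebaker's rationalized arcsine unit (RAU):
#' `RAU = (146 / pi) * (asin(sqrt(x / (n + 1))) + asin(sqrt((x + 1) / (n + 1)))) - 23`.
#' The transform stabilizes the variance of proportion-correct data and is
#' close to the percent scale over the mid range (`rau_transform(48, 96)`
#' is exactly 50).
#'
#' @param x Correct count(s), `0 <= x <= n`.
#' @param n Trial count(s), `n >= 1`.
#' @return RAU value(s).
#' @export
rau_transform <- function(x, n) {
  stopifnot(all(n >= 1))
  if (any(x < 0 | x > n)) stop("x must lie in [0, n]")
  (146 / pi) * (asin(sqrt(x / (n + 1))) + asin(sqrt((x + 1) / (n + 1)))) - 23
}

#' Cousineau-Morey within-participant standard errors
#'
#' Removes between-participant offsets by subtracting each participant's
#' row mean and adding the grand mean, computes the per-condition standard
#' error of the normalized values, and applies Morey's bias correction
#' `sqrt(C / (C - 1))` for `C` conditions.
#'
#' @param m Complete participants x conditions numeric matrix
#'   (>= 2 rows, >= 2 columns).
#' @return Named numeric vector of per-condition standard errors.
#' @export
morey_within_se <- function(m) {
  m <- as.matrix(m)
  stopifnot(nrow(m) >= 2, ncol(m) >= 2, !anyNA(m))
  normalized <- m - rowMeans(m) + mean(m)
  se <- apply(normalized, 2, stats::sd) / sqrt(nrow(m))
  se * sqrt(ncol(m) / (ncol(m) - 1))
}
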