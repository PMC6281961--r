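# Orchestration: simulate -> extract -> score -> analyze -> report.
# Each labeled test of the two experiments' analysis batteries appears
# exactly once in the report.

EXP1_TEST_LABELS <- c(
  "baseline_contrast", "predictive_contrast", "sensory_contrast",
  "accuracy_blocked_vs_random", "accuracy_indentation_correlation",
  "indentation_count_blocked_vs_random", "cov_convergence",
  "first_vs_last_force", "last_touch_choice")

EXP2_TEST_LABELS <- c(
  "questionnaire_manipulation", "accuracy_rau_motivation",
  "effort_motivation", "sensory_contrast",
  "sensory_by_motivation_contrast", "sensory_by_half_contrast")

test_row <- function(label, x) {
  tibble::tibble(label = label, statistic = x$statistic, df = x$df,
                 p = x$p, tail = x$tail, effect = x$effect_estimate,
                 n = x$n)
}

cor_row <- function(label, x) {
  tibble::tibble(label = label, statistic = x$r, df = x$df, p = x$p,
                 tail = "two_sided", effect = x$r, n = x$n)
}

trials_of <- function(dataset) {
  if (inherits(dataset, "haptic_dataset")) dataset$trials else dataset
}

qc_of <- function(trials) {
  qc <- attr(trials, "qc")
  if (is.null(qc)) qc <- list(n_trials = nrow(trials), n_excluded = 0L,
                              excluded_uids = character(0))
  qc
}

# participant x condition mean table with Cousineau-Morey within-participant SEs
morey_condition_table <- function(cm, keys) {
  cm$cell <- do.call(paste, c(cm[keys], sep = "|"))
  wide <- tidyr::pivot_wider(cm[, c("participant", "cell", "value")],
                             names_from = "cell", values_from = "value")
  m <- as.matrix(wide[, -1, drop = FALSE])
  se <- morey_within_se(m)
  out <- unique(cm[, keys])
  out$cell <- do.call(paste, c(out[keys], sep = "|"))
  out$mean <- colMeans(m)[out$cell]
  out$within_se <- se[out$cell]
  out$cell <- NULL
  out
}

per_participant <- function(trials, value_expr, by = NULL) {
  dplyr::summarise(
    dplyr::group_by(trials, dplyr::across(dplyr::all_of(c("participant", by)))),
    value = value_expr(dplyr::pick(dplyr::everything())), .groups = "drop")
}

paired_by_level <- function(tab, col, level_a, level_b) {
  wide <- tidyr::pivot_wider(tab, names_from = dplyr::all_of(col),
                             values_from = "value")
  wide <- wide[order(wide$participant), ]
  list(a = wide[[level_a]], b = wide[[level_b]])
}

#' Full analysis battery of the predictability experiment
#'
#' Runs, on a per-trial feature table, the complete analysis of the
#' blocked/random softness-discrimination experiment: the baseline
#' contrast (first-indentation peak forces in the random condition,
#' two-sided -- no category effect should exist when neither predictive
#' nor sensory signals are available), the one-sided linear contrasts of
#' the predictive (blocked - random) and sensory (last - first)
#' difference scores, the blocked-vs-random accuracy and
#' indentation-count paired t tests, the across-participant correlation
#' between indentation count and accuracy, the coefficient-of-variation
#' convergence test, the overall first-vs-last force test, and the
#' proportion of trials whose last-touched stimulus matches the choice.
#'
#' @param dataset A `"haptic_dataset"` (from [simulate_dataset()]) or a
#'   per-trial feature table with schedule metadata (e.g. from
#'   [extract_features()]).
#' @param weights Contrast weights (default [contrast_weights()]).
#' @return A list of class `"analysis_report"` with elements
#'   `schema_version`, `experiment`, `n_participants`, `tests` (one row
#'   per labeled test), `condition_means` (with Morey within-participant
#'   SEs) and `qc`.
#' @export
run_experiment1_analysis <- function(dataset, weights = NULL) {
  trials <- trials_of(dataset)
  need <- c("participant", "category", "presentation_order", "first_peak",
            "last_peak", "n_indentations", "correct")
  if (!all(need %in% names(trials))) {
    stop("feature table lacks required columns: ",
         paste(setdiff(need, names(trials)), collapse = ", "))
  }
  cm <- condition_means(trials, "peak", by = c("category", "presentation_order"))

  # baseline: first indentation, random condition, one matrix cell per category
  base <- cm[cm$moment == "first" & cm$presentation_order == "random", ]
  base$score <- base$value
  base_m <- scores_matrix(base, "baseline")
  tests <- list(
    test_row("baseline_contrast",
             linear_contrast_test(base_m, weights, "two_sided")),
    test_row("predictive_contrast",
             linear_contrast_test(difference_scores(cm, "predictive"),
                                  weights, "one_sided_positive")),
    test_row("sensory_contrast",
             linear_contrast_test(difference_scores(cm, "sensory"),
                                  weights, "one_sided_positive")))

  acc <- per_participant(trials, function(d) mean(d$correct) * 100,
                         by = "presentation_order")
  ab <- paired_by_level(acc, "presentation_order", "blocked", "random")
  tests <- c(tests, list(
    test_row("accuracy_blocked_vs_random",
             paired_t_test(ab$a, ab$b, "two_sided"))))

  overall <- dplyr::summarise(
    dplyr::group_by(trials, .data$participant),
    acc = mean(.data$correct) * 100,
    n_ind = mean(.data$n_indentations), .groups = "drop")
  tests <- c(tests, list(
    cor_row("accuracy_indentation_correlation",
            pearson_correlation(overall$n_ind, overall$acc))))

  cnt <- per_participant(trials, function(d) mean(d$n_indentations),
                         by = "presentation_order")
  cb <- paired_by_level(cnt, "presentation_order", "blocked", "random")
  tests <- c(tests, list(
    test_row("indentation_count_blocked_vs_random",
             paired_t_test(cb$a, cb$b, "two_sided")),
    test_row("cov_convergence", cov_convergence_test(trials))))

  fl <- dplyr::summarise(
    dplyr::group_by(trials, .data$participant),
    first = mean(.data$first_peak), last = mean(.data$last_peak),
    .groups = "drop")
  tests <- c(tests, list(
    test_row("first_vs_last_force",
             paired_t_test(fl$first, fl$last, "two_sided"))))

  lt <- dplyr::summarise(
    dplyr::group_by(trials[!is.na(trials$last_touch_matches_choice), ],
                    .data$participant),
    value = mean(.data$last_touch_matches_choice) * 100, .groups = "drop")
  tests <- c(tests, list(
    test_row("last_touch_choice",
             paired_t_test(lt$value, rep(50, nrow(lt)), "two_sided"))))

  report <- list(
    schema_version = "1.0",
    experiment = 1L,
    n_participants = length(unique(trials$participant)),
    tests = dplyr::bind_rows(tests),
    condition_means = morey_condition_table(
      cm, c("category", "presentation_order", "moment")),
    last_touch_match_pct = mean(lt$value),
    qc = qc_of(trials))
  stopifnot(identical(sort(report$tests$label), sort(EXP1_TEST_LABELS)))
  structure(report, class = "analysis_report")
}

#' Full analysis battery of the motivation experiment
#'
#' Applies the motivation-manipulation inclusion criterion, then runs:
#' the paired test of uncorrected questionnaire scores between parts, the
#' one-sided paired tests of accuracy (rationalized-arcsine transformed)
#' and energetic effort (sum of peak forces per trial) between motivation
#' parts, the overall one-sided sensory contrast, the one-sided
#' motivation-moderation contrast (the planted interaction between
#' motivation and the category contrast on sensory difference scores),
#' and the two-sided experimental-half moderation contrast (the confound
#' check: the first/second half of the session must not explain the
#' moderation).
#'
#' @param dataset A `"haptic_dataset"` or per-trial feature table with a
#'   `motivation_part` column.
#' @param scores Motivation scores: either the output of
#'   [correct_motivation()] or a raw item table as returned by
#'   [simulate_questionnaires()]`$items` (scored and corrected
#'   internally).
#' @param weights Contrast weights (default `(-1, 1)` for soft/hard).
#' @param key Item key, used only when `scores` is an item table.
#' @return A list of class `"analysis_report"`; `included` lists the
#'   participants entering the final sample.
#' @export
run_experiment2_analysis <- function(dataset, scores, weights = NULL,
                                     key = default_item_key()) {
  trials <- trials_of(dataset)
  need <- c("participant", "category", "motivation_part", "block",
            "first_peak", "last_peak", "effort", "correct")
  if (!all(need %in% names(trials))) {
    stop("feature table lacks required columns: ",
         paste(setdiff(need, names(trials)), collapse = ", "))
  }
  if (!"corrected" %in% names(scores)) {
    if (all(c("instrument", "item_id") %in% names(scores))) {
      scores <- correct_motivation(score_motivation(scores, key))
    } else {
      scores <- correct_motivation(scores)
    }
  }
  included <- apply_inclusion(scores)
  included <- intersect(included, unique(trials$participant))
  if (!length(included)) stop("no participants pass the inclusion criterion")
  trials <- trials[trials$participant %in% included, ]
  scores_inc <- scores[scores$participant %in% included, ]

  qs <- paired_by_level(
    dplyr::rename(scores_inc[, c("participant", "part", "uncorrected")],
                  value = "uncorrected"),
    "part", "motivation", "demotivation")
  tests <- list(
    test_row("questionnaire_manipulation",
             paired_t_test(qs$a, qs$b, "two_sided")))

  acc <- per_participant(trials,
                         function(d) rau_transform(sum(d$correct), nrow(d)),
                         by = "motivation_part")
  am <- paired_by_level(acc, "motivation_part", "motivation", "demotivation")
  eff <- per_participant(trials, function(d) mean(d$effort),
                         by = "motivation_part")
  em <- paired_by_level(eff, "motivation_part", "motivation", "demotivation")
  tests <- c(tests, list(
    test_row("accuracy_rau_motivation",
             paired_t_test(am$a, am$b, "one_sided_positive")),
    test_row("effort_motivation",
             paired_t_test(em$a, em$b, "one_sided_positive"))))

  cm <- condition_means(trials, "peak", by = c("category", "motivation_part"))
  tests <- c(tests, list(
    test_row("sensory_contrast",
             linear_contrast_test(difference_scores(cm, "sensory"),
                                  weights, "one_sided_positive")),
    test_row("sensory_by_motivation_contrast",
             linear_contrast_test(
               difference_scores(cm, "sensory_by_motivation"),
               weights, "one_sided_positive"))))

  trials$half <- ifelse(trials$block <= 2, "first", "second")
  cmh <- condition_means(trials, "peak", by = c("category", "half"))
  tests <- c(tests, list(
    test_row("sensory_by_half_contrast",
             linear_contrast_test(
               difference_scores(cmh, "sensory_by_motivation",
                                 moderator = "half",
                                 moderator_levels = c("first", "second")),
               weights, "two_sided"))))

  report <- list(
    schema_version = "1.0",
    experiment = 2L,
    n_participants = length(included),
    included = included,
    questionnaire_means = dplyr::summarise(
      dplyr::group_by(scores_inc, .data$part),
      uncorrected_mean = mean(.data$uncorrected),
      uncorrected_sd = stats::sd(.data$uncorrected), .groups = "drop"),
    tests = dplyr::bind_rows(tests),
    condition_means = morey_condition_table(
      cm, c("category", "motivation_part", "moment")),
    qc = qc_of(trials))
  stopifnot(identical(sort(report$tests$label), sort(EXP2_TEST_LABELS)))
  structure(report, class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("Softness-exploration analysis report (experiment %d, n = %d)\n",
              x$experiment, x$n_participants))
  print(as.data.frame(x$tests), digits = 4)
  invisible(x)
}

#' Serialize an analysis report to canonical JSON
#'
#' @param report An `"analysis_report"`.
#' @return A JSON string; identical configurations and seeds give
#'   byte-identical output.
#' @export
report_json <- function(report) {
  as.character(jsonlite::toJSON(unclass(report), dataframe = "columns",
                                digits = NA, auto_unbox = TRUE, null = "null"))
}

#' Simulate a complete predictability experiment
#'
#' Builds the counterbalanced multi-participant design and simulates the
#' trial table (and optionally traces) in one call.
#'
#' @inheritParams build_exp1_design
#' @inheritParams simulate_dataset
#' @param blocked_reps,random_reps Repetitions per combination (see
#'   [build_exp1_schedule()]).
#' @return A `"haptic_dataset"`.
#' @export
simulate_experiment1 <- function(n_participants = 16L, seed = 1L,
                                 effects = effect_config(),
                                 observer = observer_config(),
                                 blocked_reps = 24L, random_reps = 6L,
                                 traces = FALSE) {
  sched <- build_exp1_design(n_participants, seed = derive_seed(seed, 1),
                             blocked_reps = blocked_reps,
                             random_reps = random_reps)
  simulate_dataset(sched, effects, observer, seed = derive_seed(seed, 2),
                   traces = traces)
}

#' Simulate a complete motivation experiment, questionnaires included
#'
#' @inheritParams build_exp2_design
#' @inheritParams simulate_dataset
#' @inheritParams simulate_questionnaires
#' @param reps Repetitions per combination and block (printed design: 14).
#' @return A `"haptic_dataset"` whose `questionnaires` element holds the
#'   simulated item table and planted truth.
#' @export
simulate_experiment2 <- function(n_participants = 30L, seed = 1L,
                                 effects = effect_config(),
                                 observer = observer_config(),
                                 reps = 14L,
                                 motivation_shift = 10,
                                 manipulation_failure_rate = 14 / 30,
                                 traces = FALSE, ...) {
  sched <- build_exp2_design(n_participants, seed = derive_seed(seed, 1),
                             reps = reps)
  ds <- simulate_dataset(sched, effects, observer, seed = derive_seed(seed, 2),
                         traces = traces)
  ds$questionnaires <- simulate_questionnaires(
    n_participants, motivation_shift = motivation_shift,
    manipulation_failure_rate = manipulation_failure_rate,
    seed = derive_seed(seed, 3), ...)
  ds
}

#' Recover the planted adjustment parameters from a dataset
#'
#' Inverts the linear generative model: with contrast weights `w`, the
#' expected per-participant contrast score of the predictive
#' (blocked - random) difference matrix is `beta_pred * sum(w^2)`, and of
#' the sensory (last - first) matrix `beta_sens * sum(w^2)` (times the
#' motivation gain where applicable), so dividing the mean contrast score
#' by `sum(w^2)` estimates the slope.  The drift is the grand mean
#' last-minus-first difference (category weights cancel by balance).
#'
#' @param dataset A `"haptic_dataset"` or feature table from the
#'   predictability design.
#' @param weights Contrast weights (default [contrast_weights()]).
#' @return List with `beta_pred`, `beta_sens`, `gamma_drift` estimates.
#' @export
estimate_effects <- function(dataset, weights = NULL) {
  trials <- trials_of(dataset)
  cm <- condition_means(trials, "peak", by = c("category", "presentation_order"))
  pred <- difference_scores(cm, "predictive")
  sens <- difference_scores(cm, "sensory")
  if (is.null(weights)) weights <- contrast_weights(ncol(pred))
  ssq <- sum(weights^2)
  fl <- dplyr::summarise(
    dplyr::group_by(trials, .data$participant),
    d = mean(.data$last_peak) - mean(.data$first_peak), .groups = "drop")
  list(beta_pred = mean(unclass(pred) %*% weights) / ssq,
       beta_sens = mean(unclass(sens) %*% weights) / ssq,
       gamma_drift = mean(fl$d))
}
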