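# Stimuli are silicone rubber discs abstracted to a single physical quantity:
# compliance (mm/N), the surface displacement produced per unit normal force.
# Larger compliance = softer object.

#' Softness category labels, ordered from softest to hardest
#'
#' Category labels are used as an ordered factor throughout the package.
#' The soft-to-hard ordering fixes the sign convention of the default
#' linear contrast weights: positive contrasts mean "larger values for
#' harder categories".
#'
#' @param experiment 1 (four categories) or 2 (soft and hard only).
#' @return Character vector of category labels, softest first.
#' @export
softness_categories <- function(experiment = 1) {
  if (experiment == 1) {
    c("soft", "medium_soft", "medium_hard", "hard")
  } else {
    c("soft", "hard")
  }
}

category_factor <- function(x, experiment = NULL) {
  levels <- if (is.null(experiment)) {
    if (all(unique(as.character(x)) %in% softness_categories(2)) &&
        length(unique(as.character(x))) <= 2) {
      softness_categories(2)
    } else {
      softness_categories(1)
    }
  } else {
    softness_categories(experiment)
  }
  factor(as.character(x), levels = levels)
}

#' Estimate compliance from force-displacement samples
#'
#' Compliance is defined as the slope of the ordinary least-squares
#' regression line of vertical surface displacement on applied normal
#' force, fitted over a restricted force range (default 0 to 9 N,
#' inclusive).  Samples outside the fit range are ignored.  The intercept
#' is estimated, not forced through the origin.
#'
#' @param force Numeric vector of applied forces (N), non-negative.
#' @param displacement Numeric vector of surface displacements (mm), same
#'   length as `force`.
#' @param fit_range Length-2 numeric, inclusive force bounds (N) used for
#'   the fit.
#' @return Compliance estimate in mm/N (regression slope).
#' @examples
#' f <- 0:9
#' estimate_compliance(f, 0.5 * f) # 0.5
#' @export
estimate_compliance <- function(force, displacement, fit_range = c(0, 9)) {
  stopifnot(is.numeric(force), is.numeric(displacement),
            length(force) == length(displacement),
            length(fit_range) == 2, fit_range[1] <= fit_range[2])
  if (any(force < 0)) {
    stop("forces must be non-negative")
  }
  keep <- force >= fit_range[1] & force <= fit_range[2]
  f <- force[keep]
  d <- displacement[keep]
  if (length(f) < 2 || length(unique(f)) < 2) {
    stop("degenerate fit: need at least 2 in-range samples with distinct forces")
  }
  unname(stats::coef(stats::lm(d ~ f))[2])
}

#' The twelve compliance stimuli of the main discrimination experiment
#'
#' Four softness categories, each holding one standard and two comparison
#' stimuli.  Compliances (mm/N): hard 0.14 (s), 0.12 and 0.15 (c);
#' medium hard 0.21 (s), 0.18 and 0.24 (c); medium soft 0.37 (s), 0.29 and
#' 0.46 (c); soft 0.74 (s), 0.62 and 0.88 (c).  Comparisons differ from
#' their standard by roughly one just-noticeable difference.
#'
#' @return A tibble with columns `id`, `category` (ordered factor,
#'   soft first), `role` (`"standard"` or `"comparison"`) and
#'   `compliance` (mm/N).
#' @export
exp1_stimuli <- function() {
  sets <- list(
    hard        = c(s = 0.14, c1 = 0.12, c2 = 0.15),
    medium_hard = c(s = 0.21, c1 = 0.18, c2 = 0.24),
    medium_soft = c(s = 0.37, c1 = 0.29, c2 = 0.46),
    soft        = c(s = 0.74, c1 = 0.62, c2 = 0.88)
  )
  stimulus_table(sets, experiment = 1)
}

#' The stimuli of the motivation experiment
#'
#' Two softness categories.  Each standard (the middle compliance of its
#' triplet) is paired with an easier and a harder comparison:
#' soft 0.67 (s), 0.61 and 0.73 (c); hard 0.156 (s), 0.152 and 0.162 (c).
#'
#' @return A tibble in the same format as [exp1_stimuli()].
#' @export
exp2_stimuli <- function() {
  sets <- list(
    hard = c(s = 0.156, c1 = 0.152, c2 = 0.162),
    soft = c(s = 0.67,  c1 = 0.61,  c2 = 0.73)
  )
  stimulus_table(sets, experiment = 2)
}

stimulus_table <- function(sets, experiment) {
  rows <- lapply(names(sets), function(cat) {
    v <- sets[[cat]]
    tibble::tibble(
      id = paste(cat, names(v), sep = "_"),
      category = cat,
      role = ifelse(names(v) == "s", "standard", "comparison"),
      compliance = unname(v)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$category <- category_factor(out$category, experiment)
  out <- out[order(out$category, out$id), ]
  tibble::as_tibble(out)
}

#' Weber-fraction specification for JND-spaced comparison stimuli
#'
#' Discrimination thresholds for compliance follow Weber-like behavior,
#' with different fractions at the hard and soft ends of the stimulus
#' range: 21.2% at a hard anchor and 13.5% at a soft anchor.  Fractions
#' for intermediate standards are interpolated linearly in log compliance
#' between the anchors and clamped at the ends.
#'
#' @param fraction_hard,fraction_soft Weber fractions (dimensionless, in
#'   (0, 1)) at the two anchor compliances.
#' @param anchor_hard,anchor_soft Anchor compliances (mm/N),
#'   `anchor_soft > anchor_hard`.
#' @return A list of class `"weber_spec"`.
#' @export
weber_spec <- function(fraction_hard = 0.212, fraction_soft = 0.135,
                       anchor_hard = 0.14, anchor_soft = 0.74) {
  # fractions of exactly 0 are admitted as the degenerate zero-JND case
  stopifnot(fraction_hard >= 0, fraction_hard < 1,
            fraction_soft >= 0, fraction_soft < 1,
            anchor_hard > 0, anchor_soft > anchor_hard)
  structure(list(fraction_hard = fraction_hard, fraction_soft = fraction_soft,
                 anchor_hard = anchor_hard, anchor_soft = anchor_soft),
            class = "weber_spec")
}

#' Interpolated Weber fraction at a given compliance
#'
#' Linear interpolation of the Weber fraction against log(compliance)
#' between the two anchors of a [weber_spec()]; compliances outside the
#' anchor interval are clamped to the nearest anchor's fraction.
#'
#' @param compliance Compliance value(s) in mm/N.
#' @param spec A [weber_spec()].
#' @return Weber fraction(s), same length as `compliance`.
#' @export
weber_fraction_at <- function(compliance, spec = weber_spec()) {
  stopifnot(inherits(spec, "weber_spec"), all(compliance > 0))
  x <- log(pmin(pmax(compliance, spec$anchor_hard), spec$anchor_soft))
  t <- (x - log(spec$anchor_hard)) / (log(spec$anchor_soft) - log(spec$anchor_hard))
  spec$fraction_hard + t * (spec$fraction_soft - spec$fraction_hard)
}

#' JND-spaced comparison compliances around a standard
#'
#' Given a standard compliance, returns the pair of comparisons lying one
#' just-noticeable difference below and above it:
#' `standard * (1 - w)` and `standard * (1 + w)`, where `w` is the
#' interpolated Weber fraction at the standard.
#'
#' @param standard Standard compliance (mm/N); must lie within the
#'   spec's anchor interval.
#' @param spec A [weber_spec()].
#' @return Named numeric vector `c(lower = , upper = )`.
#' @export
weber_comparisons <- function(standard, spec = weber_spec()) {
  stopifnot(length(standard) == 1, standard > 0)
  if (standard < spec$anchor_hard || standard > spec$anchor_soft) {
    stop("standard compliance outside the anchor interval [",
         spec$anchor_hard, ", ", spec$anchor_soft, "] mm/N")
  }
  w <- weber_fraction_at(standard, spec)
  c(lower = standard * (1 - w), upper = standard * (1 + w))
}
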