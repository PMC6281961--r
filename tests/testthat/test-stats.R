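# Condition means, difference scores, contrast and paired tests, CoV
# convergence, the rationalized arcsine transform, and Morey SEs.

test_that("condition means equal hand-computed cell averages", {
  ft <- toy_features()
  cm <- condition_means(ft, "peak", by = c("category", "presentation_order"))
  # two trials per cell differing by 0.2: mean = base + 0.1
  cell <- cm[cm$participant == 2 & cm$category == "medium_soft" &
               cm$presentation_order == "blocked" & cm$moment == "first", ]
  expect_equal(cell$value, 2 + 2 / 10 + 0.5 + 0.1)
  cell_l <- cm[cm$participant == 2 & cm$category == "medium_soft" &
                 cm$presentation_order == "blocked" & cm$moment == "last", ]
  expect_equal(cell_l$value, cell$value + 1)

  # row order of the feature table is irrelevant
  set.seed(3)
  cm_perm <- condition_means(ft[sample(nrow(ft)), ], "peak",
                             by = c("category", "presentation_order"))
  expect_equal(cm, cm_perm)

  # an empty cell is an error naming the participant
  ft_bad <- ft[!(ft$participant == 3 & ft$category == "hard" &
                   ft$presentation_order == "random"), ]
  expect_error(condition_means(ft_bad, "peak",
                               by = c("category", "presentation_order")),
               "empty condition cell")
})

test_that("difference scores implement the three contrast modes", {
  ft <- toy_features()
  cm <- condition_means(ft, "peak", by = c("category", "presentation_order"))
  pred <- difference_scores(cm, "predictive")
  expect_equal(dim(pred), c(3L, 4L))
  expect_equal(colnames(pred),
               c("soft", "medium_soft", "medium_hard", "hard"))
  # planted blocked - random difference is 0.5 everywhere
  expect_true(all(abs(unclass(pred) - 0.5) < 1e-12))
  sens <- difference_scores(cm, "sensory")
  expect_true(all(abs(unclass(sens) - 1) < 1e-12))

  # blocked == random collapses the predictive scores to zero
  ft0 <- ft
  ft0$first_peak <- ft0$first_peak -
    ifelse(ft0$presentation_order == "blocked", 0.5, 0)
  ft0$last_peak <- ft0$first_peak + 1
  cm0 <- condition_means(ft0, "peak", by = c("category", "presentation_order"))
  expect_true(all(abs(unclass(difference_scores(cm0, "predictive"))) < 1e-12))

  # identical moderator levels give a zero moderation matrix
  ft$motivation_part <- ifelse(ft$rep == 1, "motivation", "demotivation")
  cmm <- condition_means(ft, "peak", by = c("category", "motivation_part"))
  mod <- difference_scores(cmm, "sensory_by_motivation")
  expect_true(all(abs(unclass(mod)) < 1e-12))
})

test_that("the linear contrast test matches its one-sample-t oracle", {
  w <- contrast_weights(4)
  expect_equal(w, c(-3, -1, 1, 3))
  cs <- c(0.8, 1.1, 0.9, 1.3, 1.0)
  m <- outer(cs, w)          # rows proportional to the weights
  res <- linear_contrast_test(m, tail = "one_sided_positive")
  L <- as.vector(m %*% w)    # textbook oracle
  t_or <- mean(L) / (sd(L) / sqrt(5))
  expect_equal(res$statistic, t_or)
  expect_equal(res$df, 4L)
  expect_equal(res$p, pt(t_or, 4, lower.tail = FALSE))
  expect_lt(res$p, 0.05)
  expect_gt(res$statistic, 0)
  expect_equal(res$effect_estimate, mean(L))

  # adding a constant per row changes nothing (weights sum to zero)
  shifted <- m + c(5, -2, 0.3, 1, 7)
  expect_equal(linear_contrast_test(shifted, tail = "one_sided_positive")$statistic,
               res$statistic)

  # t is invariant to positive rescaling of the weights
  res2 <- linear_contrast_test(m, weights = 10 * w, tail = "one_sided_positive")
  expect_equal(res2$statistic, res$statistic)

  # cross-check against stats::t.test on the contrast scores
  ht <- t.test(L, alternative = "greater")
  expect_equal(res$statistic, unname(ht$statistic))
  expect_equal(res$p, ht$p.value)

  expect_error(linear_contrast_test(m, weights = c(1, 1, 1, 1)),
               "sum to zero")
  expect_error(linear_contrast_test(matrix(1, 4, 4)), "zero variance")
})

test_that("a two-category contrast is exactly a paired t test", {
  set.seed(14)
  a <- rnorm(12, 5)
  b <- rnorm(12, 4.5)
  m <- cbind(soft = b, hard = a)
  for (tail in c("two_sided", "one_sided_positive")) {
    ct <- linear_contrast_test(m, tail = tail)
    pt_ <- paired_t_test(a, b, tail = tail)
    expect_equal(ct$statistic, pt_$statistic)
    expect_equal(ct$p, pt_$p)
    expect_equal(ct$df, pt_$df)
    # the contrast effect (-1, +1) is twice... no: weights (-1, 1) give a - b
    expect_equal(ct$effect_estimate, pt_$effect_estimate)
  }
})

test_that("paired t matches the textbook formula and tail convention", {
  set.seed(2)
  b <- rnorm(10, 3, 1)
  a <- b + 0.4 + rnorm(10, 0, 0.2)
  res <- paired_t_test(a, b, "two_sided")
  d <- a - b
  t_or <- mean(d) / (sd(d) / sqrt(10))
  expect_equal(res$statistic, t_or)
  expect_equal(res$p, 2 * pt(abs(t_or), 9, lower.tail = FALSE))
  one <- paired_t_test(a, b, "one_sided_positive")
  expect_equal(res$p, 2 * one$p)       # t > 0 here
  expect_gt(res$statistic, 0)
  expect_error(paired_t_test(a, a + 1, "two_sided"), "zero variance")
})

test_that("pearson correlation matches the covariance-formula oracle", {
  x <- 1:8
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)
  set.seed(5)
  x16 <- rnorm(16)
  y16 <- 0.5 * x16 + rnorm(16)
  r_or <- sum((x16 - mean(x16)) * (y16 - mean(y16))) /
    sqrt(sum((x16 - mean(x16))^2) * sum((y16 - mean(y16))^2))
  res <- pearson_correlation(x16, y16)
  expect_equal(res$r, r_or)
  expect_equal(res$df, 14)
  expect_error(pearson_correlation(rep(1, 5), rnorm(5)), "constant")
})

test_that("coefficient-of-variation convergence behaves as defined", {
  ft <- tibble::tibble(
    participant = rep(1:4, each = 20),
    first_peak = abs(rnorm(80, 5, 1)) + 0.5)
  # identical first and last peaks: zero CoV difference, degenerate test
  ft$last_peak <- ft$first_peak
  expect_error(cov_convergence_test(ft), "zero variance")

  # scaling a participant's peaks leaves their CoV unchanged
  per_cov <- function(x) sd(x) / mean(x)
  p1 <- ft$first_peak[ft$participant == 1]
  expect_equal(per_cov(3.7 * p1), per_cov(p1))

  # planted convergence: last peaks are less variable
  set.seed(6)
  ft$last_peak <- rep(tapply(ft$first_peak, ft$participant, mean), each = 20) +
    rnorm(80, 0, 0.3)
  res <- cov_convergence_test(ft)
  expect_equal(res$tail, "one_sided_positive")
  expect_gt(res$statistic, 0)
})

test_that("the rationalized arcsine transform follows Studebaker's formula", {
  # half correct of 96: the two arcsine terms are complementary, RAU = 50
  expect_equal(rau_transform(48, 96), 50)
  oracle0 <- (146 / pi) * (asin(sqrt(0 / 97)) + asin(sqrt(1 / 97))) - 23
  expect_equal(rau_transform(0, 96), oracle0)
  # strictly monotone in the correct count
  expect_true(all(diff(rau_transform(0:96, 96)) > 0))
  expect_error(rau_transform(97, 96), "\\[0, n\\]")
  expect_error(rau_transform(-1, 96), "\\[0, n\\]")
})

test_that("Morey within-participant SEs match explicit normalization", {
  # additive participant offsets + condition effects: SEs exactly zero
  m <- outer(c(0, 2, 5), rep(1, 4)) + outer(rep(1, 3), c(1, 2, 3, 4))
  expect_equal(unname(morey_within_se(m)), rep(0, 4))

  set.seed(9)
  m2 <- matrix(rnorm(12), 3, 4)
  se <- morey_within_se(m2)
  # explicit Cousineau normalization + Morey correction oracle
  norm <- m2 - rowMeans(m2) + mean(m2)
  oracle <- apply(norm, 2, sd) / sqrt(3) * sqrt(4 / 3)
  expect_equal(unname(se), unname(oracle))

  # adding a constant to one participant's row changes nothing
  m3 <- m2
  m3[2, ] <- m3[2, ] + 11
  expect_equal(morey_within_se(m3), se)

  # 3 x 2 toy matrix, fully hand-computed
  toy <- matrix(c(1, 2, 3, 2, 4, 6), nrow = 3)
  norm_toy <- toy - rowMeans(toy) + mean(toy)
  expect_equal(unname(morey_within_se(toy)),
               unname(apply(norm_toy, 2, sd) / sqrt(3) * sqrt(2)))
})
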