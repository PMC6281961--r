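# Trial-schedule construction: Latin squares, block composition,
# balancing, reproducibility, and the reward accrual rule.

test_that("latin square orderings place every item once per position", {
  expect_equal(latin_square_orders(1), matrix(1L, 1, 1))
  ls4 <- latin_square_orders(4)
  expect_equal(dim(ls4), c(4L, 4L))
  # brute-force validation of the Latin-square property
  for (col in 1:4) expect_setequal(ls4[, col], 1:4)
  for (row in 1:4) expect_setequal(ls4[row, ], 1:4)
  expect_error(latin_square_orders(0), "positive integer")
})

test_that("the predictability schedule reproduces the printed trial counts", {
  sch <- build_exp1_schedule(1, "blocked", seed = 11)
  expect_equal(nrow(sch), 1536)
  blocks <- dplyr::count(sch, session, block)
  expect_equal(nrow(blocks), 16)
  expect_true(all(blocks$n == 96))

  # sessions alternate blocked/random starting as requested
  per_sess <- unique(sch[, c("session", "presentation_order")])
  expect_equal(per_sess$presentation_order[order(per_sess$session)],
               c("blocked", "random", "blocked", "random"))
  sch_r <- build_exp1_schedule(2, "random", seed = 11)
  expect_equal(unique(sch_r$presentation_order[sch_r$session == 1]), "random")

  # blocked blocks: one category, each (pair x positioning) combination 24x
  b1 <- sch[sch$session == 1 & sch$block == 1, ]
  expect_equal(length(unique(as.character(b1$category))), 1)
  combos <- table(b1$comparison_id, b1$standard_side)
  expect_true(all(combos == 24))

  # random blocks: all 8 pairs, each (pair x positioning) combination 6x
  r1 <- sch[sch$session == 2 & sch$block == 1, ]
  expect_equal(length(unique(r1$comparison_id)), 8)
  combos_r <- table(r1$comparison_id, r1$standard_side)
  expect_true(all(combos_r == 6))
})

test_that("standard side and first touch are balanced within blocks", {
  sch <- small_exp1_schedule(seed = 5)
  bal <- dplyr::count(sch, session, block, standard_side)
  sides <- tidyr::pivot_wider(bal, names_from = standard_side, values_from = n)
  expect_true(all(sides$left == sides$right))
  ft <- dplyr::count(sch, session, block, comparison_id, standard_side,
                     first_touch_side)
  # blocked reps = 2: each combination has one left-first and one right-first
  blocked <- ft[ft$session %in% c(1, 3), ]
  expect_true(all(blocked$n == 1))
})

test_that("category order is fixed across a participant's blocked sessions", {
  ord <- c("medium_hard", "soft", "hard", "medium_soft")
  sch <- build_exp1_schedule(3, "blocked", category_order = ord, seed = 2,
                             blocked_reps = 2, random_reps = 1)
  for (sess in c(1, 3)) {
    got <- vapply(1:4, function(b) {
      as.character(sch$category[sch$session == sess & sch$block == b][1])
    }, character(1))
    expect_equal(got, ord)
  }
  expect_error(build_exp1_schedule(1, category_order = c("soft", "hard")),
               "permutation")
})

test_that("schedules are byte-identical given the same seed", {
  a <- build_exp1_schedule(4, "random", seed = 9, blocked_reps = 2,
                           random_reps = 1)
  b <- build_exp1_schedule(4, "random", seed = 9, blocked_reps = 2,
                           random_reps = 1)
  expect_identical(a, b)
  c_ <- build_exp1_schedule(4, "random", seed = 10, blocked_reps = 2,
                            random_reps = 1)
  expect_false(identical(a$comparison_id, c_$comparison_id))

  d <- build_exp2_schedule(1, "motivation", seed = 3)
  e <- build_exp2_schedule(1, "motivation", seed = 3)
  expect_identical(d, e)
})

test_that("the motivation schedule reproduces the printed structure", {
  sch <- build_exp2_schedule(1, "motivation", seed = 7)
  expect_equal(nrow(sch), 448)
  expect_true(all(table(sch$block) == 112))
  # each of the 8 pair combinations 14 times per block
  for (b in 1:4) {
    combos <- table(sch$comparison_id[sch$block == b],
                    sch$standard_side[sch$block == b])
    expect_true(all(combos == 14))
  }
  # two consecutive blocks per part, ordered by start_part
  parts <- vapply(1:4, function(b) sch$motivation_part[sch$block == b][1],
                  character(1))
  expect_equal(parts, c("motivation", "motivation",
                        "demotivation", "demotivation"))
  sch_d <- build_exp2_schedule(2, "demotivation", seed = 7)
  expect_equal(sch_d$motivation_part[sch_d$block == 1][1], "demotivation")

  # points: 56 trials at 50 and 56 at 100 per motivation block; 0 otherwise
  for (b in 1:2) {
    expect_equal(as.vector(table(sch$points_at_stake[sch$block == b])),
                 c(56L, 56L))
  }
  expect_true(all(sch$points_at_stake[sch$motivation_part == "demotivation"] == 0))
})

test_that("multi-participant designs counterbalance start conditions", {
  des <- small_exp1_design(n = 4, seed = 1)
  starts <- vapply(1:4, function(p) {
    des$presentation_order[des$participant == p & des$session == 1][1]
  }, character(1))
  expect_equal(starts, c("blocked", "random", "blocked", "random"))

  des2 <- small_exp2_design(n = 4, seed = 1)
  firsts <- vapply(1:4, function(p) {
    des2$motivation_part[des2$participant == p & des2$block == 1][1]
  }, character(1))
  expect_equal(sum(firsts == "motivation"), 2L)
  expect_equal(sum(firsts == "demotivation"), 2L)
  # forced 3/1 split
  des3 <- build_exp2_design(4, seed = 1, n_motivation_first = 3, reps = 2)
  firsts3 <- vapply(1:4, function(p) {
    des3$motivation_part[des3$participant == p & des3$block == 1][1]
  }, character(1))
  expect_equal(sum(firsts3 == "motivation"), 3)
})

test_that("reward accrual pays one euro per 1,000 points", {
  r <- accrue_reward(rep(50, 20), seed = 1)
  expect_equal(r$euros, 1)
  expect_equal(r$crossing_trials, 20)
  expect_true(all(r$feedback_trials - r$crossing_trials %in% 1:3))

  expect_equal(accrue_reward(rep(0, 100))$euros, 0)

  set.seed(8)
  pts <- sample(c(0, 50, 100), 500, replace = TRUE)
  r2 <- accrue_reward(pts, seed = 2)
  expect_equal(r2$euros, floor(sum(pts) / 1000))          # cumulative-sum oracle
  oracle_cross <- which(diff(c(0, floor(cumsum(pts) / 1000))) > 0)
  expect_equal(r2$crossing_trials, oracle_cross)
})
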