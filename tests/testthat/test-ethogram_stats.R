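make_ethogram <- function(n, flagged, behavior = "scratch_ground",
                          treatment = "robot", birds_touched = 0) {
  df <- tibble::tibble(
    video_id = paste0("v", seq_len(n)),
    week = rep_len(1:6, n),
    treatment = treatment,
    close_approach = FALSE, peck_robot = FALSE, jump_on_robot = FALSE,
    touched_by_robot = birds_touched > 0, pushed_by_robot = FALSE,
    scratch_ground = FALSE, peck_ground = FALSE,
    birds_touched = birds_touched
  )
  df[[behavior]][seq_len(flagged)] <- TRUE
  df
}

test_that("proportions count videos with any behavior of the group flagged", {
  rec <- make_ethogram(19, 16)
  p <- behavior_proportions(rec, behavior_groups()$ground)
  expect_equal(p$successes, 16)
  expect_equal(p$trials, 19)
  expect_equal(p$proportion, 100 * 16 / 19)  # prints as the rounded 84%
  expect_equal(round(p$proportion), 84)
  expect_lt(p$p_value, 1e-6)

  all_on <- behavior_proportions(make_ethogram(10, 10),
                                 behavior_groups()$ground)
  expect_equal(all_on$proportion, 100)
})

test_that("proportions are permutation invariant and group-wide", {
  rec <- make_ethogram(12, 5, behavior = "peck_robot")
  rec$close_approach[8] <- TRUE  # different behavior, same group
  p1 <- behavior_proportions(rec, behavior_groups()$bird_to_robot)
  expect_equal(p1$successes, 6)
  withr::with_seed(2, shuffled <- rec[sample(nrow(rec)), ])
  p2 <- behavior_proportions(shuffled, behavior_groups()$bird_to_robot)
  expect_equal(p2$proportion, p1$proportion)
  expect_equal(p2$p_value, p1$p_value)
})

test_that("the binomial occurrence test matches its closed form", {
  n <- 15
  p0 <- 0.01
  none <- behavior_proportions(make_ethogram(n, 0),
                               behavior_groups()$ground, null_p = p0)
  expect_equal(none$proportion, 0)
  expect_equal(none$p_value, 1)  # P(X >= 0) is certain
  one <- behavior_proportions(make_ethogram(n, 1),
                              behavior_groups()$ground, null_p = p0)
  expect_equal(one$p_value, 1 - (1 - p0)^n, tolerance = 1e-12)
  expect_error(behavior_proportions(make_ethogram(0, 0),
                                    behavior_groups()$ground),
               class = "flockzone_parameter_error")
  expect_error(behavior_proportions(make_ethogram(5, 1), "flying"),
               class = "flockzone_parameter_error")
})

test_that("birds-touched summary gives mean and SEM per week and overall", {
  rec <- make_ethogram(3, 0, birds_touched = c(4, 4, 4))
  rec$week <- c(1, 1, 1)
  s <- birds_touched_summary(rec)
  overall <- s[s$week == "overall", ]
  expect_equal(overall$mean, 4)
  expect_equal(overall$sem, 0)

  rec2 <- make_ethogram(2, 0, birds_touched = c(2, 6))
  rec2$week <- c(2, 2)
  s2 <- birds_touched_summary(rec2)
  overall2 <- s2[s2$week == "overall", ]
  expect_equal(overall2$mean, 4)
  expect_equal(overall2$sem, 2)  # sd/sqrt(n) = (2*sqrt(2))/sqrt(2)
  expect_true(overall2$mean >= 2 && overall2$mean <= 6)

  ctl <- make_ethogram(4, 0, treatment = "control")
  expect_error(birds_touched_summary(ctl),
               class = "flockzone_parameter_error")
})

test_that("rank transform uses ascending mid-ranks", {
  expect_equal(rank_transform(c(10, 20, 30)), c(1, 2, 3))
  expect_equal(rank_transform(c(5, 5, 9)), c(1.5, 1.5, 3))
  expect_error(rank_transform(c(1, NA)), class = "flockzone_parameter_error")
  expect_error(rank_transform(numeric(0)),
               class = "flockzone_parameter_error")
  withr::with_seed(8, v <- rnorm(100))
  r <- rank_transform(v)
  expect_equal(sum(r), 100 * 101 / 2)
  # argsort oracle on a tie-free vector
  expect_equal(r[order(v)], 1:100)
})

test_that("ethogram CSV round-trips and invalid tables are rejected", {
  rec <- make_ethogram(6, 3, birds_touched = c(2, 0, 1, 0, 0, 0))
  rec$touched_by_robot <- rec$birds_touched > 0
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(dplyr::mutate(rec, dplyr::across(
    dplyr::all_of(c("close_approach", "peck_robot", "jump_on_robot",
                    "touched_by_robot", "pushed_by_robot",
                    "scratch_ground", "peck_ground")), as.integer
  )), path)
  back <- read_ethogram(path)
  expect_equal(back$scratch_ground, rec$scratch_ground)
  expect_equal(back$birds_touched, rec$birds_touched)

  bad <- rec
  bad$birds_touched <- 0
  bad$birds_touched[1] <- 3
  bad$touched_by_robot <- FALSE
  bad$pushed_by_robot <- FALSE
  readr::write_csv(bad, path)
  expect_error(read_ethogram(path), class = "flockzone_parse_error")
})

test_that("the long table is tidy with within-timepoint ranks", {
  withr::with_seed(4, {
    summaries <- tibble::tibble(
      video_id = paste0("v", 1:8),
      week = rep(c(1, 6), each = 4),
      treatment = rep(c("robot", "control"), 4),
      batch = rep(1:2, 4),
      moment_prior_pct = runif(8, 90, 130),
      minute_after_pct = runif(8, 5, 110),
      two_min_after_pct = runif(8, 5, 115)
    )
  })
  long <- density_long_table(summaries)
  expect_equal(nrow(long), 24)
  expect_setequal(unique(long$timepoint),
                  c("moment_prior", "minute_after", "two_min_after"))
  per_tp <- split(long$rank, long$timepoint)
  for (r in per_tp) expect_equal(sum(r), 8 * 9 / 2)
  sub <- long[long$timepoint == "minute_after", ]
  expect_equal(sub$value[order(sub$rank)],
               sort(summaries$minute_after_pct))
})
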