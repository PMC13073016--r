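test_that("annualised rate follows the events / days x 365.25 definition", {
  expect_equal(annualized_rate(3, 365.25), 3)
  expect_equal(annualized_rate(1, 1), 365.25)
  expect_equal(annualized_rate(0, 200), 0)
  expect_error(annualized_rate(2, 0), "follow_up_days")
  expect_error(annualized_rate(-1, 10), "non-negative")
})

test_that("annualised rate is linear in events and scale-invariant in time", {
  set.seed(11)
  for (i in 1:50) {
    e <- sample(0:40, 1); d <- runif(1, 10, 1000); k <- runif(1, 0.1, 10)
    expect_equal(annualized_rate(k * e, k * d), annualized_rate(e, d))
    expect_equal(annualized_rate(3 * e, d), 3 * annualized_rate(e, d))
  }
})

test_that("adherence percentage and its domain errors", {
  expect_equal(adherence_pct(45, 50), 90)
  expect_equal(adherence_pct(50, 50), 100)
  expect_equal(adherence_pct(0, 50), 0)
  expect_error(adherence_pct(10, 0), "expected")
})

test_that("level sum score anchors, bounds and permutation invariance", {
  expect_equal(level_sum_score(c(1, 1, 1, 1, 1)), 5)
  expect_equal(level_sum_score(c(5, 5, 5, 5, 5)), 25)
  expect_equal(level_sum_score(c(1, 2, 3, 4, 5)), 15)
  expect_error(level_sum_score(c(1, 2, 3, 4)), "five")
  expect_error(level_sum_score(c(0, 2, 3, 4, 5)), "1..5")
  set.seed(7)
  for (i in 1:20) {
    lv <- sample(1:5, 5, replace = TRUE)
    s <- level_sum_score(lv)
    expect_true(s >= 5 && s <= 25)
    expect_equal(level_sum_score(sample(lv)), s)
  }
})

test_that("months_to_days uses the 30.4375-day month", {
  expect_equal(months_to_days(12), 365.25)
  expect_equal(months_to_days(1), 30.4375)
})

test_that("ABR banding rounds half-up then maps the printed integer bands", {
  cfg <- load_instrument("B", "prophylaxis")
  abr <- config_item(cfg, "abr")
  expect_equal(bucket(abr, 0.0), 0L)
  expect_equal(bucket(abr, 5.2), 3L)
  expect_equal(bucket(abr, 2.4), 1L)  # rounds to 2 -> band "1-2"
  expect_equal(bucket(abr, 0.4), 0L)  # sub-half rates stay in the "0" band
  expect_equal(bucket(abr, 2.5), 2L)  # half-up: 2.5 -> 3 -> band "3-4"
})

test_that("bucketed ranks are monotone non-decreasing over a raw-value grid", {
  cfg <- load_instrument("A", "prophylaxis")
  grids <- list(
    abr = seq(0, 6, by = 0.1),
    ajbr = seq(0, 4, by = 0.1),
    pj_count = 0:8,
    tj_count = 0:5,
    hjhs_change = -3:6,
    headus_change = -2:4,
    qol_current = 5:25,
    qol_change = -4:5
  )
  for (id in names(grids)) {
    item <- config_item(cfg, id)
    ranks <- vapply(grids[[id]], function(v) bucket(item, v), integer(1))
    expect_true(all(diff(ranks) >= 0), info = id)
    expect_true(all(ranks >= 0 & ranks < item$scale_size), info = id)
  }
  # adherence bands run the other way: higher adherence is clinically better
  adh <- config_item(cfg, "adherence")
  adh_ranks <- vapply(seq(0, 100, by = 0.5), function(v) bucket(adh, v), integer(1))
  expect_true(all(diff(adh_ranks) <= 0))
})

test_that("adherence boundaries follow the printed inequalities literally", {
  cfg <- load_instrument("B", "prophylaxis")
  adh <- config_item(cfg, "adherence")
  expect_equal(bucket(adh, 95), 0L)    # >90
  expect_equal(bucket(adh, 90.01), 0L)
  expect_equal(bucket(adh, 90), 1L)    # closed [80, 90]
  expect_equal(bucket(adh, 80), 1L)
  expect_equal(bucket(adh, 79.9), 2L)  # <80
})

test_that("score-change bands read worsening thresholds as floors", {
  cfg <- load_instrument("A", "prophylaxis")
  hjhs <- config_item(cfg, "hjhs_change")
  expect_equal(vapply(c(-2, 0, 1, 2, 3, 4, 7), function(v) bucket(hjhs, v),
                      integer(1)),
               c(0L, 0L, 0L, 1L, 1L, 2L, 2L))
  headus <- config_item(cfg, "headus_change")
  expect_equal(vapply(c(-1, 0, 1, 2, 5), function(v) bucket(headus, v),
                      integer(1)),
               c(0L, 0L, 1L, 2L, 2L))
  qolc <- config_item(cfg, "qol_change")
  expect_equal(vapply(c(-3, 0, 1, 2, 3, 6), function(v) bucket(qolc, v),
                      integer(1)),
               c(0L, 0L, 1L, 1L, 2L, 2L))
})

test_that("categorical levels map directly and invalid ones fail loudly", {
  cfg <- load_instrument("A", "prophylaxis")
  expect_equal(bucket(config_item(cfg, "pj_trend"), "absent_or_decreased"), 0L)
  expect_equal(bucket(config_item(cfg, "tj_trend"), "increased"), 2L)
  expect_equal(bucket(config_item(cfg, "trough_sat"), "very_satisfactory"), 0L)
  expect_equal(bucket(config_item(cfg, "trough_sat"), "not_at_all_satisfactory"), 3L)
  expect_error(bucket(config_item(cfg, "pj_trend"), "worse"), "one of")
  expect_error(bucket(config_item(cfg, "qol_current"), 4), "5..25")
})

test_that("responses_from_raw computes, buckets and assembles a complete response set", {
  cfg <- load_instrument("A", "prophylaxis")
  rec <- list(
    bleed_count = 3, joint_bleed_count = 1, follow_up_days = 365.25,
    infusions_given = 45, infusions_expected = 50,
    eq5d_mobility = 1, eq5d_selfcare = 1, eq5d_activities = 2, eq5d_pain = 2,
    eq5d_anxiety = 1,
    eq5d_baseline_mobility = 1, eq5d_baseline_selfcare = 1,
    eq5d_baseline_activities = 1, eq5d_baseline_pain = 1,
    eq5d_baseline_anxiety = 1,
    hjhs_delta = 2, headus_delta = 0, pj_count = 1, tj_count = 0,
    pj_trend = "stable", tj_trend = "absent_or_decreased",
    trough_satisfaction = "quite_satisfactory"
  )
  rs <- responses_from_raw(cfg, rec, patient_id = "p7")
  expect_s3_class(rs, "hmt_responses")
  expect_equal(rs$answers[["abr"]], 2L)        # ABR 3 -> band "3-4"
  expect_equal(rs$answers[["ajbr"]], 1L)       # AJBR 1
  expect_equal(rs$answers[["adherence"]], 1L)  # 90% -> middle band
  expect_equal(rs$answers[["qol_current"]], 1L)  # LSS 7 -> "7-11"
  expect_equal(rs$answers[["qol_change"]], 1L)   # LSS rose by 2
  expect_equal(rs$answers[["hjhs_change"]], 1L)
  expect_equal(rs$answers[["trough_sat"]], 1L)
  # the assembled set scores without error
  expect_s3_class(composite_score(cfg, rs), "hmt_score")
  # missing required fields are named
  expect_error(responses_from_raw(cfg, rec[setdiff(names(rec), "bleed_count")]),
               "bleed_count")
  # inconsistent counts are rejected
  bad <- rec; bad$joint_bleed_count <- 9
  expect_error(responses_from_raw(cfg, bad), "exceeds")
})
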