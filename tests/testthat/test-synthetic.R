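target_hb <- c(pharmacokinetics = 18, bleeding_episodes = 32,
               joint_health = 27, adherence_qol = 23)

test_that("simulated panels satisfy the constant-sum constraint and are seed-reproducible", {
  panel <- simulate_panel(10, target_hb, concentration = 50, seed = 7)
  expect_length(panel, 10)
  for (a in panel) {
    expect_equal(nrow(validate_allocation(a)), 0)
    expect_equal(sum(a$values), 100, tolerance = 1e-9)
  }
  again <- simulate_panel(10, target_hb, concentration = 50, seed = 7)
  expect_identical(panel, again)
  different <- simulate_panel(10, target_hb, concentration = 50, seed = 8)
  expect_false(identical(panel, different))
  expect_error(simulate_panel(10, c(x = 60, y = 50), seed = 1), "sum to 100")
})

test_that("integer mode apportions every allocation to integers summing exactly to 100", {
  panel <- simulate_panel(25, target_hb, concentration = 30, integer_mode = TRUE,
                          seed = 3)
  for (a in panel) {
    expect_true(all(a$values == round(a$values)))
    expect_identical(sum(a$values), 100)
  }
})

test_that("generators leave the caller's random stream untouched", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(simulate_panel(5, target_hb, seed = 9))
  expect_identical(runif(1), before)
})

test_that("a concentrated panel recovers the target weights with full consensus", {
  panel <- simulate_panel(16, target_hb, concentration = 500, seed = 41)
  tab <- summarize_round(panel)
  expect_true(all(abs(tab$median - unname(target_hb)) <= 2))
  expect_true(all(tab$consensus))
  ws <- derive_weights(panel)
  expect_true(all(abs(ws$weights - target_hb) <= 2))
  expect_equal(sum(ws$weights), 100, tolerance = 1e-9)
})

test_that("full round-2 compliance projects every value into bounds and shrinks the IQR", {
  for (seed in 1:100) {
    panel <- simulate_panel(8, target_hb, concentration = 40, seed = seed)
    tab1 <- summarize_round(panel)
    bounds <- round2_bounds(tab1)
    r2 <- simulate_round2(panel, bounds, compliance = 1, seed = seed)
    findings <- check_round2(r2, bounds)
    expect_false(any(findings$violation))
    expect_true(all(findings$in_bounds))
    for (a in r2) expect_equal(sum(a$values), 100, tolerance = 1e-6)
    tab2 <- summarize_round(r2)
    expect_true(all(tab2$iqr <= tab1$iqr + 1e-9), info = seed)
  }
})

test_that("zero compliance keeps deviants outside bounds, each with a justification", {
  panel <- simulate_panel(12, target_hb, concentration = 40, seed = 5)
  bounds <- round2_bounds(summarize_round(panel))
  r2 <- simulate_round2(panel, bounds, compliance = 0, seed = 5)
  findings <- check_round2(r2, bounds)
  outside <- findings[!findings$in_bounds, ]
  expect_gt(nrow(outside), 0)
  expect_true(all(outside$justification_present))
  expect_false(any(findings$violation))
})

test_that("cohort severity anchors force the extreme profiles", {
  cfg <- load_instrument("B", "prophylaxis")
  best <- simulate_cohort(5, severity = 0, config = cfg, seed = 2)
  worst <- simulate_cohort(5, severity = 1, config = cfg, seed = 2)
  for (r in best) {
    s <- composite_score(cfg, r)
    expect_identical(s$composite, 0)
    expect_identical(s$category, "Excellent")
  }
  for (r in worst) {
    s <- composite_score(cfg, r)
    expect_identical(s$composite, 100)
    expect_identical(s$category, "Critical")
  }
})

test_that("mean composite score is non-decreasing in cohort severity", {
  cfg <- load_instrument("A", "prophylaxis")
  means <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(sev) {
    cohort <- simulate_cohort(500, sev, cfg, seed = 77)
    mean(vapply(cohort, function(r) composite_score(cfg, r)$composite,
                numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) >= 0))
})

test_that("simulated raw records recover the nominal bleeding rate in expectation", {
  recs <- simulate_raw_records(2000, bleed_rate_per_year = 4,
                               follow_up_days = 365.25, seed = 13)
  abrs <- annualized_rate(recs$bleed_count, recs$follow_up_days)
  expect_lt(abs(mean(abrs) - 4), 0.2)
  expect_true(all(recs$joint_bleed_count <= recs$bleed_count))

  quiet <- simulate_raw_records(50, bleed_rate_per_year = 0,
                                follow_up_days = 200, seed = 1)
  expect_true(all(quiet$bleed_count == 0))
  cfg <- load_instrument("A", "on_demand")
  abr_item <- config_item(cfg, "abr")
  expect_true(all(vapply(seq_len(nrow(quiet)), function(i) {
    bucket(abr_item, annualized_rate(quiet$bleed_count[i],
                                     quiet$follow_up_days[i]))
  }, integer(1)) == 0L))

  full <- simulate_raw_records(40, 2, 365.25, adherence_mean = 100, seed = 4)
  expect_true(all(adherence_pct(full$infusions_given,
                                full$infusions_expected) == 100))
})

test_that("raw records feed the whole pipeline through to scores", {
  cfg <- load_instrument("A", "prophylaxis")
  recs <- simulate_raw_records(20, 3, 365.25, seed = 21)
  scores <- vapply(seq_len(nrow(recs)), function(i) {
    rs <- responses_from_raw(cfg, recs[i, ], patient_id = recs$record_id[i])
    composite_score(cfg, rs)$composite
  }, numeric(1))
  expect_true(all(scores >= 0 & scores <= 100))
})
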