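test_that("constant-sum allocations validate against the 100-point budget", {
  a <- allocation("r1", 1, "domain", c(x = 50, y = 30, z = 20))
  expect_equal(nrow(validate_allocation(a)), 0)

  over <- allocation("r1", 1, "domain", c(x = 50, y = 30, z = 25))
  rep <- validate_allocation(over)
  expect_true(any(grepl("sum is 105", rep$message)))

  neg <- allocation("r1", 1, "domain", c(x = 120, y = -20))
  rep <- validate_allocation(neg)
  expect_true(any(grepl("negative", rep$message)))
})

test_that("quartile summary matches hand-derived linear-interpolation values", {
  s <- quartile_summary(c(10, 10, 10, 10))
  expect_equal(s$iqr, 0)
  expect_true(s$consensus)

  s <- quartile_summary(c(10, 20, 30, 40))
  expect_equal(s$q1, 17.5)
  expect_equal(s$q3, 32.5)
  expect_equal(s$iqr, 15)
  expect_false(s$consensus)

  s <- quartile_summary(c(30, 32, 32, 34))
  expect_equal(s$iqr, 1)
  expect_true(s$consensus)

  expect_error(quartile_summary(42), "two raters")
})

test_that("consensus is strict: iqr exactly at the threshold fails", {
  # five raters, q1 = 10, q3 = 18 under linear interpolation -> iqr exactly 8
  s <- quartile_summary(c(10, 10, 14, 18, 18))
  expect_equal(s$iqr, 8)
  expect_false(s$consensus)
  expect_true(quartile_summary(c(10, 10, 14, 18, 18),
                               delphi_config(consensus_threshold = 8.5))$consensus)
})

test_that("linear quantiles agree with the independent interpolation oracle", {
  set.seed(99)
  for (i in 1:1000) {
    n <- sample(3:30, 1)
    x <- round(runif(n, 0, 100), 2)
    s <- quartile_summary(x)
    expect_equal(c(s$q1, s$median, s$q3), oracle_quantile(x, c(.25, .5, .75)),
                 tolerance = 1e-12)
  }
})

test_that("alternative quantile conventions are selectable and agree on constant panels", {
  x <- c(12, 15, 18, 22, 30)
  for (m in c("linear", "nearest", "tukey")) {
    s <- quartile_summary(rep(20, 6), delphi_config(quantile_method = m))
    expect_equal(c(s$q1, s$median, s$q3), c(20, 20, 20), info = m)
  }
  expect_equal(quartile_summary(x, delphi_config(quantile_method = "tukey"))$q1,
               stats::fivenum(x)[2])
})

test_that("summarising a constant panel reproduces the allocation with IQR 0", {
  target <- c(pharmacokinetics = 18, bleeding_episodes = 32,
              joint_health = 27, adherence_qol = 23)
  panel <- lapply(1:12, function(i) {
    allocation(paste0("r", i), 1, "domain", target)
  })
  tab <- summarize_round(panel)
  expect_equal(tab$median, unname(target))
  expect_equal(tab$iqr, rep(0, 4))
  expect_true(all(tab$consensus))
  expect_equal(tab$n, rep(12, 4))
})

test_that("summarize_round rejects mixed scopes and mismatched slot sets", {
  a <- allocation("r1", 1, "domain", c(x = 60, y = 40))
  b <- allocation("r2", 1, "items:joint_health", c(x = 60, y = 40))
  expect_error(summarize_round(list(a, b)), "mix scopes")
  c2 <- allocation("r2", 1, "domain", c(x = 60, z = 40))
  expect_error(summarize_round(list(a, c2)), "different slots")
  sym <- summarize_round(list(
    allocation("r1", 1, "domain", c(x = 40, y = 60)),
    allocation("r2", 1, "domain", c(x = 60, y = 40))
  ))
  expect_equal(sym$median, c(50, 50))
})

test_that("round-2 bounds are the closed interquartile interval from round 1", {
  panel <- list(
    allocation("r1", 1, "domain", c(x = 10, y = 90)),
    allocation("r2", 1, "domain", c(x = 20, y = 80)),
    allocation("r3", 1, "domain", c(x = 30, y = 70)),
    allocation("r4", 1, "domain", c(x = 40, y = 60))
  )
  b <- round2_bounds(summarize_round(panel))
  expect_equal(b$x, c(17.5, 32.5))
  expect_equal(b$y, c(67.5, 82.5))
  const <- lapply(1:4, function(i) allocation(paste0("r", i), 1, "domain",
                                              c(x = 25, y = 75)))
  bc <- round2_bounds(summarize_round(const))
  expect_equal(bc$x, c(25, 25))
  expect_length(round2_bounds(summarize_round(panel)[0, ]), 0)
})

test_that("round-2 checks flag unjustified out-of-bounds values only", {
  bounds <- list(x = c(17.5, 32.5), y = c(67.5, 82.5))
  inside <- allocation("r1", 2, "domain", c(x = 20, y = 80))
  justified <- allocation("r2", 2, "domain", c(x = 10, y = 90),
                          justifications = c(x = "sticks to original rating",
                                             y = "sticks to original rating"))
  silent <- allocation("r3", 2, "domain", c(x = 40, y = 60))
  findings <- check_round2(list(inside, justified, silent), bounds)
  expect_equal(nrow(findings), 6)
  expect_false(any(findings$violation[findings$rater_id == "r1"]))
  r2 <- findings[findings$rater_id == "r2", ]
  expect_true(all(!r2$in_bounds & r2$justification_present & !r2$violation))
  expect_true(all(findings$violation[findings$rater_id == "r3"]))
  # boundary values are in bounds (closed interval)
  edge <- check_round2(list(allocation("r4", 2, "domain", c(x = 17.5, y = 82.5))),
                       bounds)
  expect_true(all(edge$in_bounds))
  expect_error(check_round2(list(allocation("r5", 2, "domain", c(q = 100))),
                            bounds), "no round-1 bounds")
})

test_that("derived weights are the round-2 medians, renormalised to 100 when needed", {
  target <- c(pharmacokinetics = 18, bleeding_episodes = 32,
              joint_health = 27, adherence_qol = 23)
  panel <- lapply(1:9, function(i) allocation(paste0("r", i), 2, "domain", target))
  ws <- derive_weights(panel)
  expect_equal(ws$weights, target)
  expect_false(ws$renormalised)
  expect_equal(ws$sum_raw, 100)

  # medians that do not sum to 100 get proportionally rescaled
  skewed <- list(
    allocation("r1", 2, "domain", c(x = 20, y = 40, z = 40)),
    allocation("r2", 2, "domain", c(x = 30, y = 30, z = 40)),
    allocation("r3", 2, "domain", c(x = 40, y = 40, z = 20))
  )
  ws2 <- derive_weights(skewed)
  expect_equal(ws2$sum_raw, 110)  # per-slot medians 30, 40, 40
  expect_true(ws2$renormalised)
  expect_equal(sum(ws2$weights), 100, tolerance = 1e-9)
  expect_equal(unname(ws2$weights), c(30, 40, 40) * 100 / 110)
})

test_that("strict bound enforcement aborts derivation on unjustified deviations", {
  bounds <- list(x = c(20, 30), y = c(70, 80))
  ok <- allocation("r1", 2, "domain", c(x = 25, y = 75))
  stray <- allocation("r2", 2, "domain", c(x = 40, y = 60))
  expect_error(derive_weights(list(ok, stray), bounds = bounds),
               "unjustified out-of-bounds")
  lenient <- delphi_config(strict_bounds = FALSE)
  expect_s3_class(derive_weights(list(ok, stray), lenient, bounds = bounds),
                  "hmt_weightset")
  excused <- allocation("r2", 2, "domain", c(x = 40, y = 60),
                        justifications = c(x = "why", y = "why"))
  expect_s3_class(derive_weights(list(ok, excused), bounds = bounds),
                  "hmt_weightset")
})
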