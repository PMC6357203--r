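test_that("divided fraction is recovered across the dilution range", {
  for (q in c(0.1, 0.3, 0.5, 0.8)) {
    ev <- simulate_dilution_events(1e5, q, intensity_cv = 0.05,
                                   seed = 50 + round(100 * q))
    est <- estimate_divided_fraction(ev)
    expect_lt(abs(est$percent_divided_platelets / 100 - q), 0.02)
    expect_lt(abs(est$percent_divided_events / 100 - 2 * q / (1 + q)),
              0.03)
  }
  # q = 0, no leakage: unimodal, falls back to the half-dilution boundary
  # and scores (almost) nothing as divided
  ev0 <- simulate_dilution_events(5000, 0, seed = 2)
  est0 <- suppressWarnings(estimate_divided_fraction(ev0))
  expect_lt(est0$percent_divided_events, 0.5)
})

test_that("divided-event percentage is scale invariant and monotone in q", {
  ev <- simulate_dilution_events(2e4, 0.3, seed = 4)
  a <- estimate_divided_fraction(ev)
  ev_scaled <- ev
  ev_scaled$intensity <- ev_scaled$intensity * 137.5
  b <- estimate_divided_fraction(ev_scaled)
  expect_equal(a$percent_divided_events, b$percent_divided_events)

  grid <- c(0.05, 0.2, 0.4, 0.6, 0.8)
  pct <- vapply(grid, function(q) {
    estimate_divided_fraction(
      simulate_dilution_events(2e4, q, seed = 77)
    )$percent_divided_events
  }, numeric(1))
  expect_true(all(diff(pct) >= 0))
})

test_that("valley boundary sits between the generation modes and falls
           back when unimodal", {
  ev <- simulate_dilution_events(5e4, 0.4, seed = 9)
  est <- estimate_divided_fraction(ev, method = "valley")
  expect_lt(est$boundary, est$gen0_mode)
  expect_gt(est$boundary_log2, est$gen0_mode_log2 - 1)
  half <- estimate_divided_fraction(ev, method = "half_dilution")
  expect_equal(half$boundary_log2, half$gen0_mode_log2 - 0.5)
  # a single tight cluster has no interior valley
  tight <- 1000 * 2^rnorm(2000, 0, 0.02)
  expect_warning(est_u <- estimate_divided_fraction(tight), "half-dilution")
  expect_equal(est_u$method, "half_dilution")
  expect_error(estimate_divided_fraction(1:100), "200 events")
})

test_that("event CSV round trip preserves the estimate", {
  ev <- simulate_dilution_events(5000, 0.3, seed = 15)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dilution_events(ev, path)
  back <- read_dilution_events(path)
  expect_s3_class(back, "dilution_events")
  expect_equal(
    estimate_divided_fraction(back)$percent_divided_events,
    estimate_divided_fraction(ev)$percent_divided_events)
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("foo,bar", "1,2"), bad)
  expect_error(read_dilution_events(bad), "event_id")
})

test_that("group summaries reproduce the published mean +/- SD rows", {
  tab <- summarize_division_table(cfse_division_percentages())
  hi20 <- tab[tab$timepoint == "twenty_hours" & tab$mfi == "high", ]
  lo20 <- tab[tab$timepoint == "twenty_hours" & tab$mfi == "low", ]
  expect_equal(hi20$n, 12)
  # agreement with the published rows to their printed precision
  expect_lt(abs(hi20$mean - 85.6), 0.051)
  expect_lt(abs(hi20$sd - 10.1), 0.051)
  expect_lt(abs(lo20$mean - 75.5), 0.051)
  expect_lt(abs(lo20$sd - 20.2), 0.051)
  # degenerate groups
  one <- data.frame(timepoint = "t", mfi = "m", percent_divided = 5)
  expect_error(summarize_division_table(one), "fewer than two")
  rep2 <- data.frame(timepoint = "t", mfi = "m",
                     percent_divided = c(7, 7))
  s <- summarize_division_table(rep2)
  expect_equal(s$mean, 7)
  expect_equal(s$sd, 0)
})
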