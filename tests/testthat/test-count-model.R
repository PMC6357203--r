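test_that("binomial expectation reproduces the published percentages", {
  e <- expected_doublet_proportions(67, 60)
  expect_equal(round(100 * c(e$p_rr, e$p_rg, e$p_gg), 1),
               c(27.8, 49.8, 22.3))
  e6 <- expected_doublet_proportions(171, 167)
  expect_equal(round(100 * c(e6$p_rr, e6$p_rg, e6$p_gg), 1),
               c(25.6, 50.0, 24.4))
  # symmetry
  for (n in c(1, 7, 1000)) {
    e <- expected_doublet_proportions(n, n)
    expect_equal(c(e$p_rr, e$p_rg, e$p_gg), c(0.25, 0.5, 0.25))
  }
  expect_error(expected_doublet_proportions(0, 0, "EMPTY"), "EMPTY")
})

test_that("expected proportions are normalised for any input size", {
  set.seed(1)
  for (i in 1:200) {
    n <- sample.int(1e6, 2)
    e <- expected_doublet_proportions(n[1], n[2])
    expect_lt(abs(e$p_rr + e$p_rg + e$p_gg - 1), 1e-12)
    expect_gt(e$p_rr, 0)
    expect_gt(e$p_gg, 0)
  }
})

test_that("tail test matches the published probabilities", {
  # cultured MCX1 and initial MCX3
  expect_equal(doublet_null_test(fc(171, 167, 28, 22, 8))$p_le,
               1.76e-8, tolerance = 0.01)
  expect_equal(round(doublet_null_test(fc(407, 448, 11, 12, 32))$p_le, 2),
               0.89)
  # centred statistic: d_rg exactly at expectation
  x <- fc(100, 100, 5, 5, 10)
  tt <- doublet_null_test(x)
  expect_equal(tt$z, 0)
  expect_equal(tt$p_le, 0.5)
})

test_that("exact binomial tail matches brute-force summation and differs
           from the normal approximation at small counts", {
  x <- fc(67, 60, 3, 3, 5)
  exact <- doublet_null_test(x, method = "exact_binomial")
  p <- expected_doublet_proportions(67, 60)$p_rg
  expect_equal(exact$p_le, binom_lower_tail(5, 11, p), tolerance = 1e-12)
  expect_equal(exact$p_le, 0.50, tolerance = 0.02)
  approx <- doublet_null_test(x, method = "normal_approx")
  expect_equal(approx$p_le, 0.39, tolerance = 0.02)
  expect_gt(abs(exact$p_le - approx$p_le), 0.05)
})

test_that("tail test rejects undefined inputs", {
  expect_error(doublet_null_test(fc(10, 10, 0, 0, 0)), "no doublets")
  expect_error(doublet_null_test(fc(10, 0, 1, 0, 0)), "single colour")
})

test_that("division estimator reproduces the published fractions", {
  e <- estimate_division_fractions(fc(171, 167, 28, 22, 8))
  expect_equal(round(100 * c(e$f_red, e$f_green), 1), c(16.4, 12.0))
  e5 <- estimate_division_fractions(fc(114, 110, 4, 5, 27))
  expect_equal(round(100 * c(e5$f_red, e5$f_green), 1), c(-8.2, -6.6))
  # perfect 1:2:1 doublet pattern: no division signal
  e0 <- estimate_division_fractions(fc(100, 100, 5, 5, 10))
  expect_equal(e0$f_red, 0)
  expect_equal(e0$f_green, 0)
  expect_equal(e0$r0, 100)
  expect_equal(e0$g0, 100)
})

test_that("division estimate satisfies its internal identities", {
  set.seed(7)
  for (i in 1:50) {
    x <- random_counts()
    e <- estimate_division_fractions(x)
    expect_equal(x$n_red, e$r0 * (1 + e$f_red), tolerance = 1e-9)
    expect_equal(x$n_green, e$g0 * (1 + e$f_green), tolerance = 1e-9)
    expect_equal(e$htb_rr, x$d_rg * e$r0 / (2 * e$g0), tolerance = 1e-9)
  }
})

test_that("closed form agrees with the numerical-root oracle", {
  set.seed(11)
  for (i in 1:200) {
    x <- random_counts()
    e <- estimate_division_fractions(x)
    o <- division_fractions_numeric(x)
    expect_equal(e$f_red, o[["f_red"]], tolerance = 1e-6)
    expect_equal(e$f_green, o[["f_green"]], tolerance = 1e-6)
  }
})

test_that("estimator is equivariant under colour swap and p is invariant", {
  set.seed(3)
  for (i in 1:30) {
    x <- random_counts()
    y <- fc(x$n_green, x$n_red, x$d_gg, x$d_rr, x$d_rg)
    ex <- estimate_division_fractions(x)
    ey <- estimate_division_fractions(y)
    expect_equal(ex$f_red, ey$f_green, tolerance = 1e-12)
    expect_equal(ex$f_green, ey$f_red, tolerance = 1e-12)
    expect_equal(doublet_null_test(x)$p_le, doublet_null_test(y)$p_le,
                 tolerance = 1e-15)
  }
})

test_that("exact binomial doublet pattern is a fixed point of the estimator", {
  set.seed(5)
  for (i in 1:20) {
    r0 <- sample(100:2000, 1)
    g0 <- sample(100:2000, 1)
    H <- sample(10:50, 1)
    r <- r0 / (r0 + g0); g <- 1 - r
    x <- field_counts(r0, g0, H * r^2, H * g^2, H * 2 * r * g,
                      integer_counts = FALSE)
    e <- estimate_division_fractions(x)
    expect_lt(abs(e$f_red), 1e-10)
    expect_lt(abs(e$f_green), 1e-10)
  }
})

test_that("F_r increases strictly with d_rr, all else fixed", {
  f_at <- function(d_rr) {
    estimate_division_fractions(fc(200, 190, d_rr, 10, 12))$f_red
  }
  vals <- vapply(5:40, f_at, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("estimator errors on degenerate and single-colour counts", {
  # any internally consistent count table keeps the denominators positive
  # (n_green - d_gg - d_rg/2 = s_g + d_gg + d_rg/2 > 0), so the degenerate
  # branch can only be reached by corrupted records
  corrupt <- structure(list(experiment = "corrupt", condition = "cultured",
                            n_red = 100, n_green = 10, d_rr = 2,
                            d_gg = 2, d_rg = 36),
                       class = "field_counts")
  expect_error(estimate_division_fractions(corrupt), "degenerate")
  expect_error(estimate_division_fractions(fc(50, 0, 2, 0, 0)),
               "both colours")
})

test_that("analyze_experiment bundles the published column values", {
  a <- analyze_experiment(fc(171, 167, 28, 22, 8, "MCX1"), ci = FALSE)
  expect_equal(round(unname(a$observed_pct), 1), c(48.3, 13.8, 37.9))
  expect_equal(round(unname(a$expected_pct), 1), c(25.6, 50.0, 24.4))
  a4 <- analyze_experiment(fc(125, 104, 7, 6, 20, "MCX4", "initial"),
                           ci = FALSE)
  expect_equal(round(a4$p_le, 2), 0.90)
  expect_error(analyze_experiment(fc(0, 0, 0, 0, 0)), "no doublets|platelets")
})
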