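test_that("simulation_truth enforces its feasibility invariants", {
  expect_error(simulation_truth(r0 = 10, g0 = 10, n_contact_pairs = 11),
               "infeasible")
  expect_error(simulation_truth(division_offset = 5, contact_distance = 3),
               "division_offset")
  expect_error(simulate_counts(
    simulation_truth(r0 = 0, g0 = 0, n_contact_pairs = 0)))
})

test_that("expectation mode is an exact fixed point of the estimator", {
  s <- simulate_counts(simulation_truth(1000, 1000, 100, 0, 0,
                                        "expectation"))
  expect_equal(s$counts$d_rr, 25)
  expect_equal(s$counts$d_rg, 50)
  expect_equal(s$counts$d_gg, 25)
  e0 <- estimate_division_fractions(s$counts)
  expect_equal(e0$f_red, 0, tolerance = 1e-12)

  s2 <- simulate_counts(simulation_truth(1000, 1000, 100, 0.15, 0.10,
                                         "expectation"))
  e2 <- estimate_division_fractions(s2$counts)
  expect_equal(e2$f_red, 0.15, tolerance = 1e-9)
  expect_equal(e2$f_green, 0.10, tolerance = 1e-9)
  # asymmetric colours too
  s3 <- simulate_counts(simulation_truth(800, 1200, 60, 0.2, 0.05,
                                         "expectation"))
  e3 <- estimate_division_fractions(s3$counts)
  expect_equal(e3$f_red, 0.2, tolerance = 1e-9)
  expect_equal(e3$f_green, 0.05, tolerance = 1e-9)
})

test_that("sampling mode conserves platelets and is seed-deterministic", {
  for (seed in 1:20) {
    s <- simulate_counts(simulation_truth(500, 400, 50, 0.2, 0.1,
                                          "sampling", seed = seed))
    expect_equal(s$counts$n_red + s$counts$n_green,
                 900 + s$n_divisions)
  }
  a <- simulate_counts(simulation_truth(mode = "sampling", seed = 4))
  b <- simulate_counts(simulation_truth(mode = "sampling", seed = 4))
  expect_identical(unclass(a$counts), unclass(b$counts))
})

test_that("sampling-mode estimand accounts for the contact exclusion", {
  truth <- simulation_truth(5000, 5000, 200, 0.12, 0.12, "sampling")
  expect_equal(unname(true_division_fractions(truth)),
               rep(0.12 * 4800 / 5000, 2))
  expect_equal(unname(true_division_fractions(
    simulation_truth(1000, 1000, 100, 0.15, 0.1, "expectation"))),
    c(0.15, 0.1))
})

test_that("spatial mode excludes multiplets and reports ground truth", {
  s <- simulate_counts(simulation_truth(165, 165, mode = "spatial",
                                        seed = 2))
  gt <- s$ground_truth
  expect_setequal(setdiff(unique(gt$class), "multiplet"),
                  c("singlet", "htb_doublet", "division_doublet"))
  expect_equal(s$n_excluded, sum(gt$class == "multiplet"))
  kept <- gt[gt$class != "multiplet", ]
  expect_equal(s$counts$n_red, sum(kept$channel == "red"))
  expect_equal(s$counts$n_green, sum(kept$channel == "green"))
  # doublet members lie within contact distance
  two <- kept[kept$class %in% c("htb_doublet", "division_doublet"), ]
  for (cid in unique(two$cluster_id)) {
    m <- two[two$cluster_id == cid, ]
    expect_equal(nrow(m), 2)
    expect_lte(sqrt(diff(m$x)^2 + diff(m$y)^2), 3)
  }
})

test_that("shrinking the contact distance removes happen-to-be doublets", {
  s <- simulate_counts(simulation_truth(
    165, 165, f_red = 0.15, f_green = 0.15, mode = "spatial",
    contact_distance = 0.5, division_offset = 0.3, seed = 8))
  gt <- s$ground_truth
  expect_equal(sum(gt$class == "htb_doublet"), 0)
  expect_gt(sum(gt$class == "division_doublet"), 0)
  expect_equal(s$counts$d_rg, 0)
})

test_that("dilution events honour the event-count identity 2q/(1+q)", {
  q <- 0.3
  ev <- simulate_dilution_events(1e5, q, seed = 12)
  expect_equal(mean(ev$generation == 1), 2 * q / (1 + q),
               tolerance = 0.01)
  # one division replaces one event by two
  expect_equal(nrow(ev),
               attr(ev, "n_platelets") + sum(ev$generation == 1) / 2)
  # determinism
  ev2 <- simulate_dilution_events(1e5, q, seed = 12)
  expect_identical(ev$intensity, ev2$intensity)
})

test_that("undivided, leak-free populations stay inside the sort gate", {
  ev <- simulate_dilution_events(5000, 0, leak_fraction = 0, seed = 3)
  gate <- attr(ev, "gate")
  expect_true(all(ev$intensity >= gate["low"] * 0.8 &
                    ev$intensity <= gate["high"] * 1.2))
  expect_true(all(ev$generation == 0))
  # leaked events fall below the gate
  evl <- simulate_dilution_events(5000, 0, leak_fraction = 0.1, seed = 3)
  expect_true(all(evl$intensity[evl$leaked] < gate["low"]))
  expect_gt(sum(evl$leaked), 0)
  expect_error(simulate_dilution_events(100, 0.5, gate_width = 0),
               "gate_width")
})
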