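# Independent oracles and fixture builders used across test files.

fc <- function(n_red, n_green, d_rr, d_gg, d_rg, experiment = "test",
               condition = "cultured") {
  field_counts(n_red, n_green, d_rr, d_gg, d_rg,
               experiment = experiment, condition = condition)
}

# Numerical-root oracle for the division-fraction system: expresses R0 as a
# function of G0 from the red doublet balance and finds the root of the
# green balance by 1-D bisection -- a solution path independent of the
# closed form under test.
division_fractions_numeric <- function(counts) {
  a <- counts$d_rg / 2
  r0_of <- function(g0) (counts$n_red - counts$d_rr) * g0 / (g0 - a)
  res_green <- function(g0) {
    r0 <- r0_of(g0)
    a * g0 / r0 + counts$n_green - g0 - counts$d_gg
  }
  lower <- a + 1e-9 + 1e-12 * a
  upper <- 2 * (counts$n_green + counts$d_rg + 10)
  g0 <- stats::uniroot(res_green, c(lower, upper), tol = 1e-12)$root
  r0 <- r0_of(g0)
  c(f_red = counts$n_red / r0 - 1, f_green = counts$n_green / g0 - 1)
}

# Brute-force binomial lower tail by direct summation.
binom_lower_tail <- function(k, size, prob) {
  sum(vapply(0:k, function(i) {
    choose(size, i) * prob^i * (1 - prob)^(size - i)
  }, numeric(1)))
}

# Random valid count vector: singlets and doublet classes drawn directly,
# totals derived, so every draw satisfies the count invariants.
random_counts <- function() {
  s_r <- sample(30:500, 1)
  s_g <- sample(30:500, 1)
  d_rr <- sample(0:30, 1)
  d_gg <- sample(0:30, 1)
  d_rg <- sample(1:30, 1)
  fc(s_r + 2 * d_rr + d_rg, s_g + 2 * d_gg + d_rg, d_rr, d_gg, d_rg)
}
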