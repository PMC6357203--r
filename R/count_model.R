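#' Binomial null proportions for doublet colour composition
#'
#' When two platelet populations labelled red and green are mixed and no
#' platelet divides, a doublet forms only by incidental contact of two
#' independent platelets. Its colour combination then follows the binomial
#' pattern: with `R` red and `G` green platelets the red-red, red-green and
#' green-green classes occur in proportions `R^2/(R+G)^2`, `2RG/(R+G)^2` and
#' `G^2/(R+G)^2`. Departures from this pattern — specifically a deficit of
#' red-green doublets — are the signature of division, since a platelet and
#' its progeny always share a colour.
#'
#' @param n_red,n_green Total platelets of each colour.
#' @param experiment Optional label used in error messages.
#' @return An object of class `"binomial_expectation"`: a list with
#'   proportions `p_rr`, `p_rg`, `p_gg` summing to 1.
#' @examples
#' expected_doublet_proportions(67, 60)
#' @export
expected_doublet_proportions <- function(n_red, n_green, experiment = "") {
  stopifnot(is.numeric(n_red), is.numeric(n_green),
            n_red >= 0, n_green >= 0)
  tot <- n_red + n_green
  if (tot <= 0) {
    stop("no platelets counted",
         if (nzchar(experiment)) paste0(" in experiment '", experiment, "'"),
         ": cannot form doublet expectations", call. = FALSE)
  }
  r <- n_red / tot
  g <- n_green / tot
  structure(list(p_rr = r^2, p_rg = 2 * r * g, p_gg = g^2),
            class = "binomial_expectation")
}

#' @export
print.binomial_expectation <- function(x, ...) {
  cat(sprintf("Binomial doublet expectation: RR %.1f%%, RG %.1f%%, GG %.1f%%\n",
              100 * x$p_rr, 100 * x$p_rg, 100 * x$p_gg))
  invisible(x)
}

#' Tail test for a deficit of two-colour doublets
#'
#' Under the no-division null each of the `T = d_rr + d_gg + d_rg` doublets
#' is red-green with probability `p_rg` from
#' [expected_doublet_proportions()], so the red-green count is
#' `Binomial(T, p_rg)`. The test reports the probability that the red-green
#' count is equal to or smaller than the observed one: a small value means
#' two-colour doublets are depleted, i.e. single-colour doublets are in
#' excess, which only division produces.
#'
#' The default `"normal_approx"` method uses the normal approximation
#' without continuity correction,
#' `p = Phi((d_rg - T p_rg) / sqrt(T p_rg (1 - p_rg)))`.
#' `"exact_binomial"` sums the binomial lower tail and is offered as a
#' diagnostic; at small `T` the two can differ noticeably (e.g. 0.39 vs
#' 0.50 at `T = 11`).
#'
#' @param counts A [field_counts()] object with at least one doublet.
#' @param method `"normal_approx"` (default) or `"exact_binomial"`.
#' @return An object of class `"doublet_null_test"`: a list with
#'   `t_doublets`, `observed_fracs` (RR/RG/GG shares among doublets),
#'   `expected` (the [expected_doublet_proportions()] object), `z` (the
#'   standardized statistic; `NA` for the exact method), `p_le`, and
#'   `method`.
#' @examples
#' mcx1 <- field_counts(171, 167, 28, 22, 8, "MCX1", "cultured")
#' doublet_null_test(mcx1)
#' @export
doublet_null_test <- function(counts,
                              method = c("normal_approx", "exact_binomial")) {
  stopifnot(inherits(counts, "field_counts"))
  method <- match.arg(method)
  t_doublets <- total_doublets(counts)
  if (t_doublets < 1) {
    stop("no doublets observed in experiment '", counts$experiment,
         "': the composition test is undefined", call. = FALSE)
  }
  expected <- expected_doublet_proportions(counts$n_red, counts$n_green,
                                           counts$experiment)
  p <- expected$p_rg
  if (p <= 0 || p >= 1) {
    stop("experiment '", counts$experiment, "' has a single colour ",
         "(red-green probability ", p, "); the test needs both colours",
         call. = FALSE)
  }
  observed <- c(rr = counts$d_rr, rg = counts$d_rg,
                gg = counts$d_gg) / t_doublets
  if (method == "normal_approx") {
    z <- (counts$d_rg - t_doublets * p) / sqrt(t_doublets * p * (1 - p))
    p_le <- stats::pnorm(z)
  } else {
    z <- NA_real_
    p_le <- stats::pbinom(counts$d_rg, t_doublets, p)
  }
  structure(list(t_doublets = t_doublets, observed_fracs = observed,
                 expected = expected, z = z, p_le = p_le, method = method,
                 experiment = counts$experiment,
                 condition = counts$condition),
            class = "doublet_null_test")
}

#' @export
print.doublet_null_test <- function(x, ...) {
  cat(sprintf("Doublet composition test [%s, %s] (%s)\n",
              if (nzchar(x$experiment)) x$experiment else "unnamed",
              x$condition, x$method))
  cat(sprintf("  observed RR/RG/GG: %.1f / %.1f / %.1f %% of %d doublets\n",
              100 * x$observed_fracs[["rr"]], 100 * x$observed_fracs[["rg"]],
              100 * x$observed_fracs[["gg"]], x$t_doublets))
  cat(sprintf("  expected RR/RG/GG: %.1f / %.1f / %.1f %%\n",
              100 * x$expected$p_rr, 100 * x$expected$p_rg,
              100 * x$expected$p_gg))
  cat(sprintf("  P(RG <= observed) = %s\n", format(signif(x$p_le, 3))))
  invisible(x)
}

#' Division fractions from singlet and doublet counts
#'
#' Solves the count-balance system of the two-colour semisolid-culture
#' experiment for the fraction of originally seeded platelets of each colour
#' that divided during culture. Writing `R0`, `G0` for the unknown original
#' inputs and `F_r`, `F_g` for the division fractions, the observables obey
#'
#' * `n_red  = R0 (1 + F_r)` and `n_green = G0 (1 + F_g)` — every division
#'   adds one platelet of the same colour;
#' * happen-to-be (contact) red-red doublets stand to red-green doublets in
#'   the binomial ratio `R0 : 2 G0`, so they number `d_rg R0 / (2 G0)`
#'   (symmetrically for green-green);
#' * `d_rr = d_rg R0 / (2 G0) + F_r R0` and
#'   `d_gg = d_rg G0 / (2 R0) + F_g G0` — observed single-colour doublets
#'   are contact doublets plus division doublets.
#'
#' Eliminating `F_r`, `F_g` gives a closed form: with `a = d_rg / 2`,
#' `A = n_red - d_rr`, `B = n_green - d_gg` and `t = (A - a) / (B - a)`,
#' the solution is `R0 = A + a t`, `G0 = B + a / t`, and
#' `F_r = n_red / R0 - 1`, `F_g = n_green / G0 - 1`. Sampling noise can make
#' the fractions negative; negative estimates are returned unclamped.
#'
#' @param counts A [field_counts()] object (integer or real-valued).
#' @return An object of class `"division_estimate"`: a list with `f_red`,
#'   `f_green` (fractions, not percent), `r0`, `g0`, the implied contact
#'   doublet counts `htb_rr`, `htb_gg`, and `ci_red`, `ci_green` (filled by
#'   [bootstrap_division_ci()], otherwise `NA`).
#' @examples
#' mcx1 <- field_counts(171, 167, 28, 22, 8, "MCX1", "cultured")
#' est <- estimate_division_fractions(mcx1)
#' round(100 * c(est$f_red, est$f_green), 1)  # 16.4, 12.0
#' @export
estimate_division_fractions <- function(counts) {
  stopifnot(inherits(counts, "field_counts"))
  if (counts$n_red <= 0 || counts$n_green <= 0) {
    stop("experiment '", counts$experiment,
         "': both colours must be present", call. = FALSE)
  }
  a <- counts$d_rg / 2
  A <- counts$n_red - counts$d_rr
  B <- counts$n_green - counts$d_gg
  if (A - a <= 0 || B - a <= 0) {
    stop("degenerate counts in experiment '", counts$experiment,
         "': n_red - d_rr - d_rg/2 and n_green - d_gg - d_rg/2 must be ",
         "positive", call. = FALSE)
  }
  t <- (A - a) / (B - a)
  r0 <- A + a * t
  g0 <- B + a / t
  if (r0 <= 0 || g0 <= 0) {
    stop("infeasible solution for experiment '", counts$experiment,
         "': inferred original inputs are not positive", call. = FALSE)
  }
  f_red <- counts$n_red / r0 - 1
  f_green <- counts$n_green / g0 - 1

  # residual check on the two doublet balances
  res_rr <- a * r0 / g0 + f_red * r0 - counts$d_rr
  res_gg <- a * g0 / r0 + f_green * g0 - counts$d_gg
  scale_rr <- max(1, abs(counts$d_rr))
  scale_gg <- max(1, abs(counts$d_gg))
  if (abs(res_rr) / scale_rr > 1e-9 || abs(res_gg) / scale_gg > 1e-9) {
    stop("internal error: closed-form solution does not satisfy the ",
         "doublet balances (residuals ", signif(res_rr, 3), ", ",
         signif(res_gg, 3), ")", call. = FALSE)
  }
  structure(list(f_red = f_red, f_green = f_green, r0 = r0, g0 = g0,
                 htb_rr = a * r0 / g0, htb_gg = a * g0 / r0,
                 ci_red = c(NA_real_, NA_real_),
                 ci_green = c(NA_real_, NA_real_),
                 n_boot = NA_integer_, seed = NA_integer_,
                 experiment = counts$experiment,
                 condition = counts$condition),
            class = "division_estimate")
}

#' @export
print.division_estimate <- function(x, ...) {
  fmt_ci <- function(ci) {
    if (all(is.na(ci))) "" else
      sprintf(" (95%% CI %.1f to %.1f)", 100 * ci[1], 100 * ci[2])
  }
  cat(sprintf("Division fractions [%s, %s]\n",
              if (nzchar(x$experiment)) x$experiment else "unnamed",
              x$condition))
  cat(sprintf("  F_r = %.1f%%%s\n", 100 * x$f_red, fmt_ci(x$ci_red)))
  cat(sprintf("  F_g = %.1f%%%s\n", 100 * x$f_green, fmt_ci(x$ci_green)))
  cat(sprintf("  inferred inputs R0 = %.1f, G0 = %.1f; contact doublets ",
              x$r0, x$g0))
  cat(sprintf("RR %.2f, GG %.2f\n", x$htb_rr, x$htb_gg))
  invisible(x)
}

# Vectorised closed-form estimator used by the bootstrap: takes parallel
# count vectors, returns a matrix with columns f_red, f_green and an
# attribute `ok` marking replicates where the solution exists.
division_fractions_vec <- function(n_red, n_green, d_rr, d_gg, d_rg) {
  a <- d_rg / 2
  A <- n_red - d_rr
  B <- n_green - d_gg
  ok <- (A - a) > 0 & (B - a) > 0
  t <- (A - a) / (B - a)
  r0 <- A + a * t
  g0 <- B + a / t
  ok <- ok & r0 > 0 & g0 > 0 & n_red > 0 & n_green > 0
  out <- cbind(f_red = n_red / r0 - 1, f_green = n_green / g0 - 1)
  out[!ok, ] <- NA_real_
  attr(out, "ok") <- ok
  out
}

#' Percentile-bootstrap confidence intervals for division fractions
#'
#' Resamples the observed field counts, re-estimates the division fractions
#' on each replicate with the closed form of
#' [estimate_division_fractions()], and returns percentile intervals.
#' Two resampling schemes are available:
#'
#' * `"poisson"` (default): each of the five independent field totals
#'   (red singlets, green singlets, and the three doublet classes) is
#'   resampled as a Poisson count around its observed value — the natural
#'   sampling model for object counts accumulated over randomly chosen
#'   microscopic fields.
#' * `"multinomial"`: the doublet class vector is resampled from a
#'   multinomial over the observed doublet total with the observed class
#'   proportions, and the singlet totals from Poissons. This conditions on
#'   the doublet total and yields somewhat narrower intervals.
#'
#' @param counts A [field_counts()] object.
#' @param n_boot Number of bootstrap replicates (at least 100).
#' @param level Interval level, default 0.95.
#' @param seed Integer seed; the result is a pure function of
#'   (`counts`, `n_boot`, `level`, `seed`). If `NULL` a seed is drawn and
#'   recorded in the result.
#' @param scheme Resampling scheme, see Details.
#' @return A list with `ci_red` and `ci_green` (lower/upper bounds as
#'   fractions), `n_ok` (replicates where the estimator existed), `n_boot`,
#'   `level`, `scheme` and `seed`. If the estimator fails on more than 20%
#'   of replicates a warning reports the achieved replicate count.
#' @examples
#' mcx1 <- field_counts(171, 167, 28, 22, 8, "MCX1", "cultured")
#' bootstrap_division_ci(mcx1, n_boot = 1000, seed = 1)$ci_red
#' @export
bootstrap_division_ci <- function(counts, n_boot = 10000, level = 0.95,
                                  seed = NULL,
                                  scheme = c("poisson", "multinomial")) {
  stopifnot(inherits(counts, "field_counts"),
            is.numeric(n_boot), n_boot >= 100,
            is.numeric(level), level > 0, level < 1)
  scheme <- match.arg(scheme)
  t_doublets <- total_doublets(counts)
  if (t_doublets < 1) {
    stop("no doublets in experiment '", counts$experiment,
         "': division fractions cannot be resampled", call. = FALSE)
  }
  # fail fast if the point estimate itself is degenerate
  estimate_division_fractions(counts)
  seed <- seed %||% draw_seed()
  n_boot <- as.integer(n_boot)
  s <- singlet_counts(counts)

  f <- with_seed(seed, {
    if (scheme == "multinomial") {
      d <- stats::rmultinom(n_boot, t_doublets,
                            c(counts$d_rr, counts$d_gg, counts$d_rg) /
                              t_doublets)
      d_rr <- d[1, ]; d_gg <- d[2, ]; d_rg <- d[3, ]
    } else {
      d_rr <- stats::rpois(n_boot, counts$d_rr)
      d_gg <- stats::rpois(n_boot, counts$d_gg)
      d_rg <- stats::rpois(n_boot, counts$d_rg)
    }
    s_r <- stats::rpois(n_boot, s[["s_r"]])
    s_g <- stats::rpois(n_boot, s[["s_g"]])
    division_fractions_vec(s_r + 2 * d_rr + d_rg, s_g + 2 * d_gg + d_rg,
                           d_rr, d_gg, d_rg)
  })
  ok <- attr(f, "ok")
  n_ok <- sum(ok)
  if (n_ok < 0.8 * n_boot) {
    warning("division estimator failed on ", n_boot - n_ok, " of ", n_boot,
            " bootstrap replicates for experiment '", counts$experiment,
            "'; intervals use the ", n_ok, " achieved replicates",
            call. = FALSE)
  }
  if (n_ok < 2) {
    stop("too few valid bootstrap replicates (", n_ok, ") for experiment '",
         counts$experiment, "'", call. = FALSE)
  }
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  list(ci_red = unname(stats::quantile(f[ok, "f_red"], probs)),
       ci_green = unname(stats::quantile(f[ok, "f_green"], probs)),
       n_ok = n_ok, n_boot = n_boot, level = level, scheme = scheme,
       seed = seed)
}

#' Full analysis of one two-colour counting experiment
#'
#' Bundles the three statistics computed from one set of field counts: the
#' observed and expected doublet class percentages, the lower-tail
#' probability of the red-green doublet count under the no-division null,
#' and the division fractions with bootstrap confidence intervals.
#'
#' @inheritParams bootstrap_division_ci
#' @param method Tail-test method passed to [doublet_null_test()].
#' @param ci If `FALSE`, skip the bootstrap (the CI fields are `NA`).
#' @return An object of class `"doublet_analysis"`: a list with
#'   `experiment`, `condition`, `counts`, `t_doublets`, `observed_pct` and
#'   `expected_pct` (named RR/RG/GG percentages), `p_le`, `f_red_pct`,
#'   `f_green_pct`, `ci_red_pct`, `ci_green_pct`, `r0`, `g0`, `n_boot`,
#'   `seed`.
#' @examples
#' mcx1 <- field_counts(171, 167, 28, 22, 8, "MCX1", "cultured")
#' analyze_experiment(mcx1, n_boot = 1000, seed = 1)
#' @export
analyze_experiment <- function(counts, n_boot = 10000, level = 0.95,
                               seed = NULL, method = "normal_approx",
                               ci = TRUE) {
  stopifnot(inherits(counts, "field_counts"))
  test <- doublet_null_test(counts, method = method)
  est <- estimate_division_fractions(counts)
  if (ci) {
    seed <- seed %||% draw_seed()
    boot <- bootstrap_division_ci(counts, n_boot = n_boot, level = level,
                                  seed = seed)
    est$ci_red <- boot$ci_red
    est$ci_green <- boot$ci_green
    est$n_boot <- boot$n_boot
    est$seed <- boot$seed
  }
  structure(
    list(experiment = counts$experiment, condition = counts$condition,
         counts = counts, t_doublets = test$t_doublets,
         observed_pct = 100 * test$observed_fracs,
         expected_pct = 100 * c(rr = test$expected$p_rr,
                                rg = test$expected$p_rg,
                                gg = test$expected$p_gg),
         p_le = test$p_le,
         f_red_pct = 100 * est$f_red, f_green_pct = 100 * est$f_green,
         ci_red_pct = 100 * est$ci_red, ci_green_pct = 100 * est$ci_green,
         r0 = est$r0, g0 = est$g0,
         n_boot = est$n_boot, seed = est$seed, level = level,
         method = method),
    class = "doublet_analysis"
  )
}

#' @export
print.doublet_analysis <- function(x, ...) {
  cat(sprintf("Experiment %s (%s): %d doublets\n",
              if (nzchar(x$experiment)) x$experiment else "unnamed",
              x$condition, x$t_doublets))
  cat(sprintf("  doublet %% RR/RG/GG observed: %.1f / %.1f / %.1f\n",
              x$observed_pct[["rr"]], x$observed_pct[["rg"]],
              x$observed_pct[["gg"]]))
  cat(sprintf("               expected: %.1f / %.1f / %.1f\n",
              x$expected_pct[["rr"]], x$expected_pct[["rg"]],
              x$expected_pct[["gg"]]))
  cat(sprintf("  P(RG <= observed) = %s\n", format(signif(x$p_le, 3))))
  fmt_ci <- function(ci) if (all(is.na(ci))) "" else
    sprintf(" (%.1f to %.1f)", ci[1], ci[2])
  cat(sprintf("  F_r = %.1f%%%s, F_g = %.1f%%%s\n",
              x$f_red_pct, fmt_ci(x$ci_red_pct),
              x$f_green_pct, fmt_ci(x$ci_green_pct)))
  invisible(x)
}

#' Analyse a table of counting experiments
#'
#' Runs [analyze_experiment()] on every row of a counts table and collects
#' the results into a flat `data.frame` mirroring the published layout:
#' observed and expected doublet percentages, tail-test probability, and
#' division fractions with confidence intervals, one row per
#' experiment/condition.
#'
#' @param counts A counts `data.frame` ([read_counts_csv()] schema) or a
#'   path to a counts CSV.
#' @inheritParams analyze_experiment
#' @return A `data.frame` with one row per experiment/condition.
#' @examples
#' analyze_counts(semisolid_culture_counts(), n_boot = 500, seed = 1)
#' @export
analyze_counts <- function(counts, n_boot = 10000, level = 0.95,
                           seed = NULL, method = "normal_approx",
                           ci = TRUE) {
  if (is.character(counts)) counts <- read_counts_csv(counts)
  stopifnot(is.data.frame(counts), nrow(counts) >= 1)
  seed <- seed %||% draw_seed()
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    fc <- as_field_counts(counts[i, ])
    # per-row sub-seed keeps rows independent yet reproducible
    a <- analyze_experiment(fc, n_boot = n_boot, level = level,
                            seed = (seed + i - 1) %% .Machine$integer.max,
                            method = method, ci = ci)
    data.frame(
      experiment = a$experiment, condition = a$condition,
      n_red = fc$n_red, n_green = fc$n_green,
      d_rr = fc$d_rr, d_gg = fc$d_gg, d_rg = fc$d_rg,
      t_doublets = a$t_doublets,
      obs_rr_pct = a$observed_pct[["rr"]],
      obs_rg_pct = a$observed_pct[["rg"]],
      obs_gg_pct = a$observed_pct[["gg"]],
      exp_rr_pct = a$expected_pct[["rr"]],
      exp_rg_pct = a$expected_pct[["rg"]],
      exp_gg_pct = a$expected_pct[["gg"]],
      p_le = a$p_le,
      f_red_pct = a$f_red_pct, f_green_pct = a$f_green_pct,
      ci_red_lo_pct = a$ci_red_pct[1], ci_red_hi_pct = a$ci_red_pct[2],
      ci_green_lo_pct = a$ci_green_pct[1],
      ci_green_hi_pct = a$ci_green_pct[2],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "seed") <- seed
  out
}
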