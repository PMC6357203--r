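#' Generative parameters for a synthetic semisolid-culture experiment
#'
#' Defines the ground truth of a simulated two-colour mixing experiment:
#' how many red and green platelets are seeded into the surveyed fields
#' (`r0`, `g0`), how many incidental-contact ("happen-to-be") doublet pairs
#' form while the platelet/medium mixture is dispensed (`n_contact_pairs`),
#' and which fraction of each colour divides during culture (`f_red`,
#' `f_green`), each division leaving a same-colour doublet in place.
#'
#' Three fidelities are available:
#' * `"expectation"` — deterministic real-valued counts equal to their
#'   expectations; the division estimator recovers `f_red`, `f_green`
#'   exactly, which makes this mode the algebraic fixed point used in
#'   round-trip tests.
#' * `"sampling"` — contact pairs drawn multinomially from the binomial
#'   colour pattern and consumed without replacement; every remaining
#'   non-contacted platelet divides independently with its colour's
#'   probability. Contacted platelets do not divide, so the generative
#'   model coincides with the estimator's assumptions.
#' * `"spatial"` — platelets placed uniformly (with a hard-core minimum
#'   separation, since platelets are solid bodies) over `n_fields`
#'   rectangular fields; a dividing platelet places its progeny at
#'   `division_offset`; clusters are formed by single-link grouping at
#'   `contact_distance` and clusters of three or more platelets are
#'   excluded from the counts, as in the microscopy protocol. Contact
#'   doublets arise here from density, not from `n_contact_pairs`.
#'
#' The defaults mirror the published experiments: roughly 165 platelets of
#' each colour over ten 100 x 100 um fields, around 25 contact pairs, and a
#' 12% division fraction per colour (the observed six-hour fractions ranged
#' from about 9 to 17%).
#'
#' @param r0,g0 Original platelet inputs per colour (positive integers).
#' @param n_contact_pairs Happen-to-be doublet budget `H`
#'   (`2 * H <= r0 + g0`). Ignored by the spatial mode.
#' @param f_red,f_green Division probabilities in `[0, 1]`.
#' @param mode Simulation fidelity, see Details.
#' @param field_width,field_height Field size in micrometres.
#' @param n_fields Number of surveyed fields.
#' @param contact_distance Centre-to-centre distance (um) below which two
#'   platelets count as touching.
#' @param division_offset Centre-to-centre distance (um) between a platelet
#'   and its progeny; must be below `contact_distance`.
#' @param min_separation Hard-core minimum centre distance (um) between
#'   independently placed platelets (spatial mode).
#' @param seed Integer seed; `NULL` lets [simulate_counts()] draw and
#'   record one.
#' @return An object of class `"simulation_truth"`.
#' @examples
#' truth <- simulation_truth(r0 = 1000, g0 = 1000, n_contact_pairs = 100,
#'                           f_red = 0.15, f_green = 0.10,
#'                           mode = "expectation")
#' simulate_counts(truth)$counts
#' @export
simulation_truth <- function(r0 = 165, g0 = 165, n_contact_pairs = 25,
                             f_red = 0.12, f_green = 0.12,
                             mode = c("expectation", "sampling", "spatial"),
                             field_width = 100, field_height = 100,
                             n_fields = 10, contact_distance = 3,
                             division_offset = 2.2, min_separation = 2,
                             seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(is_count(r0), is_count(g0), r0 + g0 > 0,
            is_count(n_contact_pairs),
            is.numeric(f_red), f_red >= 0, f_red <= 1,
            is.numeric(f_green), f_green >= 0, f_green <= 1,
            field_width > 0, field_height > 0, is_count(n_fields),
            n_fields >= 1, contact_distance > 0, min_separation >= 0)
  if (2 * n_contact_pairs > r0 + g0) {
    stop("infeasible contact budget: 2 * n_contact_pairs exceeds the ",
         "number of platelets", call. = FALSE)
  }
  if (division_offset >= contact_distance) {
    stop("division_offset must be smaller than contact_distance, ",
         "otherwise progeny would not register as doublets", call. = FALSE)
  }
  structure(list(r0 = r0, g0 = g0, n_contact_pairs = n_contact_pairs,
                 f_red = f_red, f_green = f_green, mode = mode,
                 field_width = field_width, field_height = field_height,
                 n_fields = n_fields, contact_distance = contact_distance,
                 division_offset = division_offset,
                 min_separation = min_separation, seed = seed),
            class = "simulation_truth")
}

#' True division fractions implied by simulation parameters
#'
#' Returns the estimand of [estimate_division_fractions()] under a given
#' [simulation_truth()] — the expected fraction of originally seeded
#' platelets of each colour that divide. In expectation mode this is
#' (`f_red`, `f_green`) exactly. In sampling mode contacted platelets are
#' barred from dividing, so the expected divided fraction of colour red is
#' `f_red * (r0 - 2 H r) / r0` with `r = r0 / (r0 + g0)` (symmetrically
#' for green): the division probability applies only to the expected
#' non-contacted platelets. In spatial mode every platelet may divide and
#' the estimand is (`f_red`, `f_green`), though multiplet exclusion biases
#' the estimator slightly at high density.
#'
#' @param truth A [simulation_truth()] object.
#' @return Named numeric vector `c(f_red, f_green)`.
#' @examples
#' true_division_fractions(
#'   simulation_truth(5000, 5000, 200, 0.12, 0.12, "sampling"))
#' @export
true_division_fractions <- function(truth) {
  stopifnot(inherits(truth, "simulation_truth"))
  if (truth$mode == "sampling") {
    r <- truth$r0 / (truth$r0 + truth$g0)
    g <- 1 - r
    H <- truth$n_contact_pairs
    c(f_red = truth$f_red * (truth$r0 - 2 * H * r) / truth$r0,
      f_green = truth$f_green * (truth$g0 - 2 * H * g) / truth$g0)
  } else {
    c(f_red = truth$f_red, f_green = truth$f_green)
  }
}

#' Simulate a two-colour semisolid-culture experiment
#'
#' Generates the observable field counts (and, in spatial mode, the full
#' per-platelet ground truth) implied by a [simulation_truth()].
#'
#' @param truth A [simulation_truth()] object.
#' @param round_counts In expectation mode, round the real-valued counts to
#'   integers (default `FALSE`).
#' @return An object of class `"doublet_simulation"`: a list with
#'   * `counts` — a [field_counts()] object;
#'   * `truth` — the generating parameters, with the realised seed filled
#'     in;
#'   * `n_divisions` — total divisions (`NA` in expectation mode, where the
#'     expected value is real);
#'   * `ground_truth` — spatial mode only: a `data.frame` with one row per
#'     rendered platelet (`field`, `x`, `y` in um with the origin at the
#'     top-left corner and y pointing down, `channel`, `cluster_id`,
#'     `class` one of singlet/htb_doublet/division_doublet/multiplet);
#'   * `n_excluded` — spatial mode: platelets dropped as multiplet members.
#' @examples
#' truth <- simulation_truth(mode = "sampling", seed = 7)
#' simulate_counts(truth)$counts
#' @export
simulate_counts <- function(truth, round_counts = FALSE) {
  stopifnot(inherits(truth, "simulation_truth"))
  switch(truth$mode,
         expectation = simulate_counts_expectation(truth, round_counts),
         sampling = simulate_counts_sampling(truth),
         spatial = simulate_counts_spatial(truth))
}

simulate_counts_expectation <- function(truth, round_counts) {
  r <- truth$r0 / (truth$r0 + truth$g0)
  g <- 1 - r
  H <- truth$n_contact_pairs
  d_rr <- H * r^2 + truth$f_red * truth$r0
  d_rg <- H * 2 * r * g
  d_gg <- H * g^2 + truth$f_green * truth$g0
  n_red <- truth$r0 * (1 + truth$f_red)
  n_green <- truth$g0 * (1 + truth$f_green)
  if (round_counts) {
    d_rr <- round(d_rr); d_rg <- round(d_rg); d_gg <- round(d_gg)
    n_red <- round(n_red); n_green <- round(n_green)
  }
  counts <- field_counts(n_red, n_green, d_rr, d_gg, d_rg,
                         experiment = "simulated", condition = "cultured",
                         integer_counts = round_counts)
  structure(list(counts = counts, truth = truth, n_divisions = NA_real_,
                 ground_truth = NULL, n_excluded = 0L),
            class = "doublet_simulation")
}

simulate_counts_sampling <- function(truth) {
  seed <- truth$seed %||% draw_seed()
  truth$seed <- seed
  r0 <- truth$r0; g0 <- truth$g0
  H <- truth$n_contact_pairs
  r <- r0 / (r0 + g0)
  g <- 1 - r
  with_seed(seed, {
    cls <- if (H > 0) {
      drop(stats::rmultinom(1, H, c(r^2, 2 * r * g, g^2)))
    } else {
      c(0L, 0L, 0L)
    }
    h_rr <- cls[1]; h_rg <- cls[2]; h_gg <- cls[3]
    red_used <- 2 * h_rr + h_rg
    green_used <- 2 * h_gg + h_rg
    if (red_used > r0 || green_used > g0) {
      stop("contact draw consumed more platelets of one colour than ",
           "seeded; lower n_contact_pairs relative to r0/g0", call. = FALSE)
    }
    div_red <- stats::rbinom(1, r0 - red_used, truth$f_red)
    div_green <- stats::rbinom(1, g0 - green_used, truth$f_green)
    counts <- field_counts(r0 + div_red, g0 + div_green,
                           d_rr = h_rr + div_red, d_gg = h_gg + div_green,
                           d_rg = h_rg,
                           experiment = "simulated", condition = "cultured")
    structure(list(counts = counts, truth = truth,
                   n_divisions = div_red + div_green,
                   ground_truth = NULL, n_excluded = 0L),
              class = "doublet_simulation")
  })
}

# Place n points uniformly in a field with a hard-core minimum separation
# by dart throwing. Returns an n x 2 matrix.
place_hardcore <- function(n, width, height, min_sep, max_tries = 200) {
  pts <- matrix(NA_real_, n, 2)
  if (n == 0) return(pts)
  min_sep2 <- min_sep^2
  k <- 0L
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      p <- c(stats::runif(1, 0, width), stats::runif(1, 0, height))
      if (k == 0L ||
          min((pts[seq_len(k), 1] - p[1])^2 +
              (pts[seq_len(k), 2] - p[2])^2) >= min_sep2) {
        k <- k + 1L
        pts[k, ] <- p
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("could not place ", n, " platelets with a ", min_sep,
           " um minimum separation in a ", width, " x ", height,
           " um field; lower the density", call. = FALSE)
    }
  }
  pts
}

# Single-link clustering by union-find on pairwise distances <= threshold.
# Returns integer cluster labels (1-based, arbitrary order).
single_link_clusters <- function(x, y, threshold) {
  n <- length(x)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (n > 1 && threshold >= 0) {
    thr2 <- threshold^2
    for (i in seq_len(n - 1L)) {
      d2 <- (x[(i + 1L):n] - x[i])^2 + (y[(i + 1L):n] - y[i])^2
      for (j in which(d2 <= thr2)) {
        ri <- find(i); rj <- find(i + j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

simulate_counts_spatial <- function(truth) {
  seed <- truth$seed %||% draw_seed()
  truth$seed <- seed
  with_seed(seed, {
    n0 <- truth$r0 + truth$g0
    if (n0 == 0) stop("zero platelets to place", call. = FALSE)
    field_of <- sample.int(truth$n_fields, n0, replace = TRUE)
    channel <- rep(c("red", "green"), c(truth$r0, truth$g0))
    rows <- vector("list", truth$n_fields)
    for (fld in seq_len(truth$n_fields)) {
      idx <- which(field_of == fld)
      pts <- place_hardcore(length(idx), truth$field_width,
                            truth$field_height, truth$min_separation)
      parent_id <- seq_along(idx)
      df <- data.frame(field = fld, x = pts[, 1], y = pts[, 2],
                       channel = channel[idx], parent = parent_id,
                       is_progeny = FALSE, stringsAsFactors = FALSE)
      # divisions: progeny placed at division_offset, pushed inside bounds
      p_div <- ifelse(df$channel == "red", truth$f_red, truth$f_green)
      divides <- stats::runif(nrow(df)) < p_div
      if (any(divides)) {
        prog <- df[divides, ]
        for (i in seq_len(nrow(prog))) {
          repeat {
            ang <- stats::runif(1, 0, 2 * pi)
            nx <- prog$x[i] + truth$division_offset * cos(ang)
            ny <- prog$y[i] + truth$division_offset * sin(ang)
            if (nx >= 0 && nx <= truth$field_width &&
                ny >= 0 && ny <= truth$field_height) {
              prog$x[i] <- nx; prog$y[i] <- ny
              break
            }
          }
        }
        prog$is_progeny <- TRUE
        df <- rbind(df, prog)
      }
      df$cluster_local <- single_link_clusters(df$x, df$y,
                                               truth$contact_distance)
      rows[[fld]] <- df
    }
    gt <- do.call(rbind, rows)
    gt$cluster_id <- as.integer(interaction(gt$field, gt$cluster_local,
                                            drop = TRUE))
    gt$cluster_local <- NULL

    # classify clusters
    size <- table(gt$cluster_id)
    gt$size <- as.integer(size[as.character(gt$cluster_id)])
    gt$class <- ifelse(gt$size >= 3, "multiplet",
                       ifelse(gt$size == 1, "singlet", "htb_doublet"))
    # a size-2 cluster is a division doublet iff it is a parent-progeny pair
    two <- gt$size == 2
    if (any(two)) {
      for (cid in unique(gt$cluster_id[two])) {
        m <- gt$cluster_id == cid
        if (sum(m) == 2 && length(unique(gt$parent[m])) == 1 &&
            length(unique(gt$field[m])) == 1 && any(gt$is_progeny[m])) {
          gt$class[m] <- "division_doublet"
        }
      }
    }

    kept <- gt[gt$class != "multiplet", ]
    n_red <- sum(kept$channel == "red")
    n_green <- sum(kept$channel == "green")
    pair_combo <- function(m) paste(sort(kept$channel[m]), collapse = "-")
    d_rr <- d_gg <- d_rg <- 0L
    for (cid in unique(kept$cluster_id[kept$size == 2])) {
      m <- kept$cluster_id == cid
      combo <- pair_combo(m)
      if (combo == "red-red") d_rr <- d_rr + 1L
      else if (combo == "green-green") d_gg <- d_gg + 1L
      else d_rg <- d_rg + 1L
    }
    counts <- field_counts(n_red, n_green, d_rr, d_gg, d_rg,
                           experiment = "simulated", condition = "cultured")
    gt_out <- gt[, c("field", "x", "y", "channel", "cluster_id", "class")]
    attr(gt_out, "field_width") <- truth$field_width
    attr(gt_out, "field_height") <- truth$field_height
    attr(gt_out, "n_fields") <- truth$n_fields
    structure(list(counts = counts, truth = truth,
                   n_divisions = sum(gt$is_progeny),
                   ground_truth = gt_out,
                   n_excluded = sum(gt$class == "multiplet")),
              class = "doublet_simulation")
  })
}

#' @export
print.doublet_simulation <- function(x, ...) {
  cat(sprintf("Simulated semisolid culture (%s mode, seed %s)\n",
              x$truth$mode, format(x$truth$seed)))
  print(x$counts)
  if (!is.null(x$ground_truth)) {
    cat(sprintf("  ground truth: %d platelets over %d field(s), %d excluded as multiplet members\n",
                nrow(x$ground_truth), x$truth$n_fields, x$n_excluded))
  }
  invisible(x)
}

#' Simulate a dye-dilution event list
#'
#' Emulates the CFSE dilution assay: platelets are sorted through a narrow
#' fluorescence gate, cultured, and re-analysed. Generation-0 events carry
#' log-normal intensities truncated to the sort gate; a platelet that
#' divides is replaced by two events at half the parent intensity, each
#' multiplied by a log-normal factor with unit mean and coefficient of
#' variation `intensity_cv`. A fraction `leak_fraction` of events is
#' re-drawn below the gate, emulating the small "divided" percentages seen
#' immediately after sorting.
#'
#' Since one division replaces one event by two, a platelet division
#' fraction `q` yields an expected divided-event fraction `2q / (1 + q)`.
#'
#' @param n_platelets Number of sorted platelets.
#' @param divided_fraction Fraction `q` of platelets that divide.
#' @param gate_center Centre of the sort gate in log10 intensity units.
#' @param gate_width Full width of the sort gate in log10 units (> 0).
#' @param intensity_cv Coefficient of variation of the per-event intensity
#'   factor.
#' @param leak_fraction Fraction of events re-drawn below the gate.
#' @param seed Integer seed (`NULL` draws and records one).
#' @return An object of class `"dilution_events"`: a `data.frame` with
#'   columns `event_id`, `intensity`, `generation` (0 or 1) and `leaked`,
#'   with attributes `gate` (low/high linear intensity bounds), `seed`,
#'   `n_platelets` and `divided_fraction`.
#' @examples
#' ev <- simulate_dilution_events(5000, 0.3, seed = 1)
#' estimate_divided_fraction(ev)
#' @export
simulate_dilution_events <- function(n_platelets, divided_fraction,
                                     gate_center = 3, gate_width = 0.1,
                                     intensity_cv = 0.05,
                                     leak_fraction = 0, seed = NULL) {
  stopifnot(is_count(n_platelets), n_platelets >= 1,
            is.numeric(divided_fraction),
            divided_fraction >= 0, divided_fraction <= 1,
            is.numeric(leak_fraction),
            leak_fraction >= 0, leak_fraction <= 1,
            is.numeric(intensity_cv), intensity_cv >= 0)
  if (gate_width <= 0) stop("gate_width must be positive", call. = FALSE)
  seed <- seed %||% draw_seed()
  gate <- c(low = 10^(gate_center - gate_width / 2),
            high = 10^(gate_center + gate_width / 2))
  with_seed(seed, {
    # log10 intensity ~ Normal(centre, gate_width) truncated to the gate
    lo <- gate_center - gate_width / 2
    hi <- gate_center + gate_width / 2
    u <- stats::runif(n_platelets,
                      stats::pnorm(lo, gate_center, gate_width),
                      stats::pnorm(hi, gate_center, gate_width))
    parent <- 10^stats::qnorm(u, gate_center, gate_width)
    divides <- stats::runif(n_platelets) < divided_fraction
    sdlog <- sqrt(log(1 + intensity_cv^2))
    jitter <- function(n) stats::rlnorm(n, -sdlog^2 / 2, sdlog)
    gen0 <- parent[!divides] * jitter(sum(!divides))
    kids <- rep(parent[divides] / 2, each = 2) *
      jitter(2 * sum(divides))
    intensity <- c(gen0, kids)
    generation <- rep(c(0L, 1L), c(length(gen0), length(kids)))
    leaked <- stats::runif(length(intensity)) < leak_fraction
    if (any(leaked)) {
      # leaked events read below the gate, in the half-intensity region
      intensity[leaked] <- 10^stats::runif(sum(leaked),
                                           lo - 2 * log10(2),
                                           lo - 0.5 * log10(2))
    }
    out <- data.frame(event_id = seq_along(intensity),
                      intensity = intensity,
                      generation = generation, leaked = leaked)
    structure(out, gate = gate, seed = seed, n_platelets = n_platelets,
              divided_fraction = divided_fraction,
              class = c("dilution_events", "data.frame"))
  })
}
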