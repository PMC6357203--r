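#' Estimate the divided fraction from a dye-dilution event list
#'
#' In a CFSE dilution assay the tracking dye halves at each division, so
#' events from divided platelets form a discrete cluster one log2 unit
#' below the undivided (generation-0) cluster. This function locates the
#' generation-0 mode on the log2 intensity axis as the highest-intensity
#' peak of a kernel-smoothed density, places a class boundary, and reports
#' the fraction of events below it.
#'
#' Two boundary rules are available: `"valley"` (default) takes the deepest
#' density minimum in the one-log2-unit interval below the generation-0
#' mode; `"half_dilution"` places the boundary exactly half a log2 unit
#' below the mode. When the density has no interior minimum in that
#' interval (effectively unimodal data), the valley method falls back to
#' the half-dilution boundary with a warning.
#'
#' Because one division replaces one event by two, the divided *event*
#' fraction `e` and the divided *platelet* fraction `q` are linked by
#' `e = 2q / (1 + q)`, i.e. `q = e / (2 - e)`; both are reported.
#'
#' @param events A `"dilution_events"` object ([simulate_dilution_events()]
#'   or [read_dilution_events()]), or a numeric vector of intensities.
#'   At least 200 events are required.
#' @param method `"valley"` or `"half_dilution"`.
#' @param min_peak_frac A density local maximum must reach this fraction of
#'   the global density maximum to count as a mode (guards against noise
#'   ripples).
#' @return An object of class `"dilution_estimate"`: a list with
#'   `percent_divided_events`, `percent_divided_platelets`, `gen0_mode` and
#'   `boundary` (linear intensity units), their log2 counterparts, `method`
#'   (the method actually used) and `n_events`.
#' @examples
#' ev <- simulate_dilution_events(20000, 0.3, seed = 1)
#' estimate_divided_fraction(ev)
#' @export
estimate_divided_fraction <- function(events,
                                      method = c("valley", "half_dilution"),
                                      min_peak_frac = 0.05) {
  method <- match.arg(method)
  intensity <- if (is.numeric(events)) events else events$intensity
  if (length(intensity) < 200) {
    stop("at least 200 events are required (got ", length(intensity), ")",
         call. = FALSE)
  }
  if (any(intensity <= 0)) {
    stop("intensities must be positive", call. = FALSE)
  }
  x <- log2(intensity)
  d <- stats::density(x)
  y <- d$y
  n <- length(y)
  peaks <- which(y > c(-Inf, y[-n]) & y > c(y[-1], Inf) &
                   y >= min_peak_frac * max(y))
  if (!length(peaks)) stop("no density mode found", call. = FALSE)
  gen0_log2 <- d$x[peaks[length(peaks)]]

  used <- method
  boundary_log2 <- NA_real_
  if (method == "valley") {
    inside <- which(d$x > gen0_log2 - 1 & d$x < gen0_log2)
    mins <- which(y < c(Inf, y[-n]) & y < c(y[-1], Inf))
    # a genuine inter-generation valley separates two modes: without a
    # second mode below generation 0 the data are unimodal and tail-edge
    # minima of the density grid are not valleys
    peak_y <- y[peaks[length(peaks)]]
    mins <- intersect(mins, inside)
    mins <- mins[y[mins] <= 0.5 * peak_y]
    if (length(peaks) < 2) mins <- integer(0)
    if (length(mins)) {
      boundary_log2 <- d$x[mins[which.min(y[mins])]]
    } else {
      warning("no interior density minimum below the generation-0 mode; ",
              "falling back to the half-dilution boundary", call. = FALSE)
      used <- "half_dilution"
    }
  }
  if (used == "half_dilution") boundary_log2 <- gen0_log2 - 0.5

  e <- mean(x < boundary_log2)
  q <- e / (2 - e)
  structure(list(percent_divided_events = 100 * e,
                 percent_divided_platelets = 100 * q,
                 gen0_mode = 2^gen0_log2, boundary = 2^boundary_log2,
                 gen0_mode_log2 = gen0_log2, boundary_log2 = boundary_log2,
                 method = used, n_events = length(intensity)),
            class = "dilution_estimate")
}

#' @export
print.dilution_estimate <- function(x, ...) {
  cat(sprintf("Dye-dilution estimate (%s boundary, %d events)\n",
              x$method, x$n_events))
  cat(sprintf("  divided events:    %.1f%%\n", x$percent_divided_events))
  cat(sprintf("  divided platelets: %.1f%%\n",
              x$percent_divided_platelets))
  cat(sprintf("  generation-0 mode at %.3g, boundary at %.3g (a.u.)\n",
              x$gen0_mode, x$boundary))
  invisible(x)
}

#' @export
plot.dilution_estimate <- function(x, events = NULL, ...) {
  if (!is.null(events)) {
    intensity <- if (is.numeric(events)) events else events$intensity
    graphics::hist(log2(intensity), breaks = 100, freq = FALSE,
                   main = "Dye-dilution intensity distribution",
                   xlab = "log2 intensity (a.u.)", ...)
  }
  graphics::abline(v = x$gen0_mode_log2, col = "forestgreen", lwd = 2)
  graphics::abline(v = x$boundary_log2, col = "firebrick", lty = 2,
                   lwd = 2)
  invisible(x)
}

#' Read and write dye-dilution event lists
#'
#' The event CSV has the header `event_id,intensity[,generation]`;
#' intensities are arbitrary positive fluorescence units.
#'
#' @param path Path to an event CSV.
#' @return `read_dilution_events()` returns a `"dilution_events"`
#'   `data.frame`.
#' @export
read_dilution_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("event_id", "intensity") %in% names(df))) {
    stop("event file '", path,
         "' must have columns event_id and intensity", call. = FALSE)
  }
  if (any(df$intensity <= 0)) {
    stop("event file '", path, "' contains non-positive intensities",
         call. = FALSE)
  }
  class(df) <- c("dilution_events", "data.frame")
  df
}

#' @rdname read_dilution_events
#' @param events A `"dilution_events"` object.
#' @export
write_dilution_events <- function(events, path) {
  cols <- intersect(c("event_id", "intensity", "generation"),
                    names(events))
  utils::write.csv(as.data.frame(events)[cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Group summaries of per-experiment division percentages
#'
#' Summarises division percentages (one value per experiment) by group —
#' typically time point crossed with labelling strength — as arithmetic
#' mean and sample standard deviation (n - 1 denominator), the format in
#' which dye-dilution experiment series are conventionally reported.
#'
#' @param data A `data.frame` with one row per experiment.
#' @param value Name of the numeric column to summarise.
#' @param by Character vector of grouping columns.
#' @return A `data.frame` with the grouping columns plus `n`, `mean`, `sd`.
#'   Groups with fewer than two values are an error.
#' @examples
#' tab <- cfse_division_percentages()
#' summarize_division_table(tab)
#' @export
summarize_division_table <- function(data, value = "percent_divided",
                                     by = c("timepoint", "mfi")) {
  stopifnot(is.data.frame(data), value %in% names(data),
            all(by %in% names(data)))
  groups <- split(data[[value]], data[by], drop = TRUE)
  if (!length(groups)) stop("no groups to summarise", call. = FALSE)
  small <- names(groups)[vapply(groups, length, integer(1)) < 2]
  if (length(small)) {
    stop("group(s) with fewer than two values: ",
         paste(small, collapse = ", "), call. = FALSE)
  }
  keys <- do.call(rbind, strsplit(names(groups), ".", fixed = TRUE))
  out <- data.frame(keys, stringsAsFactors = FALSE)
  names(out) <- by
  out$n <- vapply(groups, length, integer(1))
  out$mean <- vapply(groups, mean, numeric(1))
  out$sd <- vapply(groups, stats::sd, numeric(1))
  rownames(out) <- NULL
  out
}

#' Packaged per-experiment CFSE division percentages
#'
#' The published dye-dilution series: the percentage of platelets scored as
#' divided (reduced CFSE fluorescence) for each sorted preparation, by time
#' point (initial, six hours, twenty hours of culture) and labelling
#' strength (high/low mean fluorescence intensity of the sort gate).
#'
#' @return A `data.frame` with columns `sort`, `timepoint`, `mfi`,
#'   `percent_divided`.
#' @examples
#' summarize_division_table(cfse_division_percentages())
#' @export
cfse_division_percentages <- function() {
  utils::read.csv(system.file("extdata", "cfse_division.csv",
                              package = "plateletdiv", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Two-sample comparison of division percentages between groups
#'
#' Convenience wrapper comparing division percentages between two groups
#' (e.g. strongly vs weakly labelled preparations) with a configurable
#' two-sample test. Provided for completeness; the choice of test is the
#' caller's.
#'
#' @param x,y Numeric vectors of per-experiment percentages.
#' @param test `"t"` (Welch), `"paired_t"` or `"wilcoxon"`.
#' @return The corresponding `htest` object.
#' @export
compare_division_groups <- function(x, y,
                                    test = c("t", "paired_t", "wilcoxon")) {
  test <- match.arg(test)
  switch(test,
         t = stats::t.test(x, y),
         paired_t = stats::t.test(x, y, paired = TRUE),
         wilcoxon = stats::wilcox.test(x, y))
}
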