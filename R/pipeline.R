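#' Analyse a counts CSV and write a JSON report
#'
#' End-to-end wrapper around [analyze_counts()]: reads and validates a
#' counts CSV, analyses every experiment/condition row, optionally writes a
#' JSON report (one record per row, all fields of [analyze_experiment()]),
#' and returns the result table. Identical inputs and seed give
#' byte-identical reports; no timestamps enter the JSON.
#'
#' @param input Path to a counts CSV ([read_counts_csv()] schema) or a
#'   counts `data.frame`.
#' @param output_json Optional path for the JSON report.
#' @inheritParams analyze_counts
#' @return The [analyze_counts()] `data.frame`, invisibly when
#'   `output_json` is given.
#' @examples
#' res <- analyze_counts_file(semisolid_culture_counts(),
#'                            n_boot = 500, seed = 1)
#' res[res$experiment == "MCX1", c("condition", "f_red_pct", "p_le")]
#' @export
analyze_counts_file <- function(input, output_json = NULL, n_boot = 10000,
                                level = 0.95, seed = NULL,
                                method = "normal_approx", ci = TRUE) {
  res <- analyze_counts(input, n_boot = n_boot, level = level, seed = seed,
                        method = method, ci = ci)
  if (!is.null(output_json)) {
    records <- lapply(seq_len(nrow(res)), function(i) as.list(res[i, ]))
    jsonlite::write_json(
      list(seed = attr(res, "seed"), n_boot = n_boot, level = level,
           method = method, results = records),
      output_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(res))
  }
  res
}

#' Simulate an experiment and write its outputs to disk
#'
#' Convenience wrapper tying the simulator to the file formats of the
#' pipeline: runs [simulate_counts()], writes the counts CSV, and in
#' spatial mode optionally renders and writes the two-channel field images
#' plus the ground-truth CSV.
#'
#' @param truth A [simulation_truth()] object.
#' @param dir Output directory (created if missing).
#' @param render Render field images (spatial mode only).
#' @param format Image format for [write_field_images()].
#' @param ... Passed to [render_fields()].
#' @return Invisibly, the [simulate_counts()] result with an added
#'   `paths` element.
#' @export
simulate_to_files <- function(truth, dir, render = FALSE,
                              format = "tiff", ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_counts(truth)
  counts_path <- file.path(dir, "counts.csv")
  cdf <- data.frame(experiment = sim$counts$experiment,
                    condition = sim$counts$condition,
                    n_red = sim$counts$n_red, n_green = sim$counts$n_green,
                    d_rr = sim$counts$d_rr, d_gg = sim$counts$d_gg,
                    d_rg = sim$counts$d_rg)
  write_counts_csv(cdf, counts_path)
  paths <- list(counts = counts_path)
  if (!is.null(sim$ground_truth)) {
    gt_path <- file.path(dir, "ground_truth.csv")
    utils::write.csv(sim$ground_truth, gt_path, row.names = FALSE,
                     quote = FALSE)
    paths$ground_truth <- gt_path
    if (render) {
      imgs <- render_fields(sim$ground_truth, seed = sim$truth$seed, ...)
      paths$images <- write_field_images(imgs, dir, format = format)
    }
  }
  sim$paths <- paths
  invisible(sim)
}

#' Quantify a dye-dilution event CSV and write a JSON summary
#'
#' @param input Path to an event CSV ([read_dilution_events()] schema) or
#'   a `"dilution_events"` object.
#' @param output_json Optional path for the JSON summary.
#' @inheritParams estimate_divided_fraction
#' @return The [estimate_divided_fraction()] result, invisibly when
#'   `output_json` is given.
#' @export
dilution_report <- function(input, output_json = NULL, method = "valley") {
  events <- if (is.character(input)) read_dilution_events(input) else input
  est <- estimate_divided_fraction(events, method = method)
  if (!is.null(output_json)) {
    jsonlite::write_json(unclass(est), output_json, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    return(invisible(est))
  }
  est
}
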