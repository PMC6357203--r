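#' Field counts from a two-colour doublet-counting experiment
#'
#' `field_counts()` bundles the five observable counts of a two-colour
#' semisolid-culture experiment: the total number of red and green platelets
#' seen across the surveyed microscopic fields, and the number of red-red,
#' green-green and red-green doublets among them. These five numbers are the
#' entire input of the binomial composition test
#' ([doublet_null_test()]) and of the division-fraction estimator
#' ([estimate_division_fractions()]).
#'
#' The totals count every platelet of a colour, whether it sits alone or in a
#' doublet, so the implied singlet counts are
#' `s_r = n_red - 2 * d_rr - d_rg` and `s_g = n_green - 2 * d_gg - d_rg`;
#' both must be non-negative. Platelets in clusters of three or more are
#' excluded before counting.
#'
#' @param n_red,n_green Total platelets of each colour across all fields.
#' @param d_rr,d_gg,d_rg Doublet counts by colour combination.
#' @param experiment Character label for the experiment (e.g. `"MCX1"`).
#' @param condition Character label for the culture condition. Canonical
#'   values are `"initial"` (counted before culture) and `"cultured"`
#'   (after six hours), but any label is accepted so that e.g. drug-treated
#'   arms can reuse the container.
#' @param integer_counts If `TRUE` (default) all counts must be integers.
#'   Expectation-level simulations produce real-valued counts; they set this
#'   to `FALSE`.
#'
#' @return An object of class `"field_counts"`: a list with elements
#'   `experiment`, `condition`, `n_red`, `n_green`, `d_rr`, `d_gg`, `d_rg`.
#' @examples
#' fc <- field_counts(171, 167, d_rr = 28, d_gg = 22, d_rg = 8,
#'                    experiment = "MCX1", condition = "cultured")
#' singlet_counts(fc)
#' @seealso [read_counts_csv()], [semisolid_culture_counts()]
#' @export
field_counts <- function(n_red, n_green, d_rr, d_gg, d_rg,
                         experiment = "", condition = "cultured",
                         integer_counts = TRUE) {
  vals <- c(n_red = n_red, n_green = n_green,
            d_rr = d_rr, d_gg = d_gg, d_rg = d_rg)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("all counts must be finite and non-negative (experiment '",
         experiment, "')", call. = FALSE)
  }
  if (integer_counts && !all(vapply(vals, is_count, logical(1)))) {
    stop("counts must be non-negative integers (experiment '",
         experiment, "'); use integer_counts = FALSE for real-valued ",
         "expectation counts", call. = FALSE)
  }
  s_r <- n_red - 2 * d_rr - d_rg
  s_g <- n_green - 2 * d_gg - d_rg
  if (s_r < 0 || s_g < 0) {
    stop("inconsistent counts for experiment '", experiment,
         "': totals must satisfy n_red >= 2*d_rr + d_rg and ",
         "n_green >= 2*d_gg + d_rg (implied singlets ", signif(s_r, 6),
         ", ", signif(s_g, 6), ")", call. = FALSE)
  }
  structure(
    list(experiment = as.character(experiment),
         condition = as.character(condition),
         n_red = as.numeric(n_red), n_green = as.numeric(n_green),
         d_rr = as.numeric(d_rr), d_gg = as.numeric(d_gg),
         d_rg = as.numeric(d_rg)),
    class = "field_counts"
  )
}

#' @export
print.field_counts <- function(x, ...) {
  s <- singlet_counts(x)
  cat(sprintf("Field counts [%s, %s]\n",
              if (nzchar(x$experiment)) x$experiment else "unnamed",
              x$condition))
  cat(sprintf("  platelets: %g red, %g green (singlets %g / %g)\n",
              x$n_red, x$n_green, s[["s_r"]], s[["s_g"]]))
  cat(sprintf("  doublets:  RR %g, GG %g, RG %g (total %g)\n",
              x$d_rr, x$d_gg, x$d_rg, x$d_rr + x$d_gg + x$d_rg))
  invisible(x)
}

#' Singlet counts implied by a set of field counts
#'
#' @param counts A [field_counts()] object.
#' @return Named numeric vector with elements `s_r` and `s_g`.
#' @export
singlet_counts <- function(counts) {
  stopifnot(inherits(counts, "field_counts"))
  c(s_r = counts$n_red - 2 * counts$d_rr - counts$d_rg,
    s_g = counts$n_green - 2 * counts$d_gg - counts$d_rg)
}

#' Total doublets in a set of field counts
#' @param counts A [field_counts()] object.
#' @return Single number `d_rr + d_gg + d_rg`.
#' @export
total_doublets <- function(counts) {
  stopifnot(inherits(counts, "field_counts"))
  counts$d_rr + counts$d_gg + counts$d_rg
}

counts_columns <- c("experiment", "condition",
                    "n_red", "n_green", "d_rr", "d_gg", "d_rg")

#' Read and write count tables
#'
#' A counts CSV holds one experiment/condition per row with the header
#' `experiment,condition,n_red,n_green,d_rr,d_gg,d_rg` (UTF-8, header
#' required). Every row is validated through [field_counts()] on read.
#'
#' @param path Path to a CSV file.
#' @return `read_counts_csv()` returns a `data.frame` with the seven columns
#'   above, one row per experiment/condition.
#' @examples
#' path <- system.file("extdata", "semisolid_counts.csv",
#'                     package = "plateletdiv")
#' head(read_counts_csv(path))
#' @export
read_counts_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  missing_cols <- setdiff(counts_columns, names(df))
  if (length(missing_cols)) {
    stop("counts file '", path, "' is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[counts_columns]
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    tryCatch(
      field_counts(row$n_red, row$n_green, row$d_rr, row$d_gg, row$d_rg,
                   experiment = row$experiment, condition = row$condition),
      error = function(e) stop("row ", i, " of '", path, "': ",
                               conditionMessage(e), call. = FALSE)
    )
  }
  df
}

#' @rdname read_counts_csv
#' @param counts A `data.frame` with the counts columns, or a single
#'   [field_counts()] object.
#' @export
write_counts_csv <- function(counts, path) {
  if (inherits(counts, "field_counts")) {
    counts <- as.data.frame(unclass(counts))
  }
  stopifnot(all(counts_columns %in% names(counts)))
  utils::write.csv(counts[counts_columns], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# Turn one row of a counts data.frame into a field_counts object.
as_field_counts <- function(row) {
  field_counts(row$n_red, row$n_green, row$d_rr, row$d_gg, row$d_rg,
               experiment = row$experiment, condition = row$condition)
}

#' Packaged count tables from the semisolid-culture experiments
#'
#' `semisolid_culture_counts()` returns the singlet/doublet count tables of
#' the six two-colour semisolid-culture experiments (MCX1-MCX6), each counted
#' once before culture (`condition == "initial"`) and once after six hours
#' (`condition == "cultured"`). `cytoskeletal_counts()` returns the
#' corresponding tables for the cytoskeletal-inhibitor series (taxol,
#' nocodazole, cytochalasin D; mock vs treated six-hour cultures).
#'
#' The counts were decoded from the published per-class doublet percentages
#' (e.g. a red-red doublet share of 48.3% among 58 doublets gives 28) and
#' cross-checked against the published expected percentages, tail-test
#' probabilities and division fractions.
#'
#' @return A `data.frame` in the [read_counts_csv()] schema.
#' @examples
#' semisolid_culture_counts()
#' @export
semisolid_culture_counts <- function() {
  read_counts_csv(system.file("extdata", "semisolid_counts.csv",
                              package = "plateletdiv", mustWork = TRUE))
}

#' @rdname semisolid_culture_counts
#' @export
cytoskeletal_counts <- function() {
  read_counts_csv(system.file("extdata", "cytoskeletal_counts.csv",
                              package = "plateletdiv", mustWork = TRUE))
}
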