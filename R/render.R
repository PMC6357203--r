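#' Render two-channel fluorescence field images from a spot ground truth
#'
#' Produces synthetic confocal-like field images: each platelet is rendered
#' in its acquisition channel as an isotropic 2-D Gaussian of integrated
#' intensity `photon_scale`, integrated exactly over the pixel grid, on a
#' uniform `background`. With `noise = "poisson_gaussian"`, Poisson shot
#' noise plus Gaussian read noise is added. Output is clamped to the 16-bit
#' range; the two channels are perfectly registered.
#'
#' Coordinates are continuous micrometres with the origin at the top-left
#' corner and y pointing down; the pixel with 0-based index `(i, j)` covers
#' `[i, i+1) x [j, j+1)` times `pixel_size`.
#'
#' @param ground_truth A `data.frame` with columns `field`, `x`, `y`
#'   (micrometres) and `channel` (`"red"`/`"green"`), as produced by
#'   [simulate_counts()] in spatial mode.
#' @param psf_sigma Gaussian spot width (um), standard deviation.
#' @param pixel_size Pixel pitch (um); must not exceed `psf_sigma`, so
#'   spots are adequately sampled.
#' @param photon_scale Integrated photon count per spot.
#' @param background Uniform background level (counts).
#' @param noise `"none"` or `"poisson_gaussian"`.
#' @param read_noise Gaussian read noise standard deviation (counts), used
#'   only with `noise = "poisson_gaussian"`.
#' @param field_width,field_height Field extent (um); defaults are taken
#'   from attributes of `ground_truth` when present.
#' @param n_fields Number of fields to render; defaults to the attribute or
#'   the maximum field index.
#' @param seed Integer seed for the noise (`NULL` draws one).
#' @return An object of class `"field_images"`: a list with one element per
#'   field, each a list with matrices `red` and `green` (rows = y), and
#'   attributes `pixel_size` and `seed`. Spots outside the field are
#'   clipped with a warning.
#' @examples
#' sim <- simulate_counts(simulation_truth(r0 = 20, g0 = 20, n_fields = 2,
#'                                         mode = "spatial", seed = 3))
#' imgs <- render_fields(sim$ground_truth, seed = 3)
#' dim(imgs[[1]]$red)
#' @export
render_fields <- function(ground_truth, psf_sigma = 0.3, pixel_size = 0.15,
                          photon_scale = 5000, background = 100,
                          noise = c("none", "poisson_gaussian"),
                          read_noise = 3,
                          field_width = NULL, field_height = NULL,
                          n_fields = NULL, seed = NULL) {
  noise <- match.arg(noise)
  stopifnot(is.data.frame(ground_truth),
            all(c("field", "x", "y", "channel") %in% names(ground_truth)))
  if (pixel_size > psf_sigma) {
    stop("pixel_size must not exceed psf_sigma: spots would be ",
         "undersampled", call. = FALSE)
  }
  field_width <- field_width %||% attr(ground_truth, "field_width") %||% 100
  field_height <- field_height %||% attr(ground_truth, "field_height") %||%
    100
  n_fields <- n_fields %||% attr(ground_truth, "n_fields") %||%
    max(ground_truth$field, 1)
  nx <- ceiling(field_width / pixel_size)
  ny <- ceiling(field_height / pixel_size)
  sigma_px <- psf_sigma / pixel_size

  outside <- ground_truth$x < 0 | ground_truth$x > field_width |
    ground_truth$y < 0 | ground_truth$y > field_height
  if (any(outside)) {
    warning(sum(outside), " spot(s) outside the field were clipped",
            call. = FALSE)
    ground_truth <- ground_truth[!outside, ]
  }

  render_channel <- function(spots) {
    img <- matrix(background, nrow = ny, ncol = nx)
    half <- ceiling(5 * sigma_px)
    for (k in seq_len(nrow(spots))) {
      cx <- spots$x[k] / pixel_size   # continuous 0-based pixel coords
      cy <- spots$y[k] / pixel_size
      jc <- floor(cx); ic <- floor(cy)
      js <- max(0, jc - half):min(nx - 1, jc + half)
      is <- max(0, ic - half):min(ny - 1, ic + half)
      wx <- stats::pnorm(js + 1, cx, sigma_px) -
        stats::pnorm(js, cx, sigma_px)
      wy <- stats::pnorm(is + 1, cy, sigma_px) -
        stats::pnorm(is, cy, sigma_px)
      img[is + 1, js + 1] <- img[is + 1, js + 1] +
        photon_scale * (wy %o% wx)
    }
    img
  }

  seed <- seed %||% draw_seed()
  fields <- with_seed(seed, {
    lapply(seq_len(n_fields), function(fld) {
      sub <- ground_truth[ground_truth$field == fld, , drop = FALSE]
      chans <- lapply(c(red = "red", green = "green"), function(ch) {
        img <- render_channel(sub[sub$channel == ch, , drop = FALSE])
        if (noise == "poisson_gaussian") {
          img <- matrix(stats::rpois(length(img), img) +
                          stats::rnorm(length(img), 0, read_noise),
                        nrow = nrow(img))
        }
        matrix(pmin(pmax(round(img), 0), 65535), nrow = ny)
      })
      chans
    })
  })
  structure(fields, pixel_size = pixel_size, seed = seed,
            class = "field_images")
}

#' @export
print.field_images <- function(x, ...) {
  d <- dim(x[[1]]$red)
  cat(sprintf(
    "Two-channel field images: %d field(s), %d x %d px, %g um/px\n",
    length(x), d[2], d[1], attr(x, "pixel_size")))
  invisible(x)
}

#' Write and read two-channel field images
#'
#' `write_field_images()` stores each channel of each field as a
#' grey-scale image named `field<i>_<channel>.<ext>` under `dir`.
#' `read_field_images()` reads such a set back into a `"field_images"`
#' object. TIFF output is 16-bit and lossless; PNG output is 8-bit (the
#' intensity range is quantised to 256 levels) and intended for quick
#' visual inspection, not quantitative reanalysis.
#'
#' @param images A `"field_images"` object from [render_fields()].
#' @param dir Output directory (created if missing).
#' @param format `"tiff"` or `"png"`.
#' @return `write_field_images()` returns the written paths invisibly;
#'   `read_field_images()` returns a `"field_images"` object.
#' @export
write_field_images <- function(images, dir, format = c("tiff", "png")) {
  format <- match.arg(format)
  stopifnot(inherits(images, "field_images"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "tiff") "tif" else "png"
  paths <- character(0)
  for (fld in seq_along(images)) {
    for (ch in c("red", "green")) {
      path <- file.path(dir, sprintf("field%02d_%s.%s", fld, ch, ext))
      img <- images[[fld]][[ch]] / 65535
      if (format == "tiff") {
        tiff::writeTIFF(img, path, bits.per.sample = 16)
      } else {
        png::writePNG(img, path)
      }
      paths <- c(paths, path)
    }
  }
  invisible(paths)
}

#' @rdname write_field_images
#' @param red_paths,green_paths Parallel character vectors of per-field
#'   image paths for the two channels.
#' @param pixel_size Pixel pitch (um) of the stored images.
#' @export
read_field_images <- function(red_paths, green_paths, pixel_size = 0.15) {
  stopifnot(length(red_paths) == length(green_paths),
            length(red_paths) >= 1)
  read_one <- function(path) {
    img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
      png::readPNG(path)
    } else {
      tiff::readTIFF(path)
    }
    if (length(dim(img)) == 3) img <- img[, , 1]
    round(img * 65535)
  }
  fields <- Map(function(r, g) list(red = read_one(r),
                                    green = read_one(g)),
                red_paths, green_paths)
  names(fields) <- NULL
  structure(fields, pixel_size = pixel_size, seed = NA_integer_,
            class = "field_images")
}
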