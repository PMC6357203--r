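test_that("flat images yield no spots and bad input errors", {
  expect_equal(nrow(detect_spots(matrix(100, 64, 64))), 0)
  expect_error(detect_spots(array(1, c(4, 4, 2))), "matrix")
  expect_error(detect_spots(1:10), "matrix")
})

test_that("noiseless well-separated spots are recovered with sub-pixel
           accuracy", {
  set.seed(21)
  n <- 25
  gx <- rep(seq(10, 90, length.out = 5), 5) + runif(n, -2, 2)
  gy <- rep(seq(10, 90, length.out = 5), each = 5) + runif(n, -2, 2)
  gt <- data.frame(field = 1, x = gx, y = gy, channel = "red")
  imgs <- render_fields(gt, psf_sigma = 0.3, pixel_size = 0.15,
                        noise = "none", seed = 1)
  spots <- detect_spots(imgs[[1]]$red, psf_sigma_px = 2, pixel_size = 0.15)
  expect_equal(nrow(spots), n)
  err_px <- vapply(seq_len(n), function(i) {
    min(sqrt((spots$x - gx[i])^2 + (spots$y - gy[i])^2)) / 0.15
  }, numeric(1))
  expect_lt(max(err_px), 0.1)
})

test_that("detection stays accurate under Poisson noise", {
  set.seed(31)
  n_per <- 25
  hits <- 0; found <- 0
  for (fld in 1:4) {
    gx <- rep(seq(10, 90, length.out = 5), 5) + runif(n_per, -2, 2)
    gy <- rep(seq(10, 90, length.out = 5), each = 5) + runif(n_per, -2, 2)
    gt <- data.frame(field = 1, x = gx, y = gy, channel = "red")
    imgs <- render_fields(gt, photon_scale = 5000, background = 100,
                          noise = "poisson_gaussian", seed = 100 + fld)
    spots <- detect_spots(imgs[[1]]$red, psf_sigma_px = 2,
                          pixel_size = 0.15)
    found <- found + nrow(spots)
    hits <- hits + sum(vapply(seq_len(n_per), function(i) {
      any(sqrt((spots$x - gx[i])^2 + (spots$y - gy[i])^2) < 1)
    }, logical(1)))
  }
  recall <- hits / (4 * n_per)
  precision <- hits / found
  expect_gte(recall, 0.99)
  expect_gte(precision, 0.99)
})

test_that("proximity clustering classifies colour combinations", {
  # two red spots just inside the contact distance: one RR doublet
  red <- data.frame(x = c(10, 10 + 2.97), y = c(10, 10))
  cl <- cluster_particles(red, data.frame(x = numeric(0), y = numeric(0)),
                          contact_distance = 3)
  expect_equal(cl$clusters$combo, "RR")
  # just outside: two singlets
  red2 <- data.frame(x = c(10, 13.1), y = c(10, 10))
  cl2 <- cluster_particles(red2, data.frame(x = numeric(0),
                                            y = numeric(0)), 3)
  expect_equal(sort(cl2$clusters$combo), c("R", "R"))
  # red+green at 0.8 x contact distance: one RG doublet
  cl3 <- cluster_particles(data.frame(x = 10, y = 10),
                           data.frame(x = 12.4, y = 10), 3)
  expect_equal(cl3$clusters$combo, "RG")
  # collinear chain red-green-red: one multiplet, zero doublets
  cl4 <- cluster_particles(data.frame(x = c(10, 14), y = c(10, 10)),
                           data.frame(x = 12, y = 10), 3)
  expect_equal(cl4$clusters$class, "multiplet")
  expect_equal(sum(cl4$clusters$class == "doublet"), 0)
  expect_error(cluster_particles(red, red, -1), "non-negative")
})

test_that("clustering is invariant under channel swap and translation", {
  set.seed(41)
  red <- data.frame(x = runif(30, 0, 50), y = runif(30, 0, 50))
  green <- data.frame(x = runif(25, 0, 50), y = runif(25, 0, 50))
  a <- cluster_particles(red, green, 3)$clusters
  b <- cluster_particles(green, red, 3)$clusters
  swap <- c(R = "G", G = "R", RR = "GG", GG = "RR", RG = "RG",
            multi = "multi")
  combo_a <- ifelse(a$combo == "", "multi", a$combo)
  combo_b <- ifelse(b$combo == "", "multi", b$combo)
  expect_equal(sort(unname(swap[combo_a])), sort(combo_b))
  shift <- function(df) data.frame(x = df$x + 17.3, y = df$y - 4.1)
  d <- cluster_particles(shift(red), shift(green), 3)$clusters
  expect_equal(table(a$combo), table(d$combo))
  # determinism
  expect_identical(a, cluster_particles(red, green, 3)$clusters)
})

test_that("count_fields aggregates fields and flags borders", {
  # one field, one red spot
  gt <- data.frame(field = 1, x = 50, y = 50, channel = "red")
  imgs <- render_fields(gt, seed = 1)
  res <- count_fields(imgs)
  expect_equal(res$counts$n_red, 1)
  expect_equal(res$counts$n_green, 0)
  expect_equal(total_doublets(res$counts), 0)
  expect_error(count_fields(list()), "no fields")
})

test_that("imaging round trip reproduces simulator counts exactly", {
  truth <- simulation_truth(r0 = 165, g0 = 165, mode = "spatial",
                            seed = 11)
  sim <- simulate_counts(truth)
  imgs <- render_fields(sim$ground_truth, noise = "none", seed = 11)
  res <- count_fields(imgs, contact_distance = 3)
  expect_equal(unclass(res$counts)[3:7], unclass(sim$counts)[3:7])
})

test_that("field images survive a TIFF and PNG disk round trip", {
  gt <- data.frame(field = rep(1:2, each = 3),
                   x = rep(c(20, 50, 80), 2), y = rep(c(30, 60, 20), 2),
                   channel = rep(c("red", "green", "red"), 2))
  imgs <- render_fields(gt, n_fields = 2, seed = 6)
  # TIFF: lossless 16-bit
  dir <- withr::local_tempdir()
  write_field_images(imgs, dir, format = "tiff")
  back <- read_field_images(
    file.path(dir, sprintf("field%02d_red.tif", 1:2)),
    file.path(dir, sprintf("field%02d_green.tif", 1:2)),
    pixel_size = 0.15)
  expect_equal(back[[1]]$red, imgs[[1]]$red, ignore_attr = TRUE)
  expect_equal(back[[2]]$green, imgs[[2]]$green, ignore_attr = TRUE)
  # PNG: 8-bit, faithful to within one quantisation step
  dir2 <- withr::local_tempdir()
  write_field_images(imgs, dir2, format = "png")
  back2 <- read_field_images(
    file.path(dir2, sprintf("field%02d_red.png", 1:2)),
    file.path(dir2, sprintf("field%02d_green.png", 1:2)),
    pixel_size = 0.15)
  expect_lt(max(abs(back2[[1]]$red - imgs[[1]]$red)), 65535 / 255)
})
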