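test_that("sRGB conversion hits the D65 reference points and the gray axis", {
  expect_equal(srgb_to_lab(matrix(c(255, 255, 255), 1)),
               cbind(L = 100, a = 0, b = 0), tolerance = 1e-8)
  expect_equal(srgb_to_lab(matrix(c(0, 0, 0), 1)),
               cbind(L = 0, a = 0, b = 0), tolerance = 1e-8)
  # sRGB primary red under D65, computed from the standard formulas
  red <- srgb_to_lab(matrix(c(255, 0, 0), 1))
  expect_equal(unname(red[1, ]), c(53.24, 80.09, 67.20), tolerance = 1e-3)
  # neutral grays must sit exactly on the a = b = 0 line
  grays <- srgb_to_lab(cbind(0:255, 0:255, 0:255))
  expect_lt(max(abs(grays[, c("a", "b")])), 1e-6)
  expect_true(all(diff(grays[, "L"]) > 0))
  expect_error(srgb_to_lab(matrix(c(256, 0, 0), 1)), "0, 255")
  expect_error(srgb_to_lab(matrix(c(-1, 0, 0), 1)), "0, 255")
})

test_that("sRGB conversion agrees with an independent implementation", {
  skip_if_not_installed("farver")
  set.seed(1)
  px <- matrix(sample(0:255, 300, replace = TRUE), ncol = 3)
  ours <- srgb_to_lab(px)
  theirs <- farver::convert_colour(px, from = "rgb", to = "lab")
  expect_lt(max(abs(ours - unname(as.matrix(theirs)))), 0.05)
})

test_that("pixel sampling is reproducible and respects masks", {
  # uniform image: every sampled pixel identical
  img <- array(0.5, dim = c(4, 5, 3))
  s <- sample_pixels(img, n = 100, seed = 1)
  expect_equal(s$n, 100)
  expect_equal(max(apply(s$pixels, 2, function(x) diff(range(x)))), 0)
  # determinism under a fixed seed
  big <- array(runif(40 * 40 * 3), dim = c(40, 40, 3))
  expect_identical(sample_pixels(big, 500, seed = 7)$pixels,
                   sample_pixels(big, 500, seed = 7)$pixels)
  # alpha channel masks out background
  rgba <- array(0, dim = c(10, 10, 4))
  rgba[, , 1] <- 1                      # red everywhere
  rgba[1:5, , 4] <- 1                   # only top half visible
  rgba[6:10, , 2] <- 1                  # bottom half yellow, transparent
  s2 <- sample_pixels(rgba, 200, seed = 2)
  expect_equal(nrow(unique(s2$pixels)), 1)
  expect_equal(unname(s2$pixels[1, ]),
               unname(srgb_to_lab(matrix(c(255, 0, 0), 1))[1, ]))
  rgba[, , 4] <- 0
  expect_error(sample_pixels(rgba, 10), "foreground")
  # designated background color is excluded
  img2 <- array(1, dim = c(10, 10, 3))
  img2[1, 1, ] <- 0
  s3 <- sample_pixels(img2, 1000, seed = 3, background = c(255, 255, 255))
  expect_true(all(s3$pixels[, "L"] == 0))
})

test_that("two-color sampling proportions fall within binomial error", {
  img <- array(0, dim = c(200, 200, 3))   # black
  img[1:100, 1:200, ] <- 1                # half white -> then adjust to 3:1
  img[101:150, 1:200, ] <- 1              # 3/4 white, 1/4 black
  s <- sample_pixels(img, n = 50000, seed = 11)
  frac_white <- mean(s$pixels[, "L"] > 50)
  # 0.75 +/- 4 sd, sd = sqrt(.75*.25/50000) ~ 0.0019
  expect_gt(frac_white, 0.75 - 4 * 0.0019383)
  expect_lt(frac_white, 0.75 + 4 * 0.0019383)
})

test_that("centroids are per-axis means lying in the pixel bounding box", {
  expect_equal(unname(centroid(matrix(c(50, 10, -10), 1))),
               c(50, 10, -10))
  expect_equal(unname(centroid(rbind(c(0, 0, 0), c(100, 0, 0)))),
               c(50, 0, 0))
  set.seed(4)
  px <- cbind(runif(500, 0, 100), runif(500, -80, 80), runif(500, -80, 80))
  ce <- centroid(px)
  expect_true(all(ce >= apply(px, 2, min) & ce <= apply(px, 2, max)))
  expect_error(centroid(px[0, , drop = FALSE]), "empty")
})

test_that("dichromatism is a symmetric Euclidean distance, oriented female to male", {
  c0 <- c(12, -3, 40)
  expect_equal(dichromatism(c0, c0)$D_mag, 0)
  d <- dichromatism(c(0, 0, 0), c(3, 4, 0))
  expect_equal(d$D_mag, 5)
  expect_equal(unname(d$D_vec), c(-3, -4, 0))   # male minus female
  swapped <- dichromatism(c(3, 4, 0), c(0, 0, 0))
  expect_equal(swapped$D_mag, d$D_mag)
  expect_equal(unname(swapped$D_vec), -unname(d$D_vec))
  # rigid rotation in (a, b) leaves centroid distances unchanged
  set.seed(5)
  th <- runif(1, 0, 2 * pi)
  R2 <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  rot <- function(x) c(x[1], as.vector(R2 %*% x[2:3]))
  for (i in 1:10) {
    a <- c(runif(1, 0, 100), runif(2, -50, 50))
    b <- c(runif(1, 0, 100), runif(2, -50, 50))
    expect_equal(dichromatism(rot(a), rot(b))$D_mag,
                 dichromatism(a, b)$D_mag)
  }
  # triangle inequality
  set.seed(6)
  for (i in 1:20) {
    x <- matrix(runif(9, -50, 50), 3)
    expect_lte(dichromatism(x[1, ], x[3, ])$D_mag,
               dichromatism(x[1, ], x[2, ])$D_mag +
                 dichromatism(x[2, ], x[3, ])$D_mag + 1e-12)
  }
})

test_that("palette profiles recover separable colors; 2-opt never worsens the tour", {
  red <- matrix(rep(c(53, 80, 67), each = 50), ncol = 3)
  blue <- matrix(rep(c(32, 79, -108), each = 50), ncol = 3)
  pp <- palette_profile(list(r = red, b = blue, mix = rbind(red, blue)),
                        k = 2, seed = 1)
  expect_equal(dim(pp$palette), c(2, 3))
  expect_true(all(rowSums(pp$fractions) == 1))
  expect_setequal(round(pp$palette[, 1]), c(53, 32))
  expect_equal(sort(unname(pp$fractions["mix", ])), c(0.5, 0.5))
  expect_true(all(pp$fractions[c("r", "b"), ] %in% c(0, 1)))
  # k = 1 gives unit fraction vectors
  p1 <- palette_profile(list(a = red, b = blue), k = 1)
  expect_true(all(p1$fractions == 1))
  expect_error(palette_profile(list(a = red), k = 2), "distinct")
  # the exchange improvement step can only shorten the insertion tour
  set.seed(9)
  for (i in 1:5) {
    pts <- matrix(rnorm(3 * 25), ncol = 3)
    tour <- dichroma:::.tsp_order(pts)
    expect_lte(tour$len_final, tour$len_insertion + 1e-9)
    expect_setequal(tour$order, 1:25)
  }
})

test_that("pairwise structure correlation recovers identity and scaling", {
  set.seed(10)
  A <- data.frame(sample_id = paste0("s", 1:8),
                  L = runif(8, 0, 100), a = rnorm(8, 0, 30),
                  b = rnorm(8, 0, 30))
  same <- structure_correlation(A, A)
  expect_equal(same$r, rep(1, 3))
  expect_equal(same$slope, rep(1, 3))
  expect_equal(attr(same, "n_pairs"), choose(8, 2))
  B <- A
  B[, c("L", "a", "b")] <- 0.5 * B[, c("L", "a", "b")]
  halved <- structure_correlation(A, B)
  expect_equal(halved$r, rep(1, 3))
  expect_equal(halved$slope, rep(0.5, 3))
  B2 <- A
  B2$sample_id[1] <- "zz"
  expect_error(structure_correlation(A, B2), "same sample identifiers")
})
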