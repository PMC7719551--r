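# Color metrics: pixel samples, CIELAB centroids, dichromatism, palettes.

#' Convert sRGB pixels to CIELAB coordinates
#'
#' Standard sRGB -> linear RGB -> XYZ (D65 white, 2 degree observer) ->
#' CIELAB conversion. CIELAB is approximately perceptually uniform, so the
#' Euclidean distance between two colors (Delta E) is comparable anywhere
#' in the space; all downstream analyses rely on this.
#'
#' @param pixels numeric matrix or data frame with three columns (R, G, B),
#'   each channel in \[0, 255\]. Non-integer values are accepted.
#' @return a numeric matrix with columns `L`, `a`, `b`. `L` (lightness) is
#'   in \[0, 100\]; `a` (green-red) and `b` (blue-yellow) lie within the
#'   sRGB gamut (|a|, |b| < 128).
#' @details The sRGB-to-XYZ matrix is the IEC 61966-2-1 standard matrix
#'   with the reference white taken as the image of RGB = (1, 1, 1), so
#'   neutral grays map exactly onto the a = b = 0 axis and white to
#'   L = 100.
#' @examples
#' srgb_to_lab(rbind(c(255, 255, 255), c(255, 0, 0)))
#' @export
srgb_to_lab <- function(pixels) {
  px <- as.matrix(pixels)
  if (ncol(px) != 3)
    stop("`pixels` must have three columns (R, G, B).")
  if (any(!is.finite(px)) || any(px < 0) || any(px > 255))
    stop("RGB channels must be finite and in [0, 255].")
  s <- px / 255
  lin <- ifelse(s <= 0.04045, s / 12.92, ((s + 0.055) / 1.055)^2.4)
  M <- matrix(c(0.4124, 0.3576, 0.1805,
                0.2126, 0.7152, 0.0722,
                0.0193, 0.1192, 0.9505), 3, 3, byrow = TRUE)
  xyz <- lin %*% t(M)
  xyz <- sweep(xyz, 2, rowSums(M), "/")   # normalize to the D65 white
  delta <- 6 / 29
  fwd <- function(t) ifelse(t > delta^3, t^(1 / 3),
                            t / (3 * delta^2) + 4 / 29)
  fx <- fwd(xyz[, 1]); fy <- fwd(xyz[, 2]); fz <- fwd(xyz[, 3])
  lab <- cbind(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
  rownames(lab) <- NULL
  lab
}

#' Construct a pixel sample
#'
#' Bundles a matrix of CIELAB pixels with species/sex metadata and checks
#' the CIELAB invariants.
#'
#' @param lab numeric matrix with columns L, a, b (n >= 1 rows).
#' @param species_id,sex optional metadata carried through to centroids.
#' @return an object of class `pixel_sample`.
#' @export
pixel_sample <- function(lab, species_id = NA_character_, sex = NA_character_) {
  lab <- as.matrix(lab)
  if (nrow(lab) < 1) stop("a pixel sample needs at least one pixel.")
  if (ncol(lab) != 3) stop("`lab` must have three columns (L, a, b).")
  if (any(!is.finite(lab))) stop("pixel coordinates must be finite.")
  tol <- 1e-6
  if (any(lab[, 1] < -tol | lab[, 1] > 100 + tol))
    stop("L must lie in [0, 100].")
  if (any(abs(lab[, 2:3]) >= 128 + tol))
    stop("a and b must lie within the sRGB gamut (|a|, |b| < 128).")
  colnames(lab) <- c("L", "a", "b")
  structure(list(species_id = species_id, sex = sex, pixels = lab,
                 n = nrow(lab)),
            class = "pixel_sample")
}

#' @export
print.pixel_sample <- function(x, ...) {
  cat("Pixel sample:", x$n, "CIELAB pixels",
      if (!is.na(x$species_id)) paste0("(", x$species_id,
                                       if (!is.na(x$sex)) paste0(", ", x$sex),
                                       ")"), "\n")
  invisible(x)
}

#' Sample foreground pixels from an image
#'
#' Draws `n` pixels uniformly at random from the non-background pixels of
#' a raster image and converts them to CIELAB. Background is defined by
#' full transparency (alpha = 0 in an RGBA image) and/or an exact match to
#' a designated background color; only the drawn subject is informative.
#' If the foreground holds fewer than `n` pixels, sampling is with
#' replacement so that `n` stays fixed.
#'
#' @param image either a numeric array of dimension height x width x 3
#'   (RGB) or height x width x 4 (RGBA), with values in \[0, 1\] or
#'   \[0, 255\], or the path to a PNG file (requires the png package).
#' @param n number of pixels to draw (default 50000).
#' @param seed optional integer seed for reproducible sampling.
#' @param background optional length-3 RGB vector (0-255 scale); pixels
#'   matching it (within half a 8-bit step) are excluded.
#' @param species_id,sex metadata passed to [pixel_sample()].
#' @return a [pixel_sample()] of `n` CIELAB pixels.
#' @export
sample_pixels <- function(image, n = 50000, seed = NULL, background = NULL,
                          species_id = NA_character_, sex = NA_character_) {
  if (is.character(image)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("reading image files requires the png package.")
    image <- png::readPNG(image)
  }
  if (length(dim(image)) == 2)            # grayscale
    image <- array(rep(image, 3), dim = c(dim(image), 3))
  if (length(dim(image)) != 3 || !(dim(image)[3] %in% c(3, 4)))
    stop("`image` must be an H x W x 3 (RGB) or H x W x 4 (RGBA) array.")
  if (max(image) > 1) image <- image / 255
  np <- prod(dim(image)[1:2])
  rgb <- cbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
               as.vector(image[, , 3])) * 255
  keep <- rep(TRUE, np)
  if (dim(image)[3] == 4)
    keep <- keep & as.vector(image[, , 4]) > 0
  if (!is.null(background)) {
    stopifnot(length(background) == 3)
    keep <- keep & rowSums(abs(sweep(rgb, 2, background)) > 0.5) > 0
  }
  idx <- which(keep)
  if (!length(idx)) stop("image has no foreground pixels to sample.")
  if (!is.null(seed)) set.seed(seed)
  take <- if (length(idx) >= n) sample(idx, n) else sample(idx, n, replace = TRUE)
  pixel_sample(srgb_to_lab(rgb[take, , drop = FALSE]),
               species_id = species_id, sex = sex)
}

#' Color centroid of a pixel sample
#'
#' The per-axis arithmetic mean of the sample's CIELAB coordinates: the
#' "average color" used as the species/sex phenotype throughout.
#'
#' @param sample a [pixel_sample()] or a numeric matrix with columns
#'   L, a, b.
#' @return a named numeric vector `c(L, a, b)`.
#' @export
centroid <- function(sample) {
  m <- if (inherits(sample, "pixel_sample")) sample$pixels else as.matrix(sample)
  if (nrow(m) < 1) stop("cannot compute the centroid of an empty sample.")
  if (any(!is.finite(m))) stop("pixel coordinates must be finite.")
  stats::setNames(colMeans(m), c("L", "a", "b"))
}

#' Dichromatism between two sex centroids
#'
#' The dichromatism vector is the directed difference between the male and
#' female centroids, `D_vec = c_m - c_f` (it points from the female toward
#' the male phenotype), and its Euclidean norm `D_mag` is the dichromatism
#' magnitude Delta E. With this orientation the effective rate
#' `s = (m - f) . D_hat` computed downstream is positive exactly when
#' dichromatism is increasing.
#'
#' @param c_m,c_f male and female centroids, numeric length-3 (L, a, b).
#' @param species_id optional identifier carried in the record.
#' @return an object of class `dimorphism_record` with elements `c_m`,
#'   `c_f`, `D_vec`, `D_mag`.
#' @examples
#' dichromatism(c(0, 0, 0), c(3, 4, 0))$D_mag   # 5
#' @export
dichromatism <- function(c_m, c_f, species_id = NA_character_) {
  c_m <- as.numeric(c_m); c_f <- as.numeric(c_f)
  if (length(c_m) != 3 || length(c_f) != 3 ||
      any(!is.finite(c_m)) || any(!is.finite(c_f)))
    stop("centroids must be finite length-3 (L, a, b) vectors.")
  d <- stats::setNames(c_m - c_f, c("L", "a", "b"))
  structure(list(species_id = species_id, c_m = c_m, c_f = c_f,
                 D_vec = d, D_mag = sqrt(sum(d^2))),
            class = "dimorphism_record")
}

#' @export
print.dimorphism_record <- function(x, ...) {
  cat("Dimorphism record",
      if (!is.na(x$species_id)) paste0("[", x$species_id, "]"),
      sprintf(": ||D|| = %.3f\n", x$D_mag))
  invisible(x)
}

#' Per-species dichromatism from a centroid table
#'
#' @param centroids data frame with columns `species_id`, `sex`
#'   ("male"/"female"), `L`, `a`, `b`; one row per species and sex.
#' @return data frame with one row per species: the dichromatism vector
#'   (`D_L`, `D_a`, `D_b`, male minus female) and magnitude `D_mag`.
#' @export
species_dichromatism <- function(centroids) {
  cm <- .centroid_matrices(centroids)
  d <- cm$male - cm$female
  data.frame(species_id = rownames(d), D_L = d[, 1], D_a = d[, 2],
             D_b = d[, 3], D_mag = .norm_rows(d), row.names = NULL)
}

#' Shared color palette and per-sample color profiles
#'
#' Pools pixels from all samples, clusters them into a shared palette of
#' `k` colors with k-means in CIELAB, and reports the fraction of each
#' sample's pixels falling in each cluster. For display, clusters are
#' ordered along a Travelling-Salesman tour over the cluster centers
#' (arbitrary insertion followed by two-edge-exchange improvement), so
#' perceptually similar colors sit next to each other. Visualization-only
#' output; no downstream statistic depends on it.
#'
#' @param samples a named list of [pixel_sample()] objects or CIELAB pixel
#'   matrices; names identify the samples.
#' @param k palette size (default 50).
#' @param seed optional seed for the k-means initialization.
#' @return a list of class `palette_profile`: `palette` (k x 3 CIELAB
#'   centers in tour order), `fractions` (samples x k, rows sum to 1), and
#'   `order` (the tour over the original cluster indices).
#' @export
palette_profile <- function(samples, k = 50, seed = NULL) {
  mats <- lapply(samples, function(s)
    if (inherits(s, "pixel_sample")) s$pixels else as.matrix(s))
  if (is.null(names(mats)) || any(!nzchar(names(mats))))
    names(mats) <- paste0("sample", seq_along(mats))
  pooled <- do.call(rbind, mats)
  grp <- rep(names(mats), vapply(mats, nrow, 1L))
  if (k < 1) stop("`k` must be at least 1.")
  n_distinct <- nrow(unique(pooled))
  if (k > n_distinct)
    stop("`k` exceeds the number of distinct colors (", n_distinct, ").")
  if (!is.null(seed)) set.seed(seed)
  km <- if (k == 1) {
    list(centers = matrix(colMeans(pooled), 1, dimnames = list(NULL, colnames(pooled))),
         cluster = rep(1L, nrow(pooled)))
  } else {
    stats::kmeans(pooled, centers = k, iter.max = 100, nstart = 5)
  }
  frac <- t(vapply(split(km$cluster, grp)[names(mats)], function(cl)
    tabulate(cl, nbins = k) / length(cl), numeric(k)))
  if (k == 1) frac <- matrix(frac, ncol = 1, dimnames = list(names(mats), NULL))
  tour <- .tsp_order(km$centers)
  structure(list(palette = km$centers[tour$order, , drop = FALSE],
                 fractions = frac[, tour$order, drop = FALSE],
                 order = tour$order),
            class = "palette_profile")
}

# Open-path ordering of points via a TSP heuristic: build a closed tour by
# arbitrary insertion (cheapest position, cities in index order), improve
# with 2-opt until no exchange helps, then cut the longest edge.
#' @noRd
.tsp_order <- function(points) {
  p <- nrow(points)
  if (p == 1) return(list(order = 1L, len_insertion = 0, len_final = 0))
  D <- as.matrix(stats::dist(points))
  tour <- c(1L, 2L)
  if (p > 2) for (city in 3L:p) {
    nt <- length(tour)
    nxt <- c(tour[-1], tour[1])
    gain <- D[tour, city] + D[city, nxt] - D[cbind(tour, nxt)]
    pos <- which.min(gain)
    tour <- append(tour, city, after = pos)
  }
  tour_len <- function(t) sum(D[cbind(t, c(t[-1], t[1]))])
  len_ins <- tour_len(tour)
  # 2-opt: reverse tour[i..j] while any exchange shortens the tour
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (i in 1:(p - 1)) {
      for (j in (i + 1):p) {
        if (i == 1 && j == p) next
        a <- tour[if (i == 1) p else i - 1]; b <- tour[i]
        c_ <- tour[j]; d <- tour[if (j == p) 1 else j + 1]
        if (D[a, c_] + D[b, d] < D[a, b] + D[c_, d] - 1e-12) {
          tour[i:j] <- rev(tour[i:j])
          improved <- TRUE
        }
      }
    }
  }
  len_fin <- tour_len(tour)
  edges <- D[cbind(tour, c(tour[-1], tour[1]))]
  cut <- which.max(edges)                     # break the weakest link
  ord <- if (cut == length(tour)) tour else c(tour[(cut + 1):p], tour[1:cut])
  list(order = ord, len_insertion = len_ins, len_final = len_fin)
}

#' Compare the color-space structure of two centroid datasets
#'
#' Validates one set of centroids (e.g. from field-guide drawings) against
#' another for the same samples (e.g. from standardized photographs). For
#' each CIELAB axis, all signed pairwise differences among samples are
#' computed within each dataset — pairs (i, j) with i < j under
#' lexicographic sample-ID order, so the orientation is reproducible — and
#' the two sets of differences are correlated (Pearson r) and regressed
#' (B on A). A high r with a slope away from 1 means the datasets agree on
#' relative color structure but differ in scale.
#'
#' @param set_A,set_B data frames with columns `sample_id`, `L`, `a`, `b`
#'   for the same sample identifiers (at least 3 samples).
#' @return data frame with one row per axis: `axis`, `r`, `slope`; the
#'   number of pairs is attached as attribute `n_pairs`.
#' @export
structure_correlation <- function(set_A, set_B) {
  ck <- function(s, nm) {
    s <- as.data.frame(s)
    if (!all(c("sample_id", "L", "a", "b") %in% names(s)))
      stop(nm, " needs columns sample_id, L, a, b.")
    s[order(s$sample_id), , drop = FALSE]
  }
  A <- ck(set_A, "set_A"); B <- ck(set_B, "set_B")
  if (!identical(as.character(A$sample_id), as.character(B$sample_id)))
    stop("the two sets must contain the same sample identifiers.")
  if (nrow(A) < 3) stop("need at least 3 samples.")
  ut <- upper.tri(diag(nrow(A)))
  res <- lapply(c("L", "a", "b"), function(ax) {
    dA <- outer(A[[ax]], A[[ax]], "-")[ut]
    dB <- outer(B[[ax]], B[[ax]], "-")[ut]
    data.frame(axis = ax, r = stats::cor(dA, dB),
               slope = stats::cov(dA, dB) / stats::var(dA))
  })
  out <- do.call(rbind, res)
  attr(out, "n_pairs") <- sum(ut)
  out
}
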