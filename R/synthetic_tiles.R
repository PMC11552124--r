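#' Closed-form features of an elliptical nucleus
#'
#' Analytic ground truth for a synthetic ellipse: area \code{pi*a*b},
#' perimeter by the Ramanujan approximation
#' \code{pi*(3*(a+b) - sqrt((3a+b)*(a+3b)))} (relative error < 1e-4 for the
#' aspect ratios used here), calipers \code{2a} and \code{2b}, eccentricity
#' \code{sqrt(1 - (b/a)^2)}, and circularity from area and perimeter.
#'
#' @param a,b semi-major and semi-minor axes in um, \code{a >= b > 0}.
#' @return one-row data.frame in the \code{\link{nuclear_feature_names}}
#'   schema.
#' @examples
#' ellipse_truth_features(2.5, 2.5)   # disk: area ~19.63, circularity ~1
#' @export
ellipse_truth_features <- function(a, b) {
  stopifnot(a >= b, b > 0)
  area <- pi * a * b
  perim <- pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
  data.frame(area_um2 = area, perimeter_um = perim,
             circularity = 4 * pi * area / perim^2,
             max_caliper_um = 2 * a, min_caliper_um = 2 * b,
             eccentricity = sqrt(1 - (b / a)^2))
}

#' Generate a synthetic tile scene of elliptical nuclei
#'
#' Places non-overlapping ellipses uniformly in a square tile: stromal
#' nuclei carry hematoxylin only, DAB-positive (epithelial/leukocyte
#' stand-in) nuclei carry hematoxylin plus a DAB strength above the
#' exclusion threshold. Each nucleus records its analytic truth features,
#' so the full render-deconvolve-segment-measure chain can be checked
#' against closed forms. Deterministic for a fixed seed.
#'
#' @param n_stromal,n_dab_positive nucleus counts (>= 0).
#' @param tile_um tile edge length in um (default 60).
#' @param shape list of shape parameters: means/SDs of the semi-axes in um
#'   and the stain strengths. Defaults emulate benign-PT-like nuclei
#'   (semi-axes ~3.3 x 1.75 um). Set \code{a_sd = b_sd = 0} for exact
#'   shapes.
#' @param seed integer RNG seed (required: scenes are reproducible).
#' @param margin_um clearance kept between nuclei and to the tile border
#'   (default 1.5 um; 0 allows touching).
#' @param max_tries placement retries per nucleus before an infeasible-
#'   packing error (default 2000).
#' @return object of class \code{tile_scene}: data.frame with one row per
#'   nucleus (\code{id, x_um, y_um, a_um, b_um, theta, h_strength,
#'   dab_strength}), truth features in the attribute \code{"truth"}, and
#'   \code{tile_um} in an attribute.
#' @examples
#' sc <- generate_tile_scene(10, 3, seed = 1)
#' attr(sc, "truth")[1, ]
#' @export
generate_tile_scene <- function(n_stromal, n_dab_positive, tile_um = 60,
                                shape = list(), seed, margin_um = 1.5,
                                max_tries = 2000) {
  stopifnot(n_stromal >= 0, n_dab_positive >= 0, tile_um > 0)
  if (missing(seed)) stop("a seed is required for reproducible scenes")
  sh <- utils::modifyList(
    list(a_mean = 3.3, a_sd = 0.3, b_mean = 1.75, b_sd = 0.2,
         h_strength = 0.7, h_sd = 0.05, dab_strength = 0.6),
    shape)
  n <- n_stromal + n_dab_positive
  cols <- c("id", "x_um", "y_um", "a_um", "b_um", "theta",
            "h_strength", "dab_strength")
  if (n == 0) {
    sc <- stats::setNames(as.data.frame(matrix(numeric(), 0, length(cols))),
                          cols)
    attr(sc, "truth") <- ellipse_truth_features(1, 1)[0, ]
    attr(sc, "tile_um") <- tile_um
    class(sc) <- c("tile_scene", "data.frame")
    return(sc)
  }
  set.seed(as.integer(seed))
  a <- pmax(0.5, stats::rnorm(n, sh$a_mean, sh$a_sd))
  b <- pmax(0.3, stats::rnorm(n, sh$b_mean, sh$b_sd))
  swap <- b > a
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  theta <- stats::runif(n, 0, pi)
  hstr <- pmax(0.05, stats::rnorm(n, sh$h_strength, sh$h_sd))
  dstr <- c(rep(0, n_stromal), rep(sh$dab_strength, n_dab_positive))
  # greedy non-overlap placement: centre distance > sum of semi-majors
  # (conservative bound) + margin
  xs <- ys <- numeric(n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      x <- stats::runif(1, a[i] + margin_um, tile_um - a[i] - margin_um)
      y <- stats::runif(1, a[i] + margin_um, tile_um - a[i] - margin_um)
      if (i == 1 ||
          all(sqrt((xs[seq_len(i - 1)] - x)^2 +
                   (ys[seq_len(i - 1)] - y)^2) >
              a[seq_len(i - 1)] + a[i] + margin_um)) {
        xs[i] <- x; ys[i] <- y; placed <- TRUE; break
      }
    }
    if (!placed)
      stop("infeasible packing: could not place nucleus ", i, " of ", n,
           " in a ", tile_um, " um tile after ", max_tries, " tries")
  }
  sc <- data.frame(id = seq_len(n), x_um = xs, y_um = ys, a_um = a,
                   b_um = b, theta = theta, h_strength = hstr,
                   dab_strength = dstr)
  truth <- do.call(rbind, Map(ellipse_truth_features, a, b))
  truth <- cbind(id = sc$id, truth)
  attr(sc, "truth") <- truth
  attr(sc, "tile_um") <- tile_um
  class(sc) <- c("tile_scene", "data.frame")
  sc
}

#' Render a tile scene to an RGB image with ground-truth labels
#'
#' Inverse of colour deconvolution: each pixel's OD is the stain-strength
#' weighted mixture of the stain vectors over the nuclei covering it, and
#' intensity follows Beer-Lambert, \code{I = I0 * 10^(-OD)}, with
#' background pixels at \code{I0}. Optional Gaussian sensor noise (off by
#' default so oracles stay tight) and 8-bit quantisation (on by default,
#' matching scanner output).
#'
#' @param scene a \code{\link{generate_tile_scene}} result.
#' @param sv stain vectors (default \code{\link{hdab_stain_vectors}()}).
#' @param pixel_size um per pixel (default 0.25).
#' @param noise_sd Gaussian intensity noise SD in counts (default 0).
#' @param quantize round to integer 8-bit intensities (default TRUE).
#' @return list with \code{rgb} (h x w x 3 array in \code{[0, I0]}),
#'   \code{label} (integer matrix, each pixel at most one nucleus id) and
#'   \code{pixel_size}.
#' @export
render_tile <- function(scene, sv = hdab_stain_vectors(),
                        pixel_size = 0.25, noise_sd = 0, quantize = TRUE) {
  stopifnot(inherits(scene, "tile_scene"), pixel_size > 0)
  tile_um <- attr(scene, "tile_um")
  npx <- ceiling(tile_um / pixel_size)
  if (nrow(scene) > 0 &&
      any(scene$x_um + scene$a_um > tile_um |
          scene$y_um + scene$a_um > tile_um |
          scene$x_um - scene$a_um < 0 | scene$y_um - scene$a_um < 0))
    stop("tile too small for scene extent")
  hmap <- matrix(0, npx, npx)
  dmap <- matrix(0, npx, npx)
  label <- matrix(0L, npx, npx)
  for (i in seq_len(nrow(scene))) {
    r <- scene[i, ]
    # bounding box in pixel indices (pixel centre of index k is (k-0.5)*ps)
    i0 <- max(1L, floor((r$x_um - r$a_um) / pixel_size))
    i1 <- min(npx, ceiling((r$x_um + r$a_um) / pixel_size) + 1L)
    j0 <- max(1L, floor((r$y_um - r$a_um) / pixel_size))
    j1 <- min(npx, ceiling((r$y_um + r$a_um) / pixel_size) + 1L)
    ii <- i0:i1; jj <- j0:j1
    X <- (matrix(ii, length(ii), length(jj)) - 0.5) * pixel_size - r$x_um
    Y <- (matrix(jj, length(ii), length(jj), byrow = TRUE) - 0.5) *
      pixel_size - r$y_um
    Xr <- X * cos(r$theta) + Y * sin(r$theta)
    Yr <- -X * sin(r$theta) + Y * cos(r$theta)
    inside <- (Xr / r$a_um)^2 + (Yr / r$b_um)^2 <= 1
    sub <- label[ii, jj]
    free <- inside & sub == 0L      # first nucleus claims a contested pixel
    sub[free] <- as.integer(r$id)
    label[ii, jj] <- sub
    hs <- hmap[ii, jj]; hs[free] <- hs[free] + r$h_strength
    hmap[ii, jj] <- hs
    ds <- dmap[ii, jj]; ds[free] <- ds[free] + r$dab_strength
    dmap[ii, jj] <- ds
  }
  rgb <- array(0, c(npx, npx, 3))
  for (ch in 1:3) {
    od <- hmap * sv$hematoxylin[ch] + dmap * sv$dab[ch]
    rgb[, , ch] <- sv$I0 * 10^(-od)
  }
  if (noise_sd > 0)
    rgb <- rgb + array(stats::rnorm(length(rgb), 0, noise_sd), dim(rgb))
  rgb[rgb < 0] <- 0; rgb[rgb > sv$I0] <- sv$I0
  if (quantize) rgb <- round(rgb)
  list(rgb = rgb, label = label, pixel_size = pixel_size)
}

#' Write / read a rendered tile as TIFF
#'
#' The RGB image is written as 8-bit TIFF and the ground-truth label mask
#' as 16-bit TIFF; the micrometre calibration travels in a small JSON
#' sidecar file (\code{<rgb_path>.meta.json}) so a re-read tile keeps its
#' pixel size.
#'
#' @param tile a \code{\link{render_tile}} result.
#' @param rgb_path,label_path output file paths (label optional).
#' @return invisibly, the rgb path.
#' @export
write_tile_tiff <- function(tile, rgb_path, label_path = NULL) {
  tiff::writeTIFF(tile$rgb / 255, rgb_path, bits.per.sample = 8L,
                  reduce = TRUE)
  jsonlite::write_json(list(pixel_size_um = tile$pixel_size),
                       paste0(rgb_path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(label_path))
    tiff::writeTIFF(tile$label / 65535, label_path, bits.per.sample = 16L,
                    reduce = TRUE)
  invisible(rgb_path)
}

#' @rdname write_tile_tiff
#' @param rgb_path path of a tile written by \code{write_tile_tiff}.
#' @export
read_tile_tiff <- function(rgb_path) {
  img <- tiff::readTIFF(rgb_path)
  meta <- paste0(rgb_path, ".meta.json")
  pixel_size <- if (file.exists(meta))
    jsonlite::read_json(meta)$pixel_size_um else NA_real_
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  list(rgb = img * 255, pixel_size = pixel_size)
}

#' Run the measurement pipeline on one rendered tile
#'
#' Convenience composition of the full chain on a rendered (or scanned)
#' tile: OD conversion, colour deconvolution, nucleus segmentation, DAB
#' exclusion and feature measurement.
#'
#' @param tile list with \code{rgb} and \code{pixel_size} (a
#'   \code{\link{render_tile}} result or \code{\link{read_tile_tiff}}).
#' @param sv stain vectors.
#' @param params \code{\link{segmentation_params}}; its \code{pixel_size}
#'   is overridden by the tile's.
#' @return list with the \code{segmentation} and the per-nucleus
#'   \code{features} data.frame (retained nuclei only).
#' @export
measure_tile <- function(tile, sv = hdab_stain_vectors(),
                         params = segmentation_params()) {
  params$pixel_size <- tile$pixel_size
  od <- rgb_to_od(tile$rgb, I0 = sv$I0)
  st <- deconvolve_stains(od, sv)
  seg <- segment_nuclei(st$hematoxylin, params)
  seg <- exclude_dab_positive(seg, st$dab, params)
  list(segmentation = seg, features = measure_nuclei(seg))
}
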