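#' Polygon area and perimeter
#'
#' Area by the shoelace formula (absolute value, so traversal direction is
#' irrelevant) and perimeter as the sum of edge lengths, for a closed simple
#' polygon given as an n x 2 vertex matrix in calibrated micrometre
#' coordinates. The closing edge is implicit.
#'
#' @param poly numeric matrix, n >= 3 rows, columns x and y (um).
#' @param check if TRUE (default), reject self-intersecting polygons.
#' @return named numeric vector \code{c(area =, perimeter =)} in um^2 / um.
#' @examples
#' sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' polygon_area_perimeter(sq)   # area 1, perimeter 4
#' @export
polygon_area_perimeter <- function(poly, check = TRUE) {
  poly <- as.matrix(poly)
  if (nrow(poly) < 3 || ncol(poly) != 2)
    stop("polygon needs >= 3 vertices and 2 columns")
  if (check && polygon_self_intersects(poly))
    stop("polygon is self-intersecting")
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  area <- abs(sum(x * yn - xn * y)) / 2
  perimeter <- sum(sqrt((xn - x)^2 + (yn - y)^2))
  c(area = area, perimeter = perimeter)
}

# Segment-pair sweep; O(n^2) but nucleus contours are small. Shared
# endpoints between adjacent edges are not intersections.
polygon_self_intersects <- function(poly) {
  n <- nrow(poly)
  if (n < 4) return(FALSE)
  p <- rbind(poly, poly[1, ])
  seg_int <- function(a1, a2, b1, b2) {
    d1 <- cross2(b2 - b1, a1 - b1); d2 <- cross2(b2 - b1, a2 - b1)
    d3 <- cross2(a2 - a1, b1 - a1); d4 <- cross2(a2 - a1, b2 - a1)
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      if (j == i || j == i + 1 || (i == 1 && j == n)) next
      if (seg_int(p[i, ], p[i + 1, ], p[j, ], p[j + 1, ])) return(TRUE)
    }
  }
  FALSE
}

cross2 <- function(u, v) u[1] * v[2] - u[2] * v[1]

#' Circularity of a shape
#'
#' \code{4 * pi * area / perimeter^2}: 1 for a perfect circle, approaching 0
#' for elongated shapes. By the isoperimetric inequality no simple polygon
#' exceeds 1.
#'
#' @param area,perimeter positive numerics (um^2, um); vectorised.
#' @return dimensionless circularity in (0, 1].
#' @examples
#' circularity(pi * 2.5^2, 2 * pi * 2.5)   # 1
#' circularity(1, 4)                       # square: pi/4
#' @export
circularity <- function(area, perimeter) {
  if (any(area <= 0) || any(perimeter <= 0))
    stop("area and perimeter must be positive")
  4 * pi * area / perimeter^2
}

#' Maximum and minimum caliper (Feret) diameters
#'
#' The maximum caliper is the diameter of the convex hull (largest pairwise
#' vertex distance); the minimum caliper is the width, i.e. the smallest
#' distance between parallel supporting lines, attained perpendicular to a
#' hull edge (the rotating-calipers result). Concave shapes inherit the
#' calipers of their hull.
#'
#' @param poly n x 2 vertex matrix (um), n >= 3.
#' @return named vector \code{c(max_caliper =, min_caliper =)} in um. A
#'   degenerate (collinear) polygon yields \code{min_caliper = 0} with a
#'   warning.
#' @examples
#' rect <- cbind(c(0, 3, 3, 0), c(0, 0, 4, 4))
#' caliper_diameters(rect)   # diagonal 5, width 3
#' @export
caliper_diameters <- function(poly) {
  poly <- as.matrix(poly)
  if (nrow(poly) < 3 || ncol(poly) != 2)
    stop("polygon needs >= 3 vertices and 2 columns")
  h <- grDevices::chull(poly)
  hull <- poly[h, , drop = FALSE]
  nh <- nrow(hull)
  if (nh < 3) {
    warning("degenerate (collinear) polygon; min_caliper = 0")
    d <- if (nh == 1) 0 else max(stats::dist(poly))
    return(c(max_caliper = d, min_caliper = 0))
  }
  max_cal <- max(stats::dist(hull))
  # width: for each hull edge direction, the farthest vertex distance from
  # the edge's supporting line; minimum over edges.
  width <- Inf
  for (i in seq_len(nh)) {
    j <- i %% nh + 1
    e <- hull[j, ] - hull[i, ]
    len <- sqrt(sum(e^2))
    if (len < .Machine$double.eps) next
    nrm <- c(-e[2], e[1]) / len
    d <- abs(sweep(hull, 2, hull[i, ]) %*% nrm)
    width <- min(width, max(d))
  }
  c(max_caliper = max_cal, min_caliper = width)
}

#' Eccentricity from second-order moments
#'
#' Elongation of the moment-equivalent ellipse,
#' \eqn{\sqrt{1 - (b/a)^2}} where \eqn{a \ge b} are its semi-axes: 0 for a
#' circle, approaching 1 for a sliver. Accepts either a logical/0-1 pixel
#' mask (moments over pixel coordinates, the regionprops convention) or a
#' boundary polygon (exact polygon moments via Green's theorem).
#'
#' @param x logical or 0/1 matrix mask, or an n x 2 vertex matrix.
#' @return dimensionless eccentricity in \code{[0, 1)}.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 256)[-1]
#' shape_eccentricity(cbind(2 * cos(th), sin(th)))   # a = 2b: ~0.866
#' @export
shape_eccentricity <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) == 2 && !all(x %in% c(0, 1, TRUE, FALSE))) {
    mom <- polygon_central_moments(x)
  } else {
    ij <- which(x != 0, arr.ind = TRUE)
    if (nrow(ij) == 0) stop("empty mask")
    cx <- mean(ij[, 1]); cy <- mean(ij[, 2])
    mom <- c(mu20 = mean((ij[, 1] - cx)^2),
             mu02 = mean((ij[, 2] - cy)^2),
             mu11 = mean((ij[, 1] - cx) * (ij[, 2] - cy)))
  }
  tr <- mom["mu20"] + mom["mu02"]
  det2 <- sqrt((mom["mu20"] - mom["mu02"])^2 + 4 * mom["mu11"]^2)
  l1 <- (tr + det2) / 2
  l2 <- (tr - det2) / 2
  if (l1 <= 0) stop("degenerate shape: zero second moment")
  unname(sqrt(max(0, 1 - l2 / l1)))
}

# Normalised central moments of a simple polygon (area-weighted), by the
# standard Green's-theorem formulas; orientation-independent.
polygon_central_moments <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  a <- x * yn - xn * y
  A <- sum(a) / 2
  if (abs(A) < .Machine$double.eps) stop("degenerate polygon: zero area")
  cx <- sum((x + xn) * a) / (6 * A)
  cy <- sum((y + yn) * a) / (6 * A)
  x0 <- x - cx; y0 <- y - cy
  xn0 <- xn - cx; yn0 <- yn - cy
  a0 <- x0 * yn0 - xn0 * y0
  mu20 <- sum(a0 * (x0^2 + x0 * xn0 + xn0^2)) / 12
  mu02 <- sum(a0 * (y0^2 + y0 * yn0 + yn0^2)) / 12
  mu11 <- sum(a0 * (2 * x0 * y0 + x0 * yn0 + xn0 * y0 + 2 * xn0 * yn0)) / 24
  s <- sign(A)
  c(mu20 = s * mu20 / abs(A), mu02 = s * mu02 / abs(A),
    mu11 = s * mu11 / abs(A))
}

#' Six nuclear shape features for one segmented nucleus
#'
#' Composes the descriptor operations on a nucleus from a
#' \code{\link{segment_nuclei}} result: area and perimeter from the traced
#' boundary polygon with a half-pixel boundary correction, circularity from
#' those, calipers from the raw contour's convex hull (plus the same
#' half-pixel correction), and eccentricity from the pixel-mask moments.
#' All lengths scale linearly and areas quadratically with
#' \code{pixel_size}.
#'
#' The correction treats traced vertices (pixel centres) as lying half a
#' pixel inside the true stain boundary and measures the outward parallel
#' body at distance 1/2 px: perimeter gains \code{pi} px and area gains
#' \code{P/2 + pi/4} px^2. The corrected pair still satisfies
#' \code{4*pi*area <= perimeter^2} whenever the uncorrected polygon does,
#' so circularity never exceeds 1.
#'
#' @param contour_px n x 2 matrix of raw boundary coordinates in pixel
#'   units (pixel centres).
#' @param mask logical matrix, the nucleus pixel mask (for eccentricity).
#' @param pixel_size um per pixel.
#' @param contour_smooth odd integer window of the circular moving-average
#'   vertex smoothing applied before area/perimeter measurement (default 5;
#'   1 disables).
#' @return one-row data.frame: \code{area_um2, perimeter_um, circularity,
#'   max_caliper_um, min_caliper_um, eccentricity}.
#' @seealso \code{\link{segment_nuclei}}, which calls this for every
#'   retained nucleus.
#' @export
compute_nucleus_features <- function(contour_px, mask, pixel_size,
                                     contour_smooth = 5) {
  stopifnot(pixel_size > 0)
  sp <- smooth_polygon(contour_px, contour_smooth)
  ap <- polygon_area_perimeter(sp, check = FALSE)
  P_px <- ap["perimeter"] + pi
  A_px <- ap["area"] + ap["perimeter"] / 2 + pi / 4
  cal <- caliper_diameters(contour_px) + 0.5
  ecc <- shape_eccentricity(mask)
  data.frame(area_um2 = unname(A_px) * pixel_size^2,
             perimeter_um = unname(P_px) * pixel_size,
             circularity = unname(4 * pi * A_px / P_px^2),
             max_caliper_um = unname(cal["max_caliper"]) * pixel_size,
             min_caliper_um = unname(cal["min_caliper"]) * pixel_size,
             eccentricity = ecc)
}

# circular moving average of polygon vertices; window w (odd), w <= n
smooth_polygon <- function(poly, w) {
  n <- nrow(poly)
  if (w < 3 || n < w) return(poly)
  k <- (w - 1) %/% 2
  idx <- function(i) ((i - 1) %% n) + 1
  out <- poly
  for (i in seq_len(n))
    out[i, ] <- colMeans(poly[idx((i - k):(i + k)), , drop = FALSE])
  out
}

#' Aggregate per-nucleus features to a case summary
#'
#' Mean, median (average-of-middle-two), min and max for each of the six
#' features over all retained nuclei of a case, plus the nucleus count. The
#' per-case mean is the value consumed by the diagnostic scores; median and
#' range are diagnostics.
#'
#' @param features data.frame with the six feature columns (one row per
#'   nucleus), e.g. rbind-ed \code{\link{compute_nucleus_features}} output.
#' @param case_id scalar identifier.
#' @return data.frame with one row per feature and columns \code{case_id,
#'   feature, mean, median, min, max, n}.
#' @export
summarize_case <- function(features, case_id) {
  cols <- nuclear_feature_names()
  missing_cols <- setdiff(cols, names(features))
  if (length(missing_cols))
    stop("missing feature columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(features) == 0)
    stop("case ", case_id, " has zero retained nuclei and cannot be scored")
  do.call(rbind, lapply(cols, function(f) {
    v <- features[[f]]
    data.frame(case_id = case_id, feature = f, mean = mean(v),
               median = stats::median(v), min = min(v), max = max(v),
               n = length(v))
  }))
}

#' @rdname summarize_case
#' @export
nuclear_feature_names <- function() {
  c("area_um2", "perimeter_um", "circularity",
    "max_caliper_um", "min_caliper_um", "eccentricity")
}
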