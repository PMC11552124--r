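# Geometry fixtures and independent oracles used across test files.

# regular n-gon of circumradius r (approximates a circle for large n)
regular_polygon <- function(n, r = 1, cx = 0, cy = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}

# rasterized ellipse mask, semi-axes in pixels, optional rotation
rasterize_ellipse <- function(a_px, b_px, theta = 0, pad = 5) {
  ext <- ceiling(max(a_px, b_px)) + pad
  n <- 2 * ext + 1
  xs <- matrix(rep(seq_len(n), n), n) - (ext + 1)
  ys <- t(xs)
  xr <- xs * cos(theta) + ys * sin(theta)
  yr <- -xs * sin(theta) + ys * cos(theta)
  (xr / a_px)^2 + (yr / b_px)^2 <= 1
}

# brute-force caliper oracle: projection span over a dense direction grid.
# The width minimum sits flush against a polygon edge where the span
# function is kinked, so the grid alone converges only linearly; the edge
# normal angles are added to the direction set to capture the exact minima.
brute_calipers <- function(poly, n_dir = 3600) {
  th <- seq(0, pi, length.out = n_dir + 1)[-(n_dir + 1)]
  e <- diff(rbind(poly, poly[1, ]))
  th <- c(th, atan2(e[, 2], e[, 1]) + pi / 2)
  spans <- vapply(th, function(t) {
    p <- poly[, 1] * cos(t) + poly[, 2] * sin(t)
    max(p) - min(p)
  }, 0)
  c(max_caliper = max(spans), min_caliper = min(spans))
}

# random convex polygon: convex hull of random points
random_convex_polygon <- function(n_pts = 30, scale = 3) {
  p <- matrix(stats::runif(2 * n_pts, -scale, scale), ncol = 2)
  h <- grDevices::chull(p)
  p[h, , drop = FALSE]
}

# independent log-rank oracle: direct O-E / V sum over event times
brute_logrank <- function(group, times, events) {
  g <- as.integer(factor(group)) - 1L
  ts <- sort(unique(times[events == 1]))
  O1 <- E1 <- V <- 0
  for (t in ts) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d <- sum(events == 1 & times == t)
    d1 <- sum(events == 1 & times == t & g == 1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}

# brute-force AUC: concordant pair fraction with half-credit ties
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# shared small rendered-scene fixture (built once per test run)
small_scene_tile <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sc <- generate_tile_scene(10, 3, seed = 11)
      cache <<- list(scene = sc, tile = render_tile(sc))
    }
    cache
  }
})
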