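#' Segmentation parameter set
#'
#' Parameters of the stromal-nucleus detector. The hematoxylin-OD threshold
#' and DAB-exclusion threshold mirror the thresholding stage of QuPath-style
#' cell detection; exact values are calibration choices, so all are plain
#' configuration with documented defaults.
#'
#' @param h_threshold foreground threshold on smoothed hematoxylin OD
#'   (default 0.1).
#' @param dab_threshold mean-DAB-OD exclusion threshold per nucleus
#'   (default 0.2).
#' @param min_area_um2,max_area_um2 retained-nucleus area bounds in um^2
#'   (defaults 5 and 100).
#' @param smoothing_um Gaussian pre-smoothing scale in um (default 0.5).
#' @param pixel_size calibration in um per pixel (default 0.25).
#' @param contour_smooth vertex-smoothing window for boundary tracing
#'   (odd integer, default 5).
#' @param refine boundary refinement after watershed: \code{"halfmax"}
#'   (default) re-thresholds each detected nucleus at half its peak
#'   edge-map OD, which localises a blurred step edge at the true stain
#'   boundary; \code{"none"} keeps the raw threshold mask (whose boundary
#'   is dilated by roughly the smoothing scale).
#' @param edge_smoothing_um smoothing scale of the edge-localisation map
#'   used by the half-max refinement. Boundary displacement of a curved
#'   edge grows with the square of the blur scale, so the edge map wants
#'   the lightest blur that still suppresses pixel noise; default half of
#'   \code{smoothing_um}.
#' @return a \code{segmentation_params} list.
#' @export
segmentation_params <- function(h_threshold = 0.1, dab_threshold = 0.2,
                                min_area_um2 = 5, max_area_um2 = 100,
                                smoothing_um = 0.5, pixel_size = 0.25,
                                contour_smooth = 5,
                                refine = c("halfmax", "none"),
                                edge_smoothing_um = smoothing_um / 2) {
  stopifnot(h_threshold >= 0, dab_threshold >= 0,
            min_area_um2 > 0, min_area_um2 < max_area_um2,
            smoothing_um >= 0, edge_smoothing_um >= 0, pixel_size > 0)
  structure(list(h_threshold = h_threshold, dab_threshold = dab_threshold,
                 min_area_um2 = min_area_um2, max_area_um2 = max_area_um2,
                 smoothing_um = smoothing_um, pixel_size = pixel_size,
                 contour_smooth = contour_smooth,
                 refine = match.arg(refine),
                 edge_smoothing_um = edge_smoothing_um),
            class = "segmentation_params")
}

#' Segment nuclei from a hematoxylin optical-density map
#'
#' Threshold-plus-watershed nucleus detection: the OD map is Gaussian
#' smoothed, thresholded, touching nuclei are split by watershed on the
#' distance transform of the foreground, components outside the calibrated
#' area bounds are discarded, and each retained nucleus gets a traced
#' boundary contour and per-nucleus mean ODs. An optional region-of-interest
#' mask (the pathologist-annotated stromal compartment) restricts detection
#' to nuclei whose centroid falls inside it.
#'
#' @param h_map numeric matrix of hematoxylin OD
#'   (\code{\link{deconvolve_stains}} output).
#' @param params a \code{\link{segmentation_params}} object.
#' @param roi optional logical matrix of the same dimensions; nuclei with
#'   centroid outside are dropped. Default: whole tile.
#' @return object of class \code{labeled_segmentation}: list with
#'   \code{labels} (integer matrix, 0 = background), \code{nuclei}
#'   (data.frame: \code{nucleus_id, centroid_x_px, centroid_y_px,
#'   area_px, mean_h_od, mean_dab_od, dab_excluded}), \code{contours}
#'   (list of n x 2 pixel-coordinate matrices) and \code{params}. An empty
#'   result is valid.
#' @export
segment_nuclei <- function(h_map, params = segmentation_params(),
                           roi = NULL) {
  stopifnot(is.matrix(h_map), inherits(params, "segmentation_params"))
  sigma_px <- params$smoothing_um / params$pixel_size
  sm <- if (sigma_px > 0.3) {
    as.matrix(EBImage::gblur(EBImage::Image(h_map), sigma = sigma_px))
  } else h_map
  fg <- sm >= params$h_threshold
  empty <- function() {
    structure(list(labels = matrix(0L, nrow(h_map), ncol(h_map)),
                   nuclei = empty_nucleus_table(),
                   contours = list(), params = params),
              class = "labeled_segmentation")
  }
  if (!any(fg)) return(empty())
  dm <- EBImage::distmap(EBImage::Image(fg))
  lab <- as.matrix(EBImage::watershed(dm, tolerance = 1, ext = 1))
  storage.mode(lab) <- "integer"
  if (params$refine == "halfmax" && max(lab) > 0) {
    sigma_edge <- params$edge_smoothing_um / params$pixel_size
    sme <- if (sigma_edge > 0.3) {
      as.matrix(EBImage::gblur(EBImage::Image(h_map), sigma = sigma_edge))
    } else h_map
    ref <- matrix(0L, nrow(lab), ncol(lab))
    for (k in seq_len(max(lab))) {
      m <- lab == k
      cut <- max(params$h_threshold, 0.5 * max(sme[m]))
      mr <- m & sme >= cut
      if (!any(mr)) next
      # refinement can in principle disconnect a component; keep the
      # largest piece so each nucleus stays one connected region
      cc <- as.matrix(EBImage::bwlabel(EBImage::Image(mr * 1)))
      sizes <- tabulate(cc[cc > 0])
      ref[cc == which.max(sizes)] <- k
    }
    lab <- ref
  }
  # area filter in pixel units
  px_area <- tabulate(lab[lab > 0])
  lo <- params$min_area_um2 / params$pixel_size^2
  hi <- params$max_area_um2 / params$pixel_size^2
  keep <- which(px_area >= lo & px_area <= hi)
  if (length(keep) == 0) return(empty())
  relut <- integer(max(lab))
  relut[keep] <- seq_along(keep)
  lab[lab > 0] <- relut[lab[lab > 0]]
  contours <- EBImage::ocontour(EBImage::Image(lab))
  ids <- seq_along(keep)
  cx <- cy <- ar <- mh <- numeric(length(ids))
  for (k in ids) {
    ij <- which(lab == k, arr.ind = TRUE)
    cx[k] <- mean(ij[, 1]); cy[k] <- mean(ij[, 2])
    ar[k] <- nrow(ij)
    mh[k] <- mean(h_map[ij])
  }
  nuc <- data.frame(nucleus_id = ids, centroid_x_px = cx,
                    centroid_y_px = cy, area_px = ar, mean_h_od = mh,
                    mean_dab_od = NA_real_, dab_excluded = FALSE)
  if (!is.null(roi)) {
    stopifnot(is.logical(roi), all(dim(roi) == dim(h_map)))
    inside <- roi[cbind(pmin(pmax(round(cx), 1), nrow(roi)),
                        pmin(pmax(round(cy), 1), ncol(roi)))]
    drop_ids <- nuc$nucleus_id[!inside]
    if (length(drop_ids)) {
      lab[lab %in% drop_ids] <- 0L
      keep2 <- which(inside)
      relut2 <- integer(length(ids)); relut2[keep2] <- seq_along(keep2)
      lab[lab > 0] <- relut2[lab[lab > 0]]
      nuc <- nuc[inside, , drop = FALSE]
      nuc$nucleus_id <- seq_len(nrow(nuc))
      contours <- contours[keep2]
      rownames(nuc) <- NULL
    }
  }
  structure(list(labels = lab, nuclei = nuc, contours = contours,
                 params = params),
            class = "labeled_segmentation")
}

empty_nucleus_table <- function() {
  data.frame(nucleus_id = integer(), centroid_x_px = numeric(),
             centroid_y_px = numeric(), area_px = numeric(),
             mean_h_od = numeric(), mean_dab_od = numeric(),
             dab_excluded = logical())
}

#' @export
print.labeled_segmentation <- function(x, ...) {
  cat(sprintf("labeled_segmentation: %d nuclei (%d DAB-excluded) on %d x %d px\n",
              nrow(x$nuclei), sum(x$nuclei$dab_excluded),
              nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

#' Flag DAB-positive nuclei for exclusion
#'
#' Stromal morphometry must not include epithelial or leukocyte nuclei;
#' these are marked by the DAB chromogen (cytokeratin / LCA cocktail). A
#' nucleus is flagged excluded iff its mean DAB OD over the nucleus pixels
#' exceeds the threshold; retained nuclei are the unflagged ones.
#'
#' @param seg a \code{\link{segment_nuclei}} result.
#' @param dab_map numeric matrix of DAB OD, same geometry as the
#'   segmentation.
#' @param params \code{\link{segmentation_params}} supplying
#'   \code{dab_threshold}; defaults to the one stored in \code{seg}.
#' @return \code{seg} with \code{mean_dab_od} filled and
#'   \code{dab_excluded} set.
#' @export
exclude_dab_positive <- function(seg, dab_map, params = seg$params) {
  stopifnot(inherits(seg, "labeled_segmentation"),
            all(dim(dab_map) == dim(seg$labels)))
  for (k in seg$nuclei$nucleus_id) {
    seg$nuclei$mean_dab_od[seg$nuclei$nucleus_id == k] <-
      mean(dab_map[seg$labels == k])
  }
  seg$nuclei$dab_excluded <- seg$nuclei$mean_dab_od > params$dab_threshold
  seg
}

#' Measure nuclear features for all retained nuclei of a segmentation
#'
#' Runs \code{\link{compute_nucleus_features}} on every nucleus not flagged
#' by \code{\link{exclude_dab_positive}} (or on all nuclei when
#' \code{include_excluded = TRUE}, with the flag carried in the output).
#'
#' @param seg a \code{labeled_segmentation}.
#' @param include_excluded measure DAB-excluded nuclei too (default FALSE).
#' @return data.frame with \code{nucleus_id}, the six feature columns and
#'   \code{dab_excluded}; zero rows if nothing retained.
#' @export
measure_nuclei <- function(seg, include_excluded = FALSE) {
  stopifnot(inherits(seg, "labeled_segmentation"))
  ids <- seg$nuclei$nucleus_id
  if (!include_excluded) ids <- ids[!seg$nuclei$dab_excluded]
  out <- lapply(ids, function(k) {
    ft <- compute_nucleus_features(
      seg$contours[[k]], seg$labels == k,
      pixel_size = seg$params$pixel_size,
      contour_smooth = seg$params$contour_smooth)
    cbind(nucleus_id = k, ft,
          dab_excluded = seg$nuclei$dab_excluded[seg$nuclei$nucleus_id == k])
  })
  if (length(out) == 0) {
    return(cbind(data.frame(nucleus_id = integer()),
                 stats::setNames(as.data.frame(matrix(numeric(), 0, 6)),
                                 nuclear_feature_names()),
                 data.frame(dab_excluded = logical())))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Axis-aligned tiling of a slide extent
#'
#' Covers a rectangular extent with a grid of tiles (default 2000 um
#' square, the tiling used for whole-slide morphometry); edge tiles are
#' truncated to the extent. Nuclei are assigned to exactly one tile by
#' centroid via \code{\link{assign_tile}}, so per-tile counts sum to the
#' total.
#'
#' @param extent_um numeric length-2, slide width and height in um.
#' @param tile_size_um tile edge length in um (default 2000).
#' @return data.frame: \code{tile_id, x0, y0, x1, y1} (um, half-open
#'   \code{[x0, x1)} except the final row/column which closes the extent).
#' @examples
#' nrow(tile_grid(c(5000, 5000)))   # 9 tiles, edge tiles 1000 um
#' @export
tile_grid <- function(extent_um, tile_size_um = 2000) {
  stopifnot(length(extent_um) == 2, all(extent_um > 0), tile_size_um > 0)
  nx <- ceiling(extent_um[1] / tile_size_um)
  ny <- ceiling(extent_um[2] / tile_size_um)
  g <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
  data.frame(tile_id = seq_len(nrow(g)),
             x0 = (g$ix - 1) * tile_size_um,
             y0 = (g$iy - 1) * tile_size_um,
             x1 = pmin(g$ix * tile_size_um, extent_um[1]),
             y1 = pmin(g$iy * tile_size_um, extent_um[2]))
}

#' @rdname tile_grid
#' @param x,y centroid coordinates in um (vectorised); points on a shared
#'   tile boundary belong to the lower-index tile, so assignment is a
#'   partition.
#' @param extent_um as in \code{tile_grid}.
#' @return \code{assign_tile}: integer tile ids matching \code{tile_grid}.
#' @export
assign_tile <- function(x, y, extent_um, tile_size_um = 2000) {
  stopifnot(all(x >= 0 & x <= extent_um[1]),
            all(y >= 0 & y <= extent_um[2]))
  nx <- ceiling(extent_um[1] / tile_size_um)
  ix <- pmax(1, pmin(nx, ceiling(x / tile_size_um)))
  ny <- ceiling(extent_um[2] / tile_size_um)
  iy <- pmax(1, pmin(ny, ceiling(y / tile_size_um)))
  as.integer((iy - 1) * nx + ix)
}
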