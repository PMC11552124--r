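#' Stain vector sets for colour deconvolution
#'
#' A stain vector set holds unit-norm optical-density (OD) vectors for
#' hematoxylin, DAB and a residual channel, plus the background intensity
#' \code{I0}. The residual vector completes the basis as the normalised
#' cross product of the hematoxylin and DAB vectors, so the 3x3 stain
#' matrix is always invertible for non-collinear H and D.
#'
#' @param hematoxylin,dab numeric length-3 OD-per-RGB-channel vectors;
#'   normalised internally. Must be non-negative and non-collinear.
#' @param I0 background (unstained) intensity, default 255 for 8-bit input.
#' @return An object of class \code{stain_vectors}: list with unit vectors
#'   \code{hematoxylin}, \code{dab}, \code{residual}, the stain matrix
#'   \code{M} (columns H, D, residual), its condition number \code{kappa},
#'   and \code{I0}.
#' @examples
#' sv <- hdab_stain_vectors()
#' sv$kappa
#' @export
stain_vectors <- function(hematoxylin, dab, I0 = 255) {
  stopifnot(length(hematoxylin) == 3, length(dab) == 3, I0 > 0)
  if (any(hematoxylin < 0) || any(dab < 0))
    stop("stain vectors must be non-negative")
  h <- hematoxylin / sqrt(sum(hematoxylin^2))
  d <- dab / sqrt(sum(dab^2))
  r <- c(h[2] * d[3] - h[3] * d[2],
         h[3] * d[1] - h[1] * d[3],
         h[1] * d[2] - h[2] * d[1])
  nr <- sqrt(sum(r^2))
  if (nr < 1e-8) stop("hematoxylin and DAB vectors are collinear")
  r <- r / nr
  M <- cbind(hematoxylin = h, dab = d, residual = r)
  structure(
    list(hematoxylin = h, dab = d, residual = r, M = M,
         kappa = kappa(M, exact = TRUE), I0 = I0),
    class = "stain_vectors")
}

#' @describeIn stain_vectors Standard H-DAB vectors (Ruifrok-Johnston
#'   values), the defaults throughout the package; override for a scanner-
#'   specific calibration.
#' @export
hdab_stain_vectors <- function(I0 = 255) {
  stain_vectors(hematoxylin = c(0.65, 0.70, 0.29),
                dab = c(0.27, 0.57, 0.78), I0 = I0)
}

#' @export
print.stain_vectors <- function(x, ...) {
  cat("H-DAB stain vectors (unit OD per RGB channel)\n")
  print(round(x$M, 4))
  cat(sprintf("condition number %.3f, I0 = %g\n", x$kappa, x$I0))
  invisible(x)
}

#' Read or write stain vectors as JSON
#'
#' @param path file path.
#' @param sv a \code{\link{stain_vectors}} object.
#' @return \code{read_stain_vectors} returns a \code{stain_vectors} object;
#'   \code{write_stain_vectors} invisibly returns \code{path}.
#' @export
read_stain_vectors <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  stain_vectors(j$hematoxylin, j$dab, I0 = if (is.null(j$I0)) 255 else j$I0)
}

#' @rdname read_stain_vectors
#' @export
write_stain_vectors <- function(sv, path) {
  stopifnot(inherits(sv, "stain_vectors"))
  jsonlite::write_json(
    list(hematoxylin = sv$hematoxylin, dab = sv$dab, I0 = sv$I0),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Convert an RGB image to optical density
#'
#' Per-channel Beer-Lambert absorbance: \code{OD = log10(I0 / max(I, eps))}
#' with \code{eps} one intensity count guarding the logarithm at zero
#' intensity. Background pixels at \code{I0} map to exactly 0 OD and OD is
#' monotone decreasing in intensity.
#'
#' @param img numeric array \code{h x w x 3} (or a length-3 vector for a
#'   single pixel) with intensities in \code{[0, I0]}.
#' @param I0 background intensity (default 255).
#' @param eps floor applied to intensities before the log (default 1 count).
#' @return array (or vector) of the same shape, OD values \eqn{\ge 0}.
#' @examples
#' rgb_to_od(c(26, 26, 26))           # ~0.9916 per channel
#' rgb_to_od(c(255, 255, 255))        # background -> 0
#' @export
rgb_to_od <- function(img, I0 = 255, eps = 1) {
  if (is.null(dim(img))) {
    if (length(img) != 3) stop("expected 3 channels")
  } else if (length(dim(img)) != 3 || dim(img)[3] != 3) {
    stop("expected an h x w x 3 array")
  }
  if (any(img < 0) || any(img > I0)) stop("intensities must lie in [0, I0]")
  log10(I0 / pmax(img, eps))
}

#' Colour deconvolution of an OD image into stain strengths
#'
#' Solves the linear Beer-Lambert mixture \code{OD = M s} per pixel by
#' inverting the 3x3 stain matrix, the standard brightfield unmixing of
#' hematoxylin and DAB. Small negative strengths (noise outside the stain
#' simplex) are clipped to zero; the fraction of clipped pixel-channels is
#' attached as a diagnostic.
#'
#' @param od OD array \code{h x w x 3} from \code{\link{rgb_to_od}}, or a
#'   length-3 OD vector.
#' @param sv a \code{\link{stain_vectors}} object.
#' @return list with matrices (or scalars) \code{hematoxylin}, \code{dab},
#'   \code{residual} and the numeric \code{clipped_fraction}.
#' @examples
#' sv <- hdab_stain_vectors()
#' deconvolve_stains(0.5 * sv$hematoxylin + 0.3 * sv$dab, sv)
#' @export
deconvolve_stains <- function(od, sv) {
  stopifnot(inherits(sv, "stain_vectors"))
  Minv <- solve(sv$M)
  single <- is.null(dim(od))
  if (single) {
    s <- drop(Minv %*% od)
  } else {
    d <- dim(od)
    flat <- matrix(od, ncol = 3)        # pixels x channels
    s <- flat %*% t(Minv)               # pixels x stains
  }
  clipped <- mean(s < -1e-12)
  s[s < 0] <- 0
  if (single) {
    out <- list(hematoxylin = unname(s[1]), dab = unname(s[2]),
                residual = unname(s[3]))
  } else {
    out <- list(hematoxylin = matrix(s[, 1], d[1], d[2]),
                dab = matrix(s[, 2], d[1], d[2]),
                residual = matrix(s[, 3], d[1], d[2]))
  }
  out$clipped_fraction <- clipped
  out
}
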