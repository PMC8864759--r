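#' Extract the green channel of an RGB field image
#'
#' Hematoxylin-stained nuclei absorb green light most strongly, so of the
#' three channels the green one carries the highest nucleus/background
#' contrast; the whole downstream pipeline operates on it alone.
#'
#' @param img Integer array `H x W x 3` with values 0-255.
#' @return Numeric matrix `H x W` (values 0-255).
#' @export
extract_green <- function(img) {
  stopifnot(length(dim(img)) == 3, dim(img)[3] >= 2)
  g <- img[, , 2]
  storage.mode(g) <- "double"
  g
}

#' Subtract a smooth illumination background from a grayscale image
#'
#' Estimates the background as the grayscale morphological closing of the
#' image with a disc structuring element (for dark objects on a bright
#' field, closing removes every object smaller than the disc and leaves the
#' smooth illumination surface), then returns `255 + img - background`,
#' clipped to \[0, 255\]. The background therefore maps to a flat bright
#' level while object/background contrast is preserved; a flat input maps to
#' a flat output.
#'
#' @param img Numeric matrix, values 0-255.
#' @param rolling_radius_px Disc radius in pixels; must exceed the nuclear
#'   radius and be smaller than the image. Default 50.
#' @return Numeric matrix 0-255, same size.
#' @export
subtract_background <- function(img, rolling_radius_px = 50L) {
  r <- as.integer(rolling_radius_px)
  if (r < 1) stop("rolling_radius_px must be >= 1")
  if (2 * r + 1 > min(dim(img))) stop("rolling_radius_px larger than the image")
  H <- nrow(img); W <- ncol(img)
  # replicate-pad by the radius so the closing sees no artificial border
  ri <- min(r, H - 1L); rj <- min(r, W - 1L)
  pad <- img[c(rep(1L, ri), 1:H, rep(H, ri)), c(rep(1L, rj), 1:W, rep(W, rj))]
  brush <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
  bg <- as.matrix(EBImage::closing(pad / 255, brush)) * 255
  bg <- bg[(ri + 1):(ri + H), (rj + 1):(rj + W)]
  matrix(round(clip255(255 + img - bg)), H, W)
}

#' Automatic histogram threshold and nucleus mask
#'
#' Computes an automatic threshold on the 256-bin gray histogram and returns
#' the dark-object mask `img <= threshold` (nuclei are dark on a bright
#' field). Two classic methods are available: Otsu (maximise between-class
#' variance; default) and IsoData (iterative intermeans). A constant image
#' has no separable classes: the result is an empty mask flagged
#' `degenerate = TRUE` rather than an error.
#'
#' @param img Numeric matrix, values 0-255 (rounded to integers internally).
#' @param method `"otsu"` or `"isodata"`.
#' @return List with `threshold` (0-255, or `NA` if degenerate), `mask`
#'   (logical matrix, `TRUE` = nucleus pixel) and `degenerate` (logical).
#' @export
auto_threshold <- function(img, method = c("otsu", "isodata")) {
  method <- match.arg(method)
  if (length(img) == 0) stop("empty image")
  v <- as.integer(round(clip255(img)))
  h <- tabulate(v + 1L, nbins = 256L)
  if (sum(h > 0) < 2) {
    return(list(threshold = NA_real_,
                mask = matrix(FALSE, nrow(img), ncol(img)), degenerate = TRUE))
  }
  thr <- if (method == "otsu") otsu_threshold(h) else isodata_threshold(h)
  list(threshold = thr, mask = matrix(v <= thr, nrow(img), ncol(img)),
       degenerate = FALSE)
}

# Otsu's method on a 256-bin histogram: the threshold t (class 0 = values
# <= t) maximising the between-class variance, computed from cumulative
# moments; ties resolved to the smallest t.
otsu_threshold <- function(h) {
  p <- h / sum(h)
  levels <- 0:255
  w0 <- cumsum(p)
  mu <- cumsum(p * levels)
  mu_t <- mu[256]
  t_cand <- 1:255                       # thresholds 0..254
  w0c <- w0[t_cand]; muc <- mu[t_cand]
  valid <- w0c > 0 & w0c < 1
  sigma_b <- rep(-Inf, 255)
  sigma_b[valid] <- (mu_t * w0c[valid] - muc[valid])^2 /
    (w0c[valid] * (1 - w0c[valid]))
  which.max(sigma_b) - 1L
}

# IsoData / intermeans: iterate t <- mean of the two class means.
isodata_threshold <- function(h) {
  levels <- 0:255
  t_old <- -1
  t <- sum(h * levels) / sum(h)
  it <- 0L
  while (abs(t - t_old) > 0.5 && it < 100L) {
    t_old <- t
    lo <- levels <= t_old
    m0 <- sum(h[lo] * levels[lo]) / max(sum(h[lo]), 1)
    m1 <- sum(h[!lo] * levels[!lo]) / max(sum(h[!lo]), 1)
    t <- (m0 + m1) / 2
    it <- it + 1L
  }
  as.integer(floor(t))
}

#' Fill holes inside mask components
#'
#' Nuclei are solid objects; chromatin texture can punch spurious holes at
#' the threshold, which would corrupt area and intensity statistics. Holes
#' (background regions not connected to the image border) are filled before
#' particle analysis.
#'
#' @param mask Logical matrix.
#' @return Logical matrix with all interior holes filled.
#' @export
fill_holes <- function(mask) {
  filled <- EBImage::fillHull(EBImage::Image(mask * 1))
  as.matrix(filled) > 0.5
}

#' Segment nuclei in an RGB field image
#'
#' Runs the full segmentation chain: green-channel extraction, background
#' subtraction, automatic thresholding and hole filling. The returned gray
#' image is the background-subtracted green channel - the single intensity
#' substrate used both for thresholding and for all downstream per-particle
#' intensity statistics.
#'
#' @param img Integer RGB array `H x W x 3` (0-255).
#' @param config A [dia_config()].
#' @return List with `gray` (background-subtracted green channel), `mask`
#'   (logical nucleus mask, holes filled), `threshold` and `degenerate`.
#' @export
segment_nuclei <- function(img, config = dia_config()) {
  gray <- subtract_background(extract_green(img), config$background_radius)
  th <- auto_threshold(gray, config$threshold_method)
  mask <- th$mask
  if (!th$degenerate) mask <- fill_holes(mask)
  list(gray = gray, mask = mask, threshold = th$threshold,
       degenerate = th$degenerate)
}
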