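# Stem/background separation: hue-gated Otsu segmentation, denoising,
# largest-component selection and the morphological internal-gradient
# contour.

#' Otsu's threshold from a 256-bin histogram
#'
#' Returns the grey level maximising the between-class variance when the
#' histogram is split into levels `<= threshold` and `> threshold`. Ties are
#' broken by the smallest level. A single-valued histogram is degenerate:
#' the function warns and returns that value.
#'
#' @param histogram Numeric vector of 256 non-negative counts for levels
#'   0-255, with positive total.
#' @return The threshold level (integer in 0-255).
#' @examples
#' h <- numeric(256); h[11] <- 40; h[201] <- 60
#' otsu_threshold(h)   # any level in [10, 200) separates; smallest returned
#' @export
otsu_threshold <- function(histogram) {
  stopifnot(length(histogram) == 256, all(histogram >= 0))
  total <- sum(histogram)
  if (total <= 0) {
    rlang::abort("histogram has zero total count",
                 class = "stemdepth_parameter_error")
  }
  lv <- 0:255
  if (sum(histogram > 0) == 1) {
    rlang::warn("single-valued histogram; threshold is degenerate",
                class = "stemdepth_degenerate_warning")
    return(lv[histogram > 0])
  }
  p <- histogram / total
  w0 <- cumsum(p)                # class 0: levels <= t
  m <- cumsum(p * lv)
  mt <- m[256]
  w1 <- 1 - w0
  # between-class variance for t = 0..254; undefined where a class is empty
  num <- (mt * w0 - m)^2
  sb <- ifelse(w0 > 0 & w1 > 0, num / (w0 * w1), -Inf)[1:255]
  lv[which.max(sb)]              # which.max takes the first (smallest) argmax
}

#' Segment a stem from the background in HSV colour space
#'
#' Converts the image to HSV, keeps pixels whose hue falls inside
#' `hue_range`, then applies Otsu's threshold to the saturation channel of
#' the gated pixels; the mask is the conjunction (hue in gate AND saturation
#' above threshold). When all gated saturations are identical there is
#' nothing for Otsu to split and the whole hue gate is returned.
#'
#' @param rgb 3-channel colour array `[row, col, 3]`, values in `[0, 1]`
#'   (as read by [read_image()]) or 8-bit integers in `[0, 255]`.
#' @param hue_range Length-2 hue gate in degrees on a 0-360 scale; default
#'   `c(35, 85)` targets green vegetation against soil.
#' @return A `{0,1}` integer matrix matching the image grid.
#' @export
hsv_otsu_segment <- function(rgb, hue_range = c(35, 85)) {
  stopifnot(length(dim(rgb)) == 3, dim(rgb)[3] == 3)
  if (max(rgb) > 1) rgb <- rgb / 255
  nr <- dim(rgb)[1]; nc <- dim(rgb)[2]
  hsv <- grDevices::rgb2hsv(rbind(as.vector(rgb[, , 1]),
                                  as.vector(rgb[, , 2]),
                                  as.vector(rgb[, , 3])), maxColorValue = 1)
  hue <- hsv[1, ] * 360
  sat <- hsv[2, ]
  gate <- hue >= hue_range[1] & hue <= hue_range[2]
  mask <- matrix(0L, nr, nc)
  if (!any(gate)) {
    rlang::warn("no pixel passes the hue gate; returning an empty mask",
                class = "stemdepth_empty_mask_warning")
    return(mask)
  }
  s255 <- pmin(pmax(round(sat * 255), 0), 255)
  hist256 <- tabulate(s255[gate] + 1L, nbins = 256)
  if (sum(hist256 > 0) == 1) {
    # all gated pixels share one saturation: the gate itself is the split
    mask[gate] <- 1L
    return(mask)
  }
  thr <- otsu_threshold(hist256)
  mask[gate & s255 > thr] <- 1L
  mask
}

#' Denoise a binary mask
#'
#' Median filtering (majority vote), re-binarisation and one morphological
#' opening, mirroring the usual cleanup between colour thresholding and
#' contour extraction. Borders are handled by reflection so an all-ones mask
#' passes through unchanged.
#'
#' @param mask `{0,1}` matrix.
#' @param median_ksize Odd median window size; default 5.
#' @param open_ksize Odd opening kernel size (cross-shaped element, the 3x3
#'   "ellipse" of common libraries); default 3.
#' @return Denoised `{0,1}` matrix.
#' @export
denoise <- function(mask, median_ksize = 5, open_ksize = 3) {
  check_binary(mask)
  m <- binary_median(mask, median_ksize)
  binary_open(m, open_ksize, shape = "cross")
}

#' Keep only the largest connected foreground component
#'
#' Components are 8-connected; ties in pixel count are broken in favour of
#' the component whose top-left-most pixel comes first in row-major order.
#'
#' @param mask `{0,1}` matrix with at least one foreground pixel.
#' @return `{0,1}` matrix containing a single component.
#' @export
largest_component <- function(mask) {
  check_binary(mask)
  if (!any(mask > 0)) {
    rlang::abort("mask is empty", class = "stemdepth_empty_mask_error")
  }
  lab <- label_components8(mask)
  counts <- tabulate(lab[lab > 0])
  best <- which.max(counts)      # first maximum = smallest label = earliest
  (lab == best) + 0L             # top-left pixel in row-major scan order
}

#' Internal morphological gradient contour
#'
#' Returns `mask - erode(mask)`: the one-to-two-pixel inner boundary of the
#' object. Every contour pixel is adjacent to background and the contour is
#' a subset of the mask.
#'
#' @param mask `{0,1}` matrix.
#' @param ksize Odd erosion kernel size (cross-shaped element); default 3.
#' @return `{0,1}` contour matrix.
#' @export
internal_gradient_contour <- function(mask, ksize = 3) {
  check_binary(mask)
  mask - binary_erode(mask, ksize, shape = "cross")
}

check_binary <- function(mask) {
  if (!is.matrix(mask) || !all(mask %in% c(0, 1))) {
    rlang::abort("mask must be a {0,1} matrix",
                 class = "stemdepth_parameter_error")
  }
  invisible(mask)
}
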