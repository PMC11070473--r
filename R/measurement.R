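# End-to-end diameter measurement: scanline/contour intersections, depth
# back-projection, the opencv -> color -> depth frame choreography, and the
# Euclidean chord; plus the checkerboard pinhole baseline and point-cloud
# annotation.

#' Intersect a horizontal scanline with the stem contour
#'
#' From a centreline point, walk left and right along the same image row to
#' the nearest contour pixel on each side. When the contour is two pixels
#' thick the pixel nearest the centre is taken.
#'
#' @param contour `{0,1}` contour matrix.
#' @param center `(col, row)` centre point, 0-based; `col` may be
#'   fractional.
#' @return A list with `left_px` and `right_px`, each `(col, row)`.
#' @export
scanline_intersections <- function(contour, center) {
  check_binary(contour)
  ccol <- center[[1]]; crow <- round(center[[2]])
  if (crow < 0 || crow >= nrow(contour)) {
    rlang::abort("scanline row outside the image",
                 class = "stemdepth_open_contour_error")
  }
  cc <- which(contour[crow + 1, ] > 0) - 1
  lt <- cc[cc < ccol]; rt <- cc[cc > ccol]
  if (length(lt) == 0 || length(rt) == 0) {
    rlang::abort(sprintf("open contour on row %d: no edge on %s side",
                         crow, if (length(lt) == 0) "left" else "right"),
                 class = "stemdepth_open_contour_error")
  }
  list(left_px = c(col = max(lt), row = crow),
       right_px = c(col = min(rt), row = crow))
}

#' Euclidean distance between two 3-D points, in millimetres
#'
#' @param p,q [point3()] objects sharing a frame tag.
#' @return `1000 * sqrt(dx^2 + dy^2 + dz^2)`.
#' @export
euclidean_distance <- function(p, q) {
  if (point_frame(p) != point_frame(q)) {
    rlang::abort(sprintf("points are in different frames ('%s' vs '%s')",
                         point_frame(p), point_frame(q)),
                 class = "stemdepth_frame_error")
  }
  1000 * sqrt(sum((unclass(p) - unclass(q))^2))
}

#' Measure the stem diameter along one scanline
#'
#' Runs the full per-scanline chain: (1) edge pixels from
#' [scanline_intersections()]; (2) a single shared depth taken from the
#' aligned raster at the centreline point (falling back to the median of
#' valid depths in a surrounding window, since silhouette-edge pixels often
#' sample background or are invalid on stereo sensors); (3) back-projection
#' of both edge pixels with the colour intrinsics; (4) [flip_yz()] into the
#' colour-stream frame; (5) [rigid_transform()] with the colour-to-depth
#' extrinsics; (6) the Euclidean chord -- identical in both frames because
#' rigid maps are isometries, which is asserted on every measurement.
#'
#' @param aligned_depth Integer depth matrix on the colour grid (output of
#'   [align_depth_to_color()]); 0 is invalid.
#' @param contour `{0,1}` contour matrix on the colour grid.
#' @param skeleton_pt `(col, row)` centreline point, 0-based.
#' @param cam [camera_model()].
#' @param fallback_window Odd side length of the median-depth fallback
#'   window around the centre; default 5.
#' @param edge_offset_px Half-width of the pixel footprint added outward on
#'   each side before back-projection (default 0.5). A boundary pixel's
#'   centre sits inside the true silhouette by half a pixel on average, so
#'   the chord between pixel centres systematically loses one pixel of
#'   width; spanning the outer edges of the boundary pixels removes that
#'   bias. Set to 0 to back-project the raw pixel centres.
#' @return A one-row tibble with the centre/edge pixels, the depth used
#'   (metres), the edge points in the colour and depth frames (list
#'   columns of [point3()]) and `diameter_mm`.
#' @export
measure_at_scanline <- function(aligned_depth, contour, skeleton_pt, cam,
                                fallback_window = 5, edge_offset_px = 0.5) {
  edges <- scanline_intersections(contour, skeleton_pt)
  edges$left_px[["col"]] <- max(edges$left_px[["col"]] - edge_offset_px, 0)
  edges$right_px[["col"]] <- min(edges$right_px[["col"]] + edge_offset_px,
                                 cam$color$width - 1)
  ccol <- as.integer(round(skeleton_pt[[1]])); crow <- as.integer(round(skeleton_pt[[2]]))
  d_units <- aligned_depth[crow + 1, ccol + 1]
  if (d_units == 0) {
    r <- (fallback_window - 1) / 2
    rr <- max(1, crow + 1 - r):min(nrow(aligned_depth), crow + 1 + r)
    cc <- max(1, ccol + 1 - r):min(ncol(aligned_depth), ccol + 1 + r)
    win <- aligned_depth[rr, cc]
    if (!any(win > 0)) {
      rlang::abort(sprintf("no valid depth near (%d, %d)", ccol, crow),
                   class = "stemdepth_no_depth_error")
    }
    d_units <- stats::median(win[win > 0])
  }
  depth_m <- d_units * cam$depth_scale
  p_cv <- lapply(list(edges$left_px, edges$right_px),
                 function(px) backproject(px, depth_m, cam$color))
  p_color <- lapply(p_cv, flip_yz)
  p_depth <- lapply(p_color, rigid_transform, ext = cam$color_to_depth)
  d_color <- euclidean_distance(p_color[[1]], p_color[[2]])
  d_depth <- euclidean_distance(p_depth[[1]], p_depth[[2]])
  stopifnot(abs(d_color - d_depth) < 1e-9)
  tibble::tibble(
    center_col = skeleton_pt[[1]], center_row = skeleton_pt[[2]],
    left_col = edges$left_px[["col"]], right_col = edges$right_px[["col"]],
    row = edges$left_px[["row"]],
    depth_used = depth_m,
    p_left = list(p_color[[1]]), p_right = list(p_color[[2]]),
    p_left_depthframe = list(p_depth[[1]]),
    p_right_depthframe = list(p_depth[[2]]),
    diameter_mm = d_depth)
}

#' Measure a stem from an RGB-D frame
#'
#' Orchestrates the whole pipeline: depth-to-colour alignment,
#' [hsv_otsu_segment()], [denoise()], [largest_component()],
#' [internal_gradient_contour()] and [thin()], then `n_scanlines` evenly
#' spaced centreline points in the region of interest, one
#' [measure_at_scanline()] per point, and the median of the successful
#' scanlines as the stem's diameter. Failed scanlines are skipped and
#' recorded with their reason; the measurement fails only when every
#' scanline does.
#'
#' @param rgb Colour array `[row, col, 3]`.
#' @param depth Integer depth matrix. On the depth sensor grid by default;
#'   set `aligned = TRUE` if it is already on the colour grid.
#' @param cam [camera_model()].
#' @param roi Row region of interest: either absolute 0-based rows
#'   `c(r1, r2)`, or fractions in `(0, 1]` of the stem bounding-box height
#'   (e.g. `c(0.55, 0.80)`), resolved against the segmented mask.
#' @param n_scanlines Number of repeated scanline measurements; default 3.
#' @param hue_range Hue gate passed to [hsv_otsu_segment()].
#' @param prune Skeleton branch-pruning passes (see [prune_skeleton()]);
#'   default 0 (off).
#' @param aligned Set `TRUE` when `depth` is already aligned to the colour
#'   grid.
#' @param edge_offset_px Pixel-footprint correction passed to
#'   [measure_at_scanline()]; default 0.5.
#' @param keep_masks Keep the intermediate rasters in the result (for
#'   inspection/plots); default `FALSE`.
#' @return An object of class `stem_result`: a list with `diameter_mm`
#'   (the aggregate), `scanlines` (tibble of per-scanline measurements),
#'   `failures` (tibble of skipped scanlines and reasons), `aggregation`
#'   (`"median"`), `roi` (resolved absolute rows) and `params`.
#' @export
measure_stem <- function(rgb, depth, cam, roi = c(0.55, 0.80),
                         n_scanlines = 3, hue_range = c(35, 85),
                         prune = 0, aligned = FALSE, edge_offset_px = 0.5,
                         keep_masks = FALSE) {
  adepth <- if (aligned) depth else align_depth_to_color(depth, cam)
  mask <- hsv_otsu_segment(rgb, hue_range)
  if (!any(mask > 0)) {
    rlang::abort("segmentation produced an empty mask",
                 class = "stemdepth_measurement_failed_error")
  }
  mask <- largest_component(denoise(mask))
  contour <- internal_gradient_contour(mask)
  skel <- thin(mask)
  if (prune > 0) skel <- prune_skeleton(skel, prune)
  roi_abs <- resolve_roi(roi, mask)
  pts <- skeleton_points_in_roi(skel, roi_abs, n_scanlines)
  meas <- list(); fails <- list()
  for (i in seq_len(nrow(pts))) {
    res <- tryCatch(
      measure_at_scanline(adepth, contour, c(pts$col[i], pts$row[i]), cam,
                          edge_offset_px = edge_offset_px),
      error = function(e) e)
    if (inherits(res, "error")) {
      fails[[length(fails) + 1]] <-
        tibble::tibble(col = pts$col[i], row = pts$row[i],
                       reason = conditionMessage(res))
    } else {
      meas[[length(meas) + 1]] <- res
    }
  }
  if (length(meas) == 0) {
    rlang::abort(paste0("all scanlines failed:\n  ",
                        paste(vapply(fails, function(f) f$reason, ""),
                              collapse = "\n  ")),
                 class = "stemdepth_measurement_failed_error")
  }
  scan <- dplyr::bind_rows(meas)
  out <- list(
    diameter_mm = stats::median(scan$diameter_mm),
    scanlines = scan,
    failures = if (length(fails)) dplyr::bind_rows(fails) else
      tibble::tibble(col = numeric(), row = numeric(), reason = character()),
    aggregation = "median",
    roi = roi_abs,
    params = list(n_scanlines = n_scanlines, hue_range = hue_range,
                  prune = prune, depth_fallback_window = 5,
                  edge_offset_px = edge_offset_px,
                  median_ksize = 5, open_ksize = 3, gradient_ksize = 3))
  if (keep_masks) out$masks <- list(mask = mask, contour = contour,
                                    skeleton = skel, aligned_depth = adepth)
  structure(out, class = "stem_result")
}

resolve_roi <- function(roi, mask) {
  stopifnot(length(roi) == 2, roi[1] <= roi[2])
  if (all(roi > 0 & roi <= 1) && !all(roi == round(roi))) {
    rows <- range(((which(mask > 0)) - 1) %% nrow(mask))
    h <- rows[2] - rows[1]
    round(c(rows[1] + roi[1] * h, rows[1] + roi[2] * h))
  } else {
    round(roi)
  }
}

#' @export
print.stem_result <- function(x, ...) {
  cat(sprintf("<stem_result> diameter %.2f mm (%s of %d scanline%s, %d failed)\n",
              x$diameter_mm, x$aggregation, nrow(x$scanlines),
              if (nrow(x$scanlines) == 1) "" else "s", nrow(x$failures)))
  invisible(x)
}

#' @export
#' @rdname stem_result_tidiers
#' @method tidy stem_result
tidy.stem_result <- function(x, ...) {
  dplyr::select(x$scanlines, "center_col", "center_row", "left_col",
                "right_col", "depth_used", "diameter_mm")
}

#' Tidiers for stem measurement results
#'
#' `tidy()` returns the per-scanline measurements; `glance()` a one-row
#' summary.
#'
#' @param x A `stem_result`.
#' @param ... Unused.
#' @name stem_result_tidiers
#' @export
#' @method glance stem_result
glance.stem_result <- function(x, ...) {
  tibble::tibble(diameter_mm = x$diameter_mm,
                 n_scanlines_ok = nrow(x$scanlines),
                 n_scanlines_failed = nrow(x$failures),
                 aggregation = x$aggregation,
                 roi_min = x$roi[1], roi_max = x$roi[2])
}

#' @export
#' @method autoplot stem_result
autoplot.stem_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$center_row, y = .data$diameter_mm)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = object$diameter_mm, linetype = 2) +
    ggplot2::labs(x = "scanline row (px)", y = "diameter (mm)",
                  title = sprintf("Stem diameter: %.2f mm (%s)",
                                  object$diameter_mm, object$aggregation))
}

#' Checkerboard pinhole-imaging baseline
#'
#' Converts a pixel width to millimetres with the ground-sample distance of
#' a reference checkerboard at the stem's approximate plane:
#' `pixel_width * square_mm / square_px`. Used only to compare the
#' depth-based method against reference-object scaling.
#'
#' @param pixel_width Stem width in pixels (>= 0).
#' @param square_px Checkerboard square side in pixels (> 0).
#' @param square_mm Checkerboard square side in millimetres (> 0).
#' @return Diameter estimate in millimetres.
#' @export
pinhole_baseline <- function(pixel_width, square_px, square_mm) {
  if (square_px <= 0 || square_mm <= 0 || pixel_width < 0) {
    rlang::abort("pixel_width must be >= 0 and square sizes > 0",
                 class = "stemdepth_parameter_error")
  }
  pixel_width * square_mm / square_px
}

#' Mark measured points in a point cloud
#'
#' Recolours cloud vertices within `radius_mm` of any measured point red
#' and appends the measured points themselves as red vertices, leaving the
#' geometry untouched, so that the mapped 3-D coordinates can be verified
#' visually on the stem surface.
#'
#' @param cloud Tibble with columns `x, y, z` (metres, depth-camera frame)
#'   and optionally `red, green, blue` (0-255).
#' @param points List of [point3()] in the depth frame.
#' @param radius_mm Recolouring radius; 0 recolours nothing and only
#'   appends markers.
#' @return The annotated cloud tibble.
#' @export
annotate_pointcloud <- function(cloud, points, radius_mm = 2) {
  if (nrow(cloud) == 0) {
    rlang::warn("empty point cloud", class = "stemdepth_empty_cloud_warning")
  }
  if (!all(c("red", "green", "blue") %in% names(cloud))) {
    cloud$red <- 200L; cloud$green <- 200L; cloud$blue <- 200L
  }
  for (p in points) {
    stopifnot(point_frame(p) == "depth")
    if (nrow(cloud) > 0 && radius_mm > 0) {
      d2 <- (cloud$x - p[[1]])^2 + (cloud$y - p[[2]])^2 + (cloud$z - p[[3]])^2
      hit <- d2 <= (radius_mm / 1000)^2
      cloud$red[hit] <- 255L; cloud$green[hit] <- 0L; cloud$blue[hit] <- 0L
    }
  }
  marks <- tibble::tibble(
    x = vapply(points, `[[`, 0, 1), y = vapply(points, `[[`, 0, 2),
    z = vapply(points, `[[`, 0, 3),
    red = 255L, green = 0L, blue = 0L)
  dplyr::bind_rows(cloud, marks)
}
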