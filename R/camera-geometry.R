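# Pinhole-camera math: back-projection, projection, frame flips, rigid
# transforms and depth-to-color image alignment.
#
# Conventions used throughout the package:
#  * pixels are 0-based (col, row) pairs with col along the image x axis and
#    the pixel centre at integer coordinates, matching the intrinsics
#    (cx, cy) convention of camera SDKs;
#  * rasters are R matrices indexed [row + 1, col + 1];
#  * back-projected points live in the "opencv" convention of their camera
#    (x right, y down, z forward); `flip_yz()` bridges to the point-cloud
#    ("viewer") convention in which extrinsics are stated.

#' Camera intrinsic parameters
#'
#' Focal lengths and principal point of an undistorted pinhole camera, in
#' pixels, together with the sensor raster size.
#'
#' @param fx,fy Focal lengths along the image x and y axes (pixels, > 0).
#' @param cx,cy Principal point column and row (0-based pixels, inside the
#'   image).
#' @param width,height Image size in columns and rows.
#' @return An object of class `intrinsics`.
#' @examples
#' intr <- intrinsics(fx = 610, fy = 610, cx = 424, cy = 240,
#'                    width = 848, height = 480)
#' @export
intrinsics <- function(fx, fy, cx, cy, width, height) {
  stopifnot(fx > 0, fy > 0, width >= 1, height >= 1)
  if (cx < 0 || cx >= width || cy < 0 || cy >= height) {
    rlang::abort("principal point must lie inside the image",
                 class = "stemdepth_parameter_error")
  }
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy,
                 width = as.integer(width), height = as.integer(height)),
            class = "intrinsics")
}

#' @export
print.intrinsics <- function(x, ...) {
  cat(sprintf("<intrinsics> %dx%d  fx=%.2f fy=%.2f cx=%.2f cy=%.2f\n",
              x$width, x$height, x$fx, x$fy, x$cx, x$cy))
  invisible(x)
}

#' Rigid extrinsic transform between two camera frames
#'
#' @param R 3x3 rotation matrix (orthonormal, determinant +1).
#' @param t Length-3 translation vector in metres.
#' @param from,to Frame tags of the source and destination frames
#'   (one of `"color"`, `"depth"`, `"opencv"`).
#' @return An object of class `extrinsics`.
#' @export
extrinsics <- function(R, t = c(0, 0, 0), from = "depth", to = "color") {
  R <- matrix(as.numeric(R), 3, 3)
  t <- as.numeric(t)
  stopifnot(length(t) == 3)
  if (max(abs(crossprod(R) - diag(3))) > 1e-9 || abs(det(R) - 1) > 1e-9) {
    rlang::abort("R must be a proper rotation (R'R = I, det = +1)",
                 class = "stemdepth_parameter_error")
  }
  structure(list(R = R, t = t, from = from, to = to), class = "extrinsics")
}

#' Invert an extrinsic transform
#'
#' @param ext An [extrinsics()] object.
#' @return The inverse transform (`R' = t(R)`, `t' = -t(R) %*% t`), with the
#'   frame tags swapped.
#' @export
invert_extrinsics <- function(ext) {
  extrinsics(t(ext$R), -as.vector(t(ext$R) %*% ext$t),
             from = ext$to, to = ext$from)
}

#' Full RGB-D camera model
#'
#' Bundles the colour and depth intrinsics, the depth-to-colour extrinsics
#' (stated between the point-cloud-convention frames; see [flip_yz()]) and
#' the depth quantisation scale. The colour-to-depth transform is derived as
#' the exact inverse.
#'
#' @param color,depth [intrinsics()] of the colour and depth sensors.
#' @param depth_to_color [extrinsics()] mapping depth-frame points to the
#'   colour frame. Defaults to identity.
#' @param depth_scale Metres per stored depth unit (> 0); default 0.001
#'   (millimetre depth units).
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(color, depth = color,
                         depth_to_color = extrinsics(diag(3)),
                         depth_scale = 0.001) {
  stopifnot(inherits(color, "intrinsics"), inherits(depth, "intrinsics"),
            inherits(depth_to_color, "extrinsics"), depth_scale > 0)
  d2c <- extrinsics(depth_to_color$R, depth_to_color$t,
                    from = "depth", to = "color")
  structure(list(color = color, depth = depth,
                 depth_to_color = d2c,
                 color_to_depth = invert_extrinsics(d2c),
                 depth_scale = depth_scale),
            class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat("<camera_model>\n  color: "); print(x$color)
  cat("  depth: "); print(x$depth)
  cat(sprintf("  depth_scale: %g m/unit  |t(depth->color)| = %.4f m\n",
              x$depth_scale, sqrt(sum(x$depth_to_color$t^2))))
  invisible(x)
}

#' Frame-tagged 3-D point
#'
#' @param x,y,z Coordinates in metres.
#' @param frame Frame tag: `"color"`, `"depth"` or `"opencv"`.
#' @return A named numeric vector of class `point3` with a `frame` attribute.
#' @export
point3 <- function(x, y, z, frame) {
  frame <- match.arg(frame, c("color", "depth", "opencv"))
  structure(c(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z)),
            frame = frame, class = "point3")
}

#' @export
print.point3 <- function(x, ...) {
  cat(sprintf("<point3 %s> (%.6f, %.6f, %.6f) m\n",
              attr(x, "frame"), x[1], x[2], x[3]))
  invisible(x)
}

#' Frame tag of a point
#' @param p A [point3()].
#' @return The frame tag string.
#' @export
point_frame <- function(p) attr(p, "frame")

#' Back-project a pixel to a 3-D point
#'
#' Recovers the 3-D point on the ray through `pixel` at depth `depth_m`
#' using the pinhole model: `Z = d`, `X = (col - cx) / fx * Z`,
#' `Y = (row - cy) / fy * Z`.
#'
#' @param pixel Length-2 `(col, row)` pixel, 0-based; may be fractional.
#' @param depth_m Depth along the optical axis in metres (> 0).
#' @param intr [intrinsics()] of the camera observing the pixel.
#' @param frame Frame tag given to the result; back-projection works in the
#'   camera's OpenCV-style frame, so the default is `"opencv"`.
#' @return A [point3()] with `z = depth_m`.
#' @examples
#' intr <- intrinsics(600, 600, 424, 240, 848, 480)
#' backproject(c(424, 240), 1, intr)   # the principal-point ray: (0, 0, 1)
#' @export
backproject <- function(pixel, depth_m, intr, frame = "opencv") {
  if (!is.numeric(depth_m) || length(depth_m) != 1 || depth_m <= 0) {
    rlang::abort("depth must be a single positive number",
                 class = "stemdepth_invalid_depth")
  }
  col <- pixel[[1]]; row <- pixel[[2]]
  if (col < 0 || col > intr$width - 1 || row < 0 || row > intr$height - 1) {
    rlang::abort(sprintf("pixel (%g, %g) outside %dx%d image",
                         col, row, intr$width, intr$height),
                 class = "stemdepth_bounds_error")
  }
  point3((col - intr$cx) / intr$fx * depth_m,
         (row - intr$cy) / intr$fy * depth_m,
         depth_m, frame = frame)
}

#' Project a 3-D point to a continuous pixel
#'
#' Inverse of [backproject()]: `col = fx * x / z + cx`,
#' `row = fy * y / z + cy`.
#'
#' @param p [point3()] with `z > 0` (in front of the camera).
#' @param intr [intrinsics()].
#' @return Numeric `(col, row)`, 0-based, possibly fractional and possibly
#'   outside the raster.
#' @export
project <- function(p, intr) {
  if (p[[3]] <= 0) {
    rlang::abort("point is behind the camera (z <= 0)",
                 class = "stemdepth_behind_camera")
  }
  c(col = intr$fx * p[[1]] / p[[3]] + intr$cx,
    row = intr$fy * p[[2]] / p[[3]] + intr$cy)
}

#' Flip the y and z axes of a point
#'
#' Bridges the OpenCV image-processing convention (x right, y down,
#' z forward) and the point-cloud viewer convention of the colour stream
#' (x right, y up, z toward the viewer): `(x, y, z) -> (x, -y, -z)`.
#' Applying it twice restores the input.
#'
#' @param p [point3()] tagged `"opencv"` (forward flip) or `"color"`
#'   (undo flip).
#' @return The flipped point, retagged `"color"` (or `"opencv"`).
#' @export
flip_yz <- function(p) {
  fr <- point_frame(p)
  if (!fr %in% c("opencv", "color")) {
    rlang::abort("flip_yz expects an 'opencv' or 'color' tagged point",
                 class = "stemdepth_frame_error")
  }
  point3(p[[1]], -p[[2]], -p[[3]],
         frame = if (fr == "opencv") "color" else "opencv")
}

#' Apply a rigid transform to a point
#'
#' `p' = R p + t`. The point's frame tag must match the transform's source
#' frame; the result is retagged with the destination frame.
#'
#' @param p [point3()].
#' @param ext [extrinsics()].
#' @return Transformed [point3()].
#' @export
rigid_transform <- function(p, ext) {
  if (point_frame(p) != ext$from) {
    rlang::abort(sprintf("point frame '%s' does not match transform source '%s'",
                         point_frame(p), ext$from),
                 class = "stemdepth_frame_error")
  }
  q <- as.vector(ext$R %*% c(p[[1]], p[[2]], p[[3]]) + ext$t)
  point3(q[1], q[2], q[3], frame = ext$to)
}

# diag(1,-1,-1) conjugation: the same rigid motion expressed between the
# OpenCV-convention frames when (R, t) is stated between the flipped
# (viewer-convention) frames. flip o (R,t) o flip = (DRD, Dt).
conjugate_extrinsics_opencv <- function(ext) {
  D <- diag(c(1, -1, -1))
  list(R = D %*% ext$R %*% D, t = as.vector(D %*% ext$t))
}

#' Align a depth raster onto the colour pixel grid
#'
#' Each valid depth pixel is back-projected with the depth intrinsics,
#' moved into the colour camera's frame with the depth-to-colour
#' extrinsics, projected with the colour intrinsics, and splatted onto the
#' nearest colour-grid pixel. When several depth pixels land on the same
#' target the smallest Z wins (z-buffer). Output depths are re-quantised
#' with the model's `depth_scale`; pixels that receive no splat are 0
#' (invalid), so the aligned raster may contain holes.
#'
#' @param depth_img Integer matrix of depth units on the depth sensor grid;
#'   0 marks invalid pixels.
#' @param cam [camera_model()].
#' @return Integer matrix of depth units on the colour grid.
#' @export
align_depth_to_color <- function(depth_img, cam) {
  di <- cam$depth; ci <- cam$color
  if (nrow(depth_img) != di$height || ncol(depth_img) != di$width) {
    rlang::abort(sprintf("depth image is %dx%d but depth intrinsics expect %dx%d",
                         nrow(depth_img), ncol(depth_img), di$height, di$width),
                 class = "stemdepth_shape_error")
  }
  out <- matrix(0L, ci$height, ci$width)
  idx <- which(depth_img > 0)
  if (length(idx) == 0) return(out)
  row0 <- (idx - 1) %% nrow(depth_img)        # 0-based raster coords
  col0 <- (idx - 1) %/% nrow(depth_img)
  z <- as.numeric(depth_img[idx]) * cam$depth_scale
  x <- (col0 - di$cx) / di$fx * z
  y <- (row0 - di$cy) / di$fy * z
  eo <- conjugate_extrinsics_opencv(cam$depth_to_color)
  p <- eo$R %*% rbind(x, y, z) + eo$t
  keep <- p[3, ] > 0
  u <- round(ci$fx * p[1, keep] / p[3, keep] + ci$cx)
  v <- round(ci$fy * p[2, keep] / p[3, keep] + ci$cy)
  zc <- p[3, keep]
  inb <- u >= 0 & u <= ci$width - 1 & v >= 0 & v <= ci$height - 1
  u <- u[inb]; v <- v[inb]; zc <- zc[inb]
  if (length(u) == 0) return(out)
  q <- as.integer(round(zc / cam$depth_scale))
  q[q < 1L] <- 1L                             # keep valid splats nonzero
  ord <- order(zc, decreasing = TRUE)         # nearest written last wins
  out[cbind(v[ord] + 1, u[ord] + 1)] <- q[ord]
  out
}

#' Read or write a camera-parameter config
#'
#' Config files are JSON or YAML with keys `color` and `depth`
#' (`fx, fy, cx, cy, width, height` each), `depth_to_color`
#' (`R`: 9 floats row-major, `t`: 3 floats, metres) and `depth_scale`.
#' JSON is written with full floating-point precision so a write/read
#' round-trip is bit-exact.
#'
#' @param path File path; format chosen by extension (`.json`, `.yaml`/`.yml`).
#' @return A [camera_model()].
#' @export
read_camera_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path)
  }
  as_intr <- function(l) {
    intrinsics(as.numeric(l$fx), as.numeric(l$fy), as.numeric(l$cx),
               as.numeric(l$cy), as.integer(l$width), as.integer(l$height))
  }
  ext <- extrinsics(matrix(as.numeric(cfg$depth_to_color$R), 3, 3, byrow = TRUE),
                    as.numeric(cfg$depth_to_color$t))
  camera_model(color = as_intr(cfg$color), depth = as_intr(cfg$depth),
               depth_to_color = ext, depth_scale = as.numeric(cfg$depth_scale))
}

#' @param cam [camera_model()] to serialise.
#' @rdname read_camera_config
#' @export
write_camera_config <- function(cam, path) {
  num <- function(x) unclass(x)
  cfg <- list(
    color = num(cam$color)[c("fx", "fy", "cx", "cy", "width", "height")],
    depth = num(cam$depth)[c("fx", "fy", "cx", "cy", "width", "height")],
    depth_to_color = list(R = as.vector(t(cam$depth_to_color$R)),
                          t = cam$depth_to_color$t),
    depth_scale = cam$depth_scale)
  if (grepl("\\.ya?ml$", path)) {
    # serialise doubles as 17-significant-digit strings: the YAML emitter's
    # own float formatting loses precision, and R re-parses these exactly
    g17 <- function(x) {
      if (is.numeric(x) && any(x != round(x))) sprintf("%.17g", x) else x
    }
    cfg <- rapply(cfg, g17, how = "replace")
    writeLines(yaml::as.yaml(cfg), path)
  } else {
    writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = I(17)), path)
  }
  invisible(path)
}
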