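# File interop: 16-bit depth rasters, 8-bit colour images, PLY point
# clouds, batch manifests and the batch pipeline driver.

#' Read and write 16-bit depth rasters
#'
#' Depth is persisted as an unsigned 16-bit single-channel raster; the
#' value 0 is the invalid-depth sentinel and the metres-per-unit scale
#' travels alongside (argument/attribute), not in the pixel data.
#' `read_depth()` accepts 16-bit grayscale PNG or TIFF; `write_depth()`
#' emits 16-bit TIFF (lossless). A write/read round-trip is bit-exact.
#'
#' @param path File path (`.png`, `.tif`/`.tiff`).
#' @param depth_scale Metres per depth unit, attached to the result as the
#'   `depth_scale` attribute.
#' @return `read_depth()`: an integer matrix of depth units.
#' @export
read_depth <- function(path, depth_scale = 0.001) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path, info = TRUE)
    info <- attr(img, "info")
    if (is.null(info) || info$bit.depth != 16) {
      rlang::abort("depth PNG must be 16-bit", class = "stemdepth_format_error")
    }
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    img <- suppressWarnings(tiff::readTIFF(path, info = TRUE))
    bits <- attr(img, "bits.per.sample")
    if (!is.null(bits) && bits != 16) {
      rlang::abort("depth TIFF must be 16-bit", class = "stemdepth_format_error")
    }
  } else {
    rlang::abort("unsupported depth raster format", class = "stemdepth_format_error")
  }
  if (length(dim(img)) != 2) {
    rlang::abort("depth raster must be single-channel",
                 class = "stemdepth_format_error")
  }
  m <- matrix(as.integer(round(img * 65535)), nrow(img), ncol(img))
  attr(m, "depth_scale") <- depth_scale
  m
}

#' @param depth Integer matrix of depth units (0-65535).
#' @rdname read_depth
#' @export
write_depth <- function(depth, path) {
  stopifnot(is.matrix(depth), all(depth >= 0), all(depth <= 65535))
  tiff::writeTIFF(depth / 65535, path, bits.per.sample = 16,
                  compression = "none")
  invisible(path)
}

#' Read and write 8-bit colour images
#'
#' Thin wrappers around the PNG reader/writer returning `[row, col, 3]`
#' arrays with values in `[0, 1]`.
#'
#' @param path PNG file path.
#' @return `read_image()`: a numeric array.
#' @export
read_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3 && dim(img)[3] == 4) img <- img[, , 1:3]
  img
}

#' @param rgb `[row, col, 3]` array in `[0, 1]`.
#' @rdname read_image
#' @export
write_image <- function(rgb, path) {
  png::writePNG(rgb, path)
  invisible(path)
}

#' Write a binary mask as an 8-bit PNG
#'
#' Foreground is stored as 255, background as 0.
#'
#' @param mask `{0,1}` matrix.
#' @param path PNG file path.
#' @export
write_mask <- function(mask, path) {
  check_binary(mask)
  png::writePNG(mask * 1.0, path)
  invisible(path)
}

#' Read and write PLY point clouds
#'
#' Supports PLY 1.0 with a single `vertex` element carrying float
#' `x, y, z` and optionally uchar `red, green, blue`, in `ascii` or
#' `binary_little_endian` encoding. Coordinates are preserved to float32
#' precision, colours exactly.
#'
#' @param path PLY file path.
#' @return `read_ply()`: a tibble with columns `x, y, z` and, when
#'   present, `red, green, blue`.
#' @export
read_ply <- function(path) {
  raw <- readBin(path, raw(), file.size(path))
  hdr_end <- find_ply_header_end(raw)
  hdr <- strsplit(rawToChar(raw[1:hdr_end]), "\r?\n")[[1]]
  if (hdr[1] != "ply") {
    rlang::abort("not a PLY file", class = "stemdepth_format_error")
  }
  fmt <- sub("^format ([a-z_0-9.]+).*$", "\\1",
             grep("^format ", hdr, value = TRUE)[1])
  if (!fmt %in% c("ascii", "binary_little_endian")) {
    rlang::abort(paste("unsupported PLY format:", fmt),
                 class = "stemdepth_format_error")
  }
  el <- grep("^element ", hdr)
  if (length(el) != 1 || !grepl("^element vertex ", hdr[el])) {
    rlang::abort("only a single 'vertex' element is supported",
                 class = "stemdepth_format_error")
  }
  n <- as.integer(sub("^element vertex ", "", hdr[el]))
  props <- hdr[grep("^property ", hdr)]
  pr <- do.call(rbind, strsplit(props, " +"))
  types <- pr[, 2]; names <- pr[, 3]
  if (!all(types %in% c("float", "float32", "uchar", "uint8"))) {
    rlang::abort("unsupported vertex property types",
                 class = "stemdepth_format_error")
  }
  sizes <- ifelse(types %in% c("float", "float32"), 4L, 1L)
  if (n == 0) {
    out <- tibble::as_tibble(stats::setNames(
      lapply(types, function(t) if (t %in% c("float", "float32")) numeric() else integer()),
      names))
    return(out)
  }
  if (fmt == "ascii") {
    txt <- rawToChar(raw[(hdr_end + 1):length(raw)])
    dat <- utils::read.table(text = txt, nrows = n, col.names = names)
    out <- tibble::as_tibble(dat)
    for (i in seq_along(names)) {
      out[[names[i]]] <- if (sizes[i] == 4) as.numeric(round(out[[names[i]]], 7))
                         else as.integer(out[[names[i]]])
    }
    return(out)
  }
  stride <- sum(sizes)
  body <- raw[(hdr_end + 1):(hdr_end + n * stride)]
  bm <- matrix(body, nrow = stride)
  off <- cumsum(c(0, sizes[-length(sizes)]))
  cols <- lapply(seq_along(names), function(i) {
    bytes <- as.vector(bm[(off[i] + 1):(off[i] + sizes[i]), , drop = FALSE])
    if (sizes[i] == 4) readBin(bytes, numeric(), n, size = 4, endian = "little")
    else as.integer(bytes)
  })
  tibble::as_tibble(stats::setNames(cols, names))
}

find_ply_header_end <- function(raw) {
  pat <- charToRaw("end_header")
  limit <- min(length(raw), 65536)
  hits <- which(raw[1:limit] == pat[1])
  for (h in hits) {
    if (h + length(pat) <= length(raw) &&
        identical(raw[h:(h + length(pat) - 1)], pat)) {
      j <- h + length(pat)
      if (j <= length(raw) && raw[j] == charToRaw("\r")) j <- j + 1
      if (j <= length(raw) && raw[j] == charToRaw("\n")) return(j)
      return(j - 1)
    }
  }
  rlang::abort("PLY header has no end_header line",
               class = "stemdepth_format_error")
}

#' @param cloud Tibble with columns `x, y, z` (and optionally
#'   `red, green, blue` 0-255).
#' @param format `"binary_little_endian"` (default) or `"ascii"`.
#' @rdname read_ply
#' @export
write_ply <- function(cloud, path, format = c("binary_little_endian", "ascii")) {
  format <- match.arg(format)
  stopifnot(all(c("x", "y", "z") %in% names(cloud)))
  has_rgb <- all(c("red", "green", "blue") %in% names(cloud))
  n <- nrow(cloud)
  hdr <- c("ply", paste("format", format, "1.0"),
           paste("element vertex", n),
           "property float x", "property float y", "property float z",
           if (has_rgb) c("property uchar red", "property uchar green",
                          "property uchar blue"),
           "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  if (n == 0) return(invisible(path))
  xyz <- t(as.matrix(cloud[, c("x", "y", "z")]))
  if (format == "ascii") {
    lines <- if (has_rgb) {
      sprintf("%.9g %.9g %.9g %d %d %d", xyz[1, ], xyz[2, ], xyz[3, ],
              cloud$red, cloud$green, cloud$blue)
    } else {
      sprintf("%.9g %.9g %.9g", xyz[1, ], xyz[2, ], xyz[3, ])
    }
    writeLines(lines, con, sep = "\n")
  } else {
    fb <- writeBin(as.numeric(xyz), raw(), size = 4, endian = "little")
    fm <- matrix(fb, nrow = 12)
    body <- if (has_rgb) {
      rbind(fm, matrix(as.raw(rbind(cloud$red, cloud$green, cloud$blue)), 3))
    } else fm
    writeBin(as.vector(body), con)
  }
  invisible(path)
}

#' Read a batch manifest
#'
#' A CSV listing one RGB-D frame per row with columns `id`, `rgb_path`,
#' `depth_path`, `camera_config`, `roi` (as `"lo:hi"`, fractional or
#' absolute rows) and optionally `true_mm`. Relative paths are resolved
#' against the manifest's directory. Ids must be unique.
#'
#' @param path Manifest CSV path.
#' @return A tibble, one row per frame.
#' @export
read_manifest <- function(path) {
  m <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  need <- c("id", "rgb_path", "depth_path", "camera_config", "roi")
  if (!all(need %in% names(m))) {
    rlang::abort(paste("manifest needs columns:", paste(need, collapse = ", ")),
                 class = "stemdepth_format_error")
  }
  if (anyDuplicated(m$id)) {
    rlang::abort("manifest ids must be unique", class = "stemdepth_format_error")
  }
  base <- dirname(path)
  for (col in c("rgb_path", "depth_path", "camera_config")) {
    rel <- !grepl("^(/|[A-Za-z]:)", m[[col]])
    m[[col]][rel] <- file.path(base, m[[col]][rel])
  }
  m
}

parse_roi <- function(s) as.numeric(strsplit(s, "[:,]")[[1]])

#' Run the measurement pipeline over a batch manifest
#'
#' Measures every frame of the manifest independently (no cross-frame
#' state), records per-frame failures without stopping the batch, and --
#' when `true_mm` is present for at least two successful frames -- attaches
#' a [stem_metrics()] report over the batch.
#'
#' @param manifest A manifest tibble (see [read_manifest()]) or a path to
#'   a manifest CSV.
#' @param out_dir Optional directory to write `results.csv` and one JSON
#'   result per frame.
#' @param n_scanlines Scanlines per frame; default 3.
#' @return A list of class `pipeline_result` with `results` (tibble:
#'   `id`, `diameter_mm`, `n_scanlines_ok`, `roi`, `status`, and when
#'   available `true_mm`, `abs_err_mm`) and `metrics` (a
#'   [stem_metrics()] report or `NULL`).
#' @export
run_pipeline <- function(manifest, out_dir = NULL, n_scanlines = 3) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (nrow(manifest) == 0) {
    rlang::warn("empty manifest", class = "stemdepth_empty_manifest_warning")
    return(structure(list(results = tibble::tibble(
      id = character(), diameter_mm = numeric(), n_scanlines_ok = integer(),
      roi = character(), status = character()), metrics = NULL),
      class = "pipeline_result"))
  }
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- purrr::map(seq_len(nrow(manifest)), function(i) {
    fr <- manifest[i, ]
    res <- tryCatch({
      cam <- read_camera_config(fr$camera_config)
      rgb <- read_image(fr$rgb_path)
      depth <- read_depth(fr$depth_path, cam$depth_scale)
      sr <- measure_stem(rgb, depth, cam, roi = parse_roi(fr$roi),
                         n_scanlines = n_scanlines)
      if (!is.null(out_dir)) {
        jsonlite::write_json(
          list(id = fr$id, diameter_mm = sr$diameter_mm,
               aggregation = sr$aggregation, roi = sr$roi,
               scanlines = tidy(sr), params = sr$params),
          file.path(out_dir, paste0(fr$id, ".json")),
          auto_unbox = TRUE, digits = NA)
      }
      tibble::tibble(id = as.character(fr$id), diameter_mm = sr$diameter_mm,
                     n_scanlines_ok = nrow(sr$scanlines),
                     roi = fr$roi, status = "ok")
    }, error = function(e) {
      tibble::tibble(id = as.character(fr$id), diameter_mm = NA_real_,
                     n_scanlines_ok = 0L, roi = fr$roi,
                     status = paste("error:", conditionMessage(e)))
    })
    res
  })
  results <- dplyr::bind_rows(rows)
  metrics <- NULL
  if ("true_mm" %in% names(manifest)) {
    results$true_mm <- manifest$true_mm
    results$abs_err_mm <- abs(results$diameter_mm - results$true_mm)
    ok <- results$status == "ok" & !is.na(results$true_mm)
    if (sum(ok) >= 2) {
      metrics <- stem_metrics(tibble::tibble(
        measured_mm = results$diameter_mm[ok], true_mm = results$true_mm[ok]))
    }
  }
  if (!is.null(out_dir)) {
    utils::write.csv(results, file.path(out_dir, "results.csv"),
                     row.names = FALSE)
  }
  structure(list(results = results, metrics = metrics),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d frame%s, %d ok\n", nrow(x$results),
              if (nrow(x$results) == 1) "" else "s",
              sum(x$results$status == "ok")))
  if (!is.null(x$metrics)) print(x$metrics)
  invisible(x)
}
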