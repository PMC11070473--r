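# Two-subiteration thinning of a binary mask to a one-pixel centreline,
# and selection of centreline points inside a row region of interest.
#
# A border pixel is deletable in sub-step A when
#   2 <= N <= 6,  S = 1,  north*east*south = 0,  east*south*west = 0
# and in sub-step B when
#   2 <= N <= 6,  S = 1,  north*east*west = 0,  north*south*west = 0,
# where N counts foreground 8-neighbours and S counts 0->1 transitions in
# the clockwise cyclic neighbour sequence starting at north. Deletions
# within a sub-step are simultaneous (evaluated on the sub-step's input),
# which keeps the skeleton orientation-unbiased. Pixels beyond the raster
# are background.

#' Neighbour statistics of a 3x3 window
#'
#' @param window 3x3 binary matrix; the centre is the pixel under test.
#' @return A list with `N`, the number of foreground pixels among the 8
#'   neighbours, and `S`, the number of 0-to-1 transitions in the clockwise
#'   cyclic sequence north, NE, east, SE, south, SW, west, NW.
#' @export
neighbor_stats <- function(window) {
  stopifnot(all(dim(window) == c(3, 3)), all(window %in% c(0, 1)))
  s <- c(window[1, 2], window[1, 3], window[2, 3], window[3, 3],
         window[3, 2], window[3, 1], window[2, 1], window[1, 1])
  list(N = sum(s), S = sum(s == 0 & c(s[-1], s[1]) == 1))
}

#' Thin a binary mask to its skeleton
#'
#' Iterates the paired deletion sub-steps until no pixel qualifies and
#' returns the fixed point. Thinning only deletes, so the skeleton is a
#' subset of the input, and the result is idempotent.
#'
#' @param mask `{0,1}` matrix.
#' @param max_iter Iteration cap; exceeding it raises a non-convergence
#'   error (diagnostic only -- finite masks converge).
#' @return `{0,1}` skeleton matrix of the same shape.
#' @export
thin <- function(mask, max_iter = 1000) {
  check_binary(mask)
  fg <- which(mask > 0)
  if (length(fg) == 0) return(mask + 0L)
  # work on the bounding box only; one background ring gives the correct
  # beyond-raster-is-background semantics
  r0 <- range((fg - 1) %% nrow(mask)); c0 <- range((fg - 1) %/% nrow(mask))
  m <- mask[(r0[1] + 1):(r0[2] + 1), (c0[1] + 1):(c0[2] + 1), drop = FALSE]
  m <- thin_core(m, max_iter)
  out <- matrix(0L, nrow(mask), ncol(mask))
  out[(r0[1] + 1):(r0[2] + 1), (c0[1] + 1):(c0[2] + 1)] <- m
  out
}

thin_core <- function(m, max_iter) {
  nr <- nrow(m); nc <- ncol(m)
  substep <- function(m, first) {
    z <- matrix(0L, nr + 2, nc + 2)
    z[2:(nr + 1), 2:(nc + 1)] <- m
    nb <- function(dr, dc) z[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
    n <- nb(-1, 0); ne <- nb(-1, 1); e <- nb(0, 1); se <- nb(1, 1)
    s <- nb(1, 0);  sw <- nb(1, -1); w <- nb(0, -1); nw <- nb(-1, -1)
    N <- n + ne + e + se + s + sw + w + nw
    S <- (n == 0 & ne == 1) + (ne == 0 & e == 1) + (e == 0 & se == 1) +
         (se == 0 & s == 1) + (s == 0 & sw == 1) + (sw == 0 & w == 1) +
         (w == 0 & nw == 1) + (nw == 0 & n == 1)
    del <- m == 1 & N >= 2 & N <= 6 & S == 1 &
      (if (first) n * e * s == 0 & e * s * w == 0
       else       n * e * w == 0 & n * s * w == 0)
    m[del] <- 0L
    list(m = m, changed = any(del))
  }
  for (i in seq_len(max_iter)) {
    a <- substep(m, TRUE)
    b <- substep(a$m, FALSE)
    m <- b$m
    if (!a$changed && !b$changed) return(m)
  }
  rlang::abort("thinning did not converge within max_iter iterations",
               class = "stemdepth_nonconvergence_error")
}

#' Prune short skeleton branches
#'
#' Optional cleanup for field masks whose leaf stubs leave short side
#' branches on the skeleton: endpoints are peeled `min_branch` times, which
#' removes branches shorter than `min_branch` pixels while junctions and
#' the main line survive. Off by default.
#'
#' @param skeleton `{0,1}` skeleton matrix.
#' @param min_branch Number of peeling passes; 0 disables pruning.
#' @return Pruned `{0,1}` matrix.
#' @export
prune_skeleton <- function(skeleton, min_branch = 0) {
  check_binary(skeleton)
  m <- skeleton + 0L
  for (i in seq_len(min_branch)) {
    nr <- nrow(m); nc <- ncol(m)
    z <- matrix(0L, nr + 2, nc + 2); z[2:(nr + 1), 2:(nc + 1)] <- m
    nb <- function(dr, dc) z[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
    N <- nb(-1, 0) + nb(-1, 1) + nb(0, 1) + nb(1, 1) +
         nb(1, 0) + nb(1, -1) + nb(0, -1) + nb(-1, -1)
    ep <- m == 1 & N <= 1
    if (!any(ep)) break
    m[ep] <- 0L
  }
  m
}

#' Pick evenly spaced centreline points inside a row region of interest
#'
#' Lists the skeleton pixels whose row lies in `roi` (sorted by row) and
#' marks `n_scanlines` of them at rows evenly spaced across the interval;
#' each target row snaps to the nearest populated skeleton row, and a row
#' holding several skeleton pixels contributes its median column.
#'
#' @param skeleton `{0,1}` skeleton matrix.
#' @param roi Length-2 inclusive row interval, 0-based.
#' @param n_scanlines Number of points to select; default 3.
#' @return A tibble with columns `col`, `row` (0-based), one row per
#'   selected point, sorted by `row`.
#' @export
skeleton_points_in_roi <- function(skeleton, roi, n_scanlines = 3) {
  check_binary(skeleton)
  stopifnot(length(roi) == 2, roi[1] <= roi[2], n_scanlines >= 1)
  idx <- which(skeleton > 0)
  rows <- (idx - 1) %% nrow(skeleton)
  cols <- (idx - 1) %/% nrow(skeleton)
  keep <- rows >= roi[1] & rows <= roi[2]
  if (!any(keep)) {
    rlang::abort("no skeleton pixel inside the region of interest",
                 class = "stemdepth_empty_roi_error")
  }
  rows <- rows[keep]; cols <- cols[keep]
  targets <- round(seq(roi[1], roi[2], length.out = n_scanlines))
  avail <- sort(unique(rows))
  pick <- vapply(targets, function(t) avail[which.min(abs(avail - t))], 0)
  pick <- unique(pick)
  out <- tibble::tibble(
    row = pick,
    col = vapply(pick, function(r) stats::median(cols[rows == r]), 0))
  dplyr::arrange(dplyr::select(out, "col", "row"), .data$row)
}
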