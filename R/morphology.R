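# Small-kernel binary morphology on {0,1} matrices, with reflection padding
# at the borders so that filters never erode the raster edge (an all-ones
# mask stays all ones). Kernels are tiny (3x3, 5x5), so shifted-submatrix
# arithmetic is both fast and exactly auditable.

# reflect-pad a matrix by p pixels on every side
pad_reflect <- function(m, p) {
  nr <- nrow(m); nc <- ncol(m)
  if (p >= nr || p >= nc) {
    rlang::abort("kernel larger than image", class = "stemdepth_parameter_error")
  }
  ri <- c(rev(seq_len(p)), seq_len(nr), nr - seq_len(p) + 1)
  ci <- c(rev(seq_len(p)), seq_len(nc), nc - seq_len(p) + 1)
  m[ri, ci]
}

# offsets (drow, dcol) of a structuring element: "cross" (the 3x3 ellipse of
# common image libraries) or full "square"
se_offsets <- function(ksize, shape = c("cross", "square")) {
  shape <- match.arg(shape)
  r <- (ksize - 1) / 2
  g <- expand.grid(dr = -r:r, dc = -r:r)
  if (shape == "cross") g <- g[g$dr == 0 | g$dc == 0, ]
  g
}

morph_apply <- function(mask, ksize, shape, op) {
  stopifnot(ksize %% 2 == 1)
  r <- (ksize - 1) / 2
  pm <- pad_reflect(mask, r)
  nr <- nrow(mask); nc <- ncol(mask)
  off <- se_offsets(ksize, shape)
  acc <- NULL
  for (i in seq_len(nrow(off))) {
    blk <- pm[(1 + r + off$dr[i]):(nr + r + off$dr[i]),
              (1 + r + off$dc[i]):(nc + r + off$dc[i]), drop = FALSE]
    acc <- if (is.null(acc)) blk else op(acc, blk)
  }
  acc
}

binary_erode <- function(mask, ksize = 3, shape = "cross") {
  morph_apply(mask, ksize, shape, pmin)
}

binary_dilate <- function(mask, ksize = 3, shape = "cross") {
  morph_apply(mask, ksize, shape, pmax)
}

binary_open <- function(mask, ksize = 3, shape = "cross") {
  binary_dilate(binary_erode(mask, ksize, shape), ksize, shape)
}

# windowed sum over a k x k box, reflection padded
box_sum <- function(m, ksize) {
  r <- (ksize - 1) / 2
  pm <- pad_reflect(m, r)
  cs <- apply(pm, 2, cumsum)
  cs <- rbind(0, cs)
  rowsum <- cs[(2 * r + 2):nrow(cs), , drop = FALSE] -
    cs[1:(nrow(cs) - 2 * r - 1), , drop = FALSE]
  cs2 <- t(apply(rowsum, 1, cumsum))
  cs2 <- cbind(0, cs2)
  cs2[, (2 * r + 2):ncol(cs2), drop = FALSE] -
    cs2[, 1:(ncol(cs2) - 2 * r - 1), drop = FALSE]
}

# binary median filter: majority vote in a k x k window
binary_median <- function(mask, ksize = 5) {
  (box_sum(mask, ksize) >= (ksize * ksize + 1) / 2) + 0L
}

# 8-connected component labelling by vectorised breadth-first flood fill
label_components8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  fg <- which(mask > 0)
  if (length(fg) == 0) return(lab)
  neighbours <- function(idx) {
    r <- (idx - 1L) %% nr; c <- (idx - 1L) %/% nr
    out <- integer(0)
    for (dc in -1:1) for (dr in -1:1) {
      if (dr == 0 && dc == 0) next
      ok <- r + dr >= 0 & r + dr < nr & c + dc >= 0 & c + dc < nc
      out <- c(out, idx[ok] + dr + dc * nr)
    }
    out
  }
  current <- 0L
  inmask <- logical(nr * nc); inmask[fg] <- TRUE
  # scan order: row-major over 0-based (row, col) so the first unlabelled
  # pixel found is the component's top-left-most pixel
  scan <- fg[order((fg - 1L) %% nr, (fg - 1L) %/% nr)]
  for (s in scan) {
    if (lab[s] != 0L) next
    current <- current + 1L
    frontier <- s
    lab[s] <- current
    while (length(frontier)) {
      nb <- unique(neighbours(frontier))
      nb <- nb[inmask[nb] & lab[nb] == 0L]
      lab[nb] <- current
      frontier <- nb
    }
  }
  lab
}
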