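# Brute-force reference implementations used as independent oracles.
# These are written for clarity (explicit per-pixel loops), never for
# speed, and deliberately share no code with the package internals.

# exhaustive Otsu: scan all 256 split levels, maximise between-class
# variance directly from its definition, smallest level on ties
oracle_otsu <- function(h) {
  total <- sum(h)
  best <- -Inf; best_t <- NA
  for (t in 0:254) {
    n0 <- sum(h[1:(t + 1)]); n1 <- total - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum((0:t) * h[1:(t + 1)]) / n0
    mu1 <- sum(((t + 1):255) * h[(t + 2):256]) / n1
    v <- (n0 / total) * (n1 / total) * (mu0 - mu1)^2
    if (v > best + 1e-12) { best <- v; best_t <- t }
  }
  best_t
}

# reference two-subiteration thinning, per-pixel loops over a zero-padded
# copy, neighbours named P2..P9 clockwise from north as in the original
# algorithm statement
oracle_thin <- function(mask) {
  m <- mask
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      del <- matrix(FALSE, nrow(m), ncol(m))
      z <- matrix(0L, nrow(m) + 2, ncol(m) + 2)
      z[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
      for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
        if (m[i, j] != 1) next
        zi <- i + 1; zj <- j + 1
        p <- c(z[zi - 1, zj], z[zi - 1, zj + 1], z[zi, zj + 1],
               z[zi + 1, zj + 1], z[zi + 1, zj], z[zi + 1, zj - 1],
               z[zi, zj - 1], z[zi - 1, zj - 1])  # P2..P9 clockwise
        B <- sum(p)
        A <- sum(p == 0 & c(p[-1], p[1]) == 1)
        cond <- if (phase == 1) {
          p[1] * p[3] * p[5] == 0 && p[3] * p[5] * p[7] == 0
        } else {
          p[1] * p[3] * p[7] == 0 && p[1] * p[5] * p[7] == 0
        }
        if (B >= 2 && B <= 6 && A == 1 && cond) del[i, j] <- TRUE
      }
      if (any(del)) { m[del] <- 0L; changed <- TRUE }
    }
    if (!changed) return(m)
  }
}

# queue-based 8-connected flood fill
oracle_label <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (j in seq_len(ncol(mask))) for (i in seq_len(nrow(mask))) {
    if (mask[i, j] == 1 && lab[i, j] == 0L) {
      cur <- cur + 1L
      queue <- list(c(i, j)); lab[i, j] <- cur
      while (length(queue)) {
        q <- queue[[1]]; queue <- queue[-1]
        for (di in -1:1) for (dj in -1:1) {
          ii <- q[1] + di; jj <- q[2] + dj
          if (ii >= 1 && ii <= nrow(mask) && jj >= 1 && jj <= ncol(mask) &&
              mask[ii, jj] == 1 && lab[ii, jj] == 0L) {
            lab[ii, jj] <- cur
            queue[[length(queue) + 1]] <- c(ii, jj)
          }
        }
      }
    }
  }
  lab
}

# per-pixel median filter + opening with reflected borders (cross element)
oracle_denoise <- function(mask, med_k = 5, open_k = 3) {
  refl <- function(i, n) {
    if (i < 1) 1 - i else if (i > n) 2 * n - i + 1 else i
  }
  at <- function(m, i, j) m[refl(i, nrow(m)), refl(j, ncol(m))]
  win <- function(m, i, j, r) {
    v <- c()
    for (di in -r:r) for (dj in -r:r) v <- c(v, at(m, i + di, j + dj))
    v
  }
  med <- mask
  r <- (med_k - 1) / 2
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    med[i, j] <- as.integer(sum(win(mask, i, j, r)) >= (med_k^2 + 1) / 2)
  }
  cross <- function(m, i, j) {
    c(m[refl(i, nrow(m)), refl(j, ncol(m))], at(m, i - 1, j),
      at(m, i + 1, j), at(m, i, j - 1), at(m, i, j + 1))
  }
  er <- med
  for (i in seq_len(nrow(med))) for (j in seq_len(ncol(med))) {
    er[i, j] <- as.integer(all(cross(med, i, j) == 1))
  }
  di <- er
  for (i in seq_len(nrow(er))) for (j in seq_len(ncol(er))) {
    di[i, j] <- as.integer(any(cross(er, i, j) == 1))
  }
  di
}

# two-sided signed-rank p-value by enumerating every sign assignment
oracle_wilcoxon_exact <- function(w, k) {
  d <- w - k
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  rk <- rank(abs(d))
  center <- sum(rk) / 2
  obs <- abs(sum(rk[d > 0]) - center)
  count <- 0L
  for (code in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(code)[1:n])
    if (abs(sum(rk[bits == 1]) - center) >= obs - 1e-12) count <- count + 1L
  }
  count / 2^n
}

# random blob mask: union of random discs, fixed by the caller's seed
random_blob_mask <- function(nr = 36, nc = 36, n_discs = 4) {
  m <- matrix(0L, nr, nc)
  for (b in seq_len(n_discs)) {
    ci <- sample(5:(nr - 5), 1); cj <- sample(5:(nc - 5), 1)
    r <- sample(2:6, 1)
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      if ((i - ci)^2 + (j - cj)^2 <= r^2) m[i, j] <- 1L
    }
  }
  m
}

# small camera for fast module-level scenes (renders ~20x faster than the
# full 848x480 default)
small_camera <- function() {
  camera_model(
    color = intrinsics(300, 300, 159.5, 119.5, 320, 240),
    depth = intrinsics(260, 260, 160.2, 120.4, 320, 240),
    depth_to_color = extrinsics(diag(3), c(0.0147, 0, 0)),
    depth_scale = 0.001)
}

small_scene <- function(...) {
  scene_spec(cam = small_camera(), ...)
}

# coordinates of a point3 without its frame attribute, for comparisons
pt_xyz <- function(p) stats::setNames(as.numeric(p), c("x", "y", "z"))
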