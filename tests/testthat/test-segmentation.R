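test_that("Otsu threshold matches the exhaustive between-class-variance scan", {
  # bimodal two-spike histogram: any level in [10, 200) separates; the
  # smallest is returned and the classes split perfectly
  h <- numeric(256); h[11] <- 40; h[201] <- 60
  t0 <- otsu_threshold(h)
  expect_identical(t0, oracle_otsu(h))
  lv <- c(rep(10, 40), rep(200, 60))
  expect_true(all((lv <= t0) == (lv == 10)))
  set.seed(21)
  for (i in 1:25) {
    h <- rpois(256, lambda = sample(c(0.5, 2, 20), 256, replace = TRUE))
    if (sum(h) == 0 || sum(h > 0) < 2) next
    expect_identical(otsu_threshold(h), oracle_otsu(h))
  }
  # uniform histogram: tie-broken to the brute-force (smallest) level
  hu <- rep(4, 256)
  expect_identical(otsu_threshold(hu), oracle_otsu(hu))
  expect_warning(otsu_threshold(c(rep(0, 100), 5, rep(0, 155))),
                 class = "stemdepth_degenerate_warning")
  expect_error(otsu_threshold(numeric(256)), class = "stemdepth_parameter_error")
})

test_that("Otsu agrees with an independent image-library implementation", {
  set.seed(33)
  img <- matrix(c(rnorm(3000, 80, 12), rnorm(3000, 180, 15)), 60, 100)
  img <- pmin(pmax(round(img), 0), 255)
  h <- tabulate(as.vector(img) + 1L, nbins = 256)
  ours <- otsu_threshold(h)
  eb <- round(EBImage::otsu(EBImage::Image(img / 255), range = c(0, 1),
                            levels = 256) * 255)
  # the libraries bin [0,1] differently (k/255 grid vs 256 equal bins), so
  # thresholds differ by a few levels; both must fall in the valley between
  # the two class modes (80 and 180)
  expect_true(ours > 100 && ours < 165)
  expect_true(eb > 100 && eb < 165)
})

test_that("hue-gated Otsu segmentation separates green from brown exactly", {
  rgb <- array(0, c(40, 60, 3))
  rgb[, , 1] <- 0.55; rgb[, , 2] <- 0.35; rgb[, , 3] <- 0.15  # brown, H = 30
  patch_r <- 10:25; patch_c <- 20:35
  rgb[patch_r, patch_c, 1] <- 0.55                            # green, H ~ 81
  rgb[patch_r, patch_c, 2] <- 0.80
  rgb[patch_r, patch_c, 3] <- 0.10
  mask <- hsv_otsu_segment(rgb, hue_range = c(35, 85))
  truth <- matrix(0L, 40, 60); truth[patch_r, patch_c] <- 1L
  expect_identical(mask, truth)
  # all-black image: nothing passes the gate, empty mask with a warning
  expect_warning(m0 <- hsv_otsu_segment(array(0, c(8, 8, 3))),
                 class = "stemdepth_empty_mask_warning")
  expect_true(all(m0 == 0))
})

test_that("segmentation covers a noiseless rendered stem almost exactly", {
  sc <- render_scene(small_scene(diameter_mm = 30, distance_m = 0.5))
  mask <- hsv_otsu_segment(sc$rgb)
  sil <- sc$truth$silhouette
  expect_gte(sum(mask * sil) / sum(sil), 0.95)       # >= 95% of stem found
  expect_lte(sum(mask * (1 - sil)) / sum(mask), 0.05)  # <= 5% background
})

test_that("denoise removes speckle, keeps blobs, and matches the per-pixel oracle", {
  m <- matrix(0L, 40, 80)
  m[10:30, 20:60] <- 1L
  set.seed(9)
  speck <- m
  off <- which(m == 0)
  spots <- sample(off, 25)
  speck[spots] <- 1L
  out <- denoise(speck)
  expect_true(all(out[spots] == 0))  # isolated speckles removed
  expect_true(all(out[12:28, 22:58] == 1))  # blob interior preserved
  expect_identical(out, oracle_denoise(speck))
  allones <- matrix(1L, 20, 20)
  expect_identical(denoise(allones), allones)  # reflection borders: no erosion
  # random speckle field over a solid bar vs the brute-force reference
  set.seed(10)
  bar <- matrix(0L, 30, 60); bar[8:22, 5:55] <- 1L
  noisy <- bar; noisy[sample(length(bar), 18)] <- 1L
  expect_identical(denoise(noisy), oracle_denoise(noisy))
  expect_error(denoise(matrix(1L, 3, 3), median_ksize = 9),
               class = "stemdepth_parameter_error")
})

test_that("largest_component keeps the biggest 8-connected blob", {
  m <- matrix(0L, 30, 30)
  m[2:11, 2:6] <- 1L       # 50 px
  m[20:24, 20:21] <- 1L    # 10 px
  out <- largest_component(m)
  expect_equal(sum(out), 50)
  expect_true(all(out[2:11, 2:6] == 1))
  single <- matrix(0L, 10, 10); single[3:6, 3:6] <- 1L
  expect_identical(largest_component(single), single)
  expect_error(largest_component(matrix(0L, 5, 5)),
               class = "stemdepth_empty_mask_error")
})

test_that("component labelling agrees with a flood-fill oracle on random blobs", {
  set.seed(14)
  for (i in 1:8) {
    m <- random_blob_mask(30, 30, n_discs = 5)
    if (!any(m == 1)) next
    keep <- largest_component(m)
    lab <- oracle_label(m)
    counts <- tabulate(lab[lab > 0])
    expect_equal(sum(keep), max(counts))
    # the kept set is exactly one oracle component
    ids <- unique(lab[keep == 1])
    expect_length(ids, 1)
    expect_equal(sum(lab == ids), sum(keep))
  }
})

test_that("internal gradient contour is the object's inner boundary", {
  sq <- matrix(0L, 20, 20); sq[6:15, 6:15] <- 1L   # 10x10 solid square
  ring <- internal_gradient_contour(sq)
  expect_equal(sum(ring), 36)                      # forced by geometry
  expect_true(all(ring[sq == 0] == 0))             # contour within mask
  # vertical 5-px bar: two edge lines plus end caps, checked per pixel
  bar <- matrix(0L, 30, 20); bar[5:25, 8:12] <- 1L
  ct <- internal_gradient_contour(bar)
  expected <- bar
  expected[6:24, 9:11] <- 0L
  expect_identical(ct, expected)
  # set algebra on random blobs: contour == mask minus eroded interior
  set.seed(15)
  for (i in 1:5) {
    m <- random_blob_mask(25, 25, 3)
    ctr <- internal_gradient_contour(m)
    expect_true(all(ctr <= m))
    inner <- m - ctr
    expect_true(all(ctr * inner == 0))
    # every contour pixel touches background within its 8-neighbourhood
    idx <- which(ctr == 1)
    pad <- matrix(0L, 27, 27); pad[2:26, 2:26] <- m
    for (id in idx) {
      r <- (id - 1) %% 25 + 2; c <- (id - 1) %/% 25 + 2
      expect_lt(min(pad[(r - 1):(r + 1), (c - 1):(c + 1)]), 1)
    }
  }
})

test_that("masks written as PNG read back unchanged", {
  m <- random_blob_mask(20, 20, 2)
  f <- withr::local_tempfile(fileext = ".png")
  write_mask(m, f)
  back <- (read_image(f) > 0.5) + 0L
  expect_identical(matrix(back, 20, 20), m)
})
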