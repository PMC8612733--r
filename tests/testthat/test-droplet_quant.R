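test_that("dark-frame subtraction removes the scalar offset and clamps at zero", {
  img <- image2d(matrix(100, 8, 8))
  dark <- image2d(matrix(10, 8, 8))
  expect_equal(unclass(subtract_dark_frame(img, dark)),
               matrix(90, 8, 8), ignore_attr = TRUE)
  # mixed dark pixels reduce to their mean; negatives clamp
  img2 <- image2d(matrix(c(20, 10), 1, 2))
  dark2 <- image2d(matrix(c(12, 13), 1, 2))
  expect_equal(as.numeric(subtract_dark_frame(img2, dark2)), c(7.5, 0))
  expect_error(subtract_dark_frame(img, image2d(matrix(1, 4, 4))),
               "shape")
})

test_that("constant images yield an empty (but valid) mask", {
  m <- make_droplet_mask(image2d(matrix(5, 32, 32)))
  expect_identical(m$n_droplets, 0L)
  expect_true(all(m$labels == 0))
  expect_identical(dim(m$labels), c(32L, 32L))
})

test_that("a hard-edged disk is segmented with exactly its rasterized area", {
  shape <- c(64L, 64L)
  disk <- disk_pixels(shape, c(32, 32), 5)
  px <- matrix(10, shape[1], shape[2]); px[disk] <- 100
  m <- make_droplet_mask(image2d(px))
  expect_identical(m$n_droplets, 1L)
  expect_identical(sum(m$labels > 0), sum(disk))
  expect_true(all((m$labels > 0) == disk))
})

test_that("an isolated hot pixel is removed by the despeckle step itself", {
  shape <- c(64L, 64L)
  disk <- disk_pixels(shape, c(32, 32), 5)
  px <- matrix(10, shape[1], shape[2]); px[disk] <- 100
  px[5, 5] <- 100
  # min_area 1 so only the median despeckle can remove the hot pixel
  m <- make_droplet_mask(image2d(px), mask_params(min_area_px = 1))
  expect_identical(m$n_droplets, 1L)
  expect_false(m$labels[5, 5] > 0)
})

test_that("labeling matches a BFS oracle with 8-connectivity on random fields", {
  withr::with_seed(7, {
    for (rep in 1:5) {
      bin <- matrix(runif(40 * 40) < 0.05, 40, 40)
      px <- matrix(10, 40, 40); px[bin] <- 100
      m <- make_droplet_mask(image2d(px),
                             mask_params(median_radius_px = 0, min_area_px = 1))
      oracle <- bfs_label(bin)
      expect_identical(m$n_droplets, max(oracle))
      # identical partition of pixels into components
      expect_identical(m$labels > 0, oracle > 0)
      agree <- tapply(m$labels[bin], oracle[bin],
                      function(v) length(unique(v)))
      expect_true(all(agree == 1))
    }
  })
})

test_that("droplet labels follow raster-scan order and min_area filters small blobs", {
  px <- matrix(10, 32, 32)
  px[20:24, 2:6] <- 100     # big blob, later row
  px[2:4, 20:22] <- 100     # small blob (9 px), earlier row
  px[10, 10] <- 100         # single pixel
  m <- make_droplet_mask(image2d(px), mask_params(min_area_px = 1))
  expect_identical(m$n_droplets, 2L)  # hot pixel despeckled
  expect_identical(m$labels[2, 20], 1L)   # first in raster order
  expect_identical(m$labels[20, 2], 2L)
  m2 <- make_droplet_mask(image2d(px), mask_params(min_area_px = 10))
  expect_identical(m2$n_droplets, 1L)
})

test_that("droplet statistics equal a pixel-loop oracle", {
  px <- matrix(10, 64, 64)
  px[10:12, 10:12] <- 100                       # 9 px at 100
  d2 <- disk_pixels(c(64L, 64L), c(40, 40), 4)
  px[d2] <- 120
  img <- image2d(px, pixel_size_um = 0.2)
  m <- make_droplet_mask(img)
  st <- droplet_stats(img, m)
  expect_identical(nrow(st), 2L)
  expect_equal(st$mean_intensity, c(100, 120))
  expect_equal(st$integrated_intensity[1], 900)
  expect_equal(st$area_px[2], sum(d2))
  expect_equal(st$area_um2, st$area_px * 0.04)
  # centroids, 0-based (row, col)
  expect_equal(st$centroid_row[1], 10)  # rows 10:12 are 0-based 9:11
  expect_equal(st$centroid_col[1], 10)
  expect_identical(nrow(droplet_stats(img, make_droplet_mask(image2d(matrix(1, 64, 64))))),
                   0L)
})

test_that("field quantification reproduces hand-computed PC and RC", {
  px <- matrix(10, 64, 64)
  d1 <- disk_pixels(c(64L, 64L), c(20, 20), 4)
  d2 <- disk_pixels(c(64L, 64L), c(45, 45), 4)
  px[d1] <- 80; px[d2] <- 120
  img <- image2d(px)
  fq <- field_quant(img, make_droplet_mask(img))
  expect_equal(fq$I_DP, 100)
  expect_equal(fq$I_LP, 10)
  expect_equal(fq$PC, 10)
  # one 9-px droplet at 100 over 4087 px at 10
  px2 <- matrix(10, 64, 64); px2[30:32, 30:32] <- 100
  img2 <- image2d(px2)
  fq2 <- field_quant(img2, make_droplet_mask(img2))
  expect_equal(fq2$RC, 900 / (900 + 40870))
  expect_equal(fq2$I_in + fq2$I_out, sum(px2))
  # no droplets: RC = 0, PC missing
  fq0 <- field_quant(image2d(matrix(7, 32, 32)),
                     make_droplet_mask(image2d(matrix(7, 32, 32))))
  expect_identical(fq0$RC, 0)
  expect_true(is.na(fq0$PC))
  expect_identical(fq0$flag, "no-droplets")
})

test_that("two-channel quantification masks from the protein channel only", {
  spec <- droplet_field_spec(n_droplets = 6, seed = 21)
  f <- gen_droplet_field(spec, channel2 = list(I_dense = 50, I_dilute = 5))
  tc <- field_quant_two_channel(f$image, f$channel2)
  expect_equal(tc$rna$PC, 10)
  expect_equal(tc$protein$PC, 10)
  # uniform RNA channel: no partitioning, PC = 1
  flat <- image2d(matrix(20, spec$shape[1], spec$shape[2]))
  tc2 <- field_quant_two_channel(f$image, flat)
  expect_equal(tc2$rna$PC, 1)
  # protein field with no droplets: both RC = 0
  blank <- image2d(matrix(10, 32, 32))
  tc3 <- field_quant_two_channel(blank, image2d(matrix(30, 32, 32)))
  expect_identical(tc3$protein$RC, 0)
  expect_identical(tc3$rna$RC, 0)
  expect_error(field_quant_two_channel(blank, image2d(matrix(1, 8, 8))),
               "shape")
})

test_that("pixel-sum identity and analytic PC/RC hold across seeded noiseless fields", {
  for (seed in 1:10) {
    spec <- droplet_field_spec(shape = c(128L, 128L), n_droplets = 5,
                               radius_px = c(3L, 6L), seed = seed)
    f <- gen_droplet_field(spec)
    img <- f$image
    m <- make_droplet_mask(img)
    fq <- field_quant(img, m)
    expect_identical(fq$I_in + fq$I_out, sum(unclass(img)))
    expect_identical(fq$n_droplets, spec$n_droplets)
    expect_equal(fq$PC, f$truth$pc, tolerance = 0)
    expect_equal(fq$RC, f$truth$rc, tolerance = 0)
  }
})

test_that("PC and RC are invariant to droplet relabeling", {
  f <- gen_droplet_field(droplet_field_spec(n_droplets = 5, seed = 9))
  m <- make_droplet_mask(f$image)
  fq <- field_quant(f$image, m)
  perm <- rev(seq_len(m$n_droplets))
  m2 <- m
  m2$labels[m$labels > 0] <- perm[m$labels[m$labels > 0]]
  fq2 <- field_quant(f$image, m2)
  expect_equal(fq2$PC, fq$PC)
  expect_equal(fq2$RC, fq$RC)
})

test_that("raising the dense intensity never decreases PC or RC", {
  pcs <- rcs <- numeric(0)
  for (I_dense in c(40, 80, 160, 320)) {
    f <- gen_droplet_field(droplet_field_spec(n_droplets = 5, I_dense = I_dense,
                                              seed = 4))
    fq <- field_quant(f$image, make_droplet_mask(f$image))
    pcs <- c(pcs, fq$PC); rcs <- c(rcs, fq$RC)
  }
  expect_true(all(diff(pcs) >= 0))
  expect_true(all(diff(rcs) >= 0))
})

test_that("concentration sweep reports per-concentration summaries and the onset", {
  mk <- function(conc, n) {
    spec <- droplet_field_spec(n_droplets = n, seed = 100 + conc * 10 + n)
    f <- gen_droplet_field(spec)
    list(concentration_uM = conc,
         quant = field_quant(f$image, make_droplet_mask(f$image)))
  }
  fields <- list(mk(1, 0), mk(3, 0), mk(5, 4), mk(5, 6), mk(10, 8))
  sw <- concentration_sweep(fields)
  expect_identical(sw$onset_uM, 5)
  expect_identical(nrow(sw$table), 4L)
  expect_equal(sw$table$mean_n_droplets[sw$table$concentration_uM == 5], 5)
  # all-empty sweep: no onset
  sw0 <- concentration_sweep(list(mk(1, 0), mk(2, 0)))
  expect_true(is.na(sw0$onset_uM))
  # single concentration: one row
  expect_identical(nrow(concentration_sweep(list(mk(5, 3)))$table), 1L)
  expect_error(concentration_sweep(list()), "empty")
})
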