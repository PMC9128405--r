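test_that("well-separated nuclei are segmented with sub-pixel centroids", {
  q <- quantified_tile(seed = 5, n_cells = 20, positive_fraction = 0)
  expect_equal(max(q$nuclei$labels), 20L)
  cen <- mask_centroids(q$nuclei)
  tr <- q$sim$truth$centroids
  d <- sqrt(outer(cen$x, tr$x, "-")^2 + outer(cen$y, tr$y, "-")^2)
  expect_lte(max(apply(d, 2, min)), 1)
})

test_that("blank background yields an empty mask, not an error", {
  q <- quantified_tile(seed = 2, n_cells = 0)
  expect_equal(max(q$nuclei$labels), 0L)
  expect_equal(nrow(mask_centroids(q$nuclei)), 0L)
  # exactly-zero plane too
  mk <- segment_nuclei(matrix(0, 64, 64), mpp = 0.5)
  expect_equal(max(mk$labels), 0L)
})

test_that("distance-transform watershed splits touching disks", {
  # two disks of radius 8 px whose centres sit 1.8 r apart
  # (overlapping by 20% of the radius)
  h <- matrix(0, 96, 96)
  r <- 8
  for (ctr in list(c(40, 48), c(40 + 1.8 * r, 48))) {
    dd <- outer((seq_len(96) - 0.5 - ctr[2])^2,
                (seq_len(96) - 0.5 - ctr[1])^2, "+")
    h[dd <= r^2] <- 0.75
  }
  mk <- segment_nuclei(h, mpp = 0.5, max_area_um2 = 200)
  expect_equal(max(mk$labels), 2L)
})

test_that("nucleus count matches ground truth on default tiles", {
  for (seed in 1:3) {
    q <- quantified_tile(seed = seed, n_cells = 35)
    expect_equal(max(q$nuclei$labels), 35L)
  }
})

test_that("ring pixel count matches the annulus of the discrete disk", {
  # single disk r = 5 px; ring width 2 um at mpp 0.5 = 4 px. The ring is
  # the Euclidean-distance dilation (pixels within 4 px of a nucleus
  # pixel) minus the nucleus - the convention of cell-expansion tools.
  lab <- matrix(0L, 64, 64)
  dd <- outer((seq_len(64) - 0.5 - 32)^2, (seq_len(64) - 0.5 - 32)^2, "+")
  lab[dd <= 25] <- 1L
  mk <- structure(list(labels = lab, mpp = 0.5), class = "label_mask")
  rg <- ring_regions(mk, ring_width_um = 2)
  n_ring <- sum(rg$labels == 1L)
  # independent brute-force oracle: per-pixel minimum distance to any
  # nucleus pixel centre
  idx <- which(lab == 1L)
  ny <- ((idx - 1) %% 64) + 0.5; nx <- ((idx - 1) %/% 64) + 0.5
  bg <- which(lab == 0L)
  by <- ((bg - 1) %% 64) + 0.5; bx <- ((bg - 1) %/% 64) + 0.5
  mind <- apply(sqrt(outer(bx, nx, "-")^2 + outer(by, ny, "-")^2), 1, min)
  expect_equal(n_ring, sum(mind <= 4))
  # and the count tracks the continuous annulus pi (9^2 - 5^2) ~ 176 up
  # to the half-pixel boundary discretization of both circles
  expect_lt(abs(n_ring - pi * (9^2 - 5^2)) / (pi * (9^2 - 5^2)), 0.12)
})

test_that("rings are clipped at the border and never overlap nuclei", {
  lab <- matrix(0L, 48, 48)
  dd <- outer((seq_len(48) - 0.5 - 3)^2, (seq_len(48) - 0.5 - 24)^2, "+")
  lab[dd <= 16] <- 1L                      # nucleus near the top border
  mk <- structure(list(labels = lab, mpp = 0.5), class = "label_mask")
  expect_silent(rg <- ring_regions(mk, 2))
  expect_equal(sum(rg$labels > 0 & mk$labels > 0), 0L)
})

test_that("rings of adjacent nuclei are disjoint and claim by nearest centroid", {
  q <- quantified_tile(seed = 9, n_cells = 25, positive_fraction = 0)
  rg <- ring_regions(q$nuclei, 2)
  expect_equal(sum(rg$labels > 0 & q$nuclei$labels > 0), 0L)
  # each ring pixel's label is the nearest nucleus centroid
  cen <- mask_centroids(q$nuclei)
  idx <- which(rg$labels > 0)
  rows <- ((idx - 1) %% nrow(rg$labels)) + 0.5
  cols <- ((idx - 1) %/% nrow(rg$labels)) + 0.5
  d2 <- outer(cols, cen$x, "-")^2 + outer(rows, cen$y, "-")^2
  expect_equal(rg$labels[idx], cen$label[max.col(-d2, "first")])
})

test_that("label masks survive a 16-bit TIFF round trip", {
  q <- quantified_tile(seed = 4, n_cells = 10, width = 128, height = 128)
  path <- tempfile(fileext = ".tif")
  write_label_mask(q$nuclei, path)
  back <- read_label_mask(path, mpp = 0.5)
  expect_identical(back$labels, q$nuclei$labels)
})

test_that("area filter removes out-of-range objects", {
  h <- matrix(0, 96, 96)
  dd1 <- outer((seq_len(96) - 0.5 - 20)^2, (seq_len(96) - 0.5 - 20)^2, "+")
  h[dd1 <= 2^2] <- 0.75                    # ~12 px ~ 3 um^2: too small
  dd2 <- outer((seq_len(96) - 0.5 - 60)^2, (seq_len(96) - 0.5 - 60)^2, "+")
  h[dd2 <= 8^2] <- 0.75                    # ~200 px ~ 50 um^2: kept
  mk <- segment_nuclei(h, mpp = 0.5)
  expect_equal(max(mk$labels), 1L)
  expect_gt(sum(mk$labels == 1L), 100)
})
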