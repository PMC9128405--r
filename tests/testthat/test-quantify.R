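test_that("DAB positivity mask thresholds strictly and validates the cutoff", {
  expect_equal(sum(dab_positive_mask(matrix(0, 10, 10), 0.3)), 0L)
  m <- matrix(0.3, 4, 4)
  expect_false(any(dab_positive_mask(m, 0.3)))   # strict >
  expect_true(all(dab_positive_mask(m + 1e-9, 0.3)))
  expect_error(dab_positive_mask(m, 0), "positive")
})

test_that("mask area matches painted area after a full RGB round trip", {
  # rectangle painted at DAB OD 0.6 over the background, noise-free
  m <- hdab_stain_matrix()
  H <- 120; W <- 120
  bg_od <- -log10((c(244, 242, 245) + 1) / 255)
  dab <- matrix(0, H, W); dab[31:90, 41:100] <- 0.6
  img <- array(0, c(H, W, 3))
  for (ch in 1:3)
    img[, , ch] <- round(255 * 10^(-(bg_od[ch] + dab * m["dab", ch])) - 1)
  dec <- deconvolve(rgb_to_od(img), m)
  mask <- dab_positive_mask(dec$dab, 0.3)
  painted <- sum(dab > 0)
  expect_lt(abs(sum(mask) - painted) / painted, 0.02)
  expect_false(any(dab_positive_mask(dec$dab, 0.7)))  # cutoff above paint
})

test_that("nuclear-pattern positives are called under the nucleus rule", {
  q <- quantified_tile(seed = 21, n_cells = 20, positive_fraction = 0.5)
  pos <- dab_positive_mask(q$od$dab, 0.3)
  cells <- call_positive_cells(q$nuclei, NULL, pos, "nucleus_overlap", 0.05)
  expect_equal(nrow(cells), 20L)
  expect_equal(sum(cells$positive), 10L)
  expect_true(all(cells$overlap_fraction[cells$positive] >= 0.05))
})

test_that("membranous staining crosses over between compartment rules", {
  q <- quantified_tile(seed = 22, n_cells = 20, positive_fraction = 0.5,
                       stain_pattern = "membranous")
  pos <- dab_positive_mask(q$od$dab, 0.3)
  rings <- ring_regions(q$nuclei, 2)
  nuc_rule <- call_positive_cells(q$nuclei, NULL, pos, "nucleus_overlap", 0.05)
  ring_rule <- call_positive_cells(q$nuclei, rings, pos, "ring_overlap", 0.05)
  expect_equal(sum(nuc_rule$positive), 0L)
  expect_equal(sum(ring_rule$positive), 10L)
})

test_that("empty label mask yields an empty record list", {
  mk <- structure(list(labels = matrix(0L, 32, 32), mpp = 0.5),
                  class = "label_mask")
  cells <- call_positive_cells(mk, NULL, matrix(TRUE, 32, 32),
                               "nucleus_overlap", 0.05)
  expect_equal(nrow(cells), 0L)
  expect_error(call_positive_cells(mk, NULL, matrix(TRUE, 16, 16),
                                   "nucleus_overlap"), "shape")
})

test_that("ROI area arithmetic: tumor minus contained necrosis", {
  ann <- list(
    tumor = list(cbind(x = c(0, 1000, 1000, 0), y = c(0, 0, 1000, 1000))),
    necrosis = list(cbind(x = c(100, 300, 300, 100), y = c(100, 100, 300, 300))))
  roi <- build_roi(ann, 1000, 1000, mpp = 0.5)
  expect_equal(roi$area_mm2, (1e6 - 4e4) * 0.25 / 1e6)   # 0.24 mm^2
})

test_that("disjoint and partially overlapping necrosis subtract correctly", {
  tumor <- list(cbind(x = c(0, 100, 100, 0), y = c(0, 0, 100, 100)))
  # disjoint necrosis: no effect
  roi1 <- build_roi(list(tumor = tumor,
                         necrosis = list(cbind(x = c(150, 180, 180, 150),
                                               y = c(10, 10, 40, 40)))),
                    200, 200, mpp = 1)
  expect_equal(roi1$area_mm2, 1e4 / 1e6)
  # partial overlap: only the intersection [50,100] x [0,50] is removed
  roi2 <- build_roi(list(tumor = tumor,
                         necrosis = list(cbind(x = c(50, 150, 150, 50),
                                               y = c(-50, -50, 50, 50)))),
                    200, 200, mpp = 1)
  expect_equal(roi2$area_mm2, (1e4 - 2500) / 1e6)
  expect_error(build_roi(list(tumor = list(), necrosis = list()), 10, 10, 1),
               "empty ROI")
})

test_that("annotation GeoJSON round-trips through the QuPath dialect", {
  tumor <- cbind(x = c(0, 64, 64, 0), y = c(0, 0, 64, 64))
  necro <- list(cbind(x = c(10, 20, 20, 10), y = c(10, 10, 20, 20)))
  path <- tempfile(fileext = ".geojson")
  write_annotations_geojson(tumor, necro, path)
  back <- read_annotations_geojson(path)
  expect_equal(length(back$tumor), 1L)
  expect_equal(length(back$necrosis), 1L)
  expect_equal(back$tumor[[1]][1:4, ], tumor, ignore_attr = TRUE)
})

test_that("density arithmetic and necrosis exclusion", {
  roi <- build_roi(list(tumor = list(cbind(x = c(0, 100, 100, 0),
                                           y = c(0, 0, 100, 100))),
                        necrosis = list()), 100, 100, mpp = sqrt(0.5 * 1e6) / 100)
  expect_equal(roi$area_mm2, 0.5, tolerance = 1e-12)
  cells <- data.frame(x = runif(50, 1, 99), y = runif(50, 1, 99),
                      positive = TRUE)
  expect_equal(compute_density(cells, roi)$density, 100)
  none <- cells; none$positive <- FALSE
  expect_equal(compute_density(none, roi)$density, 0)
})

test_that("generator cells inside necrosis are excluded from the density", {
  p <- ihc_sim_params(n_cells = 60, positive_fraction = 1,
                      necrosis_fraction = 0.25, seed = 31)
  sim <- generate_ihc_image(p)
  tr <- sim$truth
  roi <- build_roi(list(tumor = list(tr$tumor_polygon),
                        necrosis = tr$necrosis_polygons),
                   p$width, p$height, p$mpp)
  expect_equal(roi$area_mm2, tr$roi_area_mm2, tolerance = 1e-12)
  cells <- data.frame(x = tr$centroids$x, y = tr$centroids$y,
                      positive = tr$positive)
  in_necro <- tr$centroids$x >= tr$necrosis_polygons[[1]][1, "x"] &
              tr$centroids$y >= tr$necrosis_polygons[[1]][1, "y"]
  d <- compute_density(cells, roi)
  expect_equal(d$positive_count, sum(!in_necro))
})

test_that("density is invariant to tiling into quadrants", {
  q <- quantified_tile(seed = 41, n_cells = 30, positive_fraction = 0.6)
  pos <- dab_positive_mask(q$od$dab, 0.3)
  cells <- call_positive_cells(q$nuclei, NULL, pos, "nucleus_overlap", 0.05)
  W <- q$params$width; H <- q$params$height; mpp <- q$params$mpp
  whole <- compute_density(cells, build_roi(
    list(tumor = list(cbind(x = c(0, W, W, 0), y = c(0, 0, H, H))),
         necrosis = list()), W, H, mpp))
  quads <- expand.grid(x0 = c(0, W / 2), y0 = c(0, H / 2))
  counts <- 0; areas <- 0
  for (i in seq_len(4)) {
    x0 <- quads$x0[i]; y0 <- quads$y0[i]
    roi <- build_roi(list(tumor = list(cbind(
      x = c(x0, x0 + W / 2, x0 + W / 2, x0),
      y = c(y0, y0, y0 + H / 2, y0 + H / 2))), necrosis = list()),
      W, H, mpp)
    dq <- compute_density(cells, roi)
    counts <- counts + dq$positive_count
    areas <- areas + dq$roi_area_mm2
  }
  expect_equal(counts, whole$positive_count)
  expect_equal(areas, whole$roi_area_mm2, tolerance = 1e-12)
  expect_equal(counts / areas, whole$density, tolerance = 1e-12)
})

test_that("end-to-end density on synthetic tiles stays within 5% of truth", {
  cfg <- run_config()
  for (spec in list(list(seed = 51, pattern = "nuclear", marker = "CD3"),
                    list(seed = 52, pattern = "membranous", marker = "CD45RO"))) {
    p <- ihc_sim_params(n_cells = 60, positive_fraction = 0.4,
                        stain_pattern = spec$pattern, seed = spec$seed)
    sim <- generate_ihc_image(p)
    ann <- list(tumor = list(sim$truth$tumor_polygon), necrosis = list())
    q <- quantify_tile(sim$image, ann, spec$marker, cfg, "P1")
    truth_density <- sum(sim$truth$positive) / sim$truth$roi_area_mm2
    expect_lt(abs(q$density$density - truth_density) / truth_density, 0.05)
  }
})
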