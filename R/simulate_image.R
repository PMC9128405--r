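#' Simulated H-DAB IHC tiles with exact ground truth
#'
#' The generator paints elliptical nuclei in haematoxylin-like colour on a
#' near-white background; marker-positive cells additionally carry DAB
#' chromogen, either over the nucleus (nuclear stains such as CD3/CD8
#' visualised against the nuclear compartment) or as a perinuclear ring
#' (membranous stains such as CD45RO). Chromogens are painted along the
#' default H-DAB stain vectors in optical-density space and converted back
#' to 8-bit RGB, so colour deconvolution recovers them. Every painted cell
#' is recorded in the returned ground truth.
#'
#' @name simulate-images
NULL

#' Parameters for the IHC tile simulator
#'
#' @param width,height tile size in pixels (>= 64).
#' @param mpp microns per pixel (> 0); default 0.5, typical for x200 scans.
#' @param n_cells number of nuclei to place.
#' @param positive_fraction fraction of cells painted marker-positive; the
#'   positive count is exactly `round(n_cells * positive_fraction)`.
#' @param stain_pattern `"nuclear"` (DAB over the nucleus) or
#'   `"membranous"` (DAB ring around the nucleus).
#' @param nucleus_radius_range min/max nucleus radius in microns.
#' @param dab_od_positive peak DAB optical density painted in positive
#'   regions; default 0.6.
#' @param haematoxylin_od nuclear haematoxylin optical density; default 0.75.
#' @param ring_width_um width of the painted membranous rim in microns;
#'   default 1 (a thin membrane stain, narrower than the 2 um scoring
#'   annulus so a cell's rim stays out of its neighbours' annuli at the
#'   default spacing).
#' @param noise_sd Gaussian pixel noise (8-bit RGB units) added to the
#'   rendered tile; default 3. Set 0 for a noise-free tile.
#' @param necrosis_fraction fraction of the tile covered by a necrosis
#'   rectangle (annotated, excluded from the ROI); cells are still placed
#'   there so exclusion logic can be exercised.
#' @param min_spacing_factor minimum centroid distance as a multiple of the
#'   maximum radius. The default 2.5 keeps nuclei well separated
#'   (the regime the watershed segmenter is validated in); lower it
#'   (e.g. 1.2) for a touching-cells stress mode.
#' @param seed integer seed; the simulation is bit-reproducible given the
#'   same parameters and seed.
#' @return a list of class `ihc_sim_params`.
#' @export
ihc_sim_params <- function(width = 512L, height = 512L, mpp = 0.5,
                           n_cells = 100L, positive_fraction = 0.3,
                           stain_pattern = c("nuclear", "membranous"),
                           nucleus_radius_range = c(2.0, 4.0),
                           dab_od_positive = 0.6,
                           haematoxylin_od = 0.75,
                           ring_width_um = 1.0,
                           noise_sd = 3,
                           necrosis_fraction = 0,
                           min_spacing_factor = 2.5,
                           seed = 1L) {
  stain_pattern <- match.arg(stain_pattern)
  stopifnot(width >= 64, height >= 64, mpp > 0, n_cells >= 0,
            positive_fraction >= 0, positive_fraction <= 1,
            all(nucleus_radius_range > 0),
            nucleus_radius_range[1] <= nucleus_radius_range[2],
            dab_od_positive > 0, ring_width_um > 0, noise_sd >= 0,
            necrosis_fraction >= 0, necrosis_fraction <= 1)
  p <- list(width = as.integer(width), height = as.integer(height),
            mpp = mpp, n_cells = as.integer(n_cells),
            positive_fraction = positive_fraction,
            stain_pattern = stain_pattern,
            nucleus_radius_range = nucleus_radius_range,
            dab_od_positive = dab_od_positive,
            haematoxylin_od = haematoxylin_od,
            ring_width_um = ring_width_um,
            noise_sd = noise_sd,
            necrosis_fraction = necrosis_fraction,
            min_spacing_factor = min_spacing_factor,
            seed = as.integer(seed))
  class(p) <- "ihc_sim_params"
  p
}

# ellipse membership of pixel centres within a bounding box; returns a
# logical matrix plus its row/col index ranges (clipped to the image)
.ellipse_mask <- function(cx, cy, a, b, theta, width, height, scale = 1) {
  a <- a * scale; b <- b * scale
  r_ext <- max(a, b)
  rows <- max(1L, floor(cy - r_ext)):min(height, ceiling(cy + r_ext + 1))
  cols <- max(1L, floor(cx - r_ext)):min(width, ceiling(cx + r_ext + 1))
  # pixel (row i, col j), 1-based, has centre (j - 0.5, i - 0.5)
  xc <- outer(rep(1, length(rows)), cols - 0.5) - cx
  yc <- outer(rows - 0.5, rep(1, length(cols))) - cy
  u <- xc * cos(theta) + yc * sin(theta)
  v <- -xc * sin(theta) + yc * cos(theta)
  list(rows = rows, cols = cols, mask = (u / a)^2 + (v / b)^2 <= 1)
}

#' Generate a synthetic H-DAB tile with ground truth
#'
#' @param params an [ihc_sim_params()] object.
#' @return list with components:
#'   \describe{
#'     \item{image}{`height x width x 3` numeric array, 8-bit RGB values.}
#'     \item{truth}{list: `centroids` (data.frame `x`, `y` in pixel units,
#'       origin at the top-left corner), `positive` logical vector,
#'       `radius_px`, `tumor_polygon` and `necrosis_polygons` (x/y
#'       matrices in pixel units), `roi_area_mm2`, `mpp`.}
#'   }
#' @details Cell centroids are placed by rejection sampling with a minimum
#'   pairwise spacing of `min_spacing_factor` times the maximum radius; if
#'   `200 * n_cells` proposals are exhausted the tile is too crowded and an
#'   error is raised.
#' @export
generate_ihc_image <- function(params) {
  stopifnot(inherits(params, "ihc_sim_params"))
  set.seed(params$seed)
  W <- params$width; H <- params$height; mpp <- params$mpp
  r_px <- params$nucleus_radius_range / mpp
  ring_px <- params$ring_width_um / mpp
  margin <- r_px[2] * 1.2 + ring_px + 2
  min_d <- params$min_spacing_factor * r_px[2]

  n <- params$n_cells
  cx <- cy <- numeric(0)
  tries <- 0L; budget <- max(200L * n, 1000L)
  while (length(cx) < n) {
    if (tries >= budget)
      stop("placement error: could not place ", n, " cells with spacing ",
           signif(min_d, 3), " px in ", W, "x", H, " tile")
    px <- runif(1, margin, W - margin)
    py <- runif(1, margin, H - margin)
    tries <- tries + 1L
    if (length(cx) == 0L || min((cx - px)^2 + (cy - py)^2) >= min_d^2) {
      cx <- c(cx, px); cy <- c(cy, py)
    }
  }

  n_pos <- round(n * params$positive_fraction)
  positive <- rep(FALSE, n)
  if (n_pos > 0) positive[sample.int(n, n_pos)] <- TRUE

  radius <- if (n > 0) runif(n, r_px[1], r_px[2]) else numeric(0)
  ecc <- if (n > 0) runif(n, 1, 1.15) else numeric(0)
  theta <- if (n > 0) runif(n, 0, pi) else numeric(0)

  h_od <- matrix(0, H, W)
  dab_od <- matrix(0, H, W)
  for (k in seq_len(n)) {
    a <- radius[k] * ecc[k]; b <- radius[k] / ecc[k]
    em <- .ellipse_mask(cx[k], cy[k], a, b, theta[k], W, H)
    sub <- h_od[em$rows, em$cols]
    sub[em$mask] <- params$haematoxylin_od
    h_od[em$rows, em$cols] <- sub
    if (positive[k]) {
      if (params$stain_pattern == "nuclear") {
        dsub <- dab_od[em$rows, em$cols]
        dsub[em$mask] <- params$dab_od_positive
        dab_od[em$rows, em$cols] <- dsub
      } else {
        outer_m <- .ellipse_mask(cx[k], cy[k], a + ring_px, b + ring_px,
                                 theta[k], W, H)
        inner <- matrix(FALSE, length(outer_m$rows), length(outer_m$cols))
        ri <- match(em$rows, outer_m$rows); ci <- match(em$cols, outer_m$cols)
        inner[ri, ci] <- em$mask
        ring <- outer_m$mask & !inner
        dsub <- dab_od[outer_m$rows, outer_m$cols]
        dsub[ring] <- params$dab_od_positive
        dab_od[outer_m$rows, outer_m$cols] <- dsub
      }
    }
  }

  # necrosis rectangle in the lower-right corner, aligned to pixel bounds
  necrosis_polygons <- list()
  necro_px <- 0
  if (params$necrosis_fraction > 0) {
    side_x <- floor(W * sqrt(params$necrosis_fraction))
    side_y <- floor(H * sqrt(params$necrosis_fraction))
    x0 <- W - side_x; y0 <- H - side_y
    necrosis_polygons[[1]] <- cbind(x = c(x0, W, W, x0),
                                    y = c(y0, y0, H, H))
    necro_px <- side_x * side_y
  }
  tumor_polygon <- cbind(x = c(0, W, W, 0), y = c(0, 0, H, H))
  roi_area_mm2 <- (W * H - necro_px) * mpp^2 / 1e6

  # OD -> RGB along the default stain vectors, over a near-white background
  m <- hdab_stain_matrix()
  bg <- c(244, 242, 245)
  bg_od <- -log10((bg + 1) / 255)
  img <- array(0, c(H, W, 3))
  for (ch in 1:3) {
    od_ch <- bg_od[ch] + h_od * m["haematoxylin", ch] + dab_od * m["dab", ch]
    img[, , ch] <- 255 * 10^(-od_ch) - 1
  }
  if (params$noise_sd > 0)
    img <- img + array(rnorm(H * W * 3, 0, params$noise_sd), c(H, W, 3))
  img <- round(pmin(pmax(img, 0), 255))

  truth <- list(
    centroids = data.frame(x = cx, y = cy),
    positive = positive,
    radius_px = radius,
    tumor_polygon = tumor_polygon,
    necrosis_polygons = necrosis_polygons,
    roi_area_mm2 = roi_area_mm2,
    mpp = mpp
  )
  list(image = img, truth = truth)
}

#' Write a simulated tile and its annotations to disk
#'
#' The image goes out as PNG, the tumor/necrosis polygons as a GeoJSON
#' FeatureCollection in the QuPath export dialect
#' (`properties.classification.name` of `"Tumor"` or `"Necrosis"`), and
#' the ground truth as JSON.
#'
#' @param sim result of [generate_ihc_image()].
#' @param dir output directory (created if needed).
#' @param stem file stem, e.g. `"patient01_CD3"`.
#' @return invisibly, the paths written.
#' @export
write_ihc_sim <- function(sim, dir, stem) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  img_path <- file.path(dir, paste0(stem, ".png"))
  png::writePNG(sim$image / 255, img_path)
  ann_path <- file.path(dir, paste0(stem, ".geojson"))
  write_annotations_geojson(sim$truth$tumor_polygon,
                            sim$truth$necrosis_polygons, ann_path)
  truth_path <- file.path(dir, paste0(stem, "_truth.json"))
  tr <- sim$truth
  jsonlite::write_json(
    list(centroids = tr$centroids, positive = tr$positive,
         radius_px = tr$radius_px, roi_area_mm2 = tr$roi_area_mm2,
         mpp = tr$mpp),
    truth_path, auto_unbox = TRUE, digits = NA)
  invisible(c(image = img_path, annotations = ann_path, truth = truth_path))
}

#' Write tumor/necrosis polygons as a QuPath-style GeoJSON FeatureCollection
#'
#' @param tumor_polygon x/y matrix (pixel units) or list of such matrices.
#' @param necrosis_polygons list of x/y matrices (possibly empty).
#' @param path output file.
#' @export
write_annotations_geojson <- function(tumor_polygon, necrosis_polygons, path) {
  if (is.matrix(tumor_polygon)) tumor_polygon <- list(tumor_polygon)
  feat <- function(poly, cls) {
    ring <- rbind(poly, poly[1, , drop = FALSE])           # closed ring
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(unname(split(ring, row(ring))))),
         properties = list(classification = list(name = cls)))
  }
  features <- c(lapply(tumor_polygon, feat, cls = "Tumor"),
                lapply(necrosis_polygons, feat, cls = "Necrosis"))
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an 8-bit RGB image tile (PNG or TIFF)
#'
#' @param path image file; extension decides the reader.
#' @return numeric `h x w x 3` array on the 0-255 scale.
#' @export
read_rgb_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = , tiff = tiff::readTIFF(path),
                stop("unsupported image format: ", ext))
  if (length(dim(img)) == 2L) stop("expected an RGB image, got one plane")
  if (dim(img)[3] > 3L) img <- img[, , 1:3]
  round(img * 255)
}
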