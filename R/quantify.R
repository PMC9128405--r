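#' Positive-cell calling and densities over the tumor ROI
#'
#' A pixel is DAB-positive when its unmixed DAB optical density exceeds a
#' pre-defined cutoff (in practice calibrated on control slides; see
#' [calibrate_dab_cutoff()]). A cell is marker-positive when the
#' DAB-positive area overlaps its scoring compartment - the nucleus for
#' nuclear-pattern markers (CD3, CD8) or the perinuclear ring for
#' membranous markers (CD45RO) - by at least a minimum fraction of the
#' compartment. Densities are positive cells per mm^2 of the region of
#' interest: annotated tumor minus necrosis.
#'
#' @name quantify
NULL

#' Threshold the DAB plane into a positivity mask
#'
#' @param dab_plane matrix of DAB optical densities (the `dab` plane of an
#'   `od_image`).
#' @param od_cutoff positive iff OD strictly greater than this (> 0);
#'   default 0.3.
#' @return logical matrix.
#' @export
dab_positive_mask <- function(dab_plane, od_cutoff = 0.3) {
  if (!is.numeric(od_cutoff) || od_cutoff <= 0)
    stop("od_cutoff must be a positive optical density")
  stopifnot(is.matrix(dab_plane))
  dab_plane > od_cutoff
}

#' Calibrate the DAB cutoff from negative-control images
#'
#' Sets the cutoff at a high quantile of the pooled DAB OD of control
#' tiles (tiles with no true chromogen), so nearly all control pixels
#' score negative.
#'
#' @param control_images list of RGB arrays, or a directory of PNG/TIFF
#'   control tiles.
#' @param quantile pooled-OD quantile used as the cutoff; default 0.99.
#' @param m stain matrix for unmixing.
#' @return numeric cutoff (optical density).
#' @export
calibrate_dab_cutoff <- function(control_images, quantile = 0.99,
                                 m = hdab_stain_matrix()) {
  if (is.character(control_images)) {
    files <- list.files(control_images, "\\.(png|tif|tiff)$",
                        full.names = TRUE, ignore.case = TRUE)
    if (length(files) == 0L) stop("no control images found")
    control_images <- lapply(files, read_rgb_image)
  }
  pooled <- unlist(lapply(control_images, function(img)
    as.numeric(deconvolve(rgb_to_od(img), m)$dab)))
  as.numeric(stats::quantile(pooled, quantile))
}

#' Call marker-positive cells by compartment overlap
#'
#' @param nuclei `label_mask` of nuclei.
#' @param rings `label_mask` of perinuclear rings (required when
#'   `compartment = "ring_overlap"`).
#' @param positive logical matrix from [dab_positive_mask()], same shape.
#' @param compartment `"nucleus_overlap"` (CD3/CD8-style nuclear scoring)
#'   or `"ring_overlap"` (CD45RO-style membranous scoring).
#' @param min_overlap_fraction minimum fraction of the compartment that
#'   must be DAB-positive for a positive call; default 0.05 (robust to
#'   single-pixel bleed; set near 0 for any-overlap).
#' @return data.frame, one row per cell: `cell_id`, `x`, `y` (centroid,
#'   pixel units), `nucleus_area_um2`, `overlap_fraction`, `positive`.
#' @export
call_positive_cells <- function(nuclei, rings = NULL, positive,
                                compartment = c("nucleus_overlap", "ring_overlap"),
                                min_overlap_fraction = 0.05) {
  compartment <- match.arg(compartment)
  stopifnot(inherits(nuclei, "label_mask"), is.matrix(positive),
            min_overlap_fraction >= 0, min_overlap_fraction <= 1)
  if (!identical(dim(nuclei$labels), dim(positive)))
    stop("shape mismatch between label mask and positivity mask")
  comp <- if (compartment == "nucleus_overlap") nuclei else {
    if (is.null(rings)) stop("ring_overlap scoring requires a ring mask")
    if (!identical(dim(rings$labels), dim(nuclei$labels)))
      stop("shape mismatch between nucleus and ring masks")
    rings
  }
  cen <- mask_centroids(nuclei)
  if (nrow(cen) == 0L)
    return(data.frame(cell_id = integer(0), x = numeric(0), y = numeric(0),
                      nucleus_area_um2 = numeric(0),
                      overlap_fraction = numeric(0), positive = logical(0)))
  k <- max(nuclei$labels)
  comp_size <- tabulate(comp$labels[comp$labels > 0L], k)
  pos_size <- tabulate(comp$labels[comp$labels > 0L & positive], k)
  frac <- ifelse(comp_size > 0L, pos_size / comp_size, 0)
  data.frame(
    cell_id = cen$label,
    x = cen$x, y = cen$y,
    nucleus_area_um2 = cen$area_px * nuclei$mpp^2,
    overlap_fraction = frac,
    positive = frac >= min_overlap_fraction & comp_size > 0L
  )
}

# scanline rasterization of polygons onto the pixel grid: a pixel belongs
# to the polygon iff its centre (col - 0.5, row - 0.5) is inside
# (even-odd rule, half-open [x_left, x_right) spans so shared edges are
# claimed exactly once)
.rasterize_polygons <- function(polys, width, height) {
  out <- matrix(FALSE, height, width)
  for (poly in polys) {
    x <- poly[, 1]; y <- poly[, 2]
    n <- length(x)
    x2 <- x[c(2:n, 1)]; y2 <- y[c(2:n, 1)]
    for (i in seq_len(height)) {
      yc <- i - 0.5
      hit <- (y <= yc & y2 > yc) | (y2 <= yc & y > yc)
      if (!any(hit)) next
      cross <- x[hit] + (yc - y[hit]) * (x2[hit] - x[hit]) / (y2[hit] - y[hit])
      cross <- sort(cross)
      for (s in seq(1L, length(cross) - 1L, by = 2L)) {
        j1 <- ceiling(cross[s] + 0.5)           # first pixel with centre >= left
        j2 <- ceiling(cross[s + 1L] - 0.5)      # last pixel with centre < right
        if (j2 >= j1)
          out[i, max(1L, j1):min(width, j2)] <- TRUE
      }
    }
  }
  out
}

#' Build the region of interest from tumor/necrosis annotations
#'
#' The effective region is the union of tumor polygons minus the union of
#' necrosis polygons, rasterized on the pixel grid (pixel-centre
#' membership, half-open spans). Area is the rasterized pixel count times
#' `mpp^2 / 1e6`.
#'
#' @param annotations path to a QuPath-style GeoJSON FeatureCollection, or
#'   a list with elements `tumor` and `necrosis` (lists of x/y matrices in
#'   pixel units).
#' @param width,height tile size in pixels.
#' @param mpp microns per pixel.
#' @return an `roi_geometry`: list with logical matrix `effective`,
#'   `area_mm2`, the polygon lists, and `mpp`.
#' @export
build_roi <- function(annotations, width, height, mpp) {
  if (is.character(annotations))
    annotations <- read_annotations_geojson(annotations)
  tumor <- annotations$tumor
  necrosis <- annotations$necrosis
  if (length(tumor) == 0L) stop("empty ROI: no tumor polygon in annotations")
  eff <- .rasterize_polygons(tumor, width, height)
  if (length(necrosis) > 0L)
    eff <- eff & !.rasterize_polygons(necrosis, width, height)
  structure(list(effective = eff,
                 area_mm2 = sum(eff) * mpp^2 / 1e6,
                 tumor = tumor, necrosis = necrosis, mpp = mpp),
            class = "roi_geometry")
}

#' Read QuPath-style GeoJSON tumor/necrosis annotations
#'
#' @param path GeoJSON FeatureCollection whose features carry
#'   `properties.classification.name` of `"Tumor"` or `"Necrosis"`.
#' @return list with `tumor` and `necrosis`, each a list of x/y matrices.
#' @export
read_annotations_geojson <- function(path) {
  g <- jsonlite::read_json(path)
  tumor <- list(); necrosis <- list()
  for (f in g$features) {
    cls <- f$properties$classification$name
    if (is.null(cls)) next
    geom <- f$geometry
    rings <- if (identical(geom$type, "Polygon")) list(geom$coordinates)
             else if (identical(geom$type, "MultiPolygon")) geom$coordinates
             else next
    for (poly in rings) {
      ring <- poly[[1]]                      # exterior ring only
      m <- do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
      colnames(m) <- c("x", "y")
      if (cls == "Tumor") tumor[[length(tumor) + 1L]] <- m
      else if (cls == "Necrosis") necrosis[[length(necrosis) + 1L]] <- m
    }
  }
  list(tumor = tumor, necrosis = necrosis)
}

#' Density of positive cells over the ROI
#'
#' Counts positive cells whose centroid pixel lies inside the effective
#' region (centroid membership makes densities tile-additive) and divides
#' by the ROI area.
#'
#' @param cells data.frame from [call_positive_cells()].
#' @param roi an `roi_geometry` from [build_roi()].
#' @param patient_id,marker identifiers carried into the record.
#' @return one-row data.frame: `patient_id`, `marker`, `positive_count`,
#'   `roi_area_mm2`, `density` (cells/mm^2).
#' @export
compute_density <- function(cells, roi, patient_id = NA_character_,
                            marker = NA_character_) {
  stopifnot(inherits(roi, "roi_geometry"))
  if (roi$area_mm2 <= 0) stop("empty ROI: zero area")
  inside <- logical(nrow(cells))
  if (nrow(cells) > 0L) {
    row <- pmin(pmax(floor(cells$y) + 1L, 1L), nrow(roi$effective))
    col <- pmin(pmax(floor(cells$x) + 1L, 1L), ncol(roi$effective))
    inside <- roi$effective[cbind(row, col)]
  }
  n_pos <- sum(cells$positive & inside)
  data.frame(patient_id = patient_id, marker = marker,
             positive_count = n_pos, roi_area_mm2 = roi$area_mm2,
             density = n_pos / roi$area_mm2)
}

#' Quantify one marker tile end to end
#'
#' Convenience chain: OD transform, H-DAB deconvolution, nucleus
#' segmentation (plus rings for membranous scoring), DAB thresholding,
#' positivity calls, ROI and density.
#'
#' @param image RGB array (0-255) or image file path.
#' @param annotations GeoJSON path or polygon list for [build_roi()].
#' @param marker one of `"CD3"`, `"CD8"`, `"CD45RO"`; picks the scoring
#'   compartment (nucleus for CD3/CD8, ring for CD45RO).
#' @param config a [run_config()]; supplies mpp, stain vectors, DAB
#'   cutoff, ring width, overlap fraction and area bounds.
#' @param patient_id identifier for the output record.
#' @return list with `cells` (per-cell calls) and `density` (one-row
#'   density record).
#' @export
quantify_tile <- function(image, annotations, marker, config = run_config(),
                          patient_id = NA_character_) {
  if (is.character(image)) image <- read_rgb_image(image)
  od <- deconvolve(rgb_to_od(image, config$i0), config$stain_matrix,
                   mpp = config$mpp)
  nuclei <- segment_nuclei(od, mpp = config$mpp,
                           min_area_um2 = config$min_area_um2,
                           max_area_um2 = config$max_area_um2)
  compartment <- if (marker == "CD45RO") "ring_overlap" else "nucleus_overlap"
  rings <- if (compartment == "ring_overlap")
    ring_regions(nuclei, config$ring_width_um) else NULL
  pos <- dab_positive_mask(od$dab, config$dab_od_cutoff)
  cells <- call_positive_cells(nuclei, rings, pos, compartment,
                               config$min_overlap_fraction)
  roi <- build_roi(annotations, ncol(od$dab), nrow(od$dab), config$mpp)
  dens <- compute_density(cells, roi, patient_id, marker)
  list(cells = cells, density = dens)
}
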