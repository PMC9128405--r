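#' Nucleus segmentation and perinuclear ring compartments
#'
#' Nuclei are segmented from the unmixed haematoxylin optical-density
#' plane with a classical pipeline: Otsu threshold, hole filling,
#' distance-transform watershed to split touching objects, and an area
#' filter. The module's contract is a labelled mask; masks produced by any
#' external segmenter (e.g. a learned model) can be imported via
#' [read_label_mask()] and used interchangeably downstream.
#'
#' @name segmentation
NULL

.new_label_mask <- function(labels, mpp) {
  structure(list(labels = labels, mpp = mpp), class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("label_mask: %d x %d px, %d objects, mpp = %s\n",
              nrow(x$labels), ncol(x$labels), max(x$labels), format(x$mpp)))
  invisible(x)
}

#' Segment nuclei from a haematoxylin OD plane
#'
#' @param h_channel non-negative matrix of haematoxylin optical densities
#'   (the `haematoxylin` plane of an `od_image`), or an `od_image`.
#' @param mpp microns per pixel; taken from the `od_image` if not given.
#' @param min_area_um2,max_area_um2 area bounds in square microns; objects
#'   outside the range are dropped. Defaults 8-120 um^2 bracket
#'   lymphocyte through tumor nuclei at x200 resolution.
#' @param watershed_tolerance minimum depth (in distance-map units) between
#'   two catchment basins for a split; default 1.
#' @param min_od absolute floor on the foreground threshold; the Otsu
#'   threshold is never taken below this, so sensor noise on empty glass
#'   (OD fluctuations well under 0.1) is never segmented. Default 0.15.
#' @return a `label_mask`: integer matrix with 0 = background and
#'   consecutive labels 1..K, plus `mpp`.
#' @details A blank plane (nothing above threshold, or nothing surviving
#'   the area filter) yields an empty mask with zero labels, not an error.
#' @export
segment_nuclei <- function(h_channel, mpp = NULL,
                           min_area_um2 = 8, max_area_um2 = 120,
                           watershed_tolerance = 1, min_od = 0.15) {
  if (inherits(h_channel, "od_image")) {
    if (is.null(mpp)) mpp <- h_channel$mpp
    h_channel <- h_channel$haematoxylin
  }
  if (is.null(mpp) || is.na(mpp)) stop("mpp must be supplied")
  stopifnot(is.matrix(h_channel), all(h_channel >= 0))

  empty <- .new_label_mask(matrix(0L, nrow(h_channel), ncol(h_channel)), mpp)
  mx <- max(h_channel)
  if (mx <= min_od) return(empty)

  thr <- EBImage::otsu(EBImage::Image(h_channel / mx), range = c(0, 1)) * mx
  binary <- h_channel > max(thr, min_od)
  if (!any(binary)) return(empty)

  binary <- EBImage::fillHull(EBImage::Image(binary))
  dm <- EBImage::distmap(binary)
  lab <- EBImage::watershed(dm, tolerance = watershed_tolerance)
  lab <- matrix(as.integer(EBImage::imageData(lab)),
                nrow(h_channel), ncol(h_channel))

  px_area <- tabulate(lab)
  area_um2 <- px_area * mpp^2
  keep <- which(area_um2 >= min_area_um2 & area_um2 <= max_area_um2)
  if (length(keep) == 0L) return(empty)
  remap <- integer(max(lab))
  remap[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(lab), ncol(lab))
  nz <- lab > 0L
  out[nz] <- remap[lab[nz]]
  .new_label_mask(out, mpp)
}

#' Object centroids and areas of a label mask
#'
#' @param mask a `label_mask`.
#' @return data.frame with `label`, `x`, `y` (pixel units, top-left
#'   origin, pixel centres at half-integers) and `area_px`.
#' @export
mask_centroids <- function(mask) {
  lab <- mask$labels
  k <- max(lab)
  if (k == 0L)
    return(data.frame(label = integer(0), x = numeric(0), y = numeric(0),
                      area_px = integer(0)))
  idx <- which(lab > 0L)
  labs <- lab[idx]
  rows <- ((idx - 1L) %% nrow(lab)) + 1L
  cols <- ((idx - 1L) %/% nrow(lab)) + 1L
  area <- tabulate(labs, k)
  data.frame(
    label = seq_len(k),
    x = as.numeric(tapply(cols - 0.5, labs, mean)),
    y = as.numeric(tapply(rows - 0.5, labs, mean)),
    area_px = area
  )
}

#' Ring-shaped perinuclear compartments
#'
#' The ring of nucleus k is the background within a Euclidean distance of
#' `round(ring_width_um / mpp)` pixels of any nucleus (computed by
#' distance transform, i.e. an exact disc dilation) minus all nucleus
#' pixels, so rings never overlap any nucleus. A background pixel claimed
#' by several rings is assigned to the nucleus with the nearest centroid.
#' Rings are clipped at the image border.
#'
#' @param nuclei a `label_mask` from [segment_nuclei()].
#' @param ring_width_um ring width in microns (> 0); default 2.
#' @return a `label_mask` whose label k marks the ring of nucleus k
#'   (disjoint from all nuclei and from every other ring).
#' @export
ring_regions <- function(nuclei, ring_width_um = 2) {
  stopifnot(inherits(nuclei, "label_mask"), ring_width_um > 0)
  mpp <- nuclei$mpp
  if (is.null(mpp) || is.na(mpp)) stop("mpp missing from label mask")
  lab <- nuclei$labels
  r_px <- max(1L, round(ring_width_um / mpp))
  ring <- matrix(0L, nrow(lab), ncol(lab))
  if (max(lab) == 0L) return(.new_label_mask(ring, mpp))

  bg_dist <- EBImage::distmap(EBImage::Image(lab == 0L))
  bg_dist <- matrix(as.numeric(EBImage::imageData(bg_dist)),
                    nrow(lab), ncol(lab))
  cand <- which(lab == 0L & bg_dist > 0 & bg_dist <= r_px)
  if (length(cand) == 0L) return(.new_label_mask(ring, mpp))

  cen <- mask_centroids(nuclei)
  rows <- ((cand - 1L) %% nrow(lab)) + 0.5
  cols <- ((cand - 1L) %/% nrow(lab)) + 0.5
  # nearest nucleus centroid claims the pixel; chunked to bound memory
  nearest <- integer(length(cand))
  step <- 20000L
  for (s in seq(1L, length(cand), by = step)) {
    e <- min(s + step - 1L, length(cand))
    d2 <- outer(cols[s:e], cen$x, "-")^2 + outer(rows[s:e], cen$y, "-")^2
    nearest[s:e] <- cen$label[max.col(-d2, ties.method = "first")]
  }
  ring[cand] <- nearest
  .new_label_mask(ring, mpp)
}

#' Import / export label masks as 16-bit single-plane TIFF
#'
#' Lets externally produced segmentations (any tool that can emit a
#' labelled image) enter the pipeline.
#'
#' @param path TIFF file.
#' @param mask a `label_mask` (for writing).
#' @param mpp microns per pixel to attach on read.
#' @export
write_label_mask <- function(mask, path) {
  if (max(mask$labels) > 65535L) stop("more than 65535 labels")
  tiff::writeTIFF(mask$labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_label_mask
#' @export
read_label_mask <- function(path, mpp) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  .new_label_mask(matrix(as.integer(round(m * 65535)), nrow(m), ncol(m)), mpp)
}
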