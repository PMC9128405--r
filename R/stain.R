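#' Stain separation for H-DAB immunohistochemistry
#'
#' RGB brightfield images of chromogen-stained tissue are converted to
#' optical density (Beer-Lambert: stain amounts are additive in OD space)
#' and unmixed into per-stain concentration planes with a known stain
#' colour matrix (Ruifrok-Johnston colour deconvolution).
#'
#' @name stain
NULL

#' Convert an 8-bit RGB image to optical density
#'
#' Applies the Beer-Lambert transform `OD = -log10((I + 1) / i0)` per
#' channel. The +1 guard keeps the OD finite at intensity 0.
#'
#' @param img numeric array `height x width x 3` with values in `[0, i0]`
#'   (8-bit convention, 255 = white), or a single pixel as a length-3
#'   vector.
#' @param i0 incident (white) intensity; default 255.
#' @return array of the same shape holding per-channel optical densities
#'   (all `>= 0`; clipped at 0 for intensities above `i0`).
#' @examples
#' rgb_to_od(c(26, 26, 26))      # ~0.975 per channel
#' rgb_to_od(c(255, 255, 255))   # ~0 (white transmits fully)
#' @export
rgb_to_od <- function(img, i0 = 255) {
  if (i0 <= 0) stop("i0 must be positive")
  if (is.vector(img) && length(img) == 3L) img <- array(img, c(1L, 1L, 3L))
  d <- dim(img)
  if (length(d) != 3L || d[3] != 3L)
    stop("expected an RGB image: array with dim c(h, w, 3)")
  od <- -log10((img + 1) / i0)
  od[od < 0] <- 0
  od
}

#' Default H-DAB stain matrix
#'
#' Standard haematoxylin and DAB colour vectors in RGB optical-density
#' space, each normalised to unit Euclidean length; the residual vector is
#' their normalised cross product, so the three rows span OD space.
#'
#' @return a `stain_matrix`: 3 x 3 numeric matrix with rows
#'   `haematoxylin`, `dab`, `residual` and columns `r`, `g`, `b`.
#' @export
hdab_stain_matrix <- function() {
  stain_matrix(h = c(0.650, 0.704, 0.286), dab = c(0.269, 0.568, 0.779))
}

#' Build a stain matrix from haematoxylin and DAB colour vectors
#'
#' @param h,dab length-3 RGB optical-density direction of each stain
#'   (normalised internally).
#' @param residual optional third vector; default is the normalised cross
#'   product of `h` and `dab` (orthogonal to both).
#' @return unit-row 3 x 3 matrix of class `stain_matrix`.
#' @export
stain_matrix <- function(h, dab, residual = NULL) {
  unit <- function(v) {
    n <- sqrt(sum(v^2))
    if (n < 1e-12) stop("stain vector has zero length")
    v / n
  }
  h <- unit(h); dab <- unit(dab)
  if (is.null(residual)) {
    residual <- c(h[2] * dab[3] - h[3] * dab[2],
                  h[3] * dab[1] - h[1] * dab[3],
                  h[1] * dab[2] - h[2] * dab[1])
  }
  residual <- unit(residual)
  m <- rbind(haematoxylin = h, dab = dab, residual = residual)
  colnames(m) <- c("r", "g", "b")
  sv <- svd(m)$d
  if (sv[3] <= 0 || sv[1] / sv[3] >= 1e6)
    stop("stain matrix is ill-conditioned (condition number >= 1e6)")
  class(m) <- c("stain_matrix", "matrix", "array")
  m
}

#' Unmix optical densities into per-stain concentration planes
#'
#' Solves, per pixel, `od = c %*% M` for the concentration vector `c`,
#' where the rows of `M` are the unit stain vectors. Negative
#' concentrations (noise pixels outside the stain simplex) are clipped to
#' zero: concentrations are physical amounts.
#'
#' @param od optical-density array `h x w x 3` from [rgb_to_od()].
#' @param m a `stain_matrix`; default [hdab_stain_matrix()].
#' @param mpp microns per pixel, carried on the result for downstream
#'   area conversions.
#' @return an `od_image`: list with matrices `haematoxylin`, `dab`,
#'   `residual` (each `h x w`, non-negative) and `mpp`.
#' @export
deconvolve <- function(od, m = hdab_stain_matrix(), mpp = NA_real_) {
  d <- dim(od)
  if (length(d) != 3L || d[3] != 3L)
    stop("expected an OD array with dim c(h, w, 3)")
  minv <- tryCatch(solve(t(m)), error = function(e)
    stop("singular stain matrix: ", conditionMessage(e)))
  flat <- matrix(od, ncol = 3L)            # pixels x rgb
  conc <- flat %*% t(minv)                 # pixels x stains: od = conc %*% m
  conc[conc < 0] <- 0
  out <- list(
    haematoxylin = matrix(conc[, 1], d[1], d[2]),
    dab          = matrix(conc[, 2], d[1], d[2]),
    residual     = matrix(conc[, 3], d[1], d[2]),
    mpp          = mpp
  )
  class(out) <- "od_image"
  out
}

#' @export
print.od_image <- function(x, ...) {
  cat(sprintf("od_image: %d x %d px, mpp = %s\n",
              nrow(x$haematoxylin), ncol(x$haematoxylin),
              format(x$mpp)))
  cat(sprintf("  haematoxylin OD: max %.3f   DAB OD: max %.3f\n",
              max(x$haematoxylin), max(x$dab)))
  invisible(x)
}

#' Write an unmixed channel as a single-plane TIFF for visual QC
#'
#' @param od an `od_image`.
#' @param channel one of `"haematoxylin"`, `"dab"`, `"residual"`.
#' @param path output file; OD is rescaled by `max_od` into `[0, 1]`.
#' @param max_od OD mapped to full intensity; default 2.
#' @export
write_channel_tiff <- function(od, channel = c("haematoxylin", "dab", "residual"),
                               path, max_od = 2) {
  channel <- match.arg(channel)
  plane <- pmin(od[[channel]] / max_od, 1)
  tiff::writeTIFF(plane, path, bits.per.sample = 16L)
  invisible(path)
}
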