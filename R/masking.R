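# Cloud, land and intertidal masking, plus tide-sensitivity flagging.
#
# Masks are logical matrices on the scene grid with TRUE = excluded.

#' Cloud mask from the QA band
#'
#' A pixel is masked if and only if its quality code is one of the configured
#' cloud codes. Codes outside the known set pass through unmasked and are
#' counted in the `unknown_codes` attribute (QA bit dialects differ across
#' product collections, so the code sets are configurable).
#'
#' @param qa integer matrix of per-pixel quality codes.
#' @param cloud_codes integer codes that mean cloud (default `4L`).
#' @param known_codes all codes considered known; anything else is logged.
#' @return Logical mask matrix (TRUE = cloud) with attribute
#'   `unknown_codes` (table of unrecognized codes, possibly empty).
#' @export
cloud_mask_from_qa <- function(qa, cloud_codes = 4L,
                               known_codes = c(1L, cloud_codes)) {
  stopifnot(is.matrix(qa))
  m <- matrix(qa %in% cloud_codes, nrow(qa), ncol(qa))
  unknown <- qa[!(qa %in% known_codes)]
  if (length(unknown))
    kc_log("cloud_mask_from_qa: %d pixels with unknown QA codes left unmasked",
           length(unknown))
  attr(m, "unknown_codes") <- table(unknown)
  m
}

#' Land mask from a digital elevation model
#'
#' Masks any pixel with elevation strictly greater than zero meters; a pixel
#' at exactly 0 m is not masked. Missing elevations are treated
#' conservatively as land (masked) and counted.
#'
#' @param dem numeric elevation matrix (m), co-registered with the scene.
#' @return Logical mask matrix (TRUE = land) with attribute `n_missing`.
#' @export
land_mask_from_dem <- function(dem) {
  stopifnot(is.matrix(dem))
  miss <- is.na(dem)
  m <- (dem > 0) | miss
  if (any(miss))
    kc_log("land_mask_from_dem: %d missing elevations masked as land",
           sum(miss))
  attr(m, "n_missing") <- sum(miss)
  m
}

#' Modified Normalized Difference Water Index
#'
#' `MNDWI = (green - swir) / (green + swir)`, element-wise. Undefined where
#' the denominator is zero (propagated as `NA`). On non-negative inputs the
#' index is bounded in `[-1, 1]`; open water is strongly positive, exposed
#' land/intertidal strongly negative, independent of floating kelp (which
#' barely affects the SWIR band).
#'
#' @param green,swir reflectance matrices (co-registered).
#' @return Numeric matrix of index values.
#' @export
compute_mndwi <- function(green, swir) {
  stopifnot(is.matrix(green), is.matrix(swir), all(dim(green) == dim(swir)))
  den <- green + swir
  out <- (green - swir) / den
  out[den == 0] <- NA_real_
  out
}

#' Intertidal mask from a low-tide reference scene
#'
#' Computes MNDWI from the green and first shortwave-infrared band of a
#' cloud-free reference scene acquired at a negative low tide, and masks
#' every pixel with MNDWI strictly less than the threshold (default 0.1; a
#' pixel at exactly 0.1 is not masked). Pixels already masked as land or
#' cloud are excluded from consideration.
#'
#' @param reference_scene a `kelp_scene` acquired at negative tide height.
#' @param land_mask optional logical land mask to exclude.
#' @param cloud_mask optional logical cloud mask to exclude.
#' @param threshold MNDWI threshold (default 0.1, strict `<`).
#' @return Logical mask matrix (TRUE = intertidal).
#' @export
intertidal_mask <- function(reference_scene, land_mask = NULL,
                            cloud_mask = NULL, threshold = 0.1) {
  stopifnot(inherits(reference_scene, "kelp_scene"))
  if (reference_scene$tide_height >= 0)
    warning("reference scene was not acquired at a negative tide height")
  dm <- dim(reference_scene$bands)
  idx <- compute_mndwi(matrix(reference_scene$bands[, , "green"], dm[1], dm[2]),
                       matrix(reference_scene$bands[, , "swir1"], dm[1], dm[2]))
  m <- !is.na(idx) & idx < threshold
  if (!is.null(land_mask)) m[land_mask] <- FALSE
  if (!is.null(cloud_mask)) m[cloud_mask] <- FALSE
  m
}

#' Pixels adjacent to land
#'
#' 8-connectivity dilation of the land mask minus the land itself: the ring
#' of water pixels touching land, used to restrict tidal-artifact flagging.
#'
#' @param land_mask logical land mask.
#' @return Logical matrix, TRUE for non-land pixels touching land.
#' @export
land_adjacency <- function(land_mask) {
  stopifnot(is.matrix(land_mask))
  nr <- nrow(land_mask); nc <- ncol(land_mask)
  out <- matrix(FALSE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    rt <- max(1, 1 - dr):min(nr, nr - dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    ct <- max(1, 1 - dc):min(nc, nc - dc)
    out[rt, ct] <- out[rt, ct] | land_mask[rs, cs]
  }
  out & !land_mask
}

#' Flag pixels whose canopy area tracks tide height
#'
#' Intertidal contamination shows up as emergent "canopy" that shrinks as the
#' tide rises. For every land-adjacent pixel with enough paired observations,
#' the ordinary least-squares slope of canopy area against tide height is
#' computed; a pixel is flagged when the slope is negative and the two-sided
#' t-test p-value is below `alpha`. Flagged pixels are reported (not
#' removed): the report supports a manual review step, and `remove = TRUE`
#' opts in to automatic removal.
#'
#' @param area_series numeric matrix, one row per pixel (row-major pixel
#'   order) and one column per acquisition, of estimated canopy areas (m^2);
#'   or a 3-d array `nrow x ncol x n_acq`.
#' @param tide_heights tide height (m) per acquisition.
#' @param land_adjacent logical matrix from [land_adjacency()]; only
#'   adjacent pixels are candidates.
#' @param alpha two-sided significance level (default 0.05).
#' @param min_n minimum paired observations per pixel (default 8).
#' @return A data frame with columns `row`, `col`, `slope`, `p` for flagged
#'   pixels, with attribute `n_constant` counting candidate pixels skipped
#'   for having constant area.
#' @export
flag_tidal_pixels <- function(area_series, tide_heights, land_adjacent,
                              alpha = 0.05, min_n = 8L) {
  if (is.array(area_series) && length(dim(area_series)) == 3L) {
    dm <- dim(area_series)
    area_series <- matrix(area_series, dm[1] * dm[2], dm[3])
  }
  stopifnot(is.matrix(area_series), is.matrix(land_adjacent),
            ncol(area_series) == length(tide_heights),
            nrow(area_series) == length(land_adjacent))
  nr <- nrow(land_adjacent)
  cand <- which(as.vector(land_adjacent))
  out <- list(); n_const <- 0L
  for (i in cand) {
    y <- area_series[i, ]; x <- tide_heights
    ok <- is.finite(y) & is.finite(x)
    if (sum(ok) < min_n) next
    y <- y[ok]; x <- x[ok]
    if (stats::sd(y) == 0 || stats::sd(x) == 0) { n_const <- n_const + 1L; next }
    n <- length(y)
    sxx <- sum((x - mean(x))^2)
    b <- sum((x - mean(x)) * (y - mean(y))) / sxx
    res <- y - mean(y) - b * (x - mean(x))
    s2 <- sum(res^2) / (n - 2)
    if (s2 == 0) {
      p <- 0
    } else {
      tstat <- b / sqrt(s2 / sxx)
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
    if (b < 0 && p < alpha)
      out[[length(out) + 1L]] <- data.frame(
        row = ((i - 1L) %% nr) + 1L, col = ((i - 1L) %/% nr) + 1L,
        slope = b, p = p)
  }
  if (n_const)
    kc_log("flag_tidal_pixels: %d constant-area candidate pixels skipped",
           n_const)
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(row = integer(0), col = integer(0),
               slope = numeric(0), p = numeric(0))
  attr(res, "n_constant") <- n_const
  res
}

#' Combine masks
#'
#' Pixel-wise union of any number of logical masks (TRUE = excluded).
#' Idempotent: applying the union twice equals applying it once.
#'
#' @param ... logical mask matrices of identical dimension.
#' @return Logical mask matrix.
#' @export
combine_masks <- function(...) {
  ms <- list(...)
  stopifnot(length(ms) >= 1L)
  out <- ms[[1]]
  for (m in ms[-1]) {
    stopifnot(all(dim(m) == dim(out)))
    out <- out | m
  }
  out
}
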