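# Readers and writers for the interchange formats: multiband TIFF rasters
# with JSON sidecar metadata, GeoJSON cell grids, and the canonical CSV
# schema mirroring the platform download format.
#
# Conventions (used everywhere): projected meters, north-up rasters with the
# origin at the top-left corner, pixel-center georeferencing, half-open
# cells. Bands are stored as 32-bit float TIFF samples, so round-trips are
# exact to float32 precision. TIFF has no missing-value notion, so every
# float raster is written with a companion validity channel.

write_sidecar <- function(meta, path) {
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

read_sidecar <- function(path) {
  f <- paste0(path, ".json")
  if (!file.exists(f)) stop("missing sidecar metadata file: ", f)
  jsonlite::fromJSON(f)
}

#' Write / read a scene
#'
#' `write_scene()` stores the six reflectance bands as a 6-channel 32-bit
#' float TIFF, the QA band as an 8-bit TIFF, and the acquisition metadata
#' (date, sensor generation, tide height, pixel size) in a JSON sidecar.
#' `read_scene()` reverses it; band values round-trip to float32 precision.
#'
#' @param scene a `kelp_scene`.
#' @param path base path without extension; writes `<path>.tif`,
#'   `<path>_qa.tif` and `<path>.json`.
#' @return `write_scene()` returns `path` invisibly; `read_scene()` a
#'   `kelp_scene`.
#' @export
write_scene <- function(scene, path) {
  stopifnot(inherits(scene, "kelp_scene"))
  pages <- lapply(seq_len(dim(scene$bands)[3]),
                  function(b) scene$bands[, , b])
  suppressWarnings(tiff::writeTIFF(pages, paste0(path, ".tif"),
                                   bits.per.sample = 32L, reduce = FALSE))
  suppressWarnings(tiff::writeTIFF(scene$qa / 255, paste0(path, "_qa.tif"),
                                   bits.per.sample = 8L))
  write_sidecar(list(type = "kelp_scene",
                     acquired = format(scene$acquired),
                     sensor_generation = scene$sensor_generation,
                     tide_height = scene$tide_height,
                     pixel_size = scene$pixel_size,
                     bands = kelp_bands(),
                     dim = dim(scene$bands)), path)
  invisible(path)
}

#' @rdname write_scene
#' @export
read_scene <- function(path) {
  meta <- read_sidecar(path)
  if (!identical(meta$type, "kelp_scene"))
    stop("sidecar does not describe a scene: ", path)
  pages <- tryCatch(suppressWarnings(tiff::readTIFF(paste0(path, ".tif"),
                                                    all = TRUE)),
                    error = function(e) stop("unreadable scene TIFF: ",
                                             conditionMessage(e)))
  bands <- array(unlist(pages), c(dim(pages[[1]]), length(pages)))
  if (!all(dim(bands) == meta$dim))
    stop("band array dimensions do not match sidecar for ", path)
  dimnames(bands) <- list(NULL, NULL, kelp_bands())
  qa <- round(suppressWarnings(tiff::readTIFF(paste0(path, "_qa.tif"))) * 255)
  structure(list(bands = bands, qa = matrix(as.integer(qa), meta$dim[1]),
                 acquired = as.Date(meta$acquired),
                 sensor_generation = meta$sensor_generation,
                 tide_height = meta$tide_height,
                 pixel_size = meta$pixel_size),
            class = "kelp_scene")
}

#' Write / read a single-band raster
#'
#' Stores a numeric matrix (fraction, area, truth, index values) as a
#' two-channel float TIFF — values plus a validity channel encoding `NA` —
#' with a JSON sidecar recording the value scale, so values outside `[0, 1]`
#' (e.g. areas in m^2) survive.
#'
#' @param x numeric matrix.
#' @param path base path without extension.
#' @param meta optional named list merged into the sidecar.
#' @return `write_raster()` returns `path` invisibly; `read_raster()` the
#'   matrix with `NA`s restored.
#' @export
write_raster <- function(x, path, meta = list()) {
  stopifnot(is.matrix(x))
  scale <- suppressWarnings(max(1, max(abs(x), na.rm = TRUE)))
  if (!is.finite(scale)) scale <- 1
  v <- x / scale                      # in [-1, 1]
  signed <- any(x < 0, na.rm = TRUE)
  if (signed) v <- (v + 1) / 2        # remap to [0, 1] for storage
  v[is.na(v)] <- 0
  arr <- array(c(v, !is.na(x)), c(nrow(x), ncol(x), 2L))
  meta$signed <- signed
  suppressWarnings(tiff::writeTIFF(arr, paste0(path, ".tif"),
                                   bits.per.sample = 32L, reduce = FALSE))
  write_sidecar(c(list(type = "kelp_raster", scale = scale,
                       dim = dim(x)), meta), path)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  meta <- read_sidecar(path)
  if (!identical(meta$type, "kelp_raster"))
    stop("sidecar does not describe a raster: ", path)
  arr <- tryCatch(suppressWarnings(tiff::readTIFF(paste0(path, ".tif"))),
                  error = function(e) stop("unreadable raster TIFF: ",
                                           conditionMessage(e)))
  v <- arr[, , 1]
  if (isTRUE(meta$signed)) v <- v * 2 - 1
  out <- v * meta$scale
  out[arr[, , 2] < 0.5] <- NA_real_
  out
}

#' Write / read a binary mask
#'
#' Masks are stored as single-band 8-bit TIFFs with values 0/1.
#'
#' @param mask logical matrix (TRUE = excluded).
#' @param path base path without extension.
#' @return `write_mask()` returns `path` invisibly; `read_mask()` a logical
#'   matrix.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.matrix(mask), is.logical(mask))
  suppressWarnings(tiff::writeTIFF(mask * 1, paste0(path, ".tif"),
                                   bits.per.sample = 8L))
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  suppressWarnings(tiff::readTIFF(paste0(path, ".tif"))) > 0.5
}

# equirectangular projection anchored at the domain's top-left corner
xy_to_lonlat <- function(x, y, domain) {
  lat <- domain$lat0 + (y - domain$y0) / 111320
  lon <- domain$lon0 + (x - domain$x0) / (111320 * cos(domain$lat0 * pi / 180))
  cbind(lon, lat)
}

#' Write / read grid cells as GeoJSON
#'
#' Cells are encoded as GeoJSON polygon features (geographic lon/lat ring
#' corners, per the GeoJSON convention) with the projected corner
#' coordinates, id and nominal size carried as properties. `read_cells()`
#' validates that every feature is a non-degenerate rectangle and that cells
#' are pairwise disjoint, and computes each centroid latitude as the mean of
#' the four corner latitudes.
#'
#' @param cells a `kelp_cells` frame (from [make_grid_cells()]).
#' @param path output `.geojson` path.
#' @param domain the [scene_domain()] supplying the geographic anchor.
#' @return `write_cells()` returns `path` invisibly; `read_cells()` a
#'   `kelp_cells` data frame.
#' @export
write_cells <- function(cells, path, domain) {
  feats <- lapply(seq_len(nrow(cells)), function(i) {
    cl <- cells[i, ]
    corners <- rbind(c(cl$x0, cl$y0), c(cl$x1, cl$y0), c(cl$x1, cl$y1),
                     c(cl$x0, cl$y1), c(cl$x0, cl$y0))
    ll <- xy_to_lonlat(corners[, 1], corners[, 2], domain)
    list(type = "Feature",
         properties = list(id = cl$id, size_m = cl$size_m,
                           x0 = cl$x0, y0 = cl$y0, x1 = cl$x1, y1 = cl$y1),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ll)),
                           function(j) as.numeric(ll[j, ])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cells
#' @export
read_cells <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection")) stop("not a FeatureCollection")
  rows <- lapply(gj$features, function(ft) {
    pr <- ft$properties
    if (is.null(pr$id)) stop("feature without id")
    ring <- ft$geometry$coordinates[[1]]
    lats <- vapply(ring, function(p) as.numeric(p[[2]]), numeric(1))
    # drop the closing vertex before averaging corner latitudes
    lats <- lats[-length(lats)]
    if (pr$x1 <= pr$x0 || pr$y1 <= pr$y0)
      stop("degenerate cell polygon: ", pr$id)
    data.frame(id = pr$id, x0 = pr$x0, x1 = pr$x1, y0 = pr$y0, y1 = pr$y1,
               size_m = pr$size_m %||% (pr$x1 - pr$x0),
               latitude = mean(lats))
  })
  out <- do.call(rbind, rows)
  # pairwise disjointness on the half-open rectangles
  if (nrow(out) > 1L) {
    for (i in seq_len(nrow(out) - 1L)) for (j in (i + 1L):nrow(out)) {
      if (out$x0[i] < out$x1[j] && out$x1[i] > out$x0[j] &&
          out$y0[i] < out$y1[j] && out$y1[i] > out$y0[j])
        stop("overlapping cells: ", out$id[i], " and ", out$id[j])
    }
  }
  class(out) <- c("kelp_cells", "data.frame")
  out
}

#' Canonical cell-quarter CSV
#'
#' The interchange schema between aggregation and statistics, mirroring the
#' downloadable comma-separated format: one row per cell and quarter with
#' columns `cell_id`, `year`, `quarter`, `area_m2`, `stderr_m2`,
#' `n_overpasses`, `cloud_fraction`, `missing`.
#'
#' @param tab data frame in the canonical schema.
#' @param path output `.csv` path.
#' @return `write_cell_csv()` returns `path` invisibly; `read_cell_csv()`
#'   the data frame.
#' @export
write_cell_csv <- function(tab, path) {
  need <- c("cell_id", "year", "quarter", "area_m2", "stderr_m2",
            "n_overpasses", "cloud_fraction", "missing")
  stopifnot(all(need %in% names(tab)))
  utils::write.csv(tab[, need], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_csv
#' @export
read_cell_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
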