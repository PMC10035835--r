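# Seasonal per-pixel statistics, habitat masks, grid-cell aggregation with
# the missing-data rules, annual maxima, and regional sums.

#' Seasonal (quarterly) per-pixel canopy statistics
#'
#' Reduces all acquisitions of one quarter to a per-pixel mean canopy area,
#' its standard error, and the number of cloud-free overpasses. A pixel
#' enters the mean only for acquisitions where it was observed (`NA` area =
#' masked). `stderr = sd / sqrt(n)` (0 when `n = 1`); pixels never observed
#' in the quarter are missing with `n = 0`.
#'
#' @param area_list list of canopy-area matrices (m^2), one per acquisition,
#'   `NA` where the pixel was masked.
#' @return List of matrices `mean`, `stderr`, `n`.
#' @export
seasonal_pixel_stats <- function(area_list) {
  stopifnot(is.list(area_list))
  if (length(area_list) == 0L) stop("no acquisitions in quarter")
  dm <- dim(area_list[[1]])
  A <- vapply(area_list, function(m) { stopifnot(all(dim(m) == dm)); m },
              area_list[[1]])
  obs <- !is.na(A)
  n <- apply(obs, c(1, 2), sum)
  s <- apply(A, c(1, 2), function(v) sum(v, na.rm = TRUE))
  mean_area <- ifelse(n > 0, s / n, NA_real_)
  sd_area <- apply(A, c(1, 2), function(v) stats::sd(v, na.rm = TRUE))
  stderr <- ifelse(n > 1, sd_area / sqrt(n), ifelse(n == 1, 0, NA_real_))
  list(mean = mean_area, stderr = stderr, n = n)
}

#' Potential kelp habitat
#'
#' A pixel belongs to the potential kelp habitat if canopy (fraction > 0)
#' was detected there in at least one acquisition over the full series.
#'
#' @param fraction_list list of kelp-fraction matrices across the whole
#'   series (`NA` = masked).
#' @return Logical habitat matrix.
#' @export
derive_habitat_mask <- function(fraction_list) {
  stopifnot(is.list(fraction_list), length(fraction_list) >= 1L)
  out <- matrix(FALSE, nrow(fraction_list[[1]]), ncol(fraction_list[[1]]))
  for (f in fraction_list) out <- out | (!is.na(f) & f > 0)
  out
}

#' Build a rectangular grid of analysis cells
#'
#' Tiles the domain with square cells of `cell_px` pixels on a side.
#' Cell rectangles are half-open `[x0, x1) x [y0, y1)` on pixel centers, so
#' the grid is disjoint and tiles without double counting. Each cell carries
#' the latitude of its centroid, derived from the domain's geographic
#' anchor.
#'
#' @param domain a [scene_domain()].
#' @param cell_px cell edge length in pixels.
#' @return Data frame of class `kelp_cells` with columns `id`, `x0`, `x1`,
#'   `y0`, `y1` (projected m), `size_m`, `latitude`, `row0`, `row1`, `col0`,
#'   `col1` (pixel index ranges).
#' @export
make_grid_cells <- function(domain, cell_px = 20L) {
  stopifnot(inherits(domain, "kelp_domain"), cell_px >= 1)
  ps <- domain$pixel_size
  nrc <- floor(domain$nrow / cell_px); ncc <- floor(domain$ncol / cell_px)
  if (nrc < 1 || ncc < 1) stop("cell size exceeds domain")
  rows <- list(); k <- 0L
  for (i in seq_len(nrc)) for (j in seq_len(ncc)) {
    k <- k + 1L
    r0 <- (i - 1L) * cell_px + 1L; c0 <- (j - 1L) * cell_px + 1L
    x0 <- domain$x0 + (c0 - 1L) * ps
    y1 <- domain$y0 - (r0 - 1L) * ps           # y decreases with row
    x1 <- x0 + cell_px * ps; y0 <- y1 - cell_px * ps
    yc <- (y0 + y1) / 2
    rows[[k]] <- data.frame(
      id = sprintf("cell_%02d_%02d", i, j),
      x0 = x0, x1 = x1, y0 = y0, y1 = y1, size_m = cell_px * ps,
      latitude = domain$lat0 + (yc - domain$y0) / 111320,
      row0 = r0, row1 = r0 + cell_px - 1L,
      col0 = c0, col1 = c0 + cell_px - 1L)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("kelp_cells", "data.frame")
  out
}

#' Pixel indices covered by a cell
#'
#' Membership is decided by the pixel center falling inside the cell's
#' half-open rectangle `[x0, x1) x [y0, y1)`.
#'
#' @param cell one row of a `kelp_cells` frame (or any list with `x0`, `x1`,
#'   `y0`, `y1`).
#' @param domain the [scene_domain()] providing grid geometry.
#' @return Integer vector of pixel indices (column-major).
#' @export
cell_pixels <- function(cell, domain) {
  ps <- domain$pixel_size
  cx <- domain$x0 + (seq_len(domain$ncol) - 0.5) * ps
  cy <- domain$y0 - (seq_len(domain$nrow) - 0.5) * ps
  cols <- which(cx >= cell$x0 & cx < cell$x1)
  rowsv <- which(cy >= cell$y0 & cy < cell$y1)
  if (!length(cols) || !length(rowsv)) stop("cell lies outside the raster")
  as.integer(outer(rowsv, (cols - 1L) * domain$nrow, `+`))
}

#' Aggregate one cell for one quarter
#'
#' Sums the seasonal mean canopy area over the cell's habitat pixels. If the
#' fraction of the cell's habitat pixels without a single cloud-free
#' acquisition exceeds the threshold (strictly greater than 25% by default),
#' the whole cell-quarter is missing. Habitat pixels unobserved in a
#' non-missing quarter contribute 0, never `NA`: missingness is triggered
#' only by the cloud rule.
#'
#' @param stats a [seasonal_pixel_stats()] result.
#' @param pixels integer pixel indices of the cell (from [cell_pixels()]).
#' @param habitat logical habitat matrix.
#' @param cloud_threshold missing-data threshold on the unobserved habitat
#'   fraction (default 0.25, strict `>`).
#' @return List with `area_m2` (or `NA` if missing), `missing` flag,
#'   `cloud_fraction` (unobserved habitat fraction), `stderr_m2`
#'   (quadrature-combined), and `n_overpasses` (max over the cell).
#' @export
aggregate_cell_quarter <- function(stats, pixels, habitat,
                                   cloud_threshold = 0.25) {
  hab_px <- pixels[habitat[pixels]]
  if (length(hab_px) == 0L)
    return(list(area_m2 = 0, missing = FALSE, cloud_fraction = 0,
                stderr_m2 = 0, n_overpasses = max(stats$n[pixels], 0)))
  unobs <- mean(stats$n[hab_px] == 0)
  if (unobs > cloud_threshold)
    return(list(area_m2 = NA_real_, missing = TRUE, cloud_fraction = unobs,
                stderr_m2 = NA_real_, n_overpasses = max(stats$n[hab_px])))
  obs <- hab_px[stats$n[hab_px] > 0]
  list(area_m2 = sum(stats$mean[obs]),
       missing = FALSE, cloud_fraction = unobs,
       stderr_m2 = sqrt(sum(stats$stderr[obs]^2)),
       n_overpasses = max(stats$n[hab_px]))
}

#' Filter cells by habitat extent
#'
#' Cells with fewer habitat pixels than the threshold are excluded (strictly
#' fewer: a cell with exactly the threshold is retained). The conventional
#' thresholds are 500 pixels for 10 x 10 km cells and 25 for 1 x 1 km cells.
#'
#' @param cells a `kelp_cells` frame.
#' @param habitat logical habitat matrix.
#' @param domain the [scene_domain()].
#' @param threshold minimum habitat pixel count to retain a cell.
#' @return The retained subset of `cells`, with a `habitat_pixels` column
#'   added (all cells, retained or not, are described in attribute
#'   `habitat_counts`).
#' @export
filter_cells_by_habitat <- function(cells, habitat, domain, threshold = 25L) {
  counts <- vapply(seq_len(nrow(cells)), function(i) {
    px <- cell_pixels(cells[i, ], domain)
    sum(habitat[px])
  }, integer(1))
  keep <- counts >= threshold
  out <- cells[keep, , drop = FALSE]
  out$habitat_pixels <- counts[keep]
  attr(out, "habitat_counts") <- stats::setNames(counts, cells$id)
  out
}

#' Annual maximum canopy area per cell
#'
#' Reduces a quarterly cell series to the annual maximum over non-missing
#' quarters; a year with two or more missing quarters is itself treated as
#' missing (one missing quarter is tolerated).
#'
#' @param quarterly data frame with columns `year`, `quarter`, `area_m2`,
#'   `missing`.
#' @param max_missing_quarters a year is missing when it has at least this
#'   many missing quarters (default 2).
#' @return Data frame with `year`, `area_m2` (NA when missing),
#'   `n_missing_quarters`, `missing`.
#' @export
annual_max <- function(quarterly, max_missing_quarters = 2L) {
  stopifnot(all(c("year", "quarter", "area_m2", "missing") %in%
                  names(quarterly)))
  out <- lapply(split(quarterly, quarterly$year), function(d) {
    nm <- sum(d$missing | is.na(d$area_m2))
    miss <- nm >= max_missing_quarters
    val <- if (miss || all(is.na(d$area_m2))) NA_real_ else
      max(d$area_m2, na.rm = TRUE)
    data.frame(year = d$year[1], area_m2 = val,
               n_missing_quarters = nm, missing = miss || is.na(val))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$year), ]
}

#' Regional annual canopy area
#'
#' Sums cell annual maxima over a region. A regional year is missing when
#' strictly more than half of the region's cells were missing more than one
#' quarter that year. In non-missing years, cells whose own annual value is
#' missing contribute 0 by default (with a log entry); `strict = TRUE`
#' propagates them as missing instead. The published record does not state
#' which behavior was used, so both are available and the choice is
#' explicit.
#'
#' @param annual_by_cell data frame with columns `cell_id`, `year`,
#'   `area_m2`, `n_missing_quarters`.
#' @param strict if `TRUE`, any missing member cell makes the regional year
#'   missing.
#' @return Data frame with `year`, `area_m2` (NA when missing), `missing`,
#'   `n_cells_missing`.
#' @export
regional_annual <- function(annual_by_cell, strict = FALSE) {
  stopifnot(all(c("cell_id", "year", "area_m2", "n_missing_quarters") %in%
                  names(annual_by_cell)))
  if (nrow(annual_by_cell) == 0L) stop("empty region")
  out <- lapply(split(annual_by_cell, annual_by_cell$year), function(d) {
    bad <- d$n_missing_quarters >= 2L
    miss <- sum(bad) > nrow(d) / 2
    if (!miss) {
      vals <- d$area_m2
      if (anyNA(vals)) {
        if (strict) miss <- TRUE else {
          kc_log("regional_annual: year %d: %d missing cells contribute 0",
                 d$year[1], sum(is.na(vals)))
          vals[is.na(vals)] <- 0
        }
      }
    }
    data.frame(year = d$year[1],
               area_m2 = if (miss) NA_real_ else sum(vals),
               missing = miss, n_cells_missing = sum(bad))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$year), ]
}
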