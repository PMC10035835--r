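# Synthetic Landsat-like scene generation with known ground truth.
#
# The generator emulates the ingredients the real analysis consumes: six-band
# surface reflectance, a QA band marking clouds, a DEM, tide heights, and a
# multi-decade canopy trajectory (secular trend + decadal oscillation + AR
# noise + an imposed heatwave collapse/recovery). Kelp pixels are exact linear
# kelp/seawater mixtures so downstream unmixing can be checked against truth.

#' Synthetic spectral library
#'
#' Builds a six-band spectral library: a single static kelp canopy endmember
#' (high near-infrared reflectance), a seawater base spectrum with near-zero
#' NIR, per-band seawater variability parameters (sun-glint/turbidity
#' analogues), and land and cloud spectra. Spectra are plausible shapes, not
#' measurements; no claim of spectral realism is made.
#'
#' @param seed integer seed; output is deterministic per seed.
#' @return An object of class `kelp_spectral_library`: a list with elements
#'   `kelp_endmember`, `seawater_base`, `seawater_variability`,
#'   `land_spectrum`, `cloud_spectrum`, each a named numeric vector over
#'   [kelp_bands()].
#' @export
generate_spectral_library <- function(seed = 1L) {
  bands <- kelp_bands()
  jit <- function(x, frac = 0.1) x * (1 + stats::runif(length(x), -frac, frac))
  lib <- local_seed(seed, {
    # SWIR stays low over floating canopy (water absorption), which is why
    # the MNDWI intertidal test is insensitive to kelp
    kelp  <- jit(c(0.020, 0.045, 0.030, 0.300, 0.015, 0.008))
    water <- jit(c(0.040, 0.050, 0.030, 0.008, 0.004, 0.003))
    varb  <- jit(c(0.010, 0.012, 0.012, 0.005, 0.003, 0.002))
    land  <- jit(c(0.100, 0.120, 0.140, 0.200, 0.220, 0.180))
    cloud <- jit(c(0.600, 0.600, 0.590, 0.580, 0.450, 0.400), 0.05)
    list(kelp_endmember = kelp, seawater_base = water,
         seawater_variability = varb, land_spectrum = land,
         cloud_spectrum = cloud)
  })
  lib <- lapply(lib, function(x) stats::setNames(clamp01(x), bands))
  # kelp NIR must clearly exceed seawater NIR for canopy to be detectable
  stopifnot(lib$kelp_endmember["nir"] > lib$seawater_base["nir"])
  structure(lib, class = "kelp_spectral_library")
}

#' Scene ground truth
#'
#' Container for the per-pixel truth behind a synthetic scene: true kelp
#' fractional cover, true class map, and the tide height at acquisition.
#'
#' @param kelp_fraction numeric matrix of true fractional cover in `[0, 1]`.
#' @param class_map character matrix over
#'   `{"kelp","seawater","cloud","land","intertidal"}`, same dimensions.
#' @param tide_height tide height in meters at acquisition time.
#' @return An object of class `kelp_scene_truth`.
#' @export
scene_truth <- function(kelp_fraction, class_map, tide_height = 0) {
  stopifnot(is.matrix(kelp_fraction), is.matrix(class_map),
            all(dim(kelp_fraction) == dim(class_map)))
  if (any(kelp_fraction < 0 | kelp_fraction > 1, na.rm = TRUE))
    stop("kelp_fraction must lie in [0, 1]")
  bad <- kelp_fraction > 0 & class_map != "kelp"
  if (any(bad, na.rm = TRUE))
    stop("kelp_fraction > 0 requires class_map == 'kelp'")
  ok <- class_map %in% c("kelp", "seawater", "cloud", "land", "intertidal")
  if (!all(ok)) stop("unknown class in class_map: ",
                     paste(unique(class_map[!ok]), collapse = ", "))
  structure(list(kelp_fraction = kelp_fraction, class_map = class_map,
                 tide_height = tide_height),
            class = "kelp_scene_truth")
}

#' Synthetic coastal domain
#'
#' Defines the fixed geography of a synthetic archive: grid size, pixel size,
#' projected origin, a land strip with positive elevation, an intertidal
#' fringe at elevation exactly zero, and the set of potential kelp habitat
#' pixels with their per-pixel maximum attainable canopy fraction.
#'
#' @param nrow,ncol grid dimensions in pixels.
#' @param pixel_size pixel edge length in meters (default 30, so one pixel
#'   covers 900 m^2).
#' @param land_cols,intertidal_cols,habitat_cols column index vectors for the
#'   land strip, the intertidal fringe, and the offshore kelp habitat band.
#' @param x0,y0 projected coordinates (m) of the top-left corner.
#' @param lat0,lon0 geographic coordinates of the top-left corner, used for
#'   cell centroid latitudes.
#' @param seed seed for the per-pixel habitat quality field.
#' @return An object of class `kelp_domain` with the DEM, the habitat
#'   fraction-capacity matrix `fmax`, and grid geometry.
#' @export
scene_domain <- function(nrow = 40L, ncol = 40L, pixel_size = 30,
                         land_cols = 1:3, intertidal_cols = 4L,
                         habitat_cols = 8:38,
                         x0 = 5e5, y0 = 4e6, lat0 = 36.5, lon0 = -122,
                         seed = 101L) {
  stopifnot(nrow >= 1, ncol >= 1, pixel_size > 0)
  if (length(habitat_cols) < 1L) stop("domain must contain habitat pixels")
  dem <- matrix(-10, nrow, ncol)
  dem[, land_cols] <- 5 + 25 * (length(land_cols):1) / length(land_cols)
  dem[, intertidal_cols] <- 0  # exactly zero: below the strict > 0 land rule
  fmax <- matrix(0, nrow, ncol)
  fmax[, habitat_cols] <- local_seed(seed,
    stats::runif(nrow * length(habitat_cols), 0.35, 0.95))
  structure(list(nrow = as.integer(nrow), ncol = as.integer(ncol),
                 pixel_size = pixel_size, dem = dem, fmax = fmax,
                 land_cols = land_cols, intertidal_cols = intertidal_cols,
                 habitat_cols = habitat_cols,
                 x0 = x0, y0 = y0, lat0 = lat0, lon0 = lon0,
                 capacity_m2 = sum(fmax) * pixel_size^2),
            class = "kelp_domain")
}

#' Synthetic tide-height series
#'
#' Bounded, approximately zero-mean oscillatory tide heights standing in for
#' tide-station predictions at acquisition times.
#'
#' @param seed integer seed.
#' @param n number of acquisition times (must be >= 1).
#' @param amplitude overall amplitude in meters; 0 gives a constant series.
#' @return Numeric vector of `n` tide heights (m).
#' @export
generate_tide_series <- function(seed, n, amplitude = 1) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  local_seed(seed, {
    ph <- stats::runif(2, 0, 2 * pi)
    t <- seq_len(n)
    amplitude * (0.6 * sin(2 * pi * t / 7.3 + ph[1]) +
                 0.4 * sin(2 * pi * t / 3.9 + ph[2]))
  })
}

# Random cloud blobs covering approximately `coverage` of the grid.
make_cloud_mask <- function(nrow, ncol, coverage, seed) {
  m <- matrix(FALSE, nrow, ncol)
  if (coverage <= 0) return(m)
  if (coverage >= 0.99) return(!m)
  local_seed(seed, {
    rr <- row(m); cc <- col(m)
    guard <- 0L
    while (mean(m) < coverage && guard < 200L) {
      cy <- stats::runif(1, 1, nrow); cx <- stats::runif(1, 1, ncol)
      rad <- stats::runif(1, 2, max(3, min(nrow, ncol) / 6))
      m <- m | ((rr - cy)^2 + (cc - cx)^2 <= rad^2)
      guard <- guard + 1L
    }
    m
  })
}

#' Generate one synthetic scene from ground truth
#'
#' Assembles a six-band reflectance scene from a truth map and a spectral
#' library. Kelp pixels are exact linear mixtures
#' `f * E_kelp + (1 - f) * E_water(pixel)` of the kelp endmember and a
#' spatially varying seawater spectrum; seawater varies smoothly across the
#' scene (glint/turbidity analogue). Cloud pixels take the cloud spectrum and
#' are marked in the QA band; land pixels take the land spectrum; intertidal
#' pixels look land-like when exposed (negative tide) and water-like
#' otherwise. Optional independent Gaussian noise per band is truncated to
#' `[0, 1]`.
#'
#' @param truth a [scene_truth()] object.
#' @param library a [generate_spectral_library()] result.
#' @param noise_sd per-band Gaussian noise standard deviation (reflectance
#'   units, >= 0).
#' @param seed integer seed.
#' @param acquired acquisition date (`Date` or coercible).
#' @param sensor_generation `"TM/ETM+"` or `"OLI"`.
#' @param qa_codes named list with `clear` and `cloud` integer codes for the
#'   QA band.
#' @return An object of class `kelp_scene`: bands array
#'   (`nrow x ncol x 6`), integer `qa` matrix, and acquisition metadata.
#' @export
generate_scene <- function(truth, library, noise_sd = 0, seed = 1L,
                           acquired = as.Date("2000-07-01"),
                           sensor_generation = c("TM/ETM+", "OLI"),
                           qa_codes = list(clear = 1L, cloud = 4L)) {
  stopifnot(inherits(truth, "kelp_scene_truth"),
            inherits(library, "kelp_spectral_library"))
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  sensor_generation <- match.arg(sensor_generation)
  nr <- nrow(truth$class_map); nc <- ncol(truth$class_map)
  bands <- kelp_bands()

  local_seed(seed, {
    # smooth seawater variability field: planar gradient + per-scene offset
    a <- stats::rnorm(3, 0, 0.8)
    g <- a[1] * (col(truth$class_map) / nc - 0.5) +
         a[2] * (row(truth$class_map) / nr - 0.5) + a[3] * 0.3
    arr <- array(NA_real_, c(nr, nc, 6L), dimnames = list(NULL, NULL, bands))
    for (b in seq_along(bands)) {
      w <- clamp01(library$seawater_base[b] + library$seawater_variability[b] * g)
      layer <- w  # seawater everywhere by default
      k <- truth$class_map == "kelp"
      layer[k] <- truth$kelp_fraction[k] * library$kelp_endmember[b] +
        (1 - truth$kelp_fraction[k]) * w[k]
      layer[truth$class_map == "land"] <- library$land_spectrum[b]
      it <- truth$class_map == "intertidal"
      if (truth$tide_height < 0) {
        layer[it] <- 0.6 * library$land_spectrum[b] + 0.4 * library$seawater_base[b]
      } else {
        layer[it] <- library$seawater_base[b]
      }
      layer[truth$class_map == "cloud"] <- library$cloud_spectrum[b]
      if (noise_sd > 0)
        layer <- clamp01(layer + stats::rnorm(nr * nc, 0, noise_sd))
      arr[, , b] <- layer
    }
    qa <- matrix(qa_codes$clear, nr, nc)
    qa[truth$class_map == "cloud"] <- qa_codes$cloud
    structure(list(bands = arr, qa = qa, acquired = as.Date(acquired),
                   sensor_generation = sensor_generation,
                   tide_height = truth$tide_height,
                   pixel_size = 30),
              class = "kelp_scene")
  })
}

#' Multi-decade canopy dynamics configuration
#'
#' Collects the parameters of the simulated canopy trajectory. The annual
#' series is built in normalized units (fraction of the configured baseline
#' area): a linear trend, an optional decadal sinusoidal oscillation, and
#' stationary AR noise. Years inside `heatwave_years` are pinned to
#' `heatwave_depth` times the mean of the deterministic baseline component,
#' and years after the heatwave to `recovery_level` times that mean, so the
#' disturbance magnitude is known exactly by construction.
#'
#' @param n_years number of simulated years (default 38, i.e. 1984-2021).
#' @param start_year first calendar year.
#' @param quarters_per_year fixed at 4 (calendar quarters).
#' @param acquisitions_per_quarter cloud-capable acquisitions per quarter.
#' @param baseline_area nominal canopy area scale in m^2; if `NULL` it is set
#'   to 60% of the domain habitat capacity when the series is generated.
#' @param trend true slope in fraction-of-baseline per year (e.g. -0.008 for
#'   -0.8% per year).
#' @param ar_order,ar_coefficients AR order (0, 1 or 2) and coefficients of
#'   the interannual noise; must define a stationary process.
#' @param noise_sd marginal standard deviation of the AR noise, in m^2; if
#'   `NULL`, 5% of `baseline_area`.
#' @param oscillation_period,oscillation_amplitude decadal oscillation period
#'   (years) and amplitude (m^2; `NULL` means 5% of `baseline_area`; 0
#'   disables).
#' @param heatwave_years integer vector of heatwave calendar years (default
#'   2014:2016); `NULL` disables the disturbance.
#' @param heatwave_depth fraction of the baseline mean retained during the
#'   heatwave (>= 0).
#' @param recovery_level fraction of the baseline mean after the heatwave.
#' @param season_weights within-year quarterly profile, max 1 (so the annual
#'   maximum equals the annual value).
#' @param reflectance_noise_sd per-band scene noise (reflectance units).
#' @param cloud_cover mean per-acquisition cloud blob coverage fraction.
#' @param clouded_quarter_prob probability that an entire quarter is fully
#'   clouded (exercises the missing-data rules).
#' @param oli_start_year first year attributed to the OLI sensor generation.
#' @param seed master seed; all randomness derives from it.
#' @return An object of class `kelp_dynamics_config`.
#' @export
dynamics_config <- function(n_years = 38L, start_year = 1984L,
                            quarters_per_year = 4L,
                            acquisitions_per_quarter = 3L,
                            baseline_area = NULL,
                            trend = -0.008,
                            ar_order = 1L, ar_coefficients = 0.3,
                            noise_sd = NULL,
                            oscillation_period = 10, oscillation_amplitude = NULL,
                            heatwave_years = 2014:2016,
                            heatwave_depth = 0.2, recovery_level = 0.8,
                            season_weights = c(0.70, 0.85, 1.00, 0.80),
                            reflectance_noise_sd = 0.01,
                            cloud_cover = 0.05, clouded_quarter_prob = 0.02,
                            oli_start_year = 2013L,
                            seed = 1L) {
  stopifnot(n_years >= 1, quarters_per_year == 4L,
            acquisitions_per_quarter >= 1,
            heatwave_depth >= 0, recovery_level >= 0,
            length(season_weights) == 4L, max(season_weights) == 1)
  ar_order <- as.integer(ar_order)
  if (!ar_order %in% 0:2) stop("ar_order must be 0, 1 or 2")
  if (ar_order == 0L) ar_coefficients <- numeric(0)
  if (length(ar_coefficients) != ar_order)
    stop("ar_coefficients must have length ar_order")
  if (ar_order > 0 &&
      any(Mod(polyroot(c(1, -ar_coefficients))) <= 1 + 1e-8))
    stop("ar_coefficients do not define a stationary process")
  structure(list(n_years = as.integer(n_years),
                 start_year = as.integer(start_year),
                 quarters_per_year = 4L,
                 acquisitions_per_quarter = as.integer(acquisitions_per_quarter),
                 baseline_area = baseline_area, trend = trend,
                 ar_order = ar_order, ar_coefficients = ar_coefficients,
                 noise_sd = noise_sd,
                 oscillation_period = oscillation_period,
                 oscillation_amplitude = oscillation_amplitude,
                 heatwave_years = heatwave_years,
                 heatwave_depth = heatwave_depth,
                 recovery_level = recovery_level,
                 season_weights = season_weights,
                 reflectance_noise_sd = reflectance_noise_sd,
                 cloud_cover = cloud_cover,
                 clouded_quarter_prob = clouded_quarter_prob,
                 oli_start_year = as.integer(oli_start_year),
                 seed = seed),
            class = "kelp_dynamics_config")
}

# Simulate the true annual series (normalized units) from a config.
# Returns data.frame(year, det, value, period) where period is one of
# "baseline", "heatwave", "recovery".
simulate_annual_truth <- function(config) {
  years <- config$start_year + seq_len(config$n_years) - 1L
  t <- seq_along(years)
  det <- 1 + config$trend * (t - 1)
  osc_rel <- if (is.null(config$oscillation_amplitude)) 0.05 else
    config$oscillation_amplitude / config$baseline_area
  if (osc_rel > 0 && config$oscillation_period > 0)
    det <- det + osc_rel * sin(2 * pi * (t - 1) / config$oscillation_period)
  hw <- config$heatwave_years
  period <- rep("baseline", length(years))
  if (!is.null(hw) && length(hw)) {
    period[years %in% hw] <- "heatwave"
    period[years > max(hw)] <- "recovery"
  }
  base_idx <- period == "baseline"
  if (!any(base_idx)) stop("dynamics leave no baseline years")
  noise_rel <- if (is.null(config$noise_sd)) 0.05 else
    config$noise_sd / config$baseline_area
  eps <- numeric(length(years))
  if (noise_rel > 0) {
    eps <- local_seed(child_seed(config$seed, 1L), {
      if (config$ar_order == 0L) {
        stats::rnorm(length(years), 0, noise_rel)
      } else {
        as.numeric(stats::arima.sim(
          list(ar = config$ar_coefficients), n = length(years),
          sd = noise_rel * sqrt(ar_innovation_scale(config$ar_coefficients))))
      }
    })
  }
  value <- det + eps
  det_base_mean <- mean(det[base_idx])
  value[period == "heatwave"] <- config$heatwave_depth * det_base_mean
  value[period == "recovery"] <- config$recovery_level * det_base_mean
  value <- pmax(value, 0.01)
  data.frame(year = years, det = det, value = value, period = period,
             stringsAsFactors = FALSE)
}

# Ratio innovation_var / marginal_var for a stationary AR process, so a
# requested marginal sd can be converted to an innovation sd.
ar_innovation_scale <- function(phi) {
  p <- length(phi)
  if (p == 0L) return(1)
  rho <- ar_autocorr(phi, p)
  1 - sum(phi * rho[2:(p + 1)])
}

# Stationary autocorrelations rho(0..max_lag) of an AR(p) process via the
# Yule-Walker equations and the AR recursion.
ar_autocorr <- function(phi, max_lag) {
  p <- length(phi)
  rho <- numeric(max_lag + 1L)
  rho[1] <- 1
  if (p == 0L || max_lag == 0L) return(rho)
  if (p == 1L) {
    for (h in seq_len(max_lag)) rho[h + 1] <- phi * rho[h]
  } else if (p == 2L) {
    rho[2] <- phi[1] / (1 - phi[2])
    if (max_lag >= 2)
      for (h in 2:max_lag)
        rho[h + 1] <- phi[1] * rho[h] + phi[2] * rho[h - 1]
  } else stop("AR order > 2 not supported")
  rho
}

#' Generate a multi-decade synthetic scene archive
#'
#' Runs the configured canopy dynamics over a domain and produces, for each
#' quarter of each year, `acquisitions_per_quarter` scenes with ground truth.
#' The summed true kelp area in a quarter follows the configured trajectory
#' exactly (per-pixel fractions scale a fixed habitat-quality field, so the
#' truth is reproduced without discretization error). Clouds are random blobs
#' per acquisition; occasionally a whole quarter is fully clouded to exercise
#' the missing-data rules.
#'
#' @param config a [dynamics_config()] object.
#' @param domain a [scene_domain()] object.
#' @param library optional [generate_spectral_library()] result; generated
#'   from the config seed if missing.
#' @return An object of class `kelp_archive`: a list with `acquisitions`
#'   (each holding `scene`, `truth`, `year`, `quarter`), `truth_annual` and
#'   `truth_quarterly` data frames of true areas in m^2, plus the library,
#'   domain and config.
#' @export
generate_scene_series <- function(config, domain, library = NULL) {
  stopifnot(inherits(config, "kelp_dynamics_config"),
            inherits(domain, "kelp_domain"))
  if (sum(domain$fmax) == 0) stop("domain has no habitat pixels")
  if (is.null(config$baseline_area))
    config$baseline_area <- 0.6 * domain$capacity_m2
  if (is.null(library)) library <- generate_spectral_library(child_seed(config$seed, 2L))

  ann <- simulate_annual_truth(config)
  px_area <- domain$pixel_size^2
  max_area <- 0.95 * domain$capacity_m2
  ann$area_m2 <- pmin(ann$value * config$baseline_area, max_area)
  if (any(ann$value * config$baseline_area > max_area))
    warning("annual canopy truncated at 95% of domain habitat capacity")

  n_acq_total <- config$n_years * 4L * config$acquisitions_per_quarter
  tides <- generate_tide_series(child_seed(config$seed, 3L), n_acq_total,
                                amplitude = 1)
  cm <- domain$dem > 0
  base_class <- matrix("seawater", domain$nrow, domain$ncol)
  base_class[, domain$land_cols] <- "land"
  base_class[, domain$intertidal_cols] <- "intertidal"

  # Spatial allocation by occupancy: habitat pixels are filled to their
  # per-pixel capacity in fixed quality order until the target area is met
  # (one marginal pixel takes the remainder). Canopy loss thus contracts
  # extent while surviving patches stay dense, as observed in real
  # collapses, and occupied pixels keep detectable fractions.
  hab_idx <- which(domain$fmax > 0)
  ord <- hab_idx[order(domain$fmax[hab_idx], hab_idx, decreasing = TRUE)]
  cumcap <- cumsum(domain$fmax[ord])
  fill_fractions <- function(S) {
    frac <- matrix(0, domain$nrow, domain$ncol)
    if (S <= 0) return(frac)
    k <- findInterval(S, cumcap)
    if (k > 0) frac[ord[seq_len(k)]] <- domain$fmax[ord[seq_len(k)]]
    rem <- S - if (k > 0) cumcap[k] else 0
    if (rem > 1e-12 && k < length(ord)) frac[ord[k + 1L]] <- rem
    frac
  }

  qtr_rows <- list(); acqs <- list(); idx <- 0L
  clouded <- local_seed(child_seed(config$seed, 4L),
    stats::runif(config$n_years * 4L) < config$clouded_quarter_prob)
  for (i in seq_len(config$n_years)) {
    for (q in 1:4) {
      qi <- (i - 1L) * 4L + q
      area_q <- min(ann$area_m2[i] * config$season_weights[q],
                    sum(domain$fmax) * px_area)
      frac <- fill_fractions(area_q / px_area)
      class_map <- base_class
      class_map[frac > 0] <- "kelp"
      qtr_rows[[qi]] <- data.frame(year = ann$year[i], quarter = q,
                                   area_m2 = area_q)
      for (k in seq_len(config$acquisitions_per_quarter)) {
        idx <- idx + 1L
        cover <- if (clouded[qi]) 1 else config$cloud_cover
        cl <- make_cloud_mask(domain$nrow, domain$ncol, cover,
                              child_seed(config$seed, 10L + idx))
        cmap <- class_map; cmap[cl] <- "cloud"
        fr <- frac; fr[cl] <- 0
        truth <- scene_truth(fr, cmap, tide_height = tides[idx])
        gen <- if (ann$year[i] >= config$oli_start_year) "OLI" else "TM/ETM+"
        day <- as.Date(sprintf("%d-%02d-15", ann$year[i], (q - 1L) * 3L + 1L)) +
          (k - 1L) * 24L
        scene <- generate_scene(truth, library,
                                noise_sd = config$reflectance_noise_sd,
                                seed = child_seed(config$seed, 5000L + idx),
                                acquired = day, sensor_generation = gen)
        acqs[[idx]] <- list(scene = scene, truth = truth,
                            quarter_fraction = frac,
                            year = ann$year[i], quarter = q, index = idx)
      }
    }
  }
  structure(list(acquisitions = acqs,
                 truth_annual = ann[, c("year", "area_m2", "period")],
                 truth_quarterly = do.call(rbind, qtr_rows),
                 library = library, domain = domain, config = config),
            class = "kelp_archive")
}

#' @export
print.kelp_archive <- function(x, ...) {
  cat(sprintf("<kelp_archive> %d years x 4 quarters x %d acquisitions (%d scenes)\n",
              x$config$n_years, x$config$acquisitions_per_quarter,
              length(x$acquisitions)))
  cat(sprintf("  domain %d x %d px @ %g m; habitat capacity %.0f m^2\n",
              x$domain$nrow, x$domain$ncol, x$domain$pixel_size,
              x$domain$capacity_m2))
  invisible(x)
}
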