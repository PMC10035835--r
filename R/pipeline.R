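# End-to-end orchestration: simulate -> mask -> classify -> unmix ->
# aggregate -> trend/heatwave statistics, with structured per-stage counts
# and deterministic outputs (all randomness flows from the config seed).

#' Pipeline configuration
#'
#' Collects every tunable constant of the processing chain: the synthetic
#' dynamics and domain, the masking thresholds (MNDWI 0.1, cloud 25%), the
#' habitat thresholds (500 pixels for 10 km cells, 25 for 1 km cells), the
#' heatwave windows, the candidate AR orders, the pixel area (900 m^2), and
#' the master seed.
#'
#' @param dynamics a [dynamics_config()].
#' @param domain a [scene_domain()].
#' @param cell_px analysis-cell edge length in pixels.
#' @param habitat_threshold minimum habitat pixels to retain a cell.
#' @param cloud_threshold cell-quarter missing-data threshold (strict `>`).
#' @param mndwi_threshold intertidal MNDWI threshold (strict `<`).
#' @param baseline_years,event_years,recovery_years,recent_window heatwave
#'   analysis windows.
#' @param ar_orders candidate AR orders for trend fitting.
#' @param trend_years optional year subset for the trend fit (`NULL` = all
#'   years).
#' @param pixel_area pixel footprint in m^2.
#' @param n_seawater_endmembers per-scene seawater endmember count.
#' @param seed master seed (overrides the dynamics seed).
#' @return An object of class `kelp_pipeline_config`.
#' @export
pipeline_config <- function(dynamics = dynamics_config(),
                            domain = scene_domain(),
                            cell_px = 20L,
                            habitat_threshold = 25L,
                            cloud_threshold = 0.25,
                            mndwi_threshold = 0.1,
                            baseline_years = 1984:2013,
                            event_years = 2014:2016,
                            recovery_years = 2017:2021,
                            recent_window = 2014:2021,
                            ar_orders = 0:2,
                            trend_years = NULL,
                            pixel_area = 900,
                            n_seawater_endmembers = 30L,
                            seed = 1L) {
  stopifnot(cloud_threshold > 0, cloud_threshold < 1,
            pixel_area > 0, habitat_threshold >= 0)
  dynamics$seed <- seed
  structure(list(dynamics = dynamics, domain = domain, cell_px = cell_px,
                 habitat_threshold = as.integer(habitat_threshold),
                 cloud_threshold = cloud_threshold,
                 mndwi_threshold = mndwi_threshold,
                 baseline_years = baseline_years, event_years = event_years,
                 recovery_years = recovery_years,
                 recent_window = recent_window,
                 ar_orders = ar_orders, trend_years = trend_years,
                 pixel_area = pixel_area,
                 n_seawater_endmembers = as.integer(n_seawater_endmembers),
                 seed = seed),
            class = "kelp_pipeline_config")
}

config_hash <- function(config) {
  fnv1a32(jsonlite::toJSON(lapply(unclass(config), function(x)
    if (is.list(x)) lapply(unclass(x), unclass) else unclass(x)),
    auto_unbox = TRUE, digits = NA, null = "null"))
}

# Train one classifier per sensor generation, accumulating acquisitions of
# that generation until all four classes appear in the training pool.
train_generation_classifiers <- function(archive, seed, n_train = 1500L) {
  gens <- unique(vapply(archive$acquisitions,
                        function(a) a$scene$sensor_generation, character(1)))
  out <- list()
  for (g in gens) {
    idx <- which(vapply(archive$acquisitions,
                        function(a) a$scene$sensor_generation == g, logical(1)))
    X <- NULL; cls <- character(0)
    for (i in idx) {
      a <- archive$acquisitions[[i]]
      tc <- a$truth$class_map
      tc[tc == "intertidal"] <- "land"  # classifier's 4-class label space
      Xi <- matrix(a$scene$bands, length(tc), 6L)
      X <- rbind(X, Xi); cls <- c(cls, as.vector(tc))
      if (length(unique(cls)) == 4L && length(cls) >= n_train) break
    }
    keep <- local_seed(child_seed(seed, 20L + match(g, gens)), {
      # stratified subsample so rare classes survive
      unlist(lapply(split(seq_along(cls), cls), function(ii)
        if (length(ii) > n_train %/% 2L) sample(ii, n_train %/% 2L) else ii))
    })
    Xn <- normalize_bands(X[keep, , drop = FALSE])
    km <- cluster_training_spectra(Xn, k = 15L,
                                   seed = child_seed(seed, 30L + match(g, gens)))
    lab <- assign_cluster_classes(km$cluster, cls[keep])
    out[[g]] <- train_decision_tree(Xn, lab, sensor_generation = g)
  }
  out
}

#' Run the full pipeline
#'
#' Executes every stage on a synthetic archive: scene simulation, cloud /
#' land / intertidal masking, per-generation classifier training and scene
#' classification, MESMA unmixing, seasonal statistics, habitat and cell
#' aggregation with the missing-data rules, annual maxima, the regional
#' sum, max-normalized GLS-AR trend fitting, and heatwave response /
#' recovery / recent-state metrics (regionally and per cell). Identical
#' configurations produce byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, the canonical CSVs
#'   (cell-quarter table, per-cell results, regional annual series) and a
#'   JSON run log (stage counts, config hash, seed) are written there.
#' @return A list with the cell tables, regional series, `kelp_trend` fit,
#'   heatwave metrics, per-cell results, tidal flag report, stage log, and
#'   the archive truth for validation.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "kelp_pipeline_config"))
  log <- list(config_hash = config_hash(config), seed = config$seed)
  domain <- config$domain

  # --- simulate -------------------------------------------------------
  archive <- generate_scene_series(config$dynamics, domain)
  n_acq <- length(archive$acquisitions)
  log$n_scenes <- n_acq

  # --- static masks ---------------------------------------------------
  land <- land_mask_from_dem(domain$dem)
  ref_truth <- scene_truth(matrix(0, domain$nrow, domain$ncol),
                           {
                             m <- matrix("seawater", domain$nrow, domain$ncol)
                             m[, domain$land_cols] <- "land"
                             m[, domain$intertidal_cols] <- "intertidal"
                             m
                           }, tide_height = -0.5)
  ref_scene <- generate_scene(ref_truth, archive$library, noise_sd = 0,
                              seed = child_seed(config$seed, 7L))
  intertidal <- intertidal_mask(ref_scene, land_mask = land,
                                threshold = config$mndwi_threshold)
  static_mask <- combine_masks(land, intertidal)
  log$n_land_masked <- sum(land)
  log$n_intertidal_masked <- sum(intertidal)

  # --- classify + unmix ------------------------------------------------
  classifiers <- train_generation_classifiers(archive, config$seed)
  log$training_accuracy <- vapply(classifiers,
                                  function(cf) cf$training_accuracy, numeric(1))
  fractions <- vector("list", n_acq)
  areas <- vector("list", n_acq)
  n_kelp_px <- 0L
  for (i in seq_len(n_acq)) {
    a <- archive$acquisitions[[i]]
    cmask <- cloud_mask_from_qa(a$scene$qa)
    cmap <- classify_scene(a$scene, classifiers[[a$scene$sensor_generation]],
                           cloud_mask = cmask, land_mask = static_mask)
    if (any(cmap == "seawater")) {
      ems <- select_seawater_endmembers(a$scene, cmap,
                                        n = config$n_seawater_endmembers,
                                        seed = child_seed(config$seed, 100L + i))
      um <- unmix_scene(a$scene, cmap,
                        archive$library$kelp_endmember[unmix_bands()], ems)
      fr <- um$fraction
    } else {
      fr <- matrix(NA_real_, domain$nrow, domain$ncol)
      fr[!(cmask | static_mask)] <- 0
    }
    n_kelp_px <- n_kelp_px + sum(cmap == "kelp", na.rm = TRUE)
    fractions[[i]] <- fr
    areas[[i]] <- fraction_to_area(fr, config$pixel_area)
  }
  log$n_kelp_pixels_classified <- n_kelp_px

  # --- aggregate -------------------------------------------------------
  habitat <- derive_habitat_mask(fractions)
  log$n_habitat_pixels <- sum(habitat)
  cells <- make_grid_cells(domain, config$cell_px)
  cells <- filter_cells_by_habitat(cells, habitat, domain,
                                   threshold = config$habitat_threshold)
  log$n_cells_retained <- nrow(cells)
  log$n_cells_excluded <- length(attr(cells, "habitat_counts")) - nrow(cells)
  if (nrow(cells) == 0L) stop("aggregate stage failed: no cells retained")

  meta <- vapply(archive$acquisitions, function(a) c(a$year, a$quarter),
                 numeric(2))
  key <- paste(meta[1, ], meta[2, ])
  quarters <- unique(data.frame(year = meta[1, ], quarter = meta[2, ]))
  rows <- list(); r <- 0L
  for (qi in seq_len(nrow(quarters))) {
    sel <- which(key == paste(quarters$year[qi], quarters$quarter[qi]))
    stats_q <- seasonal_pixel_stats(areas[sel])
    for (ci in seq_len(nrow(cells))) {
      px <- cell_pixels(cells[ci, ], domain)
      agg <- aggregate_cell_quarter(stats_q, px, habitat,
                                    cloud_threshold = config$cloud_threshold)
      r <- r + 1L
      rows[[r]] <- data.frame(cell_id = cells$id[ci],
                              year = quarters$year[qi],
                              quarter = quarters$quarter[qi],
                              area_m2 = agg$area_m2,
                              stderr_m2 = agg$stderr_m2,
                              n_overpasses = agg$n_overpasses,
                              cloud_fraction = agg$cloud_fraction,
                              missing = agg$missing)
    }
  }
  cell_quarterly <- do.call(rbind, rows)

  cell_annual <- do.call(rbind, lapply(split(cell_quarterly,
                                             cell_quarterly$cell_id),
    function(d) cbind(cell_id = d$cell_id[1], annual_max(d))))
  rownames(cell_annual) <- NULL
  regional <- regional_annual(cell_annual)
  log$n_years_missing <- sum(regional$missing)

  # --- statistics ------------------------------------------------------
  trend_input <- regional[!regional$missing, ]
  if (!is.null(config$trend_years))
    trend_input <- trend_input[trend_input$year %in% config$trend_years, ]
  trend <- kelp_trend(normalize_by_max(trend_input$area_m2),
                      trend_input$year, orders = config$ar_orders)
  reg_series <- stats::setNames(regional$area_m2, regional$year)
  heatwave <- list(
    response_pct = heatwave_response(reg_series, config$baseline_years,
                                     config$event_years),
    recovery_pct = heatwave_recovery(reg_series, config$baseline_years,
                                     config$recovery_years),
    recent_state_pct = recent_state(reg_series, config$baseline_years,
                                    config$recent_window),
    baseline_mean_m2 = mean(reg_series[names(reg_series) %in%
                              as.character(config$baseline_years)],
                            na.rm = TRUE))

  per_cell <- do.call(rbind, lapply(seq_len(nrow(cells)), function(ci) {
    d <- cell_annual[cell_annual$cell_id == cells$id[ci] & !cell_annual$missing, ]
    s <- stats::setNames(d$area_m2, d$year)
    tr <- tryCatch({
      di <- d
      if (!is.null(config$trend_years))
        di <- d[d$year %in% config$trend_years, ]
      kelp_trend(normalize_by_max(di$area_m2), di$year,
                 orders = config$ar_orders)
    }, error = function(e) NULL)
    data.frame(cell_id = cells$id[ci], latitude = cells$latitude[ci],
               slope_pct_yr = tr$slope_pct %||% NA_real_,
               stderr = tr$stderr_pct %||% NA_real_,
               p = tr$p_value %||% NA_real_,
               ar_order = tr$ar_order %||% NA_integer_,
               response_pct = heatwave_response(s, config$baseline_years,
                                                config$event_years),
               recovery_pct = heatwave_recovery(s, config$baseline_years,
                                                config$recovery_years),
               recent_pct = recent_state(s, config$baseline_years,
                                         config$recent_window))
  }))

  # --- tidal-artifact flags -------------------------------------------
  adj <- land_adjacency(land | intertidal)
  tides <- vapply(archive$acquisitions, function(a) a$scene$tide_height,
                  numeric(1))
  area_mat <- vapply(areas, as.vector, numeric(domain$nrow * domain$ncol))
  tidal_flags <- flag_tidal_pixels(area_mat, tides, adj)
  log$n_tidal_flags <- nrow(tidal_flags)

  out <- list(cells = cells, habitat = habitat,
              cell_quarterly = cell_quarterly, cell_annual = cell_annual,
              regional_annual = regional, trend = trend,
              heatwave = heatwave, per_cell = per_cell,
              tidal_flags = tidal_flags, log = log,
              truth_annual = archive$truth_annual,
              config = config)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cell_csv(cell_quarterly, file.path(out_dir, "cell_quarterly.csv"))
    utils::write.csv(per_cell, file.path(out_dir, "per_cell_results.csv"),
                     row.names = FALSE)
    utils::write.csv(regional, file.path(out_dir, "regional_annual.csv"),
                     row.names = FALSE)
    utils::write.csv(tidal_flags, file.path(out_dir, "tidal_flags.csv"),
                     row.names = FALSE)
    jsonlite::write_json(log, file.path(out_dir, "run_info.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
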