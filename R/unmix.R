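# Multiple endmember spectral mixture analysis (MESMA).
#
# Each kelp-class pixel is modeled as a two-endmember linear mixture of the
# single static kelp endmember and each of ~30 per-scene seawater
# endmembers; the minimum-RMSE model supplies the kelp fractional cover.
# Only the blue, green, red and NIR bands enter the fit.

#' Select per-scene seawater endmembers
#'
#' Samples `n` seawater spectra from the pixels classified as seawater in
#' one scene. Sampling is spatially stratified (the scene is divided into a
#' coarse block grid and pixels are drawn proportionally from occupied
#' blocks) so that spectrally distinct water masses — glint fields, turbidity
#' plumes — are all represented. Deterministic per seed.
#'
#' @param scene a `kelp_scene`.
#' @param class_map character class matrix from [classify_scene()].
#' @param n number of endmembers (default 30).
#' @param seed integer seed.
#' @param blocks stratification grid size per axis (default 4).
#' @return Matrix `n x 4` of seawater spectra over [unmix_bands()], with the
#'   sampled pixel indices in attribute `pixels`. If fewer than `n` seawater
#'   pixels exist, all are returned with a warning.
#' @export
select_seawater_endmembers <- function(scene, class_map, n = 30L, seed = 1L,
                                       blocks = 4L) {
  stopifnot(inherits(scene, "kelp_scene"), is.matrix(class_map))
  nr <- nrow(class_map); nc <- ncol(class_map)
  sea <- which(class_map == "seawater")
  if (length(sea) == 0L) stop("scene has no seawater-class pixels")
  X <- matrix(scene$bands[, , unmix_bands()], nr * nc, 4L)
  colnames(X) <- unmix_bands()
  if (length(sea) <= n) {
    if (length(sea) < n)
      warning("only ", length(sea), " seawater pixels available; using all")
    em <- X[sea, , drop = FALSE]
    attr(em, "pixels") <- sea
    return(em)
  }
  # block id per candidate pixel
  br <- pmin(blocks, ceiling(((sea - 1L) %% nr + 1L) / (nr / blocks)))
  bc <- pmin(blocks, ceiling(((sea - 1L) %/% nr + 1L) / (nc / blocks)))
  blk <- (br - 1L) * blocks + bc
  picked <- local_seed(seed, {
    by_blk <- split(sea, blk)
    # proportional allocation with at least one draw per occupied block
    alloc <- pmax(1L, round(n * lengths(by_blk) / length(sea)))
    sel <- unlist(mapply(function(px, a) {
      if (length(px) == 1L) rep(px, min(a, 1L)) else sample(px, min(a, length(px)))
    }, by_blk, alloc, SIMPLIFY = FALSE), use.names = FALSE)
    if (length(sel) > n) sel <- sort(sample(sel, n))
    while (length(sel) < n) {
      extra <- sample(setdiff(sea, sel), min(n - length(sel),
                                             length(sea) - length(sel)))
      sel <- sort(c(sel, extra))
    }
    sel
  })
  em <- X[picked, , drop = FALSE]
  attr(em, "pixels") <- picked
  em
}

#' Unmix a single pixel spectrum
#'
#' For each candidate seawater endmember `W`, fits the two-endmember
#' sum-to-one mixture `x ~ f*K + (1-f)*W` by least squares using the closed
#' form `f* = sum_b (x_b - W_b)(K_b - W_b) / sum_b (K_b - W_b)^2`, clamps
#' `f*` to `[0, 1]` (so the reported model is a feasible proportion), and
#' evaluates the RMSE of the clamped model over the four bands. The
#' minimum-RMSE candidate wins; RMSE ties break to the lowest endmember
#' index for determinism.
#'
#' @param x numeric vector of 4 reflectances (blue, green, red, NIR).
#' @param kelp_em kelp endmember (4 bands).
#' @param water_ems matrix of seawater endmembers (rows = candidates, 4
#'   columns).
#' @return List with `fraction` (in `[0, 1]`), `rmse`, and
#'   `selected_endmember` (row index of the winning candidate).
#' @export
unmix_pixel <- function(x, kelp_em, water_ems) {
  stopifnot(length(x) == 4L, all(is.finite(x)), length(kelp_em) == 4L)
  if (is.null(dim(water_ems))) water_ems <- matrix(water_ems, nrow = 1L)
  stopifnot(ncol(water_ems) == 4L)
  D <- matrix(kelp_em, nrow(water_ems), 4L, byrow = TRUE) - water_ems
  ss <- rowSums(D^2)
  valid <- ss > 0
  if (!any(valid)) stop("all candidate seawater endmembers equal the kelp endmember")
  Xd <- matrix(x, nrow(water_ems), 4L, byrow = TRUE) - water_ems
  f <- clamp01(rowSums(Xd * D) / ss)
  resid <- Xd - f * D
  rmse <- sqrt(rowMeans(resid^2))
  rmse[!valid] <- Inf
  best <- unname(which.min(rmse))  # first minimum: lowest index wins ties
  list(fraction = unname(f[best]), rmse = unname(rmse[best]),
       selected_endmember = best)
}

#' Unmix every kelp-class pixel of a scene
#'
#' Runs [unmix_pixel()] over all pixels classified as kelp. Non-kelp
#' unmasked pixels get fraction 0; masked pixels (class `"cloud"`,
#' `"land"`, or `NA`) get `NA`.
#'
#' @param scene a `kelp_scene`.
#' @param class_map class matrix from [classify_scene()].
#' @param kelp_em kelp endmember (4 bands).
#' @param water_ems matrix of per-scene seawater endmembers.
#' @return List with `fraction` matrix, `rmse` matrix (NA off-kelp) and
#'   `selected` endmember-index matrix.
#' @export
unmix_scene <- function(scene, class_map, kelp_em, water_ems) {
  stopifnot(inherits(scene, "kelp_scene"), is.matrix(class_map))
  nr <- nrow(class_map); nc <- ncol(class_map)
  frac <- matrix(0, nr, nc)
  rmse <- matrix(NA_real_, nr, nc)
  sel <- matrix(NA_integer_, nr, nc)
  frac[is.na(class_map) | class_map %in% c("cloud", "land")] <- NA_real_
  kelp_px <- which(class_map == "kelp")
  if (length(kelp_px)) {
    X <- matrix(scene$bands[, , unmix_bands()], nr * nc, 4L)[kelp_px, , drop = FALSE]
    if (is.null(dim(water_ems))) water_ems <- matrix(water_ems, nrow = 1L)
    m <- nrow(water_ems)
    D <- matrix(kelp_em, m, 4L, byrow = TRUE) - water_ems
    ss <- rowSums(D^2)
    if (!any(ss > 0)) stop("all candidate seawater endmembers equal the kelp endmember")
    bestF <- rep(NA_real_, nrow(X)); bestR <- rep(Inf, nrow(X))
    bestI <- rep(NA_integer_, nrow(X))
    for (j in seq_len(m)) {       # iterate candidates; pixels vectorized
      if (ss[j] == 0) next
      Xd <- sweep(X, 2L, water_ems[j, ])
      f <- clamp01(Xd %*% D[j, ] / ss[j])[, 1]
      resid <- Xd - outer(f, D[j, ])
      r <- sqrt(rowMeans(resid^2))
      upd <- r < bestR              # strict <: ties keep the lower index
      bestF[upd] <- f[upd]; bestR[upd] <- r[upd]; bestI[upd] <- j
    }
    frac[kelp_px] <- bestF
    rmse[kelp_px] <- bestR
    sel[kelp_px] <- bestI
  }
  list(fraction = frac, rmse = rmse, selected = sel)
}

#' Convert fractional cover to canopy area
#'
#' Multiplies each fractional value by the pixel footprint area; with the
#' default 30 m pixels a fully covered pixel converts to 900 m^2. Missing
#' fractions propagate.
#'
#' @param fraction numeric matrix (or vector) of fractions in `[0, 1]`.
#' @param pixel_area pixel footprint in m^2 (default 900).
#' @return Canopy area in m^2, same shape as `fraction`.
#' @export
fraction_to_area <- function(fraction, pixel_area = 900) {
  if (!is.numeric(pixel_area) || length(pixel_area) != 1L || pixel_area <= 0)
    stop("pixel_area must be a positive scalar")
  if (any(fraction < 0 | fraction > 1, na.rm = TRUE))
    stop("fractions must lie in [0, 1]")
  fraction * pixel_area
}
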