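# Shared fixtures built in code: a small coastal domain, a fixed spectral
# library, and convenience constructors for hand-made scenes.

clamp01 <- function(x) pmin(pmax(x, 0), 1)

tiny_domain <- function(nrow = 20L, ncol = 20L) {
  scene_domain(nrow = nrow, ncol = ncol, land_cols = 1:2,
               intertidal_cols = 3L,
               habitat_cols = seq.int(min(8L, ncol), min(18L, ncol)),
               seed = 101L)
}

fixed_library <- function() generate_spectral_library(42L)

# Scene with bands set directly (for masking/index tests); all-clear QA.
manual_scene <- function(bands, tide_height = 0,
                         sensor_generation = "TM/ETM+") {
  stopifnot(length(dim(bands)) == 3L, dim(bands)[3] == 6L)
  dimnames(bands) <- list(NULL, NULL, kelp_bands())
  structure(list(bands = bands, qa = matrix(1L, dim(bands)[1], dim(bands)[2]),
                 acquired = as.Date("2000-07-01"),
                 sensor_generation = sensor_generation,
                 tide_height = tide_height, pixel_size = 30),
            class = "kelp_scene")
}

# Uniform-class truth over an nr x nc grid.
uniform_truth <- function(nr, nc, class = "seawater", fraction = 0,
                          tide_height = 0) {
  fr <- matrix(ifelse(class == "kelp", fraction, 0), nr, nc)
  scene_truth(fr, matrix(class, nr, nc), tide_height)
}

# Brute-force reference: grid search over f in {0, 1e-4, ..., 1} for each
# candidate endmember, returning the global minimum-RMSE mixture model.
grid_unmix <- function(x, K, W, step = 1e-4) {
  fg <- seq(0, 1, by = step)
  best <- list(rmse = Inf)
  for (j in seq_len(nrow(W))) {
    D <- K - W[j, ]
    if (all(D == 0)) next
    xd <- x - W[j, ]
    R <- sqrt(rowMeans((matrix(xd, length(fg), 4, byrow = TRUE) -
                          outer(fg, D))^2))
    i <- which.min(R)
    if (R[i] < best$rmse)
      best <- list(fraction = fg[i], rmse = R[i], selected_endmember = j)
  }
  best
}

# A small candidate seawater endmember set around the library base spectrum.
water_set <- function(lib, n = 5, seed = 3) {
  set.seed(seed)
  W <- matrix(rep(lib$seawater_base[unmix_bands()], n), n, 4, byrow = TRUE)
  W + matrix(rnorm(n * 4, 0, 0.01), n, 4)
}

# Synthetic normalized spectra in k well-separated blobs.
blob_spectra <- function(k = 3L, per = 30L, seed = 7L) {
  set.seed(seed)
  centers <- matrix(stats::runif(k * 6, 0.2, 3), k, 6)
  centers <- centers[order(centers[, 1]), , drop = FALSE]
  X <- do.call(rbind, lapply(seq_len(k), function(i)
    matrix(rep(centers[i, ], per), per, 6, byrow = TRUE) +
      matrix(stats::rnorm(per * 6, 0, 0.01), per, 6)))
  list(x = X, truth = rep(seq_len(k), each = per))
}
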