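test_that("seasonal statistics match direct recomputation", {
  a1 <- matrix(300, 2, 2); a2 <- matrix(600, 2, 2); a3 <- matrix(900, 2, 2)
  st <- seasonal_pixel_stats(list(a1, a2, a3))
  expect_equal(st$mean[1, 1], 600)
  expect_equal(st$n[1, 1], 3)
  expect_equal(st$stderr[1, 1], sd(c(300, 600, 900)) / sqrt(3))
  # pixel cloudy in all acquisitions -> missing with n = 0
  a1[2, 2] <- a2[2, 2] <- a3[2, 2] <- NA
  st2 <- seasonal_pixel_stats(list(a1, a2, a3))
  expect_true(is.na(st2$mean[2, 2]))
  expect_equal(st2$n[2, 2], 0)
  # single observation: stderr 0
  a2[1, 2] <- a3[1, 2] <- NA
  st3 <- seasonal_pixel_stats(list(a1, a2, a3))
  expect_equal(st3$stderr[1, 2], 0)
  expect_equal(st3$n[1, 2], 1)
  # brute-force oracle on random data with random missingness
  set.seed(5)
  mats <- lapply(1:4, function(i) {
    m <- matrix(runif(36, 0, 900), 6, 6)
    m[runif(36) < 0.3] <- NA
    m
  })
  st4 <- seasonal_pixel_stats(mats)
  for (i in 1:6) for (j in 1:6) {
    v <- vapply(mats, function(m) m[i, j], numeric(1))
    v <- v[!is.na(v)]
    if (length(v) == 0) {
      expect_true(is.na(st4$mean[i, j]))
    } else {
      expect_equal(st4$mean[i, j], mean(v))
      expect_equal(st4$stderr[i, j],
                   if (length(v) == 1) 0 else sd(v) / sqrt(length(v)))
    }
  }
})

test_that("habitat is the union of kelp detections across the series", {
  f0 <- matrix(0, 4, 4)
  expect_false(any(derive_habitat_mask(list(f0, f0))))
  f1 <- f0; f1[2, 3] <- 0.2
  h <- derive_habitat_mask(list(f0, f1, f0))
  expect_identical(which(h), which(f1 > 0))
  set.seed(6)
  fl <- lapply(1:5, function(i) {
    m <- matrix(rbinom(25, 1, 0.2) * runif(25), 5, 5)
    m[runif(25) < 0.2] <- NA
    m
  })
  h2 <- derive_habitat_mask(fl)
  ref <- Reduce(`|`, lapply(fl, function(m) !is.na(m) & m > 0))
  expect_identical(h2, ref)
})

test_that("the 25% cloud rule is strict on the habitat denominator", {
  dom <- tiny_domain(8, 8)
  habitat <- matrix(FALSE, 8, 8); habitat[, 5:8] <- TRUE
  cells <- make_grid_cells(dom, 8)   # one cell covering the grid: 32 habitat px
  px <- cell_pixels(cells[1, ], dom)
  mk_stats <- function(n_unobs) {
    n <- matrix(3, 8, 8)
    hab_idx <- which(habitat)
    n[hab_idx[seq_len(n_unobs)]] <- 0
    mean_area <- matrix(450, 8, 8); mean_area[n == 0] <- NA
    list(mean = mean_area, stderr = matrix(0, 8, 8), n = n)
  }
  # 8/32 = 25% exactly unobserved: NOT missing
  agg25 <- aggregate_cell_quarter(mk_stats(8), px, habitat)
  expect_false(agg25$missing)
  expect_equal(agg25$area_m2, 450 * 24)
  # 9/32 > 25%: missing
  agg26 <- aggregate_cell_quarter(mk_stats(9), px, habitat)
  expect_true(agg26$missing)
  expect_true(is.na(agg26$area_m2))
  # simple sum: two kelp pixels of 450 each
  st <- list(mean = matrix(0, 8, 8), stderr = matrix(0, 8, 8),
             n = matrix(2, 8, 8))
  st$mean[which(habitat)[1:2]] <- 450
  expect_equal(aggregate_cell_quarter(st, px, habitat)$area_m2, 900)
})

test_that("habitat thresholds exclude cells strictly below the cutoff", {
  dom <- tiny_domain(20, 20)
  cells <- make_grid_cells(dom, 10)  # 4 cells of 100 px
  habitat <- matrix(FALSE, 20, 20)
  habitat[1:10, 1:10][seq_len(49)] <- TRUE    # cell 1: 49
  habitat[1:10, 11:20][seq_len(50)] <- TRUE   # cell 2: 50 (boundary)
  habitat[11:20, 1:10][seq_len(80)] <- TRUE   # cell 3: 80
  kept <- filter_cells_by_habitat(cells, habitat, dom, threshold = 50)
  expect_setequal(kept$id, c("cell_01_02", "cell_02_01"))
  expect_equal(sort(unname(attr(kept, "habitat_counts"))), c(0, 49, 50, 80))
  # brute-force filter oracle at a different threshold
  kept2 <- filter_cells_by_habitat(cells, habitat, dom, threshold = 49)
  counts <- attr(kept2, "habitat_counts")
  expect_setequal(kept2$id, names(counts)[counts >= 49])
})

test_that("annual maxima tolerate one missing quarter but not two", {
  q <- data.frame(year = 2000, quarter = 1:4,
                  area_m2 = c(100, 400, 200, 150), missing = FALSE)
  expect_equal(annual_max(q)$area_m2, 400)
  q$area_m2[2:3] <- NA; q$missing[2:3] <- TRUE
  a2 <- annual_max(q)
  expect_true(a2$missing)
  expect_true(is.na(a2$area_m2))
  q$missing[2] <- FALSE; q$area_m2[2] <- NA  # NA value counts as missing too
  expect_true(annual_max(q)$missing)
  q3 <- data.frame(year = 2000, quarter = 1:4,
                   area_m2 = c(100, NA, 200, 150),
                   missing = c(FALSE, TRUE, FALSE, FALSE))
  a3 <- annual_max(q3)
  expect_false(a3$missing)
  expect_equal(a3$area_m2, 200)
  # annual max dominates every non-missing quarterly value
  set.seed(7)
  qr <- data.frame(year = rep(2001:2005, each = 4), quarter = 1:4,
                   area_m2 = runif(20, 0, 1000), missing = FALSE)
  am <- annual_max(qr)
  for (y in 2001:2005)
    expect_true(all(qr$area_m2[qr$year == y] <= am$area_m2[am$year == y]))
})

test_that("regional sums follow the strict majority missing rule", {
  mk <- function(nm) data.frame(cell_id = paste0("c", seq_along(nm)),
                                year = 2000,
                                area_m2 = ifelse(nm >= 2, NA, seq_along(nm)),
                                n_missing_quarters = nm)
  # 4 cells, values 1..4 (in km^2 scale terms): sum
  r <- regional_annual(mk(c(0, 0, 0, 0)))
  expect_equal(r$area_m2, 10)
  # 3 of 4 cells missing > 1 quarter: regional year missing
  expect_true(regional_annual(mk(c(2, 3, 2, 0)))$missing)
  # exactly 2 of 4: not more than half, so NOT missing
  r2 <- regional_annual(mk(c(2, 2, 0, 0)))
  expect_false(r2$missing)
  expect_equal(r2$area_m2, 3 + 4)  # missing cells contribute 0 by default
  # strict propagation variant
  expect_true(regional_annual(mk(c(2, 2, 0, 0)), strict = TRUE)$missing)
  empty <- data.frame(cell_id = character(0), year = integer(0),
                      area_m2 = numeric(0), n_missing_quarters = integer(0))
  expect_error(regional_annual(empty), "empty region")
})

test_that("cell aggregation equals a naive per-pixel double loop", {
  set.seed(8)
  for (rep in 1:20) {
    nr <- sample(6:12, 1); nc <- sample(6:12, 1)
    cpx <- sample(2:4, 1)
    dom <- scene_domain(nrow = nr, ncol = nc, land_cols = integer(0),
                        intertidal_cols = integer(0),
                        habitat_cols = seq_len(nc), seed = rep)
    cells <- make_grid_cells(dom, cpx)
    habitat <- matrix(runif(nr * nc) < 0.7, nr, nc)
    n <- matrix(sample(0:3, nr * nc, replace = TRUE), nr, nc)
    mean_area <- matrix(runif(nr * nc, 0, 900), nr, nc)
    mean_area[n == 0] <- NA
    st <- list(mean = mean_area, stderr = matrix(0, nr, nc), n = n)
    ci <- sample(nrow(cells), 1)
    cell <- cells[ci, ]
    agg <- aggregate_cell_quarter(st, cell_pixels(cell, dom), habitat)
    # naive loop over all pixels, testing rectangle membership by center
    tot <- 0; n_hab <- 0; n_unobs <- 0
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      cx <- dom$x0 + (j - 0.5) * dom$pixel_size
      cy <- dom$y0 - (i - 0.5) * dom$pixel_size
      if (cx >= cell$x0 && cx < cell$x1 && cy >= cell$y0 && cy < cell$y1 &&
          habitat[i, j]) {
        n_hab <- n_hab + 1
        if (n[i, j] == 0) n_unobs <- n_unobs + 1
        else tot <- tot + mean_area[i, j]
      }
    }
    if (n_hab == 0) {
      expect_equal(agg$area_m2, 0)
    } else if (n_unobs / n_hab > 0.25) {
      expect_true(agg$missing)
    } else {
      expect_false(agg$missing)
      expect_equal(agg$area_m2, tot)
    }
  }
})

test_that("cells tile the raster disjointly under the half-open rule", {
  dom <- tiny_domain(12, 12)
  cells <- make_grid_cells(dom, 6)
  all_px <- sort(unlist(lapply(seq_len(nrow(cells)), function(i)
    cell_pixels(cells[i, ], dom))))
  expect_identical(all_px, seq_len(12L * 12L))  # every pixel exactly once
})
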