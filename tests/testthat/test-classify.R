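test_that("band normalization is exact, scale-invariant and idempotent", {
  expect_equal(normalize_bands(rep(0.1, 6)), rep(1, 6))
  x <- c(0.06, 0.04, 0.02, 0.20, 0.04, 0.00)
  expect_equal(normalize_bands(x), x / 0.06)
  expect_equal(normalize_bands(3 * x), normalize_bands(x))
  expect_equal(normalize_bands(normalize_bands(x)), normalize_bands(x))
  expect_error(normalize_bands(rep(0, 6)), "all-zero")
  # matrix form agrees with row-wise vector form
  set.seed(4)
  X <- matrix(runif(60, 0.01, 0.5), 10, 6)
  expect_equal(normalize_bands(X)[3, ], normalize_bands(X[3, ]))
  expect_true(all(abs(rowMeans(normalize_bands(X)) - 1) < 1e-12))
})

test_that("k-means recovers well-separated blobs up to label permutation", {
  bl <- blob_spectra(k = 3, per = 40)
  km <- cluster_training_spectra(bl$x, k = 3, seed = 1)
  # every truth blob maps to exactly one cluster
  tab <- table(bl$truth, km$cluster)
  expect_true(all(rowSums(tab > 0) == 1))
  expect_true(all(colSums(tab > 0) == 1))
  # determinism and duplicate handling
  km2 <- cluster_training_spectra(bl$x, k = 3, seed = 1)
  expect_identical(km$cluster, km2$cluster)
  dup <- which(duplicated(bl$x) | duplicated(bl$x, fromLast = TRUE))
  Xd <- rbind(bl$x, bl$x[1, , drop = FALSE])
  kmd <- cluster_training_spectra(Xd, k = 3, seed = 2)
  expect_equal(kmd$cluster[1], kmd$cluster[nrow(Xd)])
  expect_error(cluster_training_spectra(bl$x[1:10, ], k = 15), "at least k")
})

test_that("k-means assignment is a nearest-centroid fixed point", {
  bl <- blob_spectra(k = 4, per = 25, seed = 9)
  km <- cluster_training_spectra(bl$x, k = 4, seed = 3)
  d2 <- vapply(seq_len(4), function(j)
    rowSums(sweep(bl$x, 2, km$centers[j, ])^2), numeric(nrow(bl$x)))
  expect_equal(unname(km$cluster), unname(apply(d2, 1, which.min)))
})

test_that("cluster class assignment follows the majority truth class", {
  labels <- c(1, 1, 1, 2, 2, 2)
  truth <- c("kelp", "kelp", "kelp", "seawater", "seawater", "seawater")
  expect_equal(assign_cluster_classes(labels, truth), truth)
  mixed <- c("kelp", "kelp", "seawater", "seawater", "seawater", "seawater")
  got <- assign_cluster_classes(labels, mixed)
  expect_equal(got[1:3], rep("kelp", 3))      # majority within cluster 1
  expect_equal(got[4:6], rep("seawater", 3))
  expect_error(assign_cluster_classes(labels, character(0)), "empty")
  expect_error(assign_cluster_classes(labels, c(`1` = "kelp")), "without")
  named <- assign_cluster_classes(labels, c(`1` = "kelp", `2` = "land"))
  expect_equal(named, c(rep("kelp", 3), rep("land", 3)))
})

test_that("an NIR-separable problem is solved by a depth-1 tree", {
  set.seed(6)
  n <- 60
  kelp <- cbind(matrix(runif(n * 3, 0.2, 0.6), n, 3),
                runif(n, 2.5, 4), matrix(runif(n * 2, 0.1, 0.4), n, 2))
  sea <- cbind(matrix(runif(n * 3, 0.8, 1.6), n, 3),
               runif(n, 0.0, 0.4), matrix(runif(n * 2, 0.1, 0.4), n, 2))
  X <- rbind(kelp, sea)
  cls <- rep(c("kelp", "seawater"), each = n)
  cf <- train_decision_tree(X, cls, "TM/ETM+", max_depth = 1)
  expect_equal(cf$training_accuracy, 1)
  # exhaustive split-search oracle: some single-band threshold separates
  sep <- any(vapply(1:6, function(b)
    max(X[cls == "kelp", b]) < min(X[cls != "kelp", b]) ||
      min(X[cls == "kelp", b]) > max(X[cls != "kelp", b]), logical(1)))
  expect_true(sep)
})

test_that("conflicting labels bound accuracy at the majority fraction", {
  X <- matrix(rep(c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5), 10), 10, 6, byrow = TRUE)
  cls <- c(rep("kelp", 7), rep("seawater", 3))
  cf <- train_decision_tree(X, cls, "OLI")
  expect_equal(cf$training_accuracy, 0.7)
  expect_error(train_decision_tree(X, rep("kelp", 10), "OLI"), "2 classes")
})

test_that("sensor generations use independent classifiers", {
  bl <- blob_spectra(k = 2, per = 20, seed = 5)
  cls <- ifelse(bl$truth == 1, "kelp", "seawater")
  c_tm <- train_decision_tree(bl$x, cls, "TM/ETM+")
  c_oli <- train_decision_tree(bl$x, cls, "OLI")
  expect_equal(c_tm$sensor_generation, "TM/ETM+")
  expect_equal(c_oli$sensor_generation, "OLI")
  sc <- manual_scene(array(0.2, c(3, 3, 6)), sensor_generation = "OLI")
  expect_error(classify_scene(sc, c_tm), "does not match")
})

test_that("a noiseless synthetic scene classifies to its truth map", {
  dom <- tiny_domain()
  lib <- fixed_library()
  fr <- 0.6 * dom$fmax
  cm <- matrix("seawater", dom$nrow, dom$ncol)
  cm[, dom$land_cols] <- "land"
  cm[, dom$intertidal_cols] <- "intertidal"
  cm[fr > 0] <- "kelp"
  cm[1:3, 10:12] <- "cloud"; fr[1:3, 10:12] <- 0
  truth <- scene_truth(fr, cm, tide_height = -0.5)
  sc <- generate_scene(truth, lib, noise_sd = 0, seed = 13)
  # training pool sampled from the same truth (automated cluster labeling)
  cls4 <- cm; cls4[cls4 == "intertidal"] <- "land"
  X <- normalize_bands(matrix(sc$bands, length(cm), 6))
  km <- cluster_training_spectra(X, k = 15, seed = 2)
  lab <- assign_cluster_classes(km$cluster, as.vector(cls4))
  cf <- train_decision_tree(X, lab, "TM/ETM+")
  # masked pixels carry the mask class; unmasked pixels must match truth
  cmask <- cloud_mask_from_qa(sc$qa)
  land <- land_mask_from_dem(dom$dem)
  pred <- classify_scene(sc, cf, cloud_mask = cmask, land_mask = land)
  expect_true(all(pred[cmask] == "cloud"))
  expect_true(all(pred[land] == "land"))
  unmasked <- !(cmask | land)
  expect_gte(mean(pred[unmasked] == cls4[unmasked]), 0.99)
})
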