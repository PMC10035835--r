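# Band-normalized decision-tree pixel classification.
#
# Spectra are brightness-normalized (each band divided by the 6-band mean),
# grouped by k-means to build a training set, labeled by cluster, and fed to
# a CART decision tree with one independent classifier per sensor generation.

#' Brightness-normalize spectra
#'
#' Divides each of the six band values by their mean, so the normalized
#' spectrum has mean exactly 1. Normalization is invariant to overall
#' brightness scaling (sun glint, haze) and idempotent. The exact formula is
#' a package choice: any positive rescaling of the input maps to the same
#' output.
#'
#' @param x numeric vector of 6 reflectances, or a matrix with 6 columns
#'   (one spectrum per row).
#' @return Normalized spectrum (same shape as input).
#' @export
normalize_bands <- function(x) {
  if (is.null(dim(x))) {
    stopifnot(length(x) == 6L)
    m <- mean(x)
    if (!is.finite(m) || m <= 0) stop("cannot normalize all-zero spectrum")
    return(x / m)
  }
  stopifnot(ncol(x) == 6L)
  m <- rowMeans(x)
  if (any(!is.finite(m) | m <= 0))
    stop("cannot normalize all-zero spectrum")
  x / m
}

#' Cluster training spectra with k-means
#'
#' Groups normalized spectra into `k` clusters (Euclidean distance) as the
#' unsupervised seeding step of classifier training. Runs `nstart` seeded
#' restarts and keeps the lowest-inertia solution, so results are
#' deterministic per seed.
#'
#' @param spectra matrix of normalized spectra (rows = spectra, 6 columns).
#' @param k number of clusters (default 15).
#' @param seed integer seed.
#' @param nstart number of random restarts (default 10).
#' @return Object of class `kmeans` (cluster labels in `$cluster`).
#' @export
cluster_training_spectra <- function(spectra, k = 15L, seed = 1L,
                                     nstart = 10L) {
  stopifnot(is.matrix(spectra))
  if (nrow(spectra) < k)
    stop("need at least k = ", k, " spectra, got ", nrow(spectra))
  local_seed(seed,
    stats::kmeans(spectra, centers = k, nstart = nstart, iter.max = 100L))
}

#' Assign classes to clusters
#'
#' Converts cluster labels into per-spectrum class labels. `mapping` is
#' either a named character vector (cluster id -> class), supporting an
#' explicit user-provided assignment, or a character vector of true classes
#' per spectrum, in which case each cluster receives the majority truth class
#' of its members (the automated stand-in for manual cluster labeling).
#'
#' @param labels integer cluster labels per spectrum.
#' @param mapping named cluster->class vector, or per-spectrum truth classes.
#' @return Character vector of class labels per spectrum.
#' @export
assign_cluster_classes <- function(labels, mapping) {
  stopifnot(length(labels) >= 1L)
  if (length(mapping) == 0L) stop("empty class mapping")
  if (!is.null(names(mapping)) && all(nzchar(names(mapping)))) {
    map <- mapping
  } else {
    if (length(mapping) != length(labels))
      stop("per-spectrum truth must match labels length")
    map <- vapply(split(as.character(mapping), labels), function(cls) {
      tab <- sort(table(cls), decreasing = TRUE)
      names(tab)[1]
    }, character(1))
  }
  miss <- setdiff(as.character(unique(labels)), names(map))
  if (length(miss))
    stop("clusters without a class mapping: ", paste(miss, collapse = ", "))
  unname(map[as.character(labels)])
}

#' Train a decision-tree pixel classifier
#'
#' Fits a CART binary decision tree (Gini impurity, axis-aligned splits on
#' the six normalized bands, no pruning) mapping normalized spectra to the
#' four classes kelp canopy / seawater / cloud / land. One classifier is
#' trained per sensor generation; classifiers share no parameters.
#'
#' @param spectra matrix of normalized spectra (6 columns).
#' @param classes character class labels per spectrum (>= 2 distinct).
#' @param sensor_generation `"TM/ETM+"` or `"OLI"`; stored and enforced at
#'   prediction time.
#' @param max_depth maximum tree depth (default 8).
#' @return Object of class `kelp_classifier` with the fitted `rpart` tree,
#'   the sensor generation tag and the training accuracy.
#' @export
train_decision_tree <- function(spectra, classes,
                                sensor_generation = c("TM/ETM+", "OLI"),
                                max_depth = 8L) {
  sensor_generation <- match.arg(sensor_generation)
  stopifnot(is.matrix(spectra), nrow(spectra) == length(classes))
  if (length(unique(classes)) < 2L)
    stop("training data must contain at least 2 classes")
  df <- as.data.frame(spectra)
  colnames(df) <- kelp_bands()
  df$class <- factor(classes)
  fit <- rpart::rpart(class ~ ., data = df, method = "class",
                      parms = list(split = "gini"),
                      control = rpart::rpart.control(
                        cp = 0, minsplit = 2L, minbucket = 1L,
                        maxdepth = max_depth, xval = 0L))
  pred <- predict(fit, df, type = "class")
  structure(list(tree = fit, sensor_generation = sensor_generation,
                 classes = levels(df$class),
                 training_accuracy = mean(pred == df$class)),
            class = "kelp_classifier")
}

#' @export
print.kelp_classifier <- function(x, ...) {
  cat(sprintf("<kelp_classifier> %s; %d classes; training accuracy %.3f\n",
              x$sensor_generation, length(x$classes), x$training_accuracy))
  invisible(x)
}

#' Classify every pixel of a scene
#'
#' Normalizes each unmasked pixel spectrum and routes it through the trained
#' decision tree. Masked pixels carry their mask class directly: cloud-mask
#' pixels become `"cloud"`, land/intertidal-mask pixels become `"land"`.
#' Only pixels classified as kelp proceed to spectral unmixing, which
#' suppresses glint- or turbidity-brightened seawater pixels that would
#' otherwise unmix to spurious positive fractions.
#'
#' @param scene a `kelp_scene`.
#' @param classifier a [train_decision_tree()] result whose sensor
#'   generation matches the scene's.
#' @param cloud_mask,land_mask optional logical masks.
#' @return Character matrix of class labels.
#' @export
classify_scene <- function(scene, classifier, cloud_mask = NULL,
                           land_mask = NULL) {
  stopifnot(inherits(scene, "kelp_scene"),
            inherits(classifier, "kelp_classifier"))
  if (!identical(scene$sensor_generation, classifier$sensor_generation))
    stop("classifier generation (", classifier$sensor_generation,
         ") does not match scene (", scene$sensor_generation, ")")
  nr <- dim(scene$bands)[1]; nc <- dim(scene$bands)[2]
  X <- matrix(scene$bands, nr * nc, 6L)
  colnames(X) <- kelp_bands()
  masked <- rep(FALSE, nr * nc)
  out <- matrix(NA_character_, nr, nc)
  if (!is.null(cloud_mask)) { out[cloud_mask] <- "cloud"; masked <- masked | as.vector(cloud_mask) }
  if (!is.null(land_mask))  { out[land_mask & is.na(out)] <- "land"
                              masked <- masked | as.vector(land_mask) }
  todo <- which(!masked)
  if (length(todo)) {
    Xn <- normalize_bands(X[todo, , drop = FALSE])
    pred <- predict(classifier$tree, as.data.frame(Xn), type = "class")
    out[todo] <- as.character(pred)
  }
  out
}
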