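#' Ordered behavior class set for a plate format
#'
#' 24-well recordings support five classes; in 96-well plates scoots and
#' R-turns cannot be told apart reliably (fish follow the curved wall), so
#' they merge into a single "movement" class, giving four. The order is fixed
#' and load-bearing: majority-vote ties are broken toward the earlier label,
#' so the least eventful call (stationary) wins ties.
#'
#' @param plate_format 24 or 96.
#' @return character vector of ordered class labels.
#' @export
class_set <- function(plate_format) {
  if (plate_format == 24)
    c("stationary", "scoot", "turn", "AsLB", "VsLB")
  else if (plate_format == 96)
    c("stationary", "movement", "AsLB", "VsLB")
  else stop("format error: plate_format must be 24 or 96")
}

#' Stratified train/test split
#'
#' Splits example indices 90/10 (by default) within each class, so both
#' subsets keep the class proportions and no class ends up absent from the
#' test set at small n. Deterministic for a fixed seed.
#'
#' @param labels character or factor vector of class labels.
#' @param train_frac fraction of each class assigned to training; default 0.9.
#' @param seed RNG seed.
#' @return list with integer index vectors \code{train} and \code{test}.
#' @export
split_dataset <- function(labels, train_frac = 0.9, seed = 1) {
  labels <- as.character(labels)
  cnt <- table(labels)
  if (any(cnt < 2))
    stop("stratification error: class '", names(cnt)[cnt < 2][1],
         "' has fewer than 2 examples")
  set.seed(seed)
  train <- integer(0)
  for (cl in names(cnt)) {
    idx <- which(labels == cl)
    n_tr <- max(1L, min(length(idx) - 1L, round(train_frac * length(idx))))
    train <- c(train, sort(sample(idx, n_tr)))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

#' Train a behavior classifier (PCA + random forest)
#'
#' Fits the deployable classifier: the training feature vectors (already
#' normalized with the dataset scalars) are projected by a PCA fit on the
#' training data only — centered, not whitened, keeping the smallest number
#' of components that explains at least \code{pca_var} (default 95%) of the
#' training variance — and a random forest is fit on the projected features.
#' The returned object is self-contained for inference: it carries the
#' normalization scalars, the PCA center and rotation, the forest, the
#' ordered class set and the flattening-order descriptor.
#'
#' @param features a \code{feature_matrix} (see [featurize()]) or a bare
#'   numeric matrix of normalized feature vectors (training rows only).
#' @param labels class label per row, each in \code{classes}.
#' @param classes ordered class labels, e.g. [class_set()] of the plate
#'   format. Defaults to the feature matrix's plate format.
#' @param pca_var minimum fraction of training variance retained; default
#'   0.95.
#' @param pca_seed RNG seed recorded for the PCA stage (the exact
#'   eigendecomposition used here is deterministic; the seed is kept for
#'   provenance and to mirror pipelines whose randomized PCA solvers need
#'   one); default 2023.
#' @param rf_seed seed for the forest's bootstrap/feature sampling.
#' @param ntree,mtry,min_split forest hyperparameters (see [rf_fit()]).
#' @return object of class \code{behavior_classifier}.
#' @export
train_classifier <- function(features, labels, classes = NULL,
                             pca_var = 0.95, pca_seed = 2023, rf_seed = 1,
                             ntree = 100, mtry = NULL, min_split = 2) {
  if (inherits(features, "feature_matrix")) {
    x <- features$vectors
    stats <- list(norm_max = features$norm_max, norm_mean = features$norm_mean)
    W <- features$W
    if (is.null(classes)) classes <- class_set(features$plate_format)
    plate <- features$plate_format
  } else {
    x <- as.matrix(features)
    stats <- list(norm_max = 1, norm_mean = 0)
    W <- ncol(x) / 16
    plate <- NA
    if (is.null(classes)) classes <- sort(unique(as.character(labels)))
  }
  labels <- as.character(labels)
  if (!all(labels %in% classes))
    stop("unknown label(s): ",
         paste(setdiff(labels, classes), collapse = ", "))
  if (nrow(x) != length(labels))
    stop("features and labels disagree: ", nrow(x), " vs ", length(labels))
  sds <- apply(x, 2, stats::sd)
  if (all(sds == 0)) stop("PCA error: all features are constant")

  set.seed(pca_seed)
  pca <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  evar <- pca$sdev^2 / sum(pca$sdev^2)
  ncomp <- which(cumsum(evar) >= pca_var)[1]
  rotation <- pca$rotation[, seq_len(ncomp), drop = FALSE]
  proj <- pca$x[, seq_len(ncomp), drop = FALSE]

  y <- factor(labels, levels = classes)
  forest <- rf_fit(proj, y, ntree = ntree, mtry = mtry,
                   min_split = min_split, seed = rf_seed)

  structure(list(
    classes = classes, plate_format = plate, stats = stats, W = W,
    pca = list(center = pca$center, rotation = rotation,
               explained_var = evar[seq_len(ncomp)],
               retained_var = sum(evar[seq_len(ncomp)]),
               var_target = pca_var, seed = pca_seed),
    forest = forest,
    flatten_order = "timepoint-major, then keypoint, then (x, y)",
    provenance = list(n_train = as.list(table(labels)),
                      trained = format(Sys.time(), "%Y-%m-%d"),
                      rf_seed = rf_seed, ntree = forest$ntree,
                      version = as.character(utils::packageVersion("fishbout")))),
    class = "behavior_classifier")
}

#' @export
print.behavior_classifier <- function(x, ...) {
  cat(sprintf("<behavior_classifier> %s-class model (%s)\n",
              length(x$classes), paste(x$classes, collapse = ", ")))
  cat(sprintf("  PCA: %d components, %.1f%% variance retained (target %.0f%%)\n",
              ncol(x$pca$rotation), 100 * x$pca$retained_var,
              100 * x$pca$var_target))
  cat(sprintf("  forest: %d trees, mtry %d; trained on %d examples\n",
              x$forest$ntree, x$forest$mtry,
              sum(unlist(x$provenance$n_train))))
  invisible(x)
}

#' @export
summary.behavior_classifier <- function(object, ...) {
  print(object)
  cat("  training examples per class:\n")
  for (cl in names(object$provenance$n_train))
    cat(sprintf("    %-10s %d\n", cl, object$provenance$n_train[[cl]]))
  cat(sprintf("  normalization: norm_max = %.6g, norm_mean = %.6g\n",
              object$stats$norm_max, object$stats$norm_mean))
  cat("  flattening order:", object$flatten_order, "\n")
  invisible(object)
}

## Coerce predict() input to a normalized feature matrix using the
## classifier's frozen stats; returns list(vectors, usable).
.classifier_features <- function(object, newdata) {
  if (inherits(newdata, "behavior_windows")) {
    if (!newdata$aligned) newdata <- egocentric_align(newdata)
    fm <- featurize(newdata, stats = object$stats)
    list(vectors = fm$vectors, usable = fm$usable,
         starts = fm$window_starts)
  } else if (inherits(newdata, "feature_matrix")) {
    list(vectors = newdata$vectors, usable = newdata$usable,
         starts = newdata$window_starts)
  } else {
    x <- as.matrix(newdata)
    list(vectors = x, usable = rep(TRUE, nrow(x)), starts = NULL)
  }
}

#' Predict behavior labels for windows
#'
#' Applies the frozen normalization, the saved PCA projection and the forest.
#' Unusable windows (masked keypoints, degenerate pose) are labeled
#' \code{"unknown"} with all-NA probabilities.
#'
#' @param object a \code{behavior_classifier}.
#' @param newdata \code{behavior_windows}, a \code{feature_matrix} produced
#'   with this classifier's stats, or a bare matrix of normalized vectors.
#' @param ... unused.
#' @return list with \code{labels} (character, \code{"unknown"} allowed),
#'   \code{prob} (n x K matrix, rows sum to 1 for usable windows) and
#'   \code{window_starts} (if the input carried them).
#' @export
predict.behavior_classifier <- function(object, newdata, ...) {
  inp <- .classifier_features(object, newdata)
  expected <- length(object$pca$center)
  if (ncol(inp$vectors) != expected)
    stop("shape error: expected feature vectors of length ", expected,
         ", got ", ncol(inp$vectors))
  n <- nrow(inp$vectors)
  labels <- rep("unknown", n)
  prob <- matrix(NA_real_, n, length(object$classes),
                 dimnames = list(NULL, object$classes))
  use <- which(inp$usable)
  if (length(use)) {
    xc <- sweep(inp$vectors[use, , drop = FALSE], 2, object$pca$center)
    proj <- xc %*% object$pca$rotation
    pr <- predict(object$forest, proj, type = "prob")
    labels[use] <- as.character(predict(object$forest, proj))
    prob[use, ] <- pr
  }
  list(labels = labels, prob = prob, window_starts = inp$starts)
}

#' Evaluate a classifier on held-out data
#'
#' @param object a \code{behavior_classifier}.
#' @param features held-out feature input (same forms as
#'   [predict.behavior_classifier()]); must be disjoint from training.
#' @param labels true labels.
#' @return list with \code{confusion} (true x predicted counts),
#'   \code{confusion_prop} (row-normalized), \code{f1} per class (NA for a
#'   class absent from the test set), and \code{macro_f1}.
#' @export
evaluate_classifier <- function(object, features, labels) {
  pred <- predict(object, features)$labels
  labels <- as.character(labels)
  lv <- object$classes
  confusion <- table(factor(labels, lv), factor(pred, c(lv, "unknown")))[, lv,
                                                                  drop = FALSE]
  confusion <- unclass(confusion)
  rs <- rowSums(confusion)
  confusion_prop <- sweep(confusion, 1, ifelse(rs == 0, 1, rs), "/")
  f1 <- vapply(lv, function(cl) {
    tp <- confusion[cl, cl]
    fp <- sum(confusion[, cl]) - tp
    fn <- sum(confusion[cl, ]) - tp
    if (tp + fn == 0) return(NA_real_)   # class absent from test set
    if (2 * tp + fp + fn == 0) return(0)
    2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  list(confusion = confusion, confusion_prop = confusion_prop, f1 = f1,
       macro_f1 = mean(f1, na.rm = TRUE))
}

#' Save / load a trained classifier
#'
#' The classifier is an ordinary R object; persistence is via RDS.
#'
#' @param object a \code{behavior_classifier}.
#' @param path file path.
#' @return \code{path} (save) or the classifier (load).
#' @export
save_classifier <- function(object, path) {
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "behavior_classifier"))
    stop("format error: ", path, " does not contain a behavior_classifier")
  obj
}
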