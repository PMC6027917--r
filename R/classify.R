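CLASSIFIER_FEATURES <- c("area_um2", "perimeter_um", "form_factor",
                         "eccentricity", "mean_opd_nm", "integrated_opd")

#' Train a phenotype classifier on labeled cell records
#'
#' Fits either a random forest (100 trees by default) or a k-nearest
#' neighbors model (k = 5, on standardized features) mapping the
#' morphological/OPD feature set to phenotype labels. Training labels
#' normally come from simulator truth. The reported held-out accuracy is the
#' out-of-bag estimate for the random forest and leave-one-out
#' cross-validation for kNN.
#'
#' @param records A [extract_cell_features()] data frame.
#' @param truth_labels Character/factor vector of phenotypes, one per record.
#' @param algorithm `"random_forest"` or `"k_neighbors"`.
#' @param seed Integer seed; training is deterministic given it.
#' @param ntree Random forest size.
#' @param k Neighbor count for kNN.
#' @return An object of class `cell_classifier` with the fitted state, the
#'   fixed feature list, and `holdout_accuracy`.
#' @export
train_cell_classifier <- function(records, truth_labels,
                                  algorithm = c("random_forest",
                                                "k_neighbors"),
                                  seed = 1L, ntree = 100L, k = 5L) {
  algorithm <- match.arg(algorithm)
  if (nrow(records) != length(truth_labels)) {
    stop("one label per record required")
  }
  y <- factor(as.character(truth_labels))
  if (nlevels(y) < 2L) stop("training set must contain >= 2 classes")
  X <- as.matrix(records[, CLASSIFIER_FEATURES])
  if (anyNA(X)) stop("features contain NA")

  local_seed(seed, {
    if (algorithm == "random_forest") {
      fit <- randomForest::randomForest(x = X, y = y, ntree = ntree)
      acc <- 1 - mean(fit$predicted != y)
      list(fit = fit, acc = acc, center = NULL, scale = NULL)
    } else {
      ctr <- colMeans(X)
      scl <- apply(X, 2, stats::sd)
      scl[scl == 0] <- 1
      Xs <- scale(X, ctr, scl)
      cv <- class::knn.cv(Xs, y, k = k)
      acc <- mean(cv == y)
      list(fit = list(X = Xs, y = y, k = k), acc = acc,
           center = ctr, scale = scl)
    }
  }) -> trained

  structure(
    list(algorithm = algorithm, fit = trained$fit,
         features = CLASSIFIER_FEATURES,
         center = trained$center, scale = trained$scale,
         holdout_accuracy = trained$acc,
         levels = levels(y), seed = as.integer(seed),
         hyperparameters = list(ntree = ntree, k = k)),
    class = "cell_classifier"
  )
}

#' Apply a trained phenotype classifier
#'
#' @param model A [train_cell_classifier()] result.
#' @param records Cell records with the model's feature columns.
#' @return List with `records` (phenotype column filled; every record gets
#'   exactly one phenotype) and `counts`, the per-phenotype tally.
#' @export
apply_cell_classifier <- function(model, records) {
  stopifnot(inherits(model, "cell_classifier"))
  if (!all(model$features %in% names(records))) {
    stop("records lack the model's feature columns")
  }
  if (nrow(records) == 0) {
    return(list(records = records,
                counts = stats::setNames(integer(length(model$levels)),
                                         model$levels)))
  }
  X <- as.matrix(records[, model$features])
  pred <- if (model$algorithm == "random_forest") {
    as.character(predict(model$fit, X))
  } else {
    Xs <- scale(X, model$center, model$scale)
    as.character(class::knn(model$fit$X, Xs, model$fit$y, k = model$fit$k))
  }
  records$phenotype <- pred
  counts <- table(factor(pred, levels = model$levels))
  list(records = records, counts = as.integer(counts) |>
         stats::setNames(model$levels))
}

#' Save and load a trained classifier
#'
#' Serializes the model together with a format version and its training
#' configuration (algorithm, hyperparameters, feature list, seed), so a
#' reloaded model refuses to run if the on-disk format has drifted.
#'
#' @param model A `cell_classifier`.
#' @param path File path (RDS).
#' @return `save_cell_classifier` returns `path` invisibly;
#'   `load_cell_classifier` returns the `cell_classifier`.
#' @export
save_cell_classifier <- function(model, path) {
  stopifnot(inherits(model, "cell_classifier"))
  saveRDS(list(format_version = 1L, model = model), path)
  invisible(path)
}

#' @rdname save_cell_classifier
#' @export
load_cell_classifier <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format_version, 1L)) {
    stop("unsupported classifier file version: ", obj$format_version)
  }
  stopifnot(inherits(obj$model, "cell_classifier"))
  obj$model
}

#' @export
print.cell_classifier <- function(x, ...) {
  cat(sprintf("cell_classifier: %s, held-out accuracy %.3f (classes: %s)\n",
              x$algorithm, x$holdout_accuracy,
              paste(x$levels, collapse = ", ")))
  invisible(x)
}
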