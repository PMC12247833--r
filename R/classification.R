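# Marker-positive / cancer-cell classification and method agreement.

#' Classify cells by a (translated) intensity threshold
#'
#' Labels a cell positive when its marker intensity strictly exceeds the
#' applicable threshold (values exactly at the threshold are negative).
#' With a [ThresholdMap-class] the per-image translated threshold is
#' used (an image absent from the map is an error); a single numeric
#' applies one fixed threshold to all cells. Compose two calls for joint
#' gating (e.g. a pan-cytokeratin threshold to select cancer cells, then
#' the analysis-marker threshold).
#'
#' @param table Cell table; needs `image_id` when `thresholds` is a
#'   [ThresholdMap-class].
#' @param thresholds A [ThresholdMap-class] or a single numeric
#'   threshold.
#' @param marker Intensity column; defaults to the map's marker.
#' @param label_column Name of the label column added (default
#'   `"class"`).
#' @param positive,negative Label values (defaults `"positive"`,
#'   `"negative"`).
#' @return The table with `label_column` added (character).
#' @export
classifyByThreshold <- function(table, thresholds, marker = NULL,
                                label_column = "class",
                                positive = "positive", negative = "negative") {
  if (is(thresholds, "ThresholdMap")) {
    if (is.null(marker)) marker <- thresholds@marker
    if (!"image_id" %in% names(table))
      stop("table needs an 'image_id' column to apply a ThresholdMap")
    ids <- unique(table$image_id)
    missing <- setdiff(ids, names(thresholds@thresholds))
    if (length(missing))
      stop("no translated threshold for image(s): ",
           paste(missing, collapse = ", "))
    thr <- thresholds@thresholds[table$image_id]
  } else if (is.numeric(thresholds) && length(thresholds) == 1) {
    if (is.null(marker)) stop("marker column must be given with a fixed threshold")
    thr <- rep(thresholds, nrow(table))
  } else stop("thresholds must be a ThresholdMap or a single numeric")
  if (!marker %in% names(table))
    stop("marker column '", marker, "' missing from table")
  table[[label_column]] <- ifelse(table[[marker]] > thr, positive, negative)
  table
}

#' Train a random-forest cell classifier on intensity features
#'
#' Deterministic (seeded) random forest over the given intensity feature
#' columns. Requires at least two classes with at least five examples
#' each. Feature columns and class levels are recorded in the model so
#' prediction is self-describing.
#'
#' @param training Cell table subset with a label column.
#' @param feature_columns Character vector of feature column names
#'   (intensity statistics).
#' @param label_column Name of the class label column.
#' @param seed Integer seed.
#' @param ntree Number of trees (default 100).
#' @return An object of class `"rfCellClassifier"` with elements `forest`
#'   (the fitted [randomForest::randomForest]), `features`, `levels`,
#'   `seed`, `ntree`.
#' @export
trainRF <- function(training, feature_columns, label_column, seed = 1,
                    ntree = 100) {
  missing <- setdiff(c(feature_columns, label_column), names(training))
  if (length(missing))
    stop("columns missing from training table: ",
         paste(missing, collapse = ", "))
  y <- factor(training[[label_column]])
  if (nlevels(y) < 2)
    stop("training set has a single class: '", levels(y), "'")
  small <- table(y) < 5
  if (any(small))
    stop("classes with fewer than 5 examples: ",
         paste(names(which(small)), collapse = ", "))
  x <- training[, feature_columns, drop = FALSE]
  if (anyNA(x)) stop("training features contain NA")
  forest <- withSeed(seed,
    randomForest::randomForest(x = x, y = y, ntree = ntree))
  structure(list(forest = forest, features = feature_columns,
                 levels = levels(y), seed = seed, ntree = ntree),
            class = "rfCellClassifier")
}

#' @export
print.rfCellClassifier <- function(x, ...) {
  cat("rfCellClassifier:", x$ntree, "trees,",
      length(x$features), "features, classes:",
      paste(x$levels, collapse = ", "), "\n")
  invisible(x)
}

#' Predict cell classes with a trained random forest
#'
#' @param object An `"rfCellClassifier"` from [trainRF()].
#' @param newdata Cell table containing the model's feature columns.
#' @param ... Ignored.
#' @return Character vector of predicted labels.
#' @export
predict.rfCellClassifier <- function(object, newdata, ...) {
  missing <- setdiff(object$features, names(newdata))
  if (length(missing))
    stop("feature columns missing: ", paste(missing, collapse = ", "))
  as.character(stats::predict(object$forest,
                              newdata[, object$features, drop = FALSE]))
}

#' Agreement between two classifications
#'
#' Cross-tabulates two label vectors over the sorted union of their
#' label alphabets (rows = method A, columns = method B) and reports the
#' percent agreement `100 * trace / total`.
#'
#' @param labels_a,labels_b Equal-length label vectors.
#' @return A [ConfusionSummary-class].
#' @examples
#' s <- agreement(c("+", "+", "-", "-"), c("+", "-", "-", "-"))
#' s@agreementPct  # 75
#' @export
agreement <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors have different lengths")
  if (length(labels_a) == 0) stop("empty label vectors")
  levels <- sort(unique(c(as.character(labels_a), as.character(labels_b))),
                 method = "radix")   # locale-independent order
  fa <- factor(labels_a, levels = levels)
  fb <- factor(labels_b, levels = levels)
  counts <- unclass(table(fa, fb))
  dimnames(counts) <- list(A = levels, B = levels)
  new("ConfusionSummary", labels = levels, counts = counts,
      agreementPct = 100 * sum(diag(counts)) / length(labels_a))
}
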