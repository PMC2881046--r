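# The user-facing model: a hierarchical cosine-NN half-life classifier with
# mRMR + IFS feature optimization per stage, returned as a classed object.

fit_stage <- function(x, labels, paper_mode, stride, base) {
  labels <- droplevels(as.factor(labels))
  if (nrow(x) < 2L || nlevels(labels) < 2L)
    stop("each stage needs >= 2 rows and 2 classes")
  std <- standardize(x)
  codes <- discretize(std$x)
  ranking <- mrmr_rank(codes, labels, base = base)
  curve <- ifs_evaluate(x, labels, ranking, paper_mode = paper_mode,
                        stride = stride)
  opt <- select_optimal(curve)
  list(ranking = ranking, curve = curve, features = opt$features,
       accuracy = opt$accuracy, params = std$params,
       train = x, labels = labels)
}

#' Fit the hierarchical half-life nearest-neighbor classifier
#'
#' Fits the full pipeline on a labeled feature matrix: per stage,
#' standardize, discretize (mean +/- sd three-bin), rank features by mRMR,
#' run incremental feature selection under jackknife cross-validation of the
#' cosine-distance nearest-neighbor rule, and keep the peak feature subset.
#' Three stages are fitted on their own sub-datasets and rankings: the
#' coarse short/medium versus long/extra-long split on all rows, then
#' short versus medium and long versus extra-long within each branch.
#'
#' @param x numeric feature matrix (rows = proteins; typically the 376
#'   assembled components, but any column set works).
#' @param classes fine half-life class per row (factor or character over
#'   short/medium/long/extra_long), or `NULL` to derive from `psi`.
#' @param psi optional numeric PSI values used when `classes` is `NULL`.
#' @param paper_mode reuse global standardization inside the jackknife
#'   instead of per-fold refitting (see [jackknife()]).
#' @param stride IFS evaluation stride (see [ifs_evaluate()]).
#' @param base mutual-information logarithm base (ranking-invariant).
#' @return object of class `halflife_nna` with one fitted sub-model per
#'   stage (`coarse`, `short_medium`, `long_extra_long`), each holding its
#'   mRMR ranking, IFS curve, optimal feature subset, training data, labels
#'   and standardization parameters.
#' @seealso [predict.halflife_nna()], [plot.halflife_nna()]
#' @export
halflife_nna <- function(x, classes = NULL, psi = NULL, paper_mode = FALSE,
                         stride = 1L, base = 2) {
  x <- as.matrix(x)
  if (is.null(classes)) {
    if (is.null(psi)) stop("supply 'classes' or 'psi'")
    classes <- psi_to_class(psi)
  }
  classes <- factor(as.character(classes), levels = HALF_LIFE_LEVELS)
  if (anyNA(classes)) stop("unknown class labels")
  if (length(classes) != nrow(x)) stop("one class per row required")
  coarse <- coarse_class(classes)
  sm <- coarse == "short_medium"
  le <- !sm

  stages <- list(
    coarse = fit_stage(x, coarse, paper_mode, stride, base),
    short_medium = fit_stage(x[sm, , drop = FALSE], classes[sm],
                             paper_mode, stride, base),
    long_extra_long = fit_stage(x[le, , drop = FALSE], classes[le],
                                paper_mode, stride, base))
  structure(list(stages = stages, classes = classes,
                 paper_mode = paper_mode, stride = stride,
                 n = nrow(x), m = ncol(x), call = match.call()),
            class = "halflife_nna")
}

predict_stage <- function(stage, newdata) {
  z <- apply_standardization(newdata, stage$params)
  zt <- apply_standardization(stage$train, stage$params)
  f <- stage$features
  lab <- as.character(stage$labels)
  t(vapply(seq_len(nrow(z)), function(i) {
    p <- nn_predict(z[i, f], zt[, f, drop = FALSE], lab)
    c(label = p$label, index = p$index, distance = p$distance)
  }, c(label = "", index = "", distance = "")))
}

#' Hierarchical half-life prediction
#'
#' Stage 1 assigns the coarse label (short/medium versus long/extra-long);
#' the query is then routed to the matching stage-2 classifier for the fine
#' label, each stage using its own optimal feature subset and
#' standardization.
#'
#' @param object a fitted `halflife_nna` model.
#' @param newdata numeric matrix on the same feature columns as the training
#'   matrix.
#' @param ... unused.
#' @return data.frame with one row per query: `coarse`, `fine`, and per-stage
#'   nearest-neighbor id and distance.
#' @export
predict.halflife_nna <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$m)
    stop(sprintf("newdata has %d columns but the model was fitted on %d",
                 ncol(newdata), object$m))
  s1 <- predict_stage(object$stages$coarse, newdata)
  coarse <- factor(s1[, "label"], levels = COARSE_LEVELS)
  fine <- character(nrow(newdata))
  nn2 <- rep(NA_integer_, nrow(newdata))
  d2 <- rep(NA_real_, nrow(newdata))
  for (branch in COARSE_LEVELS) {
    idx <- which(coarse == branch)
    if (!length(idx)) next
    s2 <- predict_stage(object$stages[[branch]],
                        newdata[idx, , drop = FALSE])
    fine[idx] <- s2[, "label"]
    nn2[idx] <- as.integer(s2[, "index"])
    d2[idx] <- as.numeric(s2[, "distance"])
  }
  data.frame(
    id = rownames(newdata) %||% as.character(seq_len(nrow(newdata))),
    coarse = coarse,
    fine = factor(fine, levels = HALF_LIFE_LEVELS),
    stage1_nn = as.integer(s1[, "index"]),
    stage1_distance = as.numeric(s1[, "distance"]),
    stage2_nn = nn2,
    stage2_distance = d2,
    stringsAsFactors = FALSE)
}

#' @export
print.halflife_nna <- function(x, ...) {
  cat("Hierarchical half-life nearest-neighbor classifier\n")
  cat(sprintf("  training samples: %d, feature space: %d components\n",
              x$n, x$m))
  for (s in names(x$stages)) {
    st <- x$stages[[s]]
    cat(sprintf("  stage %-16s %3d features, jackknife accuracy %.3f\n",
                s, length(st$features), st$accuracy))
  }
  invisible(x)
}

#' @export
summary.halflife_nna <- function(object, ...) {
  out <- data.frame(
    stage = names(object$stages),
    n = vapply(object$stages, function(s) nrow(s$train), integer(1)),
    classes = vapply(object$stages, function(s)
      paste(levels(s$labels), collapse = "/"), ""),
    n_features = vapply(object$stages, function(s)
      length(s$features), integer(1)),
    jackknife_accuracy = vapply(object$stages, function(s)
      s$accuracy, numeric(1)),
    row.names = NULL)
  class(out) <- c("summary.halflife_nna", "data.frame")
  out
}

#' @export
print.summary.halflife_nna <- function(x, ...) {
  cat("Stage-wise IFS-optimized nearest-neighbor classifiers:\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Selected feature subsets of a fitted model
#'
#' @param object a fitted `halflife_nna`.
#' @param ... unused.
#' @return named list of integer feature-index vectors, one per stage, each
#'   in mRMR rank order.
#' @export
coef.halflife_nna <- function(object, ...) {
  lapply(object$stages, `[[`, "features")
}

#' Plot the IFS curves of a fitted model
#'
#' One panel per stage: jackknife accuracy versus number of ranked features,
#' peak marked.
#'
#' @param x a fitted `halflife_nna`.
#' @param ... passed to the per-panel plot.
#' @export
plot.halflife_nna <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(op))
  for (s in names(x$stages))
    plot(x$stages[[s]]$curve, main = s, ...)
  invisible(x)
}

#' Low-level hierarchical prediction from three stage models
#'
#' Routes one standardized-scale query through explicitly supplied stage
#' models. Most users should call [predict.halflife_nna()]; this entry point
#' exists for stage models assembled by hand (e.g. deserialized bundles).
#'
#' @param query numeric feature vector (full feature space, raw scale).
#' @param stage1,stage2a,stage2b stage models: lists with `train`, `labels`,
#'   `features`, `params` as produced inside [halflife_nna()] (stage2a =
#'   short/medium branch, stage2b = long/extra-long branch).
#' @return list with `coarse`, `fine`, and per-stage neighbor info.
#' @export
hierarchical_predict <- function(query, stage1, stage2a, stage2b) {
  for (st in list(stage1, stage2a, stage2b))
    if (!all(c("train", "labels", "features", "params") %in% names(st)))
      stop("each stage model needs train, labels, features and params")
  one <- function(stage) {
    z <- apply_standardization(query, stage$params)
    zt <- apply_standardization(stage$train, stage$params)
    nn_predict(z[stage$features], zt[, stage$features, drop = FALSE],
               as.character(stage$labels))
  }
  p1 <- one(stage1)
  branch <- if (p1$label == "short_medium") stage2a else stage2b
  p2 <- one(branch)
  list(coarse = p1$label, fine = p2$label,
       stage1 = p1, stage2 = p2)
}
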