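# Cosine-distance nearest-neighbor classification and jackknife
# (leave-one-out) evaluation.

#' Cosine-derived distance between two feature vectors
#'
#' `1 - (a . b) / (||a|| ||b||)`, in [0, 2]; 0 for identical directions,
#' 2 for opposite. A zero-norm vector (possible when all selected components
#' are constant in training and standardize to zero) is maximally dissimilar
#' to everything: the distance is defined as 2.
#'
#' @param a,b numeric vectors of equal length.
#' @return numeric scalar in [0, 2].
#' @export
nn_distance <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  if (length(a) == 0L) stop("empty vectors")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(2)
  d <- 1 - sum(a * b) / (na * nb)
  min(max(d, 0), 2)
}

#' Nearest-neighbor prediction for one query
#'
#' Assigns the label of the training row at minimal cosine distance; ties
#' are broken by smallest row index.
#'
#' @param query numeric vector on the same (standardized) scale and feature
#'   subset as `train_x`.
#' @param train_x training matrix (rows = samples).
#' @param train_labels one label per training row.
#' @return list with `label`, `index` (training row), `distance`.
#' @export
nn_predict <- function(query, train_x, train_labels) {
  train_x <- as.matrix(train_x)
  if (nrow(train_x) == 0L) stop("empty training set")
  if (length(train_labels) != nrow(train_x))
    stop("one label per training row required")
  d <- cosine_dist_to(query, train_x)
  i <- which.min(d)
  list(label = train_labels[i], index = i, distance = d[i])
}

# distances are snapped to 12 decimals before argmin so that exact
# geometric ties (e.g. collinear points) resolve by row index irrespective
# of floating-point summation order
snap_dist <- function(d) round(d, 12L)

# distances of one query vector to every row of x
cosine_dist_to <- function(query, x) {
  nq <- sqrt(sum(query^2))
  nr <- sqrt(rowSums(x^2))
  d <- rep(2, nrow(x))
  ok <- nr > 0 & nq > 0
  if (any(ok)) {
    d[ok] <- 1 - as.vector(x[ok, , drop = FALSE] %*% query) / (nr[ok] * nq)
    d[ok] <- pmin(pmax(d[ok], 0), 2)
  }
  snap_dist(d)
}

# full pairwise cosine distance matrix of standardized rows; diagonal NA-safe
cosine_dist_matrix <- function(z) {
  nr <- sqrt(rowSums(z^2))
  g <- tcrossprod(z)
  denom <- outer(nr, nr)
  d <- matrix(2, nrow(z), nrow(z))
  ok <- denom > 0
  d[ok] <- 1 - g[ok] / denom[ok]
  snap_dist(pmin(pmax(d, 0), 2))
}

#' Jackknife (leave-one-out) evaluation of the NN classifier
#'
#' Each row is in turn singled out and predicted from the remaining rows.
#' By default standardization is refitted on each leave-one-out training
#' fold before distances are computed (leak-free). With
#' `paper_mode = TRUE` the standardization fitted once on the full matrix is
#' reused for every fold, mirroring the protocol in which the whole
#' benchmark is standardized up front.
#'
#' @param x raw (unstandardized) numeric matrix, rows = samples, restricted
#'   to the feature subset under evaluation.
#' @param labels one class label per row (>= 2 rows required).
#' @param paper_mode reuse global standardization instead of per-fold refit.
#' @param standardize_cols set `FALSE` if `x` is already on its final scale.
#' @return list with `overall` accuracy, `per_class` named accuracy vector,
#'   `n_correct`, `n`, and the vector of `predicted` labels.
#' @export
jackknife <- function(x, labels, paper_mode = FALSE, standardize_cols = TRUE) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2L) stop("jackknife needs at least 2 rows")
  if (length(labels) != n) stop("one label per row required")
  labels <- as.factor(labels)
  predicted <- character(n)

  if (!standardize_cols || paper_mode) {
    z <- if (standardize_cols) standardize(x)$x else x
    d <- cosine_dist_matrix(z)
    diag(d) <- Inf
    for (i in seq_len(n)) predicted[i] <- as.character(labels[which.min(d[i, ])])
  } else {
    for (i in seq_len(n)) {
      if (n - 1L >= 2L) {
        fit <- standardize(x[-i, , drop = FALSE])
        zt <- fit$x
        q <- apply_standardization(x[i, ], fit$params)
      } else {  # single-row training fold: nothing to standardize on
        zt <- x[-i, , drop = FALSE]
        q <- x[i, ]
      }
      d <- cosine_dist_to(q, zt)
      predicted[i] <- as.character(labels[-i][which.min(d)])
    }
  }
  correct <- predicted == as.character(labels)
  per_class <- vapply(levels(droplevels(labels)), function(cl) {
    idx <- as.character(labels) == cl
    mean(correct[idx])
  }, numeric(1))
  list(overall = mean(correct), per_class = per_class,
       n_correct = sum(correct), n = n, predicted = predicted)
}
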