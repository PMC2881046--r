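# Incremental feature selection: evaluate nested prefixes of the mRMR
# ranking by jackknifed nearest-neighbor accuracy and locate the peak.

ranking_order <- function(ranking) {
  ord <- if (inherits(ranking, "mrmr_ranking")) ranking$feature
         else as.integer(ranking)
  if (length(ord) == 0L) stop("empty ranking")
  if (anyDuplicated(ord)) stop("ranking must not repeat features")
  ord
}

#' Nested feature sets of an mRMR ranking
#'
#' `S_i` is the set of the first `i` ranked features, for `i = 1..m`.
#'
#' @param ranking an `mrmr_ranking` or an integer vector of feature indices
#'   in rank order.
#' @return list of integer vectors with `S_i` at position `i`.
#' @export
build_ifs_sets <- function(ranking) {
  ord <- ranking_order(ranking)
  lapply(seq_along(ord), function(i) ord[seq_len(i)])
}

#' Incremental feature selection curve
#'
#' For each prefix `S_i` of the feature ranking, evaluates the jackknife
#' accuracy of the cosine-distance nearest-neighbor classifier restricted to
#' `S_i`, and records the accuracy curve and its peak (ties resolved to the
#' smallest set size). Labels may be the coarse two-class split or the fine
#' classes of one branch; rows must already be filtered to the relevant
#' sub-dataset.
#'
#' With `stride > 1` only every `stride`-th set size (plus the full set) is
#' evaluated in a first pass, and all sizes within one stride of the
#' provisional peak are then evaluated exactly.
#'
#' @param x raw feature matrix (rows = proteins of the task's sub-dataset).
#' @param labels class labels (>= 2 classes).
#' @param ranking an `mrmr_ranking` or integer vector of feature indices.
#' @param paper_mode reuse the global standardization for every fold instead
#'   of refitting per leave-one-out fold (see [jackknife()]).
#' @param stride evaluate every `stride`-th set size (default 1: all sizes).
#' @return object of class `ifs_curve`: data.frame with columns `size`,
#'   `accuracy` and one `acc_<class>` column per class, with attributes
#'   `peak_size`, `peak_accuracy` and `order`.
#' @export
ifs_evaluate <- function(x, labels, ranking, paper_mode = FALSE, stride = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  labels <- droplevels(as.factor(labels))
  if (n < 2L) stop("IFS evaluation needs at least 2 rows")
  if (nlevels(labels) < 2L) stop("IFS evaluation needs at least 2 classes")
  if (length(labels) != n) stop("one label per row required")
  ord <- ranking_order(ranking)
  if (any(ord < 1L | ord > ncol(x))) stop("ranking indexes outside the matrix")
  m <- length(ord)
  stride <- max(1L, as.integer(stride))

  sizes1 <- sort(unique(c(seq(1L, m, by = stride), m)))
  acc1 <- ifs_accuracies(x, labels, ord, sizes1, paper_mode)
  sizes <- sizes1
  acc <- acc1
  if (stride > 1L) {
    peak <- sizes1[which.max(acc1$overall)]
    refine <- setdiff(seq(max(1L, peak - stride), min(m, peak + stride)), sizes1)
    if (length(refine)) {
      acc2 <- ifs_accuracies(x, labels, ord, refine, paper_mode)
      keep <- order(c(sizes1, refine))
      sizes <- c(sizes1, refine)[keep]
      acc <- list(overall = c(acc1$overall, acc2$overall)[keep],
                  per_class = rbind(acc1$per_class, acc2$per_class)[keep, , drop = FALSE])
    }
  }
  curve <- data.frame(size = sizes, accuracy = acc$overall)
  pc <- acc$per_class
  colnames(pc) <- paste0("acc_", colnames(pc))
  curve <- cbind(curve, pc)
  peak_at <- which.max(curve$accuracy)   # first max -> smallest size
  structure(curve,
            peak_size = curve$size[peak_at],
            peak_accuracy = curve$accuracy[peak_at],
            order = ord,
            class = c("ifs_curve", "data.frame"))
}

# jackknife accuracies of the NN classifier for several prefix sizes at once.
# Exploits nesting: per leave-one-out fold the cosine numerator and the two
# squared norms are cumulative sums over ranked features, so one pass per
# fold covers every requested prefix size.
ifs_accuracies <- function(x, labels, ord, sizes, paper_mode) {
  n <- nrow(x)
  m <- length(ord)
  k <- length(sizes)
  xr <- x[, ord, drop = FALSE]
  cum <- vapply(sizes, function(s) c(rep(1, s), rep(0, m - s)), numeric(m))
  lab <- as.character(labels)
  pred <- matrix("", n, k)

  if (paper_mode) {
    z <- standardize(xr)$x
    zq <- z * z
    for (i in seq_len(n)) {
      q <- z[i, ]
      numer <- (z * rep(q, each = n)) %*% cum
      denom <- sqrt(zq %*% cum) * rep(sqrt(cumsum(q^2)[sizes]), each = n)
      d <- matrix(2, n, k)
      ok <- denom > 0
      d[ok] <- 1 - numer[ok] / denom[ok]
      d <- snap_dist(pmin(pmax(d, 0), 2))
      d[i, ] <- Inf
      pred[i, ] <- lab[apply(d, 2L, which.min)]
    }
  } else {
    S <- colSums(xr); SS <- colSums(xr * xr)
    for (i in seq_len(n)) {
      xi <- xr[i, ]
      if (n - 1L >= 2L) {
        mu <- (S - xi) / (n - 1L)
        v <- pmax((SS - xi * xi - (n - 1L) * mu * mu) / (n - 2L), 0)
        sdv <- sqrt(v)
        sc <- ifelse(sdv > 0, sdv, 1)
        zt <- sweep(sweep(xr[-i, , drop = FALSE], 2L, mu, "-"), 2L, sc, "/")
        zt[, sdv == 0] <- 0
        q <- (xi - mu) / sc
        q[sdv == 0] <- 0
      } else {
        zt <- xr[-i, , drop = FALSE]
        q <- xi
      }
      nr <- n - 1L
      numer <- (zt * rep(q, each = nr)) %*% cum
      denom <- sqrt((zt * zt) %*% cum) *
        rep(sqrt(cumsum(q^2)[sizes]), each = nr)
      d <- matrix(2, nr, k)
      ok <- denom > 0
      d[ok] <- 1 - numer[ok] / denom[ok]
      d <- snap_dist(pmin(pmax(d, 0), 2))
      pred[i, ] <- lab[-i][apply(d, 2L, which.min)]
    }
  }
  correct <- pred == lab
  per_class <- t(vapply(levels(labels), function(cl)
    colMeans(correct[lab == cl, , drop = FALSE]), numeric(k)))
  list(overall = colMeans(correct), per_class = t(per_class))
}

#' Select the optimal feature subset from an IFS curve
#'
#' Returns the prefix at the accuracy peak; plateaus resolve to the smallest
#' set size.
#'
#' @param curve an `ifs_curve` from [ifs_evaluate()].
#' @return list with `size`, `features` (integer indices, in rank order) and
#'   `accuracy`.
#' @export
select_optimal <- function(curve) {
  stopifnot(inherits(curve, "ifs_curve"))
  size <- attr(curve, "peak_size")
  list(size = size,
       features = attr(curve, "order")[seq_len(size)],
       accuracy = attr(curve, "peak_accuracy"))
}

#' @export
print.ifs_curve <- function(x, ...) {
  cat(sprintf("IFS curve over %d set sizes; peak accuracy %.4f at %d features\n",
              nrow(x), attr(x, "peak_accuracy"), attr(x, "peak_size")))
  invisible(x)
}

#' Plot an IFS curve
#'
#' Accuracy versus number of ranked features, with the peak marked.
#'
#' @param x an `ifs_curve`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ifs_curve <- function(x, ...) {
  graphics::plot(x$size, x$accuracy, type = "l",
                 xlab = "Number of features", ylab = "Jackknife accuracy", ...)
  graphics::abline(v = attr(x, "peak_size"), lty = 2, col = "grey50")
  graphics::points(attr(x, "peak_size"), attr(x, "peak_accuracy"),
                   pch = 19, col = "red3")
  invisible(x)
}
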