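# Minimum-redundancy maximum-relevance feature ranking on mean +/- sd
# three-bin discretized features, with a plug-in mutual-information
# estimator.

#' Discretize feature columns into three bins
#'
#' Each column is coded 0 if the value is below `mean - sd`, 2 if above
#' `mean + sd`, and 1 otherwise. By default the mean and (sample) standard
#' deviation are computed per column; explicit `center`/`scale` vectors (or
#' scalars) override them, e.g. (0, 1) for columns already standardized.
#'
#' @param x numeric matrix with at least 2 rows.
#' @param center,scale optional per-column threshold parameters.
#' @return integer matrix of codes in \{0, 1, 2\} with the input's dimnames.
#' @export
discretize <- function(x, center = NULL, scale = NULL) {
  x <- as.matrix(x)
  if (is.null(center) || is.null(scale)) {
    if (nrow(x) < 2L) stop("discretization needs at least 2 samples")
  }
  center <- rep_len(center %||% colMeans(x), ncol(x))
  scale <- rep_len(scale %||% apply(x, 2L, stats::sd), ncol(x))
  lo <- sweep(x, 2L, center - scale, "<")
  hi <- sweep(x, 2L, center + scale, ">")
  codes <- matrix(1L, nrow(x), ncol(x), dimnames = dimnames(x))
  codes[lo] <- 0L
  codes[hi] <- 2L
  codes
}

#' Mutual information of two discrete vectors
#'
#' Plug-in (maximum-likelihood) estimate over the empirical joint
#' distribution, with the 0 log 0 = 0 convention.
#'
#' @param x,y vectors of equal length (any discrete coding).
#' @param base logarithm base; 2 (bits) by default. Rankings built on MI are
#'   invariant to the base.
#' @return nonnegative scalar.
#' @export
mutual_information <- function(x, y, base = 2) {
  if (length(x) != length(y))
    stop("'x' and 'y' must have equal length")
  if (length(x) == 0L) stop("empty vectors")
  joint <- table(x, y) / length(x)
  px <- rowSums(joint)
  py <- colSums(joint)
  e <- outer(px, py)
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz] / e[nz])) / log(base)
}

# fast path: integer codes in 0..(kx-1), 0..(ky-1)
mi_codes <- function(x, y, kx, ky, base = 2) {
  n <- length(x)
  joint <- tabulate(x * ky + y + 1L, nbins = kx * ky) / n
  px <- rowSums(matrix(joint, kx, ky, byrow = TRUE))
  py <- colSums(matrix(joint, kx, ky, byrow = TRUE))
  e <- as.vector(t(outer(px, py)))
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz] / e[nz])) / log(base)
}

#' Rank features by maximum relevance, minimum redundancy (mRMR)
#'
#' Greedy forward ranking of discretized features: round 1 picks the feature
#' with maximal relevance (mutual information with the class label); each
#' later round picks the candidate maximizing relevance minus the mean
#' mutual information with the already-selected features (the "difference"
#' mRMR form). Ties are broken by smallest feature index. The pure-relevance
#' ordering (MaxRel) is reported alongside but only the mRMR order feeds
#' incremental feature selection.
#'
#' @param codes discretized feature matrix (see [discretize()]).
#' @param labels class labels, one per row, with at least 2 distinct values.
#' @param base MI logarithm base (does not affect the ranking).
#' @return object of class `mrmr_ranking`: a data.frame with columns `round`,
#'   `feature` (column index), `name`, `relevance`, `score` (relevance minus
#'   mean redundancy at selection time), plus attribute `maxrel` (feature
#'   indices in decreasing-relevance order).
#' @export
mrmr_rank <- function(codes, labels, base = 2) {
  codes <- as.matrix(codes)
  m <- ncol(codes)
  if (m < 1L) stop("need at least one feature")
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2L)
    stop("labels must contain at least 2 classes")
  if (length(labels) != nrow(codes))
    stop("one label per row required")
  y <- as.integer(droplevels(labels)) - 1L
  ky <- max(y) + 1L
  codes_i <- codes
  storage.mode(codes_i) <- "integer"
  kx <- max(codes_i) + 1L

  relevance <- vapply(seq_len(m), function(j)
    mi_codes(codes_i[, j], y, kx, ky, base), numeric(1))
  maxrel <- order(-relevance, seq_len(m))

  selected <- integer(0)
  score_at <- numeric(m)
  redsum <- numeric(m)       # sum of MI(candidate, selected)
  remaining <- seq_len(m)
  for (round in seq_len(m)) {
    score <- relevance[remaining] -
      if (round == 1L) 0 else redsum[remaining] / (round - 1L)
    pick <- remaining[which.max(score)]   # first max = smallest index
    score_at[round] <- max(score)
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
    if (length(remaining)) {
      xs <- codes_i[, pick]
      redsum[remaining] <- redsum[remaining] + vapply(remaining, function(j)
        mi_codes(codes_i[, j], xs, kx, kx, base), numeric(1))
    }
  }
  nm <- colnames(codes) %||% paste0("V", seq_len(m))
  structure(
    data.frame(round = seq_len(m), feature = selected, name = nm[selected],
               relevance = relevance[selected], score = score_at,
               stringsAsFactors = FALSE),
    maxrel = maxrel, class = c("mrmr_ranking", "data.frame"))
}

#' @export
print.mrmr_ranking <- function(x, n = 10L, ...) {
  cat(sprintf("mRMR ranking of %d features (top %d shown)\n",
              nrow(x), min(n, nrow(x))))
  print.data.frame(utils::head(x, n), row.names = FALSE)
  invisible(x)
}
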