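# Assembly of the full 376-component feature vector, half-life class labels,
# length filtering, KEGG enrichment scores and column standardization.

N_FEATURES <- 376L
HALF_LIFE_LEVELS <- c("short", "medium", "long", "extra_long")
COARSE_LEVELS <- c("short_medium", "long_extra_long")

#' Feature names of the 376-component representation
#'
#' `V1:V132` biochemical CTD/AAC block, `V133` sequence length, `V134:V155`
#' the 22 subcellular-location flags, `V156:V375` the 220 KEGG enrichment
#' scores, `V376` the protein-complex count.
#'
#' @return character vector `c("V1", ..., "V376")`.
#' @export
feature_names <- function() paste0("V", seq_len(N_FEATURES))

#' Map protein stability index (PSI) to a half-life class
#'
#' short: PSI < 2; medium: 2 <= PSI < 3; long: 3 <= PSI < 4;
#' extra_long: PSI >= 4.
#'
#' @param psi numeric vector of finite PSI values.
#' @return factor with levels short < medium < long < extra_long.
#' @export
psi_to_class <- function(psi) {
  if (!is.numeric(psi) || any(!is.finite(psi)))
    stop("'psi' must be finite numeric")
  cls <- cut(psi, breaks = c(-Inf, 2, 3, 4, Inf), right = FALSE,
             labels = HALF_LIFE_LEVELS)
  factor(as.character(cls), levels = HALF_LIFE_LEVELS)
}

#' Coarse (stage-1) label of a fine half-life class
#'
#' @param class factor or character of fine labels.
#' @return factor over short_medium / long_extra_long.
#' @export
coarse_class <- function(class) {
  class <- as.character(class)
  stopifnot(all(class %in% HALF_LIFE_LEVELS))
  factor(ifelse(class %in% c("short", "medium"),
                "short_medium", "long_extra_long"),
         levels = COARSE_LEVELS)
}

#' Filter protein records by sequence length
#'
#' Retains records with length in `[min_len, max_len]` (bounds inclusive;
#' the benchmark excludes sequences shorter than 50 or longer than 2700).
#'
#' @param records list of `protein_record`s.
#' @param min_len,max_len inclusive length bounds.
#' @return list with `retained` (records) and `excluded` (data.frame of id,
#'   length, reason).
#' @export
length_filter <- function(records, min_len = 50L, max_len = 2700L) {
  lens <- vapply(records, function(r) nchar(r$sequence), integer(1))
  keep <- lens >= min_len & lens <= max_len
  excluded <- data.frame(
    id = vapply(records[!keep], `[[`, "", "id"),
    length = lens[!keep],
    reason = ifelse(lens[!keep] < min_len,
                    sprintf("shorter than %d", min_len),
                    sprintf("longer than %d", max_len)),
    stringsAsFactors = FALSE)
  list(retained = records[keep], excluded = excluded)
}

#' KEGG pathway enrichment score of a protein neighborhood
#'
#' The score is \eqn{-\log_{10}} of the upper-tail hypergeometric probability
#' \eqn{P(X \ge k)} of observing at least the realized overlap `k` between a
#' protein's network neighborhood (the protein plus its neighbors) and one
#' pathway's member set, drawing `|neighbors|` elements without replacement
#' from the universe. Larger scores mean stronger overrepresentation; an
#' empty neighborhood scores 0.
#'
#' @param neighbors character/integer vector: the protein and its network
#'   neighbors.
#' @param pathway vector of pathway members; must be a subset of `universe`.
#' @param universe vector of all genes in the background universe; both
#'   `pathway` and `neighbors` must be subsets of it.
#' @return nonnegative numeric scalar.
#' @export
kegg_enrichment_score <- function(neighbors, pathway, universe) {
  if (length(universe) == 1L && is.numeric(universe))
    stop("'universe' must be the vector of universe members")
  if (!all(pathway %in% universe))
    stop("pathway contains members outside the universe")
  if (length(neighbors) == 0L) return(0)
  if (!all(neighbors %in% universe))
    stop("neighbor set contains members outside the universe")
  k <- length(intersect(neighbors, pathway))
  if (k == 0L) return(0)
  N <- length(unique(universe))
  K <- length(unique(pathway))
  n <- length(unique(neighbors))
  # upper tail P(X >= k) on the log scale for numerical stability
  logp <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE, log.p = TRUE)
  -logp / log(10)
}

#' All 220 pathway enrichment scores for one protein
#'
#' @param neighbors the protein and its neighbors.
#' @param universe a `pathway_universe` (see [generate_pathway_universe()])
#'   or a list with `universe` and `pathways` entries.
#' @return numeric vector, one score per pathway, in pathway order.
#' @export
kegg_score_vector <- function(neighbors, universe) {
  vapply(universe$pathways,
         function(p) kegg_enrichment_score(neighbors, p, universe$universe),
         numeric(1))
}

#' Assemble the 376-component feature vector of one protein
#'
#' @param record a `protein_record` (supplies the length component).
#' @param biochemical numeric vector of the 132 CTD/AAC components.
#' @param location_flags 22 binary subcellular-location flags (multi-label
#'   and all-zero both allowed).
#' @param kegg_scores 220 nonnegative enrichment scores.
#' @param complex_count nonnegative integer count of complexes the protein
#'   participates in.
#' @return named numeric vector of length 376 (names `V1:V376`).
#' @export
assemble_feature_vector <- function(record, biochemical, location_flags,
                                    kegg_scores, complex_count) {
  stopifnot(inherits(record, "protein_record"))
  if (length(biochemical) != 132L)
    stop("'biochemical' block must have length 132, got ", length(biochemical))
  if (length(location_flags) != 22L)
    stop("'location_flags' block must have length 22, got ", length(location_flags))
  if (!all(location_flags %in% c(0, 1)))
    stop("'location_flags' must be binary")
  if (length(kegg_scores) != 220L)
    stop("'kegg_scores' block must have length 220, got ", length(kegg_scores))
  if (any(kegg_scores < 0)) stop("'kegg_scores' must be nonnegative")
  if (length(complex_count) != 1L || complex_count < 0 ||
      complex_count != round(complex_count))
    stop("'complex_count' must be a single nonnegative integer")
  out <- c(unname(biochemical), nchar(record$sequence), unname(location_flags),
           unname(kegg_scores), complex_count)
  stats::setNames(out, feature_names())
}

#' Assemble the feature matrix for a set of records
#'
#' Convenience wrapper computing the biochemical block for each record and
#' binding the metadata blocks from a per-protein metadata table.
#'
#' @param records list of `protein_record`s.
#' @param metadata data.frame keyed by `id` with columns `loc_1:loc_22`,
#'   `kegg_1:kegg_220`, `complex_count`.
#' @param annotate passed to [biochemical_vector()].
#' @return numeric matrix (n x 376) with protein ids as rownames.
#' @export
assemble_feature_matrix <- function(records, metadata, annotate = FALSE) {
  ids <- vapply(records, `[[`, "", "id")
  if (!all(ids %in% metadata$id))
    stop("metadata missing for: ",
         paste(utils::head(setdiff(ids, metadata$id)), collapse = ", "))
  meta <- metadata[match(ids, metadata$id), , drop = FALSE]
  loc_cols <- paste0("loc_", 1:22)
  kegg_cols <- paste0("kegg_", 1:220)
  x <- t(vapply(seq_along(records), function(i) {
    assemble_feature_vector(
      records[[i]],
      biochemical_vector(records[[i]], annotate = annotate),
      as.numeric(meta[i, loc_cols]),
      as.numeric(meta[i, kegg_cols]),
      meta$complex_count[i])
  }, numeric(N_FEATURES)))
  rownames(x) <- ids
  colnames(x) <- feature_names()
  x
}

#' Standardize a feature matrix
#'
#' Converts each column to zero mean and unit standard deviation using the
#' training-set mean and (sample) standard deviation. Constant columns map
#' to all zeros. The transform is idempotent: standardizing an already
#' standardized matrix leaves it unchanged.
#'
#' @param x numeric matrix with at least 2 rows.
#' @return list with `x` (the standardized matrix) and `params` (an object of
#'   class `standardization_params` with `mean` and `sd` vectors).
#' @export
standardize <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("standardization needs at least 2 samples")
  mu <- colMeans(x)
  sdv <- apply(x, 2L, stats::sd)
  params <- structure(list(mean = mu, sd = sdv),
                      class = "standardization_params")
  list(x = apply_standardization(x, params), params = params)
}

#' Apply fitted standardization parameters
#'
#' @param x numeric matrix or vector on the original scale.
#' @param params a `standardization_params` object from [standardize()].
#' @return standardized matrix/vector; columns whose training sd is 0 map to
#'   0.
#' @export
apply_standardization <- function(x, params) {
  if (!inherits(params, "standardization_params"))
    stop("'params' must be fitted standardization parameters")
  vec <- is.null(dim(x))
  x <- if (vec) matrix(x, nrow = 1L) else as.matrix(x)
  if (ncol(x) != length(params$mean))
    stop("dimension mismatch between input and standardization parameters")
  s <- ifelse(params$sd > 0, params$sd, 1)
  out <- sweep(sweep(x, 2L, params$mean, "-"), 2L, s, "/")
  out[, params$sd == 0] <- 0
  if (vec) drop(out) else out
}

#' @export
print.standardization_params <- function(x, ...) {
  cat(sprintf("Standardization parameters for %d components (%d constant)\n",
              length(x$mean), sum(x$sd == 0)))
  invisible(x)
}
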