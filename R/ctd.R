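# CTD (composition / transition / distribution) descriptors of a recoded
# sequence, plus the amino-acid composition block and the assembled
# 132-component biochemical vector.

split1 <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

#' Composition of a coded string
#'
#' Fraction of positions carrying each category label, in the grouping's
#' category order.
#'
#' @param coded character string of category labels.
#' @param categories ordered category labels.
#' @return named numeric vector of per-category fractions (sums to 1).
#' @export
ctd_composition <- function(coded, categories) {
  if (!nzchar(coded)) stop("coded string is empty")
  letters <- split1(coded)
  counts <- vapply(categories, function(cc) sum(letters == cc), numeric(1))
  counts / length(letters)
}

# unordered category pairs in block order: for categories (a,b,c) the pairs
# are ab, ac, bc; for (a,b) the single pair ab
category_pairs <- function(categories) {
  k <- length(categories)
  pairs <- list()
  for (i in seq_len(k - 1L))
    for (j in (i + 1L):k)
      pairs[[length(pairs) + 1L]] <- c(categories[i], categories[j])
  names(pairs) <- vapply(pairs, paste, "", collapse = "")
  pairs
}

#' Transition fractions of a coded string
#'
#' For each unordered category pair, the number of adjacent positions whose
#' letters form that pair (in either order) divided by the total number of
#' adjacent differing positions. All zero when the string has no transitions.
#'
#' @inheritParams ctd_composition
#' @return named numeric vector, one entry per unordered category pair.
#' @export
ctd_transition <- function(coded, categories) {
  if (!nzchar(coded)) stop("coded string is empty")
  letters <- split1(coded)
  n <- length(letters)
  pairs <- category_pairs(categories)
  out <- stats::setNames(numeric(length(pairs)), names(pairs))
  if (n < 2L) return(out)
  a <- letters[-n]; b <- letters[-1L]
  total <- sum(a != b)
  if (total == 0L) return(out)
  for (p in names(pairs)) {
    x <- pairs[[p]]
    out[p] <- sum((a == x[1] & b == x[2]) | (a == x[2] & b == x[1])) / total
  }
  out
}

#' Distribution descriptors of a coded string
#'
#' For each category with `n_c > 0` occurrences, the positions of the 1st,
#' 25%, 50%, 75% and 100% occurrences (occurrence index `ceiling(q * n_c)`,
#' clamped to at least 1), each divided by the string length. A category with
#' no occurrence yields (0,0,0,0,0).
#'
#' @inheritParams ctd_composition
#' @return named numeric vector of length `5 * length(categories)`,
#'   category-major.
#' @export
ctd_distribution <- function(coded, categories) {
  if (!nzchar(coded)) stop("coded string is empty")
  letters <- split1(coded)
  n <- length(letters)
  qs <- c(0, 0.25, 0.50, 0.75, 1)
  out <- numeric(0)
  for (cc in categories) {
    pos <- which(letters == cc)
    tup <- if (length(pos) == 0L) numeric(5) else {
      idx <- pmax(1L, ceiling(qs * length(pos)))
      pos[idx] / n
    }
    names(tup) <- paste0(cc, ".", c("first", "q25", "q50", "q75", "q100"))
    out <- c(out, tup)
  }
  out
}

#' CTD block for one grouping
#'
#' Flattened composition, transition and distribution descriptors of a
#' protein recoded under one property grouping. A 3-category grouping gives
#' 21 components (3 C + 3 T + 15 D). The 2-category solvent-accessibility
#' grouping gives the reduced 7-component layout: composition of the first
#' category (hidden), the single transition fraction, and the distribution
#' 5-tuple of the first category.
#'
#' @inheritParams encode_sequence
#' @return named numeric vector of length 21 (3 categories) or 7 (2
#'   categories).
#' @export
ctd_block <- function(record, grouping) {
  coded <- encode_sequence(record, grouping)
  cats <- grouping$categories
  comp <- ctd_composition(coded, cats)
  tran <- ctd_transition(coded, cats)
  dist <- ctd_distribution(coded, cats)
  names(comp) <- paste0("C.", cats)
  names(tran) <- paste0("T.", names(tran))
  if (length(cats) == 2L) {
    out <- c(comp[1L], tran, dist[1:5])
  } else {
    out <- c(comp, tran, dist)
  }
  names(out) <- paste0(grouping$name, ".", names(out))
  out
}

#' Amino-acid composition
#'
#' Occurrence frequencies of the 20 canonical residues, in the fixed block
#' order r,k,e,d,q,n,g,a,s,t,p,h,y,c,v,l,i,m,f,w.
#'
#' @param record a `protein_record` or a plain sequence string.
#' @return named numeric vector of 20 fractions summing to 1.
#' @export
aac_vector <- function(record) {
  if (is.character(record) && length(record) == 1L)
    record <- protein_record("query", record)
  letters <- split1(record$sequence)
  counts <- vapply(AAC_ORDER, function(a) sum(letters == a), numeric(1))
  stats::setNames(counts / length(letters), paste0("AAC.", AAC_ORDER))
}

#' Full 132-component biochemical/physicochemical vector
#'
#' Concatenates the CTD blocks of the six property groupings with the
#' amino-acid composition, in the fixed index order: hydrophobicity (V1:V21),
#' secondary structure (V22:V42), solvent accessibility (V43:V49), normalized
#' van der Waals volume (V50:V70), polarity (V71:V91), polarizability
#' (V92:V112), AAC (V113:V132).
#'
#' @param record a `protein_record`. Secondary-structure and accessibility
#'   tracks are required unless `annotate = TRUE`.
#' @param annotate if `TRUE`, missing annotation tracks are filled by the
#'   deterministic stand-in annotator ([annotate_standin()]).
#' @return named numeric vector of length 132.
#' @export
biochemical_vector <- function(record, annotate = FALSE) {
  stopifnot(inherits(record, "protein_record"))
  if (annotate && (is.null(record$ss_track) || is.null(record$acc_track))) {
    ann <- annotate_standin(record$sequence)
    record$ss_track <- record$ss_track %||% ann$ss
    record$acc_track <- record$acc_track %||% ann$acc
  }
  if (is.null(record$ss_track))
    stop(sprintf("record '%s' lacks the secondary-structure track (set annotate = TRUE for the stand-in annotator)",
                 record$id))
  if (is.null(record$acc_track))
    stop(sprintf("record '%s' lacks the accessibility track (set annotate = TRUE for the stand-in annotator)",
                 record$id))
  g <- aa_groupings()
  out <- c(ctd_block(record, g$hydrophobicity),
           ctd_block(record, g$secondary_structure),
           ctd_block(record, g$solvent_accessibility),
           ctd_block(record, g$vdw_volume),
           ctd_block(record, g$polarity),
           ctd_block(record, g$polarizability),
           aac_vector(record))
  stopifnot(length(out) == 132L)
  out
}
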