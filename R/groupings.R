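AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Residue order of the amino-acid composition block (V113:V132)
AAC_ORDER <- c("R", "K", "E", "D", "Q", "N", "G", "A", "S", "T",
               "P", "H", "Y", "C", "V", "L", "I", "M", "F", "W")

#' Construct a property grouping
#'
#' A property grouping partitions an alphabet (the 20 amino acids, or an
#' annotation alphabet such as \{H,E,C\}) into 2 or 3 ordered categories.
#' CTD descriptors are computed on the sequence recoded by such a grouping.
#'
#' @param name grouping name.
#' @param categories ordered character vector of 2 or 3 category labels.
#' @param assignment named character vector mapping each alphabet letter to a
#'   category label; must be total on its alphabet and use every category.
#' @param source which string the grouping recodes: the amino-acid
#'   `"sequence"`, the secondary-structure track (`"ss"`), or the solvent
#'   accessibility track (`"acc"`).
#' @return an object of class `property_grouping`.
#' @export
property_grouping <- function(name, categories, assignment,
                              source = c("sequence", "ss", "acc")) {
  source <- match.arg(source)
  stopifnot(is.character(name), length(name) == 1L)
  if (length(categories) < 2L || length(categories) > 3L)
    stop("a property grouping must have 2 or 3 categories")
  if (anyDuplicated(categories))
    stop("category labels must be distinct")
  if (is.null(names(assignment)) || any(names(assignment) == ""))
    stop("'assignment' must be a fully named character vector")
  if (!all(assignment %in% categories))
    stop("assignment maps to unknown category label(s): ",
         paste(setdiff(assignment, categories), collapse = ", "))
  if (!all(categories %in% assignment))
    stop("every category must be used by at least one letter")
  if (source == "sequence" && !setequal(names(assignment), AA20))
    stop("a sequence grouping must partition exactly the 20 canonical residues")
  structure(
    list(name = name, categories = categories,
         assignment = assignment, source = source),
    class = "property_grouping")
}

#' @export
print.property_grouping <- function(x, ...) {
  cat("Property grouping:", x$name, "(on", x$source, "letters)\n")
  for (cc in x$categories)
    cat(" ", cc, ":", paste(names(x$assignment)[x$assignment == cc],
                            collapse = ""), "\n")
  invisible(x)
}

grouping_from_lists <- function(name, letters_by_category, source = "sequence") {
  categories <- names(letters_by_category)
  assignment <- unlist(lapply(categories, function(cc) {
    stats::setNames(rep(cc, length(letters_by_category[[cc]])),
                    letters_by_category[[cc]])
  }))
  property_grouping(name, categories, assignment, source)
}

#' Built-in property groupings
#'
#' The six groupings behind the 132-component biochemical block, in block
#' order: hydrophobicity (polar P, neutral N, hydrophobic H), secondary
#' structure (helix H, strand E, coil C, read from the annotation track),
#' solvent accessibility (hidden H, exposed E, read from the annotation
#' track), normalized van der Waals volume, polarity, and polarizability.
#' Category letter lists follow the standard CTD residue classes.
#'
#' @return named list of `property_grouping` objects.
#' @export
aa_groupings <- function() {
  list(
    hydrophobicity = grouping_from_lists("hydrophobicity", list(
      P = c("R", "K", "E", "D", "Q", "N"),
      N = c("G", "A", "S", "T", "P", "H", "Y"),
      H = c("C", "V", "L", "I", "M", "F", "W"))),
    secondary_structure = property_grouping(
      "secondary_structure", c("H", "E", "C"),
      c(H = "H", E = "E", C = "C"), source = "ss"),
    solvent_accessibility = property_grouping(
      "solvent_accessibility", c("H", "E"),
      c(H = "H", E = "E"), source = "acc"),
    vdw_volume = grouping_from_lists("vdw_volume", list(
      H = c("G", "A", "S", "C", "T", "D", "P"),
      E = c("N", "V", "E", "Q", "I", "L"),
      C = c("M", "H", "K", "F", "R", "Y", "W"))),
    polarity = grouping_from_lists("polarity", list(
      H = c("L", "I", "F", "W", "C", "M", "V", "Y"),
      E = c("G", "A", "T", "P", "S"),
      C = c("H", "Q", "R", "K", "N", "E", "D"))),
    polarizability = grouping_from_lists("polarizability", list(
      H = c("G", "A", "S", "D", "T"),
      E = c("C", "P", "N", "V", "E", "Q", "I", "L"),
      C = c("K", "M", "H", "F", "R", "Y", "W")))
  )
}

#' Construct a protein record
#'
#' @param id protein identifier.
#' @param sequence amino-acid sequence over the 20 canonical one-letter codes
#'   (lowercase accepted, stored uppercase).
#' @param ss_track optional secondary-structure track over \{H,E,C\}, same
#'   length as `sequence`.
#' @param acc_track optional solvent-accessibility track over \{H,E\}
#'   (hidden/exposed), same length as `sequence`.
#' @param sanitize if `TRUE`, drop nonstandard residues (B, J, O, U, X, Z and
#'   anything else outside the canonical 20) with a warning, removing the same
#'   positions from the annotation tracks; if `FALSE` (default) such residues
#'   are an error.
#' @return an object of class `protein_record`.
#' @export
protein_record <- function(id, sequence, ss_track = NULL, acc_track = NULL,
                           sanitize = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  letters <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!(letters %in% AA20))
  if (length(bad)) {
    if (!sanitize)
      stop(sprintf("sequence of '%s' has nonstandard residue '%s' at position %d",
                   id, letters[bad[1]], bad[1]))
    warning(sprintf("dropped %d nonstandard residue(s) from '%s'",
                    length(bad), id))
    keep <- setdiff(seq_along(letters), bad)
    letters <- letters[keep]
    if (!is.null(ss_track))
      ss_track <- paste(strsplit(toupper(ss_track), "")[[1]][keep], collapse = "")
    if (!is.null(acc_track))
      acc_track <- paste(strsplit(toupper(acc_track), "")[[1]][keep], collapse = "")
    sequence <- paste(letters, collapse = "")
  }
  if (!nzchar(sequence)) stop("sequence of '", id, "' is empty")
  check_track <- function(track, alphabet, what) {
    if (is.null(track)) return(NULL)
    track <- toupper(track)
    if (nchar(track) != nchar(sequence))
      stop(sprintf("%s track of '%s' has length %d but sequence has length %d",
                   what, id, nchar(track), nchar(sequence)))
    tl <- strsplit(track, "", fixed = TRUE)[[1]]
    off <- which(!(tl %in% alphabet))
    if (length(off))
      stop(sprintf("%s track of '%s' has invalid letter '%s' at position %d",
                   what, id, tl[off[1]], off[1]))
    track
  }
  structure(
    list(id = id, sequence = sequence,
         ss_track = check_track(ss_track, c("H", "E", "C"), "secondary-structure"),
         acc_track = check_track(acc_track, c("H", "E"), "accessibility")),
    class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("Protein record '%s': %d aa%s%s\n", x$id, nchar(x$sequence),
              if (!is.null(x$ss_track)) ", ss track" else "",
              if (!is.null(x$acc_track)) ", acc track" else ""))
  invisible(x)
}

#' Recode a protein under a property grouping
#'
#' Maps each letter of the relevant source string (amino-acid sequence, or a
#' required annotation track) to its category label, e.g. the hydrophobicity
#' grouping recodes a sequence over \{P,N,H\}.
#'
#' @param record a `protein_record` (a plain character sequence is accepted
#'   for sequence-based groupings).
#' @param grouping a `property_grouping`.
#' @return single character string of category labels, same length as the
#'   source string.
#' @export
encode_sequence <- function(record, grouping) {
  stopifnot(inherits(grouping, "property_grouping"))
  if (is.character(record) && length(record) == 1L)
    record <- protein_record("query", record)
  stopifnot(inherits(record, "protein_record"))
  src <- switch(grouping$source,
    sequence = record$sequence,
    ss = record$ss_track %||%
      stop(sprintf("record '%s' lacks the secondary-structure track required by grouping '%s'",
                   record$id, grouping$name)),
    acc = record$acc_track %||%
      stop(sprintf("record '%s' lacks the accessibility track required by grouping '%s'",
                   record$id, grouping$name)))
  letters <- strsplit(src, "", fixed = TRUE)[[1]]
  coded <- grouping$assignment[letters]
  if (anyNA(coded))
    stop(sprintf("letter '%s' at position %d of '%s' is outside the alphabet of grouping '%s'",
                 letters[which(is.na(coded))[1]], which(is.na(coded))[1],
                 record$id, grouping$name))
  paste(coded, collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Deterministic stand-in structure annotator
#'
#' Assigns per-residue secondary-structure (\{H,E,C\}) and accessibility
#' (\{H,E\}) labels from fixed residue propensity tables, then smooths
#' single-residue islands so tracks have segment structure. This is a
#' self-contained synthetic annotator so the pipeline can run on bare
#' sequences; it is not equivalent to trained structure predictors and its
#' labels carry no structural accuracy.
#'
#' @param sequence amino-acid sequence (character scalar).
#' @return list with elements `ss` and `acc`, both strings of the sequence's
#'   length.
#' @export
annotate_standin <- function(sequence) {
  letters <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  helix <- c("A", "E", "L", "M", "Q", "K", "R", "H")
  strand <- c("V", "I", "Y", "C", "W", "F", "T")
  ss <- ifelse(letters %in% helix, "H", ifelse(letters %in% strand, "E", "C"))
  buried <- c("A", "C", "F", "I", "L", "M", "V", "W", "G")
  acc <- ifelse(letters %in% buried, "H", "E")
  smooth <- function(x) {
    if (length(x) >= 3L) {
      for (i in 2:(length(x) - 1L))
        if (x[i - 1L] == x[i + 1L] && x[i] != x[i - 1L]) x[i] <- x[i - 1L]
    }
    x
  }
  list(ss = paste(smooth(ss), collapse = ""),
       acc = paste(smooth(acc), collapse = ""))
}
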