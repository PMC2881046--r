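# Readers and writers for the pipeline's plain-text formats: FASTA,
# annotation-track TSV, metadata TSV, feature-matrix TSV, standardization
# parameters and serialized model bundles.

#' Read protein records from a FASTA file
#'
#' Standard multi-record FASTA; the identifier is the first
#' whitespace-delimited token of the header. Sequences are uppercased.
#' Duplicate identifiers, empty files and empty sequences are errors.
#'
#' @param path FASTA file.
#' @param sanitize drop nonstandard residues with a warning instead of
#'   failing (see [protein_record()]).
#' @return list of `protein_record`s in file order.
#' @export
read_fasta <- function(path, sanitize = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA file has no records: ", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, "", 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  lapply(seq_along(set), function(i)
    protein_record(ids[i], as.character(set[[i]]), sanitize = sanitize))
}

#' Write protein records to FASTA
#'
#' @param records list of `protein_record`s.
#' @param path output file.
#' @export
write_fasta <- function(records, path) {
  seqs <- Biostrings::BStringSet(vapply(records, `[[`, "", "sequence"))
  names(seqs) <- vapply(records, `[[`, "", "id")
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

#' Read annotation tracks and attach them to records
#'
#' The track file is a 3-column TSV (`id`, `ss_track`, `acc_track`) keyed by
#' the records' identifiers.
#'
#' @param records list of `protein_record`s.
#' @param path track TSV.
#' @return the records with tracks attached (records without a row keep no
#'   tracks).
#' @export
read_tracks <- function(records, path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "ss_track", "acc_track")
  if (!all(need %in% names(tab)))
    stop("track file must have columns: ", paste(need, collapse = ", "))
  lapply(records, function(r) {
    j <- match(r$id, tab$id)
    if (is.na(j)) return(r)
    protein_record(r$id, r$sequence,
                   ss_track = tab$ss_track[j], acc_track = tab$acc_track[j])
  })
}

#' @rdname read_tracks
#' @export
write_tracks <- function(records, path) {
  tab <- data.frame(
    id = vapply(records, `[[`, "", "id"),
    ss_track = vapply(records, function(r) r$ss_track %||% "", ""),
    acc_track = vapply(records, function(r) r$acc_track %||% "", ""),
    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read the per-protein metadata table
#'
#' TSV with columns `id`, `psi`, `loc_1:loc_22`, `kegg_1:kegg_220` (any
#' number of kegg columns is accepted), `complex_count`.
#'
#' @param path metadata TSV.
#' @return data.frame.
#' @export
read_metadata <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", paste0("loc_", 1:22), "complex_count")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("metadata is missing column(s): ", paste(missing, collapse = ", "))
  tab
}

#' Write / read a feature matrix TSV
#'
#' One row per protein; header `id` plus the feature names.
#'
#' @param x numeric matrix with protein ids as rownames.
#' @param path TSV file.
#' @export
write_feature_matrix <- function(x, path) {
  tab <- data.frame(id = rownames(x) %||% as.character(seq_len(nrow(x))),
                    x, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  x <- as.matrix(tab[, -1, drop = FALSE])
  rownames(x) <- tab[[1]]
  x
}

#' Serialize / restore standardization parameters
#'
#' Two-row TSV (mean, sd) with one column per feature.
#'
#' @param params a `standardization_params`.
#' @param path TSV file.
#' @export
write_standardization <- function(params, path) {
  tab <- rbind(mean = params$mean, sd = params$sd)
  utils::write.table(data.frame(stat = rownames(tab), tab, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_standardization
#' @export
read_standardization <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  structure(list(mean = stats::setNames(m[1, ], colnames(m)),
                 sd = stats::setNames(m[2, ], colnames(m))),
            class = "standardization_params")
}

#' Serialize a fitted model to a directory of TSV files
#'
#' Each stage writes its feature-subset index list, training matrix, labels
#' and standardization parameters as plain TSV, so a model round-trips
#' through text.
#'
#' @param object a fitted `halflife_nna`.
#' @param dir output directory (created if needed).
#' @export
write_model <- function(object, dir) {
  stopifnot(inherits(object, "halflife_nna"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in names(object$stages)) {
    st <- object$stages[[s]]
    writeLines(as.character(st$features),
               file.path(dir, sprintf("features_%s.tsv", s)))
    write_feature_matrix(st$train, file.path(dir, sprintf("train_%s.tsv", s)))
    utils::write.table(
      data.frame(label = as.character(st$labels)),
      file.path(dir, sprintf("labels_%s.tsv", s)),
      sep = "\t", quote = FALSE, row.names = FALSE)
    write_standardization(st$params, file.path(dir, sprintf("std_%s.tsv", s)))
  }
  writeLines(c(sprintf("n\t%d", object$n), sprintf("m\t%d", object$m),
               sprintf("paper_mode\t%s", object$paper_mode)),
             file.path(dir, "model.tsv"))
  invisible(dir)
}

#' @rdname write_model
#' @export
read_model <- function(dir) {
  meta_path <- file.path(dir, "model.tsv")
  if (!file.exists(meta_path)) stop("no model bundle in ", dir)
  meta <- utils::read.delim(meta_path, header = FALSE, row.names = 1L)
  stages <- lapply(stats::setNames(nm = c("coarse", "short_medium",
                                          "long_extra_long")), function(s) {
    train <- read_feature_matrix(file.path(dir, sprintf("train_%s.tsv", s)))
    list(
      features = as.integer(readLines(file.path(dir, sprintf("features_%s.tsv", s)))),
      train = train,
      labels = factor(utils::read.delim(
        file.path(dir, sprintf("labels_%s.tsv", s)))$label),
      params = read_standardization(file.path(dir, sprintf("std_%s.tsv", s))),
      accuracy = NA_real_)
  })
  structure(list(stages = stages, paper_mode = as.logical(meta["paper_mode", 1]),
                 n = as.integer(meta["n", 1]), m = as.integer(meta["m", 1]),
                 call = quote(read_model(dir))),
            class = "halflife_nna")
}

#' Write an mRMR ranking TSV
#'
#' Columns: round, feature_index, feature_name, relevance,
#' relevance_minus_redundancy.
#'
#' @param ranking an `mrmr_ranking`.
#' @param path TSV file.
#' @export
write_ranking <- function(ranking, path) {
  utils::write.table(
    data.frame(round = ranking$round, feature_index = ranking$feature,
               feature_name = ranking$name, relevance = ranking$relevance,
               relevance_minus_redundancy = ranking$score),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an IFS curve TSV
#'
#' Columns: set_size, accuracy_overall and one accuracy column per class.
#'
#' @param curve an `ifs_curve`.
#' @param path TSV file.
#' @export
write_ifs_curve <- function(curve, path) {
  tab <- as.data.frame(curve)
  names(tab)[names(tab) == "size"] <- "set_size"
  names(tab)[names(tab) == "accuracy"] <- "accuracy_overall"
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
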