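# Self-contained synthetic benchmark generator: labeled protein sequences,
# annotation tracks, a pathway universe with network neighborhoods, and
# per-protein metadata with planted class signal, so every pipeline stage
# runs without external databases.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' Configuration of the synthetic benchmark
#'
#' Defaults mirror the benchmark's study conditions: four half-life classes
#' in proportions 223:446:706:496 and sequence lengths in [50, 2700]. Effect
#' sizes control how strongly the classes differ in expectation on the
#' planted feature families; everything else is exchangeable noise.
#'
#' @param n number of proteins.
#' @param proportions class proportions for short/medium/long/extra_long
#'   (normalized internally).
#' @param length_range inclusive sequence length range.
#' @param composition_shift per-class-step shift of hydrophobic-group
#'   residue mass (fraction units) planted in the sequences.
#' @param loc_shift per-class-step shift of the Bernoulli probability of the
#'   first three subcellular-location flags.
#' @param kegg_shift strength of the class-dependent bias of network
#'   neighborhoods toward their class's planted pathway.
#' @param complex_base mean complex count of the short class.
#' @param complex_shift increase of the mean complex count per class step
#'   (more stable proteins participate in more complexes).
#' @param n_pathways number of pathways in the universe.
#' @param universe_size number of genes in the background universe.
#' @param seed integer seed fixing all randomness.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n = 1871L,
                             proportions = c(short = 223, medium = 446,
                                             long = 706, extra_long = 496),
                             length_range = c(50L, 2700L),
                             composition_shift = 0.05,
                             loc_shift = 0.10,
                             kegg_shift = 0.5,
                             complex_base = 1,
                             complex_shift = 1,
                             n_pathways = 220L,
                             universe_size = 2000L,
                             seed = 1L) {
  if (length(proportions) != 4L || any(proportions < 0) ||
      sum(proportions) <= 0)
    stop("'proportions' must be 4 nonnegative values with positive sum")
  if (length(length_range) != 2L || length_range[1] < 1L ||
      length_range[1] > length_range[2])
    stop("invalid 'length_range'")
  if (n < 4L) stop("'n' must be at least 4")
  structure(list(
    n = as.integer(n),
    proportions = stats::setNames(proportions / sum(proportions),
                                  HALF_LIFE_LEVELS),
    length_range = as.integer(length_range),
    composition_shift = composition_shift,
    loc_shift = loc_shift,
    kegg_shift = kegg_shift,
    complex_base = complex_base,
    complex_shift = complex_shift,
    n_pathways = as.integer(n_pathways),
    universe_size = as.integer(universe_size),
    seed = as.integer(seed)), class = "synthetic_config")
}

# first-order Markov annotation track: stay probability 0.8, so segments
# have expected length 5; drawn segment-wise for speed
markov_track <- function(n, states) {
  change <- c(TRUE, stats::runif(n - 1L) < 0.2)
  seg <- cumsum(change)
  k <- length(states)
  nseg <- seg[n]
  st <- integer(nseg)
  st[1] <- sample.int(k, 1L)
  if (nseg > 1L) {
    jump <- sample.int(k - 1L, nseg - 1L, replace = TRUE)
    for (s in 2:nseg) st[s] <- ((st[s - 1L] - 1L + jump[s - 1L]) %% k) + 1L
  }
  paste(states[st[seg]], collapse = "")
}

class_residue_probs <- function(shift) {
  groups <- aa_groupings()$hydrophobicity
  hydroph <- names(groups$assignment)[groups$assignment == "H"]
  base <- stats::setNames(rep(1 / 20, 20), AA20)
  lapply(0:3, function(k) {
    p <- base
    delta <- shift * k / 3          # class steps span [0, shift]
    p[hydroph] <- p[hydroph] + delta / length(hydroph)
    p[setdiff(AA20, hydroph)] <- p[setdiff(AA20, hydroph)] -
      delta / (20 - length(hydroph))
    pmax(p, 1e-6) / sum(pmax(p, 1e-6))
  })
}

#' Generate a synthetic pathway universe
#'
#' A background gene universe, `n_pathways` member sets of it, and the first
#' four pathways reserved as the planted pathways of the four half-life
#' classes.
#'
#' @param config a `synthetic_config`.
#' @return object of class `pathway_universe`: list with `universe`
#'   (character gene ids), `pathways` (named list of member sets) and
#'   `planted` (indices of the four class-planted pathways).
#' @export
generate_pathway_universe <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed + 7L, {
    genes <- sprintf("g%04d", seq_len(config$universe_size))
    sizes <- sample(15:60, config$n_pathways, replace = TRUE)
    pathways <- lapply(sizes, function(s) sample(genes, s))
    names(pathways) <- sprintf("path_%03d", seq_len(config$n_pathways))
    structure(list(universe = genes, pathways = pathways, planted = 1:4),
              class = "pathway_universe")
  })
}

#' @export
print.pathway_universe <- function(x, ...) {
  cat(sprintf("Pathway universe: %d genes, %d pathways (planted: %s)\n",
              length(x$universe), length(x$pathways),
              paste(x$planted, collapse = ",")))
  invisible(x)
}

# neighborhood of one protein: biased toward its class's planted pathway
draw_neighbors <- function(class_idx, universe, kegg_shift) {
  n_nb <- sample(8:25, 1L)
  planted <- universe$pathways[[universe$planted[class_idx]]]
  n_planted <- stats::rbinom(1L, n_nb, min(0.9, kegg_shift * 0.5))
  n_planted <- min(n_planted, length(planted))
  c(sample(planted, n_planted),
    sample(setdiff(universe$universe, planted), n_nb - n_planted))
}

#' Generate a labeled synthetic benchmark
#'
#' Draws sequences from class-shifted residue multinomials, annotation
#' tracks from segmental Markov chains, PSI values from the class's bin,
#' subcellular-location flags and complex counts with class-shifted
#' parameters, and network neighborhoods biased toward class-planted
#' pathways. Deterministic given `config$seed`. The generated records all
#' pass the benchmark length filter.
#'
#' @param config a `synthetic_config`.
#' @param dir optional directory; when given, writes the pipeline's file
#'   formats there (`benchmark.fasta`, `tracks.tsv`, `metadata.tsv`,
#'   `labels.tsv`, `manifest.tsv`).
#' @return list with `records` (list of `protein_record`), `metadata`
#'   (data.frame with psi, loc_1:loc_22, kegg_1:kegg_220, complex_count),
#'   `labels` (factor), `universe` (the `pathway_universe`) and `config`.
#' @export
generate_benchmark <- function(config = synthetic_config(), dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  universe <- generate_pathway_universe(config)
  res <- with_seed(config$seed, {
    n <- config$n
    counts <- stats::setNames(
      diff(round(c(0, cumsum(config$proportions)) * n)), HALF_LIFE_LEVELS)
    classes <- factor(rep(HALF_LIFE_LEVELS, counts), levels = HALF_LIFE_LEVELS)
    cls_idx <- as.integer(classes)
    probs <- class_residue_probs(config$composition_shift)
    psi_lo <- c(0.5, 2, 3, 4); psi_hi <- c(2, 3, 4, 6)

    records <- vector("list", n)
    psi <- numeric(n)
    loc <- matrix(0L, n, 22L)
    kegg <- matrix(0, n, config$n_pathways)
    cmplx <- integer(n)
    for (i in seq_len(n)) {
      k <- cls_idx[i]
      len <- sample(config$length_range[1]:config$length_range[2], 1L)
      seq_i <- paste(sample(AA20, len, replace = TRUE, prob = probs[[k]]),
                     collapse = "")
      records[[i]] <- protein_record(
        sprintf("syn%05d", i), seq_i,
        ss_track = markov_track(len, c("H", "E", "C")),
        acc_track = markov_track(len, c("H", "E")))
      psi[i] <- stats::runif(1, psi_lo[k], psi_hi[k])
      p_loc <- rep(0.15, 22)
      p_loc[1:3] <- pmin(0.95, 0.15 + config$loc_shift * (k - 1L))
      loc[i, ] <- stats::rbinom(22L, 1L, p_loc)
      kegg[i, ] <- kegg_score_vector(
        draw_neighbors(k, universe, config$kegg_shift), universe)
      cmplx[i] <- stats::rpois(1L, config$complex_base +
                                 config$complex_shift * (k - 1L))
    }
    ids <- vapply(records, `[[`, "", "id")
    metadata <- data.frame(id = ids, psi = psi, stringsAsFactors = FALSE)
    metadata[paste0("loc_", 1:22)] <- as.data.frame(loc)
    metadata[paste0("kegg_", seq_len(config$n_pathways))] <- as.data.frame(kegg)
    metadata$complex_count <- cmplx
    list(records = records, metadata = metadata, labels = classes)
  })
  res$universe <- universe
  res$config <- config
  if (!is.null(dir)) write_benchmark(res, dir)
  invisible(res)
}

write_benchmark <- function(bench, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(bench$records, file.path(dir, "benchmark.fasta"))
  write_tracks(bench$records, file.path(dir, "tracks.tsv"))
  utils::write.table(bench$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(id = bench$metadata$id, class = as.character(bench$labels)),
    file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  cfg <- bench$config
  manifest <- data.frame(
    key = names(cfg)[names(cfg) != "proportions"],
    value = vapply(cfg[names(cfg) != "proportions"],
                   function(v) paste(format(v, digits = 10), collapse = ","), ""))
  manifest <- rbind(manifest, data.frame(
    key = "proportions",
    value = paste(format(cfg$proportions, digits = 10), collapse = ",")))
  utils::write.table(manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Generate a planted-signal feature matrix
#'
#' A direct feature-level benchmark for the selection machinery: the first
#' `n_informative` columns carry a class mean shift, the rest are standard
#' normal noise.
#'
#' @param n rows (samples).
#' @param m columns (features).
#' @param n_informative number of leading signal columns.
#' @param effect class mean separation of the signal columns, in sd units.
#' @param n_classes number of balanced classes.
#' @param seed integer seed.
#' @return list with `x` (n x m matrix) and `classes` (factor).
#' @export
generate_planted_matrix <- function(n = 500L, m = 50L, n_informative = 5L,
                                    effect = 1, n_classes = 2L, seed = 1L) {
  stopifnot(n_informative <= m, n_classes >= 2L)
  with_seed(seed, {
    classes <- factor(rep_len(paste0("c", seq_len(n_classes)), n))
    x <- matrix(stats::rnorm(n * m), n, m,
                dimnames = list(NULL, paste0("V", seq_len(m))))
    shift <- (as.integer(classes) - 1) * effect
    x[, seq_len(n_informative)] <- x[, seq_len(n_informative)] + shift
    list(x = x, classes = classes)
  })
}
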