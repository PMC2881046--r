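# CTD descriptors, property groupings and the 132-component biochemical block

test_that("hydrophobicity recoding reproduces the printed worked example", {
  r <- protein_record("ex", WORKED_SEQ)
  g <- aa_groupings()$hydrophobicity
  expect_identical(encode_sequence(r, g), WORKED_CODED)
})

test_that("recoding handles homogeneous and two-letter inputs", {
  g <- aa_groupings()$hydrophobicity
  expect_identical(encode_sequence("GGGG", g), "NNNN")
  expect_identical(encode_sequence("RC", g), "PH")
})

test_that("recoding rejects unknown letters and missing tracks by name", {
  g <- aa_groupings()
  expect_error(protein_record("x", "AX!A"), "position 2")
  r <- protein_record("x", "ACDE")
  expect_error(encode_sequence(r, g$secondary_structure),
               "secondary-structure track")
  expect_error(encode_sequence(r, g$solvent_accessibility),
               "accessibility track")
})

test_that("sanitization drops nonstandard residues with a warning", {
  expect_warning(r <- protein_record("x", "ACXDU", sanitize = TRUE),
                 "nonstandard")
  expect_identical(r$sequence, "ACD")
  expect_warning(
    r2 <- protein_record("x", "AXC", ss_track = "HEC", acc_track = "HHE",
                         sanitize = TRUE), "nonstandard")
  expect_identical(r2$ss_track, "HC")
})

test_that("worked-example composition, transition and distribution are exact", {
  cats <- c("P", "N", "H")
  comp <- ctd_composition(WORKED_CODED, cats)
  expect_equal(unname(comp), c(24, 16, 10) / 50)
  tran <- ctd_transition(WORKED_CODED, cats)
  expect_equal(unname(tran), c(16, 7, 8) / 31)  # PN, PH, NH
  dist <- ctd_distribution(WORKED_CODED, cats)
  expect_equal(unname(dist[1:5]), c(6, 24, 44, 64, 100) / 100)   # P
  expect_equal(unname(dist[6:10]), c(4, 28, 54, 78, 98) / 100)   # N
  expect_equal(unname(dist[11:15]), c(2, 20, 36, 74, 92) / 100)  # H
})

test_that("degenerate coded strings follow the zero conventions", {
  cats <- c("P", "N", "H")
  expect_equal(unname(ctd_composition("NNNN", cats)), c(0, 1, 0))
  expect_equal(unname(ctd_composition("PH", cats)), c(0.5, 0, 0.5))
  expect_equal(unname(ctd_transition("NNNN", cats)), c(0, 0, 0))
  expect_equal(unname(ctd_transition("PNPNP", cats)), c(1, 0, 0))
  d <- ctd_distribution("PPPP", cats)
  expect_equal(unname(d[1:5]), c(0.25, 0.25, 0.50, 0.75, 1.00))
  expect_equal(unname(d[6:15]), rep(0, 10))
  expect_error(ctd_composition("", cats), "empty")
  expect_error(ctd_transition("", cats), "empty")
  expect_error(ctd_distribution("", cats), "empty")
})

test_that("ctd_block layout: 21 components for 3 categories, 7 for accessibility", {
  g <- aa_groupings()
  r <- protein_record("ex", WORKED_SEQ)
  b <- ctd_block(r, g$hydrophobicity)
  expect_length(b, 21)
  expect_equal(unname(b[1:3]), c(0.48, 0.32, 0.20))
  len <- nchar(WORKED_SEQ)
  r2 <- protein_record("ex", WORKED_SEQ,
                       acc_track = paste(rep(c("H", "E"), length.out = len),
                                         collapse = ""))
  expect_length(ctd_block(r2, g$solvent_accessibility), 7)
  b3 <- ctd_block(protein_record("g", "GGGG"), g$hydrophobicity)
  expect_equal(unname(b3),
               c(0, 1, 0, 0, 0, 0, rep(0, 5),
                 c(0.25, 0.25, 0.50, 0.75, 1.00), rep(0, 5)))
})

test_that("CTD normalization and monotonicity hold on random coded strings", {
  set.seed(42)
  cats <- c("A", "B", "Z")
  for (i in 1:50) {
    coded <- random_coded(sample(1:60, 1), cats)
    comp <- ctd_composition(coded, cats)
    expect_equal(sum(comp), 1)
    tran <- ctd_transition(coded, cats)
    letters <- unlist(strsplit(coded, ""))
    n <- nchar(coded)
    has_trans <- n > 1 && any(letters[-1] != letters[-n])
    expect_equal(sum(tran), if (has_trans) 1 else 0)
    dist <- ctd_distribution(coded, cats)
    for (k in seq_along(cats)) {
      tup <- dist[(5 * (k - 1) + 1):(5 * k)]
      expect_true(all(diff(tup) >= 0))
      occ <- which(letters == cats[k])
      if (length(occ)) expect_equal(unname(tup[5]), max(occ) / n)
    }
    # first occurrence of the reversed string mirrors the last of the original
    rev_coded <- paste(rev(letters), collapse = "")
    for (k in seq_along(cats)) {
      occ <- which(letters == cats[k])
      if (length(occ)) {
        rd <- ctd_distribution(rev_coded, cats)
        expect_equal(unname(rd[5 * (k - 1) + 1]), (n - max(occ) + 1) / n)
      }
    }
  }
})

test_that("ctd_block agrees with the brute-force enumeration oracle", {
  set.seed(7)
  g <- aa_groupings()
  for (i in 1:20) {
    r <- random_protein(sample(10:80, 1))
    for (gr in g[c("hydrophobicity", "vdw_volume", "polarity",
                   "polarizability", "secondary_structure")]) {
      coded <- encode_sequence(r, gr)
      ora <- oracle_ctd(coded, gr$categories)
      b <- ctd_block(r, gr)
      expect_equal(unname(b), c(ora$composition, ora$transition,
                                ora$distribution))
    }
    acc <- g$solvent_accessibility
    ora <- oracle_ctd(encode_sequence(r, acc), acc$categories)
    expect_equal(unname(ctd_block(r, acc)),
                 c(ora$composition[1], ora$transition, ora$distribution[1:5]))
  }
})

test_that("amino-acid composition uses the fixed residue order and sums to 1", {
  a <- aac_vector("AAAA")
  expect_equal(sum(a), 1)
  expect_equal(unname(a["AAC.A"]), 1)
  b <- aac_vector("RK")
  expect_equal(unname(b[c("AAC.R", "AAC.K")]), c(0.5, 0.5))
  w <- aac_vector(WORKED_SEQ)
  expect_equal(sum(w), 1)
  expect_equal(unname(w["AAC.E"]), 8 / 50)  # direct count in the printed 50-mer
})

test_that("biochemical vector is 132 components in the fixed block order", {
  set.seed(11)
  r <- random_protein(60)
  v <- biochemical_vector(r)
  expect_length(v, 132)
  g <- aa_groupings()
  expect_equal(unname(v[1:21]), unname(ctd_block(r, g$hydrophobicity)))
  expect_equal(unname(v[22:42]), unname(ctd_block(r, g$secondary_structure)))
  expect_equal(unname(v[43:49]), unname(ctd_block(r, g$solvent_accessibility)))
  expect_equal(unname(v[50:70]), unname(ctd_block(r, g$vdw_volume)))
  expect_equal(unname(v[71:91]), unname(ctd_block(r, g$polarity)))
  expect_equal(unname(v[92:112]), unname(ctd_block(r, g$polarizability)))
  expect_equal(unname(v[113:132]), unname(aac_vector(r)))
  expect_identical(v, biochemical_vector(r))  # deterministic
  worked <- protein_record("w", WORKED_SEQ)
  expect_error(biochemical_vector(worked), "track")
  vw <- biochemical_vector(worked, annotate = TRUE)
  expect_equal(unname(vw[1:3]), c(0.48, 0.32, 0.20))
})

test_that("property groupings validate their invariants", {
  expect_error(property_grouping("bad", c("A"), c(x = "A")), "2 or 3")
  expect_error(property_grouping("bad", c("A", "B"), c(x = "A", y = "C"),
                                 source = "ss"), "unknown category")
  expect_error(property_grouping("bad", c("A", "B"), c(x = "A", y = "A"),
                                 source = "ss"), "at least one letter")
  # sequence groupings must partition the full 20-letter alphabet
  expect_error(property_grouping("bad", c("A", "B"),
                                 c(G = "A", P = "B")), "20 canonical")
  for (g in aa_groupings())
    if (g$source == "sequence")
      expect_setequal(names(g$assignment),
                      c("A","C","D","E","F","G","H","I","K","L",
                        "M","N","P","Q","R","S","T","V","W","Y"))
})
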