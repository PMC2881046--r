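# Half-life labels, length filter, enrichment scores, 376-vector assembly
# and standardization

test_that("PSI maps to half-life classes with the stated bin boundaries", {
  expect_equal(as.character(psi_to_class(c(1.5, 2.0, 2.9, 3.0, 3.99, 4.0))),
               c("short", "medium", "medium", "long", "long", "extra_long"))
  expect_error(psi_to_class(NaN), "finite")
  expect_error(psi_to_class(Inf), "finite")
  # step function: class is monotone nondecreasing in PSI
  psi <- sort(runif(200, -1, 7))
  cls <- as.integer(psi_to_class(psi))
  expect_true(all(diff(cls) >= 0))
  expect_equal(as.character(coarse_class(c("short", "medium", "long", "extra_long"))),
               c("short_medium", "short_medium",
                 "long_extra_long", "long_extra_long"))
})

test_that("length filter keeps the inclusive 50..2700 range and logs exclusions", {
  mk <- function(len) protein_record(paste0("p", len),
                                     strrep("A", len))
  recs <- lapply(c(49, 50, 2700, 2701), mk)
  out <- length_filter(recs)
  expect_equal(vapply(out$retained, function(r) nchar(r$sequence), 1L),
               c(50L, 2700L))
  expect_equal(nrow(out$excluded), 2)
  expect_match(out$excluded$reason[1], "shorter than 50")
  expect_match(out$excluded$reason[2], "longer than 2700")
  expect_equal(length(length_filter(list())$retained), 0)
  ok <- lapply(c(60, 100, 500), mk)
  out2 <- length_filter(ok)
  expect_equal(length(out2$retained), 3)
  expect_equal(nrow(out2$excluded), 0)
})

test_that("enrichment score matches the exhaustive hypergeometric oracle", {
  u <- paste0("g", 1:20)
  s <- kegg_enrichment_score(c("g1", "g2", "g3", "g19"), paste0("g", 1:5), u)
  expect_equal(s, -log10(155 / 4845), tolerance = 1e-12)
  expect_equal(s, -log10(oracle_hyper_tail(3, 5, 20, 4)), tolerance = 1e-12)
  # overlap 0 and the certain event both score 0
  expect_equal(kegg_enrichment_score(paste0("g", 6:9), paste0("g", 1:5), u), 0)
  expect_equal(kegg_enrichment_score(u, u, u), 0)
  expect_equal(kegg_enrichment_score(character(0), paste0("g", 1:5), u), 0)
  expect_error(kegg_enrichment_score("g1", c("g1", "zz"), u), "universe")

  set.seed(3)
  for (i in 1:40) {
    N <- sample(8:30, 1)
    uni <- paste0("g", seq_len(N))
    K <- sample(2:(N - 1), 1)
    n <- sample(1:(N - 1), 1)
    pathway <- sample(uni, K)
    neigh <- sample(uni, n)
    k <- length(intersect(neigh, pathway))
    got <- kegg_enrichment_score(neigh, pathway, uni)
    want <- if (k == 0) 0 else -log10(oracle_hyper_tail(k, K, N, n))
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("enrichment score is nonincreasing as the overlap shrinks", {
  u <- paste0("g", 1:30)
  pathway <- paste0("g", 1:10)
  scores <- sapply(5:0, function(k) {
    neigh <- paste0("g", c(seq_len(k), 10 + seq_len(5 - k)))
    kegg_enrichment_score(neigh, pathway, u)
  })
  expect_true(all(diff(scores) <= 1e-12))
  expect_equal(scores[6], 0)
})

test_that("feature vectors assemble to the fixed 376-component layout", {
  set.seed(5)
  r <- random_protein(75)
  bio <- biochemical_vector(r)
  flags <- rbinom(22, 1, 0.3)
  kegg <- rexp(220)
  v <- assemble_feature_vector(r, bio, flags, kegg, 3L)
  expect_length(v, 376)
  expect_identical(names(v), feature_names())
  expect_equal(unname(v["V133"]), 75)
  expect_equal(unname(v[paste0("V", 134:155)]), flags)
  expect_equal(unname(v[paste0("V", 156:375)]), kegg)
  expect_equal(unname(v["V376"]), 3)
  # all-zero metadata tail
  v0 <- assemble_feature_vector(r, bio, rep(0, 22), rep(0, 220), 0L)
  expect_equal(unname(v0[133:376]), c(75, rep(0, 22), rep(0, 220), 0))
  expect_identical(v, assemble_feature_vector(r, bio, flags, kegg, 3L))
  expect_error(assemble_feature_vector(r, bio[-1], flags, kegg, 1),
               "'biochemical'")
  expect_error(assemble_feature_vector(r, bio, flags[-1], kegg, 1),
               "'location_flags'")
  expect_error(assemble_feature_vector(r, bio, flags, kegg[-1], 1),
               "'kegg_scores'")
  expect_error(assemble_feature_vector(r, bio, flags, kegg, -1),
               "'complex_count'")
  expect_error(assemble_feature_vector(r, bio, flags + 5, kegg, 1), "binary")
})

test_that("standardization gives zero-mean unit-sd columns and is idempotent", {
  set.seed(8)
  x <- cbind(a = c(1, 2, 3), b = rnorm(3), const = c(5, 5, 5))
  out <- standardize(x)
  expect_equal(unname(out$x[, "a"]), c(-1, 0, 1))
  expect_equal(colMeans(out$x), c(a = 0, b = 0, const = 0))
  expect_equal(unname(out$x[, "const"]), c(0, 0, 0))
  again <- standardize(out$x)
  expect_equal(again$x, out$x, tolerance = 1e-10)
  expect_error(standardize(x[1, , drop = FALSE]), "at least 2")

  m <- matrix(rnorm(200), 20, 10)
  z <- standardize(m)$x
  expect_equal(colMeans(z), rep(0, 10), tolerance = 1e-12)
  expect_equal(apply(z, 2, sd), rep(1, 10), tolerance = 1e-12)
  # row permutation equivariance
  p <- sample(20)
  expect_equal(standardize(m[p, ])$x, z[p, ])
})

test_that("fitted parameters reproduce training rows on held-out application", {
  set.seed(9)
  m <- matrix(rnorm(60), 12, 5)
  out <- standardize(m)
  expect_equal(apply_standardization(m, out$params), out$x)
  expect_equal(apply_standardization(out$params$mean, out$params),
               rep(0, 5), ignore_attr = TRUE)
  p1 <- structure(list(mean = rep(0, 3), sd = rep(1, 3)),
                  class = "standardization_params")
  expect_equal(unname(apply_standardization(c(2, 0, 1), p1)), c(2, 0, 1))
  expect_error(apply_standardization(m, list(mean = 1)), "fitted")
  expect_error(apply_standardization(m[, 1:3], out$params), "mismatch")
})
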