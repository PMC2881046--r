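# Independent brute-force oracles. These deliberately avoid the package's
# code paths: plain loops, explicit enumeration and choose()-based sums.

WORKED_SEQ <- "MSDKPDMAEIEKFSKETIEQEKQAGESTQEKNPLPMLLPATDKSKLKKTE"
WORKED_CODED <- "HNPPNPHNPHPPHNPPNHPPPPPNNPNNPPPPNHNHHHNNNPPNPHPPNP"

# CTD of a coded string by position-by-position enumeration
oracle_ctd <- function(coded, categories) {
  letters <- unlist(strsplit(coded, ""))
  n <- length(letters)
  comp <- sapply(categories, function(cc) {
    k <- 0L
    for (l in letters) if (l == cc) k <- k + 1L
    k / n
  })
  # all unordered pairs, in first-index order
  pairs <- list()
  for (i in seq_along(categories))
    for (j in seq_along(categories))
      if (i < j) pairs[[length(pairs) + 1L]] <- categories[c(i, j)]
  diffs <- 0L
  pair_counts <- integer(length(pairs))
  for (p in seq_len(n - 1L)) {
    a <- letters[p]; b <- letters[p + 1L]
    if (a != b) {
      diffs <- diffs + 1L
      for (q in seq_along(pairs)) {
        pr <- pairs[[q]]
        if ((a == pr[1] && b == pr[2]) || (a == pr[2] && b == pr[1]))
          pair_counts[q] <- pair_counts[q] + 1L
      }
    }
  }
  trans <- if (diffs == 0L) rep(0, length(pairs)) else pair_counts / diffs
  dist <- numeric(0)
  for (cc in categories) {
    occ <- integer(0)
    for (p in seq_len(n)) if (letters[p] == cc) occ <- c(occ, p)
    tup <- if (length(occ) == 0L) rep(0, 5) else {
      sapply(c(0, .25, .5, .75, 1), function(q) {
        idx <- ceiling(q * length(occ))
        if (idx < 1L) idx <- 1L
        occ[idx] / n
      })
    }
    dist <- c(dist, tup)
  }
  list(composition = unname(comp), transition = trans, distribution = dist)
}

# plug-in mutual information by double loop over observed cells
oracle_mi <- function(x, y, base = 2) {
  n <- length(x)
  ux <- unique(x); uy <- unique(y)
  total <- 0
  for (a in ux) for (b in uy) {
    pxy <- sum(x == a & y == b) / n
    if (pxy > 0) {
      px <- sum(x == a) / n
      py <- sum(y == b) / n
      total <- total + pxy * log(pxy / (px * py), base = base)
    }
  }
  total
}

# upper-tail hypergeometric P(X >= k) by exhaustive choose() summation
oracle_hyper_tail <- function(k, K, N, n) {
  js <- k:min(K, n)
  js <- js[js >= max(0, n - (N - K))]
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# standalone column scaling for the jackknife oracle
oracle_scale <- function(train, query) {
  mu <- colMeans(train)
  sdv <- apply(train, 2, sd)
  s <- ifelse(sdv > 0, sdv, 1)
  zt <- sweep(sweep(train, 2, mu), 2, s, "/")
  zt[, sdv == 0] <- 0
  zq <- (query - mu) / s
  zq[sdv == 0] <- 0
  list(train = zt, query = zq)
}

oracle_cosd <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(2)
  1 - sum(a * b) / (na * nb)
}

# leave-one-out NN accuracy by explicit per-fold loops
oracle_jackknife <- function(x, labels, paper_mode = FALSE) {
  n <- nrow(x)
  labels <- as.character(labels)
  pred <- character(n)
  if (paper_mode) {
    mu <- colMeans(x); sdv <- apply(x, 2, sd)
    s <- ifelse(sdv > 0, sdv, 1)
    z <- sweep(sweep(x, 2, mu), 2, s, "/")
    z[, sdv == 0] <- 0
    for (i in seq_len(n)) {
      best <- Inf; pick <- NA_integer_
      for (j in seq_len(n)) {
        if (j == i) next
        d <- oracle_cosd(z[i, ], z[j, ])
        if (d < best) { best <- d; pick <- j }
      }
      pred[i] <- labels[pick]
    }
  } else {
    for (i in seq_len(n)) {
      sc <- oracle_scale(x[-i, , drop = FALSE], x[i, ])
      best <- Inf; pick <- NA_integer_
      others <- seq_len(n)[-i]
      for (j in seq_len(nrow(sc$train))) {
        d <- oracle_cosd(sc$query, sc$train[j, ])
        if (d < best) { best <- d; pick <- others[j] }
      }
      pred[i] <- labels[pick]
    }
  }
  mean(pred == labels)
}

random_coded <- function(n, categories) {
  paste(sample(categories, n, replace = TRUE), collapse = "")
}

random_protein <- function(len, id = "p1") {
  aas <- c("A","C","D","E","F","G","H","I","K","L",
           "M","N","P","Q","R","S","T","V","W","Y")
  protein_record(id, paste(sample(aas, len, replace = TRUE), collapse = ""),
                 ss_track = paste(sample(c("H","E","C"), len, TRUE), collapse = ""),
                 acc_track = paste(sample(c("H","E"), len, TRUE), collapse = ""))
}
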