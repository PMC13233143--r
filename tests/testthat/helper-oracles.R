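# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: enumeration, naive scanning, and brute-force
# definitions only.

# Upper-tail hypergeometric probability by exhaustive enumeration of all
# n-subsets of a population with K successes among N.
enum_hypergeom_tail <- function(N, K, n, k) {
  if (n == 0) return(as.numeric(k <= 0))
  subsets <- utils::combn(N, n)
  pos <- seq_len(K) # first K population members are "positive"
  hits <- apply(subsets, 2, function(s) sum(s %in% pos))
  mean(hits >= k)
}

# Brute-force Benjamini-Hochberg step-up: reject the i* smallest p-values
# where i* is the largest i with p_(i) <= i * alpha / m.
brute_bh_flags <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  ok <- which(ps <= seq_len(m) * alpha / m)
  flags <- logical(m)
  if (length(ok) > 0) flags[ord[seq_len(max(ok))]] <- TRUE
  flags
}

# Naive sliding-window occurrence scan (overlaps counted).
naive_occurrences <- function(motif, sequence) {
  l <- nchar(motif)
  n <- nchar(sequence)
  if (n < l) return(integer(0))
  starts <- seq_len(n - l + 1)
  starts[substring(sequence, starts, starts + l - 1) == motif] - 1L
}

# Naive per-motif (n, k, positions) over a sequence set.
naive_count <- function(motifs, sequences, labels) {
  purrr::map_dfr(motifs, function(m) {
    occ <- purrr::map(sequences, naive_occurrences, motif = m)
    present <- lengths(occ) > 0
    tibble::tibble(motif = m, n = sum(present),
                   k = sum(present & labels == 1),
                   total_occurrences = sum(lengths(occ)))
  })
}

# Two-sided Fisher exact p by enumeration over all tables with the observed
# margins: sum the probabilities of tables no more likely than the observed.
enum_fisher_p <- function(a, b, c_, d) {
  r1 <- a + b; c1 <- a + c_; n <- a + b + c_ + d
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(ks, c1, n - c1, r1)
  obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Shapley values by averaging marginal contributions over all orderings.
perm_shapley <- function(scorer, J) {
  perms <- combinat_perms(J)
  phi <- numeric(J)
  for (p in perms) {
    mask <- rep(FALSE, J)
    prev <- scorer(mask)
    for (j in p) {
      mask[j] <- TRUE
      cur <- scorer(mask)
      phi[j] <- phi[j] + (cur - prev)
      prev <- cur
    }
  }
  phi / length(perms)
}

combinat_perms <- function(J) {
  if (J == 1) return(list(1L))
  out <- list()
  for (p in combinat_perms(J - 1)) {
    for (pos in 0:(J - 1)) {
      out[[length(out) + 1]] <- append(p, J, after = pos)
    }
  }
  out
}

# Trapezoidal integral of a curve.
trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# Random DNA string helper.
random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Mutate a sequence by substituting a given fraction of positions.
mutate_seq <- function(s, rate) {
  v <- strsplit(s, "")[[1]]
  idx <- which(stats::runif(length(v)) < rate)
  v[idx] <- vapply(v[idx], function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1)
  }, character(1))
  paste(v, collapse = "")
}
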