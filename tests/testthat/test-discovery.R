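toy_profile <- function(weights, seq_len = NULL, k = 3) {
  J <- dim(weights)[3]
  s <- strrep("ACG", J)
  attention_profile("p1", tokenize_sequence(s, k = k), weights,
                    list(label = 1L, logit = 1, probability = 0.7))
}

test_that("head aggregation averages heads and matches sum-aggregation after normalization", {
  w <- array(0, dim = c(1, 2, 3))
  w[1, 1, ] <- c(0.2, 0.3, 0.5)
  w[1, 2, ] <- c(0.4, 0.4, 0.2)
  pr <- toy_profile(w)
  expect_equal(aggregate_heads(pr, 1), c(0.3, 0.35, 0.35))

  set.seed(8)
  for (i in 1:20) {
    H <- sample(1:6, 1); J <- sample(3:30, 1)
    w <- array(runif(H * J), dim = c(1, H, J))
    w <- sweep(w, c(1, 2), apply(w, c(1, 2), sum), "/")
    pr <- toy_profile(w)
    a_mean <- aggregate_heads(pr, 1)
    a_sum <- colSums(matrix(w[1, , ], nrow = H))
    expect_equal(normalize_scores(a_mean), normalize_scores(a_sum),
                 tolerance = 1e-12)
  }
})

test_that("max-normalization puts exactly the argmax at 1", {
  expect_equal(normalize_scores(c(0.2, 0.4)), c(0.5, 1))
  expect_equal(normalize_scores(c(2, 2, 2)), c(1, 1, 1))
  set.seed(4)
  a <- runif(50) + 0.01
  s <- normalize_scores(a)
  expect_equal(which(s == 1), which.max(a))
  expect_error(normalize_scores(c(0, 0)), "all-zero")
})

test_that("layer specificity follows the z-score form with sample sd", {
  expect_equal(layer_specificity(c(1, 1, 1, 1)), 0)
  expect_equal(layer_specificity(c(1, 0, 0, 0)), 1.5)
  expect_error(layer_specificity(1), "two tokens")
})

test_that("layer selection strategies combine and rank layers as designed", {
  J <- 10
  flat <- rep(1, J)
  peaked <- normalize_scores(c(rep(0.05, J - 1), 1))
  m <- rbind(flat, flat, flat, peaked)  # only final layer informative
  comb <- select_layers(m, strategy = "mid_final")
  expect_equal(which.max(comb), J)
  expect_equal(max(comb), 1)

  same <- rbind(peaked, peaked, peaked, peaked)
  expect_equal(select_layers(same, "mid_final"), peaked)

  sp_pick <- select_layers(m, strategy = "top_sp")
  expect_equal(sp_pick, peaked)
  expect_equal(select_layers(m, "single", layer = 1), flat / max(flat))

  m12 <- matrix(rep(flat, 12), nrow = 12, byrow = TRUE)
  m12[12, ] <- peaked
  expect_equal(which.max(select_layers(m12, "mid_final")), J)
})

test_that("candidate selection concatenates runs of passing tokens", {
  s_hat <- c(1.0, 0.9, 0.1, 0.05)
  spans <- tokenize_sequence("AAACCCGGGTTT", k = 3)
  cand <- select_candidate_motifs(s_hat, spans, "AAACCCGGGTTT")
  expect_equal(nrow(cand), 1)
  expect_equal(cand$motif, "AAACCC")
  expect_equal(c(cand$start, cand$end), c(0L, 6L))

  # all-equal scores: nothing exceeds the strict mean
  expect_equal(nrow(select_candidate_motifs(rep(1, 4), spans, "AAACCCGGGTTT")), 0)

  # single passing 3 bp token dropped by the length floor
  spans3 <- tokenize_sequence("AAACCCGGG", k = 3)
  cand3 <- select_candidate_motifs(c(1, 0.05, 0.04), spans3, "AAACCCGGG")
  expect_equal(nrow(cand3), 0)
})

test_that("automaton occurrence counts equal naive scanning", {
  occ <- count_motif_occurrences("ACGT", "ACGTACGT", labels = 1L)
  expect_equal(occ$stats$n, 1L)
  expect_equal(occ$stats$k, 1L)
  expect_equal(occ$stats$total_occurrences, 2L)

  occ2 <- count_motif_occurrences("AAA", "AAAA", labels = 0L)
  expect_equal(occ2$stats$total_occurrences, 2L)  # overlaps counted
  expect_equal(occ2$instances$start, c(0L, 1L))

  set.seed(19)
  motifs <- unique(replicate(25, random_dna(sample(4:8, 1))))
  seqs <- replicate(40, random_dna(300))
  labels <- rep(c(1L, 0L), length.out = 40)
  got <- count_motif_occurrences(motifs, seqs, labels)
  want <- naive_count(motifs, seqs, labels)
  expect_equal(dplyr::arrange(got$stats, motif),
               dplyr::arrange(want, motif))
  # positions agree too
  for (m in motifs[1:5]) {
    ours <- got$instances[got$instances$motif == m, ]
    naive <- purrr::imap_dfr(seqs, ~ tibble::tibble(
      start = naive_occurrences(m, .x), sequence_id = paste0("seq_", .y)))
    expect_equal(dplyr::arrange(ours[, c("sequence_id", "start")],
                                sequence_id, start),
                 dplyr::arrange(naive[, c("sequence_id", "start")],
                                sequence_id, start))
  }
  expect_error(count_motif_occurrences("ACGN", "ACGT", 1L), "ACGT")
})

test_that("hypergeometric tail matches exhaustive enumeration and hand values", {
  expect_equal(hypergeom_enrichment(10, 5, 4, 4), 5 / 210, tolerance = 1e-12)
  expect_equal(hypergeom_enrichment(4, 2, 2, 2), 1 / 6, tolerance = 1e-12)
  expect_equal(hypergeom_enrichment(10, 5, 4, 0), 1)
  expect_equal(hypergeom_pmf(10, 5, 4, 4), 5 / 210, tolerance = 1e-12)
  for (N in c(5, 8)) for (K in c(2, N %/% 2)) for (n in c(2, 4)) {
    for (k in max(0, n - (N - K)):min(K, n)) {
      expect_equal(hypergeom_enrichment(N, K, n, k),
                   enum_hypergeom_tail(N, K, n, k), tolerance = 1e-12)
    }
  }
  expect_error(hypergeom_enrichment(10, 5, 4, 5), "inconsistent")
})

test_that("BH correction reproduces the step-up definition", {
  one <- fdr_correct(0.005, alpha = 0.01)
  expect_equal(one$q, 0.005)
  expect_true(one$significant)
  expect_equal(fdr_correct(c(0.001, 0.02, 0.03))$q, c(0.003, 0.03, 0.03))
  expect_false(any(fdr_correct(rep(1, 5))$significant))

  set.seed(23)
  for (i in 1:50) {
    m <- sample(1:40, 1)
    p <- round(runif(m)^sample(1:3, 1), sample(2:4, 1))
    for (alpha in c(0.01, 0.05)) {
      expect_identical(fdr_correct(p, alpha)$significant,
                       brute_bh_flags(p, alpha))
    }
  }
})

test_that("sparse motifs are dropped at the instance floor", {
  stats <- tibble::tibble(motif = c("a", "b", "c"),
                          total_occurrences = c(2L, 3L, 10L))
  expect_equal(filter_min_instances(stats)$motif, c("b", "c"))
  expect_equal(nrow(filter_min_instances(stats[0, ])), 0)
})

test_that("gapless merging collapses overlapping motifs into the documented consensus", {
  m <- merge_motifs(c("ACGTAC", "CGTACG"))
  expect_equal(m$consensus, "ACGTACG")
  expect_equal(m$n_members, 2L)

  ident <- merge_motifs(c("ACGTAC", "ACGTAC"))
  expect_equal(nrow(ident), 1)

  apart <- merge_motifs(c("AAAA", "CCCC"))
  expect_equal(nrow(apart), 2)

  # idempotence: merging the consensi changes nothing
  again <- merge_motifs(m$consensus)
  expect_equal(again$consensus, m$consensus)

  # input order does not change the consensus set
  set.seed(6)
  pool <- c("GCACGTCA", "CACGTCAT", "GGCACGTC", "TTTTAAAA")
  for (i in 1:5) {
    perm <- sample(pool)
    expect_setequal(merge_motifs(perm)$consensus, merge_motifs(pool)$consensus)
  }
})

test_that("instance windows are centered, flanked, and clipped at bounds", {
  seqs <- c(s1 = strrep("ACGT", 50))
  inst <- tibble::tibble(motif = "M", sequence_id = "s1",
                         start = c(100L, 2L), end = c(106L, 8L))
  w <- extract_instance_windows(inst, seqs, flank = 12)
  expect_equal(c(w$win_start[1], w$win_end[1]), c(91L, 115L))
  expect_equal(nchar(w$window[1]), 24)
  expect_false(w$clipped[1])
  expect_equal(w$win_start[2], 0L)
  expect_true(w$clipped[2])
  td <- withr::local_tempfile(fileext = ".fa")
  extract_instance_windows(inst, seqs, path = td)
  b1 <- readBin(td, "raw", file.size(td))
  extract_instance_windows(inst, seqs, path = td)
  expect_identical(b1, readBin(td, "raw", file.size(td)))
})

test_that("set difference isolates model-B-specific motifs", {
  expect_equal(motif_set_difference(c("m1", "m2"), "m2"), "m1")
  expect_equal(motif_set_difference(c("AAAA", "CCCC"), character(0)),
               c("AAAA", "CCCC"))
  # one-mismatch 6-mers count as shared in similarity mode at 0.8
  expect_equal(motif_set_difference("ACGTAC", "ACGTAT",
                                    matching = "similarity"), character(0))
  expect_equal(motif_set_difference("ACGTAC", "ACGTAT"), "ACGTAC")
})

test_that("end-to-end discovery finds a strongly planted motif and nothing from flat profiles", {
  spec <- planted_dataset_spec(n_pos = 40, n_neg = 40, upstream = 600,
                               downstream = 200, seed = 42)
  rec <- generate_planted_dataset(spec)
  d <- discover_motifs(rec, toy_attention_provider(seed = 42))
  expect_s3_class(d, "motif_discovery")
  expect_gt(sum(d$motifs$significant), 0)
  expect_equal(evaluate_recovery(d$merged$consensus, spec$motif)$recall, 1)
  expect_true(all(d$motifs$q >= d$motifs$p))

  # kappa = 0: uniform attention, no candidates, empty but valid result
  d0 <- discover_motifs(rec, toy_attention_provider(kappa = 0, seed = 1))
  expect_equal(nrow(d0$motifs), 0)
  expect_equal(nrow(glance(d0)), 1)
})
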