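test_that("instances map to genomic coordinates with strand adjustment", {
  prov_tbl <- tibble::tibble(transcript_id = c("p", "m"), chrom = "c1",
                             tss = 10000, strand = c("+", "-"),
                             upstream = 3000, downstream = 1000)
  inst <- tibble::tibble(sequence_id = c("p", "m"), motif = "M",
                         start = 2850L, end = 2856L)
  g <- instance_to_genomic(inst, prov_tbl)
  expect_equal(g$genomic_start[g$sequence_id == "p"], 9850)
  expect_equal(g$tss_distance, c(-150, -150))
  # minus strand: genomic_start = (tss + upstream) - end
  expect_equal(g$genomic_start[g$sequence_id == "m"], 13000 - 2856)

  at_tss <- instance_to_genomic(
    tibble::tibble(sequence_id = "p", start = 3000L, end = 3006L), prov_tbl)
  expect_equal(at_tss$tss_distance, 0)
  expect_error(instance_to_genomic(
    tibble::tibble(sequence_id = "zz", start = 1L, end = 2L), prov_tbl),
    "provenance")
})

test_that("minus-strand mapping round-trips through the genome", {
  g <- setNames(generate_toy_genome(1, 8000, seed = 14), "c1")
  ann <- tibble::tibble(transcript_id = "t", chrom = "c1", tss = 5000,
                        strand = "-", tissue = "toy", expression_group = "TSp")
  rec <- extract_promoter_windows(ann, g, upstream = 2000, downstream = 500)
  inst_start <- 700L; inst_end <- 712L
  sub <- substr(rec$sequence, inst_start + 1, inst_end)
  gi <- instance_to_genomic(
    tibble::tibble(sequence_id = "t", start = inst_start, end = inst_end),
    dplyr::select(rec, transcript_id, chrom, tss, strand, upstream, downstream))
  genomic <- substr(g, gi$genomic_start + 1, gi$genomic_end)
  expect_equal(revcomp(genomic), sub)
})

test_that("tss distances survive a genome-wide strand reflection", {
  g <- setNames(generate_toy_genome(1, 6000, seed = 15), "c1")
  len <- nchar(g)
  ann <- tibble::tibble(transcript_id = paste0("t", 1:4), chrom = "c1",
                        tss = c(2000, 2500, 3000, 3500),
                        strand = c("+", "-", "+", "-"),
                        tissue = "toy", expression_group = "TSp")
  rec <- extract_promoter_windows(ann, g, 1000, 400)
  ann_f <- dplyr::mutate(ann, tss = len - tss,
                         strand = ifelse(strand == "+", "-", "+"))
  rec_f <- extract_promoter_windows(ann_f, setNames(revcomp(g), "c1"), 1000, 400)
  expect_identical(rec$sequence, rec_f$sequence)
  # identical windows => identical instance offsets => identical tss distances
  motif <- substr(rec$sequence[1], 501, 508)
  for (i in 1:4) {
    expect_identical(naive_occurrences(motif, rec$sequence[i]),
                     naive_occurrences(motif, rec_f$sequence[i]))
  }
})

test_that("binned means use the half-open TSS-anchored grid and group-by oracle", {
  inst <- tibble::tibble(tss_distance = c(-150, -150, -50, 0, 120),
                         attention = c(1, 3, 2, 5, 4))
  pp <- bin_attention_by_distance(inst)
  expect_s3_class(pp, "positional_profile")
  b <- pp$bins
  expect_equal(b$bin_start, c(-200, -100, 0, 100))
  expect_equal(b$mean_attention, c(2, 2, 5, 4))  # -150 in [-200,-100); 0 in [0,100)
  expect_equal(sum(b$count), nrow(inst))

  set.seed(27)
  rnd <- tibble::tibble(tss_distance = sample(-1500:499, 300, TRUE),
                        attention = runif(300))
  got <- bin_attention_by_distance(rnd)$bins
  oracle <- dplyr::summarise(
    dplyr::group_by(rnd, bin = floor(tss_distance / 100) * 100),
    m = mean(attention), .groups = "drop")
  expect_equal(got$mean_attention, dplyr::arrange(oracle, bin)$m)
  # order invariance
  perm <- rnd[sample(nrow(rnd)), ]
  expect_equal(bin_attention_by_distance(perm)$bins, got)
})

test_that("rolling smoothing averages available neighbors only", {
  inst <- tibble::tibble(tss_distance = c(50, 150, 250),
                         attention = c(1, 2, 3))
  b <- bin_attention_by_distance(inst)$bins
  expect_equal(b$smoothed, c(1.5, 2, 2.5))  # edges use available neighbors
})

test_that("the KDE is symmetric, unit-mass, and mode-faithful", {
  sym <- kde_distance_density(c(-300, 300, -300, 300))
  mid <- which.min(abs(sym$distance))
  expect_equal(sym$density, rev(sym$density), tolerance = 1e-9)
  expect_equal(trapz(sym$distance, sym$density), 1, tolerance = 1e-3)

  set.seed(8)
  clus <- rnorm(200, -1400, 30)
  k <- kde_distance_density(clus)
  expect_equal(trapz(k$distance, k$density), 1, tolerance = 1e-3)
  expect_lt(abs(k$distance[which.max(k$density)] + 1400), attr(k, "bw") + 30)
  expect_error(kde_distance_density(rep(5, 10)), "histogram")
})

test_that("overlap enrichment matches Fisher enumeration and flags extremes", {
  mk <- function(n, inside) tibble::tibble(
    chrom = "c1", start = seq(0, by = 1000, length.out = n),
    end = seq(0, by = 1000, length.out = n) + 100 + ifelse(inside, 0, 0))
  peaks <- tibble::tibble(chrom = "c1", start = seq(0, 9000, 1000),
                          end = seq(0, 9000, 1000) + 100)
  far <- tibble::tibble(chrom = "c1", start = seq(100000, by = 1000,
                                                  length.out = 10),
                        end = seq(100000, by = 1000, length.out = 10) + 100)
  res <- region_overlap_enrichment(mk(10, TRUE), peaks, far)
  expect_equal(res$prop_motif, 1)
  expect_equal(res$prop_background, 0)
  expect_true(res$or_infinite)
  expect_lt(res$p, 1e-4)

  # equal proportions: odds ratio 1
  res2 <- region_overlap_enrichment(
    dplyr::bind_rows(mk(2, TRUE), far[1:2, ]), peaks,
    dplyr::bind_rows(mk(2, TRUE), far[3:4, ]))
  expect_equal(res2$odds_ratio, 1)
  expect_equal(res2$p, 1)
  res3 <- region_overlap_enrichment(
    dplyr::bind_rows(mk(4, TRUE), far[1:4, ]), peaks,
    dplyr::bind_rows(mk(4, TRUE)[1:2, ], far[5:8, ]))
  expect_equal(res3$odds_ratio, (4 * 4) / (4 * 2))

  # 8/2 vs 3/7 table against the enumeration oracle
  mo <- dplyr::bind_rows(mk(8, TRUE), far[1:2, ])
  bg <- dplyr::bind_rows(mk(3, TRUE), far[3:9, ])
  res4 <- region_overlap_enrichment(mo, peaks, bg)
  expect_equal(res4$p, enum_fisher_p(8, 2, 3, 7), tolerance = 1e-12)
  expect_error(region_overlap_enrichment(mo, peaks, peaks[0, ]), "background")
})

test_that("discovery-to-positional wrapper recovers the planted position", {
  spec <- planted_dataset_spec(n_pos = 40, n_neg = 40, upstream = 600,
                               downstream = 200, seed = 42)
  rec <- generate_planted_dataset(spec)
  d <- discover_motifs(rec, toy_attention_provider(seed = 42))
  pp <- positional_profile(d, rec)
  gl <- glance(pp)
  expect_lt(abs(gl$kde_mode + 150), 100)
  expect_true(all(!is.na(pp$bins$mean_attention) |
                    pp$bins$count == 0))
})
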