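genome_fixture <- function(seed = 21, len = 10000, gc = 0.5, mask = 0) {
  generate_toy_genome(n_contigs = 1, contig_length = len, gc = gc,
                      mask_fraction = mask, seed = seed)
}

test_that("window extraction is strand-aware with exact coordinates", {
  g <- c(chr1 = paste(rep("ACGT", 50), collapse = ""))  # 200 bp
  ann <- tibble::tibble(transcript_id = c("t1", "t2"), chrom = "chr1",
                        tss = 100, strand = c("+", "-"),
                        tissue = "brain", expression_group = "TSp")
  rec <- extract_promoter_windows(ann, g, upstream = 50, downstream = 20)
  expect_equal(rec$genomic_start, c(50, 80))
  expect_equal(rec$genomic_end, c(120, 150))
  expect_equal(nchar(rec$sequence), c(70, 70))
  expect_equal(rec$sequence[1], unname(substr(g, 51, 120)))
  expect_equal(rec$sequence[2], revcomp(unname(substr(g, 81, 150))))
})

test_that("reverse-complementing the genome and flipping strands leaves windows invariant", {
  g <- setNames(generate_toy_genome(1, 1000, seed = 2), "c1")
  len <- nchar(g)
  ann <- tibble::tibble(transcript_id = paste0("t", 1:6), chrom = "c1",
                        tss = c(300, 400, 500, 600, 700, 800),
                        strand = rep(c("+", "-"), 3),
                        tissue = "toy", expression_group = "TSp")
  rec <- extract_promoter_windows(ann, g, 150, 50)
  g_flip <- setNames(revcomp(g), "c1")
  ann_flip <- dplyr::mutate(ann, tss = len - tss,
                            strand = ifelse(strand == "+", "-", "+"))
  rec_flip <- extract_promoter_windows(ann_flip, g_flip, 150, 50)
  expect_identical(rec$sequence, rec_flip$sequence)
})

test_that("out-of-bounds windows and unknown contigs are errors, not clips", {
  g <- c(chr1 = strrep("A", 200))
  ann <- tibble::tibble(transcript_id = "t1", chrom = "chr1", tss = 10,
                        strand = "+")
  expect_error(extract_promoter_windows(ann, g, 50, 20), "out of contig bounds")
  ann2 <- dplyr::mutate(ann, chrom = "chrX", tss = 100)
  expect_error(extract_promoter_windows(ann2, g, 50, 20), "absent from genome")
})

test_that("tissue labeling keeps TSp positives and configured negatives only", {
  rec <- tibble::tibble(
    transcript_id = paste0("t", 1:10),
    tissue = c(rep("brain", 4), "liver", rep("brain", 5)),
    expression_group = c("TSp", "TSp", "TSp", "Wide", "TSp", "Null", "Null",
                         "TEn", "Low", "Wide"),
    sequence = strrep("A", 10))
  lab <- label_by_tissue(rec, "brain", negative_groups = c("Wide", "Null"))
  expect_equal(sum(lab$label == 1), 3)  # TSp-liver dropped
  expect_equal(sum(lab$label == 0), 4)  # 2 Wide + 2 Null; TEn/Low dropped
  expect_false("t5" %in% lab$transcript_id)
  counts <- attr(lab, "group_counts")
  expect_equal(sum(counts$n_records), 7)
  expect_error(label_by_tissue(rec, "kidney"), "no TSp")
})

test_that("random negatives avoid the exclusion set and are reproducible", {
  g <- genome_fixture(len = 10000)
  excl <- tibble::tibble(chrom = "contig_1", start = 0, end = 4000)
  neg <- sample_random_negatives(g, excl, n = 20, length = 100, seed = 13)
  expect_equal(nrow(neg), 20)
  expect_true(all(nchar(neg$sequence) == 100))
  expect_false(any(neg$start < 4000))  # no intersection with exclusion
  expect_identical(neg, sample_random_negatives(g, excl, 20, 100, seed = 13))
  full <- tibble::tibble(chrom = "contig_1", start = 0, end = 10000)
  expect_error(sample_random_negatives(g, full, 1, 100, seed = 1,
                                       max_attempts = 50), "attempts")
})

test_that("matched negatives satisfy GC and repeat tolerances on recomputation", {
  g <- c(generate_toy_genome(1, 20000, gc = 0.35, mask_fraction = 0.1, seed = 4),
         generate_toy_genome(1, 20000, gc = 0.65, mask_fraction = 0.1, seed = 5))
  names(g) <- c("lo", "hi")
  pos <- generate_planted_dataset(
    planted_dataset_spec(n_pos = 20, n_neg = 1, upstream = 150,
                         downstream = 50, gc = 0.5, seed = 6))
  pos <- pos[pos$label == 1, ]
  m <- suppressWarnings(
    sample_matched_negatives(g, pos, gc_tolerance = 0.05,
                             repeat_tolerance = 0.15, seed = 8))
  ok <- m$matched
  expect_gt(sum(ok), 0)
  expect_true(all(abs(gc_content(m$sequence[ok]) -
                        gc_content(pos$sequence[ok])) <= 0.05 + 1e-12))
  expect_true(all(abs(repeat_fraction(m$sequence[ok]) -
                        repeat_fraction(pos$sequence[ok])) <= 0.15 + 1e-12))
})

test_that("infeasible GC matching reports per-record failures without aborting", {
  g <- genome_fixture(len = 10000, gc = 0.5)
  pos <- tibble::tibble(sequence = strrep("GC", 100))  # GC = 1.0
  expect_warning(
    m <- sample_matched_negatives(g, pos, gc_tolerance = 0.02,
                                  repeat_tolerance = 0.05, seed = 2,
                                  max_attempts = 100),
    "could not be")
  expect_equal(attr(m, "n_unmatched"), 1)
  expect_false(any(m$matched))
})

test_that("greedy identity clustering groups mutated copies, keeps unrelated apart", {
  set.seed(31)
  expect_equal(max(cluster_reduce(c(a = "ACGTACGT", b = "ACGTACGT"))$cluster), 1)
  r1 <- random_dna(1000); r2 <- random_dna(1000)
  expect_equal(max(cluster_reduce(c(r1, r2))$cluster), 2)
  seeds <- c(random_dna(600), random_dna(600))
  fam <- c(seeds[1], replicate(4, mutate_seq(seeds[1], 0.05)),
           seeds[2], replicate(4, mutate_seq(seeds[2], 0.05)))
  cl <- cluster_reduce(fam)
  expect_equal(max(cl$cluster), 2)
  expect_equal(unname(lengths(split(cl$id, cl$cluster))), c(5, 5))
  expect_equal(sum(cl$is_representative), 2)
})

test_that("stratified splits match ratios per class, partition, and reproduce", {
  rec <- tibble::tibble(transcript_id = paste0("t", 1:200),
                        label = rep(c(0L, 1L), each = 100))
  sp <- stratified_split(rec, seed = 17)
  tab <- table(sp$label, sp$split)
  expect_equal(unname(tab["0", c("train", "validation", "test")]), c(80, 10, 10))
  expect_equal(unname(tab["1", c("train", "validation", "test")]), c(80, 10, 10))
  expect_identical(sp, stratified_split(rec, seed = 17))

  small <- tibble::tibble(label = rep(c(0L, 1L), each = 10))
  tab2 <- table(stratified_split(small, seed = 1)$split,
                stratified_split(small, seed = 1)$label)
  expect_equal(unname(tab2[c("train", "validation", "test"), "0"]), c(8, 1, 1))
  expect_error(stratified_split(tibble::tibble(label = c(0L, 0L, 1L, 1L, 1L)),
                                seed = 1), "at least 3")
})

test_that("dataset FASTA round-trips with structured headers", {
  rec <- tibble::tibble(transcript_id = c("a", "b"), label = c(1L, 0L),
                        tissue = "brain", expression_group = c("TSp", "Wide"),
                        sequence = c("ACGTacgt", "TTTTCCCC"))
  td <- withr::local_tempdir()
  paths <- write_dataset(rec, td)
  fa <- read_fasta(paths[["fasta"]])
  expect_identical(unname(fa), rec$sequence)  # case preserved
  expect_match(names(fa)[1], "^a\\|1\\|all\\|brain\\|TSp$")
})
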