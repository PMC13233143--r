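#' Generate a seed-reproducible toy genome
#'
#' Draws i.i.d. bases at a controlled GC content per contig and soft-masks
#' (lowercases) randomly placed runs until a target masked fraction is
#' reached. The masked runs stand in for repeat annotation, which the
#' GC/repeat-matched negative sampler consumes.
#'
#' @param n_contigs Number of contigs.
#' @param contig_length Length of each contig in bp (>= 1000).
#' @param gc Target GC fraction, recycled across contigs.
#' @param mask_fraction Fraction of each contig to soft-mask, in `[0, 1]`.
#' @param seed Integer seed; the output is bit-reproducible.
#' @param path Optional FASTA path; when given the genome is also written
#'   to disk (case-preserving).
#' @return Named character vector of contig sequences.
#' @export
#' @examples
#' g <- generate_toy_genome(1, 2000, gc = 0.6, seed = 1)
#' gc_content(g)
generate_toy_genome <- function(n_contigs = 2, contig_length = 10000,
                                gc = 0.5, mask_fraction = 0, seed = 1,
                                path = NULL) {
  stopifnot(n_contigs >= 1, all(contig_length >= 1000))
  if (any(mask_fraction < 0 | mask_fraction > 1)) {
    abort("mask_fraction must be in [0, 1]")
  }
  gc <- rep_len(gc, n_contigs)
  mask_fraction <- rep_len(mask_fraction, n_contigs)
  len <- rep_len(contig_length, n_contigs)

  genome <- with_seed(seed, {
    purrr::map_chr(seq_len(n_contigs), function(i) {
      p <- c(A = (1 - gc[i]) / 2, C = gc[i] / 2, G = gc[i] / 2,
             T = (1 - gc[i]) / 2)
      s <- sample(names(p), len[i], replace = TRUE, prob = p)
      target <- round(mask_fraction[i] * len[i])
      if (target > 0) {
        # mask whole 100 bp blocks, trimming the last to hit the target
        block <- 100L
        n_blocks <- ceiling(len[i] / block)
        need <- ceiling(target / block)
        if (need > n_blocks) abort("mask_fraction infeasible for contig length")
        picked <- sort(sample.int(n_blocks, need))
        masked <- 0L
        for (bl in picked) {
          from <- (bl - 1L) * block + 1L
          to <- min(bl * block, len[i], from + (target - masked) - 1L)
          s[from:to] <- tolower(s[from:to])
          masked <- masked + (to - from + 1L)
        }
      }
      paste(s, collapse = "")
    })
  })
  names(genome) <- paste0("contig_", seq_len(n_contigs))
  if (!is.null(path)) write_fasta(genome, path)
  genome
}

#' Specify a planted-motif promoter dataset
#'
#' Bundles the parameters of the synthetic benchmark: promoter-length
#' windows with a short motif substituted into a configurable fraction of
#' each class, at positions drawn relative to the TSS. Defaults describe
#' the standard benchmark condition used throughout the package's tests:
#' 200 positives and 200 negatives of 2 kb (1.5 kb upstream / 0.5 kb
#' downstream of the TSS), an 8 bp motif planted in 80% of positives and
#' 5% of negatives at Gaussian(-150, 50) TSS-relative positions on a GC 0.5
#' background.
#'
#' @param n_pos,n_neg Class sizes.
#' @param upstream,downstream Window extent around the TSS in bp; sequence
#'   length is their sum.
#' @param motif Planted motif (uppercase ACGT).
#' @param plant_rate_pos,plant_rate_neg Per-class planting probabilities.
#' @param position `"gaussian"` (mean `pos_mean`, sd `pos_sd`, in bp
#'   relative to the TSS) or `"uniform"` over the window.
#' @param pos_mean,pos_sd Gaussian position parameters (bp; negative =
#'   upstream).
#' @param gc Background GC fraction.
#' @param seed Integer seed.
#' @return A `planted_dataset_spec` list.
#' @export
planted_dataset_spec <- function(n_pos = 200, n_neg = 200,
                                 upstream = 1500, downstream = 500,
                                 motif = "GCACGTCA",
                                 plant_rate_pos = 0.8, plant_rate_neg = 0.05,
                                 position = c("gaussian", "uniform"),
                                 pos_mean = -150, pos_sd = 50,
                                 gc = 0.5, seed = 1) {
  position <- match.arg(position)
  motif <- toupper(motif)
  stopifnot(
    n_pos >= 1, n_neg >= 1, upstream > 0, downstream > 0,
    plant_rate_pos >= 0, plant_rate_pos <= 1,
    plant_rate_neg >= 0, plant_rate_neg <= 1,
    gc > 0, gc < 1,
    nchar(motif) < upstream + downstream
  )
  if (!grepl("^[ACGT]+$", motif)) abort("motif must be uppercase ACGT")
  structure(
    list(n_pos = n_pos, n_neg = n_neg, upstream = upstream,
         downstream = downstream, motif = motif,
         plant_rate_pos = plant_rate_pos, plant_rate_neg = plant_rate_neg,
         position = position, pos_mean = pos_mean, pos_sd = pos_sd,
         gc = gc, seed = seed),
    class = "planted_dataset_spec"
  )
}

#' Generate a planted-motif promoter dataset
#'
#' Simulates promoter records from a [planted_dataset_spec()]: i.i.d.
#' background at the requested GC, with the motif substituted (length
#' preserved) into a random subset of each class at TSS-relative positions
#' from the configured distribution. Planted coordinates are recorded as
#' ground truth so downstream recovery can be scored.
#'
#' @param spec A [planted_dataset_spec()].
#' @return Tibble of promoter records with columns `transcript_id`,
#'   `tissue`, `expression_group`, `sequence`, `upstream`, `downstream`,
#'   `label`, `planted_start`, `planted_end` (0-based, half-open window
#'   offsets; `NA` when not planted) and `planted_tss_distance`.
#' @export
generate_planted_dataset <- function(spec) {
  stopifnot(inherits(spec, "planted_dataset_spec"))
  len <- spec$upstream + spec$downstream
  mlen <- nchar(spec$motif)
  n <- spec$n_pos + spec$n_neg
  label <- rep(c(1L, 0L), c(spec$n_pos, spec$n_neg))
  rate <- ifelse(label == 1L, spec$plant_rate_pos, spec$plant_rate_neg)

  with_seed(spec$seed, {
    bases <- c("A", "C", "G", "T")
    p <- c((1 - spec$gc) / 2, spec$gc / 2, spec$gc / 2, (1 - spec$gc) / 2)
    seqs <- vapply(seq_len(n), function(i) {
      paste(sample(bases, len, replace = TRUE, prob = p), collapse = "")
    }, character(1))
    planted <- runif(n) < rate
    start <- rep(NA_integer_, n)
    for (i in which(planted)) {
      s <- if (spec$position == "gaussian") {
        spec$upstream + round(rnorm(1, spec$pos_mean, spec$pos_sd))
      } else {
        sample.int(len - mlen + 1L, 1L) - 1L
      }
      s <- max(0L, min(len - mlen, as.integer(s)))
      start[i] <- s
      substr(seqs[i], s + 1L, s + mlen) <- spec$motif
    }
    tibble::tibble(
      transcript_id = sprintf("%s_%04d", ifelse(label == 1L, "pos", "neg"),
                              seq_len(n)),
      tissue = "toy",
      expression_group = ifelse(label == 1L, "TSp", "Null"),
      sequence = seqs,
      upstream = spec$upstream,
      downstream = spec$downstream,
      label = label,
      planted_start = start,
      planted_end = start + ifelse(is.na(start), NA_integer_, mlen),
      planted_tss_distance = start - spec$upstream
    )
  })
}

# longest common substring length between two strings (small inputs)
lcs_length <- function(a, b) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  la <- length(a); lb <- length(b)
  if (la == 0 || lb == 0) return(0L)
  prev <- integer(lb); best <- 0L
  for (i in seq_len(la)) {
    cur <- integer(lb)
    for (j in seq_len(lb)) {
      if (a[i] == b[j]) {
        cur[j] <- if (j > 1) prev[j - 1] + 1L else 1L
        if (cur[j] > best) best <- cur[j]
      }
    }
    prev <- cur
  }
  best
}

#' Score recovery of a planted motif
#'
#' A discovered motif counts as a hit when it shares a contiguous exact
#' match of at least `min_overlap` bp with the planted motif (longest
#' common substring); this covers exact recovery, discovered superstrings,
#' and truncated discoveries alike.
#'
#' @param discovered Character vector of discovered motif sequences.
#' @param planted The planted motif string.
#' @param min_overlap Minimum shared length in bp.
#' @return One-row tibble with `recall` (1 if any hit, else 0), `precision`
#'   (`NA` with `precision_defined = FALSE` when nothing was discovered),
#'   `n_discovered` and `n_hits`.
#' @export
evaluate_recovery <- function(discovered, planted, min_overlap = 4) {
  planted <- toupper(planted)
  discovered <- toupper(discovered)
  if (length(discovered) == 0) {
    return(tibble::tibble(recall = 0, precision = NA_real_,
                          precision_defined = FALSE,
                          n_discovered = 0L, n_hits = 0L))
  }
  hits <- vapply(discovered, function(d) {
    lcs_length(d, planted) >= min(min_overlap, nchar(planted))
  }, logical(1))
  tibble::tibble(
    recall = as.numeric(any(hits)),
    precision = mean(hits),
    precision_defined = TRUE,
    n_discovered = length(discovered),
    n_hits = sum(hits)
  )
}
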