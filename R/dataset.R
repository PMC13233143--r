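#' Extract TSS-anchored promoter windows from a genome
#'
#' Pulls `[-upstream, +downstream)` windows around each annotated TSS,
#' oriented 5'->3' in the direction of transcription: plus-strand records
#' return `genome[tss - upstream, tss + downstream)` and minus-strand
#' records the reverse complement of `genome[tss - downstream,
#' tss + upstream)`. Coordinates are 0-based half-open throughout. Windows
#' that would leave the contig are an error, never silently clipped —
#' truncation would break the fixed-length invariant every downstream
#' stage relies on.
#'
#' @param annotations Tibble with columns `transcript_id`, `chrom`, `tss`
#'   (0-based), `strand` (`"+"`/`"-"`), and optionally `tissue`,
#'   `expression_group`.
#' @param genome Named character vector of contig sequences (see
#'   [read_fasta()]).
#' @param upstream,downstream Window extent in bp (both > 0).
#' @return Tibble of promoter records: the annotation columns plus
#'   `sequence`, `upstream`, `downstream`, `genomic_start`, `genomic_end`.
#' @export
extract_promoter_windows <- function(annotations, genome, upstream, downstream) {
  stopifnot(upstream > 0, downstream > 0)
  req <- c("transcript_id", "chrom", "tss", "strand")
  missing_cols <- setdiff(req, names(annotations))
  if (length(missing_cols) > 0) {
    abort(paste("annotations missing columns:",
                paste(missing_cols, collapse = ", ")))
  }
  bad_chrom <- setdiff(unique(annotations$chrom), names(genome))
  if (length(bad_chrom) > 0) {
    abort(paste("chromosomes absent from genome:",
                paste(bad_chrom, collapse = ", ")))
  }
  if (!all(annotations$strand %in% c("+", "-"))) {
    abort("strand must be '+' or '-'")
  }

  clen <- nchar(genome)[annotations$chrom]
  plus <- annotations$strand == "+"
  gstart <- ifelse(plus, annotations$tss - upstream,
                   annotations$tss - downstream)
  gend <- ifelse(plus, annotations$tss + downstream,
                 annotations$tss + upstream)
  oob <- gstart < 0 | gend > clen
  if (any(oob)) {
    abort(paste0("window out of contig bounds for: ",
                 paste(annotations$transcript_id[oob], collapse = ", ")))
  }
  seqs <- substr(genome[annotations$chrom], gstart + 1, gend)
  seqs[!plus] <- revcomp(seqs[!plus])

  dplyr::mutate(tibble::as_tibble(annotations),
                sequence = unname(seqs),
                upstream = upstream, downstream = downstream,
                genomic_start = as.integer(gstart),
                genomic_end = as.integer(gend))
}

#' Label promoter records for one target tissue
#'
#' The positive class is the tissue-specific (`TSp`) group of the target
#' tissue; negatives are records whose expression group falls in
#' `negative_groups` (any tissue). Everything else — including `TSp`
#' records of other tissues — is dropped. Per-group retention counts are
#' attached as the `"group_counts"` attribute.
#'
#' @param records Promoter record tibble with `tissue` and
#'   `expression_group` columns.
#' @param tissue Target tissue name.
#' @param negative_groups Subset of `c("TEn", "Wide", "Low", "Null")`.
#' @return The labeled tibble (column `label` in `{0, 1}`).
#' @export
label_by_tissue <- function(records, tissue,
                            negative_groups = c("TEn", "Wide", "Low", "Null")) {
  if (!all(negative_groups %in% c("TEn", "Wide", "Low", "Null"))) {
    abort("negative_groups must be a subset of TEn, Wide, Low, Null")
  }
  pos <- records$expression_group == "TSp" & records$tissue == tissue
  neg <- records$expression_group %in% negative_groups
  if (!any(pos)) abort(paste0("no TSp records for tissue '", tissue, "'"))
  out <- records[pos | neg, , drop = FALSE]
  out$label <- as.integer(pos[pos | neg])
  counts <- dplyr::count(
    dplyr::mutate(out, class = ifelse(.data$label == 1, "positive", "negative")),
    .data$class, .data$expression_group, name = "n_records"
  )
  attr(out, "group_counts") <- counts
  out
}

# TRUE for each query interval that intersects any interval of the set
# (same chrom, half-open). `set` may be NULL/empty.
intersects_any <- function(chrom, start, end, set) {
  if (is.null(set) || nrow(set) == 0) return(rep(FALSE, length(start)))
  vapply(seq_along(start), function(i) {
    s <- set[set$chrom == chrom[i], , drop = FALSE]
    any(s$start < end[i] & s$end > start[i])
  }, logical(1))
}

#' Sample random non-promoter negative windows (Model A)
#'
#' Draws fixed-length windows uniformly from the genome, rejecting any
#' that intersect the exclusion set (typically all promoter windows), so
#' negatives never overlap positives. Sampling is bit-reproducible under
#' `seed`.
#'
#' @param genome Named character vector of contigs.
#' @param exclusion Tibble of half-open intervals (`chrom`, `start`,
#'   `end`) that sampled windows must not intersect; may be `NULL`.
#' @param n Number of windows.
#' @param length Window length in bp.
#' @param seed Integer seed.
#' @param max_attempts Retry budget before giving up.
#' @return Tibble with `chrom`, `start`, `end`, `sequence`.
#' @export
sample_random_negatives <- function(genome, exclusion, n, length, seed,
                                    max_attempts = 1000L * n) {
  clen <- nchar(genome)
  usable <- clen - length
  if (all(usable < 0)) abort("no contig long enough for the requested length")
  chroms <- names(genome)[usable >= 0]
  w <- (usable[usable >= 0] + 1)

  with_seed(seed, {
    out <- vector("list", n)
    got <- 0L
    attempts <- 0L
    while (got < n) {
      if (attempts >= max_attempts) {
        abort(sprintf(
          "could not place %d windows after %d attempts (placed %d)",
          n, attempts, got))
      }
      attempts <- attempts + 1L
      chrom <- sample(chroms, 1L, prob = w)
      start <- sample.int(usable[chrom] + 1L, 1L) - 1L
      if (intersects_any(chrom, start, start + length, exclusion)) next
      got <- got + 1L
      out[[got]] <- tibble::tibble(chrom = chrom, start = start,
                                   end = start + length)
    }
    res <- dplyr::bind_rows(out)
    res$sequence <- unname(substr(genome[res$chrom], res$start + 1, res$end))
    res
  })
}

#' Sample GC/repeat-matched negative windows (Model B)
#'
#' For each positive record, draws candidate windows of the same length
#' until one matches the positive's GC content (uppercase ACGT) within
#' `gc_tolerance` and its soft-masked repeat fraction within
#' `repeat_tolerance`, outside the exclusion set. Positives that cannot be
#' matched within the attempt budget are reported, not fatal: the run
#' continues and the summary carries the unmatched count.
#'
#' @param genome Named character vector of contigs (soft-masked lowercase
#'   encodes repeats).
#' @param positives Tibble with a `sequence` column (one row per positive).
#' @param gc_tolerance,repeat_tolerance Matching tolerances, in `(0, 0.5]`.
#' @param exclusion Optional interval tibble as in
#'   [sample_random_negatives()].
#' @param seed Integer seed.
#' @param max_attempts Candidate draws per positive.
#' @return Tibble with one row per positive: `matched`, `chrom`, `start`,
#'   `end`, `sequence`, `gc`, `repeat_frac`; the `"n_unmatched"` attribute
#'   summarises failures.
#' @export
sample_matched_negatives <- function(genome, positives,
                                     gc_tolerance = 0.02,
                                     repeat_tolerance = 0.05,
                                     exclusion = NULL, seed = 1,
                                     max_attempts = 2000L) {
  stopifnot(gc_tolerance > 0, gc_tolerance <= 0.5,
            repeat_tolerance > 0, repeat_tolerance <= 0.5)
  clen <- nchar(genome)
  pos_gc <- gc_content(positives$sequence)
  pos_rep <- repeat_fraction(positives$sequence)
  lens <- nchar(positives$sequence)

  with_seed(seed, {
    rows <- purrr::map(seq_len(nrow(positives)), function(i) {
      len <- lens[i]
      chroms <- names(genome)[clen >= len]
      w <- clen[chroms] - len + 1
      for (a in seq_len(max_attempts)) {
        chrom <- sample(chroms, 1L, prob = w)
        start <- sample.int(clen[chrom] - len + 1L, 1L) - 1L
        if (intersects_any(chrom, start, start + len, exclusion)) next
        cand <- substr(genome[[chrom]], start + 1, start + len)
        g <- gc_content(cand)
        r <- repeat_fraction(cand)
        if (abs(g - pos_gc[i]) <= gc_tolerance &&
            abs(r - pos_rep[i]) <= repeat_tolerance) {
          return(tibble::tibble(matched = TRUE, chrom = chrom,
                                start = start, end = start + len,
                                sequence = cand, gc = g, repeat_frac = r))
        }
      }
      tibble::tibble(matched = FALSE, chrom = NA_character_,
                     start = NA_integer_, end = NA_integer_,
                     sequence = NA_character_, gc = NA_real_,
                     repeat_frac = NA_real_)
    })
    out <- dplyr::bind_rows(rows)
    n_unmatched <- sum(!out$matched)
    if (n_unmatched > 0) {
      warn(sprintf("%d positive(s) could not be GC/repeat-matched", n_unmatched))
    }
    attr(out, "n_unmatched") <- n_unmatched
    out
  })
}

#' Reduce sequence redundancy by greedy identity clustering
#'
#' Greedy incremental clustering: sequences are processed longest-first
#' and joined to the first representative whose best ungapped alignment
#' reaches the identity threshold (fraction of the shorter sequence
#' matching) with alignment coverage of at least `coverage` of the shorter
#' sequence, and whose length ratio also satisfies `coverage`. If an
#' external clustering command is supplied it is tried first; on failure
#' the internal metric takes over with a warning.
#'
#' @param sequences Character vector (optionally named) of DNA sequences.
#' @param identity Minimum fractional identity, default 0.8.
#' @param coverage Minimum coverage fraction, default 0.8.
#' @param tool Optional external command (e.g. `"mmseqs"`); `NULL` uses
#'   the internal metric directly.
#' @return Tibble with `id`, `sequence`, `cluster`, `is_representative`.
#' @export
cluster_reduce <- function(sequences, identity = 0.8, coverage = 0.8,
                           tool = NULL) {
  if (length(sequences) == 0) abort("sequences must be non-empty")
  ids <- names(sequences) %||% paste0("seq_", seq_along(sequences))
  if (!is.null(tool)) {
    ext <- tryCatch(cluster_external(sequences, ids, identity, coverage, tool),
                    error = function(e) {
                      warn(paste0("external clustering failed (",
                                  conditionMessage(e),
                                  "); using internal metric"))
                      NULL
                    })
    if (!is.null(ext)) return(ext)
  }
  ord <- order(-nchar(sequences), sequences)
  reps <- integer(0)            # indices into original vector
  cluster <- integer(length(sequences))
  for (i in ord) {
    assigned <- FALSE
    for (r in reps) {
      lr <- nchar(sequences[r]); li <- nchar(sequences[i])
      if (min(lr, li) / max(lr, li) < coverage) next
      idn <- .ungapped_identity(toupper(sequences[r]), toupper(sequences[i]),
                                coverage)
      if (idn >= identity) {
        cluster[i] <- cluster[r]
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      reps <- c(reps, i)
      cluster[i] <- length(reps)
    }
  }
  tibble::tibble(id = ids, sequence = unname(sequences), cluster = cluster,
                 is_representative = seq_along(sequences) %in% reps)
}

# Invoke an mmseqs2-style `easy-cluster` subprocess and parse its
# cluster TSV (representative_id <tab> member_id per line).
cluster_external <- function(sequences, ids, identity, coverage, tool) {
  if (!nzchar(Sys.which(tool))) stop("tool not on PATH")
  td <- tempfile("clust")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  fa <- file.path(td, "in.fasta")
  write_fasta(setNames(sequences, ids), fa)
  status <- system2(tool,
                    c("easy-cluster", fa, file.path(td, "out"),
                      file.path(td, "tmp"),
                      "--min-seq-id", identity, "-c", coverage),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("non-zero exit status")
  tsv <- file.path(td, "out_cluster.tsv")
  if (!file.exists(tsv)) stop("cluster TSV not produced")
  map <- readr::read_tsv(tsv, col_names = c("rep", "member"),
                         show_col_types = FALSE)
  rep_of <- setNames(map$rep, map$member)[ids]
  cluster <- as.integer(factor(rep_of, levels = unique(rep_of)))
  tibble::tibble(id = ids, sequence = unname(sequences), cluster = cluster,
                 is_representative = ids == rep_of)
}

#' Stratified train/validation/test split
#'
#' Assigns records to splits per class with largest-remainder
#' apportionment, so per-class counts match the ratios within one record.
#' Deterministic under `seed`.
#'
#' @param records Tibble with a `label` column.
#' @param ratios Train/validation/test proportions summing to 1.
#' @param seed Integer seed.
#' @return `records` with a `split` column
#'   (`"train"`/`"validation"`/`"test"`).
#' @export
stratified_split <- function(records, ratios = c(0.8, 0.1, 0.1), seed = 1) {
  stopifnot(length(ratios) == 3, abs(sum(ratios) - 1) < 1e-9)
  if (length(unique(records$label)) < 2) {
    abort("both classes must be present")
  }
  tab <- table(records$label)
  if (any(tab < 3)) abort("each class needs at least 3 records to split")
  split <- character(nrow(records))
  with_seed(seed, {
    for (cl in names(tab)) {
      idx <- which(records$label == as.integer(cl))
      idx <- idx[sample.int(length(idx))]
      quota <- length(idx) * ratios
      base <- floor(quota)
      rem <- length(idx) - sum(base)
      if (rem > 0) {
        extra <- order(-(quota - base))[seq_len(rem)]
        base[extra] <- base[extra] + 1
      }
      parts <- rep(c("train", "validation", "test"), base)
      split[idx] <- parts
    }
  })
  dplyr::mutate(tibble::as_tibble(records), split = split)
}

#' Write a labeled dataset to FASTA/BED/TSV
#'
#' FASTA headers carry `id|label|split|tissue|group`; a companion BED file
#' records source intervals when genomic provenance columns are present,
#' and a TSV manifest carries the full record table minus sequences.
#'
#' @param records Labeled (and optionally split) record tibble.
#' @param dir Output directory (created if needed).
#' @param stem File name stem.
#' @return Named character vector of written paths, invisibly.
#' @export
write_dataset <- function(records, dir, stem = "dataset") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  col_or <- function(nm, default) {
    if (nm %in% names(records)) records[[nm]] else default
  }
  headers <- paste(records$transcript_id, records$label,
                   col_or("split", "all"), col_or("tissue", "."),
                   col_or("expression_group", "."), sep = "|")
  fa <- file.path(dir, paste0(stem, ".fasta"))
  write_fasta(setNames(records$sequence, headers), fa)
  paths <- c(fasta = fa)
  if (all(c("chrom", "genomic_start", "genomic_end") %in% names(records))) {
    bed <- file.path(dir, paste0(stem, ".bed"))
    readr::write_tsv(
      tibble::tibble(chrom = records$chrom, start = records$genomic_start,
                     end = records$genomic_end, name = records$transcript_id,
                     score = records$label,
                     strand = col_or("strand", "+")),
      bed, col_names = FALSE)
    paths <- c(paths, bed = bed)
  }
  tsv <- file.path(dir, paste0(stem, ".tsv"))
  readr::write_tsv(dplyr::select(tibble::as_tibble(records), -"sequence"), tsv)
  invisible(c(paths, manifest = tsv))
}
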