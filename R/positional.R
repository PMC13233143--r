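#' Map window-relative motif instances to genomic coordinates
#'
#' Converts instance offsets within extracted promoter windows back to
#' genome coordinates, adjusting for strand: plus-strand instances start
#' at `(tss - upstream) + start`, minus-strand ones at
#' `(tss + upstream) - end` (the reverse-complement reflection). The
#' TSS-relative distance is `start - upstream` in transcription
#' orientation for both strands, so profiles from either strand pool
#' directly (upstream = negative).
#'
#' @param instances Instance tibble (`sequence_id`, `start`, `end`, plus
#'   any other columns, e.g. `motif`, `attention`).
#' @param provenance Tibble keyed by `transcript_id` with `chrom`, `tss`,
#'   `strand`, `upstream`, `downstream`.
#' @return Instances joined with provenance plus `genomic_start`,
#'   `genomic_end`, `tss_distance`.
#' @export
instance_to_genomic <- function(instances, provenance) {
  req <- c("transcript_id", "chrom", "tss", "strand", "upstream", "downstream")
  missing_cols <- setdiff(req, names(provenance))
  if (length(missing_cols) > 0) {
    abort(paste("provenance missing columns:",
                paste(missing_cols, collapse = ", ")))
  }
  out <- dplyr::inner_join(instances, provenance,
                           by = c(sequence_id = "transcript_id"))
  if (nrow(out) < nrow(instances)) {
    abort("some instances lack window provenance")
  }
  plus <- out$strand == "+"
  out$genomic_start <- ifelse(plus, out$tss - out$upstream + out$start,
                              out$tss + out$upstream - out$end)
  out$genomic_end <- out$genomic_start + (out$end - out$start)
  out$tss_distance <- out$start - out$upstream
  tibble::as_tibble(out)
}

#' Mean attention of tokens overlapping each motif instance
#'
#' Attaches to each instance the mean combined normalized attention of
#' the tokens its footprint overlaps, using the per-record scores kept by
#' [discover_motifs()].
#'
#' @param instances Instance tibble (`sequence_id`, `start`, `end`).
#' @param scores Named list of `list(s_hat, spans)` per sequence id (the
#'   `scores` element of a `motif_discovery`).
#' @return `instances` with an `attention` column (`NA` where no score is
#'   available, e.g. incorrectly predicted records).
#' @export
instance_attention <- function(instances, scores) {
  att <- purrr::map_dbl(seq_len(nrow(instances)), function(i) {
    sc <- scores[[instances$sequence_id[i]]]
    if (is.null(sc)) return(NA_real_)
    hit <- sc$spans$start < instances$end[i] & sc$spans$end > instances$start[i]
    if (!any(hit)) return(NA_real_)
    mean(sc$s_hat[hit])
  })
  dplyr::mutate(instances, attention = att)
}

#' Bin instance attention by TSS distance
#'
#' Aggregates instances into 100 bp bins on a grid anchored at the TSS
#' (half-open `[edge, edge + width)`, so a distance exactly on an edge
#' falls in the right-hand bin), computes the per-bin mean attention and
#' count, and applies a centered 3-bin rolling average over the occupied
#' bins (edge bins average over their available neighbors; empty bins are
#' skipped, not imputed as zero). A Gaussian KDE of the distances is
#' attached when at least two distinct distances exist.
#'
#' @param instances Tibble with `tss_distance` and `attention` columns.
#' @param bin_width Bin width in bp (default 100).
#' @param smooth_window Rolling window in bins (odd, default 3).
#' @return A `positional_profile` object: `bins` tibble (`bin_start`,
#'   `bin_end`, `mean_attention`, `smoothed`, `count`), `kde` tibble or
#'   `NULL`, and the raw `distances`.
#' @export
bin_attention_by_distance <- function(instances, bin_width = 100,
                                      smooth_window = 3) {
  if (nrow(instances) == 0) abort("instances must be non-empty")
  stopifnot(smooth_window >= 1, smooth_window %% 2 == 1)
  d <- instances$tss_distance
  att <- instances$attention %||% rep(NA_real_, nrow(instances))
  bin_start <- floor(d / bin_width) * bin_width
  bins <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(bin_start = bin_start, attention = att),
                    .data$bin_start),
    mean_attention = mean(.data$attention, na.rm = TRUE),
    count = dplyr::n(), .groups = "drop")
  bins <- dplyr::arrange(bins, .data$bin_start)
  bins$bin_end <- bins$bin_start + bin_width
  half <- (smooth_window - 1) / 2
  nb <- nrow(bins)
  bins$smoothed <- vapply(seq_len(nb), function(i) {
    idx <- max(1, i - half):min(nb, i + half)
    mean(bins$mean_attention[idx], na.rm = TRUE)
  }, numeric(1))
  kde <- if (length(unique(d)) >= 2) kde_distance_density(d) else NULL
  structure(list(bins = dplyr::select(bins, "bin_start", "bin_end",
                                      "mean_attention", "smoothed", "count"),
                 kde = kde, distances = d,
                 bin_width = bin_width, smooth_window = smooth_window),
            class = "positional_profile")
}

#' @export
print.positional_profile <- function(x, ...) {
  cat(sprintf("<positional_profile> %d instance(s) in %d bin(s) of %d bp%s\n",
              length(x$distances), nrow(x$bins), x$bin_width,
              if (is.null(x$kde)) "" else "; KDE attached"))
  invisible(x)
}

#' Gaussian kernel density of motif-TSS distances
#'
#' Scott's-rule bandwidth by default, evaluated over
#' `[min - 3h, max + 3h]`; the curve numerically integrates to 1.
#'
#' @param distances Numeric vector with at least two distinct values.
#' @param bw Bandwidth in bp (`NULL` for Scott's rule).
#' @param n Grid size.
#' @return Tibble with `distance`, `density`; bandwidth as attribute
#'   `"bw"`.
#' @export
kde_distance_density <- function(distances, bw = NULL, n = 512) {
  if (length(unique(distances)) < 2) {
    abort("all distances identical: use a histogram instead of a KDE")
  }
  h <- bw %||% bw.nrd(distances)
  dens <- density(distances, bw = h, n = n, cut = 3)
  structure(tibble::tibble(distance = dens$x, density = dens$y), bw = h)
}

# TRUE per query region when any peak on the same chrom intersects it
region_overlaps_any <- function(regions, peaks) {
  if (requireNamespace("IRanges", quietly = TRUE) &&
      nrow(regions) > 0 && nrow(peaks) > 0) {
    out <- rep(FALSE, nrow(regions))
    for (ch in unique(regions$chrom)) {
      ri <- which(regions$chrom == ch)
      pk <- peaks[peaks$chrom == ch, , drop = FALSE]
      if (nrow(pk) == 0) next
      q <- IRanges::IRanges(start = regions$start[ri] + 1,
                            end = regions$end[ri])
      s <- IRanges::IRanges(start = pk$start + 1, end = pk$end)
      out[ri] <- IRanges::overlapsAny(q, s)
    }
    return(out)
  }
  vapply(seq_len(nrow(regions)), function(i) {
    pk <- peaks[peaks$chrom == regions$chrom[i], , drop = FALSE]
    any(pk$start < regions$end[i] & pk$end > regions$start[i])
  }, logical(1))
}

#' Overlap enrichment of motif regions against reference peaks
#'
#' Compares the proportion of motif regions overlapping at least one
#' reference peak with the same proportion for background regions, via a
#' 2x2 Fisher exact test. `reference_peaks` may be a single interval
#' tibble or a named list of peak sets; with a list, one row per set is
#' returned, ranked by the motif overlap proportion.
#'
#' @param motif_regions,background_regions Half-open interval tibbles
#'   (`chrom`, `start`, `end`), same coordinate system.
#' @param reference_peaks Interval tibble or named list thereof.
#' @return Tibble with per-set proportions, odds ratio (with an
#'   `or_infinite` flag), Fisher p-value, and `rank`.
#' @export
region_overlap_enrichment <- function(motif_regions, reference_peaks,
                                      background_regions) {
  if (is.null(background_regions) || nrow(background_regions) == 0) {
    abort("background regions must be non-empty")
  }
  peak_sets <- if (is.data.frame(reference_peaks)) {
    list(peaks = reference_peaks)
  } else reference_peaks
  rows <- purrr::imap(peak_sets, function(pk, nm) {
    mo <- region_overlaps_any(motif_regions, pk)
    bo <- region_overlaps_any(background_regions, pk)
    a <- sum(mo); b <- sum(!mo); c_ <- sum(bo); d <- sum(!bo)
    ft <- fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))
    or <- (a * d) / (b * c_)
    tibble::tibble(peak_set = nm,
                   n_motif = length(mo), n_background = length(bo),
                   prop_motif = mean(mo), prop_background = mean(bo),
                   odds_ratio = or,
                   or_infinite = is.infinite(or) | is.nan(or) & a > 0,
                   p = ft$p.value)
  })
  out <- dplyr::bind_rows(rows)
  out$rank <- rank(-out$prop_motif, ties.method = "min")
  dplyr::arrange(out, .data$rank)
}

#' Positional profile of discovered motif instances
#'
#' Convenience wrapper: takes a `motif_discovery`, keeps instances of its
#' significant motifs, attaches instance attention and TSS distances
#' (window-relative records: distance = `start - upstream`), and bins
#' them.
#'
#' @param discovery A `motif_discovery`.
#' @param records The record tibble the discovery ran on (for `upstream`).
#' @param bin_width,smooth_window Passed to [bin_attention_by_distance()].
#' @param significant_only Restrict to significant motifs (default TRUE).
#' @return A `positional_profile`, or `NULL` when there are no instances.
#' @export
positional_profile <- function(discovery, records, bin_width = 100,
                               smooth_window = 3, significant_only = TRUE) {
  inst <- discovery$instances
  if (significant_only && nrow(inst) > 0) {
    sig <- discovery$motifs$motif[discovery$motifs$significant]
    inst <- inst[inst$motif %in% sig, , drop = FALSE]
  }
  if (nrow(inst) == 0) return(NULL)
  ids <- records$transcript_id %||% paste0("seq_", seq_len(nrow(records)))
  up <- setNames(records$upstream, ids)
  inst$tss_distance <- inst$start - up[inst$sequence_id]
  inst <- instance_attention(inst, discovery$scores)
  bin_attention_by_distance(inst, bin_width = bin_width,
                            smooth_window = smooth_window)
}
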