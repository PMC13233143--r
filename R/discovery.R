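#' Aggregate attention heads within a layer
#'
#' Raw per-token attention `alpha_j` is the mean over heads of the head's
#' softmaxed `[CLS]`-to-token weight. (Sum and mean differ by the constant
#' head count, which cancels under max-normalization.)
#'
#' @param profile An `attention_profile`.
#' @param layer 1-based layer index.
#' @return Numeric vector of raw per-token scores.
#' @export
aggregate_heads <- function(profile, layer) {
  stopifnot(inherits(profile, "attention_profile"),
            layer >= 1, layer <= profile$n_layers)
  m <- profile$weights[layer, , , drop = FALSE]
  dim(m) <- dim(profile$weights)[2:3]
  colMeans(m)
}

#' Normalize token scores to the per-sequence maximum
#'
#' `s_hat_j = alpha_j / max(alpha)`, so exactly the argmax token scores 1
#' (more on ties).
#'
#' @param alpha Non-negative numeric vector with at least one positive
#'   entry.
#' @return Numeric vector with `max == 1`.
#' @export
normalize_scores <- function(alpha) {
  if (any(alpha < 0)) abort("attention scores must be non-negative")
  m <- max(alpha)
  if (m <= 0) abort("cannot normalize an all-zero score vector")
  alpha / m
}

#' Layer specificity score
#'
#' A z-score-like statistic of how peaked a layer's normalized attention
#' is: `(max(s_hat) - mean(s_hat)) / sd(s_hat)` with the sample standard
#' deviation; 0 by convention when the scores are constant.
#'
#' @param s_hat Normalized score vector (length >= 2).
#' @return Scalar specificity.
#' @export
layer_specificity <- function(s_hat) {
  if (length(s_hat) < 2) abort("specificity needs at least two tokens")
  s <- sd(s_hat)
  if (s == 0) return(0)
  (max(s_hat) - mean(s_hat)) / s
}

#' Combine per-layer normalized scores into one saliency vector
#'
#' Strategies: `"mid_final"` averages the mean of the middle layers with
#' the final layer (layers 5-7 when the model has at least 7 layers, the
#' middle third otherwise), `"single"` takes one layer, `"top_sp"` the
#' layer with the highest specificity score. The combination is
#' re-normalized to max 1.
#'
#' @param s_hat_by_layer Numeric matrix, layers in rows, tokens in
#'   columns; each row already max-normalized.
#' @param strategy Combination strategy.
#' @param layer Layer index for `strategy = "single"`.
#' @return Combined normalized score vector.
#' @export
select_layers <- function(s_hat_by_layer,
                          strategy = c("mid_final", "single", "top_sp"),
                          layer = NULL) {
  strategy <- match.arg(strategy)
  L <- nrow(s_hat_by_layer)
  combined <- switch(
    strategy,
    mid_final = {
      mid <- if (L >= 7) 5:7 else seq(floor(L / 3) + 1, ceiling(2 * L / 3))
      mid_mean <- colMeans(s_hat_by_layer[mid, , drop = FALSE])
      (mid_mean + s_hat_by_layer[L, ]) / 2
    },
    single = {
      if (is.null(layer)) abort("strategy 'single' needs a layer index")
      s_hat_by_layer[layer, ]
    },
    top_sp = {
      sp <- apply(s_hat_by_layer, 1, layer_specificity)
      s_hat_by_layer[which.max(sp), ]
    })
  normalize_scores(combined)
}

#' Select candidate motif regions from normalized attention
#'
#' A token is marked when its normalized score exceeds both the
#' per-sequence mean and twice the per-sequence minimum; maximal runs of
#' consecutive marked tokens are concatenated into one candidate region,
#' and regions shorter than `min_length` bp are discarded. When
#' `2 * min(s_hat) >= max(s_hat)` the second condition excludes every
#' token and the result is empty (a flat, uninformative profile).
#'
#' @param s_hat Combined normalized scores, aligned with `spans`.
#' @param spans Token span tibble.
#' @param sequence The underlying sequence.
#' @param min_length Minimum candidate length in bp.
#' @return Tibble with `motif`, `start`, `end`, `mean_score`, `n_tokens`
#'   (possibly zero rows).
#' @export
select_candidate_motifs <- function(s_hat, spans, sequence, min_length = 4) {
  stopifnot(length(s_hat) == nrow(spans))
  pass <- s_hat > mean(s_hat) & s_hat > 2 * min(s_hat)
  if (!any(pass)) {
    return(tibble::tibble(motif = character(0), start = integer(0),
                          end = integer(0), mean_score = numeric(0),
                          n_tokens = integer(0)))
  }
  r <- rle(pass)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1
  keep <- which(r$values)
  out <- purrr::map(keep, function(k) {
    i <- run_start[k]; j <- run_end[k]
    s <- spans$start[i]; e <- spans$end[j]
    tibble::tibble(motif = toupper(substr(sequence, s + 1, e)),
                   start = s, end = e,
                   mean_score = mean(s_hat[i:j]),
                   n_tokens = j - i + 1L)
  })
  out <- dplyr::bind_rows(out)
  out[out$end - out$start >= min_length, , drop = FALSE]
}

#' Count motif occurrences across sequences
#'
#' Multi-pattern scan with an Aho-Corasick automaton; overlapping
#' occurrences are counted. For each motif, `n` is the number of
#' sequences containing at least one occurrence, `k` the number of
#' positive-class such sequences, and every occurrence position is
#' recorded.
#'
#' @param motifs Character vector of uppercase ACGT motifs.
#' @param sequences Character vector of subject sequences.
#' @param labels Integer 0/1 class labels, one per sequence.
#' @param sequence_ids Optional identifiers (default positional).
#' @return List with `stats` (tibble `motif`, `n`, `k`,
#'   `total_occurrences`) and `instances` (tibble `motif`, `sequence_id`,
#'   `label`, `start`, `end`, 0-based half-open).
#' @export
count_motif_occurrences <- function(motifs, sequences, labels,
                                    sequence_ids = NULL) {
  if (length(motifs) == 0) abort("motifs must be non-empty")
  if (!all(grepl("^[ACGT]+$", motifs))) {
    abort("motifs must be uppercase ACGT strings")
  }
  stopifnot(length(labels) == length(sequences))
  sequence_ids <- sequence_ids %||% paste0("seq_", seq_along(sequences))
  hits <- .ac_search(motifs, sequences)
  instances <- tibble::tibble(
    motif = motifs[hits$pattern],
    sequence_id = sequence_ids[hits$subject],
    label = as.integer(labels[hits$subject]),
    start = hits$start - 1L,
    end = hits$start - 1L + nchar(motifs[hits$pattern])
  )
  per_seq <- dplyr::distinct(instances, .data$motif, .data$sequence_id,
                             .data$label)
  stats <- dplyr::summarise(
    dplyr::group_by(per_seq, .data$motif),
    n = dplyr::n(), k = sum(.data$label == 1L), .groups = "drop")
  occ <- dplyr::count(instances, .data$motif, name = "total_occurrences")
  stats <- dplyr::left_join(stats, occ, by = "motif")
  absent <- setdiff(motifs, stats$motif)
  if (length(absent) > 0) {
    stats <- dplyr::bind_rows(
      stats, tibble::tibble(motif = absent, n = 0L, k = 0L,
                            total_occurrences = 0L))
  }
  stats <- stats[match(unique(motifs), stats$motif), , drop = FALSE]
  list(stats = stats, instances = instances)
}

#' Hypergeometric enrichment p-value
#'
#' Upper-tail probability `P(X >= k)` for
#' `X ~ Hypergeom(N, K, n)`: the chance that at least `k` of the `n`
#' motif-carrying sequences are positive when `K` of the `N` sequences
#' are positive and carriers are drawn without replacement. The pmf
#' `P(X = k)` is available via [hypergeom_pmf()].
#'
#' @param N Total sequences.
#' @param K Positive sequences.
#' @param n Motif-containing sequences.
#' @param k Positive motif-containing sequences.
#' @return p-value(s) in `[0, 1]`; vectorized.
#' @export
#' @examples
#' hypergeom_enrichment(10, 5, 4, 4) # 5/210
hypergeom_enrichment <- function(N, K, n, k) {
  ok <- K <= N & n <= N & k <= pmin(K, n) & k >= 0 & n >= 0 & K >= 0
  if (!all(ok)) abort("inconsistent hypergeometric counts")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' @rdname hypergeom_enrichment
#' @export
hypergeom_pmf <- function(N, K, n, k) {
  dhyper(k, K, N - K, n)
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjusted q-values and significance flags at level `alpha`.
#'
#' @param p Numeric vector of p-values.
#' @param alpha FDR level (default 0.01).
#' @return Tibble with `p`, `q`, `significant`.
#' @export
fdr_correct <- function(p, alpha = 0.01) {
  if (any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  q <- p.adjust(p, method = "BH")
  tibble::tibble(p = p, q = q, significant = q <= alpha)
}

#' Drop motifs with too few instances
#'
#' @param stats Tibble with a `total_occurrences` column.
#' @param min_instances Minimum total occurrence count (default 3).
#' @return Filtered tibble.
#' @export
filter_min_instances <- function(stats, min_instances = 3) {
  stats[stats$total_occurrences >= min_instances, , drop = FALSE]
}

#' Greedily merge similar motifs by gapless overlap
#'
#' Motifs are processed longest-first (ties lexicographic) and collapsed
#' into an existing cluster when the best ungapped-offset alignment
#' against the cluster consensus matches at least
#' `threshold * (shorter length)` positions. The cluster consensus is the
#' positionwise majority base over member strings aligned at their best
#' offsets (ties resolved in A < C < G < T order), extended to the union
#' of member extents. Re-running the merge on its own output changes
#' nothing.
#'
#' @param motifs Character vector of motif sequences.
#' @param threshold Required match fraction of the shorter length,
#'   in `(0, 1]`.
#' @return Tibble with `consensus`, `length`, `n_members`, `members`
#'   (list-column of input motifs in each cluster).
#' @export
#' @examples
#' merge_motifs(c("ACGTAC", "CGTACG")) # one consensus "ACGTACG"
merge_motifs <- function(motifs, threshold = 0.8) {
  stopifnot(threshold > 0, threshold <= 1)
  if (length(motifs) == 0) {
    return(tibble::tibble(consensus = character(0), length = integer(0),
                          n_members = integer(0), members = list()))
  }
  ord <- order(-nchar(motifs), motifs)
  bases <- c("A", "C", "G", "T")
  clusters <- list() # each: list(counts = 4 x width matrix, members = chr)

  consensus_of <- function(counts) {
    paste(bases[apply(counts, 2, which.max)], collapse = "")
  }
  add_string <- function(counts, s, offset) {
    # place s at `offset` relative to the current profile origin
    ls <- nchar(s)
    lo <- min(0L, offset)
    hi <- max(ncol(counts), offset + ls)
    new <- matrix(0L, 4, hi - lo)
    if (ncol(counts) > 0) new[, (1 - lo):(ncol(counts) - lo)] <- counts
    idx <- match(strsplit(s, "")[[1]], bases)
    cols <- (offset - lo) + seq_len(ls)
    for (t in seq_len(ls)) new[idx[t], cols[t]] <- new[idx[t], cols[t]] + 1L
    new
  }

  for (i in ord) {
    m <- toupper(motifs[i])
    placed <- FALSE
    for (ci in seq_along(clusters)) {
      cons <- consensus_of(clusters[[ci]]$counts)
      bo <- .best_ungapped_overlap(cons, m)
      if (bo[["matches"]] >= threshold * min(nchar(cons), nchar(m))) {
        clusters[[ci]]$counts <- add_string(clusters[[ci]]$counts, m,
                                            bo[["offset"]])
        clusters[[ci]]$members <- c(clusters[[ci]]$members, motifs[i])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      clusters[[length(clusters) + 1]] <-
        list(counts = add_string(matrix(0L, 4, 0), m, 0L),
             members = motifs[i])
    }
  }
  cons <- vapply(clusters, function(cl) consensus_of(cl$counts), character(1))
  tibble::tibble(consensus = cons, length = nchar(cons),
                 n_members = vapply(clusters, function(cl)
                   length(cl$members), integer(1)),
                 members = purrr::map(clusters, "members"))
}

#' Extract fixed flanks around motif instance centers
#'
#' For each occurrence, takes the `[center - flank, center + flank)`
#' window (center = floor of the instance midpoint), clipped at sequence
#' bounds; clipped windows are flagged. Output is formatted for de novo
#' motif tools (FASTA-style headers `motif|sequence_id|start`).
#'
#' @param instances Instance tibble (`motif`, `sequence_id`, `start`,
#'   `end`).
#' @param sequences Named character vector keyed by `sequence_id`.
#' @param flank Flank size in bp (default 12).
#' @param path Optional FASTA output path.
#' @return Tibble with `name`, `window`, `win_start`, `win_end`,
#'   `clipped`.
#' @export
extract_instance_windows <- function(instances, sequences, flank = 12,
                                     path = NULL) {
  lens <- nchar(sequences)[instances$sequence_id]
  center <- (instances$start + instances$end) %/% 2L
  ws <- pmax(0L, center - as.integer(flank))
  we <- pmin(as.integer(lens), center + as.integer(flank))
  out <- tibble::tibble(
    name = paste(instances$motif, instances$sequence_id, instances$start,
                 sep = "|"),
    window = unname(substr(sequences[instances$sequence_id], ws + 1, we)),
    win_start = ws, win_end = we,
    clipped = (we - ws) < 2L * as.integer(flank))
  if (!is.null(path)) write_fasta(setNames(out$window, out$name), path)
  out
}

#' Motifs unique to one model: the B-minus-A set
#'
#' Returns motifs of `b` absent from `a`. `"exact"` matching removes only
#' identical strings (both sets are expected to be post-merge consensi);
#' `"similarity"` also treats a `b` motif as shared when its best
#' ungapped overlap with any `a` motif reaches `threshold` of the shorter
#' length.
#'
#' @param b,a Character vectors of motif sequences.
#' @param matching `"exact"` or `"similarity"`.
#' @param threshold Similarity-mode match fraction.
#' @return Character vector: the motifs of `b` not shared with `a`.
#' @export
motif_set_difference <- function(b, a, matching = c("exact", "similarity"),
                                 threshold = 0.8) {
  matching <- match.arg(matching)
  if (length(a) == 0) return(b)
  if (matching == "exact") return(setdiff(b, a))
  shared <- vapply(b, function(m) {
    any(vapply(a, function(x) {
      bo <- .best_ungapped_overlap(toupper(x), toupper(m))
      bo[["matches"]] >= threshold * min(nchar(x), nchar(m))
    }, logical(1)))
  }, logical(1))
  b[!shared]
}

#' Run attention-guided motif discovery end to end
#'
#' The full discovery stage: keep correctly predicted records, combine
#' per-layer normalized `[CLS]` attention, cut candidate regions, count
#' occurrences over the whole labeled dataset with the multi-pattern
#' scanner, drop sparse motifs, test hypergeometric enrichment of
#' positives among carriers with BH correction at `alpha`, and merge
#' significant motifs by gapless overlap. Candidate discovery uses only
#' correct predictions; the enrichment universe (`N`, `K`) is the full
#' input dataset.
#'
#' @param records Labeled record tibble (`sequence`, `label`, optionally
#'   `transcript_id`, planted ground-truth columns for toy providers).
#' @param provider An `attention_provider`.
#' @param layer_strategy,layer Passed to [select_layers()].
#' @param alpha FDR level (default 0.01).
#' @param min_instances Minimum total occurrences per motif (default 3).
#' @param min_motif_length Minimum candidate length in bp (default 4).
#' @param merge_threshold Gapless-merge match fraction (default 0.8).
#' @param source Label recorded in the result (e.g. `"ModelA"`).
#' @return A `motif_discovery` object: `motifs` (enrichment tibble),
#'   `merged` (significant consensus tibble), `instances`, per-record
#'   combined scores (`scores`), retention `counts`, and `params`.
#' @export
discover_motifs <- function(records, provider,
                            layer_strategy = "mid_final", layer = NULL,
                            alpha = 0.01, min_instances = 3,
                            min_motif_length = 4, merge_threshold = 0.8,
                            source = "ModelA") {
  fc <- filter_correct_predictions(records, provider)
  ids_all <- records$transcript_id %||% paste0("seq_", seq_len(nrow(records)))

  scores <- purrr::map(fc$profiles, function(pr) {
    sh <- t(vapply(seq_len(pr$n_layers), function(l) {
      normalize_scores(aggregate_heads(pr, l))
    }, numeric(nrow(pr$spans))))
    list(s_hat = select_layers(sh, strategy = layer_strategy, layer = layer),
         spans = pr$spans)
  })

  cand <- purrr::map(seq_along(scores), function(i) {
    sc <- scores[[i]]
    cm <- select_candidate_motifs(sc$s_hat, sc$spans, fc$records$sequence[i],
                                  min_length = min_motif_length)
    if (nrow(cm) > 0) cm$sequence_id <- names(scores)[i]
    cm
  })
  cand <- dplyr::bind_rows(cand)

  empty <- tibble::tibble(motif = character(0), length = integer(0),
                          N = integer(0), K = integer(0), n = integer(0),
                          k = integer(0), total_occurrences = integer(0),
                          p = numeric(0), q = numeric(0),
                          significant = logical(0), source = character(0))
  params <- list(layer_strategy = layer_strategy, alpha = alpha,
                 min_instances = min_instances,
                 min_motif_length = min_motif_length,
                 merge_threshold = merge_threshold, source = source)
  if (nrow(cand) == 0) {
    return(structure(list(motifs = empty,
                          merged = merge_motifs(character(0)),
                          instances = tibble::tibble(),
                          candidates = cand, scores = scores,
                          counts = fc$counts, params = params),
                     class = "motif_discovery"))
  }

  motifs <- sort(unique(cand$motif))
  occ <- count_motif_occurrences(motifs, records$sequence, records$label,
                                 sequence_ids = ids_all)
  stats <- filter_min_instances(occ$stats, min_instances)
  if (nrow(stats) == 0) {
    return(structure(list(motifs = empty,
                          merged = merge_motifs(character(0)),
                          instances = occ$instances,
                          candidates = cand, scores = scores,
                          counts = fc$counts, params = params),
                     class = "motif_discovery"))
  }

  N <- nrow(records)
  K <- sum(records$label == 1L)
  stats$p <- hypergeom_enrichment(N, K, stats$n, stats$k)
  fdr <- fdr_correct(stats$p, alpha = alpha)
  tab <- tibble::tibble(motif = stats$motif, length = nchar(stats$motif),
                        N = N, K = K, n = stats$n, k = stats$k,
                        total_occurrences = stats$total_occurrences,
                        p = stats$p, q = fdr$q,
                        significant = fdr$significant, source = source)
  tab <- dplyr::arrange(tab, .data$q, .data$motif)
  merged <- merge_motifs(tab$motif[tab$significant],
                         threshold = merge_threshold)
  structure(list(motifs = tab, merged = merged,
                 instances = occ$instances, candidates = cand,
                 scores = scores, counts = fc$counts, params = params),
            class = "motif_discovery")
}

#' @export
print.motif_discovery <- function(x, ...) {
  cat(sprintf("<motif_discovery> %s: %d motif(s) tested, %d significant (q <= %g), %d after merging\n",
              x$params$source, nrow(x$motifs), sum(x$motifs$significant),
              x$params$alpha, nrow(x$merged)))
  invisible(x)
}
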