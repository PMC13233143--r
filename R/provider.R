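#' Tokenize a DNA sequence into character spans
#'
#' Either non-overlapping fixed-length segmentation (`k`), or greedy
#' longest-match segmentation under a supplied vocabulary (which must
#' cover single nucleotides so segmentation is total). Spans tile the
#' sequence exactly: 0-based, half-open, no gaps or overlaps. The trailing
#' span of a fixed-`k` tokenization may be shorter than `k`.
#'
#' @param sequence DNA string (non-empty).
#' @param k Fixed token length (ignored when `vocabulary` is given).
#' @param vocabulary Character vector of allowed tokens.
#' @return Tibble with `token`, `start`, `end`.
#' @export
#' @examples
#' tokenize_sequence("ACGTAC", k = 3)
tokenize_sequence <- function(sequence, k = 6, vocabulary = NULL) {
  if (!nzchar(sequence)) abort("sequence must be non-empty")
  n <- nchar(sequence)
  if (is.null(vocabulary)) {
    stopifnot(k >= 1)
    starts <- seq(0L, n - 1L, by = k)
    ends <- pmin(starts + k, n)
  } else {
    vocab_len <- sort(unique(nchar(vocabulary)), decreasing = TRUE)
    vocab <- unique(vocabulary)
    starts <- integer(0); ends <- integer(0)
    pos <- 0L
    while (pos < n) {
      matched <- FALSE
      for (l in vocab_len) {
        if (pos + l > n) next
        piece <- substr(sequence, pos + 1L, pos + l)
        if (piece %in% vocab) {
          starts <- c(starts, pos); ends <- c(ends, pos + l)
          pos <- pos + l
          matched <- TRUE
          break
        }
      }
      if (!matched) {
        abort(sprintf("vocabulary cannot tokenize position %d ('%s')",
                      pos, substr(sequence, pos + 1, pos + 1)))
      }
    }
  }
  tibble::new_tibble(list(token = substring(sequence, starts + 1, ends),
                          start = as.integer(starts),
                          end = as.integer(ends)),
                     nrow = length(starts))
}

#' Construct an attention profile
#'
#' The container every downstream stage consumes: per-layer, per-head
#' softmaxed `[CLS]`-to-token attention rows plus the token spans they
#' refer to and the model's prediction. Rows are validated to be
#' probability distributions (non-negative, sum 1 within 1e-6).
#'
#' @param sequence_id Identifier string.
#' @param spans Token span tibble from [tokenize_sequence()].
#' @param weights Numeric array `[layers, heads, tokens]`.
#' @param prediction List with `label` (0/1), `logit`, `probability`.
#' @return An `attention_profile` object.
#' @export
attention_profile <- function(sequence_id, spans, weights, prediction) {
  stopifnot(length(dim(weights)) == 3, dim(weights)[3] == nrow(spans))
  if (any(weights < 0)) abort("attention weights must be non-negative")
  sums <- apply(weights, c(1, 2), sum)
  if (any(abs(sums - 1) > 1e-6)) {
    abort("each head's [CLS] attention row must sum to 1")
  }
  structure(list(sequence_id = sequence_id, spans = spans,
                 weights = weights,
                 n_layers = dim(weights)[1], n_heads = dim(weights)[2],
                 prediction = prediction),
            class = "attention_profile")
}

#' @export
print.attention_profile <- function(x, ...) {
  cat(sprintf("<attention_profile> %s: %d layers x %d heads x %d tokens; predicted %d (p=%.3f)\n",
              x$sequence_id, x$n_layers, x$n_heads, nrow(x$spans),
              x$prediction$label, x$prediction$probability))
  invisible(x)
}

# overlap in bp between token spans and a set of half-open intervals
span_overlap_bp <- function(spans, intervals) {
  if (is.null(intervals) || nrow(intervals) == 0) return(rep(0L, nrow(spans)))
  ov <- rep(0L, nrow(spans))
  for (i in seq_len(nrow(intervals))) {
    ov <- ov + pmax(0L, pmin(spans$end, intervals$end[i]) -
                      pmax(spans$start, intervals$start[i]))
  }
  ov
}

# planted-interval tibble for one record row (columns planted_start/_end)
planted_intervals <- function(record) {
  if (!("planted_start" %in% names(record)) || is.na(record$planted_start)) {
    return(tibble::tibble(start = integer(0), end = integer(0)))
  }
  tibble::tibble(start = record$planted_start, end = record$planted_end)
}

#' Deterministic toy attention provider
#'
#' A stand-in for a fine-tuned transformer that satisfies the full
#' provider contract (`tokenize` / `profile` / `scorer`) so the discovery
#' and SHAP stages can run without a trained model. Per head, the
#' `[CLS]`-to-token weight is proportional to
#' `exp(kappa * overlap_fraction) + kappa * noise_sd * U(0,1)` where
#' `overlap_fraction` is the fraction of the token covered by planted
#' intervals; rows are then normalized to sum 1. At `kappa = 0` rows are
#' exactly uniform. The classifier predicts label 1 exactly when a planted
#' interval is present; its positive logit is
#' `4 * (planted bp visible) / (planted bp total) - 2`, which also defines
#' the masked-subset scorer used for SHAP (baseline = all tokens masked).
#' Everything is deterministic: the per-sequence noise stream is seeded
#' from `seed` and a hash of the sequence.
#'
#' @param k Token length for fixed-`k` tokenization.
#' @param kappa Attention sharpness (>= 0).
#' @param n_layers,n_heads Attention geometry.
#' @param noise_sd Relative amplitude of the additive attention noise.
#' @param seed Integer seed.
#' @return An `attention_provider` object (list of closures).
#' @export
toy_attention_provider <- function(k = 6, kappa = 8, n_layers = 4,
                                   n_heads = 4, noise_sd = 0.1, seed = 1) {
  stopifnot(is.finite(kappa), kappa >= 0, n_layers >= 1, n_heads >= 1)

  tokenize <- function(sequence) tokenize_sequence(sequence, k = k)

  logit_fn <- function(visible_bp, total_bp) {
    if (total_bp == 0) return(-2)
    4 * visible_bp / total_bp - 2
  }

  profile <- function(sequence, planted = NULL, sequence_id = NULL) {
    spans <- tokenize(sequence)
    J <- nrow(spans)
    planted <- planted %||% tibble::tibble(start = integer(0), end = integer(0))
    if (nrow(planted) > 0 &&
        (any(planted$start < 0) || any(planted$end > nchar(sequence)))) {
      abort("planted intervals out of sequence bounds")
    }
    ov <- span_overlap_bp(spans, planted) / (spans$end - spans$start)
    base <- exp(kappa * ov)
    noise <- with_seed(hash_seed(seed, sequence), {
      matrix(runif(n_layers * n_heads * J), n_layers * n_heads, J)
    })
    w <- sweep(noise * kappa * noise_sd, 2, base, "+")
    w <- w / rowSums(w)
    weights <- array(0, dim = c(n_layers, n_heads, J))
    for (l in seq_len(n_layers)) {
      weights[l, , ] <- w[(l - 1) * n_heads + seq_len(n_heads), , drop = FALSE]
    }
    total_bp <- sum(planted$end - planted$start)
    logit <- logit_fn(total_bp, max(total_bp, 1L)) # full sequence: all visible
    if (total_bp == 0) logit <- -2
    attention_profile(
      sequence_id = sequence_id %||% fnv1a_hex(sequence),
      spans = spans, weights = weights,
      prediction = list(label = as.integer(total_bp > 0), logit = logit,
                        probability = plogis(logit)))
  }

  scorer <- function(sequence, planted = NULL, unmasked = NULL) {
    spans <- tokenize(sequence)
    planted <- planted %||% tibble::tibble(start = integer(0), end = integer(0))
    unmasked <- unmasked %||% rep(TRUE, nrow(spans))
    stopifnot(length(unmasked) == nrow(spans))
    total_bp <- sum(planted$end - planted$start)
    visible <- sum(span_overlap_bp(spans[unmasked, , drop = FALSE], planted))
    logit_fn(visible, total_bp)
  }

  structure(list(type = "toy", k = k, kappa = kappa, n_layers = n_layers,
                 n_heads = n_heads, noise_sd = noise_sd, seed = seed,
                 tokenize = tokenize, profile = profile, scorer = scorer),
            class = "attention_provider")
}

#' @export
print.attention_provider <- function(x, ...) {
  cat(sprintf("<attention_provider> %s: k=%d, kappa=%g, %d layers x %d heads\n",
              x$type, x$k, x$kappa, x$n_layers, x$n_heads))
  invisible(x)
}

#' Keep only records the model classifies correctly
#'
#' Attention is only trustworthy where the model is right, so motif
#' discovery consumes profiles from correctly predicted records only.
#' Profiles are computed once here and carried along.
#'
#' @param records Labeled record tibble (columns `sequence`, `label`,
#'   optionally `transcript_id`, `planted_start`, `planted_end`).
#' @param provider An `attention_provider`.
#' @return List with `records` (the retained subset), `profiles` (named
#'   list of `attention_profile`s for retained records) and `counts`
#'   (per-class retained/total tibble).
#' @export
filter_correct_predictions <- function(records, provider) {
  if (!("label" %in% names(records))) abort("records must carry a label")
  ids <- records$transcript_id %||% paste0("seq_", seq_len(nrow(records)))
  profiles <- purrr::map(seq_len(nrow(records)), function(i) {
    provider$profile(records$sequence[i],
                     planted = planted_intervals(records[i, ]),
                     sequence_id = ids[i])
  })
  predicted <- purrr::map_int(profiles, ~ .x$prediction$label)
  keep <- predicted == records$label
  counts <- tibble::tibble(label = c(0L, 1L),
                           total = c(sum(records$label == 0),
                                     sum(records$label == 1)),
                           retained = c(sum(keep & records$label == 0),
                                        sum(keep & records$label == 1)))
  list(records = records[keep, , drop = FALSE],
       profiles = setNames(profiles[keep], ids[keep]),
       counts = counts)
}
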