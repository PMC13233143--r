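# enumerate all interior coalitions (sizes 1..J-1) as a logical matrix
all_coalitions <- function(J) {
  n <- 2^J - 2
  z <- matrix(FALSE, n, J)
  for (i in seq_len(n)) {
    z[i, ] <- as.logical(bitwAnd(i, 2^(seq_len(J) - 1)))
  }
  z
}

#' Kernel SHAP token attribution
#'
#' Weighted-least-squares Shapley value estimate with the Shapley kernel.
#' The value function is a black-box scorer over masking patterns
#' (`TRUE` = token present); the baseline is the all-masked pattern.
#' When `2^J - 2 <= n_coalitions` every interior coalition is enumerated
#' and kernel-weighted, which makes the estimate exact; otherwise
#' coalitions are sampled (sizes drawn with probability proportional to
#' the aggregated kernel mass `1 / (s (J - s))`). The efficiency
#' constraint `sum(phi) = f(full) - f(empty)` is imposed exactly by
#' eliminating one coefficient, so local accuracy always holds.
#'
#' @param scorer Function taking a logical mask of length `n_tokens` and
#'   returning the positive-class logit.
#' @param n_tokens Number of tokens `J`.
#' @param n_coalitions Evaluation budget (must be at least
#'   `2 * n_tokens + 2`).
#' @param seed Integer seed (sampling only).
#' @return Numeric vector of `J` Shapley values; the baseline value
#'   `f(empty)` is attached as attribute `"baseline"`.
#' @export
kernel_shap <- function(scorer, n_tokens, n_coalitions = 2 * n_tokens + 2048,
                        seed = 1) {
  J <- n_tokens
  stopifnot(J >= 1)
  if (n_coalitions < 2 * J + 2) {
    abort("n_coalitions must be at least 2 * n_tokens + 2")
  }
  v0 <- scorer(rep(FALSE, J))
  v1 <- scorer(rep(TRUE, J))
  delta <- v1 - v0
  if (J == 1) return(structure(delta, baseline = v0))

  full <- (2^J - 2) <= n_coalitions
  if (full) {
    Z <- all_coalitions(J)
    s <- rowSums(Z)
    w <- (J - 1) / (choose(J, s) * s * (J - s))
  } else {
    sizes <- 1:(J - 1)
    size_p <- 1 / (sizes * (J - sizes))
    Z <- with_seed(seed, {
      s_draw <- sample(sizes, n_coalitions, replace = TRUE,
                       prob = size_p / sum(size_p))
      t(vapply(s_draw, function(s) {
        z <- rep(FALSE, J)
        z[sample.int(J, s)] <- TRUE
        z
      }, logical(J)))
    })
    w <- rep(1, nrow(Z))
  }
  y <- apply(Z, 1, scorer) - v0
  # impose efficiency by substituting phi_J = delta - sum(phi_{-J})
  zJ <- Z[, J]
  Xt <- Z[, -J, drop = FALSE] - zJ
  yt <- y - zJ * delta
  fit <- stats::lm.wfit(x = Xt * 1, y = yt, w = w)
  phi <- fit$coefficients
  phi[is.na(phi)] <- 0
  phi <- c(phi, delta - sum(phi))
  structure(unname(phi), baseline = v0)
}

#' Exact Shapley values by enumeration
#'
#' Direct evaluation of the Shapley formula over all `2^J` coalitions,
#' used as the independent oracle for [kernel_shap()]. Refuses more than
#' 12 tokens.
#'
#' @param scorer Black-box scorer over logical masks.
#' @param n_tokens Number of tokens (at most 12).
#' @return Numeric vector of exact Shapley values with a `"baseline"`
#'   attribute.
#' @export
exact_shapley <- function(scorer, n_tokens) {
  J <- n_tokens
  if (J > 12) abort("exact enumeration refuses more than 12 tokens")
  v <- numeric(2^J)
  for (m in 0:(2^J - 1)) {
    v[m + 1] <- scorer(as.logical(bitwAnd(m, 2^(seq_len(J) - 1))))
  }
  wgt <- factorial(0:(J - 1)) * factorial(J - 1 - 0:(J - 1)) / factorial(J)
  phi <- numeric(J)
  for (j in seq_len(J)) {
    bit <- 2^(j - 1)
    for (m in 0:(2^J - 1)) {
      if (bitwAnd(m, bit) == 0) {
        s <- sum(as.logical(bitwAnd(m, 2^(seq_len(J) - 1))))
        phi[j] <- phi[j] + wgt[s + 1] * (v[m + bit + 1] - v[m + 1])
      }
    }
  }
  structure(phi, baseline = v[1])
}

#' Per-token SHAP attributions for a record set
#'
#' Runs [kernel_shap()] on every record with the provider's masked-subset
#' scorer (baseline = all tokens masked) and returns the long attribution
#' table that [summarize_tokens()] consumes.
#'
#' @param records Labeled record tibble.
#' @param provider An `attention_provider`.
#' @param n_coalitions Per-record coalition budget (`NULL` for the
#'   [kernel_shap()] default).
#' @param seed Integer seed.
#' @return Tibble with `sequence_id`, `token_text`, `position` (1-based
#'   token index), `shap_value`.
#' @export
shap_tokens <- function(records, provider, n_coalitions = NULL, seed = 1) {
  ids <- records$transcript_id %||% paste0("seq_", seq_len(nrow(records)))
  rows <- purrr::map(seq_len(nrow(records)), function(i) {
    sequence <- records$sequence[i]
    planted <- planted_intervals(records[i, ])
    spans <- provider$tokenize(sequence)
    J <- nrow(spans)
    scorer <- function(mask) provider$scorer(sequence, planted, mask)
    phi <- kernel_shap(scorer, J,
                       n_coalitions = n_coalitions %||% (2 * J + 2048),
                       seed = hash_seed(seed, ids[i]))
    tibble::tibble(sequence_id = ids[i], token_text = toupper(spans$token),
                   position = seq_len(J), shap_value = as.numeric(phi))
  })
  dplyr::bind_rows(rows)
}

#' Summarize SHAP attributions per unique token
#'
#' Groups attributions by token text across all sequences and reports the
#' occurrence count, mean SHAP value, mean absolute SHAP value (plus the
#' absolute value of the mean, so either reading of "absolute mean" is
#' available), sample standard deviation, and the normal-approximation
#' 95% CI half-width `1.96 * sd / sqrt(n)`. Tokens rarer than `min_count`
#' are dropped as noise.
#'
#' @param attributions Attribution tibble from [shap_tokens()].
#' @param min_count Minimum occurrence count (default 5, must be >= 2).
#' @return A `shap_token_summary` tibble sorted by mean absolute SHAP.
#' @export
summarize_tokens <- function(attributions, min_count = 5) {
  stopifnot(min_count >= 2)
  out <- dplyr::summarise(
    dplyr::group_by(attributions, .data$token_text),
    n = dplyr::n(),
    mean_shap = mean(.data$shap_value),
    abs_mean_shap = mean(abs(.data$shap_value)),
    abs_of_mean = abs(mean(.data$shap_value)),
    sd = sd(.data$shap_value),
    .groups = "drop")
  out$ci_half_width <- 1.96 * out$sd / sqrt(out$n)
  out <- out[out$n >= min_count, , drop = FALSE]
  out <- dplyr::arrange(out, dplyr::desc(.data$abs_mean_shap),
                        .data$token_text)
  class(out) <- c("shap_token_summary", class(out))
  out
}

#' Rank summarized tokens and split by contribution sign
#'
#' Stable descending sort on the chosen key (ties broken lexicographically
#' by token), truncated to the top `k`, with each token tagged as a
#' positive or negative contributor by the sign of its mean SHAP value.
#'
#' @param summary A [summarize_tokens()] table.
#' @param by Ranking key: `"abs_mean"`, `"mean"`, or `"frequency"`.
#' @param top_k Number of tokens to keep.
#' @return Tibble with `rank` and `direction` columns added.
#' @export
rank_tokens <- function(summary, by = c("abs_mean", "mean", "frequency"),
                        top_k = 10) {
  by <- match.arg(by)
  stopifnot(top_k >= 1)
  key <- switch(by, abs_mean = summary$abs_mean_shap,
                mean = summary$mean_shap, frequency = summary$n)
  ord <- order(-key, summary$token_text)
  out <- tibble::as_tibble(summary)[ord, , drop = FALSE]
  out <- head(out, top_k)
  out$rank <- seq_len(nrow(out))
  out$direction <- dplyr::case_when(out$mean_shap > 0 ~ "positive",
                                    out$mean_shap < 0 ~ "negative",
                                    TRUE ~ "zero")
  out
}
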