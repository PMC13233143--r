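#' Tidy a motif discovery result
#'
#' @param x A `motif_discovery`.
#' @param ... Unused.
#' @return The motif enrichment tibble (one row per tested motif).
#' @method tidy motif_discovery
#' @export
tidy.motif_discovery <- function(x, ...) {
  x$motifs
}

#' One-row summary of a motif discovery result
#'
#' @param x A `motif_discovery`.
#' @param ... Unused.
#' @return One-row tibble with retention, testing, and merge counts.
#' @method glance motif_discovery
#' @export
glance.motif_discovery <- function(x, ...) {
  dplyr::mutate(pipeline_report(x),
                n_retained = sum(x$counts$retained),
                n_records = sum(x$counts$total))
}

#' Tidy a positional profile
#'
#' @param x A `positional_profile`.
#' @param ... Unused.
#' @return The per-bin tibble.
#' @method tidy positional_profile
#' @export
tidy.positional_profile <- function(x, ...) {
  x$bins
}

#' One-row summary of a positional profile
#'
#' @param x A `positional_profile`.
#' @param ... Unused.
#' @return One-row tibble with instance counts and the smoothed-peak bin.
#' @method glance positional_profile
#' @export
glance.positional_profile <- function(x, ...) {
  peak <- x$bins$bin_start[which.max(x$bins$smoothed)]
  tibble::tibble(n_instances = length(x$distances),
                 n_bins = nrow(x$bins),
                 bin_width = x$bin_width,
                 peak_bin_start = peak,
                 kde_mode = if (is.null(x$kde)) NA_real_ else
                   x$kde$distance[which.max(x$kde$density)])
}
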