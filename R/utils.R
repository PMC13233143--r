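#' Reverse complement of DNA strings
#'
#' Case-preserving reverse complement. Soft-masked (lowercase) bases stay
#' lowercase so repeat annotation survives the operation; `N`/`n` map to
#' themselves.
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of reverse-complemented strings.
#' @export
#' @examples
#' revcomp("ACGTn")
revcomp <- function(x) {
  flipped <- chartr("ACGTacgtNn", "TGCAtgcaNn", x)
  vapply(flipped, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' GC content of DNA strings
#'
#' Fraction of G/C among unambiguous A/C/G/T bases, case-insensitive.
#' Returns `NaN` for sequences with no unambiguous base.
#'
#' @param x Character vector of DNA strings.
#' @return Numeric vector of GC fractions.
#' @export
gc_content <- function(x) {
  up <- toupper(x)
  gc <- stringr::str_count(up, "[GC]")
  acgt <- stringr::str_count(up, "[ACGT]")
  gc / acgt
}

#' Soft-masked (repeat) fraction of DNA strings
#'
#' Proportion of lowercase bases, the conventional encoding of
#' repeat-annotated (soft-masked) sequence in genome FASTA files.
#'
#' @param x Character vector of DNA strings.
#' @return Numeric vector in `[0, 1]`.
#' @export
repeat_fraction <- function(x) {
  stringr::str_count(x, "[acgtn]") / nchar(x)
}

# Deterministic per-record seed derived from a base seed and a string id.
# Vectorized position-weighted checksum folded into [0, 2^31); only needs
# to spread distinct ids over distinct RNG streams, not to be cryptographic.
hash_seed <- function(seed, id) {
  b <- utf8ToInt(as.character(id))
  h <- sum(b * (seq_along(b) %% 9973 + 1)) %% 2147483647
  as.integer((h + as.numeric(seed) * 7919) %% 2147483647)
}

# Run code under a local RNG state seeded deterministically.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# FNV-1a hash of a string rendered as 8 hex digits; used for run manifests.
# Kept in doubles (R has no unsigned 32-bit type): the xor only touches the
# low byte, so it can be done on the low byte alone.
fnv1a_hex <- function(x) {
  h <- 2166136261
  for (b in utf8ToInt(x)) {
    lb <- h %% 256
    h <- h - lb + bitwXor(as.integer(lb), as.integer(b))
    lo <- (h %% 65536) * 16777619
    hi <- (h %/% 65536) * 16777619 %% 65536
    h <- (lo + hi * 65536) %% 4294967296
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

#' Write DNA sequences to a FASTA file
#'
#' Plain-text writer that preserves case (soft-masking). Wraps at 70
#' columns.
#'
#' @param x Named character vector of sequences.
#' @param path Output file path.
#' @param width Line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70) {
  stopifnot(!is.null(names(x)), all(nzchar(names(x))))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(x)) {
    writeLines(paste0(">", names(x)[i]), con)
    s <- x[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' Case-preserving reader (lowercase soft-masking kept). Uses Biostrings
#' when available, otherwise a plain-text fallback.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::readBStringSet(path)
    return(setNames(as.character(ss), names(ss)))
  }
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) abort("not a FASTA file: no '>' header found")
  idx <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], idx[!hdr]), paste, character(1), collapse = "")
  names(seqs) <- sub("^>\\s*", "", lines[hdr])[as.integer(names(seqs))]
  seqs
}
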