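# Coordinate convention used throughout: 0-based, half-open intervals on the
# top strand; positions on a circular sequence are reduced modulo its length.

#' Validate a DNA sequence
#'
#' Checks that a string is non-empty strict DNA over the alphabet ACGT.
#' Lowercase input is uppercased; IUPAC ambiguity codes and U are rejected.
#'
#' @param seq character scalar.
#' @param what label used in error messages.
#' @return The validated, uppercased sequence.
#' @export
as_dna <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop(what, " must be a single character string", call. = FALSE)
  seq <- toupper(seq)
  if (nchar(seq) == 0L)
    stop(what, " must have length >= 1", call. = FALSE)
  if (grepl("[^ACGT]", seq)) {
    bad <- unique(strsplit(gsub("[ACGT]", "", seq), "")[[1]])
    stop(what, " contains non-ACGT characters: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  seq
}

#' Reverse complement
#'
#' @param seq DNA string (ACGT only) or character vector of them.
#' @return Reverse complement(s), same length as input.
#' @examples
#' revcomp("ACGT")  # "ACGT"
#' revcomp("AAAA")  # "TTTT"
#' @export
revcomp <- function(seq) {
  if (length(seq) == 1L) {
    as_dna(seq)
  } else {
    invisible(lapply(seq, as_dna))
  }
  comp <- chartr("ACGT", "TGCA", toupper(seq))
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""),
         character(1))
}

#' GC content of a DNA sequence
#'
#' @param seq DNA string, length >= 1.
#' @return Fraction of G+C bases in `[0, 1]`.
#' @export
gc_content <- function(seq) {
  seq <- as_dna(seq)
  n <- nchar(seq)
  gc <- n - nchar(gsub("[GC]", "", seq))
  gc / n
}

# Booth's least-rotation algorithm; returns the 0-based start index of the
# lexicographically smallest rotation.
least_rotation_index <- function(seq) {
  s <- utf8ToInt(paste0(seq, seq))
  n <- nchar(seq)
  f <- rep(-1L, 2L * n)
  k <- 0L
  for (j in 2:(2L * n)) {
    sj <- s[j]
    i <- f[j - k - 1L]
    while (i != -1L && sj != s[k + i + 2L]) {
      if (sj < s[k + i + 2L]) k <- j - i - 2L
      i <- f[i + 1L]
    }
    if (sj != s[k + i + 2L]) {
      if (sj < s[k + 1L]) k <- j - 1L
      f[j - k] <- -1L
    } else {
      f[j - k] <- i + 1L
    }
  }
  k
}

#' Canonical form of a circular DNA sequence
#'
#' Returns the lexicographically smallest rotation of the sequence or of its
#' reverse complement, whichever is smaller. Two circular sequences represent
#' the same molecule (up to rotation and strand flip) iff their canonical
#' forms are identical.
#'
#' @param circular_seq DNA string interpreted as a circle.
#' @return Canonical linear representation.
#' @export
rotate_to_canonical <- function(circular_seq) {
  s <- as_dna(circular_seq)
  n <- nchar(s)
  if (n == 1L) return(s)
  best_of <- function(x) {
    k <- least_rotation_index(x)
    substr(paste0(x, x), k + 1L, k + n)
  }
  a <- best_of(s)
  b <- best_of(revcomp(s))
  if (a <= b) a else b
}

# Circular substring of `len` characters starting at 0-based position `from`.
circ_sub <- function(seq, from, len) {
  n <- nchar(seq)
  stopifnot(len <= n)
  from <- ((from %% n) + n) %% n
  if (from + len <= n) {
    substr(seq, from + 1L, from + len)
  } else {
    paste0(substr(seq, from + 1L, n), substr(seq, 1L, from + len - n))
  }
}

# All k-mers of a linear sequence (character vector; empty if too short).
kmers_of <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1L), k:n)
}

# Deterministic sub-seed derived from a base seed and a stream name, so each
# fixture component consumes an independent stream (kept below 2^31).
derive_seed <- function(seed, stream) {
  codes <- utf8ToInt(stream)
  h <- as.double(seed %% 2147483647L)
  for (c in codes) h <- (h * 131 + c) %% 2147483629
  as.integer(h)
}
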