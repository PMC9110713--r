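# Minimal GenBank flat-file support (LOCUS / FEATURES / ORIGIN), enough to
# ingest annotated fragments and round-trip the feature table. Sequence
# records are strict DNA; features keep their key, location string, and
# qualifiers.

#' Read a GenBank flat file
#'
#' Parses the LOCUS name, the FEATURES table (key, location, qualifiers) and
#' the ORIGIN sequence block.
#'
#' @param path GenBank file.
#' @return list with `name`, `sequence`, and `features` (data.frame with
#'   columns `record`, `key`, `location`, `qualifier`, `value`).
#' @export
read_genbank <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !grepl("^LOCUS", lines[1]))
    stop("format error in ", path, " line 1: expected LOCUS", call. = FALSE)
  name <- strsplit(trimws(sub("^LOCUS", "", lines[1])), "\\s+")[[1]][1]

  fstart <- grep("^FEATURES", lines)
  ostart <- grep("^ORIGIN", lines)
  if (!length(ostart))
    stop("format error in ", path, ": no ORIGIN block", call. = FALSE)
  ostart <- ostart[1]

  features <- NULL
  if (length(fstart)) {
    block <- lines[(fstart[1] + 1L):(ostart - 1L)]
    block <- block[!grepl("^\\S", block)]  # drop any stray top-level lines
    rows <- list()
    key <- loc <- NULL
    qual <- character(0)
    flush <- function() {
      if (is.null(key)) return()
      if (!length(qual)) qual <- c("." = ".")
      rows[[length(rows) + 1L]] <<- data.frame(
        record = name, key = key, location = loc,
        qualifier = names(qual), value = unname(qual),
        stringsAsFactors = FALSE)
    }
    pending_q <- NULL
    for (ln in block) {
      if (grepl("^ {5}\\S", ln)) {                # new feature
        if (!is.null(pending_q)) { qual <- c(qual, pending_q); pending_q <- NULL }
        flush()
        parts <- strsplit(trimws(ln), "\\s+")[[1]]
        key <- parts[1]
        loc <- paste(parts[-1], collapse = "")
        qual <- character(0)
      } else if (grepl("^ +/", ln)) {             # qualifier
        if (!is.null(pending_q)) { qual <- c(qual, pending_q); pending_q <- NULL }
        q <- sub("^ +/", "", ln)
        if (grepl("=", q)) {
          k <- sub("=.*$", "", q)
          v <- sub("^[^=]*=", "", q)
          v <- gsub("^\"|\"$", "", v)
        } else {
          k <- q; v <- "true"
        }
        pending_q <- stats::setNames(v, k)
      } else if (!is.null(pending_q)) {           # continuation line
        pending_q[] <- paste0(pending_q, gsub("^\\s+|\"$", "", ln))
      } else if (!is.null(loc)) {                 # location continuation
        loc <- paste0(loc, trimws(ln))
      }
    }
    if (!is.null(pending_q)) qual <- c(qual, pending_q)
    flush()
    if (length(rows)) features <- do.call(rbind, rows)
  }

  seq_lines <- lines[(ostart + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  seq <- gsub("[0-9 /]", "", paste(seq_lines, collapse = ""))
  bad <- grep("[^ACGTacgt]", seq)
  if (length(bad) || grepl("[^ACGTacgt]", seq)) {
    ln <- ostart + which(grepl("[^ACGTacgt0-9 ]",
                               seq_lines))[1]
    stop("validation error in ", path, " line ", ln,
         ": non-ACGT character in sequence", call. = FALSE)
  }
  list(name = name, sequence = as_dna(seq, what = paste0(path, " sequence")),
       features = features)
}

#' Write a GenBank flat file
#'
#' @param name LOCUS name.
#' @param sequence DNA string.
#' @param path output file.
#' @param features optional data.frame with columns `key`, `location`,
#'   `qualifier`, `value` (one row per qualifier; rows with the same
#'   key+location form one feature).
#' @param circular mark the molecule circular in the LOCUS line.
#' @return `path` invisibly.
#' @export
write_genbank <- function(name, sequence, path, features = NULL,
                          circular = TRUE) {
  sequence <- as_dna(sequence)
  n <- nchar(sequence)
  out <- c(sprintf("LOCUS       %-16s %d bp    DNA     %s   SYN",
                   name, n, if (circular) "circular" else "linear"),
           sprintf("DEFINITION  %s.", name),
           "FEATURES             Location/Qualifiers")
  if (!is.null(features) && nrow(features)) {
    keyloc <- paste(features$key, features$location, sep = "\r")
    for (kl in unique(keyloc)) {
      rows <- features[keyloc == kl, , drop = FALSE]
      out <- c(out, sprintf("     %-16s%s", rows$key[1], rows$location[1]))
      for (i in seq_len(nrow(rows)))
        if (rows$qualifier[i] != ".")
          out <- c(out, sprintf("                     /%s=\"%s\"",
                                rows$qualifier[i], rows$value[i]))
    }
  }
  out <- c(out, "ORIGIN")
  lower <- tolower(sequence)
  for (start in seq(1L, n, by = 60L)) {
    chunk <- substr(lower, start, min(start + 59L, n))
    blocks <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", start, paste(blocks, collapse = " ")))
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}
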