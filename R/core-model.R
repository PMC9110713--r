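# Core data model: Fragment, PlasmidDesign, Junction.
#
# Fragments are the raw abutting parts: the circular target sequence is their
# in-order concatenation. The 24-bp junction homology shared by adjacent PCR
# amplicons is NOT part of the raw fragments; it is installed later by primer
# overhangs once recognition sites are chosen.

SEARCH_FLANK <- 40L   # bp taken from each side of a fragment boundary
WINDOW_LEN <- 24L     # recognition sequence length
GUIDE_LEN <- 16L      # one guide DNA
STICKY_LEN <- 12L     # 5' overhang left by ARE digestion

#' Create a Fragment
#'
#' @param id short unique identifier.
#' @param sequence DNA string (ACGT; lowercase accepted and uppercased).
#' @param role one of `"backbone"`, `"insert"`, `"linker"`.
#' @param order_index 0-based position in the assembly.
#' @param template_id optional id of the PCR template source.
#' @return An object of class `fragment`.
#' @export
fragment <- function(id, sequence, role = c("insert", "backbone", "linker"),
                     order_index = 0L, template_id = NA_character_) {
  role <- match.arg(role)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- as_dna(sequence, what = paste0("fragment '", id, "' sequence"))
  order_index <- as.integer(order_index)
  if (is.na(order_index) || order_index < 0L)
    stop("order_index must be an integer >= 0", call. = FALSE)
  structure(
    list(id = id, sequence = sequence, role = role,
         order_index = order_index, template_id = template_id),
    class = "fragment")
}

#' Assemble a PlasmidDesign from fragments
#'
#' Orders the fragments by `order_index`, concatenates them into the circular
#' target sequence, and builds one junction per adjacent pair (including the
#' wrap-around pair), each with its 80-nt guide search space (40 nt from the
#' end of each adjoining fragment).
#'
#' @param name design name.
#' @param fragments list of [fragment()] objects with contiguous
#'   `order_index` values `0..n-1`.
#' @return An object of class `plasmid_design` with elements `name`,
#'   `fragments`, `target_sequence`, `junctions`.
#' @export
plasmid_design <- function(name, fragments) {
  stopifnot(is.list(fragments), length(fragments) >= 1L)
  ok <- vapply(fragments, inherits, logical(1), "fragment")
  if (!all(ok)) stop("all elements must be fragment objects", call. = FALSE)
  ids <- vapply(fragments, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop("duplicate fragment id: ", ids[duplicated(ids)][1], call. = FALSE)
  idx <- vapply(fragments, `[[`, integer(1), "order_index")
  if (!identical(sort(idx), seq_along(fragments) - 1L))
    stop("order_index values must be a contiguous 0..n-1 permutation",
         call. = FALSE)
  fragments <- fragments[order(idx)]
  target <- paste(vapply(fragments, `[[`, character(1), "sequence"),
                  collapse = "")
  design <- structure(
    list(name = name, fragments = fragments,
         target_sequence = target, junctions = NULL),
    class = "plasmid_design")
  design$junctions <- build_junctions(design)
  design
}

# Fragment interval [start, end) in target coordinates (0-based).
fragment_intervals <- function(design) {
  lens <- vapply(design$fragments, function(f) nchar(f$sequence), integer(1))
  ends <- cumsum(lens)
  starts <- ends - lens
  data.frame(id = vapply(design$fragments, `[[`, character(1), "id"),
             start = starts, end = ends, length = lens,
             stringsAsFactors = FALSE)
}

build_junctions <- function(design) {
  n <- length(design$fragments)
  iv <- fragment_intervals(design)
  lapply(seq_len(n) - 1L, function(j) {
    up <- j + 1L
    down <- if (j == n - 1L) 1L else j + 2L
    junction(design, index = j,
             upstream = iv$id[up], downstream = iv$id[down],
             boundary = iv$end[up])
  })
}

junction <- function(design, index, upstream, downstream, boundary) {
  n <- nchar(design$target_sequence)
  iv <- fragment_intervals(design)
  for (fid in c(upstream, downstream)) {
    len <- iv$length[iv$id == fid]
    role <- design$fragments[[which(iv$id == fid)]]$role
    if (len < SEARCH_FLANK && role != "linker")
      stop("fragment '", fid, "' is shorter than ", SEARCH_FLANK,
           " bp; only linker-role fragments may take the small-fragment ",
           "workflow", call. = FALSE)
  }
  origin <- ((boundary - SEARCH_FLANK) %% n + n) %% n
  structure(
    list(index = as.integer(index),
         upstream_fragment_id = upstream,
         downstream_fragment_id = downstream,
         boundary = as.integer(boundary %% n),
         search_space = circ_sub(design$target_sequence, origin,
                                 2L * SEARCH_FLANK),
         search_space_origin = as.integer(origin),
         chosen_site = NULL),
    class = "junction")
}

#' @export
print.plasmid_design <- function(x, ...) {
  cat("<plasmid_design> ", x$name, "\n", sep = "")
  cat("  fragments: ", length(x$fragments),
      "  target: ", nchar(x$target_sequence), " bp (circular)\n", sep = "")
  iv <- fragment_intervals(x)
  for (i in seq_len(nrow(iv)))
    cat(sprintf("  [%d] %s  %d bp  (%s)\n", i - 1L, iv$id[i], iv$length[i],
                x$fragments[[i]]$role))
  sites <- sum(vapply(x$junctions,
                      function(j) !is.null(j$chosen_site), logical(1)))
  cat("  junctions: ", length(x$junctions), " (", sites,
      " with chosen recognition sites)\n", sep = "")
  invisible(x)
}

#' Read a fragment-order manifest
#'
#' The manifest is a TSV with columns `fragment_id`, `file`, `role`,
#' `order_index`, and optionally `template_id`.
#'
#' @param path manifest file path.
#' @return data.frame, one row per fragment.
#' @export
read_manifest <- function(path) {
  m <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("fragment_id", "file", "role", "order_index")
  missing <- setdiff(need, names(m))
  if (length(missing))
    stop("manifest ", path, " lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (is.null(m$template_id)) m$template_id <- NA_character_
  if (anyDuplicated(m$fragment_id))
    stop("manifest lists fragment '",
         m$fragment_id[duplicated(m$fragment_id)][1],
         "' more than once", call. = FALSE)
  m
}

#' Load a plasmid design from sequence files and a manifest
#'
#' Sequence files may be FASTA (one or more records; record names must match
#' `fragment_id`s) or GenBank flat files. Fragment order follows the
#' manifest's `order_index`; the circular target sequence is the in-order
#' concatenation of the raw fragments (24-bp junction homology is added later
#' by primer design).
#'
#' @param manifest path to the manifest TSV, or a data.frame as returned by
#'   [read_manifest()].
#' @param dir directory against which relative `file` entries are resolved.
#' @param name design name (defaults to the manifest file name).
#' @return A [plasmid_design()] with junctions built. GenBank feature tables
#'   are attached as the `features` attribute (a data.frame) for reporting.
#' @export
load_design <- function(manifest, dir = ".", name = NULL) {
  if (is.character(manifest)) {
    if (is.null(name))
      name <- sub("\\.[^.]*$", "", basename(manifest))
    manifest <- read_manifest(manifest)
  }
  if (is.null(name)) name <- "design"
  feats <- list()
  seqs <- list()
  for (f in unique(manifest$file)) {
    path <- if (file.exists(f)) f else file.path(dir, f)
    if (!file.exists(path))
      stop("sequence file not found: ", f, call. = FALSE)
    rec <- read_sequences(path)
    seqs[names(rec$sequences)] <- rec$sequences
    if (!is.null(rec$features)) feats[[path]] <- rec$features
  }
  frags <- lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    s <- seqs[[row$fragment_id]]
    if (is.null(s))
      stop("fragment '", row$fragment_id, "' not found in file ",
           row$file, call. = FALSE)
    fragment(row$fragment_id, s, role = row$role,
             order_index = row$order_index,
             template_id = if (is.na(row$template_id)) NA_character_
                           else row$template_id)
  })
  design <- plasmid_design(name, frags)
  if (length(feats))
    attr(design, "features") <- do.call(rbind, unname(feats))
  design
}

# Dispatch on file content: GenBank flat files start with LOCUS.
read_sequences <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("^LOCUS", first)) {
    gb <- read_genbank(path)
    list(sequences = stats::setNames(list(gb$sequence), gb$name),
         features = gb$features)
  } else if (grepl("^>", first)) {
    set <- Biostrings::readDNAStringSet(path)
    seqs <- as.character(set)
    names(seqs) <- sub("\\s.*$", "", names(set))
    for (i in seq_along(seqs))
      seqs[[i]] <- as_dna(seqs[[i]], what = paste0("record '",
                                                   names(seqs)[i], "'"))
    list(sequences = as.list(seqs), features = NULL)
  } else {
    stop("cannot parse ", path,
         ": line 1 is neither a FASTA header nor a GenBank LOCUS line",
         call. = FALSE)
  }
}

#' Serialize a design to JSON
#'
#' @param design a `plasmid_design`.
#' @param path output file; if `NULL` the JSON string is returned.
#' @return `path` invisibly, or the JSON string.
#' @export
write_design_json <- function(design, path = NULL) {
  x <- list(
    name = design$name,
    target_sequence = design$target_sequence,
    fragments = lapply(design$fragments, function(f)
      f[c("id", "sequence", "role", "order_index", "template_id")]),
    junctions = lapply(design$junctions, function(j)
      j[c("index", "upstream_fragment_id", "downstream_fragment_id",
          "search_space", "search_space_origin")]))
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(path)
}

#' Read a design back from JSON
#'
#' @param path file written by [write_design_json()].
#' @return A `plasmid_design`.
#' @export
read_design_json <- function(path) {
  x <- jsonlite::read_json(path)
  frags <- lapply(x$fragments, function(f)
    fragment(f$id, f$sequence, role = f$role, order_index = f$order_index,
             template_id = if (is.null(f$template_id)) NA_character_
                           else f$template_id))
  plasmid_design(x$name, frags)
}
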