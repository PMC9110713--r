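# Synthetic design generator. Emulates the envelope of real assembly jobs —
# 3-11 fragments, fragment sizes in the few-hundred-bp to few-kb range, GC
# content up to ~0.77, optionally several identical internal repeats (e.g.
# the same promoter reused in four expression cassettes) — while keeping the
# terminal 40 bp of every fragment repeat-free so the guide search space is
# usable by construction.

#' Specification for a synthetic plasmid design
#'
#' @param n_fragments number of fragments (>= 1).
#' @param size_range `c(min_bp, max_bp)` fragment-length range; `min_bp`
#'   must be >= 100.
#' @param gc_target target GC fraction; realized per-fragment GC is held
#'   within +/- 3 percentage points by a rejection loop.
#' @param n_repeats number of fragments carrying one identical planted
#'   internal repeat (0 disables).
#' @param repeat_length repeat length in bp; must leave 40-bp repeat-free
#'   fragment ends.
#' @param seed integer seed; the same spec yields byte-identical designs.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_fragments = 5L, size_range = c(800L, 2500L),
                         gc_target = 0.5, n_repeats = 0L,
                         repeat_length = 500L, seed = 1L) {
  n_fragments <- as.integer(n_fragments)
  size_range <- as.integer(size_range)
  stopifnot(n_fragments >= 1L, length(size_range) == 2L,
            gc_target >= 0, gc_target <= 1, n_repeats >= 0L)
  if (size_range[1] < 100L)
    stop("size_range minimum must be >= 100 bp", call. = FALSE)
  if (size_range[1] > size_range[2])
    stop("size_range must be (min, max) with min <= max", call. = FALSE)
  if (n_repeats > 0L && repeat_length + 2L * SEARCH_FLANK > size_range[1])
    stop("repeat_length ", repeat_length, " cannot fit inside a ",
         size_range[1], " bp fragment with ", SEARCH_FLANK,
         " bp repeat-free ends", call. = FALSE)
  if (n_repeats > n_fragments)
    stop("n_repeats cannot exceed n_fragments", call. = FALSE)
  structure(list(n_fragments = n_fragments, size_range = size_range,
                 gc_target = gc_target, n_repeats = as.integer(n_repeats),
                 repeat_length = as.integer(repeat_length),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

# Random DNA of length n with GC held within tol of target (rejection loop).
random_dna <- function(n, gc_target, tol = 0.03) {
  p <- c(A = (1 - gc_target) / 2, C = gc_target / 2,
         G = gc_target / 2, T = (1 - gc_target) / 2)
  for (i in 1:200) {
    s <- paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
    if (abs(gc_content(s) - gc_target) <= tol) return(s)
  }
  stop("could not reach GC target ", gc_target, " within +/-", tol,
       call. = FALSE)
}

#' Generate a synthetic plasmid design
#'
#' Draws fragment lengths uniformly from `size_range`, samples bases i.i.d.
#' with `p(G) = p(C) = gc_target / 2` under a +/- 3 pp rejection loop, and,
#' if requested, plants one identical `repeat_length`-bp subsequence
#' internally in `n_repeats` distinct fragments, never within 40 bp of a
#' fragment end. Each random draw uses a named sub-stream of `spec$seed`, so
#' the fixtures are reproducible component-by-component.
#'
#' @param spec a [fixture_spec()].
#' @return A [plasmid_design()]; the planted repeat (if any) is attached as
#'   the `planted_repeat` attribute.
#' @export
generate_design <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr_seed <- function(stream, expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    set.seed(derive_seed(spec$seed, stream))
    on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
            else assign(".Random.seed", old, envir = globalenv()))
    expr
  }
  lens <- withr_seed("lengths",
    sample(seq(spec$size_range[1], spec$size_range[2]), spec$n_fragments,
           replace = TRUE))
  seqs <- vapply(seq_len(spec$n_fragments), function(i)
    withr_seed(paste0("fragment", i),
               random_dna(lens[i], spec$gc_target)), character(1))

  rep_seq <- NULL
  if (spec$n_repeats > 0L) {
    rep_seq <- withr_seed("repeat",
                          random_dna(spec$repeat_length, spec$gc_target))
    carriers <- withr_seed("carriers",
      sample(seq_len(spec$n_fragments), spec$n_repeats))
    for (i in carriers) {
      lo <- SEARCH_FLANK + 1L
      hi <- lens[i] - SEARCH_FLANK - spec$repeat_length + 1L
      pos <- withr_seed(paste0("repeat_pos", i),
                        sample(seq(lo, hi), 1L))
      substr(seqs[i], pos, pos + spec$repeat_length - 1L) <- rep_seq
    }
  }

  frags <- lapply(seq_len(spec$n_fragments), function(i)
    fragment(sprintf("f%02d", i), seqs[i],
             role = if (i == 1L) "backbone" else "insert",
             order_index = i - 1L,
             template_id = sprintf("t%02d", i)))
  design <- plasmid_design(
    sprintf("fixture_n%d_gc%02.0f_s%d", spec$n_fragments,
            100 * spec$gc_target, spec$seed),
    frags)
  attr(design, "planted_repeat") <- rep_seq
  design
}

#' Simulate a measured fragment-concentration table
#'
#' Emulates the post-PCR quantification sheet used for equimolar mixing:
#' one concentration per fragment, drawn uniformly from `range`.
#'
#' @param design a `plasmid_design`.
#' @param seed integer seed.
#' @param range `c(lo, hi)` concentration range in ng/uL.
#' @return data.frame with columns `fragment_id`, `ng_per_uL`.
#' @export
generate_concentration_table <- function(design, seed = 1L,
                                         range = c(20, 150)) {
  set.seed(derive_seed(seed, "concentrations"))
  ids <- vapply(design$fragments, `[[`, character(1), "id")
  data.frame(fragment_id = ids,
             ng_per_uL = round(runif(length(ids), range[1], range[2]), 2),
             stringsAsFactors = FALSE)
}

#' Write a design to disk as FASTA + manifest + concentrations
#'
#' Produces per-fragment FASTA files, a manifest TSV consumable by
#' [load_design()], a GenBank rendering of the circular target, and a
#' concentration CSV.
#'
#' @param design a `plasmid_design`.
#' @param dir output directory (created if needed).
#' @param seed seed for the concentration table.
#' @return Invisibly, the manifest path.
#' @export
write_design_files <- function(design, dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- vapply(design$fragments, `[[`, character(1), "id")
  files <- paste0(ids, ".fasta")
  for (i in seq_along(design$fragments)) {
    set <- Biostrings::DNAStringSet(design$fragments[[i]]$sequence)
    names(set) <- ids[i]
    Biostrings::writeXStringSet(set, file.path(dir, files[i]))
  }
  manifest <- data.frame(
    fragment_id = ids, file = files,
    role = vapply(design$fragments, `[[`, character(1), "role"),
    order_index = vapply(design$fragments, `[[`, integer(1), "order_index"),
    template_id = vapply(design$fragments, `[[`, character(1),
                         "template_id"),
    stringsAsFactors = FALSE)
  mpath <- file.path(dir, "manifest.tsv")
  write.table(manifest, mpath, sep = "\t", quote = FALSE, row.names = FALSE)
  iv <- fragment_intervals(design)
  feats <- data.frame(
    key = "misc_feature",
    location = sprintf("%d..%d", iv$start + 1L, iv$end),
    qualifier = "label", value = iv$id, stringsAsFactors = FALSE)
  write_genbank(design$name, design$target_sequence,
                file.path(dir, paste0(design$name, ".gb")),
                features = feats)
  conc <- generate_concentration_table(design, seed = seed)
  write.csv(conc, file.path(dir, "concentrations.csv"), row.names = FALSE,
            quote = FALSE)
  invisible(mpath)
}
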