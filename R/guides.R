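# Recognition-site (guide) design. Each junction's 80-nt search space (40 nt
# from the end of each adjoining fragment) is scanned for a 24-bp recognition
# sequence satisfying the digestion filters (GC, G-quadruplex, homopolymer
# runs, off-target k-mer uniqueness) and the ligation criteria against all
# previously finalized sticky ends. The two 16-nt guides program strand cuts
# at window positions 6 (top) and 18 (bottom), leaving the central 12-mer as
# a 5' overhang.

#' Digestion filter criteria
#'
#' @param gc_min,gc_max inclusive GC bounds on the 24-bp window.
#' @param max_at_run longest tolerated homopolymer run of A (and,
#'   separately, of T); runs strictly longer fail.
#' @param gquad_min_run,gquad_loop_min,gquad_loop_max G-quadruplex motif
#'   parameters: four runs of >= `gquad_min_run` G separated by loops of
#'   `gquad_loop_min`-`gquad_loop_max` nt, on either strand.
#' @param offtarget_k k-mer size for the off-target uniqueness scan.
#' @param wt_preference_gc,mutant_preference_gc,mutant_only_fragment_gc
#'   GC cutoffs for the enzyme-mode suggestion (see
#'   [suggest_enzyme_mode()]).
#' @return Object of class `digestion_criteria`.
#' @export
digestion_criteria <- function(gc_min = 0.0, gc_max = 0.75, max_at_run = 4L,
                               gquad_min_run = 3L, gquad_loop_min = 1L,
                               gquad_loop_max = 7L, offtarget_k = 12L,
                               wt_preference_gc = 0.10,
                               mutant_preference_gc = 0.50,
                               mutant_only_fragment_gc = 0.65) {
  if (!(gc_min >= 0 && gc_min < gc_max && gc_max <= 1))
    stop("need 0 <= gc_min < gc_max <= 1", call. = FALSE)
  structure(list(gc_min = gc_min, gc_max = gc_max,
                 max_at_run = as.integer(max_at_run),
                 gquad_min_run = as.integer(gquad_min_run),
                 gquad_loop_min = as.integer(gquad_loop_min),
                 gquad_loop_max = as.integer(gquad_loop_max),
                 offtarget_k = as.integer(offtarget_k),
                 wt_preference_gc = wt_preference_gc,
                 mutant_preference_gc = mutant_preference_gc,
                 mutant_only_fragment_gc = mutant_only_fragment_gc),
            class = "digestion_criteria")
}

#' Build [digestion_criteria()] from a pipeline configuration
#'
#' @param config nested config list from [load_config()].
#' @return A `digestion_criteria`.
#' @export
criteria_from_config <- function(config = default_config()) {
  d <- config$digestion; e <- config$enzyme_mode
  digestion_criteria(gc_min = d$gc_min, gc_max = d$gc_max,
                     max_at_run = d$max_at_run,
                     gquad_min_run = d$gquad_min_run,
                     gquad_loop_min = d$gquad_loop_min,
                     gquad_loop_max = d$gquad_loop_max,
                     offtarget_k = d$offtarget_k,
                     wt_preference_gc = e$wt_preference_gc,
                     mutant_preference_gc = e$mutant_preference_gc,
                     mutant_only_fragment_gc = e$mutant_only_fragment_gc)
}

#' Build the guide search space of a junction
#'
#' Concatenates the last 40 nt of the upstream fragment with the first 40 nt
#' of the downstream fragment (handled circularly for the wrap-around
#' junction).
#'
#' @param design a `plasmid_design`.
#' @param junction_index 0-based junction index.
#' @return The 80-nt search-space string.
#' @export
build_search_space <- function(design, junction_index) {
  j <- design$junctions[[junction_index + 1L]]
  if (is.null(j)) stop("no junction ", junction_index, call. = FALSE)
  j$search_space
}

#' Enumerate candidate recognition windows
#'
#' All 24-nt sliding windows (stride 1) of a search space; an 80-nt search
#' space yields 57 candidates.
#'
#' @param search_space DNA string, length >= 24 (80 in the standard flow).
#' @return data.frame with columns `offset` (0-based) and `window`.
#' @export
enumerate_candidates <- function(search_space) {
  search_space <- as_dna(search_space, "search space")
  L <- nchar(search_space)
  if (L < WINDOW_LEN)
    stop("search space shorter than ", WINDOW_LEN, " nt", call. = FALSE)
  offs <- 0:(L - WINDOW_LEN)
  data.frame(offset = offs,
             window = substring(search_space, offs + 1L, offs + WINDOW_LEN),
             stringsAsFactors = FALSE)
}

gquad_regex <- function(criteria) {
  g <- criteria$gquad_min_run
  sprintf("G{%d,}([ACGT]{%d,%d}G{%d,}){3}",
          g, criteria$gquad_loop_min, criteria$gquad_loop_max, g)
}

#' Off-target k-mer library
#'
#' Indexes every k-mer (top strand) of the circular target sequence and of
#' every PCR template (the raw fragment sequences), so window filters can ask
#' how often a k-mer occurs on either strand anywhere in the design.
#'
#' @param design a `plasmid_design`.
#' @param k k-mer size (default 12, the sticky-end length).
#' @return Object of class `offtarget_library`.
#' @export
offtarget_library <- function(design, k = 12L) {
  target <- design$target_sequence
  doubled <- paste0(target, substr(target, 1L, k - 1L))
  counts <- table(c(kmers_of(doubled, k),
                    unlist(lapply(design$fragments,
                                  function(f) kmers_of(f$sequence, k)))))
  structure(list(k = as.integer(k),
                 counts = counts,
                 intervals = fragment_intervals(design),
                 target_length = nchar(target)),
            class = "offtarget_library")
}

# Total top-strand occurrences of each query k-mer across the library.
lib_count <- function(lib, kmers) {
  v <- as.vector(lib$counts[kmers])
  v[is.na(v)] <- 0L
  v
}

# How many library sequences are expected to contain the k-mer that occupies
# circular target interval [pos, pos + k): the target itself plus every
# fragment template fully containing the interval.
expected_hits <- function(lib, pos) {
  n <- lib$target_length
  pos <- ((pos %% n) + n) %% n
  rel <- ((pos - lib$intervals$start) %% n + n) %% n
  1L + sum(rel + lib$k <= lib$intervals$length)
}

#' Apply the digestion filters to one candidate window
#'
#' Evaluates, in order: GC content within bounds; absence of a G-quadruplex
#' motif on either strand; no homopolymer run of more than `max_at_run` A's
#' or T's; and off-target uniqueness of the three cut-defining 12-mers (the
#' sticky end and each guide's cut-spanning k-mer) across both strands of
#' the indexed library, excluding the intended locus.
#'
#' @param window 24-nt candidate.
#' @param criteria a [digestion_criteria()].
#' @param offtargets an [offtarget_library()], or `NULL` to skip the
#'   off-target criterion (relaxed mode for isolated window screening).
#' @param locus_pos 0-based position of the window start in the circular
#'   target (needed when `offtargets` is given).
#' @return A `filter_report`: data.frame with columns `criterion`, `value`,
#'   `pass`, plus attribute `pass` (overall verdict).
#' @export
apply_digestion_filters <- function(window, criteria = digestion_criteria(),
                                    offtargets = NULL, locus_pos = NULL) {
  window <- as_dna(window, "window")
  if (nchar(window) != WINDOW_LEN)
    stop("window must be ", WINDOW_LEN, " nt", call. = FALSE)

  gc <- gc_content(window)
  gc_pass <- gc >= criteria$gc_min && gc <= criteria$gc_max

  rx <- gquad_regex(criteria)
  gq <- grepl(rx, window) || grepl(rx, revcomp(window))

  runs <- function(base) {
    m <- gregexpr(paste0(base, "+"), window)[[1]]
    if (m[1] == -1L) 0L else max(attr(m, "match.length"))
  }
  max_run <- max(runs("A"), runs("T"))
  run_pass <- max_run <= criteria$max_at_run

  if (!is.null(offtargets)) {
    k <- offtargets$k
    stopifnot(!is.null(locus_pos))
    # cut-defining k-mers: left guide's cut-spanning, sticky end, right
    # guide's cut-spanning (for default geometry: window[0,12), [6,18),
    # [12,24))
    starts <- c(0L, (WINDOW_LEN - k) %/% 2L, WINDOW_LEN - k)
    starts <- unique(pmax(0L, pmin(starts, WINDOW_LEN - k)))
    km <- substring(window, starts + 1L, starts + k)
    obs <- lib_count(offtargets, km) + lib_count(offtargets, revcomp(km))
    exp <- vapply(starts, function(s) expected_hits(offtargets,
                                                    locus_pos + s),
                  integer(1))
    ot_pass <- all(obs == exp)
    ot_value <- max(obs - exp)
  } else {
    ot_pass <- TRUE
    ot_value <- NA_real_
  }

  rep <- data.frame(
    criterion = c("gc_content", "g_quadruplex", "homopolymer_run",
                  "off_target"),
    value = c(gc, as.numeric(gq), max_run, ot_value),
    pass = c(gc_pass, !gq, run_pass, ot_pass),
    stringsAsFactors = FALSE)
  attr(rep, "pass") <- all(rep$pass)
  class(rep) <- c("filter_report", "data.frame")
  rep
}

#' Suggest which PfAgo enzymes to use
#'
#' Mutant-only (PfAgo*) is suggested when any fragment's GC reaches
#' `mutant_only_fragment_gc`; otherwise the WT + mutant one-pot mix is
#' suggested. The per-junction window preference (WT-preferred at low window
#' GC, mutant-preferred at high) is attached as the `preference` attribute.
#'
#' @param fragment_gcs GC fractions of all fragments.
#' @param window_gc GC fraction of the junction's recognition window.
#' @param criteria a [digestion_criteria()].
#' @return `"wt_and_mutant"` or `"mutant_only"`, with attribute
#'   `preference` in `{"wt", "mutant", "neutral"}`.
#' @export
suggest_enzyme_mode <- function(fragment_gcs, window_gc,
                                criteria = digestion_criteria()) {
  stopifnot(all(fragment_gcs >= 0 & fragment_gcs <= 1),
            window_gc >= 0, window_gc <= 1)
  mode <- if (max(fragment_gcs) >= criteria$mutant_only_fragment_gc)
    "mutant_only" else "wt_and_mutant"
  pref <- if (window_gc <= criteria$wt_preference_gc) "wt"
          else if (window_gc >= criteria$mutant_preference_gc) "mutant"
          else "neutral"
  structure(mode, preference = pref)
}

#' Cut geometry for guide derivation
#'
#' @param top_cut,bottom_cut 0-based positions of the top- and bottom-strand
#'   cuts within the 24-bp window (cut falls before that index on the top
#'   strand coordinate).
#' @param guide_length guide DNA length (16).
#' @param guide_cut_index guide position after which the scissile bond falls
#'   (PfAgo cleaves between guide positions 10 and 11).
#' @return Object of class `cut_geometry`.
#' @export
cut_geometry <- function(top_cut = 6L, bottom_cut = 18L, guide_length = 16L,
                         guide_cut_index = 10L) {
  structure(list(top_cut = as.integer(top_cut),
                 bottom_cut = as.integer(bottom_cut),
                 guide_length = as.integer(guide_length),
                 guide_cut_index = as.integer(guide_cut_index)),
            class = "cut_geometry")
}

#' Derive the guide pair and sticky end of a recognition window
#'
#' With the default geometry the top strand is cut after window position 5
#' and the bottom strand after position 17 (0-based), so the central 12-mer
#' `window[6..18)` becomes the 5' overhang. The top-strand guide is the
#' reverse complement of the window bases it anneals to, positioned so the
#' scissile bond faces guide position `guide_cut_index`; the bottom-strand
#' guide reads the top strand directly.
#'
#' @param window 24-nt recognition sequence.
#' @param geometry a [cut_geometry()].
#' @return list with `guide_top`, `guide_bottom` (16 nt each) and
#'   `sticky_end` (12 nt).
#' @export
derive_guides <- function(window, geometry = cut_geometry()) {
  window <- as_dna(window, "window")
  if (nchar(window) != WINDOW_LEN)
    stop("window must be ", WINDOW_LEN, " nt", call. = FALSE)
  g <- geometry
  top_start <- g$top_cut - (g$guide_length - g$guide_cut_index)
  bot_start <- g$bottom_cut - g$guide_cut_index
  if (top_start < 0L || bot_start < 0L ||
      top_start + g$guide_length > WINDOW_LEN ||
      bot_start + g$guide_length > WINDOW_LEN)
    stop("cut geometry places a guide outside the recognition window",
         call. = FALSE)
  list(
    guide_top = revcomp(substr(window, top_start + 1L,
                               top_start + g$guide_length)),
    guide_bottom = substr(window, bot_start + 1L,
                          bot_start + g$guide_length),
    sticky_end = substr(window, g$top_cut + 1L, g$bottom_cut))
}

new_recognition_site <- function(junction_index, window_offset, window,
                                 guides, enzyme_mode, filter_report) {
  structure(
    list(junction_index = as.integer(junction_index),
         window_offset = as.integer(window_offset),
         sequence24 = window,
         guide_top = guides$guide_top,
         guide_bottom = guides$guide_bottom,
         sticky_end = guides$sticky_end,
         enzyme_mode = as.character(enzyme_mode),
         enzyme_preference = attr(enzyme_mode, "preference"),
         filter_report = filter_report),
    class = "recognition_site")
}

# Center-outward scan order over window offsets 0..max_off: 28, 27, 29, 26,
# 30, ... keeps the chosen site near the fragment boundary so primer tails
# stay short.
scan_order <- function(max_off = 56L, center = 28L) {
  d <- 0:max_off
  offs <- unique(as.vector(rbind(center - d, center + d)))
  offs[offs >= 0L & offs <= max_off]
}

#' Select a recognition site for every junction
#'
#' Greedy, sequential by junction index: candidates are scanned
#' center-outward from the fragment boundary; the first window passing all
#' digestion filters and the ligation criteria against every previously
#' finalized sticky end (non-palindromic, cognate pair not reused, all
#' non-cognate duplex scores below the fidelity threshold) is kept.
#'
#' @param design a `plasmid_design`.
#' @param criteria a [digestion_criteria()].
#' @param model a [fidelity_model()].
#' @param geometry a [cut_geometry()].
#' @param offtargets an [offtarget_library()]; built from the design when
#'   `NULL`.
#' @return The design with `chosen_site` set on every junction.
#' @export
select_sites <- function(design, criteria = digestion_criteria(),
                         model = fidelity_model(),
                         geometry = cut_geometry(), offtargets = NULL) {
  if (is.null(offtargets))
    offtargets <- offtarget_library(design, k = criteria$offtarget_k)
  frag_gcs <- vapply(design$fragments,
                     function(f) gc_content(f$sequence), numeric(1))
  chosen_ends <- character(0)

  for (ji in seq_along(design$junctions)) {
    j <- design$junctions[[ji]]
    cand <- enumerate_candidates(j$search_space)
    fail_log <- list()
    site <- NULL
    for (off in scan_order(nrow(cand) - 1L)) {
      w <- cand$window[cand$offset == off]
      rep <- apply_digestion_filters(
        w, criteria, offtargets,
        locus_pos = j$search_space_origin + off)
      if (!attr(rep, "pass")) {
        fail_log[[as.character(off)]] <-
          paste(rep$criterion[!rep$pass], collapse = "+")
        next
      }
      guides <- derive_guides(w, geometry)
      ok <- ligation_admissible(guides$sticky_end, chosen_ends, model)
      if (!ok$pass) {
        fail_log[[as.character(off)]] <- ok$reason
        next
      }
      mode <- suggest_enzyme_mode(frag_gcs, gc_content(w), criteria)
      site <- new_recognition_site(j$index, off, w, guides, mode, rep)
      break
    }
    if (is.null(site)) {
      reasons <- vapply(names(fail_log), function(o)
        paste0("offset ", o, ": ", fail_log[[o]]), character(1))
      stop(structure(class = c("design_infeasible", "error", "condition"),
                     list(message = paste0(
                            "no feasible recognition window at junction ",
                            j$index, " (", j$upstream_fragment_id, " -> ",
                            j$downstream_fragment_id, "):\n  ",
                            paste(reasons, collapse = "\n  ")),
                          call = sys.call(-1),
                          junction = j$index, failures = fail_log)))
    }
    design$junctions[[ji]]$chosen_site <- site
    chosen_ends <- c(chosen_ends, site$sticky_end)
  }
  design
}

#' Export chosen guides as an oligo order table
#'
#' @param design a `plasmid_design` processed by [select_sites()].
#' @return data.frame with columns `name`, `sequence`, `scale`.
#' @export
guide_order_sheet <- function(design) {
  rows <- lapply(design$junctions, function(j) {
    s <- j$chosen_site
    if (is.null(s)) stop("junction ", j$index, " has no chosen site",
                         call. = FALSE)
    data.frame(
      name = sprintf("%s_j%02d_%s", design$name, j$index, c("gT", "gB")),
      sequence = c(s$guide_top, s$guide_bottom),
      scale = "25nm", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
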