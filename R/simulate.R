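# In-silico execution of the assembly chemistry: guide-directed digestion of
# each amplicon terminus (strand cuts at window positions 6 and 18, leaving
# the central 12-mer as a 5' overhang), then ligation of compatible sticky
# ends — strictly Watson-Crick, or thresholded on the fidelity model to
# enumerate predicted misassemblies.

#' Digest one amplicon with its designed recognition sites
#'
#' Applies the two strand cuts of the geometry at each terminus carrying a
#' recognition site. The retained duplex keeps 12-nt 5' overhangs whose
#' top-strand reading equals the site's sticky end; the trimmed terminal
#' pieces are recorded as released oligos.
#'
#' @param amplicon amplicon sequence (top strand).
#' @param left_site,right_site `recognition_site`s expected at the left and
#'   right terminus (either may be `NULL` for an undigested end).
#' @param geometry a [cut_geometry()].
#' @return Object of class `digested_fragment`: `core` (duplex region
#'   between the two bottom/top cuts), `left_overhang` (5' top-strand
#'   protrusion), `right_overhang` (5' bottom-strand protrusion, 5'->3'),
#'   `released_oligos` (single-strand pieces), `total_nt` bookkeeping.
#' @export
simulate_digestion <- function(amplicon, left_site = NULL,
                               right_site = NULL,
                               geometry = cut_geometry()) {
  amplicon <- as_dna(amplicon, "amplicon")
  n <- nchar(amplicon)
  tc <- geometry$top_cut; bc <- geometry$bottom_cut
  released <- character(0)

  left_overhang <- ""
  start_top <- 1L; start_bot <- 1L
  if (!is.null(left_site)) {
    if (substr(amplicon, 1L, WINDOW_LEN) != left_site$sequence24)
      stop("left terminus of amplicon does not carry recognition sequence ",
           "of junction ", left_site$junction_index, call. = FALSE)
    start_top <- tc + 1L
    start_bot <- bc + 1L
    left_overhang <- substr(amplicon, tc + 1L, bc)
    released <- c(released,
                  left_top = substr(amplicon, 1L, tc),       # 5' top piece
                  left_bottom = revcomp(substr(amplicon, 1L, bc)))
  }
  right_overhang <- ""
  end_top <- n; end_bot <- n
  if (!is.null(right_site)) {
    wstart <- n - WINDOW_LEN + 1L
    if (substr(amplicon, wstart, n) != right_site$sequence24)
      stop("right terminus of amplicon does not carry recognition ",
           "sequence of junction ", right_site$junction_index,
           call. = FALSE)
    end_top <- wstart - 1L + tc
    end_bot <- wstart - 1L + bc
    right_overhang <- revcomp(substr(amplicon, end_top + 1L, end_bot))
    released <- c(released,
                  right_top = substr(amplicon, end_top + 1L, n),
                  right_bottom = revcomp(substr(amplicon, end_bot + 1L, n)))
  }
  released <- released[nchar(released) > 0L]
  structure(
    list(top_strand = substr(amplicon, start_top, end_top),
         bottom_span = c(start_bot, end_bot),
         left_overhang = left_overhang,
         right_overhang = right_overhang,
         released_oligos = released,
         total_nt = (end_top - start_top + 1L) +
                    (end_bot - start_bot + 1L) +
                    sum(nchar(released))),
    class = "digested_fragment")
}

# sticky-compatibility of A's right end with B's left end
ends_join <- function(a, b, model, mode) {
  if (!nchar(a$right_overhang) || !nchar(b$left_overhang)) return(FALSE)
  if (mode == "strict_wc")
    identical(b$left_overhang, revcomp(a$right_overhang))
  else
    duplex_score(a$right_overhang, b$left_overhang, model) >=
      model$threshold
}

#' Ligate digested fragments
#'
#' `strict_wc` mode joins only perfectly complementary overhangs;
#' `threshold` mode joins any pair whose duplex score reaches the fidelity
#' threshold, exhaustively enumerating the circular products that could
#' form (at most one copy of each fragment per circle; concatemers are out
#' of scope). Fragment orientation is fixed by the 5'-overhang chemistry.
#'
#' @param fragments named list of `digested_fragment`s.
#' @param model a [fidelity_model()].
#' @param mode `"strict_wc"` or `"threshold"`.
#' @return list with `circular` (list of `assembly_product`s: `members`,
#'   `sequence`, `junction_scores`) and `linear` (maximal unjoinable
#'   partial chains, as member-id vectors).
#' @export
simulate_ligation <- function(fragments, model = fidelity_model(),
                              mode = c("strict_wc", "threshold")) {
  mode <- match.arg(mode)
  stopifnot(length(fragments) >= 1L)
  ids <- names(fragments)
  if (is.null(ids)) ids <- as.character(seq_along(fragments))
  nfrag <- length(fragments)
  adj <- matrix(FALSE, nfrag, nfrag, dimnames = list(ids, ids))
  for (i in seq_len(nfrag)) for (j in seq_len(nfrag))
    adj[i, j] <- ends_join(fragments[[i]], fragments[[j]], model, mode)

  circles <- list()
  # DFS from each anchor; only cycles whose minimum member is the anchor are
  # kept, so each circular product is enumerated once
  path <- integer(0)
  dfs <- function(anchor, v) {
    path[length(path) + 1L] <<- v
    for (w in which(adj[v, ])) {
      if (w == anchor && length(path) >= 1L) {
        circles[[length(circles) + 1L]] <<- path
      } else if (w > anchor && !(w %in% path)) {
        dfs(anchor, w)
      }
    }
    path <<- path[-length(path)]
  }
  for (a in seq_len(nfrag)) dfs(a, a)

  products <- lapply(circles, function(members) {
    # the retained top strand begins at the top cut and already carries the
    # single-stranded left overhang as its prefix, so concatenation of the
    # top strands is the ligated circle's top strand
    seqs <- vapply(members, function(i) fragments[[i]]$top_strand,
                   character(1))
    scores <- vapply(seq_along(members), function(k) {
      a <- fragments[[members[k]]]
      b <- fragments[[members[if (k == length(members)) 1L else k + 1L]]]
      duplex_score(a$right_overhang, b$left_overhang, model)
    }, numeric(1))
    structure(list(members = ids[members],
                   sequence = paste(seqs, collapse = ""),
                   junction_scores = scores,
                   circular = TRUE),
              class = "assembly_product")
  })

  in_circle <- unique(unlist(circles))
  loose <- setdiff(seq_len(nfrag), in_circle)
  linear <- lapply(loose, function(i) ids[i])
  list(circular = products, linear = linear)
}

#' End-to-end round-trip check of a finished design
#'
#' Simulates PCR of every fragment, digestion of every amplicon terminus,
#' and strict Watson-Crick ligation, then compares the canonical rotation
#' of the single circular product with that of the designed target
#' sequence. Also flags released guide-sized oligos that are complementary
#' to any overhang (potential re-ligation interference).
#'
#' @param design a `plasmid_design` processed by [select_sites()].
#' @param pairs primer pairs from [design_primers()].
#' @param model a [fidelity_model()].
#' @param geometry a [cut_geometry()].
#' @return list with `pass`, `n_products`, `product` (canonical sequence),
#'   `target` (canonical target), `diff` (first differing position, or
#'   `NA`), `oligo_religation_risk`.
#' @export
round_trip_check <- function(design, pairs, model = fidelity_model(),
                             geometry = cut_geometry()) {
  nfrag <- length(design$fragments)
  digested <- vector("list", nfrag)
  names(digested) <- vapply(design$fragments, `[[`, character(1), "id")
  released <- data.frame(oligo = character(0), junction = integer(0))
  for (i in seq_len(nfrag)) {
    frag <- design$fragments[[i]]
    left <- design$junctions[[if (i == 1L) nfrag else i - 1L]]$chosen_site
    right <- design$junctions[[i]]$chosen_site
    d <- tryCatch({
      amplicon <- simulate_pcr(frag$sequence, pairs[[i]])
      simulate_digestion(amplicon, left, right, geometry)
    }, error = function(e) e)
    if (inherits(d, "error"))
      # a corrupted amplicon terminus (or non-annealing primer) fails the
      # round trip rather than aborting it
      return(list(pass = FALSE, n_products = 0L,
                  product = NA_character_,
                  target = rotate_to_canonical(design$target_sequence),
                  diff = NA_integer_, oligo_religation_risk = NA,
                  failure = conditionMessage(d)))
    digested[[i]] <- d
    ro <- d$released_oligos
    if (length(ro))
      released <- rbind(released, data.frame(
        oligo = unname(ro),
        junction = ifelse(grepl("^left", names(ro)),
                          left$junction_index, right$junction_index)))
  }
  lig <- simulate_ligation(digested, model, mode = "strict_wc")
  # cross-talk flag: a released single-strand piece from one junction's cut
  # that carries another junction's overhang (either strand) could bridge
  # ends it was never designed for
  sticky <- vapply(design$junctions,
                   function(j) j$chosen_site$sticky_end, character(1))
  risk <- any(vapply(seq_len(nrow(released)), function(r) {
    others <- sticky[seq_along(sticky) != released$junction[r] + 1L]
    any(vapply(others, function(s)
      grepl(s, released$oligo[r], fixed = TRUE) ||
        grepl(revcomp(s), released$oligo[r], fixed = TRUE),
      logical(1)))
  }, logical(1)))

  if (length(lig$circular) != 1L)
    return(list(pass = FALSE, n_products = length(lig$circular),
                product = NA_character_,
                target = rotate_to_canonical(design$target_sequence),
                diff = NA_integer_, oligo_religation_risk = risk))
  product <- rotate_to_canonical(lig$circular[[1]]$sequence)
  target <- rotate_to_canonical(design$target_sequence)
  diff_at <- NA_integer_
  if (!identical(product, target)) {
    pc <- strsplit(product, "")[[1]]
    tc <- strsplit(target, "")[[1]]
    m <- min(length(pc), length(tc))
    neq <- which(pc[seq_len(m)] != tc[seq_len(m)])
    diff_at <- if (length(neq)) neq[1] else m + 1L
  }
  list(pass = identical(product, target), n_products = 1L,
       product = product, target = target, diff = diff_at,
       oligo_religation_risk = risk)
}
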