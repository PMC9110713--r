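# Primer design. Each fragment is amplified with tailed primers: the 3'
# binding region anneals at the fragment terminus on its template; the 5'
# tail installs whatever part of the junction's 24-bp recognition sequence
# falls outside the raw fragment, so adjacent amplicons share exactly that
# 24-mer. Binding regions start at 18 nt and are resized by GC/Tm rules,
# then the forward/reverse pair is balanced to within 1 degC.

#' Size a primer binding region
#'
#' Starts from the terminal 18 bp of the annealing strand. If that seed's
#' GC is below `gc_low` the region is extended 3'-ward one base at a time
#' (up to `binding_max`) until the melting temperature reaches the floor;
#' if above `gc_high` it may shrink (down to `binding_min`) while the Tm
#' stays at or above the floor.
#'
#' @param strand annealing-strand sequence, 5'->3', starting at the primer's
#'   5' end (for a reverse primer pass the reverse complement of the
#'   template tail).
#' @param config pipeline configuration (`primers` section is used).
#' @param params a [tm_parameters()]; built from the config when `NULL`.
#' @return list with `binding` (the chosen region), `tm`, and `warning`
#'   (`NA` or a message when the Tm floor is unreachable).
#' @export
size_binding_site <- function(strand, config = default_config(),
                              params = NULL) {
  p <- config$primers
  if (is.null(params)) params <- do.call(tm_parameters, unname_tm(p$tm))
  strand <- as_dna(strand, "annealing strand")
  if (nchar(strand) < p$start_length)
    stop("annealing strand shorter than the ", p$start_length,
         " bp seed region", call. = FALSE)
  len <- p$start_length
  seed <- substr(strand, 1L, len)
  gc <- gc_content(seed)
  tm_at <- function(l) compute_tm(substr(strand, 1L, l), params)
  warning_msg <- NA_character_
  if (gc < p$gc_low) {
    while (len < min(p$binding_max, nchar(strand)) && tm_at(len) < p$tm_floor)
      len <- len + 1L
    if (tm_at(len) < p$tm_floor)
      warning_msg <- sprintf(
        "Tm %.1f below floor %.1f at maximum binding length %d",
        tm_at(len), p$tm_floor, len)
  } else if (gc > p$gc_high) {
    while (len > p$binding_min && tm_at(len - 1L) >= p$tm_floor)
      len <- len - 1L
  }
  list(binding = substr(strand, 1L, len), tm = tm_at(len),
       warning = warning_msg)
}

unname_tm <- function(tm) tm[c("monovalent_mM", "divalent_mM", "dntp_mM",
                               "primer_nM")]

#' Balance forward/reverse primer melting temperatures
#'
#' Searches all binding-length combinations within the configured bounds
#' (only lengths available on each strand) for the pair minimizing
#' `|Tm_fwd - Tm_rev|`; ties break toward lengths closest to the current
#' pair, then toward the higher minimum Tm. Errors if no combination
#' achieves a difference of at most 1 degC.
#'
#' @param pair a `primer_pair` (from [design_primers()] internals) holding
#'   `fwd_strand`/`rev_strand` annealing strands and current binding
#'   lengths.
#' @param config pipeline configuration.
#' @param params a [tm_parameters()]; from config when `NULL`.
#' @return The pair with balanced `fwd_binding`/`rev_binding` and
#'   `fwd_tm`/`rev_tm` set; `|fwd_tm - rev_tm| <= 1`.
#' @export
balance_tm <- function(pair, config = default_config(), params = NULL) {
  p <- config$primers
  if (is.null(params)) params <- do.call(tm_parameters, unname_tm(p$tm))
  lens_f <- p$binding_min:min(p$binding_max, nchar(pair$fwd_strand))
  lens_r <- p$binding_min:min(p$binding_max, nchar(pair$rev_strand))
  tms_f <- vapply(lens_f, function(l)
    compute_tm(substr(pair$fwd_strand, 1L, l), params), numeric(1))
  tms_r <- vapply(lens_r, function(l)
    compute_tm(substr(pair$rev_strand, 1L, l), params), numeric(1))
  grid <- expand.grid(fi = seq_along(lens_f), ri = seq_along(lens_r))
  dtm <- abs(tms_f[grid$fi] - tms_r[grid$ri])
  cur_f <- nchar(pair$fwd_binding); cur_r <- nchar(pair$rev_binding)
  move <- abs(lens_f[grid$fi] - cur_f) + abs(lens_r[grid$ri] - cur_r)
  min_tm <- pmin(tms_f[grid$fi], tms_r[grid$ri])
  ord <- order(round(dtm, 10), move, -round(min_tm, 10))
  best <- grid[ord[1L], ]
  best_dtm <- dtm[ord[1L]]
  if (best_dtm > 1.0)
    stop("cannot balance primer Tm for fragment '", pair$fragment_id,
         "': best |dTm| = ", round(best_dtm, 2), " degC", call. = FALSE)
  pair$fwd_binding <- substr(pair$fwd_strand, 1L, lens_f[best$fi])
  pair$rev_binding <- substr(pair$rev_strand, 1L, lens_r[best$ri])
  pair$fwd_tm <- tms_f[best$fi]
  pair$rev_tm <- tms_r[best$ri]
  pair
}

#' Attach junction overhangs to a primer pair
#'
#' Adds the 5' tails so the fragment's amplicon carries the full 24-bp
#' recognition sequence of each flanking junction; adjacent amplicons then
#' share exactly that 24-mer. The tail length is 24 minus however much of
#' the recognition window already lies inside the raw fragment.
#'
#' @param pair a `primer_pair`.
#' @param upstream_site,downstream_site `recognition_site`s of the
#'   junctions at the fragment's 5' and 3' ends.
#' @param design the `plasmid_design` (for coordinates).
#' @param config pipeline configuration.
#' @return The pair with `fwd_overhang`/`rev_overhang` set and a
#'   `warning` field when a tail exceeds the practical synthesis length.
#' @export
attach_overhangs <- function(pair, upstream_site, downstream_site, design,
                             config = default_config()) {
  n <- nchar(design$target_sequence)
  iv <- fragment_intervals(design)
  row <- iv[iv$id == pair$fragment_id, ]
  jup <- design$junctions[[upstream_site$junction_index + 1L]]
  jdn <- design$junctions[[downstream_site$junction_index + 1L]]
  w_up <- (jup$search_space_origin + upstream_site$window_offset) %% n
  w_dn <- (jdn$search_space_origin + downstream_site$window_offset) %% n
  # tail length = amplicon bases upstream of the fragment start (from the
  # recognition-window start); at most SEARCH_FLANK by construction, and a
  # huge modular value signals the window starting inside the fragment
  fwd_oh_len <- (row$start - w_up) %% n
  if (fwd_oh_len > SEARCH_FLANK) fwd_oh_len <- 0L
  rev_oh_len <- (w_dn + WINDOW_LEN - row$end) %% n
  if (rev_oh_len > SEARCH_FLANK) rev_oh_len <- 0L
  pair$fwd_overhang <- if (fwd_oh_len > 0L)
    circ_sub(design$target_sequence, w_up, fwd_oh_len) else ""
  pair$rev_overhang <- if (rev_oh_len > 0L)
    revcomp(circ_sub(design$target_sequence, row$end, rev_oh_len)) else ""
  too_long <- max(fwd_oh_len, rev_oh_len) > config$primers$max_overhang
  if (too_long)
    pair$warning <- c(pair$warning, sprintf(
      "overhang of %d nt exceeds practical synthesis length %d",
      max(fwd_oh_len, rev_oh_len), config$primers$max_overhang))
  pair
}

#' Design PCR primers for every fragment of a design
#'
#' For each fragment: locates the amplicon implied by its two flanking
#' recognition sites, sizes both binding regions ([size_binding_site()]),
#' balances the pair to within 1 degC ([balance_tm()]), and attaches the
#' junction tails ([attach_overhangs()]).
#'
#' @param design a `plasmid_design` processed by [select_sites()].
#' @param config pipeline configuration.
#' @return list of `primer_pair` objects (fields `fragment_id`,
#'   `fwd_binding`, `rev_binding`, `fwd_overhang`, `rev_overhang`,
#'   `fwd_tm`, `rev_tm`, `warning`), one per fragment, in assembly order.
#' @export
design_primers <- function(design, config = default_config()) {
  p <- config$primers
  params <- do.call(tm_parameters, unname_tm(p$tm))
  n <- nchar(design$target_sequence)
  iv <- fragment_intervals(design)
  nfrag <- length(design$fragments)
  lapply(seq_len(nfrag), function(i) {
    frag <- design$fragments[[i]]
    up_j <- design$junctions[[if (i == 1L) nfrag else i - 1L]]
    dn_j <- design$junctions[[i]]
    if (is.null(up_j$chosen_site) || is.null(dn_j$chosen_site))
      stop("design has junctions without chosen sites; run select_sites()",
           call. = FALSE)
    w_up <- (up_j$search_space_origin +
             up_j$chosen_site$window_offset) %% n
    w_dn <- (dn_j$search_space_origin +
             dn_j$chosen_site$window_offset) %% n
    # binding regions anneal on the template where the amplicon enters the
    # raw fragment: offset > 0 when the recognition window starts inside it
    fwd_off <- (w_up - iv$start[i]) %% n
    if (fwd_off > WINDOW_LEN) fwd_off <- 0L
    rev_off <- (iv$end[i] - (w_dn + WINDOW_LEN)) %% n
    if (rev_off > WINDOW_LEN) rev_off <- 0L
    fwd_strand <- substr(frag$sequence, fwd_off + 1L, nchar(frag$sequence))
    rev_strand <- revcomp(substr(frag$sequence, 1L,
                                 nchar(frag$sequence) - rev_off))
    fsz <- size_binding_site(fwd_strand, config, params)
    rsz <- size_binding_site(rev_strand, config, params)
    pair <- structure(
      list(fragment_id = frag$id,
           fwd_strand = fwd_strand, rev_strand = rev_strand,
           fwd_binding = fsz$binding, rev_binding = rsz$binding,
           fwd_overhang = "", rev_overhang = "",
           fwd_tm = fsz$tm, rev_tm = rsz$tm,
           warning = stats::na.omit(c(fsz$warning, rsz$warning))),
      class = "primer_pair")
    pair <- balance_tm(pair, config, params)
    attach_overhangs(pair, up_j$chosen_site, dn_j$chosen_site, design,
                     config)
  })
}

#' Full primer sequences of a pair
#'
#' @param pair a `primer_pair`.
#' @return character vector `c(fwd, rev)`: overhang + binding region.
#' @export
full_primers <- function(pair) {
  c(fwd = paste0(pair$fwd_overhang, pair$fwd_binding),
    rev = paste0(pair$rev_overhang, pair$rev_binding))
}

#' Simulate PCR of one fragment
#'
#' Exact string extraction: the product is the forward tail, the template
#' span from the forward binding site through the reverse binding site, and
#' the reverse-complemented reverse tail. The binding regions must match
#' the template exactly at the fragment termini.
#'
#' @param template template sequence (the raw fragment).
#' @param pair a `primer_pair` designed for it.
#' @return Amplicon sequence.
#' @export
simulate_pcr <- function(template, pair) {
  template <- as_dna(template, "template")
  fwd_at <- regexpr(pair$fwd_binding, template, fixed = TRUE)[1]
  rev_site <- revcomp(pair$rev_binding)
  rev_at <- tail_match(template, rev_site)
  if (fwd_at == -1L || rev_at == -1L)
    stop("primer binding region does not anneal on template for fragment '",
         pair$fragment_id, "'", call. = FALSE)
  core <- substr(template, fwd_at, rev_at + nchar(rev_site) - 1L)
  paste0(pair$fwd_overhang, core, revcomp(pair$rev_overhang))
}

# last occurrence (1-based start) of pattern in x, -1 if absent
tail_match <- function(x, pattern) {
  m <- gregexpr(pattern, x, fixed = TRUE)[[1]]
  if (m[1] == -1L) -1L else m[length(m)]
}

#' Two-round extended-primer plan for a small fragment
#'
#' Fragments shorter than 80 bp (linkers, short promoters) are not amplified
#' on their own: the linker is absorbed into its downstream neighbor's
#' forward-primer tails over two PCR rounds. Round 1 installs the
#' linker-proximal half of the insert; round 2 uses the round-1 product as
#' template and completes it. The design is rebuilt with the merged
#' fragment, dropping the linker's own junction.
#'
#' @param design a `plasmid_design` containing the linker.
#' @param linker_id id of the fragment to absorb (must be < 80 bp).
#' @param config pipeline configuration.
#' @return list with `design` (merged design), `rounds` (two-round tail
#'   plan: per round, the added tail and its template), and `merged_id`.
#' @export
design_small_fragment <- function(design, linker_id,
                                  config = default_config()) {
  idx <- which(vapply(design$fragments, `[[`, character(1), "id") ==
               linker_id)
  if (!length(idx)) stop("no fragment '", linker_id, "'", call. = FALSE)
  linker <- design$fragments[[idx]]
  lin_len <- nchar(linker$sequence)
  if (lin_len >= config$primers$small_fragment_max)
    stop("fragment '", linker_id, "' is ", lin_len,
         " bp; the small-fragment workflow requires < ",
         config$primers$small_fragment_max,
         " bp - use the standard path", call. = FALSE)
  nfrag <- length(design$fragments)
  if (nfrag < 2L)
    stop("cannot absorb the only fragment of a design", call. = FALSE)
  down_idx <- if (idx == nfrag) 1L else idx + 1L
  neighbor <- design$fragments[[down_idx]]

  half <- ceiling(lin_len / 2L)
  round1_tail <- substr(linker$sequence, half + 1L, lin_len)
  round2_tail <- substr(linker$sequence, 1L, half)
  rounds <- list(
    list(round = 1L, tail = round1_tail, template = neighbor$id,
         product = paste0(round1_tail, neighbor$sequence)),
    list(round = 2L, tail = round2_tail,
         template = paste0(neighbor$id, "_r1"),
         product = paste0(linker$sequence, neighbor$sequence)))

  merged_id <- paste0(linker$id, "_", neighbor$id)
  keep <- setdiff(seq_len(nfrag), c(idx, down_idx))
  frags <- design$fragments[keep]
  frags <- c(frags, list(fragment(
    merged_id, paste0(linker$sequence, neighbor$sequence),
    role = neighbor$role, order_index = 0L,
    template_id = neighbor$template_id)))
  # renumber in original assembly order, with the merged fragment at the
  # linker's position
  ord <- vapply(design$fragments, `[[`, character(1), "id")
  ord <- ord[-down_idx]
  ord[ord == linker$id] <- merged_id
  for (i in seq_along(frags))
    frags[[i]]$order_index <- match(frags[[i]]$id, ord) - 1L
  list(design = plasmid_design(design$name, frags),
       rounds = rounds, merged_id = merged_id)
}

#' Export designed primers as an oligo order table
#'
#' @param design a `plasmid_design`.
#' @param pairs list of `primer_pair`s from [design_primers()].
#' @return data.frame with columns `name`, `sequence`, `binding_length`,
#'   `tm`, `overhang_length`.
#' @export
primer_order_sheet <- function(design, pairs) {
  rows <- lapply(pairs, function(p) {
    fp <- full_primers(p)
    data.frame(
      name = sprintf("%s_%s_%s", design$name, p$fragment_id, c("F", "R")),
      sequence = unname(fp),
      binding_length = c(nchar(p$fwd_binding), nchar(p$rev_binding)),
      tm = round(c(p$fwd_tm, p$rev_tm), 2),
      overhang_length = c(nchar(p$fwd_overhang), nchar(p$rev_overhang)),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
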