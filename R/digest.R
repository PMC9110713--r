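# Verification-digest planning: in-silico restriction digestion of the
# assembled circular plasmid, selection of enzyme combinations whose band
# patterns separate cleanly on a capillary electrophoresis instrument, and
# matching of predicted to observed band sizes.

#' Load a restriction-enzyme table
#'
#' @param path TSV with columns `name`, `site` (IUPAC recognition
#'   sequence), `cut_top`, `cut_bottom` (cut offsets from the site start on
#'   the top/bottom strands); `NULL` loads the packaged table of ~35 common
#'   6/8-cutters.
#' @return data.frame of enzymes.
#' @export
enzyme_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "restriction_enzymes.tsv",
                        package = "agodesign", mustWork = TRUE)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "site", "cut_top", "cut_bottom")
  if (!all(need %in% names(tab)))
    stop("enzyme table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(tab$name))
    stop("duplicate enzyme names in table", call. = FALSE)
  bad <- grepl(sprintf("[^%s]", paste(names(Biostrings::IUPAC_CODE_MAP),
                                      collapse = "")), tab$site)
  if (any(bad))
    stop("invalid IUPAC recognition sequence for ",
         paste(tab$name[bad], collapse = ", "), call. = FALSE)
  tab
}

# Top-strand cut coordinates (0-based) of one enzyme on a circular sequence,
# both orientations, IUPAC-expanded.
cut_positions <- function(circular_seq, enzyme_row) {
  n <- nchar(circular_seq)
  site <- enzyme_row$site
  slen <- nchar(site)
  doubled <- Biostrings::DNAString(
    paste0(circular_seq, substr(circular_seq, 1L, slen - 1L)))
  hits <- function(pat)
    Biostrings::start(Biostrings::matchPattern(pat, doubled, fixed = FALSE))
  fwd <- hits(site)
  fwd <- fwd[fwd <= n] - 1L
  cuts <- (fwd + enzyme_row$cut_top) %% n
  rc <- revcomp(site)
  rev <- hits(rc)
  rev <- rev[rev <= n] - 1L
  # on a bottom-strand site the top-strand cut sits cut_bottom from the
  # site's right edge
  cuts <- c(cuts, (rev + slen - enzyme_row$cut_bottom) %% n)
  sort(unique(as.integer(cuts)))
}

#' In-silico digest of a circular sequence
#'
#' Locates every recognition site of the given enzymes on both strands
#' (IUPAC codes expanded) and returns the inter-cut distances around the
#' circle.
#'
#' @param circular_seq plasmid sequence (circular).
#' @param enzymes character vector of 1+ enzyme names.
#' @param table an [enzyme_table()].
#' @return Sorted integer vector of band sizes (bp); a single cut gives one
#'   full-length band; no cut gives `integer(0)` with attribute
#'   `no_cut = TRUE`.
#' @export
digest <- function(circular_seq, enzymes, table = enzyme_table()) {
  circular_seq <- as_dna(circular_seq, "plasmid sequence")
  unknown <- setdiff(enzymes, table$name)
  if (length(unknown))
    stop("unknown enzyme(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cuts <- sort(unique(unlist(lapply(enzymes, function(e)
    cut_positions(circular_seq, table[table$name == e, ])))))
  n <- nchar(circular_seq)
  if (!length(cuts))
    return(structure(integer(0), no_cut = TRUE))
  if (length(cuts) == 1L) return(n)
  sizes <- diff(c(cuts, cuts[1] + n))
  stopifnot(sum(sizes) == n)  # conservation: bands tile the circle
  sort(as.integer(sizes))
}

#' Separation criteria for verification digests
#'
#' @param min_band smallest acceptable band (default 100 bp).
#' @param max_band largest acceptable band (default 9500 bp).
#' @param accuracy_A sizing accuracy of the electrophoresis instrument
#'   (default 0.1): adjacent bands closer than `A x band size` are
#'   indistinguishable.
#' @param gap_reference which band of an adjacent pair anchors the gap
#'   criterion: `"larger"` (conservative default) or `"smaller"`.
#' @return Object of class `separation_criteria`.
#' @export
separation_criteria <- function(min_band = 100L, max_band = 9500L,
                                accuracy_A = 0.1,
                                gap_reference = c("larger", "smaller")) {
  gap_reference <- match.arg(gap_reference)
  stopifnot(min_band > 0, min_band < max_band,
            accuracy_A > 0, accuracy_A < 1)
  structure(list(min_band = as.integer(min_band),
                 max_band = as.integer(max_band),
                 accuracy_A = accuracy_A, gap_reference = gap_reference),
            class = "separation_criteria")
}

assess_bands <- function(bands, criteria) {
  if (!length(bands)) return("no_cut")
  if (min(bands) < criteria$min_band) return("too_small")
  if (max(bands) > criteria$max_band) return("too_large")
  if (length(bands) > 1L) {
    b <- sort(bands)
    ref <- if (criteria$gap_reference == "larger") b[-1L]
           else b[-length(b)]
    if (any(diff(b) < criteria$accuracy_A * ref)) return("too_close")
  }
  NA_character_
}

#' Select verification-digest enzyme combinations
#'
#' Evaluates every single and pairwise digest of the plasmid, discards
#' combinations whose predicted bands violate the separation criteria, and
#' ranks accepted plans by band count (more informative first), ties broken
#' by the larger minimum adjacent-gap ratio.
#'
#' @param circular_seq plasmid sequence.
#' @param table an [enzyme_table()].
#' @param criteria a [separation_criteria()].
#' @param max_enzymes 1 or 2 enzymes per combination (default 2).
#' @return list of `digest_plan` objects (fields `enzymes`,
#'   `predicted_bands`, `accepted`, `rejection_reason`), accepted plans
#'   first in rank order, rejected plans after.
#' @export
select_combinations <- function(circular_seq, table = enzyme_table(),
                                criteria = separation_criteria(),
                                max_enzymes = 2L) {
  stopifnot(nrow(table) >= 1L)
  combos <- as.list(table$name)
  if (max_enzymes >= 2L && nrow(table) >= 2L)
    combos <- c(combos,
                combn(table$name, 2L, simplify = FALSE))
  plans <- lapply(combos, function(enzymes) {
    bands <- digest(circular_seq, enzymes, table)
    reason <- assess_bands(bands, criteria)
    min_gap_ratio <- if (length(bands) > 1L) {
      b <- sort(bands)
      ref <- if (criteria$gap_reference == "larger") b[-1L]
             else b[-length(b)]
      min(diff(b) / ref)
    } else Inf
    structure(list(enzymes = enzymes,
                   predicted_bands = as.integer(bands),
                   accepted = is.na(reason),
                   rejection_reason = reason,
                   min_gap_ratio = min_gap_ratio),
              class = "digest_plan")
  })
  acc <- vapply(plans, `[[`, logical(1), "accepted")
  nb <- vapply(plans, function(p) length(p$predicted_bands), integer(1))
  gap <- vapply(plans, `[[`, numeric(1), "min_gap_ratio")
  ord <- order(!acc, -nb, -gap)
  plans[ord]
}

#' Enzymes accepted across a whole plasmid batch
#'
#' Intersects the accepted enzyme combinations of every plasmid so one
#' digest protocol can verify the full batch.
#'
#' @param plasmids named list of circular sequences.
#' @param table an [enzyme_table()].
#' @param criteria a [separation_criteria()].
#' @param max_enzymes combination arity cap.
#' @return list with `common` (character vector of combination labels
#'   accepted for every plasmid, `"EcoRI"` or `"EcoRI+NdeI"`) and
#'   `per_plasmid` (each plasmid's accepted plans, as fallbacks).
#' @export
common_enzymes <- function(plasmids, table = enzyme_table(),
                           criteria = separation_criteria(),
                           max_enzymes = 2L) {
  stopifnot(length(plasmids) >= 1L)
  per <- lapply(plasmids, function(s)
    Filter(function(p) p$accepted,
           select_combinations(s, table, criteria, max_enzymes)))
  labels <- lapply(per, function(plans)
    vapply(plans, function(p) paste(sort(p$enzymes), collapse = "+"),
           character(1)))
  common <- Reduce(intersect, labels)
  list(common = common, per_plasmid = per)
}

#' Match predicted to observed band sizes
#'
#' Greedy one-to-one pairing in sorted order; a pairing matches when
#' `|observed - predicted| <= tolerance x predicted`. The verdict passes
#' iff every predicted band is matched and no unexplained observed band
#' remains above the noise floor.
#'
#' @param predicted,observed band sizes in bp.
#' @param tolerance relative sizing tolerance (default 0.1, the instrument
#'   accuracy).
#' @param noise_floor observed bands at or below this size are ignored
#'   (default 50 bp).
#' @return list with `pass`, `pairs` (data.frame predicted/observed),
#'   `unmatched_predicted`, `unexplained_observed`.
#' @export
match_bands <- function(predicted, observed, tolerance = 0.1,
                        noise_floor = 50) {
  stopifnot(tolerance > 0, tolerance < 1)
  pred <- sort(predicted)
  obs <- sort(observed[observed > noise_floor])
  pairs <- data.frame(predicted = numeric(0), observed = numeric(0))
  un_p <- numeric(0)
  for (p in pred) {
    ok <- which(abs(obs - p) <= tolerance * p)
    if (length(ok)) {
      pairs <- rbind(pairs, data.frame(predicted = p, observed = obs[ok[1]]))
      obs <- obs[-ok[1]]
    } else un_p <- c(un_p, p)
  }
  list(pass = !length(un_p) && !length(obs),
       pairs = pairs, unmatched_predicted = un_p,
       unexplained_observed = obs)
}

#' Read a Fragment-Analyzer-style observed-band CSV
#'
#' @param path CSV with columns `well`, `size_bp` (and optionally `RFU`,
#'   ignored).
#' @return named list of numeric band-size vectors, one per well.
#' @export
read_observed_bands <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("well", "size_bp") %in% names(x)))
    stop("observed-band CSV needs columns well, size_bp", call. = FALSE)
  split(x$size_bp, x$well)
}
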