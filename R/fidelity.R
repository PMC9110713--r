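# Sticky-end orthogonality under a ligase mismatch-fidelity model. Cognate
# ends are exact reverse complements and score 12; every other pairing is
# scored position-wise from a 4x4 mismatch weight table and must stay below
# the ligation threshold for the end set to be accepted.

#' Ligase mismatch-fidelity model
#'
#' Scores a 12-nt overhang pair position-wise (antiparallel) from a 4x4
#' pairing-weight table. The packaged default table has the qualitative
#' shape of a thermostable high-fidelity ligase profile (Watson-Crick = 1,
#' G.T wobble = 0.3, all other mismatches = 0.05) and can be replaced by any
#' measured profile via `table_path`.
#'
#' @param table_path TSV with columns `base_a`, `base_b`, `weight`
#'   (16 rows); `NULL` loads the packaged default.
#' @param threshold maximum tolerated non-cognate duplex score
#'   (default 8 of 12).
#' @return Object of class `fidelity_model` with a 4x4 `score_matrix`.
#' @export
fidelity_model <- function(table_path = NULL, threshold = 8.0) {
  if (is.null(table_path))
    table_path <- system.file("extdata", "ligase_fidelity_synthetic.tsv",
                              package = "agodesign", mustWork = TRUE)
  tab <- read.delim(table_path, stringsAsFactors = FALSE)
  need <- c("base_a", "base_b", "weight")
  if (!all(need %in% names(tab)) || nrow(tab) != 16L)
    stop("fidelity table must have 16 rows of (base_a, base_b, weight)",
         call. = FALSE)
  m <- matrix(NA_real_, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                              c("A", "C", "G", "T")))
  for (i in seq_len(16)) m[tab$base_a[i], tab$base_b[i]] <- tab$weight[i]
  if (anyNA(m)) stop("fidelity table does not cover all 16 base pairs",
                     call. = FALSE)
  wc <- c(A = "T", C = "G", G = "C", T = "A")
  if (!all(abs(m[cbind(names(wc), wc)] - 1) < 1e-12))
    stop("Watson-Crick pairings must score exactly 1 so a cognate 12-mer ",
         "pair scores 12", call. = FALSE)
  structure(list(score_matrix = m, threshold = threshold,
                 table_source = table_path),
            class = "fidelity_model")
}

#' Is a sticky end palindromic?
#'
#' A palindromic (self-complementary) overhang can ligate to a copy of
#' itself and is excluded from designs.
#'
#' @param end 12-nt overhang sequence (5'->3' of the protruding strand).
#' @return logical.
#' @export
is_palindromic <- function(end) {
  end <- as_dna(end, "sticky end")
  if (nchar(end) != STICKY_LEN)
    stop("sticky end must be ", STICKY_LEN, " nt", call. = FALSE)
  identical(end, revcomp(end))
}

#' Duplex score of two sticky ends
#'
#' Antiparallel position-wise score: position `i` of `end_a` is paired with
#' position `13 - i` of `end_b` and scored by the model's pairing-weight
#' matrix. A cognate pair (exact reverse complements) scores 12; the score
#' is symmetric in its arguments.
#'
#' @param end_a,end_b 12-nt overhang sequences (each 5'->3').
#' @param model a [fidelity_model()].
#' @return Score in `[0, 12]`.
#' @export
duplex_score <- function(end_a, end_b, model = fidelity_model()) {
  end_a <- as_dna(end_a, "end_a"); end_b <- as_dna(end_b, "end_b")
  if (nchar(end_a) != STICKY_LEN || nchar(end_b) != STICKY_LEN)
    stop("sticky ends must be ", STICKY_LEN, " nt", call. = FALSE)
  a <- strsplit(end_a, "", fixed = TRUE)[[1]]
  b <- rev(strsplit(end_b, "", fixed = TRUE)[[1]])
  sum(model$score_matrix[cbind(a, b)])
}

# Ligation admissibility of a new sticky end against previously chosen ones:
# non-palindromic, cognate pair not already used, and every non-cognate
# pairing (against each prior end, its complement, and itself) below the
# threshold.
ligation_admissible <- function(end, chosen_ends, model) {
  if (is_palindromic(end))
    return(list(pass = FALSE, reason = "palindromic_sticky_end"))
  rc <- revcomp(end)
  if (end %in% c(chosen_ends, revcomp(chosen_ends)))
    return(list(pass = FALSE, reason = "duplicate_sticky_end"))
  self_score <- duplex_score(end, end, model)
  if (self_score >= model$threshold)
    return(list(pass = FALSE, reason = "self_ligation_score"))
  for (prev in chosen_ends) {
    scores <- c(duplex_score(end, prev, model),
                duplex_score(end, revcomp(prev), model),
                duplex_score(rc, prev, model),
                duplex_score(rc, revcomp(prev), model))
    if (max(scores) >= model$threshold)
      return(list(pass = FALSE, reason = "mismatch_ligation_score"))
  }
  list(pass = TRUE, reason = NA_character_)
}

#' Orthogonality check of a sticky-end set
#'
#' A set of junction overhangs passes iff (a) no end is palindromic, (b) no
#' two junctions use the same cognate pair, and (c) every non-cognate
#' pairing among the physical ends (each overhang and its complement)
#' scores below the model threshold.
#'
#' @param ends character vector of 12-nt overhangs, one per junction, or a
#'   `plasmid_design` processed by [select_sites()].
#' @param model a [fidelity_model()].
#' @return list with `pass`, `max_noncognate` score, `worst_pair`
#'   (junction index pair attaining it), and `reason` on failure.
#' @export
orthogonality_check <- function(ends, model = fidelity_model()) {
  if (inherits(ends, "plasmid_design"))
    ends <- vapply(ends$junctions,
                   function(j) j$chosen_site$sticky_end, character(1))
  stopifnot(length(ends) >= 1L)
  for (e in ends)
    if (is_palindromic(e))
      return(list(pass = FALSE, reason = "palindromic_sticky_end",
                  max_noncognate = NA_real_, worst_pair = NULL))
  pairs <- cbind(ends, revcomp(ends))
  canon <- apply(pairs, 1, function(p) paste(sort(p), collapse = "|"))
  if (anyDuplicated(canon))
    return(list(pass = FALSE, reason = "duplicate_sticky_end",
                max_noncognate = NA_real_,
                worst_pair = which(canon %in% canon[duplicated(canon)])))
  # physical ends: overhang and complement per junction
  phys <- data.frame(junction = rep(seq_along(ends) - 1L, 2L),
                     seq = c(ends, revcomp(ends)),
                     cognate_of = c(revcomp(ends), ends),
                     stringsAsFactors = FALSE)
  worst <- -Inf; worst_pair <- NULL
  for (i in seq_len(nrow(phys))) for (jj in i:nrow(phys)) {
    if (phys$cognate_of[i] == phys$seq[jj] &&
        phys$junction[i] == phys$junction[jj]) next
    s <- duplex_score(phys$seq[i], phys$seq[jj], model)
    if (s > worst) { worst <- s
      worst_pair <- c(phys$junction[i], phys$junction[jj]) }
  }
  list(pass = worst < model$threshold,
       reason = if (worst < model$threshold) NA_character_
                else "mismatch_ligation_score",
       max_noncognate = worst, worst_pair = worst_pair)
}
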