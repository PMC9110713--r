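# Every tunable threshold of the pipeline lives in one nested config list,
# serializable as YAML so command-line runs can swap it wholesale.

#' Default pipeline configuration
#'
#' Returns the full nested list of tunable thresholds with their defaults:
#'
#' * `digestion`: recognition-window filters — GC bounds `[0, 0.75]`,
#'   homopolymer cap (runs of >4 A or >4 T fail), G-quadruplex motif
#'   parameters, off-target k-mer size (12).
#' * `enzyme_mode`: GC cutoffs steering the WT-PfAgo / PfAgo* suggestion
#'   (0.10 / 0.50 window preference, 0.65 fragment cutoff for mutant-only).
#' * `geometry`: ARE cut geometry — top/bottom strand cut positions 6 and 18
#'   inside the 24-bp window (yielding the central 12-nt 5' overhang), guide
#'   length 16, guide cut index 10 (scissile bond between guide positions
#'   10 and 11).
#' * `ligation`: mismatch-ligation score threshold (8 of 12).
#' * `primers`: Tm floor 58 degC, binding-length bounds `[15, 36]`, GC
#'   branch thresholds 0.40/0.60, Tm model salt/concentration parameters,
#'   max primer tail 40 nt.
#' * `digest_check`: band-size window `[100, 9500]` bp, Fragment Analyzer
#'   accuracy `A = 0.1`, noise floor 50 bp.
#' * `worklists`: acoustic/tip volume routing (acoustic < 3 uL, droplet
#'   granularity 2.5 nL), per-reaction PCR transfer volumes, plate packing
#'   (92 reactions per 96-well plate, ladder wells A1/H12).
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    digestion = list(
      gc_min = 0.0, gc_max = 0.75,
      max_at_run = 4L,
      gquad_min_run = 3L, gquad_loop_min = 1L, gquad_loop_max = 7L,
      offtarget_k = 12L),
    enzyme_mode = list(
      wt_preference_gc = 0.10,
      mutant_preference_gc = 0.50,
      mutant_only_fragment_gc = 0.65),
    geometry = list(
      top_cut = 6L, bottom_cut = 18L,
      guide_length = 16L, guide_cut_index = 10L),
    ligation = list(
      threshold = 8.0,
      fidelity_table = NULL),   # NULL -> packaged HiFi-Taq-shaped table
    primers = list(
      tm_floor = 58, binding_min = 15L, binding_max = 36L,
      gc_low = 0.40, gc_high = 0.60,
      start_length = 18L, max_overhang = 40L,
      small_fragment_max = 80L,
      tm = list(monovalent_mM = 50, divalent_mM = 1.5,
                dntp_mM = 0.6, primer_nM = 50)),
    digest_check = list(
      min_band = 100L, max_band = 9500L, accuracy_A = 0.1,
      gap_reference = "larger",   # which adjacent band anchors the gap rule
      noise_floor = 50L, match_tolerance = 0.1),
    worklists = list(
      acoustic_max_uL = 3.0, tip_min_uL = 1.0, droplet_nL = 2.5,
      pcr_primer_uL = 0.5, pcr_template_uL = 0.5,
      reactions_per_plate = 92L, ladder_wells = c("A1", "H12"),
      hydration_target_uM = 100,
      equimolar_total_ng = 1000,
      concentration_range = c(20, 150)))
}

#' Load a configuration YAML, filling unset values from the defaults
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return Nested config list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  merge_into <- function(base, over) {
    for (k in names(over)) {
      if (is.list(over[[k]]) && is.list(base[[k]]))
        base[[k]] <- merge_into(base[[k]], over[[k]])
      else base[[k]] <- over[[k]]
    }
    base
  }
  merge_into(cfg, user)
}

#' Write a configuration list as YAML
#'
#' @param config nested config list.
#' @param path output file.
#' @return `path` invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
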