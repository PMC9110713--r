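# Liquid-handler worklist compilation. Picklists are plain data.frames with
# the acoustic-dispenser cherry-pick column layout (volumes in nL for
# acoustic steps, uL for tip-based steps); 96-well PCR plates hold at most
# 92 reactions with wells A1 and H12 reserved for the sizing ladder.

#' Well ids of a plate in column-major fill order
#'
#' `A1, B1, ... H1, A2, ...` for 96-well; rows A-P and columns 1-24 for
#' 384-well.
#'
#' @param format 96 or 384.
#' @return Character vector of well ids.
#' @export
plate_wells <- function(format = 96L) {
  if (format == 96L) { rows <- LETTERS[1:8]; cols <- 1:12 }
  else if (format == 384L) { rows <- LETTERS[1:16]; cols <- 1:24 }
  else stop("format must be 96 or 384", call. = FALSE)
  as.vector(vapply(cols, function(c) paste0(rows, c),
                   character(length(rows))))
}

valid_well <- function(well, format = 96L) {
  rx <- if (format == 96L) "^[A-H](1[0-2]|[1-9])$"
        else "^[A-P](1[0-9]|2[0-4]|[1-9])$"
  grepl(rx, well)
}

new_picklist <- function(step, rows, instrument = c("acoustic",
                                                    "tip_based")) {
  instrument <- match.arg(instrument)
  stopifnot(all(rows$volume > 0))
  structure(rows, step = step, instrument = instrument,
            class = c("picklist", "data.frame"))
}

picklist_row <- function(source_plate, source_well, dest_plate, dest_well,
                         volume, unit) {
  data.frame(source_plate = source_plate, source_well = source_well,
             dest_plate = dest_plate, dest_well = dest_well,
             volume = volume, unit = unit, stringsAsFactors = FALSE)
}

#' Write a picklist as an instrument CSV
#'
#' Acoustic picklists use the cherry-pick header (`Source Plate Name`,
#' `Source Well`, `Destination Plate Name`, `Destination Well`,
#' `Transfer Volume`) with volumes in nL; tip-based picklists carry a
#' plainer header with volumes in uL.
#'
#' @param picklist a picklist data.frame.
#' @param path output CSV.
#' @return `path` invisibly.
#' @export
write_picklist <- function(picklist, path) {
  if (attr(picklist, "instrument") == "acoustic") {
    out <- data.frame(
      `Source Plate Name` = picklist$source_plate,
      `Source Well` = picklist$source_well,
      `Destination Plate Name` = picklist$dest_plate,
      `Destination Well` = picklist$dest_well,
      `Transfer Volume` = ifelse(picklist$unit == "uL",
                                 picklist$volume * 1000, picklist$volume),
      check.names = FALSE)
  } else {
    out <- data.frame(
      source_plate = picklist$source_plate,
      source_well = picklist$source_well,
      dest_plate = picklist$dest_plate,
      dest_well = picklist$dest_well,
      volume_uL = ifelse(picklist$unit == "nL",
                         picklist$volume / 1000, picklist$volume))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a picklist CSV
#'
#' @param path CSV written by [write_picklist()].
#' @return data.frame in the internal picklist layout.
#' @export
read_picklist <- function(path) {
  x <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if ("Transfer Volume" %in% names(x)) {
    new_picklist("reparsed", picklist_row(
      x[["Source Plate Name"]], x[["Source Well"]],
      x[["Destination Plate Name"]], x[["Destination Well"]],
      x[["Transfer Volume"]], "nL"), "acoustic")
  } else {
    new_picklist("reparsed", picklist_row(
      x$source_plate, x$source_well, x$dest_plate, x$dest_well,
      x$volume_uL, "uL"), "tip_based")
  }
}

#' Deduplicate oligos across a batch
#'
#' Exact-sequence deduplication of primer/guide order tables, with a usage
#' map recording every consumer of each unique oligo.
#'
#' @param sheets named list of order tables (data.frames with columns
#'   `name`, `sequence`), one per plasmid.
#' @return list with `order_sheet` (unique oligos: `oligo_id`, `sequence`,
#'   `n_uses`), `usage` (data.frame `oligo_id`, `plasmid`, `name`),
#'   `total`, `unique`.
#' @export
dedupe_oligos <- function(sheets) {
  stopifnot(length(sheets) >= 1L)
  all <- do.call(rbind, lapply(names(sheets), function(p)
    data.frame(plasmid = p, name = sheets[[p]]$name,
               sequence = sheets[[p]]$sequence, stringsAsFactors = FALSE)))
  uniq <- unique(all$sequence)
  ids <- sprintf("oligo_%04d", seq_along(uniq))
  all$oligo_id <- ids[match(all$sequence, uniq)]
  list(order_sheet = data.frame(
         oligo_id = ids, sequence = uniq,
         n_uses = as.vector(table(all$oligo_id)[ids]),
         stringsAsFactors = FALSE),
       usage = all[, c("oligo_id", "plasmid", "name")],
       total = nrow(all), unique = length(uniq))
}

#' Hydration picklist for lyophilized oligos
#'
#' Volume of water per well to reach the target concentration:
#' `uL = nmol / target_uM * 1000`.
#'
#' @param sheet data.frame with columns `well`, `nmol` (manufacturer
#'   synthesis report).
#' @param target_uM target concentration (default 100 uM).
#' @param plate plate name for both source (water) and destination.
#' @return A tip-based picklist in plate-scan order.
#' @export
hydration_picklist <- function(sheet, target_uM = 100,
                               plate = "oligo_plate") {
  if (!all(c("well", "nmol") %in% names(sheet)))
    stop("sheet needs columns well, nmol", call. = FALSE)
  bad <- is.na(sheet$nmol) | sheet$nmol <= 0
  if (any(bad))
    stop("missing/invalid nmol for well(s): ",
         paste(sheet$well[bad], collapse = ", "), call. = FALSE)
  ord <- order(match(sheet$well, plate_wells(96L)))
  sheet <- sheet[ord, ]
  new_picklist("hydration", picklist_row(
    "water_trough", "A1", plate, sheet$well,
    sheet$nmol / target_uM * 1000, "uL"), "tip_based")
}

# destination wells for `n` reactions: column-major, skipping reserved
# ladder wells, at most `per_plate` per plate
reaction_layout <- function(n, per_plate = 92L,
                            reserved = c("A1", "H12"),
                            plate_prefix = "pcr_plate") {
  usable <- setdiff(plate_wells(96L), reserved)
  if (per_plate > length(usable))
    stop("cannot fit ", per_plate, " reactions in a 96-well plate with ",
         length(reserved), " reserved wells", call. = FALSE)
  usable <- usable[seq_len(per_plate)]
  plate_no <- (seq_len(n) - 1L) %/% per_plate + 1L
  data.frame(reaction = seq_len(n),
             dest_plate = sprintf("%s_%d", plate_prefix, plate_no),
             dest_well = usable[(seq_len(n) - 1L) %% per_plate + 1L],
             stringsAsFactors = FALSE)
}

#' PCR setup picklists
#'
#' Packs the batch's PCR reactions 92 per 96-well plate (column-major,
#' ladder wells A1/H12 reserved) and emits one acoustic transfer row per
#' reagent (forward primer, reverse primer, template) per reaction from
#' their 384-well source locations.
#'
#' @param reactions data.frame with one row per reaction: `reaction_id`,
#'   `fwd_well`, `rev_well`, `template_well` (384-well source wells) and
#'   optionally `source_plate` (default `"source_384"`).
#' @param config pipeline configuration (`worklists` section).
#' @return list with `picklist` (acoustic) and `layout` (data.frame
#'   reaction -> destination plate/well).
#' @export
pcr_setup_picklists <- function(reactions, config = default_config()) {
  w <- config$worklists
  need <- c("reaction_id", "fwd_well", "rev_well", "template_well")
  missing_col <- setdiff(need, names(reactions))
  if (length(missing_col))
    stop("reactions table lacks ", paste(missing_col, collapse = ", "),
         call. = FALSE)
  for (col in c("fwd_well", "rev_well", "template_well")) {
    bad <- is.na(reactions[[col]]) | !valid_well(reactions[[col]], 384L)
    if (any(bad))
      stop("reaction '", reactions$reaction_id[which(bad)[1]],
           "' has no valid 384-well source in ", col, call. = FALSE)
  }
  if (is.null(reactions$source_plate))
    reactions$source_plate <- "source_384"
  layout <- reaction_layout(nrow(reactions), w$reactions_per_plate,
                            w$ladder_wells)
  layout$reaction_id <- reactions$reaction_id
  rows <- do.call(rbind, lapply(seq_len(nrow(reactions)), function(i) {
    picklist_row(
      reactions$source_plate[i],
      c(reactions$fwd_well[i], reactions$rev_well[i],
        reactions$template_well[i]),
      layout$dest_plate[i], layout$dest_well[i],
      c(w$pcr_primer_uL, w$pcr_primer_uL, w$pcr_template_uL), "uL")
  }))
  list(picklist = new_picklist("pcr_setup", rows, "acoustic"),
       layout = layout[, c("reaction_id", "dest_plate", "dest_well")])
}

#' Equimolar fragment-mixing picklist
#'
#' Equimolar pooling means per-fragment mass proportional to length:
#' `m_i = total_ng * L_i / sum(L)`; the transfer volume is `m_i / conc_i`.
#' Transfers under 3 uL are routed to the acoustic dispenser; volumes below
#' the droplet granularity raise an error row.
#'
#' @param concentrations data.frame with `fragment_id`, `ng_per_uL`.
#' @param lengths named numeric vector of fragment lengths (bp).
#' @param total_ng total pooled mass (default 1000 ng).
#' @param config pipeline configuration.
#' @param dest destination `c(plate, well)`.
#' @return An acoustic picklist with extra columns `fragment_id`, `mass_ng`,
#'   `instrument_hint`.
#' @export
equimolar_mix_picklist <- function(concentrations, lengths,
                                   total_ng = NULL,
                                   config = default_config(),
                                   dest = c("assembly_plate", "A1")) {
  w <- config$worklists
  if (is.null(total_ng)) total_ng <- w$equimolar_total_ng
  stopifnot(all(concentrations$ng_per_uL > 0))
  L <- lengths[concentrations$fragment_id]
  if (anyNA(L))
    stop("missing length for fragment(s): ",
         paste(concentrations$fragment_id[is.na(L)], collapse = ", "),
         call. = FALSE)
  mass <- total_ng * L / sum(L)
  vol_uL <- mass / concentrations$ng_per_uL
  if (any(vol_uL * 1000 < w$droplet_nL))
    stop("transfer volume below the ", w$droplet_nL,
         " nL droplet granularity for fragment(s): ",
         paste(concentrations$fragment_id[vol_uL * 1000 < w$droplet_nL],
               collapse = ", "), call. = FALSE)
  rows <- picklist_row("fragment_plate",
                       plate_wells(96L)[seq_len(nrow(concentrations))],
                       dest[1], dest[2], vol_uL, "uL")
  rows$fragment_id <- concentrations$fragment_id
  rows$mass_ng <- mass
  rows$instrument_hint <- ifelse(vol_uL < w$acoustic_max_uL,
                                 "acoustic", "tip_based")
  new_picklist("equimolar_mix", rows, "acoustic")
}

#' Consolidate failed PCRs into a fresh plate
#'
#' @param qc data.frame covering every reaction: `reaction_id`,
#'   `source_plate`, `source_well`, `pass` (logical).
#' @param volume_uL volume to move per failed reaction.
#' @param config pipeline configuration.
#' @return list with `picklist` (tip-based; empty when nothing failed) and
#'   `mapping` (old -> new wells).
#' @export
failed_pcr_picklist <- function(qc, volume_uL = 10,
                                config = default_config()) {
  w <- config$worklists
  need <- c("reaction_id", "source_plate", "source_well", "pass")
  if (!all(need %in% names(qc)))
    stop("qc table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  failed <- qc[!qc$pass, , drop = FALSE]
  if (!nrow(failed)) {
    empty <- picklist_row(character(0), character(0), character(0),
                          character(0), numeric(0), character(0))
    return(list(picklist = new_picklist("failed_pcr_rework", empty,
                                        "tip_based"),
                mapping = data.frame()))
  }
  layout <- reaction_layout(nrow(failed), w$reactions_per_plate,
                            w$ladder_wells, plate_prefix = "rework_plate")
  rows <- picklist_row(failed$source_plate, failed$source_well,
                       layout$dest_plate, layout$dest_well,
                       rep(volume_uL, nrow(failed)), "uL")
  list(picklist = new_picklist("failed_pcr_rework", rows, "tip_based"),
       mapping = data.frame(reaction_id = failed$reaction_id,
                            old_plate = failed$source_plate,
                            old_well = failed$source_well,
                            new_plate = layout$dest_plate,
                            new_well = layout$dest_well,
                            stringsAsFactors = FALSE))
}
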