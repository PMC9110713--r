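mk_reactions <- function(n) {
  src <- plate_wells(384L)
  data.frame(reaction_id = sprintf("rx%03d", seq_len(n)),
             fwd_well = src[seq_len(n)],
             rev_well = src[seq_len(n) + n],
             template_well = src[((seq_len(n) - 1L) %% 80L) + 1L],
             stringsAsFactors = FALSE)
}

test_that("oligo deduplication keeps one order row per unique sequence", {
  shared <- random_seq(30, seed = 131)
  sheets <- list(
    p1 = data.frame(name = c("p1_F", "p1_R"),
                    sequence = c(shared, random_seq(28))),
    p2 = data.frame(name = c("p2_F", "p2_R"),
                    sequence = c(shared, random_seq(28))))
  res <- dedupe_oligos(sheets)
  expect_identical(res$total, 4L)
  expect_identical(res$unique, 3L)
  shared_id <- res$order_sheet$oligo_id[res$order_sheet$sequence == shared]
  expect_identical(sum(res$usage$oligo_id == shared_id), 2L)
  # no duplicates: order sheet size == input size; set oracle on a batch
  d <- designed_fixture(n = 5, gc = 0.5, seed = 7)
  sheet <- rbind(primer_order_sheet(d, design_primers(d))[, c("name", "sequence")],
                 guide_order_sheet(d)[, c("name", "sequence")])
  res2 <- dedupe_oligos(list(fix = sheet))
  expect_identical(res2$unique, length(unique(sheet$sequence)))
})

test_that("hydration volumes follow nmol / target_uM * 1000", {
  sheet <- data.frame(well = c("A1", "B1", "C1"), nmol = c(10, 2.5, 7.2))
  pl <- hydration_picklist(sheet, target_uM = 100)
  expect_equal(pl$volume, c(100, 25, 72))
  expect_identical(attr(pl, "instrument"), "tip_based")
  expect_error(hydration_picklist(data.frame(well = "A1", nmol = NA)),
               "A1")
  # full 96-row sheet matches hand arithmetic
  full <- data.frame(well = plate_wells(96L), nmol = seq(1, 20.05, 0.2))
  pl96 <- hydration_picklist(full, target_uM = 100)
  expect_equal(pl96$volume, full$nmol / 100 * 1000)
})

test_that("150 reactions pack as 92 + 58 with ladder wells reserved", {
  res <- pcr_setup_picklists(mk_reactions(150))
  tab <- table(res$layout$dest_plate)
  expect_identical(as.integer(tab[["pcr_plate_1"]]), 92L)
  expect_identical(as.integer(tab[["pcr_plate_2"]]), 58L)
  expect_false(any(res$layout$dest_well %in% c("A1", "H12")))
  # single reaction still avoids the reserved wells
  one <- pcr_setup_picklists(mk_reactions(1))
  expect_false(one$layout$dest_well %in% c("A1", "H12"))
  expect_identical(one$layout$dest_well, "B1")  # column-major after A1
})

test_that("PCR picklists re-parse and sum to the per-reaction recipe", {
  res <- pcr_setup_picklists(mk_reactions(10))
  path <- withr::local_tempfile(fileext = ".csv")
  write_picklist(res$picklist, path)
  back <- read_picklist(path)
  expect_identical(nrow(back), 30L)  # 3 transfers per reaction
  per_well <- tapply(back$volume, paste(back$dest_plate, back$dest_well),
                     sum)
  cfg <- default_config()$worklists
  recipe_nL <- (2 * cfg$pcr_primer_uL + cfg$pcr_template_uL) * 1000
  expect_true(all(per_well == recipe_nL))
})

test_that("equimolar mixing gives mass proportional to length and equal moles", {
  conc <- data.frame(fragment_id = c("a", "b"), ng_per_uL = c(50, 50))
  pl <- equimolar_mix_picklist(conc, c(a = 1000, b = 2000),
                               total_ng = 1000)
  expect_equal(pl$mass_ng, c(1000 / 3, 2000 / 3), tolerance = 1e-12)
  # equal lengths and concentrations -> equal volumes
  conc2 <- data.frame(fragment_id = c("a", "b"), ng_per_uL = c(80, 80))
  pl2 <- equimolar_mix_picklist(conc2, c(a = 1500, b = 1500),
                                total_ng = 1000)
  expect_equal(pl2$volume[1], pl2$volume[2])
  # seeded fixture: moles = mass / (657 * L) equal within 1e-9 relative
  d <- generate_design(fixture_spec(n_fragments = 7, seed = 7))
  conc3 <- generate_concentration_table(d, seed = 7)
  lens <- vapply(d$fragments, function(f) nchar(f$sequence), numeric(1))
  names(lens) <- vapply(d$fragments, `[[`, character(1), "id")
  pl3 <- equimolar_mix_picklist(conc3, lens, total_ng = 1000)
  moles <- pl3$mass_ng / (657 * lens[pl3$fragment_id])
  expect_lt(diff(range(moles)) / mean(moles), 1e-9)
  # instrument routing: sub-3-uL rows go acoustic
  expect_identical(pl3$instrument_hint,
                   ifelse(pl3$volume < 3, "acoustic", "tip_based"))
})

test_that("failed-PCR consolidation repacks only the failures", {
  qc <- data.frame(reaction_id = sprintf("r%02d", 1:10),
                   source_plate = rep(c("pcr_plate_1", "pcr_plate_2"), 5),
                   source_well = plate_wells(96L)[3:12],
                   pass = rep(c(TRUE, FALSE), 5))
  res <- failed_pcr_picklist(qc)
  expect_identical(nrow(res$picklist), 5L)
  expect_setequal(res$mapping$reaction_id,
                  qc$reaction_id[!qc$pass])
  expect_false(any(res$mapping$new_well %in% c("A1", "H12")))
  # zero failures -> empty picklist
  qc$pass <- TRUE
  none <- failed_pcr_picklist(qc)
  expect_identical(nrow(none$picklist), 0L)
})

test_that("well ids validate against plate formats", {
  expect_true(all(agodesign:::valid_well(plate_wells(96L), 96L)))
  expect_true(all(agodesign:::valid_well(plate_wells(384L), 384L)))
  expect_false(agodesign:::valid_well("I1", 96L))
  expect_false(agodesign:::valid_well("A25", 384L))
  expect_false(agodesign:::valid_well("A01", 96L))
})
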