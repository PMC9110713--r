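test_that("search spaces join 40 bp from each adjoining fragment", {
  up <- paste0(random_seq(160, seed = 51), strrep("A", 40))
  down <- paste0(strrep("C", 40), random_seq(160))
  d <- plasmid_design("x", list(fragment("u", up, order_index = 0),
                                fragment("v", down, order_index = 1)))
  expect_identical(build_search_space(d, 0),
                   paste0(strrep("A", 40), strrep("C", 40)))
  # wrap-around junction spans the origin: manual splice oracle
  ss <- build_search_space(d, 1)
  manual <- paste0(substr(down, nchar(down) - 39, nchar(down)),
                   substr(up, 1, 40))
  expect_identical(ss, manual)
})

test_that("an 80-nt search space yields 57 stride-1 windows covering both ends", {
  ss <- random_seq(80, seed = 52)
  cand <- enumerate_candidates(ss)
  expect_identical(nrow(cand), 57L)
  expect_identical(cand$window[cand$offset == 0], substr(ss, 1, 24))
  expect_identical(cand$window[cand$offset == 56], substr(ss, 57, 80))
  expect_identical(nrow(enumerate_candidates(random_seq(24))), 1L)
  expect_error(enumerate_candidates(random_seq(20)), "shorter")
  # generic count: L - 23 windows
  for (L in c(30L, 50L, 100L))
    expect_identical(nrow(enumerate_candidates(random_seq(L))), L - 23L)
})

test_that("digestion filters enforce homopolymer, GC, and G-quadruplex rules", {
  # run of 5 A's fails; run of exactly 4 passes (boundary inclusive)
  w5 <- paste0("AAAAA", "GCGTCGATCGTAGCTAGCT")
  r5 <- apply_digestion_filters(w5)
  expect_false(r5$pass[r5$criterion == "homopolymer_run"])
  w4 <- paste0("AAAA", "GCGTCGATCGTAGCTAGCTG")
  r4 <- apply_digestion_filters(w4)
  expect_true(r4$pass[r4$criterion == "homopolymer_run"])
  expect_true(attr(r4, "pass"))
  # T-runs are screened like A-runs
  wt <- paste0("TTTTT", "GCGTCGATCGTAGCTAGCT")
  expect_false(attr(apply_digestion_filters(wt), "pass"))
  # GC 19/24 fails the 0.75 cap; GC 18/24 sits exactly on it and passes
  whi <- paste0(strrep("GC", 9), "G", "ATATA")
  expect_equal(gc_content(whi), 19 / 24)
  expect_false(attr(apply_digestion_filters(whi), "pass"))
  wok <- paste0(strrep("GC", 9), "ATATAT")
  expect_equal(gc_content(wok), 0.75)
  expect_true(all(apply_digestion_filters(wok)$pass[
    apply_digestion_filters(wok)$criterion == "gc_content"]))
  # G-quadruplex motif on either strand
  g4 <- "GGGAGGGTGGGAGGGTACGTAGCT"
  rg <- apply_digestion_filters(g4)
  expect_false(rg$pass[rg$criterion == "g_quadruplex"])
  c4 <- revcomp(g4)
  rc <- apply_digestion_filters(c4)
  expect_false(rc$pass[rc$criterion == "g_quadruplex"])
})

test_that("off-target filter catches a sticky end duplicated elsewhere", {
  d <- generate_design(fixture_spec(n_fragments = 3,
                                    size_range = c(500, 700),
                                    gc_target = 0.5, seed = 61))
  lib <- offtarget_library(d, k = 12)
  j <- d$junctions[[1]]
  cand <- enumerate_candidates(j$search_space)
  w <- cand$window[cand$offset == 28]
  clean <- apply_digestion_filters(w, offtargets = lib,
                                   locus_pos = j$search_space_origin + 28)
  expect_true(clean$pass[clean$criterion == "off_target"])
  # plant the window's central 12-mer in another fragment and re-index:
  # exhaustive string search now finds it twice, and the filter fails
  sticky <- substr(w, 7, 18)
  f3 <- d$fragments[[3]]$sequence
  substr(f3, 200, 211) <- sticky
  d2 <- plasmid_design("dup", list(
    fragment("f01", d$fragments[[1]]$sequence, order_index = 0),
    fragment("f02", d$fragments[[2]]$sequence, order_index = 1),
    fragment("f03", f3, order_index = 2)))
  lib2 <- offtarget_library(d2, k = 12)
  dirty <- apply_digestion_filters(w, offtargets = lib2,
                                   locus_pos = j$search_space_origin + 28)
  expect_false(dirty$pass[dirty$criterion == "off_target"])
})

test_that("enzyme-mode suggestion follows the GC cutoffs", {
  expect_identical(as.character(
    suggest_enzyme_mode(c(0.72, 0.74, 0.73), 0.5)), "mutant_only")
  m <- suggest_enzyme_mode(c(0.5, 0.45), 0.10)
  expect_identical(as.character(m), "wt_and_mutant")
  expect_identical(attr(m, "preference"), "wt")
  m2 <- suggest_enzyme_mode(c(0.36, 0.36), 0.50)
  expect_identical(attr(m2, "preference"), "mutant")
  m3 <- suggest_enzyme_mode(c(0.36, 0.36), 0.30)
  expect_identical(attr(m3, "preference"), "neutral")
})

test_that("derived guides have the stated geometry", {
  set.seed(71)
  for (i in 1:50) {
    w <- random_seq(24)
    g <- derive_guides(w)
    expect_identical(nchar(g$guide_top), 16L)
    expect_identical(nchar(g$guide_bottom), 16L)
    expect_identical(nchar(g$sticky_end), 12L)
    expect_identical(g$sticky_end, substr(w, 7, 18))
    # guides anneal to their strands: top guide is the revcomp of window
    # bases 1-16, bottom guide reads window bases 9-24
    expect_identical(g$guide_top, revcomp(substr(w, 1, 16)))
    expect_identical(g$guide_bottom, substr(w, 9, 24))
  }
  expect_error(derive_guides(random_seq(24),
                             cut_geometry(top_cut = 2)), "outside")
})

test_that("digestion of a site-bearing amplicon reproduces the sticky end", {
  set.seed(72)
  for (i in 1:200) {
    w <- random_seq(24)
    g <- derive_guides(w)
    site <- list(junction_index = 0L, sequence24 = w,
                 sticky_end = g$sticky_end)
    amplicon <- paste0(w, random_seq(80))
    dig <- simulate_digestion(amplicon, left_site = site)
    expect_identical(dig$left_overhang, g$sticky_end)
  }
})

test_that("select_sites is greedy, deterministic, and idempotent under re-filtering", {
  d <- designed_fixture(n = 5, gc = 0.5, seed = 7)
  expect_true(all(vapply(d$junctions,
                         function(j) !is.null(j$chosen_site), logical(1))))
  # determinism: a fresh run picks identical windows
  d2 <- select_sites(generate_design(
    fixture_spec(n_fragments = 5, size_range = c(800, 1500),
                 gc_target = 0.5, seed = 7)))
  expect_identical(
    vapply(d$junctions, function(j) j$chosen_site$sequence24, character(1)),
    vapply(d2$junctions, function(j) j$chosen_site$sequence24,
           character(1)))
  # every finalized site still passes every digestion filter
  lib <- offtarget_library(d)
  for (j in d$junctions) {
    s <- j$chosen_site
    rep <- apply_digestion_filters(
      s$sequence24, offtargets = lib,
      locus_pos = j$search_space_origin + s$window_offset)
    expect_true(attr(rep, "pass"))
  }
})

test_that("an all-A search space is reported infeasible with per-window reasons", {
  up <- paste0(random_seq(100, seed = 73), strrep("A", 40))
  down <- paste0(strrep("A", 40), random_seq(100))
  d <- plasmid_design("bad", list(fragment("u", up, order_index = 0),
                                  fragment("v", down, order_index = 1)))
  err <- tryCatch(select_sites(d), design_infeasible = function(e) e)
  expect_s3_class(err, "design_infeasible")
  expect_match(conditionMessage(err), "homopolymer")
  expect_identical(length(err$failures), 57L)
})

test_that("a junction rejects a sticky end already used by an earlier junction", {
  # engineer two junctions whose boundary-centered windows are identical:
  # the second junction must not reuse the same cognate pair
  core <- random_seq(24, seed = 74)
  mk <- function(seed) random_seq(300, seed = seed)
  u1 <- paste0(mk(75), substr(core, 1, 12))
  v1 <- paste0(substr(core, 13, 24), mk(76))
  u2 <- paste0(mk(77), substr(core, 1, 12))
  v2 <- paste0(substr(core, 13, 24), mk(78))
  d <- plasmid_design("twin", list(
    fragment("a", paste0(v1, u2), order_index = 0),
    fragment("b", paste0(v2, u1), order_index = 1)))
  # junction 0 (a->b) and junction 1 (b->a) both see `core` at offset 28
  res <- tryCatch(select_sites(d), design_infeasible = function(e) e)
  if (inherits(res, "design_infeasible")) {
    expect_match(conditionMessage(res), "duplicate|off_target|mismatch")
  } else {
    ends <- vapply(res$junctions,
                   function(j) j$chosen_site$sticky_end, character(1))
    expect_false(ends[1] == ends[2])
    expect_false(ends[1] == revcomp(ends[2]))
  }
})
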