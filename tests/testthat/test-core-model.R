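test_that("revcomp is an involution and rejects bad alphabets", {
  expect_identical(revcomp("ACGT"), "ACGT")
  expect_identical(revcomp("AAAA"), "TTTT")
  set.seed(11)
  for (i in 1:20) {
    s <- random_seq(100)
    expect_identical(revcomp(revcomp(s)), s)
  }
  expect_error(revcomp("ACGU"), "non-ACGT")
  expect_error(revcomp("ACGN"), "non-ACGT")
})

test_that("gc_content matches per-character counting", {
  expect_equal(gc_content("ATAT"), 0)
  expect_equal(gc_content("GCGC"), 1)
  expect_error(gc_content(""), "length >= 1")
  set.seed(12)
  for (i in 1:1000) {
    s <- random_seq(24)
    counts <- table(factor(strsplit(s, "")[[1]], levels = c("A","C","G","T")))
    expect_equal(gc_content(s), (counts[["G"]] + counts[["C"]]) / 24)
  }
})

test_that("canonical rotation matches all-rotations brute force", {
  # all rotations of one circle (and its reflection) share a canonical form
  for (s in c("GTA", "TAG", "AGT"))
    expect_identical(rotate_to_canonical(s), oracle_canonical("GTA"))
  set.seed(13)
  for (i in 1:25) {
    s <- random_seq(sample(5:40, 1))
    expect_identical(rotate_to_canonical(s), oracle_canonical(s))
    expect_identical(rotate_to_canonical(s), rotate_to_canonical(revcomp(s)))
  }
  s <- random_seq(1000, seed = 14)
  rot <- paste0(substr(s, 101, 1000), substr(s, 1, 100))
  expect_identical(rotate_to_canonical(s), rotate_to_canonical(rot))
})

test_that("rotation/reflection equality is an equivalence relation", {
  set.seed(15)
  for (i in 1:10) {
    a <- random_seq(60)
    b <- paste0(substr(a, 13, 60), substr(a, 1, 12))  # rotation of a
    c <- revcomp(b)                                   # reflection of b
    ca <- rotate_to_canonical(a)
    expect_identical(ca, rotate_to_canonical(a))            # reflexive
    expect_identical(rotate_to_canonical(b), ca)            # symmetric pair
    expect_identical(rotate_to_canonical(c), ca)            # transitive
  }
})

test_that("plasmid_design builds one junction per fragment with 80-nt search spaces", {
  frags <- lapply(1:3, function(i)
    fragment(paste0("f", i), random_seq(200, seed = 20 + i),
             order_index = i - 1))
  d <- plasmid_design("tri", frags)
  expect_length(d$junctions, 3)
  expect_identical(nchar(d$target_sequence), 600L)
  for (j in d$junctions) {
    expect_identical(nchar(j$search_space), 80L)
    expect_identical(
      j$search_space,
      circ_sub_test(d$target_sequence, j$search_space_origin, 80))
  }
  # single-fragment design: the wrap-around junction joins tail to head
  solo <- plasmid_design("solo", list(fragment("f1", random_seq(300))))
  expect_length(solo$junctions, 1)
  expect_identical(solo$junctions[[1]]$upstream_fragment_id, "f1")
  expect_identical(solo$junctions[[1]]$downstream_fragment_id, "f1")
})

test_that("design invariants reject malformed inputs", {
  f <- function(id, oi) fragment(id, random_seq(150), order_index = oi)
  expect_error(plasmid_design("x", list(f("a", 0), f("a", 1))),
               "duplicate fragment id")
  expect_error(plasmid_design("x", list(f("a", 0), f("b", 2))),
               "contiguous")
  expect_error(fragment("a", "ACGTN"), "non-ACGT")
})

test_that("load_design round-trips fixture files and manifests", {
  dir <- withr::local_tempdir()
  spec <- fixture_spec(n_fragments = 4, size_range = c(300, 600),
                       gc_target = 0.45, seed = 31)
  d <- generate_design(spec)
  manifest <- write_design_files(d, dir)
  loaded <- load_design(manifest, dir = dir)
  expect_identical(loaded$target_sequence, d$target_sequence)
  expect_identical(
    vapply(loaded$fragments, `[[`, character(1), "id"),
    vapply(d$fragments, `[[`, character(1), "id"))
  # JSON round trip preserves the design
  jpath <- file.path(dir, "design.json")
  write_design_json(loaded, jpath)
  again <- read_design_json(jpath)
  expect_identical(again$target_sequence, d$target_sequence)
})

test_that("GenBank writer/reader round-trips sequence and feature table", {
  dir <- withr::local_tempdir()
  s <- random_seq(350, seed = 33)
  feats <- data.frame(
    key = c("misc_feature", "misc_feature", "promoter"),
    location = c("1..120", "121..350", "10..45"),
    qualifier = c("label", "label", "note"),
    value = c("partA", "partB", "synthetic test promoter"),
    stringsAsFactors = FALSE)
  path <- file.path(dir, "x.gb")
  write_genbank("testplasmid", s, path, features = feats)
  gb <- read_genbank(path)
  expect_identical(gb$name, "testplasmid")
  expect_identical(gb$sequence, s)
  expect_identical(gb$features$key, feats$key)
  expect_identical(gb$features$location, feats$location)
  expect_identical(gb$features$value, feats$value)
  # and load_design accepts a GenBank file via a manifest
  write.table(data.frame(fragment_id = "testplasmid", file = "x.gb",
                         role = "backbone", order_index = 0),
              file.path(dir, "m.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  d <- load_design(file.path(dir, "m.tsv"), dir = dir)
  expect_identical(d$target_sequence, s)
  expect_s3_class(attr(d, "features"), "data.frame")
})
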