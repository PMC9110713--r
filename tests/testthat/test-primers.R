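test_that("binding-site sizing follows the GC branches", {
  cfg <- default_config()
  # a balanced 18-mer seed above the Tm floor is returned unchanged
  strand <- paste0("AGCGTACGTTAGCCAGTT", random_seq(30, seed = 91))
  expect_equal(gc_content(substr(strand, 1, 18)), 0.5)
  sz <- size_binding_site(strand)
  if (sz$tm >= cfg$primers$tm_floor)
    expect_identical(nchar(sz$binding), 18L)
  # an AT-only terminus must extend beyond 18 bp
  at <- paste0(strrep("AT", 12), random_seq(20, seed = 92))
  sz_at <- size_binding_site(at)
  expect_gt(nchar(sz_at$binding), 18L)
  # a GC-only terminus may shrink below 18 while holding the floor
  gc <- paste0(strrep("GC", 12), random_seq(20, seed = 93))
  sz_gc <- size_binding_site(gc)
  expect_lt(nchar(sz_gc$binding), 18L)
  expect_gte(nchar(sz_gc$binding), 15L)
  expect_gte(sz_gc$tm, cfg$primers$tm_floor)
})

test_that("balance_tm minimizes |dTm| over the length grid and honors the 1 degC cap", {
  cfg <- default_config()
  fwd <- random_seq(60, seed = 94)
  pair <- structure(list(fragment_id = "x", fwd_strand = fwd,
                         rev_strand = fwd,  # identical strands
                         fwd_binding = substr(fwd, 1, 18),
                         rev_binding = substr(fwd, 1, 18),
                         fwd_tm = NA_real_, rev_tm = NA_real_),
                    class = "primer_pair")
  bal <- balance_tm(pair)
  expect_equal(bal$fwd_tm, bal$rev_tm)
  expect_identical(bal$fwd_binding, bal$rev_binding)
  # random strand pairs: result matches an exhaustive grid oracle
  set.seed(95)
  for (i in 1:10) {
    f <- random_seq(40); r <- random_seq(40)
    p <- structure(list(fragment_id = "y", fwd_strand = f, rev_strand = r,
                        fwd_binding = substr(f, 1, 18),
                        rev_binding = substr(r, 1, 18),
                        fwd_tm = NA_real_, rev_tm = NA_real_),
                   class = "primer_pair")
    b <- balance_tm(p)
    bounds <- 15:36  # configured binding-length range; strands are 40 nt
    grid_best <- min(outer(
      vapply(bounds, function(l) compute_tm(substr(f, 1, l)), numeric(1)),
      vapply(bounds, function(l) compute_tm(substr(r, 1, l)), numeric(1)),
      function(x, y) abs(x - y)))
    expect_equal(abs(b$fwd_tm - b$rev_tm), grid_best, tolerance = 1e-9)
    expect_lte(abs(b$fwd_tm - b$rev_tm), 1.0)
  }
})

test_that("adversarial AT-rich vs GC-rich pairs either balance or fail loudly", {
  at <- strrep("AT", 20); gc <- strrep("GC", 20)
  p <- structure(list(fragment_id = "z", fwd_strand = at, rev_strand = gc,
                      fwd_binding = substr(at, 1, 18),
                      rev_binding = substr(gc, 1, 18),
                      fwd_tm = NA_real_, rev_tm = NA_real_),
                 class = "primer_pair")
  res <- tryCatch(balance_tm(p), error = function(e) e)
  if (inherits(res, "error")) {
    expect_match(conditionMessage(res), "cannot balance")
  } else {
    expect_lte(abs(res$fwd_tm - res$rev_tm), 1.0)
  }
})

test_that("designed pairs share exactly the 24-bp junction homology between amplicons", {
  d <- designed_fixture(n = 5, gc = 0.5, seed = 7)
  pairs <- design_primers(d)
  amps <- vapply(seq_along(pairs), function(i)
    simulate_pcr(d$fragments[[i]]$sequence, pairs[[i]]), character(1))
  n <- length(amps)
  for (i in seq_len(n)) {
    nxt <- if (i == n) 1L else i + 1L
    tail24 <- substr(amps[i], nchar(amps[i]) - 23, nchar(amps[i]))
    head24 <- substr(amps[nxt], 1, 24)
    expect_identical(tail24, head24)
    expect_identical(tail24, d$junctions[[i]]$chosen_site$sequence24)
  }
  for (p in pairs) expect_lte(abs(p$fwd_tm - p$rev_tm), 1.0)
})

test_that("overhang lengths follow the window position geometry", {
  d <- designed_fixture(n = 5, gc = 0.5, seed = 7)
  pairs <- design_primers(d)
  n <- nchar(d$target_sequence)
  iv <- agodesign:::fragment_intervals(d)
  for (i in seq_along(pairs)) {
    up_j <- d$junctions[[if (i == 1) length(pairs) else i - 1]]
    off <- up_j$chosen_site$window_offset
    expected <- max(0L, 40L - off)
    expect_identical(nchar(pairs[[i]]$fwd_overhang), expected)
  }
})

test_that("small fragments are absorbed downstream across two PCR rounds", {
  linker <- random_seq(60, seed = 96)
  frags <- list(
    fragment("f1", random_seq(600, seed = 97), order_index = 0),
    fragment("lnk", linker, role = "linker", order_index = 1),
    fragment("f2", random_seq(600, seed = 98), order_index = 2))
  d <- plasmid_design("lk", frags)
  plan <- design_small_fragment(d, "lnk")
  expect_length(plan$design$fragments, 2)
  expect_length(plan$design$junctions, 2)   # one fewer junction
  # two-round tails reconstruct linker + neighbor exactly
  expect_identical(plan$rounds[[2]]$product,
                   paste0(linker, frags[[3]]$sequence))
  expect_identical(paste0(plan$rounds[[2]]$tail, plan$rounds[[1]]$tail),
                   linker)
  # merged design preserves the circular sequence
  expect_identical(rotate_to_canonical(plan$design$target_sequence),
                   rotate_to_canonical(d$target_sequence))
  # boundary cases: 79 bp accepted, 80 bp must use the standard path
  d79 <- plasmid_design("a", list(
    fragment("f1", random_seq(300, seed = 99), order_index = 0),
    fragment("lnk", random_seq(79), role = "linker", order_index = 1)))
  expect_silent(design_small_fragment(d79, "lnk"))
  d80 <- plasmid_design("b", list(
    fragment("f1", random_seq(300, seed = 100), order_index = 0),
    fragment("lnk", random_seq(80), role = "linker", order_index = 1)))
  expect_error(design_small_fragment(d80, "lnk"), "standard path")
})

test_that("primer order sheets carry full tailed sequences", {
  d <- designed_fixture(n = 5, gc = 0.5, seed = 7)
  pairs <- design_primers(d)
  sheet <- primer_order_sheet(d, pairs)
  expect_identical(nrow(sheet), 10L)
  expect_true(all(nchar(sheet$sequence) ==
                  sheet$binding_length + sheet$overhang_length))
})
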