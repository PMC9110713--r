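# Shared fixtures and independent brute-force oracles.

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# designed fixture with sites chosen, cached per parameter set
designed_fixture <- local({
  cache <- list()
  function(n = 5, gc = 0.5, seed = 7, sizes = c(800, 1500), repeats = 0) {
    key <- paste(n, gc, seed, sizes[1], sizes[2], repeats, sep = "_")
    if (is.null(cache[[key]])) {
      spec <- fixture_spec(n_fragments = n, size_range = sizes,
                           gc_target = gc, n_repeats = repeats,
                           repeat_length = 500, seed = seed)
      cache[[key]] <<- select_sites(generate_design(spec))
    }
    cache[[key]]
  }
})

# brute-force canonical rotation: materialize every rotation of the
# sequence and of its reverse complement, take the minimum
oracle_canonical <- function(s) {
  rots <- function(x) {
    n <- nchar(x)
    d <- paste0(x, x)
    vapply(seq_len(n), function(i) substr(d, i, i + n - 1L), character(1))
  }
  min(c(rots(s), rots(revcomp(s))))
}

# brute-force duplex score from first principles
oracle_duplex <- function(a, b, m) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  tot <- 0
  for (i in 1:12) tot <- tot + m[av[i], bv[12 - i + 1]]
  tot
}

# quadratic digest scanner: check every rotation start for each site
oracle_digest <- function(circ, enzymes, table) {
  n <- nchar(circ)
  expand <- function(iupac) {
    map <- Biostrings::IUPAC_CODE_MAP
    chars <- strsplit(iupac, "")[[1]]
    opts <- lapply(chars, function(c) strsplit(map[[c]], "")[[1]])
    apply(expand.grid(opts, stringsAsFactors = FALSE), 1, paste,
          collapse = "")
  }
  cuts <- integer(0)
  for (e in enzymes) {
    row <- table[table$name == e, ]
    slen <- nchar(row$site)
    pats_f <- expand(row$site)
    pats_r <- expand(revcomp(row$site))
    for (p0 in 0:(n - 1)) {
      w <- circ_sub_test(circ, p0, slen)
      if (w %in% pats_f) cuts <- c(cuts, (p0 + row$cut_top) %% n)
      if (w %in% pats_r) cuts <- c(cuts, (p0 + slen - row$cut_bottom) %% n)
    }
  }
  cuts <- sort(unique(cuts))
  if (!length(cuts)) return(integer(0))
  if (length(cuts) == 1) return(n)
  sort(diff(c(cuts, cuts[1] + n)))
}

circ_sub_test <- function(seq, from, len) {
  n <- nchar(seq)
  from <- from %% n
  if (from + len <= n) substr(seq, from + 1, from + len)
  else paste0(substr(seq, from + 1, n), substr(seq, 1, from + len - n))
}
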