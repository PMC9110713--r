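# agodesign

Design toolkit for multi-fragment plasmid assembly with PfAgo-based
artificial restriction enzymes (AREs).

*Pyrococcus furiosus* Argonaute (PfAgo) loaded with a pair of 16-nt
single-stranded DNA guides cleaves a programmable 24-bp recognition
sequence, leaving 12-nt 5′ sticky ends. Because the recognition sequence is
set by the guides rather than by a fixed enzyme site, any junction between
two DNA fragments can be turned into a ligation-ready sticky end — but only
if the guides digest efficiently and the resulting overhangs ligate
uniquely. `agodesign` automates that design problem for scientists building
plasmids from an ordered set of fragments, and for biofoundry operators who
need the downstream paperwork (primers, verification digests, robot
worklists) generated consistently.

## What it computes

For a circular design of *n* fragments (one junction per adjacent pair,
including the wrap-around):

1. **Recognition sites** — each junction's guide search space is the 80-nt
   window joining 40 bp from the ends of the adjoining fragments, giving 57
   candidate 24-bp recognition sequences. Candidates are screened
   center-outward by digestion filters: GC content within [0, 0.75],
   no G-quadruplex motif `G{3,}(N{1-7}G{3,}){3}` on either strand, no run of
   more than 4 consecutive A's or T's, and off-target uniqueness of the
   cut-defining 12-mers across both strands of the whole design. The two
   16-nt guides are placed so the strand cuts fall after window positions 6
   (top) and 18 (bottom), leaving the central 12-mer as the 5′ overhang.
2. **Sticky-end orthogonality** — overhangs are scored pairwise under a
   ligase mismatch-fidelity model (position-wise sum, Watson–Crick = 1,
   wobble = 0.3, other mismatches = 0.05): a set passes iff no end is
   palindromic, no cognate pair is reused, and every non-cognate pairing
   scores below 8 of 12.
3. **Primers** — each fragment's amplicon carries the full 24-bp
   recognition sequence at both termini via 5′ tails, so adjacent amplicons
   share exactly 24 bp of homology. Binding regions start at 18 nt, are
   resized by GC rules, and forward/reverse melting temperatures are
   balanced to within 1 °C using a nearest-neighbor Tm model
   (SantaLucia 1998 unified parameters with salt correction). Fragments
   under 80 bp are absorbed into a neighbor through a two-round
   extended-primer workflow.
4. **Verification digests** — single and double restriction digests of the
   assembled circle are screened so that the smallest predicted band is
   ≥ 100 bp, the largest ≤ 9500 bp, and adjacent bands differ by at least
   0.1 × band size; batches get a common-enzyme intersection, and observed
   electrophoresis bands are matched to predictions within 10 %.
5. **Assembly simulation** — in-silico PCR, digestion, and ligation prove
   each design scarless: the unique circular product must equal the target
   sequence exactly (up to rotation). Threshold-mode ligation enumerates
   predicted misassemblies.
6. **Worklists** — acoustic/tip liquid-handler picklists for oligo
   hydration, PCR setup (92 reactions per 96-well plate, ladder wells
   A1/H12 reserved), equimolar fragment pooling (mass ∝ length), and
   failed-PCR consolidation.

A seeded fixture generator (`fixture_spec()` / `generate_design()`)
produces synthetic designs with controlled fragment counts, sizes, GC
content, and planted repeats, so the whole pipeline is testable offline.

## Worked example

```r
library(agodesign)

spec   <- fixture_spec(n_fragments = 5, size_range = c(800, 1500),
                       gc_target = 0.5, seed = 7)
design <- select_sites(generate_design(spec))
design
#> <plasmid_design> fixture_n5_gc50_s7
#>   fragments: 5  target: 4784 bp (circular)
#>   [0] f01  903 bp  (backbone)
#>   [1] f02  907 bp  (insert)
#>   [2] f03  1343 bp  (insert)
#>   [3] f04  813 bp  (insert)
#>   [4] f05  818 bp  (insert)
#>   junctions: 5 (5 with chosen recognition sites)

site <- design$junctions[[1]]$chosen_site
site[c("sequence24", "guide_top", "guide_bottom", "sticky_end")]
#> $sequence24   "TCTCGCGCCCCCTCCTGGCGTAGG"
#> $guide_top    "AGGAGGGGGCGCGAGA"
#> $guide_bottom "CCCCTCCTGGCGTAGG"
#> $sticky_end   "GCCCCCTCCTGG"

pairs <- design_primers(design)
max(sapply(pairs, function(p) abs(p$fwd_tm - p$rev_tm)))
#> [1] 0.1349831           # every pair balanced well inside 1 degC

round_trip_check(design, pairs)[c("pass", "n_products")]
#> $pass TRUE  $n_products 1   # simulated assembly is scarless

plans <- Filter(function(p) p$accepted,
                select_combinations(design$target_sequence))
plans[[1]][c("enzymes", "predicted_bands")]
#> $enzymes "StuI" "BspEI"
#> $predicted_bands 229 508 1149 2898
```

The chosen recognition sequence is the 24-bp window nearest the fragment
boundary that passed every digestion filter; its central 12-mer
(`GCCCCCTCCTGG`) becomes the junction's sticky end. The digest plan means a
StuI+BspEI double digest of a correct clone shows four bands, every band
between 100 and 9500 bp and each adjacent pair separated by more than 10 %.

A shell front end with the same surface is installed as `exec/agodesign`
(subcommands `fixture`, `load`, `design`, `check-ends`, `primers`,
`verify-plan`, `match-bands`, `simulate`).

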