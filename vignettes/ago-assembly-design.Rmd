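---
title: "Designing PfAgo/ARE plasmid assemblies with agodesign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing PfAgo/ARE plasmid assemblies with agodesign}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agodesign)
```

## The design problem

PfAgo loaded with two 16-nt DNA guides behaves as an artificial restriction
enzyme: the guides jointly address a 24-bp duplex window and direct one cut
on each strand. With the cuts staggered by 12 bp, digestion leaves a 12-nt
5′ overhang, and two DNA molecules whose termini carry the same 24-bp
window ligate seamlessly — the overhang and its complement reconstitute the
original sequence, so the junction is scarless by construction.

A multi-fragment circular assembly therefore needs, per junction, one
24-bp recognition sequence such that (i) PfAgo digests it efficiently,
(ii) its sticky end ligates only with its cognate partner, and (iii) the
PCR primers that install the shared windows on the amplicons are
practical. `agodesign` treats these as sequential, greedy decisions per
junction, which keeps the search deterministic and the failure reports
attributable to a specific junction and filter.

## Data model and conventions

Fragments are the raw abutting parts: the circular target is their
in-order concatenation, and the 24-bp junction homology is *not* part of
the fragments — it is installed by primer tails once sites are chosen.
All coordinates are 0-based, half-open, on the top strand; circular
positions are reduced modulo plasmid length. GenBank or FASTA files plus a
manifest TSV (`fragment_id`, `file`, `role`, `order_index`, `template_id`)
define a design; a seeded generator builds synthetic ones.

## Recognition-site selection

Each junction's search space joins 40 bp from the ends of the adjoining
fragments (80 nt, hence 57 sliding 24-bp candidates). Candidates are
scanned **center-outward** from the fragment boundary (offsets 28, 27, 29,
26, 30, …): the ordering is a package choice — it keeps the chosen window
near the natural junction so primer tails stay short (12 nt each at the
central offset), and it makes "first passing window wins" deterministic.

Digestion filters, in order, with defaults and units:

* **GC content** of the window within [0, 0.75]. The upper bound reflects
  the efficient-cleavage range of the WT + mutant enzyme pair; windows
  around 80 % GC digest poorly. Both bounds are config-exposed.
* **G-quadruplex**: the minimal motif `G{3,}(N{1,7}G{3,}){3}` on either
  strand. The criterion names the structure, not a thermodynamic model;
  run length and loop bounds are configurable.
* **Homopolymer runs**: a run of more than 4 consecutive A's, or more than
  4 consecutive T's, fails; exactly 4 passes. A-runs and T-runs are
  screened separately (a literal reading of the rule; mixed A/T runs pass).
* **Off-target uniqueness** (k = 12): the three cut-defining 12-mers of the
  window (the future sticky end and each guide's cut-spanning 12-mer) must
  occur, on either strand of the indexed library (circular target plus all
  PCR templates), only at the intended locus. k equals the overhang length
  because the overhang is the functional unit a stray complement could
  hijack; the index deliberately excludes host genome sequence.

The enzyme suggestion is a coarse GC policy: mutant-only (PfAgo*) when any
fragment reaches 65 % GC, otherwise the WT + mutant one-pot mix, with a
per-junction annotation (WT-preferred at window GC ≤ 10 %,
mutant-preferred at ≥ 50 %). The cutoffs digitize qualitative activity
trends and are all configurable.

**Cut geometry.** Guides are placed so the scissile bond faces guide
position 10/11: the top-strand guide is the reverse complement of window
bases 1–16 (cut after position 6), the bottom-strand guide reads window
bases 9–24 (cut after position 18). The geometry is validated by a
round-trip invariant — simulated digestion of any site-bearing amplicon
must reproduce the declared sticky end — rather than asserted from
literature; any consistent geometry satisfying that invariant yields
identical assemblies.

## Ligation fidelity

Sticky ends are screened with a position-wise, ungapped duplex score from
a 4×4 pairing-weight table (cognate pair = 12 by construction). The
packaged table (Watson–Crick = 1, G·T/T·G = 0.3, other mismatches = 0.05,
threshold 8.0) is a **synthetic stand-in** with the qualitative shape of a
thermostable high-fidelity ligase profile: the measured profile of the
ligase is not public in a reusable form, so the table ships as a TSV the
user can replace, and the threshold is explicitly a placeholder default.
Scoring is in-register only; out-of-register annealing is excluded
separately by the off-target 12-mer uniqueness rule.

A set of ends passes when no end is palindromic (a palindrome self-ligates),
no cognate pair is reused, and every non-cognate pairing — including an
end against itself and against every earlier end, in both orientations —
scores below threshold. During site selection this check runs greedily
against previously finalized ends; `orthogonality_check()` re-validates a
finished set globally.

## Primer design

Binding regions start from the terminal 18 bp of the annealing strand:
below 40 % GC they extend one base at a time until the melting temperature
reaches the floor; above 60 % GC they may shrink while holding it. The
pair is then balanced by exhaustive search over both binding lengths,
minimizing |ΔTm| with deterministic tie-breaks (smallest length change,
then higher minimum Tm), and must end within 1 °C — an explicit error
otherwise, never a silent violation.

Tm is computed with the unified nearest-neighbor ΔH/ΔS set
(SantaLucia 1998), duplex-initiation terms, the entropic salt correction
`0.368·(N−1)·ln[Na+]eff` with divalents converted by
`[Na+]eff = [Na+] + 120·√([Mg²⁺] − [dNTP])` (mM), and a primer-in-excess
strand-concentration term (defaults: 50 mM monovalent, 1.5 mM Mg²⁺,
0.6 mM dNTP, 50 nM primer). Tails are excluded from Tm, matching practice
for tailed primers. Defaults chosen as package policy, config-exposed:
Tm floor 58 °C; binding-length bounds **[15, 36]** — the upper bound sits
at the usual hard cap of the short-oligo NN regime because a fragment pair
with one GC-rich and one AT-rich terminus can be unbalanceable within 30 nt
while balancing cleanly by 33–36 nt; GC branch thresholds 0.40/0.60.

Fragments under 80 bp (linkers, short promoters) cannot host a junction on
each side; they are absorbed into the downstream neighbor (deterministic
default, manifest-overridable) via two PCR rounds: round 1's tail installs
the linker-proximal half, round 2 completes it using round 1 as template.
The design is rebuilt with the merged fragment, dropping one junction.

## Verification digests

Predicted digests place every recognition site of each enzyme (IUPAC
expanded, both strands) on the circle and take inter-cut distances. Single
and double digests are screened against three criteria: smallest band
≥ 100 bp, largest ≤ 9500 bp, and adjacent bands separated by at least
0.1 × band size — with "band size" read as the **larger** band of the pair,
the conservative reading (a config flag switches to the smaller).
Combinations are capped at two enzymes. Accepted plans rank by band count,
then by minimum gap ratio. The shipped enzyme table (~35 common
6/8-cutters) is a replaceable stand-in; nicking and methylation
sensitivity are not modeled. Band matching is greedy one-to-one in sorted
order within a 10 % relative tolerance, ignoring observed peaks at or
below a 50-bp noise floor.

## Assembly simulation

PCR is exact string extraction (no polymerase error model); digestion
applies the cut geometry at each site-bearing terminus, conserving every
nucleotide across retained duplex, overhangs, and released oligos;
ligation joins a right overhang to a left overhang when they are exact
reverse complements (`strict_wc`) or when their duplex score reaches the
threshold (`threshold` mode, for misassembly prediction). Circular
products are enumerated by DFS over the join graph with each fragment used
at most once and no concatemers — the combinatorial envelope the fidelity
screen is meant to exclude, not an exhaustive polymer model. Fragment
orientation is fixed: with directional 5′ overhangs, a flipped fragment
would need both its ends' reverse complements to find partners, which the
orthogonality screen already rejects.

`round_trip_check()` is the package's definition of success: one circular
product whose canonical rotation (lexicographically smallest rotation of
the sequence or its reverse complement) equals the target's. A corrupted
amplicon terminus fails the round trip with the digestion refusal recorded
instead of aborting. Released 12-mer re-ligation is not simulated, but a
released oligo carrying another junction's overhang sequence is flagged as
a cross-talk risk.

## The fixture generator

Synthetic designs emulate the realistic job envelope: 3–11 fragments,
fragment sizes from a few hundred bp to a few kb, GC targets up to ~0.77,
and optionally several identical planted repeats (the same promoter reused
across expression cassettes, e.g. four 500-bp copies). Bases are sampled
i.i.d. with p(G) = p(C) = GC/2 under a ±3-percentage-point rejection loop
(simple and seed-stable); repeats are planted internally, never within
40 bp of a fragment end, so the guide search space is repeat-free by
construction — mirroring the claim that ARE-based design tolerates internal
repeats because junctions, not fragment bodies, host the recognition
sites. One integer seed drives a named sub-stream per component, so adding
a component does not perturb the others. What the fixtures do *not*
emulate: real promoter/gene composition, compositional skew, methylation,
or hard-to-amplify structures; passing tests demonstrate the design
algebra, not wet-lab success rates.

## Numerical and degenerate-input choices

* Candidate count is L − 23 for any search space of length L ≥ 24; shorter
  inputs are an error, not a silent empty result.
* A single-fragment design has one wrap-around junction joining its tail
  to its head; all junction arithmetic is modular.
* `balance_tm` ties break deterministically; reruns of any stage on the
  same inputs are byte-identical.
* Digest conservation (bands sum to plasmid length) is asserted on every
  call, not only in tests.
* Equimolar pooling uses 657 g·mol⁻¹·bp⁻¹ for dsDNA; transfers below the
  2.5-nL droplet granularity are errors, sub-3-µL transfers route to the
  acoustic dispenser, and 96-well PCR plates hold at most 92 reactions
  with A1/H12 reserved for ladders (column-major fill — a package choice;
  the instrument does not care).

## Problem sizes used in the shipped tests

The test suite runs fixtures of 3–11 fragments with fragment sizes
600–1500 bp (plasmids roughly 2–12 kb), GC targets 0.35–0.75, one
repeat-bearing design (4 × 500 bp), 100 random digest circles, and 10,000
random sticky-end pairs — sizes chosen so the full suite documents the
design space broadly while staying quick to run on a laptop.

## Known limitations

* No thermodynamic model of PfAgo cleavage efficiency and no
  position-dependent base-preference scoring; filters are pass/fail rules.
* The fidelity table is a shaped placeholder until a measured ligase
  profile is substituted; the ligation threshold has no published value.
* Off-target indexing covers the design and its templates, not a host
  genome.
* No primer-dimer or secondary-structure screening.
* Overhang length is fixed at 12 nt; alternative overhang sizes are out of
  scope.
* Observed-band input is sized peaks; no electropherogram processing.
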