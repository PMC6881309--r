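---
title: "Models and design choices behind pstwalk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices behind pstwalk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pstwalk)
```

# The method in brief

Palindromic sequence-targeted PCR walks from a known sequence into unknown
flanking DNA. The walking (PST) primer is `adapter (19 nt) + dN10 + 6-nt
palindrome`, read 5′ to 3′. The palindrome is a restriction-enzyme
recognition site; because a DNA palindrome equals its own reverse
complement, the primer can anchor at such a site on either strand, with
the fully degenerate block pairing whichever flank faces the
sequence-specific primer (SSP). Round 1 pairs one SSP with one PST primer;
round 2 re-amplifies with the same or a nested SSP plus a tail primer
identical to the adapter. This package implements the computational side:
primer construction and auditing, site scanning and spacing statistics,
and exact virtual amplification.

# Coordinate and sequence conventions

Sequences are validated against the 15-letter IUPAC alphabet; lower-case
(soft-masked) input is uppercased without tracking masking, and U is
silently mapped to T on ingest (parts of the bundled SSP catalog derive
from mRNA references). Internally all coordinates are 0-based half-open;
user-facing tables (GRanges, TSV reports) are 1-based inclusive, and BED
export shifts back automatically. This split mirrors common practice in
range arithmetic and avoids off-by-one errors at interval ends.

Palindromy is defined only on unambiguous sequences: a degenerate pattern
denotes a pool of molecules, some of which would not be palindromic, so
`isPalindrome()` refuses degenerate input rather than guessing.

# Sequence metrics

**GC content** (`gcPercent()`) weights each IUPAC code by its expected G+C
fraction under equimolar synthesis: 1 for G/C/S, 0 for A/T/W, 0.5 for
R/Y/K/M/N, 2/3 for B/V, 1/3 for D/H. This convention is what makes the
catalog's printed values reproducible: a dN10 + GACGTC core gives
(10 × 0.5 + 4)/16 = 56.25 → 56.3, and the S in SSP 5315 must count 1.0 to
give its printed 50.0. Report columns round half-up to one decimal, the
convention evidently used in the original tables (plain IEEE rounding
would print 56.2).

**Linguistic complexity** (`linguisticComplexity()`) is the vocabulary
ratio: distinct k-mers observed, summed over k = 1..`max_word`, divided by
the maximum attainable `min(4^k, L - k + 1)`. The default `max_word = 2`
is a reverse-engineered choice: it is the unique small word range that
reproduces every printed catalog value, e.g. ATCGAT has 4 distinct 1-mers
and 4 distinct 2-mers out of 4 + 5, i.e. 88.9 → 89, while GGATCC scores
9/9 = 100. A full-catalog regression test pins all 25 values (the four
89-scoring palindromes are ATCGAT, GATATC, GCTAGC, GCATGC).

**Melting temperature** (`meltingTemperature()`) uses the unified
nearest-neighbor duplex parameters (stack ΔH/ΔS plus terminal initiation
terms), an entropic salt correction of 0.368 × (N−1) × ln[monovalent]
cal mol⁻¹ K⁻¹, the square-root equivalence folding Mg²⁺ into the
effective monovalent concentration (adding 120√(mM Mg) mM), and the
bimolecular term R ln(C_T/4) with C_T the primer concentration. Two
presets carry the reaction conditions the catalog states:
`PST_CONDITIONS` (50 mM monovalent, 2 mM Mg²⁺, 0.5 µM primer) and
`SSP_CONDITIONS` (50 mM, no Mg²⁺, 0.25 µM). Degenerate positions
contribute the arithmetic mean of the stack parameters over their allowed
realizations — the mean-behaviour reading of an equimolar pool; extremes
would instead describe the most or least stable species.

A known limitation, stated plainly: the catalog's printed Tm column comes
from a proprietary calculator and is *not* reproduced by any standard open
parameterization. For the tail primer (19 nt, 68% GC, 50 mM monovalent,
0.25 µM) the printed value is 69.1 °C while this package computes
60.1 °C and other open NN implementations give 62–64 °C depending on salt
correction and concentration-term conventions. The printed Tm (and the
tail primer's printed 68.1% GC, which is not 13/19) are therefore carried
in the catalog as `printed_*` reference columns but never asserted; tests
check model properties instead (duplex symmetry, GC monotonicity, exact
agreement with an independently hand-summed evaluation of the same
parameter set).

**Hairpin and dimer screens** are combinatorial, not free-energy
minimization: the method uses them qualitatively (a 3′-terminal hairpin or
an extensible dimer is "unfavorable"), and a run-enumeration screen is
exactly checkable by brute force. `hairpinScreen()` reports maximal
antiparallel self-complementary stems of ≥ `min_stem` pairs enclosing a
loop of ≥ `min_loop` bases; `dimerScreen()` reports maximal ungapped
antiparallel runs between two primers. Stability is a simple pair-weight
sum (G:C = 3, A:T = 2); degenerate positions never pair, which makes the
screens conservative for the dN block. Every catalog PST primer
self-dimerizes at its 3′-terminal palindrome — by construction, since the
palindrome pairs with itself — which is why the protocol recommends a hot
start; the screens surface this as a flagged report rather than a
failure. One point where intuition misleads: alternating AT runs *do*
form stems (ATAT is its own reverse complement), and the screen reports
them; only sequences with no spaced self-complementarity, such as
homopolymers, are stem-free.

# Primer validation rules

`validateSsp()` encodes the published SSP selection rules: length
25–35 nt, weighted GC 40–60%, Tm ≥ 65 °C, no self-dimer run involving the
3′ terminus, and (when a nested parent is declared) no overlap with the
parent. Verdicts are returned as data, never thrown: the bundled catalog
itself violates some of its own rules (SSPs 5410, 5412 and 5445 are 39,
36 and 23 nt; 5411 is 60.7% GC; several printed Tm values sit below
65 °C under the catalog's own stated conditions). The Tm and overlap
rules are marked advisory for this reason; regression tests assert that
the deviations are exactly the documented ones, so a catalog edit cannot
silently change what passes. `validatePstPrimer()` checks the palindrome
GC band 33.3–66.7% (inclusive, admitting the 2/6 and 4/6 compositions
that make up the whole catalog), reports palindrome LC, and screens the
adapter against the core for 3′-terminal complementarity.

The catalog is stored as plain TSV under `inst/extdata/` rather than code
constants, so it can be audited line by line; `loadCatalog()` rebuilds
every primer through `buildPstPrimer()` and fails loudly on any
inconsistency (wrong row count, non-palindromic 3′ block, adapter/tail
mismatch).

# Site scanning and the spacing model

`scanPstSites()` matches the exact motif on the plus strand only —
exhaustive for palindromes — counts overlapping occurrences, and never
matches across N (assembly gaps must not create phantom sites). Pooled
genome reports never compute a gap across record boundaries; distances
between scaffolds are meaningless.

The analytic model treats the genome as i.i.d. bases with
P(G) = P(C) = g/2: a motif with k G/C bases among n hits any position with
probability (g/2)^k((1−g)/2)^(n−k), mean inter-site distance 1/p, and
expected product length 1/(2p) — half the mean gap, because an SSP lands
uniformly between two sites. At g = 0.5 every 6-mer gives 4096 bp and
every 8-mer 65536 bp; 8-nt palindromes run through the same machinery with
no special casing. Real genomes are not i.i.d. (isochores, repeats, CpG
depletion), so the model is a planning heuristic, not a claim about any
particular genome; the package's tests verify convergence only on
synthetic i.i.d. sequence, within three standard errors of the mean gap.

# Virtual PCR geometry

An SSP annealing site is accepted when the primer matches with at most
`sspMaxMismatches` mismatches (default 0) *and* its 3′-terminal
`sspSeedLen` bases (default 3) match perfectly — a mismatched 3′ terminus
is not extensible. Degenerate SSP codes match by IUPAC containment;
footprints overlapping N never anneal. The defaults are deliberately
conservative: the method gives no quantitative mismatch model, and
exact-match predictions are the ones an independent string-level
simulator can certify.

The PST primer is modeled as annealing *only* at palindromic sites: the
recommended high annealing temperatures are the method's central
specificity mechanism, so off-site annealing is deliberately out of
model. At a site starting at p, the "−" orientation (degenerate block
pairing the right flank, footprint `[p, p + 6 + 10)`) extends leftward;
the "+" orientation mirrors it. An orientation is feasible only when its
flank lies inside the template and is N-free. For a forward SSP with 5′
coordinate s and a site at p, the round-2 product is
`(p + 16 − s) + 19` bp; with a nested round-2 SSP the length is
recomputed from the nested site nearest the outer SSP, and outer sites
whose product contains no nested site yield nothing. Products are
filtered to the amplifiable window (defaults 100–3000 bp, the practical
polymerase range); round 1 must also not exceed the upper bound.
Amplicons are deduplicated by (SSP site, PST site, orientation), and
nested sites inside a longer product still emit their own shorter
predictions — all co-occur in a real reaction. PST–PST side products
(site pairs with facing feasible orientations within range) are
enumerated only on request and flagged, never scored: their suppression
in practice is kinetic and unquantified.

Thermal-profile constants (cycle counts, temperatures, the 1/6 dilution)
are carried as metadata in CLI output headers only; no yield or kinetic
model is attempted.

# The synthetic-data generator

`generateGenome()` draws i.i.d. bases at a stated GC content from a
seeded generator, writes implants at fixed coordinates, then destroys
every background occurrence of an implanted (or explicitly forbidden)
motif by resampling a base outside any implant footprint. Ground truth is
therefore exhaustive, enabling equality assertions instead of tolerances;
the `forbidden` list extends this guarantee to whole-catalog screens.
`generatePopulation()` emulates fingerprinting across accessions: one
indel per variant between the SSP and PST implants (with junction hits
purged the same way), so product-length differences equal the implanted
indel sizes exactly, and optionally a deleted site yielding no product.
What the generator does *not* emulate: repeat structure, compositional
heterogeneity, sequencing error. Passing tests certify the geometry and
bookkeeping of the method on clean templates, not performance on real
genomes.

Problem sizes used by the test suite — 200 random 1.2-kb virtual-PCR
fixtures against the string-extension oracle, a 1-Mb spacing fixture,
20-kb purge fixtures — were chosen as the smallest sizes at which the
statistical checks have comfortable power.

# Numerical and degenerate-input choices

* Rounding for report columns is half-up (one decimal for Tm/GC, integer
  for LC), matching the printed catalog; raw values are returned
  unrounded.
* `spacingStats()` on fewer than two sites reports NA means rather than
  erroring; `analyticSpacing()` at the GC boundaries reports NA when the
  motif requires the absent base class.
* Empty hairpin/dimer screens return zero-row frames, not errors.
* Ties in the walk table are broken deterministically
  (ssp id, pst id, record, round-2 length, coordinate), shortest products
  first within a combination — the order gel bands would be read.

# Open choices resolved here

Two ambiguities in the source material were resolved as follows. The SSP
design conditions are quoted once as 0.25 µM primer and once as 25 µM — a
hundredfold discrepancy; both presets are constructible via
`ionicConditions()`, `SSP_CONDITIONS` carries the 0.25 µM reading (the
one attached to the printed tables), and no correctness claim hangs on
either. Whether the published "no self-dimers" SSP rule means a ΔG
threshold or a run-length rule is unstated; the run-length screen is the
implemented proxy, consistent with the combinatorial treatment used for
hairpins. The prose also mentions 30 PST primers where the catalog table
lists 25; the package follows the table.

# Known limitations

* Tm values are model-consistent, not calculator-compatible (see above);
  comparisons against the printed column are advisory at best.
* The i.i.d. spacing model ignores composition structure of real
  genomes; published mean-distance ranges for real assemblies are not
  asserted.
* The annealing model is exact-match-with-seed; weak or mismatched
  annealing, primer titration and competition between products are out of
  scope, as is any gel-intensity simulation.
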