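# pstwalk

Primer design, genome scanning and virtual amplification for **palindromic
sequence-targeted PCR (PST-PCR)**, a rapid genome-walking method.

## The problem and the method

Genome walking captures unknown DNA adjacent to a region whose sequence is
known. PST-PCR does this with a distinctive *walking primer* (a **PST
primer**) built, 5′ to 3′, from three blocks:

    5'-[ adapter, 19 nt, invariant ]-[ dN x 10 ]-[ 6-nt palindrome ]-3'

The 3′-terminal block is a short DNA palindrome — a restriction-enzyme
recognition site such as GGATCC (BamHI) — which reads identically on both
strands and is scattered arbitrarily-but-predictably through any genome
(**PST sites**). The fully degenerate block lets the primer pair with
whatever flanks a site, and the adapter provides a defined handle. The
degenerate block plus the palindrome is the **core**, the only part that
base-pairs with template.

A walk is a two-round PCR. Round 1 pairs one sequence-specific primer
(**SSP**) annealing in the known region with one PST primer anchoring at a
palindromic site in the unknown region; round 2 re-amplifies with the same
(or a nested) SSP plus a **tail primer** identical to the 19-nt adapter.
Because the tail has the same length as the adapter it replaces, round-1
and round-2 products have equal length unless a nested SSP shortens them.

For an SSP whose 5′ end sits at template coordinate *s* (extending
rightward) and a palindromic site starting at *p*, the predicted
second-round product length is

    len = (p + |palindrome| + |dN block| - s) + |tail|

The expected product length on an unknown genome follows from site spacing:
under an i.i.d. base model with GC content *g*, a motif with *k* G/C and
*m* A/T bases occurs with per-position probability *P* = (g/2)^k ((1−g)/2)^m,
the mean inter-site distance is 1/*P* (4096 bp for any 6-mer at *g* = 0.5),
and the expected product is half that, truncated in practice to the
amplifiable window of roughly 100 bp – 3 kb.

## What the package provides

* `loadCatalog()` — the bundled primer catalog: 25 PST primers
  (ids 5601–5623, 5326, 5327; one per restriction site), the universal
  tail primer 5600, and 12 SSPs targeting the *VRN1* gene of *Poaceae*.
* `gcPercent()`, `meltingTemperature()`, `linguisticComplexity()`,
  `hairpinScreen()`, `dimerScreen()` — the sequence metrics used to design
  and audit primers, with IUPAC degenerate codes handled throughout
  (`validatePstPrimer()`, `validateSsp()` apply the published rules).
* `scanPstSites()`, `spacingStats()`, `analyticSpacing()`,
  `genomeReport()` — genome-wide palindromic-site scanning with spacing
  statistics, BED export and the analytic i.i.d. model.
* `findSspSites()`, `findPstAnneal()`, `predictAmplicons()`,
  `enumerateSideProducts()`, `runWalk()` — virtual two-round PST-PCR on
  arbitrary templates, including the Cartesian SSP × PST screen and
  PST–PST side-product flagging.
* `fixtureSpec()`, `generateGenome()`, `generatePopulation()` — seeded
  synthetic templates with exhaustive ground truth (background occurrences
  of implanted motifs are destroyed, so scanners and the virtual PCR can
  be checked exactly).
* `inst/scripts/pstwalk` — a command-line front end with subcommands
  `scan`, `design`, `virtual-pcr` and `fixture`.

## Worked example

Predict the walk product for SSP 5315 paired with PST primer 5605 (BamHI)
on a template carrying the SSP site at position 100 and a GGATCC site at
position 600 (0-based):

```r
library(pstwalk)
cat <- loadCatalog()

tpl <- paste(rep(c("A", "C"), length.out = 1000), collapse = "")
ins <- function(tpl, s, at)
    paste0(substr(tpl, 1, at), s, substr(tpl, at + nchar(s) + 1, nchar(tpl)))
tpl <- ins(tpl, "CTGAAGCGGATCGAGAACAAGATCAACC", 100)  # 5315, S realized as G
tpl <- ins(tpl, "GGATCC", 600)

predictAmplicons(tpl, cat$ssp[["5315"]], cat$pst[["5605"]])
```

```
 ssp_id pst_id   record start end strand orientation site_pos round1_len_bp
   5315   5605 template   100 616      + SSP-forward      600           535
 round2_len_bp side_product
           535        FALSE
```

The product spans template 100–616 (SSP footprint through the far edge of
the PST core) and the 535-bp length is (600 − 100) + 6 + 10 + 19: template
distance, palindrome, degenerate block, tail. Round-1 and round-2 lengths
coincide because the tail replaces the equally long adapter.

The catalog metrics report mirrors a primer-design table (Tm from the
open nearest-neighbor model; GC% weights degenerate positions, so each
core N contributes 0.5; LC is the k ≤ 2 vocabulary ratio of the
palindrome):

```r
head(primerMetricsTable(cat), 4)
```

```
   id                            sequence palindrome enzyme Tm_C GC_pct LC_pct
 5600                 GTTGCGGCAGGTCCTCACC       <NA>   <NA> 60.1   68.4     80
 5601 GTTGCGGCAGGTCCTCACCNNNNNNNNNNGACGTC     GACGTC  AatII 57.3   56.3    100
 5602 GTTGCGGCAGGTCCTCACCNNNNNNNNNNAACGTT     AACGTT   AclI 54.4   43.8    100
 5603 GTTGCGGCAGGTCCTCACCNNNNNNNNNNTTCGAA     TTCGAA  AsuII 53.8   43.8    100
```

And the spacing model for an EcoRI-site walk on a GC-neutral genome:

```r
analyticSpacing(0.5, "GAATTC")
```

```
  motif sequence_id n_sites sequence_length mean_distance_bp density_per_kb
 GAATTC        <NA>      NA              NA             4096      0.2441406
 expected_product_bp
                2048
```

From a shell, the same machinery:

```sh
inst/scripts/pstwalk fixture --length 10000 --gc 0.5 --seed 7 \
    --implant site:GGATCC:600 --fasta g.fa --truth g.tsv
inst/scripts/pstwalk scan --fasta g.fa --motifs GGATCC --bed sites.bed \
    --stats stats.tsv
inst/scripts/pstwalk virtual-pcr --template g.fa --ssp 5315 --pst all \
    --out amplicons.tsv --products products.fa
```

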