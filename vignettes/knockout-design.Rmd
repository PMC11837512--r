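---
title: "Designing knockout guides for cytosine base editors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing knockout guides for cytosine base editors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bestop)
```

## The editing model

A cytosine base editor (CBE) is a Cas9 nickase fused to a cytidine
deaminase. Guided by a 20-nt spacer to a protospacer adjacent to an NGG PAM,
the deaminase converts cytosines on the displaced strand to uracil; repair
and replication resolve the lesion to a net C:G → T:A substitution, without
a double-strand break or donor DNA. Deamination is efficient only inside a
short window at the PAM-distal end of the protospacer.

`bestop` uses the field's protospacer numbering throughout: the NGG PAM
occupies positions 0–2 and the spacer runs from −20 (5′, PAM-distal) to −1
(PAM-proximal). Two window models are provided:

* **canonical** — positions −20…−16, the classical ~5-bp Target-AID window
  (the default, and the window used for genome-wide summaries);
* **extended** — positions −20…−13. Editing at −15/−14 is still efficient
  and −13 is edited at markedly lower efficiency, so the extension trades
  guide-count for per-guide confidence. We treat window membership as
  binary; per-position efficiency weighting is out of scope.

## From edits to premature stop codons

Applied inside a protein-coding gene, C→T edits can convert sense codons
into stop codons. Enumerating all 64 codons, both strands and every edit
subset (`pre_stop_codons()`) closes the rule set at exactly four codons:

| codon | edit strand | edits (offset) | stop |
|-------|-------------|----------------|------|
| CGA (Arg) | coding | C at 0 | TGA |
| CAG (Gln) | coding | C at 0 | TAG |
| CAA (Gln) | coding | C at 0 | TAA |
| TGG (Trp) | template | one or both Cs of the CCA | TGA, TAG or TAA |

The designer (`design_guides()`) does not apply this table blindly: each
candidate (site, gene) pair is classified by mapping every window cytosine
onto the gene's reading frame (0-based half-open coordinates internally;
conversion only at the GFF3/BED boundary), assembling codons across CDS
segment junctions in translation order, and checking which permitted edit
subsets produce a stop upstream of the gene's first native stop. A stop at
any earlier codon counts as inactivating, including the penultimate codon;
an optional `max_relative_position` filter is available but off by default,
because genome-wide data show inactivating codons distributed across the
whole coding region.

### Edit policies

The published rule "either one or both Cs" motivates two policies:

* `any-subset` (default): a guide qualifies if *some* non-empty subset of
  its window edits creates a premature stop; the minimal subset is recorded.
* `all-window-cs`: every window cytosine is assumed co-edited (consistent
  with the observed >80% co-conversion of neighbouring window Cs), and the
  guide qualifies if the fully edited sequence carries a premature stop.

A useful property falls out of the chemistry: the two policies classify
identically. A created stop codon (TAA/TAG/TGA) contains no coding-strand C,
so coding-strand co-edits cannot touch it; template-strand co-edits inside a
created stop map TGA→TAA and TAG→TAA, which are still stops. Co-edits can
therefore change *which* stop is recorded, but never destroy qualification.
We implement both policies literally and test their equivalence as a
property rather than assuming it.

### Uniqueness

Published genome-wide counts are phrased in terms of *unique* gRNAs without
an explicit off-target metric. We adopt the minimal defensible reading: a
guide is unique when its exact 20-nt spacer immediately 5′ of an NGG occurs
exactly once in the genome, counting both strands. This is exact-multiplicity
counting, not a mismatch-tolerant off-target search, and it is checkable
against a brute-force recount of all sites. Non-unique guides stay in the
catalog, flagged; coverage statistics count unique guides by default.

One catalog row corresponds to one (site, gene) pair; coverage statistics
count distinct spacers per gene, so a spacer hitting a gene from one site is
one guide no matter how many window cytosines contribute to the stop.

## Coverage statistics

`summarize_coverage()` reports, for a gene universe taken from the
annotation: the number and fraction of editable genes (≥1 unique guide),
per-gene distributions of guides and of editable codons (distinct codon
indices reachable by ≥1 guide — one codon can be reachable by several guides),
and the distribution of relative stop positions (`codon_index / codon_count`)
in ten equal bins on [0, 1) by default; the bin width is a parameter since no
standard granularity exists. Genes whose CDS length is not a multiple of 3 or
contains N remain in the denominator but are excluded from design — excluding
them from the numerator is the conservative choice for an editable-fraction
statistic. Non-coding features (tRNA/rRNA without CDS) are not part of the
universe: premature-stop logic only applies to protein-coding genes.

Contigs are treated as linear by default; `circular = TRUE` extends PAM
scanning across the origin (bacterial chromosomes are typically circular,
but origin-spanning guides are a negligible fraction and complicate
coordinate reporting, so the option is off unless requested).

## Sanger-trace editing efficiencies

For wet-lab quantification the package implements the standard
per-position frequency definitions on a base-signal table (position,
reference base, A/C/G/T signals — the output of trace-processing tools;
chromatogram parsing itself is upstream and out of scope):

* C-to-T efficiency = T / (A + T + C + G),
* C-to-G efficiency = G / (A + T + C + G),

computed for reference-C positions (`profile_target()`). Both are scale
invariant in the signals. No "edited / not edited" clone-level threshold is
imposed, since published efficiencies are reported as continuous fractions.

## The synthetic genome generator and the oracle

Because no real genome ships with the package, testing rests on two legs.

**Generator** (`make_genome()`): builds a multi-gene genome whose guide set
is known *by construction*. Background CDS codons are drawn only from the 57
codons that are neither stops nor pre-stop codons, so a premature stop can
arise solely at planted codons; plants position a pre-stop codon so that its
editable base sits at a requested window position of a constructed NGG site
(for TGG, the coding-strand CC of the minus-strand PAM is forced upstream).
Secondary NGG sites can legitimately reach a planted codon, so the manifest
records the oracle-computed expected guide set alongside the planted list,
and the generator self-checks that every expected guide hits a planted codon
and every planted target is recovered. Decoys plant pre-stop codons that are
untargetable (editable base at −11, inside the protospacer but beyond the
extended window, or with any window-range GG excluded) and are verified to
yield nothing. Defaults — 20 genes of 250–450 codons with 150–400 bp
intergenic spacers (~25–30 kb), one plant per gene at a canonical window
position — give a study-sized prokaryotic fixture; everything is a pure
function of the seed.

What the fixtures deliberately do **not** emulate: real codon usage and GC
content (background codons are uniform over the safe pool, so pre-stop codon
density is far below a real genome's), overlapping genes, annotation errors,
and repeat-induced non-unique spacers. Passing tests therefore demonstrate
correctness of the scanning/frame/classification logic, not calibration of
coverage percentages against any real organism; genome-scale coverage checks
require a real genome and annotation (see `coverage_report()`).

**Oracle** (`brute_force_design()`): an independent implementation that
never looks at the codon rule table. It enumerates every 23-mer NGG site,
literally applies each permitted edit combination to the sequence,
re-extracts and re-translates every overlapping CDS from first principles,
and reports (site, gene) pairs that gained an in-frame stop before the
native one. The central test of the package is set equality between
`design_guides()` and this oracle over 20 seeded genomes × both windows ×
both policies, with 100% planted recall and zero false positives. The oracle
is quadratic on purpose and intended for genomes up to ~100 kb.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open everywhere internally; GFF3 (1-based
  inclusive) and BED (0-based half-open) conversions happen only at I/O.
* FASTA input is uppercased, `U` maps to `T`; characters outside A/C/G/T/N
  are an error by default or maskable to N. Sites containing N in spacer or
  PAM are dropped. Duplicate contig ids are an error.
* Overlapping PAMs (e.g. runs of G) each define their own protospacer.
* Among qualifying edit subsets the designer records the minimal one
  (fewest edits; ties broken by offset order); among qualifying codons, the
  earliest. Guides overlapping two genes are classified independently per
  gene.
* Sort order of catalogs is (contig, protospacer start, strand, gene), and
  all exports use fixed numeric formatting, so identical inputs produce
  byte-identical files.
* Fixture sizes in the shipped tests (6–20 genes, 80–450 codons) were chosen
  as the smallest sizes that still exercise both strands, both windows,
  multi-contig assembly and secondary sites.

## Known limitations

* NGG PAMs only; no activity scoring of spacers; no mismatch-tolerant
  off-target search beyond exact spacer multiplicity.
* C-to-G (glycosylase) editing is supported in the efficiency metrics but
  not in guide design: no validated design rule set exists for transversion
  outcomes.
* GenBank flat files are not parsed; supply FASTA + GFF3.
* Eukaryotic splicing is out of scope; multi-interval CDS are joined in
  translation order, which covers simple bacterial/archaeal cases and
  spliced CDS whose segments are annotated.
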