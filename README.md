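# bestop

Genome-wide design of knockout guides for CRISPR **cytosine base editors**,
plus Sanger-trace editing-efficiency metrics.

Cytosine base editors (a Cas9 nickase fused to a cytidine deaminase, e.g.
nCas9(D10A)–AID) convert C·G base pairs to T·A inside a short deamination
window at the PAM-distal end of the protospacer (positions −20…−16 of the
spacer, numbering the NGG PAM as 0–2; an extended window to −13 is
selectable). Placed inside a protein-coding gene, such edits can create a
premature stop codon and inactivate the gene without a double-strand break
or donor DNA — the base-editing analogue of a knockout. The complete rule
set, derived here by exhaustive enumeration over all 64 codons and verified
rather than assumed, is:

| sense codon | strand edited | result |
|---|---|---|
| CGA (Arg) | coding, C→T | TGA (opal) |
| CAG (Gln) | coding, C→T | TAG (amber) |
| CAA (Gln) | coding, C→T | TAA (ochre) |
| TGG (Trp) | template (CCA), one or both C→T | TGA / TAG / TAA |

`bestop` scans both strands of a genome (FASTA) for 20-nt protospacers with
NGG PAMs, maps the editable window cytosines onto reading frames from a GFF3
annotation, and emits a catalog of guides whose edits introduce an in-frame
stop upstream of the native stop, together with spacer-uniqueness flags,
genome-wide coverage summaries (editable genes, guides/editable codons per
gene, relative stop positions), a synthetic-genome generator with planted
targets, and an independent brute-force oracle used to validate the designer.
It is aimed at microbial strain engineers designing single or multiplex
gene inactivations with CBEs.

## Worked example

```r
library(bestop)

# a synthetic 6-gene genome with one planted target per gene
fix    <- make_genome(n_genes = 6, seed = 101, codon_range = c(80, 120))
genome <- load_genome(fix$fasta)
genes  <- load_annotation(fix$gff3, genome)

catalog <- design_guides(genome, genes, design_config(window = "canonical"))
catalog
#> guide_catalog: 10 guides (10 unique-spacer), 6 gene(s)
#>   gene_id contig strand spacer_start spacer_end               spacer pam
#> 1    g001   ctg1      -          450        470 GCGACTAAGAAAGAGCCCCC CGG
#> 2    g002   ctg1      +         1016       1036 CAAACGACACACAATCCGGT CGG
#> 3    g003   ctg1      -         1525       1545 TGTCAGTCCCGGTTTGATGT CGG
#> 4    g004   ctg1      +         2048       2068 TACAACCCTGTCGTCCAGCA AGG
#> 5    g005   ctg1      -         2699       2719 GCAATCGTTCGATCCTTTGG GGG
#>   edit_strand codon_index original_codon edited_codon stop_codon edit_offsets
#> 1      coding          44            CGA          TGA        TGA            0
#> ...
```

Each row is one (protospacer, gene) pair: where the spacer sits (0-based
half-open genome coordinates, strand of the protospacer), which codon is
edited, the minimal C→T edit set that creates the stop (`edit_positions` in
protospacer numbering), the resulting stop codon, the stop's relative
position inside the gene, and whether the 20-nt spacer is unique in the
genome (exactly one spacer+NGG occurrence over both strands).

```r
summarize_coverage(catalog, genes)
#> coverage_summary: 6/6 genes editable (100.0%) [unique-spacer guides]
#> guides per gene:         0:0  1:4  2:1  3:0  >=4:1
#> editable codons per gene: 0:0  1:6  2:0  3:0  >=4:0
```

Editing efficiencies from a Sanger-trace base-frequency table (the two
targetable Cs of a spacer, e.g. positions −19/−17):

```r
tab <- data.frame(position = c(5, 7), ref = "C",
                  A = c(1, 0), C = c(17, 6), G = c(1, 2), T = c(81, 92))
profile_target(tab, c(5, 7))
#>   position ref ct_efficiency cg_efficiency
#> 1        5   C          0.81          0.01
#> 2        7   C          0.92          0.02
```

`ct_efficiency` is T/(A+T+C+G) at a reference-C position; `cg_efficiency`
is the G analogue (glycosylase-editor outcomes).

## Command line

```sh
bestop=$(Rscript -e 'cat(system.file("cli","bestop",package="bestop"))')
$bestop fixture --n-genes 10 --seed 7 --out-prefix fix
$bestop design  --fasta fix.fa --gff fix.gff3 --window canonical --out-prefix run
$bestop stats   --catalog run.guides.tsv --fasta fix.fa --gff fix.gff3 --out summary.tsv
$bestop efficiency --table trace.tsv --targets 5,7 --out eff.tsv
```

`design` writes the guide TSV, a BED6 of protospacer spans, and a
provenance sidecar (config + genome MD5); all exports are byte-deterministic.

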