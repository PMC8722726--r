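# chimerafuse

Chimeric RNA design and breakpoint analysis for RNA-driven gene fusion.

Some cancer fusion genes (the motivating case is JAZF1–SUZ12 in
endometrial stromal sarcoma) can be *induced* by expressing a short
designer "chimeric RNA" whose two ~50 nt arms are antisense to intronic
windows of the two partner genes. The design exploits a structural
feature: regions where the **sense** genomic strand of gene A can pair
with the **sense** genomic strand of gene B form an imperfect *genomic
DNA stem*, and a chimeric RNA hybridising to the intronic DNA next to
that stem creates a three-way junction that can license breakage and
rejoining. The rearranged allele joins the two genes at intronic
breakpoints; splicing then removes the new intron, so the fusion mRNA
junction lies on annotated exon boundaries (for JAZF1–SUZ12: exons 1–3
of the upstream gene joined to exons 2–16 of the downstream gene,
junction exon 3 → exon 2).

`chimerafuse` implements that whole desk-side workflow for any two
annotated genes:

* **stem discovery** — affine-gap Smith–Waterman (Rcpp) of each A
  intron (sense) against the reverse complement of each B intron, so a
  match column *is* a sense–sense base pair; BLAST-like default scoring
  (+2 / −3, gap 5 + 2·L), thresholds `min_length` ≥ 20 columns and
  `min_identity` ≥ 0.7;
* **chimera design** — 50 nt arms abutting the stem windows, antisense
  and sense orientations as mutual reverse complements, U6 pol-III
  cassette inserts with `TTTTTT` terminator checks, batch design with a
  per-arm uniqueness screen;
* **fusion modelling** — rearranged allele
  `senseA[0..bpA] + insertion + senseB[bpB..]`, lifted annotation, and
  the spliced fusion transcript;
* **breakpoint inference** — single-base breakpoints, untemplated
  insertions and microhomology from junction-spanning Sanger-length
  reads (anchored split scan, exact against an exhaustive oracle on
  clean reads);
* **in-silico PCR** — nested RT-PCR schemes (including the
  characteristic two-band final round) and 56×10-style multiplex
  tiling scans that bracket an unknown genomic breakpoint;
* **synthetic data** — a deterministic two-gene genome emulating the
  JAZF1/SUZ12 configuration (5-exon gene with a 54 kb·scale intron 3,
  16-exon gene with a 2.7 kb·scale intron 1, planted stem and fusion
  events), so everything is testable offline.

## Worked example

```r
library(chimerafuse)

spec <- fusion_preset("jazf1-suz12-like", scale = 0.05, seed = 7)
gen  <- generate_genome(spec)           # two contigs + gene models + truth

stems <- find_stems(gen$gene_a, gen$gene_b, gen$genome)
stems[[1]]
#> <genomic_stem> score 63, 44 cols, identity 0.886
#>   A intron 3  contigA:2147-2190 (+)
#>   B intron 1  contigB:575-618 (+)
writeLines(stem_alignment_text(stems[[1]]))
#> A sense  5'-ATGGAATAATACCCATCATAACTCAGTATACATTTCTAGATCAG-3'
#>             ||| |||||||| |||||||||| ||||||||||| ||||| ||
#> B rc     3'-ATGTAATAATACTCATCATAACTTAGTATACATTTTTAGATTAG-5'
```

The top stem is the planted one: a 44-column alignment at 88.6%
identity between intron 3 of the 5-exon gene and intron 1 of the
16-exon gene, shown as A's sense strand paired with the reverse
complement of B's sense strand. Designing the antisense chimera on it:

```r
chimera <- design_chimera(stems[[1]], gen$gene_a, gen$gene_b, gen$genome)
chimera
#> <chimeric_rna> chimera-1 (antisense), 2 x 50 nt arms, order 'ab'
#>   arm A -> contigA:2097-2146 (+)
#>   arm B -> contigB:619-668 (+)
#>   5'-TCTGCGTGAATTGCAGCAGCCTGCTAGTGTACTCGAAGCCTAACACAATAGTTTCC...-3'
```

Each 50 nt arm abuts its stem window (arm A upstream, arm B
downstream) and, reverse-complemented, occurs verbatim and uniquely at
its target. Modelling the planted fusion event "y" (which carries an
untemplated `"AA"` insertion) and inverting it from a junction read:

```r
ev     <- gen$truth$events[[2]]                      # event "y"
allele <- make_fusion_allele(gen$genome, gen$gene_a, gen$gene_b, ev)
splice_fusion_transcript(allele)
#> <fusion_transcript> 2444 nt, junction exon 3 -> exon 2

mat <- generate_fusion_materials(gen)                # alleles + reads
infer_breakpoint(mat$reads[["read_y_1"]],
                 gen$genome[["contigA"]], gen$genome[["contigB"]])
#> <fusion_inference> bpA=3361 bpB=630 ins='AA' microhomology=0
#>                    (A window 3361-3361, 0 mismatches)
```

The transcript keeps the 3 upstream and 15 downstream exons with the
canonical exon 3 → exon 2 junction, and inference recovers the planted
breakpoints and the 2 nt insertion exactly (breakpoints are 0-based
last-retained/first-retained positions; reports print 1-based).

## Command line

```sh
exec/chimerafuse simulate --preset jazf1-suz12-like --scale 0.05 --seed 7 --out syn
exec/chimerafuse find-stems --genome syn/genome.fasta --annotation syn/genes.gff3 \
    --gene-a geneA --gene-b geneB --out stems.tsv
exec/chimerafuse run --config config.json    # full pipeline + manifest
```

Subcommands: `simulate`, `find-stems`, `design`, `predict-transcript`,
`infer-breakpoint`, `ispcr`, `tile`, `scan`, `run` (JSON config, md5
provenance manifest; flags override config values).

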