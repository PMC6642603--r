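# tgscan

Characterizing a transgenic plant line from sequencing data means answering
a handful of concrete questions: *where* did the T-DNA construct integrate,
*what* was lost at the integration site, *which* construct sits at which
site, is a host gene disrupted and on how many alleles, and does the line
otherwise differ from its wild-type parent in genome and transcriptome?
`tgscan` implements the computational core of that workup as a tidyverse-
style R package for people analyzing paired-end DNA and RNA sequencing of
transgenic lines (typically mapped against a draft plant genome plus the
construct sequences).

Everything operates on plain tibbles (alignments from SAM text, variants
from a VCF subset, gene models from GFF3), so each stage can be inspected,
filtered and piped with dplyr.

## What it computes

**Insertion sites.** Read pairs with one primary mate on a host scaffold
and the other on a construct are *bridging pairs*, labeled P/C/T by the
promoter/cassette/terminator segment they hit. Pairs cluster into candidate
sites; clusters with fewer than 10 P+T pairs are dropped. Split (chimeric)
reads localize each junction at base-pair precision from the leftmost
mapping position by performing the CIGAR operations: a host-side segment
clipped at its 3' end puts the junction at `pos + ref_span - 1`, a 5'-clip
at `pos`. With junctions on both sides, the host bases lost to the
integration are `|pos_T - pos_P| - 1`; reads aligned continuously across
the junction call the insertion hom/het.

**Fusion transcripts and disruption zygosity.** Read pairs with one mate on
a transgene cassette and the other on a host transcript evidence a fusion
transcript; per-exon coverage shows the step a strong constitutive promoter
produces downstream of the insertion intron. A gene is called homozygously
disrupted only when no template links the two flanking exons *and* both
exons are adequately covered. Fusion evidence assigns constructs to sites
directly, the remaining construct by elimination.

**Variants.** A pileup genotyper (no likelihood model) feeds two filter
cascades: *genomic* (calling quality >= 20, mean MQ >= 20, coverage 4 to a
sample-specific maximum, MQ0 fraction <= 0.10, >= 1 alternative read per
strand) and *transcriptomic* (additionally: alt fraction >= 0.9, SNVs
within 10 nt of an indel, indels within 100 nt of each other, and 3-SNV
clusters within 10 nt removed). Consensus errors are subtracted
position-wise from a self-mapping call set. Divergence between accessions
is summarized as SNVs per megabase of CDS positions covered at >= 4x, with
Ti/Tv ratios and a codon-level impact classifier.

**Expression.** Union-mode fragment counting with masking of RNAi target
regions, depth or median-of-ratios normalization, FPKM/TPM with the
sample-specific TPM threshold `1e6 / sum(FPKM)` (the TPM value of
`FPKM = 1`), and threshold-gated differential-expression calls
(mean normalized count >= 10, `|LFC| >= 0.5`, TPM above threshold in at
least one condition).

**Gene sets.** Expression hints (exonpart coverage segments clamped into
[20, 300]; intron spans from spliced reads), the three retention rules
(>= 1% hint support, <= 10 nt CDS overlap with transposable elements,
peptides >= 10 aa), the twelve descriptive gene-set metrics, and a tiered
homology-annotation cascade whose aligned fraction is the maximum query
coverage by mutually compatible (non-overlapping) HSPs, found by weighted
interval scheduling.

A synthetic-data module (`make_host_genome()`, `transgene_spec()`,
`apply_insertion()`, `simulate_genomic_pairs()`, `simulate_rnaseq()`,
`plant_variants()`) generates genomes, insertions, read sets and exact
truth tables so the whole pipeline is testable offline.

## Worked example

```r
library(tgscan)

hg   <- make_host_genome(n_scaffolds = 1, lengths = 100000, n_genes = 3,
                         seed = 7)
fuct <- transgene_spec("FucT")   # 4,768-nt insert
xylt <- transgene_spec("XylT")   # 4,536-nt insert

ins <- apply_insertion(hg$genome, fuct, "scaf1", left_junction = 27872,
                       deleted = 28, zygosity = "hom", models = hg$models)
sim <- simulate_genomic_pairs(ins$haplotypes,
                              reference_dict(hg$genome, list(fuct, xylt)),
                              read_sim_config(depth = 30, seed = 3))

scan <- insertion_scan(sim$alignments, list(fuct, xylt))
tidy(scan)
#> # A tibble: 1 x 14
#>   scaffold anchor_start anchor_end p_pairs t_pairs c_pairs construct
#>   <chr>           <int>      <int>   <int>   <int>   <int> <chr>
#> 1 scaf1           27178      28575      75      71       0 FucT
#> # i 7 more variables: support <int>, junction_p <int>, junction_t <int>,
#> #   lesion <chr>, deleted <int>, zygosity <chr>, wildtype_spanning <int>
```

The scan found one candidate site supported by 146 bridging pairs, placed
the promoter-side junction at 27,872 and the terminator-side junction at
27,901 (both exact), inferred the 28-base deletion between them, and called
the insertion homozygous (no wild-type junction-spanning reads).
`autoplot(scan)` draws the bridging-pair evidence with the called junctions.

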