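---
title: "Characterizing transgene integrations: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing transgene integrations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tgscan)
```

This vignette explains the models behind `tgscan`, the parameters that
matter, what the synthetic-data generator does and does not emulate, and
the design decisions taken where the procedure was genuinely open.

## The evidence model for integration sites

A transgene integration leaves two signatures in paired-end genomic reads
mapped against a combined host + construct reference:

* **Bridging pairs** — templates with one mate on a host scaffold and the
  other on the construct. The construct mate is labeled by the construct
  segment (promoter `P`, cassette `C`, terminator `T`) it maximally
  overlaps. Because sequencing fragments are much shorter than the
  construct, `P` and `T` pairs cluster on opposite flanks of the site,
  which is what lets the two junctions be told apart.
* **Chimeric (split) reads** — single reads whose prefix and suffix align
  to different references, represented as a primary alignment plus a
  supplementary alignment with soft clips. The junction is computed from
  the leftmost mapping position by performing the CIGAR operations on the
  host-side segment: 3'-clipped segments end at the junction
  (`pos + ref_span - 1`), 5'-clipped segments start at it (`pos`).

Candidates need at least `min_support = 10` P+T pairs — weakly connected
scaffolds are overwhelmingly mapping noise in repeat-rich plant genomes.
Support is counted per clustered site over both sides jointly; the split
into P and T counts is reported alongside. The cluster window defaults to
twice the upper insert bound estimated from proper-pair template lengths,
since a bridging pair's host anchor must lie within one fragment length of
its junction.

**Junction convention.** A junction coordinate is the *last retained host
base* (1-based) adjacent to the construct on its side. Under this
convention a clean insertion has `pos_T = pos_P + 1`, and the bases deleted
at the site are `|pos_T - pos_P| - 1`. This is the only convention in which
a junction pair like (27872, 27901) yields a 28-base deletion; a negative
count (overlapping junctions) is flagged `complex` rather than forced into
a deletion, which is also how a site in repeat-dense, possibly misassembled
sequence is reported when one side has no chimeric support at all.

Several chimeric reads vote on each junction; the modal position is
reported, ties break to the smaller coordinate and carry a flag. On
error-free simulated data every read votes for the true coordinate, so the
mode is exact; on real data the mode absorbs stray alignment jitter.

**Insertion zygosity.** Reads aligned continuously (no clips, at least 5
aligned bases on either side) across the 5' junction boundary can only come
from an unmodified haplotype. Zero such reads with local depth of at least
10 calls the site homozygous; three or more call it heterozygous; anything
between is `undetermined`. The depth condition prevents calling
homozygosity from missing data.

## Fusion transcripts and disruption zygosity

When an insertion lands inside a gene, the construct's constitutive
promoter can drive a fusion transcript consisting of cassette sequence
spliced onto the downstream host exons. Evidence is read pairs with one
mate on the cassette ("insert mate") and one on the host transcript ("host
mate"), scanned in transcriptome space. For real data the reads are cropped
to 36 nt first (`transform_reads()`), because junction-spanning reads only
align end-to-end when they are short; the genome-space coverage profile
uses full-length reads, where the 5'-to-3' coverage step across the
insertion intron is the visual signature.

Wild-type support for a gene disrupted in intron *k* is any template
linking exon *k* to exon *k + 1*: a mate pair with one mate on each exon,
or a single read splice-mapped across that intron. Spliced single reads are
equivalent evidence and strictly increase sensitivity, so they count by
default; `count_spliced_singles = FALSE` restores a strict pairs-only
reading. A homozygous-disruption call requires wild-type support to be
exactly zero *and* both flanking exons to average at least 10x coverage.
`min_fusion_support` defaults to 3 pairs — the threshold is not prescribed
anywhere, and 3 independent templates is the conventional floor for
structural evidence; the observed case had 11.

Constructs are assigned to sites by their cassette-specific fusion
evidence; when exactly one construct and one candidate remain, the
assignment completes by elimination and is flagged as such, mirroring how a
second site in unresolvable repetitive sequence still receives its
construct.

## Variant filter cascades

`pileup_genotype()` is intentionally simple: per-position base counts
(bases under BQ 20 excluded), strand-split alternative counts, mean mapping
quality and MQ0 fraction, SNVs from plurality non-reference bases and
indels from `I`/`D` CIGAR operations in the left-aligned anchored-base
convention. It computes no genotype likelihood and leaves `qual` as `NA`;
a filter rule whose annotation is missing does not reject. Raw call counts
therefore need not match a likelihood-based caller; the filter semantics
downstream are what the package reproduces exactly.

The **genomic** dialect: calling quality and mean MQ at least 20, coverage
between 4 and a sample-specific maximum, MQ0 fraction at most 0.10, and at
least one alternative read on each strand. The coverage ceiling defaults to
`round(1.45 x mean depth)` when not supplied, the approximate ratio of the
published per-sample ceilings to their mean depths (30 at 21x, 38 at 26x);
it is always overridable. The **transcriptomic** dialect adds an
alternative-allele fraction of at least 0.9 (single-genotype material) and
three positional exclusions targeting alignment artifacts: SNVs within
10 nt of an indel, both members of an indel pair within 100 nt, and all
members of any 3-SNV cluster spanning at most 10 nt.

Two open points were resolved as follows. The positional exclusions are
evaluated on the raw candidate set *before* per-variant quality rules:
artifact clusters should suppress their neighbors even if some members
independently fail other filters (configurable by filtering first). The
cluster rule removes *all* members of a qualifying cluster, not just
interior ones — the artifact interpretation taints every member. One
printed rule reads as a *minimum* MQ0 fraction; it is enforced as a maximum
(matching the genomic dialect), since requiring ambiguously mapped reads
would select for exactly the artifacts the cascade removes; a flag restores
the literal reading.

Consensus-error subtraction removes, position-wise and allele-agnostically,
every site that also varies when reads of the reference genotype are mapped
back to their own assembly. Divergence between accessions is
`SNVs / Mbp of CDS positions covered >= 4x`; the display value is rounded
half-to-even to integers, full precision is retained. The impact classifier
reproduces the standard codon-level categories (synonymous LOW; missense
and in-frame indels MODERATE; frameshift, stop gain/loss, start loss and
the two intronic bases at exon boundaries HIGH; everything else MODIFIER).

## Expression gates

Counting is union-mode per gene: a template counts once for the single gene
whose exons its aligned blocks overlap; ambiguous templates count for
nobody. Fragments overlapping RNAi target regions are removed before
counting, because transgene-derived reads would otherwise inflate the
targeted genes' counts. FPKM uses the merged-exon union length per gene
(matching union-mode counting). TPM follows
`TPM_i = FPKM_i / sum_j FPKM_j * 1e6`; the sample-specific expression
threshold is the TPM at `FPKM = 1`, i.e. `1e6 / sum(FPKM)` (values near
3.4 at typical library sizes).

The differential-expression result reproduces the deterministic gates only:
mean normalized count at least 10 across all replicates and conditions
(normalized counts, since depth differences would otherwise leak into the
gate), `|LFC| >= 0.5` with pseudocount 1, and the TPM threshold met by
every replicate of at least one condition. No dispersion model, no
p-values: significance testing under a negative-binomial model is a
well-solved problem elsewhere and is out of scope here; the gate logic is
the part specific to this workflow.

## Gene-set QC and annotation

Hint support for a predicted transcript is the fraction of its exonic
length covered by at least one exonpart hint, with 1% as the retention
floor — exonic length is the natural denominator because hints are exonic
evidence. Hint coverages are clipped into [20, 300] by default (`drop` mode
removes sub-floor hints instead; the wording "applying a minimum coverage
to each hint" is ambiguous between the two). The transposable-element rule
tolerates at most 10 nt of summed CDS overlap against the merged repeat
track; peptides under 10 aa are dropped. The rejection ledger names the
failed rule(s) per transcript and partitions the input exactly.

The annotation cascade maps protein queries against taxonomically ranked
databases, nearest clade first, and stops at the first tier with a passing
hit (E-value <= 1e-10, alignment >= 70 aa, identity >= 90%, an
aligned-fraction criterion, and a description that is not
"uncharacterized"/"unknown"/"hypothetical"). The aligned fraction is the
maximal query coverage by pairwise non-overlapping HSPs, computed by
weighted-interval scheduling that maximizes covered length (not summed HSP
score — the quantity is defined as coverage). The printed direction of the
aligned-fraction filter (a *ceiling* of 90%) would reject near-full-length
matches, which is suspected to be an erratum; both comparators ship
(`"max"` 0.90 as the replication default, `"min"` 0.70 as the conventional
coverage floor) and the mode used is recorded in the output.

## The synthetic-data generator

The generator defines the conditions under which the pipeline is validated:

* **Host genome** — random scaffolds at GC 0.4 with embedded multi-exon
  genes (ATG start, stop codon, GT..AG introns, 2-6 exons, CDS = exons)
  and labeled repeat intervals. Real draft assemblies add misassembly,
  collapsed repeats and N gaps, which the generator does not emulate —
  passing tests show algorithmic correctness, not robustness to assembly
  pathology (the `complex`-lesion path is exercised by censoring evidence
  instead).
* **Constructs** — 25-nt border repeats, a 2,774-nt promoter, cassettes of
  1,072/840 nt and an 872-nt terminator, giving insert lengths of 4,768 and
  4,536 nt; the segment split beyond the published insert and cassette
  lengths is a package choice consistent with the rounded published part
  sizes.
* **Reads** — 2 x 125 nt pairs from fragments drawn
  normal(700, 50) truncated at twice the read length. Only the fragment
  peak (700) and the mapper's insert bounds (500/775) are published; the
  SD of 50 is a package choice exposed in `read_sim_config()` and is
  consistent with those bounds at wide quantiles. Errors are uniform
  substitutions; no quality decay along the cycle, no error indels (the
  filter cascades are tested by injecting artifacts explicitly). Truth
  alignments are emitted directly from simulation coordinates — exact by
  construction, so recovery tests are exact; chimeric reads appear as
  primary + supplementary records with soft clips on both.
* **Variants** — Poisson-distributed SNV counts at a per-Mbp rate with
  transitions drawn at `titv / (titv + 1)`, optional anchored-base indels.
* **RNA** — fragments per transcript Poisson with mean
  `depth x abundance x length / (2 x read length)`, so abundance 1 averages
  `depth` coverage; fusion transcripts concatenate the cassette onto a host
  transcript suffix with downstream splicing preserved.

## Numerical and coordinate conventions

All intervals are 1-based and closed, the IRanges/Bioconductor convention;
GFF3, SAM and VCF coordinates pass through unshifted, and only BED I/O
converts. User-facing junction and variant positions are therefore directly
comparable to published coordinates. Merging, overlap and coverage go
through IRanges; the CIGAR arithmetic central to junction calling is
implemented in the package and has vectorized fast paths for clip-M-clip
records.

Problem sizes in the validation suite: insertion recovery runs 50 scenarios
on a 1-Mbp host at 30x error-free coverage with deletions of 0-500 bases
and hom/het zygosity; rate calibration plants 10, 67 and 8,152 SNVs/Mbp on
a 1-Mbp CDS track at 10x and requires recovery within `3 * sqrt(rate)`;
Ti/Tv calibration plants about 50,000 SNVs at ratio 1.4 and requires
recovery within 0.05; the positional filter rules are checked against
brute-force neighborhood scans on 10,000 random layouts; the HSP scheduler
is checked against the exhaustive-subset optimum on 1,000 instances of up
to 10 HSPs. These sizes make every property a sharp test while each suite
stays in the minutes range on one core.

## Known limitations

* The pileup genotyper is not a genotype-likelihood model; raw call counts
  on real data will differ from likelihood-based callers even when the
  downstream filter behavior is identical.
* Repeat-mediated rearrangements at an integration site are reported as
  `complex`, never reconstructed; general structural-variant calling is out
  of scope.
* Fusion detection quantifies evidence as read-pair counts; it does not
  reconstruct isoforms or estimate fusion transcript abundance.
* Two haplotypes only; no polyploid simulation; PCR duplicates are
  collapsed by start-coordinate key, not by UMI.
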