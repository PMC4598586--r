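---
title: "Methods: simulating and analysing double-digest RRBS"
author: "rrbsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing double-digest RRBS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`rrbsim` implements a complete, closed-loop reduced-representation bisulfite
sequencing (RRBS) study on synthetic data: a genome simulator whose output
feeds an analysis pipeline, so that every estimate the pipeline produces can
be compared against a known ground truth. The design target is the
double-digest protocol used for plant methylomes: genomic DNA is cut with
SacI (GAGCTC) and MseI (TTAA), fragments of 250-500 bp are gel-selected,
bisulfite-converted, and sequenced as non-directional paired-end 100 bp
reads; reads are trimmed to 75 bp, quality-filtered, aligned in three-letter
space with at most one mismatch, and per-cytosine methylation levels are
called at ten-fold minimum depth after masking sites disrupted by
sample-versus-reference SNPs detected from a parallel (non-bisulfite) ddRAD
library.

The scientific quantities of interest are per-context methylation levels
(CG, CHG, CHH; H = A, C or T), their distribution over genomic components
(TE bodies, exons, introns, promoters, flanks), chromosome-scale window
profiles, metagene profiles, and the stratification of genic methylation and
expression by polyploid subgenome (LF/MF1/MF2) and gene copy number (1-3).

# The synthetic genome and methylome

`generate_genome()` draws i.i.d. sequence at a configurable GC content
(default 0.42, a plant-euchromatin-like value) and lays out non-overlapping
gene models (1-5 exons of 120-400 bp, introns of 80-300 bp, random strand,
subgenome and copy-class labels) and TE intervals (300-1500 bp), with a
configurable fraction of TEs confined to a central "pericentromeric" block
that genes avoid. Tandem/inverted repeat tracks are annotation intervals
only. An i.i.d. genome differs from a real one in an important way for
RRBS: real plant genomes are TpA-depleted, so MseI sites are rarer and
fragments longer than in an i.i.d. sequence of the same composition. The
synthetic capture fraction per Mb is therefore lower than a real genome
would give; the acceptance-scale run sizes below were chosen to compensate.

`generate_methylome()` assigns every cytosine a true level from a
(component x context) model, with component priority TE > exon > intron >
promoter > flank > intergenic, reflecting the dominance of TE methylation.
Default component means follow the canonical plant ordering (CG >= CHG >=
CHH everywhere; TE > intron > exon), with TE (88.0/54.0/17.7%), intron
(54.4/22.0/5.9%) and exon (25.1/8.8/2.7%) at published component-scale
values; promoter, flank and intergenic means (27/35/45% CG) are the
package's own choices for plausible intermediate levels. Three distribution
families are available per cell: `two_point` (the bimodal pattern of plant
CG), `beta` (intermediate CHG/CHH variability; concentration 2 by default)
and `constant` (degenerate, used for parameter-recovery calibrations where
the per-molecule methylation probability itself is the target).

# Read simulation

Each selected fragment receives Poisson-many molecules; a molecule draws its
bisulfite strand (OT/OB/CTOT/CTOB, uniform for a non-directional library)
and then a single binary methylation state per cytosine at that cytosine's
true level — per molecule, not per read, so overlapping mates are always
consistent. Unmethylated cytosines convert to T with efficiency 0.995 (a
typical two-round conversion figure; the default is declared, not
inferred), methylated cytosines never convert. Sequencing errors
(substitution, 0.001/base) and Phred+33 qualities (mostly Q40 with a small
low-quality tail, ~1.2% of bases below Q30) are applied afterwards. Read
names carry the ground-truth origin (`chrom:start:end:strand:bs:molecule`),
which the tests use as a provenance oracle. Because a bisulfite molecule
reports cytosines on one strand only, the simulator samples twice the
target coverage in pairs so that the realised informative depth per
cytosine matches `mean_coverage`.

What the simulator does *not* model: PCR duplicates and amplification bias,
gel-mobility variation, adapter read-through, indels, M-bias, and
methylation-sensitive enzyme behaviour. Passing tests therefore demonstrate
correctness of the analysis logic under a clean error model, not robustness
to every artefact of real libraries.

# Alignment

`align_bs_reads()` evaluates the four bisulfite-strand hypotheses in
three-letter space: the read is C->T (or G->A) converted and compared with
the correspondingly converted reference, so bisulfite conversion can never
count as a mismatch. Candidate locations come from exact 20-mer seeds at
two read offsets; since trimmed reads (75 bp) are longer than twice the
seed, a single mismatch cannot hit both seeds, making seed-and-verify
exhaustive at the 1-mismatch budget (the test suite checks agreement with a
full-scan oracle). A pair is reported only when both mates align in proper
orientation with insert at most 500 bp (the size-selection bound) and the
pair has a strictly unique best score; ties are counted ambiguous,
mirroring a uniquely-mapped-reads rule. There is no quality-aware scoring,
soft-clipping or indel handling — the simulator emits none and the
mismatch budget is the contract.

# Calling, SNP masking and numerical choices

Pileup walks each aligned mate in top-strand orientation. Only the
informative strand contributes (OT/CTOT for top-strand cytosines, OB/CTOB
for bottom-strand). At overlapping mate positions read 1's base is taken
(one molecule, one observation); bases below Q20 are skipped; C (or G, on
the bottom strand in top orientation) counts methylated and T (or A)
unmethylated. Levels are emitted at coverage >= 10. CG sites are kept
per-strand (no symmetric merging), matching per-cytosine locus counting.

SNP calling from the ddRAD arm is deliberately permissive — one
high-quality (>= Q20) non-reference base suffices — because its purpose is
conservative masking, not genotyping. A methylation site is masked when a
candidate SNP falls anywhere in its context-defining window (C..C+1 for CG,
C..C+2 for CHG/CHH, strand-oriented); the motif-window rule is a package
choice where a C-only rule would also be defensible, and it is configurable
in spirit via `mask_sites()`' inputs.

Other numerical conventions: 0-based half-open coordinates internally
(BED-style), 1-based only in emitted GFF3/SAM/VCF; the >5% low-quality
filter uses strict inequality (a 75-bp mate with exactly 3 bases under Q30
is retained, 4 is discarded); size-selection bounds are inclusive at both
ends; window profiles use unweighted site means per window; component,
stratum and expression-class means are pooled over reads (levels derive
from reads), with the unweighted site mean also reported.

# Profiles and stratification

Window profiles use 200 kb windows advancing 100 kb (the last partial
window included). Metagene profiles split each feature body into 10
equal-length bins (remainder bases to the last bin) and 1 kb flanks into
fixed 100-bp bins, mirroring minus-strand features so bin 1 is 5'; the
100-bp flank bin width is a display choice to align flank and body bins
visually. The level histogram separates exact zero from ten 10% bins, the
resolution at which plant CG methylation appears bimodal.

Stratified comparisons pool methylated/unmethylated read counts per
stratum and use the 2x2 chi-square without continuity correction, declaring
significance at the fixed criterion 6.63 (the 0.99 quantile of the 1-df
null, P < 0.01) with no multiplicity correction — a fixed-threshold scheme,
noted as such. Expression classes are RPKM <= 5 (low), 5-50 (medium),
> 50 (high); class-composition contrasts use the 2-df chi-square on the
3-class counts, and compact significance letters are assigned greedily in
descending order of high-class fraction (strata sharing a letter are not
significantly different; ties break by stratum name).

# The expression generator

`generate_expression()` draws log-normal RPKM with stratum-specific
locations (defaults encode LF > MF2 > MF1 and single-copy < multi-copy, the
hierarchy expected from biased fractionation), a common log-scale
dispersion (1.5), and a negative coupling between a gene's mean genic CG
methylation (centred) and its log expression (-2 by default). Coupling zero
gives the null model used in the association tests.

# Problem sizes, calibrations and their rationale

Two acceptance-scale runs are used (see `scripts/acceptance.R`):

* **Run A** (~2 Mb, 600 genes, 400 TEs, 20x coverage, conversion 0.995,
  error 0.001): component CG truth is set *constant* at the component means
  (the per-molecule methylation probability is the quantity being
  recovered), so the pooled estimator's error is read-count limited. With
  >= 100 called sites per component at depth ~20, the binomial SE of each
  pooled component mean is <= 0.5 percentage points, comfortably inside the
  2-point recovery band; the only systematic terms are the conversion
  failure bias, (1 - level) x 0.005 <= 0.4 points, and a smaller error-rate
  term.
* **Run B** (~8 Mb, uniform two-point CG mixture with P(methylated) =
  0.524): with a two-point site mixture the pooled mean is site-count
  limited, with SE sqrt(p(1-p)/n_sites). The run is sized to yield roughly
  4,500-5,500 called CG sites, i.e. SE ~0.7 points against the 1.5-point
  band. A component-calibrated model fixes the genome-wide mean through the
  component weights, which is why the genome-wide mixture is a separate run
  rather than a re-reading of run A.

The injected-effect power property is checked at the pooled-count level
(50,000 reads per stratum, adjacent offsets of 2 percentage points), where
the 2x2 test's non-centrality makes all three pairwise comparisons
significant essentially always; at the 10,000-read floor the same 2-point
offsets would sit near 70% power per pair, so the larger (still compliant)
read count is the declared study condition.

# Known limitations

* The i.i.d. genome under-captures relative to a TpA-depleted real genome;
  capture fractions are not comparable to published percentages.
* Ambiguous alignment is resolved by discarding ties only; there is no
  multi-mapping rescue, so highly repetitive synthetic genomes lose
  coverage in duplicated regions by design.
* The SNP caller has no genotype model; heterozygous sites in a real
  diploid would be masked less reliably than the clean homozygous
  substitutions simulated here.
* Expression enters as an RPKM table; no read-level RNA-seq is simulated.
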