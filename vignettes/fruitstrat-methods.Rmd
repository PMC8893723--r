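---
title: "Methods: gene ages, allele-specific expression and conserved orthogroups in fungal development"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene ages, allele-specific expression and conserved orthogroups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fruitstrat)
```

# The problem

Fruiting bodies of mushroom-forming fungi are complex multicellular
(CM) structures built by a developmental program layered on top of much
older machinery (meiosis, sporulation, general metabolism). Three
questions drive the analyses in this package: which genes are
*developmentally expressed* across a stage series; how the
*evolutionary age* of a gene relates to its expression (including the
transcriptome-level age profile across development); and how the two
haploid nuclei of a dikaryotic strain contribute to the transcriptome
(*allele-specific expression*, ASE), as opposed to sequence-level
effects such as RNA editing. A final component separates conserved
orthogroups whose developmental expression is shared with a
simple-development outgroup from those specific to CM species.

Every stage of the pipeline is driven by a handful of published
thresholds; the package's defaults equal those values, so a default run
is a faithful reimplementation of the rules, and every threshold is a
configuration field.

# Developmentally expressed genes

Per gene, replicate FPKM values are averaged within each
(stage, tissue) group. The fold change is the largest larger/smaller
ratio of group means over all pairs of **non-VM** groups; a gene is
developmental at threshold *t* (2 or 4) when that ratio reaches *t*,
its peak group mean exceeds 4 FPKM, and the globally maximal group —
vegetative mycelium included — is not VM (genes peaking in VM are
excluded outright and flagged).

Design choices where the rule statement is ambiguous:

* Fold changes are computed on group means, not per replicate pair —
  the group-level comparison is stable to outlier replicates.
* Group means are floored at 0.1 FPKM inside ratios, so on/off genes
  pass with a large finite fold change instead of an infinite one. The
  floor only matters below detection level; at the default thresholds
  a gene must anyway peak above 4 FPKM.
* The FPKM > 4 condition is tested against the peak group mean
  ("detectable at the peak"), not against every group — otherwise any
  silent stage would disqualify an on/off gene.
* VM exclusion applies to the global maximum only; VM groups never
  enter the pairwise comparisons. Tissue types within a stage are
  treated as ordinary groups, so stage-vs-stage and tissue-vs-tissue
  contrasts are symmetric.

# Gene ages and the transcriptome age index

Ages live on the root-to-focal-tip path of a rooted species tree,
numbered 1 at the root and increasing to K at the focal tip (the
youngest stratum; a gene found only in the focal species has age K).
An orthogroup's age is the node where the MRCA of its species attaches
to that path; an MRCA off the path is projected to its deepest on-path
ancestor, because ages must live on the focal lineage. Species loss can
only shrink the species set, so inferred ages are monotone: losses can
make an orthogroup look younger (larger node number), never older —
this exact property is asserted in the tests.

The transcriptome age index of a stage is the expression-weighted mean
age, `TAI = Σ RAᵢ eᵢ / Σ eᵢ`. Two choices deserve comment:

* `eᵢ = log2(FPKMᵢ + 1)`. The source formula says "log2 FPKM" but is
  silent on zeros, where the logarithm is undefined and negative
  weights would be meaningless. The pseudocount keeps unexpressed genes
  at weight 0 and is the standard transform; a config switch
  (`tai_log_mode = "log2_drop"`) instead drops genes below 1 FPKM and
  uses the bare logarithm, for sensitivity analysis.
* `RAᵢ` is the raw node number, matching how node numbers are used as
  age values; `normalize_ages()` provides the min–max-normalized
  variant, but raw is the default and the two give identical rankings.

Tissue samples of a stage are averaged per replicate before the index
is computed; TAI is computed per replicate and then averaged, so
replicate scatter is available. A stage with no expression at all has
no defined TAI and is reported missing with a warning. TAI is a convex
combination of ages, so it always lies between the youngest and oldest
stratum, and adding a gene whose age equals the current TAI is a fixed
point — both are asserted as properties rather than the (only
asymptotically true) invariance under rescaling.

Enrichment of a gene set across age strata uses a two-sided Fisher
exact test per stratum (flagged/unflagged × in-age/other) with
Benjamini–Hochberg correction across strata, reporting the sample odds
ratio for direction — over- and underrepresentation are both
meaningful. Trends of a statistic across ordered strata use the
Mann–Kendall test; for n ≤ 10 without ties the two-sided p-value is
exact (inversion-number distribution over all n! orderings), otherwise
the normal approximation with tie and continuity corrections is used.

# Allele-specific expression

Reads are assigned to a parental nucleus by Hamming distance (number of
mismatching SNPs) against the two parental haplotypes over the SNPs the
read covers. A read is indecisive when (i) Hd > 1 from both genomes,
(ii) Hd > 15 from any genome, or (iii) the distances tie (a read
covering no SNP ties at 0–0). Rule (ii) is implemented literally: a
read with Hd 0 and 16 is discarded as too divergent. The literal
reading may not be the intent (arguably only the *closer* genome's
divergence matters), so `divergent_rule = "closer"` is available; the
default does not guess.

Per gene and sample, `AS = A/(A+B)` over decisively assigned reads, and
the ratio is masked to 0.5 (i.e., treated as equal expression) when the
gene's total FPKM is below 2, fewer than 16 decisive reads exist, or
more than 80 % of reads are indecisive. Total gene FPKM is used for the
first rule — "expression too low" refers to the gene, not one allele.

Classification then works per (stage, tissue) group: all replicates
must be biased toward the same nucleus — strictly on one side of 0.5,
with any masked replicate breaking the group, the literal reading of
"in all biological replicates" — and the geometric mean of replicate
AS must exceed 0.8 for S4 or 0.68 for S2 (nucleus-B bias mirrors the
test onto 1 − AS against the 0.2 / 0.31 limits; a config switch
compares the direct geometric mean against the lower limit instead).
S4 takes precedence, S2 is the 2–4-fold band, and genes qualifying
nowhere are EE, so {EE, S2, S4} partition the gene set. Chromosome- and
genome-level balance are summarized as CRR and NRR, the per-contig and
global ratios of summed per-nucleus FPKM.

# Variant partitioning and the editing negative control

At each read base over a known site: bases under Phred 30 (or Ns) are
discarded; where the parents agree and the read disagrees, the site is
an RNA-editing / technical candidate (`both_diff`); where the parents
differ, a base matching exactly one parent is an allele marker for that
parent. A base matching *neither* parent at a differing site is also
routed to the candidate stream but flagged `third_allele` — the source
rules are silent on this case and the flag preserves the information.
The partition is exhaustive and exclusive by construction and is
verified by enumerating every (base, alleles, Phred) combination.

Editing candidates are aggregated per site into variant read support
(VRS), total read support (RS) and relative variant frequency
(RVF = VRS/RS), filtered at configurable thresholds, and scored for
A→I compatibility (A→G on the annotated transcript strand, T→C on the
minus strand; strand comes from annotation, not read inference). The
default thresholds (VRS ≥ 3, RS ≥ 10, RVF ≥ 0.1) are explicit artifact
defaults — the published filter cascade's exact values are not
reproduced here — and the retained-candidate A→G fraction is the
statistic of interest: mismatches planted uniformly over the 12
substitution types yield a fraction statistically indistinguishable
from 1/12, the negative-control analogue of the published finding.

# Orthology and conserved orthogroups

Hits are filtered by asymmetric coverage (≥ 0.2 of the longer protein,
≥ 0.8 of the shorter), which drops aspecific hits while keeping gene
fragments. Families are Markov-clustered at inflation 2.0 on a graph
weighted by Nident/qlen. The MCL implementation adds self-loops at each
vertex's maximum incident weight (standard stabilization), column
normalizes, alternates expansion and inflation with pruning at 1e-8,
and reads clusters from the connected components of the converged
matrix; clusters and members are ordered lexicographically, so the
partition is independent of input order. Non-convergence at the
iteration cap returns the current partition with a warning.

Single-copy orthogroups are built from reciprocal best hits at
e ≤ 1e-5, with best-hit ties broken by bitscore, then e-value, then
label (determinism; the source is silent). A member is spurious when
its bitscore to the seed is at least three times lower than the mean of
the other members' and it shares < 50 % of its hits with the seed's;
the filter removes the worst offender and re-evaluates to a fixed
point, so the outcome does not depend on member order. An orthogroup is
a conserved developmental orthogroup when developmentally expressed
(FC > 2) in ≥ 4 species with proportion ≥ 0.5; the proportion's
denominator defaults to the species *possessing* the orthogroup (the
phrase is ambiguous; the presence-based denominator keeps the rule
meaningful for patchy orthogroups) with the all-species denominator as
a switch. Conserved orthogroups split into *shared* (outgroup ortholog
developmental at FC > 2), *cm_missing* (absent from the outgroup) and
*cm_nondev* (present, not developmental); the three categories are
additive over the conserved set. Upstream-region divergence between
parental alleles is quantified as percent identity of a global
end-to-end alignment (match +1, mismatch −1, gap −2) of the region
from 1 kb upstream to 200 nt downstream of the transcription start.

# The synthetic world

The generators produce every pipeline input with planted ground truth,
under a default design of VM plus five fruiting-body groups (P1, P3,
YFB, FB cap and stipe), three replicates each — the stage/tissue
structure of a resolved mushroom series.

* **Expression**: gene baselines are N(4, 1.5) on the log2 scale
  (median ~16 FPKM, so planted genes are comfortably detectable);
  replicate noise is lognormal with sd 0.25 log2 units (typical
  replicate scatter); 20 % of genes get one non-VM group boosted by a
  fold change uniform on [4, 16]; 5 % get the boost in VM instead, to
  exercise the exclusion rule (these carry `vm_max = TRUE` and are not
  counted as developmental truth, keeping the truth-table invariant
  `planted_fc = 1 ⇔ not developmental` intact).
* **Allele counts**: per gene/sample totals are Poisson(200); 20 % of
  reads are withheld as indecisive; decisive reads split binomially at
  the gene's true AS ratio — 0.5 for EE, uniform over the 2–4-fold
  band (0.69, 0.80] (or its mirror) for S2, beyond (0.80, 1] for S4 —
  constant across samples of a gene.
* **Reads**: each read observes the variants in a window from a random
  site; bases flip to a uniformly chosen other base at the error rate;
  truth records the parent of origin.
* **Orthogroups**: born on a uniformly chosen tree node, inherited by
  descendant species minus independent losses; groups losing the focal
  species are redrawn. The recorded true age is the birth node's
  projection onto the numbered path, which is exactly what age
  assignment recovers when nothing is lost.

What the synthetic world does **not** emulate: real genome sequences
and alignment artifacts, library-size and normalization effects (the
generator emits FPKM directly), stage-dependent AS ratios,
overdispersed counts, or correlated gene modules. A green recovery
test therefore establishes that the classifiers invert the generative
rules at realistic noise — not that they would reproduce any particular
dataset's counts.

One boundary effect is worth knowing about and is quantified by the
acceptance suite: planted S2 ratios extend to the fourfold boundary
0.80 inclusive, while the S4 call takes the maximum of six per-group
geometric means, each with sd ≈ 0.02 at depth 200. Planted S2 genes
within a couple of centiles of 0.80 are therefore frequently called S4
(never EE), which caps S2 exact-class recovery around 80 % in this
world even though the classifier applies its rule exactly. S4 recovery
and the EE→S4 false-call rate are unaffected (≥ 95 % and ≤ 1 %).

# Numerical choices and degenerate inputs

* Fold-change pseudo-floor 0.1 FPKM; ratios of two silent groups are 1.
* Geometric means are computed on raw ratios; a replicate AS of exactly
  0 or 1 at S4 depth would zero the mean — masked replicates (the only
  realistic source of extreme ratios at low counts) already break the
  group before that happens.
* Exact Mann–Kendall p-values switch to the tie/continuity-corrected
  normal approximation above n = 10 or under ties.
* MCL pruning at 1e-8 and convergence at max-absolute-change < 1e-6;
  attractor ties cannot arise in the outputs because cluster read-out
  uses symmetrized components.
* A read covering zero SNPs is indecisive (tie at 0–0) and counts into
  the indecisive pool, as unassigned reads do in the source pipeline.
* Zero denominators (CRR/NRR, AS with no decisive reads, empty age
  strata) are reported missing rather than fabricated.
* Coordinates are 1-based inclusive end to end — the R/VCF convention;
  the only half-open arithmetic (simulated read windows) is internal to
  the generator.

# Known limitations

* The RNA-editing stage implements only the variant-partition front
  end and the configurable VRS/RS/RVF filters, not the full published
  filter cascade (poly-A proximity, alignment diagnostics); its
  thresholds are explicitly non-canonical defaults.
* `build_rbh_groups` assembles star-shaped groups around seed-species
  proteins; it does not attempt multi-seed transitive merging.
* The pipeline orchestrator chains the expression/age/ASE stages; the
  orthology operations are exposed as functions (and fully tested) but
  are not part of the default synthetic run, which generates no
  proteome-scale hit tables.
* Species-tree inference, normalization (TMM), alignment, and dN/dS
  are out of scope; the package consumes their outputs.
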