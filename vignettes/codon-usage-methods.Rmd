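---
title: "Methods: codon usage bias and host co-adaptation in cubtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: codon usage bias and host co-adaptation in cubtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cubtools)
```

## Scope and model

`cubtools` quantifies codon usage bias (CUB) in parasite coding sequences
and its relationship to a host's codon usage. The unit of analysis is a
validated coding sequence (CDS) decomposed into codons under the standard
genetic code (NCBI table 1); analyses run per organism over a list of
parasite collections plus exactly one host collection. The package does not
model phylogeny or sequence evolution: every statistic is a function of
codon counts, so two genes with equal counts are equivalent everywhere.

Throughout, the 59 codons belonging to a synonymous family of size k ≥ 2
(9 two-fold, Ile's three-fold, 5 four-fold, and the whole six-fold Leu,
Ser, Arg families) carry all family statistics. Stop codons and the
single-codon amino acids Met (ATG) and Trp (TGG) are counted but never
enter family statistics — a stop has no synonymous family, and a family of
size one carries no usage information. Six-fold families are treated as
single k = 6 families everywhere, never split into 4+2 sub-boxes; one
convention, applied uniformly to ENc, RSCU, and every per-family
statistic, keeps indices comparable across functions.

## Input validation and QC

`validate_cds()` upper-cases, drops a trailing partial codon (1–2 nt) with
a warning, rejects sequences containing any non-ACGT character, and keeps
but flags sequences with internal stop codons. Rejection rather than codon
masking keeps every downstream count denominator exact; the cost — losing
sequences with a single ambiguity code — is acceptable for CDS sets, which
are typically clean. Internal stops are retained because they are often
annotation artifacts near sequence ends and removing the whole gene would
bias length distributions; since stops carry no family statistics, they
are harmless downstream. Every parsed sequence appears in the QC report as
retained, rejected, or filtered, and the three counts always sum to the
parsed count.

`filter_by_length()` bounds are in amino acids (codons), inclusive on both
ends. Length units are stated explicitly in the function documentation
because length cutoffs quoted in the literature are sometimes nucleotide
counts; the amino-acid reading is used consistently here.

## Gene-level indices

Wright's ENc uses per-family homozygosity `F = (n·Σp² − 1)/(n − 1)` for
families with n ≥ 2, class averages within degeneracy classes, and
`ENc = 2 + 9/F̄₂ + 1/F̄₃ + 5/F̄₄ + 3/F̄₆` capped at 61. Missing-class
rules: amino acids with n < 2 are dropped from their class average; an
empty three-fold class (Ile unused) is replaced by (F̄₂ + F̄₄)/2; an empty
two-, four- or six-fold class makes the estimator undefined (`NA`) — the
modified estimator is the intended fallback for short genes. The modified
ENc computes `F = Σp̃²` from pseudocounted frequencies
`p̃ᵢ = (nᵢ + 1)/(n + k)` for every family (absent families contribute
their uniform value 1/k), so it is defined on any non-empty gene.

MILC, B, MCB, CAI, MELP, FOP and E follow the formulas in the README. Two
shared conventions matter more than the individual formulas:

* **Reference pseudocount policy.** Whenever any codon of a family has
  zero count in a reference table, 1 is added to every codon of that
  family (only). This keeps reference frequencies and CAI weights strictly
  positive without disturbing well-observed families, and it is applied
  identically in MILC/B/MCB references, CAI weights, and host frequencies
  for RCDI. A warning reports the families touched.
* **Host-free reference.** When no host is supplied, MILC, B and MCB use
  the organism's own pooled codon counts as the implicit reference (tables
  record `reference_used = "self"`). Pooling, rather than per-gene
  self-reference, measures each gene against its genomic background —
  the standard use of these statistics. CAI, FOP, MELP, E, RCDI and SiD
  are meaningless without a reference set and refuse to run host-free.

E's identity case (gene equal to both background and reference) is 0/0;
it is defined as 1 there, matching the index's interpretation of 1 as
"equally close to both". MELP is `NA` when the denominator MILC is not
positive, which occurs only for genes essentially identical to the
reference.

RCDI takes host per-family codon frequencies, not any ENc value: the
deoptimization index is defined on frequencies, and the package's API
reflects that. Note that RCDI's per-family plug-in frequency estimator has
an upward O(Σ(k−1)/N) bias — about 1.4% at 3,000 codons and proportionally
larger for short genes — so organism means, not single short genes, are the
right identity diagnostic.

## Dinucleotide permutation z-scores

For each record and dinucleotide d, `z_d = (obs_d − mean) / sd` over the
permutation distribution of the overlapping count (windows cross codon
boundaries; the standard convention), with sd using the n − 1 denominator.
The statistic is the **count**, not the frequency: under fixed-length
permutation the two are equivalent, and the count-based contract stays
well-defined under resampling too. Cells with zero permutation sd are
`NA` (undefined), never 0 — a homopolymer is not evidence of neutrality.

Null models: base shuffling (permutation or resampling of bases), codon
shuffling (frame-preserving), and synonymous-codon resampling, which draws
each codon uniformly from its synonymy group (stops resample among stops)
and therefore preserves the protein exactly. Defaults are 100 permutations
and shuffling without replacement. Each record derives its own RNG stream
from a hash of (global seed, organism, id), so results are independent of
collection order and reproducible bit-for-bit. Synonymous resampling uses
uniform family weights; organism-weighted resampling is out of scope.

The suite checks calibration by generating records from the syncodon null
itself (500 records of 150 codons, 100 permutations) and verifying that
per-dinucleotide rejection at |z| > 1.96 lands in [0.03, 0.08].

## Composition diagnostics

PR2 coordinates use third positions of the five four-fold families only
(Ala, Gly, Pro, Thr, Val) when `fold4_only = TRUE` — the conservative
reading that excludes six-fold families' four-fold sub-boxes, whose third
positions are not fully unconstrained. Stops are excluded there (no stop
is in a four-fold family) but included in plain position-3 tallies. Points
with a zero denominator are excluded with a warning rather than plotted at
infinity.

The neutrality fit is ordinary least squares of GC12 on GC3 with the
two-sided t-test p-value for the slope. Both R² and R are reported, since
figures in the field label either. The fit requires n ≥ 3 and non-constant
GC3.

The ENc–GC3 reference curve is `ENc*(s) = 2 + s + 29/(s² + (1 − s)²)`,
sampled at 512 points and capped at 61 for display consistency. The curve
is *not* symmetric about s = 0.5 (the linear `+s` term breaks symmetry);
its maximum 60.5 is at s = 0.5.

## Multivariate analysis

PCA runs on centered, unscaled organism-mean RSCU rows (plus one host
row). RSCU is already normalized within families, so unit-variance scaling
would overweight rare families; a `scale.` flag exists for users who want
it. Rows default to organism means — one point per organism, matching the
single-point-per-organism display the analysis feeds — with a
`per_sequence` option. Component signs are fixed by forcing each
component's largest-magnitude loading positive, making scores reproducible
across linear-algebra backends. K-means uses 25 restarts under the caller's
seed; hierarchical clustering accepts the stats::hclust linkage spellings,
including "ward.D" (Ward on squared Euclidean) and "ward.D2" (unsquared).
Heatmap distances handle undefined cells pairwise; all-undefined rows are
dropped with a warning.

## Synthetic data generator

`simulate_cds_collection()` draws each sequence as ATG + body + TAA, with
body amino acids sampled from a declared composition (default: uniform
over the 18 degenerate amino acids, which keeps every family statistic
well populated at modest lengths) and codons drawn from the within-family
normalization of a weight profile. The generator therefore emulates
exactly the quantity the indices measure — within-family codon choice —
under an i.i.d. codon model, and records its truth (family frequencies,
expected body GC3, parameters) for recovery tests.

What it does **not** emulate: amino-acid composition of real proteomes,
codon autocorrelation along genes, dinucleotide constraints that cross
codon boundaries (CpG suppression), length/expression covariation, or
phylogenetic structure. Passing tests on generated data therefore validate
the *estimators* — their formulas, ranges, identities and calibration —
not any biological claim about real parasites.

Default study conditions used by the test suite and the acceptance script:
parasite collections of 4–15 genes of 100–350 codons, hosts of 6–20 genes
of 250–400 codons, identity checks at 3,000 codons, calibration at 500
records × 100 permutations, slope recovery at n = 200 genes. These sizes
give each statistic enough data to be well-defined while keeping the whole
suite at desk scale (about a minute).

## Degenerate inputs and tie-breaks

* One-codon genes: Wright ENc undefined, modified ENc defined; CAI/FOP
  defined when the gene has ≥ 1 family codon.
* Optimal-codon ties in FOP: all tied codons are optimal, reported via a
  message.
* Zero-norm RSCU vectors make SiD an error (not 0.5): they arise only
  from empty genes, which is a caller error.
* Duplicate FASTA ids are suffixed `_1`, `_2`, … with a warning; header
  truncation at the separator never silently merges records.

## Limitations

* Standard genetic code only; organisms with alternative codes (e.g.
  mitochondrial genomes) are out of scope.
* One host per analysis; multi-host co-adaptation contrasts require
  separate runs.
* tAI, codon-pair bias, correspondence analysis and Karlin's dinucleotide
  odds ratios are deliberately not implemented.
* The dinucleotide z-score measures deviation from a *sequence-local*
  null; it does not correct for genome-wide composition.
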