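---
title: "Methods: quantifying processing escape from somatic missense variants"
author: "procescape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying processing escape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(procescape)
```

## The problem

Antigen presentation by MHC class I begins with proteasomal degradation:
the proteasome's catalytic β-subunits cut preferentially after particular
residues, and the C-terminus of a presented epitope is fixed by such a
cut. A somatic missense mutation near a candidate epitope can therefore
abolish presentation without touching the epitope's MHC anchor residues,
simply by removing the cleavage site that liberates it — or it can leave
presentation intact but destroy T-cell recognition. Tumours enriched for
such *processing mutations* acquire an immune-escape route that is
invisible to PD-L1 assays. This package turns that idea into a concrete,
testable pipeline and couples it to the cohort-level statistics (burden
dichotomization, prevalence comparison, survival regression) used to ask
whether processing escape carries prognostic information.

## Pipeline and assumptions

The stages run strictly in order; each consumes only tabular outputs of
its predecessors, and every stage is exposed as a plain function.

**Variant evidence.** Calls are read per ALT allele from VCF; the VAF is
always recomputed from allele depths when both `AD` and `DP` are present,
because depth is what the filters reason about. The filters — total depth
> 500, variant depth > 20, 3% < VAF < 90%, then VAF > 25% for the
processing arm — are all strict inequalities ("above"/"below"), so
boundary values are excluded. The upper VAF bound discards
formalin-fixation artifacts; the 25% selection restricts to clonally
prominent mutations whose epitopes are actually produced at scale.

**Missense annotation.** Only single-nucleotide substitutions whose codon
translates to a different non-stop amino acid are annotated; nonsense,
synonymous and non-coding changes are dropped, and indels or fusions are
expected to enter the clinical table as pre-made annotations. Every
transcript variant is annotated independently; de-duplication to the
genomic variant happens only at patient aggregation, so an isoform-rich
gene does not inflate a patient's mutational load. Coordinates are
1-based genomically (VCF convention) and 1-based in CDS/protein space;
minus-strand transcripts complement the genomic alleles before codon
lookup.

**Epitope space.** The analysis is local by design: only windows covering
the mutated residue are generated, because a single substitution cannot
change cleavage probabilities far from itself under a position-weight
model. For length $k$, a position $p$ in a protein of length $L$ yields
$\min(k,\, p,\, L-p+1,\, L-k+1)$ windows (verified against brute force in
the tests). Epitope lengths and flank width are configuration: length 9
is the default (the canonical class I length; lengths 8–11 are
supported), and 10 flanking residues per side cover the neighbourhood a
cleavage model with a ±2 window can ever see, with margin for wider
models.

**Cleavage scoring and the 50% rule.** Both backends satisfy one
contract: a per-residue cleavage probability vector over the flanked
peptide. The internal backend is a logistic position-weight model,
$P(\text{cleave after } i) = \sigma(b + \sum_o W[o, a_{i+o}])$, with a
strong preference for cutting after hydrophobic, aromatic and basic
residues. Its weights are an in-package scoring scheme, documented and
shipped as delimited text — *not* the trained weights of any external
neural-network predictor; numerical reproduction of such predictors is a
non-goal. The external backend parses whitespace/tab-delimited
position–residue–score tables produced elsewhere, validates the residue
column against the context, and clips scores into [0, 1] with a warning.

The decision rule — "altered processing" when wildtype and mutant
cleavage probabilities differ by 50% — is read as an **absolute**
probability difference ≥ 0.50, assessed at the epitope's **C-terminal
cleavage site**. Both readings were genuinely open: the absolute reading
is scale-free given probabilities in [0, 1] and keeps the rule symmetric
in wildtype and mutant; the C-terminal site is where the proteasome fixes
an epitope's boundary, and the C-terminal-trained model family is the
primary one in this analysis tradition. A relative-difference rule and an
all-positions site policy remain available as configuration
(`rule = "relative"`, `sites = "all"`). A mutation's verdict is the OR
over all of its windows and transcripts: one altered epitope suffices to
change what is presented.

**Presentation and fate.** Binding uses additive position-specific
matrices on the log10-IC50 scale, one per supertype representative (A01,
A02, A03, A24, A26, B07, B08, B27, B39, B44, B58, B62 — the canonical
12-supertype panel; the panel is config-driven) and per length 8–11. The
shipped matrices are motif-style: anchor preferences at position 2 and
the C-terminus, baseline intercept log10(50 000 nM), so a peptide
matching both anchors falls below the standard 500 nM binder cut-off and
one matching neither is a clear non-binder. They are deterministic
in-package models, again not a re-trained affinity predictor. Binding is
any-allele: an epitope is "lost" only when *no* panel allele binds at
the threshold.

Immunogenicity is a masked positional sum: anchor positions 1, 2 and the
C-terminus contribute zero (they face the MHC groove, not the TCR), and
interior positions contribute weight × amino-acid enrichment, with
aromatic/large-hydrophobic residues enriched. The TCR rule declares a
mutant epitope activating when its score strictly exceeds
$\bar{s}_{wt} - 2\,\mathrm{sd}(s_{wt})$ over the mutation's **entire**
wildtype window set (all windows, all transcripts). Two conventions were
open and are fixed as: strict `>` for "exceed", and the **population**
standard deviation (denominator $n$) — the wildtype window set is the
complete population of correspondents for that mutation, and the rule
then stays well-defined for a single wildtype window, degenerating to
`mut > wt`. The three fates (`lost_binding`, `bound_not_immunogenic`,
`bound_immunogenic`) are a partition by construction, and the tests
assert the counts sum to the altered-epitope total on every run.

**Cohort statistics.** Burden groups follow the stated rule — none /
exactly one ("low") / more than one ("high") — with a merged two-level
view (high vs low∪none) for survival contrasts. TPS categories are <1,
1–49, ≥50; missing TPS maps to "unknown" and leaves that variable's
denominator. Summary percentages round **half-up** at the precision the
source tables print (1 decimal, integers for the epitope-fate
fractions); R's default half-to-even rounding reproduces several printed
values incorrectly, which is why the package carries its own rounding
helper. Fisher's exact test reports the sample cross-product odds ratio
(the conditional MLE is available as an option) with a two-sided p from
exhaustive hypergeometric enumeration — tables with probability at most
the observed one, using the conventional $1 + 10^{-7}$ tolerance factor
so that ties of equal probability are included despite floating-point
noise. Zero marginals flag the OR as undefined; the Haldane–Anscombe 0.5
correction is opt-in, never silent.

**Survival.** Kaplan–Meier, logrank and Cox models delegate to the
`survival` package behind thin module surfaces. Ties are handled by
Efron's method — unstated in the source analysis, but the standard
default and the accurate choice for month-granular times. Each fit
reports hazard ratios with 95% CIs and all three whole-model tests
(likelihood-ratio, score/logrank, Wald); the score test on a single
binary covariate equals the logrank statistic, which the tests assert
numerically. Non-convergence or separation (infinite coefficients) flags
the fit and suppresses hazard ratios rather than reporting garbage.
Within each model the per-covariate p-values are Benjamini–Hochberg
adjusted; significance is read at 0.05 after adjustment. Advanced-stage
subset models drop surgery as a covariate, since advanced-stage patients
do not receive surgery as primary therapy and the covariate degenerates.
The mutational-load high/low cut-point is not specified anywhere for
loads (only for processing burden), so it is an explicit configuration
parameter (`load_cut`, default 1).

## The synthetic generator: what it emulates, and what it does not

The generator exists because the study's individual-level data are
unpublished; only marginal counts are printed. Its defaults are therefore
*paper-shaped*: 179 patients; per-patient missense counts concentrated on
0/1/2 (masses 0.25/0.28/0.27, tail to 5) so the burden density shows the
reported low-count maxima; processing fraction 146/302 among missense
mutations; TPS categories at the exact reported fractions 32/41/106 of
179; a 0.508 advanced-stage share; immunotherapy rare (7%) as in the
cohort. Survival is exponential with log-linear hazard in burden, stage
and therapy (default true HRs: 2.0 for high burden, 2.2 for advanced
stage, protective effects for chemotherapy/surgery), baseline median 20
months, uniform administrative censoring over 120 months. Where the
source states no value (therapy rates, hazard magnitudes, censoring),
the defaults were chosen once as clinically plausible for an aggressive
NSCLC cohort and are not tuned thereafter.

Ground truth is **exact, not probabilistic**: the default cleavage model
assigns identical weights to all residues within a cleavage class
(strong = F L I V M W Y K R, weak = the rest) at every offset, with ±3
logits at the cut position and ∓0.1 at neighbours. A planted
processing-positive mutation is a single-nucleotide, cross-class
missense change: in the window ending at the mutated residue, the
cleavage probability at the C-terminal site moves by at least
$|\sigma(x+3)-\sigma(x-3)| \ge 0.89$ for any neighbour context $x \in
[-0.4, 0.4]$, always clearing the 0.5 threshold. A planted negative is a
within-class change, which leaves every profile bit-identical (delta
exactly 0). Mutations are planted at least 12 codons from either
terminus so the full window set exists. This is a co-design contract —
the tests require ≥ 99% end-to-end agreement between planted flags and
pipeline calls, and structurally the agreement is 100%.

What the generator does **not** emulate: read-level sequencing noise
(depths and VAFs are drawn directly), germline variation and clonal
structure, linkage between nearby mutations (each is planted
independently; multi-mutant peptides are a stated non-goal), dependence
between burden, stage and therapy (generated independently — the joint
distribution is unpublished), and the 4/179 patients without molecular
data. Passing tests on synthetic cohorts therefore demonstrate the
pipeline's internal correctness and the statistics' calibration, not
that any particular real cohort will show the reported effect sizes; the
printed cohort percentages are reproduced from the transcribed count
fixture, never from simulation.

## Numerical choices and degenerate inputs

* Sub-seeds for every stage are derived deterministically from one user
  seed (kept below $2^{31}$); identical configuration implies
  byte-identical outputs, which the tests assert via file checksums.
* Cleavage offsets outside the flanked context are skipped (no padding
  residue is invented); unknown residues are an error by default, or
  zero-weight with a warning.
* The conditional-MLE odds ratio solves the noncentral hypergeometric
  mean equation by bisection on the log scale with weights normalized by
  their maximum, so extreme tables do not overflow.
* `km_estimate` defines the median as the first time with $S \le 0.5$,
  `NA` (never reached) when the curve stays above.
* Degenerate cases: proteins shorter than the smallest epitope length
  yield an empty window set with a warning; an empty variant table flows
  through every stage as empty tables, not errors; constant covariates
  and zero-event strata are rejected before fitting.

## Problem sizes in the tests

The suite exercises the pipeline at sizes chosen to make the statistical
assertions sharp while staying desk-scale: exhaustive substitution of a
29-codon transcript against a translation oracle; 1 000 random
window-count triples; all 46 375 contingency tables with total ≤ 30
against exhaustive enumeration; 200 Cox cohorts of n = 300 for
parameter recovery and coverage; 1 000 null simulations of n = 100 for
the type-I error of the score test; and a 200-patient end-to-end cohort
for the planted-truth contract.

## Known limitations

* The shipped cleavage, binding and immunogenicity models are
  motif-style stand-ins with documented, deterministic coefficients;
  absolute IC50 values and cleavage probabilities are not comparable to
  trained predictors, and real-data analyses should parse external
  predictor output through the provided readers instead.
* Phasing of nearby somatic variants into combined mutant peptides is
  not attempted.
* The exact 2×2 cell counts behind the published cohort-comparison odds
  ratios are not printed, so those odds ratios are not asserted
  anywhere; the comparison machinery itself is tested against exact
  enumeration.
* MHC class II, pan-allele binding prediction, time-varying covariates
  and competing risks are out of scope.
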