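# procescape

Tumour cells escape T-cell killing in more ways than expressing PD-L1. A
missense mutation can change how the proteasome cleaves the protein around
a candidate neo-epitope, so that the altered peptide is never generated,
no longer binds any MHC class I supertype, or binds but fails to activate
a T-cell receptor. Such **processing mutations** constitute a
PD-L1-independent immune-escape mechanism with prognostic relevance in
aggressive lung tumours, notably pulmonary sarcomatoid carcinoma (PSC).

`procescape` implements the full analysis for a patient cohort, from raw
somatic variant calls to survival correlates, for bioinformaticians and
translational researchers who want to quantify processing escape in their
own cohorts or study the method's statistical behaviour on synthetic data.

## The method

1. **Evidence filtering.** Somatic calls are kept when read depth > 500,
   variant-supporting depth > 20 and 3% < VAF < 90% (the upper bound
   excludes fixation artifacts); calls enter the processing analysis only
   with VAF > 25%. All four thresholds are strict.
2. **Missense annotation.** Retained SNVs are projected onto transcript
   models (codon-level, strand-aware, one annotation per transcript
   variant).
3. **Epitope space.** For each mutation, every k-mer window (default
   k = 9) covering the mutated residue is enumerated, wildtype and mutant
   side by side, with up to 10 flanking residues per side — a mid-protein
   position yields min(k, pos, L − pos + 1, L − k + 1) = k windows.
4. **Processing call.** Per-position proteasomal cleavage probabilities
   are computed for both flanked peptides (matrix backend, or parsed from
   an external predictor's output). A window has *altered processing*
   when the cleavage probabilities at its C-terminal cleavage site differ
   by at least 0.50:

   |P(cleave | wildtype) − P(cleave | mutant)| ≥ 0.5

   A mutation is a processing mutation when any of its windows is altered.
5. **Epitope fate.** Each altered epitope is scored against the 12 MHC
   class I supertype representatives (additive log10-IC50 matrices,
   binder at IC50 ≤ 500 nM) and for immunogenicity (masked positional
   weight × amino-acid enrichment). An epitope is TCR-activating when its
   score exceeds mean(wildtype scores) − 2 × sd. Fates partition into
   `lost_binding`, `bound_not_immunogenic`, `bound_immunogenic`.
6. **Cohort statistics.** Per-patient burden (none / exactly one = low /
   more than one = high), PD-L1 TPS categories (<1 / 1–49 / ≥50),
   Fisher's exact cohort comparison (sample odds ratio + exact
   enumeration p), Kaplan–Meier curves, Cox proportional hazards (Efron
   ties; likelihood-ratio, score-logrank and Wald tests) and
   Benjamini–Hochberg FDR adjustment.

A synthetic cohort generator plants processing mutations whose ground
truth is exact by construction (co-designed with the default cleavage
model), so the whole pipeline is testable without any patient data.

## Worked example

```r
library(procescape)

cfg    <- simulation_config(seed = 42, n_patients = 60)
cohort <- generate_cohort(cfg)
input  <- file.path(tempdir(), "cohort")
write_cohort(cohort, input)               # clinical.tsv, VCFs, transcriptome

report <- run_pipeline(pipeline_config(input_dir = input,
                                       out_dir = file.path(tempdir(), "results")))
print(report)
#> <escape_report>
#>   patients: 60; missense mutations: 111; processing: 51 (45.9%)
#>   altered epitopes: 68 (lost binding 57, bound/not immunogenic 0, bound/immunogenic 11)
#>   burden (high vs low/none) logrank p = 0.1351
#>   cohort Cox model: score-logrank p = 1.598e-07

print(report$cox_all)
#> <survival_fit> n = 60, events = 46
#>                 term                    hr           p
#>       burden_twohigh  3.409 [1.479, 7.860] 0.004003692
#>  stage_groupadvanced 4.189 [1.595, 11.001] 0.003643104
#>     chemotherapyTRUE  0.941 [0.504, 1.757] 0.848230355
#>          surgeryTRUE  0.382 [0.150, 0.972] 0.043361051
#>    immunotherapyTRUE  0.310 [0.038, 2.566] 0.277629818
#> LR p = 8.557e-08, score-logrank p = 1.598e-07, Wald p = 2.772e-06
```

Reading the output: 51 of the 111 simulated missense mutations altered
proteasomal processing (45.9%, matching the generator's configured
fraction of 146/302 ≈ 48%); most altered epitopes lost all supertype
binding. In the Cox model a high processing-mutation burden (more than
one) carries a hazard ratio of 3.4 for death — the generator planted a
true HR of 2 on burden and 2.2 on advanced stage, both recovered within
their confidence intervals at this small n.

The published cohort's marginal tables ship as a transcribed count
fixture; the summary stage recomputes each percentage:

```r
head(cohort_summary(paper_fixture())[, 2:7], 3)
#>   variable category count denominator percentage
#> 1      age     le60    54         179       30.2
#> 2      age     gt60   125         179       69.8
#> 3      sex      men   105         179       58.7
```

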