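---
title: "Genomic scars, UPD and double hits in transformed SCLC exomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic scars, UPD and double hits in transformed SCLC exomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sclcscars)
library(dplyr)
```

## The analysis problem

Small cell lung cancer (SCLC) can arise de novo, or by histological
transformation from an EGFR-mutant lung adenocarcinoma (LUAD) under the
selective pressure of EGFR tyrosine-kinase inhibitors. The two routes
produce tumours with the same morphology but different genomic histories:
transformed SCLC inherits the EGFR-mutant clone of its LUAD ancestor, while
de novo SCLC typically carries a heavy smoking-associated mutation load.
Whole-exome sequencing of the three tissue types — primary LUAD before
transformation, transformed SCLC, and de novo SCLC — lets those histories
be read out as somatic mutations, allele-specific copy-number changes,
genomic-scar scores and mutational signatures.

`sclcscars` implements the downstream analysis stack for that comparison:

1. consensus filtering of dual-caller somatic variant calls (with a
   panel-of-normals path for tumour-only samples),
2. allele-specific copy-number classification, with copy-neutral LOH
   (uniparental disomy, UPD) as a first-class state,
3. chromosome-arm event calling and genome-wide SCNA fractions,
4. genomic-scar scores (HRD-LOH, telomeric allelic imbalance, large-scale
   state transitions) and their sum, the HRD score,
5. Knudson double-hit integration of mutations (Event 1) with copy loss or
   UPD (Event 2),
6. 96-context mutational-signature deconvolution by non-negative least
   squares,
7. tumour mutational burden and cohort statistics (exact Wilcoxon and
   Fisher tests, BH adjustment).

Upstream steps — read processing, alignment, the callers themselves
(MuTect2/VarScan2 roles), ASCAT/CNVkit segmentation, annotation — are
consumed as inputs, not re-implemented.

## Variant filtering

A variant from a matched tumour/normal pair is considered a valid somatic
mutation when

* both callers report it, with somatic p-value $\le 0.1$ for SNVs and
  $\le 0.05$ for INDELs and tumour VAF $> 2\%$; **or** the solo-rescue
  caller (the VarScan2 role, caller B) alone reports it with tumour VAF
  $> 5\%$;

and it additionally passes all of: matched-normal VAF $< 1\%$,
alt-supporting reads in the normal $< 5$ (SNV) / $< 2$ (INDEL), no overlap
with simple-repeat/segmental-duplication regions (tested on the variant
start position), and minimum population allele frequency across the
annotation databases $< 1\%$. Inclusive ($\le$) versus strict ($<$, $>$)
boundaries follow the rule text exactly and are asserted in the tests at
the boundary values.

Three interpretation points were genuinely open and are resolved as
follows, all configurable:

* the "VAF below 1%" germline rule is read as a gate on the matched-normal
  VAF (germline leakage), consistent with the adjacent normal-read rule;
* the solo-rescue role is a parameter (`solo_vaf`, caller B by default)
  rather than a hard-coded caller name;
* when both callers report a variant, evidence fields are taken from
  caller B (which natively carries the somatic p-value), falling back to
  caller A; missing normal evidence passes the germline gates.

The tumour-only path fails closed: a candidate must be absent from the
panel of normals, at or below 0.001 population frequency in both the 1000
Genomes and gnomAD fields, and either judged damaging by SIFT or PolyPhen
or truncating. Candidates with no annotation at all are rejected with a
warning, because this path is defined as the stricter one.

## Copy-number states and arms

Segments carry a total and a minor-allele copy number. Against a diploid
reference (`ploidy_ref = 2`; tumour-ploidy adjustment is deliberately out
of scope and flagged as a knob):

* `upd` — total 2, minor 0: copy-neutral LOH;
* `loss` — total below 2; `gain` — total above 2;
* `is_loh` — independent flag for minor 0 with at least one copy left.

Tumour-only log-ratios are discretised to copy number 0-4 at the fixed
cut points $-1.1, -0.4, 0.3, 0.7$, with lower-exclusive/upper-inclusive
bins (only the four cut points are prescribed; the bin closure is our
choice, asserted in tests).

Arm-level events use the bundled hg19 arm table: 22 autosomes, acrocentric
p arms (13, 14, 15, 21, 22) excluded, 39 analysable arms. An arm carries a
state when at least half its length (configurable `min_fraction`) is
covered in that state; ties break by covered fraction, then by the
priority UPD > loss > gain. Segments crossing the centromere are split at
its edges first. SCNA fractions are plain bp ratios over the arm-table
genome and are deliberately not forced to sum to one.

## Scar scores

The three scar components follow the published conventions the HRD score
is built on:

* **HRD-LOH** — LOH regions longer than 15 Mb (strictly greater; the
  standard convention for the printed "15 Mb") that do not span a whole
  chromosome. Touching LOH pieces merge into maximal regions; a gap lying
  exactly over the centromere is bridged, so a chromosome LOH on both arms
  forms one whole-chromosome region and is excluded. Region length is
  covered bp; the whole-chromosome test compares against the chromosome's
  analysable arm bp with a 1 bp tolerance.
* **TAI** — maximal allelic-imbalance regions ($2\,n_{minor} \ne
  n_{total}$) clipped to arms (hence never crossing the centromere) that
  reach the arm's telomeric end within 1 kb and exceed a 1 Mb noise floor.
  No upper bound and no whole-arm exclusion is applied.
* **LST** — after dropping sub-3 Mb pieces and re-merging equal-state
  neighbours, each junction between two regions of at least 10 Mb
  separated by at most 3 Mb counts one transition; computed per arm, so no
  break is ever counted across the centromere.

The source text paraphrases these definitions without operational details
(smoothing, size floors, boundary closure); the defaults above are the
cited scar-calculator conventions and every one of them is a documented
argument. `hrd_score()` computes the three components from one shared
arm-clipped view and equals the standalone scores by construction — a
compositional identity the tests assert, along with merge invariance
(splitting any segment into same-state halves changes nothing) and
equality with brute-force interval-scan oracles on random profiles.

## Double hits

For each gene, a somatic mutation is Event 1 and a copy loss or UPD over
the locus is Event 2; `double_hit = Event1 AND Event2`. A gene carries an
Event 2 state when at least half of its body (configurable) lies in
segments of that state, with UPD taking priority over loss when both
qualify — copy-neutral LOH is the second hit of interest here. The cohort
double-hit rate divides by mutated samples only, matching the way such
rates are quoted (e.g. the share of TP53-mutant samples that also lost or
UPD'd 17p13.1). Biallelic mutation-plus-mutation cases are not counted as
double hits: calling them requires phasing, which exome data does not
give. Pathway summaries count member genes per state for the six DNA
damage repair pathways (BER, NER, FA, HRR, NHEJ, MMR), Notch and
stem-cell/ADC-target sets; per sample the counts partition the gene set.

The bundled `demo_genes()` table carries approximate hg19 coordinates for
a 23-gene demonstration panel; real analyses should supply their own gene
BED.

## Signatures

Spectra are built by collapsing SNVs onto the pyrimidine strand into the
canonical 96 trinucleotide contexts. Exposures are fitted by non-negative
least squares on the normalised spectrum: the printed method is "multiple
linear regression", but signature activities are mixture weights and
cannot be negative, so the constrained fit is the faithful reading (it is
also what the cited deconvolution tool does). Signatures whose normalised
weight falls below `drop_threshold = 0.06` (the conventional minor-
signature cut, configurable) are removed and the rest refitted until
stable; final weights are renormalised to sum one and the residual norm is
reported. The fit is deterministic — an active-set NNLS solve with no
random initialisation — so repeated fits are bit-identical.

The packaged `toy_signature_matrix()` is a synthetic four-column stand-in
(CpG-focused SBS1-like, C>A-heavy SBS4-like, broad SBS5-like, flat) built
in code for tests and examples; the real COSMIC catalogue is user-supplied
input via `read_signature_matrix()` and was never vendored. Which
signatures enter the fit defaults to every column of the supplied matrix.

## Statistics

TMB divides qualifying mutations by a 38 Mb exome (the target size of the
capture design named in the study methods; the exact denominator is not
printed, so it is an argument). Nonsynonymous-only counting is the
default, also configurable, since the source does not state whether
synonymous calls were included. Continuous omics features are compared
with the two-sided Wilcoxon rank-sum test (exact for small tie-free
samples, normal approximation with tie and continuity correction
otherwise); proportions use Fisher's exact test with the probability-mass
two-sided definition and the conditional-MLE odds ratio. The frequency
scan adds Benjamini-Hochberg adjustment across features as a safeguard and
reports raw p-values alongside. Degenerate inputs are handled explicitly:
identical groups give p = 1 with a flag, and a zero-margin 2x2 table gives
p = 1 with an undefined (NA) odds ratio.

## The synthetic cohort

No sequence data accompanies the study design this package targets, so the
generator is a first-class module that emulates its group structure: 5
primary LUAD, 10 transformed SCLC (the post-QC count) and 18 de novo SCLC
samples. The planted contrasts are the study conditions:

| parameter | primary LUAD | transformed | de novo | basis |
|---|---|---|---|---|
| EGFR mutation probability | 1.00 | 1.00 | 0.17 | reported frequencies |
| TP53 mutation probability | 0.60 | 0.70 | 0.89 | reported frequencies |
| RB1 mutation probability | 0.40 | 0.30 | 0.50 | reported frequencies |
| mean TMB (nonsyn/Mb) | 3 | 4 | 8 | free parameter; only the ordering (de novo higher) is reported |
| UPD arm rate | 0.03 | 0.15 | 0.05 | free parameter; transformed-high ordering is reported |
| loss / gain arm rates | 0.08 / 0.05 | 0.20 / 0.08 | 0.15 / 0.10 | loss > gain, gain similar across groups |
| signature mix | SBS1/SBS5 | SBS1/SBS5 | SBS1/SBS4/SBS5 | SBS4 exclusive to de novo; SBS1 ubiquitous |

Per-sample TMB values, arm rates and signature weights are nowhere printed
in the source, so the free parameters above were chosen once as plausible
desk-scale values preserving every reported ordering, and are not tuned
thereafter.

Mechanics worth knowing when interpreting test results:

* Mutation counts are Poisson around `mean_tmb * exome_mb`; trinucleotide
  contexts are drawn directly from the signature-mix columns, so no
  reference FASTA is needed and the spectra are exactly
  signature-consistent. About 20% extra synonymous and 8% frameshift-INDEL
  calls are added around the nonsynonymous core.
* Caller behaviour: 85% of true variants appear in both callers
  (`caller_overlap`), the remainder split between caller-A-only (never
  rescued) and caller-B-only calls whose VAFs straddle the 5% solo rule.
  About 90% of true variants draw a passing somatic p-value. A
  contamination class (~25% of the true burden) fails exactly one gate
  each — germline leakage, common population frequency, poor somatic
  p-value, or sub-2% VAF — giving the filter something real to remove.
  Planted driver mutations are emitted as clonal, dual-caller, high-VAF
  events, so the per-group driver frequencies survive filtering; the
  evidence lottery applies to passengers.
* Segments tile each analysable arm exactly, with events anchored at the
  telomeric end (as arm-level losses and UPDs overwhelmingly are), an
  optional same-state split (exercising merge invariance) and a neutral
  remainder. UPD/loss/gain arms are drawn per arm from the per-group
  rates, so arm-event recovery is a clean binomial problem.

What the generator does **not** emulate — and hence what green tests do
not show about real exomes: subclonality and purity/ploidy mixtures,
caller-specific error profiles, FFPE artefact spectra, interstitial
(non-telomeric) segmental events, realistic gene-level mutation hotspots
beyond the planted drivers, and correlation between mutation status and
copy-number background (Event 1 and Event 2 are planted independently, so
synthetic double-hit rates equal the product of the marginal rates rather
than the elevated co-occurrence real tumours show).

## Reproducibility and problem sizes

All randomness flows from the single integer seed in `cohort_spec()`; a
spec reproduces its cohort byte for byte, and `run_pipeline()` writes
stage TSVs plus a manifest whose reruns are bit-identical (the test suite
hashes them). The test suite runs the oracle-equivalence checks at 20
samples x 1000 variants for the filter, 500 random segment profiles for
the scar scores, and 100 seeded replicates at 50 samples per compared
group for the planted-parameter recovery — sizes chosen so the full suite
completes in a few minutes on one core while keeping the binomial error
of every recovery check well inside its assertion band.

```{r example, eval = FALSE}
cohort <- generate_cohort(cohort_spec(seed = 1))
muts <- consensus_filter_cohort(cohort$variants)
feats <- cohort_features(muts, cohort$segments, cohort$clinical)
compare_features(feats, cohorts = c("denovo", "transformed"))
```

## Known limitations

* UPD is called against a diploid baseline; in genome-doubled tumours
  copy-neutral LOH at total 4 would be labelled gain-with-LOH, not UPD.
  The `is_loh` flag and the `ploidy_ref` argument are the escape hatches.
* The arm-call and gene-overlap thresholds (0.5 of the arm or gene body)
  are conventions, not published values; both are arguments.
* Scar scores are segment-level; probe/SNP-level estimation from BAF
  tracks is out of scope.
* The demonstration gene panel and signature matrix are small synthetic
  stand-ins; conclusions about real cohorts require the real resources.
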