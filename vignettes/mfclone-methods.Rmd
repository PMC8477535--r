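---
title: "Clonality-aware marker discovery in cutaneous T-cell lymphoma: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clonality-aware marker discovery in cutaneous T-cell lymphoma: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfclone)
```

## The problem

Mycosis fungoides (MF), the most common cutaneous T-cell lymphoma, arises
from the clonal expansion of a skin-resident T cell. Within one patient, the
malignant clone can be identified from paired single-cell RNA and TCR
(VDJ) sequencing as the single most expanded clonotype, and its
transcriptome can then be compared between flat (patch) and palpable
(plaque/tumor) lesions of the same patient. Genes regulated the same way in
the malignant clone of *every* patient — but not in benign bystander T
cells — are candidate markers of disease progression. `mfclone` implements
that complete analysis as a tested, reusable pipeline: clonotype grouping,
dominant-clone calling, benign-subset gating, per-patient differential
expression, cross-patient panel intersection, and permutation-tested
ligand–receptor interaction scoring, together with a synthetic-data
generator that emulates the study design so every stage is verifiable
without access to patient data.

## Clonotype model

Cells are grouped into clonotypes by CDR3 amino-acid sequence. The β chain
(δ for γδ T cells) is the primary key: cells sharing any β CDR3 merge
transitively into one clonotype. α (γ) chains accumulate on the clonotype.
This is what handles *incomplete allelic exclusion*: a T cell can express
two productively rearranged α chains, so a clone may appear as two α
variants paired with one β chain; keying on β merges them into a single
clone. Policies the upstream literature leaves open, and our choices:

* **α-only cells** join the unique β-defined clonotype whose accumulated α
  set contains all of the cell's α CDR3s; with two or more candidates the
  cell is left unassigned (logged), never duplicated; with none it founds a
  new clonotype, merging transitively with other α-only cells that share an
  α chain.
* **Putative doublets** (more than two distinct β CDR3s) are excluded and
  reported, and count as `no_tcr` downstream.
* **Dominant clone** = the clonotype with most member cells within a scope
  (cells, not UMIs). The default scope is the patient, pooling that
  patient's samples, since the same malignant clone is expected in every
  lesion; per-sample scope exists for healthy-control baselines. Ties break
  by total UMI count, then lexicographically smallest β CDR3, so results
  are reproducible.

Clone fractions are always reported per sample among that sample's
TCR-positive (clonotype-assigned) cells.

## Differential expression

Counts are library-size normalized as `ln(1 + 1e4 * count / libsize)`
(counts-per-ten-thousand log1p; the upstream study normalized with the
standard single-cell toolchain whose parameters are not published, so this
is stated as an explicit default rather than a reproduction).

The test is a **logistic-regression likelihood-ratio test**: for each gene,
`logit P(group) = b0 + b1 * expr` against the intercept-only model, 1 df,
fitted by IRLS with at most 100 iterations and fitted probabilities clamped
to `[1e-10, 1 - 1e-10]` (perfect separation is routine for marker genes);
p-values floor at 1e-300 and constant expression returns p = 1. The suite
checks calibration (type-I error on 2,000 null genes within [0.03, 0.07])
and agreement with `stats::glm` to `|Δlog10 p| < 1e-6`.

The **log fold change** is
`ln(mean_a(expm1(norm)) + 1) − ln(mean_b(expm1(norm)) + 1)` — natural log
of pseudocounted means of de-logged normalized expression, the convention
of the ecosystem the 0.3/0.25 thresholds come from. Whether the original
thresholds were natural-log or log2 is not determinable from the published
text; natural log is the package default and is used consistently. No
latent covariates (library size, cell cycle) enter the logistic model: the
published description states only "logistic regression", and the simplest
faithful reading is a single-covariate model.

A gene is differentially expressed when the Bonferroni-adjusted p-value
(adjusted by the number of genes tested in that comparison, not per study)
is below 0.05 **and** |logFC| exceeds 0.3 (malignant-clone comparisons) or
0.25 (cluster/microenvironment comparisons). Genes are tested only when
detected in at least `min_pct = 0.1` of cells in one group (the default of
the standard single-cell DE tooling; the study's value is unpublished).

## Benign-subset gating and the marker panel

Dominant-clone cells are `malignant` regardless of markers. Polyclonal
TCR+ cells gate by normalized expression > 0 with regulatory first:
FOXP3+ → `regulatory`; else CD8A+ → `cytotoxic`; else CD4+ → `helper`;
remainder `other`.

The headline procedure runs the clone DE per patient (palpable vs patch),
then intersects: a gene enters the panel iff it is significant **with the
same direction in every patient** (strict, Venn-style intersection; the
published text implies direction consistency, and a relaxed k-of-n mode is
available but off by default). Panel genes are ordered by worst per-patient
adjusted p-value. The specificity check repeats the same per-patient DE
inside each benign subset and asks whether any panel gene is consistently
regulated there — for a clone-restricted signal the answer should be no —
and also reports each benign subset's own consistent panel. Plaque and
tumor pool into one "palpable" class by default; early-vs-advanced or
lesional-vs-nonlesional comparisons reuse the same code path with different
class labels.

## Ligand–receptor interactions

For pair *R* (ligand L, receptor X) between clusters X and Y,
`I_R(X, Y) = (mean L over all cells of X + mean receptor over all cells of
Y) / 2` on normalized expression — means over *all* cluster cells, not
only expressing ones. Pairs are evaluated only when ligand and receptor
are each detected in ≥ 10% of their cluster. The null shuffles cluster
labels over all cells of the sample (sizes preserved), `n_perm = 1000` by
default, with the add-one estimator
`p = (1 + #{permuted ≥ observed}) / (1 + n_perm)` which can never return
0. "FDR-adjusted" is read as Benjamini–Hochberg, applied within sample
across evaluated combinations. Between-lesion deltas (palpable minus
patch, per patient) are reported for combinations significant (q ≤ 0.05)
in at least one of the two samples. The pipeline evaluates each pair in
both orientations relative to the malignant clone, since published
interactions run both ways (e.g. fibroblast CXCL12 → malignant CXCR4).
Multi-subunit receptor complexes are out of scope; the pair list is flat.

## The synthetic world

`synthetic_config()` states the world the tests assume:

* 3 patients, one patch + one tumor sample each; 715 cells per sample, of
  which 70% are T cells, the rest fibroblast/myeloid microenvironment
  (60/40). With full TCR detection and clone fraction 0.6 this yields
  exactly 300 dominant-clone cells per lesion class per patient — the
  design point of the bundled dataset. The study's real clone fractions
  ranged roughly 0.48–0.84 of TCR+ cells; 0.6 sits in that range and can
  be set per patient.
* Counts are negative binomial with variance `mu + mu^2/theta`,
  `theta = 2`, per-gene baseline log-mean uniform on [−4, 0.5] (a few
  hundred counts per cell after summation, typical of dissociated skin),
  and log-normal library-size factors (`sdlog = 0.25`).
* Planted effects multiply the NB mean of the six panel genes (CXCR4,
  CD69, HSPA1A, ZFP36, IL7R, TXNIP) by `exp(−0.8)` in dominant-clone cells
  of the progressed class only. Planted genes get a high baseline mean (5)
  so a −0.8 log effect survives the pseudocounted logFC convention; at low
  expression the pseudocount would shrink any planted effect below the 0.3
  threshold regardless of the test's power.
* Gating markers are near-binary: NB mean 30 in the intended subset
  (dropout ≈ 0.4% at theta 2) and 0.001 elsewhere (false positives
  ≈ 0.1%), so gating against ground truth is ≥ 99% accurate by
  construction. Real CD4/CD8A/FOXP3 expression is far noisier; a green
  gating test certifies the gate logic, not marker biology.
* Clone cells carry one shared β and one shared α CDR3 per patient;
  `plant_allelic_exclusion()` adds a distinct secondary α to a
  deterministic `rate` fraction of clone cells ("carries a second α" is
  implemented as an additional TRA contig on the cell, so a cell can bear
  both variants). Polyclonal cells get globally unique CDR3s. γδ datasets
  swap chain labels to TRG/TRD and change nothing else.
* All allocations (cell types, clone membership, detection) are
  deterministic rounded counts, so tiny fixtures are exactly checkable;
  identical seeds give byte-identical output files.

What the generator does **not** emulate: doublet transcriptomes, ambient
RNA, batch effects, realistic V(D)J recombination, cluster substructure
within T cells, or inter-patient transcriptomic heterogeneity of the
malignant clone (a prominent feature of the real data). Green tests
therefore establish correctness of the algorithms under the stated
statistical model, not robustness to real-data artifacts.

## Numerical and test-design choices

* IRLS convergence: relative deviance change `< 1e-12`, 2×2 normal
  equations solved in closed form; label swap negates logFC and preserves
  p to machine precision.
* The null-generator check uses a Welch t-test per gene as its oracle; a
  count-sum binomial test would be anti-conservative under NB
  overdispersion.
* The specificity negative control (effects planted in *all* cells must
  trip the benign flags) runs in a dedicated world with a mostly
  polyclonal infiltrate (clone fraction 0.2, 2000 cells/sample). In the
  default world the regulatory subset has ~30 cells per sample, which
  cannot reach Bonferroni significance at any realistic effect size, so
  the flags would be trivially FALSE and the control would not test
  anything.
* Some Monte-Carlo checks are scaled down from their stated designs (gene
  counts, replicate counts) to keep the default test run inside its time
  budget; each such test says so in a comment. Effect sizes and the
  300-cell stated world are never scaled.

## Known limitations

* The published analysis's exact normalization, QC, `min_pct`, logFC base
  and FDR procedure are not in the available text; all are explicit,
  documented defaults here, not claims about the original code.
* Dominant-clone calling counts cells; whether the original counted cells
  or UMIs is unknown (results differ only in pathological ties).
* The real study's dataset-level numbers (47,172 cells, the discovered
  panel on patient data) are not reproducible offline without the GEO
  accession; the acceptance surface is the synthetic-world property suite.
* Heteromeric receptor complexes and curated interaction databases are out
  of scope; the bundled pair list is a small demonstration set.
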