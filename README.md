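# mfclone

Clonality-aware single-cell analysis of cutaneous T-cell lymphoma (CTCL)
progression.

In mycosis fungoides — the most common CTCL — a single malignant T-cell
clone dominates each patient's skin lesions. Pairing single-cell RNA
sequencing with TCR (VDJ) sequencing lets you identify that clone as the
most expanded clonotype, split every cell into *malignant* vs *benign*, and
ask which genes change in the malignant clone as flat patches progress to
palpable plaques/tumors — in every patient, and nowhere else. `mfclone`
implements that pipeline for analysts working with 10x-style expression +
VDJ output:

* **Clonotype grouping** from CDR3 amino-acid sequences, with the β (or δ)
  chain as primary key so that two α variants arising from incomplete
  allelic exclusion merge into one clone; dominant-clone calling per
  patient with deterministic tie-breaking.
* **Benign-subset gating**: helper (CD4+ FOXP3−), regulatory (FOXP3+) and
  cytotoxic (CD8A+ FOXP3−) polyclonal T cells.
* **Differential expression** by logistic-regression likelihood-ratio test
  with Bonferroni correction; a gene is a DEG when adjusted p < 0.05 and
  |logFC| > 0.3 (malignant clone) or 0.25 (microenvironment), with
  logFC = ln of pseudocounted group means of de-logged normalized
  expression.
* **Cross-patient marker panel**: the strict, direction-consistent
  intersection of per-patient DEG lists, plus a specificity check that the
  panel is *not* consistently regulated in any benign subset.
* **Ligand–receptor interaction scores** I_R(X,Y) = mean of the ligand's
  mean expression in cluster X and the receptor's in cluster Y, with a
  cluster-label permutation null, add-one empirical p-values,
  Benjamini–Hochberg FDR, and palpable-minus-patch deltas.
* A **synthetic-data generator** (negative-binomial counts, planted
  clone-restricted effects, allelic-exclusion contigs) that emulates the
  paired-lesion study design, so the whole pipeline is testable end to end
  without patient data.

## Worked example

The bundled configuration simulates 3 patients with one patch and one tumor
sample each (300 dominant-clone cells per lesion class per patient) and
plants a −0.8 log-fold-change on six genes in the malignant clone of the
tumor samples only:

```r
library(mfclone)
cfg <- default_run_config(out_dir = "mfclone_out", seed = 1)
res <- run_pipeline(cfg, stages = c("de", "panel"))
#> [mfclone] 4290 cells, 2000 genes, 6180 contigs across 6 samples
#> [mfclone] dominant clone clone_0001 in P01_patch: 60.0% of 500 TCR+ cells
#> ...
#> [mfclone] panel: up = {}, down = {TXNIP, ZFP36, IL7R, CXCR4, CD69, HSPA1A}

res$panel
#> marker_panel (3 patients, consistency >= 3):
#>   up:   (none)
#>   down: TXNIP, ZFP36, IL7R, CXCR4, CD69, HSPA1A

head(res$per_patient_de$P01[, c("gene", "logfc", "p_adj", "direction")])
#>     gene      logfc        p_adj direction
#> 1   IL7R -0.8970671 3.131420e-19      down
#> 2  TXNIP -0.8537489 1.469432e-17      down
#> 3  ZFP36 -0.7641909 4.746012e-16      down
#> 4 HSPA1A -0.7409781 1.407013e-14      down
#> 5   CD69 -0.8314567 2.025240e-14      down
#> 6  CXCR4 -0.6311702 3.384244e-09      down

subset(res$specificity$flags, gene == "CXCR4")
#>        subset  gene direction consistent
#> 4      helper CXCR4      down      FALSE
#> 10 regulatory CXCR4      down      FALSE
#> 16  cytotoxic CXCR4      down      FALSE
```

Reading the output: each patient's dominant clone occupies exactly 60% of
that sample's 500 TCR+ cells (the stated simulation design); the
cross-patient panel recovers exactly the six planted genes, all
downregulated, with the per-patient evidence (log fold changes near the
planted −0.8, Bonferroni-adjusted p-values) behind it; and no benign
subset shows the same consistent regulation — the planted signal is
correctly localized to the malignant clone. Every table is also written
under `out_dir` (`panel.tsv`, `clones.tsv`, `interactions.tsv`, …) next to
a `manifest.json` with checksums, seed and stage timings.

The same stages run from files (MatrixMarket counts + metadata CSV + 10x
contig CSV) via `run_pipeline()` with input paths, or from the command
line:

```sh
Rscript inst/cli/mfclone.R simulate --out-dir data --seed 1
Rscript inst/cli/mfclone.R run --counts data/matrix.mtx --features data/features.tsv \
    --barcodes data/barcodes.tsv --metadata data/metadata.csv \
    --contigs data/contigs.csv --out-dir out --seed 1
```

## Documentation

See `vignettes/mfclone-methods.Rmd` for the statistical model, every
tunable default and its rationale, what the synthetic world does and does
not emulate, and known limitations.
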