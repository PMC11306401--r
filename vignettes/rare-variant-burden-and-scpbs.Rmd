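---
title: "Rare-variant burden testing and the single-cell polygenic burden score"
author: "rvburden authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-variant burden testing and the single-cell polygenic burden score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rvburden)
```

## The analysis problem

Exome case-control studies of severe, early-onset phenotypes — extreme myopia
is the motivating example throughout this package — look for an excess of
rare, functionally severe variants in cases. Because qualifying variants are
individually very rare (minor allele frequency below 0.5% in the cohort and
in public reference panels), association testing collapses them: a sample is
coded as a *carrier* of a gene (or gene set) if it carries at least one
qualifying allele, and carrier status is tested against case status. The
package implements this analysis end to end, from genotype/variant/sample
quality control through gene- and set-level burden tests, and extends it to
single-cell resolution with the single-cell polygenic burden score (scPBS).

## Qualifying variants

Coding variants are assigned exactly one of five classes:

* **PTV** — protein-truncating: `frameshift_variant`,
  `splice_acceptor_variant`, `splice_donor_variant`, `stop_gained`,
  `start_lost`.
* **D_MIS** — damaging missense: *probably damaging* (PolyPhen-2) **and**
  *deleterious* (SIFT) **and** CADD > 20. All three are required. A missense
  variant with a missing categorical predictor can never be D_MIS: the rule
  is a conjunction, and we read missing evidence as failure to establish
  damage, not as damage.
* **B_MIS** — benign missense: (*tolerated* **and** *benign*) **or**
  CADD < 15. The CADD route is an independent benign criterion, so it alone
  can classify a variant with missing categorical predictors.
* **SYNONYMOUS** — `synonymous_variant`; used as the negative-control class
  in every burden analysis.
* **OTHER** — everything else, including missense variants satisfying
  neither rule set (e.g. *possibly damaging* predictions, or CADD between 15
  and 20).

A variant *qualifies* when its class is eligible and its folded minor-allele
frequency is below the threshold (default 0.005) in the cohort **and** in
every supplied reference panel; a panel in which the variant is absent
contributes frequency 0.

## Quality control

Call-level, site-level and sample-level filters follow standard exome QC:

| filter | rule |
|---|---|
| genotype call | DP ≥ 10, GQ ≥ 20, het allele balance in [0.2, 0.8] |
| variant site | not low-complexity, VQSR pass, call rate ≥ 90%, HWE exact P ≥ 1e-6 |
| sample | call rate ≥ 0.9, mean depth ≥ 10, mean GQ ≥ 65, then 4-SD outlier removal on Ti/Tv, het/hom, ins/del ratios |

Site filters are applied with a fixed priority (low-complexity, VQSR, call
rate, HWE) and the first matching reason is reported, so drop reasons are
reproducible. The ratio-outlier step is a single pass: means and SDs are
computed once over samples passing the hard thresholds, not iterated, which
keeps the filter deterministic and order-free.

The HWE test is the exact conditional test: given the observed allele
counts, it sums the probabilities of all heterozygote configurations no more
probable than the observed one (no mid-P). It is computed on the combined
case-control cohort. Genetic sex is inferred from the X-chromosome
inbreeding coefficient $F = 1 - \mathrm{het}_{obs}/\mathrm{het}_{exp}$, with
$F > 0.8$ male and $F < 0.4$ female; both cutoffs are strict, so boundary
values are classified ambiguous and excluded.

Ancestry principal components are computed on common variants (folded
MAF > 1%): dosages are centred at $2p$ and scaled by $\sqrt{2p(1-p)}$,
missing dosages are mean-imputed, and sample scores come from the singular
value decomposition. Each PC's sign is fixed so that its largest-magnitude
variant loading is positive, and greedy nearest-neighbour control matching
in the top three PCs breaks distance ties by the lexicographically smallest
control id — both conventions exist purely so reruns are bit-identical.

## Burden testing

Two tests are provided behind one dispatch (`unit_burden_test`):

**Fisher's exact test** on the carrier 2×2 table, two-sided by the
minimum-likelihood convention (the sum of hypergeometric probabilities not
exceeding the observed table's). The odds ratio reported is the sample OR
$ad/bc$, with a Haldane–Anscombe 0.5 correction (flagged) only when a cell
is zero, and a normal-approximation CI on the log-OR scale. This pairing
reproduces printed worked examples exactly — e.g. the carrier table
8/449 cases vs 11/9606 controls gives OR 15.82 and $P = 7.27\times10^{-7}$ —
whereas the conditional-MLE OR of `stats::fisher.test` would not.

**Firth penalized logistic regression** of case status on the carrier
indicator plus covariates (sex, PC1–10, total exome count — the most
conservative model and the default). The fit maximises the Jeffreys-prior
penalized likelihood $\ell(\beta) + \tfrac12\log|I(\beta)|$ by Newton steps
on the modified score with step-halving, so estimates are finite even under
complete separation (a real concern when a gene's carriers are all cases).
Convergence requires the largest modified-score component below 1e-6 and the
largest update below 1e-8, within 100 iterations.

Inference on the carrier coefficient uses the **penalized likelihood-ratio
test with the profile penalty**: the null model constrains the carrier
coefficient to zero while the penalty still uses the full design's
information matrix. This detail matters. Refitting the null on a reduced
design changes the dimension of the Jeffreys penalty and we measured a
type-I error near 0.21 at the 0.05 level under that variant; the profile
form is calibrated (0.044–0.050 over 2000 null simulations at n = 200/200,
which is also asserted by the test suite). Wald standard errors and CIs are
reported alongside because the LRT gives only a P value.

The *total exome count* covariate — each sample's summed qualifying alleles
over all four classes — absorbs residual technical variation in per-sample
variant yield.

### Scans and nulls

* `collapsing_scan` runs the per-gene carrier FET over every gene with at
  least one qualifying variant, sets the Bonferroni threshold at
  0.05 divided by that gene count, and builds the expected P-value
  distribution for QQ plots by permuting case-control labels, sorting each
  permutation's P values, and averaging across permutations — an empirical
  null that respects the discreteness of rare-carrier FETs, which makes the
  uniform assumption badly wrong.
* `geneset_scan` tests carrier-of-set indicators per gene set and controls
  the FDR with Benjamini–Hochberg across the scanned collection (set-level
  scans are screens, so FDR rather than family-wise control).
* `length_matched_empirical_p` guards set-level hits against gene-length
  confounding (long genes accumulate more rare variants): B random sets
  matching the target's composition across coding-length *deciles* are
  drawn, and the empirical P is $(1 + \#\{\text{resampled} \ge
  \text{observed}\})/(B+1)$, never zero by construction. Deciles are our
  binning choice; the matching granularity was otherwise unspecified.
* `genomic_control_lambda` computes $\lambda_{GC} =
  \mathrm{median}(\chi^2)/q_{0.5}(\chi^2_1)$ and deflates statistics only
  when $\lambda > 1$.

Every resampling routine takes an explicit seed and restores the global RNG
state on exit; nothing in the package consumes global randomness silently.

## scPBS: mapping burden onto single cells

scPBS asks, for each cell of an scRNA-seq dataset, whether the genes that
are *specifically expressed in that cell* are enriched for case-carried rare
PTVs. Five stages:

1. **Specificity** (`tpm_and_specificity`): mean counts per cell type are
   scaled to one million (TPM); specificity of gene $g$ in type $c$ is
   $\mathrm{TPM}_{gc}/\max_{c'}\mathrm{TPM}_{gc'}$, in [0, 1], with every
   expressed gene attaining 1 in its argmax type.
2. **Per-cell gene sets** (`per_cell_gene_sets`): genes are scored per cell
   by (cell's log-normalized expression) × (specificity of the cell's
   type), and the top 10% of the cell's expressed genes are selected, ties
   broken lexicographically. The defining wording for these sets was
   ambiguous ("highly expressed genes specific to each cell"); this rule
   uses both stated ingredients — cell-level expression and type-level
   specificity — with the 10% convention used everywhere else in the
   analysis, and the fraction is a parameter.
3. **Per-cell burden** (`per_cell_burden_score`): Firth regression of case
   status on carrier-of-set plus the full covariate set; the cell's scPBS is
   the fitted carrier log-OR. We use the log-OR (not the OR) so the score is
   symmetric around no-effect; other implementations may differ. Cells
   whose set has no carriers get scPBS 0 with a null flag and are excluded
   downstream rather than imputed. Fits are cached by carrier pattern and
   the covariate-only null is shared, so a dataset's cost scales with the
   number of distinct carrier patterns, not cells.
4. **Trait-relevant genes** (`trait_relevant_genes`): Pearson correlation of
   each gene's expression with scPBS across non-flagged cells; zero-variance
   genes are excluded; the top 10% by signed correlation are the
   trait-relevant genes.
5. **rvTRS** (`rvtrs_score`): the cell's mean expression of trait-relevant
   genes minus a bin-matched control mean — genes are binned into 25
   equal-frequency bins of average expression and 100 control genes are
   drawn per trait gene (the conventional module-score defaults), seeded.
   Subtracting bin-matched controls removes the component of the score that
   merely tracks library size and mean expression.

`celltype_marker_genes` supports the coarser cell-type-level enrichment
analysis: one-vs-rest Wilcoxon rank-sum ranking with positive-only
natural-log fold change ≥ 0.25 and within-type detection ≥ 0.1, keeping the
top 10% of the dataset's genes per type. We rank with a rank-sum statistic
rather than a mixed-model DE test: with the same filters the ranking is
what matters here, and the rank-sum is exact, fast and dependency-free.
The "top 10%" is taken of the full gene registry (truncated to filter
passers), matching the "10% most specific genes per cell type" convention.

## The synthetic-data generator

Real cohorts of this kind are restricted-access, so the package ships
generators that every stage is tested against:

* `simulate_cohort` draws per-gene carrier indicators — controls at the
  baseline carrier rate (default 0.01 per gene), cases at the baseline odds
  scaled by the planted odds ratio, so the planted OR is exactly the
  carrier-level estimand — then materialises one heterozygous synthetic PTV
  per carrier (three variants per gene by default, echoing the worked
  example's three-variant gene). Covariates are sex ~ Bernoulli(0.5),
  PC1–10 ~ N(0,1) and a Poisson(100) total exome count.
* `simulate_expression` draws negative-binomial counts (dispersion 0.5)
  around lognormal baseline means, up-shifts each type's disjoint marker
  block by a natural-log fold change (default 2), and emits labels plus a
  Gaussian-blob 2-D embedding.
* `simulate_linked_dataset` couples the two the way scPBS assumes: the
  carrier enrichment is planted exactly in the designated causal type's
  marker genes.

The generator simulates carriers, not sites: the downstream analyses
collapse to carriers anyway, and carrier-level simulation makes the planted
OR exact. It deliberately does **not** simulate linkage disequilibrium,
realistic site-frequency spectra, sequencing reads, batch effects or
doublets. Passing recovery tests on these fixtures therefore demonstrates
that the statistical machinery finds the signal it is pointed at — not that
the pipeline is robust to the full messiness of real exomes or real
dissociation artifacts.

## Problem sizes and what the tests assert

The suite's heavier, seeded checks (all in `tests/testthat/`):

* FET and HWE agree with brute-force enumeration oracles to 1e-12 across
  sweeps of tables with margins up to 200; Firth fits agree with a
  grid-maximised penalized likelihood to 1e-4 in $\beta$ on two-parameter
  problems, including a complete-separation case.
* The covariate-adjusted Firth burden test has type-I error in [0.03, 0.07]
  at $\alpha = 0.05$ over 2000 null simulations of 200 cases / 200 controls;
  $\lambda_{GC} = 1.00 \pm 0.02$ on $10^5$ uniform P values.
* On 20 replicates of the linked simulation (5 types × 200 cells, 500/500
  samples, planted OR 5), the causal type has the highest median rvTRS in at
  least 19, and the planted set / a causal gene ranks first in the gene-set
  and collapsing scans in at least 95% of replicates.

These sizes are the package's chosen verification conditions: large enough
that calibration and recovery are statistically meaningful, small enough to
run routinely.

## Known limitations

* SKAT/SKAT-O/ACAT-style variance-component tests are not reimplemented;
  externally computed per-gene P values can be reported alongside.
* Clustering, batch correction and embeddings are consumed as inputs, never
  computed; scPBS inherits whatever is wrong with the upstream cell-type
  labels, and specificity is only as fine as those labels.
* The FET path ignores covariates by construction; stratification control
  in the scans comes from upstream PC matching, not from the test itself.
* The Firth penalty acts approximately like half a pseudo-observation per
  cell, so on very sparse tables the fitted OR differs from the sample OR by
  a few percent (the worked 8/441/11/9595 table fits at 16.06 against a
  sample OR of 15.82); the two are reported by different code paths and
  should be quoted as such.
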