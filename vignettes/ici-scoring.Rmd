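---
title: "Characterizing tumor immune infiltration and the ICI score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing tumor immune infiltration and the ICI score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis in one paragraph

Bulk tumor expression mixes signals from malignant cells with those of
infiltrating immune cells, and the composition of that infiltrate carries
prognostic and predictive information. `iciscope` characterizes the immune
cell infiltration (ICI) of a bulk expression cohort in five linked steps:
(1) estimate per-sample immune cell fractions by nu-support-vector
regression against a cell-type reference signature (the CIBERSORT scheme);
(2) cluster samples on those fractions by resampling-based consensus
clustering into immune subtypes; (3) find genes differentially expressed
across the subtypes with an empirical-Bayes moderated t-test; (4) split
those genes into two opposing signatures — genes rising with the immune
level (signature A) and genes falling with it (signature B) — optionally
reduced by a shadow-feature random-forest selector, and score every sample
as

\[ \mathrm{ICI\ score} = \mathrm{PC1}_A - \mathrm{PC1}_B , \]

the difference between the first-principal-component scores of the two
gene blocks; (5) dichotomize the score at the maximally selected log-rank
cutoff and test its association with overall survival, tumor mutation
burden (TMB), pathway enrichment, and therapy response.

# The model, stage by stage

## Deconvolution

For each sample the genes shared with the signature matrix are z-scored in
the bulk column and in every signature column, and a linear nu-SVR is fitted
for each $\nu \in \{0.25, 0.5, 0.75\}$. The fit with the smallest
reconstruction RMSE wins; negative coefficients are clipped to zero and the
remainder renormalized to sum to one — so the output rows are convex
weights. Because both sides are standardized, the fractions are invariant to
positive rescaling of a bulk profile, which is what makes mixed-platform
cohorts tractable. An optional permutation p-value (gene-shuffled bulk
vectors) measures whether a sample resembles the signature space at all; no
sample filtering is applied by default. Quantile normalization of the
mixture, part of the original array-mode recipe, is available but off by
default.

The package deliberately ships no reference matrix: the published 22-type
LM22 signature is licensed separately and can be dropped in as a TSV. Tests
and the synthetic cohort use `make_signature_matrix()`, a block-structured
synthetic analogue with the same shape (22 types × 10 markers each).

## Immune and stromal scores

`ssgsea_score()` is a rank-based single-sample enrichment score: genes are
ordered by decreasing expression, an in-set ECDF weighted by
$\mathrm{rank}^{\alpha}$ (default $\alpha = 0.25$) is compared against the
uniform out-of-set ECDF, and the integrated difference is the score. Using
ranks makes the score invariant to any strictly monotone transform of a
sample's expression, so linear and log-scale cohorts score identically.
`estimate_scores()` applies it to immune and stromal marker sets and sums
the two, mirroring the ESTIMATE construction. One boundary case is fixed by
convention: if a set covers every gene there is no out-of-set mass and the
score is defined as 0.

## Consensus clustering and the choice of k

`consensus_cluster()` follows the standard subsampling recipe: draw 80% of
items, cluster with Ward hierarchical clustering on Euclidean distance
(k-means is available), and record for every item pair the fraction of
co-clusterings among co-samplings. The method default of 1,000 repetitions
matches common practice for publication-grade stability; the pipeline
default is 200, a desk-scale size chosen so a full cohort run stays under a
minute — stability of the planted-structure recovery at that size is
checked in the test suite.

Selecting k from the consensus CDF needs care. The textbook delta-area
statistic sets $\Delta(2) = A(2)$ (the raw area) and
$\Delta(k) = (A(k)-A(k-1))/A(k-1)$ beyond; taking the literal argmax then
almost always returns k = 2, because the raw area dominates the relative
gains. What practitioners actually read off the delta-area plot is the
elbow: the last k before the relative gain collapses. `consensus_cluster()`
operationalizes that as the k maximizing the drop ratio
$\Delta(k)/\Delta(k+1)$, which recovers planted 2-, 3- and 4-cluster
structures across seeds in our tests. A consequence worth knowing: the
largest k in `k_range` can never be chosen automatically. The pipeline pins
k = 3 for both the immune subtypes and the gene clusters — three immune
phenotypes (inflamed, desert, excluded) is the structure this analysis is
built around — and the delta-area choice is reported alongside for
diagnostics.

Cluster labels out of any clustering run are arbitrary integers, so the
pipeline canonicalizes them: clusters are relettered A, B, C by decreasing
mean immune score. "A" is therefore always the most immune-infiltrated
subtype, reproducibly across runs and seeds.

## Differential expression

`moderated_t_test()` is a two-group empirical-Bayes moderated t: gene-wise
residual variances $s_g^2$ with $d$ degrees of freedom are shrunk toward a
prior $(d_0, s_0^2)$ fitted by matching the moments of $\log s_g^2$ to a
scaled-F model (with `trigamma` inversion by Newton iteration), giving the
posterior variance $(d_0 s_0^2 + d s_g^2)/(d_0 + d)$ and a t-statistic on
$d_0 + d$ degrees of freedom. Degenerate genes never divide by zero: a gene
constant in both groups has zero fold change and p = 1, and when the data
show no excess dispersion over chi-square sampling noise the prior df is
infinite and the statistic becomes a z-score against the pooled variance.
The suite cross-checks the statistics against an independent
empirical-Bayes implementation on a shared fixture, and calibrates type-I
error on null genes.

DEG selection runs one-vs-rest contrasts (one per cluster), BH-adjusts
within each contrast, and takes the union of genes with
$|\log_2 \mathrm{FC}| > 1$ and adjusted p < 0.05 in at least one contrast.
"Absolute fold-change > 1" is read on the log2 scale — the conventional
limma reading, i.e. a two-fold change; `fc_scale = "linear"` switches the
interpretation for cohorts annotated otherwise. One-vs-rest (rather than
all pairwise contrasts) yields a single union list naturally indexed by the
subtype a gene marks.

## Signatures and the ICI score

Samples are re-clustered on the DEG expression (gene clusters), again
canonicalized by immune score. Each DEG's expression is then
Spearman-correlated with the gene-cluster rank ordered from least to most
immune-favorable: positive genes form signature A, negative genes signature
B, and genes with |rho| below 1e-12 are excluded rather than forced into a
side. The shadow-feature selector (`boruta_select()`) optionally reduces
the DEG set first: each iteration appends permuted copies of every feature
to a random-forest fit, a feature scores a hit when it out-ranks the best
shadow, and hit counts are tested against Binomial(n, 1/2) with BH
correction. The selection target is the gene-cluster label — the quantity
the signatures are defined against.

`pc1_score()` z-scores each gene across samples and projects samples on the
first principal component. Because an eigenvector's sign is arbitrary, the
score's sign is anchored: it must correlate positively with the mean
z-scored expression of its gene block. Without the anchor the ICI score
would flip sign from run to run; with it, swapping signatures A and B
negates the score exactly, which the tests assert. When a configuration
splits a signature into sub-blocks their PC1 scores are summed, matching
the gene-expression-grade-index style of aggregate scoring; with the
default single block per signature the sum is just that block's PC1.

## Survival, mutation, enrichment, response

Kaplan-Meier curves, log-rank tests and Cox fits are delegated to the
`survival` package (Breslow tie handling); the maximally selected cutoff is
implemented here: the standardized two-group log-rank statistic is
evaluated at every midpoint between consecutive distinct score values for
which both groups keep at least 10% of the cohort, and the argmax wins
(ties break toward the lower cutoff). No multiplicity-corrected p-value is
attached to the selected cutoff — the cutoff is used for grouping, and
downstream tests are reported as-is, mirroring how such cutoffs are used in
practice. Midpoints (not observed values) make group assignment
unambiguous.

TMB is the count of non-synonymous records per sample, with the
conventional MAF classification set (missense, nonsense, nonstop,
frameshifts, in-frame indels, splice site, translation start). Samples
absent from the MAF count as wild-type everywhere — consistent with the
shipped published contrast table, whose group margins are constant across
genes. Per-gene high/low contrasts use the Pearson chi-square *with* Yates
continuity correction: the uncorrected statistic does not reproduce the
published table's p-values, the corrected one reproduces every row to at
least three significant figures, and the regression test pins that. The
TMB high/low split defaults to the cohort median (configurable); the
source analysis did not state its threshold.

Preranked GSEA uses the weighted running-sum enrichment score with
gene-label permutations — deterministic under a seed, unlike phenotype
permutation — and the standard pooled positive/negative null for the FDR.
The pipeline's ranking metric is the moderated t of high vs low ICI score
group. Over-representation uses the upper-tail hypergeometric against a
user-stated universe. No gene-set database ships with the package; gene
sets come from GMT files (the pipeline's synthetic run uses the signature
matrix's own marker sets).

ROC analysis dichotomizes RECIST response as CR/PR = responder, SD/PD =
non-responder (the standard convention; the source analysis plots
categories without stating its coding), computes AUC by the midrank
Mann-Whitney formula, and the response-rate contrast is a 2×k chi-square
without continuity correction (df > 1).

# The synthetic cohort: what it emulates and what it does not

`simulate_cohort()` provides ground truth for every stage. Expression is a
convex mixture of the synthetic signature's cell-type profiles, with
per-subtype Dirichlet concentrations encoding three immune phenotypes —
subtype A concentrates CD8 T, activated NK, activated memory CD4 and Tfh
(inflamed); subtype B is dominated by M0 macrophages, activated mast and
resting NK with low totals (desert); subtype C concentrates B cells, Tregs
and M1/M2 macrophages (excluded) — plus gene-wise log-normal noise
(sd 0.2 by default) and 300 unstructured background genes. Survival times
are exponential with hazard proportional to
$\exp(\log\mathrm{HR} \times \text{latent immune level})$, the simplest
model satisfying proportional hazards, so a Cox fit on the truth recovers
the planted coefficient in expectation; the default log HR is −1 per SD of
the latent cytotoxic fraction, and censoring is an independent 30%.
Mutations are Poisson background burden (means 45/55 in the immune-high /
immune-low halves, a mild negative TMB-immunity link) plus Bernoulli driver
hits with odds 2.5 enriched in the immune-low group; response labels come
from a proportional-odds model on the latent immune level. All generators
are pure functions of their seed.

What the generator does *not* emulate: gene-gene correlation beyond the
mixture structure, platform/batch effects, probe-level artifacts,
copy-number-driven expression, or non-proportional hazards. Passing the
end-to-end tests therefore shows the machinery is correct and the score
recoverable under the assumed generative model — not that any particular
clinical cohort will behave as cleanly.

# Numerical choices and degenerate inputs

* Duplicate gene rows on load collapse to the row with the highest mean
  expression (the common multi-probe convention; the choice is a
  convention, not a derivation).
* Expression scale is an explicit tag; conversions (`fpkm_to_tpm()`,
  `to_log2()`) are explicit operations, with only a heuristic warning
  (max value < 30 suggests log2) and never silent conversion. Survival time
  units are carried as metadata and never converted.
* Zero-variance genes are dropped (with a warning) before PC1; an empty
  signature contributes a zero term with a warning rather than an error.
* A 2×2 contrast with a zero margin reports p = NA with a degenerate flag.
* Cox fits where one group has no events are flagged monotone and reported
  with an unbounded CI.
* Consensus entries for item pairs never co-sampled are NA, and their count
  is reported; at the default repetition counts the event does not occur.
* Ranked-list ties take average ranks everywhere ranks are used; cutoff
  ties break toward the lower cutoff; equal mutation frequencies rank
  alphabetically.

# Problem sizes used by the checks

The test suite and the acceptance script run the full pipeline on the
default 300-sample cohort with 100 consensus repetitions, 10 shadow-feature
iterations (80 trees) and 50 GSEA permutations — sizes chosen so a complete
run takes well under a minute while every recovery margin stays wide (the
score-truth Spearman correlation, required to reach 0.7, sits above 0.8 at
these sizes). Component checks use 1,000 null genes for t-calibration, 200
random sets for GSEA calibration, 100 random vectors for the BH oracle, and
the planted three-blob fixture (n = 60) for consensus recovery.

# Limitations

The deconvolution is relative (fractions sum to one): it cannot express
overall infiltration on an absolute scale, and a reference signature
missing a present cell type redistributes that type's signal. The ICI score
is cohort-relative — PC1 is fitted per cohort, so scores are not
transferable across cohorts without refitting, exactly as in the original
construction. The maximally selected cutoff is optimistically biased by
construction; treat downstream log-rank p-values as descriptive. The
moderated t assumes roughly normal log-scale expression; counts should be
transformed (e.g. to log TPM) first.
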