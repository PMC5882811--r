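---
title: "Methods: multi-omic inference of CTL infiltration drivers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omic inference of CTL infiltration drivers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Cytotoxic T lymphocyte (CTL) infiltration of solid tumors predicts
immunotherapy response, but its drivers differ across cancer lineages. In
mutation-driven ("M-class") cancers, CTL levels track the neoantigen burden
produced by somatic mutations. In copy-number-driven ("C-class") cancers,
that relationship vanishes; instead, CTL levels track activation of the DNA
double-strand-break kinase ATM (phosphorylation at S1981), which drives
secretion of T-cell-recruiting cytokines (CCL5, CXCL9, CXCL10, IL16).

`ctlomics` implements the full inference chain that supports this picture:

1. **Proteomic CTL calling** — a tumor is CTL-high when both the CD8 marker
   and granzyme B are detected at the protein level, CTL-low when neither
   is. Samples with exactly one marker detected are *unclassified* and
   excluded from two-group contrasts: the co-detection rule defines only the
   two extremes, and forcing mixed samples into either group would dilute
   both.
2. **iTRAQ missing-value handling** — 4-plex labeling shares detection
   within a run, so absence is interpreted per run: if any sample in a
   4-plex detects a protein, missing samples are set to 10% of the lowest
   detected value for that protein in that run; if none does, the protein is
   excluded for that run. The rule operates on the abundance scale —
   "10% of the lowest value" is meaningless after a log transform. The
   "lowest detectable value" is taken per protein per run (a global per-run
   floor would be a property of the instrument, not of the protein).
3. **Differential statistics** — Welch (unequal-variance) two-sample t per
   feature, high minus low, with Benjamini-Hochberg q-values. Welch is the
   robust default when a bare "t statistic" is called for; the brute-force
   oracle in the tests evaluates the same closed form independently.
4. **The RNA-seq CTL score** — elastic-net logistic regression of the
   CTL-high call on `log2(count + 1)` for CD8A, GZMB and PRF1. The binomial
   link is used because the target is the binary CTL-high label. Mixing
   parameter `penalty_mix = 0.5` balances ridge stability against lasso
   sparsity; penalty strength comes from 5-fold stratified cross-validation
   at `lambda.1se`, which prefers the sparsest model within one standard
   error of the optimum — this is what lets an uninformative marker (e.g. a
   perforin transcript carrying no signal) be dropped with coefficient
   exactly zero.
5. **Signature derivation** — a stratified train/test split, 1000
   class-stratified subsamples (fraction 0.8, without replacement) of the
   training group recording per-gene Welch p and log2 fold change, and a
   grid search over (p threshold, |fold change| threshold, fraction of
   iterations) cells. A gene enters a cell's signature when it satisfies
   *both* criteria jointly within an iteration in at least the required
   fraction of iterations (the joint reading is a design decision; the
   per-criterion alternative is weaker and harder to interpret). Cells are
   scored by held-out test AUC of the signature score — the weighted mean of
   member-gene log2 values with per-gene weight equal to the signed median
   fold change across iterations — and ties prefer the smaller signature,
   then the smaller p threshold. Held-out AUC is the natural objective
   given that the split exists solely to keep selection and evaluation
   apart.
6. **Preranked GSEA** — the weighted Kolmogorov-Smirnov running sum:
   +`|w|^1 / sum(|w| over members)` at member positions,
   −`1/(N − N_members)` elsewhere; the enrichment score is the signed
   extremum of largest absolute value, and the leading edge is the member
   subset at or before the peak (at or after the trough for negative
   scores). Significance uses gene-set-label permutation — random same-size
   feature sets — which is the standard null for preranked input;
   `p = (#{|null ES| ≥ |ES|} + 1)/(n_perm + 1)` and
   `NES = ES / mean(|null ES| of matching sign)`.
7. **Network enrichment** — the ATM first+second neighborhood is taken by
   breadth-first search on the curated interaction network *before* edge
   filtering (the neighborhood definition belongs to the curated topology;
   filtering then prunes it). Edges are kept when their endpoints' phospho
   signals correlate (Spearman, two-sided, best |r| site pair when a protein
   has several sites) at BH FDR 10%; both correlation signs count, and
   edges without phospho coverage are removed and reported separately.
   Cytokine-TF enrichment compares the observed count of promoter-binding
   TFs inside the network against counts in uniformly drawn equal-size
   protein subsets of the universe (all proteins of the interaction input),
   with the plus-one empirical p. Uniform sampling is a deliberate,
   labelled choice; degree-preserving nulls are out of scope.
8. **Correlation machinery** — Spearman with midranks and the two-sided t
   approximation `t = r sqrt((n−2)/(1−r²))`; the correlation-loss test
   subsamples both groups to the smaller group's size (without replacement,
   1000 iterations) and compares the two correlation distributions by
   Wilcoxon rank-sum; pan-cancer tables adjust the per-cohort p-values by
   Holm-Šidák *within* each comparison family (ATM and neoantigen
   separately, matching how per-family bars are annotated); the headline
   cross-cohort contrast is the Spearman correlation between the per-cohort
   (CTL, ATM) and (CTL, neoantigen) coefficients.

# The synthetic-cohort generator

Real inputs for this framework are controlled-access tumor proteomes and
RNA-seq; the generator emulates their statistical structure with full ground
truth so every stage is testable at desk scale.

Per sample, a latent Gaussian CTL level `z` is drawn; the top
`frac_ctl_high` fraction is CTL-high. The generator then builds:

- **Protein log2 abundances** (default 160 proteins): baselines `N(6, 1)`,
  unit noise. The markers CD8A/GZMB/PRF1 are based at 4.8 — near the
  detection boundary — and carry `ctl_marker_effect` (default 2 log2 units,
  a strong but realistic co-detection effect) in CTL-high samples plus a
  continuous term `0.5 z`: marker transcripts and proteins belong to the
  infiltrating cells themselves, so their abundance scales with
  infiltration rather than switching.
- **iTRAQ missingness**: samples are partitioned into consecutive runs of 4
  (run assignments for the real data are unpublished; consecutive
  assignment is the simplest faithful stand-in), and values under the run's
  `detection_threshold` abundance quantile are missing. The default 0.25
  makes unshifted markers drop out frequently in CTL-low samples, which is
  exactly the signal the co-detection call uses.
- **RNA counts**: negative binomial (size 10) with log2 means tied to the
  protein means plus `N(0, 0.5)` noise, giving a tunable positive
  transcript-protein correlation — the property the secreted-factor filter
  keys on.
- **Coupling structure**: in C-class cohorts phospho-ATM satisfies
  `patm = ρ z + sqrt(1−ρ²) ε` (`ρ = atm_ctl_coupling`, default 0.6) in
  ATM-wild-type samples and is an independent draw in ATM-altered samples
  (`mutant_fraction`, default 0.25); cytokine expression follows the same
  driver, severed in altered samples. In M-class cohorts the ATM coupling
  is zero and neoantigen counts couple to `z` instead (negative binomial on
  `exp(3.9 + 0.8 g)` with `g = ρ z + sqrt(1−ρ²) ε`). The RPPA total-ATM
  proxy is `0.85 patm + noise`, reflecting that total ATM tracks, but is
  not, the phospho mark.
- **PPI/TF test bed**: an Erdős–Rényi graph (600 nodes, edge probability
  0.025) containing ATM, with half the nodes designated TFs and 120 TFs
  binding each cytokine promoter. The sizes are chosen so the discrete null
  distribution of binder-in-subset counts has many attainable values: a
  plus-one empirical p over a coarse discrete statistic is necessarily
  conservative, and fine support keeps its type-I rate near nominal at
  α = 0.05. With planting on, 85% of each cytokine's binders are drawn
  from ATM's 2-neighborhood; off, placement is uniform, which is the
  calibration null.

Default cohort size is 80 samples (the scale of the breast proteome cohort
this framework was built around); pan-cancer panels in the tests use 13
cohorts of 150 samples, reflecting that transcriptome cohorts run larger
than proteome ones.

What the generator does *not* emulate: real copy-number landscapes or
mutational signatures, sequence-level neoantigens, batch effects beyond the
4-plex structure, degree-correlated interaction networks, or inter-gene
correlation beyond the planted couplings. Passing tests therefore
demonstrate that the *inference machinery* recovers planted structure and
is calibrated under its null — not that the biological conclusions
transfer to any particular real cohort.

# Numerical choices and degenerate inputs

- The GSEA running sum is accumulated step by step in double precision
  (rather than `cumsum`, which carries extended precision on common
  platforms) so any direct reimplementation reproduces it bit for bit; it
  must return to zero within 1e−12. All-zero member weights fall back to
  equal hit increments.
- Zero-variance features get an undefined t statistic, p = 1 and a flag;
  zero-variance correlation inputs return a flagged `NA` with a warning.
- Wilcoxon rank-sum is exact by full enumeration (midranks, two-sided
  p = `min(1, 2 min(P(W ≤ w), P(W ≥ w)))`) up to 12 pooled observations and
  a tie-corrected normal approximation (no continuity correction) beyond;
  with every observation tied the variance is zero and p = 1.
- When both correlation-loss groups have the same size, the subsample *is*
  the full group each iteration, so both distributions are point masses:
  the Wilcoxon p is then driven entirely by separation of the two constants
  (p → 0 for any real difference, p = 1 for none). The subsample size
  equals the smaller group by design ("equal sample size"); iteration
  variability only matters for unequal groups, which is the realistic case.
- ROC ties are counted 1/2 (midrank Mann-Whitney), which equals the
  trapezoidal area; grid-search ties prefer smaller signatures, then
  smaller p thresholds, making the search deterministic.
- Empirical enrichment p-values use the plus-one rule throughout and can
  never be 0.
- All generators and resampling operations take explicit integer seeds and
  are bit-reproducible under them.

# Problem sizes used by the checks

The test suite validates exactness against brute-force oracles (enumeration
of subsets and rank assignments, all-pairs concordance, direct running
sums) on universes small enough to enumerate (≤ 15 proteins, ≤ 12 ranked
features, ≤ 50-feature lists), and statistical behavior at study scale:
1000 simulated graphs for null calibration, 100 replicates of the
correlation-loss test at 100 samples per group, 50 replicates of signature
recovery with 10 planted genes among 500 nulls at 60 samples per class, and
50 replicates of 13-cohort pan-cancer panels. `scripts/acceptance.R`
re-runs one instance of each analysis from scratch and writes the resulting
quantities as JSON.

# Known limitations

- The elastic-net coefficients of the published score are not reproduced
  numerically (the original training data are not distributable); the
  score's *behavior* — sparsity, separation, downstream correlations — is
  what is validated.
- The uniform-subset enrichment null ignores degree structure; on real
  interaction networks a degree-aware null would be more stringent.
- Holm-Šidák assumes independence or positive dependence within a family
  for strict control; with 13 cohorts per family this is the conventional
  choice, not a guarantee.
- The grid-search objective (held-out AUC) selects among few, highly
  correlated cells; on pure-noise data the selected AUC is therefore
  optimistically biased by a few hundredths, which the null-calibration
  check bounds rather than removes.
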