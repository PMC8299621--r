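---
title: "Modeling site-level RNA cleavage efficiency from degradome sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling site-level RNA cleavage efficiency from degradome sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Degradome sequencing protocols (TREseq, PARE and relatives) capture the 5'
ends of uncapped RNA degradation intermediates transcriptome-wide, so each
read marks an endonucleolytic cleavage position. Cleavage is far from
uniform: some positions within an mRNA are cut orders of magnitude more
efficiently than others, and understanding which sequence and translational
features drive that preference is the scientific question this package
addresses, with *Arabidopsis thaliana* mRNA decay as the motivating system.

`cleavefeat` turns the analysis into a reusable, fully tested pipeline:

1. **Scoring.** Per-position degradome 5'-end counts are normalized to
   each gene's capped-read abundance, giving the cleavage score at the
   site level, `CS_site = reads / cap_total`, and its per-gene sum
   `CS_gene`. Ribosome-protected-fragment counts are normalized the same
   way (`RO_site`, `RO_gene`).
2. **Reliability filtering.** Only genes with more than 50 capped reads
   are scored; genes are retained when more than 20% of their positions
   carry at least one degradome read and their `CS_gene` lies strictly
   between the 5th and 95th percentiles; putative miRNA-guided cleavage
   sites can be removed through an exclusion list. Genes are then split
   9:1 into training and test sets — at the gene level, so sites of one
   gene never straddle the split.
3. **Featurization.** An exhaustive window scan around every cleavage
   site plus whole-RNA/region features (details below).
4. **Pruning.** Features with `|Spearman rho| < 0.1` against `CS_site`
   are dropped; multi-collinear groups (pairwise `|rho| >= 0.6`) are
   collapsed, keeping the member most correlated with the objective.
5. **Model fitting.** L1 (LASSO) or L2 (Ridge) penalized linear
   regression of the cleavage score, with ten-fold gene-grouped
   cross-validation over a log-spaced penalty grid, test-set evaluation
   (MSE and Pearson r), and signed coefficient reports grouped by feature
   category and scope.

## The model

For site $i$ with feature vector $x_i = (x_{i1},\dots,x_{ip})$ the linear
predictor is $\hat y_i = \alpha + \beta \cdot x_i$. Fits minimize

$$\frac{1}{2n}\sum_i (y_i - \hat y_i)^2 + \lambda P(\beta),
\qquad P(\beta) = \lVert\beta\rVert_1 \;\text{(L1)}
\quad\text{or}\quad \tfrac12\lVert\beta\rVert_2^2 \;\text{(L2)},$$

with the intercept unpenalized. Two conventions deserve explicit mention
because they are not fixed by the scientific description of the method:

* **Penalty scaling.** The per-sample $1/(2n)$ convention above is the
  one used by glmnet and by the common Python solvers, and it is what
  makes a grid of $\lambda \in [10^{-10}, 10^{-1}]$ (and the published
  choice $\lambda = 0.01$) meaningful. Under it the ridge solution equals
  the closed form $(Z^\top Z + n\lambda I)^{-1} Z^\top y$ on the centered
  standardized design — the oracle the acceptance tests check to 1e-6.
  L1 fits are delegated to glmnet's coordinate descent (convergence
  threshold 1e-12); L2 fits use an in-package SVD of the standardized
  design, because glmnet's ridge path stops ~1e-3 short of the closed
  form.
* **Objective transform.** `CS_site` is a heavy-tailed ratio of counts,
  so the default objective is `log10(CS_site)`; `transform = "raw"`
  reproduces the untransformed objective. All rank-correlation pruning is
  unaffected (Spearman is invariant to monotone transforms).

Features are z-scored on training statistics before fitting, so
coefficients are comparable across categories in the signed coefficient
reports. Cross-validation folds are assigned per gene, consistent with the
gene-level split, and the selected $\lambda$ is by default the largest one
whose mean CV MSE stays within 5% of the minimum — the sparsest model that
maintains MSE. A fixed override (e.g. 0.01) bypasses selection.

## The feature space

Around-site coordinates have no position 0: the cleavage point lies
between offsets −1 and +1, and +1 is the nucleotide whose 5' end the
degradome read detects. Within ±30 nt, every contiguous window of lengths
1–60 at every 1-nt placement is enumerated (1,830 windows), and for each
window the package computes overlapping k-mer frequencies (k = 1, 2 by
default: mono- and di-nucleotides are the token sizes that appear in the
reported models), in-frame codon frequencies and the corresponding
amino-acid frequencies. Secondary-structure stability is scored in windows
of lengths 5–60 placed every 5 nt (78 windows); ribosome occupancy is
averaged over windows within ±200 nt, truncated at transcript bounds
rather than dropped (a ±200 context requirement would discard most sites).

Whole-RNA features cover each region (5'-UTR, CDS, 3'-UTR, whole): k-mer
frequencies, 50-nt 5'/3' end-block k-mer frequencies (truncated for short
regions), a structure score, the RO sum, and — for the CDS — codon and
amino-acid frequencies plus 10-codon start/stop blocks.

Conventions chosen where the method description is silent:

* Codon frequencies count all in-frame codons overlapping the window
  (stop codons included); amino-acid denominators exclude stops, which
  encode no residue. A site window in a UTR has codon/amino-acid
  frequency 0.
* Around-site codon features are computed in frame only.
* Sites lacking the full ±30 sequence context are dropped (not padded).
* Region and transcript lengths are *not* emitted as features.
* Both pruning thresholds act on `|rho|` — negative predictors appear
  prominently among the reported coefficients, so signed filtering would
  contradict the results the method produces.
* The pairwise decorrelation rule is realized greedily: features are
  visited by decreasing `|target correlation|` (ties by column order) and
  accepted only if below 0.6 against everything already accepted. The
  output provably contains no pair at `|rho| >= 0.6` (asserted
  exhaustively in tests).
* Correlations are computed on training rows only, to avoid leakage into
  the test set.

## Structure scoring

The default folding engine is a weighted base-pair-maximization dynamic
program over nested structures: pair weights GC = −3, AU = −2, GU = −1,
minimum hairpin loop of 3 unpaired nucleotides. It is a deliberately
simple, dependency-free stand-in for a thermodynamic folder — adequate as
a *relative* stability feature, not a physical energy. A real
nearest-neighbor engine (e.g. an RNAfold binding) can be plugged in via
`options(cleavefeat.fold_backend = function(seq) ...)` and then takes
precedence. The dynamic program is verified against exhaustive structure
enumeration for all tested sequences up to 12 nt.

## The synthetic world

`sim_config()` describes a stated world, not a tuning dial: 50 genes with
5'-UTRs of 40–80 nt, CDSs of 180–220 codons (AUG start, single stop, no
internal in-frame stop), 3'-UTRs of 60–120 nt; log-normal gene abundances
(median 200, log-sd 0.5); candidate sites are CDS-internal positions with
full sequence context, subsampled at density 0.4 — chosen so the cleaved
fraction (~0.29 of transcript length) clears the 20% reliability filter
comfortably and ~10,000 analyzed sites result. Per site,

$$\log_{10} CS_i = \alpha_0 + \textstyle\sum_j \beta_j z_{ij} + \varepsilon_i,
\qquad \varepsilon_i \sim N(0, \sigma_\varepsilon^2),$$

with $\alpha_0 = -1.3$, $\sigma_\varepsilon = 0.5$, and $z$ the planted
features computed by the real feature-extraction code and z-scored across
candidate sites — so planted coefficients are in SD units, directly
comparable to the standardized fitted coefficients. Degradome reads are
Poisson with mean `abundance × CS × depth` (~50 reads at a median site),
cap reads Poisson at position 0, and RPF reads Poisson concentrated in the
CDS (UTRs at 5% of the CDS rate) with a per-gene log-normal occupancy
factor. Optional gamma mixing adds over-dispersion.

**Planted-effect identifiability.** The default planted set is ten
single-nucleotide effects, one per offset in −5..+5, |β| between 0.3 and
0.5 with mixed signs. Its layout is constrained by the pipeline itself:
decorrelation keeps only the most target-correlated member of any
correlated group, so a planted effect is recoverable only if no other
feature can out-correlate it. Two a-priori constraints follow: planted
windows must be pairwise disjoint (a wider window containing a planted
position dilutes its signal by $1/\sqrt{L}$), and — because the four
nucleotide indicators at one position anti-correlate at about −1/3, so a
two-position proxy window leaks $-\beta_{nb}/3$ of an adjacent planted
effect — adjacent planted effects must satisfy
$\beta_{nb}/\beta_p > -1.24$. The default layout arranges signs in two
contiguous blocks with the largest magnitudes facing each other at the
sign boundary, which satisfies the inequality everywhere.

**What a green test does and does not establish.** The generator emulates
the statistical structure the analysis assumes: log-linear site effects,
Poisson sampling, abundance normalization, mRNA architecture. It does not
emulate miRNA-guided cleavage, positional biases of real ribosomes,
fragment-length artifacts, or the correlated feature structure of real
transcriptomes. Green recovery tests therefore establish that the pipeline
is a correct implementation of the method, not that the method's
biological conclusions transfer.

## Acceptance scenarios

*Parameter recovery* (fixed seed 11): the default world above; the
pipeline (score → filter → split → featurize → prune → CV → fit at the
sparsity-leaning λ) must recover at least 8 of 10 planted effects with
correct signs and at most 10 false positives. Measured across several
seeds during development: 9–10 recovered, 0–5 false positives.

*Evaluation sanity* (fixed seed 21): with planted signal variance equal to
noise variance (SNR = 1), the best achievable test correlation is
$\sqrt{SNR/(1+SNR)} \approx 0.707$; the measured test r must lie within
±0.05 of the value computed from the realized ground-truth SNR. Two
scenario details are validity preconditions of that comparison, not
tuning: uniform |β| = 0.25 with σ~ε~ = √(Σβ²), and degradome depth 50
(median ~500 reads/site). Because zero-read sites drop out of the sparse
CS table, a wide log10-CS distribution at low depth truncates the
objective's lower tail and attenuates r well below the analytic limit;
at the stated depth truncation is below 1%. For this criterion λ is the
CV-MSE minimizer (tolerance 0): the check concerns prediction accuracy,
not the sparsity rule.

## Numerical and degenerate-input choices

* Percentiles for the `CS_gene` band use linear-interpolation quantiles
  (R type 7); the band is strict ("between").
* The 20% cleaved-fraction filter is applied before the percentile band
  is computed, and "cleaved" means at least one raw degradome read.
* Constant feature columns get target correlation 0 (flagged) and scale
  1 during standardization, forcing coefficient 0.
* A constant prediction vector reports Pearson r = 0 with an explicit
  flag rather than NA.
* Ties in the decorrelation ordering break by column order; column order
  itself is the deterministic spec order (category, scope, region/window,
  token).
* Degenerate CV folds (constant objective) are skipped with a log
  message; fold assignment is gene-grouped and seeded.
* Zero-length regions yield 0 for all their features, with a logged flag.

## Limitations

* The default folding score is not a thermodynamic energy; plug in a real
  folder for physical MFE values.
* miRNA-target identification is out of scope; the pipeline only consumes
  a precomputed exclusion list.
* Read trimming, alignment and genome-to-transcript mapping are upstream
  of this package: inputs are transcript-coordinate 5'-end count tracks.
* The published full-scale headline numbers (test r = 0.74 with all
  features; 0.68 sequence-only; 0.71 on an exogenous gene; 1,191 → 155
  selected features) require the deposited sequencing data and are not
  reproducible at desk scale; the package reproduces the *procedure* and
  verifies it on synthetic ground truth.
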