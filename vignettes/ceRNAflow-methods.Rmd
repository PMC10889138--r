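---
title: "Methods: trait-anchored ceRNA network inference"
author: "ceRNAflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trait-anchored ceRNA network inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models, the screening rules, the
numerical choices and the synthetic-study design behind `ceRNAflow`. The
package targets the analysis pattern of whole-transcriptome stress
studies in plants: two genotypes profiled over a stress time course
(here 0/4/12/24/48 h, three replicates each, thirty samples in total)
with matched mRNA, lncRNA and miRNA counts and a panel of nine
physiological traits (SOD, POD, CAT, T-AOC, MDA, OH⁻, proline, soluble
sugar, soluble protein), ending in a lncRNA–miRNA–mRNA competitive
triplet network anchored to the antioxidant traits.

## lncRNA filtering and positional classification

Candidates are transcripts whose *exon-sum* length is at least 200 nt
(the conventional lncRNA length bound; the boundary is inclusive, so a
200 nt transcript survives) and whose precomputed coding-potential flag
is false. Coding-potential assessment itself (CPC2, Pfam, Rfam) is out
of scope and consumed as that flag.

Classification against the coding annotation uses a fixed priority:

1. **sense** — ≥ 1 bp of exonic overlap with a coding exon on the same
   strand;
2. **antisense** — exonic overlap on the opposite strand;
3. **intronic** — the whole lncRNA span inside a single intron of one
   coding transcript, either strand, with no exonic overlap anywhere;
4. **intergenic** — everything else.

Decisions that the literature leaves open, made here and configurable
nowhere (they are definitional): exon evidence beats intron containment;
overlap means at least one shared base (no minimum-overlap fraction);
"intronic" accepts either strand; per-gene aggregation takes the
most-specific class over isoforms, and the supporting partner gene is
the one with the largest summed exonic overlap. A lncRNA on a
chromosome absent from the coding annotation is classified intergenic
with a warning rather than an error, so partial annotations degrade
gracefully.

Coordinates are handled in the Bioconductor convention (1-based, closed
intervals, `GRanges`); the GTF reader/writer is the single conversion
site against the file dialect.

## Normalization and differential expression

Counts are normalized by **median-of-ratios** size factors
(`factor_j = median_g count_gj / geomean_g`, over genes positive in all
samples, rescaled to geometric mean one). FPKM uses the shared
mRNA+lncRNA library size; miRNA uses TPM with unit lengths
(counts-proportional). Correlation-based stages work on
`log2(FPKM + 1)` / `log2(TPM + 1)`.

The DE caller is a desk-scale negative-binomial Wald test:

* dispersion `α` in `var = μ + αμ²` is estimated per gene by method of
  moments on normalized counts, pooled within groups;
* a parametric mean–dispersion trend `α(μ) = a0 + a1/μ` is fitted to
  the positive estimates (median fallback when degenerate);
* gene-wise estimates are shrunk toward the trend in log space with
  weight 0.9; non-positive moment estimates fall back to the trend, with
  a floor of 1e−8 (Poisson-like);
* the Wald statistic is the log fold change over its delta-method
  standard error `(Σ_j 1/s_j)/(n² μ) + α/n` per group, referred to the
  standard normal. A pseudocount of 0.5 enters the fold-change and
  1/μ terms only.

The normal reference with strong trend shrinkage is a calibration
choice: with three replicates per group the gene-wise moment estimate is
so noisy that a t reference over-corrects, while the strongly shrunk
normal Wald test holds its nominal size (the acceptance suite measures
the empirical type-I rate on 2,000 null genes at μ = 100, α = 0.1,
3 vs 3 and requires it in [0.03, 0.07]).

Thresholds follow the screening rules of the motivating study, both
boundaries inclusive: fold change ≥ 2 with BH FDR ≤ 0.01 for mRNA and
lncRNA; fold change ≥ 1.5 with raw p ≤ 0.05 for miRNA. "FDR" is
Benjamini–Hochberg (delegated to `stats::p.adjust`); the procedure is
not named in the source convention, so BH is the documented assumption.
Each contrast (each time point vs 0 h within each variety) is an
independent call with no cross-contrast adjustment. Scale invariance
under rescaling one library is exact for the size factor itself and
approximate (at the 1e−2 level) for the statistics, because the
geometric-mean reference and the pseudocount are not scale-free; this is
shared with the reference implementations of this test family.

## Weighted co-expression core

* **Adjacency**: unsigned `a_ij = |cor(x_i, x_j)|^β` (Pearson), default
  β = 7; a signed variant `((1 + cor)/2)^β` is available by flag.
  Unsigned is the default because the motivating analysis names neither.
* **Topological overlap**:
  `ω_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 − a_ij)` with
  `L_ij = Σ_{u≠i,j} a_iu a_uj`, `ω_ii = 1`, computed by one matrix
  product (the zero diagonal makes the u = i, j terms vanish). An O(n³)
  brute-force loop is the test oracle.
* **Module detection**: average-linkage `hclust` on `1 − ω`, *static*
  cut at a fixed dissimilarity height (default 0.95), branches smaller
  than `minSize = 30` unassigned (label 0), then iterative merging of
  modules whose eigengenes correlate above 0.8. A cut at a quantile of
  the merge heights is available but not recommended: when many
  unclustered background genes crowd the top of the dendrogram the
  upper height quantiles sit above the module-joining merges and the
  cut collapses everything into one block — the fixed height is robust
  across a wide band (0.90–0.97 on the reference fixture).
* **Eigengenes**: first singular vector of the per-gene standardized
  module submatrix, unit norm, sign-oriented so its correlation with the
  mean module profile is nonnegative; a singleton module returns that
  gene's standardized profile.
* **Module–trait**: Pearson r with the closed-form two-sided p from
  `t = r√((n−2)/(1−r²))` on n−2 df.
* **Hubs**: top five genes by intramodular connectivity
  `kWithin = Σ_{j∈module} a_ij`; exact ties break lexicographically so
  results are reproducible.
* **Input filter**: features with FPKM > 1 in ≥ 10% of samples and
  positive variance enter the network. The motivating study says only
  "after filtering"; this filter is the package's documented stand-in,
  not an inference about the original choice. Only coding genes enter
  module detection here; which feature set entered the original network
  is unstated.

## OPLS-DA and VIP

NIPALS orthogonal projections to latent structures: `nOrtho` components
of variation orthogonal to the class response are stripped
(`w_o ∝ p − (w'p)w`), then one predictive component is fitted. With a
single response column the predictive weight has the closed form
`w ∝ X'y`, which the tests use as an independent reference; with
`nOrtho = 0` the model is plain PLS-DA. Weight vectors are unit-norm
and sign-oriented (largest-magnitude element positive). Binary classes
use a centered ±1 response; more levels are dummy-coded (PLS2).

`VIP_j = √(p · Σ_a w_ja² SS_a / Σ_a SS_a)` over the predictive
component(s) only; orthogonal components are excluded (the common
alternative convention of including them is deliberately not the
default, and with one predictive component the SS weights cancel so
`ΣVIP² = p` holds exactly). Traits with VIP > 1 pass the screen.

The class factor for the trait screen is the stress *phase* — early
(0/4/12 h) vs late (24/48 h) — rather than the five time points
individually: with three replicates a five-class discriminant analysis
is badly underdetermined, and the phase contrast captures the
accumulate-then-peak physiology of the antioxidant traits.

Small closed forms live in the same module: degree of leaf curling
`DLC = (Lg − Ln)/Lg × 100` and qPCR relative expression `2^−ΔΔCt`.
Module gene-set enrichment is the upper-tail hypergeometric test
(`stats::phyper`) with BH across sets, ranked by p.

## Targeting layers

* **miRNA target scoring** uses the canonical plant small-RNA penalty
  scheme: per aligned position Watson–Crick 0, G:U wobble 0.5, mismatch
  1, penalties doubled at miRNA positions 2–13, site score = sum,
  default cutoff 4.0. The original study used TargetFinder, whose
  internals its text does not specify; this scheme is that tool's
  standard rule and every constant is configurable. Prediction slides
  the miRNA along the full transcript (whether the original scan used
  transcripts or 3′ regions is unstated; full transcripts chosen), with
  a mismatch-count prefilter (≤ 2·cutoff non-WC positions) followed by
  exact rescoring, so results equal an exhaustive scan.
* **cis targets**: a coding gene links to a lncRNA when their spans
  overlap or the gap between them is below 100 kb (span anchoring; the
  source convention does not define the anchor point, and the boundary
  is implemented strictly: gap 99,999 links, 100,001 does not).
* **trans targets**: Pearson r across samples with the t-map p-value;
  the rule is strict as printed — r > 0.9 AND p < 0.01. At least four
  samples are required and fewer than ten warns.

## ceRNA assembly

Candidate mRNAs are the three-way intersection of DE mRNAs, genes of
the trait-selected modules, and targets of DE miRNAs. Candidate lncRNAs
are the DE lncRNAs (module membership is required of mRNAs only).
For each miRNA targeting a candidate mRNA g and a candidate lncRNA l,
the triplet (l, m, g) is emitted iff `r(m,g) ≤ −0.5` and
`r(m,l) ≤ −0.5`, both with p ≤ 0.05. The −0.5/0.05 defaults quantify
"negatively co-expressed", which the motivating text leaves
unquantified; both are configurable and echoed in the run report. An
optional positive lncRNA–mRNA co-expression filter (common ceRNA
practice) exists but is off by default, and requiring the lncRNA itself
to sit in the trait module is likewise exposed as a flag, default off —
the source text is ambiguous on both. Output is ordered
lexicographically and is invariant to input row order; emitted
correlations are stored with the triplet so the predicate can be
re-audited from the persisted matrices.

## The synthetic study

`simulateStudy()` generates the full reference dataset with ground
truth. Defaults (the package's study conditions):

| parameter | default | meaning |
|---|---|---|
| design | 2 × 5 × 3 | varieties × time points (0/4/12/24/48 h) × replicates |
| nCoding / nLnc / nMirna | 800 / 60 / 60 | feature panel sizes |
| nModules / moduleSizes | 5 / 50 each | planted co-expression modules (coding genes) |
| withinModuleCor | 0.9 | latent within-module correlation ρ |
| nbDispersion | 0.1 | NB α in var = μ + αμ² |
| baseMeanLog2Range | [5, 9] | per-gene baseline log2 mean |
| geneAmplitude / mirnaAmplitude | 2 / 1.5 | log2 amplitude of the latent signal |
| deEffectLog2fc / nDeGenes | 2 / 60 | planted background DE step at t > 0 |
| nTriplets / tripletCoupling | 10 / 0.9 | planted ceRNA triplets |
| traitNoiseSd | 0.1 | driver-trait noise sd |
| classMix | 0.75 | time-trend share of the driver eigengenes |

Mechanics, in draw order (one RNG stream from `seed`; identical configs
are bit-reproducible): sequences → eigengene latents → gene latents →
miRNA latents → lncRNA latents → counts → traits.

* **Annotation**: coding genes on a 250 kb grid (two 1 kb exons, 2 kb
  intron, alternating strand); lncRNA loci constructed per positional
  class by geometry (antisense/sense over a host exon, intronic inside
  the host intron, intergenic midway between genes and therefore
  > 100 kb from both); class proportions default to values typical of
  plant annotations (43/38/8/11%). Unrealizable requests (more loci
  than host positions) fail naming the class.
* **Eigengenes** are condition-level (replicates share them, plus a
  0.15 sd jitter), as in a real time course. The two *driver* modules
  carry the stress time trend (`classMix`·trend + orthogonalized
  condition noise); the condition noise of every module is
  orthogonalized against the trend, the phase contrast and the other
  modules, so the planted modules are distinct by construction (the
  drivers share only the trend, correlation `classMix²` ≈ 0.56, safely
  below the 0.8 eigengene-merge threshold).
* **Genes**: module members mix their eigengene at √ρ with iid noise,
  amplitude 2 log2; background features are quiet, housekeeping-like
  (0.3 log2 amplitude) — realistic, and necessary for median-of-ratios
  normalization to stay anchored when a third of the genome responds.
  Background DE genes add a ±2 log2 step at all stressed time points.
* **Triplets**: each planted miRNA's latent is the *negative* of its
  driver eigengene mixed at the coupling strength c; its lncRNA partner
  is anti-coupled to the miRNA latent at c; its mRNA partner is a
  driver-module member. Latent correlations are therefore −c·√ρ
  (miRNA–mRNA) and −c (miRNA–lncRNA), attenuated in the observed data
  by count noise and compositional normalization. Exact
  reverse-complement target sites are embedded in the partner sequences
  at a known position; all other sequences are random, so spurious
  target pairs are vanishingly rare at the score-4 cutoff.
* **Traits**: SOD = −E1 + noise, POD = −E2 + noise (sign −1, matching
  the negative module–trait correlations the motivating study reports),
  OH = phase contrast + noise, and six pure-noise traits — so exactly
  SOD, POD and OH are discriminative, mirroring the VIP > 1 trio.

What the generator does *not* emulate: read-level artifacts (mapping,
GC, positional bias), batch effects, isoform complexity (one transcript
per gene), lncRNA–mRNA sequence homology, miRNA biogenesis, and
library-size variation beyond what NB sampling induces. Passing the
recovery suite therefore demonstrates the pipeline's correctness on
data satisfying its model assumptions, not robustness to the full
messiness of real RNA-seq.

Panel sizes were chosen so that signal carriers are a minority of each
library: with a tiny panel in which half the miRNAs co-vary, TPM (a
compositional normalization) subtracts the shared signal and planted
correlations collapse toward the threshold — a real phenomenon the test
fixture should not be dominated by.

## Problem sizes and runtime

The reference study is 800 + 60 + 60 features × 30 samples, a scale at
which the full pipeline (eight DE contrasts, an 800-gene TOM,
eigengene merging, targeting and assembly) completes in well under a
minute, and the complete test suite plus the acceptance script run in a
few minutes on one CPU. Calibration checks use 2,000 genes; oracle
equivalence uses fifty 20-gene networks.

## Known limitations

* The DE caller is a single two-group Wald test: no covariates, no
  outlier refitting, no independent filtering; behavioral parity with
  DESeq2 or edgeR is not claimed.
* Module detection is the static-cut variant, not Dynamic Hybrid tree
  cut; for data with nested or tightly adjacent modules the fixed
  height is a coarser instrument, and numerical parity with the WGCNA
  package is not claimed.
* OPLS-DA ships no cross-validated R²/Q² diagnostics or permutation
  tests; VIP screening should be read as ranking, not inference.
* The targeting scorer is ungapped; thermodynamic models, bulges and
  conservation filters are out of scope.
* Triplet assembly uses marginal correlations; it does not compute
  conditional-independence or sensitivity-style ceRNA scores.
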