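---
title: "Detecting allelic variation in diel transcription with dielscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting allelic variation in diel transcription with dielscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dielscan)
```

## The problem

Plant transcriptomes reorganize massively over the 24-hour day–night
cycle, and the promoter sequence upstream of a gene is a major
determinant of whether, and how strongly, that gene cycles. In a
diverse panel of inbred lines, the same pan-gene can cycle in some
genotypes and stay flat in others. When that difference co-segregates
with the promoter haplotype, it is evidence for *cis*-regulated,
heritable variation in diel expression — the raw material selection can
act on when day length changes, as it does when a crop moves poleward.

`dielscan` implements this analysis end to end for a two-design study:

* a **field design** — many inbreds (default 24), one series per
  inbred, sampled every 2 h for 24 h (hours 6 through 28, 12 points);
* a **growth-chamber design** — a few genotypes (default 4), sampled
  every 3 h for 30 h (11 points) with 2 replicates, used to confirm
  candidates found in the field.

Because the raw study data are external, the package ships a
synthetic-data generator with a complete ground-truth ledger, so every
stage can be exercised and validated without downloads.

## The rhythmicity model

Each (gene, genotype) series is modeled as a fixed-period sinusoid

$$y(t) = M + A\,\sin(2\pi t/T + \varphi) + \varepsilon,
  \qquad \varepsilon \sim N(0, \sigma^2),\; T = 24\ \mathrm h,$$

with MESOR $M$ (rhythm-adjusted mean), amplitude $A \ge 0$ and phase
$\varphi$ (reported to users as the peak time in hours). Writing
$A\sin(\omega t + \varphi) = a\sin\omega t + b\cos\omega t$ makes the
model linear in $(M, a, b)$, so the maximum-likelihood fit is ordinary
least squares on the sine/cosine basis, with
$A = \sqrt{a^2 + b^2}$ and $\varphi = \mathrm{atan2}(b, a)$. The test
suite verifies on seeded instances that this linearized fit coincides
with a nonlinear grid-search MLE to $|\Delta A| < 10^{-6}$.

Rhythmicity is tested by the likelihood ratio against an
intercept-only model, $\mathrm{LR} = n\log(\mathrm{RSS}_0 /
\mathrm{RSS}_1)$ on 2 degrees of freedom. **Inference default.** At
diel series lengths ($n = 12$) the large-sample $\chi^2_2$ reference is
visibly anticonservative (about 3% rejection at nominal 1%), so the
default p-value uses the exact finite-sample route: the LR statistic is
a monotone function of the nested-model F statistic, which follows
$F(2, n-3)$ exactly under Gaussian errors. `method = "asymptotic"`
restores the $\chi^2$ reference. A numerically perfect fit is reported
as $p = 0$ with a `perfect_fit` flag.

The between-group amplitude test (`lr_diff_amplitude`) compares a full
model with per-group $(A, \varphi, M)$ to a reduced model with a shared
amplitude, per-group phase and MESOR, and a pooled error variance. The
reduced fit profiles the likelihood over the shared amplitude: for a
fixed $A$ the inner minimization over $(\varphi, M)$ is a smooth
problem on the circle solved by multi-start 1-D optimization; the outer
profile over $A$ is bracketed on a grid and refined. The statistic is
referred to $F(1, n-6)$ by default for the same finite-sample reason;
simulations in the test suite confirm near-nominal rejection rates.
Replicate series within a group are pooled into one likelihood with
independent errors — the chamber design's two pots per timepoint are
treated exactly this way.

The relative amplitude is defined as $A/M$ (undefined, `NA`, when
$M \le 0$). This is the amplitude on a fold-change-like scale and is
one of the three labels the promoter model is trained on.

## DDR detection: the field stage

A pan-gene shows *Differential Diel Regulation* (DDR) when its diel
expression range — max minus min abundance across the time course,
replicates averaged per timepoint first — differs by promoter
haplotype. Per pan-gene the package computes each inbred's diel range,
groups inbreds by haplotype, and tests association with a
Kruskal–Wallis statistic whose null distribution comes from 10,000
haplotype-label permutations.

Implementation notes that matter for correctness and speed:

* Ranks are invariant under label permutation, so the rank vector and
  tie correction are computed once and each permutation reduces to
  group sums of a permuted rank vector; all 10,000 permutations are one
  matrix product per gene.
* When the number of distinct label assignments is at most 200 the null
  is enumerated exhaustively and the p-value is the exact proportion;
  otherwise the sampled estimator $(1 + \#\{H^\ast \ge H\})/(1 +
  n_\mathrm{perm})$ is used, so p-values never reach 0 and never fall
  below $1/(n_\mathrm{perm}+1)$.
* Singleton haplotype groups are retained (the statistic tolerates
  them); a pan-gene with fewer than two haplotypes is reported
  untestable rather than dropped silently.

A pan-gene is a **DDR candidate** when all three rules hold: KW
permutation p < 0.05; at least 6 inbreds individually rhythmic at
p < 0.01; and at least 6 inbreds with baseline abundance above 50.
"Baseline abundance" is not pinned down by the upstream definition of
the filter; this package uses the mean normalized abundance across the
time course (robust and simple; the accessor is a single place to
change if a pre-dawn or median definition is preferred).

Candidates are **confirmed** in the chamber design by grouping its
genotypes by haplotype: one haplotype means the gene is untestable; two
haplotypes give a single amplitude-difference test; three or more give
all pairwise tests with the minimum p-value kept, deliberately without
multiplicity correction, and significance declared at p < 0.01.

## Enrichment stage

Four statistics connect DDR candidates to independent evidence:

* **GWAS signal** (`gwas_enrichment`): the mean over candidates of the
  minimum association p-value within gene ± 1000 bp, compared to 1,000
  draws of equally many genes from a null set (lower is enriched).
  Genes whose window contains no SNP are dropped from the mean and
  counted. Four standard null sets are built by `null_gene_sets()`:
  all genes; transcribed genes; genes cycling in ≥ 2 inbreds; genes
  cycling in ≥ 22 inbreds.
* **Adaptation-SNP overlap** (`adaptation_overlap_enrichment`): the
  count of adaptation-candidate SNPs inside candidate windows versus
  the same count on null gene draws (higher is enriched). Ties count
  toward the null — with a strict "more than" rule a degenerate
  all-zero overlap distribution would report maximal enrichment, which
  is the wrong answer for empty evidence.
* **Per-site Fst** (`weir_cockerham_fst`): the Weir–Cockerham
  variance-components estimator for two diploid populations,
  $\hat F_{ST} = a/(a+b+c)$, used to rank SNPs between phenotype
  extremes; `top_k_snps` keeps the 10,000 highest with ties at the
  cutoff broken by genomic order. The estimator may be slightly
  negative near zero differentiation; monomorphic sites are `NA`.
* **Fisher's combined test** (`fisher_combined`):
  $-2\sum\ln p_i \sim \chi^2_{2k}$, for aggregating the per-experiment
  enrichment p-values.

The night−day eQTL stage regresses the per-individual night minus day
expression difference on additive SNP dosage within 5,000 bp of the
focal gene (`cis_eqtl_scan`), then asks whether cis-eQTL co-localize
with GWAS hits (p < 1e-5) more often than 10,000 random SNP draws
matched for minor-allele-frequency decile and distance-to-nearest-gene
bin (0, ≤500, ≤1000, ≤2500, ≤5000, >5000 bp). The matching bins are a
discretization choice: the matching criteria are principled, the
binning is configurable convention. Empty strata widen to neighboring
MAF bins with a warning.

All sampled enrichment tests switch to exhaustive enumeration when the
number of distinct null draws is at most 5,000, and all use the
bias-safe $(1+\#)/(1+n)$ estimator, so the test suite can check the
sampled and enumerated routes against each other.

## The synthetic study and what it does (not) emulate

`sim_config()` defaults *are* the study conditions; they were fixed
from the design, not adjusted to test outcomes:

* 24 inbreds, 200 pan-genes, 90% core; field and chamber grids as
  above.
* 30% of pan-genes rhythmic; 10% DDR. DDR genes carry two amplitude
  classes, 0 versus 3 abundance units, with each class carried by at
  least 6 of 24 inbreds. The floor reflects the regime the detector is
  built for: the ≥ 6-cycling-inbreds candidacy rule cannot be met by a
  variant whose high-amplitude class is rarer than 6 carriers, and
  consensus promoter haplotypes at ≥ 25% frequency are the common-variant
  setting of a diversity panel.
* MESOR lognormal around 100 (sdlog 0.4 across genes, 0.1 across
  genotypes within gene), so the baseline > 50 expression filter is
  active but not binding for most genes; phase uniform; noise additive
  Gaussian with σ = 0.3 on the normalized scale, zero-clipped —
  matching the Gaussian likelihood of the rhythmicity test so
  calibration properties are exact.
* Promoters are 1,500 bp i.i.d. background at 45% GC, one sequence per
  (pan-gene, haplotype) shared by all carriers; haplotypes with
  positive amplitude receive 1–3 copies of the Evening Element
  AAATATCT at recorded positions. Sequence and amplitude therefore
  co-vary exactly as the haplotype model prescribes.
* SNP p-values are Uniform(0,1) in the background and Beta(0.1, 1)
  within 1 kb of DDR genes when the spike is enabled; adaptation
  candidates are near-DDR SNPs with probability 0.3 plus a 2%
  background; genotypes, when requested, are Hardy–Weinberg draws at
  the SNP's allele frequency.

Deliberately **not** emulated: linkage disequilibrium between SNPs,
read-level count noise (the generator produces normalized abundances
directly), non-sinusoidal waveforms, shared-cell-type composition
effects, and genuine phylogenetic structure among inbreds. Passing the
truth-recovery tests therefore demonstrates that the statistics do what
they claim under their own model assumptions — not that real maize data
meet those assumptions.

## The promoter sequence model

The promoter model maps one-hot-encoded sequence (−1000/+500 bp around
the TSS, N as 0.25 in each row) to three continuous rhythmicity labels
— relative amplitude, −log10 rhythmicity p (capped at 20 so perfect
fits do not produce infinite targets), and R² — through the
convolution → max-pool → bidirectional-LSTM → dense topology
familiar from DanQ-class genomics models. No deep-learning framework
is available to R in this package's dependency footprint, so the
network is implemented directly on base matrix algebra with
hand-derived gradients; the test suite checks every parameter block
against numerical derivatives, and training is bit-reproducible under
a fixed seed (single-threaded).

Architecture and training choices (desk scale, configurable):

* 32 filters × 13 bp, valid-mode convolution, ReLU, non-overlapping
  max-pool of width 6; 16 LSTM units per direction.
* The sequence readout is the per-unit **maximum over time** of the
  BiLSTM hidden states. A mean-over-time readout was tried first and
  starved the gradient — a 1–3-copy motif occupies a few of ~250
  pooled positions, and averaging dilutes it ~100-fold; the max
  readout routes the gradient to the position that detected the motif,
  which is the right inductive bias for presence-style signals.
* Forget-gate biases initialize at 1 (standard practice to keep cell
  memory alive early in training).
* Loss is the unweighted sum of per-output MSE on labels standardized
  with training-set statistics; optimizer is Adam (base lr 5e-3 at
  desk scale, batch 64) with a cosine-decayed learning rate and
  decoupled weight decay (AdamW, 1e-2 at desk scale) on weight
  matrices. The decay and the weight decay are what make the learned
  filters *specific*: without them filters spread credit over
  background and their extracted motifs blur.
* Desk-scale training runs 50 epochs on ~600–700 promoters from 4
  genotypes, split 3 train / 1 validation **by genotype**, so no
  pan-gene's alleles straddle the split. Paper-scale settings (500
  epochs, 12/3 genotypes) are reachable through `cnn_config()`.

Trained filters become motifs by the activation-alignment route:
collect the filter-width subsequences wherever the activation reaches
half that filter's maximum, build a position frequency matrix with
pseudocount 1 (filters with fewer than 10 sites are dropped).
`motif_match_score` compares a learned PFM to a reference (PFM or
IUPAC string) by the maximum over ungapped offsets (overlap ≥ 5
columns) and both strands of the mean per-column Pearson correlation,
with zero-variance columns contributing 0.

## Numerical conventions

* Coordinates are 0-based half-open everywhere (BED convention); the
  TSS of a minus-strand gene is its larger coordinate; promoter
  windows truncate at position 0.
* Size factors are median-of-ratios with the reference set restricted
  to genes with no zero count, computed within each genotype's sample
  set (each inbred is quantified against its own genome, so
  normalization is within-genotype across timepoints).
* Sinusoid fits require ≥ 4 observations at ≥ 3 distinct times and a
  full-rank basis; constant series give $A = 0$, $R^2 = 0$, LR 0.
* Permutation seeds: scans derive independent per-gene seeds from the
  master seed, so per-gene results do not depend on scan order.
* Top-k and enumeration tie-breaks are deterministic (genomic order;
  first-index argmax in pooling).

## Problem sizes used by the checks

The shipped tests and the acceptance script run, per stage: 10,000
null simulations for LR calibration; the full default study (24
inbreds × 200 pan-genes, 10,000 KW permutations per gene) for DDR
truth recovery; 200 replicate enrichment runs for calibration checks;
2,000 SNPs for the panmixia Fst check; and five independent
seed/simulation pairs for planted-motif recovery. These sizes were
chosen as the smallest at which the binomial/Monte-Carlo error of each
check is well inside the asserted bounds.

## Known limitations

* The fixed 24-h period means impulse-like, sawtooth, or
  period-shifted dynamics are invisible to the LR test by design.
* The amplitude-difference profile likelihood assumes a common error
  variance across haplotype groups.
* The matched-overlap null treats SNPs as exchangeable within strata;
  real linkage disequilibrium would require block-aware draws.
* The promoter model at desk scale demonstrates motif recovery on
  synthetic promoters; nothing here claims genome-scale predictive
  accuracy on real tissue data.
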