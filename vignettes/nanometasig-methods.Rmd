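---
title: "Methods: consensus ENM signatures, from meta-analysis to dose response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus ENM signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical machinery of `nanometasig`: the
models each stage assumes, the tunable parameters and their defaults, what
the synthetic-data generator emulates, and the numerical and design
choices made where conventions were genuinely open.

## 1. Input model

The unit of evidence is a *contrast*: one exposure condition (one ENM, one
biological system, one duration, one dose) summarised per gene by a log2
fold change, a p-value and a BH-adjusted p-value. A `de_collection` holds
complete gene × contrast matrices over the genes shared by all contrasts,
plus per-contrast metadata (system, duration class, ENM group, sample
size). Preprocessing and differential-expression testing happen upstream;
this package consumes their outputs.

## 2. Ensemble meta-analysis

Three methods with different strengths are combined rather than trusting
any one:

* **Effect size.** Each two-sided p is converted to a χ² quantile on 1 df,
  then φ = √(χ²/n) and Cohen's d = 2φ/√(1−φ²) with variance 4/n, pooled by
  fixed-effect inverse-variance weighting; direction comes from
  sign(logFC). Two numerical guards: p-values are clipped at 1e-300, and φ
  is capped just below 1 (χ² ≥ n would otherwise make d infinite — with
  per-contrast n = 6, any p below ~0.014 reaches the cap, so extreme
  p-values yield a large, finite, rank-preserving d). Per-contrast sample
  size defaults to 6, typical of the small exposure studies the method is
  aimed at, and is configurable in the metadata.
* **Fisher's sum of logs.** X² = −2Σ ln p on 2k df. Exact under
  independent uniform nulls; the type-I error at α = 0.05 is verified to
  sit in [0.035, 0.065] on 1,000 null genes × 10 contrasts.
* **Rank product (one-class).** Genes are ranked within each contrast by
  ascending p (average ranks on ties); RP is the geometric mean of a
  gene's ranks. The null treats a gene's ranks as independent uniforms;
  it is enumerated exhaustively when G^D ≤ 2·10⁵ (then p-values are
  exact) and sampled with +1 smoothing otherwise. The statistic is
  invariant to monotone transforms of p by construction.

Each method ranks genes by its combined statistic (effect-size and Fisher
by p, RP by the RP value), and the **Borda** mean rank merges them; all
ties break lexicographically on gene id so results are deterministic. The
optional fold-change-weighted variant replaces the within-contrast
statistic of the rank-product arm with |logFC|·(−log10 p); the weighting
is a package choice, as only the existence of such a variant is
established practice.

Robustness is assessed by cumulatively removing ENM groups and comparing
the reduced consensus with the full one (Kendall's τ with the
normal-approximation test, plus an OLS fit of position on position with
its R² and F-test).

## 3. Signature cut

Pre-ranked GSEA uses the standard weighted running sum: gains
|s|^exponent normalised over the set's hits, losses 1/(N−N_hits), ES = the
extremum of largest absolute value, whose index is the leading-edge peak.
The null samples random same-size gene sets (the pipeline consumes ranks,
not sample-level data, so phenotype permutation is not available);
p-values are two-sided on |ES| with +1 smoothing, BH-adjusted across sets,
and sets outside 15–1000 in-universe genes are dropped before testing.

The signature cut collects the peak positions of all significant sets and
takes their 10th percentile, pooled across collections, with the type-7
(linearly interpolated) quantile rounded up to an integer position. The
rule is monotone: adding a significant set with a larger peak never
shrinks the signature.

## 4. Duration classes, frequency scores, persistence

Duration boundaries: in vitro ≤24 h short, >24–72 h intermediate, >72 h
long; in vivo ≤3 d short, >3 d–1 month intermediate, beyond that long,
with "1 month" fixed at 30 days. The frequency score of a gene in a
(system, duration-class) group is the percentage of that group's
contrasts where its BH-adjusted p is below α = 0.05; "significant" is
taken as adjusted rather than nominal significance so the score has a
stable meaning across collections of different size.

Profiles are clustered with `hclust` on Euclidean distances and Ward's
linkage (`ward.D2`), cut at `n_clusters` (default 4). Among clusters whose
mean long-duration frequency reaches 40%, the one with the highest mean is
selected (ties: larger cluster, then smallest label). **Sensitivity to
k:** when each duration class contains only a handful of contrasts the
frequency score is coarse (steps of 25% at four contrasts), within-class
variation inflates, and k = 4 can split the persistent block — the
single-cluster selection rule then under-selects. The demo configuration
therefore clusters at k = 2; at compendium scale (thousands of genes, many
contrasts per class) the default k = 4 recovers the planted persistent set
with Jaccard > 0.9.

## 5. Promoter analysis

Promoters are the [−500, +100) window around the TSS in 0-based half-open
coordinates; BED input is taken at face value (TSS = `start` for +,
`end − 1` for −); minus-strand windows are mirrored and
reverse-complemented so every sequence reads 5'→3' on the gene's strand
and is exactly 600 bp; windows off the contig raise an error rather than
being padded.

The built-in finder is a deliberately simplified any-number-of-repetitions
EM, not a MEME reimplementation, and is documented as not bit-compatible
with it:

* **Seeding.** For each width in [6, 15], candidate words are the most
  background-enriched w-mers of a *training* half of the sequences,
  re-ranked by their Hamming-1-ball counts (instances of a real motif
  scatter into one-mismatch words; coincidental exact repeats do not) and
  filtered so shifted variants of one word cannot occupy every slot
  (shared w−2 core on either strand). Six seeds per width by default.
* **EM.** The PWM (pseudocount 0.25/cell) and a site prior γ (capped at
  0.005) are refined for 10 iterations against a 0-order background
  estimated from the input. Two stabilisers matter: positions with
  posterior below 1e-4 are excluded from the M-step (they only blur the
  columns), and only positions that are local score maxima within one
  motif width on their own sequence enter the update — without the latter,
  overlapping shifted windows of a single site (G-runs, near-palindromes)
  smear the columns into degenerate run motifs.
* **Significance.** On the *held-out* half — independent of everything the
  model saw — sites are counted at score thresholds whose exact background
  tail probabilities (computed by column-wise convolution of the
  discretized score distribution; the scan uses the same discretized
  matrix so threshold and count agree exactly) are at most 1e-6, 1e-5,
  1e-4 and 1e-3; each count gets a binomial upper-tail p, and the best
  level is Bonferroni-corrected for the number of levels and of
  width×seed candidates tried. Soft matrices (e.g. near-palindromic
  motifs whose two alignments mix) only attain the looser tails, which is
  why several levels are tested. Motifs passing 0.05 are re-fitted on all
  sequences and shadows (a consensus contained in an already-kept one on
  either strand) are collapsed.

Matching against a PWM library maximises, over alignment offsets (≥6
overlapping columns) and strands, the mean column-wise Pearson correlation
of the normalised matrices; 0.8 is the default acceptance threshold.
Family overrepresentation is the one-sided Fisher exact test of matched
vs unmatched library profiles × C2H2–ZNF vs other; an empty matched set
returns p = 1 rather than erroring. Positional enrichment of target genes
along the consensus rank uses a sliding-window density and a one-sided
Kolmogorov–Smirnov test for shift toward the top.

## 6. Nanodescriptors and descriptor–gene association

Unit policy: molecular weight in g/mol, density in g/cm³, lengths in nm,
temperature in K; N_A = 6.02214076e23. The liquid-drop relations are
implemented literally (r_w = (3M/4πρN_A)^⅓ with the cm³→nm³ conversion
folded in; n = (r₀/r_w)³; S = 4n^{−⅓}; SV = S/(1−S), flagged undefined
when S ≥ 1, i.e. below 64 units; h = 0.01(T−273)r^0.35, negative below
273 K and flagged but allowed). The coordination-number cutoff is
R = 1.2·(r_i + r_j), the scaled *sum* of the two atoms' ionic radii — the
standard bonding-cutoff convention for metal–oxygen pairs. The
surface-normal force is the projection (x·f_x + y·f_y + z·f_z)/d with d
the distance from the centre of mass; coordinates are taken as already
centred, and d = 0 errors.

For descriptor–gene association, log2 fold changes are winsorized per gene
at the 5th/95th percentiles (the quantiles are configurable; the layer
carries occasional extreme values), descriptors get a signed cube root
(the sign convention for negative values is a package choice), and
Pearson correlation is computed on pairwise-complete cases with at least
3 pairs (missing otherwise). Each descriptor's top 10% of genes by
absolute correlation is tested by pre-ranked GSEA on the consensus rank;
descriptors passing BH-adjusted p < 0.01 are reported as linked.

## 7. AOP enrichment

Per-event one-sided Fisher exact tests with Bonferroni correction across
tested events (adjusted p < 0.05). A whole AOP is reported iff the union
of its events' genes is enriched at nominal p < 0.05 *and* at least
one-third of its events individually pass nominal 0.05 — the one-third
rule uses unadjusted per-event significance, and all listed events (MIEs
and AOs included) count toward the denominator.

## 8. Benchmark-dose analysis

Five mean functions — linear, quadratic, power (a + b·x^g, g ∈ [0.1, 8]),
exponential (a·e^{bx}) and Hill (a + b·x^n/(k^n + x^n)) — are fitted by
least squares under a constant-variance Gaussian likelihood (σ counted as
a parameter). Model selection uses **AICc**: dose series have 12–15
observations for 3–5 parameters, where plain AIC is known to over-select
flexible models; with the small-sample correction the generating family
is recovered in ≳85% of low-noise simulations. Lack of fit is an F-test
against the saturated per-dose-means model.

The benchmark response is BMRF·σ̂ with BMRF = 1.349 (≈10% shift of a
normal response distribution); the BMD is the smallest dose where the
fitted curve deviates from its fitted control value by that amount
(direction auto-detected from the fit; undefined and flagged if the curve
never reaches it within the dose range). BMDL/BMDU come from the profile
likelihood: for a candidate benchmark dose, one mean parameter is
eliminated through the benchmark constraint, the rest (and σ) are
re-maximised, and the limits are where the profile deviance crosses the
χ²₁ quantile of the two-sided 90% level; the search brackets
[BMD/100, 10·max dose], with unbounded profiles flagged (such genes fall
to the ratio filters). By construction BMDL ≤ BMD ≤ BMDU whenever all are
defined. The filter cascade removes genes with lack-of-fit p ≤ 0.01,
undefined estimates, BMD or BMDU above the highest tested dose, or ratios
exceeding BMD/BMDL > 20, BMDU/BMD > 20, BMDU/BMDL > 40 (strict
inequalities, as removal rules).

## 9. The synthetic-data generator

The generator emulates the statistical structure of a heterogeneous
exposure compendium; it is the ground truth against which every stage is
validated.

* **DE collection.** Null genes draw z ~ N(0, 1) per contrast; planted
  genes draw z ~ N(s_g(d + η_e + δ_j), 1) with a fixed per-gene direction
  s_g = ±1, baseline effect d (default 1.0), a contrast-level
  heterogeneity shift δ_j ~ N(0, 0.3), and an ENM-group potency factor
  η_e ~ N(0, 0.8) shared by all planted genes — the latent structure a
  material descriptor can track. p-values are two-sided normal tails, BH
  adjusted within contrast; log2FC is proportional to z.
* **Persistent core.** A fraction (default 0.3) of planted genes is
  *persistent*: in long-duration contrasts their standardized effect is
  d + 4.5 regardless of the ENM's potency, representing a shared
  long-term mechanism. The boost is computed from the detection
  requirement, not tuned: at compendium scale the within-contrast BH
  threshold sits near |z| ≈ 3.3, so a per-contrast detection probability
  of ~0.99 — i.e. genuinely persistent significance, which the 40%
  frequency rule presumes — needs a mean |z| around 5.5.
* **Promoters.** 0-order background sequences; each planted gene receives
  each of six distinct GC-rich zinc-finger-style consensus words
  (`znf_consensus_words()`) with probability `insertion_prob` (instances
  sampled from a 0.9-concentration PFM, uniform position and strand);
  non-planted genes at `background_prob`. The accompanying synthetic PWM
  library (10 family, 90 other profiles) provides the matching
  background.
* **Descriptors.** A linked descriptor is the sign-aligned mean per-ENM
  fold-change profile of its linked genes (dominated by η) plus noise;
  unlinked descriptors are pure noise; cells go missing independently at
  a configurable rate.
* **Dose series.** Linear or Hill responses plus constant-variance noise;
  the recorded true BMD is BMRF·σ/|b| for linear genes and the numeric
  inversion otherwise.
* **AOP annotation.** Events sample the universe uniformly except
  designated enriched events, which over-sample the target set at a given
  odds ratio.

All randomness flows from one integer master seed through a counter-based
splitting scheme (`split_seed`), so modules regenerate independently and
the full pipeline is byte-deterministic for a fixed seed.

**What passing tests do and do not show.** Recovery on this generator
demonstrates that each stage extracts exactly the structure it claims to
extract, at realistic effect sizes and sample counts. It does not
exercise microarray preprocessing artefacts, batch effects, correlated
gene-gene backgrounds, higher-order promoter sequence composition, or
annotation noise — real compendia are harder on all of these, and the
out-of-scope preprocessing (normalisation, batch correction, ortholog
mapping) must be handled upstream. Two small-sample caveats are worth
knowing: with only ~8–12 ENM groups, a noise descriptor can align with
the latent potency factor by chance (the demo occasionally selects one
extra descriptor), and motif discovery needs on the order of 25+
instances per word to be reliable — the word-level recovery is
intentionally borderline below that.

## 10. Problem sizes used in the shipped checks

The default generator configuration is 2,000 genes × 24 contrasts with
150 planted (consensus AUROC ≥ 0.9, persistent Jaccard ≥ 0.8). The demo
pipeline runs 600 genes × 24 contrasts end-to-end in ~20 s. Motif checks
use 200 promoters (40% planted at insertion 0.4 vs 5% background) and 20
background-only replicates; benchmark-dose checks use 50 replicates of a
5-dose, 3-replicate linear design. These sizes are the package's choice
of a compact but statistically meaningful regime; all are configurable.
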