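# nanometasig

Consensus transcriptomic signatures of engineered nanomaterial (ENM)
exposure, from heterogeneous differential-expression compendia to
regulatory and dose-response characterisation.

## The problem

Toxicogenomic evidence for ENMs is scattered over dozens of small
microarray and RNA-seq studies that differ in material, biological system,
exposure duration and dose. No single contrast is representative, but the
compendium as a whole carries a shared mechanism-of-action signal.
`nanometasig` implements a complete analysis chain for extracting and
characterising that signal:

1. **Ensemble meta-analysis.** For every gene, per-contrast p-values are
   combined three ways — a fixed-effect effect-size model (p → χ²(1 df) →
   φ = √(χ²/n) → Cohen's *d* = 2φ/√(1−φ²), var *d* = 4/n, inverse-variance
   pooling), Fisher's sum of logs (X² = −2Σln p on 2k df), and the one-class
   rank product (geometric mean of within-contrast ranks, permutation
   null). The three per-method rankings are merged by Borda mean rank.
2. **Peak-based signature cut.** Pre-ranked GSEA runs pathway collections
   against the consensus rank; the leading-edge peak positions of all
   significantly enriched sets are pooled and the cut is placed at their
   10th percentile, yielding the exposure signature.
3. **Persistence analysis.** Contrasts are grouped by exposure system and
   duration class (in vitro: ≤24 h short, ≤72 h intermediate, longer =
   long; in vivo: ≤3 d, ≤30 d, longer). A gene's frequency score is the
   percentage of a group's contrasts in which it is BH-significant.
   Ward/Euclidean clustering of these profiles isolates the cluster of
   genes deregulated in at least 40% of long-term contrasts.
4. **Promoter regulation.** Promoters ([−500, +100) around the TSS,
   strand-aware) of persistent genes are scanned by a built-in EM motif
   finder (widths 6–15, any number of repetitions, held-out binomial
   significance). Discovered motifs are matched against a JASPAR-style PWM
   library and tested for overrepresentation of the Cys2-His2 zinc-finger
   (C2H2–ZNF) transcription-factor family by one-sided Fisher exact test.
5. **Nanodescriptors.** Liquid-drop-model descriptors (Wigner–Seitz radius
   r_w = (3M/4πρN_A)^⅓, agglomerate count n = (r₀/r_w)³, surface ratio
   S = 4n^{−⅓}, surface–volume ratio SV = S/(1−S), interfacial thickness
   h = 0.01(T−273)r^0.35), atomistic coordination numbers and
   surface-normal force projections. Descriptor–gene association uses
   winsorized log2FC, cube-root-transformed descriptors, pairwise-complete
   Pearson correlation, and GSEA of each descriptor's top-10% correlated
   genes on the consensus rank (BH-adjusted p < 0.01).
6. **Adverse outcome pathways.** Fisher overrepresentation of target genes
   in MIE/KE/AO event gene sets (Bonferroni), and whole-AOP reporting when
   the union-of-genes test passes 0.05 *and* at least one-third of the
   AOP's events are individually significant.
7. **Benchmark dose.** Five dose-response models (linear, quadratic,
   power, exponential, Hill) fitted under constant variance; lowest-AICc
   model selected; BMD at benchmark response 1.349·SD with
   profile-likelihood BMDL/BMDU; filter cascade (lack-of-fit p > 0.01,
   estimates within the dose range, BMD/BMDL ≤ 20, BMDU/BMD ≤ 20,
   BMDU/BMDL ≤ 40); fraction of dose-dependent genes covered by the
   zinc-finger target set.

A first-class synthetic-data generator (`synth_config()`,
`generate_de_collection()`, `generate_promoters()`, ...) plants known
signature genes, persistent genes, promoter motifs, descriptor links and
dose-responsive genes, so every stage is verifiable by parameter recovery.

## Worked example

```r
library(nanometasig)
report <- run_pipeline(demo_config(seed = 42))
print(report)
```

```
nanometasig run (20.7s, config 32127c6a)
stage outputs:
  inputs       <outdir>/de_stats.tsv
  meta         <outdir>/consensus_rank.tsv
  gsea         <outdir>/gsea_results.tsv
  cluster      <outdir>/frequency_in_vitro.tsv
  promoter     <outdir>/motifs.tsv
  descriptors  <outdir>/descriptor_gsea.tsv
  aop          <outdir>/aop_events.tsv
  bmd          <outdir>/bmd_results.tsv
summary:
  n_genes                  600
  n_contrasts              24
  signature_size           140
  n_persistent             69
  overlap_shared           68
  n_motifs                 3
  n_matched_family         3
  n_selected_descriptors   3
  n_significant_events     4
  n_kept_aops              1
  n_dose_dependent         10
  dose_target_fraction     90
recovery vs ground truth:
  consensus_auroc          0.9868
  persistent_jaccard       0.9855
  family_fisher_p          0.0007421
  target_density_ks_p      0
```

Reading the output: from a synthetic compendium of 600 genes × 24
contrasts with a planted 150-gene signature, the Borda consensus separates
planted from null genes with AUROC 0.987; the GSEA peak cut keeps 140
genes; frequency clustering recovers the planted persistent core almost
exactly (Jaccard 0.986, 68 genes shared between the in vitro and in vivo
clusters); all 3 discovered promoter motifs match zinc-finger library
profiles (family Fisher p = 7.4e-4); 3 of 8 descriptors — exactly the
planted ones — are linked to the signature; the enriched AOP passes the
one-third rule; and 9 of the 10 dose-dependent genes (90%) are
zinc-finger targets.

Every stage is also callable on its own (`run_meta_analysis()`,
`preranked_gsea()`, `frequency_scores()`, `discover_motifs()`,
`liquid_drop_descriptors()`, `enrich_aops()`, `bmd_analysis()`, ...), and
configs can be read from YAML via `read_pipeline_config()`.

### Atomistic structure input

`read_xyz()` reads plain XYZ files with an extended dialect: columns 5–7,
when present, are the per-atom force vector (`fx fy fz`) used by
`surface_normal_force()`. Coordinates are taken relative to the centre of
mass.

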