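---
title: "Scoring transcript damage from synonymous and intronic variants"
author: "trapscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring transcript damage from synonymous and intronic variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trapscore)
```

## The problem

Variant prioritization tools built around amino-acid substitutions or
evolutionary conservation systematically miss variants that damage a gene
through its *transcript*: a synonymous substitution can weaken the donor
site of its exon, complete a cryptic splice core that competes with the
authentic junction, or delete an exonic splicing enhancer. These events
are frequently species-specific and weakly conserved, so conservation
scores are blind to many of them. `trapscore` implements a
transcript-centred scoring framework: sequence-level splicing features are
extracted per variant-in-transcript and combined by a random forest whose
vote fraction is the pathogenicity score.

## Splice-site scoring model

Both splice-site classes are modeled as position-specific scoring matrices
(PSSMs) over base frequencies:

* **donor (5'ss)**: last 3 exonic + first 6 intronic nucleotides, K = 9,
  with the invariant GT (or GC) core at positions 4–5;
* **acceptor (3'ss)**: last 20 intronic + first 3 exonic nucleotides,
  K = 23, with the invariant AG core at positions 19–20.

Only introns whose boundary dinucleotides are G[T/C]..AG contribute, and
both matrices are trained from the same intron set. A window is scored as
the sum of `log2` frequencies of its bases and normalized to 0–100 between
the bounds `Min` and `Max`.

Numerical choices:

* **Pseudocounts.** One count per base per position is added before
  normalizing frequencies (Laplace), so `log2` never sees zero. At
  realistic training sizes this preserves the ordering of sites.
* **Normalization bounds.** `Min`/`Max` are the *analytic* extremes over
  all possible K-mers (`sum of per-position min/max log2 f`). This reading
  is deterministic, independent of which sites happen to be annotated, and
  guarantees every genomic motif maps into [0, 100]; the argmax motif
  scores exactly 100 and the argmin exactly 0. `build_pssms(...,
  bounds = "annotated")` computes the alternative reading (extremes over
  the annotated training sites) for comparison; under it, unannotated
  motifs can fall outside the observed range and are clamped.
* **Windows containing `N`** score as missing and are imputed as 0 in the
  feature vector, with a warning.

## The 20-feature vector

For each variant and each harboring transcript (intronic variants attach
to the nearest exon; equidistant ties go to the upstream exon):

| block | features |
|---|---|
| site strength | `acc_score_ref/alt`, `don_score_ref/alt`, `acc_delta`, `don_delta` |
| cryptic sites | `cryptic5_score`, `cryptic3_score`, `cryptic5_lost`, `cryptic3_lost` |
| interactions | `splice_site_overall`, `variant_splice_score` |
| regulatory | `esr_created/disrupted`, `silencer_created/disrupted`, `combined_esr_score`, `negated_esr_score` |
| context | `gerp_rs`, `dist_nearest_ss` |

The post-substitution site score is computed only when the variant lies
inside the corresponding window; otherwise the delta is zero. The cryptic
scan is *gated on a core change*: only the two dinucleotide frames
overlapping the variant are examined, and a GT (donor) or AG (acceptor)
present in exactly one allele triggers scoring of the implied full window
on that allele; the maximum per class is kept. The regulatory scan
compares `2k-1`-nucleotide windows centred on the variant between alleles,
counting set k-mers present at an offset in one allele but not the other;
it applies to exonic variants only.

The two interaction features deserve comment because their exact original
compositions are not fully specified anywhere public: the framework's
stated logic weights a new splice site by the strength of the existing one
(a strong existing site nullifies a cryptic gain, a weak one is highly
affected).
They are implemented here as max-of-damage compositions —

```
splice_site_overall  = max over classes of max(0, cryptic - existing_same_class)
variant_splice_score = max(splice_site_overall, -acc_delta, -don_delta,
                           cryptic5_lost, cryptic3_lost)
```

— and are deliberately isolated behind the feature registry
(`feature_registry()`) so alternative compositions can be swapped in.
They should be read as TraP-like, not bit-compatible with precomputed
TraP score resources. A CpG gain/loss classifier is computed and exported
(`cpg_feature()`) but excluded from the default registry, as it does not
enter the final model.

Missing conservation is imputed as 0 with a `gerp_missing` flag rather
than dropping the variant: scoring positions without conservation support
is a core behavior, not an error state.

## The forest

`trap_train()` fits 1,000 trees with `floor(sqrt(N))` candidate features
per split (4 for the 20-feature registry), unweighted classes by default
(a `classwt` argument enables balancing for synthetic experiments). The
score is the exact fraction of trees voting pathogenic, so `score * 1000`
is always an integer vote count. Out-of-bag error is the model's internal
accuracy estimate; importances are mean decrease in Gini.
`trap_cv()` implements repeated 10-fold cross-validation: per repeat the
rows are shuffled, each fold's held-out tenth is scored by a forest trained
on the rest, and one AUC is computed from the pooled held-out scores; the
headline number is the mean over repeats. Folds are deliberately
unstratified (a shuffle leaving a single-class training fold is redrawn),
and AUC is pooled per repeat rather than averaged per fold — with 10% folds
of a ~500-row set, per-fold AUCs would be too noisy to average meaningfully.
Tier thresholds default to 0.459/0.93; `trap_train_gerpless()` drops
`gerp_rs` (19 features) and defaults to 0.66/0.955.

All randomness is pinned by a `seed` argument; identical seeds reproduce
models, folds and scores exactly.

## Evaluation statistics

* `roc_auc()` sweeps every distinct score (ties grouped) and integrates by
  trapezoid, which makes the AUC identical to the Mann–Whitney U statistic
  normalized by `n1 * n0`; this identity is asserted in the tests, and the
  sweep is cross-checked against pROC.
* `mann_whitney()` uses exact enumeration for groups of at most 8 without
  ties, otherwise the tie-corrected normal approximation.
* `binned_maf_correlation()` reads "5% score intervals" as equal-count
  quantile bins rather than equal-width score bins: scores of this kind
  are strongly right-skewed, and equal-width bins would be nearly empty
  over most of the upper range. Pearson correlation with its parametric
  p-value is computed over the 20 bin means. Duplicate quantile breaks
  (massive ties) merge bins, with a message.
* `qq_compare()` sorts the smaller set and linearly interpolates the order
  statistics of the larger set at matching plotting positions; comparing a
  set to itself returns the identity exactly.
* `fisher_enrichment(k, n, K, N)` tests over-representation one-sided via
  the 2x2 table `(k, n-k | K, N-K)`: the background column is the full
  reference gene set, against which a seven-gene list is negligible.

## The synthetic benchmark and what it does (not) show

The generator exists so that every module is testable end to end with no
downloads. Its defaults are the package's study conditions:

* 30 genes, 4 exons each, exon lengths 90–150 nt, introns 60–120 nt,
  strand drawn uniformly, 5% GC-core donors;
* donor strength levels 95/85/72 and acceptor levels 90/75/60 normalized
  units, hit to within ±5 after rebuilding the PSSMs from the emitted
  annotation. The donor levels sit higher than the acceptor levels
  because the invariant GT core occupies two of nine positions with
  near-full range under the analytic normalization, which bounds the
  feasible *population mean* donor score from below (~80); acceptor
  windows spread the core over 23 positions and admit lower levels.
* 500 variants per bundle: 15% donor-disrupting (site score drop >= 5
  units), 15% acceptor-disrupting (drop >= 3 units — a single base carries
  only a few normalized units of a 23-position motif), 15% creating a
  strong cryptic donor (normalized score >= 84), 15% gaining or losing a
  regulatory hexamer, 40% neutral. Every candidate is verified through
  the real feature machinery so each class activates exactly its
  designated feature block; the label is pathogenic iff the class is
  non-neutral.
* conservation: baseline Normal(0, 1) plus a +3 mean shift at splice
  windows, with 20% of sites left unelevated so that some truly
  functional positions look unconserved.

Site strengths are realized by a fixed-design assignment rather than
per-site search: the per-position base-count matrix of each site class is
chosen first (its consensus weight calibrated so the implied population
mean matches the mean target — the total score across sites is an
invariant of the matrix), and bases are then distributed to sites by
count-preserving swaps, hill-climbing on squared target gaps with
single- and double-position exchanges. Because swaps never change the
counts, the PSSM rebuilt from the finished annotation equals the design
matrix and every site scores its designed strength. For very small
genomes (fewer than about five genes) the discrete token spectrum can
make some target combinations unreachable; the generator then raises the
documented infeasibility error rather than emitting off-target sites.

Noise enters only through the conservation track; sequence effects are
exact, and effect magnitudes come in discrete levels so monotonicity of
the score in damage size is testable. The motif sets shipped by the
generator are deliberately synthetic stand-ins (G-free hexamers, disjoint
across sets, written as `motifs_synthetic_*.txt`): real SR-protein binding
catalogs are user-supplied files. Consequently, a high cross-validated AUC
on these bundles demonstrates that the pipeline recovers engineered,
orthogonal, noise-free signal — it says nothing about performance on real
genomes, where features correlate, effect sizes blur, annotations are
incomplete, and labels are uncertain. The recommended thresholds (0.459,
0.93) are carried as defaults for interface fidelity; models trained on
synthetic bundles have their own score scale, and the tier labels for such
models are only meaningful relative to it.

## Degenerate inputs and tie-breaks

* Variants outside every gene span yield an empty context list, not an
  error; they simply receive no score.
* First exons have no acceptor, last exons no donor: the corresponding
  scores are 0-imputed and distances are `NA`; `dist_nearest_ss` uses the
  junctions that exist.
* Multi-allelic VCF rows are split; non-SNV alleles are skipped with a
  warning. REF alleles are checked against the genome when it is given.
* A PSSM with `Max == Min` (degenerate frequency matrix) refuses to
  normalize.
* Duplicate conservation positions: last record wins, with a warning.

## Problem sizes

The test-suite and acceptance script run on the study-condition bundle
(30 genes, 500 variants), with repeated cross-validation at 3 repeats of
10 folds, and exhaustive oracles on a 100-nt three-exon toy gene (all 300
SNVs, both strands) and on all 4^K motifs for toy matrices up to K = 6.
These sizes were chosen as the smallest at which the engineered classes
are all populated and the statistical checks are stable.

## Known limitations

* No branch-point or polypyrimidine-specific features beyond the 23-nt
  acceptor window; no RNA secondary structure; no indel support.
* The interaction features approximate the framework's stated logic, as
  described above.
* The per-variant summary over transcripts is the maximum score —
  the conservative, worst-case clinical convention; no other aggregation
  is offered.
* Scores from models trained on synthetic bundles are not comparable to
  precomputed TraP score resources.
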