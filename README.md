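# trapscore

Synonymous and intronic single-nucleotide variants are routinely discarded
in genome interpretation because they leave the protein sequence intact and
often sit at weakly conserved positions. Yet such variants can destroy a
transcript: they can weaken an exon's splice sites, create competing
cryptic splice sites, or gain and lose binding sites for splicing
regulatory proteins. `trapscore` implements a transcript-inferred
pathogenicity (TraP) scoring framework for exactly this class of variant,
for use by statistical geneticists and method developers who want the full
pipeline — feature extraction, model, evaluation statistics, and a
synthetic benchmark generator — under one roof and runnable without any
external data downloads.

## The model

**Splice-site PSSMs.** Donor (5'ss) and acceptor (3'ss) position-specific
scoring matrices are built from every annotated intron whose boundary
dinucleotides are G[T/C]..AG. The donor motif is the last 3 exonic plus
first 6 intronic nucleotides (K = 9); the acceptor motif is the last 20
intronic plus first 3 exonic nucleotides (K = 23). A motif
A = A_1...A_K is scored

    score = sum_{i=1..K} log2 f(i, A_i)

where `f(i, b)` is the pseudocounted base frequency at motif position `i`,
and normalized to 0–100 by

    score' = 100 * (score - Min) / (Max - Min)

with `Min`/`Max` the analytic extremes over all possible K-mers.

**Features.** For each variant, in each transcript that harbors it, 20
features are computed: acceptor/donor strength before and after the
substitution and their deltas; best normalized score of any
newly created or destroyed cryptic GT/AG core (the implied full window is
scored on the alternate or reference sequence); two interaction summaries
(`splice_site_overall` weighs a cryptic gain against the strength of the
existing site of the same class, `variant_splice_score` is the single
worst-damage summary); counts of enhancer and silencer k-mers gained and
lost around the variant; a conservation score (rejected-substitutions
style) at the position; and distance to the nearest splice site.

**Forest.** A 1,000-tree random forest with floor(sqrt(N)) features per
split is trained on labeled variants. The TraP score of a variant is the
fraction of trees voting "pathogenic" — a score of 0.45 means exactly 450
trees voted pathogenic. Recommended tiers: `< 0.459` benign,
`[0.459, 0.93)` possibly damaging, `>= 0.93` probably damaging (a
conservation-free model variant uses 0.66/0.955).

**Evaluation toolkit.** ROC/AUC with grouped ties (the AUC equals the
normalized Mann–Whitney U), sensitivity/specificity at a threshold,
Mann–Whitney comparisons, 20-bin score-vs-allele-frequency correlation,
non-parametric quantile–quantile comparison with interpolation of the
larger set, and one-sided gene-list enrichment (Fisher's exact test).

**Synthetic benchmark.** `sim_config()` / `end_to_end_fixture()` generate
mini-genomes (multi-exon genes with GT/GC..AG introns tuned to target
splice-site strengths), engineered variant classes (donor/acceptor
disruption, strong cryptic creation, regulatory motif hits, neutral), a
conservation track elevated at functional sites, and toy motif sets —
everything the pipeline needs, deterministic per seed.

## Worked example

```r
library(trapscore)

cfg <- sim_config(n_genes = 6L, n_variants = 60L, seed = 3L)
fx  <- end_to_end_fixture(cfg, dir = "demo")        # FASTA/GTF/VCF/tracks

cons  <- load_conservation(fx$paths[["conservation"]])
feats <- featurize_variants(fx$variants, fx$transcripts, fx$genome,
                            fx$pssms, fx$motif_sets, cons)
model <- trap_train(feats, fx$truth$pathogenic, seed = 7)
model
#> TraP model: 1000 trees, mtry=4, 20 features, OOB error 0.0167

sc <- trap_score(model, feats)
head(cbind(feats[, c("contig", "pos", "ref", "alt")],
           class = fx$truth$class, trap = sc$trap, tier = sc$tier))
#>  contig pos ref alt            class  trap              tier
#>  gene04 368   A   G    donor_disrupt 0.990 probably_damaging
#>  gene06 553   A   T acceptor_disrupt 0.990 probably_damaging
#>  gene02 383   A   C    donor_disrupt 0.989 probably_damaging
#>  ...
#>  gene01  79   C   G          neutral 0.046            benign

trap_cv(feats, fx$truth$pathogenic, folds = 10, repeats = 3, seed = 7)$mean_auc
#> [1] 0.998
head(feature_importance(model), 3)
#>               feature     gini
#>  variant_splice_score 6.956000
#>       dist_nearest_ss 3.950955
#>     negated_esr_score 2.657814
```

The out-of-bag error is the forest's internal cross-validation estimate;
the engineered damaging variants score near 1 and neutral variants near 0,
and the worst-damage splice summary dominates the Gini importances.

A command-line wrapper over the same functions ships in
`inst/cli/trap.R`:

```sh
Rscript inst/cli/trap.R simulate --outdir demo --seed 3 --n-genes 6 --n-variants 60
Rscript inst/cli/trap.R build-pssm --gtf demo/annotation.gtf --fasta demo/genome.fa --out demo/pssms.tsv
Rscript inst/cli/trap.R score --vcf demo/variants.vcf --gtf demo/annotation.gtf \
    --fasta demo/genome.fa --model demo/model.rds --out demo/scores.tsv
```

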