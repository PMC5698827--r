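# MetaGeneDSN

Gene prediction in short metagenomic DNA fragments with a deep stacking
network.

## The problem

Shotgun metagenomic sequencing yields millions of short reads (hundreds of
bp) from thousands of uncultured species. Assembly is often impossible, so
genes must be called directly on the fragments — where most genes are
truncated at one or both fragment ends and the source genome (hence its
codon usage) is unknown. The task reduces to a binary decision: is a given
candidate open reading frame (ORF) in a fragment coding or noncoding?

## The method

MetaGeneDSN implements the Meta-MFDL approach: multi-feature fusion plus a
deep stacking network (DSN).

**Candidate ORFs.** All six reading frames of each fragment are scanned.
Besides complete ORFs (start codon through stop codon), fragment-truncated
candidates missing the upstream end, the downstream end, or both are
enumerated; candidates shorter than 60 bp are discarded.

**Features.** Each candidate is encoded as a fused 119-dimensional vector

```
X = [ X_ORFC | X_MC | X_MA | X_ZCPS | X_ZCPD ]
```

* `X_ORFC` (1): ORF length coverage *l/L*, the ORF length relative to its
  fragment;
* `X_MC` (64): monocodon usage — codon frequencies, stop codons included;
* `X_MA` (21): monoamino acid usage — 20 amino acids + STOP via the
  standard genetic code;
* `X_ZCPS` (9): Z-curve transform of codon-position-specific nucleotide
  frequencies, `x_i = (a_i+g_i) − (c_i+t_i)`, `y_i = (a_i+c_i) − (g_i+t_i)`,
  `z_i = (a_i+t_i) − (g_i+c_i)` for codon positions `i = 1,2,3`;
* `X_ZCPD` (24): the same three axes applied to phase-specific dinucleotide
  frequencies `p_12(MN)`, `p_23(MN)`.

**Classifier.** A DSN stacks simple modules (linear input, sigmoid hidden
layer, linear output). For module input `X` and one-hot targets `T`, the
hidden output is `H = σ(WᵀX)` and the upper weights have the closed-form
least-squares solution `U = (HHᵀ)⁻¹HTᵀ`; the squared error `E = ‖UᵀH − T‖²`
can be further reduced by batch gradient descent on `W` with `U` eliminated
through its closed form. The bottom module's `W` is pretrained as a
Bernoulli restricted Boltzmann machine by contrastive divergence; each
later module takes the raw features concatenated with all previous module
outputs as its input. Evaluation uses TPR (sensitivity), PPV (precision),
ACC and F1 (harmonic mean of PPV and TPR), with coding as the positive
class.

Because the original benchmark corpus (133 RefSeq genomes) is not bundled,
the package ships a synthetic genome simulator that plants codon-biased
genes in neutral intergenic sequence with exact annotations, so the whole
pipeline — fragmentation, ORF extraction, labeling, feature fusion,
training, cross-validation — runs self-contained.

## Worked example

```r
library(MetaGeneDSN)

spec <- syntheticGenomeSpec(genomeLen = 200000, seed = 42)   # 200 kb genome
se   <- makeLabeledDataset(spec, fragLen = 700, coverage = 1, seed = 43)
table(SummarizedExperiment::colData(se)$label)
#>    coding noncoding
#>       209      2226

idx <- sampleBalanced(SummarizedExperiment::colData(se)$label, 150, seed = 44)
x   <- SummarizedExperiment::assay(se)[, idx]
y   <- SummarizedExperiment::colData(se)$label[idx]

fit <- trainDsn(x, y, dsnTrainConfig(seed = 45))
fit
#> DsnModel (deep stacking network)
#>   modules:      3
#>   hidden units: 128
#>   raw features: 119
#>   classes:      coding, noncoding
#>   training squared error by module: 0.339646 -> 0.0808739 -> 0.0245816

cv <- kfoldCv(x, y, k = 10, config = dsnTrainConfig(seed = 45), seed = 46)
cv$summary
#>   metric  mean     sd
#> 1    TPR 0.987 0.0281
#> 2    PPV 0.901 0.0581
#> 3    ACC 0.937 0.0367
#> 4     F1 0.941 0.0319
```

The per-module error trace shows each stacked module tightening the fit on
the training data; the 10-fold cross-validation summary reports mean ± sd
of sensitivity, precision, accuracy and F1 over held-out folds. On this
small balanced sample (300 candidates) the planted codon bias is recovered
at ~94% accuracy; larger samples reach >99% (see the methods vignette).

A command-line wrapper with `simulate`, `train`, `predict`, `evaluate` and
`cv` subcommands is installed at

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts", "metagene-dsn.R",
                                       package = "MetaGeneDSN"))')" --help
```

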