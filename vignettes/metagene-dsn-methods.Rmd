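---
title: "Methods: ORF features and the deep stacking network"
author: "MetaGeneDSN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ORF features and the deep stacking network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes and why the
open design choices were made the way they were. Nothing here states an
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. The prediction problem

A metagenomic fragment of length $L$ (typically 700 bp for Sanger-like or
120 bp for short-read-like data) is scanned in all six reading frames for
candidate open reading frames. A candidate is *complete* when it has both a
start and a stop codon; fragment truncation also produces candidates
missing the upstream end (first in-frame codon through the first stop),
the downstream end (a start codon through the frame's last whole codon),
or both ends (the frame holds neither a stop nor a start, so the whole
frame is the candidate). Candidates shorter than 60 bp carry too little
compositional information and are discarded. The classifier's task is to
decide, from sequence-intrinsic features only, whether a candidate is
coding or noncoding.

Per stop-to-stop segment at most one candidate is emitted, anchored at the
segment's first start codon; nested shorter ORFs sharing the same stop are
deliberately not enumerated (they would be near-duplicates of their parent
and explode the candidate count without adding label information). The
start codon set defaults to the prokaryotic `ATG/GTG/TTG` and is a
parameter of `extractOrfs()`.

## 2. The fused descriptor

Every candidate becomes a 119-dimensional vector in fixed component order
`[ORFC | MCU(64) | MAU(21) | ZCPS(9) | ZCPD(24)]`:

* **ORF coverage** $l/L$. Coding ORFs are systematically longer than
  spurious ORFs, because evolved codon usage avoids in-frame stops.
* **Monocodon usage**: frequencies of the 64 codons (stops included) among
  the candidate's codons, in lexicographic DNA order `AAA..TTT`.
* **Monoamino acid usage**: the 20 amino acids (alphabetical one-letter
  order) plus STOP, translated with the standard genetic code, relative to
  the same codon total. This is a fixed linear image of the monocodon
  block — the aggregation is asserted as a test invariant.
* **Z-curve descriptors**: the purine−pyrimidine, amino−keto and
  weak−strong contrasts applied per codon position (9 values) and to
  intra-codon dinucleotide frequencies at phases 1–2 and 2–3 (24 values).
  Every entry lies in $[-1, 1]$.

Denominator conventions the source description leaves open, fixed here
once: the codon total $N$ *includes* the stop codon (consistent with a
64-codon usage vector that lists the three stop codons); dinucleotide
frequencies are normalized per phase by the same countable-codon total.
Codons containing `N` remain in the candidate's span but are excluded from
every tally ("countable" codons); a candidate with more than 10% ambiguous
codons is dropped. For truncated candidates the codon phase is defined by
the candidate's own codon list (anchored at its stop codon when the
upstream end is missing), not by fragment position — the descriptors are
properties *of the ORF*, complete or not.

Frequencies use the DNA alphabet; RNA-style codon names map `U → T`.

## 3. The deep stacking network

Each module is a single-hidden-layer perceptron: input $X$ ($D_m \times
N$, bias row included), hidden output $H = \sigma(W^\top X)$, linear output
$Y = U^\top H$, squared error $E = \lVert Y - T\rVert^2$ against one-hot
targets. For fixed $W$ the optimal upper weights are the ridge-stabilized
closed form

$$U = (HH^\top + \varepsilon I)^{-1} H T^\top, \qquad \varepsilon = 10^{-8}.$$

Module $m$'s input concatenates the standardized raw features with the
outputs of modules $1..m-1$ plus a constant bias row, so its input
dimension is $D + (m-1)C + 1$.

**Fine tuning.** The printed update rule in the source description of this
method family is typographically garbled (and, taken literally, *ascends*
the objective), so the package defines the unambiguous mathematical object
behind it: gradient descent on $E(W)$ with $U$ eliminated through its
closed form. Because $U^*(W)$ is the minimizer, the envelope theorem
reduces the total derivative to the partial derivative through $H$:

$$\frac{\partial E}{\partial W}
  = X\left[\left(2\,U(U^\top H - T)\right) \circ H \circ (1-H)\right]^\top.$$

This gradient is verified against central finite differences (relative
error below $10^{-5}$) in the test suite. Steps that would increase $E$
are halved until they descend, so the error trace is non-increasing by
construction; $U$ is refit after every accepted step.

**Initialization.** The bottom module's $W$ is pretrained as a
Bernoulli–Bernoulli restricted Boltzmann machine (CD-1) on inputs min-max
scaled to $[0,1]$, with the learned hidden bias folded into the bias row.
Upper modules are *warm-started from their predecessor*: the shared input
rows copy the previous module's trained $W$, and the rows receiving the
newly stacked output get small seeded Gaussian values ($\sigma = 0.01$).
A module therefore begins essentially at its predecessor's error and fine
tuning can only improve it — which makes the empirically asserted
monotone-stacking property (module $m$'s training error no worse than
module $m-1$'s within 1%) robust. Pure random initialization of upper
modules was tried first and broke that property reliably at small hidden
sizes, which is why the warm start is the package's design choice.

**Scaling.** Raw features are z-standardized for the network and min-max
scaled to $[0,1]$ for the RBM; both scalers are fitted on the training
data and stored in the model, so prediction applies exactly the training
transformation. Biases are handled by the appended constant row.

### Tunable parameters (defaults)

| parameter | default | rationale |
|---|---|---|
| modules | 3 | deep enough to show stacking gains, cheap to train |
| hidden units $L$ | 128 | comfortable for $D{=}119$ with $N$ in the thousands |
| RBM | CD-1, 10 epochs, lr 0.1, batch 100 | standard contrastive-divergence practice |
| fine tuning | 20 epochs, $\eta = 10^{-3}$, step halving | descent guaranteed by halving |
| ridge $\varepsilon$ | $10^{-8}$ | numerical solvability without noticeable bias |

The original method report does not state its module count, hidden size or
learning rate; these defaults are the package's own and live in
`dsnTrainConfig()`. All randomness (RBM, warm starts, sampling, folds)
derives from explicit integer seeds; identical configuration and seed
reproduce bit-identical model files (models serialize to JSON with 17
significant digits, which round-trips IEEE doubles exactly).

## 4. Labeling and evaluation protocol

With an annotated genome, a candidate is labeled *coding* when, mapped to
genome coordinates, it overlaps an annotated gene on the same strand, in
the same reading frame, over at least 80% of its length (the threshold is
a parameter; the convention follows neural-network gene callers of this
family). Otherwise it is *noncoding*.

Coordinates follow the Bioconductor convention throughout (1-based
inclusive, `GRanges` for annotations, GFF3 on disk via `rtracklayer`).

Metrics are TPR, PPV, ACC and F1 with coding as the positive class;
ratios with zero denominators are reported as `NA` with a flag, never as
silent zeros. Cross-validation is stratified (balanced training sets are
the protocol of this method family), with the sample standard deviation
($n-1$) over folds reported alongside the mean. Repeated-run summary
tables are aggregated column-wise — including the deviation columns, which
is how the published overall rows of such tables are formed. Published F1
columns are per-fold averages, so they can differ in the third decimal
from the F1 of the averaged TPR/PPV; the package reports per-fold means
and the tests assert agreement within that ambiguity.

**Independence of folds.** Fragments drawn at random from a genome
overlap, so the same genomic ORF is re-observed in several fragments,
truncated differently at the fragment ends. Left in place, such
near-duplicates straddle cross-validation folds and a high-capacity model
partially memorizes them: on null data (no compositional signal at all)
the apparent held-out accuracy reached 0.77 at 3-fold coverage purely from
this leakage. `deduplicateOrfs()` therefore keeps one candidate per
genomic ORF locus — anchored at the 3' in-frame stop when present, else
the 5' start, else the exact span, retaining the longest observation — and
is on by default in `makeLabeledDataset()`. With deduplication the null
condition sits at chance level, as it must.

## 5. The synthetic genome generator

`generateGenome()` emulates a prokaryotic chromosome for pipeline testing:
non-overlapping genes on both strands (forced `ATG` start, body codons
drawn i.i.d. from a codon-bias distribution, terminal stop), separated by
i.i.d. intergenic nucleotides, with exact `GRanges` annotations. Defaults:
gene density 0.6, mean gene length 600 bp (gamma-distributed, rounded to
whole codons, minimum 90 bp), and a strong clean codon bias concentrating
80% of probability on 8 randomly chosen sense codons.

The codon-bias vector is defined over all 64 codons. The default puts zero
mass on stops, producing stop-free gene bodies as in real coding sequence. Allowing stop
mass is deliberate: with the uniform distribution (1/64 each,
`uniformCodonBias()`) gene bodies are statistically identical to uniform
intergenic sequence, so labels carry no sequence signal — the null
condition for calibrating the pipeline. A uniform bias over *sense* codons
only would not be null: stop-free gene bodies produce long ORFs, and ORF
length alone classifies real genomes at ~90% accuracy in this method
family's own ablations.

What the generator does **not** emulate: sequencing errors (fragmentation
is error-free by design), GC gradients, overlapping genes, operon
structure, or realistic gene-length and intergenic-length distributions
beyond their first moments. Passing the end-to-end tests therefore shows
the pipeline and classifier work when the planted signal is present and
find nothing when it is absent — not that real-genome accuracies are
reproduced, which would require the original multi-genome corpus.

Fragmentation samples start positions uniformly with replacement and
assigns each fragment a random strand; the fragment count is
$\lfloor \text{coverage} \times \text{genomeLen} / \text{fragLen} \rfloor$,
so coverage is an expectation, matching a "random split" at 1-fold within
rounding.

## 6. Problem sizes used by the tests and acceptance script

The end-to-end experiments run at sizes chosen to give stable estimates on
a single CPU in minutes: the signal condition uses a 2 Mb genome, 700 bp
fragments at 1-fold coverage (the training-set condition of this method
family), 2000 deduplicated candidates per class, 10-fold stratified CV
with the default configuration; the null condition a 1.3 Mb uniform
genome and 1500 per class. Feature-correctness properties run on 1000
random ORFs; the ORF scanner is checked against an exhaustive
position-by-position oracle on 1000 (tests) / 500 (acceptance script)
random 200 bp fragments.

## 7. Known limitations

* Translation-initiation-site rescoring is out of scope; the first
  in-segment start codon defines the candidate, which can overshoot the
  true start upstream.
* The labeling rule needs fragment provenance; candidates from plain FASTA
  input can be scored but not labeled.
* The DSN is batch-trained; datasets far beyond $10^5$ candidates would
  need minibatching that the method's per-module closed form does not
  naturally provide.
* The two-class architecture generalizes to $C > 2$ in the algebra, but
  only the coding/noncoding case is exercised and supported.
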