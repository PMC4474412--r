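---
title: "Motif discovery from k-mer over-representation and signal shape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif discovery from k-mer over-representation and signal shape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifshape)
```

## The problem

Transcription factors (TFs) bind short, degenerate DNA patterns (motifs).
Given a set of ChIP-seq peak regions, word-count motif finders enumerate
all k-mers, keep those occurring more often than a background model
predicts, and assemble the survivors into position frequency matrices
(PFMs). Their classic failure mode is spurious over-representation:
tandem repeats and low-complexity words can be as enriched as real
binding words, and nothing in the sequence alone distinguishes them.

`motifshape` augments the word-count approach with *shape features* of
genome-wide signal tracks - DNase I hypersensitivity and histone
modification marks - aggregated around the occurrences of each candidate
word. Around genuine binding sites these signals form sharp, symmetric
peaks; around spurious repeat words they tend to be flat, noisy or
asymmetric. Scoring that difference demotes the impostors.

## The model

### Over-representation

For word length $K$ (default 9, suited to 100-200 bp ChIP-seq peaks), all
occurrences of every k-mer are indexed exactly, on both strands by
default: the reading of the minus strand at a position is recorded under
its own (reverse-complement) key, so a word and its reverse complement
are separate keys whose counts each pool both strands. Windows containing
`N` or masked lowercase bases are skipped.

The background is a Markov chain of order 0 or 1 (default 1; in practice
the two orders behave almost identically) fitted to the target regions
with add-one smoothing. Five background sequence sets with exactly the
input's region-length multiset are simulated, and each word's expected
count $\lambda$ is its average simulated count (floored at 0.5 when a
word never appears, so the odds ratio stays finite). Counts are treated
as Poisson:

$$P(WC \ge wc) = 1 - \Phi\!\left(\frac{wc - \lambda}{\sqrt{\lambda}}\right),$$

the Gaussian approximation being used only for $\lambda > 50$, where its
worst-case disagreement with the exact Poisson tail is below 0.02; for
smaller means the exact tail is used directly. (The approximation is
*valid* from $\lambda \approx 10$, but between 10 and 50 its worst-case
error reaches 0.04, and the exact tail costs nothing.) No
multiple-testing correction is applied - null distributions vary from
word to word - and self-overlap of words is deliberately left
uncorrected; instead a small p-value threshold (default $10^{-6}$)
selects candidates. Note that the uncorrected self-overlap inflates the
odds ratio of tandem-repeat words, which is precisely the failure mode
the shape features target.

### Mark distributions and shape scores

For each candidate word and each track, per-bp signal in windows of
$\pm$ 1000 bp (the scale at which flanking histone-mark structure is
visible) around every occurrence midpoint is collected - minus-strand
windows reversed so profiles align in motif orientation - and summed
into 25 bp bins: the word's *mark distribution* $\varphi(X)$, here $B =
80$ bins. The profile is normalized to unit mass and smoothed by
discrete Fourier transform, removing the top $5/8$ of the frequency
components (conjugate pairs together, DC always kept), flooring negative
ringing at zero and renormalizing: $f(X)$.

Three shape scores summarize $f$:

* **Intensity** $S_I = \frac{1}{wc}\sum\varphi(X)$ - mean total window
  signal per occurrence.
* **Kurtosis** $S_K = \frac{E(f(X)-EX)^4}{(E(f(X)-EX)^2)^2} - 3$,
  treating $f$ as a probability mass over bin positions. Sharp peaks
  score high; a flat profile scores $\approx -1.2$; all mass in one bin
  is capped at 50.
* **Asymmetry** $S_A = \tfrac12 D_{KL}(f_{lhs}\|f_{rhs}) + \tfrac12
  D_{KL}(f_{rhs}\|f_{lhs})$, where the right half is mirrored before
  comparison, so $S_A$ measures deviation from mirror symmetry about the
  motif centre. Both halves get a pseudo-mass of $10^{-6}$ per bin. A
  symmetric peak scores 0; translation-periodic (repeat-like) and
  irregular profiles score high.

The mirroring convention is a deliberate choice: it makes $S_A$ vanish
exactly for any profile symmetric about the occurrence centre, which is
the property that distinguishes centred binding footprints from
repeat-like periodic signal.

### The combined score

$$S = z(S_W) + \beta_I\, z(S_I) + \beta_K\, z(S_K) - \beta_A\, z(S_A),
\qquad S_W = wc/\lambda .$$

The four scores live on incommensurable scales (a ratio, track units,
a unitless kurtosis, nats), and across a candidate set of at most a few
dozen words their distributions are small-sample and heavy-tailed - the
odds ratio especially, because $\lambda$ is estimated from five
simulations and repeat words clump. $z(\cdot)$ is therefore the *normal
scores* (van der Waerden, rank-based) transform across the candidate
set, applied per track and averaged across tracks for the signal
features. It is monotone, so with all $\beta = 0$ the ranking is exactly
the odds-ratio ranking; and it is robust, so shipped default weights
($\beta_I = 0.3$, $\beta_K = 0.5$, $\beta_A = 0.5$) are portable across
datasets. Plain mean/sd z-scores were rejected because outlier repeat
families dominate the pooled standard deviation and mute the shape
features at any fixed weights. Asymmetry is negated in the combination
(high asymmetry is evidence against a word), so all weights are
non-negative; the supported way to fit them to a dataset is the
validation-AUROC grid search in `grid_search_betas()`.

### From seeds to motifs

Each top-ranked seed (default: 30) is *generalized* by enumerating all
$4K$ single-position substitutions and reading each variant's count off
the index - 32 lookups for $K=8$; multi-mismatch words are deliberately
not enumerated, which slightly biases weak columns and is accounted for
in the recovery analysis below. The resulting primary PFMs are clustered:
the distance between two motifs is one minus the best Pearson correlation
of their flattened, pseudocount-normalized (0.25 per cell) probability
sub-matrices over all relative offsets with at least
$\max(4, \lceil L/2\rceil)$ overlapping columns and both orientations;
pairs with no admissible overlap get a sentinel distance of 2 and are
never merged. In signal-augmented mode a symmetrized-KL term between
smoothed mark distributions, rescaled to $[0,1)$ as $KL/(1+KL)$, is
mixed in with weight `beta_cluster` (default 0.2).

Average-linkage hierarchical clustering is cut at the number of clusters
chosen by the gap statistic (20 reference datasets of uniformly sampled
row-stochastic $L\times4$ matrices, paired with uniform-noise profiles
when marks are in use; one-standard-error rule; the distance-2 sentinel
is enforced by splitting any cluster into alignable connected
components). Cluster members are star-aligned to the highest-scoring
member, counts summed over the union span, mark profiles
support-weighted-averaged, and the merged motif trimmed: end columns
with information content below 0.3 bits or support below 10% of the
maximum column support are stripped, never below four columns.

Output motifs are ranked by their best member's combined score, with
support breaking ties. Ranking by `support * score` was considered and
rejected: with rank-normalized scores near zero the product is
meaningless, and raw support would let shifted-word repeat families
(whose deterministic planting or genomic tandem structure spawns many
strong shifted variants) outrank shape-backed motifs regardless of the
signal evidence.

## Site scanning and evaluation

A straightforward log-odds scanner stands in for an external site
caller: windows on both strands score
$\sum_i \log_2 (p_{motif}/p_{bg})$ against the order-0 background, sites
above a per-motif fractional threshold (default 70% of the maximum
attainable score) are reported, and overlapping same-motif sites resolve
greedily to the best-scoring one. It makes no claim to reproduce any
particular external caller's site counts.

Site-level accuracy follows the summit-window protocol: each ChIP-seq
summit is flanked by 650 bp per side - 1300 bp, 13 bins of 100 bp - with
the central bin centred on the summit. TP is the number of summits whose
central bin contains a predicted-site midpoint (closer than 50 bp), FP
the number of flanking bins (12 per summit) containing one, FN and TN
the complements; sweeping the scanner threshold yields an ROC whose
trapezoidal area (with (0,0) and (1,1) anchors) is the AUROC. Note the
13-bin geometry requires the flank to be an odd multiple of half the
bin width. Cross-validation divides the regions into ten partitions:
eight train the finder, one selects the scanner threshold, one is held
out for the reported AUROC, with partitions rotating between folds and
the top 3 motifs scanned.

## The synthetic benchmark

All tests run on fully synthetic fixtures from `make_fixture()`:
background sequence from a configurable Markov chain (default uniform
order 0), one instance of a known PFM planted at the centre of a random
fraction of regions, per-track signal of controlled shape (Gaussian,
flat, flat-plus-noise, or asymmetric two-sided Gaussian) laid over each
planted instance, and summits written at jittered instance midpoints.
The benchmark operating point is 2000 regions of 200 bp with a 9-bp PFM
of 0.85 column dominance planted in 40% of regions, a DNase-like
Gaussian peak track ($\sigma$ = 75 bp, in the range of real DNase
footprint aggregates) and a flat-noise decoy track; regions are spaced
2 kb apart on a synthetic chromosome so signal windows never overlap.
These sizes keep a full discovery run in seconds while leaving planted
words two orders of magnitude above background expectation - comparable
to a well-enriched ChIP-seq dataset.

`make_spurious_word_fixture()` additionally plants a tandem-repeat decoy
(default `CTCTCTCTC`) in a disjoint set of regions. The decoy count is
matched to the *expected consensus-word count* of the PFM-sampled motif
($n \cdot d^{K}$ instances, since the decoy is planted deterministically),
and its signal - asymmetric by default - is scaled so its window
integral matches the motif track's: the two words then differ in signal
*shape* only, which is exactly the contrast the shape scores claim to
detect.

What the fixtures do *not* emulate: read-level noise, inter-mark
correlation, sequence composition bias, overlapping motif instances,
repeat families beyond single-word tandems, and real peak-length
variation. Passing these benchmarks therefore demonstrates the
machinery is correct and the shape features carry the intended signal,
not that the defaults are optimal for any particular organism or assay.

## Numerical and validation choices

* **Gaussian/Poisson cutoff.** Exact Poisson tail below $\lambda = 50$,
  Gaussian above; see the rationale under *Over-representation*.
* **PFM recovery validation.** The single-substitution readout estimates
  column $i$ only from instances that are consensus at the other $K-1$
  positions - an effective sample of $n\,d^{K-1}$. At the benchmark
  dominance $d = 0.85$ and $n = 500$ that is ~136 instances per column,
  whose sampling noise alone exceeds a 0.05 per-entry bound. The
  recovery check therefore plants a $d = 0.95$ PFM at rate 1 and counts
  on the planting strand, isolating the estimator property (absence of
  bias) from fixture noise floors.
* **Weight fitting for the decoy benchmark.** Validation AUROC is
  computed from the top motif only; with more motifs the objective goes
  blind to the ranking (the true motif is scanned regardless of rank).
  Many weight settings tie on a synthetic validation set; ties break
  toward the smallest L1 norm.
* **Determinism.** Every source of randomness - background simulation,
  fixture generation, gap-statistic references, partition assignment -
  derives from the single `seed` in `motif_config()` (order-1 chains are
  driven by pre-drawn uniforms, so the compiled sampler stays under R's
  RNG). Two runs with identical inputs and config are byte-identical.
* **Degenerate inputs.** All-zero mark distributions fall back to
  uniform with a warning; zero-variance profiles cap the kurtosis; words
  with no occurrences are flagged unscorable; a motif weak in every
  column is returned untrimmed with a warning.

## A worked run

```{r, eval = FALSE}
fx <- make_fixture(fixture_spec(seed = 1))
cfg <- motif_config(seed = 1)

disc <- discover_motifs(fx$regions, tracks = fx$tracks, config = cfg)
tidy(disc)       # one row per motif: consensus, support, score
glance(disc)     # run summary

ev <- evaluate_motifs(disc, fx$regions, fx$summits, cfg)
autoplot(ev)     # ROC curve
```

## Known limitations

* Seeds of a single $K$ per run; multi-K discovery means concatenating
  runs before clustering.
* The scanner is a plain log-odds caller without match p-value
  calibration; absolute site counts are not comparable across motif
  lengths.
* The gap statistic's reference (uniform row-stochastic matrices) is
  diffuse; on real, strongly structured candidate sets it tends toward
  conservative (small) cluster numbers, which the sentinel rule only
  partially offsets.
* Signal aggregation assumes tracks and regions share one coordinate
  system; no liftover, and no correction for copy-number or mappability
  artefacts in the tracks.
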