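---
title: "Methods: multi-label plasmid host range prediction with missing labels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-label plasmid host range prediction with missing labels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmidhostr)
```

## The problem

Plasmid reference databases record, for each sequence, the single bacterial
genus it was isolated from. Broad-host-range plasmids, however, replicate
and persist in several genera, so the recorded label sets are
systematically incomplete: every unobserved true host is a *missing
positive*. Training an ordinary multi-label classifier on such data teaches
it to suppress exactly the labels we want it to discover. `plasmidhostr`
attacks this from two sides: it *augments* the training labels with
high-precision pseudo hosts mined from protein content, and it *softens*
the loss on negative labels so the model can re-interpret confident
negatives as missing positives during training.

A secondary problem is evaluation: without curated multi-host annotations
there is no test set. Near-identical sequence pairs (by convention,
identity and coverage strictly above 99%) annotated with *different* genera
are treated as one plasmid observed in both; unioning labels over
transitively merged components yields a multi-host test set.

## Protein-cluster significance

Plasmid proteins are clustered (externally, e.g. CD-HIT at 0.9; the package
parses `.clstr` files) and tallied into a PC-by-genus count table
$|P_{i,j}|$. With PCs as words and genera as documents, classic TF-IDF is

$$\mathrm{TFIDF}_{i,j} = \frac{|P_{i,j}|}{|P_{\cdot j}|}\,
  \log\frac{|G|}{|G_i|},$$

where $|P_{\cdot j}|$ is the protein total of genus $j$, $|G|$ the number
of genera and $|G_i|$ the number of genera in which PC $i$ occurs. Two
defects motivate the augmented score: a PC present in every genus scores
exactly zero everywhere (the IDF vanishes), and a small genus-private PC is
dwarfed inside its genus by large shared backbone clusters. The augmented
score multiplies in the cluster's own cross-genus relative frequency and
smooths/shifts the IDF:

$$\mathrm{score}_{i,j} = \frac{|P_{i,j}|}{|P_{\cdot j}|}\,
  \frac{|P_{i,j}|}{|P_{i\cdot}|}
  \left(\log\frac{|G|+1}{|G_i|+1} + 1\right).$$

A ubiquitous PC now keeps a positive (if small) score where it occurs,
while a cluster concentrated in one genus gains a factor close to 1 from
the relative-frequency term and the largest possible IDF. Both scores are
non-negative and zero exactly where the count is zero (the augmented score;
TF-IDF is additionally zero for ubiquitous rows) — properties the test
suite asserts against brute-force evaluation.

Design choices worth recording:

* The normalizer $|P_j|$ of plain TF-IDF is read as the *occurrence total*
  $|P_{\cdot j}| = \sum_i |P_{i,j}|$, so both scores share one normalizer.
  The alternative reading (number of distinct PCs in genus $j$) changes
  every column by a constant factor and therefore does not change any
  pseudo-label decision, which depends only on cross-genus ratios after
  normalization; the occurrence reading was adopted for internal
  consistency.
* Natural logarithms throughout.
* Rows and columns are ordered lexicographically (C locale) so serialized
  matrices are bit-stable.
* All-zero rows/columns are dropped at table construction and never scored.

## Pseudo-label assignment

For a training plasmid $s$ with observed host $H_s$ and protein multiset
$P_s$ (one entry per encoded protein — multiplicity counts, because $|P_s|$
is defined as the number of encoded proteins):

$$\bar W_j = \frac{1}{|P_s|}\sum_{i \in P_s} \mathrm{score}_{i,j}, \qquad
  W'_j = \frac{\bar W_j}{\sum_{j \ne H_s} \bar W_j}.$$

A single non-host genus with $W'_j \ge 0.5$ becomes the pseudo label; the
plasmid keeps at most two labels. Degenerate cases are resolved toward
precision:

* all non-host weights zero → the normalization is undefined → no pseudo
  label (the plasmid simply lacks cross-genus evidence);
* an exact two-way tie at $W' = 0.5$ (the only way two genera can qualify)
  → no pseudo label, with a warning;
* proteins whose PC is absent from the score matrix contribute zero weight
  but still count in $|P_s|$, diluting the evidence conservatively.

The 0.5 default makes "at most one pseudo label" a theorem rather than a
policy; the threshold is exposed (`pseudo_threshold`) because stricter
values trade recall for precision monotonically (the suite asserts the
monotonicity). Significance scores are computed on the full training
corpus, including each query plasmid's own proteins; a leave-one-out
variant was considered and not adopted — with thousands of plasmids per
corpus a single plasmid's contribution to its own PC rows is negligible,
and the non-LOO form keeps the score matrix a single corpus-level artifact.
Pseudo-labelling is strictly a training-time augmentation; nothing in the
prediction path can reach it.

## Sequence features and encoders

Prediction uses nucleotide features only (protein annotations are not
assumed at inference time):

* **Dense (nn) encoder input:** the 4-mer frequency vector (256
  dimensions, lexicographic A<C<G<T order). Overlapping k-mers are counted
  left to right; words containing ambiguity codes are skipped; counts are
  normalized by the number of valid words. Reverse complements are *not*
  collapsed — strand composition is part of the signal — and plasmids are
  encoded as linear by default, with a `circular` flag that appends the
  first $k-1$ bases to count wrap-around words.
* **Convolutional (cnn) encoder input:** one-hot windows (4 channels,
  default length 2048, stride 2048, final window zero-padded; ambiguous
  bases become all-zero columns). Per-window embeddings are mean-pooled
  over positions and windows.
* `nn+cnn` concatenates the two embeddings.

The exact k, window geometry and layer widths are free design choices of
this package, fixed once and exposed in `train_config()`.

## The classifier and its loss

The classifier head emits one independent sigmoid probability per genus.
The loss building blocks are

$$L^+ = (1-p)^{\gamma_+}\log p, \qquad L^- = p^{\gamma_-}\log(1-p),$$

with $\gamma_+ < \gamma_-$ (defaults 1 and 4, the usual asymmetric-loss
convention): negatives vastly outnumber positives in multi-label host
prediction, so easy negatives must be down-weighted harder. After a
warm-up of `warmup_epochs` epochs — warm-up exists because the switch below
is only meaningful once the model has some discriminative ability — the
negative branch self-corrects:

$$L^-_{\mathrm{eff}}(p_i) = \mathbb{1}(p_i < \tau)\,L^-(p_i) +
  \mathbb{1}(p_i \ge \tau)\,L^+(p_i),$$

i.e. a negative label predicted above $\tau$ (default 0.9) is treated as a
missing positive and *pulled up* rather than pushed down. The indicator is
evaluated per element on the current probability as a hard switch with no
gradient of its own. With $\gamma_+ = \gamma_- = 0$ and $\tau$ off, the
loss is exactly mean binary cross-entropy (asserted to $10^{-9}$), which is
how the ablation benchmark is trained.

Numerical choices: probabilities are clamped to $[\varepsilon,
1-\varepsilon]$ with $\varepsilon = 10^{-8}$ before any logarithm;
gradients are the analytic derivatives of the clamped expressions
(validated against finite differences); the finite-difference direction
test in the suite confirms that a confident negative ($p \ge \tau$) is
pushed upward once self-correction is active.

The network itself is a lightweight native implementation (base R matrix
code, Adam optimizer, manual backpropagation). Defaults: hidden width 64,
batch size 64, learning rate $10^{-3}$, 60 epochs with warm-up 10.
Shorter schedules (e.g. 30 epochs) leave the model underfit at the
package's study scale — probabilities linger near initialization, which
inflates the number of genera above the 0.4 decision threshold. Parameter
initialization and batch order derive entirely from `config$seed`, so
training is bit-reproducible.

Prediction calls every genus with probability *strictly* above
`decision_threshold` (default 0.4). Empty call sets are allowed by
default; `min_one = TRUE` falls back to the argmax genus and flags the
fallback, for downstream users who need a call for every plasmid.

## Multi-host test-set construction and metrics

A BLAST-style hit qualifies when identity and the coverage of **both**
sequences (alignment length over each sequence's length) are strictly
above 99%. "Above" is read as strict inequality, and two-sided coverage is
the symmetric choice given that the convention does not specify a side.
Qualifying pairs with different genus labels form edges; connected
components are merged transitively (the only order-independent resolution
of chains) and every member receives the union of its component's labels.
Records with fewer than two encoded genes are then dropped. Construction
is order-independent under permutation of the hit table, and single-genus
components cannot arise (edges require differing labels) — both asserted
in the suite against a union-find oracle.

Metrics: per-genus recall $tp/(tp+fn)$ and precision $tp/(tp+fp)$, with
$0/0$ precision defined as 0; macro averages run unweighted over genera
with at least one true instance; F1 is the harmonic mean of the two
*macro* averages, $2RP/(R+P)$ — per-genus-averaged F1 is a different
statistic and does not reproduce the aggregation used by published
multi-label host-range benchmarks, which the acceptance suite pins on
printed (recall, precision, F1) triples. Top-k accuracy ranks genera by
probability with lexicographic tie-breaks for determinism.

## The synthetic corpus generator

The generator builds corpora in which every quantity the pipeline
estimates has a sealed ground truth:

* each genus gets `markers_per_genus` exclusive marker PCs and a private
  nucleotide composition (base probabilities proportional to
  $\exp(\text{kmer\_bias\_strength}\cdot z)$, $z \sim N(0,1)^4$ — strength 0
  means identical composition everywhere, ~1 a clearly learnable signal);
* `n_backbone_pcs` backbone PCs are shared by all genera;
* a `dual_host_fraction` of plasmids carries two true hosts, at least one
  marker PC from *each*, and gene segments sampled from a mixture of the
  two compositions; the observed label is drawn uniformly from the true
  hosts, so the second host is hidden from the training view;
* `mask_labels()` returns the visible single-label view plus a sealed key;
  `score_against_truth()` counts an assigned extra genus as correct iff it
  is a hidden true host.

Defaults — 20 genera, 100 plasmids per genus, 10% dual-host plasmids,
30 markers per genus, 120 backbone PCs, 6–24 genes of 200–800 bases,
marker-gene fraction 0.4, bias strength 1.0 — were chosen once as a
desk-scale analogue of a realistic corpus: marker fraction 0.4 reflects
that host-informative genes (transposases, relaxases, replication
machinery) are a large minority of plasmid genes; gene counts and lengths
bracket typical small plasmids; 10% dual-host matches the order of
magnitude of cross-genus pairs found in reference databases. At this scale
the suite asserts pseudo-label precision ≥ 0.90 against the sealed key,
and that hidden-host recall is non-decreasing across the ablation
benchmark → +pseudo → full model, with the full model strictly better than
the benchmark, across three seeds.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: real plasmid architecture (oriV, MOB typing,
operon structure), amino-acid-level clustering noise (PC assignments are
given directly rather than derived from simulated protein sequences),
shared k-mer composition between phylogenetically close genera,
contig-level fragmentation or sequencing error, and host-range skew beyond
two genera. The two-host cap mirrors the at-most-one-pseudo-label
contract; corpora with broader host ranges would need a different
assignment rule.

## Known limitations

* The classifier expects complete plasmid sequences; behaviour on contigs
  is untested by design.
* Self-correction trades precision for recall aggressively when the model
  is well fit to a small genus universe; on corpora with few genera the
  full model tends to over-call, and `tau` or the decision threshold
  should be raised accordingly.
* The significance scores are computed from observed labels, which the
  hidden hosts contaminate slightly (a dual-host plasmid deposits its
  second host's markers under its observed genus); at realistic dual-host
  fractions this dilution is small, but it grows with
  `dual_host_fraction`.
* Problem sizes in the test and acceptance runs (2000-plasmid corpora,
  60-epoch schedules, three seeds for the ablation) are the package's
  chosen desk-scale study conditions; corpus-scale benchmarks on public
  databases require external data and longer training.
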