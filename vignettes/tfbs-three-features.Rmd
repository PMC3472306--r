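---
title: "Three-feature characterization of TF binding sites: models and design notes"
author: "tfbstrio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-feature characterization of TF binding sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfbstrio)
```

## The problem

Transcription factors (TFs) regulate genes by binding short DNA segments
(TFBSs), mostly in promoters. A TFBS can be described from three largely
independent angles:

* **Sequence** — how well the segment matches the TF's position weight matrix
  (PWM);
* **Structure** — the conformational and physicochemical profile of the
  segment, read off dinucleotide property scales (twist, roll, stacking
  energy, duplex stability, ...);
* **Evolution** — whether the segment matches a catalog of conserved
  regulatory motifs, and how conserved that motif is.

`tfbstrio` implements per-segment scores for all three features, decision-tree
identification models built on them (singly and combined), and three analyses
of TF-to-TFBS *correspondence*: do similar TFs bind similar sites (sequence
level), do structurally classed TFs bind structurally clustered sites
(structure level), and are conserved TFs paired with conserved sites
(evolution level)?

Because the curated inputs behind such a study (a licensed TFBS database,
promoter collections, ortholog databases) cannot be redistributed, the package
ships a synthetic-world generator that plants each of the signals the
analyses look for, at desk scale. One published input *is* included: the
270-row table of per-TF conservation scores and mean TFBS evolution scores,
on which the evolution-level correlation is reproduced exactly.

## The three scores

**Sequence.** For a segment $b_1 \dots b_n$ and a PWM with per-position base
frequencies $f_{ij}$ and background probabilities $P_i$,

$$\mathrm{score} = \sum_{j=1}^{n} f_{b_j j}\, C_j, \qquad
  C_j = \sum_{i \in \{A,C,G,T\}} f_{ij} \log_2 \frac{f_{ij}}{P_i},$$

with the convention $0 \log 0 = 0$. Both strands are scored (the reverse
complement against the same PWM) and the larger value is kept. The score is
deliberately left unnormalized; no pseudocount is added to $f$ at scoring
time, so a zero-frequency base contributes zero. The background defaults to
uniform 0.25 and can be replaced by the mononucleotide frequencies of a
fitted background model. When a segment is longer than the PWM, every window
is scored and the best window is used — curated site lengths vary around the
matrix length.

**Structure.** For each of 38 dinucleotide attributes $x$,

$$\mathrm{score} = \frac{1}{n-1} \sum_{j=1}^{n-1} x(b_j b_{j+1}),$$

computed on the given orientation only (the defining formula makes no strand
statement). The bundled property table is a deterministic synthetic stand-in:
its attribute names follow the standard vocabulary and its values sit on
realistic scales, but they are not measured values — analyses of real data
should substitute a measured table via `read_property_table()`. Nothing in
the machinery depends on the particular values.

**Evolution.** A segment is compared with every catalog motif by ungapped
sliding of the shorter string along the longer, over both strands of the
segment, scoring the fraction of positions where the segment base is
compatible with the motif's IUPAC code. If the best fraction reaches the
catalog threshold (default 0.95) the motif "matches"; the segment's evolution
feature is the maximum conservation score over matching motifs, else 0. The
alignment rule and the both-strand scan are this package's choices: conserved
motifs are strandless, and an ungapped slide normalized by the shorter length
is the simplest similarity for which a 0.95 threshold is meaningful.

## Negative instances and balanced sets

Negatives are synthesized, not sampled from real promoters: a 3rd-order
Markov chain (add-one smoothing; unseen contexts fall back to uniform) is fit
to promoter sequences, 5 kb pseudo-sequences are generated from it, and each
is cut into consecutive non-overlapping windows of the TF's average site
length (nearest integer; the trailing remainder is discarded). Ten balanced
sets per TF are then assembled: all positives plus an equal-size random draw
from the pool, without replacement within a set and independently across
sets. The "hidden Markov model" label sometimes attached to this construction
is read here as a plain order-3 chain — with no hidden state the chain is
what "same nucleotide distribution" identifies.

## Models and evaluation

Five models are built per instance set:

* **control** — a threshold on the min–max-normalized PWM similarity
  (`(Current - Min)/(Max - Min)`), the operating rule of classical PWM
  matchers. The cutoff is chosen on the training folds by maximizing
  specificity subject to non-zero sensitivity, which reproduces the
  high-specificity / low-sensitivity signature such matchers show.
* **sequence / structure / evolution** — a decision tree on the single
  feature block.
* **hybrid** — a decision tree on all 40 columns (39 without a PWM), after
  correlation-based feature selection (CFS) *inside the training fold*.

Trees use the entropy split criterion with cost-complexity pruning at the
internal cross-validation 1-SE point (`rpart`); this is a behavioral rather
than bit-exact reading of classic C4.5-style induction — the original's exact
pruning settings are not recoverable, so determinism under a fixed seed plus
the separability/permutation-null properties are the contract. CFS maximizes
$k\,\bar r_{cf} / \sqrt{k + k(k-1)\bar r_{ff}}$ by best-first forward search
stopping after five non-improving expansions, and falls back to the single
best-correlated column rather than returning an empty set.

Evaluation is stratified 10-fold cross-validation. Confusion counts are
pooled over folds (micro-average) — with balanced sets of tens of instances,
per-fold metrics are too grainy to average stably — and the AUC is the
rank-based (Mann–Whitney, ties at one half) area over the pooled test-fold
scores. Sensitivity, specificity and accuracy follow their standard
definitions; a metric whose denominator is empty is `NA`, never silently 0.

## Correspondence analyses

**Sequence level.** TF proteins and TFBS segments are clustered by
single-linkage over pairwise local alignments (BLOSUM62 for protein, +1/−2
for DNA), linking two sequences when the alignment covers at least fraction
$L$ of *both* and has at least $S\%$ identity over aligned columns — the
documented semantics of blastclust's `-L`/`-S`, without promising identical
output to the NCBI binary. Each TFBS cluster is rewritten as its owning TF
names; a TF cluster is *matched* if some rewritten cluster contains over 90%
of it, or their intersection-over-union exceeds 2/3. The association between
TF co-clustering and TFBS co-clustering is tested one-sidedly by a Fisher
test over all unordered TF pairs (same TF cluster? × co-occurring in at
least one rewritten TFBS cluster?) — the contingency construction is this
package's choice, as the pairwise table is the only construction consistent
with "association between the two clusterings".

**Structure level.** The split frequency of each structure attribute across
all trained structure/hybrid trees is recorded; the 75th quantile of the
frequency vector is bootstrapped (10,000 replicates), and attributes with
frequency above the midpoint of the 2.5%/97.5% bootstrap interval are
selected ("midpoint of the interval" is one of two defensible readings of an
ambiguous rule; the midpoint is deterministic given the interval). Each TF is
encoded as the mean of the selected attributes over its positive sites,
standardized — the attributes live on heterogeneous physical scales. The
number of TFBS classes is chosen by Gaussian-mixture BIC over $k = 1..10$,
and K-means (k-means++-like seeding via 50 restarts) clusters the encodings
with that $k$. A TF class maps to a TFBS class when more than 90% of its
members land in a single K-means cluster.

**Evolution level.** Per TF, the conservation score is the ortholog count
normalized by a reference species count (the packaged table's granularity is
consistent with a denominator near 96), and the TFBS-side score is the mean
evolution feature over its positive sites. Correspondence is the Spearman
rank correlation (tie-corrected average ranks) with a one-sided p-value from
$t = r\sqrt{(n-2)/(1-r^2)}$.

```{r table270}
res <- conservation_correspondence(conservation_table_270())
unlist(res)
```

## The synthetic world

`generate_world()` plants every signal the pipeline is meant to detect:

* protein families (a root sequence, family ancestors at divergence 0.6,
  members at 0.05 — i.i.d. per-site substitution; phylogenetic realism is out
  of scope);
* one consensus per family, member consensi lightly mutated, per-TF PWMs as
  Dirichlet draws concentrated on the consensus (concentration 12), so PWM
  similarity tracks protein similarity;
* 30 sites per TF sampled column-wise from its PWM (every TF passes the
  more-than-10-sites inclusion rule);
* an AT-rich, CpG-depleted order-3 promoter corpus;
* a 174-motif catalog holding each TF's consensus plus random decoys, with a
  per-TF embedding probability: embedded sites are exact consensus copies and
  therefore match the catalog at threshold 0.95;
* a Gaussian copula (latent correlation $2\sin(\pi\rho/6)$, so the *Spearman*
  correlation is targeted exactly) couples each TF's ortholog count with its
  embedding probability and motif score, planting a rank correlation between
  TF conservation and mean TFBS evolution feature. Binomial site-sampling
  noise attenuates the realized correlation by a few percent at 30 sites per
  TF.

`plant_structure_classes()` rebuilds the world for structure-level tests:
class skeleton consensi are drawn from distinct two-base alphabets (distinct
dinucleotide composition is exactly the axis the structure feature reads),
all members of a class share one flat consensus PWM, the embedded-site count
is fixed, and within-class variability is injected per site at rate
$0.5/\mathrm{separation}$. These three choices make the per-TF encodings
approximately i.i.d. Gaussian within a class: per-TF Dirichlet PWMs, per-TF
embedding rates, or per-TF consensus mutations each add a systematic per-TF
offset that mixture-model selection resolves into spurious subcomponents long
before it merges true classes. With classes of realistic size (tens of TFs),
BIC then recovers the planted class number reliably; at a dozen TFs per class
it does not, which is a property of BIC at that sample size, not of the
mapping rule.

What the generator does *not* emulate: real promoter composition beyond
order-3 statistics, real TRANSFAC site-length heterogeneity, indel evolution,
and correlated attribute noise. Passing tests therefore demonstrate that the
machinery detects the planted statistical structure at these scales — not
that the effect sizes match any particular biological dataset.

## Numerical and reproducibility choices

* All stochastic steps take explicit integer seeds; sub-streams are derived
  arithmetically (kept below $2^{31}$), and RNG state is restored after each
  seeded block, so calls do not perturb the caller's RNG.
* PWM columns are validated to sum to 1 within $10^{-6}$ and renormalized;
  information content uses $0\log 0 = 0$; a background of 0 under a non-zero
  frequency is an error, not an `-Inf`.
* Match-style similarity returns 1 when a PWM is completely uninformative
  (`Max == Min`).
* Tree split ties and all other classifier nondeterminism are pinned by the
  seed; identical inputs and seeds give identical predictions.
* Degenerate inputs error early and by name: empty training sets, constant
  labels, one-class AUC, unmapped TFBS ids, constant conservation columns,
  all-identical encodings.

## Problem sizes used by the packaged analyses

The packaged evaluation scripts and tests run, per analysis: 20 TFs × 10
balanced sets under 10-fold cross-validation for the model suite; 10 families
× 7 TFs × 10 sites (within-family divergence 0.02 — binding specificity is
strongly conserved within a family) for sequence-level matching with 100
re-pairing permutations; 270 TFs in four classes of 56/79/93/42 for
structure-level mapping; and n = 270 conservation pairs, matching the scale
of the packaged table, for evolution-level recovery (the planted-correlation
estimate is averaged over five replicate worlds; a single replicate has
sampling spread $\approx 1/\sqrt{n}$ around the planted value).

## Known limitations

* The bundled dinucleotide property table is synthetic; results on real data
  require a measured table.
* The blastclust emulation reproduces the -L/-S *semantics*; cluster-level
  agreement with the NCBI binary on real data is not guaranteed, and for very
  short segments the both-sequence coverage rule makes end mismatches
  decisive.
* The Fisher-test construction and the bootstrap "midpoint" rule are
  documented choices among several defensible readings.
* Class-number estimation by mixture BIC needs tens of points per class;
  below that it overfits tight clusters regardless of how well separated
  they are.
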