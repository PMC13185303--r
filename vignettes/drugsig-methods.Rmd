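---
title: "Signature-based drug repurposing: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signature-based drug repurposing: models, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drugsig)
```

## The model

`drugsig` implements a proteome-wide signature approach to drug
repurposing. The working hypothesis is that a drug's therapeutic behavior
is summarized by its pattern of interactions across an entire proteome,
and that compounds with similar interaction patterns are likely to share
indications. Everything in the package derives from one object: the
**interaction matrix**, a compounds-by-proteins matrix whose entry
$s(c, p) \in [0, 1]$ is a predicted interaction score between compound $c$
and protein $p$. Row $c$ is compound $c$'s *interaction signature*.

### Scoring compound-protein pairs

Scores come from a docking surrogate that consumes binding-site
predictions rather than running docking. Each protein carries zero or more
predicted sites, each with a confidence $w \in [0, 1]$ and a template
ligand represented as a circular-substructure fingerprint (ECFP4
convention: hashed substructures of radius 2). For a query compound with
fingerprint $q$,

$$ s(c, p) = D(q, \ell^*) \cdot w^*, $$

where $\ell^*$ is the template with the highest Sorenson-Dice similarity
$D(q,\ell) = 2|q \cap \ell| / (|q| + |\ell|)$ to the query and $w^*$ is
that site's confidence. The selection rule is deliberately *argmax over
Dice, then multiply by that site's confidence*: the alternative reading,
maximizing the product $D \cdot w$ over sites, is available via
`score_compound_protein(..., method = "max_product")` because the informal
description of such scorers is ambiguous between the two; the two rules
differ whenever a weaker-matching template sits on a much more confident
site. Dice ties across sites resolve to the higher confidence (the
stronger site call). Proteins with no predicted sites score 0 against
every compound.

Two conventions are worth flagging because they are genuine choices:

* **Empty fingerprints score 0 against everything, including each
  other.** A featureless parse carries no evidence; returning 1 for two
  empty sets would manufacture perfect similarity out of parse failures.
* **Heavy atoms** are non-hydrogen atoms of the parsed structure.
  Compounds that fail to parse are excluded with a warning rather than
  aborting a batch.

### Ranked similarity lists

Signatures are compared all-against-all with **cosine distance**,
$1 - \frac{x \cdot y}{\|x\|\,\|y\|}$, applied to the raw non-negative
signature rows without centering or scaling. For non-negative vectors
this lies in $[0, 1]$. Degenerate rows need conventions: one all-zero
vector against a non-zero vector is maximally distant (1); two all-zero
vectors are indistinguishable (0). Each compound's *similarity list* is
every other compound sorted by ascending distance. All ordering in the
package follows a single contract -- ascending key, ties broken by
C-locale lexicographic compound id -- so every ranking is a total order
and every run is reproducible across platforms. Ranks run $1..M-1$ with
no gaps.

The fingerprint baseline replaces cosine-on-signatures with
$1 - \text{Tanimoto}$ on compound fingerprints
($T(a,b) = |a \cap b| / |a \cup b|$), under the same ordering contract.
Dice and Tanimoto are linked by $D = 2T/(1+T)$, which the test suite
verifies to machine precision; either coefficient therefore induces the
same ranking, and the package uses Dice where template ligands are
compared (scoring) and Tanimoto where drug-drug similarity is compared
(the baseline), matching field convention.

### The uniqueness filter

Approved-drug libraries are full of near-duplicate "me too" analogs, and
a fingerprint pipeline recovers them at the very top of each list,
inflating benchmark scores without saying anything about mechanism.
`apply_uniqueness_filter()` therefore zeroes, per query list of length
$L$, the similarity of the $k = \lceil 0.02\,L \rceil$ most-similar
neighbors (distance set to 1) and re-sorts. Three decisions here:

* Filtered pairs are **kept in the list at distance 1**, not removed, so
  list lengths and all cutoff arithmetic downstream are unchanged, while
  the pairs can no longer contribute to top-$N$ recovery.
* $k$ uses **ceiling**, not floor, so the filter is never a silent no-op
  on short lists.
* The filter implements the **percentile rule**, not an absolute
  similarity threshold. On a particular dataset the 98th percentile may
  happen to correspond to some absolute Tanimoto value, but that
  correspondence is data-dependent; an absolute-threshold mode
  (`threshold =`) is provided for sensitivity analyses only.

### Fusion

Two pipelines over the same compound universe can be fused per
query/neighbor pair. The score-product operator converts distances to
similarities, multiplies, and converts back:
$d_f = 1 - (1 - d_a)(1 - d_b)$. Rank operators (min, max, mean, sum,
product of the two ranks) and the product of distances are also provided.
Rank keys are divided by their maximum attainable value before being
stored -- a strictly monotone rescaling that changes nothing about the
ordering but keeps the fused object a valid pipeline with distances in
$[0, 1]$, so fused pipelines can be benchmarked, filtered and re-fused
like any other.

## Benchmarking

Benchmarking is leave-one-out recovery of known drug-indication
associations, restricted to indications with at least two approved drugs
(one to hold out, one to recover).

* **Indication accuracy (IA)**: the percentage of an indication's
  approved drugs whose top-$N$ similarity list contains at least one
  *other* approved drug for that indication. **AIA** is the unweighted
  mean over indications (no weighting by indication size: each indication
  is one experiment).
* **Consensus list**: every approved drug votes with its top-$N$; a
  compound's consensus score is its vote count, its average score the
  mean rank over the lists that voted for it. Entries order by
  (descending votes, ascending average rank, ascending id).
* **nIA**: the percentage of approved drugs found in the top-$N$ of the
  indication's own consensus list; **nAIA** is its mean over indications.
* **NDCG**: binary relevance (position relevant iff occupied by another
  approved drug), $\mathrm{DCG}@N = \sum_j \mathrm{rel}_j / \log_2(j+1)$,
  normalized by the ideal DCG that packs the
  $\min(K - 1, N)$ relevant items into the head; averaged over an
  indication's approved queries. **nNDCG** applies the same construction
  once to the consensus ordering with ideal over $\min(K, N)$. The
  discount, binary relevance and truncated ideal are the standard
  information-retrieval definition, stated here because "NDCG" alone
  underdetermines them.

**One vote rule deserves emphasis**: a neighbor contributes a consensus
vote only if it is within the voting cutoff *and* has positive similarity
(distance < 1). Zero similarity is zero evidence, and this is precisely
what makes uniqueness-filtered pairs inert in consensus metrics. It also
makes the perfect-duplicate limit exact: without it, the arbitrary
id-ordered tie block at distance 1 would leak into voters' top-$N$ and
collect one more vote than any approved drug can (a drug cannot vote for
itself), capping nIA below 100 in a study designed to be perfect.

The voting cutoff defaults to the evaluation cutoff at each cutoff level,
and is exposed (`voting_cutoff`) because the two are conceptually
distinct.

### Random controls

The IA chance baseline is closed-form. For a query drug, the top-$N$ of a
random ranking is a uniform size-$N$ subset of the other $M - 1$
compounds, $K - 1$ of which are relevant, so

$$ P(\ge 1 \text{ hit}) = 1 - \binom{M-K}{N} \Big/ \binom{M-1}{N}, $$

and $100\times$ this value is the expected IA of a random pipeline. The
consensus metrics have no convenient closed form (votes across lists
interact), so their controls are seeded Monte-Carlo: each voter list is
replaced by an independent uniform permutation (default 100 replicates)
and the metric means are reported. `control = "closed_form"` skips the
permutation controls for speed and leaves them `NA`.

## Candidate prediction

`predict_candidates()` ranks every compound by (consensus score, average
rank, id) and attaches a binomial tail probability: the chance of
collecting at least the observed number of votes if each of the $K$
voting lists independently contained the compound in its voting window
with probability $p$. The package sets $p = N_{\text{vote}} / (M - 1)$ and
logs both parameters: published tables of this kind rarely state the
parameterization, and back-calculating one from printed probabilities is
not reliable, so the package commits to the transparent choice and keeps
it configurable. The average score is the mean rank over only the lists
that actually voted for the compound, which keeps it bounded by the
voting cutoff. Drugs already approved for the indication are retained and
flagged rather than silently removed -- whether "novel" excludes them is
a presentation decision for the caller (`exclude_approved`).

## Target-overlap analysis

For corroboration, each candidate's strongest predicted targets (its
signature row, ranked) are compared against curated *gold standard*
protein sets via three views: the frequency distribution of gold proteins
across rank bins (1-20, 21-40, ... by default), the cumulative percentage
of gold proteins recovered as a function of rank cutoff, and the Jaccard
coefficient between the union of per-candidate top-10 targets and the
gold set. When a candidate *group* is pooled, a gold protein's rank is its
**best (minimum) rank across the group** -- the natural reading of
"recovered by rank $r$" for a set of candidates, and the rule is logged
because other poolings (mean rank, per-candidate counting) are
defensible. Frequency distributions are emitted normalized both within
the overlapping set and against the full gold set, since either
normalization can be wanted. Control groups are a seeded uniform random
draw of matching size and the bottom of the candidate list, the latter
pre-filtered to $\ge 5$ heavy atoms so that trivially tiny fragments do
not stand in for "bad candidates".

## The synthetic study generator

Real inputs for this kind of platform are enormous (tens of thousands of
compounds and proteins, curated association databases). The package
instead ships a first-class generator whose output exercises every stage:

* Indication $i$ owns $K$ dedicated approved drugs and $G$ dedicated
  *driver proteins*. Approved drugs score
  $\mathrm{clip}(\text{signal} + \mathcal{N}(0, \sigma), 0, 1)$ on their
  drivers; all other cells are sparse background, non-zero with
  probability `background_density` and then Beta(2, 8)-distributed.
  The Beta background is right-skewed, the qualitative shape of
  similarity-times-confidence products: most scores are small, few are
  large.
* Fingerprints are uniform random feature sets, except `n_analog_pairs`
  planted analog pairs that share enough features to reach a configured
  Tanimoto floor (default 0.9). Pairs are planted across *different*
  indications, so cross-indication analog crowding -- exactly what the
  uniqueness filter exists to suppress -- is present by construction.
* The gold standard of each indication is its driver set, making
  target-overlap analyses self-validating: top candidates for a planted
  indication should recover drivers; random groups should not.
* A binding-site library (random confidences and templates) is included
  so signature construction can be exercised end to end; the planted
  matrix itself is generated directly so the planted structure is exact
  rather than filtered through the scorer.

Default sizes are $M = 500$, $P = 300$, $I = 50$, $K = 4$, $G = 5$,
signal 0.8, noise sd 0.05, background density 0.2 -- small enough that
the full four-pipeline comparison runs in seconds on one CPU, large
enough that chance baselines are far from the planted signal. All
generation is deterministic given the seed.

Two limits anchor the test suite. With `signal = 0, noise_sd = 0` the
study is null and benchmark metrics must match the chance controls; the
suite checks mean IA over 200 unplanted indications against the
hypergeometric expectation within three standard errors. With
`signal = 1, noise_sd = 0, background_density = 0` co-indicated drugs
have identical signatures and IA, AIA, nIA, nAIA must equal 100 and
NDCG, nNDCG equal 1 *exactly* at every cutoff.

### What the generator does not emulate

Passing these tests demonstrates correctness of the machinery, not
real-world performance. The generator's background is independent across
cells, whereas real interaction signatures have strong column structure
(promiscuous proteins, protein-family correlations); its fingerprints
are unrelated to its interaction matrix, so the fingerprint pipeline
carries no indication signal beyond the planted analog pairs -- in the
shipped synthetic comparison the fingerprint baseline hovers near chance
by design, whereas on real libraries ligand similarity is a strong
(analog-driven) predictor; and indications are disjoint blocks, while
real drug-indication maps overlap heavily. Conclusions about *relative
pipeline performance on real data* cannot be read off the synthetic
comparison.

## Numerical and degenerate-input policy

* Cosine values are clamped to $[0, 1]$ after the dot product to absorb
  floating-point excursions; distances of exactly 1 are meaningful
  (zero similarity) and are tested with strict comparisons.
* Interaction scores outside $[0, 1]$, malformed cells and duplicate ids
  are load errors that name the offending row/column; nothing is coerced
  or imputed. Missing optional fields (fingerprints, heavy-atom counts)
  fail loudly in the operations that need them.
* Binomial tails use the numerically stable cumulative distribution
  (`pbinom`), hypergeometric controls use `phyper` on log-scale
  binomials; both are cross-checked against direct summation and
  exhaustive enumeration in the tests.
* All stochastic components (generator, null lists, Monte-Carlo controls,
  random candidate groups) consume explicit seeds and record them.

## Problem sizes used by the shipped analyses

The acceptance script and test suite run: the default $500 \times 300$
study for the four-pipeline comparison; 200 unplanted indications on a
500-compound universe for null calibration; a $60 \times 40$
perfect-duplicate study; twenty replicates of a $200 \times 300$,
10-indication planted study (signal 0.9, noise 0.01) for recovery and for
the top-versus-random target-overlap contrast, using a voting cutoff of
20 (top 10% of each list, the scaled analog of voting with the top 100 of
a 13k-compound library) and candidate groups of 24; and brute-force
oracle comparisons on universes of at most 12 compounds, where exhaustive
enumeration is feasible. These sizes were chosen so the whole suite
completes in well under a minute of compute per component while keeping
Monte-Carlo standard errors small relative to the effects tested.

## Known limitations

* The scorer consumes binding-site predictions; it cannot be better than
  they are, and it makes no attempt to rescale or calibrate confidences.
* Exact all-against-all ranking only: $O(M^2)$ distances,
  appropriate for desk-scale libraries (thousands of compounds), with no
  approximate nearest-neighbor path.
* The binomial null treats voting lists as independent; voters with
  correlated signatures (the interesting case) violate this, so the
  probabilities are a ranking aid, not calibrated p-values.
* Consensus-metric controls are Monte-Carlo and inherit simulation error;
  they are reported as means over a stated number of replicates.
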