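---
title: "Partially function-to-topic modeling of protein function"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partially function-to-topic modeling of protein function}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the representation

Most sequenced proteins lack experimentally verified function
annotations.  Casting function prediction as multi-label classification,
each protein carries a set of Gene Ontology (GO) terms, and the goal is
to rank the label universe for an unannotated protein.  `pftp` treats a
protein sequence as a text document: the "words" are overlapping
amino-acid blocks (k-mers, default length 2, stride 1) over the
20-letter residue alphabet, and a protein is reduced to its bag-of-words
count vector over a fixed block vocabulary of size $W$.  Tokenization is
configurable (`--word-length`, `--stride`, a `--mixed-lengths` option
emitting all lengths $1..k$, and a `--keep-ambiguous` option retaining
blocks with non-standard letters such as `X`); the default drops blocks
containing letters outside the 20-letter alphabet, and case is
normalized before tokenization since FASTA case carries no meaning here.

## The model

The model is a partially labeled supervised topic model.  The global
topic space $\{1,\dots,K\}$ is partitioned into $L$ disjoint subsets
$\mathbb{K}_l$ of $m$ topics, one per function label, plus a background
subset $\mathbb{K}_B$ of $B$ topics attached to a latent background
label that is active in *every* protein and absorbs sequence features
shared across functions, so $K = mL + B$.  The background block occupies
topic indices $1..B$ and each label's block follows contiguously, so the
layout is reproducible and serializable.

Each topic $k$ has a word distribution
$\theta_k \sim \mathrm{Dir}(\lambda)$ over the vocabulary; each extended
label $l$ has a topic mixture $\pi_l \sim \mathrm{Dir}(\alpha)$
supported on its own subset $\mathbb{K}_l$; and each document $d$ has a
label mixture $\psi_d \sim \mathrm{Dir}(\beta)$ over its $L_d$ active
extended labels (its annotated labels plus the background, encoded by
the binary vector $\Lambda_d$).  Every token draws a label
$l_{dn} \sim \psi_d$, a topic $z_{dn} \sim \pi_{l_{dn}}$ restricted to
$\mathbb{K}_{l_{dn}}$, and a word $w_{dn} \sim \theta_{z_{dn}}$.  With
$m = 1$ and no background the model collapses to Labeled-LDA (one topic
per label), which the test suite verifies exactly against an
independently coded Labeled-LDA reference.

### The restricted-support reading

The model description admits two readings of the topic-mixture prior:
$\pi_l$ as a $K$-dimensional vector with mass allowed anywhere, or as a
$K_l$-dimensional vector supported on $\mathbb{K}_l$ only.  We adopt the
restricted reading throughout: the unrestricted one would let a label
leak probability onto other labels' topics, making the partition
vacuous.  Concretely this puts $\alpha K_l + N_l$ (not $\alpha K + N_l$)
in the denominator of the topic factor below, which is the unique choice
consistent with the collapsed joint distribution under the restricted
prior — the test suite enforces this consistency by comparing the
implemented conditional against a brute-force evaluation of the
collapsed joint on enumerable instances.  One visible consequence: on an
empty count state the conditional is uniform over admissible labels and
uniform *within* each subset, not uniform over all (label, topic) pairs
when subset sizes differ.

## Inference

### Training

Training integrates out $(\pi, \theta, \psi)$ analytically and runs a
collapsed Gibbs sampler over the joint per-token assignment
$(l_{dn}, z_{dn})$.  With the token removed from the counts
(superscript $\setminus dn$), the unnormalized weight of a candidate
pair $(l, k)$, $l$ active in document $d$, $k \in \mathbb{K}_l$, is

$$
\left(\beta + N_{dl}^{\setminus dn}\right)\cdot
\frac{\alpha + N_{lk}^{\setminus dn}}{\alpha K_l + N_l^{\setminus dn}}\cdot
\frac{\lambda + N_{kw}^{\setminus dn}}{\lambda W + N_k^{\setminus dn}},
$$

where $N_{dl}, N_{lk}, N_{kw}$ are the document-label, label-topic and
topic-word counts with totals $N_d, N_l, N_k$.  The document-level
denominator of the label factor is constant across candidates and is
dropped; the multinomial coefficients of the finite-sample derivation
cancel in the ratio and are never computed.  The pair is drawn jointly
(one categorical over $\sum_l K_l$ candidates) rather than
label-then-topic, matching the joint conditional.  Sweeps visit tokens
in a fixed document-major order; counts are maintained incrementally and
cross-checked against recounting in the tests.

Estimates are posterior means given a state,
$\hat\psi_{dl} = (\beta + N_{dl})/(\beta L_d + N_d)$,
$\hat\pi_{lk} = (\alpha + N_{lk})/(\alpha K_l + N_l)$ for
$k \in \mathbb{K}_l$,
$\hat\theta_{kw} = (\lambda + N_{kw})/(\lambda W + N_k)$,
averaged over the retained samples of one chain (after burn-in, at the
thinning interval).  The partition pins the label-to-subset
correspondence, so labels cannot switch across samples; topics *within*
a subset are exchangeable, which is why recovery experiments match
topics within subsets before comparing (see the identifiability note
below).  Multiple chains are run independently on consecutive seeds and
reported separately, never averaged, since within-subset topic identity
is chain-specific.  The collapsed log joint (log-Gamma form) is traced
every 100 sweeps as a convergence diagnostic only; it fluctuates around
the posterior's typical set and is not expected to increase
monotonically, and no adaptive convergence detection is attempted —
schedules are fixed.

### Prediction

New proteins are scored by fold-in: $\hat\pi$ and $\hat\theta$ are
frozen at their trained point estimates (new data must not mutate the
model), every extended label is admissible
($\Lambda_d \equiv \mathbf{1}$), and only the per-document label counts
are resampled with per-token weight
$(\beta + N_{dl}^{\setminus dn})\,\hat\pi_{lk}\,\hat\theta_{kw}$.  The
averaged $\hat\psi_d$ gives a raw mixture over the $L$ labels plus the
background (summing to 1); scores over the real labels are also reported
renormalized with the background excluded.  An alternative consistent
with "constraining the global parameters" would resample against frozen
counts plus priors; frozen point estimates were chosen as the cleaner
contract.  A document with no in-vocabulary token receives the uniform
prior mixture and is flagged in the output rather than dropped.
Binarization for set-valued metrics predicts a label when its
renormalized score reaches the threshold $\tau$ (ties included), default
$\tau = 1/L$, the uniform baseline.

## Default parameters

| parameter | meaning | default | why |
|---|---|---|---|
| $k$ | block length (residues) | 2 | $W = 400$ two-mers balance resolution and sparsity |
| stride | window step (residues) | 1 | overlapping windows keep all local context |
| $m$ | topics per label | 3 | middle of the stable range $K \in [2L, 4L]$ |
| $B$ | background topics | 1 | one shared background; configurable |
| $\alpha$ | label-topic concentration | $50/K$ | standard topic-model heuristic |
| $\lambda$ | topic-word concentration | $200/W$ | standard heuristic; larger = flatter topics |
| $\beta$ | document-label concentration | 0.01 | sparse per-protein label usage |
| training schedule | sweeps/burn-in/thin | 2000/1000/50 | 20 retained samples |
| prediction schedule | sweeps/burn-in/thin | 1000/500/50 | 10 retained samples |

All randomness flows through a single integer seed (chain $c$ uses
seed$+c-1$); fixed seed, fixed visit order and deterministic tie rules
make every result bit-reproducible.

## The synthetic generator

`sample_model()`/`sample_corpus()` simulate from the generative process
above and export every ground truth (true $\pi, \theta, \psi$ and token
assignments), providing the fixtures for the test suite and the recovery
experiments.  The default fixture is $D = 300$ documents, $L = 4$
labels, $m = 2$, $B = 1$, $W = 60$, two labels per document, $N_d = 120$
tokens, with generative concentrations $\alpha = 0.5$, $\beta = 0.5$,
$\lambda = 0.1$ — small enough for minutes-scale tests, structured
enough that held-out label recovery is non-trivial.  Label co-assignment
defaults to a uniform choice of label pairs (a Bernoulli scheme is
available); tokens per document are fixed by default (Poisson option).
The simulator targets the model's own assumptions and deliberately does
*not* imitate real proteome k-mer statistics, GO-term co-occurrence
structure, or annotation noise — so passing recovery and prediction
tests demonstrates the correctness of the inference machinery, not
real-data performance.  Recovery experiments train under the generative
concentrations (the standard choice for sampler-validation studies); the
heuristic defaults $50/K$ and $200/W$ remain in place for real
corpora.

## What is and is not identifiable

Because $\pi_l$ is a *global* (corpus-level) mixture, the tokens of a
given label are, marginally, i.i.d. draws from the single mixture
$\phi_l = \sum_{k \in \mathbb{K}_l} \pi_{lk}\theta_k$.  A mixture of
multinomials observed through single draws is identifiable only up to
$\phi_l$: any re-decomposition of $\phi_l$ into $m$ components lies on a
likelihood ridge, and the sparse Dirichlet prior populates that ridge
with many equivalent sparse corners (arbitrary word partitions), not
merely the $m!$ within-subset permutations.  For $m \ge 2$ the
individual within-subset $\theta_k$ therefore cannot be consistently
recovered from data simulated by the model itself, no matter how much
data is provided; the test suite instead verifies that the identifiable
label-level word distributions $\phi_l$ are recovered and improve with
document length, and that held-out label ranking is strong.  The
dedicated within-subset recovery check is retained in the acceptance
suite and documents this limit empirically.  This does not affect
prediction, which depends on the $\phi_l$ only.

## Evaluation conventions

Six metrics are computed from the score matrix and true label sets:
Hamming loss (on binarized predictions, with the threshold recorded in
the report), one-error, average precision (label ranking), and three
precision-recall areas — pooled over all document-label pairs, macro
over labels, and frequency-weighted by label prevalence
$w_l = n_l / \sum n_l$.  PR curves are built by sweeping a threshold
over the distinct scores with trapezoidal integration over recall,
prepending the recall-0 point at the first point's precision.  Ranking
ties break deterministically by label order.  Documents with empty true
label sets are excluded from ranking metrics, and labels without
positive documents are excluded from the per-label means; both
exclusions are logged.  Exact numeric parity with any particular
published PR interpolation is not claimed; the convention is documented
so comparisons within this package are internally consistent.

## Numerical and degenerate-input choices

Weights are computed in double precision directly (no log-space needed
for per-token conditionals; products of three bounded factors);
categorical draws guard the final index against rounding.  Empty
documents are valid everywhere (all-zero bag-of-words rows, uniform
prior predictions).  Training documents with no observed label are
rejected by default — the model is supervised — with an
`allow_unlabeled` escape hatch assigning background-only rows.  A
vocabulary that prunes to zero blocks, a schedule retaining no samples,
and inadmissible assignments all raise typed errors that the CLI maps
to exit codes (2 usage/config, 3 data format, 4 internal).

## Problem sizes in the test suite

The suite checks the sampler against exhaustive enumeration on
instances small enough to enumerate (4-token stationarity, 16
configurations, $10^5$ recorded sweeps; conditional oracle on up to 6
tokens), runs recovery and held-out prediction at the default fixture
with the training schedule scaled to 500 sweeps / 250 burn-in, and
compares all metrics against definition-level brute force on 1000 random
instances with $D \le 3$, $L \le 3$.  These sizes are the package's
choice of enumerable-yet-informative problems; real-corpus runs use the
full default schedules.

## Limitations

Labels are flat identifiers: no GO-hierarchy semantics, no true-path
propagation, no hierarchy-aware evaluation.  No label-space reduction is
performed (external pre-processing such as Boolean matrix decomposition
can be applied upstream and inverted downstream).  Inference is
single-machine collapsed Gibbs; no variational path, no hyperparameter
optimization, no streaming.  And as discussed above, within-subset
topics are reported as found by one chain and should be interpreted as
one representative decomposition of each label's word distribution, not
as uniquely recoverable structure.
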