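---
title: "Minwise-hashing sketches for compound-protein interaction prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minwise-hashing sketches for compound-protein interaction prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpisketch)
```

## The model

A compound is a binary substructure fingerprint $\Phi(C) \in \{0,1\}^D$, a
protein a binary domain fingerprint $\Phi(P) \in \{0,1\}^{D'}$. A
compound-protein pair is their tensor product
$\Phi(C,P) = \Phi(C) \otimes \Phi(P)$, laid out compound-major: tensor bit
$c \cdot D' + p$ is active iff compound bit $c$ and protein bit $p$ both
are. Interaction prediction is binary classification of pairs with a linear
score $f(C,P) = w^\top \Phi(C,P)$, so each weight is attached to one
substructure-domain co-occurrence — that is the interpretability the tensor
representation buys. Its cost is dimension: at the scale of public
descriptor sets ($D = 881$, $D' = 4137$) the pair space has
$3{,}644{,}697$ coordinates and the number of pairs is the product of the
compound and protein counts.

The package's core is the sketching pipeline that removes this cost:

1. **Minwise hashing.** The pair fingerprint is identified with its active
   set $S \subseteq \{0,\dots,M-1\}$, $M = D D'$. For $\ell$ seeded random
   permutations $\pi_k$ of $[0, M)$, the signature is
   $t_k = \min \pi_k(S)$. Two sets collide at coordinate $k$ with
   probability exactly their Jaccard similarity
   $J = |S_i \cap S_j| / |S_i \cup S_j|$, so the expected signature Hamming
   distance is $\ell (1-J)$.
2. **Additional hashing.** Storing raw minhash values costs a machine word
   each. Every $t_k$ is therefore folded by one seeded 2-universal hash
   $h$ into $\{0,\dots,N-1\}$ with $N \ll M$. Equal values still always
   collide; unequal ones collide with probability $1/N$, giving the
   per-coordinate collision law
   $$\Pr[s_{ik} = s_{jk}] = 1 - \tfrac{N-1}{N}\,(1 - J).$$
   The law converges to $J$ as $N$ grows and is already flat for
   $N \gtrsim 2^8$ (`plot_collision_law()` draws this), which is why small
   bin counts are essentially free.
3. **Compact fingerprints.** The $\ell$ bins are one-hot expanded and
   concatenated into an $\ell N$-bit vector with exactly $\ell$ ones. The
   inner product of two compact fingerprints counts bin matches, so the
   Gram matrix is positive semidefinite by construction and its entries
   track the Jaccard kernel — the linear model on sketches emulates a
   kernel machine that would be infeasible to train directly.
4. **Linear classification.** On compact fingerprints (or, for comparison,
   on the raw tensor features) the package fits
   $$\min_w\; R(w) + C \sum_i \max(1 - y_i\, w^\top x_i,\, 0),$$
   with $R(w) = \|w\|_1$ (sparse, interpretable; "MH-L1SVM") or
   $R(w) = \tfrac12\|w\|_2^2$ ("MH-L2SVM"). The equations are sometimes
   written without $C$ and with an unsquared L2 norm; the package uses the
   convention above — the one the standard linear-SVM solvers optimize —
   so $C$ sweeps like $10^{-5}\dots10^5$ mean what practitioners expect.
5. **Weight recovery.** A sketch weight sits at coordinate $kN + b$. For
   interpretation the package computes, for each tensor feature $i$,
   $$\tilde w_i = \frac{1}{\ell} \sum_{k} w[\,kN + h(\pi_k(i))\,],$$
   the forward composition that is arithmetically identical to applying
   $h^{-1}$ (one-to-many) and then $\pi_k^{-1}$ to every compact
   coordinate and averaging. "Average" here means over the $\ell$ blocks —
   each block contributes exactly one weight per tensor feature, which
   makes the estimator's scale independent of $\ell$; dividing additionally
   by $h$-preimage multiplicities was the alternative reading and is
   deliberately not used. `top_features()` then ranks features by weight,
   with ties broken by ascending tensor index so output is deterministic.

## Parameters that matter

| parameter | meaning | default | notes |
|---|---|---|---|
| `ell` | sketch length (number of permutations) | 10 | collision noise shrinks as $1/\sqrt{\ell}$; at desk scale $10\lceil\log_2 M\rceil$ is a safe choice |
| `n_bins` (N) | additional-hash range | $2^{16}$, capped at $M$ | the collision law saturates by $N \approx 2^8$ |
| `C` | hinge-loss weight | 1 | sweep $10^{-5}\dots10^5$ and pick by CV AUC; compact rows have constant sum $\ell$, so useful `C` values scale inversely with $\ell$ |
| `regularization` | L1 or L2 | L2 | L1 for feature extraction; it recovers markedly fewer nonzero tensor features |
| `mode` | permutation realization | `explicit` | exact seeded permutations up to $M \approx 2^{24}$; `universal` approximates $\pi_k(x) = (a_k x + b_k) \bmod p_M$ for larger universes (and then hash values live in $[0, p_M)$, $p_M$ the smallest prime $\ge M$) |

A hash family is fully reconstructible from `(ell, m, n_bins, master_seed,
mode)`: per-permutation seeds and the $h$ parameters are derived from the
master seed by a fixed integer mix, so serialized models carry five numbers
instead of an $M$-sized table.

## Cross-validation schemes

*Pair-wise* CV randomly partitions labeled pairs into five folds of
near-equal size (remainders go to the lowest-numbered folds) — the setting
of filling in missing interactions among known entities. *Block-wise* CV
partitions compounds and proteins separately; fold $i$ tests the pairs in
compound-block $i$ × protein-block $i$ and trains only on pairs whose
compound and protein both lie outside those blocks, so straddling pairs are
used in neither — the cold-start setting. The pairing of compound-block $i$
with protein-block $i$ (five test blocks) matches the "train on the
remaining four-by-four" description; a `blockwise_pairing = "grid"` option
provides the 25-combination variant. Model selection follows the published
protocol: the $C$ maximizing mean test-fold AUC is reported (a nested
selection is not applied by default, since the protocol being reproduced
selects on the test fold). AUC is the Mann-Whitney statistic with midrank
tie handling. Unlabeled pairs are treated as negatives when sampling — the
gold standard lists positives only — which is an assumption, not a fact.

## The synthetic generator

`generate_synthetic_dataset()` emulates the statistical shape the method
assumes: compound and protein bits i.i.d. Bernoulli (defaults: 100 × 80
entities, $D = 50$, $D' = 40$, density 0.1 — the sparse regime of
substructure/domain fingerprints), and labels from a planted sparse linear
model — `n_planted` tensor features (default 20) with weights
$\pm$`effect_scale` — because that is exactly the classifier's hypothesis
class, so ground truth exists for recovery tests. Pairs are scored by the
sum of planted weights on their active tensor features, the top-scoring
fraction is labeled positive, and labels are flipped with probability
`label_noise`.

Two numerical choices deserve note. First, raw scores are heavily tied
(most pairs touch no planted feature), so a seeded uniform jitter at the
$10^{-9}$ scale breaks ties before the quantile is taken; otherwise no
threshold could realize the requested positive fraction. Second, the
pre-noise positive fraction is noise-compensated,
$p_0 = (p - \eta)/(1 - 2\eta)$ for target $p$ and flip rate $\eta$, so the
*realized post-noise* fraction is centred on the target rather than biased
upward by the flips.

What the generator does **not** model: substructure co-occurrence
structure, domain grammar, compound series, promiscuous proteins, or any
correlation between entity frequency and label. Passing tests therefore
demonstrate the machinery (sketching laws, solver correctness, recovery,
protocol behavior) — not screening performance on real chemogenomic data,
whose label structure is far less linear.

## Solvers and numerical choices

No linear-SVM library is a dependency; the two optimizers are part of the
package, and tests check them against independent oracles (a long-run
projected subgradient method, and an interior-point QP on the L2 dual).

* **L2-hinge: dual coordinate descent.** One box-constrained dual variable
  per example, updated in a fixed cyclic order (determinism without a
  random permutation), with $Q_{ii} = \|x_i\|_2^2$ precomputable because
  features are binary. Stopping is certified by the duality gap of the best
  primal iterate: converged when gap $\le$ `tolerance`
  $\times \max(1, |\text{objective}|)$.
* **L1-hinge: ADMM.** The hinge is nonsmooth *and* couples coordinates, so
  plain cyclic coordinate descent can stall at non-optimal corners (this
  was observed, not hypothesized). The split $z = \mathrm{diag}(y) X w$
  alternates (i) a lasso $w$-step solved by cyclic coordinate descent with
  soft-thresholding — which is where exact zeros come from — (ii) the
  closed-form hinge prox for $z$, and (iii) dual ascent on $u$, with
  $\rho = \max(1, C)$. Convergence is declared when the best objective has
  settled to `tolerance` and the primal residual is below $10^{-3}$.

Both solvers return the best primal iterate encountered; its objective,
recorded per sweep, is the monotone quantity the tests monitor. Defaults:
`tolerance = 1e-3` (relative), `max_iterations = 1000` sweeps; hitting the
cap flags the model and warns rather than failing. The bias term is off by
default — compact rows have constant sum $\ell$, which largely absorbs an
intercept — and when enabled it is an implicit regularized constant feature
for L2 (the augmentation convention) and an unpenalized coordinate for L1.

Degenerate inputs are typed errors, not silent fixes: empty feature sets
(an all-zero compound or protein) abort encoding with the offending pair
named, because assigning them a sentinel bin would bias the collision
statistics — `skip_empty = TRUE` (or `--skip-empty`) drops them with a
warning instead; single-class training sets, two empty sets given to
`jaccard()`, and single-class AUC calls all raise classed conditions.
Indices are 0-based half-open throughout; the 1-based ranges conventional
in print are a presentation difference only (`minwise_min()` keeps the
1-based presentation for the classic worked example).

## Problem sizes used in the checks

The shipped tests exercise the laws at $\ell$ up to 5000 permutations over
universes of a few hundred elements, classifier comparisons on the default
100 × 80 generator (8,000 pairs, $M = 2000$, $\ell = 10\lceil\log_2
M\rceil = 110$), and CV-scheme comparisons on a 60 × 40 panel over an
$M = 80$ universe across ten replicate seeds — sizes chosen so the whole
suite runs in a couple of minutes on one core while keeping the binomial
test bands (3 standard errors) tight enough to be informative.

## Known limitations

* Blockwise CV discards straddling pairs, so its training sets are ~64% of
  the data at 5 folds; its AUCs are not directly comparable to pairwise
  ones in absolute terms (the tests compare orderings, not levels).
* The `universal` permutation mode is a 2-universal approximation; its
  collision statistics are close to but not exactly the permutation law,
  and hash values may exceed $M - 1$ (they live modulo a prime
  $p_M \ge M$).
* Weight recovery is an unbiased-in-$\ell$ estimator of sketch-averaged
  weights, not of the direct-model weights; correlation with direct
  training improves with $\ell$ but bin collisions blur small effects.
* $b$-bit truncation of minhash values, weighted sketches, and LSH-based
  candidate retrieval are out of scope; only the one-hot additional-hash
  construction is implemented.
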