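---
title: "Predicting protein-protein interactions from domain coevolution with a conditional random field"
author: "domcrf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting protein-protein interactions from domain coevolution with a conditional random field}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The modeling problem

Most proteins are built from conserved sequence modules — domains — and
physical interaction between two proteins is usually mediated by a
specific pair of domains.  `domcrf` predicts whether two proteins
interact from three ingredients:

1. the domain composition of each protein,
2. a set of protein pairs with binary interaction labels, and
3. one multiple sequence alignment per domain family, with each row
   tagged by the organism it comes from.

The generative backbone is the classical noisy-OR domain interaction
model: each unordered domain pair $(m, n)$ interacts with probability
$\lambda_{mn}$, independently of all others, and proteins $P_i, P_j$
interact iff at least one domain pair contained in them interacts,

$$\Pr(P_{ij} = 1) \;=\; 1 - \prod_{(m,n) \in P_{ij}} (1 - \lambda_{mn}).$$

The package's central estimator replaces this generative model with a
discriminatively trained conditional random field (CRF) whose latent
variables are the domain-pair interaction indicators and whose
conditioning data are per-domain-pair *coevolution scores* computed from
the alignments.  The association and expectation-maximization (EM)
estimators of $\lambda_{mn}$ are included as baselines, and a
cross-validation harness scores all of them by ROC/AUC.

## Coevolution as mutual information between alignment columns

Residues at an interaction interface co-substitute: a mutation on one
side selects for compensatory mutations on the other.  Statistically
this appears as mutual information (MI) between a column of one domain's
alignment and a column of its partner's.

Because the two alignments index rows independently, rows must first be
paired: rows sharing an organism tag are matched greedily in file order,
up to the smaller per-organism count; unmatched rows are dropped and
contribute to no frequency (`pair_rows()`).  With $M$ paired rows,
column frequencies $f_i(A)$ and joint frequencies $f_{ij}(A, B)$ are
counted over the 21-symbol alphabet (20 amino acids plus the gap, which
is deliberately treated as a 21st residue so that gap covariation is
counted like any other), and

$$MI_{ij} = \sum_{A,B} f_{ij}(A,B)\,
   \ln \frac{f_{ij}(A,B)}{f_i(A) f_j(B)} .$$

Natural logarithms are used throughout; every MI quantity and every
threshold in the package is in nats.

**Pseudocounts.**  MI requires strictly positive frequencies.  The
package uses the count-based convention of the coevolution literature:
$\eta$ pseudo-observations spread uniformly over the alphabet,

$$\tilde f = \frac{\mathrm{count} + \eta/q}{M + \eta}, \qquad
  q = 21 \text{ (marginals)},\; q = 441 \text{ (joints)},$$

with $\eta = 1$ by default (one pseudo-observation).  Every table sums
to one, every entry is positive, and — crucially — the regularization
fades as $1/M$, so deep alignments retain the full MI scale; this is
what makes an 0.8-nat threshold on domain scores meaningful.  The
alternative frequency-mixture convention, $(f + \eta/q)/(1+\eta)$, was
rejected because at $\eta = 1$ it blends every table 50% toward
uniform regardless of depth, capping the score of even a perfectly
coupled uniform column pair near 0.93 nats and pushing realistic
scores far below any fixed threshold near 0.8.  The chosen form also
has the exact property that the pseudocounted joint marginalizes to the
pseudocounted marginal (because $21 \cdot \eta/441 = \eta/21$), which
is what allows the fast entropy-decomposition implementation
($MI = H_i + H_j - H_{ij}$ with count-indexed lookup tables) in the
C++ core.  The form lives behind the two frequency functions so another
convention could be swapped in.

**Shuffle null.**  Even independent columns show positive sample MI,
more so for skewed marginals.  The null level is estimated by shuffling
the row pairing uniformly at random (marginals preserved, joint
structure destroyed), recomputing MI with identical pseudocounts, and
averaging over 400 repetitions — a Monte-Carlo estimate whose
correctness is checked in the tests against full enumeration of all
$M!$ pairings at small $M$.

**Gap masking.**  Columns whose gap fraction among the *paired* rows
exceeds 0.20 (strictly) are excluded; gap-heavy columns otherwise
dominate the maximum below.  The fraction is computed on the paired rows
because those are exactly the rows the frequencies count.

**The domain-pair score.**  The score of domains $D_m, D_n$ is

$$M_{mn} = \max_{i,j \ \mathrm{unmasked}} \big( MI_{ij} -
   \langle MI^{\mathrm{shuffle}}_{ij} \rangle \big),$$

the maximum of the *corrected* MI over column pairs — the correction is
applied per position before the max, and negative corrected values are
not clamped, so a fully uninformative pair can score slightly below
zero.  For a domain paired with itself the diagonal $i = j$ is excluded
(its MI is the column's entropy, not coevolution).  The computation is
made symmetric and order-independent by canonicalizing the domain order
and deriving the shuffle RNG stream from the global seed plus the sorted
pair of domain ids, so `compute_domain_mi(a, b)` is bit-identical to
`compute_domain_mi(b, a)` and a table of scores does not depend on the
order pairs are processed in.

If fewer than two rows can be paired, or every column is masked, the
score is reported as unavailable (`NA`) rather than zero, and the CRF
silently falls back to its MI-free feature for that pair.

## The conditional random field

For each labeled protein pair $P_{ij}$ and each contained domain pair
$(m,n)$ (one latent variable per domain *type* pair — repeated domains
do not multiply variables), the joint model is

$$\Pr(p, d \mid M) = \frac{1}{Z_{ij}} \exp \sum_{(m,n) \in P_{ij}}
   \lambda_{mn}\, g^{(mn)}(p, d_{mn}),$$

with the local feature table

| | $d = 0$ | $d = 1$ |
|---|---|---|
| $p = 0$ | $0$ | $-1$ |
| $p = 1$ | $0$ | $\sigma(M_{mn} - c)$ |

where $\sigma(x) = 1/(1+e^{-x})$ and $c$ (default 0.8, on the same nat
scale as $M_{mn}$) marks the MI level above which coevolution is taken
as evidence for interaction; values 0.6–1.0 behave similarly.  The $-1$
entry penalizes the configuration "domains interact while their proteins
do not", which the noisy-OR law forbids outright.  The MI-free variant
replaces the sigmoid by the constant $+1$ and is otherwise identical,
so the two variants differ only in how strongly a domain pair's latent
"on" state is rewarded when the proteins interact.

Because the exponent is additive over domain pairs, the sum over the
$2^K$ latent states factorizes exactly:

$$S_p = \prod_{(m,n)} \left( e^{\lambda_{mn} g(p,0)} +
        e^{\lambda_{mn} g(p,1)} \right), \qquad
  Z_{ij} = S_1 + S_0, \qquad \Pr(P_{ij} = 1 \mid M) = S_1 / Z_{ij},$$

all held in log space with `logaddexp`.  The conditional log-likelihood
$\ell(\lambda) = \sum_{ij} (\log S_{p_{ij}} - \log Z_{ij})$ and its
observed-minus-expected gradient are exact; both are verified in the
tests against brute-force enumeration over all $2^{K+1}$ joint states
and against central finite differences.

**Training.**  Weights start at $\lambda = 0$ (every prediction 1/2)
and are fitted by limited-memory BFGS (`stats::optim`, history 6,
projected-gradient tolerance $10^{-5}$, at most 500 iterations).  The
weights are left unconstrained: the noisy-OR reparameterization
$\lambda = \log(1 - \Pr(D_{mn}=1))$ would suggest $\lambda \le 0$, but
the CRF is a strictly more general model and imposing the sign would
forfeit that generality.  A caveat recorded honestly: with the latent
state summed inside the numerator, $\ell$ is a difference of
convex terms, so global concavity is not guaranteed by the usual
log-sum-exp argument; the tests probe this empirically by checking that
training from multiple starting points reaches the same objective on
small instances.  An optional $l_1$ penalty (off by default) is
available for experimentation with sparsity.

**Prediction.**  Test pairs are scored by $S_1/Z_{ij}$.  Domain pairs
never seen in training contribute neutral $\lambda = 0$ factors — a
zero weight makes both latent states equally likely regardless of the
feature value, so no MI lookup is needed for them.  Separately, the
evaluation protocol excludes test pairs *none* of whose domain pairs
received a trained parameter.

## Baselines

* **Association**: $\lambda_{mn} = I_{mn} / N_{mn}$, the interacting
  fraction among labeled protein pairs containing $(m,n)$.
* **APM** (association probabilistic method) generalizes the numerator
  to a sum of fractional interaction strengths $\rho_{ij}$; with binary
  labels it reduces to the association method exactly, a property the
  tests assert with a literal APM implementation.
* **EM**: maximum likelihood under the noisy-OR observation model with
  false-negative rate $fn$ (default 0.8 — interaction screens miss most
  true interactions) via
  $\lambda^{(t+1)}_{mn} = N_{mn}^{-1} \sum_{ij \ni mn}
  \Pr(D_{mn}=1 \mid O_{ij}=o_{ij}, \lambda^{(t)})$, initialized from
  the association solution.  The observation model also needs a
  false-positive rate; it is not part of the published recursion's
  constants, so the package defaults to $fp = 10^{-4}$ (the order used
  in the original EM work): with $fp = 0$ an observed interaction whose
  domain pairs all carry $\lambda = 0$ would have probability zero and
  the posterior would be undefined.

## Evaluation protocol

Negatives are drawn uniformly without replacement from the unordered
protein pairs not in the positive set, as many as there are positives.
Cross-validation uses a stratified random 5-fold split derived from the
run seed (the split protocol only says "five datasets"; stratification
is this package's choice, and one fixed partition is used per run
seed).  Within each fold, every method is fitted on the training folds
and scored on both the training pairs and the held-out pairs, keeping
only held-out pairs that contain at least one domain pair present in
that fold's training data.  AUC is the Mann-Whitney rank statistic with
midrank ties (equivalent to trapezoidal integration of the swept ROC
curve, asserted to $10^{-10}$ in the tests); a filtered test fold with a
single class yields an undefined AUC, reported as missing and excluded
from the average with a warning rather than imputed at 0.5.

## The synthetic benchmark generator

Real inputs of this kind (curated interaction databases, domain
assignments, family alignments) are large external downloads, so the
package ships a generator that reproduces the *statistical structure*
the estimator relies on at desk scale:

* 200 proteins over 60 domain families, each protein carrying 1–3
  distinct domains;
* 5 designated "truly interacting" domain pairs, drawn among pairs
  occurring in at least 50 protein pairs (so the signal is represented
  in every training fold), each with interaction probability
  $\lambda^* = 0.8$;
* labels from the noisy-OR law with observation noise $fn^* = 0.1$,
  $fp^* = 0$, subsampled to 150 positive + 150 negative pairs;
* alignments of depth 100 (one sequence per organism, 100 organisms —
  shallow for a real family but deep enough for a stable 441-cell joint
  table), 20 columns per domain, background columns i.i.d. from
  per-column Dirichlet(0.5) residue profiles, 5% independent gaps;
* for each designated pair, exactly one coevolving column pair drawn
  from the mixture $\varepsilon\,\mathrm{uniform}^2 + (1-\varepsilon)\,
  \mathrm{identity\ coupling}$ over 20 symbols, with $\varepsilon$
  solved so the joint MI equals the 1.5-nat target.  Confining the
  signal to one column pair mirrors the max-over-positions definition
  of $M_{mn}$ and keeps the expected score analytically approachable.
  An optional confound knob plants equally coevolving but
  non-interacting pairs.

Everything is a deterministic function of the configuration seed; the
tests assert byte-identical reruns.

What the generator deliberately does **not** emulate: phylogeny
(organisms are i.i.d., so there is no shared-ancestry inflation of MI
and no need for the APC-style corrections real alignments invite),
realistic domain lengths, indel structure, or correlated gap patterns.
Passing the recovery tests therefore shows that the estimator chain —
pairing, pseudocounts, null correction, CRF training, evaluation — is
implemented correctly and can extract a planted coevolution/interaction
signal; it does not certify performance on real proteome-scale data.

A further honest observation from this design: at the default
conditions the labels are a nearly noiseless function of five domain
pairs, so the discriminative CRF sits close to its performance ceiling
with or without the MI feature.  In the shipped five-seed recovery
study the two CRF variants land within a few thousandths of an AUC
point of each other, with the sign of the difference flipping between
seeds, and a control run that replaces the measured scores with an
oracle MI (designated pairs far above $c$, background far below) moves
the with-MI variant ahead by well under 0.001 — confirming that the MI
feature is wired correctly but has no headroom to demonstrate its value
here.  The decisive, stable gap at these conditions is between the CRF
variants and the generative baselines (about 0.2 AUC held out).  On
sparse, noisy real data — where labels alone cannot pin down the domain
pair responsible — the MI conditioning is the component expected to
carry the advantage, and the corresponding recovery assertion is kept
strict rather than weakened to fit this ceiling-limited regime.

## Numerical choices and degenerate inputs

* All likelihoods in log space; `logaddexp` via the max-shift identity.
* Tiny negative MI from float cancellation is clamped to zero; corrected
  (null-subtracted) values are *not* clamped.
* Ambiguous residue codes (B, J, O, U, X, Z) and anything outside the
  alphabet map to the gap with a warning; Stockholm `.` and lowercase
  are normalized first.  This keeps the alphabet at exactly 21 symbols.
* RNG streams are derived from one user seed by hashing a task label
  (e.g. the sorted domain-pair id), so results are independent of
  processing order and safely below R's 32-bit seed limit.
* $M < 2$ paired rows, all-masked columns, or a self pair with a single
  column (only the excluded diagonal) produce an explicit
  "MI unavailable" result, not a zero.
* EM posteriors are guarded against zero denominators; probabilities
  escaping $[0,1]$ by more than rounding noise raise a warning and are
  clamped.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run the full pipeline at the
default generator conditions above (300 labeled pairs, ~800 distinct
domain pairs, alignment depth 100), the recovery study over five seeds,
and the oracle checks (enumeration, finite differences, permutation
enumeration) at small sizes ($K \le 12$, $M \le 5$) where brute force
is exact.  These sizes were chosen so the whole suite runs in minutes
on a single core while keeping every check at full fidelity.

## Limitations

* MI is a pairwise signal; indirect (chained) coevolution is not
  disentangled — direct-coupling style inference is out of scope.
* One latent variable per domain-type pair means repeated domains in a
  protein contribute once, matching the factor-graph picture but
  discarding copy-number information.
* The shuffle null corrects marginal-composition bias but not
  phylogenetic correlation, which the synthetic data does not contain.
* Association/EM training AUCs near 1 reflect memorization of sparse
  domain-pair statistics; as the published analyses of this model family
  note, such training performance indicates overfitting, which is why
  all comparisons rest on held-out AUC.
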