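# domcrf

Domain-based prediction of protein–protein interactions (PPI) with a
conditional random field conditioned on coevolutionary mutual
information.

## What it does, and for whom

Physical interaction between proteins is usually mediated by a specific
pair of domains, and residues at a domain–domain interface coevolve:
substitutions on one side select for compensatory substitutions on the
other.  `domcrf` is for computational biologists who have (a) protein
domain compositions, (b) a set of labeled interacting / non-interacting
protein pairs, and (c) per-domain multiple sequence alignments with
organism-tagged rows, and who want calibrated interaction probabilities
for new protein pairs.

Three estimator families are provided on a common evaluation harness:

* **CRF (with / without MI)** — the package's core.  Protein-pair labels
  $p_{ij}$ and latent domain-pair interaction indicators $d_{mn}$ form a
  bipartite factor graph; the local feature rewards the configuration
  "proteins interact, domain pair on" by $\sigma(M_{mn} - c)$ (or a
  constant $+1$ in the MI-free variant) and penalizes "domain pair on,
  proteins don't" by $-1$.  The latent sum factorizes exactly, so the
  likelihood, its gradient, and the predictive probability
  $\Pr(p_{ij}=1\mid M) = S_1/Z_{ij}$ are all closed-form; training is
  limited-memory BFGS.
* **Association** — $\lambda_{mn} = I_{mn}/N_{mn}$, the interacting
  fraction among protein pairs containing $(m,n)$ (equal to the APM
  estimator on binary labels).
* **EM** — maximum likelihood for the noisy-OR model
  $\Pr(p_{ij}=1) = 1-\prod_{(m,n)\in P_{ij}}(1-\lambda_{mn})$ with a
  false-negative observation rate (default 0.8).

The coevolution score of a domain pair is

$$M_{mn} = \max_{i,j}\big(MI_{ij} - \langle MI^{\mathrm{shuffle}}_{ij}\rangle\big),$$

the maximum over non-gappy alignment column pairs of the mutual
information between organism-paired columns, minus its 400-shuffle
permutation null, with count-based pseudocounts (η = 1) over the
21-symbol alphabet (20 amino acids + gap).  All logs are natural; all
MI quantities are in nats.

A seeded synthetic-data generator emulates the whole input stack
(multi-organism alignments with planted coevolving column pairs,
noisy-OR interaction networks), so everything is testable without
external databases.  See the vignette
(`vignettes/domain-crf-ppi.Rmd`) for the full model description and
design rationale.

## Worked example

```r
library(domcrf)

cfg <- synthetic_config(n_domains = 12, n_proteins = 50, n_organisms = 40,
                        n_cols = 10, n_true_pairs = 2, n_positive = 40,
                        n_negative = 40, min_pair_occurrence = 10, seed = 42)
ds <- generate_dataset(cfg)
ds$truth$true_dps
#> [1] "DOM002|DOM010" "DOM012|DOM012"

fg <- build_factor_graph(ds$proteins, ds$labels)
fg
#> factor_graph: 80 labeled protein pairs (40 positive), 64 domain pairs, 246 edges

mi_tab <- domain_mi_table(ds$alignments, dp_split(fg$dp_ids), seed = 42)
head(mi_tab[order(-mi_tab$m_mn), ], 4)
#>    domain_a domain_b      m_mn n_positions_used  M      seed
#> 64   DOM012   DOM012 0.4946445               90 40 750240935
#> 19   DOM002   DOM010 0.4159384              100 40 410211351
#> 54   DOM008   DOM010 0.2932837              100 40 129655198
#> 48   DOM007   DOM007 0.2674079               90 40 534328474

mi <- mi_scores_from_table(mi_tab)
run <- cross_validate(ds$proteins, ds$labels, mi, folds = 5, seed = 42)
run$summary
#>     method train_auc  test_auc n_folds_defined
#> 1   crf_mi 0.9994141 0.9307292               5
#> 2 crf_nomi 0.9994141 0.9291667               5
#> 3       em 0.9807617 0.9000000               5
#> 4    assoc 0.9761719 0.8729167               5
```

Reading the output: the two planted coevolving domain pairs head the
MI ranking (`m_mn` ≈ 0.49 and 0.42 nats above their shuffle nulls,
versus ≤ 0.29 for background pairs), and five-fold cross-validation
ranks the methods in the expected order — the MI-conditioned CRF first,
the MI-free CRF close behind, then EM and association.  Training AUCs
near 1 are expected here: the generative baselines effectively memorize
sparse domain-pair statistics, which is why model comparison uses the
held-out columns.

The same pipeline is scriptable from a shell via the bundled CLI
wrapper:

```sh
DOMCRF=$(Rscript -e 'cat(system.file("cli/domcrf.R", package = "domcrf"))')
Rscript $DOMCRF simulate --config inst/extdata/demo/config.json --out demo_data --seed 7
Rscript $DOMCRF mi --alignments demo_data \
    --compositions demo_data/compositions.tsv \
    --interactions demo_data/interactions.tsv -o demo_mi.tsv --seed 7
Rscript $DOMCRF train --variant mi --mi demo_mi.tsv \
    --compositions demo_data/compositions.tsv \
    --interactions demo_data/interactions.tsv -o demo_model.tsv
Rscript $DOMCRF evaluate --methods crf-mi,crf,em,assoc \
    --compositions demo_data/compositions.tsv \
    --interactions demo_data/interactions.tsv \
    --mi demo_mi.tsv -o demo_eval.tsv --seed 7
```

Subcommands: `simulate`, `mi`, `mi-hist`, `train`, `predict`,
`baseline`, `evaluate`; every knob (η, c, shuffle count, gap threshold,
fn, fp, folds, seed) is a flag with the package default.

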