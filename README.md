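# adjevol

Probabilistic reconstruction of ancestral gene orders from extant gene
adjacencies and reconciled gene phylogenies.

## The problem

Gene order evolves: rearrangements create and break *adjacencies* (unordered
pairs of consecutive genes), while gene duplications and losses change the
gene content those adjacencies connect. Parsimony tools reconstruct ancestral
adjacencies by minimizing changes, but give no measure of support and
underestimate change on long branches. `adjevol` instead treats each
adjacency as a two-state (absent/present) character evolving along a
structure derived from *reconciled gene trees* — gene trees whose nodes are
annotated with the species they belong to and the event (speciation,
duplication, loss) at each bifurcation — and computes, for every possible
ancestral adjacency, a posterior probability of presence.

The pipeline:

1. extant gene orders are decomposed into adjacencies;
2. adjacencies are clustered into homology classes, each reducing to a pair
   of gene subtrees rooted at the most ancient distinct common ancestors of
   the class's extremities;
3. each class is expanded into a *tree of possible adjacencies*: its nodes
   are all same-species pairs of gene-tree nodes, plus duplication nodes and
   loss leaves ("?" state);
4. a binary birth/death model is run on these trees by Felsenstein pruning;
   the forest likelihood is maximized over the model parameters and,
   optionally, the species-tree branch lengths;
5. an inside–outside pass yields posterior probabilities of presence for all
   ancestral adjacencies, summarized per ancestral species;
6. a Sankoff parsimony baseline is computed on the same trees and its
   reconstructions are scored by their model posteriors.

## The model

An adjacency is a binary character with gain rate `q01 = (kappa+1)/2` and
loss rate `q10 = (kappa+1)/(2 kappa)`, so that `kappa` is the gain/loss
ratio and one event per adjacency per unit branch length is expected at
stationarity. The transition probabilities are

    P01(t) = kappa (1 - exp(-lambda t)) / (kappa + 1),
    lambda = (kappa + 1)^2 / (2 kappa).

Duplications inside a branch have no date. When one gene of an adjacency
duplicates, the adjacency is transmitted to exactly one copy (whether the
duplication is tandem or remote); the other copy starts in state absent at a
date uniform on the branch, giving the date-averaged kernel
`N1(t) = (1/t) ∫ P(τ) dτ` for the duplication-born lineage. When both genes
duplicate on the same branch, the duplication node has four children; the
kernel is the uniform average over the ordered pair of duplication dates,
`N11(t) = (2/t²) ∫∫ P(u) ⊗ P(v) ⊗ P(v)`, combined with `P(t)` for the
inheriting lineage (a Kronecker product of parallel processes). Which child
inherits, which gene duplicated first, and where the first-born lineage is
transmitted at the second duplication are unknown, so the likelihood
averages uniformly over all 16 scenarios of this generative process. Loss
leaves carry an undetermined state and contribute a factor one. The model
supports at most one duplication per gene lineage between two speciations;
classes violating the restriction are reported and skipped.

## Worked example

Simulate a six-species dataset, fit the model and reconstruct ancestral
adjacencies (the YAML config ships with the package):

```r
library(adjevol)
cfg <- system.file("extdata", "pipeline6.yaml", package = "adjevol")
out <- tempfile()
run_pipeline(cfg, "simulate", outdir = out, seed = 5)
#> simulate: 30 classes, 10 observations dropped
run_pipeline(cfg, "fit", outdir = out, seed = 5)
#> fit: logLik -89.70169, kappa 0.3286193
run_pipeline(cfg, "ancestral", outdir = out, seed = 5)
#> ancestral: 58 ancestral adjacencies with posterior > 0.9
run_pipeline(cfg, "compare", outdir = out, seed = 5)
#> compare: 33 parsimony adjacencies; fraction > 0.9 = 0.8181818, fraction < 0.5 = 0
```

`fit.json` holds the maximum-likelihood `kappa` (gain/loss ratio), root
presence probability and log-likelihood; `posteriors.tsv` lists every
possible ancestral adjacency with its posterior probability of presence;
`summary.tsv` gives, per species, the gene count, the adjacencies above the
posterior threshold and the genes involved in more than two of them (the
conflict measure); `comparison.tsv`/`histogram.tsv` score the parsimony
reconstruction against the model posteriors. The same commands are available
from a shell via the installed `exec/adjevol` script.

Lower-level entry points (`parse_species_tree`, `parse_reconciled_gene_tree`,
`lca_reconcile`, `build_adjacency_classes`, `build_adjacency_forest`,
`forest_loglik`, `optimize_parameters`, `compute_posteriors`,
`parsimony_forest`, `simulate_dataset`, ...) expose each pipeline stage; see
the methods vignette (`vignettes/adjacency-evolution.Rmd`) for the model
details and design choices.

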