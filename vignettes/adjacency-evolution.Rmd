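---
title: "Modeling gene-adjacency evolution on reconciled phylogenies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling gene-adjacency evolution on reconciled phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adjevol)
```

## Scope and data

`adjevol` reconstructs ancestral gene adjacencies — unordered pairs of
consecutive genes — given three inputs: a rooted binary species tree with
branch lengths, reconciled gene trees (every node annotated with its species
and with the event at the bifurcation: speciation, duplication, or loss),
and extant gene orders per species and scaffold. Adjacencies are not
oriented. Branch lengths are in expected adjacency events per adjacency per
branch: the model's generator is normalized so that exactly one gain-or-loss
event per unit length is expected at stationarity, which makes fitted branch
lengths directly interpretable as rearrangement intensities. Gene-tree
branch lengths are deliberately ignored: the date of a duplication between
two speciations is treated as unknown rather than fixed from molecular
branch lengths, and is integrated out (below).

## From gene orders to trees of possible adjacencies

Extant adjacencies are clustered into homology classes: two adjacencies are
equivalent when, for some pairing of their extremities, each extremity pair
has a common gene-tree ancestor and the two ancestors live in the same
species. The package evaluates this condition over *all* ancestor pairs (not
only the LCAs): because species assignments are monotone along a gene tree,
the species of the common ancestors of two genes form a contiguous interval
of a species-tree ancestor chain, and the condition reduces to an interval
intersection. Classes are the transitive closure under union–find. Each
class gets a pair of root ancestors — the most ancient distinct common
ancestors of its extremities, i.e. the gene-tree roots when the two
extremities belong to different families — and reconstruction proceeds on
the two subtrees below them. Because the roots are the most ancient
ancestors, many possible ancestral adjacencies far predate any observed
adjacency; these legitimately receive low posterior support.

When both extremities of an adjacency lie in the same family (tandem
arrays), both extremity pairings are tested and the first satisfying pairing
fixes the member's orientation; a parity conflict around an odd cycle (two
valid but incompatible pairings) is resolved in favour of the earlier
assignment. This situation is rare and the choice only affects which of two
symmetric orientations labels the class.

The *tree of possible adjacencies* of a class has one node per same-species
pair of speciation/extant nodes under the class roots. A pair whose two gene
lineages descend one species step without duplication is connected by a
single edge carrying the species branch length; if either lineage
duplicates, a duplication node is interposed: it is attached to its parent
by a zero-duration bookkeeping edge (its state *is* the state at the parent
speciation) and spans the full species branch with the duplication kernels.
Loss of either gene on a branch produces a loss leaf with undetermined
state "?", which contributes a factor one to the likelihood — losing a gene
tells us nothing about whether a rearrangement also occurred. If the two
class roots live in different species, the maximal same-species pairs each
root an independent component; components are treated as probabilistically
independent (how they might be linked above their roots is not defined by
the model).

## The evolutionary model

Presence/absence of an adjacency follows a two-state Markov process with
gain rate $q_{01} = (\kappa+1)/2$ and loss rate $q_{10} =
(\kappa+1)/(2\kappa)$, so $\kappa$ is the gain/loss ratio, the stationary
distribution is $(1, \kappa)/(\kappa+1)$, and the stationary event flux is
one per unit length. With $\lambda = (\kappa+1)^2/(2\kappa)$,

$$P_{01}(t) = \frac{\kappa\,(1 - e^{-\lambda t})}{\kappa + 1}, \qquad
  P_{11}(t) = \frac{\kappa + e^{-\lambda t}}{\kappa + 1}.$$

**Duplications.** When one gene of an adjacency duplicates, the adjacency is
transmitted to exactly one of the two copies — true for tandem and remote
duplications alike — and the other copy starts absent. The duplication date
is uniform on the species branch, so the duplication-born lineage evolves
for a uniform residual time, giving the averaged kernel
$N^1(t) = \frac1t \int_0^t P(\tau)\,d\tau$ (only its source-absent row is
needed). With duplications in *both* gene trees on the same branch the node
has four children and the kernel integrates uniformly over the ordered pair
of dates:

$$N^{11}(t) = \frac{2}{t^2}\int_0^t P(u) \otimes \int_0^u P(v)\otimes
P(v)\,dv\,du,$$

used through the $(x,0,0,0)$ components of $P(t)\otimes N^{11}(t)$: the
inheriting lineage carries the state across the whole branch, the lineage
born at the first duplication evolves from absent for the first residual
time, and the two lineages born at the second duplication evolve from
absent for the second residual time.

**Scenario averaging.** Which child inherits is unknown; so is which gene
duplicated first; and so is where the first-born lineage is transmitted when
the second duplication splits it. Writing the generative process out, these
choices are three independent uniform draws, giving $4 \times 2 \times 2 =
16$ equally weighted scenarios mapping kernel slots to the four children. A
tempting simplification forces the first-born lineage to keep the same copy
of the second-duplicated gene as the inheriting child (8 scenarios), but it
is not the law of the stated process: the package's Gillespie simulator —
written independently of the likelihood code — rejects the 8-scenario
child-outcome distribution decisively (z ≈ 19 at $10^5$ replicates) while
matching the 16-scenario average within Monte-Carlo error. The 16-scenario
average is therefore the implemented semantics, in the bottom-up pass and in
the matching top-down pass. For a single duplication the same logic yields
the familiar two-assignment average.

At most one duplication is allowed per gene lineage between two
speciations; the combinatorics of nested same-branch duplications grow
quickly and such families are reported and skipped (the simulator likewise
rejects and resamples them, mirroring the filtering a practitioner would
apply to the input families).

**Closed forms and numerical safety.** $P$, $N^1$ and $N^{11}$ are evaluated
in closed form: every integrand is a linear combination of $\{1, u,
e^{-\lambda u}, u e^{-\lambda u}, e^{-2\lambda u}, e^{-3\lambda u}\}$ and is
integrated term by term, with `expm1` guarding the $1 - e^{-x}$ differences.
Below $\lambda t < 10^{-5}$ the $N^{11}$ closed form cancels
catastrophically (relative error grows like $\epsilon/\lambda t$) and a
first-order series in $t$ is used instead; the two branches agree with
adaptive quadrature to better than $10^{-8}$ on both sides of the switch.
The test suite cross-checks all kernels against matrix exponentials,
adaptive/nested quadrature, and the Gillespie oracle.

## Likelihood, optimization, posteriors

Each tree of possible adjacencies is pruned bottom-up: speciation nodes
multiply their children's contributions through $P(t)$; duplication nodes
average over scenarios as above; "?" leaves contribute 1. The root is closed
with a root presence probability $\rho$, a free parameter defaulting to the
stationary $\kappa/(\kappa+1)$ — keeping the root prior free is what makes
fitting "non-stationary" and, because the chain is reversible, it is also
what renders the two root-adjacent branch lengths separately identifiable.
Trees are independent, so the forest log-likelihood is the sum; identically
shaped trees (common in simulations and in dense duplication-free data) are
grouped by a structural hash and pruned in one vectorized pass. Per-node
rescaling guards against underflow.

Fitting maximizes the forest log-likelihood over any subset of $\{\kappa,
\rho, \text{branch lengths}\}$ by L-BFGS-B on log/logit-transformed
coordinates with bounds $\kappa \in [10^{-3}, 10^3]$, lengths $\in
[10^{-6}, 100]$, $\rho \in [10^{-6}, 1-10^{-6}]$. Branch-length
optimization can be restricted to duplication-free trees
(`dup_free_only`), trading information for speed on large datasets. A
top-down (inside–outside) pass, folding transitions and duplication
scenarios exactly as the upward pass does, gives per-node outside
likelihoods; posteriors are the normalized products. On 200 random trees
covering all node types, log-likelihoods and posteriors agree with
brute-force enumeration over all ancestral state assignments to $10^{-9}$
relative error (they agree to machine precision in practice). No
pattern-weight factorization over child-state multisets is needed: with at
most four children per duplication node, plain enumeration over the $2^n$
child-state vectors is already negligible work.

The per-species summary reports, for each ancestral species, the gene
count, the adjacencies above a posterior threshold (default 0.9), and the
genes carried by more than two such adjacencies — the degree-conflict
measure that quantifies how far the supported adjacency set is from a
linear gene order. Assembling the supported adjacencies into chromosomes is
out of scope by design: conflicts mostly trace back to gene-tree errors,
and a probability-annotated adjacency set keeps that signal visible instead
of hiding it in an arbitrary linearization.

## Parsimony baseline

For comparison, a Sankoff pass computes minimum-change ancestral states on
the same trees with unit gain/break costs; "?" leaves are free, and the
zero-duration attachment edge of a duplication node cannot change state.
Ties break toward absent at the root and then toward the parent's state (a
convention; the reference parsimony tool's tie-breaking is undocumented).
The comparison reports, over the ancestral adjacencies that parsimony
declares present, the fraction with posterior above 0.9 and below 0.5, plus
a posterior histogram of the parsimony subset against all possible
adjacencies. Under short branches essentially every parsimony
reconstruction is highly supported; under long branches a substantial
fraction drops below 0.5 — the probabilistic model integrates over all
histories where parsimony commits to one.

## The synthetic-data generator

The simulator produces data under exactly the model's assumptions: gene
families evolve along the species tree by a birth/death process
(duplication and loss rates per gene per unit branch length, exponential
waiting times), and each class's adjacency history follows the two-state
Gillespie process on the resulting tree of possible adjacencies, with
uniform duplication dates and uniform transmission — the same generative
process the kernels integrate, which is what lets the simulator serve as
the kernels' independent Monte-Carlo oracle. An observation-drop fraction
removes present extant adjacencies to emulate assembly fragmentation;
observed gene orders are threaded into per-species scaffolds (path
decomposition; the rare conflict edges from duplication-born parallel
adjacencies are dropped and counted).

Default conditions (chosen once, as plausible for a clade of a dozen
insect-scale genomes): branch lengths 0.06–0.41 events per adjacency on the
packaged 6- and 12-taxon trees, duplication rate 0.1 and loss rate 0.2 per
gene per unit length, $\kappa = 0.5$, root presence probability 0.9, drop
fraction 0.2. Classes are simulated independently with a fresh family pair
each; there is no genome-level rearrangement process (no inversions moving
several adjacencies jointly), no joint duplication of consecutive genes,
and no same-family (tandem) classes. Passing parameter-recovery tests
therefore validates the inference machinery under the model's own
assumptions — they say nothing about model misspecification on real
genomes, where adjacencies are not independent and assembly artifacts are
not uniform drops.

Problem sizes used by the validation runs: parameter recovery uses 2000
duplication-free, loss-free classes on the 12-taxon tree at $\kappa = 1.5$
and $\rho = 0.9$ (loss-free isolates branch-length information; simulating
at the default non-stationary $\rho$ keeps the root-adjacent branches
identifiable), recovering $\kappa$ within 10% and branch lengths with
Pearson $r > 0.95$ against truth; the deep internal branches are the least
identifiable and dominate the residual spread. The parsimony comparisons
use 300 classes with branch lengths scaled by 0.1 (short regime) and 8
(long regime). Kernel oracles use $10^5$ Gillespie replicates.

## Known limitations

* One duplication per gene lineage between speciations; violating classes
  are skipped, not modeled.
* No horizontal transfer, no joint duplications, no site-specific
  ("fragile region") rate variation — the rate is shared by all classes.
* Class components rooted in different species are treated as independent.
* Clustering is quadratic in the adjacencies per family pair (fine at
  genome scale, where classes are small).
* Posteriors are not assembled into linear chromosomes (see above).
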