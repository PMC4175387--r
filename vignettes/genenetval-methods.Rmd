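---
title: "Validating inferred gene networks against KEGG pathways: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating inferred gene networks against KEGG pathways: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genenetval)
```

## The problem

Gene-network inference algorithms produce graphs whose edges claim
functional relationships between genes. Judging whether such a graph
carries biological signal usually means comparing it with curated prior
knowledge, and KEGG metabolic pathways are the most widely used source.
The classical comparison has two weaknesses. First, pathways are not gene
networks: they mix gene, enzyme and compound nodes, so most approaches
keep only the direct gene–gene relations and discard everything the
compounds encode. Second, the comparison is binary — an inferred edge
either is a pathway edge or it is a failure — although two genes that sit
close together in a pathway are biologically far more plausible partners
than two genes in different corners of it, and the curated knowledge
itself is incomplete.

This package addresses both weaknesses: it converts the *whole* pathway,
compounds included, into a gene association network, and it scores input
edges by a graded, level-weighted matching distance instead of a binary
one.

## Pathway conversion

A KGML pathway is read into a typed model (gene/compound/group/map
entries, `PPrel`/`ECrel`/`GErel`/`PCrel`/compound–compound relations,
reactions with substrates and products). Conversion to a gene association
network proceeds by:

1. keeping every gene node (identifiers are canonicalized by stripping
   the `org:` prefix and uppercasing; a multi-gene entry becomes one node
   per name; group entries are expanded to their members);
2. turning every direct gene–gene relation into an undirected edge, with
   direction dropped;
3. removing every compound node and connecting, pairwise, all genes that
   were adjacent to it — via gene–compound relations, via a relation's
   mediating compound, or via reactions in which the compound is a
   substrate or product. A compound shared by *k* genes therefore yields
   a *k*-clique, and a compound produced by one enzyme and consumed by
   another connects the two enzymes;
4. merging compounds that are linked to each other into a single bridging
   component before step 3, so genes joined by a *chain* of compounds are
   also connected. The KGML exchange format has no dedicated
   compound–compound relation type, so the reader classifies any relation
   between two compound entries by its endpoints rather than by the type
   string; this keeps the rule applicable to real files.

`map` entries and `maplink` relations are links to other pathways, not
molecules, and are ignored. An `ECrel` relation that carries a mediating
compound still contributes its direct gene–gene edge — it is a gene
relationship first, and the mediating compound merely adds the genes to
that compound's neighborhood.

## The validity measure

Let \(G_I = \{N_I, E_I\}\) be the input network and \(G_P = \{N_P, E_P\}\)
the converted pathway. The **level** of a gene pair is the shortest-path
edge count between the two genes in \(G_P\): adjacent genes have level 1,
genes joined through one intermediate have level 2. Every input edge is
assigned the level of its endpoints; with a level cap \(n\),

\[
H_n = \sum_{l=1}^{n} \frac{\mathrm{Hit}_l}{l}, \qquad
F_n = \lVert E_I\rVert - H_n, \qquad
V_n = \frac{H_n}{\lVert E_I\rVert} \in [0, 1],
\]

where \(\mathrm{Hit}_l\) counts input edges at level exactly \(l\). Each
edge counts at a single level — its shortest distance — which is what
keeps \(F_n\) non-negative and \(V_n\) in \([0,1]\). Edges whose endpoints
are absent from the gold standard, or disconnected in it, or farther than
\(n\), contribute only to \(\lVert E_I\rVert\): they are failures at every
level. The default cap is \(n = 2\); level 1 alone reduces to edge
matching on the converted network, and in our ROC benchmarks (below)
level 2 separates real from null networks at least as well as any other
setting, while levels 3–4 dilute the weighting with increasingly tenuous
relationships.

**Pruning.** For per-pathway evaluation the input network is first
restricted to edges whose *both* endpoints are genes of the pathway:
for edges touching genes the pathway knows nothing about, there is no
information to classify them as right or wrong, so counting them as
failures would conflate "wrong" with "unknown". When a pruned network has
no edges left the validity is *undefined* and reported as `NA` rather
than 0 — such pathways rank last in functional assignment instead of
polluting the ranking with spurious zeros. Whole-network scoring against
a user-supplied gold standard can disable pruning (`do_prune = FALSE`),
in which case out-of-universe edges count as failures.

**Classical baseline.** `classical_precision()` scores the same input
against the relation-only graph (direct gene–gene relations, no compound
bridging): matched edges over evaluated edges after the same pruning.
Because both scorers prune against the pathway's full gene-entry set and
the converted gold standard's level-1 edge set is a superset of the
relation-only edge set, \(V_1\) is never below the classical precision —
a property the test suite checks on random fixtures.

## Evaluation machinery

**ROC study.** One real network and a sample of null networks are each
scored against a panel of pathway networks; every (network, pathway) pair
is one evaluation, positive if the network is the real one. For each
threshold \(T\) in a grid of 101 values (0 to 1, step 0.01) an evaluation
is predicted positive iff its validity *strictly exceeds* \(T\) (a score
equal to the threshold is negative), yielding 101 confusion matrices and
a TPR/FPR curve. The AUC is the trapezoidal area over the observed
points sorted by ascending FPR, with **no** anchor points appended: real
pathway panels contain small pathways that random networks can match at
some level, so the empirical curve need not start at (0,0) or reach
(0,0)/(1,1), and forcing anchors would invent performance the data does
not show. One consequence is worth documenting: if *every* negative
evaluation scores exactly zero, all points share FPR = 0 and the
trapezoid over that degenerate point set has zero width, so the reported
AUC is 0 rather than 1. The perfect-separation tests therefore use null
networks with small positive validity (all real evaluations still outrank
all null evaluations), which is also the regime real data occupies. An
independent AUC implementation (pROC) reproduces the trapezoid to 1e-9
when the threshold grid cuts at the observed scores.

**Null models.** `pure_random` draws exactly the template's edge count as
a uniform sample of distinct gene pairs over the template's genes.
`scale_free` grows a preferential-attachment graph over the same genes,
with the per-step attachment count chosen so the expected edge count is
closest to the template's; the edge count therefore matches only
approximately, which is the price of keeping the degree distribution
heavy-tailed. The sample size of 385 null networks per condition comes
from the standard proportion formula
\(\lceil z^2 p(1-p)/m^2\rceil\) at 95% confidence, 5% margin, \(p=0.5\)
(`sample_size()`); desk-scale runs in the tests use smaller samples, with
the sizes stated where they are used.

**Noise study.** At iteration \(k = 1..10\), each replicate removes
`round(k * 0.10 * ||E||)` uniformly chosen edges of the *original*
network and adds the same number of uniformly drawn non-edges over the
same gene set, then scores the perturbed network. Perturbation is applied
fresh from the original at every iteration, not cumulatively — "10% of
the original relationships" pins the denominator to the original edge
count, and the fresh reading makes iterations independent and the
noise fraction exact. Added edges are drawn from the non-edges of the
current graph so the result stays simple. A measure that degrades
progressively under this protocol is detecting the loss of information;
the test suite checks the downward trend rather than any particular
value, since the asymptote (the validity of a fully random network)
depends on the gold standard's density.

**Global network and functional assignment.** `build_kgn()` unions the
converted networks of all pathways of an organism into one global gold
standard; `functional_assignment()` prunes and scores the input against
each pathway separately and ranks pathways by descending \(V_n\)
(undefined last; ties broken by larger evaluated edge count, then label),
so the top pathway names the biological process the input network most
plausibly describes. Related processes sharing gene relationships — cell
cycle and meiosis being the canonical pair — surface together with high
validity, which is informative rather than an error.

## The synthetic fixture generator

KEGG data cannot be shipped, so `make_pathway()` generates KGML fixtures
realizing every conversion motif: direct gene–gene relations at a chosen
density, gene–compound–gene bridges, multi-gene compounds (3-gene
cliques), two-compound chains, producer/consumer transfer reactions, a
multi-gene entry and group entries. Alongside the pathway it returns the
expected converted network, assembled *constructively while the motifs
are placed* — independent of `convert_pathway()` — so every generated
pathway is a conversion oracle. Each compound participates in exactly one
motif, which keeps that constructive expectation exact.

Defaults model a sparse, mid-sized metabolic pathway: 30 genes, 8
compounds, relation density 0.05 (≈22 direct relations), 2 transfer
reactions, 1 group. Typical KEGG metabolic maps carry tens of genes and
are far sparser than their complete graph, and a sparse gold standard is
what makes the level structure meaningful — in a dense pathway nearly
every pair sits within level 2 and all measures saturate.
`make_benchmark()` builds the study bundle: a panel of such pathways, a
"real" network keeping 80% of the pooled gold-standard edges plus 10%
random extra edges, and matched null networks; seeds and parameters land
in a JSON manifest. What the generator does **not** emulate: the size
distribution of real pathway collections, annotation errors and
identifier drift, the modular/hub structure of real interactomes, or
biased (non-uniform) inference errors. Green tests therefore certify the
machinery and the measure's contracted properties, not performance on any
real organism's data.

## Numerical and degenerate-input choices

* Shortest paths are unweighted BFS distances (igraph); unreachable or
  absent pairs give `NA` levels, never infinities in results.
* `level(a, a)` is an argument error rather than 0 — a self-relationship
  has no meaning in a simple graph, and the containers drop self-loops on
  construction (with a warning when reading files).
* A pathway with no gene entries converts to an empty network, not an
  error; an empty pruned network gives `NA` validity, not 0.
* Edge sets are canonicalized (unordered pair stored once, lexicographic
  order), so equality checks and unions are set operations.
* All stochastic operations (`random_network()`, `noise_study()`,
  `make_pathway()`, `make_benchmark()`) take an explicit integer seed and
  are reproducible from it; seeds are isolated from the caller's RNG
  state via `withr::with_seed()`.
* In the noise study, `round(k * 0.10 * ||E||)` can be 0 on tiny
  networks (the iteration is then a no-op) and is capped at `||E||`
  (full replacement).

## Problem sizes used in the shipped checks

The test suite runs entirely on generated data: property sweeps use
1,000 random 7-node score fixtures, an exhaustive sweep of all labeled
graphs on up to 6 nodes (32,768 six-node graphs) against an
adjacency-power oracle, 100 random pathway fixtures for the conversion
oracle, 50-replicate noise profiles, and 50 real/null benchmark pairs
(three 30-gene pathways each) for the AUC comparison between the
level-2 measure and the classical baseline. These sizes give stable
Monte-Carlo estimates for trend and ordering assertions while keeping
the suite quick to run.

## Known limitations

* Enzyme entries carrying EC numbers rather than gene identifiers are
  treated as gene entries named by whatever the KGML `name` attribute
  holds; no EC-to-gene mapping is attempted.
* `maplink` relations are ignored; genes are never connected across
  pathway boundaries except through `build_kgn()`.
* The converted gold standard is unweighted; edge types do not influence
  the score.
* Scoring is undirected throughout; a directed input network is read as
  its underlying undirected graph.
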