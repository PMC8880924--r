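---
title: "Models and methods behind dinoResolve"
author: "dinoResolve authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dinoResolve}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dinoResolve)
```

# The scientific question

Dinoflagellate species — *Gambierdiscus* and its ciguatoxin-producing
relatives prominent among them — are routinely delimited from single-locus
ribosomal DNA phylogenies: the SSU, the ITS/5.8S, or the 5' divergent
domains of the LSU (D1-D2 / D1-D3 / D1-D6, treated here as one region,
`LSU5prime`). Whether such single-locus clades delimit species as reliably
as multigene phylogenies is an empirical question with two halves:

1. a *pipeline* half — curating single-copy orthologs out of transcriptome
   assemblies, building a concatenated multigene phylogeny, and asking
   whether each gene's signal is congruent with the concatenated tree; and
2. a *survey* half — classifying, species by species, whether published
   rDNA phylogenies resolve described species, and summarizing the result.

dinoResolve implements both halves as tested, seed-reproducible code, plus
synthetic-data generators that make every stage verifiable without any
external download: the generators plant known orthologs, paralogs, noise
contigs, rDNA allele arrays and survey outcomes, and every recovery claim
in the test suite is checked against that planted truth.

# The tree engine

All model-based steps run on one internal engine so that distances,
likelihoods, branch-length optimization and simulation share identical
semantics.

**Substitution model.** General time-reversible (GTR):
$Q_{ij} = s_{ij}\pi_j$ for $i \ne j$, with exchangeabilities
$s = (s_{AC}, s_{AG}, s_{AT}, s_{CG}, s_{CT}, s_{GT})$ and stationary
frequencies $\pi$. $Q$ is rescaled so that $-\sum_i \pi_i Q_{ii} = 1$;
branch lengths are expected substitutions per site. Transition matrices
come from the eigendecomposition of the symmetrized matrix
$\Pi^{1/2} Q \Pi^{-1/2}$.

**Rate variation.** Discrete Gamma with $k$ equal-weight categories at the
quantile midpoints $r_c \propto F^{-1}\!\big(\tfrac{2c-1}{2k}\big)$ of a
Gamma(shape $\alpha$, mean 1) distribution, renormalized to mean exactly 1.
The default is $k = 4$, the conventional GTR+Gamma setting. Site
likelihoods average over categories.

**Likelihood.** Felsenstein's pruning algorithm over compressed site
patterns, with per-node rescaling, implemented as a small C++ kernel. Gaps
and ambiguous residues enter as partial-likelihood vectors of ones
(missing data). The kernel is validated in the test suite against explicit
enumeration over all ancestral state assignments (agreement to $10^{-10}$
on hundreds of random instances) and against an independent
implementation.

**Distances.** Pairwise comparisons use only columns where both sequences
are unambiguous. Available corrections: raw $p$; Jukes–Cantor
$d = -\tfrac34\ln(1-\tfrac{4p}{3})$; Kimura's protein correction
$d = -\ln(1 - p - 0.2p^2)$, the standard closed-form surrogate for
Dayhoff/JTT maximum-likelihood distances (the elimination rules that
consume these distances only need rank consistency, which the surrogate
preserves at the relevant divergences); and a GTR maximum-likelihood
distance that optimizes the two-sequence likelihood over the divergence
time. Distances at or past a model's singularity are capped at 5.0
substitutions/site and flagged as saturated, keeping downstream means
finite while marking the cell unreliable.

**Tree building.** Neighbor joining (via `ape::nj`, negative branch
lengths clamped to zero) followed by coordinate-wise branch-length
optimization (golden-section search per edge, cycled until the
log-likelihood improves by less than `tol`, default $10^{-4}$; the
log-likelihood never decreases). This NJ + optimization pair is the
engine's stand-in for a full maximum-likelihood topology search: every
downstream consumer uses only the (topology, branch lengths, supports)
triple, and the acceptance checks are oracle- and property-based, so the
search strategy itself is not load-bearing. Nonparametric bootstrap
supports are percentages of column-resampled NJ replicates containing each
bipartition of the point-estimate tree, stored as internal node labels so
they survive Newick round trips.

**Simulation.** Root states are drawn from $\pi$; states evolve along each
branch by $\exp(Qt)$; under Gamma rate variation each site keeps one rate
category across the whole tree, as sequence simulators conventionally do.

# Ortholog curation

The screening and curation pipeline mirrors how single-copy orthologs are
pulled from transcriptome assemblies against a reference gene panel:

1. **Reciprocal best hits.** Contigs are scored against the panel by
   Smith–Waterman local alignment with affine gaps (raw scores, not
   bitscores — only ranking matters downstream). An exact-word prefilter
   (word size 11, at least 2 shared words) restricts scoring to plausibly
   homologous pairs, as seeded search tools do; it can be disabled. A
   (gene, taxon, contig) hit survives only if the contig's best gene is
   that gene and the contig ranks within the top `max_hits` for the gene
   in that taxon; scores below `score_floor` (default 50, which chance
   30-mer matches cannot reach under the default 2/−3/−5/−2 scoring) are
   dropped.
2. **Hit-count rule.** A gene is selected when every represented taxon
   contributes between 1 and 4 hits and enough taxa are represented
   (coverage floor 0.8). The hit window is counted per taxon, not summed
   across taxa: the downstream paralog analysis inspects all top hits from
   all taxa, which implies per-taxon multiplicity.
3. **Member anchoring.** Contigs carry flanking untranslated sequence, so
   each member is projected onto its reference gene's coordinates via the
   local alignment before any column-based comparison. The pipeline
   consumes alignments; it does not construct multiple alignments de novo.
4. **Mean-distance rule.** A member whose mean distance to the others
   exceeds `distance_factor` (default 2) times the grand mean of all
   off-diagonal distances is eliminated — once, not iterated, since
   iteration could cascade a family to empty. The rule's wording admits a
   second reading (a leave-one-out mean); it is available as
   `mean_basis = "leaveout"` but not the default.
5. **Duplicate resolution and identity gap.** Within-taxon duplicates that
   form an exclusive clade resolve to the longest sequence (ties by id).
   A member whose mean percent identity sits at least `identity_gap`
   (default 20) percentage points below the next-lowest average is
   eliminated; the source description of this rule is garbled, and the
   ≥20-point-gap reading used here is deliberately conservative.
   No automatic "conspicuously long branch" criterion is applied — the
   diameter and outlier rules already police long branches, and any
   numeric threshold would be invented.
6. **Paralog groups.** The maximal clades of the unrooted gene tree (both
   sides of every edge considered) containing at most one member per taxon
   partition the family; the most taxon-complete group wins, ties broken
   by the lowest mean within-group distance. If no group covers at least
   80% of the ingroup taxa ("all or nearly all" made operational), the
   gene is dropped.
7. **Tree QC.** Genes are rejected when the gene-tree diameter (maximal
   patristic leaf-leaf distance) exceeds 1 substitution/site, and/or when
   the ingroup and outgroup are not reciprocally monophyletic (no edge of
   the unrooted tree separates them exactly).

`runCuration()` chains these stages, logs every member elimination with
its rule and numeric evidence, reports the monotone stage counters
(candidates → hit rule → group selection → tree QC), and emits the
supermatrix (missing taxa gap-filled per gene block, gaps treated as
missing data), a 1-based partition table, and the final bootstrapped tree.
Per-gene QC trees are NJ trees on JC distances by default (GTR-ML
available); the final tree uses 500-replicate-style bootstrapping scaled
to the problem (the default benchmark uses fewer replicates purely because
supports there are consumed as structure, not as published values).

# Congruence testing

For each gene, the parametric bootstrap asks whether the gene's own signal
is consistent with the concatenated-analysis topology:

1. the concatenated topology's branch lengths are re-fit on the gene
   alignment;
2. `n_reps` (100 by default) replicate alignments of the gene's length are
   simulated on that fitted tree under GTR;
3. each replicate is analyzed exactly like the observed gene — tree
   inferred (NJ) and branch lengths optimized — and its log-likelihood
   recorded;
4. the observed gene's own-tree log-likelihood and its
   concatenated-topology log-likelihood are placed on the replicate
   distribution as percentiles; a gene whose own-tree percentile leaves
   the central 98% interval (two-sided level 0.02, an explicit number in
   place of histogram inspection) is flagged discordant.

Two design points deserve emphasis. First, the replicates are simulated on
the *concatenated* topology with gene-specific re-fitted branch lengths
(the gene-tree alternative is available via `refit_topology` and the
`gene_tree` argument). Second, the replicate statistic deliberately
mirrors the observed statistic — both are "inferred-tree" likelihoods. If
replicates were instead re-fit on the fixed simulating topology while the
observed value used the gene's own inferred tree, the observed statistic
would be stochastically larger than the replicates even under perfect
congruence, and the percentile would be mis-calibrated. With the
symmetric construction the test is calibrated (genes truly simulated on
the concatenated topology are flagged at about the nominal rate) and
powerful against a conflicting topology with a long internal branch; both
properties are measured, not assumed, in the acceptance tests. Shared GTR
parameters are used across replicates; per-replicate model re-estimation
is out of scope.

# Species delimitation and the survey

**The five-way classifier.** For each species $S$ on a phylogeny (rooted
on a declared outgroup, otherwise near the midpoint of the longest
leaf-to-leaf path), let $C$ be the smallest clade containing all $S$
leaves:

* **Y** — $C$ is exclusively $S$, $|S| \ge 2$, and $C$'s support clears
  the threshold (default 80, the conventional cutoff below which branches
  are drawn as unsupported; applied only when supports exist);
* **YP** — $S$ is a singleton whose leaf lies inside no other species'
  minimal clade (the "distinct branch" notion made operational as a
  containment test — the underlying idea has no quantitative published
  criterion);
* **YA** — all foreign leaves inside $C$ are flagged as suspected
  misidentifications;
* **NA** — foreign leaves inside $C$ carry evidence-of-distinctness flags;
* **N** — otherwise.

YA and NA require explicit leaf flags because in the survey they derive
from reading original species descriptions, not from topology.

**Compound calls and categories.** Calls from multiple phylogenies join
as "/"-separated compounds in the fixed order Y, YP, YA, N, NA. The
three-category mapping is closed-world: N, NA, N/NA, N/YA and Y/N are
*not resolved*; YA, Y/YA and YP/YA are *ambiguous*; Y and YP are
*resolved*; anything else is an error rather than a guess.
`summarizeSurvey()` restricts to described species and reports counts and
half-up one-decimal percentages per region. One arithmetic note: from the
published count triple (34, 8, 591) the SSU not-resolved percentage is
34/633 = 5.37%, which rounds to 5.4 under any standard rule although the
source table prints 5.3; the implementation follows arithmetic. The
resolved-column percentages (93.4 / 97.2 / 93.6) agree with the printed
table exactly, which also confirms that ambiguous entries sit in the
denominators. `regionAgreement()` compares two regions over entries
(species *and* ribotypes) present in both, with ambiguous siding with
resolved by default.

**The decision tree.** `recommendDescriptionCase()` encodes the five-case
scheme for weighting morphology against rDNA when describing a species:
concordant-and-divergent (1a/1b), morphologically distinct but rDNA
identical (2), rDNA distinct but morphology overlapping or
indistinguishable (3a/3b), outright conflict (4), and no evidence of
separation (5). The enumeration is total.

# What the synthetic generators emulate

**Species trees.** Ultrametric ingroup plus outgroup clade, every
root-to-tip path equal to `depth` (default 0.15 substitutions/site, the
scale of congeneric dinoflagellate rDNA divergence). By default the split
depths are respaced evenly between crown and present: raw coalescent
depths concentrate splits at the present and produce sister "species"
that are molecularly indistinguishable, which is not the situation of
described species the survey concerns. The raw coalescent spacing is kept
(`spacing = "coalescent"`) precisely to generate that failure mode on
demand.

**Gene families and libraries.** Duplications copy whole clades (a root
duplication yields two clades that each mirror the species tree — the
signature the partition rule must detect); duplicate copies evolve twice
as fast, reflecting relaxed constraint on redundant copies, which also
makes the original copy the tighter group. The default benchmark plants,
across 60 genes and 7 + 3 taxa: 70% clean single-copy orthologs, 20%
root-duplication paralog families, and 10% genes evolved on a tree whose
outgroup was scrambled into the ingroup (which tree QC must reject);
plus, per taxon, 5 noise contigs from a first-order Markov chain fitted
to the ortholog base composition — a harder negative control than uniform
random sequence. Gene length is 300 nt with random 20–60 nt flanks. These
sizes make the full pipeline run in about a minute and are stated here as
the package's chosen benchmark scale. The generators emit gap-free
homologous cores (no indel process), so anchored members align exactly;
real transcriptome data additionally contain indels, chimeras and
assembly artifacts that this benchmark deliberately does not model —
passing it shows the *rules* are implemented correctly, not that any
particular real dataset would survive them.

**rDNA arrays under concerted evolution.** Each species lineage carries
`n_alleles` copies evolving independently along the species tree.
Concerted evolution is modelled as recurrent conversion rounds in which
each functional copy is replaced by the lineage consensus with
probability `h` per round. Because gene conversion operates continuously
over the generations a lineage spans, rounds recur: before each
speciation in the parent array, after it in each daughter array, at two
interior points of every branch, and at sampling. A copy therefore
escapes its species' history only by missing every round since the
species originated — with `h = 0.9` that is a once-in-thousands event —
while `h = 0` switches homogenization off entirely and lets copies
coalesce far above the species level (the recently-diverged-species
failure mode, where rDNA genuinely cannot resolve species). Pseudogenes
escape conversion permanently with probability `pseudoProb` per copy and
thereafter evolve at `rho` times the base rate. Escapes are drawn on the
younger half of the terminal branch: a pseudogene as old as its species
accumulates indels and decay that would keep it from being recovered and
identified as that locus at all, and its patristic margin to the species
cluster shrinks to zero, so sampled, recognizable pseudogene copies are
young ones. The upshot matches what is seen in real arrays: pseudogenes
form divergent within-species subclusters but remain species-specific.
This is an event-based caricature of continuous gene conversion — it
reproduces the qualitative regimes (full homogenization, realistic
pseudogene-bearing arrays, deep-coalescence breakdown) and is not a
quantitative population-genetic model.

**Survey fixtures.** Per (species, region), a category is drawn from the
configured probabilities and a compound call is sampled from that
category's closed list, so the mapping recovers the drawn category by
construction; a fraction of entries exist in only some regions, and a
fraction of rows are undescribed ribotypes. `syntheticSurveyArchive()`
builds a wholly synthetic archive whose aggregate tallies (described
species, dual-region instances, discordances concentrated in one genus)
are supplied as arguments — useful for exercising the agreement
statistics against known totals; it transcribes nothing from any real
survey.

# Numerical choices and degenerate inputs

* Saturated distances: capped at 5.0 and flagged; zero shared columns
  between a pair is an error naming the pair.
* NJ: negative intermediate branch lengths clamped to 0; the two-taxon
  "tree" is the single edge split evenly across a root node.
* Branch-length search: bounded to $[10^{-9}, 10]$ substitutions/site per
  edge; convergence when a full cycle improves the log-likelihood by less
  than `tol`; the accepted value never decreases the likelihood.
* Families with fewer than 3 members skip the distance-based filters with
  a warning rather than an error, so small genes degrade gracefully.
* Filter ties: equal-length duplicates resolve to the lexicographically
  first id; equal paralog groups resolve by size then lexicographic
  order — all pipelines are deterministic given their seed.
* Alignment columns are 0-based internally and 1-based in all reports and
  partition files.

# Problem sizes

The shipped tests and the acceptance script run, by design, at desk
scale: likelihood oracles on trees of 3–5 taxa and 2–4 sites (where exact
enumeration is feasible), the curation benchmark at 60 genes x 10 taxa x
300 nt, delimitation over 20 seeded replicates of 6 + 1 species with 4
alleles of 800 nt, and congruence calibration over 100 + 100 seeded
trials of 5-taxon, 300-nt genes with 100 replicates each. These sizes are
the package's chosen benchmark conditions; all of them scale up by
argument.

# Known limitations

* No protein likelihood: protein support is limited to corrected
  distances (the screening accepts pre-translated input).
* No multiple-alignment construction and no indel simulation; members are
  anchored to reference coordinates by pairwise local alignment.
* NJ + branch-length optimization stands in for full ML topology search;
  bootstrap supports are NJ supports.
* The concerted-evolution model is event-based, not a population-genetic
  conversion model, and pseudogene decay/loss is encoded only through the
  young-escape rule.
* The five-way classifier reproduces the survey's *rules*; judgment calls
  that the original survey made from reading species descriptions enter
  only through explicit leaf flags.
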