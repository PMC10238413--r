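---
title: "MSY haplotype trees: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MSY haplotype trees: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msytree)
```

# The model

The male-specific region of the Y chromosome (MSY) is strictly
paternally inherited and does not recombine: a sample of males is
related by a single rooted genealogy, and every polymorphism arose once
on one branch of it, barring recurrent mutation. Over the ~5 Mb of
single-copy Y sequence that is reliably callable, per-site mutation
rates of order 10⁻⁹ per year make recurrent hits at a site vanishingly
rare, so binary variants polarized against an outgroup (for horses, the
donkey) satisfy the infinite-sites model almost perfectly. This licenses
two simplifications that shape the whole package:

1. **The haplotype tree is a perfect phylogeny.** Each variant's derived
   state defines a clade; the clades form a laminar family; the tree can
   be read off the variants directly, with each variant sitting on
   exactly one branch as that branch's diagnostic *identifier*. No
   heuristic tree search is needed, and branch "lengths" are integer
   mutation counts.
2. **Rare conflicts are homoplasy, not signal.** A variant whose derived
   set is incompatible (four-gamete test) with the rest is excluded from
   topology and placed afterwards by exact small parsimony on the fixed
   tree, recorded in a ledger with its extra-step count.

# Tree construction

Variants are processed by descending derived count (ties broken by
coordinate). Compatibility is checked pairwise on observed data: a pair
fails when the joint patterns (1,0), (0,1) and (1,1) all occur; a greedy
pass in processing order accepts each variant unless it conflicts with
an already-accepted one. Accepted variants are grouped by their observed
derived-sample set and the groups are attached root-to-tip by
containment. Samples with identical placements collapse to one tip
haplotype; multifurcations are preserved, never arbitrarily resolved.

**Missing data.** Two rules keep missingness from distorting topology:

* *Routing.* A sample missing a call at a splitting variant is routed by
  its non-missing identifiers: at each node the walk descends into the
  child subtree holding the majority of the sample's observed derived
  calls, refuses branches where the sample is observed ancestral, and
  stops at the deepest certain node (flagging the sample) when evidence
  conflicts or ties.
* *Single-origin merging.* When a group's observed derived set is a
  subset of an existing branch's set and the branch's extra members are
  all unobserved at the group's variants, the two are observationally
  indistinguishable; the group is merged onto the branch rather than
  fabricating a nested branch out of missingness. Without this rule,
  every masked call at a multi-identifier branch would split off a
  spurious sub-branch and poison downstream imputation.

Both rules are exact no-ops on complete data: there the construction
recovers the generating tree and every identifier's true branch, which
is the package's headline acceptance property (100 seeded simulations,
exact equality required).

**Determinism.** Child ordering in exports is canonical (descending
subtree sample count, then smallest member sample id, then label), so
Newick output and branch tables are byte-stable across runs and
invariant to input row/column permutations.

# Homoplasy placement

`place_homoplasic()` scores a binary character on the fixed tree by
dynamic programming over the two states (cost of a subtree given the
parent state), with the root constrained to the ancestral state, then
backtraces preferring the parent's state so mutations are pushed tipward
deterministically. The score is verified exhaustively against brute
force — every internal-state assignment enumerated — for all rooted
multifurcating tree shapes with up to 8 tips crossed with all 2⁸ tip
characters. Scores depend only on (shape, character), so this sweep
covers every labelled tree of that size.

# Tree-guided imputation

A missing cell (sample *s*, variant *v* on branch *b*) is imputed:

* **1** when *b* lies on *s*'s root path **and** *s* shows at least one
  observed derived call on *b* itself or deeper on its path
  (corroboration);
* **0** when *s* is observed ancestral at another identifier of *b*, or
  carries an observed derived call on a branch disjoint from *b*;
* **0** when *v* has no observed derived call at all (it sits on no
  branch; the parsimonious state is ancestral), provided *s*'s placement
  rests on at least one observed derived call;
* otherwise the cell stays missing and is counted unresolved.

Variants are processed rootward-to-tipward so deeper certainty
propagates first. Observed cells are never altered; a second pass
imputes nothing (idempotence); and because imputed states follow the
tree, imputation cannot create four-gamete conflicts that were absent
before.

The corroboration threshold (≥ 1 supporting identifier) was chosen over
unconditional path imputation to protect against mis-placed low-coverage
samples. Note an information-theoretic floor: under random masking, a
variant whose *every* carrier is masked cannot be recovered by any
method. At realistic cohort sizes (the generator's default of 170
samples) this floor is a few cells in several thousand and the
mask-and-recover acceptance bar (≥ 99% at 5% masking) is met; in very
small cohorts (tens of samples) with many singleton variants the floor
alone can exceed 1%, which is a property of the data, not the rule.

# Marker-panel assignment

A diagnostic panel maps each marker to one branch of a known haplogroup
tree. Assignment walks the branch tree from the root following derived
calls and stops at the deepest derived branch. The label is that
branch's name when it is a panel leaf (a major haplogroup, mjHG), or the
branch name with `*` when genotyped markers below are all ancestral (an
inner-node placement). A derived call below an observed-ancestral
ancestor is reported `inconsistent` with the conflicting pair named —
never silently dropped. A missing marker on the path does *not* truncate
the walk when a deeper marker is derived: assay dropout is treated as
unobserved rather than ancestral (the alternative would misclassify
every dropout as an inner-node sample); such assignments are flagged
`path-gap`. Nested extension panels (`refine_panel()`) re-assign only
the samples carrying the targeted label, so refinement is monotone:
added markers can only move a sample to a descendant label.

# Ancient placement

Ancient samples arrive as pseudo-haploid calls at identifier positions.
Two thresholds, both configurable, define the procedure:

* **Eligibility**: coverage of at least `min_fraction` (default 0.5) of
  the identifier panel, assessed on the full panel before any
  branch-informative restriction — with the standard 96-site backbone
  panel, exactly 48 sites qualifies and 47 does not.
* **Branch passing**: at least `min_derived_fraction` (default 0.5) of
  the branch's *genotyped* identifiers derived and zero ancestral. The
  fraction is taken over genotyped sites, not the full identifier set:
  at ~50-60% coverage the full-set reading would leave most eligible
  samples unassignable. An `error_tolerance` parameter (ancestral calls
  tolerated on a passing branch) exists for sensitivity analysis and is
  0 by default — a single ancestral call blocks a branch.

The traversal is tree-aware: starting at the root, only the child
branches of the node reached so far are examined, the walk descends into
the passing child, and a child showing both derived and ancestral states
(with no passing sibling) ends the walk at that branch's own internal
node. These internal nodes, labelled from a Greek-letter pool in
root-to-tip order, represent lineages that diverged mid-branch and are
seen only in ancient samples. A flat scan over all branches regardless
of position was rejected: under a nonzero error rate it would assign
samples of one root lineage to internal nodes of the *sibling* lineage
(a single erroneous derived call among the many genotyped sites of a
long sibling branch suffices), which contradicts the clean clustering
the rule is meant to reproduce. For error-free calls the two readings
agree.

Samples landing in the basal multifurcating clade are refined over its
child mjHG identifier sets with the same counting rule
(`refine_da1()`); when nothing passes they stay basal, flagged
`uninformative` if no child identifier was covered at all.

One consequence of the zero-tolerance rule worth knowing: at a 1%
per-call error rate, a sample whose path crosses a branch with ~30
genotyped identifiers has a ~25% chance of one erroneous ancestral call
there, and then stops at that branch's internal node rather than
descending to its true clade. The acceptance harness therefore scores an
internal placement on the sample's true root path as correct; exact
clade recovery is required only at error rate 0.

# Diversity and dating

* Watterson's θ per site: S/(aL), a = Σ_{i=1}^{n−1} 1/i. The surveyed
  length defaults to L = 5,063,000 bp (the single-copy Y target) and is
  configurable, including to per-group callable lengths.
* Mean pairwise differences: mean over all n(n−1)/2 pairs of differing
  sites, pairwise-complete over missingness (target-enriched and
  whole-genome samples have very different missingness profiles, so
  complete-case comparison would discard most pairs). The dispersion is
  the sample standard deviation over pairs (a variance option exists);
  published tables rarely state which dispersion they print, so the
  choice is recorded in the output.
* Node ages: t = k/(μL) for k mutations, default clock
  μ = 1.69 × 10⁻⁹ /site/year; the 95% interval is the exact Poisson
  interval on k divided by μL. For k = 0 this gives [0, 3.689/(μL)].

# The simulator

`sim_config()` states one world and the tests never tune it after
looking at outcomes:

* clock μ = 1.69 × 10⁻⁹ /site/year, L = 5,063,000 bp;
* a backbone with the field's dated nodes: basal domestic
  multifurcation *da1* at 4,000 years BP, Crown at 1,500 BP, the *d*
  split (db vs da1) at 4,500 BP just above the ~4,200 BP domestication
  horizon. Ages the literature does not pin down were fixed once: the
  root (p/d) split at 9,500 BP — deep enough that the *p* and *d* stems
  carry many identifiers, as observed panels do — and clade TMRCAs of
  2,500-3,000 BP. Within-clade genealogies are Kingman-style coalescent
  subtrees rescaled to the clade TMRCA;
* mutations are Poisson per branch (μ·L·years) at distinct sites
  (infinite sites), so simulated matrices are four-gamete clean by
  construction;
* modern matrices: 170 samples by default, allocated ~70% to the Crown,
  i.i.d. missingness (default 2%); one optional STR evolving by
  stepwise ±1 drift, used only as a terminal haplotype splitter;
* ancient samples: per-sample callability Beta(2,2) rescaled to
  [0.2, 1] (mean 60%, emulating very uneven coverage), per-call error
  1% (symmetric by default; a derived-only mode mimics
  deamination-driven false derived calls), true placements drawn over
  clades and mid-branch positions, with identifier positions spaced
  evenly along branches so a mid-branch lineage has a well-defined
  derived prefix. `msy_backbone_panel()` reproduces the structure of
  the practical 96-identifier backbone (18/47/22/9).

What a green simulation establishes — and what it does not. The
generator produces exactly the statistical structure the methods assume:
single-origin binary characters on one genealogy, independent
missingness, independent call errors. Real data violate these in known
ways the simulator does not model: reference and mapping artefacts
concentrate missingness and errors at specific sites rather than
i.i.d.; ascertainment of panel markers biases frequency spectra;
deamination errors are strand- and context-dependent; and the single
STR mutates recurrently. Green tests therefore establish correctness of
the *rules*, not robustness to every artefact of a sequencing pipeline.

# Numerical choices and degenerate inputs

* Ties everywhere are broken deterministically (coordinate order for
  variants, lexicographic sample ids, subtree size then minimum sample
  id for child ordering), so all outputs are byte-reproducible.
* `ceiling()` is used for both the eligibility count and the
  branch-passing count, matching "at least half".
* A matrix with zero polarized variants is an error; all-identical
  samples build a single-node tree (not an error); an all-missing
  ancient sample is unassignable, never an exception.
* Heterozygous diploid-encoded calls on the haploid Y become missing
  (they indicate mapping artefacts), with a warning, rather than
  discarding the sample.
* Indels are binary presence/absence characters pooled with SNPs; the
  STR is excluded from topology (stepwise mutation violates the binary
  single-origin model) and appended only to haplotype strings.

# Known limitations

* The filter thresholds (site missingness ≤ 0.2, sample missingness
  ≤ 0.3) are package defaults standing in for study-specific pipelines;
  they are logged on every run and must be overridden to reproduce any
  particular published call set.
* The haplogroup suffix grammar and the Greek-letter pool are
  deterministic stand-ins for published nomenclature, which encodes
  history (variant name prefixes, breed mnemonics) that cannot be
  derived from genotypes alone.
* Homoplasic variants are reported and placed but their missing cells
  are not imputed.
* The perfect-phylogeny construction assumes polarization is correct;
  a mis-polarized variant appears as homoplasy rather than being
  re-oriented.
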