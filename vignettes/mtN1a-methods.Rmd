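---
title: "Methods: motif-based N1a classification, median networks and rho dating"
author: "mtN1a"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motif-based N1a classification, median networks and rho dating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtN1a)
```

## The analysis this package implements

Human mitochondrial DNA is non-recombining and maternally inherited, so
its variation forms a single genealogy whose named branches (haplogroups)
are defined by diagnostic mutations. This package implements the analysis
chain used in phylogeographic studies of haplogroup N1a: published
haplotypes are available almost exclusively as control-region
*motifs* — hyphen-separated lists of positions that differ from the
revised Cambridge reference sequence (rCRS), HVS-I positions written
minus 16000 (so `147A` means np 16147, derived base A). The chain is:

1. parse and emit motif nomenclature, and variant-call complete
   mitogenomes against the reference (`parseMotif`, `formatMotif`,
   `callVariants`);
2. assign each haplotype to the finest N1a subclade by motif matching
   and near-matching against a nested clade-definition tree
   (`loadCladeTree`, `assignClade`, `classifyTable`);
3. reconstruct the phylogeny of complete sequences as a reduced median
   network and extract a most-parsimonious rooted mutation tree
   (`encodeBinary`, `reducedMedianNetwork`, `extractTree`);
4. date subclades with the rho statistic and Saillard standard errors
   under several molecular-clock calibrations (`rhoStatistic`,
   `sigmaSaillard`, `estimateAges`);
5. summarise geographic structure: per-region subclade frequencies and
   the haplotype-heterogeneity chi-square (`cladeFrequencyReport`,
   `buildContingencyTable`, `chiSquareHeterogeneity`).

A ground-truth simulator (`simulationConfig`, `simulateGenealogy`,
`emitSequences`, `emitMotifTable`) makes every stage testable without
any external download.

## Reference, coordinates and exclusions

All coordinates are rCRS coordinates. Because this package is built and
tested fully offline, the shipped reference FASTA
(`inst/extdata/rcrs_synthetic.fa`) is a *synthetic* 16,569-nt stand-in
generated deterministically by `syntheticReferenceSequence()`: the
coordinate system, windows and gene map are the real ones, only the base
sequence is synthetic (with a few bases pinned so that the explicit-base
tokens of the packaged survey, e.g. `147G`/`147A`, are transversions as
in the real genome). Every computation is coordinate- or self-consistent
codon-based, so replacing the FASTA with the real rCRS changes nothing
structurally.

Window defaults: HVS-I 16024–16569, HVS-II 1–576, coding region
577–16023. The control-region windows deliberately span the whole
control region rather than the narrower classical sequencing windows,
because published motif tables contain tokens such as `463` (np 16463)
and HVS-II `41` that would otherwise be unparseable. Both windows are
constructor arguments of `rCRSAnnotation()`.

Exclusion policy (three distinct rules, applied where they are
scientifically meaningful rather than globally):

* np 16519 is never scored by variant calling, encoding or simulation;
* insertions/deletions inside the poly(C) tracts (16180–16195, 303–315)
  are never scored — tract *length* is unreliable, but substitutions at
  tract positions such as 16183 or 16189 are ordinary, phylogenetically
  diagnostic markers and are kept (16189 defines a subclade);
* `parseMotif`/`formatMotif` are exactly literal, so the packaged survey
  round-trips byte-for-byte; exclusions belong to scoring, not parsing.

## The clade tree and the near-matching classifier

The shipped tree (`inst/extdata/clade_tree_n1a.yaml`) encodes the N1a
subclade phylogeny: the basal control motif
16147G-16172-16223-16248-16355 and coding 2702 for N1a; 16147A plus
coding 3336 for N1a1; 16320 for N1a1a; the purely coding 8164, 9300 and
the back mutation @2702 for N1a1a1; 16189 plus coding 6641 for N1a1a1a;
16086 with a reverted 16172 and the HVS-II motif 152-199-204-207 for
N1a1a2; 16154 for N1a1a3; and N1a1b as the N1a1 branch lacking 16320
(an anti-diagnostic).

Each clade's accumulated root-to-clade profile is scored against a
record's typed segments. The scoring is a simple additive evidence
model, chosen a priori from the structure of published N1a surveys:

* a diagnostic observed with the expected derived state scores `+w`;
* observed at the position with a different derived state, `+w/2`
  (recurrent mutations at 16147 switch between G and A within N1a);
* missing, or explicitly reverted with `@`, scores `-min(w, 1)`;
* a satisfied back-mutation diagnostic scores `+w` (its absence *is*
  the evidence), a violated one `-min(w, 1)`;
* a present anti-diagnostic scores `-min(w, 1)`; private mutations are
  not penalised (real surveys carry up to four of them per record).

Weights default to 1. The shipped tree upweights the highly specific
16086 and HVS-II 207 (weight 2), downweights the hypervariable 16189
(0.5), the soft loss of 16172 on the N1a1a2 stem (0.5), and the
widespread HVS-II 152/199/204 background (0.25). The penalty cap at 1
makes a high-weight diagnostic strong evidence when present without
making its absence worse than any other single missing mutation — an
asymmetry analogous to a log-likelihood ratio with unequal error rates.

*Admissibility.* In `near` mode a clade stays admissible while no single
clade level has more than `near_tolerance` (default 1) fully missing
diagnostics; in `strict` mode the whole visible profile must match
perfectly. Diagnostics in untyped segments (coding for HVS-only survey
rows; HVS-II where the table leaves it blank) are skipped entirely, not
counted as missing.

*Tie-breaks.* A score tie between a clade and its ancestor resolves to
the deeper clade: HVS-only records cannot display N1a1a1's purely coding
diagnostics, and surveys label such records with the finest compatible
subclade. Ties between unrelated clades resolve to their most recent
common ancestor with status `ambiguous`. Two consequences are worth
naming: with HVS-only data N1a1a is indistinguishable from N1a1a1, and
N1a1 from N1a1b; the classifier deterministically reports the deeper
member, which is also how the published tables are labelled. The test
suite treats these pairs as equivalence classes.

## Reduced median networks and tree extraction

Haplotypes are recoded as a 0/1 matrix over segregating binary
characters keyed by (position, derived state) — a triallelic position
such as 16147 (C→G and C→A) simply yields two characters sharing the
position tag. Constant characters are removed (and reported), duplicate
rows collapse with multiplicities summed.

`reducedMedianNetwork()` then follows the classical reduced-median
scheme for binary data:

1. *Reduction.* For each pair of incompatible characters (all four
   gametes present, weighted by multiplicity), if one character's
   carrier frequency exceeds `r` times the other's (default `r = 2`,
   the conventional default of the algorithm's reference
   implementation), the conflict is resolved in favour of the stronger
   character: the weaker one is treated as recurrent and split into two
   characters, one per background.
2. *Median closure.* Remaining conflicts are closed under
   majority-consensus vectors of node triples until no new vector
   arises (with a safety cap, default 512 nodes, that warns if hit).
3. *Linking.* Two vectors are joined when no third vector lies
   geodesically between them; multi-mutation links are subdivided by
   inferred intermediates with sites in ascending position order, so
   every edge carries exactly one character and the network is
   bit-reproducible.

`extractTree()` selects the minimum-weight subtree of the network
connecting all observed haplotypes plus the outgroup attachment. The
outgroup state defaults to the all-reference vector; if it matches no
node uniquely, the candidates are listed and an explicit `root=` is
required. For up to 12 required nodes the Steiner minimum is found
exactly by Dreyfus–Wagner dynamic programming over the network graph
(the network provably contains the most-parsimonious trees, and the
test suite checks the score against an exhaustive/ratchet search with
phangorn); beyond that a shortest-path MST heuristic is used — exact
whenever the data are homoplasy-free, in which case the network is
already the unique perfect phylogeny. Manually resolved homoplasies are
expressed as forced edges: the forced edge is inserted and the cycle it
creates is broken at its heaviest other edge, so the score can only
stay or grow. All orderings (sites ascending, node ids lexicographic)
are deterministic.

## Rho dating

With the root the inferred ancestral haplotype, the rho statistic is the
multiplicity-weighted mean number of (class-filtered) mutations on
root-to-tip paths; identical sampled haplotypes count once per
individual. Its standard error follows the Saillard estimator

$$\sigma^2 \;=\; \sum_{\text{edges } e}\Big(\tfrac{n_e}{n}\Big)^2\, m_e,$$

where $n_e$ is the number of sampled mtDNAs below edge $e$ and $m_e$ the
class-filtered mutation count on it. Ages are $\rho \times$ rate and
$\sigma \times$ rate; values are kept unrounded internally and rounded
to the nearest year only in written reports.

Two clocks are supported: *all coding-region base substitutions*
(any substitution within 577–16023; indels never count) and *synonymous
transitions only* (transitions leaving the amino acid unchanged in
**every** overlapping protein-coding frame, translated under the
vertebrate mitochondrial code; minus-strand ND6 is handled via the
reverse complement; substitutions in trailing partial codons are never
called synonymous). The all-frames rule for overlapping genes
(ATP8/ATP6, ND4L/ND4) is a deliberate conservative choice.

The shipped calibration table carries six entries (two coding, four
synonymous, one label shared between classes) whose years-per-mutation
values were back-derived by the package authors from published subclade
age tables with integer-valued rho, and match widely used published
clocks (coding ≈5140 y and ≈4610 y per substitution; synonymous ≈6764,
≈7650, ≈7884 and ≈7990 y per transition). They are defaults to be
confirmed against the cited rate papers, and `readCalibrations()`
accepts any replacement table.

## Heterogeneity and frequency tables

Haplotype identity in contingency tables is the canonically formatted
HVS-I motif (`motifKey`); HVS-II is ignored by default because survey
rows are typed inconsistently for it. Columns are sampling-origin
labels after an explicit, user-visible grouping map. The shipped
default map pools the three Kazakh-origin labels (`Kazakhstan`,
`Kazakhs`, `Kazakh-South Siberia`) into one group — they sample the
same population under different names — which yields a 10 × 10 table
(d.f. 81) for the N1a1a1a test; the test always reports its d.f. so any
other grouping is transparent. The chi-square is Pearson's without
continuity correction, with the p value from the upper tail; expected
counts below 5 (the normal case for sparse haplotype tables) produce a
warning, never a refusal, and the test suite checks the analytic p
against a Monte-Carlo null in the well-behaved regime.

## The simulator: what it emulates and what it does not

`simulateGenealogy()` draws a star, Yule or user-supplied topology with
branch lengths in years (depths rescaled to `tmrcaYears`) and plants
Poisson(length/rate) mutations per class on every edge, uniformly over
each class's legal site set. The three classes are disjoint by
construction: synonymous transitions live on the exactly enumerated
synonymous site set, `coding_substitution` on the remaining coding
sites, `control` on the control-region windows minus exclusions. The
"all coding substitutions" clock therefore counts both coding classes,
at the implied harmonic rate returned by `impliedYearsPerMutation()`.
Defaults mirror the shipped study conditions: 19 tips, TMRCA 23,541
years, rates (21,408; 6,764; 20,180) years per mutation so that the
implied all-coding rate is ≈5,140 y and the synonymous rate ≈6,764 y.

Positions are sampled *without replacement across the whole genealogy*,
so simulated data are homoplasy-free unless `backMutations` is
requested; this matches the assumption behind manual homoplasy
resolution in network analyses, and homoplastic instances for the
network tests are constructed explicitly instead. The simulator does
**not** emulate rate heterogeneity across sites, hypervariable hotspot
recurrence, sequencing error, heteroplasmy or ancient-DNA damage —
passing tests therefore demonstrate correctness of the estimators under
the clock model, not robustness to those real-data features.

`emitMotifTable()` writes survey-style records carrying a clade's full
control-region diagnostic profile plus at most `maxPrivate` (default 2)
Poisson(0.5) private control mutations drawn away from every diagnostic
position, with origins drawn from the configured regional probabilities.

## Numerical choices and problem sizes

* Variant calling uses a banded global aligner (band adapted to the
  length difference; unit edit costs; deterministic tie-breaks), with a
  fast positional-diff path for equal-length, sparsely different pairs.
  Indels are normalised to the 3' end of homopolymer runs, the standard
  mtDNA nomenclature convention.
* The test suite sizes are chosen to keep a full run in a few minutes:
  1,000 seeded apply-then-call round-trip cases; 1,000 star replicates
  for the rho ± 2σ coverage property (n = 19, where the exact Poisson
  coverage of the interval is 95.3%, comfortably above the 93%
  criterion — at n = 8 it would only be 93.8%, which is why the
  end-to-end pipeline check also runs at the study size n = 19, 400
  replicates); 500 emitted records per clade for classifier recovery;
  exhaustive parsimony oracles up to 8 taxa and a ratchet search at
  9–10.
* `set.seed` is applied inside every simulation entry point, so equal
  seeds give byte-identical outputs.

## Known limitations

* The classifier's weights are calibrated for the N1a tree shipped
  here; a different haplogroup's config may want different weights
  (they are ordinary config entries).
* The reduced-median closure is capped (default 512 nodes); extremely
  conflicted matrices warn and return a partial network.
* `readNewickTree()` restores multiplicity 1 per sampled node; trees
  with collapsed duplicate haplotypes should be rebuilt from data
  rather than re-read from Newick when multiplicities matter.
* Ages inherit every caveat of the fixed-rate clocks; no
  time-dependent or purifying-selection correction is applied beyond
  choosing among the shipped calibrations.
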