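---
title: "Karyotype characters on a phylogeny: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Karyotype characters on a phylogeny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyevo)
```

This vignette is the package's own account of its methods: the
morphometric model, the character-coding rules, the parsimony algorithm,
the synthetic-data model behind the validation experiments, and the design
choices made where the underlying study left the design open.

## Karyotype morphometrics

A karyotype is an ordered list of homologous chromosome pairs, ranked by
size (pair 1 = largest). Each pair carries a short arm p and long arm q
(p ≤ q by definition), and is summarized by the centromeric index
CI = p/(p + q), a dimensionless quantity in [0, 0.5]: 0.5 means a median
centromere, 0 a terminal one.

**Morphology thresholds.** CI is classified into four classes with
inclusive lower bounds: metacentric [0.37, 0.5], submetacentric
[0.25, 0.37), subtelocentric [0.125, 0.25), telocentric [0, 0.125). These
are the CI equivalents of the classical arm-ratio (q/p) cut-offs 1.7, 3.0
and 7.0 used throughout amphibian cytogenetics. The cut-offs reproduce
every CI → class pairing the packaged dataset records, including the
deliberately awkward ones: CI 0.25 is submetacentric ("almost
subtelocentric"), CI 0.41 and 0.46 are metacentric. The thresholds are an
argument (`ci_thresholds()`) everywhere they are used, so other published
schemes can be substituted; the defaults above are frozen as the package's
reference scheme.

**Fundamental number.** FN counts chromosome arms over the somatic
complement: 2 per bi-armed chromosome, 1 per telocentric. The convention
that *subtelocentric chromosomes count as bi-armed* is a genuine choice —
schemes differ — and is calibrated against the packaged records: the
*Hyloscirtus palmeri* karyotype (12 bi-armed pairs including a
subtelocentric pair 4) must give FN = 48, and *H. larinopygion* (11
bi-armed pairs + 1 telocentric pair) FN = 46. Under this convention
2n ≤ FN ≤ 2·2n always, with equality on the right exactly when no
telocentric is present.

**Ploidy and supernumeraries.** 2n = ploidy · x; the packaged triploid
*Boana pulchella* specimen (ploidy 3, x = 12, 2n = 36) is stored as its own
specimen-level record rather than merged into the species, because it is an
individual anomaly, not a species attribute. B chromosomes sit outside the
A complement: they are excluded from 2n, x, FN and from the 100%
relative-length normalization, and their size is expressed as percent of
the haploid A-complement total (the packaged B chromosome of *Boana
leucocheila* is 3.11% of the haploid set, CI 0.46).

**Heteromorphic pairs** (e.g. pair 8 of one *Boana boans* male, pair 11 of
*B. punctata* females, the XY pair 2 of *Hyloscirtus alytolylax*) are
stored as two half-records on one pair index, distinguished by a homologue
flag; karyotype-level summaries (FN, idiograms) use the modal homologue
(stored as homologue "A", the commonly observed condition).

**What the packaged records do not carry.** The study's raw per-pair
measurements live in a supplementary table that is not reproduced in its
main text, so packaged pairs store morphology classes and the few CI values
printed in prose — not arm lengths. Consequently relative-length and
idiogram computations are exercised on generated karyotypes with known
lengths, and the packaged records are validated on the invariants that do
not need lengths.

## Character coding

Two unordered multistate characters are coded per taxon:

- **basic number x**, alphabet {9, 10, 11, 12, 13} — a taxon whose basic
  number is not printed is MISSING, never inferred from relatives; a basic
  number outside the alphabet is a coding error, not a silent extension;
- **NOR-bearing pair**, with explicit homology rules mapping raw pair
  numbers to coded states.

The NOR rules encode hypotheses about which chromosomes are "the same"
across species, and they are deliberately data, not code
(`default_nor_mapping()`, serializable as JSON):

1. *Taxon-private pair-4 states.* The pair-4 NORs of *Bokermannohyla
   alvarengai*, *Hyloscirtus alytolylax* (4p) and *H. palmeri* (4q) are
   conspicuously different and are treated as independent transformations.
   On an unordered character, coding them as three private states `4a`,
   `4b`, `4c` achieves exactly that — no reconstruction can connect them
   more cheaply than any other pair of states — without a step matrix.
2. *Pair 9 → state 11.* NORs on pair 9 (the *Aplastodiscus albosignatus*
   group) are treated as homeologous to the small NOR-bearing pair 11 of
   most cophomantines. The rule is applied genus-agnostically because the
   one polymorphic record (*Boana prasina*, NORs on pairs 9 and 12) needs
   it too; it yields the multistate cell {11, 12}.
3. *Medium-pair states, genus-scoped (default) or literal.* Observations
   on pairs 6 or 7 are ambiguous between two readings of the source
   material: a state alphabet listing pair 6, and results naming pair 7 as
   a group-level synapomorphy, with the *Aplastodiscus* pair-6/7 conditions
   called "apparently homeologous". The default rule collapses medium-pair
   observations within a genus to one state (*Aplastodiscus* → `6`,
   *Boana* → `7`), preserving both statements; `medium_rule = "literal"`
   keeps raw pair numbers. Neither reading is asserted as the original
   intent; both are reproducible.

Polymorphic NORs become multistate cells, which parsimony treats as
cost-free ambiguity. Literature records without a voucherable karyotype
(the *Boana fasciata* record) are included but carry a caution flag so they
can be excluded by configuration.

## The condensed reference tree

The packaged tree condenses the published reference phylogeny to the
clades the study's text names: Cophomantini as
(*Myersiohyla*, (*Hyloscirtus*, (*Bokermannohyla*, (*Aplastodiscus*,
*Boana*)))), species groups as clades (internally unresolved polytomies
unless the text implies structure), the remaining hyline tribes as three
condensed modal tips (x = 12, NOR state 11 — their modal conditions as the
text states them), and the two non-hyline outgroup lineages as modal tips
(x = 13, NOR MISSING). Three internal resolutions are adopted beyond the
group level, each anchored in an explicit textual claim:

- the 2n = 22 species of the *Boana albopunctata* group form a clade;
- the *B. polytaenia* and *B. semiguttata* clades are sisters, and
  (*B. caingua*, *B. prasina*, *B. pulchella*) form a clade within the
  *B. pulchella* group;
- the *Aplastodiscus albofrenatus* group is resolved as
  (*arildae*, *ehrhardti*, (*albofrenatus*, *eugenioi*)). The study reports
  an optimization ambiguity at this group's base caused by the position of
  *A. arildae* but does not print the group's internal topology; this
  resolution is consistent with the published group phylogeny and is the
  configuration in which the base-node MPR set is exactly
  {medium pair, 11}, i.e. the reported ambiguity. This is the package's
  own choice and is recorded here rather than asserted as the original
  figure's topology.

Branch lengths are ignored throughout: the analysis is parsimony on
topology.

## Unordered parsimony on multifurcating trees

`reconstruct()` implements the count-based generalization of Fitch
optimization to rooted trees with polytomies. Down pass, leaves to root:
at node v with children c₁…c_k, each state s receives a vote from every
child whose preliminary set contains s; with M the maximal vote count, the
preliminary set K(v) is the set of states with M votes and the node adds
k − M steps to the tree length. Up pass, root to leaves: the final (MPR)
set F(v) is F(parent) when F(parent) ⊆ K(v), and otherwise
K(v) ∪ (F(parent) ∩ L(v)), where L(v) holds the states one vote short.
F(v) is exactly the set of states node v attains in at least one
minimum-length reconstruction; |F(v)| > 1 flags genuine ambiguity.

Numerical/degenerate-input choices:

- MISSING leaves enter the down pass with the full alphabet at zero cost,
  so adding an unscored taxon can never increase tree length;
- polymorphic leaf cells enter as given, cost-free (standard treatment);
- a character with fewer than two non-MISSING leaves is a degenerate-input
  error rather than a trivial answer;
- trees are used as rooted as written — no outgroup re-rooting logic;
- ambiguity is reported via MPR sets; no ACCTRAN/DELTRAN choice is imposed.
  `resolve_assignment()` exposes both flavours for exploration, picking a
  jointly optimal single assignment by unit-cost dynamic programming with
  ties broken toward (DELTRAN) or away from (ACCTRAN) the parent state.

**Synapomorphy rule.** A branch is reported as carrying a candidate
synapomorphy when the child's MPR set is a single state absent from the
parent's MPR set: a derived state fixed on the clade's stem. Changes into
still-ambiguous sets are listed among branch transformations but not
called synapomorphies.

**Correctness checking** is by dual route: an exhaustive brute-force
oracle (`brute_force_length()`) enumerates every internal-node labelling
on small instances and recovers both the minimum length and the exact MPR
sets; the test suite compares the two implementations on hundreds of
random instances (trees with polytomies, MISSING and polymorphic cells),
and additionally cross-checks lengths against an independent parsimony
implementation (phangorn) on bifurcating instances. The oracle is capped
at instances where alphabet^(internal nodes) stays enumerable and refuses
larger ones.

## Synthetic data: what it emulates and what it does not

`simulate_karyotype()` emulates measurement of a metaphase plate: true
total pair lengths are log-normal (right-skewed, strictly positive, as
chromosome size distributions are), true centromere positions uniform on
a CI range, and each arm measurement receives independent multiplicative
log-normal noise — measurement error scales with arm length, and the
published summaries report per-pair standard deviations without a model,
so a multiplicative error is the natural minimal choice. Defaults
(12 pairs, noise_sd 0.05 on the log scale) mirror a modal 2n = 24
karyotype measured with moderate care. The generator does **not** emulate
rank-assignment errors beyond those induced by length noise, banding
patterns, or inter-cell variation within an individual; a passing
reclassification test therefore shows threshold robustness to measurement
noise, not robustness to chromosome misidentification.

`simulate_character()` evolves an unordered character by a per-branch jump
probability (uniform root state; on each branch, with probability c the
state jumps to a uniformly chosen different state). A jump probability per
branch — rather than a rate × branch length — is used because the
condensed reference tree has no meaningful branch lengths. The recorded
history bounds parsimony from above: tree length can never exceed the
realized number of changes, and this is asserted on every simulated
replicate. `recovery_experiment()` reports, per change probability, mean
tree length, mean realized changes, the frequency with which the true root
state lies in the root MPR set, and root-ambiguity frequency. At c = 0
recovery is exactly 1; mean length grows with c. These experiments use a
16-leaf tree with 50–100 replicates per grid point — sizes at which the
Monte-Carlo means are stable to well under the effects being checked while
the whole suite stays fast.

## Known limitations

- The packaged dataset covers only values printed in the study's main
  text; supplementary measurement tables and the species-level literature
  registry are represented by their printed per-genus totals, not by
  invented rows. The C-band registry (8 + 33 + 9 + 3 = 53) is therefore a
  totals table, not an enumerable species list.
- The condensed tree's unresolved polytomies are *soft*: the count-based
  algorithm treats them natively, but finer published resolutions could
  shift less-inclusive optimizations.
- Heterochromatin band descriptors are stored verbatim and are not coded
  as phylogenetic characters: band homology across species is explicitly
  not established, and band transcription from prose is representative
  rather than exhaustive.
- Parsimony is the only reconstruction criterion offered; no
  likelihood/Bayesian ancestral estimation, and no tree search — the
  topology is always an input.
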