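# karyevo

Karyotype morphometrics and parsimony ancestral-state analysis of
chromosome evolution in cophomantine treefrogs (Hylidae: Hylinae:
Cophomantini — *Aplastodiscus*, *Boana*, *Bokermannohyla*, *Hyloscirtus*,
*Myersiohyla*).

Amphibian cytogenetics summarizes a species' chromosome complement by a
handful of characters: the somatic chromosome number 2n and basic number x
(2n = ploidy · x), the fundamental number FN (count of chromosome arms:
bi-armed chromosomes contribute two, telocentrics one), per-pair morphology
classified from the centromeric index CI = p/(p+q) ∈ [0, 0.5] (metacentric
≥ 0.37, submetacentric [0.25, 0.37), subtelocentric [0.125, 0.25),
telocentric < 0.125), and the chromosome pair bearing the nucleolar
organizer region (NOR). Treated as unordered multistate characters on a
reference phylogeny, x and the NOR-bearing pair become evidence for clades:
a derived state fixed on a clade's stem branch is a candidate synapomorphy.

The package provides, for whoever needs to redo or extend this kind of
analysis:

- **karyotype morphometrics** — CI, morphology classification with
  configurable thresholds, FN, percent relative lengths, structural
  validation, idiogram geometry, and a CSV dialect that round-trips
  karyotypes bit-identically;
- **character coding** — explicit, config-driven homology rules mapping raw
  NOR observations to coded states (taxon-private states for the three
  non-homologous pair-4 conditions, pair 9 → 11 small-chromosome homeology,
  genus-scoped medium-pair states), multistate cells for polymorphic NORs,
  MISSING for silent records; NEXUS / TNT xread / CSV matrix I/O;
- **unordered parsimony** — Hartigan-style count-based reconstruction on
  rooted, possibly multifurcating trees: minimum tree length, per-node MPR
  state sets, branch transformations, synapomorphy candidates and
  ambiguity flags, plus a brute-force enumeration oracle and
  ACCTRAN/DELTRAN single-assignment resolution;
- **the packaged Cophomantini dataset** — karyotypes of the 28 newly
  studied species, literature records named in the study's text, a
  condensed reference tree, per-genus taxonomy (181 described species) and
  C-band (53 species) registries;
- **simulators** — noisy arm-length measurements with known truth, and
  discrete-character histories evolved by per-branch jump probability, with
  a root-recovery experiment harness.

## Worked example

```r
library(karyevo)
d <- load_cophomantini()

fundamental_number(d$karyotypes$Hyloscirtus_alytolylax)
#> [1] 38

rx <- reconstruct(d$tree, d$matrix, "x")
rx$mpr[["Hylinae"]]
#> [1] "12"

rn <- reconstruct(d$tree, d$matrix, "nor_position")
rn$mpr[["Hylinae"]]
#> [1] "11"
synapomorphies(rn)$synapomorphies[, c("clade", "state", "n_tips")]
#>                                   clade state n_tips
#> 1             Bokermannohyla_alvarengai    4a      1
#> 2             Bokermannohyla_ibitiguara     1      1
#> 3           Boana_albopunctata_22_clade     8      4
#> 4                    Boana_almendarizae    12      1
#> 5 Boana_caingua_prasina_pulchella_clade    12      3
#> 6    Boana_polytaenia_semiguttata_clade     1      5
#> 7               Boana_semilineata_group     7      6
#> 8                     Boana_geographica     1      1
#> 9                         Boana_wavrini    11      1
rn$ambiguous_nodes
#> [1] "Hyloscirtus"  "Hyloscirtus_bogotensis_group"
#> [3] "Hyloscirtus_armatus_larinopygion_clade"
#> [5] "Aplastodiscus_albofrenatus_group"
```

Reading: the ancestral basic number of Hylinae optimizes to a fixed x = 12,
with independent reductions inside *Aplastodiscus*, *Hyloscirtus*
(*H. alytolylax*, x = 10) and the 2n = 22 clade of the *Boana albopunctata*
group (x = 11). NORs on the small pair 11 are the fixed ancestral hyline
condition; NORs on pair 12 mark the (*B. caingua*, *B. prasina*,
*B. pulchella*) clade, NORs on pair 1 the *B. polytaenia* + *B. semiguttata*
clade, and NORs on the medium pair mark a clade within the *B. semilineata*
group, while the base of the *A. albofrenatus* group stays ambiguous
(MPR = {medium pair, 11}) because of the position of *A. arildae*.

## The analysis workflow

Numbered drivers under `analysis/` rerun the full study pipeline and write
their tables under `results/`:

1. `01_classify_karyotypes.R` — morphometrics + validation of every record;
2. `02_encode_characters.R` — character coding, matrix regeneration check,
   NEXUS/TNT/CSV export;
3. `03_optimize_characters.R` — both reconstructions, synapomorphy and
   ambiguity reports, annotated Newick;
4. `04_simulation_experiments.R` — oracle agreement, root-recovery vs
   change probability, misclassification vs measurement noise.

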