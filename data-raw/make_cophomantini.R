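## Builds the packaged Cophomantini dataset under inst/extdata/ from the
## values printed in the source study's main text (karyotype descriptions,
## species/technique table, per-genus registry counts, condensed phylogeny).
## Run from the package root:  Rscript data-raw/make_cophomantini.R

devtools::load_all(".", quiet = TRUE)

out <- file.path("inst", "extdata")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

## ---------------------------------------------------------------- species --
## taxon_level: species = karyotyped taxon (here or literature);
## condensed = clade-level modal tip of the reference topology;
## specimen = individual anomaly kept as its own record.
sp <- function(taxon, genus, group, level = "species", studied = FALSE,
               n = NA, tech = NA, ploidy = 2L, x = NA, nor = NA,
               nor_arm = NA, nor_pos = NA, sex = NA, caution = FALSE,
               note = NA, prov = NA) {
  data.frame(taxon = taxon, genus = genus, species_group = group,
             taxon_level = level, studied_here = studied, n_specimens = n,
             techniques = tech, ploidy = ploidy, x = x, nor_pairs = nor,
             nor_arm = nor_arm, nor_position = nor_pos, sex_system = sex,
             caution = caution, note = note, provenance = prov,
             stringsAsFactors = FALSE)
}
ACDR <- "AgNOR;Cbands;DAPI-CMA3;rDNA-FISH"
ACD  <- "AgNOR;Cbands;DAPI-CMA3"

species <- rbind(
  ## --- outgroups and condensed hyline tribes (modal states) ---------------
  sp("Phyllomedusinae_modal", "Phyllomedusinae", NA, "condensed", x = 13,
     prov = "discussion:basic_numbers"),
  sp("Pelodryadinae_modal", "Pelodryadinae", NA, "condensed", x = 13,
     prov = "discussion:basic_numbers"),
  sp("Dendropsophini_modal", "Dendropsophini", NA, "condensed", x = 12,
     nor = "11", prov = "introduction+discussion:modal_hylinae"),
  sp("Hylini_modal", "Hylini", NA, "condensed", x = 12, nor = "11",
     prov = "introduction+discussion:modal_hylinae"),
  sp("Lophyohylini_modal", "Lophyohylini", NA, "condensed", x = 12,
     nor = "11", prov = "introduction+discussion:modal_hylinae"),
  ## --- Cophomantini -------------------------------------------------------
  sp("Myersiohyla_spp", "Myersiohyla", NA, "condensed",
     note = "karyotype unknown", prov = "discussion:basic_numbers"),
  sp("Hyloscirtus_alytolylax", "Hyloscirtus", "H_bogotensis_group",
     studied = TRUE, n = "2F,3M", tech = ACD, x = 10, nor = "4",
     nor_arm = "p", nor_pos = "terminal", sex = "XY",
     prov = "table1+results:hyloscirtus"),
  sp("Hyloscirtus_palmeri", "Hyloscirtus", "H_bogotensis_group",
     studied = TRUE, n = "1F", tech = ACDR, x = 12, nor = "4",
     nor_arm = "q", nor_pos = "terminal", prov = "table1+results:hyloscirtus"),
  sp("Hyloscirtus_armatus", "Hyloscirtus", "H_armatus_group", x = 12,
     note = "24 chromosomes reported in literature, figures not shown",
     prov = "discussion:basic_numbers"),
  sp("Hyloscirtus_larinopygion", "Hyloscirtus", "H_larinopygion_group",
     studied = TRUE, n = "2M", tech = ACDR, x = 12, nor = "1",
     nor_arm = "p", nor_pos = "terminal", prov = "table1+results:hyloscirtus"),
  sp("Bokermannohyla_spp", "Bokermannohyla", NA, "condensed", x = 12,
     nor = "11", note = "genus modal condition",
     prov = "discussion:basic_numbers+nor_locations"),
  sp("Bokermannohyla_alvarengai", "Bokermannohyla", NA, x = 12, nor = "4",
     prov = "discussion:nor_locations"),
  sp("Bokermannohyla_ibitiguara", "Bokermannohyla", NA, x = 12, nor = "1",
     prov = "discussion:nor_locations"),
  sp("Aplastodiscus_cochranae", "Aplastodiscus", "A_perviridis_group",
     x = 12, nor = "11", prov = "discussion:basic_numbers+nor_locations"),
  sp("Aplastodiscus_perviridis", "Aplastodiscus", "A_perviridis_group",
     x = 12, nor = "11", prov = "discussion:basic_numbers+nor_locations"),
  sp("Aplastodiscus_arildae", "Aplastodiscus", "A_albofrenatus_group",
     x = 11, nor = "11", prov = "discussion:nor_locations"),
  sp("Aplastodiscus_ehrhardti", "Aplastodiscus", "A_albofrenatus_group",
     x = 11, nor = "6or7", prov = "discussion:nor_locations"),
  sp("Aplastodiscus_albofrenatus", "Aplastodiscus", "A_albofrenatus_group",
     x = 11, nor = "6or7", prov = "discussion:nor_locations"),
  sp("Aplastodiscus_eugenioi", "Aplastodiscus", "A_albofrenatus_group",
     x = 11, nor = "6or7", prov = "discussion:nor_locations"),
  sp("Aplastodiscus_albosignatus", "Aplastodiscus", "A_albosignatus_group",
     x = 10, nor = "9", prov = "discussion:nor_locations"),
  sp("Aplastodiscus_callipygius", "Aplastodiscus", "A_albosignatus_group",
     nor = "9", note = "basic number not printed in main text",
     prov = "discussion:nor_locations"),
  sp("Aplastodiscus_leucopygius", "Aplastodiscus", "A_albosignatus_group",
     x = 9, nor = "9", prov = "discussion:nor_locations"),
  ## --- Boana albopunctata group -------------------------------------------
  sp("Boana_albopunctata", "Boana", "B_albopunctata_group", x = 11,
     nor = "8", prov = "discussion:albopunctata_group"),
  sp("Boana_cf_alfaroi", "Boana", "B_albopunctata_group", studied = TRUE,
     n = "1M,1U", tech = "rDNA-FISH", x = 11, nor = "8", nor_arm = "p",
     nor_pos = "terminal", prov = "table1+results:albopunctata_group"),
  sp("Boana_leucocheila", "Boana", "B_albopunctata_group", studied = TRUE,
     n = "3M", tech = "AgNOR;DAPI-CMA3;rDNA-FISH", x = 11, nor = "8",
     nor_arm = "p", nor_pos = "terminal",
     note = "B chromosome in 2 of 3 specimens",
     prov = "table1+results:albopunctata_group"),
  sp("Boana_multifasciata", "Boana", "B_albopunctata_group", studied = TRUE,
     n = "3M,1U", tech = ACDR, x = 11, nor = "8", nor_arm = "p",
     nor_pos = "terminal",
     note = "literature reports 2n=24; this karyotype 2n=22 near type locality",
     prov = "table1+results:albopunctata_group"),
  sp("Boana_almendarizae", "Boana", "B_albopunctata_group", studied = TRUE,
     n = "2M", tech = ACD, x = 12, nor = "12",
     prov = "table1+results:albopunctata_group"),
  sp("Boana_calcarata", "Boana", "B_albopunctata_group", studied = TRUE,
     n = "1M", tech = "Cbands", x = 12,
     prov = "table1+results:albopunctata_group"),
  sp("Boana_cf_lanciformis", "Boana", "B_albopunctata_group", studied = TRUE,
     n = "1M", tech = "AgNOR", x = 12, nor = "11", nor_arm = "q",
     nor_pos = "terminal",
     note = "literature reports 2n=22 for B. lanciformis; cryptic diversity",
     prov = "table1+results:albopunctata_group"),
  sp("Boana_fasciata", "Boana", "B_albopunctata_group", x = 12,
     caution = TRUE, note = "no voucher specimen; record flagged",
     prov = "discussion:albopunctata_group"),
  sp("Boana_heilprini", "Boana", "B_albopunctata_group", studied = TRUE,
     n = "1F,1M", tech = "DAPI-CMA3", x = 12,
     note = "NOR not established; terminal DAPI-/CMA3+ signals on pair 11",
     prov = "table1+results:albopunctata_group"),
  sp("Boana_raniceps", "Boana", "B_albopunctata_group", studied = TRUE,
     n = "1F,14M,1J,2U", tech = ACDR, x = 12, nor = "11", nor_arm = "q",
     nor_pos = "terminal", prov = "table1+results:albopunctata_group"),
  ## --- Boana faber / pellucens groups --------------------------------------
  sp("Boana_faber", "Boana", "B_faber_group", studied = TRUE, n = "3M",
     tech = ACDR, x = 12, nor = "11", nor_arm = "q", nor_pos = "terminal",
     prov = "table1+results:faber_pellucens_groups"),
  sp("Boana_pellucens", "Boana", "B_pellucens_group", studied = TRUE,
     n = "2M", tech = ACDR, x = 12, nor = "11", nor_arm = "q",
     nor_pos = "interstitial", prov = "table1+results:faber_pellucens_groups"),
  ## --- Boana pulchella group ------------------------------------------------
  sp("Boana_albonigra", "Boana", "B_pulchella_group", studied = TRUE,
     n = "1F,2M", tech = ACD, x = 12, nor = "11", nor_arm = "q",
     nor_pos = "interstitial", prov = "table1+results:pulchella_group"),
  sp("Boana_bischoffi", "Boana", "B_pulchella_group", studied = TRUE,
     n = "1M", tech = "AgNOR;Cbands", x = 12, nor = "11", nor_arm = "q",
     nor_pos = "interstitial", prov = "table1+results:pulchella_group"),
  sp("Boana_caingua", "Boana", "B_pulchella_group", studied = TRUE,
     n = "1F,12M", tech = ACD, x = 12, nor = "12",
     nor_pos = "interstitial", prov = "table1+results:pulchella_group"),
  sp("Boana_cipoensis", "Boana", "B_pulchella_group", studied = TRUE,
     n = "4M", tech = ACDR, x = 12, nor = "1", nor_arm = "p",
     nor_pos = "terminal", prov = "table1+results:pulchella_group"),
  sp("Boana_cordobae", "Boana", "B_pulchella_group", studied = TRUE,
     n = "2F,9M", tech = ACD, x = 12, nor = "11", nor_arm = "q",
     nor_pos = "terminal", prov = "table1+results:pulchella_group"),
  sp("Boana_curupi", "Boana", "B_pulchella_group", studied = TRUE,
     n = "6M", tech = ACD, x = 12, nor = "1", nor_arm = "p",
     nor_pos = "terminal", prov = "table1+results:pulchella_group"),
  sp("Boana_guentheri", "Boana", "B_pulchella_group", nor = "11",
     prov = "discussion:heterochromatin"),
  sp("Boana_joaquini", "Boana", "B_pulchella_group", nor = "1",
     prov = "discussion:nor_locations"),
  sp("Boana_marginata", "Boana", "B_pulchella_group", nor = "11",
     prov = "discussion:heterochromatin"),
  sp("Boana_marianitae", "Boana", "B_pulchella_group", studied = TRUE,
     n = "2M", tech = ACD, x = 12, nor = "11", nor_arm = "q",
     nor_pos = "interstitial", prov = "table1+results:pulchella_group"),
  sp("Boana_prasina", "Boana", "B_pulchella_group", nor = "9;12",
     note = "polymorphic NOR condition", prov = "discussion:nor_locations"),
  sp("Boana_pulchella", "Boana", "B_pulchella_group", studied = TRUE,
     n = "3F,34M,1J", tech = ACD, x = 12, nor = "12", nor_pos = "terminal",
     prov = "table1+results:pulchella_group"),
  sp("Boana_riojana", "Boana", "B_pulchella_group", studied = TRUE,
     n = "6F,8M", tech = ACDR, x = 12, nor = "11", nor_arm = "q",
     nor_pos = "interstitial", prov = "table1+results:pulchella_group"),
  sp("Boana_semiguttata", "Boana", "B_pulchella_group", nor = "1",
     prov = "discussion:nor_locations"),
  sp("Boana_stellae", "Boana", "B_pulchella_group", studied = TRUE,
     n = "1F,8M", tech = ACDR, x = 12, nor = "1", nor_arm = "p",
     nor_pos = "terminal", prov = "table1+results:pulchella_group"),
  ## triploid individual kept as its own specimen-level record
  sp("Boana_pulchella_LGE11504", "Boana", "B_pulchella_group", "specimen",
     studied = TRUE, n = "1M", tech = "AgNOR;Cbands", ploidy = 3L, x = 12,
     nor = "12", nor_pos = "terminal",
     note = "spontaneous triploid (2n = 3x = 36); trivalents and microspermatids in meiosis",
     prov = "results:pulchella_group"),
  ## --- Boana punctata group -------------------------------------------------
  sp("Boana_cinerascens", "Boana", "B_punctata_group", studied = TRUE,
     n = "7M,1U", tech = ACDR, x = 12, nor = "11", nor_arm = "q",
     nor_pos = "interstitial", prov = "table1+results:punctata_group"),
  sp("Boana_punctata", "Boana", "B_punctata_group", studied = TRUE,
     n = "2F", tech = ACDR, x = 12, nor = "11",
     note = "pair 11 heteromorphic (11A metacentric, 11B submetacentric); Ag-NOR size heteromorphism in one specimen",
     prov = "table1+results:punctata_group"),
  ## --- Boana semilineata group ----------------------------------------------
  sp("Boana_boans", "Boana", "B_semilineata_group", studied = TRUE,
     n = "2M,1U", tech = ACDR, x = 12, nor = "7", nor_arm = "q",
     nor_pos = "interstitial",
     note = "pair 8 heteromorphism in one male (8A submetacentric, 8B metacentric)",
     prov = "table1+results:semilineata_group"),
  sp("Boana_cf_semilineata", "Boana", "B_semilineata_group", studied = TRUE,
     n = "1M,1U", tech = ACDR, x = 12, nor = "7", nor_arm = "q",
     nor_pos = "interstitial", prov = "table1+results:semilineata_group"),
  sp("Boana_geographica", "Boana", "B_semilineata_group", nor = "1",
     nor_pos = "centromeric", prov = "discussion:nor_locations"),
  sp("Boana_pombali", "Boana", "B_semilineata_group", nor = "7",
     nor_pos = "interstitial", prov = "discussion:nor_locations"),
  sp("Boana_semilineata", "Boana", "B_semilineata_group", nor = "7",
     nor_pos = "interstitial", prov = "discussion:nor_locations"),
  sp("Boana_wavrini", "Boana", "B_semilineata_group", studied = TRUE,
     n = "1M,2U", tech = ACDR, x = 12, nor = "11", nor_arm = "q",
     nor_pos = "interstitial", prov = "table1+results:semilineata_group")
)
write.csv(species, file.path(out, "cophomantini_species.csv"),
          row.names = FALSE, na = "", fileEncoding = "UTF-8")

## ------------------------------------------------------------- karyotypes --
## Morphology strings: one token per pair, 1 = largest.
M <- c(m = "metacentric", sm = "submetacentric", st = "subtelocentric",
       t = "telocentric")
morph <- function(s) unname(M[strsplit(s, " ")[[1]]])

mk <- function(taxon, spec, sp_row = species[species$taxon == taxon, ]) {
  m <- morph(spec)
  pairs <- lapply(seq_along(m), function(i)
    chromosome_pair(i, morphology = m[i]))
  nor_pair <- suppressWarnings(as.integer(sp_row$nor_pairs))
  if (!is.na(nor_pair)) {
    k <- which(vapply(pairs, function(p) p$pair_index, 1L) == nor_pair)
    pairs[[k]]$nor_arm <- sp_row$nor_arm
    pairs[[k]]$nor_position <- sp_row$nor_position
  }
  karyotype(taxon, pairs, ploidy = sp_row$ploidy,
            group = sp_row$species_group,
            sex_system = sp_row$sex_system, source = "this_study")
}

specs <- list(
  Hyloscirtus_alytolylax   = "m m sm sm sm m t m m m",
  Hyloscirtus_palmeri      = "m m sm st sm sm m sm m m m m",
  Hyloscirtus_larinopygion = "m m sm st sm sm sm m m m m t",
  Boana_cf_alfaroi         = "m m sm sm sm sm sm m m sm m",
  Boana_leucocheila        = "m m sm sm sm sm m m m sm m",
  Boana_multifasciata      = "m m sm st sm st sm m m sm m",
  Boana_almendarizae       = "m m sm sm sm sm sm m sm m m m",
  Boana_calcarata          = "m m sm st sm sm m m m m m m",
  Boana_cf_lanciformis     = "m m sm st sm st sm m m sm sm m",
  Boana_heilprini          = "m m sm sm m sm sm m sm m m sm",
  Boana_raniceps           = "m m sm st sm sm m m sm m m sm",
  Boana_faber              = "m m sm st sm st st m sm sm m m",
  Boana_pellucens          = "m m sm sm sm sm m m sm m sm m",
  Boana_cinerascens        = "m m sm st sm st sm m m sm m m",
  Boana_punctata           = "m m sm sm sm st sm m m sm m sm",
  Boana_boans              = "m m sm st sm sm sm sm m m m m",
  Boana_cf_semilineata     = "m m sm st sm sm sm sm sm m m m",
  Boana_wavrini            = "m m sm st sm sm sm sm m m m m",
  Boana_albonigra          = "m m sm st sm st sm sm m m m m",
  Boana_bischoffi          = "m m sm st sm st sm sm m m m m",
  Boana_caingua            = "m m sm st sm st sm m m m m m",
  Boana_cipoensis          = "m m sm st sm st sm sm m m m m",
  Boana_cordobae           = "m m sm st sm st sm m m m m m",
  Boana_curupi             = "m m sm st sm st sm sm m m m m",
  Boana_marianitae         = "m m sm st sm st sm sm m m m m",
  Boana_pulchella          = "m m sm st sm st sm m m m m m",
  Boana_riojana            = "m m sm st sm st sm sm m m m m",
  Boana_stellae            = "m m sm st sm st sm sm m m m m"
)

karyos <- lapply(names(specs), function(tx) mk(tx, specs[[tx]]))
names(karyos) <- names(specs)

## printed centromeric indices (Results prose)
set_ci <- function(k, pair, ci) {
  i <- which(vapply(k$pairs, function(p) p$pair_index, 1L) == pair)[1]
  k$pairs[[i]]$ci <- ci
  k
}
karyos$Boana_boans          <- set_ci(karyos$Boana_boans, 5, 0.35)
karyos$Boana_cf_semilineata <- set_ci(karyos$Boana_cf_semilineata, 5, 0.34)
karyos$Boana_wavrini        <- set_ci(karyos$Boana_wavrini, 5, 0.25)

## heteromorphic pairs stored as two half-records on one pair index
hetero <- function(k, pair, morphA, morphB, ciA = NA, ciB = NA,
                   bandsB = NA) {
  i <- which(vapply(k$pairs, function(p) p$pair_index, 1L) == pair)[1]
  base <- k$pairs[[i]]
  A <- chromosome_pair(pair, ci = ciA, morphology = morphA, homologue = "A",
                       nor_arm = base$nor_arm,
                       nor_position = base$nor_position)
  B <- chromosome_pair(pair, ci = ciB, morphology = morphB, homologue = "B",
                       bands = bandsB)
  k$pairs <- append(k$pairs[-i], list(A, B), after = i - 1)
  k
}
karyos$Boana_boans <- hetero(karyos$Boana_boans, 8,
                             "submetacentric", "metacentric", 0.34, 0.41)
karyos$Boana_punctata <- hetero(karyos$Boana_punctata, 11,
                                "metacentric", "submetacentric")
## XX/XY: 2Y of H. alytolylax carries a male-limited centromeric DAPI+ band
karyos$Hyloscirtus_alytolylax <-
  hetero(karyos$Hyloscirtus_alytolylax, 2, "metacentric", "metacentric",
         bandsB = "centromeric:DAPI+:male-limited")

## B chromosome of B. leucocheila: 3.11% of the haploid set, CI 0.46
karyos$Boana_leucocheila$b_chromosomes <-
  list(b_chromosome(rel_length = 3.11, ci = 0.46,
                    mitotically_stable = TRUE))

## triploid B. pulchella specimen: same pair morphology, ploidy 3
tri <- mk("Boana_pulchella_LGE11504", specs$Boana_pulchella)
tri$source <- "this_study"
karyos$Boana_pulchella_LGE11504 <- tri

write_karyotype_csv(karyos, file.path(out, "cophomantini_karyotypes.csv"))

## ------------------------------------------------------------------- tree --
## Condensed reference topology assembled from the text's clade statements;
## species groups enter as clades, internally unresolved except where the
## text implies structure (2n = 22 albopunctata clade; polytaenia +
## semiguttata clades; caingua/prasina/pulchella; albofrenatus-group
## resolution consistent with the reported base ambiguity).
tree_txt <- paste0(
 "((Myersiohyla_spp,",
   "(((Hyloscirtus_alytolylax,Hyloscirtus_palmeri)Hyloscirtus_bogotensis_group,",
     "(Hyloscirtus_armatus,Hyloscirtus_larinopygion)Hyloscirtus_armatus_larinopygion_clade)Hyloscirtus,",
    "((Bokermannohyla_spp,Bokermannohyla_alvarengai,Bokermannohyla_ibitiguara)Bokermannohyla,",
     "(((Aplastodiscus_cochranae,Aplastodiscus_perviridis)Aplastodiscus_perviridis_group,",
       "(Aplastodiscus_arildae,Aplastodiscus_ehrhardti,",
        "(Aplastodiscus_albofrenatus,Aplastodiscus_eugenioi))Aplastodiscus_albofrenatus_group,",
       "(Aplastodiscus_albosignatus,Aplastodiscus_callipygius,Aplastodiscus_leucopygius)Aplastodiscus_albosignatus_group",
      ")Aplastodiscus,",
      "(((Boana_albopunctata,Boana_cf_alfaroi,Boana_leucocheila,Boana_multifasciata)Boana_albopunctata_22_clade,",
        "Boana_almendarizae,Boana_calcarata,Boana_cf_lanciformis,Boana_fasciata,Boana_heilprini,Boana_raniceps",
       ")Boana_albopunctata_group,",
       "Boana_faber,Boana_pellucens,",
       "((Boana_caingua,Boana_prasina,Boana_pulchella)Boana_caingua_prasina_pulchella_clade,",
        "(Boana_cipoensis,",
         "(Boana_curupi,Boana_joaquini,Boana_semiguttata,Boana_stellae)Boana_semiguttata_clade",
        ")Boana_polytaenia_semiguttata_clade,",
        "Boana_albonigra,Boana_bischoffi,Boana_cordobae,Boana_guentheri,",
        "Boana_marginata,Boana_marianitae,Boana_riojana)Boana_pulchella_group,",
       "(Boana_cinerascens,Boana_punctata)Boana_punctata_group,",
       "(Boana_boans,Boana_cf_semilineata,Boana_geographica,Boana_pombali,",
        "Boana_semilineata,Boana_wavrini)Boana_semilineata_group",
      ")Boana)))Cophomantini,",
  "(Dendropsophini_modal,Hylini_modal,Lophyohylini_modal))Hylinae,",
 "(Pelodryadinae_modal,Phyllomedusinae_modal));")
writeLines(tree_txt, file.path(out, "cophomantini_tree.nwk"))
stopifnot(!is.null(parse_newick(tree_txt)))

## ----------------------------------------------------------- registries ----
write.csv(data.frame(genus = c("Aplastodiscus", "Boana", "Bokermannohyla",
                               "Hyloscirtus", "Myersiohyla"),
                     described_species = c(15L, 92L, 32L, 36L, 6L)),
          file.path(out, "taxonomy_registry.csv"), row.names = FALSE)
write.csv(data.frame(genus = c("Aplastodiscus", "Boana", "Bokermannohyla",
                               "Hyloscirtus"),
                     c_band_species = c(8L, 33L, 9L, 3L)),
          file.path(out, "cband_registry.csv"), row.names = FALSE)

## ------------------------------------------------- NOR mapping + matrix ----
map <- default_nor_mapping("genus")
jsonlite::write_json(list(rules = map$rules, alphabet = map$alphabet,
                          medium_rule = map$medium_rule),
                     file.path(out, "nor_mapping.json"),
                     auto_unbox = TRUE, pretty = TRUE)

tax <- species[species$taxon_level != "specimen", ]
mat <- build_character_matrix(
  data.frame(taxon = tax$taxon, genus = tax$genus,
             x = suppressWarnings(as.integer(tax$x)),
             nor_pairs = ifelse(is.na(tax$nor_pairs) | tax$nor_pairs == "",
                                NA, tax$nor_pairs),
             stringsAsFactors = FALSE))
write_matrix(mat, file.path(out, "cophomantini_matrix.nex"), "nexus")

## consistency: matrix taxa == tree leaves
tr <- parse_newick(file = file.path(out, "cophomantini_tree.nwk"))
stopifnot(setequal(tr$tip.label, mat$taxa))
cat("dataset written:", nrow(species), "records,", length(mat$taxa),
    "matrix taxa,", length(tr$tip.label), "tree leaves\n")
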