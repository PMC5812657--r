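d <- load_cophomantini()

test_that("every packaged karyotype passes validation and matches its record", {
  for (k in d$karyotypes) expect_length(validate_karyotype(k), 0)
  sp <- d$species
  aly <- d$karyotypes$Hyloscirtus_alytolylax
  expect_equal(aly$diploid_number_2n, 20)
  expect_equal(aly$sex_system, "XY")
  arow <- sp[sp$taxon == "Hyloscirtus_alytolylax", ]
  expect_equal(arow$nor_pairs, "4")
  expect_equal(arow$nor_arm, "p")
  leu <- d$karyotypes$Boana_leucocheila
  expect_length(leu$b_chromosomes, 1)
  expect_equal(leu$b_chromosomes[[1]]$rel_length, 3.11)
  expect_equal(leu$b_chromosomes[[1]]$ci, 0.46)
  expect_equal(leu$b_chromosomes[[1]]$morphology, "metacentric")
  ## karyotyped species' x equals the coded record
  for (nm in names(d$karyotypes)) {
    row <- sp[sp$taxon == nm, ]
    expect_equal(d$karyotypes[[nm]]$basic_number_x, as.integer(row$x),
                 info = nm)
    expect_equal(d$karyotypes[[nm]]$ploidy, as.integer(row$ploidy), info = nm)
  }
})

test_that("matrix taxa, tree leaves and record table are mutually consistent", {
  expect_setequal(d$tree$tip.label, d$matrix$taxa)
  non_spec <- d$species[d$species$taxon_level != "specimen", ]
  expect_setequal(non_spec$taxon, d$matrix$taxa)
  expect_false(anyDuplicated(d$species$taxon) > 0)
  expect_true(all(d$species$provenance != "" & !is.na(d$species$provenance)))
  cop <- d$species[!d$species$genus %in%
                     c("Phyllomedusinae", "Pelodryadinae", "Dendropsophini",
                       "Hylini", "Lophyohylini"), ]
  expect_true(all(cop$genus %in% c("Aplastodiscus", "Boana",
                                   "Bokermannohyla", "Hyloscirtus",
                                   "Myersiohyla")))
})

test_that("the shipped matrix regenerates from the records byte-identically", {
  rebuilt <- rebuild_cophomantini_matrix(d)
  expect_true(matrices_identical(rebuilt, d$matrix))
  f <- withr::local_tempfile(fileext = ".nex")
  write_matrix(rebuilt, f, "nexus")
  shipped <- system.file("extdata", "cophomantini_matrix.nex",
                         package = "karyevo")
  expect_identical(readLines(f), readLines(shipped))
})

test_that("the NOR alphabet carries the declared states and private pair-4 states", {
  ab <- d$matrix$alphabets$nor_position
  expect_true(all(c("1", "2", "6", "8", "11", "12") %in% ab))
  expect_true(all(c("4a", "4b", "4c") %in% ab))
  used <- unique(unlist(d$matrix$cells[, "nor_position"]))
  used <- used[!is.na(used)]
  expect_true(all(used %in% ab))
})

test_that("registry counts reproduce the review totals", {
  expect_equal(registry_counts(d$species, "studied_here", genus = "Boana"), 25)
  expect_equal(registry_counts(d$species, "studied_here",
                               genus = "Hyloscirtus"), 3)
  tot <- taxonomy_total(d$taxonomy_registry)
  expect_equal(tot, 181)
  expect_equal(tot, sum(c(15, 92, 32, 36, 6)))
  cb <- registry_counts(d$species, "c_band_known",
                        cband_registry = d$cband_registry)
  expect_equal(unname(cb[c("Aplastodiscus", "Boana", "Bokermannohyla",
                           "Hyloscirtus")]), c(8, 33, 9, 3))
  expect_equal(unname(cb["total"]), 53)
  ## technique filters count species-level records
  expect_equal(unname(registry_counts(d$species, "technique:Cbands",
                                      genus = "Hyloscirtus")), 3)
  empty <- registry_counts(d$species[0, ], "studied_here")
  expect_equal(unname(empty["total"]), 0)
  expect_error(registry_counts(d$species, "nonsense"), "config error")
})

test_that("the triploid record is specimen-level with 2n = 3x = 36", {
  tri <- d$karyotypes$Boana_pulchella_LGE11504
  expect_equal(tri$ploidy, 3L)
  expect_equal(tri$diploid_number_2n, 36)
  row <- d$species[d$species$taxon == "Boana_pulchella_LGE11504", ]
  expect_equal(row$taxon_level, "specimen")
  expect_false("Boana_pulchella_LGE11504" %in% d$matrix$taxa)
})
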