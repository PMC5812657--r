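records_fixture <- function() {
  data.frame(
    taxon = c("Hyloscirtus_alytolylax", "Boana_leucocheila",
              "Myersiohyla_spp", "Hyloscirtus_palmeri",
              "Aplastodiscus_leucopygius", "Boana_prasina",
              "Bokermannohyla_alvarengai", "Aplastodiscus_ehrhardti",
              "Boana_boans"),
    genus = c("Hyloscirtus", "Boana", "Myersiohyla", "Hyloscirtus",
              "Aplastodiscus", "Boana", "Bokermannohyla", "Aplastodiscus",
              "Boana"),
    x = c(10L, 11L, NA, 12L, 9L, NA, 12L, 11L, 12L),
    nor_pairs = c("4", "8", NA, "4", "9", "9;12", "4", "6or7", "7"),
    stringsAsFactors = FALSE)
}

test_that("basic-number coding uses the {9..13} alphabet and flags outliers", {
  col <- encode_basic_number(records_fixture())
  expect_identical(col[["Hyloscirtus_alytolylax"]], "10")
  expect_identical(col[["Boana_leucocheila"]], "11")
  expect_identical(col[["Myersiohyla_spp"]], NA_character_)
  bad <- data.frame(taxon = "Dendropsophus_sp", x = 15L)
  expect_error(encode_basic_number(bad), "Dendropsophus_sp")
})

test_that("NOR coding applies the homology rules of the default mapping", {
  col <- encode_nor_position(records_fixture())
  ## pair 9 is homeologous to the small NOR-bearing pair 11
  expect_identical(col[["Aplastodiscus_leucopygius"]], "11")
  ## the three pair-4 conditions are independent private states
  expect_identical(col[["Hyloscirtus_alytolylax"]], "4b")
  expect_identical(col[["Hyloscirtus_palmeri"]], "4c")
  expect_identical(col[["Bokermannohyla_alvarengai"]], "4a")
  expect_false(col[["Hyloscirtus_alytolylax"]] ==
               col[["Hyloscirtus_palmeri"]])
  ## polymorphic NORs become a multi-state cell
  expect_identical(col[["Boana_prasina"]], c("11", "12"))
  ## genus-scoped medium-pair states
  expect_identical(col[["Aplastodiscus_ehrhardti"]], "6")
  expect_identical(col[["Boana_boans"]], "7")
  expect_identical(col[["Myersiohyla_spp"]], NA_character_)
  ## a raw pair with no rule is a coding error naming the taxon
  bad <- data.frame(taxon = "t1", genus = "Boana", nor_pairs = "3")
  expect_error(encode_nor_position(bad), "coding error.*t1")
})

test_that("the literal medium-pair reading is available through the mapping", {
  lit <- default_nor_mapping("literal")
  ## under the literal reading '6or7' has no rule; plain 6 and 7 stay as-is
  rec <- data.frame(taxon = c("a", "b"), genus = c("Aplastodiscus", "Boana"),
                    nor_pairs = c("6", "7"))
  expect_identical(unname(unlist(encode_nor_position(rec, lit))), c("6", "7"))
  expect_error(
    encode_nor_position(data.frame(taxon = "a", genus = "Aplastodiscus",
                                   nor_pairs = "6or7"), lit),
    "coding error")
})

test_that("coding is deterministic and order-independent", {
  rec <- records_fixture()
  m1 <- build_character_matrix(rec)
  perm <- c(4, 2, 9, 1, 3, 8, 5, 7, 6)
  m2 <- build_character_matrix(rec[perm, ])
  expect_identical(m2$taxa, rec$taxon[perm])
  for (tx in rec$taxon)
    for (ch in c("x", "nor_position"))
      expect_identical(cell_states(m1, tx, ch), cell_states(m2, tx, ch))
})

test_that("cells outside the declared alphabet are rejected", {
  expect_error(character_matrix("t1", "c1", list(list("Z")),
                                alphabets = list(c1 = c("0", "1"))),
               "outside alphabet")
  m <- one_char_matrix(list(a = "0", b = "1"), c("0", "1"))
  expect_error(cell_states(m, "a", "nope"), "unknown character")
})
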