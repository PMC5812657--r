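#' Load the packaged Cophomantini cytogenetic dataset
#'
#' The dataset transcribes, from the source study's main text only, the
#' karyotypes of the 28 newly studied species (3 \emph{Hyloscirtus}, 25
#' \emph{Boana}), the literature records named in the text, a triploid
#' \emph{Boana pulchella} specimen, the per-genus taxonomy and C-band
#' registries, the NOR homology mapping, the coded two-character matrix
#' (basic number x; NOR-bearing pair) and the condensed reference phylogeny.
#' Non-cophomantine clades enter as condensed modal tips so the Hylinae
#' node exists on the tree. No value absent from the main text is invented:
#' where prose is silent a field is MISSING.
#'
#' @return A list: `species` (record table), `karyotypes` (named list of
#'   [karyotype()] objects for the newly studied taxa), `matrix`
#'   (the coded [character_matrix()]), `tree` (condensed `phylo`),
#'   `taxonomy_registry`, `cband_registry`, `mapping` (NOR homology rules).
#' @export
load_cophomantini <- function() {
  path <- function(f) system.file("extdata", f, package = "karyevo",
                                  mustWork = TRUE)
  species <- utils::read.csv(path("cophomantini_species.csv"),
                             stringsAsFactors = FALSE, na.strings = "")
  species$studied_here <- as.logical(species$studied_here)
  species$caution <- as.logical(species$caution)
  karyotypes <- read_karyotype_csv(path("cophomantini_karyotypes.csv"))
  matrix <- read_matrix(path("cophomantini_matrix.nex"), "nexus")
  tree <- parse_newick(file = path("cophomantini_tree.nwk"))
  taxonomy <- utils::read.csv(path("taxonomy_registry.csv"),
                              stringsAsFactors = FALSE)
  cband <- utils::read.csv(path("cband_registry.csv"),
                           stringsAsFactors = FALSE)
  mapping <- read_nor_mapping(path("nor_mapping.json"))
  list(species = species, karyotypes = karyotypes, matrix = matrix,
       tree = tree, taxonomy_registry = taxonomy, cband_registry = cband,
       mapping = mapping)
}

#' Rebuild the coded character matrix from the species records
#'
#' Applies [build_character_matrix()] to the species-level records
#' (specimen-level rows excluded); the result regenerates the shipped
#' matrix byte-identically.
#'
#' @param dataset Output of [load_cophomantini()].
#' @return A [character_matrix()].
#' @export
rebuild_cophomantini_matrix <- function(dataset = load_cophomantini()) {
  tax <- dataset$species[dataset$species$taxon_level != "specimen", ]
  build_character_matrix(
    data.frame(taxon = tax$taxon, genus = tax$genus,
               x = suppressWarnings(as.integer(tax$x)),
               nor_pairs = tax$nor_pairs, stringsAsFactors = FALSE),
    mapping = dataset$mapping)
}

#' Per-genus counts over the species records
#'
#' Counts species by genus under a filter. Record-derived filters
#' (`studied_here`, `technique:<name>`, `group:<name>`, `all`) count
#' species-level rows of the record table (specimen-level rows belong to an
#' already-counted species and are skipped); the `c_band_known` filter
#' serves the packaged per-genus C-band review totals, which summarize
#' literature beyond the record rows.
#'
#' @param records The `species` record table (see [load_cophomantini()]).
#' @param filter One of "all", "studied_here", "c_band_known",
#'   "technique:<name>", "group:<name>". NULL counts all records.
#' @param genus Optional single genus; returns that genus' count.
#' @param cband_registry Packaged C-band totals; defaults to the shipped
#'   registry (required only for `c_band_known`).
#' @return A named integer vector of per-genus counts plus `total`, or a
#'   single count when `genus` is given.
#' @export
registry_counts <- function(records, filter = "all", genus = NULL,
                            cband_registry = NULL) {
  if (is.null(filter)) filter <- "all"
  if (filter == "c_band_known") {
    if (is.null(cband_registry))
      cband_registry <- load_cophomantini()$cband_registry
    counts <- stats::setNames(as.integer(cband_registry$c_band_species),
                              cband_registry$genus)
  } else {
    if ("taxon_level" %in% names(records))
      records <- records[records$taxon_level != "specimen", , drop = FALSE]
    keep <- if (filter == "all") rep(TRUE, nrow(records))
    else if (filter == "studied_here") records$studied_here %in% TRUE
    else if (startsWith(filter, "technique:")) {
      tech <- sub("^technique:", "", filter)
      vapply(records$techniques, function(t)
        !is.na(t) && tech %in% strsplit(t, ";", fixed = TRUE)[[1]],
        logical(1), USE.NAMES = FALSE)
    } else if (startsWith(filter, "group:")) {
      g <- sub("^group:", "", filter)
      records$species_group %in% g
    } else stop("config error: unknown filter key '", filter, "'")
    sub <- records[keep, , drop = FALSE]
    counts <- if (nrow(sub) == 0) integer(0)
              else table(sub$genus)
    counts <- stats::setNames(as.integer(counts), names(counts))
  }
  full <- c(counts, total = sum(counts))
  if (!is.null(genus)) {
    return(if (genus %in% names(full)) full[[genus]] else 0L)
  }
  full
}

#' Described-species taxonomy registry consistency
#'
#' @param taxonomy_registry Data.frame genus / described_species.
#' @return The total described-species count (sum over genera).
#' @export
taxonomy_total <- function(taxonomy_registry) {
  sum(as.integer(taxonomy_registry$described_species))
}
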