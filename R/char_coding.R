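#' Default NOR homology mapping
#'
#' Rules translating a raw NOR-bearing pair number into a coded character
#' state. The default encodes the homology hypotheses used throughout the
#' package:
#' \itemize{
#'   \item pair-4 NORs in \emph{Bokermannohyla alvarengai},
#'     \emph{Hyloscirtus alytolylax} and \emph{H. palmeri} are conspicuously
#'     different (4 centromere-proximal vs 4p vs 4q) and are coded as three
#'     taxon-private states `4a`, `4b`, `4c` — independent transformations
#'     on an unordered character, with no step matrix needed;
#'   \item pair-9 NORs are treated as homeologous to the small NOR-bearing
#'     pair 11 of most cophomantines and recoded as state `11`;
#'   \item medium-pair NORs (pairs 6 or 7): under `medium_rule = "genus"`
#'     (default) observations collapse to one genus-scoped medium-pair
#'     state — `6` within \emph{Aplastodiscus} (whose pair 6/7 NORs are
#'     apparently homeologous) and `7` within \emph{Boana}; under
#'     `medium_rule = "literal"` raw pair numbers are kept as printed.
#' }
#' Rule precedence is species > genus > global; the first matching rule in
#' that order wins, and a raw pair with no applicable rule is a coding error.
#'
#' @param medium_rule "genus" (default) or "literal".
#' @return An object of class `nor_state_mapping`: a rules data.frame and
#'   the declared coded-state alphabet.
#' @export
default_nor_mapping <- function(medium_rule = c("genus", "literal")) {
  medium_rule <- match.arg(medium_rule)
  rules <- rbind(
    data.frame(scope_type = "species", scope = "Bokermannohyla_alvarengai",
               raw = "4", state = "4a", stringsAsFactors = FALSE),
    data.frame(scope_type = "species", scope = "Hyloscirtus_alytolylax",
               raw = "4", state = "4b", stringsAsFactors = FALSE),
    data.frame(scope_type = "species", scope = "Hyloscirtus_palmeri",
               raw = "4", state = "4c", stringsAsFactors = FALSE),
    data.frame(scope_type = "*", scope = "*", raw = "9", state = "11",
               stringsAsFactors = FALSE))
  if (medium_rule == "genus") {
    rules <- rbind(rules,
      data.frame(scope_type = "genus", scope = "Aplastodiscus",
                 raw = c("6", "7", "6or7"), state = "6",
                 stringsAsFactors = FALSE),
      data.frame(scope_type = "genus", scope = "Boana",
                 raw = "7", state = "7", stringsAsFactors = FALSE))
  } else {
    rules <- rbind(rules,
      data.frame(scope_type = "*", scope = "*", raw = c("6", "7"),
                 state = c("6", "7"), stringsAsFactors = FALSE))
  }
  identity_states <- c("1", "2", "6", "8", "11", "12")
  rules <- rbind(rules,
    data.frame(scope_type = "*", scope = "*", raw = identity_states,
               state = identity_states, stringsAsFactors = FALSE))
  structure(list(rules = rules,
                 alphabet = c("1", "2", "4a", "4b", "4c", "6", "7", "8",
                              "11", "12"),
                 medium_rule = medium_rule),
            class = "nor_state_mapping")
}

#' Read a NOR homology mapping from a JSON config document
#'
#' The document holds `rules` (array of objects with scope_type, scope,
#' raw, state) and `alphabet` (array of coded states).
#'
#' @param path JSON file path.
#' @return A `nor_state_mapping`.
#' @export
read_nor_mapping <- function(path) {
  doc <- jsonlite::fromJSON(path)
  rules <- as.data.frame(doc$rules, stringsAsFactors = FALSE)
  for (cn in c("scope_type", "scope", "raw", "state"))
    rules[[cn]] <- as.character(rules[[cn]])
  m <- structure(list(rules = rules, alphabet = as.character(doc$alphabet),
                      medium_rule = doc$medium_rule %||% "custom"),
                 class = "nor_state_mapping")
  bad <- setdiff(rules$state, m$alphabet)
  if (length(bad) > 0)
    stop("mapping states outside declared alphabet: ",
         paste(bad, collapse = ", "))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

apply_nor_rule <- function(mapping, taxon, genus, raw) {
  r <- mapping$rules
  hit <- r[r$scope_type == "species" & r$scope == taxon & r$raw == raw, ]
  if (nrow(hit) == 0)
    hit <- r[r$scope_type == "genus" & !is.na(genus) & r$scope == genus &
             r$raw == raw, ]
  if (nrow(hit) == 0)
    hit <- r[r$scope_type == "*" & r$raw == raw, ]
  if (nrow(hit) == 0)
    stop("coding error: no NOR homology rule for raw pair '", raw,
         "' in taxon ", taxon)
  st <- unique(hit$state)
  if (length(st) > 1)
    stop("coding error: raw pair '", raw, "' maps to multiple states for ",
         taxon)
  st
}

#' Taxa-by-characters matrix of unordered multistate characters
#'
#' Cells are non-empty state sets (character vectors); a missing entry is
#' `NA`. Every character carries an explicit state alphabet; all characters
#' are unordered.
#'
#' @param taxa Ordered unique taxon labels.
#' @param characters Ordered character labels.
#' @param cells A list-matrix (taxa x characters) of state vectors or a
#'   list of per-character lists.
#' @param alphabets Named list: per character, its state alphabet.
#' @return An object of class `character_matrix`.
#' @export
character_matrix <- function(taxa, characters, cells, alphabets) {
  if (anyDuplicated(taxa)) stop("taxa labels must be unique")
  if (!is.matrix(cells)) {
    m <- matrix(vector("list", length(taxa) * length(characters)),
                nrow = length(taxa), ncol = length(characters))
    for (j in seq_along(characters))
      for (i in seq_along(taxa)) m[[i, j]] <- cells[[j]][[i]]
    cells <- m
  }
  dimnames(cells) <- list(taxa, characters)
  for (j in seq_along(characters)) {
    ab <- alphabets[[characters[j]]]
    for (i in seq_along(taxa)) {
      s <- cells[[i, j]]
      if (is.null(s) || (length(s) == 1 && is.na(s))) { cells[[i, j]] <- NA_character_; next }
      if (length(s) == 0) stop("empty (non-missing) state set for ", taxa[i])
      if (!all(s %in% ab))
        stop("state(s) ", paste(setdiff(s, ab), collapse = ","),
             " outside alphabet of character ", characters[j],
             " (taxon ", taxa[i], ")")
    }
  }
  structure(list(taxa = taxa, characters = characters, cells = cells,
                 alphabets = alphabets,
                 ordering = stats::setNames(rep("unordered",
                                                length(characters)),
                                            characters)),
            class = "character_matrix")
}

#' @export
print.character_matrix <- function(x, ...) {
  cat(sprintf("character_matrix: %d taxa x %d characters (%s)\n",
              length(x$taxa), length(x$characters),
              paste(x$characters, collapse = ", ")))
  invisible(x)
}

#' States of one matrix cell
#' @param matrix A [character_matrix()].
#' @param taxon,character Row/column labels.
#' @return Character vector of states, or `NA` if missing.
#' @export
cell_states <- function(matrix, taxon, character) {
  if (!character %in% matrix$characters)
    stop("unknown character: ", character)
  if (!taxon %in% matrix$taxa) stop("unknown taxon: ", taxon)
  matrix$cells[[taxon, character]]
}

#' Code the basic chromosome number x as an unordered character
#'
#' One state per taxon from the alphabet {9, 10, 11, 12, 13}; taxa without
#' data are MISSING. A basic number outside the alphabet is a coding error
#' naming the taxon.
#'
#' @param records A data.frame with columns `taxon` and `x` (integer or NA).
#' @param alphabet Permitted states, as character.
#' @return A list of per-taxon state vectors (length-1 or `NA`), named by
#'   taxon, suitable as a [character_matrix()] column.
#' @export
encode_basic_number <- function(records,
                                alphabet = as.character(9:13)) {
  out <- vector("list", nrow(records))
  names(out) <- records$taxon
  for (i in seq_len(nrow(records))) {
    x <- records$x[i]
    if (is.na(x)) { out[[i]] <- NA_character_; next }
    s <- as.character(as.integer(x))
    if (!s %in% alphabet)
      stop("coding error: basic number ", s, " outside alphabet for taxon ",
           records$taxon[i])
    out[[i]] <- s
  }
  out
}

#' Code the NOR-bearing pair as an unordered character
#'
#' Applies a [default_nor_mapping()]-style rule set to each taxon's raw
#' NOR-bearing pair(s). Polymorphic NORs (several raw pairs, separated by
#' ";") become multi-state cells; taxa without NOR data are MISSING.
#'
#' @param records A data.frame with columns `taxon`, `genus` and
#'   `nor_pairs` (semicolon-separated raw pair numbers, or NA).
#' @param mapping A `nor_state_mapping`.
#' @return A named list of per-taxon coded state vectors.
#' @export
encode_nor_position <- function(records, mapping = default_nor_mapping()) {
  out <- vector("list", nrow(records))
  names(out) <- records$taxon
  for (i in seq_len(nrow(records))) {
    raw <- records$nor_pairs[i]
    if (is.na(raw) || raw == "") { out[[i]] <- NA_character_; next }
    raws <- strsplit(raw, ";", fixed = TRUE)[[1]]
    states <- unique(vapply(raws, function(r)
      apply_nor_rule(mapping, records$taxon[i], records$genus[i], trimws(r)),
      character(1)))
    out[[i]] <- sort_states(states, mapping$alphabet)
  }
  out
}

## order a state set by its alphabet position (canonical cell form)
sort_states <- function(states, alphabet) {
  states[order(match(states, alphabet))]
}

#' Build the two-character matrix (x, nor_position) from species records
#'
#' @param records A data.frame with columns `taxon`, `genus`, `x`,
#'   `nor_pairs`.
#' @param mapping NOR homology rules.
#' @param x_alphabet Permitted basic-number states.
#' @return A [character_matrix()] with characters `x` and `nor_position`.
#' @export
build_character_matrix <- function(records, mapping = default_nor_mapping(),
                                   x_alphabet = as.character(9:13)) {
  xs <- encode_basic_number(records, x_alphabet)
  nors <- encode_nor_position(records, mapping)
  character_matrix(records$taxon, c("x", "nor_position"),
                   list(xs, nors),
                   alphabets = list(x = x_alphabet,
                                    nor_position = mapping$alphabet))
}
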