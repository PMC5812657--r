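#' Column order of the karyotype CSV dialect
#'
#' One row per homologue half-record or pair, plus one row per B chromosome
#' (`b_flag = TRUE`). UTF-8, header required.
#' @export
KARYO_CSV_COLUMNS <- c("species", "group", "source", "sex_system", "ploidy",
                       "pair_index", "homologue", "p_len", "q_len", "ci",
                       "morphology", "rel_length", "nor_arm", "nor_position",
                       "bands", "b_flag", "b_stable")

#' Write karyotypes to the package CSV dialect
#'
#' One row per homologue half-record, one extra row per B chromosome.
#' Numeric fields are written at full precision so that
#' [read_karyotype_csv()] reproduces every field bit-identically.
#'
#' @param karyos A single [karyotype()] or a list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_karyotype_csv <- function(karyos, path) {
  if (inherits(karyos, "karyotype")) karyos <- list(karyos)
  rows <- lapply(karyos, function(k) {
    pair_rows <- lapply(k$pairs, function(p) data.frame(
      species = k$species, group = k$group, source = k$source,
      sex_system = k$sex_system, ploidy = k$ploidy,
      pair_index = p$pair_index, homologue = p$homologue,
      p_len = p$p_len, q_len = p$q_len, ci = p$ci,
      morphology = p$morphology, rel_length = p$rel_length,
      nor_arm = p$nor_arm, nor_position = p$nor_position, bands = p$bands,
      b_flag = FALSE, b_stable = NA, stringsAsFactors = FALSE))
    b_rows <- lapply(k$b_chromosomes, function(b) data.frame(
      species = k$species, group = k$group, source = k$source,
      sex_system = k$sex_system, ploidy = k$ploidy,
      pair_index = NA_integer_, homologue = NA_character_,
      p_len = NA_real_, q_len = NA_real_, ci = b$ci,
      morphology = b$morphology, rel_length = b$rel_length,
      nor_arm = NA_character_, nor_position = NA_character_,
      bands = NA_character_, b_flag = TRUE, b_stable = b$mitotically_stable,
      stringsAsFactors = FALSE))
    do.call(rbind, c(pair_rows, b_rows))
  })
  df <- do.call(rbind, rows)
  num <- c("p_len", "q_len", "ci", "rel_length")
  for (cn in num) df[[cn]] <- format_full(df[[cn]])
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8", na = "")
  invisible(path)
}

## full-precision decimal rendering that survives a read/parse cycle exactly
format_full <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return(NA_character_)
    format(v, digits = 17, scientific = FALSE, trim = TRUE)
  }, character(1))
  out
}

#' Read karyotypes from the package CSV dialect
#'
#' Inverse of [write_karyotype_csv()] on its own output. `ci`, `morphology`
#' and `rel_length` are derived from the arm lengths when the columns are
#' empty; arms supplied in either order are oriented so that p <= q before
#' the centromeric index is computed.
#'
#' @param path CSV file path.
#' @param thresholds CI class bounds used for derivation.
#' @param derive When TRUE, fill in missing ci/morphology/rel_length from
#'   the arm lengths.
#' @return A named list of [karyotype()] objects, one per species.
#' @export
read_karyotype_csv <- function(path, thresholds = ci_thresholds(),
                               derive = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                        na.strings = "", colClasses = "character")
  missing_cols <- setdiff(setdiff(KARYO_CSV_COLUMNS, c("sex_system", "b_stable")),
                          names(df))
  if (length(missing_cols) > 0)
    stop("malformed karyotype CSV: missing columns ",
         paste(missing_cols, collapse = ", "))
  if (!"sex_system" %in% names(df)) df$sex_system <- NA_character_
  if (!"b_stable" %in% names(df)) df$b_stable <- NA
  for (cn in c("p_len", "q_len", "ci", "rel_length"))
    df[[cn]] <- as.numeric(df[[cn]])
  df$ploidy <- as.integer(df$ploidy)
  df$pair_index <- as.integer(df$pair_index)
  df$b_flag <- as.logical(df$b_flag)
  df$b_stable <- as.logical(df$b_stable)

  out <- list()
  for (sp in unique(df$species)) {
    sub <- df[df$species == sp, , drop = FALSE]
    prs <- sub[!sub$b_flag, , drop = FALSE]
    pairs <- lapply(seq_len(nrow(prs)), function(i) {
      r <- prs[i, ]
      p <- r$p_len; q <- r$q_len
      if (derive && !is.na(p) && !is.na(q) && p > q) { tmp <- p; p <- r$q_len; q <- tmp }
      ci <- r$ci
      if (derive && is.na(ci) && !is.na(p) && !is.na(q))
        ci <- centromeric_index(p, q)
      morph <- r$morphology
      if (derive && is.na(morph) && !is.na(ci))
        morph <- classify_morphology(ci, thresholds)
      chromosome_pair(r$pair_index, p_len = p, q_len = q, ci = ci,
                      morphology = morph, rel_length = r$rel_length,
                      homologue = r$homologue, nor_arm = r$nor_arm,
                      nor_position = r$nor_position, bands = r$bands,
                      thresholds = thresholds)
    })
    if (derive) {
      tot <- vapply(pairs, function(p) p$p_len + p$q_len, numeric(1))
      if (!any(is.na(tot))) {
        rel <- 100 * tot / sum(tot)
        for (i in seq_along(pairs))
          if (is.na(pairs[[i]]$rel_length)) pairs[[i]]$rel_length <- rel[i]
      }
    }
    bs <- sub[sub$b_flag, , drop = FALSE]
    b_list <- lapply(seq_len(nrow(bs)), function(i)
      b_chromosome(rel_length = bs$rel_length[i], ci = bs$ci[i],
                   morphology = bs$morphology[i],
                   mitotically_stable = bs$b_stable[i]))
    out[[sp]] <- karyotype(sp, pairs, ploidy = prs$ploidy[1],
                           group = prs$group[1], b_chromosomes = b_list,
                           sex_system = prs$sex_system[1],
                           source = prs$source[1])
  }
  out
}

#' Write idiogram coordinates as TSV
#'
#' @param coords Output of [idiogram_coords()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_idiogram_tsv <- function(coords, path) {
  utils::write.table(coords, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
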