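MATRIX_SYMBOLS <- strsplit("0123456789ABCDEFGHIJKLMNOPQRSTUVWXYZ", "")[[1]]

## per-character symbol table: alphabet state -> single output symbol
symbol_table <- function(alphabet) {
  if (length(alphabet) > length(MATRIX_SYMBOLS))
    stop("format error: character has more states (", length(alphabet),
         ") than available symbols")
  stats::setNames(MATRIX_SYMBOLS[seq_along(alphabet)], alphabet)
}

cell_to_symbols <- function(states, tab, poly_open, poly_close) {
  if (length(states) == 1 && is.na(states)) return("?")
  syms <- unname(tab[states])
  if (length(syms) == 1) return(syms)
  paste0(poly_open, paste(syms, collapse = ""), poly_close)
}

legend_lines <- function(matrix) {
  vapply(matrix$characters, function(ch) {
    tab <- symbol_table(matrix$alphabets[[ch]])
    paste0("KARYEVO-LEGEND char=", ch, " ",
           paste(paste0(unname(tab), "=", names(tab)), collapse = " "))
  }, character(1))
}

parse_legend <- function(lines) {
  lines <- grep("KARYEVO-LEGEND", lines, value = TRUE, fixed = TRUE)
  if (length(lines) == 0) stop("parse error: no state legend found")
  alphabets <- list()
  for (ln in lines) {
    ln <- sub(".*KARYEVO-LEGEND\\s+", "", ln)
    ln <- sub("[]'\\]]*$", "", ln)
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    ch <- sub("^char=", "", parts[1])
    kv <- strsplit(parts[-1], "=", fixed = TRUE)
    syms <- vapply(kv, `[`, character(1), 1)
    states <- vapply(kv, `[`, character(1), 2)
    alphabets[[ch]] <- stats::setNames(states, syms)
  }
  alphabets
}

#' Write a character matrix to NEXUS, TNT xread or CSV
#'
#' Non-numeric and multi-digit states are remapped per character to unique
#' single symbols; the symbol legend is embedded (as a comment in NEXUS/TNT,
#' as header lines in CSV) so [read_matrix()] restores the original state
#' names exactly. MISSING cells are written as `?`; polymorphic cells use
#' `{..}` in NEXUS, `[..]` in TNT and `/`-separated states in CSV.
#'
#' @param matrix A [character_matrix()].
#' @param path Output file path.
#' @param format "nexus", "tnt" or "csv".
#' @return `path`, invisibly.
#' @export
write_matrix <- function(matrix, path, format = c("nexus", "tnt", "csv")) {
  format <- match.arg(format)
  ntax <- length(matrix$taxa)
  nchar_ <- length(matrix$characters)
  if (ntax == 0 || nchar_ == 0) stop("format error: empty matrix")
  tabs <- lapply(matrix$characters, function(ch)
    symbol_table(matrix$alphabets[[ch]]))
  names(tabs) <- matrix$characters

  if (format == "csv") {
    lines <- c("#karyevo-matrix", paste0("#", legend_lines(matrix)),
               paste(c("taxon", matrix$characters), collapse = ","))
    for (i in seq_len(ntax)) {
      cells <- vapply(matrix$characters, function(ch) {
        s <- matrix$cells[[i, ch]]
        if (length(s) == 1 && is.na(s)) "?" else paste(s, collapse = "/")
      }, character(1))
      lines <- c(lines, paste(c(matrix$taxa[i], cells), collapse = ","))
    }
    writeLines(lines, path, useBytes = TRUE)
    return(invisible(path))
  }

  rows <- vapply(seq_len(ntax), function(i) {
    cells <- vapply(matrix$characters, function(ch)
      cell_to_symbols(matrix$cells[[i, ch]], tabs[[ch]],
                      if (format == "nexus") "{" else "[",
                      if (format == "nexus") "}" else "]"), character(1))
    paste0(format(matrix$taxa[i], width = max(nchar(matrix$taxa)) + 2),
           paste(cells, collapse = ""))
  }, character(1))

  if (format == "nexus") {
    syms <- sort(unique(unlist(lapply(tabs, unname))))
    lines <- c("#NEXUS", "",
               paste0("[", legend_lines(matrix), "]"),
               "", "BEGIN DATA;",
               sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", ntax, nchar_),
               sprintf("  FORMAT DATATYPE=STANDARD MISSING=? SYMBOLS=\"%s\";",
                       paste(syms, collapse = "")),
               "  MATRIX", paste0("    ", rows), "  ;", "END;")
  } else {
    lines <- c("xread",
               paste0("'", paste(legend_lines(matrix), collapse = "\n"), "'"),
               sprintf("%d %d", nchar_, ntax), rows, ";")
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

split_symbol_row <- function(body, poly_open, poly_close, line_no) {
  out <- character(0)
  i <- 1
  chars <- strsplit(body, "")[[1]]
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == poly_open) {
      j <- i + 1
      grp <- character(0)
      while (j <= length(chars) && chars[j] != poly_close) {
        grp <- c(grp, chars[j]); j <- j + 1
      }
      if (j > length(chars))
        stop("parse error at line ", line_no, ": unclosed polymorphism group")
      out <- c(out, paste(grp, collapse = ""))
      i <- j + 1
    } else {
      out <- c(out, ch)
      i <- i + 1
    }
  }
  out
}

decode_cell <- function(symgrp, alphabet_map, character, line_no) {
  if (symgrp == "?") return(NA_character_)
  syms <- strsplit(symgrp, "")[[1]]
  unknown <- setdiff(syms, names(alphabet_map))
  if (length(unknown) > 0)
    stop("parse error at line ", line_no, ": unknown symbol '",
         unknown[1], "' for character ", character)
  unname(alphabet_map[syms])
}

#' Read a character matrix written by [write_matrix()]
#'
#' Exact inverse of [write_matrix()] on its own output for every supported
#' format. Malformed input raises a parse error naming the offending line.
#'
#' @param path File path.
#' @param format "nexus", "tnt" or "csv".
#' @return A [character_matrix()].
#' @export
read_matrix <- function(path, format = c("nexus", "tnt", "csv")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (length(lines) == 0) stop("parse error: empty matrix file")

  if (format == "csv") {
    legend <- parse_legend(lines)
    body <- lines[!startsWith(lines, "#")]
    if (length(body) < 2) stop("parse error: no data rows")
    header <- strsplit(body[1], ",", fixed = TRUE)[[1]]
    characters <- header[-1]
    taxa <- character(0)
    cells <- lapply(characters, function(ch) list())
    names(cells) <- characters
    for (k in 2:length(body)) {
      f <- strsplit(body[k], ",", fixed = TRUE)[[1]]
      if (length(f) != length(header))
        stop("parse error at line ", k, ": expected ", length(header),
             " fields")
      taxa <- c(taxa, f[1])
      for (j in seq_along(characters)) {
        v <- f[j + 1]
        st <- if (v == "?") NA_character_
              else strsplit(v, "/", fixed = TRUE)[[1]]
        if (!all(is.na(st))) {
          bad <- setdiff(st, unname(legend[[characters[j]]]))
          if (length(bad) > 0)
            stop("parse error at line ", k, ": unknown state '", bad[1], "'")
        }
        cells[[characters[j]]][[length(taxa)]] <- st
      }
    }
    alphabets <- lapply(legend, unname)
    return(character_matrix(taxa, characters, cells, alphabets))
  }

  legend <- parse_legend(lines)
  characters <- names(legend)
  if (format == "nexus") {
    mstart <- grep("^\\s*MATRIX\\s*$", lines)
    if (length(mstart) != 1) stop("parse error: MATRIX block not found")
    rows <- character(0)
    taxa_lines <- integer(0)
    for (k in (mstart + 1):length(lines)) {
      ln <- trimws(lines[k])
      if (ln == ";" || grepl("^END;", ln)) break
      if (ln == "") next
      rows <- c(rows, ln); taxa_lines <- c(taxa_lines, k)
    }
    poly <- c("{", "}")
  } else {
    hdr <- grep("^\\s*\\d+\\s+\\d+\\s*$", lines)
    if (length(hdr) == 0) stop("parse error: TNT dimensions line not found")
    hdr <- hdr[1]
    rows <- character(0)
    taxa_lines <- integer(0)
    for (k in (hdr + 1):length(lines)) {
      ln <- trimws(lines[k])
      if (ln == ";") break
      if (ln == "") next
      rows <- c(rows, ln); taxa_lines <- c(taxa_lines, k)
    }
    poly <- c("[", "]")
  }
  if (length(rows) == 0) stop("parse error: no matrix rows")

  taxa <- character(0)
  cells <- lapply(characters, function(ch) list())
  names(cells) <- characters
  for (r in seq_along(rows)) {
    m <- regmatches(rows[r], regexec("^(\\S+)\\s+(\\S.*)$", rows[r]))[[1]]
    if (length(m) != 3)
      stop("parse error at line ", taxa_lines[r], ": malformed matrix row")
    taxa <- c(taxa, m[2])
    grps <- split_symbol_row(gsub("\\s", "", m[3]), poly[1], poly[2],
                             taxa_lines[r])
    if (length(grps) != length(characters))
      stop("parse error at line ", taxa_lines[r], ": expected ",
           length(characters), " characters, found ", length(grps))
    for (j in seq_along(characters))
      cells[[characters[j]]][[length(taxa)]] <-
        decode_cell(grps[j], legend[[characters[j]]], characters[j],
                    taxa_lines[r])
  }
  alphabets <- lapply(legend, unname)
  character_matrix(taxa, characters, cells, alphabets)
}

#' Test two character matrices for exact equality
#' @param a,b [character_matrix()] objects.
#' @return TRUE/FALSE.
#' @export
matrices_identical <- function(a, b) {
  if (!identical(a$taxa, b$taxa) || !identical(a$characters, b$characters))
    return(FALSE)
  if (!identical(lapply(a$alphabets, as.character),
                 lapply(b$alphabets, as.character))) return(FALSE)
  for (i in seq_along(a$taxa))
    for (j in seq_along(a$characters))
      if (!identical(a$cells[[i, j]], b$cells[[i, j]])) return(FALSE)
  TRUE
}
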