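#' Centromeric-index thresholds for chromosome morphology classes
#'
#' Default class limits on the centromeric index CI = p/(p + q). The limits
#' are the CI equivalents of the classical arm-ratio cut-offs 1.7, 3.0 and
#' 7.0: metacentric CI in \[0.37, 0.5\], submetacentric \[0.25, 0.37),
#' subtelocentric \[0.125, 0.25), telocentric \[0, 0.125). Lower bounds are
#' inclusive, so a pair at CI = 0.25 is submetacentric ("almost
#' subtelocentric").
#'
#' @param metacentric,submetacentric,subtelocentric Lower CI bound of each
#'   bi-armed class (inclusive). Values below the subtelocentric bound are
#'   telocentric.
#' @return A named numeric vector of class lower bounds, ordered from
#'   metacentric down to telocentric.
#' @export
ci_thresholds <- function(metacentric = 0.37, submetacentric = 0.25,
                          subtelocentric = 0.125) {
  th <- c(metacentric = metacentric, submetacentric = submetacentric,
          subtelocentric = subtelocentric, telocentric = 0)
  if (is.unsorted(rev(th), strictly = TRUE))
    stop("thresholds must decrease strictly from metacentric to telocentric")
  if (metacentric > 0.5) stop("metacentric lower bound cannot exceed 0.5")
  th
}

#' Morphology class labels, largest short arm first
#' @export
MORPHOLOGY_CLASSES <- c("metacentric", "submetacentric", "subtelocentric",
                        "telocentric")

#' Centromeric index of a chromosome
#'
#' CI = p / (p + q), where p is the short and q the long arm. By definition
#' p <= q, so the index lies in \[0, 0.5\]: 0.5 is a perfectly metacentric
#' chromosome, 0 a telocentric one. Inputs must already be oriented
#' (use [orient_arms()] when the measurement order is unknown).
#'
#' @param p_len Short-arm length (>= 0, any consistent unit).
#' @param q_len Long-arm length (> 0, same unit).
#' @return The centromeric index, a number in \[0, 0.5\]. Vectorized.
#' @examples
#' centromeric_index(1, 1)      # 0.5, metacentric symmetry
#' centromeric_index(0, 2.3)    # 0, telocentric limit
#' centromeric_index(0.41, 0.59)
#' @export
centromeric_index <- function(p_len, q_len) {
  if (any(p_len < 0) || any(q_len <= 0))
    stop("invalid measurement: arm lengths must satisfy p >= 0 and q > 0")
  if (any(p_len > q_len))
    stop("invalid measurement: p > q; orient arms so p is the short arm first")
  p_len / (p_len + q_len)
}

#' Orient a pair of arm measurements so that p <= q
#'
#' @param a,b Arm lengths in either order.
#' @return A list with components `p` and `q`, `p <= q` elementwise.
#' @export
orient_arms <- function(a, b) {
  list(p = pmin(a, b), q = pmax(a, b))
}

#' Classify chromosome morphology from the centromeric index
#'
#' Deterministic mapping of CI to {metacentric, submetacentric,
#' subtelocentric, telocentric} using inclusive lower bounds (see
#' [ci_thresholds()]).
#'
#' @param ci Centromeric index values in \[0, 0.5\].
#' @param thresholds Class bounds, as produced by [ci_thresholds()].
#' @return A character vector of class labels.
#' @examples
#' classify_morphology(c(0.41, 0.34, 0.25, 0.46))
#' @export
classify_morphology <- function(ci, thresholds = ci_thresholds()) {
  if (any(is.na(ci)) || any(ci < 0) || any(ci > 0.5))
    stop("ci outside [0, 0.5]")
  out <- character(length(ci))
  out[ci >= thresholds[["metacentric"]]] <- "metacentric"
  out[ci < thresholds[["metacentric"]] &
      ci >= thresholds[["submetacentric"]]] <- "submetacentric"
  out[ci < thresholds[["submetacentric"]] &
      ci >= thresholds[["subtelocentric"]]] <- "subtelocentric"
  out[ci < thresholds[["subtelocentric"]]] <- "telocentric"
  out
}

#' One homologous chromosome pair of a karyotype
#'
#' A pair carries its size rank (1 = largest), optionally arm lengths, the
#' centromeric index, the morphology class, the percent relative length,
#' an optional NOR annotation and free-form band descriptors. Heteromorphic
#' pairs are represented by two half-records sharing one `pair_index` and
#' distinguished by `homologue` ("A"/"B"); ordinary pairs use `homologue = NA`.
#'
#' @param pair_index Integer rank of the pair, 1 = largest.
#' @param p_len,q_len Optional oriented arm lengths (p <= q).
#' @param ci Centromeric index; derived from the arms when absent.
#' @param morphology Morphology class; derived from `ci` when absent.
#' @param rel_length Percent of the haploid A-complement length.
#' @param homologue "A", "B" or NA for a homomorphic pair.
#' @param nor_arm NOR-bearing arm: "p", "q" or "centromeric".
#' @param nor_position "terminal", "interstitial" or "centromeric".
#' @param bands Semicolon-separated categorical band descriptors.
#' @param thresholds CI class bounds used for derivation/consistency.
#' @return An object of class `chromosome_pair` (a named list).
#' @export
chromosome_pair <- function(pair_index, p_len = NA_real_, q_len = NA_real_,
                            ci = NA_real_, morphology = NA_character_,
                            rel_length = NA_real_, homologue = NA_character_,
                            nor_arm = NA_character_, nor_position = NA_character_,
                            bands = NA_character_,
                            thresholds = ci_thresholds()) {
  if (!is.na(p_len) && !is.na(q_len)) {
    if (p_len > q_len) stop("invalid measurement: p_len > q_len")
    derived_ci <- centromeric_index(p_len, q_len)
    if (is.na(ci)) ci <- derived_ci
    else if (abs(ci - derived_ci) > 5e-3)
      stop("supplied ci inconsistent with arm lengths for pair ", pair_index)
  }
  if (!is.na(ci)) {
    if (ci < 0 || ci > 0.5) stop("ci outside [0, 0.5] for pair ", pair_index)
    derived_m <- classify_morphology(ci, thresholds)
    if (is.na(morphology)) morphology <- derived_m
    else if (morphology != derived_m)
      stop("morphology '", morphology, "' inconsistent with ci ", ci,
           " for pair ", pair_index)
  }
  if (!is.na(morphology) && !morphology %in% MORPHOLOGY_CLASSES)
    stop("unknown morphology class: ", morphology)
  if (!is.na(rel_length) && rel_length <= 0)
    stop("rel_length must be positive for pair ", pair_index)
  structure(list(pair_index = as.integer(pair_index), p_len = p_len,
                 q_len = q_len, ci = ci, morphology = morphology,
                 rel_length = rel_length, homologue = homologue,
                 nor_arm = nor_arm, nor_position = nor_position,
                 bands = bands),
            class = "chromosome_pair")
}

#' A supernumerary (B) chromosome
#'
#' B chromosomes sit outside the standard (A) complement: they are excluded
#' from 2n, x, FN and from the 100% relative-length normalization; their
#' size is expressed against the A-complement haploid total.
#'
#' @param rel_length Percent of the A-complement haploid length.
#' @param ci Centromeric index in \[0, 0.5\].
#' @param morphology Morphology class; derived from `ci` when absent.
#' @param mitotically_stable Logical flag.
#' @return An object of class `b_chromosome`.
#' @export
b_chromosome <- function(rel_length, ci = NA_real_,
                         morphology = NA_character_,
                         mitotically_stable = NA) {
  if (!is.na(ci)) {
    if (ci < 0 || ci > 0.5) stop("B chromosome ci outside [0, 0.5]")
    if (is.na(morphology)) morphology <- classify_morphology(ci)
  }
  structure(list(rel_length = rel_length, ci = ci, morphology = morphology,
                 mitotically_stable = mitotically_stable),
            class = "b_chromosome")
}

#' A species' chromosome complement
#'
#' Bundles the ordered pair list with the complement-level quantities:
#' ploidy, basic number x (haploid pair count), somatic number 2n
#' (= ploidy * x), and optional B chromosomes and sex-system descriptor.
#'
#' @param species Taxon label.
#' @param pairs List of [chromosome_pair()] objects (half-records allowed).
#' @param ploidy Integer >= 1 (2 diploid, 3 triploid).
#' @param group Species-group label.
#' @param basic_number_x Haploid pair count; inferred from `pairs` if absent.
#' @param b_chromosomes Optional list of [b_chromosome()] objects.
#' @param sex_system Optional descriptor, e.g. "XY".
#' @param source "this_study" or "literature".
#' @return An object of class `karyotype`.
#' @export
karyotype <- function(species, pairs, ploidy = 2L, group = NA_character_,
                      basic_number_x = NULL, b_chromosomes = list(),
                      sex_system = NA_character_, source = "this_study") {
  idx <- vapply(pairs, function(p) p$pair_index, integer(1))
  if (is.null(basic_number_x)) basic_number_x <- length(unique(idx))
  structure(list(species = species, group = group, ploidy = as.integer(ploidy),
                 basic_number_x = as.integer(basic_number_x),
                 diploid_number_2n = as.integer(ploidy * basic_number_x),
                 pairs = pairs, b_chromosomes = b_chromosomes,
                 sex_system = sex_system, source = source),
            class = "karyotype")
}

#' @export
print.karyotype <- function(x, ...) {
  cat(sprintf("Karyotype of %s: 2n = %dx = %d, %d pairs, source: %s\n",
              x$species, x$ploidy, x$diploid_number_2n,
              x$basic_number_x, x$source))
  invisible(x)
}

## modal morphology per pair_index: heteromorphic half-records collapse to the
## morphology of homologue A (the commonly observed condition), ties broken by
## first occurrence.
pair_modal_morphology <- function(karyo) {
  idx <- vapply(karyo$pairs, function(p) p$pair_index, integer(1))
  vapply(sort(unique(idx)), function(i) {
    ps <- karyo$pairs[idx == i]
    m <- vapply(ps, function(p) p$morphology, character(1))
    if (length(ps) > 1L) {
      hom <- vapply(ps, function(p) p$homologue, character(1))
      if (any(!is.na(hom) & hom == "A")) return(m[which(!is.na(hom) & hom == "A")[1]])
    }
    m[1]
  }, character(1))
}

#' Fundamental number (FN) of a karyotype
#'
#' FN counts chromosome arms in the somatic complement: every bi-armed
#' chromosome (metacentric, submetacentric or subtelocentric) contributes
#' two arms, every telocentric one. Counts run over chromosomes
#' (pairs x ploidy); B chromosomes are excluded. Heteromorphic pairs use the
#' modal homologue. Bounds: 2n <= FN <= 2 * 2n.
#'
#' @param karyo A [karyotype()].
#' @return Integer FN.
#' @export
fundamental_number <- function(karyo) {
  m <- pair_modal_morphology(karyo)
  if (any(is.na(m)))
    stop("incomplete karyotype: missing morphology for some pairs of ",
         karyo$species)
  biarmed <- m %in% c("metacentric", "submetacentric", "subtelocentric")
  as.integer(karyo$ploidy * (2L * sum(biarmed) + sum(!biarmed)))
}

#' Percent relative lengths over the haploid A-complement
#'
#' Each pair's total length (p + q) as a percentage of the summed haploid
#' A-complement length. B chromosomes are measured against the same
#' A-complement denominator, so the A pairs alone sum to 100.
#'
#' @param karyo A [karyotype()] whose pairs carry arm lengths.
#' @return Numeric vector of percentages, one per pair (order of `pairs`).
#' @export
relative_lengths <- function(karyo) {
  tot <- vapply(karyo$pairs, function(p) p$p_len + p$q_len, numeric(1))
  if (any(is.na(tot)))
    stop("incomplete karyotype: arm lengths missing in ", karyo$species)
  denom <- sum(tot)
  if (denom <= 0) stop("degenerate input: zero-length complement")
  100 * tot / denom
}

#' Relative length of one pair or B chromosome
#'
#' @param pair A [chromosome_pair()] or [b_chromosome()]; a B chromosome must
#'   carry arm lengths in `p_len`/`q_len`-equivalent fields or a precomputed
#'   total via `total_length`.
#' @param karyo The [karyotype()] providing the A-complement denominator.
#' @param total_length Optional explicit total length of the element.
#' @return Percent of the haploid A-complement length.
#' @export
relative_length <- function(pair, karyo, total_length = NULL) {
  tot <- vapply(karyo$pairs, function(p) p$p_len + p$q_len, numeric(1))
  if (any(is.na(tot))) stop("incomplete karyotype: arm lengths missing")
  denom <- sum(tot)
  if (denom <= 0) stop("degenerate input: zero-length complement")
  num <- if (!is.null(total_length)) total_length else pair$p_len + pair$q_len
  100 * num / denom
}

#' Validate a karyotype against its structural invariants
#'
#' Reports (never raises) violations of: 2n = ploidy * x; pair count = x;
#' CI within \[0, 0.5\]; morphology consistent with CI under the supplied
#' thresholds; relative lengths summing to 100 (B chromosomes excluded);
#' FN bounds 2n <= FN <= 2 * 2n. Checks involving optional fields are
#' skipped where the fields are absent.
#'
#' @param karyo A [karyotype()].
#' @param thresholds CI class bounds.
#' @param tol Tolerance on the relative-length sum.
#' @return Character vector of violation messages; empty if all hold.
#' @export
validate_karyotype <- function(karyo, thresholds = ci_thresholds(),
                               tol = 1e-6) {
  v <- character(0)
  idx <- vapply(karyo$pairs, function(p) p$pair_index, integer(1))
  if (karyo$diploid_number_2n != karyo$ploidy * karyo$basic_number_x)
    v <- c(v, sprintf("diploid_number_2n: %d != ploidy %d x basic_number %d",
                      karyo$diploid_number_2n, karyo$ploidy,
                      karyo$basic_number_x))
  if (length(unique(idx)) != karyo$basic_number_x)
    v <- c(v, sprintf("pairs: %d distinct pair indices, basic_number_x is %d",
                      length(unique(idx)), karyo$basic_number_x))
  for (p in karyo$pairs) {
    if (!is.na(p$ci) && (p$ci < 0 || p$ci > 0.5))
      v <- c(v, sprintf("pair %d: ci %.3f outside [0, 0.5]", p$pair_index, p$ci))
    else if (!is.na(p$ci) && !is.na(p$morphology) &&
             classify_morphology(p$ci, thresholds) != p$morphology)
      v <- c(v, sprintf("pair %d: morphology '%s' inconsistent with ci %.3f",
                        p$pair_index, p$morphology, p$ci))
    if (!is.na(p$rel_length) && p$rel_length <= 0)
      v <- c(v, sprintf("pair %d: rel_length not positive", p$pair_index))
  }
  rel <- vapply(karyo$pairs, function(p) p$rel_length, numeric(1))
  hom <- vapply(karyo$pairs, function(p) p$homologue, character(1))
  keep <- is.na(hom) | hom == "A"   # one homologue per pair in the sum
  if (!any(is.na(rel[keep])) && length(rel[keep]) > 0 &&
      abs(sum(rel[keep]) - 100) > tol)
    v <- c(v, sprintf("rel_length: haploid complement sums to %.6f, not 100",
                      sum(rel[keep])))
  for (b in karyo$b_chromosomes)
    if (!is.na(b$ci) && (b$ci < 0 || b$ci > 0.5))
      v <- c(v, sprintf("B chromosome: ci %.3f outside [0, 0.5]", b$ci))
  m <- tryCatch(pair_modal_morphology(karyo), error = function(e) NA)
  if (!anyNA(m)) {
    fn <- fundamental_number(karyo)
    if (fn < karyo$diploid_number_2n || fn > 2L * karyo$diploid_number_2n)
      v <- c(v, sprintf("FN %d outside [2n, 2*2n] = [%d, %d]", fn,
                        karyo$diploid_number_2n, 2L * karyo$diploid_number_2n))
  }
  v
}

#' Idiogram drawing segments for a karyotype
#'
#' Pure geometry for a scaled idiogram: one rectangle per arm, split at the
#' centromere (p arm above y = 0, q arm below), heights proportional to
#' percent relative length. A telocentric pair yields a single q segment.
#' Band annotations are emitted as overlay segments. Renderer-agnostic.
#'
#' @param karyo A [karyotype()] whose pairs carry `rel_length` and `ci`.
#' @param width Rectangle width in x units.
#' @param gap Horizontal gap between pairs.
#' @return A data.frame with columns pair_index, segment ("p", "q" or
#'   "band"), x0, y0, x1, y1, annotation.
#' @export
idiogram_coords <- function(karyo, width = 0.6, gap = 1) {
  idx <- vapply(karyo$pairs, function(p) p$pair_index, integer(1))
  hom <- vapply(karyo$pairs, function(p) p$homologue, character(1))
  keep <- is.na(hom) | hom == "A"
  pairs <- karyo$pairs[keep][order(idx[keep])]
  rows <- list()
  for (k in seq_along(pairs)) {
    p <- pairs[[k]]
    if (is.na(p$rel_length))
      stop("incomplete karyotype: rel_length missing for pair ", p$pair_index)
    if (is.na(p$ci))
      stop("incomplete karyotype: ci missing for pair ", p$pair_index)
    x0 <- (k - 1) * gap
    p_h <- p$rel_length * p$ci          # short-arm share of the pair height
    q_h <- p$rel_length * (1 - p$ci)
    if (p_h > 0)
      rows[[length(rows) + 1L]] <- data.frame(
        pair_index = p$pair_index, segment = "p", x0 = x0, y0 = 0,
        x1 = x0 + width, y1 = p_h, annotation = NA_character_)
    rows[[length(rows) + 1L]] <- data.frame(
      pair_index = p$pair_index, segment = "q", x0 = x0, y0 = -q_h,
      x1 = x0 + width, y1 = 0, annotation = NA_character_)
    if (!is.na(p$bands)) {
      for (b in strsplit(p$bands, ";", fixed = TRUE)[[1]]) {
        rows[[length(rows) + 1L]] <- data.frame(
          pair_index = p$pair_index, segment = "band", x0 = x0,
          y0 = NA_real_, x1 = x0 + width, y1 = NA_real_, annotation = b)
      }
    }
  }
  do.call(rbind, rows)
}
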