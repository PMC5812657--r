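#' Simulate noisy karyotype arm-length measurements with known truth
#'
#' Emulates microscope measurement of a Giemsa-stained metaphase: true pair
#' lengths are drawn from a right-skewed positive (log-normal) distribution,
#' pairs are size-ranked (1 = largest), true centromere positions are drawn
#' uniformly, and each arm measurement receives independent multiplicative
#' log-normal noise — measurement error on chromosome arms scales with arm
#' size.
#'
#' @param n_pairs Number of pairs (>= 1).
#' @param meanlog,sdlog Log-normal parameters of the true total pair length.
#' @param ci_range True centromeric-index range sampled uniformly.
#' @param noise_sd Standard deviation of the per-arm multiplicative
#'   (log-scale) noise; 0 gives exact measurements.
#' @param seed Integer seed; same seed, same output.
#' @return A list with `measurements` (data.frame: pair_index, p_len, q_len
#'   ranked by measured size) and `truth` (data.frame: true lengths, true
#'   CI, true morphology, plus the noise level and seed as attributes).
#' @export
simulate_karyotype <- function(n_pairs, meanlog = log(10), sdlog = 0.5,
                               ci_range = c(0.02, 0.5), noise_sd = 0.05,
                               seed = 1) {
  if (n_pairs < 1) stop("config error: n_pairs must be >= 1")
  if (noise_sd < 0) stop("config error: noise_sd must be >= 0")
  if (sdlog < 0 || ci_range[1] < 0 || ci_range[2] > 0.5 ||
      ci_range[1] > ci_range[2])
    stop("config error: invalid length/ci parameters")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  total <- stats::rlnorm(n_pairs, meanlog, sdlog)
  true_ci <- stats::runif(n_pairs, ci_range[1], ci_range[2])
  ord <- order(total, decreasing = TRUE)
  total <- total[ord]; true_ci <- true_ci[ord]
  p_true <- total * true_ci
  q_true <- total * (1 - true_ci)
  p_meas <- p_true * exp(stats::rnorm(n_pairs, 0, noise_sd))
  q_meas <- q_true * exp(stats::rnorm(n_pairs, 0, noise_sd))
  o <- orient_arms(p_meas, q_meas)
  size_order <- order(o$p + o$q, decreasing = TRUE)
  ## measurement row j is the j-th largest *measured* pair; true_pair links
  ## it back to its row in the truth table (ranks can swap under noise)
  measurements <- data.frame(pair_index = seq_len(n_pairs),
                             p_len = o$p[size_order], q_len = o$q[size_order],
                             true_pair = size_order)
  truth <- data.frame(pair_index = seq_len(n_pairs),
                      p_true = p_true, q_true = q_true, ci_true = true_ci,
                      morphology_true = classify_morphology(true_ci))
  attr(truth, "noise_sd") <- noise_sd
  attr(truth, "seed") <- seed
  list(measurements = measurements, truth = truth)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Evolve an unordered discrete character along a tree
#'
#' The root state is uniform on the alphabet; along each branch the state
#' jumps, with probability `change_prob`, to a uniformly chosen different
#' state. A per-branch jump probability (rather than rate x branch length)
#' is used because condensed reference topologies carry no meaningful
#' branch lengths. The full realized history is recorded.
#'
#' @param tree A rooted `phylo`.
#' @param change_prob Per-branch change probability in \[0, 1).
#' @param alphabet Character states (>= 2).
#' @param seed Integer seed.
#' @return A list: `tip_states` (named character vector), `node_states`
#'   (all nodes), `changes` (data.frame parent, child, from, to of realized
#'   changes), `root_state`, `change_prob`, `seed`.
#' @export
simulate_character <- function(tree, change_prob, alphabet = c("0", "1"),
                               seed = 1) {
  if (length(alphabet) < 2) stop("input error: alphabet needs >= 2 states")
  if (change_prob < 0 || change_prob >= 1)
    stop("input error: change_prob must lie in [0, 1)")
  ntip <- length(tree$tip.label)
  if (is.null(tree$edge) || ntip < 2) stop("input error: degenerate tree")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  nnode <- ntip + tree$Nnode
  st <- character(nnode)
  root <- ntip + 1L
  st[root] <- sample(alphabet, 1)
  nn <- node_names(tree)
  ord <- order(node_depths(tree))
  changes <- list()
  for (v in ord) {
    if (v == root) next
    u <- tree$edge[match(v, tree$edge[, 2]), 1]
    if (stats::runif(1) < change_prob) {
      st[v] <- sample(setdiff(alphabet, st[u]), 1)
      changes[[length(changes) + 1L]] <- data.frame(
        parent = nn[u], child = nn[v], from = st[u], to = st[v],
        stringsAsFactors = FALSE)
    } else st[v] <- st[u]
  }
  changes <- if (length(changes)) do.call(rbind, changes)
             else data.frame(parent = character(0), child = character(0),
                             from = character(0), to = character(0))
  list(tip_states = stats::setNames(st[seq_len(ntip)], tree$tip.label),
       node_states = stats::setNames(st, nn),
       changes = changes, root_state = st[root],
       change_prob = change_prob, seed = seed)
}

## wrap simulated tip states as a one-character matrix
tip_states_matrix <- function(tip_states, alphabet,
                              character = "sim") {
  character_matrix(names(tip_states), character,
                   list(as.list(unname(tip_states))),
                   alphabets = stats::setNames(list(alphabet), character))
}

#' Parsimony root-state recovery experiment
#'
#' For each per-branch change probability on a grid, evolves `replicates`
#' characters on the tree, reconstructs each with [reconstruct()], and
#' summarizes: mean parsimony length, mean realized changes, root-recovery
#' frequency (true root state contained in the root MPR set) and root
#' ambiguity frequency.
#'
#' @param tree A rooted `phylo`.
#' @param change_probs Numeric grid of per-branch change probabilities.
#' @param replicates Replicates per grid point.
#' @param alphabet Character states.
#' @param seed Integer seed (replicate seeds are derived deterministically).
#' @return A data.frame with one row per grid point: change_prob,
#'   mean_length, mean_changes, recovery_freq, ambiguity_freq, replicates.
#' @export
recovery_experiment <- function(tree, change_probs = c(0, 0.05, 0.1, 0.2),
                                replicates = 100,
                                alphabet = as.character(0:3), seed = 1) {
  if (any(change_probs < 0 | change_probs >= 1))
    stop("config error: change_probs must lie in [0, 1)")
  rows <- lapply(seq_along(change_probs), function(gi) {
    cp <- change_probs[gi]
    lens <- changes <- numeric(replicates)
    recovered <- ambiguous <- logical(replicates)
    for (r in seq_len(replicates)) {
      sim <- simulate_character(tree, cp, alphabet,
                                seed = (seed * 1000L + gi * 101L + r) %% .Machine$integer.max)
      m <- tip_states_matrix(sim$tip_states, alphabet)
      rec <- reconstruct(tree, m, "sim")
      root_name <- node_names(tree)[length(tree$tip.label) + 1L]
      root_mpr <- rec$mpr[[root_name]]
      lens[r] <- rec$length
      changes[r] <- nrow(sim$changes)
      recovered[r] <- sim$root_state %in% root_mpr
      ambiguous[r] <- length(root_mpr) > 1
      if (rec$length > nrow(sim$changes))
        stop("internal error: parsimony length exceeded realized changes")
    }
    data.frame(change_prob = cp, mean_length = mean(lens),
               mean_changes = mean(changes), recovery_freq = mean(recovered),
               ambiguity_freq = mean(ambiguous), replicates = replicates)
  })
  do.call(rbind, rows)
}

#' Random character matrix generator (testing utility)
#'
#' Uniform random state sets over a random alphabet, with configurable
#' missing and polymorphic cell probabilities; used by the round-trip and
#' oracle property tests.
#'
#' @param n_taxa,n_characters Matrix dimensions.
#' @param n_states Alphabet size per character.
#' @param p_missing,p_poly Per-cell probabilities of MISSING and of a
#'   2-state polymorphic cell.
#' @param seed Integer seed.
#' @return A [character_matrix()].
#' @export
random_character_matrix <- function(n_taxa, n_characters = 2, n_states = 4,
                                    p_missing = 0.1, p_poly = 0.1, seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  taxa <- paste0("t", seq_len(n_taxa))
  chars <- paste0("c", seq_len(n_characters))
  alphabets <- stats::setNames(
    rep(list(as.character(seq_len(n_states) - 1L)), n_characters), chars)
  cells <- lapply(chars, function(ch) {
    lapply(seq_len(n_taxa), function(i) {
      u <- stats::runif(1)
      ab <- alphabets[[ch]]
      if (u < p_missing) NA_character_
      else if (u < p_missing + p_poly && n_states >= 2)
        sort_states(sample(ab, 2), ab)
      else sample(ab, 1)
    })
  })
  character_matrix(taxa, chars, cells, alphabets)
}
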