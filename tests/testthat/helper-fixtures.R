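## shared fixtures: random rooted trees (with polytomies), small matrices,
## and a fully measured synthetic karyotype

random_tree <- function(n_leaves, seed, polytomies = TRUE) {
  set.seed(seed)
  tr <- ape::rtree(n_leaves, rooted = TRUE)
  if (polytomies && n_leaves > 3) {
    tr$edge.length <- stats::runif(nrow(tr$edge))
    tr <- ape::di2multi(tr, tol = 0.35)
  }
  tr$edge.length <- NULL
  tr
}

## single-character matrix from a named state-set list
one_char_matrix <- function(states, alphabet, character = "c1") {
  character_matrix(names(states), character, list(unname(states)),
                   alphabets = stats::setNames(list(alphabet), character))
}

quartet_tree <- function() parse_newick("((A,B),(C,D));")

## a measured karyotype with exact arm lengths (arbitrary units)
measured_karyotype <- function(n_pairs = 6, seed = 42) {
  set.seed(seed)
  tot <- sort(stats::rlnorm(n_pairs, log(10), 0.4), decreasing = TRUE)
  ci <- stats::runif(n_pairs, 0.05, 0.5)
  pairs <- lapply(seq_len(n_pairs), function(i)
    chromosome_pair(i, p_len = tot[i] * ci[i], q_len = tot[i] * (1 - ci[i]),
                    rel_length = 100 * tot[i] / sum(tot)))
  karyotype(paste0("sim_sp_", seed), pairs, group = "sim_group")
}

## evaluate the cost of one full assignment (independent of reconstruct())
assignment_cost <- function(tree, assignment) {
  sum(vapply(seq_len(nrow(tree$edge)), function(e) {
    as.integer(assignment[[tree$edge[e, 1]]] != assignment[[tree$edge[e, 2]]])
  }, integer(1)))
}
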