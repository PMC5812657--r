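#' Parse a rooted Newick tree
#'
#' Thin validated wrapper around [ape::read.tree()]: polytomies and internal
#' node labels are preserved, branch lengths are ignored (parsimony uses
#' topology only). Unbalanced parentheses and duplicate leaf labels are
#' parse errors.
#'
#' @param text Newick string, or NULL to read from `file`.
#' @param file Path to a Newick file.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
parse_newick <- function(text = NULL, file = NULL) {
  if (is.null(text)) {
    if (is.null(file)) stop("supply text or file")
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close)
    stop("parse error: unbalanced parentheses in Newick")
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop("parse error: not a valid Newick tree")
  if (anyDuplicated(tree$tip.label))
    stop("parse error: duplicate leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  tree
}

## node display names: tips by label, internal nodes by label where present,
## otherwise "N<ape index>"
node_names <- function(tree) {
  ntip <- length(tree$tip.label)
  nn <- c(tree$tip.label, rep(NA_character_, tree$Nnode))
  if (!is.null(tree$node.label)) {
    lab <- tree$node.label
    lab[is.na(lab) | lab == ""] <- NA_character_
    nn[ntip + seq_len(tree$Nnode)] <- lab
  }
  idx <- which(is.na(nn))
  nn[idx] <- paste0("N", idx)
  nn
}

children_list <- function(tree) {
  nnode <- length(tree$tip.label) + tree$Nnode
  kids <- vector("list", nnode)
  for (e in seq_len(nrow(tree$edge)))
    kids[[tree$edge[e, 1]]] <- c(kids[[tree$edge[e, 1]]], tree$edge[e, 2])
  kids
}

## leaf state sets as a logical (node x state) matrix; missing = full alphabet
leaf_state_matrix <- function(tree, matrix, character, alphabet) {
  ntip <- length(tree$tip.label)
  L <- matrix(FALSE, nrow = ntip, ncol = length(alphabet))
  for (i in seq_len(ntip)) {
    tip <- tree$tip.label[i]
    if (!tip %in% matrix$taxa)
      stop("lookup error: tree leaf '", tip, "' absent from matrix")
    s <- cell_states(matrix, tip, character)
    if (length(s) == 1 && is.na(s)) L[i, ] <- TRUE
    else L[i, match(s, alphabet)] <- TRUE
  }
  L
}

#' Unordered-parsimony ancestral-state reconstruction
#'
#' Multifurcation-safe generalization of Fitch optimization (Hartigan's
#' count-based algorithm). The down pass selects, at each node, the states
#' attained by a maximal number of children and accrues
#' (children - maximal count) steps; the up pass converts the preliminary
#' sets into MPR sets — the states a node attains in at least one
#' minimum-step reconstruction. MISSING leaves carry the full alphabet at
#' zero cost; polymorphic leaf cells enter the down pass as given,
#' cost-free.
#'
#' @param tree A rooted `phylo` (polytomies allowed).
#' @param matrix A [character_matrix()].
#' @param character Character label to optimize.
#' @return An object of class `reconstruction`: list with `character`,
#'   `length` (minimum steps), `mpr` (named list of per-node MPR state
#'   sets, tips included), `node_names`, `transformations` (data.frame of
#'   branches whose MPR set changes: parent, child, from, to), and
#'   `ambiguous_nodes` (internal nodes with |MPR| > 1).
#' @export
reconstruct <- function(tree, matrix, character) {
  if (!character %in% matrix$characters)
    stop("lookup error: character '", character, "' absent from matrix")
  alphabet <- matrix$alphabets[[character]]
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  L <- leaf_state_matrix(tree, matrix, character, alphabet)
  non_missing <- sum(vapply(tree$tip.label, function(tip) {
    s <- cell_states(matrix, tip, character)
    !(length(s) == 1 && is.na(s))
  }, logical(1)))
  if (non_missing < 2)
    stop("degenerate input: fewer than 2 leaves with non-MISSING states for ",
         character)

  kids <- children_list(tree)
  K <- matrix(FALSE, nnode, length(alphabet))   # preliminary (down-pass) sets
  Lm1 <- matrix(FALSE, nnode, length(alphabet)) # states one vote short
  K[seq_len(ntip), ] <- L
  len <- 0L
  for (v in internal_postorder(tree)) {
    ch <- kids[[v]]
    counts <- colSums(K[ch, , drop = FALSE])
    M <- max(counts)
    K[v, ] <- counts == M
    Lm1[v, ] <- counts == M - 1
    len <- len + length(ch) - M
  }

  FM <- matrix(FALSE, nnode, length(alphabet))  # final MPR sets
  FM[root, ] <- K[root, ]
  ord <- order(node_depths(tree))               # root -> leaves
  for (v in ord) {
    if (v == root) next
    u <- tree$edge[match(v, tree$edge[, 2]), 1]
    if (all(K[v, ][FM[u, ]])) FM[v, ] <- FM[u, ]
    else FM[v, ] <- K[v, ] | (FM[u, ] & Lm1[v, ])
  }

  nn <- node_names(tree)
  mpr <- lapply(seq_len(nnode), function(v) alphabet[FM[v, ]])
  names(mpr) <- nn

  trans <- list()
  for (e in seq_len(nrow(tree$edge))) {
    u <- tree$edge[e, 1]; v <- tree$edge[e, 2]
    if (!identical(FM[u, ], FM[v, ]))
      trans[[length(trans) + 1L]] <- data.frame(
        parent = nn[u], child = nn[v],
        from = paste(alphabet[FM[u, ]], collapse = "/"),
        to = paste(alphabet[FM[v, ]], collapse = "/"),
        stringsAsFactors = FALSE)
  }
  trans <- if (length(trans)) do.call(rbind, trans)
           else data.frame(parent = character(0), child = character(0),
                           from = character(0), to = character(0))
  internal <- (ntip + 1L):nnode
  ambiguous <- nn[internal][rowSums(FM[internal, , drop = FALSE]) > 1]
  structure(list(character = character, length = as.integer(len), mpr = mpr,
                 node_names = nn, tree = tree, alphabet = alphabet,
                 transformations = trans, ambiguous_nodes = ambiguous),
            class = "reconstruction")
}

#' @export
print.reconstruction <- function(x, ...) {
  cat(sprintf("Parsimony reconstruction of '%s': length %d, %d ambiguous node(s)\n",
              x$character, x$length, length(x$ambiguous_nodes)))
  invisible(x)
}

## depth of every node from the root (root = 0); robust to edge ordering
node_depths <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  d <- rep(NA_real_, nnode)
  d[ntip + 1L] <- 0
  repeat {
    done <- TRUE
    for (e in seq_len(nrow(tree$edge))) {
      u <- tree$edge[e, 1]; v <- tree$edge[e, 2]
      if (!is.na(d[u]) && is.na(d[v])) { d[v] <- d[u] + 1; done <- FALSE }
    }
    if (done) break
  }
  d
}

## internal nodes ordered children-before-parents (deepest first)
internal_postorder <- function(tree) {
  ntip <- length(tree$tip.label)
  ints <- (ntip + 1L):(ntip + tree$Nnode)
  d <- node_depths(tree)
  ints[order(d[ints], decreasing = TRUE)]
}

#' Candidate synapomorphies and ambiguity report
#'
#' Branches on which the MPR set changes to a single state absent from the
#' parent's MPR set — a derived state fixed on the stem of the subtended
#' clade — plus the nodes left ambiguous (|MPR| > 1).
#'
#' @param result A [reconstruct()] result.
#' @param tree The tree the result was computed on (defaults to the one
#'   stored in the result).
#' @return A list with `synapomorphies` (data.frame: clade stem node, state,
#'   parent states, tip count of the clade) and `ambiguous_nodes`.
#' @export
synapomorphies <- function(result, tree = result$tree) {
  nn <- result$node_names
  rows <- list()
  for (k in seq_len(nrow(result$transformations))) {
    tr <- result$transformations[k, ]
    to_states <- strsplit(tr$to, "/", fixed = TRUE)[[1]]
    from_states <- strsplit(tr$from, "/", fixed = TRUE)[[1]]
    if (length(to_states) == 1 && !to_states %in% from_states) {
      v <- which(nn == tr$child)
      ntips <- if (v <= length(tree$tip.label)) 1L
               else length(clade_tips(tree, v))
      rows[[length(rows) + 1L]] <- data.frame(
        clade = tr$child, state = to_states, parent_states = tr$from,
        n_tips = ntips, stringsAsFactors = FALSE)
    }
  }
  syn <- if (length(rows)) do.call(rbind, rows)
         else data.frame(clade = character(0), state = character(0),
                         parent_states = character(0), n_tips = integer(0))
  list(synapomorphies = syn, ambiguous_nodes = result$ambiguous_nodes)
}

#' Tip labels subtended by a node
#' @param tree A `phylo`.
#' @param node ape node index (or internal node label).
#' @return Character vector of tip labels.
#' @export
clade_tips <- function(tree, node) {
  if (is.character(node)) {
    nn <- node_names(tree)
    node <- which(nn == node)
    if (length(node) != 1) stop("lookup error: node label not found")
  }
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  kids <- children_list(tree)
  acc <- character(0)
  stack <- node
  while (length(stack)) {
    v <- stack[1]; stack <- stack[-1]
    if (v <= ntip) acc <- c(acc, tree$tip.label[v])
    else stack <- c(stack, kids[[v]])
  }
  acc
}

#' Exhaustive-enumeration parsimony oracle
#'
#' Exact minimum number of state changes over all ancestral assignments,
#' by brute-force enumeration of every internal-node labelling. A leaf
#' contributes no cost when the adjoining internal state lies in its state
#' set (polymorphism/MISSING are satisfiable for free), one step otherwise.
#' Intended for testing on small instances only.
#'
#' @param tree A rooted `phylo`.
#' @param matrix A [character_matrix()].
#' @param character Character label.
#' @param max_assignments Enumeration cap; larger instances are a size
#'   error.
#' @param return_mpr When TRUE also return the exact per-internal-node MPR
#'   sets attained across all minimum-cost assignments.
#' @return The minimum length (integer), or a list(length, mpr) when
#'   `return_mpr = TRUE`.
#' @export
brute_force_length <- function(tree, matrix, character,
                               max_assignments = 2e6, return_mpr = FALSE) {
  alphabet <- matrix$alphabets[[character]]
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  ncomb <- length(alphabet)^nint
  if (ncomb > max_assignments)
    stop("size error: ", ncomb, " assignments exceed the enumeration cap")
  L <- leaf_state_matrix(tree, matrix, character, alphabet)
  edges <- tree$edge
  grid <- as.matrix(expand.grid(rep(list(seq_along(alphabet)), nint)))
  costs <- integer(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    assign <- grid[g, ]
    cost <- 0L
    for (e in seq_len(nrow(edges))) {
      u <- edges[e, 1]; v <- edges[e, 2]
      su <- assign[u - ntip]
      if (v <= ntip) cost <- cost + as.integer(!L[v, su])
      else cost <- cost + as.integer(assign[v - ntip] != su)
    }
    costs[g] <- cost
  }
  len <- min(costs)
  if (!return_mpr) return(as.integer(len))
  best <- grid[costs == len, , drop = FALSE]
  mpr <- lapply(seq_len(nint), function(j) alphabet[sort(unique(best[, j]))])
  names(mpr) <- node_names(tree)[ntip + seq_len(nint)]
  list(length = as.integer(len), mpr = mpr)
}

#' Resolve one most-parsimonious assignment (ACCTRAN/DELTRAN flavour)
#'
#' Picks a single jointly-optimal state per node via unit-cost Sankoff
#' subtree costs, breaking ties toward the parent state (DELTRAN, delaying
#' changes) or away from it (ACCTRAN, accelerating them).
#'
#' @param tree A rooted `phylo`.
#' @param matrix A [character_matrix()].
#' @param character Character label.
#' @param method "deltran" or "acctran".
#' @return Named character vector: one state per node.
#' @export
resolve_assignment <- function(tree, matrix, character,
                               method = c("deltran", "acctran")) {
  method <- match.arg(method)
  alphabet <- matrix$alphabets[[character]]
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  L <- leaf_state_matrix(tree, matrix, character, alphabet)
  BIG <- 1e9
  C <- matrix(0, nnode, length(alphabet))   # min subtree cost given state
  C[seq_len(ntip), ] <- ifelse(L, 0, BIG)
  ## leaves with any allowed state cost 0 in it; a mismatching parent pays on
  ## the edge below, handled via the child-min recursion
  kids <- children_list(tree)
  for (v in internal_postorder(tree)) {
    acc <- numeric(length(alphabet))
    for (w in kids[[v]]) {
      cw <- C[w, ]
      acc <- acc + pmin(cw, min(cw) + 1)
    }
    C[v, ] <- acc
  }
  out <- integer(nnode)
  root <- ntip + 1L
  cand <- which(C[root, ] == min(C[root, ]))
  out[root] <- cand[1]
  for (v in order(node_depths(tree))) {
    if (v == root) next
    u <- tree$edge[match(v, tree$edge[, 2]), 1]
    su <- out[u]
    tot <- C[v, ] + as.integer(seq_along(alphabet) != su)
    cand <- which(tot == min(tot))
    out[v] <- if (method == "deltran" && su %in% cand) su
              else if (method == "acctran" && any(cand != su)) cand[cand != su][1]
              else cand[1]
  }
  stats::setNames(alphabet[out], node_names(tree))
}

#' Write a reconstruction report as JSON
#'
#' Per-node MPR sets keyed by node label, the branch transformation list
#' and the tree length.
#'
#' @param result A [reconstruct()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reconstruction_json <- function(result, path) {
  jsonlite::write_json(
    list(character = result$character, length = result$length,
         mpr = result$mpr, transformations = result$transformations,
         ambiguous_nodes = result$ambiguous_nodes),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Annotated Newick with MPR sets as node comments
#'
#' @param result A [reconstruct()] result.
#' @return A Newick string in which every internal node label carries its
#'   MPR state set as `label|s1/s2`.
#' @export
annotated_newick <- function(result) {
  tree <- result$tree
  ntip <- length(tree$tip.label)
  nn <- result$node_names
  lab <- vapply((ntip + 1L):(ntip + tree$Nnode), function(v)
    paste0(nn[v], "|", paste(result$mpr[[v]], collapse = "/")),
    character(1))
  t2 <- tree
  t2$node.label <- lab
  ape::write.tree(t2)
}
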