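# Maximum-parsimony machinery over unrooted binary trees.
#
# Internal tree representation ("utree"): a list with
#   edge    - integer matrix (E x 2) of undirected node pairs
#   n_tip   - number of tips; tips are node ids 1..n_tip, internal ids are
#             any integers > n_tip (not necessarily contiguous)
# Character states are bitmasks (A=1, C=2, G=4, T=8; gap/missing = 15,
# i.e. full ambiguity, so a gap never forces a change).

CHAR_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L, "-" = 15L, N = 15L)

# encode alignment -> list(states = n_tip x n_pattern bitmask matrix,
#                          weights = pattern multiplicities)
encode_alignment <- function(aln) {
  m <- aln_matrix(aln)
  bits <- matrix(CHAR_BITS[m], nrow = nrow(m))
  if (anyNA(bits)) stop("alignment contains characters outside A,C,G,T,-")
  key <- apply(bits, 2, paste, collapse = ".")
  first <- !duplicated(key)
  weights <- as.vector(table(factor(key, levels = key[first])))
  list(states = bits[, first, drop = FALSE], weights = weights,
       tip_labels = rownames(m))
}

utree_triple <- function(i, j, k, n_tip) {
  list(edge = rbind(c(i, n_tip + 1L), c(j, n_tip + 1L), c(k, n_tip + 1L)),
       n_tip = n_tip)
}

# split edge `ei` with a new internal node and hang tip `tip` off it
attach_tip <- function(tree, tip, ei) {
  a <- tree$edge[ei, 1]; b <- tree$edge[ei, 2]
  new <- max(tree$edge, tree$n_tip) + 1L
  tree$edge <- rbind(tree$edge[-ei, , drop = FALSE],
                     c(a, new), c(new, b), c(tip, new))
  tree
}

# adjacency list keyed by node id
utree_adj <- function(tree) {
  nodes <- sort(unique(as.vector(tree$edge)))
  adj <- vector("list", max(nodes))
  for (i in seq_len(nrow(tree$edge))) {
    a <- tree$edge[i, 1]; b <- tree$edge[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# Fitch parsimony score of a utree given encoded states/weights.
# Roots at an arbitrary internal node and combines children pairwise; for
# the trifurcation arising from an unrooted binary tree this equals the
# rooting-invariant Fitch count.
fitch_score_utree <- function(tree, enc) {
  states <- enc$states; weights <- enc$weights
  S <- ncol(states)
  adj <- utree_adj(tree)
  nodes <- sort(unique(as.vector(tree$edge)))
  internal <- nodes[nodes > tree$n_tip]
  if (!length(internal)) {            # 2-tip tree
    inter <- bitwAnd(states[tree$edge[1, 1], ], states[tree$edge[1, 2], ])
    return(sum(weights[inter == 0L]))
  }
  root <- internal[1]
  # DFS over internal nodes; reversed visit order puts children first
  parent <- integer(max(nodes))          # 0 = no parent
  stack <- root; visit <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    visit <- c(visit, v)
    for (w in adj[[v]]) {
      if (w > tree$n_tip && w != parent[v]) {
        parent[w] <- v
        stack <- c(stack, w)
      }
    }
  }
  node_state <- vector("list", max(nodes))
  changes <- integer(S)
  for (v in rev(visit)) {
    st <- NULL
    for (w in adj[[v]]) {
      if (w == parent[v]) next
      ws <- if (w <= tree$n_tip) states[w, ] else node_state[[w]]
      if (is.null(st)) {
        st <- ws
      } else {
        inter <- bitwAnd(st, ws)
        zero <- inter == 0L
        changes[zero] <- changes[zero] + 1L
        st <- ifelse(zero, bitwOr(st, ws), inter)
      }
    }
    node_state[[v]] <- st
  }
  sum(changes * weights)
}

# all SPR neighbors of an unrooted binary utree
spr_neighbors <- function(tree) {
  E <- nrow(tree$edge)
  adj <- utree_adj(tree)
  deg <- vapply(seq_along(adj), function(i) length(adj[[i]]), 0L)
  out <- list()
  for (ei in seq_len(E)) {
    for (dir in 1:2) {
      u <- tree$edge[ei, dir]; v <- tree$edge[ei, 3 - dir]
      # prune the component containing v; u must be internal (degree 3)
      if (deg[u] != 3L) next
      # nodes of the pruned component (BFS from v avoiding u)
      comp <- v; frontier <- v
      while (length(frontier)) {
        nxt <- setdiff(unlist(adj[frontier]), c(comp, u))
        comp <- c(comp, nxt); frontier <- nxt
      }
      in_comp <- logical(max(tree$edge)); in_comp[comp] <- TRUE
      ab <- setdiff(adj[[u]], v)        # u's remaining neighbors
      # edges of the remaining tree after suppressing u
      keep <- !(tree$edge[, 1] == u | tree$edge[, 2] == u) &
        !(in_comp[tree$edge[, 1]] | in_comp[tree$edge[, 2]])
      rest <- rbind(tree$edge[keep, , drop = FALSE], ab)
      sub_keep <- in_comp[tree$edge[, 1]] & in_comp[tree$edge[, 2]]
      sub <- tree$edge[sub_keep, , drop = FALSE]
      # regraft onto every remaining edge except the suppression edge (ab)
      for (ti in seq_len(nrow(rest) - 1L)) {   # last row is ab
        p <- rest[ti, 1]; q <- rest[ti, 2]
        new_edge <- rbind(rest[-ti, , drop = FALSE],
                          c(p, u), c(u, q), c(u, v), sub)
        out[[length(out) + 1L]] <- list(edge = new_edge, n_tip = tree$n_tip)
      }
    }
  }
  out
}

# greedy stepwise addition for one addition order
stepwise_tree <- function(enc, order, n_tip) {
  tree <- utree_triple(order[1], order[2], order[3], n_tip)
  for (tip in order[-(1:3)]) {
    best <- NULL; best_len <- Inf
    for (ei in seq_len(nrow(tree$edge))) {
      cand <- attach_tip(tree, tip, ei)
      len <- fitch_score_utree(cand, enc)
      if (len < best_len) {
        best <- cand; best_len <- len
      }
    }
    tree <- best
  }
  tree
}

# first-improvement SPR hill climb
spr_climb <- function(tree, enc) {
  len <- fitch_score_utree(tree, enc)
  repeat {
    improved <- FALSE
    for (nb in spr_neighbors(tree)) {
      l2 <- fitch_score_utree(nb, enc)
      if (l2 < len) {
        tree <- nb; len <- l2; improved <- TRUE
        break
      }
    }
    if (!improved) break
  }
  list(tree = tree, length = len)
}

# enumerate all unrooted binary topologies over tips 1..n (n <= 7 sensible)
enumerate_topologies <- function(n) {
  stopifnot(n >= 3)
  trees <- list(utree_triple(1L, 2L, 3L, n))
  for (tip in seq(4L, length.out = max(0L, n - 3L))) {
    trees <- unlist(lapply(trees, function(tr) {
      lapply(seq_len(nrow(tr$edge)), function(ei) attach_tip(tr, tip, ei))
    }), recursive = FALSE)
  }
  trees
}

# non-trivial bipartitions of a utree, keyed by the sorted tip labels of
# the side not containing tip 1
utree_bipartitions <- function(tree, labels) {
  adj <- utree_adj(tree)
  out <- character(0)
  for (ei in seq_len(nrow(tree$edge))) {
    u <- tree$edge[ei, 1]; v <- tree$edge[ei, 2]
    comp <- v; frontier <- v
    while (length(frontier)) {
      nxt <- setdiff(unlist(adj[frontier]), c(comp, u))
      comp <- c(comp, nxt); frontier <- nxt
    }
    tips <- comp[comp <= tree$n_tip]
    if (1L %in% tips) tips <- setdiff(seq_len(tree$n_tip), tips)
    if (length(tips) < 2L || length(tips) > tree$n_tip - 2L) next
    out <- c(out, paste(sort(labels[tips]), collapse = "|"))
  }
  unique(out)
}

# newick string for a utree (rooted at the internal node adjacent to tip 1)
utree_newick <- function(tree, labels, node_labels = NULL) {
  adj <- utree_adj(tree)
  recurse <- function(v, from) {
    if (v <= tree$n_tip) return(labels[v])
    kids <- setdiff(adj[[v]], from)
    inner <- paste(vapply(kids, recurse, "", from = v), collapse = ",")
    lab <- if (!is.null(node_labels)) node_labels(v, from) else ""
    paste0("(", inner, ")", lab)
  }
  if (tree$n_tip == 2L) {
    return(paste0("(", labels[1], ",", labels[2], ");"))
  }
  root <- adj[[1L]][1L]
  kids <- setdiff(adj[[root]], 1L)
  paste0("(", labels[1L], ",",
         paste(vapply(kids, recurse, "", from = root), collapse = ","),
         ");")
}

utree_to_phylo <- function(tree, labels) {
  ape::read.tree(text = utree_newick(tree, labels))
}

phylo_to_utree <- function(phy, labels) {
  phy <- ape::unroot(phy)
  if (!setequal(phy$tip.label, labels)) {
    stop("tree tips do not match alignment samples")
  }
  n <- length(labels)
  perm <- match(phy$tip.label, labels)
  edge <- phy$edge
  remap <- function(z) ifelse(z <= n, perm[z], z)
  list(edge = cbind(remap(edge[, 1]), remap(edge[, 2])), n_tip = n)
}

restore_rng <- function(seed) {
  if (is.null(seed)) return(invisible(NULL))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

#' Fitch parsimony length of a topology
#'
#' Scores a fixed tree against a fingerprint alignment: the sum over
#' columns of the minimum number of character-state changes (Fitch
#' counting). Gaps are missing data — a gapped taxon can take any state
#' and never forces a change.
#'
#' @param topology an `ape::phylo` tree whose tip labels are exactly the
#'   alignment's sample ids (rooted trees are unrooted first).
#' @param aln a `fingerprint_alignment`.
#' @return integer parsimony length.
#' @export
fitch_length <- function(topology, aln) {
  stopifnot(inherits(aln, "fingerprint_alignment"))
  enc <- encode_alignment(aln)
  tree <- phylo_to_utree(topology, enc$tip_labels)
  fitch_score_utree(tree, enc)
}

#' Heuristic maximum-parsimony search
#'
#' For each of `n_random_additions` random addition orders, builds a
#' greedy stepwise-addition starting tree and then hill-climbs with
#' subtree-pruning-regrafting (SPR) rearrangements, taking the first
#' improving move until no rearrangement shortens the tree. The shortest
#' tree found across starts is reported; ties are broken by first find
#' under the seeded order, so results are reproducible given `seed`.
#'
#' @param aln a `fingerprint_alignment` with at least 4 samples.
#' @param n_random_additions number of random addition-order starts.
#' @param seed optional integer seed for the addition orders.
#' @return list of class `mp_tree` with `tree` (an `ape::phylo`),
#'   `length` (parsimony length), `n_starts`, and the internal `utree`.
#' @export
search_mp <- function(aln, n_random_additions = 10, seed = NULL) {
  stopifnot(inherits(aln, "fingerprint_alignment"))
  n <- length(aln$sample_ids)
  if (n < 4L) stop("maximum-parsimony search needs >= 4 samples")
  restore <- restore_rng(seed)
  if (!is.null(seed)) on.exit(restore())
  enc <- encode_alignment(aln)
  best <- NULL
  for (i in seq_len(n_random_additions)) {
    ord <- sample.int(n)
    res <- spr_climb(stepwise_tree(enc, ord, n), enc)
    if (is.null(best) || res$length < best$length) best <- res
  }
  structure(list(tree = utree_to_phylo(best$tree, aln$sample_ids),
                 length = best$length,
                 n_starts = n_random_additions,
                 utree = best$tree),
            class = "mp_tree")
}

#' @export
print.mp_tree <- function(x, ...) {
  cat("maximum-parsimony tree:", length(x$tree$tip.label), "tips, length",
      x$length, "\n")
  invisible(x)
}

#' Bootstrap support for a maximum-parsimony tree
#'
#' Resamples alignment columns with replacement, re-runs the parsimony
#' search on each replicate, and reports for every internal edge of the
#' reference tree the percentage of replicate best trees containing the
#' same bipartition.
#'
#' @param aln a `fingerprint_alignment`.
#' @param replicates number of bootstrap replicates.
#' @param seed optional integer seed (drives both the reference search,
#'   if needed, and the resampling).
#' @param n_random_additions addition-order starts per replicate search
#'   (a reduced count is customary inside the bootstrap).
#' @param tree optional `mp_tree` to annotate; found by [search_mp()] with
#'   10 starts when omitted.
#' @return list with `supports` (named numeric vector, percentages per
#'   bipartition of the reference tree), `tree` (the reference `mp_tree`),
#'   `phylo` (reference tree with node labels = supports), and
#'   `replicates`.
#' @export
bootstrap_support <- function(aln, replicates = 100, seed = NULL,
                              n_random_additions = 3, tree = NULL) {
  stopifnot(replicates >= 1)
  restore <- restore_rng(seed)
  if (!is.null(seed)) on.exit(restore())
  if (is.null(tree)) tree <- search_mp(aln, n_random_additions = 10)
  labels <- aln$sample_ids
  ref_bip <- utree_bipartitions(tree$utree, labels)
  hits <- stats::setNames(numeric(length(ref_bip)), ref_bip)
  m <- aln_matrix(aln)
  S <- ncol(m)
  for (r in seq_len(replicates)) {
    cols <- sample.int(S, S, replace = TRUE)
    rep_aln <- structure(list(sample_ids = labels,
                              seqs = unname(apply(m[, cols, drop = FALSE], 1,
                                                  paste, collapse = "")),
                              site_map = aln$site_map[cols, , drop = FALSE]),
                         class = "fingerprint_alignment")
    rep_tree <- search_mp(rep_aln, n_random_additions = n_random_additions)
    rep_bip <- utree_bipartitions(rep_tree$utree, labels)
    found <- ref_bip %in% rep_bip
    hits[found] <- hits[found] + 1
  }
  supports <- 100 * hits / replicates
  phylo <- annotate_supports(tree$utree, labels, supports)
  list(supports = supports, tree = tree, phylo = phylo,
       replicates = replicates)
}

# phylo with bootstrap percentages as internal-node labels
annotate_supports <- function(utree, labels, supports) {
  adj <- utree_adj(utree)
  node_lab <- function(v, from) {
    comp <- v; frontier <- v
    while (length(frontier)) {
      nxt <- setdiff(unlist(adj[frontier]), c(comp, from))
      comp <- c(comp, nxt); frontier <- nxt
    }
    tips <- comp[comp <= utree$n_tip]
    if (1L %in% tips) tips <- setdiff(seq_len(utree$n_tip), tips)
    if (length(tips) < 2L || length(tips) > utree$n_tip - 2L) return("")
    key <- paste(sort(labels[tips]), collapse = "|")
    if (key %in% names(supports)) format(supports[[key]], trim = TRUE) else ""
  }
  ape::read.tree(text = utree_newick(utree, labels, node_labels = node_lab))
}
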