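## phylogeny: binary presence/absence characters, Hamming distances, and
## maximum-parsimony clonal trees rooted at the all-zero ancestral state
## ("node 0", the unmutated urothelium).
##
## Characters are binary and scored with Fitch optimisation (reversible;
## the paper-style irreversible Dollo variant is not implemented -- see the
## methods vignette).  Internally the three possible Fitch state sets {0},
## {1}, {0,1} are encoded as integers 1, 2, 3 so set intersection/union are
## bitwAnd/bitwOr, vectorised across deduplicated character patterns with
## multiplicity weights.

#' Binarise a VAF matrix into presence/absence characters
#'
#' @param vafs a [vaf_matrix()].
#' @param threshold presence threshold in (0, 1); present iff
#'   `VAF >= threshold`.
#' @return list of class `character_matrix` with `m` (samples x mutations
#'   0/1 matrix; fields become samples) and `dropped` (count of all-absent
#'   mutation columns removed).
#' @export
binarize <- function(vafs, threshold = 0.01) {
  pres <- t(presence_matrix(vafs, threshold))
  keep <- colSums(pres) > 0L
  structure(list(m = (pres * 1L)[, keep, drop = FALSE],
                 dropped = sum(!keep)),
            class = "character_matrix")
}

#' Hamming distance matrix between samples
#'
#' @param chars a `character_matrix` (see [binarize()]) or a plain binary
#'   samples x characters matrix.
#' @return symmetric integer matrix of counts of differing characters.
#' @export
hamming_matrix <- function(chars) {
  m <- if (inherits(chars, "character_matrix")) chars$m else chars
  assert_that(is.matrix(m) && nrow(m) >= 2L, "need >= 2 samples")
  assert_that(all(m %in% c(0L, 1L)), "characters must be binary 0/1")
  d <- as.matrix(stats::dist(m, method = "manhattan"))
  storage.mode(d) <- "integer"
  d
}

## ---- internal Fitch machinery ------------------------------------------

## Deduplicate character columns into patterns with integer weights.
## Returns list(states = P x L integer matrix of leaf codes (1 = {0},
## 2 = {1}); leaf 1 is the all-zero ancestral leaf), w (weights),
## pattern_of (original character -> pattern row).
pack_patterns <- function(m) {
  key <- apply(m, 2L, paste, collapse = "")
  uniq <- !duplicated(key)
  pat <- m[, uniq, drop = FALSE]
  pattern_of <- match(key, key[uniq])
  w <- tabulate(pattern_of, nbins = sum(uniq))
  L <- nrow(m) + 1L
  states <- matrix(1L, ncol(pat), L)     # leaf 1: ancestral all-zero
  states[, -1L] <- t(pat) + 1L           # 0 -> code 1, 1 -> code 2
  list(states = states, w = w, pattern_of = pattern_of)
}

## Root an unrooted binary tree (edge list E, leaves 1..L present) at leaf 1
## and return traversal structure.
root_structure <- function(E, n_nodes) {
  adj <- vector("list", n_nodes)
  for (k in seq_len(nrow(E))) {
    a <- E[k, 1L]; b <- E[k, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  parent <- integer(n_nodes)
  order <- integer(0)
  stack <- 1L
  parent[1L] <- 0L
  seen <- logical(n_nodes)
  seen[1L] <- TRUE
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    order <- c(order, v)
    for (u in adj[[v]]) if (!seen[u]) {
      seen[u] <- TRUE
      parent[u] <- v
      stack <- c(stack, u)
    }
  }
  has_parent <- which(parent > 0L)
  children <- split(has_parent, parent[has_parent])
  list(adj = adj, parent = parent, preorder = order,
       children = children)
}

## Fitch downpass score of the tree in edge list E rooted at leaf 1.
## states: P x n_nodes-capable matrix of leaf codes; w: pattern weights.
## Returns list(score, S (node state-set codes), rs (root structure)).
fitch_down <- function(E, states, w, want_states = FALSE) {
  n_nodes <- max(E)
  present <- sort(unique(as.integer(E)))
  if (nrow(E) == 1L) {                    # two leaves, single edge
    a <- states[, E[1L, 1L]]; b <- states[, E[1L, 2L]]
    sc <- sum(w[bitwAnd(a, b) == 0L])
    if (!want_states) return(list(score = sc))
    S <- matrix(0L, length(w), n_nodes)
    S[, present] <- states[, present]
    rs <- root_structure(E, n_nodes)
    return(list(score = sc, S = S, rs = rs))
  }
  rs <- root_structure(E, n_nodes)
  S <- matrix(0L, nrow(states), n_nodes)
  sc <- 0
  po <- rev(rs$preorder)
  for (v in po) {
    kids <- rs$children[[as.character(v)]]
    if (is.null(kids)) {                  # leaf
      S[, v] <- states[, v]
    } else {
      a <- S[, kids[1L]]
      b <- if (length(kids) > 1L) S[, kids[2L]] else NULL
      if (is.null(b)) { S[, v] <- a; next }
      inter <- bitwAnd(a, b)
      emp <- inter == 0L
      sc <- sc + sum(w[emp])
      S[, v] <- ifelse(emp, bitwOr(a, b), inter)
    }
  }
  ## root contribution: leaf 1 carries state {0}; the edge (1, v0) adds a
  ## change wherever 0 is not in v0's downpass state set.
  v0 <- rs$children[["1"]]
  if (!is.null(v0)) {
    r <- S[, v0[1L]]
    sc <- sc + sum(w[bitwAnd(r, 1L) == 0L])
  }
  list(score = sc, S = if (want_states) S else NULL, rs = rs)
}

insert_leaf <- function(E, row, leaf, internal) {
  u <- E[row, 1L]; v <- E[row, 2L]
  E[row, ] <- c(u, internal)
  rbind(E, c(v, internal), c(leaf, internal))
}

## Exhaustive branch-and-bound search over all unrooted topologies.
enumerate_best <- function(states, w, L) {
  best <- Inf
  bestE <- NULL
  E0 <- rbind(c(1L, L + 1L), c(2L, L + 1L), c(3L, L + 1L))
  rec <- function(E, next_leaf, next_internal) {
    sc <- fitch_down(E, states, w)$score
    if (sc >= best) return(invisible())
    if (next_leaf > L) {
      best <<- sc
      bestE <<- E
      return(invisible())
    }
    for (row in seq_len(nrow(E))) {
      rec(insert_leaf(E, row, next_leaf, next_internal),
          next_leaf + 1L, next_internal + 1L)
    }
    invisible()
  }
  if (L == 3L) {
    best <- fitch_down(E0, states, w)$score
    bestE <- E0
  } else {
    rec(E0, 4L, L + 2L)
  }
  list(E = bestE, score = best)
}

## One stepwise-addition + NNI hill-climbing run.
stepwise_nni <- function(states, w, L, order_rest) {
  ord <- c(1L, order_rest)
  E <- rbind(c(ord[1L], L + 1L), c(ord[2L], L + 1L), c(ord[3L], L + 1L))
  next_internal <- L + 2L
  for (k in seq_along(ord)[-(1:3)]) {
    leaf <- ord[k]
    scores <- vapply(seq_len(nrow(E)), function(row) {
      fitch_down(insert_leaf(E, row, leaf, next_internal), states, w)$score
    }, numeric(1))
    E <- insert_leaf(E, which.min(scores), leaf, next_internal)
    next_internal <- next_internal + 1L
  }
  sc <- fitch_down(E, states, w)$score
  ## NNI hill climbing
  repeat {
    improved <- FALSE
    internal_edges <- which(E[, 1L] > L & E[, 2L] > L)
    for (k in internal_edges) {
      u <- E[k, 1L]; v <- E[k, 2L]
      nb_u <- setdiff(which(E[, 1L] == u | E[, 2L] == u), k)
      nb_v <- setdiff(which(E[, 1L] == v | E[, 2L] == v), k)
      if (length(nb_u) < 2L || length(nb_v) < 1L) next
      eu <- nb_u[1L]                       # edge carrying neighbour b of u
      b <- if (E[eu, 1L] == u) E[eu, 2L] else E[eu, 1L]
      for (ev in nb_v) {
        cnode <- if (E[ev, 1L] == v) E[ev, 2L] else E[ev, 1L]
        E2 <- E
        E2[eu, ] <- c(u, cnode)
        E2[ev, ] <- c(v, b)
        sc2 <- fitch_down(E2, states, w)$score
        if (sc2 < sc) {
          E <- E2
          sc <- sc2
          improved <- TRUE
          break
        }
      }
      if (improved) break
    }
    if (!improved) break
  }
  list(E = E, score = sc)
}

## ---- public API ---------------------------------------------------------

#' Maximum-parsimony clonal tree rooted at the ancestral state
#'
#' Builds an unrooted binary tree over the samples plus a pseudo-leaf
#' carrying the all-zero ancestral state, scores it with Fitch
#' optimisation, and roots it at that pseudo-leaf ("node0").  Edge lengths
#' are the character changes assigned to each edge by the Fitch
#' downpass/uppass most-parsimonious labelling (ties resolved toward the
#' parent, which propagates the ancestral state 0 downward).
#'
#' @param chars a `character_matrix` from [binarize()] or a binary
#'   samples x mutations matrix with row names.
#' @param method `"auto"` (exhaustive for <= 7 samples, else heuristic),
#'   `"exhaustive"` (global optimum by branch-and-bound enumeration,
#'   allowed up to 9 samples), or `"heuristic"` (stepwise addition under
#'   `seed` with `restarts` random addition orders, then
#'   nearest-neighbour-interchange hill climbing).
#' @param seed integer seed for the heuristic's random addition orders.
#' @param restarts number of stepwise-addition restarts (default 25).
#' @return list of class `clade_tree`: `edges` (data frame `parent, child,
#'   length` in node ids), `labels` (node id -> label; samples keep their
#'   names, the root is `"node0"`), `root` (node id of node0), `score`
#'   (total parsimony score), `per_character` (changes per input character),
#'   `n_samples`, `method`, and `leaf_states` (the character matrix used).
#' @export
parsimony_tree <- function(chars, method = c("auto", "exhaustive", "heuristic"),
                           seed = 1L, restarts = 25L) {
  method <- match.arg(method)
  m <- if (inherits(chars, "character_matrix")) chars$m else chars
  assert_that(is.matrix(m), "chars must be a matrix")
  assert_that(all(m %in% c(0L, 1L)), "characters must be binary 0/1")
  if (is.null(rownames(m))) rownames(m) <- paste0("S", seq_len(nrow(m)))
  n_samples <- nrow(m)
  if (n_samples < 2L) {
    labels <- c("node0", rownames(m))
    edges <- if (n_samples == 1L) {
      data.frame(parent = 1L, child = 2L, length = sum(m))
    } else data.frame(parent = integer(0), child = integer(0),
                      length = integer(0))
    return(structure(list(edges = edges, labels = labels, root = 1L,
                          score = if (n_samples == 1L) sum(m) else 0L,
                          per_character = if (ncol(m)) as.integer(m[1L, ])
                                          else integer(0),
                          n_samples = n_samples, method = "degenerate",
                          leaf_states = m),
                     class = "clade_tree"))
  }
  pk <- pack_patterns(m)
  L <- n_samples + 1L
  if (method == "auto") method <- if (n_samples <= 7L) "exhaustive" else "heuristic"
  if (method == "exhaustive") {
    assert_that(n_samples <= 9L,
                "exhaustive search limited to 9 samples (got %d)", n_samples)
    res <- enumerate_best(pk$states, pk$w, L)
  } else {
    old <- .Random.seed_guard(seed)
    on.exit(old(), add = TRUE)
    res <- NULL
    for (r in seq_len(restarts)) {
      ord <- 1L + sample.int(n_samples)
      cand <- stepwise_nni(pk$states, pk$w, L, ord)
      if (is.null(res) || cand$score < res$score) res <- cand
    }
  }
  finish_tree(res$E, res$score, pk, m, L, method)
}

## Final Fitch labelling, edge lengths, per-character changes, tree object.
finish_tree <- function(E, score, pk, m, L, method) {
  fd <- fitch_down(E, pk$states, pk$w, want_states = TRUE)
  n_nodes <- max(E)
  Fs <- matrix(0L, nrow(pk$states), n_nodes)   # final singleton codes
  pre <- fd$rs$preorder
  Fs[, 1L] <- 1L
  for (v in pre[-1L]) {
    p <- fd$rs$parent[v]
    fp <- Fs[, p]
    sv <- fd$S[, v]
    keep <- bitwAnd(sv, fp) != 0L
    Fs[, v] <- ifelse(keep, fp, sv)       # sv is a singleton when disjoint
  }
  parent <- ifelse(fd$rs$parent[E[, 2L]] == E[, 1L], E[, 1L], E[, 2L])
  child <- ifelse(parent == E[, 1L], E[, 2L], E[, 1L])
  diff_mat <- vapply(seq_len(nrow(E)),
                     function(k) (Fs[, parent[k]] != Fs[, child[k]]) * 1L,
                     integer(nrow(pk$states)))
  if (is.null(dim(diff_mat))) diff_mat <- matrix(diff_mat, nrow = 1L)
  elen <- as.integer(pk$w %*% diff_mat)
  per_pattern <- rowSums(diff_mat)
  per_character <- as.integer(per_pattern[pk$pattern_of])
  labels <- character(n_nodes)
  labels[1L] <- "node0"
  labels[2L:L] <- rownames(m)
  internal <- setdiff(seq_len(n_nodes), seq_len(L))
  labels[internal] <- paste0("node", seq_along(internal))
  structure(list(edges = data.frame(parent = parent, child = child,
                                    length = as.integer(elen)),
                 labels = labels, root = 1L, score = as.integer(score),
                 per_character = per_character,
                 n_samples = L - 1L, method = method, leaf_states = m),
            class = "clade_tree")
}

#' @export
print.clade_tree <- function(x, ...) {
  cat(sprintf("clade_tree: %d samples, parsimony score %d (%s)\n",
              x$n_samples, x$score, x$method))
  invisible(x)
}

#' Deterministic sample ordering from a clonal tree
#'
#' Depth-first leaf ordering from node0; at every node children are visited
#' by increasing subtree leaf count, ties broken by the alphabetically
#' smallest leaf label in the subtree.  Used to order heatmap rows.
#'
#' @param tree a `clade_tree`.
#' @return character vector of sample labels.
#' @export
tree_sample_order <- function(tree) {
  if (tree$n_samples == 0L) return(character(0))
  if (nrow(tree$edges) == 0L) return(tree$labels[-1L])
  kids <- split(tree$edges$child, tree$edges$parent)
  n_nodes <- length(tree$labels)
  is_leaf <- !(seq_len(n_nodes) %in% tree$edges$parent)
  info <- vector("list", n_nodes)
  walk_info <- function(v) {
    if (is_leaf[v]) {
      info[[v]] <<- list(size = 1L, min_label = tree$labels[v])
      return(info[[v]])
    }
    ch <- kids[[as.character(v)]]
    sub <- lapply(ch, walk_info)
    info[[v]] <<- list(size = sum(vapply(sub, `[[`, integer(1), "size")),
                       min_label = min(vapply(sub, `[[`, character(1),
                                              "min_label")))
    info[[v]]
  }
  walk_info(tree$root)
  out <- character(0)
  walk <- function(v) {
    if (is_leaf[v]) {
      if (v != tree$root) out <<- c(out, tree$labels[v])
      return(invisible())
    }
    ch <- kids[[as.character(v)]]
    sizes <- vapply(ch, function(u) info[[u]]$size, integer(1))
    labs <- vapply(ch, function(u) info[[u]]$min_label, character(1))
    for (u in ch[order(sizes, labs)]) walk(u)
  }
  walk(tree$root)
  out
}

#' Newick serialisation of a clonal tree
#'
#' @param tree a `clade_tree`.
#' @return single Newick string rooted at node0, with integer edge lengths.
#' @export
as_newick <- function(tree) {
  if (nrow(tree$edges) == 0L) return(sprintf("%s;", tree$labels[1L]))
  kids <- split(seq_len(nrow(tree$edges)), tree$edges$parent)
  build <- function(v) {
    rows <- kids[[as.character(v)]]
    if (is.null(rows)) return(tree$labels[v])
    inner <- vapply(rows, function(k) {
      sprintf("%s:%d", build(tree$edges$child[k]), tree$edges$length[k])
    }, character(1))
    sprintf("(%s)%s", paste(inner, collapse = ","), tree$labels[v])
  }
  paste0(build(tree$root), ";")
}

#' Write a clonal tree to a Newick file
#' @param tree a `clade_tree`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  writeLines(as_newick(tree), path)
  invisible(path)
}
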