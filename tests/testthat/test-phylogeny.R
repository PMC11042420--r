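test_that("binarize thresholds, drops empty columns, is monotone", {
  ## mutations are rows; M02 never reaches the threshold anywhere
  v <- vm(rbind(M01 = c(0.02, 0.005, 0.3), M02 = c(0.005, 0.009, 0.0)))
  ch <- binarize(v, 0.01)
  expect_equal(ch$dropped, 1L)
  expect_identical(dim(ch$m), c(3L, 1L))  # 3 fields-as-samples x 1 mutation
  expect_equal(unname(ch$m[, "M01"]), c(1L, 0L, 1L))
  ## raising the threshold never adds presences
  set.seed(3)
  m <- matrix(stats::runif(60, 0, 0.2), 6, 10)
  lo <- binarize(vm(m), 0.01)
  hi <- binarize(vm(m), 0.05)
  expect_lte(sum(hi$m), sum(lo$m))
})

test_that("hamming distances count differing characters and are metric", {
  m <- rbind(a = c(0, 1, 0), b = c(0, 1, 1), c = c(0, 1, 0))
  d <- hamming_matrix(m)
  expect_equal(d["a", "b"], 1L)
  expect_equal(d["a", "c"], 0L)
  set.seed(7)
  r <- matrix(stats::rbinom(500, 1, 0.5), 10, 50)
  d <- hamming_matrix(r)
  expect_true(all(d == t(d)))
  for (i in 1:10) for (j in 1:10) for (k in 1:10) {
    expect_lte(d[i, j], d[i, k] + d[k, j])
  }
})

test_that("perfect phylogenies score at the polymorphic-character bound", {
  ## nested characters: score equals number of characters
  m <- rbind(S1 = c(1, 0, 0), S2 = c(1, 1, 0), S3 = c(1, 1, 1),
             S4 = c(0, 0, 0))
  tr <- parsimony_tree(m, method = "exhaustive")
  expect_equal(tr$score, 3L)
  expect_equal(sum(tr$edges$length), tr$score)
  expect_equal(sum(tr$per_character), tr$score)
  ## incompatible pair of characters must exceed the bound
  m2 <- rbind(S1 = c(1, 0), S2 = c(0, 1), S3 = c(1, 1), S4 = c(0, 0))
  tr2 <- parsimony_tree(m2, method = "exhaustive")
  expect_gt(tr2$score, 2L)
  ## general lower bound on random instances
  set.seed(11)
  for (rep in 1:5) {
    mm <- matrix(stats::rbinom(5 * 12, 1, 0.4), 5, 12)
    rownames(mm) <- paste0("S", 1:5)
    ## the all-zero ancestor counts as a sample for the bound
    n_poly <- sum(apply(rbind(mm, 0L), 2L, function(x)
      length(unique(x)) > 1L))
    tr <- parsimony_tree(mm, method = "exhaustive")
    expect_gte(tr$score, n_poly)
  }
})

test_that("duplicate samples are joined by a zero-length path", {
  m <- rbind(S1 = c(1, 1, 0), S2 = c(1, 1, 0), S3 = c(0, 0, 1),
             S4 = c(0, 1, 1))
  tr <- parsimony_tree(m, method = "exhaustive")
  d <- hamming_matrix(m)
  ## path length between the duplicate leaves must be 0
  parent <- integer(length(tr$labels))
  elen <- integer(length(tr$labels))
  parent[tr$edges$child] <- tr$edges$parent
  elen[tr$edges$child] <- tr$edges$length
  path_up <- function(v) {              # nodes from v up to the root
    out <- v
    while (v != tr$root) { v <- parent[v]; out <- c(out, v) }
    out
  }
  p1 <- path_up(which(tr$labels == "S1"))
  p2 <- path_up(which(tr$labels == "S2"))
  common <- intersect(p1, p2)[1L]
  below1 <- p1[seq_len(which(p1 == common) - 1L)]
  below2 <- p2[seq_len(which(p2 == common) - 1L)]
  expect_equal(sum(elen[below1]) + sum(elen[below2]), 0L)
})

test_that("Fitch per-character changes match brute-force labelling minima", {
  set.seed(23)
  for (rep in 1:8) {
    L <- sample(4:6, 1)
    m <- matrix(stats::rbinom(L * 12, 1, 0.5), L, 12)
    rownames(m) <- paste0("S", seq_len(L))
    tr <- parsimony_tree(m, method = "heuristic", seed = rep, restarts = 3)
    for (ch in seq_len(ncol(m))) {
      states <- as.list(stats::setNames(m[, ch], rownames(m)))
      expect_equal(tr$per_character[ch], brute_char_score(tr, states))
    }
    expect_equal(sum(tr$per_character), tr$score)
    expect_equal(sum(tr$edges$length), tr$score)
  }
})

test_that("heuristic search equals the exhaustive optimum on small instances", {
  set.seed(29)
  hits <- 0L
  for (rep in 1:20) {
    L <- sample(4:6, 1)
    m <- matrix(stats::rbinom(L * 15, 1, 0.4), L, 15)
    rownames(m) <- paste0("S", seq_len(L))
    ex <- parsimony_tree(m, method = "exhaustive")
    he <- parsimony_tree(m, method = "heuristic", seed = rep, restarts = 5)
    expect_gte(he$score, ex$score)
    if (he$score == ex$score) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("sample ordering is deterministic with documented tie-breaks", {
  m <- rbind(S3 = c(1, 0), S1 = c(0, 1), S2 = c(1, 1))
  tr <- parsimony_tree(m, method = "exhaustive")
  o1 <- tree_sample_order(tr)
  o2 <- tree_sample_order(tr)
  expect_identical(o1, o2)
  expect_setequal(o1, rownames(m))
  ## identical rows: order is deterministic and equal-size sibling leaves
  ## come out label-sorted
  ms <- rbind(Sc = c(1, 0, 0), Sa = c(1, 0, 0), Sb = c(1, 0, 0))
  trs <- parsimony_tree(ms, method = "exhaustive")
  os <- tree_sample_order(trs)
  expect_identical(os, tree_sample_order(trs))
  expect_setequal(os, rownames(ms))
  ## the final cherry holds two size-1 subtrees: tie broken by label
  expect_true(os[2L] < os[3L])
})

test_that("degenerate inputs give degenerate trees and valid Newick", {
  t1 <- parsimony_tree(matrix(c(1L, 0L, 1L), 1, 3,
                              dimnames = list("S1", NULL)))
  expect_equal(t1$score, 2L)
  expect_match(as_newick(t1), "^\\(S1:2\\)node0;$")
  m <- rbind(S1 = c(1, 0), S2 = c(1, 1))
  tr <- parsimony_tree(m)
  nwk <- as_newick(tr)
  expect_match(nwk, ";$")
  expect_equal(lengths(regmatches(nwk, gregexpr("S[12]", nwk))), 2L)
  path <- tempfile(fileext = ".nwk")
  write_tree_newick(tr, path)
  expect_identical(readLines(path), nwk)
})
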