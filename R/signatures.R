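## signatures: 6-class and 96-motif catalogs, simplex-constrained signature
## refitting, bootstrap significance, and group comparisons.
##
## The refit solves  min_H (WH - V)' (WH - V)  subject to H >= 0 and
## sum(H) = 1, a convex QP over the probability simplex.  It is solved as
## non-negative least squares on an augmented system with a penalty row
## enforcing the sum constraint, followed by exact renormalisation; the test
## suite checks the solution against an independent projected-gradient
## oracle.

#' Construct a signature matrix
#'
#' @param W numeric 96 x K matrix, non-negative, rows in canonical motif
#'   order (rownames must be the canonical labels), each column summing to 1
#'   within `1e-6`.
#' @return `W` with class `signature_matrix`, columns exactly renormalised.
#' @export
signature_matrix <- function(W) {
  assert_that(is.matrix(W) && nrow(W) == 96L, "W must be a 96 x K matrix")
  assert_that(ncol(W) >= 1L, "signature matrix has no signature columns")
  assert_that(all(W >= 0), "negative entry in signature matrix")
  if (is.null(rownames(W))) rownames(W) <- canonical_motifs()
  assert_that(identical(rownames(W), canonical_motifs()),
              "signature matrix rows are not in canonical motif order")
  cs <- colSums(W)
  bad <- which(abs(cs - 1) > 1e-6)
  assert_that(length(bad) == 0L,
              "signature column '%s' sums to %.6f, not 1",
              colnames(W)[bad[1L]] %||% as.character(bad[1L]), cs[bad[1L]])
  W <- sweep(W, 2L, cs, "/")
  if (is.null(colnames(W))) colnames(W) <- paste0("Signature.", seq_len(ncol(W)))
  class(W) <- c("signature_matrix", class(W))
  W
}

select_snvs <- function(records, selection = NULL) {
  rec <- records[records$variant_type == "SNV", , drop = FALSE]
  if (!is.null(selection)) rec <- rec[rec$mutation_id %in% selection, , drop = FALSE]
  rec
}

#' Six-class substitution spectrum
#'
#' Counts SNVs by substitution class (`C>A, C>G, C>T, T>A, T>C, T>G`),
#' complementing purine-reference changes to the pyrimidine strand.
#'
#' @param records mutation record data frame.
#' @param selection optional character vector of mutation ids to restrict to.
#' @return named integer 6-vector; `sum` equals the number of selected SNVs.
#' @export
substitution_spectrum <- function(records, selection = NULL) {
  rec <- select_snvs(records, selection)
  counts <- integer(6L)
  names(counts) <- SUBSTITUTION_CLASSES
  if (nrow(rec) > 0L) {
    idx <- substitution_index(rec$ref, rec$alt)
    tab <- tabulate(idx, nbins = 6L)
    counts[] <- tab
  }
  counts
}

#' 96-motif trinucleotide catalog
#'
#' Bins SNVs into the 96 canonical trinucleotide motifs (pyrimidine
#' reference; purine-reference contexts are reverse-complemented).
#'
#' @param records mutation record data frame with a `context` column.
#' @param selection optional character vector of mutation ids.
#' @param on_missing `"error"` (default) rejects SNVs without context,
#'   listing their ids; `"skip"` drops them with a warning.
#' @return list of class `spectrum_catalog` with `counts6`, `counts96`
#'   (named by motif), `n` (total SNVs binned) and `V` (`counts96 / n` on
#'   the probability simplex).
#' @export
context_catalog96 <- function(records, selection = NULL,
                              on_missing = c("error", "skip")) {
  on_missing <- match.arg(on_missing)
  rec <- select_snvs(records, selection)
  has_ctx <- !is.na(rec$context) & nzchar(rec$context %||% "")
  if (!all(has_ctx)) {
    ids <- rec$mutation_id[!has_ctx]
    if (on_missing == "error") {
      stop_of("SNV(s) without trinucleotide context: %s",
              paste(utils::head(ids, 10L), collapse = ", "))
    }
    warning(sprintf("skipping %d SNV(s) without context", length(ids)))
    rec <- rec[has_ctx, , drop = FALSE]
  }
  assert_that(nrow(rec) >= 1L, "no SNVs with context in selection")
  idx <- motif_index(rec$ref, rec$alt, rec$context)
  counts96 <- tabulate(idx, nbins = 96L)
  names(counts96) <- canonical_motifs()
  counts6 <- tapply(counts96, rep(SUBSTITUTION_CLASSES, each = 16L), sum)
  counts6 <- as.integer(counts6[SUBSTITUTION_CLASSES])
  names(counts6) <- SUBSTITUTION_CLASSES
  structure(list(counts6 = counts6, counts96 = counts96,
                 n = sum(counts96), V = counts96 / sum(counts96)),
            class = "spectrum_catalog")
}

## Lawson-Hanson non-negative least squares, min ||Ax - y|| s.t. x >= 0.
nnls_fit <- function(A, y) {
  n <- ncol(A)
  x <- numeric(n)
  passive <- logical(n)
  tol <- 1e-12 * max(abs(crossprod(A, y)))
  w <- drop(crossprod(A, y - A %*% x))
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (all(passive) || max(w[!passive]) <= tol || iter > 30L * n) break
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      s <- numeric(n)
      coefs <- qr.coef(qr(A[, passive, drop = FALSE]), y)
      coefs[is.na(coefs)] <- 0
      s[passive] <- coefs
      if (min(s[passive]) > 0) { x <- s; break }
      q <- passive & (s <= 0)
      alpha <- min(x[q] / (x[q] - s[q]))
      x <- x + alpha * (s - x)
      passive <- passive & (x > 1e-14)
      x[!passive] <- 0
    }
    w <- drop(crossprod(A, y - A %*% x))
  }
  x
}

#' Fit signature weights on the probability simplex
#'
#' Solves `min_H (WH - V)'(WH - V)` with `H >= 0`, `sum(H) = 1`.
#'
#' @param V numeric 96-vector on the probability simplex (a motif catalog's
#'   `V`), or a `spectrum_catalog`.
#' @param W a [signature_matrix()].
#' @param strict when `TRUE` (default) reject `V` off the simplex beyond
#'   `1e-8`; otherwise renormalise with a warning.
#' @return list of class `weight_result` with `H` (named weight vector,
#'   non-negative, summing to 1) and `objective` (the residual sum of
#'   squares at `H`).
#' @export
fit_signature_weights <- function(V, W, strict = TRUE) {
  if (inherits(V, "spectrum_catalog")) V <- V$V
  assert_that(length(V) == 96L, "V must have 96 entries")
  assert_that(all(V >= 0), "V has negative entries")
  s <- sum(V)
  if (abs(s - 1) > 1e-8) {
    if (strict) stop_of("V is not on the probability simplex (sum = %.8f)", s)
    warning("renormalising V to the simplex")
  }
  V <- V / s
  assert_that(ncol(W) >= 1L, "signature matrix has no columns (K = 0)")
  penalty <- 1e3
  A <- rbind(unclass(W), rep(penalty, ncol(W)))
  y <- c(V, penalty)
  H <- nnls_fit(A, y)
  assert_that(sum(H) > 0, "degenerate NNLS solution (all-zero weights)")
  H <- H / sum(H)
  names(H) <- colnames(W)
  resid <- drop(unclass(W) %*% H) - V
  structure(list(H = H, objective = sum(resid^2)), class = "weight_result")
}

#' Bootstrap significance of signature contributions
#'
#' Resamples the selected SNVs with replacement `B` times, rebuilds the
#' 96-motif catalog, and refits the weights.  Two empirical p-value
#' definitions are reported:
#' \describe{
#'   \item{`p_null` (default criterion)}{fraction of replicates in which a
#'     signature's weight is `<= w0` (default 0.01), i.e. the probability
#'     that its contribution is not robustly above background.}
#'   \item{`p_literal`}{fraction of replicate weights greater than or equal
#'     to the observed weight; descriptive only, not null-calibrated.}
#' }
#' A signature is flagged significant when `p_null < alpha`
#' (default 0.005).
#'
#' @param records mutation record data frame.
#' @param W a [signature_matrix()].
#' @param B number of bootstrap replicates (default 2000).
#' @param seed integer RNG seed (required; the run is deterministic given it).
#' @param selection optional mutation-id subset.
#' @param w0 background weight for the null definition.
#' @param alpha significance threshold on `p_null`.
#' @return list of class `signature_bootstrap` with `H_obs`, `p_null`,
#'   `p_literal`, `significant`, `B`, `seed`, `w0`, `alpha`, and the
#'   `B x K` matrix of replicate weights `H_boot`.
#' @export
bootstrap_signature_pvalues <- function(records, W, B = 2000L, seed,
                                        selection = NULL, w0 = 0.01,
                                        alpha = 0.005) {
  assert_that(is_count(B, 1L), "B must be a positive integer")
  assert_that(!missing(seed), "an explicit seed is required")
  rec <- select_snvs(records, selection)
  rec <- rec[!is.na(rec$context) & nzchar(rec$context), , drop = FALSE]
  n <- nrow(rec)
  assert_that(n >= 1L, "no SNVs with context to bootstrap")
  obs <- fit_signature_weights(context_catalog96(rec), W)
  idx_all <- motif_index(rec$ref, rec$alt, rec$context)
  K <- ncol(W)
  H_boot <- matrix(NA_real_, B, K, dimnames = list(NULL, colnames(W)))
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  for (b in seq_len(B)) {
    take <- sample.int(n, n, replace = TRUE)
    counts <- tabulate(idx_all[take], nbins = 96L)
    H_boot[b, ] <- fit_signature_weights(counts / n, W)$H
  }
  p_null <- colMeans(H_boot <= w0)
  p_literal <- colMeans(sweep(H_boot, 2L, obs$H, ">=") * 1)
  structure(list(H_obs = obs$H, objective = obs$objective,
                 p_null = p_null, p_literal = p_literal,
                 significant = p_null < alpha,
                 B = B, seed = seed, w0 = w0, alpha = alpha,
                 H_boot = H_boot),
            class = "signature_bootstrap")
}

## Save/seed/restore guard so seeded routines do not disturb the caller's RNG
## stream.  Returns a restore closure.
.Random.seed_guard <- function(seed) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}

#' Compare catalogs or weights across sample groups
#'
#' @param x input depending on `mode`:
#'   \describe{
#'     \item{`"spectrum"`}{a 6 x G (classes x groups) count matrix; tested
#'       with an r x c exact test (full enumeration when the table total is
#'       below `enum_limit`, otherwise Monte-Carlo with `mc_B` tables under
#'       the fixed internal seed 2024).}
#'     \item{`"motif"`}{a 96 x S matrix of per-sample motif proportions with
#'       `groups` naming exactly two groups; per-motif two-sample
#'       Wilcoxon rank-sum tests (mid-ranks, normal approximation with
#'       continuity correction) with Benjamini-Hochberg FDR.}
#'     \item{`"weights"`}{a K x S matrix of per-sample signature weights with
#'       `groups` over >= 2 groups; per-signature Kruskal-Wallis tests.}
#'   }
#' @param groups factor/character of group labels for the columns of `x`
#'   (ignored for `mode = "spectrum"`).
#' @param mode one of `"spectrum"`, `"motif"`, `"weights"`.
#' @param enum_limit table-total bound below which the exact test uses full
#'   enumeration.
#' @param mc_B Monte-Carlo replicate count for large tables.
#' @return data frame of test results (and for `"spectrum"` a single-row
#'   data frame with the p-value and method used).
#' @export
compare_groups <- function(x, groups = NULL,
                           mode = c("spectrum", "motif", "weights"),
                           enum_limit = 30L, mc_B = 1e5L) {
  mode <- match.arg(mode)
  if (mode == "spectrum") {
    assert_that(is.matrix(x) && ncol(x) >= 2L, "need counts for >= 2 groups")
    assert_that(all(colSums(x) > 0), "empty group in spectrum table")
    keep <- rowSums(x) > 0
    x <- x[keep, , drop = FALSE]
    if (sum(x) <= enum_limit) {
      p <- stats::fisher.test(x)$p.value
      method <- "exact enumeration"
    } else {
      old <- .Random.seed_guard(2024L)
      on.exit(old(), add = TRUE)
      p <- stats::fisher.test(x, simulate.p.value = TRUE, B = mc_B)$p.value
      method <- sprintf("Monte-Carlo exact (B = %d)", mc_B)
    }
    return(data.frame(mode = "spectrum", p = p, method = method,
                      stringsAsFactors = FALSE))
  }
  assert_that(!is.null(groups) && length(groups) == ncol(x),
              "groups must label the columns of x")
  groups <- as.factor(droplevels(as.factor(groups)))
  assert_that(all(table(groups) > 0) && nlevels(groups) >= 2L,
              "need >= 2 non-empty groups")
  if (mode == "motif") {
    assert_that(nlevels(groups) == 2L, "motif mode needs exactly two groups")
    a <- groups == levels(groups)[1L]
    p <- apply(x, 1L, function(v) {
      if (all(v == v[1L])) return(1)
      stats::wilcox.test(v[a], v[!a], exact = FALSE, correct = TRUE)$p.value
    })
    return(data.frame(feature = rownames(x) %||% seq_len(nrow(x)),
                      p = p, fdr = stats::p.adjust(p, "BH"),
                      row.names = NULL, stringsAsFactors = FALSE))
  }
  ## weights: Kruskal-Wallis per signature
  p <- apply(x, 1L, function(v) {
    if (all(v == v[1L])) return(1)
    stats::kruskal.test(v, groups)$p.value
  })
  data.frame(signature = rownames(x) %||% seq_len(nrow(x)),
             p = p, row.names = NULL, stringsAsFactors = FALSE)
}
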