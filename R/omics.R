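## omics_scores: downstream proteome/metabolome statistics.

#' Half-minimum imputation of missing abundances
#'
#' Every missing entry is replaced by half of the smallest observed value
#' in the entire matrix; observed entries are untouched.  Idempotent.
#'
#' @param m numeric features x samples matrix with `NA` for missing values.
#' @return matrix without missing values.
#' @export
impute_half_min <- function(m) {
  assert_that(any(!is.na(m)), "all-missing matrix: nothing to impute from")
  m[is.na(m)] <- min(m, na.rm = TRUE) / 2
  m
}

#' Differential features between two sample groups
#'
#' Two-sample t-test on log2 abundances (Welch by default); the fold change
#' is the linear-scale ratio of group means.  A feature is flagged when
#' `p < p_cut` and the fold change exceeds `fc_cut` in either direction.
#'
#' @param m numeric features x samples matrix (no missing values; impute
#'   first).
#' @param groups vector of group labels for the columns of `m`.
#' @param group_a,group_b the two groups to compare (`a` vs `b`; positive
#'   log2FC means higher in `a`).
#' @param log2_transform apply `log2` before testing (default `TRUE`;
#'   a pseudocount is not added, so zero abundances must be imputed away).
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @param p_cut,fc_cut significance and fold-change cutoffs (defaults 0.05
#'   and 1.5).
#' @return data frame `feature, mean_a, mean_b, fc, log2fc, p, flag`.
#' @export
differential_features <- function(m, groups, group_a, group_b,
                                  log2_transform = TRUE, var_equal = FALSE,
                                  p_cut = 0.05, fc_cut = 1.5) {
  a <- which(groups == group_a)
  b <- which(groups == group_b)
  assert_that(length(a) >= 2L && length(b) >= 2L,
              "need >= 2 samples per group")
  lm2 <- if (log2_transform) log2(m) else m
  assert_that(all(is.finite(lm2[, c(a, b)])),
              "non-finite values after log2; impute zeros/missing first")
  n <- nrow(m)
  p <- numeric(n)
  for (i in seq_len(n)) {
    x <- lm2[i, a]; y <- lm2[i, b]
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      p[i] <- if (mean(x) == mean(y)) 1 else 0
    } else {
      p[i] <- stats::t.test(x, y, var.equal = var_equal)$p.value
    }
  }
  mean_a <- rowMeans(m[, a, drop = FALSE])
  mean_b <- rowMeans(m[, b, drop = FALSE])
  fc <- mean_a / mean_b
  data.frame(feature = rownames(m) %||% as.character(seq_len(n)),
             mean_a = mean_a, mean_b = mean_b, fc = fc, log2fc = log2(fc),
             p = p,
             flag = p < p_cut & (fc > fc_cut | fc < 1 / fc_cut),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Monotonic-trend feature selection along disease progression
#'
#' A feature is monotonically up when its group means strictly increase
#' along the ordered groups (default `NU_LGIN -> HGIN -> UC`) and the first
#' ordered group exceeds the control mean; down is symmetric.
#'
#' @param m numeric features x samples matrix (no missing values).
#' @param groups vector of group labels for the columns.
#' @param ordered_groups progression order (default
#'   `c("NU_LGIN", "HGIN", "UC")`).
#' @param reference control group label (default `"control"`).
#' @param eps tolerance on each strict comparison (default 0).
#' @return list with character vectors `up` and `down` and the matrix
#'   `means` (features x groups, control first).
#' @export
monotonic_features <- function(m, groups,
                               ordered_groups = c("NU_LGIN", "HGIN", "UC"),
                               reference = "control", eps = 0) {
  for (g in c(reference, ordered_groups)) {
    assert_that(any(groups == g), "group '%s' has no samples", g)
  }
  means <- sapply(c(reference, ordered_groups), function(g) {
    rowMeans(m[, groups == g, drop = FALSE])
  })
  rownames(means) <- rownames(m)
  step_up <- sapply(seq_along(ordered_groups), function(j) {
    means[, j + 1L] > means[, j] + eps
  })
  step_dn <- sapply(seq_along(ordered_groups), function(j) {
    means[, j + 1L] < means[, j] - eps
  })
  feats <- rownames(m) %||% as.character(seq_len(nrow(m)))
  list(up = feats[rowSums(step_up) == length(ordered_groups)],
       down = feats[rowSums(step_dn) == length(ordered_groups)],
       means = means)
}

#' Single-sample set enrichment (ssGSEA)
#'
#' Per sample, features are ranked by abundance (mid-ranks on ties).  The
#' enrichment score of a set is the sum over the descending-rank walk of
#' the difference between the weighted in-set empirical CDF (rank values
#' raised to `weight_exponent`, normalised over the set) and the uniform
#' out-of-set ECDF (the integral form of the running-sum statistic).
#'
#' @param m numeric features x samples matrix (no missing values), feature
#'   ids as row names.
#' @param sets named list of character vectors (e.g. [read_gmt()]).  Members
#'   absent from `m` are dropped with a warning; sets with fewer than two
#'   remaining members are dropped.  A set equal to the whole feature space
#'   is an error (empty complement).
#' @param weight_exponent rank-weighting exponent tau (default 0.75;
#'   0 gives the unweighted Kolmogorov-style walk).
#' @param normalize divide all scores by `max(score) - min(score)` over the
#'   whole matrix (a single affine transform).
#' @return pathways x samples matrix of enrichment scores.
#' @export
ssgsea <- function(m, sets, weight_exponent = 0.75, normalize = FALSE) {
  assert_that(!is.null(rownames(m)), "m needs feature row names")
  N <- nrow(m)
  kept <- list()
  for (nm in names(sets)) {
    members <- intersect(sets[[nm]], rownames(m))
    if (length(members) < length(sets[[nm]])) {
      warning(sprintf("set '%s': %d member(s) absent from the matrix",
                      nm, length(sets[[nm]]) - length(members)))
    }
    assert_that(length(members) < N,
                "set '%s' covers the entire feature space (empty complement)",
                nm)
    if (length(members) >= 2L) kept[[nm]] <- members
  }
  assert_that(length(kept) >= 1L, "no usable pathway sets")
  scores <- matrix(NA_real_, length(kept), ncol(m),
                   dimnames = list(names(kept), colnames(m)))
  for (s in seq_len(ncol(m))) {
    r <- rank(m[, s])                     # mid-ranks; larger = more abundant
    ord <- order(r, decreasing = TRUE)
    rw <- r^weight_exponent
    for (k in seq_along(kept)) {
      inset <- rownames(m) %in% kept[[k]]
      w_in <- ifelse(inset, rw, 0)[ord]
      w_out <- ifelse(inset, 0, 1)[ord]
      p_in <- cumsum(w_in) / sum(w_in)
      p_out <- cumsum(w_out) / (N - sum(inset))
      scores[k, s] <- sum(p_in - p_out)
    }
  }
  if (normalize) {
    rng <- max(scores) - min(scores)
    assert_that(rng > 0, "degenerate score range; cannot normalize")
    scores <- scores / rng
  }
  scores
}
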