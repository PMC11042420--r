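## Independent oracles used to cross-check the package's implementations.
## These are deliberately naive and slow: they share no code with the
## routines they verify.

## Euclidean projection onto the probability simplex (sort-based).
proj_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  k <- max(which(u + (1 - css) / seq_along(u) > 0))
  tau <- (1 - css[k]) / k
  pmax(v + tau, 0)
}

## Projected-gradient solver for min ||W h - V||^2 on the simplex, run to
## convergence; the oracle for fit_signature_weights.
pg_simplex_fit <- function(V, W, iters = 5e4, tol = 1e-14) {
  W <- unclass(W)
  K <- ncol(W)
  WtW <- crossprod(W)
  WtV <- drop(crossprod(W, V))
  L <- 2 * max(eigen(WtW, symmetric = TRUE, only.values = TRUE)$values)
  h <- rep(1 / K, K)
  for (it in seq_len(iters)) {
    g <- 2 * (drop(WtW %*% h) - WtV)
    h_new <- proj_simplex(h - g / L)
    if (max(abs(h_new - h)) < tol) { h <- h_new; break }
    h <- h_new
  }
  h
}

## Naive per-sample ssGSEA: explicit walk down the ranked feature list.
naive_ssgsea_one <- function(abund, set_members, tau) {
  N <- length(abund)
  r <- rank(abund)
  ord <- order(r, decreasing = TRUE)
  feats <- names(abund)[ord]
  inset <- feats %in% set_members
  denom_in <- sum((r[ord][inset])^tau)
  denom_out <- N - sum(inset)
  p_in <- p_out <- 0
  es <- 0
  for (j in seq_len(N)) {
    if (inset[j]) p_in <- p_in + (r[ord][j])^tau / denom_in
    else p_out <- p_out + 1 / denom_out
    es <- es + (p_in - p_out)
  }
  as.numeric(es)
}

## Brute-force minimum parsimony changes for one binary character on a
## fixed tree: enumerate every labelling of the internal nodes.
brute_char_score <- function(tree, leaf_states_row) {
  edges <- tree$edges
  nodes <- sort(unique(c(edges$parent, edges$child)))
  leaves <- setdiff(nodes, edges$parent)
  internal <- setdiff(nodes, c(leaves, tree$root))
  state <- integer(max(nodes))
  state[tree$root] <- 0L
  labs <- tree$labels
  for (lf in leaves) state[lf] <- leaf_states_row[[labs[lf]]]
  if (length(internal) == 0L) {
    return(sum(state[edges$parent] != state[edges$child]))
  }
  best <- Inf
  for (mask in 0:(2^length(internal) - 1L)) {
    state[internal] <- bitwAnd(bitwShiftR(mask, seq_along(internal) - 1L), 1L)
    best <- min(best, sum(state[edges$parent] != state[edges$child]))
  }
  best
}

## Exact two-sided Fisher p for a 2x2 table by full hypergeometric
## enumeration (sum of table probabilities <= observed probability).
fisher_2x2_enum <- function(tab) {
  m <- sum(tab[1L, ])
  n <- sum(tab[2L, ])
  k <- sum(tab[, 1L])
  x_obs <- tab[1L, 1L]
  xs <- max(0L, k - n):min(k, m)
  probs <- stats::dhyper(xs, m, n, k)
  p_obs <- stats::dhyper(x_obs, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

## Exact mean of the i-th seeded clone VAF: numeric quadrature of the
## defining integral (not the package's pgamma form).
ev_quadrature <- function(a, b, cc, i) {
  if (i == 0L) return(exp(a) / cc)
  f <- function(u) u^(i - 1) * exp(-u) / factorial(i - 1)
  exp(a) * (b / (a + b))^i *
    stats::integrate(f, 0, a + b, rel.tol = 1e-12)$value / cc
}
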