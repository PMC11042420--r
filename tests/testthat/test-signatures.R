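test_that("substitution spectra use the pyrimidine-reference convention", {
  rec <- records_of(ref = c("G", "A", "C"), alt = c("A", "C", "A"))
  sp <- substitution_spectrum(rec)
  expect_equal(sum(sp), 3L)               # conservation
  expect_equal(unname(sp["C>T"]), 1L)     # G>A complements to C>T
  expect_equal(unname(sp["T>G"]), 1L)     # A>C complements to T>G
  expect_equal(unname(sp["C>A"]), 1L)
  ## indels are never counted
  rec2 <- rbind(rec, records_of("AT", "A", variant_type = "DEL"))
  rec2$mutation_id <- sprintf("R%03d", seq_len(nrow(rec2)))
  expect_equal(sum(substitution_spectrum(rec2)), 3L)
})

test_that("96-motif binning reverse-complements purine contexts", {
  cat <- context_catalog96(records_of("C", "T", "TCA"))
  expect_equal(unname(cat$counts96["T[C>T]A"]), 1L)
  ## hand reverse complement: TGA with G>A maps to the same bin
  cat2 <- context_catalog96(records_of("G", "A", "TGA"))
  expect_identical(cat2$counts96, cat$counts96)
  ## context/ref mismatch rejected
  expect_error(context_catalog96(records_of("A", "G", "ACA")),
               "center")
  ## missing context: error listing ids, or skip under the flag
  rec <- records_of(c("C", "C"), c("T", "T"), c("TCA", NA))
  expect_error(context_catalog96(rec), "R002")
  expect_warning(got <- context_catalog96(rec, on_missing = "skip"),
                 "skipping 1")
  expect_equal(got$n, 1L)
  ## catalog conservation over a partition
  set.seed(41)
  sc <- simulate_catalog(rep(1 / 30, 30), synthetic_signature_matrix(),
                         300, seed = 8)
  half <- sc$records$mutation_id[1:150]
  c1 <- context_catalog96(sc$records, selection = half)
  c2 <- context_catalog96(sc$records,
                          selection = setdiff(sc$records$mutation_id, half))
  expect_identical(c1$counts96 + c2$counts96,
                   context_catalog96(sc$records)$counts96)
  expect_equal(sum(c1$counts6), 150L)
})

test_that("simplex-constrained refit recovers exact mixtures", {
  W <- synthetic_signature_matrix(K = 8)
  ## V equal to one column -> unit weight on it, objective 0
  fit <- fit_signature_weights(unclass(W)[, 3L], W)
  expect_lt(fit$objective, 1e-18)
  expect_equal(unname(fit$H[3L]), 1, tolerance = 1e-8)
  ## disjoint-support two-signature mixture -> closed-form weights
  Wd <- matrix(0, 96, 2)
  Wd[1:48, 1L] <- 1 / 48
  Wd[49:96, 2L] <- 1 / 48
  rownames(Wd) <- canonical_motifs()
  Wd <- signature_matrix(Wd)
  V <- 0.7 * unclass(Wd)[, 1L] + 0.3 * unclass(Wd)[, 2L]
  fit <- fit_signature_weights(V, Wd)
  expect_equal(unname(fit$H), c(0.7, 0.3), tolerance = 1e-10)
  ## simplex feasibility always holds
  expect_equal(sum(fit$H), 1, tolerance = 1e-8)
  expect_true(all(fit$H >= 0))
  ## V off the simplex: error under strict, warning otherwise
  expect_error(fit_signature_weights(V * 2, Wd), "simplex")
  expect_warning(fit_signature_weights(V * 2, Wd, strict = FALSE),
                 "renormalising")
})

test_that("refit matches the projected-gradient oracle on random mixtures", {
  W <- synthetic_signature_matrix(K = 30)
  set.seed(17)
  for (rep in 1:3) {
    Hs <- stats::rgamma(30, 0.4)
    Hs <- Hs / sum(Hs)
    V <- drop(unclass(W) %*% Hs)
    fit <- fit_signature_weights(V, W)
    oracle <- pg_simplex_fit(V, W)
    expect_lt(max(abs(fit$H - oracle)), 1e-4)
    expect_lt(fit$objective, 1e-10)
  }
})

test_that("adding a signature never increases the refit objective", {
  W <- synthetic_signature_matrix(K = 10)
  set.seed(19)
  V <- stats::rgamma(96, 1)
  V <- V / sum(V)
  sub <- signature_matrix(unclass(W)[, 1:6])
  full <- signature_matrix(unclass(W)[, 1:7])
  expect_lte(fit_signature_weights(V, full)$objective,
             fit_signature_weights(V, sub)$objective + 1e-12)
})

test_that("refit L1 error shrinks as the catalog grows", {
  W <- synthetic_signature_matrix()
  Hs <- numeric(30)
  Hs[c(2, 9, 27)] <- c(0.5, 0.3, 0.2)
  err <- vapply(c(100L, 1000L, 10000L), function(n) {
    sc <- simulate_catalog(Hs, W, n, seed = n)
    sum(abs(fit_signature_weights(sc$catalog, W)$H - Hs))
  }, numeric(1))
  expect_true(err[3L] < err[1L])
  expect_true(err[2L] < err[1L])
})

test_that("bootstrap p-values are deterministic, granular and calibrated", {
  W <- synthetic_signature_matrix(K = 10)
  H1 <- c(1, rep(0, 9))
  sc <- simulate_catalog(H1, W, 400, seed = 21)
  b1 <- bootstrap_signature_pvalues(sc$records, W, B = 40, seed = 99)
  b2 <- bootstrap_signature_pvalues(sc$records, W, B = 40, seed = 99)
  expect_identical(b1$p_null, b2$p_null)          # same seed, same result
  expect_identical(b1$p_literal, b2$p_literal)
  bB1 <- bootstrap_signature_pvalues(sc$records, W, B = 1, seed = 3)
  expect_true(all(bB1$p_null %in% c(0, 1)))       # granularity 1/B
  ## pure-signature catalog concentrates weight on that signature
  expect_lt(b1$p_null[1L], 0.005)
  expect_true(b1$significant[1L])
  expect_gt(mean(b1$H_boot[, 1L]), 0.95)
  expect_error(bootstrap_signature_pvalues(sc$records, W, B = 10),
               "seed")
})

test_that("group comparisons cover spectrum, motif and weight modes", {
  ## identical spectra -> p = 1
  tab <- cbind(g1 = c(5, 5, 5, 5, 5, 5), g2 = c(5, 5, 5, 5, 5, 5))
  expect_equal(compare_groups(tab, mode = "spectrum")$p, 1)
  ## 2x2 exact test equals hypergeometric enumeration
  set.seed(13)
  for (rep in 1:10) {
    t22 <- matrix(stats::rpois(4, 4) + 1L, 2, 2)
    if (sum(t22) > 30) next
    got <- compare_groups(t22, mode = "spectrum")
    expect_match(got$method, "enumeration")
    expect_equal(got$p, fisher_2x2_enum(t22), tolerance = 1e-7)
  }
  ## large tables switch to seeded Monte-Carlo and stay reproducible
  big <- matrix(c(40, 10, 25, 25, 10, 40), 2, 3) * 3L
  p1 <- compare_groups(big, mode = "spectrum")
  p2 <- compare_groups(big, mode = "spectrum")
  expect_match(p1$method, "Monte-Carlo")
  expect_identical(p1$p, p2$p)
  expect_error(compare_groups(cbind(g1 = c(1, 0), g2 = c(0, 0)),
                              mode = "spectrum"), "empty group")
  ## motif mode: BH-adjusted rank-sum p-values
  set.seed(14)
  x <- matrix(stats::runif(96 * 10), 96, 10,
              dimnames = list(canonical_motifs(), NULL))
  x[1L, 6:10] <- x[1L, 6:10] + 2
  groups <- rep(c("a", "b"), each = 5)
  mot <- compare_groups(x, groups, mode = "motif")
  expect_equal(mot$fdr, stats::p.adjust(mot$p, "BH"))
  expect_lt(mot$p[1L], 0.05)
  ## weights mode: Kruskal-Wallis across three groups
  w <- matrix(stats::runif(5 * 12), 5, 12,
              dimnames = list(paste0("S", 1:5), NULL))
  w[2L, 9:12] <- w[2L, 9:12] + 5
  kw <- compare_groups(w, rep(c("x", "y", "z"), each = 4), mode = "weights")
  expect_equal(nrow(kw), 5L)
  expect_lt(kw$p[2L], 0.05)
})
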