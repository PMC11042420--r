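## synthetic_data: whole-organ datasets with known ground truth.
##
## Clone growth is deterministic-exponential conditional on Poisson seeding
## times, matching the expectation structure of the chronology estimator;
## read sampling is binomial at per-field depth.  All generators are
## deterministic given (config, seed).

#' Synthetic 96 x K signature matrix
#'
#' A stand-in for a COSMIC-v2-format signature catalog: each column is a
#' sparse Dirichlet draw over the 96 canonical motifs.  Synthetic -- the
#' columns are not the published signatures, only the format matches.
#'
#' @param K number of signatures (default 30).
#' @param concentration Dirichlet concentration per motif (default 0.2;
#'   smaller = sparser, easier-to-separate signatures).
#' @param seed RNG seed (default 101).
#' @return a [signature_matrix()] with columns `Signature.1 ..
#'   Signature.K`.
#' @export
synthetic_signature_matrix <- function(K = 30L, concentration = 0.2,
                                       seed = 101L) {
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  W <- matrix(stats::rgamma(96L * K, shape = concentration), 96L, K)
  W <- sweep(W, 2L, colSums(W), "/")
  rownames(W) <- canonical_motifs()
  colnames(W) <- paste0("Signature.", seq_len(K))
  signature_matrix(W)
}

## Decode canonical motif index -> (ref, alt, context).
motif_decode <- function(idx) {
  sub <- (idx - 1L) %/% 16L + 1L
  rest <- (idx - 1L) %% 16L
  p5 <- DNA_BASES[rest %/% 4L + 1L]
  p3 <- DNA_BASES[rest %% 4L + 1L]
  ref <- substr(SUBSTITUTION_CLASSES[sub], 1L, 1L)
  alt <- substr(SUBSTITUTION_CLASSES[sub], 3L, 3L)
  list(ref = ref, alt = alt, context = paste0(p5, ref, p3))
}

#' Simulate a mutation catalog from a signature mixture
#'
#' Draws `n` SNVs: each picks a generating signature with probability
#' `H`, then a motif from that signature's column of `W`.
#'
#' @param H simplex weight vector over the columns of `W`.
#' @param W a [signature_matrix()].
#' @param n number of SNVs.
#' @param seed RNG seed.
#' @return list with `records` (a mutation record data frame with
#'   contexts), `catalog` (its [context_catalog96()]) and `signature_of`
#'   (integer vector of generating signature indices).
#' @export
simulate_catalog <- function(H, W, n, seed) {
  assert_that(abs(sum(H) - 1) < 1e-8 && all(H >= 0), "H must be on the simplex")
  assert_that(is_count(n, 1L), "n must be a positive integer")
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  z <- sample.int(ncol(W), n, replace = TRUE, prob = H)
  idx <- vapply(z, function(k) {
    sample.int(96L, 1L, prob = W[, k])
  }, integer(1))
  dec <- motif_decode(idx)
  records <- data.frame(
    mutation_id = sprintf("C%05d", seq_len(n)),
    gene = sprintf("G%04d", sample.int(5000L, n, replace = TRUE)),
    chrom = "1", pos = seq_len(n),
    ref = dec$ref, alt = dec$alt,
    variant_type = "SNV", coding_effect = "non_silent",
    context = dec$context, stringsAsFactors = FALSE)
  list(records = records, catalog = context_catalog96(records),
       signature_of = z)
}

#' Simulate per-field true VAFs of one mutant clone
#'
#' The primary clone in `seed_field` has deterministic size
#' `exp(rho * t)`.  Secondary seeding times are a Poisson process of
#' intensity `nu` on `[0, t]`; each secondary clone of size
#' `exp(rho * (t - t_i))` lands in a distinct field drawn uniformly
#' without replacement from the remaining fields (overflow clones merge
#' into the last assigned field).  Per-field VAF is clone size divided by
#' `2 * cells`, capped at 0.5 (heterozygous diploid ceiling).
#'
#' @param rho effective proliferation rate (1/year).
#' @param nu immigration intensity (1/year).
#' @param t clone age (years).
#' @param n_fields number of mucosal fields.
#' @param cells uroprogenitor cells per field.
#' @param seed_field index of the field holding the primary clone.
#' @param seed optional RNG seed; `NULL` uses (and advances) the caller's
#'   RNG stream.
#' @return list with `vaf` (length-`n_fields` true VAF vector),
#'   `n_seeded` (secondary clones drawn), `cap_events` (fields whose VAF
#'   hit the 0.5 cap) and `seed_times`.
#' @export
simulate_clone_field_vafs <- function(rho, nu, t, n_fields, cells,
                                      seed_field = 1L, seed = NULL) {
  assert_that(n_fields >= 1L, "n_fields must be >= 1")
  assert_that(rho >= 0 && nu >= 0 && t >= 0, "rho, nu, t must be >= 0")
  if (!is.null(seed)) {
    old <- .Random.seed_guard(seed)
    on.exit(old(), add = TRUE)
  }
  cc <- 2 * cells
  n_sec <- stats::rpois(1L, nu * t)
  times <- sort(stats::runif(n_sec, 0, t))
  sizes <- exp(rho * (t - times))
  field_sizes <- numeric(n_fields)
  field_sizes[seed_field] <- exp(rho * t)
  if (n_sec > 0L) {
    open <- setdiff(seq_len(n_fields), seed_field)
    n_direct <- min(n_sec, length(open))
    if (n_direct > 0L) {
      pick <- if (length(open) == 1L) open else
        sample(open, n_direct, replace = FALSE)
      field_sizes[pick] <- sizes[seq_len(n_direct)]
      if (n_sec > n_direct) {   # overflow: merge into the last field used
        field_sizes[pick[n_direct]] <-
          field_sizes[pick[n_direct]] + sum(sizes[-seq_len(n_direct)])
      }
    }
  }
  vaf <- field_sizes / cc
  cap_events <- sum(vaf > 0.5)
  vaf <- pmin(vaf, 0.5)
  list(vaf = vaf, n_seeded = n_sec, cap_events = cap_events,
       seed_times = times)
}

## Planted histology gradient: UC in the (1,1) corner, HGIN around it,
## LGIN in the next ring, NU elsewhere.
plant_histology <- function(row, col) {
  d <- pmax(row - 1L, col - 1L)
  ifelse(d <= 1L, "UC", ifelse(d == 2L, "HGIN",
                               ifelse(d == 3L, "LGIN", "NU")))
}

#' Simulate a whole-organ mucosal mutation map
#'
#' Generates a field grid with a planted histology gradient and three
#' planted mutation classes driven by the branching process:
#' \describe{
#'   \item{alpha}{no immigration (`nu = 0`, private), old
#'     (`t ~ U(10, 30)`), primary VAF `~ U(0.01, 0.15)`.}
#'   \item{beta}{moderate immigration (`b = nu t ~ U(10, 25)`), low VAFs
#'     (primary `~ U(0.05, 0.15)`), intermediate age (`t ~ U(3, 8)`).}
#'   \item{gamma}{strongly supercritical growth (`a = rho t ~ U(13, 20)`,
#'     clone sizes far above the field pool, so present fields sit at the
#'     heterozygous 0.5 VAF ceiling), wide spread (`b ~ U(15, 30)`),
#'     young (`t ~ U(0.5, 2.5)`).}
#' }
#' Observed VAFs are binomial draws at per-field depths
#' `~ Normal(coverage_mean, coverage_sd)` truncated at 30 and rounded.
#' SNV trinucleotide contexts are drawn from the signature mixture
#' `W %*% H_star`; a small share of records become context-free
#' insertions/deletions.
#'
#' @param n_alpha,n_beta,n_gamma planted class counts (defaults 1000, 50,
#'   30).
#' @param grid_rows,grid_cols,n_fields field grid (defaults 5 x 8 grid,
#'   first 38 wells used).
#' @param cells uroprogenitor cells per field (default 5e3).
#' @param coverage_mean,coverage_sd sequencing depth distribution
#'   (defaults 300 and 85.3).
#' @param H_star generating signature mixture (default: weight 0.45, 0.25,
#'   0.15, 0.10, 0.05 on signatures 1, 6, 12, 20, 24 of `W`).
#' @param W a [signature_matrix()] (default
#'   [synthetic_signature_matrix()]).
#' @param frac_indel,frac_silent shares of indel records (INS/DEL, no
#'   context) and silent records.
#' @param driver_prob per-class probability that a mutation hits a driver
#'   gene.
#' @param seed RNG seed (default 7).
#' @param out_dir optional directory; when given, writes
#'   `mutations.tsv` (long dialect), `fields.tsv` and `truth.json`.
#' @return list with `records`, `vafs` (a [vaf_matrix()] with depths),
#'   `map` (an [organ_map()]), `truth` (per-mutation generating
#'   parameters: `class_true, rho, nu, t_true, a_true, b_true, seed_field,
#'   signature, is_driver`), `true_vafs` (uncensored true VAF matrix),
#'   `driver_genes`, and `config`.
#' @export
simulate_whole_organ <- function(n_alpha = 1000L, n_beta = 50L,
                                 n_gamma = 30L,
                                 grid_rows = 5L, grid_cols = 8L,
                                 n_fields = 38L, cells = 5e3,
                                 coverage_mean = 300, coverage_sd = 85.3,
                                 H_star = NULL, W = NULL,
                                 frac_indel = 0.058, frac_silent = 0.3,
                                 driver_prob = c(alpha = 0.05, beta = 0.15,
                                                 gamma = 0.30),
                                 seed = 7L, out_dir = NULL) {
  assert_that(n_fields <= grid_rows * grid_cols,
              "grid %dx%d cannot hold %d fields", grid_rows, grid_cols,
              n_fields)
  assert_that(n_alpha >= 0 && n_beta >= 0 && n_gamma >= 0,
              "class counts must be >= 0")
  if (is.null(W)) W <- synthetic_signature_matrix()
  if (is.null(H_star)) {
    H_star <- numeric(ncol(W))
    H_star[c(1L, 6L, 12L, 20L, 24L)] <- c(0.45, 0.25, 0.15, 0.10, 0.05)
  }
  assert_that(abs(sum(H_star) - 1) < 1e-8, "H_star must be on the simplex")
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)

  grid <- expand.grid(col = seq_len(grid_cols), row = seq_len(grid_rows))
  grid <- grid[seq_len(n_fields), ]
  map <- organ_map(sprintf("F%02d", seq_len(n_fields)),
                   grid$row, grid$col,
                   plant_histology(grid$row, grid$col))

  n <- n_alpha + n_beta + n_gamma
  assert_that(n >= 1L, "no mutations requested")
  cls <- rep(c("alpha", "beta", "gamma"), c(n_alpha, n_beta, n_gamma))
  cc <- 2 * cells
  t_true <- rho <- nu <- numeric(n)
  for (i in seq_len(n)) {
    if (cls[i] == "alpha") {
      t_true[i] <- stats::runif(1, 10, 30)
      a <- log(stats::runif(1, 0.01, 0.15) * cc)
      rho[i] <- a / t_true[i]
      nu[i] <- 0
    } else if (cls[i] == "beta") {
      t_true[i] <- stats::runif(1, 3, 8)
      a <- log(stats::runif(1, 0.05, 0.15) * cc)
      rho[i] <- a / t_true[i]
      nu[i] <- stats::runif(1, 10, 25) / t_true[i]
    } else {
      t_true[i] <- stats::runif(1, 0.5, 2.5)
      rho[i] <- stats::runif(1, 13, 20) / t_true[i]
      nu[i] <- stats::runif(1, 15, 30) / t_true[i]
    }
  }
  seed_field <- sample.int(n_fields, n, replace = TRUE)
  true_vafs <- matrix(0, n, n_fields)
  for (i in seq_len(n)) {
    true_vafs[i, ] <- simulate_clone_field_vafs(rho[i], nu[i], t_true[i],
                                                n_fields, cells,
                                                seed_field[i])$vaf
  }
  depth <- matrix(pmax(30, round(stats::rnorm(n * n_fields, coverage_mean,
                                              coverage_sd))),
                  n, n_fields)
  obs <- matrix(stats::rbinom(n * n_fields, depth, true_vafs), n, n_fields) /
    depth

  ids <- sprintf("M%05d", seq_len(n))
  vtype <- sample(c("SNV", "INS", "DEL"), n, replace = TRUE,
                  prob = c(1 - frac_indel, frac_indel * 0.6,
                           frac_indel * 0.4))
  z <- sample.int(ncol(W), n, replace = TRUE, prob = H_star)
  motif <- vapply(z, function(k) sample.int(96L, 1L, prob = W[, k]),
                  integer(1))
  dec <- motif_decode(motif)
  ref <- dec$ref; alt <- dec$alt; context <- dec$context
  ins <- vtype == "INS"; del <- vtype == "DEL"
  ref[ins] <- "A"; alt[ins] <- "AT"; context[ins] <- NA_character_
  ref[del] <- "AT"; alt[del] <- "A"; context[del] <- NA_character_
  driver_genes <- sprintf("DRV%02d", 1:50)
  is_driver <- stats::runif(n) < driver_prob[cls]
  gene <- ifelse(is_driver,
                 driver_genes[sample.int(50L, n, replace = TRUE)],
                 sprintf("G%04d", sample.int(8000L, n, replace = TRUE)))
  records <- data.frame(
    mutation_id = ids, gene = gene, chrom = "1",
    pos = 1000L + seq_len(n), ref = ref, alt = alt,
    variant_type = vtype,
    coding_effect = ifelse(stats::runif(n) < frac_silent, "silent",
                           "non_silent"),
    context = context, stringsAsFactors = FALSE)
  records$is_cosmic_driver <- is_driver

  dimnames(obs) <- list(ids, map$field_id)
  dimnames(depth) <- dimnames(obs)
  dimnames(true_vafs) <- dimnames(obs)
  vafs <- vaf_matrix(obs, missing = matrix(FALSE, n, n_fields),
                     depth = depth)
  truth <- data.frame(mutation_id = ids, class_true = cls,
                      rho = rho, nu = nu, t_true = t_true,
                      a_true = rho * t_true, b_true = nu * t_true,
                      seed_field = map$field_id[seed_field],
                      signature = colnames(W)[z],
                      is_driver = is_driver, stringsAsFactors = FALSE)
  out <- list(records = records, vafs = vafs, map = map, truth = truth,
              true_vafs = true_vafs, driver_genes = driver_genes,
              config = list(n_alpha = n_alpha, n_beta = n_beta,
                            n_gamma = n_gamma, n_fields = n_fields,
                            cells = cells, coverage_mean = coverage_mean,
                            coverage_sd = coverage_sd, seed = seed))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_mutation_table(records, vafs, file.path(out_dir, "mutations.tsv"))
    write_field_annotations(map, file.path(out_dir, "fields.tsv"))
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         digits = NA, auto_unbox = TRUE)
  }
  out
}

#' Simulate a model-consistent age-recovery cohort
#'
#' Draws mutation ages uniformly and immigration loads `b = nu t`
#' uniformly, then sets the proliferation rate from the migration law
#' `nu = nu0 * rho^sigma` so that the forward model and the age inversion
#' agree exactly.  Defaults are calibrated (see the methods vignette) so
#' the whole age range stays inside the observable VAF window
#' `[presence threshold, 0.5 cap]` at depth-300 binomial read noise.
#'
#' @param n cohort size (default 200).
#' @param t_range,b_range uniform ranges for age (years) and expected
#'   seeding count.
#' @param cells uroprogenitor cells per field (default 60; the observable
#'   window constrains `log(0.01 * 2 * cells)` from below).
#' @param nu0 reference migration rate (default 3.5e4, calibrated so the
#'   youngest clones clear the presence threshold).
#' @param sigma migration-law exponent (default 6).
#' @param n_fields fields per organ (default 60).
#' @param depth fixed binomial read depth (default 300).
#' @param seed RNG seed.
#' @return list with `vafs` (a [vaf_matrix()]), `truth` (per-mutation
#'   `t_true, b_true, a_true, rho, nu`) and `config` (a matching
#'   [chronology_config()]).
#' @export
simulate_age_cohort <- function(n = 200L, t_range = c(1, 30),
                                b_range = c(3, 25), cells = 60,
                                nu0 = 3.5e4, sigma = 6, n_fields = 60L,
                                depth = 300L, seed = 11L) {
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  t_true <- stats::runif(n, t_range[1L], t_range[2L])
  b_true <- stats::runif(n, b_range[1L], b_range[2L])
  nu <- b_true / t_true
  rho <- (b_true / (t_true * nu0))^(1 / sigma)
  a_true <- rho * t_true
  obs <- matrix(0, n, n_fields,
                dimnames = list(sprintf("A%04d", seq_len(n)),
                                sprintf("F%03d", seq_len(n_fields))))
  for (i in seq_len(n)) {
    tv <- simulate_clone_field_vafs(rho[i], nu[i], t_true[i], n_fields,
                                    cells, seed_field = 1L)$vaf
    obs[i, ] <- stats::rbinom(n_fields, depth, tv) / depth
  }
  dmat <- matrix(as.numeric(depth), n, n_fields, dimnames = dimnames(obs))
  list(vafs = vaf_matrix(obs, missing = matrix(FALSE, n, n_fields),
                         depth = dmat),
       truth = data.frame(mutation_id = rownames(obs), t_true = t_true,
                          b_true = b_true, a_true = a_true, rho = rho,
                          nu = nu, stringsAsFactors = FALSE),
       config = chronology_config(sigma = sigma, nu0 = nu0, cells = cells))
}

#' Simulate an omics abundance matrix with planted monotone trends
#'
#' Baseline abundances are log-normal; planted monotone features multiply
#' their group means by `effect` per progression step starting at the
#' control group; missingness is completely at random.
#'
#' @param n_features total features (default 2000).
#' @param group_sizes named sample counts, in order
#'   `control, NU_LGIN, HGIN, UC`.
#' @param n_up,n_down planted monotone feature counts (defaults 50, 50).
#' @param effect multiplicative per-step effect (default 1.5).
#' @param noise_sd log2-scale noise standard deviation (default 0.25).
#' @param missing_rate MCAR missingness (default 0.05).
#' @param seed RNG seed.
#' @return list with `matrix` (features x samples, `NA` missing),
#'   `groups`, and `truth` (`up`, `down` feature-id vectors).
#' @export
simulate_omics <- function(n_features = 2000L,
                           group_sizes = c(control = 6L, NU_LGIN = 12L,
                                           HGIN = 10L, UC = 10L),
                           n_up = 50L, n_down = 50L, effect = 1.5,
                           noise_sd = 0.25, missing_rate = 0.05,
                           seed = 23L) {
  assert_that(all(group_sizes >= 2L), "each group needs >= 2 samples")
  assert_that(n_up + n_down <= n_features, "too many planted features")
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  groups <- rep(names(group_sizes), group_sizes)
  ns <- length(groups)
  step <- match(groups, names(group_sizes)) - 1L  # control = 0 .. UC = 3
  feats <- sprintf("P%05d", seq_len(n_features))
  up <- feats[seq_len(n_up)]
  down <- feats[n_up + seq_len(n_down)]
  base <- stats::rnorm(n_features, mean = 10, sd = 1.5)   # log2 scale
  shift <- matrix(0, n_features, ns)
  shift[seq_len(n_up), ] <- matrix(rep(step, each = n_up), n_up) *
    log2(effect)
  if (n_down > 0L) {
    shift[n_up + seq_len(n_down), ] <-
      -matrix(rep(step, each = n_down), n_down) * log2(effect)
  }
  lg <- base + shift + matrix(stats::rnorm(n_features * ns, 0, noise_sd),
                              n_features, ns)
  m <- 2^lg
  if (missing_rate > 0) {
    m[matrix(stats::runif(n_features * ns) < missing_rate,
             n_features, ns)] <- NA
  }
  dimnames(m) <- list(feats, sprintf("%s_%02d", groups,
                                     stats::ave(seq_len(ns), groups,
                                                FUN = seq_along)))
  list(matrix = m, groups = groups, truth = list(up = up, down = down))
}
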