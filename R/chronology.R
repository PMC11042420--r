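## chronology: time-continuous Markov branching process with Poisson
## immigration.
##
## A mutant clone born t years ago grows deterministically as exp(rho * t)
## with rho = lambda * s (effective self-renewal rate, 1/year) and seeds
## secondary clones into new mucosal fields at Poisson rate nu (1/year).
## With c = 2 * N_cells haploid genomes per sampled field, the expected VAF
## of the i-th seeded clone (i = 0 is the primary) is
##
##   EV_0 = exp(a) / c
##   EV_i = exp(a) * (b / (a + b))^i * P(i, a + b) / c ,  i >= 1
##
## where a = rho * t, b = nu * t and P(i, x) is the regularised lower
## incomplete gamma function with integer shape i.  Estimating (a, b) from
## the sorted per-field VAF profile of a mutation and assuming the migration
## law nu = nu0 * rho^sigma yields the proliferation-rate proxy rho and the
## mutation age t:
##
##   rho = (b / (a * nu0))^(1/(sigma-1))
##   t   = a^(1 + 1/(sigma-1)) * (nu0 / b)^(1/(sigma-1))  =  a / rho .

#' Chronology model configuration
#'
#' @param sigma exponent of the migration law `nu = nu0 * rho^sigma`
#'   (must be > 1; default 6).
#' @param nu0 reference migration rate (1/year); calibrates the absolute
#'   age scale (default 1).
#' @param cells uroprogenitor cell count per sampled field; the VAF
#'   normaliser is `c = 2 * cells` haploid genomes (default 5e3, the
#'   best-fit value; scans cover 1e2 - 1e5).
#' @param i_max truncation of the clone index for expected-VAF sequences.
#' @param a_max,b_max optimiser box bounds for the (a, b) fit.
#' @param phase_cutoff_years dormant/progressive split: progressive iff
#'   `t < phase_cutoff_years` (default 5).
#' @param vaf_threshold presence threshold used when extracting a
#'   mutation's observed per-field VAFs.
#' @return list of class `chronology_config`.
#' @export
chronology_config <- function(sigma = 6, nu0 = 1.0, cells = 5e3, i_max = 25L,
                              a_max = 50, b_max = 50,
                              phase_cutoff_years = 5.0,
                              vaf_threshold = 0.01) {
  assert_that(sigma > 1, "sigma must exceed 1")
  assert_that(nu0 > 0, "nu0 must be positive")
  assert_that(cells >= 1, "cells must be >= 1")
  assert_that(is_count(i_max, 1L), "i_max must be a positive integer")
  structure(list(sigma = sigma, nu0 = nu0, cells = cells,
                 c = 2 * cells, i_max = as.integer(i_max),
                 a_max = a_max, b_max = b_max,
                 phase_cutoff_years = phase_cutoff_years,
                 vaf_threshold = vaf_threshold),
            class = "chronology_config")
}

#' Expected VAF sequence of successive clones
#'
#' @param a `rho * t` (dimensionless growth exponent), >= 0.
#' @param b `nu * t` (expected number of secondary seedings), >= 0.
#' @param c haploid genome count `2 * cells`, > 0.
#' @param i_max largest clone index.
#' @return numeric vector `EV_0 .. EV_{i_max}`.  `EV_0 = exp(a)/c`; for
#'   `i >= 1`, `EV_i = exp(a) (b/(a+b))^i P(i, a+b) / c`, evaluated in log
#'   space.  With `a + b = 0` all immigration terms are 0.
#' @export
expected_vaf_sequence <- function(a, b, c, i_max = 25L) {
  assert_that(a >= 0 && b >= 0, "a and b must be non-negative")
  assert_that(c > 0, "c must be positive")
  i <- seq_len(i_max)
  ev0 <- exp(a) / c
  if (a + b == 0 || b == 0) return(c(ev0, rep(0, i_max)))
  ## log EV_i = a + i log(b/(a+b)) + log P(i, a+b) - log c
  logp <- stats::pgamma(a + b, shape = i, log.p = TRUE)
  evi <- exp(a + i * (log(b) - log(a + b)) + logp - log(c))
  c(ev0, evi)
}

#' Fit (a, b) to a mutation's observed per-field VAFs
#'
#' Observed VAFs at or above the presence threshold are sorted in
#' decreasing order and paired with the expected sequence
#' `EV_0, EV_1, ...`; `(a, b)` minimises the sum of squared differences
#' over the box `[0, a_max] x [0, b_max]`.  The optimiser is deterministic:
#' Nelder-Mead from a fixed 5-point multistart grid followed by bounded
#' coordinate refinement (a simplex-then-bounded-scalar scheme).
#'
#' @param vaf_row numeric vector of per-field VAFs for one mutation.
#' @param config a [chronology_config()].
#' @return list with `a`, `b`, `sse`, `k` (fields used) and `flag`
#'   (`"ok"`, or `"single_field"` when only one field is present, in which
#'   case `a = max(0, log(v * c))` solves `EV_0 = v` and `b` is
#'   unidentifiable and returned as 0).
#' @export
fit_ab <- function(vaf_row, config = chronology_config()) {
  v <- sort(vaf_row[vaf_row >= config$vaf_threshold], decreasing = TRUE)
  k <- length(v)
  assert_that(k >= 1L, "all VAFs below the presence threshold; nothing to fit")
  cc <- config$c
  if (k == 1L) {
    return(list(a = max(0, log(v * cc)), b = 0, sse = 0, k = 1L,
                flag = "single_field"))
  }
  obj <- function(par) {
    a <- min(max(par[1L], 0), config$a_max)
    b <- min(max(par[2L], 0), config$b_max)
    ev <- expected_vaf_sequence(a, b, cc, k - 1L)
    sum((ev - v)^2)
  }
  a0 <- min(max(log(max(v) * cc), 0.01), config$a_max)
  b_starts <- c(0.5, 2, 5, 15, max(k - 1, 0.5))
  best <- NULL
  for (b0 in b_starts) {
    fit <- stats::optim(c(a0, b0), obj, method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  a <- min(max(best$par[1L], 0), config$a_max)
  b <- min(max(best$par[2L], 0), config$b_max)
  ## bounded coordinate refinement
  for (pass in 1:3) {
    oa <- stats::optimize(function(x) obj(c(x, b)), c(0, config$a_max),
                          tol = 1e-10)
    a <- oa$minimum
    ob <- stats::optimize(function(x) obj(c(a, x)), c(0, config$b_max),
                          tol = 1e-10)
    b <- ob$minimum
  }
  sse <- obj(c(a, b))
  flag <- if (best$convergence != 0L) "no_convergence" else "ok"
  list(a = a, b = b, sse = sse, k = k, flag = flag)
}

#' Invert (a, b) to proliferation rate and mutation age
#'
#' Under the migration law `nu = nu0 * rho^sigma`,
#' `rho = (b/(a*nu0))^(1/(sigma-1))` and `t = a / rho`.
#'
#' @param a,b fitted coefficients, both strictly positive.
#' @param config a [chronology_config()].
#' @return list with `rho` (1/year) and `t` (years); the identity
#'   `t * rho = a` holds to floating-point accuracy.
#' @export
invert_to_age <- function(a, b, config = chronology_config()) {
  assert_that(a > 0 && b > 0,
              "undefined age: a and b must both be positive (a=%g, b=%g)", a, b)
  e <- 1 / (config$sigma - 1)
  rho <- (b / (a * config$nu0))^e
  t <- a / rho
  list(rho = rho, t = t)
}

#' Assign dormant/progressive phase from a mutation age
#'
#' @param t mutation age(s) in years.
#' @param config a [chronology_config()]; progressive iff
#'   `t < phase_cutoff_years` (strict; `t` equal to the cutoff is dormant).
#' @return character vector `"dormant"`/`"progressive"`.
#' @export
assign_phase <- function(t, config = chronology_config()) {
  assert_that(all(t >= 0), "ages must be non-negative")
  ifelse(t < config$phase_cutoff_years, "progressive", "dormant")
}

#' Fit the chronology model to every mutation of a VAF matrix
#'
#' @param vafs a [vaf_matrix()].
#' @param config a [chronology_config()].
#' @return data frame with one row per mutation present somewhere:
#'   `mutation_id, a, b, sse, k, flag, rho, t, sel_proxy` (`a/b`, the
#'   selection-coefficient proxy) and `phase`; `rho`, `t`, `sel_proxy` and
#'   `phase` are `NA` where `b` is unidentifiable.
#' @export
fit_chronology <- function(vafs, config = chronology_config()) {
  ids <- rownames(vafs$values)
  vals <- vafs$values
  vals[vafs$missing] <- 0
  res <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    v <- vals[i, ]
    if (!any(v >= config$vaf_threshold)) next
    f <- fit_ab(v, config)
    row <- data.frame(mutation_id = ids[i], a = f$a, b = f$b, sse = f$sse,
                      k = f$k, flag = f$flag, rho = NA_real_, t = NA_real_,
                      sel_proxy = NA_real_, phase = NA_character_,
                      stringsAsFactors = FALSE)
    if (f$a > 0 && f$b > 0) {
      inv <- invert_to_age(f$a, f$b, config)
      row$rho <- inv$rho
      row$t <- inv$t
      row$sel_proxy <- f$a / f$b
      row$phase <- assign_phase(inv$t, config)
    }
    res[[i]] <- row
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Scan the uroprogenitor cell count against total fit error
#'
#' Refits every mutation at each cell count and reports the summed SSE;
#' the minimiser is flagged.
#'
#' @param vafs a [vaf_matrix()].
#' @param config a [chronology_config()] (its `cells` entry is overridden).
#' @param cells_grid cell counts to scan (default `1e2, 1e3, 5e3, 1e4, 1e5`).
#' @return data frame `cells, total_sse, n_fit, best`.
#' @export
scan_cells <- function(vafs, config = chronology_config(),
                       cells_grid = c(1e2, 1e3, 5e3, 1e4, 1e5)) {
  rows <- lapply(cells_grid, function(nc) {
    cfg <- config
    cfg$cells <- nc
    cfg$c <- 2 * nc
    fits <- fit_chronology(vafs, cfg)
    data.frame(cells = nc, total_sse = sum(fits$sse), n_fit = nrow(fits))
  })
  out <- do.call(rbind, rows)
  out$best <- seq_len(nrow(out)) == which.min(out$total_sse)
  out
}

#' Chronology report: ages, phases and mutagenesis by phase
#'
#' @param fits output of [fit_chronology()].
#' @param calls output of [classify_mutations()] aligned by mutation id.
#' @param records mutation record data frame.
#' @param truth optional data frame with `mutation_id` and planted `t_true`
#'   (from the synthetic generator); when given, planted per-class age
#'   medians are reported alongside the estimated ones.
#' @return list with `per_class` (estimated and, when available, planted
#'   age medians per alpha/beta/gamma class), `per_phase` (mutation counts
#'   split silent/non-silent and median fitted VAF-model parameters per
#'   phase), and `fits` (the joined per-mutation table).
#' @export
chronology_report <- function(fits, calls, records, truth = NULL) {
  tab <- merge(fits, calls[, c("mutation_id", "class")], by = "mutation_id")
  tab <- merge(tab, records[, c("mutation_id", "coding_effect")],
               by = "mutation_id", all.x = TRUE)
  if (!is.null(truth)) {
    tab <- merge(tab, truth[, c("mutation_id", "t_true")],
                 by = "mutation_id", all.x = TRUE)
  }
  per_class <- do.call(rbind, lapply(CLASS_LEVELS, function(cl) {
    sel <- tab$class == cl
    data.frame(class = cl, n = sum(sel),
               n_aged = sum(sel & !is.na(tab$t)),
               median_t = stats::median(tab$t[sel], na.rm = TRUE),
               median_sel_proxy = stats::median(tab$sel_proxy[sel],
                                                na.rm = TRUE),
               median_t_true = if (is.null(truth)) NA_real_ else
                 stats::median(tab$t_true[sel], na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  per_phase <- do.call(rbind, lapply(c("dormant", "progressive"), function(ph) {
    sel <- !is.na(tab$phase) & tab$phase == ph
    data.frame(phase = ph, n = sum(sel),
               n_silent = sum(sel & tab$coding_effect == "silent",
                              na.rm = TRUE),
               n_non_silent = sum(sel & tab$coding_effect == "non_silent",
                                  na.rm = TRUE),
               median_t = stats::median(tab$t[sel], na.rm = TRUE),
               median_a = stats::median(tab$a[sel], na.rm = TRUE),
               median_b = stats::median(tab$b[sel], na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  list(per_class = per_class, per_phase = per_phase, fits = tab)
}
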