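## mutation_classes: spatial spread categories and alpha/beta/gamma clonality
## classes for per-field VAF profiles.
##
## A mutation is "present" in a field when its VAF passes the presence
## threshold (default 0.01, the display threshold used for field-level maps).
## Private mutations (one field) are class alpha.  Mutations spread over
## several fields are gamma when their median VAF across present fields
## exceeds the high-VAF cutoff (strictly > 0.20), beta when at least a
## `consistency` share of present fields sit strictly below the cutoff, and
## otherwise beta with a "mixed" warning flag.

SPREAD_LEVELS <- c("private", "regional_2_10", "regional_11_20",
                   "widespread_21_30", "widespread_gt30")
CLASS_LEVELS <- c("alpha", "beta", "gamma")

#' Presence matrix at a VAF threshold
#'
#' @param vafs a [vaf_matrix()].
#' @param vaf_threshold presence threshold in the open interval (0, 1);
#'   an entry is present when `VAF >= vaf_threshold`.  Default `0.01`.
#' @param min_depth optional minimum read depth; requires depths in `vafs`.
#' @return logical mutations x fields matrix; masked-missing entries are
#'   `FALSE`.
#' @export
presence_matrix <- function(vafs, vaf_threshold = 0.01, min_depth = NULL) {
  assert_that(inherits(vafs, "vaf_matrix"), "vafs must be a vaf_matrix")
  assert_that(is.numeric(vaf_threshold) && vaf_threshold > 0 && vaf_threshold < 1,
              "vaf_threshold must lie in (0, 1)")
  pres <- vafs$values >= vaf_threshold & !vafs$missing
  if (!is.null(min_depth)) {
    assert_that(!is.null(vafs$depth), "min_depth given but vafs carries no depths")
    pres <- pres & !is.na(vafs$depth) & vafs$depth >= min_depth
  }
  pres
}

#' Spread category from a field count
#'
#' @param n_fields_present integer vector of counts of fields in which each
#'   mutation is present (all >= 1).
#' @return factor with levels `private, regional_2_10, regional_11_20,
#'   widespread_21_30, widespread_gt30`.
#' @export
spread_category <- function(n_fields_present) {
  assert_that(all(n_fields_present >= 1),
              "mutation absent everywhere (n_fields_present = 0)")
  cut(n_fields_present, breaks = c(0, 1, 10, 20, 30, Inf),
      labels = SPREAD_LEVELS, right = TRUE)
}

#' Classify mutations into alpha/beta/gamma clonality classes
#'
#' @param vafs a [vaf_matrix()].
#' @param vaf_threshold presence threshold, see [presence_matrix()].
#' @param high_vaf high-VAF cutoff; gamma requires median present VAF
#'   strictly above it.  Default `0.20`.
#' @param consistency minimum share of present fields strictly below
#'   `high_vaf` for a clean beta call.  Default `0.90`.
#' @param min_depth optional minimum read depth for presence.
#' @return data frame with one row per mutation present somewhere:
#'   `mutation_id, n_fields_present, spread, median_vaf_present,
#'   frac_fields_below_high, class, mixed` (logical warning flag).
#'   Mutations present nowhere are dropped with a warning.
#' @export
classify_mutations <- function(vafs, vaf_threshold = 0.01, high_vaf = 0.20,
                               consistency = 0.90, min_depth = NULL) {
  pres <- presence_matrix(vafs, vaf_threshold, min_depth)
  n_pres <- rowSums(pres)
  if (any(n_pres == 0L)) {
    warning(sprintf("%d mutation(s) present in no field were dropped",
                    sum(n_pres == 0L)))
  }
  keep <- n_pres > 0L
  assert_that(any(keep), "mutation absent everywhere: no mutation passes the presence threshold")
  ids <- rownames(vafs$values)[keep]
  n <- n_pres[keep]
  med <- numeric(length(ids))
  frac_lo <- numeric(length(ids))
  vals <- vafs$values
  for (k in seq_along(ids)) {
    i <- which(keep)[k]
    v <- vals[i, pres[i, ]]
    med[k] <- stats::median(v)
    frac_lo[k] <- mean(v < high_vaf)
  }
  cls <- character(length(ids))
  mixed <- logical(length(ids))
  for (k in seq_along(ids)) {
    if (n[k] == 1L) {
      cls[k] <- "alpha"
    } else if (med[k] > high_vaf) {
      cls[k] <- "gamma"
    } else if (frac_lo[k] >= consistency) {
      cls[k] <- "beta"
    } else {
      cls[k] <- "beta"
      mixed[k] <- TRUE
    }
  }
  data.frame(mutation_id = ids,
             n_fields_present = as.integer(n),
             spread = spread_category(n),
             median_vaf_present = med,
             frac_fields_below_high = frac_lo,
             class = factor(cls, levels = CLASS_LEVELS),
             mixed = mixed,
             stringsAsFactors = FALSE)
}

#' Classify a single mutation from its VAF row
#'
#' Convenience wrapper around the same rule as [classify_mutations()].
#'
#' @param vaf_row numeric vector of per-field VAFs.
#' @param vaf_threshold,high_vaf,consistency see [classify_mutations()].
#' @return one-row data frame as in [classify_mutations()].
#' @export
classify_mutation <- function(vaf_row, vaf_threshold = 0.01, high_vaf = 0.20,
                              consistency = 0.90) {
  m <- matrix(vaf_row, nrow = 1,
              dimnames = list("m", paste0("f", seq_along(vaf_row))))
  classify_mutations(vaf_matrix(m), vaf_threshold, high_vaf, consistency)
}

#' Optional monotone-trend annotation for beta-type mutations
#'
#' Flags whether a mutation's median VAF over present fields increases
#' strictly along the histology groups NU_LGIN -> HGIN -> UC.  This is a
#' descriptive annotation, not part of the classification rule.
#'
#' @param vafs a [vaf_matrix()].
#' @param map an [organ_map()] covering the columns of `vafs`.
#' @param vaf_threshold presence threshold.
#' @return logical vector named by mutation_id; `NA` when fewer than two
#'   groups contain present fields.
#' @export
vaf_trend_flag <- function(vafs, map, vaf_threshold = 0.01) {
  pres <- presence_matrix(vafs, vaf_threshold)
  grp <- map$group[match(colnames(vafs$values), map$field_id)]
  out <- rep(NA, nrow(vafs$values))
  names(out) <- rownames(vafs$values)
  for (i in seq_len(nrow(vafs$values))) {
    meds <- vapply(HISTOLOGY_GROUPS, function(g) {
      sel <- pres[i, ] & grp == g
      if (!any(sel)) NA_real_ else stats::median(vafs$values[i, sel])
    }, numeric(1))
    meds <- meds[!is.na(meds)]
    if (length(meds) >= 2L) out[i] <- all(diff(meds) > 0)
  }
  out
}

#' Summaries of class calls across fields and histology groups
#'
#' @param calls output of [classify_mutations()].
#' @param records mutation record data frame (needs `mutation_id`; driver
#'   fractions use `is_cosmic_driver` when available).
#' @param map an [organ_map()].
#' @param vafs the [vaf_matrix()] the calls came from.
#' @param vaf_threshold presence threshold used for the calls.
#' @param hist_breaks breakpoints for pooled per-class VAF histograms.
#' @return list with elements `per_field` (field x class counts of present
#'   mutations plus histology), `per_group` (per histology group box-plot
#'   statistics of total burden), `driver_fraction` (per class), and
#'   `vaf_histograms` (per class counts over `hist_breaks`).
#' @export
class_summary <- function(calls, records, map, vafs, vaf_threshold = 0.01,
                          hist_breaks = seq(0, 1, by = 0.05)) {
  pres <- presence_matrix(vafs, vaf_threshold)
  pres <- pres[calls$mutation_id, , drop = FALSE]
  per_field <- sapply(CLASS_LEVELS, function(cl) {
    colSums(pres[calls$class == cl, , drop = FALSE])
  })
  per_field <- as.data.frame(per_field)
  per_field$field_id <- rownames(per_field)
  per_field$total <- rowSums(per_field[, CLASS_LEVELS])
  per_field$histology <- map$histology[match(per_field$field_id, map$field_id)]
  per_field$group <- map$group[match(per_field$field_id, map$field_id)]
  rownames(per_field) <- NULL
  per_field <- per_field[, c("field_id", "histology", "group",
                             CLASS_LEVELS, "total")]

  per_group <- do.call(rbind, lapply(HISTOLOGY_GROUPS, function(g) {
    tot <- per_field$total[per_field$group == g]
    if (length(tot) == 0L) return(NULL)
    q <- stats::quantile(tot, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(group = g, n_fields = length(tot), q1 = q[1], median = q[2],
               q3 = q[3], stringsAsFactors = FALSE)
  }))

  driver <- records$is_cosmic_driver %||% rep(FALSE, nrow(records))
  names(driver) <- records$mutation_id
  driver_fraction <- vapply(CLASS_LEVELS, function(cl) {
    ids <- calls$mutation_id[calls$class == cl]
    if (length(ids) == 0L) return(NA_real_)
    mean(driver[ids])
  }, numeric(1))

  vaf_histograms <- lapply(stats::setNames(CLASS_LEVELS, CLASS_LEVELS),
    function(cl) {
      ids <- calls$mutation_id[calls$class == cl]
      if (length(ids) == 0L) return(integer(length(hist_breaks) - 1L))
      v <- vafs$values[ids, , drop = FALSE][pres[ids, , drop = FALSE]]
      graphics::hist(v, breaks = hist_breaks, plot = FALSE)$counts
    })

  list(per_field = per_field, per_group = per_group,
       driver_fraction = driver_fraction, vaf_histograms = vaf_histograms,
       hist_breaks = hist_breaks)
}
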