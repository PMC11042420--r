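test_that("presence matrix applies threshold, mask and depth filter", {
  v <- vm(rbind(c(0.005, 0.02, 0.0)))
  expect_identical(unname(presence_matrix(v, 0.01)[1L, ]),
                   c(FALSE, TRUE, FALSE))
  expect_error(presence_matrix(v, 0), "\\(0, 1\\)")
  expect_error(presence_matrix(v, 1), "\\(0, 1\\)")
  expect_false(any(presence_matrix(vm(rbind(c(0, 0, 0))), 0.01)))
  ## masked entries are absent even when the stored value passes
  mask <- matrix(c(FALSE, TRUE, FALSE), 1L)
  v2 <- vm(rbind(c(0.5, 0.5, 0.5)), missing = mask)
  expect_identical(unname(presence_matrix(v2, 0.01)[1L, ]),
                   c(TRUE, FALSE, TRUE))
  ## depth filter
  v3 <- vm(rbind(c(0.5, 0.5)), depth = rbind(c(100, 10)))
  expect_identical(unname(presence_matrix(v3, 0.01, min_depth = 30)[1L, ]),
                   c(TRUE, FALSE))
})

test_that("spread categories follow the field-count bins", {
  expect_identical(as.character(spread_category(c(1, 2, 10, 11, 12, 20, 21,
                                                  30, 31, 35))),
                   c("private", "regional_2_10", "regional_2_10",
                     "regional_11_20", "regional_11_20", "regional_11_20",
                     "widespread_21_30", "widespread_21_30",
                     "widespread_gt30", "widespread_gt30"))
  expect_error(spread_category(0), "absent everywhere")
})

test_that("alpha/beta/gamma calls follow the spread and VAF rules", {
  ## private, low VAF -> alpha
  expect_identical(as.character(classify_mutation(c(0.05, 0, 0))$class),
                   "alpha")
  ## 18 fields, VAFs in [0.02, 0.15] -> beta
  v <- c(seq(0.02, 0.15, length.out = 18), rep(0, 4))
  expect_identical(as.character(classify_mutation(v)$class), "beta")
  ## 30 fields, median 0.35 -> gamma
  v <- c(rep(0.35, 30), rep(0, 5))
  call <- classify_mutation(v)
  expect_identical(as.character(call$class), "gamma")
  expect_identical(as.character(call$spread), "widespread_21_30")
  ## median exactly at the cutoff is not gamma (strict >)
  expect_identical(as.character(classify_mutation(rep(0.20, 5))$class),
                   "beta")
  ## mixed profile: spread but neither consistently low nor median-high
  call <- classify_mutation(c(rep(0.05, 6), rep(0.45, 4)))
  expect_identical(as.character(call$class), "beta")
  expect_true(call$mixed)
  ## absent everywhere
  expect_error(suppressWarnings(classify_mutation(c(0, 0))),
               "absent everywhere")
})

test_that("class calls partition mutations and alpha <=> private", {
  set.seed(31)
  for (rep in 1:5) {
    m <- matrix(stats::rbinom(40 * 12, 1, 0.3) *
                  stats::runif(40 * 12, 0.01, 0.6), 40, 12)
    keep <- rowSums(m >= 0.01) > 0
    calls <- suppressWarnings(classify_mutations(vm(m)))
    expect_equal(nrow(calls), sum(keep))
    expect_setequal(as.character(unique(calls$class)),
                    intersect(c("alpha", "beta", "gamma"),
                              as.character(calls$class)))
    expect_identical(calls$class == "alpha", calls$spread == "private")
    ## raising the threshold never increases n_fields_present
    calls2 <- suppressWarnings(classify_mutations(vm(m),
                                                  vaf_threshold = 0.05))
    shared <- intersect(calls$mutation_id, calls2$mutation_id)
    expect_true(all(
      calls2$n_fields_present[match(shared, calls2$mutation_id)] <=
        calls$n_fields_present[match(shared, calls$mutation_id)]))
  }
})

test_that("planted class labels are recovered from a small organ", {
  sim <- simulate_whole_organ(n_alpha = 100, n_beta = 10, n_gamma = 5,
                              seed = 12)
  calls <- suppressWarnings(classify_mutations(sim$vafs))
  tab <- merge(calls, sim$truth, by = "mutation_id")
  expect_gt(mean(as.character(tab$class) == tab$class_true), 0.95)
  cnt <- table(factor(tab$class_true, c("alpha", "beta", "gamma")))
  expect_identical(unname(cnt[c("beta", "gamma")]),
                   table(factor(c(rep("b", 10), rep("g", 5))))[c("b", "g")],
                   ignore_attr = TRUE)
})

test_that("class_summary aggregates per field, group and driver status", {
  sim <- simulate_whole_organ(n_alpha = 60, n_beta = 8, n_gamma = 4,
                              seed = 5)
  calls <- suppressWarnings(classify_mutations(sim$vafs))
  s <- class_summary(calls, sim$records, sim$map, sim$vafs)
  expect_setequal(s$per_field$field_id, sim$map$field_id)
  expect_true(all(s$per_field$total ==
                    rowSums(s$per_field[, c("alpha", "beta", "gamma")])))
  expect_setequal(s$per_group$group, c("NU_LGIN", "HGIN", "UC"))
  expect_true(all(s$per_group$q1 <= s$per_group$median &
                    s$per_group$median <= s$per_group$q3))
  expect_true(all(s$driver_fraction >= 0 & s$driver_fraction <= 1,
                  na.rm = TRUE))
  ## all driver flags false -> all fractions zero
  rec0 <- sim$records
  rec0$is_cosmic_driver <- FALSE
  s0 <- class_summary(calls, rec0, sim$map, sim$vafs)
  expect_true(all(s0$driver_fraction == 0, na.rm = TRUE))
  ## histogram counts cover every present VAF observation
  pres <- presence_matrix(sim$vafs)[calls$mutation_id, ]
  expect_equal(sum(unlist(s$vaf_histograms)), sum(pres))
})

test_that("trend annotation flags monotone group medians", {
  map <- organ_map(c("A", "B", "C"), c(1, 1, 1), 1:3,
                   c("NU", "HGIN", "UC"))
  v <- vm(rbind(up = c(0.05, 0.10, 0.20), down = c(0.20, 0.10, 0.05)))
  colnames(v$values) <- c("A", "B", "C")  # align with map
  v <- vaf_matrix(v$values)
  fl <- vaf_trend_flag(v, map)
  expect_true(fl[["up"]])
  expect_false(fl[["down"]])
})
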