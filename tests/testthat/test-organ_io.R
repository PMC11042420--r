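test_that("long tables parse into aligned records and VAF matrix", {
  mt <- read_mutation_table(fixture_long_table(), "long")
  expect_identical(dim(mt$vafs$values), c(3L, 2L))
  expect_equal(nrow(mt$records), 3L)
  expect_true(all(mt$vafs$values == 0.1))
  expect_false(any(mt$vafs$missing))
})

test_that("wide and long dialects give identical in-memory objects", {
  long <- read_mutation_table(fixture_long_table(), "long")
  wide <- read_mutation_table(fixture_wide_table(), "wide")
  expect_identical(long$vafs$values, wide$vafs$values)
  expect_identical(long$records, wide$records)
})

test_that("malformed and conflicting mutation tables are rejected", {
  expect_error(read_mutation_table(fixture_long_table(vaf = "1.5"), "long"),
               "malformed VAF.*row 1.*M01.*F01")
  ## duplicate (mutation, field) pair
  lines <- readLines(fixture_long_table())
  expect_error(read_mutation_table(write_lines_tmp(c(lines, lines[2L])),
                                   "long"),
               "duplicate \\(mutation, field\\)")
  ## conflicting annotation for one mutation id
  bad <- sub("TP53\t17\t7577121", "KRAS\t12\t25398284", lines[2L])
  expect_error(read_mutation_table(write_lines_tmp(c(lines[-2L], bad)),
                                   "long"),
               "conflicting annotations.*M01")
  ## missing mandatory column
  noref <- sapply(strsplit(lines, "\t"), function(p) paste(p[-5L],
                                                           collapse = "\t"))
  expect_error(read_mutation_table(write_lines_tmp(noref), "long"),
               "lacks column.*ref")
})

test_that("parse -> write -> parse is the identity for mutation tables", {
  sim <- simulate_whole_organ(n_alpha = 30, n_beta = 5, n_gamma = 3,
                              seed = 42)
  path <- tempfile(fileext = ".tsv")
  write_mutation_table(sim$records, sim$vafs, path)
  back <- read_mutation_table(path, "long")
  expect_equal(back$vafs$values, sim$vafs$values)
  expect_equal(back$vafs$depth, sim$vafs$depth)
  cols <- intersect(names(back$records), names(sim$records))
  ord <- match(back$records$mutation_id, sim$records$mutation_id)
  expect_equal(back$records[cols], sim$records[ord, cols],
               ignore_attr = TRUE)
})

test_that("field annotations parse, derive groups, and reject bad codes", {
  map <- read_field_annotations(fixture_field_table(38))
  expect_s3_class(map, "organ_map")
  expect_equal(nrow(map), 38L)
  expect_identical(map$group[map$histology == "LGIN"],
                   rep("NU_LGIN", sum(map$histology == "LGIN")))
  expect_identical(map$group[map$histology == "NU"],
                   rep("NU_LGIN", sum(map$histology == "NU")))
  lines <- readLines(fixture_field_table(4))
  lines[3L] <- sub("\tLGIN", "\tXX", lines[3L])
  expect_error(read_field_annotations(write_lines_tmp(lines)),
               "unknown histology code.*XX")
  expect_error(read_field_annotations(write_lines_tmp(c(lines[1:2],
                                                        lines[2L]))),
               "duplicate field_id")
  ## round trip
  path <- tempfile(fileext = ".tsv")
  write_field_annotations(map, path)
  expect_equal(read_field_annotations(path), map)
})

test_that("signature matrix reader normalises order and validates sums", {
  W <- synthetic_signature_matrix(K = 5)
  got <- read_signature_matrix(fixture_signature_csv(W))
  expect_equal(unclass(got), unclass(W), tolerance = 1e-12)
  ## shuffled rows give the same matrix
  set.seed(9)
  got2 <- read_signature_matrix(fixture_signature_csv(W, shuffle = TRUE))
  expect_equal(unclass(got2), unclass(W), tolerance = 1e-12)
  ## a 96 x 30 file yields 30 signatures
  W30 <- synthetic_signature_matrix(K = 30)
  expect_equal(ncol(read_signature_matrix(fixture_signature_csv(W30))), 30L)
  ## bad column sum
  Wbad <- unclass(W)
  Wbad[, 2L] <- Wbad[, 2L] * 0.8
  df <- data.frame(motif = rownames(W), Wbad, check.names = FALSE)
  p <- tempfile(fileext = ".csv")
  utils::write.csv(df, p, row.names = FALSE)
  expect_error(read_signature_matrix(p), "sums to 0.8")
  ## negative entry
  Wneg <- unclass(W)
  Wneg[1L, 1L] <- -Wneg[1L, 1L]
  Wneg[, 1L] <- Wneg[, 1L] / sum(Wneg[, 1L])
  df <- data.frame(motif = rownames(W), Wneg, check.names = FALSE)
  utils::write.csv(df, p, row.names = FALSE)
  expect_error(read_signature_matrix(p), "negative")
  ## wrong row count
  utils::write.csv(df[1:95, ], p, row.names = FALSE)
  expect_error(read_signature_matrix(p), "96 rows")
})

test_that("GMT and abundance readers work", {
  gmt <- write_lines_tmp(c("setA\tdesc\tP1\tP2\tP3",
                           "setB\tdesc\tP2\tP4"), ext = ".gmt")
  sets <- read_gmt(gmt)
  expect_named(sets, c("setA", "setB"))
  expect_identical(sets$setA, c("P1", "P2", "P3"))
  expect_error(read_gmt(write_lines_tmp("lonely\tdesc", ext = ".gmt")),
               "fewer than 3")
  ab <- write_lines_tmp(c("feature\ts1\ts2", "P1\t1.5\t2", "P2\tNA\t0.5"))
  m <- read_abundance_matrix(ab)
  expect_identical(dim(m), c(2L, 2L))
  expect_true(is.na(m["P2", "s1"]))
})
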