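## organ_io: readers/writers and the in-memory whole-organ data model.
##
## Three tabular inputs are supported: a MAF-like mutation table (long or wide
## dialect), a field-annotation table describing the mucosal sampling grid,
## and a 96 x K signature matrix CSV.  GMT pathway sets and plain TSV
## abundance matrices for the omics module are read here as well.

HISTOLOGY_CODES <- c("NU", "LGIN", "HGIN", "UC")
HISTOLOGY_GROUPS <- c("NU_LGIN", "HGIN", "UC")

MUTATION_COLUMNS <- c("mutation_id", "gene", "chrom", "pos", "ref", "alt",
                      "variant_type", "coding_effect")
VARIANT_TYPES <- c("SNV", "INS", "DEL")
CODING_EFFECTS <- c("silent", "non_silent")

#' Histology group of a histology code
#'
#' Fields labelled NU (normal urothelium) and LGIN (low-grade intraurothelial
#' neoplasia) are merged into a single `NU_LGIN` group; HGIN and UC map to
#' themselves.
#'
#' @param histology character vector of codes among `NU, LGIN, HGIN, UC`.
#' @return character vector of group labels among `NU_LGIN, HGIN, UC`.
#' @export
histology_group <- function(histology) {
  bad <- setdiff(unique(histology), HISTOLOGY_CODES)
  assert_that(length(bad) == 0L, "unknown histology code(s): %s",
              paste(bad, collapse = ", "))
  ifelse(histology %in% c("NU", "LGIN"), "NU_LGIN", histology)
}

#' Construct an organ map
#'
#' An organ map is the catalogue of mucosal fields sampled from the
#' whole-organ grid: one row per field with its grid coordinates and
#' histologic call.
#'
#' @param field_id character vector of unique field identifiers.
#' @param row,col non-negative integer grid indices.
#' @param histology character vector of codes among `NU, LGIN, HGIN, UC`.
#' @return a data frame of class `organ_map` with columns
#'   `field_id, row, col, histology, group`.
#' @export
organ_map <- function(field_id, row, col, histology) {
  field_id <- as.character(field_id)
  assert_that(!anyDuplicated(field_id), "duplicate field_id: %s",
              paste(unique(field_id[duplicated(field_id)]), collapse = ", "))
  assert_that(all(row >= 0) && all(col >= 0), "grid indices must be >= 0")
  assert_that(length(row) == length(field_id) && length(col) == length(field_id)
              && length(histology) == length(field_id),
              "organ_map column lengths differ")
  out <- data.frame(field_id = field_id, row = as.integer(row),
                    col = as.integer(col), histology = histology,
                    group = histology_group(histology),
                    stringsAsFactors = FALSE)
  class(out) <- c("organ_map", "data.frame")
  out
}

#' Read a field-annotation table
#'
#' Expects a TSV with columns `field_id, row, col, histology`.
#'
#' @param path path to the TSV file.
#' @return an [organ_map()].
#' @export
read_field_annotations <- function(path) {
  assert_that(file.exists(path), "no such file: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(field_id = "character"))
  need <- c("field_id", "row", "col", "histology")
  miss <- setdiff(need, names(df))
  assert_that(length(miss) == 0L, "field annotation file %s lacks column(s): %s",
              path, paste(miss, collapse = ", "))
  organ_map(df$field_id, df$row, df$col, df$histology)
}

#' Write a field-annotation table
#' @param map an [organ_map()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_field_annotations <- function(map, path) {
  utils::write.table(map[, c("field_id", "row", "col", "histology")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_mutation_records <- function(rec) {
  miss <- setdiff(MUTATION_COLUMNS, names(rec))
  assert_that(length(miss) == 0L, "mutation table lacks column(s): %s",
              paste(miss, collapse = ", "))
  assert_that(!anyDuplicated(rec$mutation_id), "duplicate mutation_id: %s",
              paste(unique(rec$mutation_id[duplicated(rec$mutation_id)]),
                    collapse = ", "))
  assert_that(all(rec$pos >= 1), "positions are 1-based and must be >= 1")
  bad <- setdiff(unique(rec$variant_type), VARIANT_TYPES)
  assert_that(length(bad) == 0L, "unknown variant_type: %s",
              paste(bad, collapse = ", "))
  bad <- setdiff(unique(rec$coding_effect), CODING_EFFECTS)
  assert_that(length(bad) == 0L, "unknown coding_effect: %s",
              paste(bad, collapse = ", "))
  snv <- rec$variant_type == "SNV"
  if (any(snv)) {
    ok <- nchar(rec$ref[snv]) == 1L & nchar(rec$alt[snv]) == 1L &
      rec$ref[snv] != rec$alt[snv] &
      rec$ref[snv] %in% DNA_BASES & rec$alt[snv] %in% DNA_BASES
    assert_that(all(ok), "invalid SNV ref/alt for mutation(s): %s",
                paste(rec$mutation_id[snv][!ok], collapse = ", "))
    if (!is.null(rec$context)) {
      has <- snv & !is.na(rec$context) & nzchar(rec$context)
      if (any(has)) {
        okc <- nchar(rec$context[has]) == 3L &
          substr(rec$context[has], 2L, 2L) == rec$ref[has]
        assert_that(all(okc),
                    "context middle base must equal ref for mutation(s): %s",
                    paste(rec$mutation_id[has][!okc], collapse = ", "))
      }
    }
  }
  invisible(rec)
}

#' Construct a VAF matrix
#'
#' Mutations x fields matrix of variant allele frequencies with an explicit
#' missing mask (entries never observed are stored as 0 and masked) and an
#' optional matching read-depth matrix.
#'
#' @param values numeric matrix in `[0, 1]`, rows named by mutation_id,
#'   columns by field_id.
#' @param missing logical matrix of the same shape; `TRUE` marks entries that
#'   were never observed.
#' @param depth optional integer matrix of read depths.
#' @return a list of class `vaf_matrix` with elements
#'   `values, missing, depth, mutations, fields`.
#' @export
vaf_matrix <- function(values, missing = NULL, depth = NULL) {
  assert_that(is.matrix(values) && is.numeric(values), "values must be a matrix")
  assert_that(!is.null(rownames(values)) && !is.null(colnames(values)),
              "values must have mutation and field dimnames")
  assert_that(!anyDuplicated(rownames(values)) && !anyDuplicated(colnames(values)),
              "row/column labels must be unique")
  bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
  assert_that(nrow(bad) == 0L || length(bad) == 0L,
              "VAF outside [0,1] for mutation '%s' in field '%s'",
              rownames(values)[bad[1L]], colnames(values)[bad[2L]])
  if (is.null(missing)) missing <- is.na(values)
  missing <- missing | is.na(values)
  values[is.na(values)] <- 0
  assert_that(identical(dim(missing), dim(values)), "missing mask shape mismatch")
  if (!is.null(depth)) {
    assert_that(identical(dim(depth), dim(values)), "depth matrix shape mismatch")
    assert_that(all(depth[!missing] >= 0), "negative read depth")
  }
  structure(list(values = values, missing = missing, depth = depth,
                 mutations = rownames(values), fields = colnames(values)),
            class = "vaf_matrix")
}

#' @export
print.vaf_matrix <- function(x, ...) {
  cat(sprintf("vaf_matrix: %d mutations x %d fields (%d observed entries%s)\n",
              nrow(x$values), ncol(x$values), sum(!x$missing),
              if (is.null(x$depth)) "" else ", with depths"))
  invisible(x)
}

#' Read a mutation table
#'
#' Two dialects are supported.  The *long* dialect has one row per observed
#' (mutation, field) pair and columns
#' `mutation_id, gene, chrom, pos, ref, alt, variant_type, coding_effect,
#' context, field_id, vaf` plus an optional `depth`.  The *wide* dialect has
#' one row per mutation with the same annotation columns followed by one VAF
#' column per field (any column that is not an annotation column is taken to
#' be a field).  Pairs absent from a long table, and `NA` cells in a wide
#' table, are recorded in the missing mask.
#'
#' @param path path to the TSV file.
#' @param dialect `"long"` or `"wide"`.
#' @param driver_genes optional character vector of driver gene symbols; when
#'   given, records gain a logical `is_cosmic_driver` column.
#' @return `list(records = <data.frame>, vafs = <vaf_matrix>)`.
#' @export
read_mutation_table <- function(path, dialect = c("long", "wide"),
                                driver_genes = NULL) {
  dialect <- match.arg(dialect)
  assert_that(file.exists(path), "no such file: %s", path)
  ## read everything as character first: type inference would turn an
  ## all-"T" ref/alt column into logicals
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE, colClasses = "character")
  if ("pos" %in% names(df)) df$pos <- as.integer(df$pos)
  if (dialect == "long") {
    if ("vaf" %in% names(df)) df$vaf <- as.numeric(df$vaf)
    if ("depth" %in% names(df)) df$depth <- as.numeric(df$depth)
  } else {
    for (nm in setdiff(names(df), c(MUTATION_COLUMNS, "context"))) {
      df[[nm]] <- as.numeric(df[[nm]])
    }
  }
  if (dialect == "long") {
    need <- c(MUTATION_COLUMNS, "field_id", "vaf")
    miss <- setdiff(need, names(df))
    assert_that(length(miss) == 0L, "long mutation table lacks column(s): %s",
                paste(miss, collapse = ", "))
    bad <- which(!is.finite(df$vaf) | df$vaf < 0 | df$vaf > 1)
    assert_that(length(bad) == 0L,
                "malformed VAF %s outside [0,1] at row %d (mutation '%s', field '%s')",
                format(df$vaf[bad[1L]]), bad[1L],
                df$mutation_id[bad[1L]], df$field_id[bad[1L]])
    key <- paste(df$mutation_id, df$field_id, sep = "\r")
    dup <- duplicated(key)
    assert_that(!any(dup), "duplicate (mutation, field) pair(s): %s",
                paste(unique(paste0(df$mutation_id[dup], "/", df$field_id[dup])),
                      collapse = ", "))
    ann_cols <- intersect(c(MUTATION_COLUMNS, "context"), names(df))
    rec <- unique(df[, ann_cols])
    dup_ann <- duplicated(rec$mutation_id)
    assert_that(!any(dup_ann),
                "conflicting annotations for mutation_id: %s",
                paste(unique(rec$mutation_id[dup_ann]), collapse = ", "))
    fields <- sort(unique(as.character(df$field_id)))
    muts <- rec$mutation_id
    vals <- matrix(NA_real_, length(muts), length(fields),
                   dimnames = list(muts, fields))
    vals[cbind(match(df$mutation_id, muts), match(df$field_id, fields))] <- df$vaf
    depth <- NULL
    if ("depth" %in% names(df)) {
      depth <- matrix(NA_real_, length(muts), length(fields),
                      dimnames = list(muts, fields))
      depth[cbind(match(df$mutation_id, muts),
                  match(df$field_id, fields))] <- df$depth
    }
  } else {
    ann_cols <- intersect(c(MUTATION_COLUMNS, "context"), names(df))
    miss <- setdiff(MUTATION_COLUMNS, ann_cols)
    assert_that(length(miss) == 0L, "wide mutation table lacks column(s): %s",
                paste(miss, collapse = ", "))
    field_cols <- setdiff(names(df), c(ann_cols, "depth"))
    assert_that(length(field_cols) >= 1L, "wide mutation table has no field columns")
    dup <- duplicated(df$mutation_id)
    assert_that(!any(dup), "duplicate mutation_id: %s",
                paste(unique(df$mutation_id[dup]), collapse = ", "))
    rec <- df[, ann_cols]
    vals <- as.matrix(df[, field_cols, drop = FALSE])
    storage.mode(vals) <- "double"
    rownames(vals) <- df$mutation_id
    bad <- which(!is.na(vals) & (vals < 0 | vals > 1), arr.ind = TRUE)
    assert_that(nrow(bad) == 0L,
                "malformed VAF outside [0,1] for mutation '%s', field '%s'",
                rownames(vals)[bad[1L]], colnames(vals)[bad[2L]])
    vals <- vals[, sort(colnames(vals)), drop = FALSE]
    depth <- NULL
  }
  rownames(rec) <- NULL
  if (is.null(rec$context)) rec$context <- NA_character_
  rec$context[!is.na(rec$context) & !nzchar(rec$context)] <- NA_character_
  validate_mutation_records(rec)
  if (!is.null(driver_genes)) rec$is_cosmic_driver <- rec$gene %in% driver_genes
  list(records = rec, vafs = vaf_matrix(vals, depth = depth))
}

#' Write a mutation table in the long dialect
#'
#' Only observed (unmasked) entries are emitted, so a read/write/read
#' round trip is the identity.
#'
#' @param records mutation record data frame.
#' @param vafs a [vaf_matrix()] aligned with `records`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_mutation_table <- function(records, vafs, path) {
  obs <- which(!vafs$missing, arr.ind = TRUE)
  ann_cols <- intersect(c(MUTATION_COLUMNS, "context"), names(records))
  i <- match(rownames(vafs$values)[obs[, 1L]], records$mutation_id)
  out <- records[i, ann_cols]
  out$field_id <- colnames(vafs$values)[obs[, 2L]]
  out$vaf <- vafs$values[obs]
  if (!is.null(vafs$depth)) out$depth <- vafs$depth[obs]
  out <- out[order(out$mutation_id, out$field_id), ]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a 96 x K signature matrix CSV
#'
#' The first column must hold motif labels in the `A[C>A]A` form; remaining
#' columns are signatures.  Rows may appear in any order and are normalised
#' to the canonical motif order (substitution classes `C>A, C>G, C>T, T>A,
#' T>C, T>G`, then 5' base, then 3' base, each in A,C,G,T order).  Columns
#' must each sum to 1 within `1e-6` and are renormalised exactly.
#'
#' @param path path to the CSV file.
#' @return a [signature_matrix()].
#' @export
read_signature_matrix <- function(path) {
  assert_that(file.exists(path), "no such file: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  assert_that(nrow(df) == 96L, "signature matrix must have 96 rows, found %d",
              nrow(df))
  motifs <- as.character(df[[1L]])
  W <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(W) <- "double"
  rownames(W) <- motifs
  canon <- canonical_motifs()
  miss <- setdiff(canon, motifs)
  assert_that(length(miss) == 0L, "missing motif row(s): %s",
              paste(utils::head(miss, 5L), collapse = ", "))
  W <- W[canon, , drop = FALSE]
  signature_matrix(W)
}

#' Write a signature matrix CSV
#' @param W a [signature_matrix()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_signature_matrix <- function(W, path) {
  df <- data.frame(motif = rownames(W), W, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read pathway sets in GMT format
#'
#' Tab-separated lines: set name, description, then member ids.  Duplicate
#' members within a set are dropped.
#'
#' @param path path to the GMT file.
#' @return named list of character vectors of member ids.
#' @export
read_gmt <- function(path) {
  assert_that(file.exists(path), "no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    assert_that(length(parts) >= 3L, "GMT line with fewer than 3 fields: %s",
                substr(ln, 1, 40))
    members <- unique(parts[-(1:2)])
    members <- members[nzchar(members)]
    assert_that(length(members) >= 1L, "empty pathway set '%s'", parts[1L])
    assert_that(is.null(sets[[parts[1L]]]), "duplicate pathway set '%s'", parts[1L])
    sets[[parts[1L]]] <- members
  }
  sets
}

#' Read a feature-abundance matrix TSV
#'
#' First column feature ids, remaining columns samples; empty cells or `NA`
#' are treated as missing.
#'
#' @param path path to the TSV file.
#' @return numeric matrix (features x samples) with `NA` for missing values.
#' @export
read_abundance_matrix <- function(path) {
  assert_that(file.exists(path), "no such file: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1L]])
  assert_that(all(is.na(m) | m >= 0), "negative abundance value")
  m
}
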