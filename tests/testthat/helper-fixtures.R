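## In-code fixtures: tiny tables written to tempfiles at test time.

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

## A 3-mutation x 2-field long-dialect mutation table, all VAFs 0.1.
fixture_long_table <- function(vaf = "0.1") {
  hdr <- paste("mutation_id", "gene", "chrom", "pos", "ref", "alt",
               "variant_type", "coding_effect", "context", "field_id",
               "vaf", sep = "\t")
  rows <- c()
  for (m in 1:3) {
    for (f in c("F01", "F02")) {
      rows <- c(rows, paste(sprintf("M%02d", m), "TP53", "17",
                            7577120 + m, "C", "T", "SNV", "non_silent",
                            "ACA", f, vaf, sep = "\t"))
    }
  }
  write_lines_tmp(c(hdr, rows))
}

## The same content in the wide dialect.
fixture_wide_table <- function() {
  hdr <- paste("mutation_id", "gene", "chrom", "pos", "ref", "alt",
               "variant_type", "coding_effect", "context", "F01", "F02",
               sep = "\t")
  rows <- vapply(1:3, function(m) {
    paste(sprintf("M%02d", m), "TP53", "17", 7577120 + m, "C", "T",
          "SNV", "non_silent", "ACA", "0.1", "0.1", sep = "\t")
  }, character(1))
  write_lines_tmp(c(hdr, rows))
}

fixture_field_table <- function(n = 38) {
  hist <- rep(c("NU", "LGIN", "HGIN", "UC"), length.out = n)
  c_hdr <- "field_id\trow\tcol\thistology"
  rows <- sprintf("F%02d\t%d\t%d\t%s", seq_len(n),
                  (seq_len(n) - 1L) %/% 8L + 1L,
                  (seq_len(n) - 1L) %% 8L + 1L, hist)
  write_lines_tmp(c(c_hdr, rows))
}

fixture_signature_csv <- function(W = synthetic_signature_matrix(K = 5),
                                  shuffle = FALSE) {
  path <- tempfile(fileext = ".csv")
  if (shuffle) {
    ord <- sample(96L)
    df <- data.frame(motif = rownames(W)[ord],
                     unclass(W)[ord, , drop = FALSE], check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    write_signature_matrix(W, path)
  }
  path
}

## Minimal record table for spectrum tests.
records_of <- function(ref, alt, context = NA_character_,
                       variant_type = "SNV", coding_effect = "non_silent") {
  n <- length(ref)
  data.frame(mutation_id = sprintf("R%03d", seq_len(n)),
             gene = "G", chrom = "1", pos = seq_len(n),
             ref = ref, alt = alt, variant_type = variant_type,
             coding_effect = coding_effect, context = context,
             stringsAsFactors = FALSE)
}

## Small vaf_matrix from a plain matrix.
vm <- function(m, ...) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("M%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("F%02d", seq_len(ncol(m)))
  vaf_matrix(m, ...)
}
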