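# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_of <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop_of(fmt, ...)
  invisible(TRUE)
}

#' @noRd
is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == floor(x)
}

is_fraction <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

DNA_BASES <- c("A", "C", "G", "T")
DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Reverse-complement a nucleotide string
#'
#' Vectorised over `x`; only A/C/G/T are accepted.
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("TGA")  # "TCA"
revcomp <- function(x) {
  vapply(x, function(s) {
    b <- strsplit(s, "", fixed = TRUE)[[1]]
    assert_that(all(b %in% DNA_BASES), "non-ACGT base in '%s'", s)
    paste(rev(unname(DNA_COMPLEMENT[b])), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

## Canonical 96-motif order: substitution classes C>A, C>G, C>T, T>A, T>C, T>G;
## within each class the 5' flanking base cycles slowest (A,C,G,T), then the
## 3' base (A,C,G,T).  Labels use the conventional "A[C>A]A" form.
SUBSTITUTION_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

canonical_motifs <- function() {
  out <- character(96)
  k <- 1L
  for (sub in SUBSTITUTION_CLASSES) {
    for (p5 in DNA_BASES) {
      for (p3 in DNA_BASES) {
        out[k] <- sprintf("%s[%s]%s", p5, sub, p3)
        k <- k + 1L
      }
    }
  }
  out
}

## Map (ref, alt, context) for an SNV to its canonical motif index in 1..96.
## Purine-reference changes are reverse-complemented to pyrimidine reference.
motif_index <- function(ref, alt, context) {
  n <- length(ref)
  assert_that(length(alt) == n && length(context) == n,
              "ref/alt/context length mismatch")
  idx <- integer(n)
  for (i in seq_len(n)) {
    r <- ref[i]; a <- alt[i]; ctx <- context[i]
    assert_that(nchar(ctx) == 3L, "context '%s' is not a 3-mer", ctx)
    assert_that(substr(ctx, 2L, 2L) == r,
                "context '%s' center does not match ref '%s'", ctx, r)
    assert_that(r %in% DNA_BASES && a %in% DNA_BASES && r != a,
                "invalid SNV ref/alt pair '%s>%s'", r, a)
    if (r %in% c("A", "G")) { # purine reference: flip strand
      ctx <- revcomp(ctx)
      r <- unname(DNA_COMPLEMENT[r])
      a <- unname(DNA_COMPLEMENT[a])
    }
    sub <- match(paste0(r, ">", a), SUBSTITUTION_CLASSES)
    p5 <- match(substr(ctx, 1L, 1L), DNA_BASES)
    p3 <- match(substr(ctx, 3L, 3L), DNA_BASES)
    idx[i] <- (sub - 1L) * 16L + (p5 - 1L) * 4L + p3
  }
  idx
}

## 6-class index of an SNV (1..6 in SUBSTITUTION_CLASSES order).
substitution_index <- function(ref, alt) {
  n <- length(ref)
  idx <- integer(n)
  for (i in seq_len(n)) {
    r <- ref[i]; a <- alt[i]
    assert_that(r %in% DNA_BASES && a %in% DNA_BASES && r != a,
                "invalid SNV ref/alt pair '%s>%s'", r, a)
    if (r %in% c("A", "G")) {
      r <- unname(DNA_COMPLEMENT[r]); a <- unname(DNA_COMPLEMENT[a])
    }
    idx[i] <- match(paste0(r, ">", a), SUBSTITUTION_CLASSES)
  }
  idx
}
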