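# Internal sequence helpers. Windows and guides are short fixed-width strings,
# so plain chartr/substring arithmetic is used throughout.

DNA_BASES <- c("A", "C", "G", "T")
RNA_BASES <- c("A", "C", "G", "U")

chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

collapse <- function(x) paste0(x, collapse = "")

comp_dna <- function(x) chartr("ACGT", "TGCA", x)

revcomp_dna <- function(x) collapse(rev(chars(comp_dna(x))))

# RNA base that Watson-Crick pairs a given DNA base (guides are written as the
# RNA complement of the strand they physically pair).
rna_pairing_base <- function(x) chartr("ACGT", "UGCA", x)

# RNA transliteration of a DNA string (T -> U); same base identity, RNA alphabet.
dna_to_rna <- function(x) chartr("T", "U", x)

# circular substring: `len` characters starting at `from` (1-based), wrapping.
circ_substr <- function(s, from, len) {
  n <- nchar(s)
  idx <- ((from - 1L + seq_len(len) - 1L) %% n) + 1L
  collapse(chars(s)[idx])
}

assert_scalar_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(what, " must be a single character string", call. = FALSE)
  invisible(x)
}

assert_dna <- function(x, what = "sequence") {
  assert_scalar_string(x, what)
  bad <- setdiff(unique(chars(x)), DNA_BASES)
  if (length(bad))
    stop(what, " contains characters outside {A,C,G,T}: ",
         paste(bad, collapse = ", "),
         " (ambiguity codes are not expanded)", call. = FALSE)
  invisible(x)
}

assert_rna <- function(x, what = "sequence") {
  assert_scalar_string(x, what)
  bad <- setdiff(unique(chars(x)), RNA_BASES)
  if (length(bad))
    stop(what, " contains characters outside {A,C,G,U}: ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
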