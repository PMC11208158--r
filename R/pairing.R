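#' Classify an RNA-DNA base pair
#'
#' Watson-Crick pairs (RNA:DNA) are A:T, U:A, G:C and C:G. The wobble class
#' holds G:T (observed between guide and DNA in the wild-type system, e.g.
#' G53 against tT11*) and U:G, included for policy symmetry although only G:T
#' is structurally evidenced. Everything else is a mismatch. Under the
#' `strict` policy only Watson-Crick pairs count as paired; under
#' `permissive`, wobble pairs count too.
#'
#' @param rna_base Single RNA base (A/C/G/U).
#' @param dna_base Single DNA base (A/C/G/T).
#' @param policy `"permissive"` (default) or `"strict"`.
#' @return List with `class` (`"watson-crick"`, `"wobble"` or `"mismatch"`)
#'   and `paired` (logical).
#' @examples
#' classify_pair("G", "T")$class            # wobble
#' classify_pair("G", "T", "strict")$paired # FALSE
#' @export
classify_pair <- function(rna_base, dna_base,
                          policy = c("permissive", "strict")) {
  policy <- match.arg(policy)
  cls <- pair_class(rna_base, dna_base)
  list(class = cls,
       paired = cls == "watson-crick" ||
         (policy == "permissive" && cls == "wobble"))
}

WC_PAIRS <- c(A = "T", U = "A", G = "C", C = "G")      # RNA base -> DNA base
WOBBLE_PAIRS <- c(G = "T", U = "G")

pair_class <- function(rna_base, dna_base) {
  if (!rna_base %in% RNA_BASES) stop("invalid RNA base: ", rna_base,
                                     call. = FALSE)
  if (!dna_base %in% DNA_BASES) stop("invalid DNA base: ", dna_base,
                                     call. = FALSE)
  if (identical(WC_PAIRS[[rna_base]], dna_base)) return("watson-crick")
  if (rna_base %in% names(WOBBLE_PAIRS) &&
      identical(WOBBLE_PAIRS[[rna_base]], dna_base)) return("wobble")
  "mismatch"
}

# vectorised internal variant over equal-length character vectors
pair_class_vec <- function(rna, dna) {
  mapply(pair_class, rna, dna, USE.NAMES = FALSE)
}

is_paired <- function(cls, policy) {
  cls == "watson-crick" | (policy == "permissive" & cls == "wobble")
}

#' Evaluate a guide segment against a DNA segment
#'
#' Scores a guide (RNA) against a DNA segment position by position. With
#' `antiparallel = TRUE` (the physical register) the guide read 5'->3' is
#' scored against the DNA read 3'->5', i.e. guide position k pairs DNA
#' position `n + 1 - k`. Results are reported in guide coordinates.
#'
#' @param guide RNA string.
#' @param dna DNA string of equal length.
#' @param antiparallel Score against the reversed DNA (default `TRUE`).
#' @param policy Pairing policy for the overall verdict.
#' @return A `PairingReport`: `table` (data.frame with `guide_pos`,
#'   `rna`, `dna`, `class`, `paired`), `counts` (named integer vector over
#'   the three classes), `all_paired` (logical verdict), `policy`.
#' @examples
#' evaluate_segment("UCU", "AGA")$all_paired  # TRUE: U:A, C:G, U:A
#' @export
evaluate_segment <- function(guide, dna, antiparallel = TRUE,
                             policy = c("permissive", "strict")) {
  policy <- match.arg(policy)
  guide <- toupper(guide); dna <- toupper(dna)
  assert_rna(guide, "guide")
  assert_dna(dna, "dna")
  if (nchar(guide) != nchar(dna))
    stop("guide and DNA segments must have equal length", call. = FALSE)
  g <- chars(guide)
  d <- chars(dna)
  if (antiparallel) d <- rev(d)
  cls <- pair_class_vec(g, d)
  paired <- is_paired(cls, policy)
  tab <- data.frame(guide_pos = seq_along(g), rna = g, dna = d,
                    class = cls, paired = paired, stringsAsFactors = FALSE)
  counts <- stats::setNames(
    as.integer(table(factor(cls, levels = c("watson-crick", "wobble",
                                            "mismatch")))),
    c("watson-crick", "wobble", "mismatch"))
  structure(list(table = tab, counts = counts,
                 all_paired = all(paired), policy = policy),
            class = "PairingReport")
}

#' Full RNA x DNA pairing table
#'
#' The 4 x 4 classification of every RNA/DNA base combination, suitable for
#' TSV export as documentation.
#'
#' @param path Optional file path; when given, the table is written as TSV.
#' @return `data.frame` with columns `rna`, `dna`, `class` (invisibly when
#'   written to file).
#' @export
pairing_table <- function(path = NULL) {
  grid <- expand.grid(rna = RNA_BASES, dna = DNA_BASES,
                      stringsAsFactors = FALSE)
  grid$class <- pair_class_vec(grid$rna, grid$dna)
  if (!is.null(path)) {
    utils::write.table(grid, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(grid))
  }
  grid
}
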