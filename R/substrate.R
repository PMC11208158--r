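#' Construct a 14-position duplex recognition window
#'
#' The recognition window spans 14 duplex positions. The top strand is given
#' 5'->3' (positions 1..14); the bottom strand is stored 5'->3' with its own
#' starred numbering 1*..14*, and top position `i` lies across bottom position
#' `15 - i`. When `bottom` is omitted it defaults to the reverse complement of
#' `top` (a "WT-complementary" window). Windows may deliberately violate
#' complementarity (mismatch constructs); per-position duplex mismatch flags
#' are computed under the `15 - i` convention and stored in `$mismatch`
#' (indexed by top position).
#'
#' The core dinucleotide occupies top positions 8-9 (its complement sits at
#' bottom 6*-7*).
#'
#' @param top Top strand, 14 characters over A/C/G/T.
#' @param bottom Optional bottom strand (5'->3', 14 characters).
#' @param role `"target"`, `"donor"` or `"junction"`.
#' @return A `DnaWindow` object.
#' @examples
#' w <- make_window("ACGTACGCTGACTA")
#' w$bottom                 # "TAGTCAGCGTACGT"
#' validate_core(w)$verdict # "pass"
#' @export
make_window <- function(top, bottom = NULL,
                        role = c("target", "donor", "junction")) {
  role <- match.arg(role)
  top <- toupper(top)
  assert_dna(top, "top strand")
  if (nchar(top) != 14L)
    stop("top strand must have exactly 14 positions, got ", nchar(top),
         call. = FALSE)
  if (is.null(bottom)) bottom <- revcomp_dna(top)
  bottom <- toupper(bottom)
  assert_dna(bottom, "bottom strand")
  if (nchar(bottom) != 14L)
    stop("bottom strand must have exactly 14 positions, got ", nchar(bottom),
         call. = FALSE)
  tc <- chars(top); bc <- chars(bottom)
  mismatch <- bc[15L - seq_len(14L)] != comp_dna(tc)
  structure(list(top = top, bottom = bottom, role = role,
                 mismatch = mismatch),
            class = "DnaWindow")
}

#' @export
print.DnaWindow <- function(x, ...) {
  cat("DnaWindow (", x$role, ")\n", sep = "")
  cat("  top    5'-", x$top, "-3'  (1..14, core at 8-9: ",
      substr(x$top, 8, 9), ")\n", sep = "")
  cat("  bottom 3'-", collapse(rev(chars(x$bottom))),
      "-5'  (14*..1*)\n", sep = "")
  if (any(x$mismatch))
    cat("  duplex mismatches at top positions: ",
        paste(which(x$mismatch), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# base of a window strand at a window position (bottom positions are starred,
# i.e. given in bottom-strand numbering)
window_base <- function(w, strand, pos) {
  s <- if (strand == "top") w$top else w$bottom
  substring(s, pos, pos)
}

#' Validate the core dinucleotide of a window
#'
#' Recombination requires a T at top position 9 (recognised by the enzyme
#' main chain and nearly invariant); position 8 is preferentially C, with G
#' also well tolerated and A/T supported but weaker. Verdicts: `"pass"` for
#' CT, `"pass-with-warning"` for GT/AT/TT, `"fail"` whenever position 9 is
#' not T. The report is role-independent.
#'
#' @param w A `DnaWindow`.
#' @return A `CoreReport` list: `core`, `position9_ok`, `position8_class`,
#'   `verdict`, `rank` (ordinal preference: CT=1, GT=2, AT/TT=3).
#' @export
validate_core <- function(w) {
  stopifnot(inherits(w, "DnaWindow"))
  p8 <- substr(w$top, 8, 8)
  p9 <- substr(w$top, 9, 9)
  ok9 <- identical(p9, "T")
  verdict <- if (!ok9) "fail" else if (p8 == "C") "pass" else "pass-with-warning"
  rank <- if (!ok9) NA_integer_ else switch(p8, C = 1L, G = 2L, 3L)
  structure(list(core = paste0(p8, p9), position9_ok = ok9,
                 position8_class = p8, verdict = verdict, rank = rank),
            class = "CoreReport")
}

#' Construct a substrate molecule
#'
#' A full-length DNA duplex (represented by its top strand) carrying one
#' recognition window. Circular topology allows the window to wrap the
#' origin. `window_strand = "-"` declares that the recognition window reads
#' on the reverse strand (used for inverted-orientation recombination).
#'
#' @param sequence Top-strand sequence (A/C/G/T).
#' @param topology `"linear"` or `"circular"`.
#' @param window_start 1-based offset of window position 1 within `sequence`.
#' @param role `"target"` or `"donor"`.
#' @param window_strand `"+"` or `"-"`.
#' @return A `SubstrateMolecule` object.
#' @export
substrate_molecule <- function(sequence, topology = c("linear", "circular"),
                               window_start = 1L,
                               role = c("target", "donor"),
                               window_strand = c("+", "-")) {
  topology <- match.arg(topology)
  role <- match.arg(role)
  window_strand <- match.arg(window_strand)
  sequence <- toupper(sequence)
  assert_dna(sequence, "sequence")
  L <- nchar(sequence)
  window_start <- as.integer(window_start)
  if (window_start < 1L || window_start > L)
    stop("window_start must lie in 1..", L, call. = FALSE)
  structure(list(sequence = sequence, topology = topology,
                 window_start = window_start, role = role,
                 window_strand = window_strand, length = L),
            class = "SubstrateMolecule")
}

#' Extract the recognition window of a substrate molecule
#'
#' @param m A `SubstrateMolecule`.
#' @return A `DnaWindow` (WT-complementary by construction).
#' @export
window_of <- function(m) {
  stopifnot(inherits(m, "SubstrateMolecule"))
  if (m$topology == "linear" && m$window_start + 13L > m$length)
    stop("window does not fit within the linear sequence", call. = FALSE)
  top <- if (m$topology == "circular")
    circ_substr(m$sequence, m$window_start, 14L)
  else substr(m$sequence, m$window_start, m$window_start + 13L)
  if (m$window_strand == "-") top <- revcomp_dna(top)
  make_window(top, role = m$role)
}

#' Scan a molecule for candidate core dinucleotides
#'
#' Enumerates every window placement (both strands; wraparound on circular
#' molecules) whose top position 9 is T, and ranks hits by core preference:
#' CT first, then GT, then AT/TT, ties broken by ascending offset. A hit on
#' the reverse strand is reported with strand `"-"` and `window_start` in the
#' coordinates of the reverse-complement sequence (its own window).
#'
#' @param m A `SubstrateMolecule`.
#' @return `data.frame` with columns `window_start`, `strand`, `core`,
#'   `verdict`, ordered by rank then offset. Empty (with a warning) for a
#'   linear sequence shorter than 14.
#' @export
scan_cores <- function(m) {
  stopifnot(inherits(m, "SubstrateMolecule"))
  empty <- data.frame(window_start = integer(0), strand = character(0),
                      core = character(0), verdict = character(0),
                      stringsAsFactors = FALSE)
  if (m$topology == "linear" && m$length < 14L) {
    warning("sequence shorter than a 14-bp window; no placements scanned",
            call. = FALSE)
    return(empty)
  }
  scan_one <- function(s, strand) {
    L <- nchar(s)
    offs <- if (m$topology == "circular") seq_len(L) else seq_len(L - 13L)
    sc <- chars(s)
    p9 <- sc[((offs + 7L) %% L) + 1L]   # window position 9 = offset + 8
    offs <- offs[p9 == "T"]
    if (!length(offs)) return(empty)
    p8 <- sc[((offs + 6L) %% L) + 1L]
    core <- paste0(p8, "T")
    rank <- ifelse(p8 == "C", 1L, ifelse(p8 == "G", 2L, 3L))
    verdict <- ifelse(p8 == "C", "pass", "pass-with-warning")
    data.frame(window_start = offs, strand = strand, core = core,
               verdict = verdict, rank = rank, stringsAsFactors = FALSE)
  }
  fw <- scan_one(m$sequence, "+")
  rv <- scan_one(revcomp_dna(m$sequence), "-")
  hits <- rbind(fw, rv)
  if (!nrow(hits)) return(empty)
  hits <- hits[order(hits$rank, hits$window_start, hits$strand), ]
  rownames(hits) <- NULL
  hits[c("window_start", "strand", "core", "verdict")]
}

#' Introduce the structural mismatch-trapping substitutions
#'
#' Reproduces the construct used to stabilise synaptic complexes for
#' structural analysis: top-strand positions 2-7 are each replaced by the
#' complement of the original top base, guaranteeing a duplex mismatch at all
#' six positions while leaving the bottom strand and the core (8-9)
#' untouched.
#'
#' @param w A WT-complementary `DnaWindow` (no pre-existing mismatches at
#'   positions 2-7; re-trapping is an error).
#' @return A new `DnaWindow` with six mismatch flags set at positions 2-7.
#' @export
trap_mismatches <- function(w) {
  stopifnot(inherits(w, "DnaWindow"))
  if (any(w$mismatch[2:7]))
    stop("window already carries mismatches at positions 2-7 ",
         "(double-trapping is not supported)", call. = FALSE)
  tc <- chars(w$top)
  tc[2:7] <- comp_dna(tc[2:7])
  make_window(collapse(tc), w$bottom, role = w$role)
}
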