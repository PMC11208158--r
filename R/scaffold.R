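#' Reference region map of the IS621 bridge RNA scaffold
#'
#' Coordinates (1-based, closed) of the annotated regions of the 177-nt IS621
#' bridge RNA: the 5' stem loop, the target-binding loop (TBL) with its left
#' and right target guides (LTG, RTG), the right-target-guide extension slots,
#' the TBL handshake guide, the donor-binding loop (DBL) with left and right
#' donor guides (LDG, RDG), the flipped-out spacers, the DBL handshake guide,
#' the linker regions and the DBL stem loop (DBL-SL). Each entry is an integer
#' vector of scaffold positions; `RDG` is non-contiguous because positions
#' 159-160 are flipped-out spacers rather than pairing positions.
#'
#' The 5' stem loop boundary (1..31) is inferred from the length difference
#' between the full scaffold (177 nt) and the stem-loop deletion mutant
#' (146 nt); all other coordinates are the published ones.
#'
#' @return Named list of integer position vectors.
#' @export
default_region_map <- function() {
  list(
    five_prime_stem_loop = 1:31,
    TBL         = 34:98,
    DBL         = 110:177,
    LTG         = 50:58,
    RTG         = 77:80,
    RTG_ext     = 74:76,
    HSG_T       = 81:82,
    LDG         = 123:130,
    RDG         = c(157L, 158L, 161L, 162:165),
    spacers     = c(159L, 160L),
    HSG_D       = 166:167,
    TBL_linkers = c(47:49, 59L, 72:73, 83:86),
    DBL_linkers = c(121:122, 131:132, 155:156, 168L),
    DBL_SL      = 137:147
  )
}

#' Conserved scaffold nucleotides
#'
#' The flipped-out A nucleotides (positions 43 and 67 in the TBL, 116 and 150
#' in the DBL) and the syn-conformation G nucleotides (48 and 72 in the TBL,
#' 121 and 155 in the DBL) are highly conserved across IS110-family elements
#' and are recognised by the recombinase; design operations refuse to rewrite
#' them.
#'
#' @return Named character vector mapping position (as name) to required base.
#' @export
conserved_nucleotides <- function() {
  c(`43` = "A", `67` = "A", `116` = "A", `150` = "A",
    `48` = "G", `72` = "G", `121` = "G", `155` = "G")
}

programmable_regions <- c("LTG", "RTG", "RTG_ext", "HSG_T",
                          "LDG", "RDG", "HSG_D")

#' Load and annotate a bridge RNA scaffold
#'
#' Builds an annotated `BridgeRNA` from a scaffold sequence and a region map.
#' `T` characters are silently converted to `U` (a message records the
#' conversion). The sequence length must equal the last coordinate of the
#' region map. Deviations from the conserved nucleotides are reported as
#' warnings, one per position, because user scaffolds may be orthologues;
#' writing those positions later (see [apply_variant()]) is an error.
#'
#' @param sequence Scaffold sequence, a single string over A/C/G/U (T allowed,
#'   converted to U).
#' @param region_map Named list of integer position vectors; defaults to the
#'   IS621 reference map ([default_region_map()]).
#' @param conserved Named character vector of conserved positions
#'   ([conserved_nucleotides()]).
#' @return A `BridgeRNA` object: list with elements `sequence`, `length`,
#'   `regions`, `programmable_mask`, `conserved`, `conservation_violations`.
#' @examples
#' b <- load_scaffold(random_scaffold(seed = 1))
#' b$length
#' @export
load_scaffold <- function(sequence,
                          region_map = default_region_map(),
                          conserved = conserved_nucleotides()) {
  assert_scalar_string(sequence, "scaffold sequence")
  sequence <- toupper(sequence)
  if (grepl("T", sequence, fixed = TRUE)) {
    message("load_scaffold: converted T -> U in input scaffold")
    sequence <- chartr("T", "U", sequence)
  }
  assert_rna(sequence, "scaffold sequence")
  L <- max(unlist(region_map))
  if (nchar(sequence) != L)
    stop("scaffold length (", nchar(sequence),
         ") does not match the region map's last coordinate (", L, ")",
         call. = FALSE)
  bad <- unlist(lapply(region_map, function(p) p[p < 1L | p > L]))
  if (length(bad))
    stop("region map contains positions outside 1..", L, call. = FALSE)

  pos <- as.integer(names(conserved))
  have <- substring(sequence, pos, pos)
  viol <- pos[have != conserved]
  for (p in viol)
    warning("scaffold position ", p, " is ",
            substring(sequence, p, p), ", expected conserved ",
            conserved[[as.character(p)]], call. = FALSE)

  mask <- sort(unique(unlist(region_map[intersect(programmable_regions,
                                                  names(region_map))])))
  structure(list(
    sequence = sequence,
    length = L,
    regions = lapply(region_map, as.integer),
    programmable_mask = as.integer(mask),
    conserved = conserved,
    conservation_violations = as.integer(viol)
  ), class = "BridgeRNA")
}

#' @export
print.BridgeRNA <- function(x, ...) {
  cat("BridgeRNA scaffold, ", x$length, " nt\n", sep = "")
  cat("  regions: ", paste(names(x$regions), collapse = ", "), "\n", sep = "")
  cat("  programmable positions: ", length(x$programmable_mask), "\n", sep = "")
  if (length(x$conservation_violations))
    cat("  conserved-position deviations at: ",
        paste(x$conservation_violations, collapse = ", "), "\n", sep = "")
  invisible(x)
}

scaffold_base <- function(b, pos) substring(b$sequence, pos, pos)

#' Describe an engineered scaffold variant
#'
#' Three variant kinds are supported: deletion of the 5' stem loop (positions
#' 1..31, yielding the 146-nt scaffold), replacement of DBL-SL nucleotides
#' 137-147 with a GAAA tetraloop (170 nt), and arbitrary point substitutions.
#'
#' @param kind One of `"delete-5p-stem-loop"`, `"dblsl-gaaa-tetraloop"`,
#'   `"point-substitutions"`.
#' @param substitutions For point substitutions, a named character vector
#'   (names = positions, values = new RNA bases).
#' @return A `ScaffoldVariant` object.
#' @export
scaffold_variant <- function(kind = c("delete-5p-stem-loop",
                                      "dblsl-gaaa-tetraloop",
                                      "point-substitutions"),
                             substitutions = NULL) {
  kind <- match.arg(kind)
  if (kind == "point-substitutions") {
    if (is.null(substitutions) || is.null(names(substitutions)))
      stop("point-substitutions require a named vector of (position = base)",
           call. = FALSE)
    bases <- toupper(unname(substitutions))
    if (!all(bases %in% RNA_BASES))
      stop("substitution bases must be RNA bases (A/C/G/U)", call. = FALSE)
    substitutions <- stats::setNames(bases, names(substitutions))
  }
  structure(list(kind = kind, substitutions = substitutions),
            class = "ScaffoldVariant")
}

# Re-index region/conserved positions after removing `removed` (a contiguous
# 1-based block) and inserting `inserted_len` new positions in its place.
# Regions that intersected the removed block acquire the inserted block.
remap_positions <- function(pos, removed, inserted_len) {
  r0 <- min(removed); r1 <- max(removed)
  shift <- length(removed) - inserted_len
  kept <- pos[pos < r0 | pos > r1]
  out <- ifelse(kept > r1, kept - shift, kept)
  if (inserted_len > 0L && any(pos >= r0 & pos <= r1))
    out <- c(out, seq.int(r0, length.out = inserted_len))
  sort(unique(as.integer(out)))
}

#' Apply an engineered variant to a scaffold
#'
#' Deletions and replacements shift all downstream region and conserved-base
#' coordinates consistently; point substitutions at conserved positions are
#' refused with an error naming the position. Bases outside the variant
#' footprint are never changed.
#'
#' @param b A `BridgeRNA`.
#' @param v A `ScaffoldVariant`.
#' @return A new, re-annotated `BridgeRNA`.
#' @examples
#' b <- load_scaffold(random_scaffold(seed = 1))
#' apply_variant(b, scaffold_variant("delete-5p-stem-loop"))$length  # 146
#' @export
apply_variant <- function(b, v) {
  stopifnot(inherits(b, "BridgeRNA"), inherits(v, "ScaffoldVariant"))
  s <- chars(b$sequence)

  if (v$kind == "point-substitutions") {
    pos <- as.integer(names(v$substitutions))
    if (any(pos < 1L | pos > b$length))
      stop("substitution position outside scaffold (1..", b$length, ")",
           call. = FALSE)
    hit <- intersect(pos, as.integer(names(b$conserved)))
    if (length(hit))
      stop("substitution at conserved position ",
           paste(sort(hit), collapse = ", "), " is not allowed",
           call. = FALSE)
    s[pos] <- unname(v$substitutions)
    out <- b
    out$sequence <- collapse(s)
    return(out)
  }

  if (v$kind == "delete-5p-stem-loop") {
    removed <- b$regions[["five_prime_stem_loop"]]
    if (is.null(removed))
      stop("scaffold has no annotated five_prime_stem_loop region",
           call. = FALSE)
    insert <- character(0)
  } else { # dblsl-gaaa-tetraloop
    removed <- 137:147
    if (is.null(b$regions[["DBL_SL"]]) ||
        !all(removed %in% b$regions[["DBL_SL"]]))
      stop("scaffold DBL_SL annotation does not cover positions 137-147",
           call. = FALSE)
    insert <- chars("GAAA")
  }

  r0 <- min(removed); r1 <- max(removed)
  new_seq <- c(s[seq_len(r0 - 1L)], insert,
               if (r1 < b$length) s[(r1 + 1L):b$length] else character(0))
  regions <- lapply(b$regions, remap_positions,
                    removed = removed, inserted_len = length(insert))
  regions <- regions[vapply(regions, length, 1L) > 0L]
  cpos <- as.integer(names(b$conserved))
  keep <- !(cpos %in% removed)
  newc <- cpos[keep]
  shift <- length(removed) - length(insert)
  newc <- ifelse(newc > r1, newc - shift, newc)
  conserved <- stats::setNames(unname(b$conserved[keep]), newc)

  mask <- sort(unique(unlist(regions[intersect(programmable_regions,
                                               names(regions))])))
  structure(list(
    sequence = collapse(new_seq),
    length = length(new_seq),
    regions = regions,
    programmable_mask = as.integer(mask),
    conserved = conserved,
    conservation_violations = integer(0)
  ), class = "BridgeRNA")
}

#' Region annotation string
#'
#' One character per scaffold position labelling the region it belongs to
#' (documentation aid in the spirit of a dot-bracket string; not a
#' thermodynamic structure). Nested regions overwrite their parent, so e.g.
#' the handshake guides show as `h`/`H` inside the TBL/DBL.
#'
#' @param b A `BridgeRNA`.
#' @return A single string of length `b$length`.
#' @export
region_annotation <- function(b) {
  codes <- c(five_prime_stem_loop = "5", TBL = "t", DBL = "d",
             TBL_linkers = "-", DBL_linkers = "-", DBL_SL = "s",
             LTG = "L", RTG = "R", RTG_ext = "r", HSG_T = "h",
             LDG = "l", RDG = "G", spacers = "x", HSG_D = "H")
  ann <- rep(".", b$length)
  for (nm in names(codes)) {
    p <- b$regions[[nm]]
    if (!is.null(p)) ann[p] <- codes[[nm]]
  }
  collapse(ann)
}

# ---- region map serialization (positions as closed intervals) --------------

positions_to_intervals <- function(p) {
  p <- sort(unique(as.integer(p)))
  br <- c(0L, which(diff(p) != 1L), length(p))
  lapply(seq_len(length(br) - 1L), function(i) {
    seg <- p[(br[i] + 1L):br[i + 1L]]
    c(min(seg), max(seg))
  })
}

#' Write / read a region map
#'
#' The map is serialized as JSON with each region as a list of closed
#' `[start, end]` intervals (1-based). Writing is canonical, so a map
#' round-trips byte-identically through `write_region_map()` /
#' `read_region_map()`.
#'
#' @param regions Named list of integer position vectors.
#' @param path File path.
#' @return `read_region_map()` returns the named list of position vectors.
#' @export
write_region_map <- function(regions, path) {
  iv <- lapply(regions, positions_to_intervals)
  json <- jsonlite::toJSON(iv, auto_unbox = FALSE, pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_region_map
#' @export
read_region_map <- function(path) {
  iv <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(iv, function(region)
    sort(unique(unlist(lapply(region, function(ab)
      seq.int(ab[[1]], ab[[2]]))))))
}

#' Read a scaffold from FASTA
#'
#' @param path FASTA file with a single RNA (or DNA, T converted to U) record.
#' @inheritParams load_scaffold
#' @return A `BridgeRNA`.
#' @export
read_scaffold_fasta <- function(path, region_map = default_region_map()) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) != 1L)
    stop("expected exactly one scaffold record in ", path, call. = FALSE)
  load_scaffold(as.character(set[[1]]), region_map = region_map)
}
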