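#' Options controlling bridge RNA design
#'
#' @param rtg_extension Also program the RTG extension slots (scaffold
#'   positions 74-76) against target top 14..12; extending the RTG-right
#'   target complementarity stabilises the synaptic complex.
#' @param hsg_mode How the handshake guides (HSGs) are programmed.
#'   `"post-HSB"` (default, the productive configuration) pairs each HSG with
#'   the *non-cognate* top strand so the new pairs only form after strand
#'   exchange; `"pre-HSB"` pairs the cognate strand, which traps the complex
#'   in the locked state and is experimentally non-productive (a prominent
#'   warning is emitted); `"keep-scaffold"` leaves HSG bases untouched, for
#'   orthologue scaffolds.
#' @param policy Pairing policy used when validating designs.
#' @return A `DesignOptions` list.
#' @export
design_options <- function(rtg_extension = FALSE,
                           hsg_mode = c("post-HSB", "pre-HSB",
                                        "keep-scaffold"),
                           policy = c("permissive", "strict")) {
  structure(list(rtg_extension = isTRUE(rtg_extension),
                 hsg_mode = match.arg(hsg_mode),
                 policy = match.arg(policy)),
            class = "DesignOptions")
}

# The guide <-> DNA registers. Each row: one programmable scaffold position,
# the window/strand/position it physically pairs (antiparallel register).
# Bottom positions are in starred (bottom-strand) numbering.
design_registers <- function(hsg_mode = "post-HSB", rtg_extension = FALSE) {
  reg <- function(region, rna_pos, molecule, strand, dna_pos)
    data.frame(region = region, rna_pos = rna_pos, molecule = molecule,
               strand = strand, dna_pos = dna_pos, stringsAsFactors = FALSE)
  rows <- list(
    reg("LTG", 50:58, "target", "bottom", 14:6),
    reg("RTG", 77:80, "target", "top", 11:8),
    if (rtg_extension) reg("RTG_ext", 74:76, "target", "top", 14:12),
    reg("LDG", 123:130, "donor", "bottom", 14:7),
    reg("RDG", c(157L, 158L, 161L, 162:165), "donor", "top",
        c(14L, 13L, 12L, 11:8))
  )
  if (hsg_mode != "keep-scaffold") {
    hsg_t_mol <- if (hsg_mode == "post-HSB") "donor" else "target"
    hsg_d_mol <- if (hsg_mode == "post-HSB") "target" else "donor"
    rows <- c(rows, list(
      reg("HSG_T", 81:82, hsg_t_mol, "top", 7:6),
      reg("HSG_D", 166:167, hsg_d_mol, "top", 7:6)
    ))
  }
  do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
}

# Cognate handshake-pairing check shared by the design engine and the
# simulator: each HSG position against its own molecule's top strand at
# window positions 7 and 6, continuing the antiparallel register of the
# adjacent guide. Locked as soon as any position pairs under `policy`.
hsg_cognate_pairs <- function(brna_seq, target, donor,
                              policy = "permissive") {
  tab <- data.frame(
    hsg = c("HSG_T", "HSG_T", "HSG_D", "HSG_D"),
    rna_pos = c(81L, 82L, 166L, 167L),
    molecule = c("target", "target", "donor", "donor"),
    dna_pos = c(7L, 6L, 7L, 6L),
    stringsAsFactors = FALSE)
  win <- list(target = target, donor = donor)
  tab$rna <- substring(brna_seq, tab$rna_pos, tab$rna_pos)
  tab$dna <- mapply(function(m, p) window_base(win[[m]], "top", p),
                    tab$molecule, tab$dna_pos, USE.NAMES = FALSE)
  tab$class <- pair_class_vec(tab$rna, tab$dna)
  tab$paired <- is_paired(tab$class, policy)
  tab
}

#' Predict the handshake lock state
#'
#' A bridge RNA whose handshake guides base pair with their *cognate* top
#' strand (HSG-T with target top 7-6, HSG-D with donor top 7-6) traps the
#' synaptic complex in the pre-strand-exchange locked state; any cognate
#' pairing at an HSG position (permissive policy by default) predicts lock.
#'
#' @param b A `BridgeRNA` (or a plain scaffold sequence string).
#' @param target,donor Target and donor `DnaWindow`s.
#' @param policy Pairing policy used for the cognate check.
#' @return List with `locked` (logical) and `pairs` (the per-position cognate
#'   pairing table).
#' @export
predict_lock <- function(b, target, donor, policy = "permissive") {
  seq <- if (inherits(b, "BridgeRNA")) b$sequence else b
  tab <- hsg_cognate_pairs(seq, target, donor, policy)
  list(locked = any(tab$paired), pairs = tab)
}

#' Design a bridge RNA against a target and a donor window
#'
#' Rewrites the programmable guide positions of the scaffold so that each
#' guide segment is the Watson-Crick RNA complement of the strand it
#' physically pairs, in the antiparallel register: LTG (50-58) against target
#' bottom 14*..6*, RTG (77-80) against target top 11..8, the optional RTG
#' extension (74-76) against target top 14..12, LDG (123-130) against donor
#' bottom 14*..7*, RDG (157-158, 161, 162-165) against donor top 14, 13, 12,
#' 11..8, and the handshake guides per `opts$hsg_mode` (post-HSB: HSG-T
#' 81-82 against donor top 7,6 and HSG-D 166-167 against target top 7,6;
#' pre-HSB: each against its cognate window). Positions 159-160 (flipped-out
#' spacers) and every non-programmable position are left byte-identical.
#'
#' Both windows must pass [validate_core()] (verdict not `"fail"`); differing
#' target/donor cores trigger a warning about a junction heteroduplex at
#' positions 8-9.
#'
#' @param scaffold A `BridgeRNA` annotated with the default region map.
#' @param target,donor `DnaWindow`s.
#' @param opts A `DesignOptions` object.
#' @return List with `brna` (the designed `BridgeRNA`) and `report` (a
#'   `DesignReport`: pairing diagram, core reports, core-identity check, lock
#'   prediction, rewritten positions).
#' @examples
#' sc <- load_scaffold(random_scaffold(seed = 1))
#' tw <- make_window("ACGTACGCTGACTA", role = "target")
#' dw <- make_window("TTCAGATCTTGATT", role = "donor")
#' d <- design_bridge_rna(sc, tw, dw, design_options(rtg_extension = TRUE))
#' substr(d$brna$sequence, 50, 58)  # LTG: "ACGUACGCU"
#' @export
design_bridge_rna <- function(scaffold, target, donor,
                              opts = design_options()) {
  stopifnot(inherits(scaffold, "BridgeRNA"),
            inherits(target, "DnaWindow"), inherits(donor, "DnaWindow"),
            inherits(opts, "DesignOptions"))
  needed <- c("LTG", "RTG", "RTG_ext", "HSG_T", "LDG", "RDG", "HSG_D")
  if (!all(needed %in% names(scaffold$regions)))
    stop("scaffold lacks the default guide-region annotation (",
         paste(setdiff(needed, names(scaffold$regions)), collapse = ", "),
         ")", call. = FALSE)
  tcore <- validate_core(target)
  dcore <- validate_core(donor)
  if (tcore$verdict == "fail")
    stop("target core '", tcore$core, "' fails validation ",
         "(position 9 must be T)", call. = FALSE)
  if (dcore$verdict == "fail")
    stop("donor core '", dcore$core, "' fails validation ",
         "(position 9 must be T)", call. = FALSE)
  same_core <- identical(tcore$core, dcore$core)
  if (!same_core)
    warning("target core (", tcore$core, ") and donor core (", dcore$core,
            ") differ: recombination junctions will carry a heteroduplex ",
            "at window positions 8-9", call. = FALSE)
  if (opts$hsg_mode == "pre-HSB")
    warning("pre-HSB handshake programming traps the synaptic complex in ",
            "the locked state and is experimentally non-productive",
            call. = FALSE)

  reg <- design_registers(opts$hsg_mode, opts$rtg_extension)
  win <- list(target = target, donor = donor)
  reg$dna <- mapply(function(m, s, p) window_base(win[[m]], s, p),
                    reg$molecule, reg$strand, reg$dna_pos, USE.NAMES = FALSE)
  reg$rna <- rna_pairing_base(reg$dna)

  if (!all(reg$rna_pos %in% scaffold$programmable_mask))
    stop("internal error: design would write outside the programmable mask",
         call. = FALSE)

  s <- chars(scaffold$sequence)
  s[reg$rna_pos] <- reg$rna
  brna <- scaffold
  brna$sequence <- collapse(s)

  reg$class <- pair_class_vec(reg$rna, reg$dna)
  lock <- predict_lock(brna, target, donor, policy = "permissive")
  report <- structure(list(
    diagram = reg,
    core_target = tcore, core_donor = dcore,
    core_identity = same_core,
    hsg_mode = opts$hsg_mode,
    rtg_extension = opts$rtg_extension,
    lock = lock$locked,
    hsg_cognate = lock$pairs,
    rewritten = sort(reg$rna_pos),
    n_mismatch = sum(!is_paired(reg$class, opts$policy))
  ), class = "DesignReport")
  list(brna = brna, report = report)
}

#' Validate a bridge RNA against a target/donor window pair
#'
#' Re-evaluates every guide region of an annotated bridge RNA against the
#' strand and positions it is assigned to pair, reports per-position pair
#' classes and mismatches, and predicts the handshake lock state. Nothing is
#' modified.
#'
#' @param b A `BridgeRNA` annotated with the default region map.
#' @param target,donor `DnaWindow`s.
#' @param hsg_mode The handshake register to validate against (default
#'   `"post-HSB"`, the productive configuration).
#' @param rtg_extension Whether positions 74-76 should be evaluated as RTG
#'   extension guides.
#' @param policy Pairing policy (`"permissive"` accepts wobble pairs, which
#'   the wild-type scaffold uses; designs are emitted WC-only).
#' @return A `DesignReport` (see [design_bridge_rna()]); `n_mismatch` counts
#'   guide positions that do not pair under `policy`, and `lock` carries the
#'   cognate-handshake prediction.
#' @export
validate_design <- function(b, target, donor, hsg_mode = "post-HSB",
                            rtg_extension = FALSE,
                            policy = c("permissive", "strict")) {
  policy <- match.arg(policy)
  stopifnot(inherits(b, "BridgeRNA"),
            inherits(target, "DnaWindow"), inherits(donor, "DnaWindow"))
  reg <- design_registers(hsg_mode, rtg_extension)
  win <- list(target = target, donor = donor)
  reg$dna <- mapply(function(m, s, p) window_base(win[[m]], s, p),
                    reg$molecule, reg$strand, reg$dna_pos, USE.NAMES = FALSE)
  reg$rna <- substring(b$sequence, reg$rna_pos, reg$rna_pos)
  reg$class <- pair_class_vec(reg$rna, reg$dna)
  reg$paired <- is_paired(reg$class, policy)
  lock <- predict_lock(b, target, donor, policy = "permissive")
  structure(list(
    diagram = reg,
    core_target = validate_core(target), core_donor = validate_core(donor),
    core_identity = identical(validate_core(target)$core,
                              validate_core(donor)$core),
    hsg_mode = hsg_mode, rtg_extension = rtg_extension,
    lock = lock$locked,
    hsg_cognate = lock$pairs,
    rewritten = integer(0),
    n_mismatch = sum(!reg$paired)
  ), class = "DesignReport")
}

#' @export
print.DesignReport <- function(x, ...) {
  cat("DesignReport (hsg_mode = ", x$hsg_mode,
      if (x$rtg_extension) ", RTG extension", ")\n", sep = "")
  cat("  cores: target ", x$core_target$core, " (", x$core_target$verdict,
      "), donor ", x$core_donor$core, " (", x$core_donor$verdict, ")",
      if (!x$core_identity) "  [cores differ]", "\n", sep = "")
  cat("  lock prediction: ", if (x$lock) "LOCKED (cognate handshake pairing)"
      else "not locked", "\n", sep = "")
  cat("  guide mismatches: ", x$n_mismatch, "\n", sep = "")
  d <- x$diagram
  for (rgn in unique(d$region)) {
    rows <- d[d$region == rgn, ]
    cat(sprintf("  %-8s %s %3d..%-3d  5'-%s-3'  ~  %s %s %s..%s\n",
                rgn, "bRNA", min(rows$rna_pos), max(rows$rna_pos),
                collapse(rows$rna), rows$molecule[1], rows$strand[1],
                rows$dna_pos[1], rows$dna_pos[nrow(rows)]))
  }
  invisible(x)
}
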