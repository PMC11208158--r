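#' Build one half of the synaptic complex
#'
#' A half complex is a recombinase dimer loaded with one loop of a bridge RNA
#' and its bound DNA window: a TBL half (dimer binding the target-binding
#' loop and target DNA) or a DBL half (donor-binding loop and donor DNA).
#' The two loops of a single synaptic complex are contributed by two
#' different bridge RNA molecules, so each half carries its own `BridgeRNA`.
#'
#' @param brna A `BridgeRNA`.
#' @param window The `DnaWindow` bound by this half.
#' @param loop `"TBL"` or `"DBL"`.
#' @return A `HalfComplex` object.
#' @export
half_complex <- function(brna, window, loop = c("TBL", "DBL")) {
  loop <- match.arg(loop)
  stopifnot(inherits(brna, "BridgeRNA"), inherits(window, "DnaWindow"))
  structure(list(brna = brna, window = window, loop = loop),
            class = "HalfComplex")
}

#' Assemble the tetrameric synaptic complex
#'
#' Synapsis requires the DBL stem loop (DBL-SL) contact with the RuvC domain
#' of the opposite dimer. A TBL + DBL pair (target-donor) assembles the
#' canonical four-protomer complex; two DBL halves (donor-donor) also
#' assemble, since both constituent dimers present a DBL-SL; two TBL halves
#' (target-target) are refused with a `SynapsisError`, mirroring the absence
#' of target-target recombination in vitro.
#'
#' Protomer bookkeeping is symbolic: the dimer of protomers 1-2 binds the
#' TBL/target half, protomers 3-4 the DBL/donor half. Composite active sites
#' span the dimers: RuvC.1+Tnp.4 and RuvC.3+Tnp.2 cut the target and donor
#' top strands; RuvC.2+Tnp.3 and RuvC.4+Tnp.1 cut the target and donor
#' bottom strands.
#'
#' @param half_a,half_b `HalfComplex` objects (order irrelevant).
#' @return A `SynapticState` at stage `"synapsed"`.
#' @export
form_synapse <- function(half_a, half_b) {
  stopifnot(inherits(half_a, "HalfComplex"), inherits(half_b, "HalfComplex"))
  loops <- c(half_a$loop, half_b$loop)
  if (all(loops == "TBL"))
    stop(errorCondition(
      paste("target-target synapsis refused: two TBL halves lack the",
            "DBL-SL contact with RuvC required to assemble the tetrameric",
            "synaptic complex"),
      class = c("SynapsisError", "error", "condition")))
  if (all(loops == "DBL")) {
    target_half <- half_a; donor_half <- half_b
    provenance <- "donor-donor"
    notes <- paste("donor-donor synapsis: both halves are DBL complexes;",
                   "protomer labels 1-2 are assigned to the first half")
  } else {
    target_half <- if (half_a$loop == "TBL") half_a else half_b
    donor_half  <- if (half_a$loop == "TBL") half_b else half_a
    provenance <- "target-donor"
    notes <- character(0)
  }
  protomers <- data.frame(
    protomer = 1:4,
    dimer = c("1-2", "1-2", "3-4", "3-4"),
    binds = c(rep(paste0(target_half$loop, "/",
                         target_half$window$role), 2),
              rep(paste0(donor_half$loop, "/",
                         donor_half$window$role), 2)),
    stringsAsFactors = FALSE)
  structure(list(
    stage = "synapsed",
    target_half = target_half,
    donor_half = donor_half,
    provenance = provenance,
    protomers = protomers,
    covalent_links = empty_links(),
    cuts = empty_cuts(),
    exchanged_tops = FALSE,
    junctions = NULL,
    trajectory = "synapsed",
    notes = notes
  ), class = "SynapticState")
}

empty_links <- function()
  data.frame(serine = character(0), molecule = character(0),
             strand = character(0), position = integer(0),
             stringsAsFactors = FALSE)

empty_cuts <- function()
  data.frame(molecule = character(0), strand = character(0),
             five_prime_pos = integer(0), stringsAsFactors = FALSE)

link <- function(serine, molecule, strand, position)
  data.frame(serine = serine, molecule = molecule, strand = strand,
             position = as.integer(position), stringsAsFactors = FALSE)

# cognate handshake check for one half against its own window top 6-7
half_locks <- function(half, policy = "permissive") {
  pos <- if (half$loop == "TBL") c(81L, 82L) else c(166L, 167L)
  rna <- substring(half$brna$sequence, pos, pos)
  dna <- c(window_base(half$window, "top", 7L),
           window_base(half$window, "top", 6L))
  any(is_paired(pair_class_vec(rna, dna), policy))
}

#' Advance the synaptic complex by one reaction step
#'
#' Transitions of the reaction state machine:
#' \describe{
#'   \item{synapsed -> top-cleaved}{Both top strands are cut 3' of window
#'     position 9 (between 9 and 10); S241 of protomer 4 links covalently to
#'     target top position 10 and S241 of protomer 2 to donor top 10
#'     (5'-phosphoserine intermediates).}
#'   \item{top-cleaved -> locked | hj-intermediate}{If either bound bridge
#'     RNA's handshake guide pairs its cognate top strand at window positions
#'     6-7 (permissive policy) the complex is trapped in the locked state
#'     (absorbing). Otherwise the top strands are exchanged and religated at
#'     both junctions, the serines are released, and a Holliday junction
#'     intermediate forms.}
#'   \item{hj-intermediate -> hj-resolved}{Both bottom strands are cut
#'     between positions 9* and 10*; S241 of protomer 3 links to target
#'     bottom 10* and S241 of protomer 1 to donor bottom 10*.}
#'   \item{hj-resolved -> products}{Bottom strands are exchanged and ligated
#'     (modelled as deterministic; recorded as a modelling assumption in the
#'     trajectory notes) and the junction windows with their heteroduplex
#'     flags are produced.}
#' }
#' Stepping a `locked` state is a no-op with a warning; stepping `products`
#' is a silent no-op.
#'
#' @param s A `SynapticState`.
#' @return The advanced `SynapticState`.
#' @export
synapse_step <- function(s) {
  stopifnot(inherits(s, "SynapticState"))
  tw <- s$target_half$window
  dw <- s$donor_half$window
  advance <- function(s, stage) {
    s$stage <- stage
    s$trajectory <- c(s$trajectory, stage)
    s
  }
  switch(s$stage,
    "synapsed" = {
      s$cuts <- rbind(s$cuts,
                      data.frame(molecule = c("target", "donor"),
                                 strand = "top", five_prime_pos = 9L,
                                 stringsAsFactors = FALSE))
      s$covalent_links <- rbind(
        link("S241.4", "target", "top", 10L),
        link("S241.2", "donor", "top", 10L))
      advance(s, "top-cleaved")
    },
    "top-cleaved" = {
      if (half_locks(s$target_half) || half_locks(s$donor_half)) {
        s$notes <- c(s$notes,
                     "cognate handshake base pairing traps the complex in the pre-strand-exchange locked state")
        advance(s, "locked")
      } else {
        s$covalent_links <- empty_links()
        s$exchanged_tops <- TRUE
        s$notes <- c(s$notes,
                     "top strands exchanged and religated (phosphodiester bonds at both junctions)")
        advance(s, "hj-intermediate")
      }
    },
    "locked" = {
      warning("synaptic complex is locked; no further transitions",
              call. = FALSE)
      s
    },
    "hj-intermediate" = {
      s$cuts <- rbind(s$cuts,
                      data.frame(molecule = c("target", "donor"),
                                 strand = "bottom", five_prime_pos = 9L,
                                 stringsAsFactors = FALSE))
      s$covalent_links <- rbind(
        link("S241.3", "target", "bottom", 10L),
        link("S241.1", "donor", "bottom", 10L))
      advance(s, "hj-resolved")
    },
    "hj-resolved" = {
      s$covalent_links <- empty_links()
      s$junctions <- junction_windows(tw, dw)
      s$notes <- c(s$notes,
                   "bottom-strand exchange and ligation modelled as deterministic in-simulator steps")
      advance(s, "products")
    },
    "products" = s
  )
}

#' Run the reaction to completion
#'
#' Repeatedly applies [synapse_step()] until the trajectory reaches
#' `products` or the absorbing `locked` state.
#'
#' @param s A `SynapticState` (typically from [form_synapse()]).
#' @return A `SynapseTrajectory`: list with `states` (every visited state),
#'   `stages` (character vector of stage names) and `final`.
#' @export
synapse_run <- function(s) {
  states <- list(s)
  while (!s$stage %in% c("locked", "products")) {
    s <- synapse_step(s)
    states[[length(states) + 1L]] <- s
  }
  structure(list(states = states,
                 stages = vapply(states, `[[`, "", "stage"),
                 final = s),
            class = "SynapseTrajectory")
}

#' @export
print.SynapticState <- function(x, ...) {
  cat("SynapticState: ", paste(x$trajectory, collapse = " -> "), "\n",
      sep = "")
  if (nrow(x$covalent_links)) {
    cat("  covalent 5'-phosphoserine links:\n")
    for (i in seq_len(nrow(x$covalent_links)))
      cat(sprintf("    %s <-> %s %s position %d%s\n",
                  x$covalent_links$serine[i], x$covalent_links$molecule[i],
                  x$covalent_links$strand[i], x$covalent_links$position[i],
                  if (x$covalent_links$strand[i] == "bottom") "*" else ""))
  }
  invisible(x)
}

# Junction windows after both exchanges. Junction A: target-left/donor-right;
# junction B: donor-left/target-right. Top crossover 3' of window position 9,
# bottom crossover 3' of 9* (i.e. across top positions 5|6).
junction_windows <- function(tw, dw) {
  ja <- make_window(paste0(substr(tw$top, 1, 9), substr(dw$top, 10, 14)),
                    paste0(substr(dw$bottom, 1, 9),
                           substr(tw$bottom, 10, 14)),
                    role = "junction")
  jb <- make_window(paste0(substr(dw$top, 1, 9), substr(tw$top, 10, 14)),
                    paste0(substr(tw$bottom, 1, 9),
                           substr(dw$bottom, 10, 14)),
                    role = "junction")
  parent_top <- c(rep("target", 9), rep("donor", 5))
  # across top position i sits bottom position 15 - i
  parent_bottom_a <- c(rep("target", 5), rep("donor", 9))  # across-top coords
  list(
    junction_a = ja, junction_b = jb,
    heteroduplex_a = which(ja$mismatch),
    heteroduplex_b = which(jb$mismatch),
    parent_top_a = parent_top,
    parent_top_b = rev(c(rep("target", 5), rep("donor", 9))),
    parent_bottom_a = parent_bottom_a,
    parent_bottom_b = c(rep("donor", 5), rep("target", 9))
  )
}

# ---- full-molecule splicing ------------------------------------------------

# A product molecule stores the top strand plus the "aligned bottom": the
# base on the complementary strand across each top position (so position i of
# `bottom_aligned` faces position i of `top`). Heteroduplex positions are
# where the two are non-complementary.
product_molecule <- function(top, bottom_aligned, topology,
                             parent_top, parent_bottom) {
  het <- which(chars(bottom_aligned) != comp_dna(chars(top)))
  structure(list(top = top, bottom_aligned = bottom_aligned,
                 topology = topology, length = nchar(top),
                 parent_top = parent_top, parent_bottom = parent_bottom,
                 heteroduplex = het),
            class = "ProductMolecule")
}

#' @export
print.ProductMolecule <- function(x, ...) {
  cat("ProductMolecule (", x$topology, "), ", x$length, " bp",
      if (length(x$heteroduplex))
        paste0(", heteroduplex at ",
               paste(x$heteroduplex, collapse = ", ")),
      "\n", sep = "")
  invisible(x)
}

# linear segment helpers (1-based closed ranges; circ_* wraps)
seg <- function(s, from, to) if (to < from) "" else substr(s, from, to)
cseg <- function(s, from, len) circ_substr(s, from, len)

#' Recombine two substrate molecules
#'
#' Runs the full reaction (synapsis, top cleavage, handshake gate, Holliday
#' junction formation and resolution) on the two recognition windows and, if
#' the reaction completes, splices the full-length molecules at the two
#' junctions. Crossovers follow the cleavage registers: top strands cross 3'
#' of window position 9, bottom strands 3' of position 9* (4 nt staggered),
#' which is what creates the junction heteroduplex at window positions 6-7
#' when target and donor differ there.
#'
#' Topology handling: linear target x circular donor gives one linear product
#' with the donor inserted (insertion); linear x linear gives two linear
#' products; circular x circular gives one fused circle. With
#' `same_molecule = TRUE` the two windows lie on one molecule: direct
#' orientation (both windows on `+`) excises a circle, inverted orientation
#' (donor window on `-`) inverts the intervening segment.
#'
#' @param target,donor `SubstrateMolecule`s (for `same_molecule = TRUE`, the
#'   same sequence with the two window placements).
#' @param b The designed `BridgeRNA` (used for both loops; the two loops of
#'   one synaptic complex come from two copies of the molecule).
#' @param same_molecule Both windows lie on a single molecule.
#' @return A `RecombinationProducts` object: `products` (list of
#'   `ProductMolecule`s), `junctions` (junction windows A and B with
#'   heteroduplex flags and parent maps), `stages`, `outcome` (one of
#'   `"insertion"`, `"two-linear"`, `"fusion"`, `"excision"`,
#'   `"inversion"`), `notes`.
#' @seealso [repair_products()] to resolve heteroduplex positions.
#' @export
recombine_molecules <- function(target, donor, b, same_molecule = FALSE) {
  stopifnot(inherits(target, "SubstrateMolecule"),
            inherits(donor, "SubstrateMolecule"),
            inherits(b, "BridgeRNA"))
  tw <- window_of(target)
  dw <- window_of(donor)
  traj <- synapse_run(form_synapse(half_complex(b, tw, "TBL"),
                                   half_complex(b, dw, "DBL")))
  if (traj$final$stage == "locked")
    stop(errorCondition(
      paste("recombination did not complete: the synaptic complex is",
            "trapped in the locked state by cognate handshake pairing"),
      class = c("ProductsUnavailable", "error", "condition"),
      trajectory = traj))
  jn <- traj$final$junctions

  ts <- target$sequence; ds <- donor$sequence
  tB <- comp_dna(ts); dB <- comp_dna(ds)     # aligned complementary strand
  wt <- target$window_start; wd <- donor$window_start
  Lt <- target$length; Ld <- donor$length
  ct <- wt + 8L; cd <- wd + 8L               # top crossover coordinates
  bt <- wt + 4L; bd <- wd + 4L               # bottom crossover coordinates

  outcome <- NULL
  products <- list()

  if (same_molecule) {
    if (!identical(ts, ds) || !identical(target$topology, donor$topology))
      stop("same_molecule = TRUE requires both windows on one molecule",
           call. = FALSE)
    a <- min(wt, wd); z <- max(wt, wd)
    ca <- a + 8L; cz <- z + 8L; ba <- a + 4L; bz <- z + 4L
    if (donor$window_strand == "+") {
      outcome <- "excision"
      circle <- product_molecule(
        seg(ts, ca + 1L, cz),
        paste0(seg(tB, ca + 1L, bz), seg(tB, ba + 1L, ca)),
        "circular",
        parent_top = "excised segment", parent_bottom = "excised segment")
      shortened <- product_molecule(
        paste0(seg(ts, 1L, ca), seg(ts, cz + 1L, Lt)),
        paste0(seg(tB, 1L, ba), seg(tB, bz + 1L, Lt)),
        target$topology,
        parent_top = "flanks", parent_bottom = "flanks")
      products <- list(circle, shortened)
    } else {
      outcome <- "inversion"
      inv_top <- paste0(seg(ts, 1L, ca),
                        revcomp_dna(seg(ts, ca + 1L, bz)),
                        seg(ts, bz + 1L, Lt))
      inv_bot <- paste0(seg(tB, 1L, ba),
                        collapse(rev(chars(seg(ts, ba + 1L, cz)))),
                        seg(tB, cz + 1L, Lt))
      products <- list(product_molecule(inv_top, inv_bot, target$topology,
                                        parent_top = "inverted",
                                        parent_bottom = "inverted"))
    }
  } else if (target$topology == "linear" && donor$topology == "circular") {
    outcome <- "insertion"
    products <- list(product_molecule(
      paste0(seg(ts, 1L, ct), cseg(ds, cd + 1L, Ld), seg(ts, ct + 1L, Lt)),
      paste0(seg(tB, 1L, bt), cseg(dB, bd + 1L, Ld), seg(tB, bt + 1L, Lt)),
      "linear",
      parent_top = c(target = ct, donor = Ld, target2 = Lt - ct),
      parent_bottom = c(target = bt, donor = Ld, target2 = Lt - bt)))
  } else if (target$topology == "circular" && donor$topology == "linear") {
    outcome <- "insertion"
    products <- list(product_molecule(
      paste0(seg(ds, 1L, cd), cseg(ts, ct + 1L, Lt), seg(ds, cd + 1L, Ld)),
      paste0(seg(dB, 1L, bd), cseg(tB, bt + 1L, Lt), seg(dB, bd + 1L, Ld)),
      "linear",
      parent_top = c(donor = cd, target = Lt, donor2 = Ld - cd),
      parent_bottom = c(donor = bd, target = Lt, donor2 = Ld - bd)))
  } else if (target$topology == "linear" && donor$topology == "linear") {
    outcome <- "two-linear"
    p1 <- product_molecule(
      paste0(seg(ts, 1L, ct), seg(ds, cd + 1L, Ld)),
      paste0(seg(tB, 1L, bt), seg(dB, bd + 1L, Ld)),
      "linear",
      parent_top = c(target = ct, donor = Ld - cd),
      parent_bottom = c(target = bt, donor = Ld - bd))
    p2 <- product_molecule(
      paste0(seg(ds, 1L, cd), seg(ts, ct + 1L, Lt)),
      paste0(seg(dB, 1L, bd), seg(tB, bt + 1L, Lt)),
      "linear",
      parent_top = c(donor = cd, target = Lt - ct),
      parent_bottom = c(donor = bd, target = Lt - bt))
    products <- list(p1, p2)
  } else { # circular x circular -> fused circle
    outcome <- "fusion"
    products <- list(product_molecule(
      paste0(cseg(ts, ct + 1L, Lt), cseg(ds, cd + 1L, Ld)),
      paste0(cseg(tB, ct + 1L, Lt - 4L), cseg(dB, bd + 1L, Ld),
             seg(tB, bt + 1L, ct)),
      "circular",
      parent_top = c(target = Lt, donor = Ld),
      parent_bottom = c(target = Lt, donor = Ld)))
  }

  structure(list(
    products = products,
    junctions = jn,
    stages = traj$stages,
    trajectory = traj,
    outcome = outcome,
    notes = traj$final$notes
  ), class = "RecombinationProducts")
}

#' Window-level recombination products
#'
#' Runs the state machine on two windows alone (no flanking sequence) and
#' returns the junction windows; a convenience wrapper around
#' [form_synapse()] / [synapse_run()].
#'
#' @param b A designed `BridgeRNA`.
#' @param target,donor `DnaWindow`s.
#' @return A `RecombinationProducts` with `products = list()` and the
#'   junction windows filled in.
#' @export
recombine_windows <- function(b, target, donor) {
  traj <- synapse_run(form_synapse(half_complex(b, target, "TBL"),
                                   half_complex(b, donor, "DBL")))
  if (traj$final$stage == "locked")
    stop(errorCondition(
      "recombination did not complete: locked state",
      class = c("ProductsUnavailable", "error", "condition"),
      trajectory = traj))
  structure(list(products = list(), junctions = traj$final$junctions,
                 stages = traj$stages, trajectory = traj,
                 outcome = "windows", notes = traj$final$notes),
            class = "RecombinationProducts")
}

#' Resolve junction heteroduplexes
#'
#' Heteroduplex positions in products (top and bottom strands from different
#' parents and non-complementary, window positions 6-7 for identical cores)
#' are presumed excised and repaired in vivo. `"top-wins"` rewrites the
#' bottom strand to the complement of the top base, `"bottom-wins"` the
#' reverse; `"leave"` returns the input unchanged.
#'
#' @param p A `RecombinationProducts`.
#' @param policy `"top-wins"`, `"bottom-wins"` or `"leave"`.
#' @return A `RecombinationProducts` with the chosen strand propagated and
#'   heteroduplex flags cleared (unless `"leave"`).
#' @export
repair_products <- function(p, policy = c("top-wins", "bottom-wins",
                                          "leave")) {
  policy <- match.arg(policy)
  stopifnot(inherits(p, "RecombinationProducts"))
  if (policy == "leave") return(p)

  fix_window <- function(w) {
    mm <- which(w$mismatch)
    if (!length(mm)) return(w)
    tc <- chars(w$top); bc <- chars(w$bottom)
    if (policy == "top-wins") bc[15L - mm] <- comp_dna(tc[mm])
    else                      tc[mm] <- comp_dna(bc[15L - mm])
    make_window(collapse(tc), collapse(bc), role = w$role)
  }
  fix_product <- function(m) {
    if (!length(m$heteroduplex)) return(m)
    tc <- chars(m$top); bc <- chars(m$bottom_aligned)
    if (policy == "top-wins") bc[m$heteroduplex] <- comp_dna(tc[m$heteroduplex])
    else                      tc[m$heteroduplex] <- comp_dna(bc[m$heteroduplex])
    product_molecule(collapse(tc), collapse(bc), m$topology,
                     m$parent_top, m$parent_bottom)
  }
  if (!is.null(p$junctions)) {
    p$junctions$junction_a <- fix_window(p$junctions$junction_a)
    p$junctions$junction_b <- fix_window(p$junctions$junction_b)
    p$junctions$heteroduplex_a <- which(p$junctions$junction_a$mismatch)
    p$junctions$heteroduplex_b <- which(p$junctions$junction_b$mismatch)
  }
  p$products <- lapply(p$products, fix_product)
  p
}

#' @export
print.RecombinationProducts <- function(x, ...) {
  cat("RecombinationProducts (", x$outcome, ")\n", sep = "")
  cat("  stages: ", paste(x$stages, collapse = " -> "), "\n", sep = "")
  if (!is.null(x$junctions)) {
    cat("  junction A top 5'-", x$junctions$junction_a$top, "-3'",
        if (length(x$junctions$heteroduplex_a))
          paste0("  heteroduplex at ",
                 paste(x$junctions$heteroduplex_a, collapse = ",")),
        "\n", sep = "")
    cat("  junction B top 5'-", x$junctions$junction_b$top, "-3'",
        if (length(x$junctions$heteroduplex_b))
          paste0("  heteroduplex at ",
                 paste(x$junctions$heteroduplex_b, collapse = ",")),
        "\n", sep = "")
  }
  for (m in x$products) print(m)
  invisible(x)
}
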