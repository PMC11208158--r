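#' Random scaffold placeholder
#'
#' A 177-nt random RNA sequence with the conserved A/G nucleotides planted at
#' their reference positions, for tests and examples that do not need the
#' real wild-type scaffold (whose base identities at non-programmable
#' positions are not modelled). Labelled synthetic: every base outside the
#' conserved set is random.
#'
#' @param seed Integer seed.
#' @param length Scaffold length (default 177).
#' @return A single RNA string.
#' @export
random_scaffold <- function(seed, length = 177L) {
  set.seed(seed)
  s <- sample(RNA_BASES, length, replace = TRUE)
  cons <- conserved_nucleotides()
  pos <- as.integer(names(cons))
  pos <- pos[pos <= length]
  s[pos] <- cons[as.character(pos)]
  collapse(s)
}

# TRUE when a post-HSB design for these windows would coincidentally pair a
# handshake guide with its cognate base (target and donor sharing bases at
# window positions 6-7), which locks the complex even in the productive
# configuration.
coincidental_handshake <- function(target_top, donor_top) {
  t76 <- chars(substr(target_top, 6, 7))[2:1]  # positions 7, 6
  d76 <- chars(substr(donor_top, 6, 7))[2:1]
  hsg_t <- rna_pairing_base(d76)  # HSG-T written against donor top 7,6
  hsg_d <- rna_pairing_base(t76)  # HSG-D written against target top 7,6
  any(is_paired(pair_class_vec(c(hsg_t, hsg_d), c(t76, d76)), "permissive"))
}

#' Generate seeded recombination fixtures
#'
#' Produces `n_pairs` of (target window, donor window): WT-complementary
#' duplexes with guaranteed CT cores at positions 8-9 and random bases
#' elsewhere, plus one scaffold placeholder ([random_scaffold()]). Emulating
#' genuine target/donor site pairs - which differ at the handshake positions -
#' donor bases at window positions 6-7 are resampled until the post-HSB
#' handshake guides carry no coincidental cognate pairing, so every generated
#' pair supports a productive (unlocked) post-HSB design.
#'
#' @param seed Integer seed; identical seeds give identical fixtures.
#' @param n_pairs Number of window pairs (>= 1).
#' @return List with `pairs` (list of `list(target, donor)` `DnaWindow`s) and
#'   `scaffold` (a `BridgeRNA`).
#' @export
generate_fixtures <- function(seed, n_pairs) {
  if (n_pairs < 1L) stop("n_pairs must be >= 1", call. = FALSE)
  set.seed(seed)
  random_top <- function() {
    s <- sample(DNA_BASES, 14L, replace = TRUE)
    s[8:9] <- c("C", "T")
    collapse(s)
  }
  pairs <- vector("list", n_pairs)
  for (k in seq_len(n_pairs)) {
    t_top <- random_top()
    d_top <- random_top()
    while (coincidental_handshake(t_top, d_top)) {
      dc <- chars(d_top)
      dc[6:7] <- sample(DNA_BASES, 2L, replace = TRUE)
      d_top <- collapse(dc)
    }
    pairs[[k]] <- list(target = make_window(t_top, role = "target"),
                       donor = make_window(d_top, role = "donor"))
  }
  scaffold_seed <- sample.int(.Machine$integer.max, 1L)
  list(pairs = pairs,
       scaffold = load_scaffold(random_scaffold(scaffold_seed)))
}
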