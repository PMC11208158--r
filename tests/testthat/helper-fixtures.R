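# Shared fixtures and independent oracles for the test suite.

# worked-example windows used throughout
target_top_wk <- "ACGTACGCTGACTA"
donor_top_wk <- "TTCAGATCTTGATT"

worked_scaffold <- function() load_scaffold(random_scaffold(seed = 1))

worked_windows <- function() list(
  target = make_window(target_top_wk, role = "target"),
  donor = make_window(donor_top_wk, role = "donor"))

worked_design <- function(hsg_mode = "post-HSB", rtg_extension = TRUE) {
  w <- worked_windows()
  suppressWarnings(design_bridge_rna(worked_scaffold(), w$target, w$donor,
                                     design_options(rtg_extension,
                                                    hsg_mode)))
}

# independent reverse-complement oracle (no package internals)
oracle_revcomp <- function(x) {
  map <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(map[strsplit(x, "")[[1]]]), collapse = "")
}

# independent splice oracle for junction windows: concatenate-and-cut with
# the 9|10 (top) and 9*|10* (bottom) crossover rules, written directly from
# substring arithmetic rather than via the state machine.
oracle_junctions <- function(t_top, d_top) {
  t_bot <- oracle_revcomp(t_top)
  d_bot <- oracle_revcomp(d_top)
  list(
    a_top = paste0(substr(t_top, 1, 9), substr(d_top, 10, 14)),
    a_bot = paste0(substr(d_bot, 1, 9), substr(t_bot, 10, 14)),
    b_top = paste0(substr(d_top, 1, 9), substr(t_top, 10, 14)),
    b_bot = paste0(substr(t_bot, 1, 9), substr(d_bot, 10, 14)))
}

# brute-force heteroduplex oracle: positions where the junction duplex is
# non-complementary under the 15 - i convention
oracle_heteroduplex <- function(top, bottom) {
  map <- c(A = "T", C = "G", G = "C", T = "A")
  tc <- strsplit(top, "")[[1]]
  bc <- strsplit(bottom, "")[[1]]
  which(bc[15 - seq_len(14)] != map[tc])
}

random_window_top <- function(core = c("C", "T")) {
  s <- sample(c("A", "C", "G", "T"), 14, replace = TRUE)
  s[8:9] <- core
  paste(s, collapse = "")
}
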