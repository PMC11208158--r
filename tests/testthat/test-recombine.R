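test_that("synapsis requires a DBL-SL: TBL+DBL and DBL+DBL form, TBL+TBL refuses", {
  w <- worked_windows()
  d <- worked_design()
  tbl <- half_complex(d$brna, w$target, "TBL")
  dbl <- half_complex(d$brna, w$donor, "DBL")
  s <- form_synapse(tbl, dbl)
  expect_identical(s$stage, "synapsed")
  expect_identical(nrow(s$protomers), 4L)
  expect_identical(s$provenance, "target-donor")
  expect_error(form_synapse(tbl, tbl), class = "SynapsisError")
  expect_error(form_synapse(tbl, tbl), "DBL-SL")
  dd <- form_synapse(dbl, half_complex(d$brna, w$donor, "DBL"))
  expect_identical(dd$provenance, "donor-donor")
  # donor-donor runs to completion
  expect_identical(synapse_run(dd)$final$stage, "products")
})

test_that("the reaction cycle records cuts and phosphoserine links at the printed registers", {
  w <- worked_windows()
  d <- worked_design()
  s <- form_synapse(half_complex(d$brna, w$target, "TBL"),
                    half_complex(d$brna, w$donor, "DBL"))
  s <- synapse_step(s)
  expect_identical(s$stage, "top-cleaved")
  # top cuts between window positions 9 and 10 on both molecules
  top_cuts <- s$cuts[s$cuts$strand == "top", ]
  expect_identical(top_cuts$five_prime_pos, c(9L, 9L))
  # S241.4 <-> target top 10, S241.2 <-> donor top 10
  expect_equal(
    s$covalent_links[s$covalent_links$serine == "S241.4", c("molecule", "position")],
    data.frame(molecule = "target", position = 10L), ignore_attr = TRUE)
  expect_equal(
    s$covalent_links[s$covalent_links$serine == "S241.2", c("molecule", "position")],
    data.frame(molecule = "donor", position = 10L), ignore_attr = TRUE)

  s <- synapse_step(s)
  expect_identical(s$stage, "hj-intermediate")
  expect_identical(nrow(s$covalent_links), 0L)  # serines released on religation

  s <- synapse_step(s)
  expect_identical(s$stage, "hj-resolved")
  bottom_cuts <- s$cuts[s$cuts$strand == "bottom", ]
  expect_identical(bottom_cuts$five_prime_pos, c(9L, 9L))
  links <- s$covalent_links
  expect_equal(links[links$serine == "S241.3", c("molecule", "strand", "position")],
                   data.frame(molecule = "target", strand = "bottom",
                              position = 10L), ignore_attr = TRUE)
  expect_equal(links[links$serine == "S241.1", c("molecule", "strand", "position")],
                   data.frame(molecule = "donor", strand = "bottom",
                              position = 10L), ignore_attr = TRUE)

  s <- synapse_step(s)
  expect_identical(s$stage, "products")
  expect_identical(s$trajectory,
                   c("synapsed", "top-cleaved", "hj-intermediate",
                     "hj-resolved", "products"))
  # stepping a finished reaction is a no-op
  expect_identical(synapse_step(s)$stage, "products")
})

test_that("pre-HSB complexes stop at the absorbing locked state", {
  w <- worked_windows()
  d <- worked_design(hsg_mode = "pre-HSB")
  traj <- synapse_run(form_synapse(half_complex(d$brna, w$target, "TBL"),
                                   half_complex(d$brna, w$donor, "DBL")))
  expect_identical(traj$final$stage, "locked")
  expect_identical(tail(traj$stages, 1), "locked")
  expect_null(traj$final$junctions)
  expect_warning(synapse_step(traj$final), "locked")
})

test_that("junction windows match the worked example and the splice oracle", {
  w <- worked_windows()
  d <- worked_design()
  p <- recombine_windows(d$brna, w$target, w$donor)
  expect_identical(p$junctions$junction_a$top, "ACGTACGCTTGATT")
  expect_identical(p$junctions$junction_a$bottom, "AATCAAGATTACGT")
  expect_identical(p$junctions$heteroduplex_a, c(6L, 7L))
  expect_identical(p$junctions$junction_b$top, "TTCAGATCTGACTA")
  expect_identical(p$junctions$junction_b$bottom, "TAGTCAGCGCTGAA")
  expect_identical(p$junctions$heteroduplex_b, c(6L, 7L))
})

test_that("self-recombination of identical windows is sequence-neutral", {
  sc <- worked_scaffold()
  w <- make_window(target_top_wk, role = "target")
  w2 <- make_window(target_top_wk, role = "donor")
  # identical windows share all bases at 6-7, so a post-HSB handshake would
  # be unavoidably cognate; keep-scaffold HSGs set to A pair neither C nor G
  # (target top 6,7 = C,G), keeping the complex unlocked
  d <- design_bridge_rna(sc, w, w2, design_options(hsg_mode = "keep-scaffold"))
  d$brna <- apply_variant(d$brna,
                          scaffold_variant("point-substitutions",
                                           c(`81` = "A", `82` = "A",
                                             `166` = "A", `167` = "A")))
  expect_false(predict_lock(d$brna, w, w2)$locked)
  p <- recombine_windows(d$brna, w, w2)
  expect_identical(p$junctions$junction_a$top, target_top_wk)
  expect_length(p$junctions$heteroduplex_a, 0)
  expect_length(p$junctions$heteroduplex_b, 0)
})

test_that("junction sequences equal the independent splice oracle on random pairs", {
  fx <- generate_fixtures(seed = 1234, n_pairs = 60)
  for (pair in fx$pairs) {
    d <- design_bridge_rna(fx$scaffold, pair$target, pair$donor,
                           design_options())
    p <- recombine_windows(d$brna, pair$target, pair$donor)
    want <- oracle_junctions(pair$target$top, pair$donor$top)
    expect_identical(p$junctions$junction_a$top, want$a_top)
    expect_identical(p$junctions$junction_a$bottom, want$a_bot)
    expect_identical(p$junctions$junction_b$top, want$b_top)
    expect_identical(p$junctions$junction_b$bottom, want$b_bot)
    # heteroduplex flags subset {6,7} for identical (CT) cores, empty iff
    # the two tops agree at 6-7
    flags <- union(p$junctions$heteroduplex_a, p$junctions$heteroduplex_b)
    expect_true(all(flags %in% c(6L, 7L)))
    same67 <- substr(pair$target$top, 6, 7) == substr(pair$donor$top, 6, 7)
    expect_identical(length(flags) == 0, same67)
  }
})

test_that("insertion of a circular donor conserves every nucleotide", {
  set.seed(5150)
  fx <- generate_fixtures(seed = 5150, n_pairs = 1)
  tpad <- paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE),
                collapse = "")
  dpad <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
                collapse = "")
  target <- substrate_molecule(paste0(tpad, fx$pairs[[1]]$target$top, tpad),
                               window_start = 21, role = "target")
  donor <- substrate_molecule(paste0(fx$pairs[[1]]$donor$top, dpad),
                              topology = "circular", window_start = 1,
                              role = "donor")
  d <- design_bridge_rna(fx$scaffold, fx$pairs[[1]]$target,
                         fx$pairs[[1]]$donor, design_options())
  p <- recombine_molecules(target, donor, d$brna)
  expect_identical(p$outcome, "insertion")
  expect_length(p$products, 1)
  prod <- p$products[[1]]
  expect_identical(prod$length, target$length + donor$length)
  expect_identical(nchar(prod$bottom_aligned), prod$length)
  # base content of the top strands is conserved
  expect_identical(sort(strsplit(paste0(target$sequence, donor$sequence),
                                 "")[[1]]),
                   sort(strsplit(prod$top, "")[[1]]))
  # both junction cores present; heteroduplex only at the staggered overlap
  # junction A heteroduplex sits at target window 6-7 (product 26-27);
  # junction B at donor window 6-7, which the circular splice places at
  # product positions 70-71 for these offsets and lengths
  expect_true(all(prod$heteroduplex %in% c(26L, 27L, 70L, 71L)))
})

test_that("linear x linear recombination yields two conserved products", {
  fx <- generate_fixtures(seed = 808, n_pairs = 5)
  for (pair in fx$pairs) {
    tpad <- paste(sample(c("A", "C", "G", "T"), 15, replace = TRUE),
                  collapse = "")
    dpad <- paste(sample(c("A", "C", "G", "T"), 25, replace = TRUE),
                  collapse = "")
    target <- substrate_molecule(paste0(tpad, pair$target$top, tpad),
                                 window_start = 16, role = "target")
    donor <- substrate_molecule(paste0(dpad, pair$donor$top, dpad),
                                window_start = 26, role = "donor")
    d <- design_bridge_rna(fx$scaffold, pair$target, pair$donor,
                           design_options())
    p <- recombine_molecules(target, donor, d$brna)
    expect_identical(p$outcome, "two-linear")
    lens_top <- vapply(p$products, function(m) nchar(m$top), 1L)
    lens_bot <- vapply(p$products, function(m) nchar(m$bottom_aligned), 1L)
    expect_identical(sum(lens_top), target$length + donor$length)
    expect_identical(sum(lens_bot), target$length + donor$length)
    # junction A product carries target-left then donor-right
    expect_identical(substr(p$products[[1]]$top, 1, 16 + 8),
                     substr(target$sequence, 1, 16 + 8))
  }
})

test_that("direct repeats excise a circle; inverted orientation inverts", {
  fx <- generate_fixtures(seed = 4242, n_pairs = 1)
  pair <- fx$pairs[[1]]
  mid <- "GGATCCGGATCCGGATCC"
  seqd <- paste0("AAAA", pair$target$top, mid, pair$donor$top, "TTTT")
  a <- 5L; b <- a + 14L + nchar(mid)
  target <- substrate_molecule(seqd, window_start = a, role = "target")
  donor_direct <- substrate_molecule(seqd, window_start = b, role = "donor")
  d <- design_bridge_rna(fx$scaffold, pair$target, pair$donor,
                         design_options())
  p <- recombine_molecules(target, donor_direct, d$brna,
                           same_molecule = TRUE)
  expect_identical(p$outcome, "excision")
  circ <- p$products[[1]]; lin <- p$products[[2]]
  expect_identical(circ$topology, "circular")
  expect_identical(circ$length + lin$length, nchar(seqd))
  expect_identical(circ$top, substr(seqd, a + 9, b + 8))
  # inverted orientation: donor window annotated on the minus strand
  seqi <- paste0("AAAA", pair$target$top, mid,
                 oracle_revcomp(pair$donor$top), "TTTT")
  di <- substrate_molecule(seqi, window_start = b, role = "donor",
                           window_strand = "-")
  ti <- substrate_molecule(seqi, window_start = a, role = "target")
  pi_ <- recombine_molecules(ti, di, d$brna, same_molecule = TRUE)
  expect_identical(pi_$outcome, "inversion")
  inv <- pi_$products[[1]]
  expect_identical(inv$length, nchar(seqi))
  expect_identical(substr(inv$top, 1, a + 8), substr(seqi, 1, a + 8))
  expect_identical(substr(inv$top, a + 9, b + 4),
                   oracle_revcomp(substr(seqi, a + 9, b + 4)))
})

test_that("locked reactions raise ProductsUnavailable carrying the trajectory", {
  w <- worked_windows()
  d <- worked_design(hsg_mode = "pre-HSB")
  target <- substrate_molecule(paste0("GGGGG", w$target$top, "GGGGG"),
                               window_start = 6, role = "target")
  donor <- substrate_molecule(paste0(w$donor$top, "CCCCC"),
                              topology = "circular", role = "donor")
  err <- tryCatch(recombine_molecules(target, donor, d$brna),
                  ProductsUnavailable = function(e) e)
  expect_s3_class(err, "ProductsUnavailable")
  expect_identical(tail(err$trajectory$stages, 1), "locked")
})

test_that("repair policies resolve heteroduplexes to the chosen strand", {
  w <- worked_windows()
  d <- worked_design()
  p <- recombine_windows(d$brna, w$target, w$donor)
  top <- repair_products(p, "top-wins")
  expect_length(top$junctions$heteroduplex_a, 0)
  expect_length(top$junctions$heteroduplex_b, 0)
  # bottom 9*,8* rewritten to the complement of (target) top 6,7
  expect_identical(substr(top$junctions$junction_a$bottom, 8, 9),
                   paste0(chartr("ACGT", "TGCA",
                                 substr(w$target$top, 7, 7)),
                          chartr("ACGT", "TGCA",
                                 substr(w$target$top, 6, 6))))
  expect_identical(top$junctions$junction_a$top, p$junctions$junction_a$top)
  bottom <- repair_products(p, "bottom-wins")
  expect_length(bottom$junctions$heteroduplex_a, 0)
  expect_identical(bottom$junctions$junction_a$bottom,
                   p$junctions$junction_a$bottom)
  # leave is byte-identical; repairing a clean product changes nothing
  expect_identical(repair_products(p, "leave"), p)
  expect_identical(repair_products(top, "top-wins"), top)
})
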