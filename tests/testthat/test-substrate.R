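test_that("windows default to the reverse-complement bottom strand", {
  w <- make_window(target_top_wk)
  expect_identical(w$bottom, oracle_revcomp(target_top_wk))
  expect_false(any(w$mismatch))
  # property: round trip holds for random tops
  set.seed(42)
  for (i in 1:25) {
    top <- random_window_top(sample(c("A", "C", "G", "T"), 2, replace = TRUE))
    expect_identical(make_window(top)$bottom, oracle_revcomp(top))
  }
})

test_that("a planted bottom-strand change flags one mismatch at top 15 - j", {
  bottom <- strsplit(oracle_revcomp(target_top_wk), "")[[1]]
  bottom[9] <- setdiff(c("A", "C", "G", "T"), bottom[9])[1]
  w <- make_window(target_top_wk, paste(bottom, collapse = ""))
  expect_identical(which(w$mismatch), 6L)  # 15 - 9
})

test_that("window length and alphabet are validated", {
  expect_error(make_window("ACGTACGCTGACT"), "14")
  expect_error(make_window("ACGTACGCTGACTN"), "A,C,G,T")
})

test_that("core verdicts follow the CT > GT > AT/TT preference", {
  mk <- function(core) {
    s <- strsplit(target_top_wk, "")[[1]]
    s[8:9] <- strsplit(core, "")[[1]]
    make_window(paste(s, collapse = ""))
  }
  expect_identical(validate_core(mk("CT"))$verdict, "pass")
  gt <- validate_core(mk("GT"))
  expect_identical(gt$verdict, "pass-with-warning")
  expect_identical(gt$position8_class, "G")
  expect_identical(validate_core(mk("AT"))$verdict, "pass-with-warning")
  expect_identical(validate_core(mk("TT"))$verdict, "pass-with-warning")
  ca <- validate_core(mk("CA"))
  expect_identical(ca$verdict, "fail")
  expect_false(ca$position9_ok)
  # ordinal ranks: C first, G second, A and T tied
  expect_lt(validate_core(mk("CT"))$rank, validate_core(mk("GT"))$rank)
  expect_identical(validate_core(mk("AT"))$rank, validate_core(mk("TT"))$rank)
})

test_that("scan_cores finds the single CT placement in a minimal linear sequence", {
  m <- substrate_molecule("AAAAAAACTAAAAA", role = "target")
  hits <- scan_cores(m)
  ct <- hits[hits$core == "CT", ]
  expect_identical(nrow(ct), 1L)
  expect_identical(ct$strand, "+")
  expect_identical(ct$window_start, 1L)
})

test_that("sequences with no T on either strand yield zero hits", {
  m <- substrate_molecule("CCCGGGCCCGGGCC", role = "target")
  expect_identical(nrow(scan_cores(m)), 0L)
})

test_that("circular scan reports CT cores wrapping the origin", {
  # CT sits at positions 1-2; the window placing it at 8-9 starts at L - 6
  s <- "CTGGGGGGGGGGGG"
  m <- substrate_molecule(s, topology = "circular", role = "target")
  hits <- scan_cores(m)
  fw <- hits[hits$strand == "+", ]
  expect_identical(fw$window_start, 8L)  # 8 + 7 wraps to position 1
  expect_identical(fw$core, "CT")
})

test_that("scan_cores agrees with brute-force enumeration on random sequences", {
  set.seed(99)
  brute <- function(seq, circular) {
    hits <- list()
    for (strand in c("+", "-")) {
      s <- if (strand == "+") seq else oracle_revcomp(seq)
      L <- nchar(s)
      doubled <- paste0(s, s)
      offs <- if (circular) seq_len(L) else seq_len(max(L - 13, 0))
      for (o in offs) {
        win <- substr(doubled, o, o + 13)
        if (substr(win, 9, 9) == "T")
          hits[[length(hits) + 1]] <- data.frame(
            window_start = o, strand = strand,
            core = substr(win, 8, 9), stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, hits)
  }
  for (rep in 1:10) {
    L <- sample(14:300, 1)
    circular <- rep %% 2 == 0
    seq <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                 collapse = "")
    m <- substrate_molecule(seq,
                            topology = if (circular) "circular" else "linear",
                            role = "target")
    got <- scan_cores(m)
    want <- brute(seq, circular)
    if (is.null(want)) {
      expect_identical(nrow(got), 0L)
    } else {
      key <- function(d) sort(paste(d$window_start, d$strand, d$core))
      expect_identical(key(got), key(want))
    }
  }
})

test_that("linear sequences shorter than a window warn and return empty", {
  m <- substrate_molecule("ACT", window_start = 1, role = "target")
  expect_error(window_of(m), "does not fit")
  expect_warning(hits <- scan_cores(m), "shorter")
  expect_identical(nrow(hits), 0L)
})

test_that("scan ranking puts CT before GT before AT/TT, ties by offset", {
  # GT at offset 1 core slot, CT later: CT must still rank first
  s <- "AAAAAAAGTAAAACTAAAAAA"
  m <- substrate_molecule(s, role = "target")
  hits <- scan_cores(m)
  fw <- hits[hits$strand == "+", ]
  expect_identical(fw$core[1], "CT")
  expect_true(all(diff(match(fw$core, c("CT", "GT", "AT", "TT"))) >= 0))
})

test_that("trap_mismatches substitutes exactly positions 2-7 with complements", {
  w <- make_window(target_top_wk)
  t <- trap_mismatches(w)
  expect_identical(substr(t$top, 2, 7), "GCATGC")  # complement of CGTACG
  expect_identical(which(t$mismatch), 2:7)
  expect_identical(t$bottom, w$bottom)
  expect_identical(substr(t$top, 8, 9), substr(w$top, 8, 9))  # core untouched
  expect_identical(substr(t$top, 1, 1), substr(w$top, 1, 1))
  expect_identical(substr(t$top, 8, 14), substr(w$top, 8, 14))
  # round trip: restoring 2-7 from the bottom strand clears all mismatches
  tc <- strsplit(t$top, "")[[1]]
  bc <- strsplit(t$bottom, "")[[1]]
  map <- c(A = "T", C = "G", G = "C", T = "A")
  tc[2:7] <- map[bc[15 - (2:7)]]
  restored <- make_window(paste(tc, collapse = ""), t$bottom)
  expect_false(any(restored$mismatch))
  # double-trapping is refused
  expect_error(trap_mismatches(t), "double-trapping")
})

test_that("window extraction from molecules honours offset, wrap and strand", {
  seq <- paste0("GGGGG", target_top_wk, "CCCCC")
  m <- substrate_molecule(seq, window_start = 6, role = "target")
  expect_identical(window_of(m)$top, target_top_wk)
  # circular wraparound
  rot <- paste0(substr(target_top_wk, 8, 14), "GGGGGG",
                substr(target_top_wk, 1, 7))
  mc <- substrate_molecule(rot, topology = "circular", window_start = 14,
                           role = "donor")
  expect_identical(window_of(mc)$top, target_top_wk)
  # minus-strand window reads the reverse complement
  mrc <- substrate_molecule(oracle_revcomp(seq), window_start = 6,
                            role = "target", window_strand = "-")
  expect_identical(window_of(mrc)$top, target_top_wk)
})
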