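# bridgerec

Sequence-level toolkit for **bridge-RNA-guided DNA recombination**, the
mechanism used by IS110-family insertion sequences such as *E. coli* IS621.
These elements encode a single recombinase and a 177-nt bridge RNA (bRNA)
whose two programmable loops — a target-binding loop (TBL) and a
donor-binding loop (DBL) — independently specify a 14-bp target window and a
14-bp donor window, making the system a general programmable tool for DNA
insertion, excision and inversion.

`bridgerec` is for people who want to design bridge RNAs against chosen
substrates and reason about the reaction's sequence-level consequences:

* **Scaffold model** — annotated 177-position scaffold (TBL 34–98, DBL
  110–177, guides LTG 50–58, RTG 77–80, LDG 123–130, RDG 157–165, handshake
  guides 81–82 and 166–167; conserved A/G nucleotides protected), plus
  engineered variants (5′ stem-loop deletion → 146 nt, DBL-SL GAAA
  tetraloop → 170 nt, point substitutions).
* **Design engine** — `design_bridge_rna()` rewrites only the programmable
  positions, writing each guide as the Watson–Crick RNA complement of the
  strand it physically pairs in the antiparallel register, and predicts the
  handshake "lock" state (cognate handshake pairing traps the complex and
  blocks strand exchange).
* **Reaction simulator** — an explicit state machine over
  `synapsed → top-cleaved → (locked | hj-intermediate) → hj-resolved →
  products`: top strands cut 3′ of window position 9 with covalent
  5′-phosphoserine intermediates (S241.4 ↔ target top 10, S241.2 ↔ donor
  top 10), bottom strands cut 3′ of 9\* at Holliday-junction resolution
  (S241.3 ↔ target bottom 10\*, S241.1 ↔ donor bottom 10\*), junctions
  spliced with the 4-nt stagger that yields the characteristic heteroduplex
  at window positions 6–7. Target–target synapsis is refused (no DBL stem
  loop contact); donor–donor completes.
* **Signed covariation score** — `signed_scores()` computes a normalized
  covariation score between DNA-site columns and bRNA columns in \[−1, +1\]:
  −1 means top-strand base pairing, +1 bottom-strand base pairing
  (mutual information + APC behind the scale; see the methods vignette).

## Worked example

```r
library(bridgerec)

sc <- load_scaffold(random_scaffold(seed = 1))   # synthetic 177-nt scaffold
tw <- make_window("ACGTACGCTGACTA", role = "target")
dw <- make_window("TTCAGATCTTGATT", role = "donor")

d <- design_bridge_rna(sc, tw, dw, design_options(rtg_extension = TRUE))
substr(d$brna$sequence, 50, 58)
#> [1] "ACGUACGCU"        # LTG = RNA complement of target bottom 14*..6*
substr(d$brna$sequence, 166, 167)
#> [1] "CG"               # HSG-D programmed against target top 7,6 (post-HSB)
d$report$lock
#> [1] FALSE              # no cognate handshake pairing: reaction can proceed

p <- recombine_windows(d$brna, tw, dw)
p$stages
#> [1] "synapsed" "top-cleaved" "hj-intermediate" "hj-resolved" "products"
p$junctions$junction_a$top
#> [1] "ACGTACGCTTGATT"   # target top 1-9 + donor top 10-14
p$junctions$heteroduplex_a
#> [1] 6 7                # parents differ at 6-7: junction heteroduplex
```

The LTG reads `ACGUACGCU` because complementing the target *bottom* strand
reproduces the transliterated target top 1–9; the junction A top strand is
the target's first nine positions joined to the donor's last five (the top
strands cross over between window positions 9 and 10); and positions 6–7 are
flagged because the bottom strand there still derives from the donor, four
nucleotides out of register with the top-strand crossover.

A design whose handshake guides pair their *cognate* window
(`design_options(hsg_mode = "pre-HSB")`) cleaves but stops at the absorbing
`locked` state and yields no products, matching the non-productive pre-HSB
configuration.

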