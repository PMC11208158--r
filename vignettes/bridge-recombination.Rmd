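---
title: "Modelling bridge-RNA-guided DNA recombination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling bridge-RNA-guided DNA recombination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bridgerec)
```

## The system being modelled

IS110-family insertion sequences such as *E. coli* IS621 move through a
circular double-stranded DNA intermediate. The element encodes a single small
recombinase and a 177-nt non-coding *bridge RNA* (bRNA) with two
independently programmable loops: a target-binding loop (TBL, nucleotides
34–98) whose left and right target guides (LTG, RTG) base pair with the
bottom and top strands of the genomic target site, and a donor-binding loop
(DBL, nucleotides 110–177) whose left and right donor guides (LDG, RDG) read
the donor (the element's circular form) the same way. Recombination happens
inside a 14-bp recognition window on each DNA (top strand positions 1–14,
bottom strand starred and numbered antiparallel, so top `i` faces bottom
`15 − i`), centred on a core dinucleotide at top positions 8–9 that both
substrates share — canonically CT.

`bridgerec` models this system at sequence level. It does three things:

1. **Scaffold model and design engine** — an annotated scaffold
   (`load_scaffold()`, `default_region_map()`) and a designer
   (`design_bridge_rna()`) that rewrites only the programmable guide
   positions, as the Watson–Crick RNA complement of the strand each guide
   physically pairs.
2. **Reaction simulator** — an explicit state machine
   (`form_synapse()`, `synapse_step()`, `synapse_run()`,
   `recombine_molecules()`) over the four chemical steps: top-strand
   cleavage, handshake-gated strand exchange, Holliday-junction formation,
   and bottom-strand resolution, with symbolic covalent-intermediate
   bookkeeping.
3. **Signed covariation score** (`signed_scores()`) — a normalized
   covariation statistic between DNA-site columns and bRNA columns whose
   sign encodes which strand a bRNA position pairs: −1 for top-strand
   pairing, +1 for bottom-strand pairing.

## The scaffold model

Regions are annotated as 1-based closed position sets. The guide registers
are exactly the published ones: LTG 50–58 against target bottom 14\*–6\*,
RTG 77–80 against target top 11–8, RTG-extension slots 74–76 against target
top 14–12, LDG 123–130 against donor bottom 14\*–7\*, RDG
157–158/161/162–165 against donor top 14, 13, 12, 11–8, and the handshake
guides 81–82 (TBL) and 166–167 (DBL) against top positions 7 and 6.
Positions 159–160 are flipped-out spacers and are never written. Eight
nucleotides (A43, A67, A116, A150; G48, G72, G121, G155) are conserved
across the family and recognised by the protein; loading a scaffold that
deviates from them only warns (orthologues are legitimate inputs), but any
operation that would *write* them fails.

Two boundaries required a decision:

* **The 5′ stem loop** is only characterised by the length difference
  between the full scaffold (177 nt) and its stem-loop deletion mutant
  (146 nt); we fix it at positions 1–31 and document it as inferred.
* **Position 161** is treated as a programmable RDG position pairing donor
  top 12. The wild type shows a non-canonical G161 pair there and the
  productive engineered variant makes it canonical, so the design engine
  owns the position even though interval notations for the RDG omit it.
* The internal stem registers of the TBL/DBL are *not* modelled: design
  never rewrites stems, so intervals suffice and no secondary-structure
  prediction is attempted.

## Pairing model

RNA:DNA Watson–Crick pairs are A:T, U:A, G:C, C:G. G:T wobble pairing is
treated as pairing-competent because the wild-type guides use it; U:G is
included in the wobble class for symmetry, flagged separately so a stricter
policy can exclude it (there is no in vivo evidence either way). The default
policy for *validating* designs is permissive (wobble counts); generated
guides are always emitted Watson–Crick-only.

## The handshake gate and the lock rule

After top-strand cleavage, exchange requires the handshake guides (HSGs) to
pair the *incoming, non-cognate* top strand. Programming them against the
cognate strand instead (pre-HSB mode) produces robust cleavage but traps the
complex in a "locked" pre-exchange state. The simulator implements this gate
as: **locked as soon as any HSG position pairs its cognate top-strand base
at window positions 7/6, under the permissive policy**. A single-position
rule was chosen because a single cognate point change at position 166 (the
G166A reprogramming, which lets the DBL handshake pair donor top 7) is
sufficient to suppress recombination dramatically in vivo; requiring both
positions of an HSG to pair would miss that phenotype.

A consequence worth knowing: if target and donor happen to share bases at
window positions 6–7, even a post-HSB design pairs cognately by coincidence
and the simulation locks. This is faithful — for identical handshake
sequences the pre/post distinction collapses — but it means "post-HSB
always completes" is only true for substrate pairs that differ at those
positions. The fixture generator (below) emulates that biological situation.

## The reaction state machine

Stages: `synapsed → top-cleaved → (locked | hj-intermediate) → hj-resolved →
products`. The numbers are fixed by the chemistry:

* Top strands cut 3′ of window position 9 on both substrates, with
  5′-phosphoserine links S241.4 ↔ target top 10 and S241.2 ↔ donor top 10.
* Bottom strands cut 3′ of 9\*, links S241.3 ↔ target bottom 10\* and
  S241.1 ↔ donor bottom 10\*.
* Junction A window: target top 1–9 + donor top 10–14 over donor bottom
  1\*–9\* + target bottom 10\*–14\*; junction B symmetric.

Because the top crossover (after position 9) and the bottom crossover (after
9\*, i.e. across top 5|6) are staggered by 4 nt, junction duplexes carry a
heteroduplex wherever the parents differ inside the stagger: positions 6–7
for identical cores, extending into 8–9 if the cores differ.
`repair_products()` resolves these to either strand, mirroring host repair.

Two hedged observations are modelled as deterministic simulator steps and
recorded as notes in the trajectory rather than as alternatives: the partial
religation seen in the first post-exchange state is collapsed into a single
`hj-intermediate` stage (no occupancy fractions), and bottom-strand exchange
plus final ligation — whose catalyst is unresolved — always completes.
Protomer and active-site labels are symbolic bookkeeping only; no structural
coordinates, kinetics or yields are modelled. Bottom-strand target–donor
pairs at positions 3\*–5\* are functionally neutral and are ignored.

Synapsis asymmetry is enforced at assembly: two TBL halves cannot form a
complex (no DBL stem loop to make the licensing RuvC contact), so
target–target recombination is refused with a `SynapsisError`, while
donor–donor assemblies (two DBL-SLs) proceed.

Full-molecule splicing is topology-aware: linear × circular inserts the
donor circle; linear × linear gives the two reciprocal linears;
circular × circular fuses; two sites on one molecule excise (direct repeats)
or invert (inverted orientation). For inversion the printed registers only
cover the two-molecule reaction, so we place the inverted segment between
the top-strand crossover of the plus-strand site and the corresponding
register of the minus-strand site, keeping the 4-nt bottom stagger at both
junctions; this is the package's convention, not a published register.

## The signed covariation score

The published analysis pipeline couples an external pseudo-likelihood tool
(CCMpred) to a concordance sign. The pipeline's *own contribution* — the
signed, normalized scale on \[−1, +1\] — is implemented exactly; for the raw
covariation statistic we use mutual information with the average-product
correction (APC), floored at zero, a standard internal stand-in for coupling
scores that needs no external binary. Normalization is by the matrix maximum
(the normalization method is not stated in the source analysis; min–max is
the choice that makes the printed bounds ±1 attainable, and the function is
pluggable). Concordance is computed from the top strand only: for DNA
column *i* and bRNA column *j*, `f_bottom` is the fraction of records whose
bRNA base is the transliteration of the top-strand base (the signature of a
guide pairing the bottom strand), `f_top` the fraction whose bRNA base is
its RNA complement, and the sign is `sign(f_bottom − f_top)` (0 at balance).
A perfectly covarying, perfectly concordant planted pair therefore scores
exactly +1 (bottom mode) or −1 (top mode), which is what the acceptance
script recomputes.

## The synthetic-data generator

`generate_fixtures()` defines the study conditions for all property suites:
WT-complementary 14-bp window pairs with CT cores planted at 8–9 and all
other positions uniform random, plus a 177-nt scaffold placeholder with the
conserved bases planted (the wild-type base identities outside the
programmable and conserved sets are not printed in the main text, so the
placeholder is explicitly synthetic). Donor positions 6–7 are resampled
until the post-HSB handshake carries no coincidental cognate pairing — the
generator emulates genuine target/donor site pairs, which differ at the
handshake positions; without this condition roughly one random pair in six
would lock for reasons unrelated to design correctness (see the lock-rule
section). `simulate_alignment()` generates paired alignments with planted
covarying columns at a chosen error rate.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: phylogenetic correlation between alignment records
(records are i.i.d.), realistic base composition, indels/gaps, flanking
genomic context effects, and any notion of recombination efficiency.

## Problem sizes and numerical choices

The property suites run 1000 random window pairs for the splice-oracle and
lock-agreement checks, 100 seeded replicates at 20 % planted noise
(n = 200 records, 14 × 30 columns) for covariation sign recovery, and
50 full-molecule runs with random flanks for conservation; these sizes make
every stochastic claim a regression-tested threshold while keeping the suite
around a minute of runtime. All randomness is seeded; ambiguity codes are
rejected rather than expanded; T inputs to RNA loaders are converted to U
with a logged message; serialized region maps are canonical JSON so they
round-trip byte-identically.

## A worked example

```{r example, eval = FALSE}
sc <- load_scaffold(random_scaffold(seed = 1))
tw <- make_window("ACGTACGCTGACTA", role = "target")
dw <- make_window("TTCAGATCTTGATT", role = "donor")
d <- design_bridge_rna(sc, tw, dw, design_options(rtg_extension = TRUE))
substr(d$brna$sequence, 50, 58)   # LTG "ACGUACGCU"
d$report$lock                     # FALSE

p <- recombine_windows(d$brna, tw, dw)
p$junctions$junction_a$top        # "ACGTACGCTTGATT"
p$junctions$heteroduplex_a        # 6 7
```

## Known limitations

* No efficiency or kinetics: core preference is ordinal (C ≥ G > A ≈ T at
  position 8) and the lock flag is categorical; no numeric weights are
  invented.
* Off-target/genome-wide specificity scoring is out of scope
  (`scan_cores()` ranks candidate windows on one molecule only).
* The excision step that *forms* the circular donor from a genomic element,
  and bRNA homologue search in new elements, are not modelled.
* The wild-type scaffold's full sequence is not shipped; users supply their
  own (any 177-nt scaffold, or an orthologue with a matching region map).
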