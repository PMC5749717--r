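---
title: "Methods: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mobius)
```

This vignette is the package's own account of the science it implements:
the digestion–ligation model and its assumptions, the routing standard,
the planner's rules, the domestication statistics, and every place where
the design was genuinely open and a choice had to be made. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. Sequence model and cut arithmetic

A `dna_molecule` is the top strand 5′→3′ over a strict A/C/G/T alphabet
with `linear` or `circular` topology. Coordinates are **0-based,
half-open, on the top strand**; circular arithmetic is modulo length
with the origin between positions `len-1` and `0`. This makes junction
bookkeeping unambiguous: a cut "at `c`" always means between positions
`c-1` and `c`. Degenerate IUPAC codes are rejected rather than expanded
— the toolkit never needs them, and rejection surfaces input errors at
parse time.

A Type IIS enzyme is `(recognition, spacer, overhang_len)`. For a
top-strand (`+`) recognition at position `p`,

```
cut_top    = p + |recognition| + spacer
cut_bottom = cut_top + overhang_len
```

and mirrored arithmetic on `-` (`cut_top = p - spacer - overhang_len`,
where `p` is the 0-based start of the recognition's top-strand
footprint). The built-ins are AarI = CACCTGC(4/8) and BsaI =
GGTCTC(1/5); AarI's geometry is as published for the framework, while
BsaI's (1/5) is the fixed constant of the modular-cloning literature
(the framework's description does not restate it). Both leave 4-nt 5′
extensions.

**Overhang token convention.** Every sticky end is recorded as the
*top-strand 4-mer spanning the cut* (`[cut_top, cut_top + 4)`). This
collapses the top/bottom 5′-extension asymmetry into a single comparable
token: two ends are ligation-compatible *iff* their tokens are equal,
which turns ligation into label matching on a directed multigraph. A
fragment `core` includes both terminal tokens, so for a circular parent
with `k` cuts, `sum(nchar(core) - 4) == parent length` — an invariant
the tests assert on random constructs. When a fragment is flipped, its
new left token is the reverse complement of its old right token.

`carries_sites` counts recognitions intact within the *double-stranded*
region of a fragment (the terminal 4-nt single-stranded extensions are
excluded, since the enzyme cannot bind there). A recognition destroyed
by a cut through it is therefore not reported for the fragments — which
is exactly what makes the mUAV's overlapping-site junctions work
(section 5).

## 2. One-pot reaction model

`simulate_one_pot()` digests the acceptor and all inserts, then
enumerates circular products: nodes are overhang tokens, directed edges
are fragments (both orientations of every fragment; the acceptor's
backbone fragment — identified by its `resistance` feature annotation,
not by size, which is robust on synthetic fixtures — is fixed in
forward orientation to canonicalise rotations/reflections). A product
is a simple cycle using each physical fragment at most once, containing
the backbone exactly once, capped at `max_cycle_len = 12` fragments:
concatemers and tandem repeats are outside the product model, matching
the minimal circular products that colony screening selects.

A product is **valid** iff the closed circle contains zero intact
recognition sites of the reaction enzyme on either strand. This single
rule reproduces negative screening: the dropout fragment keeps its
recognitions, so backbone+dropout re-ligation closes a circle but never
validates. The simulator demands a *unique* valid product; multiple
distinct valid products are reported as `overhang_clash` when duplicate
junction labels are present (the injected-fault case) and
`multiple_valid_products` otherwise, rather than silently picking one —
mirroring the physics, where both species would transform. Palindromic
(self-complementary) 4-mers are accepted with a fidelity warning, not
an error: the standard uses none, and the source framework is silent on
them.

Not modelled, deliberately: ligase/buffer kinetics, thermocycling,
overhang-fidelity mismatch rates, transformation/colony statistics, and
homologous recombination between similar cargo (a rare failure mode
noted for the wet-lab system; products here are sequence-exact).

## 3. The routing standard as data

The standard lives in `mobius_standard()` and is exportable as one YAML
document, so an alternative overhang standard is a config file, not a
code change. The fixed constants: mUAV fusion sites CTCT/TGAG; Level 1
inner overhangs GGAG/CGCT (BsaI acceptance) for all four vectors; Level
2 inner GGAG/ACCC (AarI acceptance); linker upstream CGCT (End-to-End)
or CAGA/GTCA/CTTG (Middle-to-End 1/2/3), payload CAGA/GTCA/CTTG/CGCT
(4A/4B/4Γ/4Δ) or CGCT (all Middle-to-End), downstream ACCC for all
seven; 50-bp linkers; markers amilCP/spisPink/sfGFP; chloramphenicol
(pSB1C3) for mUAV/Level 2 and kanamycin (pSB1K3) for Level 1.

Two points were genuinely open:

* **Per-vector outer overhangs.** The Level 1 outer table
  A→(GGAG,CAGA), B→(CAGA,GTCA), Γ→(GTCA,CTTG), Δ→(CTTG,CGCT) and the
  Level 2 outer 5′ column (GGAG/CAGA/GTCA/CTTG) are not printed as an
  explicit table anywhere; they are fixed here as the unique assignment
  consistent with every quoted linker overhang, with each vector having
  a unique 3′ overhang, and with the published 5-, 7-, 8-, 12- and
  16-TU routes. The consistency check is executable: the simulator
  reproduces all of those builds with a unique valid product
  (`test-acceptance.R`, criterion 5).
* **"Level 2 vectors have the same 5′ overhangs as Level 1 vectors"**
  can be read as inner or outer 5′. The model satisfies both readings
  simultaneously (inner 5′ is GGAG everywhere; outer 5′ columns of the
  two levels are identical), so nothing hangs on the ambiguity.

Internal part junctions (promoter↔CDS at AATG, CDS↔terminator at GCTT)
ship as a configurable table defaulting to the MoClo/Phytobrick
convention, because the standard only fixes the TU boundaries
GGAG…CGCT and declares compatibility with those kits by construction.
Greek vector names are ASCII-aliased (G, D) in machine interfaces.

## 4. The planner

`plan_assembly(n)` is deterministic and greedy: TUs are packed
left-to-right into chunks of four with one trailing remainder (7 =
4+3, never 3+4 — matching the published route), chunk *j* goes to the
Level 2 vector at position `((j-1) mod 4)+1`, and linkers follow one
rule: size `k < 4` → Middle-to-End `Mk`; size 4 and last in its Level 1
fusion group → 4Δ; otherwise the End-to-End linker of the chunk's
position. The "terminal full chunk takes 4Δ" default is a choice, not a
quoted rule (the published 4-TU operon build leaves its linker
unstated): 4Δ's CGCT payload keeps every finished construct re-clonable
back into Level 1, which is what "continuing assembly" requires, so
plans never paint themselves into a corner. `extend_plan()` exploits
exactly that: the existing construct re-enters as item 1 of a new round
(with one Level 1 fusion step first if it currently sits in a Level 2
vector).

Step-counting convention: plans *include* the round-1 Level 1 reactions
that build each TU from its parts. This keeps `plan(1)` meaningful (a
single Level 1 product), makes `simulate_plan()` honest end-to-end from
Level 0 plasmids, and leaves the published reaction counts recoverable
as the steps with `round > 1` (e.g. 64 TUs: 16 Level 2 + 4 Level 1 + 1
Level 2 = 21 reactions after TU construction). Single-chunk plans
(n ≤ 4) stop at the Level 2 product, as in the published 4-TU operon
build; `rounds` then satisfies `ceiling(log4(n)) + 1` for n > 1, in
line with the capacity law `capacity(t) = 4^(t-1)`.

## 5. The synthetic toolkit: what it emulates, what it does not

`build_toolkit()` generates all 16 vectors with the *site architecture*
of the standard; it makes **no claim of sequence identity** to the
deposited plasmids. Markers and resistance genes are length-realistic
labelled stubs (amilCP ≈ 680 nt, spisPink ≈ 690 nt, sfGFP ≈ 710 nt,
CmR ≈ 660 nt, KanR ≈ 816 nt, ori stub 2000 nt); colour phenotype is
metadata. Random stubs are rejection-sampled free of AarI/BsaI (both
strands) and of EcoRI/PstI, so the demarcation sites stay unique; after
assembly each vector's total site counts are verified and the stubs
regenerated on the rare accidental junction-spanning site (bounded
retries). Generation is a pure function of `fixture_config` — same
seed, bit-identical toolkit — and dummy-part generation is
prefix-stable in `n`.

The mUAV junctions use the overlapping-site layout inferred from "AarI
cuts through the BsaI sequence": the left junction reads `GGTCTCT` (AarI
exposes CTCT at its positions 3–6; BsaI, spacer T, exposes the insert's
first 4 nt) and the right reads `TGAGACC` (T + reverse-complement
BsaI; AarI exposes TGAG). It is the unique compact layout consistent
with CTCT/TGAG fusion sites and with BsaI exposing the standard part
overhangs after insert ligation, and it is validated by the end-to-end
oracle (design → amplify → mUAV reaction → BsaI release reproduces
every role's declared overhangs) rather than by sequence comparison.
Level 1/2 outer release sites use plain non-overlapping placements —
overlap is only structurally necessary at the mUAV junctions. Auxiliary
linkers are exactly 50 bp (token-inclusive top-strand span):
`upstream(4) + 15 + payload(4) + 1 + GAGACC + 16 + ACCC(4)`, with the
internal BsaI recognition on the bottom strand so later release keeps
it on the discarded backbone side.

A green fixture test therefore establishes that the *routing logic* —
overhang assignments, site placement, linker selection, marker
exclusion, order preservation — is coherent and executable. It does
not establish anything about the real deposited sequences: restriction
band sizes, construct sizes in kb, expression, or colony counts are all
out of scope.

## 6. Domestication statistics and editing

The burden model is i.i.d. uniform bases (GC = 50%), both strands:
density `2·4^-L` per enzyme, summed over a set. The percent reduction
`100·(1 − density(new)/density(ref))` gives 58.33% for {6,7} vs
{6,6,6} and 37.5% vs {6,6}. Whether one counts one strand or both is
immaterial — the factor 2 cancels in the ratio — so the published
figures are reproduced under either reading; the package documents
this rather than guessing. A GC-weighted density is offered
(`site_density(..., gc =)`) for exploration but the headline numbers
use the uniform model, matching the implicit arithmetic of the claims.
Monte-Carlo scanning of 10⁶ bp of random sequence converges to the
closed form within sampling error (criterion 1).

`domesticate_cds()` removes sites with single-codon synonymous edits
under a fix-point loop (re-scan after each edit, bounded by sequence
length, so overlapping sites are safe). Edits must break the targeted
site and create no new forbidden site. Tie-break, for determinism:
third-position-only changes first, then highest codon usage (a bundled
usage table in E. coli K-12 convention — a tie-break, not a biological
claim), then lowest position. Sites spanning only Met/Trp codons are
correctly reported unresolvable. Non-coding parts are scanned and
reported but never auto-edited: there is no stated rule for editing
promoters or terminators, and silent damage there would be invisible.

## 7. Onboarding primers

Tails are `clamp (GG) + CACCTGC + 4-nt spacer + fusion 4-mer (CTCT
forward / reverse-complement of TGAG reverse) + standard overhang +
annealing region`. The 4-nt spacer is forced by AarI's (4/8) geometry —
it places the cut exactly on the fusion 4-mer. Spacer bases default to
AAAA and rotate through a fixed alphabet if the context would create an
unintended site; tails are checked against the first 10 cargo
nucleotides. The melting estimate is a Wallace rule (2·AT + 4·GC) over
an 18–25-nt annealing window — a design aid with honest error bars of
several degrees, not a thermodynamic model; hairpin/dimer screening and
codon optimisation are out of scope. Templates with internal AarI/BsaI
sites are refused with a pointer to `domesticate_cds()`.

## 8. Numerical and degenerate-input choices

* Cut coordinates off a linear end → geometry error (the physical digest
  cannot happen); a circular molecule with zero sites → returned intact,
  flagged `uncut`.
* Product enumeration caps at 12 fragments and 50 discovered cycles —
  both far above any standard reaction (max 6 fragments per product) —
  purely as combinatorial guards.
* Identical products reached by symmetric paths are deduplicated by
  their backbone-anchored sequence before uniqueness is judged.
* All randomness (fixtures, tests, acceptance script) flows through
  explicit seeds; `with_seed()` restores the caller's RNG stream.

## 9. Known limitations

End-point idealisation (every compatible junction ligates; no fidelity
model); no methylation sensitivity, star activity, partial digestion or
nicking; no concatemers; no homologous-recombination artifacts; GenBank
I/O is a small round-tripping dialect, not a full parser; and the
fixtures stand in for — never reproduce — the deposited vectors.
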