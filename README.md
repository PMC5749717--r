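# mobius

In silico Golden Gate cloning with the Mobius Assembly standard: Type IIS
digestion mechanics, one-pot digestion–ligation simulation, hierarchical
multi-transcriptional-unit (TU) planning, restriction-site domestication,
onboarding primer design, and a fully synthetic 16-vector toolkit for
testing — no external sequence downloads required.

## The problem and who this is for

Mobius Assembly is a two-level modular cloning framework for synthetic
biologists building multi-gene constructs. Standard parts (promoters,
coding sequences, terminators) are stored in a universal acceptor (mUAV)
and released by **BsaI** (GGTCTC(1/5)); single TUs are built in one of
four Level 1 acceptor vectors (A, B, Γ, Δ) and released by **AarI**
(CACCTGC(4/8)); up to four TUs fuse in a Level 2 vector with the help of
one of seven Auxiliary Plasmid linkers, and the two levels alternate so
that capacity grows geometrically, `a_n = a_1 r^(n-1)` with `a_1 = 1`,
`r = 4`: 1, 4, 16, 64, … TUs. Because every sticky end is a 4-nt 5′
extension, two fragment ends ligate exactly when their overhang 4-mers
match; a correct product consumes every recognition site of the reaction
enzyme and is therefore irreversible, while dropout-marker re-ligation
retains its sites and stays cuttable (the in silico counterpart of
white-vs-coloured colony screening).

Swapping a second 6-bp cutter for the rare 7-bp cutter AarI also shrinks
the *domestication* burden (internal sites that must be removed from
parts): under an i.i.d. uniform-base model an enzyme set has expected
site density `sum(2 * 4^-L)` per bp, so {6,7} vs three 6-bp cutters is a
58.3% reduction and vs two 6-bp cutters 37.5%.

This package simulates all of it: `digest()` implements the cut
arithmetic, `simulate_one_pot()` enumerates circular ligation products
over the overhang-matching graph and demands a unique valid product,
`plan_assembly(n)` emits the reaction schedule (vectors + linkers) for
any `n`, `simulate_plan()` executes it end-to-end on the synthetic
toolkit, `domesticate_cds()` removes forbidden sites by synonymous
codon edits, and `design_primers()` builds mUAV onboarding tails.

## Worked example: a 7-TU construct

```r
library(mobius)
plan_assembly(7)
```

```
<assembly_plan> 7 TU(s), 10 step(s), 3 round(s)
  [s01] round 1, Level 1, vector L1-A <- tu:1
  ...
  [s08] round 2, Level 2, vector L2-A + linker 4A <- s01, s02, s03, s04
  [s09] round 2, Level 2, vector L2-B + linker M3 <- s05, s06, s07
  [s10] round 3, Level 1, vector L1-A <- s08, s09
```

Round 1 builds each TU from its Level 0 parts; round 2 packs TUs 1–4
into Level 2 vector A with End-to-End linker 4A and TUs 5–7 into vector
B with Middle-to-End linker 3 (M3); round 3 fuses both Level 2 cassettes
in Level 1 vector A — the published 7-TU routing.

```r
tk    <- build_toolkit(fixture_config(seed = 1))
cargo <- build_dummy_tu_parts(fixture_config(seed = 1), 7)
res   <- simulate_plan(plan_assembly(7), tk, cargo)
res
#> <assembly_product> mobius_7TU: 10292 bp circular, 3 fragment(s), valid
payload_order(res)
#> payload_01 ... payload_07          (input order preserved)
nrow(find_sites(res$molecule, "BsaI"))
#> 0                                  (reaction enzyme fully consumed)
burden_reduction(c(6, 7), c(6, 6, 6))
#> 58.33333
```

`valid` means the closed circle carries zero intact sites of the final
reaction's enzyme; the 10,292 bp figure is the synthetic-fixture size
(real deposited vector sizes are out of scope by design).

## Command line

```sh
Rscript inst/cli/mobius.R toolkit --seed 1 --out toolkit/   # 16 GenBank files
Rscript inst/cli/mobius.R plan --n 7 --out plans/           # YAML + bench sheet
Rscript inst/cli/mobius.R simulate --n 7 --out out/         # product GenBank
Rscript inst/cli/mobius.R scan --strict parts.fasta --out scan/
Rscript inst/cli/mobius.R burden
```

## Documentation

See the methods vignette (`vignettes/mobius-methods.Rmd`) for the model,
its assumptions, every tunable default, what the synthetic fixtures do
and do not establish, and known limitations.
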