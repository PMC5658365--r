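---
title: "Forging Bacillus integrative vectors in silico: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forging Bacillus integrative vectors in silico: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sevaforge)
```

This vignette explains the models behind `sevaforge`, the parameters that
matter, and the choices made where the design was genuinely open.  It
states no empirical result that the test suite and `scripts/acceptance.R`
do not themselves compute.

## The duplex model

A `ds_seq` stores the forward strand over the *full extent* of the duplex,
0-based and half-open, together with typed ends.  A 5' overhang at a cut is
represented once in the bases and marked in the `end_spec` of both
neighboring fragments: the downstream fragment's left end carries the
overhang as written on the top strand, the upstream fragment's right end
carries its reverse complement (the protruding bottom strand read 5'->3').
Two ends ligate iff their polarities match and one overhang is the reverse
complement of the other; blunt joins blunt.  Mismatched-overhang ligation
is never allowed — ligase infidelity is out of scope.

Cut geometry is data, not code: each enzyme row carries its recognition
pattern and the two cut offsets from the 3' end of the site
(e.g. BsaI GGTCTC(1/5)); `cut_bottom - cut_top` gives overhang length and
polarity, which also covers within-site cutters such as ApaI (−1/−5, 4 nt
3' overhang) and blunt cutters (EcoRV, −3/−3).  Circular sequences are
scanned doubled and deduplicated modulo length; product identity for
circles is the lexicographically smallest rotation of either strand
(Booth's algorithm), so equality tests are rotation- and strand-invariant.

Two cut windows that overlap (two enzymes cutting within each other's
overhang) make the fragment set ill-defined; `digest()` refuses with an
"ambiguous digestion" error naming the positions rather than picking an
order silently.

## Assembly as enumeration, not kinetics

The one-pot Golden Gate reaction is modelled as *all stable cycles*:
every part is digested, oriented fragments become graph nodes, compatible
end pairs become edges, and every simple cycle up to a size bound (default
6 oriented fragments) is a candidate circular product.  This is
deterministic and matches the screening logic of the wet protocol — the
reaction's selection acts through re-cleavability (correct junctions lose
the recognition site) and plate-level screening, not through concentrations,
so no kinetic parameters are modelled.  Each physical fragment is used at
most once per circle; multimeric concatemers beyond the size bound are not
enumerated (the size bound is configurable when duplicated-part isomers are
of interest).

Products are classified from fragment provenance and surviving feature
annotations: a *final vector* must contain the destination's bla marker and
exactly one each of the up, cargo-resistance and down kept fragments; a
cycle that restores a circular entry part is a *re-ligated entry* (the
destination's case is singled out as *recircularized destination*);
everything else is a by-product.  Stability is re-checked from sequence —
a product is stable iff the assembly enzyme finds no remaining site — so
the "correct junctions lose the site" property is verified, never assumed.
Color prediction keys on intact reporter features (mRFP1 red, mkate2 light
red, lacZ-alpha variants blue on X-Gal, otherwise white); it deliberately
uses labels, not sequence, because the fixtures use sentinel genes.

BtgZI is kept in the registry and accepted by the engine, but it is never
auto-selected and draws a warning: one-pot assembly with it is not part of
the validated default set.

## The MCS-IIS synthesizer

`design_mcs_iis()` places one unit of
`recognition + spacer(cut offset) + overhang` per enzyme, left to right,
then verifies its own output with `find_sites()`: each enzyme must have
exactly one site whose excised window equals the requested overhang, and no
extra occurrences on either strand.  Spacer bases come from a fixed pool
read at a variant-dependent offset; if a unit junction happens to spell a
recognition site, the next of up to 32 variants is tried.  The same
machinery generates primer tails (4 nt pad + recognition + spacer +
overhang before the annealing region, 16 pad variants), and every designed
primer pair is verified by simulated PCR plus digestion before it is
returned — the released fragment must be exactly
`overhang + arm + overhang`.

Because each enzyme's unit carries its own copy of the fusion window, the
scar left in the assembled vector differs slightly by enzyme, while the
junction overhang itself is identical — which is the published contract of
the polylinker.  The registry's eight polylinker entries (B1/B2 ... F2) are
this synthesizer's output: ids ending in 2 are forward (recognitions
upstream of the window, part downstream), ids ending in 1 the mirror image.

## Parameters with units and defaults

| parameter | default | why |
|---|---|---|
| homology arm length | 400 bp | recommended working length; shorter arms cost integration efficiency |
| arm hard floor | 70 bp | below this the design is rejected, not warned |
| enzyme priority | BsaI > BbsI > BsmBI > AarI | the first three are the high-efficiency set; AarI last (lower activity, but rarest site: 7 bp recognition) |
| assembly size bound | 6 oriented fragments | covers the 4-part assembly plus small isomers |
| Tm model | nearest-neighbor, unified parameters; 0.5 uM primer, 50 mM Na+ | deterministic, bit-for-bit reproducible primer output |
| annealing length | grow from 18 nt until Tm >= 60 °C, cap 30 nt | standard PCR practice |
| linearization enzyme | ApaI | must cut once, in the replication part; cutting between the arm outer boundaries is refused |
| forbidden-site set | AscI, SwaI, MluI | the named boundary/exchange enzymes; configurable data, since the full standard's list lives outside this package |

## Integration semantics

`double_crossover()` requires exact, unique, same-strand matches of both
arms with up preceding down, and replaces the genomic interval between the
matches with the vector's integration part.  Exact matching is a decision,
not a limitation: the recombination mechanism needs identity, and a
diverged strain needs new arms, so fuzzy matching would silently design the
wrong experiment.  Arms found only on the minus strand are handled by
flipping the genome and mirroring the result, which makes the
strand-symmetry property hold by construction.  A circular vector is
refused with a pointer to linearization (single-crossover integration is
not simulated), and re-integration into an already-edited genome is
detected (the region between the arms already equals the integration part)
and rejected — single-copy semantics.  The length invariant
`|edited| = |genome| − deleted + inserted` is asserted on every call.

## What the fixtures emulate — and what they do not

`make_toy_genome()` and `make_entry_set()` produce sequences that are
random except where structure matters: GC fraction 0.43 (Bacillus-like),
annotated loci including a >= 10 kb "prophage" so large deletions are
routine, polylinkers from the synthesizer, a planted unique ApaI site in
the destination ori, and sentinel genes (bla, neo, mRFP1, ...) that are
labelled random sequence, not ORFs.  Recognition sites of the five assembly
enzymes, ApaI and the forbidden set are excluded from random sequence by
deterministic midpoint substitution; spurious sites created at block
junctions are repaired without touching polylinkers, planted sites or
user-supplied arms (for the forbidden set, an unrepairable junction site is
tolerated rather than fatal, since it does not affect the chemistry).  The
entry set self-checks at generation time: it must assemble to exactly one
final vector.

Passing tests on these fixtures shows the *logic* is right — geometry,
enumeration, classification, bookkeeping.  It does not show anything about
biological efficiency: colony counts, assembly yields, transformation rates
and locus-dependent expression are wet-lab outcomes with no computable
counterpart here, and real genomes have repeats that can defeat the
unique-arm requirement, which the simulator surfaces as errors rather than
resolves.

## Numerical and degenerate-input choices

* All coordinates are integers; there is no floating-point state anywhere
  in sequence handling, so results are platform- and locale-independent
  (the Tm model's doubles affect only reported temperatures, and primer
  lengths through a deterministic threshold).
* Zero-length deletion intervals (pure insertion) are supported; a
  zero-site digestion returns the molecule unchanged, flagged uncut; an
  uncut part in an assembly is passed through inert.
* Ties in product ordering are broken by classification, then length, then
  canonical sequence — output order is deterministic.
* Fixture generation rejects infeasible configurations (genome too small
  for the configured loci; site exclusion not converging within bounded
  iterations) instead of looping.
* Scales used by the shipped checks: 200-nt random sequences against the
  exhaustive site-scan oracle; 3–5-fragment sets against factorial
  assembly enumeration; multi-kilobase genomes for integration surgery,
  plus one 280 kb genome with a 130 kb interval; 16–50 kb genomes for
  full-pipeline round trips.  These sizes exercise every code path
  (including origin wraps and prophage-scale deletions) while keeping the
  whole suite fast.

## Known limitations

* GenBank I/O is a documented dialect: topology in LOCUS, features as
  `misc_feature`/`label`, sticky ends as structured COMMENT lines (the
  format has no native field for them).  Files from other software parse
  only if they use these conventions; FASTA drops end typing with a
  warning.
* The B, E and F junction overhangs and the polylinker base sequences are
  synthetic stand-ins satisfying the published invariants; anyone holding
  the deposited sequences can replace the registry data files without code
  changes.
* Partial digestion, star activity, methylation sensitivity and ligase
  infidelity are not modelled; incubation protocols are metadata only.
* The storage-vector route (blunt cloning into the EcoRV-linearized up/down
  storage vectors) emits tail-less primers and names the vector to use, but
  insert orientation is the user's verification task, as in the bench
  protocol.
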