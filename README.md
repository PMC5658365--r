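# sevaforge

In-silico construction of standardized integrative vectors for *Bacillus
subtilis* and its relatives.

Chromosomal integration in *Bacillus* works by double homologous
recombination (allelic replacement): a vector carrying two homology arms
(*up* and *down*, ~400 bp each) swaps the genomic interval between the arm
matches for the vector's integration part (cargo plus a *Bacillus*
resistance marker).  Building such a vector for a new locus traditionally
means re-cloning both arms.  The toolbox modelled here instead assembles
every final vector freshly from four *entry* parts in a one-pot Golden Gate
reaction: an *up* fragment, a *down* fragment, a *cargo-resistance* vector
and a *destination* vector (the *E. coli* replication part), wired together
by four 4-nt fusion-site overhangs named B, C, E and F.  Each entry part is
flanked by a special polylinker (MCS-IIS) in which five type IIS enzymes
(BsaI, BbsI, BsmBI, AarI, BtgZI) are each positioned to excise the *same*
overhang, so the practitioner can pick whichever enzyme has no site in the
homology arms.  Correctly assembled junctions lose the recognition site and
accumulate as the only stable product; re-ligated entry vectors stay
substrates, and colony color (mRFP1 red / lacZ-alpha blue / mKate2 light
red) reports what a colony carries.  Final vectors follow a SEVA-style
three-digit nomenclature (marker, ori, cargo) plus a *Bacillus* marker
letter and locus suffix.

`sevaforge` implements this entire workflow as deterministic sequence
computation, for people who design such constructs or teach/verify the
logic:

* **Digestion geometry** — type IIS/IIP cut sites with typed sticky ends on
  linear and circular DNA (`find_sites()`, `digest()`, `ligate_fragments()`).
* **One-pot assembly** — enumeration of every circular product from a part
  set (compatibility graph + simple cycles), with classification
  (final vector, recircularized destination, re-ligated entry, by-product),
  stability (re-cleavability) and colony-color prediction (`golden_gate()`).
* **Registry + nomenclature** — the toolbox catalog (24 vectors, 7
  *Bacillus* markers, B/C/E/F fusion sites) and the name codec
  (`lookup_part()`, `decode_name()`, `encode_name()`).
* **Design** — homology-arm extraction, enzyme selection, primer tails with
  a nearest-neighbor Tm model, MCS-IIS synthesis, SEVA compliance checks
  (`extract_arms()`, `select_enzyme()`, `design_primers()`,
  `design_mcs_iis()`, `check_seva_compliance()`).
* **Integration** — ApaI linearization in the replication part and exact
  double-crossover surgery, from 0-bp deletions up to prophage-scale
  (130 kb) excisions (`linearize()`, `double_crossover()`).
* **Fixtures** — a seeded generator for toy genomes and structurally
  correct entry sets, so everything above is testable offline
  (`make_toy_genome()`, `make_entry_set()`).

The junction overhang C = GCGA is the published value; the B, E and F
overhangs shipped in the registry are synthetic placeholders that satisfy
all fusion-site invariants (non-palindromic, pairwise Hamming distance >= 2)
and are flagged `canonical = FALSE`.  Likewise the registry polylinker
sequences are synthesized by `design_mcs_iis()` to the published contract,
not transcribed bases.

## Worked example

Delete a 12 kb "prophage" from a toy genome:

```r
library(sevaforge)

cfg    <- fixture_config(seed = 1)            # 50 kb toy genome, 400 bp arms
genome <- make_toy_genome(cfg)
arms   <- extract_arms(genome, feature = "prophage")

(enz <- select_enzyme(list(arms$up, arms$down)))
#> <enzyme BsaI GGTCTC(1/5) IIS>

design_primers(arms$up, "up", enz)
#> <primer_pair up side, enzyme BsaI>
#>   fwd (30 nt anneal, Tm 56.9 C): ATCTGGTCTCACCATCTGCTACGAGTAATTTATGGATTAAATGCA
#>   rev (29 nt anneal, Tm 60.6 C): CAGCGGTCTCCTCGCCTGCCTAGTGTTACTACGTGTAGAGGTTG

parts    <- make_entry_set(cfg, arms = arms)  # toy cargo + destination vectors
products <- golden_gate(parts, enz)
assembly_summary(products)[1:5, 1:4]
#>    classification length color stable
#> 1    final_vector   1474 white   TRUE
#> 2 other_byproduct    314   red  FALSE
#> 3 other_byproduct    424 white  FALSE
#> 4 other_byproduct    538 white  FALSE
#> 5 other_byproduct    538 white  FALSE

double_crossover(genome, linearize(products[[1]]$sequence))
#> <integration: deleted 12000 bp at [400, 12400), inserted 292 bp>
#> <ds_seq circular, 38292 bp, id=toy_genome_seed1>

suggest_name("pBSd141R", "pBSc241M", "prophage")
#> [1] "pBS141M-prophage"
```

Reading the output: only one product is stable (its junctions lost the
BsaI sites) and it is the final vector; the 314 bp red by-product is the
re-circularized destination stuffer, counter-selected on the plate by its
mRFP1 color.  The genome shrinks by the 12 kb interval and gains the 292 bp
integration part (cargo + marker + junction scars), and the suggested name
encodes ampicillin marker [1], pRO1600/ColE1 ori [4], default MCS [1],
MLS marker [M] and the locus.

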