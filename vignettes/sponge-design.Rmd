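---
title: "Designing circular miRNA sponges with circsponge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing circular miRNA sponges with circsponge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circsponge)
```

## The design problem

A miRNA sponge is a transcript carrying multiple tandem binding sites
(MBS) complementary to a target miRNA. Expressed at high copy number it
competes with the miRNA's natural targets and de-represses them. Two
engineering choices make a sponge effective and durable:

* **Bulged sites.** A perfectly complementary site is sliced by
  AGO2, destroying the sponge. Each MBS therefore pairs the miRNA
  perfectly everywhere *except* a central block of deliberate
  mismatches — the bulge — opposite the miRNA's catalytic centre.
  Bulged sites bind stably but cannot be cleaved.
* **Circularization.** Inserting the sponge cassette between two
  inverted ALU repeats of a circularizing expression vector produces a
  back-spliced, covalently closed circular RNA with no free 5' or 3'
  end, which resists exonucleolytic decay.

`circsponge` implements the design procedure, a sequence-level model of
the back-spliced transcript, and the in-silico validation that a
designed cassette does what it claims: the right number of sites, the
right duplex geometry, no stray restriction sites, no off-target seed
matches.

## The reference design

The package defaults encode the reference miR-21 sponge: 7 MBS, a
bulge mispairing miRNA positions 10–13, 4-nt spacers between
consecutive MBS, an EcoRV recognition site (GATATC) at the 5' end and
SacII (CCGCGG) at the 3' end for directional cloning, with all four
cloning enzymes (EcoRV, SacII, HindIII, EcoRI — the latter two flank
the EGFP reporter in the destination vector) forbidden anywhere inside
the cassette.

```{r}
m21 <- mir21()
params <- design_params()
sc <- assemble_insert(m21, params)
summary(sc)
pair_duplex(m21, build_mbs(m21, params))
```

The insert length obeys the closed form
$|f_5| + n\,L + (n-1)\,s + |f_3|$ — for the defaults
$6 + 7\times22 + 6\times4 + 6 = 190$ bp.

## Parameters and the choices behind them

**Bulge coordinates are miRNA positions.** The bulge exists to block
the AGO2 catalytic centre, which is positioned relative to the *guide*,
so the window is declared in miRNA coordinates. For a 22-nt miRNA, MBS
positions 10–13 oppose miRNA positions 10–13 under antiparallel pairing
($23-p$), so the two readings coincide for miR-21; for other lengths
the miRNA-coordinate reading is the biologically meaningful one. The
literature variously centres the bulge on positions 9–12 or 10–13; the
window is an explicit parameter (`bulge_window`) rather than a constant.
The validator refuses windows overlapping the seed (positions 2–8):
seed pairing is what recruits the miRNA in the first place.

**Bulge base choice: the identity policy.** The source procedure states
the bulge's position and width but not which mismatching bases were
synthesized. The default `identity` policy places the miRNA's own base
opposite itself (A:A, C:C, G:G, U:U). This is the only uniform rule
that excludes both Watson–Crick *and* G:U wobble pairing for all four
bases, and it needs no RNG, so a design is a pure function of its
parameters. `seeded_random` instead draws uniformly from the
non-pairing bases (two to three options per position) under the design
seed, for when sequence diversity across bulges matters (e.g. synthesis
constraints).

**Spacers: length fixed, composition searched.** Only the spacer length
(4 nt) is prescribed; composition is free. Arbitrary spacers can
accidentally create an extra seed match (changing the site count) or a
forbidden restriction site (breaking cloning). `make_spacer` therefore
rejection-samples random 4-mers and keeps the first that, in its
MBS–spacer–MBS context, creates neither — checked with the package's
own scanners over the joined window. The search is driven by the design
seed (one seed, full reproducibility; per-gap seeds are derived from it)
and aborts with advice after a bounded number of attempts. Spacers are
placed strictly *between* MBS ($n-1$ of them), not outside the
outermost sites.

**G:U wobble counts as non-pairing.** For site classification and for
bulge construction, a wobble is treated as a mismatch. This is the
conservative convention: a bulge base that wobble-pairs would partially
restore helical geometry, and a seed "match" through wobble is a much
weaker site. The duplex report still distinguishes wobble (`o`) from
true mismatch (`.`) and weights it 0.5 in its default score
($n_{WC} + 0.5\,n_{wobble} - n_{mismatch}$); the weights are arguments,
the score is descriptive, not thermodynamic.

**Seed-site taxonomy.** Off-target checks need a principled notion of
"site", so the scanner implements the canonical classes: 6mer (pairs
miRNA 2–7), 7mer-m8 (2–8), 7mer-A1 (2–7 plus A opposite position 1),
8mer (both). Each seed-core occurrence is reported once at its best
class; overlapping hits are all reported, deduplication is the
caller's concern. Decoy validation counts only the strong classes
(7mer and up).

## The circular model

Back-splicing is modelled at the sequence level only: the circularized
region is exactly the insert between the ALU arms, with the EcoRV/SacII
bases retained inside the circle (whether the synthesized circle
retains them is not documented; retaining them is the conservative
model, and the junction window makes the assumption explicit and
checkable). ALU arms, promoter and the EGFP reporter — which sits
outside the ALU pair and reports transfection, not circle content —
are not sequence-modelled. Splicing thermodynamics and ALU pairing
efficiency are out of scope.

The canonical rotation of a transcript starts at the first base of the
5' flank, so circular coordinates match insert coordinates. Circular
scanning uses the doubled-sequence technique (hits whose start lies in
the first copy), and circular equality canonicalizes via the
lexicographically minimal rotation — both choices are deterministic and
easy to verify against brute-force rotation oracles, which the test
suite does. `junction_window(tx, w)` returns the last $w$ plus first
$w$ bases, the region a junction-spanning RT-PCR assay would target:

```{r}
tx <- backsplice(sc)
junction_window(tx, 6)
```

## Validation and decoy panels

`validate_construct` re-derives every design guarantee from the
assembled sequence alone: exact site count by scanning, per-MBS duplex
geometry (perfect seed, bulge-width mismatches inside the window), no
internal forbidden restriction sites (the two terminal flank copies
exempted), feature-table tiling, and zero strong seed matches for a
decoy miRNA panel. Failures are report rows, not exceptions, so a
report can be serialized (TSV/JSON) and acted on.

Decoy panels are synthetic miRNAs drawn uniformly (length 20–24 nt, GC
30–70%, seeded) with two rejection rules: a decoy may not share the
target's 6mer seed, and — when a `screen` sequence is supplied — may
not have any seed match on it. The screen matters: a random 7mer
complement occurs in a 190-nt cassette with roughly 2% probability per
decoy, so unscreened random panels occasionally "fail" a perfectly good
design by chance. A screened panel tests the machinery
deterministically; it does not, and cannot, certify the design against
the real transcriptome — that would require transcriptome-wide scanning,
which is out of scope.

Synthetic random miRNAs emulate composition only; they have none of the
structure of real miRNA families (shared seeds, conserved 3'
complementarity). Passing the random-panel check therefore shows the
scanner and validator work as specified, not that a design is clean
against any particular species' miRNA complement. For a real project,
supply a miRBase panel FASTA.

One further caveat surfaced by property testing: some targets
*inherently* embed a forbidden recognition sequence inside their own
binding sites (the MBS is the target's complement, so the designer has
no freedom there). The validator flags such designs rather than
silently altering them; choosing different cloning enzymes is the
correct fix.

## Degenerate inputs and numerical conventions

Internal coordinates are 0-based half-open; all rendered output
(GenBank, reports) is 1-based inclusive. A width-0 bulge
(`bulge_window = NULL`) yields perfectly complementary sites — useful
as a control and for the cleavable-sponge comparison. `spacer_len = 0`
is legal and yields an empty spacer (linear sequences may be empty for
exactly this reason; circular ones may not). Ambiguity codes are
rejected outright: the procedure is undefined for ambiguous bases.
Lowercase input is upper-cased. Duplicate FASTA ids are an error, not a
warning, because downstream feature tables key on ids.

## Problem sizes in the test suite

The property suites run at sizes chosen to exercise every code path
while keeping the suite quick to iterate: involution and rotation
oracles on random sequences up to 80 nt (equality oracle to 64 nt),
scanner-vs-brute-force equivalence on sequences up to 300 nt with
planted sites, rotation invariance over all rotations of a 60-nt
two-site circle, the assembly length closed form over 100 random
miRNAs of 15–30 nt, and validator success over 50 seeded random
designs. The full suite completes in well under a minute.

## Known limitations

* No thermodynamics: no folding, no binding free energies, no
  context-style site scoring. Site calls are purely combinatorial.
* The duplex model is gap-free; true bulge loop structure is not
  modelled (the design geometry keeps miRNA and site the same length,
  so nothing is lost for designed constructs).
* Byte-identity with any particular synthesized construct is
  unverifiable where the source procedure leaves composition open
  (spacer sequences, bulge bases); what the package guarantees is that
  every emitted design satisfies the stated constraints, verifiable by
  `validate_construct` on the sequence alone.
* The back-splice model assumes circularization succeeds; it does not
  predict circularization efficiency.
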