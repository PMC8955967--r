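# circsponge

Design and in-silico validation of **circular miRNA sponges**: RNA
decoys that sequester an overexpressed microRNA (the worked example
throughout is hsa-miR-21-5p, a driver of proliferation and migration in
non-small-cell lung cancer) by presenting many tandem binding sites on
a covalently closed circular transcript.

The package is for molecular biologists building sponge constructs and
for computational people auditing them. It covers the whole design
surface:

* **Bulged binding sites.** Each miRNA binding site (MBS) is the
  reverse complement of the target with a central bulge — a contiguous
  block of deliberate mismatches opposite miRNA positions 10–13 (the
  AGO2 catalytic centre) — so the sponge binds stably but cannot be
  sliced. Default geometry: 7 MBS, 4-mismatch bulge, 4-nt spacers
  between sites.
* **Cloning-ready cassette.** The insert is emitted as
  `EcoRV – (MBS + spacer)… – SacII` DNA for directional cloning between
  the ALU arms of a circularizing expression vector, with all cloning
  enzymes (EcoRV, SacII, HindIII, EcoRI) guaranteed absent from the
  interior. Insert length obeys
  `|f5| + n·L + (n−1)·s + |f3|` (= 190 bp for the default miR-21
  design).
* **Back-splice model.** `backsplice()` derives the circular
  transcript; scanners are junction-aware (doubled-sequence technique)
  and `junction_window()` extracts the circle-specific junction
  sequence that RT-PCR assays target.
* **Scanners and reports.** Canonical seed-site classes (6mer,
  7mer-A1, 7mer-m8, 8mer), full perfect/bulged site detection,
  restriction-site scanning, and positional duplex reports with
  WC / G:U-wobble / mismatch calls (`score = n_WC + 0.5·n_wobble −
  n_mismatch`).
* **Validation.** `validate_construct()` re-derives every guarantee
  from the sequence alone: site count, per-MBS duplex geometry,
  restriction cleanliness, feature tiling, and zero strong seed matches
  for a (seeded, reproducible) decoy miRNA panel.
* **Assay formulas.** The closed forms used alongside sponge
  experiments: 2^−ΔΔCt relative expression, spheroid volume
  `V = a·b²·π/6`, relative volume and percent inhibition.

IO is standard: miRBase-style FASTA in, FASTA/GenBank (with full
feature annotation and a design-parameter metadata snapshot) and
TSV/JSON reports out.

## Worked example

```r
library(circsponge)

m21 <- mir21()                  # hsa-miR-21-5p, UAGCUUAUCAGACUGAUGUUGA
params <- design_params()       # 7 MBS, bulge 10-13, 4-nt spacers
sc <- assemble_insert(m21, params)
summary(sc)
#> Sponge insert for hsa-miR-21-5p
#>   length: 190 bp; 7 MBS of 22 nt; 6 spacers of 4 nt
#>   bulge (miRNA positions): 10-13; flanks EcoRV/SacII; seed 1

pair_duplex(m21, build_mbs(m21, params))
#> hsa-miR-21-5p duplex: 18 WC, 0 wobble, 4 mismatch (score 14)
#>   miRNA 3'-AGUUGUAGUCAGACUAUUCGAU-5'
#>            |||||||||....|||||||||
#>   site  5'-UCAACAUCACAGAGAUAAGCUA-3'

tx <- backsplice(sc)
junction_window(tx, 6)          # the circle-specific junction sequence
#> <nt_seq RNA linear, 12 nt>
#> CCGCGGGAUAUC

validate_construct(sc, m21, generate_decoy_panel(m21, 20, 42,
                                                 screen = tx$seq))
#> <validation_report for hsa-miR-21-5p: PASS>
#>   [ok  ] site_count       7 full sites found, 7 expected
#>   [ok  ] mbs_duplex       7 MBS with perfect seed pairing and 4 bulge mismatches
#>   [ok  ] restriction      no internal forbidden sites
#>   [ok  ] decoy_offtargets no strong seed match for 20 decoy(s)
#>   [ok  ] tiling           features tile the insert exactly
```

Reading the duplex report: the site pairs the miRNA perfectly over the
seed (positions 2–8, right-hand block) and everywhere else except the
four bulge positions 10–13 (`....`), where the identity policy places
the miRNA's own base opposite itself — a choice that can neither
Watson–Crick- nor wobble-pair, for any base. The junction window
`CCGCGG|GAUAUC` is the SacII flank joined back onto the EcoRV flank:
it exists only on the circle, which is how junction-spanning RT-PCR
distinguishes circular from linear sponge.

The assay helpers are one-liners:

```r
relative_expression(25, 20, 24, 21)   # 2^-ddCt  -> 0.25
spheroid_volume(1.2, 0.9)             # a*b^2*pi/6 -> 0.5089 mm^3
percent_inhibition(0.532, 1)          # -> 46.8 %
```

## Command line

A thin wrapper over the same functions is installed at
`system.file("scripts", "circsponge", package = "circsponge")`:

```sh
circsponge design --seq UAGCUUAUCAGACUGAUGUUGA --id hsa-miR-21-5p \
           --seed 1 --decoys 20 --out-prefix m21
circsponge scan --fasta m21.fasta --mirna panel.fasta --out hits.tsv
circsponge validate --construct m21.gb --seq UAGCUUAUCAGACUGAUGUUGA
circsponge circ --construct m21.gb --window 6
circsponge metrics --table ct.tsv --kind qpcr
```

`design` writes GenBank + FASTA + validation TSV/JSON; `validate`
exits 0/2 for pass/fail; everything logs to stderr and keeps data on
stdout or in files. Parameters can come from a YAML config
(`--config`), with flags taking precedence.

## Package layout

`R/seq_core.R` sequences, alphabets, miRNAs · `R/sponge_design.R`
MBS/spacer/insert construction and validation · `R/circular_model.R`
back-splicing, rotation, junction views · `R/site_scanner.R` seed,
full-site and restriction scanning · `R/duplex_report.R` positional
pairing reports · `R/assay_metrics.R` closed-form assay formulas ·
`R/construct_io.R` GenBank/FASTA IO · `R/fixtures.R` seeded synthetic
miRNA/decoy generators · `R/cli.R` the command line. The methods
vignette (`vignettes/sponge-design.Rmd`) explains the design decisions
and their rationale.
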