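# mirrorCode

Detection of CARC/CRAC cholesterol-recognition motifs in transmembrane
domains, with leaflet assignment from membrane topology.

## What it does and for whom

Cholesterol binds many membrane receptors through short linear motifs on
their transmembrane (TM) helices:

* **CRAC**: `(L/V) - X(1-5) - (Y/F) - X(1-5) - (K/R)`
* **CARC** (the mirror consensus): `(K/R) - X(1-5) - (F/Y/W) - X(1-5) - (L/V)`

both read N- to C-terminal, with 1-5 unconstrained spacer residues between
the three anchors (basic / central aromatic / branched aliphatic). The
motifs are *vectorial*: the basic anchor snorkels to the aqueous interface,
so on an oriented TM helix the motif's position decides which membrane
leaflet its cholesterol occupies. A helix carrying a CARC in one leaflet
*and* a CRAC in the other — the **mirror code** — can bind two tail-to-tail
cholesterol molecules simultaneously.

`mirrorCode` is for membrane-protein scientists who want to survey
candidate cholesterol-binding sites from sequence + TM annotation alone.
It enumerates all overlapping motifs, extends annotated TM boundaries to
interfacial Lys/Arg residues, selects the largest motif of each overlap
cluster, assigns leaflets, and classifies each TM domain as
`dual_mirror`, `carc_only`, `crac_only` or `none`. It also ships a
synthetic-protein generator with planted motifs (exact ground truth for
validation), shuffle-based null frequencies, and two desk-scale wet-lab
utilities: critical-insertion-pressure extrapolation from Langmuir
monolayer isotherms and deuterium quadrupolar splittings under motional
averaging.

## Worked example

The cannabinoid receptor CB1 with its seven annotated TM helices
(reference fixture shipped with the package):

```r
library(mirrorCode)
ext <- system.file("extdata", package = "mirrorCode")
cb1 <- readProteins(file.path(ext, "CB1_P21554_synthetic.fasta"),
                    file.path(ext, "CB1_P21554_tm.tsv"))[[1]]
scanProtein(cb1)
#> ScanReport: CB1_P21554_synthetic
#>   7 TM domain(s): 2 dual-mirror, 1 CARC-only, 1 CRAC-only, 3 without motif
#>   motifs:
#>     TM3  CARC 186-196 (basic/aromatic/aliphatic at 186/191/196) leaflet=outer
#>     TM3  CRAC 204-214 (basic/aromatic/aliphatic at 214/208/204) leaflet=inner
#>     TM4  CARC 232-239 (basic/aromatic/aliphatic at 232/237/239) leaflet=inner
#>     TM5  CRAC 288-300 (basic/aromatic/aliphatic at 300/294/288) leaflet=inner
#>     TM7  CARC 376-387 (basic/aromatic/aliphatic at 376/381/387) leaflet=outer
#>     TM7  CRAC 392-400 (basic/aromatic/aliphatic at 400/397/392) leaflet=inner
```

Reading: TM3 and TM7 each carry the full mirror duet — a CARC serving the
outer leaflet and a CRAC serving the inner one — so each could bind two
tail-to-tail cholesterol molecules. TM4 has a lone CARC and TM5 a lone
CRAC (both inner leaflet); TM1, TM2 and TM6 have no motif. Note TM3: the
annotated helix is 188-212, but the scanner extends it to the flanking
arginines (186-214), without which both motifs would be missed.

Single peptides work directly, preserving native numbering:

```r
scanPeptide("RVCFLAML", offset = 455, kind = "CARC")
#>   kind start end pos_basic pos_aromatic pos_aliphatic span maximal
#> 1 CARC   455 462       455          458           462    8    TRUE
```

the prototype acetylcholine-receptor gamma-TM4 CARC: Arg-455 / Phe-458 /
Leu-462.

A command-line front end is installed with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("scripts", "mirrorcode.R", package = "mirrorCode"))') \
    scan --fasta proteins.fasta --tm tm.tsv --out results --format tsv
```

with `peptide`, `simulate`, `monolayer` and `quad` subcommands for
peptide queries, synthetic data generation, insertion-isotherm analysis
(`pi_c` as the x-intercept of the pressure-increase line) and
quadrupolar-splitting calculations.

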