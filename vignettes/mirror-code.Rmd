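---
title: "Scanning transmembrane domains for the CARC/CRAC cholesterol mirror code"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning transmembrane domains for the CARC/CRAC cholesterol mirror code}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirrorCode)
```

## The biological problem

Cholesterol modulates many membrane receptors by binding directly to their
transmembrane (TM) helices. Two short linear consensus motifs describe most
of these non-annular binding sites:

* **CRAC** (cholesterol recognition amino acid consensus), read N- to
  C-terminal: `(L/V) - X(1-5) - (Y/F) - X(1-5) - (K/R)`;
* **CARC**, its mirror image: `(K/R) - X(1-5) - (F/Y/W) - X(1-5) - (L/V)`.

Each motif is an *anchor triad* — one basic, one central aromatic, one
branched aliphatic residue — separated by one to five completely
unconstrained spacer residues. The triad chemistry matches cholesterol's
architecture: the aromatic ring stacks against the sterol rings (CH-pi),
the aliphatic side chain packs against the methyl "spikes", and the basic
side chain hydrogen-bonds the 3-beta-OH group at the membrane interface.

Both motifs are **vectorial**. Because the basic anchor must reach the
aqueous phase (Lys/Arg snorkeling) while the aliphatic anchor buries into
the bilayer core, the position of a motif along an oriented TM helix
decides which leaflet its cholesterol occupies. On a helix whose
N-terminal end faces the extracellular milieu, a CARC near that end serves
the **outer** leaflet and a CRAC near the C-terminal end serves the
**inner** leaflet; helices of opposite orientation swap the labels. A TM
helix carrying both motifs, one per leaflet, can bind two tail-to-tail
cholesterol molecules simultaneously — the *mirror* arrangement this
package is named after. `scanProtein()` classifies every annotated TM as
`dual_mirror`, `carc_only`, `crac_only` or `none` accordingly.

## The scanning model, step by step

For each annotated TM segment the pipeline:

1. **Orients** the helix: with an extracellular N-terminus, odd-indexed
   TMs have their N-end facing the outer leaflet and even-indexed TMs the
   inner one (`orientTMs()`); a cytoplasmic N-terminus reverses the
   parity. This covers single-pass type I/II proteins and polytopic
   proteins such as GPCRs alike.
2. **Extends** the annotated boundaries (`extendTM()`): database TM
   annotations routinely exclude the interfacial Lys/Arg residues that
   motifs are anchored on, so the scanner looks up to `window` residues
   beyond each boundary and, if it finds a basic residue, moves the
   boundary to the outermost one. The extension never crosses a
   neighbouring TM segment.
3. **Enumerates** every CARC and CRAC triad inside the extended segment
   (`enumerateMotifs()`), exhaustively and allowing overlaps. Spacers are
   deliberately unconstrained — anchor-class letters and even ambiguity
   codes may sit between anchors; only the three anchor positions are
   class-checked. The cannabinoid receptor TM3 CARC (186-196) has both a
   Phe and a Lys inside its spacers, so any spacer restriction would be
   wrong.
4. **Selects maximal representatives** (`selectMaximal()`): overlapping
   triads of one kind are clustered (shared residues, transitively) and
   the largest span represents each cluster. Ties go to the smallest
   start, then the smallest aromatic position — the published rule only
   says "largest", so the tie-break is our deterministic refinement.
5. **Assigns leaflets** (`assignLeaflet()`): the motif belongs to the
   leaflet of the TM half that contains its *basic* anchor, the residue
   that fixes the motif at one interface. Halves split at the integer
   midpoint `floor((extended_start + extended_end)/2)`; an anchor exactly
   at the midpoint counts as N-terminal half. Using the basic anchor
   rather than the motif midpoint follows the snorkeling logic and is
   robust to very long motifs that straddle the midpoint.
6. **Classifies** the TM (`classifyTM()`): at least one CARC and one CRAC
   in *opposite* leaflets make a `dual_mirror` domain. Both kinds in the
   same leaflet is a geometrically different situation (found, e.g., at
   single endings of ABC-transporter helices); it is classified `none`
   but flagged `distant_pair` so it is never silently conflated with the
   mirror arrangement.

## Tunable parameters and their defaults

| parameter | default | meaning |
|---|---|---|
| `spacerMin`, `spacerMax` | 1, 5 | spacer residues between anchors |
| `aromaticCarc` | F, Y, W | CARC aromatic class |
| `aromaticCrac` | Y, F (`strictCrac`: Y) | CRAC aromatic class |
| `aliphatic` | L, V (`allowIle`: + I) | aliphatic class |
| `window` | 2 | boundary extension distance (residues/side) |
| `maximalOnly` | `TRUE` | report cluster representatives only |

Three defaults deserve justification:

* **CRAC aromatic = \{Y, F\}.** The original CRAC consensus demanded Tyr,
  but cholesterol's CH-pi stacking works equally well with Phe, and the
  cannabinoid CB1 receptor's TM3 CRAC (204-VGSLFLTAIDR-214) contains no
  Tyr at all. Purists can set `strictCrac = TRUE`.
* **Ile off by default.** The consensus as usually written is (L/V), yet
  branched Ile is sterically equivalent and the serotonin 5-HT7 TM7 CRAC
  peptide is anchored on an Ile. With the canonical classes that peptide's
  largest valid CRAC is Leu-anchored (span 12); admitting Ile adds the
  published Ile-anchored triad to the same overlap cluster. Both readings
  are available (`allowIle`), and in all-matches mode neither is
  suppressed.
* **Extension window = 2.** The CB1 worked example extends TM3 from the
  database-annotated 188-212 to 186-214, i.e. by exactly two residues to
  the flanking arginines, and every validation case in this package is
  reproduced at that distance. A wider default is tempting ("charged
  residues lining TM domains are often not annotated") but measurably
  overcalls: at window 5 the CB1 sequence picks up an Arg five residues
  upstream of TM2 and a Lys five residues downstream of TM6, creating
  motifs in two domains that the reference analysis classifies as
  motif-free. The window stays configurable for proteins with deeper
  interfacial basics.

## What the synthetic generator emulates — and what it does not

`syntheticProtein()` builds membrane proteins with known ground truth:
TM segments of 20-26 hydrophobic residues joined by 8-15 residue loops,
with requested motifs written into requested leaflet halves
(`plantSpec()`). The default background alphabet excludes K, R, F, Y and
W, so *no motif can exist that was not planted*: every motif needs a
basic and an aromatic anchor. This makes plant-and-recover tests exact
(the planted triad must be found with its kind, leaflet and all three
anchor positions) and false-positive tests absolute (a plant-free protein
must yield zero motifs). The background legitimately retains Leu/Val/Ile
— motifs do not need them to be absent, and removing them would make the
sequences unrealistically non-hydrophobic.

A TM that carries a plant is built at 26 residues so that any spacer
combination (motif length up to 13) fits entirely within one half; two
plants on one TM must target opposite leaflets for the same reason. A
`"realistic"` background mode draws residues from a hydrophobic TM
frequency table instead; it produces natural-looking sequences but
forfeits the exactness guarantees.

What passing these tests shows: the enumeration, extension, leaflet and
classification machinery is correct on sequences whose truth is known.
What it does not show: that real TM annotations are accurate, that the
consensus motifs imply functional cholesterol binding (an energetic and
structural question outside sequence analysis), or anything about motif
enrichment in real proteomes — `shuffleNull()` provides per-sequence
composition-preserving null frequencies, not proteome statistics.

## Reference fixtures

Offline validation uses two plain-text fixtures under `inst/extdata/`,
both labelled `synthetic` because they are reconstructions rather than
database downloads:

* `CB1_P21554_synthetic.fasta` — a 472-residue reconstruction of the
  human cannabinoid receptor 1. All motif-bearing TM regions are pinned
  to published residue coordinates (CARC 186-196, CRAC 204-214, CARC
  232-239, CRAC ending at Lys-300), and the conserved GPCR landmarks
  (DRY 213-215, CWxP 355-358, NPxxY 393-397) fall at self-consistent
  positions; termini are approximate. The accompanying TM table carries
  the seven annotated helix boundaries.
* `TSPO_TM5_synthetic.fasta` — the translocator-protein TM5
  neighbourhood rebuilt around its published anchors (CARC with Arg-135
  and Tyr-138; CRAC 149-VLNYYVWR-156), embedded in anchor-free filler
  with four dummy TMs to preserve helix parity.

One published TSPO statement cannot be satisfied by the grammar: a CARC
"between residues 135 and 146" would need an aliphatic anchor at 146,
which is a Phe, and the Tyr-138-to-146 spacing exceeds five. The scanner
reports what the grammar yields — the maximal CARC 135-144 — and the
Arg-135 anchor, which is the load-bearing claim. Similarly, the CB1 TM5
CRAC is printed with an impossible start coordinate (591-...-300); the end
(Lys-300) is treated as authoritative, and the scanner's maximal cluster
representative (288-300) strictly contains the printed 291-300 triad,
which remains visible in all-matches mode.

## Monolayer analysis

`estimatePiC()` implements the standard Langmuir-monolayer analysis of
peptide insertion: monolayers are prepared at increasing initial surface
pressures $\pi_0$, the maximal peptide-induced pressure increase
$\Delta\pi_{max}$ is recorded for each, and the **critical insertion
pressure** $\pi_c$ is the x-intercept of the (decreasing) line
$\Delta\pi_{max} = a + b\,\pi_0$, fitted by ordinary least squares. The
linear extrapolation is standard monolayer practice; published analyses
plot the isotherm without stating a fit, so OLS with an analytic
x-intercept ($\pi_c = -a/b$) is pinned here and documented. A slope
$\ge 0$ raises an error (no extrapolable $\pi_c$); two exact points are
accepted (they define the line), three or more are recommended and yield
a residual standard error. $\pi_c$ is scale-equivariant: multiplying all
$\Delta\pi_{max}$ by a positive constant moves $a$ and $b$ together and
leaves the intercept unchanged.

`fitInsertionKinetics()` fits adsorption kinetics to a mono-exponential
approach to saturation, $\Delta\pi(t) = \Delta\pi_{max}(1 - e^{-kt})$,
with initial velocity $v_0 = k\,\Delta\pi_{max}$. The mono-exponential
form is this package's modelling choice (published kinetic curves come
without an equation); when the nonlinear fit fails to converge the
finite-difference slope over the first two points is reported as $v_0$
with a `fallback` flag. Validation is by self-consistency on synthetic
data: noiseless traces recover their parameters to six decimals, and
noisy isotherms at the instrument accuracy of 0.25 mN/m recover $\pi_c$
without bias over 1000 seeded replicates (the experimental values 42.5,
32.5, 28 and 42 mN/m serve only as synthetic scenario parameters; raw
experimental points are not published, so they are not reproduced here).

## Quadrupolar splittings

For a deuterated group each fast motional mode (rotation about an axis at
angle $\beta$ to the C-D tensor) scales the quadrupolar coupling by the
second-order Legendre factor $\tfrac12(3\cos^2\beta - 1)$; independent
fast modes multiply, and mode order is immaterial. The package adopts the
powder-pattern (Pake) horn-splitting convention
$\Delta\nu = \tfrac34\,\chi_{eff}$, stated explicitly because splittings
are often reported without one. With the static methyl coupling
$\chi = 167$ kHz and rapid rotation about the C-CD$_3$ bond at the
tetrahedral angle ($\arccos(1/3) = 70.53^\circ$, scaling factor exactly
$1/3$), the predicted splitting is $\tfrac34 \times 167 / 3 = 41.75$ kHz
— consistent with the ~38 kHz measured on lyophilized TM peptides, the
shortfall reflecting additional librational averaging that is not
quantified here and therefore not modelled. At the magic angle
($54.74^\circ$) the factor vanishes and so does the splitting.

## Numerical and design notes

* Coordinates are 1-based inclusive (UniProt convention) everywhere
  inside the package; BED output converts to 0-based half-open intervals
  at export, and the conversion round-trips losslessly.
* Reports are deterministic: enumeration orders matches by start, then
  aromatic position, then end; writers emit byte-identical files for
  identical inputs.
* Sequence input is uppercased and stripped of gaps; characters outside
  the 20 standard residues can serve as spacers but never as anchors.
* Proteins without TM annotation are not scanned whole-sequence by the
  pipeline (leaflet logic is undefined without topology);
  `scanPeptide()` covers position-only queries explicitly.
* Problem sizes used by the validation suites — 10,000 sampled sequences
  (length <= 15, 10-letter alphabet) for brute-force oracle equivalence,
  200 synthetic proteins for plant-and-recover, 1000 replicates for the
  $\pi_c$ noise study — were chosen to exercise every code path while
  keeping the whole suite interactive.

## Known limitations

* The scanner predicts *candidate* motifs; affinity, occupancy and
  function require structural or biophysical follow-up.
* TM boundaries are taken from the user's annotation and may drift across
  database releases; validation pins the printed boundaries.
* A single residue may legitimately anchor two overlapping motifs of
  different kinds; the scanner allows this and reports both.
* `shuffleNull()` preserves composition only; it is not a significance
  test against any proteome-scale background.
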