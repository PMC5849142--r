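# hsoligo

Analysis tools for structurally defined heparan sulfate (HS) and heparin
oligosaccharides — the compound class produced by chemoenzymatic synthesis
on a UV-detectable aglycone and used as NMR/MS reference standards in
heparin quality control.

HS/heparin chains are linear (1→4)-linked polymers of alternating uronic
acid (β-D-GlcA or its C5 epimer α-L-IdoA, optionally 2-*O*-sulfated) and
α-D-glucosamine residues (*N*-acetyl, *N*-sulfo or free amine; optionally
3-*O*- and/or 6-*O*-sulfated). The package is aimed at people who make,
verify or assign such oligosaccharides:

* **Sequence model.** A plain-text grammar for the field's naming
  convention (`GlcNS6S(1-4)GlcA(1-4)...-pNA-N3`), with validation
  (strict ring alternation, legal sulfation positions), search for the
  antithrombin-binding pentasaccharide motif
  GlcNS6S–GlcA–GlcNS3S6S–IdoA2S–GlcNS6S, and sulfation statistics
  (sulfo groups per disaccharide, %IdoA).
* **Mass spectrometry.** Elemental composition under the neutral
  free-acid convention, average and monoisotopic masses, and
  negative-mode ESI charge-state ladders *m/z = (M − z·m_H)/z*.
* **NMR shift prediction.** The anomeric ¹H/¹³C shift of each residue is
  looked up from a context model keyed on the residue class and its
  *reducing-side* neighbor (the non-reducing neighbor has minimal
  influence), plus the ³J(H1,H2) coupling class — ≈4 Hz for α-anomeric
  protons (glucosamine, iduronate), ≈8 Hz for β (glucuronate).
* **Peak assignment.** Observed anomeric peak lists are assigned to a
  candidate sequence by minimum-cost bipartite matching
  (Σ|ΔδH| + 0.1·|ΔδC| + J-mismatch penalty), exhaustively for ≤ 8
  residues and by a Hungarian solver beyond; candidate structures can be
  ranked against a spectrum for QC.
* **Route planning.** The enzymes of the chemoenzymatic toolbox (pmHS2
  elongation with UDP-GlcNAc/GlcNTFA/GlcA, de-*N*-TFA + NST, the
  reversible C5-epimerase, 2-OST/6-OST/3-OST-1) are encoded with their
  substrate-specificity rules; breadth-first search plans shortest
  routes from the monosaccharide seed acceptor to a target and
  enumerates the reachable library.
* **Simulation.** Noisy anomeric peak lists with Gaussian scatter and
  optional dropout, with ground truth, for validating assignment
  performance.

## Worked example: hexasaccharide 14

Compound **14** is the GlcNS3S6S-containing hexasaccharide used as the
worked characterization example throughout.

```r
library(hsoligo)

cmp14 <- get_fixture("14")$oligo
cmp14
#> <hs_oligo> hexasaccharide, aglycone pNA-N3
#>   GlcNS6S(1-4)GlcA(1-4)GlcNS3S6S(1-4)IdoA2S(1-4)GlcNS6S(1-4)GlcA-pNA-N3
#>   labels: A=GlcNS6S, B=GlcA, C=GlcNS3S6S, D=IdoA2S, E=GlcNS6S, F=GlcA

oligo_mass(cmp14)
#> C48H73N7O56S8  average 1900.6 Da, monoisotopic 1899.1 Da

esi_ladder(average_mass(cmp14), 4:6)
#> Negative-mode ESI ladder [M - zH]^z-
#>   z = 4   m/z = 474.14
#>   z = 5   m/z = 379.11
#>   z = 6   m/z = 315.76

predict_shifts(cmp14)
#> Predicted anomeric shifts (1H/13C, D2O 298 K)
#>  label   residue          context delta_h delta_c             j  note
#>      A   GlcNS6S    GlcA-neighbor    5.52    97.1 ~4 Hz (alpha)
#>      B      GlcA GlcNX6S-neighbor    4.54       -  ~8 Hz (beta)
#>      C GlcNS3S6S    IdoA-neighbor    5.43    96.0 ~4 Hz (alpha)
#>      D    IdoA2S GlcNX6S-neighbor    5.18    99.0 ~4 Hz (alpha) broad
#>      E   GlcNS6S    GlcA-neighbor    5.52    97.1 ~4 Hz (alpha)
#>      F      GlcA     aglycone-pNA    5.07       -  ~8 Hz (beta)
```

The computed average mass (1900.6 Da) identifies the intact compound in
negative-mode ESI-MS at charge states 4–6. The six predicted anomeric
signals confirm a hexasaccharide; the three α-glucosamine protons sit in
the 5.4–5.6 ppm window, the downfield 5.43 ppm signal is diagnostic of
the 3-*O*-sulfated residue C, the broad 5.18 ppm signal is the IdoA2S
(ring-conformer exchange), and 5.07 ppm is the reducing-end GlcA
deshielded by the aromatic aglycone. Assigning the two printed β-proton
signals:

```r
assign_peaks(cmp14, hs_peaklist(c(4.56, 5.07)), mode = "partial")
#> Peak assignment (partial mode), total cost 0.0200
#>  label   residue peak ppm_h pred_h    d_h flag
#>      A   GlcNS6S   NA     -   5.52      -
#>      B      GlcA    1  4.56   4.54 +0.020
#>      ...
#>      F      GlcA    2  5.07   5.07 +0.000
```

and planning the synthesis from the pentasaccharide intermediate VI:

```r
plan_route(get_fixture("VI")$oligo, cmp14)$steps$action
#> [1] "pmHS2+GlcNTFA" "deTFA+NST" "6-OST" "3-OST-1"
```

A thin command-line wrapper is installed at
`system.file("cli", "hsoligo.R", package = "hsoligo")`, e.g.
`Rscript hsoligo.R mass --seq "GlcA-pNA-N3"`.

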