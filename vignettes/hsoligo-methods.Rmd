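---
title: "Models and methods behind hsoligo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hsoligo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsoligo)
```

This vignette explains the models, rules and numerical choices the
package implements, what its synthetic data do and do not emulate, and
the design decisions taken where more than one reading was defensible.

## The sequence model

Heparan sulfate and heparin chains are strict alternations of uronic
acid and glucosamine rings joined by (1→4) glycosidic bonds. The package
stores a chain as an ordered residue vector, index 1 at the non-reducing
end, labelled A, B, C, … — the convention used when assigning these
compounds by NMR. Linkage is not stored per bond: it is invariably
(1→4), and the anomeric configuration is a function of ring type alone
(β for GlcA, α for IdoA and GlcN), which is exactly what the measured
³J(H1,H2) values report (≈8 Hz for β, ≈4 Hz for α).

The residue vocabulary is the full working alphabet of the
chemoenzymatic toolbox, including the transient states a chain passes
through mid-synthesis (GlcNTFA, free-amine GlcN), so that routes can be
represented at every step, not only at their characterized endpoints.
Two hard invariants are enforced at construction: sulfation positions
must be legal for the ring type (2-*O* on uronates; 3-*O*/6-*O* on
glucosamines), and a 3-*O*-sulfated glucosamine must be *N*-sulfated —
3-OST-1 acts on GlcNS(6S) acceptors, so GlcNAc3S cannot arise in this
chemistry and the parser refuses it.

### Built-in compounds and their provenance

Each fixture carries a `flag`. `"printed"` structures (seed, IV, V, VI,
14) are stated residue-by-residue in the source characterization.
`"reconstructed"` structures are pinned down only by route logic, and we
made the following choices:

* **III** is the trisaccharide: the intermediates span trisaccharide to
  heptasaccharide, and with I, II, IV–VI pentasaccharides and VII the
  heptasaccharide, the trisaccharide slot falls to III.
* **II** (one GlcNAc, one GlcNS): which glucosamine is which is shown
  only in a scheme drawing. We place GlcNAc at residue D (the first
  glucosamine added during elongation) and GlcNS at B.
* **28 and 46** are obtained by replaying the documented route — extend
  VI by one (28) or three (46) residues, de-TFA + *N*-sulfate,
  6-*O*-sulfate globally, then 3-*O*-sulfate at the unique preferred
  site (see the 3-OST-1 rule below).
* **65** carries its single 2-*O*-sulfo on the *internal* GlcA of
  intermediate IV; the regiochemistry is not stated, and the internal
  site is the one flanked by the *N*-sulfoglucosamines that 2-OST
  recognizes in its canonical reaction. **66** sulfates both eligible
  GlcA residues.

## Mass computation

Compositions use the neutral free-acid convention (–SO₃H, –COOH): the
deconvoluted ESI-MS masses of these compounds are reported on that
scale, and the calculated 1900.6 Da for hexasaccharide 14 is reproduced
only under it. A chain's composition is the sum of free monosaccharide
formulas minus one water per glycosidic bond; the aglycone is the
corresponding phenol condensed with loss of one further water
(pNA-N₃ = C₁₂H₁₆N₄O₂; *p*NP = C₆H₅NO₃). Average masses use IUPAC 2013
conventional atomic weights and monoisotopic masses the
principal-isotope masses, both stored to five decimals; the two are
computed from the same composition, so their difference is purely the
weight table. For the C₄₈H₇₃N₇O₅₆S₈ hexasaccharide the average mass is
1900.6 Da and the monoisotopic 1899.1 Da — about 1.5 Da apart, which is
why the reported calculated value of 1900.6 must be an average mass;
the package adopts that convention throughout.

The ESI ladder is plain deprotonation arithmetic,
*m/z = (M − z·m_H)/z* with *m_H* = 1.00794 Da. Sodium/potassium adducts
and in-source sulfate loss are deliberately not modeled.

An independent per-residue increment table (dehydrated residue masses,
e.g. GlcNS6S = 321.27) is kept in the test suite as an oracle; the two
mass paths agree to < 0.01 Da on every fixture.

## The anomeric shift model

The model's single structural assumption: the anomeric ¹H/¹³C shift of
a residue depends on its own substitution state and on the residue
attached to its *reducing* side, and on nothing else. The non-reducing
neighbor has a minimal effect and is ignored — no second-neighbor
corrections are applied. The model ships as a versioned CSV
(`inst/extdata/shift_table.csv`) of (residue class, context class) rows
with ¹H and, where established, ¹³C values and tolerances; users can
substitute their own calibration file.

Context classes and choices:

* For glucosamines the context is the uronate family: GlcA-type versus
  IdoA-type. IdoA and IdoA2S form one merged context, as the source
  data group them. We symmetrically merge GlcA and GlcA2S into the
  GlcA-type context; without this, chains containing the rare GlcA2S
  would be unpredictable, and the grouping mirrors the IdoA(±2S) one.
* For uronates the context is the glucosamine neighbor's substitution:
  the decisive feature is the 6-*O*-sulfo group (GlcNX vs GlcNX6S,
  X = Ac or SO₃), which moves GlcA from 4.43 to 4.54 ppm — a larger
  effect than the neighbor's *N*-substituent, which the classes
  therefore ignore.
* The reducing-end residue takes an aglycone context: the aromatic ring
  of the pNA-N₃ tag deshields the anomeric proton of the terminal GlcA
  to 5.07 ppm. No calibration exists for *p*NP-linked or free reducing
  ends, or for glucosamines on the aglycone, so those are *unresolved*
  rather than guessed.

Combinations absent from the model — GlcNS3S6S in a GlcA context,
GlcNAc next to an iduronate, anything involving GlcNTFA or free-amine
GlcN — produce an explicit error listing the offending residues
(`partial = TRUE` returns NA rows instead). Missing ¹³C values are
represented as absent and never imputed. Where the source states no
tolerance we default to ±0.05 ppm ¹H and ±0.5 ppm ¹³C, wide enough to
cover the known 4.54-predicted/4.56-observed gap for a GlcA before a
6-*O*-sulfated neighbor. IdoA2S predictions carry a `"broad"` note:
its anomeric signal is broadened by exchange among ring conformers
(¹C₄ chair, ²S₀ skew-boat, ⁴C₁ chair), a lineshape effect outside this
model's scope.

## Peak assignment

Assignment is minimum-cost bipartite matching between observed peaks
and predicted residues with pair cost
|ΔδH| + *w*·|ΔδC| + *J*-mismatch penalty. Defaults: *w* = 0.1 per ppm
(¹³C dispersions run roughly ten times the ¹H ones, so this weight puts
the two dimensions on comparable footing) and a 1.0 ppm-equivalent
penalty for pairing a peak whose measured *J* implies one anomeric
configuration with a residue of the other — large enough to be
near-disqualifying against sub-0.1-ppm shift deviations. Missing
optional dimensions (¹³C, *J*) contribute zero cost rather than a
penalty. Instances with ≤ 8 residues are solved by exhaustive
enumeration of bijections in lexicographic label order, which also
fixes the deterministic tie-break; larger instances use an O(n³)
Hungarian solver, verified against the exhaustive path in the tests.
Partial mode pads the cost matrix with zero-cost dummy peaks, leaving
the surplus residues explicitly unassigned — the practical situation
where only a subset of signals is resolved.

One caveat the recovery statistics must respect: chemically equivalent
residue contexts produce *identical* predictions (in hexasaccharide 14,
residues A and E are both GlcNS6S with a GlcA on the reducing side), and
no assignment method can distinguish them. Recovery is therefore judged
up to exchange of spectroscopically indistinguishable residues — mapping
a peak to either member of such an equivalence class counts as correct.
When all predictions are distinct this reduces to exact recovery.

## The enzyme rule set and route planner

Actions and their eligibility rules:

* **pmHS2 elongation** (UDP-GlcNAc, UDP-GlcNTFA or UDP-GlcA donors)
  adds one residue at the non-reducing end, respecting alternation.
* **deTFA+NST** converts every GlcNTFA to GlcNS in one step: the
  chemical deprotection and the enzymatic *N*-sulfation are always run
  as a unit, so the model treats them atomically.
* **C5-epimerase** acts only on an unsulfated GlcA flanked by *two*
  *N*-sulfoglucosamines; GlcNS, GlcNS6S and GlcNS3S6S all count as
  GlcNS-class, since *N*-sulfation is the stated determinant. The
  enzyme is bidirectional: the forward (GlcA→IdoA) and reverse
  (IdoA→GlcA) directions are modeled as two committed actions, and the
  planner's visited-set deduplication terminates the resulting cycles.
  The equilibrium mixture itself is not modeled.
* **C5-epi + 2-OST** in one pot traps the transient IdoA as IdoA2S — a
  committed step, because the epimerase cannot act on a 2-*O*-sulfated
  residue. Consequently no reachable state ever reverts an IdoA2S, and
  GlcA2S is likewise never epimerized (the lock invariant, tested over
  the full depth-12 enumeration).
* **2-OST-on-GlcA** (site-selective) sulfates a GlcA adjacent to at
  least one GlcNS-class residue. The aglycone-bearing reducing-terminal
  GlcA is excluded by default (no documented reaction sulfates it;
  a flag allows it). On intermediate IV this yields two sites — the
  internal C and the non-reducing-terminal A — which is what makes both
  the mono- (65) and di-sulfated (66) products reachable; eligible
  sites are ordered internal-first, so single-site application gives
  the internal product.
* **6-OST** sulfates every GlcNS and GlcNAc lacking a 6-*O*-sulfo
  group in one step (the 6-OST-1/6-OST-3 pair is used jointly and
  states no site split, so they are one merged global action).
* **3-OST-1** (site-selective) requires a GlcA on the non-reducing side
  of its GlcNS acceptor; when several sites qualify, those with IdoA2S
  on the reducing side are preferred (this reproduces the unique
  documented sites in the hepta- and octasaccharide products). Whether
  the acceptor must already be 6-*O*-sulfated is not settled; every
  documented use acts on GlcNS6S, so `require_6s_for_3ost` defaults to
  `TRUE` and is a flag.

`plan_route()` is breadth-first search over canonical sequence strings
with a fixed action ordering, so shortest routes are found and identical
inputs give identical output; the default depth bound is 20 steps, and
an exhausted bound returns an explicit infeasibility report rather than
an error. `validate_route()` replays a route step by step, re-checking
eligibility at each intermediate state. `enumerate_library()` returns
every distinct structure reachable within a step budget (from the
monosaccharide seed, 9,697 structures within 12 steps).

## Synthetic data

`simulate_peaklist()` draws one peak per residue at the model prediction
plus independent Gaussian noise, shuffles rows, and optionally drops a
fraction of peaks, returning the ground-truth mapping. Defaults
σ_H = 0.02 ppm and σ_C = 0.2 ppm sit mid-range of the model's stated
dispersions (±0.02–0.04 ppm ¹H, ±0.2–0.3 ppm ¹³C), which we read as
measurement scatter across compounds. A single seed controls each
simulated spectrum, so every run is exactly reproducible.

What the simulator emulates is a clean anomeric-region read-out of a
pure compound. It does **not** model lineshape or linewidth (notably the
broad IdoA2S signal), peak overlap and the merging of coincident
signals, solvent, temperature or cation effects (such as the EDTA
sensitivity of IdoA2S shifts), or any systematic calibration offset.
Passing recovery tests on these simulations therefore demonstrate the
correctness and noise robustness of the matching machinery — not
assignment performance on crowded real spectra, where overlap, not
Gaussian scatter, is the binding constraint.

## Problem sizes and numerical notes

The test suite exercises round-trips on 250 random chains, matching
oracle equivalence on random cost matrices up to n = 8 (8! = 40,320
bijections), 200-replicate Monte-Carlo recovery at σ_H = 0.01 ppm, a
1,000-replicate dispersion check, and the full depth-12 reachability
enumeration — sizes chosen so the whole suite completes in about two
minutes on a single CPU while still covering the state space the
fixtures live in. Costs and masses are compared at 10⁻⁹–10⁻¹² where
exactness is expected, at the stated chemical tolerances (0.01–0.1 Da,
0.05 ppm) where a convention is being reproduced. Assignment ties are
impossible to rank scientifically and are broken lexicographically by
residue label; candidate-ranking ties break by sequence string.

## Known limitations

* The shift model is a lookup, not a physical model: contexts absent
  from the calibration are refused, and accuracy inherits the source
  calibration's scope (D₂O, 298 K, anomeric positions only; no ring
  protons, no 2D cross-peak prediction).
* GlcA2S context merging (above) extrapolates the GlcA row to GlcA2S
  neighbors; no measured counter-example exists, but none confirms it
  either.
* The planner optimizes step count only — no yields, kinetics, donor
  stoichiometry or purification cost.
* Reconstructed fixtures (II, III, VII, 28, 46, 65, 66) are route-logic
  inferences and are flagged as such; downstream conclusions that
  depend on their exact structures should treat the flag as a caveat.
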