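---
title: "Methods: hydrogen-bond nomenclature, spectral assignment and NBO sums for capped chalcogen peptides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hydrogen-bond nomenclature, spectral assignment and NBO sums}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepconf)
```

pepconf analyses the conformational landscape of capped dipeptides
Ac-X-Phe-NH₂ whose first residue carries a thioether (Met) or selenoether
(Se-Met) side chain.  This vignette is the package's own account of the
models and conventions it implements, the parameters that matter, and the
limits of what its tests demonstrate.

## The structural model

A conformer is an ordered atom table (element, Cartesian coordinates in Å,
semantic role, residue index), an undirected covalent bond set, and two
relative energies in kJ/mol: the 0 K electronic energy and the 300 K free
energy, both relative to the most stable conformer of the set.  The
package uses a polar-hydrogen representation: all heavy atoms plus the
amide hydrogens.  Aliphatic and aromatic hydrogens play no role in any
operation implemented here (ring counting, dihedrals over heavy atoms,
NH-donor geometry), so omitting them keeps every fixture small without
losing information.

Bonds are inferred from distances: atoms are bonded when
`d ≤ scale · (r_cov(e1) + r_cov(e2))` with single-bond covalent radii
(H 0.31, C 0.76, N 0.71, O 0.66, S 1.05, Se 1.20 Å) and `scale = 1.20`.
A hydrogen acquiring two heavy-atom bonds under this rule is treated as a
hard error, since every later step assumes a unique N–H direction.  Roles
(backbone N/CA/C′/O, side-chain Cβ/Cγ/Y/Cε, caps) are perceived from the
bond graph alone, so conformers read from XYZ or PDB files in arbitrary
atom order annotate identically to built ones; non-template molecules
require an explicit role table.

## Ring-count nomenclature

Every NH⋯O/S/Se contact is named by the atom count of the shortest
covalent path from the donor **hydrogen** to the acceptor, inclusive of
both endpoints.  This convention — the hydrogen is counted — is what makes
the standard names come out: C5 for the intra-residue NH⋯O=C contact, C7
for the γ-turn, C10 for the β-turn, 6 for the intra-residue NH⋯Y and 7
for its inter-residue counterpart.  Some literature counts exclude the
hydrogen; anyone comparing ring numbers across sources should check this
first.  Side-chain acceptors additionally carry the Greek position of the
acceptor relative to Cα (β, γ, δ, …) as a superscript, so the thioether
sulfur of a Cys-like residue gives 5^γ^ where Met's gives 6^δ^.  Ring
counting is purely topological: tests verify invariance under coordinate
jitter and rigid motion.

A γ-turn (C7) bond encloses exactly one residue; the package assigns the
inverse form L when that residue's ψ is positive and the direct form D
otherwise.  Whether the original assignment practice used the ψ sign or
full turn geometry is not documented; the ψ-sign rule is simple, total,
and flips correctly under mirror symmetry (verified by test).

## Geometric criteria

The detection thresholds are conventions, exposed in the configuration:

| parameter | default | why |
|---|---|---|
| max H⋯A distance, O | 2.6 Å | upper range of moderate NH⋯O=C bonds |
| max H⋯A distance, S/Se | 3.0 Å | reported NH⋯S/Se contacts sit at 2.48–2.59 Å, comfortably inside |
| min N–H⋯A angle | 95° | see below |
| NH–π: H⋯centroid | 3.0 Å | typical amide-to-arene contact range |
| NH–π: elevation above ring plane | 30° | rejects in-plane grazing approaches |

The angular gate deserves a note.  A cutoff near 110° is common for
generic hydrogen bonds, but the C5 pseudo-cycle is so small that its
N–H⋯O angle is geometrically capped near 100–105° (the idealized template
used here tops out at ~103° even at full backbone extension).  A 110°
gate would therefore silently erase the C5 class — a structurally
meaningful interaction — from every conformer.  The default is 95°, low
enough to admit C5 and still high enough to reject the ~60–70° cis-amide
H⋯O contact of the carboxamide group (ring size 4), which is the nearest
spurious candidate.

Rotamer classes bin a torsion into 120°-wide half-open windows after
wrapping to (−180°, 180°]: (0, 120] → g+, (−120, 0] → g−, remainder → a.
The windows are a convention (the underlying practice names classes
without printing cutoffs); boundary behaviour is pinned by tests.

## Family labels, fingerprints, clusters

A conformer has three NH slots: residue-1 NH, residue-2 (Phe) NH, and the
carboxamide NH₂ (both hydrogens pooled).  A slot's status is its
interaction symbol, a slash-joined pair when one NH is doubly engaged
(longer ring written first, e.g. `7δ/5`), or `f` when free.  Subscripts
follow the field's labelling practice: slot 1 carries the χ3 class of the
chalcogen side chain (the terminal-group orientation that controls the
lone-pair presentation), slot 2 the Phe χ1 class, slot 3 the L/D
chirality when it donates a C7 bond.

The fingerprint pairs the subscript-stripped backbone statuses with the
(χ1, χ2, χ3, Phe χ1) rotamer string; families are fingerprint-equality
classes.  Within a family, near-duplicate geometries (heavy-atom RMSD
after Kabsch superposition below 0.3 Å) are merged keeping the
lowest-free-energy member.  RMSD is used only for intra-family
deduplication, never for family definition, mirroring label-based
regrouping practice.  The hand-written Kabsch superposition is
cross-checked in the tests against bio3d's least-squares fit.

Boltzmann populations use R = 8.314462618 J mol⁻¹ K⁻¹ and are computed
after subtracting the minimum ΔG, which makes the weights
shift-invariant and numerically safe for any magnitude of input.

## Frequency scaling and band regions

Scaled positions are affine in the harmonic frequency,
`f_scaled = a + b·f_harmonic`, per mode class:

| mode class | a (cm⁻¹) | b |
|---|---|---|
| peptide NH | 372.8 | 0.86953 |
| NH₂ sym | 1209.8 | 0.63115 |
| NH₂ antisym | 1324.1 | 0.60872 |

`b > 0` is enforced so scaling preserves band ordering.  The calibration
concept carries a typical accuracy of ~20 cm⁻¹, which is also the default
assignment tolerance.  `calibrate_scaling()` refits such a law from
(harmonic, reference) pairs by ordinary least squares; with noiseless
pairs it reproduces the generating law to numerical precision, which the
acceptance checks exercise with 50 uniform draws over 3300–3700 cm⁻¹.

Band regions default to: hydrogen-bonded < 3400, weak interactions
(C5, π) 3420–3460, free NH 3460–3510, NH₂ antisym 3510–3560 cm⁻¹; the
3400–3420 gap and anything above 3560 classify as `unclassified`.  The
source practice gives anchor values, not closed intervals; the bounds are
configurable.

## Band matching and assignment

Given an experimental band list (with optional excluded bands, e.g. a
feature attributed to a co-populated minor species) and a candidate stick
spectrum, the pairing minimising the sum of squared deviations is found
by dynamic programming over the monotone (non-crossing) alignments of the
two sorted lists.  For squared costs on sorted sequences the optimal
assignment never crosses, so this is exact for equal and unequal counts
alike; the test suite verifies equality with brute-force enumeration over
all pairings for every size up to 6 bands.  Scores are the RMS and
maximum unsigned deviation (rms ≤ max always).  Candidates outside the
300 K free-energy window (default 10 kJ/mol) rank last; within the
window, ranking is by RMS with ties broken by ΔG then maximum error, and
a best match with RMS above 20 cm⁻¹ is reported as unassigned.  An
optional strict mode confines NH₂-antisym bands to NH₂-antisym modes.

## The synthetic generator

The builder assembles conformers from internal coordinates by sequential
placement (bond length, valence angle, torsion), so every requested
dihedral is reproduced exactly by construction.  Template geometry uses
standard amide values (C–N 1.335, N–H 1.01, C=O 1.229, Cα–Cβ 1.53,
C–S 1.81, C–Se 1.955 Å; trigonal/tetrahedral angles; Cβ branch offset
−122.5° for L-residues).  The fixture catalog covers the named low-energy
forms — two β-turn forms (6δ with χ3 anti or gauche−), two semi-extended
forms (C5 + inter-residue 7δ + L γ-turn, Phe g+ or g−) and the fully
extended form with a doubly engaged 7δ/5 NH — plus an intermolecular
methylacetamide/dimethyl-chalcogenide complex for the constraint-free
reference approach.  Side-chain torsions in the catalog were tuned so the
built H⋯Se distances sit at the reported equilibrium values (251/249 pm
for the 6δ forms, 258/249 pm for the 7δ forms); the χ2 difference between
the two semi-extended entries encodes the reported noncovalent
compression of the NH⋯Se contact by the Phe orientation.  Backbone
presets (β-turn (−60, −30)/(−90, 0); γ-L (−80, +70); extended
(−160, 160)) were chosen so the intended bonds form under the default
criteria — asserted by the label-closure tests, not assumed.

The spectral generator is an explicit stand-in, not physics.  Free
carriers sit at fixed scaled-axis base positions (peptide NH 3485, NH₂
sym 3435, antisym 3545 cm⁻¹).  Hydrogen-bonded carriers are red-shifted
by `S0 · exp(−(r − r0)/λ)` with an approach-class amplitude: S0 = 240
cm⁻¹ for the inter-residue 7δ approach, 140 cm⁻¹ for the less efficient
intra-residue 6δ one, 160 cm⁻¹ for backbone C7/C10; r0 = 2.50 (Se),
2.46 (S), 1.80 (O) Å; λ = 0.125 Å for S/Se and 0.35 Å for O.  These
numbers were set once from the reported magnitudes — shifts up to
~200 cm⁻¹, ~20 cm⁻¹ between the two 6δ forms a few pm apart, and the
greater efficiency of the 7δ approach — and are treated as ground truth
for the machinery only.  C5 and π contacts apply fixed 45/40 cm⁻¹
shifts, and the NH₂ antisym stretch receives 15% of its slot's shift.
Harmonic frequencies are produced by inverting the scaling laws, so the
pipeline's scaled output reproduces the intended positions exactly at
zero jitter.  What passing tests therefore show is that the machinery —
detection, labelling, scaling, pairing, ranking — is internally
consistent and recovers planted ground truth; they say nothing about
whether a real spectrum of a real molecule would be assigned correctly.
Real data add anharmonicity, Fermi resonances, intensity effects and
conformer interconversion, all out of scope.

The synthetic NBO generator emits two lone-pair channels per NH⋯S/Se bond
with totals following `ln ΣE = c − d·r` (defaults c = 9.65, d = 0.025
pm⁻¹, i.e. ~30 kJ/mol at 250 pm), split 70/30 between n_Y and n′_Y, plus
small C5 (2.0 kJ/mol) and π (1.5 kJ/mol) channels into the same σ*; the
decay fit recovers (c, d) exactly at zero noise and within standard
errors at 5% noise.

## Numerical choices and degenerate inputs

Torsions are signed IUPAC angles in (−180°, 180]; collinear triples raise
an undefined-torsion error rather than returning a value.  The builder
rejects geometries with any non-bonded pair under 0.8 Å, naming the
clashing pair.  Energies written to XYZ comments round-trip exactly
(17 significant digits).  kcal↔kJ conversion uses the thermochemical
factor 4.184 exactly.  Disconnected donor/acceptor pairs (intermolecular
complexes) carry ring length NA and the symbol `x`; `ring_size()` errors
on them, by contract.  All randomness in the generators sits behind
explicit seeds; seeded runs are bit-for-bit reproducible.

Problem sizes throughout the tests are the study's natural ones: 27-atom
conformers, 4-band spectra, a 5-member catalog, calibration sets of
50–200 points, and a 100-trial assignment benchmark — everything runs in
seconds on one core.

## Known limitations

* The template covers Ac-X-Phe-NH₂ (X = Met/Se-Met) natively; other
  sequences need a user-supplied role table and currently get no χ
  subscripts.
* Stick spectra are positions only; no intensities, lineshapes,
  anharmonicity or mode coupling.
* The energy and NBO values attached to fixtures are nominal inputs, not
  computed quantities; the package never claims energetic realism.
* L/D γ-turn chirality from the ψ sign is a convention; exotic ring
  geometries near ψ ≈ 0 would be assigned unstably.
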