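---
title: "Local-conformation analysis of secondary-structure shape and deformation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local-conformation analysis of secondary-structure shape and deformation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sadef)
```

## The model

`sadef` treats a protein backbone as a sequence of local conformations.
Overlapping windows of four consecutive Cα atoms are summarized by four
descriptors — the inter-carbon distances d₁ (1–3), d₂ (1–4), d₃ (2–4) and
the oriented projection P₄ of the fourth carbon onto the plane of the first
three — and the descriptor sequence is decoded into 27 structural letters
with a hidden Markov model: multivariate Gaussian emissions per letter and a
Markov prior over letter successions, solved by the Viterbi algorithm in log
space.  The decoding therefore balances *how much a fragment looks like a
prototype* against *which letters tend to follow each other*; this prior
smooths noisy fragment-level assignments, which matters below.

Four letters (`a`, `A`, `V`, `W`) cover α-helix conformations, five
(`L`, `M`, `N`, `T`, `X`) β-strands, thirteen loops, and five the
helix/strand borders.  Within a class the letters distinguish *shapes*:
`A` is the straight helix, `a`/`V` curved and kinked variants; `T`/`M` are
straight extended strands, `L`/`N` curved ones.  A chain of *n* unbroken
residues yields *n* − 3 letters, and residue *r* inherits the letter of the
window *r*−2 → *r*+1, so per-residue properties (solvent accessibility,
compartment) can be attached to letters.

### The sign convention for P₄

P₄ is the signed distance of Cα₄ from the plane of Cα₁–Cα₃ along the normal
(Cα₂−Cα₁)×(Cα₃−Cα₂).  This makes windows of a right-handed α-helix
positive, and mirror reflection flips only P₄'s sign — both properties are
enforced by tests.  Fragments whose first three carbons are collinear
(triangle area ≤ 10⁻⁶ Å²) have no defined plane; they are flagged invalid,
receive no letter, and split the decoding into independent runs rather than
contaminating their neighbours.

### The shipped alphabet model is a synthetic reconstruction

The published estimates of the 27-letter model (descriptor means,
covariances, transition matrix) are not redistributed here.  The shipped
model file (`inst/extdata/sa27_model_synthetic.json`, loaded by
`default_alphabet_model()`) was reconstructed once from geometry: helix and
strand prototypes were computed from parametric ideal backbones (helix
radius 2.3 Å, rise 1.5 Å/residue, twist 100°/residue; extended pleated
strand with 3.8 Å steps), and loop/border prototypes were placed to span the
descriptor space following the letters' qualitative signatures (surface
loop-letters: long d₁, short d₃, low or negative P₄; core loop-letters:
short d₁, positive P₄; borders intermediate).  Emissions use a shared
isotropic variance of 0.5 Å² and transitions favour self (0.55 for regular
letters, 0.35 otherwise) and same-class successors 2:1 over the rest, so
decoding behaves like a regularized nearest-prototype assignment.

Consequences to keep in mind:

* encodings are qualitatively faithful (straight vs curved helices,
  extended strands, loops) but not letter-exact against published encodings
  of real structures;
* the PCA of this descriptor table puts 54.8% of (standardized) variance on
  the first axis and 30.2% on the second — close to, but not identical
  with, the 58%/29% reported for the published table.  The acceptance test
  for that figure is therefore expected to fail with the shipped model and
  documents this limitation; supplying a fitted model file restores the
  intended check.

A fitted model in the same JSON schema (keys `letters`, `ss_class`,
`emission$mean`, `emission$cov` — diagonal or full, `transition`,
`initial`) drops in via `load_alphabet_model()`; validation checks the
class partition (4/5/13/3/2), row-stochasticity to 10⁻⁶ and
positive-definite covariances.

## Compartments from solvent accessibility

Relative accessibilities are computed with an internal Shrake–Rupley
engine: each atom's solvent-expanded sphere is sampled with a deterministic
golden-spiral lattice (default 960 points/atom, <2% error against
closed-form one- and two-sphere areas; doubling the density moves a sphere
area by <0.5%).  The probe radius defaults to 1.4 Å.  Residue areas are
expressed as percentages of the residue's area in an extended ALA-X-ALA
tripeptide, built internally from idealized bond geometry with extended
(trans) dihedrals; the twenty reference areas agree with published
NACCESS-convention reference totals within 15% (worst cases Leu and Gly,
both driven by radius-set differences).  Chirality does not matter here:
surface areas are mirror-invariant.

Each residue of the analysed chain gets three accessibilities — alone
(*A_chain*), with the partner of interest (*A_interf*), with all chains of
the entry (*A_complex*) — and one compartment:

| compartment | rule |
|---|---|
| interface | A_chain > 5% and A_chain − A_interf > 1 point |
| surface | A_chain > 5% and \|A_chain − A_complex\| ≤ 0.05 |
| core | A_chain < 5% and \|A_chain − A_complex\| ≤ 0.05 |
| undefined | anything else (excluded from statistics) |

Two deliberate readings: equality with "no accessibility change" is
implemented as \|Δ\| ≤ 0.05 points because fixed-precision areas make exact
floating-point zero ill-defined; and a residue sitting exactly at the 5%
burial threshold is undefined (both inequalities are strict).  The
interface rule is evaluated first; since A_complex ≤ A_interf the rules are
mutually exclusive and the order only resolves tolerance-edge cases.
Hetero atoms and waters are excluded from all contexts by default.
*A_complex* uses all chains of the file as given, without assembly
expansion.

## Preference statistics

All statistics run on the letters × {interface, surface, core} count table.

* **KLd**: for letter *sl* with class *ss* (its own secondary-structure
  class, borders pooled as one class),
  KLd(sl) = Σ_cp p(sl,cp) ln(p(sl,cp)/p(ss,cp)), with 0·ln(0/q) = 0.  The
  quantity 2·N_sl·KLd is referred to χ²(df = 2); the 0.95 quantile is 5.99.
  A null calibration (letter drawn from its class distribution,
  N_sl = 500, 10,000 replicates) rejects in 5% ± 1% of draws.
* **Z-scores**: Z = (N_obs − N_exp)/√N_exp with
  N_exp = (class total in cp₁) × f_cp₂(sl).  The (O−E)/√E form is the
  standard Poisson-approximation score and is consistent with the rule that
  N_exp must exceed 5 for the score to be meaningful.  The reference count
  is the *class* total in cp₁ — reading it as the letter's own count would
  be circular.  Bonferroni thresholds default to a two-sided family of
  (letters in class) × 3 comparisons; both the family size and sidedness
  are arguments, because no standard convention exactly reproduces
  published threshold values (|2.5|, |2.6|, |2.9|), which fall between the
  one-sided and two-sided families.
* **Correspondence analysis** of the count table is simple CA — SVD of the
  standardized-residual matrix — because the input is a plain two-way
  contingency table; with three compartments there are at most two axes.
* **PCA** of the 27 × 4 descriptor table standardizes columns by default
  (distances and a signed projection have different spreads); raw
  covariance is available as an option.
* **Preferential percentage** per class and compartment:
  Exp(sl,cp) = N_total(sl) × (class total in cp)/(class total), and the
  reported value is Σ max(Obs − Exp, 0)/Σ Obs over the class's letters in
  that compartment.  The denominator is the *compartment-wise* observed
  count; the overall "all" figure uses the class's full observed count.

## Deformation analysis

Bound and unbound conformations of a chain are paired by global sequence
alignment (match +1, mismatch −1, gap −2); mismatched aligned columns are
dropped, since a letter change at a mutated position may reflect the
mutation rather than deformation, and pairings below 80% identity are
rejected outright.  Transitions are counted in the compartment of the
*bound* residue: the interface exists only in the bound state, and unbound
positions inherit it through the position map.

P(sl₁,sl₂) conditions on deformed letters — the count of sl₁ → sl₂ over all
off-diagonal counts of sl₁ — so letters with different deformation *rates*
remain comparable; rows with no deformation are reported absent rather than
zero-filled.  ΔP = P_interf − P_surf isolates interaction-induced
substitutions under the assumption that intrinsic flexibility produces
similar substitutions at interface and surface; rows present on one side
only are zero-filled and flagged.  Exposure differences for deformed loop
positions use D = A_chain(unbound) − A_chain(bound, disjoint) — the
disjoint chain in both states — so D measures the conformational change
itself, not the partner's shadow; negative D means higher exposure upon
binding.  RMSD between matched Cα sets uses Kabsch superposition with the
determinant correction that forbids improper rotations.

## What the synthetic generators emulate — and what they do not

The generators produce every input the pipeline consumes:

* `make_helix()` / `make_strand()` — parametric traces whose windows carry
  the canonical descriptor fingerprints (helix d₁ ≈ 5.43, d₂ ≈ 5.05 Å;
  strand d₂ ≈ 10 Å); a `curvature` argument bends the axis along a circular
  arc, and for a bent helix the window descriptors oscillate with the phase
  between bend and helical twist — exactly the inside/outside-of-the-bend
  asymmetry real curved helices show, and the reason a gently curved helix
  may still decode as a smoothed run of `A` until the bend dominates.
* `make_loop()` — seeded self-avoiding random walks with 3.8 Å steps.
* `make_complex()` — two chains at a controlled separation (default 9 Å
  between helix axes gives a genuine interface: facing residues lose >1
  point of accessibility), represented as one Cα pseudo-atom per residue of
  radius 3.0 Å.  Compartment logic depends on relative accessibility
  *changes*, which the pseudo-atom representation preserves; absolute
  percentages are referenced to the central atom of an ideal extended
  pseudo-atom triplet.
* `sample_counts()` / `mutate_sequence()` — multinomial count tables with
  planted compartment preferences, and bound-state letter sequences with
  per-compartment deformation rates and a controlled substitution matrix.

They do **not** emulate sidechain packing, real loop ensembles
(Ramachandran statistics), crystallographic noise, or hetero-ligand
contacts.  Tests passing on synthetic complexes therefore validate the
machinery — encoding, compartment logic, statistics, recovery of planted
signal — not the biological letter distributions of real interfaces, which
require curated complex datasets outside this package's scope.

## Numerical choices and problem sizes

* Viterbi ties break toward the earlier letter in canonical order, making
  decoding deterministic; equality in log scores is the only tie source.
* Altloc records keep the highest occupancy (ties: first in file); chain
  breaks are distance-defined (steps outside 2.5–4.5 Å), so renumbered but
  geometrically continuous chains stay whole; multi-model files use the
  first model by default.
* All generators take explicit seeds and restore the caller's RNG state.
* Test and acceptance problem sizes were chosen for desk-scale runs:
  10,000 replicates for the null calibration, 100 seeded simulations for
  preference recovery (letter total 2000), 50 for substitution recovery
  (400 positions), 100 toy models (≤5 states, ≤6 fragments) for the
  exhaustive-enumeration check; the full suite runs in well under a minute.

## Known limitations

* Letter-exact encodings of real PDB entries require the fitted alphabet
  model; with the synthetic model only shape-level conclusions are
  supported.
* The Shrake–Rupley engine is pure R and quadratic in atom pairs; it is
  comfortable to a few thousand atoms per context but not tuned for
  proteome-scale scans.
* mmCIF files, symmetry/assembly expansion and hydrogens are out of scope;
  the headline distributional percentages of large curated complex datasets
  cannot be reproduced without those datasets.
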