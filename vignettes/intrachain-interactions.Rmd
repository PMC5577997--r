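---
title: "Detecting and comparing intrachain interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and comparing intrachain interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icebonds)
library(dplyr)
```

## Scope and model

`icebonds` quantifies two classes of stabilizing intrachain interactions in
single-chain protein coordinate models — hydrogen bonds and salt bridges —
and compares the resulting interaction networks across orthologous proteins
from different species. The motivating system is the trio of 20S proteasome
catalytic subunits (β1, β2, β5) from an Antarctic icefish (*Chionodraco
hamatus*), a temperate sea bass (*Dicentrarchus labrax*) and an Antarctic
notothenioid (*Trematomus bernacchii*), where interaction counts serve as
coarse proxies for the relative structural robustness of the orthologs.

Detection is purely geometric. No energies, no electrostatics: an
interaction either satisfies the distance/angle criteria or it does not.
That makes results exactly reproducible given coordinates and criteria, and
makes the criteria themselves the scientifically meaningful knobs.

## Salt-bridge criterion

A salt bridge is scored between an acidic side-chain carboxylate
(Asp OD1/OD2, Glu OE1/OE2) and a basic side-chain nitrogen (Lys NZ,
Arg NE/NH1/NH2, His ND1/NE2) when the minimum O⋯N distance is at most
`max_no_distance`. Defaults and rationale:

* `max_no_distance = 4.0` Å — the common Barlow–Thornton convention for
  ion pairs. Reference analyses of this system do not state their in-house
  criterion, so a conventional, configurable value is the only defensible
  choice; sensitivity can be probed by varying the cutoff
  (`salt_bridge_criteria(max_no_distance = ...)`), and the bridge set is
  provably monotone in it.
* `include_his = TRUE` — the reference pair lists for these subunits
  contain His partners (e.g. `Asp184||His189`), so His is counted as basic
  (protonated imidazolium) by default.
* `include_termini = FALSE` — the comparison works on side-chain pairs
  only; the charged N-terminus/OXT can be switched on for other uses.

The counting unit is the **residue pair**: one record regardless of how
many atom pairs qualify. This matches the one-row-per-pair format of the
cross-species pair lists.

## Hydrogen-bond criteria

Donors are N/O/S atoms carrying (or inferably carrying) a hydrogen;
acceptors are carbonyl, carboxylate and hydroxyl oxygens, each with a
covalent antecedent that defines its lone-pair direction. With a hydrogen
available the bond requires

* d(D,A) ≤ `max_da` (3.9 Å),
* d(H,A) ≤ `max_ha` (2.5 Å),
* ∠(D–H⋯A) ≥ `min_dha_angle` (90°),

the permissive HBplus-style geometry widely used for counting "potential"
hydrogen bonds in models that carry no experimental hydrogens. Covalently
bonded (1–2), angle-related (1–3) and intra-residue pairs are excluded.
The counting unit is the **donor-atom/acceptor-atom pair**, so a
bidentate arrangement contributes one record per atom pair.

Homology models have no hydrogens, so `infer_polar_hydrogens()` builds
them where the heavy-atom geometry fixes their position: backbone amide H
in the C(prev)–N–CA plane along the external bisector at N–H = 1.0 Å, and
sp2 side-chain NH/NH2 groups (Arg, Asn, Gln, Trp, His) analogously.
Rotatable donors — Ser/Thr/Tyr hydroxyls, Lys NZ, Cys SG — and amides
missing their antecedent (chain-initial N, chain breaks) cannot be placed
without a rotamer search, which would import modelling assumptions into a
counting exercise. They instead use a heavy-atom-only fallback:
d(D,A) ≤ `heavy_only_max_da` (3.5 Å, stricter to compensate for the
missing directionality) and ∠(D⋯A–antecedent) ≥ `min_daa_angle` (90°).
His ring nitrogens are treated as donors and not acceptors, consistent
with counting His as basic in the salt-bridge chemistry; this is a
deliberate, documented protonation choice, not a fact about any particular
model.

## Cross-species comparison

Salt-bridge pairs are compared across species as canonical text labels,
`Glu184||Arg211`, matched by **exact residue name and number**. The
orthologs in the motivating system have equal residue counts per subunit
(237/199/271 for β1/β2/β5) and share model numbering, so exact matching is
the transparent choice; for orthologs of unequal length an alignment-based
renumbering would be required first (the sequence-comparison tools provide
the alignment, but automatic renumbering is intentionally not wired into
the partition, to keep matching auditable).

`conserved_partition()` classifies each distinct pair as `conserved`
(present in every species), `unique` (exactly one) or `shared_partial`
(at least two but not all). `shared_partial` is computed even though the
headline comparisons only quote conserved and unique counts: without it
the three classes would not partition the input, and the partition
invariant — every (species, pair) row lands in exactly one class — is
asserted on every call.

One quirk of the transcribed β1 reference lists deserves a note: the label
`Asp191||Arg28` appears for all three species, while the typographic
"conserved" row of the third species instead carries `Asp191||Arg38`.
Exact-label intersection classifies `Asp191||Arg28` as conserved and
`Asp191||Arg38` as species-specific, which reproduces the stated counts
(five conserved β1 pairs; four specific to *T. bernacchii*). The package
does not silently "correct" such entries; what is in the table is what is
partitioned.

Count aggregation and ranking are deliberately plain: species totals are
sums over chains; `diff_stats()` reports the absolute difference and its
percentage of the larger total, rounded half-up to one decimal (483 vs 486
hydrogen bonds → 3 bonds, 0.6 %); `rank_stability()` orders species by
descending total with alphabetical, flagged tie-breaks. Half-up rounding
is chosen over R's banker's rounding so that reported percentages match
hand calculation.

## Sequence comparison

`align_global()` wraps Needleman–Wunsch global alignment (BLOSUM62, gap
open 10 / extend 0.5 — the de facto standard for close orthologs, where
results are insensitive to reasonable parameter changes).
`classify_substitution()` follows the Clustal similarity-group convention:
*conservative* = same strong group, *semi-conservative* = same weak group
only, otherwise *non-conservative*. Polarity changes are flagged against
an explicit three-class scheme — nonpolar {A V L I M F W P G}, polar
uncharged {S T C Y N Q}, charged {D E K R H} — because "a change in
polarity" is otherwise untestable. Gap columns are never classified; they
are counted separately in the report summary. Alignment tie-breaking
follows the alignment engine's deterministic traceback; scores (the
quantity with a unique optimum) are what the validation suite pins down.

## Synthetic fixtures and what they show

The generators in this package are first-class, tested code, not ad hoc
test scaffolding:

* `make_ion_pair(separation, acidic, basic)` — two idealized residues,
  side chain to side chain, positioned (via monotone root-finding on a
  rigid translation) so the minimum charged O⋯N distance equals the
  requested separation to within 0.01 Å.
* `make_helix(n)` — an ideal α-helix backbone (φ = −57°, ψ = −47°,
  ω = 180°, standard bond geometry) whose manifest is the i → i−4
  amide-to-carbonyl ladder (n − 4 bonds).
* `make_ortholog_trio(shared, private)` — three chains with identical
  numbering, planting conserved and species-specific bridges on a wide
  lattice, with the expected conservation partition as ground truth.
* `make_random_chain(n)` — idealized residues at random positions and
  orientations in a box: a dense unstructured field of donors, acceptors
  and charged groups for detector-versus-oracle comparison.

Every planted interaction keeps a **guard band of 0.2 Å** to the nearest
criterion threshold, and perturbation noise in tests stays below a third
of that band, so floating-point effects can never flip an expectation and
manifest checks are exact rather than tolerance-based. Generation is a
pure function of its arguments and seed.

These fixtures emulate the geometry that matters to the detectors —
charged-group separations, a backbone hydrogen-bond ladder, identical
cross-species numbering — and nothing else. They are not physically
realistic conformations: no packing, no Ramachandran statistics, no
solvent. Passing the synthetic suite therefore demonstrates that the
detectors implement their stated geometric definitions exactly; it cannot
demonstrate that those definitions match the unreported criteria behind
any particular published count. That is why per-chain absolute counts from
real models are treated as criteria-dependent outputs, not as
reproduction targets, while the aggregation, partition, difference and
ranking layers — which operate on counts and labels — are validated
against the published species-level figures exactly.

## Validation design and problem sizes

The test suite validates the detectors by dual route: an independent
brute-force all-pairs oracle (plain nested loops, written separately from
the vectorized implementation) must agree **exactly** — set equality on
interaction records — on 1000 seeded random chains of 8–12 residues, plus
ideal-geometry fixtures. Invariance suites check rigid-motion invariance
(distances stable to 10⁻⁶ Å), cutoff monotonicity, atom-order independence
and determinism. Alignment scores are checked against an exhaustive Gotoh
affine-gap dynamic program on all sequence pairs of length ≤ 5 over a
two-letter alphabet (1953 pairs) plus 200 seeded pairs of length 6–8 over
four letters. These sizes were chosen to exercise every code path many
times over while keeping the full suite comfortably runnable on a laptop;
the acceptance script re-runs smaller seeded versions (300 chains, 300
alignments) and reports agreement percentages.

## Numerical choices

* Coordinates are Å throughout; PDB output at the format's native 0.001 Å
  precision, and round-tripping through `write_structure()` /
  `read_structure()` is the identity on retained fields.
* Alternate locations resolve to the highest occupancy, ties by altloc
  letter; `"first"` keeps file order.
* Ion-pair placement solves a monotone 1-D root problem
  (`uniroot`, tolerance 10⁻⁶ Å).
* Salt-bridge records break atom-pair ties (equal minimum distances)
  lexicographically by atom name; hydrogen-bond records pick, among
  qualifying hydrogens of a donor, the one closest to the acceptor.
* Percentage differences round half-up to one decimal.
* Degenerate inputs return empty tibbles (chargeless chains, empty FASTA)
  where emptiness is a valid answer, and informative errors where it is
  not (empty structures, malformed labels, mixed-chain partitions).

## Limitations

* Absolute hydrogen-bond and salt-bridge counts are criteria-dependent;
  comparisons of counts are only meaningful under identical criteria,
  which is why every report embeds the criteria used.
* Hydrogen inference covers unambiguous sp2 donors only; rotatable donors
  go through the heavy-atom fallback, which is blind to hydroxyl rotamer
  effects.
* His is globally treated as protonated/basic; no per-residue protonation
  assignment.
* Only intrachain interactions are considered — no interface analysis
  across subunits, no π–cation or hydrophobic contacts, and no claim that
  interaction counts causally explain measured biochemical stability.
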