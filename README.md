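# icebonds

Intrachain hydrogen bonds and salt bridges as structural-stability proxies
in orthologous proteins, with the proteasome catalytic subunits of three
fish species as the motivating case.

## The problem

Cold-adapted (psychrophilic) organisms are expected to trade structural
rigidity for flexibility in their proteins, and the balance is partly set
by weak intrachain interactions: hydrogen bonds and salt bridges. Given
single-chain 3D models of the 20S proteasome catalytic subunits (β1, β2,
β5) from the icefish *Chionodraco hamatus*, the temperate sea bass
*Dicentrarchus labrax* and the Antarctic notothenioid *Trematomus
bernacchii*, the analysis asks:

* how many intrachain hydrogen bonds and salt bridges does each subunit
  carry, and what are the species totals;
* which salt-bridge residue pairs are conserved across the three orthologs
  and which are species-specific;
* how do the orthologous sequences differ (percent identity, conservation
  class of each substitution, polarity changes);
* what stability ordering do the interaction counts suggest.

`icebonds` implements that pipeline as composable, tibble-first functions.

## The core definitions

* **Salt bridge** — for an acidic residue *a* (Asp/Glu) and a basic residue
  *b* (Lys/Arg/His), a bridge exists when

  min over charged atoms ( d(O<sub>a</sub>, N<sub>b</sub>) ) ≤ r<sub>c</sub>,

  with charged atoms Asp OD1/OD2, Glu OE1/OE2, Lys NZ, Arg NE/NH1/NH2,
  His ND1/NE2 and cutoff r<sub>c</sub> = 4.0 Å by default (Barlow–Thornton
  convention). Counting unit: the residue pair.
* **Hydrogen bond** — donor D (N/O/S bearing an explicit or inferable H)
  and acceptor A (carbonyl, carboxylate or hydroxyl O) form a bond when
  d(D,A) ≤ 3.9 Å, d(H,A) ≤ 2.5 Å and ∠(D–H⋯A) ≥ 90°; donors whose H
  position is rotationally ambiguous use a heavy-atom-only fallback
  (d(D,A) ≤ 3.5 Å, ∠(D⋯A–antecedent) ≥ 90°). Counting unit: the
  donor-atom/acceptor-atom pair. Polar hydrogens are inferred from the
  heavy-atom geometry where that is unambiguous.
* **Conservation partition** — pair labels (`Glu184||Arg211`) are matched
  across species by exact residue name + number and split into
  *conserved* (all species), *unique* (one species) and *shared_partial*
  (some but not all) — a disjoint partition of every species' pair set.
* **Substitutions** — global Needleman–Wunsch alignment (BLOSUM62,
  gap open 10 / extend 0.5), Clustal strong/weak-group conservation
  classes, and a three-class polarity scheme
  (nonpolar / polar-uncharged / charged) for polarity-change flags.

## Worked example

Species profiles and stability ranking from the per-chain counts shipped
with the package:

```r
library(icebonds)

counts <- read_count_table(system.file("extdata",
  "subunit_interaction_counts.tsv", package = "icebonds"))
species_profiles(counts)
#> # A tibble: 3 × 4
#>   species       n_chains hbonds saltbridges
#>   <chr>            <int>  <int>       <int>
#> 1 C. hamatus           3    483          22
#> 2 D. labrax            3    486          20
#> 3 T. bernacchii        3    503          25

diff_stats(483, 486)
#> # A tibble: 1 × 2
#>   absolute_difference percent_of_larger
#>                 <int>             <dbl>
#> 1                   3               0.6

rank_stability(species_profiles(counts), "saltbridges")
#> # A tibble: 3 × 4
#>    rank species       total tied
#>   <int> <chr>         <int> <lgl>
#> 1     1 T. bernacchii    25 FALSE
#> 2     2 C. hamatus       22 FALSE
#> 3     3 D. labrax        20 FALSE
```

The two temperate/sub-Antarctic species differ by only 3 hydrogen bonds
(0.6 % of the larger total), while the Antarctic species carries the most
salt bridges — the ranking `T. bernacchii > C. hamatus > D. labrax`.

Cross-species conservation of the salt-bridge pairs:

```r
pairs <- read_pair_table(system.file("extdata",
  "salt_bridge_pairs.tsv", package = "icebonds"))
part <- conserved_partition(dplyr::filter(pairs, chain == "beta1"))
glance(part)
#> # A tibble: 1 × 5
#>   n_species n_pairs conserved shared_partial unique
#>       <int>   <int>     <int>          <int>  <int>
#> 1         3      12         5              0      7
unique_pair_counts(part)
#> # A tibble: 3 × 2
#>   species       unique_pairs
#>   <chr>                <int>
#> 1 C. hamatus               2
#> 2 D. labrax                1
#> 3 T. bernacchii            4
```

Detection runs directly on coordinates — here on a synthetic fixture with
a known answer:

```r
fx <- make_ion_pair(3.5, "GLU", "LYS")   # charged O...N at exactly 3.5 A
detect_salt_bridges(fx$structure)$pair
#> [1] "Glu1||Lys2"

hx <- make_helix(12)                      # ideal alpha-helix backbone
nrow(detect_hbonds(hx$structure))         # the i -> i-4 ladder
#> [1] 8
```

`autoplot()` methods and `plot_interaction_counts()` give ggplot2 views of
profiles and partitions; `run_detect()`, `run_compare()` and
`run_seqcomp()` bundle the pipeline with TSV/JSON output, and
`inst/cli/icebonds.R` exposes them as shell subcommands.

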