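# hdxmd

Differential HDX-MS and molecular-dynamics hydrogen-bond occupancy analysis
for protein–ligand binding.

## The problem

When a small molecule binds and rigidifies part of a protein, backbone amide
hydrogens in the stabilized region spend more time hydrogen-bonded and
therefore exchange more slowly with solvent deuterium. Two complementary
measurements see this: **differential HDX-MS** (deuteration of the free vs
ligand-bound protein, intact and per peptic peptide) and **MD simulation**
(per-amide H-bond occupancy in free vs bound trajectories). `hdxmd` implements
both sides and the semi-empirical bridge between them, for structural
biologists and drug-discovery groups who want per-residue interpretation of
peptide-level HDX protection.

## What it computes

**MD side.** H-bonds are detected per frame with the Baker–Hubbard criterion
(H···O distance ≤ *d*<sub>cut</sub> = 2.5 Å and N–H···O angle ≥ 120°).
Per-replicate occupancies *o* = bonded frames / *F* are averaged per state;
bonds below a 40 % lifetime in **both** states are filtered out, and a kept
bond is a significant binding response when

&nbsp;&nbsp;&nbsp;&nbsp;|Δ| = |mean *o*(bound) − mean *o*(free)| ≥ 0.20.

Donor-level maps use the per-frame union over acceptors, with sub-threshold
donors imputed to zero.

**MS side.** Intact deuteration from envelope centroids with in-exchange
(0 s point) subtraction and the D2O-fraction correction
*protons* = Δ*m* / *f*<sub>D2O</sub>; peptide-level
%D = 100 Δ*m* / (*n*<sub>ex</sub> · *f*<sub>D2O</sub>) with
*n*<sub>ex</sub> = length − 1 − internal prolines; free-minus-bound
differential matrices on a blue-white-red palette; shortest-peptide residue
consensus; optional back-exchange correction (÷ (1 − bx)).

**Linkage.** Per-peptide predicted Δprotons = Σ donor Δ-occupancy over the
span, compared with observed Δdeuterons by Spearman rank correlation and sign
concordance; total predicted protection; single-structure H-bond census for
crystal structures (with geometric amide-H placement).

**Synthetic truth.** Generators for flickering two-state H-bond trajectories
on an ideal helix (Markov chains with exact stationary occupancy) and for
deuterated isotope envelopes (Poisson-binomial × natural ¹³C), coupled into
paired free/bound experiments with a known protected residue set.

## Worked example

A paired synthetic experiment with 8 donors (residues 10–17) whose occupancy
shifts by Δp = 0.5 on binding, analysed exactly like a real dataset:

```r
library(hdxmd)
fl <- flicker_spec(n_residues = 30, protected = 10:17, F = 500,
                   replicates = 3, seed = 42)
bundle <- simulate_hdx_experiment(fl, matched_uptake_spec(fl),
                                  time_points = c(0, 20))
topo <- build_topology(bundle$structure)
tab <- differential_hbonds(
  bundle$trajectories[grepl("^free", names(bundle$trajectories))],
  bundle$trajectories[grepl("^bound", names(bundle$trajectories))], topo)
tab
#> <hdx_occupancy_table> 26 H-bonds (26 kept, 8 significant), R=3 free / 3 bound
tab$pairs[tab$pairs$significant,
          c("donor_res", "acceptor_res", "occ_free_mean", "occ_bound_mean", "delta")]
#>    donor_res acceptor_res occ_free_mean occ_bound_mean delta
#> 6         10            6         0.409          0.957 0.549
#> 7         11            7         0.379          0.923 0.545
#> ...                                         (8 rows, donors 10-17)
```

All 8 planted shifts are recovered, none of the 18 stable scaffold bonds is
called. The matched intact spectra give the whole-protein readout:

```r
rec <- intact_uptake_curve(bundle$spectra, bundle$reference_spectrum)
differential_intact(rec, 20)$protected_protons
#> 2.59    # protons protected at 20 s (ground-truth expectation 2.82)
```

and the linkage report ties the two sides together:

```r
dmap <- donor_residue_map(tab, topo)
mat <- differential_matrix(correct_uptake(bundle$peptide_table))
linkage_report(dmap, mat)
#> <hdx_linkage_report> 6 peptides, Spearman rho = 0.971, sign concordance = 0.83
```

The classic intact-mass arithmetic is a one-liner: an 8.8 Da centroid
difference measured in 80 % D2O is

```r
protons_from_shift(8.8, 0.8)
#> 11
```

i.e. ~11 backbone protons gained protection on complex formation.

A command-line front end over the same functions is installed at
`inst/scripts/hdxmd` (subcommands `simulate`, `hbonds`, `diff-hbonds`,
`intact`, `bottomup`, `link`, `crystal-count`), with YAML config, flag
overrides, and byte-deterministic outputs for a fixed seed.

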