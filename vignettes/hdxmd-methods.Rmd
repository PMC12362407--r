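---
title: "Methods: linking MD hydrogen-bond occupancy to differential HDX-MS protection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking MD hydrogen-bond occupancy to differential HDX-MS protection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdxmd)
```

## The measurement model

Backbone amide hydrogens exchange with solvent deuterium at rates governed by
their hydrogen-bonding status: an amide N–H engaged in a stable hydrogen bond
is protected, a free amide exchanges quickly. A differential HDX-MS experiment
measures this protection twice — once for the free protein, once for the
ligand-bound protein — and the difference localizes ligand-induced
stabilization. MD simulations of the same two states provide the complementary
atomistic readout: for every backbone amide donor, the fraction of trajectory
frames in which it is hydrogen-bonded (its *occupancy*). The simplifying
assumption connecting the two, which this package adopts throughout, is that a
hydrogen spending more frames bonded is proportionally more protected, so a
change in occupancy upon binding predicts a like-sized change in the number of
protected protons. This is a semi-empirical bridge, not a kinetic model: no
exchange-rate constants or protection-factor free energies are estimated.

## Hydrogen-bond detection and occupancy

Bonds are detected with the Baker–Hubbard geometric criterion: a
donor/acceptor pair is bonded in a frame iff the distance is at most `d_cut`
(default 2.5 Å) **and** the donor–hydrogen–acceptor angle at the hydrogen is
at least `theta_min` (default 120°). Both boundaries are inclusive. Only
backbone amide N–H donors and backbone carbonyl O acceptors are enumerated by
default; the geometry kernel itself accepts arbitrary atom triplets so
side-chain acceptors can be probed manually. Donors exclude chain-initial
residues, residues directly after a chain break, and prolines — the residues
with no exchangeable backbone amide.

A deliberate interpretive choice: a 2.5 Å cutoff between the *heavy* donor and
acceptor atoms would be sterically implausible (the N–O distance of a good
backbone hydrogen bond is ~2.9–3.0 Å), while 2.5 Å is exactly the canonical
hydrogen–acceptor cutoff. The distance is therefore measured H···O by
default, with `distance_endpoint = "heavy"` available for sensitivity
analysis.

Occupancy is computed per replicate as bonded frames / total frames, then
aggregated as an **unweighted mean over replicates** within each state (not a
pooled-frame fraction); a pair absent from one replicate counts as occupancy 0
there — the bond simply never formed, which is information, not missingness.
The differential is `delta = mean(bound) − mean(free)`.

Two thresholds then structure the output:

* **Lifetime filter** (`lifetime_min`, default 0.40): a bond is kept iff its
  mean occupancy reaches the threshold in *at least one* state. Transient
  bonds below threshold in both states would have exchanged anyway and carry
  no protection signal; a bond stable in either state is informative. The
  boundary is inclusive, with a 1e-9 guard so that means assembled by
  floating-point arithmetic cannot flip a call exactly at threshold.
* **Significance cutoff** (`delta_sig`, default 0.20): a kept bond is called
  significant iff `|delta| >= 0.20` (20 percentage points of occupancy). The
  filter takes precedence — a dropped bond is never significant.

For per-residue maps the package uses the **per-frame union** convention: a
donor's occupancy is the fraction of frames it is bonded to *any* acceptor, so
a donor that swaps acceptors without opening scores 1.0, which is what
exchange protection demands. Donors whose every bond fell below the lifetime
filter are imputed to 0, and donors with no bonds at all appear at 0, so every
amide is present in the map. Because the choice between per-donor-union and
per-pair summaries is genuinely open, a `per_pair` variant (largest kept
shift per donor) is also provided.

## HDX-MS processing

**Intact protein.** Deuteration is measured as the intensity-weighted centroid
of the deconvoluted neutral-mass envelope (5% base-peak threshold by default;
`threshold = 0` gives the exact full-envelope centroid). Each state's nominal
0 s point estimates in-exchange and is subtracted from that state's own curve.
The centroid difference is converted to protons by the D2O-fraction
correction alone: `protons = delta_mass / f_d2o`, so an 8.8 Da difference at
80% D2O is 11 protons. Back-exchange (default estimate 0.30, from a fully
deuterated standard via `back_exchange_fraction()`) is deliberately **not**
applied by default — the headline differential numbers in this workflow are
conventionally reported with the D2O correction only — but
`apply_backexchange = TRUE` divides by `1 − back_exchange` where the absolute
scale matters. Ligand saturation under assay conditions is checked with the
exact 1:1 binding quadratic (`ligand_saturation()`), since a protection
difference is only interpretable when the bound sample is actually bound.

**Bottom-up.** Peptide-level percent deuteration uses
`%D = 100 · Δm / (n_ex · f_d2o)` with `n_ex = length − 1 − (internal
prolines)` — the common convention that discounts only the peptide's
N-terminal residue; it is configurable in spirit by supplying your own
counts. The free-minus-bound matrix is displayed on a blue-white-red palette
that is symmetric about zero and saturates red at the maximum observed
positive (protection) cell. Residue-level consensus takes, for each covered
residue, the value of the *shortest* covering peptide (ties to the smaller
start): the shortest peptide carries the highest spatial resolution. Peptides
observed in only one state are reported as missing rows, never dropped
silently.

## The linkage metric

Observed peptide differentials are converted from `%D` to absolute deuterons
(`Δ%D · n_ex · f_d2o / 100`) so both axes are proton counts, then compared at
a single reference time (default 20 s, the exchange time at which total
deuteration correlates best with the hydrogen-bond census of a folded
structure). The per-peptide prediction is the sum of donor-map differentials
over the peptide span; the total predicted protection sums positive gains
only, with losses totalled separately and the count of donors at or above
`delta_sig` reported alongside. Agreement is quantified two ways — Spearman
rank correlation across peptides and the fraction of sign-concordant
peptides — because the appropriate strength-of-agreement statistic for this
semi-empirical comparison is itself an open question.

`count_structure_hbonds()` applies single-frame detection to a crystal
structure (placing amide hydrogens geometrically if absent) to give the
bonded/total amide census that anchors the intact-HDX numbers.

## Amide hydrogen placement

Crystal structures usually lack hydrogens, and the angle term of the
detection criterion needs them. For each eligible donor the amide H is placed
at 1.01 Å from N, in the C(i−1)–N–CA plane, along the direction opposite the
bisector of the C(i−1)→N and CA→N unit vectors. This construction is exact on
ideal peptide geometry, rotation/translation equivariant, and deterministic.

## Synthetic ground truth

Because real trajectories and raw LC-MS data for any given system are rarely
depositable at test scale, the package ships generators that emulate the two
phenomena the pipeline must recover, with known truth:

* **Flickering bonds** (`flicker_spec()` / `simulate_two_state_trajectory()`):
  an ideal poly-alanine α-helix (φ = −57°, ψ = −47°, ideal bond geometry;
  every i→i−4 bond satisfies the default criterion at H···O = 2.11 Å, 165°)
  in which designated donors flicker as two-state Markov chains. The
  persistence parameter `q` is the probability of keeping the current state
  at each step, otherwise the state is redrawn Bernoulli(p); this keeps the
  stationary bonded probability exactly `p` for any `q` and makes the lag-1
  autocorrelation equal to `q`, so the effective number of independent frames
  is `F_eff = F(1−q)/(1+q)` — the quantity used in recovery tolerances. Open
  frames displace the acceptor oxygen along the H→O axis to `1.5 · d_cut`,
  unambiguously breaking the bond.
* **Deuterated envelopes** (`uptake_spec()` /
  `simulate_deuterated_envelope()`): independent-site (EX2-like) exchange
  with first-order per-amide kinetics
  `p_i(t) = 1 − (1 − in_exchange)·exp(−k_i t)`, an incorporation probability
  `p_i · f_d2o · (1 − back_exchange)` per amide, a Poisson-binomial deuteron
  distribution computed by exact convolution, and a binomial natural ¹³C
  envelope. Points are laid out on exact masses (ΔmD = 1.00628 Da,
  Δm¹³C = 1.00336 Da) and points sharing a 0.01 Da bin are merged by
  intensity-weighted mean mass — merging this way (rather than snapping to
  bin centers) preserves the full-envelope centroid exactly, so
  centroid-level identities hold to numerical precision (≈1e-12 observed).
* **Paired experiments** (`simulate_hdx_experiment()` with
  `matched_uptake_spec()`): one protected residue set drives both sides — the
  occupancy shift in the trajectories and the exchange suppression in the
  spectra, coupled so that the exchange-probability difference at the
  reference time equals the occupancy shift Δp. Peptide centroids are exact
  expectations (noise-free) so that recovery failures isolate pipeline
  defects rather than sampling noise.

Default generator conditions, fixed once: a 30-residue helix, 500 frames per
trajectory, 3 replicates per state, persistence `q = 0.85` (strongly
autocorrelated flicker, as transient loop bonds show), 8 protected donors
(residues 10–17) shifting from `p_free = 0.45` to `p_bound = 0.95`
(Δp = 0.5), remaining scaffold donors at 0.97 in both states, 80% D2O, 30%
back-exchange, 5% in-exchange, and a 0/20/40/80/160 s time grid. These mirror
a triplicated 500-frame simulation design with a strongly stabilized loop.

**What the generators do not emulate** — and hence what passing tests do not
show about real data: force-field physics and concerted conformational
change (bonds flicker independently), correlated EX1 exchange, realistic
peptic digestion (peptide spans are user-chosen), chromatographic or
deconvolution artefacts, and measurement noise on peptide centroids.

## Numerical choices and degenerate inputs

* Detection boundaries are inclusive; occupancy thresholds carry a 1e-9
  floating-point guard.
* Coincident hydrogen and acceptor coordinates raise an undefined-angle
  error rather than returning an arbitrary angle.
* Multi-model trajectories must have a constant atom count; the first model
  defines the reference topology. Structures round-trip through PDB text at
  the format's 3-decimal (1e-3 Å) precision.
* The binding quadratic uses the numerically stable root and guards the
  discriminant at relative 1e-9.
* Per-residue B-factor projection writes `100 × value` clipped to
  [−99.99, 999.99] in columns 61–66.
* Spearman correlation requires ≥3 peptides; below that the report carries a
  warning status and omits the coefficient rather than fabricating one.

## Problem sizes

The shipped test-scale conditions (30-residue helix, F = 500, R = 3 per
state) were chosen as the smallest design that exercises replicate
aggregation, the lifetime filter, and the significance call with comfortable
statistical margins: at `q = 0.85`, `F_eff ≈ 40` per replicate, so a planted
Δp = 0.5 sits >3 standard errors from the 0.20 cutoff with three replicates.
Property suites use 8–12-residue systems where an exhaustive double-loop
oracle is cheap.

## Known limitations

* Occupancy is a frame-count statistic; no attempt is made to convert it to
  exchange rates or protection free energies, so the linkage is ordinal in
  spirit (hence rank correlation).
* Only backbone–backbone bonds enter the default enumeration; side-chain
  acceptor bonds contribute real protection that this census misses.
* Whether occupancy differences should be computed on pooled frames rather
  than replicate means is unstated in common practice; the package fixes
  replicate means and retains per-replicate values for spread reporting.
* The amide inventory of a construct (tags, N-terminus) is reported from the
  package's own topology definition; published totals counted by other
  conventions can differ by a few amides.
```{r}
# a compact end-to-end run at reduced scale
fl <- flicker_spec(n_residues = 16, protected = c(9, 10, 11), F = 100,
                   replicates = 2, seed = 1)
bundle <- simulate_hdx_experiment(fl, matched_uptake_spec(fl),
                                  time_points = c(0, 20))
topo <- build_topology(bundle$structure)
tab <- differential_hbonds(
  bundle$trajectories[grepl("^free", names(bundle$trajectories))],
  bundle$trajectories[grepl("^bound", names(bundle$trajectories))],
  topo
)
tab
donor_residue_map(tab, topo)
```
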