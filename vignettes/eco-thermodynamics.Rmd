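---
title: "Eco-thermodynamics of methanogenic communities: models and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Eco-thermodynamics of methanogenic communities: models and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecothermo)
```

# The problem

In methanogenic ecosystems (anaerobic digesters, sediments, guts), organic
matter is mineralised by a cascade of fermenting and syntrophic organisms
whose electrons converge on a shared H~2~ pool. Many catabolic reactions are
exergonic only while H~2~ stays low: butyrate oxidation to acetate, for
example, is operable only below a few pascals of H~2~ when butyrate itself
sits at the micromolar levels typical in situ, while glucose fermentation
remains favorable beyond a kilopascal. This package quantifies that
asymmetry — the *H~2~ conflict* — and propagates it through genome-resolved
community analysis: which organisms encode H~2~-sensitive (HS) metabolisms,
which routes they use to dispose of electrons (H~2~, formate, O~2~,
extracellular transfer), and whether their transcriptomes show those
pathways running.

# Gibbs energies

## Formation energies and standard states

All reaction energies are sums of standard transformed Gibbs energies of
formation (ΔG~f~°′, kJ/mol, 298.15 K, pH 7) over a bundled,
versioned constants table (`formation_energies()`), compiled from the
classical anaerobic-bioenergetics literature (Thauer-convention values,
with NBS-style enthalpies where those exist). Conventions:

* aqueous species: standard state 1 M, activities are molar concentrations;
* gases: standard state 1 atm (101 325 Pa); user-facing pressures are Pa;
* liquid water: unit activity;
* H^+^: enters only through pH. The table stores pH-7 transformed values,
  so at pH 7 no extra term appears; at pH ≠ 7 each net proton
  contributes RT ln10 (7 − pH).

Ionic-strength and activity-coefficient corrections are out of scope:
activities equal concentrations. HCO~3~^−^ is treated as the stated
species (no CO~2~ speciation).

A handful of table rows (branched fatty-acid isomers, one aqueous thiol)
have no primary tabulated value; they are estimated from isomerisation
equilibria or gas-phase values plus a Henry's-law transfer term, and are
marked in the table's `source` column. These estimates are the package's
own synthesis, not literature values.

## Temperature correction

The table is at 25 °C; the default in-situ conditions are 37 °C.
When *every* compound in a reaction has a tabulated enthalpy of formation,
the standard energy is extrapolated per compound with the Gibbs–Helmholtz
relation, ΔG°(T) = ΔH° − (T/298.15)
(ΔH° − ΔG°~298~). When any compound lacks an
enthalpy, the whole reaction is evaluated with the 298.15 K free energies
(only the explicit RT terms feel the temperature). We deliberately do
*not* mix corrected and uncorrected compounds within one reaction:
partial correction produces hybrids that are inconsistent with either
regime (for butyrate oxidation the hybrid moves the H~2~ threshold
several-fold away from both consistent answers). Enthalpies are shipped
for water, the gases, C1 species, acetate and glucose — species with
well-established calorimetric values — and intentionally omitted for
higher fatty acids and amino acids, where aqueous-ion enthalpies vary
across compilations by more than the 12 K extrapolation is worth.
Consequences of this choice are visible and documented: reactions of the
C1/sugar economy are fully temperature-corrected, fatty-acid and
amino-acid reactions are pinned to 298 K free energies, and the
acceptance checks on thermodynamic reproductions carry a stated
±15% band for exactly this reason.

## In-situ conditions

`digester_conditions()` encodes the default condition set: 37 °C,
pH 7, 300 µM acetate, 10 µM other fatty acids, 1 mM
NH~4~^+^, 50 mM HCO~3~^−^, 50 kPa CH~4~, 3.9 × 10^−4^ atm
H~2~S, 2.5 µM formate (the in-situ digester estimate), and 0.1
µM for every other aqueous compound. ΔG~ATPsynthesis~ = 60
kJ/mol. Dissolved O~2~ is supplied in nM and converted to an effective
partial pressure through a fixed Henry constant of 1.3 × 10^−3^
M/atm (documented here because the literature states nanomolar
concentrations without a pressure convention).

# ATP yields and the carrier ledger

Each pathway carries a ledger of ATP and reduced-carrier counts per
reaction turnover. Net ATP is

ATP~gen~ − ATP~cons~ − x·ΔNADH + x·ΔFdH~2~
− 2x·ΔETFH~2~ − 2x·Δquinol,

with x the ATP synthase ATP:H^+^ ratio (1/3 for organotrophy, 1/5 for
methanogenesis and for propionate/acetate oxidation, 1/4 for
isovalerate). The weights are ion-translocation equivalents: NADH
re-oxidation to H~2~/formate costs one reverse-electron-transport loop
(x), reduced ferredoxin re-oxidation through ion-pumping complexes
*recovers* x per electron, and ETF and quinol each cost two loops (2x).
**Ferredoxin is counted per single electron transferred** (one reduced
2-electron ferredoxin = 2 units); NADH, ETF and quinol are counted per
2-electron carrier. Only this basis reproduces the canonical worked
examples: glucose → 2 acetate (4 ATP, 2 NADH, 4 ferredoxin units,
x = 1/3) yields 4.67, and butyrate → 2 acetate (1 ATP, 1 ETFH~2~,
the β-oxidation NADH disposed at no ion-motive cost under the
shortest-electron-route convention) yields 0.33. Cytosolic,
non-ion-translocating H~2~ generation from reduced ferredoxin or NADH is
not an allowed route in any ledger.

Ledgers beyond those two worked examples (propionate, isovalerate,
acetate oxidation, the methanogenesis variants, the amino acids) are
best-effort reconstructions from standard anaerobic biochemistry and are
marked `canonical: false` in the catalog. Where a pathway's membrane
electron flow traverses two ion-costing loops (succinate →
menaquinone → formate in propionate oxidation), the ledger counts
the quinol slot twice; the ledger is bookkeeping of translocation
equivalents, not an enzyme census. The methyl-reducing methanogenesis
ledger credits one 2-electron ferredoxin per CH~4~ (Mvh/Hdr
bifurcation re-oxidised with ion translocation), i.e. ATP = 2x = 0.4 at
x = 1/5.

# H~2~ thresholds and HS/HT classification

ΔG is affine in ln p~H2~, so the threshold pressure solving
ΔG~reaction~ + ATP·ΔG~ATPsynthesis~ = 0 has a closed form
(`h2_max()`), checked in the tests against a bisection oracle. For
H~2~-producing pathways it is the maximum tolerable pressure; for
H~2~-consuming ones, the minimum usable pressure. Pathways with
threshold below 100 Pa are H~2~-sensitive (HS), at or above it
H~2~-tolerant (HT); the boundary value itself is classified HT, a
convention fixed in `HS_HT_BOUNDARY_PA` (the defining inequalities are
strict on both sides and leave the point undefined). A reaction with no
H~2~ term (lysine fermentation, acetoclastic methanogenesis) has no
threshold and is reported as not applicable rather than forced into a
class.

`o2_redirect()` rebuilds the balanced reaction when a fraction of the
H~2~-equivalent electron pairs reduce O~2~ to water instead of protons
to H~2~ (bd-oxidase style, no ion translocation credited), then
recomputes the threshold and in-situ ΔG — the mechanism by which a
strict anaerobe can roughly double its H~2~ ceiling with 1% of electrons
at 50 nM O~2~. `formate_h2_equivalence()` converts a formate
concentration to the H~2~ pressure with the same electron-carrying
power via the formate/bicarbonate couple.

## A documented residual

The methyl-reducing methanogenesis minimum computes to ≈ 0.26 Pa
under default conditions, above the ≈ 0.1 Pa cited for this
metabolism. The discrepancy traces to aqueous methanethiol, for which no
primary transformed formation energy exists; the shipped value (−7.59
kJ/mol) is derived from the gas-phase value and a Henry's-law transfer
term. Reproducing 0.1 Pa would require −5.15 kJ/mol, a value we
cannot source, so the computed number is reported as-is rather than the
constant being tuned. The qualitative conclusion — methyl-reducing
methanogens can pull H~2~ roughly an order of magnitude below the
H~2~/CO~2~ minimum of ≈ 1.7 Pa — is unaffected.

# Rule-based metabolic reconstruction

A capacity is asserted for a MAG and pathway only when four criteria
hold simultaneously (`capacity_predict()`):

1. **Completeness** — every enzyme step has at least one gene carrying
   one of the step's alternative ortholog labels.
2. **Carrier re-oxidation** — every electron carrier the pathway
   generates reaches at least one disposal sink (H~2~ via encoded
   hydrogenase classes, formate via formate dehydrogenases, O~2~ via bd
   oxidase, extracellular transfer via validated multiheme cytochromes)
   through the directed graph of encoded transfer enzymes (Rnf:
   NADH↔Fd; Nfn: NADPH↔NADH/Fd; Fix: ETF→quinol; Efd:
   ETF→Fd; Flox-Hdr: NADH→Fd; plus Ndh). Reachability is
   computed with igraph and tested against exhaustive path enumeration.
3. **Energy conservation** — ledger ATP yield > 0.
4. **In-situ exergonicity** — net ΔG < 0 under the default
   conditions. In-situ H~2~ spans roughly 0.1 Pa (methyl-reducing
   partner methanogens) to 10 Pa (bulk digester measurements), so
   H~2~-producing pathways are checked at the low end and H~2~-consuming
   pathways at the high end of that span. This makes the criterion
   discriminative: pathways whose ceiling sits below even the lowest
   maintainable H~2~ (some branched-chain amino-acid oxidations under
   the shipped constants) are rejected as not exergonic.

Pathways whose directionality cannot be resolved from sequence alone
(alanine, glutamate, aspartate under this catalog) are always emitted
with an `ambiguous` flag and never silently counted as capacities.
Capacities are predicted per MAG first and only then unioned over the
species cluster, so no chimeric reconstruction can arise; both levels
are retained.

**Multi-subunit complexes** (Rnf, hydrogenases, formate dehydrogenases,
bd oxidase, …) are credited only when their subunits co-localise:
one contig, same strand, consecutive with intergenic gaps ≤ 500 bp
(`OPERON_GAP_MAX`, configurable) — or split across exactly two contig
ends, each partial run terminating at a contig boundary. "Boundary" is
judged against the annotated gene order, since contig lengths are not
part of the annotation input.

**Sequence rules.** Conductive pilins: aromatic residues {F, W, Y, H}
(the aromatic set is a documented constant; histidine is included as
aromatic) must make up ≥ 9% of the peptide *and* every disjoint
20-residue window must contain at least one aromatic — "evenly
distributed" is implemented as disjoint windows, not sliding ones, a
deliberate disambiguation. Multiheme cytochromes: ≥ 2 CXXCH
heme-binding motifs (overlap-aware, case-insensitive; `heme_min`
configurable) on a protein whose supplied localization is membrane or
extracellular — signal-peptide and transmembrane prediction are inputs,
not computations.

**Species clustering** is single-linkage over the pairwise mutation
distance graph at cutoff 0.05 (≈ 95% ANI), with deterministic labels
(lexicographically smallest member).

# Metatranscriptomic activity

RPKM values are normalised per MAG to the **median of non-zero** RPKM of
its coding genes (the plain median is a documented switch; the non-zero
form is the default because silent genes otherwise deflate the reference
level of partially expressed genomes). Normalisation is scale-invariant
and idempotent. A pathway is *active* in a reactor when every step's
best gene has replicate-averaged (arithmetic mean over the triplicate)
normalised level ≥ 1.

Cluster activity fractions are reported with two denominators: all
mapped reads, and — after a first activity call on the all-reads
denominator — reads mapped to active species only. The ambiguity between
the two conventions is surfaced, not hidden; both columns appear in the
output. A cluster is *active* when its fraction reaches 0.4% (bacteria)
or 0.3% (archaea) in at least one reactor. A cluster *consistently
expresses* a pathway (ECM50) when the pathway is active in at least 50%
of qualifying reactors — those where the cluster holds ≥ 0.05% of
the mapped metatranscriptome; with no qualifying reactor the call is
undefined (NA), never FALSE.

# Community statistics

Pearson correlations use the product-moment formula with two-sided
p-values from the t transform on n − 2 degrees of freedom; group
comparisons use Student's pooled-variance two-sided t test (the
spreadsheet T.DIST convention) with a Welch switch; both are verified
against the stats-package reference implementations to 10^−8^. No
multiple-testing correction is applied by default, matching the practice
of reporting raw p-values in this literature; `p.adjust` can be applied
downstream. PCA is centered, unit-variance scaled (constant columns
dropped with a note), with component signs fixed
largest-loading-positive so results are row-order invariant, and with
normal-theory 95% ellipses (chi-square quantile on the 2×2 score
covariance) per group — ≥ 3 rows required per ellipse.

# The synthetic community

`generate_community()` plants a nine-reactor digester panel
(25–55 °C, triplicate metatranscriptomes) with niches drawn from
the template set: hydrolytic HS+HT couplers, a formate-only fatty-acid
syntroph (formate dehydrogenases, no hydrogenase), an O~2~-respiring
anaerobe, a conductive-pili/cytochrome electrogen, an acetoclastic
archaeon with formate uptake, a methyl-reducing methanogen (absent from
the thermophilic reactors), an H~2~-tolerant fermenter, and an inactive
residual niche held at ≈ 0.2% abundance so the activity thresholds
must exclude it. Expression is baseline × log-normal noise
(σ = 0.5 by default, the regime in which planted active genes clear
the normalised threshold in ≥ 95% of calls); read counts are
multinomial around the planted abundance profile; within-cluster MAG
distances are ≤ 0.04 and between-cluster ≥ 0.1 (distances are
generated directly; genome-sketch distance computation is out of
scope). Everything is a deterministic function of the seed, and a
ground-truth ledger records every planted capacity, activity and ECM50
expectation for scoring.

What the generator does *not* emulate — and therefore what passing
round-trip tests do not establish about real data: annotation error and
ortholog mislabeling (labels are drawn from the catalog vocabulary),
partial-gene and frame-shift artifacts of assembly, strain heterogeneity
within clusters, compositional coupling between niches, and read-mapping
ambiguity. The generator's dropout knob removes whole genes, which
mimics incomplete MAGs but not misannotation.

## Problem sizes

The default community is deliberately desk-scale: 9 niches, 11 MAGs, 9
reactors × 3 replicates, ≈ 18 000 expression records, a
20-pathway catalog. The round-trip acceptance checks run 20 seeds at
σ = 0.5; the solver-vs-oracle check uses 50 randomized reactions;
null statistics use 400 simulations. The community-scale counts of a
full survey (hundreds of MAGs, thousands of genes per genome) are not
reproduced at this scale, and the statistics stage is validated by
procedure and calibration (reference agreement, type-I error), not by
matching any survey's printed p-values.

# Numerical choices and degenerate inputs

* Closed-form threshold solving is exact in ln p; the tests require
  agreement with bisection to < 0.1% and a residual |ΔG| <
  10^−6^ kJ/mol at the solved pressure.
* Rational stoichiometries (½ O~2~) are plain doubles; balance
  checking tolerates 10^−9^ per element.
* All-zero reactions have ΔG = 0; all-zero expression vectors give
  NA normalised levels with a warning; empty qualifying-reactor sets
  give NA ECM50 calls; zero-variance features give NA correlations —
  degenerate cases are reported, never silently coerced.
* Randomness is routed through the single community seed; generation
  restores the caller's RNG state.

# Known limitations

* The constants table is small and curated for the catalog's reactions;
  adding pathways may require adding compounds (the loader validates
  element and charge balance on entry).
* Thresholds for amino-acid pathways inherit the larger uncertainties of
  amino-acid formation energies; their HS/HT side of the 100 Pa boundary
  is robust, their absolute values less so.
* The carrier-reoxidation graph abstracts enzyme specificity into a
  small node set; bifurcating enzymes are represented by their edge
  pairs, not by joint constraints on both branches.
* Localization (signal peptide / transmembrane) is trusted input; the
  multiheme-cytochrome call is only as good as that metadata.
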