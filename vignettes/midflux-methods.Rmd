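---
title: "Methods: stable-isotope tracing flux analysis with midflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stable-isotope tracing flux analysis with midflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(midflux)
```

## The measurement and its models

A constant-rate tracer infusion (jugular-vein catheter, syringe pump at
0.1 uL/min per g body weight) is run for about 2.5 h so that circulating
and tissue labeling plateau. Everything in this package rests on that
pseudo-steady-state assumption: the algebra below is steady-state algebra,
and none of it is valid for pre-plateau time courses (no compartmental or
kinetic flux modeling is attempted).

The atomic data unit is the **mass isotopomer distribution** (MID): the
fractions `f[0..N]` of a metabolite's isotopologues M+0..M+N, where N is
the number of atoms of the tracer element. Two scalar summaries drive all
estimators:

* the **atom fraction** `L = sum(i * f[i]) / N`, the proportion of
  tracer-element atoms carrying label, and
* the **normalized labeling** `L_{Y<-X} = L_Y / L_X`, the labeling of a
  downstream metabolite Y relative to the infused tracer X.

### Natural-abundance correction

Measured MIDs are contaminated by naturally occurring heavy isotopes
(1.07% 13C above all). `build_correction_matrix()` constructs the forward
operator M whose column j is the expected measured MID of a molecule with
exactly j labeled atoms; `correct_mid()` inverts it by solving

    minimize ||M x - raw||_2   subject to   x >= 0,

then renormalizing x to sum to 1. The non-negativity constraint (rather
than an unconstrained solve followed by clipping) is deliberate: clipping
after the fact biases small fractions upward, while the constrained
least-squares fit is the standard remedy and is what the tests'
adversarial-noise property checks. Numerically, M is lower triangular with
a positive diagonal, so the exact triangular solve *is* the unconstrained
least-squares solution; the implementation accepts it whenever it is
already feasible and falls back to Lawson–Hanson NNLS
(`pracma::lsqnonneg`) otherwise. The fit residual is kept as a QC field.

Two resolution modes exist because what interferes with an isotopologue
peak depends on the instrument. The default `"high"` mode assumes the
140,000-resolution Orbitrap class of instrument, which mass-resolves 15N
and 2H satellites away from 13C isotopologues: only the tracer element's
own isotopes enter the matrix. `"unit"` mode convolves the natural
patterns of every element in the formula, as appropriate for
unit-resolution data. Default abundances are standard IUPAC values (13C
0.0107, 2H 0.000115, 15N 0.00364, plus O and S minor isotopes),
overridable via a delimited file (`read_isotope_abundances()`).

The U-13C,15N glutamine tracer is treated as a carbon tracer (N = 5
carbons) throughout, since every readout taken from it is a carbon-fate
readout; in high-resolution mode its 15N shifts are resolved away and
never enter the matrix. A limitation: `"unit"` mode models *natural* 15N
only, not the tracer's own enriched nitrogen, so dual-label glutamine data
should be corrected in the default high mode.

### Circulatory turnover flux

For an infused metabolite, serum labeling dilutes endogenous production:
`F_circ = R (1 - L) / L`, with `R = concentration (mmol/L) x pump rate
(uL/min/g)` in nmol/min per g. The estimate diverges as `L -> 0`, so
labeling below `l_min` (default 0.005) is refused rather than returned;
the threshold is configurable and exists purely as a numerical guard —
with the reference concentrations (glucose 500, glutamine 150, methionine
15/30 mmol/L) serum enrichments land in the 5–30% range where the
estimator is well conditioned.

### Direct nutrient contributions

With one infusion arm per circulating nutrient, the normalized labeling of
a tissue target under arm j satisfies

    measured[j] = sum_i cross[j, i] * f[i],    cross[j, j] = 1,

where `cross[j, i]` is the serum labeling of nutrient i normalized to the
infused tracer j (metabolic interconversion, e.g. glucose carbon appearing
in serum glutamine), and `f[i]` is the direct contribution of nutrient i.
`direct_contributions()` solves this square system. The cross matrix is
indexed arm-by-nutrient (rows are infusion arms); with the conventional
two-nutrient system the worked example
`cross = [[1, 0.2], [0.3, 1]], measured = [0.5, 0.4]` eliminates to
`f = (0.4468, 0.2660)`.

Contributions are fractions by construction, so the default solve is
box-constrained to `[0, 1]` (projected quasi-Newton on the least-squares
objective with analytic gradient; interior solutions shortcut to the exact
solve, which is identical there). The unconstrained exact solution is
always reported alongside, and entries pinned at a bound are flagged, so
boundary-active estimates are visible rather than silent. Systems with
condition number above 1e8 are rejected as singular. Normalized labelings
are sanity-bounded to `[0, 1.5]` — values slightly above 1 can occur with
noise, values beyond that indicate a labeling or pairing error.

Because the serum cross terms and the tissue measurements come from
*different animals* (different infusion arms), a per-animal joint solve
does not exist in this design. The default therefore averages per-animal
atom fractions within each diet x state group (mean labeling first, ratios
second) and solves once per group; a `per_animal` option pairs animals by
index across arms for users who want a per-animal spread. Uncertainty of
the solved contributions comes from a nonparametric bootstrap (default
1000 seeded draws) that resamples animals within each arm and reruns the
entire mean-ratio-solve chain, keeping resampled cross terms and measured
vectors internally consistent; intervals are 2.5/97.5 percentiles.

### De novo lipogenesis from heavy water

After 2H2O in drinking water (20% for 9 days in the reference protocol),
newly synthesized fatty acids incorporate deuterium from body water.
`lipogenesis_enrichment()` reduces a 2H-corrected fatty-acid MID to the
mean number of labeled hydrogens per molecule, `sum(i * f[i])`, and
divides by `n_exchangeable_H x water_enrichment`. With the default
`n_exchangeable_H = 1` the result is the plain water-normalized labeling
fraction; setting it to the number of water-derived hydrogens per
molecule (defaults 22 for C18:1 and C18:0, 20 for C16:0, following the
usual count of exchangeable positions in palmitate/oleate synthesis)
rescales it to a newly synthesized fraction. Body-water enrichment is an
input column per animal, not a constant: protocols differ in whether they
use measured serum water enrichment or the nominal intake value, and the
pipeline deliberately takes whatever the user measured.

### Protein synthesis and clinical formulas

Relative protein synthesis after a 13C-methionine infusion is
`protein content x (tissue-protein Met labeling) / (serum Met labeling)`,
normalized to the control-diet group mean per tissue. HOMA-IR is
implemented exactly as the mass-unit formula
`insulin (uU/mL) x glucose (mg/dL) / 22.5`; note that the widespread
variant divides *molar* glucose by 22.5 (equivalently mg/dL by 405), so
values from this function are on the mass-unit/22.5 scale — the
documentation of `homa_ir()` flags this. OGTT summary uses trapezoidal
integration, the field's standard in the absence of a stated rule.

## The forward simulator

`generate_experiment()` produces a complete experiment — serum panels per
arm, tissue targets, a 2H2O fatty-acid arm, manifest, truth record — in
the same table dialect the readers consume. Ground truth defaults are
chosen once as realistic refed-mouse magnitudes: circulatory fluxes around
150 (glucose), 60 (glutamine) and 20 (methionine) nmol/min per g with a
seeded ±20–25% spread per diet/state; serum cross-labelings
`L_{gln<-glc} = 0.15`, `L_{glc<-gln} = 0.05`; per-tissue contribution
vectors drawn with glucose dominant and total modeled contribution capped
at 0.9; newly synthesized lipid fractions 0.1–0.6; body-water 2H
enrichment 2%, the scale at which the lipogenesis arithmetic in this
package is exercised.

The measurement model, in order:

1. a true within-molecule distribution — an unlabeled/fully-labeled
   mixture for the infused tracer itself (a U-13C tracer molecule is
   either entirely heavy or entirely endogenous), a per-atom binomial for
   downstream metabolites (adequate because every estimator consumes atom
   fractions, not positional isotopomers), and an
   unlabeled/newly-synthesized mixture with binomial water-hydrogen
   incorporation for fatty acids;
2. convolution with natural abundance via the same forward matrix the
   correction inverts;
3. censoring of isotopologues whose noise-free expected fraction falls
   below a detection limit (never M+0). The limit defaults to the MID
   noise sd itself: peaks indistinguishable from the noise floor are not
   integrated by peak-picking software, and real exports simply lack those
   rows. Tying the limit to the noise level also means a noise-free
   simulation censors nothing, preserving exact identifiability;
4. additive Gaussian noise (sd `mid_sd`, default 0.005) on the retained
   fractions, clipped at zero and renormalized — the fraction-level error
   typical of well-integrated isotopologue ratios;
5. scaling to intensities with a per-sample log-normal total-signal factor
   (CV `intensity_cv`, default 5%). This factor multiplies all
   isotopologues of a sample together, as loading/ionization variation
   does, and therefore cancels exactly when fractions are re-formed — it
   makes the tables look like instrument output without changing any
   estimate.

Inter-animal biological variability is multiplicative Gaussian jitter on
the true labeling quantities (CV `animal_cv`, default 5%). Identical
config and seed give byte-identical output files.

What the simulator does *not* emulate — chromatography, ionization
efficiency differences between isotopologues, tracer impurity, positional
isotopomer structure, kinetic labeling curves — bounds what passing
recovery tests show: they validate the estimators against the stated
steady-state models, not against every artifact of real LC-MS data.

## Validation scale and numerical choices

The test suite validates by parameter recovery at deliberate sizes:
noise-free identifiability to machine precision on the full default design
(two diets, eight tissues, three targets); 200 seeded replicates of a
one-diet, two-arm, five-animal experiment at measurement noise sd 0.005
for flux and contribution recovery; 24 replicate arms per truth level for
lipogenesis recovery; 100 random formulas (up to 30 carbons) for the
correction round trip; and brute-force grid search (step 1e-3 on
`[0, 1]^2`) as the independent oracle for the constrained solver. These
sizes keep the whole suite at a few minutes on one core while leaving the
recovery criteria statistically meaningful.

Numerical details worth knowing: correction matrices are cached per
(formula, tracer, dimension, mode, abundance table); MIDs shorter than
N+1 are zero-padded before correction, and isotopologues beyond M+N are
dropped with a warning; all-zero and negative-beyond-tolerance
measurements are classed errors, not silent NAs; every declared failure
mode carries a condition class (`midflux_*`) that the CLI maps to exit
status 1 (analysis errors) or 2 (usage errors).

## Known limitations

* Steady-state only; no ODE-based metabolic flux analysis.
* No tracer-impurity correction (isotopic purity of the infusate is
  assumed 1).
* The binomial downstream-labeling model ignores positional information;
  fine for atom-fraction estimators, wrong for isotopomer-resolved work.
* `unit` resolution mode does not model enriched (non-natural) secondary
  labels such as the 15N of dual-label glutamine.
* Bootstrap intervals quantify animal-resampling uncertainty only, not
  systematic errors such as unmodeled nutrients in the cross system.
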