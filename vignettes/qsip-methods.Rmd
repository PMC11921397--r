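---
title: "Quantitative stable isotope probing with qsipr: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative stable isotope probing with qsipr: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsipr)
```

## The measurement

DNA stable isotope probing (SIP) feeds a community a substrate enriched in a
heavy isotope — here `^13`C-labeled acetate against a `^12`C control — and
asks which taxa assimilated it. Organisms that built the label into their
genomes produce denser DNA, and isopycnic CsCl centrifugation converts that
mass difference into a position difference along a buoyant-density gradient.
The gradient is recovered as ordered fractions (twelve in the design this
package mirrors), whose densities are read by refractometry
(`ri_to_density()`), and which are sequenced either individually or pooled
into three canonical density groups — light, medium (intermediate) and heavy
(`density_group_scheme()`, `assign_density_group()`).

Quantitative SIP (qSIP) turns the resulting amplicon counts into a
per-taxon estimate of isotope incorporation. The observable is the taxon's
**weighted average density** (WAD) over a core's fractions or groups,

$$W = \sum_i x_i \rho_i,$$

with \(x_i\) the taxon's abundance in fraction \(i\) normalized over the
fractions used and \(\rho_i\) the fraction's density (`compute_wad()`).
Comparing \(W\) between labeled and unlabeled replicate cores gives the
density shift \(Z = W_{lab} - W_{light}\), which the chain of
`gc_from_wad()`, `molecular_weight_light()`, `heavy_max_mass()`,
`labeled_mass()` and `atom_fraction_excess()` converts to **atom fraction
excess** — the fraction of the taxon's carbon that is `^13`C above natural
abundance (reported as atom percent excess, APE, when multiplied by 100).

## The enrichment chain

The chain rests on linear empirical relations plus nucleotide composition:

* GC content from unlabeled density:
  \(G = (W_{light} - 1.646057)/0.083506\).
* Mean nucleotide weight of unlabeled DNA:
  \(M_{light} = 0.496\,G + 307.691\) g/mol.
* Carbon atoms per average nucleotide from base composition:
  \(N_C(G) = 10 - 0.5\,G\) (A, T and G nucleotides carry ten carbons,
  C carries nine).
* Mass ceiling at full substitution:
  \(M_{heavymax} = M_{light} + N_C(G)\,(1 - b)\,\Delta m\), with
  \(b = 0.01111233\) the natural `^13`C atom fraction already present in
  \(M_{light}\) and \(\Delta m = 1.003355\) Da the isotope mass
  difference.
* Labeled mass from the proportionality of relative density and relative
  mass change: \(M_{lab} = (Z/W_{light} + 1)\,M_{light}\).
* Atom fraction excess:
  \(A = \dfrac{M_{lab} - M_{light}}{M_{heavymax} - M_{light}}\,(1 - b)\).

All constants live in `enrichment_constants()` and are overridable; only
the background \(b\) and \(\Delta m\) are physical, the others are
empirical calibrations. Negative \(A\) (labeled WAD below unlabeled) is
reported as-is — activity calling, not clipping, enforces positivity.

Running the chain in reverse (`forward_density_shift()`) predicts the
density of labeled DNA and is the physics of the simulator. The chain is
self-consistent: `atom_fraction_from_shift()` inverts it to machine
precision, and two printed anchors fall out of it directly — DNA at
1.700 g/mL labeled at 99 atom % bands at 1.75 g/mL (two decimals), and a
zero shift returns exactly the background atom fraction. The
`scripts/acceptance.R` script recomputes both.

```{r anchors}
round(forward_density_shift(1.700, atom_fraction = 0.99), 2)
atom_fraction_from_shift(1.72, 1.72)
```

## Replicate-core bootstrap and activity calling

Replicate soil cores — not fractions, not reads — are the exchangeable
unit, and there are few of them (two or three per treatment). All
uncertainty statements therefore come from resampling cores with
replacement, 1,000 draws by default. For each draw the labeled and
unlabeled arms are resampled independently, their per-draw means
differenced, and the whole enrichment chain evaluated on the draw, so the
APE interval propagates the nonlinearity of the chain rather than
linearizing it. Draws are summarized by their mean and a percentile
interval (2.5/97.5 for the default 95% level).

With \(n = 3\) cores the plain percentile interval is known to be too
narrow: the resample distribution carries the \(n\)-divisor variance
bias, and the realized one-sided error of a nominal 2.5% bound is several
times larger (the package's own null simulations put the plain variant
near 13% false calls). The default interval is therefore the *expanded*
percentile: draw means are rescaled about the sample mean by
\(\sqrt{n/(n-1)}\) before taking percentiles (Hesterberg, *Am. Stat.*
2015). Under the reference simulation below this brings the null
false-call rate to ≈4.5%, close to the ≤5% a one-sided 2.5% rule should
deliver. `ci_method = "percentile"` restores the plain interval for
comparison with analyses that used it.

A taxon is called **active** when its mean APE is positive and the lower
95% bound is above zero (`call_active()`). Taxa observed only in labeled
cores have no unlabeled WAD and no APE; they are instead called active
when the lower bound of their own WAD exceeds the upper bound of the
labeled treatment's community-average WAD (`call_active_label_only()`) —
banding credibly heavier than the treatment as a whole. `qsip()` routes
every taxon automatically and records the route (`ci_rule`,
`label_only_rule`, `not_active`) in its results.

## Absolute abundance: QSEQ normalization

Counts are compositional per sample; WAD weighting needs abundances
proportional to each taxon's DNA mass in each fraction. The pipeline
multiplies relative abundances by the sample's total 16S rRNA gene copies
from qPCR (`qseq_normalize()`), so column sums equal the qPCR totals and
within-sample ratios are untouched. For the cross-fraction weighting to
be meaningful, the per-sample totals must scale with the DNA recovered in
that fraction or group — copies per nanogram of the DNA loaded on the
gradient, not per nanogram of the diluted qPCR input. The simulator
draws its totals accordingly (each sample's share of the core's DNA,
times the per-ng copy yield, times lognormal noise). If totals on
another basis are supplied, shifts remain detectable but WADs acquire a
composition-dependent distortion; the package does not attempt to repair
that.

Upstream filtering mirrors common amplicon practice and is configurable:
samples outside `k = 2` standard deviations of the mean sequencing depth
are removed, with mean and SD computed once over all input samples
(`filter_samples_by_depth()`); taxa lacking a per-sample count of at
least 3 in at least `ceiling(0.02 · n_samples)` samples are removed
(`filter_rare_taxa()`). The prevalence reading of the rule ("at least
three times in 2% of samples") is per-sample count ≥ 3 — the common
prevalence-filter idiom; both thresholds are arguments, which also covers
the alternative total-count reading. Order is fixed: depth filter →
rare-taxon filter → relative abundance → QSEQ; every step emits a
`filter_report` whose dimensions reconcile exactly, and samples lacking
qPCR records are dropped with a report entry rather than erroring.

## Density bookkeeping

The canonical pooling scheme is light [1.65, 1.69), medium [1.69, 1.75),
heavy [1.75, 1.80] g/mL. Published group bounds in this design leave
small gaps (1.689–1.69, 1.749–1.75); the scheme closes them by treating
the listed bounds as half-open bin edges, because no measured fraction
may be unassignable. Boundary densities belong to the upper bin; the top
edge is closed. The default refractive-index calibration
(density = 10.9276 · RI − 13.593) is the conventional 20 °C CsCl
relation; laboratories correct for temperature and buffer, so
`ri_calibration()` takes arbitrary constants. Readings outside
(1.3, 1.5) convert with a warning and a flag rather than an error.

## The simulator and what it does (not) emulate

`simulate_qsip_experiment()` forward-simulates the full observation
chain with known truth: GC contents set unlabeled WADs; true excess
shifts labeled WADs through the forward model; each taxon's DNA mass is
split over density bins by a Gaussian band integrated over bin bounds
(`group_mass_fractions()`); reads are multinomial at fixed depth; qPCR
totals are mass-proportional with lognormal noise; density-group samples
drop out at a configurable rate (never the last sample of a core).

Reference conditions (the defaults) describe the emulated study design
and are held fixed across the test suite:

| parameter | default | rationale |
|---|---|---|
| taxa | 200 | desk-scale community, ≥100 per activity class |
| active fraction | 0.5 at APE ~ U(1%, 10%) | spans undetectable to clearly labeled |
| GC | N(0.55, 0.08) on [0.25, 0.80] | soil-like; implies WADs ≈ N(1.692, 0.007) g/mL |
| relative abundance | lognormal, sdlog 1 | typical ASV rank-abundance skew |
| cores | 3 + 3 | the labeled/control replication of the design |
| depth | 50,000 reads/sample | MiSeq-scale per-fraction libraries |
| banding SD | 0.005 g/mL | sheared genomic DNA band width in CsCl |
| qPCR CV | 20% lognormal | assay-level variation; efficiencies 93–100% imply no fixed variance, this is a field-typical figure |
| dropout | 5% per group sample | occasional failed fraction groups, as real cores show |

The simulator does **not** model read errors or chimeras (it starts at
ASV counts, like the pipeline), primer or copy-number bias, density
measurement error, taxon-to-taxon interactions beyond shared multinomial
sampling, or partial labeling heterogeneity within a taxon. Passing
recovery tests therefore demonstrates that the *inference chain* is
correct and calibrated under the stated noise model — not that any real
dataset meets that model.

## Resolution, quantization and missing groups

Two readout modes exist because pooling has a real statistical price.
With three pooled groups, every WAD is a convex combination of three
fixed group densities: a density shift moves the WAD only by moving mass
across a group boundary. A 3% APE shift is ~0.0016 g/mL, so with a
0.005 g/mL band only taxa banding within ~2.5 band-SDs of a boundary
respond measurably, and the response is amplified or attenuated by band
position. Grouped-mode sensitivity is therefore structurally limited and
taxon-dependent (the test suite demonstrates fraction mode detecting
weak enrichment that grouped mode misses); per-taxon APE from pooled
groups should be read as a detection statistic more than an unbiased
measurement. With per-fraction data (12 fractions here), quantization is
below the noise floor and recovered APE is unbiased — the suite verifies
a mean signed error indistinguishable from zero over 20 simulations at
zero qPCR noise, and exact recovery (≤ 1e-6) in a noise-free fine-grid
run.

Cores missing density groups are tolerated: WADs are computed over the
samples a core actually has, and the fit's `cores` table records
`groups_used` per core. Tolerance is not innocence — losing the light
group biases that core's WADs upward (a hand fixture in the suite shows
it), and because one lost DNA-bearing sample displaces *every* taxon's
WAD in that core simultaneously, dropout inflates replicate scatter
collectively and, in a control core, can push the whole experiment's
false calls in one direction. The recovery and calibration benchmarks
therefore run on complete gradients (dropout 0) at the reference
conditions above: sensitivity ≥90% for APE ≥3%, false calls within
binomial reach of 5%, and the dropout pathology is exercised separately.
Inspect `fit$cores` before trusting a fit on incomplete gradients.

## Numerical choices and degenerate inputs

* GC outside [−0.05, 1.05] warns; mass formulas use GC clamped to
  [0, 1] while the raw value is kept in the results.
* An all-zero abundance profile has no WAD (`NA`); a taxon absent from a
  core simply contributes no replicate there, and per-taxon replicate
  counts are reported (`n_labeled`, `n_unlabeled`).
* Bootstrap draws consume one RNG stream governed by `seed`, which is
  recorded (with `n_draws`) in every result row; `method = "exhaustive"`
  enumerates all \(n^n\) resamples exactly for \(n \le 8\).
* Activity calling uses strict inequalities; an exactly-zero APE is not
  active. At zero simulated noise the sign of a truly-zero estimate is
  floating-point cancellation residue (~1e-13 APE), which is why the
  noise-free suite asserts magnitudes, not calls, for unenriched taxa.
* `run_pipeline()` validates its configuration before computing,
  executes simulate/load → preprocess → qsip → summarize, aborts on the
  first failing stage with the partial manifest attached to the error,
  and writes `manifest.json` with file digests so deterministic stages
  can be re-verified byte-for-byte.

Test-suite problem sizes are deliberately desk-scale — 200–500 taxa,
1,000 bootstrap draws, 20-seed bias replication — chosen so the entire
suite completes in well under a minute while keeping every statistical
assertion's Monte-Carlo error far below its tolerance.

## Known limitations

* Only `^13`C chemistry is implemented; other heavy isotopes change the
  per-nucleotide atom counts and mass shift and are out of scope.
* The GC–density and GC–mass relations are empirical calibrations;
  taxa with unusual genome chemistry will inherit their error. Constants
  are arguments precisely so sensitivity to them can be probed.
* Bootstrap intervals over 2–3 cores, expanded or not, are coarse: with
  two cores the interval has at most four support points. The label-only
  rule in particular is a conservative screen, not an estimate.
* Grouped-density APE is position-dependent (see above); cross-study
  comparison of APE magnitudes from 3-group data should be avoided.
* Genus-level aggregation reports activity called at ASV level summed to
  genus; a genus mixing active and inactive ASVs is represented only by
  its active members' abundance.
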