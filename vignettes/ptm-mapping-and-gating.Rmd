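---
title: "PTM site mapping and single-channel gating analysis with VDACmods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PTM site mapping and single-channel gating analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(VDACmods)
```

## The problem

Voltage-dependent anion-selective channels (VDACs) are the main metabolite
pores of the outer mitochondrial membrane. Under oxidative stress their
residues accumulate non-enzymatic, largely irreversible post-translational
modifications (PTMs): methionines oxidize to the sulfoxide, cysteines
over-oxidize to sulfonic acid or are succinated by fumarate, and
asparagines deamidate to aspartate through a cyclic succinimide
intermediate. Bottom-up proteomics localizes these events: the protein is
digested with trypsin and chymotrypsin, peptides are identified by
high-resolution LC-MS/MS, and the relative abundance of a modified versus
unmodified site is estimated from the absolute intensities of the
corresponding molecular ions across technical replicates. When a
modification (such as deamidation of an asparagine in a cytosol-facing
loop) is suspected of changing channel function, the mutant protein is
reconstituted in a planar lipid bilayer and its single-channel conductance
and voltage dependence are measured.

VDACmods implements this computational chain as reusable, tested pieces:
mass/fragment arithmetic for modified peptides, in-silico digestion and
coverage, intensity-ratio site quantification, MS/MS annotation with the
diagnostic methionine-sulfoxide neutral loss, and planar-bilayer trace
analysis, plus generators that synthesize every input so the chain can be
exercised end to end without instrument data.

## The mass scale

All masses are monoisotopic. Residue masses are the standard values for
the 20 proteinogenic residues; water (18.010565 Da), the proton charge
carrier (1.007276 Da), ammonia (17.026549 Da) and methanesulfenic acid
(63.998301 Da) are package constants. A peptidoform's neutral mass is

$$M = \sum_i m_{\mathrm{res}(i)} + m_{\mathrm{H_2O}} + \sum_j \Delta_j,$$

the residue sum plus water plus the deltas of its localized modifications,
and the protonated ion convention $m/z = (M + z\,m_p)/z$ is the only
charge model: no adducts, one modification per site, conflicting
assignments rejected by the `Peptidoform` validity method rather than
merged.

The modification registry is deliberately closed: carbamidomethyl
(+57.021464, the iodoacetamide adduct marking a cysteine that was
*reduced* when alkylated, hence the reference state in Ox/Red ratios), Met
sulfoxide (+15.994915), Cys sulfonic acid (+47.984744), Asn/Gln
deamidation (+0.984016), the succinimide intermediate (-17.026549, which
is exactly deamidation minus water), Cys succination (+116.010959),
aspartate methyl ester (+14.015650 on D), protein-N-terminal acetylation
(+42.010565), and `none`. An isoaspartate methyl ester at a site encoded
as Asn is the composition deamidation + methyl ester (net +14.999666
relative to Asn); because the package enforces one modification per
position, such a form is represented on the deamidated, D-encoded
sequence. One published peptide of this type carries a printed m/z about
0.012 above what its own stated composition yields; the package documents
rather than reconciles it, and no test asserts it.

Comparisons against published "calculated m/z" columns use a ±0.001
tolerance: the rounding conventions of other software's constants are
unknown, and the observed agreement is within ±0.0006 across all
twenty-nine values the package reproduces.

## Digestion, numbering and coverage

`digest()` applies Keil-style rules - trypsin cleaves after K/R, never
before P; chymotrypsin (high specificity) after F/W/Y/L, never before P -
and emits all peptides with up to `maxMissed` (default 3) missed
cleavages. The rule choice is corroborated by the data the package
reproduces: a published tryptic peptide retains an internal Arg-Pro bond,
and chymotryptic peptides end in leucine.

Coordinates count the initiator methionine even though it is absent from
the mature protein, because every published site label (Met26, Cys229,
Asn215) uses that convention; consequently the N-terminal tryptic peptide
of a mature protein starts at position 2. Coverage percentages divide by
the *mature* length (282 for the bundled fixture), which is how "279 of
282 residues = 98.9%" arises when only the Arg119-Arg120 tryptic
dipeptide (too short to observe) and one tyrosine are missed. Peptides of
length 1 are emitted rather than filtered so that exactly this kind of
gap appears naturally.

The bundled FASTA (`vdac3_synthetic.fasta`) is a synthetic stand-in, not
the database entry: it satisfies every constraint the published tables
impose (all peptide sequences at their printed coordinates, the Met/Cys
landmark positions, mature length 282) but the connecting segments are
invented. Tests and examples treat it as what it is - a fixture that makes
the published coordinates reproducible offline.

## Intensity-ratio site quantification

For a site $s$, modification $m$ and reference state $r$, each technical
replicate contributes

$$\rho = \frac{\sum_{\text{evidence with } m \text{ at } s} I}
              {\sum_{\text{evidence with } r \text{ at } s} I},$$

summing over charge states and over all peptides covering the site before
dividing. Pooling-then-dividing is the least-surprising estimator, is
scale invariant, and degrades gracefully: when the reference form is
absent from every replicate the site is flagged *fully modified* (rendered
as a dash) instead of producing an infinite ratio; replicates where only
the reference is absent are dropped with a warning. The summary is the
mean and sample SD over the replicate ratios - the "Avg / Dev St over
triplicates" convention. A row counts toward the reference only when the
site is explicitly in the reference form: carbamidomethylated for
cysteines, unmodified for Met/Asn; peptides not covering the site are
ignored. Whether published ratios summed intensities or took best ions per
charge state is not stated anywhere we could check; summation is this
package's documented choice.

Deamidation site occupancy is reported as
$100 \times I_{deam}/(I_{deam}+I_{norm})$ pooled over replicates, so a
deam/norm ratio of 0.1 reads as 10% of molecules deamidated.

## MS/MS annotation and the 64 Da diagnostic

`fragmentLadder()` emits all $b_i$ and $y_i$ ions ($i = 1..n-1$) at the
requested charges with -H2O and -NH3 variants, plus a -CH3SOH
(63.998301 Da) variant for every fragment spanning a Met-sulfoxide - the
classic confirmation that an observed +16 Da shift is MetO rather than
another isobaric event. Singly charged complementary pairs obey
$b_i + y_{n-i} = \mathrm{prec}(1+) + m_p$ to 1e-6, which the tests check
against independently summed prefix masses.

`annotateSpectrum()` matches peaks to the ladder greedily by smallest
|ppm| within a tolerance (default 10 ppm, a high-resolution instrument
setting; configurable), ties broken by lower charge, then b before y, then
lower index, each peak and each ion used at most once. Neutral-loss
variants only become eligible after their backbone ion has matched, which
keeps the MetO diagnostic from firing on noise peaks. Matching uses m/z
only, so intensity scaling cannot change an annotation. The
`fractionMatched` statistic is the fraction of *theoretical* ions matched,
so removing observed peaks can only lower it.

## Planar-bilayer analysis

Single-channel conductance at a constant holding potential (default
+10 mV in 1 M KCl) is estimated by `detectSteps()`: a running median
(default 5 ms window) suppresses point noise, level changes larger than
`minStep` across the filter span mark gating events, and the modal
absolute step amplitude divided by |V| gives the modal conductance - a
4.5 pA step at +10 mV is 450 pS, a 6 pA step 600 pS, and a low-conducting
substate of about 3 pA corresponds to 300 pS. Amplitudes are differences
between level medians, so constant baseline offsets cancel. The amplitude
histogram uses 0.2 pA bins by default.

Voltage dependence uses the classic triangular ramp (0 to ±50 mV; the
default period is 100 s, i.e. 10 mHz). `ivCurve()` pairs each sample with
the instantaneous ramp voltage and averages within voltage bins over all
cycles; the reported Vm of a bin is the mean voltage actually sampled in
it, not the bin center, so a noiseless ohmic trace stays exactly ohmic
after binning. `voltageDependence()` converts to chord conductance
G = I/Vm (bins with |Vm| below 0.5 mV are dropped - chord conductance is
undefined at 0 mV), and normalizes by G0, the mean conductance in the
low-voltage band |Vm| ≤ 10 mV, the usual open-state reference for these
channels. An ohmic channel gives G/G0 ≡ 1; voltage-gated closure produces
the bell-shaped decline toward high |Vm|.

## What the generators emulate - and what they do not

`simulateEvidence()` plants a true modified/reference ratio per site and
emits, per replicate, reference and modified rows sharing one
peptide-level abundance, split across 2+ and 3+ charge states (so
estimators must pool charges), with independent multiplicative lognormal
noise. Lognormal noise is the standard model for label-free MS
intensities. The defaults are the study conditions: 3 technical
replicates and CV 0.05, a typical technical-replicate spread for summed
MS1 intensities on a high-resolution instrument. With CV = 0 the planted
ratio is recovered exactly, which closes the loop on the estimator.

`simulateSpectrum()` plants the full fragment ladder with uniform m/z
jitter bounded by ±`jitterPpm` plus uniform noise peaks.
`simulateTrace()` runs a discrete-time Markov model: a closed level, an
open level (default 450 pS) and optional conducting substates with
occupancies, a logistic voltage-dependent closure rate (default maximal
rate 0: the ohmic, wild-type-like regime), and Gaussian current noise.

None of these reproduce real-data pathologies: chromatographic
interference and co-elution, missing evidence rows, isotope-envelope
overlap, detector saturation, bilayer drift, 1/f noise or multi-channel
insertions. Passing tests therefore demonstrate correctness of the
estimators under the stated noise models, not robustness to everything an
instrument can produce. Conversely the biological contrasts between cell
lines are carried by fixture datasets with planted values - the package
makes no claim of re-deriving biology.

All generators require an explicit seed and are bit-reproducible given
one; seeds are mandatory precisely so that no analysis can silently
depend on an ambient RNG state.

## Numerical and design choices

* Ties in annotation are broken deterministically (|ppm|, charge, series,
  index); digestion output is sorted by start then length; ratio tables
  are ordered by site, modification, cell line. Re-running any stage with
  the same inputs reproduces reports byte for byte.
* The sample SD over replicates is reported as-is; a single defined
  replicate yields SD `NA`, and a site with no defined replicate is
  flagged rather than given a value.
* `digest()` returns a plain data.frame (sequence/start/end/missed)
  rather than a list of Peptidoform objects: the table is what coverage,
  uniqueness, reports and simulators consume; `asPeptidoforms()` converts
  when mass arithmetic is needed.
* The published missed-cleavage ceiling is unstated; the default of 3 is
  generous (the published peptides need at most 1) without exploding the
  search space.
* Problem sizes in the test suite are chosen to exercise the estimators'
  asymptotics at small cost: 100 replicates for the unbiasedness check,
  20-200 s of simulated trace at 0.5-2 kHz for conductance recovery.
* The command-line surface is a thin wrapper (`inst/scripts/`) over the
  exported functions; the functions are the interface.

## Known limitations

* Semi-specific and non-specific digestion, a/c/x/z ions, internal
  fragments, isotope envelopes and average masses are out of scope.
* Identification is taken as given (evidence tables are input); there is
  no search scoring or FDR control.
* The two-Boltzmann gating fit, dwell-time kinetics and selectivity
  analysis are not implemented; `voltageDependence()` stops at G/G0.
* The bundled protein fixture is synthetic between the published
  peptides, as described above.
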