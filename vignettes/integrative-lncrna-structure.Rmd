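---
title: "Integrative structure analysis of long noncoding RNAs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative structure analysis of long noncoding RNAs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncstruct)
```

## The problem

Large multi-domain lncRNAs such as MEG3 fold into modular secondary
structures whose function can hinge on a handful of long-range tertiary
contacts. The experimental programme that dissects such an architecture
combines several independent measurement types: chemical probing (SHAPE
reagents, DMS, hydroxyl radical footprinting) read out either by capillary
fragment analysis or by mutational profiling (MaP) sequencing;
probing-directed secondary-structure prediction; differential probing of
the same transcript inside cells versus protein-free; sequence scanning
for complementarity-based pseudoknots ("kissing loops") with compensatory
mutagenesis to validate them; covariation analysis across homologs; and
single-particle AFM plus Mg^2+^ titrations of the hydration radius to
quantify tertiary compaction. `lncstruct` implements each of these stages
as composable R functions, together with seeded generators that emulate
every input class so the whole pipeline is exercisable and testable
without experimental data. The `analysis/` scripts in the repository run
the stages in order on one synthetic study.

The motivating biology is the H11–H27 interaction of MEG3: a GUGAG motif
in a hairpin terminal loop pairs with any one of six downstream tandem
repeats (TR1–TR6) lying in a single-stranded region several hundred
nucleotides away, forming alternative, mutually exclusive kissing-loop
pseudoknots. The package's defaults are chosen so the synthetic core
reproduces that architecture: a 360-nt transcript with five stems, the
motif at positions 78–82 of a hairpin loop, and six contiguous 5-nt
repeats starting 200+ nt downstream, each pairing the motif with four
Watson–Crick pairs and one G·U wobble (the wobble sits opposite the
central G, as in the natural G–U pair that a G→C / U→G double mutant
rescues).

## Reactivity processing

Raw per-nucleotide signals are held in `reactivity_profile` objects with
`NA` as the no-data marker (written as `-999` in files). Replicates are
averaged position-wise *before* normalization (`combine_replicates`).

**Box-plot normalization** (`normalize_boxplot`) implements the standard
SHAPE convention: values above `Q3 + 1.5·IQR` are outliers (at most 10% of
the finite values are excluded), the normalization factor is the mean of
the top decile of the survivors, and all values are divided by it. The
2%/8% alternative (drop the top 2%, average the next 8%) is available via
`method = "percentile2_8"`. The rule is scale-invariant and idempotent —
renormalizing a normalized profile returns factor 1 exactly — properties
the test suite asserts against a direct-sort oracle. Quartiles use R's
default (type 7) definition.

**Classification** uses two built-in schemes: `shape3` with boundaries
0.40/0.85 (not / moderately / very reactive) and `hrf4` with
0.29/0.58/0.86 (four solvent-protection classes). Interval membership is
left-closed with the top class strictly open above the last boundary, so
0.40 and 0.85 both classify as "moderately reactive". The placement of a
value exactly at 0.40 is a package decision (the two adjacent class
definitions overlap at the boundary); the choice is encoded in one place
and the boundary behaviour is pinned by tests at ±10^-9^.

**MaP counts** become raw reactivities as the difference of per-channel
mutation rates (modified minus untreated); positions with read depth below
`min_depth` (default 1,000 — a package default, configurable) in either
channel become no-data, and negative raw values are retained (flagged)
until normalization. Overlapping primer reads merge by averaging
(`merge_primer_reads`), and a mutant profile is placed on a reference
scale by least squares through the origin (`scale_to_reference`,
factor `Σ t·r / Σ t²`).

## Probing-directed folding

`fold_mfe` and `pair_probabilities` share one energy model
(`folding_params`): a simplified nearest-neighbor scheme with a 6×6
stacking table over the canonical pair types and affine hairpin, bulge,
internal-loop and multiloop penalties, with interior loops capped at 30
unpaired nucleotides. The default stack table derives from per-pair
strengths (GC 2.4, AU 1.1, GU 0.8 kcal/mol, averaged over the two stacked
pairs); every term is replaceable through `folding_params`, so the model
is configuration, not constant. This is deliberately *not* the full
Turner 2004 rule set: the package's guarantees are internal consistency
(the dynamic program provably equals exhaustive enumeration over all
nested structures, with and without probing data — the suite checks 200
random sequences) and recovery of planted structures, not replication of
any external folding program's output.

Probing data enters as the pseudo-energy `m·ln(S+1) + b` per paired
nucleotide (defaults m = 2.6, b = −0.8 kcal/mol, the convention of
probing-directed folding pipelines), charged once per nucleotide rather
than once per stack participation — the simpler variant. No-data
positions contribute zero; reactivities in (−0.3, 0) clamp to zero and
values below −0.3 are rejected as data errors.

Pair probabilities come from a McCaskill-style inside–outside computation
over the same unambiguous decomposition, with per-nucleotide rescaling by
`exp(MFE/(n·RT))` to avoid overflow (RT = 0.616 kcal/mol, 37 °C).
Per-position normalization `Σ_j p(i,j) + p_unpaired(i) = 1` is exact by
construction and verified against Boltzmann sums from enumeration to
10^-6^. The positional Shannon entropy uses log base 10 over the outcomes
{each partner, unpaired}. Pseudoknot-aware folding is out of scope by
design: kissing pairs are annotated post hoc on a `[]` bracket layer by
the scanner, mirroring the two-step logic of hairpin-level folding
followed by tertiary-contact inference.

## Differential probing

`delta_call` implements the deltaSHAPE-style procedure: both profiles are
smoothed (centered mean, window 3), the difference `Δ = smooth(ex) −
smooth(in)` is screened by the Z-factor `1 − 1.96·(err_ex + err_in)/|Δ|`
and by the standard score `(Δ − mean Δ)/sd Δ` (cutoff 1.0), and a call
additionally requires ≥ 3 passing positions within a 5-nt site window.
All five constants live in `delta_params`; the published tool's defaults
are adopted since the analysis they implement does not pin them further.
Standard errors are supplied by the caller (per-replicate sd/√n when
replicates exist, else a constant). Positive Δ — more reactive
protein-free — is reported as `protected_in_vivo`. Under the default
constants the suite measures ≥ 80% positional sensitivity on a planted
10-nt, Δ = 0.6 protection at noise sd 0.05, with a null false-positive
rate below 1% over a thousand null profile pairs.

## Kissing-loop discovery and rescue design

`scan_kissing` slides a k-window (default k = 5, the GUGAG scale) over
every hairpin loop of the input structure and tests every distal k-window
for antiparallel complementarity — Watson–Crick plus, by default, G·U
wobble, a default forced by the biology (natural kissing pairs include
wobbles, and their rescues are U→G substitutions). Candidates must be
single-stranded in the input structure (violations 0 by default,
relaxable for noisy structures) and at least 100 nt away (long-range
contacts only; configurable). Hits are labeled TR1…TRn 5′→3′ and
registers sharing loop positions form one mutual-exclusivity group — the
tool reports all alternative registers rather than choosing among them,
since the competing conformations are the finding, not a nuisance.

`design_compensatory` returns, for a loop point mutation, the unique
repeat-side substitution restoring a Watson–Crick pair; enumerating a
group (`design_rescue_panel`) yields one double mutant per register. The
suite closes the loop: every designed double mutant, applied to the
sequence and re-scanned, restores its register's full pair count.

`covariation` scores alignment column pairs by
`fraction_canonical + 2·compensatory_fraction`, where compensatory rows
are canonical but differ from the modal pair at both columns; the weight
2 is a package choice. Significance comes from a permutation null that
shuffles each column independently (preserving composition), reported as
an E-value — the expected number of tested pairs with a null score at
least as high. This is an explicit, simplified stand-in for dedicated
covariation statistics (R-scape and kin), adequate for ranking planted
signal against background but not a substitute for their calibrated
tests. `repeat_conservation` counts wobble-aware motif complements per
degapped row and applies a minimum-count rule (default 3, the level
conserved across mammalian MEG3 homologs).

## Compaction analytics

`compute_psd` computes row-wise periodograms along the fast scan axis
(optionally the slow axis, for datasets whose fast axis carries tip
resonance), mean-detrending each line — no window function by default,
the simplest faithful treatment; power is normalized so its sum over
positive frequencies equals the line variance (Parseval, asserted to 1%
in tests), and spectra average over lines then particles.

`fit_autoaffine` fits `PSD(f) = a₀·f^{−γ}` by weighted least squares in
log–log space over two caller-chosen frequency ranges and intersects the
lines analytically; the characteristic length is `L = 1/f*` in the cycles
convention or `2π/f*` in the angular convention — the two differ by 2π
and the convention is attached to every result, since spectra can be
plotted against either axis. `suggest_psd_ranges` makes the range choice
reproducible by anchoring it to two spectral features: the steep
form-factor decay (from the half-power knee to the first spectral
minimum) and the shallow sidelobe/noise tail beyond the minimum. For a
flat-topped particle of footprint d the first minimum sits near 1/d, so
the crossover tracks the particle footprint; with the default 250-nm
crops this recovers a planted 30-nm footprint within ~15%, and the length
increases monotonically with footprint across 15–85 nm. Two caveats are
inherent and documented: the crossover drifts above 1/d as the footprint
approaches the crop size (the plateau is then barely resolved — use
larger crops), and for multi-domain particles the first minimum reads the
*domain* scale rather than the envelope, which is exactly the dual-scale
behaviour multi-domain particles show in real spectra.

`fit_hill` fits `R_h(c) = R_∞ + (R_0 − R_∞)/(1 + (c/C_½)^n)` by
Levenberg–Marquardt with data-driven starts. The Hill isotherm is the
package's model choice for Mg^2+^-driven folding: it is the standard RNA
folding isotherm and reduces to the midpoint definition when only C_½ is
of interest. The fit reports percent compaction `100·(R_0 − R_∞)/R_0`,
flags midpoints outside the data range, and flags (but still fits)
increasing trends. `compare_constructs` reports the saturation-radius
difference `100·(R_∞,b − R_∞,a)/R_∞,a`, positive when construct b stays
less compact — the quantity that separates a folding-defective mutant
from its wild type; below the midpoint the two fitted curves coincide by
construction.

## The synthetic-data generators

Every generator takes an explicit seed, is deterministic given it, and
restores the caller's RNG state. What they emulate, and what they do not:

* `gen_core` plants the kissing-loop architecture exactly (stems, motif,
  wobble-aware repeats) in otherwise random sequence, then runs a repair
  pass mutating stray bases until no accidental loop-window/single-strand
  complement remains — so the planted registers are provably the complete
  ground truth, which is what makes scanner precision measurable. Real
  transcripts carry no such guarantee.
* `simulate_reactivity` draws paired positions from Exponential(mean
  0.15) and unpaired from Gamma(shape 2, scale 0.5), clipped at 4.0, with
  5% no-data. These defaults reproduce the three-class occupancy pattern
  of SHAPE data (paired positions mostly below 0.40) without claiming any
  experiment's noise spectrum; they are stand-ins and remain
  configurable. Position-correlated noise and primer-proximal artifacts
  are not modeled.
* `simulate_map_counts` uses binomial counts at rate `0.002 +
  0.02·reactivity` — typical mutational-profiling magnitudes, again
  configurable; sequencing reads themselves are out of scope.
* `simulate_alignment` uses a star phylogeny (independent descendants of
  one ancestor) with per-column substitution and a compensatory
  probability for paired columns; species keep 3–6 intact repeats. A star
  is the simplest model with tunable covariation; tree-structured
  evolution, indels and rate heterogeneity are deliberately absent, so
  passing covariation tests says nothing about phylogenetic confounding
  in real alignments.
* `simulate_heightmap` builds flat-topped (tanh-edged, 2-nm edge) domes
  of 1.5-nm amplitude — a single 65-nm dome (compact), three 30-nm domes
  in an 85-nm envelope (intermediate), or a thin meandering filament
  (denatured) — on 250-nm crops at 0.98 nm/pixel, plus Gaussian pixel
  noise (sd 0.05 nm). Amplitudes are plausible RNA heights but PSD
  conclusions depend only on lateral scales. Tip convolution, scanner
  drift and stripe noise are not modeled.
* `simulate_titration` evaluates the Hill form exactly on a log-spaced
  0.01–100 mM grid (12 points) plus Gaussian noise. The default truth
  (R_0 = 12 nm, R_∞ = 9.6 nm, i.e. 20% compaction, C_½ = 1 mM, n = 2) is
  a realistic compacting-RNA scenario.

## Numerical choices and degenerate inputs

Coordinates are 1-based inclusive throughout (the convention in which a
114-nt exon spans 936–1049). The no-data sentinel is `-999` on disk and
`NA` in memory, so arithmetic cannot silently absorb it. The variable
exon of the long splice variant is stored as an opaque insertion of
configurable length (default 141 nt) because only its length, not its
sequence, is determined — insertions map to `NA` reference coordinates.
Degenerate inputs fail loudly: all-no-data profiles, flat titrations,
parallel auto-affine fits, unbalanced dot-brackets, doubly-paired
positions, overlapping deletions. Ties in the MFE traceback resolve
deterministically (hairpin before interior before multiloop at equal
energy); energies are compared at 10^-7^ kcal/mol.

Test problem sizes are chosen to exhaust the combinatorics where feasible
and sample where not: enumeration oracles run to 22 nt (hundreds of
random sequences), partition-function cross-checks to 15 nt at 10^-6^,
scanner closure over 60+ random layouts, differential-probing specificity
over 10^3^ null pairs of 500 nt, and particle-field recovery over 8–20
particles per condition.

## Known limitations

The energy model is intentionally reduced (no dangles, no coaxial
stacking, no special loops), so absolute folding energies are not
comparable to Turner-model programs even though structure recovery on
planted cores is excellent. The covariation E-value is a permutation
stand-in, not a calibrated phylogenetic test. The PSD length requires a
resolvable plateau (crop comfortably larger than the particle) and reads
domain scales for multi-domain particles. Windowed/consensus folding for
very long transcripts is not implemented; sequences up to ~2,000 nt fold
in one pass, which covers the transcripts this pipeline targets.
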