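---
title: "Modeling and analysing in vitro ribozyme selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and analysing in vitro ribozyme selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboselect)
library(dplyr)
```

## The problem

In vitro selection of ligand-responsive self-cleaving ribozymes
(aptazymes) alternates two complementary steps. In a *positive* step the
pool is exposed to the ligand and only molecules that have cleaved are
carried forward; in a *negative* step the ligand is withheld and only
full-length (uncleaved) molecules survive. One positive step followed by
one negative step is a *selection cycle*; after each step the surviving
material is PCR-amplified back to working quantity. A genuine switch —
a sequence that cleaves with ligand and stays intact without it — gains
through both steps, while constitutively active and catalytically dead
sequences are each purged by one of them.

`riboselect` implements the quantitative machinery around such an
experiment: a degenerate control-library model, the selection fitness
metric and cycle dynamics, fitness quantification from gel band
intensities, variant counting and enrichment estimation from per-round
amplicon sequencing, and a synthetic-data generator that produces every
input with known ground truth.

## The control library

The built-in template (`control_template()`) describes a 1024-member
library built on a theophylline-activated hammerhead ribozyme: five fully
randomized loci (positions 52, 63, 73, 74, 81 on the reference), with the
positive control (PC) genotype C/C/U/C/G. Two design rules structure the
library:

* loss of G at position 81 (with the fixed C at position 76) abolishes
  catalysis, so 3/4 of the library — 768 sequences — is **inactive**;
* the D/U/C/A/G genotype pattern removes the ligand-sensing C at
  position 52 while hard-wiring an active conformation, giving three
  **constitutively active** (CA) sequences.

`classify_variants()` applies these rules in a fixed order — off-template
substitutions first, then the inactive rule, then PC, then CA, then
OTHER — which makes the classes mutually exclusive and reproduces the
partition 1 PC / 768 inactive / 3 CA / 252 other exactly. Putting the
inactive rule ahead of the CA pattern is what makes "lack of G at 81"
override everything else, so the inactive class is exactly 3/4 of the
library.

```{r partition}
tpl <- control_template()
classify_variants(enumerate_variants(tpl), tpl) |> count(class)
```

The reference sequence shipped with the template is a synthetic stand-in:
it satisfies every positional constraint the design rules use (PC bases
at the five loci, C at 76, A at 68) but is not a published sequence. All
enumeration and classification results depend only on the loci, so they
are independent of the surrounding bases; sequence-level operations
(read trimming, genotype extraction) treat the stand-in as the reference
and are exercised against data generated from it.

## Fitness and selection dynamics

For variant $i$ let $r_i^{(+)}$ and $r_i^{(-)}$ be the molar fractions of
its transcripts cleaved under positive and negative selection conditions.
Its per-cycle survival propensity is

$$\mathrm{fitness}_i = r_i^{(+)}\,\bigl(1 - r_i^{(-)}\bigr),$$

the product of the fractions retained by each step. Fitness is directly
proportional to the rate of enrichment: with ideal selection, one cycle
multiplies each frequency by $\mathrm{fitness}_i$ and renormalizes
(`simulate_selection()` with `epsilon = 0` is verified against this
closed form to $10^{-12}$ in the test suite). Both the inactive class
($r^{(+)} \approx 0$) and the CA class ($r^{(-)} \approx 1$) have fitness
$\approx 0$; the two classes are nevertheless distinguishable in the
dynamics, because inactive sequences fall on positive steps and rebound
on negative steps while CA sequences do the opposite — the
characteristic sawtooth of alternating selection.

Two departures from the ideal model are built in:

* **Background leakage `epsilon`** (default $10^{-3}$ per step). With
  perfect selection a zero-fitness class is extinct after one cycle,
  whereas real experiments observe such sequences persisting at roughly
  $10^{-5}$–$10^{-6}$ frequency. `epsilon` is the probability that the
  "wrong" species survives a step (ligation infidelity, incomplete bead
  washing) and is tunable per step polarity.
* **Finite-pool bottlenecks** (`n_molecules`, default $10^{6}$ in the
  generator). After each step the pool is resampled multinomially at the
  stated number of molecules, so rare variants drift and can go extinct.
  Deviations from the deterministic trajectory shrink as
  $1/\sqrt{n_\text{molecules}}$, which the tests confirm over four orders
  of magnitude.

PCR amplification between steps is modeled as exact renormalization —
no per-variant amplification bias — matching the framing under which the
fitness metric is derived.

### The lumped two-type model

Early in a selection nearly all competitors have similar (near-zero)
fitness, so the pool collapses to "target vs background": if the
background is diluted at a common rate, the target's odds are multiplied
by $\rho = f_\text{target}/f_\text{background}$ each cycle,

$$\mathrm{odds}_n = \frac{x_0}{1-x_0}\rho^{\,n}, \qquad
  x_n = \frac{\mathrm{odds}_n}{1+\mathrm{odds}_n},$$

implemented in `lumped_trajectory()` and inverted by
`cycles_to_threshold()`. Under the calibration $x_0 = 1/1024$, $\rho = 4$
the target passes 50% of the pool at cycle 5 and reaches 98.5% by cycle
8 — the planning numbers for a five-to-eight-cycle experiment. The
effective background fitness of a concrete pool is the
frequency-weighted mean fitness excluding the target
(`effective_background_fitness()`); $\rho$ for the default control
library is considerably larger than 4, because the initial background is
dominated by near-zero-fitness classes, so five cycles is a conservative
plan.

## Quantifying fitness from gels

Cleavage assays are read out on denaturing gels. Band fluorescence is
proportional to mass, so molar amounts are intensities divided by
species length in nucleotides (`molar_amount()`; per-base mass
differences are below 2% and the shared constant cancels in the ratio).
The cleaved fraction of a lane is $r = C/(C+F)$ on molar amounts
(`cleaved_fraction()`, `band_fractions()`), which is invariant to imager
gain. `fitness_scan()` pairs positive (ligand present) and
ligand-free measurements by condition label — exact string equality, no
fuzzy matching — and applies the fitness metric;
`select_optimal_condition()` picks the maximal-fitness condition,
breaking ties toward the shortest incubation (least background-cleavage
exposure). Fractions pushed outside $[0,1]$ by gel noise are clipped
with a warning rather than rejected, since negative baselines are a
routine densitometry artifact.

## Counting variants from sequencing reads

Each selection round is sequenced as an amplicon pool.
`count_variants()` takes a round manifest (file, cycle, polarity) and,
per read: optionally merges read pairs (`merge_pairs()`, best ungapped
overlap, quality-resolved disagreements, ties become N), anchors the
constant flanks at the read ends allowing one mismatch per flank by
default (`trim_flanks()`, trying the reverse complement before
rejecting), and extracts the genotype by end-to-end comparison with the
reference (`genotype_from_sequence()`). Bases at the degenerate loci
become the genotype; every other mismatch is recorded as an off-template
substitution (named e.g. `A68U`), with reads beyond `max_off_template`
(default 2) rejected. Cassettes containing N after merging are rejected
rather than imputed. Counting is invariant to read order and strand
orientation, and per-round rejection reasons are retained
(`count_rejects()`).

The merger and trimmer are deliberately minimal re-implementations so
the pipeline has no external binary dependencies; they are not
general-purpose read processors (no quality trimming, no indels, no
demultiplexing).

### Estimating the enrichment ratio

`estimate_fitness_ratio()` fits $\ln \mathrm{odds}$ of the target's
frequency against cycle index by weighted least squares and
exponentiates the slope. Weights are the inverse binomial variances of
the observed log-odds, $w_t = n_t \hat p_t (1-\hat p_t)$; because these
variances are known rather than estimated from residuals, the interval
uses a normal quantile instead of a $t$ quantile — with six points this
is what keeps the nominal 95% interval covering at $\approx 95\%$ in the
calibration tests. Counts of 0 (or full depth) receive a 0.5
Haldane–Anscombe pseudocount; non-boundary counts are used as-is, so
noise-free log-linear data recover $\rho$ exactly. By default the fit
uses cycle-end rounds (the initial pool and each post-negative-step
round), avoiding the within-cycle sawtooth; `rounds = "all"` fits every
round at half-cycle spacing.

`compare_trajectories()` scores observed against simulated dynamics with
$R^2 = 1 - SS_\mathrm{res}/SS_\mathrm{tot}$ on raw frequencies over the
shared rounds (at least 3). Raw frequencies are the default because the
headline comparison is about absolute trajectory agreement; a log10
option exists for dynamics spanning many decades, at the cost of
requiring strictly positive frequencies.

## The synthetic-data generator

`generate_round_fastqs()` produces a complete selection experiment with
known ground truth. The defaults mirror the control experiment's shape:
the 1024-member library starting uniform, 5 cycles (positive step first),
$\varepsilon = 10^{-3}$, a $10^{6}$-molecule bottleneck between steps,
and 16,600 reads per sequenced pool (initial + every post-step pool, 11
rounds) — 16-fold library coverage per round.

Cleavage profiles are drawn per phenotype class (`profile_spec()`):

| class | $r^{(+)}$ | $r^{(-)}$ | rationale |
|---|---|---|---|
| PC | 0.8595 (fixed) | 0.1274 (fixed) | measured saturating cleavage; fitness $\approx 0.75$, a well-optimized switch |
| inactive | Beta(2, 150) | Beta(2, 150) | ~1.3% residual cleavage either way; fitness < 0.05 in >99% of draws |
| CA | Beta(150, 2) | Beta(150, 2) | near-complete cleavage regardless of ligand; killed by $r^{(-)}$ |
| other | Beta(2, 3) | Beta(2, 3) | broad: partial, variably leaky switches; a few can rival the PC, as real selections find |

Two error channels are modeled. *Synthesis errors* spawn off-template
variants at library construction: a per-base substitution rate of
$10^{-4}$ over the 105 non-degenerate positions puts ~1% of initial
molecules off-template. Rather than tracking every possible error
molecule, the generator spawns a configurable number of distinct
single-substitution variants (default 50) carrying that total frequency,
with phenotypes drawn from the broad class — an off-template
substitution has an unknown effect, and selections have recovered active
off-template isolates. They are spawned once, at synthesis, matching the
interpretation that enriched off-template sequences pre-existed in the
library. *Sequencing errors* are independent per-base substitutions
(default $10^{-3}$) applied to each read. The ground-truth table
records, per round and variant, both the true pool frequency and the
expected read-level frequency
$x \,(1-e)^{L_\text{cassette}}$ — an error anywhere in the cassette
moves a read to a different variant id, while flank errors cause
variant-independent rejections that cancel in frequencies. Quality
strings are uniform Q30, since no stage uses qualities except pair-merge
tie-breaking.

`generate_gel_scan()` emulates the condition-optimization experiment
with a co-transcriptional cleavage model: molecules are born uniformly
over the reaction time and cleave first-order at rate $k$, giving
$r(T) = 1 - (1-e^{-kT})/(kT)$ (verified against a Monte-Carlo birth-time
oracle). The default rates $k_+ = 2\,\mathrm{min}^{-1}$,
$k_- = 0.055\,\mathrm{min}^{-1}$ were calibrated once, a priori, to the
reported fitness ordering for short versus doubled transcription times
(~0.73 at 10 min vs ~0.59 at 20 min): ligand-dependent cleavage
saturates within minutes while background cleavage accrues slowly, so
fitness decays with incubation time. In TRT mode (simultaneous
transcription and reverse transcription), partial reverse transcription
halts cleavage after `tau` minutes (default 8), making the response
independent of incubation time beyond `tau`. Band intensities are molar
amount × length with multiplicative lognormal noise of a given CV.

### What the generator does *not* emulate

Passing tests against this generator demonstrate internal consistency —
the pipeline recovers what the model put in — not real-data robustness.
Not modeled: PCR amplification bias and chimeras, indels and
length-varying reads, position- or context-dependent sequencing error,
quality-score variation, ligation-efficiency differences between
sequences, condition drift across cycles (profiles are constant), and
secondary-structure effects on any step.

## Numerical choices and degenerate inputs

* Pools are renormalized after every operation; emitted frequencies sum
  to 1 within $10^{-12}$.
* `cycles_to_threshold()` guards its ceiling against floating-point
  boundary error by verifying the returned $n$ (and $n-1$) against the
  closed form.
* An all-zero-weight selection step (nothing survives) is an error, not
  a silent NaN; a single-variant pool makes the background fitness
  undefined and errors likewise.
* `transcription_cleavage_fraction()` switches to its series limit
  $kT/2$ below $kT = 10^{-8}$ to avoid cancellation.
* Enumeration order is deterministic (lexicographic, A < C < G < U),
  and every stochastic function takes a seed and restores the caller's
  RNG state.

## Problem sizes used in validation

The shipped tests and the acceptance script run the full default
experiment (1024 variants + 50 off-template, 5 cycles, 11 rounds ×
16,600 reads) once, plus 200-replicate recovery calibrations at study
depth and reduced-scale pipeline compositions (16-member toy library,
hundreds to thousands of reads) for the per-operation checks; the whole
suite completes in well under a minute on a laptop.

## Limitations

The fitness metric summarizes a variant by two scalars; sequences whose
cleavage kinetics interact with the selection schedule (slow folders,
condition-dependent misfolding) violate the constant-profile assumption.
The lumped model is accurate only while the background is homogeneous —
in the default experiment it degrades after roughly three cycles as
high-fitness competitors emerge, which is exactly the regime the
full simulation (and the $R^2$ comparison against it) is for. The
trimmer assumes fixed-layout amplicons; reads from other library
architectures need their own extraction step.
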