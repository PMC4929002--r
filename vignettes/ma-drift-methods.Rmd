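---
title: "Drift, detection and mutational variance in MA lines: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drift, detection and mutational variance in MA lines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(madrift)
```

# The experimental design being modelled

A mutation accumulation (MA) experiment splits a single inbred progenitor
into replicate lines and propagates each at a tiny census size (here 10
females × 10 males) for `t` generations. At that size selection is nearly
powerless: a new mutation's fate is decided by drift, so non-lethal
mutations accumulate at close to the rate they arise. Sequencing the lines
at generation `t` against the parental stock reveals the mutations; trait
panels on the same lines measure how fast mutation rebuilds quantitative
variance. `madrift` models the whole chain, and ships a generator for every
input so each estimator can be validated against known truth.

# The drift model

All drift machinery works on the *effective* haploid population size
`2Ne`, not the census 40: the likelihood for `2Ne` is defined directly on
the Wright–Fisher chain with `2Ne` haploid genomes, so simulating at
census size with a separate offspring-variance mechanism would add a
parameter the inference cannot see. A new mutation enters at one copy; each
generation the copy number is resampled `Binomial(2Ne, freq)`; 0 and `2Ne`
are absorbing.

`expected_spectrum()` implements the calibration design used for
inference: `reps` lines, **one new mutation per line per generation**, for
`t = 60` generations. A mutation arising in generation `g` therefore
receives `t − g` resampling steps — the generation-`t` cohort is sampled
unevolved. At generation `t` each mutation's frequency is estimated from
`sample_n = 200` chromosomes drawn binomially (with replacement — the only
construction consistent with sampling 200 from fewer than 200 haploids),
and the mutation is *detected* when the sampled frequency strictly exceeds
the calling cutoff 0.2. The detection probability `p` is the detected
fraction of all `t · reps` mutations; the expected spectrum `P` is the
distribution of detected mutations over the 16 half-open bins
`(0.20, 0.25], …, (0.95, 1.00]`. Both conventions (timing of the final
cohort, strictness of the cutoff, half-open bins) were fixed by requiring
internal consistency of the chain's closed-form expectation; the
bin-notation ambiguity is resolved uniformly as `(lo, hi]`, so a frequency
of exactly 0.25 falls in the first bin.

Two implementation notes:

* **Aggregated simulation.** Unlinked neutral trajectories are
  exchangeable given their copy number, so instead of tracking `t · reps`
  individual trajectories the simulator propagates the *count of mutations
  per copy-number state* and draws multinomial transitions per state. The
  result is distributionally identical to per-mutation simulation (the
  test suite checks this against an independent per-trajectory engine) and
  its cost is independent of `reps`, so 60 million mutations per grid
  point are routine. The per-mutation engine (`wf_trajectories()`,
  `simulate_ma_lines()`) is retained for the data generator, where
  per-line histories matter.
* **Common random numbers.** `estimate_ne()` derives one sub-seed per grid
  point from the master seed, so profile roughness reflects the data, not
  independent simulation noise.

`p` conditions on nothing: it averages over all `t · reps` origins,
including mutations already lost. With that definition the simulated
detection probabilities at the fitted sizes are ~6.2% (2Ne = 23) and
~7.2% (2Ne = 19), and the rate estimator `mu = m / (t · 2Ne · p · B)`
inverts the expected detected count. The product `2Ne · p(2Ne)` is the
only way `2Ne` enters the rate; `ne_sensitivity()` reports its relative
spread `100 · (max − min)/min` over the grid (≈ 28% over 10..40; the
spread definition with `min` in the denominator is a documented choice).

`fixation_probability()` provides Kimura's diffusion closed form
`u = (1 − e^{−2s})/(1 − e^{−4sNe})` with the neutral limit `1/(2Ne)`; the
tests verify it against an exact absorbing-Markov-chain solve for small
populations within 2% for `|4Ne s| ≤ 1`.

# Mutation calling

`call_mutations()` evaluates each (site, line, allele) candidate at
eligible sites against the six filters listed in the README. Choices the
filter text leaves open, fixed here:

* Frequency clauses are strict: `> 0.20` for the mutant line, `> 0.05`
  for leakage into another line.
* The strand-bias 2×2 table is (mutant +, mutant −, other +, other −)
  within the mutant line — the standard construction.
* "Alleles observed" means alleles with ≥ 1 read; clause (6)'s "any
  reads" likewise means ≥ 1 read.
* The ancestral allele is the parental majority allele (ties broken
  alphabetically, deterministically).
* When two lines share a high-frequency allele at a site, each is
  evaluated against all others, so clauses (5)–(6) can eliminate both.
* `classify_mutation()` tie-break: any length-changing event that is not a
  pure prefix insertion/deletion is COMPLEX; equal-length events with ≥ 2
  substituted positions are MBS.
* Coordinates are 1-based inclusive in VCF output; gene intervals for
  `mutations_per_gene()` are 0-based half-open, and a call inside
  overlapping genes counts in every one of them.

`fisher_exact_2x2()` enumerates the hypergeometric distribution directly
(two-sided: sum of table probabilities ≤ observed, with the customary
`1 + 1e-7` tolerance); it is cross-checked against `stats::fisher.test`
over all tables with margins ≤ 12. The DUST complexity score uses the
classic triplet count `S = Σ cᵢ(cᵢ−1)/2 / (w−1)` on the single fixed
±20 bp window of a call — no sliding sub-window minimization, since the
score is used only as a per-site complexity scale.

# Quantitative genetics

`partition_variance()` uses REML (`lme4`, the standard tool for this
model) rather than raw ANOVA moments; on balanced designs the two agree to
numerical precision (tested), and REML handles unbalanced panels and
truncates negative components at zero. The test of `V_line > 0` is a
likelihood-ratio test against the boundary null `½χ²₀ + ½χ²₁`; the null
REML log-likelihood of the intercept-only model is computed in closed form
(verified numerically against lme4's REML criterion at the boundary).
FDR control across traits is Benjamini–Hochberg.

The drift correction `k = 2[t − (2Ne − 5)(1 − e^{−t/2Ne})]` converts the
accumulated among-line variance into the per-generation mutational
variance `Vm = V_MA / k`; its default `2Ne = 21` averages the X (19) and
autosomal (23) fits and is overridable. Mode-specific environmental
variance: pooled expression measurements use `Ve = n · V_within` with
`n = 10` flies per pool (an upward-biased Ve, hence a conservative h²m,
because the technical variance of the assay cannot be separated); sleep
traits use `V_within`; bristle counts add the between-replicate (vial)
component. Analyses are per sex throughout; the bristle Ve sums components
within sex before any cross-sex averaging.

The normal-quantile transform maps values to quantiles of
`N(median, (1.4824 · MAD)²)` at plotting positions `rank/(n + 1)` (ties
averaged). The 1.4824 factor only rescales the output — rank-based
inference is unaffected — and a raw-MAD transform is available via
`scale_factor = 1`. The two-normal expression mixture is fit by EM via
`mclust`; a gene is "expressed" when its posterior for the high-mean
component is ≥ 2/3, and the cutoff is the smallest value reaching that
posterior. Because the EM initialization is deterministic
(model-based hierarchical clustering), degeneracy is detected not by
restarting but by model comparison: if one component fits better by BIC,
or a component weight vanishes, or the means are indistinguishable, the
fit is refused.

`sequence_variance_sum()` links sequence to trait variance: dosages are
0–2 copies per line (twice the within-line frequency while segregating),
and the n−1 sample variance is summed over loci. In MA mode the sum is
divided by `k` and augmented with mutations segregating *below* the 0.2
cutoff: the expected number of such mutations per detected one is
`p_below/p` from the same drift simulation, and each is assigned a drawn
sub-cutoff sampled frequency in one random line. `selection_report()`
then assembles `Vm/Vg`, the neutral `1/(4N)` with `N = π/(4μ)`, the
sequence-based ratio, the effect-size ratio (their exact quotient), the
pleiotropic `s = Vm/Vg`, and the house-of-cards locus number
`n = Vg/(4μVs)` with `Vs` a multiple (default 20) of `Ve`.

# The synthetic-data generator

The generator's defaults are the study conditions: 23 lines, `t = 60`,
`2Ne = 23` haploids, mean depth 30 truncated to [15, 250], GC content
0.4248, X fraction 0.2. What it emulates: Poisson(`2Ne·μ·B`) new
mutations per line per generation (infinite-sites: collisions re-drawn),
binomial read sampling at the line frequency, uniform sequencing errors at
rate 10⁻³, binomial strand splitting, balanced trait panels with
independent normal line and residual effects, and inbred panels with 0/2
dosages at specified frequencies. The depth distribution is truncated
Poisson — no distribution is prescribed by the design, and any unimodal
count model within the eligibility bounds serves; depth is also the only
place coverage variability enters. X-linkage is handled solely through a
separate `2Ne` parameter (no hemizygosity or dosage model).

What it does **not** emulate — and hence what passing tests cannot show:
alignment and mapping artefacts, indel realignment errors, PCR duplicates,
context-dependent error spectra, linked selection among mutations, or
microarray probe effects. Recall and false-call rates measured here are
properties of the read-count model, not of any aligner.

# Problem sizes and numerical choices

Simulation sizes in the shipped tests and scripts are chosen so the whole
chain demonstrates its statistical properties at desk scale: genomes of
2×10⁴ bases with correspondingly raised mutation rates (μ = 2×10⁻⁶) keep
expected detected counts near the real experiment's ~60 per line while a
full synthetic run completes in seconds; `reps = 10⁶` simulated lines per
grid point (6×10⁷ mutations) make Monte-Carlo noise on `p` ~3×10⁻⁵, far
below the quantities compared. Rate-recovery checks use the median over
seeded replicate runs; 2Ne-recovery uses 100 spectra of 1,000 mutations.
The ML grid is integer-valued with ties broken toward smaller `2Ne` and no
interpolation — the estimate is reported as an integer by design.
Degenerate inputs are refused loudly: empty spectra, zero MAD, all-zero
Fisher tables (p = 1 by convention), `S = 0` windows (complexity `+Inf`),
monomorphic panels (all components zero, LRT p = 1).

# Known limitations

* The detection model applies the 0.2 cutoff to a 200-chromosome sample,
  while real calling applies it to read counts at varying depth; at depth
  30 the two differ by ~3% in `p` (the discreteness of 7/30 > 0.2 acts as
  a slightly stricter cutoff), well inside the rate estimator's tolerance.
* `estimate_ne` treats pooled mutations as independent draws from the
  spectrum; linkage within a line is ignored (mutations per line are few).
* The neutral-site restriction for inference is the caller's
  responsibility (a chromosome-class or site mask); the package does not
  annotate codons.
* The house-of-cards and pleiotropic summaries are algebraic assemblies of
  their inputs, not fits; they inherit whatever bias those inputs carry.
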