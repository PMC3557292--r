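---
title: "The finite-hybridization model behind tilecall: assumptions, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The finite-hybridization model behind tilecall}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`tilecall` detects single-nucleotide substitutions by comparing two-sample
tiling-array intensities against a physical model of hybridization. This
vignette is the package's account of that model: what it assumes, which
parameters matter, how the synthetic-data generator was designed, and where
open design decisions were settled.

## The array and its coordinate conventions

A design tiles a genome at resolution $r$ with 21-mer perfect-match (PM)
probes whose *position* is the genomic coordinate of the central (11th)
base; consecutive tiled positions alternate strands (even tiled index =
forward, a fixed convention since only "alternating" is inherent to the
design). For each PM probe, mismatch (MM) probes substitute the central
probe-sequence character. Coordinates are 1-based and closed; genomes are
circular by default (the bacterial case), and a linear genome simply loses
the 10 positions at each end. On reverse-strand probes the MM substitution
is defined in probe space — the probe's own 11th character is replaced — not
in genome space; the two conventions differ only in labeling (the
probe-space alternatives are the complements of the genome-space ones), and
probe space keeps the probe set literally "the PM sequence with three
alternative central characters" on both strands.

## The intensity model

The linear-scale intensity of probe $p$ is

$$I_p \;=\; A\,\frac{K_s + K_{ns} C_{ns}}{1 + K_f + K_s + K_{ns} C_{ns}} + B,
\qquad K_x = e^{\alpha G_x},$$

a single-site competitive-binding (Langmuir-type) isotherm: the probe is
either free, self-folded (statistical weight $K_f$), or occupied by a
specific or non-specific target. Finite target amounts, the specific target
concentration, and the total probe amount are absorbed into the fitted
scalars $A$ and the energy offsets, which is why the specific term appears
as a bare $K_s$. $B$ is the optical background; the model intensity is
strictly between $B$ and $A + B$. The free energies are position-weighted
triplet sums,

$$G_s(p) = \sum_{k=2}^{20} w_k\,
\varepsilon^{s}_{\mathrm{triplet}(p,k)},\qquad
G_{ns}(p) = \sum_{k=2}^{20} w_k\, \varepsilon^{ns}_{\mathrm{triplet}(p,k)},$$

sharing one weight profile $w_2 \le \dots \le w_{11} \ge \dots \ge w_{20}$
that decays toward the probe ends (dangling ends contribute less binding
energy). Every probe–target mismatch subtracts a penalty
$\delta(t, b) \ge 0$ from $G_s$, indexed by the *reference* triplet context
at the mismatch site and the substituted base. Mismatch counts follow from
the geometry: MM probes carry one designed central mismatch even against
reference DNA; a PM probe spanning a genuine substitution carries one; an MM
probe spanning it off-center carries two; and the MM probe whose central
alternative equals the mutant base becomes a perfect match (zero). A single
substitution per probe span is assumed throughout — the simulator enforces a
minimum spacing, the caller does not check it. When both duplex strands at a
mismatch site differ from the reference (an MM probe centered exactly on a
substitution to a third base), the penalty is indexed by the mutant base;
the case is a single mismatch either way and the choice only relabels one
penalty entry.

The parameter count is fixed at $64 + 64 + 192 + 19 + 4 = 343$: penalties
are context triplet $\times$ 3 alternative bases with no position index (the
position dependence of mismatch impact is carried entirely by the weights
through the triplet sums), and exactly four global scalars
($\alpha, A, B, C_{ns}$) remain after absorbing concentrations. Temperature
and the gas constant are folded into the dimensionless fitted scale
$\alpha$; all energies are in arbitrary fitted units, so no unit conversion
is attempted anywhere.

### Numerical evaluation

`fh_log_intensity()` works entirely in log space (`logsumexp` for numerator
and denominator), so arbitrarily large energies cannot overflow, and
$G_s = -\infty$ cleanly encodes an absent specific target (a deleted
locus, which then hybridizes non-specifically only). Predicted
mutant/reference log ratios are exactly zero for probes that do not span
the hypothesized substitution.

## Self-folding

The package replaces full secondary-structure prediction with a
deterministic stem-loop estimator: enumerate every stem candidate
(`seq[i..i+l-1]` pairing the reverse complement of `seq[j..j+l-1]`, stem
length $\ge 2$, loop $\ge$ `min_loop` bases), score it as the sum of
nearest-neighbor stack terms minus a loop-closure penalty, and return the
best score clamped at zero. Defaults are the unified DNA/DNA stacking
free-energy magnitudes at 37&nbsp;°C (SantaLucia 1998), a loop penalty of
3.5 kcal/mol and a 3-nt minimum loop — standard hairpin-scale constants.
This captures the dominant effect (hairpin-prone probes are dimmer) without
a partition function; per-probe energies computed by any external tool can
be supplied instead through the `folding` argument / TSV, and every
pipeline function treats folding as exogenous input.

## Fitting

The 343 parameters are estimated from the *reference* sample alone by
minimizing the residual sum of squares between observed and predicted log
intensities over all probes. MM probes carry their central-mismatch penalty
into this fit, so all penalty entries are exercised without any mutant data;
mutant/reference ratios would be degenerate here because only one sample
exists at fitting time. The optimizer is a seeded differential-evolution
population search, with two pragmatic additions that only affect how fast
the same objective is minimized:

* the population is seeded around an alternating-least-squares heuristic
  (invert the saturation to an approximate per-probe adjusted energy, then
  alternate ridge solves for the triplet energies and the weight profile,
  and read penalties off PM–MM energy gaps), and
* the best member is refined by bounded Levenberg–Marquardt
  (`minpack.lm::nls.lm`).

Both stages are deterministic given the seed, and the best-so-far objective
is non-increasing by construction. Default bounds: energies and penalties in
$[0, 10]$, weights in $[0, 1]$, scalars searched on the log scale within
wide positive ranges. Candidates with non-finite objectives are discarded
and counted, never propagated. Genome-scale fitting uses a uniformly
sampled, seeded probe subset (`subset_fraction`); on the problem sizes used
in the test suite (3–50 kbp genomes, 3–12 thousand fitted probes) the
noise-free fit reaches the observed intensities to well below 0.01 RMSE in
log units, and noisy fits settle at the noise floor. The parameterization is
not fully identifiable (e.g. a constant shift between weights and energies),
so recovery is always judged on *predictions* — intensities and
substitution-induced ratios — not on the raw parameter vectors.

## Detection

For each genome position $i$, the null residual
$D_i = \sum_{p \ni i} (\log I^{mut}_p - \log I^{wt}_p)^2$ sums over all
probes whose 21-base span covers $i$ (84 probes in the full design). A
substitution inflates $D$ over a ±10 bp neighborhood, so screening uses a
centered running average of $D$ (default window 11 bp, configurable; the
choice only needs to be comparable to the probe span) against
$\theta_R = \overline{D} + k\,\mathrm{sd}(D)$ with $k = 2$ by default.

Because high-residual regions themselves distort the moments of $D$, the
screen is iterative: runs above the current threshold are masked (with a
margin of 20 bp of probe reach plus the smoothing half-window), the
threshold is recomputed from the remaining — null — positions, and the
process repeats until the mask stabilizes (capped at 10 iterations). This
matters at two scales: a deletion contributes enormous residuals over its
whole span, and on small simulated genomes the implanted substitutions are
dense enough to inflate $\mathrm{sd}(D)$ many-fold. The emitted regions are
the maximal runs at the final threshold: runs of 10–79 bp are substitution
candidates; runs of ≥ 80 bp are flagged *structural* (deletion-like) and
excluded from calling; runs under 10 bp are attributed to noise. On circular
genomes a run crossing the origin is merged.

Within each candidate region the caller maximizes the log-likelihood ratio
$L_i(b) = E_i(\mathrm{ref}) - E_i(b)$, where $E_i(b)$ is the residual of
observed ratios against those predicted under the substitution hypothesis —
the normal-error log-likelihood ratio up to a neglected constant, assuming
homoscedastic relative errors. One call per region; ties break to the
smaller position, then base order A&lt;C&lt;G&lt;T; the threshold
$\theta_L$ is strict at both this and the screening stage.

$\theta_L$ has no default. It is either user-supplied or calibrated on data
with known truth by maximizing TP − FP over the sweep of per-region maxima
(`threshold_curve()` + `best_threshold()`). The sweep grid includes the
midpoints between consecutive observed maxima, so the larger-theta tie rule
settles *halfway between* the weakest accepted and strongest rejected
region rather than exactly on an observed value; a threshold pinned to an
observed noise maximum transfers poorly to datasets whose noise maxima sit
slightly higher (reduced-resolution subsets of the same experiment being
the canonical case).

## The synthetic-data generator

No array data are publicly available for this method, so the simulator is
the test bed and defines the study conditions. It emulates: a two-sample
(reference vs mutant) experiment on a random i.i.d. genome of specified GC
content; a ground-truth model drawn uniformly per parameter group with a
unimodal weight profile; implanted substitutions at a minimum spacing
(≥ 22 bp, so no probe sees two) with uniformly chosen alternative bases;
deletions realized as loss of specific binding over the deleted span; and
multiplicative log-normal measurement noise (the standard first-order model
for array intensities), i.i.d. per probe and sample.

Default conditions (a 50 kbp circular genome, 20 substitutions at ≥ 100 bp
spacing, noise sd 0.05, seed 17) are the desk-scale benchmark. The model
sampling ranges were chosen once so the simulated data *look like* array
data: roughly two decades of intensity dynamic range, moderate probe-site
saturation, mismatch-driven intensity drops several-fold larger than the
measurement noise, and a non-specific floor a few percent of full scale.
The resolution study uses a denser truth set (100 substitutions) so that
sensitivity granularity (1/n per substitution) is fine enough to resolve
the monotone decline across resolutions.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: spatial chip artifacts and scanner
saturation, probe-synthesis failures, batch and wash effects, replicate
arrays, correlated noise, genome repeats and compositional bias (i.i.d.
bases), transposon insertions, and multi-substitution clusters. The
truth-filtering step (`filter_truth_substitutions()`: neighbors within
21 bp, repeated 21-mers on either strand, extreme GC windows, with
configurable GC bounds defaulting to 0.2/0.8) exists precisely because real
genomes violate these assumptions; on i.i.d. simulated genomes it rarely
removes anything.

## Degenerate inputs and edge rules

Non-ACGT genome characters drop the tiled positions whose window touches
them (warned, with a count). Multi-record FASTA is rejected. Intensity
tables must be strictly positive at load. Even running-average windows and
unsupported resolutions (only {1,3,5,7,9,11,13}, from a full design) are
rejected. Triplet context at the ends of a *linear* genome clamps the
missing neighbor to the terminal base — a corner case that cannot occur on
circular genomes and affects at most the outermost two positions. The
reduced-resolution strand pattern stays alternating because every supported
resolution is odd.

## Known limitations

* The per-probe closed form is the package's own consolidation of the FH
  lineage (shared effective target pools, probe-site saturation, folding as
  a competing state); fitted parameters are effective, not calorimetric.
* One call per candidate region: two true substitutions closer than the
  region scale would yield one call (the simulator's spacing rules this
  out; real data would not).
* Structural regions are flagged, not resolved — no breakpoint or
  copy-number estimation.
* The LLR assumes independent homoscedastic ratio errors across probes;
  shared-target competition induces weak correlations the model ignores.
* Threshold calibration requires known truth (simulation or a
  strain pair with a reference comparison); without it, $\theta_L$ must be
  supplied.
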