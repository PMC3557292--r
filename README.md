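# tilecall

Physical-model-based calling of single-nucleotide substitutions from
high-density resequencing (tiling) microarrays.

## The problem

A 1-bp-resolution tiling array interrogates every position of a genome with a
21-mer perfect-match (PM) probe (identified by its central, 11th base) plus
three mismatch (MM) probes that substitute the central base, alternating
strands between consecutive positions. Hybridizing genomic DNA of a reference
strain and of a mutant strain and comparing per-probe intensities in principle
reveals every single-base substitution — but probe signal depends strongly and
non-linearly on probe sequence, non-specific binding adds false signal, and
probes saturate. `tilecall` addresses this with an explicit thermodynamic
model of hybridization instead of empirical regression, and is aimed at
anyone analyzing (or simulating and benchmarking) two-sample tiling-array
resequencing experiments.

## The model

The log signal intensity of probe *p* is modeled by a finite-hybridization
(FH) isotherm that accounts for finite probe and target amounts, non-specific
binding, and probe self-folding:

```
I_p = A * (K_s + K_ns * C_ns) / (1 + K_f + K_s + K_ns * C_ns) + B,
K_x = exp(alpha * G_x)
```

where `G_s` and `G_ns` are position-weighted nearest-neighbor (triplet)
free energies of specific and non-specific binding,

```
G_s(p) = sum_{k=2..20} w_k * eps[triplet(p, k)],
```

`G_f` is a stem-loop self-folding energy, and `A`, `B`, `C_ns`, `alpha` are
global scalars. Each probe–target mismatch subtracts a penalty `delta(t, b)`
from `G_s`, indexed by the reference triplet context at the mismatch site and
the substituted base: an MM probe carries one designed mismatch, a PM probe
spanning a genuine substitution carries one, an MM probe spanning it
off-center carries two, and the MM probe whose central base equals the mutant
base becomes a perfect match. In total the model has **343 free parameters**
(64 + 64 specific/non-specific triplet energies, 192 penalties, 19 position
weights, 4 scalars), fitted to reference-sample intensities by a seeded
population search with a Levenberg–Marquardt polish.

Detection then works on mutant/reference log-intensity ratios: per genome
position the null residual `D_i` sums squared observed ratios over all
covering probes; candidate regions are runs where the running average of `D`
exceeds `theta_R = mean(D) + k*sd(D)` (10–79 bp runs are substitution
candidates, ≥ 80 bp runs are flagged structural/deletion-like and excluded);
within each candidate region the call maximizes the log-likelihood ratio
`L_i(b) = E_i(ref) − E_i(b)`, where `E_i(b)` is the residual against the
ratios predicted under the hypothesis "base *i* substituted to *b*", and is
emitted if it exceeds `theta_L`.

Because the original array data are not publicly deposited, the package ships
a first-class forward simulator (`simulate_dataset()`) producing seeded
genomes, ground-truth models, implanted substitutions/deletions, and
log-normally noised intensity tables, plus evaluation tools (truth filtering,
call matching, sensitivity curves, threshold calibration).

## Worked example

Simulate a two-sample experiment on a 10 kb circular genome with 5 implanted
substitutions and 5% log-normal noise, fit the model to the reference sample,
and call substitutions:

```r
library(tilecall)

cfg <- sim_config(genome_length = 10000, n_substitutions = 5,
                  min_spacing = 300, noise_sd = 0.05, seed = 17)
sim <- simulate_dataset(cfg)
sim$design
#> tiling_design: sim (10000 bp, circular), resolution 1 bp, mm_mode=all_three, 40000 probes

fc  <- fit_config(seed = 17, population_size = 16, generations = 25,
                  subset_fraction = 0.15)
fit <- fit_parameters(sim$design, sim$wt, fc, folding = sim$folding)
fit
#> fh_fit: objective 14.6568 after 25 generation(s) + LM polish (seed 17)

prof  <- residual_profile(fit$model, sim$design, sim$wt, sim$mut,
                          folding = sim$folding)
regs  <- screen_candidate_regions(prof)
best  <- region_max_llr(fit$model, sim$design, sim$wt, sim$mut, regs,
                        sim$folding)
theta <- best_threshold(threshold_curve(best, sim$truth, tol_bp = 2))
calls <- best[best$llr > theta]
calls[, c("position", "ref", "alt", "llr")]
#>    position    ref    alt      llr
#> 1:     1215      A      T 18.29246
#> 2:     1899      T      C 48.17389
#> 3:     4637      T      A 50.89038
#> 4:     5986      G      A 15.29264
#> 5:     8358      A      T 39.27469

match_calls(calls, sim$truth, tol_bp = 2)
#> evaluation_result: TP 5 / 5 (sensitivity 1.000), FP 0, FN 0; exact position 5, exact position+base 5
```

The fit objective (14.66 over 6,000 probes) sits at the noise floor
(≈ n·σ² = 6000·0.0025 = 15), and every implanted substitution is recovered at
its exact position and base with no false positives. Calls export to VCF
(`write_calls_vcf()`), structural regions to BED (`write_regions_bed()`).

A command-line interface with subcommands `design`, `simulate`, `fit`,
`call`, and `evaluate` is installed at `inst/cli/tilecall`.

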