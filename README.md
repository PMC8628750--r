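# circapanel

Circadian rhythmicity testing and damped-cosinor parameter estimation for
replicated qPCR time courses from synchronized cell cultures.

## The problem

After a serum shock synchronizes the cellular clocks in a culture, core
clock transcripts such as *BMAL1* (positive arm) and *PER2* (negative arm)
oscillate with a period near 24 h and, in healthy tissue, roughly 12 h
apart (anti-phase). Sampling every 4 h for 48 h with 5–6 biological
replicates per time point and quantifying by RT-qPCR gives short, noisy,
replicated series. Three questions follow:

1. **Is a series rhythmic at all?** No single test is reliable for short
   series, so `circapanel` runs a complementary battery: a Lomb–Scargle
   permutation test (max normalized power over periods 6–50 h, values
   shuffled across slots), a JTK-Cycle-style test (max tie-corrected
   Kendall τ against cosine templates over a period × phase grid), a
   RAIN-style umbrella test (max Mack–Wolfe statistic over candidate peak
   positions on the folded time grid; arbitrary waveforms, rank-based),
   and an ECHO-style bounded-period fit test (F-test of a damped cosine
   with period constrained to 24–32 h, after linear detrending).
2. **Do two conditions oscillate differently?** A robust-harmonic-
   regression differential test (DODR-style): after linear detrending,
   each condition gets a Huber M-estimated fit of
   `M + βc cos(2πt/T) + βs sin(2πt/T)`; the Wald quadratic form on
   `Δ(βc, βs)` is referred to χ²(2), or to an exact within-time-point
   label-permutation null.
3. **What are the circadian parameters?** Weighted nonlinear least squares
   of the damped cosine with linear baseline

   y(t) = A e^(−λt) cos(2π(t−θ)/τ) + m t + b

   with per-point weights 1/Var(time point), λ ∈ [−0.05, 0.05]
   (λ < 0 grows, λ > 0 damps), Wald 95% CIs, and an unweighted R² that may
   go negative (lack of fit). Derived metrics: peak time into each cycle
   (θ mod τ), baseline change (m × 48 h), envelope growth rate (−λ), and
   the peak-offset/anti-phase relationship between two genes.

Raw Ct tables are converted to relative expression by the 2^−ΔΔCt method
(reference gene, replicate-matched calibrator) and normalized to each
biological replicate's temporal mean. A synthetic-data generator emulates
the full design (including Ct-level tables and the n = 5 missingness of
the metastatic line) so the whole pipeline is testable end to end; presets
`"H16N2"`, `"21PT"`, `"21MT-1"` carry published parameter columns for a
breast-cancer progression panel.

## Worked example

```r
library(circapanel)

cfg <- analysis_config(preset = "H16N2", noise_sd = 0.05, seed = 11,
                       rhythm = rhythm_test_config(n_permutations = 1000))
res <- run_analysis(cfg)

subset(res$rhythm_results, gene == "BMAL1",
       select = c(method, statistic, p_value))
#>              method    statistic      p_value
#> 1     rain_umbrella    8.4909382 9.990010e-04
#> 2 lomb_scargle_perm   34.6259115 9.990010e-04
#> 3      jtk_template    0.8448083 9.990010e-04
#> 4          echo_fit 1752.5365337 6.636185e-71

res$parameter_table[1, c("Amplitude", "Period", "Phase", "R2")]
#>   Amplitude   Period    Phase       R2
#> 1 0.4356529 26.27749 11.60983 0.989943

res$phase_relationships
#>   cell_line gene_a gene_b offset_h mean_period antiphase
#> 1     H16N2  BMAL1   PER2 11.04742    26.31229      TRUE
```

All four battery members reject rhythmicity at their permutation floor
(p = 1/1001 ≈ 0.001) or far below; the fitted period (26.28 h), peak time
(11.61 h into each cycle) and the 11.05 h anti-phase offset recover the
generator's truth (period 26.546 h, peak 11.402 h, offset 10.9 h) from
data with 5% noise. `res$differential_results` holds the pairwise
DODR-style comparisons when several cell lines are analyzed.

Command line (same stages as subcommands):

```sh
Rscript inst/cli/circapanel.R simulate --preset H16N2 --noise-sd 0.05 --seed 7 --out out/
Rscript inst/cli/circapanel.R run --input out/panel.csv --seed 7 --out out/ --permutations 1000
```

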