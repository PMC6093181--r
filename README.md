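# refchip — reference-peak normalization for quantitative differential ChIP-seq

`refchip` normalizes two-condition ChIP-seq experiments in which occupancy
changes genome-wide — the regime where every read-depth-based normalization
fails. When a treatment removes most of a transcription factor's binding
(e.g. degradation of the estrogen receptor by a SERD), normalizing to total
or in-peak read counts redistributes the lost signal and makes unchanged
sites look induced. The fix is experimental: an internal standard of
**unchanged reference peaks**, obtained either from a *parallel-factor*
pull-down (a second antibody against an unaffected factor such as CTCF in
the same immunoprecipitation) or from a xenogeneic *spike-in*.

For reference peaks with control/treated replicate mean counts $x_i, y_i$,
the package fits the through-origin regression
$m = \sum_i x_i y_i / \sum_i x_i^2$ — the gradient that equals 1 when no
systematic bias exists — and applies the **normalization coefficient**
$c = 1/m$ to the treated counts, restoring a unit gradient exactly.
Alternatively, DESeq2-style size factors are estimated from the
reference-peak submatrix only. Corrected scalings feed a negative-binomial
Wald test per peak ($\log\mu_{ij} = \beta_0 + \beta_1\,\text{treated}_j +
\log s_j$) with Benjamini–Hochberg FDR control.

The package also provides peak-set algebra (species partitioning of
combined-genome calls, a 500 bp exclusion filter deriving clean reference
sets, consensus peaks), strand-aware 5'-end read counting from indexed BAM,
subsampling stability analysis of the coefficient, cross-normalization of
single-factor to parallel-factor experiments, and a synthetic-data
generator that reproduces the statistical structure the method assumes
(including the antibody-competition failure mode of cross-reacting
spike-ins). See the vignette in `vignettes/` for the model, assumptions and
design choices.

## Worked example

```r
library(refchip)

# a synthetic parallel-factor experiment: 2,000 target peaks (80% with true
# losses), 5,000 unchanged reference peaks, 3v3 replicates, and a 0.8x
# efficiency bias on the treated libraries
cfg <- simulation_config(n_target_peaks = 2000, n_control_peaks = 5000,
                         n_spikein_peaks = 0, true_treated_scaling = 0.8,
                         fraction_changed = 0.8, seed = 42)
sim <- generate_experiment(cfg)
ctrl <- sim$truth$name[sim$truth$channel == "control"]

fit <- normalization_coefficient(sim$counts, ctrl, sim$samples,
                                 c("control", "treated"))
print(fit)
#> refchip normalization coefficient (linear space)
#>   gradient m = 0.781315  coefficient c = 1/m = 1.27989
#>   control peaks: 5000   residual SE: 19.8

res <- differential_pipeline(sim$counts, ctrl, sim$samples,
                             c("control", "treated"),
                             normalization_mode = "control_size_factors")
```

The gradient below 1 is the efficiency bias seen through the reference
peaks (true value 0.8); `c` is the correction that restores gradient 1.
The pipeline tests the 2,000 target peaks only (reference peaks are
excluded by construction): it recovers 98.1% of the true losses at
FDR < 0.05, and among the 400 truly unchanged target peaks it miscalls 12,
versus 24 under library-total normalization of the same data — with
stronger contrasts between the modes the larger the bias.

A command-line interface wrapping the same functions is installed at
`exec/refchip` (`refchip simulate | peaks | normalize | test | stability`);
run it with `Rscript $(Rscript -e 'cat(system.file("exec", "refchip",
package = "refchip"))') <subcommand> ...`.

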