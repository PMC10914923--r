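# sangeredit

Quantitative targeted RNA-editing analysis from Sanger chromatograms.

In TRIBE/HyperTRIBE-style assays an RNA-binding protein is fused to a
deaminase — an ADAR catalytic domain (A→I, read as A→G) or an APOBEC
(C→U, read as C→T) — so that RNAs bound by the protein acquire editing
marks. For a single reporter or transcript the readout is simple and cheap:
RT-PCR the region, Sanger sequence it, and quantify the editing level at
every substrate position from the trace. `sangeredit` is that readout as a
reproducible pipeline, for molecular biologists running such assays and for
anyone who needs defensible editing percentages out of AB1 files.

## The statistic

At each candidate adenosine the relative editing is the peak-area ratio

    e = area(G) / (area(A) + area(G))        (T/(C+T) in C→T mode)

computed per biological replicate. The per-position mean of negative-control
replicates (b̄) is subtracted from each sample replicate, giving corrected
values with mean c̄ and across-replicate sample SD s_c. A site is called
significant only if **both**

1. `c̄ − 3·s_c > 0` — corrected editing more than three SDs above zero, and
2. `r̄ ≥ 2·b̄` — uncorrected sample mean at least twice the control mean
   (reduces to `r̄ > 0` when the control mean is numerically zero).

The package also covers the two companion quantifications — calibration of
peak-ratio linearity from template mixing series (OLS slope/intercept/r²)
and the CAPS restriction assay (cleaved fraction from Bioanalyzer band
tables, Welch two-tailed t between groups) — plus a synthetic chromatogram
generator with known ground-truth editing that makes the whole pipeline
testable end to end.

## Worked example

Simulate a 4-vs-4 replicate experiment on a 20-nt amplicon with true
editing 0.6 at position 7 and 0.3 at position 12, then run the full caller:

```r
library(sangeredit)
ref <- "CATCTCATCTCATCTCATCT"
ex  <- simulate_experiment(ref,
                           edits = data.frame(position = c(7, 12),
                                              fraction = c(0.6, 0.3)),
                           n_sample = 4, n_control = 4, seed = 5)
run <- call_editing(ex$sample, ex$control, ref)
run$results[, c("ref_position", "raw_mean", "control_mean",
                "corrected_mean", "corrected_sd", "significant")]
#>    ref_position   raw_mean control_mean corrected_mean corrected_sd significant
#> 2             2 0.01682578   0.01703245  -0.0002066736  0.003043448       FALSE
#> 7             7 0.59872009   0.01588691   0.5828331799  0.009228508        TRUE
#> 12           12 0.31574906   0.02063875   0.2951103136  0.016629116        TRUE
#> 17           17 0.01706049   0.01734289  -0.0002823979  0.001335668       FALSE
run$summary$n_significant
#> [1] 2
```

The two truly edited positions are recovered close to their true fractions
(0.583 and 0.295 after background correction) and are the only significant
calls; the unedited positions show the ~1.7% crosstalk/noise background
that control subtraction removes. `plot_editing_profile(run$results)` draws
the per-position editing profile with significant sites highlighted, and
`write_results()` / `write_run_summary()` export the TSV and JSON shown
above.

External data enter the same pipeline: `read_ab1()` for AB1 traces,
`read_peak_table()` for exported peak-area (or precomputed-ratio)
worksheets with remappable column names, `read_band_table()` for
Bioanalyzer CSVs.

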