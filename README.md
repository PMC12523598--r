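# bracketqc

Risk-based multistage statistical quality control (SQC) design for
high-throughput clinical laboratories.

Laboratories running in continuous mode report patient results under
*bracketed* internal QC: a run of patient samples becomes final only
when the QC event closing it passes. The design problem is to choose,
per measurement procedure and analyzer, (i) how many patient samples
may sit between QC events and (ii) which Westgard control rule closes
each bracket, so that quality assurance is guaranteed without wasting
control measurements on methods that do not need them. `bracketqc` is
aimed at clinical chemists and laboratory statisticians who want that
chain reproducible and testable instead of spreadsheet-bound.

## The model

For each control level, bias and imprecision in percent give the sigma
metric at an allowable total error TEa:

    SE% = (observed mean − target) / target × 100
    σ   = (TEa − |SE|) / CV

Control rules are evaluated on standardized deviations; under a
persistent shift Δ (SD units) a single rule with limit k rejects an
event of N controls with probability 1 − (1 − p)^N where
p = 1 − Φ(k − Δ) + Φ(−k − Δ). The critical shift of a σ-sigma
procedure is Δ_crit = σ − 1.65 (defect rate 5%).

A patient result is unreliable when its total error exceeds TEa, with
probability dpE(σ, Δ) = 1 − Φ(σ − Δ) + Φ(−σ − Δ). With run size n,
per-event detection probability P = Ped(Δ) and q = 1 − P, the expected
number of unreliable *final* results per error episode is

    E(Nuf) = dpE(σ, Δ) · n · (q/2 + q²/P)

(uniform error onset, bracketed release; see the vignette for the
accounting convention and its simulator validation). Maximizing over Δ
and bounding Max E(Nuf) ≤ 1 yields the largest safe run size per rule
and sigma — the run-size nomogram. Multistage plans pair a **startup**
rule (brackets a daily workload, Ped ≥ 0.9 at Δ_crit) with a
**monitor** rule (brackets one run, Pfr ≤ 0.05), and per-analyzer
consolidation reduces the plan zoo to one general plan plus
individualized plans for the lower-sigma parameters.

## Worked example

A procedure at sigma 5 with a daily workload of 200 samples:

```r
library(bracketqc)
wl <- categorize_workload(200)
#> Workload 200/day -> run size 50, category C
startup <- design_startup(5, wl)
monitor <- design_monitor(5, wl)
c(startup = startup$label, monitor = monitor$label)
#>   startup   monitor
#> "1_2s N1" "1_3s N1"
rejection_probability(startup, critical_shift(5))
#> [1] 0.9114921
false_rejection_probability(monitor)
#> [1] 0.002699796
max_run_size(startup, 5)
#> [1] 381
```

The 2.0-SD single rule detects the critical shift (3.35 SD) with
probability 0.91 and its risk-bounded run size (381) covers the whole
daily workload, so it qualifies as startup; the 3.0-SD rule monitors
with a 0.27% false-rejection rate. Together they form plan 3 of the
catalogue (`plan_catalogue()`). The risk profile behind the bound:

```r
max_enuf(qc_rule("1_2.5s", 1), 6, 250)
#> Max E(Nuf) = 0.2196 at shift 4.13 SD (rule 1_2.5s N1, sigma 6, run size 250)
```

End to end, from IQC summaries to consolidated plans:

```r
fx  <- generate_lab_fixture(seed = 22, n_analyzers = 2, n_parameters = 6)
out <- run_pipeline(fx$iqc, fx$tea, fx$workload, out_dir = "qc_out")
out$summary$sigma_band_counts
#>   analyzer <4 4-5 5-6 >=6
#> 1      an1  2   0   3   1
#> 2      an2  0   0   1   2
```

The package also ships a transcribed six-analyzer example-laboratory
dataset (`lab_sigma_fixture()`, `lab_plan_fixture()`); consolidating
its plan table reproduces the adopted configuration, e.g.:

```r
consolidate_all(lab_plan_fixture())[["Alinity c2"]]
#> Alinity c2: general plan 2 (21 parameters)
#>   individualized plan 5: Creatinine
#>   individualized plan 6: GGT, Total Protein
#>   uncovered (sigma < 4): Chloride, Sodium
```

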