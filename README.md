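# ritfit

Quantifying pod shatter resistance in Brassica from Random Impact Test
(RIT) assays.

Premature pod opening (shatter) causes substantial seed loss in oilseed
rape. The RIT measures a genotype's resistance: 20 dry fruits are shaken
with steel balls in 8-second bursts and the number of intact pods is
counted after each burst, in triplicate assays per genotype. `ritfit`
turns those interval counts into a single resistance phenotype — the
**RIT₅₀ half-life** — and compares genotypes against a wild-type
reference.

## Model

For one assay with N₀ pods, the intact count over cumulative shaking
time t is fitted with the two-parameter exponential decay

    count(t) = A · exp(−b · t)

by unweighted nonlinear least squares (A ≈ N₀ is the intercept, b the
decay rate in 1/s). The RIT₅₀ is the time at which half the *initial*
pods have shattered, read off the fitted curve:

    RIT₅₀ = ln(2A / N₀) / b

Its standard error comes from first-order error propagation (the delta
method) with gradient g = (1/(Ab), −RIT₅₀/b) applied to the parameter
covariance. Because the same pods are re-inspected at every interval,
the counts are strongly correlated; the default covariance therefore
propagates the binomial-survival covariance of the count process
through the linearized fit (a sandwich estimator), which a parametric
bootstrap confirms is calibrated (see the methods vignette). Replicate
RIT₅₀ values are averaged per genotype and compared to the reference
with a two-sample t-test, reported with fold changes and the usual
significance stars (\*p < 0.05, \*\*p < 0.01, \*\*\*p < 0.001).

A stochastic simulator (exponential pod break-times observed as
interval counts, marginally Binomial(N₀, e^(−bt))) makes the whole
pipeline testable without lab data.

## Worked example

```r
library(ritfit)

# a wild type (true RIT50 = 10 s) and a 2.5x more resistant mutant,
# in protocol triplicates of 20 pods on an 8-s grid
sims <- list(sim_config("WT",  true_half_life_s = 10, seed = 1),
             sim_config("mut", true_half_life_s = 25, seed = 1))
ds  <- simulate_dataset(sims, reference = "WT")

res  <- estimate_half_lives(ds)          # fit + RIT50 per assay
sums <- summarize_all_genotypes(res$table)
rank_genotypes(sums, reference = "WT")
```

```
  genotype n_reps mean_rit50_s  se_s diff_s fold_change p_value p_holm stars
1      mut      3        25.95 3.134  14.49       2.263  0.0161 0.0161     *
2       WT      3        11.47 1.810   0.00       1.000      NA     NA
```

One row per genotype, ranked by mean RIT₅₀ (seconds): the mutant's
pods survive shaking about 2.3× longer than wild type (true ratio
2.5), and the difference is significant at the 5% level (`p_holm` is
the Holm-adjusted p-value across all non-reference genotypes). Per
assay, `half_life()` additionally reports a delta-method confidence
interval, e.g.

```r
half_life(fit_decay(ds$assays[[1]]))
#> <half_life_estimate> WT/r1: RIT50 = 14.51 s (se 3.415, 95% CI [7.8161, 21.203])
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/ritfit.R` with subcommands `simulate`, `fit` and `compare`
(see `?cmd_fit`; outputs are plain CSV tables plus a JSON run
manifest).

## Acceptance script

`scripts/acceptance.R` re-runs the complete simulate → fit → compare
chain from scratch at a given seed — generating triplicate assays for
a wild type and a 2.5× resistant mutant, fitting every assay, and
printing the ranked genotype comparison — then writes its JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
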