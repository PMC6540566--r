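# groupedscore

Efficient score tests for **grouped failure-time phenotypes** — outcomes
observed only up to a treatment cycle, dose step, or assessment interval.
Drug toxicities reported by cycle, IC50s bracketed by a dose grid and
tumours found between screening visits are all grouped failure times, and
treating them as tied continuous times (Breslow/Efron corrections in a
Cox model) can attenuate effect estimates badly. This package is for
statistical geneticists and biostatisticians who want genome-wide
variant, gene, or pathway association analysis on such phenotypes with
proper discrete-time likelihood inference.

## The model and the statistic

Time is split into `r` intervals `[t_{j-1}, t_j)`. With `alpha_j` the
baseline probability of surviving interval `j` and
`w_i = exp(x_i beta + z_i' theta)` the subject's relative risk, each
record — interval index `k_i`, event flag `delta_i` — contributes

    L_i = (1 - alpha_{k_i}^{w_i})^{delta_i} * prod_{j < k_i} alpha_j^{w_i}.

The nuisance parameters `eta = (alpha, theta)` are estimated **once**
under the null `beta = 0` (Newton on the complementary log-log scale,
initialized at the closed-form life-table estimate). Each variant is then
tested with the partitioned efficient score statistic

    W = (sum_i S_beta,i(0, eta-hat))^2
        / [ n ( I_bb - I_bn I_nn^{-1} I_bn' ) ]  ~  chi-square(1),

so a genome-wide scan costs one null fit plus `O(n(q+r))` per variant.
Per-variant effect sizes are joint MLEs with observed-information
standard errors; Bonferroni-adjusted p-values and Storey q-values are
attached; per-sample score contributions feed kernel (SKAT-type)
gene/pathway statistics with exact chi-square-mixture p-values. A
simulator and an operating-characteristics harness reproduce the
type-I-error, bias and power study design. See the vignette
(`vignettes/grouped-failure-time-scans.Rmd`) for the full account.

## A worked example

```r
library(groupedscore)

# a 500-subject cohort, six cycles, one causal variant (beta = 0.6),
# censoring calibrated to a 60% event rate
cfg <- sim_config(n = 500, beta = 0.6, maf = 0.3,
                  target_event_rate = 0.6, seed = 42)
sim <- simulate_grouped(cfg)

fit <- fit_null(sim$data)
fit
#> <grouped_null_fit> n = 500, 4 free interval(s), 2 covariate(s)
#>   loglik -319.7423; converged in 5 iteration(s), |score| = 5.68e-14

G <- cbind(causal = sim$x,
           sapply(1:4, function(j) rbinom(500, 2, 0.25)))
colnames(G)[2:5] <- paste0("null", 1:4)
rownames(G) <- sim$data$sample_id

scan_variants(sim$data, G, fit = fit, beta_est = TRUE)
#> # A tibble: 5 x 9
#>   variant_id     n   maf   stat      pvalue      fwer_p   qvalue beta_hat status
#> 1 causal       500 0.29  27.2   0.000000185 0.000000925  9.25e-7   0.491  ok
#> 2 null1        500 0.258  0.205 0.651       1            6.51e-1   0.0462 ok
#> 3 null2        500 0.242  0.399 0.528       1            6.51e-1   0.0630 ok
#> 4 null3        500 0.267  1.48  0.224       1            3.73e-1  -0.123  ok
#> 5 null4        500 0.231  1.57  0.211       1            3.73e-1   0.123  ok
```

The causal variant is recovered at `p = 1.9e-7` (Bonferroni `9.2e-7`)
with `beta_hat = 0.49` (the MLE of the log hazard ratio per dosage copy;
the truth is 0.6, within one standard error here), while the four null
variants sit on the null distribution. `autoplot(scan)` draws the QQ
plot; `gene_set_stats()` aggregates scan contributions over gene sets;
`read_genotypes()` ingests TSV, PLINK BED, or VCF dosages; and the thin
CLI under `inst/cli/groupedscore` exposes `scan`, `simulate`, `opchar`
and `genestat` subcommands for shell pipelines.

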